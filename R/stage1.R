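# Stage 1: SNP -> imputed-IDP weight matrices from summary statistics.
# Marginal GWAS z-scores are converted to standardized marginal regression
# coefficients and turned into joint weights through the inverse LD matrix;
# LD clumping thins the instrument set per IDP and an F-test screens gene-IDP
# pairs for instrument strength.

#' Convert a marginal GWAS z-score to a standardized regression coefficient
#'
#' `beta = z / sqrt(n - 2 + z^2)`, the sample correlation implied by the Wald
#' t/z statistic of a simple linear regression on a standardized predictor.
#'
#' @param z marginal z-score(s).
#' @param n GWAS sample size(s), `n >= 3`; recycled against `z`.
#' @return standardized marginal coefficient(s), strictly inside (-1, 1).
#' @export
z_to_marginal_beta <- function(z, n) {
  if (any(n < 3)) stop("sample size n must be >= 3")
  z / sqrt(n - 2 + z^2)
}

#' Ridge term for an ill-conditioned LD matrix
#'
#' Returns 0 when the condition number of `R` is below `cond_max`, otherwise
#' `0.001 * mean(diag(R))`.
#'
#' @param R LD (correlation) matrix.
#' @param cond_max condition-number threshold triggering regularization.
#' @return nonnegative scalar ridge term.
#' @export
default_ridge <- function(R, cond_max = 1e8) {
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  cond <- if (min(ev) <= 0) Inf else max(ev) / min(ev)
  if (cond > cond_max) 0.001 * mean(diag(R)) else 0
}

#' Joint SNP weights from marginal coefficients and LD
#'
#' Solves `(R + ridge_eps * I) w = b`. With `ridge_eps = 0` this is the exact
#' multiple-regression coefficient vector implied by the marginal coefficients
#' under the panel LD.
#'
#' @param b numeric vector (or J x K matrix, one column per IDP) of
#'   standardized marginal coefficients, in the SNP order of `ld`.
#' @param ld LD correlation matrix over the same SNPs.
#' @param ridge_eps nonnegative ridge added to the diagonal (default 0).
#' @return weight vector (or matrix) of the same shape as `b`.
#' @export
joint_weights <- function(b, ld, ridge_eps = 0) {
  was_vector <- is.null(dim(b))
  b <- as.matrix(b)
  if (nrow(b) != nrow(ld))
    stop("dimension mismatch: length(b) = ", nrow(b), ", nrow(ld) = ", nrow(ld))
  if (ridge_eps < 0) stop("ridge_eps must be nonnegative")
  A <- as.matrix(unclass(ld))
  if (ridge_eps > 0) diag(A) <- diag(A) + ridge_eps
  w <- tryCatch(solve(A, b), error = function(e) {
    stop("LD matrix is numerically singular; supply a positive ridge_eps ",
         "(e.g. default_ridge(ld))", call. = FALSE)
  })
  if (was_vector) w <- drop(w)
  w
}

#' Greedy LD clumping
#'
#' Repeatedly keeps the remaining SNP with the smallest p-value (ties broken by
#' smaller genomic position) and removes all remaining SNPs within `radius_bp`
#' whose squared correlation with it exceeds `r2_cutoff`. P-values are the
#' two-sided normal tail of the z-scores.
#'
#' @param table a `gwas_table` carrying `snp_id, pos, z`.
#' @param ld LD matrix covering (at least) the table's SNPs.
#' @param radius_bp clump radius in base pairs (default 1 Mb).
#' @param r2_cutoff squared-correlation threshold (default 0.5; SNPs with
#'   `r^2 > r2_cutoff` to an index SNP are clumped away).
#' @return character vector of kept SNP ids in genomic order.
#' @export
ld_clump <- function(table, ld, radius_bp = 1e6, r2_cutoff = 0.5) {
  ids <- table$snp_id
  if (!all(ids %in% rownames(ld)))
    stop("SNP(s) missing from LD matrix: ",
         paste(setdiff(ids, rownames(ld)), collapse = ", "))
  p <- 2 * stats::pnorm(-abs(table$z))
  pos <- table$pos
  R2 <- as.matrix(unclass(ld))[ids, ids, drop = FALSE]^2
  unclumped <- rep(TRUE, length(ids))
  kept <- logical(length(ids))
  while (any(unclumped)) {
    cand <- which(unclumped)
    idx <- cand[order(p[cand], pos[cand])][1]
    kept[idx] <- TRUE
    unclumped[idx] <- FALSE
    prune <- unclumped & abs(pos - pos[idx]) <= radius_bp & R2[idx, ] > r2_cutoff
    unclumped[prune] <- FALSE
  }
  ids[kept][order(pos[kept])]
}

#' Merge per-IDP clump-retained SNP sets
#'
#' Set union of the per-IDP kept SNP ids, returned in genomic order.
#'
#' @param per_idp_keeps list of character vectors of SNP ids.
#' @param positions named integer vector of genomic positions (names = SNP ids)
#'   used for ordering.
#' @return character vector, the union in genomic order.
#' @export
merge_clump_sets <- function(per_idp_keeps, positions) {
  ids <- unique(unlist(per_idp_keeps, use.names = FALSE))
  if (!length(ids)) return(character(0))
  miss <- setdiff(ids, names(positions))
  if (length(miss)) stop("position missing for: ", paste(miss, collapse = ", "))
  ids[order(positions[ids])]
}

#' Gene-IDP instrument-strength screen
#'
#' Reconstructs the joint-model coefficient of determination from summary
#' statistics, `R2 = b' R^{-1} b` (clipped to [0, 0.999999]), forms the overall
#' F statistic `F = (R2/J) / ((1-R2)/(n-J-1))` and its upper-tail p-value on
#' `(J, n-J-1)` degrees of freedom, and keeps the pair when `p < p_threshold`.
#'
#' @param b standardized marginal coefficients over the gene's SNPs.
#' @param ld LD matrix over the same SNPs, same order.
#' @param n GWAS sample size; must satisfy `J < n - 1`.
#' @param p_threshold retention threshold (default 5e-5).
#' @param ridge_eps ridge used in the joint solve (default [default_ridge()]).
#' @return list with `keep` (logical), `p` (F-test p-value), `r2`, `f_stat`.
#' @export
gene_idp_screen <- function(b, ld, n, p_threshold = 5e-5,
                            ridge_eps = default_ridge(ld)) {
  J <- length(b)
  if (J >= n - 1) stop("need J < n - 1 for the F-test screen (J = ", J,
                       ", n = ", n, ")")
  r2 <- sum(b * joint_weights(b, ld, ridge_eps))
  r2 <- min(max(r2, 0), 0.999999)
  f <- (r2 / J) / ((1 - r2) / (n - J - 1))
  p <- stats::pf(f, J, n - J - 1, lower.tail = FALSE)
  list(keep = p < p_threshold, p = p, r2 = r2, f_stat = f)
}

#' Default Stage-1 configuration
#'
#' @param clump_radius_bp clumping radius in base pairs.
#' @param clump_r2 clumping squared-correlation cutoff.
#' @param screen_p gene-IDP F-test retention threshold.
#' @param clump,screen logical switches for the clumping and screening steps
#'   (both on in the real-data pipeline; simulation experiments disable them).
#' @param ridge_cond_max condition-number threshold for the automatic ridge.
#' @return a named list of configuration values.
#' @export
stage1_config <- function(clump_radius_bp = 1e6, clump_r2 = 0.5,
                          screen_p = 5e-5, clump = TRUE, screen = TRUE,
                          ridge_cond_max = 1e8) {
  list(clump_radius_bp = clump_radius_bp, clump_r2 = clump_r2,
       screen_p = screen_p, clump = clump, screen = screen,
       ridge_cond_max = ridge_cond_max)
}

#' Build per-modality Stage-1 weight matrices for one gene
#'
#' For each IDP: clump its windowed GWAS table; merge the per-IDP kept SNP sets
#' into a single gene-level SNP set; convert z-scores to marginal coefficients
#' on the merged set; solve the joint weights through the LD matrix; and apply
#' the F-test screen. Screened-out IDPs contribute no column. SNPs absent from
#' an IDP's table receive weight 0 in its column.
#'
#' @param idp_tables named list of `gwas_table`s (one per IDP), already
#'   harmonized to the panel alleles and windowed to the gene.
#' @param ld LD matrix covering the union of the tables' SNPs.
#' @param modality_map named character vector, IDP id -> modality label.
#' @param config list from [stage1_config()].
#' @return named list of weight matrices, one per modality present in
#'   `modality_map`: each has `snp_ids` x kept-IDP matrix `W` plus attributes
#'   `screen_p` (per-IDP screen p-values) and `modality`. Modalities with no
#'   surviving IDP get a zero-column matrix.
#' @export
build_weight_matrix <- function(idp_tables, ld, modality_map,
                                config = stage1_config()) {
  if (is.null(names(idp_tables)) || any(names(idp_tables) == ""))
    stop("idp_tables must be a named list (names = IDP ids)")
  unmapped <- setdiff(names(idp_tables), names(modality_map))
  if (length(unmapped))
    stop("IDP(s) missing from modality map: ", paste(unmapped, collapse = ", "))

  positions <- do.call(rbind, lapply(idp_tables, function(t)
    data.frame(snp_id = t$snp_id, pos = t$pos)))
  positions <- positions[!duplicated(positions$snp_id), ]
  posv <- stats::setNames(positions$pos, positions$snp_id)

  keeps <- lapply(idp_tables, function(tab) {
    if (isTRUE(config$clump))
      ld_clump(tab, ld, config$clump_radius_bp, config$clump_r2)
    else tab$snp_id
  })
  merged <- merge_clump_sets(keeps, posv)
  if (!length(merged)) stop("no SNPs available after clumping")
  R <- as.matrix(unclass(ld))[merged, merged, drop = FALSE]
  ridge <- default_ridge(R, config$ridge_cond_max)

  cols <- lapply(names(idp_tables), function(id) {
    tab <- idp_tables[[id]]
    present <- merged[merged %in% tab$snp_id]
    row <- match(present, tab$snp_id)
    b <- z_to_marginal_beta(tab$z[row], tab$n[row])
    Rsub <- R[present, present, drop = FALSE]
    w <- joint_weights(b, Rsub, default_ridge(Rsub, config$ridge_cond_max))
    scr <- if (isTRUE(config$screen))
      gene_idp_screen(b, Rsub, stats::median(tab$n[row]), config$screen_p)
    else list(keep = TRUE, p = NA_real_)
    full <- stats::setNames(numeric(length(merged)), merged)
    full[present] <- w
    list(w = full, keep = scr$keep, p = scr$p)
  })
  names(cols) <- names(idp_tables)

  out <- list()
  for (mod in unique(modality_map[names(idp_tables)])) {
    ids <- names(idp_tables)[modality_map[names(idp_tables)] == mod]
    kept_ids <- ids[vapply(cols[ids], `[[`, logical(1), "keep")]
    dropped <- setdiff(ids, kept_ids)
    if (length(dropped))
      message("modality ", mod, ": ", length(dropped),
              " IDP(s) removed by the instrument-strength screen: ",
              paste(dropped, collapse = ", "))
    W <- matrix(0, length(merged), length(kept_ids),
                dimnames = list(merged, kept_ids))
    for (id in kept_ids) W[, id] <- cols[[id]]$w
    attr(W, "modality") <- mod
    attr(W, "screen_p") <- vapply(cols[ids], `[[`, numeric(1), "p")
    out[[mod]] <- W
  }
  out
}
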