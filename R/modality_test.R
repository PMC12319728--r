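# The modality-level score test. For a tested modality with Stage-1 weight
# matrix A1 and an adjustment matrix A2 (imputed IDPs of the other modalities
# plus, optionally, an all-ones burden column absorbing residual direct genetic
# effects), the score vector and its null covariance are, in summary form,
#
#   S      = A1'z - A1' R A2 (A2' R A2)^{-1} A2' z
#   Cov(S) = A1' R A1 - A1' R A2 (A2' R A2)^{-1} A2' R A1
#
# with z the disease GWAS z-scores and R the SNP LD matrix. The statistic
# T = S'S follows a mixture of 1-df chi-squares with weights the eigenvalues
# of Cov(S) under the null of no effect through the tested modality.

.as_plain_matrix <- function(x) {
  x <- as.matrix(unclass(x))
  storage.mode(x) <- "double"
  x
}

# Cross-products needed by both S and Cov(S); drops collinear adjustment
# columns by rank-revealing QR on A2'RA2 and records which were dropped.
.score_core <- function(A1, A2, R, z) {
  A1 <- .as_plain_matrix(A1)
  R <- .as_plain_matrix(R)
  J <- nrow(R)
  if (nrow(A1) != J) stop("A1 and ld cover different SNP counts")
  if (length(z) != J) stop("z and ld cover different SNP counts")
  dropped <- character(0)
  if (is.null(A2) || (!is.null(dim(A2)) && ncol(A2) == 0)) {
    A2 <- NULL
  } else {
    A2 <- .as_plain_matrix(A2)
    if (nrow(A2) != J) stop("A2 and ld cover different SNP counts")
    M <- crossprod(A2, R %*% A2)
    qa <- qr(M)
    if (qa$rank < ncol(A2)) {
      keep <- sort(qa$pivot[seq_len(qa$rank)])
      ids <- colnames(A2)
      if (is.null(ids)) ids <- paste0("adj", seq_len(ncol(A2)))
      dropped <- ids[-keep]
      warning("dropped ", length(dropped), " collinear adjustment column(s): ",
              paste(dropped, collapse = ", "), call. = FALSE)
      A2 <- A2[, keep, drop = FALSE]
    }
  }
  RA1 <- R %*% A1
  if (is.null(A2)) {
    S <- drop(crossprod(A1, z))
    covS <- crossprod(A1, RA1)
  } else {
    RA2 <- R %*% A2
    M <- crossprod(A2, RA2)
    X <- solve(M, cbind(crossprod(A2, z), crossprod(RA2, A1)))
    A1RA2 <- crossprod(A1, RA2)
    S <- drop(crossprod(A1, z)) - drop(A1RA2 %*% X[, 1])
    covS <- crossprod(A1, RA1) - A1RA2 %*% X[, -1, drop = FALSE]
  }
  covS <- (covS + t(covS)) / 2
  list(S = S, cov_S = covS, dropped = dropped)
}

#' Score vector of the modality-level test
#'
#' `S = A1'z - A1' R A2 (A2' R A2)^{-1} A2' z`; with no adjustment columns this
#' reduces to `A1'z`.
#'
#' @param A1 J x K1 weight matrix of the tested modality.
#' @param A2 J x K2 adjustment matrix (other-modality weights and/or the
#'   all-ones burden column), or `NULL` for no adjustment.
#' @param ld J x J LD matrix.
#' @param z length-J disease GWAS z-score vector, in the same SNP order.
#' @return numeric score vector of length K1.
#' @export
score_vector <- function(A1, A2, ld, z) {
  .score_core(A1, A2, ld, z)$S
}

#' Null covariance of the score vector
#'
#' `Cov(S) = A1' R A1 - A1' R A2 (A2' R A2)^{-1} A2' R A1`, symmetrized;
#' positive semi-definite up to numerical noise (eigenvalues within `-1e-8`
#' are clipped to zero downstream).
#'
#' @inheritParams score_vector
#' @return symmetric K1 x K1 matrix.
#' @export
cov_score <- function(A1, A2, ld) {
  .score_core(A1, A2, ld, rep(0, nrow(.as_plain_matrix(ld))))$cov_S
}

#' Modality test statistic
#'
#' `T = S'S`, the squared Euclidean norm of the score vector.
#'
#' @param S score vector.
#' @return nonnegative scalar.
#' @export
test_statistic <- function(S) sum(S^2)

.eigen_weights <- function(covS) {
  ev <- eigen(covS, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8))
    warning("score covariance has eigenvalue ", min(ev),
            " below -1e-8; clipping", call. = FALSE)
  pmax(ev, 0)
}

# Assemble the A2 adjustment matrix from the non-tested weight matrices and
# the burden column. `weights` is a named list of J x K matrices over a common
# SNP set.
.assemble_adjustment <- function(weights, tested_modality, snp_ids,
                                 adjust_other, adjust_direct) {
  blocks <- list()
  if (adjust_other) {
    for (mod in setdiff(names(weights), tested_modality)) {
      W <- weights[[mod]]
      if (ncol(W) > 0) {
        colnames(W) <- paste(mod, colnames(W), sep = ":")
        blocks[[length(blocks) + 1L]] <- W
      }
    }
  }
  if (adjust_direct)
    blocks[[length(blocks) + 1L]] <-
      matrix(1, length(snp_ids), 1, dimnames = list(snp_ids, "direct_burden"))
  if (!length(blocks)) NULL else do.call(cbind, blocks)
}

#' Modality-level score test for one gene
#'
#' Assembles the tested modality's weight matrix A1 and the adjustment matrix
#' A2 (other modalities' weights if `adjust_other`, plus an all-ones burden
#' column if `adjust_direct`), computes the score vector, its null covariance
#' and eigenvalues, the statistic `T = S'S`, and the mixture chi-square
#' p-value.
#'
#' @param weights named list of Stage-1 weight matrices (one per modality) over
#'   a common SNP set, as returned by [build_weight_matrix()].
#' @param z_disease disease GWAS z-scores, named by SNP id or in the weight
#'   matrices' SNP order.
#' @param ld LD matrix over the same SNPs.
#' @param tested_modality name of the modality under test.
#' @param gene_id identifier recorded in the result.
#' @param adjust_other adjust for the genetically imputed IDPs of the other
#'   modalities (default `TRUE`).
#' @param adjust_direct adjust for residual direct genetic effects via the
#'   all-ones burden column (default `TRUE`).
#' @param p_method p-value method passed to [mixture_chisq_pvalue()].
#' @param mc_draws,seed Monte Carlo controls for [mixture_chisq_pvalue()].
#' @return an object of class `miwas_test`: a list with `gene_id, modality,
#'   T, p_value, K1, n_snps, p_method, mc_draws, S, cov_S, eigenvalues,
#'   adjust_other, adjust_direct, dropped_adjust`. A modality with zero
#'   surviving IDP columns yields a no-test result (`T` and `p_value` `NA`).
#' @export
modality_test <- function(weights, z_disease, ld, tested_modality,
                          gene_id = NA_character_,
                          adjust_other = TRUE, adjust_direct = TRUE,
                          p_method = "auto", mc_draws = 1e6, seed = NULL) {
  if (!tested_modality %in% names(weights))
    stop("tested modality ", tested_modality, " not among weight matrices")
  A1 <- weights[[tested_modality]]
  snp_ids <- rownames(A1)
  z <- .align_z(z_disease, snp_ids)
  if (ncol(A1) == 0) {
    message("gene ", gene_id, ": modality ", tested_modality,
            " has no surviving IDPs; no test performed")
    res <- list(gene_id = gene_id, modality = tested_modality, T = NA_real_,
                p_value = NA_real_, K1 = 0L, n_snps = length(snp_ids),
                p_method = "no_test", mc_draws = NA_real_, S = numeric(0),
                cov_S = matrix(0, 0, 0), eigenvalues = numeric(0),
                adjust_other = adjust_other, adjust_direct = adjust_direct,
                dropped_adjust = character(0))
    class(res) <- "miwas_test"
    return(res)
  }
  A2 <- .assemble_adjustment(weights, tested_modality, snp_ids,
                             adjust_other, adjust_direct)
  core <- .score_core(A1, A2, ld, z)
  lam <- .eigen_weights(core$cov_S)
  Tstat <- test_statistic(core$S)
  pv <- mixture_chisq_pvalue(Tstat, lam, method = p_method,
                             mc_draws = mc_draws, seed = seed)
  res <- list(gene_id = gene_id, modality = tested_modality, T = Tstat,
              p_value = pv$p, K1 = ncol(A1), n_snps = length(snp_ids),
              p_method = pv$method,
              mc_draws = if (!is.null(pv$mc_draws)) pv$mc_draws else NA_real_,
              S = core$S, cov_S = core$cov_S, eigenvalues = lam,
              adjust_other = adjust_other, adjust_direct = adjust_direct,
              dropped_adjust = core$dropped)
  class(res) <- "miwas_test"
  res
}

.align_z <- function(z, snp_ids) {
  if (inherits(z, "gwas_table") || is.data.frame(z)) {
    idx <- match(snp_ids, z$snp_id)
    if (anyNA(idx)) stop("disease GWAS missing SNP(s): ",
                         paste(snp_ids[is.na(idx)], collapse = ", "))
    return(z$z[idx])
  }
  if (!is.null(names(z))) {
    idx <- match(snp_ids, names(z))
    if (anyNA(idx)) stop("z vector missing SNP(s): ",
                         paste(snp_ids[is.na(idx)], collapse = ", "))
    return(unname(z[idx]))
  }
  if (length(z) != length(snp_ids))
    stop("unnamed z vector has wrong length")
  z
}

#' @export
print.miwas_test <- function(x, ...) {
  cat("Modality-level IWAS score test\n")
  cat("  gene:", x$gene_id, "  modality:", x$modality, "\n")
  cat("  SNPs:", x$n_snps, "  tested IDPs (K1):", x$K1, "\n")
  cat("  adjusted: other modalities =", x$adjust_other,
      ", direct burden =", x$adjust_direct, "\n")
  if (x$p_method == "no_test") {
    cat("  no test (no surviving IDP columns)\n")
  } else {
    cat(sprintf("  T = %.6g,  p = %.4g  (%s)\n", x$T, x$p_value, x$p_method))
  }
  invisible(x)
}

#' Per-IDP univariate tests within a modality
#'
#' Runs the score test separately for each IDP column of the tested modality.
#' With `adjusted = TRUE` (comparator "IDP-specific"), each test adjusts for
#' the other modalities' imputed IDPs and the burden column, exactly as the
#' modality-level test does; with `adjusted = FALSE` this is the classic
#' univariate IWAS with no pleiotropy adjustment. Family-wise error across the
#' K1 IDPs is controlled by Bonferroni.
#'
#' @inheritParams modality_test
#' @param adjusted logical: adjust for other modalities and the direct-effect
#'   burden column (`TRUE`), or test each IDP with no adjustment (`FALSE`).
#' @param alpha family-wise significance level for the Bonferroni flags.
#' @return an object of class `miwas_idp_tests`: a data.frame with one row per
#'   IDP (`idp, T, p_value, p_method`) plus attributes `bonferroni_threshold`
#'   and `p_min_adjusted` (Bonferroni-adjusted minimum p).
#' @export
idp_specific_test <- function(weights, z_disease, ld, tested_modality,
                              gene_id = NA_character_, adjusted = TRUE,
                              alpha = 0.05, p_method = "auto",
                              mc_draws = 1e6, seed = NULL) {
  if (!tested_modality %in% names(weights))
    stop("tested modality ", tested_modality, " not among weight matrices")
  A1 <- weights[[tested_modality]]
  idps <- colnames(A1)
  rows <- lapply(idps, function(id) {
    w1 <- weights
    w1[[tested_modality]] <- A1[, id, drop = FALSE]
    r <- modality_test(w1, z_disease, ld, tested_modality, gene_id,
                       adjust_other = adjusted, adjust_direct = adjusted,
                       p_method = p_method, mc_draws = mc_draws, seed = seed)
    data.frame(idp = id, T = r$T, p_value = r$p_value,
               p_method = r$p_method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(idp = character(0), T = numeric(0),
                      p_value = numeric(0), p_method = character(0))
  bf <- bonferroni_adjust(out$p_value, alpha = alpha)
  out$significant <- bf$significant
  attr(out, "bonferroni_threshold") <- bf$threshold
  attr(out, "p_min_adjusted") <-
    if (nrow(out)) min(1, nrow(out) * min(out$p_value)) else NA_real_
  attr(out, "gene_id") <- gene_id
  attr(out, "modality") <- tested_modality
  class(out) <- c("miwas_idp_tests", class(out))
  out
}

#' Bonferroni correction
#'
#' Flags p-values significant when strictly below `alpha / m`.
#'
#' @param p_values numeric vector of p-values.
#' @param alpha family-wise significance level.
#' @param m number of tests (default `length(p_values)`).
#' @return list with `significant` (logical vector) and `threshold`
#'   (`alpha / m`).
#' @export
bonferroni_adjust <- function(p_values, alpha = 0.05, m = length(p_values)) {
  if (m < 1) stop("m must be >= 1")
  thr <- alpha / m
  list(significant = p_values < thr, threshold = thr)
}
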