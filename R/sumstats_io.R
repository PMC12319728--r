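# Reading, harmonizing and windowing GWAS summary statistics, LD sources and
# gene annotations. All coordinates are 1-based; windows are inclusive at both
# ends. Tables are plain data.frames with canonical column names
# (snp_id, chrom, pos, effect_allele, other_allele, z, n).

.GWAS_CANONICAL <- c(snp_id = "SNP", chrom = "CHR", pos = "POS",
                     effect_allele = "A1", other_allele = "A2",
                     z = "Z", n = "N")

#' Read a GWAS summary-statistics table
#'
#' Reads a whitespace- or tab-delimited text file with a header into a
#' canonical GWAS table. Default column names are `SNP, CHR, POS, A1, A2, Z, N`
#' (`A1` = effect allele); `column_map` renames them. Rows whose z-score or
#' sample size cannot be parsed as finite numbers are dropped with a message.
#'
#' @param path path to a delimited text file with a header row.
#' @param column_map named character vector mapping canonical field names
#'   (`snp_id, chrom, pos, effect_allele, other_allele, z, n`) to the file's
#'   column names; only the names you wish to override need be given.
#' @return a `data.frame` of class `gwas_table` with canonical columns.
#' @export
read_gwas_table <- function(path, column_map = NULL) {
  cmap <- .GWAS_CANONICAL
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), names(cmap))
    if (length(bad))
      stop("unknown field(s) in column_map: ", paste(bad, collapse = ", "))
    cmap[names(column_map)] <- column_map
  }
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "")
  missing_cols <- setdiff(unname(cmap), names(raw))
  if (length(missing_cols))
    stop("mandatory column(s) missing from ", path, ": ",
         paste(missing_cols, collapse = ", "))
  tab <- data.frame(
    snp_id        = as.character(raw[[cmap["snp_id"]]]),
    chrom         = as.character(raw[[cmap["chrom"]]]),
    pos           = as.integer(raw[[cmap["pos"]]]),
    effect_allele = toupper(as.character(raw[[cmap["effect_allele"]]])),
    other_allele  = toupper(as.character(raw[[cmap["other_allele"]]])),
    z             = suppressWarnings(as.numeric(raw[[cmap["z"]]])),
    n             = suppressWarnings(as.numeric(raw[[cmap["n"]]])),
    stringsAsFactors = FALSE
  )
  bad <- !is.finite(tab$z) | !is.finite(tab$n)
  if (any(bad)) {
    message(sum(bad), " row(s) with unparseable z or n dropped from ", path)
    tab <- tab[!bad, , drop = FALSE]
  }
  as_gwas_table(tab)
}

#' Construct a GWAS table from canonical columns
#'
#' Validates the invariants of a summary-statistics table: unique SNP ids,
#' positions >= 1, distinct alleles, and sample sizes >= 3 (needed for the
#' z-to-beta transform).
#'
#' @param x a data.frame with columns `snp_id, chrom, pos, effect_allele,
#'   other_allele, z, n`.
#' @return `x`, row-name free, with class `gwas_table` prepended.
#' @export
as_gwas_table <- function(x) {
  need <- names(.GWAS_CANONICAL)
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("gwas_table needs column(s): ", paste(miss, collapse = ", "))
  dup <- x$snp_id[duplicated(x$snp_id)]
  if (length(dup))
    stop("duplicate snp_id in table: ", paste(unique(dup), collapse = ", "))
  if (any(x$pos < 1L)) stop("pos must be >= 1")
  if (any(x$effect_allele == x$other_allele))
    stop("effect_allele equals other_allele for: ",
         paste(x$snp_id[x$effect_allele == x$other_allele], collapse = ", "))
  if (any(x$n < 3)) stop("sample size n must be >= 3 for every SNP")
  rownames(x) <- NULL
  class(x) <- unique(c("gwas_table", class(x)))
  x
}

#' Write a GWAS table
#'
#' Writes the canonical columns tab-delimited with header `SNP CHR POS A1 A2 Z N`.
#'
#' @param x a `gwas_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gwas_table <- function(x, path) {
  out <- x[names(.GWAS_CANONICAL)]
  names(out) <- unname(.GWAS_CANONICAL)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.is_ambiguous <- function(a1, a2) {
  p <- paste0(a1, a2)
  p %in% c("AT", "TA", "CG", "GC")
}

#' Harmonize alleles of a GWAS table against a reference table
#'
#' Restricts `target` to the SNPs shared with `reference` (in reference order),
#' negates z where the effect/other alleles are swapped relative to the
#' reference, and drops strand-ambiguous (A/T, C/G) pairs as well as allele
#' pairs irreconcilable even after swapping. The operation is idempotent.
#'
#' @param target a `gwas_table` to be aligned.
#' @param reference a `gwas_table` defining allele orientation and SNP order.
#' @return the harmonized `gwas_table` (alleles rewritten to the reference
#'   orientation).
#' @export
harmonize_alleles <- function(target, reference) {
  shared <- intersect(reference$snp_id, target$snp_id)
  if (!length(shared))
    stop("no SNPs shared between target and reference tables")
  ref <- reference[match(shared, reference$snp_id), , drop = FALSE]
  tgt <- target[match(shared, target$snp_id), , drop = FALSE]

  ambig <- .is_ambiguous(tgt$effect_allele, tgt$other_allele) |
    .is_ambiguous(ref$effect_allele, ref$other_allele)
  same    <- tgt$effect_allele == ref$effect_allele &
             tgt$other_allele  == ref$other_allele
  swapped <- tgt$effect_allele == ref$other_allele &
             tgt$other_allele  == ref$effect_allele

  n_ambig <- sum(ambig)
  n_irrec <- sum(!ambig & !same & !swapped)
  if (n_ambig) message(n_ambig, " strand-ambiguous SNP(s) dropped")
  if (n_irrec) message(n_irrec, " SNP(s) with irreconcilable alleles dropped")

  keep <- !ambig & (same | swapped)
  out <- tgt[keep, , drop = FALSE]
  flip <- swapped[keep]
  out$z[flip] <- -out$z[flip]
  out$effect_allele <- ref$effect_allele[keep]
  out$other_allele  <- ref$other_allele[keep]
  if (!nrow(out)) stop("no SNPs left after allele harmonization")
  as_gwas_table(out)
}

#' LD matrix from a reference-panel dosage matrix
#'
#' Computes the SNP-by-SNP Pearson correlation matrix R from the columns of a
#' panel genotype (dosage) matrix, with a unit diagonal enforced exactly.
#'
#' @param genotypes numeric matrix, panel subjects in rows, SNPs in columns;
#'   column names are taken as SNP ids.
#' @return a symmetric correlation matrix of class `ld_matrix` with SNP ids as
#'   dimnames.
#' @export
ld_from_panel <- function(genotypes) {
  genotypes <- as.matrix(genotypes)
  v <- apply(genotypes, 2, stats::var)
  if (any(v == 0 | !is.finite(v))) {
    ids <- colnames(genotypes)
    if (is.null(ids)) ids <- paste0("col", seq_len(ncol(genotypes)))
    stop("zero-variance panel column(s): ",
         paste(ids[v == 0 | !is.finite(v)], collapse = ", "))
  }
  R <- stats::cor(genotypes)
  R <- (R + t(R)) / 2
  diag(R) <- 1
  if (is.null(colnames(genotypes)))
    dimnames(R) <- list(paste0("snp", seq_len(ncol(R))),
                        paste0("snp", seq_len(ncol(R))))
  class(R) <- c("ld_matrix", class(R))
  R
}

#' Read an LD matrix from square delimited text
#'
#' Expects a square numeric table whose first row and first column hold SNP
#' ids (as written by [write_ld_matrix()]).
#'
#' @param path input file path.
#' @return an `ld_matrix`.
#' @export
read_ld_matrix <- function(path) {
  tab <- utils::read.table(path, header = TRUE, row.names = 1,
                           check.names = FALSE)
  R <- as.matrix(tab)
  if (nrow(R) != ncol(R)) stop("LD matrix file is not square: ", path)
  if (!isTRUE(all.equal(rownames(R), colnames(R))))
    stop("LD matrix row/column ids disagree: ", path)
  if (max(abs(R - t(R))) > 1e-10) stop("LD matrix is not symmetric: ", path)
  if (max(abs(diag(R) - 1)) > 1e-10) stop("LD matrix diagonal is not 1: ", path)
  R <- (R + t(R)) / 2
  diag(R) <- 1
  class(R) <- c("ld_matrix", class(R))
  R
}

#' Write an LD matrix as square delimited text
#'
#' @param R an `ld_matrix` (or any square matrix with dimnames).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(R, path) {
  utils::write.table(as.matrix(unclass(R)), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Gene regions from BED-like annotation text
#'
#' Reads a 4+ column BED-like file (chrom, start, end, gene_id). BED's 0-based
#' half-open starts are converted to 1-based inclusive coordinates on read
#' (start + 1; end unchanged).
#'
#' @param path BED-like annotation file (no header).
#' @param window_bp flanking window in base pairs attached to every region
#'   (default 1 Mb).
#' @return data.frame with columns `gene_id, chrom, start, end, window_bp`.
#' @export
read_gene_bed <- function(path, window_bp = 1e6) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("gene annotation needs >= 4 columns: ", path)
  out <- data.frame(gene_id = as.character(tab[[4]]),
                    chrom = as.character(tab[[1]]),
                    start = as.integer(tab[[2]]) + 1L,
                    end = as.integer(tab[[3]]),
                    window_bp = as.integer(window_bp),
                    stringsAsFactors = FALSE)
  if (any(out$start > out$end)) stop("gene with start > end in ", path)
  out
}

#' Read an IDP-to-modality map
#'
#' Two-column delimited text (header `IDP  MODALITY`) assigning each
#' imaging-derived phenotype to exactly one modality.
#'
#' @param path input file path.
#' @return named character vector, names = IDP ids, values = modality labels.
#' @export
read_modality_map <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("modality map needs 2 columns: ", path)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    stop("IDP(s) mapped more than once: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  stats::setNames(as.character(tab[[2]]), ids)
}

#' Restrict a GWAS table to a gene window
#'
#' Keeps SNPs on the gene's chromosome with
#' `start - window_bp <= pos <= end + window_bp`, inclusive at both ends.
#'
#' @param table a `gwas_table`.
#' @param region a single-row data.frame (or list) with `chrom, start, end` and
#'   optionally `window_bp` (default 1 Mb).
#' @return the windowed `gwas_table` (possibly with zero rows).
#' @export
extract_gene_window <- function(table, region) {
  wb <- if (!is.null(region$window_bp)) region$window_bp else 1e6
  lo <- region$start - wb
  hi <- region$end + wb
  keep <- table$chrom == region$chrom & table$pos >= lo & table$pos <= hi
  out <- table[keep, , drop = FALSE]
  if (!nrow(out))
    message("no SNPs in window for gene ",
            if (!is.null(region$gene_id)) region$gene_id else "<region>")
  rownames(out) <- NULL
  out
}

#' Filter SNPs by missingness and median-impute the rest
#'
#' Removes SNPs (columns) whose missing fraction exceeds `max_missing`
#' and replaces remaining missing entries by the per-SNP median of observed
#' dosages.
#'
#' @param genotypes numeric matrix with `NA` marking missing dosages.
#' @param max_missing maximal tolerated missing fraction per SNP (default 0.01).
#' @return list with `genotypes` (imputed matrix) and `kept` (column ids kept).
#' @export
filter_missingness <- function(genotypes, max_missing = 0.01) {
  genotypes <- as.matrix(genotypes)
  ids <- colnames(genotypes)
  if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(genotypes)))
  miss_frac <- colMeans(is.na(genotypes))
  drop <- miss_frac > max_missing
  if (any(drop))
    message(sum(drop), " SNP(s) dropped for missingness > ", max_missing, ": ",
            paste(ids[drop], collapse = ", "))
  out <- genotypes[, !drop, drop = FALSE]
  for (j in seq_len(ncol(out))) {
    na <- is.na(out[, j])
    if (any(na)) out[na, j] <- stats::median(out[!na, j])
  }
  list(genotypes = out, kept = ids[!drop])
}
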