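# Small builders used across the suite.

toy_gwas <- function(snp_id, z, pos = seq_along(snp_id) * 1000L,
                     chrom = "1", a1 = "A", a2 = "G", n = 1000) {
  as_gwas_table(data.frame(
    snp_id = snp_id, chrom = chrom, pos = as.integer(pos),
    effect_allele = rep_len(a1, length(snp_id)),
    other_allele = rep_len(a2, length(snp_id)),
    z = z, n = n, stringsAsFactors = FALSE))
}

toy_ld <- function(R, ids = paste0("rs", seq_len(nrow(R)))) {
  dimnames(R) <- list(ids, ids)
  class(R) <- c("ld_matrix", class(R))
  R
}

# small simulated dataset reused by several files
small_params <- function(...) {
  sim_params(n = 600, J = 12, K = 3, Q = 2, ...)
}
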