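# End-to-end workflows behind the command-line interface: (a) real-data-style
# testing from summary-statistics files, (b) simulation experiments driven by
# a YAML configuration, (c) generation of a self-contained toy fixture set.

#' Gene x modality tests from summary statistics
#'
#' The full summary-statistics workflow: for every gene and every modality,
#' window the disease and per-IDP GWAS tables to the gene's 1 Mb flanked
#' region, harmonize alleles to the disease table, build Stage-1 weights
#' (clumping, z-to-beta, joint weights through the LD matrix, F-test screen),
#' and run the modality-level score test adjusting for the other modalities
#' and the direct-effect burden column. Two Bonferroni flags accompany each
#' row: against the global threshold `alpha / (number of tests performed)` and
#' against the modality-specific threshold `alpha / (tests within that
#' modality)`.
#'
#' @param disease_gwas a `gwas_table` for the disease trait.
#' @param idp_tables named list of `gwas_table`s, one per IDP.
#' @param ld an `ld_matrix` covering the SNPs used (from a panel or file).
#' @param genes data.frame from [read_gene_bed()].
#' @param modality_map named character vector, IDP id -> modality.
#' @param config Stage-1 configuration from [stage1_config()].
#' @param adjust_other,adjust_direct adjustment switches (default both `TRUE`).
#' @param alpha family-wise level for the Bonferroni columns.
#' @param p_method,mc_draws,seed p-value controls (see
#'   [mixture_chisq_pvalue()]).
#' @return object of class `miwas_results`: a data.frame with one row per
#'   gene x modality (`gene_id, chrom, modality, n_snps, K1, T, p_value,
#'   p_method, adjust_other, adjust_direct, sig_global, sig_modality`), plus
#'   attributes `alpha`, `global_threshold` and `modality_thresholds`.
#' @export
miwas_gene_tests <- function(disease_gwas, idp_tables, ld, genes,
                             modality_map, config = stage1_config(),
                             adjust_other = TRUE, adjust_direct = TRUE,
                             alpha = 0.05, p_method = "auto",
                             mc_draws = 1e6, seed = NULL) {
  if (!nrow(genes)) stop("empty gene set")
  panel_ids <- rownames(ld)
  disease_gwas <- disease_gwas[disease_gwas$snp_id %in% panel_ids, ,
                               drop = FALSE]
  rows <- list()
  for (gi in seq_len(nrow(genes))) {
    region <- genes[gi, ]
    dis_win <- extract_gene_window(disease_gwas, region)
    if (!nrow(dis_win)) {
      message("gene ", region$gene_id, ": no disease GWAS SNPs in window; skipped")
      next
    }
    idp_win <- lapply(idp_tables, function(tab) {
      w <- extract_gene_window(tab, region)
      w <- w[w$snp_id %in% dis_win$snp_id, , drop = FALSE]
      if (nrow(w)) tryCatch(harmonize_alleles(w, dis_win),
                            error = function(e) NULL)
      else NULL
    })
    idp_win <- Filter(Negate(is.null), idp_win)
    if (!length(idp_win)) {
      message("gene ", region$gene_id, ": no IDP GWAS SNPs in window; skipped")
      next
    }
    weights <- build_weight_matrix(idp_win, ld, modality_map, config)
    snps <- rownames(weights[[1]])
    z <- stats::setNames(dis_win$z[match(snps, dis_win$snp_id)], snps)
    for (mod in names(weights)) {
      res <- modality_test(weights, z, ld[snps, snps, drop = FALSE], mod,
                           gene_id = region$gene_id,
                           adjust_other = adjust_other,
                           adjust_direct = adjust_direct,
                           p_method = p_method, mc_draws = mc_draws,
                           seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = region$gene_id, chrom = region$chrom, modality = mod,
        n_snps = res$n_snps, K1 = res$K1, T = res$T, p_value = res$p_value,
        p_method = res$p_method, adjust_other = adjust_other,
        adjust_direct = adjust_direct, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no gene produced any testable window")
  out <- do.call(rbind, rows)
  tested <- !is.na(out$p_value)
  m_global <- sum(tested)
  out$sig_global <- FALSE
  if (m_global)
    out$sig_global[tested] <-
      bonferroni_adjust(out$p_value[tested], alpha, m_global)$significant
  out$sig_modality <- FALSE
  mod_thresholds <- c()
  for (mod in unique(out$modality)) {
    sel <- tested & out$modality == mod
    m_mod <- sum(sel)
    if (m_mod) {
      bf <- bonferroni_adjust(out$p_value[sel], alpha, m_mod)
      out$sig_modality[sel] <- bf$significant
      mod_thresholds[mod] <- bf$threshold
    }
  }
  attr(out, "alpha") <- alpha
  attr(out, "global_threshold") <- if (m_global) alpha / m_global else NA_real_
  attr(out, "modality_thresholds") <- mod_thresholds
  class(out) <- c("miwas_results", class(out))
  out
}

#' Write a gene x modality results table
#'
#' Tab-delimited, re-readable by [read_miwas_results()].
#'
#' @param results a `miwas_results` data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_miwas_results <- function(results, path) {
  utils::write.table(as.data.frame(results), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene x modality results table written by [write_miwas_results()]
#'
#' @param path input file path.
#' @return data.frame.
#' @export
read_miwas_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

# ---- simulation study configuration -----------------------------------------

#' Read a simulation-study configuration (YAML)
#'
#' Keys: `experiment` (`"null"` or `"power"`), any [sim_params()] field,
#' `n_reps`, `seed`, and per experiment `alpha_levels`/`methods` (null) or
#' `tau_grid`/`scenarios`/`alpha` (power).
#'
#' @param path YAML file path.
#' @return named list.
#' @export
read_sim_config <- function(path) yaml::read_yaml(path)

#' Write a simulation-study configuration (YAML)
#'
#' @param config named list as in [read_sim_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run a simulation study from a configuration
#'
#' Dispatches to [run_null_experiment()] or [run_power_experiment()] and, when
#' `out_prefix` is given, writes the result table
#' (`<prefix>_<experiment>.tsv`) and a machine-readable metadata block
#' (`<prefix>_metadata.yaml`: full parameters, seed, package version) that
#' round-trips through [read_sim_config()].
#'
#' @param config named list (or YAML path) as in [read_sim_config()].
#' @param out_prefix optional output path prefix.
#' @return the experiment result object, invisibly when writing.
#' @export
run_simulation_study <- function(config, out_prefix = NULL) {
  if (is.character(config)) config <- read_sim_config(config)
  experiment <- match.arg(config$experiment, c("null", "power"))
  par_names <- names(formals(sim_params))
  params <- do.call(sim_params, config[intersect(names(config), par_names)])
  seed <- if (!is.null(config$seed)) config$seed else 1
  n_reps <- if (!is.null(config$n_reps)) config$n_reps else 5000
  if (experiment == "null") {
    res <- run_null_experiment(
      params, n_reps = n_reps,
      alpha_levels = if (!is.null(config$alpha_levels))
        unlist(config$alpha_levels) else c(0.05, 0.01),
      methods = if (!is.null(config$methods)) unlist(config$methods) else 1:4,
      seed = seed)
  } else {
    if (is.null(config$tau_grid)) stop("power experiment needs tau_grid")
    res <- run_power_experiment(
      params, tau_grid = unlist(config$tau_grid),
      scenarios = if (!is.null(config$scenarios))
        unlist(config$scenarios) else c("dense", "sparse"),
      n_reps = n_reps,
      alpha = if (!is.null(config$alpha)) config$alpha else 0.05,
      methods = if (!is.null(config$methods)) unlist(config$methods) else 1:2,
      seed = seed)
  }
  if (!is.null(out_prefix)) {
    utils::write.table(as.data.frame(res),
                       paste0(out_prefix, "_", experiment, ".tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    meta <- c(list(experiment = experiment, n_reps = n_reps, seed = seed,
                   package_version = as.character(utils::packageVersion("miwas"))),
              unclass(params))
    write_sim_config(meta, paste0(out_prefix, "_metadata.yaml"))
    return(invisible(res))
  }
  res
}

#' Write a self-contained toy fixture set
#'
#' Simulates a small two-gene, two-modality dataset and writes every input the
#' summary-statistics workflow needs: a disease GWAS table, per-IDP GWAS
#' tables, a panel dosage matrix, its LD matrix, a BED gene annotation and a
#' modality map. All files are plain text and parseable by the package's own
#' readers.
#'
#' @param dir output directory (created if absent).
#' @param seed integer seed (fixtures are byte-identical for a fixed seed).
#' @param n subjects used to generate the toy summary statistics.
#' @param n_panel reference-panel subjects written to `panel.tsv`.
#' @return named list of the written file paths, invisibly.
#' @export
write_example_fixtures <- function(dir, seed = 1, n = 1500, n_panel = 250) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  J_loc <- 15                       # SNPs per gene locus
  loci <- list(gene_a = 1.00e6, gene_b = 5.00e6)
  # strongly heritable toy IDPs so the default instrument-strength screen
  # retains them and the example exercises the whole pipeline
  params <- sim_params(n = n, J = J_loc * length(loci), K = 2, Q = 2,
                       sd_alpha = 0.6, sd_delta = 3)
  d <- simulate_dataset(params)
  pos <- unlist(lapply(loci, function(p0) p0 + (seq_len(J_loc) - 1) * 4000))
  idp_ids <- unlist(lapply(seq_len(params$Q), function(q)
    sprintf("mod%d_idp%02d", q, seq_len(params$K))))
  modality <- rep(c("sMRI", "dMRI"), each = params$K)

  paths <- list()
  Mall <- do.call(cbind, d$M)
  for (i in seq_along(idp_ids)) {
    ss <- individual_to_sumstats(d$G_std, Mall[, i], model = "linear",
                                 positions = pos)
    paths[[paste0("idp_", idp_ids[i])]] <-
      write_gwas_table(ss$gwas, file.path(dir, paste0(idp_ids[i], ".tsv")))
  }
  ss_dis <- individual_to_sumstats(d$G_std, d$y, model = "linear",
                                   positions = pos)
  paths$disease <- write_gwas_table(ss_dis$gwas, file.path(dir, "disease.tsv"))

  panel <- gen_genotype_matrix(n_panel, params$J, params$maf, params$ld_rho)$raw
  utils::write.table(panel, file.path(dir, "panel.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths$panel <- file.path(dir, "panel.tsv")
  paths$ld <- write_ld_matrix(ss_dis$ld, file.path(dir, "ld.tsv"))

  bed <- data.frame(chrom = "1",
                    start = vapply(loci, function(p0) p0 + 2e4, 0) - 1,
                    end = vapply(loci, function(p0) p0 + 3e4, 0),
                    gene_id = names(loci))
  utils::write.table(bed, file.path(dir, "genes.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  paths$genes <- file.path(dir, "genes.bed")

  utils::write.table(data.frame(IDP = idp_ids, MODALITY = modality),
                     file.path(dir, "modality_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths$modality_map <- file.path(dir, "modality_map.tsv")
  invisible(paths)
}
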