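# Type-I error and power experiments. Per replicate: simulate a dataset,
# derive marginal GWAS summary statistics and the sample LD matrix, build
# Stage-1 joint weights (no clumping or screening in the experiments), and
# compute the four comparator p-values:
#   Method 1  modality-level test adjusting other modalities + direct burden
#   Method 2  per-IDP adjusted tests, Bonferroni over the K tested IDPs
#   Method 3  modality-level test with no adjustment
#   Method 4  per-IDP unadjusted tests (univariate IWAS), Bonferroni
# Methods 2 and 4 are reported as Bonferroni-adjusted minimum p-values so that
# rejection at level alpha is `p < alpha` uniformly across methods.

.METHOD_LABELS <- c("1" = "proposed", "2" = "idp_specific",
                    "3" = "proposed_unadjusted", "4" = "uv_iwas")

# p-values of methods 1-4 for one replicate's summary statistics. mc_seed is
# only consumed when the auto policy selects the Monte Carlo route (tested
# modality of 5 or fewer IDPs with unequal eigenvalues).
.method_pvalues <- function(W, K, z_dis, R, methods, mc_seed = 1,
                            mc_draws = 1e5) {
  A1 <- W[, seq_len(K), drop = FALSE]
  A2 <- cbind(W[, -seq_len(K), drop = FALSE],
              direct_burden = rep(1, nrow(W)))
  out <- c("1" = NA_real_, "2" = NA_real_, "3" = NA_real_, "4" = NA_real_)
  if (any(c(1, 2) %in% methods)) {
    core <- .score_core(A1, A2, R, z_dis)
    if (1 %in% methods) {
      lam <- .eigen_weights(core$cov_S)
      pv <- mixture_chisq_pvalue(test_statistic(core$S), lam,
                                 mc_draws = mc_draws, seed = mc_seed)
      out["1"] <- pv$p
    }
    if (2 %in% methods) {
      p_k <- stats::pchisq(core$S^2 / diag(core$cov_S), df = 1,
                           lower.tail = FALSE)
      out["2"] <- min(1, K * min(p_k))
    }
  }
  if (any(c(3, 4) %in% methods)) {
    core0 <- .score_core(A1, NULL, R, z_dis)
    if (3 %in% methods) {
      lam0 <- .eigen_weights(core0$cov_S)
      pv0 <- mixture_chisq_pvalue(test_statistic(core0$S), lam0,
                                  mc_draws = mc_draws, seed = mc_seed + 1L)
      out["3"] <- pv0$p
    }
    if (4 %in% methods) {
      p_k0 <- stats::pchisq(core0$S^2 / diag(core0$cov_S), df = 1,
                            lower.tail = FALSE)
      out["4"] <- min(1, K * min(p_k0))
    }
  }
  out
}

# One replicate: simulate, summarize, weight, test. Returns the method
# p-values (named "1".."4"). Stage-1 screening/clumping are off, per the
# experiment design.
.replicate_once <- function(params, structure, methods) {
  d <- simulate_dataset(params, structure = structure)
  n <- params$n
  G <- d$G_std
  R <- crossprod(G) / (n - 1)
  diag(R) <- 1
  # per-IDP marginal z and standardized marginal betas (modality 1 first)
  Mall <- do.call(cbind, d$M)
  r <- crossprod(G, scale(Mall)) / (n - 1)
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  z_idp <- r * sqrt((n - 2) / (1 - r^2))
  b <- z_to_marginal_beta(z_idp, n)
  W <- joint_weights(b, R, default_ridge(R))
  z_dis <- if (params$trait_type == "continuous")
    .z_linear_wald(G, d$y)
  else
    .z_logistic_wald(G, d$y)
  keep <- is.finite(z_dis)
  if (!all(keep)) {
    W <- W[keep, , drop = FALSE]
    R <- R[keep, keep, drop = FALSE]
    z_dis <- z_dis[keep]
  }
  mc_seed <- sample.int(.Machine$integer.max - 1L, 1)
  .method_pvalues(W, params$K, z_dis, R, methods, mc_seed = mc_seed)
}

.mc_se <- function(rate, n_reps) sqrt(rate * (1 - rate) / n_reps)

#' Empirical Type-I error experiment
#'
#' Simulates `n_reps` null-scenario datasets, derives summary statistics,
#' runs the selected methods, and reports per-method empirical rejection rates
#' at each nominal level with Monte Carlo standard errors.
#'
#' @param params a `miwas_sim_params` object with `scenario = "null"`.
#' @param n_reps number of replicate datasets.
#' @param alpha_levels nominal levels (default 0.05 and 0.01).
#' @param methods subset of `1:4` (see the method table above).
#' @param seed integer seed for the whole experiment.
#' @return object of class `miwas_null_exp`: a data.frame with columns
#'   `method, method_label, level, rate, mc_se, n_reps, trait_type`, carrying
#'   the per-replicate p-value matrix as attribute `p_values`.
#' @export
run_null_experiment <- function(params, n_reps,
                                alpha_levels = c(0.05, 0.01),
                                methods = 1:4, seed = 1) {
  if (params$scenario != "null")
    stop("run_null_experiment requires scenario = 'null'")
  set.seed(seed)
  structure <- latent_binary_ld(params$J, params$maf, params$ld_rho)
  P <- t(vapply(seq_len(n_reps),
                function(i) .replicate_once(params, structure, methods),
                numeric(4)))
  rows <- expand.grid(method = methods, level = alpha_levels,
                      KEEP.OUT.ATTRS = FALSE)
  rows$method_label <- unname(.METHOD_LABELS[as.character(rows$method)])
  rows$rate <- mapply(function(m, a) mean(P[, as.character(m)] < a),
                      rows$method, rows$level)
  rows$mc_se <- .mc_se(rows$rate, n_reps)
  rows$n_reps <- n_reps
  rows$trait_type <- params$trait_type
  rows <- rows[c("method", "method_label", "level", "rate", "mc_se",
                 "n_reps", "trait_type")]
  attr(rows, "p_values") <- P
  attr(rows, "seed") <- seed
  class(rows) <- c("miwas_null_exp", class(rows))
  rows
}

#' Statistical power experiment
#'
#' For each scenario and each signal scale `tau` in `tau_grid`, simulates
#' `n_reps` datasets and reports the rejection fraction of the selected
#' methods at level `alpha`, with Monte Carlo standard errors. A `tau` of 0 is
#' run as the null scenario (its rate is the Type-I error).
#'
#' @param params a `miwas_sim_params` object (its `scenario`/`tau` are
#'   overridden per grid cell).
#' @param tau_grid nonnegative signal scales.
#' @param scenarios subset of `c("dense", "sparse")`.
#' @param n_reps replicates per (scenario, tau) cell.
#' @param alpha rejection level (default 0.05).
#' @param methods subset of `1:4` (default `1:2`).
#' @param seed integer seed.
#' @return object of class `miwas_power_exp`: a data.frame with columns
#'   `method, method_label, scenario, tau, power, mc_se, n_reps, trait_type`.
#' @export
run_power_experiment <- function(params, tau_grid,
                                 scenarios = c("dense", "sparse"),
                                 n_reps = 500, alpha = 0.05, methods = 1:2,
                                 seed = 1) {
  if (any(tau_grid < 0)) stop("tau_grid must be nonnegative")
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  set.seed(seed)
  structure <- latent_binary_ld(params$J, params$maf, params$ld_rho)
  out <- list()
  for (sc in scenarios) {
    for (tau in tau_grid) {
      args <- unclass(params)
      args$scenario <- if (tau == 0) "null" else sc
      args$tau <- tau
      cell <- do.call(sim_params, args)
      P <- t(vapply(seq_len(n_reps),
                    function(i) .replicate_once(cell, structure, methods),
                    numeric(4)))
      for (m in methods) {
        pow <- mean(P[, as.character(m)] < alpha)
        out[[length(out) + 1L]] <- data.frame(
          method = m, method_label = unname(.METHOD_LABELS[as.character(m)]),
          scenario = sc, tau = tau, power = pow,
          mc_se = .mc_se(pow, n_reps), n_reps = n_reps,
          trait_type = params$trait_type, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  attr(res, "alpha") <- alpha
  attr(res, "seed") <- seed
  class(res) <- c("miwas_power_exp", class(res))
  res
}

#' @export
print.miwas_null_exp <- function(x, ...) {
  cat("Empirical Type-I error (", x$trait_type[1], " trait, ",
      x$n_reps[1], " replicates)\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
print.miwas_power_exp <- function(x, ...) {
  cat("Empirical power at level ", attr(x, "alpha"), " (",
      x$trait_type[1], " trait, ", x$n_reps[1], " replicates per cell)\n",
      sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
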