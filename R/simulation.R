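# Generative model for the validation experiments. One gene of J correlated
# biallelic SNPs (multivariate binary via a dichotomized latent Gaussian with
# AR(1)-decaying target correlations), Q imaging modalities of K IDPs each,
# an unobserved confounder u feeding both the IDPs and the trait, a direct
# genetic (burden) effect on the trait, and a continuous or binary (logistic)
# trait. Structural equations act on the 0/1 dosage scale by default; the
# burden term is standardized so the stated trait calibration (prevalence,
# genotype R-squared bounds) holds. Marginal GWAS summary statistics and the
# sample LD matrix are derived from each realized dataset.

#' Simulation parameters
#'
#' Defaults encode the validation study's conditions: n = 2000 subjects,
#' J = 58 SNPs with AR(1)-decaying binary correlations (base 0.5) and allele
#' frequency 0.3, Q = 2 modalities of K = 10 IDPs, SNP-to-IDP effects
#' `alpha ~ N(0, 0.3^2)`, confounder loadings `gamma ~ N(0, 1)`, IDP noise sd
#' 5, non-tested-modality trait effects `beta(2) ~ N(0, 0.05^2)`, direct
#' (burden) effect `mu = 1`, confounder effect `theta = 1`, continuous-trait
#' noise sd 4, logistic intercept -2.
#'
#' @param n subjects per dataset.
#' @param J SNPs in the gene.
#' @param K IDPs per modality.
#' @param Q number of modalities (modality 1 is the tested one).
#' @param sd_alpha sd of the SNP-to-IDP effects.
#' @param sd_gamma sd of the confounder-to-IDP loadings.
#' @param sd_beta2 sd of the non-tested-modality trait effects.
#' @param mu direct genetic (burden) effect on the trait.
#' @param theta confounder effect on the trait.
#' @param sd_delta IDP residual noise sd.
#' @param sd_eps continuous-trait residual noise sd.
#' @param logit_intercept intercept of the binary-trait logistic model.
#' @param tau sd of the tested-modality trait effects; must be 0 exactly when
#'   `scenario = "null"` and positive otherwise.
#' @param scenario `"null"` (no tested-modality effect), `"dense"` (all K
#'   tested-modality IDPs causal, `beta(1) ~ N(0, tau^2)`) or `"sparse"`
#'   (only the first IDP causal).
#' @param trait_type `"continuous"` or `"binary"`.
#' @param maf allele frequency of the generated SNPs (0 < maf < 0.5).
#' @param ld_rho base of the AR(1) target correlation between SNP dosages,
#'   `corr(j, j') = ld_rho^|j - j'|`.
#' @param genotype_scale scale on which genotypes enter the structural
#'   equations: `"dosage"` (0/1 allele counts; default) or `"standardized"`.
#' @param standardize_burden standardize the burden `sum_j g_j` to unit
#'   variance before applying `mu` (default `TRUE`).
#' @param haplotype_sum generate 0/1/2 dosages as the sum of two independent
#'   haplotype draws instead of a single binary draw (default `FALSE`).
#' @return an object of class `miwas_sim_params` (a validated named list).
#' @export
sim_params <- function(n = 2000, J = 58, K = 10, Q = 2,
                       sd_alpha = 0.3, sd_gamma = 1, sd_beta2 = 0.05,
                       mu = 1, theta = 1, sd_delta = 5, sd_eps = 4,
                       logit_intercept = -2, tau = 0,
                       scenario = c("null", "dense", "sparse"),
                       trait_type = c("continuous", "binary"),
                       maf = 0.3, ld_rho = 0.5,
                       genotype_scale = c("dosage", "standardized"),
                       standardize_burden = TRUE, haplotype_sum = FALSE) {
  scenario <- match.arg(scenario)
  trait_type <- match.arg(trait_type)
  genotype_scale <- match.arg(genotype_scale)
  if (any(c(sd_alpha, sd_gamma, sd_beta2, sd_delta, sd_eps, tau) < 0))
    stop("all standard deviations must be nonnegative")
  if (maf <= 0 || maf >= 0.5) stop("maf must lie in (0, 0.5)")
  if (scenario == "null" && tau != 0)
    stop("scenario 'null' requires tau = 0")
  if (scenario != "null" && tau <= 0)
    stop("scenario '", scenario, "' requires tau > 0")
  p <- list(n = n, J = J, K = K, Q = Q, sd_alpha = sd_alpha,
            sd_gamma = sd_gamma, sd_beta2 = sd_beta2, mu = mu, theta = theta,
            sd_delta = sd_delta, sd_eps = sd_eps,
            logit_intercept = logit_intercept, tau = tau,
            scenario = scenario, trait_type = trait_type, maf = maf,
            ld_rho = ld_rho, genotype_scale = genotype_scale,
            standardize_burden = standardize_burden,
            haplotype_sum = haplotype_sum)
  class(p) <- "miwas_sim_params"
  p
}

#' @export
print.miwas_sim_params <- function(x, ...) {
  cat("Simulation parameters:\n")
  cat(sprintf("  n = %d, J = %d SNPs (maf %.2f, AR corr base %.2f), %d modalities x %d IDPs\n",
              x$n, x$J, x$maf, x$ld_rho, x$Q, x$K))
  cat(sprintf("  scenario = %s (tau = %g), trait = %s\n",
              x$scenario, x$tau, x$trait_type))
  cat(sprintf("  sd_alpha %.2g, sd_gamma %.2g, sd_beta2 %.2g, mu %.2g, theta %.2g, sd_delta %.2g, sd_eps %.2g\n",
              x$sd_alpha, x$sd_gamma, x$sd_beta2, x$mu, x$theta, x$sd_delta,
              x$sd_eps))
  invisible(x)
}

# Pr(Z1 > t, Z2 > t) for standard bivariate normal with correlation rho.
.bvn_upper <- function(t, rho) {
  if (abs(rho) >= 1) {
    if (rho >= 1) return(stats::pnorm(t, lower.tail = FALSE))
    return(max(0, 1 - 2 * stats::pnorm(t)))
  }
  f <- function(x)
    stats::dnorm(x) * stats::pnorm((rho * x - t) / sqrt(1 - rho^2))
  stats::integrate(f, t, Inf, rel.tol = 1e-10)$value
}

# Correlation of two {0,1} indicators 1(Z > t) under latent correlation rho.
.binary_corr <- function(rho, t, p) {
  (.bvn_upper(t, rho) - p^2) / (p * (1 - p))
}

#' Latent-Gaussian structure for correlated binary SNPs
#'
#' Solves, for each target binary correlation `ld_rho^d` (lag d), the latent
#' normal correlation whose dichotomization at the `maf` quantile induces it,
#' and returns the Cholesky factor of the latent correlation matrix. Targets
#' outside the feasible range of the threshold construction are clipped to the
#' attainable bound with a message.
#'
#' @param J number of SNPs.
#' @param maf marginal success probability of each binary SNP.
#' @param ld_rho AR(1) base of the target binary correlations.
#' @return list with `chol` (upper Cholesky factor of the latent correlation
#'   matrix), `threshold` (latent dichotomization point), `latent_corr`
#'   (per-lag latent correlations) and the inputs.
#' @export
latent_binary_ld <- function(J, maf, ld_rho) {
  t0 <- stats::qnorm(1 - maf)
  lags <- seq_len(max(J - 1, 0))
  targets <- ld_rho^lags
  r_lo <- .binary_corr(-1, t0, maf)
  r_hi <- .binary_corr(1, t0, maf)   # = 1 for equal margins
  lat <- numeric(length(lags))
  for (i in seq_along(lags)) {
    tg <- targets[i]
    if (abs(tg) < 1e-12) { lat[i] <- 0; next }
    if (tg >= r_hi - 1e-12 || tg <= r_lo + 1e-12) {
      clipped <- min(max(tg, r_lo + 1e-6), r_hi - 1e-6)
      message("binary correlation target ", signif(tg, 4),
              " at lag ", lags[i], " clipped to the feasible bound")
      tg <- clipped
    }
    lat[i] <- stats::uniroot(function(r) .binary_corr(r, t0, maf) - tg,
                             c(-0.9999, 0.9999), tol = 1e-10)$root
  }
  Sigma <- diag(J)
  for (i in seq_along(lags))
    Sigma[abs(row(Sigma) - col(Sigma)) == lags[i]] <- lat[i]
  ch <- tryCatch(chol(Sigma), error = function(e) {
    ev <- eigen(Sigma, symmetric = TRUE)
    chol(ev$vectors %*% diag(pmax(ev$values, 1e-10)) %*% t(ev$vectors))
  })
  list(chol = ch, threshold = t0, latent_corr = lat, J = J, maf = maf,
       ld_rho = ld_rho)
}

#' Generate a correlated binary genotype matrix
#'
#' Draws latent multivariate normals, dichotomizes at the allele-frequency
#' quantile, and standardizes columns. With `haplotype_sum = TRUE`, dosages are
#' the sum of two independent haplotype draws (values 0/1/2).
#'
#' @param n subjects.
#' @param J SNPs.
#' @param maf allele frequency.
#' @param ld_rho AR(1) base of the target binary correlations.
#' @param seed optional integer seed.
#' @param structure optional precomputed [latent_binary_ld()] result (reused
#'   across replicates for speed).
#' @param haplotype_sum sum of two haplotype draws instead of one binary draw.
#' @return list with `raw` (0/1 or 0/1/2 dosage matrix), `std` (column-
#'   standardized matrix: sample mean 0, sample variance 1) and `structure`.
#' @export
gen_genotype_matrix <- function(n, J, maf = 0.3, ld_rho = 0.5, seed = NULL,
                                structure = NULL, haplotype_sum = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(structure)) structure <- latent_binary_ld(J, maf, ld_rho)
  draw <- function() {
    Z <- matrix(stats::rnorm(n * J), n, J) %*% structure$chol
    (Z > structure$threshold) * 1
  }
  raw <- draw()
  if (haplotype_sum) raw <- raw + draw()
  colnames(raw) <- sprintf("snp%02d", seq_len(J))
  sds <- apply(raw, 2, stats::sd)
  if (any(sds == 0))
    stop("monomorphic SNP column(s) generated (increase n or maf): ",
         paste(colnames(raw)[sds == 0], collapse = ", "))
  std <- scale(raw)
  attr(std, "scaled:center") <- NULL
  attr(std, "scaled:scale") <- NULL
  list(raw = raw, std = std, structure = structure)
}

#' Generate one modality's IDP matrix
#'
#' `m_k = sum_j g_j alpha_jk + u gamma_k + delta_k` with
#' `alpha_jk ~ N(0, sd_alpha^2)`, `gamma_k ~ N(0, sd_gamma^2)`,
#' `delta ~ N(0, sd_delta^2)`. The drawn `alpha` and `gamma` are attached as
#' attributes for parameter-recovery checks.
#'
#' @param G genotype matrix on the structural scale (n x J).
#' @param u length-n confounder vector.
#' @param params a `miwas_sim_params` object.
#' @param modality_index which modality is being generated (labels only).
#' @param seed optional integer seed.
#' @return n x K IDP matrix with attributes `alpha` (J x K) and `gamma` (K).
#' @export
gen_idp_matrix <- function(G, u, params, modality_index = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(G); J <- ncol(G); K <- params$K
  alpha <- matrix(stats::rnorm(J * K, 0, params$sd_alpha), J, K)
  gamma <- stats::rnorm(K, 0, params$sd_gamma)
  M <- G %*% alpha + outer(u, gamma) +
    matrix(stats::rnorm(n * K, 0, params$sd_delta), n, K)
  colnames(M) <- sprintf("mod%d_idp%02d", modality_index, seq_len(K))
  attr(M, "alpha") <- alpha
  attr(M, "gamma") <- gamma
  M
}

#' Generate the trait
#'
#' Continuous: `y = burden * mu + sum_qk m_k(q) beta_k(q) + u * theta + eps`;
#' binary: `logit(E[y]) = intercept + (same linear predictor)`. The tested
#' modality's effects follow the scenario (`null`: all zero; `dense`: all
#' `N(0, tau^2)`; `sparse`: only the first `N(0, tau^2)`); every other
#' modality's effects are `N(0, sd_beta2^2)`. The burden is `sum_j g_j`,
#' standardized when `params$standardize_burden` is `TRUE`.
#'
#' @param G genotype matrix on the structural scale.
#' @param M_list list of per-modality IDP matrices (modality 1 first).
#' @param u confounder vector.
#' @param params a `miwas_sim_params` object.
#' @param seed optional integer seed.
#' @return list with `y`, `eta` (linear predictor excluding trait noise),
#'   `beta1` (tested-modality effects), `beta2` (list of other-modality
#'   effects), and for binary traits `prob`.
#' @export
gen_trait <- function(G, M_list, u, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- params$K
  beta1 <- switch(params$scenario,
    null = numeric(K),
    dense = stats::rnorm(K, 0, params$tau),
    sparse = c(stats::rnorm(1, 0, params$tau), numeric(K - 1)))
  beta2 <- lapply(seq_len(params$Q - 1) + 1, function(q)
    stats::rnorm(K, 0, params$sd_beta2))
  burden <- rowSums(G)
  if (isTRUE(params$standardize_burden))
    burden <- (burden - mean(burden)) / stats::sd(burden)
  eta <- burden * params$mu + drop(M_list[[1]] %*% beta1) + u * params$theta
  if (params$Q > 1)
    for (i in seq_along(beta2))
      eta <- eta + drop(M_list[[i + 1]] %*% beta2[[i]])
  if (params$trait_type == "continuous") {
    y <- eta + stats::rnorm(length(eta), 0, params$sd_eps)
    list(y = y, eta = eta, beta1 = beta1, beta2 = beta2)
  } else {
    prob <- stats::plogis(params$logit_intercept + eta)
    y <- stats::rbinom(length(eta), 1, prob)
    list(y = y, eta = eta, beta1 = beta1, beta2 = beta2, prob = prob)
  }
}

#' Simulate one complete dataset
#'
#' Draws genotypes, confounder, the Q modality IDP matrices and the trait.
#'
#' @param params a `miwas_sim_params` object.
#' @param seed integer seed.
#' @param structure optional precomputed [latent_binary_ld()] result.
#' @return object of class `miwas_sim_data`: list with `G_raw`, `G_std`, `M`
#'   (list of modality matrices), `y`, `u`, `beta1`, `beta2`, `params`.
#' @export
simulate_dataset <- function(params, seed = NULL, structure = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- gen_genotype_matrix(params$n, params$J, params$maf, params$ld_rho,
                           structure = structure,
                           haplotype_sum = params$haplotype_sum)
  u <- stats::rnorm(params$n)
  Gs <- if (params$genotype_scale == "dosage") g$raw else g$std
  M <- lapply(seq_len(params$Q), function(q)
    gen_idp_matrix(Gs, u, params, modality_index = q))
  tr <- gen_trait(Gs, M, u, params)
  out <- list(G_raw = g$raw, G_std = g$std, M = M, y = tr$y, u = u,
              eta = tr$eta, beta1 = tr$beta1, beta2 = tr$beta2,
              params = params)
  class(out) <- "miwas_sim_data"
  out
}

# ---- marginal GWAS from individual-level data --------------------------------

# Wald z from simple linear regression of y on each standardized column of G.
.z_linear_wald <- function(G_std, y) {
  n <- nrow(G_std)
  r <- drop(stats::cor(G_std, y))
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  r * sqrt((n - 2) / (1 - r^2))
}

# Score-form z with a common variance plug-in: z = G'y_c / (sd(y) sqrt(n-1)).
.z_linear_score <- function(G_std, y) {
  n <- nrow(G_std)
  yc <- y - mean(y)
  drop(crossprod(G_std, yc)) / (stats::sd(y) * sqrt(n - 1))
}

# Vectorized univariate logistic regressions (intercept + one SNP), Wald z for
# the SNP slope. Columns failing to converge (separation) get NA.
.z_logistic_wald <- function(G_std, y, max_iter = 30, tol = 1e-10) {
  n <- nrow(G_std); J <- ncol(G_std)
  b0 <- rep(stats::qlogis(max(min(mean(y), 1 - 1e-8), 1e-8)), J)
  b1 <- numeric(J)
  se1 <- rep(NA_real_, J)
  for (it in seq_len(max_iter)) {
    Eta <- sweep(sweep(G_std, 2, b1, "*"), 2, b0, "+")
    P <- stats::plogis(Eta)
    W <- P * (1 - P)
    Res <- y - P
    U0 <- colSums(Res)
    U1 <- colSums(G_std * Res)
    I00 <- colSums(W)
    I01 <- colSums(W * G_std)
    I11 <- colSums(W * G_std * G_std)
    det <- I00 * I11 - I01^2
    d0 <- (I11 * U0 - I01 * U1) / det
    d1 <- (I00 * U1 - I01 * U0) / det
    bad <- !is.finite(d0) | !is.finite(d1)
    d0[bad] <- 0; d1[bad] <- 0
    b0 <- b0 + d0; b1 <- b1 + d1
    if (max(abs(d0), abs(d1)) < tol) break
  }
  se1 <- sqrt(I00 / det)
  z <- b1 / se1
  z[!is.finite(z) | abs(b1) > 15] <- NA_real_
  z
}

#' Marginal GWAS summary statistics from individual-level data
#'
#' Per SNP: for a continuous outcome, the Wald z of the simple linear
#' regression of the outcome on the standardized dosage (or the score-form z
#' with a common variance plug-in when `z_method = "score"`); for a binary
#' outcome, the Wald z of the univariate logistic regression. Also returns the
#' sample LD matrix `R = G'G/(n-1)`.
#'
#' @param G_std column-standardized genotype matrix.
#' @param outcome outcome vector (a trait or one IDP).
#' @param model `"linear"` or `"logistic"`.
#' @param z_method `"wald"` (GWAS convention, default) or `"score"`
#'   (linear model only; exact score-form used by the individual-level
#'   equivalence oracle).
#' @param chrom,pos0,spacing synthetic annotation for the emitted table
#'   (chromosome label, first position, inter-SNP spacing in bp).
#' @param positions optional explicit per-SNP positions overriding
#'   `pos0`/`spacing`.
#' @return list with `gwas` (a `gwas_table`; SNPs with failed logistic fits
#'   are dropped with a message) and `ld` (the sample correlation matrix).
#' @export
individual_to_sumstats <- function(G_std, outcome,
                                   model = c("linear", "logistic"),
                                   z_method = c("wald", "score"),
                                   chrom = "1", pos0 = 1e6, spacing = 1e4,
                                   positions = NULL) {
  model <- match.arg(model)
  z_method <- match.arg(z_method)
  n <- nrow(G_std)
  z <- if (model == "linear") {
    if (z_method == "wald") .z_linear_wald(G_std, outcome)
    else .z_linear_score(G_std, outcome)
  } else {
    if (z_method == "score") stop("score-form z is defined for the linear model only")
    .z_logistic_wald(G_std, outcome)
  }
  ids <- colnames(G_std)
  if (is.null(ids)) ids <- sprintf("snp%02d", seq_len(ncol(G_std)))
  if (is.null(positions)) positions <- pos0 + (seq_len(ncol(G_std)) - 1) * spacing
  keep <- is.finite(z)
  if (any(!keep))
    message(sum(!keep), " SNP(s) dropped (logistic fit failed): ",
            paste(ids[!keep], collapse = ", "))
  tab <- as_gwas_table(data.frame(
    snp_id = ids[keep], chrom = chrom,
    pos = as.integer(positions[keep]),
    effect_allele = "A", other_allele = "G",
    z = z[keep], n = n, stringsAsFactors = FALSE))
  R <- ld_from_panel(G_std[, keep, drop = FALSE])
  list(gwas = tab, ld = R)
}

#' Individual-level modality score test (oracle route)
#'
#' Computes the modality-level statistic directly from individual-level
#' matrices, bypassing summary statistics entirely: Stage-1 OLS weights, the
#' imputed-IDP score `S = A1'G'(I - P)y / n` with `P` the projection onto the
#' adjustment design (imputed other-modality IDPs and the genotype burden),
#' and the plug-in covariance `var(y) * A1'G'(I - P)G A1 / n^2`. Continuous
#' traits only; used as the independent cross-check of the summary path.
#'
#' @param G_std column-standardized genotype matrix.
#' @param M1 tested-modality IDP matrix (columns standardized internally).
#' @param M_other list of other-modality IDP matrices (may be empty).
#' @param y continuous trait vector.
#' @param adjust_other,adjust_direct adjustment switches, as in
#'   [modality_test()].
#' @param p_method p-value method for [mixture_chisq_pvalue()].
#' @param seed Monte Carlo seed, if needed.
#' @return list with `S`, `cov_S`, `eigenvalues`, `T`, `p_value`, `p_method`.
#' @export
individual_level_test <- function(G_std, M1, M_other = list(), y,
                                  adjust_other = TRUE, adjust_direct = TRUE,
                                  p_method = "auto", seed = NULL) {
  n <- nrow(G_std)
  GtG <- crossprod(G_std)
  ols <- function(M) solve(GtG, crossprod(G_std, scale(M)))
  A1 <- ols(M1)
  Mhat1 <- G_std %*% A1
  design <- NULL
  if (adjust_other && length(M_other))
    design <- do.call(cbind, lapply(M_other, function(M) G_std %*% ols(M)))
  if (adjust_direct)
    design <- cbind(design, rowSums(G_std))
  if (is.null(design)) {
    resid_y <- y
    M1r <- Mhat1
  } else {
    qd <- qr(design)
    resid_y <- qr.resid(qd, y)
    M1r <- qr.resid(qd, Mhat1)
  }
  S <- drop(crossprod(Mhat1, resid_y)) / n
  covS <- stats::var(y) * crossprod(M1r) / n^2
  covS <- (covS + t(covS)) / 2
  lam <- .eigen_weights(covS)
  Tstat <- test_statistic(S)
  pv <- mixture_chisq_pvalue(Tstat, lam, method = p_method, seed = seed)
  list(S = S, cov_S = covS, eigenvalues = lam, T = Tstat,
       p_value = pv$p, p_method = pv$method)
}
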