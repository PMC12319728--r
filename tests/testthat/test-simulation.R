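# The generative model: correlated binary genotypes, confounded IDPs, traits,
# derived summary statistics, and the summary/individual-level equivalence.

test_that("sim_params validates the scenario/tau coupling", {
  p <- sim_params()
  expect_s3_class(p, "miwas_sim_params")
  expect_equal(p$scenario, "null")
  expect_error(sim_params(tau = 0.1), "tau = 0")
  expect_error(sim_params(scenario = "dense"), "tau > 0")
  expect_error(sim_params(maf = 0.6), "maf")
  expect_silent(sim_params(scenario = "sparse", tau = 0.2))
  expect_output(print(p), "Simulation parameters")
})

test_that("genotype generator hits marginal frequency, LD target and shape", {
  g <- gen_genotype_matrix(20000, 12, maf = 0.3, ld_rho = 0, seed = 5)
  expect_true(all(g$raw %in% c(0, 1)))
  expect_equal(dim(g$raw), c(20000, 12))
  freq <- colMeans(g$raw)
  expect_true(all(abs(freq - 0.3) < 3 * sqrt(0.3 * 0.7 / 20000) + 0.005))
  offdiag <- cor(g$raw); diag(offdiag) <- 0
  expect_lt(max(abs(offdiag)), 0.03)

  # strong AR target recovered from a large sample
  g9 <- gen_genotype_matrix(20000, 6, maf = 0.3, ld_rho = 0.9, seed = 6)
  adj <- sapply(1:5, function(j) cor(g9$raw[, j], g9$raw[, j + 1]))
  expect_true(all(abs(adj - 0.9) < 0.02))

  # standardization is exact in sample moments
  expect_lt(max(abs(colMeans(g$std))), 1e-12)
  expect_lt(max(abs(apply(g$std, 2, var) - 1)), 1e-12)

  # haplotype-sum option produces 0/1/2 dosages
  g2 <- gen_genotype_matrix(2000, 4, maf = 0.3, ld_rho = 0.5, seed = 7,
                            haplotype_sum = TRUE)
  expect_true(all(g2$raw %in% c(0, 1, 2)))
})

test_that("latent structure solves binary correlations and clips infeasible ones", {
  st <- latent_binary_ld(5, 0.3, 0.5)
  # latent correlations exceed the induced binary ones for thresholded normals
  expect_true(all(st$latent_corr[1:2] > c(0.5, 0.25)))
  # round trip: the latent value reproduces the target binary correlation
  r1 <- miwas:::.binary_corr(st$latent_corr[1], st$threshold, 0.3)
  expect_equal(r1, 0.5, tolerance = 1e-8)
  # an infeasible negative target (below the Frechet bound) is clipped
  expect_message(latent_binary_ld(2, 0.1, -0.99), "clipped")
})

test_that("IDP generator composes genetic, confounder and noise parts", {
  p <- small_params(sd_delta = 2)
  set.seed(3)
  u <- rnorm(p$n)
  G <- gen_genotype_matrix(p$n, p$J, p$maf, p$ld_rho, seed = 4)$raw
  # degenerate: no genetic or confounder signal leaves pure noise
  p0 <- small_params(sd_alpha = 0, sd_gamma = 0, sd_delta = 2)
  M0 <- gen_idp_matrix(G, u, p0, seed = 5)
  expect_equal(mean(apply(M0, 2, var)), 4, tolerance = 0.4)
  expect_equal(max(abs(attr(M0, "alpha"))), 0)

  # parameter recovery: OLS on (G, u) recovers alpha and gamma
  pr <- sim_params(n = 50000, J = 10, K = 4)
  Gr <- gen_genotype_matrix(pr$n, pr$J, pr$maf, pr$ld_rho, seed = 8)$raw
  ur <- rnorm(pr$n)
  Mr <- gen_idp_matrix(Gr, ur, pr, seed = 9)
  X <- cbind(1, Gr, ur)
  coefs <- qr.coef(qr(X), Mr)
  rmse_alpha <- sqrt(mean((coefs[2:(pr$J + 1), ] - attr(Mr, "alpha"))^2))
  rmse_gamma <- sqrt(mean((coefs[pr$J + 2, ] - attr(Mr, "gamma"))^2))
  expect_lt(rmse_alpha, 0.09)
  expect_lt(rmse_gamma, 0.06)
})

test_that("trait generator follows scenario semantics and the logistic link", {
  p <- small_params()
  set.seed(11)
  d <- simulate_dataset(p)
  expect_equal(d$beta1, rep(0, p$K))

  ps <- small_params(scenario = "sparse", tau = 0.3)
  ds <- simulate_dataset(ps, seed = 12)
  expect_equal(ds$beta1[-1], rep(0, ps$K - 1))
  expect_false(ds$beta1[1] == 0)

  pd <- small_params(scenario = "dense", tau = 0.3)
  dd <- simulate_dataset(pd, seed = 13)
  expect_true(all(dd$beta1 != 0))

  # intercept-only logistic model: prevalence = 1/(1 + e^2)
  p0 <- sim_params(n = 50000, J = 8, K = 2, Q = 2, trait_type = "binary",
                   mu = 0, theta = 0, sd_alpha = 0, sd_gamma = 0,
                   sd_beta2 = 0)
  d0 <- simulate_dataset(p0, seed = 14)
  expect_lt(abs(mean(d0$y) - 1 / (1 + exp(2))), 0.005)
  expect_true(all(d0$y %in% c(0, 1)))
})

test_that("derived summary statistics are calibrated under the null", {
  # trait independent of genotypes: z approximately standard normal
  set.seed(21)
  zs <- unlist(lapply(1:50, function(i) {
    G <- gen_genotype_matrix(800, 10, 0.3, 0.5)$std
    y <- rnorm(800)
    individual_to_sumstats(G, y, model = "linear")$gwas$z
  }))
  expect_lt(abs(mean(zs)), 0.1)
  expect_lt(abs(var(zs) - 1), 0.25)

  # perfect association: z grows with n and keeps the sign
  G <- gen_genotype_matrix(500, 3, 0.3, 0, seed = 22)$std
  y <- G[, 1]
  ss <- individual_to_sumstats(G, y, model = "linear")
  expect_gt(ss$gwas$z[1], 100)
  expect_equal(unname(diag(ss$ld)), rep(1, 3))
})

test_that("vectorized logistic Wald z matches glm", {
  set.seed(31)
  G <- gen_genotype_matrix(400, 4, 0.3, 0.4)$std
  y <- rbinom(400, 1, plogis(-1 + 0.5 * G[, 2]))
  z_fast <- miwas:::.z_logistic_wald(G, y)
  z_glm <- apply(G, 2, function(g)
    summary(glm(y ~ g, family = binomial()))$coefficients["g", "z value"])
  expect_equal(unname(z_fast), unname(z_glm), tolerance = 1e-6)
})

test_that("summary path reproduces the individual-level statistic exactly", {
  # continuous trait, no screening: score-form summaries give identical p
  p <- small_params()
  d <- simulate_dataset(p, seed = 41)
  n <- p$n
  G <- d$G_std
  R <- crossprod(G) / (n - 1); diag(R) <- 1

  # summary route built only from z-scores and R
  b1 <- cor(G, scale(d$M[[1]]))
  b2 <- cor(G, scale(d$M[[2]]))
  A1 <- joint_weights(b1, R)
  A2 <- cbind(joint_weights(b2, R), 1)
  z_dis <- individual_to_sumstats(G, d$y, model = "linear",
                                  z_method = "score")$gwas$z
  S_sum <- score_vector(A1, A2, R, z_dis)
  C_sum <- cov_score(A1, A2, R)
  lam <- pmax(eigen(C_sum, symmetric = TRUE, only.values = TRUE)$values, 0)
  p_sum <- mixture_chisq_pvalue(test_statistic(S_sum), lam, seed = 1)$p

  # individual route from raw matrices only (same p-value policy and seed)
  ind <- individual_level_test(G, d$M[[1]], list(d$M[[2]]), d$y, seed = 1)
  expect_lt(abs(ind$p_value - p_sum), 1e-8)
  # the two score vectors agree up to one global scale factor
  ratio <- S_sum / ind$S
  expect_lt(diff(range(ratio)), 1e-8 * abs(mean(ratio)))
})

test_that("experiment drivers report rates with Monte Carlo uncertainty", {
  p <- small_params()
  # degenerate replicate count: the rate is 0 or 1
  r1 <- run_null_experiment(p, n_reps = 1, methods = 1, seed = 3)
  expect_true(all(r1$rate[r1$method == 1] %in% c(0, 1)))

  r <- run_null_experiment(p, n_reps = 40, methods = c(1, 4), seed = 4)
  expect_s3_class(r, "miwas_null_exp")
  expect_equal(sort(unique(r$level)), c(0.01, 0.05))
  expect_true(all(r$rate >= 0 & r$rate <= 1))
  expect_true(all(r$mc_se >= 0))
  P <- attr(r, "p_values")
  expect_equal(dim(P), c(40, 4))
  expect_true(all(is.na(P[, c("2", "3")])))
  # reproducible with the same seed
  r2 <- run_null_experiment(p, n_reps = 40, methods = c(1, 4), seed = 4)
  expect_equal(attr(r2, "p_values"), P)

  pw <- run_power_experiment(small_params(), tau_grid = c(0, 0.4),
                             scenarios = "dense", n_reps = 12, seed = 5)
  expect_s3_class(pw, "miwas_power_exp")
  expect_equal(nrow(pw), 4)  # 2 methods x 2 tau
  expect_true(all(pw$power >= 0 & pw$power <= 1))
  expect_output(print(pw), "Empirical power")
})
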