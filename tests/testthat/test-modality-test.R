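# The modality-level score test: score vector, covariance, statistic,
# assembly, comparators, and their algebraic properties.

test_that("score_vector reduces correctly with and without adjustment", {
  R <- diag(2); z <- c(1, 2)
  A1 <- matrix(c(1, 0), 2, 1)
  A2 <- matrix(c(0, 1), 2, 1)
  # orthogonal adjustment leaves the tested projection: S = 1
  expect_equal(score_vector(A1, A2, R, z), 1)
  # no adjustment: S = A1'z
  expect_equal(score_vector(A1, NULL, R, z), 1)
  set.seed(2)
  A1b <- matrix(rnorm(6), 3, 2)
  zb <- rnorm(3)
  expect_equal(score_vector(A1b, NULL, diag(3), zb), drop(crossprod(A1b, zb)))
  # testing a column that is itself adjusted annihilates the score
  a <- matrix(c(0.3, 0.7), 2, 1)
  Rc <- matrix(c(1, 0.4, 0.4, 1), 2)
  expect_equal(score_vector(a, a, Rc, c(1.5, -2)), 0)
})

test_that("cov_score projection algebra holds", {
  set.seed(4)
  R <- 0.5^abs(outer(1:4, 1:4, "-"))
  A1 <- matrix(rnorm(4), 4, 1)
  # no adjustment: A1' R A1
  expect_equal(cov_score(A1, NULL, R), crossprod(A1, R %*% A1))
  # adjustment R-orthogonal to A1 leaves the covariance unchanged
  A2 <- matrix(rnorm(4), 4, 1)
  A2perp <- A2 - A1 %*% solve(crossprod(A1, R %*% A1),
                              crossprod(A1, R %*% A2))
  expect_equal(crossprod(A1, R %*% A2perp)[1, 1], 0, tolerance = 1e-12)
  expect_equal(cov_score(A1, A2perp, R), crossprod(A1, R %*% A1),
               tolerance = 1e-10)
  # tested column inside span(A2): covariance collapses to zero
  A2span <- cbind(2 * A1, rnorm(4))
  expect_equal(max(abs(cov_score(A1, A2span, R))), 0, tolerance = 1e-10)
})

test_that("test_statistic is the squared norm and T decomposes on eigenbasis", {
  expect_equal(test_statistic(1), 1)
  expect_equal(test_statistic(c(3, 4)), 25)
  expect_equal(test_statistic(2 * c(3, 4)), 4 * 25)
  set.seed(8)
  # T equals the sum of squared projections of S on the eigenvectors of cov(S)
  R <- 0.6^abs(outer(1:6, 1:6, "-"))
  A1 <- matrix(rnorm(18), 6, 3)
  A2 <- matrix(rnorm(12), 6, 2)
  z <- rnorm(6)
  S <- score_vector(A1, A2, R, z)
  C <- cov_score(A1, A2, R)
  V <- eigen(C, symmetric = TRUE)$vectors
  expect_equal(test_statistic(S), sum(drop(crossprod(V, S))^2))
})

test_that("scaling the tested weights rescales T and eigenvalues, not p", {
  set.seed(12)
  R <- 0.5^abs(outer(1:8, 1:8, "-"))
  A1 <- matrix(rnorm(8 * 6, 0, 0.3), 8, 6)
  A2 <- cbind(matrix(rnorm(8 * 2, 0, 0.3), 8, 2), 1)
  z <- rnorm(8)
  base_S <- score_vector(A1, A2, R, z)
  base_C <- cov_score(A1, A2, R)
  base_lam <- eigen(base_C, symmetric = TRUE, only.values = TRUE)$values
  for (c0 in c(0.1, 3, 50)) {
    S <- score_vector(c0 * A1, A2, R, z)
    C <- cov_score(c0 * A1, A2, R)
    lam <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(test_statistic(S), c0^2 * test_statistic(base_S),
                 tolerance = 1e-10)
    expect_equal(lam, c0^2 * base_lam, tolerance = 1e-10)
    expect_equal(mixture_chisq_pvalue(test_statistic(S), pmax(lam, 0),
                                      seed = 1)$p,
                 mixture_chisq_pvalue(test_statistic(base_S),
                                      pmax(base_lam, 0), seed = 1)$p,
                 tolerance = 1e-9)
  }
})

# small weight-matrix setup reused below
toy_weights <- function(J = 8, K1 = 3, K2 = 2, seed = 77) {
  set.seed(seed)
  ids <- sprintf("rs%02d", 1:J)
  R <- toy_ld(0.5^abs(outer(1:J, 1:J, "-")), ids)
  W1 <- matrix(rnorm(J * K1, 0, 0.3), J, K1,
               dimnames = list(ids, paste0("s", 1:K1)))
  W2 <- matrix(rnorm(J * K2, 0, 0.3), J, K2,
               dimnames = list(ids, paste0("d", 1:K2)))
  z <- setNames(rnorm(J), ids)
  list(w = list(sMRI = W1, dMRI = W2), R = R, z = z)
}

test_that("modality_test assembles the full pipeline with provenance", {
  tw <- toy_weights()
  res <- modality_test(tw$w, tw$z, tw$R, "sMRI", gene_id = "g1", seed = 3)
  expect_s3_class(res, "miwas_test")
  expect_equal(res$K1, 3)
  expect_equal(res$n_snps, 8)
  expect_gte(res$T, 0)
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  expect_equal(length(res$eigenvalues), 3)
  expect_true(all(diff(res$eigenvalues) <= 1e-12))
  # determinism with identical inputs and seed
  res2 <- modality_test(tw$w, tw$z, tw$R, "sMRI", gene_id = "g1", seed = 3)
  expect_identical(res, res2)
  # unadjusted configuration reduces to S = A1'z
  res0 <- modality_test(tw$w, tw$z, tw$R, "sMRI", adjust_other = FALSE,
                        adjust_direct = FALSE, seed = 3)
  expect_equal(res0$S, drop(crossprod(tw$w$sMRI, unname(tw$z[rownames(tw$w$sMRI)]))))
  expect_output(print(res), "Modality-level")
})

test_that("a modality with no surviving IDPs yields a no-test result", {
  tw <- toy_weights()
  tw$w$sMRI <- tw$w$sMRI[, 0, drop = FALSE]
  expect_message(res <- modality_test(tw$w, tw$z, tw$R, "sMRI"), "no surviving")
  expect_equal(res$p_method, "no_test")
  expect_true(is.na(res$p_value))
})

test_that("K1 = 1 modality test equals the two-sided Gaussian score test", {
  tw <- toy_weights(K1 = 1)
  res <- modality_test(tw$w, tw$z, tw$R, "sMRI", seed = 5)
  S <- score_vector(tw$w$sMRI,
                    cbind(tw$w$dMRI, 1), tw$R, unname(tw$z))
  C <- cov_score(tw$w$sMRI, cbind(tw$w$dMRI, 1), tw$R)
  p_gauss <- 2 * pnorm(-abs(unname(S) / sqrt(C[1, 1])))
  expect_equal(res$p_value, p_gauss, tolerance = 1e-12)
  expect_equal(res$p_method, "exact_chisq")
})

test_that("univariate comparators follow their configuration", {
  tw <- toy_weights()
  adj <- idp_specific_test(tw$w, tw$z, tw$R, "sMRI", adjusted = TRUE, seed = 1)
  expect_equal(nrow(adj), 3)
  expect_equal(attr(adj, "bonferroni_threshold"), 0.05 / 3)
  # unadjusted univariate IWAS on identity LD: T = (a'z)^2, lambda = a'a
  J <- 5
  ids <- sprintf("q%d", 1:J)
  a <- matrix(rnorm(J), J, 1, dimnames = list(ids, "only"))
  z <- setNames(rnorm(J), ids)
  w1 <- list(m1 = a, m2 = matrix(0, J, 0, dimnames = list(ids, NULL)))
  un <- idp_specific_test(w1, z, toy_ld(diag(J), ids), "m1",
                          adjusted = FALSE, seed = 1)
  expect_equal(un$T, as.numeric(crossprod(a, z))^2)
  expect_equal(un$p_value,
               pchisq(un$T / sum(a^2), 1, lower.tail = FALSE))
  # a single-IDP modality: the adjusted univariate test IS the modality test
  tw1 <- toy_weights(K1 = 1)
  one <- idp_specific_test(tw1$w, tw1$z, tw1$R, "sMRI", adjusted = TRUE,
                           seed = 2)
  full <- modality_test(tw1$w, tw1$z, tw1$R, "sMRI", seed = 2)
  expect_equal(one$p_value, full$p_value)
  expect_equal(one$T, full$T)
})

test_that("per-IDP p-values are invariant to adjustment column order", {
  tw <- toy_weights(K2 = 4, seed = 99)
  base <- idp_specific_test(tw$w, tw$z, tw$R, "sMRI", seed = 1)
  perm <- tw
  perm$w$dMRI <- perm$w$dMRI[, c(3, 1, 4, 2)]
  shuf <- idp_specific_test(perm$w, perm$z, perm$R, "sMRI", seed = 1)
  expect_equal(shuf$p_value, base$p_value, tolerance = 1e-10)
})

test_that("collinear adjustment columns are dropped with a warning", {
  tw <- toy_weights()
  tw$w$dMRI <- cbind(tw$w$dMRI, dup = tw$w$dMRI[, 1])
  expect_warning(res <- modality_test(tw$w, tw$z, tw$R, "sMRI", seed = 1),
                 "collinear")
  expect_equal(length(res$dropped_adjust), 1)
  expect_true(is.finite(res$p_value))
})

test_that("bonferroni_adjust uses a strict threshold", {
  out <- bonferroni_adjust(c(0.004, 0.005, 0.02), alpha = 0.05, m = 10)
  expect_equal(out$threshold, 0.005)
  expect_equal(out$significant, c(TRUE, FALSE, FALSE))
  expect_equal(bonferroni_adjust(0.04, 0.05, m = 1)$threshold, 0.05)
  expect_error(bonferroni_adjust(0.5, m = 0), "m must be")
})
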