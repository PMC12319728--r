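# P-values for positively weighted mixtures of 1-df chi-square variables,
# Pr(sum_k lambda_k * chisq_1 > q). Three routes: Davies-type numerical
# inversion of the characteristic function (Imhof's integral), Liu-Tang-Zhang
# moment matching to a noncentral chi-square, and Monte Carlo with the
# (1 + hits)/(1 + draws) estimator. The `auto` policy follows the test's
# published usage: numerical inversion when more than 5 eigenvalues remain,
# Monte Carlo otherwise, Liu as fallback when the inversion misbehaves; the
# all-equal-eigenvalue case collapses analytically to a scaled K-df chi-square
# and is computed exactly.

#' Davies-type numerical inversion (Imhof's integral)
#'
#' Computes `Pr(sum lambda_k chisq_1k > q)` by numerical inversion of the
#' characteristic function,
#' `p = 1/2 + (1/pi) * int_0^inf sin(theta(u)) / (u rho(u)) du` with
#' `theta(u) = sum_k atan(lambda_k u)/2 - q u / 2` and
#' `rho(u) = prod_k (1 + lambda_k^2 u^2)^{1/4}`. The integrand oscillates with
#' a polynomially decaying envelope, so the integral is evaluated adaptively
#' up to the first sign change of `sin(theta)` past theta's maximum and then
#' as an alternating series of half-cycle segments between successive zeros,
#' summed with iterated Euler averaging when the envelope decays slowly.
#'
#' @param q observed statistic (scalar, `>= 0`).
#' @param lambda positive mixture weights.
#' @return the upper-tail probability, or `NA` if the quadrature fails or
#'   leaves `[0, 1]`.
#' @export
imhof_pvalue <- function(q, lambda) {
  if (q <= 0) return(1)
  theta1 <- function(u) 0.5 * sum(atan(lambda * u)) - 0.5 * q * u
  f <- function(u) {
    out <- numeric(length(u))
    tiny <- u < 1e-12
    out[tiny] <- (sum(lambda) - q) / 2
    ub <- u[!tiny]
    th <- 0.5 * colSums(atan(outer(lambda, ub))) - 0.5 * q * ub
    lr <- 0.25 * colSums(log1p(outer(lambda^2, ub^2)))
    out[!tiny] <- sin(th) * exp(-lr) / ub
    out
  }
  quad <- function(lo, hi)
    stats::integrate(f, lo, hi, rel.tol = 1e-11, abs.tol = 1e-14,
                     subdivisions = 500L)$value
  # maximizer of theta (theta' is strictly decreasing)
  dtheta <- function(u) 0.5 * sum(lambda / (1 + (lambda * u)^2)) - 0.5 * q
  u_star <- 0
  if (dtheta(0) > 0) {
    hi <- 1
    while (dtheta(hi) > 0) hi <- hi * 2
    u_star <- stats::uniroot(dtheta, c(0, hi), tol = 1e-12)$root
  }
  # successive solutions of theta(u) = -j*pi beyond u_star (theta decreasing
  # there); segment boundaries where sin(theta) changes sign
  next_root <- function(target, lo) {
    hi <- max(lo, u_star) + 1
    while (theta1(hi) > target) hi <- lo + (hi - lo) * 2
    stats::uniroot(function(u) theta1(u) - target, c(lo, hi),
                   tol = 1e-13)$root
  }
  val <- tryCatch({
    c0 <- if (theta1(0) >= 0 && u_star > 0) next_root(0, u_star) else 0
    total <- if (c0 > 0) quad(0, c0) else 0
    terms <- numeric(0)
    lo <- c0
    max_seg <- 120L
    for (j in seq_len(max_seg)) {
      hi <- next_root(-j * pi, lo)
      t_j <- quad(lo, hi)
      terms <- c(terms, t_j)
      lo <- hi
      if (abs(t_j) < 1e-14) break
    }
    if (abs(terms[length(terms)]) < 1e-14) {
      total + sum(terms)
    } else {
      # iterated Euler averaging of the alternating tail
      ps <- cumsum(terms)
      while (length(ps) > 1) ps <- (ps[-1] + ps[-length(ps)]) / 2
      total + ps
    }
  }, error = function(e) NA_real_)
  if (!is.finite(val)) return(NA_real_)
  p <- 0.5 + val / pi
  if (p <= 0 || p > 1) NA_real_ else p
}

#' Liu-Tang-Zhang moment-matching approximation
#'
#' Matches the first moments and skewness/kurtosis of the mixture to a single
#' (non)central chi-square and evaluates its survival function.
#'
#' @inheritParams imhof_pvalue
#' @return the approximate upper-tail probability.
#' @export
liu_pvalue <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    l <- 1 / s2
    a <- sqrt(l)
    d <- 0
  }
  mu_q <- c1; sigma_q <- sqrt(2 * c2)
  mu_x <- l + d; sigma_x <- sqrt(2) * a
  stats::pchisq((q - mu_q) / sigma_q * sigma_x + mu_x, df = l, ncp = d,
                lower.tail = FALSE)
}

.mc_mixture_pvalue <- function(q, lambda, mc_draws, chunk = 1e5) {
  hits <- 0
  left <- mc_draws
  K <- length(lambda)
  while (left > 0) {
    m <- min(chunk, left)
    draws <- matrix(stats::rnorm(m * K)^2, m, K) %*% lambda
    hits <- hits + sum(draws >= q)
    left <- left - m
  }
  (1 + hits) / (1 + mc_draws)
}

#' P-value of a weighted mixture of 1-df chi-squares
#'
#' Computes `Pr(sum_k lambda_k chisq_1k > q)`. Eigenvalues below
#' `1e-12 * max(lambda)` are discarded first. Method `"auto"` uses the exact
#' scaled chi-square survival function when all retained eigenvalues are equal,
#' Davies-type numerical inversion when more than 5 eigenvalues remain, and
#' Monte Carlo otherwise; Liu moment matching is the fallback whenever the
#' inversion fails or returns a value outside (0, 1].
#'
#' @param q observed statistic, `>= 0`.
#' @param lambda nonnegative mixture weights (eigenvalues of the score
#'   covariance), not all zero.
#' @param method one of `"auto"`, `"davies"`, `"liu"`, `"monte_carlo"`,
#'   `"exact_chisq"` (the last requires all-equal eigenvalues).
#' @param mc_draws Monte Carlo sample size (default 1e6); the estimator is
#'   `(1 + hits) / (1 + draws)` so the p-value is never exactly 0.
#' @param seed integer seed, required for any Monte Carlo path.
#' @return list with `p`, `method` (the method actually used) and, for Monte
#'   Carlo, `mc_draws`. A degenerate test (all eigenvalues zero) returns
#'   `p = NA` and `method = "no_test"`.
#' @export
mixture_chisq_pvalue <- function(q, lambda,
                                 method = c("auto", "davies", "liu",
                                            "monte_carlo", "exact_chisq"),
                                 mc_draws = 1e6, seed = NULL) {
  method <- match.arg(method)
  if (q < 0) stop("statistic q must be nonnegative")
  if (any(lambda < -1e-8)) stop("negative eigenvalue beyond tolerance")
  lambda <- pmax(lambda, 0)
  if (all(lambda == 0)) return(list(p = NA_real_, method = "no_test"))
  lambda <- lambda[lambda > 1e-12 * max(lambda)]
  K <- length(lambda)
  equal <- (max(lambda) - min(lambda)) <= 1e-9 * max(lambda)

  if (method == "exact_chisq" && !equal)
    stop("exact_chisq requires all-equal eigenvalues")
  if (method == "auto")
    method <- if (equal) "exact_chisq" else if (K > 5) "davies" else "monte_carlo"

  if (method == "exact_chisq")
    return(list(p = stats::pchisq(q / lambda[1], df = K, lower.tail = FALSE),
                method = "exact_chisq"))
  if (method == "davies") {
    p <- imhof_pvalue(q, lambda)
    if (is.na(p)) return(list(p = liu_pvalue(q, lambda), method = "liu"))
    return(list(p = p, method = "davies"))
  }
  if (method == "liu")
    return(list(p = liu_pvalue(q, lambda), method = "liu"))
  # monte_carlo
  if (is.null(seed)) stop("a seed is required for the Monte Carlo p-value")
  set.seed(seed)
  list(p = .mc_mixture_pvalue(q, lambda, mc_draws),
       method = "monte_carlo", mc_draws = mc_draws)
}
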