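#' Fit the beta model of the allele-frequency spectrum
#'
#' The risk model assumes the panel's alternate-allele frequencies follow a
#' beta distribution with shape parameters written \eqn{(a', b')}; the
#' closed-form no-allele probability [compute_dn()] then uses the shifted
#' shapes \eqn{a = a' + 1}, \eqn{b = b' + 1}. `fit_beta()` estimates
#' \eqn{(a', b')} from a frequency sample.
#'
#' Two estimators are provided. `"moments"` (the default) matches the first
#' two sample moments; it is the estimator that reproduces the published
#' parameter tables for neutral site-frequency spectra, whose \eqn{1/f}-like
#' density a two-parameter beta can only approximate (the maximum-likelihood
#' fit of such a spectrum is pulled toward the boundary and lands elsewhere).
#' `"mle"` is the exact maximum-likelihood fit (BFGS on the log shapes,
#' gradient tolerance 1e-8), preferable when the sample really is
#' beta-distributed.
#'
#' @param f Numeric vector of frequencies in (0, 1), or an [snp_panel].
#' @param method `"moments"` or `"mle"`.
#' @return An object of class `beta_params`: list with `a_prime`, `b_prime`,
#'   `a`, `b`, `method`, `n`.
#' @export
#' @examples
#' fit_beta(rbeta(10000, 2, 5), method = "mle")
fit_beta <- function(f, method = c("moments", "mle")) {
  method <- match.arg(method)
  if (inherits(f, "snp_panel")) f <- f$f
  f <- as.numeric(f)
  if (length(f) < 2 || any(!is.finite(f)) || any(f <= 0) || any(f >= 1)) {
    abort("`f` must hold at least 2 frequencies strictly inside (0, 1)")
  }
  if (stats::var(f) == 0) abort("degenerate sample: all frequencies equal")
  mu <- mean(f); v <- stats::var(f)
  if (v >= mu * (1 - mu)) {
    abort("sample variance too large for a beta model")
  }
  k <- mu * (1 - mu) / v - 1
  mom <- c(a = mu * k, b = (1 - mu) * k)
  est <- mom
  if (method == "mle") {
    s1 <- mean(log(f)); s2 <- mean(log1p(-f))
    nll <- function(p) {
      a <- exp(p[1]); b <- exp(p[2])
      lbeta(a, b) - (a - 1) * s1 - (b - 1) * s2
    }
    grad <- function(p) {
      a <- exp(p[1]); b <- exp(p[2])
      dab <- digamma(a + b)
      c(a * (digamma(a) - dab - s1), b * (digamma(b) - dab - s2))
    }
    fit <- stats::optim(log(pmax(mom, 1e-3)), nll, grad, method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 500))
    if (max(abs(grad(fit$par))) > 1e-8 * (1 + abs(fit$value))) {
      warn("beta MLE gradient did not reach the 1e-8 tolerance")
    }
    est <- exp(fit$par)
  }
  structure(
    list(a_prime = unname(est[1]), b_prime = unname(est[2]),
         a = unname(est[1]) + 1, b = unname(est[2]) + 1,
         method = method, n = length(f)),
    class = "beta_params"
  )
}

#' Construct beta parameters directly
#'
#' Wraps known shape parameters \eqn{(a', b')} -- e.g. the published values
#' for a reference panel -- into the object [fit_beta()] would return.
#'
#' @param a_prime,b_prime Positive beta shape parameters of the frequency
#'   spectrum.
#' @return A `beta_params` object.
#' @export
beta_params <- function(a_prime, b_prime) {
  if (a_prime < 0 || b_prime < 0) abort("shape parameters must be non-negative")
  structure(list(a_prime = a_prime, b_prime = b_prime,
                 a = a_prime + 1, b = b_prime + 1,
                 method = "given", n = NA_integer_),
            class = "beta_params")
}

#' @export
print.beta_params <- function(x, ...) {
  cat(sprintf("<beta_params> a' = %.7g, b' = %.7g (%s)\n",
              x$a_prime, x$b_prime, x$method))
  invisible(x)
}

#' @export
tidy.beta_params <- function(x, ...) {
  tibble(term = c("a_prime", "b_prime"),
         estimate = c(x$a_prime, x$b_prime),
         method = x$method)
}

#' The no-allele probability D_N
#'
#' `D_N` is the probability that none of `N` genomes carries the alternate
#' allele at a site where the queried individual carries it. Under the beta
#' spectrum model it is approximated in closed form as
#' \deqn{D_N \approx \frac{\Gamma(a+b)}{\Gamma(b)\,(2N+a+b)^a}}
#' with \eqn{a = a'+1}, \eqn{b = b'+1} (the shift reflects that queried
#' sites are the ones the target carries, which size-biases the frequency).
#' Evaluated in log space so large `N` cannot overflow. `D_0` is defined as
#' 1: with no other genome, the allele is certainly absent.
#'
#' @param N Number of genomes (vectorized, each >= 0).
#' @param params A `beta_params` object.
#' @return Numeric vector of probabilities, strictly decreasing in `N`.
#' @export
#' @examples
#' compute_dn(100, beta_params(0.1848, 0.85))
compute_dn <- function(N, params) {
  stopifnot(inherits(params, "beta_params"))
  if (any(N < 0) || any(N != floor(N))) abort("`N` must be non-negative integers")
  a <- params$a; b <- params$b
  out <- exp(lgamma(a + b) - lgamma(b) - a * log(2 * N + a + b))
  out[N == 0] <- 1
  out
}

#' Exact beta expectation of the no-allele probability
#'
#' The quantity [compute_dn()] approximates, evaluated exactly:
#' \eqn{E_{f\sim Beta(a,b)}[(1-f)^{2N}] = B(a, b+2N)/B(a, b)} (log-beta
#' form). Used as the independent oracle for the approximation quality.
#'
#' @inheritParams compute_dn
#' @return Numeric vector.
#' @export
exact_dn <- function(N, params) {
  stopifnot(inherits(params, "beta_params"))
  a <- params$a; b <- params$b
  out <- exp(lbeta(a, b + 2 * N) - lbeta(a, b))
  out[N == 0] <- 1
  out
}

#' Expected query budget
#'
#' The number of beacon queries the adversary is expected to need for a
#' beacon of `N` members: \eqn{n \sim N^{a'+1}}. Returned unrounded; callers
#' floor it when an integer budget is required.
#'
#' @inheritParams compute_dn
#' @return Numeric vector.
#' @export
expected_queries <- function(N, params) {
  stopifnot(inherits(params, "beta_params"))
  if (any(N < 1)) abort("`N` must be >= 1")
  N^(params$a_prime + 1)
}

#' Risk profile and decision threshold of a beacon
#'
#' Assembles the full closed-form risk analysis for a beacon of `N` members
#' under the beta spectrum model: the no-allele probabilities `D_N` and
#' `D_{N-1}`, the query budget `n = floor(N^(a'+1))` (overridable), the null
#' response rate `theta0 = 1 - D_N`, the alternative rate
#' `theta1 = 1 - delta * D_{N-1}`, the normal-approximation standard error
#' `sigma0 = sqrt(D_N (1-D_N) / n)` and the decision threshold
#' \deqn{t'_\alpha = \lfloor n (z \sigma_0 + \theta_0) \rfloor}
#' on the count of yes-answers. With `paper_z = TRUE` (default) and
#' `alpha = 0.05` the rounded normal quantile `z = 1.65` from the published
#' tables is used; otherwise the exact upper-`alpha` quantile.
#'
#' `t'` is reported as the minimum number of yes-answers that concludes
#' membership: fewer than `t'` yes-answers and the target is declared absent
#' (see [decide_membership()] for the two published rule readings).
#'
#' @param N Beacon member count (>= 1). For `N = 1`, `D_0 = 1` is used and
#'   the profile is flagged (`d_n1_flagged`).
#' @param params A `beta_params` object.
#' @param delta Sequencing mismatch rate in \[0, 1).
#' @param alpha False-positive level in (0, 0.5].
#' @param n Optional query budget overriding `floor(N^(a'+1))`; partial
#'   budgets stay calibrated because the threshold is recomputed at the `n`
#'   actually issued.
#' @param paper_z Use `z = 1.65` at `alpha = 0.05` (table compatibility).
#' @return An object of class `risk_profile`.
#' @export
#' @examples
#' compute_threshold(498, beta_params(0.1131, 0.8574), delta = 1e-3)
compute_threshold <- function(N, params, delta = 1e-3, alpha = 0.05,
                              n = NULL, paper_z = TRUE) {
  assert_count(N, "N")
  stopifnot(inherits(params, "beta_params"))
  assert_scalar_prob(delta, "delta", allow_one = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 0.5) {
    abort("`alpha` must be in (0, 0.5]")
  }
  d_n <- compute_dn(N, params)
  d_n1 <- compute_dn(N - 1, params)
  if (is.null(n)) n <- floor(expected_queries(N, params))
  assert_count(n, "n")
  z <- if (paper_z && isTRUE(all.equal(alpha, 0.05))) 1.65 else
    stats::qnorm(1 - alpha)
  theta0 <- 1 - d_n
  theta1 <- 1 - delta * d_n1
  sigma0 <- sqrt(d_n * (1 - d_n) / n)
  t_prime <- floor(n * (z * sigma0 + theta0))
  structure(
    list(N = as.integer(N), delta = delta, alpha = alpha, params = params,
         d_n = d_n, d_n1 = d_n1, d_n1_flagged = (N == 1),
         n = n, theta0 = theta0, theta1 = theta1, sigma0 = sigma0,
         z = z, t_alpha_prime = t_prime, t_alpha_ratio = t_prime / n),
    class = "risk_profile"
  )
}

#' @export
print.risk_profile <- function(x, ...) {
  cat(sprintf(
    "<risk_profile> N = %d, a' = %.5g, b' = %.5g, delta = %g, alpha = %g\n",
    x$N, x$params$a_prime, x$params$b_prime, x$delta, x$alpha))
  cat(sprintf("  D_N = %.8g, D_{N-1} = %.8g, n = %d, t'_alpha = %d (z = %g)\n",
              x$d_n, x$d_n1, as.integer(x$n), as.integer(x$t_alpha_prime), x$z))
  invisible(x)
}

#' @export
tidy.risk_profile <- function(x, ...) {
  tibble(
    term = c("D_N", "D_N1", "n", "theta0", "theta1", "sigma0", "z", "t_alpha_prime"),
    estimate = c(x$d_n, x$d_n1, x$n, x$theta0, x$theta1, x$sigma0, x$z,
                 x$t_alpha_prime)
  )
}

#' @export
glance.risk_profile <- function(x, ...) {
  tibble(N = x$N, a_prime = x$params$a_prime, b_prime = x$params$b_prime,
         delta = x$delta, alpha = x$alpha, d_n = x$d_n, n = x$n,
         t_alpha_prime = x$t_alpha_prime)
}

#' Risk report over several beacons
#'
#' One risk profile per row of `rows`, rendered as a tibble with the same
#' columns as the published threshold table: label, `N`, `a'`, `b'`, `D_N`,
#' `n` and `t'_alpha`. Regenerating a report is deterministic.
#'
#' @param rows Data frame with columns `label`, `N`, `a_prime`, `b_prime`.
#' @param delta,alpha,paper_z Passed to [compute_threshold()].
#' @return A tibble with one row per beacon.
#' @export
#' @examples
#' risk_report(example_beacon_params())
risk_report <- function(rows, delta = 1e-3, alpha = 0.05, paper_z = TRUE) {
  stopifnot(is.data.frame(rows))
  need <- c("label", "N", "a_prime", "b_prime")
  if (!all(need %in% names(rows))) {
    abort(sprintf("`rows` must have columns %s", paste(need, collapse = ", ")))
  }
  if (nrow(rows) == 0) {
    return(tibble(label = character(), N = integer(), a_prime = double(),
                  b_prime = double(), d_n = double(), n = double(),
                  t_alpha_prime = double()))
  }
  purrr::pmap_dfr(rows[need], function(label, N, a_prime, b_prime) {
    prof <- tryCatch(
      compute_threshold(N, beta_params(a_prime, b_prime),
                        delta = delta, alpha = alpha, paper_z = paper_z),
      error = function(e) abort(sprintf("row '%s': %s", label, conditionMessage(e)))
    )
    tibble(label = label, N = as.integer(N), a_prime = a_prime,
           b_prime = b_prime, d_n = prof$d_n, n = prof$n,
           t_alpha_prime = prof$t_alpha_prime)
  })
}

#' Published beacon parameters
#'
#' The five example beacons of the published threshold table: reference
#' panels (1000 Genomes Phase 1 full and Affymetrix subsets, GoNL, SSMP) and
#' the neutral-model simulation, each with its member count and the beta
#' shape parameters precomputed from the underlying dataset.
#'
#' @return A tibble with columns `label`, `N`, `a_prime`, `b_prime`.
#' @export
example_beacon_params <- function() {
  tibble(
    label = c("1k Genomes Phase 1", "1k Genomes Phase 1 Affymetrix",
              "GoNL", "SSMP", "Simulation"),
    N = c(1092L, 1074L, 498L, 100L, 2000L),
    a_prime = c(0.0735, 0.6483, 0.1131, 0.1848, 0.1178793),
    b_prime = c(1.0096, 1.2876, 0.8574, 0.8500, 1.1188360)
  )
}
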