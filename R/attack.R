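#' Select beacon query positions for a target
#'
#' The adversary queries the sites where the copy of the target genome they
#' hold carries at least one alternate allele. The sites are shuffled with
#' the seed (the published attack does not fix an order; a random order
#' makes partial budgets exchangeable) and truncated to the budget. If the
#' target carries fewer alternate sites than the budget, all of them are
#' returned and the shortfall is recorded.
#'
#' @param target_row Integer genotype vector (the adversary's copy).
#' @param panel The [snp_panel] the genotypes are indexed against.
#' @param budget Maximum number of queries (>= 0).
#' @param seed Optional integer seed for the shuffle.
#' @return A tibble of queries (`chrom`, `pos`, `allele`, `panel_row`) with
#'   attributes `shortfall` (queries short of the budget) and `inconclusive`
#'   (`TRUE` when the target has no alternate sites at all).
#' @export
select_query_positions <- function(target_row, panel, budget, seed = NULL) {
  stopifnot(inherits(panel, "snp_panel"))
  assert_count(budget, "budget", min = 0)
  target_row <- check_genotype_row(target_row, panel)
  alt <- which(target_row > 0L)
  inconclusive <- length(alt) == 0L
  take <- min(budget, length(alt))
  idx <- if (length(alt)) {
    with_seed_maybe(seed, sample(alt, length(alt)))[seq_len(take)]
  } else integer()
  out <- tibble(chrom = panel$chrom[idx], pos = panel$pos[idx],
                allele = "ALT", panel_row = idx)
  attr(out, "shortfall") <- as.integer(budget - take)
  attr(out, "inconclusive") <- inconclusive
  out
}

#' Collect beacon responses for a query list
#'
#' Issues the queries in order and records the yes/no answers as a 0/1
#' response vector.
#'
#' @param db A `beacon_db`.
#' @param queries A query tibble from [select_query_positions()] (or any
#'   data frame with `chrom`, `pos`, `allele`).
#' @return Integer 0/1 vector, one entry per query, order preserved.
#' @export
collect_responses <- function(db, queries) {
  stopifnot(inherits(db, "beacon_db"), is.data.frame(queries))
  if (nrow(queries) == 0) return(integer())
  as.integer(query_beacon(db, queries$chrom, queries$pos, queries$allele))
}

#' Likelihood-ratio statistics for a response vector
#'
#' Computes the two binomial log-likelihoods of the response vector -- under
#' the null (target not in the beacon: per-query yes-probability
#' \eqn{1 - D_N}) and the alternative (target in the beacon:
#' \eqn{1 - \delta D_{N-1}}) -- and the log likelihood-ratio
#' \eqn{\Lambda = L_{H_0} - L_{H_1}}, both term-by-term and in the reduced
#' linear form \eqn{\Lambda = nB + C\sum x_i} with
#' \eqn{B = \log(D_N / \delta D_{N-1})} and
#' \eqn{C = \log(\delta D_{N-1}(1-D_N) / (D_N(1-\delta D_{N-1})))}.
#' The two forms agree to floating-point accuracy; `C <= 0` whenever
#' \eqn{\delta D_{N-1} \le D_N}, which is what lets the decision reduce to a
#' threshold on \eqn{\sum x_i}.
#'
#' With `delta = 0` the alternative assigns probability zero to any "no"
#' answer; observing one then makes the in-beacon hypothesis impossible
#' (`l_h1 = -Inf`, flag `h1_impossible`) rather than raising a numeric error.
#'
#' @param x Integer 0/1 response vector.
#' @param d_n,d_n1 No-allele probabilities `D_N` and `D_{N-1}` in (0, 1).
#' @param delta Mismatch rate in \[0, 1).
#' @return An object of class `lrt_stats`.
#' @export
#' @examples
#' lrt_statistics(c(1, 1, 0, 1), d_n = 0.2, d_n1 = 0.25, delta = 0.1)
lrt_statistics <- function(x, d_n, d_n1, delta) {
  if (!all(x %in% 0:1)) abort("`x` must be a 0/1 vector")
  assert_scalar_prob(delta, "delta", allow_one = FALSE)
  if (d_n <= 0 || d_n >= 1 || d_n1 <= 0 || d_n1 >= 1) {
    abort("`d_n` and `d_n1` must lie strictly inside (0, 1)")
  }
  if (delta * d_n1 > d_n) {
    abort("`delta * d_n1` must not exceed `d_n` (decision-rule direction)")
  }
  x <- as.integer(x)
  n <- length(x); sum_x <- sum(x)
  q1 <- delta * d_n1                     # P(no | in beacon)
  l_h0 <- sum_x * log(1 - d_n) + (n - sum_x) * log(d_n)
  h1_impossible <- q1 == 0 && sum_x < n
  l_h1 <- if (q1 == 0) {
    if (h1_impossible) -Inf else 0       # all yes: sum_x * log(1) = 0
  } else {
    sum_x * log(1 - q1) + (n - sum_x) * log(q1)
  }
  if (q1 == 0) {
    B <- Inf; C <- -Inf
    lambda <- if (h1_impossible) Inf else n * log(d_n / 1) + sum_x * log((1 - d_n) / d_n) # degenerate; equals l_h0
  } else {
    B <- log(d_n / q1)
    C <- log(q1 * (1 - d_n) / (d_n * (1 - q1)))
    lambda <- n * B + C * sum_x
  }
  structure(
    list(n = n, sum_x = sum_x, r_e = if (n > 0) sum_x / n else NA_real_,
         l_h0 = l_h0, l_h1 = l_h1, B = B, C = C,
         lambda = if (is.finite(l_h1)) l_h0 - l_h1 else Inf,
         lambda_linear = lambda, h1_impossible = h1_impossible),
    class = "lrt_stats"
  )
}

#' @export
print.lrt_stats <- function(x, ...) {
  cat(sprintf("<lrt_stats> n = %d, sum_x = %d, lambda = %.6g (B = %.4g, C = %.4g)\n",
              x$n, x$sum_x, x$lambda, x$B, x$C))
  invisible(x)
}

#' Membership decision from a yes-count
#'
#' Applies the threshold rule to the attack statistics, recomputing the
#' threshold from the risk profile at the number of queries actually issued
#' (`stats$n`), so partial budgets remain calibrated.
#'
#' Two readings of the published rule are provided. `"min_yes"` (default)
#' declares membership when the yes-count reaches the threshold
#' (\eqn{\sum x_i \ge t'_\alpha}) -- the operational reading under which
#' "`t'` yes-answers are needed to conclude presence", and the only reading
#' under which the attack has power at the published budgets, where
#' \eqn{t'_\alpha} equals the full budget. `"strict"` requires
#' \eqn{\sum x_i > t'_\alpha}, the literal inequality of the threshold
#' derivation; it is conservative and degenerates to "never reject" whenever
#' \eqn{n \le z^2 (1-D_N)/D_N}, the crossover below which
#' \eqn{t'_\alpha(n) = n}.
#'
#' Targets with no queries are never declared members; the result carries
#' `inconclusive = TRUE` in that case.
#'
#' @param stats An `lrt_stats` object (or a list with `n` and `sum_x`).
#' @param profile A `risk_profile` from [compute_threshold()].
#' @param rule `"min_yes"` or `"strict"`.
#' @return Logical: `TRUE` iff the null ("not in the beacon") is rejected.
#'   Attributes: `t_alpha_prime` (threshold at the issued `n`),
#'   `inconclusive`.
#' @export
decide_membership <- function(stats, profile, rule = c("min_yes", "strict")) {
  rule <- match.arg(rule)
  stopifnot(inherits(profile, "risk_profile"))
  n <- stats$n; sum_x <- stats$sum_x
  if (n == 0) {
    return(structure(FALSE, t_alpha_prime = NA_real_, inconclusive = TRUE))
  }
  t_prime <- threshold_at(profile, n)
  reject <- if (rule == "strict") sum_x > t_prime else sum_x >= t_prime
  structure(reject, t_alpha_prime = t_prime, inconclusive = FALSE)
}

# threshold recomputed at an arbitrary issued budget n
threshold_at <- function(profile, n) {
  floor(n * profile$theta0 +
          profile$z * sqrt(n * profile$d_n * (1 - profile$d_n)))
}

#' Model-implied power of the attack
#'
#' The power the two-binomial response model predicts at a query budget `n`:
#' the upper tail of Binomial(`n`, \eqn{\theta_1}) beyond the threshold
#' recomputed at `n`, with \eqn{\theta_1 = 1 - \delta D_{N-1}}. The
#' companion quantity to the empirical power curve of
#' [run_attack_cohort()].
#'
#' @param profile A `risk_profile`.
#' @param n Query budget(s), vectorized.
#' @param rule Threshold rule as in [decide_membership()].
#' @return Numeric vector of powers in \[0, 1\].
#' @export
power_analytic <- function(profile, n, rule = c("min_yes", "strict")) {
  rule <- match.arg(rule)
  stopifnot(inherits(profile, "risk_profile"))
  if (any(n < 1)) abort("`n` must be >= 1")
  vapply(n, function(ni) {
    t_prime <- threshold_at(profile, ni)
    cut <- if (rule == "strict") t_prime else t_prime - 1
    if (cut >= ni) return(0)
    stats::pbinom(cut, ni, profile$theta1, lower.tail = FALSE)
  }, numeric(1))
}

#' Run the membership attack over a target cohort
#'
#' The full attack loop of the simulation study: for each target, degrade
#' the adversary's copy with sequencing error `delta`, select up to `budget`
#' query positions among its alternate-allele sites, collect the beacon's
#' yes/no answers and apply the threshold decision at the issued budget.
#' Cohort power is the fraction of truly-in-beacon targets declared members;
#' the type-I error is the fraction of out-of-beacon targets declared
#' members. Deterministic given `seed`.
#'
#' @param beacon A `beacon_db`.
#' @param genotypes The `genotype_matrix` the cohort is drawn from (its
#'   `panel` attribute is used for query selection and, unless `params` is
#'   given, for the attacker's beta fit).
#' @param cases Row indices of in-beacon targets (must be beacon members for
#'   the truth labels to be meaningful).
#' @param controls Row indices of out-of-beacon targets.
#' @param budgets Integer vector of query budgets to evaluate.
#' @param delta Sequencing mismatch rate applied to the adversary's copies.
#' @param alpha False-positive level of the decision threshold.
#' @param params Optional `beta_params` for the attacker's model; default is
#'   the moment fit of the panel frequencies (the adversary's assumed
#'   background knowledge).
#' @param seed Optional integer seed.
#' @param rule Decision rule, see [decide_membership()].
#' @param paper_z Use the rounded `z = 1.65` at `alpha = 0.05`.
#' @return An object of class `attack_outcome`: list with `targets` (one row
#'   per target x budget), `summary` (power / type-I error per budget with
#'   binomial standard errors) and the `risk_profile` used.
#' @export
run_attack_cohort <- function(beacon, genotypes, cases, controls, budgets,
                              delta = 1e-3, alpha = 0.05, params = NULL,
                              seed = NULL, rule = c("min_yes", "strict"),
                              paper_z = TRUE) {
  rule <- match.arg(rule)
  stopifnot(inherits(genotypes, "genotype_matrix"))
  panel <- attr(genotypes, "panel")
  rows <- rbind(genotypes[cases, , drop = FALSE],
                genotypes[controls, , drop = FALSE])
  truth <- rep(c(TRUE, FALSE), c(length(cases), length(controls)))
  ids <- c(paste0("case_", cases), paste0("control_", controls))
  copies <- t(vapply(seq_len(nrow(rows)), function(i) {
    apply_sequencing_error(rows[i, ], delta, seed = child_seed(seed, i))
  }, integer(ncol(rows))))
  attack_targets(beacon, panel, copies, truth, budgets,
                 delta = delta, alpha = alpha, params = params,
                 seed = child_seed(seed, 0L), rule = rule,
                 paper_z = paper_z, ids = ids)
}

#' Attack a set of adversary-held genome copies
#'
#' Lower-level engine behind [run_attack_cohort()]: takes the adversary's
#' copies directly (already degraded, or relatives built with
#' [make_relative()]) together with the truth labels, and evaluates the
#' attack at each budget. Useful for the relatives analysis, where the
#' adversary holds a relative's genome while the labelled target is a beacon
#' member.
#'
#' @param beacon A `beacon_db`.
#' @param panel The [snp_panel] the copies are indexed against.
#' @param copies Integer matrix, one adversary-held genome per row.
#' @param truth Logical vector: is the (true) target in the beacon?
#' @inheritParams run_attack_cohort
#' @param ids Optional target identifiers.
#' @return An `attack_outcome`, as for [run_attack_cohort()].
#' @export
attack_targets <- function(beacon, panel, copies, truth, budgets,
                           delta = 1e-3, alpha = 0.05, params = NULL,
                           seed = NULL, rule = c("min_yes", "strict"),
                           paper_z = TRUE, ids = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(beacon, "beacon_db"), inherits(panel, "snp_panel"),
            is.matrix(copies), length(truth) == nrow(copies))
  budgets <- sort(unique(as.integer(budgets)))
  if (length(budgets) == 0) abort("`budgets` must be non-empty")
  if (is.null(params)) params <- fit_beta(panel)
  profile <- compute_threshold(beacon$N, params, delta = delta, alpha = alpha,
                               paper_z = paper_z)
  if (is.null(ids)) ids <- paste0("target_", seq_len(nrow(copies)))

  # fast path: beacon catalogued in panel order (the simulated pipeline)
  aligned <- nrow(beacon$catalog) == nrow(panel) &&
    all(beacon$catalog$pos == panel$pos) &&
    all(beacon$catalog$chrom == panel$chrom) &&
    all(beacon$catalog$allele == "ALT")
  presence <- if (aligned) beacon$catalog$present else NULL
  q1 <- delta * profile$d_n1

  per_target <- purrr::map_dfr(seq_len(nrow(copies)), function(i) {
    queries <- select_query_positions(copies[i, ], panel, max(budgets),
                                      seed = child_seed(seed, i))
    x_all <- if (aligned) as.integer(presence[queries$panel_row]) else
      collect_responses(beacon, queries)
    purrr::map_dfr(budgets, function(b) {
      n_iss <- min(b, length(x_all))
      sum_x <- if (n_iss > 0) sum(x_all[seq_len(n_iss)]) else 0L
      stats <- list(n = n_iss, sum_x = sum_x)
      dec <- decide_membership(stats, profile, rule = rule)
      lambda <- if (q1 > 0 && n_iss > 0) {
        n_iss * log(profile$d_n / q1) +
          log(q1 * (1 - profile$d_n) / (profile$d_n * (1 - q1))) * sum_x
      } else NA_real_
      tibble(target = ids[i], in_beacon = truth[i], budget = b,
             n_queries = n_iss, shortfall = b - n_iss, sum_x = sum_x,
             lambda = lambda,
             t_alpha_prime = as.numeric(attr(dec, "t_alpha_prime")),
             reject = as.logical(dec),
             inconclusive = attr(dec, "inconclusive"))
    })
  })

  summary <- per_target |>
    group_by(.data$budget) |>
    summarise(
      n_cases = sum(.data$in_beacon),
      n_controls = sum(!.data$in_beacon),
      power = mean(.data$reject[.data$in_beacon]),
      type1 = mean(.data$reject[!.data$in_beacon]),
      se_power = sqrt(.data$power * (1 - .data$power) / .data$n_cases),
      se_type1 = sqrt(.data$type1 * (1 - .data$type1) / .data$n_controls),
      .groups = "drop"
    )
  structure(list(targets = per_target, summary = summary,
                 profile = profile, rule = rule),
            class = "attack_outcome")
}

#' @export
print.attack_outcome <- function(x, ...) {
  cat(sprintf("<attack_outcome> N = %d beacon, %d targets, rule = %s\n",
              x$profile$N, length(unique(x$targets$target)), x$rule))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.attack_outcome <- function(x, ...) x$summary

#' @export
glance.attack_outcome <- function(x, ...) {
  best <- x$summary[which.max(x$summary$budget), ]
  tibble(N = x$profile$N, delta = x$profile$delta, alpha = x$profile$alpha,
         max_budget = best$budget, power = best$power, type1 = best$type1)
}
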