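test_that("query selection targets alt sites, shuffles with the seed and truncates", {
  panel <- tiny_panel()
  row <- c(0L, 1L, 2L, 0L, 1L)
  q <- select_query_positions(row, panel, budget = 10, seed = 1)
  expect_setequal(q$panel_row, c(2, 3, 5))
  expect_identical(attr(q, "shortfall"), 7L)
  expect_false(attr(q, "inconclusive"))

  q2 <- select_query_positions(row, panel, budget = 2, seed = 1)
  expect_equal(nrow(q2), 2)
  expect_identical(q2$panel_row, q$panel_row[1:2])

  q0 <- select_query_positions(c(0L, 0L, 0L, 0L, 0L), panel, budget = 5)
  expect_equal(nrow(q0), 0)
  expect_true(attr(q0, "inconclusive"))
})

test_that("alt-site counts per target match the Hardy-Weinberg closed form", {
  panel <- sample_neutral_frequencies(2e4, 5000, seed = 51)
  g <- sample_genotypes(panel, 50, seed = 52)
  counts <- rowSums(g > 0)
  p <- 1 - (1 - panel$f)^2
  expect_lt(abs(mean(counts) - sum(p)),
            3 * sqrt(sum(p * (1 - p)) / 50))
})

test_that("collect_responses returns ordered 0/1 answers", {
  panel <- tiny_panel()
  g <- manual_genotypes(c(1, 0, 2, 0, 1), panel)
  db <- build_beacon(g, 1)
  q <- select_query_positions(c(0L, 1L, 1L, 1L, 0L), panel, 10, seed = 2)
  x <- collect_responses(db, q)
  expect_identical(x, as.integer(db$catalog$present[q$panel_row]))
  expect_identical(collect_responses(db, q[0, ]), integer())

  # a member's own alt sites are always present
  q_self <- select_query_positions(g[1, ], panel, 10, seed = 3)
  expect_true(all(collect_responses(db, q_self) == 1L))
})

test_that("the reduced LRT form equals the term-by-term likelihoods", {
  set.seed(53)
  for (rep in 1:1000) {
    n <- sample(1:40, 1)
    x <- stats::rbinom(n, 1, stats::runif(1))
    d_n1 <- stats::runif(1, 0.05, 0.95)
    delta <- stats::runif(1, 0.01, 0.9)
    d_n <- stats::runif(1, delta * d_n1, 0.999)
    s <- lrt_statistics(x, d_n, d_n1, delta)
    q1 <- delta * d_n1
    l0 <- sum(x * log(1 - d_n) + (1 - x) * log(d_n))
    l1 <- sum(x * log(1 - q1) + (1 - x) * log(q1))
    expect_equal(s$l_h0, l0, tolerance = 1e-12)
    expect_equal(s$l_h1, l1, tolerance = 1e-12)
    expect_lt(abs(s$lambda - (l0 - l1)), 1e-9 * (1 + abs(s$lambda)))
    expect_lt(abs(s$lambda_linear - s$lambda), 1e-9 * (1 + abs(s$lambda)))
    if (q1 < d_n) expect_lt(s$C, 0)
  }
})

test_that("LRT degenerate and boundary cases behave as the algebra says", {
  # D_N = delta * D_{N-1}: the hypotheses coincide
  s <- lrt_statistics(c(1, 0, 1, 1), d_n = 0.1, d_n1 = 0.5, delta = 0.2)
  expect_equal(s$B, 0)
  expect_equal(s$C, 0)
  expect_equal(s$lambda, 0)

  # all yes: Lambda = n log((1-D_N)/(1-delta D_{N-1}))
  s2 <- lrt_statistics(rep(1, 7), d_n = 0.3, d_n1 = 0.35, delta = 0.1)
  expect_equal(s2$lambda, 7 * log(0.7 / (1 - 0.035)), tolerance = 1e-12)

  # delta = 0 and a "no" answer: membership impossible under the exact model
  s3 <- lrt_statistics(c(1, 0), d_n = 0.3, d_n1 = 0.35, delta = 0)
  expect_true(s3$h1_impossible)
  expect_identical(s3$l_h1, -Inf)

  expect_error(lrt_statistics(c(1, 0), d_n = 0.01, d_n1 = 0.9, delta = 0.5),
               "must not exceed")
})

test_that("decision rules implement both threshold readings", {
  p <- beta_params(0.1848, 0.85)
  prof <- compute_threshold(100, p, delta = 1e-3, alpha = 0.05)
  n <- 2000
  t_prime <- floor(n * prof$theta0 + prof$z * sqrt(n * prof$d_n * (1 - prof$d_n)))

  at <- list(n = n, sum_x = t_prime)
  below <- list(n = n, sum_x = t_prime - 1)
  above <- list(n = n, sum_x = t_prime + 1)

  # operational reading: t' yes-answers conclude membership
  expect_true(as.logical(decide_membership(at, prof, rule = "min_yes")))
  expect_false(as.logical(decide_membership(below, prof, rule = "min_yes")))
  # literal strict inequality
  expect_false(as.logical(decide_membership(at, prof, rule = "strict")))
  expect_true(as.logical(decide_membership(above, prof, rule = "strict")))

  # no queries: never declared a member, flagged inconclusive
  non <- decide_membership(list(n = 0, sum_x = 0), prof)
  expect_false(as.logical(non))
  expect_true(attr(non, "inconclusive"))
})

test_that("the strict decision is calibrated in the CLT regime", {
  p <- beta_params(0.1848, 0.85)
  prof <- compute_threshold(20, p, delta = 1e-3, alpha = 0.05, n = 2000,
                            paper_z = FALSE)
  set.seed(54)
  rejects <- stats::rbinom(1e4, 2000, prof$theta0) |>
    vapply(function(sx) {
      as.logical(decide_membership(list(n = 2000, sum_x = sx), prof,
                                   rule = "strict"))
    }, logical(1))
  gap <- stats::dbinom(prof$t_alpha_prime + 1, 2000, prof$theta0)
  expect_lt(abs(mean(rejects) - 0.05), 3 * sqrt(0.05 * 0.95 / 1e4) + gap)
})

test_that("analytic power matches Monte-Carlo binomial sampling", {
  p <- beta_params(0.1131, 0.8574)
  prof <- compute_threshold(498, p, delta = 1e-3, alpha = 0.05)
  n <- prof$n  # 1005
  for (rule in c("min_yes", "strict")) {
    pow <- power_analytic(prof, n, rule = rule)
    set.seed(55)
    draws <- stats::rbinom(1e5, n, prof$theta1)
    t_prime <- prof$t_alpha_prime
    emp <- if (rule == "strict") mean(draws > t_prime) else mean(draws >= t_prime)
    se <- sqrt(max(pow * (1 - pow), 1e-6) / 1e5)
    expect_lt(abs(pow - emp), 3 * se + 1e-4)
  }
})

test_that("under the strict rule power at delta = 0 steps at the z^2(1-D)/D crossover", {
  p <- beta_params(0.1848, 0.85)
  prof <- compute_threshold(100, p, delta = 0, alpha = 0.05)
  expect_equal(prof$theta1, 1)
  n_star <- prof$z^2 * (1 - prof$d_n) / prof$d_n
  below <- floor(n_star * 0.9); above <- ceiling(n_star * 1.1)
  expect_equal(power_analytic(prof, below, rule = "strict"), 0)
  expect_equal(power_analytic(prof, above, rule = "strict"), 1)
  # the step sits within a few counts of the crossover
  grid <- seq.int(floor(n_star) - 50, ceiling(n_star) + 50)
  pw <- power_analytic(prof, grid, rule = "strict")
  jump <- grid[match(1, pw)]
  expect_lt(abs(jump - n_star), 50)
})

test_that("cohort attack: members separate from non-members at scale", {
  study <- beacon_power_study(num_snps = 2e4, population_size = 5000,
                              beacon_size = 100, cases = 60, controls = 60,
                              budgets = c(0, 200, 500, 1000, 2000), seed = 56)
  s <- study$summary

  # budget 0: nothing is ever rejected
  expect_equal(s$power[s$budget == 0], 0)
  expect_equal(s$type1[s$budget == 0], 0)

  # power is monotone non-decreasing in budget up to one SE
  pw <- s$power[s$budget > 0]
  se <- s$se_power[s$budget > 0]
  expect_true(all(diff(pw) >= -(se[-1] + se[-length(se)])))

  # at the largest budget members are detected, and the false-positive rate
  # stays near the nominal level
  expect_gt(pw[length(pw)], 0.95)
  expect_lt(s$type1[s$budget == 2000], 0.05 + 3 * s$se_type1[s$budget == 2000] + 0.05)

  # reruns with the same seed are bit-identical
  study2 <- beacon_power_study(num_snps = 2e4, population_size = 5000,
                               beacon_size = 100, cases = 60, controls = 60,
                               budgets = c(0, 200, 500, 1000, 2000), seed = 56)
  expect_identical(study$targets, study2$targets)
})

test_that("yes-counts follow the two-binomial law under the model's premises", {
  # The response model assumes queried-site frequencies are Beta(a, b) with
  # a = a'+1, b = b'+1; under that premise each out-of-beacon answer is
  # marginally Bernoulli(1 - D_N) and each in-beacon answer
  # Bernoulli(1 - delta * D_{N-1}), independently. Simulate that world
  # through the beacon machinery and compare moments.
  params <- beta_params(0.1131, 0.8574)
  N <- 100; n <- 1000; targets <- 300; delta <- 0.3
  set.seed(57)
  f <- stats::rbeta(n * targets, params$a, params$b)

  # out-of-beacon: a site answers yes unless none of the N genomes carries it
  absent <- stats::runif(n * targets) < (1 - f)^(2 * N)
  db <- beacon_db(tibble::tibble(chrom = "1", pos = seq_along(f) - 1L,
                                 allele = "ALT", present = !absent), N = N)
  sum_x <- vapply(seq_len(targets), function(t) {
    q <- tibble::tibble(chrom = "1", pos = (t - 1L) * n + seq_len(n) - 1L,
                        allele = "ALT")
    sum(collect_responses(db, q))
  }, numeric(1))
  theta0 <- 1 - exact_dn(N, params)
  expect_lt(abs(mean(sum_x) - n * theta0),
            3 * sqrt(n * theta0 * (1 - theta0) / targets))
  model_var <- n * theta0 * (1 - theta0)
  # no-counts are near-Poisson, so use the count-data SE of a sample variance
  lam0 <- n * (1 - theta0)
  expect_lt(abs(stats::var(sum_x) - model_var),
            3 * sqrt((lam0 + 2 * lam0^2) / targets))

  # in-beacon: a "no" needs a sequencing mismatch (delta) and absence among
  # the other N-1 genomes
  no_ans <- stats::runif(n * targets) < delta * (1 - f)^(2 * (N - 1))
  sum_x1 <- colSums(matrix(!no_ans, nrow = n))
  theta1 <- 1 - delta * exact_dn(N - 1, params)
  expect_lt(abs(mean(sum_x1) - n * theta1),
            3 * sqrt(n * theta1 * (1 - theta1) / targets))
  model_var1 <- n * theta1 * (1 - theta1)
  lam1 <- n * (1 - theta1)
  expect_lt(abs(stats::var(sum_x1) - model_var1),
            3 * sqrt((lam1 + 2 * lam1^2) / targets))
})

test_that("generative no-rates are binomial and within a factor two of D_N", {
  # The neutral-panel pipeline selects every alt-carrying site, while the
  # closed-form D_N corresponds to heterozygosity-weighted site use, so the
  # model value is a ~20% underestimate of the generative per-query no-rate;
  # it must stay the right order of magnitude, and the counts themselves
  # must be binomial at the empirical rate.
  study <- beacon_power_study(num_snps = 2e4, population_size = 5000,
                              beacon_size = 100, cases = 2, controls = 150,
                              budgets = 1000, delta = 1e-3, seed = 60)
  no_counts <- 1000 - study$targets$sum_x[!study$targets$in_beacon]
  p_hat <- mean(no_counts) / 1000
  ratio <- p_hat / study$profile$d_n
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
  emp_var <- 1000 * p_hat * (1 - p_hat)
  lam <- mean(no_counts)
  expect_lt(abs(stats::var(no_counts) - emp_var),
            3 * sqrt((lam + 2 * lam^2) / 150))

  # in-beacon copies with reversion-only error answer yes at every queried
  # site, consistent with 1 - delta * D_{N-1} to the model's resolution
  study2 <- beacon_power_study(num_snps = 2e4, population_size = 5000,
                               beacon_size = 100, cases = 100, controls = 1,
                               budgets = 1000, delta = 1e-3, seed = 61)
  sum_x1 <- study2$targets$sum_x[study2$targets$in_beacon]
  model_mean <- 1000 * study2$profile$theta1
  model_sd <- sqrt(1000 * study2$profile$theta1 * (1 - study2$profile$theta1))
  expect_lt(abs(mean(sum_x1) - model_mean), 3 * model_sd / sqrt(100) + 0.01)
})

test_that("relatives' power is ordered by kinship and twins match members", {
  budgets <- 1000
  powers <- vapply(c(1, 0.5, 0.25, 0.125), function(phi) {
    beacon_power_study(num_snps = 2e4, population_size = 5000,
                       beacon_size = 100, cases = 80, controls = 2,
                       budgets = budgets, phi = phi, seed = 61)$summary$power
  }, numeric(1))
  member <- beacon_power_study(num_snps = 2e4, population_size = 5000,
                               beacon_size = 100, cases = 80, controls = 2,
                               budgets = budgets, seed = 61)$summary$power
  se <- sqrt(pmax(powers * (1 - powers), 0.25 / 80) / 80)
  expect_true(all(diff(powers) <= se[-1] + se[-length(se)]))  # non-increasing
  expect_equal(powers[1], member)  # twins share the whole genome
})
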