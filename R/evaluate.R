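#' Accuracy of a perturbed beacon
#'
#' Compares a perturbed beacon against its raw original, entry-wise over the
#' full catalogued position set, and tallies the confusion counts: true
#' positives (yes kept yes), true negatives (no kept no), false positives
#' (no turned yes) and false negatives (yes turned no). Accuracy is
#' \deqn{\frac{N_{TP} + N_{TN}}{N_{TP} + N_{TN} + N_{FP} + N_{FN}}.}
#'
#' @param raw_db The unperturbed `beacon_db`.
#' @param perturbed_db The perturbed `beacon_db` (same catalogue).
#' @return A one-row tibble with `n_tp`, `n_tn`, `n_fp`, `n_fn`, `accuracy`.
#' @export
#' @examples
#' panel <- sample_neutral_frequencies(500, 1000, seed = 1)
#' g <- sample_genotypes(panel, 20, seed = 2)
#' db <- build_beacon(g, 1:10)
#' confusion_accuracy(db, perturb_eliminate_random(db, 0.9, seed = 3))
confusion_accuracy <- function(raw_db, perturbed_db) {
  stopifnot(inherits(raw_db, "beacon_db"), inherits(perturbed_db, "beacon_db"))
  k1 <- beacon_key(raw_db$catalog$chrom, raw_db$catalog$pos, raw_db$catalog$allele)
  k2 <- beacon_key(perturbed_db$catalog$chrom, perturbed_db$catalog$pos,
                   perturbed_db$catalog$allele)
  if (length(k1) != length(k2) || !all(k1 == k2)) {
    diff <- length(setdiff(k1, k2)) + length(setdiff(k2, k1))
    abort(sprintf("catalogues differ (%d triples in the symmetric difference)",
                  diff))
  }
  truth <- raw_db$catalog$present
  rep_ <- perturbed_db$catalog$present
  tibble(
    n_tp = sum(truth & rep_), n_tn = sum(!truth & !rep_),
    n_fp = sum(!truth & rep_), n_fn = sum(truth & !rep_),
    accuracy = mean(truth == rep_)
  )
}

#' Privacy-utility sweep
#'
#' For each bias value: perturb the beacon with the chosen mechanism,
#' measure the whole-catalogue accuracy, rerun the cohort attack at a fixed
#' query budget against the perturbed beacon, and record the achieved
#' accuracy, attack power, type-I error and the differential-privacy epsilon
#' of the (equivalent two-coin) mechanism. The qualitative result is the
#' privacy-utility curve: power is non-decreasing in accuracy.
#'
#' By default (`recalibrate = TRUE`) the attack threshold is recomputed for
#' the perturbed response distribution: under a mechanism answering
#' truthfully with probability `q`, the null yes-rate becomes
#' \eqn{\theta_0^{q} = q\,\theta_0 + (1-q)(1-\theta_0)} and the threshold
#' uses the matching binomial standard error. With `recalibrate = FALSE`
#' the unperturbed threshold is reused (the weaker adversary unaware of the
#' mechanism).
#'
#' @param beacon The raw `beacon_db`.
#' @param genotypes,cases,controls,delta,alpha,params,paper_z As in
#'   [run_attack_cohort()].
#' @param biases Numeric vector of bias values (\[0, 1\] or percent scale).
#' @param budget Single query budget for the attack.
#' @param mechanism `"biased_rr"` or `"eliminate_random"`.
#' @param recalibrate Recompute the threshold for the perturbed response
#'   distribution (default) or reuse the unperturbed one.
#' @param seed Optional integer seed.
#' @return A tibble of class `privacy_utility` with one row per bias:
#'   `bias`, `accuracy`, `power`, `type1`, `epsilon`, `budget`.
#' @export
privacy_utility_sweep <- function(beacon, genotypes, cases, controls, biases,
                                  budget, mechanism = c("biased_rr",
                                                        "eliminate_random"),
                                  delta = 1e-3, alpha = 0.05, params = NULL,
                                  recalibrate = TRUE, seed = NULL,
                                  paper_z = TRUE) {
  mechanism <- match.arg(mechanism)
  if (length(biases) == 0) abort("`biases` must be non-empty")
  stopifnot(inherits(beacon, "beacon_db"), inherits(genotypes, "genotype_matrix"))
  panel <- attr(genotypes, "panel")
  if (is.null(params)) params <- fit_beta(panel)
  out <- purrr::imap_dfr(as.numeric(biases), function(bias, k) {
    b <- normalize_bias(bias)
    pert <- tryCatch({
      if (mechanism == "biased_rr") {
        perturb_randomized_response(beacon, b, seed = child_seed(seed, k))
      } else {
        perturb_eliminate_random(beacon, b, seed = child_seed(seed, k))
      }
    }, error = function(e) {
      abort(sprintf("bias %g: %s", bias, conditionMessage(e)))
    })
    acc <- confusion_accuracy(beacon, pert)$accuracy
    q <- pert$mechanism$true_answer_prob
    prof <- compute_threshold(beacon$N, params, delta = delta, alpha = alpha,
                              paper_z = paper_z)
    if (recalibrate) {
      # perturbed null yes-rate and its binomial sd, swapped into the profile
      theta0q <- q * prof$theta0 + (1 - q) * (1 - prof$theta0)
      prof$theta0 <- theta0q
      prof$d_n <- 1 - theta0q   # threshold_at() uses d_n for the sd term
      prof$theta1 <- q * prof$theta1 + (1 - q) * (1 - prof$theta1)
    }
    res <- attack_targets(
      pert, panel,
      copies = rbind(genotypes[cases, , drop = FALSE],
                     genotypes[controls, , drop = FALSE]),
      truth = rep(c(TRUE, FALSE), c(length(cases), length(controls))),
      budgets = budget, delta = delta, alpha = alpha, params = params,
      seed = child_seed(seed, 1000L + k), paper_z = paper_z
    )
    # attack_targets builds its own profile from the raw model; re-decide
    # against the (possibly recalibrated) one
    t_pt <- res$targets
    t_pt$t_alpha_prime <- vapply(t_pt$n_queries, function(nq) {
      if (nq == 0) NA_real_ else threshold_at(prof, nq)
    }, numeric(1))
    t_pt$reject <- !is.na(t_pt$t_alpha_prime) & t_pt$sum_x >= t_pt$t_alpha_prime
    tibble(
      bias = b, mechanism = mechanism, accuracy = acc,
      power = mean(t_pt$reject[t_pt$in_beacon]),
      type1 = mean(t_pt$reject[!t_pt$in_beacon]),
      epsilon = pert$mechanism$epsilon, budget = as.integer(budget),
      recalibrated = recalibrate
    )
  })
  class(out) <- c("privacy_utility", class(out))
  out
}
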