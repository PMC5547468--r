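#' End-to-end membership-attack power study
#'
#' The complete simulation protocol behind the attack's power curves, in one
#' call: sample a neutral-spectrum panel for a population of
#' `population_size` diploids, draw genotypes for the beacon members and the
#' out-of-beacon controls, build the beacon, fit the attacker's beta model
#' to the panel, and run the cohort attack at the given budgets.
#'
#' Only the genomes the study actually touches (`beacon_size` members plus
#' `controls` non-members) are materialized; the rest of the population
#' enters solely through the frequency spectrum, which is statistically
#' equivalent and keeps memory flat in `population_size`.
#'
#' @param num_snps Panel size (number of biallelic SNPs).
#' @param population_size Diploid population size behind the neutral
#'   spectrum.
#' @param beacon_size Number of beacon members `N`.
#' @param cases Number of in-beacon targets (drawn from the members).
#' @param controls Number of out-of-beacon targets.
#' @param budgets Query budgets to evaluate.
#' @param delta Sequencing mismatch rate applied to the adversary's copies.
#' @param alpha False-positive level.
#' @param phi Optional kinship coefficient: when given, the adversary holds
#'   a relative (sharing fraction `phi`) of each in-beacon target instead of
#'   the target's own genome.
#' @param seed Integer seed; the study is fully reproducible.
#' @param rule Decision rule, see [decide_membership()].
#' @return An `attack_outcome` (see [run_attack_cohort()]) with the panel
#'   attached as attribute `panel` and the beacon as attribute `beacon`.
#' @export
#' @examples
#' study <- beacon_power_study(num_snps = 2000, population_size = 2000,
#'                             beacon_size = 50, cases = 20, controls = 20,
#'                             budgets = c(100, 400), seed = 1)
#' study$summary
beacon_power_study <- function(num_snps, population_size, beacon_size,
                               cases, controls, budgets, delta = 1e-3,
                               alpha = 0.05, phi = NULL, seed = 1,
                               rule = c("min_yes", "strict")) {
  rule <- match.arg(rule)
  assert_count(cases, "cases"); assert_count(controls, "controls")
  if (cases > beacon_size) abort("`cases` cannot exceed `beacon_size`")
  if (beacon_size + controls > population_size) {
    abort("`beacon_size + controls` cannot exceed `population_size`")
  }
  panel <- sample_neutral_frequencies(num_snps, population_size,
                                      seed = child_seed(seed, 1))
  geno <- sample_genotypes(panel, beacon_size + controls,
                           seed = child_seed(seed, 2))
  db <- build_beacon(geno, seq_len(beacon_size))
  params <- fit_beta(panel)
  case_idx <- seq_len(cases)
  control_idx <- beacon_size + seq_len(controls)
  res <- if (is.null(phi)) {
    run_attack_cohort(db, geno, case_idx, control_idx, budgets,
                      delta = delta, alpha = alpha, params = params,
                      seed = child_seed(seed, 3), rule = rule)
  } else {
    copies <- t(vapply(c(case_idx, control_idx), function(i) {
      row <- if (i <= beacon_size) {
        make_relative(geno[i, ], panel, phi, seed = child_seed(seed, 100L + i))
      } else geno[i, ]
      apply_sequencing_error(row, delta, seed = child_seed(seed, 200L + i))
    }, integer(num_snps)))
    attack_targets(db, panel, copies,
                   truth = rep(c(TRUE, FALSE), c(cases, controls)),
                   budgets = budgets, delta = delta, alpha = alpha,
                   params = params, seed = child_seed(seed, 3), rule = rule)
  }
  attr(res, "panel") <- panel
  attr(res, "beacon") <- db
  res
}
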