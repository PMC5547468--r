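#' Randomized perturbation of a beacon database
#'
#' Two preprocessing mechanisms trade beacon accuracy for member privacy by
#' randomizing the stored presence bits before any query is answered. Both
#' keep the member count and the catalogued position set intact and only
#' flip presence bits, so repeated queries are consistent (the preprocessing
#' deployment is the default precisely because an online coin could be
#' averaged away by repeating a query; see [answer_online()]).
#'
#' * `perturb_eliminate_random()` ("eliminating random positions"): each bit
#'   is kept with probability `bias` and flipped with probability
#'   `1 - bias`, producing false positives and false negatives at rate
#'   `1 - bias`.
#' * `perturb_randomized_response()` ("biased randomized response"): the
#'   two-coin scheme -- with probability `bias` the true bit is kept;
#'   otherwise a second `bias`-coin is flipped, keeping the bit on success
#'   and flipping it on failure. The net true-answer probability is
#'   `1 - (1 - bias)^2`, and the mechanism satisfies
#'   \eqn{\epsilon}-differential privacy with
#'   \eqn{\epsilon = |\ln(1/(1-b)^2 - 1)|} (see [epsilon_of_bias()]).
#'
#' The mechanisms are equivalent up to the bias mapping
#' \eqn{b_1 = 2 b_2 - b_2^2} ([bias_equivalence()]).
#'
#' Bias may be given on the \[0, 1\] scale or as a percentage in (1, 100\]
#' (the experiment scale: 50/75/90); percentages are normalized.
#'
#' @param db A `beacon_db`.
#' @param bias Truth-retention parameter, \[0, 1\] or percent.
#' @param seed Optional integer seed; the same seed reproduces the same
#'   perturbed database.
#' @param deletion_only For `perturb_eliminate_random()` only: restrict the
#'   perturbation to presence-to-absence deletions (no false positives), for
#'   comparison with the symmetric default.
#' @return A `beacon_db` with `provenance = "perturbed"` and mechanism
#'   metadata (mechanism name, bias, epsilon of the equivalent two-coin
#'   scheme).
#' @export
#' @examples
#' panel <- sample_neutral_frequencies(200, 1000, seed = 1)
#' g <- sample_genotypes(panel, 20, seed = 2)
#' db <- build_beacon(g, 1:10)
#' perturb_randomized_response(db, bias = 0.75, seed = 3)
perturb_eliminate_random <- function(db, bias, seed = NULL,
                                     deletion_only = FALSE) {
  bias <- normalize_bias(bias)
  stopifnot(inherits(db, "beacon_db"))
  out <- db
  flipped <- with_seed_maybe(seed, stats::runif(nrow(db$catalog)) >= bias)
  if (deletion_only) flipped <- flipped & db$catalog$present
  out$catalog$present <- xor(db$catalog$present, flipped)
  out$provenance <- "perturbed"
  out$mechanism <- list(
    mechanism = if (deletion_only) "eliminate_random_deletion" else "eliminate_random",
    bias = bias, true_answer_prob = bias,
    epsilon = epsilon_value(1 - sqrt(1 - bias))  # two-coin bias with same retention
  )
  out
}

#' @rdname perturb_eliminate_random
#' @export
perturb_randomized_response <- function(db, bias, seed = NULL) {
  bias <- normalize_bias(bias)
  stopifnot(inherits(db, "beacon_db"))
  out <- db
  flipped <- with_seed_maybe(seed, {
    m <- nrow(db$catalog)
    first <- stats::runif(m) < bias      # keep outright
    second <- stats::runif(m) < bias     # second coin: keep on success
    !first & !second
  })
  out$catalog$present <- xor(db$catalog$present, flipped)
  out$provenance <- "perturbed"
  out$mechanism <- list(mechanism = "biased_rr", bias = bias,
                        true_answer_prob = 1 - (1 - bias)^2,
                        epsilon = epsilon_value(bias))
  out
}

normalize_bias <- function(bias) {
  if (!is.numeric(bias) || length(bias) != 1L || is.na(bias) || bias < 0 ||
      bias > 100) {
    abort("`bias` must be a single number in [0, 1] or a percent in (1, 100]")
  }
  if (bias > 1) bias <- bias / 100
  bias
}

epsilon_value <- function(b) {
  if (b <= 0 || b >= 1) return(Inf)
  abs(log(1 / (1 - b)^2 - 1))
}

#' Differential-privacy level of the two-coin mechanism
#'
#' The biased randomized-response mechanism with truth-retention bias `b`
#' satisfies \eqn{\epsilon}-differential privacy with
#' \deqn{\epsilon = \left|\ln\!\left(\frac{1}{(1-b)^2} - 1\right)\right|.}
#' The guarantee is perfect (\eqn{\epsilon = 0}) at \eqn{b = 1 - 1/\sqrt 2},
#' where yes and no responses are equally likely under either truth. At
#' `b = 1` the mechanism is deterministic and discloses everything
#' (\eqn{\epsilon = \infty}); at `b = 0` it deterministically inverts every
#' bit, which is equally disclosing. Both ends are flagged.
#'
#' @param bias Truth-retention parameter, \[0, 1\] or percent scale.
#' @return A list of class `dp_guarantee` with `bias`, `epsilon` and
#'   `flag` (`"ok"`, `"zero"` at the perfect-privacy root, or
#'   `"deterministic"` at the disclosing ends).
#' @export
#' @examples
#' epsilon_of_bias(0.5)$epsilon   # ln(3)
epsilon_of_bias <- function(bias) {
  b <- normalize_bias(bias)
  root <- 1 - 1 / sqrt(2)
  flag <- if (b == 0 || b == 1) "deterministic"
          else if (isTRUE(all.equal(b, root))) "zero"
          else "ok"
  eps <- if (flag == "zero") 0 else epsilon_value(b)
  structure(list(bias = b, epsilon = eps, flag = flag),
            class = "dp_guarantee")
}

#' @export
print.dp_guarantee <- function(x, ...) {
  cat(sprintf("<dp_guarantee> bias = %g, epsilon = %g (%s)\n",
              x$bias, x$epsilon, x$flag))
  invisible(x)
}

#' Bias equivalence between the two mechanisms
#'
#' The two-coin mechanism with bias `b2` answers truthfully with probability
#' \eqn{1 - (1 - b_2)^2}; the single-flip mechanism matches it exactly at
#' \deqn{b_1 = 2 b_2 - b_2^2.}
#'
#' @param b2 Two-coin bias, \[0, 1\] or percent.
#' @return The equivalent single-flip bias `b1` in \[0, 1\].
#' @export
#' @examples
#' bias_equivalence(0.5)  # 0.75
bias_equivalence <- function(b2) {
  b2 <- normalize_bias(b2)
  2 * b2 - b2^2
}

#' Answer a single query through an online mechanism
#'
#' Perturbs the true answer at query time instead of preprocessing the
#' database. Included for completeness and as a demonstration of why
#' preprocessing is the default: an online coin is re-flipped on every
#' query, so an adversary repeating the same query and taking a majority
#' vote recovers the true bit with probability approaching one.
#'
#' @param db A `beacon_db` (queried raw).
#' @param chrom,pos,allele Query triple (`pos` 0-based).
#' @param mechanism `"eliminate_random"` or `"biased_rr"`.
#' @param bias Truth-retention parameter.
#' @param seed Optional integer seed (for reproducible demonstrations).
#' @return Logical answer.
#' @export
answer_online <- function(db, chrom, pos, allele = "ALT",
                          mechanism = c("biased_rr", "eliminate_random"),
                          bias = 1, seed = NULL) {
  mechanism <- match.arg(mechanism)
  bias <- normalize_bias(bias)
  truth <- query_beacon(db, chrom, pos, allele)
  flip <- with_seed_maybe(seed, {
    if (mechanism == "eliminate_random") {
      stats::runif(length(truth)) >= bias
    } else {
      first <- stats::runif(length(truth)) < bias
      second <- stats::runif(length(truth)) < bias
      !first & !second
    }
  })
  xor(truth, flip)
}
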