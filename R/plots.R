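#' Plot an attack power curve
#'
#' Power of the membership test (and the empirical type-I error) against the
#' number of queries issued, the standard summary figure of the simulation
#' study.
#'
#' @param object An `attack_outcome` from [run_attack_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.attack_outcome <- function(object, ...) {
  dat <- object$summary |>
    tidyr::pivot_longer(c("power", "type1"), names_to = "measure",
                        values_to = "rate")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$budget, y = .data$rate,
                                    colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(
      values = c(power = "#1b7837", type1 = "#762a83"),
      labels = c(power = "power (in-beacon targets)",
                 type1 = "type-I error (out-of-beacon)")) +
    ggplot2::labs(x = "queries issued", y = "rejection rate", colour = NULL,
                  title = sprintf("LRT membership attack, beacon of N = %d",
                                  object$profile$N)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a privacy-utility curve
#'
#' Attack power against achieved beacon accuracy across a bias sweep, the
#' privacy-utility tradeoff of the perturbation mechanisms.
#'
#' @param object A `privacy_utility` tibble from [privacy_utility_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.privacy_utility <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$accuracy, y = .data$power)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$bias), size = 2) +
    ggplot2::scale_colour_viridis_c(name = "bias") +
    ggplot2::labs(x = "beacon accuracy (utility)",
                  y = sprintf("attack power at %d queries (privacy loss)",
                              object$budget[1]),
                  title = "Privacy-utility tradeoff") +
    ggplot2::theme_minimal()
}

#' Plot a risk profile's response-count model
#'
#' The two binomial yes-count distributions of the risk model -- under the
#' null (target absent) and the alternative (target present) -- together
#' with the decision threshold, visualizing how separable the hypotheses are
#' for a given beacon.
#'
#' @param profile A `risk_profile` from [compute_threshold()].
#' @param n Query budget to draw the distributions at (default: the
#'   profile's `n`).
#' @return A ggplot object.
#' @export
plot_risk_profile <- function(profile, n = NULL) {
  stopifnot(inherits(profile, "risk_profile"))
  if (is.null(n)) n <- profile$n
  lo <- max(0, floor(n * min(profile$theta0, profile$theta1) -
                       4 * sqrt(n * profile$d_n)))
  ks <- lo:n
  dat <- dplyr::bind_rows(
    tibble(k = ks, p = stats::dbinom(ks, n, profile$theta0),
           hypothesis = "absent (H0)"),
    tibble(k = ks, p = stats::dbinom(ks, n, profile$theta1),
           hypothesis = "present (H1)")
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$k, y = .data$p,
                                    colour = .data$hypothesis)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = threshold_at(profile, n),
                        linetype = "dashed", colour = "red") +
    ggplot2::scale_colour_manual(values = c("absent (H0)" = "black",
                                            "present (H1)" = "#1b7837")) +
    ggplot2::labs(x = "yes-answers among n queries", y = "probability",
                  colour = NULL,
                  title = sprintf("Response model, N = %d, n = %d, t' = %d",
                                  profile$N, as.integer(n),
                                  as.integer(threshold_at(profile, n)))) +
    ggplot2::theme_minimal()
}
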