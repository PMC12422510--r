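#' Simulation-based parameter recovery study
#'
#' Repeatedly simulates a cohort from a configuration with known truth and
#' refits the three-level model, collecting the replicate estimates of one
#' coefficient per requested outcome: the age slope by default, or the
#' age-by-moderator interaction when `moderator` is given. This is the
#' package's standard check that the estimation machinery recovers the
#' generating fixed effects.
#'
#' @param config A [sim_config()].
#' @param outcomes Outcome columns to fit (e.g. `"std_sed"`).
#' @param n_rep Number of replicates.
#' @param seed Master seed; replicate seeds are drawn from it, so the whole
#'   study is reproducible.
#' @param moderator Optional binary moderator passed to [fit_interaction()];
#'   the collected coefficient is then the interaction term.
#' @return Tibble: `outcome`, `replicate`, `term`, `estimate`, `se`,
#'   `ci_low`, `ci_high`, `singular`.
#' @seealso [summarize_recovery()]
#' @export
recovery_study <- function(config = sim_config(),
                           outcomes = c("std_sed", "std_lpa", "std_mvpa"),
                           n_rep = 50L, seed = 1L, moderator = NULL) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_rep)
  dplyr::bind_rows(lapply(seq_len(n_rep), function(r) {
    sim <- simulate_cohort(config, seed = seeds[r])
    dplyr::bind_rows(lapply(outcomes, function(o) {
      fit <- if (is.null(moderator)) {
        fit_three_level(sim$data, o)
      } else {
        fit_interaction(sim$data, o, moderator)
      }
      row <- if (is.null(moderator)) {
        fit$tidy[fit$tidy$term == "decimal_age", ]
      } else {
        fit$tidy[startsWith(fit$tidy$term, "decimal_age:"), ]
      }
      tibble::tibble(outcome = o, replicate = r, term = row$term,
                     estimate = row$beta, se = row$se,
                     ci_low = row$ci_low, ci_high = row$ci_high,
                     singular = fit$singular)
    }))
  }))
}

#' Summarize a recovery study against the generating truth
#'
#' @param res Output of [recovery_study()].
#' @param truths Named numeric: generating truth per outcome.
#' @return Tibble per outcome: `truth`, `mean_estimate`, `mc_se` (Monte
#'   Carlo standard error of the mean estimate), `z` (deviation of the
#'   mean from truth in MC-SE units), and `coverage` of the nominal 95%
#'   intervals.
#' @export
summarize_recovery <- function(res, truths) {
  res |>
    dplyr::mutate(truth = unname(truths[sub("^std_", "", .data$outcome)])) |>
    dplyr::summarise(
      truth = .data$truth[1L],
      mean_estimate = mean(.data$estimate),
      mc_se = sd(.data$estimate) / sqrt(dplyr::n()),
      coverage = mean(.data$ci_low <= .data$truth & .data$truth <= .data$ci_high),
      .by = "outcome"
    ) |>
    dplyr::mutate(z = (.data$mean_estimate - .data$truth) / .data$mc_se)
}
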