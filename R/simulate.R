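#' Synthetic-cohort configuration
#'
#' Bundles the generating parameters for [simulate_cohort()]. Defaults
#' describe a pooled multi-study child cohort: 5 studies of 100
#' participants each observed at 2-3 waves, baseline ages centred on 10.6
#' (SD 2.1) years within 4.1-15.8, first follow-up ~2.5 (SD 1.4) years
#' after baseline and second ~4.3 (SD 1.1) years cumulative. Behaviour
#' levels at the reference age and the default annual age slopes (+24.9
#' sedentary, -22.4 light, -2.5 MVPA min/day/year) correspond to a total
#' daily wear budget of about 800 minutes.
#'
#' @param n_studies,participants_per_study Hierarchy size.
#' @param wave_probs Named probabilities for the number of waves (names
#'   `"2"`, `"3"`).
#' @param baseline_age `list(mean, sd, min, max)` for baseline decimal age.
#' @param wave_gap `list(t1_mean, t1_sd, t2_mean, t2_sd, min_gap)`: follow-up
#'   gaps in years; `t2_*` is cumulative from baseline.
#' @param level_at_ref Named outcome means (min/day) at `ref_age` for the
#'   male, spring, reference stream cell.
#' @param ref_age Age (years) at which `level_at_ref` applies.
#' @param slopes Named fixed age slopes (min/day/year).
#' @param sex_effects Named female-vs-male intercept offsets (min/day).
#' @param sex_age_interaction Named additional age slope for girls.
#' @param season_effects 3x4 matrix-like list: per outcome, offsets for
#'   `summer`, `autumn`, `winter` relative to spring.
#' @param study_sd,participant_sd,resid_sd Named SDs of the study random
#'   intercept, participant random intercept, and residual, per outcome.
#'   Defaults are calibrated so that every outcome's expected value stays
#'   at least three total SDs away from the `[0, wear_target]` bounds over
#'   the whole design envelope (both sexes, ages from the youngest baseline
#'   to the oldest baseline plus the mean cumulative follow-up): truncation
#'   then affects a negligible fraction of rows and the linear
#'   data-generating process stays effectively linear, which is what the
#'   parameter-recovery tests require. This keeps MVPA's marginal SD well
#'   below values seen in real cohorts; a configuration that violates the
#'   three-SD rule triggers a warning rather than an error.
#' @param wear_target Total daily wear budget (min/day); outcomes are
#'   truncated into `[0, wear_target]` (events counted in the truth record).
#' @param wear_sd Between-wave SD of observed mean daily wear (min/day).
#' @param valid_day_range Integer range of valid days per wave.
#' @param prev Named prevalences: `male`, `white`, `low_mid_edu`.
#' @param weight_probs Probabilities for underweight/normal/overweight-obese.
#' @param streams Streams to generate: `"all"` or any of
#'   `c("weekday", "weekend")` (stacked long when both).
#' @param weekend_offset,weekend_slope_delta Named intercept offset and
#'   additional age slope for weekend rows relative to weekdays; used only
#'   when both streams are generated (stacked design).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_studies = 5L,
                       participants_per_study = 100L,
                       wave_probs = c(`2` = 0.5, `3` = 0.5),
                       baseline_age = list(mean = 10.6, sd = 2.1,
                                           min = 4.1, max = 15.8),
                       wave_gap = list(t1_mean = 2.5, t1_sd = 1.4,
                                       t2_mean = 4.3, t2_sd = 1.1,
                                       min_gap = 0.5),
                       level_at_ref = c(sed = 355.7, lpa = 388.5, mvpa = 55.9),
                       ref_age = 10.6,
                       slopes = c(sed = 24.9, lpa = -22.4, mvpa = -2.5),
                       sex_effects = c(sed = -9.5, lpa = 33.1, mvpa = -23.7),
                       sex_age_interaction = c(sed = 0, lpa = 0, mvpa = 0),
                       season_effects = list(
                         sed = c(summer = -8, autumn = 2, winter = 6),
                         lpa = c(summer = 5, autumn = -2, winter = -4),
                         mvpa = c(summer = 3, autumn = -1, winter = -2)
                       ),
                       study_sd = c(sed = 16, lpa = 15, mvpa = 2),
                       participant_sd = c(sed = 44, lpa = 40, mvpa = 4),
                       resid_sd = c(sed = 34, lpa = 30, mvpa = 3),
                       wear_target = 800,
                       wear_sd = 45,
                       valid_day_range = c(4L, 7L),
                       prev = c(male = 0.445, white = 0.892, low_mid_edu = 0.269),
                       weight_probs = c(underweight = 0.084, normal = 0.715,
                                        overweight_obese = 0.201),
                       streams = "all",
                       weekend_offset = c(sed = -31.9, lpa = -19.5, mvpa = -0.7),
                       weekend_slope_delta = c(sed = -0.2, lpa = 1.0, mvpa = -0.8)) {
  cfg <- as.list(environment())
  stopifnot(all(c("sed", "lpa", "mvpa") %in% names(cfg$slopes)),
            all(cfg$study_sd >= 0), all(cfg$participant_sd >= 0),
            all(cfg$resid_sd >= 0), cfg$wear_target > 0)
  if (sum(pmax(cfg$level_at_ref, 0)) > 1.05 * cfg$wear_target) {
    abort("expected behaviour composition exceeds the wear budget",
          class = "actichange_config_error")
  }
  ok <- all(cfg$streams %in% c("all", "weekday", "weekend"))
  if (!ok || ("all" %in% cfg$streams && length(cfg$streams) > 1L)) {
    abort("streams must be 'all' or a subset of c('weekday','weekend')",
          class = "actichange_config_error")
  }
  cfg <- structure(cfg, class = "sim_config")
  check_sim_bounds(cfg)
  cfg
}

# warn when an expected outcome comes within 3 total SDs of the truncation
# bounds anywhere on the design envelope (both sexes, baseline-age range
# extended by the mean cumulative follow-up, all generated streams)
check_sim_bounds <- function(cfg) {
  ages <- c(cfg$baseline_age$min,
            cfg$baseline_age$max + cfg$wave_gap$t2_mean)
  stacked <- length(cfg$streams) > 1L
  intercepts <- cfg$level_at_ref - cfg$slopes * cfg$ref_age -
    (1 - cfg$prev[["male"]]) * cfg$sex_effects
  for (o in c("sed", "lpa", "mvpa")) {
    tot_sd <- sqrt(cfg$study_sd[[o]]^2 + cfg$participant_sd[[o]]^2 +
                     cfg$resid_sd[[o]]^2)
    for (female in c(0, 1)) {
      for (weekend in if (stacked) c(0, 1) else 0) {
        mu <- intercepts[[o]] +
          (cfg$slopes[[o]] + cfg$sex_age_interaction[[o]] * female +
             if (weekend) cfg$weekend_slope_delta[[o]] else 0) * ages +
          cfg$sex_effects[[o]] * female +
          if (weekend) cfg$weekend_offset[[o]] else 0
        if (any(mu < 3 * tot_sd) || any(mu > cfg$wear_target - 3 * tot_sd)) {
          warn(sprintf(
            "%s mean comes within 3 SDs of the [0, %s] bounds on the design envelope; truncation may bias slope recovery",
            o, cfg$wear_target))
          return(invisible(FALSE))
        }
      }
    }
  }
  invisible(TRUE)
}

rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0L) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Simulate a multi-study longitudinal cohort
#'
#' Draws a study/participant hierarchy, covariates, assessment schedule
#' and wave-level standardized behaviour outcomes from a linear
#' mixed-model data-generating process: for each outcome,
#' `value = intercept + slope * age + sex effect + season effect
#' (+ moderator interactions + stream effects) + study intercept +
#' participant intercept + residual`, truncated into `[0, wear_target]`.
#' Wave-level wear statistics and raw (non-standardized) intensity
#' minutes are derived so that the wear-standardization step can be
#' exercised end to end: raw intensities are the outcome composition
#' rescaled to the wave's observed wear, hence standardizing them back at
#' the pooled wear recovers a composition summing exactly to pooled wear.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed; with a fixed seed the output is
#'   fully reproducible.
#' @return List with `data` (the analysis tibble, one row per
#'   participant-wave-stream) and `truth` (generating fixed effects,
#'   realised study/participant effects, per-row expected values, and the
#'   truncation count).
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_studies = 2, participants_per_study = 20),
#'                        seed = 1)
#' head(sim$data)
simulate_cohort <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  outs <- c("sed", "lpa", "mvpa")
  # anchor the male (reference) intercept so the population mean at ref_age
  # equals level_at_ref given the configured sex mix
  intercepts <- config$level_at_ref - config$slopes * config$ref_age -
    (1 - config$prev[["male"]]) * config$sex_effects

  studies <- sprintf("S%02d", seq_len(config$n_studies))
  study_re <- sapply(outs, function(o) rnorm(config$n_studies, 0, config$study_sd[[o]]))
  study_re <- matrix(study_re, nrow = config$n_studies,
                     dimnames = list(studies, outs))

  n_part <- config$n_studies * config$participants_per_study
  part <- tibble::tibble(
    study_id = rep(studies, each = config$participants_per_study),
    participant_id = sprintf("%s_P%03d", .data$study_id,
                             rep(seq_len(config$participants_per_study),
                                 times = config$n_studies)),
    sex = factor(ifelse(runif(n_part) < config$prev[["male"]],
                        "male", "female"), levels = c("male", "female")),
    ethnicity = factor(ifelse(runif(n_part) < config$prev[["white"]],
                              "white", "non-white"),
                       levels = c("white", "non-white")),
    maternal_education = factor(
      ifelse(runif(n_part) < config$prev[["low_mid_edu"]], "low-mid", "high"),
      levels = c("low-mid", "high")),
    weight_group = factor(
      sample(names(config$weight_probs), n_part, replace = TRUE,
             prob = config$weight_probs),
      levels = names(config$weight_probs)),
    baseline_age = rtrunc_norm(n_part, config$baseline_age$mean,
                               config$baseline_age$sd,
                               config$baseline_age$min, config$baseline_age$max),
    n_waves = sample(as.integer(names(config$wave_probs)), n_part,
                     replace = TRUE, prob = config$wave_probs)
  )
  part_re <- sapply(outs, function(o) rnorm(n_part, 0, config$participant_sd[[o]]))
  part_re <- matrix(part_re, nrow = n_part,
                    dimnames = list(part$participant_id, outs))

  gap1 <- rtrunc_norm(n_part, config$wave_gap$t1_mean, config$wave_gap$t1_sd,
                      lo = config$wave_gap$min_gap)
  gap2 <- pmax(rtrunc_norm(n_part, config$wave_gap$t2_mean, config$wave_gap$t2_sd,
                           lo = config$wave_gap$min_gap),
               gap1 + config$wave_gap$min_gap)

  idx <- rep(seq_len(n_part), part$n_waves)
  wave_index <- sequence(part$n_waves)
  gap <- ifelse(wave_index == 1L, 0,
                ifelse(wave_index == 2L, gap1[idx], gap2[idx]))
  waves <- part[idx, ] |>
    dplyr::mutate(
      wave_index = wave_index,
      decimal_age = .data$baseline_age + gap,
      season = factor(sample(c("spring", "summer", "autumn", "winter"),
                             dplyr::n(), replace = TRUE),
                      levels = c("spring", "summer", "autumn", "winter")),
      age_group = age_group(.data$baseline_age),
      n_valid_days = sample(seq(config$valid_day_range[1L],
                                config$valid_day_range[2L]),
                            dplyr::n(), replace = TRUE),
      mean_wear_min = rtrunc_norm(dplyr::n(), config$wear_target,
                                  config$wear_sd, lo = 600, hi = 1020)
    )

  # stacked stream rows
  rows <- dplyr::bind_rows(lapply(config$streams, function(s) {
    dplyr::mutate(waves, stream = s)
  })) |>
    dplyr::mutate(stream = factor(.data$stream,
                                  levels = intersect(c("all", "weekday", "weekend"),
                                                     config$streams)))

  female <- as.numeric(rows$sex == "female")
  # weekend offsets/slope deltas describe the weekday-weekend contrast and
  # apply only in the stacked two-stream design; a single named stream is
  # generated from the base parameters directly
  weekend <- if (length(config$streams) > 1L) {
    as.numeric(rows$stream == "weekend")
  } else {
    numeric(nrow(rows))
  }
  n_trunc <- 0L
  for (o in outs) {
    seas <- c(spring = 0, config$season_effects[[o]])[as.character(rows$season)]
    mu <- intercepts[[o]] +
      (config$slopes[[o]] + config$sex_age_interaction[[o]] * female +
         config$weekend_slope_delta[[o]] * weekend) * rows$decimal_age +
      config$sex_effects[[o]] * female +
      config$weekend_offset[[o]] * weekend +
      unname(seas) +
      unname(study_re[rows$study_id, o]) +
      unname(part_re[rows$participant_id, o])
    y <- mu + rnorm(nrow(rows), 0, config$resid_sd[[o]])
    y_t <- pmin(pmax(y, 0), config$wear_target)
    n_trunc <- n_trunc + sum(y_t != y)
    rows[[paste0("mu_", o)]] <- mu
    rows[[paste0("std_", o)]] <- y_t
  }
  # raw minutes at the wave's observed wear: composition shares times wear
  total <- rows$std_sed + rows$std_lpa + rows$std_mvpa
  rows$raw_sed <- rows$std_sed / total * rows$mean_wear_min
  rows$raw_lpa <- rows$std_lpa / total * rows$mean_wear_min
  rows$raw_mvpa <- rows$std_mvpa / total * rows$mean_wear_min

  truth <- list(
    intercepts = intercepts,
    slopes = config$slopes,
    sex_effects = config$sex_effects,
    sex_age_interaction = config$sex_age_interaction,
    season_effects = config$season_effects,
    weekend_offset = config$weekend_offset,
    weekend_slope_delta = config$weekend_slope_delta,
    study_effects = study_re,
    participant_effects = part_re,
    expected = rows[c("participant_id", "wave_index", "stream",
                      "mu_sed", "mu_lpa", "mu_mvpa")],
    n_truncated = n_trunc
  )
  rows <- dplyr::select(rows, -dplyr::starts_with("mu_"), -"n_waves")
  list(data = rows, truth = truth)
}
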