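# small cohorts for model behaviour tests
null_config <- function(...) {
  sim_config(n_studies = 3L, participants_per_study = 40L,
             study_sd = c(sed = 0, lpa = 0, mvpa = 0),
             participant_sd = c(sed = 0, lpa = 0, mvpa = 0), ...)
}

test_that("with zero random-effect variances the fit collapses to OLS", {
  # When the generating random-effect variances are zero, the REML variance
  # estimates land on the boundary in roughly half of realisations; when
  # they do, the mixed-model fixed effects are exactly GLS = OLS. Check the
  # identity on boundary fits, and statistical agreement otherwise.
  cfg <- null_config(slopes = c(sed = 0, lpa = 0, mvpa = 0))
  n_boundary <- 0L
  for (seed in 301:306) {
    sim <- simulate_cohort(cfg, seed = seed)
    fit <- fit_three_level(sim$data, "std_sed")
    ols <- lm(std_sed ~ decimal_age + sex + season, data = sim$data)
    age <- fit$tidy[fit$tidy$term == "decimal_age", ]
    expect_lt(abs(age$beta), 1e-6 + 4 * age$se)  # zero generating age effect
    if (fit$singular &&
        fit$varcomp[["study"]] < 1e-8 && fit$varcomp[["participant"]] < 1e-8) {
      n_boundary <- n_boundary + 1L
      expect_equal(fit$tidy$beta, unname(coef(ols)), tolerance = 1e-6)
    } else {
      # interior variance estimates: GLS stays close to OLS
      expect_lt(max(abs(fit$tidy$beta - unname(coef(ols)))), 1.5)
    }
  }
  expect_gt(n_boundary, 0L)
})

test_that("replicating whole studies leaves estimates invariant, shrinks SEs", {
  # duplicating every top-level cluster doubles the REML objective without
  # changing its maximiser: fixed effects are exactly invariant
  sim <- simulate_cohort(sim_config(n_studies = 3L, participants_per_study = 40L),
                         seed = 310)
  fit <- fit_three_level(sim$data, "std_sed")
  clone <- dplyr::mutate(sim$data,
                         study_id = paste0(study_id, "_b"),
                         participant_id = paste0(participant_id, "_b"))
  fitd <- fit_three_level(dplyr::bind_rows(sim$data, clone), "std_sed")
  # with few studies the REML profile is flat in the study variance, so
  # intercept-block terms carry optimizer noise; the age slope is sharply
  # identified and must agree
  b <- function(f) f$tidy$beta[f$tidy$term == "decimal_age"]
  expect_equal(b(fitd), b(fit), tolerance = 1e-3)
  expect_lt(max(abs(fitd$tidy$beta - fit$tidy$beta)), 0.5)
  expect_true(all(fitd$tidy$se < fit$tidy$se))
})

test_that("a single replicate recovers the generating slope and variances", {
  sim <- simulate_cohort(seed = 303)
  fit <- fit_three_level(sim$data, "std_sed")
  age <- fit$tidy[fit$tidy$term == "decimal_age", ]
  expect_lt(abs(age$beta - 24.9), 4 * age$se)
  expect_true(age$ci_low <= age$beta && age$beta <= age$ci_high)
  expect_equal(fit$n_studies, 5L)
  expect_equal(fit$n_participants, 500L)
  # variance components are on the generating scale (SDs 16 / 44 / 34)
  expect_gt(fit$varcomp[["participant"]], 0)
  expect_equal(sqrt(fit$varcomp[["residual"]]), 34, tolerance = 0.2)
})

test_that("degenerate designs raise instead of fitting nonsense", {
  sim <- simulate_cohort(sim_config(n_studies = 2L, participants_per_study = 30L),
                         seed = 304)
  one_study <- dplyr::filter(sim$data, study_id == "S01")
  expect_error(fit_three_level(one_study, "std_sed"),
               class = "actichange_degenerate_design_error")
  no_repeat <- dplyr::filter(sim$data, wave_index == 1L)
  expect_error(fit_three_level(no_repeat, "std_sed"),
               class = "actichange_degenerate_design_error")
  allmale <- dplyr::mutate(sim$data, sex = factor("male", c("male", "female")))
  expect_error(fit_interaction(allmale, "std_sed", "sex"),
               class = "actichange_degenerate_design_error")
})

test_that("rows with missing covariates are dropped with a message", {
  sim <- simulate_cohort(sim_config(n_studies = 3L, participants_per_study = 30L),
                         seed = 305)
  d <- sim$data
  d$sex[1:5] <- NA
  expect_message(fit <- fit_three_level(d, "std_sed"), "dropping 5")
  expect_equal(fit$n_obs, nrow(d) - 5L)
  expect_equal(fit$n_dropped, 5L)
})

test_that("interaction fits estimate slope differences; null when none", {
  # equal slopes in both sexes: interaction compatible with zero
  sim0 <- simulate_cohort(seed = 306)
  f0 <- fit_interaction(sim0$data, "std_sed", "sex")
  inter0 <- f0$tidy[f0$tidy$term == "decimal_age:sexfemale", ]
  expect_lt(abs(inter0$beta), 3.5 * inter0$se)

  cfg <- sim_config(slopes = c(sed = 23.5, lpa = -22.4, mvpa = -2.5),
                    sex_age_interaction = c(sed = 2.5, lpa = 0, mvpa = 0))
  sim <- simulate_cohort(cfg, seed = 307)
  f <- fit_interaction(sim$data, "std_sed", "sex")
  inter <- f$tidy[f$tidy$term == "decimal_age:sexfemale", ]
  expect_lt(abs(inter$beta - 2.5), 4 * inter$se)

  # implied slopes: reference and reference + interaction
  sl <- moderated_slopes(f)
  expect_equal(sl$slope[2] - sl$slope[1], inter$beta)

  # stratified slopes agree with the interaction decomposition
  strat <- fit_stratified(sim$data, "std_sed", "sex")
  b_m <- strat$male$tidy$beta[strat$male$tidy$term == "decimal_age"]
  b_f <- strat$female$tidy$beta[strat$female$tidy$term == "decimal_age"]
  expect_lt(abs(b_m - sl$slope[1]), 3 * inter$se)
  expect_lt(abs(b_f - sl$slope[2]), 3 * inter$se)
})

test_that("day-of-week moderation works on stacked weekday/weekend rows", {
  cfg <- suppressWarnings(sim_config(
    streams = c("weekday", "weekend"),
    weekend_offset = c(sed = -31.9, lpa = -19.5, mvpa = -0.7),
    weekend_slope_delta = c(sed = 0, lpa = 1.0, mvpa = 0)
  ))
  sim <- simulate_cohort(cfg, seed = 308)
  f <- fit_interaction(sim$data, "std_lpa", "stream")
  inter <- f$tidy[f$tidy$term == "decimal_age:streamweekend", ]
  expect_lt(abs(inter$beta - 1.0), 4 * inter$se)
  main <- f$tidy[f$tidy$term == "streamweekend", ]
  expect_lt(abs(main$beta - (-19.5)), 4 * main$se)
})

test_that("tidy reports round to one decimal and keep full precision", {
  tab <- tibble::tibble(term = "decimal_age", beta = 24.93, se = 0.21,
                        ci_low = 24.51, ci_high = 25.34, p = 1e-10)
  fake <- structure(list(tidy = tab, n_obs = 10L, n_participants = 5L,
                         n_studies = 2L, singular = FALSE, converged = TRUE),
                    class = "actichange_fit")
  rep <- tidy_report(fake)
  expect_equal(rep$label, "24.9 (24.5, 25.3)")
  expect_equal(rep$beta, 24.93)
  expect_equal(format_estimate(-2.5, -2.6, -2.3), "-2.5 (-2.6, -2.3)")
  expect_equal(nrow(tidy_report(list())), 0L)
  skipped <- list(a = NULL, b = fake)
  expect_equal(nrow(tidy_report(skipped)), 1L)
})

test_that("moderated_slopes reads plain coefficient tables too", {
  tab <- tibble::tibble(term = c("age", "age:sexfemale"), beta = c(23.5, 2.5))
  sl <- moderated_slopes(tab, exposure = "age")
  expect_equal(sl$slope, c(23.5, 26.0))
  expect_error(moderated_slopes(tibble::tibble(term = "age", beta = 1),
                                exposure = "age"),
               class = "actichange_config_error")
})
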