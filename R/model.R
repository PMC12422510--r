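#' Three-level mixed-effects model of annual change
#'
#' Fits a linear mixed model of a standardized behaviour outcome (min/day)
#' on decimal age, with fixed adjustment for sex and season and random
#' intercepts for study and for participant nested within study: time
#' points (level one) within participants (level two) within studies
#' (level three). Estimation is by REML; the age coefficient is the
#' per-year-of-age change in the outcome. Confidence intervals and
#' p-values are Wald (normal approximation).
#'
#' @param data Analysis tibble; must contain the outcome column, the
#'   exposure, the adjustment columns, `study_id` and `participant_id`.
#' @param outcome Name of the outcome column (e.g. `"std_sed"`).
#' @param exposure Name of the exposure column (default `"decimal_age"`).
#' @param adjust Character vector of fixed adjustment covariates.
#' @param moderator Optional binary moderator column: adds its main effect
#'   and an exposure-by-moderator interaction.
#' @param random_slope If `TRUE`, adds a participant-level random slope on
#'   the exposure (sensitivity analysis; default random intercepts only).
#' @return An object of class `actichange_fit`: list with `tidy`
#'   (term/beta/se/ci_low/ci_high/p), `varcomp` (study, participant,
#'   residual variances), `n_obs`, `n_participants`, `n_studies`,
#'   `n_dropped` (rows lost to missing data), `singular`, `converged`,
#'   `spec`, and the underlying `lme4` fit as `model`.
#' @export
fit_three_level <- function(data, outcome, exposure = "decimal_age",
                            adjust = c("sex", "season"), moderator = NULL,
                            random_slope = FALSE) {
  adjust <- setdiff(adjust, moderator)
  vars <- c(outcome, exposure, adjust, moderator, "study_id", "participant_id")
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0L) {
    abort(paste("missing columns:", paste(missing_cols, collapse = ", ")),
          class = "actichange_config_error")
  }
  complete <- stats::complete.cases(data[vars])
  n_dropped <- sum(!complete)
  if (n_dropped > 0L) {
    inform(sprintf("dropping %d row(s) with missing outcome or covariates", n_dropped))
  }
  d <- droplevels(data[complete, vars])
  if (dplyr::n_distinct(d$study_id) < 2L) {
    abort("need at least 2 studies for a study-level random intercept",
          class = "actichange_degenerate_design_error")
  }
  if (!any(duplicated(paste(d$study_id, d$participant_id)))) {
    abort("no participant has repeated measurements", class = "actichange_degenerate_design_error")
  }
  if (!is.null(moderator)) {
    lev <- unique(stats::na.omit(d[[moderator]]))
    if (length(lev) < 2L) {
      abort(sprintf("moderator '%s' has a single level", moderator),
            class = "actichange_degenerate_design_error")
    }
    if (length(lev) > 2L) {
      abort(sprintf("moderator '%s' must be binary", moderator),
            class = "actichange_degenerate_design_error")
    }
  }
  adjust_used <- adjust[vapply(adjust, function(a) {
    length(unique(stats::na.omit(d[[a]]))) > 1L
  }, logical(1))]
  fixed <- c(exposure, adjust_used,
             if (!is.null(moderator)) c(moderator, paste0(exposure, ":", moderator)))
  re <- if (random_slope) {
    sprintf("(1 | study_id) + (1 + %s | study_id:participant_id)", exposure)
  } else {
    "(1 | study_id) + (1 | study_id:participant_id)"
  }
  fml <- as.formula(paste(outcome, "~", paste(c(fixed, re), collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = d, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    warning = function(w) {
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    }
  )
  singular <- lme4::isSingular(fit, tol = 1e-5)
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  z <- beta / se
  crit <- qnorm(0.975)
  vc <- as.data.frame(lme4::VarCorr(fit))
  getvar <- function(grp) {
    v <- vc$vcov[vc$grp == grp & (is.na(vc$var1) | vc$var1 == "(Intercept)") & is.na(vc$var2)]
    if (length(v) == 0L) NA_real_ else v[1L]
  }
  structure(
    list(
      tidy = tibble::tibble(
        term = names(beta),
        beta = unname(beta),
        se = unname(se),
        ci_low = unname(beta - crit * se),
        ci_high = unname(beta + crit * se),
        p = unname(2 * pnorm(-abs(z)))
      ),
      varcomp = c(
        study = getvar("study_id"),
        participant = getvar("study_id:participant_id"),
        residual = vc$vcov[vc$grp == "Residual"][1L]
      ),
      n_obs = nrow(d),
      n_participants = dplyr::n_distinct(paste(d$study_id, d$participant_id)),
      n_studies = dplyr::n_distinct(d$study_id),
      n_dropped = n_dropped,
      singular = singular,
      converged = converged,
      spec = list(outcome = outcome, exposure = exposure, adjust = adjust_used,
                  moderator = moderator, random_slope = random_slope),
      model = fit
    ),
    class = "actichange_fit"
  )
}

#' @export
#' @method print actichange_fit
print.actichange_fit <- function(x, ...) {
  cat(sprintf("Three-level mixed model: %s ~ %s%s\n", x$spec$outcome,
              paste(c(x$spec$exposure, x$spec$adjust), collapse = " + "),
              if (!is.null(x$spec$moderator))
                sprintf(" (moderated by %s)", x$spec$moderator) else ""))
  cat(sprintf("  %d observations, %d participants, %d studies%s%s\n",
              x$n_obs, x$n_participants, x$n_studies,
              if (x$singular) " [singular fit]" else "",
              if (!x$converged) " [convergence warning]" else ""))
  print(as.data.frame(x$tidy), digits = 4)
  cat(sprintf("  variance components: study %.2f, participant %.2f, residual %.2f\n",
              x$varcomp[["study"]], x$varcomp[["participant"]],
              x$varcomp[["residual"]]))
  invisible(x)
}

#' Stratified model fits
#'
#' Fits the three-level model independently within each level of a
#' stratification variable. Strata whose design is degenerate (e.g., a
#' single study) are skipped and reported, not silently dropped.
#'
#' @inheritParams fit_three_level
#' @param strata Name of the stratification column.
#' @return Named list of `actichange_fit` objects (one per stratum level);
#'   skipped strata appear as `NULL` with a warning, and the skip reasons
#'   are attached as attribute `"skipped"`.
#' @export
fit_stratified <- function(data, outcome, strata, exposure = "decimal_age",
                           adjust = c("sex", "season")) {
  adjust <- setdiff(adjust, strata)
  levels_present <- unique(stats::na.omit(data[[strata]]))
  if (length(levels_present) < 2L) {
    warn(sprintf("'%s' has a single level present; returning one stratum", strata))
  }
  skipped <- character()
  fits <- lapply(as.character(sort(levels_present)), function(lev) {
    sub <- data[!is.na(data[[strata]]) & data[[strata]] == lev, , drop = FALSE]
    tryCatch(
      fit_three_level(sub, outcome, exposure, adjust),
      error = function(e) {
        skipped[[lev]] <<- conditionMessage(e)
        warn(sprintf("stratum %s = %s skipped: %s", strata, lev,
                     conditionMessage(e)))
        NULL
      }
    )
  })
  names(fits) <- as.character(sort(levels_present))
  attr(fits, "skipped") <- skipped
  fits
}

#' Effect-modification (interaction) model
#'
#' Adds a binary moderator and its interaction with the exposure to the
#' three-level model. The exposure coefficient is then the slope in the
#' moderator's reference level; the interaction coefficient is the
#' between-group difference in slope. For day-of-week moderation, supply
#' weekday and weekend wave rows stacked long with a `stream` column and
#' pass `moderator = "stream"`; the participant random intercept is shared
#' across the stacked rows.
#'
#' @inheritParams fit_three_level
#' @param moderator Binary moderator column name.
#' @return An `actichange_fit`.
#' @export
fit_interaction <- function(data, outcome, moderator,
                            exposure = "decimal_age",
                            adjust = c("sex", "season")) {
  fit_three_level(data, outcome, exposure, adjust, moderator = moderator)
}

#' Implied slope in each moderator level
#'
#' For an interaction model, the non-reference group's slope is the
#' reference (exposure) coefficient plus the interaction coefficient.
#' Accepts either an `actichange_fit` or any data frame with `term` and
#' `beta` columns containing one exposure row and one `exposure:moderator`
#' row.
#'
#' @param x Fit or coefficient table.
#' @param exposure Exposure term name (matched as prefix for the
#'   interaction row).
#' @return Tibble with `level` (`reference` / `modified`) and `slope`.
#' @export
#' @examples
#' tab <- tibble::tibble(term = c("age", "age:sexfemale"), beta = c(23.5, 2.5))
#' moderated_slopes(tab, exposure = "age")  # 23.5 and 26.0
moderated_slopes <- function(x, exposure = "decimal_age") {
  tab <- if (inherits(x, "actichange_fit")) x$tidy else x
  main <- tab$beta[tab$term == exposure]
  inter <- tab$beta[startsWith(tab$term, paste0(exposure, ":"))]
  if (length(main) != 1L || length(inter) != 1L) {
    abort("need exactly one exposure row and one interaction row",
          class = "actichange_config_error")
  }
  tibble::tibble(level = c("reference", "modified"),
                 slope = c(main, main + inter))
}

#' Tidy coefficient report
#'
#' Binds fits into one long coefficient table with full-precision
#' estimates plus a formatted `"beta (ci_low, ci_high)"` string rounded to
#' one decimal place for presentation.
#'
#' @param fits An `actichange_fit`, or a (possibly named) list of them
#'   (`NULL` entries from skipped strata are dropped).
#' @param digits Decimal places for the formatted string.
#' @return Tibble with columns `fit`, `term`, `beta`, `se`, `ci_low`,
#'   `ci_high`, `p`, `label`, `n_obs`, `n_participants`, `n_studies`,
#'   `singular`, `converged`.
#' @export
tidy_report <- function(fits, digits = 1) {
  if (inherits(fits, "actichange_fit")) fits <- list(fits)
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0L) {
    return(tibble::tibble(fit = character(), term = character(),
                          beta = numeric(), se = numeric(),
                          ci_low = numeric(), ci_high = numeric(),
                          p = numeric(), label = character(),
                          n_obs = integer(), n_participants = integer(),
                          n_studies = integer(), singular = logical(),
                          converged = logical()))
  }
  if (is.null(names(fits))) names(fits) <- paste0("fit", seq_along(fits))
  dplyr::bind_rows(lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    f$tidy |>
      dplyr::mutate(
        fit = nm, .before = 1L
      ) |>
      dplyr::mutate(
        label = format_estimate(.data$beta, .data$ci_low, .data$ci_high, digits),
        n_obs = f$n_obs, n_participants = f$n_participants,
        n_studies = f$n_studies, singular = f$singular,
        converged = f$converged
      )
  }))
}

#' Format "beta (95% CI)" strings
#'
#' @param beta,ci_low,ci_high Numeric vectors.
#' @param digits Decimal places.
#' @return Character vector like `"24.9 (24.5, 25.3)"`; negative values use
#'   a plain ASCII minus.
#' @export
format_estimate <- function(beta, ci_low, ci_high, digits = 1) {
  fmt <- function(v) sprintf(paste0("%.", digits, "f"), v)
  sprintf("%s (%s, %s)", fmt(beta), fmt(ci_low), fmt(ci_high))
}
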