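#' SF-12 case thresholds
#'
#' A person counts as a case of depressive disorder when their MCS-12 score
#' is at or below `mcs_case_max` (default 45.6; a score of 45.7 or more is
#' not a case), and as a case of a clinically significant physical health
#' problem when their PCS-12 score is at or below `pcs_case_max` (default
#' 50).
#'
#' @param mcs_case_max,pcs_case_max Case-defining maxima, in `(0, 100)`.
#' @return Object of class `health_thresholds`.
#' @export
health_thresholds <- function(mcs_case_max = 45.6, pcs_case_max = 50) {
  if (mcs_case_max <= 0 || mcs_case_max >= 100 ||
      pcs_case_max <= 0 || pcs_case_max >= 100) {
    stop("case thresholds must lie in (0, 100)", call. = FALSE)
  }
  structure(list(mcs_case_max = mcs_case_max, pcs_case_max = pcs_case_max),
            class = "health_thresholds")
}

#' Impute baseline SF-12 scores for a cross-sectional population
#'
#' The microsimulation base population carries no SF-12 instrument, so
#' baseline scores are imputed as the fitted model's linear predictor
#' (evaluated at baseline transformed income, with `x_within = 0`) plus a
#' seeded normal residual draw, clipped to the instrument range `[0, 100]`.
#'
#' @param population Person table carrying every covariate the model used.
#' @param coeffs A `coefficient_set` for one outcome.
#' @param income Baseline net equivalised income (GBP/month) per row.
#' @param residual_sd Score-point sd of the imputation draw.
#' @param seed Integer seed.
#' @return Numeric vector of imputed baseline scores.
#' @export
impute_baseline_scores <- function(population, coeffs, income,
                                   residual_sd = 8, seed = 1) {
  x <- transform_income(income, coeffs$transform)
  lp <- linear_predictor(coeffs, population, x_between = x)
  noise <- if (residual_sd > 0) {
    with_seed(derive_seed(seed, paste0("impute_", coeffs$outcome)),
              stats::rnorm(length(lp), 0, residual_sd))
  } else 0
  pmin(pmax(lp + noise, 0), 100)
}

#' Predicted SF-12 score change from an income change
#'
#' Uses the between coefficient -- the effect of a permanent difference in
#' income level -- to forecast the score change implied by moving from the
#' baseline to the reform income:
#' `delta = beta_between * (f(income_reform) - f(income_base))` with `f` the
#' model's income transform (GBP 1 floor under log).
#'
#' @param income_base,income_reform Net equivalised incomes, GBP/month.
#' @param coeffs_mcs,coeffs_pcs `coefficient_set` objects for the two
#'   outcomes (either may be omitted as `NULL`).
#' @param transform Income transform; must match the coefficient sets.
#' @return Data frame with `dincome_f` (the transformed-income change) and
#'   `delta_mcs`, `delta_pcs` where the corresponding coefficients were
#'   supplied.
#' @export
predict_score_change <- function(income_base, income_reform,
                                 coeffs_mcs = NULL, coeffs_pcs = NULL,
                                 transform = "log") {
  for (cs in list(coeffs_mcs, coeffs_pcs)) {
    if (!is.null(cs) && cs$transform != transform) {
      stop("income transform mismatch: coefficients use ", cs$transform,
           ", config says ", transform, call. = FALSE)
    }
  }
  if (any(income_base < 0 | income_reform < 0)) {
    stop("incomes must be >= 0", call. = FALSE)
  }
  df <- transform_income(income_reform, transform) -
    transform_income(income_base, transform)
  out <- data.frame(dincome_f = df)
  if (!is.null(coeffs_mcs)) out$delta_mcs <- coeffs_mcs$beta_between * df
  if (!is.null(coeffs_pcs)) out$delta_pcs <- coeffs_pcs$beta_between * df
  out
}

#' Weighted case count
#'
#' Sum of weights over persons whose score is at or below the case-defining
#' threshold.
#'
#' @param scores Numeric scores.
#' @param threshold_max Case-defining maximum (score <= threshold is a case).
#' @param weights Grossing weights, aligned with `scores`.
#' @return Weighted number of cases.
#' @export
count_cases <- function(scores, threshold_max, weights = rep(1, length(scores))) {
  stopifnot(length(scores) == length(weights))
  sum(weights[scores <= threshold_max])
}

#' Build per-person health states for a reform
#'
#' Combines imputed baseline scores with predicted score changes into the
#' person-level table consumed by [cases_prevented()].
#'
#' @param population Adult person table (covariates + `weight`).
#' @param income_base,income_reform Net equivalised incomes per person.
#' @param coeffs_mcs,coeffs_pcs Fitted `coefficient_set`s.
#' @param residual_sd,seed Imputation noise parameters (see
#'   [impute_baseline_scores()]).
#' @return Data frame of class `person_health_state` with baseline scores,
#'   deltas, reform scores (base + delta exactly) and weights.
#' @export
person_health_states <- function(population, income_base, income_reform,
                                 coeffs_mcs, coeffs_pcs,
                                 residual_sd = 8, seed = 1) {
  stopifnot(nrow(population) == length(income_base),
            length(income_base) == length(income_reform))
  ch <- predict_score_change(income_base, income_reform, coeffs_mcs,
                             coeffs_pcs, transform = coeffs_mcs$transform)
  out <- data.frame(
    person_id = population$person_id %||% seq_len(nrow(population)),
    mcs_base = impute_baseline_scores(population, coeffs_mcs, income_base,
                                      residual_sd, seed),
    pcs_base = impute_baseline_scores(population, coeffs_pcs, income_base,
                                      residual_sd, seed),
    delta_mcs = ch$delta_mcs,
    delta_pcs = ch$delta_pcs,
    dincome_f = ch$dincome_f,
    weight = population$weight %||% rep(1, nrow(population))
  )
  out$mcs_reform <- out$mcs_base + out$delta_mcs
  out$pcs_reform <- out$pcs_base + out$delta_pcs
  class(out) <- c("person_health_state", "data.frame")
  out
}

#' Weighted cases prevented or postponed, with bootstrap CIs
#'
#' Net annual weighted case difference between baseline and reform for both
#' outcomes: cases at baseline minus cases at reform (new cases created by
#' income losses are netted off). Confidence intervals propagate coefficient
#' uncertainty only: for each bootstrap replicate's between coefficient the
#' deltas are recomputed while the baseline imputation draws stay fixed, and
#' percentile 2.5/97.5 bounds of the prevented count are reported.
#'
#' @param states A `person_health_state` table from [person_health_states()].
#' @param thresholds A [health_thresholds()].
#' @param coeffs_mcs,coeffs_pcs Optional `coefficient_set`s carrying
#'   `bootstrap_draws`; when absent (or without draws) CIs are omitted.
#' @return Data frame of class `case_change_report`, one row per outcome:
#'   `cases_base`, `cases_reform`, `cases_prevented`, `ci_lower`, `ci_upper`.
#' @export
cases_prevented <- function(states, thresholds = health_thresholds(),
                            coeffs_mcs = NULL, coeffs_pcs = NULL) {
  one <- function(base, delta, thr, coeffs) {
    cb <- count_cases(base, thr, states$weight)
    cr <- count_cases(base + delta, thr, states$weight)
    prevented <- cb - cr
    ci <- c(NA_real_, NA_real_)
    if (!is.null(coeffs) && !is.null(coeffs$bootstrap_draws) &&
        nrow(coeffs$bootstrap_draws) >= 2) {
      bb <- coeffs$bootstrap_draws[, "x_between"]
      prev_rep <- vapply(bb, function(b) {
        cb - count_cases(base + b * states$dincome_f, thr, states$weight)
      }, numeric(1))
      ci <- stats::quantile(prev_rep, c(0.025, 0.975), names = FALSE)
    }
    c(cases_base = cb, cases_reform = cr, cases_prevented = prevented,
      ci_lower = ci[1], ci_upper = ci[2])
  }
  m <- one(states$mcs_base, states$delta_mcs, thresholds$mcs_case_max,
           coeffs_mcs)
  p <- one(states$pcs_base, states$delta_pcs, thresholds$pcs_case_max,
           coeffs_pcs)
  out <- data.frame(
    outcome = c("depressive_disorder", "physical_health_problem"),
    rbind(m, p),
    row.names = NULL
  )
  class(out) <- c("case_change_report", "data.frame")
  out
}
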