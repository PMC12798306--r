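#' Linear SF-12 to SF-6D crosswalk
#'
#' A configurable linear mapping from SF-12 component scores to SF-6D
#' utility: `utility = intercept + coef_mcs * MCS + coef_pcs * PCS`, clamped
#' to `[floor, ceiling]`. The reference analyses use a proprietary converter;
#' this package ships a transparent linear crosswalk whose slopes sit in the
#' range of published SF-12 to SF-6D mappings and whose intercept is
#' calibrated so a population with mean MCS 50.47 and PCS 50.18 has mean
#' utility 0.7857. The floor default is the published SF-6D (SF-12) valuation
#' floor.
#'
#' @param intercept Utility at MCS = PCS = 0 (before clamping).
#' @param coef_mcs,coef_pcs Utility per score point.
#' @param floor,ceiling Utility bounds; `floor < ceiling <= 1`.
#' @return Object of class `sf6d_crosswalk`.
#' @export
sf6d_crosswalk <- function(intercept = 0.7857 - 0.0050 * 50.47 - 0.0098 * 50.18,
                           coef_mcs = 0.0050,
                           coef_pcs = 0.0098,
                           floor = 0.345,
                           ceiling = 1.0) {
  if (!(floor < ceiling && ceiling <= 1)) {
    stop("need floor < ceiling <= 1", call. = FALSE)
  }
  structure(list(intercept = intercept, coef_mcs = coef_mcs,
                 coef_pcs = coef_pcs, floor = floor, ceiling = ceiling),
            class = "sf6d_crosswalk")
}

#' SF-6D utility change from SF-12 score changes
#'
#' `delta_utility = coef_mcs * delta_mcs + coef_pcs * delta_pcs`. When
#' baseline component scores are supplied, baseline and reform utilities are
#' clamped to the crosswalk's `[floor, ceiling]` before differencing, so no
#' person's utility can exceed full health (1.0) or fall below the
#' instrument floor.
#'
#' @param delta_mcs,delta_pcs Score-point changes.
#' @param crosswalk A [sf6d_crosswalk()].
#' @param mcs_base,pcs_base Optional baseline scores enabling the clamp.
#' @return Utility change per person.
#' @export
sf6d_delta <- function(delta_mcs, delta_pcs, crosswalk = sf6d_crosswalk(),
                       mcs_base = NULL, pcs_base = NULL) {
  raw <- crosswalk$coef_mcs * delta_mcs + crosswalk$coef_pcs * delta_pcs
  if (is.null(mcs_base) || is.null(pcs_base)) return(raw)
  clamp <- function(u) pmin(pmax(u, crosswalk$floor), crosswalk$ceiling)
  u0 <- clamp(crosswalk$intercept + crosswalk$coef_mcs * mcs_base +
                crosswalk$coef_pcs * pcs_base)
  u1 <- clamp(crosswalk$intercept + crosswalk$coef_mcs * (mcs_base + delta_mcs) +
                crosswalk$coef_pcs * (pcs_base + delta_pcs))
  u1 - u0
}

#' Annual QALYs gained
#'
#' Weighted sum of per-person utility changes, treated as an annual impact;
#' totals over a multi-year policy are `annual * years`.
#'
#' @param delta_utility Utility change per person.
#' @param weights Grossing weights (> 0).
#' @param years Years the policy is in operation.
#' @return QALYs (per year when `years = 1`).
#' @export
qalys_gained <- function(delta_utility, weights = rep(1, length(delta_utility)),
                         years = 1) {
  stopifnot(all(weights > 0))
  sum(weights * delta_utility) * years
}

#' Monetary value of QALYs gained
#'
#' @param qalys Number of QALYs.
#' @param value_per_qaly GBP per QALY (default 30,000, the upper NICE
#'   cost-effectiveness threshold).
#' @param green_book_multiplier Multiplier converting to the HM Treasury
#'   Green Book QALY value used in cross-sector appraisal (70,000/30,000,
#'   printed as 2.33).
#' @return List with `value` (GBP), `value_bn` (GBP billions, 2 d.p.),
#'   `value_green_book` (GBP).
#' @export
monetise <- function(qalys, value_per_qaly = 30000,
                     green_book_multiplier = 2.33) {
  v <- qalys * value_per_qaly
  list(value = v,
       value_bn = round(v / 1e9, 2),
       value_green_book = v * green_book_multiplier)
}

#' Default synthetic years-of-life multiplier table
#'
#' Sex- and age-band-specific multipliers converting a person's QALY gain
#' into years of life expectancy gained. This default table is synthetic:
#' values decline with age, are slightly higher for women, and are
#' calibrated so the population-average multiplier under the default adult
#' age mix is about 1.3, the ratio implied by published aggregate YLG and
#' QALY figures. Supply a published table for substantive work.
#'
#' @return Data frame with `sex`, `age_band`, `multiplier`.
#' @export
default_ylg_multipliers <- function() {
  bands <- c("18-24", "25-34", "35-44", "45-54", "55-64", "65+")
  base <- c(1.9, 1.7, 1.5, 1.4, 1.2, 1.0)
  rbind(
    data.frame(sex = "female", age_band = bands, multiplier = base + 0.05),
    data.frame(sex = "male", age_band = bands, multiplier = base - 0.05)
  )
}

#' Years of Life Gained from per-person QALY gains
#'
#' `YLG = sum(weight * person_qalys * multiplier(sex, age band))`.
#'
#' @param person_qalys Per-person annual QALY gain (utility change).
#' @param sex,age_band Person characteristics, matched against the
#'   multiplier table.
#' @param weights Grossing weights.
#' @param multipliers Table as from [default_ylg_multipliers()].
#' @return Total years of life gained.
#' @export
years_of_life_gained <- function(person_qalys, sex, age_band,
                                 weights = rep(1, length(person_qalys)),
                                 multipliers = default_ylg_multipliers()) {
  key <- paste(sex, age_band)
  mkey <- paste(multipliers$sex, multipliers$age_band)
  hit <- match(key, mkey)
  if (anyNA(hit)) {
    stop("no YLG multiplier for: ",
         paste(unique(key[is.na(hit)]), collapse = ", "), call. = FALSE)
  }
  sum(weights * person_qalys * multipliers$multiplier[hit])
}

#' Cost model for depressive-disorder treatment savings
#'
#' Unit costs per treated case per year under two perspectives: the NHS and
#' personal social services (third-party payer) perspective, and a total
#' perspective adding primary/community care, secondary care, social care,
#' informal care and patients' other costs. Default unit costs are
#' back-derived from the published aggregate savings and case counts
#' (approximately GBP 2,040 NHS/PSS and GBP 9,105 total per treated case per
#' year, already in 2023 prices, hence `cpi_factor_to_2023 = 1`); they are
#' derived defaults, not primary cost data. Only half of prevented cases are
#' assumed diagnosed and treated (`treated_share = 0.5`).
#'
#' @param unit_cost_nhs_pss,unit_cost_total GBP per treated case per year.
#' @param treated_share Fraction of cases that incur treatment costs.
#' @param cpi_factor_to_2023 CPI uprating factor applied to unit costs.
#' @return Object of class `cost_model`.
#' @export
cost_model <- function(unit_cost_nhs_pss = mean(c(126e6 / 62000,
                                                  549e6 / 268500,
                                                  1026e6 / 502500)),
                       unit_cost_total = mean(c(563e6 / 62000,
                                                2449e6 / 268500,
                                                4579e6 / 502500)),
                       treated_share = 0.5,
                       cpi_factor_to_2023 = 1) {
  if (unit_cost_total < unit_cost_nhs_pss || unit_cost_nhs_pss < 0) {
    stop("need unit_cost_total >= unit_cost_nhs_pss >= 0", call. = FALSE)
  }
  if (treated_share < 0 || treated_share > 1) {
    stop("treated_share must be in [0, 1]", call. = FALSE)
  }
  structure(list(unit_cost_nhs_pss = unit_cost_nhs_pss,
                 unit_cost_total = unit_cost_total,
                 treated_share = treated_share,
                 cpi_factor_to_2023 = cpi_factor_to_2023),
            class = "cost_model")
}

#' Cost savings from depressive-disorder cases prevented
#'
#' `savings = cases_prevented * treated_share * unit_cost * cpi_factor` per
#' perspective; CI bounds apply the same formula to the case-count CI
#' bounds. Physical-health case reports are refused: physical-health cost
#' savings are out of the model's scope (no comparable unit-cost base).
#'
#' @param case_report One row of a `case_change_report` (or the full report,
#'   from which the depressive-disorder row is taken).
#' @param costs A [cost_model()].
#' @return Data frame with one row per perspective: `savings`, `ci_lower`,
#'   `ci_upper` (GBP/year, 2023 prices).
#' @export
cost_savings <- function(case_report, costs = cost_model()) {
  if (is.data.frame(case_report) && "outcome" %in% names(case_report)) {
    if (all(case_report$outcome != "depressive_disorder")) {
      stop("cost savings are modelled for depressive disorder only; ",
           "physical-health savings are out of scope", call. = FALSE)
    }
    case_report <- case_report[case_report$outcome == "depressive_disorder", ]
  }
  f <- function(cases, unit) {
    cases * costs$treated_share * unit * costs$cpi_factor_to_2023
  }
  do.call(rbind, lapply(
    list(c("nhs_pss", costs$unit_cost_nhs_pss),
         c("total", costs$unit_cost_total)),
    function(p) {
      unit <- as.numeric(p[2])
      data.frame(
        perspective = p[1],
        savings = f(case_report$cases_prevented, unit),
        ci_lower = f(case_report$ci_lower, unit),
        ci_upper = f(case_report$ci_upper, unit)
      )
    }
  ))
}

#' Valuation configuration
#'
#' Bundles the SF-6D crosswalk, the monetary value per QALY, the years-of-
#' life multiplier table and the treatment cost model.
#'
#' @param crosswalk A [sf6d_crosswalk()].
#' @param value_per_qaly GBP per QALY (> 0).
#' @param green_book_multiplier Cross-sector appraisal multiplier.
#' @param ylg_multipliers Table as from [default_ylg_multipliers()].
#' @param costs A [cost_model()].
#' @return Object of class `valuation_config`.
#' @export
valuation_config <- function(crosswalk = sf6d_crosswalk(),
                             value_per_qaly = 30000,
                             green_book_multiplier = 2.33,
                             ylg_multipliers = default_ylg_multipliers(),
                             costs = cost_model()) {
  if (value_per_qaly <= 0) stop("value_per_qaly must be > 0", call. = FALSE)
  if (any(ylg_multipliers$multiplier < 0)) {
    stop("YLG multipliers must be >= 0", call. = FALSE)
  }
  structure(list(crosswalk = crosswalk, value_per_qaly = value_per_qaly,
                 green_book_multiplier = green_book_multiplier,
                 ylg_multipliers = ylg_multipliers, costs = costs),
            class = "valuation_config")
}
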