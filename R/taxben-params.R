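#' Parameters of the stylised UK tax-benefit system
#'
#' A deliberately simplified, fully parameterised stand-in for the UK direct
#' tax and benefit system: one marginal income-tax schedule, one National
#' Insurance schedule, Child Benefit, the State Pension, and a Universal
#' Credit (UC) style means-tested benefit with a taper on net earnings and a
#' pound-for-pound offset of unearned income. Amounts follow 2023/24 UK
#' values by default but every element is configuration, not statute.
#'
#' @param income_tax_bands Data frame with columns `threshold` (GBP/year,
#'   nondecreasing) and `rate` (in `[0,1]`): marginal rate applying above each
#'   threshold.
#' @param ni_bands Same structure for National Insurance.
#' @param child_benefit_first,child_benefit_subsequent GBP/week for the first
#'   and each subsequent child.
#' @param state_pension GBP/week per person at or above `pension_age`.
#' @param pension_age Years (default 65, aligning with the Basic Income
#'   schemes' 65+ band).
#' @param uc_standard_allowance Named vector, GBP/month, by family type
#'   (`single`, `couple`).
#' @param uc_child_element GBP/month per child.
#' @param uc_taper Fraction of net household earnings above the disregard
#'   withdrawn from UC.
#' @param uc_earnings_disregard GBP/month of net earnings ignored by the
#'   taper (work allowance).
#' @param uc_takeup Probability that an entitled household claims UC; draws
#'   are an independent seeded Bernoulli per household when `< 1`.
#' @param funding_adjustment Optional list with `rate_increase_pp`
#'   (percentage points added to every nonzero income-tax rate) and
#'   `personal_allowance_delta` (GBP/year added to the first nonzero-rate
#'   threshold), applied to the reform system only.
#'
#' @return Object of class `taxben_params`.
#' @export
taxben_params <- function(income_tax_bands = data.frame(
                            threshold = c(0, 12570, 50270, 125140),
                            rate = c(0, 0.20, 0.40, 0.45)),
                          ni_bands = data.frame(
                            threshold = c(0, 12570, 50270),
                            rate = c(0, 0.12, 0.02)),
                          child_benefit_first = 24.00,
                          child_benefit_subsequent = 15.90,
                          state_pension = 203.85,
                          pension_age = 65,
                          uc_standard_allowance = c(single = 368.74,
                                                    couple = 578.82),
                          uc_child_element = 269.58,
                          uc_taper = 0.55,
                          uc_earnings_disregard = 344,
                          uc_takeup = 1,
                          funding_adjustment = NULL) {
  check_schedule <- function(b, what) {
    if (!all(c("threshold", "rate") %in% names(b))) {
      stop(what, " must have threshold and rate columns", call. = FALSE)
    }
    if (is.unsorted(b$threshold)) {
      stop(what, " thresholds must be nondecreasing", call. = FALSE)
    }
    if (any(b$rate < 0 | b$rate > 1)) {
      stop(what, " rates must be in [0, 1]", call. = FALSE)
    }
  }
  check_schedule(income_tax_bands, "income_tax_bands")
  check_schedule(ni_bands, "ni_bands")
  if (uc_taper < 0 || uc_taper > 1) stop("uc_taper must be in [0, 1]", call. = FALSE)
  if (uc_takeup < 0 || uc_takeup > 1) stop("uc_takeup must be in [0, 1]", call. = FALSE)
  structure(
    list(income_tax_bands = income_tax_bands,
         ni_bands = ni_bands,
         child_benefit_first = child_benefit_first,
         child_benefit_subsequent = child_benefit_subsequent,
         state_pension = state_pension,
         pension_age = pension_age,
         uc_standard_allowance = uc_standard_allowance,
         uc_child_element = uc_child_element,
         uc_taper = uc_taper,
         uc_earnings_disregard = uc_earnings_disregard,
         uc_takeup = uc_takeup,
         funding_adjustment = funding_adjustment),
    class = "taxben_params"
  )
}

#' Define a Basic Income scheme
#'
#' A Basic Income scheme pays a universal weekly amount per person by age
#' band (under 18; 18 to below 65; 65+), replaces a configurable set of
#' non-means-tested benefits one for one, and is counted as unearned income
#' in the UC calculation net of a configurable monthly disregard.
#'
#' @param name Scheme label.
#' @param rate_child GBP/week per person under 18.
#' @param rate_adult GBP/week per person aged 18 to below 65.
#' @param rate_65plus GBP/week per person aged 65+.
#' @param replaces Character subset of `c("child_benefit", "state_pension")`.
#' @param uc_bi_disregard GBP/month of Basic Income ignored when computing UC
#'   unearned income (applied per household).
#' @return Object of class `scheme_definition`.
#' @export
scheme_definition <- function(name, rate_child, rate_adult, rate_65plus,
                              replaces = c("child_benefit", "state_pension"),
                              uc_bi_disregard = 0) {
  known <- c("child_benefit", "state_pension")
  if (length(replaces) && !all(replaces %in% known)) {
    stop("unknown benefit in replaces: ",
         paste(setdiff(replaces, known), collapse = ", "), call. = FALSE)
  }
  if (any(c(rate_child, rate_adult, rate_65plus, uc_bi_disregard) < 0)) {
    stop("scheme rates and disregard must be >= 0", call. = FALSE)
  }
  structure(
    list(name = name, rate_child = rate_child, rate_adult = rate_adult,
         rate_65plus = rate_65plus, replaces = replaces,
         uc_bi_disregard = uc_bi_disregard),
    class = "scheme_definition"
  )
}

#' The three modelled Basic Income schemes
#'
#' Weekly rates (child / adult 18-64 / 65+): Starter 50/75/205, Intermediate
#' 75/185/205, and a Minimum Income Standard level scheme 100/295/295. The
#' Starter and Intermediate schemes carry a small UC disregard (default GBP
#' 10/month) so low-income UC recipients gain from the reform; the MIS-level
#' scheme pays enough that no disregard is needed.
#'
#' @param disregard GBP/month UC disregard for schemes 1 and 2.
#' @return Named list of three [scheme_definition()] objects.
#' @export
bi_schemes <- function(disregard = 10) {
  list(
    scheme1 = scheme_definition("scheme1", 50, 75, 205,
                                uc_bi_disregard = disregard),
    scheme2 = scheme_definition("scheme2", 75, 185, 205,
                                uc_bi_disregard = disregard),
    scheme3 = scheme_definition("scheme3", 100, 295, 295,
                                uc_bi_disregard = 0)
  )
}

#' @export
print.scheme_definition <- function(x, ...) {
  cat(sprintf("<scheme_definition> %s: GBP/week %g child, %g adult, %g 65+;",
              x$name, x$rate_child, x$rate_adult, x$rate_65plus),
      "\n  replaces:", paste(x$replaces, collapse = ", "),
      " UC disregard:", x$uc_bi_disregard, "GBP/month\n")
  invisible(x)
}
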