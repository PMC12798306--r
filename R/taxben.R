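#' OECD-modified equivalence factor
#'
#' First household member aged 14+ contributes 1.0, each additional member
#' aged 14+ contributes 0.5, and each child aged 0-13 contributes 0.3.
#' Equivalised income is unequivalised income divided by this factor.
#'
#' @param ages Numeric vector of member ages (>= 1 member).
#' @return The equivalence factor (dimensionless).
#' @export
equivalence_factor <- function(ages) {
  if (length(ages) == 0) stop("household must have at least one member", call. = FALSE)
  n_adult <- sum(ages >= 14)
  n_child <- sum(ages < 14)
  if (n_adult == 0) return(0.3 * n_child)
  1 + 0.5 * (n_adult - 1) + 0.3 * n_child
}

# Marginal-schedule amount due on an annual income, vectorised over incomes.
schedule_amount <- function(annual, bands) {
  out <- numeric(length(annual))
  k <- nrow(bands)
  upper <- c(bands$threshold[-1], Inf)
  for (i in seq_len(k)) {
    out <- out + bands$rate[i] *
      pmax(0, pmin(annual, upper[i]) - bands$threshold[i])
  }
  out
}

adjusted_tax_bands <- function(params) {
  fa <- params$funding_adjustment
  bands <- params$income_tax_bands
  if (is.null(fa)) return(bands)
  inc <- fa$rate_increase_pp %||% 0
  pad <- fa$personal_allowance_delta %||% 0
  bands$rate <- ifelse(bands$rate > 0, pmin(1, bands$rate + inc / 100), bands$rate)
  nz <- which(bands$rate > 0)
  if (length(nz) && pad != 0) {
    bands$threshold[nz[1]] <- max(0, bands$threshold[nz[1]] + pad)
    bands$threshold <- cummax(bands$threshold)
  }
  bands
}

# Core household calculator shared by baseline and reform. `persons` must
# carry household_id, age, earned_income, unearned_income. Returns one row
# per household (ordered by household_id). `claims` is the per-household UC
# take-up outcome; BI is included only when `scheme` is given.
calc_households <- function(persons, params, scheme = NULL, claims = NULL,
                            reform_tax = FALSE) {
  req <- c("household_id", "age", "earned_income", "unearned_income")
  if (!all(req %in% names(persons))) {
    stop("persons table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(persons$earned_income < 0 | persons$unearned_income < 0)) {
    stop("negative gross income", call. = FALSE)
  }
  hid <- persons$household_id
  hids <- sort(unique(hid))
  idx <- match(hid, hids)
  nh <- length(hids)

  tax_bands <- if (reform_tax) adjusted_tax_bands(params) else params$income_tax_bands
  tax_p <- schedule_amount(persons$earned_income * 12, tax_bands) / 12
  ni_p <- schedule_amount(persons$earned_income * 12, params$ni_bands) / 12

  agg <- function(x) {
    out <- numeric(nh)
    s <- rowsum(x, idx)
    out[as.integer(rownames(s))] <- s
    out
  }
  gross_earned <- agg(persons$earned_income)
  tax <- agg(tax_p)
  ni <- agg(ni_p)
  unearned <- agg(persons$unearned_income)
  n_child <- agg(as.numeric(persons$age < 18))
  n_adult_1864 <- agg(as.numeric(persons$age >= 18 & persons$age < params$pension_age))
  n_pension <- agg(as.numeric(persons$age >= params$pension_age))
  n_adult14 <- agg(as.numeric(persons$age >= 14))

  cb <- ifelse(n_child > 0,
               weekly_to_monthly(params$child_benefit_first +
                                   params$child_benefit_subsequent *
                                   pmax(0, n_child - 1)),
               0)
  sp <- weekly_to_monthly(params$state_pension) * n_pension

  bi <- numeric(nh)
  bi_counted <- numeric(nh)
  if (!is.null(scheme)) {
    n_adult_bi <- n_adult_1864
    n_65 <- agg(as.numeric(persons$age >= 65))
    n_18to64 <- agg(as.numeric(persons$age >= 18 & persons$age < 65))
    bi <- weekly_to_monthly(scheme$rate_child * n_child +
                              scheme$rate_adult * n_18to64 +
                              scheme$rate_65plus * n_65)
    bi_counted <- pmax(0, bi - scheme$uc_bi_disregard)
    if ("child_benefit" %in% scheme$replaces) cb <- numeric(nh)
    if ("state_pension" %in% scheme$replaces) sp <- numeric(nh)
  }

  net_earnings <- gross_earned - tax - ni
  uc_unearned <- unearned + sp + bi_counted
  fam <- ifelse(n_adult14 >= 2, "couple", "single")
  allowance <- unname(params$uc_standard_allowance[fam]) +
    params$uc_child_element * n_child
  eligible <- n_adult_1864 >= 1
  uc_entitlement <- pmax(
    0,
    allowance -
      params$uc_taper * pmax(0, net_earnings - params$uc_earnings_disregard) -
      uc_unearned
  )
  uc_entitlement[!eligible] <- 0
  if (is.null(claims)) claims <- rep(TRUE, nh)
  uc <- uc_entitlement * as.numeric(claims)

  data.frame(
    household_id = hids,
    gross_earned = gross_earned,
    tax = tax, ni = ni,
    unearned = unearned,
    child_benefit = cb,
    state_pension = sp,
    uc = uc,
    bi = bi,
    net_income = gross_earned + unearned - tax - ni + cb + sp + uc + bi,
    n_children = n_child,
    stringsAsFactors = FALSE
  )
}

uc_claim_draw <- function(nh, params, seed) {
  if (params$uc_takeup >= 1) return(rep(TRUE, nh))
  with_seed(derive_seed(seed %||% 0, "uc_takeup"),
            stats::runif(nh) < params$uc_takeup)
}

#' Baseline net household income under the stylised system
#'
#' Net monthly household income before housing costs: gross earned and
#' unearned income minus income tax and National Insurance, plus Child
#' Benefit, State Pension (members at or above pension age) and Universal
#' Credit where entitled. UC is the standard allowance plus child elements,
#' less the taper applied to net earnings above the disregard, less unearned
#' income, floored at zero, and subject to a seeded take-up draw when
#' `uc_takeup < 1`.
#'
#' @param persons Person table with `household_id`, `age`, `earned_income`,
#'   `unearned_income` (GBP/month, gross).
#' @param params A [taxben_params()].
#' @param seed Seed for the UC take-up draw (ignored when `uc_takeup = 1`).
#' @return Data frame, one row per household, with income components and
#'   `net_income` (GBP/month).
#' @export
baseline_net_income <- function(persons, params = taxben_params(), seed = NULL) {
  nh <- length(unique(persons$household_id))
  claims <- uc_claim_draw(nh, params, seed)
  calc_households(persons, params, scheme = NULL, claims = claims)
}

#' Apply a Basic Income scheme to a population
#'
#' Computes baseline and reform net incomes for every household. Under the
#' reform, Basic Income is paid per person by age band, the replaced benefits
#' (Child Benefit, State Pension) are removed one for one, Basic Income net
#' of the scheme's monthly disregard is counted as UC unearned income
#' (flooring UC at zero), and any configured funding adjustment is applied to
#' the reform income-tax schedule. The UC take-up draw is shared between
#' baseline and reform so income changes are not polluted by take-up noise.
#'
#' @inheritParams baseline_net_income
#' @param scheme A [scheme_definition()].
#' @return Data frame of class `income_result`, one row per household:
#'   baseline and reform net and equivalised incomes, `bi_received`,
#'   `benefits_lost`, `taxes_delta`, UC amounts, the household grossing
#'   weight (`weight_hh`, households represented), member counts.
#' @export
apply_scheme <- function(persons, scheme, params = taxben_params(),
                         seed = NULL) {
  stopifnot(inherits(scheme, "scheme_definition"))
  nh <- length(unique(persons$household_id))
  claims <- uc_claim_draw(nh, params, seed)
  base <- calc_households(persons, params, scheme = NULL, claims = claims)
  reform <- calc_households(persons, params, scheme = scheme, claims = claims,
                            reform_tax = !is.null(params$funding_adjustment))

  hids <- base$household_id
  split_ages <- split(persons$age, persons$household_id)
  split_ages <- split_ages[as.character(hids)]
  equiv <- vapply(split_ages, equivalence_factor, numeric(1))
  n_persons <- lengths(split_ages)

  w <- if ("weight" %in% names(persons)) {
    # uniform person weight w means the sampled household stands for w
    # households of identical composition
    vapply(split(persons$weight, persons$household_id)[as.character(hids)],
           function(x) mean(x), numeric(1))
  } else {
    rep(1, length(hids))
  }

  out <- data.frame(
    household_id = hids,
    net_income_base = base$net_income,
    net_income_reform = reform$net_income,
    equiv_factor = unname(equiv),
    bi_received = reform$bi,
    benefits_lost = (base$child_benefit - reform$child_benefit) +
      (base$state_pension - reform$state_pension),
    taxes_delta = (reform$tax + reform$ni) - (base$tax + base$ni),
    uc_base = base$uc,
    uc_reform = reform$uc,
    weight_hh = unname(w),
    n_persons = unname(n_persons),
    n_children = base$n_children,
    stringsAsFactors = FALSE
  )
  out$net_equiv_base <- out$net_income_base / out$equiv_factor
  out$net_equiv_reform <- out$net_income_reform / out$equiv_factor
  # flag means-tested-benefit recipients who lose from the reform: the UC
  # disregard is meant to protect them, but a household whose UC is
  # exhausted mid-absorption can still lose replaced benefits (e.g. Child
  # Benefit) that UC does not compensate
  out$low_income_loser <- out$uc_base > 0 &
    out$net_income_reform < out$net_income_base - 1e-9
  attr(out, "scheme") <- scheme$name
  class(out) <- c("income_result", "data.frame")
  out
}

#' Marginal deduction rate for a household's reference earner
#'
#' Net gain lost from an extra pound of gross earnings: `1 - (change in net
#' household income) / (change in gross earnings)` when the highest-earning
#' member's gross earnings rise by `delta`, taking into account income tax,
#' National Insurance and the UC taper.
#'
#' @param persons Person table for one or more households.
#' @param params A [taxben_params()].
#' @param scheme Optional [scheme_definition()]; when given, the MDR is
#'   computed under the reform system.
#' @param delta Earnings increment, GBP/month (> 0).
#' @param seed Take-up seed (shared across both evaluations).
#' @return Named numeric vector of MDRs, one per household with an earner.
#' @export
marginal_deduction_rate <- function(persons, params = taxben_params(),
                                    scheme = NULL, delta = 1, seed = NULL) {
  if (delta <= 0) stop("delta must be > 0", call. = FALSE)
  earners <- tapply(persons$earned_income, persons$household_id, max)
  if (all(earners <= 0)) stop("household has no earner", call. = FALSE)
  nh <- length(unique(persons$household_id))
  claims <- uc_claim_draw(nh, params, seed)
  net_for <- function(p) {
    calc_households(p, params, scheme = scheme, claims = claims,
                    reform_tax = !is.null(scheme) &&
                      !is.null(params$funding_adjustment))$net_income
  }
  net0 <- net_for(persons)
  bumped <- persons
  for (h in unique(persons$household_id)) {
    rows <- which(persons$household_id == h)
    if (max(persons$earned_income[rows]) <= 0) next
    ref <- rows[which.max(persons$earned_income[rows])]
    bumped$earned_income[ref] <- bumped$earned_income[ref] + delta
  }
  net1 <- net_for(bumped)
  mdr <- 1 - (net1 - net0) / delta
  names(mdr) <- as.character(sort(unique(persons$household_id)))
  mdr[names(earners)[earners > 0]]
}
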