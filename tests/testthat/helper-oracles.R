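# Independent brute-force oracles, coded separately from the package's
# vectorised implementations.

# Marginal schedule, scalar.
oracle_schedule <- function(annual, thresholds, rates) {
  due <- 0
  for (i in seq_along(thresholds)) {
    upper <- if (i < length(thresholds)) thresholds[i + 1] else Inf
    if (annual > thresholds[i]) {
      due <- due + rates[i] * (min(annual, upper) - thresholds[i])
    }
  }
  due
}

# Net monthly income of a single household, scalar loop. `bi` is the list
# of scheme settings or NULL for baseline; assumes full UC take-up.
oracle_net_income <- function(ages, earned, unearned, params, scheme = NULL) {
  tb <- params$income_tax_bands
  nb <- params$ni_bands
  tax <- 0; ni <- 0
  for (i in seq_along(ages)) {
    tax <- tax + oracle_schedule(earned[i] * 12, tb$threshold, tb$rate) / 12
    ni <- ni + oracle_schedule(earned[i] * 12, nb$threshold, nb$rate) / 12
  }
  n_child <- sum(ages < 18)
  cb <- 0
  if (n_child >= 1) {
    cb <- (params$child_benefit_first +
             params$child_benefit_subsequent * (n_child - 1)) * 52 / 12
  }
  sp <- sum(ages >= params$pension_age) * params$state_pension * 52 / 12
  bi <- 0; bi_counted <- 0
  if (!is.null(scheme)) {
    for (a in ages) {
      bi <- bi + (if (a < 18) scheme$rate_child
                  else if (a < 65) scheme$rate_adult
                  else scheme$rate_65plus) * 52 / 12
    }
    bi_counted <- max(0, bi - scheme$uc_bi_disregard)
    if ("child_benefit" %in% scheme$replaces) cb <- 0
    if ("state_pension" %in% scheme$replaces) sp <- 0
  }
  net_earn <- sum(earned) - tax - ni
  fam <- if (sum(ages >= 14) >= 2) "couple" else "single"
  allowance <- params$uc_standard_allowance[[fam]] +
    params$uc_child_element * n_child
  uc <- 0
  if (any(ages >= 18 & ages < params$pension_age)) {
    uc <- max(0, allowance -
                params$uc_taper * max(0, net_earn - params$uc_earnings_disregard) -
                (sum(unearned) + sp + bi_counted))
  }
  sum(earned) + sum(unearned) - tax - ni + cb + sp + uc + bi
}

# Weighted Gini via the pairwise mean-absolute-difference formula.
oracle_gini_pairwise <- function(x, w) {
  n <- length(x)
  s <- 0
  for (i in 1:n) for (j in 1:n) s <- s + w[i] * w[j] * abs(x[i] - x[j])
  mu <- sum(w * x) / sum(w)
  s / (2 * sum(w)^2 * mu)
}

# Small person table for taxben tests: one row per member.
make_household <- function(hid, ages, earned = rep(0, length(ages)),
                           unearned = rep(0, length(ages))) {
  data.frame(household_id = hid, age = ages, earned_income = earned,
             unearned_income = unearned)
}

# Four stylised family types over an earnings grid (reference earner gets
# all the earnings).
grid_population <- function(earnings) {
  types <- list(single = 35, couple = c(40, 38), couple_child = c(40, 38, 8),
                pensioner = 70)
  out <- NULL
  hid <- 0
  for (e in earnings) {
    for (ty in names(types)) {
      hid <- hid + 1
      ages <- types[[ty]]
      earned <- c(e, rep(0, length(ages) - 1))
      out <- rbind(out, make_household(hid, ages, earned))
    }
  }
  out
}

# Quick fitted coefficient set (with bootstrap draws) on a small panel,
# shared by impact/valuation tests.
fitted_coefs <- function(n = 400, reps = 40, seed = 11,
                         truth = true_health_model()) {
  pan <- gen_panel(panel_config(n_households = n, seed = seed), truth)
  sp_m <- model_spec("MCS", truth$transform, controls = "sex",
                     estimator = "pooled_ols_clustered")
  sp_p <- model_spec("PCS", truth$transform, controls = "sex",
                     estimator = "pooled_ols_clustered")
  list(MCS = bootstrap_ci(pan, sp_m, reps = reps, seed = seed),
       PCS = bootstrap_ci(pan, sp_p, reps = reps, seed = seed))
}
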