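#' Configuration for synthetic survey populations
#'
#' Describes a synthetic household population: its size, demographic mix,
#' income process and grossing target. The same configuration type drives both
#' the cross-sectional generator ([gen_cross_section()]), which emulates a
#' Family Resources Survey style microsimulation base, and the longitudinal
#' generator ([gen_panel()]), which emulates an Understanding Society style
#' balanced panel of individuals.
#'
#' @param n_households Number of sampled households (for the panel generator,
#'   the number of panel individuals, one adult per sampled household).
#' @param n_waves Number of panel waves (>= 2; default 12).
#' @param seed Integer seed; identical configuration + seed gives identical
#'   output.
#' @param demographic_mix Named list of categorical marginal proportions. Each
#'   element is a named numeric vector summing to 1. Recognised elements:
#'   `age_band` (adult bands `18-24` ... `65+`), `sex`, `region`, `tenure`,
#'   `ethnicity`, `marital_status`, `employment_status`, `education`,
#'   `adults_per_household`, `children_per_household` (names are counts).
#'   Missing elements fall back to defaults patterned on published UK survey
#'   marginals.
#' @param income_model List with elements `log_mean`, `log_sd` (mean and sd of
#'   log monthly income: individual gross earnings among the employed for the
#'   cross-section; person-mean net equivalised household income for the
#'   panel), `persistence` (AR(1) coefficient of the transitory log-income
#'   deviation, in `[0, 1]`) and `transitory_sd` (stationary sd of that
#'   deviation).
#' @param grossing_target Total number of individuals the sample represents;
#'   person weights are normalised to sum to this.
#' @param attrition_prob Per-person, per-wave independent probability that a
#'   panel observation is missing (waves 2+; wave 1 always observed). Default 0.
#'
#' @return An object of class `population_config`.
#' @export
population_config <- function(n_households = 1000,
                              n_waves = 12,
                              seed = 1,
                              demographic_mix = list(),
                              income_model = list(),
                              grossing_target = 5.3e7,
                              attrition_prob = 0) {
  mix <- utils::modifyList(default_demographic_mix(), demographic_mix)
  for (nm in names(mix)) assert_proportions(mix[[nm]], nm)
  im <- utils::modifyList(
    list(log_mean = log(2660), log_sd = 0.7, persistence = 0.5,
         transitory_sd = 0.3),
    income_model
  )
  if (im$persistence < 0 || im$persistence > 1) {
    stop("income_model$persistence must be in [0, 1]", call. = FALSE)
  }
  if (n_waves < 2) stop("n_waves must be >= 2", call. = FALSE)
  if (attrition_prob < 0 || attrition_prob >= 1) {
    stop("attrition_prob must be in [0, 1)", call. = FALSE)
  }
  structure(
    list(n_households = as.integer(n_households),
         n_waves = as.integer(n_waves),
         seed = as.integer(seed),
         demographic_mix = mix,
         income_model = im,
         grossing_target = grossing_target,
         attrition_prob = attrition_prob),
    class = "population_config"
  )
}

# Marginal proportions patterned on the FRS-style adult population the
# microsimulation base emulates. Only marginals are matched; no joint
# census-style calibration is attempted.
default_demographic_mix <- function() {
  list(
    age_band = c(`18-24` = 0.0475, `25-34` = 0.1245, `35-44` = 0.1508,
                 `45-54` = 0.1565, `55-64` = 0.1884, `65+` = 0.3323),
    sex = c(female = 0.468, male = 0.532),
    region = c(england = 0.7389, scotland = 0.1086, wales = 0.0488,
               northern_ireland = 0.1037),
    tenure = c(own = 0.7519, rent_social = 0.0994, rent_private = 0.0641,
               other = 0.0846),
    ethnicity = c(white = 0.9106, mixed = 0.0097, south_asian = 0.0361,
                  other_asian = 0.0107, black = 0.0201, other = 0.0128),
    marital_status = c(single = 0.1768, cohabiting = 0.1127, married = 0.5450,
                       divorced = 0.0719, widowed = 0.0716, other = 0.0220),
    employment_status = c(employed = 0.5354, unemployed = 0.0142,
                          family_care = 0.0191, student = 0.0129,
                          sick_disabled = 0.0598, retired = 0.3219,
                          other = 0.0367),
    education = c(degree = 0.3364, other_higher = 0.1308, a_level = 0.1609,
                  gcse = 0.1748, other_qual = 0.0514, none = 0.1457),
    adults_per_household = c(`1` = 0.39, `2` = 0.46, `3` = 0.13, `4` = 0.02),
    children_per_household = c(`0` = 0.78, `1` = 0.13, `2` = 0.07, `3` = 0.02)
  )
}

#' Panel-flavoured population configuration
#'
#' [population_config()] preset whose demographic mix and income anchor follow
#' a 12-wave balanced household panel of UK adults: income is person-mean net
#' equivalised monthly household income (anchor ~ GBP 2,400/month), and the
#' sex mix is exposed as configuration rather than asserted.
#'
#' @inheritParams population_config
#' @param ... Passed to [population_config()].
#' @return A `population_config`.
#' @export
panel_config <- function(n_households = 2000, seed = 1, ...) {
  args <- list(...)
  mix <- utils::modifyList(
    list(
      age_band = c(`18-24` = 0.0198, `25-34` = 0.0951, `35-44` = 0.1704,
                   `45-54` = 0.2221, `55-64` = 0.2368, `65+` = 0.2558),
      sex = c(female = 0.4234, male = 0.5766)
    ),
    args$demographic_mix %||% list()
  )
  im <- utils::modifyList(
    list(log_mean = log(2412), log_sd = 0.5, persistence = 0.5,
         transitory_sd = 0.3),
    args$income_model %||% list()
  )
  args$demographic_mix <- mix
  args$income_model <- im
  do.call(population_config,
          c(list(n_households = n_households, seed = seed), args))
}

#' Ground-truth income-health model for the panel generator
#'
#' Parameters of the known linear within-between structure used to simulate
#' SF-12 component scores, so that estimator recovery can be tested against
#' known coefficients. Scores are generated as
#' `intercept + beta_between * xbar_i + beta_within * (x_it - xbar_i) +
#' controls + lag_coefficient * prior_case + a_i + e_it`
#' where `x` is transformed income (log by default), `xbar_i` the person's
#' empirical mean over waves, `a_i ~ N(0, sigma_individual^2)` and
#' `e_it ~ N(0, sigma_resid^2)`.
#'
#' @param beta_between_mcs,beta_within_mcs,beta_between_pcs,beta_within_pcs
#'   Score points per unit of transformed income.
#' @param intercept_mcs,intercept_pcs Model intercepts (score points).
#' @param control_effects Named list mapping a covariate name to a named
#'   numeric vector of additive level effects (reference levels omitted or 0).
#' @param sigma_individual Between-person random-intercept sd (>= 0).
#' @param sigma_resid Occasion-level residual sd (> 0).
#' @param lag_coefficient Additive effect of having been a case (score below
#'   the case threshold) at the previous wave; `|lag_coefficient|` < 1 is not
#'   required -- it is a score-point effect, not an AR weight on the score.
#' @param transform Income transform, `"log"` (with GBP 1 floor) or
#'   `"linear"`.
#'
#' @return An object of class `true_health_model`.
#' @export
true_health_model <- function(beta_between_mcs = 2.0,
                              beta_within_mcs = 1.0,
                              beta_between_pcs = 1.5,
                              beta_within_pcs = 0.6,
                              intercept_mcs = 34.9,
                              intercept_pcs = 38.5,
                              control_effects = list(sex = c(male = 0.8)),
                              sigma_individual = 6,
                              sigma_resid = 6,
                              lag_coefficient = 0,
                              transform = c("log", "linear")) {
  transform <- match.arg(transform)
  if (sigma_individual < 0) stop("sigma_individual must be >= 0", call. = FALSE)
  if (sigma_resid <= 0) stop("sigma_resid must be > 0", call. = FALSE)
  structure(
    list(beta_between_mcs = beta_between_mcs,
         beta_within_mcs = beta_within_mcs,
         beta_between_pcs = beta_between_pcs,
         beta_within_pcs = beta_within_pcs,
         intercept_mcs = intercept_mcs,
         intercept_pcs = intercept_pcs,
         control_effects = control_effects,
         sigma_individual = sigma_individual,
         sigma_resid = sigma_resid,
         lag_coefficient = lag_coefficient,
         transform = transform),
    class = "true_health_model"
  )
}

age_from_band <- function(band) {
  lo <- c(`18-24` = 18, `25-34` = 25, `35-44` = 35, `45-54` = 45,
          `55-64` = 55, `65+` = 65)
  hi <- c(`18-24` = 24, `25-34` = 34, `35-44` = 44, `45-54` = 54,
          `55-64` = 64, `65+` = 90)
  lo[band] + floor(stats::runif(length(band)) * (hi[band] - lo[band] + 1))
}

band_from_age <- function(age) {
  cut(age, breaks = c(-Inf, 24, 34, 44, 54, 64, Inf),
      labels = c("18-24", "25-34", "35-44", "45-54", "55-64", "65+"))
}

#' Generate a synthetic household cross-section
#'
#' Draws a seeded synthetic population of households and persons emulating a
#' microsimulation base: household composition (OECD-definition adults aged
#' 14+, here generated as adults 18+ and children 0-13), adult demographics
#' from the configured marginal mixes, gross monthly earned income (log-normal
#' among the employed) and occasional unearned income. Person weights are
#' uniform and normalised so they sum to `config$grossing_target`.
#'
#' @param config A [population_config()].
#' @return List with elements `households` (household_id, region, tenure,
#'   n_adults, n_children, weight) and `persons` (one row per person;
#'   children carry age and demographic placeholders only).
#' @export
gen_cross_section <- function(config) {
  stopifnot(inherits(config, "population_config"))
  mix <- config$demographic_mix
  with_seed(config$seed, {
    nh <- config$n_households
    n_ad <- as.integer(sample_categorical(nh, mix$adults_per_household))
    n_ch <- as.integer(sample_categorical(nh, mix$children_per_household))
    region <- sample_categorical(nh, mix$region)
    tenure <- sample_categorical(nh, mix$tenure)

    hid_ad <- rep(seq_len(nh), n_ad)
    na_tot <- length(hid_ad)
    band <- sample_categorical(na_tot, mix$age_band)
    adults <- data.frame(
      household_id = hid_ad,
      age = age_from_band(band),
      age_band = band,
      sex = sample_categorical(na_tot, mix$sex),
      ethnicity = sample_categorical(na_tot, mix$ethnicity),
      region = region[hid_ad],
      marital_status = sample_categorical(na_tot, mix$marital_status),
      employment_status = sample_categorical(na_tot, mix$employment_status),
      education = sample_categorical(na_tot, mix$education),
      stringsAsFactors = FALSE
    )
    emp <- adults$employment_status == "employed"
    earned <- numeric(na_tot)
    earned[emp] <- stats::rlnorm(sum(emp), config$income_model$log_mean,
                                 config$income_model$log_sd)
    has_unearned <- stats::runif(na_tot) < 0.15
    unearned <- numeric(na_tot)
    unearned[has_unearned] <- stats::rlnorm(sum(has_unearned), 5, 0.8)
    adults$earned_income <- earned
    adults$unearned_income <- unearned

    hid_ch <- rep(seq_len(nh), n_ch)
    children <- if (length(hid_ch)) {
      data.frame(
        household_id = hid_ch,
        age = sample.int(14, length(hid_ch), replace = TRUE) - 1L,
        age_band = NA_character_, sex = NA_character_,
        ethnicity = NA_character_, region = region[hid_ch],
        marital_status = NA_character_, employment_status = NA_character_,
        education = NA_character_,
        earned_income = 0, unearned_income = 0,
        stringsAsFactors = FALSE
      )
    } else {
      adults[0, ]
    }
    persons <- rbind(adults, children)
    persons <- persons[order(persons$household_id, -persons$age), ]
    persons$person_id <- seq_len(nrow(persons))
    persons$weight <- config$grossing_target / nrow(persons)
    rownames(persons) <- NULL

    households <- data.frame(
      household_id = seq_len(nh),
      region = region,
      tenure = tenure,
      n_adults = n_ad,
      n_children = n_ch,
      stringsAsFactors = FALSE
    )
    households$weight <- tapply(persons$weight, persons$household_id, sum)[
      as.character(households$household_id)]
    list(households = households, persons = persons)
  })
}

#' Generate a synthetic balanced panel with known income-health structure
#'
#' Simulates person-wave records of net equivalised monthly household income
#' and SF-12 mental (MCS) and physical (PCS) component scores from the known
#' linear model in `truth`. Log income follows a person mean plus a
#' stationary AR(1) transitory deviation, giving controllable within/between
#' variance shares. Scores are clipped to the instrument range `[0, 100]`;
#' the clipping rate is recorded and must stay below 1%.
#'
#' @param config A [population_config()]; `n_households` is the number of
#'   panel individuals.
#' @param truth A [true_health_model()].
#' @return Data frame of class `panel_table` with columns `person_id`, `wave`,
#'   `net_equiv_income`, `mcs`, `pcs`, fixed covariates, `prior_case_mcs`,
#'   `prior_case_pcs`, `attrition`. Attributes: `truth` (the generator
#'   parameters), `linpred` (noise-free linear predictors), `clip_rate`.
#' @export
gen_panel <- function(config, truth = true_health_model()) {
  stopifnot(inherits(config, "population_config"),
            inherits(truth, "true_health_model"))
  if (config$n_waves < 2) stop("n_waves must be >= 2", call. = FALSE)
  mix <- config$demographic_mix
  im <- config$income_model
  with_seed(config$seed, {
    n <- config$n_households
    tt <- config$n_waves
    band <- sample_categorical(n, mix$age_band)
    person <- data.frame(
      person_id = seq_len(n),
      age_band = band,
      age = age_from_band(band),
      sex = sample_categorical(n, mix$sex),
      region = sample_categorical(n, mix$region),
      education = sample_categorical(n, mix$education),
      stringsAsFactors = FALSE
    )
    mu_i <- stats::rnorm(n, im$log_mean, im$log_sd)
    rho <- im$persistence
    u <- matrix(0, n, tt)
    u[, 1] <- stats::rnorm(n, 0, im$transitory_sd)
    innov_sd <- im$transitory_sd * sqrt(1 - rho^2)
    for (t in seq_len(tt)[-1]) {
      u[, t] <- rho * u[, t - 1] + stats::rnorm(n, 0, innov_sd)
    }
    log_inc <- mu_i + u
    income <- exp(log_inc)

    x <- transform_income(income, truth$transform)
    xbar <- rowMeans(x)
    xw <- x - xbar

    ctrl <- control_effect_vector(truth$control_effects, person)
    a_mcs <- stats::rnorm(n, 0, truth$sigma_individual)
    a_pcs <- stats::rnorm(n, 0, truth$sigma_individual)

    mcs <- pcs <- lp_mcs <- lp_pcs <- matrix(NA_real_, n, tt)
    prior_mcs <- prior_pcs <- matrix(FALSE, n, tt)
    thr <- health_thresholds()
    for (t in seq_len(tt)) {
      if (t > 1) {
        prior_mcs[, t] <- mcs[, t - 1] <= thr$mcs_case_max
        prior_pcs[, t] <- pcs[, t - 1] <= thr$pcs_case_max
      }
      lp_mcs[, t] <- truth$intercept_mcs + truth$beta_between_mcs * xbar +
        truth$beta_within_mcs * xw[, t] + ctrl +
        truth$lag_coefficient * prior_mcs[, t]
      lp_pcs[, t] <- truth$intercept_pcs + truth$beta_between_pcs * xbar +
        truth$beta_within_pcs * xw[, t] + ctrl +
        truth$lag_coefficient * prior_pcs[, t]
      mcs[, t] <- lp_mcs[, t] + a_mcs + stats::rnorm(n, 0, truth$sigma_resid)
      pcs[, t] <- lp_pcs[, t] + a_pcs + stats::rnorm(n, 0, truth$sigma_resid)
    }
    n_clip <- sum(mcs < 0 | mcs > 100) + sum(pcs < 0 | pcs > 100)
    clip_rate <- n_clip / (2 * n * tt)
    mcs <- pmin(pmax(mcs, 0), 100)
    pcs <- pmin(pmax(pcs, 0), 100)

    panel <- data.frame(
      person_id = rep(person$person_id, tt),
      wave = rep(seq_len(tt), each = n),
      net_equiv_income = as.vector(income),
      mcs = as.vector(mcs),
      pcs = as.vector(pcs),
      age_band = rep(person$age_band, tt),
      age = rep(person$age, tt),
      sex = rep(person$sex, tt),
      region = rep(person$region, tt),
      education = rep(person$education, tt),
      prior_case_mcs = as.vector(prior_mcs),
      prior_case_pcs = as.vector(prior_pcs),
      attrition = FALSE,
      stringsAsFactors = FALSE
    )
    if (config$attrition_prob > 0) {
      miss <- stats::runif(nrow(panel)) < config$attrition_prob & panel$wave > 1
      gone <- unique(panel$person_id[miss])
      panel$attrition <- panel$person_id %in% gone
      panel <- panel[!miss, ]
    }
    panel <- panel[order(panel$person_id, panel$wave), ]
    rownames(panel) <- NULL
    attr(panel, "truth") <- truth
    attr(panel, "linpred") <- data.frame(
      person_id = rep(person$person_id, tt),
      wave = rep(seq_len(tt), each = n),
      lp_mcs = as.vector(lp_mcs), lp_pcs = as.vector(lp_pcs)
    )
    attr(panel, "clip_rate") <- clip_rate
    class(panel) <- c("panel_table", "data.frame")
    panel
  })
}

control_effect_vector <- function(control_effects, person) {
  out <- numeric(nrow(person))
  for (cv in names(control_effects)) {
    if (!cv %in% names(person)) {
      stop("control effect refers to unknown covariate: ", cv, call. = FALSE)
    }
    eff <- control_effects[[cv]]
    hit <- match(person[[cv]], names(eff))
    out <- out + ifelse(is.na(hit), 0, eff[hit])
  }
  out
}

transform_income <- function(income, transform) {
  switch(transform,
         log = log(pmax(income, 1)),
         linear = income,
         stop("unknown income transform: ", transform, call. = FALSE))
}

#' Restrict a panel to individuals observed in every wave
#'
#' Keeps only persons present in all waves spanned by the panel (a balanced
#' panel). Retained records keep their `attrition` flag for optional use as a
#' control covariate.
#'
#' @param panel A panel data frame with `person_id` and `wave` columns.
#' @return The balanced subset, with attributes `n_dropped` (persons removed)
#'   and `n_retained`.
#' @export
make_balanced <- function(panel) {
  stopifnot(all(c("person_id", "wave") %in% names(panel)))
  waves <- sort(unique(panel$wave))
  counts <- table(panel$person_id)
  complete <- names(counts)[counts == length(waves)]
  out <- panel[as.character(panel$person_id) %in% complete, , drop = FALSE]
  n_dropped <- length(counts) - length(complete)
  if (nrow(out) == 0) {
    stop("no person observed in all ", length(waves), " waves (",
         length(counts), " persons dropped)", call. = FALSE)
  }
  rownames(out) <- NULL
  for (a in c("truth", "clip_rate")) attr(out, a) <- attr(panel, a)
  attr(out, "n_dropped") <- n_dropped
  attr(out, "n_retained") <- length(complete)
  class(out) <- unique(c("panel_table", class(out)))
  out
}

#' @export
print.population_config <- function(x, ...) {
  cat("<population_config>\n")
  cat("  households:", x$n_households, " waves:", x$n_waves,
      " seed:", x$seed, "\n")
  cat("  income: logN(", round(x$income_model$log_mean, 3), ",",
      x$income_model$log_sd, "), persistence", x$income_model$persistence,
      ", transitory sd", x$income_model$transitory_sd, "\n")
  cat("  grossing target:", format(x$grossing_target, big.mark = ","), "\n")
  invisible(x)
}

#' @export
print.true_health_model <- function(x, ...) {
  cat("<true_health_model> (", x$transform, " income)\n", sep = "")
  cat(sprintf("  MCS: between %.3g within %.3g  PCS: between %.3g within %.3g\n",
              x$beta_between_mcs, x$beta_within_mcs,
              x$beta_between_pcs, x$beta_within_pcs))
  cat(sprintf("  sigma_individual %.3g  sigma_resid %.3g  lag %.3g\n",
              x$sigma_individual, x$sigma_resid, x$lag_coefficient))
  invisible(x)
}
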