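#' End-to-end run configuration
#'
#' Bundles every stage's configuration: the synthetic cross-section and
#' panel, the ground-truth health model, the tax-benefit parameters, the
#' schemes, the panel model specification, the bootstrap size, the case
#' thresholds and the valuation settings. One master seed drives every
#' stochastic stage through stage-specific derived seeds, all recorded in
#' the output manifest.
#'
#' @param population [population_config()] for the cross-section.
#' @param panel [population_config()] (e.g. [panel_config()]) for the panel.
#' @param truth [true_health_model()] generating the panel's scores.
#' @param schemes Named list of [scheme_definition()]s.
#' @param params [taxben_params()].
#' @param controls Control covariates for the panel model.
#' @param estimator Panel estimator (see [model_spec()]).
#' @param include_lagged_case See [model_spec()].
#' @param bootstrap_reps Bootstrap repetitions (reference analysis: 1,000).
#' @param thresholds [health_thresholds()].
#' @param valuation [valuation_config()].
#' @param residual_sd Baseline-score imputation sd (score points).
#' @param seed Master integer seed.
#' @return Object of class `run_config`.
#' @export
run_config <- function(population = population_config(n_households = 1000),
                       panel = panel_config(n_households = 2000),
                       truth = true_health_model(),
                       schemes = bi_schemes(),
                       params = taxben_params(),
                       controls = c("sex"),
                       estimator = "random_effects",
                       include_lagged_case = FALSE,
                       bootstrap_reps = 1000,
                       thresholds = health_thresholds(),
                       valuation = valuation_config(),
                       residual_sd = 8,
                       seed = 1) {
  structure(
    list(population = population, panel = panel, truth = truth,
         schemes = schemes, params = params, controls = controls,
         estimator = estimator, include_lagged_case = include_lagged_case,
         bootstrap_reps = bootstrap_reps, thresholds = thresholds,
         valuation = valuation, residual_sd = residual_sd,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

cached <- function(cache_dir, key, expr) {
  if (is.null(cache_dir)) return(expr)
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(cache_dir, paste0(key, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  val <- expr
  saveRDS(val, path)
  val
}

#' Run the full microsimulation pipeline
#'
#' Executes generate, tax-benefit, model fit, health impact and valuation in
#' order and returns a results bundle mirroring the reference analysis's
#' output tables: per-scheme cases prevented (both outcomes), QALYs and
#' their monetary value, years of life gained, depressive-disorder cost
#' savings by perspective, distributional reports, and a manifest with
#' seeds and a configuration hash. Confidence intervals throughout propagate
#' coefficient (bootstrap) uncertainty with imputation draws held fixed;
#' MCS and PCS bootstrap replicates share the resampling seed so they are
#' paired within replicate.
#'
#' @param config A [run_config()].
#' @param cache_dir Optional directory for stage caching keyed by
#'   configuration hash (bootstrap refits dominate runtime).
#' @param verbose Log stage-level record counts and weighted totals.
#' @return Object of class `results_bundle`.
#' @export
run_pipeline <- function(config, cache_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(...)
  h <- function(x) rlang::hash(x)
  seed <- config$seed

  say("stage gen: cross-section of ", config$population$n_households,
      " households")
  cross <- cached(cache_dir, paste0("cross_", h(config$population)),
                  gen_cross_section(config$population))
  say("  persons: ", nrow(cross$persons), ", weighted total: ",
      format(sum(cross$persons$weight), big.mark = ","))

  say("stage gen: panel of ", config$panel$n_households, " persons x ",
      config$panel$n_waves, " waves")
  panel <- cached(cache_dir, paste0("panel_", h(list(config$panel, config$truth))),
                  {
                    p <- gen_panel(config$panel, config$truth)
                    if (config$panel$attrition_prob > 0) make_balanced(p) else p
                  })

  fit_seed <- derive_seed(seed, "bootstrap")
  specs <- lapply(c("MCS", "PCS"), function(oc) {
    model_spec(outcome = oc, income_transform = config$truth$transform,
               controls = config$controls,
               include_lagged_case = config$include_lagged_case,
               estimator = config$estimator)
  })
  say("stage fit: within-between model, ", config$bootstrap_reps,
      " bootstrap reps")
  coefs <- cached(
    cache_dir,
    paste0("fit_", h(list(config$panel, config$truth, specs,
                          config$bootstrap_reps, fit_seed))),
    lapply(specs, function(sp) {
      bootstrap_ci(panel, sp, reps = config$bootstrap_reps, seed = fit_seed)
    })
  )
  names(coefs) <- c("MCS", "PCS")

  adults <- cross$persons[cross$persons$age >= 18, , drop = FALSE]
  vc <- config$valuation
  cw <- vc$crosswalk
  impute_seed <- derive_seed(seed, "impute")
  takeup_seed <- derive_seed(seed, "takeup")

  cases_tab <- qaly_tab <- ylg_tab <- cost_tab <- NULL
  dist_reports <- list()
  for (nm in names(config$schemes)) {
    scheme <- config$schemes[[nm]]
    say("stage taxben+impact: ", nm)
    res <- apply_scheme(cross$persons, scheme, config$params,
                        seed = takeup_seed)
    ix <- match(adults$household_id, res$household_id)
    inc_base <- res$net_equiv_base[ix]
    inc_reform <- res$net_equiv_reform[ix]

    states <- person_health_states(adults, inc_base, inc_reform,
                                   coefs$MCS, coefs$PCS,
                                   residual_sd = config$residual_sd,
                                   seed = impute_seed)
    cases <- cases_prevented(states, config$thresholds, coefs$MCS, coefs$PCS)
    cases$scheme <- nm
    cases_tab <- rbind(cases_tab, cases)

    du <- sf6d_delta(states$delta_mcs, states$delta_pcs, cw,
                     mcs_base = states$mcs_base, pcs_base = states$pcs_base)
    q_point <- qalys_gained(du, states$weight)

    # replicate QALY/YLG totals are linear in the paired between draws
    bm <- coefs$MCS$bootstrap_draws[, "x_between"]
    bp <- coefs$PCS$bootstrap_draws[, "x_between"]
    npair <- min(length(bm), length(bp))
    s_q <- sum(states$weight * states$dincome_f)
    mult <- ylg_multiplier_for(adults, vc$ylg_multipliers)
    s_y <- sum(states$weight * mult * states$dincome_f)
    q_rep <- (cw$coef_mcs * bm[seq_len(npair)] +
                cw$coef_pcs * bp[seq_len(npair)]) * s_q
    y_rep <- (cw$coef_mcs * bm[seq_len(npair)] +
                cw$coef_pcs * bp[seq_len(npair)]) * s_y
    q_ci <- stats::quantile(q_rep, c(0.025, 0.975), names = FALSE)
    y_ci <- stats::quantile(y_rep, c(0.025, 0.975), names = FALSE)

    mon <- monetise(q_point, vc$value_per_qaly, vc$green_book_multiplier)
    qaly_tab <- rbind(qaly_tab, data.frame(
      scheme = nm, qalys = q_point, ci_lower = q_ci[1], ci_upper = q_ci[2],
      value = mon$value,
      value_ci_lower = q_ci[1] * vc$value_per_qaly,
      value_ci_upper = q_ci[2] * vc$value_per_qaly,
      value_green_book = mon$value_green_book
    ))

    ylg_point <- years_of_life_gained(du, adults$sex, adults$age_band,
                                      states$weight, vc$ylg_multipliers)
    ylg_tab <- rbind(ylg_tab, data.frame(
      scheme = nm, ylg = ylg_point, ci_lower = y_ci[1], ci_upper = y_ci[2]
    ))

    sav <- cost_savings(cases[cases$outcome == "depressive_disorder", ],
                        vc$costs)
    sav$scheme <- nm
    cost_tab <- rbind(cost_tab, sav)

    dist_reports[[nm]] <- distributional_summary(res)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("bisim")),
    master_seed = seed,
    stage_seeds = list(bootstrap = fit_seed, impute = impute_seed,
                       uc_takeup = takeup_seed),
    config_hash = h(config),
    bootstrap_reps = config$bootstrap_reps,
    n_households = config$population$n_households,
    n_panel_persons = config$panel$n_households,
    schemes = names(config$schemes)
  )
  structure(
    list(cases = cases_tab, qalys = qaly_tab, ylg = ylg_tab,
         cost_savings = cost_tab, distributional = dist_reports,
         coefficients = coefs, manifest = manifest),
    class = "results_bundle"
  )
}

ylg_multiplier_for <- function(adults, multipliers) {
  key <- paste(adults$sex, adults$age_band)
  mkey <- paste(multipliers$sex, multipliers$age_band)
  hit <- match(key, mkey)
  if (anyNA(hit)) {
    stop("no YLG multiplier for: ",
         paste(unique(key[is.na(hit)]), collapse = ", "), call. = FALSE)
  }
  multipliers$multiplier[hit]
}

#' Write a results bundle to disk
#'
#' Emits CSV tables (cases prevented, QALYs and value, years of life
#' gained, cost savings, distributional statistics), a plain-text summary
#' and a JSON manifest. Every emitted row is checked for CI ordering
#' (lower <= central <= upper). Re-reporting a saved bundle writes
#' byte-identical files.
#'
#' @param bundle A `results_bundle`.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
report_bundle <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "results_bundle"))
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir,
                                 call. = FALSE)
  check_ci <- function(df, centre, lo = "ci_lower", hi = "ci_upper") {
    fin <- is.finite(df[[lo]]) & is.finite(df[[hi]])
    if (any(fin & (df[[lo]] > df[[centre]] | df[[centre]] > df[[hi]]))) {
      stop("CI ordering violated in emitted table", call. = FALSE)
    }
  }
  check_ci(bundle$cases, "cases_prevented")
  check_ci(bundle$qalys, "qalys")
  check_ci(bundle$ylg, "ylg")
  check_ci(bundle$cost_savings, "savings")

  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    tryCatch(utils::write.csv(df, path, row.names = FALSE),
             error = function(e) stop("write failure at ", path, ": ",
                                      conditionMessage(e), call. = FALSE))
    path
  }
  dist_flat <- do.call(rbind, lapply(names(bundle$distributional), function(nm) {
    d <- bundle$distributional[[nm]]
    data.frame(scheme = nm, gini_base = d$gini_base,
               gini_reform = d$gini_reform,
               poverty_persons_base = d$poverty$base[1],
               poverty_persons_reform = d$poverty$reform[1],
               poverty_children_base = d$poverty$base[2],
               poverty_children_reform = d$poverty$reform[2],
               exchequer_cost_annual = d$exchequer_cost_annual)
  }))
  files <- c(
    wr(bundle$cases, "cases_prevented.csv"),
    wr(bundle$qalys, "qalys.csv"),
    wr(bundle$ylg, "years_of_life_gained.csv"),
    wr(bundle$cost_savings, "cost_savings.csv"),
    wr(dist_flat, "distributional.csv")
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(bundle$manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  summary_path <- file.path(out_dir, "summary.txt")
  con <- file(summary_path, "w")
  on.exit(close(con))
  writeLines(utils::capture.output(print(bundle)), con)
  invisible(c(files, manifest_path, summary_path))
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("<results_bundle>", length(x$manifest$schemes), "scheme(s);",
      "bootstrap reps:", x$manifest$bootstrap_reps, "\n")
  dd <- x$cases[x$cases$outcome == "depressive_disorder", ]
  for (i in seq_len(nrow(dd))) {
    q <- x$qalys[x$qalys$scheme == dd$scheme[i], ]
    s <- x$cost_savings[x$cost_savings$scheme == dd$scheme[i] &
                          x$cost_savings$perspective == "nhs_pss", ]
    cat(sprintf(paste0(
      "  %s: %s depressive cases prevented/yr (95%% CI %s-%s); ",
      "%s QALYs (GBP %.2f bn); NHS/PSS savings GBP %.0f m\n"),
      dd$scheme[i],
      format(round(dd$cases_prevented[i]), big.mark = ","),
      format(round(dd$ci_lower[i]), big.mark = ","),
      format(round(dd$ci_upper[i]), big.mark = ","),
      format(round(q$qalys), big.mark = ","),
      q$value / 1e9, s$savings / 1e6))
  }
  invisible(x)
}
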