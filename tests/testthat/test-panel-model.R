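make_panel <- function(ids, waves, income) {
  data.frame(person_id = rep(ids, each = waves),
             wave = rep(seq_len(waves), length(ids)),
             net_equiv_income = income,
             mcs = 50, pcs = 50, sex = "female")
}

test_that("income decomposition identities hold", {
  p <- make_panel(1:3, 4, rep(c(1000, 2000, 1500), each = 4))
  d <- decompose_income(p, "log")
  expect_equal(as.vector(tapply(d$x_within, d$person_id, mean)), rep(0, 3))
  expect_equal(d$x_between + d$x_within, log(d$net_equiv_income))
  expect_true(all(d$x_within[d$person_id == 1] == 0))  # constant income

  two <- make_panel(1, 2, c(exp(4), exp(6)))
  d2 <- decompose_income(two, "log")
  expect_equal(d2$x_between, c(5, 5))
  expect_equal(d2$x_within, c(-1, 1))

  unbal <- p[-1, ]
  expect_error(decompose_income(unbal, "log"), "balanced")
  dup <- rbind(p, p[1, ])
  expect_error(decompose_income(dup, "log"), class = "error")
})

test_that("noise-free panels are recovered to high precision by both estimators", {
  truth <- true_health_model(sigma_individual = 0, sigma_resid = 1e-8,
                             control_effects = list(sex = c(male = 0.8)))
  pan <- gen_panel(panel_config(n_households = 300, seed = 17), truth)
  for (oc in c("MCS", "PCS")) {
    sp <- model_spec(oc, "log", controls = "sex",
                     estimator = "pooled_ols_clustered")
    fit <- fit_within_between(pan, sp)
    bw_true <- if (oc == "MCS") truth$beta_within_mcs else truth$beta_within_pcs
    bb_true <- if (oc == "MCS") truth$beta_between_mcs else truth$beta_between_pcs
    expect_equal(fit$beta_within, bw_true, tolerance = 1e-6)
    expect_equal(fit$beta_between, bb_true, tolerance = 1e-6)
    expect_equal(unname(fit$control_coefficients[["sexmale"]]), 0.8,
                 tolerance = 1e-5)
  }
  # random effects and pooled OLS agree on the income coefficients
  sp_re <- model_spec("MCS", "log", controls = "sex",
                      estimator = "random_effects")
  fit_re <- suppressMessages(fit_within_between(pan, sp_re))
  expect_equal(fit_re$beta_between, truth$beta_between_mcs, tolerance = 1e-4)
  expect_equal(fit_re$beta_within, truth$beta_within_mcs, tolerance = 1e-4)
})

test_that("random-effects estimator recovers noisy ground truth", {
  truth <- true_health_model()
  pan <- gen_panel(panel_config(n_households = 800, seed = 23), truth)
  fit <- fit_within_between(pan, model_spec("MCS", "log", controls = "sex"))
  se <- fit$se[["x_between"]]
  expect_lt(abs(fit$beta_between - truth$beta_between_mcs), 4 * se)
  expect_equal(fit$n_observations, 800 * 12)
  expect_equal(fit$n_individuals, 800)
})

test_that("estimates are invariant to row ordering", {
  pan <- gen_panel(panel_config(n_households = 150, seed = 31))
  sp <- model_spec("MCS", "log", controls = "sex",
                   estimator = "pooled_ols_clustered")
  f1 <- fit_within_between(pan, sp)
  set.seed(1)
  f2 <- fit_within_between(pan[sample(nrow(pan)), ], sp)
  expect_equal(f1$beta_between, f2$beta_between, tolerance = 1e-10)
  expect_equal(f1$beta_within, f2$beta_within, tolerance = 1e-10)
})

test_that("linear-transform coefficients rescale as 1/k under income scaling", {
  pan <- gen_panel(panel_config(n_households = 200, seed = 37),
                   true_health_model(transform = "linear",
                                     beta_between_mcs = 0.002,
                                     beta_within_mcs = 0.001,
                                     intercept_mcs = 45))
  sp <- model_spec("MCS", "linear", controls = "sex",
                   estimator = "pooled_ols_clustered")
  f1 <- fit_within_between(pan, sp)
  pan2 <- pan
  pan2$net_equiv_income <- pan2$net_equiv_income * 10
  f2 <- fit_within_between(pan2, sp)
  expect_equal(f2$beta_between, f1$beta_between / 10, tolerance = 1e-8)
  expect_equal(f2$beta_within, f1$beta_within / 10, tolerance = 1e-8)
})

test_that("degenerate designs are reported, not silently absorbed", {
  # zero within-variance: every person's income constant over waves
  p <- make_panel(1:40, 3, rep(exp(rnorm(40, 7.5, 0.5)), each = 3))
  set.seed(2)
  p$mcs <- 40 + 2 * log(p$net_equiv_income) + rnorm(nrow(p))
  fit <- fit_within_between(p, model_spec("MCS", "log", controls = NULL,
                                          estimator = "pooled_ols_clustered"))
  expect_true(is.na(fit$beta_within))
  expect_false(is.na(fit$beta_between))

  # collinear control
  pan <- gen_panel(panel_config(n_households = 50, seed = 41))
  pan$sex2 <- pan$sex
  expect_error(
    fit_within_between(pan, model_spec("MCS", "log",
                                       controls = c("sex", "sex2"),
                                       estimator = "pooled_ols_clustered")),
    "collinear")
  expect_error(
    fit_within_between(pan, model_spec("MCS", "log", controls = "nonexistent")),
    "not found")
})

test_that("lagged-case models drop the first wave and use the indicator", {
  truth <- true_health_model(lag_coefficient = -2)
  pan <- gen_panel(panel_config(n_households = 400, seed = 43), truth)
  sp <- model_spec("MCS", "log", controls = "sex", include_lagged_case = TRUE,
                   estimator = "pooled_ols_clustered")
  fit <- fit_within_between(pan, sp)
  expect_equal(fit$n_observations, 400 * 11)
  expect_true("prior_case_mcsTRUE" %in% names(fit$control_coefficients))
  expect_lt(fit$control_coefficients[["prior_case_mcsTRUE"]], 0)
})

test_that("in-package clustered covariance matches sandwich", {
  skip_if_not_installed("sandwich")
  pan <- gen_panel(panel_config(n_households = 120, seed = 47))
  pan <- decompose_income(pan, "log")
  fit_lm <- lm(mcs ~ x_within + x_between + sex, data = pan)
  V_ref <- sandwich::vcovCL(fit_lm, cluster = pan$person_id, type = "HC1")
  sp <- model_spec("MCS", "log", controls = "sex",
                   estimator = "pooled_ols_clustered")
  fit <- fit_within_between(pan, sp)
  expect_equal(fit$se[["x_between"]], sqrt(V_ref["x_between", "x_between"]),
               tolerance = 1e-6)
  expect_equal(fit$se[["x_within"]], sqrt(V_ref["x_within", "x_within"]),
               tolerance = 1e-6)
})

test_that("bootstrap is seeded, person-blocked and percentile-bounded", {
  pan <- gen_panel(panel_config(n_households = 250, seed = 53))
  sp <- model_spec("MCS", "log", controls = "sex",
                   estimator = "pooled_ols_clustered")
  b1 <- bootstrap_ci(pan, sp, reps = 40, seed = 99)
  b2 <- bootstrap_ci(pan, sp, reps = 40, seed = 99)
  expect_identical(b1$ci_lower, b2$ci_lower)
  expect_identical(b1$bootstrap_draws, b2$bootstrap_draws)
  expect_lte(b1$ci_lower[["x_between"]], b1$beta_between)
  expect_gte(b1$ci_upper[["x_between"]], b1$beta_between)
  expect_equal(b1$bootstrap_reps, 40)
  expect_error(bootstrap_ci(pan, sp, reps = 1), "reps")
})

test_that("bootstrap spread approximates the analytic clustered SE", {
  pan <- gen_panel(panel_config(n_households = 1000, seed = 59))
  sp <- model_spec("MCS", "log", controls = "sex",
                   estimator = "pooled_ols_clustered")
  b <- bootstrap_ci(pan, sp, reps = 200, seed = 61)
  ratio <- sd(b$bootstrap_draws[, "x_between"]) / b$se[["x_between"]]
  expect_gt(ratio, 0.75)
  expect_lt(ratio, 1.25)
})

test_that("random-effects bootstrap runs and brackets the point estimate", {
  pan <- gen_panel(panel_config(n_households = 100, seed = 67))
  sp <- model_spec("MCS", "log", controls = "sex",
                   estimator = "random_effects")
  b <- suppressMessages(bootstrap_ci(pan, sp, reps = 8, seed = 3))
  expect_lte(b$ci_lower[["x_between"]], b$beta_between)
  expect_gte(b$ci_upper[["x_between"]], b$beta_between)
})

test_that("coefficient sets round-trip through JSON", {
  pan <- gen_panel(panel_config(n_households = 80, seed = 71))
  sp <- model_spec("MCS", "log", controls = "sex",
                   estimator = "pooled_ols_clustered")
  cs <- bootstrap_ci(pan, sp, reps = 10, seed = 5)
  path <- tempfile(fileext = ".json")
  write_coefficient_set(cs, path)
  cs2 <- read_coefficient_set(path)
  expect_equal(cs2$beta_between, cs$beta_between)
  expect_equal(unname(cs2$ci_lower["x_between"]),
               unname(cs$ci_lower[["x_between"]]))
  expect_equal(dim(cs2$bootstrap_draws), dim(cs$bootstrap_draws))
  lp1 <- linear_predictor(cs, data.frame(sex = "male"), x_between = 7.5)
  lp2 <- linear_predictor(cs2, data.frame(sex = "male"), x_between = 7.5)
  expect_equal(lp1, lp2)
})
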