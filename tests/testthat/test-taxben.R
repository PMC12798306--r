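test_that("OECD-modified equivalence factors", {
  expect_equal(equivalence_factor(40), 1.0)
  expect_equal(equivalence_factor(c(40, 38, 8)), 1.8)
  expect_equal(equivalence_factor(c(70, 68)), 1.5)
  expect_equal(equivalence_factor(c(30, 16, 10, 2)), 2.1)
  expect_error(equivalence_factor(numeric(0)), "at least one member")
})

test_that("UC floor and taper exhaustion behave as defined", {
  params <- taxben_params(uc_standard_allowance = c(single = 400, couple = 600),
                          uc_child_element = 0, uc_takeup = 1)
  hh <- make_household(1, 30)
  expect_equal(baseline_net_income(hh, params)$net_income, 400)

  rich <- make_household(1, 45, earned = 20000)
  out <- baseline_net_income(rich, params)
  expect_equal(out$uc, 0)

  expect_error(baseline_net_income(make_household(1, 30, earned = -5), params),
               "negative")
})

test_that("calculator matches the brute-force oracle on an earnings grid", {
  params <- taxben_params()
  earnings <- seq(0, 12000, length.out = 250)  # GBP/month, 250 x 4 types
  pop <- grid_population(earnings)
  got <- baseline_net_income(pop, params)
  want <- vapply(split(pop, pop$household_id), function(h) {
    oracle_net_income(h$age, h$earned_income, h$unearned_income, params)
  }, numeric(1))
  expect_equal(got$net_income, unname(want[as.character(got$household_id)]),
               tolerance = 1e-12)

  s1 <- bi_schemes()$scheme1
  ref <- apply_scheme(pop, s1, params)
  want_r <- vapply(split(pop, pop$household_id), function(h) {
    oracle_net_income(h$age, h$earned_income, h$unearned_income, params, s1)
  }, numeric(1))
  expect_equal(ref$net_income_reform,
               unname(want_r[as.character(ref$household_id)]),
               tolerance = 1e-12)
})

test_that("scheme payment rules match their definitions", {
  params <- taxben_params()
  s1 <- bi_schemes()$scheme1

  fam <- make_household(1, c(40, 35, 8), earned = c(4000, 0, 0))
  res <- apply_scheme(fam, s1, params)
  expect_equal(res$bi_received, weekly_to_monthly(75 + 75 + 50))

  # single pensioner: BI GBP 205/week replaces a GBP 200/week State Pension
  p200 <- taxben_params(state_pension = 200)
  pens <- make_household(1, 70)
  res2 <- apply_scheme(pens, s1, p200)
  expect_equal(res2$net_income_reform - res2$net_income_base,
               weekly_to_monthly(205 - 200))

  # no-disregard scheme: UC falls pound for pound with BI until the floor
  params3 <- taxben_params(uc_standard_allowance = c(single = 600, couple = 800),
                           state_pension = 0)
  s3 <- bi_schemes()$scheme3
  adult <- make_household(1, 30)
  r3 <- apply_scheme(adult, s3, params3)
  bi <- weekly_to_monthly(295)
  expect_equal(r3$uc_reform, max(0, 600 - bi))
  expect_equal(r3$uc_base, 600)

  expect_error(scheme_definition("bad", 10, 10, 10, replaces = "housing"),
               "unknown benefit")
})

test_that("one-for-one replacement holds where UC stays positive", {
  params <- taxben_params(uc_takeup = 1)
  scheme <- scheme_definition("s", 20, 30, 80, uc_bi_disregard = 0)
  set.seed(1)
  pop <- do.call(rbind, lapply(1:60, function(h) {
    ages <- sample(c(25, 40, 70, 8), sample(1:3, 1), replace = TRUE)
    make_household(h, ages, earned = round(runif(length(ages), 0, 800)))
  }))
  res <- apply_scheme(pop, scheme, params)
  keep <- res$uc_reform > 0 & res$uc_base > 0
  expect_true(any(keep))
  dnet <- res$net_income_reform - res$net_income_base
  # accounting identity: change = BI - replaced benefits - UC offset
  expect_equal(res$bi_received - res$benefits_lost -
                 (res$uc_base - res$uc_reform), dnet,
               tolerance = 1e-9, ignore_attr = TRUE)
  # UC absorbs BI exactly (net of the removed State Pension, which was
  # itself UC-counted unearned income): for childless UC recipients whose
  # UC stays positive the reform is income-neutral; households with
  # children additionally lose Child Benefit, which sits outside UC
  cb <- ifelse(res$n_children > 0,
               weekly_to_monthly(params$child_benefit_first +
                                   params$child_benefit_subsequent *
                                   pmax(0, res$n_children - 1)), 0)
  expect_equal(dnet[keep], -cb[keep], tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(abs(dnet[keep & res$n_children == 0]) < 1e-9))
})

test_that("raising BI rates never lowers reform net income", {
  params <- taxben_params()
  set.seed(7)
  pop <- do.call(rbind, lapply(1:80, function(h) {
    ages <- sample(c(5, 25, 45, 70), sample(1:4, 1), replace = TRUE)
    make_household(h, ages, earned = round(runif(length(ages), 0, 5000)))
  }))
  lo <- scheme_definition("lo", 50, 75, 205, uc_bi_disregard = 10)
  hi <- scheme_definition("hi", 60, 95, 225, uc_bi_disregard = 10)
  expect_true(all(apply_scheme(pop, hi, params)$net_income_reform -
                    apply_scheme(pop, lo, params)$net_income_reform >= -1e-9))
})

test_that("null scheme reproduces the baseline exactly", {
  params <- taxben_params()
  set.seed(3)
  pop <- grid_population(runif(50, 0, 6000))
  null_scheme <- scheme_definition("null", 0, 0, 0, replaces = character(0))
  res <- apply_scheme(pop, null_scheme, params)
  expect_identical(res$net_income_reform, res$net_income_base)
  expect_true(all(res$bi_received == 0))
})

test_that("low-income losers are flagged, and vanish when the disregard covers lost benefits", {
  params <- taxben_params()
  set.seed(5)
  pop <- do.call(rbind, lapply(1:100, function(h) {
    ages <- sample(c(3, 10, 28, 42, 68), sample(1:4, 1), replace = TRUE)
    make_household(h, ages, earned = round(runif(length(ages), 0, 1500)))
  }))
  for (s in bi_schemes()[c("scheme1", "scheme2")]) {
    res <- apply_scheme(pop, s, params)
    # the flag identifies exactly the UC recipients who lose
    expect_identical(res$low_income_loser,
                     res$uc_base > 0 &
                       res$net_income_reform < res$net_income_base - 1e-9)
    # any loss is bounded by the lost Child Benefit (UC absorbs the rest)
    loss <- res$net_income_base - res$net_income_reform
    expect_true(all(loss[res$low_income_loser] <=
                      weekly_to_monthly(params$child_benefit_first +
                                          2 * params$child_benefit_subsequent) +
                      1e-9))
  }
  # a disregard at least as large as the largest lost Child Benefit
  # guarantees no UC-receiving household loses
  generous <- scheme_definition("s1_big_disregard", 50, 75, 205,
                                uc_bi_disregard = 250)
  res2 <- apply_scheme(pop, generous, params)
  expect_false(any(res2$low_income_loser))
})

test_that("partial UC take-up is a seeded Bernoulli shared across systems", {
  params <- taxben_params(uc_takeup = 0.6)
  pop <- do.call(rbind, lapply(1:200, function(h) make_household(h, 30)))
  a <- baseline_net_income(pop, params, seed = 4)
  b <- baseline_net_income(pop, params, seed = 4)
  expect_identical(a, b)
  c2 <- baseline_net_income(pop, params, seed = 5)
  expect_false(identical(a$uc, c2$uc))
  share <- mean(a$uc > 0)
  expect_lt(abs(share - 0.6), 3 * sqrt(0.6 * 0.4 / 200))
  # same draw under reform: non-claimants get no UC in either system
  res <- apply_scheme(pop, bi_schemes()$scheme1, params, seed = 4)
  expect_identical(res$uc_base > 0, a$uc > 0)
})

test_that("funding adjustment raises reform taxes only", {
  params <- taxben_params(funding_adjustment = list(rate_increase_pp = 2))
  hh <- make_household(1, 40, earned = 4000)
  res <- apply_scheme(hh, bi_schemes()$scheme1, params)
  # 2pp on annual earnings above the personal allowance
  expect_equal(res$taxes_delta, 0.02 * (4000 * 12 - 12570) / 12,
               tolerance = 1e-9)
})

test_that("marginal deduction rates match their closed forms and the oracle", {
  params <- taxben_params(uc_standard_allowance = c(single = 400, couple = 600))
  # earnings below tax, NI and UC-disregard thresholds: nothing withdrawn
  low <- make_household(1, 30, earned = 200)
  expect_equal(unname(marginal_deduction_rate(low, params)), 0)

  # on the taper only (below tax/NI thresholds, above the work allowance)
  taper_only <- make_household(1, 30, earned = 800)
  expect_equal(unname(marginal_deduction_rate(taper_only, params)), 0.55,
               tolerance = 1e-9)

  # basic-rate taxpayer on the taper: oracle finite difference
  params2 <- taxben_params(uc_standard_allowance = c(single = 2000,
                                                     couple = 2500))
  mid <- make_household(1, 30, earned = 1500)
  got <- unname(marginal_deduction_rate(mid, params2, delta = 1))
  n0 <- oracle_net_income(30, 1500, 0, params2)
  n1 <- oracle_net_income(30, 1501, 0, params2)
  expect_equal(got, 1 - (n1 - n0), tolerance = 1e-9)
  expect_equal(got, 1 - (1 - 0.2 - 0.12) * (1 - 0.55), tolerance = 1e-9)

  expect_error(marginal_deduction_rate(make_household(1, 30), params),
               "no earner")
  expect_error(marginal_deduction_rate(mid, params, delta = 0), "delta")
})

test_that("weighted Gini matches closed forms and the pairwise oracle", {
  expect_equal(weighted_gini(rep(5, 10)), 0)
  expect_equal(weighted_gini(c(0, 7), c(1, 1)), 0.5)
  set.seed(12)
  x <- rlnorm(200, 7, 0.8)
  w <- runif(200, 0.5, 3)
  expect_equal(weighted_gini(x, w), oracle_gini_pairwise(x, w),
               tolerance = 1e-12)
  expect_error(weighted_gini(x, -w), "positive")
})

test_that("distributional summary reports coherent statistics", {
  params <- taxben_params()
  cs <- gen_cross_section(population_config(n_households = 300, seed = 14))
  res <- apply_scheme(cs$persons, bi_schemes()$scheme1, params)
  rep1 <- distributional_summary(res)
  expect_gte(rep1$gini_base, 0)
  expect_lt(rep1$gini_reform, rep1$gini_base)  # redistribution reduces Gini
  expect_equal(sum(rep1$winners_losers$households), sum(res$weight_hh))
  expect_equal(nrow(rep1$quintiles), 5)
  expect_true(all(diff(rep1$quintiles$mean_equiv_base) > 0))
  expect_lte(rep1$poverty$reform[1], rep1$poverty$base[1])
  bad <- res
  bad$weight_hh[1] <- 0
  expect_error(distributional_summary(bad), "weights")
  expect_error(distributional_summary(res[1, ]), "2 households")
})
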