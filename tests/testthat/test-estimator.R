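test_that("annualize and bleeding_burden reproduce the published arithmetic", {
  expect_equal(annualize(255657, 6), 42609.5)
  expect_equal(round_half_away(annualize(255657, 6)), 42610)
  expect_equal(annualize(0, 6), 0)
  expect_equal(annualize(12, 4), 3)
  expect_error(annualize(12, 0), "n_years")

  expect_equal(bleeding_burden(255657), 10652.375)
  expect_equal(round_half_away(bleeding_burden(255657)), 10652)
  expect_equal(bleeding_burden(0), 0)
  expect_equal(bleeding_burden(2400, 6, p_bleed = 0.5), 200)
  expect_error(bleeding_burden(100, p_bleed = 1.2), "p_bleed")
})

test_that("scenario validation enforces ordered bounds and subgroup range", {
  expect_error(scenario_spec("x", 0.32, 0.43, 0.18), "rrr_low")
  expect_error(scenario_spec("x", 0.32, 0.18, 0.43, subgroup_fraction = 0),
               "subgroup")
  sc <- scenario_spec("x", 0.32, 0.18, 0.43)
  expect_s3_class(sc, "scenario_spec")
})

test_that("avoidable_deaths propagates RRR confidence bounds", {
  burden <- bleeding_burden(255657)
  within1 <- avoidable_deaths(burden, scenario_spec("within_1h", 0.32, 0.18, 0.43))
  expect_equal(within1$point, 3408.76)
  expect_equal(within1$rounded_point, 3409)
  expect_equal(within1$rounded_high, 4581)
  # computed lower bound is 1917.4275; published tables print 1918 (flagged,
  # not targeted)
  expect_equal(within1$rounded_low, 1917)

  late <- avoidable_deaths(burden, scenario_spec("1_to_3h", 0.21, 0.03, 0.36))
  expect_equal(late$point, 2236.99875, tolerance = 1e-12)
  expect_equal(late$rounded_point, 2237)
  expect_equal(late$rounded_low, 320)
  expect_equal(late$rounded_high, 3835)

  expect_equal(avoidable_deaths(burden, scenario_spec("null", 0, 0, 0))$point, 0)
  expect_equal(avoidable_deaths(1000, scenario_spec("s", 0.4, 0.4, 0.4,
                                                    subgroup_fraction = 0.5))$point,
               200)
})

test_that("strategy comparisons difference points, exact or rounded", {
  burden <- bleeding_burden(255657)
  within1 <- avoidable_deaths(burden, scenario_spec("within_1h", 0.32, 0.18, 0.43))
  late <- avoidable_deaths(burden, scenario_spec("1_to_3h", 0.21, 0.03, 0.36))
  cmp <- compare_strategies(within1, late)
  expect_equal(cmp$annual_lives_lost, 1171.76125, tolerance = 1e-12)
  expect_equal(cmp$rounded, 1172)
  expect_equal(compare_strategies(within1, within1)$rounded, 0)

  # rounded-operand mode differences the printed report values
  a <- avoidable_deaths(10.6, scenario_spec("a", 1, 1, 1))
  b <- avoidable_deaths(3.4, scenario_spec("b", 1, 1, 1))
  expect_equal(compare_strategies(a, b)$rounded, 7)
  expect_equal(compare_strategies(a, b, use_rounded = TRUE)$rounded, 8)

  other <- avoidable_deaths(burden, scenario_spec("x", 0.1, 0.1, 0.1),
                            stratum_label = "MA")
  expect_error(compare_strategies(within1, other), "strata")
})

test_that("default scenarios load from config and take exact vitals fractions", {
  sc <- default_scenarios()
  expect_setequal(names(sc), c("within_1h", "1_to_3h", "hypotensive_only_1h",
                               "hypo_or_tachy_1h"))
  expect_equal(sc$within_1h$rrr_point, 0.32)
  expect_equal(sc$`1_to_3h`$rrr_low, 0.03)
  expect_equal(sc$hypotensive_only_1h$subgroup_fraction, 0.181)
  expect_equal(sc$hypo_or_tachy_1h$subgroup_fraction, 0.402)

  vit <- structure(list(p_hypotensive = 90 / 500, p_tachy_or_hypo = 200 / 500),
                   class = "vitals_summary")
  sc2 <- default_scenarios(vit)
  expect_equal(sc2$hypotensive_only_1h$subgroup_fraction, 0.18)
  expect_equal(sc2$hypo_or_tachy_1h$subgroup_fraction, 0.4)
})

test_that("estimator properties: linearity, ordering, dominance, additivity", {
  set.seed(99)
  for (i in 1:25) {
    r <- sort(runif(3))
    sc <- scenario_spec("s", r[2], r[1], r[3],
                        subgroup_fraction = runif(1, 0.05, 1))
    burden <- runif(1, 0, 20000)
    e <- avoidable_deaths(burden, sc)
    expect_lte(e$low, e$point)
    expect_lte(e$point, e$high)
    e2 <- avoidable_deaths(2 * burden, sc)
    expect_equal(e2$point, 2 * e$point)
    expect_equal(e2$high, 2 * e$high)
    # dominance: elementwise-larger (subgroup, rrr) never yields less
    sc_dom <- scenario_spec("d", min(1, r[2] + 0.1), r[1], min(1, r[3] + 0.1),
                            subgroup_fraction = 1)
    expect_gte(avoidable_deaths(burden, sc_dom)$point, e$point)
  }

  by_state <- c(MA = 600, NY = 0, TX = 1234.5, CA = 98765)
  scs <- default_scenarios()
  est <- estimate_by_state(by_state, scenarios = scs)
  for (nm in names(scs)) {
    state_sum <- sum(est$point[est$scenario == nm])
    nat <- avoidable_deaths(bleeding_burden(sum(by_state)), scs[[nm]])$point
    expect_equal(state_sum, nat, tolerance = 1e-9)
  }
})

test_that("estimate_by_state handles degenerate inputs and bad codes", {
  sc <- list(within_1h = scenario_spec("within_1h", 0.32, 0.18, 0.43))
  est <- estimate_by_state(c(MA = 600, NY = 0), scenarios = sc)
  expect_equal(est$point[est$stratum == "MA"], 8)
  expect_equal(est$point[est$stratum == "NY"], 0)
  single <- estimate_by_state(c(TX = 255657), scenarios = sc)
  expect_equal(single$point, 3408.76)
  expect_error(estimate_by_state(c(ZZ = 5), scenarios = sc), "ZZ")
  expect_error(estimate_by_state(c(MA = -1), scenarios = sc), "non-negative")
})
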