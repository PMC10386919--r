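live_curve_spec <- function(integration = "integrated", include_startup = TRUE) {
  tpl <- observed_templates()$live
  specs <- canonical_scenarios(tpl, n = 1, include_startup = include_startup)
  list(
    tpl = tpl,
    spec = specs[[if (integration == "integrated") "ngo_integrated" else "ngo_standalone"]]
  )
}

test_that("integrated curves decline monotonically toward the asymptote", {
  x <- live_curve_spec("integrated")
  curve <- cost_curve(x$tpl, x$spec)
  expect_true(all(diff(curve$per_participant) <= 1e-9))
  expect_true(all(curve$per_participant >= attr(curve, "asymptote") - 1e-9))
})

test_that("stand-alone curves are sawtoothed, rising only at hiring thresholds", {
  x <- live_curve_spec("stand_alone")
  curve <- cost_curve(x$tpl, x$spec)
  rises <- which(diff(curve$per_participant) > 0)
  expect_gt(length(rises), 0) # jagged, not monotone
  cap <- x$spec$counselor_capacity
  for (i in rises) {
    # each rise brackets a point where another counselor must be hired
    expect_gt(ceiling(curve$n[i + 1] / cap), ceiling(curve$n[i] / cap))
  }
  # restricted to exact staffing multiples the curve is non-increasing
  multiples <- curve$n %% cap == 0
  if (sum(multiples) > 1) {
    expect_true(all(diff(curve$per_participant[multiples]) <= 1e-9))
  }
  expect_true(all(curve$per_participant >= attr(curve, "asymptote") - 1e-9))
})

test_that("a one-point grid equals the scenario cost divided by n", {
  x <- live_curve_spec("integrated")
  curve <- cost_curve(x$tpl, x$spec, grid = 487)
  s <- x$spec
  s$n_participants <- 487
  expect_equal(curve$per_participant, apply_scenario(x$tpl, s)$total / 487)
})

test_that("grids must be strictly increasing and positive", {
  x <- live_curve_spec()
  expect_error(cost_curve(x$tpl, x$spec, grid = c(40, 40)),
    class = "boostercost_validation_error"
  )
  expect_error(cost_curve(x$tpl, x$spec, grid = c(0, 40)),
    class = "boostercost_validation_error"
  )
  expect_error(cost_curve(x$tpl, x$spec, grid = numeric(0)),
    class = "boostercost_validation_error"
  )
})

test_that("crossover detection follows the sign-change-with-tie rule", {
  x <- live_curve_spec("integrated")
  a <- cost_curve(x$tpl, x$spec, grid = seq(40, 400, 40))
  # identical curves: difference identically zero, tie resolves to the start
  expect_equal(find_crossover(a, a), 40)
  # constant offset: never crosses
  b <- a
  b$per_participant <- b$per_participant + 5
  expect_true(is.na(find_crossover(a, b)))
  # mismatched grids are an error
  c2 <- cost_curve(x$tpl, x$spec, grid = seq(40, 440, 40))
  expect_error(find_crossover(a, c2), class = "boostercost_validation_error")
})

test_that("live and IVR curves cross within the grid when start-up is amortized", {
  tpls <- observed_templates()
  live <- cost_curve(
    tpls$live,
    canonical_scenarios(tpls$live, 1, include_startup = TRUE)$ngo_integrated
  )
  ivr <- cost_curve(
    tpls$ivr,
    canonical_scenarios(tpls$ivr, 1, include_startup = TRUE)$ngo_integrated
  )
  cross <- find_crossover(live, ivr)
  expect_false(is.na(cross))
  expect_gte(cross, 40)
  expect_lte(cross, 3200)
  # live starts cheaper: its extra per-head counselor time only outweighs
  # IVR's larger fixed costs once those are spread over many participants
  expect_lt(live$per_participant[1], ivr$per_participant[1])
})

test_that("SMS stays above IVR at the top of the grid", {
  tpls <- observed_templates()
  sms_unit <- sum(tpls$sms$participant_units$unit)
  ivr_unit <- sum(tpls$ivr$participant_units$unit)
  expect_gt(sms_unit, ivr_unit) # driven by participant phone credit
  sms <- cost_curve(
    tpls$sms,
    canonical_scenarios(tpls$sms, 1, include_startup = TRUE)$ngo_integrated
  )
  ivr <- cost_curve(
    tpls$ivr,
    canonical_scenarios(tpls$ivr, 1, include_startup = TRUE)$ngo_integrated
  )
  top <- length(sms$n)
  expect_gt(sms$per_participant[top], ivr$per_participant[top])
})

test_that("the asymptote is the numerical large-n limit", {
  tpls <- observed_templates()
  for (arm in c("live", "sms", "ivr")) {
    for (scale_conn in c(FALSE, TRUE)) {
      spec <- canonical_scenarios(
        tpls[[arm]], 1,
        include_startup = TRUE, scale_connectivity = scale_conn
      )$ngo_integrated
      spec$n_participants <- 1e6
      at_large_n <- apply_scenario(tpls[[arm]], spec)$total / 1e6
      asym <- asymptotic_cost(tpls[[arm]], spec)
      expect_lt(abs(at_large_n - asym) / asym, 0.005)
    }
  }
})

test_that("asymptote components behave as limits should", {
  tpl <- observed_templates()$live
  # no counselor cost: the limit is the participant-level unit cost
  free_staff <- scenario_spec(
    "ngo", "integrated", 100,
    counselor_capacity = tpl$capacity_default,
    salary_table = c(oversight = 0, counselor = 0),
    counselor_overhead = 0
  )
  expect_equal(
    asymptotic_cost(tpl, free_staff),
    sum(tpl$participant_units$unit)
  )
  # doubling capacity halves the counselor term
  base <- canonical_scenarios(tpl, 1)$ngo_integrated
  doubled <- canonical_scenarios(tpl, 1, capacity = 2 * tpl$capacity_default)$ngo_integrated
  unit <- sum(tpl$participant_units$unit)
  expect_equal(
    asymptotic_cost(tpl, doubled) - unit,
    (asymptotic_cost(tpl, base) - unit) / 2
  )
})

test_that("curves export to delimited text and plot", {
  x <- live_curve_spec()
  curve <- cost_curve(x$tpl, x$spec, grid = seq(40, 200, 40))
  path <- withr::local_tempfile(fileext = ".csv")
  export_curves(curve, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$per_participant, curve$per_participant)
  p <- plot_cost_curves(curve)
  expect_s3_class(p, "ggplot")
})
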