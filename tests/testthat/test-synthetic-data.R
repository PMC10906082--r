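test_that("simulated digitized curves are deterministic and law-consistent", {
  truth <- parametric_survival("exponential", rate = 0.1)
  k1 <- simulate_km(truth, n = 500, censor_time = 24, seed = 13)
  k2 <- simulate_km(truth, n = 500, censor_time = 24, seed = 13)
  expect_identical(k1$coords, k2$coords)
  expect_identical(k1$risk_table, k2$risk_table)
  cf1 <- withr::local_tempfile(fileext = ".csv")
  rf1 <- withr::local_tempfile(fileext = ".csv")
  cf2 <- withr::local_tempfile(fileext = ".csv")
  rf2 <- withr::local_tempfile(fileext = ".csv")
  write_km_csv(k1, cf1, rf1); write_km_csv(k2, cf2, rf2)
  expect_identical(readLines(cf1), readLines(cf2))
  expect_identical(readLines(rf1), readLines(rf2))
})

test_that("a large simulated curve matches its generating law", {
  km <- simulate_km(parametric_survival("exponential", rate = 0.1),
                    n = 10000, censor_time = 30, seed = 17)
  s10 <- km$coords$survival[km$coords$time == 10]
  expect_lt(abs(s10 - exp(-1)), 0.02)
})

test_that("degenerate censoring is refused by the generator itself", {
  expect_error(simulate_km(parametric_survival("exponential", rate = 0.1),
                           n = 100, censor_time = 0, seed = 1),
               "censoring time must be > 0")
})

test_that("simulate -> reconstruct -> fit recovers weibull and exponential truths", {
  sc <- ground_truth_scenario()
  wb <- sc$models$brigatinib
  km <- simulate_km(wb, n = 500, censor_time = 36, seed = sc$seed)
  ipd <- reconstruct_ipd(km)
  fit <- fit_parametric(ipd, "weibull")
  truth <- unlist(wb$params)
  expect_true(all(abs(fit$fit$params - truth) / truth < 0.15))

  ex <- sc$models$bsc_os
  km2 <- simulate_km(ex, n = 500, censor_time = 36, seed = sc$seed + 1)
  fit2 <- fit_parametric(reconstruct_ipd(km2), "exponential")
  expect_lt(abs(fit2$fit$params[["rate"]] - ex$params[["rate"]]) /
              ex$params[["rate"]], 0.15)
})

test_that("the base-case configuration carries the published inputs", {
  cfg <- base_config_cached()
  expect_silent(validate_config(cfg))
  expect_equal(unlist(cfg$utilities[c("line1", "line2", "line3", "line4")],
                      use.names = FALSE),
               c(0.71, 0.67, 0.59, 0.46))
  expect_equal(cfg$settings$annual_discount_rate, 0.03)
  expect_equal(cfg$settings$wtp, 150000)
  expect_equal(cfg$settings$cycle_length, 1)
  expect_equal(unlist(cfg$patient, use.names = FALSE), c(1.72, 65, 70))
  expect_equal(cfg$drugs$brigatinib$cycle_cost, 20143.91)
  # the generator's ALK-inhibitor curve targets 12-month survival 0.67 and
  # the chemotherapy comparator 0.43
  sc <- ground_truth_scenario()
  expect_equal(survival_at(sc$models$brigatinib, 12), 0.67, tolerance = 1e-9)
  expect_equal(survival_at(sc$models$chemotherapy, 12), 0.43, tolerance = 1e-9)
})

test_that("calibration hits all four base-case targets and leaves printed inputs alone", {
  cfg <- base_config_cached()
  cal <- calibrated_config_cached()
  res <- suppressWarnings(evaluate_strategies(cal))
  expect_equal(res$cost, c(219712, 196513), tolerance = 0.01)
  expect_equal(res$qalys, c(0.70, 0.76), tolerance = 0.01)
  inc <- attr(res, "incremental")
  expect_identical(inc$delta_cost, res$cost[1] - res$cost[2])
  expect_identical(inc$delta_qalys, res$qalys[1] - res$qalys[2])
  # printed inputs untouched by calibration
  expect_identical(cal$utilities, cfg$utilities)
  expect_identical(cal$drugs$brigatinib$cycle_cost,
                   cfg$drugs$brigatinib$cycle_cost)
  expect_identical(cal$settings, cfg$settings)
})

test_that("a configuration already meeting the targets is returned unchanged", {
  cal <- calibrated_config_cached()
  again <- calibrate_to_base_case(cal)
  expect_identical(again, cal)
})

test_that("configurations survive a YAML round trip", {
  cal <- calibrated_config_cached()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_config(cal, f)
  back <- read_config(f)
  r1 <- suppressWarnings(evaluate_strategies(cal))
  r2 <- suppressWarnings(evaluate_strategies(back))
  expect_equal(r1$cost, r2$cost, tolerance = 1e-9)
  expect_equal(r1$qalys, r2$qalys, tolerance = 1e-9)
})

test_that("configuration paths resolve and invalid ones are named", {
  cfg <- base_config_cached()
  expect_equal(config_get(cfg, "utilities.line2"), 0.67)
  cfg2 <- config_set(cfg, "utilities.line2", 0.5)
  expect_equal(config_get(cfg2, "utilities.line2"), 0.5)
  expect_error(config_get(cfg, "utilities.line9"), "utilities.line9")
  expect_error(config_set(cfg, "no.such.path", 1), "no.such.path")
})

test_that("result objects render plot-ready ggplot figures", {
  cfg <- calibrated_config_cached()
  psa <- run_psa(cfg, n_iter = 10, seed = 5)
  expect_s3_class(autoplot(ceac(psa, c(0, 150000))), "ggplot")
  expect_s3_class(autoplot(ce_scatter(psa)), "ggplot")
  rng <- param_range("drugs.brigatinib.cycle_cost",
                     config_get(cfg, "drugs.brigatinib.cycle_cost"),
                     decrease_only = TRUE)
  expect_s3_class(plot_tornado(one_way_dsa(cfg, rng)), "ggplot")
  st <- strategy_from_config(cfg, "A")
  tr <- suppressWarnings(run_cohort(st, settings_from_config(cfg),
                                    life_table_from_config(cfg)))
  expect_s3_class(autoplot(tr), "ggplot")
})
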