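test_that("default ranges encode the published one-way bounds", {
  cfg <- base_config_cached()
  rng <- default_dsa_ranges(cfg)
  brig <- rng[rng$parameter == "drugs.brigatinib.cycle_cost", ]
  expect_equal(brig$low, 16115.128, tolerance = 1e-6)
  expect_equal(brig$high, 20143.91)   # price decrease only
  u2 <- rng[rng$parameter == "utilities.line2", ]
  expect_equal(c(u2$low, u2$base, u2$high), c(0.536, 0.67, 0.804))
  expect_identical(u2$distribution, "beta")
  expect_true(all(rng$low <= rng$base & rng$base <= rng$high))
})

test_that("tornado spread is exactly zero for an unused parameter and positive for prices", {
  cfg <- calibrated_config_cached()
  rng <- dplyr::bind_rows(
    param_range("patient.weight", 65),  # resolvable but unused by the model
    param_range("drugs.brigatinib.cycle_cost",
                config_get(cfg, "drugs.brigatinib.cycle_cost"),
                decrease_only = TRUE)
  )
  tor <- one_way_dsa(cfg, rng)
  expect_identical(tor$spread[tor$parameter == "patient.weight"], 0)
  brig <- tor[tor$parameter == "drugs.brigatinib.cycle_cost", ]
  expect_gt(brig$spread, 0)
  base_icer <- attr(tor, "icer_base")
  expect_true(base_icer >= min(brig$icer_low, brig$icer_high) - 1e-9 &&
                base_icer <= max(brig$icer_low, brig$icer_high) + 1e-9)
  expect_error(one_way_dsa(cfg, param_range("drugs.nonexistent.cycle_cost", 1)),
               "drugs.nonexistent.cycle_cost")
})

test_that("PSA draws are deterministic, moment-matched, and respect zero dispersion", {
  rng <- dplyr::bind_rows(
    param_range("a", 1000, distribution = "gamma"),
    param_range("b", 0.67, distribution = "beta"),
    param_range("c", 5, distribution = "fixed")
  )
  d1 <- draw_psa_params(rng, seed = 3, iteration = 7)
  d2 <- draw_psa_params(rng, seed = 3, iteration = 7)
  expect_identical(d1, d2)
  d3 <- draw_psa_params(rng, seed = 3, iteration = 8)
  expect_false(identical(d1$value, d3$value))
  expect_identical(d1$value[3], 5)

  rng0 <- param_range("a", 1000, se = 0)
  expect_identical(draw_psa_params(rng0, 1, 1)$value, 1000)

  # gamma moment matching at base 1000, se 200, 100,000 draws
  g <- purrr::map_dfr(1:500, ~ param_range(paste0("p", .x), 1000, se = 200))
  x <- unlist(purrr::map(1:200, ~ draw_psa_params(g, 1, .x)$value))
  expect_equal(mean(x), 1000, tolerance = 0.02)
  expect_equal(stats::sd(x), 200, tolerance = 0.05)
})

test_that("infeasible beta moment matching falls back to a bounded uniform", {
  rng <- param_range("u", 0.5, low = 0.2, high = 0.8, distribution = "beta",
                     se = 0.6)
  expect_warning(d <- draw_psa_params(rng, 1, 1), "uniform")
  expect_true(d$value >= 0.2 && d$value <= 0.8)
})

test_that("an all-fixed PSA reproduces the base case in every iteration", {
  cfg <- calibrated_config_cached()
  rng <- param_range("drugs.brigatinib.cycle_cost",
                     config_get(cfg, "drugs.brigatinib.cycle_cost"),
                     distribution = "fixed")
  psa <- run_psa(cfg, rng, n_iter = 5, seed = 2)
  base <- suppressWarnings(evaluate_strategies(cfg))
  for (it in 1:5) {
    d <- psa$draws[psa$draws$iteration == it, ]
    expect_equal(d$cost, base$cost, tolerance = 1e-12)
    expect_equal(d$qalys, base$qalys, tolerance = 1e-12)
  }
})

test_that("the full PSA pipeline is bitwise reproducible given the seed", {
  cfg <- calibrated_config_cached()
  p1 <- run_psa(cfg, n_iter = 20, seed = 11)
  p2 <- run_psa(cfg, n_iter = 20, seed = 11)
  expect_identical(p1$draws, p2$draws)
  expect_identical(ce_scatter(p1), ce_scatter(p2))
  p3 <- run_psa(cfg, n_iter = 20, seed = 12)
  expect_false(identical(p1$draws, p3$draws))
})

test_that("CEAC probabilities are normalized and follow cost at zero WTP", {
  cfg <- calibrated_config_cached()
  psa <- run_psa(cfg, n_iter = 50, seed = 4)
  cc <- ceac(psa, wtp_grid = seq(0, 3e5, by = 5e4))
  norm <- dplyr::summarise(dplyr::group_by(cc, wtp),
                           total = sum(probability), .groups = "drop")
  expect_equal(norm$total, rep(1, nrow(norm)), tolerance = 1e-12)
  # at WTP 0 the cheaper strategy wins each iteration
  at0 <- cc[cc$wtp == 0, ]
  wide <- tidyr::pivot_wider(psa$draws, id_cols = iteration,
                             names_from = strategy, values_from = cost)
  frac_a_cheaper <- mean(wide$A < wide$B)
  expect_equal(at0$probability[at0$strategy == "A"], frac_a_cheaper)
})

test_that("a strictly dominated strategy has a zero CEAC under zero variance", {
  cfg <- calibrated_config_cached()
  rng <- param_range("drugs.brigatinib.cycle_cost",
                     config_get(cfg, "drugs.brigatinib.cycle_cost"),
                     distribution = "fixed")
  psa <- run_psa(cfg, rng, n_iter = 10, seed = 6)
  cc <- ceac(psa, wtp_grid = c(1000, 50000, 150000, 5e5))
  expect_true(all(cc$probability[cc$strategy == "A"] == 0))
  sc <- ce_scatter(psa)
  expect_equal(nrow(sc), 10L)
  inc <- attr(suppressWarnings(evaluate_strategies(cfg)), "incremental")
  expect_equal(sc$delta_cost, rep(inc$delta_cost, 10), tolerance = 1e-9)
  expect_equal(sc$delta_qalys, rep(inc$delta_qalys, 10), tolerance = 1e-9)
})
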