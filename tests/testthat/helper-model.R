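# shared fixtures built in code; the calibrated configuration is cached so
# the (deterministic) calibration runs once per test session

.fixture_cache <- new.env(parent = emptyenv())

base_config_cached <- function() {
  if (is.null(.fixture_cache$base)) {
    .fixture_cache$base <- make_base_case_config()
  }
  .fixture_cache$base
}

calibrated_config_cached <- function() {
  if (is.null(.fixture_cache$calibrated)) {
    .fixture_cache$calibrated <- calibrate_to_base_case(base_config_cached())
  }
  .fixture_cache$calibrated
}

zero_life_table <- function() {
  life_table(tibble::tibble(age = 0:100, annual_mortality = 0))
}

# one-line toy strategy: progression leads to an immediately-fatal,
# zero-utility BSC state, so totals reflect the single line only
toy_strategy <- function(rate = 0.1, utility = 1, cost = 0,
                         ae_profile = NULL) {
  strategy_definition(
    "toy",
    list(line_spec("only", parametric_survival("exponential", rate = rate),
                   utility = utility, cycle_cost = cost,
                   ae_profile = ae_profile)),
    bsc_os_model = parametric_survival("exponential", rate = 50),
    bsc_utility = 0, bsc_cycle_cost = 0
  )
}

random_valid_strategy <- function() {
  lines <- purrr::map(1:4, function(i) {
    line_spec(paste0("line", i),
              parametric_survival("weibull",
                                  rate = stats::runif(1, 0.01, 0.3),
                                  shape = stats::runif(1, 0.7, 1.6)),
              utility = stats::runif(1, 0.3, 0.9),
              cycle_cost = stats::runif(1, 100, 20000))
  })
  strategy_definition(
    "random", lines,
    bsc_os_model = parametric_survival("exponential",
                                       rate = stats::runif(1, 0.05, 0.4)),
    bsc_utility = stats::runif(1, 0.2, 0.6),
    bsc_cycle_cost = stats::runif(1, 0, 2000)
  )
}
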