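test_that("exponential fit equals the closed-form MLE d / T, censoring included", {
  ipd <- tibble::tibble(time = c(2, 4, 7, 12, 15, 20),
                        event = c(1, 1, 0, 1, 0, 1))
  rep <- fit_parametric(ipd, "exponential")
  expect_identical(rep$fit$params[["rate"]], sum(ipd$event) / sum(ipd$time))
  expect_true(rep$converged)
})

test_that("all-censored input is rejected with a 'no events' error", {
  expect_error(fit_parametric(tibble::tibble(time = c(1, 2), event = c(0, 0)),
                              "weibull"), "no events")
  expect_error(fit_parametric(tibble::tibble(time = 1, event = 1), "weibull"),
               "at least 2")
  expect_error(fit_parametric(tibble::tibble(time = c(0, 2), event = c(1, 1)),
                              "weibull"), "> 0")
})

test_that("weibull fit recovers generating parameters within 15% at n = 500", {
  set.seed(500)
  ipd <- tibble::tibble(time = stats::rweibull(500, 1.3, 0.08^(-1 / 1.3)),
                        event = 1L)
  rep <- suppressWarnings(fit_parametric(ipd, "weibull"))
  expect_lt(abs(rep$fit$params[["rate"]] - 0.08) / 0.08, 0.15)
  expect_lt(abs(rep$fit$params[["shape"]] - 1.3) / 1.3, 0.15)
})

test_that("every family recovers its own parameters within 10% at n = 2000", {
  gens <- list(
    exponential = list(r = function(n) stats::rexp(n, 0.1),
                       truth = c(rate = 0.1)),
    weibull = list(r = function(n) stats::rweibull(n, 1.3, 0.08^(-1 / 1.3)),
                   truth = c(rate = 0.08, shape = 1.3)),
    gamma = list(r = function(n) stats::rgamma(n, 2, 0.25),
                 truth = c(shape = 2, rate = 0.25)),
    gompertz = list(r = function(n) flexsurv::rgompertz(n, 0.08, 0.05),
                    truth = c(shape = 0.08, rate = 0.05)),
    gengamma = list(r = function(n) flexsurv::rgengamma.orig(n, shape = 1.2,
                                                             scale = 8, k = 1.5),
                    truth = c(shape = 1.2, scale = 8, k = 1.5)),
    lognormal = list(r = function(n) stats::rlnorm(n, 2, 0.6),
                     truth = c(meanlog = 2, sdlog = 0.6)),
    loglogistic = list(r = function(n) flexsurv::rllogis(n, 2, 8),
                       truth = c(shape = 2, scale = 8))
  )
  for (fam in names(gens)) {
    set.seed(7)
    ipd <- tibble::tibble(time = gens[[fam]]$r(2000), event = 1L)
    rep <- suppressWarnings(fit_parametric(ipd, fam))
    truth <- gens[[fam]]$truth[names(rep$fit$params)]
    expect_true(all(abs(rep$fit$params - truth) / abs(truth) < 0.10),
                label = paste(fam, "parameter recovery"))
  }
})

test_that("attained log-likelihood matches the independent flexsurv fit", {
  set.seed(21)
  tm <- stats::rweibull(300, 1.2, 10)
  ipd <- tibble::tibble(time = pmin(tm, 15), event = as.integer(tm <= 15))
  mine <- suppressWarnings(fit_parametric(ipd, "weibull"))
  ref <- flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = ipd,
                               dist = "weibull")
  expect_equal(mine$fit$loglik, ref$loglik, tolerance = 1e-5)
  # parameter conversion: package rate/shape <-> flexsurv shape/scale
  expect_equal(mine$fit$params[["shape"]], unname(ref$res["shape", "est"]),
               tolerance = 1e-3)
  expect_equal(mine$fit$params[["rate"]]^(-1 / mine$fit$params[["shape"]]),
               unname(ref$res["scale", "est"]), tolerance = 1e-3)
})

test_that("AIC and BIC identities hold exactly", {
  set.seed(3)
  ipd <- tibble::tibble(time = stats::rexp(80, 0.2), event = 1L)
  for (fam in c("exponential", "weibull", "gengamma")) {
    rep <- suppressWarnings(fit_parametric(ipd, fam))
    expect_identical(rep$aic, 2 * rep$fit$n_params - 2 * rep$fit$loglik)
    expect_identical(rep$bic,
                     rep$fit$n_params * log(rep$n_obs) - 2 * rep$fit$loglik)
  }
})

test_that("model selection minimizes the criterion with documented tie-breaks", {
  mk <- function(family, params, loglik, n_obs = 100) {
    fit <- do.call(parametric_survival,
                   c(list(family), as.list(params), loglik = loglik))
    seqcea:::new_fit_report(fit, n_obs = n_obs, converged = TRUE)
  }
  a <- mk("weibull", c(rate = 0.1, shape = 1), loglik = -48)     # aic 100
  b <- mk("gamma", c(shape = 1, rate = 0.1), loglik = -58)       # aic 120
  expect_identical(select_model(list(a, b), "aic")$fit$family, "weibull")
  # equal criterion: fewer parameters win
  c1 <- mk("exponential", c(rate = 0.1), loglik = -49)           # aic 100
  expect_identical(select_model(list(a, c1), "aic")$fit$family, "exponential")
  # equal criterion and parameter count: canonical family order
  d <- mk("gamma", c(shape = 1, rate = 0.1), loglik = -48)       # aic 100
  expect_identical(select_model(list(d, a), "aic")$fit$family, "weibull")
  expect_error(select_model(list(), "aic"), "empty")
})

test_that("seven-family screen on a large weibull sample picks a law close to truth", {
  set.seed(12)
  truth <- parametric_survival("weibull", rate = 0.08, shape = 1.3)
  ipd <- tibble::tibble(time = stats::rweibull(3000, 1.3, 0.08^(-1 / 1.3)),
                        event = 1L)
  reports <- fit_all_families(ipd)
  best <- select_model(reports, "aic")
  # gengamma nests the weibull, so either may win
  expect_true(best$fit$family %in% c("weibull", "gengamma"))
  tt <- seq(0, 60, by = 1)
  expect_lt(max(abs(survival_at(best$fit, tt) - survival_at(truth, tt))), 0.03)
})

test_that("tidy/glance/report tables expose the flat CSV shape", {
  set.seed(4)
  ipd <- tibble::tibble(time = stats::rexp(60, 0.1), event = 1L)
  reports <- fit_all_families(ipd, c("exponential", "weibull"))
  tab <- fit_report_table(reports)
  expect_named(tab, c("family", "term", "estimate", "loglik", "aic", "bic",
                      "n_obs"))
  expect_equal(nrow(tab), 3L)  # 1 exponential + 2 weibull parameters
  expect_equal(nrow(glance(reports$weibull)), 1L)
})
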