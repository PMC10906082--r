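# Parametric survival families used for progression-free and overall survival
# extrapolation. All times are in months.
#
# Parameterizations (fixed so fitted values are reproducible across tools):
#   exponential  rate lambda > 0                S(t) = exp(-lambda * t)
#   weibull      rate lambda > 0, shape gamma>0 S(t) = exp(-lambda * t^gamma)
#   gamma        shape > 0, rate > 0            stats::pgamma
#   gompertz     shape (real), rate > 0         flexsurv::pgompertz
#   gengamma     shape > 0, scale > 0, k > 0    flexsurv::pgengamma.orig
#   lognormal    meanlog (real), sdlog > 0      stats::plnorm
#   loglogistic  shape > 0, scale > 0           flexsurv::pllogis
#
# Conversion to common survival-literature conventions: the weibull rate/shape
# pair maps to stats::pweibull via shape = gamma, scale = lambda^(-1/gamma);
# gengamma with k = 1 reduces to the weibull with shape = shape and
# scale = scale; gompertz with shape -> 0 tends to the exponential with the
# same rate.

#' Supported parametric survival families
#'
#' The canonical family order is also the documented tie-break order used by
#' [select_model()].
#'
#' @return Character vector of family names.
#' @export
survival_families <- function() {
  c("exponential", "weibull", "gamma", "gompertz", "gengamma",
    "lognormal", "loglogistic")
}

# registry: parameter names, which must be strictly positive, and the
# survival / density functions under the package parameterization
family_registry <- function(family) {
  reg <- list(
    exponential = list(
      pars = "rate", positive = "rate",
      surv = function(t, p) exp(-p[["rate"]] * t),
      dens = function(t, p, log = FALSE) stats::dexp(t, p[["rate"]], log = log),
      quant = function(q, p) stats::qexp(q, p[["rate"]])
    ),
    weibull = list(
      pars = c("rate", "shape"), positive = c("rate", "shape"),
      surv = function(t, p) exp(-p[["rate"]] * t^p[["shape"]]),
      dens = function(t, p, log = FALSE) {
        stats::dweibull(t, shape = p[["shape"]],
                        scale = p[["rate"]]^(-1 / p[["shape"]]), log = log)
      },
      quant = function(q, p) {
        stats::qweibull(q, shape = p[["shape"]],
                        scale = p[["rate"]]^(-1 / p[["shape"]]))
      }
    ),
    gamma = list(
      pars = c("shape", "rate"), positive = c("shape", "rate"),
      surv = function(t, p) {
        stats::pgamma(t, shape = p[["shape"]], rate = p[["rate"]],
                      lower.tail = FALSE)
      },
      dens = function(t, p, log = FALSE) {
        stats::dgamma(t, shape = p[["shape"]], rate = p[["rate"]], log = log)
      },
      quant = function(q, p) stats::qgamma(q, shape = p[["shape"]], rate = p[["rate"]])
    ),
    gompertz = list(
      pars = c("shape", "rate"), positive = "rate",
      surv = function(t, p) {
        flexsurv::pgompertz(t, shape = p[["shape"]], rate = p[["rate"]],
                            lower.tail = FALSE)
      },
      dens = function(t, p, log = FALSE) {
        flexsurv::dgompertz(t, shape = p[["shape"]], rate = p[["rate"]], log = log)
      },
      quant = function(q, p) flexsurv::qgompertz(q, shape = p[["shape"]], rate = p[["rate"]])
    ),
    gengamma = list(
      pars = c("shape", "scale", "k"), positive = c("shape", "scale", "k"),
      surv = function(t, p) {
        flexsurv::pgengamma.orig(t, shape = p[["shape"]], scale = p[["scale"]],
                                 k = p[["k"]], lower.tail = FALSE)
      },
      dens = function(t, p, log = FALSE) {
        flexsurv::dgengamma.orig(t, shape = p[["shape"]], scale = p[["scale"]],
                                 k = p[["k"]], log = log)
      },
      quant = function(q, p) {
        flexsurv::qgengamma.orig(q, shape = p[["shape"]], scale = p[["scale"]],
                                 k = p[["k"]])
      }
    ),
    lognormal = list(
      pars = c("meanlog", "sdlog"), positive = "sdlog",
      surv = function(t, p) {
        stats::plnorm(t, meanlog = p[["meanlog"]], sdlog = p[["sdlog"]],
                      lower.tail = FALSE)
      },
      dens = function(t, p, log = FALSE) {
        stats::dlnorm(t, meanlog = p[["meanlog"]], sdlog = p[["sdlog"]], log = log)
      },
      quant = function(q, p) stats::qlnorm(q, meanlog = p[["meanlog"]], sdlog = p[["sdlog"]])
    ),
    loglogistic = list(
      pars = c("shape", "scale"), positive = c("shape", "scale"),
      surv = function(t, p) {
        flexsurv::pllogis(t, shape = p[["shape"]], scale = p[["scale"]],
                          lower.tail = FALSE)
      },
      dens = function(t, p, log = FALSE) {
        flexsurv::dllogis(t, shape = p[["shape"]], scale = p[["scale"]], log = log)
      },
      quant = function(q, p) flexsurv::qllogis(q, shape = p[["shape"]], scale = p[["scale"]])
    )
  )
  if (!family %in% names(reg)) {
    stop("unknown survival family: ", family, call. = FALSE)
  }
  reg[[family]]
}

check_params <- function(family, params) {
  reg <- family_registry(family)
  params <- unlist(params)
  missing <- setdiff(reg$pars, names(params))
  if (length(missing) > 0) {
    stop("family '", family, "' requires parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  params <- params[reg$pars]
  if (any(!is.finite(params))) {
    bad <- reg$pars[!is.finite(params)][1]
    stop("parameter '", bad, "' must be finite", call. = FALSE)
  }
  for (nm in reg$positive) {
    if (params[[nm]] <= 0) {
      stop("parameter '", nm, "' must be > 0 for family '", family, "'",
           call. = FALSE)
    }
  }
  params
}

#' Construct a parametric survival law
#'
#' @param family One of [survival_families()].
#' @param ... Named parameters of that family, e.g.
#'   `parametric_survival("weibull", rate = 0.05, shape = 1.5)` for
#'   \eqn{S(t) = \exp(-0.05\, t^{1.5})} with `t` in months.
#' @param loglik Optional attained log-likelihood (filled by
#'   [fit_parametric()]).
#'
#' @return An object of class `parametric_survival` with fields `family`,
#'   `params`, `loglik` and `n_params`.
#' @examples
#' ps <- parametric_survival("weibull", rate = 0.05, shape = 1.5)
#' survival_at(ps, c(0, 10))
#' @export
parametric_survival <- function(family, ..., loglik = NA_real_) {
  family <- match.arg(family, survival_families())
  params <- check_params(family, list(...))
  structure(
    list(family = family, params = params, loglik = loglik,
         n_params = length(params)),
    class = "parametric_survival"
  )
}

#' @export
print.parametric_survival <- function(x, ...) {
  cat("<parametric_survival> ", x$family, "\n", sep = "")
  cat("  ", paste(names(x$params), signif(x$params, 6), sep = " = ",
                  collapse = ", "), "\n", sep = "")
  if (!is.na(x$loglik)) cat("  loglik = ", signif(x$loglik, 8), "\n", sep = "")
  invisible(x)
}

#' Survival probability S(t)
#'
#' Evaluates the survivor function of a fitted or specified parametric law.
#'
#' @param dist A [parametric_survival()] object.
#' @param t Time(s) in months, all `>= 0`.
#'
#' @return Numeric vector of survival probabilities in `[0, 1]`, with
#'   `S(0) = 1`.
#' @export
survival_at <- function(dist, t) {
  stopifnot(inherits(dist, "parametric_survival"))
  if (any(t < 0)) stop("t must be >= 0 (got negative time)", call. = FALSE)
  params <- check_params(dist$family, dist$params)
  s <- family_registry(dist$family)$surv(t, params)
  pmin(pmax(s, 0), 1)
}

# log density, used by the censored likelihood
log_density_at <- function(dist, t) {
  params <- check_params(dist$family, dist$params)
  family_registry(dist$family)$dens(t, params, log = TRUE)
}

# quantile function (inverse CDF), used by the synthetic-data generator
quantile_at <- function(dist, q) {
  params <- check_params(dist$family, dist$params)
  family_registry(dist$family)$quant(q, params)
}

#' Per-cycle transition probability from a survival law
#'
#' Probability of leaving the state during the cycle ending at time `t`,
#' conditional on having stayed up to `t - u`:
#' \deqn{tp(t, u) = 1 - S(t) / S(t - u).}
#' For the weibull law under this package's rate/shape parameterization this
#' equals \eqn{1 - \exp\{\lambda (t-u)^\gamma - \lambda t^\gamma\}}; for every
#' other family the same survival-ratio definition is used, which is the
#' unique generalization consistent with the survivor function.
#'
#' @param dist A [parametric_survival()] object.
#' @param t End-of-cycle time(s) in months, `t >= u`.
#' @param u Cycle length in months, `> 0`.
#'
#' @return Numeric vector of probabilities in `[0, 1]`. If `S(t - u) = 0` the
#'   transition probability is reported as 1 with a warning.
#' @examples
#' wb <- parametric_survival("weibull", rate = 0.05, shape = 1.5)
#' transition_probability(wb, t = 10, u = 1)
#' @export
transition_probability <- function(dist, t, u) {
  stopifnot(inherits(dist, "parametric_survival"))
  if (length(u) != 1 || u <= 0) stop("u must be a single value > 0", call. = FALSE)
  if (any(t < u)) stop("t must be >= u", call. = FALSE)
  s_t <- survival_at(dist, t)
  s_prev <- survival_at(dist, t - u)
  tp <- ifelse(s_prev == 0, 1, 1 - s_t / s_prev)
  if (any(s_prev == 0)) {
    warning("S(t - u) = 0: transition probability reported as 1", call. = FALSE)
  }
  pmin(pmax(tp, 0), 1)
}
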