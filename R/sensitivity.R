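# One-way deterministic sensitivity analysis (tornado), probabilistic
# sensitivity analysis by Monte-Carlo parameter draws, cost-effectiveness
# acceptability curves and the incremental scatter.

#' Define a parameter range for sensitivity analysis
#'
#' The default range is +/-20% of the base value and the default PSA
#' dispersion is a standard error of 20% of base. Cost parameters
#' conventionally draw from a moment-matched gamma distribution, utilities
#' and probabilities from a moment-matched beta.
#'
#' @param parameter Dot-separated configuration path (see [config_get()]).
#' @param base Base value.
#' @param low,high One-way range bounds (`low <= base <= high`).
#' @param distribution PSA distribution: `"gamma"`, `"beta"` or `"fixed"`.
#' @param se PSA standard error (default `0.2 * base`).
#' @param decrease_only If `TRUE`, the high bound is pinned to base (used for
#'   on-patent drug prices that will not rise).
#' @return A one-row tibble.
#' @export
param_range <- function(parameter, base, low = 0.8 * base, high = 1.2 * base,
                        distribution = c("gamma", "beta", "fixed"),
                        se = 0.2 * base, decrease_only = FALSE) {
  distribution <- match.arg(distribution)
  if (decrease_only) high <- base
  if (low > base || base > high) {
    stop("need low <= base <= high for '", parameter, "'", call. = FALSE)
  }
  if (distribution == "beta" && (base < 0 || base > 1)) {
    stop("beta-distributed parameter '", parameter, "' must lie in [0, 1]",
         call. = FALSE)
  }
  tibble::tibble(parameter = parameter, base = base, low = low, high = high,
                 distribution = distribution, se = se)
}

#' Default sensitivity ranges for a model configuration
#'
#' Costs get +/-20% gamma ranges (tyrosine-kinase-inhibitor prices
#' decrease-only), utilities +/-20% beta ranges. Survival parameters are not
#' varied.
#'
#' @param config A model configuration.
#' @return A tibble of parameter ranges, one row per parameter.
#' @export
default_dsa_ranges <- function(config) {
  cost_path <- function(drug) paste0("drugs.", drug, ".cycle_cost")
  rows <- list(
    param_range(cost_path("brigatinib"), config_get(config, cost_path("brigatinib")),
                decrease_only = TRUE),
    param_range(cost_path("lorlatinib"), config_get(config, cost_path("lorlatinib")),
                decrease_only = TRUE),
    param_range(cost_path("chemotherapy"), config_get(config, cost_path("chemotherapy"))),
    param_range(cost_path("docetaxel"), config_get(config, cost_path("docetaxel"))),
    param_range(cost_path("bsc"), config_get(config, cost_path("bsc")))
  )
  for (u in c("line1", "line2", "line3", "line4", "bsc")) {
    p <- paste0("utilities.", u)
    rows <- c(rows, list(param_range(p, config_get(config, p),
                                     distribution = "beta")))
  }
  for (drug in names(config$drugs)) {
    for (ae in names(config$drugs[[drug]]$ae %||% list())) {
      p <- paste0("drugs.", drug, ".ae.", ae, ".cost")
      rows <- c(rows, list(param_range(p, config_get(config, p))))
    }
  }
  dplyr::bind_rows(rows)
}

incremental_icer <- function(config) {
  res <- evaluate_strategies(config)
  attr(res, "incremental")$icer
}

#' One-way deterministic sensitivity analysis (tornado table)
#'
#' Re-runs the model with each parameter at its low and at its high bound,
#' all others at base, and reports the two incremental cost-effectiveness
#' ratios and the absolute spread between them, sorted descending — the
#' plot-ready form of a tornado diagram.
#'
#' @param config A model configuration.
#' @param ranges Parameter ranges, e.g. from [default_dsa_ranges()].
#' @return A tibble of class `cea_dsa` with columns `parameter`, `low`,
#'   `high`, `icer_low`, `icer_high`, `spread` and `icer_base` as an
#'   attribute.
#' @export
one_way_dsa <- function(config, ranges = default_dsa_ranges(config)) {
  base_icer <- incremental_icer(config)
  out <- purrr::pmap_dfr(
    ranges[, c("parameter", "low", "high")],
    function(parameter, low, high) {
      il <- incremental_icer(config_set(config, parameter, low))
      ih <- incremental_icer(config_set(config, parameter, high))
      tibble::tibble(parameter = parameter, low = low, high = high,
                     icer_low = il, icer_high = ih,
                     spread = abs(ih - il))
    }
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$spread))
  class(out) <- c("cea_dsa", class(out))
  attr(out, "icer_base") <- base_icer
  out
}

psa_iteration_seed <- function(seed, iteration) {
  (as.numeric(seed) * 1009 + as.numeric(iteration) * 9973) %% 2147483647
}

#' Draw one PSA parameter assignment
#'
#' Gamma draws are moment-matched to (base, se) via shape = (base/se)^2,
#' rate = base/se^2; beta draws are moment-matched via the usual mean/variance
#' identities. If beta moment-matching is infeasible (se too large) the draw
#' falls back to uniform on `[low, high]` with a warning. One assignment is
#' drawn per iteration and shared by all strategies. Draws are deterministic
#' given `(seed, iteration)`.
#'
#' @param ranges Parameter ranges (see [param_range()]).
#' @param seed Master seed.
#' @param iteration Iteration number (1-based).
#' @return A tibble with columns `parameter` and `value`.
#' @export
draw_psa_params <- function(ranges, seed, iteration) {
  set.seed(psa_iteration_seed(seed, iteration))
  value <- purrr::pmap_dbl(
    ranges[, c("parameter", "base", "low", "high", "distribution", "se")],
    function(parameter, base, low, high, distribution, se) {
      if (distribution == "fixed" || se == 0 || base == 0) return(base)
      if (distribution == "gamma") {
        shape <- (base / se)^2
        return(stats::rgamma(1, shape = shape, rate = base / se^2))
      }
      # beta
      v <- se^2
      if (v >= base * (1 - base)) {
        warning("beta moment-matching infeasible for '", parameter,
                "'; falling back to uniform on [low, high]", call. = FALSE)
        return(stats::runif(1, low, high))
      }
      nu <- base * (1 - base) / v - 1
      stats::rbeta(1, shape1 = base * nu, shape2 = (1 - base) * nu)
    }
  )
  tibble::tibble(parameter = ranges$parameter, value = value)
}

#' Probabilistic sensitivity analysis
#'
#' For each iteration, draws one value per parameter (shared across
#' strategies), applies the assignment to the configuration, runs both
#' strategies and records discounted cost and QALYs. When no varied parameter
#' touches survival laws or model settings, the cohort traces are computed
#' once and only the accumulation step is repeated, which is exact because
#' state occupancy depends only on survival and mortality inputs. Iterations
#' violating model preconditions are skipped and counted.
#'
#' @param config A model configuration.
#' @param ranges Parameter ranges; default [default_dsa_ranges()].
#' @param n_iter Number of Monte-Carlo iterations.
#' @param seed Master seed; the full result is reproducible given the seed.
#' @return An object of class `cea_psa`: list with `draws` (tibble:
#'   `iteration`, `strategy`, `cost`, `qalys`), `n_iter`, `seed`, `skipped`
#'   and `wtp`.
#' @export
run_psa <- function(config, ranges = default_dsa_ranges(config),
                    n_iter = 1000, seed = 1) {
  stopifnot(n_iter >= 1)
  validate_config(config)
  settings <- settings_from_config(config)
  lt <- life_table_from_config(config)
  sids <- names(config$strategies)

  slow_path <- any(grepl("^(survival|settings|life_table)", ranges$parameter))
  traces <- NULL
  if (!slow_path) {
    traces <- purrr::map(sids, function(sid) {
      run_cohort(strategy_from_config(config, sid), settings, lt)
    })
    names(traces) <- sids
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)

  skipped <- 0L
  draws <- purrr::map_dfr(seq_len(n_iter), function(it) {
    assignment <- draw_psa_params(ranges, seed, it)
    cfg <- config
    for (j in seq_len(nrow(assignment))) {
      cfg <- config_set(cfg, assignment$parameter[j], assignment$value[j])
    }
    res <- tryCatch(
      purrr::map_dfr(sids, function(sid) {
        strat <- strategy_from_config(cfg, sid)
        trace <- if (slow_path) {
          run_cohort(strat, settings_from_config(cfg),
                     life_table_from_config(cfg))
        } else {
          traces[[sid]]
        }
        dplyr::bind_cols(
          tibble::tibble(iteration = it, strategy = sid),
          accumulate(trace, strat,
                     if (slow_path) settings_from_config(cfg) else settings)
        )
      }),
      error = function(e) NULL
    )
    if (is.null(res)) skipped <<- skipped + 1L
    res
  })

  structure(
    list(draws = draws, n_iter = n_iter, seed = seed, skipped = skipped,
         wtp = settings$wtp),
    class = "cea_psa"
  )
}

#' @export
print.cea_psa <- function(x, ...) {
  cat("<cea_psa> ", x$n_iter, " iterations (", x$skipped, " skipped), seed ",
      x$seed, "\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' Tidy PSA draws
#'
#' @param x A `cea_psa`.
#' @param ... Unused.
#' @return The per-iteration draw tibble.
#' @method tidy cea_psa
#' @export
tidy.cea_psa <- function(x, ...) x$draws

#' PSA summary
#'
#' @param x A `cea_psa`.
#' @param wtp Willingness-to-pay used for the cost-effectiveness probability;
#'   defaults to the configuration's threshold.
#' @param ... Unused.
#' @return One row per strategy: mean cost, mean QALYs and the probability of
#'   being cost-effective (highest net monetary benefit) at `wtp`.
#' @method glance cea_psa
#' @export
glance.cea_psa <- function(x, wtp = x$wtp, ...) {
  cc <- ceac(x, wtp)
  means <- dplyr::summarise(dplyr::group_by(x$draws, .data$strategy),
                            mean_cost = mean(.data$cost),
                            mean_qalys = mean(.data$qalys), .groups = "drop")
  dplyr::left_join(means, cc[, c("strategy", "probability")], by = "strategy")
}

#' Cost-effectiveness acceptability curves
#'
#' At each willingness-to-pay value, the probability that a strategy is
#' cost-effective is the fraction of PSA iterations in which it attains the
#' maximal net monetary benefit; ties are split equally, so probabilities sum
#' to 1 across strategies at every threshold.
#'
#' @param psa A `cea_psa` from [run_psa()].
#' @param wtp_grid Vector of willingness-to-pay values, dollars per QALY.
#' @return A tibble of class `cea_ceac` with columns `wtp`, `strategy`,
#'   `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 300000, by = 25000)) {
  stopifnot(inherits(psa, "cea_psa"), nrow(psa$draws) > 0)
  out <- purrr::map_dfr(wtp_grid, function(w) {
    d <- dplyr::mutate(psa$draws, nmb = .data$qalys * w - .data$cost)
    d <- dplyr::mutate(
      dplyr::group_by(d, .data$iteration),
      win = (.data$nmb >= max(.data$nmb) - 1e-9) /
        sum(.data$nmb >= max(.data$nmb) - 1e-9)
    )
    dplyr::summarise(dplyr::group_by(dplyr::ungroup(d), .data$strategy),
                     probability = mean(.data$win), .groups = "drop") |>
      dplyr::mutate(wtp = w)
  })
  out <- out[, c("wtp", "strategy", "probability")]
  class(out) <- c("cea_ceac", class(out))
  out
}

#' Incremental cost-effectiveness scatter
#'
#' Per-iteration incremental pairs of the first strategy versus the second
#' (first minus second), plot-ready for the PSA scatter diagram.
#'
#' @param psa A `cea_psa` from [run_psa()].
#' @return A tibble of class `cea_scatter` with columns `iteration`,
#'   `delta_cost`, `delta_qalys`.
#' @export
ce_scatter <- function(psa) {
  stopifnot(inherits(psa, "cea_psa"), nrow(psa$draws) > 0)
  sids <- unique(psa$draws$strategy)
  stopifnot(length(sids) >= 2)
  wide <- tidyr::pivot_wider(psa$draws, id_cols = "iteration",
                             names_from = "strategy",
                             values_from = c("cost", "qalys"))
  out <- tibble::tibble(
    iteration = wide$iteration,
    delta_cost = wide[[paste0("cost_", sids[1])]] -
      wide[[paste0("cost_", sids[2])]],
    delta_qalys = wide[[paste0("qalys_", sids[1])]] -
      wide[[paste0("qalys_", sids[2])]]
  )
  class(out) <- c("cea_scatter", class(out))
  out
}
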