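# Structured model configuration: strategies, per-line survival laws, costs,
# utilities, adverse-event profiles, life table and settings, serializable to
# YAML, plus assembly into strategy objects and end-to-end evaluation.

#' Convert a plain list to a parametric survival law
#'
#' @param x A `parametric_survival` or a list with elements `family` and
#'   `params` (named list), as stored in a configuration file.
#' @return A [parametric_survival()].
#' @export
as_parametric_survival <- function(x) {
  if (inherits(x, "parametric_survival")) return(x)
  do.call(parametric_survival, c(list(x$family), as.list(x$params)))
}

survival_to_list <- function(dist) {
  list(family = dist$family, params = as.list(dist$params))
}

#' Get / set a configuration value by dot-separated path
#'
#' Paths address nested configuration elements, e.g.
#' `"drugs.brigatinib.cycle_cost"` or `"utilities.line2"`.
#'
#' @param config A model configuration (class `cea_config`).
#' @param path Dot-separated path string.
#' @param value Replacement value (for `config_set`).
#' @return `config_get` returns the value; `config_set` the updated
#'   configuration.
#' @export
config_get <- function(config, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  out <- purrr::pluck(config, !!!as.list(parts))
  if (is.null(out)) {
    stop("configuration path not found: '", path, "'", call. = FALSE)
  }
  out
}

#' @rdname config_get
#' @export
config_set <- function(config, path, value) {
  config_get(config, path)  # errors on unresolvable paths
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  purrr::assign_in(config, as.list(parts), value)
}

#' Validate a model configuration
#'
#' Checks structural completeness: two strategies of four lines each, every
#' referenced drug present with a non-negative cycle cost, utilities and
#' adverse-event incidences in `[0, 1]`, survival laws for every line and for
#' BSC, a life table, and positive settings.
#'
#' @param config A model configuration.
#' @return `config`, invisibly; errors describe the first violation found.
#' @export
validate_config <- function(config) {
  needed <- c("settings", "patient", "utilities", "drugs", "survival",
              "strategies", "life_table")
  missing <- setdiff(needed, names(config))
  if (length(missing) > 0) {
    stop("configuration lacks section(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (u in c("line1", "line2", "line3", "line4", "bsc")) {
    val <- config$utilities[[u]]
    if (is.null(val) || val < 0 || val > 1) {
      stop("utility '", u, "' missing or outside [0, 1]", call. = FALSE)
    }
  }
  for (sid in names(config$strategies)) {
    st <- config$strategies[[sid]]
    if (length(st$lines) != 4) {
      stop("strategy '", sid, "' must have exactly 4 treatment lines",
           call. = FALSE)
    }
    for (drug in st$lines) {
      if (is.null(config$drugs[[drug]])) {
        stop("strategy '", sid, "' references unknown drug '", drug, "'",
             call. = FALSE)
      }
    }
    for (i in 1:4) {
      if (is.null(config$survival[[sid]][[paste0("line", i)]])) {
        stop("missing survival law for strategy '", sid, "' line ", i,
             call. = FALSE)
      }
    }
  }
  for (drug in names(config$drugs)) {
    d <- config$drugs[[drug]]
    if (is.null(d$cycle_cost) || d$cycle_cost < 0) {
      stop("drug '", drug, "' needs a non-negative cycle_cost", call. = FALSE)
    }
    for (ae in names(d$ae %||% list())) {
      inc <- d$ae[[ae]]$incidence
      if (inc < 0 || inc > 1) {
        stop("incidence of '", ae, "' for '", drug, "' outside [0, 1]",
             call. = FALSE)
      }
    }
  }
  if (is.null(config$survival$bsc_os)) {
    stop("missing BSC overall-survival law", call. = FALSE)
  }
  invisible(config)
}

ae_list_to_tibble <- function(ae) {
  if (is.null(ae) || length(ae) == 0) return(NULL)
  purrr::imap_dfr(ae, function(x, nm) {
    tibble::tibble(event = nm, incidence = x$incidence, cost = x$cost,
                   disutility = x$disutility)
  })
}

#' Assemble a strategy object from a configuration
#'
#' @param config A validated model configuration.
#' @param id Strategy identifier (a name of `config$strategies`).
#' @return A [strategy_definition()].
#' @export
strategy_from_config <- function(config, id) {
  st <- config$strategies[[id]]
  if (is.null(st)) stop("unknown strategy '", id, "'", call. = FALSE)
  lines <- purrr::imap(st$lines, function(drug, i) {
    line_spec(
      name = drug,
      pfs_model = as_parametric_survival(config$survival[[id]][[paste0("line", i)]]),
      utility = config$utilities[[paste0("line", i)]],
      cycle_cost = config$drugs[[drug]]$cycle_cost,
      ae_profile = ae_list_to_tibble(config$drugs[[drug]]$ae)
    )
  })
  strategy_definition(
    label = st$label %||% id,
    lines = lines,
    bsc_os_model = as_parametric_survival(config$survival$bsc_os),
    bsc_utility = config$utilities$bsc,
    bsc_cycle_cost = config$drugs$bsc$cycle_cost %||% 0
  )
}

#' Extract model settings / life table from a configuration
#'
#' @param config A model configuration.
#' @return A [model_settings()] or [life_table()].
#' @export
settings_from_config <- function(config) {
  do.call(model_settings, config$settings)
}

#' @rdname settings_from_config
#' @export
life_table_from_config <- function(config) {
  life_table(tibble::as_tibble(config$life_table))
}

#' Evaluate every strategy in a configuration
#'
#' Runs the cohort model for each strategy and accumulates discounted costs
#' and QALYs; the incremental comparison (first strategy versus second) is
#' attached as attribute `"incremental"`.
#'
#' @param config A model configuration.
#' @return A tibble of class `cea_results` with columns `strategy`, `label`,
#'   `cost`, `qalys`.
#' @export
evaluate_strategies <- function(config) {
  validate_config(config)
  settings <- settings_from_config(config)
  lt <- life_table_from_config(config)
  res <- purrr::imap_dfr(config$strategies, function(st, sid) {
    strat <- strategy_from_config(config, sid)
    trace <- run_cohort(strat, settings, lt)
    dplyr::bind_cols(tibble::tibble(strategy = sid, label = strat$label),
                     accumulate(trace, strat, settings))
  })
  if (nrow(res) >= 2) {
    attr(res, "incremental") <- icer(
      list(cost = res$cost[1], qalys = res$qalys[1]),
      list(cost = res$cost[2], qalys = res$qalys[2])
    )
  }
  class(res) <- c("cea_results", class(res))
  res
}

#' Base-case results in published-table layout
#'
#' One row per strategy plus the incremental columns on the second row
#' (second strategy minus first), mirroring the usual base-case table of a
#' cost-effectiveness analysis.
#'
#' @param results A `cea_results` from [evaluate_strategies()].
#' @return A tibble with `arm`, `cost`, `delta_cost`, `qalys`, `delta_qalys`,
#'   `icer`, `dominance`.
#' @export
results_table <- function(results) {
  inc <- attr(results, "incremental")
  stopifnot(!is.null(inc))
  # table convention: increments of the second arm relative to the first
  tibble::tibble(
    arm = results$label,
    cost = results$cost,
    delta_cost = c(NA_real_, -inc$delta_cost),
    qalys = results$qalys,
    delta_qalys = c(NA_real_, -inc$delta_qalys),
    icer = c(NA_real_, inc$icer),
    dominance = c(NA_character_,
                  switch(inc$dominance,
                         dominated = "dominant", dominant = "dominated",
                         inc$dominance))
  )
}

#' @export
print.cea_results <- function(x, ...) {
  cat("Cost-effectiveness results\n")
  print(results_table(x), ...)
  invisible(x)
}

#' Read / write a model configuration as YAML
#'
#' @param file Path to a YAML configuration file.
#' @param config A model configuration.
#' @return `read_config` returns the configuration; `write_config` the path,
#'   invisibly.
#' @export
read_config <- function(file) {
  config <- yaml::read_yaml(file)
  config$life_table <- tibble::as_tibble(config$life_table)
  class(config) <- c("cea_config", "list")
  validate_config(config)
  config
}

#' @rdname read_config
#' @export
write_config <- function(config, file) {
  out <- unclass(config)
  out$life_table <- as.list(tibble::as_tibble(out$life_table))
  yaml::write_yaml(out, file, precision = 15)
  invisible(file)
}
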