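# Semi-Markov cohort engine: four treatment lines, best supportive care and
# death, with time-in-state (tunnel) strata so that per-line progression
# probabilities can depend on time since line entry.

#' Specify one treatment line
#'
#' @param name Label for the line (e.g. the regimen name).
#' @param pfs_model A [parametric_survival()] governing progression-free
#'   survival; the progression clock restarts at entry into the line.
#' @param utility Health-state utility in `[0, 1]`.
#' @param cycle_cost Cost per model cycle (drug acquisition, administration,
#'   disease management), in dollars.
#' @param ae_profile Optional data frame of grade >= 3 adverse events with
#'   columns `event`, `incidence` (in `[0, 1]`), `cost` (one-time, dollars)
#'   and `disutility` (one-time QALY decrement).
#' @return An object of class `line_spec`.
#' @export
line_spec <- function(name, pfs_model, utility, cycle_cost,
                      ae_profile = NULL) {
  stopifnot(inherits(pfs_model, "parametric_survival"))
  if (utility < 0 || utility > 1) stop("utility must lie in [0, 1]", call. = FALSE)
  if (cycle_cost < 0) stop("cycle_cost must be >= 0", call. = FALSE)
  if (!is.null(ae_profile)) {
    ae_profile <- tibble::as_tibble(ae_profile)
    stopifnot(all(c("event", "incidence", "cost", "disutility") %in%
                    names(ae_profile)))
    if (any(ae_profile$incidence < 0 | ae_profile$incidence > 1)) {
      stop("adverse-event incidences must lie in [0, 1]", call. = FALSE)
    }
    if (any(ae_profile$cost < 0) || any(ae_profile$disutility < 0)) {
      stop("adverse-event costs and disutilities must be >= 0", call. = FALSE)
    }
  }
  structure(
    list(name = name, pfs_model = pfs_model, utility = utility,
         cycle_cost = cycle_cost, ae_profile = ae_profile),
    class = "line_spec"
  )
}

# expected one-time adverse-event cost / disutility per patient entering
ae_entry_cost <- function(line) {
  if (is.null(line$ae_profile)) return(0)
  sum(line$ae_profile$incidence * line$ae_profile$cost)
}
ae_entry_disutility <- function(line) {
  if (is.null(line$ae_profile)) return(0)
  sum(line$ae_profile$incidence * line$ae_profile$disutility)
}

#' Define a treatment-sequencing strategy
#'
#' An ordered sequence of treatment lines followed by best supportive care
#' (BSC) and death. Progression from the last line enters BSC; death from BSC
#' is governed by `os_model` (overall survival with the clock restarting at
#' BSC entry) or background mortality, whichever is greater in a cycle.
#'
#' @param label Strategy label.
#' @param lines List of [line_spec()] objects in treatment order (the
#'   sequencing analysis shipped with the package uses exactly four).
#' @param bsc_os_model A [parametric_survival()] for overall survival on BSC.
#' @param bsc_utility Utility of the BSC state.
#' @param bsc_cycle_cost Cost per cycle in BSC.
#' @return An object of class `strategy_definition`.
#' @export
strategy_definition <- function(label, lines, bsc_os_model,
                                bsc_utility = 0.46, bsc_cycle_cost = 0) {
  stopifnot(length(lines) >= 1,
            all(purrr::map_lgl(lines, inherits, "line_spec")),
            inherits(bsc_os_model, "parametric_survival"))
  structure(
    list(label = label, lines = lines, bsc_os_model = bsc_os_model,
         bsc_utility = bsc_utility, bsc_cycle_cost = bsc_cycle_cost),
    class = "strategy_definition"
  )
}

#' Model settings
#'
#' @param cycle_length Cycle length in months (1 in the shipped analysis).
#' @param annual_discount_rate Annual discount rate applied identically to
#'   costs and QALYs (default 0.03).
#' @param start_age Cohort age at model start, years.
#' @param age_cap Lifetime horizon realized as an age cap (years).
#' @param wtp Willingness-to-pay threshold, dollars per QALY.
#' @param ae_timing `"line_entry"` charges each line's adverse-event cost and
#'   disutility to the cohort fraction entering that line (first cycle on the
#'   line); `"model_start"` charges the full expected burden of every line's
#'   profile once, at model cycle 0.
#' @return An object of class `model_settings`.
#' @export
model_settings <- function(cycle_length = 1, annual_discount_rate = 0.03,
                           start_age = 58, age_cap = 100, wtp = 150000,
                           ae_timing = c("line_entry", "model_start")) {
  ae_timing <- match.arg(ae_timing)
  structure(
    list(cycle_length = cycle_length,
         annual_discount_rate = annual_discount_rate,
         start_age = start_age, age_cap = age_cap, wtp = wtp,
         ae_timing = ae_timing),
    class = "model_settings"
  )
}

#' Single-stratum transition probabilities
#'
#' Death (background mortality) is applied before progression within a cycle,
#' so the raw progression probability from the survival-ratio formula is
#' scaled by the probability of surviving the cycle:
#' `p_progress = tp((k+1) u, u) * (1 - p_die)`.
#'
#' @param line A [line_spec()].
#' @param cycles_in_state Completed cycles in the line, `k >= 0`.
#' @param lt A [life_table()].
#' @param age Current age in years.
#' @param cycle_length Cycle length in months.
#' @return Named numeric vector `(p_stay, p_progress, p_die)`, summing to 1.
#' @export
cycle_transition <- function(line, cycles_in_state, lt, age,
                             cycle_length = 1) {
  stopifnot(cycles_in_state >= 0)
  p_die <- monthly_mortality(lt, age)
  tp <- transition_probability(line$pfs_model,
                               t = (cycles_in_state + 1) * cycle_length,
                               u = cycle_length)
  p_progress <- tp * (1 - p_die)
  c(p_stay = 1 - p_progress - p_die, p_progress = p_progress, p_die = p_die)
}

#' Run the cohort model for one strategy
#'
#' The cohort starts fully in line 1 with zero cycles in state. Each cycle,
#' every (state, time-in-state) stratum dies with the age-matched background
#' monthly probability, then progresses with the time-dependent survival-ratio
#' probability of its line; progression from the last line enters BSC, where
#' the per-cycle death probability is the larger of the BSC overall-survival
#' transition probability and background mortality. The simulation stops when
#' death occupancy exceeds `1 - 1e-6` or the cohort reaches the age cap; in
#' the latter case a warning reports the surviving fraction.
#'
#' @param strategy A [strategy_definition()].
#' @param settings A [model_settings()].
#' @param lt A [life_table()].
#' @return A tibble of class `cea_trace` with one row per (cycle, state):
#'   columns `cycle` (0-based), `state`, `occupancy` (fraction of cohort) and
#'   `entering` (fraction in its first cycle in that state, used for one-time
#'   adverse-event effects). States are the line names, `"bsc"` and
#'   `"death"`.
#' @export
run_cohort <- function(strategy, settings, lt) {
  stopifnot(inherits(strategy, "strategy_definition"),
            inherits(settings, "model_settings"))
  u <- settings$cycle_length
  n_lines <- length(strategy$lines)
  max_cycles <- ceiling((settings$age_cap - settings$start_age) * 12 / u)
  state_names <- c(purrr::map_chr(strategy$lines, "name"), "bsc", "death")

  # per-line raw progression probabilities by time-in-state k = 0, 1, ...
  # (suppressed warning: S(t-u) underflows to 0 far beyond cohort extinction,
  # where the transition probability is correctly 1)
  tp_line <- purrr::map(strategy$lines, function(ln) {
    suppressWarnings(
      transition_probability(ln$pfs_model, t = (1:max_cycles) * u, u = u))
  })
  tp_bsc <- suppressWarnings(
    transition_probability(strategy$bsc_os_model, t = (1:max_cycles) * u,
                           u = u))

  occ <- c(purrr::map(seq_len(n_lines), ~ numeric(0)), list(numeric(0)))
  occ[[1]] <- 1  # line 1, k = 0
  dead <- 0

  rows_cycle <- integer(0); rows_state <- character(0)
  rows_occ <- numeric(0); rows_enter <- numeric(0)
  final_cycle <- max_cycles
  for (cyc in 0:max_cycles) {
    totals <- purrr::map_dbl(occ, sum)
    rows_cycle <- c(rows_cycle, rep(cyc, n_lines + 2))
    rows_state <- c(rows_state, state_names)
    rows_occ <- c(rows_occ, totals, dead)
    rows_enter <- c(rows_enter,
                    purrr::map_dbl(occ, ~ if (length(.x) > 0) .x[1] else 0),
                    0)
    if (dead > 1 - 1e-6 || cyc == max_cycles) {
      final_cycle <- cyc
      break
    }

    q_m <- monthly_mortality(lt, settings$start_age + cyc * u / 12)
    new_occ <- vector("list", n_lines + 1)
    inflow <- 0
    for (i in seq_len(n_lines)) {
      v <- occ[[i]]
      len <- length(v)
      if (len == 0) {
        new_occ[[i]] <- c(inflow, numeric(0))
        inflow <- 0
        next
      }
      surv <- v * (1 - q_m)
      prog <- surv * tp_line[[i]][seq_len(len)]
      stay <- surv - prog
      dead <- dead + sum(v) * q_m
      new_occ[[i]] <- c(inflow, stay)
      inflow <- sum(prog)
    }
    vb <- occ[[n_lines + 1]]
    lenb <- length(vb)
    if (lenb > 0) {
      p_die_b <- pmax(tp_bsc[seq_len(lenb)], q_m)
      dead <- dead + sum(vb * p_die_b)
      new_occ[[n_lines + 1]] <- c(inflow, vb * (1 - p_die_b))
    } else {
      new_occ[[n_lines + 1]] <- c(inflow, numeric(0))
    }
    occ <- new_occ
  }

  alive <- 1 - dead
  if (final_cycle == max_cycles && alive > 1e-6) {
    warning(sprintf(
      "age cap reached with %.2g%% of the cohort alive; totals are truncated",
      100 * alive), call. = FALSE)
  }

  out <- tibble::tibble(
    cycle = rows_cycle,
    state = factor(rows_state, levels = state_names),
    occupancy = rows_occ,
    entering = rows_enter
  )
  class(out) <- c("cea_trace", class(out))
  attr(out, "strategy_label") <- strategy$label
  attr(out, "n_lines") <- n_lines
  out
}

state_value_table <- function(strategy) {
  lines <- strategy$lines
  tibble::tibble(
    state = c(purrr::map_chr(lines, "name"), "bsc", "death"),
    utility = c(purrr::map_dbl(lines, "utility"), strategy$bsc_utility, 0),
    cycle_cost = c(purrr::map_dbl(lines, "cycle_cost"),
                   strategy$bsc_cycle_cost, 0),
    ae_cost = c(purrr::map_dbl(lines, ae_entry_cost), 0, 0),
    ae_disutility = c(purrr::map_dbl(lines, ae_entry_disutility), 0, 0)
  )
}

#' Accumulate discounted costs and QALYs over a cohort trace
#'
#' Costs and utilities accrue at the beginning of each cycle with no
#' half-cycle correction; the discount factor for cycle `c` (0-based) is
#' \eqn{(1 + r)^{-c/12}} with `r` the annual rate, applied identically to
#' costs and QALYs. Each cycle contributes `occupancy * cycle_cost` to cost
#' and `occupancy * utility / 12` to QALYs per state. One-time adverse-event
#' costs and disutilities are charged to the cohort fraction entering a line
#' (or, under `ae_timing = "model_start"`, the full expected burden of every
#' line at cycle 0), weighted by incidence.
#'
#' @param trace A `cea_trace` from [run_cohort()].
#' @param strategy The [strategy_definition()] that produced it.
#' @param settings A [model_settings()].
#' @return A one-row tibble with `cost` and `qalys`.
#' @export
accumulate <- function(trace, strategy, settings) {
  vals <- state_value_table(strategy)
  r <- settings$annual_discount_rate
  u <- settings$cycle_length
  df <- dplyr::left_join(trace, vals, by = "state")
  disc <- (1 + r)^(-df$cycle * u / 12)

  cost <- sum(df$occupancy * df$cycle_cost * disc)
  qalys <- sum(df$occupancy * df$utility * (u / 12) * disc)
  if (settings$ae_timing == "line_entry") {
    cost <- cost + sum(df$entering * df$ae_cost * disc)
    qalys <- qalys - sum(df$entering * df$ae_disutility * disc)
  } else {
    cost <- cost + sum(vals$ae_cost)
    qalys <- qalys - sum(vals$ae_disutility)
  }
  tibble::tibble(cost = cost, qalys = qalys)
}
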