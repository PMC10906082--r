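# Reconstruction of pseudo individual-patient data from digitized
# Kaplan-Meier coordinates plus numbers at risk, and the product-limit
# estimator used as its round-trip validation oracle.

#' Bundle digitized Kaplan-Meier coordinates with a risk table
#'
#' Hand-digitized curves wobble, so survival values are clipped to be
#' non-increasing (running minimum) before use; the reconstruction algorithm
#' assumes a monotone input curve. A `(0, 1)` origin is prepended when absent.
#'
#' @param coords Data frame with columns `time` (months, strictly increasing)
#'   and `survival` (probabilities).
#' @param risk_table Data frame with columns `time` and `n_at_risk`
#'   (non-increasing integers), at least two rows.
#' @param total_events_reported Optional integer: total event count printed
#'   with the source figure, used as a secondary constraint for event
#'   allocation after the last risk-table time.
#'
#' @return An object of class `digitized_km`.
#' @export
digitized_km <- function(coords, risk_table, total_events_reported = NULL) {
  coords <- tibble::as_tibble(coords)[, c("time", "survival")]
  risk_table <- tibble::as_tibble(risk_table)[, c("time", "n_at_risk")]
  if (nrow(coords) == 0) stop("empty coordinate table", call. = FALSE)
  if (coords$time[1] != 0) {
    coords <- dplyr::bind_rows(tibble::tibble(time = 0, survival = 1), coords)
  }
  if (any(diff(coords$time) <= 0)) {
    stop("coordinate times must be strictly increasing", call. = FALSE)
  }
  if (any(coords$survival > 1 + 1e-9) || any(coords$survival < -1e-9)) {
    stop("survival values must lie in [0, 1]", call. = FALSE)
  }
  coords$survival <- cummin(pmin(coords$survival, 1))
  if (nrow(risk_table) < 2) {
    stop("risk table needs at least two entries", call. = FALSE)
  }
  if (any(diff(risk_table$time) <= 0)) {
    stop("risk-table times must be strictly increasing", call. = FALSE)
  }
  if (any(diff(risk_table$n_at_risk) > 0)) {
    stop("numbers at risk must be non-increasing", call. = FALSE)
  }
  structure(
    list(coords = coords, risk_table = risk_table,
         total_events_reported = total_events_reported),
    class = "digitized_km"
  )
}

#' @export
print.digitized_km <- function(x, ...) {
  cat("<digitized_km> ", nrow(x$coords), " coordinates, risk table at ",
      nrow(x$risk_table), " times (n = ", x$risk_table$n_at_risk[1], ")\n",
      sep = "")
  invisible(x)
}

#' Reconstruct pseudo individual-patient data from a digitized KM curve
#'
#' Within each interval between consecutive risk-table times, event and
#' censoring counts are allocated so that (a) the product-limit estimator of
#' the output tracks the digitized coordinates and (b) the number at risk at
#' each risk-table time is matched exactly. Censoring times are spread
#' uniformly within each interval; events are placed at the digitized drop
#' times and precede censorings at tied times. After the last risk-table time
#' events are read off the remaining drops (rescaled to
#' `total_events_reported` when that is supplied) and the residual cohort is
#' administratively censored at the last coordinate time.
#'
#' @param km A [digitized_km()] object.
#' @return A tibble of class `pseudo_ipd` with columns `time` (months) and
#'   `event` (1 = progression/death, 0 = censored); the number of rows equals
#'   the number at risk at the first risk-table time.
#' @export
reconstruct_ipd <- function(km) {
  stopifnot(inherits(km, "digitized_km"))
  coords <- km$coords
  rt <- km$risk_table

  ev_times <- numeric(0)
  cens_times <- numeric(0)
  s_run <- 1       # reconstructed KM at the current position
  n_cur_global <- rt$n_at_risk[1]

  alloc_interval <- function(idx, n_start, n_end_target, s_start, t_lo, t_hi) {
    # returns list(ev, cens, s_end) or NULL if infeasible
    pts <- coords[coords$time > t_lo & coords$time <= t_hi, ]
    c_guess <- 0
    for (iter in 1:200) {
      if (c_guess > 0) {
        ct <- t_lo + (seq_len(c_guess) - 0.5) * (t_hi - t_lo) / c_guess
      } else {
        ct <- numeric(0)
      }
      n_cur <- n_start
      s_cur <- s_start
      ev <- numeric(0)
      prev_t <- t_lo
      for (i in seq_len(nrow(pts))) {
        ti <- pts$time[i]
        # censorings strictly before this drop leave the risk set first
        n_cur <- n_cur - sum(ct >= prev_t & ct < ti)
        d <- 0
        if (n_cur > 0 && s_cur > 0) {
          d <- round(n_cur * (1 - pts$survival[i] / s_cur))
          d <- max(0, min(d, n_cur))
          if (d > 0) {
            s_cur <- s_cur * (1 - d / n_cur)
            ev <- c(ev, rep(ti, d))
            n_cur <- n_cur - d
          }
        }
        prev_t <- ti
      }
      n_cur <- n_cur - sum(ct >= prev_t & ct <= t_hi)
      diff <- n_cur - n_end_target
      if (diff == 0) {
        return(list(ev = ev, cens = ct, s_end = s_cur))
      }
      c_guess <- c_guess + diff
      if (c_guess < 0) return(NULL)
    }
    NULL
  }

  for (k in seq_len(nrow(rt) - 1)) {
    res <- alloc_interval(
      k, n_start = n_cur_global, n_end_target = rt$n_at_risk[k + 1],
      s_start = s_run, t_lo = rt$time[k], t_hi = rt$time[k + 1]
    )
    if (is.null(res)) {
      stop("risk table inconsistent with any non-negative allocation in ",
           "interval [", rt$time[k], ", ", rt$time[k + 1], "]", call. = FALSE)
    }
    ev_times <- c(ev_times, res$ev)
    cens_times <- c(cens_times, res$cens)
    s_run <- res$s_end
    n_cur_global <- rt$n_at_risk[k + 1]
  }

  # drops after the last risk-table time: no interior censoring assumed
  t_last <- rt$time[nrow(rt)]
  tail_pts <- coords[coords$time > t_last, ]
  n_cur <- n_cur_global
  s_cur <- s_run
  tail_ev <- numeric(0)
  for (i in seq_len(nrow(tail_pts))) {
    if (n_cur <= 0 || s_cur <= 0) break
    d <- round(n_cur * (1 - tail_pts$survival[i] / s_cur))
    d <- max(0, min(d, n_cur))
    if (d > 0) {
      s_cur <- s_cur * (1 - d / n_cur)
      tail_ev <- c(tail_ev, rep(tail_pts$time[i], d))
      n_cur <- n_cur - d
    }
  }
  if (!is.null(km$total_events_reported)) {
    deficit <- km$total_events_reported - (length(ev_times) + length(tail_ev))
    if (deficit > 0 && n_cur > 0) {
      extra <- min(deficit, n_cur)
      tail_ev <- c(tail_ev, rep(max(coords$time), extra))
      n_cur <- n_cur - extra
    } else if (deficit < 0 && length(tail_ev) > 0) {
      drop <- min(-deficit, length(tail_ev))
      tail_ev <- tail_ev[seq_len(length(tail_ev) - drop)]
      n_cur <- n_cur + drop
    }
  }
  ev_times <- c(ev_times, tail_ev)
  if (n_cur > 0) cens_times <- c(cens_times, rep(max(coords$time), n_cur))

  out <- dplyr::arrange(
    tibble::tibble(
      time = c(ev_times, cens_times),
      event = c(rep(1L, length(ev_times)), rep(0L, length(cens_times)))
    ),
    .data$time, dplyr::desc(.data$event)
  )
  class(out) <- c("pseudo_ipd", class(out))
  out
}

#' Product-limit (Kaplan-Meier) estimate of pseudo-IPD
#'
#' Conventional handling of ties: events precede censorings at identical
#' times, so both deplete the same risk set but only events produce a drop.
#'
#' @param ipd Data frame with columns `time` and `event`.
#' @return A tibble of class `km_curve` with columns `time`, `survival`,
#'   `n_risk`, `n_event`, `n_censor`, starting at `(0, 1)`.
#' @export
km_estimate <- function(ipd) {
  ipd <- tibble::as_tibble(ipd)
  if (nrow(ipd) == 0) stop("empty pseudo-IPD", call. = FALSE)
  stopifnot(all(c("time", "event") %in% names(ipd)))
  times <- sort(unique(ipd$time))
  n <- nrow(ipd)
  surv <- 1
  rows <- purrr::map_dfr(times, function(tt) {
    at_risk <- sum(ipd$time >= tt)
    d <- sum(ipd$time == tt & ipd$event == 1)
    cns <- sum(ipd$time == tt & ipd$event == 0)
    if (at_risk > 0 && d > 0) surv <<- surv * (1 - d / at_risk)
    tibble::tibble(time = tt, survival = surv, n_risk = at_risk,
                   n_event = d, n_censor = cns)
  })
  out <- dplyr::bind_rows(
    tibble::tibble(time = 0, survival = 1, n_risk = n, n_event = 0L,
                   n_censor = 0L),
    rows[rows$time > 0, , drop = FALSE]
  )
  class(out) <- c("km_curve", class(out))
  out
}

# step-function evaluation of a KM curve at arbitrary times
km_survival_at <- function(curve, t) {
  f <- stats::stepfun(curve$time[-1], curve$survival, right = FALSE)
  f(t)
}

#' Sample a KM curve onto a digitization grid with a risk table
#'
#' @param curve A `km_curve` (from [km_estimate()]).
#' @param ipd The pseudo-IPD behind the curve, used for the risk table.
#' @param coord_times Times at which to read off coordinates.
#' @param risk_times Times for the number-at-risk table.
#' @return A [digitized_km()] object.
#' @export
as_digitized_km <- function(curve, ipd, coord_times, risk_times) {
  coords <- tibble::tibble(
    time = coord_times,
    survival = km_survival_at(curve, coord_times)
  )
  risk_times <- risk_times[risk_times <= max(ipd$time)]
  rt <- tibble::tibble(
    time = risk_times,
    n_at_risk = purrr::map_int(risk_times, ~ sum(ipd$time >= .x))
  )
  digitized_km(coords, rt, total_events_reported = sum(ipd$event == 1))
}

#' Read a digitized KM curve from CSV files
#'
#' @param coords_file CSV with columns `time`, `survival`.
#' @param risk_file CSV with columns `time`, `n_at_risk`.
#' @param total_events_reported Optional integer.
#' @return A [digitized_km()] object.
#' @export
read_km_csv <- function(coords_file, risk_file, total_events_reported = NULL) {
  digitized_km(
    readr::read_csv(coords_file, show_col_types = FALSE),
    readr::read_csv(risk_file, show_col_types = FALSE),
    total_events_reported = total_events_reported
  )
}

#' Write a digitized KM curve to CSV files
#'
#' @param km A [digitized_km()] object.
#' @param coords_file,risk_file Output paths.
#' @return `km`, invisibly.
#' @export
write_km_csv <- function(km, coords_file, risk_file) {
  readr::write_csv(km$coords, coords_file)
  readr::write_csv(km$risk_table, risk_file)
  invisible(km)
}
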