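# Age-matched background mortality from an annual life table.

#' Construct a life table
#'
#' @param table Data frame with columns `age` (contiguous integer years) and
#'   `annual_mortality` (probability of dying within the year).
#' @return A tibble of class `life_table`.
#' @export
life_table <- function(table) {
  tab <- tibble::as_tibble(table)[, c("age", "annual_mortality")]
  if (any(diff(tab$age) != 1)) stop("ages must be contiguous", call. = FALSE)
  if (any(tab$annual_mortality < 0 | tab$annual_mortality > 1)) {
    stop("annual mortality must lie in [0, 1]", call. = FALSE)
  }
  class(tab) <- c("life_table", class(tab))
  tab
}

#' Monthly background mortality at a given age
#'
#' Converts the annual probability q(age) to a monthly probability under a
#' constant hazard within the year: \eqn{1 - (1 - q)^{1/12}}. Ages beyond the
#' table end carry probability 1.
#'
#' @param lt A [life_table()].
#' @param age Age(s) in years (fractional ages use the attained whole year).
#' @return Monthly death probabilities in `[0, 1]`.
#' @export
monthly_mortality <- function(lt, age) {
  stopifnot(inherits(lt, "life_table"))
  if (any(age < min(lt$age))) {
    stop("age below the start of the life table", call. = FALSE)
  }
  idx <- floor(age) - min(lt$age) + 1
  q <- ifelse(idx > nrow(lt), 1, lt$annual_mortality[pmin(idx, nrow(lt))])
  1 - (1 - q)^(1 / 12)
}

#' Synthetic life table with Gompertz-Makeham mortality
#'
#' A plausible monotone annual mortality schedule,
#' \eqn{q(a) = \min(1, A + B e^{c a})}, spanning ages 0 to `max_age`. With the
#' defaults the annual probability at age 58 is about 0.008, in the vicinity
#' of general-population values for high-income countries.
#'
#' @param max_age Last tabulated age (years).
#' @param makeham Age-independent component A.
#' @param b,c Gompertz level and slope.
#' @return A [life_table()].
#' @export
synthetic_life_table <- function(max_age = 100, makeham = 2e-4, b = 3e-5,
                                 c = 0.095) {
  ages <- 0:max_age
  q <- pmin(1, makeham + b * exp(c * ages))
  life_table(tibble::tibble(age = ages, annual_mortality = q))
}

#' Read a life table from CSV
#'
#' @param file CSV with columns `age`, `annual_mortality`.
#' @return A [life_table()].
#' @export
read_life_table_csv <- function(file) {
  life_table(readr::read_csv(file, show_col_types = FALSE))
}
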