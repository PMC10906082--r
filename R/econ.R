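# Drug dosing, per-cycle cost construction, inflation adjustment and
# incremental economics (ICER, net monetary benefit, dominance).

#' Reference patient profile for dosing
#'
#' @param bsa Body surface area, m^2.
#' @param weight Body weight, kg.
#' @param crcl Creatinine clearance, mL/min.
#' @return An object of class `patient_profile`.
#' @export
patient_profile <- function(bsa = 1.72, weight = 65, crcl = 70) {
  stopifnot(bsa > 0, weight > 0, crcl > 0)
  structure(list(bsa = bsa, weight = weight, crcl = crcl),
            class = "patient_profile")
}

#' Specify a drug dosing schedule
#'
#' @param drug Drug name.
#' @param rule Dosing rule: `"flat"` (mg per administration), `"per_bsa"`
#'   (mg/m^2), `"per_weight"` (mg/kg) or `"carboplatin_auc"` (target AUC via
#'   the Calvert formula, dose = AUC x (CrCl + 25)).
#' @param dose Dose quantity under the rule.
#' @param admins_per_cycle Administrations per model cycle.
#' @param unit_price Price per mg (or per Calvert-formula mg), dollars.
#' @param admin_fee Administration fee per administration, dollars.
#' @return An object of class `drug_schedule`.
#' @export
drug_schedule <- function(drug, rule = c("flat", "per_bsa", "per_weight",
                                         "carboplatin_auc"),
                          dose, admins_per_cycle = 1, unit_price = 0,
                          admin_fee = 0) {
  rule <- match.arg(rule)
  stopifnot(dose >= 0, admins_per_cycle >= 0, unit_price >= 0, admin_fee >= 0)
  structure(
    list(drug = drug, rule = rule, dose = dose,
         admins_per_cycle = admins_per_cycle, unit_price = unit_price,
         admin_fee = admin_fee),
    class = "drug_schedule"
  )
}

#' Dose per administration, in mg
#'
#' @param schedule A [drug_schedule()].
#' @param patient A [patient_profile()].
#' @return Dose in mg.
#' @examples
#' pt <- patient_profile()
#' dose_per_administration(drug_schedule("pemetrexed", "per_bsa", 500), pt)
#' dose_per_administration(drug_schedule("carboplatin", "carboplatin_auc", 5), pt)
#' @export
dose_per_administration <- function(schedule, patient) {
  stopifnot(inherits(schedule, "drug_schedule"),
            inherits(patient, "patient_profile"))
  switch(schedule$rule,
    flat = schedule$dose,
    per_bsa = schedule$dose * patient$bsa,
    per_weight = schedule$dose * patient$weight,
    carboplatin_auc = schedule$dose * (patient$crcl + 25),
    stop("unknown dosing rule: ", schedule$rule, call. = FALSE)
  )
}

#' Per-cycle cost of a treatment line
#'
#' Sums drug acquisition (dose x unit price) and administration fees over all
#' schedules, adds the monthly follow-up cost (laboratory tests and an office
#' visit) and amortizes tumour imaging performed every `imaging_interval`
#' cycles.
#'
#' @param schedules List of [drug_schedule()] objects for the line.
#' @param patient A [patient_profile()].
#' @param followup_cost Monthly follow-up cost, dollars.
#' @param imaging_cost Cost per imaging procedure, dollars.
#' @param imaging_interval Cycles between imaging procedures.
#' @return Cost per cycle, dollars.
#' @export
cycle_cost <- function(schedules, patient = patient_profile(),
                       followup_cost = 0, imaging_cost = 0,
                       imaging_interval = 3) {
  if (inherits(schedules, "drug_schedule")) schedules <- list(schedules)
  drug <- sum(purrr::map_dbl(schedules, function(s) {
    (dose_per_administration(s, patient) * s$unit_price + s$admin_fee) *
      s$admins_per_cycle
  }))
  drug + followup_cost + imaging_cost / imaging_interval
}

#' Inflation-adjust a cost
#'
#' Multiplies by a user-supplied consumer-price-index ratio (target-year index
#' over source-year index).
#'
#' @param cost Cost(s) in dollars.
#' @param index_ratio Positive CPI ratio.
#' @return Adjusted cost(s).
#' @export
adjust_inflation <- function(cost, index_ratio) {
  if (any(index_ratio <= 0)) {
    stop("index_ratio must be > 0", call. = FALSE)
  }
  cost * index_ratio
}

#' Incremental cost-effectiveness of strategy A versus strategy B
#'
#' Computes `delta_cost = cost_A - cost_B` and
#' `delta_qalys = qalys_A - qalys_B`. Strategy A is labelled `"dominated"`
#' when it costs more and yields fewer QALYs, and `"dominant"` when it costs
#' less and yields more. The signed quotient `delta_cost / delta_qalys` is
#' reported alongside the label whenever `delta_qalys != 0` (conventional in
#' published tables even under dominance); when `delta_qalys == 0` the ICER
#' is undefined and the comparison is by cost alone.
#'
#' @param outcome_a,outcome_b Lists, one-row data frames or named vectors
#'   with elements `cost` and `qalys`.
#' @return A one-row tibble of class `cea_icer` with `delta_cost`,
#'   `delta_qalys`, `icer` and `dominance` (one of `"dominated"`,
#'   `"dominant"`, `"icer"`, `"cheaper"`, `"costlier"`, `"equivalent"`).
#' @examples
#' icer(list(cost = 219712, qalys = 0.70), list(cost = 196513, qalys = 0.76))
#' @export
icer <- function(outcome_a, outcome_b) {
  a <- as.list(outcome_a); b <- as.list(outcome_b)
  stopifnot(is.finite(a$cost[[1]]), is.finite(a$qalys[[1]]),
            is.finite(b$cost[[1]]), is.finite(b$qalys[[1]]))
  dc <- a$cost[[1]] - b$cost[[1]]
  dq <- a$qalys[[1]] - b$qalys[[1]]
  if (dq == 0) {
    dominance <- if (dc < 0) "cheaper" else if (dc > 0) "costlier" else "equivalent"
    ratio <- NA_real_
  } else {
    ratio <- dc / dq
    dominance <- if (dc > 0 && dq < 0) "dominated"
                 else if (dc < 0 && dq > 0) "dominant"
                 else "icer"
  }
  out <- tibble::tibble(delta_cost = dc, delta_qalys = dq, icer = ratio,
                        dominance = dominance)
  class(out) <- c("cea_icer", class(out))
  out
}

#' Net monetary benefit
#'
#' @param outcome List/one-row data frame with `cost` and `qalys`.
#' @param wtp Willingness-to-pay threshold, dollars per QALY (`>= 0`).
#' @return `qalys * wtp - cost`, dollars.
#' @export
nmb <- function(outcome, wtp) {
  stopifnot(wtp >= 0)
  o <- as.list(outcome)
  o$qalys[[1]] * wtp - o$cost[[1]]
}
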