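#' Convert a dose specification to ng PTX-equivalent
#'
#' All dosing in the model is expressed as ng of PTX-equivalent mass
#' entering a layer's central compartment. Supported input units:
#' micrograms (`"ug"`), body-weight-normalized milligrams per kilogram
#' (`"mg_per_kg"`), and MSC cell counts (`"msc"`, converted at the nominal
#' PTX payload per 10^6 cells).
#'
#' @param value dose magnitude (> 0).
#' @param unit `"ug"`, `"mg_per_kg"` or `"msc"`.
#' @param body_weight animal body weight in kg (used for `"mg_per_kg"`).
#' @param ug_per_1e6 PTX-equivalent micrograms per 10^6 MSCs.
#' @return Dose in ng.
#' @examples
#' to_ptx_equivalent(5, "ug")              # 5000 ng
#' to_ptx_equivalent(0.25, "mg_per_kg")    # also 5000 ng at 0.02 kg
#' to_ptx_equivalent(1e6, "msc")           # 25000 ng
#' @export
to_ptx_equivalent <- function(value, unit = c("ug", "mg_per_kg", "msc"),
                              body_weight = 0.02, ug_per_1e6 = 25) {
  unit <- match.arg(unit)
  if (!is.numeric(value) || any(value <= 0) || !all(is.finite(value)))
    stop("to_ptx_equivalent: dose value must be positive and finite")
  switch(unit,
         ug = value * 1000,
         mg_per_kg = value * body_weight * 1e6,
         msc = value / 1e6 * ug_per_1e6 * 1000)
}

#' A single bolus dose event
#'
#' @param time dose time, h (>= 0).
#' @param amount PTX-equivalent amount, ng (> 0).
#' @param layer target layer: `"free"`, `"np"` or `"msc"`; the dose is an
#'   instantaneous bolus into that layer's central compartment.
#' @return A one-row data frame with columns `time`, `amount`, `layer`.
#' @export
dose_event <- function(time, amount, layer = c("msc", "np", "free")) {
  layer <- match.arg(layer)
  if (time < 0) stop("dose_event: time must be >= 0")
  if (amount <= 0) stop("dose_event: amount must be > 0")
  data.frame(time = time, amount = amount, layer = layer,
             stringsAsFactors = FALSE)
}

#' A dosing regimen: an ordered set of dose events
#'
#' @param ... one or more [dose_event()] rows (or data frames of them).
#' @param label short label for reports.
#' @return Object of class `regimen`: a data frame of events sorted by
#'   time, with a `label` attribute.
#' @export
regimen <- function(..., label = "regimen") {
  ev <- do.call(rbind, list(...))
  if (is.null(ev) || nrow(ev) == 0L) stop("regimen: at least one dose event required")
  ev <- ev[order(ev$time), , drop = FALSE]
  rownames(ev) <- NULL
  structure(ev, label = label, class = c("regimen", "data.frame"))
}

#' Standard study regimens
#'
#' `regimen_pk_bolus()` is the single-dose disposition-study regimen: one
#' 5 ug (5000 ng) IV bolus into the topmost layer of the chosen
#' formulation. `regimen_efficacy()` builds the multi-dose efficacy
#' regimens: 40 mg/kg on days 0, 4 and 8 for the free-drug and NP arms,
#' and a 10^6-MSC loading dose followed by maintenance MSC doses at a
#' fixed interval for the nano-MSC arm.
#'
#' @param arm `"ptx"`, `"np"` or `"msc"`.
#' @param body_weight kg.
#' @param msc_maintenance maintenance dose in MSC count (nano-MSC arm).
#' @param interval_days maintenance dosing interval, days (nano-MSC arm).
#' @param horizon_days last day on which a maintenance dose may fall.
#' @return A [regimen()].
#' @export
regimen_pk_bolus <- function(arm = c("msc", "np", "ptx")) {
  arm <- match.arg(arm)
  layer <- switch(arm, ptx = "free", np = "np", msc = "msc")
  regimen(dose_event(0, to_ptx_equivalent(5, "ug"), layer),
          label = paste0("single 5 ug bolus (", arm, ")"))
}

#' @rdname regimen_pk_bolus
#' @export
regimen_efficacy <- function(arm = c("msc", "np", "ptx"), body_weight = 0.02,
                             msc_maintenance = 0.5e6, interval_days = 14,
                             horizon_days = 63) {
  arm <- match.arg(arm)
  if (arm %in% c("ptx", "np")) {
    layer <- if (arm == "ptx") "free" else "np"
    amt <- to_ptx_equivalent(40, "mg_per_kg", body_weight = body_weight)
    ev <- do.call(rbind, lapply(c(0, 4, 8) * 24, dose_event,
                                amount = amt, layer = layer))
    return(regimen(ev, label = paste0("40 mg/kg d0,4,8 (", arm, ")")))
  }
  load_amt <- to_ptx_equivalent(1e6, "msc")
  maint_amt <- to_ptx_equivalent(msc_maintenance, "msc")
  mt <- seq(interval_days, horizon_days, by = interval_days) * 24
  ev <- rbind(dose_event(0, load_amt, "msc"),
              do.call(rbind, lapply(mt, dose_event, amount = maint_amt,
                                    layer = "msc")))
  regimen(ev, label = sprintf("1e6 MSC d0 + %.3ge6 q%gd", msc_maintenance / 1e6,
                              interval_days))
}
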