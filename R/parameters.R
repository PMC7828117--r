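#' Parameters for a small-molecule PK layer
#'
#' One disposition layer of the tumor-bearing mouse PK model (free
#' paclitaxel, or paclitaxel still encapsulated in PLGA nanoparticles).
#' Each layer is a three-compartment model: central, peripheral and tumor,
#' with linear elimination from the central compartment and tumor uptake
#' through parallel vascular-exchange and surface-exchange processes.
#'
#' @param CL clearance from the central compartment (mL/h).
#' @param CLD distributional clearance central <-> peripheral (mL/h).
#' @param Vc central volume of distribution (mL).
#' @param Vp peripheral volume of distribution (mL).
#' @param fu plasma-to-blood ratio applied to the central concentration in
#'   the plasma observation model (unitless, in (0, 1]).
#' @param P tumor capillary permeability (cm/h).
#' @param D tumor surface diffusivity (cm^2/h).
#' @param E tumor accessible fraction (unitless, in (0, 1]).
#' @return An object of class `sm_layer_params`.
#' @export
sm_layer_params <- function(CL, CLD, Vc, Vp, fu, P, D, E) {
  p <- list(CL = CL, CLD = CLD, Vc = Vc, Vp = Vp, fu = fu, P = P, D = D, E = E)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("sm_layer_params: '", nm, "' must be a single positive finite number")
  }
  if (E > 1) stop("sm_layer_params: accessible fraction E must be in (0, 1]")
  if (fu > 1) stop("sm_layer_params: plasma-to-blood ratio fu must be in (0, 1]")
  structure(p, class = "sm_layer_params")
}

#' Parameters for the nano-MSC carrier layer
#'
#' The MSC layer moves drug mass by two unidirectional extravasation
#' processes out of the central compartment (to tumor and to peripheral);
#' there is no systemic clearance and no back-transfer. Its dynamics are
#' written on amounts only; `Vc` enters solely through the plasma
#' observation model, and `Vp` appears in no equation at all (it is carried
#' for completeness of the reported parameter set).
#'
#' @param Kct central-to-tumor first-order transfer rate constant (1/h).
#' @param Kcp central-to-peripheral first-order transfer rate constant (1/h).
#' @param Vc central volume of distribution (mL), observation model only.
#' @param Vp peripheral volume of distribution (mL), unused in the dynamics.
#' @return An object of class `msc_layer_params`.
#' @export
msc_layer_params <- function(Kct, Kcp, Vc, Vp) {
  p <- list(Kct = Kct, Kcp = Kcp, Vc = Vc, Vp = Vp)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("msc_layer_params: '", nm, "' must be a single positive finite number")
  }
  structure(p, class = "msc_layer_params")
}

#' Inter-layer transfer rate constants
#'
#' @param Krel first-order drug release rate constant (1/h); applies to the
#'   NP layer and, by the fast-efflux assumption, to the MSC layer as well.
#' @param Kexo first-order nanoparticle exocytosis rate constant on a
#'   drug-mass basis (1/h), i.e. already scaled by the drug loading.
#' @param loading drug loading of the nanoparticles (mg PTX per mg NP).
#' @return An object of class `transfer_params`.
#' @export
transfer_params <- function(Krel, Kexo, loading = 0.148) {
  if (!is.numeric(Krel) || length(Krel) != 1L || !is.finite(Krel) || Krel <= 0)
    stop("transfer_params: Krel must be a single positive number")
  if (!is.numeric(Kexo) || length(Kexo) != 1L || !is.finite(Kexo) || Kexo <= 0)
    stop("transfer_params: Kexo must be a single positive number")
  if (!is.numeric(loading) || length(loading) != 1L || loading <= 0 || loading >= 1)
    stop("transfer_params: loading must be in (0, 1)")
  structure(list(Krel = Krel, Kexo = Kexo, loading = loading),
            class = "transfer_params")
}

#' Tumor geometry driving the exchange fluxes
#'
#' Holds the tumor volume and the radii that scale the vascular- and
#' surface-exchange processes. With `dynamic = TRUE` (the PD configuration)
#' the volume and radius are recomputed from the tumor-burden state at
#' every right-hand-side evaluation via the bioluminescence calibration and
#' the sphere relation; the stored `VT`/`Rtumor` then only serve as the
#' static-PK fallback.
#'
#' @param VT tumor volume (mL).
#' @param Rtumor tumor radius (cm). Defaults to the sphere radius of `VT`.
#' @param Rcap radius of tumor-associated capillaries (cm).
#' @param RKrogh inter-capillary (Krogh) half-distance (cm).
#' @param dynamic logical; recompute `VT`/`Rtumor` from tumor burden
#'   during PD integration.
#' @return An object of class `tumor_geometry`.
#' @export
tumor_geometry <- function(VT = 0.3, Rtumor = NULL, Rcap = 0.0075,
                           RKrogh = 0.0008, dynamic = FALSE) {
  if (is.null(Rtumor)) Rtumor <- radius_from_volume(VT)
  p <- list(VT = VT, Rtumor = Rtumor, Rcap = Rcap, RKrogh = RKrogh)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("tumor_geometry: '", nm, "' must be a single positive finite number")
  }
  p$dynamic <- isTRUE(dynamic)
  structure(p, class = "tumor_geometry")
}

#' Tumor-growth (PD) model parameters
#'
#' Exponential tumor growth with three parallel kill terms driven by the
#' tumor-compartment concentrations of free drug (saturable), NP-bound drug
#' (saturable) and MSC-associated drug (linear). Growth rate, baseline
#' bioluminescence and residual-error CV are arm-specific; a single
#' log-normal between-subject variability term acts on the baseline.
#'
#' Arms are named `control`, `ptx`, `np` and `msc` throughout the package.
#'
#' @param Kg0 named numeric vector of first-order growth rate constants
#'   (1/h), one per arm.
#' @param TVBL named numeric vector of baseline tumor bioluminescence
#'   (10^6 photon/s), one per arm.
#' @param Kmax_PTX maximal kill rate induced by free drug (1/h).
#' @param Kmax_NP maximal kill rate induced by NP-bound drug (1/h).
#' @param K_MSC linear kill coefficient for MSC-associated drug
#'   (1/(h*(ng/mL))).
#' @param IC50_PTX free-drug tumor concentration at half-maximal kill (ng/mL).
#' @param IC50_NP NP-bound tumor concentration at half-maximal kill (ng/mL).
#' @param omega_TVBL between-subject standard deviation of the baseline on
#'   the log scale.
#' @param sigma named numeric vector of proportional residual-error CVs,
#'   one per arm.
#' @return An object of class `pd_params`.
#' @export
pd_params <- function(Kg0, TVBL, Kmax_PTX, Kmax_NP, K_MSC,
                      IC50_PTX, IC50_NP, omega_TVBL, sigma) {
  arms <- c("control", "ptx", "np", "msc")
  for (v in list(Kg0 = Kg0, TVBL = TVBL, sigma = sigma)) {
    if (!all(arms %in% names(v)))
      stop("pd_params: Kg0, TVBL and sigma must be named vectors covering arms ",
           paste(arms, collapse = ", "))
  }
  scalars <- list(Kmax_PTX = Kmax_PTX, Kmax_NP = Kmax_NP, K_MSC = K_MSC,
                  IC50_PTX = IC50_PTX, IC50_NP = IC50_NP)
  for (nm in names(scalars)) {
    v <- scalars[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("pd_params: '", nm, "' must be a single positive finite number")
  }
  if (any(Kg0 <= 0) || any(TVBL <= 0)) stop("pd_params: Kg0 and TVBL must be positive")
  if (omega_TVBL < 0 || any(sigma < 0)) stop("pd_params: omega and sigma must be >= 0")
  structure(list(Kg0 = Kg0[arms], TVBL = TVBL[arms], Kmax_PTX = Kmax_PTX,
                 Kmax_NP = Kmax_NP, K_MSC = K_MSC, IC50_PTX = IC50_PTX,
                 IC50_NP = IC50_NP, omega_TVBL = omega_TVBL,
                 sigma = sigma[arms]), class = "pd_params")
}

#' Bioluminescence-to-volume power calibration
#'
#' `VT = a * TV^b` maps tumor bioluminescence `TV` (10^6 photon/s) to tumor
#' volume `VT` (mL); a power function keeps the predicted volume strictly
#' positive for any positive burden.
#'
#' @param a scale (mL per (10^6 photon/s)^b), positive.
#' @param b exponent (unitless).
#' @return An object of class `bl_calibration`.
#' @export
bl_calibration <- function(a, b) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("bl_calibration: a must be a single positive number")
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b))
    stop("bl_calibration: b must be a single finite number")
  structure(list(a = a, b = b), class = "bl_calibration")
}

#' Built-in parameter set for the nano-MSC study
#'
#' The canonical parameter set of the modeled 2021 nano-MSC study in the
#' orthotopic A549 lung-tumor mouse: literature-derived exchange constants,
#' the in-vitro-derived release and exocytosis rate constants, the reported
#' PK estimates for all three layers, and the reported PD estimates with
#' their residual-error and between-subject-variability terms. Units are
#' ng, mL, h, and 10^6 photon/s.
#'
#' The bioluminescence calibration exponents (`cal`) were never reported
#' numerically; the defaults here are the package's own choice, pinned by
#' two consistency requirements: a volume near the 0.3 mL static-PK
#' assumption at early (baseline-scale) burdens, and a mouse-plausible
#' (~1 mL) volume at endpoint burdens. Both are met by a flat power
#' relation (`a = 0.4`, `b = 0.25`); it can be overridden.
#'
#' @param ... named overrides replacing any top-level element
#'   (e.g. `cal = bl_calibration(0.1, 0.8)`, `body_weight = 0.025`).
#' @return A list with elements `ptx`, `np`, `msc` (layer parameters),
#'   `transfer`, `geometry`, `pd`, `cal`, `sigma_pk` (arm x tissue matrix of
#'   proportional residual CVs for the PK studies), `body_weight` (kg) and
#'   `msc_dose_ug_per_1e6` (PTX-equivalent micrograms per 10^6 MSCs).
#' @export
nanomsc_params <- function(...) {
  sigma_pk <- matrix(c(1.16, 0.649,
                       0.812, 0.545,
                       0.873, 0.581),
                     nrow = 3, byrow = TRUE,
                     dimnames = list(c("ptx", "np", "msc"), c("plasma", "lung")))
  base <- list(
    ptx = sm_layer_params(CL = 0.909, CLD = 0.336, Vc = 6.64, Vp = 18.5,
                          fu = 0.0237, P = 0.0875, D = 0.01, E = 0.44),
    np = sm_layer_params(CL = 0.241, CLD = 0.0627, Vc = 1.32, Vp = 43.2,
                         fu = 0.00302, P = 0.00035, D = 3.6e-6, E = 0.055),
    msc = msc_layer_params(Kct = 1.45, Kcp = 10.2, Vc = 7.15e-8, Vp = 15021),
    transfer = transfer_params(Krel = 0.0085, Kexo = 0.081, loading = 0.148),
    geometry = tumor_geometry(VT = 0.3, Rtumor = 0.42),
    pd = pd_params(
      Kg0 = c(control = 0.00339, ptx = 0.00372, np = 0.00417, msc = 0.00588),
      TVBL = c(control = 0.360, ptx = 0.376, np = 0.539, msc = 0.227),
      Kmax_PTX = 0.00343, Kmax_NP = 0.000427, K_MSC = 4.35e-6,
      IC50_PTX = 1.5, IC50_NP = 5.7,
      omega_TVBL = 0.964,
      sigma = c(control = 0.493, ptx = 0.668, np = 0.624, msc = 0.622)),
    cal = bl_calibration(a = 0.4, b = 0.25),
    sigma_pk = sigma_pk,
    body_weight = 0.02,
    msc_dose_ug_per_1e6 = 25)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(base))
    if (length(bad)) stop("nanomsc_params: unknown element(s): ",
                          paste(bad, collapse = ", "))
    base[names(dots)] <- dots
  }
  base
}

# Flat symbol names used for serialized parameter tables; these are the
# conventional symbols of the study's parameter tables.
.flat_map <- list(
  ptx = c(CL = "CL_PTX", CLD = "CLD_PTX", Vc = "V_PTXcentral",
          Vp = "V_PTXperipheral", fu = "f_uPTX", P = "P_PTX", D = "D_PTX",
          E = "E_PTX"),
  np = c(CL = "CL_NP", CLD = "CLD_NP", Vc = "V_NPcentral",
         Vp = "V_NPperipheral", fu = "f_uNP", P = "P_NP", D = "D_NP",
         E = "E_NP"),
  msc = c(Kct = "K_ct", Kcp = "K_cp", Vc = "V_MSCcentral",
          Vp = "V_MSCperipheral"),
  transfer = c(Krel = "K_rel", Kexo = "K_exo", loading = "PTX_loading"),
  geometry = c(VT = "VT", Rtumor = "R_tumor", Rcap = "R_cap",
               RKrogh = "R_krogh"))

#' Flatten a parameter set to conventional symbol names
#'
#' Serializes the PK side of a parameter set as a flat key-to-value numeric
#' vector using the conventional symbol names (`CL_PTX`, `V_NPcentral`,
#' `K_ct`, ...), suitable for writing as JSON or two-column text.
#'
#' @param params a parameter set as returned by [nanomsc_params()].
#' @return Named numeric vector.
#' @seealso [write_param_set()], [read_param_set()]
#' @export
flatten_params <- function(params) {
  out <- numeric(0)
  for (blk in names(.flat_map)) {
    map <- .flat_map[[blk]]
    v <- unlist(params[[blk]][names(map)])
    names(v) <- unname(map)
    out <- c(out, v)
  }
  out
}

#' Rebuild a parameter set from flat symbol names
#'
#' Inverse of [flatten_params()]: keys present in `flat` override the
#' corresponding entries of `base` (default [nanomsc_params()]).
#'
#' @param flat named numeric vector with conventional symbol names.
#' @param base parameter set supplying any keys not present in `flat`.
#' @return A full parameter set list.
#' @export
unflatten_params <- function(flat, base = nanomsc_params()) {
  known <- unlist(lapply(.flat_map, unname))
  bad <- setdiff(names(flat), known)
  if (length(bad)) stop("unflatten_params: unknown key(s): ",
                        paste(bad, collapse = ", "))
  for (blk in names(.flat_map)) {
    map <- .flat_map[[blk]]
    cur <- unclass(base[[blk]])
    for (fld in names(map)) {
      if (map[[fld]] %in% names(flat)) cur[[fld]] <- unname(flat[[map[[fld]]]])
    }
    base[[blk]] <- do.call(switch(blk,
                                  ptx = sm_layer_params, np = sm_layer_params,
                                  msc = msc_layer_params,
                                  transfer = transfer_params,
                                  geometry = function(VT, Rtumor, Rcap, RKrogh, dynamic = FALSE)
                                    tumor_geometry(VT, Rtumor, Rcap, RKrogh, dynamic)),
                           cur[names(map)])
  }
  base
}

#' Write / read a flat parameter table as JSON
#'
#' @param params parameter set (written) or path (read).
#' @param path file path.
#' @return `read_param_set` returns a named numeric vector.
#' @export
write_param_set <- function(params, path) {
  jsonlite::write_json(as.list(flatten_params(params)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_param_set
#' @export
read_param_set <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  unlist(v)
}
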