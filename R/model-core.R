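#' @useDynLib nanomsc, .registration = TRUE
#' @importFrom stats approx coef dnorm integrate lm median nlminb optim
#'   optimHess optimize pnorm qnorm quantile residuals rlnorm rnorm runif sd
#'   setNames var vcov
#' @importFrom utils head read.csv tail write.csv
"_PACKAGE"

# canonical state ordering used everywhere (amounts in ng PTX-equivalent)
.pk_state_names <- c("A_PTXcentral", "A_PTXtumor", "A_PTXperipheral",
                     "A_NPcentral", "A_NPtumor", "A_NPperipheral",
                     "A_MSCcentral", "A_MSCtumor", "A_MSCperipheral")

#' Net tumor exchange flux for a small-molecule layer
#'
#' Parallel vascular exchange (capillary permeation, scaled by the
#' capillary radius and the Krogh inter-capillary distance) and surface
#' exchange (diffusion across the tumor surface, scaled by the tumor
#' radius) between the central compartment and the tumor compartment:
#'
#' `flux = (2*P*Rcap/RKrogh^2 + 6*D/Rtumor^2) * VT * (Cc*E - Ct)`
#'
#' Positive flux moves drug into the tumor.
#'
#' @param Cc source (central) concentration, ng/mL.
#' @param Ct tumor concentration, ng/mL.
#' @param layer an [sm_layer_params()] object (supplies `P`, `D`, `E`).
#' @param geom a [tumor_geometry()] object.
#' @return Net flux in ng/h.
#' @export
tumor_exchange_flux <- function(Cc, Ct, layer, geom) {
  if (!all(is.finite(c(Cc, Ct)))) stop("tumor_exchange_flux: non-finite concentration")
  if (geom$Rtumor <= 0 || geom$RKrogh <= 0)
    stop("tumor_exchange_flux: Rtumor and RKrogh must be positive")
  k <- 2 * layer$P * geom$Rcap / geom$RKrogh^2 + 6 * layer$D / geom$Rtumor^2
  k * geom$VT * (Cc * layer$E - Ct)
}

#' Right-hand side of the free-drug (bottom layer) PK model
#'
#' Three-compartment model: central/peripheral distribution `CLD*(Cp-Cc)`,
#' linear elimination `CL*Cc` from the central compartment only, and tumor
#' uptake via [tumor_exchange_flux()].
#'
#' @param state named or ordered numeric vector `(A_central, A_tumor,
#'   A_peripheral)`, ng.
#' @param p an [sm_layer_params()] object.
#' @param geom a [tumor_geometry()] object.
#' @return Numeric vector of derivatives, ng/h.
#' @export
rhs_ptx_solution <- function(state, p, geom) {
  if (length(state) != 3L) stop("rhs_ptx_solution: state must have 3 compartments")
  Cc <- state[[1L]] / p$Vc
  Ct <- state[[2L]] / geom$VT
  fx <- tumor_exchange_flux(Cc, Ct, p, geom)
  dist <- p$CLD * (state[[3L]] / p$Vp - Cc)
  c(dist - p$CL * Cc - fx,
    fx,
    -dist)
}

#' Right-hand side of the NP + free-drug (middle layer) PK model
#'
#' Two stacked three-compartment layers. The NP layer has its own
#' disposition parameters and loses drug by first-order release
#' (`Krel * A`) from every compartment; each released amount appears in the
#' matching free-drug compartment.
#'
#' @param state numeric vector of 6 amounts, ordered free drug (central,
#'   tumor, peripheral) then NP (central, tumor, peripheral), ng.
#' @param pNP,pPTX [sm_layer_params()] for the NP and free-drug layers.
#' @param tr a [transfer_params()] object (supplies `Krel`).
#' @param geom a [tumor_geometry()] object.
#' @return Numeric vector of 6 derivatives, ng/h.
#' @export
rhs_ptx_plga <- function(state, pNP, pPTX, tr, geom) {
  if (length(state) != 6L) stop("rhs_ptx_plga: state must have 6 compartments")
  sP <- state[1:3]; sN <- state[4:6]
  dN <- rhs_ptx_solution(sN, pNP, geom) - tr$Krel * sN
  dP <- rhs_ptx_solution(sP, pPTX, geom) + tr$Krel * sN
  c(dP, dN)
}

#' Right-hand side of the full nano-MSC (top layer) PK model
#'
#' Adds the MSC carrier layer on top of the NP + free-drug system. The MSC
#' central compartment loses mass by two unidirectional extravasation
#' processes (`Kct` to tumor, `Kcp` to peripheral); every MSC compartment
#' additionally loses `Kexo * A` (nanoparticle exocytosis, feeding the
#' matching NP compartment) and `Krel * A` (drug release, feeding the
#' matching free-drug compartment).
#'
#' @param state numeric vector of 9 amounts ordered free drug, NP, MSC
#'   (each central, tumor, peripheral), ng.
#' @param pNP,pPTX [sm_layer_params()] for the NP and free-drug layers.
#' @param m an [msc_layer_params()] object.
#' @param tr a [transfer_params()] object.
#' @param geom a [tumor_geometry()] object.
#' @return Numeric vector of 9 derivatives, ng/h.
#' @export
rhs_nanomsc <- function(state, pNP, pPTX, m, tr, geom) {
  if (length(state) != 9L) stop("rhs_nanomsc: state must have 9 compartments")
  sP <- state[1:3]; sN <- state[4:6]; sM <- state[7:9]
  dM <- c(-(m$Kct + m$Kcp) * sM[1L], m$Kct * sM[1L], m$Kcp * sM[1L]) -
    (tr$Krel + tr$Kexo) * sM
  dN <- rhs_ptx_solution(sN, pNP, geom) - tr$Krel * sN + tr$Kexo * sM
  dP <- rhs_ptx_solution(sP, pPTX, geom) + tr$Krel * sN + tr$Krel * sM
  c(dP, dN, dM)
}

#' Tumor-kill rates from tumor-compartment concentrations
#'
#' Saturable (Emax-type) kill for free and NP-bound drug,
#' `Kmax * C / (IC50 + C)`, and linear unsaturable kill `K_MSC * C` for
#' MSC-associated drug.
#'
#' @param C_PTX,C_NP,C_MSC tumor-compartment concentrations (ng/mL) of the
#'   three drug forms.
#' @param pd a [pd_params()] object.
#' @return Named numeric vector `c(ptx =, np =, msc =)` of kill rates, 1/h.
#' @export
kill_rates <- function(C_PTX, C_NP, C_MSC, pd) {
  if (any(c(C_PTX, C_NP, C_MSC) < 0)) stop("kill_rates: negative concentration")
  c(ptx = pd$Kmax_PTX * C_PTX / (pd$IC50_PTX + C_PTX),
    np = pd$Kmax_NP * C_NP / (pd$IC50_NP + C_NP),
    msc = pd$K_MSC * C_MSC)
}

#' Tumor volume from bioluminescence
#'
#' Power calibration `VT = a * TV^b`; strictly positive for all positive
#' burdens, which is the reason a power function is used.
#'
#' @param TV tumor bioluminescence, 10^6 photon/s (> 0; vectorized).
#' @param cal a [bl_calibration()] object.
#' @return Tumor volume, mL.
#' @export
volume_from_bioluminescence <- function(TV, cal) {
  if (any(TV <= 0)) stop("volume_from_bioluminescence: TV must be positive")
  cal$a * TV^cal$b
}

#' Tumor radius from volume (sphere assumption)
#'
#' @param VT tumor volume, mL (> 0; vectorized).
#' @return Radius `(3*VT/(4*pi))^(1/3)`, cm.
#' @export
radius_from_volume <- function(VT) {
  if (any(VT <= 0)) stop("radius_from_volume: VT must be positive")
  (3 * VT / (4 * pi))^(1 / 3)
}

#' Observed (measured) plasma PTX concentration
#'
#' Sums the central-compartment concentrations of the layers present in an
#' arm. The free-drug and NP central concentrations are multiplied by their
#' plasma-to-blood ratios `fu`; the MSC layer carries no such ratio and
#' contributes `A/Vc` directly.
#'
#' @param state numeric vector of 9 amounts in canonical order (shorter
#'   vectors are zero-padded on the right), ng.
#' @param pPTX,pNP [sm_layer_params()]; `m` an [msc_layer_params()].
#' @param m MSC layer parameters.
#' @param arm one of `"ptx"`, `"np"`, `"msc"`: which layers physically
#'   exist for the administered formulation.
#' @return Total measured plasma concentration, ng/mL.
#' @export
observed_plasma_concentration <- function(state, pPTX, pNP, m,
                                          arm = c("msc", "np", "ptx")) {
  arm <- match.arg(arm)
  state <- c(state, numeric(9L - length(state)))
  out <- pPTX$fu * state[1L] / pPTX$Vc
  if (arm %in% c("np", "msc")) out <- out + pNP$fu * state[4L] / pNP$Vc
  if (arm == "msc") out <- out + state[7L] / m$Vc
  out
}

#' Observed (measured) lung PTX concentration
#'
#' The tumor compartment represents the tumor-bearing lungs; the measured
#' lung concentration is the total tumor-compartment amount over the tumor
#' volume.
#'
#' @param state numeric vector of 9 amounts in canonical order (shorter
#'   vectors are zero-padded), ng.
#' @param geom a [tumor_geometry()] object.
#' @return Total lung concentration, ng/mL.
#' @export
observed_lung_concentration <- function(state, geom) {
  if (geom$VT <= 0) stop("observed_lung_concentration: VT must be positive")
  state <- c(state, numeric(9L - length(state)))
  (state[2L] + state[5L] + state[8L]) / geom$VT
}

#' Rate matrix of the (static-geometry) linear PK system
#'
#' With static tumor geometry all three PK layer models are linear
#' time-invariant systems, `dA/dt = M A`. This builds the 3-, 6- or
#' 9-state rate matrix for the requested model, in the canonical state
#' ordering; trajectories then follow from the matrix exponential
#' (see [solve_pk_linear()]).
#'
#' @param model `"ptx"` (3 states), `"np"` (6 states) or `"msc"` (9
#'   states).
#' @param params full parameter set, see [nanomsc_params()].
#' @return Square numeric matrix with dimnames in canonical state order.
#' @export
pk_rate_matrix <- function(model = c("msc", "np", "ptx"), params) {
  model <- match.arg(model)
  g <- params$geometry
  blk <- function(p) {
    ex <- (2 * p$P * g$Rcap / g$RKrogh^2 + 6 * p$D / g$Rtumor^2) * g$VT
    matrix(c(-p$CL / p$Vc - p$CLD / p$Vc - ex * p$E / p$Vc, ex / g$VT, p$CLD / p$Vp,
             ex * p$E / p$Vc, -ex / g$VT, 0,
             p$CLD / p$Vc, 0, -p$CLD / p$Vp),
           nrow = 3, byrow = TRUE)
  }
  n <- switch(model, ptx = 3L, np = 6L, msc = 9L)
  M <- matrix(0, n, n)
  M[1:3, 1:3] <- blk(params$ptx)
  if (n >= 6L) {
    Krel <- params$transfer$Krel
    M[4:6, 4:6] <- blk(params$np) - diag(Krel, 3)
    M[1:3, 4:6] <- M[1:3, 4:6] + diag(Krel, 3)
  }
  if (n == 9L) {
    m <- params$msc; tr <- params$transfer
    Mm <- -diag(tr$Krel + tr$Kexo, 3)
    Mm[1, 1] <- Mm[1, 1] - (m$Kct + m$Kcp)
    Mm[2, 1] <- m$Kct
    Mm[3, 1] <- m$Kcp
    M[7:9, 7:9] <- Mm
    M[4:6, 7:9] <- M[4:6, 7:9] + diag(tr$Kexo, 3)
    M[1:3, 7:9] <- M[1:3, 7:9] + diag(tr$Krel, 3)
  }
  dimnames(M) <- list(.pk_state_names[1:n], .pk_state_names[1:n])
  M
}
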