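# In-vitro calibration fits: first-order association (drug release from
# PLGA NPs), first-order decay (NP exocytosis from MSCs), and the log-log
# power calibration relating tumor bioluminescence to tumor volume.
# Rate constants are fitted on the log scale with starting values from a
# log-linear regression, which is robust on the 5-8-point datasets these
# calibrations come from.

.r_squared <- function(y, fitted) {
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(if (ss_res == 0) 1 else NA_real_)
  1 - ss_res / ss_tot
}

#' Fit a first-order association model to cumulative release data
#'
#' Least-squares fit of `y(t) = plateau * (1 - exp(-Krel * t))` to
#' cumulative percent-released time courses, as used to derive the drug
#' release rate constant from in-vitro nanoparticle release studies.
#'
#' @param times sampling times, h (>= 0).
#' @param release cumulative release, percent of load (0-100 scale).
#' @return List with `plateau`, `Krel` (1/h), `r_squared`, `fitted`.
#' @export
fit_first_order_association <- function(times, release) {
  if (length(times) < 3L) stop("fit_first_order_association: need >= 3 points")
  if (any(times < 0)) stop("fit_first_order_association: negative times")
  # assay noise can push cumulative release somewhat past 100%
  if (any(release < 0 | release > 150))
    stop("fit_first_order_association: release must be within [0, 150]")
  # log-linear start: log(1 - y/plateau0) = -K t with plateau0 slightly
  # above the maximum observed value
  p0 <- max(release) * 1.05 + 1e-6
  pos <- times > 0 & release < p0
  k0 <- max(1e-6, mean(-log(pmax(1e-12, 1 - release[pos] / p0)) / times[pos]))
  df <- data.frame(t = times, y = release)
  fit <- minpack.lm::nlsLM(y ~ plateau * (1 - exp(-exp(lk) * t)), data = df,
                           start = list(plateau = p0, lk = log(k0)),
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!fit$convInfo$isConv) stop("fit_first_order_association: no convergence")
  cf <- coef(fit)
  fitted <- cf[["plateau"]] * (1 - exp(-exp(cf[["lk"]]) * times))
  list(plateau = cf[["plateau"]], Krel = exp(cf[["lk"]]),
       r_squared = .r_squared(release, fitted), fitted = fitted)
}

#' Fit a first-order decay model to retention data
#'
#' Least-squares fit of `y(t) = y0 * exp(-Kexo * t)` to percent-retained
#' time courses, as used to derive the nanoparticle exocytosis rate
#' constant (on an NP-mass basis) from in-vitro exocytosis studies.
#'
#' @param times sampling times, h (>= 0).
#' @param retained retained fraction, percent of initial.
#' @return List with `y0`, `Kexo` (1/h, NP-mass basis), `r_squared`,
#'   `fitted`.
#' @export
fit_first_order_decay <- function(times, retained) {
  if (length(times) < 3L) stop("fit_first_order_decay: need >= 3 points")
  if (any(times < 0)) stop("fit_first_order_decay: negative times")
  if (any(retained <= 0)) stop("fit_first_order_decay: retained values must be > 0")
  ll <- lm(log(retained) ~ times)
  k0 <- max(1e-6, -coef(ll)[[2L]])
  y00 <- exp(coef(ll)[[1L]])
  df <- data.frame(t = times, y = retained)
  fit <- minpack.lm::nlsLM(y ~ y0 * exp(-exp(lk) * t), data = df,
                           start = list(y0 = y00, lk = log(k0)),
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!fit$convInfo$isConv) stop("fit_first_order_decay: no convergence")
  cf <- coef(fit)
  fitted <- cf[["y0"]] * exp(-exp(cf[["lk"]]) * times)
  list(y0 = cf[["y0"]], Kexo = exp(cf[["lk"]]),
       r_squared = .r_squared(retained, fitted), fitted = fitted)
}

#' Rescale the exocytosis rate constant to a drug-mass basis
#'
#' The exocytosis constant is estimated from nanoparticle-mass retention
#' but the PK model tracks PTX mass, so the NP-mass constant is multiplied
#' by the drug loading (mg PTX per mg NP).
#'
#' @param Kexo_NPmass exocytosis rate constant on an NP-mass basis, 1/h.
#' @param loading drug loading, mg PTX per mg NP.
#' @return Rate constant on a PTX-mass basis, 1/h (unrounded).
#' @examples
#' mass_scale_kexo(0.56, 0.148)  # 0.08288 -> reported as 0.083
#' @export
mass_scale_kexo <- function(Kexo_NPmass, loading) {
  if (Kexo_NPmass <= 0 || loading <= 0)
    stop("mass_scale_kexo: inputs must be positive")
  Kexo_NPmass * loading
}

#' Fit the bioluminescence-to-volume power calibration
#'
#' Ordinary least squares on `log(VT) ~ log(TV)` (the spreadsheet power
#' trendline procedure), after converting tumor weight to volume at an
#' assumed tissue density of 1 g/mL.
#'
#' @param TV tumor bioluminescence, 10^6 photon/s.
#' @param weight tumor weight, g.
#' @return List with `cal` (a [bl_calibration()]), `r_squared` (on the
#'   log-log scale) and the underlying `lm` fit.
#' @export
fit_power_calibration <- function(TV, weight) {
  if (length(TV) < 3L) stop("fit_power_calibration: need >= 3 pairs")
  if (any(TV <= 0) || any(weight <= 0))
    stop("fit_power_calibration: all pairs must be positive")
  VT <- weight / 1  # 1 g/mL tissue density
  fit <- lm(log(VT) ~ log(TV))
  cf <- coef(fit)
  # R^2 assembled directly: summary.lm() warns on exact power-law data
  list(cal = bl_calibration(a = exp(cf[[1L]]), b = cf[[2L]]),
       r_squared = .r_squared(log(VT), fitted(fit)), fit = fit)
}
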