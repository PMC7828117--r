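# Trajectory solvers. Two routes are provided on purpose:
#  * solve_pk_linear(): with static geometry every PK layer model is a
#    linear time-invariant system, so trajectories follow exactly from the
#    matrix exponential of the rate matrix. This is the estimation hot
#    path (naive-pooled PK fits) and carries no truncation error.
#  * solve_pkpd_ode(): the general route through deSolve's lsoda with the
#    compiled right-hand side; required for the coupled PD system, whose
#    dynamic tumor geometry makes it nonlinear, and usable for any PK
#    simulation. The system is stiff (the MSC plasma phase has a ~0.06 h
#    half-life and the free-drug tumor exchange equilibrates on the
#    ~1/2000 h scale, against release half-lives of ~80 h), hence the
#    stiff-capable solver and tight default tolerances.

.layer_state <- c(free = 1L, np = 4L, msc = 7L)

.pack_parms <- function(params, dynamic = FALSE, pd = NULL, arm = NULL,
                        tv_floor = 1e-6) {
  p <- params
  v <- c(p$ptx$CL, p$ptx$CLD, p$ptx$Vc, p$ptx$Vp, p$ptx$E, p$ptx$P, p$ptx$D,
         p$np$CL, p$np$CLD, p$np$Vc, p$np$Vp, p$np$E, p$np$P, p$np$D,
         p$transfer$Krel, p$transfer$Kexo, p$msc$Kct, p$msc$Kcp,
         p$geometry$VT, p$geometry$Rtumor, p$geometry$Rcap, p$geometry$RKrogh,
         as.numeric(dynamic), p$cal$a, p$cal$b, tv_floor)
  if (is.null(pd)) {
    v <- c(v, 0, 0, 1, 0, 1, 0, 0)
  } else {
    v <- c(v, pd$Kg0[[arm]], pd$Kmax_PTX, pd$IC50_PTX, pd$Kmax_NP,
           pd$IC50_NP, pd$K_MSC, 1)
  }
  v
}

#' Integrate the PK or coupled PK-PD system (general ODE route)
#'
#' Integrates the full 11-state system (9 PK amounts, tumor burden TV, and
#' a cumulative eliminated-mass accumulator) with `deSolve::lsoda` and the
#' package's compiled right-hand side. Doses are instantaneous boluses
#' added to the target layer's central compartment at their event times.
#'
#' @param params full parameter set, see [nanomsc_params()].
#' @param doses a [regimen()] or data frame with columns `time`, `amount`,
#'   `layer`, or `NULL` for a dose-free system.
#' @param times strictly increasing output times, h.
#' @param dynamic logical; recompute tumor geometry from TV through the
#'   power calibration at every evaluation (PD configuration).
#' @param pd a [pd_params()] object to activate the tumor-growth equation,
#'   or `NULL` to freeze TV.
#' @param arm arm label selecting `Kg0` when `pd` is given.
#' @param TV0 initial tumor burden (10^6 photon/s); required when `pd` or
#'   `dynamic` is used.
#' @param rtol,atol solver tolerances.
#' @param tv_floor lower guard on TV inside the geometry calibration.
#' @return Data frame: `time`, the nine amounts (canonical names), `TV`,
#'   `A_eliminated`, `VT`.
#' @export
solve_pkpd_ode <- function(params, doses, times, dynamic = FALSE, pd = NULL,
                           arm = NULL, TV0 = NA_real_, rtol = 1e-8,
                           atol = 1e-10, tv_floor = 1e-6) {
  if (is.unsorted(times, strictly = TRUE)) stop("solve_pkpd_ode: times must be strictly increasing")
  if ((dynamic || !is.null(pd)) && !is.finite(TV0))
    stop("solve_pkpd_ode: TV0 required for a dynamic/PD run")
  y <- c(numeric(9L), if (is.finite(TV0)) TV0 else 1, 0)
  names(y) <- c(.pk_state_names, "TV", "A_eliminated")
  evd <- NULL
  if (!is.null(doses) && nrow(doses) > 0L) {
    # integration always starts at t = 0: only doses at t <= 0 are initial
    # conditions, every later dose is an event
    at0 <- doses$time <= 0
    for (i in which(at0)) {
      j <- .layer_state[[doses$layer[i]]]
      y[j] <- y[j] + doses$amount[i]
    }
    late <- doses[!at0, , drop = FALSE]
    if (nrow(late) > 0L) {
      evd <- data.frame(var = .pk_state_names[.layer_state[late$layer]],
                        time = late$time, value = late$amount, method = "add")
    }
  }
  tt <- sort(unique(c(0, times, evd$time)))
  out <- deSolve::lsoda(y, tt, func = "nanomsc_derivs", parms =
                          .pack_parms(params, dynamic, pd, arm, tv_floor),
                        dllname = "nanomsc", initfunc = "nanomsc_init",
                        nout = 1L, outnames = "VT", rtol = rtol, atol = atol,
                        maxsteps = 50000,
                        events = if (is.null(evd)) NULL else list(data = evd))
  out <- as.data.frame(out)
  out <- out[out$time %in% times, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# matrix-exponential propagation: x(t) = expm(M t) x0 for several t,
# through the eigenbasis when it is well conditioned, else Matrix::expm
.expm_traj <- function(M, x0, times) {
  n <- length(x0)
  e <- tryCatch(eigen(M), error = function(e) NULL)
  if (!is.null(e)) {
    co <- tryCatch(solve(e$vectors, x0 + 0i), error = function(er) NULL)
    if (!is.null(co) &&
        max(abs(Re(as.vector(e$vectors %*% co)) - x0)) <=
          1e-9 * (1 + max(abs(x0)))) {
      X <- vapply(times, function(t)
        if (t == 0) x0
        else Re(as.vector(e$vectors %*% (exp(e$values * t) * co))),
        numeric(n))
      return(t(matrix(X, nrow = n)))
    }
  }
  t(vapply(times, function(t)
    as.vector(as.matrix(Matrix::expm(M * t)) %*% x0), numeric(n)))
}

#' Exact trajectories of the static-geometry (linear) PK system
#'
#' Propagates the linear PK system through the matrix exponential of its
#' rate matrix ([pk_rate_matrix()]), handling multi-dose regimens by
#' piecewise propagation between dose events. Exact up to linear-algebra
#' round-off; no ODE truncation error.
#'
#' @param model `"ptx"`, `"np"` or `"msc"` (3, 6 or 9 states).
#' @param params full parameter set (static geometry is taken from
#'   `params$geometry`).
#' @param doses a [regimen()] or data frame (`time`, `amount`, `layer`);
#'   layers must exist in the chosen model.
#' @param times output times, h (non-negative, increasing).
#' @return Data frame: `time` plus the model's state amounts.
#' @export
solve_pk_linear <- function(model = c("msc", "np", "ptx"), params, doses,
                            times) {
  model <- match.arg(model)
  n <- switch(model, ptx = 3L, np = 6L, msc = 9L)
  if (any(diff(times) <= 0)) stop("solve_pk_linear: times must be increasing")
  M <- pk_rate_matrix(model, params)
  if (is.null(doses) || nrow(doses) == 0L) stop("solve_pk_linear: empty regimen")
  if (any(.layer_state[doses$layer] > n))
    stop("solve_pk_linear: dose targets a layer absent from model '", model, "'")
  doses <- doses[order(doses$time), , drop = FALSE]
  out <- matrix(NA_real_, length(times), n)
  x <- numeric(n); t0 <- 0
  add_dose <- function(x, i) {
    j <- .layer_state[[doses$layer[i]]]
    x[j] <- x[j] + doses$amount[i]
    x
  }
  # propagation always starts at t = 0; doses at t <= 0 enter the state
  # directly, so a t = 0 output row is post-dose (the initial-condition
  # convention)
  for (i in which(doses$time <= 0)) x <- add_dose(x, i)
  # later events: the event time itself reports the pre-dose state (the
  # convention of the lsoda event handler), the bolus lands just after
  for (te in unique(doses$time[doses$time > 0])) {
    sel <- which(times >= t0 & times <= te & is.na(out[, 1L]))
    if (length(sel)) out[sel, ] <- .expm_traj(M, x, times[sel] - t0)
    x <- .expm_traj(M, x, te - t0)[1L, ]
    for (i in which(doses$time == te)) x <- add_dose(x, i)
    t0 <- te
  }
  sel <- which(is.na(out[, 1L]))
  if (length(sel)) out[sel, ] <- .expm_traj(M, x, times[sel] - t0)
  out <- data.frame(time = times, out)
  names(out) <- c("time", .pk_state_names[1:n])
  out
}

# compile a regimen into the flat structures of the C trajectory walker:
# amounts dosed at t = 0 per state, and later bolus events (0-based state)
.compile_regimen <- function(doses) {
  d0 <- numeric(11L)
  if (is.null(doses) || nrow(doses) == 0L)
    return(list(d0 = d0, t = numeric(0), s = integer(0), a = numeric(0)))
  st <- .layer_state[doses$layer]
  early <- doses$time <= 0
  for (i in which(early)) d0[st[i]] <- d0[st[i]] + doses$amount[i]
  list(d0 = d0, t = doses$time[!early], s = as.integer(st[!early] - 1L),
       a = doses$amount[!early])
}

.etd_solve <- function(pv, y0, creg, times, h, hfine = 0.02, window = 6) {
  res <- .C("nanomsc_etd", as.double(pv), y = as.double(y0),
            as.integer(length(times)), as.double(times),
            as.integer(length(creg$t)), as.double(creg$t),
            as.integer(creg$s), as.double(creg$a), as.double(h),
            as.double(hfine), as.double(window),
            out = double(length(times) * 11L), PACKAGE = "nanomsc")
  matrix(res$out, length(times), 11L)
}

#' Integrate the PK / PK-PD system with the exponential integrator
#'
#' Alternative to [solve_pkpd_ode()] built for the estimation hot path:
#' each compartment balance is scalar-linear given the others, so over a
#' substep the solver applies exact exponential updates with the
#' couplings frozen, refined by a Heun-type corrector. Unconditionally
#' stable on the stiff exchange modes; accuracy is governed by the
#' substep `h` (second order). Doses are state jumps at substep
#' boundaries; like the lsoda route, an output falling on a dose time
#' reports the pre-dose state (doses at `t <= times[1]` are in the
#' initial condition).
#'
#' @inheritParams solve_pkpd_ode
#' @param h largest substep, h (default 0.5).
#' @param hfine,window substep and length (h) of the refined window that
#'   follows each dose event, resolving the fast carrier-to-tumor
#'   build-up.
#' @return Data frame with the same columns as [solve_pkpd_ode()]
#'   (without the auxiliary `VT` column).
#' @export
solve_pkpd_etd <- function(params, doses, times, dynamic = FALSE, pd = NULL,
                           arm = NULL, TV0 = NA_real_, h = 0.5,
                           hfine = 0.02, window = 6, tv_floor = 1e-6) {
  if (is.unsorted(times, strictly = TRUE))
    stop("solve_pkpd_etd: times must be strictly increasing")
  if ((dynamic || !is.null(pd)) && !is.finite(TV0))
    stop("solve_pkpd_etd: TV0 required for a dynamic/PD run")
  creg <- .compile_regimen(doses)
  y0 <- creg$d0
  y0[10L] <- if (is.finite(TV0)) TV0 else 1
  pv <- .pack_parms(params, dynamic, pd, arm, tv_floor)
  out <- .etd_solve(pv, y0, creg, times, h, hfine, window)
  out <- data.frame(time = times, out)
  names(out) <- c("time", .pk_state_names, "TV", "A_eliminated")
  out
}
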