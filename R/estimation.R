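# Naive-pooled maximum-likelihood PK estimation, fitted layer by layer.
#
# The destructive-sampling design yields one observation per animal, so no
# between-subject variability is identifiable and all variability is
# residual: the pooled proportional-error ML here is the exact likelihood
# for that design (a first-order method with no random effects reduces to
# it). Structural parameters and error CVs are estimated jointly on the
# log scale; literature-derived exchange constants and the in-vitro rate
# constants stay fixed.

.seed_guard <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", globalenv())
  on.exit(if (has) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' -2 log-likelihood of a proportional-error model
#'
#' Core pooled objective: `sum(log(2*pi*sigma_i^2*f_i^2) +
#' (y_i-f_i)^2/(sigma_i^2*f_i^2))`, the exact -2LL for observations
#' `y = f*(1+eps)`, `eps ~ N(0, sigma^2)`.
#'
#' @param y observed values (> 0 after the zero-exclusion rule).
#' @param f model predictions (must be > 0).
#' @param sigma proportional error CV per record (recycled).
#' @return The -2 log-likelihood (OFV contribution).
#' @export
nll_proportional <- function(y, f, sigma) {
  if (any(f <= 0)) {
    bad <- which(f <= 0)[1L]
    stop("nll_proportional: nonpositive prediction at record ", bad)
  }
  sigma <- rep_len(sigma, length(y))
  sum(log(2 * pi * sigma^2 * f^2) + (y - f)^2 / (sigma^2 * f^2))
}

# free parameters per PK layer (log scale), in fit order
.pk_free <- list(
  ptx = c("CL", "CLD", "Vc", "Vp", "fu"),
  np = c("CL", "CLD", "Vc", "Vp", "fu"),
  msc = c("Kct", "Kcp", "Vc"))

# insert a named log-scale theta into a parameter set for one layer
.pk_apply_theta <- function(params, layer, theta) {
  fields <- .pk_free[[layer]]
  blk <- unclass(params[[layer]])
  for (fld in fields) blk[[fld]] <- exp(theta[[paste0(layer, ".", fld)]])
  params[[layer]] <- structure(blk, class = class(params[[layer]]))
  params
}

# model predictions for a PK observation table (single-bolus study design)
.pk_predict <- function(data, layer, params, dose_ng = 5000) {
  reg <- regimen_pk_bolus(layer)
  reg$amount <- dose_ng
  tt <- sort(unique(data$TIME))
  if (nrow(reg) == 1L && reg$time[1L] == 0) {
    # single-bolus fast path: one eigendecomposition serves all times
    M <- pk_rate_matrix(layer, params)
    x0 <- numeric(nrow(M))
    x0[.layer_state[[reg$layer[1L]]]] <- reg$amount[1L]
    st <- .expm_traj(M, x0, tt)
  } else {
    sol <- solve_pk_linear(layer, params, reg, tt)
    st <- as.matrix(sol[, -1L, drop = FALSE])
  }
  st <- cbind(st, matrix(0, nrow(st), 9L - ncol(st)))
  fp <- params$ptx$fu * st[, 1L] / params$ptx$Vc
  if (layer %in% c("np", "msc")) fp <- fp + params$np$fu * st[, 4L] / params$np$Vc
  if (layer == "msc") fp <- fp + st[, 7L] / params$msc$Vc
  fl <- (st[, 2L] + st[, 5L] + st[, 8L]) / params$geometry$VT
  idx <- match(data$TIME, tt)
  ifelse(data$TYPE == "plasma", fp[idx], fl[idx])
}

#' Pooled proportional-error OFV for one PK layer
#'
#' Evaluates the naive-pooled -2 log-likelihood of a PK layer's free
#' parameters against a single-bolus destructive-sampling study, with
#' separate proportional error CVs for plasma and lung.
#'
#' @param theta named log-scale parameter vector: the layer's free
#'   structural parameters (named `<layer>.<field>`, e.g. `ptx.CL`) plus
#'   `sigma.plasma` and `sigma.lung`.
#' @param data observation table with columns `TIME`, `TYPE`
#'   (`"plasma"`/`"lung"`), `DV`; uncensored PK records only.
#' @param layer `"ptx"`, `"np"` or `"msc"`.
#' @param params full parameter set supplying everything not in `theta`
#'   (lower-layer estimates, literature constants, geometry).
#' @param dose_ng administered bolus, ng.
#' @return OFV (numeric scalar).
#' @export
nll_pooled_proportional <- function(theta, data, layer, params,
                                    dose_ng = 5000) {
  params <- .pk_apply_theta(params, layer, theta)
  f <- .pk_predict(data, layer, params, dose_ng)
  sig <- ifelse(data$TYPE == "plasma", exp(theta[["sigma.plasma"]]),
                exp(theta[["sigma.lung"]]))
  nll_proportional(data$DV, f, sig)
}

.fit_result <- function(estimates, log_estimates, ofv, cov_log, convergence,
                        fixed, stage, meta = list()) {
  rse <- rep(NA_real_, length(estimates))
  names(rse) <- names(estimates)
  if (!is.null(cov_log)) {
    d <- diag(cov_log)
    ok <- is.finite(d) & d >= 0
    # log-parameterization delta method: SE(p)/p = SD(log p)
    rse[ok] <- 100 * sqrt(d[ok])
  }
  structure(list(estimates = estimates, log_estimates = log_estimates,
                 ofv = ofv, cov_log = cov_log, rse = rse,
                 convergence = convergence, fixed = fixed, stage = stage,
                 meta = meta),
            class = "nanomsc_fit")
}

#' @export
print.nanomsc_fit <- function(x, ...) {
  cat("<nanomsc fit>", x$stage, "\n")
  cat("  OFV:", format(x$ofv, digits = 8), "\n")
  tab <- data.frame(estimate = signif(x$estimates, 4),
                    rse_pct = round(x$rse, 1))
  print(tab)
  if (length(x$fixed))
    cat("  fixed:", paste(names(x$fixed), "<-", x$fixed, collapse = "; "), "\n")
  invisible(x)
}

# multi-start log-scale minimization: jittered restarts guard shallow local
# minima, then a Nelder-Mead polish
.minimize_ml <- function(obj, start, n_starts = 5, jitter_sd = 0.3,
                         seed = 20210112, lower = -Inf, upper = Inf,
                         iter_max = 300, polish = TRUE) {
  starts <- list(start)
  if (n_starts > 1L) {
    jit <- .seed_guard(seed, lapply(seq_len(n_starts - 1L), function(i)
      start + rnorm(length(start), sd = jitter_sd)))
    starts <- c(starts, lapply(jit, function(s) pmin(pmax(s, lower), upper)))
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(nlminb(s, obj, lower = lower, upper = upper,
                           control = list(iter.max = iter_max,
                                          eval.max = 4L * iter_max)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$objective < best$objective))
      best <- fit
  }
  if (is.null(best)) stop("optimization failed from all starting points")
  if (polish) {
    # derivative-free polish; clamp into the box so the bounds survive
    clamp <- function(th) pmin(pmax(th, lower), upper)
    pol <- tryCatch(
      optim(best$par, function(th) obj(clamp(th)), method = "Nelder-Mead",
            control = list(maxit = 400, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(pol) && pol$value < best$objective)
      best <- list(par = clamp(pol$par), objective = pol$value,
                   convergence = pol$convergence,
                   message = "Nelder-Mead polish", iterations = NA)
  }
  best
}

#' Fit one PK layer by naive-pooled maximum likelihood
#'
#' Implements the layer-by-layer workflow: the free-drug (bottom) layer is
#' fitted first; its estimates are then fixed and the NP (middle) layer
#' grafted on and fitted to the NP-arm data; finally the MSC (top) layer is
#' fitted with both lower layers fixed. Literature exchange constants
#' (P, D, E, Rcap, RKrogh) and the in-vitro rate constants (Krel, Kexo)
#' are never estimated.
#'
#' @param data observation table for the layer's arm (columns `TIME`,
#'   `TYPE`, `DV`); zero/negative DVs must already be excluded.
#' @param layer `"ptx"`, `"np"` or `"msc"`.
#' @param params base parameter set (initial values for the free
#'   parameters are taken from it unless `init` is given).
#' @param fixed_lower list of `nanomsc_fit` results for the lower layers,
#'   in order (`list(bottom)` for `"np"`, `list(bottom, middle)` for
#'   `"msc"`); their estimates are fixed into `params`.
#' @param init optional named log-scale start vector.
#' @param dose_ng administered bolus, ng.
#' @param sigma_init starting proportional error CV.
#' @param n_starts number of jittered optimizer starts.
#' @param hessian compute the Hessian-based covariance/RSE.
#' @return A `nanomsc_fit` with layer estimates, the two error CVs, OFV,
#'   covariance, RSE and fixed-parameter provenance.
#' @export
fit_pk_layer <- function(data, layer = c("ptx", "np", "msc"), params,
                         fixed_lower = list(), init = NULL, dose_ng = 5000,
                         sigma_init = 0.5, n_starts = 5, hessian = TRUE) {
  layer <- match.arg(layer)
  need <- switch(layer, ptx = 0L, np = 1L, msc = 2L)
  if (length(fixed_lower) < need)
    stop("fit_pk_layer: layer '", layer, "' requires ", need,
         " lower-layer fit result(s)")
  fixed <- c(P = "literature", D = "literature", E = "literature",
             Rcap = "literature", RKrogh = "literature")
  lower_names <- c("ptx", "np")
  for (k in seq_len(need)) {
    fr <- fixed_lower[[k]]
    if (!inherits(fr, "nanomsc_fit"))
      stop("fit_pk_layer: fixed_lower must contain nanomsc_fit objects")
    lay <- lower_names[k]
    est <- fr$estimates
    sel <- grep(paste0("^", lay, "\\."), names(est), value = TRUE)
    blk <- unclass(params[[lay]])
    for (nm in sel) blk[[sub("^[a-z]+\\.", "", nm)]] <- est[[nm]]
    params[[lay]] <- structure(blk, class = class(params[[lay]]))
    fixed[sel] <- paste0("fit_pk_layer(", lay, ")")
  }
  if (layer %in% c("np", "msc")) fixed["K_rel"] <- "in-vitro fit"
  if (layer == "msc") fixed["K_exo"] <- "in-vitro fit"
  if (any(data$DV <= 0)) stop("fit_pk_layer: exclude nonpositive DVs before fitting")

  fields <- .pk_free[[layer]]
  if (is.null(init)) {
    init <- log(unlist(unclass(params[[layer]])[fields]))
    names(init) <- paste0(layer, ".", fields)
    init <- c(init, sigma.plasma = log(sigma_init), sigma.lung = log(sigma_init))
  }
  lower <- rep(-Inf, length(init))
  lower[grep("^sigma", names(init))] <- log(1e-3)
  obj <- function(th) {
    names(th) <- names(init)
    tryCatch(nll_pooled_proportional(th, data, layer, params, dose_ng),
             error = function(e) 1e10)
  }
  best <- .minimize_ml(obj, init, n_starts = n_starts, lower = lower)
  th <- best$par
  names(th) <- names(init)
  cov_log <- NULL
  if (hessian) {
    H <- tryCatch(optimHess(th, obj), error = function(e) NULL)
    if (!is.null(H)) {
      cv <- tryCatch(2 * solve(H), error = function(e) NULL)  # OFV = -2LL
      if (!is.null(cv)) {
        dimnames(cv) <- list(names(th), names(th))
        cov_log <- cv
      }
    }
  }
  .fit_result(estimates = exp(th), log_estimates = th, ofv = best$objective,
              cov_log = cov_log,
              convergence = list(code = best$convergence,
                                 message = best$message),
              fixed = fixed, stage = paste0("pk-", layer),
              meta = list(n_obs = nrow(data), dose_ng = dose_ng))
}

#' Relative standard errors from a fit's covariance
#'
#' RSE% per parameter from the inverse-Hessian covariance on the log
#' scale (delta method: the SE of `log p` is the relative SE of `p`).
#' Parameters with a non-finite or negative variance (indefinite Hessian)
#' get `NA` rather than failing the whole table.
#'
#' @param fit a `nanomsc_fit`.
#' @return Data frame with `parameter`, `estimate`, `rse_pct`.
#' @export
rse_from_hessian <- function(fit) {
  rse <- rep(NA_real_, length(fit$estimates))
  if (!is.null(fit$cov_log)) {
    d <- diag(fit$cov_log)
    ok <- is.finite(d) & d >= 0
    rse[ok] <- 100 * sqrt(d[ok])
  }
  data.frame(parameter = names(fit$estimates),
             estimate = unname(fit$estimates),
             rse_pct = rse,
             row.names = NULL)
}
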