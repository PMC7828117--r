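# Model-evaluation diagnostics: prediction-corrected visual predictive
# check (pcVPC) and goodness-of-fit summaries. Bins are the nominal
# sampling times (the studies have fixed schedules, so data-driven
# binning would only add noise); simulated replicates reuse the observed
# design including the dropout *rule*, so censoring is endogenous in the
# simulations.

#' Prediction-corrected visual predictive check
#'
#' Simulates `n_sim` replicate studies at the design of the observed data
#' (between-subject variability, residual error, and the tumor-burden
#' dropout rule), prediction-corrects observed and simulated values by
#' `bin-median population prediction / record population prediction`, and
#' returns the observed 10/50/90th percentiles per bin together with
#' simulation-based 95% bands for each percentile, stratified by arm.
#'
#' @param data observed bioluminescence table (uncensored records are
#'   used for the percentiles).
#' @param params fitted parameter set (typical values + omega + sigma).
#' @param regimens named list mapping arm to [regimen()] / `NULL`.
#' @param n_sim number of simulated replicates (>= 100).
#' @param dropout_threshold the design's dropout threshold.
#' @param seed RNG seed.
#' @return List: `observed` (arm, bin, percentile, value), `simulated`
#'   (arm, bin, percentile, lo, mid, hi across replicates).
#' @export
pcvpc <- function(data, params, regimens, n_sim = 200,
                  dropout_threshold = Inf, seed = 1) {
  if (n_sim < 100) stop("pcvpc: n_sim must be >= 100")
  obs <- data[data$CENS == 0L & data$DV > 0, , drop = FALSE]
  arms <- unique(obs$ARM)
  bins <- sort(unique(obs$TIME))
  # population predictions (eta = 0) per arm and bin
  pred <- list()
  for (arm in arms)
    pred[[arm]] <- setNames(
      predict_pd_animal(params, arm, regimens[[arm]], bins, eta = 0), bins)
  pc_correct <- function(df) {
    out <- df
    for (arm in arms) {
      sel <- out$ARM == arm
      p <- pred[[arm]][as.character(out$TIME[sel])]
      if (any(p <= 0)) stop("pcvpc: nonpositive population prediction (arm ",
                            arm, ")")
      binmed <- tapply(p, out$TIME[sel], median)
      out$DV[sel] <- out$DV[sel] * unname(binmed[as.character(out$TIME[sel])]) / p
    }
    out
  }
  probs <- c(0.1, 0.5, 0.9)
  pct <- function(df) {
    res <- list()
    for (arm in arms) {
      sub <- df[df$ARM == arm, ]
      for (b in unique(sub$TIME)) {
        v <- sub$DV[sub$TIME == b]
        res[[length(res) + 1L]] <- data.frame(
          ARM = arm, bin = b, percentile = c("p10", "p50", "p90"),
          value = quantile(v, probs, names = FALSE))
      }
    }
    do.call(rbind, c(res, make.row.names = FALSE))
  }
  obs_pct <- pct(pc_correct(obs))
  # per-arm animal counts of the observed design
  n_by_arm <- vapply(arms, function(a) length(unique(obs$ID[obs$ARM == a])),
                     integer(1))
  sim_pct <- vector("list", n_sim)
  for (s in seq_len(n_sim)) {
    rep_s <- generate_pd_study(params, arms = arms,
                               n_per_arm = max(n_by_arm),
                               schedule = bins,
                               dropout_threshold = dropout_threshold,
                               regimens = regimens, seed = seed + s)
    so <- rep_s$observations
    so <- so[so$DV > 0, , drop = FALSE]
    sp <- pct(pc_correct(so))
    sp$replicate <- s
    sim_pct[[s]] <- sp
  }
  simall <- do.call(rbind, sim_pct)
  key <- interaction(simall$ARM, simall$bin, simall$percentile, drop = TRUE)
  lo <- tapply(simall$value, key, quantile, probs = 0.025, names = FALSE)
  mid <- tapply(simall$value, key, median)
  hi <- tapply(simall$value, key, quantile, probs = 0.975, names = FALSE)
  parts <- do.call(rbind, strsplit(names(lo), ".", fixed = TRUE))
  simulated <- data.frame(ARM = parts[, 1L], bin = as.numeric(parts[, 2L]),
                          percentile = parts[, 3L], lo = as.numeric(lo),
                          mid = as.numeric(mid), hi = as.numeric(hi),
                          row.names = NULL)
  list(observed = obs_pct, simulated = simulated)
}

#' Goodness-of-fit table
#'
#' Per-record population predictions (eta = 0), individual predictions at
#' the empirical Bayes mode, and proportional residuals
#' `(y - f)/(sigma*f)` for continuous records; censored records carry no
#' residual and are flagged.
#'
#' @param data an [apply_modified_m3()]-prepared table.
#' @param fit a `nanomsc_fit` from [fit_pd()] (its `meta` supplies the
#'   fitted parameters, regimens and eta modes).
#' @return Data frame: the input records plus `PRED`, `IPRED`, `RES_PROP`.
#' @export
gof_table <- function(data, fit) {
  params <- fit$meta$params
  regimens <- fit$meta$regimens
  etas <- fit$meta$eta
  out <- data
  out$PRED <- NA_real_; out$IPRED <- NA_real_; out$RES_PROP <- NA_real_
  for (id in unique(data$ID)) {
    sel <- which(out$ID == id)
    arm <- out$ARM[sel[1L]]
    tt <- out$TIME[sel]
    out$PRED[sel] <- predict_pd_animal(params, arm, regimens[[arm]], tt, 0)
    eta <- if (id %in% names(etas)) etas[[id]] else 0
    out$IPRED[sel] <- predict_pd_animal(params, arm, regimens[[arm]], tt, eta)
  }
  cont <- out$CENS == 0L
  sig <- params$pd$sigma[out$ARM[cont]]
  out$RES_PROP[cont] <- (out$DV[cont] - out$IPRED[cont]) /
    (sig * out$IPRED[cont])
  out
}
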