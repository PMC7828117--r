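# Synthetic-study generators. Each generator is a pure function of
# (truth, design, seed) and emits the same long observation format the
# estimation stack consumes, so every stage of the analysis is testable
# end to end without any external data.

.trunc_prop_noise <- function(n, sigma) {
  # proportional noise truncated at -0.999 keeps y = f*(1+eps) positive
  # in the PD generator; PK records falling at/below zero are instead
  # excluded downstream, emulating the zero-concentration exclusion rule
  pmax(rnorm(n, 0, sigma), -0.999)
}

#' Generate a destructive-sampling PK study
#'
#' Emulates the single-dose disposition study: three formulation arms, a
#' fixed sacrifice schedule, `n_per` mice per time point, plasma and lung
#' sampled from each mouse, a single 5 ug IV bolus, and proportional
#' residual error with arm- and tissue-specific CVs. Each record carries a
#' distinct subject ID (one sample per animal). Records at or below the
#' quantification limit are excluded, as zero concentrations were in the
#' original analysis.
#'
#' @param params truth parameter set (including `sigma_pk`).
#' @param arms formulation arms to generate.
#' @param times sacrifice times, h.
#' @param n_per mice per arm x time point.
#' @param dose_ug administered dose, ug.
#' @param loq lower quantification limit (ng/mL); records `<= loq` drop.
#' @param seed RNG seed.
#' @return Observation table (`ID`, `ARM`, `TIME`, `TYPE`, `DV`, `CENS`,
#'   `ULIM`, `AMT`, `EVID`) with attributes `n_generated` (record count
#'   before exclusions) and `truth`.
#' @export
generate_pk_study <- function(params, arms = c("ptx", "np", "msc"),
                              times = c(2, 24, 48, 120, 288), n_per = 3,
                              dose_ug = 5, loq = 0, seed = 1) {
  if (n_per < 1 || !length(times) || any(times < 0))
    stop("generate_pk_study: invalid design")
  dose_ng <- to_ptx_equivalent(dose_ug, "ug")
  rows <- list()
  .seed_guard(seed, {
    for (arm in arms) {
      reg <- regimen_pk_bolus(arm)
      reg$amount <- dose_ng
      prof <- simulate_pk_profiles(arm, params, reg, times = sort(times))
      for (tissue in c("plasma", "lung")) {
        f <- prof[[paste0(tissue, "_total")]][match(times, prof$time)]
        sig <- params$sigma_pk[arm, tissue]
        for (k in seq_along(times)) {
          eps <- rnorm(n_per, 0, sig)
          rows[[length(rows) + 1L]] <- data.frame(
            ID = sprintf("PK_%s_%g_%s_%d", arm, times[k], tissue,
                         seq_len(n_per)),
            ARM = arm, TIME = times[k], TYPE = tissue,
            DV = f[k] * (1 + eps), CENS = 0L, ULIM = NA_real_,
            AMT = NA_real_, EVID = 0L)
        }
      }
    }
  })
  out <- do.call(rbind, rows)
  n_gen <- nrow(out)
  out <- out[out$DV > loq, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_generated") <- n_gen
  attr(out, "truth") <- params
  out
}

#' Generate a tumor-bioluminescence efficacy (PD) study
#'
#' Emulates the four-arm efficacy study: log-normal between-subject
#' variability on the baseline, coupled PK-PD latent trajectories with
#' dynamic tumor geometry, proportional residual error, and tumor-burden
#' driven dropout: an animal dies at the first scheduled visit whose
#' (noisy) measurement would exceed the threshold; that measurement is
#' not recorded -- the animal died carrying a high burden before it could
#' be measured -- and all later visits are missing. Dropout therefore
#' selects against high observed values, which is exactly the
#' treatment-effect-masking mechanism the modified-M3 likelihood is meant
#' to repair.
#'
#' @param params truth parameter set (PD block plus calibration).
#' @param arms arms to generate.
#' @param n_per_arm animals per arm.
#' @param schedule nominal observation times, h.
#' @param dropout_threshold latent-burden dropout threshold
#'   (10^6 photon/s); must exceed every baseline. `Inf` disables dropout.
#' @param regimens named list mapping arm to [regimen()] (or `NULL`).
#' @param seed RNG seed.
#' @return List: `observations` (long table with post-dropout gaps),
#'   `latent` (noise-free trajectories for all scheduled times), `eta`
#'   (named draws), `schedule`, `regimens`.
#' @export
generate_pd_study <- function(params, arms = c("control", "ptx", "np", "msc"),
                              n_per_arm = 8,
                              schedule = seq(0, 1512, by = 84),
                              dropout_threshold = 60, regimens = NULL,
                              seed = 1) {
  if (dropout_threshold <= max(params$pd$TVBL[arms]))
    stop("generate_pd_study: dropout threshold must exceed every baseline")
  if (is.null(regimens))
    regimens <- list(control = NULL, ptx = regimen_efficacy("ptx"),
                     np = regimen_efficacy("np"), msc = regimen_efficacy("msc"))
  omega <- params$pd$omega_TVBL
  obs <- list(); lat <- list(); etas <- numeric(0)
  .seed_guard(seed, {
    for (arm in arms) {
      for (i in seq_len(n_per_arm)) {
        id <- sprintf("PD_%s_%02d", arm, i)
        eta <- rnorm(1, 0, omega)
        etas[id] <- eta
        tv <- predict_pd_animal(params, arm, regimens[[arm]], schedule, eta,
                                rtol = 1e-8, atol = 1e-10)
        lat[[id]] <- data.frame(ID = id, ARM = arm, TIME = schedule, TV = tv)
        eps <- .trunc_prop_noise(length(schedule), params$pd$sigma[[arm]])
        y <- tv * (1 + eps)
        drop_at <- which(y > dropout_threshold)
        keep <- if (length(drop_at)) seq_len(drop_at[1L] - 1L)
                else seq_along(schedule)
        if (!length(keep)) next
        obs[[id]] <- data.frame(
          ID = id, ARM = arm, TIME = schedule[keep], TYPE = "bioluminescence",
          DV = y[keep], CENS = 0L, ULIM = NA_real_,
          AMT = NA_real_, EVID = 0L)
      }
    }
  })
  observations <- do.call(rbind, c(obs, make.row.names = FALSE))
  latent <- do.call(rbind, c(lat, make.row.names = FALSE))
  list(observations = observations, latent = latent, eta = etas,
       schedule = schedule, regimens = regimens,
       dropout_threshold = dropout_threshold)
}

#' Generate in-vitro release and exocytosis time courses
#'
#' Cumulative release `100*(1 - exp(-Krel*t))` and retention
#' `100*exp(-Kexo*t)`, each with proportional noise.
#'
#' @param Krel,Kexo truth rate constants, 1/h (`Kexo` on the NP-mass
#'   basis, as measured in vitro).
#' @param times_release,times_exo sampling times, h.
#' @param cv proportional noise CV.
#' @param seed RNG seed.
#' @return List of two data frames `release` (`time`, `released_pct`) and
#'   `exocytosis` (`time`, `retained_pct`).
#' @export
generate_release_exocytosis_data <- function(Krel = 0.0085, Kexo = 0.56,
                                             times_release = c(4, 24, 72, 168, 336),
                                             times_exo = c(0.5, 1, 2, 4, 8, 24),
                                             cv = 0.1, seed = 1) {
  if (any(c(times_release, times_exo) <= 0) ||
      is.unsorted(times_release) || is.unsorted(times_exo))
    stop("generate_release_exocytosis_data: times must be positive and increasing")
  .seed_guard(seed, {
    rel <- 100 * (1 - exp(-Krel * times_release)) *
      (1 + .trunc_prop_noise(length(times_release), cv))
    ret <- 100 * exp(-Kexo * times_exo) *
      (1 + .trunc_prop_noise(length(times_exo), cv))
    list(release = data.frame(time = times_release, released_pct = rel),
         exocytosis = data.frame(time = times_exo, retained_pct = ret))
  })
}

#' Generate tumor weight / bioluminescence calibration pairs
#'
#' Burdens sampled log-uniformly over `TV_range`; weights follow the
#' power law `a*TV^b` (at 1 g/mL) with proportional noise.
#'
#' @param a,b truth calibration parameters.
#' @param sigma proportional noise CV.
#' @param n number of pairs.
#' @param TV_range bioluminescence range, 10^6 photon/s.
#' @param seed RNG seed.
#' @return Data frame `TV`, `weight_g`.
#' @export
generate_calibration_pairs <- function(a = 0.4, b = 0.25, sigma = 0.2,
                                       n = 8, TV_range = c(0.5, 500),
                                       seed = 1) {
  if (n < 3) stop("generate_calibration_pairs: need n >= 3")
  .seed_guard(seed, {
    TV <- exp(runif(n, log(TV_range[1L]), log(TV_range[2L])))
    w <- a * TV^b * (1 + .trunc_prop_noise(n, sigma))
    data.frame(TV = TV, weight_g = w)
  })
}
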