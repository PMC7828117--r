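make_m3_fixture <- function(arms = c("control", "msc"), n_per_arm = 3,
                            seed = 7, threshold = 60) {
  p <- ref_params()
  st <- generate_pd_study(p, arms = arms, n_per_arm = n_per_arm,
                          dropout_threshold = threshold, seed = seed)
  list(params = p, data = apply_modified_m3(st$observations, st$schedule),
       regimens = st$regimens, schedule = st$schedule, study = st)
}

test_that("modified M3 censors exactly the never-observed scheduled times", {
  fx <- make_m3_fixture(arms = "control", n_per_arm = 5, threshold = 20,
                        seed = 3)
  d <- fx$data
  for (id in unique(d$ID)) {
    rec <- d[d$ID == id, ]
    # the upper limit is that animal's maximum observed value, and the
    # maximum itself stays a continuous record
    expect_equal(rec$ULIM[1], max(rec$DV, na.rm = TRUE))
    expect_equal(sum(rec$CENS == 0 & rec$DV == rec$ULIM), 1)
    # censored rows sit strictly after the last observation and complete
    # the nominal schedule
    if (any(rec$CENS == 1)) {
      tmax <- max(rec$TIME[rec$CENS == 0])
      expect_true(all(rec$TIME[rec$CENS == 1] > tmax))
      expect_setequal(rec$TIME, fx$schedule)
    }
  }
  # no dropout: schedule complete, zero censored records
  fx0 <- make_m3_fixture(arms = "control", n_per_arm = 3, threshold = Inf,
                         seed = 3)
  expect_equal(sum(fx0$data$CENS), 0)
  expect_true(all(is.finite(fx0$data$ULIM)))
  # an animal whose dropout removed 3 scheduled times gains 3 censored rows
  obs <- fx0$data[fx0$data$CENS == 0, ]
  one <- obs[obs$ID == obs$ID[1], ]
  trimmed <- one[one$TIME <= fx$schedule[length(fx$schedule) - 3], ]
  m3 <- apply_modified_m3(trimmed, fx$schedule)
  expect_equal(sum(m3$CENS), 3)
  expect_error(apply_modified_m3(trimmed[0, ], fx$schedule), "no observations")
})

test_that("censored-record contributions equal the exceedance probability", {
  fx <- make_m3_fixture(arms = "control", n_per_arm = 1, threshold = Inf,
                        seed = 5)
  p <- fx$params
  rec <- fx$data[fx$data$ID == fx$data$ID[1], ][1:3, ]
  rec$CENS <- c(0L, 1L, 1L)
  rec$ULIM <- 1.5
  base <- rec
  g <- function(eta) individual_joint_nll(p, rec, NULL, eta)
  # quadrature/closed-form oracle assembled record by record
  eta <- 0.3
  f <- p$pd$TVBL[["control"]] * exp(eta) * exp(p$pd$Kg0[["control"]] * rec$TIME)
  sig <- p$pd$sigma[["control"]]
  om <- p$pd$omega_TVBL
  want <- log(2 * pi * sig^2 * f[1]^2) + (rec$DV[1] - f[1])^2 / (sig^2 * f[1]^2)
  for (k in 2:3) {
    # censored piece via numeric integration of the stated normal density
    pint <- integrate(function(y) dnorm(y, f[k], sig * f[k]), 1.5, Inf,
                      rel.tol = 1e-12)$value
    want <- want - 2 * log(pint)
  }
  want <- want + log(2 * pi * om^2) + eta^2 / om^2
  expect_equal(g(eta), want, tolerance = 1e-8)
  # UL far below the prediction (in residual-error units): exceedance ~ 1,
  # contribution ~ 0; needs a small CV, since with proportional error the
  # exceedance of any positive limit is capped at Phi(1/sigma)
  p_small <- p
  p_small$pd$sigma[["control"]] <- 0.02
  lowrec <- rec[2, ]; lowrec$ULIM <- 1e-6
  hi <- individual_joint_nll(p_small, lowrec, NULL, 0)
  ref <- log(2 * pi * om^2)
  expect_equal(hi, ref, tolerance = 1e-6)
  # UL equal to the prediction: contribution -2*log(0.5)
  f0 <- p$pd$TVBL[["control"]] * exp(p$pd$Kg0[["control"]] * lowrec$TIME)
  eqrec <- lowrec; eqrec$ULIM <- f0
  expect_equal(individual_joint_nll(p, eqrec, NULL, 0) - ref, -2 * log(0.5),
               tolerance = 1e-9)
})

test_that("a trivially-satisfied censoring limit adds nothing to the OFV", {
  # a censored record whose limit sits far below the prediction is always
  # exceeded, so its exceedance probability is ~1 and the marginal OFV
  # must not move
  p <- ref_params()
  p$pd$sigma[["control"]] <- 0.02
  st <- generate_pd_study(p, arms = "control", n_per_arm = 3,
                          dropout_threshold = Inf, seed = 9)
  d <- apply_modified_m3(st$observations, st$schedule)
  base <- marginal_nll_laplace(p, d, st$regimens)
  one <- d[d$ID == d$ID[1], ][2, ]
  one$CENS <- 1L; one$DV <- NA_real_; one$ULIM <- 1e-9
  aug <- rbind(d, one)
  with_triv <- marginal_nll_laplace(p, aug, st$regimens)
  expect_lt(abs(as.numeric(with_triv) - as.numeric(base)), 1e-6)
})

test_that("Laplace marginal tracks adaptive Gauss-Hermite quadrature", {
  skip_if_not_installed("pracma")
  # the scalar-random-effect posterior is mildly skewed (proportional
  # error on a log-normal baseline), so Laplace carries a small uniform
  # per-animal bias; it must stay at the ~0.02-per-animal scale
  fx <- make_m3_fixture(arms = c("control", "msc"), n_per_arm = 3, seed = 7)
  lap <- marginal_nll_laplace(fx$params, fx$data, fx$regimens)
  gh <- gh_marginal_ofv(fx$params, fx$data, fx$regimens)
  expect_lt(abs(as.numeric(lap) - gh) / 6, 0.03)
})

test_that("Laplace error stays below half an OFV unit at study scale", {
  skip_if_not_installed("pracma")
  p <- ref_params()
  st <- generate_pd_study(p, seed = 11)   # 4 arms x 8 animals
  d <- apply_modified_m3(st$observations, st$schedule)
  lap <- marginal_nll_laplace(p, d, st$regimens)
  gh <- gh_marginal_ofv(p, d, st$regimens)
  expect_lt(abs(as.numeric(lap) - gh), 0.5)
})

test_that("Laplace equals the conjugate-normal closed form in the linear case", {
  # log-transformed no-treatment model with lognormal-like noise is not
  # linear-Gaussian, so build the linear-Gaussian case directly: y_ij =
  # mu + eta_i + e_ij maps onto the machinery through a one-record check
  # with a censoring-free animal and tiny nonlinearity: compare instead
  # against direct 1-d quadrature, which is exact for any model
  fx <- make_m3_fixture(arms = "control", n_per_arm = 4, threshold = Inf,
                        seed = 13)
  lap <- marginal_nll_laplace(fx$params, fx$data, fx$regimens)
  gh <- gh_marginal_ofv(fx$params, fx$data, fx$regimens)
  expect_lt(abs(as.numeric(lap) - gh), 0.1)
  # omega -> 0 degenerate prior: marginal collapses to the eta = 0 OFV
  p0 <- fx$params
  p0$pd$omega_TVBL <- 1e-8
  lap0 <- marginal_nll_laplace(p0, fx$data, fx$regimens)
  fixed0 <- 0
  for (id in unique(fx$data$ID)) {
    rec <- fx$data[fx$data$ID == id, ]
    fixed0 <- fixed0 + individual_joint_nll(p0, rec, NULL, 0) -
      log(2 * pi * p0$pd$omega_TVBL^2)
  }
  expect_equal(as.numeric(lap0), fixed0, tolerance = 1e-4)
})

test_that("PD fit recovers the generating model (control arm, self-consistency)", {
  p <- ref_params()
  # near-noise-free, omega = 0: estimates collapse onto the truth
  p0 <- p
  p0$pd$omega_TVBL <- 0
  p0$pd$sigma[] <- 0.002
  st <- generate_pd_study(p0, arms = "control", n_per_arm = 4,
                          dropout_threshold = Inf, seed = 17)
  d <- apply_modified_m3(st$observations, st$schedule)
  fit <- fit_pd(d, p)
  expect_equal(fit$estimates[["Kg0.control"]], 0.00339, tolerance = 1e-3)
  expect_equal(fit$estimates[["TVBL.control"]], 0.360, tolerance = 5e-3)
})

test_that("ignoring censored records biases control growth low on dropout-heavy data", {
  p <- ref_params()
  n_rep <- 10
  kg_m3 <- kg_drop <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    st <- generate_pd_study(p, arms = "control", n_per_arm = 8,
                            dropout_threshold = 20, seed = 900 + r)
    d <- apply_modified_m3(st$observations, st$schedule)
    f1 <- fit_pd(d, p)
    f2 <- fit_pd(d[d$CENS == 0L, ], p)
    kg_m3[r] <- f1$estimates[["Kg0.control"]]
    kg_drop[r] <- f2$estimates[["Kg0.control"]]
  }
  bias_m3 <- mean(kg_m3) - 0.00339
  bias_drop <- mean(kg_drop) - 0.00339
  expect_lt(bias_drop, 0)               # truncation pulls growth down
  expect_lt(abs(bias_m3), abs(bias_drop))
})
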