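test_that("tumor exchange flux matches the two-process formula and its symmetries", {
  p <- ref_params()
  geom <- p$geometry
  # equilibrium: Cc*E == Ct gives zero flux at any magnitude
  expect_equal(tumor_exchange_flux(100, 100 * p$ptx$E, p$ptx, geom), 0)
  expect_equal(tumor_exchange_flux(1e6, 1e6 * p$ptx$E, p$ptx, geom), 0)
  # reference-value evaluation of the two exchange terms
  fx <- tumor_exchange_flux(100, 0, p$ptx, geom)
  k <- 2 * 0.0875 * 0.0075 / 0.0008^2 + 6 * 0.01 / 0.42^2
  expect_equal(fx, k * 0.3 * 100 * 0.44, tolerance = 1e-12)
  expect_equal(fx, 2.708e4, tolerance = 1e-3)
  # linearity in VT at fixed concentrations and radii
  geom2 <- tumor_geometry(VT = 0.6, Rtumor = geom$Rtumor, Rcap = geom$Rcap,
                          RKrogh = geom$RKrogh)
  expect_equal(tumor_exchange_flux(100, 0, p$ptx, geom2), 2 * fx)
  expect_error(tumor_exchange_flux(NaN, 0, p$ptx, geom), "non-finite")
})

test_that("free-drug layer reduces to the analytic two-compartment model", {
  lay <- no_exchange_layer(CL = 0.909, CLD = 0.336, Vc = 6.64, Vp = 18.5)
  p <- ref_params(ptx = lay)
  tt <- c(0, 1, 5, 24, 96, 288)
  sol <- solve_pk_linear("ptx", p, regimen(dose_event(0, 5000, "free")), tt)
  expect_equal(sol$A_PTXcentral,
               biexp_central(tt, 5000, 0.909, 0.336, 6.64, 18.5),
               tolerance = 1e-6)
  # zero state has zero derivatives; CL = 0 conserves total mass
  expect_equal(rhs_ptx_solution(c(0, 0, 0), p$ptx, p$geometry), c(0, 0, 0))
  d <- rhs_ptx_solution(c(10, 5, 3), ref_params()$ptx, ref_params()$geometry)
  lay0 <- sm_layer_params(CL = 1e-14, CLD = 0.336, Vc = 6.64, Vp = 18.5,
                          fu = 0.0237, P = 0.0875, D = 0.01, E = 0.44)
  d0 <- rhs_ptx_solution(c(10, 5, 3), lay0, ref_params()$geometry)
  expect_equal(sum(d0), 0, tolerance = 1e-12)
})

test_that("NP layer releases first order into the free-drug layer", {
  p <- ref_params()
  # Krel ~ 0 decouples: NP sub-system equals the free-layer model run
  # with NP parameters
  ptr <- transfer_params(Krel = 1e-14, Kexo = 0.081)
  pA <- ref_params(transfer = ptr)
  tt <- c(0, 2, 24, 120)
  solA <- solve_pk_linear("np", pA, regimen(dose_event(0, 5000, "np")), tt)
  pB <- ref_params(ptx = pA$np)  # run NP params through the bottom model
  solB <- solve_pk_linear("ptx", pB, regimen(dose_event(0, 5000, "free")), tt)
  expect_equal(solA$A_NPcentral, solB$A_PTXcentral, tolerance = 1e-8)
  expect_equal(solA$A_NPtumor, solB$A_PTXtumor, tolerance = 1e-8)
  # mass conservation with both clearances off
  pC <- ref_params()
  pC$ptx <- no_exchange_layer(1e-14, 0.336, 6.64, 18.5)
  pC$np <- no_exchange_layer(1e-14, 0.0627, 1.32, 43.2)
  solC <- solve_pk_linear("np", pC, regimen(dose_event(0, 5000, "np")),
                          c(0, 100, 1000))
  expect_equal(rowSums(solC[, -1L]), rep(5000, 3), tolerance = 1e-7)
  # closed-form first-order transfer with exchange and distribution off
  pD <- ref_params()
  pD$ptx <- no_exchange_layer(1e-14, 1e-14, 6.64, 18.5)
  pD$np <- no_exchange_layer(1e-14, 1e-14, 1.32, 43.2)
  tt2 <- c(0, 10, 50, 200)
  solD <- solve_pk_linear("np", pD, regimen(dose_event(0, 1000, "np")), tt2)
  expect_equal(solD$A_PTXcentral, 1000 * (1 - exp(-0.0085 * tt2)),
               tolerance = 1e-6)
})

test_that("MSC layer follows the lumped mono-exponential and conserves mass", {
  p <- ref_params()
  tt <- c(0, 0.05, 0.2, 0.5, 1, 2)
  sol <- solve_pk_linear("msc", p, regimen(dose_event(0, 5000, "msc")), tt)
  lump <- 1.45 + 10.2 + 0.0085 + 0.081
  expect_equal(sol$A_MSCcentral, 5000 * exp(-lump * tt), tolerance = 1e-6)
  # nine-compartment total conserved when both clearances are off
  p0 <- ref_params()
  p0$ptx <- no_exchange_layer(1e-14, 0.336, 6.64, 18.5)
  p0$np <- no_exchange_layer(1e-14, 0.0627, 1.32, 43.2)
  sol0 <- solve_pk_linear("msc", p0, regimen(dose_event(0, 5000, "msc")),
                          c(0, 50, 500, 1000))
  expect_equal(rowSums(sol0[, -1L]), rep(5000, 4), tolerance = 1e-7)
  # all transfer rates frozen: MSC amounts static, others stay zero
  pF <- ref_params(msc = msc_layer_params(1e-14, 1e-14, 7.15e-8, 15021),
                   transfer = transfer_params(1e-14, 1e-14))
  dF <- rhs_nanomsc(c(rep(0, 6), 100, 50, 25), pF$np, pF$ptx, pF$msc,
                    pF$transfer, pF$geometry)
  expect_equal(dF, rep(0, 9), tolerance = 1e-10)
})

test_that("compiled RHS agrees with the R reference right-hand sides", {
  p <- ref_params()
  tt <- c(0, 0.5, 2, 24, 64, 120, 288)
  for (model in c("ptx", "np", "msc")) {
    layer <- switch(model, ptx = "free", np = "np", msc = "msc")
    ode <- solve_pkpd_ode(p, regimen(dose_event(0, 5000, layer)), tt)
    ref <- ode_reference(model, p, 5000, tt)
    n <- switch(model, ptx = 3L, np = 6L, msc = 9L)
    cols <- switch(model, ptx = 1:3, np = c(1:3, 4:6), msc = 1:9)
    got <- as.matrix(ode[, 1 + cols])
    want <- ref[, 1 + seq_len(n)]
    expect_equal(unname(got), unname(want), tolerance = 1e-6)
  }
})

test_that("kill rates are Emax-shaped for free/NP drug and linear for MSC", {
  pd <- ref_params()$pd
  expect_equal(unname(kill_rates(0, 0, 0, pd)), c(0, 0, 0))
  # half-maximal at the IC50 by construction
  expect_equal(kill_rates(pd$IC50_PTX, 0, 0, pd)[["ptx"]], pd$Kmax_PTX / 2)
  expect_equal(kill_rates(0, pd$IC50_NP, 0, pd)[["np"]], pd$Kmax_NP / 2)
  # linear unsaturable MSC kill
  expect_equal(kill_rates(0, 0, 1000, pd)[["msc"]], 4.35e-3, tolerance = 1e-10)
  expect_equal(kill_rates(0, 0, 2000, pd)[["msc"]],
               2 * kill_rates(0, 0, 1000, pd)[["msc"]])
  expect_error(kill_rates(-1, 0, 0, pd), "negative")
})

test_that("drug-free tumor growth is exactly exponential", {
  p <- ref_params()
  tt <- c(0, 10, 100, 500, 1512)
  tv <- predict_pd_animal(p, "control", NULL, tt, eta = 0)
  expect_equal(tv, 0.360 * exp(0.00339 * tt), tolerance = 1e-10)
  expect_equal(tv[tt == 100], 0.5053, tolerance = 1e-4)
  # eta scales the whole trajectory
  tv2 <- predict_pd_animal(p, "control", NULL, tt, eta = log(2))
  expect_equal(tv2, 2 * tv, tolerance = 1e-10)
  # drug-free growth through the full ODE matches the closed form too
  out <- solve_pkpd_ode(p, NULL, tt, dynamic = TRUE, pd = p$pd,
                        arm = "control", TV0 = 0.360, rtol = 1e-11,
                        atol = 1e-13)
  expect_equal(out$TV, 0.360 * exp(0.00339 * tt), tolerance = 1e-8)
})

test_that("dynamic geometry keeps the sphere/power relations pointwise", {
  p <- ref_params()
  tt <- seq(0, 1512, by = 126)
  out <- solve_pkpd_ode(p, regimen_efficacy("msc"), tt, dynamic = TRUE,
                        pd = p$pd, arm = "msc", TV0 = 0.227)
  expect_equal(out$VT, volume_from_bioluminescence(pmax(out$TV, 1e-6), p$cal),
               tolerance = 1e-8)
  expect_equal(radius_from_volume(out$VT)^3 * 4 * pi / 3, out$VT,
               tolerance = 1e-10)
})

test_that("volume and radius conversions are exact and invertible", {
  expect_equal(volume_from_bioluminescence(7.3, bl_calibration(1, 1)), 7.3)
  expect_equal(volume_from_bioluminescence(7.3, bl_calibration(2.5, 0)), 2.5)
  cal <- bl_calibration(0.4, 0.25)
  tv <- c(0.1, 1, 42, 900)
  vt <- volume_from_bioluminescence(tv, cal)
  expect_equal((vt / cal$a)^(1 / cal$b), tv, tolerance = 1e-10)
  expect_error(volume_from_bioluminescence(-1, cal), "positive")
  expect_equal(radius_from_volume(4 * pi / 3), 1)
  expect_equal(radius_from_volume(0.3), 0.415, tolerance = 1e-3)
  expect_equal(radius_from_volume(8 * 0.3), 2 * radius_from_volume(0.3))
  expect_error(radius_from_volume(0), "positive")
})

test_that("observation model applies fu to small-molecule layers only", {
  p <- ref_params()
  expect_equal(observed_plasma_concentration(numeric(9), p$ptx, p$np, p$msc,
                                             "msc"), 0)
  st <- numeric(9); st[1] <- 6640
  expect_equal(observed_plasma_concentration(st, p$ptx, p$np, p$msc, "ptx"),
               23.7, tolerance = 1e-10)
  # MSC contribution uses raw A/V and decays with the lumped plasma rate
  sol <- solve_pk_linear("msc", p, regimen(dose_event(0, 5000, "msc")),
                         c(0, 2))
  expect_lt(sol$A_MSCcentral[2] / 5000, 1e-8)
  # lung concentration is additive across forms
  st2 <- numeric(9); st2[c(2, 5, 8)] <- 30
  expect_equal(observed_lung_concentration(st2, p$geometry), 300)
})

test_that("trajectories from nonnegative starts stay nonnegative", {
  p <- ref_params()
  sol <- solve_pkpd_ode(p, regimen(dose_event(0, 5000, "msc")),
                        seq(0, 1000, by = 10))
  expect_true(all(as.matrix(sol[, 2:10]) > -1e-9 * 5000))
})
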