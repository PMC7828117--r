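test_that("first-order association fit recovers noise-free kinetics exactly", {
  tt <- c(4, 24, 72, 168, 336)
  y <- 100 * (1 - exp(-0.0085 * tt))
  fit <- fit_first_order_association(tt, y)
  expect_equal(fit$Krel, 0.0085, tolerance = 1e-6)
  expect_equal(fit$plateau, 100, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_error(fit_first_order_association(c(1, 2), c(10, 20)), ">= 3")
  expect_error(fit_first_order_association(tt, y + 200), "within")
})

test_that("first-order decay fit matches the log-linear closed form", {
  tt <- c(0.5, 1, 2, 4, 8, 24)
  y <- 100 * exp(-0.56 * tt)
  fit <- fit_first_order_decay(tt, y)
  expect_equal(fit$Kexo, 0.56, tolerance = 1e-8)
  expect_equal(fit$y0, 100, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # log-linear regression oracle agrees on noise-free data
  ll <- lm(log(y) ~ tt)
  expect_equal(fit$Kexo, -unname(coef(ll)[2]), tolerance = 1e-8)
  expect_equal(fit$y0, exp(unname(coef(ll)[1])), tolerance = 1e-8)
})

test_that("rate-constant fits are time-scale consistent", {
  tt <- c(4, 24, 72, 168, 336)
  y <- 95 * (1 - exp(-0.0085 * tt)) * (1 + c(0.05, -0.04, 0.02, -0.01, 0.03))
  f_h <- fit_first_order_association(tt, y)
  f_d <- fit_first_order_association(tt / 24, y)  # times in days
  expect_equal(f_d$Krel, 24 * f_h$Krel, tolerance = 1e-6)
  expect_equal(f_d$r_squared, f_h$r_squared, tolerance = 1e-8)
  yd <- 100 * exp(-0.56 * tt[1:4]) * (1 + c(0.02, -0.03, 0.01, 0.04))
  d_h <- fit_first_order_decay(tt[1:4], yd)
  d_d <- fit_first_order_decay(tt[1:4] / 24, yd)
  expect_equal(d_d$Kexo, 24 * d_h$Kexo, tolerance = 1e-6)
})

test_that("exocytosis mass scaling multiplies by the drug loading", {
  expect_equal(mass_scale_kexo(0.56, 0.148), 0.08288, tolerance = 1e-12)
  expect_equal(round(mass_scale_kexo(0.56, 0.148), 3), 0.083)
  expect_equal(mass_scale_kexo(0.7, 1), 0.7)
  expect_equal(mass_scale_kexo(1.0, 0.5), 0.5)
  expect_error(mass_scale_kexo(-1, 0.148), "positive")
})

test_that("power calibration is exact on power-law data and log-log linear", {
  TV <- c(0.5, 2, 8, 40, 120, 300)
  w <- 0.05 * TV^0.8
  fit <- fit_power_calibration(TV, w)
  expect_equal(fit$cal$a, 0.05, tolerance = 1e-10)
  expect_equal(fit$cal$b, 0.8, tolerance = 1e-10)
  # identity data: slope 1, intercept 0 on log-log axes
  fit1 <- fit_power_calibration(TV, TV)
  expect_equal(unname(coef(fit1$fit)), c(0, 1), tolerance = 1e-12)
  expect_error(fit_power_calibration(c(1, -2, 3), c(1, 2, 3)), "positive")
})

test_that("Monte-Carlo recovery of in-vitro constants at study noise", {
  # release truth (0.0085) with 10% CV; decay truth (0.56)
  n_rep <- 60
  krel <- kexo <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    dd <- generate_release_exocytosis_data(cv = 0.1, seed = 400 + r)
    krel[r] <- fit_first_order_association(dd$release$time,
                                           dd$release$released_pct)$Krel
    kexo[r] <- fit_first_order_decay(dd$exocytosis$time,
                                     dd$exocytosis$retained_pct)$Kexo
  }
  # the 5-point release design leaves ~15% median sampling error in Krel
  # (plateau/rate trade-off), so the per-replicate check is on the Monte
  # Carlo mean; the 6-point decay design pins Kexo much harder
  expect_lt(abs(mean(krel) - 0.0085) / 0.0085, 0.15)
  expect_gte(mean(abs(krel - 0.0085) / 0.0085 <= 0.5), 0.9)
  expect_gte(mean(abs(kexo - 0.56) / 0.56 <= 0.15), 0.8)
})

test_that("calibration-exponent recovery across replicate 8-pair studies", {
  n_rep <- 100
  b <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    pairs <- generate_calibration_pairs(sigma = 0.2, seed = 700 + r)
    b[r] <- fit_power_calibration(pairs$TV, pairs$weight_g)$cal$b
  }
  expect_gte(mean(abs(b - 0.25) / 0.25 <= 0.25), 0.8)
})
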