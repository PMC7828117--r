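test_that("PK profile totals are the sum of the per-form series", {
  p <- ref_params()
  prof <- simulate_pk_profiles("msc", p, regimen_pk_bolus("msc"),
                               times = seq(0, 288, by = 1))
  expect_equal(prof$lung_total, prof$lung_free + prof$lung_np + prof$lung_msc)
  expect_equal(prof$plasma_total,
               prof$plasma_free + prof$plasma_np + prof$plasma_msc)
  # lung MSC-form declines monotonically after its peak
  pk <- which.max(prof$lung_msc)
  expect_true(all(diff(prof$lung_msc[pk:nrow(prof)]) <= 0))
  expect_error(simulate_pk_profiles("msc", p, NULL), "empty")
})

test_that("crossover search finds the bracketed dominance change", {
  p <- ref_params()
  prof <- simulate_pk_profiles("msc", p, regimen_pk_bolus("msc"),
                               times = seq(0, 288, by = 0.25))
  tc <- dominant_form_crossover(prof)
  expect_gt(tc, 56); expect_lt(tc, 72)
  # at the crossover the free series passes the competing maximum
  below <- prof$time < tc - 0.5
  after <- prof$time > tc + 0.5 & prof$time < 100
  expect_true(all(prof$lung_free[below] <=
                  pmax(prof$lung_np, prof$lung_msc)[below]))
  expect_true(all(prof$lung_free[after] >
                  pmax(prof$lung_np, prof$lung_msc)[after]))
  # everywhere-dominant series returns the first grid time; permuting the
  # series labels asks the same question of another form
  expect_equal(dominant_form_crossover(
    prof[prof$time >= 100, ],
    series = c("lung_free", "lung_np", "lung_msc")), 100)
  tc_msc <- dominant_form_crossover(prof, series = c("lung_msc", "lung_free",
                                                     "lung_np"))
  expect_lt(tc_msc, 0.01)  # MSC form dominates essentially immediately
  expect_true(is.na(suppressMessages(dominant_form_crossover(
    prof[prof$time < 30, ]))))
})

test_that("population bands collapse to the typical curve when omega is 0", {
  p <- ref_params()
  p$pd$omega_TVBL <- 0
  sim <- simulate_population(p, NULL, "control", n = 8, seed = 5,
                             times = seq(0, 500, by = 50))
  typical <- 0.360 * exp(0.00339 * seq(0, 500, by = 50))
  expect_equal(sim$summary$median, typical, tolerance = 1e-10)
  expect_equal(sim$summary$p10, sim$summary$p90, tolerance = 1e-12)
})

test_that("population simulation is seed-reproducible and median-consistent", {
  p <- ref_params()
  tt <- seq(0, 1000, by = 100)
  s1 <- simulate_population(p, NULL, "control", n = 40, seed = 9, times = tt)
  s2 <- simulate_population(p, NULL, "control", n = 40, seed = 9, times = tt)
  expect_identical(s1$trajectories, s2$trajectories)
  s3 <- simulate_population(p, NULL, "control", n = 40, seed = 10, times = tt)
  expect_false(identical(s1$trajectories, s3$trajectories))
  # log-normal BSV: the population median tracks the typical trajectory
  big <- simulate_population(p, NULL, "control", n = 4000, seed = 2,
                             times = c(0, 500, 1000))
  expect_equal(big$summary$median, 0.360 * exp(0.00339 * c(0, 500, 1000)),
               tolerance = 0.05)
  # percentile bands are ordered at every time
  expect_true(all(s1$summary$p10 <= s1$summary$median))
  expect_true(all(s1$summary$median <= s1$summary$p90))
})

test_that("a stronger maximal kill never raises the tumor burden", {
  p <- ref_params()
  tt <- seq(0, 1512, by = 168)
  tv_base <- predict_pd_animal(p, "ptx", regimen_efficacy("ptx"), tt, 0)
  p_hi <- p
  p_hi$pd$Kmax_PTX <- 2 * p$pd$Kmax_PTX
  tv_hi <- predict_pd_animal(p_hi, "ptx", regimen_efficacy("ptx"), tt, 0)
  expect_true(all(tv_hi <= tv_base + 1e-10))
})

test_that("scenario grid reproduces the dosing and rate-constant orderings", {
  p <- ref_params()
  sc <- scenario_grid(p)
  res <- run_scenarios(sc, n = 30, seed = 4, times = seq(0, 1512, by = 8))
  tab <- res$table
  med <- setNames(tab$end_median, tab$scenario)
  # equal-total-dose interval scenarios dose the same cumulative amount
  tot <- vapply(sc[c("interval_q14d", "interval_q7d", "interval_q3.5d")],
                function(s) sum(s$regimen$amount), numeric(1))
  expect_equal(unname(tot), rep(tot[[1]], 3))
  # end-horizon burden non-increasing in maintenance dose
  dose_meds <- med[c("dose_0.25e6", "dose_0.5e6", "dose_0.75e6", "dose_2e6")]
  expect_true(all(diff(dose_meds) <= 0))
  # non-decreasing in Kexo
  kexo_meds <- med[c("kexo_0.06", "kexo_0.081", "kexo_0.1")]
  expect_true(all(diff(kexo_meds) >= 0))
  # interval spread below the dose-grid spread; Krel spread below Kexo's
  rel_spread <- function(v) (max(v) - min(v)) / min(v)
  expect_lt(rel_spread(med[c("interval_q14d", "interval_q7d",
                             "interval_q3.5d")]),
            rel_spread(med[c("dose_0.25e6", "dose_2e6")]))
  expect_lt(rel_spread(med[c("krel_0.00425", "krel_0.0085", "krel_0.017")]),
            rel_spread(med[c("kexo_0.06", "kexo_0.081", "kexo_0.1")]))
  # identical scenarios give identical summaries under one seed
  res2 <- run_scenarios(sc["dose_0.5e6"], n = 30, seed = 4,
                        times = seq(0, 1512, by = 8))
  expect_equal(res2$table$end_median, med[["dose_0.5e6"]])
  expect_error(run_scenarios(c(sc[1], sc[1])), "duplicate")
})
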