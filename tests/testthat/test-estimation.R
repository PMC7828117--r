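test_that("proportional-error OFV matches a per-record summation oracle", {
  set.seed(31)
  y <- exp(rnorm(10, 2, 1))
  f <- y * (1 + rnorm(10, 0, 0.1))
  sig <- runif(10, 0.2, 0.8)
  # brute-force independent summation
  want <- 0
  for (i in 1:10)
    want <- want + log(2 * pi * sig[i]^2 * f[i]^2) +
      (y[i] - f[i])^2 / (sig[i]^2 * f[i]^2)
  expect_equal(nll_proportional(y, f, sig), want, tolerance = 1e-10)
  # single record at y = f, sigma = 1, f = 1 contributes log(2*pi)
  expect_equal(nll_proportional(1, 1, 1), log(2 * pi))
  # proportional-error scale invariance of the standardized residual term
  a <- nll_proportional(y, f, sig)
  b <- nll_proportional(2 * y, 2 * f, sig)
  expect_equal(b - a, 10 * 2 * log(2), tolerance = 1e-9)
  expect_error(nll_proportional(y, c(-1, f[-1]), sig), "nonpositive")
})

test_that("bottom-layer fit is self-consistent on noise-free data", {
  p <- ref_params()
  p0 <- p
  p0$sigma_pk[, ] <- 1e-12
  d <- generate_pk_study(p0, arms = "ptx", seed = 5)
  fit <- fit_pk_layer(d, "ptx", p, n_starts = 1, hessian = FALSE)
  for (nm in c("CL", "CLD", "Vc", "Vp", "fu"))
    expect_equal(fit$estimates[[paste0("ptx.", nm)]], p$ptx[[nm]],
                 tolerance = 1e-3)
})

test_that("layer-by-layer workflow enforces ordering and fixes lower layers", {
  p <- ref_params()
  d <- generate_pk_study(p, seed = 21)
  expect_error(fit_pk_layer(d[d$ARM == "np", ], "np", p), "lower-layer")
  expect_error(fit_pk_layer(d[d$ARM == "msc", ], "msc", p,
                            fixed_lower = list()), "lower-layer")
  bot <- fit_pk_layer(d[d$ARM == "ptx", ], "ptx", p, n_starts = 1,
                      hessian = FALSE)
  mid <- fit_pk_layer(d[d$ARM == "np", ], "np", p, fixed_lower = list(bot),
                      n_starts = 1, hessian = FALSE)
  # upper fits leave the lower layer untouched: refitting bottom after the
  # middle fit reproduces its estimates
  bot2 <- fit_pk_layer(d[d$ARM == "ptx", ], "ptx", p, n_starts = 1,
                       hessian = FALSE)
  expect_equal(bot2$estimates, bot$estimates, tolerance = 1e-8)
  expect_true(any(grepl("fit_pk_layer\\(ptx\\)", mid$fixed)))
  expect_error(fit_pk_layer(transform(d[d$ARM == "ptx", ], DV = DV - min(DV)),
                            "ptx", p), "nonpositive")
})

test_that("free-drug clearance is recovered at the study design", {
  p <- ref_params()
  n_rep <- 40
  cl <- rep(NA_real_, n_rep)
  for (r in seq_len(n_rep)) {
    d <- generate_pk_study(p, arms = "ptx", seed = 5000 + r)
    fit <- tryCatch(fit_pk_layer(d, "ptx", p, n_starts = 1, hessian = FALSE),
                    error = function(e) NULL)
    if (!is.null(fit)) cl[r] <- fit$estimates[["ptx.CL"]]
  }
  ok <- mean(abs(cl - 0.909) / 0.909 <= 0.3, na.rm = TRUE)
  expect_gte(ok, 0.7)
  # the estimator is centred near the truth
  expect_lt(abs(median(cl, na.rm = TRUE) - 0.909) / 0.909, 0.2)
})

test_that("a denser design tightens clearance recovery", {
  p <- ref_params()
  n_rep <- 12
  rel_sparse <- rel_dense <- rep(NA_real_, n_rep)
  for (r in seq_len(n_rep)) {
    ds <- generate_pk_study(p, arms = "ptx", seed = 7000 + r)
    dd <- generate_pk_study(p, arms = "ptx",
                            times = c(2, 12, 24, 48, 96, 144, 192, 240, 288),
                            n_per = 10, seed = 7000 + r)
    fs <- tryCatch(fit_pk_layer(ds, "ptx", p, n_starts = 1, hessian = FALSE),
                   error = function(e) NULL)
    fd <- tryCatch(fit_pk_layer(dd, "ptx", p, n_starts = 1, hessian = FALSE),
                   error = function(e) NULL)
    if (!is.null(fs)) rel_sparse[r] <- abs(fs$estimates[["ptx.CL"]] - 0.909) / 0.909
    if (!is.null(fd)) rel_dense[r] <- abs(fd$estimates[["ptx.CL"]] - 0.909) / 0.909
  }
  expect_lt(median(rel_dense, na.rm = TRUE), median(rel_sparse, na.rm = TRUE))
  expect_gte(mean(rel_dense <= 0.1, na.rm = TRUE), 0.5)
})

test_that("RSE table reflects curvature and tolerates indefinite directions", {
  p <- ref_params()
  d <- generate_pk_study(p, arms = "ptx", seed = 33)
  fit <- fit_pk_layer(d, "ptx", p, n_starts = 1, hessian = TRUE)
  tab <- rse_from_hessian(fit)
  expect_true(all(c("parameter", "estimate", "rse_pct") %in% names(tab)))
  expect_true(all(tab$rse_pct[is.finite(tab$rse_pct)] >= 0))
  # finite-difference Hessian oracle on the fitted objective
  obj <- function(th) {
    names(th) <- names(fit$log_estimates)
    nll_pooled_proportional(th, d, "ptx", p)
  }
  H <- optimHess(fit$log_estimates, obj)
  se_or <- sqrt(diag(2 * solve(H)))
  good <- is.finite(tab$rse_pct)
  expect_equal(tab$rse_pct[good], unname(100 * se_or[good]), tolerance = 0.02)
  # a fabricated huge-curvature direction has near-zero RSE
  f2 <- fit
  f2$cov_log <- diag(c(1e-12, rep(0.1, length(fit$estimates) - 1)))
  dimnames(f2$cov_log) <- dimnames(fit$cov_log)
  expect_lt(rse_from_hessian(f2)$rse_pct[1], 1e-3)
})
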