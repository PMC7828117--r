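# Shared fixtures and independent oracles for the test suite.

ref_params <- function(...) nanomsc_params(...)

# an sm layer with numerically-off tumor exchange (closed-form reductions)
no_exchange_layer <- function(CL, CLD, Vc, Vp, fu = 0.5) {
  sm_layer_params(CL = CL, CLD = CLD, Vc = Vc, Vp = Vp, fu = fu,
                  P = 1e-14, D = 1e-14, E = 1e-6)
}

# analytic central-compartment amount of a two-compartment bolus model
# (independent closed form: eigenvalues of the 2x2 micro-rate system)
biexp_central <- function(t, dose, CL, CLD, Vc, Vp) {
  k10 <- CL / Vc; k12 <- CLD / Vc; k21 <- CLD / Vp
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  a <- (s + disc) / 2; b <- (s - disc) / 2
  dose * ((a - k21) / (a - b) * exp(-a * t) + (k21 - b) / (a - b) * exp(-b * t))
}

# 64-node adaptive Gauss-Hermite -2 log marginal likelihood, centered and
# scaled at the joint mode; oracle for the Laplace approximation
gh_marginal_ofv <- function(params, data, regimens, nodes = 64) {
  gh <- pracma::gaussHermite(nodes)
  total <- 0
  for (id in unique(data$ID)) {
    rec <- data[data$ID == id, , drop = FALSE]
    arm <- rec$ARM[1L]
    g <- function(eta) individual_joint_nll(params, rec, regimens[[arm]], eta)
    opt <- optimize(g, c(-8, 8))
    h <- 1e-3
    d2 <- (g(opt$minimum + h) - 2 * opt$objective + g(opt$minimum - h)) / h^2
    s <- sqrt(2 / max(d2, 1e-8))
    vals <- vapply(gh$x, function(x) {
      eta <- opt$minimum + sqrt(2) * s * x
      exp(-0.5 * (g(eta) - opt$objective))
    }, numeric(1))
    integ <- sqrt(2) * s * sum(gh$w * vals * exp(gh$x^2))
    total <- total + opt$objective - 2 * log(integ)
  }
  total
}

# deSolve integration of the R-level reference right-hand sides; the
# independent route checked against the compiled/matrix-exponential paths
ode_reference <- function(model, params, dose, times) {
  n <- switch(model, ptx = 3L, np = 6L, msc = 9L)
  y0 <- numeric(n)
  y0[switch(model, ptx = 1L, np = 4L, msc = 7L)] <- dose
  rhs <- function(t, y, parms) {
    d <- switch(model,
      ptx = rhs_ptx_solution(y, params$ptx, params$geometry),
      np = rhs_ptx_plga(y, params$np, params$ptx, params$transfer,
                        params$geometry),
      msc = rhs_nanomsc(y, params$np, params$ptx, params$msc,
                        params$transfer, params$geometry))
    list(d)
  }
  deSolve::lsoda(y0, times, rhs, NULL, rtol = 1e-10, atol = 1e-12)
}
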