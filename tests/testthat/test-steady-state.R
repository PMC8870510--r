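test_that("a dead network is already at steady state", {
  mp <- default_baseline()
  p <- mp$p
  p$vmax[] <- 0
  p$environment$k_use <- 0
  p$environment$basal_load <- 0
  p$environment$leak_rate <- 0
  init <- reference_state(mp$m)
  res <- integrate_to_steady_state(mp$m, p, init = init)
  expect_true(res$converged)
  expect_equal(res$state, init, tolerance = 1e-9)
  expect_equal(res$time_to_converge, 0)
})

test_that("the default configuration reaches a bounded steady state", {
  res <- default_steady_state()
  expect_true(res$converged)
  expect_true(res$bounded)
  expect_lt(res$diagnostics$residual, 1e-6)
  expect_false(is.null(res$readouts))
})

test_that("an absurd concentration ceiling is reported as unbounded", {
  mp <- default_baseline()
  res <- suppressWarnings(integrate_to_steady_state(
    mp$m, mp$p, opts = solver_options(bound_cap = 1, t_max = 100)))
  expect_false(res$bounded)
})

test_that("the flux-balance audit agrees with the solver and rejects perturbations", {
  res <- default_steady_state()
  expect_lt(flux_balance_residual(res), 1e-6)
  shifted <- res
  shifted$state[["F6P"]] <- shifted$state[["F6P"]] * 1.1
  expect_gt(flux_balance_residual(shifted), 1e-6)
})

test_that("an independent root-finder confirms the integrator's steady state", {
  skip_if_not_installed("pracma")
  res <- default_steady_state()
  mp <- default_baseline()
  dyn <- names(res$state)
  S <- ccmsim:::stoichiometry_matrix(mp$m, mp$p$yields)
  free <- dyn[rowSums(abs(S)) > 0]
  f <- function(v) {
    st <- res$state
    st[free] <- v
    compute_derivatives(st, mp$p, mp$m)[free]
  }
  root <- pracma::fsolve(f, res$state[free], tol = 1e-12)
  expect_equal(unname(root$x), unname(res$state[free]), tolerance = 1e-6)
})

test_that("ATP production balances consumption at steady state", {
  res <- default_steady_state()
  mp <- default_baseline()
  f <- res$fluxes
  a <- vapply(mp$m$reactions, function(r) {
    s <- r$atp_stoich
    if (!is.na(r$atp_yield_key)) s <- s + mp$p$yields[[r$atp_yield_key]]
    s
  }, numeric(1))
  production <- sum(pmax(a, 0) * f[names(a)])
  consumption <- -sum(pmin(a, 0) * f[names(a)])
  expect_equal(production, consumption, tolerance = 1e-6 * production)
})

test_that("readouts reduce to the defining arithmetic", {
  res <- default_steady_state()
  ro <- res$readouts
  f <- res$fluxes
  expect_equal(ro$OCR_proxy, f[["R19"]] + f[["R20"]])
  expect_equal(ro$ECAR_proxy, f[["R7"]])
  p <- res$parameters
  expect_equal(ro$atp_adp_ratio,
               res$state[["ATP"]] / (p$pools$A_tot - res$state[["ATP"]]))
  expect_equal(ro$tca_flux_akgdh, f[["R12"]])
  expect_error(derived_readouts(list(converged = FALSE)), "not converged")
})

test_that("shutting a pathway zeroes its readout", {
  mp <- default_baseline()
  p <- set_environment(mp$p, "O2", 0)
  p <- scale_activity(p, "PC", 0)
  p$regulation$amp_FBP <- 1
  res <- suppressWarnings(integrate_to_steady_state(mp$m, p))
  expect_true(res$converged)
  expect_equal(res$readouts$OCR_proxy, 0)
  p2 <- scale_activity(mp$p, "LDH", 0)
  p2$regulation$amp_FBP <- 1
  p2 <- set_environment(p2, "k_use", 12)
  res2 <- suppressWarnings(integrate_to_steady_state(mp$m, p2))
  expect_true(res2$converged)
  expect_equal(res2$readouts$ECAR_proxy, 0)
})

test_that("the lactate-only ATP yield is exactly 2 for any feasible kinetics", {
  # stoichiometric invariance: the yield does not depend on kinetic constants
  mp <- default_baseline()
  set.seed(421)
  for (i in 1:4) {
    p <- mp$p
    for (k in c("RIB", "LIP", "ACC", "ACLY", "AKGEXP", "PDH", "PC")) {
      p <- ccmsim:::set_activity(p, k, 0)
    }
    p <- set_environment(p, "Gln_ext", 0)
    p$regulation$amp_FBP <- 1
    # perturb the kinetic constants that the lactate route actually uses
    jitter <- function(x) x * exp(stats::runif(1, -0.3, 0.3))
    for (rid in c("R1", "R3", "R4", "R6", "R7")) {
      p$vmax[[rid]] <- jitter(p$vmax[[rid]])
    }
    p$km$R7[["PYR"]] <- jitter(p$km$R7[["PYR"]])
    p <- set_environment(p, "k_use", jitter(p$environment$k_use))
    res <- suppressWarnings(integrate_to_steady_state(mp$m, p))
    expect_true(res$converged, info = paste("replicate", i))
    expect_equal(atp_yield_per_glucose(res), 2, tolerance = 1e-5,
                 info = paste("replicate", i))
  }
})

test_that("yield accounting refuses glutamine-fed states and zero uptake", {
  res <- default_steady_state()
  expect_error(atp_yield_per_glucose(res), "glutamine")
  expect_error(atp_yield_per_glucose(list(converged = FALSE)), "not converged")
})
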