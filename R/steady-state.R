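# Steady-state machinery: stiff integration to stationarity, Newton polish,
# convergence/boundedness diagnostics, and derived phenotype readouts.

#' Solver options
#'
#' @param abs_tol,rel_tol Integration tolerances passed to the stiff solver.
#' @param ss_tol Steady-state criterion: maximum absolute time derivative
#'   (mM/h) below which the run is declared converged.
#' @param t_max Maximum integrated time (h).
#' @param bound_cap Concentration ceiling (mM); any species exceeding it
#'   declares the run unbounded.
#' @return A `ccm_solver_options` list.
#' @export
solver_options <- function(abs_tol = 1e-12, rel_tol = 1e-8, ss_tol = 1e-6,
                           t_max = 1e4, bound_cap = 1e4) {
  opts <- list(abs_tol = abs_tol, rel_tol = rel_tol, ss_tol = ss_tol,
               t_max = t_max, bound_cap = bound_cap)
  if (any(unlist(opts) <= 0)) stop("solver options must all be positive")
  class(opts) <- "ccm_solver_options"
  opts
}

# Fast closures shared by the integrator and the Newton polish.
rhs_context <- function(m, p) {
  plan <- flux_plan(m, p)
  S <- stoichiometry_matrix(m, p$yields)
  xn <- plan$xnames
  list(
    plan = plan, S = S,
    deriv = function(y) {
      drop(S %*% eval_fluxes(augment_state(y, p, m, xn), plan))
    },
    flux = function(y) eval_fluxes(augment_state(y, p, m, xn), plan)
  )
}

# Damped Newton polish on the non-trivial components of the system. Species
# whose stoichiometric row is identically zero (the inert cytosolic citrate
# pool; ATP in the clamped variant) are held fixed. Best-effort: returns the
# input state unchanged when the Jacobian is singular or no step improves the
# residual.
newton_polish <- function(state, ctx, m, p, max_iter = 20, tol = 1e-10) {
  dyn <- dynamic_species(m)
  free <- dyn[rowSums(abs(ctx$S)) > 0]
  upper <- rep(Inf, length(free))
  names(upper) <- free
  if ("ATP" %in% free) upper[["ATP"]] <- p$pools$A_tot
  if ("NADH_m" %in% free) upper[["NADH_m"]] <- p$pools$N_tot_m
  if ("FADH2_m" %in% free) upper[["FADH2_m"]] <- p$pools$F_tot_m
  if ("NADH_c" %in% free) upper[["NADH_c"]] <- p$pools$N_tot_c
  y <- state
  ffun <- function(v) {
    y2 <- y; y2[free] <- v
    ctx$deriv(y2)[free]
  }
  v <- y[free]
  fv <- ffun(v)
  for (it in seq_len(max_iter)) {
    if (max(abs(fv)) < tol) break
    J <- numeric_jacobian(ffun, v, fv)
    step <- tryCatch(solve(J, -fv), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    improved <- FALSE
    lambda <- 1
    for (k in 1:8) {
      v_new <- pmin(pmax(v + lambda * step, 0), upper)
      f_new <- ffun(v_new)
      if (all(is.finite(f_new)) && max(abs(f_new)) < max(abs(fv))) {
        v <- v_new; fv <- f_new; improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }
  y[free] <- v
  y
}

# Linear stability of a candidate equilibrium: all eigenvalues of the
# Jacobian over the non-trivial species must have non-positive real part
# (structurally zero modes from drained dead-end pools are ignored).
is_stable_point <- function(y, ctx, m, p) {
  free <- dynamic_species(m)[rowSums(abs(ctx$S)) > 0]
  f <- function(v) { yy <- y; yy[free] <- v; ctx$deriv(yy)[free] }
  J <- numeric_jacobian(f, y[free])
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[Mod(ev) > 1e-9]
  length(ev) == 0 || max(Re(ev)) < 1e-6
}

numeric_jacobian <- function(f, v, fv = f(v)) {
  n <- length(v)
  J <- matrix(0, n, n)
  h <- pmax(abs(v), 1e-4) * 1e-7
  for (j in seq_len(n)) {
    vj <- v; vj[j] <- vj[j] + h[j]
    J[, j] <- (f(vj) - fv) / h[j]
  }
  J
}

#' Integrate the model to steady state
#'
#' Integrates the ODE system with a stiff-capable method (`deSolve::lsoda`)
#' in geometrically growing time chunks until the maximum absolute derivative
#' falls below `ss_tol` or `t_max` is reached, then polishes the answer with a
#' damped Newton root solve seeded at the integrator's endpoint. Integration
#' (rather than naive root finding from an arbitrary guess) selects the stable
#' steady state in the basin of the supplied initial condition, which matters
#' wherever the system is bistable. Convergence and boundedness are reported
#' honestly; the final state is returned even when unconverged.
#'
#' @param m A `ccm_model`.
#' @param p A `ccm_parameters`.
#' @param init Named initial concentration vector; defaults to
#'   [default_initial_state()].
#' @param opts A [solver_options()] list.
#' @return A `ccm_steady_state` object with components `state`, `fluxes`,
#'   `converged`, `bounded`, `time_to_converge`, `readouts` (see
#'   [derived_readouts()]; `NULL` when unconverged), `diagnostics`, and the
#'   `model`/`parameters` used.
#' @examples
#' m <- build_default_network(); p <- default_parameters(m)
#' res <- integrate_to_steady_state(m, p)
#' res$converged
#' @export
integrate_to_steady_state <- function(m, p, init = default_initial_state(m, p),
                                      opts = solver_options()) {
  validate_parameters(p, m)
  validate_state(init, m, p)
  dyn <- dynamic_species(m)
  y <- pmax(init[dyn], 0)
  # continuation re-feeds solved states; keep them strictly inside pool bounds
  y[["ATP"]] <- min(y[["ATP"]], p$pools$A_tot)
  y[["NADH_m"]] <- min(y[["NADH_m"]], p$pools$N_tot_m)
  y[["FADH2_m"]] <- min(y[["FADH2_m"]], p$pools$F_tot_m)
  if ("NADH_c" %in% dyn) y[["NADH_c"]] <- min(y[["NADH_c"]], p$pools$N_tot_c)
  ctx <- rhs_context(m, p)
  rhs <- function(t, y, parms) list(ctx$deriv(y))

  converged <- FALSE
  bounded <- TRUE
  method <- "integrator"
  t_now <- 0
  t_next <- 1
  resid <- max(abs(ctx$deriv(y)))
  if (resid < opts$ss_tol) converged <- TRUE
  while (!converged && t_now < opts$t_max && bounded) {
    chunk <- min(t_next, opts$t_max) - t_now
    sol <- tryCatch(
      deSolve::lsoda(y, c(0, chunk), rhs, parms = NULL,
                     rtol = opts$rel_tol, atol = opts$abs_tol,
                     maxsteps = 50000),
      error = function(e) NULL
    )
    if (is.null(sol) || nrow(sol) < 2 || any(!is.finite(sol[nrow(sol), -1]))) {
      bounded <- FALSE
      break
    }
    y_new <- sol[nrow(sol), -1]
    names(y_new) <- dyn
    if (any(y_new < -1e-9)) {
      bounded <- FALSE
      break
    }
    y <- pmax(y_new, 0)
    t_now <- min(t_next, opts$t_max)
    t_next <- t_next * 10
    if (any(y > opts$bound_cap)) {
      bounded <- FALSE
      break
    }
    resid <- max(abs(ctx$deriv(y)))
    if (resid < opts$ss_tol) converged <- TRUE
    # a long-lived oscillatory transient can coexist with a stable steady
    # state; once well past the fast transients, try a root solve from the
    # current orbit and accept the answer only if it is a verified, linearly
    # stable equilibrium
    if (!converged && bounded && t_now >= 1000) {
      y_try <- newton_polish(y, ctx, m, p, max_iter = 40, tol = opts$ss_tol / 10)
      r_try <- max(abs(ctx$deriv(y_try)))
      if (is.finite(r_try) && r_try < opts$ss_tol &&
          all(y_try >= -1e-9) && is_stable_point(y_try, ctx, m, p)) {
        y <- pmax(y_try, 0)
        resid <- r_try
        converged <- TRUE
        method <- "newton_fallback"
      }
    }
  }

  newton_delta <- NA_real_
  resid_integrator <- resid
  if (converged && bounded) {
    y_pol <- newton_polish(y, ctx, m, p)
    resid_pol <- max(abs(ctx$deriv(y_pol)))
    newton_delta <- max(abs(y_pol - y) / pmax(abs(y), 1e-12))
    if (is.finite(resid_pol) && resid_pol <= resid) {
      y <- y_pol
      resid <- resid_pol
    }
  }

  res <- list(
    state = y,
    fluxes = ctx$flux(y),
    converged = converged,
    bounded = bounded,
    time_to_converge = if (converged) t_now else NA_real_,
    diagnostics = list(
      residual = resid,
      residual_integrator = resid_integrator,
      newton_delta = newton_delta,
      method = method,
      ss_tol = opts$ss_tol,
      t_max = opts$t_max
    ),
    model = m,
    parameters = p
  )
  class(res) <- "ccm_steady_state"
  res$readouts <- if (converged && bounded) derived_readouts(res) else NULL
  res
}

#' @export
print.ccm_steady_state <- function(x, ...) {
  cat(sprintf(
    "<ccm_steady_state> converged=%s bounded=%s (max|dC/dt| = %.3g mM/h at t <= %g h)\n",
    x$converged, x$bounded, x$diagnostics$residual,
    if (is.na(x$time_to_converge)) x$diagnostics$t_max else x$time_to_converge
  ))
  if (!is.null(x$readouts)) {
    r <- x$readouts
    cat(sprintf("  uptake=%.4g lactate=%.4g OCR=%.4g lipid=%.4g FA=%.4g ATP:ADP=%.3g\n",
                r$glucose_uptake, r$ECAR_proxy, r$OCR_proxy, r$lipid_flux,
                r$fa_flux, r$atp_adp_ratio))
  }
  invisible(x)
}

#' Independent flux-balance residual of a solved state
#'
#' Recomputes the time derivatives at `res$state` from scratch (stoichiometry
#' times freshly evaluated fluxes) and returns the maximum absolute value --
#' an audit of the solver's convergence claim that does not reuse any
#' quantity stored by the integrator.
#'
#' @param res A `ccm_steady_state`.
#' @param m,p Model and parameters (default: those stored in `res`).
#' @return Maximum absolute derivative (mM/h).
#' @export
flux_balance_residual <- function(res, m = res$model, p = res$parameters) {
  max(abs(compute_derivatives(res$state, p, m)))
}

#' Phenotype readouts of a converged steady state
#'
#' Deterministic arithmetic on the steady-state fluxes and concentrations:
#' `OCR_proxy` (total oxygen-consuming ETC flux, R19+R20), `ECAR_proxy`
#' (lactate export, R7), `atp_adp_ratio`, the anabolic branch fluxes
#' (`lipid_flux` R5, `ribose_flux` R2, `fa_flux` R18), the ATP-consuming load
#' (`atp_use_flux` R21), the TCA-cycle flux in both conventions used for the
#' respiration readout (`tca_flux_akgdh`, the alpha-ketoglutarate
#' dehydrogenase flux R12, and `tca_flux_etc`, the oxygen-dependent NADH
#' reoxidation flux R19), `glucose_uptake` (R1), `gln_uptake` (R14),
#' `akg_export_flux` (R22) and the mitochondrial `nad_ratio_m`.
#'
#' @param res A converged `ccm_steady_state`.
#' @return Named list of non-negative readouts.
#' @export
derived_readouts <- function(res) {
  if (!isTRUE(res$converged)) stop("derived_readouts: result is not converged")
  f <- res$fluxes
  s <- res$state
  p <- res$parameters
  adp <- p$pools$A_tot - s[["ATP"]]
  nad_m <- p$pools$N_tot_m - s[["NADH_m"]]
  extended <- res$model$variant == "extended"
  c(list(
    OCR_proxy = f[["R19"]] + f[["R20"]],
    ECAR_proxy = f[["R7"]],
    atp_adp_ratio = if (adp > 0) s[["ATP"]] / adp else Inf,
    lipid_flux = f[["R5"]],
    ribose_flux = f[["R2"]],
    fa_flux = f[["R18"]],
    atp_use_flux = f[["R21"]],
    tca_flux_akgdh = f[["R12"]],
    tca_flux_etc = f[["R19"]],
    glucose_uptake = f[["R1"]],
    gln_uptake = f[["R14"]],
    akg_export_flux = f[["R22"]],
    nad_ratio_m = if (s[["NADH_m"]] > 0) nad_m / s[["NADH_m"]] else Inf
  ),
  if (extended) {
    nadh_c <- s[["NADH_c"]]
    list(
      nad_ratio_c = if (nadh_c > 0) (p$pools$N_tot_c - nadh_c) / nadh_c else Inf,
      nad_use_flux = f[["R24"]]
    )
  })
}

#' Cytosolic redox readouts of the extended model
#'
#' The two quantities the dynamic-redox extension exists to report: the
#' cytosolic NAD+:NADH ratio, `(N_tot_c - NADH_c) / NADH_c`, and the
#' NAD+-use flux (R24) -- the proliferation-rate proxy when NAD+
#' availability, rather than carbon, limits biosynthesis.
#'
#' @param res A converged `ccm_steady_state` solved on the extended model.
#' @return List with `nad_ratio_c` and `nad_use_flux`.
#' @export
nad_readouts <- function(res) {
  if (res$model$variant != "extended") {
    stop("nad_readouts: requires a result from the extended model")
  }
  if (!isTRUE(res$converged)) stop("nad_readouts: result is not converged")
  res$readouts[c("nad_ratio_c", "nad_use_flux")]
}

#' ATP yield per glucose molecule
#'
#' Stoichiometric accounting at steady state: gross ATP production flux (the
#' substrate-level terms of lower glycolysis and the TCA GTP step plus the
#' P/O-weighted ETC fluxes) minus the ATP invested in glucose processing
#' (uptake/hexokinase and PFK), plus a shuttle credit of `n_shuttle` ATP per
#' net cytosolic NADH handed to the mitochondria (`max(0, R6 - R7)`), divided
#' by the glucose uptake flux. In the lactate-only regime the credit vanishes
#' and the yield is exactly 2 by stoichiometry; with full oxidation it is 30
#' (glycerol-3-phosphate shuttle accounting, `n_shuttle = n_F`) or 32
#' (malate-aspartate accounting, `n_shuttle = n_N`).
#'
#' @param res A converged `ccm_steady_state` solved with `Gln_ext = 0` (so all
#'   ATP traces to glucose) and positive glucose uptake.
#' @param p Parameters (default: stored in `res`).
#' @param n_shuttle ATP credited per net cytosolic NADH oxidised; defaults to
#'   `p$yields$n_shuttle`.
#' @return Dimensionless ATP-per-glucose ratio.
#' @export
atp_yield_per_glucose <- function(res, p = res$parameters,
                                  n_shuttle = p$yields$n_shuttle) {
  if (!isTRUE(res$converged)) stop("atp_yield_per_glucose: result not converged")
  f <- res$fluxes
  if (f[["R1"]] <= 0) stop("atp_yield_per_glucose: zero glucose uptake")
  if (p$environment$Gln_ext > 0 && f[["R14"]] > 1e-9) {
    stop("atp_yield_per_glucose: glutamine is being consumed; yield is not glucose-attributable")
  }
  gross <- 2 * f[["R6"]] + f[["R12"]] +
    p$yields$n_N * f[["R19"]] + p$yields$n_F * f[["R20"]]
  invested <- f[["R1"]] + f[["R3"]]
  credit <- n_shuttle * max(0, f[["R6"]] - f[["R7"]])
  (gross - invested + credit) / f[["R1"]]
}
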