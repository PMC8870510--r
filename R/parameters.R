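# Calibrated default parameter set.
#
# Kinetic constants for a lumped network of this kind are not identifiable
# from any single data source; the defaults below form one frozen, versioned
# calibration chosen so that every scenario in the preset catalogue reaches a
# bounded steady state and the qualitative regulatory behaviour (ATP-inhibited
# PFK with FBP product activation, oxygen-gated respiration, glutamine- and
# PC-driven anaplerosis) is expressed at realistic concentration scales
# (metabolites 0.01-5 mM, adenine pool 3 mM, fluxes of order 0.1-10 mM/h).
# See the methods vignette for the reasoning behind individual choices.

default_vmax <- c(
  R1 = 4, R2 = 0.4, R3 = 16, R4 = 20, R5 = 1.2, R6 = 60, R7 = 25,
  R8 = 3, R9 = 60, R10 = 20, R11 = 8, R12 = 20, R13 = 1, R14 = 0.4,
  R15 = 2, R16 = 3, R17 = 4, R18 = 8, R19 = 60, R20 = 60, R21 = 1,
  R22 = 0.3, R23 = 12, R24 = 8
)

default_km <- list(
  R1 = c(GLC_ext = 1, ATP = 0.3),
  R2 = c(F6P = 0.5, ATP = 0.6),
  R3 = c(F6P = 0.4),
  R4 = c(FBP = 1),
  R5 = c(TP = 0.1, ATP = 0.6),
  R6 = c(TP = 0.15, ADP = 0.02, NAD_c = 0.05),
  R7 = c(PYR = 0.5, NADH_c = 0.02),
  R8 = c(PYR = 0.3, NAD_m = 0.1),
  R9 = c(ACCOA_m = 0.1, OAA_m = 0.05),
  R10 = c(CIT_m = 0.3, NAD_m = 0.1),
  R11 = c(AKG_m = 0.3),
  R12 = c(AKG_m = 0.3, NAD_m = 0.1, FAD_m = 0.1, ADP = 0.15),
  R13 = c(k_f = 40, k_r = 2000),
  R14 = c(GLN_ext = 0.5, NAD_m = 0.1),
  R15 = c(PYR = 0.5, ATP = 0.15),
  R16 = c(MAL_m = 0.3, NAD_m = 0.02),
  R17 = c(CIT_m = 0.3, ATP = 0.15),
  R18 = c(ACCOA_c = 0.2, ATP = 0.15),
  R19 = c(NADH_m = 0.2, O2 = 0.05, ADP = 0.1),
  R20 = c(FADH2_m = 0.2, O2 = 0.05, ADP = 0.1),
  R21 = c(ATP = 1),
  R22 = c(AKG_m = 1),
  R23 = c(NADH_c = 0.2),
  R24 = c(NAD_c = 0.1, TP = 0.3)
)

default_activity <- function(m) {
  keys <- unique(vapply(m$reactions, `[[`, "", "activity_key"))
  a <- stats::setNames(rep(1, length(keys)), keys)
  # Reductive carboxylation is an induced pathway: NADPH is untracked, so a
  # resting R10/R11 cycle would be an unpaid NADH source. Hypoxia scenarios
  # switch it on explicitly.
  if ("IDH_NADPH" %in% keys) a[["IDH_NADPH"]] <- 0
  a
}

#' Default calibrated parameter set
#'
#' Returns the frozen default `ccm_parameters` for a model: base maximal rates
#' (mM/h), half-saturation constants (mM), the PFK regulation constants,
#' environment settings (extracellular glucose and glutamine, oxygen
#' saturation, ATP-demand rate), conserved pool totals, ATP-yield (P/O)
#' coefficients, and per-enzyme activity multipliers (all 1 except the
#' inducible NADPH-dependent IDH, which defaults to 0).
#'
#' @param m A `ccm_model` from [build_default_network()] or
#'   [build_extended_network()].
#' @return A `ccm_parameters` object (a validated list with components
#'   `vmax`, `km`, `regulation`, `environment`, `pools`, `yields`, `activity`).
#' @examples
#' p <- default_parameters(build_default_network())
#' p$yields$n_N   # ATP credited per mitochondrial NADH oxidised
#' @export
default_parameters <- function(m = build_default_network()) {
  rids <- reaction_ids(m)
  p <- list(
    vmax = default_vmax[rids],
    km = default_km[rids],
    regulation = list(
      K_I_ATP = 1.6, n_ATP = 6,
      K_A_FBP = 0.05, n_FBP = 4, amp_FBP = 8
    ),
    environment = list(
      Glc_ext = 5, Gln_ext = 2, O2 = 1,
      k_use = 6, basal_load = 0.1, leak_rate = 0.2
    ),
    pools = list(
      A_tot = 3, N_tot_m = 1, F_tot_m = 1, r_NAD_c = 10, N_tot_c = 0.6
    ),
    yields = list(n_N = 2.5, n_F = 1.5, n_shuttle = 1.5),
    activity = default_activity(m)
  )
  class(p) <- "ccm_parameters"
  validate_parameters(p, m)
  p
}

validate_parameters <- function(p, m = NULL) {
  stopifnot(is.list(p))
  if (any(p$vmax < 0)) stop("vmax values must be >= 0")
  if (any(unlist(p$km) <= 0)) stop("km values must be > 0")
  r <- p$regulation
  if (r$K_I_ATP <= 0 || r$K_A_FBP <= 0) stop("regulation constants must be > 0")
  if (r$n_ATP < 1 || r$n_FBP < 1) stop("Hill exponents must be >= 1")
  if (r$amp_FBP < 1) stop("amp_FBP must be >= 1")
  e <- p$environment
  if (e$O2 < 0 || e$O2 > 1) stop("O2 must lie in [0, 1]")
  if (e$Glc_ext < 0 || e$Gln_ext < 0) stop("external nutrient levels must be >= 0")
  if (e$k_use < 0 || e$basal_load < 0 || e$leak_rate < 0) {
    stop("load rates must be >= 0")
  }
  if (any(unlist(p$pools) <= 0)) stop("pool totals must be > 0")
  y <- p$yields
  if (y$n_N <= 0 || y$n_F <= 0) stop("yield coefficients must be > 0")
  if (y$n_F > y$n_N) stop("n_F must not exceed n_N")
  if (!isTRUE(all.equal(y$n_shuttle, y$n_F)) &&
      !isTRUE(all.equal(y$n_shuttle, y$n_N))) {
    stop("n_shuttle must equal n_F or n_N")
  }
  if (any(p$activity < 0)) stop("activity multipliers must be >= 0")
  if (!is.null(m)) {
    keys <- unique(vapply(m$reactions, `[[`, "", "activity_key"))
    missing <- setdiff(keys, names(p$activity))
    if (length(missing) > 0) {
      stop("activity multipliers missing for: ", paste(missing, collapse = ", "))
    }
  }
  invisible(p)
}

#' @export
print.ccm_parameters <- function(x, ...) {
  e <- x$environment
  cat("<ccm_parameters>\n")
  cat(sprintf("  environment: Glc_ext=%g Gln_ext=%g O2=%g k_use=%g basal_load=%g (mM, mM/h)\n",
              e$Glc_ext, e$Gln_ext, e$O2, e$k_use, e$basal_load))
  cat(sprintf("  pools: A_tot=%g N_tot_m=%g F_tot_m=%g r_NAD_c=%g\n",
              x$pools$A_tot, x$pools$N_tot_m, x$pools$F_tot_m, x$pools$r_NAD_c))
  cat(sprintf("  yields: n_N=%g n_F=%g n_shuttle=%g ATP per carrier\n",
              x$yields$n_N, x$yields$n_F, x$yields$n_shuttle))
  nondef <- x$activity[x$activity != 1]
  if (length(nondef) > 0) {
    cat("  non-unit activities:",
        paste(sprintf("%s=%g", names(nondef), nondef), collapse = " "), "\n")
  }
  invisible(x)
}

#' Scale an enzyme activity multiplier
#'
#' Up/down-regulation of an enzyme is modelled as a multiplicative factor on
#' the reaction's maximal velocity. Returns a modified copy; the input is
#' unchanged.
#'
#' @param p A `ccm_parameters` object.
#' @param activity_key Name of the multiplier (e.g. `"LDH"`, `"PDH"`).
#' @param factor Non-negative fold-change applied multiplicatively.
#' @return The modified `ccm_parameters`.
#' @examples
#' p <- default_parameters()
#' p2 <- scale_activity(p, "LDH", 10)
#' p2$activity[["LDH"]] / p$activity[["LDH"]]
#' @export
scale_activity <- function(p, activity_key, factor) {
  if (factor < 0) stop("scale_activity: factor must be >= 0")
  if (!activity_key %in% names(p$activity)) {
    stop(sprintf("unknown activity key '%s'; valid keys: %s",
                 activity_key, paste(names(p$activity), collapse = ", ")))
  }
  p$activity[[activity_key]] <- p$activity[[activity_key]] * factor
  p
}

# Set an activity multiplier to an absolute value (presets use this so the
# configuration is independent of the current value).
set_activity <- function(p, activity_key, value) {
  p$activity[[activity_key]] <- 1
  scale_activity(p, activity_key, value)
}

# Set an environment field with validation.
set_environment <- function(p, name, value) {
  if (!name %in% names(p$environment)) {
    stop(sprintf("unknown environment setting '%s'; valid: %s",
                 name, paste(names(p$environment), collapse = ", ")))
  }
  p$environment[[name]] <- value
  validate_parameters(p)
  p
}

#' Default initial state
#'
#' A strictly interior starting concentration vector (mM) for the dynamic
#' species; pool-bounded species start at roughly half their totals. The
#' glycolytic switch is bistable over part of parameter space, so the
#' starting basin matters and is chosen explicitly: the `"resting"` regime
#' starts FBP below the PFK activation threshold (the switch disengaged),
#' the `"proliferative"` regime starts with the switch engaged (FBP above
#' threshold, glycolytic intermediates charged).
#'
#' @param m A `ccm_model`.
#' @param p A `ccm_parameters` (pool totals bound the carrier species).
#' @param regime `"resting"` (default) or `"proliferative"`.
#' @return Named numeric vector over the model's dynamic species.
#' @export
default_initial_state <- function(m, p = default_parameters(m),
                                  regime = c("resting", "proliferative")) {
  regime <- match.arg(regime)
  init <- if (regime == "resting") {
    c(F6P = 0.2, FBP = 0.01, TP = 0.05, PYR = 0.1, ACCOA_c = 0.1, CIT_c = 0.1,
      ATP = 0.5 * p$pools$A_tot, ACCOA_m = 0.1, OAA_m = 0.05, CIT_m = 0.3,
      AKG_m = 0.3, MAL_m = 0.3, NADH_m = 0.3 * p$pools$N_tot_m,
      FADH2_m = 0.3 * p$pools$F_tot_m)
  } else {
    c(F6P = 0.5, FBP = 0.3, TP = 0.3, PYR = 0.5, ACCOA_c = 0.1, CIT_c = 0.1,
      ATP = 0.5 * p$pools$A_tot, ACCOA_m = 0.1, OAA_m = 0.05, CIT_m = 0.3,
      AKG_m = 0.3, MAL_m = 0.3, NADH_m = 0.3 * p$pools$N_tot_m,
      FADH2_m = 0.3 * p$pools$F_tot_m)
  }
  if (m$variant == "extended") {
    init <- c(init, NADH_c = p$pools$N_tot_c / (1 + p$pools$r_NAD_c))
  }
  init[dynamic_species(m)]
}

# State invariant checks (non-negative, pool-bounded).
validate_state <- function(state, m, p, tol = 1e-9) {
  dyn <- dynamic_species(m)
  if (!all(dyn %in% names(state))) {
    stop("state is missing species: ",
         paste(setdiff(dyn, names(state)), collapse = ", "))
  }
  if (any(!is.finite(state[dyn]))) stop("non-finite concentration in state")
  if (any(state[dyn] < -tol)) stop("negative concentration in state")
  if (state[["ATP"]] > p$pools$A_tot + tol) stop("ATP exceeds adenine pool total")
  if (state[["NADH_m"]] > p$pools$N_tot_m + tol) stop("NADH_m exceeds NAD pool total")
  if (state[["FADH2_m"]] > p$pools$F_tot_m + tol) stop("FADH2_m exceeds FAD pool total")
  if ("NADH_c" %in% dyn && state[["NADH_c"]] > p$pools$N_tot_c + tol) {
    stop("NADH_c exceeds cytosolic NAD pool total")
  }
  invisible(state)
}
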