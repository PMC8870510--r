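# Flux assembly.
#
# For speed inside the integrator, the (model, parameters) pair is compiled
# once into a flat evaluation plan: for each reaction a template code, integer
# indices into an augmented concentration vector (dynamic state + derived
# pool complements + environment), half-saturation constants, the effective
# Vmax (base rate x activity multiplier) and any modifier terms. The public
# compute_fluxes()/compute_derivatives() build the plan on the fly.

TEMPLATE_SAT <- 1L
TEMPLATE_PFK <- 2L
TEMPLATE_MDH <- 3L
TEMPLATE_ETC <- 4L
TEMPLATE_LOAD <- 5L

# Names of derived/environment entries appended after the dynamic species.
augmented_names <- function(m) {
  c(dynamic_species(m), "ADP", "NAD_m", "FAD_m", "NAD_c",
    "GLC_ext", "GLN_ext", "O2")
}

# Fill the derived + environment tail of the augmented vector.
augment_state <- function(state, p, m, xnames) {
  x <- numeric(length(xnames))
  names(x) <- xnames
  dyn <- dynamic_species(m)
  x[dyn] <- pmax(state[dyn], 0)
  x[["ADP"]] <- max(p$pools$A_tot - x[["ATP"]], 0)
  x[["NAD_m"]] <- max(p$pools$N_tot_m - x[["NADH_m"]], 0)
  x[["FAD_m"]] <- max(p$pools$F_tot_m - x[["FADH2_m"]], 0)
  x[["NAD_c"]] <- if (m$variant == "extended") {
    max(p$pools$N_tot_c - x[["NADH_c"]], 0)
  } else {
    # fixed cytosolic redox poise in the baseline model
    p$pools$N_tot_c * p$pools$r_NAD_c / (1 + p$pools$r_NAD_c)
  }
  x[["GLC_ext"]] <- p$environment$Glc_ext
  x[["GLN_ext"]] <- p$environment$Gln_ext
  x[["O2"]] <- p$environment$O2
  x
}

flux_plan <- function(m, p) {
  xnames <- augmented_names(m)
  idx_of <- function(ids) {
    i <- match(ids, xnames)
    if (anyNA(i)) stop("unknown species referenced: ",
                       paste(ids[is.na(i)], collapse = ", "))
    i
  }
  plans <- lapply(m$reactions, function(r) {
    v <- p$vmax[[r$reaction_id]] * p$activity[[r$activity_key]]
    type <- switch(r$rate_template,
      saturating = TEMPLATE_SAT, saturating2 = TEMPLATE_SAT,
      pfk = TEMPLATE_PFK, reversible_mdh = TEMPLATE_MDH,
      etc = TEMPLATE_ETC, load = TEMPLATE_LOAD,
      stop("unknown rate template: ", r$rate_template)
    )
    kmv <- p$km[[r$reaction_id]]
    pl <- list(type = type, v = v, km = unname(kmv))
    if (type == TEMPLATE_SAT || type == TEMPLATE_ETC) {
      if (!all(r$substrates %in% names(kmv))) {
        stop(r$reaction_id, ": km entries missing for declared substrates")
      }
      kmv <- kmv[r$substrates]
      pl$km <- unname(kmv)
      pl$idx <- idx_of(names(kmv))
    } else if (type == TEMPLATE_PFK) {
      pl$idx <- idx_of(c("F6P", "ATP", "FBP"))
      pl$km <- kmv[["F6P"]]
      pl$reg <- p$regulation
    } else if (type == TEMPLATE_MDH) {
      pl$idx <- idx_of(c("MAL_m", "NAD_m", "OAA_m", "NADH_m"))
      pl$kf <- kmv[["k_f"]]; pl$kr <- kmv[["k_r"]]
    } else if (type == TEMPLATE_LOAD) {
      pl$idx <- idx_of("ATP")
      pl$km <- kmv[["ATP"]]
      pl$basal <- p$environment$basal_load
      pl$k_use <- p$environment$k_use
      pl$leak <- p$environment$leak_rate
    }
    pl$mods <- lapply(r$modifiers, function(mod) {
      list(idx = idx_of(mod$species), role = mod$role,
           k = mod$k, n = mod$n, amp = mod$amp)
    })
    pl
  })
  list(xnames = xnames, plans = plans, rids = reaction_ids(m))
}

eval_fluxes <- function(x, plan) {
  plans <- plan$plans
  flux <- numeric(length(plans))
  for (i in seq_along(plans)) {
    pl <- plans[[i]]
    type <- pl$type
    if (type == TEMPLATE_SAT || type == TEMPLATE_ETC) {
      s <- x[pl$idx]
      f <- pl$v * prod(s / (pl$km + s))
    } else if (type == TEMPLATE_PFK) {
      s <- x[pl$idx]
      reg <- pl$reg
      fbpn <- s[3]^reg$n_FBP
      f <- pl$v * s[1] / (pl$km + s[1]) *
        1 / (1 + (s[2] / reg$K_I_ATP)^reg$n_ATP) *
        (1 + (reg$amp_FBP - 1) * fbpn / (reg$K_A_FBP^reg$n_FBP + fbpn))
    } else if (type == TEMPLATE_MDH) {
      s <- x[pl$idx]
      f <- pl$v * (pl$kf * s[1] * s[2] - pl$kr * s[3] * s[4])
    } else { # load
      atp <- x[pl$idx]
      # the whole load vanishes as ATP -> 0 (no substrate, no consumption)
      f <- pl$v * (pl$basal + pl$k_use * atp / (pl$km + atp) + pl$leak * atp) *
        atp / (0.01 + atp)
    }
    for (mod in pl$mods) {
      xm <- x[mod$idx]
      f <- f * if (mod$role == "inhibitor") {
        1 / (1 + (xm / mod$k)^mod$n)
      } else {
        xn <- xm^mod$n
        1 + (mod$amp - 1) * xn / (mod$k^mod$n + xn)
      }
    }
    flux[i] <- f
  }
  names(flux) <- plan$rids
  flux
}

#' Evaluate all reaction fluxes at a state
#'
#' Assembles the full flux vector (mM/h): each reaction's rate-law template
#' evaluated at the given concentrations with its activity multiplier applied.
#' Deterministic; all fluxes are non-negative except the reversible malate
#' dehydrogenase (R13), whose sign gives the net direction.
#'
#' @param state Named concentration vector over the model's dynamic species (mM).
#' @param p A `ccm_parameters`.
#' @param m A `ccm_model`.
#' @return Named flux vector, one entry per reaction.
#' @examples
#' m <- build_default_network(); p <- default_parameters(m)
#' compute_fluxes(default_initial_state(m, p), p, m)
#' @export
compute_fluxes <- function(state, p, m) {
  validate_state(state, m, p)
  plan <- flux_plan(m, p)
  eval_fluxes(augment_state(state, p, m, plan$xnames), plan)
}

#' Time derivatives of all dynamic species
#'
#' `dC/dt = S %*% flux` with the stoichiometric matrix assembled from the
#' carbon stoichiometry, the ATP ledger (including the P/O yield coefficients
#' on the two ETC entries) and the redox-carrier ledger. In the clamped-ATP
#' variant the ATP row is zeroed. In the baseline model cytosolic NADH is not
#' a state: its turnover enters only the yield accounting.
#'
#' @inheritParams compute_fluxes
#' @return Named vector of rates (mM/h), one per dynamic species.
#' @export
compute_derivatives <- function(state, p, m) {
  flux <- compute_fluxes(state, p, m)
  S <- stoichiometry_matrix(m, p$yields)
  drop(S %*% flux)
}
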