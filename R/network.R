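# Network catalogue: species, reactions, stoichiometry, regulation.
#
# Concentrations are mM, fluxes mM/h, time h. Carbon is tracked per molecule
# (CO2 and the excretion/biosynthesis sinks included) so every reaction can be
# audited for carbon balance. ATP and the redox carriers are kept in separate
# stoichiometric ledgers (atp_stoich, redox_stoich) on top of the carbon
# stoichiometry; ADP, NAD+_m, FAD_m (and NAD+_c in the extended model) are
# derived from conserved pool totals, never stored as state.

new_species <- function(species_id, compartment, carbons, pool_id = NA_character_) {
  data.frame(
    species_id = species_id, compartment = compartment,
    carbons = as.integer(carbons), pool_id = pool_id,
    stringsAsFactors = FALSE
  )
}

new_reaction <- function(reaction_id, name, stoich = numeric(), atp_stoich = 0,
                         atp_yield_key = NA_character_, redox_stoich = numeric(),
                         rate_template = "saturating", substrates = character(),
                         modifiers = list(), activity_key) {
  list(
    reaction_id = reaction_id, name = name, stoich = stoich,
    atp_stoich = atp_stoich, atp_yield_key = atp_yield_key,
    redox_stoich = redox_stoich, rate_template = rate_template,
    substrates = substrates, modifiers = modifiers, activity_key = activity_key
  )
}

species_table <- function(extended = FALSE) {
  sp <- rbind(
    new_species("F6P", "cytosol", 6),
    new_species("FBP", "cytosol", 6),
    new_species("TP", "cytosol", 3),
    new_species("PYR", "cytosol", 3),
    new_species("ACCOA_c", "cytosol", 2),
    new_species("CIT_c", "cytosol", 6),
    new_species("ATP", "cytosol", 0, "adenine"),
    new_species("ACCOA_m", "mitochondrion", 2),
    new_species("OAA_m", "mitochondrion", 4),
    new_species("CIT_m", "mitochondrion", 6),
    new_species("AKG_m", "mitochondrion", 5),
    new_species("MAL_m", "mitochondrion", 4),
    new_species("NADH_m", "mitochondrion", 0, "mito_NAD"),
    new_species("FADH2_m", "mitochondrion", 0, "mito_FAD")
  )
  if (extended) sp <- rbind(sp, new_species("NADH_c", "cytosol", 0, "cyto_NAD"))
  rbind(
    sp,
    new_species("GLC_ext", "boundary", 6),
    new_species("GLN_ext", "boundary", 5),
    new_species("CO2", "boundary", 1),
    new_species("NH3", "boundary", 0),
    new_species("LAC", "sink", 3),
    new_species("RIBOSE", "sink", 5),
    new_species("PLIPID", "sink", 3),
    new_species("FA", "sink", 2),
    new_species("AKG_sink", "sink", 5)
  )
}

reaction_catalogue <- function(extended = FALSE) {
  rx <- list(
    new_reaction("R1", "glucose uptake + hexokinase (lumped upper glycolysis)",
      stoich = c(GLC_ext = -1, F6P = 1), atp_stoich = -1,
      substrates = c("GLC_ext", "ATP"),
      modifiers = list(
        # product feedback of the lumped upper-glycolysis step: hexose
        # phosphate accumulation throttles uptake (hexokinase G6P inhibition)
        list(species = "F6P", role = "inhibitor", k = 0.5, n = 2),
        # reduced-order backpressure from the lower pathway (stands for the
        # PK<-PYR ... HK<-G6P product-inhibition chain of the unlumped pathway)
        list(species = "PYR", role = "inhibitor", k = 3, n = 2)
      ),
      activity_key = "GLUT1"
    ),
    new_reaction("R2", "ribose synthesis branch (oxidative PPP entry)",
      stoich = c(F6P = -1, RIBOSE = 1, CO2 = 1), atp_stoich = -1,
      substrates = c("F6P", "ATP"), activity_key = "RIB"
    ),
    new_reaction("R3", "phosphofructokinase",
      stoich = c(F6P = -1, FBP = 1), atp_stoich = -1,
      rate_template = "pfk", substrates = "F6P", activity_key = "PFK"
    ),
    new_reaction("R4", "aldolase",
      stoich = c(FBP = -1, TP = 2), substrates = "FBP", activity_key = "ALD"
    ),
    new_reaction("R5", "phospholipid synthesis branch",
      stoich = c(TP = -1, PLIPID = 1), atp_stoich = -1,
      substrates = c("TP", "ATP"), activity_key = "LIP"
    ),
    new_reaction("R6", "lower glycolysis (GAPDH..PK lump)",
      stoich = c(TP = -1, PYR = 1), atp_stoich = 2,
      redox_stoich = c(NADH_c = 1),
      # ADP is a substrate (phosphoglycerate kinase / pyruvate kinase):
      # substrate-level phosphorylation halts when the pool is fully charged
      substrates = if (extended) c("TP", "ADP", "NAD_c") else c("TP", "ADP"),
      activity_key = "GAPDH"
    ),
    new_reaction("R7", "lactate dehydrogenase + lactate export",
      stoich = c(PYR = -1, LAC = 1), redox_stoich = c(NADH_c = -1),
      substrates = if (extended) c("PYR", "NADH_c") else "PYR",
      activity_key = "LDH"
    ),
    new_reaction("R8", "pyruvate dehydrogenase",
      stoich = c(PYR = -1, ACCOA_m = 1, CO2 = 1), redox_stoich = c(NADH_m = 1),
      substrates = c("PYR", "NAD_m"),
      modifiers = list(
        # PDH product inhibition by acetyl-CoA: mitochondrial entry halts
        # when the downstream condensation step is oxaloacetate-starved
        list(species = "ACCOA_m", role = "inhibitor", k = 0.5, n = 2)
      ),
      activity_key = "PDH"
    ),
    new_reaction("R9", "citrate synthase",
      stoich = c(ACCOA_m = -1, OAA_m = -1, CIT_m = 1),
      rate_template = "saturating2", substrates = c("ACCOA_m", "OAA_m"),
      activity_key = "CS"
    ),
    new_reaction("R10", "NAD+-dependent isocitrate dehydrogenase (oxidative)",
      stoich = c(CIT_m = -1, AKG_m = 1, CO2 = 1), redox_stoich = c(NADH_m = 1),
      substrates = c("CIT_m", "NAD_m"), activity_key = "IDH"
    ),
    new_reaction("R11", "NADPH-dependent IDH (reductive carboxylation)",
      stoich = c(AKG_m = -1, CO2 = -1, CIT_m = 1),
      substrates = "AKG_m", activity_key = "IDH_NADPH"
    ),
    new_reaction("R12", "AKGDH + SCS + SDH + fumarase (lumped TCA span)",
      stoich = c(AKG_m = -1, MAL_m = 1, CO2 = 1), atp_stoich = 1,
      redox_stoich = c(NADH_m = 1, FADH2_m = 1),
      substrates = c("AKG_m", "NAD_m", "FAD_m", "ADP"),
      modifiers = list(
        # product inhibition by malate: the span stalls when its product
        # accumulates, propagating downstream congestion back to the
        # glutamine entry point instead of accumulating malate without bound
        list(species = "MAL_m", role = "inhibitor", k = 1, n = 2)
      ),
      activity_key = "AKGDH"
    ),
    new_reaction("R13", "malate dehydrogenase (reversible)",
      stoich = c(MAL_m = -1, OAA_m = 1), redox_stoich = c(NADH_m = 1),
      rate_template = "reversible_mdh", substrates = character(),
      activity_key = "MDH"
    ),
    new_reaction("R14", "glutaminase + glutamate dehydrogenase (lumped)",
      stoich = c(GLN_ext = -1, AKG_m = 1, NH3 = 2), redox_stoich = c(NADH_m = 1),
      substrates = c("GLN_ext", "NAD_m"),
      modifiers = list(
        # product inhibition: accumulated alpha-ketoglutarate throttles
        # glutamine entry so the anaplerotic influx stays bounded when the
        # downstream TCA span stalls
        list(species = "AKG_m", role = "inhibitor", k = 1.5, n = 2)
      ),
      activity_key = "GLS"
    ),
    new_reaction("R15", "pyruvate carboxylase",
      stoich = c(PYR = -1, CO2 = -1, OAA_m = 1), atp_stoich = -1,
      substrates = c("PYR", "ATP"),
      modifiers = list(
        # product inhibition: anaplerotic OAA synthesis stands down when
        # oxaloacetate is already plentiful (PC is tightly regulated in vivo)
        list(species = "OAA_m", role = "inhibitor", k = 0.05, n = 2)
      ),
      activity_key = "PC"
    ),
    new_reaction("R16", "malic enzyme 2",
      stoich = c(MAL_m = -1, PYR = 1, CO2 = 1), redox_stoich = c(NADH_m = 1),
      substrates = c("MAL_m", "NAD_m"), activity_key = "ME2"
    ),
    new_reaction("R17", "citrate export + ATP-citrate lyase (OAA returned as malate)",
      stoich = c(CIT_m = -1, ACCOA_c = 1, MAL_m = 1), atp_stoich = -1,
      substrates = c("CIT_m", "ATP"), activity_key = "ACLY"
    ),
    new_reaction("R18", "ACC + fatty-acid synthesis",
      stoich = c(ACCOA_c = -1, FA = 1), atp_stoich = -1,
      substrates = c("ACCOA_c", "ATP"), activity_key = "ACC"
    ),
    new_reaction("R19", "electron transport chain, NADH entry",
      redox_stoich = c(NADH_m = -1), atp_yield_key = "n_N",
      rate_template = "etc", substrates = c("NADH_m", "O2", "ADP"),
      activity_key = "ETC"
    ),
    new_reaction("R20", "electron transport chain, FADH2 entry",
      redox_stoich = c(FADH2_m = -1), atp_yield_key = "n_F",
      rate_template = "etc", substrates = c("FADH2_m", "O2", "ADP"),
      activity_key = "ETC"
    ),
    new_reaction("R21", "ATP-consuming load (housekeeping + demand)",
      atp_stoich = -1, rate_template = "load", substrates = "ATP",
      activity_key = "LOAD"
    ),
    new_reaction("R22", "alpha-ketoglutarate export",
      stoich = c(AKG_m = -1, AKG_sink = 1), substrates = "AKG_m",
      activity_key = "AKGEXP"
    )
  )
  if (extended) {
    rx <- c(rx, list(
      new_reaction("R23", "glycerol-3-phosphate shuttle (electrons to FAD level)",
        redox_stoich = c(NADH_c = -1, FADH2_m = 1),
        substrates = "NADH_c", activity_key = "SHUTTLE"
      ),
      new_reaction("R24", "cytosolic NAD+-use flux (biosynthetic demand)",
        # oxidative biosynthetic demand: consumes NAD+ while oxidising a
        # glycolytic carbon intermediate, so the proliferation proxy needs
        # both redox capacity and carbon substrate
        redox_stoich = c(NADH_c = 1),
        substrates = c("NAD_c", "TP"), activity_key = "NADUSE"
      )
    ))
  }
  names(rx) <- vapply(rx, `[[`, "", "reaction_id")
  rx
}

#' Build the baseline metabolic network
#'
#' Constructs the reaction network covering glycolysis with its anabolic
#' branch points (ribose and phospholipid synthesis), the pyruvate fate
#' branch (LDH vs PDH), the TCA cycle, a simplified two-entry electron
#' transport chain, glutaminolysis, and the anaplerotic routes (pyruvate
#' carboxylase, reductive carboxylation, malic enzyme) plus citrate export
#' to fatty-acid synthesis, an ATP-consuming load, and alpha-ketoglutarate
#' export. 22 reactions over 14 dynamic species; in the baseline variant the
#' cytosolic NAD+:NADH ratio is held fixed (its turnover is recorded for
#' yield accounting only).
#'
#' @param clamp_atp If `TRUE`, the ATP concentration is held constant during
#'   integration (its time derivative is zeroed), the modelling device used to
#'   study glycolytic branch fluxes decoupled from energy feedback.
#' @return A `ccm_model` object: species table, reaction catalogue, variant.
#' @examples
#' m <- build_default_network()
#' nrow(m$species[m$species$compartment %in% c("cytosol", "mitochondrion"), ])
#' @seealso [build_extended_network()], [reaction_carbon_residuals()]
#' @export
build_default_network <- function(clamp_atp = FALSE) {
  m <- list(
    variant = "baseline",
    clamp_atp = isTRUE(clamp_atp),
    species = species_table(extended = FALSE),
    reactions = reaction_catalogue(extended = FALSE)
  )
  class(m) <- "ccm_model"
  m
}

#' Build the extended network with dynamic cytosolic redox
#'
#' Baseline catalogue plus: cytosolic NADH becomes a dynamic species (conserved
#' pool `N_tot_c`); lower glycolysis consumes cytosolic NAD+ and LDH consumes
#' cytosolic NADH; R23 is the glycerol-3-phosphate shuttle delivering cytosolic
#' NADH electrons to the mitochondrial FAD pool; R24 is a saturating cytosolic
#' NAD+-use flux standing for NAD+-consuming biosynthetic demand (its flux is
#' the proliferation proxy when redox capacity, not carbon, is limiting).
#'
#' @inheritParams build_default_network
#' @return A `ccm_model` with `variant = "extended"`.
#' @export
build_extended_network <- function(clamp_atp = FALSE) {
  m <- list(
    variant = "extended",
    clamp_atp = isTRUE(clamp_atp),
    species = species_table(extended = TRUE),
    reactions = reaction_catalogue(extended = TRUE)
  )
  class(m) <- "ccm_model"
  m
}

#' @export
print.ccm_model <- function(x, ...) {
  dyn <- dynamic_species(x)
  cat(sprintf(
    "<ccm_model> %s variant%s: %d reactions, %d dynamic species\n",
    x$variant, if (x$clamp_atp) " (ATP clamped)" else "",
    length(x$reactions), length(dyn)
  ))
  cat("  dynamic:", paste(dyn, collapse = ", "), "\n")
  invisible(x)
}

# Dynamic (state-carrying) species ids, in canonical state order.
dynamic_species <- function(m) {
  m$species$species_id[m$species$compartment %in% c("cytosol", "mitochondrion")]
}

reaction_ids <- function(m) names(m$reactions)

#' Per-reaction carbon balance residuals
#'
#' Audits the catalogue: for every reaction, sums signed stoichiometric
#' coefficient times carbon count over all participating species (CO2 and the
#' boundary/sink species included). A balanced catalogue returns all zeros;
#' electron-only and phosphate-only reactions (ETC, load, shuttle, NAD+-use)
#' move no carbon and are zero by construction.
#'
#' @param m A `ccm_model`.
#' @return Named numeric vector, one signed residual (carbons per event) per
#'   reaction.
#' @export
reaction_carbon_residuals <- function(m) {
  carbons <- stats::setNames(m$species$carbons, m$species$species_id)
  vapply(m$reactions, function(r) {
    st <- r$stoich
    if (length(st) == 0) return(0)
    unknown <- setdiff(names(st), names(carbons))
    if (length(unknown) > 0) {
      stop("unknown species in stoichiometry: ", paste(unknown, collapse = ", "))
    }
    sum(st * carbons[names(st)])
  }, numeric(1))
}

# Stoichiometric matrix over dynamic species (rows) x reactions (columns),
# with the ATP row assembled from atp_stoich plus the P/O yield coefficients
# and the carrier rows from redox_stoich. `yields` is p$yields.
stoichiometry_matrix <- function(m, yields) {
  dyn <- dynamic_species(m)
  rids <- reaction_ids(m)
  S <- matrix(0, nrow = length(dyn), ncol = length(rids),
              dimnames = list(dyn, rids))
  for (r in m$reactions) {
    st <- r$stoich[names(r$stoich) %in% dyn]
    if (length(st) > 0) S[names(st), r$reaction_id] <- st
    a <- r$atp_stoich
    if (!is.na(r$atp_yield_key)) a <- a + yields[[r$atp_yield_key]]
    if (a != 0) S["ATP", r$reaction_id] <- S["ATP", r$reaction_id] + a
    rs <- r$redox_stoich[names(r$redox_stoich) %in% dyn]
    if (length(rs) > 0) {
      S[names(rs), r$reaction_id] <- S[names(rs), r$reaction_id] + rs
    }
  }
  if (m$clamp_atp) S["ATP", ] <- 0
  S
}
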