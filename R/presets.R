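# Scenario presets: each named preset runs a scripted in-silico experiment
# (a sweep, grid, or paired comparison) with the frozen default parameter
# set plus the scenario's stated condition overrides, returns tidy tables,
# and embeds the qualitative assertion(s) the scenario is expected to
# satisfy, so validate_model() can run them all.
#
# Scenario conventions, chosen once and documented in the methods vignette:
# - "hypoxia" means O2 = 0.003 (0.3% of saturating); "anoxia" means O2 = 0.
# - anoxic scenarios silence pyruvate carboxylase: with the ETC off, reverse
#   MDH is the only NADH sink, and carboxylation-derived carbon would
#   accumulate as malate without bound.
# - scenarios whose claim is a smooth dose-response (crossover maps, anoxic
#   load, yield accounting) run with the FBP activation silenced
#   (amp_FBP = 1): the allosteric switch creates hysteretic jumps and
#   relaxation oscillations that are the subject of the hysteresis preset,
#   not of these claims.
# - "high" activity means a 10-fold multiplier, "low" 0.1-fold, matching the
#   Warburg/OXPHOS phenotype definitions.

preset_opts <- function() solver_options(t_max = 2e3)

silence_fbp <- function(p) {
  p$regulation$amp_FBP <- 1
  p
}

assertion <- function(pass, detail) list(pass = isTRUE(pass), detail = detail)

new_preset_result <- function(preset, tables, assertions, parameters) {
  structure(list(preset = preset, tables = tables, assertions = assertions,
                 parameters = parameters),
            class = "ccm_preset_result")
}

#' @export
print.ccm_preset_result <- function(x, ...) {
  ok <- vapply(x$assertions, `[[`, TRUE, "pass")
  cat(sprintf("<ccm_preset_result> %s: %d/%d assertions pass\n",
              x$preset, sum(ok), length(ok)))
  for (nm in names(x$assertions)) {
    a <- x$assertions[[nm]]
    cat(sprintf("  [%s] %s: %s\n", if (a$pass) "ok" else "FAIL", nm, a$detail))
  }
  invisible(x)
}

# increasing/decreasing helpers tolerant of flagged unconverged points
conv_vals <- function(tab, col) {
  v <- tab[[col]][tab$converged]
  v[is.finite(v)]
}

mostly_monotone <- function(v, direction = 1, slack = 0.02) {
  if (length(v) < 2) return(FALSE)
  d <- direction * diff(v)
  all(d >= -slack * pmax(abs(v[-length(v)]), 1e-12))
}

# -- individual presets ------------------------------------------------------

preset_uptake_anabolic <- function(opts) {
  m <- build_default_network(clamp_atp = TRUE)
  p <- silence_fbp(default_parameters(m))
  sw <- run_sweep(m, p, sweep_spec("activity.GLUT1",
                                   10^seq(-0.7, 0.7, length.out = 15), "up"),
                  opts = opts)
  rib <- conv_vals(sw$table, "ribose_flux")
  lip <- conv_vals(sw$table, "lipid_flux")
  new_preset_result("uptake-anabolic", list(sweep = sw$table), list(
    ribose_increases_with_uptake = assertion(
      mostly_monotone(rib, 1, 0.02) && rib[length(rib)] > rib[1],
      sprintf("ribose flux %.3g -> %.3g mM/h across the uptake sweep",
              rib[1], rib[length(rib)])),
    lipid_increases_with_uptake = assertion(
      mostly_monotone(lip, 1, 1e-6),
      sprintf("phospholipid flux %.3g -> %.3g mM/h", lip[1], lip[length(lip)]))
  ), p)
}

preset_pdh_ldh_grid <- function(opts) {
  m <- build_default_network(clamp_atp = TRUE)
  p0 <- default_parameters(m)
  rows <- list()
  for (pdh in c(1, 4)) for (ldh in c(1, 4)) {
    p <- set_activity(set_activity(p0, "PDH", pdh), "LDH", ldh)
    r <- integrate_to_steady_state(m, p, opts = opts)
    rows[[length(rows) + 1]] <- data.frame(
      pdh = pdh, ldh = ldh, converged = r$converged,
      glucose_uptake = r$fluxes[["R1"]], lipid_flux = r$fluxes[["R5"]])
  }
  tab <- do.call(rbind, rows)
  base <- tab[tab$pdh == 1 & tab$ldh == 1, ]
  up_ok <- all(tab$glucose_uptake[-1] > base$glucose_uptake) &&
    all(tab$converged)
  lip_ok <- all(tab$lipid_flux[tab$pdh > 1 | tab$ldh > 1] > base$lipid_flux)
  new_preset_result("pdh-ldh-grid", list(grid = tab), list(
    uptake_rises_with_either_enzyme = assertion(
      up_ok, sprintf("uptake %.4g (1x1) vs %.4g (4x4) mM/h at clamped ATP",
                     base$glucose_uptake, tab$glucose_uptake[4])),
    lipid_rises_with_either_enzyme = assertion(
      lip_ok, sprintf("lipid %.4g (1x1) vs %.4g (4x4) mM/h",
                      base$lipid_flux, tab$lipid_flux[4]))
  ), p0)
}

preset_pdh_sweep <- function(opts) {
  m <- build_default_network()
  p <- default_parameters(m)
  p <- silence_fbp(p)
  sw <- run_sweep(m, p, sweep_spec("activity.PDH",
                                   10^seq(-1, 0.3, length.out = 13), "up"),
                  init = default_initial_state(m, p, "proliferative"),
                  opts = opts)
  lip <- conv_vals(sw$table, "lipid_flux")
  aa <- conv_vals(sw$table, "atp_adp_ratio")
  new_preset_result("pdh-sweep", list(sweep = sw$table), list(
    lipid_eventually_falls = assertion(
      length(lip) > 2 && lip[length(lip)] < 0.5 * max(lip),
      sprintf("lipid flux peaks at %.3g and ends at %.3g mM/h",
              max(lip), lip[length(lip)])),
    atp_adp_rises = assertion(
      length(aa) > 2 && aa[length(aa)] > aa[1],
      sprintf("ATP:ADP %.3g -> %.3g across the PDH sweep",
              aa[1], aa[length(aa)]))
  ), p)
}

preset_ldh_hysteresis <- function(opts) {
  m <- build_default_network()
  p <- default_parameters(m)
  vals <- 10^seq(log10(0.02), log10(20), length.out = 19)
  sw <- run_sweep(m, p, sweep_spec("activity.LDH", vals, "both"), opts = opts)
  rep_full <- detect_bistability(sw, readout = "lipid_flux")
  sw1 <- run_sweep(m, silence_fbp(p), sweep_spec("activity.LDH", vals, "both"),
                   opts = opts)
  rep_ctrl <- detect_bistability(sw1, readout = "lipid_flux")
  new_preset_result("ldh-hysteresis", list(
    sweep = sw$table, sweep_no_activation = sw1$table,
    window = data.frame(bistable = rep_full$bistable,
                        down_transition = rep_full$down_transition,
                        up_transition = rep_full$up_transition,
                        max_branch_gap = rep_full$max_branch_gap)
  ), list(
    bistable_with_activation = assertion(
      rep_full$bistable,
      sprintf("hysteresis window [%.3g, %.3g], branch gap %.2g",
              rep_full$window[1], rep_full$window[2], rep_full$max_branch_gap)),
    monostable_without_activation = assertion(
      !rep_ctrl$bistable,
      "up and down sweeps coincide once FBP activation is silenced")
  ), p)
}

crossover_k_use_grid <- function() 10^seq(log10(7), log10(60), length.out = 10)

preset_atp_demand_crossover <- function(opts) {
  m <- build_default_network()
  p <- silence_fbp(default_parameters(m))
  kus <- crossover_k_use_grid()
  pm_lip <- optimal_phenotype_map(m, p, kus, readout = "lipid_flux", opts = opts)
  pm_use <- optimal_phenotype_map(m, p, kus, readout = "atp_use_flux", opts = opts)
  w_lip <- pm_lip$winner
  wide_use <- merge(
    pm_use$table[pm_use$table$phenotype == "Warburg", c("k_use", "value")],
    pm_use$table[pm_use$table$phenotype == "OXPHOS", c("k_use", "value")],
    by = "k_use", suffixes = c("_warburg", "_oxphos"))
  new_preset_result("atp-demand-crossover", list(
    lipid = pm_lip$table, lipid_winner = pm_lip$winner,
    atp_use = pm_use$table
  ), list(
    warburg_wins_at_low_demand = assertion(
      nrow(w_lip) > 0 && w_lip$winner[1] == "Warburg",
      sprintf("winner at k_use=%.3g is %s", w_lip$k_use[1], w_lip$winner[1])),
    oxphos_wins_at_high_demand = assertion(
      nrow(w_lip) > 0 && w_lip$winner[nrow(w_lip)] == "OXPHOS",
      sprintf("winner at k_use=%.3g is %s",
              w_lip$k_use[nrow(w_lip)], w_lip$winner[nrow(w_lip)])),
    single_crossover = assertion(
      !is.null(pm_lip$crossovers) && nrow(pm_lip$crossovers) == 1,
      if (!is.null(pm_lip$crossovers))
        sprintf("winner changes once, between k_use %.3g and %.3g",
                pm_lip$crossovers$k_use_low[1], pm_lip$crossovers$k_use_high[1])
      else "no crossover detected"),
    oxphos_maximises_atp_use_throughout = assertion(
      all(wide_use$value_oxphos >= wide_use$value_warburg * 0.999, na.rm = TRUE),
      "high-PDH configuration maximises the ATP-consuming flux at every demand")
  ), p)
}

preset_anoxic_load <- function(opts) {
  m <- build_default_network()
  p <- default_parameters(m)
  p <- set_environment(p, "O2", 0)
  p <- set_activity(p, "PC", 0)
  p <- silence_fbp(p)
  sw <- run_sweep(m, p, sweep_spec("environment.k_use",
                                   seq(0.5, 8, length.out = 10), "up"),
                  opts = opts)
  ec <- sw$table$ECAR_proxy
  ok <- all(sw$table$converged) && all(diff(ec) > 0)
  new_preset_result("anoxic-load", list(sweep = sw$table), list(
    lactate_rises_with_demand = assertion(
      ok, sprintf("anoxic lactate export %.3g -> %.3g mM/h, strictly increasing",
                  ec[1], ec[length(ec)]))
  ), p)
}

preset_glut1_sweep <- function(opts) {
  m <- build_default_network()
  p <- default_parameters(m)
  p <- set_activity(p, "PDH", 10)
  p <- set_environment(p, "k_use", 40)
  sw <- run_sweep(m, p, sweep_spec("activity.GLUT1",
                                   10^seq(-0.7, 0.7, length.out = 15), "up"),
                  init = default_initial_state(m, p, "proliferative"),
                  opts = opts)
  lip <- conv_vals(sw$table, "lipid_flux")
  new_preset_result("glut1-sweep", list(sweep = sw$table), list(
    lipid_nondecreasing_in_glut1 = assertion(
      mostly_monotone(lip, 1, 0.02),
      sprintf("lipid flux %.3g -> %.3g mM/h under high PDH and high demand",
              lip[1], lip[length(lip)]))
  ), p)
}

gln_sweep_values <- function() c(0.001, 0.003, 0.01, 0.03, 0.1, 0.3, 1, 2, 5)

gln_anaplerosis_params <- function() {
  m <- build_default_network()
  p <- default_parameters(m)
  p <- set_activity(p, "ACC", 10)
  p <- set_activity(p, "PC", 0)
  p <- set_environment(p, "k_use", 12)
  list(m = m, p = p)
}

preset_gln_tca_shutdown <- function(opts) {
  mp <- gln_anaplerosis_params()
  sw <- run_sweep(mp$m, mp$p, sweep_spec("environment.Gln_ext",
                                         gln_sweep_values(), "up"),
                  init = default_initial_state(mp$m, mp$p, "proliferative"),
                  opts = opts)
  tca <- sw$table$tca_flux_akgdh
  lo <- tca[1]; hi <- max(conv_vals(sw$table, "tca_flux_akgdh"))
  new_preset_result("gln-tca-shutdown", list(sweep = sw$table), list(
    tca_shuts_down_without_glutamine = assertion(
      sw$table$converged[1] && is.finite(hi) && lo < 0.01 * hi,
      sprintf("TCA (AKGDH) flux %.3g mM/h at ~zero glutamine vs %.3g replete (%.2f%%)",
              lo, hi, 100 * lo / hi))
  ), mp$p)
}

preset_gln_fatty_acid <- function(opts) {
  mp <- gln_anaplerosis_params()
  sw <- run_sweep(mp$m, mp$p, sweep_spec("environment.Gln_ext",
                                         gln_sweep_values(), "up"),
                  init = default_initial_state(mp$m, mp$p, "proliferative"),
                  opts = opts)
  fa <- conv_vals(sw$table, "fa_flux")
  new_preset_result("gln-fatty-acid", list(sweep = sw$table), list(
    fa_flux_rises_with_glutamine = assertion(
      length(fa) > 3 && fa[length(fa)] > 5 * fa[1] && mostly_monotone(fa, 1, 0.15),
      sprintf("fatty-acid flux %.3g -> %.3g mM/h across the glutamine sweep",
              fa[1], fa[length(fa)]))
  ), mp$p)
}

# shared configurations for the oxidative vs reductive glutamine comparison
normoxic_oxidative_params <- function() {
  m <- build_default_network()
  p <- set_activity(default_parameters(m), "ACC", 10)
  # the oxidative-vs-reductive glutamine comparison isolates the
  # glutamine-driven anaplerotic routes; PC is silenced as in the
  # glutamine-shutdown scenario
  p <- set_activity(p, "PC", 0)
  list(m = m, p = p)
}

hypoxic_reductive_params <- function(idh = 20) {
  m <- build_default_network()
  p <- set_activity(default_parameters(m), "ACC", 10)
  p <- set_activity(p, "PC", 0)
  p <- set_environment(p, "O2", 0.003)
  p <- set_activity(p, "IDH_NADPH", idh)
  list(m = m, p = p)
}

preset_hypoxia_reductive <- function(opts) {
  red0 <- hypoxic_reductive_params(0)
  red1 <- hypoxic_reductive_params(20)
  norm <- normoxic_oxidative_params()
  r0 <- integrate_to_steady_state(red0$m, red0$p, opts = opts)
  r1 <- integrate_to_steady_state(red1$m, red1$p, opts = opts)
  rn <- integrate_to_steady_state(norm$m, norm$p, opts = opts)
  tab <- data.frame(
    condition = c("hypoxia_idh_off", "hypoxia_idh_high", "normoxia_oxidative"),
    converged = c(r0$converged, r1$converged, rn$converged),
    fa_flux = c(r0$fluxes[["R18"]], r1$fluxes[["R18"]], rn$fluxes[["R18"]]),
    OCR_proxy = c(r0$readouts$OCR_proxy, r1$readouts$OCR_proxy,
                  rn$readouts$OCR_proxy))
  new_preset_result("hypoxia-reductive", list(comparison = tab), list(
    fa_requires_nadph_idh_under_hypoxia = assertion(
      r1$fluxes[["R18"]] >= 10 * r0$fluxes[["R18"]],
      sprintf("hypoxic fatty-acid flux %.3g (IDH high) vs %.3g (IDH off) mM/h",
              r1$fluxes[["R18"]], r0$fluxes[["R18"]])),
    reductive_mode_sustains_fa_synthesis = assertion(
      r1$fluxes[["R18"]] >= 0.5 * rn$fluxes[["R18"]],
      sprintf("hypoxic reductive fa flux %.3g vs normoxic oxidative %.3g mM/h",
              r1$fluxes[["R18"]], rn$fluxes[["R18"]]))
  ), red1$p)
}

preset_tca_intermediate_ratios <- function(opts) {
  red <- hypoxic_reductive_params(20)
  norm <- normoxic_oxidative_params()
  r1 <- integrate_to_steady_state(red$m, red$p, opts = opts)
  rn <- integrate_to_steady_state(norm$m, norm$p, opts = opts)
  sp <- c("CIT_m", "AKG_m", "MAL_m", "OAA_m")
  tab <- data.frame(
    quantity = c(sp, "nad_ratio_m"),
    normoxic = c(rn$state[sp], rn$readouts$nad_ratio_m),
    hypoxic_reductive = c(r1$state[sp], r1$readouts$nad_ratio_m))
  tab$ratio_norm_over_hyp <- tab$normoxic / tab$hypoxic_reductive
  dep <- tab$ratio_norm_over_hyp[tab$quantity %in% c("AKG_m", "OAA_m")]
  nadr <- tab$ratio_norm_over_hyp[tab$quantity == "nad_ratio_m"]
  new_preset_result("tca-intermediate-ratios", list(ratios = tab), list(
    intermediates_depleted_in_reductive_mode = assertion(
      all(dep > 1),
      sprintf("normoxic:hypoxic concentration ratios AKG %.3g, OAA %.3g",
              dep[1], dep[2])),
    mito_nad_ratio_falls_under_hypoxia = assertion(
      nadr > 1, sprintf("normoxic:hypoxic mitochondrial NAD+:NADH ratio %.3g", nadr))
  ), red$p)
}

pc_rescue_params <- function(pc) {
  m <- build_default_network()
  p <- set_activity(default_parameters(m), "ACC", 10)
  p <- set_environment(p, "Gln_ext", 0.005)
  p <- set_environment(p, "k_use", 12)
  p <- set_activity(p, "PC", pc)
  list(m = m, p = p)
}

preset_pc_rescue <- function(opts) {
  lo <- pc_rescue_params(0)
  hi <- pc_rescue_params(10)
  r0 <- integrate_to_steady_state(lo$m, lo$p, opts = opts)
  r1 <- integrate_to_steady_state(hi$m, hi$p, opts = opts)
  tab <- data.frame(pc_activity = c(0, 10),
                    converged = c(r0$converged, r1$converged),
                    fa_flux = c(r0$fluxes[["R18"]], r1$fluxes[["R18"]]))
  new_preset_result("pc-rescue", list(comparison = tab), list(
    pc_restores_fa_synthesis_at_low_gln = assertion(
      r1$fluxes[["R18"]] >= 10 * r0$fluxes[["R18"]],
      sprintf("fatty-acid flux %.3g (PC high) vs %.3g (PC off) mM/h at 5 uM glutamine",
              r1$fluxes[["R18"]], r0$fluxes[["R18"]]))
  ), hi$p)
}

preset_pc_signature <- function(opts) {
  # comparison at clamped ATP: holding the energy state fixed isolates the
  # carbon-allocation signature of the two anaplerotic strategies (the PC
  # route consumes two pyruvate molecules per citrate, the glutamine route
  # one, and only the glutamine route turns the full TCA span)
  m <- build_default_network(clamp_atp = TRUE)
  p_pc <- set_activity(default_parameters(m), "ACC", 10)
  p_pc <- set_environment(p_pc, "Gln_ext", 0.005)
  p_pc <- set_activity(p_pc, "PC", 10)
  r_pc <- integrate_to_steady_state(m, p_pc, opts = opts)
  target_fa <- r_pc$fluxes[["R18"]]
  # glutamine-reliant configuration, glutamine titrated to match the PC
  # cell's fatty-acid synthesis flux (deterministic bisection)
  base <- set_activity(default_parameters(m), "ACC", 10)
  base <- set_activity(base, "PC", 0)
  fa_at <- function(gln) {
    r <- integrate_to_steady_state(m, set_environment(base, "Gln_ext", gln),
                                   opts = opts)
    list(fa = if (r$converged) r$fluxes[["R18"]] else NA_real_, res = r)
  }
  lo <- 0.005; hi <- 20
  r_lo <- fa_at(lo); r_hi <- fa_at(hi)
  r_gln <- r_hi$res
  if (is.finite(r_lo$fa) && is.finite(r_hi$fa) &&
      r_lo$fa < target_fa && target_fa < r_hi$fa) {
    for (i in 1:18) {
      mid <- sqrt(lo * hi)
      r_mid <- fa_at(mid)
      if (!is.finite(r_mid$fa)) break
      if (r_mid$fa < target_fa) lo <- mid else hi <- mid
      r_gln <- r_mid$res
      if (abs(r_mid$fa - target_fa) < 0.02 * target_fa) break
    }
  }
  tab <- data.frame(
    configuration = c("pc_reliant", "gln_reliant"),
    converged = c(r_pc$converged, r_gln$converged),
    Gln_ext = c(0.005, r_gln$parameters$environment$Gln_ext),
    fa_flux = c(r_pc$fluxes[["R18"]], r_gln$fluxes[["R18"]]),
    OCR_proxy = c(r_pc$readouts$OCR_proxy, r_gln$readouts$OCR_proxy),
    ECAR_proxy = c(r_pc$readouts$ECAR_proxy, r_gln$readouts$ECAR_proxy))
  matched <- abs(tab$fa_flux[2] - tab$fa_flux[1]) <= 0.1 * tab$fa_flux[1]
  new_preset_result("pc-signature", list(comparison = tab), list(
    fa_fluxes_matched = assertion(
      matched, sprintf("fatty-acid flux %.3g (PC) vs %.3g (Gln) mM/h",
                       tab$fa_flux[1], tab$fa_flux[2])),
    pc_reliance_lowers_ocr = assertion(
      tab$OCR_proxy[1] < tab$OCR_proxy[2],
      sprintf("OCR %.3g (PC) vs %.3g (Gln) mM/h", tab$OCR_proxy[1], tab$OCR_proxy[2])),
    pc_reliance_lowers_ecar = assertion(
      tab$ECAR_proxy[1] < tab$ECAR_proxy[2],
      sprintf("ECAR %.3g (PC) vs %.3g (Gln) mM/h",
              tab$ECAR_proxy[1], tab$ECAR_proxy[2]))
  ), p_pc)
}

glc_deprivation_params <- function() {
  m <- build_default_network()
  p <- set_environment(default_parameters(m), "Glc_ext", 0.001)
  # close the alpha-ketoglutarate efflux so glutamine carbon can only leave
  # through the full malic-enzyme route: the scenario isolates the
  # glutamine-driven TCA cycle
  p <- set_activity(p, "AKGEXP", 0)
  list(m = m, p = p)
}

preset_glc_deprivation_atp <- function(opts) {
  mp <- glc_deprivation_params()
  sw <- run_sweep(mp$m, mp$p, sweep_spec("activity.ME2",
                                         10^seq(-2.5, 1, length.out = 13), "up"),
                  opts = opts)
  au <- conv_vals(sw$table, "atp_use_flux")
  new_preset_result("glc-deprivation-atp", list(sweep = sw$table), list(
    atp_use_rises_with_me2 = assertion(
      length(au) > 3 && au[length(au)] > 1.05 * au[1] && mostly_monotone(au, 1, 0.05),
      sprintf("ATP-consuming flux %.3g -> %.3g mM/h across the ME2 sweep",
              au[1], au[length(au)]))
  ), mp$p)
}

preset_glc_deprivation_lipid <- function(opts) {
  mp <- glc_deprivation_params()
  sw <- run_sweep(mp$m, mp$p, sweep_spec("activity.ME2",
                                         10^seq(-2, 1, length.out = 13), "up"),
                  opts = opts)
  m <- build_default_network()
  p_rep <- default_parameters(m)
  r_rep <- integrate_to_steady_state(
    m, p_rep, init = default_initial_state(m, p_rep, "proliferative"),
    opts = opts)
  lip <- conv_vals(sw$table, "lipid_flux")
  rep_lip <- r_rep$fluxes[["R5"]]
  new_preset_result("glc-deprivation-lipid", list(
    sweep = sw$table,
    replete = data.frame(lipid_flux = rep_lip, converged = r_rep$converged)
  ), list(
    lipid_stays_low_without_glucose = assertion(
      r_rep$converged && length(lip) > 0 && all(lip < 0.01 * rep_lip),
      sprintf("max lipid flux %.3g vs glucose-replete %.3g mM/h (%.2f%%)",
              max(lip), rep_lip, 100 * max(lip) / rep_lip))
  ), mp$p)
}

preset_glc_deprivation_oxygen <- function(opts) {
  mp <- glc_deprivation_params()
  p_ox <- set_activity(mp$p, "ME2", 10)
  r_ox <- integrate_to_steady_state(mp$m, p_ox, opts = opts)
  p_an <- set_environment(p_ox, "O2", 0)
  p_an <- set_activity(p_an, "PC", 0)
  r_an <- integrate_to_steady_state(mp$m, p_an, opts = opts)
  tab <- data.frame(O2 = c(1, 0),
                    converged = c(r_ox$converged, r_an$converged),
                    atp_use_flux = c(r_ox$fluxes[["R21"]], r_an$fluxes[["R21"]]))
  new_preset_result("glc-deprivation-oxygen", list(comparison = tab), list(
    oxygen_required_for_gln_derived_atp = assertion(
      r_an$fluxes[["R21"]] < 0.2 * r_ox$fluxes[["R21"]],
      sprintf("ATP-consuming flux %.3g (normoxia) vs %.3g (anoxia) mM/h",
              r_ox$fluxes[["R21"]], r_an$fluxes[["R21"]]))
  ), p_ox)
}

preset_akg_export_modes <- function(opts) {
  red <- hypoxic_reductive_params(20)
  norm <- normoxic_oxidative_params()
  r1 <- integrate_to_steady_state(red$m, red$p, opts = opts)
  rn <- integrate_to_steady_state(norm$m, norm$p, opts = opts)
  tab <- data.frame(
    mode = c("oxidative_normoxic", "reductive_hypoxic"),
    converged = c(rn$converged, r1$converged),
    akg_export_flux = c(rn$fluxes[["R22"]], r1$fluxes[["R22"]]))
  hi <- max(tab$akg_export_flux); lo <- min(tab$akg_export_flux)
  new_preset_result("akg-export-modes", list(comparison = tab), list(
    export_differs_between_modes = assertion(
      hi > 0 && (hi - lo) / hi > 0.2,
      sprintf("alpha-ketoglutarate export %.3g (oxidative) vs %.3g (reductive) mM/h",
              tab$akg_export_flux[1], tab$akg_export_flux[2]))
  ), norm$p)
}

preset_redox_pdh_sweep <- function(opts) {
  m <- build_extended_network()
  p <- default_parameters(m)
  sw <- run_sweep(m, p, sweep_spec("activity.PDH",
                                   10^seq(log10(0.15), 1, length.out = 13), "up"),
                  init = default_initial_state(m, p, "proliferative"),
                  opts = opts)
  ratio <- conv_vals(sw$table, "nad_ratio_c")
  use <- conv_vals(sw$table, "nad_use_flux")
  new_preset_result("redox-pdh-sweep", list(sweep = sw$table), list(
    cytosolic_nad_ratio_falls_with_pdh = assertion(
      length(ratio) > 3 && ratio[length(ratio)] < ratio[1] &&
        mostly_monotone(ratio, -1, 0.05),
      sprintf("cytosolic NAD+:NADH %.3g -> %.3g across the PDH sweep",
              ratio[1], ratio[length(ratio)])),
    nad_use_flux_falls_with_pdh = assertion(
      length(use) > 3 && use[length(use)] < use[1] &&
        mostly_monotone(use, -1, 0.05),
      sprintf("NAD+-use flux %.3g -> %.3g mM/h", use[1], use[length(use)]))
  ), p)
}

preset_redox_crossover <- function(opts) {
  m <- build_extended_network()
  p <- silence_fbp(default_parameters(m))
  # with dynamic cytosolic redox the glycolytic branch engages at somewhat
  # higher demand, so the scanned band sits slightly above the baseline one
  kus <- 10^seq(log10(11), log10(70), length.out = 8)
  pm <- optimal_phenotype_map(m, p, kus,
                              readout = "nad_use_flux", opts = opts)
  w <- pm$winner
  new_preset_result("redox-crossover", list(
    map = pm$table, winner = pm$winner
  ), list(
    warburg_maximises_nad_use_at_low_demand = assertion(
      nrow(w) > 0 && w$winner[1] == "Warburg",
      sprintf("winner at k_use=%.3g is %s", w$k_use[1], w$winner[1])),
    oxphos_maximises_nad_use_at_high_demand = assertion(
      nrow(w) > 0 && w$winner[nrow(w)] == "OXPHOS",
      sprintf("winner at k_use=%.3g is %s",
              w$k_use[nrow(w)], w$winner[nrow(w)]))
  ), p)
}

yield_scenario_params <- function(regime = c("lactate", "oxidative")) {
  regime <- match.arg(regime)
  m <- build_default_network()
  p <- default_parameters(m)
  # all efflux branches closed so the stoichiometric yield is exact, and the
  # allosteric switch silenced so the regime has a unique steady state
  for (k in c("RIB", "LIP", "ACC", "ACLY", "AKGEXP")) p <- set_activity(p, k, 0)
  p <- set_environment(p, "Gln_ext", 0)
  p <- silence_fbp(p)
  if (regime == "lactate") {
    p <- set_activity(p, "PDH", 0)
    p <- set_activity(p, "PC", 0)
  } else {
    p <- set_activity(p, "LDH", 0)
    p <- set_activity(p, "PDH", 10)
    # demand high enough that the adenine pool stays interior
    p <- set_environment(p, "k_use", 12)
  }
  list(m = m, p = p)
}

#' ATP-yield scenarios
#'
#' Solves the two bookkeeping regimes in which the ATP yield per glucose is
#' stoichiometrically forced: the lactate-only regime (mitochondrial entry
#' and all anabolic/efflux branches closed; yield exactly 2) and the
#' full-oxidation regime (lactate export closed, PDH high, normoxia; yield
#' 30 with FAD-level shuttle accounting or 32 with NADH-level accounting).
#'
#' @param opts [solver_options()].
#' @return A `ccm_preset_result` with the solved yields and assertions.
#' @export
preset_yield_regimes <- function(opts = preset_opts()) {
  lac <- yield_scenario_params("lactate")
  oxi <- yield_scenario_params("oxidative")
  r_lac <- integrate_to_steady_state(lac$m, lac$p, opts = opts)
  r_oxi <- integrate_to_steady_state(oxi$m, oxi$p, opts = opts)
  y_lac <- atp_yield_per_glucose(r_lac)
  y_f <- atp_yield_per_glucose(r_oxi, n_shuttle = r_oxi$parameters$yields$n_F)
  y_n <- atp_yield_per_glucose(r_oxi, n_shuttle = r_oxi$parameters$yields$n_N)
  tab <- data.frame(
    regime = c("lactate_only", "full_oxidation_fad_shuttle",
               "full_oxidation_nadh_shuttle"),
    converged = c(r_lac$converged, r_oxi$converged, r_oxi$converged),
    atp_per_glucose = c(y_lac, y_f, y_n))
  new_preset_result("yield-regimes", list(yields = tab), list(
    lactate_yield_exactly_two = assertion(
      r_lac$converged && abs(y_lac - 2) < 1e-4,
      sprintf("lactate-only yield %.6f ATP per glucose", y_lac)),
    oxidative_yield_at_least_thirty = assertion(
      r_oxi$converged && y_f >= 30 - 1e-3,
      sprintf("full-oxidation yield %.4f (FAD shuttle) / %.4f (NADH shuttle)",
              y_f, y_n)),
    yield_ratio_below_one_tenth = assertion(
      y_lac / y_f <= 0.1,
      sprintf("lactate:oxidative yield ratio %.4f", y_lac / y_f))
  ), oxi$p)
}

# -- catalogue and driver ----------------------------------------------------

preset_catalogue <- function() {
  list(
    "uptake-anabolic" = preset_uptake_anabolic,
    "pdh-ldh-grid" = preset_pdh_ldh_grid,
    "pdh-sweep" = preset_pdh_sweep,
    "ldh-hysteresis" = preset_ldh_hysteresis,
    "atp-demand-crossover" = preset_atp_demand_crossover,
    "anoxic-load" = preset_anoxic_load,
    "glut1-sweep" = preset_glut1_sweep,
    "gln-tca-shutdown" = preset_gln_tca_shutdown,
    "gln-fatty-acid" = preset_gln_fatty_acid,
    "hypoxia-reductive" = preset_hypoxia_reductive,
    "tca-intermediate-ratios" = preset_tca_intermediate_ratios,
    "pc-rescue" = preset_pc_rescue,
    "pc-signature" = preset_pc_signature,
    "glc-deprivation-atp" = preset_glc_deprivation_atp,
    "glc-deprivation-lipid" = preset_glc_deprivation_lipid,
    "glc-deprivation-oxygen" = preset_glc_deprivation_oxygen,
    "akg-export-modes" = preset_akg_export_modes,
    "yield-regimes" = function(opts) preset_yield_regimes(opts),
    "redox-pdh-sweep" = preset_redox_pdh_sweep,
    "redox-crossover" = preset_redox_crossover
  )
}

#' List available scenario presets
#'
#' @return Character vector of preset names.
#' @export
list_presets <- function() names(preset_catalogue())

#' Run a named scenario preset
#'
#' Each preset reproduces one of the package's canonical in-silico
#' experiments (anabolic response to uptake, the bistable glycolytic switch,
#' the demand-dependent phenotype crossover, glutamine/PC anaplerosis,
#' reductive carboxylation under hypoxia, glucose deprivation, the dynamic
#' cytosolic-redox extension, and the stoichiometric ATP-yield regimes) with
#' the frozen default parameters plus the scenario's stated condition
#' overrides. Results are deterministic: rerunning a preset reproduces
#' identical tables.
#'
#' @param name Preset id; see [list_presets()].
#' @param opts [solver_options()]; presets default to a 2000 h integration
#'   ceiling.
#' @return A `ccm_preset_result`: tidy `tables`, named `assertions` (each a
#'   pass flag plus a human-readable detail), and the parameter set used.
#' @export
run_preset <- function(name, opts = preset_opts()) {
  cat_fns <- preset_catalogue()
  if (!name %in% names(cat_fns)) {
    stop(sprintf("unknown preset '%s'; available: %s",
                 name, paste(names(cat_fns), collapse = ", ")))
  }
  cat_fns[[name]](opts)
}

#' Run the full scenario validation suite
#'
#' Runs every preset in the catalogue and collects all embedded assertions.
#'
#' @param opts [solver_options()].
#' @param presets Optional subset of preset names.
#' @return A data.frame with one row per assertion (`preset`, `assertion`,
#'   `pass`, `detail`) with the list of `ccm_preset_result`s attached as
#'   attribute `"results"`.
#' @export
validate_model <- function(opts = preset_opts(), presets = list_presets()) {
  results <- lapply(presets, run_preset, opts = opts)
  names(results) <- presets
  rows <- do.call(rbind, lapply(results, function(r) {
    data.frame(preset = r$preset, assertion = names(r$assertions),
               pass = vapply(r$assertions, `[[`, TRUE, "pass"),
               detail = vapply(r$assertions, `[[`, "", "detail"),
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  attr(rows, "results") <- results
  rows
}
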