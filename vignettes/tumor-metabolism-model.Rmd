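---
title: "A kinetic model of tumor central carbon metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A kinetic model of tumor central carbon metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccmsim)
```

## The model

`ccmsim` simulates the steady-state behaviour of central carbon metabolism in
a fast-proliferating (tumor) cell as a system of ordinary differential
equations over 14 dynamic metabolite concentrations (mM), with fluxes in
mM h^-1^ and time in hours. The network lumps pathways at the branch points
that matter for the questions the model answers:

* **Glycolysis** is resolved into uptake + hexokinase (R1),
  phosphofructokinase (R3), aldolase (R4), and a single lower-glycolysis step
  (R6) crediting 2 ATP per triose phosphate, so a glucose that leaves as
  lactate nets exactly 2 ATP.
* **Anabolic branches** draw ribose from the hexose-phosphate pool (R2) and
  phospholipid precursors from the triose pool (R5); both consume ATP, as
  nucleotide and lipid synthesis do. The phospholipid flux is the package's
  proliferation proxy.
* **The pyruvate branch point** splits between lactate dehydrogenase plus
  export (R7) and pyruvate dehydrogenase (R8) — aerobic glycolysis versus
  mitochondrial oxidation.
* **The TCA cycle** keeps citrate synthase (R9), NAD^+^-IDH (R10), and a
  lumped span from alpha-ketoglutarate to malate (R12: AKGDH + succinyl-CoA
  synthetase + SDH + fumarase, crediting 1 GTP, 1 NADH, 1 FADH~2~), a
  reversible malate dehydrogenase (R13), and the anaplerotic entries:
  glutaminolysis (R14), pyruvate carboxylase (R15), malic enzyme (R16), and
  NADPH-dependent reductive carboxylation (R11). Citrate export + ATP-citrate
  lyase (R17) feeds acetyl-CoA carboxylase/fatty-acid synthesis (R18), with
  the cytosolic oxaloacetate returned to the malate pool so carbon closes
  without a cytosolic OAA sub-model.
* **Oxidative phosphorylation** is a simplified two-entry electron transport
  chain (R19 for NADH, R20 for FADH~2~), saturating in the reduced carrier,
  oxygen, and ADP, crediting the textbook P/O yields `n_N = 2.5` and
  `n_F = 1.5` ATP per carrier.
* **ATP demand** (R21) is a basal housekeeping term plus a saturating demand
  term whose scale `k_use` is the swept "rate of ATP consumption", plus a
  small leak proportional to ATP; the whole load vanishes as ATP goes to 0.
* A small **alpha-ketoglutarate export** (R22) represents overflow of excess
  glutamine-derived carbon.

ADP, mitochondrial NAD^+^ and FAD are never stored: they are derived from
conserved pool totals (`A_tot`, `N_tot_m`, `F_tot_m`), so the pools are
closed by construction. Every reaction is carbon-balanced once CO~2~ and the
excretion/biosynthesis sinks are counted; `reaction_carbon_residuals()`
audits this. Oxygen is a dimensionless saturation in [0, 1], an environment
setting rather than a dynamic species. The cytosolic citrate entry in the
state vector is a placeholder pool of the lumped ACLY treatment: no default
reaction moves it.

Phosphofructokinase carries the regulatory core: Hill inhibition by ATP
(`K_I_ATP` = 1.6 mM, `n_ATP` = 6 on a 3 mM adenine pool) and Hill activation
by its product fructose-1,6-bisphosphate (`K_A_FBP` = 0.05 mM, `n_FBP` = 4,
maximal fold-activation `amp_FBP` = 8). The product activation is a positive
feedback loop: once PFK output raises FBP past its activation threshold, PFK
activates further. Together with the saturating aldolase sink this makes the
glycolytic switch bistable over part of parameter space — the mechanism
behind the hysteresis the package detects.

## Reduced-order feedbacks

Because whole pathway segments are lumped into single irreversible steps, the
product inhibitions that the unlumped chains would provide have to be
restored explicitly, otherwise intermediate pools grow without bound whenever
a downstream step stalls. The catalogue therefore carries a small set of
modifier terms, each standing for a known physiological brake:

* R1 is inhibited by F6P (hexokinase product inhibition) and, weakly, by
  pyruvate (the PK <- PYR ... HK <- G6P product-inhibition chain of the
  unlumped pathway, collapsed to one factor).
* R8 (PDH) is inhibited by its product acetyl-CoA.
* R12 (the AKG -> malate span) is inhibited by malate, and R14 (glutamine
  entry) by alpha-ketoglutarate, so congestion anywhere in the cycle
  propagates back to the glutamine influx instead of accumulating.
* R15 (pyruvate carboxylase) is inhibited by oxaloacetate — PC is tightly
  regulated in vivo and stands down when its product is plentiful.
* The reversible MDH uses `k_r` 50-fold larger than `k_f`: the equilibrium
  strongly favours malate, as it does thermodynamically, which keeps
  oxaloacetate in the micromolar range.

## Calibrated defaults

No single literature source fixes the constants of a lumped network at this
resolution, so the defaults in `default_parameters()` are one frozen
calibration, chosen so that every scenario in the preset catalogue reaches a
bounded steady state and expresses the qualitative regulatory behaviour at
realistic scales: metabolites 0.01–5 mM, a 3 mM adenine pool, fluxes of
order 0.1–10 mM h^-1^, glucose 5 mM and glutamine 2 mM in the medium. The
default ATP demand (`k_use` = 6 mM h^-1^) sits where the glycolytic switch is
bistable along the LDH axis. The NADPH-dependent IDH defaults to activity 0:
NADPH is untracked, so a resting oxidative/reductive IDH cycle would be an
unpaid NADH source; hypoxia scenarios switch the pathway on explicitly.

## Solving to steady state

`integrate_to_steady_state()` integrates with `deSolve::lsoda` in
geometrically growing time chunks (1, 10, 100, ... h) until the maximum
absolute derivative falls below `ss_tol` (10^-6^ mM h^-1^ by default) or
`t_max` (10^4^ h) is reached, then polishes the answer with a damped Newton
root solve. Integration rather than naive root finding selects the stable
steady state in the basin of the supplied initial condition — essential
wherever the system is bistable. Two initial-state regimes are provided:
`"resting"` starts with FBP below the PFK activation threshold (the switch
disengaged), `"proliferative"` with the switch engaged. Where a long-lived
oscillatory transient coexists with a stable equilibrium, the solver also
attempts a Newton solve from the orbit once past t = 1000 h and accepts the
answer only if it is a verified, linearly stable equilibrium (eigenvalue
check); `diagnostics$method` records when this path was used. Unconverged or
unbounded runs are flagged, never silently accepted.

Reported steady states satisfy three independent audits, all under test:
the recomputed flux-balance residual is below `ss_tol`; total ATP production
equals total consumption; and carbon inflow equals the rate of change of
carbon held in dynamic species plus outflow through the sinks.

## Scenario presets and their conventions

`run_preset()` reproduces the package's canonical in-silico experiments;
`validate_model()` runs all of them and collects their embedded assertions.
A few conventions are fixed once, here:

* **Hypoxia** means O~2~ = 0.003 (0.3 % of saturation); **anoxia** means 0.
* **Anoxic scenarios silence pyruvate carboxylase.** Under strict anoxia the
  reverse MDH is the only NADH sink left, and carboxylation-derived carbon
  would accumulate as malate without bound; with PC off the mitochondrial
  branch freezes cleanly and anaerobic glycolysis carries the cell.
* **Smooth dose-response scenarios run with the FBP activation silenced**
  (`amp_FBP = 1`). The phenotype crossover, the anoxic load response, the
  uptake/PDH sweeps and the yield regimes make claims that do not concern
  the bistable switch; with the activation on, those protocols would ride
  through hysteretic jumps and relaxation oscillations that belong to the
  dedicated hysteresis preset. The hysteresis preset itself runs the full
  regulation and demonstrates both that the window exists and that it
  vanishes when the activation is silenced.
* **The phenotype crossover scans `k_use` over [7, 60] mM h^-1^** — the
  demand decade bracketed by the glycolytic supply capacity (about 2 ATP per
  glucose times the maximal uptake) and the oxidative capacity (about 30).
  Below the band both phenotypes idle against the ATP ceiling; above it both
  collapse. Within it, the aerobic-glycolysis configuration wins the
  phospholipid flux at low demand (15-fold more carbon pushed per ATP made)
  and the oxidative configuration wins at high demand (the glycolytic
  configuration can no longer supply the load and its ATP-dependent
  anabolism fails).
* **Glutamine-anaplerosis scenarios silence PC** (its glutamine-independent
  anaplerosis is the subject of the separate PC presets) and run at a
  proliferative demand (`k_use` = 12) so glycolysis stays active as the
  citrate acceptor supply varies.
* **Glucose-deprivation scenarios close the AKG export** so glutamine carbon
  can only leave through the full malic-enzyme route, which is exactly the
  route whose necessity the scenario demonstrates.
* **The PC-signature comparison runs at clamped ATP.** Holding the energy
  state fixed isolates the carbon-allocation signature of the two
  anaplerotic strategies: the PC route spends two pyruvate molecules per
  citrate and skips the NADH-generating TCA span, so at matched fatty-acid
  synthesis it shows both lower respiration and lower lactate export than
  the glutamine route. The glutamine-reliant partner is titrated to the same
  fatty-acid flux by a deterministic bisection on medium glutamine.
* **Yield regimes close every efflux branch** (ribose, phospholipid,
  fatty-acid, citrate export, AKG export) so the ATP yield per glucose is
  stoichiometrically forced — exactly 2 in the lactate-only regime and
  exactly 30 (FAD-level shuttle credit) or 32 (NADH-level credit) under full
  oxidation — independent of every kinetic constant. The full-oxidation
  regime uses `k_use` = 12 so the adenine pool stays interior.

## The dynamic-redox extension

`build_extended_network()` replaces the baseline's fixed cytosolic
NAD^+^:NADH ratio with a dynamic cytosolic pool: lower glycolysis consumes
NAD^+^~c~, LDH consumes NADH~c~, a glycerol-3-phosphate shuttle (R23)
delivers cytosolic NADH electrons to the mitochondrial FAD pool (yield
`n_F`; the DHAP/G3P carbon round-trip is net zero and not tracked), and an
NAD^+^-use flux (R24) stands for the NAD^+^-consuming oxidative biosynthesis
that limits proliferation when redox capacity rather than carbon is the
constraint. R24 consumes a glycolytic carbon intermediate alongside NAD^+^ —
biosynthetic NAD^+^ use oxidizes carbon substrates, and without the carbon
co-substrate the readout could not distinguish a starved cell from a
proliferating one. With the demand off and the shuttle far from limiting,
the extension reproduces the baseline's phospholipid flux within 5 %.

## Numerical choices and degenerate inputs

Integration tolerances default to `rel_tol` 10^-8^ and `abs_tol` 10^-12^ so
that the -10^-9^ mM positivity floor is meaningful; concentrations are
clamped at zero inside rate evaluation and all rate laws vanish at zero
substrate. The concentration ceiling `bound_cap` (10^4^ mM) declares runaway
trajectories unbounded. Presets integrate to at most 2000 h; steady states
in the catalogue typically converge within 100 h. Preset grids use 10–19
log-spaced points per axis — enough to localise transitions while keeping
the full validation suite around one to two minutes. Hysteresis detection
calls a relative jump of more than 20 % between adjacent converged grid
points a transition, requires the up- and down-sweep transitions to differ
by more than one grid step, and excludes flagged unconverged points (the
fold of a hysteresis loop is often flanked by slow oscillatory transients;
these are reported as unconverged, not interpolated).

## What passing the suite does and does not show

The preset assertions mirror qualitative claims: yield arithmetic,
bistability and its loss, winner orderings, shutdown and rescue ratios,
direction of concentration shifts. The kinetic constants are a calibration,
not measurements, so absolute fluxes and the positions of transitions are
model-scale quantities; only their orderings, ratios and the stoichiometric
yields carry over to real cells. The model also omits, by design:
beta-oxidation, ROS and glutathione chemistry, ammonia recycling, an
explicit malate–aspartate shuttle (handled only as a yield-accounting
option via `n_shuttle`), membrane-potential detail of the respiratory
chain, and any gene-regulatory coupling. Within those limits, the package
gives a reproducible, auditable account of why a proliferating cell can
prefer fermenting glucose it could have oxidized.
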