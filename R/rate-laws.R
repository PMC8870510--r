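#' Michaelis-Menten saturation rate
#'
#' Elementary saturating (hyperbolic) rate law `vmax * s / (km + s)`. All the
#' irreversible enzymatic steps in the network are built from products of such
#' factors; multi-substrate reactions multiply independent saturation factors.
#'
#' @param vmax Maximal rate (mM/h), `>= 0`.
#' @param km Half-saturation constant (mM), `> 0`.
#' @param s Substrate concentration (mM), `>= 0`.
#' @return Rate in mM/h; 0 at `s = 0`, approaching `vmax` as `s` grows.
#' @examples
#' saturating_rate(1, 1, 1)   # half-saturation: 0.5
#' saturating_rate(2, 1, 0)   # no substrate: 0
#' @export
saturating_rate <- function(vmax, km, s) {
  if (any(vmax < 0)) stop("saturating_rate: vmax must be >= 0")
  if (any(km <= 0)) stop("saturating_rate: km must be > 0")
  if (any(s < 0)) stop("saturating_rate: negative substrate concentration")
  vmax * s / (km + s)
}

#' Hill-type inhibition factor
#'
#' Dimensionless factor `1 / (1 + (x / ki)^n)`: 1 with no inhibitor, 1/2 at
#' `x = ki`, approaching 0 at saturating inhibitor. Used for the allosteric
#' inhibition of phosphofructokinase by ATP and for product-feedback modifiers.
#'
#' @param x Inhibitor concentration (mM), `>= 0`.
#' @param ki Half-inhibition constant (mM), `> 0`.
#' @param n Hill exponent, `>= 1`.
#' @return Dimensionless multiplier in (0, 1].
#' @examples
#' inhibition_factor(0, 2, 4)   # 1
#' inhibition_factor(2, 2, 4)   # 0.5
#' inhibition_factor(4, 2, 4)   # 1/17
#' @export
inhibition_factor <- function(x, ki, n) {
  if (any(ki <= 0)) stop("inhibition_factor: ki must be > 0")
  if (any(n < 1)) stop("inhibition_factor: n must be >= 1")
  if (any(x < 0)) stop("inhibition_factor: negative concentration")
  1 / (1 + (x / ki)^n)
}

#' Hill-type activation factor
#'
#' Dimensionless factor `1 + (amp - 1) * x^n / (ka^n + x^n)`: 1 with no
#' activator and `amp` at saturation. Used for the allosteric activation of
#' phosphofructokinase by its product fructose-1,6-bisphosphate, the positive
#' feedback loop behind the bistable glycolytic switch.
#'
#' @param x Activator concentration (mM), `>= 0`.
#' @param ka Half-activation constant (mM), `> 0`.
#' @param n Hill exponent, `>= 1`.
#' @param amp Maximal fold-activation, `>= 1`.
#' @return Dimensionless multiplier in [1, amp).
#' @examples
#' activation_factor(0, 0.3, 2, 5)    # 1
#' activation_factor(0.3, 0.3, 2, 5)  # midpoint: 3
#' @export
activation_factor <- function(x, ka, n, amp) {
  if (any(ka <= 0)) stop("activation_factor: ka must be > 0")
  if (any(n < 1)) stop("activation_factor: n must be >= 1")
  if (any(amp < 1)) stop("activation_factor: amp must be >= 1")
  if (any(x < 0)) stop("activation_factor: negative concentration")
  xn <- x^n
  1 + (amp - 1) * xn / (ka^n + xn)
}

#' Phosphofructokinase rate law
#'
#' The regulated glycolytic gatekeeper: saturating in fructose-6-phosphate,
#' inhibited by ATP (Hill), activated by its product FBP (Hill fold-change).
#' Monotone increasing in F6P and FBP and decreasing in ATP.
#'
#' @param f6p,atp,fbp Concentrations (mM).
#' @param p A [default_parameters()] parameter set (uses `vmax$R3`,
#'   `km$R3[["F6P"]]`, the regulation constants `K_I_ATP`, `n_ATP`, `K_A_FBP`,
#'   `n_FBP`, `amp_FBP`, and `activity$PFK`).
#' @return Rate (mM/h).
#' @export
pfk_rate <- function(f6p, atp, fbp, p) {
  r <- p$regulation
  p$activity[["PFK"]] *
    saturating_rate(p$vmax[["R3"]], p$km[["R3"]][["F6P"]], f6p) *
    inhibition_factor(atp, r$K_I_ATP, r$n_ATP) *
    activation_factor(fbp, r$K_A_FBP, r$n_FBP, r$amp_FBP)
}

#' Reversible malate dehydrogenase rate law
#'
#' Net forward rate of MAL + NAD+ -> OAA + NADH as a reversible
#' mass-action-with-saturation form `kf * mal * nad - kr * oaa * nadh`, both
#' terms scaled by the MDH activity multiplier. The sign gives the net
#' direction; the rate is zero when the mass-action ratio equals `kf / kr`.
#'
#' @param mal,oaa,nadh_m,nad_m Concentrations (mM).
#' @param p Parameter set (uses `km$R13[["k_f"]]`, `km$R13[["k_r"]]`,
#'   `activity$MDH`).
#' @return Signed rate (mM/h); negative means net OAA -> MAL.
#' @export
reversible_mdh_rate <- function(mal, oaa, nadh_m, nad_m, p) {
  if (any(c(mal, oaa, nadh_m, nad_m) < 0)) {
    stop("reversible_mdh_rate: negative concentration")
  }
  kk <- p$km[["R13"]]
  p$activity[["MDH"]] * (kk[["k_f"]] * mal * nad_m - kk[["k_r"]] * oaa * nadh_m)
}

#' Electron-transport-chain rate law
#'
#' Simplified respiratory-chain step: saturating in the reduced carrier
#' (mitochondrial NADH or FADH2), in oxygen availability, and in ADP (the
#' phosphate acceptor). Zero under anoxia or when the adenine pool is fully
#' phosphorylated. ATP stoichiometry (the P/O yield) is credited when fluxes
#' are assembled, not here.
#'
#' @param carrier Reduced carrier concentration (mM).
#' @param o2 Oxygen saturation, dimensionless in \[0, 1\].
#' @param adp ADP concentration (mM).
#' @param vmax Maximal rate (mM/h).
#' @param km_carrier,km_o2,km_adp Half-saturation constants.
#' @return Rate (mM/h).
#' @export
etc_rate <- function(carrier, o2, adp, vmax, km_carrier, km_o2, km_adp) {
  if (any(o2 < 0 | o2 > 1)) stop("etc_rate: o2 must lie in [0, 1]")
  saturating_rate(vmax, km_carrier, carrier) *
    (o2 / (km_o2 + o2)) *
    (adp / (km_adp + adp))
}

# ATP-demand rate: basal housekeeping load, a demand term that saturates in
# ATP so the load cannot pathologically exceed supply, and a small
# proton-leak/futile-cycle term proportional to ATP that keeps the adenine
# pool interior when production capacity far exceeds demand.
load_rate <- function(atp, basal_load, k_use, k_load, leak_rate = 0) {
  (basal_load + k_use * atp / (k_load + atp) + leak_rate * atp) *
    atp / (0.01 + atp)
}
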