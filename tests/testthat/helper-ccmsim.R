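# Shared fixtures: expensive steady-state solves are computed once per run
# and cached for all test files.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

default_baseline <- function() {
  cached("baseline", {
    m <- build_default_network()
    p <- default_parameters(m)
    list(m = m, p = p)
  })
}

default_steady_state <- function() {
  cached("steady", {
    mp <- default_baseline()
    suppressWarnings(integrate_to_steady_state(mp$m, mp$p))
  })
}

# a pinned, strictly interior reference state used for hand evaluation
reference_state <- function(m) {
  st <- c(
    F6P = 0.6, FBP = 0.08, TP = 0.12, PYR = 0.35, ACCOA_c = 0.05,
    CIT_c = 0.1, ATP = 1.8, ACCOA_m = 0.07, OAA_m = 0.02, CIT_m = 0.25,
    AKG_m = 0.4, MAL_m = 0.3, NADH_m = 0.45, FADH2_m = 0.2
  )
  if (m$variant == "extended") st <- c(st, NADH_c = 0.05)
  st[names(st) %in% m$species$species_id]
}
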