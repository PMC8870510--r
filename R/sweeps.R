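# Parameter sweeps with state continuation, hysteresis detection, and
# phenotype-crossover mapping.

#' Specify a parameter sweep
#'
#' @param param_path Dotted path of the swept quantity: `"activity.<KEY>"`
#'   (an enzyme activity multiplier, set absolutely) or
#'   `"environment.<name>"` (e.g. `"environment.k_use"`).
#' @param values Numeric vector of values, strictly monotone.
#' @param direction `"up"` (as given, ascending), `"down"` (descending), or
#'   `"both"`.
#' @param continuation Use each converged steady state as the next initial
#'   condition (`TRUE`, default). Continuation is what exposes hysteresis:
#'   each branch keeps the system in the basin it is already in.
#' @param readouts Optional character vector restricting the readout columns.
#' @return A `ccm_sweep_spec`.
#' @export
sweep_spec <- function(param_path, values, direction = c("both", "up", "down"),
                       continuation = TRUE, readouts = NULL) {
  direction <- match.arg(direction)
  values <- as.numeric(values)
  if (length(values) < 1 || any(!is.finite(values))) {
    stop("sweep values must be finite")
  }
  values <- sort(unique(values))
  parts <- strsplit(param_path, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !parts[1] %in% c("activity", "environment")) {
    stop("param_path must be 'activity.<KEY>' or 'environment.<name>'")
  }
  structure(
    list(param_path = param_path, values = values, direction = direction,
         continuation = isTRUE(continuation), readouts = readouts),
    class = "ccm_sweep_spec"
  )
}

# Apply a dotted param path to a parameter set (absolute value).
set_param_path <- function(p, param_path, value) {
  parts <- strsplit(param_path, ".", fixed = TRUE)[[1]]
  if (parts[1] == "activity") {
    set_activity(p, parts[2], value)
  } else if (parts[1] == "environment") {
    set_environment(p, parts[2], value)
  } else {
    stop("unknown parameter path: ", param_path)
  }
}

sweep_one_direction <- function(m, p, spec, direction, init, opts) {
  vals <- if (direction == "up") spec$values else rev(spec$values)
  results <- vector("list", length(vals))
  st <- init
  for (i in seq_along(vals)) {
    pv <- set_param_path(p, spec$param_path, vals[i])
    r <- integrate_to_steady_state(m, pv, init = st, opts = opts)
    results[[i]] <- r
    if (spec$continuation && r$converged && r$bounded) st <- r$state
  }
  names(results) <- as.character(vals)
  results
}

sweep_table <- function(results, direction, spec) {
  ro_names <- unique(unlist(lapply(results, function(r) names(r$readouts))))
  if (!is.null(spec$readouts)) ro_names <- intersect(ro_names, spec$readouts)
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    base <- data.frame(
      direction = direction,
      swept_value = as.numeric(names(results)[i]),
      converged = r$converged, bounded = r$bounded,
      stringsAsFactors = FALSE
    )
    for (nm in ro_names) {
      base[[nm]] <- if (!is.null(r$readouts)) r$readouts[[nm]] else NA_real_
    }
    base
  })
  do.call(rbind, rows)
}

#' Run a parameter sweep to steady state
#'
#' Solves the model to steady state at each swept value, optionally in both
#' directions with state continuation (the up-sweep starts from the steady
#' state at the lowest value, the down-sweep from the highest). Unconverged
#' points are flagged and the sweep continues.
#'
#' @param m A `ccm_model`.
#' @param p A `ccm_parameters`.
#' @param spec A [sweep_spec()].
#' @param init Initial state used to seed each direction's first point;
#'   defaults to [default_initial_state()].
#' @param opts [solver_options()].
#' @return A `ccm_sweep`: list with `table` (one row per direction x swept
#'   value, readouts as columns), `results` (full `ccm_steady_state` objects
#'   per direction), and `spec`.
#' @export
run_sweep <- function(m, p, spec, init = default_initial_state(m, p),
                      opts = solver_options()) {
  stopifnot(inherits(spec, "ccm_sweep_spec"))
  dirs <- switch(spec$direction, both = c("up", "down"), up = "up", down = "down")
  results <- list()
  tabs <- list()
  for (d in dirs) {
    res_d <- sweep_one_direction(m, p, spec, d, init, opts)
    results[[d]] <- res_d
    tab <- sweep_table(res_d, d, spec)
    # present each direction in ascending order of the swept value
    tabs[[d]] <- tab[order(tab$swept_value), , drop = FALSE]
  }
  out <- list(table = do.call(rbind, tabs), results = results, spec = spec)
  rownames(out$table) <- NULL
  class(out) <- "ccm_sweep"
  out
}

#' @export
print.ccm_sweep <- function(x, ...) {
  cat(sprintf("<ccm_sweep> %s over %d values (%s)\n", x$spec$param_path,
              length(x$spec$values), x$spec$direction))
  print(utils::head(x$table, 10))
  if (nrow(x$table) > 10) cat("...", nrow(x$table) - 10, "more rows\n")
  invisible(x)
}

# Extract (swept_value, readout, converged) for one direction from a
# ccm_sweep or from a plain data.frame already in that shape.
branch_frame <- function(x, direction, readout) {
  tab <- if (inherits(x, "ccm_sweep")) x$table[x$table$direction == direction, ]
         else x
  if (!readout %in% names(tab)) stop("readout not present: ", readout)
  conv <- if ("converged" %in% names(tab)) tab$converged else TRUE
  out <- data.frame(swept_value = tab$swept_value, value = tab[[readout]],
                    converged = conv)
  out[order(out$swept_value), ]
}

#' Detect bistability from paired up/down sweeps
#'
#' Locates the largest jump between adjacent grid points in each sweep
#' direction. The system is reported bistable when the two transition
#' locations differ by more than one grid step and the two branches differ by
#' more than `jump_threshold` (relative) between the transitions -- the
#' signature of hysteresis.
#'
#' @param up,down A `ccm_sweep` containing the respective direction, or plain
#'   data.frames with columns `swept_value` and the readout. A single
#'   `ccm_sweep` run with `direction = "both"` may be passed as `up` with
#'   `down` missing.
#' @param readout Name of the readout column to analyse (e.g. `"lipid_flux"`).
#' @param jump_threshold Relative change between branches that counts as a
#'   jump (default 0.2).
#' @return A `ccm_hysteresis` list: `bistable`, `up_transition`,
#'   `down_transition`, `window`, `max_branch_gap`.
#' @export
detect_bistability <- function(up, down = NULL, readout = "lipid_flux",
                               jump_threshold = 0.2) {
  if (is.null(down)) {
    if (!inherits(up, "ccm_sweep")) stop("down sweep missing")
    down <- up
  }
  bu <- branch_frame(up, "up", readout)
  bd <- branch_frame(down, "down", readout)
  if (nrow(bu) != nrow(bd) ||
      max(abs(bu$swept_value - bd$swept_value) /
            pmax(abs(bu$swept_value), 1e-300)) > 1e-8) {
    stop("up and down sweeps must share the same grid")
  }
  grid <- bu$swept_value
  # unconverged points (e.g. oscillatory transients near a fold) carry no
  # steady-state readout; jumps are located between consecutive converged
  # points
  largest_jump <- function(b) {
    keep <- which(b$converged & is.finite(b$value))
    if (length(keep) < 2) return(list(i = NA_integer_, size = 0))
    v <- b$value[keep]
    dj <- abs(diff(v)) / pmax(pmin(abs(v[-1]), abs(v[-length(v)])), 1e-12)
    i <- which.max(dj)
    list(i = keep[i], after = keep[i + 1], size = dj[i])
  }
  ju <- largest_jump(bu)
  jd <- largest_jump(bd)
  if (is.na(ju$i) || is.na(jd$i)) {
    return(structure(list(bistable = FALSE, up_transition = NA_real_,
                          down_transition = NA_real_, window = c(NA_real_, NA_real_),
                          max_branch_gap = 0, readout = readout,
                          jump_threshold = jump_threshold),
                     class = "ccm_hysteresis"))
  }
  # up-sweep leaves the low branch after grid index ju$i; the down-sweep
  # (read in ascending order) joins the low branch at index jd$after
  up_transition <- grid[ju$after]
  down_transition <- grid[jd$after]
  lo <- min(ju$i, jd$i); hi <- max(ju$i, jd$i)
  inside <- seq(lo + 1, hi)
  ok <- bu$converged[inside] & bd$converged[inside]
  gap <- abs(bu$value[inside] - bd$value[inside]) /
    pmax(pmin(abs(bu$value[inside]), abs(bd$value[inside])), 1e-12)
  gap <- gap[ok]
  bistable <- (hi - lo) >= 1 && ju$i != jd$i &&
    any(gap > jump_threshold, na.rm = TRUE) &&
    ju$size > jump_threshold && jd$size > jump_threshold
  structure(list(
    bistable = bistable,
    up_transition = up_transition,
    down_transition = down_transition,
    window = sort(c(down_transition, up_transition)),
    max_branch_gap = if (length(gap)) max(gap, na.rm = TRUE) else 0,
    readout = readout, jump_threshold = jump_threshold
  ), class = "ccm_hysteresis")
}

#' @export
print.ccm_hysteresis <- function(x, ...) {
  cat(sprintf("<ccm_hysteresis> %s: bistable=%s window=[%g, %g] gap=%.2f\n",
              x$readout, x$bistable, x$window[1], x$window[2],
              x$max_branch_gap))
  invisible(x)
}

#' Canonical metabolic phenotype configurations
#'
#' The two poles of the lactate-vs-oxidation branch decision, as absolute
#' activity multipliers relative to the defaults: the aerobic-glycolysis
#' ("Warburg") configuration up-regulates LDH tenfold and down-regulates PDH
#' tenfold; the oxidative ("OXPHOS") configuration does the reverse.
#'
#' @return Named list of named activity-multiplier vectors.
#' @export
warburg_phenotypes <- function() {
  list(
    Warburg = c(LDH = 10, PDH = 0.1),
    OXPHOS = c(LDH = 0.1, PDH = 10)
  )
}

apply_phenotype <- function(p, config) {
  for (k in names(config)) p <- set_activity(p, k, config[[k]])
  p
}

#' Map the optimal phenotype across ATP-demand rates
#'
#' For each ATP-consumption rate `k_use`, solves every named phenotype
#' configuration to steady state (with per-phenotype continuation along the
#' `k_use` axis) and records which phenotype maximises the chosen readout.
#' Reports the crossover interval(s) where the winner changes.
#'
#' @param m,p Model and parameters.
#' @param k_use_values Ascending ATP-demand rates (mM/h) to scan.
#' @param phenotypes Named list of activity configurations; default
#'   [warburg_phenotypes()].
#' @param readout Readout maximised (default `"lipid_flux"`, the
#'   proliferation proxy).
#' @param opts [solver_options()].
#' @return A `ccm_phenotype_map`: `table` (k_use x phenotype readouts),
#'   `winner` (per k_use), `crossovers` (data.frame of winner changes with the
#'   bracketing k_use interval).
#' @export
optimal_phenotype_map <- function(m, p, k_use_values,
                                  phenotypes = warburg_phenotypes(),
                                  readout = "lipid_flux",
                                  opts = solver_options()) {
  if (length(phenotypes) < 2) stop("need at least two phenotypes")
  k_use_values <- sort(as.numeric(k_use_values))
  rows <- list()
  for (ph in names(phenotypes)) {
    pp <- apply_phenotype(p, phenotypes[[ph]])
    st <- default_initial_state(m, pp)
    for (k in k_use_values) {
      pk <- set_environment(pp, "k_use", k)
      r <- integrate_to_steady_state(m, pk, init = st, opts = opts)
      if (r$converged && r$bounded) st <- r$state
      val <- if (!is.null(r$readouts)) r$readouts[[readout]] else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        k_use = k, phenotype = ph, value = val, converged = r$converged,
        stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, rows)
  winner <- do.call(rbind, lapply(split(tab, tab$k_use), function(d) {
    d <- d[d$converged & !is.na(d$value), ]
    if (nrow(d) == 0) return(NULL)
    data.frame(k_use = d$k_use[1], winner = d$phenotype[which.max(d$value)],
               stringsAsFactors = FALSE)
  }))
  winner <- winner[order(winner$k_use), ]
  rownames(winner) <- NULL
  cross <- NULL
  if (nrow(winner) > 1) {
    ch <- which(winner$winner[-1] != winner$winner[-nrow(winner)])
    if (length(ch)) {
      cross <- data.frame(
        k_use_low = winner$k_use[ch], k_use_high = winner$k_use[ch + 1],
        from = winner$winner[ch], to = winner$winner[ch + 1],
        stringsAsFactors = FALSE
      )
    }
  }
  structure(list(table = tab, winner = winner, crossovers = cross,
                 readout = readout),
            class = "ccm_phenotype_map")
}

#' @export
print.ccm_phenotype_map <- function(x, ...) {
  cat(sprintf("<ccm_phenotype_map> readout=%s over %d demand rates\n",
              x$readout, nrow(x$winner)))
  if (!is.null(x$crossovers)) {
    for (i in seq_len(nrow(x$crossovers))) {
      cat(sprintf("  winner %s -> %s between k_use %g and %g\n",
                  x$crossovers$from[i], x$crossovers$to[i],
                  x$crossovers$k_use_low[i], x$crossovers$k_use_high[i]))
    }
  } else cat("  no crossover\n")
  invisible(x)
}
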