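# Configuration loading, model serialization, and result output.

config_schema <- function() {
  list(
    top = c("model_variant", "environment", "activity", "solver", "preset",
            "sweep", "out_dir"),
    environment = c("Glc_ext", "Gln_ext", "O2", "k_use", "basal_load", "leak_rate"),
    solver = c("abs_tol", "rel_tol", "ss_tol", "t_max", "bound_cap"),
    sweep = c("param", "from", "to", "points", "direction", "readout")
  )
}

nearest_key <- function(key, valid) {
  d <- as.numeric(utils::adist(key, valid, ignore.case = TRUE))
  # prefer transposition-style typos (same letters, different order), which
  # plain edit distance cannot distinguish from substitutions
  letters_of <- function(s) paste(sort(strsplit(tolower(s), "")[[1]]), collapse = "")
  d <- d - 0.5 * (letters_of(key) == vapply(valid, letters_of, ""))
  valid[which.min(d)]
}

check_keys <- function(given, valid, where) {
  unknown <- setdiff(given, valid)
  if (length(unknown) > 0) {
    stop(sprintf("unknown %s key '%s'; did you mean '%s'?",
                 where, unknown[1], nearest_key(unknown[1], valid)),
         call. = FALSE)
  }
}

#' Load a run configuration
#'
#' Parses a YAML configuration (plain scalars only) into a validated
#' `ccm_run_config`. Recognised sections: `model_variant` (baseline,
#' extended, or clamped-ATP), `environment` and `activity` overrides,
#' `solver` options, a `preset` name or a `sweep` request, and `out_dir`.
#' Unknown keys are rejected with a message naming the nearest valid key;
#' every omitted setting is filled with its default explicitly.
#'
#' @param path Path to a YAML file.
#' @return A `ccm_run_config` list with `model`, `parameters`, `solver`,
#'   `preset`, `sweep`, `out_dir`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a YAML mapping")
  sch <- config_schema()
  check_keys(names(raw), sch$top, "config")

  variant <- raw$model_variant %||% "baseline"
  if (!variant %in% c("baseline", "extended", "clamped-ATP")) {
    stop("model_variant must be one of baseline, extended, clamped-ATP")
  }
  m <- switch(variant,
    baseline = build_default_network(),
    extended = build_extended_network(),
    `clamped-ATP` = build_default_network(clamp_atp = TRUE)
  )
  p <- default_parameters(m)

  if (!is.null(raw$environment)) {
    check_keys(names(raw$environment), sch$environment, "environment")
    for (k in names(raw$environment)) {
      v <- raw$environment[[k]]
      if (!is.numeric(v)) stop("environment values must be numeric")
      p <- set_environment(p, k, v)
    }
  }
  if (!is.null(raw$activity)) {
    check_keys(names(raw$activity), names(p$activity), "activity")
    for (k in names(raw$activity)) {
      v <- raw$activity[[k]]
      if (!is.numeric(v) || v < 0) stop("activity values must be numeric >= 0")
      p <- set_activity(p, k, v)
    }
  }
  sopts <- solver_options()
  if (!is.null(raw$solver)) {
    check_keys(names(raw$solver), sch$solver, "solver")
    for (k in names(raw$solver)) sopts[[k]] <- raw$solver[[k]]
    sopts <- do.call(solver_options, unclass(sopts))
  }
  sweep <- NULL
  if (!is.null(raw$sweep)) {
    check_keys(names(raw$sweep), sch$sweep, "sweep")
    sweep <- raw$sweep
  }
  cfg <- list(
    model = m, parameters = p, solver = sopts,
    preset = raw$preset, sweep = sweep,
    out_dir = raw$out_dir %||% "."
  )
  class(cfg) <- "ccm_run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- model YAML round-trip ---------------------------------------------------

#' Serialize a model definition to YAML
#'
#' Writes the full network catalogue (species with compartments, carbon
#' counts and pool membership; reactions with stoichiometry, ATP/redox
#' ledgers, rate-law template, modifiers and activity key) as a YAML
#' document. [model_from_yaml()] restores it losslessly.
#'
#' @param m A `ccm_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
model_to_yaml <- function(m, path) {
  doc <- list(
    variant = m$variant,
    clamp_atp = m$clamp_atp,
    species = lapply(seq_len(nrow(m$species)), function(i) {
      s <- m$species[i, ]
      list(species_id = s$species_id, compartment = s$compartment,
           carbons = s$carbons,
           pool_id = if (is.na(s$pool_id)) NULL else s$pool_id)
    }),
    reactions = lapply(unname(m$reactions), function(r) {
      list(
        reaction_id = r$reaction_id, name = r$name,
        stoich = as.list(r$stoich),
        atp_stoich = r$atp_stoich,
        atp_yield_key = if (is.na(r$atp_yield_key)) NULL else r$atp_yield_key,
        redox_stoich = as.list(r$redox_stoich),
        rate_template = r$rate_template,
        substrates = as.list(r$substrates),
        modifiers = r$modifiers,
        activity_key = r$activity_key
      )
    })
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Restore a model definition from YAML
#'
#' @param path Path written by [model_to_yaml()].
#' @return A `ccm_model`.
#' @export
model_from_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  species <- do.call(rbind, lapply(doc$species, function(s) {
    new_species(s$species_id, s$compartment, s$carbons,
                s$pool_id %||% NA_character_)
  }))
  named_num <- function(x) {
    if (length(x) == 0) return(numeric())
    stats::setNames(as.numeric(unlist(x)), names(x))
  }
  reactions <- lapply(doc$reactions, function(r) {
    new_reaction(
      r$reaction_id, r$name,
      stoich = named_num(r$stoich),
      atp_stoich = r$atp_stoich,
      atp_yield_key = r$atp_yield_key %||% NA_character_,
      redox_stoich = named_num(r$redox_stoich),
      rate_template = r$rate_template,
      substrates = as.character(unlist(r$substrates)),
      modifiers = r$modifiers %||% list(),
      activity_key = r$activity_key
    )
  })
  names(reactions) <- vapply(reactions, `[[`, "", "reaction_id")
  m <- list(variant = doc$variant, clamp_atp = isTRUE(doc$clamp_atp),
            species = species, reactions = reactions)
  class(m) <- "ccm_model"
  m
}

# -- result output -----------------------------------------------------------

parameter_hash <- function(p) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(unclass(p), tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}

run_metadata <- function(p, opts = NULL, extra = list()) {
  c(list(
    package = "ccmsim",
    version = as.character(utils::packageVersion("ccmsim")),
    parameter_hash = parameter_hash(p),
    solver = if (!is.null(opts)) unclass(opts),
    deterministic = TRUE
  ), extra)
}

steady_state_record <- function(res) {
  conc <- as.list(res$state)
  names(conc) <- paste0("conc_", names(conc))
  flx <- as.list(res$fluxes)
  names(flx) <- paste0("flux_", names(flx))
  ro <- if (!is.null(res$readouts)) res$readouts else list()
  if (length(ro)) names(ro) <- paste0("readout_", names(ro))
  as.data.frame(c(list(converged = res$converged, bounded = res$bounded),
                  conc, flx, ro))
}

melt_sweep_table <- function(tab) {
  id_cols <- intersect(c("direction", "swept_value", "converged", "bounded",
                         "k_use", "phenotype", "value"), names(tab))
  ro_cols <- setdiff(names(tab), id_cols)
  if (length(ro_cols) == 0) return(tab)
  long <- do.call(rbind, lapply(ro_cols, function(nm) {
    d <- tab[intersect(c("direction", "swept_value", "converged"), names(tab))]
    d$readout <- nm
    d$value <- tab[[nm]]
    d
  }))
  ord <- intersect(c("direction", "swept_value", "readout", "value", "converged"),
                   names(long))
  long <- long[do.call(order, long[intersect(c("readout", "direction", "swept_value"),
                                             names(long))])    , ord, drop = FALSE]
  rownames(long) <- NULL
  long
}

#' Write results to CSV plus JSON metadata
#'
#' Writes a tidy CSV and a JSON metadata file (package version, parameter
#' hash, solver options) for a solved object: a single `ccm_steady_state`
#' becomes a one-row flat record of concentrations, fluxes, and readouts; a
#' `ccm_sweep` becomes a long table (direction, swept_value, readout, value,
#' converged); a `ccm_phenotype_map` or a preset result writes one CSV per
#' table. Output is plain decimal RFC-4180 CSV; re-running an identical
#' configuration reproduces byte-identical files.
#'
#' @param results A `ccm_steady_state`, `ccm_sweep`, `ccm_phenotype_map`, or
#'   `ccm_preset_result`.
#' @param out_dir Output directory (created if missing).
#' @param stem File-name stem; defaults to a name matching the object type.
#' @return Character vector of paths written, invisibly.
#' @export
write_results <- function(results, out_dir, stem = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  written <- character()
  w_csv <- function(d, name) {
    f <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(d, f, row.names = FALSE, quote = FALSE)
    written <<- c(written, f)
  }
  w_json <- function(meta, name) {
    f <- file.path(out_dir, paste0(name, "_meta.json"))
    jsonlite::write_json(meta, f, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    written <<- c(written, f)
  }
  if (inherits(results, "ccm_steady_state")) {
    stem <- stem %||% "steady_state"
    w_csv(steady_state_record(results), stem)
    w_json(run_metadata(results$parameters,
                        extra = list(diagnostics = results$diagnostics)), stem)
  } else if (inherits(results, "ccm_sweep")) {
    stem <- stem %||% "sweep"
    w_csv(melt_sweep_table(results$table), stem)
    first <- results$results[[1]][[1]]
    w_json(run_metadata(first$parameters,
                        extra = list(param_path = results$spec$param_path,
                                     direction = results$spec$direction)), stem)
  } else if (inherits(results, "ccm_phenotype_map")) {
    stem <- stem %||% "phenotype_map"
    w_csv(results$table, stem)
    w_csv(results$winner, paste0(stem, "_winner"))
    w_json(list(package = "ccmsim",
                version = as.character(utils::packageVersion("ccmsim")),
                readout = results$readout, deterministic = TRUE), stem)
  } else if (inherits(results, "ccm_preset_result")) {
    stem <- stem %||% results$preset
    for (nm in names(results$tables)) {
      w_csv(results$tables[[nm]], paste0(stem, "_", nm))
    }
    w_json(c(run_metadata(results$parameters),
             list(preset = results$preset,
                  assertions = results$assertions)), stem)
  } else {
    stop("write_results: unsupported object of class ",
         paste(class(results), collapse = "/"))
  }
  invisible(written)
}
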