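#' Assemble an experiment configuration
#'
#' Bundles everything one state-comparison experiment needs: the fixture
#' cell, input parameters, seeds, durations, analysis windows and metric
#' thresholds.  The resolved configuration is persisted alongside the
#' outputs by [run_state_comparison()].
#'
#' @param cell_id Fixture cell (1 or 2).
#' @param ivl_params Input parameters of the IVL state; defaults to the
#'   packaged set for the cell.
#' @param n_seeds Number of paired runs.
#' @param duration Simulation duration (ms).
#' @param discard Analysis-window transient (ms).
#' @param seed Master seed.
#' @param thresholds IVL metric thresholds (see [ivl_thresholds()]).
#' @param record_dt Recording interval (ms).
#' @param out_dir Output directory for [run_state_comparison()].
#' @return A list of class `ivl_experiment_config`.
#' @export
experiment_config <- function(cell_id = 1, ivl_params = NULL, n_seeds = 10,
                              duration = 10000, discard = 1000, seed = 1,
                              thresholds = ivl_thresholds(),
                              record_dt = 0.05, out_dir = tempdir()) {
  cfg <- list(cell_id = cell_id, ivl_params = ivl_params,
              n_seeds = n_seeds, duration = duration, discard = discard,
              seed = seed, thresholds = thresholds,
              record_dt = record_dt, out_dir = out_dir)
  validate_config(cfg)
}

#' Validate and normalize an experiment configuration
#'
#' Fills defaults for omitted fields (metric thresholds default to the
#' reference values of [ivl_thresholds()]; the IVL parameter set defaults
#' to the packaged set for the cell) and reports every invalid field by
#' name.
#'
#' @param cfg A list of configuration fields.
#' @return The normalized `ivl_experiment_config`, or an error listing
#'   the offending fields.
#' @export
validate_config <- function(cfg) {
  errors <- character(0)
  defaults <- list(cell_id = 1, ivl_params = NULL, n_seeds = 10,
                   duration = 10000, discard = 1000, seed = 1,
                   thresholds = NULL, record_dt = 0.05,
                   out_dir = tempdir())
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  if (is.null(cfg$thresholds)) cfg$thresholds <- ivl_thresholds()
  if (!cfg$cell_id %in% c(1, 2)) errors <- c(errors, "cell_id: must be 1 or 2")
  if (is.null(cfg$ivl_params)) {
    if (cfg$cell_id %in% c(1, 2)) {
      cfg$ivl_params <- reference_ivl_params(cfg$cell_id)
    }
  } else if (!all(c("n_exc", "n_inh", "f_exc", "f_inh") %in%
                    names(cfg$ivl_params))) {
    errors <- c(errors, "ivl_params: needs n_exc, n_inh, f_exc, f_inh")
  }
  if (!is.numeric(cfg$duration) || cfg$duration <= 0) {
    errors <- c(errors, "duration: must be positive")
  }
  if (!is.numeric(cfg$discard) || cfg$discard < 0 ||
        cfg$discard >= cfg$duration) {
    errors <- c(errors, "discard: must be in [0, duration)")
  }
  if (!is.numeric(cfg$n_seeds) || cfg$n_seeds < 1) {
    errors <- c(errors, "n_seeds: must be >= 1")
  }
  if (length(errors) > 0) {
    stop("invalid experiment configuration:\n  ",
         paste(errors, collapse = "\n  "), call. = FALSE)
  }
  structure(cfg, class = "ivl_experiment_config")
}

#' Run the end-to-end state-comparison experiment
#'
#' Executes the full protocol on a fixture cell: F-I calibration, the
#' ten-seed consistency check of the configured IVL parameter set, and
#' the paired IVL / in-vitro comparison, then writes tidy CSV outputs
#' (rates, charges, correlogram peaks, per-seed scores) and a
#' machine-readable run manifest to the configured output directory.
#' Identical configurations and seeds give byte-identical CSV outputs.
#'
#' @param cfg An `ivl_experiment_config` (see [experiment_config()]); a
#'   plain list is validated first.
#' @param model Optional pre-built fixture model (avoids refitting
#'   weights).
#' @return A list of class `ivl_report`: `comparison`
#'   (an `ivl_state_comparison`), `consistency`, `fi`, `config`, `files`.
#' @export
run_state_comparison <- function(cfg, model = NULL) {
  if (!inherits(cfg, "ivl_experiment_config")) cfg <- validate_config(cfg)
  if (is.null(model)) model <- make_reference_cell(cfg$cell_id)
  icfg <- model$input_config

  fi <- fi_line(model, search_range = model$rheobase_bracket,
                duration = cfg$duration, discard = cfg$discard)
  cons <- consistency_check(model, cfg$ivl_params, icfg,
                            n_seeds = cfg$n_seeds,
                            duration = cfg$duration, seed = cfg$seed,
                            weights = model$weights,
                            discard = cfg$discard,
                            record_dt = cfg$record_dt,
                            thresholds = cfg$thresholds)
  cmp <- compare_states(model, cfg$ivl_params, icfg,
                        n_seeds = cfg$n_seeds, duration = cfg$duration,
                        discard = cfg$discard, seed = cfg$seed,
                        weights = model$weights, fi = fi,
                        record_dt = cfg$record_dt)

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    rates = file.path(cfg$out_dir, "rates.csv"),
    charges = file.path(cfg$out_dir, "charges.csv"),
    xcorr = file.path(cfg$out_dir, "xcorr_peaks.csv"),
    scores = file.path(cfg$out_dir, "ivl_scores.csv"),
    manifest = file.path(cfg$out_dir, "manifest.json")
  )
  utils::write.csv(cmp$rates, files["rates"], row.names = FALSE)
  utils::write.csv(cmp$charges, files["charges"], row.names = FALSE)
  utils::write.csv(cmp$xcorr, files["xcorr"], row.names = FALSE)
  utils::write.csv(cons$scores, files["scores"], row.names = FALSE)
  manifest <- list(
    package = "olmivl",
    version = as.character(utils::packageVersion("olmivl")),
    cell_id = cfg$cell_id,
    ivl_params = as.list(cfg$ivl_params),
    n_seeds = cfg$n_seeds, duration = cfg$duration,
    discard = cfg$discard, seed = cfg$seed,
    seeds = derive_seeds(cfg$seed, cfg$n_seeds),
    consistency_verdict = cons$verdict,
    fi = list(m = fi$m, b = fi$b, rheobase = fi$rheobase),
    files = as.list(files[1:4])
  )
  writeLines(manifest_json(manifest), files["manifest"])

  structure(
    list(comparison = cmp, consistency = cons, fi = fi, config = cfg,
         files = files),
    class = "ivl_report"
  )
}

# minimal JSON serializer for the manifest (scalars, vectors, lists)
manifest_json <- function(x, indent = "") {
  jstr <- function(s) paste0("\"", gsub("\"", "\\\\\"", s), "\"")
  jval <- function(v) {
    if (is.null(v)) return("null")
    if (is.list(v)) return(manifest_json(v, paste0(indent, "  ")))
    if (is.character(v)) el <- vapply(v, jstr, "") else
      if (is.logical(v)) el <- ifelse(v, "true", "false") else
        el <- vapply(v, function(z) sprintf("%.17g", z), "")
    if (length(el) == 1 && is.null(names(v))) el else
      paste0("[", paste(el, collapse = ", "), "]")
  }
  if (is.null(names(x))) return(jval(unlist(x)))
  body <- vapply(names(x), function(nm) {
    paste0(indent, "  ", jstr(nm), ": ", jval(x[[nm]]))
  }, "")
  paste0("{\n", paste(body, collapse = ",\n"), "\n", indent, "}")
}

#' @export
print.ivl_report <- function(x, ...) {
  cat("<ivl_report> cell", x$config$cell_id, "-",
      x$config$n_seeds, "paired runs\n")
  cat("consistency verdict:", x$consistency$verdict, "\n")
  print(x$fi)
  cat("outputs:", dirname(x$files[1]), "\n")
  invisible(x)
}
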