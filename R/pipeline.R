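#' Run the end-to-end allele-portrait pipeline
#'
#' Orchestrates the full workflow: synthetic study generation (or CSV
#' ingest), QC gating, plate/baseline normalisation, distribution statistics,
#' grid chi-squared fitting of every strain under one or more fixed-parameter
#' backgrounds, relative allele coordinates vs. the reference strain,
#' hold-out validation at a concentration left out of training, and landscape
#' placement. Every stage's outputs are returned and, when `outdir` is
#' given, written as CSV/JSON with a provenance manifest.
#'
#' @param config a named list or path to a YAML file with (all optional)
#'   entries: `params_file` (else package defaults), `strains` (data frame
#'   strain/rho/kgal for synthetic generation), `events_file` +
#'   `controls_file` (CSV ingest instead of generation), `reference`
#'   (reference strain; default first strain), `concentrations`,
#'   `holdout_gal`, `time_grid`, `events_per_sample`, `replicates`,
#'   `plates`, `plate_offsets`, `model_cells`, `n_param_sets`, `grid`
#'   (list: rho_range, kgal_range, n_rho, n_kgal), `fit_cells`, `seed`,
#'   `outdir`.
#' @param quiet suppress progress messages.
#' @return A `gal_report` list: `inducibility`, `qc`, `fits`, `relative`,
#'   `dispersion`, `holdout`, `landscape`, `manifest`.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(list(
    params_file = NULL, strains = data.frame(
      strain = c("REF", "VAR"), rho = c(140, 40), kgal = c(0.055, 0.055)),
    events_file = NULL, controls_file = NULL, reference = NULL,
    concentrations = c(0.05, 0.1, 0.5), holdout_gal = 0.2,
    time_grid = twelve_point_grid(), events_per_sample = 4000,
    replicates = 2, plates = 1, plate_offsets = 0, model_cells = 600,
    n_param_sets = 2, grid = list(), fit_cells = 120, seed = 1,
    outdir = NULL), config)
  say <- function(...) if (!quiet) message("[galnet] ", sprintf(...))
  t0 <- Sys.time()

  params <- if (is.null(cfg$params_file)) default_params() else {
    if (!file.exists(cfg$params_file)) {
      stop("parameter file not found: ", cfg$params_file, call. = FALSE)
    }
    read_params(cfg$params_file)
  }

  if (!is.null(cfg$events_file)) {
    say("reading events from %s", cfg$events_file)
    events <- read_events(cfg$events_file)
    controls <- if (!is.null(cfg$controls_file)) {
      read_events(cfg$controls_file)
    } else NULL
    truth <- NULL
  } else {
    say("generating synthetic study (%d strains, seed %d)",
        nrow(cfg$strains), cfg$seed)
    des <- study_design(
      strains = tibble::as_tibble(cfg$strains),
      concentrations = cfg$concentrations, time_grid = cfg$time_grid,
      replicates = cfg$replicates, events_per_sample = cfg$events_per_sample,
      plates = cfg$plates, plate_offsets = cfg$plate_offsets,
      model_cells = cfg$model_cells, seed = cfg$seed)
    study <- generate_study(des, params = params)
    events <- study$events
    controls <- study$controls
    truth <- study$truth
  }

  say("gating %d events", nrow(events))
  min_cells <- min(3000, floor(0.5 * cfg$events_per_sample))
  gated <- gate_events(events, min_cells = min_cells)
  qc <- attr(gated, "qc")
  gated_ctrl <- if (!is.null(controls)) {
    gate_events(controls, min_cells = min(1000, nrow(controls)))
  } else NULL
  normed <- normalize_samples(gated, controls = gated_ctrl)

  say("distribution statistics")
  stats_tab <- event_statistics(normed)
  obs <- dplyr::rename(stats_tab, time = "time_min")

  strains <- unique(obs$strain)
  reference <- if (is.null(cfg$reference)) strains[1] else cfg$reference
  grid <- do.call(fit_grid, cfg$grid)
  sets <- alt_param_sets(cfg$n_param_sets)
  say("grid fitting %d strains x %d parameter sets (%d x %d grid)",
      length(strains), length(sets), length(grid$rho_values),
      length(grid$kgal_values))
  mf <- multi_fit(obs, fixed_sets = sets, reference = reference,
                  grid = grid, n_cells = cfg$fit_cells, seed = cfg$seed)

  say("hold-out prediction at [gal] = %g%%", cfg$holdout_gal)
  holdout <- dplyr::bind_rows(lapply(strains, function(s) {
    f <- mf$fit_objects[[paste("set1", s, sep = ".")]]
    dplyr::mutate(
      predict_holdout(f, gal = cfg$holdout_gal, time_grid = cfg$time_grid),
      strain = s)
  }))

  say("landscape placement")
  land <- landscape(grid$rho_values[seq(1, length(grid$rho_values), by = 4)],
                    grid$kgal_values[seq(1, length(grid$kgal_values), by = 4)],
                    gal = max(cfg$concentrations), params = params,
                    n_cells = 200, seed = cfg$seed)
  coords <- mf$fits |>
    dplyr::group_by(.data$strain) |>
    dplyr::summarise(rho = stats::median(.data$rho_hat),
                     kgal = stats::median(.data$kgal_hat), .groups = "drop")

  manifest <- list(
    seed = cfg$seed, reference = reference,
    parameter_sets = names(sets),
    grid = lapply(grid, range), fit_cells = cfg$fit_cells,
    config_hash = rlang::hash(cfg),
    started = format(t0), elapsed_s = as.numeric(Sys.time() - t0, "secs"))

  report <- structure(list(
    inducibility = stats_tab, qc = qc, fits = mf$fits,
    relative = mf$relative, dispersion = mf$dispersion,
    holdout = holdout, landscape = land, allele_coords = coords,
    truth = truth, manifest = manifest), class = "gal_report")

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(stats_tab, file.path(cfg$outdir, "inducibility.csv"),
                     row.names = FALSE)
    utils::write.csv(qc, file.path(cfg$outdir, "qc.csv"), row.names = FALSE)
    utils::write.csv(mf$fits, file.path(cfg$outdir, "fits.csv"),
                     row.names = FALSE)
    utils::write.csv(mf$relative, file.path(cfg$outdir, "relative.csv"),
                     row.names = FALSE)
    utils::write.csv(holdout, file.path(cfg$outdir, "holdout.csv"),
                     row.names = FALSE)
    utils::write.csv(land, file.path(cfg$outdir, "landscape.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("report written to %s", cfg$outdir)
  }
  report
}

#' @export
print.gal_report <- function(x, ...) {
  cat("<gal_report>\n  strains:",
      paste(unique(x$fits$strain), collapse = ", "),
      "\n  parameter sets:", length(unique(x$fits$set)),
      "\n  seed:", x$manifest$seed, "\n")
  print(x$dispersion)
  invisible(x)
}
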