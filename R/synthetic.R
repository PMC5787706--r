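#' Time grids of the two acquisition designs
#'
#' Twelve-point (multi-plate) and six-point (single-plate) acquisition
#' designs, in minutes after induction.
#' @export
twelve_point_grid <- function() c(0, 10, 20, 30, 40, 60, 80, 100, 130, 160,
                                  205, 250)
#' @rdname twelve_point_grid
#' @export
six_point_grid <- function() c(0, 30, 60, 80, 130, 210)

#' Study design for synthetic cytometry data
#'
#' @param strains tibble with columns `strain`, `rho`, `kgal`: the generating
#'   GAL3 coordinates of each simulated allele-replacement strain.
#' @param concentrations galactose concentrations (% w/v).
#' @param time_grid acquisition times; one of [twelve_point_grid()] (default),
#'   [six_point_grid()] or a custom ascending grid starting at 0.
#' @param replicates technical replicates per condition.
#' @param events_per_sample cytometry events recorded per sample
#'   (default 10000).
#' @param plates number of acquisition plates; samples are dealt out
#'   round-robin by time point, mirroring time courses spread over plates.
#' @param plate_offsets additive FL1 offset per plate (recycled/zero-padded
#'   to `plates`).
#' @param control_replicates control replicate samples per plate
#'   (default 24).
#' @param control_events events per control replicate.
#' @param model_cells cells in the network simulation that drives the ON
#'   fraction schedule.
#' @param seed integer seed for the whole study.
#' @return A `study_design` list.
#' @export
study_design <- function(strains = tibble::tibble(strain = c("BY", "weak"),
                                                  rho = c(140, 40),
                                                  kgal = c(0.055, 0.055)),
                         concentrations = c(0.05, 0.1, 0.5),
                         time_grid = twelve_point_grid(),
                         replicates = 2, events_per_sample = 10000,
                         plates = 1, plate_offsets = 0,
                         control_replicates = 24, control_events = 2000,
                         model_cells = 1000, seed = 1) {
  stopifnot(all(c("strain", "rho", "kgal") %in% names(strains)),
            events_per_sample >= 1, replicates >= 1, plates >= 1)
  if (length(time_grid) < 2 || time_grid[1] != 0 ||
      is.unsorted(time_grid, strictly = TRUE)) {
    stop("'time_grid' must be ascending and start at 0", call. = FALSE)
  }
  offs <- rep_len(c(plate_offsets, rep(0, plates)), plates)
  structure(list(strains = strains, concentrations = concentrations,
                 time_grid = time_grid, replicates = replicates,
                 events_per_sample = events_per_sample, plates = plates,
                 plate_offsets = offs,
                 control_replicates = control_replicates,
                 control_events = control_events,
                 model_cells = model_cells, seed = as.integer(seed)),
            class = "study_design")
}

#' Instrument noise model for synthetic events
#'
#' Emulates 10-bit cytometer acquisition: FL1 is autofluorescence plus
#' gain-scaled reporter signal under log-normal measurement noise, clipped to
#' the 10-bit range; FSC/SSC form a correlated Gaussian cloud with a debris/
#' doublet outlier fraction.
#'
#' @param autofl_mean,autofl_sd autofluorescence mean and sd (FL1 a.u.).
#' @param cv log-normal measurement coefficient of variation on the reporter
#'   contribution.
#' @param gain conversion from mature reporter counts to FL1 a.u.
#' @param saturation channel cap (10-bit: 1023).
#' @param fsc_mean,fsc_sd,ssc_mean,ssc_sd,fsc_ssc_cor scatter cloud shape.
#' @param outlier_fraction fraction of events drawn from the wide outlier
#'   cloud.
#' @return A `noise_model` list.
#' @export
noise_model <- function(autofl_mean = 35, autofl_sd = 7, cv = 0.2,
                        gain = 0.15, saturation = 1023,
                        fsc_mean = 450, fsc_sd = 60, ssc_mean = 380,
                        ssc_sd = 55, fsc_ssc_cor = 0.6,
                        outlier_fraction = 0.03) {
  stopifnot(outlier_fraction >= 0, outlier_fraction < 1, gain >= 0,
            saturation > 0)
  structure(list(autofl_mean = autofl_mean, autofl_sd = autofl_sd, cv = cv,
                 gain = gain, saturation = saturation, fsc_mean = fsc_mean,
                 fsc_sd = fsc_sd, ssc_mean = ssc_mean, ssc_sd = ssc_sd,
                 fsc_ssc_cor = fsc_ssc_cor,
                 outlier_fraction = outlier_fraction),
            class = "noise_model")
}

# correlated FSC/SSC cloud with an outlier (debris/doublet) fraction
draw_scatter <- function(n, nm) {
  z1 <- stats::rnorm(n)
  z2 <- nm$fsc_ssc_cor * z1 + sqrt(1 - nm$fsc_ssc_cor^2) * stats::rnorm(n)
  fsc <- nm$fsc_mean + nm$fsc_sd * z1
  ssc <- nm$ssc_mean + nm$ssc_sd * z2
  out <- stats::runif(n) < nm$outlier_fraction
  n_out <- sum(out)
  if (n_out) {
    # debris (small) or doublets (large), either way far from the main cloud
    big <- stats::runif(n_out) < 0.5
    fsc[out] <- ifelse(big, nm$fsc_mean * 1.8, nm$fsc_mean * 0.35) +
      stats::rnorm(n_out, sd = nm$fsc_sd * 2)
    ssc[out] <- ifelse(big, nm$ssc_mean * 1.8, nm$ssc_mean * 0.35) +
      stats::rnorm(n_out, sd = nm$ssc_sd * 2)
  }
  list(fsc = pmin(pmax(round(fsc), 0), nm$saturation),
       ssc = pmin(pmax(round(ssc), 0), nm$saturation))
}

# reporter counts -> FL1 channel values
signal_to_fl1 <- function(signal, nm) {
  n <- length(signal)
  eps <- if (nm$cv > 0) {
    stats::rnorm(n, sd = sqrt(log(1 + nm$cv^2)))
  } else rep(0, n)
  fl1 <- stats::rnorm(n, nm$autofl_mean, nm$autofl_sd) +
    nm$gain * signal * exp(eps)
  pmin(pmax(round(fl1), 0), nm$saturation)
}

#' Generate a synthetic cytometry study
#'
#' For each strain x concentration x time x replicate sample, draws
#' `events_per_sample` events whose reporter levels follow the network
#' model, maps them through the instrument [noise_model()], and annotates
#' plates, replicates and control samples, emitting the ground truth
#' alongside.
#'
#' Two backends are available. `"shortcut"` (default) runs one full
#' stochastic simulation per strain x concentration (`model_cells` cells)
#' and resamples per-event reporter signals from the simulated cells at each
#' time point — the ON fraction and signal distributions follow the
#' simulator at a fraction of its cost. `"ssa"` simulates every recorded
#' event as its own cell (slow, fully faithful).
#'
#' @param design a [study_design()].
#' @param params the GAL3-independent parameter backbone; each strain's
#'   (rho, kgal) is applied on top via [set_rho_kgal()].
#' @param noise a [noise_model()].
#' @param backend `"shortcut"` or `"ssa"`.
#' @return A list: `events` (tibble: fsc, ssc, fl1, strain, gal, time_min,
#'   replicate, plate, sample_id, true_on), `controls` (same schema),
#'   `truth` (per sample: `true_fraction_on`, the expected measured ON
#'   fraction with instrument noise marginalised — the estimand the analysis
#'   pipeline targets; `clean_fraction_on`, the fraction of events whose
#'   noise-free FL1 exceeds the threshold; `model_fraction_on`, the
#'   simulator's own inducibility; and the generating parameters),
#'   `threshold` (per strain: the signal-space and FL1-space ON thresholds)
#'   and `design`.
#' @export
generate_study <- function(design = study_design(), params = default_params(),
                           noise = noise_model(),
                           backend = c("shortcut", "ssa")) {
  backend <- match.arg(backend)
  stopifnot(inherits(design, "study_design"), inherits(noise, "noise_model"))
  with_seed(design$seed, generate_study_impl(design, params, noise, backend))
}

generate_study_impl <- function(design, params, noise, backend) {
  events <- list()
  truth <- list()
  thresholds <- list()
  plate_of_time <- (seq_along(design$time_grid) - 1L) %% design$plates + 1L
  t_final <- max(design$time_grid)
  for (si in seq_len(nrow(design$strains))) {
    s <- design$strains[si, ]
    pr <- set_rho_kgal(params, rho_gal3 = s$rho, kgal = s$kgal)
    strain_thr <- NULL  # signal-space threshold (set at the top concentration)
    strain_rows <- list()
    for (g in sort(design$concentrations, decreasing = TRUE)) {
      n_model <- if (backend == "ssa") {
        design$events_per_sample * design$replicates
      } else design$model_cells
      pop <- burn_in(pr, n_model, seed = design$seed + 1000L * si)
      ens <- simulate_induction(pop, gal = g, time_grid = design$time_grid,
                                seed = design$seed + 1000L * si)
      if (is.null(strain_thr)) strain_thr <- ensemble_threshold(ens)
      model_frac <- colMeans(ens$signal > strain_thr)
      for (ti in seq_along(design$time_grid)) {
        tm <- design$time_grid[ti]
        cell_sig <- ens$signal[, ti]
        for (r in seq_len(design$replicates)) {
          n_ev <- design$events_per_sample
          sig <- if (backend == "ssa") {
            cell_sig[((r - 1) * n_ev + 1):(r * n_ev)]
          } else {
            cell_sig[sample.int(length(cell_sig), n_ev, replace = TRUE)]
          }
          plate <- plate_of_time[ti]
          sc <- draw_scatter(n_ev, noise)
          fl1_raw <- signal_to_fl1(sig, noise)  # before plate offsets
          fl1 <- pmin(pmax(fl1_raw + design$plate_offsets[plate], 0),
                      noise$saturation)
          sid <- sprintf("%s_g%s_t%03d_r%d", s$strain, format(g), tm, r)
          strain_rows[[sid]] <- tibble::tibble(
            fsc = sc$fsc, ssc = sc$ssc, fl1 = fl1, fl1_raw = fl1_raw,
            clean_fl1 = noise$autofl_mean + noise$gain * sig,
            strain = s$strain, gal = g, time_min = tm, replicate = r,
            plate = plate, sample_id = sid,
            model_fraction_on = model_frac[ti],
            rho = s$rho, kgal = s$kgal)
        }
      }
    }
    rows <- dplyr::bind_rows(strain_rows)
    # truth labels apply the assay's own ON/OFF rule (equal-misclassification
    # between the pooled t = 0 reference and the induced latest-time mode,
    # estimated from the noisy offset-free FL1) to the noise-free FL1
    fl1_thr <- fl1_truth_threshold(rows, t_final)
    rows$true_on <- rows$clean_fl1 > fl1_thr
    # the estimand the pipeline targets: the expected measured ON fraction,
    # i.e. P(noisy FL1 > threshold | signal), noise marginalised analytically
    rows$p_on <- prob_fl1_above(rows$clean_fl1, fl1_thr, noise)
    thresholds[[s$strain]] <- tibble::tibble(
      strain = s$strain, signal_threshold = strain_thr,
      fl1_threshold = fl1_thr)
    ev <- rows[, c("fsc", "ssc", "fl1", "strain", "gal", "time_min",
                   "replicate", "plate", "sample_id", "true_on")]
    events[[s$strain]] <- ev
    truth[[s$strain]] <- rows |>
      dplyr::group_by(.data$strain, .data$gal, .data$time_min,
                      .data$replicate, .data$plate, .data$sample_id,
                      .data$rho, .data$kgal) |>
      dplyr::summarise(true_fraction_on = mean(.data$p_on),
                       clean_fraction_on = mean(.data$true_on),
                       model_fraction_on = .data$model_fraction_on[1],
                       .groups = "drop")
  }
  controls <- list()
  for (pl in seq_len(design$plates)) {
    for (r in seq_len(design$control_replicates)) {
      n_ev <- design$control_events
      sc <- draw_scatter(n_ev, noise)
      fl1 <- signal_to_fl1(rep(0, n_ev), noise) + design$plate_offsets[pl]
      fl1 <- pmin(pmax(fl1, 0), noise$saturation)
      sid <- sprintf("control_p%d_r%02d", pl, r)
      controls[[sid]] <- tibble::tibble(
        fsc = sc$fsc, ssc = sc$ssc, fl1 = fl1, strain = "control",
        gal = 0, time_min = 0, replicate = r, plate = pl, sample_id = sid,
        true_on = FALSE)
    }
  }
  list(events = dplyr::bind_rows(events), controls = dplyr::bind_rows(controls),
       truth = dplyr::bind_rows(truth),
       threshold = dplyr::bind_rows(thresholds), design = design)
}

# P(measured FL1 > t | clean FL1), marginalising the additive
# autofluorescence noise (Gaussian) and the multiplicative log-normal
# measurement noise (Gauss-type quadrature over the log-normal factor)
prob_fl1_above <- function(clean_fl1, t, noise) {
  sig_contrib <- pmax(clean_fl1 - noise$autofl_mean, 0)
  if (noise$cv > 0) {
    sdlog <- sqrt(log(1 + noise$cv^2))
    z <- seq(-4, 4, length.out = 41)
    w <- stats::dnorm(z)
    w <- w / sum(w)
    e <- exp(sdlog * z)
    p <- sapply(seq_along(z), function(k) {
      stats::pnorm((noise$autofl_mean + sig_contrib * e[k] - t) /
                     max(noise$autofl_sd, 1e-9))
    })
    drop(p %*% w)
  } else {
    stats::pnorm((noise$autofl_mean + sig_contrib - t) /
                   max(noise$autofl_sd, 1e-9))
  }
}

# cytometry-rule threshold used for ground-truth labels: OFF reference from
# pooled t = 0 offset-free FL1, ON reference from the induced latest-time
# distribution (unimodal separated mode, else upper mixture component)
fl1_truth_threshold <- function(rows, t_final) {
  off <- rows$fl1_raw[rows$time_min == 0]
  mu_off <- mean(off)
  sd_off <- max(stats::sd(off), 1e-6)
  fin <- rows$fl1_raw[rows$time_min == t_final &
                        rows$gal == max(rows$gal)]
  fallback <- stats::quantile(off, 0.99, names = FALSE) * 5
  if (length(fin) < 50) return(fallback)
  fit <- fit_fl1_mixture(fin)
  if (fit$n_components == 2L) {
    mu_on <- fit$mu_on; sd_on <- max(fit$sigma_on, 1e-6)
  } else {
    mu_on <- fit$mu_all; sd_on <- max(fit$sigma_all, 1e-6)
  }
  if (mu_on <= mu_off + 5 * sd_off) return(fallback)
  on_off_threshold(mu_off, sd_off, mu_on, sd_on)
}

#' Write / read event tables
#'
#' Long-format CSV with the fixed column order `fsc, ssc, fl1, strain, gal,
#' time_min, replicate, plate, sample_id[, true_on]`. The round trip is
#' lossless.
#'
#' @param events an event tibble.
#' @param path CSV file path.
#' @return `write_events()` returns `path` invisibly; `read_events()` the
#'   event tibble.
#' @export
write_events <- function(events, path) {
  check_events(events)
  cols <- intersect(c(EVENT_COLS, "true_on"), names(events))
  utils::write.csv(events[cols], path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA)
  check_events(df)
  df$strain <- as.character(df$strain)
  df$sample_id <- as.character(df$sample_id)
  if ("true_on" %in% names(df)) df$true_on <- as.logical(df$true_on)
  tibble::as_tibble(df)
}
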