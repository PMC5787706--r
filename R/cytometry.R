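EVENT_COLS <- c("fsc", "ssc", "fl1", "strain", "gal", "time_min", "replicate",
                "plate", "sample_id")

check_events <- function(events, need = EVENT_COLS) {
  miss <- setdiff(need, names(events))
  if (length(miss)) {
    stop("event table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(events)
}

#' Quality-control gating of cytometry events
#'
#' Per sample: (i) events with saturated signals (FSC, SSC or FL1 equal to
#' 0 or the 10-bit cap 1023) are removed; (ii) a 2D Gaussian kernel density
#' (Scott bandwidth, 128 x 128 grid) of the remaining (FSC, SSC) values
#' defines the highest-density region containing `keep_fraction` of events,
#' and only events inside it are retained; (iii) samples left with fewer than
#' `min_cells` events are dropped.
#'
#' @param events an event tibble with at least the columns `fsc`, `ssc`,
#'   `fl1` and `sample_id`.
#' @param keep_fraction fraction of unsaturated events the density gate
#'   keeps (default 0.60).
#' @param min_cells minimum retained events for a sample to survive
#'   (default 3000).
#' @param saturation channel cap (default 1023).
#' @return The gated event tibble; the per-sample QC report (sample_id,
#'   n_events, n_saturated, n_gated, kept, reason) is in `attr(, "qc")`.
#' @export
gate_events <- function(events, keep_fraction = 0.60, min_cells = 3000,
                        saturation = 1023) {
  check_events(events, c("fsc", "ssc", "fl1", "sample_id"))
  split_ev <- split(events, events$sample_id)
  qc <- list()
  kept <- list()
  for (sid in names(split_ev)) {
    ev <- split_ev[[sid]]
    sat <- ev$fsc %in% c(0, saturation) | ev$ssc %in% c(0, saturation) |
      ev$fl1 %in% c(0, saturation)
    ok <- ev[!sat, , drop = FALSE]
    if (nrow(ok) == 0L) {
      qc[[sid]] <- tibble::tibble(sample_id = sid, n_events = nrow(ev),
                                  n_saturated = sum(sat), n_gated = 0L,
                                  kept = FALSE, reason = "no unsaturated events")
      next
    }
    inside <- density_gate(ok$fsc, ok$ssc, keep_fraction)
    gated <- ok[inside, , drop = FALSE]
    keep <- nrow(gated) >= min_cells
    qc[[sid]] <- tibble::tibble(
      sample_id = sid, n_events = nrow(ev), n_saturated = sum(sat),
      n_gated = nrow(gated), kept = keep,
      reason = if (keep) NA_character_ else
        sprintf("fewer than %d cells after gating", min_cells)
    )
    if (keep) kept[[sid]] <- gated
  }
  out <- dplyr::bind_rows(kept)
  attr(out, "qc") <- dplyr::bind_rows(qc)
  out
}

# highest-density-region membership for keep_fraction of the points
density_gate <- function(x, y, keep_fraction, grid_n = 128) {
  n <- length(x)
  if (n < 10) return(rep(TRUE, n))
  # Scott's rule per dimension for a 2D Gaussian product kernel; kde2d's h is
  # the full bandwidth (it divides by 4 internally for dnorm's sd)
  hx <- 4 * stats::sd(x) * n^(-1 / 6)
  hy <- 4 * stats::sd(y) * n^(-1 / 6)
  if (hx <= 0 || hy <= 0) return(rep(TRUE, n))
  lims <- c(range(x) + c(-1, 1) * hx, range(y) + c(-1, 1) * hy)
  kd <- MASS::kde2d(x, y, h = c(hx, hy), n = grid_n, lims = lims)
  # bilinear interpolation of the density at each event
  ix <- findInterval(x, kd$x, all.inside = TRUE)
  iy <- findInterval(y, kd$y, all.inside = TRUE)
  wx <- (x - kd$x[ix]) / diff(kd$x[1:2])
  wy <- (y - kd$y[iy]) / diff(kd$y[1:2])
  dens <- kd$z[cbind(ix, iy)] * (1 - wx) * (1 - wy) +
    kd$z[cbind(ix + 1L, iy)] * wx * (1 - wy) +
    kd$z[cbind(ix, iy + 1L)] * (1 - wx) * wy +
    kd$z[cbind(ix + 1L, iy + 1L)] * wx * wy
  cut <- stats::quantile(dens, probs = 1 - keep_fraction, names = FALSE)
  dens >= cut
}

#' Plate-effect and baseline normalisation of FL1 values
#'
#' When the design spans several plates, the fixed effect of plates is
#' estimated by a one-way ANOVA on the per-control-sample mean FL1 of the
#' control replicates carried on every plate, and each plate's offset
#' (its control mean minus the grand control mean) is subtracted from all
#' FL1 values on that plate. Single-plate inputs skip the plate correction.
#' Finally the per-strain mean FL1 of the t = 0 samples is subtracted
#' (autofluorescence baseline).
#'
#' @param events gated event tibble (full schema, see [read_events()]).
#' @param controls event tibble of control replicates with at least `fl1`,
#'   `plate` and `sample_id`; required whenever `events` spans more than one
#'   plate.
#' @param baseline subtract the per-strain t = 0 mean (default TRUE).
#' @return The corrected event tibble with attributes `plate_offsets`
#'   (tibble: plate, offset) and `plate_anova_p`.
#' @export
normalize_samples <- function(events, controls = NULL, baseline = TRUE) {
  check_events(events)
  plates <- unique(events$plate)
  offsets <- tibble::tibble(plate = plates, offset = 0)
  anova_p <- NA_real_
  if (length(plates) > 1L) {
    if (is.null(controls) || nrow(controls) == 0L) {
      stop("multi-plate design: control replicates are required for the ",
           "plate correction", call. = FALSE)
    }
    check_events(controls, c("fl1", "plate", "sample_id"))
    missing_pl <- setdiff(plates, unique(controls$plate))
    if (length(missing_pl)) {
      stop("no control replicates for plate(s): ",
           paste(missing_pl, collapse = ", "), call. = FALSE)
    }
    ctrl_means <- controls |>
      dplyr::group_by(.data$plate, .data$sample_id) |>
      dplyr::summarise(mean_fl1 = mean(.data$fl1), .groups = "drop")
    fit <- stats::aov(mean_fl1 ~ factor(plate), data = ctrl_means)
    anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    grand <- mean(ctrl_means$mean_fl1)
    offsets <- ctrl_means |>
      dplyr::group_by(plate = .data$plate) |>
      dplyr::summarise(offset = mean(.data$mean_fl1) - grand, .groups = "drop")
    events <- events |>
      dplyr::left_join(offsets, by = "plate") |>
      dplyr::mutate(fl1 = .data$fl1 - .data$offset) |>
      dplyr::select(-"offset")
  }
  if (baseline) {
    base <- events |>
      dplyr::filter(.data$time_min == 0) |>
      dplyr::group_by(.data$strain) |>
      dplyr::summarise(baseline_fl1 = mean(.data$fl1), .groups = "drop")
    no_t0 <- setdiff(unique(events$strain), base$strain)
    if (length(no_t0)) {
      stop("no t = 0 sample for strain(s): ", paste(no_t0, collapse = ", "),
           call. = FALSE)
    }
    events <- events |>
      dplyr::left_join(base, by = "strain") |>
      dplyr::mutate(fl1 = .data$fl1 - .data$baseline_fl1) |>
      dplyr::select(-"baseline_fl1")
  }
  attr(events, "plate_offsets") <- offsets
  attr(events, "plate_anova_p") <- anova_p
  events
}

#' End-to-end cytometry statistics
#'
#' Runs the full distribution analysis on a gated, normalised event table:
#' the OFF reference is the pooled t = 0 cells; the ON reference pools the
#' activated cells of unimodal latest-time distributions (falling back to
#' the upper mixture components when every strain is still bimodal); the
#' equal-misclassification threshold [on_off_threshold()] between the two
#' references then yields per-condition inducibility, and per-condition
#' mixture fits yield the response amplitude.
#'
#' @param events gated + normalised event tibble.
#' @return A tibble with one row per (strain, gal, time_min): `fraction_on`,
#'   `sem`, `n_cells` and `amplitude`. The threshold and references are in
#'   `attr(, "threshold")` / `attr(, "references")`.
#' @export
event_statistics <- function(events) {
  check_events(events)
  off <- events$fl1[events$time_min == 0]
  if (length(off) < 50) stop("need t = 0 cells for the OFF reference",
                             call. = FALSE)
  mu_off <- mean(off)
  sd_off <- max(stats::sd(off), 1e-6)

  t_max <- max(events$time_min)
  late <- events[events$time_min == t_max, , drop = FALSE]
  on_pool <- numeric()
  on_from_mix <- c()
  for (s in unique(late$strain)) {
    for (g in unique(late$gal[late$strain == s])) {
      v <- late$fl1[late$strain == s & late$gal == g]
      if (length(v) < 50) next
      fit <- fit_fl1_mixture(v)
      if (fit$n_components == 1L) {
        if (fit$mu_all > mu_off + 3 * sd_off) on_pool <- c(on_pool, v)
      } else {
        on_from_mix <- rbind(on_from_mix, c(fit$mu_on, fit$sigma_on))
      }
    }
  }
  if (length(on_pool) >= 50) {
    mu_on <- mean(on_pool); sd_on <- max(stats::sd(on_pool), 1e-6)
  } else if (!is.null(on_from_mix)) {
    mu_on <- mean(on_from_mix[, 1]); sd_on <- max(mean(on_from_mix[, 2]), 1e-6)
  } else {
    stop("no activated reference population found at the latest time point",
         call. = FALSE)
  }
  thr <- on_off_threshold(mu_off, sd_off, mu_on, sd_on)

  out <- events |>
    dplyr::group_by(.data$strain, .data$gal, .data$time_min) |>
    dplyr::summarise(
      fraction_on = mean(.data$fl1 > thr),
      sem = sqrt(.data$fraction_on * (1 - .data$fraction_on) /
                   dplyr::n()),
      n_cells = dplyr::n(),
      amplitude = response_amplitude(fit_fl1_mixture(.data$fl1)),
      .groups = "drop"
    )
  attr(out, "threshold") <- thr
  attr(out, "references") <- tibble::tibble(
    component = c("OFF", "ON"), mu = c(mu_off, mu_on), sigma = c(sd_off, sd_on))
  out
}
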