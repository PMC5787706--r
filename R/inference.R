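#' Global chi-squared score between observed and predicted inducibility
#'
#' Sums `(I_obs - I_pred)^2 / sigma^2` over every (gal, time) pair, with
#' `sigma^2 = sem_obs^2 + sem_pred^2` floored at `(1 / n_pred)^2` so that
#' perfectly quiet points cannot dominate.
#'
#' @param obs tibble with columns `gal`, `time`, `fraction_on`, `sem`.
#' @param pred tibble with columns `gal`, `time`, `fraction_on`, `sem`,
#'   `n_cells` covering exactly the same (gal, time) keys.
#' @return The non-negative score.
#' @export
chi2_score <- function(obs, pred) {
  need <- c("gal", "time", "fraction_on", "sem")
  if (!all(need %in% names(obs)) || !all(need %in% names(pred))) {
    stop("'obs' and 'pred' need columns gal, time, fraction_on, sem",
         call. = FALSE)
  }
  j <- dplyr::inner_join(obs, pred, by = c("gal", "time"),
                         suffix = c("_obs", "_pred"))
  if (nrow(j) != nrow(obs) || nrow(j) != nrow(pred)) {
    stop("'obs' and 'pred' must share identical (gal, time) keys",
         call. = FALSE)
  }
  n_pred <- if ("n_cells_pred" %in% names(j)) j$n_cells_pred else
    if ("n_cells" %in% names(j)) j$n_cells else Inf
  s2 <- pmax(j$sem_obs^2 + j$sem_pred^2, (1 / n_pred)^2)
  sum((j$fraction_on_obs - j$fraction_on_pred)^2 / s2)
}

#' Log-spaced fitting grid
#'
#' @param rho_range,kgal_range length-2 ranges for the GAL3 strength and the
#'   galactose constant.
#' @param n_rho,n_kgal points per axis.
#' @return A list with the two strictly increasing axes.
#' @export
fit_grid <- function(rho_range = c(10, 1000), kgal_range = c(0.005, 0.5),
                     n_rho = 21, n_kgal = 21) {
  stopifnot(rho_range[1] > 0, kgal_range[1] > 0,
            rho_range[2] > rho_range[1], kgal_range[2] > kgal_range[1])
  list(rho_values = 10^seq(log10(rho_range[1]), log10(rho_range[2]),
                           length.out = n_rho),
       kgal_values = 10^seq(log10(kgal_range[1]), log10(kgal_range[2]),
                            length.out = n_kgal))
}

#' Grid chi-squared fit of (rho_Gal3, Kgal)
#'
#' Simulates the inducibility time course at every point of a 2D logarithmic
#' (rho_Gal3, Kgal) grid — with common random numbers across grid points —
#' for each observed galactose concentration, scores each point with
#' [chi2_score()], and returns the arg-min with half-grid-spacing (log)
#' uncertainties. Ties break toward smaller rho, then smaller Kgal. A flat
#' surface (max - min < 1) is flagged unidentifiable.
#'
#' @param obs inducibility tibble with columns `gal`, `time`, `fraction_on`,
#'   `sem` (one strain; see [multi_fit()] for panels).
#' @param grid a [fit_grid()] list.
#' @param params the fixed GAL3-independent parameter backbone.
#' @param n_cells cells simulated per grid point and concentration.
#' @param seed seed shared by all grid points (common random numbers).
#' @param threshold fixed ON/OFF signal threshold shared by every grid
#'   point. When `NULL`, the observations' own signal-space threshold
#'   (`attr(obs, "signal_threshold")`, present when `obs` came from
#'   [strain_inducibility()]) is used; failing that, one threshold is
#'   derived at the first grid point scored and then shared. A single
#'   threshold across the grid keeps the chi-squared surface free of
#'   threshold-estimation noise, which otherwise rivals the score
#'   differences between neighbouring cells.
#' @param strain optional strain label carried into the result.
#' @param extrinsic_cv passed to [burn_in()].
#' @param refine_top,refine_factor second-stage refinement: after the full
#'   grid scan, the `refine_top` best cells are re-scored with
#'   `refine_factor * n_cells` cells under an independent seed, and the
#'   arg-min is taken among the refined scores. The common random numbers
#'   that keep the first-stage surface smooth also tilt it coherently (one
#'   shared Monte Carlo draw biases every grid point the same way);
#'   refinement averages that tilt away where it matters. Set
#'   `refine_top = 0` to disable.
#' @return A `gal_fit` object; `glance()` it for the point estimates and
#'   `tidy()` for the chi-squared surface.
#' @export
grid_fit <- function(obs, grid = fit_grid(), params = default_params(),
                     n_cells = 200, seed = 1, threshold = NULL,
                     strain = NA_character_, extrinsic_cv = 0.2,
                     refine_top = 24, refine_factor = 4) {
  stopifnot(is.data.frame(obs))
  if (!all(c("gal", "time", "fraction_on", "sem") %in% names(obs))) {
    stop("'obs' needs columns gal, time, fraction_on, sem", call. = FALSE)
  }
  gals <- sort(unique(obs$gal))
  time_grid <- sort(unique(obs$time))
  if (time_grid[1] != 0) time_grid <- c(0, time_grid)
  thr <- threshold
  if (is.null(thr)) thr <- attr(obs, "signal_threshold")
  surf <- tidyr::expand_grid(rho = grid$rho_values, kgal = grid$kgal_values)
  surf$chi2 <- NA_real_
  for (i in seq_len(nrow(surf))) {
    pr <- set_rho_kgal(params, rho_gal3 = surf$rho[i], kgal = surf$kgal[i])
    pred <- strain_inducibility(pr, gals = gals, time_grid = time_grid,
                                n_cells = n_cells, seed = seed,
                                threshold = thr,
                                extrinsic_cv = extrinsic_cv)
    if (is.null(thr)) thr <- attr(pred, "signal_threshold")
    pred <- dplyr::semi_join(pred, obs, by = c("gal", "time"))
    surf$chi2[i] <- chi2_score(obs, pred)
  }
  # tie-break deterministically toward small rho, then small kgal
  ord <- order(surf$chi2, surf$rho, surf$kgal)
  refined <- NULL
  if (refine_top > 0 && refine_top < nrow(surf)) {
    top <- surf[ord[seq_len(refine_top)], c("rho", "kgal")]
    n_ref <- refine_factor * n_cells
    seed_ref <- (seed + 7919) %% .Machine$integer.max
    top$chi2 <- vapply(seq_len(nrow(top)), function(i) {
      pr <- set_rho_kgal(params, rho_gal3 = top$rho[i], kgal = top$kgal[i])
      pred <- strain_inducibility(pr, gals = gals, time_grid = time_grid,
                                  n_cells = n_ref, seed = seed_ref,
                                  threshold = thr,
                                  extrinsic_cv = extrinsic_cv)
      pred <- dplyr::semi_join(pred, obs, by = c("gal", "time"))
      chi2_score(obs, pred)
    }, numeric(1))
    refined <- top
    ord_ref <- order(top$chi2, top$rho, top$kgal)
    best <- top[ord_ref[1], ]
  } else {
    best <- surf[ord[1], ]
  }
  log_step_rho <- diff(log10(grid$rho_values[1:2]))
  log_step_kgal <- diff(log10(grid$kgal_values[1:2]))
  structure(list(
    rho_hat = best$rho, kgal_hat = best$kgal,
    rho_err = log_step_rho / 2, kgal_err = log_step_kgal / 2,
    chi2_min = best$chi2, surface = surf, refined = refined, grid = grid,
    unidentifiable = (max(surf$chi2) - min(surf$chi2)) < 1,
    params = params, n_cells = n_cells, seed = as.integer(seed),
    threshold = thr, extrinsic_cv = extrinsic_cv,
    strain = strain
  ), class = "gal_fit")
}

#' @export
print.gal_fit <- function(x, ...) {
  cat("<gal_fit>", if (!is.na(x$strain)) paste0("strain ", x$strain) else "",
      "\n  rho_Gal3 =", signif(x$rho_hat, 4), "(+/-", signif(x$rho_err, 3),
      "log10 units)\n  Kgal     =", signif(x$kgal_hat, 4), "(+/-",
      signif(x$kgal_err, 3), "log10 units)\n  chi2_min =",
      signif(x$chi2_min, 5),
      if (x$unidentifiable) "\n  [flagged unidentifiable: flat surface]" else "",
      "\n")
  invisible(x)
}

#' Sub-cell polish of a grid fit
#'
#' With many cells per prediction the chi-squared surface is a sharp,
#' diagonally oriented valley, and the generating parameters rarely sit on a
#' grid point, so the arg-min cell alone is limited to half-cell accuracy
#' with coupled (rho, Kgal) quantisation errors. `polish_fit()` re-scores
#' the best refined cells at high precision to locate the valley, then
#' exploits the valley geometry: for each of three neighbouring rho rows it
#' finds the Kgal valley floor by a three-point parabola (the cross-valley
#' direction is sharp, so these vertices are accurate), then fits a parabola
#' to the floor heights along rho to interpolate the ridge minimum, and
#' finally reads the polished Kgal off the fitted ridge line at that rho.
#' Rows and row windows expand automatically (up to `max_expand` cells)
#' when a minimum falls on an edge.
#'
#' @param fit a `gal_fit` from [grid_fit()].
#' @param obs the observation tibble the fit was scored against.
#' @param n_cells cells per prediction in the high-precision stage.
#' @param top how many of the refined cells to re-score when locating the
#'   polish centre.
#' @param max_expand maximum window expansions per direction.
#' @param seed seed for the polish stage (default derives from the fit's).
#' @return A list with `rho_star`, `kgal_star` (continuous, clamped to the
#'   scored region), the central `cell`, and the scored `points` tibble.
#' @export
polish_fit <- function(fit, obs, n_cells = 3000, top = 6, max_expand = 2,
                       seed = NULL) {
  stopifnot(inherits(fit, "gal_fit"))
  if (is.null(seed)) seed <- (fit$seed + 104729L) %% .Machine$integer.max
  grid <- fit$grid
  n_r <- length(grid$rho_values)
  n_k <- length(grid$kgal_values)
  gals <- sort(unique(obs$gal))
  time_grid <- sort(unique(obs$time))
  if (time_grid[1] != 0) time_grid <- c(0, time_grid)
  cache <- new.env(parent = emptyenv())
  score_cell <- function(ir, ik) {
    key <- paste(ir, ik)
    if (!is.null(cache[[key]])) return(cache[[key]])
    pr <- set_rho_kgal(fit$params, rho_gal3 = grid$rho_values[ir],
                       kgal = grid$kgal_values[ik])
    pred <- strain_inducibility(pr, gals = gals, time_grid = time_grid,
                                n_cells = n_cells, seed = seed,
                                threshold = fit$threshold,
                                extrinsic_cv = fit$extrinsic_cv)
    pred <- dplyr::semi_join(pred, obs, by = c("gal", "time"))
    cache[[key]] <- chi2_score(obs, pred)
    cache[[key]]
  }
  idx_of <- function(v, values) which.min(abs(log10(values) - log10(v)))
  vertex3 <- function(x, z) {
    # parabola vertex through three equispaced points, clamped to the span
    den <- z[1] - 2 * z[2] + z[3]
    if (!is.finite(den) || den <= 0) return(list(x = x[2], z = z[2]))
    h <- (x[3] - x[1]) / 2
    a <- den / (2 * h^2)
    b <- (z[3] - z[1]) / (2 * h)
    dx <- min(max(-b / (2 * a), -h), h)
    list(x = x[2] + dx, z = a * dx^2 + b * dx + z[2])
  }

  # locate the valley among the best refined (or surface) cells
  cand <- if (!is.null(fit$refined)) fit$refined else fit$surface
  cand <- cand[order(cand$chi2), ][seq_len(min(top, nrow(cand))), ]
  cand$hi <- vapply(seq_len(nrow(cand)), function(i) {
    score_cell(idx_of(cand$rho[i], grid$rho_values),
               idx_of(cand$kgal[i], grid$kgal_values))
  }, numeric(1))
  ctr <- cand[which.min(cand$hi), ]
  ir0 <- idx_of(ctr$rho, grid$rho_values)
  ik0 <- idx_of(ctr$kgal, grid$kgal_values)

  # per-row Kgal valley floor: walk to the row minimum, then 3-point vertex
  row_floor <- function(ir, ik_start) {
    ik <- max(2L, min(n_k - 1L, ik_start))
    for (step in seq_len(2 + 2 * max_expand)) {
      zs <- c(score_cell(ir, ik - 1L), score_cell(ir, ik),
              score_cell(ir, ik + 1L))
      if (which.min(zs) == 2L) break
      ik <- max(2L, min(n_k - 1L, ik + which.min(zs) - 2L))
    }
    v <- vertex3(log10(grid$kgal_values[(ik - 1):(ik + 1)]),
                 c(score_cell(ir, ik - 1L), score_cell(ir, ik),
                   score_cell(ir, ik + 1L)))
    list(k = v$x, z = v$z, ik = ik)
  }

  ir_mid <- max(2L, min(n_r - 1L, ir0))
  rows <- ir_mid + (-1:1)
  mid <- row_floor(ir_mid, ik0)
  # the valley runs diagonally: start neighbouring rows one cell off
  lo <- row_floor(rows[1], mid$ik - 1L)
  hi <- row_floor(rows[3], mid$ik + 1L)
  # walk along rho while an outer row undercuts the middle one
  for (step in seq_len(max_expand)) {
    zs <- c(lo$z, mid$z, hi$z)
    if (which.min(zs) == 2L) break
    if (zs[1] < zs[2] && rows[1] > 1L) {
      rows <- rows - 1L
      hi <- mid; mid <- lo
      lo <- row_floor(rows[1], mid$ik - 1L)
    } else if (zs[3] < zs[2] && rows[3] < n_r) {
      rows <- rows + 1L
      lo <- mid; mid <- hi
      hi <- row_floor(rows[3], mid$ik + 1L)
    } else break
  }
  xr <- log10(grid$rho_values[rows])
  vr <- vertex3(xr, c(lo$z, mid$z, hi$z))
  rho_star <- 10^min(max(vr$x, xr[1]), xr[3])
  # ridge line: least-squares fit of the row floors' Kgal vs rho
  ridge <- stats::lm(c(lo$k, mid$k, hi$k) ~ xr)
  k_star <- stats::predict(ridge, newdata = data.frame(xr = log10(rho_star)))
  k_star <- min(max(k_star, log10(grid$kgal_values[1])),
                log10(grid$kgal_values[n_k]))
  pts <- do.call(rbind, lapply(ls(cache), function(key) {
    ij <- as.integer(strsplit(key, " ")[[1]])
    data.frame(rho = grid$rho_values[ij[1]], kgal = grid$kgal_values[ij[2]],
               chi2 = cache[[key]])
  }))
  list(rho_star = rho_star, kgal_star = 10^k_star,
       cell = c(rho = grid$rho_values[ir0], kgal = grid$kgal_values[ik0]),
       points = tibble::as_tibble(pts))
}

#' Repeat the fit under alternative fixed-parameter backgrounds
#'
#' Applies [grid_fit()] to every strain in `obs` under each of the supplied
#' GAL3-independent parameter sets, then expresses each strain's
#' (rho_Gal3, Kgal) relative to the reference strain per set.
#'
#' @param obs inducibility tibble with a `strain` column in addition to
#'   `gal`, `time`, `fraction_on`, `sem`.
#' @param fixed_sets named list of [gal_params()] backbones, e.g.
#'   [alt_param_sets()].
#' @param reference strain used as the denominator of the relative values.
#' @inheritParams grid_fit
#' @return A list with `fits` (tibble: strain, set, rho_hat, kgal_hat, ...),
#'   `relative` (strain, set, rho_rel, kgal_rel) and `dispersion`
#'   (per-strain sd of log10 relative values across sets).
#' @export
multi_fit <- function(obs, fixed_sets = alt_param_sets(), reference,
                      grid = fit_grid(), n_cells = 200, seed = 1,
                      threshold = NULL, extrinsic_cv = 0.2) {
  stopifnot("strain" %in% names(obs))
  strains <- unique(obs$strain)
  if (!reference %in% strains) {
    stop("reference strain '", reference, "' not present in 'obs'",
         call. = FALSE)
  }
  rows <- list()
  fits <- list()
  for (set_id in names(fixed_sets)) {
    for (s in strains) {
      f <- grid_fit(obs[obs$strain == s, , drop = FALSE], grid = grid,
                    params = fixed_sets[[set_id]], n_cells = n_cells,
                    seed = seed, threshold = threshold, strain = s,
                    extrinsic_cv = extrinsic_cv)
      if (s == reference && f$unidentifiable) {
        stop("reference strain fit is unidentifiable under parameter set '",
             set_id, "'", call. = FALSE)
      }
      fits[[paste(set_id, s, sep = ".")]] <- f
      rows[[length(rows) + 1L]] <- tibble::tibble(
        strain = s, set = set_id, rho_hat = f$rho_hat, kgal_hat = f$kgal_hat,
        chi2_min = f$chi2_min, unidentifiable = f$unidentifiable)
    }
  }
  tab <- dplyr::bind_rows(rows)
  ref <- tab |>
    dplyr::filter(.data$strain == reference) |>
    dplyr::select("set", ref_rho = "rho_hat", ref_kgal = "kgal_hat")
  rel <- tab |>
    dplyr::left_join(ref, by = "set") |>
    dplyr::mutate(rho_rel = .data$rho_hat / .data$ref_rho,
                  kgal_rel = .data$kgal_hat / .data$ref_kgal) |>
    dplyr::select("strain", "set", "rho_rel", "kgal_rel")
  disp <- rel |>
    dplyr::group_by(.data$strain) |>
    dplyr::summarise(rho_rel_med = stats::median(.data$rho_rel),
                     kgal_rel_med = stats::median(.data$kgal_rel),
                     sd_log10_rho_rel = stats::sd(log10(.data$rho_rel)),
                     sd_log10_kgal_rel = stats::sd(log10(.data$kgal_rel)),
                     .groups = "drop")
  list(fits = tab, fit_objects = fits, relative = rel, dispersion = disp,
       reference = reference)
}

#' Forward prediction at a held-out concentration
#'
#' Simulates the inducibility time course at a concentration that was not
#' used in fitting, using the fitted (rho_Gal3, Kgal) with no further
#' adjustment.
#'
#' @param fit a `gal_fit` from [grid_fit()].
#' @param gal held-out galactose concentration (% w/v).
#' @param time_grid sampling times (minutes, starting at 0).
#' @param n_cells,seed simulation size and seed; defaults reuse the fit's.
#' @return An inducibility tibble as from [predicted_inducibility()].
#' @export
predict_holdout <- function(fit, gal, time_grid, n_cells = NULL, seed = NULL) {
  stopifnot(inherits(fit, "gal_fit"))
  if (is.null(n_cells)) n_cells <- fit$n_cells
  if (is.null(seed)) seed <- fit$seed
  pr <- set_rho_kgal(fit$params, rho_gal3 = fit$rho_hat, kgal = fit$kgal_hat)
  predicted_inducibility(pr, gal = gal, time_grid = time_grid,
                         n_cells = n_cells, seed = seed,
                         threshold = fit$threshold,
                         extrinsic_cv = fit$extrinsic_cv)
}
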