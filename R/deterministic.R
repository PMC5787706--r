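MF_NAMES <- c(paste0("p_", tolower(GENE_ORDER)), paste0("m_", tolower(GENE_ORDER)),
              paste0("P_", tolower(GENE_ORDER)), "gfp_mature")

#' Mean-field state vector
#'
#' Builds the 13-dimensional deterministic state: promoter ON probabilities,
#' mean mRNA and mean protein per gene (the REPORTER protein slot holds the
#' immature pool) plus the mature reporter.
#'
#' @param p_on,mrna,protein length-4 vectors in gene order GAL1, GAL3, GAL80,
#'   REPORTER.
#' @param gfp_mature mature reporter level.
#' @return A named numeric vector.
#' @export
mean_field_state <- function(p_on, mrna, protein, gfp_mature = 0) {
  stopifnot(length(p_on) == 4, length(mrna) == 4, length(protein) == 4)
  if (any(p_on < 0 | p_on > 1)) stop("'p_on' must lie in [0, 1]", call. = FALSE)
  if (any(c(mrna, protein, gfp_mature) < 0)) {
    stop("means must be non-negative", call. = FALSE)
  }
  stats::setNames(c(p_on, mrna, protein, gfp_mature), MF_NAMES)
}

# leak-only (OFF) steady state, the deterministic uninduced baseline
mf_off_state <- function(params) {
  g <- params$genes
  al <- vapply(g, `[[`, numeric(1), "alpha")
  be <- vapply(g, `[[`, numeric(1), "beta")
  ga <- vapply(g, `[[`, numeric(1), "gamma")
  mu <- vapply(g, `[[`, numeric(1), "mu")
  m <- al / be
  P <- ga * m / mu
  nu <- params$shared$nu_mat
  P[4] <- ga[4] * m[4] / (mu[4] + nu)      # immature reporter loses to maturation
  mean_field_state(rep(0, 4), m, P, gfp_mature = nu * P[4] / mu[4])
}

#' Mean-field time derivatives
#'
#' The deterministic reduction of the stochastic model:
#' `dp/dt = k_on (1 - p) - k_off p`, `dm/dt = alpha + delta_alpha p - beta m`,
#' `dP/dt = gamma m - mu P`, with the switching rates evaluated from the
#' current mean protein levels through [promoter_rates()]'s laws, plus the
#' reporter maturation flux.
#'
#' @param state a named vector from [mean_field_state()].
#' @param params a [gal_params()] object.
#' @param gal galactose concentration (% w/v).
#' @return Named vector of time derivatives (per minute).
#' @export
mean_field_rhs <- function(state, params, gal) {
  stopifnot(inherits(params, "gal_params"))
  p <- state[1:4]; m <- state[5:8]; P <- state[9:12]; gmat <- state[13]
  sh <- params$shared
  f <- if (gal > 0) (gal / sh$Kgal) / (1 + gal / sh$Kgal) else 0
  drive <- (f * P[1] / sh$K1)^2 + (f * P[2] / sh$K3)^2
  rep80 <- (P[3] / sh$K80)^2
  g <- params$genes
  al <- vapply(g, `[[`, numeric(1), "alpha")
  da <- vapply(g, `[[`, numeric(1), "delta_alpha")
  be <- vapply(g, `[[`, numeric(1), "beta")
  ga <- vapply(g, `[[`, numeric(1), "gamma")
  mu <- vapply(g, `[[`, numeric(1), "mu")
  ns <- vapply(g, `[[`, integer(1), "n_sites")
  kon <- sh$k0_on * drive^ns
  koff <- sh$k0_off * rep80^ns
  dp <- kon * (1 - p) - koff * p
  dm <- al + da * p - be * m
  dP <- ga * m - mu * P
  nu <- sh$nu_mat
  dP[4] <- dP[4] - nu * P[4]
  dg <- nu * P[4] - mu[4] * gmat
  stats::setNames(c(dp, dm, dP, dg), MF_NAMES)
}

#' Deterministic induction trajectory
#'
#' Integrates the mean-field equations from the uninduced (leak-only) steady
#' state with galactose applied at time 0.
#'
#' @inheritParams mean_field_rhs
#' @param times output times in minutes.
#' @param init optional initial state (default: uninduced steady state).
#' @return A tibble with `time` and the 13 state columns.
#' @export
mean_field_trajectory <- function(params, gal, times, init = NULL) {
  if (is.null(init)) init <- mf_off_state(params)
  sol <- deSolve::ode(
    y = init, times = times,
    func = function(t, y, parms) list(mean_field_rhs(y, params, gal)),
    parms = NULL, method = "lsoda", rtol = 1e-10, atol = 1e-10
  )
  out <- tibble::as_tibble(as.data.frame(sol))
  names(out)[1] <- "time"
  out
}

# solve the 3-protein fixed-point system (P1, P3, P80); returns the full
# reconstructed state or NULL when the root search fails
solve_fixed_point <- function(params, gal, start) {
  sh <- params$shared
  g <- params$genes
  al <- vapply(g, `[[`, numeric(1), "alpha")
  da <- vapply(g, `[[`, numeric(1), "delta_alpha")
  be <- vapply(g, `[[`, numeric(1), "beta")
  ga <- vapply(g, `[[`, numeric(1), "gamma")
  mu <- vapply(g, `[[`, numeric(1), "mu")
  ns <- vapply(g, `[[`, integer(1), "n_sites")
  f <- if (gal > 0) (gal / sh$Kgal) / (1 + gal / sh$Kgal) else 0
  p_of <- function(P123) {
    drive <- (f * P123[1] / sh$K1)^2 + (f * P123[2] / sh$K3)^2
    rep80 <- (P123[3] / sh$K80)^2
    kon <- sh$k0_on * drive^ns
    koff <- sh$k0_off * rep80^ns
    ifelse(kon + koff > 0, kon / (kon + koff), 0)
  }
  # work in log space: protein levels are positive and span decades
  fun <- function(z) {
    P123 <- exp(z)
    p <- p_of(P123)
    tgt <- ga[1:3] * (al[1:3] + da[1:3] * p[1:3]) / (be[1:3] * mu[1:3])
    z - log(pmax(tgt, 1e-12))
  }
  root <- tryCatch(
    suppressWarnings(pracma::fsolve(fun, log(pmax(start, 1e-9)),
                                    maxiter = 200, tol = 1e-12)),
    error = function(e) NULL
  )
  if (is.null(root) || any(!is.finite(root$x)) ||
      sqrt(sum(fun(root$x)^2)) > 1e-6) {
    return(NULL)
  }
  P123 <- exp(root$x)
  p <- p_of(P123)
  m <- (al + da * p) / be
  P <- ga * m / mu
  P[1:3] <- P123
  nu <- sh$nu_mat
  P[4] <- ga[4] * m[4] / (mu[4] + nu)
  mean_field_state(p, m, P, gfp_mature = nu * P[4] / mu[4])
}

#' Stable steady states of the deterministic network
#'
#' Multi-start root finding on the reduced (Gal1p, Gal3p, Gal80p)
#' fixed-point system: OFF-like and ON-like deterministic starts plus
#' `n_restarts` log-uniform random restarts. Duplicate roots are merged at
#' relative tolerance 1e-6 and stability is decided from the eigenvalues of
#' the finite-difference Jacobian of the full 13-state system (all real
#' parts below -1e-9).
#'
#' @inheritParams mean_field_rhs
#' @param n_restarts random restarts on top of the two deterministic starts.
#' @param seed seed for the restart draws.
#' @return A tibble with one row per distinct fixed point: the reduced
#'   coordinates `P_gal1`, `P_gal3`, `P_gal80`, the reporter level, `stable`,
#'   and a `status` attribute `"ok"` or `"failed"` when no start converged.
#' @export
steady_states <- function(params, gal, n_restarts = 16, seed = 1) {
  g <- params$genes
  al <- vapply(g, `[[`, numeric(1), "alpha")
  da <- vapply(g, `[[`, numeric(1), "delta_alpha")
  be <- vapply(g, `[[`, numeric(1), "beta")
  ga <- vapply(g, `[[`, numeric(1), "gamma")
  mu <- vapply(g, `[[`, numeric(1), "mu")
  off <- (ga * al / (be * mu))[1:3]
  on <- (ga * (al + da) / (be * mu))[1:3]
  starts <- list(off, on)
  if (n_restarts > 0) {
    u <- local_runif(seed, n_restarts * 3)
    lo <- log(off / 3); hi <- log(on * 3)
    for (i in seq_len(n_restarts)) {
      w <- u[(3 * i - 2):(3 * i)]
      starts[[length(starts) + 1L]] <- exp(lo + w * (hi - lo))
    }
  }
  roots <- list()
  for (s in starts) {
    st <- solve_fixed_point(params, gal, s)
    if (is.null(st)) next
    key <- st[9:11]
    dup <- any(vapply(roots, function(r) {
      all(abs(r[9:11] - key) <= 1e-6 * pmax(abs(key), 1e-9))
    }, logical(1)))
    if (!dup) roots[[length(roots) + 1L]] <- st
  }
  if (!length(roots)) {
    out <- tibble::tibble(P_gal1 = numeric(), P_gal3 = numeric(),
                          P_gal80 = numeric(), gfp_mature = numeric(),
                          stable = logical())
    attr(out, "status") <- "failed"
    return(out)
  }
  stable <- vapply(roots, function(st) {
    J <- pracma::jacobian(function(y) mean_field_rhs(y, params, gal), st)
    all(Re(eigen(J, only.values = TRUE)$values) < -1e-9)
  }, logical(1))
  out <- tibble::tibble(
    P_gal1 = vapply(roots, `[[`, numeric(1), "P_gal1"),
    P_gal3 = vapply(roots, `[[`, numeric(1), "P_gal3"),
    P_gal80 = vapply(roots, `[[`, numeric(1), "P_gal80"),
    gfp_mature = vapply(roots, `[[`, numeric(1), "gfp_mature"),
    stable = stable
  )
  attr(out, "status") <- "ok"
  out
}

#' Bistability scan over the (rho_Gal3, Kgal) plane
#'
#' Runs [steady_states()] on every grid point and marks points with two or
#' more stable fixed points as bistable. Root-finding failures propagate as
#' `NA` ("unknown") cells.
#'
#' @param rho_values,kgal_values grid axes (log-spaced recommended, >= 2
#'   points each).
#' @inheritParams steady_states
#' @return A tibble with `rho`, `kgal`, `n_stable` and `bistable`.
#' @export
bistability_scan <- function(rho_values, kgal_values, params, gal,
                             n_restarts = 8, seed = 1) {
  if (length(rho_values) < 2 || length(kgal_values) < 2) {
    stop("grid axes need at least 2 points each", call. = FALSE)
  }
  grid <- tidyr::expand_grid(rho = rho_values, kgal = kgal_values)
  res <- purrr::pmap(grid, function(rho, kgal) {
    pr <- set_rho_kgal(params, rho_gal3 = rho, kgal = kgal)
    ss <- steady_states(pr, gal, n_restarts = n_restarts, seed = seed)
    if (identical(attr(ss, "status"), "failed")) return(NA_integer_)
    sum(ss$stable)
  })
  grid$n_stable <- as.integer(unlist(res))
  grid$bistable <- grid$n_stable >= 2L
  grid
}

#' Classify the induction response at one parameter point
#'
#' Simulates the stochastic inducibility time course and labels the response:
#' `"binary"` when the ON fraction lingers in the coexistence band
#' `[lo, hi]` for a contiguous window of at least `window` minutes,
#' `"gradual"` when it traverses the band in under `window` minutes,
#' `"no_response"` when it never reaches `lo`, and `"intermediate"`
#' otherwise.
#'
#' @inheritParams predicted_inducibility
#' @param n_cells cells per simulation (>= 200 recommended).
#' @param time_grid sampling grid (default 0 to 250 min, 10-min steps).
#' @param lo,hi,window classifier thresholds (fractions, minutes).
#' @return A single character label; the simulated series is attached as
#'   `attr(, "series")`.
#' @export
classify_response <- function(params, gal, n_cells = 500, seed = 1,
                              time_grid = seq(0, 250, by = 10),
                              lo = 0.1, hi = 0.9, window = 40, ...) {
  ind <- predicted_inducibility(params, gal = gal, time_grid = time_grid,
                                n_cells = n_cells, seed = seed, ...)
  label <- classify_series(ind$time, ind$fraction_on, lo = lo, hi = hi,
                           window = window)
  attr(label, "series") <- ind
  label
}

# label a fraction-vs-time curve; shared by classify_response and landscape
classify_series <- function(time, frac, lo = 0.1, hi = 0.9, window = 40) {
  if (max(frac) < lo) return("no_response")
  in_band <- frac >= lo & frac <= hi
  longest <- 0
  i <- 1
  n <- length(frac)
  while (i <= n) {
    if (in_band[i]) {
      j <- i
      while (j < n && in_band[j + 1]) j <- j + 1
      longest <- max(longest, time[j] - time[i])
      i <- j + 1
    } else i <- i + 1
  }
  if (longest >= window) return("binary")
  # crossing times by linear interpolation between grid points
  cross <- function(level) {
    i <- which(frac >= level)[1]
    if (is.na(i)) return(NA_real_)
    if (i == 1) return(time[1])
    time[i - 1] + (time[i] - time[i - 1]) *
      (level - frac[i - 1]) / (frac[i] - frac[i - 1])
  }
  t_hi <- cross(hi)
  if (!is.na(t_hi) && (t_hi - cross(lo)) < window) return("gradual")
  "intermediate"
}

#' Phenotypic landscape over the (rho_Gal3, Kgal) plane
#'
#' Labels every grid point by [classify_response()] and (optionally) overlays
#' the deterministic bistability mask.
#'
#' @inheritParams bistability_scan
#' @inheritParams classify_response
#' @param bistable run [bistability_scan()] on the same grid too.
#' @return A `gal_landscape` tibble with `rho`, `kgal`, `label` and, when
#'   requested, `bistable`. Has an [ggplot2::autoplot()] method.
#' @export
landscape <- function(rho_values, kgal_values, gal, params,
                      n_cells = 300, seed = 1, bistable = FALSE, ...) {
  grid <- tidyr::expand_grid(rho = rho_values, kgal = kgal_values)
  grid$label <- purrr::pmap_chr(grid[c("rho", "kgal")], function(rho, kgal) {
    pr <- set_rho_kgal(params, rho_gal3 = rho, kgal = kgal)
    classify_response(pr, gal = gal, n_cells = n_cells, seed = seed, ...)
  })
  if (bistable && length(rho_values) >= 2 && length(kgal_values) >= 2) {
    bs <- bistability_scan(rho_values, kgal_values, params, gal, seed = seed)
    grid <- dplyr::left_join(grid, bs[c("rho", "kgal", "bistable")],
                             by = c("rho", "kgal"))
  }
  attr(grid, "gal") <- gal
  class(grid) <- c("gal_landscape", class(grid))
  grid
}
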