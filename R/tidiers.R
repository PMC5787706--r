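#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a burned-in population
#'
#' @param x a `gal_population`.
#' @param ... unused.
#' @return One row per cell: promoter states, mRNA and protein counts,
#'   mature reporter and extrinsic factor.
#' @export
tidy.gal_population <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$state))
  dplyr::mutate(out, cell = dplyr::row_number(), .before = 1)
}

#' Tidy a simulated induction ensemble
#'
#' @param x a `gal_ensemble`.
#' @param ... unused.
#' @return Long tibble: `cell`, `time_min`, `signal`, `initial_inducers`.
#' @export
tidy.gal_ensemble <- function(x, ...) {
  n_c <- nrow(x$signal)
  tibble::tibble(
    cell = rep(seq_len(n_c), times = length(x$time)),
    time_min = rep(x$time, each = n_c),
    signal = as.vector(x$signal),
    initial_inducers = rep(x$initial_inducers, times = length(x$time))
  )
}

#' Tidy / glance a mixture fit
#'
#' @param x a `gal_mixfit`.
#' @param ... unused.
#' @return `tidy()`: one row per component (`component`, `weight`, `mean`,
#'   `sd`); `glance()`: one-row model summary.
#' @export
tidy.gal_mixfit <- function(x, ...) {
  if (x$n_components == 1L) {
    tibble::tibble(component = "ALL", weight = 1, mean = x$mu_all,
                   sd = x$sigma_all)
  } else {
    tibble::tibble(component = c("OFF", "ON"),
                   weight = c(x$rho_off, x$rho_on),
                   mean = c(x$mu_off, x$mu_on),
                   sd = c(x$sigma_off, x$sigma_on))
  }
}

#' @rdname tidy.gal_mixfit
#' @export
glance.gal_mixfit <- function(x, ...) {
  tibble::tibble(n_components = x$n_components, loglik = x$loglik,
                 bic_1 = x$bic_1, bic_2 = x$bic_2, converged = x$converged,
                 n = x$n, amplitude = response_amplitude(x))
}

#' Tidy / glance a grid chi-squared fit
#'
#' @param x a `gal_fit`.
#' @param ... unused.
#' @return `tidy()`: the chi-squared surface (`rho`, `kgal`, `chi2`);
#'   `glance()`: the point estimates with log-grid uncertainties.
#' @export
tidy.gal_fit <- function(x, ...) x$surface

#' @rdname tidy.gal_fit
#' @export
glance.gal_fit <- function(x, ...) {
  tibble::tibble(strain = x$strain, rho_hat = x$rho_hat,
                 kgal_hat = x$kgal_hat, rho_err_log10 = x$rho_err,
                 kgal_err_log10 = x$kgal_err, chi2_min = x$chi2_min,
                 unidentifiable = x$unidentifiable, n_cells = x$n_cells,
                 seed = x$seed)
}
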