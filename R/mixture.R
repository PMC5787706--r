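#' Fit a one- or two-component Gaussian mixture to fluorescence values
#'
#' Bimodal reporter distributions are treated as mixtures of two normal
#' components, `rho_off * N(mu_off, sigma_off) + rho_on * N(mu_on, sigma_on)`;
#' unimodal ones as a single `N(mu_all, sigma_all)`. Both models are fitted
#' (the two-component one by EM from several deterministic quantile/k-means
#' seedings) and the bimodal fit is retained only when it clearly wins:
#' a BIC improvement above `delta_bic`, both weights above `min_weight`, and
#' component means separated by more than twice the larger sigma. This is a
#' reproducible surrogate for calling modality by eye.
#'
#' @param values numeric vector of (baseline-corrected) FL1 values, length
#'   >= 50.
#' @param delta_bic,min_weight acceptance guards for the 2-component model.
#' @param tol,max_iter EM convergence controls (absolute log-likelihood
#'   change and iteration cap).
#' @return An object of class `gal_mixfit`; see [generics::tidy()] and
#'   [response_amplitude()].
#' @export
fit_fl1_mixture <- function(values, delta_bic = 10, min_weight = 0.05,
                            tol = 1e-8, max_iter = 500) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 50) stop("need at least 50 values to fit a mixture", call. = FALSE)
  rng <- diff(range(values))
  floor_sd <- max(1e-3 * rng, 1e-6)

  mu_all <- mean(values)
  sd_all <- max(stats::sd(values), floor_sd)
  ll1 <- sum(stats::dnorm(values, mu_all, sd_all, log = TRUE))
  bic1 <- -2 * ll1 + 2 * log(n)

  out <- list(n_components = 1L, rho_off = NA_real_, rho_on = NA_real_,
              mu_off = NA_real_, mu_on = NA_real_, sigma_off = NA_real_,
              sigma_on = NA_real_, mu_all = mu_all, sigma_all = sd_all,
              loglik = ll1, converged = TRUE, n = n,
              bic_1 = bic1, bic_2 = NA_real_)
  class(out) <- "gal_mixfit"
  if (rng <= floor_sd) return(out)  # degenerate: essentially constant input

  starts <- list(
    stats::quantile(values, c(0.10, 0.90), names = FALSE),
    stats::quantile(values, c(0.25, 0.75), names = FALSE),
    stats::quantile(values, c(0.05, 0.50), names = FALSE),
    stats::quantile(values, c(0.50, 0.95), names = FALSE),
    {
      km <- try(stats::kmeans(values, centers = stats::quantile(
        values, c(0.2, 0.8), names = FALSE)), silent = TRUE)
      if (inherits(km, "try-error")) stats::quantile(values, c(0.3, 0.7),
                                                     names = FALSE)
      else sort(as.vector(km$centers))
    }
  )

  best <- NULL
  for (cen in starts) {
    if (diff(cen) < floor_sd) next
    fit <- em_two_gauss(values, mu = sort(cen), sd0 = sd_all / 2,
                        floor_sd = floor_sd, tol = tol, max_iter = max_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) return(out)
  bic2 <- -2 * best$loglik + 5 * log(n)
  out$bic_2 <- bic2

  sep <- best$mu[2] - best$mu[1]
  accept <- (bic1 - bic2) > delta_bic &&
    all(best$w > min_weight) && sep > 2 * max(best$sd)
  if (!accept) return(out)

  out$n_components <- 2L
  out$rho_off <- best$w[1]; out$rho_on <- best$w[2]
  out$mu_off <- best$mu[1]; out$mu_on <- best$mu[2]
  out$sigma_off <- best$sd[1]; out$sigma_on <- best$sd[2]
  out$loglik <- best$loglik
  out$converged <- best$converged
  out
}

# plain EM for a 2-component univariate Gaussian mixture
em_two_gauss <- function(x, mu, sd0, floor_sd, tol, max_iter) {
  w <- c(0.5, 0.5)
  sd <- c(sd0, sd0)
  sd <- pmax(sd, floor_sd)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sd[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sd[2])
    tot <- d1 + d2
    tot[tot <= 0 | !is.finite(tot)] <- .Machine$double.xmin
    r2 <- d2 / tot
    r1 <- 1 - r2
    n1 <- sum(r1); n2 <- sum(r2)
    if (n1 < 1e-8 || n2 < 1e-8) break
    mu <- c(sum(r1 * x) / n1, sum(r2 * x) / n2)
    sd <- sqrt(c(sum(r1 * (x - mu[1])^2) / n1, sum(r2 * (x - mu[2])^2) / n2))
    sd <- pmax(sd, floor_sd)
    w <- c(n1, n2) / length(x)
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  d1 <- w[1] * stats::dnorm(x, mu[1], sd[1])
  d2 <- w[2] * stats::dnorm(x, mu[2], sd[2])
  ll <- sum(log(pmax(d1 + d2, .Machine$double.xmin)))
  o <- order(mu)  # convention: component 1 = OFF (lower mean)
  list(w = w[o], mu = mu[o], sd = sd[o], loglik = ll, converged = converged)
}

#' @export
print.gal_mixfit <- function(x, ...) {
  if (x$n_components == 1L) {
    cat("<gal_mixfit> unimodal: mu =", signif(x$mu_all, 4),
        " sigma =", signif(x$sigma_all, 4), "\n")
  } else {
    cat("<gal_mixfit> bimodal: OFF", signif(x$rho_off, 3), "~N(",
        signif(x$mu_off, 4), ",", signif(x$sigma_off, 4), ")  ON",
        signif(x$rho_on, 3), "~N(", signif(x$mu_on, 4), ",",
        signif(x$sigma_on, 4), ")\n")
  }
  invisible(x)
}

#' Response amplitude of a fitted distribution
#'
#' The amplitude is the mean expression of activated cells: the overall mean
#' for a unimodal fit, the upper-component mean for a bimodal one (weight
#' free by construction).
#'
#' @param fit a `gal_mixfit` from [fit_fl1_mixture()].
#' @return The amplitude in the units of the fitted values.
#' @export
response_amplitude <- function(fit) {
  stopifnot(inherits(fit, "gal_mixfit"))
  if (fit$n_components == 1L) fit$mu_all else fit$mu_on
}

#' Equal-misclassification ON/OFF threshold
#'
#' Given Gaussian references for OFF and ON cells, returns the threshold `t`
#' at which an ON cell is as likely to fall below `t` as an OFF cell is to
#' fall above it, `P(X_ON < t) = P(X_OFF > t)`. For normal components this
#' has the closed form `(mu_on*sigma_off + mu_off*sigma_on) /
#' (sigma_off + sigma_on)`.
#'
#' @param mu_off,sigma_off OFF reference mean and sd.
#' @param mu_on,sigma_on ON reference mean and sd (requires
#'   `mu_on > mu_off`).
#' @return The threshold, in the units of the references.
#' @export
on_off_threshold <- function(mu_off, sigma_off, mu_on, sigma_on) {
  if (!all(is.finite(c(mu_off, sigma_off, mu_on, sigma_on)))) {
    stop("all arguments must be finite", call. = FALSE)
  }
  if (sigma_off <= 0 || sigma_on <= 0) {
    stop("standard deviations must be > 0", call. = FALSE)
  }
  if (mu_on <= mu_off) stop("'mu_on' must exceed 'mu_off'", call. = FALSE)
  (mu_on * sigma_off + mu_off * sigma_on) / (sigma_off + sigma_on)
}

#' Inducibility of a sample
#'
#' The fraction of cells strictly above the ON/OFF threshold, with its
#' binomial standard error.
#'
#' @param values FL1 values (nonempty numeric).
#' @param t threshold separating OFF from ON cells.
#' @return A one-row tibble with `fraction_on`, `sem` and `n_cells`.
#' @export
inducibility <- function(values, t) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0L) stop("'values' must be nonempty", call. = FALSE)
  frac <- mean(values > t)
  tibble::tibble(fraction_on = frac, sem = sqrt(frac * (1 - frac) / n),
                 n_cells = n)
}
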