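#' Number of galactose-activated proteins
#'
#' Gal1p and Gal3p are activated by galactose binding; the activated pool
#' follows a saturating first-order law
#' `protein * (gal/kgal) / (1 + gal/kgal)`, so `kgal` is the concentration at
#' which half the pool is activated.
#'
#' @param protein total protein count (>= 0; real-valued allowed).
#' @param gal galactose concentration (% w/v, >= 0).
#' @param kgal half-activation constant (% w/v, > 0).
#' @return The activated count, a real value in `[0, protein]`.
#' @examples
#' activated_count(100, gal = 0.055, kgal = 0.055)  # half-saturation: 50
#' @export
activated_count <- function(protein, gal, kgal) {
  if (!all(is.finite(protein)) || any(protein < 0)) {
    stop("'protein' must be finite and >= 0", call. = FALSE)
  }
  if (!all(is.finite(gal)) || any(gal < 0)) {
    stop("'gal' must be finite and >= 0", call. = FALSE)
  }
  if (!all(is.finite(kgal)) || any(kgal <= 0)) {
    stop("'kgal' must be finite and > 0", call. = FALSE)
  }
  x <- gal / kgal
  protein * x / (1 + x)
}

#' Promoter switching rates
#'
#' The OFF-to-ON rate is driven by activated Gal1p and Gal3p dimers,
#' `k_on = k0_on * ((Gal1p*/K1)^2 + (Gal3p*/K3)^2)^n`, and the ON-to-OFF rate
#' by Gal80p dimers, `k_off = k0_off * (Gal80p/K80)^(2n)`, with `n` the
#' number of strong activator binding sites in the promoter.
#'
#' @param gal80p total Gal80p count (>= 0).
#' @param gal1_star,gal3_star activated Gal1p and Gal3p counts (>= 0), e.g.
#'   from [activated_count()].
#' @param gene a [gene_kinetics()] record (supplies `n_sites`).
#' @param shared a [shared_constants()] object.
#' @return A named numeric vector `c(k_on =, k_off =)` in 1/min.
#' @export
promoter_rates <- function(gal80p, gal1_star, gal3_star, gene, shared) {
  stopifnot(inherits(gene, "gene_kinetics"), inherits(shared, "shared_constants"))
  counts <- c(gal80p, gal1_star, gal3_star)
  if (!all(is.finite(counts)) || any(counts < 0)) {
    stop("protein counts must be finite and >= 0", call. = FALSE)
  }
  n <- gene$n_sites
  drive <- (gal1_star / shared$K1)^2 + (gal3_star / shared$K3)^2
  c(k_on = shared$k0_on * drive^n,
    k_off = shared$k0_off * (gal80p / shared$K80)^(2 * n))
}

#' Gene strength
#'
#' The strength of a gene is the dimensionless ratio of its basal (leaky)
#' mean protein level to the effective constant of its activated form:
#' `rho = alpha * gamma / (beta * mu * K)`. For GAL3 this is the
#' meta-parameter that, together with `Kgal`, determines whether induction is
#' gradual or binary.
#'
#' @param gene a [gene_kinetics()] record with strictly positive rates.
#' @param K the effective constant for the gene's (activated) dimers.
#' @return The dimensionless strength.
#' @export
gene_strength <- function(gene, K) {
  stopifnot(inherits(gene, "gene_kinetics"))
  if (!is.finite(K) || K <= 0) stop("'K' must be finite and > 0", call. = FALSE)
  if (gene$alpha <= 0 || gene$gamma <= 0 || gene$beta <= 0 || gene$mu <= 0) {
    stop("gene strength requires strictly positive alpha, gamma, beta, mu",
         call. = FALSE)
  }
  gene$alpha * gene$gamma / (gene$beta * gene$mu * K)
}
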