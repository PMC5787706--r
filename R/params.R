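#' Kinetic parameters for one gene of the galactose network
#'
#' Bundles the telegraph-model kinetics of a single GAL gene: leaky
#' transcription `alpha` (mRNA/min, promoter OFF), the additional
#' transcription `delta_alpha` gained when the promoter is ON (so the ON-state
#' rate is `alpha + delta_alpha`), mRNA degradation `beta` (1/min),
#' translation `gamma` (protein per mRNA per min), protein
#' degradation/dilution `mu` (1/min) and the number of strong Gal4p binding
#' sites `n_sites` in the promoter.
#'
#' @param name one of `"GAL1"`, `"GAL3"`, `"GAL80"`, `"REPORTER"`.
#' @param alpha,delta_alpha,beta,gamma,mu non-negative rates (see above);
#'   `beta` and `mu` must be strictly positive.
#' @param n_sites positive integer count of strong activator binding sites.
#' @return An object of class `gene_kinetics` (a named list).
#' @export
gene_kinetics <- function(name, alpha, delta_alpha, beta, gamma, mu,
                          n_sites = 1L) {
  name <- match.arg(name, c("GAL1", "GAL3", "GAL80", "REPORTER"))
  rates <- c(alpha = alpha, delta_alpha = delta_alpha, beta = beta,
             gamma = gamma, mu = mu)
  if (!all(is.finite(rates)) || any(rates < 0)) {
    stop("all kinetic rates must be finite and non-negative", call. = FALSE)
  }
  if (beta <= 0 || mu <= 0) {
    stop("'beta' and 'mu' must be strictly positive", call. = FALSE)
  }
  n_sites <- as.integer(n_sites)
  if (is.na(n_sites) || n_sites < 1L) {
    stop("'n_sites' must be a positive integer", call. = FALSE)
  }
  structure(list(name = name, alpha = alpha, delta_alpha = delta_alpha,
                 beta = beta, gamma = gamma, mu = mu, n_sites = n_sites),
            class = "gene_kinetics")
}

#' Shared constants of the galactose network model
#'
#' @param k0_on,k0_off basal promoter OFF-to-ON and ON-to-OFF switching rates
#'   (1/min). The actual switching propensities scale these by the activator
#'   and repressor drives, see [promoter_rates()].
#' @param K1,K3,K80 effective constants (molecules) for activated Gal1p
#'   dimers, activated Gal3p dimers and Gal80p dimers; they fold dimer
#'   dissociation into a single scale per species.
#' @param Kgal galactose concentration (% w/v) at which half of the Gal1p and
#'   Gal3p pool is in the activated form.
#' @param nu_mat reporter fluorophore maturation rate (1/min).
#' @return An object of class `shared_constants`.
#' @export
shared_constants <- function(k0_on, k0_off, K1, K3, K80, Kgal, nu_mat) {
  v <- c(k0_on = k0_on, k0_off = k0_off, K1 = K1, K3 = K3, K80 = K80,
         Kgal = Kgal, nu_mat = nu_mat)
  if (!all(is.finite(v)) || any(v <= 0)) {
    stop("all shared constants must be finite and strictly positive",
         call. = FALSE)
  }
  structure(as.list(v), class = "shared_constants")
}

#' Full parameterization of the four-gene network
#'
#' @param genes a list of exactly four [gene_kinetics()] records with unique
#'   names covering GAL1, GAL3, GAL80 and REPORTER.
#' @param shared a [shared_constants()] object.
#' @return An object of class `gal_params`.
#' @export
gal_params <- function(genes, shared) {
  if (!inherits(shared, "shared_constants")) {
    stop("'shared' must be a shared_constants object", call. = FALSE)
  }
  if (length(genes) != 4L ||
      !all(vapply(genes, inherits, logical(1), "gene_kinetics"))) {
    stop("'genes' must be a list of four gene_kinetics records", call. = FALSE)
  }
  nm <- vapply(genes, `[[`, character(1), "name")
  if (!setequal(nm, c("GAL1", "GAL3", "GAL80", "REPORTER"))) {
    stop("genes must be GAL1, GAL3, GAL80 and REPORTER, each exactly once",
         call. = FALSE)
  }
  names(genes) <- nm
  genes <- genes[c("GAL1", "GAL3", "GAL80", "REPORTER")]
  structure(list(genes = genes, shared = shared), class = "gal_params")
}

#' @export
print.gal_params <- function(x, ...) {
  cat("<gal_params>  rho_Gal3 =", signif(rho_gal3(x), 4),
      " Kgal =", x$shared$Kgal, "\n")
  df <- do.call(rbind, lapply(x$genes, function(g) {
    data.frame(gene = g$name, alpha = g$alpha, delta_alpha = g$delta_alpha,
               beta = g$beta, gamma = g$gamma, mu = g$mu, n_sites = g$n_sites)
  }))
  print(df, row.names = FALSE)
  cat("shared:", paste(names(x$shared), unlist(x$shared), sep = "=",
                       collapse = "  "), "\n")
  invisible(x)
}

#' Default network parameterization
#'
#' Returns the package's calibrated default parameter set. GAL3-independent
#' kinetics use basal (leaky) protein means of order 30-100 molecules, mRNA
#' lifetimes of 20 min (`beta` = 0.05/min) and protein dilution of
#' 0.006/min (roughly a 2 h doubling time). The GAL3 translation rate is set
#' from the requested gene strength `rho_gal3` (see [gene_strength()]), and
#' `kgal` sets the galactose half-activation constant, so
#' `default_params(140, 0.055)` and `default_params(40, 0.055)` reproduce the
#' gradual and binary induction regimes at 0.5% galactose.
#'
#' @param rho_gal3 GAL3 strength, `alpha3*gamma3/(beta3*mu3*K3)`.
#' @param kgal galactose half-activation constant (% w/v).
#' @param extra named list of overrides applied on top of the defaults;
#'   entries are `genes$GAL1$alpha`-style paths given as e.g.
#'   `list(GAL1 = list(alpha = 0.02), shared = list(k0_on = 1e-5))`.
#' @return A [gal_params()] object.
#' @export
default_params <- function(rho_gal3 = 140, kgal = 0.055, extra = NULL) {
  base <- list(
    GAL1     = list(alpha = 0.010, delta_alpha = 0.20, beta = 0.05,
                    gamma = 1.0, mu = 0.006, n_sites = 1L),
    GAL3     = list(alpha = 0.015, delta_alpha = 0.60, beta = 0.05,
                    gamma = 1, mu = 0.006, n_sites = 1L),  # gamma set from rho below
    GAL80    = list(alpha = 0.060, delta_alpha = 0.06, beta = 0.05,
                    gamma = 0.5, mu = 0.006, n_sites = 1L),
    REPORTER = list(alpha = 0.040, delta_alpha = 4.00, beta = 0.10,
                    gamma = 1.0, mu = 0.006, n_sites = 1L),
    shared   = list(k0_on = 3e-5, k0_off = 0.005, K1 = 10, K3 = 1, K80 = 25,
                    Kgal = kgal, nu_mat = 0.15)
  )
  if (!is.null(extra)) {
    for (blk in names(extra)) {
      for (fld in names(extra[[blk]])) base[[blk]][[fld]] <- extra[[blk]][[fld]]
    }
  }
  genes <- lapply(c("GAL1", "GAL3", "GAL80", "REPORTER"), function(nm) {
    g <- base[[nm]]
    do.call(gene_kinetics, c(list(name = nm), g))
  })
  sh <- do.call(shared_constants, base$shared)
  p <- gal_params(genes, sh)
  set_rho_kgal(p, rho_gal3 = rho_gal3, kgal = kgal)
}

#' Re-target a parameter set to a given (rho_Gal3, Kgal)
#'
#' Realizes a requested GAL3 strength either by rescaling the effective
#' constant `K3` at fixed expression (the default: the basal Gal3p pool and
#' its relative cell-to-cell fluctuations are unchanged, and molecule counts
#' stay bounded across a fitting grid) or by rescaling the translation rate
#' `gamma3` at fixed `K3` (expression-level realization). The two are
#' dynamically equivalent: the promoter drive depends on Gal3p only through
#' `rho_Gal3` times the unit-mean expression fluctuation, so mean-field
#' trajectories are identical and the stochastic switching statistics agree
#' (see the identifiability discussion in the methods vignette). `Kgal` is
#' set directly.
#'
#' @param params a [gal_params()] object.
#' @param rho_gal3,kgal targets; `NULL` leaves the current value untouched.
#' @param realize `"K3"` (default) or `"gamma"`, see above.
#' @return The modified `gal_params` object.
#' @export
set_rho_kgal <- function(params, rho_gal3 = NULL, kgal = NULL,
                         realize = c("K3", "gamma")) {
  stopifnot(inherits(params, "gal_params"))
  realize <- match.arg(realize)
  if (!is.null(kgal)) {
    if (!is.finite(kgal) || kgal <= 0) stop("'kgal' must be > 0", call. = FALSE)
    params$shared$Kgal <- kgal
  }
  if (!is.null(rho_gal3)) {
    if (!is.finite(rho_gal3) || rho_gal3 <= 0) {
      stop("'rho_gal3' must be > 0", call. = FALSE)
    }
    g <- params$genes$GAL3
    if (realize == "K3") {
      basal <- g$alpha * g$gamma / (g$beta * g$mu)
      params$shared$K3 <- basal / rho_gal3
    } else {
      params$genes$GAL3$gamma <-
        rho_gal3 * g$beta * g$mu * params$shared$K3 / g$alpha
    }
  }
  params
}

#' Set the strengths of GAL1 and GAL80
#'
#' Rescales the GAL1 / GAL80 translation rates so that their gene strengths
#' (basal protein level over the corresponding effective constant, see
#' [gene_strength()]) hit the requested values. Used e.g. to reproduce
#' deterministic bistability scans at prescribed (rho_Gal1, rho_Gal80).
#'
#' @param params a [gal_params()] object.
#' @param rho_gal1,rho_gal80 target strengths; `NULL` leaves a gene as is.
#' @param preserve_basal_switching when re-targeting the GAL80 strength,
#'   rescale `k0_off` by `(rho_old/rho_new)^(2*n)` so the uninduced ON-to-OFF
#'   switching propensity is unchanged. The basal rate and the strength are
#'   not separately identified — only their product enters the switching
#'   laws — so this keeps a re-targeted backbone dynamically calibrated
#'   (default `TRUE`).
#' @return The modified `gal_params` object.
#' @export
set_strengths <- function(params, rho_gal1 = NULL, rho_gal80 = NULL,
                          preserve_basal_switching = TRUE) {
  stopifnot(inherits(params, "gal_params"))
  if (!is.null(rho_gal1)) {
    g <- params$genes$GAL1
    params$genes$GAL1$gamma <-
      rho_gal1 * g$beta * g$mu * params$shared$K1 / g$alpha
  }
  if (!is.null(rho_gal80)) {
    g <- params$genes$GAL80
    rho_old <- gene_strength(g, params$shared$K80)
    params$genes$GAL80$gamma <-
      rho_gal80 * g$beta * g$mu * params$shared$K80 / g$alpha
    if (preserve_basal_switching) {
      params$shared$k0_off <-
        params$shared$k0_off * (rho_old / rho_gal80)^(2 * g$n_sites)
    }
  }
  params
}

#' GAL3 strength of a parameter set
#'
#' `rho_gal3(params)` evaluates [gene_strength()] for the GAL3 gene with the
#' effective constant `K3`; analogous helpers exist through
#' `gene_strength(params$genes$GAL1, params$shared$K1)` etc.
#'
#' @param params a [gal_params()] object.
#' @return The dimensionless strength `alpha3*gamma3/(beta3*mu3*K3)`.
#' @export
rho_gal3 <- function(params) {
  stopifnot(inherits(params, "gal_params"))
  gene_strength(params$genes$GAL3, params$shared$K3)
}

#' Summaries of an allele's inferred parameters
#'
#' @param rho,kgal inferred GAL3 strength and galactose constant.
#' @param rho_rel,kgal_rel the same values relative to a reference allele.
#' @param strain optional strain label.
#' @return A one-row tibble of class `allele_summary`.
#' @export
allele_summary <- function(rho, kgal, rho_rel = NA_real_, kgal_rel = NA_real_,
                           strain = NA_character_) {
  if (!is.finite(rho) || rho <= 0 || !is.finite(kgal) || kgal <= 0) {
    stop("'rho' and 'kgal' must be finite and > 0", call. = FALSE)
  }
  out <- tibble::tibble(strain = strain, rho = rho, kgal = kgal,
                        rho_rel = rho_rel, kgal_rel = kgal_rel)
  class(out) <- c("allele_summary", class(out))
  out
}

#' Alternative GAL3-independent parameter sets
#'
#' Returns `n` parameter sets that differ in GAL3-independent kinetics
#' (GAL1/GAL80/reporter expression levels, basal switching rates) while
#' keeping the GAL3 block at the requested strength. They are used to repeat
#' the inference under different fixed backgrounds and report the dispersion
#' of the allele coordinates across backgrounds.
#'
#' @param n number of sets (default 6).
#' @param rho_gal3,kgal passed to [default_params()].
#' @return A named list of [gal_params()] objects (`set1` ... `setn`).
#' @export
alt_param_sets <- function(n = 6, rho_gal3 = 140, kgal = 0.055) {
  tweaks <- list(
    list(),                                              # the default itself
    list(GAL1  = list(alpha = 0.014, gamma = 0.8)),      # stronger GAL1 leak
    list(GAL80 = list(gamma = 1.9)),                     # more repressor
    list(GAL80 = list(gamma = 1.2)),                     # less repressor
    list(shared = list(k0_off = 0.013)),                 # stickier OFF state
    list(REPORTER = list(delta_alpha = 0.42, gamma = 2.4)),
    list(GAL1 = list(delta_alpha = 0.26)),
    list(shared = list(K80 = 28))
  )
  n <- as.integer(n)
  if (n < 1L || n > length(tweaks)) {
    stop("'n' must be between 1 and ", length(tweaks), call. = FALSE)
  }
  sets <- lapply(tweaks[seq_len(n)], function(tw) {
    default_params(rho_gal3 = rho_gal3, kgal = kgal, extra = tw)
  })
  names(sets) <- paste0("set", seq_len(n))
  sets
}

#' Read / write parameter files
#'
#' Parameter files are YAML with one block per gene (`alpha`, `delta_alpha`,
#' `beta`, `gamma`, `mu`, `n_sites`) and one `shared` block (`k0_on`,
#' `k0_off`, `K1`, `K3`, `K80`, `Kgal`, `nu_mat`). The loader validates
#' completeness and positivity through the type constructors.
#'
#' @param path file path.
#' @param params a [gal_params()] object.
#' @return `read_params()` returns a `gal_params` object; `write_params()`
#'   returns `path` invisibly.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  need <- c("GAL1", "GAL3", "GAL80", "REPORTER", "shared")
  miss <- setdiff(need, names(y))
  if (length(miss)) {
    stop("parameter file is missing block(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  genes <- lapply(need[1:4], function(nm) {
    do.call(gene_kinetics, c(list(name = nm), y[[nm]]))
  })
  gal_params(genes, do.call(shared_constants, y$shared))
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "gal_params"))
  y <- lapply(params$genes, function(g) g[setdiff(names(g), "name")])
  y$shared <- unclass(params$shared)
  yaml::write_yaml(y, path, precision = 15L)
  invisible(path)
}
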