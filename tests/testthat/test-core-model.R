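test_that("activated_count follows the saturating activation law", {
  # half-saturation and zero-galactose anchors
  expect_equal(activated_count(100, gal = 0.055, kgal = 0.055), 50)
  expect_equal(activated_count(123, gal = 0, kgal = 0.1), 0)
  # direct evaluation at the gradual-regime constant
  x <- 0.5 / 0.055
  expect_equal(activated_count(100, gal = 0.5, kgal = 0.055),
               100 * x / (1 + x), tolerance = 1e-12)
  expect_error(activated_count(-1, 0.5, 0.055), "protein")
  expect_error(activated_count(10, -0.5, 0.055), "gal")
  expect_error(activated_count(10, 0.5, 0), "kgal")
  expect_error(activated_count(Inf, 0.5, 0.055))
})

test_that("activated_count is monotone, bounded by the pool and saturates", {
  gal <- sort(stats::runif(50, 0, 2))
  a <- activated_count(200, gal, 0.055)
  expect_true(all(diff(a) >= 0))
  expect_true(all(a <= 200))
  # the activated pool approaches the total pool at saturating galactose:
  # the exact gap at gal = 1e6 * kgal is protein / (1 + 1e6)
  a <- activated_count(200, 1e6 * 0.055, 0.055)
  expect_equal(a, 200 * 1e6 / (1 + 1e6), tolerance = 1e-12)
  expect_lt(200 - a, 200 * 1.01e-6)
})

test_that("promoter switching rates follow the dimer drive laws", {
  p <- default_params()
  sh <- p$shared
  g1 <- p$genes$GAL3  # n_sites = 1
  r <- promoter_rates(gal80p = sh$K80, gal1_star = 0, gal3_star = 0,
                      gene = g1, shared = sh)
  expect_equal(unname(r["k_off"]), sh$k0_off)  # ratio 1 to any power
  expect_equal(unname(r["k_on"]), 0)           # no activated inducers
  g2 <- gene_kinetics("GAL1", 0.01, 0.2, 0.05, 1, 0.006, n_sites = 2L)
  r2 <- promoter_rates(gal80p = 0, gal1_star = sh$K1, gal3_star = sh$K3,
                       gene = g2, shared = sh)
  expect_equal(unname(r2["k_on"]), 4 * sh$k0_on)  # (1 + 1)^2
  expect_error(promoter_rates(-1, 0, 0, g1, sh), "counts")
})

test_that("log k_off is linear in n_sites with slope 2 log(Gal80p/K80)", {
  sh <- default_params()$shared
  gal80p <- 70
  koff <- vapply(1:4, function(n) {
    g <- gene_kinetics("GAL1", 0.01, 0.2, 0.05, 1, 0.006, n_sites = n)
    promoter_rates(gal80p, 0, 0, g, sh)[["k_off"]]
  }, numeric(1))
  slopes <- diff(log(koff))
  expect_equal(slopes, rep(2 * log(gal80p / sh$K80), 3), tolerance = 1e-12)
})

test_that("gene strength is alpha*gamma/(beta*mu*K) and scale invariant", {
  unit <- gene_kinetics("GAL3", 1, 0, 1, 1, 1)
  expect_equal(gene_strength(unit, K = 1), 1)
  g <- gene_kinetics("GAL3", alpha = 0.2, delta_alpha = 0, beta = 0.5,
                     gamma = 10, mu = 0.01, n_sites = 1)
  K <- 0.7
  # product of independently computed factors vs the closed form
  factors <- (0.2 / 0.5) * (10 / 0.01) * (1 / K)
  expect_equal(gene_strength(g, K), factors, tolerance = 1e-12)
  g2 <- gene_kinetics("GAL3", alpha = 2 * 0.2, delta_alpha = 0, beta = 0.5,
                      gamma = 10, mu = 0.01, n_sites = 1)
  expect_equal(gene_strength(g2, 2 * K), gene_strength(g, K),
               tolerance = 1e-12)
  expect_error(gene_strength(gene_kinetics("GAL3", 0, 0, 1, 1, 1), 1),
               "positive")
})

test_that("the parameter container exposes exactly the seven GAL3-dependent knobs", {
  p <- default_params()
  g3 <- p$genes$GAL3
  # the seven: alpha3, delta_alpha3, beta3, gamma3, mu3, K3, Kgal
  expect_named(g3[c("alpha", "delta_alpha", "beta", "gamma", "mu")],
               c("alpha", "delta_alpha", "beta", "gamma", "mu"))
  expect_true(all(c("K3", "Kgal") %in% names(p$shared)))
  # re-targeting (rho, kgal) touches only the chosen realization knob + Kgal
  p2 <- set_rho_kgal(p, rho_gal3 = 77, kgal = 0.2)  # default: K3 realization
  expect_equal(rho_gal3(p2), 77, tolerance = 1e-12)
  expect_equal(p2$shared$Kgal, 0.2)
  same <- setdiff(names(p$shared), c("Kgal", "K3"))
  expect_identical(p2$shared[same], p$shared[same])
  for (nm in c("GAL1", "GAL80", "REPORTER")) {
    expect_identical(p2$genes[[nm]], p$genes[[nm]])
  }
  expect_identical(p2$genes$GAL3, p$genes$GAL3)
  # gamma realization reaches the same strength through expression level
  p3 <- set_rho_kgal(p, rho_gal3 = 77, kgal = 0.2, realize = "gamma")
  expect_equal(rho_gal3(p3), 77, tolerance = 1e-12)
  expect_identical(p3$shared$K3, p$shared$K3)
  expect_identical(p3$genes$GAL3[c("alpha", "delta_alpha", "beta", "mu")],
                   p$genes$GAL3[c("alpha", "delta_alpha", "beta", "mu")])
})

test_that("parameter validation rejects malformed networks", {
  sh <- default_params()$shared
  g <- default_params()$genes
  expect_error(gal_params(g[1:3], sh), "four")
  g_dup <- g
  g_dup$GAL80 <- g_dup$GAL1
  expect_error(gal_params(unname(g_dup), sh), "exactly once")
  expect_error(gene_kinetics("GAL1", -0.1, 0, 1, 1, 1), "non-negative")
  expect_error(gene_kinetics("GAL1", 0.1, 0, 1, 1, 1, n_sites = 0), "n_sites")
  expect_error(shared_constants(0, 1, 1, 1, 1, 1, 1), "positive")
})

test_that("parameter YAML round trip preserves values and validates files", {
  p <- default_params(rho_gal3 = 85, kgal = 0.11)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_params(p, path)
  q <- read_params(path)
  expect_equal(q, p, tolerance = 1e-10)
  # a file missing a block fails with a named error
  y <- yaml::read_yaml(path)
  y$GAL80 <- NULL
  yaml::write_yaml(y, path)
  expect_error(read_params(path), "GAL80")
  expect_error(read_params("no/such/file.yaml"), "not found")
})

test_that("alternative backbones differ only in GAL3-independent kinetics", {
  sets <- alt_param_sets(6, rho_gal3 = 140, kgal = 0.055)
  expect_length(sets, 6)
  rhos <- vapply(sets, rho_gal3, numeric(1))
  expect_equal(unname(rhos), rep(140, 6), tolerance = 1e-10)
  expect_equal(vapply(sets, function(p) p$shared$Kgal, numeric(1)),
               setNames(rep(0.055, 6), names(sets)))
  # the sets are genuinely different backbones
  keys <- vapply(sets, function(p) paste(
    vapply(p$genes, function(g) paste(unlist(g[-1]), collapse = ","),
           character(1)), paste(unlist(p$shared), collapse = ","),
    collapse = "|"), character(1))
  expect_equal(length(unique(keys)), 6)
})
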