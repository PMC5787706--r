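test_that("density gating removes saturated events and keeps 60% of the cloud", {
  withr::local_seed(1)
  ev <- toy_sample(10000, "s1")
  ev$fl1[1:100] <- 1023  # saturated detector
  gated <- gate_events(ev, min_cells = 3000)
  qc <- attr(gated, "qc")
  expect_equal(qc$n_saturated, 100)
  expect_false(any(gated$fl1 == 1023))
  # the highest-density region retains keep_fraction of unsaturated events
  expect_equal(qc$n_gated / (10000 - qc$n_saturated), 0.60, tolerance = 0.02)
})

test_that("samples below the cell-count floor are dropped with a reason", {
  withr::local_seed(2)
  ev <- dplyr::bind_rows(toy_sample(10000, "big"), toy_sample(4900, "small"))
  gated <- gate_events(ev, min_cells = 3000)
  qc <- attr(gated, "qc")
  expect_true(qc$kept[qc$sample_id == "big"])
  # 60% of 4900 = 2940 < 3000
  expect_false(qc$kept[qc$sample_id == "small"])
  expect_match(qc$reason[qc$sample_id == "small"], "fewer than 3000")
  expect_setequal(unique(gated$sample_id), "big")
  # a fully saturated sample is dropped with its own reason
  sat <- toy_sample(200, "sat")
  sat$fl1 <- 1023
  qc2 <- attr(gate_events(sat, min_cells = 100), "qc")
  expect_match(qc2$reason, "no unsaturated")
})

test_that("plate offsets estimated from controls are removed", {
  withr::local_seed(3)
  mk <- function(plate, offset, sid) {
    s <- toy_sample(2000, sid, fl1 = rnorm(2000, 100, 10), plate = plate,
                    time_min = 60)
    s$fl1 <- s$fl1 + offset
    s
  }
  events <- dplyr::bind_rows(
    mk(1, 0, "p1a"), mk(2, 10, "p2a"),
    dplyr::mutate(toy_sample(2000, "p1t0", fl1 = rnorm(2000, 100, 10)),
                  plate = 1),
    dplyr::mutate(toy_sample(2000, "p2t0", fl1 = rnorm(2000, 110, 10)),
                  plate = 2))
  controls <- dplyr::bind_rows(lapply(1:24, function(r) {
    dplyr::bind_rows(
      toy_sample(300, sprintf("c1_%02d", r), fl1 = rnorm(300, 50, 5),
                 plate = 1, strain = "control"),
      toy_sample(300, sprintf("c2_%02d", r), fl1 = rnorm(300, 60, 5),
                 plate = 2, strain = "control"))
  }))
  out <- normalize_samples(events, controls, baseline = FALSE)
  offs <- attr(out, "plate_offsets")
  expect_equal(diff(offs$offset), 10, tolerance = 0.5)
  m1 <- mean(out$fl1[out$sample_id == "p1a"])
  m2 <- mean(out$fl1[out$sample_id == "p2a"])
  expect_lt(abs(m2 - m1), 0.5)
  expect_lt(attr(out, "plate_anova_p"), 0.01)
  # refusing multi-plate correction without controls
  expect_error(normalize_samples(events, NULL, baseline = FALSE), "control")
  expect_error(normalize_samples(events, controls[controls$plate == 1, ],
                                 baseline = FALSE), "plate")
})

test_that("single-plate designs only get the t = 0 baseline subtraction", {
  withr::local_seed(4)
  ev <- dplyr::bind_rows(
    toy_sample(1000, "t0", fl1 = rnorm(1000, 100, 5), time_min = 0),
    toy_sample(1000, "t60", fl1 = rnorm(1000, 400, 5), time_min = 60))
  out <- normalize_samples(ev)
  expect_equal(attr(out, "plate_offsets")$offset, 0)
  expect_equal(mean(out$fl1[out$time_min == 0]), 0, tolerance = 1e-9)
  expect_equal(mean(out$fl1[out$time_min == 60]),
               mean(ev$fl1[ev$time_min == 60]) -
                 mean(ev$fl1[ev$time_min == 0]), tolerance = 1e-9)
  # a strain without any t = 0 sample cannot be baselined
  expect_error(normalize_samples(toy_sample(100, "x", time_min = 30)), "t = 0")
})

test_that("the Gaussian EM recovers unimodal and bimodal structure", {
  withr::local_seed(5)
  uni <- rnorm(5000, 5, 1)
  f1 <- fit_fl1_mixture(uni)
  expect_equal(f1$n_components, 1L)
  expect_equal(f1$mu_all, 5, tolerance = 0.05)
  n_off <- 2000; n_on <- 3000
  bim <- c(rnorm(n_off, 0, 1), rnorm(n_on, 8, 1.5))
  f2 <- fit_fl1_mixture(bim)
  expect_equal(f2$n_components, 2L)
  expect_equal(f2$rho_on, 0.6, tolerance = 3 * sqrt(0.24 / 5000))
  expect_equal(f2$mu_off, 0, tolerance = 3 / sqrt(n_off))
  expect_equal(f2$mu_on, 8, tolerance = 3 * 1.5 / sqrt(n_on))
  expect_true(f2$converged)
  # coincident components collapse to the parsimonious model
  same <- c(rnorm(2500, 3, 1), rnorm(2500, 3, 1))
  expect_equal(fit_fl1_mixture(same)$n_components, 1L)
  expect_error(fit_fl1_mixture(rnorm(20)), "at least 50")
  # degenerate input gets the sigma floor, not a crash
  f0 <- fit_fl1_mixture(rep(2, 100))
  expect_equal(f0$n_components, 1L)
  expect_gt(f0$sigma_all, 0)
})

test_that("the EM agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  withr::local_seed(6)
  x <- c(rnorm(1500, 2, 1), rnorm(3500, 12, 2))
  ours <- fit_fl1_mixture(x)
  ref <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(ours$mu_off, min(ref$parameters$mean), tolerance = 0.05)
  expect_equal(ours$mu_on, max(ref$parameters$mean), tolerance = 0.05)
  expect_equal(ours$rho_on,
               ref$parameters$pro[which.max(ref$parameters$mean)],
               tolerance = 0.01)
})

test_that("response amplitude is the activated-component mean", {
  withr::local_seed(7)
  uni <- fit_fl1_mixture(rnorm(500, 5, 1))
  expect_equal(response_amplitude(uni), uni$mu_all)
  bim <- fit_fl1_mixture(c(rnorm(500, 0, 1), rnorm(4500, 8, 1)))
  expect_equal(bim$n_components, 2L)
  expect_equal(response_amplitude(bim), bim$mu_on)  # weight-free rule
  expect_equal(response_amplitude(bim), 8, tolerance = 0.1)
})

test_that("the ON/OFF threshold equalises the two misclassification tails", {
  expect_equal(on_off_threshold(0, 1, 10, 1), 5)
  expect_equal(on_off_threshold(0, 2, 9, 1), 6)
  # defining property P(X_ON < t) = P(X_OFF > t), checked against pnorm and
  # against a numeric root
  cases <- list(c(0, 1, 10, 1), c(0, 2, 9, 1), c(-3, 0.5, 4, 2.5))
  for (cs in cases) {
    t <- on_off_threshold(cs[1], cs[2], cs[3], cs[4])
    expect_equal(stats::pnorm(t, cs[3], cs[4]),
                 stats::pnorm(t, cs[1], cs[2], lower.tail = FALSE),
                 tolerance = 1e-12)
    root <- stats::uniroot(function(z) {
      stats::pnorm(z, cs[3], cs[4]) -
        stats::pnorm(z, cs[1], cs[2], lower.tail = FALSE)
    }, interval = c(cs[1], cs[3]), tol = 1e-12)$root
    expect_equal(t, root, tolerance = 1e-9)
    # translation equivariance
    expect_equal(on_off_threshold(cs[1] + 7, cs[2], cs[3] + 7, cs[4]), t + 7,
                 tolerance = 1e-12)
  }
  expect_error(on_off_threshold(5, 1, 2, 1), "exceed")
  expect_error(on_off_threshold(0, 0, 2, 1), "> 0")
})

test_that("inducibility counts strict exceedances with a binomial error", {
  r <- inducibility(c(1, 2, 3, 4), t = 2.5)
  expect_equal(r$fraction_on, 0.5)
  expect_equal(r$sem, sqrt(0.25 / 4))
  expect_equal(inducibility(c(1, 2), t = 5)$fraction_on, 0)
  expect_equal(inducibility(c(7, 8), t = 5)$fraction_on, 1)
  # boundary value: strictly greater, not >=
  expect_equal(inducibility(c(5, 6), t = 5)$fraction_on, 0.5)
  expect_error(inducibility(numeric(), 1), "nonempty")
})
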