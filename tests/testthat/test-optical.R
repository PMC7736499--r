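test_that("volume-fraction readout is a background-corrected somatic ratio", {
  expect_equal(compute_vf(100, 100), 1)              # somatic self-normalization
  expect_equal(compute_vf(6.5, 100), 0.065)          # typical PAP VF of 6-7%
  expect_equal(compute_vf(30, 110, background = 10), 0.2)
  # scale invariance in the overall intensity
  for (c in c(0.2, 3, 1e4))
    expect_equal(compute_vf(30 * c, 110 * c, 10 * c), 0.2)
  expect_error(compute_vf(5, 10, background = 10), "degenerate")
})

test_that("noiseless VF decay traces are recovered exactly", {
  t <- seq(0, 30, length.out = 30)
  vf <- 0.77 + (1 - 0.77) * exp(-t / 14)
  fit <- fit_vf_decay(t, vf)
  expect_true(fit$identifiable)
  expect_equal(fit$vf_ss, 0.77, tolerance = 1e-7)
  expect_equal(fit$tau, 14, tolerance = 1e-6)
  expect_lt(max(abs(fit$residuals)), 1e-10)
})

test_that("non-decaying VF traces are flagged unidentifiable", {
  t <- seq(0, 30, length.out = 10)
  fit <- fit_vf_decay(t, rep(1, 10))
  expect_false(fit$identifiable)
  expect_equal(fit$vf_ss, 1)
  expect_true(is.na(fit$tau))
  expect_error(fit_vf_decay(t[1:3], rep(1, 3)), "at least 5")
})

test_that("point-source diffusivity is recovered and scales linearly", {
  sc <- gen_point_source_linescan(D = 0.4, noise_sd = 0, seed = 2)
  tr <- attr(sc, "truth")
  est <- estimate_point_source_diffusivity(sc, tr$source_position, tr$puff_time)
  expect_equal(est$d_eff, 0.4, tolerance = 0.02)
  expect_equal(est$rejected_fraction, 0)
  # early lines have small fitted variance (w -> 0 as t -> 0+)
  expect_lt(est$w[1], est$w[length(est$w)] / 5)
  # doubling the generator D doubles the fitted slope
  sc2 <- gen_point_source_linescan(D = 0.8, noise_sd = 0, seed = 2)
  est2 <- estimate_point_source_diffusivity(sc2, tr$source_position, 0)
  expect_equal(est2$d_eff / est$d_eff, 2, tolerance = 0.02)
  expect_error(estimate_point_source_diffusivity(sc, source_position = 1e3),
               "outside the scan")
})

test_that("FRAP rate is reported relative to a reference", {
  t <- seq(0, 40, by = 0.5)
  mk <- function(slope) {
    y <- rep(1, length(t))
    rec <- t > 12
    y[t >= 10 & t <= 12] <- 0.3
    y[rec] <- pmin(0.3 + slope * (t[rec] - 12), 1)
    y
  }
  ref <- compute_frap_rate(t, mk(0.05), c(10, 12))
  same <- compute_frap_rate(t, mk(0.05), c(10, 12),
                            reference_rate = ref$rate)
  expect_equal(same$relative_percent, 100, tolerance = 1e-6)
  slower <- compute_frap_rate(t, mk(0.05 * 0.62), c(10, 12),
                              reference_rate = ref$rate)
  expect_equal(slower$relative_percent, 62, tolerance = 1)
  flat <- compute_frap_rate(t, mk(0), c(10, 12), reference_rate = ref$rate)
  expect_equal(flat$relative_percent, 0, tolerance = 1e-6)
  expect_error(compute_frap_rate(t[t < 9], mk(0.05)[t < 9], c(10, 12)),
               "recovery")
})

test_that("sensor profiles are pure functions of the windows", {
  sc <- gen_uncaging_linescan(noise_sd = 0, seed = 3)$pre
  tr <- attr(gen_uncaging_linescan(noise_sd = 0, seed = 3), "truth")
  # post window identical to pre window: all-zero profile
  p0 <- iglusnfr_profile(sc, c(1, 10), c(11, 20))  # both pre-onset
  expect_equal(max(abs(p0$profile)), 0)
  p1 <- iglusnfr_profile(sc, c(1, 19), c(25, 50))
  expect_equal(max(p1$profile), tr$amplitude, tolerance = 1e-9)
  p2 <- iglusnfr_profile(sc, c(1, 19), c(25, 50))
  expect_identical(p1, p2)
  expect_error(iglusnfr_profile(sc, c(1, 25), c(20, 40)), "disjoint")
})

test_that("Gaussian profile fits obey the FWHM identity", {
  x <- seq(-2, 2, by = 0.01)
  y <- exp(-x^2 / (2 * 0.1^2))
  fit <- fit_profile_fwhm(x, y, center = 0)
  expect_equal(fit$sigma, 0.1, tolerance = 1e-6)
  expect_identical(fit$fwhm / fit$sigma, 2 * sqrt(2 * log(2)))
  expect_equal(fit$fwhm, 0.23548, tolerance = 1e-4)  # 235.48 nm for 100 nm sd
  # constant baseline leaves FWHM unchanged (baseline is a free parameter)
  fitb <- fit_profile_fwhm(x, y + 5, center = 0)
  expect_equal(fitb$fwhm, fit$fwhm, tolerance = 1e-6)
  expect_equal(fitb$baseline, 5, tolerance = 1e-6)
  expect_error(fit_profile_fwhm(x, rep(1, length(x))), "flat")
})

test_that("a 9% sigma increase reads out as a 9% FWHM increase", {
  pair <- gen_uncaging_linescan(sigma_pre = 0.5, sigma_post = 0.5 * 1.090,
                                noise_sd = 0, seed = 6)
  tr <- attr(pair, "truth")
  f <- function(scan) {
    p <- iglusnfr_profile(scan, c(1, tr$onset - 1), c(tr$onset + 5, 60))
    fit_profile_fwhm(p$position, p$profile, center = tr$center)$fwhm
  }
  change <- 100 * (f(pair$post) / f(pair$pre) - 1)
  expect_equal(change, 9.0, tolerance = 0.05)
})

test_that("ratiometric responses subtract the baseline ratio", {
  set.seed(4)
  don <- 100 + rnorm(50, 0, 0.1)
  acc <- 200 + rnorm(50, 0, 0.1)
  # common scaling of both channels gives no response
  r <- ratiometric_response(3 * don, 3 * acc, baseline = 1:50)
  expect_lt(max(abs(r$dr)), 1e-2 * r$r0)
  # saturation-binding titration: half-saturation recovered within 5%
  kd <- 0.6
  conc <- seq(0, 5, by = 0.05)
  rmax <- 0.8
  donor <- 100 * (1 + rmax * conc / (kd + conc))
  acceptor <- rep(100, length(conc))
  resp <- ratiometric_response(donor, acceptor, baseline = 1)
  dr <- resp$dr
  fit <- minpack.lm::nlsLM(dr ~ a * conc / (k + conc),
                           start = list(a = 0.5, k = 0.3))
  expect_equal(unname(coef(fit)["k"]), kd, tolerance = 0.05)
  expect_error(ratiometric_response(don, 0 * acc, on_zero_acceptor = "error"),
               "acceptor")
})
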