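test_that("cross-talk fraction is the relative reduction of the resumed response", {
  mk <- function(scale) {
    epsc_series(trial = 1:12,
                amplitude = c(rep(50, 6), rep(50 * scale, 6)),
                pathway = "silent",
                phase = rep(c("nmdar_baseline", "resumed"), each = 6))
  }
  expect_equal(crosstalk_fraction(mk(1)), 0)
  expect_equal(crosstalk_fraction(mk(0.60)), 40)  # the post-LTP value
  # invariant to amplitude rescaling
  s <- mk(0.6); s$amplitude <- s$amplitude * 17
  expect_equal(crosstalk_fraction(s), 40)
  expect_error(crosstalk_fraction(mk(1)[1:7, ]), "trials")
})

test_that("cross-talk estimator is unbiased on noisy synthetic series", {
  est <- vapply(1:300, function(k) {
    s <- gen_epsc_series(n_sites = 12, p_release = 0.5, trials_per_phase = 10,
                         crosstalk = 0.40, noise_cv = 0.2, seed = k)
    crosstalk_fraction(s)
  }, numeric(1))
  expect_lt(abs(mean(est) - 40), 2)
})

test_that("per-discharge probability follows the compound model", {
  p <- per_discharge_probability(0.40, 120)
  expect_equal(100 * p, 0.425, tolerance = 0.005)  # prints as ~0.4%
  expect_equal(per_discharge_probability(0, 50), 0)
  expect_equal((1 - p)^120, 0.60, tolerance = 1e-12)
  expect_error(per_discharge_probability(1, 10), "input error")
  # forward Bernoulli simulation round trip
  set.seed(42)
  n_rec <- 1e5
  blocked <- rbinom(n_rec, 120, 0.00425) > 0
  f_sim <- mean(blocked)
  se <- sqrt(f_sim * (1 - f_sim) / n_rec)
  expect_lt(abs(f_sim - 0.40), 3 * se + 0.002)
})

test_that("subsampled nearest-neighbour distance scales as p^(-1/3)", {
  expect_equal(subsample_nn_distance(0.5, 0.02), 1.842, tolerance = 1e-3)
  expect_equal(subsample_nn_distance(0.7, 1), 0.7)
  expect_error(subsample_nn_distance(0.5, 0), "input error")
})

test_that("Poisson thinning reproduces the p^(-1/3) distance scaling", {
  set.seed(10)
  L <- 1
  n <- 20000
  pts <- matrix(runif(3 * n, 0, L), ncol = 3)
  p_keep <- 1 / 8
  keep <- pts[runif(n) < p_keep, , drop = FALSE]
  mean_nnd <- function(m) {
    # interior sources only, to avoid boundary bias
    interior <- m[apply(m > 0.2 & m < 0.8, 1, all), , drop = FALSE]
    interior <- interior[seq_len(min(1500, nrow(interior))), , drop = FALSE]
    sq <- rowSums(m^2)
    mean(vapply(seq_len(nrow(interior)), function(i) {
      d2 <- sq - 2 * (m %*% interior[i, ]) + sum(interior[i, ]^2)
      sqrt(max(0, min(d2[d2 > 1e-20])))
    }, numeric(1)))
  }
  ratio <- mean_nnd(keep) / mean_nnd(pts)
  expect_equal(ratio, p_keep^(-1 / 3), tolerance = 0.05)
})

test_that("ECS increase arithmetic is linear and matches the midpoint case", {
  expect_equal(100 * ecs_increase(0.065, 0.25, 0.175), 9.3, tolerance = 0.05)
  expect_equal(ecs_increase(0.065, 0, 0.175), 0)
  expect_equal(ecs_increase(0.065, 0.30, 0.175),
               2 * ecs_increase(0.065, 0.15, 0.175))
  expect_error(ecs_increase(0.065, 0.25, 0), "input error")
})

test_that("paired-pulse facilitation is the relative second-pulse gain", {
  expect_equal(paired_pulse_ratio(100, 175.4), 75.4)   # within-pathway value
  expect_equal(paired_pulse_ratio(100, 116.5), 16.5)   # between-pathway value
  expect_equal(paired_pulse_ratio(80, 80), 0)
  expect_error(paired_pulse_ratio(0, 10), "input error")
})

test_that("1/CV^2 matches the binomial release prediction", {
  set.seed(6)
  N <- 8; p <- 0.4; q <- 12
  amp <- rbinom(1e4, N, p) * q
  expect_equal(inv_cv_squared(amp), N * p / (1 - p), tolerance = 0.05 * N * p / (1 - p))
  expect_equal(inv_cv_squared(amp * 3.7), inv_cv_squared(amp))
  # monotone in p at fixed N
  vals <- vapply(c(0.2, 0.4, 0.6), function(pp) {
    inv_cv_squared(rbinom(1e4, N, pp) * q)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_warning(out <- inv_cv_squared(rep(5, 10)), "zero variance")
  expect_true(is.na(out))
})

test_that("MK801 block rate recovers the forward-model decay constant", {
  b <- 0.12
  k0 <- vapply(1:40, function(k) {
    s <- gen_epsc_series(n_sites = 100, p_release = 0.5,
                         trials_per_phase = 30, block_prob = b,
                         noise_cv = 0.03, seed = 100 + k)
    mk801_block_rate(s)$k0
  }, numeric(1))
  expect_equal(mean(k0), -1 / log(1 - b), tolerance = 0.1 * (-1 / log(1 - b)))
})

test_that("non-decaying MK801 series are flagged, equal pathways indistinguishable", {
  flat <- epsc_series(1:10, rep(80, 10), "active", "mk801")
  expect_false(mk801_block_rate(flat)$identifiable)
  # blockless noisy series are flagged at close to the nominal rate
  flags <- vapply(1:10, function(k) {
    s0 <- gen_epsc_series(block_prob = 0, trials_per_phase = 12,
                          noise_cv = 0.05, seed = 30 + k)
    mk801_block_rate(s0)$identifiable
  }, logical(1))
  expect_lte(sum(flags), 2)
  # two pathways with equal release probability: overlapping k0 intervals
  r1 <- mk801_block_rate(gen_epsc_series(n_sites = 60, p_release = 0.45,
                                         trials_per_phase = 40,
                                         block_prob = 0.1, noise_cv = 0.05,
                                         seed = 21))
  r2 <- mk801_block_rate(gen_epsc_series(n_sites = 60, p_release = 0.45,
                                         trials_per_phase = 40,
                                         block_prob = 0.1, noise_cv = 0.05,
                                         seed = 22))
  expect_true(r1$k0_ci[1] <= r2$k0_ci[2] && r2$k0_ci[1] <= r1$k0_ci[2])
})
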