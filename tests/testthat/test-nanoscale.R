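test_that("nearest-neighbour distances are zero against the same set", {
  set.seed(2)
  n <- 40
  locs <- localization_set(runif(n, 0, 500), runif(n, 0, 500),
                           runif(n, 0, 500),
                           rep(c("glt1", "bassoon"), each = n / 2))
  # make targets a copy of the sources
  src <- locs[locs$channel == "glt1", ]
  both <- localization_set(c(src$x, src$x), c(src$y, src$y),
                           c(src$z, src$z),
                           rep(c("glt1", "bassoon"), each = nrow(src)))
  expect_equal(nearest_neighbor_distances(both, "glt1", "bassoon"),
               rep(0, nrow(src)))
  expect_error(nearest_neighbor_distances(locs, "glt1", "homer1"),
               "empty channel")
})

test_that("uniform target points follow the Poisson nearest-neighbour law", {
  set.seed(11)
  L <- 2000; n_t <- 4000
  lambda <- n_t / L^3
  tgt <- matrix(runif(3 * n_t, 0, L), ncol = 3)
  # sources away from the field borders to avoid edge effects
  n_s <- 600
  src <- matrix(runif(3 * n_s, 300, L - 300), ncol = 3)
  locs <- localization_set(c(src[, 1], tgt[, 1]), c(src[, 2], tgt[, 2]),
                           c(src[, 3], tgt[, 3]),
                           rep(c("glt1", "bassoon"), c(n_s, n_t)))
  d <- nearest_neighbor_distances(locs, "glt1", "bassoon")
  # CDF: F(r) = 1 - exp(-4/3 pi lambda r^3)
  for (q in c(0.25, 0.5, 0.75)) {
    r_q <- (-log(1 - q) * 3 / (4 * pi * lambda))^(1 / 3)
    expect_lt(abs(mean(d <= r_q) - q), 0.06)  # ~3.5 binomial SE at n = 600
  }
})

test_that("a displaced transporter shell shifts the distance mode accordingly", {
  l1 <- gen_localizations(n_synapses = 6, glt1_radius = 150,
                          glt1_radius_sd = 15, n_per_channel = 80, seed = 7)
  l2 <- gen_localizations(n_synapses = 6, glt1_radius = 200,
                          glt1_radius_sd = 15, n_per_channel = 80, seed = 7)
  d1 <- nearest_neighbor_distances(l1, "glt1", "bassoon")
  d2 <- nearest_neighbor_distances(l2, "glt1", "bassoon")
  mode_of <- function(d) {
    dens <- nnd_density(d, bin_width = 10)
    dens$mid[which.max(dens$density)]
  }
  shift <- mode_of(d2) - mode_of(d1)
  expect_gt(shift, 30)
  expect_lt(shift, 70)
  expect_gt(median(d2), median(d1))  # post-cLTP-like rightward shift
})

test_that("distance statistics are invariant under joint rigid transforms", {
  locs <- gen_localizations(n_synapses = 3, seed = 5)
  d0 <- nearest_neighbor_distances(locs, "glt1", "bassoon")
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(locs[, c("x", "y", "z")]) %*% Rz + 123.4
  rot <- localization_set(xyz[, 1], xyz[, 2], xyz[, 3], locs$channel)
  d1 <- nearest_neighbor_distances(rot, "glt1", "bassoon")
  expect_equal(as.numeric(d0), as.numeric(d1), tolerance = 1e-7)
})

test_that("distance densities integrate to one and report group SEM", {
  set.seed(3)
  d <- rgamma(400, 4, 1 / 30)
  out <- nnd_density(d, bin_width = 20)
  expect_lt(abs(sum(out$density * 20) - 1), 1e-9)
  expect_true(all(is.na(out$sem)))
  # all-identical distances occupy one bin at density 1 / bin_width
  one <- nnd_density(rep(55, 10), bin_width = 20)
  expect_equal(sum(one$density > 0), 1L)
  expect_equal(max(one$density), 1 / 20)
  # two-group SEM matches the direct formula
  g <- rep(1:2, each = 200)
  out2 <- nnd_density(d, bin_width = 20, groups = g)
  breaks <- seq(0, max(out2$mid) + 10, by = 20)
  per <- sapply(split(d, g), function(dd) {
    hist(dd, breaks = breaks, plot = FALSE)$counts / (length(dd) * 20)
  })
  expect_equal(out2$sem, apply(per, 1, sd) / sqrt(2), tolerance = 1e-12)
  expect_lt(abs(sum(out2$density * 20) - 1), 1e-9)
})

test_that("proximity classification thresholds at one pixel / 20 nm", {
  expect_equal(classify_proximity(0), "contact")
  expect_equal(classify_proximity(20), "contact")
  expect_equal(classify_proximity(21), "no-contact")
  expect_equal(classify_proximity(25, pixel_size = 25), "contact")
  # monotone in distance
  cls <- classify_proximity(seq(0, 100, by = 5))
  expect_true(all(diff(cls == "contact") <= 0))
  expect_error(classify_proximity(-1), "negative")
})

test_that("line-profile FWHM measures widths directly", {
  px <- 19.53
  # rectangular profile of width W
  prof <- c(0, 0, rep(1, 6), 0, 0)
  expect_equal(profile_width(prof, px), 6 * px, tolerance = px)
  # sampled Gaussian within one pixel of the analytic FWHM
  x <- (0:40) * px
  sigma <- 80
  g <- exp(-(x - 400)^2 / (2 * sigma^2))
  expect_lt(abs(profile_width(g, px) - 2 * sqrt(2 * log(2)) * sigma), px)
  expect_error(profile_width(c(5, 4, 3, 2, 1), px), "edge")
})

test_that("shell VF profiles match trivial masks", {
  full <- voxel_mask(array(TRUE, c(40, 40, 40)), pitch = 10)
  empty <- voxel_mask(array(FALSE, c(40, 40, 40)), pitch = 10)
  ctr <- c(200, 200, 200)
  pf <- shell_vf(full, ctr, 100, 200)
  pe <- shell_vf(empty, ctr, 100, 200)
  expect_equal(pf$vf, rep(1, 2))
  expect_equal(pe$vf, rep(0, 2))
  expect_error(shell_vf(full, c(-10, 0, 0)), "outside")
  # truncated shells are flagged
  tr <- shell_vf(full, ctr, 100, 500)
  expect_true(any(tr$truncated))
  expect_false(tr$truncated[1])
})

test_that("a centred solid sphere reproduces the analytic shell fractions", {
  pitch <- 5
  dim3 <- rep(220, 3)
  ctr <- rep(220 * pitch / 2, 3)
  rs <- 250
  mask <- gen_masks(data.frame(cx = ctr[1], cy = ctr[2], cz = ctr[3],
                               rx = rs, ry = rs, rz = rs),
                    grid_dim = dim3, pitch = pitch)
  prof <- shell_vf(mask, ctr, 100, 500)
  analytic <- vapply(seq_len(nrow(prof)), function(k) {
    r1 <- prof$inner[k]; r2 <- prof$outer[k]
    (min(rs, r2)^3 - min(rs, r1)^3) / (r2^3 - r1^3)
  }, numeric(1))
  expect_lt(max(abs(prof$vf - analytic)), 0.02)
})
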