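# Seeded synthetic-data generators. Each generator is deterministic given
# (parameters, seed) and stores the generating truth in the "truth"
# attribute, so every analysis stage can be tested against known ground
# truth without any external data.

truth <- function(x) attr(x, "truth")

#' Synthetic astroglial volume-fraction decay trace
#'
#' `VF(t) = vf_ss + (1 - vf_ss) exp(-t / tau)` plus i.i.d. Gaussian noise,
#' normalized to a pre-induction value of 1 at t = 0.
#'
#' @param vf_ss Steady-state relative VF in (0, 1].
#' @param tau Decay time constant, min.
#' @param noise_sd Additive noise SD.
#' @param n_points Number of time points.
#' @param t_max Last time point, min.
#' @param seed RNG seed.
#' @return Data frame (time, vf) with the generating truth in
#'   `attr(, "truth")`.
#' @export
gen_vf_trace <- function(vf_ss = 0.77, tau = 14, noise_sd = 0.02,
                         n_points = 30, t_max = 30, seed = 1) {
  stopifnot(vf_ss > 0, vf_ss <= 1, tau > 0, n_points >= 2)
  set.seed(seed)
  t <- seq(0, t_max, length.out = n_points)
  model <- vf_ss + (1 - vf_ss) * exp(-t / tau)
  out <- data.frame(time = t, vf = model + rnorm(n_points, 0, noise_sd))
  attr(out, "truth") <- list(vf_ss = vf_ss, tau = tau, noise_sd = noise_sd,
                             seed = seed)
  out
}

#' Synthetic point-source diffusion linescan
#'
#' Per-line profiles proportional to `(4 pi D t)^(-1/2) exp(-(x - xc)^2 /
#' (4 D t))` for a spreading instantaneous point source, plus Gaussian noise.
#'
#' @param D Diffusion coefficient, um^2/ms.
#' @param dx Pixel pitch, um.
#' @param dt Line period, ms (default: `duration / 20`).
#' @param duration Scan duration, ms. The default, `4 / D`, tracks the bolus
#'   while its spread (`sigma = sqrt(2 D t)`, up to ~2.8 um) stays resolved
#'   within the scan.
#' @param extent Scan length, um (source at the centre).
#' @param amplitude Peak scaling of the first usable line.
#' @param noise_sd Additive noise SD.
#' @param seed RNG seed.
#' @return A [linescan()]; truth holds `D` and the source position.
#' @export
gen_point_source_linescan <- function(D = 0.4, dx = 0.2, dt = NULL,
                                      duration = NULL, extent = 20,
                                      amplitude = 100, noise_sd = 0,
                                      seed = 1) {
  stopifnot(D > 0)
  if (is.null(duration)) duration <- 4 / D
  if (is.null(dt)) dt <- duration / 20
  set.seed(seed)
  x <- seq(0, extent, by = dx)
  xc <- extent / 2
  t <- seq(dt, duration, by = dt)
  m <- t(vapply(t, function(tk) {
    amplitude * sqrt(dt / tk) * exp(-(x - xc)^2 / (4 * D * tk))
  }, numeric(length(x))))
  m <- m + rnorm(length(m), 0, noise_sd)
  # prepend the pre-puff line (t = 0)
  m <- rbind(rnorm(length(x), 0, noise_sd), m)
  scan <- linescan(m, line_period = dt, pixel_pitch = dx)
  attr(scan, "truth") <- list(D = D, source_position = xc, puff_time = 0,
                              seed = seed)
  scan
}

#' Synthetic pre/post uncaging linescan pair
#'
#' Two linescans with Gaussian response transients of widths `sigma_pre` and
#' `sigma_post` (um) around the uncaging spot, on a flat baseline; the truth
#' records the relative FWHM change `sigma_post / sigma_pre - 1`.
#'
#' @param sigma_pre,sigma_post Response SD before/after induction, um.
#' @param amplitude Peak dF/F0 of the transient.
#' @param baseline Baseline fluorescence level.
#' @param noise_sd Additive noise SD (SNR = amplitude x baseline / noise_sd).
#' @param n_lines,n_pixels Scan size.
#' @param dt Line period, ms; \code{dx} pixel pitch, um.
#' @param dx Pixel pitch, um.
#' @param onset Line index of uncaging onset.
#' @param seed RNG seed.
#' @export
gen_uncaging_linescan <- function(sigma_pre = 0.5, sigma_post = 0.545,
                                  amplitude = 1.0, baseline = 50,
                                  noise_sd = 2.5, n_lines = 60,
                                  n_pixels = 101, dt = 2, dx = 0.1,
                                  onset = 20, seed = 1) {
  stopifnot(sigma_pre > 0, sigma_post > 0)
  set.seed(seed)
  x <- (seq_len(n_pixels) - 1) * dx
  xc <- x[(n_pixels + 1) / 2]
  make <- function(sigma) {
    m <- matrix(baseline, n_lines, n_pixels)
    resp <- amplitude * baseline * exp(-(x - xc)^2 / (2 * sigma^2))
    for (i in (onset + 1):n_lines) m[i, ] <- m[i, ] + resp
    linescan(m + rnorm(length(m), 0, noise_sd), line_period = dt,
             pixel_pitch = dx)
  }
  out <- list(pre = make(sigma_pre), post = make(sigma_post))
  attr(out, "truth") <- list(sigma_pre = sigma_pre, sigma_post = sigma_post,
                             fwhm_change = sigma_post / sigma_pre - 1,
                             center = xc, onset = onset, amplitude = amplitude,
                             seed = seed)
  out
}

#' Synthetic three-channel perisynaptic localization clouds
#'
#' Per synapse: a Gaussian bassoon cluster, a Homer1 cluster displaced along
#' a random axis, and GLT1 points on a noisy spherical shell at a given
#' radial distance from the bassoon centroid, plus uniform background points.
#'
#' @param n_synapses Number of synapses.
#' @param cluster_sd Bassoon/Homer1 cluster SD, nm.
#' @param homer_offset Homer1 displacement from bassoon, nm.
#' @param glt1_radius Mean GLT1 shell radius, nm.
#' @param glt1_radius_sd Shell radius SD, nm.
#' @param n_per_channel Points per channel per synapse.
#' @param background_rate Uniform background points per channel per synapse.
#' @param field_size Field edge length, nm (synapse centres kept inside with
#'   a margin).
#' @param seed RNG seed.
#' @return A [localization_set()] with synapse ids; truth stores the shell
#'   radii.
#' @export
gen_localizations <- function(n_synapses = 5, cluster_sd = 40,
                              homer_offset = 100, glt1_radius = 150,
                              glt1_radius_sd = 30, n_per_channel = 60,
                              background_rate = 0, field_size = 4000,
                              seed = 1) {
  set.seed(seed)
  margin <- glt1_radius + 4 * glt1_radius_sd
  res <- list()
  for (s in seq_len(n_synapses)) {
    c0 <- runif(3, margin, field_size - margin)
    bas <- sweep(matrix(rnorm(3 * n_per_channel, 0, cluster_sd), ncol = 3),
                 2, c0, `+`)
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    hom <- sweep(matrix(rnorm(3 * n_per_channel, 0, cluster_sd), ncol = 3),
                 2, c0 + homer_offset * ax, `+`)
    # GLT1: radial shell around the bassoon centroid
    u <- matrix(rnorm(3 * n_per_channel), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    rr <- pmax(rnorm(n_per_channel, glt1_radius, glt1_radius_sd), 1)
    glt <- sweep(u * rr, 2, c0, `+`)
    pts <- rbind(bas, hom, glt)
    ch <- rep(c("bassoon", "homer1", "glt1"), each = n_per_channel)
    if (background_rate > 0) {
      nb <- rpois(1, background_rate * 3)
      bg <- matrix(runif(3 * nb, 0, field_size), ncol = 3)
      pts <- rbind(pts, bg)
      ch <- c(ch, sample(papsim_channels, nb, replace = TRUE))
    }
    res[[s]] <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                           channel = ch, synapse = s)
  }
  d <- do.call(rbind, res)
  out <- localization_set(d$x, d$y, d$z, d$channel, d$synapse)
  attr(out, "truth") <- list(glt1_radius = glt1_radius,
                             glt1_radius_sd = glt1_radius_sd,
                             cluster_sd = cluster_sd,
                             homer_offset = homer_offset, seed = seed)
  out
}

#' Synthetic voxel occupancy masks
#'
#' Rasterizes a set of solid spheres/ellipsoids onto a voxel grid.
#'
#' @param shapes Data frame with columns `cx, cy, cz` (centres, nm),
#'   `rx, ry, rz` (semi-axes, nm); an empty data frame gives an empty mask.
#' @param grid_dim Grid dimensions (voxels), length 3.
#' @param pitch Voxel pitch, nm.
#' @param centroids Optional PSD centroids passed to [voxel_mask()].
#' @export
gen_masks <- function(shapes, grid_dim = c(100, 100, 100), pitch = 10,
                      centroids = NULL) {
  occ <- array(FALSE, grid_dim)
  if (nrow(shapes)) {
    cx <- (seq_len(grid_dim[1]) - 0.5) * pitch
    cy <- (seq_len(grid_dim[2]) - 0.5) * pitch
    cz <- (seq_len(grid_dim[3]) - 0.5) * pitch
    for (i in seq_len(nrow(shapes))) {
      s <- shapes[i, ]
      d2 <- outer(outer(((cx - s$cx) / s$rx)^2, ((cy - s$cy) / s$ry)^2, `+`),
                  ((cz - s$cz) / s$rz)^2, `+`)
      occ <- occ | (d2 <= 1)
    }
  }
  m <- voxel_mask(occ, pitch, centroids)
  attr(m, "truth") <- list(shapes = shapes)
  m
}

#' Synthetic two-pathway EPSC series with use-dependent block
#'
#' Binomial-release amplitudes `Binomial(N, p) x q` with multiplicative
#' Gaussian noise; the MK801 phase applies cumulative per-trial block to the
#' active pathway; silent-pathway `resumed` amplitudes are scaled by
#' `(1 - crosstalk)` relative to its NMDAR baseline.
#'
#' @param n_sites Release sites N.
#' @param p_release Release probability p.
#' @param q Quantal size, pA.
#' @param trials_per_phase Trials per phase and pathway.
#' @param block_prob Per-trial open-and-block probability b in the MK801
#'   phase.
#' @param crosstalk Fraction of silent-pathway NMDARs cross-activated (and
#'   blocked) before stimulation resumes.
#' @param noise_cv Multiplicative noise CV.
#' @param seed RNG seed.
#' @return An [epsc_series()] covering both pathways; truth stores all
#'   generator parameters.
#' @export
gen_epsc_series <- function(n_sites = 10, p_release = 0.35, q = 10,
                            trials_per_phase = 10, block_prob = 0.1,
                            crosstalk = 0, noise_cv = 0.1, seed = 1) {
  stopifnot(n_sites >= 1, p_release > 0, p_release < 1, crosstalk >= 0,
            crosstalk < 1)
  set.seed(seed)
  amp <- function(n, scale = 1) {
    base <- rbinom(n, n_sites, p_release) * q * scale
    base * (1 + rnorm(n, 0, noise_cv))
  }
  rows <- list()
  tr <- 0
  add <- function(pathway, phase, values) {
    if (!length(values)) return(invisible())
    rows[[length(rows) + 1]] <<- data.frame(
      trial = tr + seq_along(values), amplitude = values,
      pathway = pathway, phase = phase)
    tr <<- tr + length(values)
  }
  for (pw in c("active", "silent")) add(pw, "ampar_baseline",
                                        amp(trials_per_phase))
  for (pw in c("active", "silent")) add(pw, "nmdar_baseline",
                                        amp(trials_per_phase))
  # MK801: active pathway only; unblocked receptor fraction decays
  unblocked <- (1 - block_prob)^(seq_len(trials_per_phase) - 1)
  add("active", "mk801", amp(trials_per_phase) * unblocked)
  add("silent", "silent_pause", numeric(0))
  add("silent", "resumed", amp(trials_per_phase, scale = 1 - crosstalk))
  d <- do.call(rbind, rows)
  out <- epsc_series(d$trial, d$amplitude, d$pathway, d$phase)
  attr(out, "truth") <- list(n_sites = n_sites, p_release = p_release, q = q,
                             block_prob = block_prob, crosstalk = crosstalk,
                             noise_cv = noise_cv, seed = seed)
  out
}
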