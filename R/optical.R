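# Light-microscopy quantification: volume-fraction readout and decay,
# FRAP recovery rate, point-source diffusivity, glutamate-sensor linescan
# profiles and ratiometric sensor responses.

#' Construct a linescan object
#'
#' @param intensity Time x position matrix of non-negative intensities.
#' @param line_period Line period, ms.
#' @param pixel_pitch Pixel pitch, um.
#' @param shutter_closed Optional (start, end) line indices of a
#'   shutter-closed interval.
#' @export
linescan <- function(intensity, line_period, pixel_pitch,
                     shutter_closed = NULL) {
  intensity <- as.matrix(intensity)
  if (!nrow(intensity) || !ncol(intensity))
    stop("input error: empty linescan")
  if (line_period <= 0 || pixel_pitch <= 0)
    stop("input error: line period and pixel pitch must be positive")
  out <- list(intensity = intensity, line_period = line_period,
              pixel_pitch = pixel_pitch, shutter_closed = shutter_closed)
  class(out) <- "papsim_linescan"
  out
}

#' Astroglial volume fraction from somatic normalization
#'
#' VF is the background-corrected ROI fluorescence normalized to the
#' background-corrected somatic fluorescence, where the soma represents 100%
#' volume fraction. Scale-invariant in the overall intensity.
#'
#' @param f_roi ROI fluorescence (scalar or vector).
#' @param f_soma Somatic fluorescence.
#' @param background Background fluorescence (default 0).
#' @return VF, dimensionless.
#' @export
compute_vf <- function(f_roi, f_soma, background = 0) {
  if (any(f_soma <= background))
    stop("degenerate normalization: somatic fluorescence must exceed background")
  (f_roi - background) / (f_soma - background)
}

#' Fit an exponential decay to steady state to a volume-fraction trace
#'
#' Fits `VF(t) = VF_ss + (1 - VF_ss) exp(-t / tau)` to a trace normalized to
#' a pre-induction mean of 1, by least squares.
#'
#' @param time Time points, min (strictly increasing, onset at 0).
#' @param vf VF values (relative, pre-induction mean 1).
#' @return List with `vf_ss`, `tau` (min), 95% confidence intervals,
#'   residuals, `converged`, and `identifiable` (FALSE for non-decaying
#'   traces, in which case `vf_ss` is the trace mean and `tau` is NA).
#' @export
fit_vf_decay <- function(time, vf) {
  stopifnot(length(time) == length(vf), all(diff(time) > 0))
  if (length(time) < 5)
    stop("input error: need at least 5 post-onset time points")
  # decaying at all? require a negative slope signal
  sl <- coef(lm(vf ~ time))[2]
  rng <- diff(range(vf))
  if (sl >= 0 || rng < 1e-12) {
    return(list(vf_ss = mean(vf), tau = NA_real_,
                vf_ss_ci = mean(vf) + c(-1.96, 1.96) * sd(vf) / sqrt(length(vf)),
                tau_ci = c(NA_real_, NA_real_),
                residuals = vf - mean(vf), converged = TRUE,
                identifiable = FALSE))
  }
  start <- list(vf_ss = max(min(vf), 1e-3),
                tau = max(diff(range(time)) / 3, 1e-3))
  fit <- try(minpack.lm::nlsLM(
    vf ~ vf_ss + (1 - vf_ss) * exp(-time / tau),
    start = start,
    lower = c(-5, 1e-6), upper = c(5, 1e6),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(list(vf_ss = mean(vf), tau = NA_real_,
                vf_ss_ci = c(NA_real_, NA_real_), tau_ci = c(NA_real_, NA_real_),
                residuals = vf - mean(vf), converged = FALSE,
                identifiable = FALSE))
  }
  est <- coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  list(vf_ss = unname(est["vf_ss"]), tau = unname(est["tau"]),
       vf_ss_ci = unname(est["vf_ss"] + c(-1.96, 1.96) * se["vf_ss"]),
       tau_ci = unname(est["tau"] + c(-1.96, 1.96) * se["tau"]),
       residuals = as.numeric(residuals(fit)), converged = TRUE,
       identifiable = TRUE)
}

# single-line Gaussian fit used by the diffusivity estimator:
# I(x) = A exp(-(x - xc)^2 / (4 w)) + b, with xc fixed
fit_line_gaussian <- function(x, y, xc) {
  a0 <- max(y) - min(y)
  if (a0 <= 0) return(NULL)
  w0 <- max((sum(y * (x - xc)^2) / sum(y)) / 2, 1e-6)
  fit <- try(minpack.lm::nlsLM(
    y ~ A * exp(-(x - xc)^2 / (4 * w)) + b,
    start = list(A = a0, w = w0, b = min(y)),
    lower = c(1e-12, 1e-9, -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 100)), silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  coef(fit)
}

#' Effective diffusivity from a point-source linescan
#'
#' Each post-puff line profile is fitted with a Gaussian
#' `A exp(-(x - xc)^2 / (4 w))` centred at the source; the variance parameter
#' `w` grows as `w = D_eff t` for diffusion from an instantaneous point
#' source, and `D_eff` is the slope of the linear fit of `w` against time.
#'
#' @param scan A [linescan()] (time x position).
#' @param source_position Source (pipette tip) position, um.
#' @param puff_time Time of the pressure pulse, ms.
#' @param through_origin Force the w(t) regression through the origin
#'   (default TRUE).
#' @param max_reject Maximal tolerated fraction of rejected line fits.
#' @return List with `d_eff` (um^2/ms), per-line `w` (um^2) and times (ms),
#'   the rejection fraction and convergence status.
#' @export
estimate_point_source_diffusivity <- function(scan, source_position,
                                              puff_time = 0,
                                              through_origin = TRUE,
                                              max_reject = 0.5) {
  stopifnot(inherits(scan, "papsim_linescan"))
  x <- (seq_len(ncol(scan$intensity)) - 1) * scan$pixel_pitch
  if (source_position < min(x) || source_position > max(x))
    stop("input error: source position outside the scan range")
  t_lines <- (seq_len(nrow(scan$intensity)) - 1) * scan$line_period
  post <- which(t_lines > puff_time)
  if (length(post) < 5)
    stop("input error: need at least 5 post-puff lines")
  # QC: a profile only informs the regression while it is resolved within the
  # scan; lines whose fitted spread exceeds a quarter of the scan length are
  # rejected (baseline and width become degenerate there)
  w_max <- (diff(range(x)) / 4)^2 / 2
  w <- rep(NA_real_, length(post))
  for (i in seq_along(post)) {
    cf <- fit_line_gaussian(x, scan$intensity[post[i], ], source_position)
    if (!is.null(cf) && cf["w"] > 0 && cf["w"] <= w_max) w[i] <- cf["w"]
  }
  ok <- !is.na(w)
  if (mean(!ok) > max_reject)
    stop("fit failure: more than ", round(100 * max_reject),
         "% of line profiles rejected")
  tt <- t_lines[post][ok] - puff_time
  ww <- w[ok]
  fit <- if (through_origin) lm(ww ~ tt - 1) else lm(ww ~ tt)
  d_eff <- unname(coef(fit)[if (through_origin) "tt" else "tt"])
  list(d_eff = d_eff, w = ww, t = tt,
       rejected_fraction = mean(!ok), converged = TRUE)
}

#' FRAP recovery rate relative to a reference
#'
#' The recovery rate is the initial slope of the normalized fluorescence
#' recovery after the shutter re-opens, estimated over the first
#' `initial_fraction` of the recovery window (or by an exponential-recovery
#' fit with `method = "exponential"`). Reported absolutely and as percent of
#' a reference rate.
#'
#' @param time Time points, s.
#' @param intensity Fluorescence trace (same length).
#' @param bleach_interval (start, end) of the bleach/shutter-closed interval,
#'   in the units of `time`.
#' @param reference_rate Optional reference recovery rate for the relative
#'   readout.
#' @param initial_fraction Fraction of the recovery window used for the
#'   initial slope.
#' @param method "initial_slope" (default) or "exponential".
#' @return List with `rate` (normalized units per time), `relative_percent`
#'   (if a reference was supplied), and the baseline used.
#' @export
compute_frap_rate <- function(time, intensity, bleach_interval,
                              reference_rate = NULL, initial_fraction = 0.2,
                              method = c("initial_slope", "exponential")) {
  method <- match.arg(method)
  stopifnot(length(time) == length(intensity))
  pre <- time < bleach_interval[1]
  post <- time > bleach_interval[2]
  if (!any(pre)) stop("input error: no pre-bleach baseline")
  if (sum(post) < 3) stop("input error: no recovery segment")
  f0 <- mean(intensity[pre])
  tr <- time[post] - bleach_interval[2]
  yr <- intensity[post] / f0
  if (method == "initial_slope") {
    win <- tr <= initial_fraction * max(tr)
    if (sum(win) < 2) win <- seq_len(max(2, sum(win)))
    rate <- unname(coef(lm(yr[win] ~ tr[win]))[2])
  } else {
    fit <- try(minpack.lm::nlsLM(yr ~ yinf - (yinf - y0) * exp(-tr / tau),
                                 start = list(yinf = max(yr), y0 = yr[1],
                                              tau = max(tr) / 3)),
               silent = TRUE)
    if (inherits(fit, "try-error")) stop("fit failure: exponential recovery fit")
    cf <- coef(fit)
    rate <- unname((cf["yinf"] - cf["y0"]) / cf["tau"])
  }
  out <- list(rate = rate, baseline = f0, method = method)
  if (!is.null(reference_rate))
    out$relative_percent <- 100 * rate / reference_rate
  out
}

#' Glutamate-sensor response profile from an uncaging linescan
#'
#' Averages the fluorescence profile over a pre-uncaging window (F0) and a
#' post-uncaging window (F) and returns the per-position relative change
#' `(F - F0) / F0`.
#'
#' @param scan A [linescan()].
#' @param pre_window (start, end) line indices of the baseline window.
#' @param post_window (start, end) line indices of the response window.
#' @return List with `position` (um), `profile` (dF/F0) and a logical `mask`
#'   of retained pixels (F0 > 0); masked-out pixels are NA with a warning.
#' @export
iglusnfr_profile <- function(scan, pre_window, post_window) {
  stopifnot(inherits(scan, "papsim_linescan"))
  if (!(pre_window[2] < post_window[1] || post_window[2] < pre_window[1]))
    stop("input error: pre and post windows must be disjoint")
  f0 <- colMeans(scan$intensity[pre_window[1]:pre_window[2], , drop = FALSE])
  f1 <- colMeans(scan$intensity[post_window[1]:post_window[2], , drop = FALSE])
  mask <- f0 > 0
  if (!any(mask)) stop("input error: baseline non-positive at every pixel")
  if (!all(mask))
    warning(sum(!mask), " pixel(s) masked (non-positive baseline)")
  profile <- rep(NA_real_, length(f0))
  profile[mask] <- (f1[mask] - f0[mask]) / f0[mask]
  list(position = (seq_along(f0) - 1) * scan$pixel_pitch,
       profile = profile, mask = mask)
}

#' Gaussian fit and FWHM of a spatial response profile
#'
#' Fits `a exp(-(x - xc)^2 / (2 sigma^2)) + b` with the centre fixed at the
#' uncaging spot (default) or free, and reports the full width at half
#' maximum `FWHM = 2 sqrt(2 ln 2) sigma`.
#'
#' @param position Positions, um.
#' @param profile Response values (single dominant peak).
#' @param center Spot position, um; ignored when `fix_center = FALSE`.
#' @param fix_center Keep the centre fixed at `center` (default TRUE).
#' @return List of class `papsim_gaussfit`: `center`, `sigma`, `amplitude`,
#'   `baseline`, `fwhm` (um), `converged`.
#' @export
fit_profile_fwhm <- function(position, profile, center = NULL,
                             fix_center = TRUE) {
  ok <- is.finite(profile)
  x <- position[ok]; y <- profile[ok]
  if (length(y) < 5 || diff(range(y)) <= 0)
    stop("fit failure: flat profile")
  if (is.null(center)) center <- x[which.max(y)]
  a0 <- max(y) - min(y)
  s0 <- max(sqrt(sum(pmax(y - min(y), 0) * (x - center)^2) /
                   sum(pmax(y - min(y), 0))), diff(range(x)) / 50)
  fit <- if (fix_center) {
    try(minpack.lm::nlsLM(y ~ a * exp(-(x - center)^2 / (2 * sigma^2)) + b,
                          start = list(a = a0, sigma = s0, b = min(y)),
                          lower = c(1e-12, 1e-9, -Inf)), silent = TRUE)
  } else {
    try(minpack.lm::nlsLM(y ~ a * exp(-(x - xc)^2 / (2 * sigma^2)) + b,
                          start = list(a = a0, xc = center, sigma = s0,
                                       b = min(y)),
                          lower = c(1e-12, -Inf, 1e-9, -Inf)), silent = TRUE)
  }
  if (inherits(fit, "try-error")) stop("fit failure: Gaussian profile fit")
  cf <- coef(fit)
  xc <- if (fix_center) center else unname(cf["xc"])
  sigma <- unname(cf["sigma"])
  out <- list(center = xc, sigma = sigma, amplitude = unname(cf["a"]),
              baseline = unname(cf["b"]),
              fwhm = 2 * sqrt(2 * log(2)) * sigma, converged = TRUE)
  class(out) <- "papsim_gaussfit"
  out
}

#' Ratiometric FRET sensor response
#'
#' Computes `R(t) = donor / acceptor` and the baseline-subtracted response
#' `dR(t) = R(t) - mean(R over the baseline window)`.
#'
#' @param donor Donor channel trace (e.g. ECFP).
#' @param acceptor Acceptor channel trace (e.g. Venus).
#' @param baseline Indices of the baseline samples (default: first 20%).
#' @param on_zero_acceptor "mask" (default) to drop such samples, or "error".
#' @return List with `r`, `dr` and the baseline ratio.
#' @export
ratiometric_response <- function(donor, acceptor,
                                 baseline = seq_len(max(1, floor(length(donor) / 5))),
                                 on_zero_acceptor = c("mask", "error")) {
  on_zero_acceptor <- match.arg(on_zero_acceptor)
  stopifnot(length(donor) == length(acceptor))
  bad <- acceptor <= 0
  if (any(bad)) {
    if (on_zero_acceptor == "error")
      stop("input error: non-positive acceptor samples")
    acceptor[bad] <- NA_real_
  }
  r <- donor / acceptor
  r0 <- mean(r[baseline], na.rm = TRUE)
  list(r = r, dr = r - r0, r0 = r0)
}
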