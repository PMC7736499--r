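# Two-pathway MK801 cross-talk quantification, release-statistics helpers
# and the spillover arithmetic (per-discharge activation probability,
# density-scaled nearest-neighbour distance, extracellular-space increase).

papsim_phases <- c("ampar_baseline", "nmdar_baseline", "mk801",
                   "silent_pause", "resumed")

#' Construct an EPSC amplitude series
#'
#' @param trial Trial index.
#' @param amplitude Response amplitude, pA (sign-normalized positive;
#'   inward currents are rectified).
#' @param pathway `"active"` or `"silent"` per trial.
#' @param phase Phase label per trial, one of `ampar_baseline`,
#'   `nmdar_baseline`, `mk801`, `silent_pause`, `resumed` (temporal order).
#' @export
epsc_series <- function(trial, amplitude, pathway, phase) {
  stopifnot(length(trial) == length(amplitude))
  amplitude <- abs(amplitude)
  pathway <- rep_len(as.character(pathway), length(amplitude))
  phase <- rep_len(as.character(phase), length(amplitude))
  if (!all(pathway %in% c("active", "silent")))
    stop("input error: pathway must be 'active' or 'silent'")
  if (!all(phase %in% papsim_phases))
    stop("input error: unknown phase label")
  ord <- match(phase, papsim_phases)
  if (is.unsorted(ord[order(trial)]))
    stop("input error: phases out of temporal order")
  out <- data.frame(trial = trial, amplitude = amplitude,
                    pathway = pathway, phase = phase)
  class(out) <- c("papsim_epsc", "data.frame")
  out
}

#' NMDAR cross-talk fraction from the silent pathway
#'
#' The percentage of silent-pathway NMDARs cross-activated (and hence
#' MK801-blocked) by discharges in the active pathway:
#' `100 (1 - mean(resumed) / mean(nmdar_baseline))`.
#'
#' @param series An [epsc_series()] (silent-pathway trials are used).
#' @param min_trials Minimum trials required in each phase.
#' @return Cross-talk, percent.
#' @export
crosstalk_fraction <- function(series, min_trials = 3) {
  s <- series[series$pathway == "silent", , drop = FALSE]
  base <- s$amplitude[s$phase == "nmdar_baseline"]
  res <- s$amplitude[s$phase == "resumed"]
  if (length(base) < min_trials || length(res) < min_trials)
    stop("input error: need >= ", min_trials,
         " trials in nmdar_baseline and resumed phases")
  if (mean(base) <= 0) stop("degenerate input: zero baseline mean")
  100 * (1 - mean(res) / mean(base))
}

#' Per-discharge activation probability from a cumulative fraction
#'
#' Under the independent-trials (compound) model, a cumulative activated
#' fraction `f` after `n` discharges implies a per-discharge probability `p`
#' solving `(1 - p)^n = 1 - f`.
#'
#' @param f Cumulative activated fraction in `[0, 1)`.
#' @param n Number of discharges (>= 1).
#' @return `p`, per-discharge probability.
#' @export
per_discharge_probability <- function(f, n) {
  if (any(f < 0 | f >= 1)) stop("input error: f must be in [0, 1)")
  if (any(n < 1)) stop("input error: n must be >= 1")
  1 - (1 - f)^(1 / n)
}

#' Nearest-neighbour distance after density subsampling
#'
#' Thinning a 3D point process to a fraction `p` of its points scales the
#' typical nearest-neighbour distance by `p^(-1/3)`.
#'
#' @param d0 Baseline nearest-neighbour distance, um.
#' @param p Retained fraction in `(0, 1]`.
#' @return Scaled distance, um.
#' @export
subsample_nn_distance <- function(d0, p) {
  if (any(d0 <= 0)) stop("input error: d0 must be positive")
  if (any(p <= 0 | p > 1)) stop("input error: p must be in (0, 1]")
  d0 * p^(-1 / 3)
}

#' Relative extracellular-space increase from a PAP volume-fraction decrease
#'
#' Tissue volume vacated by shrinking astroglial processes is gained by the
#' extracellular space: a relative PAP VF decrease `vf_decrease` of an
#' astroglial tissue fraction `vf_astro` increases an extracellular fraction
#' `ecs` by `(vf_decrease x vf_astro) / ecs` (relative).
#'
#' @param vf_astro Astroglial tissue volume fraction, e.g. 0.065.
#' @param vf_decrease Relative PAP VF decrease, e.g. 0.25.
#' @param ecs Extracellular space fraction, e.g. 0.175.
#' @return Relative ECS increase (fraction).
#' @export
ecs_increase <- function(vf_astro, vf_decrease, ecs) {
  stopifnot(vf_astro > 0, vf_astro < 1, vf_decrease >= 0, vf_decrease < 1)
  if (any(ecs <= 0)) stop("input error: ecs must be positive")
  (vf_decrease * vf_astro) / ecs
}

#' Paired-pulse facilitation
#'
#' @param a1,a2 First and second response amplitudes.
#' @return Facilitation, percent: `100 (a2 - a1) / a1`.
#' @export
paired_pulse_ratio <- function(a1, a2) {
  if (any(a1 <= 0)) stop("input error: first amplitude must be positive")
  100 * (a2 - a1) / a1
}

#' Inverse squared coefficient of variation
#'
#' `1/CV^2 = mean^2 / variance` (sample variance, denominator n-1). Under a
#' binomial release model with N sites and release probability p this
#' approaches `N p / (1 - p)`, independent of quantal size.
#'
#' @param amplitudes Trial amplitudes (>= 3, nonzero variance).
#' @return `1/CV^2`, or `NA` with a warning for zero variance.
#' @export
inv_cv_squared <- function(amplitudes) {
  if (length(amplitudes) < 3) stop("input error: need >= 3 trials")
  v <- var(amplitudes)
  if (v == 0) {
    warning("zero variance: 1/CV^2 undefined")
    return(NA_real_)
  }
  mean(amplitudes)^2 / v
}

#' MK801 use-dependent block rate
#'
#' Fits `A_k = A0 exp(-k / k0)` over trial number `k` within the MK801 phase
#' of the active pathway; `k0` (trials) indexes the release probability.
#'
#' @param series An [epsc_series()].
#' @param pathway Pathway to analyse (default `"active"`).
#' @param min_trials Minimum MK801-phase trials.
#' @return List with `k0`, its 95% CI, `a0`, `identifiable` (FALSE for
#'   non-decaying series, with `k0 = NA`).
#' @export
mk801_block_rate <- function(series, pathway = "active", min_trials = 5) {
  s <- series[series$pathway == pathway & series$phase == "mk801", ,
              drop = FALSE]
  if (nrow(s) < min_trials)
    stop("input error: need >= ", min_trials, " mk801-phase trials")
  k <- seq_len(nrow(s)) - 1
  a <- s$amplitude[order(s$trial)]
  # identifiable only if the log-linear decay is negative and significant
  lf <- suppressWarnings(summary(lm(log(pmax(a, 1e-12)) ~ k))$coefficients)
  sl <- unname(lf["k", "Estimate"])
  p_one_sided <- if (is.na(lf["k", "Pr(>|t|)"])) 1 else {
    if (sl < 0) lf["k", "Pr(>|t|)"] / 2 else 1
  }
  if (sl >= 0 || p_one_sided > 0.05) {
    return(list(k0 = NA_real_, k0_ci = c(NA_real_, NA_real_),
                a0 = mean(a), identifiable = FALSE))
  }
  fit <- try(minpack.lm::nlsLM(a ~ A0 * exp(-k / k0),
                               start = list(A0 = a[1], k0 = -1 / sl),
                               lower = c(1e-12, 1e-6)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(list(k0 = NA_real_, k0_ci = c(NA_real_, NA_real_),
                a0 = mean(a), identifiable = FALSE))
  }
  cf <- coef(fit)
  se <- summary(fit)$coefficients["k0", "Std. Error"]
  list(k0 = unname(cf["k0"]), k0_ci = unname(cf["k0"] + c(-1.96, 1.96) * se),
       a0 = unname(cf["A0"]), identifiable = TRUE)
}
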