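# Stochastic simulation of glutamate release, diffusion, transporter capture
# and extrasynaptic NMDAR activation.

#' Simulation configuration
#'
#' @param n_molecules Glutamate molecules released at the cleft centre
#'   (default 3000).
#' @param diffusion_coefficient Free diffusion coefficient, um^2/ms
#'   (default 0.4).
#' @param time_step Integration step in us. `NULL` selects the largest step
#'   satisfying `sqrt(6 D dt) <= gap_width / 4`, so narrow gaps are resolved.
#' @param total_time Simulated time, ms.
#' @param n_runs Ensemble size (default 32).
#' @param rng_seed Root seed; per-run child seeds are derived
#'   deterministically.
#' @param transporter_density Astroglial transporter surface density, um^-2.
#' @param bin_width Output bin width, ms.
#' @param probe_radius Radius (nm) beyond which free glutamate counts toward
#'   the extrasynaptic dwell readout.
#' @param binding_radius NMDAR reaction radius, nm.
#' @param p_bind Per-encounter-step NMDAR binding probability.
#' @export
sim_config <- function(n_molecules = 3000,
                       diffusion_coefficient = 0.4,
                       time_step = NULL,
                       total_time = 2,
                       n_runs = 32,
                       rng_seed = 1,
                       transporter_density = 7500,
                       bin_width = 0.02,
                       probe_radius = 150,
                       binding_radius = 6,
                       p_bind = 0.3) {
  stopifnot(n_molecules >= 0, diffusion_coefficient > 0, total_time > 0,
            n_runs >= 1, bin_width > 0, p_bind >= 0, p_bind <= 1)
  cfg <- list(n_molecules = as.integer(n_molecules),
              diffusion_coefficient = diffusion_coefficient,
              time_step = time_step,
              total_time = total_time,
              n_runs = as.integer(n_runs),
              rng_seed = as.integer(rng_seed),
              transporter_density = transporter_density,
              bin_width = bin_width,
              probe_radius = probe_radius,
              binding_radius = binding_radius,
              p_bind = p_bind)
  class(cfg) <- "papsim_sim_config"
  cfg
}

# resolve the time step (us) against the step-size invariant
resolve_time_step <- function(sim, model) {
  D_nm2_us <- sim$diffusion_coefficient * 1e3  # um^2/ms -> nm^2/us
  max_dt <- (model$gap_width / 4)^2 / (6 * D_nm2_us)
  dt <- if (is.null(sim$time_step)) max_dt else sim$time_step
  if (sqrt(6 * D_nm2_us * dt) > model$gap_width / 4 + 1e-9)
    stop("configuration error: rms step sqrt(6 D dt) exceeds gap_width / 4")
  dt
}

derive_seed <- function(root, k) (as.double(root) + 1000003 * k) %% 2147483629

#' Run one stochastic release simulation
#'
#' 3000 (by default) glutamate molecules are released at the cleft centre and
#' diffuse by Brownian steps (per-axis variance `2 D dt`); solid membranes
#' reflect; collisions with occupied astroglial membrane capture molecules
#' with a density-derived probability; captured molecules unbind or are taken
#' up per the transporter scheme; free molecules encountering an NMDAR within
#' the reaction radius bind with probability `p_bind`, driving the receptor
#' scheme.
#'
#' @param model A `papsim_geometry`.
#' @param transporters A `papsim_transporters` layout (or `NULL` for none).
#' @param receptors A `papsim_receptors` layout (or `NULL` for none).
#' @param schemes Scheme registry, see [default_schemes()].
#' @param sim A [sim_config()].
#' @param seed Seed for this run (defaults to `sim$rng_seed`).
#' @param snapshot_times Optional times (ms) at which molecule positions are
#'   recorded.
#' @return A `papsim_result` with per-bin counts (free, transporter-bound and
#'   cumulative uptake per sector, NMDAR state occupancies per sector),
#'   per-sector activation integrals and the seed used. The conservation
#'   invariant free + bound + taken-up = n_molecules holds at every bin.
#' @export
simulate_release <- function(model, transporters, receptors, schemes = default_schemes(),
                             sim = sim_config(), seed = sim$rng_seed,
                             snapshot_times = numeric(0)) {
  dt <- resolve_time_step(sim, model)
  rates <- scheme_rates(schemes)
  rates <- c(rates, p_bind = sim$p_bind, bind_radius = sim$binding_radius)

  patches <- if (is.null(transporters)) {
    matrix(numeric(0), ncol = 6)
  } else transporters$patches
  nsites <- if (is.null(transporters)) integer(4) else as.integer(transporters$counts)
  recm <- if (is.null(receptors) || nrow(receptors$positions) == 0) {
    matrix(numeric(0), ncol = 4)
  } else as.matrix(receptors$positions[, c("x", "y", "z", "sector")])

  cfg <- c(n_mol = sim$n_molecules,
           D = sim$diffusion_coefficient * 1e3,
           dt = dt,
           t_total = sim$total_time * 1e3,
           bin = max(sim$bin_width * 1e3, dt),
           probe = sim$probe_radius)

  raw <- cpp_sim_run(geom_vector(model), patches, nsites, recm, rates, cfg,
                     snapshot_times * 1e3, as.double(seed))

  rs <- raw$recstate
  # molecules held by receptors, per bin (1 per singly-, 2 per doubly-bound)
  rb <- integer(length(raw$free))
  for (s in 0:3)
    rb <- rb + rs[, 4 * s + 2] + 2L * (rs[, 4 * s + 3] + rs[, 4 * s + 4])

  out <- list(time = raw$time_ms / 1e3,   # ms
              free = raw$free,
              transporter_bound = raw$tbound,
              receptor_bound = rb,
              uptake = raw$uptake,
              receptor_states = rs,
              dwell = raw$dwell,
              open_integral = raw$open_integral,
              act_integral = raw$act_integral,
              peak_open = raw$peak_open,
              contact_any = raw$contact_any,
              contact_multi = raw$contact_multi,
              snapshots = raw$snapshots,
              n_molecules = sim$n_molecules,
              time_step = dt,
              rng_seed = seed)
  class(out) <- "papsim_result"
  total <- out$free + rowSums(out$transporter_bound) + out$receptor_bound +
    rowSums(out$uptake)
  if (any(total != sim$n_molecules))
    stop("internal error: molecule conservation violated")
  out
}

#' Run an ensemble of simulations
#'
#' @inheritParams simulate_release
#' @return List of `papsim_result`, one per run, with deterministic child
#'   seeds derived from `sim$rng_seed`.
#' @export
simulate_ensemble <- function(model, transporters, receptors,
                              schemes = default_schemes(), sim = sim_config()) {
  lapply(seq_len(sim$n_runs), function(k) {
    simulate_release(model, transporters, receptors, schemes, sim,
                     seed = derive_seed(sim$rng_seed, k))
  })
}

#' Summarise NMDAR activation and transporter capture over an ensemble
#'
#' @param results List of `papsim_result` runs.
#' @return A `papsim_activation` data.frame, one row per sector: mean and sd
#'   over runs of the peak open-receptor count, time-integrated open and
#'   doubly-bound ("activated") receptor occupancy (ms x receptors), the
#'   transporter capture (uptake) fraction, and the mean extrasynaptic dwell
#'   count beyond the probe radius.
#' @export
summarize_activation <- function(results) {
  if (inherits(results, "papsim_result")) results <- list(results)
  if (!length(results)) stop("input error: empty ensemble")
  n <- results[[1]]$n_molecules
  per_run <- function(f) t(vapply(results, f, numeric(4)))
  peak <- per_run(function(r) as.numeric(r$peak_open))
  op <- per_run(function(r) r$open_integral)
  act <- per_run(function(r) r$act_integral)
  cap <- per_run(function(r) {
    u <- r$uptake[nrow(r$uptake), ]
    if (n > 0) u / n else rep(0, 4)
  })
  dwell <- vapply(results, function(r) mean(r$dwell), numeric(1))
  out <- data.frame(
    sector = 1:4,
    peak_open_mean = colMeans(peak), peak_open_sd = apply(peak, 2, sd),
    open_integral_mean = colMeans(op), open_integral_sd = apply(op, 2, sd),
    act_integral_mean = colMeans(act), act_integral_sd = apply(act, 2, sd),
    capture_fraction_mean = colMeans(cap),
    capture_fraction_sd = apply(cap, 2, sd))
  attr(out, "n_runs") <- length(results)
  attr(out, "dwell_mean") <- mean(dwell)
  attr(out, "per_run_act") <- act
  attr(out, "per_run_open") <- op
  class(out) <- c("papsim_activation", "data.frame")
  out
}

#' Compare the four astroglial coverage scenarios in one simulation set
#'
#' Each scenario occupies one azimuthal sector of the same simulated
#' environment, so all four are probed by the same glutamate release (shared
#' random stream), as well as a matched transporter-free ensemble. A
#' sector-interaction diagnostic (fraction of membrane-contacting molecules
#' that touch more than one sector) is reported; if it exceeds `exchange_tol`
#' the comparison is returned with a warning flag.
#'
#' @param model A `papsim_geometry`.
#' @param sim A [sim_config()].
#' @param schemes Scheme registry.
#' @param scenarios Character vector of 4 scenario ids assigned to sectors
#'   1-4.
#' @param n_receptors Receptors per sector cluster.
#' @param exchange_tol Tolerance on the sector-interaction diagnostic.
#' @param include_none Also run the matched transporter-free ensemble.
#' @return A `papsim_comparison` list: `table` (one row per scenario),
#'   `diagnostic`, `warning_flag`, and the underlying summaries.
#' @export
compare_scenarios <- function(model, sim = sim_config(),
                              schemes = default_schemes(),
                              scenarios = c("baseline", "i", "ii", "iii"),
                              n_receptors = 20, exchange_tol = 0.25,
                              include_none = TRUE) {
  stopifnot(length(scenarios) == 4)
  receptors <- place_nmdars(model, n_receptors = n_receptors,
                            seed = sim$rng_seed)
  transporters <- place_transporters(model, as.list(scenarios),
                                     surface_density = sim$transporter_density,
                                     seed = sim$rng_seed, nmdar_side = "+u")
  runs <- simulate_ensemble(model, transporters, receptors, schemes, sim)
  summ <- summarize_activation(runs)

  exch <- vapply(runs, function(r) {
    if (r$contact_any > 0) r$contact_multi / r$contact_any else 0
  }, numeric(1))
  diagnostic <- mean(exch)
  warn <- diagnostic > exchange_tol
  if (warn)
    warning(sprintf("sector interaction diagnostic %.2f exceeds tolerance %.2f",
                    diagnostic, exchange_tol))

  tab <- cbind(scenario = scenarios, summ)

  none_summ <- NULL
  if (include_none) {
    none_runs <- simulate_ensemble(model, NULL, receptors, schemes, sim)
    none_summ <- summarize_activation(none_runs)
  }
  out <- list(table = tab, diagnostic = diagnostic, warning_flag = warn,
              none = none_summ, n_runs = sim$n_runs)
  class(out) <- "papsim_comparison"
  out
}

#' @export
print.papsim_comparison <- function(x, ...) {
  cat(sprintf("Scenario comparison over %d runs (sector-interaction %.2f%s)\n",
              x$n_runs, x$diagnostic,
              if (x$warning_flag) ", above tolerance" else ""))
  print(x$table[, c("scenario", "act_integral_mean", "act_integral_sd",
                    "open_integral_mean", "capture_fraction_mean")],
        row.names = FALSE)
  if (!is.null(x$none))
    cat(sprintf("Transporter-free reference activation: %.3f ms x receptors\n",
                mean(x$none$act_integral_mean)))
  invisible(x)
}

#' Free Brownian diffusion from a point source
#'
#' Obstacle-free reference simulation used for the Einstein-relation and
#' Gaussian-spread diagnostics.
#'
#' @param n Number of molecules.
#' @param D Diffusion coefficient, um^2/ms.
#' @param dt Time step, us.
#' @param times Times (ms) at which positions are recorded.
#' @param seed RNG seed.
#' @return List of n x 3 position matrices (nm), one per requested time.
#' @export
simulate_free_diffusion <- function(n, D = 0.4, dt = 0.5, times = 0.05,
                                    seed = 1) {
  steps <- as.integer(round(times * 1e3 / dt))
  stopifnot(all(steps >= 1))
  out <- cpp_free_diffusion(as.integer(n), D * 1e3, dt, steps,
                            as.double(seed))
  names(out) <- as.character(times)
  out
}
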