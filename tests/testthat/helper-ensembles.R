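# Shared, lazily computed simulation fixtures. The scenario ensembles are the
# expensive part of the suite; several tests interrogate the same runs.

.papsim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .papsim_cache))
    assign(key, force(expr), envir = .papsim_cache)
  get(key, envir = .papsim_cache)
}

test_geometry <- function() {
  cached("geometry", build_geometry(voxel_pitch = 10))
}

# reduced-scale study ensemble: per-sector scenarios baseline/i/ii/iii plus a
# matched transporter-free ensemble, 32 runs
scenario_ensembles <- function() {
  cached("scenarios", {
    m <- test_geometry()
    sim <- sim_config(n_molecules = 600, total_time = 1, n_runs = 32,
                      rng_seed = 11)
    suppressWarnings(compare_scenarios(m, sim, n_receptors = 20))
  })
}
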