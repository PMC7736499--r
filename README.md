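# papsim

Perisynaptic astroglial processes (PAPs) express high-affinity glutamate
transporters (GLT1/EAAT type) that keep the action of synaptically released
glutamate local. When PAPs withdraw from a potentiated synapse — as they do
after LTP induction at hippocampal CA3–CA1 synapses — glutamate escapes
further, activating extrasynaptic NMDA receptors and neighbouring synapses.
`papsim` is an R package for scientists studying this regime. It provides:

* **A stochastic 3D simulator** of glutamate release, Brownian diffusion,
  transporter capture and extrasynaptic NMDAR activation in a reconstructed
  synaptic environment: truncated pre/postsynaptic hemispheres with a
  300 × 20 nm apposition zone and 200 nm cleft, surrounded by 20–30 nm
  extracellular gaps calibrated to an extracellular volume fraction
  α ≈ 0.15. Four astroglial coverage scenarios (baseline; withdrawal with
  conserved transporter number; withdrawal with transporter loss; lateral
  rearrangement) occupy the four sectors of one environment and are probed
  by the same 3000-molecule release, in 32-run ensembles.
* **Quantification routines** for the measurements that surround such
  experiments: the somatic-normalized PAP volume-fraction (VF) readout and
  its exponential decay `VF(t) = VF_ss + (1 − VF_ss)·exp(−t/τ)`; FRAP
  recovery rates; point-source effective diffusivity via Gaussian variance
  regression (`w = D_eff·t`); glutamate-sensor (iGluSnFR-style) ΔF/F₀
  linescan profiles with Gaussian FWHM (`2√(2 ln 2)·σ`); ratiometric FRET
  responses; 3D nearest-neighbour distance densities for
  bassoon/Homer1/GLT1 localizations; the 20 nm proximity rule and direct
  FWHM line-profile widths; concentric-shell (100 nm, 0–0.5 µm) astroglial
  VF profiles around PSDs; two-pathway MK801 cross-talk statistics
  (cross-talk fraction, 1/CV², use-dependent block rate) and the spillover
  arithmetic (compound per-discharge probability `p = 1 − (1 − f)^{1/n}`,
  `p^{−1/3}` distance rescaling, ECS-increase estimate).
* **Seeded synthetic-data generators** for every input the analyses consume,
  each serializing its generating truth, so the whole pipeline is testable
  without any external data.

## Worked example

```r
library(papsim)

model <- build_geometry(geometry_config(voxel_pitch = 5))
model
#> Synaptic environment geometry
#>   apposition 300 x 20 nm, cleft 200 nm, gaps 25 nm
#>   packing: cubic obstacle lattice, pitch 600 nm, side 575 nm, 3x3x4 cells, central 1x1x2 vacated
#>   extracellular volume fraction: 0.1524 (voxel pitch 5 nm)
#>   astroglial membrane per sector: 0.220 um^2

sim <- sim_config(n_molecules = 600, total_time = 1, n_runs = 8, rng_seed = 1)
compare_scenarios(model, sim, n_receptors = 20)
#> Scenario comparison over 8 runs (sector-interaction 0.39, above tolerance)
#>  scenario act_integral_mean act_integral_sd open_integral_mean capture_fraction_mean
#>  baseline              5.41            1.29               0.95                 0.060
#>         i              8.57            1.00               1.30                 0.038
#>        ii              6.66            1.50               1.48                 0.054
#>       iii              4.17            1.27               0.70                 0.050
#> Transporter-free reference activation: 13.965 ms x receptors
```

The activation integral is the time-integrated count of doubly-liganded
extrasynaptic NMDARs (ms × receptors) in each sector's 200–250 nm cluster.
In this reduced-scale run, PAP withdrawal with a conserved transporter
complement (scenario i) boosts remote activation the most among the
perturbed configurations, while removing all transporters (the reference,
13.97) bounds every scenario from above — the buffering-versus-uptake
behaviour discussed in the methods vignette. The sector-interaction figure
quantifies molecule exchange between sectors of the shared cavity; it is
reported, and flagged, rather than hidden.

The desk arithmetic behind the spillover interpretation:

```r
subsample_nn_distance(0.5, 0.02)            # 1.842016  (um between 2% of synapses)
100 * per_discharge_probability(0.40, 120)  # 0.4247833 (% per discharge)
100 * ecs_increase(0.065, 0.25, 0.175)      # 9.285714  (% ECS increase)
```

Analysis of synthetic measurements follows the same pattern everywhere:
generate with a known truth, analyze, compare:

```r
trace <- gen_vf_trace(vf_ss = 0.77, tau = 14, noise_sd = 0.02, seed = 4)
fit_vf_decay(trace$time, trace$vf)[c("vf_ss", "tau")]
#> $vf_ss [1] 0.7727971
#> $tau   [1] 15.68496
```

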