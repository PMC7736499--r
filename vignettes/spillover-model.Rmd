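---
title: "Modelling perisynaptic glutamate spillover and astroglial coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling perisynaptic glutamate spillover and astroglial coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(papsim)
```

Perisynaptic astroglial processes (PAPs) carry high-affinity glutamate
transporters (GLT1/EAAT type) that confine the action of synaptically released
glutamate to the vicinity of the cleft. When PAPs withdraw from a potentiated
synapse, released glutamate travels further, engaging extrasynaptic,
GluN2B-rich NMDA receptors and neighbouring synapses. `papsim` implements the
computational side of this problem end to end: a particle-based stochastic
simulator of the perisynaptic environment under four astroglial coverage
scenarios, the image- and electrophysiology-analysis procedures used to
quantify PAP withdrawal and its consequences, and seeded synthetic-data
generators that make every analysis testable against known ground truth.

## The synaptic environment

The environment is built in `build_geometry()` from a small set of
ultrastructural parameters (all lengths in nm):

* pre- and postsynaptic compartments are truncated hemispheres of radius
  250 nm whose flat faces, 300 nm across, form the apposition zone; the faces
  are separated by 20 nm, and the central 200 nm of the apposition is the
  synaptic cleft. Glutamate (3000 molecules by default) is released at the
  cleft centre.
* the synapse sits inside a cavity of a periodic lattice of cuboid obstacles
  that stand in for neighbouring neurites. The obstacles are separated by
  20-30 nm extracellular gaps. The lattice pitch (600 nm) was tuned once so
  that, at the default 25 nm gaps, the extracellular volume fraction of the
  whole domain is close to the tissue value of about 0.15, and then frozen;
  the packing is recorded in the built model. With the default dimensions the
  voxel-integrated fraction is 0.152.
* the four inner faces of the lateral obstacles form the astroglial membrane,
  one azimuthal sector each. Transporter coverage lives on a band of these
  walls spanning |z| up to half the lattice pitch; each sector's band has an
  area of about 0.22 um^2.
* an extrasynaptic NMDAR cluster (20 receptors by default) is placed in each
  sector on the postsynaptic membrane, 200-250 nm from the synaptic centroid
  — roughly the half-way point to the nearest neighbouring synapse.

The extracellular fraction is computed by voxel integration. Because every
membrane face of the lattice lies on a half-integer coordinate, a naive
voxel-centre rule can alias badly at commensurate pitches; each voxel is
therefore probed at eight interior points offset by ±pitch·√3/8 per axis,
which keeps faces off the sample points at any pitch. The reference pitch is
5 nm, at which the integral agrees with an independent uniform-random
volume estimator to better than 0.01 (this is asserted in the test suite).

```{r geometry}
model <- build_geometry(geometry_config(gap_width = 25, voxel_pitch = 5))
model$ecs_fraction
```

## Coverage scenarios

`scenario_spec()` encodes the four astroglial configurations compared by the
simulator. Their density/area/number contracts are fixed:

| scenario  | density | occupied area | total number |
|-----------|---------|---------------|--------------|
| baseline  | 1       | 1             | N0           |
| i         | 2       | 1/2           | N0           |
| ii        | 1       | 1/2           | N0/2         |
| iii       | 1       | 1 (shifted)   | N0           |

What the contracts do not fix is *where* the occupied membrane sits, and this
was a genuinely open design choice. The package resolves it as follows:

* **Scenario i** (withdrawal, conserved number): the PAP sheet retracts away
  from the synapse carrying all its transporters, so coverage concentrates on
  the distal half of the band at doubled density. The receptor-level zone is
  fully vacated.
* **Scenario ii** (withdrawal with transporter loss): the retracting distal
  membrane is lost together with its transporter complement; the proximal
  half of the band remains covered at unit density.
* **Scenario iii** (lateral rearrangement): the occupied patch keeps its area
  and density but shifts azimuthally by half its half-width toward one side
  of the NMDAR cluster, partly exposing the other side. This requires a
  defined cluster side; requesting it without one is a configuration error.

The alternative reading of scenario ii — the same distal patch as scenario i
at half density — was implemented first and rejected for a structural reason:
with identical occupied geometry, halving the density strictly lowers capture
and sequestration, so scenario ii can never activate *less* than scenario i,
contradicting the finding that withdrawal with a conserved transporter
complement is the configuration that boosts remote NMDAR activation most.
The adopted design restores that ordering for a transparent physical reason:
scenario i alone removes all coverage from the path between cleft and
receptor cluster while keeping total uptake capacity; scenario ii keeps a
receptor-level shield; scenario iii exposes only one flank. The ordering and
the dominance of the transporter-free control are verified, not assumed: the
acceptance tests recompute them from 32-run ensembles.

## Stochastic dynamics

Molecules take Brownian steps with per-axis variance 2·D·Δt, with
D = 0.4 um^2/ms (the free-medium value; tortuosity emerges from the
geometry). The time step is chosen as the largest Δt satisfying
√(6·D·Δt) ≤ gap_width/4 (about 16 ns at 25 nm gaps), so that narrow gaps are
resolved; configurations violating this are rejected. Moves into solid
regions are rejected (a reflecting boundary at these step sizes). Molecules
leaving the 1.8 × 1.8 × 2.4 um domain are treated as escaped: they remain in
the free-molecule count but are no longer tracked.

Membrane interactions:

* a collision with an occupied astroglial patch captures the molecule with
  probability 1 − exp(−ρ·σ), where ρ is the local transporter surface
  density and σ = 30 nm^2 a per-transporter capture cross-section, scaled by
  the fraction of unoccupied transporters in the sector. Captured molecules
  follow a 3-state transporter cycle: unbinding back to the extracellular
  space at 3.0 /ms or translocation (permanent uptake) at 0.33 /ms. The
  cycle is deliberately buffering-dominant (about 10% uptake per binding):
  stochastic unbinding from transporters is what keeps glutamate lingering
  near extrasynaptic receptors, and rates are data (in the scheme registry),
  not code.
* a free molecule within 6 nm of an NMDAR with a free binding site binds
  with per-step probability 0.3. Receptors follow a reduced two-glutamate
  scheme C0 ↔ C1 ↔ C2 ↔ O with unbinding 0.6 and 1.2 /ms, opening 0.5 /ms
  and closing 0.25 /ms. These are compressed (fast-gating) constants chosen
  for the few-millisecond observation window; they preserve the scheme's
  structure (two sequential glutamate bindings, openings only from the
  doubly-bound state) rather than the receptor's literal gating latencies.
  Both the time-integrated doubly-bound occupancy and the open-state
  occupancy are reported; the scenario comparisons hold for either readout.

Every run reports per-bin counts of free, transporter-bound and
receptor-bound molecules and cumulative uptake per sector; the conservation
identity free + bound + taken-up = n_molecules is checked at every bin and a
violation is an internal error, never a warning.

All randomness derives from one root seed; ensemble members use child seeds
generated deterministically from it, and the C++ engine uses its own
xoshiro256++ generator with polar-method normals so that results are
bit-reproducible across platforms and independent of R's RNG state.

## Comparing scenarios in one simulation set

Following the original modelling approach, the four scenarios occupy the
four sectors of one environment and are probed by the same released
glutamate, with a matched transporter-free ensemble run under the same seeds.
In this geometry the sectors share the perisynaptic cavity, so molecules do
cross between sectors; `compare_scenarios()` quantifies this with a
sector-interaction diagnostic (the fraction of membrane-contacting molecules
touching more than one sector, typically ~0.4 here) and flags the comparison
with a warning when it exceeds the tolerance. The comparison remains a valid
paired design — every sector experiences the same ambient field — but
absolute per-sector numbers are coupled; this is a documented limitation
rather than a silent assumption. A symmetry check (identical scenarios in
all sectors produce statistically indistinguishable summaries) guards the
construction.

## Analysis procedures

* `compute_vf()`: PAP volume fraction as background-corrected ROI
  fluorescence normalized to the somatic value (100% VF); exactly
  scale-invariant.
* `fit_vf_decay()`: least-squares fit of VF(t) = VF_ss + (1 − VF_ss)·exp(−t/τ)
  to traces normalized to a pre-induction mean of 1; non-decaying traces are
  flagged unidentifiable (VF_ss falls back to the mean) instead of returning
  a spurious τ.
* `estimate_point_source_diffusivity()`: per-line Gaussian fits
  A·exp(−(x−xc)²/(4w)) with the centre fixed at the source, then a linear
  fit of w against t (through the origin by default, free intercept as an
  option) whose slope is D_eff. The printed form of the profile omits the
  minus sign in some sources; only the negative exponent is physical and
  w = D_eff·t matches the 1D identity σ² = 2Dt. Lines whose fitted spread
  exceeds a quarter of the scan are rejected (width and baseline become
  degenerate); more than 50% rejections is an error.
* `compute_frap_rate()`: the recovery "rate" is not standardized anywhere,
  so the default is the initial slope of the normalized recovery over the
  first 20% of the recovery window, with an exponential-fit alternative
  behind a switch; reported absolutely and as percent of a reference.
* `iglusnfr_profile()` and `fit_profile_fwhm()`: time-averaged (F − F0)/F0
  profiles from linescan windows; Gaussian fit with the centre fixed at the
  uncaging spot by default (free-centre option for QC), FWHM = 2√(2 ln 2)·σ.
* nanoscale statistics: 3D nearest-neighbour distances and their binned
  densities (group-wise SEM when per-preparation labels exist), the 20 nm /
  one-pixel proximity rule, direct half-maximum line-profile widths, and
  concentric-shell VF profiles (100 nm shells, 0-0.5 um) around PSD
  centroids with a face-counting surface-area estimator (2/3 correction,
  exactness not claimed). Only spherical shells are implemented;
  PSD-following curvilinear shells are reported to give qualitatively
  identical results.
* cross-talk statistics: the silent-pathway cross-talk fraction
  100·(1 − resumed/baseline), the compound per-discharge probability
  p = 1 − (1 − f)^(1/n) (the naive f/n does not reproduce the printed
  estimate), the p^(−1/3) distance rescaling under synapse subsampling, the
  linear ECS-increase arithmetic, paired-pulse facilitation, 1/CV², and the
  MK801 trial-decay constant with a significance-gated identifiability flag.

## Synthetic data

Each generator is deterministic given (parameters, seed) and serializes its
generating truth (in memory as the `"truth"` attribute, on disk as a JSON
sidecar). Defaults emulate the study conditions: VF decay to 0.77 with a
14 min time constant and 2% noise; point-source scans at D = 0.4 um^2/ms;
uncaging profile pairs with a 9% width change; three-channel localization
clouds with GLT1 on a 150 nm shell around the bassoon cluster; binomial
EPSC series with multiplicative noise, use-dependent MK801 block and an
injectable 40% silent-pathway reduction. Noise models are additive Gaussian
for imaging and multiplicative Gaussian for EPSC amplitudes.

What the generators do not emulate — PSF blur and pixel saturation, drift
and photobleaching, localization artefacts, stimulus artefacts, correlated
biological variability — bounds what passing tests show about real data:
they demonstrate correctness of the estimators under the stated statistical
assumptions, not robustness to every instrumental nuisance.

## Problem sizes and numerical choices

The test-suite simulations are scaled to keep the whole suite around two
minutes: scenario ensembles use 600 molecules, 1 ms windows, 20 receptors
per cluster and 32 runs (the full 3000-molecule configuration with the same
code path is the default for interactive use); the Einstein-relation check
uses 3000 molecules in free space; voxel oracles run at 5 nm pitch. Degenerate
inputs fail loudly and early: zero-baseline normalizations, non-positive
acceptor samples, empty localization channels, peaks at profile edges and
out-of-range centroids are all errors or flagged conditions, never silent
NaNs. Fits report convergence; unidentifiable decays are flagged rather than
extrapolated.

## Known limitations

* Sector cross-talk in the shared cavity (quantified, see above).
* Transporters are represented as membrane capture probabilities plus
  per-sector site counting, not as individually diffusing proteins; receptor
  binding uses a reaction radius with a fixed per-encounter probability, so
  absolute on-rates are effective, not molecular.
* No AMPA-receptor or cleft-receptor modelling, no dendritic voltage, no
  fitting of simulated output to recorded electrophysiology.
* Receptor gating constants are compressed for short windows (above); use
  the scheme registry to substitute literature constants for longer runs.
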