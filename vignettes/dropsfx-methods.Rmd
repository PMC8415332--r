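---
title: "dropsfx methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dropsfx methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropsfx)
```

# Scope

`dropsfx` analyses drop-on-demand serial femtosecond crystallography (SFX)
data: 10 Hz streams of detector frames produced by shooting picoliter
crystal-slurry drops through a pulsed X-ray beam. Because no public
deposition exists for this kind of beamtime, the package ships its own
synthetic-data generator with complete ground truth (event tables, crystal
orientations, true peak positions and intensities); every statistical
claim the package makes is validated against that ground truth. The
generator is first-class, tested code, not a test fixture.

Auto-indexing (orientation search) is deliberately out of scope:
production experiments delegate it to dedicated programs (MOSFLM, DirAx,
XDS, XGANDALF via CrystFEL). What *is* in scope is the validation step
those experiments perform around indexing — predicting spot positions
from a known cell and orientation and checking them against found peaks —
because that step, not the orientation search, carries the
cross-contamination conclusion. Orientations therefore come from
simulator ground truth or an external solutions table.

# Geometry

A single flat panel normal to the beam. With sample-to-detector distance
$D$, pixel pitch $p$, and radial offset $\rho$ from the beam center,

$$2\theta = \arctan(\rho / D), \qquad d = \frac{\lambda}{2\sin\theta},
\qquad \lambda = \frac{hc}{E},\; hc = 12.398419\ \mathrm{keV\,\mathring A}.$$

At the beam center $d$ diverges; `pixel_to_d()` returns `Inf` there and
shell binning treats it as out of range. The inverse,
`d_to_ring_radius()`, errors for $d \le \lambda/2$ (no such reflection)
and for $2\theta \ge 90^\circ$ (never intersects a flat panel).

The default geometry — 480 × 480 pixels of 354 µm at 100 mm, 9.28 keV —
is **synthetic**: it emulates an 8×8-binned large-area CCD whose edge
reaches about 2 Å, but no distance or pitch is prescribed by any
experiment, so these are configuration values. Pixels are 0-based,
(fast, slow), centers at integer coordinates, fractional beam center
allowed.

# The synthetic-data generator

## What it emulates

* **Poisson occupancy.** The crystal count per probed event is Poisson
  with mean $\lambda = c \cdot V_\text{probed}$, where $V_\text{probed} =
  f_\text{int} \cdot \frac{\pi}{6} d_\text{drop}^3$. The beam focus is far
  smaller than an 80 µm drop, so only a fraction
  $f_\text{int}$ (`interaction_fraction`, default 0.02) of the drop is
  probed. At the 400 crystals nl⁻¹ slurries this gives $\lambda \approx
  2.1$ — high hit rates with frequent multi-crystal patterns — while the
  40–50 crystals nl⁻¹ slurries give $\lambda \approx 0.24$ and low hit
  rates, the two regimes such experiments actually report. The 0.02
  default was chosen once on this physical argument; it is the single
  free parameter linking concentration to hit rate and is exposed in
  both the simulator and the budget module.
* **Diffraction.** Reflections of a crystal with reciprocal basis $B$ and
  orientation $R$ are the lattice vectors $q = RBh$ with $|q| \le
  1/d_\text{min}$ whose excitation error $\left||q + k_0| - |k_0|\right|$
  ($|k_0| = 1/\lambda$) is at most `excitation_tol`. The tolerance
  (default 2×10⁻⁴ Å⁻¹) collapses bandwidth, mosaicity and partiality into
  one number; with the default tetragonal 57.8/57.8/150.1 Å cell it
  yields on the order of 100–150 in-frame reflections per crystal,
  matching the tens-to-hundreds of peaks per hit seen in practice.
* **Intensities.** Expected photons per reflection follow
  $I_0 \exp(-B/2d^2)$ — a Debye–Waller-like single-parameter falloff
  (defaults $I_0 = 400$ photons, $B = 15$ Å²). Peaks are rasterized as
  isotropic 2D Gaussians (σ = 1 px) whose discretized pixel weights are
  normalized to sum to one, so the integrated photon mass is exact.
* **Nuisance structure.** Diffuse background (10 photons/pixel), powder
  rings from the Cu shielding at 2.09 and 1.81 Å as Gaussian annuli,
  blank frames from missed drops (`miss_probability`, default 0.08),
  buffer-only frames after `depletion_time_s` (buffer is loaded before
  sample, so runs end in a crystal-free tail), and Poisson photon noise
  converted to ADU by a gain of 5.
* **Unit cells.** The four bundled sample models (thaumatin,
  proteinase K, xylanase, alcohol dehydrogenase) carry literature-typical
  *synthetic* cells; such beamtimes do not publish their refined cells,
  so these are labeled configuration, not ground truth.

## What it does not emulate

Crystal-size distributions (a single intensity scale stands in),
mosaic-block structure, detector point-spread and saturation, polarization
and solid-angle corrections, fluid-dynamic drop tails, and nozzle-drift
time structure beyond an optional miss-probability ramp. Passing tests
therefore demonstrate the *statistical* machinery — peak finding, rate
accounting, profile scaling — on data whose structure is known, not
detector-level realism.

# Peak finding

The hit-finding criteria are the standard recipe: pixels ≥ 100 ADU,
components of ≥ 2 pixels, SNR ≥ 7, ≥ 15 peaks per hit. Two details are
not fixed by that recipe and are explicit package choices:

* **SNR estimator.** The recipe names a threshold but not an estimator.
  We use integrated background-subtracted intensity over
  $\hat\sigma_\text{bg}\sqrt{n_\text{pix}}$, with the background median
  and robust sigma (1.4826 × MAD) taken from a local annulus (default
  radii 3–6 px, ≥ 10 unmasked pixels required, otherwise the peak is
  rejected). A zero-noise annulus yields infinite SNR, which passes any
  threshold — the right limit for noise-free synthetic frames.
* **Connectivity.** 8-connectivity by default: with a 2-pixel minimum,
  diagonal fragments of one small peak must merge. 4-connectivity is
  selectable. The labeler is a sparse union-find over above-threshold
  pixels (deterministic smallest-index roots); a test cross-checks it
  against an independent image-processing implementation.

Peak lists are sorted by descending intensity with ties broken by (slow,
fast) ascending, making outputs byte-reproducible. Ring masks should be
wider than the rings they cover: the pipeline default half-width is 8 px,
four times the simulated ring σ, because a mask that clips a ring's tails
leaves threshold-crossing shoulders that generate spurious peaks — the
in-package analogue of masking "until the rings stop contributing".

# Misindexing audit

`match_fraction()` matches predicted to observed spots greedily,
predictions in decreasing-d order, each observed peak consumed at most
once (deterministic and permutation-invariant). An indexing solution is
*supported* when the matched fraction reaches `support_fraction`
(default 0.5, with `position_tolerance` = 3 px — the integration radius).
The audit scores every event against every candidate cell; an event
supported only by a foreign cell would indicate cross-contamination. The
0.5 threshold operationalizes "most predicted spots do not match actual
peaks"; it is a free parameter, and both it and the tolerance are
documented knobs rather than measured values.

Spot integration uses the 3/4/5 px disc/annulus scheme:
$\sum_\text{disc} - n_\text{disc}\cdot\overline{\text{annulus}}$, masked
pixels excluded from both regions; a fully masked annulus yields `NA`.

# Rates

* **Hit rate** = 100 × hits / patterns collected.
* **Crystal-level indexing rate** = 100 × indexed crystals (correct
  cell) / hits. Multi-crystal patterns count each lattice, so the rate
  may exceed 100%.
* **Event-level indexing rate** (time-binned series) = 100 × hits with
  ≥ 1 indexed lattice of any cell / hits in the bin; multi-crystal hits
  count once. Event-level never exceeds crystal-level.
* Rates are kept at full precision internally; display rounding is one
  decimal, half away from zero (271/1083 → 25.0). Zero-hit runs report a
  rate of 0 with an `undefined` flag — tables print 0, code can tell.
* Binned series anchor bin edges at the first run's first event and lay
  bins over the concatenated wall-clock timeline; inter-run gaps (e.g. a
  139 s wash) produce *flagged empty* bins, never zeros, and overlapping
  run intervals are a validation error. Total pattern counts are data,
  never derived from duration × rate: published run tables do not
  guarantee the product matches the printed rate denominator.

# Radial profiles

Per hit: mean Bragg intensity in resolution shells. "Uniformly divided
resolution shells" is interpreted as uniform in $q = 1/d$ (equal
reciprocal-space thickness, the crystallographic norm); uniform-in-d is
selectable. Default: 30 shells over $d \in (2, 20]$ Å, covering the
useful resolution range of the default geometry down to its ~2 Å edge.

Each per-image profile is scaled to a reference by the closed-form L2
minimizer over co-occupied shells, $s^* = \sum p_i r_i / \sum p_i^2$;
images with no co-occupied shell (or an all-zero profile) are unscalable
and skipped. The run profile is the shell-wise mean of scaled profiles
over the images occupying each shell, then divided by its mean over
occupied shells so that mean is exactly 1. Normalization is over
*occupied* shells only — unoccupied shells have no value to include. The
reference is the first hit (as quality-monitoring pipelines do, keeping
the anchor independent of later drift); because a sparse first hit is a
noisy anchor, a shell-wise median reference is offered and a warning
fires when the first hit occupies under a third of the shells.

`compare_runs()` reports $|a-b| / \frac{a+b}{2}$ per co-occupied shell
with $d \ge$ 2 Å plus the maximum. Since run profiles are mean-1
normalized, global intensity scale cancels and only shape differences
remain; a b-factor increase depresses the high-resolution end and is
detected, while same-condition runs differ only by sampling noise. The
package's damage test simulates two same-condition runs (different
seeds) and one with a 50% higher b-factor at ≥ 500 hits each, asserting
the noise-level difference stays below 0.1 and the degraded run exceeds
it.

# Sample budget

Sphere volume $\pi/6 \cdot d^3$ (80 µm → 268.1 pl; the often-quoted
"250 pl" corresponds to 78.2 µm), consumption = volume × frequency
(250 pl at 60 Hz → 0.9 µl min⁻¹; 18 µl min⁻¹ at the 1.2 kHz recycling
frequency), Poisson hit probability $1 - e^{-\lambda}$, multi-crystal
probability $P(N\ge2 \mid N\ge1)$, and the inverse estimator
$\hat c = -\ln(1 - p)/V_\text{probed}$ with an optional blank-drop
(miss) correction that divides the observed rate by $1 -
p_\text{miss}$ first. The estimator is exercised as a parameter-recovery
test: 50 runs of 1000 events at $\lambda = 1$, median within two
standard errors of its own sampling distribution.

# Numerical and testing choices

* Determinism: `simulate_run()` seeds R's RNG from `config$seed`;
  identical configurations give bit-identical event tables, frames and
  CSVs. Rotations are uniform over SO(3) via normalized Gaussian
  quaternions.
* Lattice enumeration bounds Miller indices by
  $\lceil \|a_i\| / d_\text{min} \rceil + 1$ per axis, then filters
  $|q| \le 1/d_\text{min}$; the rotation-invariant grid is cached per
  (cell, $d_\text{min}$), so per-crystal prediction reduces to one 3×N
  rotation and an excitation filter.
* Test problem sizes are chosen desk-scale: short rendered runs
  (tens of frames on a 240 × 240 test detector) for pixel-level checks,
  ground-truth-only runs (no rasterization) wherever only event tables
  and peak lists matter — e.g. the ≥ 500-hit profile comparisons — which
  keeps the full suite in minutes on one CPU while leaving every
  statistical contract at the stated sample sizes.
* Degenerate inputs error early with named fields: non-positive energies
  and distances, angles outside (0°, 180°), cells without volume,
  unreachable d-spacings, overlapping run intervals, schema-violating
  CSV/JSON files.

# Known limitations

Single flat panel only (no tilts, no multi-panel geometries); no
detector-distance or beam-center refinement; no auto-indexing; intensity
model has one global scale and one b-factor per sample rather than a
crystal-size distribution; frame stacks serialize in the package's native
R form rather than a cross-language container, with CSV/JSON for all
tabular and configuration interfaces.
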