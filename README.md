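# dropsfx

Analysis pipeline for **drop-on-demand serial femtosecond crystallography
(SFX)**.

In drop-on-demand SFX, a piezo dispenser shoots picoliter protein-crystal
slurry drops (here: spherical, ~80 µm, ~268 pl, 60 Hz) through a pulsed
X-ray free-electron laser beam running at 10 Hz. Each X-ray pulse that
intercepts a drop produces one diffraction snapshot; a frame with at least
15 Bragg peaks is a *hit*, and each hit may contain several crystal
lattices. The experimental questions are statistical: what fraction of
pulses hit crystals, what fraction of hits index with the correct unit
cell, does recycling the sample through the dispenser damage the crystals,
and how much sample does the method consume?

`dropsfx` implements the full analysis chain on synthetic data with known
ground truth:

- **geometry** — flat-detector mapping between pixels, scattering angle
  and d-spacing: `2θ = atan(ρ/D)`, `d = λ/(2 sin θ)`, `λ = hc/E`.
- **simulate** — a frame simulator: crystal occupancy per probed drop is
  Poisson with mean `λ = c·V_probed`; reflections are predicted by
  Ewald-sphere intersection of the rotated reciprocal lattice
  (`q = R·B·h`, excitation error `||q+k₀|−|k₀|| ≤ ε`); frames compose
  Gaussian Bragg peaks with Debye–Waller intensity falloff
  `I₀·exp(−B/2d²)`, powder-ring annuli (Cu shielding rings at 2.09 and
  1.81 Å), diffuse background, and Poisson photon noise.
- **peaks** — hit finding with the standard criteria: connected
  components of ≥ 2 pixels above 100 ADU with SNR ≥ 7 are peaks; ≥ 15
  peaks is a hit; powder rings are masked first.
- **validate** — spot prediction matching and the misindexing
  (cross-contamination) audit: scoring each event against every candidate
  unit cell (5% length / 1.5° angle tolerances; integration radii 3, 4, 5).
- **rates** — per-run summaries (hit rate, crystal-level indexing rate =
  indexed crystals / hits with the correct cell) and time-binned hit /
  event-level indexing-rate series with inter-run gaps.
- **radial** — run-level radially averaged Bragg-intensity profiles:
  per-image shell means, closed-form L2 scaling to the first hit's
  reference, run averaging, mean-1 normalization, and run-to-run
  comparison (the sample-damage diagnostic).
- **budget** — droplet consumption arithmetic (`V = π/6·d³`; 250 pl at
  60 Hz = 0.9 µl min⁻¹) and concentration estimation from observed hit
  rates (`ĉ = −ln(1−p)/V_probed`).

## Worked example

```r
library(dropsfx)
cfg <- pipeline_config(
  sim = sim_config(duration_s = 3, seed = 7),  # 30 frames at 10 Hz
  bin_width_s = 1, output_dir = "demo_out")
res <- run_pipeline(cfg)
res$summary[, c("n_events", "n_hits", "hit_rate_pct",
                "indexing_rate_pct", "avg_n_peaks")]
str(res$budget)
```

prints (seed 7):

```
[dropsfx] simulate: 30 events in 2.9 s
[dropsfx] peaks: 30 frames processed
[dropsfx] rates: 25 hits / 30 events
[dropsfx] radial: 29 occupied shells
  n_events n_hits hit_rate_pct indexing_rate_pct avg_n_peaks
1       30     25         83.3               220      254.36
List of 7
 $ drop_volume_pl                : num 268
 $ rate_ul_per_min               : num 0.965
 $ probed_volume_nl              : num 0.00536
 $ lambda                        : num 2.14
 $ p_hit                         : num 0.883
 $ p_multi_given_hit             : num 0.716
 $ estimated_concentration_per_nl: num 441
```

Reading it: 30 frames were simulated from a 400 crystals nl⁻¹ thaumatin
slurry; 25 exceeded the 15-peak hit threshold (83.3% hit rate — consistent
with `p_hit = 0.883` from the Poisson occupancy model, diluted by the 8%
missed-drop rate). The crystal-level indexing rate exceeds 100% because
multi-crystal hits are common at this concentration (`p_multi_given_hit =
0.72`): each pattern contributes every lattice whose predicted spots match
the found peaks. The budget block shows the 268 pl drop volume, ~0.97
µl min⁻¹ consumption at 60 Hz, and a concentration of ~441 nl⁻¹ estimated
back from the observed hit rate (truth: 400). `demo_out/` holds the peak
table, run summary, binned rate series, normalized radial profile and
budget report as CSV/JSON, each with a seed-carrying sidecar.

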