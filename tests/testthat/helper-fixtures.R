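# Shared fixtures: a small fast geometry, frame builders for the
# well-separated-peak suite, and quick ground-truth-only simulations.

# Compact detector reaching ~2 A at the edge: cheap to rasterize.
small_geom <- function() {
  beamline_geometry(detector_distance_mm = 50, pixel_pitch_um = 354,
                    beam_center = c(119.5, 119.5),
                    frame_shape = c(240L, 240L))
}

# Frame of Poisson background plus isotropic Gaussian peaks with given
# photon masses; mirrors the rendering model but built independently so
# peak-finder tests do not lean on render_frame.
peak_frame <- function(positions, masses, geom, bg_photons = 10, gain = 5,
                       sigma = 1.0, noise = TRUE) {
  ns <- geom$frame_shape[1]; nf <- geom$frame_shape[2]
  photons <- matrix(bg_photons, ns, nf)
  for (i in seq_len(nrow(positions))) {
    f0 <- positions[i, 1]; s0 <- positions[i, 2]
    fs <- max(0, floor(f0) - 5):min(nf - 1, floor(f0) + 5)
    ss <- max(0, floor(s0) - 5):min(ns - 1, floor(s0) + 5)
    w <- outer(exp(-(ss - s0)^2 / (2 * sigma^2)),
               exp(-(fs - f0)^2 / (2 * sigma^2)))
    photons[ss + 1, fs + 1] <- photons[ss + 1, fs + 1] +
      masses[i] * w / sum(w)
  }
  if (noise) {
    matrix(as.integer(stats::rpois(length(photons), photons) * gain),
           ns, nf)
  } else {
    matrix(as.integer(round(photons * gain)), ns, nf)
  }
}

# Random well-separated in-frame positions (minimum pairwise distance).
separated_positions <- function(n, geom, min_dist = 14, margin = 12) {
  ns <- geom$frame_shape[1]; nf <- geom$frame_shape[2]
  pos <- matrix(numeric(0), 0, 2)
  while (nrow(pos) < n) {
    cand <- c(stats::runif(1, margin, nf - 1 - margin),
              stats::runif(1, margin, ns - 1 - margin))
    if (!nrow(pos) ||
        min(sqrt((pos[, 1] - cand[1])^2 + (pos[, 2] - cand[2])^2)) >=
          min_dist) {
      pos <- rbind(pos, cand)
    }
  }
  pos
}

# Ground-truth-only simulated run (no rasterization): fast fixture for
# rates and radial tests.
quick_run <- function(seed, duration_s = 3, sample = default_sample(),
                      b_factor = NULL, miss = 0.08) {
  if (!is.null(b_factor)) sample$b_factor <- b_factor
  simulate_run(sim_config(
    sample = sample, drop = drop_model(miss_probability = miss),
    duration_s = duration_s, seed = seed, render = FALSE))
}

# Peak lists (from ground truth) of all hit events of a run.
hit_peak_lists <- function(run, min_peaks = 15) {
  ids <- run$events$event_id[run$events$n_true_peaks >= min_peaks]
  lapply(ids, function(ev) truth_peak_list(run, ev))
}
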