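# Synthetic drop-on-demand SFX data: Poisson crystal occupancy per probed
# drop, Ewald-sphere reflection prediction, frame rendering, run assembly.

#' Droplet delivery model
#'
#' Describes the dispensed drops: 80 um spheres at 1.5 m/s, dispensed at
#' 60 Hz for beam delivery (1.2 kHz in the recycling stress test). Only one
#' drop in six coincides with a 10 Hz pulse; the simulator emits probed
#' events only. `miss_probability` is the chance a probed pulse misses the
#' drop entirely (a blank frame); `interaction_fraction` is the fraction of
#' the drop volume the focused beam actually probes, the single free
#' parameter linking slurry concentration to hit rate.
#'
#' @param diameter_um Drop diameter in um.
#' @param speed_m_s Drop speed (metadata only).
#' @param dispense_rate_hz Dispense frequency in Hz.
#' @param miss_probability Probability a probed pulse misses the drop.
#' @param tail_hit_probability Probability a miss still clips the fluid
#'   tail (recorded in the event table; tails carry no crystals here).
#' @param interaction_fraction Fraction of drop volume probed by the beam.
#' @return An object of class `drop_model`.
#' @export
drop_model <- function(diameter_um = 80, speed_m_s = 1.5,
                       dispense_rate_hz = 60, miss_probability = 0.08,
                       tail_hit_probability = 0,
                       interaction_fraction = 0.02) {
  if (diameter_um <= 0) stop("drop diameter must be > 0")
  probs <- c(miss_probability, tail_hit_probability, interaction_fraction)
  if (any(probs < 0) || any(probs > 1)) {
    stop("probabilities and interaction_fraction must lie in [0, 1]")
  }
  structure(list(diameter_um = diameter_um, speed_m_s = speed_m_s,
                 dispense_rate_hz = dispense_rate_hz,
                 miss_probability = miss_probability,
                 tail_hit_probability = tail_hit_probability,
                 interaction_fraction = interaction_fraction),
            class = "drop_model")
}

#' Simulation configuration
#'
#' @param geometry A [beamline_geometry()].
#' @param sample A [sample_model()].
#' @param drop A [drop_model()].
#' @param duration_s Run duration in seconds.
#' @param seed Integer seed; fixes every random draw of the run.
#' @param excitation_tol Half-width of the excitation-error acceptance
#'   around the Ewald sphere, 1/Angstrom. Collapses bandwidth, mosaicity
#'   and partiality into one number.
#' @param d_min High-resolution cutoff for predicted reflections, Angstrom.
#' @param ring_bands List of `c(d_center_angstrom, width_px, amplitude)`
#'   Gaussian annuli emulating powder rings from the Cu shielding
#'   (defaults: 2.09 and 1.81 Angstrom).
#' @param background_level Mean diffuse background, photons/pixel.
#' @param noise_model If `TRUE`, pixel values are Poisson draws.
#' @param gain Detector gain, ADU/photon.
#' @param peak_sigma_px Isotropic Gaussian width of a Bragg peak, pixels.
#' @param depletion_time_s Time at which crystals run out and buffer-only
#'   frames begin (`Inf` = never).
#' @param render If `FALSE`, frames are not rasterized; only ground truth
#'   (events, crystals, true peak positions/intensities) is produced.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(geometry = beamline_geometry(),
                       sample = default_sample("thaumatin"),
                       drop = drop_model(),
                       duration_s = 30, seed = 1,
                       excitation_tol = 2e-4, d_min = 2.0,
                       ring_bands = list(c(2.09, 2, 30), c(1.81, 2, 20)),
                       background_level = 10, noise_model = TRUE,
                       gain = 5, peak_sigma_px = 1.0,
                       depletion_time_s = Inf, render = TRUE) {
  stopifnot(inherits(geometry, "beamline_geometry"),
            inherits(sample, "sample_model"),
            inherits(drop, "drop_model"))
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (excitation_tol <= 0) stop("excitation_tol must be > 0")
  if (d_min <= geometry$wavelength / 2) stop("d_min must exceed lambda/2")
  structure(list(geometry = geometry, sample = sample, drop = drop,
                 duration_s = duration_s, seed = as.integer(seed),
                 excitation_tol = excitation_tol, d_min = d_min,
                 ring_bands = ring_bands,
                 background_level = background_level,
                 noise_model = isTRUE(noise_model), gain = gain,
                 peak_sigma_px = peak_sigma_px,
                 depletion_time_s = depletion_time_s,
                 render = isTRUE(render)),
            class = "sim_config")
}

#' Poisson crystal occupancy draw
#'
#' Number of crystals in the probed sub-volume of a drop, Poisson with mean
#' `lambda = concentration * probed_volume`.
#'
#' @param concentration_per_nl Crystal number density, crystals/nl.
#' @param probed_volume_nl Probed volume, nl.
#' @param n Number of draws.
#' @return Integer vector of crystal counts.
#' @export
draw_crystal_count <- function(concentration_per_nl, probed_volume_nl,
                               n = 1) {
  if (concentration_per_nl < 0 || probed_volume_nl < 0) {
    stop("concentration and volume must be >= 0")
  }
  stats::rpois(n, concentration_per_nl * probed_volume_nl)
}

# Cache of rotation-invariant reciprocal lattice grids keyed by cell + d_min.
.lattice_cache <- new.env(parent = emptyenv())

# Reciprocal lattice points with 1/|q| >= d_min: 3 x N matrix of q vectors
# (crystal frame), with Miller indices and d attached as attributes.
lattice_points <- function(cell, d_min) {
  key <- rlang::hash(list(cell$a, cell$b, cell$c, cell$alpha, cell$beta,
                          cell$gamma, d_min))
  hit <- .lattice_cache[[key]]
  if (!is.null(hit)) return(hit)
  B <- reciprocal_basis(cell)
  A <- cell_basis(cell)
  hmax <- ceiling(sqrt(colSums(A^2)) / d_min) + 1L
  grid <- as.matrix(expand.grid(h = -hmax[1]:hmax[1],
                                k = -hmax[2]:hmax[2],
                                l = -hmax[3]:hmax[3]))
  grid <- grid[rowSums(abs(grid)) > 0L, , drop = FALSE]
  q <- B %*% t(grid)
  qlen <- sqrt(colSums(q^2))
  keep <- qlen <= 1 / d_min
  out <- list(q = q[, keep, drop = FALSE],
              hkl = grid[keep, , drop = FALSE],
              d = 1 / qlen[keep])
  if (length(ls(.lattice_cache)) > 8) {
    rm(list = ls(.lattice_cache), envir = .lattice_cache)
  }
  assign(key, out, envir = .lattice_cache)
  out
}

#' Predict reflections on the detector
#'
#' Forward model of Bragg diffraction for one crystal: enumerates
#' reciprocal-lattice vectors `q = R B h` with `|q| <= 1/d_min`, keeps
#' those whose excitation error `| |q + k0| - |k0| |` (distance from the
#' Ewald sphere, `|k0| = 1/lambda`) is at most `excitation_tol`, and
#' projects the diffracted beam `k0 + q` onto the detector plane. Only
#' positions inside the frame are returned.
#'
#' @param cell A [unit_cell()].
#' @param orientation 3x3 rotation matrix (crystal -> lab frame).
#' @param geom A [beamline_geometry()].
#' @param excitation_tol Acceptance half-width around the Ewald sphere,
#'   1/Angstrom.
#' @param d_min High-resolution cutoff, Angstrom; must exceed lambda/2.
#' @return A data frame with columns `fast`, `slow` (fractional pixels),
#'   `d` (Angstrom) and `h`, `k`, `l`, ordered by decreasing `d`.
#' @export
predict_reflections <- function(cell, orientation, geom,
                                excitation_tol = 2e-4, d_min = 2.0) {
  stopifnot(inherits(cell, "unit_cell"),
            inherits(geom, "beamline_geometry"))
  if (d_min <= geom$wavelength / 2) {
    stop("d_min must exceed lambda/2: reflections beyond are unreachable")
  }
  if (!all(dim(orientation) == c(3, 3))) stop("orientation must be 3x3")
  lat <- lattice_points(cell, d_min)
  q <- orientation %*% lat$q
  k <- 1 / geom$wavelength
  exc <- abs(sqrt(q[1, ]^2 + q[2, ]^2 + (q[3, ] + k)^2) - k)
  sel <- which(exc <= excitation_tol)
  if (!length(sel)) {
    return(data.frame(fast = numeric(0), slow = numeric(0), d = numeric(0),
                      h = integer(0), k = integer(0), l = integer(0)))
  }
  kp <- q[, sel, drop = FALSE]
  kp[3, ] <- kp[3, ] + k
  fwd <- kp[3, ] > 0
  pitch_mm <- geom$pixel_pitch_um * 1e-3
  fast <- geom$beam_center[1] +
    geom$detector_distance_mm * kp[1, ] / kp[3, ] / pitch_mm
  slow <- geom$beam_center[2] +
    geom$detector_distance_mm * kp[2, ] / kp[3, ] / pitch_mm
  inside <- fwd & fast >= 0 & fast <= geom$frame_shape[2] - 1 &
    slow >= 0 & slow <= geom$frame_shape[1] - 1
  out <- data.frame(fast = fast[inside], slow = slow[inside],
                    d = lat$d[sel][inside],
                    h = lat$hkl[sel, 1][inside],
                    k = lat$hkl[sel, 2][inside],
                    l = lat$hkl[sel, 3][inside])
  out[order(-out$d, out$slow, out$fast), , drop = FALSE]
}

# Expected photon count of a reflection: I0 * exp(-B / (2 d^2)).
reflection_photons <- function(sample, d) {
  sample$peak_scale_i0 * exp(-sample$b_factor / (2 * d^2))
}

#' Rasterize one detector frame
#'
#' Composes diffuse background, powder-ring annuli and per-reflection
#' Gaussian peaks into a photon-rate image, applies Poisson noise if
#' configured, and converts to integer ADU through the gain. Each peak is a
#' discretized isotropic 2D Gaussian whose pixel weights are normalized to
#' sum to one, so its integrated photon count is exactly the Debye-Waller
#' scaled intensity.
#'
#' @param predictions A data frame of reflections (`fast`, `slow`, `d`),
#'   e.g. rows of [predict_reflections()] output, possibly from several
#'   crystals; may be `NULL` or empty for a blank frame.
#' @param config A [sim_config()].
#' @return Integer matrix (slow x fast) of ADU values.
#' @export
render_frame <- function(predictions, config) {
  stopifnot(inherits(config, "sim_config"))
  geom <- config$geometry
  ns <- geom$frame_shape[1]; nf <- geom$frame_shape[2]
  photons <- matrix(config$background_level, nrow = ns, ncol = nf)
  if (length(config$ring_bands)) {
    r <- radius_map(geom)
    for (band in config$ring_bands) {
      r0 <- d_to_ring_radius(geom, band[1])
      photons <- photons + band[3] * exp(-(r - r0)^2 / (2 * band[2]^2))
    }
  }
  if (!is.null(predictions) && nrow(predictions)) {
    sig <- config$peak_sigma_px
    half <- max(2L, ceiling(4 * sig))
    for (i in seq_len(nrow(predictions))) {
      f0 <- predictions$fast[i]; s0 <- predictions$slow[i]
      mass <- reflection_photons(config$sample, predictions$d[i])
      fs <- max(0L, floor(f0) - half):min(nf - 1L, floor(f0) + half + 1L)
      ss <- max(0L, floor(s0) - half):min(ns - 1L, floor(s0) + half + 1L)
      if (!length(fs) || !length(ss)) next
      w <- outer(exp(-(ss - s0)^2 / (2 * sig^2)),
                 exp(-(fs - f0)^2 / (2 * sig^2)))
      w <- w / sum(w)
      photons[ss + 1L, fs + 1L] <- photons[ss + 1L, fs + 1L] + mass * w
    }
  }
  if (config$noise_model) {
    adu <- stats::rpois(length(photons), photons) * config$gain
  } else {
    adu <- round(photons * config$gain)
  }
  matrix(as.integer(adu), nrow = ns, ncol = nf)
}

#' Simulate a data-collection run
#'
#' Emits `floor(duration_s * fel_rate)` probed events on the pulse clock.
#' Each event is blank with `miss_probability`; past `depletion_time_s`
#' frames are buffer-only; otherwise the crystal count is Poisson in the
#' beam-probed sub-volume (`interaction_fraction` x drop volume). Every
#' crystal gets a uniform random orientation, predicted reflections, and
#' ground-truth peak intensities. With `render = TRUE` frames are
#' rasterized. Fixed `seed` reproduces the run exactly.
#'
#' @param config A [sim_config()].
#' @return An object of class `sfx_run`: a list with `events` (one row per
#'   event), `crystals` (one row per crystal, orientation flattened
#'   row-major), `truth_peaks` (one row per predicted reflection),
#'   `frames` (list of integer matrices, or `NULL` when not rendered),
#'   and `config`.
#' @export
simulate_run <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  geom <- config$geometry
  n_frames <- floor(config$duration_s * geom$fel_rate_hz)
  times <- (seq_len(n_frames) - 1) / geom$fel_rate_hz
  probed_nl <- drop_volume_from_diameter(config$drop$diameter_um) * 1e-3 *
    config$drop$interaction_fraction
  conc <- if (config$sample$is_buffer_only) 0 else
    config$sample$concentration_per_nl

  events <- data.frame(event_id = seq_len(n_frames) - 1L, time_s = times,
                       is_blank = FALSE, is_buffer = FALSE,
                       n_crystals = 0L, n_true_peaks = 0L)
  crystals <- list(); truth <- list()
  frames <- if (config$render) vector("list", n_frames) else NULL

  for (i in seq_len(n_frames)) {
    blank <- stats::runif(1) < config$drop$miss_probability
    buffer <- times[i] >= config$depletion_time_s
    n_cry <- 0L
    if (!blank && !buffer && conc > 0) {
      n_cry <- draw_crystal_count(conc, probed_nl)
    }
    events$is_blank[i] <- blank
    events$is_buffer[i] <- buffer
    events$n_crystals[i] <- n_cry
    ev_truth <- NULL
    if (n_cry > 0) {
      for (j in seq_len(n_cry)) {
        R <- random_rotation()
        p <- predict_reflections(config$sample$cell, R, geom,
                                 config$excitation_tol, config$d_min)
        crystals[[length(crystals) + 1L]] <- data.frame(
          event_id = events$event_id[i], crystal_index = j - 1L,
          cell_label = config$sample$cell$label,
          matrix(t(R), nrow = 1,
                 dimnames = list(NULL, paste0("r", rep(1:3, each = 3),
                                              rep(1:3, 3)))))
        if (nrow(p)) {
          p$event_id <- events$event_id[i]
          p$crystal_index <- j - 1L
          p$intensity_photons <- reflection_photons(config$sample, p$d)
          p$intensity_adu <- p$intensity_photons * config$gain
          ev_truth <- rbind(ev_truth, p)
        }
      }
    }
    if (!is.null(ev_truth)) {
      events$n_true_peaks[i] <- nrow(ev_truth)
      truth[[length(truth) + 1L]] <- ev_truth
    }
    if (config$render) frames[[i]] <- render_frame(ev_truth, config)
  }
  crystals <- if (length(crystals)) do.call(rbind, crystals) else
    data.frame(event_id = integer(0), crystal_index = integer(0),
               cell_label = character(0))
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(fast = numeric(0), slow = numeric(0), d = numeric(0),
               h = integer(0), k = integer(0), l = integer(0),
               event_id = integer(0), crystal_index = integer(0),
               intensity_photons = numeric(0), intensity_adu = numeric(0))
  rownames(truth) <- NULL
  structure(list(events = events, crystals = crystals, truth_peaks = truth,
                 frames = frames, config = config),
            class = "sfx_run")
}

#' @export
print.sfx_run <- function(x, ...) {
  cat(sprintf("Simulated SFX run: %d events (%d blank, %d buffer-only), %d crystals\n",
              nrow(x$events), sum(x$events$is_blank),
              sum(x$events$is_buffer), nrow(x$crystals)))
  cat(sprintf("  sample %s, seed %d, frames %s\n", x$config$sample$name,
              x$config$seed,
              if (is.null(x$frames)) "not rendered" else "rendered"))
  invisible(x)
}

#' Ground-truth peak lists per event
#'
#' Converts the simulator's ground-truth reflection table for one event
#' into the peak-list layout produced by [find_peaks()] (centroid,
#' intensity in ADU, d-spacing), so downstream rate and radial-profile
#' code can run on noise-free truth.
#'
#' @param run An `sfx_run` from [simulate_run()].
#' @param event_id Event identifier.
#' @return A peak-list data frame sorted by decreasing intensity.
#' @export
truth_peak_list <- function(run, event_id) {
  stopifnot(inherits(run, "sfx_run"))
  t <- run$truth_peaks[run$truth_peaks$event_id == event_id, , drop = FALSE]
  out <- data.frame(fast = t$fast, slow = t$slow,
                    n_pixels = rep(NA_integer_, nrow(t)),
                    intensity = t$intensity_adu,
                    snr = rep(Inf, nrow(t)), d = t$d)
  out <- out[order(-out$intensity, out$slow, out$fast), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_list", "data.frame")
  out
}

#' Write / read a simulated run
#'
#' `write_run` stores the event, crystal and ground-truth tables as CSV,
#' the configuration (including the seed) as a JSON sidecar, and, when
#' frames were rendered, the frame stack in the package's native serialized
#' form (`frames.rds`). `read_frames` restores a frame stack.
#'
#' @param run An `sfx_run`.
#' @param dir Output directory (created if needed).
#' @return `write_run` returns `dir` invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "sfx_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(run$crystals, file.path(dir, "crystals.csv"),
                   row.names = FALSE)
  utils::write.csv(run$truth_peaks, file.path(dir, "truth_peaks.csv"),
                   row.names = FALSE)
  cfg <- run$config
  sidecar <- list(seed = cfg$seed, duration_s = cfg$duration_s,
                  sample = cfg$sample$name,
                  concentration_per_nl = cfg$sample$concentration_per_nl,
                  excitation_tol = cfg$excitation_tol, d_min = cfg$d_min,
                  background_level = cfg$background_level, gain = cfg$gain,
                  config_hash = rlang::hash(cfg))
  jsonlite::write_json(sidecar, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(run$frames)) {
    saveRDS(list(frames = run$frames, event_id = run$events$event_id,
                 time_s = run$events$time_s),
            file.path(dir, "frames.rds"))
  }
  invisible(dir)
}

#' @rdname write_run
#' @param path Path to a `frames.rds` file.
#' @export
read_frames <- function(path) {
  if (!file.exists(path)) stop("frame stack not found: ", path)
  readRDS(path)
}
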