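# Bragg peak finding and hit classification on masked detector frames.

#' Peak-finding parameters
#'
#' Defaults follow the standard serial-crystallography hit-finding recipe
#' used at 10 Hz beamlines: a connected component of at least 2 pixels
#' above 100 ADU with signal-to-noise ratio of at least 7 counts as a
#' peak, and a frame with at least 15 peaks is a crystal hit.
#'
#' @param adu_threshold Pixel threshold in ADU.
#' @param min_pixel_count Minimum pixels in a peak component.
#' @param min_snr Minimum signal-to-noise ratio of a peak.
#' @param min_peaks_per_hit Minimum peaks for a hit.
#' @param connectivity Component connectivity, 4 or 8.
#' @param bg_annulus `c(inner, outer)` radii in pixels of the local
#'   background annulus around each component centroid.
#' @return An object of class `peak_find_params`.
#' @export
peak_find_params <- function(adu_threshold = 100, min_pixel_count = 2,
                             min_snr = 7.0, min_peaks_per_hit = 15,
                             connectivity = 8, bg_annulus = c(3, 6)) {
  if (adu_threshold <= 0 || min_snr <= 0) stop("thresholds must be > 0")
  if (min_pixel_count < 1) stop("min_pixel_count must be >= 1")
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  if (!(bg_annulus[2] > bg_annulus[1] && bg_annulus[1] > 0)) {
    stop("bg_annulus must satisfy outer > inner > 0")
  }
  structure(list(adu_threshold = adu_threshold,
                 min_pixel_count = as.integer(min_pixel_count),
                 min_snr = min_snr,
                 min_peaks_per_hit = as.integer(min_peaks_per_hit),
                 connectivity = as.integer(connectivity),
                 bg_annulus = bg_annulus),
            class = "peak_find_params")
}

#' Powder-ring pixel mask
#'
#' Builds a boolean mask (TRUE = excluded) covering annuli around the
#' powder rings of the given d-spacings — e.g. the Cu shielding rings at
#' 2.09 and 1.81 Angstrom — so they do not contribute peaks.
#'
#' @param geom A [beamline_geometry()].
#' @param bands List of `c(d_center_angstrom, half_width_px)` entries.
#' @return Logical matrix (slow x fast); `TRUE` marks excluded pixels.
#' @export
make_ring_mask <- function(geom, bands) {
  stopifnot(inherits(geom, "beamline_geometry"))
  mask <- matrix(FALSE, geom$frame_shape[1], geom$frame_shape[2])
  if (!length(bands)) return(mask)
  r <- radius_map(geom)
  for (band in bands) {
    r0 <- d_to_ring_radius(geom, band[1])
    mask <- mask | (abs(r - r0) <= band[2])
  }
  mask
}

# Sparse connected-component labeling of above-threshold pixels.
# `idx` are 1-based linear indices into an ns x nf matrix. Union-find,
# deterministic label order (first pixel in column-major order = root).
label_components <- function(idx, ns, nf, connectivity = 8) {
  n <- length(idx)
  if (!n) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  pos <- integer(ns * nf)
  pos[idx] <- seq_len(n)
  s <- (idx - 1L) %% ns          # 0-based slow (row)
  f <- (idx - 1L) %/% ns         # 0-based fast (col)
  offs <- if (connectivity == 8) {
    list(c(-1L, 0L), c(0L, -1L), c(-1L, -1L), c(1L, -1L))
  } else {
    list(c(-1L, 0L), c(0L, -1L))
  }
  for (o in offs) {
    s2 <- s + o[1]; f2 <- f + o[2]
    ok <- which(s2 >= 0L & s2 < ns & f2 >= 0L & f2 < nf)
    nb <- pos[f2[ok] * ns + s2[ok] + 1L]
    hit <- which(nb > 0L)
    for (m in hit) {
      ra <- find(ok[m]); rb <- find(nb[m])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}

#' Local background statistics in an annulus
#'
#' Median and robust sigma (1.4826 x median absolute deviation) of the
#' unmasked pixels in an annulus around a position. Used as the per-peak
#' background estimate; at least 10 unmasked pixels are required.
#'
#' @param frame Numeric matrix (slow x fast).
#' @param center `c(fast, slow)` position, 0-based pixels.
#' @param bg_annulus `c(inner, outer)` annulus radii in pixels.
#' @param mask Optional logical matrix, `TRUE` = excluded.
#' @return `list(bg_median, bg_sigma, n)` or `NULL` when fewer than 10
#'   annulus pixels are available (the caller rejects the peak).
#' @export
local_background <- function(frame, center, bg_annulus, mask = NULL) {
  ns <- nrow(frame); nf <- ncol(frame)
  r_out <- bg_annulus[2]
  fs <- max(0L, floor(center[1] - r_out)):min(nf - 1L, ceiling(center[1] + r_out))
  ss <- max(0L, floor(center[2] - r_out)):min(ns - 1L, ceiling(center[2] + r_out))
  if (!length(fs) || !length(ss)) return(NULL)
  dist <- sqrt(outer((ss - center[2])^2, (fs - center[1])^2, "+"))
  sel <- dist > bg_annulus[1] & dist <= r_out
  sub <- frame[ss + 1L, fs + 1L, drop = FALSE]
  if (!is.null(mask)) sel <- sel & !mask[ss + 1L, fs + 1L, drop = FALSE]
  vals <- sub[sel]
  if (length(vals) < 10) return(NULL)
  med <- stats::median(vals)
  list(bg_median = med,
       bg_sigma = 1.4826 * stats::median(abs(vals - med)),
       n = length(vals))
}

#' Find Bragg peaks on a frame
#'
#' Thresholds the unmasked pixels at `adu_threshold`, labels connected
#' components (4- or 8-connectivity), and keeps components with at least
#' `min_pixel_count` pixels. Each surviving component gets a local
#' background estimate from [local_background()]; its intensity is the
#' background-subtracted pixel sum, its SNR is
#' `intensity / (bg_sigma * sqrt(n_pixels))`, and components below
#' `min_snr` are dropped. Centroids are intensity-weighted. The result is
#' sorted by decreasing intensity (ties by slow then fast ascending) so
#' output is byte-reproducible.
#'
#' @param frame Integer/numeric matrix (slow x fast), ADU.
#' @param mask Logical matrix, `TRUE` = excluded; `NULL` for no mask.
#' @param params A [peak_find_params()].
#' @param geom A [beamline_geometry()] for d-spacing assignment.
#' @return A `peak_list` data frame: `fast`, `slow`, `n_pixels`,
#'   `intensity`, `snr`, `d`.
#' @export
find_peaks <- function(frame, mask = NULL, params = peak_find_params(),
                       geom = NULL) {
  stopifnot(inherits(params, "peak_find_params"))
  ns <- nrow(frame); nf <- ncol(frame)
  if (!is.null(mask) && !all(dim(mask) == dim(frame))) {
    stop("mask and frame shapes disagree")
  }
  empty <- data.frame(fast = numeric(0), slow = numeric(0),
                      n_pixels = integer(0), intensity = numeric(0),
                      snr = numeric(0), d = numeric(0))
  class(empty) <- c("peak_list", "data.frame")
  above <- frame >= params$adu_threshold
  if (!is.null(mask)) above <- above & !mask
  idx <- which(above)
  if (!length(idx)) return(empty)
  lab <- label_components(idx, ns, nf, params$connectivity)
  rows <- list()
  for (comp in split(idx, lab)) {
    np <- length(comp)
    if (np < params$min_pixel_count) next
    s <- (comp - 1L) %% ns
    f <- (comp - 1L) %/% ns
    vals <- frame[comp]
    c_fast <- sum(f * vals) / sum(vals)
    c_slow <- sum(s * vals) / sum(vals)
    bg <- local_background(frame, c(c_fast, c_slow), params$bg_annulus, mask)
    if (is.null(bg)) next
    intensity <- sum(vals - bg$bg_median)
    if (intensity <= 0) next
    snr <- if (bg$bg_sigma == 0) Inf else
      intensity / (bg$bg_sigma * sqrt(np))
    if (snr < params$min_snr) next
    w <- pmax(vals - bg$bg_median, 0)
    if (sum(w) > 0) {
      c_fast <- sum(f * w) / sum(w)
      c_slow <- sum(s * w) / sum(w)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      fast = c_fast, slow = c_slow, n_pixels = np,
      intensity = intensity, snr = snr,
      d = if (is.null(geom)) NA_real_ else pixel_to_d(geom, c_fast, c_slow))
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$intensity, out$slow, out$fast), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_list", "data.frame")
  out
}

#' Classify a frame as a crystal hit
#'
#' A frame is a hit when its peak list holds at least
#' `min_peaks_per_hit` peaks (default 15).
#'
#' @param peak_list A peak list from [find_peaks()].
#' @param params A [peak_find_params()].
#' @return Logical flag.
#' @export
classify_hit <- function(peak_list, params = peak_find_params()) {
  nrow(peak_list) >= params$min_peaks_per_hit
}

#' Write / read peak lists as CSV
#'
#' One row per peak: `event_id, peak_index, fast, slow, n_pixels,
#' intensity_adu, snr, d_angstrom`.
#'
#' @param peaks Named list of peak lists (names = event ids), or a single
#'   peak list with `event_id`.
#' @param path Output / input CSV path.
#' @export
write_peaks <- function(peaks, path) {
  if (is.data.frame(peaks)) peaks <- list(`0` = peaks)
  rows <- lapply(names(peaks), function(ev) {
    p <- peaks[[ev]]
    if (!nrow(p)) return(NULL)
    data.frame(event_id = as.integer(ev),
               peak_index = seq_len(nrow(p)) - 1L,
               fast = p$fast, slow = p$slow, n_pixels = p$n_pixels,
               intensity_adu = p$intensity, snr = p$snr, d_angstrom = p$d)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(event_id = integer(0), peak_index = integer(0),
                      fast = numeric(0), slow = numeric(0),
                      n_pixels = integer(0), intensity_adu = numeric(0),
                      snr = numeric(0), d_angstrom = numeric(0))
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peaks
#' @export
read_peaks <- function(path) {
  df <- utils::read.csv(path)
  need <- c("event_id", "fast", "slow", "n_pixels", "intensity_adu",
            "snr", "d_angstrom")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("peak file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  lapply(split(df, df$event_id), function(p) {
    out <- data.frame(fast = p$fast, slow = p$slow, n_pixels = p$n_pixels,
                      intensity = p$intensity_adu, snr = p$snr,
                      d = p$d_angstrom)
    class(out) <- c("peak_list", "data.frame")
    out
  })
}
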