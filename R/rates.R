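# Run-level and time-binned hit / indexing statistics.

# One-decimal display rounding, half away from zero (25.05 -> 25.1).
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Event records and run tables
#'
#' `event_record` captures one detector frame's analysis outcome: peak
#' count, hit flag, mean peak intensity, indexed crystal counts per
#' candidate unit cell, and the resolution limit (minimum d among matched
#' peaks) when indexed. `run_table` is an ordered collection of events for
#' one run. These are the units over which all rate statistics are defined.
#'
#' @param event_id Event identifier.
#' @param time_s Event timestamp, seconds.
#' @param n_peaks Number of Bragg peaks found.
#' @param is_hit Hit flag; must equal `n_peaks >= min_peaks_per_hit`.
#' @param mean_peak_intensity Mean peak intensity, ADU (`NA` if no peaks).
#' @param indexed_crystals Named integer vector: cell label -> number of
#'   indexed crystals in this event.
#' @param resolution_limit Minimum d among matched peaks of indexed
#'   lattices, Angstrom (`NA` when unindexed).
#' @return `event_record` returns a one-row data frame (list column for
#'   the per-cell counts).
#' @export
event_record <- function(event_id, time_s, n_peaks, is_hit,
                         mean_peak_intensity = NA_real_,
                         indexed_crystals = integer(0),
                         resolution_limit = NA_real_) {
  if (any(indexed_crystals < 0) || n_peaks < 0) stop("counts must be >= 0")
  df <- data.frame(event_id = event_id, time_s = time_s,
                   n_peaks = as.integer(n_peaks), is_hit = isTRUE(is_hit),
                   mean_peak_intensity = mean_peak_intensity,
                   resolution_limit = resolution_limit)
  df$indexed_crystals <- list(indexed_crystals)
  df
}

#' @rdname event_record
#' @param run_id Run identifier.
#' @param sample_label Label of the sample (and its correct cell).
#' @param events Data frame of event records (rbind of [event_record()]
#'   rows), times non-decreasing.
#' @param duration_s Run duration; must cover the event time span.
#' @param start_s Wall-clock start of the run (for multi-run timelines).
#' @export
run_table <- function(run_id, sample_label, events, duration_s,
                      start_s = 0) {
  if (nrow(events) && is.unsorted(events$time_s)) {
    stop("event times must be non-decreasing")
  }
  if (nrow(events) &&
      duration_s < max(events$time_s) - min(events$time_s)) {
    stop("duration_s shorter than the event time span")
  }
  structure(list(run_id = run_id, sample_label = sample_label,
                 events = events, duration_s = duration_s,
                 start_s = start_s),
            class = "run_table")
}

#' @export
print.run_table <- function(x, ...) {
  cat(sprintf("Run %s [%s]: %d events, %d hits, %.0f s\n", x$run_id,
              x$sample_label, nrow(x$events), sum(x$events$is_hit),
              x$duration_s))
  invisible(x)
}

#' Hit rate
#'
#' Percentage of collected patterns classified as hits.
#'
#' @param n_hits Number of hits.
#' @param n_events Number of collected patterns; must be > 0.
#' @return Percent, full precision.
#' @export
hit_rate <- function(n_hits, n_events) {
  if (n_events <= 0) stop("hit rate undefined: no events")
  100 * n_hits / n_events
}

#' Crystal-level indexing rate
#'
#' Ratio of indexed crystals (counting every lattice of a multi-crystal
#' pattern) to the number of hits, using the correct unit cell; may exceed
#' 100%. With zero hits the rate is reported as 0 with `undefined = TRUE`,
#' mirroring how summary tables print 0 for empty runs while keeping the
#' validity machine-readable.
#'
#' @param n_indexed Indexed crystal count with the correct cell.
#' @param n_hits Number of hits.
#' @return `list(rate, undefined)`; `rate` in percent, full precision.
#' @export
crystal_indexing_rate <- function(n_indexed, n_hits) {
  if (n_hits <= 0) return(list(rate = 0, undefined = TRUE))
  list(rate = 100 * n_indexed / n_hits, undefined = FALSE)
}

#' Event-level indexing rate
#'
#' Percentage of hits with at least one indexed crystal of any cell;
#' multi-crystal hits count once. Bins without hits are flagged undefined.
#'
#' @param is_hit Logical vector over events.
#' @param n_indexed_any Integer vector: indexed crystals (any cell) per
#'   event.
#' @return `list(rate, undefined)`.
#' @export
event_indexing_rate <- function(is_hit, n_indexed_any) {
  stopifnot(length(is_hit) == length(n_indexed_any))
  nh <- sum(is_hit)
  if (nh == 0) return(list(rate = NA_real_, undefined = TRUE))
  list(rate = 100 * sum(is_hit & n_indexed_any >= 1) / nh,
       undefined = FALSE)
}

#' Run summary statistics
#'
#' The per-run summary row: event and hit counts, hit rate, per-cell
#' indexed crystal counts, crystal-level indexing rate against the
#' sample's correct cell, mean peak count over hits, mean peak intensity
#' over all found peaks, and mean resolution limit over indexed events.
#' Rates carry one-decimal display rounding (half away from zero);
#' averages of an empty set are `NA` (printed as "-").
#'
#' @param run A [run_table()].
#' @param correct_cell Label of the correct unit cell (default: the run's
#'   sample label).
#' @return A one-row data frame (list column `indexed_by_cell`).
#' @export
run_summary <- function(run, correct_cell = run$sample_label) {
  stopifnot(inherits(run, "run_table"))
  ev <- run$events
  n_events <- nrow(ev)
  n_hits <- sum(ev$is_hit)
  per_cell <- integer(0)
  if (n_events) {
    all_counts <- ev$indexed_crystals
    labels <- unique(unlist(lapply(all_counts, names)))
    per_cell <- stats::setNames(integer(length(labels)), labels)
    for (cnt in all_counts) {
      if (length(cnt)) per_cell[names(cnt)] <- per_cell[names(cnt)] + cnt
    }
  }
  n_correct <- if (correct_cell %in% names(per_cell))
    per_cell[[correct_cell]] else 0L
  idx <- crystal_indexing_rate(n_correct, n_hits)
  indexed_any <- vapply(ev$indexed_crystals, sum, 0L)
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  out <- data.frame(
    run_id = run$run_id, sample = run$sample_label,
    duration_s = run$duration_s, n_events = n_events, n_hits = n_hits,
    hit_rate_pct = if (n_events) round_half_away(hit_rate(n_hits, n_events))
      else NA_real_,
    n_indexed_correct = n_correct,
    indexing_rate_pct = round_half_away(idx$rate),
    indexing_rate_undefined = idx$undefined,
    avg_n_peaks = mean_or_na(ev$n_peaks[ev$is_hit]),
    # over all found peaks of the run, not only hits: weight each event's
    # mean by its peak count
    avg_peak_intensity_adu = {
      wp <- ev$n_peaks > 0 & !is.na(ev$mean_peak_intensity)
      if (any(wp)) sum(ev$mean_peak_intensity[wp] * ev$n_peaks[wp]) /
        sum(ev$n_peaks[wp]) else NA_real_
    },
    avg_resolution_limit =
      mean_or_na(ev$resolution_limit[!is.na(ev$resolution_limit) &
                                       indexed_any >= 1]))
  out$indexed_by_cell <- list(per_cell)
  out
}

#' Time-binned hit and indexing rate series
#'
#' Lays uniform bins over the concatenated wall-clock timeline of several
#' runs, anchored at the first run's first event; inter-run gaps produce
#' empty bins (flagged, never zero-filled). Per bin: event and hit counts,
#' hit rate, and event-level indexing rate.
#'
#' @param runs List of [run_table()] objects with `start_s` offsets on a
#'   common clock; run intervals must not overlap.
#' @param bin_width_s Bin width in seconds (10 for coarse overviews, 5 for
#'   short runs).
#' @return A `binned_series` data frame: `bin_start_s`, `bin_end_s`,
#'   `n_events`, `n_hits`, `hit_rate_pct`, `event_indexing_rate_pct`,
#'   `valid` (FALSE for empty bins; indexing rate `NA` in hit-free bins).
#' @export
binned_series <- function(runs, bin_width_s = 10) {
  if (inherits(runs, "run_table")) runs <- list(runs)
  if (bin_width_s <= 0) stop("bin_width_s must be > 0")
  iv <- t(vapply(runs, function(r) c(r$start_s, r$start_s + r$duration_s),
                 numeric(2)))
  ord <- order(iv[, 1])
  if (length(runs) > 1) {
    for (i in seq_len(length(runs) - 1)) {
      if (iv[ord[i + 1], 1] < iv[ord[i], 2]) {
        stop("run intervals overlap on the common clock")
      }
    }
  }
  ev <- do.call(rbind, lapply(runs, function(r) {
    if (!nrow(r$events)) return(NULL)
    data.frame(t = r$start_s + r$events$time_s, is_hit = r$events$is_hit,
               idx_any = vapply(r$events$indexed_crystals, sum, 0L))
  }))
  if (is.null(ev) || !nrow(ev)) stop("no events across runs")
  t0 <- min(ev$t)
  t1 <- max(iv[, 2])
  edges <- seq(t0, t0 + bin_width_s * ceiling((t1 - t0) / bin_width_s),
               by = bin_width_s)
  bin <- findInterval(ev$t, edges, rightmost.closed = FALSE)
  nb <- length(edges) - 1L
  bin[bin == nb + 1L & ev$t == edges[length(edges)]] <- nb
  out <- data.frame(bin_start_s = edges[-length(edges)],
                    bin_end_s = edges[-1],
                    n_events = 0L, n_hits = 0L,
                    hit_rate_pct = NA_real_,
                    event_indexing_rate_pct = NA_real_,
                    valid = FALSE)
  for (b in seq_len(nb)) {
    sel <- bin == b
    if (!any(sel)) next
    out$n_events[b] <- sum(sel)
    out$n_hits[b] <- sum(ev$is_hit[sel])
    out$hit_rate_pct[b] <- hit_rate(out$n_hits[b], out$n_events[b])
    eir <- event_indexing_rate(ev$is_hit[sel], ev$idx_any[sel])
    out$event_indexing_rate_pct[b] <- eir$rate
    out$valid[b] <- TRUE
  }
  class(out) <- c("binned_series", "data.frame")
  attr(out, "bin_width_s") <- bin_width_s
  out
}

#' Plot a binned rate series
#'
#' Plain base-graphics rendering of the per-bin hit rate (solid) and
#' event-level indexing rate (dashed) against time.
#'
#' @param x A `binned_series`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.binned_series <- function(x, ...) {
  mid <- (x$bin_start_s + x$bin_end_s) / 2
  graphics::plot(mid[x$valid], x$hit_rate_pct[x$valid], type = "s",
                 xlab = "time (s)", ylab = "rate (%)", ylim = c(0, 100),
                 ...)
  ok <- x$valid & !is.na(x$event_indexing_rate_pct)
  graphics::lines(mid[ok], x$event_indexing_rate_pct[ok], type = "s",
                  lty = 2)
  graphics::legend("topright", legend = c("hit rate", "indexing rate"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Build a run table from simulator output and peak finding
#'
#' Convenience bridge: classifies every event of a simulated run from its
#' peak lists, fills indexed-crystal counts from ground truth (every
#' generated crystal with at least `support_fraction` of its reflections
#' observed counts as indexed with the sample's cell), and assembles a
#' [run_table()].
#'
#' @param run An `sfx_run` from [simulate_run()].
#' @param peaks Named list of peak lists keyed by event id (e.g. from
#'   [find_peaks()] per frame, or [truth_peak_list()]).
#' @param params A [peak_find_params()] (for the hit threshold).
#' @param mparams A [match_params()] (for the indexed-crystal check).
#' @param run_id,start_s Passed through to [run_table()].
#' @return A [run_table()].
#' @export
run_table_from_sim <- function(run, peaks, params = peak_find_params(),
                               mparams = match_params(),
                               run_id = "sim", start_s = 0) {
  stopifnot(inherits(run, "sfx_run"))
  lab <- run$config$sample$cell$label
  recs <- lapply(seq_len(nrow(run$events)), function(i) {
    ev <- run$events$event_id[i]
    p <- peaks[[as.character(ev)]]
    npk <- if (is.null(p)) 0L else nrow(p)
    hit <- npk >= params$min_peaks_per_hit
    n_idx <- 0L
    rlim <- NA_real_
    if (hit && run$events$n_crystals[i] > 0) {
      tp <- run$truth_peaks[run$truth_peaks$event_id == ev, , drop = FALSE]
      for (j in unique(tp$crystal_index)) {
        cry <- tp[tp$crystal_index == j, , drop = FALSE]
        frac <- match_fraction(cry, p, mparams$position_tolerance)
        if (frac >= mparams$support_fraction) {
          n_idx <- n_idx + 1L
          rlim <- min(rlim, min(cry$d), na.rm = TRUE)
        }
      }
    }
    event_record(
      event_id = ev, time_s = run$events$time_s[i], n_peaks = npk,
      is_hit = hit,
      mean_peak_intensity = if (npk) mean(p$intensity) else NA_real_,
      indexed_crystals = stats::setNames(n_idx, lab)[n_idx > 0],
      resolution_limit = rlim)
  })
  run_table(run_id, run$config$sample$name, do.call(rbind, recs),
            duration_s = run$config$duration_s, start_s = start_s)
}
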