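# Spot prediction matching, spot integration, and the misindexing
# (cross-contamination) audit.

#' Cell-matching and spot-matching parameters
#'
#' Defaults mirror standard serial-crystallography indexing tolerances:
#' 5% on lattice lengths and 1.5 degrees on angles. `position_tolerance`
#' (3 px, the integration radius) and `support_fraction` (0.5) govern when
#' an indexing solution counts as supported by the observed peaks; both are
#' free parameters of the audit, not measured values.
#'
#' @param length_tolerance Relative tolerance on cell lengths.
#' @param angle_tolerance Absolute tolerance on cell angles, degrees.
#' @param position_tolerance Maximum predicted-to-observed distance, px.
#' @param support_fraction Minimum matched fraction for a supported
#'   indexing solution.
#' @return An object of class `match_params`.
#' @export
match_params <- function(length_tolerance = 0.05, angle_tolerance = 1.5,
                         position_tolerance = 3, support_fraction = 0.5) {
  if (length_tolerance <= 0 || angle_tolerance <= 0 ||
      position_tolerance <= 0) {
    stop("tolerances must be > 0")
  }
  if (support_fraction <= 0 || support_fraction > 1) {
    stop("support_fraction must lie in (0, 1]")
  }
  structure(list(length_tolerance = length_tolerance,
                 angle_tolerance = angle_tolerance,
                 position_tolerance = position_tolerance,
                 support_fraction = support_fraction),
            class = "match_params")
}

#' Spot-integration radii
#'
#' The classic three-radius scheme: sum pixels within `r_int`, estimate
#' background in the `r_bg_inner`..`r_bg_outer` annulus. Defaults 3, 4, 5.
#'
#' @param r_int Integration disc radius, px.
#' @param r_bg_inner,r_bg_outer Background annulus radii, px.
#' @return An object of class `integration_radii`.
#' @export
integration_radii <- function(r_int = 3, r_bg_inner = 4, r_bg_outer = 5) {
  if (!(r_int < r_bg_inner && r_bg_inner < r_bg_outer)) {
    stop("need r_int < r_bg_inner < r_bg_outer")
  }
  structure(list(r_int = r_int, r_bg_inner = r_bg_inner,
                 r_bg_outer = r_bg_outer), class = "integration_radii")
}

#' Are two unit cells equivalent within tolerance?
#'
#' True when every length agrees within `length_tolerance` relatively and
#' every angle within `angle_tolerance` absolutely. Symmetric: the
#' relative length test uses the mean of the two lengths as denominator.
#'
#' @param cell_a,cell_b [unit_cell()] objects.
#' @param params A [match_params()].
#' @return Logical flag.
#' @export
cells_equivalent <- function(cell_a, cell_b, params = match_params()) {
  stopifnot(inherits(cell_a, "unit_cell"), inherits(cell_b, "unit_cell"))
  la <- c(cell_a$a, cell_a$b, cell_a$c)
  lb <- c(cell_b$a, cell_b$b, cell_b$c)
  aa <- c(cell_a$alpha, cell_a$beta, cell_a$gamma)
  ab <- c(cell_b$alpha, cell_b$beta, cell_b$gamma)
  all(abs(la - lb) / ((la + lb) / 2) <= params$length_tolerance) &&
    all(abs(aa - ab) <= params$angle_tolerance)
}

#' Integrate a Bragg spot
#'
#' Background-subtracted disc sum at a predicted position:
#' `sum(pixels within r_int) - n_int * mean(annulus pixels)`, with masked
#' pixels excluded from both regions.
#'
#' @param frame Numeric matrix (slow x fast).
#' @param position `c(fast, slow)`, 0-based pixels; the full outer annulus
#'   must fit inside the frame.
#' @param radii An [integration_radii()].
#' @param mask Optional logical matrix, `TRUE` = excluded.
#' @return Integrated intensity in ADU, or `NA` when the annulus (or the
#'   disc) is fully masked.
#' @export
integrate_spot <- function(frame, position, radii = integration_radii(),
                           mask = NULL) {
  stopifnot(inherits(radii, "integration_radii"))
  ns <- nrow(frame); nf <- ncol(frame)
  r <- radii$r_bg_outer
  if (position[1] - r < 0 || position[1] + r > nf - 1 ||
      position[2] - r < 0 || position[2] + r > ns - 1) {
    stop("position too close to the frame edge for the outer annulus")
  }
  fs <- floor(position[1] - r):ceiling(position[1] + r)
  ss <- floor(position[2] - r):ceiling(position[2] + r)
  dist <- sqrt(outer((ss - position[2])^2, (fs - position[1])^2, "+"))
  sub <- frame[ss + 1L, fs + 1L, drop = FALSE]
  keep <- if (is.null(mask)) TRUE else !mask[ss + 1L, fs + 1L, drop = FALSE]
  disc <- dist <= radii$r_int & keep
  annulus <- dist > radii$r_bg_inner & dist <= radii$r_bg_outer & keep
  if (!any(annulus) || !any(disc)) return(NA_real_)
  sum(sub[disc]) - sum(disc) * mean(sub[annulus])
}

#' Fraction of predicted spots matched by observed peaks
#'
#' Greedy one-to-one matching: predictions are visited in order of
#' decreasing d-spacing (deterministic), each taking its nearest unused
#' observed peak within `position_tolerance`. Returns the matched fraction
#' of predictions; an empty prediction list gives 0 by convention.
#'
#' @param predicted Data frame with `fast`, `slow` (and optionally `d`)
#'   columns, e.g. from [predict_reflections()].
#' @param observed A peak list from [find_peaks()].
#' @param position_tolerance Match radius in pixels.
#' @return Fraction in `[0, 1]`.
#' @export
match_fraction <- function(predicted, observed, position_tolerance = 3) {
  np <- if (is.null(predicted)) 0L else nrow(predicted)
  if (!np) return(0)
  no <- if (is.null(observed)) 0L else nrow(observed)
  if (!no) return(0)
  ord <- if (!is.null(predicted$d)) order(-predicted$d) else seq_len(np)
  used <- rep(FALSE, no)
  matched <- 0L
  for (i in ord) {
    dx <- observed$fast - predicted$fast[i]
    dy <- observed$slow - predicted$slow[i]
    dist2 <- dx^2 + dy^2
    dist2[used] <- Inf
    j <- which.min(dist2)
    if (dist2[j] <= position_tolerance^2) {
      used[j] <- TRUE
      matched <- matched + 1L
    }
  }
  matched / np
}

#' Misindexing (cross-contamination) audit
#'
#' Scores every event against every candidate unit cell: for each event x
#' cell with a candidate orientation, reflections are predicted and the
#' matched fraction against the observed peaks is computed. A solution is
#' "supported" when the fraction reaches `support_fraction`. Events
#' supported only by a foreign cell would indicate cross-contamination;
#' in simulation from a single sample the expected count is zero.
#'
#' @param peaks Named list of peak lists keyed by event id.
#' @param solutions Data frame of candidate solutions: `event_id`,
#'   `cell_label`, and rotation matrix entries `r11`..`r33` (row-major).
#'   See [audit_solutions()] for building one from simulator ground truth.
#' @param cells Named list of [unit_cell()] objects keyed by label.
#' @param geom A [beamline_geometry()].
#' @param params A [match_params()].
#' @param true_labels Optional named character vector (event id ->
#'   generating cell label) used to count foreign-only support.
#' @param excitation_tol,d_min Prediction parameters, as in
#'   [predict_reflections()].
#' @return A list with `table` (event_id, cell_label, n_predicted,
#'   n_matched, match_fraction, supported) and `n_foreign_only`, the
#'   number of events supported exclusively by a cell other than their
#'   generating one (`NA` when `true_labels` is missing).
#' @export
contamination_audit <- function(peaks, solutions, cells, geom,
                                params = match_params(),
                                true_labels = NULL,
                                excitation_tol = 2e-4, d_min = 2.0) {
  rows <- list()
  for (i in seq_len(nrow(solutions))) {
    ev <- as.character(solutions$event_id[i])
    lab <- solutions$cell_label[i]
    if (is.null(cells[[lab]])) stop("no cell with label ", lab)
    R <- matrix(as.numeric(solutions[i, paste0("r", rep(1:3, each = 3),
                                               rep(1:3, 3))]),
                nrow = 3, byrow = TRUE)
    pred <- predict_reflections(cells[[lab]], R, geom,
                                excitation_tol, d_min)
    obs <- peaks[[ev]]
    frac <- match_fraction(pred, obs, params$position_tolerance)
    rows[[i]] <- data.frame(
      event_id = solutions$event_id[i], cell_label = lab,
      n_predicted = nrow(pred),
      n_matched = as.integer(round(frac * nrow(pred))),
      match_fraction = frac,
      supported = frac >= params$support_fraction)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(event_id = integer(0), cell_label = character(0),
               n_predicted = integer(0), n_matched = integer(0),
               match_fraction = numeric(0), supported = logical(0))
  n_foreign <- NA_integer_
  if (!is.null(true_labels) && nrow(tab)) {
    n_foreign <- 0L
    for (ev in unique(tab$event_id)) {
      sub <- tab[tab$event_id == ev, ]
      own <- true_labels[[as.character(ev)]]
      sup <- sub$cell_label[sub$supported]
      if (length(sup) && !is.null(own) && !(own %in% sup)) {
        n_foreign <- n_foreign + 1L
      }
    }
  }
  list(table = tab, n_foreign_only = n_foreign)
}

#' Candidate solutions from simulator ground truth
#'
#' Builds the solutions table for [contamination_audit()]: each event's
#' own crystals keep their true orientations; every foreign cell gets a
#' random orientation (a misindexing candidate, as an indexing program
#' confused by noise would produce).
#'
#' @param run An `sfx_run` from [simulate_run()].
#' @param cells Named list of candidate [unit_cell()] objects.
#' @param event_ids Events to audit (default: all with >= 1 crystal).
#' @return Data frame in the layout [contamination_audit()] expects.
#' @export
audit_solutions <- function(run, cells, event_ids = NULL) {
  stopifnot(inherits(run, "sfx_run"))
  if (is.null(event_ids)) {
    event_ids <- run$events$event_id[run$events$n_crystals > 0]
  }
  rcols <- paste0("r", rep(1:3, each = 3), rep(1:3, 3))
  rows <- list()
  for (ev in event_ids) {
    own <- run$crystals[run$crystals$event_id == ev, , drop = FALSE]
    for (lab in names(cells)) {
      if (nrow(own) && lab == own$cell_label[1]) {
        r <- own[1, rcols]
      } else {
        r <- as.data.frame(matrix(t(random_rotation()), nrow = 1,
                                  dimnames = list(NULL, rcols)))
      }
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(event_id = ev, cell_label = lab), r)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an audit table as CSV
#'
#' @param audit Result of [contamination_audit()].
#' @param path Output CSV path.
#' @export
write_audit <- function(audit, path) {
  utils::write.csv(audit$table, path, row.names = FALSE)
  invisible(path)
}
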