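# Radially averaged Bragg-intensity profiles: shell binning, L2 scaling to
# a reference, run averaging, mean-1 normalization, run comparison.

#' Resolution shell grid
#'
#' Uniform shells in scattering-vector magnitude `q = 1/d` between `d_max`
#' and `d_min` (the crystallographic convention for "uniformly divided
#' resolution shells"); uniform-in-d shells are available via `spacing`.
#'
#' @param n_shells Number of shells (default 30).
#' @param d_max,d_min Resolution range in Angstrom; `d_min < d_max`.
#' @param spacing `"q"` (default) or `"d"`.
#' @return An object of class `shell_grid` with `edges_q` (increasing) and
#'   per-shell d bounds.
#' @export
shell_grid <- function(n_shells = 30, d_max = 20, d_min = 2.0,
                       spacing = c("q", "d")) {
  spacing <- match.arg(spacing)
  if (!(d_min < d_max) || d_min <= 0) stop("need 0 < d_min < d_max")
  if (n_shells < 1) stop("need at least one shell")
  edges_q <- if (spacing == "q") {
    seq(1 / d_max, 1 / d_min, length.out = n_shells + 1)
  } else {
    rev(1 / seq(d_min, d_max, length.out = n_shells + 1))
  }
  structure(list(n_shells = as.integer(n_shells), d_max = d_max,
                 d_min = d_min, spacing = spacing, edges_q = edges_q),
            class = "shell_grid")
}

same_grid <- function(a, b) {
  a$n_shells == b$n_shells && length(a$edges_q) == length(b$edges_q) &&
    all(abs(a$edges_q - b$edges_q) < 1e-12)
}

#' Per-image radial Bragg-intensity profile
#'
#' Averages peak intensities in the resolution shells of `grid`
#' (half-open bins in q: `[edge_i, edge_{i+1})`, with the last shell
#' closed). Peaks outside the grid range are ignored; shells without
#' peaks are unoccupied (`NA` value, occupancy 0).
#'
#' @param peaks A peak list with `intensity` and `d` columns.
#' @param grid A [shell_grid()].
#' @return An object of class `radial_profile`: `grid`, `values` (mean ADU
#'   per shell) and `occupancy` (peak counts).
#' @export
per_image_profile <- function(peaks, grid = shell_grid()) {
  stopifnot(inherits(grid, "shell_grid"))
  values <- rep(NA_real_, grid$n_shells)
  occupancy <- integer(grid$n_shells)
  if (!is.null(peaks) && nrow(peaks)) {
    q <- 1 / peaks$d
    bin <- findInterval(q, grid$edges_q, rightmost.closed = TRUE)
    ok <- bin >= 1 & bin <= grid$n_shells & is.finite(q)
    for (b in unique(bin[ok])) {
      sel <- ok & bin == b
      values[b] <- mean(peaks$intensity[sel])
      occupancy[b] <- sum(sel)
    }
  }
  structure(list(grid = grid, values = values, occupancy = occupancy),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("Radial profile: %d/%d occupied shells, d in (%.2f, %.2f] A\n",
              sum(x$occupancy > 0), x$grid$n_shells, x$grid$d_min,
              x$grid$d_max))
  invisible(x)
}

#' Scale a profile to a reference (closed-form L2)
#'
#' Finds the scale `s* = sum(p_i r_i) / sum(p_i^2)` minimizing the L2
#' distance `sum((s p_i - r_i)^2)` over shells occupied in both profiles.
#'
#' @param profile,reference [per_image_profile()] results on one grid.
#' @return `list(scale, profile)` with the scaled profile, or `NULL` when
#'   no co-occupied shell exists or the profile is identically zero there
#'   (an unscalable image, skipped by [run_profile()]).
#' @export
scale_to_reference <- function(profile, reference) {
  stopifnot(inherits(profile, "radial_profile"),
            inherits(reference, "radial_profile"))
  if (!same_grid(profile$grid, reference$grid)) {
    stop("profile and reference use different shell grids")
  }
  co <- profile$occupancy > 0 & reference$occupancy > 0
  if (!any(co)) return(NULL)
  p <- profile$values[co]; r <- reference$values[co]
  denom <- sum(p^2)
  if (denom == 0) return(NULL)
  s <- sum(p * r) / denom
  scaled <- profile
  scaled$values <- profile$values * s
  list(scale = s, profile = scaled)
}

#' Run-level normalized radial profile
#'
#' The per-run quality curve: every hit's per-image profile is scaled to a
#' reference profile (the first hit by default) by the closed-form L2
#' minimizer, the scaled profiles are averaged shell-wise over the images
#' occupying each shell, and the result is normalized to mean exactly 1
#' over its occupied shells.
#'
#' A first hit occupying fewer than a third of the shells makes a noisy
#' anchor; `reference_rule = "median"` instead uses the shell-wise median
#' profile over all hits. A warning flags a sparse first-hit reference.
#'
#' @param hits List of peak lists, one per hit, in acquisition order.
#' @param grid A [shell_grid()].
#' @param reference_rule `"first"` (default) or `"median"`.
#' @return A normalized `radial_profile`; occupancy counts images (not
#'   peaks) contributing to each shell.
#' @export
run_profile <- function(hits, grid = shell_grid(),
                        reference_rule = c("first", "median")) {
  reference_rule <- match.arg(reference_rule)
  if (!length(hits)) stop("run_profile needs at least one hit")
  profs <- lapply(hits, per_image_profile, grid = grid)
  reference <- if (reference_rule == "first") {
    profs[[1]]
  } else {
    vals <- vapply(profs, function(p) p$values, numeric(grid$n_shells))
    med <- apply(matrix(vals, nrow = grid$n_shells), 1, stats::median,
                 na.rm = TRUE)
    occ <- rowSums(matrix(vapply(profs, function(p) p$occupancy > 0,
                                 logical(grid$n_shells)),
                          nrow = grid$n_shells))
    structure(list(grid = grid, values = med, occupancy = occ),
              class = "radial_profile")
  }
  if (reference_rule == "first" &&
      sum(reference$occupancy > 0) < grid$n_shells / 3) {
    warning("first-hit reference occupies under 1/3 of the shells; ",
            "consider reference_rule = \"median\"")
  }
  acc <- numeric(grid$n_shells)
  n_img <- integer(grid$n_shells)
  for (p in profs) {
    sc <- scale_to_reference(p, reference)
    if (is.null(sc)) next
    occ <- sc$profile$occupancy > 0
    acc[occ] <- acc[occ] + sc$profile$values[occ]
    n_img[occ] <- n_img[occ] + 1L
  }
  if (!any(n_img > 0)) stop("no hit could be scaled to the reference")
  values <- rep(NA_real_, grid$n_shells)
  values[n_img > 0] <- acc[n_img > 0] / n_img[n_img > 0]
  values <- values / mean(values[n_img > 0])
  structure(list(grid = grid, values = values, occupancy = n_img),
            class = "radial_profile")
}

#' Compare two run profiles
#'
#' Per-shell relative difference `|a - b| / ((a + b) / 2)` over shells
#' occupied in both profiles with d-spacing at least `d_limit`, plus the
#' maximum. Because run profiles are mean-1 normalized, a global intensity
#' scale between runs cancels; what remains is shape — e.g. a
#' high-resolution depression from degraded crystals.
#'
#' @param profile_a,profile_b Normalized `radial_profile`s on one grid.
#' @param d_limit Only shells with d >= `d_limit` are compared
#'   (default 2.0 Angstrom).
#' @return `list(rel_diff, d_centers, max_rel_diff, n_shells_compared)`.
#' @export
compare_runs <- function(profile_a, profile_b, d_limit = 2.0) {
  stopifnot(inherits(profile_a, "radial_profile"),
            inherits(profile_b, "radial_profile"))
  if (!same_grid(profile_a$grid, profile_b$grid)) {
    stop("profiles use different shell grids")
  }
  g <- profile_a$grid
  q_mid <- (g$edges_q[-1] + g$edges_q[-length(g$edges_q)]) / 2
  d_mid <- 1 / q_mid
  co <- profile_a$occupancy > 0 & profile_b$occupancy > 0 &
    d_mid >= d_limit
  if (!any(co)) stop("no co-occupied shells at d >= d_limit")
  a <- profile_a$values[co]; b <- profile_b$values[co]
  rel <- abs(a - b) / ((a + b) / 2)
  list(rel_diff = rel, d_centers = d_mid[co], max_rel_diff = max(rel),
       n_shells_compared = sum(co))
}

#' Write a radial profile as CSV
#'
#' Columns: `shell_index, d_lo, d_hi, value, occupancy`.
#'
#' @param profile A `radial_profile`.
#' @param path Output CSV path.
#' @export
write_profile <- function(profile, path) {
  g <- profile$grid
  df <- data.frame(shell_index = seq_len(g$n_shells) - 1L,
                   d_lo = 1 / g$edges_q[-1],
                   d_hi = 1 / g$edges_q[-length(g$edges_q)],
                   value = profile$values,
                   occupancy = profile$occupancy)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
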