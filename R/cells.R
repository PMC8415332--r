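# Unit cells, reciprocal bases, and the sample models used by the simulator.

#' Crystal unit cell
#'
#' @param a,b,c Cell lengths in Angstrom (> 0).
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @param label Sample name attached to the cell.
#' @return An object of class `unit_cell`.
#' @examples
#' unit_cell(100, 100, 100, 90, 90, 90, label = "toy-cubic")
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                      label = "") {
  len <- c(a, b, c); ang <- c(alpha, beta, gamma)
  if (any(!is.finite(len)) || any(len <= 0)) {
    stop("cell lengths must be positive and finite")
  }
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180)) {
    stop("cell angles must lie in (0, 180) degrees")
  }
  cell <- list(a = a, b = b, c = c,
               alpha = alpha, beta = beta, gamma = gamma,
               label = as.character(label))
  class(cell) <- "unit_cell"
  if (cell_volume(cell) <= 0) stop("degenerate cell: non-positive volume")
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("Unit cell%s: a=%.2f b=%.2f c=%.2f A, angles %.1f/%.1f/%.1f deg\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Unit-cell volume
#'
#' @param cell A [unit_cell()].
#' @return Volume in cubic Angstrom.
#' @export
cell_volume <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  arg <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (arg <= 0) return(0)
  cell$a * cell$b * cell$c * sqrt(arg)
}

#' Real-space basis matrix of a cell
#'
#' Columns are the a, b, c lattice vectors in a Cartesian frame
#' (a along x, b in the xy plane).
#'
#' @param cell A [unit_cell()].
#' @return 3x3 matrix, Angstrom.
#' @export
cell_basis <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180); sg <- sin(cell$gamma * pi / 180)
  va <- c(cell$a, 0, 0)
  vb <- c(cell$b * cg, cell$b * sg, 0)
  cx <- cell$c * cb
  cy <- cell$c * (ca - cb * cg) / sg
  cz2 <- cell$c^2 - cx^2 - cy^2
  if (cz2 <= 0) stop("degenerate cell: basis is not right-handed")
  cbind(va, vb, c(cx, cy, sqrt(cz2)), deparse.level = 0)
}

#' Reciprocal basis matrix (B matrix)
#'
#' Columns are the reciprocal lattice vectors a*, b*, c* in the crystal
#' Cartesian frame, in the crystallographic convention |q| = 1/d (no 2 pi).
#' A reciprocal lattice point with Miller indices h is `q = B %*% h`.
#'
#' @param cell A [unit_cell()].
#' @return 3x3 matrix, inverse Angstrom.
#' @export
reciprocal_basis <- function(cell) {
  A <- cell_basis(cell)
  t(solve(A))  # columns a*, b*, c*; satisfies t(B) %*% A = I
}

#' Built-in sample models
#'
#' A small catalogue of sample models for the four protein samples the
#' simulator emulates (thaumatin, proteinase K, xylanase, alcohol
#' dehydrogenase) plus a buffer-only blank. The unit cells are
#' literature-typical synthetic stand-ins, not measured values — treat them
#' as configuration. Concentrations follow the dispensed slurries:
#' 400 crystals/nl for thaumatin and xylanase, 45 crystals/nl (middle of the
#' estimated 40-50 range) for proteinase K and alcohol dehydrogenase.
#'
#' @param name One of `"thaumatin"`, `"proteinase_k"`, `"xylanase"`,
#'   `"alcohol_dehydrogenase"`, `"buffer"`.
#' @return A [sample_model()].
#' @export
default_sample <- function(name = c("thaumatin", "proteinase_k", "xylanase",
                                    "alcohol_dehydrogenase", "buffer")) {
  name <- match.arg(name)
  switch(name,
    thaumatin = sample_model(
      name = "thaumatin",
      cell = unit_cell(57.8, 57.8, 150.1, 90, 90, 90, label = "thaumatin"),
      concentration_per_nl = 400),
    proteinase_k = sample_model(
      name = "proteinase_k",
      cell = unit_cell(68.2, 68.2, 108.3, 90, 90, 90, label = "proteinase_k"),
      concentration_per_nl = 45),
    xylanase = sample_model(
      name = "xylanase",
      cell = unit_cell(49.8, 59.8, 70.1, 90, 90, 90, label = "xylanase"),
      concentration_per_nl = 400),
    alcohol_dehydrogenase = sample_model(
      name = "alcohol_dehydrogenase",
      cell = unit_cell(55.5, 73.1, 92.7, 90, 90, 90,
                       label = "alcohol_dehydrogenase"),
      concentration_per_nl = 45),
    buffer = sample_model(
      name = "buffer",
      cell = unit_cell(100, 100, 100, label = "buffer"),
      concentration_per_nl = 0, peak_scale_i0 = 0, is_buffer_only = TRUE)
  )
}

#' Sample model for the simulator
#'
#' Bundles a unit cell with the slurry concentration and a two-parameter
#' intensity model: reflections carry an expected photon count
#' `I0 * exp(-B / (2 d^2))` (Debye-Waller-like falloff with a single
#' b-factor).
#'
#' @param name Sample name.
#' @param cell A [unit_cell()].
#' @param concentration_per_nl Crystal number density, crystals per nl.
#' @param peak_scale_i0 Expected photons in a reflection at infinite d.
#' @param b_factor Intensity falloff parameter, square Angstrom.
#' @param is_buffer_only If `TRUE`, the sample carries no crystals.
#' @return An object of class `sample_model`.
#' @export
sample_model <- function(name, cell, concentration_per_nl,
                         peak_scale_i0 = 400, b_factor = 15,
                         is_buffer_only = FALSE) {
  stopifnot(inherits(cell, "unit_cell"))
  if (concentration_per_nl < 0) stop("concentration must be >= 0")
  if (!is_buffer_only && peak_scale_i0 <= 0) {
    stop("peak_scale_i0 must be > 0 for a crystal-bearing sample")
  }
  structure(list(name = name, cell = cell,
                 concentration_per_nl = concentration_per_nl,
                 peak_scale_i0 = peak_scale_i0, b_factor = b_factor,
                 is_buffer_only = isTRUE(is_buffer_only)),
            class = "sample_model")
}
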