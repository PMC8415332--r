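# Uniform random rotations via unit quaternions.

#' Random rotation matrix
#'
#' Draws a rotation uniformly over SO(3) by normalizing a 4-vector of
#' standard normals to a unit quaternion.
#'
#' @param n Number of rotations.
#' @return A single 3x3 rotation matrix if `n == 1`, else a list of them.
#' @export
random_rotation <- function(n = 1) {
  out <- vector("list", n)
  for (i in seq_len(n)) {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    out[[i]] <- quaternion_to_matrix(q)
  }
  if (n == 1) out[[1]] else out
}

quaternion_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}
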