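# Small geometric helpers shared across the package. All lengths are mm,
# forces N, stresses MPa, angles degrees at the interfaces (radians inside).

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalise a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation matrix for a right-handed rotation of `angle_deg`
#' degrees about the (not necessarily unit) direction `axis`.
#'
#' @param axis length-3 direction vector of the rotation axis.
#' @param angle_deg rotation angle in degrees (right-hand rule).
#' @return a 3x3 rotation matrix.
#' @keywords internal
rotation_matrix <- function(axis, angle_deg) {
  e <- unit(axis)
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, e[3], -e[2],
                -e[3], 0, e[1],
                e[2], -e[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Rotate points (n x 3) about a line through `origin` with direction `axis`.
rotate_points <- function(pts, axis, angle_deg, origin = c(0, 0, 0)) {
  R <- rotation_matrix(axis, angle_deg)
  sweep(sweep(pts, 2, origin) %*% t(R), 2, origin, "+")
}

# Deterministic formatting used by all CSV writers so that identical runs
# produce byte-identical files.
num_fmt <- function(x, digits = 10) {
  formatC(x, digits = digits, format = "g")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_craniofem <- function(msg, class) {
  stop(structured_error(msg, class))
}

structured_error <- function(msg, class) {
  structure(class = c(class, "craniofem_error", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}
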