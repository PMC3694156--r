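#' Area-consistent nodal loads on a mesh face
#'
#' Distributes a total force over the nodes of a (plane or curved) surface
#' patch in proportion to tributary triangle areas (one third of each
#' incident triangle), i.e. the consistent nodal loads of a uniform
#' traction. Required for closed-form checks such as sigma = F/A on a bar.
#'
#' @param mesh a [tet_mesh()].
#' @param nodes node indices spanning the loaded face.
#' @param force total length-3 force vector (N) to distribute.
#' @return an `n x 6` load matrix (rows beyond the mesh are absent).
#' @export
face_load <- function(mesh, nodes, force) {
  tri <- extract_surface(mesh)
  on_face <- matrix(tri %in% nodes, ncol = 3)
  tri <- tri[rowSums(on_face) == 3L, , drop = FALSE]
  if (!nrow(tri)) stop_craniofem("node set spans no surface triangles", "craniofem_bad_input")
  ar <- triangle_areas(mesh$nodes, tri)
  w <- numeric(nrow(mesh$nodes))
  for (k in 1:3) {
    acc <- tapply(ar / 3, tri[, k], sum)
    w[as.integer(names(acc))] <- w[as.integer(names(acc))] + acc
  }
  w <- w / sum(w)
  f <- matrix(0, nrow(mesh$nodes), 6)
  f[, 1] <- w * force[1]; f[, 2] <- w * force[2]; f[, 3] <- w * force[3]
  f
}
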