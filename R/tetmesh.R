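#' Tetrahedral mesh with region labels
#'
#' Container for a volumetric mesh of four-noded (tet4) elements. Each
#' element carries a region label (`"bone"`, `"dentine"` or `"enamel"`)
#' so that distinct material properties can be assigned to canine dentine,
#' enamel shells and cortical bone. Named node sets and named surface
#' patches (triangle index matrices) ride along with the mesh and are used
#' for constraints, muscle attachment and articular surfaces.
#'
#' @param nodes numeric matrix `n x 3` of node coordinates (mm).
#' @param tets integer matrix `m x 4` of 1-based node indices. Every
#'   tetrahedron must be positively oriented (signed volume > 0).
#' @param region character vector of length `m` (or 1, recycled) of region
#'   labels per element.
#' @param node_sets named list of integer vectors (node indices).
#' @param patches named list of integer matrices `k x 3`, each row a surface
#'   triangle (outward orientation).
#' @return an object of class `tet_mesh`.
#' @seealso [validate_tet_mesh()], [extract_surface()]
#' @export
tet_mesh <- function(nodes, tets, region = "bone",
                     node_sets = list(), patches = list()) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  dimnames(nodes) <- NULL
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  if (ncol(nodes) != 3L) stop_craniofem("nodes must be an n x 3 matrix", "craniofem_bad_mesh")
  if (ncol(tets) != 4L) stop_craniofem("tets must be an m x 4 matrix", "craniofem_bad_mesh")
  region <- rep_len(as.character(region), nrow(tets))
  structure(list(nodes = nodes, tets = tets, region = region,
                 node_sets = node_sets, patches = patches),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet_mesh: %d nodes, %d tets (%s)\n",
              nrow(x$nodes), nrow(x$tets),
              paste(sprintf("%s=%d", names(table(x$region)), table(x$region)),
                    collapse = ", ")))
  if (length(x$node_sets)) cat(" node sets:", paste(names(x$node_sets), collapse = ", "), "\n")
  if (length(x$patches)) cat(" patches:", paste(names(x$patches), collapse = ", "), "\n")
  invisible(x)
}

#' Signed volumes of all tetrahedra
#'
#' @param mesh a [tet_mesh()].
#' @return numeric vector of signed volumes (mm^3); positive for correctly
#'   oriented elements.
#' @export
tet_volumes <- function(mesh) {
  nd <- mesh$nodes
  t1 <- mesh$tets[, 1]; t2 <- mesh$tets[, 2]
  t3 <- mesh$tets[, 3]; t4 <- mesh$tets[, 4]
  a <- nd[t2, , drop = FALSE] - nd[t1, , drop = FALSE]
  b <- nd[t3, , drop = FALSE] - nd[t1, , drop = FALSE]
  d <- nd[t4, , drop = FALSE] - nd[t1, , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  (cx * d[, 1] + cy * d[, 2] + cz * d[, 3]) / 6
}

#' Validate mesh invariants
#'
#' Checks that all tetrahedra are positively oriented, that no node is
#' orphaned, and that every element carries a region label.
#'
#' @param mesh a [tet_mesh()].
#' @param check_watertight also require the extracted boundary surface to be
#'   closed (every boundary edge shared by exactly two boundary triangles).
#' @return `TRUE` invisibly; otherwise a structured error.
#' @export
validate_tet_mesh <- function(mesh, check_watertight = FALSE) {
  v <- tet_volumes(mesh)
  if (any(v <= 0)) {
    stop_craniofem(sprintf("%d tetrahedra have non-positive volume (first at index %d)",
                           sum(v <= 0), which(v <= 0)[1]), "craniofem_bad_mesh")
  }
  used <- unique(as.vector(mesh$tets))
  if (length(used) != nrow(mesh$nodes)) {
    stop_craniofem(sprintf("%d orphan nodes present", nrow(mesh$nodes) - length(used)),
                   "craniofem_bad_mesh")
  }
  if (anyNA(mesh$region) || any(!nzchar(mesh$region))) {
    stop_craniofem("region labels must cover all tets", "craniofem_bad_mesh")
  }
  if (check_watertight) {
    tri <- extract_surface(mesh)
    ed <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
    key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
    if (any(table(key) != 2)) {
      stop_craniofem("extracted surface is not watertight", "craniofem_bad_mesh")
    }
  }
  invisible(TRUE)
}

#' Extract the boundary surface of a tet mesh
#'
#' Boundary triangles are the faces that belong to exactly one tetrahedron;
#' they are returned with outward orientation (normals point out of the
#' solid).
#'
#' @param mesh a [tet_mesh()].
#' @return integer matrix `k x 3` of node indices.
#' @export
extract_surface <- function(mesh) {
  tt <- mesh$tets
  # Outward faces of a positively oriented tet (a, b, c, d):
  faces <- rbind(tt[, c(1, 3, 2)], tt[, c(1, 2, 4)],
                 tt[, c(1, 4, 3)], tt[, c(2, 3, 4)])
  key <- paste(pmin(faces[, 1], pmin(faces[, 2], faces[, 3])),
               faces[, 1] + faces[, 2] + faces[, 3],
               pmax(faces[, 1], pmax(faces[, 2], faces[, 3])))
  faces[key %in% names(which(table(key) == 1)), , drop = FALSE]
}

# Areas and (area-weighted) normals of surface triangles.
triangle_areas <- function(nodes, tri) {
  a <- nodes[tri[, 2], , drop = FALSE] - nodes[tri[, 1], , drop = FALSE]
  b <- nodes[tri[, 3], , drop = FALSE] - nodes[tri[, 1], , drop = FALSE]
  nx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  ny <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  nz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sqrt(nx^2 + ny^2 + nz^2) / 2
}

triangle_normals <- function(nodes, tri, normalise = TRUE) {
  a <- nodes[tri[, 2], , drop = FALSE] - nodes[tri[, 1], , drop = FALSE]
  b <- nodes[tri[, 3], , drop = FALSE] - nodes[tri[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  if (normalise) n / pmax(sqrt(rowSums(n^2)), .Machine$double.xmin) else n
}

#' Structured box lattice meshed into tetrahedra
#'
#' Meshes the unit box divided into `nx x ny x nz` cells, each cell split
#' into six tetrahedra along its main diagonal (Kuhn subdivision, conforming
#' across cell faces), and then maps grid vertices through `mapping`. This is
#' the structural primitive behind all synthetic geometry: bars, wedge
#' crania, curved canines.
#'
#' @param nx,ny,nz number of cells along each axis.
#' @param mapping function taking an `n x 3` matrix of unit-cube coordinates
#'   and returning mapped `n x 3` coordinates; default identity.
#' @param region region label for all elements.
#' @param grid optional list with components `x`, `y`, `z` giving the
#'   (monotone) parametric grid lines in `[0, 1]`; defaults to uniform.
#' @return a [tet_mesh()] whose `node_sets` contain the six box faces
#'   (`xmin`, `xmax`, `ymin`, `ymax`, `zmin`, `zmax`) in parametric space,
#'   and whose attribute `grid_shape` stores `c(nx, ny, nz) + 1`.
#' @export
mesh_box_lattice <- function(nx, ny, nz, mapping = NULL, region = "bone",
                             grid = NULL) {
  if (min(nx, ny, nz) < 1) stop_craniofem("divisions must be >= 1", "craniofem_bad_input")
  gx <- grid$x %||% seq(0, 1, length.out = nx + 1)
  gy <- grid$y %||% seq(0, 1, length.out = ny + 1)
  gz <- grid$z %||% seq(0, 1, length.out = nz + 1)
  nxp <- length(gx); nyp <- length(gy); nzp <- length(gz)
  idx <- function(i, j, k) i + (j - 1L) * nxp + (k - 1L) * nxp * nyp
  pts <- cbind(rep(gx, times = nyp * nzp),
               rep(rep(gy, each = nxp), times = nzp),
               rep(gz, each = nxp * nyp))
  # Six Kuhn tets per cell: monotone lattice paths 000 -> 111, one per
  # permutation of the axes; identical in every cell, hence conforming.
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  ii <- rep(seq_len(nxp - 1L), times = (nyp - 1L) * (nzp - 1L))
  jj <- rep(rep(seq_len(nyp - 1L), each = nxp - 1L), times = nzp - 1L)
  kk <- rep(seq_len(nzp - 1L), each = (nxp - 1L) * (nyp - 1L))
  corner <- function(di, dj, dk) idx(ii + di, jj + dj, kk + dk)
  tet_list <- vector("list", 6L)
  for (p in seq_along(perms)) {
    steps <- perms[[p]]
    d <- matrix(0L, 4L, 3L)
    d[2L, steps[1L]] <- 1L
    d[3L, steps[1L]] <- 1L; d[3L, steps[2L]] <- 1L
    d[4L, ] <- 1L
    tet_list[[p]] <- cbind(corner(d[1, 1], d[1, 2], d[1, 3]),
                           corner(d[2, 1], d[2, 2], d[2, 3]),
                           corner(d[3, 1], d[3, 2], d[3, 3]),
                           corner(d[4, 1], d[4, 2], d[4, 3]))
  }
  tets <- do.call(rbind, tet_list)
  if (!is.null(mapping)) pts <- mapping(pts)
  m <- tet_mesh(pts, tets, region = region)
  # Fix orientation element-wise (mappings may mirror).
  v <- tet_volumes(m)
  if (any(v < 0)) {
    flip <- v < 0
    m$tets[flip, c(3, 4)] <- m$tets[flip, c(4, 3)]
  }
  tol <- 1e-9
  m$node_sets <- list(
    xmin = which(pts_face(pts, nxp, nyp, nzp, 1, 1L)),
    xmax = which(pts_face(pts, nxp, nyp, nzp, 1, nxp)),
    ymin = which(pts_face(pts, nxp, nyp, nzp, 2, 1L)),
    ymax = which(pts_face(pts, nxp, nyp, nzp, 2, nyp)),
    zmin = which(pts_face(pts, nxp, nyp, nzp, 3, 1L)),
    zmax = which(pts_face(pts, nxp, nyp, nzp, 3, nzp)))
  attr(m, "grid_shape") <- c(nxp, nyp, nzp)
  m
}

# Logical mask of lattice nodes on a given grid face (by construction order,
# independent of the mapping).
pts_face <- function(pts, nxp, nyp, nzp, axis, layer) {
  n <- nxp * nyp * nzp
  i <- ((seq_len(n) - 1L) %% nxp) + 1L
  j <- (((seq_len(n) - 1L) %/% nxp) %% nyp) + 1L
  k <- ((seq_len(n) - 1L) %/% (nxp * nyp)) + 1L
  switch(axis, i == layer, j == layer, k == layer)
}

#' Rectangular bar fixture for solver validation
#'
#' A `length x side x side` mm bar meshed into tetrahedra with the two end
#' faces tagged as node sets `"fixed"` (at x = 0) and `"loaded"` (at
#' x = length). Used for closed-form axial-stress checks (sigma = F/A).
#'
#' @param length,side bar dimensions in mm (must be positive).
#' @param n_divisions number of cells along the length (>= 1); the
#'   cross-section is divided to keep cells near-cubic.
#' @return a [tet_mesh()] with node sets `fixed` and `loaded`.
#' @export
make_bar_fixture <- function(length, side, n_divisions) {
  if (length <= 0 || side <= 0) stop_craniofem("bar dimensions must be positive", "craniofem_bad_input")
  if (n_divisions < 1) stop_craniofem("n_divisions must be >= 1", "craniofem_bad_input")
  ns <- max(1L, round(n_divisions * side / length))
  m <- mesh_box_lattice(n_divisions, ns, ns,
                        mapping = function(p) cbind(p[, 1] * length,
                                                    p[, 2] * side,
                                                    p[, 3] * side))
  m$node_sets <- list(fixed = m$node_sets$xmin, loaded = m$node_sets$xmax)
  m
}

#' Cantilever fixture for beam-theory validation
#'
#' Identical geometry to [make_bar_fixture()] but intended for transverse
#' tip loading: the `fixed` face is clamped in full and the `loaded` set
#' receives a transverse (+y) tip load, for comparison against the
#' Euler-Bernoulli deflection delta = F L^3 / (3 E I).
#'
#' @inheritParams make_bar_fixture
#' @return a [tet_mesh()] with node sets `fixed` and `loaded`.
#' @export
make_cantilever_fixture <- function(length, side, n_divisions) {
  make_bar_fixture(length, side, n_divisions)
}

# Append mesh b to mesh a (disconnected components; used to combine a
# cranium block with separately meshed canines). Node sets and patches of b
# are re-indexed and prefixed.
merge_tet_meshes <- function(a, b, prefix = NULL) {
  off <- nrow(a$nodes)
  sets_b <- lapply(b$node_sets, function(s) s + off)
  pat_b <- lapply(b$patches, function(p) p + off)
  if (!is.null(prefix) && length(sets_b)) names(sets_b) <- paste0(prefix, names(sets_b))
  if (!is.null(prefix) && length(pat_b)) names(pat_b) <- paste0(prefix, names(pat_b))
  tet_mesh(rbind(a$nodes, b$nodes), rbind(a$tets, b$tets + off),
           region = c(a$region, b$region),
           node_sets = c(a$node_sets, sets_b),
           patches = c(a$patches, pat_b))
}
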