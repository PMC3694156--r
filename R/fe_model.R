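#' Finite-element model container
#'
#' Holds nodes, tet4 solid elements with material assignments, pretensioned
#' truss elements, beams, rigid links, nodal constraints and nodal loads.
#' Every node carries six degrees of freedom (three translations, three
#' rotations); rotational DOFs that receive no stiffness from any beam or
#' rigid link are automatically suppressed at assembly.
#'
#' @param nodes numeric `n x 3` matrix of coordinates (mm).
#' @param materials named list of [material()] objects.
#' @return an object of class `fe_model`.
#' @export
fe_model <- function(nodes, materials = default_materials()) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  structure(list(nodes = nodes, materials = materials,
                 tets = NULL, tet_material = character(), tet_region = character(),
                 trusses = list(), beams = list(), rigid_links = list(),
                 constraints = list(), loads = NULL),
            class = "fe_model")
}

#' Build an FE model from a labelled tet mesh
#'
#' @param mesh a [tet_mesh()]; region labels select materials by name.
#' @param materials named list of [material()]; must cover every region.
#' @return an `fe_model`.
#' @export
fe_from_mesh <- function(mesh, materials = default_materials()) {
  mod <- fe_model(mesh$nodes, materials)
  add_tets(mod, mesh$tets, region = mesh$region)
}

#' Add tet4 elements
#'
#' @param model an [fe_model()].
#' @param tets integer `m x 4` connectivity.
#' @param region character region labels (used as material names).
#' @param material optional material name overriding `region`.
#' @return the updated model.
#' @export
add_tets <- function(model, tets, region = "bone", material = NULL) {
  region <- rep_len(region, nrow(tets))
  mat <- material %||% region
  mat <- rep_len(mat, nrow(tets))
  missing <- setdiff(unique(mat), names(model$materials))
  if (length(missing)) {
    stop_craniofem(paste0("no material defined for region(s): ",
                          paste(missing, collapse = ", ")), "craniofem_bad_material")
  }
  model$tets <- rbind(model$tets, as.matrix(tets))
  model$tet_material <- c(model$tet_material, mat)
  model$tet_region <- c(model$tet_region, region)
  model
}

#' Add extra (non-mesh) nodes
#'
#' Appends nodes (web centres, hinge axis points, muscle via-points) and
#' returns their indices in `attr(, "new_nodes")`.
#'
#' @param model an [fe_model()].
#' @param pts numeric `k x 3` matrix.
#' @return the updated model with attribute `new_nodes`.
#' @export
add_nodes <- function(model, pts) {
  pts <- matrix(pts, ncol = 3)
  idx <- nrow(model$nodes) + seq_len(nrow(pts))
  model$nodes <- rbind(model$nodes, pts)
  attr(model, "new_nodes") <- idx
  model
}

#' Add a pretensioned truss element
#'
#' Axial-force-only two-node element. The pretension is imposed as a pair
#' of equal and opposite collinear nodal forces of the stated magnitude
#' pulling the nodes together (constant-force linear treatment, no
#' geometric stiffness update).
#'
#' @param model an [fe_model()].
#' @param n1,n2 node indices (distinct).
#' @param area cross-section (mm^2, > 0).
#' @param E Young's modulus (MPa).
#' @param pretension axial pretension (N, >= 0).
#' @param group optional group tag (muscle name).
#' @return the updated model.
#' @export
add_truss <- function(model, n1, n2, area = 1, E = 10, pretension = 0, group = "") {
  if (n1 == n2) stop_craniofem("truss nodes must be distinct", "craniofem_bad_element")
  if (area <= 0) stop_craniofem("truss cross_section must be > 0", "craniofem_bad_element")
  if (pretension < 0) stop_craniofem("pretension must be >= 0", "craniofem_bad_element")
  model$trusses[[length(model$trusses) + 1L]] <-
    list(n1 = as.integer(n1), n2 = as.integer(n2), area = area, E = E,
         pretension = pretension, group = group)
  model
}

#' Add a beam element
#'
#' Three-dimensional Euler-Bernoulli beam with axial, bending and torsional
#' stiffness. `release_torsion = TRUE` removes the torsional coupling about
#' the beam axis (the rotational end release used by the jaw-hinge pivot).
#'
#' @param model an [fe_model()].
#' @param n1,n2 node indices.
#' @param A cross-section area (mm^2).
#' @param Iy,Iz second moments of area (mm^4).
#' @param J torsion constant (mm^4).
#' @param E Young's modulus (MPa); `nu` sets the shear modulus.
#' @param nu Poisson's ratio.
#' @param release_torsion drop the torsional stiffness about the beam axis.
#' @return the updated model.
#' @export
add_beam <- function(model, n1, n2, A, Iy, Iz, J, E = 20000, nu = 0.3,
                     release_torsion = FALSE) {
  if (min(A, Iy, Iz, J) <= 0) stop_craniofem("beam section properties must be positive",
                                             "craniofem_bad_element")
  model$beams[[length(model$beams) + 1L]] <-
    list(n1 = as.integer(n1), n2 = as.integer(n2), A = A, Iy = Iy, Iz = Iz,
         J = J, E = E, nu = nu, release_torsion = isTRUE(release_torsion))
  model
}

#' Add a rigid link
#'
#' Kinematic constraint slaving one or more nodes to a master node: slaves
#' move as a rigid body with the master. Implemented by exact master-slave
#' DOF elimination, not by penalty stiffness.
#'
#' @param model an [fe_model()].
#' @param master master node index.
#' @param slaves integer vector of slave node indices.
#' @return the updated model.
#' @export
add_rigid_link <- function(model, master, slaves) {
  slaves <- as.integer(slaves)
  prev <- unlist(lapply(model$rigid_links, `[[`, "slaves"))
  if (any(slaves %in% prev)) {
    stop_craniofem("a slave node appears in two rigid links", "craniofem_bad_element")
  }
  if (master %in% slaves) {
    stop_craniofem("a rigid link cannot slave its own master", "craniofem_bad_element")
  }
  model$rigid_links[[length(model$rigid_links) + 1L]] <-
    list(master = as.integer(master), slaves = slaves)
  model
}

# Resolve rigid-link chains (A <- B <- C) to their root masters: a chain of
# rigid maps composes to a single rigid map about the root, so each slave
# can be tied directly to its root master. Cycles are rejected.
resolve_rigid_links <- function(links, nnode) {
  master_of <- integer(nnode)           # 0 = not a slave
  for (rl in links) master_of[rl$slaves] <- rl$master
  root <- function(n) {
    seen <- integer(0)
    while (master_of[n] != 0L) {
      if (n %in% seen) {
        stop_craniofem("rigid links form a cycle", "craniofem_bad_element")
      }
      seen <- c(seen, n)
      n <- master_of[n]
    }
    n
  }
  out <- list()
  for (rl in links) {
    r <- root(rl$master)
    key <- as.character(r)
    out[[key]] <- c(out[[key]], rl$slaves)
  }
  lapply(names(out), function(k) list(master = as.integer(k),
                                      slaves = as.integer(out[[k]])))
}

#' Constrain nodal degrees of freedom
#'
#' @param model an [fe_model()].
#' @param nodes node indices.
#' @param dofs subset of 1:6 (1-3 translations x,y,z; 4-6 rotations).
#' @return the updated model.
#' @export
add_constraint <- function(model, nodes, dofs = 1:3) {
  dofs <- as.integer(dofs)
  if (!length(dofs) || any(dofs < 1 | dofs > 6)) {
    stop_craniofem("dofs must be a non-empty subset of 1:6", "craniofem_bad_constraint")
  }
  for (n in nodes) {
    model$constraints[[length(model$constraints) + 1L]] <-
      list(node = as.integer(n), dofs = dofs)
  }
  model
}

#' Add nodal loads
#'
#' @param model an [fe_model()].
#' @param node node index.
#' @param force length-3 force (N) or length-6 force/moment (N, N mm).
#' @return the updated model.
#' @export
add_load <- function(model, node, force) {
  if (is.null(model$loads)) model$loads <- matrix(0, nrow(model$nodes), 6)
  if (nrow(model$loads) < nrow(model$nodes)) {
    model$loads <- rbind(model$loads,
                         matrix(0, nrow(model$nodes) - nrow(model$loads), 6))
  }
  f <- c(force, rep(0, 6 - length(force)))
  model$loads[node, ] <- model$loads[node, ] + f
  model
}

#' Equivalent nodal load pair of a pretensioned truss
#'
#' Converts the pretension of a truss element into the pair of equal and
#' opposite collinear nodal forces along the current truss axis, each of
#' magnitude equal to the pretension, pulling the two nodes together. The
#' scalar force budget of a truss set is therefore `count x pretension`.
#'
#' @param model an [fe_model()] (for node coordinates).
#' @param truss a truss element as stored in `model$trusses`.
#' @return a list with `node1`, `node2` and their length-3 force vectors.
#' @export
apply_pretension <- function(model, truss) {
  d <- model$nodes[truss$n2, ] - model$nodes[truss$n1, ]
  L <- vnorm(d)
  if (L < 1e-9) stop_craniofem("zero-length truss cannot carry pretension",
                               "craniofem_bad_element")
  e <- d / L
  list(node1 = truss$n1, force1 = truss$pretension * e,
       node2 = truss$n2, force2 = -truss$pretension * e)
}

# Accumulate pretension load pairs of all trusses into an n x 6 load matrix.
pretension_loads <- function(model) {
  f <- matrix(0, nrow(model$nodes), 6)
  for (tr in model$trusses) {
    if (tr$pretension == 0) next
    p <- apply_pretension(model, tr)
    f[p$node1, 1:3] <- f[p$node1, 1:3] + p$force1
    f[p$node2, 1:3] <- f[p$node2, 1:3] + p$force2
  }
  f
}
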