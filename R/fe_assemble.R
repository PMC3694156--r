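# Element stiffness matrices and global assembly.
#
# DOF layout: node i owns global DOFs 6*(i-1) + (1..6): translations x, y, z
# then rotations x, y, z. Tet4 solids contribute translational stiffness
# only; rotational DOFs that stay unloaded after assembly and rigid-link
# reduction are suppressed automatically (exact, no penalty terms).

tet_bmatrix <- function(X) {
  A <- cbind(1, X)
  C <- solve(A)                       # rows: 1, x, y, z coefficients
  B <- matrix(0, 6, 12)
  for (i in 1:4) {
    b <- C[2, i]; c <- C[3, i]; d <- C[4, i]
    col <- 3 * (i - 1)
    B[1, col + 1] <- b
    B[2, col + 2] <- c
    B[3, col + 3] <- d
    B[4, col + 1] <- c; B[4, col + 2] <- b
    B[5, col + 2] <- d; B[5, col + 3] <- c
    B[6, col + 1] <- d; B[6, col + 3] <- b
  }
  B
}

tet_stiffness <- function(X, D) {
  V <- det(cbind(1, X)) / 6
  B <- tet_bmatrix(X)
  list(K = V * crossprod(B, D %*% B), B = B, V = V)
}

truss_stiffness <- function(x1, x2, E, A) {
  d <- x2 - x1
  L <- vnorm(d)
  e <- d / L
  k <- (E * A / L) * tcrossprod(e)
  K <- matrix(0, 6, 6)
  K[1:3, 1:3] <- k; K[4:6, 4:6] <- k
  K[1:3, 4:6] <- -k; K[4:6, 1:3] <- -k
  K
}

beam_local_axes <- function(d) {
  ex <- unit(d)
  ref <- if (abs(ex[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  ey <- unit(cross3(ref, ex))
  ez <- cross3(ex, ey)
  rbind(ex, ey, ez)
}

beam_stiffness <- function(x1, x2, bm) {
  d <- x2 - x1
  L <- vnorm(d)
  if (L < 1e-9) stop_craniofem("zero-length beam", "craniofem_bad_element")
  E <- bm$E; G <- bm$E / (2 * (1 + bm$nu))
  K <- matrix(0, 12, 12)
  a <- E * bm$A / L
  K[1, 1] <- K[7, 7] <- a; K[1, 7] <- K[7, 1] <- -a
  if (!bm$release_torsion) {
    t <- G * bm$J / L
    K[4, 4] <- K[10, 10] <- t; K[4, 10] <- K[10, 4] <- -t
  }
  bend <- function(I, dofs, sgn) {
    c1 <- 12 * E * I / L^3; c2 <- 6 * E * I / L^2
    c3 <- 4 * E * I / L;    c4 <- 2 * E * I / L
    kb <- matrix(c(c1,  sgn * c2, -c1,  sgn * c2,
                   sgn * c2, c3, -sgn * c2, c4,
                   -c1, -sgn * c2, c1, -sgn * c2,
                   sgn * c2, c4, -sgn * c2, c3), 4, 4, byrow = TRUE)
    K[dofs, dofs] <<- K[dofs, dofs] + kb
  }
  bend(bm$Iz, c(2, 6, 8, 12), +1)   # deflection in local y, rotation about z
  bend(bm$Iy, c(3, 5, 9, 11), -1)   # deflection in local z, rotation about y
  R <- beam_local_axes(d)
  Lam <- matrix(0, 12, 12)
  for (blk in 0:3) Lam[blk * 3 + 1:3, blk * 3 + 1:3] <- R
  crossprod(Lam, K %*% Lam)
}

cross_mat <- function(d) {
  matrix(c(0, -d[3], d[2],
           d[3], 0, -d[1],
           -d[2], d[1], 0), 3, 3, byrow = TRUE)
}

node_dofs <- function(n) rep(6L * (n - 1L), each = 6L) + rep(1:6, length(n))

#' Assemble the global linear system
#'
#' Builds the symmetric stiffness matrix from all tet4, truss and beam
#' elements, eliminates rigid-link slave DOFs exactly via a kinematic
#' transformation, applies nodal constraints, and suppresses rotational
#' DOFs that carry no stiffness. The result is cached for repeated solves.
#'
#' @param model an [fe_model()].
#' @return a list of class `fe_system` with the reduced stiffness, the
#'   full-to-reduced transformation and DOF bookkeeping.
#' @export
assemble <- function(model) {
  nnode <- nrow(model$nodes)
  ndof <- 6L * nnode
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  push <- function(dofs, K) {
    nz <- which(K != 0, arr.ind = TRUE)
    ii <<- c(ii, dofs[nz[, 1]])
    jj <<- c(jj, dofs[nz[, 2]])
    xx <<- c(xx, K[nz])
  }
  # tets
  if (!is.null(model$tets) && nrow(model$tets)) {
    Dmats <- lapply(model$materials, function(m) elasticity_matrix(m$E, m$nu))
    ntet <- nrow(model$tets)
    ti <- vector("list", ntet); tj <- vector("list", ntet); tx <- vector("list", ntet)
    for (e in seq_len(ntet)) {
      nd <- model$tets[e, ]
      X <- model$nodes[nd, , drop = FALSE]
      ke <- tet_stiffness(X, Dmats[[model$tet_material[e]]])$K
      dofs <- as.vector(t(outer(6L * (nd - 1L), 1:3, `+`)))
      ti[[e]] <- rep(dofs, times = 12)
      tj[[e]] <- rep(dofs, each = 12)
      tx[[e]] <- as.vector(ke)
    }
    ii <- c(ii, unlist(ti)); jj <- c(jj, unlist(tj)); xx <- c(xx, unlist(tx))
  }
  for (tr in model$trusses) {
    Kt <- truss_stiffness(model$nodes[tr$n1, ], model$nodes[tr$n2, ], tr$E, tr$area)
    dofs <- c(6L * (tr$n1 - 1L) + 1:3, 6L * (tr$n2 - 1L) + 1:3)
    push(dofs, Kt)
  }
  for (bm in model$beams) {
    Kb <- beam_stiffness(model$nodes[bm$n1, ], model$nodes[bm$n2, ], bm)
    dofs <- c(6L * (bm$n1 - 1L) + 1:6, 6L * (bm$n2 - 1L) + 1:6)
    push(dofs, Kb)
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ndof, ndof))

  # Rigid-link elimination: u_full = T u_reduced (chains resolved to roots).
  links <- resolve_rigid_links(model$rigid_links, nnode)
  slave_nodes <- unlist(lapply(links, `[[`, "slaves"))
  slave_dofs <- if (length(slave_nodes)) node_dofs(slave_nodes) else integer(0)
  keep <- setdiff(seq_len(ndof), slave_dofs)
  colmap <- integer(ndof)
  colmap[keep] <- seq_along(keep)
  ti <- keep; tjj <- colmap[keep]; tx <- rep(1, length(keep))
  for (rl in links) {
    m <- rl$master
    mdof <- 6L * (m - 1L) + 1:6
    for (s in rl$slaves) {
      d <- model$nodes[s, ] - model$nodes[m, ]
      blk <- matrix(0, 6, 6)
      blk[1:3, 1:3] <- diag(3)
      blk[1:3, 4:6] <- -cross_mat(d)   # u_s = u_m + theta_m x d
      blk[4:6, 4:6] <- diag(3)
      sdof <- 6L * (s - 1L) + 1:6
      nz <- which(blk != 0, arr.ind = TRUE)
      ti <- c(ti, sdof[nz[, 1]])
      tjj <- c(tjj, colmap[mdof][nz[, 2]])
      tx <- c(tx, blk[nz])
    }
  }
  Tmat <- Matrix::sparseMatrix(i = ti, j = tjj, x = tx,
                               dims = c(ndof, length(keep)))
  Kr <- Matrix::forceSymmetric(Matrix::crossprod(Tmat, K %*% Tmat))

  # User constraints (on reduced DOFs; slaves may not be constrained).
  fixed <- logical(length(keep))
  for (cs in model$constraints) {
    dd <- 6L * (cs$node - 1L) + cs$dofs
    if (any(colmap[dd] == 0)) {
      stop_craniofem(sprintf("node %d is a rigid-link slave and cannot be constrained",
                             cs$node), "craniofem_bad_constraint")
    }
    fixed[colmap[dd]] <- TRUE
  }
  user_fixed <- fixed
  # Suppress DOFs with (numerically) zero stiffness: rotational DOFs of
  # solid-only nodes and any rotation component left unconstrained by a
  # single-direction coupling.
  dg <- Matrix::diag(Kr)
  zero <- dg <= 1e-12 * max(dg)
  fixed <- fixed | zero

  structure(list(K = Kr, T = Tmat, keep = keep, colmap = colmap,
                 fixed = fixed, user_fixed = user_fixed,
                 ndof = ndof, nnode = nnode),
            class = "fe_system")
}

#' Count zero-energy (rigid-body) modes
#'
#' Dense eigenvalue count of the assembled, constrained system; intended
#' for small diagnostic models (an unconstrained tet reports its six
#' rigid-body modes).
#'
#' @param model an [fe_model()].
#' @param tol relative eigenvalue threshold.
#' @return integer number of near-zero eigenvalues.
#' @export
count_zero_modes <- function(model, tol = 1e-8) {
  sys <- assemble(model)
  free <- which(!sys$fixed)
  if (length(free) > 4000) {
    stop_craniofem("count_zero_modes is a dense diagnostic; model too large",
                   "craniofem_bad_input")
  }
  Kf <- as.matrix(sys$K[free, free, drop = FALSE])
  ev <- eigen(Kf, symmetric = TRUE, only.values = TRUE)$values
  sum(ev < tol * max(abs(ev)))
}
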