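# Geometric primitives of the articulation / maximum-gape analysis:
# 2D/3D gape angle, rigid ICP registration, circle (canine-arc) fitting,
# cartilage offset surfaces and point-to-surface distances.

#' Gape angle at the jaw joint
#'
#' Interior angle (degrees) at the joint vertex between the upper mesial
#' incisor, the jaw joint and the lower mesial incisor. Invariant under
#' rigid motion of the three points.
#'
#' @param upper_incisor,joint,lower_incisor length-3 points (mm).
#' @return angle in degrees, in `[0, 180]`.
#' @export
gape_angle <- function(upper_incisor, joint, lower_incisor) {
  a <- upper_incisor - joint
  b <- lower_incisor - joint
  if (vnorm(a) < 1e-12 || vnorm(b) < 1e-12) {
    stop_craniofem("gape angle needs three distinct points", "craniofem_bad_input")
  }
  cosang <- sum(a * b) / (vnorm(a) * vnorm(b))
  rad2deg(acos(pmin(1, pmax(-1, cosang))))
}

#' Iterative closest point rigid registration
#'
#' Classic ICP: alternate nearest-neighbour correspondence (source to
#' target) and least-squares rigid alignment (rotation via SVD /
#' orthogonal decomposition). The RMS correspondence distance is
#' non-increasing over iterations; iteration stops when its improvement
#' falls below `tol` or after `max_iter` rounds.
#'
#' @param source,target numeric `n x 3` point matrices (at least 3
#'   non-collinear points each).
#' @param max_iter maximum iterations.
#' @param tol RMS improvement threshold (mm).
#' @return list with rotation `R`, translation `t` (the transform maps
#'   source points as `p %*% t(R) + t`), final `rms` and the `rms_history`.
#' @export
icp_register <- function(source, target, max_iter = 50, tol = 1e-8) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (nrow(source) < 3 || nrow(target) < 3) {
    stop_craniofem("ICP needs at least 3 points in each set", "craniofem_bad_input")
  }
  if (collinear_points(source) || collinear_points(target)) {
    stop_craniofem("ICP point sets must not be collinear", "craniofem_bad_input")
  }
  R <- diag(3); tvec <- c(0, 0, 0)
  cur <- source
  hist <- numeric(0)
  for (it in seq_len(max_iter)) {
    nn <- nearest_neighbours(cur, target)
    corr <- target[nn, , drop = FALSE]
    rms <- sqrt(mean(rowSums((cur - corr)^2)))
    if (length(hist) && hist[length(hist)] - rms < tol) {
      hist <- c(hist, rms)
      break
    }
    hist <- c(hist, rms)
    fit <- kabsch(source, corr)
    R <- fit$R; tvec <- fit$t
    cur <- source %*% t(R) + matrix(tvec, nrow(source), 3, byrow = TRUE)
  }
  nn <- nearest_neighbours(cur, target)
  rms <- sqrt(mean(rowSums((cur - target[nn, , drop = FALSE])^2)))
  list(R = R, t = tvec, rms = rms, rms_history = c(hist, rms))
}

collinear_points <- function(p) {
  if (nrow(p) < 3) return(TRUE)
  s <- svd(scale(p, center = TRUE, scale = FALSE))$d
  s[2] < 1e-9 * max(s[1], 1e-300)
}

nearest_neighbours <- function(from, to) {
  # brute-force nearest neighbour; point sets in this package are small
  d2 <- outer(rowSums(from^2), rowSums(to^2), `+`) - 2 * tcrossprod(from, to)
  max.col(-d2, ties.method = "first")
}

# Least-squares rigid fit mapping p onto q (Kabsch, SVD orthogonal
# decomposition with reflection guard).
kabsch <- function(p, q) {
  cp <- colMeans(p); cq <- colMeans(q)
  H <- crossprod(sweep(p, 2, cp), sweep(q, 2, cq))
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = as.vector(cq - R %*% cp))
}

#' Least-squares circle fit in a plane
#'
#' Geometric circle fit to 2D points: algebraic (Kasa) initialisation
#' followed by Gauss-Newton refinement of the geometric distance. Used to
#' locate the centre of the arc described by the upper canine distal
#' margin in lateral view.
#'
#' @param points numeric `n x 2` matrix (n >= 3, not collinear).
#' @return object of class `arc_fit`: `center` (length 2), `radius`,
#'   `rms` residual (mm).
#' @export
fit_canine_arc <- function(points) {
  p <- as.matrix(points)
  if (ncol(p) != 2) stop_craniofem("arc points must be n x 2 (lateral-view plane)",
                                   "craniofem_bad_input")
  if (nrow(p) < 3) stop_craniofem("circle fit needs >= 3 points", "craniofem_bad_input")
  s <- svd(scale(p, center = TRUE, scale = FALSE))$d
  if (s[2] < 1e-9 * max(s[1], 1e-300)) {
    stop_craniofem("arc points are collinear; no circle fits", "craniofem_degenerate")
  }
  # Kasa: minimise ||x||^2 - 2 c.x + (|c|^2 - r^2) linearly.
  A <- cbind(2 * p, 1)
  b <- rowSums(p^2)
  sol <- qr.solve(A, b)
  cen <- sol[1:2]
  r <- sqrt(sol[3] + sum(cen^2))
  # Gauss-Newton on (cx, cy, r).
  for (it in 1:50) {
    dx <- p[, 1] - cen[1]; dy <- p[, 2] - cen[2]
    di <- sqrt(dx^2 + dy^2)
    res <- di - r
    J <- cbind(-dx / di, -dy / di, -1)
    step <- tryCatch(qr.solve(J, -res), error = function(e) rep(0, 3))
    cen <- cen + step[1:2]; r <- r + step[3]
    if (sqrt(sum(step^2)) < 1e-12 * max(1, r)) break
  }
  dx <- p[, 1] - cen[1]; dy <- p[, 2] - cen[2]
  structure(list(center = unname(cen), radius = r,
                 rms = sqrt(mean((sqrt(dx^2 + dy^2) - r)^2))),
            class = "arc_fit")
}

#' Canine arc-centre to jaw-joint ratio
#'
#' Distance of the arc centre from the fulcrum (jaw joint) expressed as a
#' fraction of the full fulcrum-to-circumference distance along the ray
#' from the fulcrum through the centre (using the far intersection of that
#' ray with the circle). A centre on the fulcrum gives 0; a fulcrum on the
#' circle gives r / 2r = 0.5.
#'
#' @param fit an [fit_canine_arc()] result.
#' @param fulcrum length-2 point (lateral-view jaw joint, mm).
#' @return the ratio in `[0, 1)`.
#' @export
arc_center_ratio <- function(fit, fulcrum) {
  d <- vnorm(fit$center - fulcrum)
  d / (d + fit$radius)
}

#' Offset a surface patch to simulate articular cartilage
#'
#' Displaces every vertex along its area-weighted vertex normal by
#' `thickness` mm (outward); the classic articular-cartilage stand-in used
#' before seating the jaw joint. On smooth patches the offset surface lies
#' within about 5% of the nominal distance; a warning is emitted if the
#' offset self-intersects grossly (folded normals).
#'
#' @param nodes `n x 3` vertex matrix of the patch.
#' @param tri `k x 3` triangle indices (outward orientation).
#' @param thickness offset distance in mm (0 returns the input).
#' @return list with displaced `nodes` and the same `tri`.
#' @export
extrude_cartilage <- function(nodes, tri, thickness = 1) {
  if (thickness == 0) return(list(nodes = nodes, tri = tri))
  n <- vertex_normals(nodes, tri)
  out <- nodes + thickness * n
  a0 <- sum(triangle_areas(nodes, tri))
  a1 <- sum(triangle_areas(out, tri))
  if (thickness > 0 && a1 < 0.2 * a0) {
    warning("cartilage offset surface appears self-intersecting (area collapse)")
  }
  list(nodes = out, tri = tri)
}

# Area-weighted vertex normals (unit length).
vertex_normals <- function(nodes, tri) {
  fn <- triangle_normals(nodes, tri, normalise = FALSE)  # area-weighted
  vn <- matrix(0, nrow(nodes), 3)
  for (k in 1:3) {
    for (c in 1:3) {
      acc <- tapply(fn[, c], tri[, k], sum)
      vn[as.integer(names(acc)), c] <- vn[as.integer(names(acc)), c] + acc
    }
  }
  vn / pmax(sqrt(rowSums(vn^2)), .Machine$double.xmin)
}

# Distance from each query point to a triangulated surface. Returns the
# unsigned distance, index of the nearest triangle, and a signed variant
# (positive outside, by the nearest triangle's orientation).
surface_distance <- function(points, nodes, tri) {
  points <- matrix(points, ncol = 3)
  v1 <- nodes[tri[, 1], , drop = FALSE]
  e0 <- nodes[tri[, 2], , drop = FALSE] - v1
  e1 <- nodes[tri[, 3], , drop = FALSE] - v1
  a <- rowSums(e0 * e0); b <- rowSums(e0 * e1); c <- rowSums(e1 * e1)
  nt <- nrow(tri)
  nrm <- triangle_normals(nodes, tri)
  dist <- numeric(nrow(points)); sgn <- numeric(nrow(points))
  nearest <- integer(nrow(points))
  for (ip in seq_len(nrow(points))) {
    p <- points[ip, ]
    dv <- v1 - matrix(p, nt, 3, byrow = TRUE)
    d <- rowSums(e0 * dv); e <- rowSums(e1 * dv)
    # Eberly point-triangle: minimise Q(s,t) over the reference triangle.
    det <- a * c - b * b
    s <- b * e - c * d
    t <- b * d - a * e
    inside <- s + t <= det & s >= 0 & t >= 0
    s1 <- ifelse(det > 0, pmin(pmax(s / pmax(det, 1e-300), 0), 1), 0)
    t1 <- ifelse(det > 0, pmin(pmax(t / pmax(det, 1e-300), 0), 1), 0)
    # clamp to edges for outside-region cases: project on each edge and take best
    cand_s <- cbind(s1, pmin(pmax(-d / pmax(a, 1e-300), 0), 1), 0,
                    pmin(pmax((c + e - b - d) / pmax(a - 2 * b + c, 1e-300), 0), 1))
    cand_t <- cbind(t1, 0, pmin(pmax(-e / pmax(c, 1e-300), 0), 1),
                    1 - pmin(pmax((c + e - b - d) / pmax(a - 2 * b + c, 1e-300), 0), 1))
    best <- rep(Inf, nt); bs <- numeric(nt); bt <- numeric(nt)
    for (k in 1:4) {
      if (k == 1) keep <- inside else keep <- rep(TRUE, nt)
      ss <- cand_s[, k]; tt <- cand_t[, k]
      q <- a * ss^2 + 2 * b * ss * tt + c * tt^2 + 2 * d * ss + 2 * e * tt + rowSums(dv * dv)
      upd <- keep & q < best
      best[upd] <- q[upd]; bs[upd] <- ss[upd]; bt[upd] <- tt[upd]
    }
    jt <- which.min(best)
    nearest[ip] <- jt
    cp <- v1[jt, ] + bs[jt] * e0[jt, ] + bt[jt] * e1[jt, ]
    dist[ip] <- sqrt(max(best[jt], 0))
    sgn[ip] <- if (sum((p - cp) * nrm[jt, ]) >= 0) 1 else -1
  }
  list(distance = dist, signed = sgn * dist, nearest = nearest)
}
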