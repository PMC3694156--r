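# Parametric synthetic skull generator.
#
# Geometry is stylized on purpose: a wedge cranium, a bar mandible, a
# cylindrical condyle/cotyle joint, curved laterally-compressed canine
# cones and an angular-process spur. The analysis pipeline, not anatomy,
# is the test target: every quantity the downstream stages recover
# (canine arc centre, maximum gape, attachment areas) is planted here with
# known ground truth.
#
# Coordinate convention: right-handed, +x anterior, +y dorsal, +z left
# lateral; the jaw-joint axis is the z-parallel line through the origin.
# The mandible is generated hanging 'unseated' by the cartilage gap; the
# gape estimator recovers the seated pose itself.

# insert stations so that no gap exceeds max_step (keeps original stations)
subdivide_stations <- function(st, max_step) {
  out <- st[1]
  for (i in seq_len(length(st) - 1)) {
    gap <- st[i + 1] - st[i]
    k <- max(1L, ceiling(gap / max_step))
    out <- c(out, st[i] + gap * seq_len(k) / k)
  }
  out
}

# linear band weight: 1 inside [z1, z2], 0 outside [z0, z3], mirrored in z
band_weight <- function(z, z0, z1, z2) {
  az <- abs(z)
  w <- (az - z0) / (z1 - z0)
  w[az <= z0] <- 0
  w[az >= z1] <- 1
  w[az > z2 * (1 + 1e-9)] <- 0   # outside the outer band edge there is no band
  w
}

skull_geometry <- function(params) {
  s <- params$skull_length / 250
  c_mm <- params$cartilage_mm
  r_c <- params$condyle_radius
  cl <- params$cotyle_clearance
  R <- r_c + cl
  beta <- deg2rad(4.5)                # condyle articular cap half-angle
  t_seat <- cl - 2 * c_mm             # seating translation (cartilage gap)
  a_pred <- t_seat + (r_c + c_mm) * sin(beta) / beta  # contact-axis height
  shelf_y <- 27 * s
  spur_rho <- 55 * s
  sin_astar <- (shelf_y - a_pred) / spur_rho
  if (sin_astar <= 0.05 || sin_astar >= 0.95) {
    stop_craniofem("infeasible gape-stop geometry for these joint parameters",
                   "craniofem_bad_input")
  }
  astar <- 180 - rad2deg(asin(sin_astar))
  alpha0 <- astar + params$gape_bone_contact_deg
  apex_seated <- c(spur_rho * cos(deg2rad(alpha0)),
                   a_pred + spur_rho * sin(deg2rad(alpha0)))
  cap_x <- R * sin(deg2rad(14))       # cotyle articular channel half-width
  list(s = s, r_c = r_c, cl = cl, R = R, beta = beta, t_seat = t_seat,
       a_pred = a_pred, shelf_y = shelf_y, spur_rho = spur_rho,
       astar = astar, alpha0 = alpha0,
       apex_gen = c(apex_seated[1], apex_seated[2] - t_seat),
       x_post = -62.5 * s, x_ant = 187.5 * s,
       palate_y = 5 * s, flat_y = 0.92 * R,
       cap_x = cap_x,
       gut0 = cap_x + 0.4 * s, gut1 = cap_x + 1.5 * s, gut2 = cap_x + 2.1 * s,
       gutter_y = R + 1.0 * s,
       x_bump = r_c * sin(beta),
       band_lo = 6.4 * s, band_hi = 7 * s, band_out = 12 * s,
       bump_taper = 10.5 * s,
       cran_half_w = 20 * s, mand_half_w = 12 * s,
       mand_x0 = -3 * s, mand_x1 = 170 * s,
       mand_top = 0.3 * s, mand_bot = -26 * s,
       canine_z = 16.5 * s, canine_w = 5 * s, canine_h = 16 * s)
}

cranium_top_fun <- function(G) {
  function(x) (55 - 30 * (x / G$s + 62.5) / 250) * G$s
}

cranium_bottom_fun <- function(G) {
  x_wall0 <- -(G$gut2 + 0.3 * G$s)
  x_wall1 <- x_wall0 - 1.1 * G$s
  base <- function(x) {
    y <- numeric(length(x))
    y[x >= 30 * G$s] <- G$palate_y
    i <- x >= 12 * G$s & x < 30 * G$s
    y[i] <- G$flat_y + (G$palate_y - G$flat_y) * (x[i] - 12 * G$s) / (18 * G$s)
    i <- x >= x_wall0 & x < 12 * G$s
    y[i] <- G$flat_y
    i <- x >= x_wall1 & x < x_wall0
    y[i] <- G$shelf_y + (G$flat_y - G$shelf_y) * (x[i] - x_wall1) / (x_wall0 - x_wall1)
    y[x < x_wall1] <- G$shelf_y
    y
  }
  # joint-channel profile across the dome bands: articular cap (radius R
  # about the hinge axis) flanked by relief gutters
  channel <- function(x) {
    ax <- abs(x)
    ifelse(ax <= G$cap_x, sqrt(pmax(G$R^2 - x^2, 0)),
      ifelse(ax <= G$gut0,
             { e <- sqrt(G$R^2 - G$cap_x^2)
               e + (G$gutter_y - e) * (ax - G$cap_x) / (G$gut0 - G$cap_x) },
        ifelse(ax <= G$gut1, G$gutter_y,
          ifelse(ax <= G$gut2,
                 G$gutter_y + (G$flat_y - G$gutter_y) * (ax - G$gut1) / (G$gut2 - G$gut1),
                 G$flat_y))))
  }
  function(x, z) {
    b <- base(x)
    w <- band_weight(z, G$band_lo, G$band_hi, G$band_out)
    inj <- abs(x) < G$gut2 & x > x_wall0
    ifelse(inj, b + w * (channel(x) - b), b)
  }
}

mandible_top_fun <- function(G) {
  function(x, z) {
    mesa <- G$x_bump + 0.6 * G$s
    bump_full <- sqrt(pmax(G$r_c^2 - pmin(abs(x), G$r_c)^2, 0)) - G$mand_top
    edge_val <- G$r_c * cos(G$beta) - G$mand_top
    bump <- ifelse(abs(x) <= G$x_bump, bump_full,
                   ifelse(abs(x) < mesa,
                          edge_val * (mesa - abs(x)) / (mesa - G$x_bump), 0))
    # the condyle bump tapers off before the side wall so that it always
    # stays under the cotyle relief channel during wide rotations
    w <- band_weight(z, G$band_lo, G$band_hi, G$mand_half_w)
    w_out <- pmin(1, pmax(0, (G$mand_half_w - abs(z)) /
                            (G$mand_half_w - G$bump_taper)))
    G$mand_top + w * w_out * pmax(bump, 0)
  }
}

build_cranium_block <- function(params, G) {
  s <- G$s
  ytop <- cranium_top_fun(G)
  ybot <- cranium_bottom_fun(G)
  f <- (params$element_budget / 5000)^(1 / 3)
  xs <- c(G$x_post, -45 * s, -30 * s, -15 * s,
          -(G$gut2 + 1.4 * s), -(G$gut2 + 0.3 * s),
          -G$gut2, -G$gut1, -G$gut0,
          seq(-G$cap_x, G$cap_x, length.out = 7),
          G$gut0, G$gut1, G$gut2,
          8 * s, 12 * s, 20 * s, 30 * s)
  xs <- sort(unique(c(xs, subdivide_stations(c(30 * s, G$x_ant), 40 * s / f))))
  zs <- c(-G$cran_half_w, -G$band_out, -G$bump_taper, -G$band_hi,
          0, G$band_hi, G$bump_taper, G$band_out, G$cran_half_w)
  ny <- max(3L, round(3 * f))
  mapping <- function(p) {
    x <- xs[1] + p[, 1] * (xs[length(xs)] - xs[1])
    z <- zs[1] + p[, 3] * (zs[length(zs)] - zs[1])
    yb <- ybot(x, z)
    cbind(x, yb + p[, 2] * (ytop(x) - yb), z)
  }
  norm01 <- function(v) (v - v[1]) / (v[length(v)] - v[1])
  mesh_box_lattice(length(xs) - 1, ny, length(zs) - 1, mapping = mapping,
                   grid = list(x = norm01(xs), z = norm01(zs)))
}

build_mandible_block <- function(params, G) {
  s <- G$s
  ytop <- mandible_top_fun(G)
  f <- (params$element_budget / 5000)^(1 / 3)
  mesa <- G$x_bump + 0.6 * s
  xs <- c(G$mand_x0, -mesa, seq(-G$x_bump, G$x_bump, length.out = 7),
          mesa, 4 * s, 8 * s)
  xs <- sort(unique(c(xs, subdivide_stations(c(8 * s, G$mand_x1), 33 * s / f))))
  zs <- c(-G$mand_half_w, -G$bump_taper, -G$band_hi, 0,
          G$band_hi, G$bump_taper, G$mand_half_w)
  ny <- max(3L, round(3 * f))
  mapping <- function(p) {
    x <- xs[1] + p[, 1] * (xs[length(xs)] - xs[1])
    z <- zs[1] + p[, 3] * (zs[length(zs)] - zs[1])
    yt <- ytop(x, z)
    cbind(x, G$mand_bot + p[, 2] * (yt - G$mand_bot), z)
  }
  norm01 <- function(v) (v - v[1]) / (v[length(v)] - v[1])
  mesh_box_lattice(length(xs) - 1, ny, length(zs) - 1, mapping = mapping,
                   grid = list(x = norm01(xs), z = norm01(zs)))
}

# Curved canine: lattice swept along the planted arc; outer (distal) surface
# lies exactly at the arc radius. Returns the mesh plus the exact arc sample
# points and tip position.
build_canine <- function(params, G, side = c("left", "right")) {
  side <- match.arg(side)
  s <- G$s
  r <- params$canine_arc_radius
  rho0 <- params$canine_arc_ratio
  d <- if (rho0 > 0) rho0 / (1 - rho0) * r else 0
  delta <- deg2rad(65)                       # centre direction below +x
  cen <- d * c(cos(delta), -sin(delta))      # lateral-plane arc centre
  ybase <- G$palate_y
  under <- ybase - cen[2]
  if (under >= r) stop_craniofem("canine arc does not reach the palate",
                                 "craniofem_bad_input")
  phi_b <- asin(under / r)
  dphi <- params$canine_length / r
  if (dphi > deg2rad(120)) stop_craniofem("canine too strongly curved",
                                          "craniofem_bad_input")
  root_frac <- 0.25
  h0 <- G$canine_h; w0 <- G$canine_w
  zc <- if (side == "left") G$canine_z else -G$canine_z
  nt <- 6L
  hfun <- function(t) h0 * (1 - 0.88 * pmin(pmax(t, 0), 1))
  wfun <- function(t) w0 * (1 - 0.85 * pmin(pmax(t, 0), 1))
  mapping <- function(p) {
    t <- -root_frac + (1 + root_frac) * p[, 1]
    phi <- phi_b - t * dphi
    rad <- r - p[, 2] * hfun(t)
    cbind(cen[1] + rad * cos(phi),
          cen[2] + rad * sin(phi),
          zc + (p[, 3] - 0.5) * wfun(t))
  }
  m <- mesh_box_lattice(nt, 2, 2, mapping = mapping, region = "dentine")
  # enamel: outer radial cell layer of the crown
  cent <- (m$nodes[m$tets[, 1], ] + m$nodes[m$tets[, 2], ] +
           m$nodes[m$tets[, 3], ] + m$nodes[m$tets[, 4], ]) / 4
  radc <- sqrt((cent[, 1] - cen[1])^2 + (cent[, 2] - cen[2])^2)
  phic <- atan2(cent[, 2] - cen[2], cent[, 1] - cen[1])
  tc <- (phi_b - phic) / dphi
  outer <- radc > r - 0.5 * hfun(tc)
  m$region[outer & tc > 0.05] <- "enamel"
  phi_t <- phi_b - dphi
  tip <- c(cen + (r - hfun(1) / 2) * c(cos(phi_t), sin(phi_t)), zc)
  t_arc <- seq(0.05, 1, length.out = 20)
  arc_pts <- cbind(cen[1] + r * cos(phi_b - t_arc * dphi),
                   cen[2] + r * sin(phi_b - t_arc * dphi))
  list(mesh = m, center = cen, radius = r, tip = tip, arc_points = arc_pts)
}

build_spur <- function(params, G) {
  s <- G$s
  apex <- c(G$apex_gen, 0)
  axis_gen <- c(0, G$a_pred - G$t_seat)
  rhat <- unit(G$apex_gen - axis_gen)
  ex <- 2.0 * s; ez <- 3 * s
  bx <- min(max(apex[1], G$mand_x0 + ex + 0.2 * s), 0.5 * s)
  base_c <- c(bx, G$mand_bot + 0.5 * s, 0)
  mapping <- function(p) {
    t <- p[, 1]
    sig <- (1 - t) + 0.1 * t
    pull <- 0.6 * s * pmax(0, (t - 2 / 3) * 3)
    px <- base_c[1] + t * (apex[1] - base_c[1]) + sig * (p[, 2] - 0.5) * 2 * ex -
      pull * rhat[1]
    py <- base_c[2] + t * (apex[2] - base_c[2]) - pull * rhat[2]
    pz <- sig * (p[, 3] - 0.5) * 2 * ez
    out <- cbind(px, py, pz)
    # the apex lattice vertex itself stays exactly on the planted point
    exact <- abs(t - 1) < 1e-12 & abs(p[, 2] - 0.5) < 1e-12 & abs(p[, 3] - 0.5) < 1e-12
    out[exact, ] <- matrix(apex, sum(exact), 3, byrow = TRUE)
    out
  }
  mesh_box_lattice(3, 2, 2, mapping = mapping)
}

#' Generate a synthetic cranium/mandible pair
#'
#' Builds the full stylized skull model: wedge cranium with cotyle channel
#' and occipital shelf, bar mandible with condyle cylinder and
#' angular-process spur, two curved canines (dentine core, enamel shell)
#' attached to the palate by rigid-link specifications, named landmarks,
#' and muscle attachment patches. Deterministic: identical parameters give
#' bitwise-identical node arrays.
#'
#' The generator plants ground truth recovered downstream: the canine
#' distal margins sample the configured arc exactly
#' (`canine_arc_points`), the bone-contact rotation of the jaw equals
#' `gape_bone_contact_deg` for the stated cartilage thickness, and muscle
#' patch areas are recorded for dry-skull checks.
#'
#' @param params a [skull_params()] object.
#' @return an object of class `skull_model`.
#' @export
make_skull_pair <- function(params) {
  if (!inherits(params, "skull_params")) params <- do.call(skull_params, params)
  G <- skull_geometry(params)
  s <- G$s

  cran <- build_cranium_block(params, G)
  canL <- build_canine(params, G, "left")
  canR <- build_canine(params, G, "right")
  n_cran_box <- nrow(cran$nodes)
  cran2 <- merge_tet_meshes(cran, canL$mesh, prefix = "canL_")
  cran2 <- merge_tet_meshes(cran2, canR$mesh, prefix = "canR_")

  mand <- build_mandible_block(params, G)
  n_mand_box <- nrow(mand$nodes)
  spur <- build_spur(params, G)
  mand2 <- merge_tet_meshes(mand, spur, prefix = "spur_")

  # Rigid-link specifications (applied when an FE model is built). Each
  # appendage (canine, angular-process spur) is tied on by one link whose
  # master is the centre node of its attachment face; the slaves are the
  # rest of that face plus the nearest parent-body nodes, so that the
  # master's rotations are anchored in the parent body (no free pivot).
  appendage_link <- function(all_nodes, face_ids, parent_limit, n_parent = 4L) {
    center <- colMeans(all_nodes[face_ids, , drop = FALSE])
    master <- face_ids[which.min(rowSums(sweep(all_nodes[face_ids, , drop = FALSE],
                                               2, center)^2))]
    d <- rowSums(sweep(all_nodes[seq_len(parent_limit), , drop = FALSE], 2, center)^2)
    ord <- order(d)
    # greedily take nearest parent nodes until they span a plane, so the
    # link cannot pivot about a line of collinear anchors
    parents <- ord[1]
    for (cand in ord[-1]) {
      pts <- all_nodes[c(parents, cand), , drop = FALSE]
      rank2 <- nrow(pts) >= 3 &&
        svd(scale(pts, center = TRUE, scale = FALSE))$d[2] > 1e-6
      parents <- c(parents, cand)
      if (length(parents) >= n_parent && rank2) break
    }
    list(master = master, slaves = c(setdiff(face_ids, master), parents))
  }
  cran_links <- list(
    appendage_link(cran2$nodes, canL$mesh$node_sets$xmin + n_cran_box, n_cran_box),
    appendage_link(cran2$nodes,
                   canR$mesh$node_sets$xmin + n_cran_box + nrow(canL$mesh$nodes),
                   n_cran_box))
  mand_links <- list(
    appendage_link(mand2$nodes, mand2$node_sets$spur_xmin, n_mand_box))

  # surface patches
  cran_tri <- extract_surface(cran2)
  mand_tri <- extract_surface(mand2)
  tri_centroids <- function(nodes, tri) {
    (nodes[tri[, 1], , drop = FALSE] + nodes[tri[, 2], , drop = FALSE] +
       nodes[tri[, 3], , drop = FALSE]) / 3
  }
  cc <- tri_centroids(cran2$nodes, cran_tri)
  cn <- triangle_normals(cran2$nodes, cran_tri)
  mc <- tri_centroids(mand2$nodes, mand_tri)
  mn <- triangle_normals(mand2$nodes, mand_tri)
  pick <- function(tri, sel) tri[sel, , drop = FALSE]

  in_band <- function(z, sgn) sgn * z > G$band_hi - 1e-9 & sgn * z < G$band_out + 1e-9
  cotyle_sel <- function(sgn) {
    abs(cc[, 1]) < G$cap_x + 1e-9 & cc[, 2] > G$flat_y - 0.2 * s &
      in_band(cc[, 3], sgn) & cn[, 2] < -0.2
  }
  condyle_sel <- function(sgn) {
    abs(mc[, 1]) < G$x_bump + 1e-9 & in_band(mc[, 3], sgn) &
      mc[, 2] > 0.5 * G$r_c & mn[, 2] > 0.7
  }
  wall_patch <- function(cents, wall_z, xr, yr) {
    abs(cents[, 3] - wall_z) < 1e-6 * max(1, abs(wall_z)) &
      cents[, 1] > xr[1] & cents[, 1] < xr[2] &
      cents[, 2] > yr[1] & cents[, 2] < yr[2]
  }
  cran2$patches <- list(
    cotyle_left = pick(cran_tri, cotyle_sel(+1)),
    cotyle_right = pick(cran_tri, cotyle_sel(-1)),
    temporalis_origin_left = pick(cran_tri, wall_patch(cc, G$cran_half_w,
                                                       c(-45, -10) * s, c(30, 50) * s)),
    temporalis_origin_right = pick(cran_tri, wall_patch(cc, -G$cran_half_w,
                                                        c(-45, -10) * s, c(30, 50) * s)),
    masseter_origin_left = pick(cran_tri, wall_patch(cc, G$cran_half_w,
                                                     c(5, 35) * s, c(14, 24) * s)),
    masseter_origin_right = pick(cran_tri, wall_patch(cc, -G$cran_half_w,
                                                      c(5, 35) * s, c(14, 24) * s)),
    mastoid_left = pick(cran_tri, wall_patch(cc, G$cran_half_w,
                                             c(-62.5, -44) * s, c(26, 38) * s)),
    mastoid_right = pick(cran_tri, wall_patch(cc, -G$cran_half_w,
                                              c(-62.5, -44) * s, c(26, 38) * s)))
  mand2$patches <- list(
    condyle_left = pick(mand_tri, condyle_sel(+1)),
    condyle_right = pick(mand_tri, condyle_sel(-1)),
    temporalis_insertion_left = pick(mand_tri, mc[, 2] < G$mand_top + 0.1 * s &
                                       mn[, 2] > 0.9 & mc[, 1] > 10 * s &
                                       mc[, 1] < 35 * s & mc[, 3] > 2 * s &
                                       mc[, 3] < 11 * s),
    temporalis_insertion_right = pick(mand_tri, mc[, 2] < G$mand_top + 0.1 * s &
                                        mn[, 2] > 0.9 & mc[, 1] > 10 * s &
                                        mc[, 1] < 35 * s & mc[, 3] < -2 * s &
                                        mc[, 3] > -11 * s),
    masseter_insertion_left = pick(mand_tri, wall_patch(mc, G$mand_half_w,
                                                        c(0, 25) * s, c(-25, -5) * s)),
    masseter_insertion_right = pick(mand_tri, wall_patch(mc, -G$mand_half_w,
                                                         c(0, 25) * s, c(-25, -5) * s)))

  # node sets for constraints
  near_node <- function(nodes, p) which.min(rowSums(sweep(nodes, 2, p)^2))
  tipL <- near_node(cran2$nodes, canL$tip)
  tipR <- near_node(cran2$nodes, canR$tip)
  occ_sel <- which(abs(cran2$nodes[, 1] - G$x_post) < 1e-9 &
                     abs(cran2$nodes[, 3]) < 8 * s &
                     cran2$nodes[, 2] > 47 * s & cran2$nodes[, 2] < 55.2 * s)
  lowL <- near_node(mand2$nodes, c(G$mand_x1 - 4 * s, G$mand_top, 9.5 * s))
  lowR <- near_node(mand2$nodes, c(G$mand_x1 - 4 * s, G$mand_top, -9.5 * s))
  cran2$node_sets <- list(occipital_condyle = occ_sel,
                          canine_tip_left = tipL, canine_tip_right = tipR)
  mand2$node_sets <- list(canine_tip_left = lowL, canine_tip_right = lowR)

  ytopf <- cranium_top_fun(G)
  lm <- rbind(
    upper_mesial_incisor = c(G$x_ant, G$palate_y, 0),
    lower_mesial_incisor = mand2$nodes[near_node(mand2$nodes,
                                                 c(G$mand_x1, G$mand_top, 0)), ],
    jaw_joint_left = c(0, 0, 9.5 * s),
    jaw_joint_right = c(0, 0, -9.5 * s),
    canine_tip_upper_left = canL$tip,
    canine_tip_upper_right = canR$tip,
    canine_tip_lower_left = mand2$nodes[lowL, ],
    canine_tip_lower_right = mand2$nodes[lowR, ],
    occipital_condyle = c(G$x_post, 51 * s, 0),
    rostrum_dorsal = c(140 * s, ytopf(140 * s) - 4 * s, 0),
    rostrum_lateral = c(150 * s, 12 * s, 14 * s),
    palate_mid = c(100 * s, 6 * s, 0),
    orbit_left = c(60 * s, ytopf(60 * s) - 6 * s, 14 * s),
    orbit_right = c(60 * s, ytopf(60 * s) - 6 * s, -14 * s),
    braincase_dorsal = c(-30 * s, ytopf(-30 * s) - 6 * s, 0),
    occiput_center = c(-55 * s, 44 * s, 0),
    mandible_corpus_left = c(80 * s, -15 * s, 8 * s),
    mandible_ramus_left = c(10 * s, -12 * s, 8 * s),
    mandible_symphysis = c(160 * s, -15 * s, 0))
  body <- c(rep("cranium", 1), "mandible", "none", "none", "cranium", "cranium",
            "mandible", "mandible", "cranium",
            "cranium", "cranium", "cranium", "cranium", "cranium", "cranium",
            "cranium", "mandible", "mandible", "mandible")
  names(body) <- rownames(lm)

  structure(list(
    cranium = cran2, mandible = mand2,
    landmarks = lm, landmark_body = body,
    canine_arc_points = list(left = canL$arc_points, right = canR$arc_points),
    arc_truth = list(center = canL$center, radius = canL$radius,
                     ratio = params$canine_arc_ratio, fulcrum = c(0, 0)),
    hinge = list(point = c(0, 0, 0), dir = c(0, 0, 1),
                 condyle_radius = G$r_c, cotyle_clearance = G$cl,
                 band_centers = c(9.5 * s, -9.5 * s)),
    gape_truth = list(bone_contact_deg = params$gape_bone_contact_deg,
                      a_pred = G$a_pred, t_seat = G$t_seat,
                      spur_apex = G$apex_gen, alpha0 = G$alpha0),
    links = list(cranium = cran_links, mandible = mand_links),
    skull_length = params$skull_length, body_mass = params$body_mass,
    params = params, geometry = G), class = "skull_model")
}

#' @export
print.skull_model <- function(x, ...) {
  cat(sprintf("skull_model: L = %g mm, mass = %g kg\n", x$skull_length, x$body_mass))
  cat(sprintf(" cranium: %d nodes / %d tets; mandible: %d nodes / %d tets\n",
              nrow(x$cranium$nodes), nrow(x$cranium$tets),
              nrow(x$mandible$nodes), nrow(x$mandible$tets)))
  cat(sprintf(" planted: arc ratio %.2f, bone-contact gape %.1f deg\n",
              x$arc_truth$ratio, x$gape_truth$bone_contact_deg))
  invisible(x)
}

#' Sample noisy points on a canine-style arc
#'
#' Generates `n` points along a circular arc (lateral-view plane) with
#' isotropic Gaussian noise, for circle-fit validation.
#'
#' @param center length-2 arc centre (mm).
#' @param radius arc radius (mm, > 0).
#' @param angular_span arc span in degrees.
#' @param n number of points (>= 3).
#' @param noise_sd isotropic noise standard deviation (mm).
#' @param seed integer seed.
#' @return an `n x 2` matrix of points.
#' @export
make_canine_arc_points <- function(center, radius, angular_span, n,
                                   noise_sd = 0, seed = 1L) {
  if (n < 3) stop_craniofem("need at least 3 arc points", "craniofem_bad_input")
  if (radius <= 0) stop_craniofem("radius must be > 0", "craniofem_bad_input")
  th <- deg2rad(seq(0, angular_span, length.out = n))
  pts <- cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
  if (noise_sd > 0) {
    rng <- local({ set.seed(seed); matrix(stats::rnorm(2 * n, 0, noise_sd), n) })
    pts <- pts + rng
  }
  pts
}
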