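# Temporomandibular joint articulation: hinge construction, rigid jaw
# rotation, and the 3D maximum-gape estimation algorithm.

#' Rotate the mandible about the jaw-joint axis
#'
#' Rigid rotation of the mandible mesh and its landmarks about the
#' anatomical hinge axis (the condyle cylinder axis). Positive angles open
#' the jaw (anterior tip moves ventrally); the cranium is untouched.
#'
#' @param skull a [make_skull_pair()] model.
#' @param angle_deg opening angle in degrees, within (-10, 150).
#' @return the skull with rotated mandible; the applied opening angle is
#'   accumulated in `skull$opening_deg`.
#' @export
rotate_mandible <- function(skull, angle_deg) {
  total <- (skull$opening_deg %||% 0) + angle_deg
  if (total <= -10 || total >= 150) {
    stop_craniofem("opening angle outside the sane range (-10, 150) degrees",
                   "craniofem_bad_input")
  }
  ax <- skull$hinge$dir
  org <- skull$hinge$point
  skull$mandible$nodes <- rotate_points(skull$mandible$nodes, ax, -angle_deg, org)
  mand_lm <- skull$landmark_body == "mandible"
  skull$landmarks[mand_lm, ] <- rotate_points(skull$landmarks[mand_lm, , drop = FALSE],
                                              ax, -angle_deg, org)
  skull$opening_deg <- (skull$opening_deg %||% 0) + angle_deg
  skull
}

# vertices and triangles of a named surface patch, as a standalone surface
patch_surface <- function(mesh, patch_names) {
  tri <- do.call(rbind, mesh$patches[patch_names])
  ids <- sort(unique(as.vector(tri)))
  remap <- integer(nrow(mesh$nodes))
  remap[ids] <- seq_along(ids)
  list(nodes = mesh$nodes[ids, , drop = FALSE],
       tri = matrix(remap[tri], ncol = 3), ids = ids)
}

#' Build the jaw hinge assembly
#'
#' Reproduces the classic articulated-skull hinge: the condyle and cotyle
#' articular plates are tied by rigid links to nodes placed on the joint
#' axis (one cranial and one mandibular axis node per side, offset along
#' the axis), and each side is closed by a stiff beam running along the
#' axis whose torsional coupling is released. The released torsion is the
#' hinge: the only free relative motion between cranium and mandible is
#' rotation about the joint axis, while the beam spiders spread the joint
#' load over the plates and avoid single-node stress singularities.
#'
#' @param skull a [make_skull_pair()] model.
#' @return a list of class `hinge_assembly` with axis points and link /
#'   beam specifications in terms of cranium and mandible node indices
#'   (resolved into a combined model by [build_bite_model()]).
#' @export
build_tmj_hinge <- function(skull) {
  for (p in c("cotyle_left", "cotyle_right")) {
    if (!nrow(skull$cranium$patches[[p]] %||% matrix(0, 0, 3))) {
      stop_craniofem(sprintf("cranium patch '%s' is missing or empty", p),
                     "craniofem_missing_patch")
    }
  }
  for (p in c("condyle_left", "condyle_right")) {
    if (!nrow(skull$mandible$patches[[p]] %||% matrix(0, 0, 3))) {
      stop_craniofem(sprintf("mandible patch '%s' is missing or empty", p),
                     "craniofem_missing_patch")
    }
  }
  org <- skull$hinge$point
  dir <- unit(skull$hinge$dir)
  G <- skull$geometry
  sides <- list(left = +1, right = -1)
  axis_nodes <- list()
  # The hinge plates extend over the whole joint region of each body (not
  # just the narrow articular strip), spreading the joint load and keeping
  # the hinge connection stiff relative to the bone.
  csurf <- unique(as.vector(extract_surface(skull$cranium)))
  msurf <- unique(as.vector(extract_surface(skull$mandible)))
  mn <- skull$mandible$nodes
  if (!is.null(skull$opening_deg) && skull$opening_deg != 0) {
    # select plate nodes in the closed-jaw reference frame
    mn <- rotate_points(mn, skull$hinge$dir, skull$opening_deg, skull$hinge$point)
  }
  for (nm in names(sides)) {
    sgn <- sides[[nm]]
    zc <- sgn * skull$hinge$band_centers[1]
    cn <- skull$cranium$nodes
    cran_ids <- csurf[abs(cn[csurf, 1]) < 4.6 * G$s &
                        sgn * cn[csurf, 3] > G$band_hi - 1e-9 &
                        sgn * cn[csurf, 3] < G$band_out + 1e-9 &
                        cn[csurf, 2] > G$flat_y - 0.6 * G$s &
                        cn[csurf, 2] < G$gutter_y + 0.6 * G$s]
    mand_ids <- msurf[abs(mn[msurf, 1]) < 4.6 * G$s &
                        sgn * mn[msurf, 3] > G$band_hi - 1e-9 &
                        sgn * mn[msurf, 3] < G$band_out + 1e-9 &
                        mn[msurf, 2] > G$mand_top - 1e-9]
    cran_ids <- sort(unique(c(cran_ids,
                              as.vector(skull$cranium$patches[[paste0("cotyle_", nm)]]))))
    mand_ids <- sort(unique(c(mand_ids,
                              as.vector(skull$mandible$patches[[paste0("condyle_", nm)]]))))
    axis_nodes[[nm]] <- list(
      cran_axis_pt = org + (zc + 1.2) * dir,
      mand_axis_pt = org + (zc - 1.2) * dir,
      cran_plate = cran_ids, mand_plate = mand_ids)
  }
  structure(list(axis = list(point = org, dir = dir), sides = axis_nodes),
            class = "hinge_assembly")
}

#' Estimate the maximum gape of a skull model
#'
#' Implements the full 3D maximum-gape algorithm: (1) the articular
#' surfaces of condyle and cotyle are offset by the articular cartilage
#' thickness along vertex normals; (2) the mandibular cartilage is seated
#' against the cranial cartilage by rigid ICP registration followed by a
#' vertical adjustment until the layers just touch; (3) the cartilage
#' contact patches (surface separation within `contact_tol`) are averaged
#' per side (area weights) and the two per-side points define the rotation
#' axis; (4) the mandible is rotated open about this axis with a bisection
#' search for the first bone-to-bone contact; (5) a soft-tissue back-off
#' angle is subtracted to give the reported maximum gape.
#'
#' @param skull a [make_skull_pair()] model (in its generated, closed pose).
#' @param cartilage_mm articular cartilage thickness (mm).
#' @param backoff_deg soft-tissue back-off subtracted from the bone-contact
#'   angle (degrees).
#' @param contact_tol surface separation treated as cartilage contact (mm).
#' @param angle_tol bisection resolution for the bone-contact angle (deg).
#' @return an object of class `gape_result` with fields `max_gape_deg`,
#'   `bone_contact_gape_deg`, `soft_tissue_backoff_deg`, `rotation_axis`
#'   (two points), `contact_points`, `gape_angle_deg` (incisor metric at
#'   the final pose), `gape_angle_sagittal_deg`, and `cartilage_mm`.
#' @export
find_max_gape <- function(skull, cartilage_mm = 1.0, backoff_deg = 2.0,
                          contact_tol = 0.05, angle_tol = 0.01) {
  s <- skull$geometry$s
  cran <- skull$cranium
  mand <- skull$mandible

  cot <- patch_surface(cran, c("cotyle_left", "cotyle_right"))
  con <- patch_surface(mand, c("condyle_left", "condyle_right"))
  cot_cart <- extrude_cartilage(cot$nodes, cot$tri, cartilage_mm)
  con_cart <- extrude_cartilage(con$nodes, con$tri, cartilage_mm)

  # (2) ICP seating of the mandibular cartilage onto the cranial cartilage
  icp <- icp_register(con_cart$nodes, cot_cart$nodes, max_iter = 60, tol = 1e-7)
  place <- function(p) p %*% t(icp$R) + matrix(icp$t, nrow(p), 3, byrow = TRUE)
  con_pts <- place(con_cart$nodes)
  # vertical adjustment until the layers just touch (no residual overlap)
  adjust <- 0
  for (it in 1:4) {
    sd <- surface_distance(con_pts, cot_cart$nodes, cot_cart$tri)
    gap <- min(sd$signed)
    adjust <- adjust + gap
    con_pts[, 2] <- con_pts[, 2] + gap
    if (abs(gap) < 1e-4) break
  }

  # (3) contact patch -> per-side area-weighted points -> rotation axis
  sd <- surface_distance(con_pts, cot_cart$nodes, cot_cart$tri)
  contact <- abs(sd$signed) <= contact_tol
  if (sum(contact) < 2) {
    stop_craniofem("no cartilage contact patch found after seating",
                   "craniofem_gape_failure")
  }
  w <- vertex_area_weights(con_cart$nodes, con_cart$tri)
  axis_pts <- lapply(c(1, -1), function(sgn) {
    sel <- contact & sgn * con_pts[, 3] > 0
    if (!any(sel)) stop_craniofem("cartilage contact is not bilateral",
                                  "craniofem_gape_failure")
    colSums(con_pts[sel, , drop = FALSE] * w[sel]) / sum(w[sel])
  })
  axis_dir <- unit(axis_pts[[1]] - axis_pts[[2]])
  axis_org <- (axis_pts[[1]] + axis_pts[[2]]) / 2

  # carry the seating transform over to the full mandible
  mand_seated <- mand$nodes %*% t(icp$R) + matrix(icp$t, nrow(mand$nodes), 3, byrow = TRUE)
  mand_seated[, 2] <- mand_seated[, 2] + adjust

  # (4) bisection for first bone-bone contact about the derived axis;
  # only the joint / occipital region of the cranium can be reached by the
  # rotating mandible, so restrict the contact search there
  ctri <- extract_surface(cran)
  ccen <- (cran$nodes[ctri[, 1], ] + cran$nodes[ctri[, 2], ] +
             cran$nodes[ctri[, 3], ]) / 3
  ctri <- ctri[ccen[, 1] < 26 * s & ccen[, 2] > -26 * s &
                 abs(ccen[, 3]) < 13.5 * s, , drop = FALSE]
  msurf <- unique(as.vector(extract_surface(mand)))
  pen_tol <- -0.02
  min_signed <- function(theta) {
    pts <- rotate_points(mand_seated[msurf, , drop = FALSE], axis_dir,
                         -theta, origin = axis_org)
    keep <- pts[, 1] < 25 * s & pts[, 2] > -25 * s
    if (!any(keep)) return(Inf)
    min(surface_distance(pts[keep, , drop = FALSE], cran$nodes, ctri)$signed)
  }
  lo <- 0; hi <- NA
  for (th in seq(4, 150, by = 4)) {
    if (min_signed(th) <= pen_tol) { hi <- th; break } else lo <- th
  }
  if (is.na(hi)) {
    stop_craniofem("no bone-bone contact found within 150 degrees",
                   "craniofem_gape_failure")
  }
  while (hi - lo > angle_tol) {
    mid <- (lo + hi) / 2
    if (min_signed(mid) <= pen_tol) hi <- mid else lo <- mid
  }
  bone_contact <- (lo + hi) / 2
  max_gape <- bone_contact - backoff_deg

  # (5) incisor gape metric at the final pose
  lm <- skull$landmarks
  upper <- lm["upper_mesial_incisor", ]
  joint <- (lm["jaw_joint_left", ] + lm["jaw_joint_right", ]) / 2
  lower0 <- lm["lower_mesial_incisor", ]
  lower_seated <- as.vector(lower0 %*% t(icp$R) + icp$t) + c(0, adjust, 0)
  lower <- as.vector(rotate_points(matrix(lower_seated, 1), axis_dir,
                                   -max_gape, origin = axis_org))
  g3 <- gape_angle(upper, joint, lower)
  # sagittal (lateral-view) projection of the same three points
  pr <- function(p) c(p[1], p[2], 0)
  gs <- gape_angle(pr(upper), pr(joint), pr(lower))

  structure(list(max_gape_deg = max_gape,
                 bone_contact_gape_deg = bone_contact,
                 soft_tissue_backoff_deg = backoff_deg,
                 rotation_axis = do.call(rbind, axis_pts),
                 contact_points = con_pts[contact, , drop = FALSE],
                 gape_angle_deg = g3, gape_angle_sagittal_deg = gs,
                 cartilage_mm = cartilage_mm,
                 icp_rms = icp$rms, seat_shift = icp$t[2] + adjust),
            class = "gape_result")
}

vertex_area_weights <- function(nodes, tri) {
  ar <- triangle_areas(nodes, tri)
  w <- numeric(nrow(nodes))
  for (k in 1:3) {
    acc <- tapply(ar / 3, tri[, k], sum)
    w[as.integer(names(acc))] <- w[as.integer(names(acc))] + acc
  }
  w
}

#' @export
print.gape_result <- function(x, ...) {
  cat(sprintf("gape_result: max gape %.2f deg (bone contact %.2f - backoff %.1f)\n",
              x$max_gape_deg, x$bone_contact_gape_deg, x$soft_tissue_backoff_deg))
  cat(sprintf(" incisor gape angle %.2f deg (sagittal %.2f); cartilage %g mm\n",
              x$gape_angle_deg, x$gape_angle_sagittal_deg, x$cartilage_mm))
  invisible(x)
}
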