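# Muscle modelling: dry-skull force estimation, adductor truss fans with
# optional via-points ('hinges' bending the line of action), and the
# head-depressor system of pretensioned trusses anchored to rigid-link
# attachment webs.

#' Dry-skull muscle force
#'
#' Classic dry-skull estimate: muscle force = projected cross-sectional
#' area x specific tension. The method ignores pennation and therefore
#' tends to underestimate the true maximal force; it is used here, as in
#' comparative practice, for relative comparisons.
#'
#' @param area projected muscle cross-section (mm^2, > 0).
#' @param specific_tension muscle specific tension (MPa); 0.3 MPa is the
#'   standard literature value.
#' @return force in N.
#' @export
dry_skull_force <- function(area, specific_tension = 0.3) {
  if (area <= 0) stop_craniofem("muscle area must be > 0", "craniofem_bad_input")
  if (specific_tension <= 0) stop_craniofem("specific tension must be > 0",
                                            "craniofem_bad_input")
  area * specific_tension
}

#' Projected (silhouette) area of a surface patch
#'
#' Area of the union of the patch triangles projected onto the plane
#' perpendicular to `normal`. Overlapping triangles (folded patches) are
#' not double-counted: the projection is rasterised and covered cells are
#' counted once.
#'
#' @param nodes `n x 3` patch vertices (mm).
#' @param tri `k x 3` triangle indices.
#' @param normal projection direction (length-3, non-degenerate).
#' @param resolution raster cell edge (mm); default resolves the patch
#'   bounding box into ~500 cells per side.
#' @return projected area in mm^2.
#' @export
projected_patch_area <- function(nodes, tri, normal, resolution = NULL) {
  if (is.null(tri) || !nrow(tri)) stop_craniofem("patch is empty", "craniofem_bad_input")
  if (vnorm(normal) < 1e-12) stop_craniofem("degenerate projection normal",
                                            "craniofem_bad_input")
  n <- unit(normal)
  ref <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  u <- unit(cross3(ref, n)); v <- cross3(n, u)
  p2 <- cbind(nodes %*% u, nodes %*% v)
  lo <- apply(p2, 2, min); hi <- apply(p2, 2, max)
  span <- max(hi - lo)
  if (span == 0) return(0)
  res <- resolution %||% (span / 500)
  nx <- max(1L, ceiling((hi[1] - lo[1]) / res))
  ny <- max(1L, ceiling((hi[2] - lo[2]) / res))
  covered <- matrix(FALSE, nx, ny)
  cx <- lo[1] + (seq_len(nx) - 0.5) * res
  cy <- lo[2] + (seq_len(ny) - 0.5) * res
  for (t in seq_len(nrow(tri))) {
    a <- p2[tri[t, 1], ]; b <- p2[tri[t, 2], ]; c <- p2[tri[t, 3], ]
    det <- (b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2])
    if (abs(det) < 1e-12) next
    xi <- which(cx >= min(a[1], b[1], c[1]) - res & cx <= max(a[1], b[1], c[1]) + res)
    yi <- which(cy >= min(a[2], b[2], c[2]) - res & cy <= max(a[2], b[2], c[2]) + res)
    if (!length(xi) || !length(yi)) next
    gx <- rep(cx[xi], times = length(yi)); gy <- rep(cy[yi], each = length(xi))
    l1 <- ((b[1] - a[1]) * (gy - a[2]) - (b[2] - a[2]) * (gx - a[1])) / det
    l2 <- ((c[1] - b[1]) * (gy - b[2]) - (c[2] - b[2]) * (gx - b[1])) / det
    l3 <- 1 - l1 - l2
    s <- sign(det)
    inside <- (s * ((b[1] - a[1]) * (gy - a[2]) - (b[2] - a[2]) * (gx - a[1])) >= 0) &
      (s * ((c[1] - b[1]) * (gy - b[2]) - (c[2] - b[2]) * (gx - b[1])) >= 0) &
      (s * ((a[1] - c[1]) * (gy - c[2]) - (a[2] - c[2]) * (gx - c[1])) >= 0)
    covered[cbind(rep(xi, times = length(yi)), rep(yi, each = length(xi)))] <-
      covered[cbind(rep(xi, times = length(yi)), rep(yi, each = length(xi)))] | inside
  }
  sum(covered) * res^2
}

# Deterministic, approximately uniform anchor sampling over a patch:
# patch nodes are ordered along their principal in-plane direction and a
# stratified pick (one anchor per stratum, seeded jitter) is taken.
sample_patch_nodes <- function(mesh, patch_name, n, seed) {
  tri <- mesh$patches[[patch_name]]
  if (is.null(tri) || !nrow(tri)) {
    stop_craniofem(sprintf("attachment patch '%s' is missing or empty", patch_name),
                   "craniofem_missing_patch")
  }
  ids <- sort(unique(as.vector(tri)))
  pts <- mesh$nodes[ids, , drop = FALSE]
  pc <- prcomp(pts, center = TRUE, scale. = FALSE)
  ord <- ids[order(pc$x[, 1])]
  rng <- local({
    set.seed(seed)
    stats::runif(n)
  })
  pick <- floor((seq_len(n) - 1 + rng * 0.999) / n * length(ord)) + 1L
  ord[pmin(pick, length(ord))]
}

#' Default jaw-adductor muscle specification
#'
#' Bilateral temporalis and masseter-complex truss fans. Group forces come
#' from the dry-skull method applied to the planted origin patch areas
#' (projected laterally); via-points near the joint emulate the wrap of
#' the muscle lines of action around the postorbital/zygomatic region so
#' that the adductors keep a closing moment at wide gape.
#'
#' @param skull a [make_skull_pair()] model.
#' @param specific_tension MPa (default 0.3).
#' @param n_trusses trusses per muscle group per side.
#' @return list of muscle group specifications.
#' @export
adductor_spec <- function(skull, specific_tension = 0.3, n_trusses = 5) {
  s <- skull$geometry$s
  groups <- list()
  for (side in c("left", "right")) {
    sgn <- if (side == "left") +1 else -1
    for (mus in c("temporalis", "masseter")) {
      opatch <- paste0(mus, if (mus == "temporalis") "_origin_" else "_origin_", side)
      ipatch <- paste0(if (mus == "temporalis") "temporalis_insertion_" else
                         "masseter_insertion_", side)
      area <- projected_patch_area(skull$cranium$nodes,
                                   skull$cranium$patches[[opatch]], c(0, 0, 1))
      force <- dry_skull_force(area, specific_tension)
      via <- if (mus == "temporalis") c(2, 15, sgn * 13.5) * s else c(10, 6, sgn * 12.8) * s
      groups[[paste0(mus, "_", side)]] <-
        list(name = paste0(mus, "_", side), origin = opatch, insertion = ipatch,
             n_trusses = n_trusses, force = force,
             force_per_truss = force / n_trusses, via = via)
    }
  }
  groups
}

#' Build jaw-adductor truss fans
#'
#' Distributes each muscle group's force over `n_trusses` truss elements
#' spanning seeded anchor points on the origin (cranium) and insertion
#' (mandible) patches. A via-point, when present, splits each truss into
#' two segments so that the pull direction at the insertion is the
#' via-to-insertion unit vector.
#'
#' @param skull a [make_skull_pair()] model.
#' @param spec list of group specifications (see [adductor_spec()]).
#' @param seed anchor-sampling seed (defaults to the skull's seed).
#' @return list of class `muscle_system`: per group, cranium/mandible
#'   anchor node indices, via point, per-truss force; total force budget.
#' @export
build_adductor_fans <- function(skull, spec = adductor_spec(skull), seed = NULL) {
  seed <- seed %||% skull$params$seed
  fans <- list()
  total <- 0
  for (g in spec) {
    o <- sample_patch_nodes(skull$cranium, g$origin, g$n_trusses, seed)
    i <- sample_patch_nodes(skull$mandible, g$insertion, g$n_trusses, seed + 1L)
    fans[[g$name]] <- list(name = g$name, cranium_nodes = o, mandible_nodes = i,
                           via = g$via, force_per_truss = g$force_per_truss,
                           n_trusses = g$n_trusses,
                           force = g$force_per_truss * g$n_trusses)
    total <- total + g$force_per_truss * g$n_trusses
  }
  structure(list(groups = fans, total_force = total, kind = "adductor"),
            class = "muscle_system")
}

#' Build the head-depressor system
#'
#' Two perpendicular rigid-link attachment webs (an ellipse and a circle)
#' with centre nodes fixed in all six degrees of freedom, placed caudal to
#' the occiput, and pretensioned trusses running from the mastoid regions
#' to the web rims: `n_sterno` trusses for the sternomastoideus (to the
#' circular web) and `n_obliquus` for the obliquus capitis (to the
#' elliptical web). The scalar force budget is
#' `(n_sterno + n_obliquus) * pretension`.
#'
#' @param skull a [make_skull_pair()] model.
#' @param ellipse_axes semi-axes are half of these major/minor diameters
#'   (mm); default proportional to skull length (40 and 26 mm at 300 mm).
#' @param circle_radius circle web radius (mm); default proportional.
#' @param n_sterno,n_obliquus truss counts.
#' @param pretension per-truss pretension (N).
#' @param standoff_frac web standoff behind the occiput, as a fraction of
#'   skull length.
#' @param seed anchor-sampling seed.
#' @return list of class `muscle_system` with webs, trusses and budget.
#' @export
build_depressor_system <- function(skull, ellipse_axes = NULL, circle_radius = NULL,
                                   n_sterno = 40, n_obliquus = 30, pretension = 25,
                                   standoff_frac = 0.5, seed = NULL) {
  L <- skull$skull_length
  ellipse_axes <- ellipse_axes %||% (c(40, 26) * L / 300)
  circle_radius <- circle_radius %||% (30 * L / 300)
  if (any(ellipse_axes <= 0) || circle_radius <= 0) {
    stop_craniofem("web dimensions must be positive", "craniofem_bad_input")
  }
  if (pretension < 0) stop_craniofem("pretension must be >= 0", "craniofem_bad_input")
  seed <- seed %||% skull$params$seed
  s <- skull$geometry$s
  ctr <- c(skull$geometry$x_post - standoff_frac * L, -10 * s, 0)
  phi_c <- 2 * pi * (seq_len(n_sterno) - 1) / n_sterno
  circle_rim <- cbind(ctr[1], ctr[2] + circle_radius * sin(phi_c),
                      ctr[3] + circle_radius * cos(phi_c))      # normal // x
  phi_e <- 2 * pi * (seq_len(n_obliquus) - 1) / n_obliquus
  ellipse_rim <- cbind(ctr[1] + ellipse_axes[1] / 2 * cos(phi_e),
                       ctr[2] + ellipse_axes[2] / 2 * sin(phi_e),
                       ctr[3])                                   # normal // z
  half <- function(n) c(ceiling(n / 2), floor(n / 2))
  anchors <- function(n, seed_off) {
    h <- half(n)
    c(sample_patch_nodes(skull$cranium, "mastoid_left", h[1], seed + seed_off),
      sample_patch_nodes(skull$cranium, "mastoid_right", h[2], seed + seed_off + 1L))
  }
  sterno_anchors <- anchors(n_sterno, 10L)
  obliquus_anchors <- anchors(n_obliquus, 20L)
  budget <- (n_sterno + n_obliquus) * pretension
  structure(list(
    webs = list(circle = list(center = ctr, rim = circle_rim, normal = c(1, 0, 0),
                              radius = circle_radius),
                ellipse = list(center = ctr, rim = ellipse_rim, normal = c(0, 0, 1),
                               axes = ellipse_axes)),
    groups = list(
      sternomastoideus = list(name = "sternomastoideus", web = "circle",
                              cranium_nodes = sterno_anchors,
                              n_trusses = n_sterno, pretension = pretension,
                              force = n_sterno * pretension),
      obliquus_capitis = list(name = "obliquus_capitis", web = "ellipse",
                              cranium_nodes = obliquus_anchors,
                              n_trusses = n_obliquus, pretension = pretension,
                              force = n_obliquus * pretension)),
    total_force = budget, kind = "depressor"), class = "muscle_system")
}

#' @export
print.muscle_system <- function(x, ...) {
  cat(sprintf("muscle_system (%s): %d group(s), total force budget %.1f N\n",
              x$kind, length(x$groups), x$total_force))
  invisible(x)
}
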