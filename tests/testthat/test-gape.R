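# Articulation and maximum-gape estimation: the gape metric, rigid
# rotation, cartilage offsets, ICP, circle fits and the planted-contact
# recovery of the full algorithm.

test_that("gape angle metric behaves like an interior angle", {
  expect_equal(gape_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  expect_equal(gape_angle(c(2, 0, 0), c(0, 0, 0), c(5, 0, 0)), 0)
  a <- c(1.2, 0.3, -0.5); j <- c(0.1, -0.2, 0.4); b <- c(-0.7, 1.1, 0.2)
  base <- gape_angle(a, j, b)
  R <- craniofem:::rotation_matrix(c(1, -2, 0.7), 63)
  t <- c(3, -1, 2)
  expect_equal(gape_angle(as.vector(R %*% a + t), as.vector(R %*% j + t),
                          as.vector(R %*% b + t)), base, tolerance = 1e-10)
  expect_error(gape_angle(j, j, b), class = "craniofem_bad_input")
})

test_that("mandible rotation is rigid, invertible and additive in gape angle", {
  sk <- default_skull()
  sk0 <- rotate_mandible(sk, 0)
  expect_equal(sk0$mandible$nodes, sk$mandible$nodes, tolerance = 1e-14)
  sk1 <- rotate_mandible(sk, 23.5)
  sk2 <- rotate_mandible(sk1, -23.5)
  expect_equal(sk2$mandible$nodes, sk$mandible$nodes, tolerance = 1e-9)
  # incisor gape angle grows by the rotation for points in the plane
  # perpendicular to the axis
  ga <- function(s) gape_angle(s$landmarks["upper_mesial_incisor", ],
                               (s$landmarks["jaw_joint_left", ] +
                                  s$landmarks["jaw_joint_right", ]) / 2,
                               s$landmarks["lower_mesial_incisor", ])
  expect_equal(ga(sk1), ga(sk) + 23.5, tolerance = 1e-6)
  expect_error(rotate_mandible(sk, 170), class = "craniofem_bad_input")
})

test_that("cartilage extrusion offsets surfaces by the requested thickness", {
  sp <- uv_sphere(10)
  ex <- extrude_cartilage(sp$nodes, sp$tri, 1)
  rr <- sqrt(rowSums(ex$nodes^2))
  expect_true(all(abs(rr - 11) < 0.05))
  ex0 <- extrude_cartilage(sp$nodes, sp$tri, 0)
  expect_identical(ex0$nodes, sp$nodes)
  # plane patch translates by exactly the thickness
  nodes <- cbind(runif(9, 0, 4), runif(9, 0, 4), 0)
  nodes <- rbind(nodes, c(0, 0, 0), c(4, 0, 0), c(4, 4, 0), c(0, 4, 0))
  tri <- t(utils::combn(10:13, 3))
  pl <- list(nodes = rbind(c(0, 0, 0), c(4, 0, 0), c(4, 4, 0), c(0, 4, 0)),
             tri = rbind(c(1, 2, 3), c(1, 3, 4)))
  exp1 <- extrude_cartilage(pl$nodes, pl$tri, 1)
  expect_equal(exp1$nodes[, 3], rep(1, 4), tolerance = 1e-12)
})

test_that("ICP recovers planted rigid transforms and decreases monotonically", {
  set.seed(11)
  src <- matrix(runif(300, -10, 10), 100)
  expect_equal(icp_register(src, src)$rms, 0, tolerance = 1e-12)
  R0 <- craniofem:::rotation_matrix(c(0.2, 0.5, 1), 10)
  tgt <- src %*% t(R0) + matrix(c(1, 2, 3), 100, 3, byrow = TRUE)
  fit <- icp_register(src, tgt, max_iter = 100)
  expect_lt(max(abs(fit$R - R0)), 1e-3)
  expect_lt(max(abs(fit$t - c(1, 2, 3))), 1e-3)
  expect_true(all(diff(fit$rms_history) <= 1e-9))
  # degenerate inputs rejected
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(icp_register(line, tgt), class = "craniofem_bad_input")
  expect_error(icp_register(src[1:2, ], tgt), class = "craniofem_bad_input")
})

test_that("circle fits are exact on exact data and order-invariant", {
  th <- c(0.3, 1.1, 2.0)
  p3 <- cbind(3 + 50 * cos(th), -2 + 50 * sin(th))
  f3 <- fit_canine_arc(p3)
  expect_equal(f3$center, c(3, -2), tolerance = 1e-6)
  expect_equal(f3$radius, 50, tolerance = 1e-6)
  pn <- make_canine_arc_points(c(0, 0), 50, 60, 20, noise_sd = 0.5, seed = 1)
  f1 <- fit_canine_arc(pn)
  f2 <- fit_canine_arc(pn[sample(20), ])
  expect_equal(f1$center, f2$center, tolerance = 1e-9)
  expect_equal(f1$radius, 50, tolerance = 1)
  expect_error(fit_canine_arc(cbind(1:5, 2 * (1:5))), class = "craniofem_degenerate")
})

test_that("arc-centre ratio follows its defining geometry", {
  f <- structure(list(center = c(10, 0), radius = 40), class = "arc_fit")
  expect_equal(arc_center_ratio(f, c(10, 0)), 0)
  # fulcrum on the circle: d = r so ratio = r / 2r = 0.5
  expect_equal(arc_center_ratio(f, c(50, 0)), 0.5)
  expect_equal(arc_center_ratio(f, c(10, 40)), 0.5)
})

test_that("hinge construction requires articular patches", {
  sk <- default_skull()
  hg <- build_tmj_hinge(sk)
  expect_length(hg$sides, 2)
  expect_gt(length(hg$sides$left$cran_plate), 3)
  expect_gt(length(hg$sides$left$mand_plate), 3)
  sk2 <- sk
  sk2$cranium$patches$cotyle_left <- NULL
  expect_error(build_tmj_hinge(sk2), regexp = "cotyle_left",
               class = "craniofem_missing_patch")
})

test_that("the hinge releases exactly one rotational degree of freedom", {
  # surrogate assembly: two bars joined by plate-to-axis rigid links and a
  # torsion-released axis beam; one bar clamped. The only zero-energy mode
  # must be the free bar's rotation about the axis.
  surrogate <- function(release) {
    a <- make_bar_fixture(4, 2, 2)
    b <- make_bar_fixture(4, 2, 2)
    nb <- nrow(a$nodes)
    bn <- b$nodes; bn[, 1] <- bn[, 1] + 5
    m <- fe_model(rbind(a$nodes, bn, c(4.5, 1, 0.6), c(4.5, 1, 1.4)))
    ax1 <- nrow(m$nodes) - 1L; ax2 <- nrow(m$nodes)
    m <- add_tets(m, a$tets, region = "bone")
    m <- add_tets(m, b$tets + nb, region = "bone")
    m <- add_rigid_link(m, ax1, a$node_sets$loaded)
    m <- add_rigid_link(m, ax2, b$node_sets$fixed + nb)
    m <- add_beam(m, ax1, ax2, A = 50, Iy = 500, Iz = 500, J = 500,
                  release_torsion = release)
    add_constraint(m, a$node_sets$fixed, 1:3)
  }
  expect_identical(count_zero_modes(surrogate(TRUE)), 1L)
  expect_identical(count_zero_modes(surrogate(FALSE)), 0L)
  # on the full skull, the bite constraints close the released rotation
  bm <- build_bite_model(default_skull())
  expect_s3_class(solve_linear(bm$model), "solve_result")
})

test_that("plate tessellation lowers the peak joint stress versus a single node", {
  sk <- default_skull()
  fans <- build_adductor_fans(sk)
  vm_near_joint <- function(mode) {
    bm <- build_bite_model(sk, adductors = fans, plate_mode = mode)
    r <- solve_bite(bm)
    cent <- (bm$model$nodes[bm$model$tets[, 1], ] +
               bm$model$nodes[bm$model$tets[, 2], ] +
               bm$model$nodes[bm$model$tets[, 3], ] +
               bm$model$nodes[bm$model$tets[, 4], ]) / 4
    near <- sqrt(cent[, 1]^2 + cent[, 2]^2) < 15 * sk$geometry$s
    max(r$result$vm[near])
  }
  expect_lte(vm_near_joint("plate"), vm_near_joint("single"))
})

test_that("maximum gape recovers the planted bone-contact angle minus backoff", {
  sk <- default_skull()     # planted bone contact at 90 degrees
  g <- find_max_gape(sk, cartilage_mm = 1, backoff_deg = 2)
  expect_equal(g$max_gape_deg, 88, tolerance = 0.5)
  expect_equal(g$max_gape_deg,
               g$bone_contact_gape_deg - g$soft_tissue_backoff_deg,
               tolerance = 1e-12)
  expect_gt(g$max_gape_deg, 0)
  expect_lt(g$max_gape_deg, 180)
  # the contact-derived rotation axis is bilateral and axis-aligned
  expect_equal(nrow(g$rotation_axis), 2)
  dirn <- g$rotation_axis[1, ] - g$rotation_axis[2, ]
  expect_gt(abs(dirn[3]) / sqrt(sum(dirn^2)), 0.99)
})

test_that("bone-contact angle is robust to the cartilage thickness", {
  sk <- default_skull()
  g10 <- find_max_gape(sk, cartilage_mm = 1.0)
  g15 <- find_max_gape(sk, cartilage_mm = 1.5)
  expect_lt(abs(g15$bone_contact_gape_deg - g10$bone_contact_gape_deg), 1.5)
  # the seating pose differs by the cartilage-gap change
  expect_equal(g10$seat_shift - g15$seat_shift, 1, tolerance = 0.15)
})

test_that("increasing joint clearance never decreases the returned gape", {
  g1 <- find_max_gape(make_skull_pair(skull_params(cotyle_clearance = 4)))
  g2 <- find_max_gape(make_skull_pair(skull_params(cotyle_clearance = 5)))
  expect_gte(g2$max_gape_deg, g1$max_gape_deg - 0.25)
})
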