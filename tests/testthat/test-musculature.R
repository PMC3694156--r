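# Muscle systems: dry-skull forces, projected silhouette areas, adductor
# fans with via-points, and the head-depressor web assembly.

test_that("dry-skull force is area times specific tension", {
  expect_equal(dry_skull_force(1000, 0.3), 300)
  expect_error(dry_skull_force(0), class = "craniofem_bad_input")
  expect_error(dry_skull_force(100, 0), class = "craniofem_bad_input")
})

test_that("projected areas: unit square, edge-on patch, degenerate normal", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  tri <- rbind(c(1, 2, 3), c(1, 3, 4))
  expect_equal(projected_patch_area(nodes, tri, c(0, 0, 1), resolution = 0.002),
               1, tolerance = 0.005)
  # patch parallel to the projection direction has (near) zero silhouette
  expect_lt(projected_patch_area(nodes, tri, c(1, 0, 0), resolution = 0.002), 0.01)
  expect_error(projected_patch_area(nodes, tri, c(0, 0, 0)),
               class = "craniofem_bad_input")
  expect_error(projected_patch_area(nodes, NULL, c(0, 0, 1)),
               class = "craniofem_bad_input")
})

test_that("folded patches are counted by silhouette, not by summed face area", {
  # two coincident unit squares stacked in z: summed area 2, silhouette 1
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                 c(0, 0, 0.2), c(1, 0, 0.2), c(1, 1, 0.2), c(0, 1, 0.2))
  tri <- rbind(c(1, 2, 3), c(1, 3, 4), c(5, 6, 7), c(5, 7, 8))
  a <- projected_patch_area(nodes, tri, c(0, 0, 1), resolution = 0.01)
  expect_equal(a, 1, tolerance = 0.01)
})

test_that("planted attachment patch areas match the analytic oracle within 2%", {
  sk <- default_skull()
  for (p in c("temporalis_origin_left", "masseter_origin_left")) {
    tri <- sk$cranium$patches[[p]]
    # oracle: the patch lies flat on the lateral wall, so its silhouette is
    # the plain sum of triangle areas (no overlap possible)
    oracle <- sum(craniofem:::triangle_areas(sk$cranium$nodes, tri))
    measured <- projected_patch_area(sk$cranium$nodes, tri, c(0, 0, 1))
    expect_equal(measured, oracle, tolerance = 0.02)
  }
})

test_that("adductor fans split the group force and span cranium to mandible", {
  sk <- default_skull()
  spec <- adductor_spec(sk, n_trusses = 10)
  for (g in spec) {
    expect_equal(g$force_per_truss * g$n_trusses, g$force, tolerance = 1e-12)
  }
  fans <- build_adductor_fans(sk, spec)
  for (g in fans$groups) {
    expect_length(g$cranium_nodes, 10)
    expect_length(g$mandible_nodes, 10)
    expect_true(all(g$cranium_nodes <= nrow(sk$cranium$nodes)))
    expect_true(all(g$mandible_nodes <= nrow(sk$mandible$nodes)))
  }
  expect_equal(fans$total_force, sum(vapply(spec, `[[`, numeric(1), "force")))
  # missing patch produces a structured failure naming the patch
  sk2 <- sk
  sk2$cranium$patches$temporalis_origin_left <- NULL
  expect_error(build_adductor_fans(sk2, spec), regexp = "temporalis_origin_left",
               class = "craniofem_missing_patch")
})

test_that("via-points bend the line of action toward the insertion", {
  sk <- default_skull()
  fans <- build_adductor_fans(sk, adductor_spec(sk, n_trusses = 3))
  bm <- build_bite_model(sk, adductors = fans)
  # find a via truss: second segment of a temporalis truss
  tr <- Filter(function(t) t$group == "temporalis_left", bm$model$trusses)
  seg2 <- tr[[2]]   # (via -> insertion)
  p <- apply_pretension(bm$model, seg2)
  dir_expected <- bm$model$nodes[seg2$n1, ] - bm$model$nodes[seg2$n2, ]
  dir_expected <- dir_expected / sqrt(sum(dir_expected^2))
  expect_equal(p$force2 / seg2$pretension, dir_expected, tolerance = 1e-12)
})

test_that("depressor system honours counts, budget and proportionality", {
  sk <- default_skull()
  dep <- build_depressor_system(sk)
  expect_equal(dep$total_force, 1750)
  expect_equal(dep$groups$sternomastoideus$n_trusses, 40)
  expect_equal(dep$groups$obliquus_capitis$n_trusses, 30)
  expect_equal(dep$groups$sternomastoideus$pretension, 25)
  expect_equal(nrow(dep$webs$circle$rim), 40)
  expect_equal(nrow(dep$webs$ellipse$rim), 30)
  # webs perpendicular
  expect_equal(sum(dep$webs$circle$normal * dep$webs$ellipse$normal), 0)
  # default web dimensions are proportional to skull length
  sk2 <- make_skull_pair(skull_params(skull_length = 500, body_mass = 100,
                                      canine_length = 160,
                                      canine_arc_radius = 200))
  dep2 <- build_depressor_system(sk2)
  expect_equal(dep2$webs$circle$radius, 2 * dep$webs$circle$radius)
  expect_equal(dep2$webs$ellipse$axes, 2 * dep$webs$ellipse$axes)
  expect_error(build_depressor_system(sk, circle_radius = -1),
               class = "craniofem_bad_input")
})
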