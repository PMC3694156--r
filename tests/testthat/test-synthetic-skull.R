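# Synthetic skull generator: determinism, budget, mesh validity, planted
# ground truth, and the standalone canine-arc point sampler.

test_that("the generator is bitwise deterministic", {
  sk1 <- default_skull()
  sk2 <- make_skull_pair(skull_params())
  expect_identical(sk1$cranium$nodes, sk2$cranium$nodes)
  expect_identical(sk1$mandible$nodes, sk2$mandible$nodes)
  expect_identical(sk1$landmarks, sk2$landmarks)
})

test_that("generated meshes are valid, watertight and within the element budget", {
  sk <- default_skull()
  expect_silent(validate_tet_mesh(sk$cranium, check_watertight = TRUE))
  expect_silent(validate_tet_mesh(sk$mandible, check_watertight = TRUE))
  ntet <- nrow(sk$cranium$tets) + nrow(sk$mandible$tets)
  expect_gt(ntet, 0.8 * 5000)
  expect_lt(ntet, 1.2 * 5000)
  expect_setequal(unique(sk$cranium$region), c("bone", "dentine", "enamel"))
  expect_true(all(sk$mandible$region == "bone"))
})

test_that("landmarks and attachment patches fulfil the model contract", {
  sk <- default_skull()
  need <- c("upper_mesial_incisor", "lower_mesial_incisor", "jaw_joint_left",
            "jaw_joint_right", "canine_tip_upper_left", "canine_tip_upper_right",
            "canine_tip_lower_left", "canine_tip_lower_right", "occipital_condyle")
  expect_true(all(need %in% rownames(sk$landmarks)))
  expect_false(anyDuplicated(rownames(sk$landmarks)) > 0)
  # bilateral joint landmarks mirror in z
  jl <- sk$landmarks["jaw_joint_left", ]; jr <- sk$landmarks["jaw_joint_right", ]
  expect_equal(jl[1:2], jr[1:2], tolerance = 1e-12)
  expect_equal(jl[3], -jr[3], tolerance = 1e-12)
  for (p in c("cotyle_left", "cotyle_right", "temporalis_origin_left",
              "masseter_origin_left", "mastoid_left")) {
    expect_gt(nrow(sk$cranium$patches[[p]]), 0)
  }
  for (p in c("condyle_left", "condyle_right", "temporalis_insertion_left",
              "masseter_insertion_left")) {
    expect_gt(nrow(sk$mandible$patches[[p]]), 0)
  }
})

test_that("canine distal margins lie exactly on the configured arc", {
  sk <- default_skull()
  for (side in c("left", "right")) {
    pts <- sk$canine_arc_points[[side]]
    d <- sqrt((pts[, 1] - sk$arc_truth$center[1])^2 +
                (pts[, 2] - sk$arc_truth$center[2])^2)
    expect_equal(d, rep(sk$arc_truth$radius, nrow(pts)), tolerance = 1e-10)
  }
})

test_that("a planted 0.33 arc-centre ratio is recovered downstream", {
  sk <- make_skull_pair(skull_params(canine_arc_ratio = 0.33))
  fit <- fit_canine_arc(sk$canine_arc_points$left)
  expect_equal(arc_center_ratio(fit, sk$arc_truth$fulcrum), 0.33, tolerance = 0.02)
})

test_that("infeasible canine geometry is rejected", {
  expect_error(skull_params(canine_length = 260),
               class = "craniofem_bad_input")
  expect_error(make_skull_pair(skull_params(canine_length = 200,
                                            canine_arc_radius = 90)),
               class = "craniofem_bad_input")
  expect_error(skull_params(cotyle_clearance = 1.5),
               class = "craniofem_bad_input")
  expect_error(skull_params(element_budget = 100), class = "craniofem_bad_input")
})

test_that("canine arc point sampler is seeded and exact at zero noise", {
  p <- make_canine_arc_points(c(3, -2), 50, 60, 20, noise_sd = 0)
  expect_equal(sqrt((p[, 1] - 3)^2 + (p[, 2] + 2)^2), rep(50, 20),
               tolerance = 1e-12)
  expect_error(make_canine_arc_points(c(0, 0), 50, 60, 2), class = "craniofem_bad_input")
  n1 <- make_canine_arc_points(c(0, 0), 50, 60, 20, noise_sd = 0.5, seed = 7)
  n2 <- make_canine_arc_points(c(0, 0), 50, 60, 20, noise_sd = 0.5, seed = 7)
  n3 <- make_canine_arc_points(c(0, 0), 50, 60, 20, noise_sd = 0.5, seed = 8)
  expect_identical(n1, n2)
  expect_false(identical(n1, n3))
  # full-circle noiseless fit has zero residual
  full <- make_canine_arc_points(c(0, 0), 50, 360, 36, noise_sd = 0)
  expect_lt(fit_canine_arc(full)$rms, 1e-9)
})
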