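# Allometric scaling, recruitment back-calculation, stress summaries and
# the comparison report.

test_that("allometric scaling is exactly multiplicative", {
  expect_equal(allometric_bite_force(100, 50, 50), 100)
  # scaling the target mass by k scales the force by k^exponent
  f1 <- allometric_bite_force(100, 50, 80, exponent = 0.7)
  f2 <- allometric_bite_force(100, 50, 80 * 3.7, exponent = 0.7)
  expect_equal(f2 / f1, exp(0.7 * log(3.7)), tolerance = 1e-14)
  expect_error(allometric_bite_force(10, 0, 5), class = "craniofem_bad_input")
  expect_error(allometric_bite_force(10, 5, 5, exponent = 1.2),
               class = "craniofem_bad_input")
})

test_that("recruitment ratios reduce to simple quotients", {
  expect_equal(recruitment_ratio(300, 300), 1)
  expect_equal(round(recruitment_ratio(3785, 1658), 1), 2.3)
  expect_equal(round(recruitment_ratio(24010, 1658), 1), 14.5)
  expect_error(recruitment_ratio(10, 0), class = "craniofem_bad_input")
})

test_that("recruitment back-calculation round-trips through a re-solve", {
  sk <- default_skull()
  fans <- build_adductor_fans(sk)
  bm <- build_bite_model(sk, adductors = fans, gape_deg = 30)
  base <- solve_bite(bm)
  target <- 2.37 * base$bite_force
  rec <- back_calculate_recruitment(bm, target, base = base)
  expect_equal(rec$scale, 2.37, tolerance = 1e-12)
  expect_equal(rec$muscle_force, 2.37 * bm$total_muscle_force, tolerance = 1e-12)
  # doubling the target doubles the scale
  rec2 <- back_calculate_recruitment(bm, 2 * target, base = base)
  expect_equal(rec2$scale, 2 * rec$scale, tolerance = 1e-12)
  # re-solving at the recruited muscle force reproduces the target
  bm2 <- bm
  for (i in seq_along(bm2$model$trusses)) {
    bm2$model$trusses[[i]]$pretension <- bm2$model$trusses[[i]]$pretension * rec$scale
  }
  r2 <- solve_bite(bm2)
  expect_equal(r2$bite_force, target, tolerance = 1e-3 * target)
})

test_that("regional mean stress follows the mean's algebra", {
  ab <- axial_bar_model(8, 1, 3)
  ab$model$tet_region <- rep(c("front", "back"), length.out = nrow(ab$model$tets))
  ab$model$tet_material <- rep("bone", nrow(ab$model$tets))
  r <- solve_linear(ab$model, loads = ab$loads)
  # uniform-stress bar: any region mean equals that stress
  expect_equal(mean_region_vm(r, "front"), 100, tolerance = 1e-6)
  expect_equal(mean_region_vm(r, "back"), 100, tolerance = 1e-6)
  expect_error(mean_region_vm(r, "nope"), class = "craniofem_bad_input")
  # merged-region mean lies between the two region means
  r2 <- r
  r2$vm <- r2$vm + ifelse(r2$region == "front", 5, -5)
  mf <- mean_region_vm(r2, "front"); mb <- mean_region_vm(r2, "back")
  r3 <- r2; r3$region <- rep("all", length(r3$region))
  ma <- mean_region_vm(r3, "all")
  expect_gte(ma, min(mf, mb)); expect_lte(ma, max(mf, mb))
  # the published cranial means give their printed ratio at one decimal
  expect_equal(round(1.074 / 0.584, 1), 1.8)
  expect_equal(round(1.577 / 0.584, 1), 2.7)
})

test_that("landmark stress sampling locates elements and scales linearly", {
  ab <- axial_bar_model(8, 1, 3)
  r <- solve_linear(ab$model, loads = ab$loads)
  lms <- rbind(inside = c(4, 0.5, 0.5), deep = c(2, 0.25, 0.75))
  lv <- mean_landmark_vm(r, ab$model, lms)
  expect_equal(unname(lv$per_landmark), c(100, 100), tolerance = 1e-6)
  r2 <- solve_linear(ab$model, loads = 2 * ab$loads)
  lv2 <- mean_landmark_vm(r2, ab$model, lms)
  expect_equal(lv2$per_landmark, 2 * lv$per_landmark, tolerance = 1e-9)
  # nearest-element fallback agrees with the enclosing element inside
  cent <- colMeans(ab$model$nodes[ab$model$tets[7, ], ])
  lv3 <- mean_landmark_vm(r, ab$model, rbind(c7 = cent))
  expect_equal(unname(lv3$per_landmark), r$vm[7], tolerance = 1e-9)
  # far-outside landmarks are flagged and excluded
  expect_warning(lv4 <- mean_landmark_vm(r, ab$model, rbind(out = c(50, 50, 50))))
  expect_true(is.na(lv4$per_landmark["out"]))
})

test_that("gape sweep matches single solves and the recruitment identity", {
  sk <- default_skull()
  sw <- gape_sweep(sk, c(20, 40), target_bite_force = 100)
  fans <- build_adductor_fans(sk, adductor_spec(sk))
  one <- solve_bite(build_bite_model(sk, adductors = fans, gape_deg = 20))
  expect_equal(sw$bite_force_N[1], one$bite_force, tolerance = 1e-9)
  expect_equal(sw$recruitment_scale, 100 / sw$bite_force_N, tolerance = 1e-12)
  expect_equal(sw$recruitment_N, sw$recruitment_scale * one$muscle_force,
               tolerance = 1e-9)
  expect_true(all(sw$feasible))
})

test_that("comparison reports compute self-consistent ratio blocks", {
  entries <- list(
    a = list(body_mass_kg = 100, muscle_recruitment_N = 1000, bite_force_N = 200,
             region_mean_vm = c(cranium = 1.0, mandible = 0.5)),
    b = list(body_mass_kg = 50, muscle_recruitment_N = 400, bite_force_N = 120,
             region_mean_vm = c(cranium = 2.0, mandible = 0.25)))
  rep <- build_comparison_report(entries, reference = "a")
  expect_equal(rep$ratios$recruitment_ratio[rep$ratios$model == "a"], 1)
  expect_equal(rep$ratios$cranium[rep$ratios$model == "b"], 2)
  expect_error(build_comparison_report(entries["a"]), class = "craniofem_bad_input")
  bad <- entries
  names(bad$b$region_mean_vm) <- c("cranium", "zygoma")
  expect_error(build_comparison_report(bad), class = "craniofem_bad_input")
})

test_that("published table values injected as inputs reproduce the printed ratios", {
  entries <- list(
    dirktooth_cat = list(body_mass_kg = 259, muscle_recruitment_N = 3785,
                         bite_force_N = 519,
                         region_mean_vm = c(tooth_root = 0.552,
                                            canine_crowns = 2.593,
                                            rest_of_cranium = 1.074)),
    pouched_saber = list(body_mass_kg = 82, muscle_recruitment_N = 24010,
                         bite_force_N = 241,
                         region_mean_vm = c(tooth_root = 0.486,
                                            canine_crowns = 2.311,
                                            rest_of_cranium = 1.577)),
    conical_cat = list(body_mass_kg = 68, muscle_recruitment_N = 1658,
                       bite_force_N = 212,
                       region_mean_vm = c(tooth_root = 0.397,
                                          canine_crowns = 1.848,
                                          rest_of_cranium = 0.584)))
  rep <- build_comparison_report(entries, reference = "conical_cat")
  rr <- rep$ratios
  expect_equal(round(rr$rest_of_cranium[rr$model == "dirktooth_cat"], 1), 1.8)
  expect_equal(round(rr$rest_of_cranium[rr$model == "pouched_saber"], 1), 2.7)
  expect_equal(round(rr$recruitment_ratio[rr$model == "dirktooth_cat"], 1), 2.3)
  expect_equal(round(rr$recruitment_ratio[rr$model == "pouched_saber"], 1), 14.5)
})

test_that("comparison tables round-trip through CSV", {
  entries <- list(
    a = list(body_mass_kg = 100, muscle_recruitment_N = 1234.5,
             bite_force_N = 210.25,
             region_mean_vm = c(cranium = 1.125, mandible = 0.5)),
    b = list(body_mass_kg = 50, muscle_recruitment_N = 432.1,
             bite_force_N = 120.75,
             region_mean_vm = c(cranium = 2.5, mandible = 0.25)))
  rep <- build_comparison_report(entries, reference = "a")
  dir <- withr::local_tempdir()
  craniofem:::write_table_csv(rep$table, file.path(dir, "adductor_table.csv"))
  craniofem:::write_table_csv(rep$ratios, file.path(dir, "adductor_ratios.csv"))
  back <- read_comparison_csv(dir, "adductor")
  expect_equal(back$table$bite_force_N, rep$table$bite_force_N)
  expect_equal(back$ratios$cranium, rep$ratios$cranium)
})
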