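# Allometric bite-force scaling, muscle-recruitment back-calculation, gape
# sweeps, and the regional / landmark von Mises summaries used to compare
# models.

#' Allometric bite-force scaling
#'
#' Scales a reference bite force to a target body mass assuming
#' `F ~ mass^exponent`; the default exponent of 2/3 reflects muscle force
#' scaling with cross-sectional area while body mass scales with volume:
#' `F_target = F_ref * (M_target / M_ref)^exponent`.
#'
#' @param reference_force reference bite force (N).
#' @param reference_mass reference body mass (kg).
#' @param target_mass target body mass (kg).
#' @param exponent allometric exponent in (0, 1]; default 2/3.
#' @return scaled bite force (N).
#' @export
allometric_bite_force <- function(reference_force, reference_mass, target_mass,
                                  exponent = 2 / 3) {
  if (reference_mass <= 0 || target_mass <= 0) {
    stop_craniofem("masses must be > 0", "craniofem_bad_input")
  }
  if (exponent <= 0 || exponent > 1) {
    stop_craniofem("exponent must lie in (0, 1]", "craniofem_bad_input")
  }
  reference_force * (target_mass / reference_mass)^exponent
}

#' Back-calculate muscle recruitment for a target bite force
#'
#' Exploits linearity of the static solves: one solve with the model's
#' nominal muscle force gives the bite reaction per unit muscle force; the
#' recruitment needed for `target_bite_force` is then a pure scale factor.
#'
#' @param bm a [build_bite_model()] with a muscle system.
#' @param target_bite_force desired canine bite reaction (N).
#' @param base optional pre-computed [solve_bite()] result of `bm`.
#' @return list with `scale` (multiplier on the nominal muscle forces),
#'   `muscle_force` (absolute recruited force, N), and `unit_bite` (the
#'   nominal-case bite force, N).
#' @export
back_calculate_recruitment <- function(bm, target_bite_force, base = NULL) {
  base <- base %||% solve_bite(bm)
  if (base$bite_force < 1e-9) {
    stop_craniofem("muscle system produces no bite reaction; cannot back-calculate",
                   "craniofem_no_reaction")
  }
  scale <- target_bite_force / base$bite_force
  list(scale = scale, muscle_force = scale * bm$total_muscle_force,
       unit_bite = base$bite_force)
}

#' Recruitment ratio between two models
#'
#' @param force_a,force_b recruited muscle forces (N); `force_b` > 0.
#' @return the dimensionless ratio a / b (report renderers round it to one
#'   decimal).
#' @export
recruitment_ratio <- function(force_a, force_b) {
  if (force_b <= 0) stop_craniofem("reference force must be > 0", "craniofem_bad_input")
  force_a / force_b
}

#' Sweep bite force and recruitment over gape angles
#'
#' For each gape angle the mandible is rotated, the muscle geometry is
#' rebuilt at the new pose, the model is solved, and two curves are
#' recorded: the canine bite reaction at fixed muscle force, and the
#' muscle recruitment needed to hold a fixed target bite force (muscle
#' tension is held constant with gape). Infeasible angles are flagged and
#' skipped.
#'
#' @param skull a [make_skull_pair()] model.
#' @param angles gape angles (degrees).
#' @param target_bite_force target for the recruitment curve (N); default
#'   is the bite force at the first angle.
#' @param adductor_seed seed for muscle anchor sampling.
#' @return data frame with columns `gape_deg`, `bite_force_N`,
#'   `recruitment_scale`, `recruitment_N`, `feasible`.
#' @export
gape_sweep <- function(skull, angles, target_bite_force = NULL,
                       adductor_seed = NULL) {
  spec <- adductor_spec(skull)
  out <- data.frame(gape_deg = angles, bite_force_N = NA_real_,
                    recruitment_scale = NA_real_, recruitment_N = NA_real_,
                    feasible = FALSE)
  total <- NULL
  for (i in seq_along(angles)) {
    r <- tryCatch({
      add <- build_adductor_fans(skull, spec, seed = adductor_seed)
      bm <- build_bite_model(skull, adductors = add, gape_deg = angles[i])
      total <- bm$total_muscle_force
      solve_bite(bm)
    }, error = function(e) e)
    if (inherits(r, "error")) {
      warning(sprintf("gape %g deg infeasible: %s", angles[i], conditionMessage(r)))
      next
    }
    out$bite_force_N[i] <- r$bite_force
    out$feasible[i] <- TRUE
  }
  ok <- which(out$feasible)
  if (length(ok)) {
    target <- target_bite_force %||% out$bite_force_N[ok[1]]
    out$recruitment_scale[ok] <- target / out$bite_force_N[ok]
    out$recruitment_N[ok] <- out$recruitment_scale[ok] * total
    attr(out, "target_bite_force") <- target
  }
  out
}

#' Mean von Mises stress of a labelled region
#'
#' Arithmetic mean of per-element von Mises stress over all elements
#' carrying the region label (the classic mean brick stress); a
#' volume-weighted variant is available.
#'
#' @param result a [solve_linear()] result (carries per-element regions).
#' @param region region label (e.g. `"dentine"`, `"enamel"`,
#'   `"cranium_bone"`, `"mandible_bone"`).
#' @param volumes optional per-element volumes (mm^3) for volume
#'   weighting.
#' @return mean von Mises stress (MPa).
#' @export
mean_region_vm <- function(result, region, volumes = NULL) {
  sel <- result$region == region
  if (!any(sel)) {
    stop_craniofem(sprintf("region '%s' is empty", region), "craniofem_bad_input")
  }
  if (is.null(volumes)) {
    mean(result$vm[sel])
  } else {
    sum(result$vm[sel] * volumes[sel]) / sum(volumes[sel])
  }
}

#' Von Mises stress at landmark points
#'
#' Samples the per-element von Mises field at homologous landmark points:
#' each landmark takes the stress of its enclosing element; a landmark
#' outside the mesh by at most `tol` mm takes the nearest element
#' centroid's value; landmarks further outside are flagged missing and
#' excluded from the mean with a warning.
#'
#' @param result a [solve_linear()] result.
#' @param model the [fe_model()] that produced it.
#' @param landmarks named matrix `k x 3` of points (mm).
#' @param tol outside tolerance (mm).
#' @return list with `per_landmark` (named vector, MPa; NA when missing)
#'   and `mean` (MPa, over located landmarks).
#' @export
mean_landmark_vm <- function(result, model, landmarks, tol = 1) {
  landmarks <- as.matrix(landmarks)
  cent <- (model$nodes[model$tets[, 1], ] + model$nodes[model$tets[, 2], ] +
             model$nodes[model$tets[, 3], ] + model$nodes[model$tets[, 4], ]) / 4
  vals <- rep(NA_real_, nrow(landmarks))
  for (i in seq_len(nrow(landmarks))) {
    p <- landmarks[i, ]
    d2 <- (cent[, 1] - p[1])^2 + (cent[, 2] - p[2])^2 + (cent[, 3] - p[3])^2
    cand <- order(d2)[1:min(30, length(d2))]
    hit <- NA_integer_
    for (e in cand) {
      A <- cbind(1, model$nodes[model$tets[e, ], ])
      bc <- tryCatch(solve(t(A), c(1, p)), error = function(e2) NULL)
      if (!is.null(bc) && all(bc > -1e-9)) { hit <- e; break }
    }
    if (!is.na(hit)) {
      vals[i] <- result$vm[hit]
    } else if (sqrt(d2[cand[1]]) <= tol + max_dist_centroid(model, cand[1])) {
      vals[i] <- result$vm[cand[1]]
    }
  }
  names(vals) <- rownames(landmarks)
  if (anyNA(vals)) {
    warning(sprintf("landmark(s) %s lie outside the mesh and were excluded",
                    paste(names(vals)[is.na(vals)], collapse = ", ")))
  }
  list(per_landmark = vals, mean = mean(vals, na.rm = TRUE))
}

# radius of the element around its centroid (for the outside tolerance)
max_dist_centroid <- function(model, e) {
  X <- model$nodes[model$tets[e, ], ]
  c0 <- colMeans(X)
  max(sqrt(rowSums(sweep(X, 2, c0)^2)))
}

#' Regional stress summary of a bite solve
#'
#' Mean brick von Mises stress for the comparative regions (tooth root =
#' canine dentine, canine crowns = enamel, rest of the cranium = cranial
#' cortical bone, mandible) plus, when landmarks are supplied, the mean
#' landmark point stress.
#'
#' @param bite a [solve_bite()] result.
#' @param bm the corresponding [build_bite_model()].
#' @param landmarks optional named landmark matrix (defaults to the
#'   skull's comparison landmark set).
#' @param volume_weighted use volume-weighted regional means.
#' @return named list of class `stress_summary`.
#' @export
stress_summary <- function(bite, bm, landmarks = NULL, volume_weighted = FALSE) {
  res <- bite$result
  vols <- NULL
  if (volume_weighted) {
    vols <- tet_volumes(tet_mesh(bm$model$nodes, bm$model$tets,
                                 region = bm$model$tet_region))
  }
  regions <- c(tooth_root = "dentine", canine_crowns = "enamel",
               rest_of_cranium = "cranium_bone", mandible = "mandible_bone")
  means <- vapply(regions, function(r) mean_region_vm(res, r, vols), numeric(1))
  lm_part <- NULL
  if (is.null(landmarks)) {
    sk <- bm$skull
    keep <- grepl("rostrum|palate|orbit|braincase|occiput|corpus|ramus|symphysis",
                  rownames(sk$landmarks))
    landmarks <- sk$landmarks[keep, , drop = FALSE]
  }
  if (nrow(landmarks)) {
    lm_part <- mean_landmark_vm(res, bm$model, landmarks)
  }
  structure(list(region_mean_vm = means,
                 landmark_vm = lm_part$per_landmark,
                 landmark_mean_vm = lm_part$mean), class = "stress_summary")
}

#' Cross-model comparison report
#'
#' Assembles the comparative table: one row per model (body mass, muscle
#' recruitment, canine bite force, regional mean von Mises stresses) and a
#' ratio block of every model against a designated reference model. The
#' choice of reference only rescales the ratio block. Entries may come
#' from the pipeline or be injected directly (e.g. published values).
#'
#' @param entries named list; each element is a list with `body_mass_kg`,
#'   `muscle_recruitment_N`, `bite_force_N` and a named numeric vector
#'   `region_mean_vm` (identical region sets across models).
#' @param reference name of the reference model (default: first entry).
#' @return object of class `comparison_report` with `table` (data frame)
#'   and `ratios` (data frame of model / reference ratios).
#' @export
build_comparison_report <- function(entries, reference = names(entries)[1]) {
  if (length(entries) < 2) {
    stop_craniofem("a comparison needs at least two models", "craniofem_bad_input")
  }
  if (!reference %in% names(entries)) {
    stop_craniofem("reference model not among the entries", "craniofem_bad_input")
  }
  regset <- lapply(entries, function(e) sort(names(e$region_mean_vm)))
  if (!all(vapply(regset, identical, logical(1), regset[[1]]))) {
    stop_craniofem("models carry inconsistent region sets", "craniofem_bad_input")
  }
  rows <- lapply(names(entries), function(nm) {
    e <- entries[[nm]]
    c(body_mass_kg = e$body_mass_kg,
      muscle_recruitment_N = e$muscle_recruitment_N,
      bite_force_N = e$bite_force_N, e$region_mean_vm)
  })
  tab <- data.frame(model = names(entries), do.call(rbind, rows),
                    check.names = FALSE, row.names = NULL)
  ref <- entries[[reference]]
  ratios <- lapply(names(entries), function(nm) {
    e <- entries[[nm]]
    c(recruitment_ratio = recruitment_ratio(e$muscle_recruitment_N,
                                            ref$muscle_recruitment_N),
      bite_force_ratio = e$bite_force_N / ref$bite_force_N,
      e$region_mean_vm / ref$region_mean_vm)
  })
  rat <- data.frame(model = names(entries), do.call(rbind, ratios),
                    check.names = FALSE, row.names = NULL)
  structure(list(table = tab, ratios = rat, reference = reference),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison_report (reference:", x$reference, ")\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) round(v, 3))
  tab$muscle_recruitment_N <- round(tab$muscle_recruitment_N)
  tab$bite_force_N <- round(tab$bite_force_N)
  print(tab, row.names = FALSE)
  cat("ratios vs", x$reference, "(one decimal):\n")
  rat <- x$ratios
  rat[vapply(rat, is.numeric, logical(1))] <-
    lapply(rat[vapply(rat, is.numeric, logical(1))], function(v) round(v, 1))
  print(rat, row.names = FALSE)
  invisible(x)
}
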