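# Pipeline driver: runs the full analysis for one configured model
# (generate -> gape -> solve -> sweep) and assembles the cross-model
# comparison that mirrors the comparative bite-force / stress tables.

#' Run all analysis stages for one configured model
#'
#' Generates the synthetic skull, estimates the maximum gape, solves the
#' jaw-adductor-driven and head-depressor-driven bites at maximum gape,
#' and sweeps bite force over gape angles. All randomness flows from the
#' configuration seed.
#'
#' @param cfg a [read_run_config()] configuration (or a path to one).
#' @param stages character subset of `c("gape", "solve", "sweep")`.
#' @return list of class `model_run` with the skull, gape result, bite
#'   solves and sweep table.
#' @export
run_model_stages <- function(cfg, stages = c("gape", "solve", "sweep")) {
  if (is.character(cfg) || !inherits(cfg, "run_config")) cfg <- read_run_config(cfg)
  mats <- config_materials(cfg)
  skull <- make_skull_pair(config_skull_params(cfg))
  out <- list(config = cfg, skull = skull)
  maxg <- NULL
  if ("gape" %in% stages || "solve" %in% stages || "sweep" %in% stages) {
    out$gape <- find_max_gape(skull, cartilage_mm = cfg$gape$cartilage_mm,
                              backoff_deg = cfg$gape$backoff_deg)
    maxg <- out$gape$max_gape_deg
  }
  spec <- adductor_spec(skull, specific_tension = cfg$muscles$specific_tension,
                        n_trusses = cfg$muscles$n_trusses)
  if ("solve" %in% stages) {
    add <- build_adductor_fans(skull, spec, seed = cfg$seed)
    bm_a <- build_bite_model(skull, adductors = add, gape_deg = maxg,
                             materials = mats)
    out$adductor_model <- bm_a
    out$adductor_bite <- solve_bite(bm_a)
    dep <- build_depressor_system(
      skull, ellipse_axes = cfg$depressors$ellipse_axes,
      circle_radius = cfg$depressors$circle_radius,
      n_sterno = cfg$depressors$n_sterno, n_obliquus = cfg$depressors$n_obliquus,
      pretension = cfg$depressors$pretension,
      standoff_frac = cfg$depressors$standoff_frac, seed = cfg$seed)
    bm_d <- build_bite_model(skull, depressors = dep, gape_deg = maxg,
                             materials = mats)
    out$depressor_model <- bm_d
    out$depressor_bite <- solve_bite(bm_d)
  }
  if ("sweep" %in% stages) {
    angles <- unique(c(cfg$sweep$angles[cfg$sweep$angles < maxg], maxg))
    out$sweep <- gape_sweep(skull, angles, adductor_seed = cfg$seed)
  }
  structure(out, class = "model_run")
}

# scaled entry for the comparison table: recruitment back-calculated to
# the allometric target, stresses rescaled by the recruitment factor
scaled_entry <- function(run, which = c("adductor", "depressor"),
                         target_bite) {
  which <- match.arg(which)
  bite <- run[[paste0(which, "_bite")]]
  bm <- run[[paste0(which, "_model")]]
  rec <- back_calculate_recruitment(bm, target_bite, base = bite)
  sm <- stress_summary(bite, bm)
  list(body_mass_kg = run$skull$body_mass,
       muscle_recruitment_N = rec$muscle_force,
       bite_force_N = target_bite,
       region_mean_vm = sm$region_mean_vm * rec$scale,
       landmark_mean_vm = sm$landmark_mean_vm * rec$scale,
       landmark_vm = sm$landmark_vm * rec$scale,
       recruitment_scale = rec$scale)
}

#' Run the cross-model comparison
#'
#' The full comparative workflow: every configured model is run through
#' generate / gape / solve / sweep; the reference model's solved bite
#' force sets the scale, every other model's target bite force follows
#' the allometric mass scaling, the muscle recruitment needed to reach it
#' is back-calculated, and regional mean von Mises stresses are rescaled
#' accordingly. Two comparison tables result: one for jaw-adductor-driven
#' and one for head-depressor-driven biting.
#'
#' @param cfgs list of configurations (paths or [read_run_config()]s).
#' @param reference name of the reference model; default the first.
#' @return list of class `pipeline_comparison` with `runs` and, per
#'   drive, a [build_comparison_report()] plus per-model gape angles and
#'   sweep tables.
#' @export
run_comparison <- function(cfgs, reference = NULL) {
  runs <- lapply(cfgs, run_model_stages)
  names(runs) <- vapply(runs, function(r) r$config$name, character(1))
  reference <- reference %||% runs[[1]]$config$scaling$reference %||% names(runs)[1]
  exponent <- runs[[1]]$config$scaling$exponent
  ref_mass <- runs[[reference]]$skull$body_mass
  reports <- list()
  for (drv in c("adductor", "depressor")) {
    ref_bite <- runs[[reference]][[paste0(drv, "_bite")]]$bite_force
    entries <- lapply(runs, function(r) {
      target <- allometric_bite_force(ref_bite, ref_mass, r$skull$body_mass,
                                      exponent)
      scaled_entry(r, drv, target)
    })
    reports[[drv]] <- build_comparison_report(entries, reference)
  }
  structure(list(runs = runs, adductor = reports$adductor,
                 depressor = reports$depressor, reference = reference,
                 exponent = exponent), class = "pipeline_comparison")
}

# deterministic CSV writers (fixed number formatting => byte-identical
# reruns under an identical seed)
write_table_csv <- function(df, path, digits = 12) {
  out <- df
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], num_fmt, digits = digits)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the comparison outputs as CSV
#'
#' Emits `<drive>_table.csv` and `<drive>_ratios.csv` (forces in N,
#' stresses in MPa, masses in kg) plus `gape.csv` and per-model
#' `sweep_<model>.csv` (angles in degrees).
#'
#' @param cmp a [run_comparison()] result.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_comparison_csv <- function(cmp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (drv in c("adductor", "depressor")) {
    rep <- cmp[[drv]]
    write_table_csv(rep$table, file.path(dir, paste0(drv, "_table.csv")))
    write_table_csv(rep$ratios, file.path(dir, paste0(drv, "_ratios.csv")))
  }
  gape <- data.frame(
    model = names(cmp$runs),
    max_gape_deg = vapply(cmp$runs, function(r) r$gape$max_gape_deg, numeric(1)),
    bone_contact_deg = vapply(cmp$runs, function(r) r$gape$bone_contact_gape_deg,
                              numeric(1)),
    incisor_gape_angle_deg = vapply(cmp$runs, function(r) r$gape$gape_angle_deg,
                                    numeric(1)))
  write_table_csv(gape, file.path(dir, "gape.csv"))
  for (nm in names(cmp$runs)) {
    write_table_csv(cmp$runs[[nm]]$sweep, file.path(dir, paste0("sweep_", nm, ".csv")))
  }
  invisible(dir)
}

#' Re-read a comparison table written by [write_comparison_csv()]
#'
#' @param dir directory holding the CSV files.
#' @param drive `"adductor"` or `"depressor"`.
#' @return list with `table` and `ratios` data frames.
#' @export
read_comparison_csv <- function(dir, drive = "adductor") {
  list(table = utils::read.csv(file.path(dir, paste0(drive, "_table.csv")),
                               check.names = FALSE),
       ratios = utils::read.csv(file.path(dir, paste0(drive, "_ratios.csv")),
                                check.names = FALSE))
}
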