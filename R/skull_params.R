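#' Parameters of the synthetic skull generator
#'
#' Describes a stylized cranium/mandible pair: a wedge cranium with a
#' cylindrical jaw-joint (condyle riding in a cotyle channel), curved
#' conical upper canines whose distal margins lie exactly on a configured
#' circular arc, and an angular-process spur placed so that bone-to-bone
#' contact during jaw opening occurs at a configured rotation angle. All
#' stated lengths are for the reference skull length of 250 mm and scale
#' linearly with `skull_length`.
#'
#' @param skull_length overall skull length in mm.
#' @param body_mass body mass in kg (carried into scaling analyses).
#' @param canine_length crown length of the upper canine along its arc (mm).
#' @param canine_arc_radius radius of the canine arc in lateral view (mm).
#' @param canine_arc_ratio planted arc-centre ratio: distance of the arc
#'   centre from the jaw joint (fulcrum) as a fraction of the full
#'   fulcrum-to-circumference distance (e.g. 0.17 or 0.33).
#' @param condyle_radius mandibular condyle cylinder radius (mm); default
#'   scales with skull length.
#' @param cotyle_clearance radial joint space between condyle and cotyle
#'   (mm); must exceed twice the articular cartilage thickness.
#' @param gape_bone_contact_deg planted jaw rotation (degrees) at which
#'   bone-bone contact occurs during opening.
#' @param cartilage_mm articular cartilage thickness assumed when planting
#'   the contact geometry (the default of the gape estimator).
#' @param element_budget approximate total tet4 count for the pair.
#' @param seed integer seed for the (reproducible) stochastic pieces
#'   downstream, e.g. muscle anchor sampling.
#' @return an object of class `skull_params`.
#' @export
skull_params <- function(skull_length = 250, body_mass = 100,
                         canine_length = 80, canine_arc_radius = 100,
                         canine_arc_ratio = 0.17,
                         condyle_radius = NULL, cotyle_clearance = NULL,
                         gape_bone_contact_deg = 90,
                         cartilage_mm = 1, element_budget = 5000,
                         seed = 1L) {
  s <- skull_length / 250
  p <- list(skull_length = skull_length, body_mass = body_mass,
            canine_length = canine_length,
            canine_arc_radius = canine_arc_radius,
            canine_arc_ratio = canine_arc_ratio,
            condyle_radius = condyle_radius %||% (8 * s),
            cotyle_clearance = cotyle_clearance %||% (4 * s),
            gape_bone_contact_deg = gape_bone_contact_deg,
            cartilage_mm = cartilage_mm,
            element_budget = element_budget, seed = as.integer(seed))
  lengths <- c(p$skull_length, p$canine_length, p$canine_arc_radius,
               p$condyle_radius, p$cotyle_clearance)
  if (any(lengths <= 0)) stop_craniofem("all lengths must be > 0", "craniofem_bad_input")
  if (p$body_mass <= 0) stop_craniofem("body mass must be > 0", "craniofem_bad_input")
  if (p$canine_arc_ratio < 0 || p$canine_arc_ratio >= 0.9) {
    stop_craniofem("canine_arc_ratio must be in [0, 0.9)", "craniofem_bad_input")
  }
  if (p$element_budget < 500) stop_craniofem("element budget must be >= 500",
                                             "craniofem_bad_input")
  if (p$canine_length >= p$skull_length) {
    stop_craniofem("canine longer than skull: infeasible geometry", "craniofem_bad_input")
  }
  if (p$cotyle_clearance <= 2 * p$cartilage_mm + 0.2) {
    stop_craniofem("cotyle clearance must exceed twice the cartilage thickness",
                   "craniofem_bad_input")
  }
  if (p$gape_bone_contact_deg < 50 || p$gape_bone_contact_deg > 103) {
    stop_craniofem("gape_bone_contact_deg must lie in [50, 103]", "craniofem_bad_input")
  }
  structure(p, class = "skull_params")
}
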