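#' Linear-elastic material
#'
#' @param name material name.
#' @param E Young's modulus in MPa (> 0).
#' @param nu Poisson's ratio, in `[0, 0.5)`.
#' @return an object of class `material`.
#' @export
material <- function(name, E, nu) {
  if (E <= 0) stop_craniofem("E must be > 0", "craniofem_bad_material")
  if (nu < 0 || nu >= 0.5) stop_craniofem("nu must be in [0, 0.5)", "craniofem_bad_material")
  structure(list(name = name, E = E, nu = nu), class = "material")
}

#' Default skull material set
#'
#' Literature-order isotropic defaults for cortical bone, canine dentine and
#' enamel. These are configurable placeholders: published comparative skull
#' models assign dentine, enamel and cortical-bone properties from prior
#' work, and every scaling or ratio result in this package is independent of
#' the absolute values chosen here.
#'
#' @return named list of [material()] objects (`bone`, `dentine`, `enamel`).
#' @export
default_materials <- function() {
  list(bone = material("bone", E = 20000, nu = 0.30),
       dentine = material("dentine", E = 21000, nu = 0.31),
       enamel = material("enamel", E = 80000, nu = 0.30))
}

# 6x6 isotropic elasticity matrix (engineering shear strains).
elasticity_matrix <- function(E, nu) {
  c1 <- E / ((1 + nu) * (1 - 2 * nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- c1 * nu
  diag(D)[1:3] <- c1 * (1 - nu)
  diag(D)[4:6] <- c1 * (1 - 2 * nu) / 2
  D
}

#' Von Mises equivalent stress
#'
#' Scalar equivalent stress of a symmetric stress tensor given in Voigt
#' order `(sxx, syy, szz, txy, tyz, tzx)` (MPa). Rotation-invariant; zero
#' for hydrostatic states.
#'
#' @param stress numeric vector of length 6, or an `n x 6` matrix.
#' @return von Mises stress (MPa), one value per row.
#' @export
von_mises <- function(stress) {
  s <- if (is.matrix(stress)) stress else matrix(stress, nrow = 1)
  if (ncol(s) != 6) stop_craniofem("stress must have 6 Voigt components", "craniofem_bad_input")
  out <- sqrt(0.5 * ((s[, 1] - s[, 2])^2 + (s[, 2] - s[, 3])^2 + (s[, 3] - s[, 1])^2) +
                3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2))
  if (is.matrix(stress)) out else out[[1]]
}
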