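# Constitutive models: transversely isotropic (poro)elastic tissues and
# tension-only structural elements.

#' Transversely isotropic poroelastic material (cartilage)
#'
#' Cartilage is treated as a transversely isotropic poroelastic (TIPE)
#' solid: the plane of isotropy is the local tangent plane of the articular
#' surface and the out-of-plane axis is the local surface normal. Fluid flow
#' follows Darcy's law with an isotropic permeability.
#'
#' All internal computation uses N, mm, MPa and s; the permeability is
#' supplied in the literature unit 1e-15 m^4/(N s) and converted at
#' construction (1 m^4/(N s) = 1e12 mm^2/(MPa s)).
#'
#' @param E_p In-plane Young's modulus (MPa).
#' @param E_t Out-of-plane Young's modulus (MPa).
#' @param nu_p In-plane Poisson's ratio.
#' @param nu_tp Out-of-plane Poisson's ratio (strain in the isotropy plane
#'   per unit strain along the out-of-plane axis under out-of-plane stress).
#' @param G_t Out-of-plane shear modulus (MPa).
#' @param permeability_k Hydraulic permeability in 1e-15 m^4/(N s).
#' @param e0 Initial void ratio.
#' @return An object of class `material_tipe`.
#' @examples
#' cart <- material_tipe(E_p = 24, E_t = 0.46, nu_p = 0.42, nu_tp = 0.06,
#'                       G_t = 12, permeability_k = 1, e0 = 4)
#' tipe_elasticity_matrix(cart)
#' @export
material_tipe <- function(E_p, E_t, nu_p, nu_tp, G_t, permeability_k, e0) {
  stopifnot(E_p > 0, E_t > 0, G_t > 0, permeability_k > 0, e0 > 0)
  if (nu_p <= -1 || nu_p >= 0.5 || nu_tp <= -1 || nu_tp >= 0.5) {
    stop("Poisson's ratios must lie in (-1, 0.5)", call. = FALSE)
  }
  mat <- structure(
    list(E_p = E_p, E_t = E_t, nu_p = nu_p, nu_tp = nu_tp, G_t = G_t,
         # mm^2 / (MPa s): value * 1e-15 m^4/(N s) * 1e12
         k_mm = permeability_k * 1e-3,
         permeability_k = permeability_k, e0 = e0,
         porosity = e0 / (1 + e0)),
    class = c("material_tipe", "material_ti")
  )
  # fail fast on thermodynamically inadmissible parameter sets
  mat$C <- tipe_elasticity_matrix(mat)
  mat
}

#' Transversely isotropic elastic material (meniscus)
#'
#' Same elastic law as [material_tipe()] without fluid fields; used for the
#' menisci, whose short-term load carriage is adequately elastic.
#'
#' @inheritParams material_tipe
#' @return An object of class `material_tie`.
#' @export
material_tie <- function(E_p, E_t, nu_p, nu_tp, G_t) {
  stopifnot(E_p > 0, E_t > 0, G_t > 0)
  if (nu_p <= -1 || nu_p >= 0.5 || nu_tp <= -1 || nu_tp >= 0.5) {
    stop("Poisson's ratios must lie in (-1, 0.5)", call. = FALSE)
  }
  mat <- structure(
    list(E_p = E_p, E_t = E_t, nu_p = nu_p, nu_tp = nu_tp, G_t = G_t),
    class = c("material_tie", "material_ti")
  )
  mat$C <- tipe_elasticity_matrix(mat)
  mat
}

#' Drained elasticity operator of a transversely isotropic material
#'
#' Assembles the 6x6 (Voigt order 11, 22, 33, 23, 13, 12) drained
#' effective-stress stiffness from the five engineering constants. Axes 1-2
#' span the plane of isotropy, axis 3 is the out-of-plane (surface normal)
#' direction. The in-plane shear modulus is closed by
#' `G_p = E_p / (2 (1 + nu_p))`. The compliance entry coupling in-plane and
#' out-of-plane normal strains is `-nu_tp / E_t`.
#'
#' @param mat A [material_tipe()] or [material_tie()] object, or a bare list
#'   with fields `E_p`, `E_t`, `nu_p`, `nu_tp`, `G_t`.
#' @return Symmetric positive-definite 6x6 matrix (MPa).
#' @export
tipe_elasticity_matrix <- function(mat) {
  E_p <- mat$E_p; E_t <- mat$E_t
  nu_p <- mat$nu_p; nu_tp <- mat$nu_tp; G_t <- mat$G_t
  G_p <- E_p / (2 * (1 + nu_p))
  S <- matrix(0, 6, 6)
  S[1, 1] <- S[2, 2] <- 1 / E_p
  S[3, 3] <- 1 / E_t
  S[1, 2] <- S[2, 1] <- -nu_p / E_p
  S[1, 3] <- S[3, 1] <- S[2, 3] <- S[3, 2] <- -nu_tp / E_t
  S[4, 4] <- S[5, 5] <- 1 / G_t
  S[6, 6] <- 1 / G_p
  ev_s <- eigen(S[1:3, 1:3], symmetric = TRUE, only.values = TRUE)$values
  if (any(ev_s <= 0)) {
    stop(
      "elasticity parameters violate thermodynamic admissibility: the ",
      "normal-strain compliance block is not positive definite ",
      "(requires nu_p < 1 and nu_tp^2 < E_t/E_p (1 - nu_p) / 2 type bounds); ",
      "offending eigenvalues: ", paste(signif(ev_s, 4), collapse = ", "),
      call. = FALSE
    )
  }
  C <- matrix(0, 6, 6)
  C[1:3, 1:3] <- solve(S[1:3, 1:3])
  C[4, 4] <- G_t
  C[5, 5] <- G_t
  C[6, 6] <- G_p
  # symmetrize away solve() roundoff
  (C + t(C)) / 2
}

#' Confined (uniaxial-strain) moduli of a transversely isotropic material
#'
#' Returns the out-of-plane confined modulus `C33` (axial stress per axial
#' strain at zero lateral strain) and the lateral coupling `C13`.
#'
#' @param mat A transversely isotropic material object.
#' @return Named list with `M_t` (= C33) and `C13`, MPa.
#' @keywords internal
confined_moduli <- function(mat) {
  C <- if (!is.null(mat$C)) mat$C else tipe_elasticity_matrix(mat)
  list(M_t = C[3, 3], C13 = C[1, 3])
}

#' Bilinear ligament spring
#'
#' Tension-only spring with a prestrain at the reference pose. The slack
#' length is `reference_length / (1 + prestrain)`, so at the reference pose
#' the spring carries `k * (L_ref - L_slack)` of tension.
#'
#' @param name Ligament name (e.g. "ACL", "PCL", "MCL", "LCL", "QT", "PT",
#'   "horn").
#' @param stiffness_k Tensile stiffness (N/mm), > 0.
#' @param prestrain Engineering strain at the reference pose, >= 0.
#' @param reference_length Length at the reference pose (mm), > 0.
#' @param endpoints Optional character vector of two attachment identifiers.
#' @return An object of class `spring_ligament`.
#' @examples
#' acl <- spring_ligament("ACL", 380, 0.05, reference_length = 30)
#' spring_force(acl, 30)  # tension at the reference pose
#' @export
spring_ligament <- function(name, stiffness_k, prestrain, reference_length,
                            endpoints = NULL) {
  stopifnot(stiffness_k > 0, prestrain >= 0, reference_length > 0)
  structure(
    list(name = name, stiffness_k = stiffness_k, prestrain = prestrain,
         reference_length = reference_length,
         slack_length = reference_length / (1 + prestrain),
         endpoints = endpoints),
    class = "spring_ligament"
  )
}

#' Tension in a bilinear ligament spring
#'
#' `tension = k * max(0, L - slack_length)`; the spring resists tension but
#' not compression.
#'
#' @param lig A [spring_ligament()].
#' @param current_length Current length (mm), > 0. Vectorized.
#' @return Tension (N), never negative.
#' @export
spring_force <- function(lig, current_length) {
  if (any(current_length <= 0)) {
    stop("degenerate geometry: ligament '", lig$name,
         "' has non-positive length", call. = FALSE)
  }
  lig$stiffness_k * pmax(0, current_length - lig$slack_length)
}

#' Linearly elastic no-compression truss
#'
#' Patellofemoral ligaments (MPFL, LPFL) are linear elastic trusses that
#' carry no compressive force. The Poisson's ratio is recorded for
#' completeness but does not enter the one-dimensional force law.
#'
#' @param name "MPFL" or "LPFL".
#' @param E Young's modulus (MPa).
#' @param cross_section_area Cross-sectional area (mm^2), > 0.
#' @param reference_length Rest length (mm), > 0.
#' @param nu Poisson's ratio (recorded, unused in the 1-D law).
#' @param endpoints Optional attachment identifiers.
#' @return An object of class `truss_ligament`.
#' @export
truss_ligament <- function(name, E, cross_section_area, reference_length,
                           nu = 0.499, endpoints = NULL) {
  stopifnot(E > 0, cross_section_area > 0, reference_length > 0)
  structure(
    list(name = name, E = E, nu = nu,
         cross_section_area = cross_section_area,
         reference_length = reference_length, endpoints = endpoints),
    class = "truss_ligament"
  )
}

#' Tension in a no-compression truss
#'
#' `tension = E * A * max(0, (L - L_ref) / L_ref)`.
#'
#' @param lig A [truss_ligament()].
#' @param current_length Current length (mm), > 0. Vectorized.
#' @return Tension (N), never negative.
#' @export
truss_force <- function(lig, current_length) {
  if (any(current_length <= 0)) {
    stop("degenerate geometry: truss '", lig$name,
         "' has non-positive length", call. = FALSE)
  }
  strain <- (current_length - lig$reference_length) / lig$reference_length
  lig$E * lig$cross_section_area * pmax(0, strain)
}
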