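# Element-level operations exposed for verification and reuse: single-element
# stiffness/force kernels, the tension-only ligament law, and the 3D von Mises
# radial return map.

# map a material card to the hex kernel (type, params) encoding; SRI types
# carry the volumetric hourglass stabilization factor (relative to the bulk
# modulus; inert for uniform dilatation and isochoric deformation)
hex_card_params <- function(card, stabilization = 0.05) {
  if (inherits(card, "orthotropic_elastic")) {
    list(type = 0L, params = as.vector(orthotropic_stiffness(card)))
  } else if (inherits(card, "isotropic_elastic")) {
    K <- card$E / (3 * (1 - 2 * card$nu))
    mu <- card$E / (2 * (1 + card$nu))
    list(type = 1L, params = c(K, mu, stabilization, rep(0, 33)))
  } else if (inherits(card, "neo_hookean")) {
    list(type = 2L, params = c(card$C10, card$D, stabilization, rep(0, 33)))
  } else stop("unsupported hex material card")
}

#' Tangent stiffness and internal force of one hexahedral element
#'
#' Total-Lagrangian 8-node hexahedron. Orthotropic cards use full 2x2x2
#' integration of a St.Venant-Kirchhoff law; isotropic and Neo-Hookean cards
#' use selective reduced integration of the volumetric term (the bulk part is
#' sampled at the centroid) so that near-incompressible tissues do not lock.
#'
#' @param element_nodes 8 x 3 matrix of reference node coordinates (mm),
#'   standard ordering (bottom quad counterclockwise, then top).
#' @param card An `orthotropic_elastic`, `isotropic_elastic` or `neo_hookean`
#'   card.
#' @param u Displacement vector of length 24 (3 dofs per node); defaults to 0.
#' @return List with `K` (24 x 24 material tangent), `K_geo` (geometric,
#'   initial-stress tangent), `f` (internal force), `von_mises` (max Cauchy
#'   von Mises over quadrature points), `volume`, `energy`, `min_detJ`.
#' @export
hex_stiffness_and_force <- function(element_nodes, card, u = numeric(24)) {
  stopifnot(is.matrix(element_nodes), nrow(element_nodes) == 8, length(u) == 24)
  hp <- hex_card_params(card)
  r <- hex_asm_cpp(element_nodes, matrix(0:7, 1, 8), hp$type,
                   matrix(hp$params, 1, 36), as.numeric(u), TRUE, TRUE)
  if (r$min_detJ <= 0) stop("negative Jacobian")
  list(K = matrix(r$Km, 24, 24), K_geo = matrix(r$Kg, 24, 24),
       f = as.vector(r$fint), von_mises = as.vector(r$vm),
       volume = as.vector(r$vol), energy = r$energy, min_detJ = r$min_detJ)
}

# plane-stress elasticity submatrices for the cortical shell: local axis 1 is
# circumferential (material x), axis 2 axial (material z)
cortical_shell_plane_stress <- function(card) {
  # cross-plane Poisson ratio paired with the axial modulus (see
  # orthotropic_stiffness)
  E1 <- card$E_xx; E2 <- card$E_zz; nu12 <- card$nu_xz; G12 <- card$G_xz
  S <- matrix(c(1 / E1, -nu12 / E2, 0,
                -nu12 / E2, 1 / E2, 0,
                0, 0, 1 / G12), 3, 3)
  list(D = solve(S), G13 = card$G_xy, G23 = card$G_yz)
}

fibre_plane_stress <- function(E, angle_deg) {
  c2 <- cos(angle_deg * pi / 180)^2
  s2 <- sin(angle_deg * pi / 180)^2
  cs <- cos(angle_deg * pi / 180) * sin(angle_deg * pi / 180)
  v <- c(c2, s2, cs)
  E * (v %o% v)
}

# balanced +/-angle laminate: two fibre families at half thickness each
fibre_laminate_plane_stress <- function(E, angle_deg) {
  0.5 * (fibre_plane_stress(E, abs(angle_deg)) +
         fibre_plane_stress(E, -abs(angle_deg)))
}

#' Tangent stiffness and internal force of one quadrilateral shell element
#'
#' Flat 4-node shell: bilinear membrane with the full Green-Lagrange in-plane
#' strain (geometric nonlinearity retained), MITC4 Mindlin bending without
#' shear locking, and a small drilling penalty. The membrane part carries
#' plane-stress von Mises plasticity when `plastic` is supplied. With
#' `bending = FALSE` the element is a pure membrane with 3 dofs per node
#' (used for the annulus fibre layers, which carry no bending stiffness).
#'
#' @param element_nodes 4 x 3 matrix of reference node coordinates (mm).
#' @param card For bending shells an `orthotropic_elastic` card (local axis 1
#'   circumferential, axis 2 axial); for membranes a list with `E` and `angle`
#'   (a balanced laminate of tension-only fibre families at +/- angle
#'   degrees, each at half the thickness).
#' @param thickness Shell thickness in mm.
#' @param u Displacement vector: 24 values (6 dof/node: 3 translations then,
#'   after all translations, 3 rotations per node) for bending shells, 12 for
#'   membranes.
#' @param bending Include bending/rotational dofs?
#' @param plastic Optional `plasticity_card` activating the elastoplastic
#'   membrane response.
#' @param state Optional 80-vector plastic state (4 gauss points x 5
#'   through-thickness layers x (plastic strain 3, equivalent plastic strain)).
#' @return List with `K`, `K_geo`, `f`, `von_mises`, `state`, `energy`.
#' @export
shell_stiffness_and_force <- function(element_nodes, card, thickness,
                                      u = NULL, bending = TRUE,
                                      plastic = NULL, state = numeric(80)) {
  stopifnot(is.matrix(element_nodes), nrow(element_nodes) == 4)
  if (thickness <= 0) stop("thickness must be positive")
  fr <- quad_area_check(element_nodes)
  if (!bending) {
    # +/-angle fibre laminate membrane (optionally tension-only families)
    if (is.null(u)) u <- numeric(12)
    to <- if (is.null(card$tension_only)) 0 else as.numeric(card$tension_only)
    par <- matrix(c(thickness, card$E, abs(card$angle), to), 1, 4)
    r <- membrane_asm_cpp(element_nodes, matrix(0:3, 1, 4), par, as.numeric(u), 12L, TRUE)
    return(list(K = matrix(r$Km, 12, 12), K_geo = matrix(r$Kg, 12, 12),
                f = as.vector(r$fint), von_mises = NA_real_,
                state = state, energy = r$energy))
  }
  ps <- cortical_shell_plane_stress(card)
  sy <- if (is.null(plastic)) -1 else plastic$yield_stress
  H <- if (is.null(plastic)) 0 else plastic$hardening_modulus
  if (is.null(u)) u <- numeric(24)
  par <- matrix(c(0, thickness, ps$D[1, 1], ps$D[1, 2], ps$D[1, 3],
                  ps$D[2, 2], ps$D[2, 3], ps$D[3, 3], ps$G13, ps$G23,
                  sy, H, 1e-3), 1, 13)
  rot <- matrix(c(12L, 15L, 18L, 21L), 1, 4)
  r <- shell_asm_cpp(element_nodes, matrix(0:3, 1, 4), rot, par,
                     as.numeric(u), matrix(state, 1, 80), 24L, TRUE)
  list(K = matrix(r$Km, 24, 24), K_geo = matrix(r$Kg, 24, 24),
       f = as.vector(r$fint), von_mises = as.vector(r$vm),
       state = as.vector(r$pstate), energy = r$energy)
}

quad_area_check <- function(X) {
  d1 <- X[3, ] - X[1, ]; d2 <- X[4, ] - X[2, ]
  if (sqrt(sum(pracma_cross(d1, d2)^2)) / 2 < 1e-12) stop("zero-area shell element")
  invisible(TRUE)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Axial force of a tension-only ligament link
#'
#' F = E A elongation / L0 when the link is stretched, zero in compression
#' (tension-only: both the force and the tangent vanish for negative
#' elongation).
#'
#' @param elongation Change of length in mm (positive = stretched).
#' @param card A row of [ligament_cards()] (fields `E`, `area`) or a list with
#'   `E` and `area`.
#' @param L0 Reference length in mm.
#' @return Axial force in N.
#' @export
link_force_tension_only <- function(elongation, card, L0) {
  if (L0 <= 0) stop("reference length must be positive")
  E <- card$E; A <- card$area
  ifelse(elongation > 0, E * A * elongation / L0, 0)
}

#' Von Mises radial return mapping (3D)
#'
#' Closed-form radial return with linear isotropic hardening: if the trial
#' von Mises stress exceeds the current yield stress
#' sigma_y0 + H alpha, the deviator is scaled back onto the hardened yield
#' surface and the equivalent plastic strain is updated by
#' delta gamma = (vm_trial - yield) / (3 mu + H).
#'
#' @param trial_stress Length-6 Voigt stress (11, 22, 33, 12, 23, 13) in MPa,
#'   or a symmetric 3 x 3 matrix.
#' @param card A [plasticity_card()].
#' @param eq_plastic Accumulated equivalent plastic strain alpha.
#' @param mu Elastic shear modulus in MPa (needed for the plastic multiplier).
#' @return List with `stress` (same shape as input), `eq_plastic`,
#'   `von_mises` of the returned stress.
#' @export
return_map_von_mises <- function(trial_stress, card, eq_plastic = 0,
                                 mu = 3000) {
  as_mat <- is.matrix(trial_stress)
  S <- if (as_mat) trial_stress else
    matrix(c(trial_stress[1], trial_stress[4], trial_stress[6],
             trial_stress[4], trial_stress[2], trial_stress[5],
             trial_stress[6], trial_stress[5], trial_stress[3]), 3, 3)
  if (any(!is.finite(S))) stop("trial stress must be finite")
  p <- sum(diag(S)) / 3
  dev <- S - p * diag(3)
  vm <- sqrt(1.5 * sum(dev^2))
  ycur <- card$yield_stress + card$hardening_modulus * eq_plastic
  if (vm <= ycur + 1e-12 * card$yield_stress) {
    out_S <- S
    dg <- 0
  } else {
    dg <- (vm - ycur) / (3 * mu + card$hardening_modulus)
    fac <- 1 - 3 * mu * dg / vm
    out_S <- fac * dev + p * diag(3)
  }
  devo <- out_S - sum(diag(out_S)) / 3 * diag(3)
  vmo <- sqrt(1.5 * sum(devo^2))
  stress <- if (as_mat) out_S else
    c(out_S[1, 1], out_S[2, 2], out_S[3, 3], out_S[1, 2], out_S[2, 3], out_S[1, 3])
  list(stress = stress, eq_plastic = eq_plastic + dg, von_mises = vmo)
}
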