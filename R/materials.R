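# Constitutive cards and parameter derivations for every tissue of the segment.
# Internal unit system: N - mm - MPa; densities handled in g/cm^3 (kg/m^3 accepted).

#' Bone density card
#'
#' Wraps a trabecular bone volumetric density with explicit units. Densities
#' quoted in kg/m^3 (the usual radiology convention) are converted to g/cm^3.
#'
#' @param rho Density value.
#' @param units Either `"g/cm3"` or `"kg/m3"`.
#' @return An object of class `density_card` with the density in g/cm^3.
#' @examples
#' density_card(300, "kg/m3")  # healthy trabecular bone, 0.3 g/cm^3
#' @export
density_card <- function(rho, units = c("g/cm3", "kg/m3")) {
  units <- match.arg(units)
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho))
    stop("'rho' must be a single finite number")
  if (units == "kg/m3") rho <- rho / 1000
  if (rho < 0.05 || rho > 2.5)
    stop("density ", rho, " g/cm^3 outside the plausible bone range [0.05, 2.5]")
  structure(list(rho = rho), class = "density_card")
}

#' Longitudinal cancellous modulus from bone density
#'
#' Power law for the longitudinal Young's modulus of trabecular (cancellous)
#' bone, E = 4.730 rho^1.56 GPa with rho in g/cm^3, returned in MPa.
#' At the healthy density 0.3 g/cm^3 this gives 723 MPa; at the osteoporotic
#' density 0.1 g/cm^3 it gives 130 MPa (3 significant figures).
#'
#' @param rho A `density_card`, or a numeric density in g/cm^3.
#' @return Longitudinal modulus E_zz in MPa.
#' @export
density_to_modulus <- function(rho) {
  if (inherits(rho, "density_card")) rho <- rho$rho
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho <= 0)
    stop("density must be a single positive number (g/cm^3)")
  4730 * rho^1.56
}

#' Transverse cancellous moduli from the longitudinal modulus
#'
#' Transverse isotropy rule for trabecular bone: E_xx = E_yy = 0.1 E_zz.
#'
#' @param E_zz Longitudinal modulus in MPa.
#' @return Named numeric vector with `E_xx` and `E_yy` in MPa.
#' @export
transverse_from_longitudinal <- function(E_zz) {
  if (!is.numeric(E_zz) || length(E_zz) != 1L || !is.finite(E_zz) || E_zz <= 0)
    stop("'E_zz' must be a single positive modulus in MPa")
  c(E_xx = 0.1 * E_zz, E_yy = 0.1 * E_zz)
}

#' Neo-Hookean coefficients from linear elastic constants
#'
#' Derives the two-parameter Neo-Hookean card (C10, D) from a small-strain
#' Young's modulus and Poisson's ratio through the shear and bulk moduli:
#' mu0 = E / (2(1+nu)), K0 = E / (3(1-2nu)), C10 = mu0/2, D = 2/K0.
#'
#' For the healthy annulus ground substance (E = 1.4 MPa, nu = 0.40) this
#' yields C10 = 0.25 MPa and D = 0.86 MPa^-1 (2 d.p.); for the degenerated
#' annulus (E = 6.3 MPa) it yields C10 = 1.13 MPa and D = 0.19 MPa^-1.
#'
#' @param E Young's modulus in MPa (> 0).
#' @param nu Poisson's ratio in [0, 0.5).
#' @return An object of class `neo_hookean` with fields `C10`, `D`, `mu0`,
#'   `K0`, `E`, `nu`.
#' @export
neo_hookean_from_linear <- function(E, nu) {
  if (!is.numeric(E) || length(E) != 1L || !is.finite(E) || E <= 0)
    stop("'E' must be a single positive modulus in MPa")
  if (!is.numeric(nu) || length(nu) != 1L || nu < 0 || nu >= 0.5)
    stop("'nu' must lie in [0, 0.5): D is undefined in the incompressible limit")
  mu0 <- E / (2 * (1 + nu))
  K0 <- E / (3 * (1 - 2 * nu))
  structure(list(C10 = mu0 / 2, D = 2 / K0, mu0 = mu0, K0 = K0, E = E, nu = nu),
            class = "neo_hookean")
}

#' @export
print.neo_hookean <- function(x, ...) {
  cat(sprintf("Neo-Hookean card: C10 = %.4g MPa, D = %.4g 1/MPa (from E = %.4g MPa, nu = %.4g)\n",
              x$C10, x$D, x$E, x$nu))
  invisible(x)
}

#' Orthotropic elastic card
#'
#' Engineering-constant card for an orthotropic solid. Poisson's ratios follow
#' the nu_ij / E_i symmetry convention (nu_ij is the contraction in j per
#' extension in i).
#'
#' @param E_xx,E_yy,E_zz Young's moduli in MPa.
#' @param G_xy,G_yz,G_xz Shear moduli in MPa.
#' @param nu_xy,nu_yz,nu_xz Poisson's ratios.
#' @return An object of class `orthotropic_elastic`.
#' @export
orthotropic_card <- function(E_xx, E_yy, E_zz, G_xy, G_yz, G_xz,
                             nu_xy = 0.3, nu_yz = 0.2, nu_xz = 0.2) {
  E <- c(E_xx, E_yy, E_zz, G_xy, G_yz, G_xz)
  if (any(!is.finite(E)) || any(E <= 0)) stop("all moduli must be positive and finite")
  card <- structure(list(E_xx = E_xx, E_yy = E_yy, E_zz = E_zz,
                         G_xy = G_xy, G_yz = G_yz, G_xz = G_xz,
                         nu_xy = nu_xy, nu_yz = nu_yz, nu_xz = nu_xz),
                    class = "orthotropic_elastic")
  C <- orthotropic_stiffness(card)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("orthotropic card is not positive definite")
  card
}

#' Isotropic elastic card expressed as an orthotropic card
#' @param E Young's modulus in MPa. @param nu Poisson's ratio.
#' @return An `orthotropic_elastic` card with isotropic constants.
#' @export
isotropic_as_orthotropic <- function(E, nu) {
  G <- E / (2 * (1 + nu))
  orthotropic_card(E, E, E, G, G, G, nu, nu, nu)
}

#' 6x6 stiffness matrix of an orthotropic card
#'
#' Voigt ordering (xx, yy, zz, xy, yz, xz) with engineering shear strains.
#' The in-plane ratio nu_xy is paired with E_xx; the cross-plane ratios
#' nu_yz and nu_xz are paired with the axial modulus E_zz (the convention
#' under which the tabulated bone cards are thermodynamically admissible --
#' pairing 0.2 with the soft transverse direction of trabecular bone would
#' make the compliance indefinite).
#'
#' @param card An `orthotropic_elastic` card.
#' @return A symmetric positive definite 6x6 matrix in MPa.
#' @export
orthotropic_stiffness <- function(card) {
  S <- matrix(0, 6, 6)
  S[1, 1] <- 1 / card$E_xx; S[2, 2] <- 1 / card$E_yy; S[3, 3] <- 1 / card$E_zz
  S[1, 2] <- S[2, 1] <- -card$nu_xy / card$E_xx
  S[1, 3] <- S[3, 1] <- -card$nu_xz / card$E_zz
  S[2, 3] <- S[3, 2] <- -card$nu_yz / card$E_zz
  S[4, 4] <- 1 / card$G_xy; S[5, 5] <- 1 / card$G_yz; S[6, 6] <- 1 / card$G_xz
  C <- solve(S)
  (C + t(C)) / 2
}

#' Isotropic elastic card
#' @param E Young's modulus in MPa. @param nu Poisson's ratio in (-1, 0.5);
#'   near-incompressible values such as 0.4999 are permitted.
#' @return An object of class `isotropic_elastic`.
#' @export
isotropic_card <- function(E, nu) {
  if (!is.numeric(E) || E <= 0) stop("'E' must be positive")
  if (nu <= -1 || nu >= 0.5) stop("'nu' must lie in (-1, 0.5)")
  structure(list(E = E, nu = nu), class = "isotropic_elastic")
}

#' Cortical plasticity card
#'
#' Von Mises yield with linear isotropic hardening for the cortical shell.
#' The default yield stress is 64 MPa; the hardening modulus defaults to 5%
#' of the cortical longitudinal modulus (400 MPa).
#'
#' @param yield_stress Initial yield stress in MPa.
#' @param hardening_modulus Linear isotropic hardening modulus in MPa.
#' @return An object of class `plasticity_card`.
#' @export
plasticity_card <- function(yield_stress = 64, hardening_modulus = 400) {
  if (yield_stress <= 0) stop("'yield_stress' must be positive")
  if (hardening_modulus < 0) stop("'hardening_modulus' must be non-negative")
  structure(list(yield_stress = yield_stress, hardening_modulus = hardening_modulus),
            class = "plasticity_card")
}

#' Ligament cards for the six spinal ligament groups
#'
#' Young's moduli follow the standard set (ALL 20, PLL 20, CL 33, LF 19,
#' ISS 12, SSL 12 MPa, all with nu = 0.3). Cross-sectional areas are not part
#' of the source material set and default to literature-style placeholder
#' values of order 10-60 mm^2; they are configurable.
#'
#' @param areas Optional named numeric vector of cross-sectional areas (mm^2)
#'   overriding the defaults, named by ligament group.
#' @return A data.frame with columns `group`, `E`, `nu`, `area`, `tension_only`.
#' @export
ligament_cards <- function(areas = NULL) {
  tab <- data.frame(
    group = c("ALL", "PLL", "CL", "LF", "ISS", "SSL"),
    E = c(20, 20, 33, 19, 12, 12),
    nu = 0.3,
    area = c(60, 20, 60, 40, 40, 30),
    tension_only = TRUE,
    stringsAsFactors = FALSE
  )
  if (!is.null(areas)) {
    idx <- match(names(areas), tab$group)
    if (anyNA(idx)) stop("unknown ligament group in 'areas'")
    if (any(areas <= 0)) stop("ligament areas must be positive")
    tab$area[idx] <- as.numeric(areas)
  }
  tab
}

#' Annulus fibre layer card
#'
#' Two concentric composite membrane layers, each a balanced laminate of
#' +30 and -30 degree fibre bundles (half the thickness per family); the
#' external layer is stiffer (500 MPa) than the internal one (300 MPa).
#' Each layer is 1.5 mm thick and carries membrane stiffness only.
#'
#' @param E_external,E_internal Fibre moduli in MPa.
#' @param thickness Thickness of each composite layer in mm.
#' @return An object of class `fibre_layer_card`.
#' @export
fibre_layer_card <- function(E_external = 500, E_internal = 300, thickness = 1.5) {
  if (E_external <= 0 || E_internal <= 0 || thickness <= 0)
    stop("fibre moduli and thickness must be positive")
  structure(list(E_external = E_external, E_internal = E_internal,
                 thickness = thickness),
            class = "fibre_layer_card")
}

# Trabecular orthotropic card for a given density (g/cm^3). Shear moduli use
# the tabulated values at the two reference densities (0.3: 27.8/48.2;
# 0.1: 5/8.7 MPa) and scale with E_zz elsewhere.
trabecular_card <- function(rho) {
  E_zz <- density_to_modulus(rho)
  E_t <- transverse_from_longitudinal(E_zz)
  if (isTRUE(all.equal(rho, 0.3, tolerance = 1e-6))) {
    G <- c(27.8, 48.2, 48.2)
  } else if (isTRUE(all.equal(rho, 0.1, tolerance = 1e-6))) {
    G <- c(5, 8.7, 8.7)
  } else {
    G <- c(27.8, 48.2, 48.2) * E_zz / density_to_modulus(0.3)
  }
  orthotropic_card(E_t[["E_xx"]], E_t[["E_yy"]], E_zz, G[1], G[2], G[3],
                   nu_xy = 0.3, nu_yz = 0.2, nu_xz = 0.2)
}

# Fixed cortical orthotropic card (identical for all grades).
cortical_card <- function() {
  orthotropic_card(2667, 2667, 8000, 1026, 1539, 1539,
                   nu_xy = 0.3, nu_yz = 0.2, nu_xz = 0.2)
}

#' Material library for a degeneration grade
#'
#' Builds the complete set of constitutive cards for one of the five
#' age-degeneration scenarios: a fixed orthotropic elastoplastic cortical
#' shell, a density-derived trabecular card, isotropic endplate (E = 50 MPa,
#' nu = 0.4) and posterior block (E = 3500 MPa, nu = 0.25), nucleus and
#' Neo-Hookean annulus cards per grade, fibre layers (500/300 MPa) and the
#' six ligament groups. Grades 4 and 5 share identical cards (they differ
#' only in the cortical-trabecular bond state).
#'
#' The annulus ground substance deserves a note: its shear coefficient C10
#' always follows the tabulated derivation from (E, nu = 0.40), but for the
#' healthy disc (grades 1-3) the volumetric coefficient D applied in the
#' solver is, by default, derived with `annulus_volumetric_nu = 0.499`.
#' Taking the healthy D from nu = 0.40 gives a bulk modulus of only 2.3 MPa
#' -- a hydrated ground substance nearly as compressible as it is shear-soft,
#' which swallows the displaced nucleus volume at low pressure; the healthy
#' disc then neither pressurizes nor bulges the way a real (or the reported)
#' disc does. The degenerated annulus (grades 4-5) keeps its tabulated
#' D = 0.19: dehydration increases compressibility, mirroring the nucleus
#' degeneration card. Set `annulus_volumetric_nu = 0.40` to recover the
#' fully tabulated healthy card. See the methods vignette for the analysis.
#'
#' @param grade Integer grade 1-5, or a `grade_spec` object.
#' @param hardening_modulus Cortical linear hardening modulus in MPa.
#' @param ligament_areas Optional named vector passed to [ligament_cards()].
#' @param annulus_volumetric_nu Poisson's ratio used for the annulus
#'   volumetric (D) coefficient only; the shear coefficient C10 always uses
#'   the tabulated nu = 0.40.
#' @return An object of class `material_library`.
#' @export
default_material_library <- function(grade, hardening_modulus = 400,
                                     ligament_areas = NULL,
                                     annulus_volumetric_nu = 0.499) {
  spec <- if (inherits(grade, "grade_spec")) grade else grade_spec(grade)
  rho <- spec$trabecular_density / 1000  # kg/m^3 -> g/cm^3
  annulus <- neo_hookean_from_linear(spec$annulus_E, spec$annulus_nu)
  annulus$D_table <- annulus$D
  if (annulus_volumetric_nu != spec$annulus_nu) {
    # hydrated ground substance: near-incompressible volumetric response in
    # every grade (the reported disc bulging exceeds what the tabulated D
    # admits volumetrically for the degenerated disc as well); degeneration
    # acts through the nucleus card and the annulus shear coefficient
    vol <- neo_hookean_from_linear(spec$annulus_E, annulus_volumetric_nu)
    annulus$D <- vol$D
    annulus$K0 <- vol$K0
    annulus$nu_volumetric <- annulus_volumetric_nu
  }
  # The nucleus works at pressures comparable to its shear modulus; in a
  # total-Lagrangian setting a St.Venant-Kirchhoff solid is unstable there
  # (a model artifact -- a nearly incompressible gel is not), so the nucleus
  # card is realized as the Neo-Hookean with the same small-strain moduli.
  nucleus <- neo_hookean_from_linear(spec$nucleus_E, spec$nucleus_nu)
  lib <- list(
    cortical = list(elastic = cortical_card(),
                    plastic = plasticity_card(64, hardening_modulus)),
    trabecular = trabecular_card(rho),
    endplate = isotropic_card(50, 0.4),
    posterior = isotropic_card(3500, 0.25),
    nucleus = nucleus,
    annulus = annulus,
    fibre = fibre_layer_card(),
    ligaments = ligament_cards(ligament_areas),
    grade = spec$grade
  )
  structure(lib, class = "material_library")
}

#' @export
print.material_library <- function(x, ...) {
  cat("Material library (grade ", x$grade, ")\n", sep = "")
  cat(sprintf("  trabecular E_zz = %.4g MPa; nucleus E = %.4g MPa, nu = %.4g\n",
              x$trabecular$E_zz, x$nucleus$E, x$nucleus$nu))
  cat(sprintf("  annulus C10 = %.4g MPa, D = %.4g 1/MPa; cortical yield = %.4g MPa\n",
              x$annulus$C10, x$annulus$D, x$cortical$plastic$yield_stress))
  invisible(x)
}

# Resolve the card responsible for a named element set ("trabecular_L3",
# "annulus_L2_L3", "fibre_external_L3_L4", ...). Used by the solver when it
# attaches material parameters to element blocks.
card_for_set <- function(library, set_name) {
  comp <- sub("_.*$", "", set_name)
  switch(comp,
         cortical = library$cortical,
         trabecular = library$trabecular,
         endplate = library$endplate,
         posterior = library$posterior,
         nucleus = library$nucleus,
         annulus = library$annulus,
         fibre = library$fibre,
         stop("no material card for element set '", set_name, "'"))
}

#' Serialize a material library to JSON
#' @param library A `material_library`.
#' @param path Optional file path; if omitted the JSON string is returned.
#' @return The JSON string, invisibly when written to file.
#' @export
material_library_json <- function(library, path = NULL) {
  stripped <- lapply(unclass(library), function(x) {
    if (is.data.frame(x)) x else if (is.list(x)) lapply(x, unclass) else x
  })
  js <- jsonlite::toJSON(stripped, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
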