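# Five grades of age-related degeneration: trabecular density loss,
# cortical-trabecular debonding, and disc degeneration.

#' Degeneration grade specification
#'
#' Returns the full scenario card for one of the five age-degeneration grades:
#' \describe{
#'   \item{grade 1}{healthy: density 300 kg/m^3, bonded, healthy disc}
#'   \item{grade 2}{osteoporotic: density 100, bonded, healthy disc}
#'   \item{grade 3}{osteoporotic: density 100, unbonded, healthy disc}
#'   \item{grade 4}{osteoporotic + disc degeneration: density 100, bonded,
#'     degenerated disc}
#'   \item{grade 5}{density 100, unbonded, degenerated disc}
#' }
#' The healthy disc has nucleus (E = 1 MPa, nu = 0.4999) and annulus ground
#' substance from E = 1.4 MPa (C10 = 0.25, D = 0.86); the degenerated disc has
#' nucleus (E = 1.66 MPa, nu = 0.4) and annulus from E = 6.3 MPa
#' (C10 = 1.13, D = 0.19). Annulus Poisson's ratio is 0.40 in both cases.
#'
#' @param g Integer grade in 1..5.
#' @return An object of class `grade_spec`.
#' @export
grade_spec <- function(g) {
  if (!is.numeric(g) || length(g) != 1L || is.na(g) || g != round(g) || g < 1 || g > 5)
    stop("grade must be an integer in 1..5")
  g <- as.integer(g)
  healthy_disc <- g <= 3
  spec <- list(
    grade = g,
    trabecular_density = if (g == 1) 300 else 100,      # kg/m^3
    bond_state = if (g %in% c(3L, 5L)) "unbonded" else "bonded",
    nucleus_E = if (healthy_disc) 1 else 1.66,
    nucleus_nu = if (healthy_disc) 0.4999 else 0.4,
    annulus_E = if (healthy_disc) 1.4 else 6.3,
    annulus_nu = 0.40
  )
  nh <- neo_hookean_from_linear(spec$annulus_E, spec$annulus_nu)
  spec$annulus_C10 <- nh$C10
  spec$annulus_D1 <- nh$D
  structure(spec, class = "grade_spec")
}

#' @export
print.grade_spec <- function(x, ...) {
  cat(sprintf(
    "Degeneration grade %d: trabecular density %g kg/m^3, cortical bond %s,\n  nucleus (E = %g MPa, nu = %g), annulus (C10 = %.3g MPa, D1 = %.3g 1/MPa)\n",
    x$grade, x$trabecular_density, x$bond_state,
    x$nucleus_E, x$nucleus_nu, x$annulus_C10, x$annulus_D1))
  invisible(x)
}

#' Apply a degeneration grade to a segment mesh
#'
#' Builds the grade's material library and sets the activity of the
#' cortical-trabecular tie constraints. In the unbonded state the ties between
#' the lateral cortical wall and the trabecular core are deactivated for the
#' vertebrae in `debond_scope`, while the shell-endplate connections are always
#' retained so the load path through the endplates survives. The operation is
#' idempotent.
#'
#' @param mesh A `segment_mesh` with interface pair sets.
#' @param spec A `grade_spec` (or integer grade).
#' @param debond_scope Character vector of vertebra labels whose lateral wall
#'   is debonded when the grade is unbonded. Defaults to `"L3"`, the vertebra
#'   whose failure the grade sweep focuses on; use
#'   `c("L2", "L3", "L4")` to debond the whole segment.
#' @param ... Passed to [default_material_library()].
#' @return A list with elements `mesh` (tie activity updated) and `materials`.
#' @export
apply_grade <- function(mesh, spec, debond_scope = "L3", ...) {
  if (!inherits(mesh, "segment_mesh")) stop("'mesh' must be a segment_mesh")
  if (!inherits(spec, "grade_spec")) spec <- grade_spec(spec)
  ip <- mesh$interface_pairs
  if (is.null(ip) || nrow(ip) == 0L) stop("mesh has no interface pair map")
  active <- rep(TRUE, nrow(ip))
  if (spec$bond_state == "unbonded") {
    off <- ip$zone == "wall" & ip$vertebra %in% debond_scope
    active[off] <- FALSE
  }
  mesh$interface_pairs$active <- active
  mesh$grade <- spec$grade
  list(mesh = mesh, materials = default_material_library(spec, ...))
}
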