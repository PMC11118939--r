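# Constitutive parameter derivations and material cards.

test_that("density power law reproduces the tabulated cancellous moduli", {
  expect_equal(signif(density_to_modulus(0.3), 3), 723)
  expect_equal(signif(density_to_modulus(0.1), 3), 130)
  expect_equal(density_to_modulus(1.0), 4730)
  # kg/m^3 input converts
  expect_equal(density_to_modulus(density_card(300, "kg/m3")),
               density_to_modulus(0.3))
  expect_error(density_to_modulus(-1), "positive")
  expect_error(density_card(3000, "g/cm3"), "range")
})

test_that("density law is strictly increasing in density", {
  rhos <- seq(0.05, 2.5, length.out = 40)
  expect_true(all(diff(vapply(rhos, density_to_modulus, 0)) > 0))
})

test_that("transverse moduli are one tenth of the longitudinal modulus", {
  expect_equal(unname(transverse_from_longitudinal(723)), c(72.3, 72.3))
  expect_equal(unname(transverse_from_longitudinal(130)), c(13, 13))
  expect_error(transverse_from_longitudinal(0), "positive")
})

test_that("Neo-Hookean coefficients match the tabulated disc cards", {
  h <- neo_hookean_from_linear(1.4, 0.40)
  expect_equal(round(h$C10, 2), 0.25)
  expect_equal(round(h$D, 2), 0.86)
  d <- neo_hookean_from_linear(6.3, 0.40)
  expect_equal(d$C10, 1.125)            # prints as 1.13 at 2 d.p.
  expect_lt(abs(d$C10 - 1.13), 0.005 + 1e-12)
  expect_equal(round(d$D, 2), 0.19)
  # hand evaluation of the four relations
  m <- neo_hookean_from_linear(6, 0.25)
  expect_equal(m$mu0, 2.4)
  expect_equal(m$C10, 1.2)
  expect_equal(m$K0, 4)
  expect_equal(m$D, 0.5)
  expect_error(neo_hookean_from_linear(1.4, 0.5), "incompressible")
})

test_that("the as-printed bulk relation with (1 + 2 nu) cannot reproduce the tabulated D", {
  # the printed form K0 = E / (3 (1 + 2 nu)) gives D = 2/K0 far from 0.86;
  # only the standard K0 = E / (3 (1 - 2 nu)) reproduces the table
  K0_misprint <- 1.4 / (3 * (1 + 2 * 0.40))
  expect_gt(abs(round(2 / K0_misprint, 2) - 0.86), 1)
  expect_equal(round(neo_hookean_from_linear(1.4, 0.40)$D, 2), 0.86)
})

test_that("Neo-Hookean round-trip recovers E from C10 and nu", {
  for (E in c(1.4, 6.3, 10)) for (nu in c(0.1, 0.4, 0.45)) {
    h <- neo_hookean_from_linear(E, nu)
    expect_equal(4 * (1 + nu) * h$C10, E, tolerance = 1e-12)
  }
})

test_that("near-incompressible nucleus is representable (K0/mu0 large)", {
  h <- neo_hookean_from_linear(1, 0.4999)
  expect_gt(h$K0 / h$mu0, 1e3)
})

test_that("every tabulated orthotropic card is symmetric positive definite", {
  for (card in list(cortical_card(), trabecular_card(0.3), trabecular_card(0.1),
                    isotropic_as_orthotropic(50, 0.4),
                    isotropic_as_orthotropic(3500, 0.25))) {
    C <- orthotropic_stiffness(card)
    expect_equal(C, t(C))
    expect_gt(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("material library wires the grade cards onto the components", {
  lib1 <- default_material_library(1)
  expect_equal(signif(lib1$trabecular$E_zz, 3), 723)
  expect_equal(lib1$nucleus$nu, 0.4999)
  expect_equal(round(lib1$annulus$C10, 2), 0.25)
  expect_equal(round(lib1$annulus$D_table, 2), 0.86)
  lib5 <- default_material_library(5)
  expect_equal(signif(lib5$trabecular$E_zz, 3), 130)
  expect_lt(abs(lib5$annulus$C10 - 1.13), 0.005 + 1e-12)
  expect_equal(lib5$nucleus$E, 1.66)
  # grades 4 and 5 differ only in bond state, not in any card
  lib4 <- default_material_library(4)
  strip <- function(l) { l$grade <- NULL; unclass(l) }
  expect_equal(strip(lib4), strip(lib5))
  # cortical card identical across grades; yield stress 64 MPa
  expect_equal(lib1$cortical$elastic, lib5$cortical$elastic)
  expect_equal(lib1$cortical$plastic$yield_stress, 64)
  # tabulated annulus volumetric coefficient is restorable
  libt <- default_material_library(1, annulus_volumetric_nu = 0.40)
  expect_equal(round(libt$annulus$D, 2), 0.86)
  expect_error(default_material_library(7), "grade")
})

test_that("ligament cards carry the six groups with the standard moduli", {
  lig <- ligament_cards()
  expect_setequal(lig$group, c("ALL", "PLL", "CL", "LF", "ISS", "SSL"))
  expect_equal(lig$E[match(c("ALL", "PLL", "CL", "LF", "ISS", "SSL"), lig$group)],
               c(20, 20, 33, 19, 12, 12))
  expect_true(all(lig$nu == 0.3))
  expect_true(all(lig$area > 0))
  over <- ligament_cards(c(ALL = 100))
  expect_equal(over$area[over$group == "ALL"], 100)
  expect_error(ligament_cards(c(XX = 10)), "unknown")
})
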