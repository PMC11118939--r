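# Five-grade degeneration scenarios and their application to a mesh.

test_that("grade specifications reproduce the degeneration table", {
  g1 <- grade_spec(1)
  expect_equal(g1$trabecular_density, 300)
  expect_equal(g1$bond_state, "bonded")
  expect_equal(g1$nucleus_E, 1)
  expect_equal(g1$nucleus_nu, 0.4999)
  expect_equal(round(g1$annulus_C10, 2), 0.25)
  g3 <- grade_spec(3)
  expect_equal(g3$trabecular_density, 100)
  expect_equal(g3$bond_state, "unbonded")
  expect_equal(g3$nucleus_E, 1)       # healthy disc cards
  g5 <- grade_spec(5)
  expect_equal(g5$bond_state, "unbonded")
  expect_equal(g5$nucleus_E, 1.66)
  expect_equal(g5$nucleus_nu, 0.4)
  expect_lt(abs(g5$annulus_C10 - 1.13), 0.005 + 1e-12)
  expect_error(grade_spec(0), "1..5")
  expect_error(grade_spec(2.5), "1..5")
  # structural relations between neighbouring grades
  g2 <- grade_spec(2); g4 <- grade_spec(4)
  expect_equal(g1$nucleus_E, g2$nucleus_E)          # 1 vs 2: density only
  expect_equal(g2[setdiff(names(g2), c("grade", "bond_state"))],
               g3[setdiff(names(g3), c("grade", "bond_state"))])  # 2 vs 3: bond only
  expect_equal(g4[setdiff(names(g4), c("grade", "bond_state"))],
               g5[setdiff(names(g5), c("grade", "bond_state"))])  # 4 vs 5: bond only
})

test_that("apply_grade toggles the lateral wall ties and is idempotent", {
  mesh <- coarse_segment()
  a1 <- apply_grade(mesh, grade_spec(1))
  expect_true(all(a1$mesh$interface_pairs$active))
  a3 <- apply_grade(mesh, grade_spec(3))          # default debond scope: L3
  ip <- a3$mesh$interface_pairs
  expect_true(all(!ip$active[ip$zone == "wall" & ip$vertebra == "L3"]))
  expect_true(all(ip$active[ip$zone == "endplate"]))
  expect_true(all(ip$active[ip$vertebra != "L3"]))
  # all-vertebra scope
  a3all <- apply_grade(mesh, grade_spec(3), debond_scope = c("L2", "L3", "L4"))
  ip2 <- a3all$mesh$interface_pairs
  expect_true(all(!ip2$active[ip2$zone == "wall"]))
  expect_true(all(ip2$active[ip2$zone == "endplate"]))
  # idempotence
  a3b <- apply_grade(a3$mesh, grade_spec(3))
  expect_identical(a3$mesh$interface_pairs, a3b$mesh$interface_pairs)
  # grade 2 vs 4: identical tie sets, different disc cards
  a2 <- apply_grade(mesh, grade_spec(2)); a4 <- apply_grade(mesh, grade_spec(4))
  expect_identical(a2$mesh$interface_pairs, a4$mesh$interface_pairs)
  expect_false(isTRUE(all.equal(a2$materials$nucleus, a4$materials$nucleus)))
})

test_that("softening and debonding each reduce the initial axial stiffness", {
  mesh <- coarse_segment()
  k_of <- function(g) {
    ag <- apply_grade(mesh, grade_spec(g))
    h <- solve_quasi_static(ag$mesh, ag$materials,
                            schedule = load_schedule(0.25, t_bar = 1))
    tb <- history_table(h)
    tb$F_kN[1] / tb$u_z_mm[1]
  }
  k1 <- k_of(1); k2 <- k_of(2); k3 <- k_of(3)
  expect_gt(k1, k2)
  expect_gt(k2, k3)
})
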