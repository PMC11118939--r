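# Parametric geometry: vertebra, disc, assembled segment, imperfection.

test_that("default vertebra mesh has the nominal dimensions and sets", {
  mesh <- build_vertebra(element_size = 3, label = "L3")
  expect_gt(nrow(mesh$hex), 0)
  expect_gt(nrow(mesh$shell), 0)
  expect_equal(max(mesh$nodes[, 3]), 30)
  # width within one element of 40 mm (shell offset adds half a thickness)
  expect_lt(abs(diff(range(mesh$nodes[, 1])) - 40), 3)
  expect_true(all(c("trabecular_L3", "posterior_L3", "cortical_L3",
                    "endplate_L3_bottom", "endplate_L3_top") %in%
                  c(mesh$hex_set, mesh$shell_set)))
  expect_silent(validate_mesh(mesh))
})

test_that("degenerate configurations are rejected", {
  expect_error(vertebra_config(cortical_thickness = 0), "positive")
  expect_error(vertebra_config(cortical_thickness = 3), "thin")
  expect_error(build_vertebra(element_size = 8), "element_size")
  expect_error(disc_config(nucleus_area_fraction = 0.25), "0.30")
  expect_error(disc_config(height = 20), "8")
})

test_that("vertebra volume is stable under refinement", {
  v3 <- mesh_volume(build_vertebra(element_size = 3))
  v2 <- mesh_volume(build_vertebra(element_size = 2))
  v1 <- mesh_volume(build_vertebra(element_size = 1))
  expect_lt(abs(v2 / v3 - 1), 0.05)
  expect_lt(abs(v1 / v2 - 1), 0.05)
  # refinement converges towards the finest estimate
  expect_lt(abs(v2 - v1), abs(v3 - v1) + 1e-9)
})

test_that("hex Jacobians stay positive across the meshing range", {
  for (h in c(3, 1.5)) {
    mesh <- assemble_segment(element_size = h)
    geo <- lumbarfe:::hex_geometry_cpp(mesh$nodes, mesh$hex - 1L)
    expect_gt(min(geo$min_detJ), 0)
  }
})

test_that("disc nucleus fraction and fibre angles match the configuration", {
  mesh <- build_disc(disc_config(nucleus_area_fraction = 0.40),
                     vertebra_config(), element_size = 2, label = "D")
  frac <- disc_area_fraction(mesh, "D")
  expect_gte(frac, 0.37)
  expect_lte(frac, 0.43)
  ang <- fibre_orientation(mesh)
  expect_setequal(unique(abs(ang)), 30)
  expect_setequal(unique(sign(ang)), c(-1, 1))
  # both fibre layers present
  expect_true(any(grepl("^fibre_external", mesh$shell_set)))
  expect_true(any(grepl("^fibre_internal", mesh$shell_set)))
})

test_that("assembled segment stacks to the nominal height with six ligament groups", {
  mesh <- coarse_segment()
  expect_equal(max(mesh$nodes[, 3]), 3 * 30 + 2 * 10)
  expect_setequal(unique(mesh$link_set), c("ALL", "PLL", "CL", "LF", "ISS", "SSL"))
  expect_true(all(table(mesh$link_set) >= 1))
  expect_silent(validate_mesh(mesh))
  # interface map is a bijection
  ip <- mesh$interface_pairs
  expect_equal(anyDuplicated(ip$shell_node), 0)
  expect_equal(anyDuplicated(ip$solid_node), 0)
  # kinematic sets and probe defined
  expect_true(all(c("base_L4", "top_endplate_L2", "probe_point_A") %in%
                  names(mesh$node_sets)))
  probe <- mesh$node_sets$probe_point_A
  expect_lt(abs(mesh$nodes[probe, 3] - (30 + 10 + 15)), 5)  # mid-height of L3
})

test_that("imperfection is bounded, seeded and reversible at zero amplitude", {
  mesh <- assemble_segment(element_size = 5)
  expect_identical(apply_imperfection(mesh, imperfection(amplitude = 0)), mesh)
  m1 <- apply_imperfection(mesh, imperfection(amplitude = 0.01, seed = 7))
  m2 <- apply_imperfection(mesh, imperfection(amplitude = 0.01, seed = 7))
  expect_identical(m1, m2)
  d <- sqrt(rowSums((m1$nodes - mesh$nodes)^2))
  expect_lte(max(d), 0.01 + 1e-12)
  expect_gt(max(d), 0)
  m3 <- apply_imperfection(mesh, imperfection(amplitude = 0.01, seed = 8))
  expect_false(identical(m1$nodes, m3$nodes))
})
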