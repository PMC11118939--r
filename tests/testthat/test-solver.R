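# Global solver verification: uniaxial column, tie-constraint equivalence,
# equilibrium, symmetry and determinism.

test_that("compressed elastic block reproduces the closed-form stiffness", {
  # 30 mm trabecular-like column, nu = 0. At a small 0.1 mm compression the
  # reaction matches E A strain / h within 1% (geometric nonlinearity small);
  # at the full 2.5 mm (8.3% strain) it matches the total-Lagrangian bar
  # closed form P = A lambda E (lambda^2 - 1)/2 within 1%.
  mesh <- box_mesh(10, 10, 30, 3, 3, 6)
  lib <- box_library(E = 700, nu = 0)
  cs <- constraint_set(mesh, fixed = "base", driven = "top_endplate")
  h_small <- solve_quasi_static(fe_model(mesh, lib, cs,
                                         load_schedule(u_z_max = 0.1, n_increments = 1)))
  expect_equal(h_small$states[[1]]$reaction_kN * 1000, 700 * 100 * (0.1 / 30),
               tolerance = 0.01)
  h <- solve_quasi_static(fe_model(mesh, lib, cs,
                                   load_schedule(u_z_max = 2.5, n_increments = 5)))
  F_fe <- h$states[[length(h$states)]]$reaction_kN * 1000
  lam <- 1 - 2.5 / 30
  F_exact <- -100 * lam * 700 * (lam^2 - 1) / 2
  expect_equal(F_fe, F_exact, tolerance = 0.01)
  # zero imposed displacement: zero reaction and stress
  h0 <- solve_quasi_static(fe_model(mesh, lib, cs,
                                    load_schedule(u_z_max = 1e-12, n_increments = 1)))
  expect_lt(abs(h0$states[[1]]$reaction_kN), 1e-9)
  expect_lt(h0$states[[1]]$vm_solid, 1e-9)
})

test_that("node-to-node ties reproduce the conforming mesh", {
  # conforming: two stacked unit cubes sharing the interface nodes
  conf <- box_mesh(1, 1, 2, 1, 1, 2)
  # tied: duplicate interface nodes coupled through the tie map
  bot <- unit_cube_nodes()
  top <- unit_cube_nodes(); top[, 3] <- top[, 3] + 1
  nodes <- rbind(bot, top)
  tied <- conf
  tied$nodes <- nodes
  tied$hex <- rbind(matrix(1:8, 1), matrix(9:16, 1))
  tied$hex_set <- rep("trabecular_T", 2)
  tied$node_sets <- list(base = which(nodes[, 3] < 1e-9),
                         top_endplate = which(nodes[, 3] > 2 - 1e-9))
  tied$node_kind <- rep("solid", 16)
  tied$interface_pairs <- data.frame(shell_node = 9:12, solid_node = 5:8,
                                     vertebra = "T", zone = "wall", active = TRUE)
  lib <- box_library(E = 10, nu = 0.3)
  sch <- load_schedule(u_z_max = 0.1, n_increments = 1)
  h1 <- solve_quasi_static(fe_model(conf, lib, constraint_set(conf), sch))
  h2 <- solve_quasi_static(fe_model(tied, lib, constraint_set(tied), sch))
  expect_lt(abs(h1$states[[1]]$reaction_kN - h2$states[[1]]$reaction_kN) /
            abs(h1$states[[1]]$reaction_kN), 1e-8)
  # interface displacements match across the tie
  U2 <- h2$states[[1]]$U
  expect_lt(max(abs(U2[9:12, ] - U2[5:8, ])), 1e-12)
})

test_that("global equilibrium holds at every converged increment", {
  mesh <- coarse_segment()
  ag <- apply_grade(mesh, grade_spec(2))
  model <- fe_model(ag$mesh, ag$materials, schedule = load_schedule(2.5, n_increments = 2))
  h <- solve_quasi_static(model)
  st <- h$states[[length(h$states)]]
  asm <- lumbarfe:::assemble_system(model, st$u_red, st$pstate, want_kg = FALSE)
  # internal force is self-equilibrated: the axial components over all
  # reduced dofs (support + driven reactions + converged free residuals)
  # sum to zero within solver tolerance
  zred <- unique(model$red_of[seq(3, 3 * model$n, 3)])
  fz_all <- sum(asm$fint[zred])
  expect_lt(abs(fz_all), 1e-6 * max(1, abs(st$reaction_kN * 1000)))
})

test_that("solution of the symmetric model is mirror-symmetric", {
  mesh <- assemble_segment(element_size = 5)   # no imperfection
  ag <- apply_grade(mesh, grade_spec(1))
  h <- solve_quasi_static(ag$mesh, ag$materials,
                          schedule = load_schedule(1, n_increments = 1),
                          tol_rel = 1e-10)
  U <- h$states[[1]]$U
  # mirror partners about the x = 0 plane
  key <- paste(round(-mesh$nodes[, 1], 6), round(mesh$nodes[, 2], 6),
               round(mesh$nodes[, 3], 6))
  self <- paste(round(mesh$nodes[, 1], 6), round(mesh$nodes[, 2], 6),
                round(mesh$nodes[, 3], 6))
  partner <- match(key, self)
  ok <- !is.na(partner)
  expect_gt(mean(ok), 0.95)
  scale <- max(abs(U))
  expect_lt(max(abs(U[ok, 1] + U[partner[ok], 1])) / scale, 1e-5)
  expect_lt(max(abs(U[ok, 2] - U[partner[ok], 2])) / scale, 1e-5)
  expect_lt(max(abs(U[ok, 3] - U[partner[ok], 3])) / scale, 1e-5)
})

test_that("repeated runs with a fixed seed are identical", {
  cfg <- run_config(grade = 2, element_size = 5, n_increments = 2, seed = 3)
  r1 <- run_single_grade(cfg)
  r2 <- run_single_grade(cfg)
  expect_identical(history_table(r1$history), history_table(r2$history))
  expect_identical(r1$metrics, r2$metrics)
})
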