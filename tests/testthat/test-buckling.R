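# Linearized buckling and geometric-stiffness properties.

test_that("column buckling load matches the Euler closed form within 5%", {
  # base clamped, top face driven by a uniform axial displacement (the face
  # cannot tilt, lateral translation free): effective length L, so
  # P_cr = pi^2 E I / L^2
  ec <- fixture("euler_column", euler_column)
  at <- assemble_tangent(ec$model, state = ec$state)
  modes <- linearized_buckling(at, nev = 2)
  expect_gte(length(modes), 1)
  Pcr <- modes[[1]]$lambda * ec$P_ref
  exact <- pi^2 * 1000 * (4^4 / 12) / 60^2
  expect_lt(abs(Pcr / exact - 1), 0.05)
})

test_that("doubling the elastic moduli doubles the buckling multiplier", {
  ec <- fixture("euler_column", euler_column)
  at <- assemble_tangent(ec$model, state = ec$state)
  l1 <- linearized_buckling(at, nev = 1)[[1]]$lambda
  # same geometric stress state, stiffness scaled by 2
  l2 <- linearized_buckling(2 * at$K_e, at$K_sigma, free = at$free, nev = 1)[[1]]$lambda
  expect_equal(l2 / l1, 2, tolerance = 1e-6)
})

test_that("geometric softening grows with axial pre-compression", {
  # smallest eigenvalue estimate of K_e + K_sigma decreases as compression
  # grows: probe via the Rayleigh quotient of the first buckling mode
  ec <- fixture("euler_column", euler_column)
  at1 <- assemble_tangent(ec$model, state = ec$state)
  mode <- linearized_buckling(at1, nev = 1)[[1]]
  phi <- mode$mode_shape
  rq <- function(at) {
    Ke <- at$K_e[at$free, at$free]; Ks <- at$K_sigma[at$free, at$free]
    as.numeric((phi %*% (Ke %*% phi) + phi %*% (Ks %*% phi)) / sum(phi^2))
  }
  h2 <- solve_quasi_static(fe_model(ec$mesh, box_library(E = 1000, nu = 0),
                                    constraint_set(ec$mesh, "base", "top_endplate"),
                                    load_schedule(u_z_max = 0.05, n_increments = 1)))
  at2 <- assemble_tangent(h2$model, state = h2$states[[1]])
  expect_lt(rq(at2), rq(at1))
})

test_that("elastic stiffness is positive definite at the reference state", {
  mesh <- coarse_segment()
  ag <- apply_grade(mesh, grade_spec(1))
  at <- assemble_tangent(ag$mesh, ag$materials)
  ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(
    at$K_e[at$free, at$free]), LDL = FALSE), error = function(e) NULL)
  expect_false(is.null(ch))
})

test_that("trabecular softening lowers the single-vertebra buckling multiplier", {
  one_vert <- function(rho) {
    mesh <- build_vertebra(element_size = 4, label = "L3")
    lib <- default_material_library(2)
    lib$trabecular <- trabecular_card(rho)
    cs <- constraint_set(mesh, fixed = "base", driven = "top_endplate")
    model <- fe_model(mesh, lib, cs, load_schedule(u_z_max = 0.1, n_increments = 1))
    h <- solve_quasi_static(model)
    at <- assemble_tangent(model, state = h$states[[1]])
    linearized_buckling(at, nev = 1)[[1]]$lambda
  }
  expect_gt(one_vert(0.3), one_vert(0.1))
})
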