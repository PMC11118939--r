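# Internal-force oracle: on small meshes the assembled internal force must
# equal the gradient of the total strain energy (central finite differences)
# for every elastic material model.

fd_gradient <- function(energy_fn, u, h = 1e-6) {
  g <- numeric(length(u))
  for (i in seq_along(u)) {
    up <- u; um <- u
    up[i] <- up[i] + h; um[i] <- um[i] - h
    g[i] <- (energy_fn(up) - energy_fn(um)) / (2 * h)
  }
  g
}

test_that("hex internal force equals the energy gradient for all material types", {
  X <- unit_cube_nodes()
  set.seed(42)
  u <- runif(24, -0.02, 0.02)
  cards <- list(
    orthotropic = trabecular_card(0.3),
    isotropic_sri = isotropic_card(50, 0.4),
    near_incompressible = isotropic_card(1, 0.4999),
    neo_hookean = neo_hookean_from_linear(1.4, 0.40)
  )
  for (nm in names(cards)) {
    card <- cards[[nm]]
    r <- hex_stiffness_and_force(X, card, u)
    g <- fd_gradient(function(v) hex_stiffness_and_force(X, card, v)$energy, u)
    expect_lt(max(abs(g - r$f)) / max(abs(r$f)), 1e-4, label = nm)
  }
})

test_that("shell and membrane internal forces equal their energy gradients", {
  X <- matrix(c(0, 0, 0, 2, 0.1, 0, 2.1, 1, 0.05, -0.1, 1.1, 0), 4, 3, byrow = TRUE)
  card <- cortical_card()
  set.seed(7)
  u <- runif(24, -1e-3, 1e-3)
  r <- shell_stiffness_and_force(X, card, thickness = 0.5, u = u)
  g <- fd_gradient(function(v)
    shell_stiffness_and_force(X, card, thickness = 0.5, u = v)$energy, u, h = 1e-7)
  expect_lt(max(abs(g - r$f)) / max(abs(r$f)), 1e-4)
  um <- runif(12, -1e-3, 1e-3)
  um[c(4, 7)] <- um[c(4, 7)] + 0.02   # net stretch so the fibres are taut
  fib <- list(E = 500, angle = -30)
  rmem <- shell_stiffness_and_force(X, fib, thickness = 0.75, u = um, bending = FALSE)
  gm <- fd_gradient(function(v)
    shell_stiffness_and_force(X, fib, thickness = 0.75, u = v, bending = FALSE)$energy,
    um, h = 1e-7)
  expect_lt(max(abs(gm - rmem$f)) / max(abs(rmem$f)), 1e-4)
})

test_that("assembled model internal force equals the total energy gradient", {
  # 27-element elastic box (under the 200-element oracle ceiling)
  mesh <- box_mesh(2, 2, 2, 3, 3, 3, jitter = 0.05, seed = 11)
  lib <- box_library(E = 10, nu = 0.3)
  model <- fe_model(mesh, lib)
  set.seed(5)
  u <- runif(model$nred, -0.01, 0.01)
  asm <- lumbarfe:::assemble_system(model, u, model$pstate0, FALSE)
  efun <- function(v) lumbarfe:::assemble_system(model, v, model$pstate0, FALSE)$energy
  g <- fd_gradient(efun, u, h = 1e-6)
  expect_lt(max(abs(g - asm$fint)) / max(abs(asm$fint)), 1e-4)
})

test_that("link force is the gradient of the tension-only energy", {
  X <- matrix(c(0, 0, 0, 3, 4, 0), 2, 3, byrow = TRUE)   # L0 = 5
  EA <- 200
  efun <- function(u) lumbarfe:::link_asm_cpp(X, matrix(0:1, 1, 2), EA, u, FALSE)$energy
  set.seed(2)
  u <- c(0, 0, 0, 0.2, 0.3, 0.1)   # stretched state
  r <- lumbarfe:::link_asm_cpp(X, matrix(0:1, 1, 2), EA, u, FALSE)
  g <- fd_gradient(efun, u, h = 1e-7)
  expect_lt(max(abs(g - as.vector(r$fint))) / max(abs(r$fint)), 1e-6)
})
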