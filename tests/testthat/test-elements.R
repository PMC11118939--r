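# Single-element oracles: hex kernels, shells, links, return mapping.

test_that("hex under uniaxial stretch with nu = 0 gives uniaxial stress", {
  X <- unit_cube_nodes()
  card <- isotropic_card(1, 0)
  u <- numeric(24); u[seq(3, 24, 3)] <- 0.001 * X[, 3]
  r <- hex_stiffness_and_force(X, card, u)
  expect_equal(r$von_mises, 0.001, tolerance = 5e-3)
  top_f <- sum(r$f[seq(3, 24, 3)][X[, 3] == 1])
  expect_equal(top_f, 0.001, tolerance = 5e-3)
  # transverse faces unloaded
  side_f <- sum(abs(r$f[seq(1, 24, 3)]))
  expect_lt(side_f, 1e-5)
  expect_equal(r$volume, 1)
})

test_that("Neo-Hookean tangent at identity equals the small-strain moduli", {
  X <- unit_cube_nodes()
  nh <- neo_hookean_from_linear(1.4, 0.40)
  r_nh <- hex_stiffness_and_force(X, nh)
  r_lin <- hex_stiffness_and_force(X, isotropic_card(1.4, 0.40))
  expect_equal(max(abs(r_nh$f)), 0)           # zero stress at identity
  expect_lt(max(abs(r_nh$K - r_lin$K)) / max(abs(r_lin$K)), 1e-6)
})

test_that("distorted patch reproduces a linear displacement field exactly", {
  # 2x2x2 box with jittered interior node; linear field imposed on the
  # boundary must be reproduced at the interior node with constant stress
  mesh <- box_mesh(1, 1, 1, 2, 2, 2, jitter = 0.12, seed = 3)
  lib <- box_library(E = 200, nu = 0.3)
  A <- matrix(c(1e-3, 4e-4, 2e-4,
                4e-4, -5e-4, 1e-4,
                2e-4, 1e-4, 8e-4), 3, 3)   # symmetric small strain
  u_lin <- t(A %*% t(mesh$nodes))
  n <- nrow(mesh$nodes)
  bnd <- which(apply(mesh$nodes, 1, function(p)
    any(abs(p - 0) < 1e-9 | abs(p - 1) < 1e-9)))
  interior <- setdiff(seq_len(n), bnd)
  cs <- constraint_set(mesh, fixed = bnd, driven = interior[1])
  model <- fe_model(mesh, lib, cs)
  # impose the linear field on the boundary directly and solve for interior
  u_red <- numeric(model$nred)
  dof_of <- function(nodes) cbind(3 * (nodes - 1) + 1, 3 * (nodes - 1) + 2, 3 * (nodes - 1) + 3)
  u_full_target <- as.vector(t(u_lin))
  u_red[model$red_of] <- 0
  # set prescribed (fixed) dofs to the linear field values
  fix_dofs <- as.vector(t(dof_of(bnd)))
  u_red[model$red_of[fix_dofs]] <- u_full_target[fix_dofs]
  # Newton on the remaining dofs
  free <- setdiff(seq_len(model$nred), unique(model$red_of[fix_dofs]))
  for (it in 1:6) {
    asm <- lumbarfe:::assemble_system(model, u_red, model$pstate0, TRUE)
    r <- -asm$fint[free]
    if (sqrt(sum(r^2)) < 1e-12) break
    K <- model$Ktemplate; K@x <- asm$Kx_m + asm$Kx_g
    du <- as.vector(Matrix::solve(K[free, free], r))
    u_red[free] <- u_red[free] + du
  }
  u_sol <- u_red[model$red_of]
  err <- max(abs(u_sol - u_full_target))
  expect_lt(err, 1e-10)
  # stress constant across elements: von Mises spread near zero
  expect_lt(diff(range(asm$vm_hex)) / max(asm$vm_hex), 1e-6)
})

test_that("shell membrane matches plane stress and fibre layers carry no bending", {
  X <- matrix(c(0, 0, 0, 2, 0, 0, 2, 1, 0, 0, 1, 0), 4, 3, byrow = TRUE)
  card <- isotropic_as_orthotropic(1000, 0.3)
  u <- numeric(24); u[c(4, 7)] <- 2e-3   # eps_x = 1e-3, eps_y = 0
  r <- shell_stiffness_and_force(X, card, thickness = 0.5, u = u)
  sx <- 1000 * 1e-3 / (1 - 0.09); sy <- 0.3 * sx
  expect_equal(r$von_mises, sqrt(sx^2 - sx * sy + sy^2), tolerance = 2e-3)
  # fibre membrane: no bending stiffness -- transverse (plate-bending) modes
  # meet zero linearized resistance at the reference state
  Dfib <- list(E = 500, angle = 30)
  w <- c(1, -1, 1, -1)                   # alternating transverse mode
  um <- numeric(12); um[seq(3, 12, 3)] <- w
  rm0 <- shell_stiffness_and_force(X, Dfib, thickness = 0.75, u = numeric(12),
                                   bending = FALSE)
  expect_lt(max(abs(rm0$K %*% um)), 1e-12)
  expect_lt(max(abs(rm0$K_geo %*% um)), 1e-12)
  expect_error(shell_stiffness_and_force(X[c(1, 1, 2, 2), ] * 0, card, 0.5),
               "zero-area")
})

test_that("clamped-free MITC4 plate converges to the thin-plate solution", {
  # simply supported square plate, uniform load: Navier series w_c =
  # 0.00406 q a^4 / D at nu = 0.3
  a <- 1; nel <- 12; t <- 0.01; E <- 1e6; nu <- 0.3
  mesh <- box_mesh(a, a, 1, nel, nel, 1)   # reuse grid helper for nodes only
  xs <- seq(0, a, length.out = nel + 1)
  nodes <- cbind(as.matrix(expand.grid(x = xs, y = xs)), 0)
  nid <- function(i, j) i + (j - 1) * (nel + 1)
  conn <- matrix(0L, nel * nel, 4); e <- 0
  for (j in 1:nel) for (i in 1:nel) {
    e <- e + 1
    conn[e, ] <- c(nid(i, j), nid(i + 1, j), nid(i + 1, j + 1), nid(i, j + 1))
  }
  nn <- nrow(nodes)
  card <- isotropic_as_orthotropic(E, nu)
  K <- matrix(0, 6 * nn, 6 * nn)
  dof_of <- function(n) c(3 * (n - 1) + 1:3, 3 * nn + 3 * (n - 1) + 1:3)
  for (e in seq_len(nrow(conn))) {
    r <- shell_stiffness_and_force(nodes[conn[e, ], ], card, thickness = t)
    d <- as.vector(vapply(conn[e, ], function(n) 3 * (n - 1) + 1:3, numeric(3)))
    d <- c(d, 3 * nn + d)
    K[d, d] <- K[d, d] + r$K
  }
  f <- numeric(6 * nn)
  f[3 * (seq_len(nn) - 1) + 3] <- (a / nel)^2   # tributary uniform load q=1
  edge <- which(nodes[, 1] %in% c(0, a) | nodes[, 2] %in% c(0, a))
  fixed <- c(as.vector(vapply(seq_len(nn), function(n) 3 * (n - 1) + 1:2, numeric(2))),
             3 * (edge - 1) + 3)
  free <- setdiff(seq_len(6 * nn), fixed)
  w <- solve(K[free, free], f[free])
  u <- numeric(6 * nn); u[free] <- w
  ctr <- nid(nel / 2 + 1, nel / 2 + 1)
  wc <- u[3 * (ctr - 1) + 3]
  D <- E * t^3 / (12 * (1 - nu^2))
  expect_equal(wc, 0.00406 / D, tolerance = 0.02)
})

test_that("tension-only ligament law", {
  card <- list(E = 20, area = 10)
  expect_equal(link_force_tension_only(0.1, card, 10), 2)
  expect_equal(link_force_tension_only(-0.5, card, 10), 0)
  expect_equal(link_force_tension_only(0, card, 10), 0)
  expect_error(link_force_tension_only(0.1, card, 0), "positive")
})

test_that("von Mises radial return maps onto the hardened yield surface", {
  card <- plasticity_card(yield_stress = 64, hardening_modulus = 0)
  # elastic: trial below yield unchanged
  r1 <- return_map_von_mises(c(43.6, 0, 0, 0, 0, 0), card)
  expect_equal(r1$stress, c(43.6, 0, 0, 0, 0, 0))
  expect_equal(r1$eq_plastic, 0)
  # boundary: exactly at yield, no plastic increment
  r2 <- return_map_von_mises(c(64, 0, 0, 0, 0, 0), card)
  expect_equal(r2$eq_plastic, 0)
  # perfect plasticity: uniaxial 100 returns to vm = 64
  r3 <- return_map_von_mises(c(100, 0, 0, 0, 0, 0), card, mu = 3000)
  expect_equal(r3$von_mises, 64, tolerance = 1e-10)
  expect_gt(r3$eq_plastic, 0)
  # hardening raises the return surface
  cardH <- plasticity_card(64, 1000)
  r4 <- return_map_von_mises(c(100, 0, 0, 0, 0, 0), cardH, mu = 3000)
  expect_gt(r4$von_mises, 64)
  expect_lt(r4$von_mises, 100)
  # plane-stress backward-Euler map agrees with the 3D map on a uniaxial state
  E <- 10000; nu <- 0.3
  Dps <- E / (1 - nu^2) * matrix(c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2), 3, 3)
  eps <- solve(Dps, c(100, 0, 0))
  ps <- lumbarfe:::ps_return_map_cpp(Dps, eps, numeric(3), 0, 64, 0)
  s <- ps$sigma
  expect_equal(sqrt(s[1]^2 - s[1] * s[2] + s[2]^2 + 3 * s[3]^2), 64, tolerance = 1e-8)
})
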