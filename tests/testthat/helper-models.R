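# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# unit cube hex: nodes in standard order (bottom quad ccw, then top)
unit_cube_nodes <- function(L = 1) {
  matrix(c(0, 0, 0, L, 0, 0, L, L, 0, 0, L, 0,
           0, 0, L, L, 0, L, L, L, L, 0, L, L),
         8, 3, byrow = TRUE)
}

# structured box mesh (nx x ny x nz cells) returning a minimal segment_mesh-like
# object usable by fe_model: hex elements of one material set
box_mesh <- function(Lx, Ly, Lz, nx, ny, nz, set = "trabecular_T",
                     jitter = 0, seed = 1) {
  xs <- seq(0, Lx, length.out = nx + 1)
  ys <- seq(0, Ly, length.out = ny + 1)
  zs <- seq(0, Lz, length.out = nz + 1)
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  if (jitter > 0) {
    set.seed(seed)
    interior <- nodes[, 1] > 0 & nodes[, 1] < Lx &
      nodes[, 2] > 0 & nodes[, 2] < Ly &
      nodes[, 3] > 0 & nodes[, 3] < Lz
    nodes[interior, ] <- nodes[interior, ] +
      matrix(runif(3 * sum(interior), -jitter, jitter), ncol = 3)
  }
  nid <- function(i, j, k) i + (j - 1) * (nx + 1) + (k - 1) * (nx + 1) * (ny + 1)
  conn <- matrix(0L, nx * ny * nz, 8)
  e <- 0L
  for (k in 1:nz) for (j in 1:ny) for (i in 1:nx) {
    e <- e + 1L
    conn[e, ] <- c(nid(i, j, k), nid(i + 1, j, k), nid(i + 1, j + 1, k), nid(i, j + 1, k),
                   nid(i, j, k + 1), nid(i + 1, j, k + 1), nid(i + 1, j + 1, k + 1), nid(i, j + 1, k + 1))
  }
  structure(list(
    nodes = nodes, hex = conn, hex_set = rep(set, nrow(conn)),
    shell = matrix(0L, 0, 4), shell_set = character(0),
    shell_thickness = numeric(0), fibre_angle = numeric(0),
    link = matrix(0L, 0, 2), link_set = character(0),
    node_sets = list(base = which(nodes[, 3] < 1e-9),
                     top_endplate = which(nodes[, 3] > Lz - 1e-9)),
    node_kind = rep("solid", nrow(nodes)),
    interface_pairs = data.frame(shell_node = integer(0), solid_node = integer(0),
                                 vertebra = character(0), zone = character(0),
                                 active = logical(0)),
    element_size = Lx / nx, labels = "T"
  ), class = "segment_mesh")
}

# material library with a single elastic solid card for box tests; expressed
# as an orthotropic (fully integrated) card so the box oracles exercise the
# exact geometric nonlinearity
box_library <- function(E = 100, nu = 0.3) {
  lib <- default_material_library(1)
  lib$trabecular <- if (nu > 0.45) isotropic_card(E, nu)
                    else isotropic_as_orthotropic(E, nu)
  lib
}

# the scaled-down imperfect segment mesh shared by integration tests
coarse_segment <- function() fixture("coarse_segment", function() {
  mesh <- assemble_segment(element_size = 5)
  apply_imperfection(mesh, imperfection(amplitude = 0.04, seed = 1))
})

# slender elastic column (clamped base, uniformly driven top face) solved to
# a small reference compression; shared by the buckling oracles
euler_column <- function(E = 1000, b = 4, L = 60, d_ref = 0.01) {
  mesh <- box_mesh(b, b, L, 4, 4, 48)
  lib <- box_library(E = E, nu = 0)
  cs <- constraint_set(mesh, fixed = "base", driven = "top_endplate")
  model <- fe_model(mesh, lib, cs, load_schedule(u_z_max = d_ref, n_increments = 1))
  h <- solve_quasi_static(model)
  list(model = model, state = h$states[[1]], mesh = mesh,
       P_ref = h$states[[1]]$reaction_kN * 1000)
}
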