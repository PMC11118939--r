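# Deformation metrics and the convergence harness.

test_that("bulge is the maximum outward radial displacement, translation-invariant", {
  mesh <- coarse_segment()
  n <- nrow(mesh$nodes)
  U0 <- matrix(0, n, 3)
  expect_equal(bulge_metric(U0, mesh, "wall_L3"), 0)
  # synthetic radial field of 0.5 mm on the wall nodes
  ids <- mesh$node_sets$wall_L3
  xy <- mesh$nodes[ids, 1:2]
  ctr <- colMeans(xy)
  rhat <- sweep(xy, 2, ctr)
  rhat <- rhat / sqrt(rowSums(rhat^2))
  U <- U0; U[ids, 1:2] <- 0.5 * rhat
  expect_equal(bulge_metric(U, mesh, "wall_L3"), 0.5, tolerance = 1e-4)
  # rigid translation leaves all metrics unchanged
  Ut <- U; Ut[, 1] <- Ut[, 1] + 3; Ut[, 2] <- Ut[, 2] - 1; Ut[, 3] <- Ut[, 3] + 2
  expect_equal(bulge_metric(Ut, mesh, "wall_L3"), 0.5, tolerance = 1e-4)
  Urig <- matrix(rep(c(1, 2, 3), each = n), n, 3)
  expect_equal(bulge_metric(Urig, mesh, "wall_L3"), 0)
  expect_equal(shear_metric(Urig, mesh, "L2_L3"), 0, tolerance = 1e-12)
  expect_equal(shortening_metric(Urig, mesh, "L3"), 0, tolerance = 1e-12)
  expect_error(bulge_metric(U0, mesh, "nope"), "unknown")
})

test_that("shear and shortening follow their definitions on synthetic fields", {
  mesh <- coarse_segment()
  n <- nrow(mesh$nodes)
  U <- matrix(0, n, 3)
  U[mesh$node_sets$disc_L2_L3_top, 1] <- 0.3
  expect_equal(shear_metric(U, mesh, "L2_L3"), 0.3, tolerance = 1e-12)
  # uniform 1% axial compression of the 10 mm disc: 0.1 mm height loss
  z <- mesh$nodes[, 3]
  Uc <- matrix(0, n, 3); Uc[, 3] <- -0.01 * z
  z0 <- min(mesh$nodes[mesh$node_sets$disc_L2_L3_bottom, 3])
  expect_equal(shortening_metric(Uc, mesh, "L2_L3"), 0.1, tolerance = 1e-9)
})

test_that("percent change convention reproduces the reported comparisons", {
  expect_equal(round(percent_more(1.04, 0.46)), 126)
  expect_equal(round(percent_more(2.25, 1.79)), 26)
  expect_equal(percent_more(5, 5), 0)
  expect_error(percent_more(1, 0), "positive")
})

test_that("convergence flag applies the at-most-threshold rule", {
  # closed-form-like runner: identical uniaxial block response at any mesh
  runner_exact <- function(h) {
    mesh <- box_mesh(10, 10, 10, round(10 / h), round(10 / h), round(10 / h))
    lib <- box_library(E = 100, nu = 0)
    hst <- solve_quasi_static(fe_model(mesh, lib, constraint_set(mesh),
                                       load_schedule(u_z_max = 0.1, n_increments = 1)))
    data.frame(element_size = h, F_kN = hst$states[[1]]$reaction_kN)
  }
  rep1 <- convergence_study(sizes = c(5, 2.5), runner = runner_exact)
  expect_true(rep1$converged)
  expect_lt(max(rep1$percent_diffs), 1e-6)
  # boundary: a 5.0% difference still passes; 5.1% does not
  mk <- function(jump) function(h) data.frame(element_size = h,
                                              F_kN = if (h == 2) 1 * (1 + jump / 100) else 1)
  expect_true(convergence_study(sizes = c(4, 2), runner = mk(5.0))$converged)
  expect_false(convergence_study(sizes = c(4, 2), runner = mk(5.1))$converged)
  # failing runs yield a flagged partial report, not an exception
  bad <- function(h) if (h < 3) stop("boom") else data.frame(element_size = h, F_kN = 1)
  expect_warning(repp <- convergence_study(sizes = c(4, 2), runner = bad), "failed")
  expect_false(repp$complete)
  expect_error(convergence_study(sizes = 3), "decreasing")
})

test_that("exported artifacts are deterministic and reloadable", {
  cfg <- run_config(grade = 1, element_size = 5, n_increments = 2, seed = 2)
  r <- run_single_grade(cfg)
  d1 <- file.path(tempdir(), "exp1"); d2 <- file.path(tempdir(), "exp2")
  f1 <- export_results(r$history, r$metrics, dir = d1)
  f2 <- export_results(r$history, r$metrics, dir = d2)
  expect_identical(readLines(f1[["csv"]]), readLines(f2[["csv"]]))
  expect_identical(readLines(f1[["json"]]), readLines(f2[["json"]]))
  js <- jsonlite::read_json(f1[["json"]])
  expect_equal(js$metrics$F_max, r$metrics$F_max, tolerance = 1e-12)
  # the VTU snapshot carries a von Mises cell field and parses as XML
  vt <- xml2::read_xml(f1[["vtu"]])
  arrays <- xml2::xml_find_all(vt, "//DataArray")
  expect_true("von_mises" %in% xml2::xml_attr(arrays, "Name"))
  expect_true("displacement" %in% xml2::xml_attr(arrays, "Name"))
  expect_error(export_results(structure(list(states = list()), class = "solution_history")),
               "empty")
})
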