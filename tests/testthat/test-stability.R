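# Plastic-onset and bifurcation detectors, failure classification.

synthetic_history <- function(t, F, vm, alpha, ux) {
  states <- lapply(seq_along(t), function(i) {
    st <- list(t_bar = t[i], reaction_kN = F[i], vm_cortical = vm[i],
               vm_solid = 0, alpha_max = alpha[i],
               u_probe = c(ux[i], 0, 0), U = NULL, n_iter = 1)
    class(st) <- "solution_state"
    st
  })
  structure(list(states = states, failed = FALSE, fail_t_bar = NA,
                 schedule = structure(list(u_z_max = 2.5, t_bar = t),
                                      class = "load_schedule")),
            class = "solution_history")
}

test_that("plastic onset is the first increment with cortical plastic strain", {
  t <- seq(0.1, 1, by = 0.1)
  h <- synthetic_history(t, F = t, vm = 50 * t, alpha = pmax(0, t - 0.55),
                         ux = 0.01 * t)
  on <- detect_plastic_onset(h)
  expect_equal(on$t_bar_pl, 0.6)
  expect_equal(on$F_pl, 0.6)
  expect_equal(on$sigma_pl, 30)
  # purely elastic: absent
  h0 <- synthetic_history(t, F = t, vm = 50 * t, alpha = rep(0, 10), ux = 0.01 * t)
  expect_null(detect_plastic_onset(h0))
  expect_error(detect_plastic_onset(synthetic_history(0.5, 1, 1, 0, 0)), "2 increments")
})

test_that("bifurcation triggers on ratio jumps and sign reversals only", {
  t <- seq(0.05, 1, by = 0.05)
  # proportional response: absent
  expect_null(detect_bifurcation(synthetic_history(t, t, 50 * t, 0 * t, 0.02 * t)))
  # ratio jump at t = 0.6 with subsequent drop in |u_x| and force: unstable
  ux <- ifelse(t < 0.6, 0.02 * t, 0.012 + (t - 0.6) * 0.5)
  ux[t > 0.8] <- ux[t == 0.8] - (t[t > 0.8] - 0.8) * 0.3
  F <- ifelse(t < 0.8, t, 0.8 - (t - 0.8))
  b <- detect_bifurcation(synthetic_history(t, F, 50 * t, 0 * t, ux))
  expect_false(is.null(b))
  expect_equal(b$t_bar_cr, 0.65, tolerance = 1e-9)
  expect_equal(b$post_buckling, "unstable")
  # sign reversal triggers too
  ux2 <- ifelse(t < 0.5, 0.02 * t, 0.02 * 0.5 - (t - 0.5) * 0.02)
  b2 <- detect_bifurcation(synthetic_history(t, t, 50 * t, 0 * t, ux2))
  expect_false(is.null(b2))
  expect_lte(abs(b2$t_bar_cr - 0.55), 0.051)
})

test_that("failure classification covers the four regimes", {
  t <- seq(0.1, 1, by = 0.1)
  h_rise <- synthetic_history(t, F = t, vm = 50 * t, alpha = pmax(0, t - 0.55),
                              ux = 0.01 * t)
  onset <- detect_plastic_onset(h_rise)
  bif <- structure(list(t_bar_cr = 0.9, F_cr = 0.9, u_x_cr = 0.01,
                        post_buckling = "stable"), class = "bifurcation_result")
  expect_equal(classify_failure(h_rise), "elastic-stable")
  expect_equal(classify_failure(h_rise, onset = onset), "plasticity-limited")
  expect_equal(classify_failure(h_rise, bif = bif), "buckling-limited")
  # onset before bifurcation with rising force: mixed (hardening continues)
  expect_equal(classify_failure(h_rise, onset = onset, bif = bif), "mixed")
  # bifurcation before onset: buckling-limited
  bif_early <- structure(list(t_bar_cr = 0.3, F_cr = 0.3, u_x_cr = 0.01,
                              post_buckling = "unstable"), class = "bifurcation_result")
  expect_equal(classify_failure(h_rise, onset = onset, bif = bif_early),
               "buckling-limited")
})

test_that("imperfect column driven past its critical load bifurcates near the analytic shortening", {
  # clamped-guided column: P_cr = pi^2 E I / L^2, critical end shortening
  # d_cr = P_cr L / (E A)
  E <- 1000; b <- 4; L <- 60
  mesh <- box_mesh(b, b, L, 4, 4, 48)
  # small seeded lateral bow (sharp bifurcation)
  bow <- 0.004 * sin(pi * mesh$nodes[, 3] / (2 * L))
  mesh$nodes[, 1] <- mesh$nodes[, 1] + bow
  lib <- box_library(E = E, nu = 0)
  cs <- constraint_set(mesh, fixed = "base", driven = "top_endplate")
  Pcr <- pi^2 * E * (b^4 / 12) / L^2
  d_cr <- Pcr * L / (E * b^2)
  d_max <- 1.8 * d_cr
  h <- solve_quasi_static(fe_model(mesh, lib, cs,
                                   load_schedule(u_z_max = d_max, n_increments = 40)))
  # probe: lateral displacement of a mid/top node
  probe <- which.max(mesh$nodes[, 3] + 0.001 * mesh$nodes[, 1])
  bif <- detect_bifurcation(h, probe = probe)
  expect_false(is.null(bif))
  expect_lt(abs(bif$t_bar_cr - d_cr / d_max), 0.1 * (d_cr / d_max) + 1 / 40)
})
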