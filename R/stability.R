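# Failure and stability detectors: plastic onset in the cortical shell,
# bifurcation at the lateral probe point, linearized buckling from the
# geometric stiffness, and the failure-mode classification.

#' Detect plastic onset in the cortical shell
#'
#' Scans a solution history for the first increment with nonzero equivalent
#' plastic strain anywhere in the cortical shell and reports the pseudo-time,
#' the axial force and the maximum cortical von Mises stress at that
#' increment. The reported onset stress is typically below the uniaxial
#' yield stress (multiaxial stress states and discretization).
#'
#' @param history A `solution_history`.
#' @param threshold Equivalent plastic strain considered nonzero.
#' @return An object of class `plastic_onset` with `t_bar_pl`, `F_pl` (kN),
#'   `sigma_pl` (MPa), or `NULL` when the run stays elastic.
#' @export
detect_plastic_onset <- function(history, threshold = 1e-8) {
  st <- history$states
  if (length(st) < 2) stop("history needs at least 2 increments")
  alpha <- vapply(st, `[[`, 0, "alpha_max")
  k <- which(alpha > threshold)[1]
  if (is.na(k)) return(NULL)
  structure(list(t_bar_pl = st[[k]]$t_bar,
                 F_pl = st[[k]]$reaction_kN,
                 sigma_pl = st[[k]]$vm_cortical),
            class = "plastic_onset")
}

#' @export
print.plastic_onset <- function(x, ...) {
  cat(sprintf("plastic onset: t_bar = %.3f, F_pl = %.3f kN, sigma_pl = %.1f MPa\n",
              x$t_bar_pl, x$F_pl, x$sigma_pl))
  invisible(x)
}

#' Detect the first bifurcation from the lateral probe response
#'
#' Declares a bifurcation at the first increment where the lateral
#' displacement at the probe point departs from proportional growth: the
#' incremental ratio du_x/dt_bar changes sign, or it exceeds `ratio_jump`
#' times the initial secant while also accelerating by at least `accel` over
#' the previous increment (the second condition keeps smooth
#' imperfection-driven growth from triggering early). Post-buckling is
#' classified as unstable when the lateral displacement magnitude
#' subsequently decreases while the force plateaus or drops.
#'
#' @param history A `solution_history`.
#' @param probe Optional node id overriding the mesh's probe point A.
#' @param ratio_jump Jump factor of the incremental lateral ratio over the
#'   initial secant declaring bifurcation.
#' @param accel Minimum growth of the incremental ratio between consecutive
#'   increments at the bifurcation.
#' @return An object of class `bifurcation_result` with `t_bar_cr`, `F_cr`
#'   (kN), `u_x_cr` (mm) and `post_buckling` in `{"stable", "unstable"}`,
#'   or `NULL` for a proportional (no-bifurcation) response.
#' @export
detect_bifurcation <- function(history, probe = NULL, ratio_jump = 10,
                               accel = 2) {
  st <- history$states
  if (length(st) < 3) return(NULL)
  ux <- if (is.null(probe)) vapply(st, function(s) s$u_probe[1], 0)
        else vapply(st, function(s) s$U[probe, 1], 0)
  tb <- vapply(st, `[[`, 0, "t_bar")
  Fk <- vapply(st, `[[`, 0, "reaction_kN")
  if (all(!is.finite(ux)) || max(abs(ux)) < 1e-10) return(NULL)
  s0 <- ux[1] / tb[1]
  r <- diff(ux) / diff(tb)
  if (abs(s0) < 1e-14) s0 <- r[1]
  if (abs(s0) < 1e-14) return(NULL)
  k <- NA_integer_
  for (i in 2:length(r)) {
    if (sign(r[i]) != sign(s0) ||
        (abs(r[i]) >= ratio_jump * abs(s0) && abs(r[i]) >= accel * abs(r[i - 1]))) {
      k <- i + 1L   # state index where the anomalous increment ends
      break
    }
  }
  if (is.na(k)) return(NULL)
  post <- "stable"
  if (k < length(st)) {
    mags <- abs(ux[k:length(st)])
    dF <- diff(Fk[k:length(st)])
    dm <- diff(mags)
    if (any(dm < 0 & dF <= abs(Fk[k]) * 1e-3)) post <- "unstable"
  }
  structure(list(t_bar_cr = tb[k], F_cr = Fk[k], u_x_cr = ux[k],
                 post_buckling = post),
            class = "bifurcation_result")
}

#' @export
print.bifurcation_result <- function(x, ...) {
  cat(sprintf("bifurcation: t_bar = %.3f, F_cr = %.3f kN, u_x = %.4f mm (%s post-buckling)\n",
              x$t_bar_cr, x$F_cr, x$u_x_cr, x$post_buckling))
  invisible(x)
}

#' Linearized buckling analysis
#'
#' Solves the generalized eigenproblem (K_e + lambda K_sigma) phi = 0 for the
#' smallest positive load multipliers lambda: the estimated critical load is
#' lambda times the load of the reference state whose geometric stiffness is
#' K_sigma. Mode shapes are normalized to unit maximum component.
#'
#' @param K_e Elastic stiffness (reduced dofs), e.g. from
#'   [assemble_tangent()]; alternatively the full list returned by
#'   [assemble_tangent()].
#' @param K_sigma Geometric stiffness at the reference load.
#' @param free Optional free-dof index restricting the operators (defaults to
#'   all rows when `K_e` is a plain matrix, or the model's free set when the
#'   [assemble_tangent()] list is supplied).
#' @param nev Number of modes requested.
#' @return List of modes, each with `lambda` and `mode_shape` (vector on the
#'   free dofs); empty when the reference state induces no buckling.
#' @export
linearized_buckling <- function(K_e, K_sigma = NULL, free = NULL, nev = 4) {
  if (is.list(K_e) && !is.null(K_e$K_e)) {
    free <- K_e$free
    K_sigma <- K_e$K_sigma
    K_e <- K_e$K_e
  }
  if (!is.null(free)) {
    K_e <- K_e[free, free, drop = FALSE]
    K_sigma <- K_sigma[free, free, drop = FALSE]
  }
  nfree <- nrow(K_e)
  nev <- min(nev, nfree - 2L)
  A <- Matrix::forceSymmetric(K_e)
  B <- Matrix::forceSymmetric(K_sigma)
  if (nfree <= 800) {
    Ad <- as.matrix(A)
    ev0 <- eigen(Ad, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev0) <= 0) stop("indefinite elastic stiffness: model error")
    M <- solve(Ad, -as.matrix(B))
    ev <- eigen(M)
    mu <- Re(ev$values)
    ord <- order(mu, decreasing = TRUE)
    out <- list()
    for (i in ord[seq_len(min(nev, length(ord)))]) {
      if (mu[i] <= 1e-12) break
      shape <- Re(ev$vectors[, i])
      out[[length(out) + 1L]] <- list(lambda = 1 / mu[i],
                                      mode_shape = shape / max(abs(shape)))
    }
    return(out)
  }
  ch <- tryCatch(Matrix::Cholesky(A, LDL = FALSE, super = FALSE, perm = TRUE),
                 error = function(e) stop("indefinite elastic stiffness: model error"))
  ex <- Matrix::expand(ch)
  L <- ex$L; P <- ex$P
  matvec <- function(x, extra = NULL) {
    v <- as.vector(Matrix::t(P) %*% Matrix::solve(Matrix::t(L), x))
    w <- -(B %*% v)
    as.vector(Matrix::solve(L, P %*% w))
  }
  ar <- igraph::arpack(matvec, sym = TRUE,
                       options = list(n = nfree, nev = nev,
                                      ncv = min(nfree, max(4 * nev + 5, 25)),
                                      which = "LA", maxiter = 3000))
  mu <- as.vector(ar$values)
  vecs <- ar$vectors
  if (is.null(dim(vecs))) vecs <- matrix(vecs, ncol = 1)
  out <- list()
  for (i in order(mu, decreasing = TRUE)) {
    if (mu[i] <= 1e-12) next
    psi <- vecs[, i]
    phi <- as.vector(Matrix::t(P) %*% Matrix::solve(Matrix::t(L), psi))
    out[[length(out) + 1L]] <- list(lambda = 1 / mu[i],
                                    mode_shape = phi / max(abs(phi)))
  }
  out
}

#' Expand a buckling mode to a nodal displacement field
#'
#' @param model An `fe_model`.
#' @param mode A mode from [linearized_buckling()] computed on the model's
#'   free dofs.
#' @return An n x 3 matrix of nodal translations (rotations dropped),
#'   normalized to unit maximum component.
#' @export
mode_to_field <- function(model, mode) {
  u_red <- numeric(model$nred)
  u_red[model$free] <- mode$mode_shape
  u_full <- u_red[model$red_of]
  U <- matrix(u_full[seq_len(3 * model$n)], model$n, 3, byrow = TRUE)
  U / max(abs(U))
}

#' Classify the failure mode of a run
#'
#' @param history A `solution_history`.
#' @param onset A `plastic_onset` or `NULL`.
#' @param bif A `bifurcation_result` or `NULL`.
#' @return One of `"elastic-stable"`, `"plasticity-limited"`,
#'   `"buckling-limited"`, `"mixed"`.
#' @export
classify_failure <- function(history, onset = NULL, bif = NULL) {
  if (is.null(onset) && is.null(bif)) return("elastic-stable")
  if (is.null(onset)) return("buckling-limited")
  if (is.null(bif)) return("plasticity-limited")
  Fk <- vapply(history$states, `[[`, 0, "reaction_kN")
  tb <- vapply(history$states, `[[`, 0, "t_bar")
  rising_after <- function(t0) {
    k <- which(tb >= t0 - 1e-12)[1]
    if (is.na(k) || k >= length(Fk)) return(TRUE)
    Fk[length(Fk)] > Fk[k] + 1e-9
  }
  if (bif$t_bar_cr < onset$t_bar_pl) return("buckling-limited")
  if (rising_after(onset$t_bar_pl)) "mixed" else "plasticity-limited"
}

#' Stability report for one run
#'
#' Bundles plastic onset, bifurcation detection and the failure-mode label.
#'
#' @param history A `solution_history`.
#' @return An object of class `stability_report`.
#' @export
stability_report <- function(history) {
  onset <- detect_plastic_onset(history)
  bif <- detect_bifurcation(history)
  structure(list(plastic_onset = onset, bifurcation = bif,
                 classification = classify_failure(history, onset, bif),
                 failed = history$failed, fail_t_bar = history$fail_t_bar),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("stability report:", x$classification, "\n")
  if (!is.null(x$plastic_onset)) print(x$plastic_onset)
  if (!is.null(x$bifurcation)) print(x$bifurcation)
  invisible(x)
}
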