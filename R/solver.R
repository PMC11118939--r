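# Quasi-static geometrically nonlinear solution: model preparation (dof
# numbering, tie-constraint elimination, sparse pattern), tangent assembly
# from the compiled element kernels, and Newton-Raphson increments under
# displacement control.

#' Displacement-controlled load schedule
#'
#' The axial load is applied by driving the top endplate down by
#' `u_z_max * t_bar` over the pseudo-time sequence `t_bar` in (0, 1].
#'
#' @param u_z_max Maximum imposed axial displacement in mm (default 2.5).
#' @param n_increments Number of uniform increments (default 50).
#' @param t_bar Optional explicit strictly-increasing pseudo-time sequence
#'   ending at 1 (excluding the initial 0).
#' @return An object of class `load_schedule`.
#' @export
load_schedule <- function(u_z_max = 2.5, n_increments = 50, t_bar = NULL) {
  if (u_z_max <= 0) stop("u_z_max must be positive")
  if (is.null(t_bar)) {
    if (n_increments < 1) stop("need at least one increment")
    if (n_increments < 5)
      warning("very coarse schedule: onset/bifurcation detection needs finer increments")
    t_bar <- seq_len(n_increments) / n_increments
  }
  if (any(diff(c(0, t_bar)) <= 0) || abs(t_bar[length(t_bar)] - 1) > 1e-12)
    stop("t_bar must be strictly increasing and end at 1")
  structure(list(u_z_max = u_z_max, t_bar = t_bar), class = "load_schedule")
}

#' Kinematic constraint set
#'
#' Fixed and driven dof groups for the displacement-controlled compression:
#' all dofs of the fixed node set are clamped, and one translational dof of
#' the driven node set follows the load schedule.
#'
#' @param mesh A `segment_mesh`.
#' @param fixed Name of the fixed node set (default the segment base), or an
#'   integer vector of node ids.
#' @param driven Name of the driven node set (default the top endplate), or
#'   an integer vector of node ids.
#' @param driven_dof Driven translation direction (1 = x, 2 = y, 3 = z).
#' @param driven_sign Sign of the imposed displacement (-1 = downward
#'   compression).
#' @return An object of class `constraint_set`.
#' @export
constraint_set <- function(mesh, fixed = NULL, driven = NULL,
                           driven_dof = 3L, driven_sign = -1) {
  ns <- mesh$node_sets
  pick <- function(x, candidates) {
    if (is.numeric(x)) return(as.integer(x))
    if (is.character(x)) {
      if (!x %in% names(ns)) stop("unknown node set '", x, "'")
      return(ns[[x]])
    }
    for (cc in candidates) if (cc %in% names(ns)) return(ns[[cc]])
    stop("mesh has none of the node sets: ", paste(candidates, collapse = ", "))
  }
  fixed_nodes <- pick(fixed, c("base_L4", "base"))
  driven_nodes <- pick(driven, c("top_endplate_L2", "top_endplate"))
  if (length(intersect(fixed_nodes, driven_nodes)))
    stop("a node cannot be both fixed and driven")
  structure(list(fixed_nodes = fixed_nodes, driven_nodes = driven_nodes,
                 driven_dof = as.integer(driven_dof), driven_sign = driven_sign),
            class = "constraint_set")
}

# ---------------------------------------------------------------------------
# Model preparation: resolves materials onto element blocks, numbers dofs
# (3 translations per node + 3 rotations per bending-shell node), eliminates
# the shell-solid tie constraints, and precomputes the sparse pattern with a
# triplet -> CSC slot map so repeated assemblies only overwrite values.
# ---------------------------------------------------------------------------

#' Prepare a finite-element model
#'
#' @param mesh A `segment_mesh` (tie activity set by [apply_grade()]).
#' @param materials A `material_library`.
#' @param constraints A [constraint_set()]; defaults to base fixed / top
#'   driven.
#' @param schedule A [load_schedule()].
#' @param drill_coef Relative drilling-rotation penalty of the bending shells.
#' @param membrane_geometric Include the fibre membranes' geometric stiffness
#'   in the tangent and in K_sigma (the kernel keeps only its tensile
#'   principal part, since bending-free membranes have zero-energy wrinkling
#'   modes).
#' @param fibre_tension_only Make the fibre families themselves slack in
#'   compression (the composite-shell reading resists in-plane compression,
#'   so this is off by default).
#' @return An environment of class `fe_model`.
#' @export
fe_model <- function(mesh, materials, constraints = NULL,
                     schedule = load_schedule(), drill_coef = 1e-3,
                     membrane_geometric = TRUE, fibre_tension_only = FALSE) {
  if (is.null(constraints)) constraints <- constraint_set(mesh)
  m <- new.env(parent = emptyenv())
  m$mesh <- mesh; m$materials <- materials
  m$constraints <- constraints; m$schedule <- schedule
  m$membrane_geometric <- membrane_geometric
  n <- nrow(mesh$nodes)
  m$n <- n

  cort <- grepl("^cortical", mesh$shell_set)
  fib <- !cort
  m$cort_sel <- cort

  rot_nodes <- sort(unique(as.vector(mesh$shell[cort, , drop = FALSE])))
  rot_base0 <- rep(-1L, n)
  if (length(rot_nodes)) rot_base0[rot_nodes] <- 3L * n + 3L * (seq_along(rot_nodes) - 1L)
  ndof <- 3L * n + 3L * length(rot_nodes)
  m$ndof <- ndof

  # --- hex material blocks ---
  usets <- unique(mesh$hex_set)
  types <- integer(nrow(mesh$hex))
  params <- matrix(0, nrow(mesh$hex), 36)
  for (s in usets) {
    card <- card_for_set(materials, s)
    if (is.list(card) && !is.null(card$elastic)) card <- card$elastic
    hp <- hex_card_params(card)
    sel <- mesh$hex_set == s
    types[sel] <- hp$type
    params[sel, ] <- matrix(hp$params, sum(sel), 36, byrow = TRUE)
  }
  m$hex_conn0 <- mesh$hex - 1L
  m$hex_types <- types
  m$hex_params <- params

  # --- cortical shells ---
  csel <- which(cort)
  ps <- cortical_shell_plane_stress(materials$cortical$elastic)
  yld <- materials$cortical$plastic
  nsc <- length(csel)
  m$shell_conn0 <- mesh$shell[csel, , drop = FALSE] - 1L
  m$shell_rotbase <- matrix(rot_base0[mesh$shell[csel, , drop = FALSE]], nsc, 4)
  m$shell_params <- matrix(rep(c(0, 0, ps$D[1, 1], ps$D[1, 2], ps$D[1, 3],
                                 ps$D[2, 2], ps$D[2, 3], ps$D[3, 3],
                                 ps$G13, ps$G23, yld$yield_stress,
                                 yld$hardening_modulus, drill_coef),
                               each = nsc), nsc, 13)
  m$shell_params[, 2] <- mesh$shell_thickness[csel]
  m$pstate0 <- matrix(0, nsc, 80)

  # --- fibre membranes: tension-only +/-angle laminates ---
  fsel <- which(fib)
  nf <- length(fsel)
  m$mem_conn0 <- mesh$shell[fsel, , drop = FALSE] - 1L
  mem_params <- matrix(0, nf, 4)
  if (nf) {
    Ef <- ifelse(grepl("^fibre_external", mesh$shell_set[fsel]),
                 materials$fibre$E_external, materials$fibre$E_internal)
    mem_params <- cbind(mesh$shell_thickness[fsel], Ef, abs(mesh$fibre_angle[fsel]),
                        as.numeric(fibre_tension_only))
  }
  m$mem_params <- mem_params

  # --- ligament links ---
  nl <- nrow(mesh$link)
  m$link_conn0 <- mesh$link - 1L
  if (nl) {
    lig <- materials$ligaments
    idx <- match(mesh$link_set, lig$group)
    if (anyNA(idx)) stop("link group without ligament card")
    m$link_EA <- lig$E[idx] * lig$area[idx]
  } else m$link_EA <- numeric(0)

  # --- tie elimination -> reduced dof numbering ---
  master <- seq_len(ndof)
  ip <- mesh$interface_pairs
  if (nrow(ip)) {
    act <- which(if (is.null(ip$active)) rep(TRUE, nrow(ip)) else ip$active)
    for (d in 1:3) {
      sd <- 3L * (ip$shell_node[act] - 1L) + d
      md <- 3L * (ip$solid_node[act] - 1L) + d
      master[sd] <- md
    }
  }
  is_master <- master == seq_len(ndof)
  red_index <- cumsum(is_master)
  red_of <- red_index[master]
  nred <- sum(is_master)
  m$red_of <- red_of
  m$nred <- nred

  # --- constraint dof groups (reduced) ---
  node_dofs <- function(nodes) {
    td <- as.vector(outer(3L * (nodes - 1L), 1:3, "+"))
    rb <- rot_base0[nodes]
    rd <- as.vector(outer(rb[rb >= 0], 1:3, "+"))
    c(td, rd)
  }
  fixed_red <- unique(red_of[node_dofs(constraints$fixed_nodes)])
  driven_red <- unique(red_of[3L * (constraints$driven_nodes - 1L) + constraints$driven_dof])
  driven_red <- setdiff(driven_red, fixed_red)
  free_red <- setdiff(seq_len(nred), c(fixed_red, driven_red))
  m$fixed <- fixed_red; m$driven <- driven_red; m$free <- free_red

  # --- triplet pattern (element-major, column-major within the block) ---
  block_dofs <- function(conn, rotbase = NULL) {
    me <- nrow(conn)
    if (!me) return(matrix(0L, 0, 0))
    nde <- 3L * ncol(conn) * (if (is.null(rotbase)) 1L else 2L)
    dm <- matrix(0L, me, nde)
    for (a in seq_len(ncol(conn))) for (d in 1:3)
      dm[, 3L * (a - 1L) + d] <- 3L * conn[, a] + d      # conn is 0-based
    if (!is.null(rotbase))
      for (a in seq_len(ncol(conn))) for (d in 1:3)
        dm[, 12L + 3L * (a - 1L) + d] <- rotbase[, a] + d
    matrix(red_of[dm], me, nde)
  }
  tri_of <- function(dm) {
    if (!nrow(dm)) return(list(i = integer(0), j = integer(0)))
    nde <- ncol(dm)
    list(i = as.vector(t(dm[, rep(seq_len(nde), times = nde), drop = FALSE])),
         j = as.vector(t(dm[, rep(seq_len(nde), each = nde), drop = FALSE])))
  }
  th <- tri_of(block_dofs(m$hex_conn0))
  ts <- tri_of(block_dofs(m$shell_conn0, m$shell_rotbase))
  tm <- tri_of(block_dofs(m$mem_conn0))
  tl <- tri_of(block_dofs(m$link_conn0))
  tri_i <- c(th$i, ts$i, tm$i, tl$i)
  tri_j <- c(th$j, ts$j, tm$j, tl$j)

  K0 <- Matrix::sparseMatrix(i = tri_i, j = tri_j, x = rep(1, length(tri_i)),
                             dims = c(nred, nred))
  colptr <- K0@p
  col_of <- rep(seq_len(nred), diff(colptr))
  csc_key <- as.numeric(K0@i + 1) + (as.numeric(col_of) - 1) * nred
  tri_key <- as.numeric(tri_i) + (as.numeric(tri_j) - 1) * nred
  m$slots <- match(tri_key, csc_key)
  m$nnz <- length(K0@x)
  K0@x[] <- 0
  m$Ktemplate <- K0

  # free-free extraction map: positions in K@x feeding Kff@x
  Kidx <- K0; Kidx@x <- as.numeric(seq_len(m$nnz))
  Kff0 <- Kidx[m$free, m$free, drop = FALSE]
  m$ff_src <- as.integer(Kff0@x)
  Kff0@x[] <- 0
  m$Kff_template <- Kff0
  m$chol <- NULL
  m$newton_clamp <- FALSE
  m$fact_age <- 99L
  m$prev_iters <- 99L
  m$shift_level <- 1L
  class(m) <- "fe_model"
  m
}

#' @export
print.fe_model <- function(x, ...) {
  cat("fe_model:", x$n, "nodes,", x$ndof, "dofs (", x$nred, "after ties );",
      length(x$free), "free\n")
  invisible(x)
}

# single full assembly at displacement state u_red; returns stiffness values
# aligned with the precomputed pattern plus reduced internal force
assemble_system <- function(model, u_red, pstate, want_kg = TRUE,
                            clamp_geo = TRUE) {
  u_full <- u_red[model$red_of]
  mesh <- model$mesh
  rh <- hex_asm_cpp(mesh$nodes, model$hex_conn0, model$hex_types,
                    model$hex_params, u_full, want_kg, TRUE, clamp_geo)
  f_full <- numeric(model$ndof)
  f_full[seq_along(rh$fint)] <- rh$fint
  Km <- list(rh$Km); Kg <- list(rh$Kg)
  vm_shell <- numeric(0); pstate_new <- pstate; energy <- rh$energy
  if (nrow(model$shell_conn0)) {
    rs <- shell_asm_cpp(mesh$nodes, model$shell_conn0, model$shell_rotbase,
                        model$shell_params, u_full, pstate, model$ndof, want_kg)
    f_full <- f_full + as.vector(rs$fint)
    Km <- c(Km, list(rs$Km)); Kg <- c(Kg, list(rs$Kg))
    vm_shell <- as.vector(rs$vm); pstate_new <- rs$pstate; energy <- energy + rs$energy
  }
  if (nrow(model$mem_conn0)) {
    rm_ <- membrane_asm_cpp(mesh$nodes, model$mem_conn0, model$mem_params,
                            u_full, model$ndof, want_kg && model$membrane_geometric)
    f_full <- f_full + as.vector(rm_$fint)
    Km <- c(Km, list(rm_$Km))
    Kg <- c(Kg, list(if (model$membrane_geometric && want_kg) rm_$Kg
                     else numeric(length(rm_$Km))))
    energy <- energy + rm_$energy
  }
  link_force <- numeric(0)
  if (nrow(model$link_conn0)) {
    rl <- link_asm_cpp(mesh$nodes, model$link_conn0, model$link_EA, u_full, want_kg)
    fl <- numeric(model$ndof); fl[seq_along(rl$fint)] <- rl$fint
    f_full <- f_full + fl
    Km <- c(Km, list(rl$Km)); Kg <- c(Kg, list(rl$Kg))
    link_force <- as.vector(rl$force); energy <- energy + rl$energy
  }
  Kx_m <- accumulate_list_cpp(model$slots, Km, model$nnz)
  Kx_g <- if (want_kg) accumulate_list_cpp(model$slots, Kg, model$nnz)
          else numeric(model$nnz)
  f_red <- accumulate_cpp(model$red_of, f_full, model$nred)
  list(Kx_m = as.vector(Kx_m), Kx_g = as.vector(Kx_g), fint = as.vector(f_red),
       vm_hex = as.vector(rh$vm), vm_shell = vm_shell, pstate = pstate_new,
       min_detJ = rh$min_detJ, min_detF = rh$min_detF, energy = energy,
       link_force = link_force, u_full = u_full)
}

#' Assemble the tangent stiffness operators
#'
#' Returns the elastic (material) stiffness K_e and the geometric
#' (initial-stress) stiffness K_sigma of the constrained model at a given
#' displacement state, as sparse symmetric operators on the reduced (tie-
#' eliminated) dofs, together with the internal force. K_e is positive
#' definite at the unloaded reference state; K_e + K_sigma is the full
#' Newton tangent (the remaining nonlinear terms of the incremental
#' formulation are contained in K_e through the deformation-dependent
#' strain-displacement operator).
#'
#' @param mesh A `segment_mesh` or an existing [fe_model()].
#' @param materials A `material_library` (ignored when `mesh` is a model).
#' @param constraints Optional [constraint_set()].
#' @param state Optional reduced displacement vector (defaults to zero) or a
#'   `solution_state` from a history.
#' @return List with `K_e`, `K_sigma`, `K_total` (dgCMatrix, reduced dofs),
#'   `fint`, `free`, `model`.
#' @export
assemble_tangent <- function(mesh, materials = NULL, constraints = NULL,
                             state = NULL) {
  model <- if (inherits(mesh, "fe_model")) mesh
           else fe_model(mesh, materials, constraints)
  u_red <- if (is.null(state)) numeric(model$nred)
           else if (is.list(state)) state$u_red else state
  pstate <- if (is.list(state) && !is.null(state$pstate)) state$pstate else model$pstate0
  asm <- assemble_system(model, u_red, pstate, want_kg = TRUE, clamp_geo = FALSE)
  Ke <- model$Ktemplate; Ke@x <- asm$Kx_m
  Ks <- model$Ktemplate; Ks@x <- asm$Kx_g
  Kt <- model$Ktemplate; Kt@x <- asm$Kx_m + asm$Kx_g
  sym_err <- max(abs(Kt - Matrix::t(Kt))) / max(abs(Kt@x), 1e-300)
  if (sym_err > 1e-8) warning("assembled tangent asymmetry ", signif(sym_err, 3))
  list(K_e = Ke, K_sigma = Ks, K_total = Kt, fint = asm$fint,
       free = model$free, model = model)
}

# factorized solve on the free-free block with cached symbolic factorization.
# The Cholesky factor may be reused across iterations and increments
# (quasi-Newton); refactor = FALSE solves with the stale factor.
#
# Past a critical point the tangent loses definiteness; the iteration matrix
# is then regularized with a diagonal shift. The shift level is sticky per
# model: a failed factorization escalates it once rather than being retried
# at every iteration (failed CHOLMOD attempts are expensive), and with a
# shifted iteration matrix the residual-driven iterations still converge to
# the same equilibria, only more slowly.
solve_free <- function(model, Kx, rhs, refactor = TRUE) {
  if (!refactor && !is.null(model$chol)) {
    x <- tryCatch(as.vector(Matrix::solve(model$chol, rhs, system = "A")),
                  error = function(e) NULL)
    if (!is.null(x) && all(is.finite(x))) return(x)
  }
  Kff <- model$Kff_template
  Kff@x <- Kx[model$ff_src]
  A0 <- Matrix::forceSymmetric(Kff)
  shifts <- c(0, 1e-6, 1e-4, 1e-2, 1)
  if (is.null(model$shift_level)) model$shift_level <- 1L
  dg <- abs(Matrix::diag(A0))
  while (model$shift_level <= length(shifts)) {
    s <- shifts[model$shift_level]
    # Marquardt-style shift relative to each dof's own diagonal stiffness:
    # negligible perturbation per dof, restores definiteness where needed
    A <- if (s > 0) A0 + Matrix::Diagonal(x = s * dg) else A0
    ch <- NULL
    if (!is.null(model$chol)) {
      ch <- tryCatch(suppressWarnings(Matrix::update(model$chol, A)),
                     error = function(e) NULL)
    }
    if (is.null(ch)) {
      ch <- tryCatch(suppressWarnings(Matrix::Cholesky(A, LDL = FALSE, super = TRUE)),
                     error = function(e) NULL)
    }
    if (!is.null(ch)) {
      x <- tryCatch(as.vector(Matrix::solve(ch, rhs, system = "A")),
                    error = function(e) NULL)
      if (!is.null(x) && all(is.finite(x))) {
        model$chol <- ch
        model$fact_age <- 0L
        return(x)
      }
    }
    model$shift_level <- model$shift_level + 1L
    gc(FALSE)
  }
  rep(NA_real_, length(rhs))
}

#' Quasi-static displacement-controlled solution
#'
#' Drives the top endplate down according to the load schedule and solves
#' the nonlinear equilibrium with Newton-Raphson iterations per increment
#' (residual tolerance 1e-6 relative / 1e-8 N absolute). Non-converged
#' increments are bisected up to `max_cuts` times; if the smallest step still
#' fails the partial history is returned with a failure flag, which itself
#' signals loss of load-bearing capacity.
#'
#' @param mesh A `segment_mesh`, or an [fe_model()] (then `materials`,
#'   `constraints`, `schedule` are taken from the model).
#' @param materials A `material_library`.
#' @param constraints Optional [constraint_set()].
#' @param schedule A [load_schedule()].
#' @param tol_rel,tol_abs Newton residual tolerances.
#' @param max_iter Newton iterations per increment.
#' @param max_cuts Maximum number of increment bisections.
#' @param verbose Print per-increment progress?
#' @return An object of class `solution_history`: list of per-increment
#'   states (`t_bar`, nodal displacements `U`, reaction force `reaction_kN`,
#'   `vm_cortical`, `vm_solid`, `alpha_max`, probe displacement), plus
#'   convergence diagnostics and the model.
#' @export
solve_quasi_static <- function(mesh, materials = NULL, constraints = NULL,
                               schedule = load_schedule(), tol_rel = 1e-6,
                               tol_abs = 1e-8, max_iter = 25, max_cuts = 4,
                               verbose = FALSE) {
  model <- if (inherits(mesh, "fe_model")) mesh
           else fe_model(mesh, materials, constraints, schedule)
  schedule <- model$schedule
  cs <- model$constraints
  n <- model$n
  probe <- model$mesh$node_sets$probe_point_A

  u <- numeric(model$nred)
  pstate <- model$pstate0
  states <- list()
  t_cur <- 0
  failed <- FALSE
  fail_t <- NA_real_
  model$fact_age <- 99L
  model$prev_iters <- 99L

  record <- function(t_bar, asm, u_red, n_iter) {
    U <- matrix(asm$u_full[seq_len(3 * n)], n, 3, byrow = TRUE)
    st <- list(
      t_bar = t_bar,
      U = U,
      u_red = u_red,
      pstate = asm$pstate,
      reaction_kN = cs$driven_sign * sum(asm$fint[model$driven]) / 1000,
      vm_cortical = if (length(asm$vm_shell)) max(asm$vm_shell) else NA_real_,
      vm_solid = max(asm$vm_hex),
      alpha_max = if (ncol(asm$pstate) > 0 && nrow(asm$pstate) > 0)
        max(asm$pstate[, seq(4, ncol(asm$pstate), by = 4)]) else 0,
      u_probe = if (!is.null(probe)) U[probe, ] else rep(NA_real_, 3),
      energy = asm$energy,
      n_iter = n_iter
    )
    class(st) <- "solution_state"
    st
  }

  newton_step <- function(t_target, max_it = max_iter) {
    # consistent-tangent predictor: linearize about the current converged
    # state and solve for the free-dof response to the prescribed increment
    # (avoids the huge fictitious strains of a naive prescribed-dof jump)
    du_p <- numeric(model$nred)
    du_p[model$driven] <- cs$driven_sign * schedule$u_z_max * t_target - u[model$driven]
    asm0 <- assemble_system(model, u, pstate, want_kg = TRUE,
                            clamp_geo = model$newton_clamp)
    K <- model$Ktemplate
    K@x <- asm0$Kx_m + asm0$Kx_g
    rhs <- -as.vector(K %*% du_p)[model$free] - asm0$fint[model$free]
    # quasi-Newton factor reuse: refactor when the previous increment was
    # hard work or the factor has served several increments
    refac <- is.null(model$chol) || model$prev_iters > 8 || model$fact_age >= 5
    du_f <- solve_free(model, asm0$Kx_m + asm0$Kx_g, rhs, refactor = refac)
    if (any(!is.finite(du_f))) return(NULL)
    u_try <- u + du_p
    u_try[model$free] <- u_try[model$free] + du_f
    u_try[model$fixed] <- 0
    rn0 <- NA_real_
    rn_prev <- Inf
    u_prev <- u_try
    backtracks <- 0L
    it <- 0L
    while (it < max_it) {
      it <- it + 1L
      asm <- assemble_system(model, u_try, pstate, want_kg = TRUE,
                             clamp_geo = model$newton_clamp)
      bad <- !is.finite(asm$min_detJ) || asm$min_detJ <= 0 ||
        !is.finite(asm$min_detF) || asm$min_detF <= 0.05
      r <- if (bad) NULL else -asm$fint[model$free]
      rn <- if (bad) Inf else sqrt(sum(r^2))
      # lazy backtracking: if the last full step made things (much) worse,
      # halve it and retry instead of iterating from the bad point
      if ((bad || (is.finite(rn_prev) && rn > 2 * rn_prev)) && backtracks < 6L) {
        u_try <- u_prev + 0.5 * (u_try - u_prev)
        backtracks <- backtracks + 1L
        it <- it - 1L
        next
      }
      if (bad || !is.finite(rn)) return(NULL)
      if (is.na(rn0)) rn0 <- max(rn, tol_abs)
      if (rn <= max(tol_rel * rn0, tol_abs))
        return(list(asm = asm, u = u_try, n_iter = it))
      if (rn > 1e8 * rn0) return(NULL)
      # refactor adaptively: whenever the stale factor stops making fast
      # progress (residual not at least halved), refresh the factorization
      du <- solve_free(model, asm$Kx_m + asm$Kx_g, r,
                       refactor = is.finite(rn_prev) && rn > 0.5 * rn_prev)
      if (any(!is.finite(du))) return(NULL)
      rn_prev <- rn
      backtracks <- 0L
      u_prev <- u_try
      u_try[model$free] <- u_try[model$free] + du
    }
    NULL
  }

  dt0 <- diff(c(0, schedule$t_bar))
  for (ti in seq_along(schedule$t_bar)) {
    t_target <- schedule$t_bar[ti]
    if (t_target <= t_cur + 1e-12) next   # already passed by a leap
    done <- FALSE
    cuts <- 0
    while (!done) {
      # march to t_target, possibly through bisected substeps; successful
      # substeps relax the cut level again so the stepping cannot stall
      step <- (t_target - t_cur) / 2^cuts
      t_next <- if (cuts == 0) t_target else t_cur + step
      res <- newton_step(t_next)
      if (is.null(res)) {
        cuts <- cuts + 1
        if (cuts > max_cuts) {
          # bisection exhausted: the path has hit a local fold (snap) that
          # small steps cannot cross. Leap over it: a predictor far past the
          # fold lands in the next smooth basin if the branch continues.
          for (k in c(4, 8, 16)) {
            t_leap <- min(t_cur + k * dt0[ti], 1)
            if (verbose) message(sprintf("  leap attempt to t_bar = %.3f", t_leap))
            res <- newton_step(t_leap, max_it = 3 * max_iter)
            if (!is.null(res)) {
              t_next <- t_leap
              break
            }
            if (t_leap >= 1) break
          }
          if (is.null(res)) {
            failed <- TRUE
            fail_t <- t_next
            break
          }
          u <- res$u
          pstate <- res$asm$pstate
          t_cur <- t_next
          cuts <- 0
          model$prev_iters <- res$n_iter
          states[[length(states) + 1L]] <- record(t_cur, res$asm, u, res$n_iter)
          ns <- length(states)
          if (ns > 1L) {
            states[[ns - 1L]]$u_red <- NULL
            states[[ns - 1L]]$pstate <- NULL
          }
          if (verbose)
            message(sprintf("t_bar = %.4f  F = %.4f kN (leap, %d it)",
                            t_cur, states[[ns]]$reaction_kN, res$n_iter))
          done <- TRUE
          next
        }
      } else {
        u <- res$u
        pstate <- res$asm$pstate
        t_cur <- t_next
        cuts <- max(0L, cuts - 1L)
        model$prev_iters <- res$n_iter
        model$fact_age <- model$fact_age + 1L
        states[[length(states) + 1L]] <- record(t_cur, res$asm, u, res$n_iter)
        # keep the displacement/plastic arrays of the latest state only; the
        # per-increment assembly churn is large, so collect eagerly
        ns <- length(states)
        if (ns > 1L) {
          states[[ns - 1L]]$u_red <- NULL
          states[[ns - 1L]]$pstate <- NULL
        }
        if (ns %% 5L == 0L) gc(FALSE)
        if (verbose)
          message(sprintf("t_bar = %.4f  F = %.4f kN  vm = %.2f MPa  (%d it)",
                          t_cur, states[[length(states)]]$reaction_kN,
                          states[[length(states)]]$vm_cortical, res$n_iter))
        if (abs(t_cur - t_target) < 1e-12) done <- TRUE
      }
    }
    if (failed) break
  }

  structure(list(states = states, failed = failed, fail_t_bar = fail_t,
                 schedule = schedule, model = model),
            class = "solution_history")
}

#' @export
print.solution_history <- function(x, ...) {
  nst <- length(x$states)
  cat("solution_history:", nst, "converged increments")
  if (x$failed) cat(" (FAILED at t_bar ~", signif(x$fail_t_bar, 4), ")")
  cat("\n")
  if (nst) {
    last <- x$states[[nst]]
    cat(sprintf("  final t_bar %.3f, reaction %.4f kN, max cortical vM %.2f MPa\n",
                last$t_bar, last$reaction_kN, last$vm_cortical))
  }
  invisible(x)
}

#' Extract the per-increment time series of a solution history
#'
#' @param history A `solution_history`.
#' @return data.frame with columns `t_bar`, `u_z_mm`, `F_kN`,
#'   `sigma_vm_max_MPa`, `sigma_vm_solid_MPa`, `alpha_max`, `u_x_A_mm`,
#'   `u_y_A_mm`.
#' @export
history_table <- function(history) {
  st <- history$states
  data.frame(
    t_bar = vapply(st, `[[`, 0, "t_bar"),
    u_z_mm = vapply(st, `[[`, 0, "t_bar") * history$schedule$u_z_max,
    F_kN = vapply(st, `[[`, 0, "reaction_kN"),
    sigma_vm_max_MPa = vapply(st, `[[`, 0, "vm_cortical"),
    sigma_vm_solid_MPa = vapply(st, `[[`, 0, "vm_solid"),
    alpha_max = vapply(st, `[[`, 0, "alpha_max"),
    u_x_A_mm = vapply(st, function(s) s$u_probe[1], 0),
    u_y_A_mm = vapply(st, function(s) s$u_probe[2], 0)
  )
}
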