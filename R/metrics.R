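# Outcome metrics: bulging, shearing, shortening, percent changes, the
# per-run metric bundle and the mesh-convergence harness.

resolve_state <- function(state) {
  if (inherits(state, "solution_history")) state <- state$states[[length(state$states)]]
  if (inherits(state, "solution_state")) return(state$U)
  if (is.matrix(state)) return(state)
  stop("'state' must be a displacement matrix, solution_state or solution_history")
}

resolve_region <- function(mesh, region) {
  if (is.character(region)) {
    if (!region %in% names(mesh$node_sets)) stop("unknown node set '", region, "'")
    region <- mesh$node_sets[[region]]
  }
  if (!length(region)) stop("empty region")
  as.integer(region)
}

#' Lateral bulge of a wall or disc region
#'
#' Maximum outward radial (horizontal) displacement over a lateral boundary
#' node set, measured relative to the region's mean lateral translation (so
#' the metric is invariant under rigid translation of the body).
#'
#' @param state Final displacement field: `solution_history`,
#'   `solution_state` or an n x 3 matrix.
#' @param mesh The `segment_mesh`.
#' @param region Node set name (e.g. `"wall_L3"`, `"disc_L2_L3_wall"`) or
#'   node ids.
#' @return Bulge in mm (>= 0).
#' @export
bulge_metric <- function(state, mesh, region) {
  U <- resolve_state(state)
  ids <- resolve_region(mesh, region)
  xy <- mesh$nodes[ids, 1:2, drop = FALSE]
  ctr <- colMeans(xy)
  rel <- sweep(xy, 2, ctr)
  rn <- sqrt(rowSums(rel^2))
  rhat <- rel / pmax(rn, 1e-12)
  uxy <- U[ids, 1:2, drop = FALSE]
  tr <- colMeans(uxy)
  urel <- sweep(uxy, 2, tr)
  max(0, max(rowSums(urel * rhat)))
}

#' Disc shearing
#'
#' Magnitude of the difference between the mean horizontal displacements of a
#' disc's cranial and caudal interfaces; invariant under rigid translation.
#'
#' @param state Displacement field (see [bulge_metric()]).
#' @param mesh The `segment_mesh`.
#' @param disc Disc label, e.g. `"L2_L3"`.
#' @return Shear in mm (>= 0).
#' @export
shear_metric <- function(state, mesh, disc) {
  U <- resolve_state(state)
  top <- mesh$node_sets[[paste0("disc_", disc, "_top")]]
  bot <- mesh$node_sets[[paste0("disc_", disc, "_bottom")]]
  if (is.null(top) || is.null(bot)) stop("missing interface sets for disc ", disc)
  d <- colMeans(U[top, 1:2, drop = FALSE]) - colMeans(U[bot, 1:2, drop = FALSE])
  sqrt(sum(d^2))
}

#' Height decrease of a vertebral body or disc
#'
#' Decrease of the mean axial distance between the cranial and caudal
#' surfaces of the body (positive = shortened); zero for rigid translation.
#'
#' @param state Displacement field (see [bulge_metric()]).
#' @param mesh The `segment_mesh`.
#' @param body Vertebra label (`"L3"`) or disc label (`"L2_L3"`).
#' @return Height decrease in mm.
#' @export
shortening_metric <- function(state, mesh, body) {
  U <- resolve_state(state)
  keys <- if (paste0("body_top_", body) %in% names(mesh$node_sets))
    paste0(c("body_top_", "body_bottom_"), body)
  else paste0("disc_", body, c("_top", "_bottom"))
  top <- mesh$node_sets[[keys[1]]]
  bot <- mesh$node_sets[[keys[2]]]
  if (is.null(top) || is.null(bot)) stop("missing surface sets for ", body)
  mean(U[bot, 3]) - mean(U[top, 3])
}

#' Percent change relative to a baseline
#'
#' `percent_more(x, base)` = 100 (x/base - 1). The convention for "X% smaller"
#' force statements is `percent_more(F_reference, F_degraded)` (the reference
#' force exceeds the degraded one by X%); "Y% more" deformation statements
#' use `percent_more(value_degraded, value_reference)`.
#'
#' @param value Measured value.
#' @param baseline Baseline (> 0).
#' @return Percent change.
#' @export
percent_more <- function(value, baseline) {
  if (any(baseline <= 0)) stop("baseline must be positive")
  100 * (value / baseline - 1)
}

#' Outcome metrics of one segment run
#'
#' @param history A `solution_history` of the full segment.
#' @return An object of class `segment_metrics`: peak force `F_max` (kN),
#'   per-disc and per-vertebra bulge, per-disc shear, per-disc and
#'   per-vertebra height decrease, and the von Mises summaries at the final
#'   increment.
#' @export
segment_metrics <- function(history) {
  mesh <- history$model$mesh
  st <- history$states[[length(history$states)]]
  Fk <- vapply(history$states, `[[`, 0, "reaction_kN")
  discs <- sub("^disc_(.*)_top$", "\\1", grep("^disc_.*_top$", names(mesh$node_sets), value = TRUE))
  verts <- sub("^wall_", "", grep("^wall_", names(mesh$node_sets), value = TRUE))
  out <- list(
    F_max = max(Fk),
    t_at_F_max = history$states[[which.max(Fk)]]$t_bar,
    disc_bulge = vapply(discs, function(d) bulge_metric(st, mesh, paste0("disc_", d, "_wall")), 0),
    wall_bulge = vapply(verts, function(v) bulge_metric(st, mesh, paste0("wall_", v)), 0),
    disc_shear = vapply(discs, function(d) shear_metric(st, mesh, d), 0),
    disc_shortening = vapply(discs, function(d) shortening_metric(st, mesh, d), 0),
    vertebra_shortening = vapply(verts, function(v) shortening_metric(st, mesh, v), 0),
    vm_cortical_max = st$vm_cortical,
    vm_solid_max = st$vm_solid,
    t_bar_final = st$t_bar
  )
  structure(out, class = "segment_metrics")
}

#' @export
print.segment_metrics <- function(x, ...) {
  cat(sprintf("segment metrics: F_max = %.3f kN (t_bar %.2f)\n", x$F_max, x$t_at_F_max))
  cat("  disc bulge [mm]: ", paste(sprintf("%s %.3f", names(x$disc_bulge), x$disc_bulge), collapse = ", "), "\n")
  cat("  wall bulge [mm]: ", paste(sprintf("%s %.3f", names(x$wall_bulge), x$wall_bulge), collapse = ", "), "\n")
  cat("  disc shear [mm]: ", paste(sprintf("%s %.3f", names(x$disc_shear), x$disc_shear), collapse = ", "), "\n")
  cat(sprintf("  max von Mises: cortical %.1f MPa, solid %.1f MPa\n",
              x$vm_cortical_max, x$vm_solid_max))
  invisible(x)
}

#' Mesh-convergence study
#'
#' Runs the same model at a sequence of decreasing element sizes and
#' tabulates the percent differences of the tracked summaries (final
#' reaction, maximum von Mises in shell and solids, wall bulge) between
#' successive resolutions. A mesh is convergent when all tracked differences
#' are at most `threshold` percent ("no more than" reading: equality passes).
#'
#' @param grade Degeneration grade for the material cards.
#' @param sizes Decreasing element sizes in mm (default 3, 2, 1).
#' @param model_kind `"vertebra"` (single body, faster) or `"segment"`.
#' @param n_increments Schedule increments per run.
#' @param u_z_max Imposed axial displacement in mm; defaults to 2.5 for the
#'   segment and the height-proportional 0.7 for a single vertebra.
#' @param threshold Convergence threshold in percent.
#' @param runner Optional function `function(element_size)` returning a
#'   one-row data.frame of summaries; overrides the built-in model run
#'   (used for cross-checks against closed-form cases).
#' @return An object of class `convergence_report` with the per-size
#'   summaries, successive percent differences and the `converged` flag.
#' @export
convergence_study <- function(grade = 2, sizes = c(3, 2, 1),
                              model_kind = c("vertebra", "segment"),
                              n_increments = 5, u_z_max = NULL,
                              threshold = 5, runner = NULL) {
  model_kind <- match.arg(model_kind)
  if (length(sizes) < 2 || any(diff(sizes) >= 0))
    stop("sizes must be at least two decreasing element sizes")
  if (is.null(u_z_max)) u_z_max <- if (model_kind == "segment") 2.5 else 0.7
  spec <- grade_spec(grade)
  if (is.null(runner)) runner <- function(h) {
    mesh <- if (model_kind == "segment") assemble_segment(element_size = h)
            else build_vertebra(element_size = h, label = "L3")
    ag <- apply_grade(mesh, spec)
    sched <- load_schedule(u_z_max = u_z_max, n_increments = n_increments)
    hist <- solve_quasi_static(ag$mesh, ag$materials, schedule = sched)
    if (!length(hist$states)) stop("no converged increment")
    st <- hist$states[[length(hist$states)]]
    wl <- grep("^wall_", names(mesh$node_sets), value = TRUE)[1]
    data.frame(element_size = h,
               F_kN = st$reaction_kN,
               vm_cortical = st$vm_cortical,
               vm_solid = st$vm_solid,
               wall_bulge = bulge_metric(st, mesh, wl),
               t_bar = st$t_bar)
  }
  rows <- list(); ok <- logical(length(sizes))
  for (si in seq_along(sizes)) {
    h <- sizes[si]
    res <- tryCatch(runner(h), error = function(e) e)
    if (inherits(res, "error")) {
      rows[[si]] <- NULL
      warning("run at size ", h, " failed: ", conditionMessage(res))
    } else {
      rows[[si]] <- res
      ok[si] <- TRUE
    }
  }
  tab <- do.call(rbind, rows[ok])
  diffs <- NULL
  if (!is.null(tab) && nrow(tab) >= 2) {
    track <- intersect(c("F_kN", "vm_cortical", "vm_solid", "wall_bulge"), names(tab))
    q <- as.matrix(tab[, track, drop = FALSE])
    diffs <- abs(100 * (q[-1, , drop = FALSE] / q[-nrow(q), , drop = FALSE] - 1))
    rownames(diffs) <- paste(tab$element_size[-nrow(tab)], "->", tab$element_size[-1], "mm")
  }
  structure(list(sizes = sizes, summaries = tab, percent_diffs = diffs,
                 complete = all(ok),
                 converged = !is.null(diffs) && nrow(diffs) >= 1 &&
                   all(diffs[nrow(diffs), ] <= threshold + 1e-9),
                 threshold = threshold),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("convergence report (threshold", x$threshold, "%):",
      if (x$converged) "CONVERGED" else "not converged",
      if (!x$complete) "(partial: some runs failed)" else "", "\n")
  if (!is.null(x$summaries)) print(x$summaries, row.names = FALSE)
  if (!is.null(x$percent_diffs)) {
    cat("successive percent differences:\n")
    print(round(x$percent_diffs, 3))
  }
  invisible(x)
}
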