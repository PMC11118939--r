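# Result export: VTK XML unstructured grids (.vtu), CSV time series and JSON
# metric bundles. The .vtu writer is a minimal ASCII implementation of the
# UnstructuredGrid format (hexahedra type 12, quads type 9, lines type 3).

#' Write a segment mesh (optionally with fields) to a VTK .vtu file
#'
#' @param mesh A `segment_mesh`.
#' @param file Output path.
#' @param displacement Optional n x 3 nodal displacement field.
#' @param cell_scalars Optional named list of per-cell numeric vectors
#'   ordered as (hexahedra, shells, links); e.g. von Mises per element.
#' @return The file path, invisibly.
#' @export
write_vtu <- function(mesh, file, displacement = NULL, cell_scalars = list()) {
  n <- nrow(mesh$nodes)
  cells <- list(mesh$hex, mesh$shell, mesh$link)
  sizes <- c(8L, 4L, 2L)
  vtk_types <- c(12L, 9L, 3L)
  ncell <- sum(vapply(cells, nrow, 0L))
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid>')
  w(sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', n, ncell))
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(apply(mesh$nodes, 1, function(r) paste(format(r, digits = 12), collapse = " ")), con)
  w('</DataArray></Points>')
  w('<Cells>')
  w('<DataArray type="Int64" Name="connectivity" format="ascii">')
  for (k in seq_along(cells)) {
    cc <- cells[[k]]
    if (nrow(cc)) writeLines(apply(cc - 1L, 1, paste, collapse = " "), con)
  }
  w('</DataArray>')
  w('<DataArray type="Int64" Name="offsets" format="ascii">')
  offs <- integer(0); run <- 0L
  for (k in seq_along(cells)) {
    nk <- nrow(cells[[k]])
    if (nk) { offs <- c(offs, run + seq_len(nk) * sizes[k]); run <- run + nk * sizes[k] }
  }
  writeLines(paste(offs, collapse = " "), con)
  w('</DataArray>')
  w('<DataArray type="UInt8" Name="types" format="ascii">')
  tys <- unlist(lapply(seq_along(cells), function(k) rep(vtk_types[k], nrow(cells[[k]]))))
  writeLines(paste(tys, collapse = " "), con)
  w('</DataArray>')
  w('</Cells>')
  # point data
  w('<PointData>')
  if (!is.null(displacement)) {
    w('<DataArray type="Float64" Name="displacement" NumberOfComponents="3" format="ascii">')
    writeLines(apply(displacement, 1, function(r) paste(format(r, digits = 12), collapse = " ")), con)
    w('</DataArray>')
  }
  w('</PointData>')
  # cell data: element-set labels as integer codes plus user scalars
  set_names <- c(mesh$hex_set, mesh$shell_set, mesh$link_set)
  codes <- as.integer(factor(set_names))
  w('<CellData>')
  w('<DataArray type="Int32" Name="element_set" format="ascii">')
  writeLines(paste(codes, collapse = " "), con)
  w('</DataArray>')
  for (nm in names(cell_scalars)) {
    vals <- cell_scalars[[nm]]
    if (length(vals) != ncell) stop("cell scalar '", nm, "' has wrong length")
    w(sprintf('<DataArray type="Float64" Name="%s" format="ascii">', nm))
    writeLines(paste(format(vals, digits = 9), collapse = " "), con)
    w('</DataArray>')
  }
  w('</CellData>')
  w('</Piece>')
  w('</UnstructuredGrid>')
  w('</VTKFile>')
  invisible(file)
}

# legend of the element_set integer codes written by write_vtu
vtu_set_legend <- function(mesh) {
  set_names <- c(mesh$hex_set, mesh$shell_set, mesh$link_set)
  f <- factor(set_names)
  data.frame(code = seq_along(levels(f)), set = levels(f))
}

#' Export a run's results to files
#'
#' Writes the per-increment CSV time series, a JSON bundle with the segment
#' metrics and stability report, and a .vtu snapshot of the final state with
#' the displacement field and per-element von Mises stress. Output is
#' deterministic for a fixed seed and configuration.
#'
#' @param history A `solution_history` with at least one converged increment.
#' @param metrics A `segment_metrics` (computed if omitted).
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
export_results <- function(history, metrics = NULL, dir = ".", prefix = "run") {
  if (!length(history$states)) stop("empty history: nothing to export")
  if (is.null(metrics)) metrics <- segment_metrics(history)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(prefix, "_history.csv"))
  utils::write.csv(history_table(history), csv, row.names = FALSE)
  rep <- stability_report(history)
  js <- file.path(dir, paste0(prefix, "_metrics.json"))
  payload <- list(
    schema_version = "1.0",
    metrics = unclass(metrics),
    stability = list(
      classification = rep$classification,
      plastic_onset = if (!is.null(rep$plastic_onset)) unclass(rep$plastic_onset),
      bifurcation = if (!is.null(rep$bifurcation)) unclass(rep$bifurcation),
      failed = rep$failed
    )
  )
  jsonlite::write_json(payload, js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  mesh <- history$model$mesh
  st <- history$states[[length(history$states)]]
  asm <- assemble_system(history$model, st$u_red, st$pstate, want_kg = FALSE)
  vm_cells <- c(asm$vm_hex,
                {v <- rep(NA_real_, nrow(mesh$shell))
                 v[history$model$cort_sel] <- asm$vm_shell
                 v},
                rep(NA_real_, nrow(mesh$link)))
  vtu <- file.path(dir, paste0(prefix, "_final.vtu"))
  write_vtu(mesh, vtu, displacement = st$U,
            cell_scalars = list(von_mises = vm_cells))
  invisible(c(csv = csv, json = js, vtu = vtu))
}
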