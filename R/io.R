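# Plain-text writers: CSV time series (fixed column order, 12 significant
# digits, byte-stable across reruns) and ASCII VTU field snapshots of the
# deformed Taylor-Hood mesh (exported as corner-node hexahedra so any VTK
# reader can load them).

ts_columns <- c("time_ms", "nominal_stress_kPa", "active_stress_kPa",
                "length_cm", "mean_Vm_mV", "mean_A2norm", "mean_gamma")

#' Write the simulation time series as CSV
#'
#' Fixed column order (`time_ms`, `nominal_stress_kPa`,
#' `active_stress_kPa`, `length_cm`, `mean_Vm_mV`, `mean_A2norm`,
#' `mean_gamma`), 12 significant digits; re-running with an identical
#' configuration reproduces the file byte-for-byte.
#'
#' @param result a `sim_result` (or a data frame with the columns above;
#'   an empty data frame yields a header-only file).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(result, path) {
  df <- if (inherits(result, "sim_result")) result$timeseries else result
  stopifnot(all(ts_columns %in% names(df)) || nrow(df) == 0)
  if (nrow(df) == 0) {
    writeLines(paste(ts_columns, collapse = ","), path)
    return(invisible(path))
  }
  df <- df[, ts_columns]
  fmt <- as.data.frame(lapply(df, function(col) formatC(col, digits = 12,
                                                        format = "g")))
  names(fmt) <- ts_columns
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a time series CSV back
#' @param path CSV path written by [write_timeseries()].
#' @return data frame.
#' @export
read_timeseries <- function(path) {
  utils::read.csv(path)
}

#' Write a VTU snapshot of the deformed mechanics state
#'
#' ASCII XML UnstructuredGrid with all geometry nodes, corner-node
#' hexahedral cells, point data (displacement) and cell data (mean
#' pressure, mean fiber stretch, mean homogenized activation per element).
#'
#' @param result a `sim_result`, or a list with `mesh`, `u`, `p`,
#'   `gamma_gp`.
#' @param path output path (.vtu).
#' @return `path`, invisibly.
#' @export
write_fields <- function(result, path) {
  mesh <- result$mesh; u <- result$u; p <- result$p
  gamma_gp <- result$gamma_gp
  kin <- gauss_point_kinematics(mesh, u)
  npts <- mesh$n_nodes
  ncell <- mesh$n_elems
  # corner nodes of each Q2 hexahedron in VTK_HEXAHEDRON order
  corner <- c(1, 3, 9, 7, 19, 21, 27, 25)
  vtk_order <- corner[c(1, 2, 4, 3, 5, 6, 8, 7)]
  conn <- mesh$elems[, vtk_order, drop = FALSE] - 1L
  pts <- mesh$nodes + u
  num <- function(x) paste(formatC(x, digits = 9, format = "g"),
                           collapse = " ")
  p_elem <- rowMeans(matrix(p[t(mesh$pelems)], ncol = 8, byrow = TRUE))
  lines <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    '  <UnstructuredGrid>',
    sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', npts, ncell),
    '      <Points>',
    '        <DataArray type="Float64" NumberOfComponents="3" format="ascii">',
    paste0("          ", apply(pts, 1, num)),
    '        </DataArray>',
    '      </Points>',
    '      <Cells>',
    '        <DataArray type="Int64" Name="connectivity" format="ascii">',
    paste0("          ", apply(conn, 1, function(r) paste(r, collapse = " "))),
    '        </DataArray>',
    '        <DataArray type="Int64" Name="offsets" format="ascii">',
    paste0("          ", paste(seq_len(ncell) * 8L, collapse = " ")),
    '        </DataArray>',
    '        <DataArray type="UInt8" Name="types" format="ascii">',
    paste0("          ", paste(rep(12L, ncell), collapse = " ")),
    '        </DataArray>',
    '      </Cells>',
    '      <PointData Vectors="displacement">',
    '        <DataArray type="Float64" Name="displacement" NumberOfComponents="3" format="ascii">',
    paste0("          ", apply(u, 1, num)),
    '        </DataArray>',
    '      </PointData>',
    '      <CellData>',
    '        <DataArray type="Float64" Name="pressure_kPa" format="ascii">',
    paste0("          ", num(p_elem)),
    '        </DataArray>',
    '        <DataArray type="Float64" Name="lambda_f" format="ascii">',
    paste0("          ", num(rowMeans(kin$lambda_f))),
    '        </DataArray>',
    '        <DataArray type="Float64" Name="gamma_bar" format="ascii">',
    paste0("          ", num(rowMeans(gamma_gp))),
    '        </DataArray>',
    '      </CellData>',
    '    </Piece>',
    '  </UnstructuredGrid>',
    '</VTKFile>')
  writeLines(lines, path)
  invisible(path)
}

#' Write fiber geometries as legacy VTK polylines
#'
#' ASCII legacy VTK PolyData with one polyline per fiber, point data
#' `Vm_mV` (nodal membrane voltage) when fiber systems are supplied.
#'
#' @param result a `sim_result` (uses its fiber systems), or a list of
#'   `n x 3` position matrices.
#' @param path output path (.vtk).
#' @return `path`, invisibly.
#' @export
write_fiber_vtk <- function(result, path) {
  if (inherits(result, "sim_result")) {
    pos <- lapply(result$fibers, function(s) s$positions)
    vm <- unlist(lapply(result$fibers, fiber_vm))
  } else {
    pos <- result
    vm <- NULL
  }
  npts <- sum(vapply(pos, nrow, integer(1)))
  num <- function(x) paste(formatC(x, digits = 9, format = "g"),
                           collapse = " ")
  lines <- c("# vtk DataFile Version 3.0", "myocemm fiber meshes", "ASCII",
             "DATASET POLYDATA", sprintf("POINTS %d double", npts),
             unlist(lapply(pos, function(p) apply(p, 1, num))))
  sizes <- vapply(pos, nrow, integer(1))
  offs <- cumsum(c(0L, sizes[-length(sizes)]))
  lines <- c(lines,
             sprintf("LINES %d %d", length(pos), sum(sizes + 1L)),
             mapply(function(n, o) paste(c(n, o + seq_len(n) - 1L),
                                         collapse = " "),
                    sizes, offs))
  if (!is.null(vm)) {
    lines <- c(lines, sprintf("POINT_DATA %d", npts),
               "SCALARS Vm_mV double 1", "LOOKUP_TABLE default", num(vm))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a 0D cell trajectory as CSV
#'
#' Columns `time_ms`, `Vm_mV`, `Ca`, `A1`, `A2` from a recorded
#' [advance_reaction()] trace.
#'
#' @param trace matrix with columns `Vm`, `Ca`, `A1`, `A2`.
#' @param dt substep size (ms).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cell_trace <- function(trace, dt, path) {
  df <- data.frame(time_ms = seq_len(nrow(trace)) * dt,
                   Vm_mV = trace[, "Vm"], Ca = trace[, "Ca"],
                   A1 = trace[, "A1"], A2 = trace[, "A2"])
  fmt <- as.data.frame(lapply(df, function(col) formatC(col, digits = 12,
                                                        format = "g")))
  names(fmt) <- names(df)
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
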