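# Field export: VTK XML unstructured grids (quadratic quads), defect-lattice
# CSV matrices, and the run manifest.

#' Write a mesh with cell data as a VTK XML unstructured grid
#'
#' Plain-text (ascii) .vtu file with the 8-node quadratic quadrilaterals and
#' any number of per-element scalar fields; readable by ParaView.
#'
#' @param mesh a `fem_mesh` (or any list with `nodes` and `elems`).
#' @param file output path.
#' @param celldata named list of per-element numeric vectors.
#' @return the file path, invisibly.
#' @export
write_vtu <- function(mesh, file, celldata = list()) {
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid><Piece NumberOfPoints="%d" NumberOfCells="%d">', nn, ne)
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(paste(mesh$nodes[, 1], mesh$nodes[, 2], 0), con)
  w('</DataArray></Points>')
  w('<Cells><DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(apply(mesh$elems - 1L, 1, paste, collapse = " "), con)
  w('</DataArray><DataArray type="Int32" Name="offsets" format="ascii">')
  writeLines(as.character(seq_len(ne) * 8L), con)
  w('</DataArray><DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(rep("23", ne), con)   # VTK_QUADRATIC_QUAD
  w('</DataArray></Cells>')
  if (length(celldata)) {
    w('<CellData>')
    for (nm in names(celldata)) {
      w('<DataArray type="Float64" Name="%s" format="ascii">', nm)
      writeLines(as.character(celldata[[nm]]), con)
      w('</DataArray>')
    }
    w('</CellData>')
  }
  w('</Piece></UnstructuredGrid></VTKFile>')
  invisible(file)
}

#' Write a defect lattice field as CSV
#'
#' 40 x 40 matrix, rows proximal-to-distal, columns from the symmetry axis
#' outward; no header.
#'
#' @param m matrix.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_defect_csv <- function(m, file) {
  write.table(m, file, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(file)
}

write_day_outputs <- function(out_dir, day, grid, last, mesh, ms) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tag <- sprintf("day%03d", day)
  write_defect_csv(grid$msc, file.path(out_dir, paste0(tag, "_msc.csv")))
  write_defect_csv(grid$ob, file.path(out_dir, paste0(tag, "_ob.csv")))
  write_defect_csv(grid$ch, file.path(out_dir, paste0(tag, "_ch.csv")))
  write_defect_csv(grid$fb, file.path(out_dir, paste0(tag, "_fb.csv")))
  write_defect_csv(fate_codes(last$fate),
                   file.path(out_dir, paste0(tag, "_fate.csv")))
  write_defect_csv(last$gamma, file.path(out_dir, paste0(tag, "_gamma.csv")))
  write_defect_csv(last$v, file.path(out_dir, paste0(tag, "_v.csv")))
  write_defect_csv(last$S, file.path(out_dir, paste0(tag, "_S.csv")))
  if (!is.null(mesh)) {
    cd <- list(E = ms$E, region = as.numeric(factor(mesh$region)))
    write_vtu(mesh, file.path(out_dir, paste0(tag, ".vtu")), cd)
  }
}

write_run_manifest <- function(config, res) {
  man <- list(scenario = config$scenario,
              backend = config$control$backend,
              days = config$days,
              scaffold = config$scaffold$architecture,
              final_composition = as.list(res$series[nrow(res$series), ]),
              package_version = as.character(utils::packageVersion("ocdheal")))
  jsonlite::write_json(man, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Export mesh nodes/elements as CSV (debugging aid)
#'
#' @param mesh a `fem_mesh`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_mesh_csv <- function(mesh, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(data.frame(r = mesh$nodes[, 1], z = mesh$nodes[, 2]),
            file.path(dir, "nodes.csv"), row.names = FALSE)
  write.csv(as.data.frame(mesh$elems),
            file.path(dir, "elements.csv"), row.names = FALSE)
  invisible(dir)
}
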