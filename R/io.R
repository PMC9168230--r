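# Writers for standard mesh formats (legacy ASCII VTK, Gmsh MSH 2.2),
# CSV summaries with units in the headers, a minimal dotted-key config
# format, and run manifests.  A small reader for the package's own VTK
# output supports round-trip checks.

.tissue_code <- function(label) match(label, TISSUES)

#' Write a tetrahedral mesh as a legacy VTK unstructured grid
#'
#' Cell data: integer `tissue` (code into [TISSUES]), and `patch` for the
#' outer boundary tagging mapped onto cells (0 where none); additional
#' per-element channels (e.g. `E_mag`) can be supplied.
#'
#' @param mesh A `tet_mesh`.
#' @param path Output file.
#' @param cell_data Optional named list of per-element numeric vectors.
#' @return The path, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, cell_data = list()) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  writeLines(c("# vtk DataFile Version 3.0",
               "tesuq labeled tetrahedral phantom mesh (mm)",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(format(mesh$nodes, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  utils::write.table(cbind(4L, mesh$elems - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(10L, m)), con)
  writeLines(sprintf("CELL_DATA %d", m), con)
  writeLines(c("SCALARS tissue int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(.tissue_code(mesh$label)), con)
  for (nm in names(cell_data)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(cell_data[[nm]], digits = 17, trim = TRUE), con)
  }
  invisible(path)
}

#' Read a VTK unstructured grid written by [write_mesh_vtk()]
#'
#' Minimal parser for round-trip verification of the package's own
#' output (ASCII legacy format, tetrahedral cells).
#'
#' @param path File written by [write_mesh_vtk()].
#' @return List with `nodes`, `elems`, `label`, and `cell_data`.
#' @export
read_mesh_vtk <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  n <- as.integer(strsplit(lines[ip], " ")[[1]][2])
  nodes <- matrix(scan(text = lines[(ip + 1):(ip + n)], quiet = TRUE),
                  n, 3, byrow = TRUE)
  ic <- grep("^CELLS", lines)[1]
  m <- as.integer(strsplit(lines[ic], " ")[[1]][2])
  cells <- matrix(scan(text = lines[(ic + 1):(ic + m)], quiet = TRUE),
                  m, 5, byrow = TRUE)
  elems <- cells[, 2:5, drop = FALSE] + 1L
  it <- grep("^SCALARS tissue", lines)[1]
  label <- TISSUES[as.integer(lines[(it + 2):(it + 1 + m)])]
  cd <- list()
  for (is in grep("^SCALARS ", lines)) {
    nm <- strsplit(lines[is], " ")[[1]][2]
    if (nm == "tissue") next
    cd[[nm]] <- as.numeric(lines[(is + 2):(is + 1 + m)])
  }
  list(nodes = nodes, elems = elems, label = label, cell_data = cd)
}

#' Write a triangulated surface as VTK polydata
#'
#' @param surface A `tri_surface`; its `channels` (plus `point_data`) are
#'   written as per-vertex scalar arrays.
#' @param path Output file.
#' @param point_data Extra named per-vertex channels.
#' @return The path, invisibly.
#' @export
write_surface_vtk <- function(surface, path, point_data = list()) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  v <- nrow(surface$vertices); f <- nrow(surface$faces)
  writeLines(c("# vtk DataFile Version 3.0",
               "tesuq mid-layer surface (mm)", "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d double", v)), con)
  utils::write.table(format(surface$vertices, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("POLYGONS %d %d", f, 4 * f), con)
  utils::write.table(cbind(3L, surface$faces - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  channels <- c(surface$channels, point_data)
  if (length(channels)) {
    writeLines(sprintf("POINT_DATA %d", v), con)
    for (nm in names(channels)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(channels[[nm]], digits = 17, trim = TRUE), con)
    }
  }
  invisible(path)
}

#' Write a mesh in Gmsh MSH 2.2 ASCII format
#'
#' Tetrahedra carry their tissue code as the physical tag.
#'
#' @param mesh A `tet_mesh`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_mesh_msh22 <- function(mesh, path) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
               "$Nodes", as.character(n)), con)
  utils::write.table(cbind(seq_len(n),
                           format(mesh$nodes, digits = 17, trim = TRUE,
                                  scientific = FALSE)),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(c("$EndNodes", "$Elements", as.character(m)), con)
  code <- .tissue_code(mesh$label)
  utils::write.table(cbind(seq_len(m), 4L, 2L, code, code, mesh$elems),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Write tidy ROI summaries to CSV
#'
#' Column headers carry the units (`value` is annotated per row by the
#' `units` column: V/m, (V/m)^2 or dimensionless).
#'
#' @param summaries Data frame from [spatial_average()] or
#'   [run_group()]`$summaries`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_summary_csv <- function(summaries, path) {
  utils::write.csv(summaries, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a dotted-key configuration file
#'
#' Minimal `key = value` format with dotted section keys
#' (`phantom.lesion_fraction = 0.0894`); values are parsed as numeric
#' vectors (comma-separated), logicals, or strings.  Lines starting with
#' `#` are comments.  Unknown keys are rejected against the documented
#' key set unless `strict = FALSE`.
#'
#' @param path Config file.
#' @param strict Reject unknown keys (default TRUE).
#' @return Named list of parsed values.
#' @export
read_run_config <- function(path, strict = TRUE) {
  known <- c("phantom.radii_mm", "phantom.lesion_fraction",
             "phantom.lesion_radius_mm", "phantom.seed",
             "mesh.edge_mm", "mesh.n_subdiv",
             "montage.name", "montage.cap_area_cm2",
             "gpc.residual_tol", "gpc.max_order", "gpc.oversampling",
             "gpc.n_validation", "gpc.max_evals", "gpc.max_coefficients",
             "run.current_mA", "run.n_line_points", "run.seed",
             "stats.alpha", "stats.n_rois",
             paste0("uncertainty.", tolower(TISSUES), ".range"),
             paste0("uncertainty.", tolower(TISSUES), ".shape"))
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (strict && !(key %in% known)) stop("unknown config key: ", key)
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num
      else if (all(parts %in% c("true", "false", "TRUE", "FALSE")))
        as.logical(toupper(parts))
      else if (length(parts) == 1) parts else parts
  }
  out
}

#' Write a configuration list back to disk
#' @param config Named list as returned by [read_run_config()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_run_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    sprintf("%s = %s", k, paste(format(v, digits = 15, trim = TRUE),
                                collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Machine-readable record of a run: config, seeds, evaluation counts,
#' validation error, wall time and output files, as JSON.
#'
#' @param path Output file.
#' @param config Named list of resolved settings.
#' @param seed Master seed.
#' @param n_model_evals,validation_error Surrogate bookkeeping.
#' @param outputs Character vector of files the run wrote.
#' @param wall_time_s Elapsed seconds.
#' @return The path, invisibly.
#' @export
write_run_manifest <- function(path, config, seed, n_model_evals = NA,
                               validation_error = NA, outputs = character(),
                               wall_time_s = NA) {
  manifest <- list(
    config = config,
    config_hash = sum(utf8ToInt(paste(deparse(config), collapse = ""))),
    seed = seed, n_model_evals = n_model_evals,
    validation_error = validation_error,
    wall_time_s = wall_time_s, outputs = outputs)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
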