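#' Export a mesh (with optional data) as legacy ASCII VTK
#'
#' Writes an unstructured-grid VTK file with region label and fiber angle
#' as cell data, plus any number of additional per-node scalar fields.
#'
#' @param mesh a \code{bz_mesh}.
#' @param path output file.
#' @param point_data named list of per-node numeric vectors (NAs written
#'   as -1e30, the conventional VTK blanking value used here).
#' @param cell_data named list of per-element numeric vectors; region and
#'   fiber angle are always included.
#' @return \code{path}, invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$elements)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "bzep tissue sheet", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", n)), con)
  writeLines(sprintf("%.6g %.6g 0", mesh$nodes[, 1L], mesh$nodes[, 2L]), con)
  writeLines(sprintf("CELLS %d %d", m, 4L * m), con)
  writeLines(sprintf("3 %d %d %d", mesh$elements[, 1L] - 1L,
                     mesh$elements[, 2L] - 1L, mesh$elements[, 3L] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("5", m), con)
  cell_data <- c(list(region = as.numeric(mesh$region == "border_zone"),
                      fiber_angle = mesh$fiber_angle), cell_data)
  writeLines(sprintf("CELL_DATA %d", m), con)
  for (nm in names(cell_data)) {
    writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"),
               con)
    v <- cell_data[[nm]]
    v[!is.finite(v)] <- -1e30
    writeLines(sprintf("%.6g", v), con)
  }
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"),
                 con)
      v <- point_data[[nm]]
      v[!is.finite(v)] <- -1e30
      writeLines(sprintf("%.6g", v), con)
    }
  }
  invisible(path)
}

#' Export a mesh as a plain-text node/element file pair
#'
#' Nodes: one \code{"x y"} line per node.  Elements: one
#' \code{"n1 n2 n3 region angle"} line per element (1-based node indices).
#'
#' @param mesh a \code{bz_mesh}.
#' @param node_path,element_path output files.
#' @return Invisibly, the two paths.
#' @export
write_mesh_text <- function(mesh, node_path, element_path) {
  writeLines(sprintf("%.8g %.8g", mesh$nodes[, 1L], mesh$nodes[, 2L]),
             node_path)
  writeLines(sprintf("%d %d %d %s %.8g", mesh$elements[, 1L],
                     mesh$elements[, 2L], mesh$elements[, 3L], mesh$region,
                     mesh$fiber_angle), element_path)
  invisible(c(node_path, element_path))
}

#' Export a node map as a plain-text table
#'
#' One \code{"node_index value"} line per defined node (masked nodes are
#' omitted).
#'
#' @param map a \code{bz_node_map}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_node_map <- function(map, path) {
  i <- which(is.finite(map$values))
  writeLines(c(sprintf("# %s (%s)", map$what, map$units),
               sprintf("%d %.8g", i, map$values[i])), path)
  invisible(path)
}

#' Save / load a cell steady-state snapshot
#'
#' Flat plain-text "name value" table, one line per state variable, with
#' model-variant metadata in comment lines; the exact representation used
#' to hand single-cell steady states to tissue runs.
#'
#' @param state a \code{bz_cell_state}.
#' @param path file path.
#' @param params optional \code{bz_cell_params} recorded as metadata.
#' @return \code{path} (write) or a \code{bz_cell_state} (read).
#' @export
write_state_snapshot <- function(state, path, params = attr(state, "params")) {
  hdr <- c("# bzep cell steady-state snapshot",
           sprintf("# model: %s", if (!is.null(params)) params$model else
             "ten Tusscher-Panfilov 2006, epicardial"),
           sprintf("# gks_scale: %g", if (!is.null(params)) params$gks_scale
                   else 1),
           sprintf("# cycle_length: %g",
                   if (!is.null(attr(state, "cycle_length")))
                     attr(state, "cycle_length") else NA),
           sprintf("# n_beats: %g", if (!is.null(attr(state, "n_beats")))
             attr(state, "n_beats") else NA))
  body <- sprintf("%s %.17g", names(state), unclass(state))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_state_snapshot
#' @export
read_state_snapshot <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  parts <- strsplit(trimws(ln), "\\s+")
  vals <- vapply(parts, function(p) as.numeric(p[2L]), 0)
  names(vals) <- vapply(parts, `[[`, "", 1L)
  ref <- cpp_cell_init()
  if (!setequal(names(vals), names(ref)))
    stop("snapshot does not contain the expected state variables")
  structure(vals[names(ref)], class = "bz_cell_state")
}

#' Write study outputs to a directory
#'
#' Per configuration: VTK file with AT/RT/gradient point data, plain-text
#' map tables, and a combined summary CSV
#' (configuration, region, max_gradient, exceedance areas).
#'
#' @param study a \code{bz_study} from [run_study()].
#' @param dir output directory (created if needed).
#' @param mesh_env internal (mesh cache reuse).
#' @return \code{dir}, invisibly.
#' @export
write_study <- function(study, dir, mesh_env = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (res in study$results) {
    if (inherits(res, "bz_study_failure")) next
    stem <- file.path(dir, gsub("[^A-Za-z0-9._-]", "_", res$label))
    cf <- res$config
    mesh <- NULL
    if (!is.null(mesh_env)) mesh <- mesh_env[[sprintf("%.6g", cf$resolution)]]
    if (is.null(mesh)) {
      g <- study$geometry
      g$resolution <- cf$resolution
      mesh <- build_mesh(g)
    }
    mesh <- assign_fibers(mesh, cf$bz_fiber_mode, cf$random_seed)
    write_vtk(mesh, paste0(stem, ".vtk"),
              point_data = list(activation_time = res$at$values,
                                repolarization_time = res$rt$values,
                                repolarization_gradient = res$gradient$values))
    write_node_map(res$at, paste0(stem, "_at.txt"))
    write_node_map(res$rt, paste0(stem, "_rt.txt"))
    write_node_map(res$gradient, paste0(stem, "_grad.txt"))
  }
  if (!is.null(study$summary))
    write.csv(study$summary, file.path(dir, "summary.csv"),
              row.names = FALSE)
  log <- c(sprintf("stimulus_amplitude_uA_cm2: %.6g", study$stimulus_amplitude),
           sprintf("cell_prepacing_beats: %d", study$cell_n_beats),
           sprintf("dt_ms: %g", study$tissue$dt),
           sprintf("cycle_length_ms: %g", study$tissue$cycle_length),
           sprintf("n_beats: %d", study$tissue$n_beats),
           sprintf("failures: %s",
                   if (length(study$failures)) paste(study$failures,
                                                     collapse = "; ")
                   else "none"))
  writeLines(log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Write / read a study configuration file (JSON)
#'
#' Captures the geometry, tissue and conductivity parameters of a run; the
#' shipped defaults reproduce the study settings (Table of conductivity
#' presets, 30 mm sheet, 10 mm scar, 2 mm BZ, CL 500 ms, 5 beats, beta
#' 0.14/um, Cm 1 uF/cm^2).
#'
#' @param path file path.
#' @param geometry a [geometry_config()].
#' @param tissue a [tissue_params()].
#' @return \code{path} (write); a list with \code{geometry} and
#'   \code{tissue} (read).
#' @export
write_run_config <- function(path, geometry = geometry_config(),
                             tissue = tissue_params()) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("the jsonlite package is required for config files")
  obj <- list(geometry = unclass(geometry), tissue = unclass(tissue),
              conductivity_presets = list(
                normal_anisotropic = as.list(conductivity_preset("normal_anisotropic")),
                decreased_transverse = as.list(conductivity_preset("decreased_transverse")),
                decreased_isotropic = as.list(conductivity_preset("decreased_isotropic"))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("the jsonlite package is required for config files")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- obj$geometry
  geometry <- geometry_config(g$sheet_size, g$scar_diameter, g$bz_thickness,
                              g$resolution, g$bz_fiber_mode, g$random_seed)
  tt <- obj$tissue
  tissue <- tissue_params(tt$beta, tt$Cm, tt$dt, tt$sample_dt,
                          tt$stimulus_amplitude, tt$stimulus_duration,
                          tt$cycle_length, tt$n_beats, tt$record_from_beat,
                          tt$rev_update_every, tt$cg_tol)
  list(geometry = geometry, tissue = tissue)
}
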