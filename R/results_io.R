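# Result serialization: summary CSV, per-frame pressure CSVs, VTK export.

.atomic_write_csv <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

#' Write stance results to a directory
#'
#' Writes `summary.csv` (fixed column order: frame, time, angle, fx, fy, fz,
#' peak_mpa, area_cm2, ux, uy, uz, n_active, iterations, residual) and one
#' `pressures/frame_NNN.csv` per solved frame (triangle_id, pressure MPa over
#' the active set). File naming is deterministic and re-running overwrites
#' atomically.
#'
#' @param result a `stance_result`.
#' @param outdir output directory (created if needed).
#' @param prefix file prefix, e.g. the method name.
#' @return character vector of files written, invisibly.
#' @export
write_results <- function(result, outdir, prefix = tolower(result$method)) {
  stopifnot(inherits(result, "stance_result"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop(sprintf("cannot create directory: %s", outdir))
  pdir <- file.path(outdir, paste0(prefix, "_pressures"))
  dir.create(pdir, showWarnings = FALSE)
  spath <- file.path(outdir, paste0(prefix, "_summary.csv"))
  .atomic_write_csv(result$summary, spath)
  written <- spath
  for (j in seq_along(result$solutions)) {
    sol <- result$solutions[[j]]
    if (is.null(sol)) next
    df <- data.frame(triangle_id = sol$active_ids,
                     pressure = as.numeric(sol$pressures))
    fpath <- file.path(pdir, sprintf("frame_%03d.csv", j))
    .atomic_write_csv(df, fpath)
    written <- c(written, fpath)
  }
  invisible(written)
}

#' Export a pressure field as legacy VTK polydata
#'
#' Writes the talar surface with per-triangle pressure as CELL_DATA, for
#' inspection in ParaView or similar viewers.
#'
#' @param surface the talar [tri_surface()].
#' @param pressure numeric vector, one value per triangle (MPa).
#' @param path output `.vtk` path.
#' @export
write_pressure_vtk <- function(surface, pressure, path) {
  stopifnot(inherits(surface, "tri_surface"),
            length(pressure) == nrow(surface$faces))
  con <- file(path, "w")
  on.exit(close(con))
  v <- surface$vertices
  f <- surface$faces
  writeLines(c("# vtk DataFile Version 3.0",
               "joint contact pressure field", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(v))), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(f), 4L * nrow(f)), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  writeLines(c(sprintf("CELL_DATA %d", nrow(f)),
               "SCALARS pressure double 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.9g", pressure), con)
  invisible(path)
}
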