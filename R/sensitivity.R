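# Global sensitivity analysis of peak contact pressure over the
# (length threshold, ligament modulus) plane.

#' Sensitivity grid of peak contact pressure
#'
#' Re-runs the full stance for every point of a uniform rectilinear grid over
#' the spring length threshold `hT` and the ligament Young's modulus `Elig`,
#' recording the maximum over frames of the peak contact pressure. Grid
#' points are independent: results are identical regardless of evaluation
#' order. A failing stance run is recorded as `NA` with its reason, without
#' aborting the grid.
#'
#' @param joint a `synthetic_joint` from [make_joint()], or a list with
#'   elements `talus`, `tibia`, `axis` and (optionally) `attachments`.
#' @param bundles ligament bundles at the reference pose, or `NULL`.
#' @param frames a `gait_frames` data frame.
#' @param material baseline [material_params()]; `h_threshold` and
#'   `E_ligament` are overridden per grid point.
#' @param solver_params a [solver_params()].
#' @param hT_range,Elig_range parameter ranges, mm and MPa.
#' @param grid `c(nx, ny)` grid size over `(hT, Elig)`.
#' @param method `"EDEM"` or `"DEM"`.
#' @return an object of class `sensitivity_grid`: `hT_values`, `Elig_values`,
#'   `response` (nx x ny matrix, MPa), `errors` (list of failure messages
#'   keyed "i,j") and metadata.
#' @export
run_sensitivity_grid <- function(joint, bundles, frames,
                                 material = material_params(),
                                 solver_params = edem::solver_params(),
                                 hT_range = c(2.5, 4.5),
                                 Elig_range = c(200, 350),
                                 grid = c(20, 20), method = "EDEM") {
  stopifnot(length(hT_range) == 2L, length(Elig_range) == 2L,
            length(grid) == 2L, all(grid >= 1L))
  hT_values <- if (grid[1] == 1L) mean(hT_range) else {
    seq(hT_range[1], hT_range[2], length.out = grid[1])
  }
  Elig_values <- if (grid[2] == 1L) mean(Elig_range) else {
    seq(Elig_range[1], Elig_range[2], length.out = grid[2])
  }
  response <- matrix(NA_real_, length(hT_values), length(Elig_values))
  errors <- list()
  for (i in seq_along(hT_values)) {
    for (j in seq_along(Elig_values)) {
      mat_ij <- material
      mat_ij$h_threshold <- hT_values[i]
      mat_ij$E_ligament <- Elig_values[j]
      bnd_ij <- if (is.null(bundles)) NULL else {
        set_ligament_modulus(bundles, Elig_values[j])
      }
      res <- tryCatch(
        run_stance(joint$talus, joint$tibia, joint$axis, bnd_ij, frames,
                   mat_ij, solver_params, method = method),
        error = function(e) e)
      if (inherits(res, "error")) {
        errors[[sprintf("%d,%d", i, j)]] <- conditionMessage(res)
      } else {
        response[i, j] <- max(res$summary$peak_mpa, na.rm = TRUE)
      }
    }
  }
  structure(list(hT_values = hT_values, Elig_values = Elig_values,
                 response = response, errors = errors,
                 method = method, material = material),
            class = "sensitivity_grid")
}

#' @export
print.sensitivity_grid <- function(x, ...) {
  cat(sprintf("<sensitivity_grid> %d x %d over hT [%.3g, %.3g] mm x Elig [%.3g, %.3g] MPa; %d failed; response %.3g..%.3g MPa\n",
              length(x$hT_values), length(x$Elig_values),
              min(x$hT_values), max(x$hT_values),
              min(x$Elig_values), max(x$Elig_values), length(x$errors),
              suppressWarnings(min(x$response, na.rm = TRUE)),
              suppressWarnings(max(x$response, na.rm = TRUE))))
  invisible(x)
}

.fd_gradient_rows <- function(resp, xs) {
  # finite differences along the first dimension; central interior, one-sided
  # at the edges; NA neighbours propagate to NA.
  n <- length(xs)
  g <- matrix(NA_real_, nrow(resp), ncol(resp))
  if (n < 2L) return(g)
  g[1, ] <- (resp[2, ] - resp[1, ]) / (xs[2] - xs[1])
  g[n, ] <- (resp[n, ] - resp[n - 1, ]) / (xs[n] - xs[n - 1])
  if (n > 2L) {
    i <- 2:(n - 1)
    g[i, ] <- (resp[i + 1, , drop = FALSE] - resp[i - 1, , drop = FALSE]) /
      (xs[i + 1] - xs[i - 1])
  }
  g
}

#' Finite-difference gradient of a sensitivity grid
#'
#' Central differences in the interior, one-sided at the edges. Grid points
#' with missing neighbours yield `NA`; a degenerate (single-point) axis is
#' fully masked.
#'
#' @param grid a `sensitivity_grid`.
#' @return list with `d_hT` (MPa/mm) and `d_Elig` (MPa/MPa) gradient matrices
#'   plus the grid axes.
#' @export
gradient_map <- function(grid) {
  stopifnot(inherits(grid, "sensitivity_grid"))
  d_hT <- .fd_gradient_rows(grid$response, grid$hT_values)
  d_Elig <- t(.fd_gradient_rows(t(grid$response), grid$Elig_values))
  miss <- is.na(grid$response)
  d_hT[miss] <- NA_real_
  d_Elig[miss] <- NA_real_
  list(d_hT = d_hT, d_Elig = d_Elig,
       hT_values = grid$hT_values, Elig_values = grid$Elig_values)
}

#' Write a sensitivity grid (and its gradient) as long-format CSV
#'
#' @param grid a `sensitivity_grid`.
#' @param path response CSV path (columns hT, Elig, response).
#' @param gradient_path optional gradient CSV path (columns hT, Elig, d_hT,
#'   d_Elig).
#' @export
write_sensitivity_csv <- function(grid, path, gradient_path = NULL) {
  long <- expand.grid(hT = grid$hT_values, Elig = grid$Elig_values,
                      KEEP.OUT.ATTRS = FALSE)
  long$response <- as.vector(grid$response)
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  if (!is.null(gradient_path)) {
    gm <- gradient_map(grid)
    long$d_hT <- as.vector(gm$d_hT)
    long$d_Elig <- as.vector(gm$d_Elig)
    long$response <- NULL
    write.csv(long, gradient_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
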