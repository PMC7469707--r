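# Gait loading input: stance-phase frames of joint angle and joint contact
# force.
#
# CSV dialect: a time column (`time_s` or `percent_stance`, strictly
# increasing), `angle_deg` (dorsiflexion positive) and three signed force
# columns in the clinical directions `force_ml_n`, `force_pa_n`, `force_si_n`
# (medial/lateral, posterior/anterior, superior/inferior; the first-named
# direction is positive). The mapping onto the anatomical frame
# +x anterior / +y superior / +z lateral is configurable because sign
# conventions for reported joint-reaction components vary between motion
# labs.

#' Default clinical-to-anatomical force mapping
#'
#' Columns `ml`, `pa`, `si` of the returned 3 x 3 matrix give the anatomical
#' (x, y, z) direction of one positive unit of each clinical force column:
#' medial = -z, posterior = -x, superior = +y for a right joint with
#' +x anterior, +y superior, +z lateral.
#'
#' @export
default_axis_mapping <- function() {
  m <- cbind(ml = c(0, 0, -1), pa = c(-1, 0, 0), si = c(0, 1, 0))
  rownames(m) <- c("x", "y", "z")
  m
}

.frames_from_raw <- function(time, angle, ml, pa, si, mapping) {
  f_anat <- cbind(ml, pa, si) %*% t(mapping)
  out <- data.frame(time = time, angle = angle,
                    force_ml_n = ml, force_pa_n = pa, force_si_n = si,
                    fx = f_anat[, 1], fy = f_anat[, 2], fz = f_anat[, 3])
  class(out) <- c("gait_frames", "data.frame")
  attr(out, "mapping") <- mapping
  out
}

#' Load a stance-phase gait table from CSV
#'
#' @param path CSV path (see the dialect described above).
#' @param mapping 3 x 3 matrix mapping the (ml, pa, si) force columns onto the
#'   anatomical (x, y, z) frame; see [default_axis_mapping()].
#' @return a `gait_frames` data frame with columns `time`, `angle`, the raw
#'   force columns, and the mapped anatomical components `fx`, `fy`, `fz` (N).
#' @export
load_gait_csv <- function(path, mapping = default_axis_mapping()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.csv(path, check.names = TRUE)
  tcol <- intersect(c("time_s", "percent_stance"), names(df))
  if (!length(tcol)) stop("gait CSV needs a 'time_s' or 'percent_stance' column")
  need <- c("angle_deg", "force_ml_n", "force_pa_n", "force_si_n")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("gait CSV is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  time <- df[[tcol[1]]]
  if (any(diff(time) <= 0)) stop("gait time column must be strictly increasing")
  .frames_from_raw(time, df$angle_deg, df$force_ml_n, df$force_pa_n,
                   df$force_si_n, mapping)
}

#' Write gait frames in the package CSV dialect
#' @param frames a `gait_frames` data frame.
#' @param path output path.
#' @export
write_gait_csv <- function(frames, path) {
  df <- data.frame(time_s = frames$time, angle_deg = frames$angle,
                   force_ml_n = frames$force_ml_n,
                   force_pa_n = frames$force_pa_n,
                   force_si_n = frames$force_si_n)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged ankle stance table
#'
#' Seven representative stance-phase frames (percent of stance, tibiotalar
#' angle, joint contact force components) for a walking trial, shipped as a
#' plain-text fixture and used as the template of the `table1_like` synthetic
#' load profile.
#'
#' @inheritParams load_gait_csv
#' @return a `gait_frames` data frame (time in percent of stance).
#' @export
ankle_stance_table <- function(mapping = default_axis_mapping()) {
  load_gait_csv(system.file("extdata", "ankle_stance_table.csv",
                            package = "edem", mustWork = TRUE),
                mapping = mapping)
}

#' Generate a synthetic stance load profile
#'
#' Shapes:
#' * `half_sine`: force magnitude `peak_force * sin(pi * t / T)` along the
#'   superior axis, joint angle ramping linearly from 0 to `peak_angle`;
#' * `table1_like`: piecewise-linear interpolation of the packaged stance
#'   table over percent-of-stance, all force columns rescaled so the peak
#'   superior force equals `peak_force`.
#'
#' The generator is fully deterministic; `seed` is accepted for interface
#' stability and ignored.
#'
#' @param n_frames number of frames (>= 3).
#' @param peak_force peak superior force (N).
#' @param peak_angle end-of-ramp dorsiflexion angle (deg, `half_sine` only).
#' @param shape `"half_sine"` or `"table1_like"`.
#' @param dt frame spacing in seconds (`half_sine` only; 65 frames at the
#'   default 0.01 s span a 0.64 s stance).
#' @param seed ignored (deterministic generator).
#' @param mapping see [default_axis_mapping()].
#' @return a `gait_frames` data frame.
#' @export
make_gait_profile <- function(n_frames, peak_force, peak_angle = 0,
                              shape = c("half_sine", "table1_like"),
                              dt = 0.01, seed = NULL,
                              mapping = default_axis_mapping()) {
  shape <- match.arg(shape)
  stopifnot(n_frames >= 3L, peak_force >= 0)
  if (shape == "half_sine") {
    j <- seq_len(n_frames) - 1L
    si <- peak_force * sin(pi * j / (n_frames - 1L))
    angle <- peak_angle * j / (n_frames - 1L)
    .frames_from_raw(j * dt, angle, rep(0, n_frames), rep(0, n_frames), si,
                     mapping)
  } else {
    base <- ankle_stance_table(mapping)
    pct <- seq(min(base$time), max(base$time), length.out = n_frames)
    scale <- peak_force / max(base$force_si_n)
    interp <- function(col) stats::approx(base$time, col, xout = pct)$y
    .frames_from_raw(pct, interp(base$angle),
                     scale * interp(base$force_ml_n),
                     scale * interp(base$force_pa_n),
                     scale * interp(base$force_si_n), mapping)
  }
}
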