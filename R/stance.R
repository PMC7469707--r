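# Stance-phase pipeline: drive the contact solver through a time series of
# joint angles and joint contact forces.
#
# Per frame: (1) re-pose the tibia (and the ligament fixed anchors) from the
# reference pose to the frame angle about the joint axis; (2) cast springs
# from the current talus pose, apply the length threshold, compute
# strain-dependent stiffnesses from the current gaps; (3) apply the frame
# force as a point load on the talus (with translation-only equilibrium and
# rotations pinned to zero only the force vector enters the balance; the load
# line through the talus centroid is recorded but produces no torque
# equation); (4) solve; (5) EDEM: translate the talus by the solved increment
# and carry the push-back state to the next frame; DEM: leave the talus at
# the reference pose.

#' Run a stance-phase simulation
#'
#' @param talus,tibia articular [tri_surface()]s at the reference pose (talar
#'   normals facing the tibia).
#' @param axis the [joint_axis()] (dorsiflexion hinge).
#' @param bundles ligament bundles from [make_bundles()], or `NULL`.
#' @param frames a `gait_frames` data frame ([load_gait_csv()],
#'   [make_gait_profile()]).
#' @param material a [material_params()].
#' @param solver_params a [solver_params()].
#' @param method `"EDEM"` (cumulative talus translation, push-back state) or
#'   `"DEM"` (talus pinned at the reference pose, stateless).
#' @param on_error `"abort"` (default) stops at the first failing frame,
#'   annotated with the frame index; `"skip"` logs the failure and records an
#'   NA summary row.
#' @param rotate_ligament_anchors rotate the fixed-side ligament anchors with
#'   the tibia each frame (default TRUE).
#' @return an object of class `stance_result`: `method`, input `frames`,
#'   per-frame `solutions`, a `summary` data frame (frame, time, angle, force,
#'   peak pressure MPa, active area cm^2, cumulative displacement mm, active
#'   count, iterations, residual norm) and reproducibility metadata.
#' @export
run_stance <- function(talus, tibia, axis, bundles, frames, material,
                       solver_params = edem::solver_params(),
                       method = c("EDEM", "DEM"),
                       on_error = c("abort", "skip"),
                       rotate_ligament_anchors = TRUE) {
  method <- match.arg(toupper(method[1]), c("EDEM", "DEM"))
  on_error <- match.arg(on_error)
  stopifnot(inherits(talus, "tri_surface"), inherits(tibia, "tri_surface"),
            inherits(frames, "data.frame"), nrow(frames) >= 1L)
  n <- nrow(talus$faces)
  state <- solver_state(n)
  nf <- nrow(frames)
  solutions <- vector("list", nf)
  summary <- data.frame(frame = seq_len(nf), time = frames$time,
                        angle = frames$angle, fx = frames$fx, fy = frames$fy,
                        fz = frames$fz, peak_mpa = NA_real_,
                        area_cm2 = NA_real_, ux = NA_real_, uy = NA_real_,
                        uz = NA_real_, n_active = NA_integer_,
                        iterations = NA_integer_, residual = NA_real_)
  for (j in seq_len(nf)) {
    ang <- frames$angle[j]
    F_applied <- c(frames$fx[j], frames$fy[j], frames$fz[j])
    step <- tryCatch({
      tib_j <- if (ang != 0) rotate_about_axis(tibia, axis, ang) else tibia
      bnd_j <- if (!is.null(bundles) && rotate_ligament_anchors && ang != 0) {
        rotate_bundle_anchors(bundles, axis, ang)
      } else bundles
      tal_j <- if (method == "EDEM" && any(state$u_cum != 0)) {
        translate_surface(talus, state$u_cum)
      } else talus
      m <- compute_stiffnesses(apply_length_threshold(
        cast_springs(tal_j, tib_j, material)))
      if (method == "EDEM") {
        r <- solve_equilibrium_edem(m, bnd_j, F_applied, state, solver_params)
        state <- r$state
        list(sol = r$solution, m = m, state = state)
      } else {
        list(sol = solve_equilibrium_dem(m, bnd_j, F_applied, solver_params),
             m = m, state = state)
      }
    }, error = function(e) e)
    if (inherits(step, "error")) {
      msg <- sprintf("frame %d (t = %g): %s", j, frames$time[j],
                     conditionMessage(step))
      if (on_error == "abort") stop(msg, call. = FALSE)
      edem_log("warn", "skipping %s", msg)
      next
    }
    state <- step$state
    pm <- pressure_map(step$sol, step$m)
    u_rep <- if (method == "EDEM") state$u_cum else c(0, 0, 0)
    summary$peak_mpa[j] <- pm$peak_mpa
    summary$area_cm2[j] <- pm$active_area_cm2
    summary$ux[j] <- u_rep[1]
    summary$uy[j] <- u_rep[2]
    summary$uz[j] <- u_rep[3]
    summary$n_active[j] <- length(step$sol$active_ids)
    summary$iterations[j] <- step$sol$iterations
    summary$residual[j] <- .norm3(step$sol$residual)
    solutions[[j]] <- step$sol
  }
  structure(list(method = method, frames = frames, solutions = solutions,
                 summary = summary, material = material,
                 solver_params = solver_params,
                 n_triangles = n,
                 geometry = list(talus = surface_fingerprint(talus),
                                 tibia = surface_fingerprint(tibia))),
            class = "stance_result")
}

#' @export
print.stance_result <- function(x, ...) {
  ok <- !is.na(x$summary$peak_mpa)
  cat(sprintf("<stance_result> %s, %d frames (%d solved); peak pressure %.3f MPa, max active area %.3f cm^2\n",
              x$method, nrow(x$summary), sum(ok),
              if (any(ok)) max(x$summary$peak_mpa[ok]) else NA_real_,
              if (any(ok)) max(x$summary$area_cm2[ok]) else NA_real_))
  invisible(x)
}

#' Compare EDEM and DEM stance results frame by frame
#'
#' Both results must come from identical inputs (same frames and talar mesh).
#' Reports per-frame and stance-averaged differences in active contact area
#' and peak pressure, and the overlap of the active sets (shared active
#' triangles / union; 1 when both are empty).
#'
#' @param edem,dem `stance_result` objects.
#' @return an object of class `method_comparison` with elements `per_frame`
#'   (data frame) and `summary` (named list of stance averages).
#' @export
compare_methods <- function(edem, dem) {
  stopifnot(inherits(edem, "stance_result"), inherits(dem, "stance_result"))
  if (nrow(edem$summary) != nrow(dem$summary)) {
    stop("mismatched frame counts between the two results")
  }
  nf <- nrow(edem$summary)
  overlap <- vapply(seq_len(nf), function(j) {
    a <- edem$solutions[[j]]$active_ids
    b <- dem$solutions[[j]]$active_ids
    if (is.null(a) || is.null(b)) return(NA_real_)
    un <- length(union(a, b))
    if (un == 0L) 1 else length(intersect(a, b)) / un
  }, numeric(1))
  per_frame <- data.frame(
    frame = edem$summary$frame,
    area_edem = edem$summary$area_cm2, area_dem = dem$summary$area_cm2,
    d_area = edem$summary$area_cm2 - dem$summary$area_cm2,
    peak_edem = edem$summary$peak_mpa, peak_dem = dem$summary$peak_mpa,
    d_peak = edem$summary$peak_mpa - dem$summary$peak_mpa,
    overlap = overlap)
  summary <- list(
    mean_area_edem = mean(per_frame$area_edem, na.rm = TRUE),
    mean_area_dem = mean(per_frame$area_dem, na.rm = TRUE),
    mean_d_area = mean(per_frame$d_area, na.rm = TRUE),
    mean_d_peak = mean(per_frame$d_peak, na.rm = TRUE),
    mean_overlap = mean(per_frame$overlap, na.rm = TRUE))
  structure(list(per_frame = per_frame, summary = summary),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("<method_comparison> stance-average active area: EDEM %.3f cm^2, DEM %.3f cm^2 (delta %.3f); mean active-set overlap %.3f\n",
              x$summary$mean_area_edem, x$summary$mean_area_dem,
              x$summary$mean_d_area, x$summary$mean_overlap))
  invisible(x)
}
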