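# The spring mattress: the elastic-foundation bed of contact springs cast
# from the talar triangles to the tibial surface.
#
# One spring slot exists per talar triangle. Status lifecycle:
#   absent         no tibial intersection along the triangle normal
#   nominal        intersects and survives the length threshold
#   over_threshold intersects but the gap exceeds the threshold
#   active         in compression at equilibrium (set by the solver)
#   released       removed during the tension-release iteration

#' Material and model parameters
#'
#' Defaults are the homogeneous cartilage properties and thresholds used for
#' the tibiotalar joint: cartilage Young's modulus 10.35 MPa, Poisson ratio
#' 0.4247, spring length threshold 3.5 mm (twice a typical undeformed
#' cartilage layer), ligament Young's modulus 255 MPa. Units are mm / N / MPa
#' throughout (1 MPa = 1 N/mm^2).
#'
#' @param E_cartilage cartilage Young's modulus (MPa).
#' @param nu cartilage Poisson ratio, in `[0, 0.5)`.
#' @param h_threshold spring length threshold (mm) defining the nominal
#'   contact region.
#' @param E_ligament ligament Young's modulus (MPa).
#' @export
material_params <- function(E_cartilage = 10.35, nu = 0.4247,
                            h_threshold = 3.5, E_ligament = 255) {
  stopifnot(is.numeric(E_cartilage), E_cartilage > 0,
            is.numeric(h_threshold), h_threshold > 0,
            is.numeric(E_ligament), E_ligament > 0)
  if (!is.numeric(nu) || nu < 0 || nu >= 0.5) {
    stop("nu must satisfy 0 <= nu < 0.5")
  }
  structure(list(E_cartilage = E_cartilage, nu = nu,
                 h_threshold = h_threshold, E_ligament = E_ligament),
            class = "material_params")
}

#' Poisson confinement factor s(nu)
#'
#' The factor `s(nu) = (1 - nu) / ((1 - 2 nu) (1 + nu))` converting Young's
#' modulus into the confined (laterally constrained) foundation modulus of the
#' spring bed. It diverges at the incompressible limit `nu = 0.5`.
#'
#' @param nu Poisson ratio, in `[0, 0.5)`.
#' @return dimensionless factor.
#' @export
poisson_factor <- function(nu) {
  if (any(!is.finite(nu)) || any(nu < 0) || any(nu >= 0.5)) {
    stop("nu must satisfy 0 <= nu < 0.5 (factor diverges at nu = 0.5)")
  }
  (1 - nu) / ((1 - 2 * nu) * (1 + nu))
}

# Below this gap (mm) the 1/h stiffness diverges; treated as mesh
# interpenetration and raised as an error rather than clamped.
.length_floor <- 1e-3

#' Cast contact springs from the talus to the tibia
#'
#' For every talar triangle a ray is cast from its centroid along its normal;
#' the spring length is the distance to the nearest positive intersection with
#' the tibial surface (back faces accepted: the tibial sheet is open).
#' Triangles whose ray misses the tibia get status `absent`; all others start
#' as `nominal` with stored push-back force 0.
#'
#' @param talus moving-bone articular [tri_surface()], normals facing the
#'   tibia (see [orient_facing()]).
#' @param tibia fixed-bone articular [tri_surface()].
#' @param material a [material_params()].
#' @return an object of class `spring_mattress`: parallel vectors/matrices
#'   `origin`, `direction`, `area`, `length`, `hit_tri`, `stiffness`,
#'   `stored_force`, `status`, plus `n` and `material`.
#' @export
cast_springs <- function(talus, tibia, material = material_params()) {
  stopifnot(inherits(talus, "tri_surface"), inherits(tibia, "tri_surface"),
            inherits(material, "material_params"))
  hits <- ray_mesh_nearest(talus$centroids, talus$normals,
                           tibia$vertices, tibia$faces)
  n <- nrow(talus$faces)
  ok <- !is.na(hits$t)
  if (!any(ok)) {
    stop("no talar normal ray intersects the tibial surface; surfaces are disjoint or mis-oriented")
  }
  structure(list(
    n = n,
    origin = talus$centroids,
    direction = talus$normals,
    area = talus$areas,
    length = hits$t,
    hit_tri = hits$tri,
    stiffness = rep(NA_real_, n),
    stored_force = numeric(n),
    status = ifelse(ok, "nominal", "absent"),
    material = material
  ), class = "spring_mattress")
}

#' @export
print.spring_mattress <- function(x, ...) {
  tab <- table(factor(x$status, levels = c("absent", "over_threshold",
                                           "nominal", "active", "released")))
  cat(sprintf("<spring_mattress> %d slots (%s)\n", x$n,
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Apply the spring length threshold
#'
#' Springs whose length is strictly greater than the material's `h_threshold`
#' are marked `over_threshold`; the remainder form the nominal contact region.
#' A length exactly equal to the threshold is kept. Idempotent: statuses are
#' recomputed from the lengths.
#'
#' @param mattress a [cast_springs()] result.
#' @return the mattress with updated statuses.
#' @export
apply_length_threshold <- function(mattress) {
  stopifnot(inherits(mattress, "spring_mattress"))
  present <- mattress$status != "absent"
  over <- present & mattress$length > mattress$material$h_threshold
  mattress$status[present] <- ifelse(over[present], "over_threshold", "nominal")
  if (!any(mattress$status == "nominal")) {
    edem_log("warn", "nominal contact region is empty at threshold %.3g mm",
             mattress$material$h_threshold)
  }
  mattress
}

#' Strain-dependent spring stiffness
#'
#' Assigns each non-absent spring the stiffness
#' `k_i = s(nu) * E * A_i / h_i` (N/mm), where `A_i` is the talar triangle
#' area and `h_i` the current spring length (local cartilage gap). Stiffness
#' therefore grows as the gap closes.
#'
#' @param mattress a thresholded [cast_springs()] result.
#' @return the mattress with `stiffness` populated.
#' @export
compute_stiffnesses <- function(mattress) {
  stopifnot(inherits(mattress, "spring_mattress"))
  present <- which(mattress$status != "absent")
  bad <- present[mattress$length[present] <= .length_floor]
  if (length(bad)) {
    stop(sprintf("spring length at triangle %d is %.3g mm (<= %.3g mm floor): surfaces interpenetrate",
                 bad[1], mattress$length[bad[1]], .length_floor))
  }
  s <- poisson_factor(mattress$material$nu)
  mattress$stiffness[present] <- s * mattress$material$E_cartilage *
    mattress$area[present] / mattress$length[present]
  mattress
}

#' Export the gap/thickness map as CSV
#'
#' Writes one row per talar triangle: `triangle_id`, `length` (mm, NA when
#' absent), `area` (mm^2), `status`.
#'
#' @param mattress a [spring_mattress].
#' @param path output CSV path.
#' @export
write_gap_map <- function(mattress, path) {
  stopifnot(inherits(mattress, "spring_mattress"))
  df <- data.frame(triangle_id = seq_len(mattress$n),
                   length = ifelse(mattress$status == "absent", NA_real_,
                                   mattress$length),
                   area = mattress$area,
                   status = mattress$status)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
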