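# Ligament bundles: tension-only linear fibres restraining talus translation.
#
# Each bundle is a set of fibres between a talus-side attachment footprint and
# a fixed-side (tibia/fibula) footprint. Fibres are linear elastic in tension
# (stiffness E * A / L0) and carry no force in compression unless the bundle
# is flagged bilateral. Rest lengths are captured at the reference pose with
# no pre-tension.

.fibre_points <- function(footprint, n) {
  footprint <- matrix(as.numeric(footprint), ncol = 3)
  if (nrow(footprint) == 1L) {
    matrix(rep(footprint, each = n), nrow = n)
  } else {
    s <- if (n == 1L) 0.5 else seq(0, 1, length.out = n)
    outer(1 - s, footprint[1, ]) + outer(s, footprint[2, ])
  }
}

#' Build ligament bundles from attachment footprints
#'
#' @param attachments named list, one entry per bundle, each a list with
#'   elements `talus` and `fixed`: a single point (length-3) or a 2 x 3
#'   segment matrix (mm). Fibres are distributed evenly along each footprint.
#'   An ankle model normally has four bundles (anterior/posterior tibiotalar,
#'   anterior/posterior talofibular); fewer raise a warning.
#' @param material a [material_params()]; supplies the ligament Young's
#'   modulus.
#' @param fibre_area fibre cross-sectional area (mm^2).
#' @param fibres_per_bundle number of fibres per bundle.
#' @param bilateral if TRUE fibres also resist compression (sensitivity
#'   checks only).
#' @return list of `ligament_bundle` objects.
#' @export
make_bundles <- function(attachments, material = material_params(),
                         fibre_area = 1, fibres_per_bundle = 5L,
                         bilateral = FALSE) {
  stopifnot(is.list(attachments), length(attachments) >= 1L,
            fibre_area > 0, fibres_per_bundle >= 1L)
  if (length(attachments) != 4L) {
    warning(sprintf("expected 4 ligament bundles, got %d", length(attachments)))
  }
  nm <- names(attachments) %||% paste0("bundle_", seq_along(attachments))
  bundles <- lapply(seq_along(attachments), function(i) {
    att <- attachments[[i]]
    tp <- .fibre_points(att$talus, fibres_per_bundle)
    fp <- .fibre_points(att$fixed, fibres_per_bundle)
    rest <- .row_norms(tp - fp)
    if (any(rest < 1e-9)) {
      stop(sprintf("bundle '%s' has coincident attachment endpoints (zero rest length)", nm[i]))
    }
    structure(list(name = nm[i], E = material$E_ligament,
                   fibre_area = fibre_area,
                   talus_points = tp, fixed_points_ref = fp,
                   fixed_points = fp, rest_lengths = rest,
                   bilateral = isTRUE(bilateral)),
              class = "ligament_bundle")
  })
  names(bundles) <- nm
  bundles
}

#' Override the ligament Young's modulus of a bundle set
#' @param bundles list of ligament bundles from [make_bundles()].
#' @param E_ligament new modulus (MPa).
#' @export
set_ligament_modulus <- function(bundles, E_ligament) {
  stopifnot(E_ligament > 0)
  lapply(bundles, function(b) {
    b$E <- E_ligament
    b
  })
}

#' Rotate the fixed-side anchors with the tibia
#'
#' Re-poses the fixed (tibia/fibula-side) attachment points from the reference
#' pose to the given joint angle. The talus-side points are handled through
#' the displacement argument of [ligament_forces()].
#'
#' @param bundles list of ligament bundles.
#' @param axis a [joint_axis()].
#' @param angle_deg absolute joint angle from the reference pose (degrees).
#' @export
rotate_bundle_anchors <- function(bundles, axis, angle_deg) {
  lapply(bundles, function(b) {
    b$fixed_points <- rotate_about_axis(b$fixed_points_ref, axis, angle_deg)
    b
  })
}

#' Ligament forces and tangent stiffness at a talus translation
#'
#' Every fibre is tension-only linear: tension `T = (E A / L0) * max(L - L0, 0)`
#' where `L` is the fibre length once the talus-side endpoint is translated by
#' `u` (mm, from the reference pose). The force on the talus acts along the
#' fibre toward the fixed side. The returned 3 x 3 matrix is the tangent
#' stiffness of the taut fibres (material + geometric terms), suitable for the
#' Newton solve of the contact equilibrium.
#'
#' @param bundles list of ligament bundles.
#' @param u total talus translation from the reference pose (mm).
#' @return list with `force` (N, on the talus), `tensions` (named list of
#'   per-fibre tensions, N) and `K` (3 x 3 N/mm, resisting stiffness).
#' @export
ligament_forces <- function(bundles, u) {
  u <- as.numeric(u)
  stopifnot(length(u) == 3L)
  force <- c(0, 0, 0)
  K <- matrix(0, 3, 3)
  tensions <- vector("list", length(bundles))
  names(tensions) <- vapply(bundles, `[[`, character(1), "name")
  for (j in seq_along(bundles)) {
    b <- bundles[[j]]
    pt <- sweep(b$talus_points, 2, u, "+")
    w <- pt - b$fixed_points
    L <- .row_norms(w)
    d <- w / L
    dl <- L - b$rest_lengths
    kf <- b$E * b$fibre_area / b$rest_lengths
    tens <- if (b$bilateral) kf * dl else kf * pmax(dl, 0)
    tensions[[j]] <- tens
    force <- force - colSums(tens * d)
    # fibres exactly at rest contribute their material stiffness (one-sided
    # kink): the tangent is taken from the taut side so the equilibrium
    # Newton sees the restraint as soon as the fibre engages
    taut <- if (b$bilateral) rep(TRUE, length(L)) else dl >= 0
    for (i in which(taut)) {
      dd <- tcrossprod(d[i, ])
      K <- K + kf[i] * dd + (tens[i] / L[i]) * (diag(3) - dd)
    }
  }
  list(force = force, tensions = tensions, K = K)
}
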