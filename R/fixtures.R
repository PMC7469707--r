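# Parametric synthetic joint fixtures with known analytic properties.
#
# Four kinds:
#   flat_congruent      two parallel plates separated by a uniform gap
#   cylinder_congruent  concentric cylinder sectors (convex talar trochlea
#                       inside a concave tibial sector), constant radial gap
#   cylinder_incongruent tibial radius exceeds talar radius + gap, so the gap
#                       grows away from the apex contact line
#   flat_with_depressions flat plates with local tibial depressions that push
#                       the gap above the length threshold (persistently
#                       inactive regions)
#
# The anatomical frame is +x anterior, +y superior, +z lateral; the tibia sits
# on the +y side of the talus and the cylinder axis (the joint axis) runs
# along +z.

.grid_faces <- function(nu, nv, flip = FALSE) {
  i <- rep(seq_len(nu - 1L), times = nv - 1L)
  j <- rep(seq_len(nv - 1L), each = nu - 1L)
  a <- (j - 1L) * nu + i
  b <- a + 1L
  d <- a + nu
  cc <- d + 1L
  f <- rbind(cbind(a, d, b), cbind(b, d, cc))
  if (flip) f <- f[, c(1L, 3L, 2L)]
  f
}

# Interleave the two triangles of each cell so that face index pairs
# (2k-1, 2k) cover cell k in both surfaces of a congruent pair.
.grid_faces_paired <- function(nu, nv, flip = FALSE) {
  f <- .grid_faces(nu, nv, flip)
  ncell <- (nu - 1L) * (nv - 1L)
  ord <- as.vector(rbind(seq_len(ncell), seq_len(ncell) + ncell))
  f[ord, , drop = FALSE]
}

.plate_surface <- function(xs, zs, height_fun, up = TRUE) {
  nu <- length(xs)
  nv <- length(zs)
  xx <- rep(xs, times = nv)
  zz <- rep(zs, each = nu)
  yy <- height_fun(xx, zz)
  tri_surface(cbind(xx, yy, zz), .grid_faces_paired(nu, nv, flip = !up))
}

.cylinder_surface <- function(radius, centre_y, phis, zs, outward = TRUE) {
  nu <- length(phis)
  nv <- length(zs)
  pp <- rep(phis, times = nv)
  zz <- rep(zs, each = nu)
  v <- cbind(radius * sin(pp), centre_y + radius * cos(pp), zz)
  # outward radial normals with the (a, d, b) winding; concave side flips
  tri_surface(v, .grid_faces_paired(nu, nv, flip = !outward))
}

.res_to_grid <- function(resolution, len_u, len_v) {
  cells <- max(4, resolution / 2)
  nu <- max(2L, round(sqrt(cells * len_u / len_v)))
  nv <- max(2L, round(cells / nu))
  c(nu + 1L, nv + 1L)  # vertex counts
}

#' Specification of a synthetic joint fixture
#'
#' @param kind one of `"flat_congruent"`, `"cylinder_congruent"`,
#'   `"cylinder_incongruent"`, `"flat_with_depressions"`.
#' @param extent plate extent `c(x, z)` in mm (flat kinds).
#' @param gap nominal cartilage gap (mm).
#' @param radius_talus talar (convex) cylinder radius (mm).
#' @param radius_tibia tibial (concave) radius (mm); required for the
#'   incongruent kind and must exceed `radius_talus + gap`.
#' @param arc_deg talar angular extent of the cylinder sector (degrees).
#' @param axis_length cylinder length along the joint axis (mm).
#' @param resolution target triangle count per surface (>= 8).
#' @param depressions list of `list(centre = c(x, z), radius, depth)` entries
#'   (flat_with_depressions); `NULL` selects two default depressions.
#' @param margin_deg extra tibial angular margin so edge rays still intersect.
#' @param seed ignored (deterministic generator), kept for interface
#'   stability.
#' @export
fixture_spec <- function(kind = c("flat_congruent", "cylinder_congruent",
                                  "cylinder_incongruent",
                                  "flat_with_depressions"),
                         extent = c(20, 20), gap = 2, radius_talus = 20,
                         radius_tibia = NULL, arc_deg = 90, axis_length = 20,
                         resolution = 800, depressions = NULL,
                         margin_deg = 6, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(gap > 0, resolution >= 8, all(extent > 0), radius_talus > 0,
            arc_deg > 0, axis_length > 0)
  if (kind == "cylinder_incongruent") {
    if (is.null(radius_tibia)) radius_tibia <- radius_talus + gap + 2.5
    if (radius_tibia <= radius_talus + gap) {
      stop("radius_tibia must exceed radius_talus + gap")
    }
  }
  if (kind == "flat_with_depressions" && is.null(depressions)) {
    depressions <- list(
      list(centre = c(-extent[1] / 4, 0), radius = extent[1] / 6, depth = 2),
      list(centre = c(extent[1] / 4, 0), radius = extent[1] / 6, depth = 2))
  }
  structure(list(kind = kind, extent = extent, gap = gap,
                 radius_talus = radius_talus, radius_tibia = radius_tibia,
                 arc_deg = arc_deg, axis_length = axis_length,
                 resolution = resolution, depressions = depressions,
                 margin_deg = margin_deg, seed = seed),
            class = "fixture_spec")
}

.default_attachments <- function(corners, up_offset = 12, out_offset = 5) {
  # corners: 4 x 3 matrix ordered (+x,-z), (+x,+z), (-x,-z), (-x,+z)
  seg <- function(p, dz = 2) rbind(p + c(0, 0, -dz), p + c(0, 0, dz))
  fixed_of <- function(p) {
    p + c(sign(p[1]) * out_offset, up_offset, sign(p[3]) * out_offset)
  }
  list(
    anterior_tibiotalar = list(talus = seg(corners[1, ]),
                               fixed = seg(fixed_of(corners[1, ]))),
    anterior_talofibular = list(talus = seg(corners[2, ]),
                                fixed = seg(fixed_of(corners[2, ]))),
    posterior_tibiotalar = list(talus = seg(corners[3, ]),
                                fixed = seg(fixed_of(corners[3, ]))),
    posterior_talofibular = list(talus = seg(corners[4, ]),
                                 fixed = seg(fixed_of(corners[4, ])))
  )
}

#' Build a synthetic joint
#'
#' Generates a talar and a tibial articular surface of the requested kind,
#' with talar normals facing the tibia, the joint axis, and four symmetric
#' ligament attachment footprints at the talar corners.
#'
#' @param spec a [fixture_spec()].
#' @return an object of class `synthetic_joint`: list with `talus`, `tibia`,
#'   `axis`, `attachments` and `info` (generator metadata; for the depression
#'   kind, `info$raised_vertices` flags the displaced tibial vertices).
#' @export
make_joint <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  info <- list(kind = spec$kind, spec = spec)
  if (spec$kind %in% c("flat_congruent", "flat_with_depressions")) {
    g <- .res_to_grid(spec$resolution, spec$extent[1], spec$extent[2])
    xs <- seq(-spec$extent[1] / 2, spec$extent[1] / 2, length.out = g[1])
    zs <- seq(-spec$extent[2] / 2, spec$extent[2] / 2, length.out = g[2])
    talus <- .plate_surface(xs, zs, function(x, z) rep(0, length(x)), up = TRUE)
    raised <- NULL
    tib_height <- function(x, z) {
      y <- rep(spec$gap, length(x))
      for (dep in spec$depressions %||% list()) {
        inside <- (x - dep$centre[1])^2 + (z - dep$centre[2])^2 <= dep$radius^2
        y[inside] <- y[inside] + dep$depth
      }
      y
    }
    tibia <- .plate_surface(xs, zs, tib_height, up = FALSE)
    if (spec$kind == "flat_with_depressions") {
      raised <- abs(tibia$vertices[, 2] - spec$gap) > 1e-12
      info$raised_vertices <- raised
    }
    axis <- joint_axis(c(0, 0, 0), c(0, 0, 1))
    corners <- rbind(c(spec$extent[1] / 2, 0, -spec$extent[2] / 2),
                     c(spec$extent[1] / 2, 0, spec$extent[2] / 2),
                     c(-spec$extent[1] / 2, 0, -spec$extent[2] / 2),
                     c(-spec$extent[1] / 2, 0, spec$extent[2] / 2))
    info$grid <- g
  } else {
    r <- spec$radius_talus
    arc <- spec$arc_deg * pi / 180
    g <- .res_to_grid(spec$resolution, r * arc, spec$axis_length)
    phis <- seq(-arc / 2, arc / 2, length.out = g[1])
    zs <- seq(-spec$axis_length / 2, spec$axis_length / 2, length.out = g[2])
    talus <- .cylinder_surface(r, 0, phis, zs, outward = TRUE)
    margin <- spec$margin_deg * pi / 180
    if (spec$kind == "cylinder_congruent") {
      R <- r + spec$gap
      cy <- 0
      psi_max <- arc / 2 + margin
    } else {
      R <- spec$radius_tibia
      cy <- r + spec$gap - R
      # where does the steepest talar ray meet the tibial circle?
      phi <- arc / 2
      b <- r - cy * cos(phi)
      cc <- r^2 - 2 * r * cy * cos(phi) + cy^2 - R^2
      t_hit <- -b + sqrt(b^2 - cc)
      hx <- r * sin(phi) + t_hit * sin(phi)
      hy <- r * cos(phi) + t_hit * cos(phi) - cy
      psi_max <- atan2(hx, hy) + margin
    }
    n_tib <- max(g[1], ceiling(g[1] * (2 * psi_max) / arc))
    psis <- seq(-psi_max, psi_max, length.out = n_tib)
    tibia <- .cylinder_surface(R, cy, psis, zs, outward = FALSE)
    axis <- joint_axis(c(0, 0, 0), c(0, 0, 1))
    xe <- r * sin(arc / 2)
    ye <- r * cos(arc / 2)
    ze <- spec$axis_length / 2
    corners <- rbind(c(xe, ye, -ze), c(xe, ye, ze),
                     c(-xe, ye, -ze), c(-xe, ye, ze))
    info$grid <- g
    info$tibia_radius <- R
    info$tibia_centre_y <- cy
  }
  structure(list(talus = talus, tibia = tibia, axis = axis,
                 attachments = .default_attachments(corners), info = info),
            class = "synthetic_joint")
}

#' @export
print.synthetic_joint <- function(x, ...) {
  cat(sprintf("<synthetic_joint> kind '%s': talus %d faces (%.2f cm^2), tibia %d faces\n",
              x$info$kind, nrow(x$talus$faces), surface_area(x$talus) / 100,
              nrow(x$tibia$faces)))
  invisible(x)
}

#' Talar triangles lying under the tibial depressions
#'
#' For the `flat_with_depressions` fixture the talar and tibial plates share
#' one grid, so each talar triangle faces the tibial triangle with the same
#' index. A talar triangle is "under a depression" when at least two of the
#' three vertices of its facing tibial triangle are displaced: the ray through
#' its centroid then measures a gap of at least two thirds of the depression
#' depth above the nominal gap.
#'
#' @param joint a `synthetic_joint` of kind `flat_with_depressions`.
#' @return integer vector of talar triangle ids.
#' @export
depression_triangle_ids <- function(joint) {
  stopifnot(inherits(joint, "synthetic_joint"),
            joint$info$kind == "flat_with_depressions")
  raised <- joint$info$raised_vertices
  f <- joint$tibia$faces
  n_raised <- raised[f[, 1]] + raised[f[, 2]] + raised[f[, 3]]
  which(n_raised >= 2L)
}
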