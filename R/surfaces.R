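# Triangulated articular surfaces and rigid transforms.
#
# A `tri_surface` stores vertices (mm) and faces together with per-triangle
# derived data (centroid, unit normal, area). Normals follow the face winding:
# for a talar articular surface they must point toward the opposing (tibial)
# surface before springs are cast.

.row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.row_norms <- function(m) sqrt(rowSums(m * m))

.triangle_data <- function(vertices, faces) {
  v1 <- vertices[faces[, 1], , drop = FALSE]
  v2 <- vertices[faces[, 2], , drop = FALSE]
  v3 <- vertices[faces[, 3], , drop = FALSE]
  cr <- .row_cross(v2 - v1, v3 - v1)
  cn <- .row_norms(cr)
  areas <- cn / 2
  normals <- cr / cn
  centroids <- (v1 + v2 + v3) / 3
  list(centroids = centroids, normals = normals, areas = areas)
}

#' Triangulated surface
#'
#' Construct a rigid triangulated surface with per-triangle centroids, unit
#' normals and areas. Faces that are geometrically degenerate (zero area,
#' including faces with repeated vertex indices) are removed with a warning.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#'   The winding order defines the normal direction (right-hand rule).
#' @return An object of class `tri_surface` with elements `vertices`, `faces`,
#'   `centroids`, `normals`, `areas`.
#' @export
tri_surface <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) < 1L) stop("surface has no faces")
  if (any(is.na(vertices))) stop("vertices contain missing values")
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    stop("face indices out of range")
  }
  cd <- .triangle_data(vertices, faces)
  repeated <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  degen <- repeated | !is.finite(cd$areas) | cd$areas < 1e-10
  if (any(degen)) {
    warning(sprintf("removed %d degenerate face(s)", sum(degen)))
    faces <- faces[!degen, , drop = FALSE]
    if (nrow(faces) == 0L) stop("empty mesh after degenerate-face removal")
    cd <- .triangle_data(vertices, faces)
  }
  structure(list(vertices = vertices, faces = faces,
                 centroids = cd$centroids, normals = cd$normals,
                 areas = cd$areas),
            class = "tri_surface")
}

#' @export
print.tri_surface <- function(x, ...) {
  cat(sprintf("<tri_surface> %d vertices, %d faces, area %.3f mm^2\n",
              nrow(x$vertices), nrow(x$faces), sum(x$areas)))
  invisible(x)
}

#' Per-triangle centroids, normals and areas
#'
#' @param surface a [tri_surface()].
#' @return list with `centroids` (n x 3, mm), `normals` (n x 3, unit) and
#'   `areas` (n, mm^2).
#' @export
triangle_properties <- function(surface) {
  stopifnot(inherits(surface, "tri_surface"))
  list(centroids = surface$centroids, normals = surface$normals,
       areas = surface$areas)
}

#' Total surface area in mm^2
#' @param surface a [tri_surface()].
#' @export
surface_area <- function(surface) sum(surface$areas)

#' Check that the face winding is consistent across the surface
#'
#' On a consistently oriented surface every interior edge is traversed in
#' opposite order by its two adjacent faces, i.e. no directed edge occurs
#' twice.
#'
#' @param surface a [tri_surface()].
#' @return logical scalar.
#' @export
is_orientation_consistent <- function(surface) {
  f <- surface$faces
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  keys <- paste(edges[, 1], edges[, 2])
  !anyDuplicated(keys)
}

#' Reverse the winding (and hence the normals) of a surface
#' @param surface a [tri_surface()].
#' @export
flip_surface <- function(surface) {
  tri_surface(surface$vertices, surface$faces[, c(1, 3, 2), drop = FALSE])
}

#' Joint axis
#'
#' A line in space given by a point (mm) and a unit direction, used as the
#' dorsiflexion/plantarflexion hinge of the modelled joint.
#'
#' @param point numeric length-3, a point on the axis (mm).
#' @param direction numeric length-3; normalised internally.
#' @export
joint_axis <- function(point, direction) {
  point <- as.numeric(point)
  direction <- as.numeric(direction)
  stopifnot(length(point) == 3L, length(direction) == 3L)
  nd <- sqrt(sum(direction^2))
  if (nd < 1e-12) stop("axis direction has zero length")
  structure(list(point = point, direction = direction / nd),
            class = "joint_axis")
}

#' @export
print.joint_axis <- function(x, ...) {
  cat(sprintf("<joint_axis> point (%.3f, %.3f, %.3f), direction (%.4f, %.4f, %.4f)\n",
              x$point[1], x$point[2], x$point[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

#' Rigid pose (rotation + translation)
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation numeric length-3 (mm).
#' @export
rigid_pose <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8) {
    stop("rotation must be orthonormal with determinant +1")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_pose")
}

#' Apply a rigid pose to a surface
#' @param surface a [tri_surface()].
#' @param pose a [rigid_pose()].
#' @export
apply_pose <- function(surface, pose) {
  stopifnot(inherits(pose, "rigid_pose"))
  v <- surface$vertices %*% t(pose$rotation)
  v <- sweep(v, 2, pose$translation, "+")
  tri_surface(v, surface$faces)
}

# Rodrigues rotation matrix about unit vector k by angle (radians).
.rodrigues <- function(k, theta) {
  kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) * cos(theta) + sin(theta) * kx + (1 - cos(theta)) * tcrossprod(k)
}

#' Rotate about a joint axis
#'
#' Rodrigues rotation of a surface or a set of points about the axis *line*
#' (the axis point is the centre of rotation). The sign convention is
#' right-handed about the axis direction; with the default anatomical frame
#' (+z lateral on a right joint) a positive angle is dorsiflexion.
#'
#' @param x a [tri_surface()], an n x 3 matrix of points, or a length-3 point.
#' @param axis a [joint_axis()].
#' @param angle_deg rotation angle in degrees.
#' @return object of the same type as `x`, rotated.
#' @export
rotate_about_axis <- function(x, axis, angle_deg) {
  UseMethod("rotate_about_axis")
}

.rotate_points <- function(p, axis, angle_deg) {
  r <- .rodrigues(axis$direction, angle_deg * pi / 180)
  shifted <- sweep(p, 2, axis$point, "-")
  sweep(shifted %*% t(r), 2, axis$point, "+")
}

#' @export
rotate_about_axis.tri_surface <- function(x, axis, angle_deg) {
  stopifnot(inherits(axis, "joint_axis"))
  tri_surface(.rotate_points(x$vertices, axis, angle_deg), x$faces)
}

#' @export
rotate_about_axis.matrix <- function(x, axis, angle_deg) {
  stopifnot(inherits(axis, "joint_axis"), ncol(x) == 3L)
  .rotate_points(x, axis, angle_deg)
}

#' @export
rotate_about_axis.numeric <- function(x, axis, angle_deg) {
  stopifnot(length(x) == 3L)
  as.numeric(.rotate_points(matrix(x, 1, 3), axis, angle_deg))
}

#' Translate a surface rigidly
#'
#' Vertices and centroids are shifted by `u`; normals and areas are carried
#' over unchanged (a translation cannot alter them).
#'
#' @param surface a [tri_surface()].
#' @param u numeric length-3 translation (mm).
#' @export
translate_surface <- function(surface, u) {
  stopifnot(inherits(surface, "tri_surface"), length(u) == 3L)
  u <- as.numeric(u)
  surface$vertices <- sweep(surface$vertices, 2, u, "+")
  surface$centroids <- sweep(surface$centroids, 2, u, "+")
  surface
}

#' Least-squares cylinder fit of the joint axis
#'
#' Fits a circular cylinder to the triangle centroids of an articular surface
#' and returns its axis. The direction is initialised from the smallest
#' eigenvector of the triangle-normal covariance (cylinder normals are
#' perpendicular to the axis), the centre and radius from an algebraic circle
#' fit of the centroids projected along that direction, and all five degrees
#' of freedom are then refined by Gauss-Newton least squares on the radial
#' residuals.
#'
#' @param surface a [tri_surface()] with at least 20 triangles, not planar.
#' @param reference_direction the returned direction is flipped, if needed, to
#'   have a positive dot product with this vector (default +z).
#' @return a [joint_axis()]; attributes `radius` (mm) and `rms` (mm, radial
#'   residual RMS) report the fit.
#' @export
fit_cylinder_axis <- function(surface, reference_direction = c(0, 0, 1)) {
  stopifnot(inherits(surface, "tri_surface"))
  if (nrow(surface$faces) < 20L) stop("cylinder fit needs at least 20 triangles")
  p <- surface$centroids
  nrm <- surface$normals

  m <- crossprod(nrm) / nrow(nrm)
  eg <- eigen(m, symmetric = TRUE)
  # eigenvalues sum to 1; a planar patch has two near-zero eigenvalues and no
  # defined axis.
  if (eg$values[2] < 1e-4) {
    stop("surface is degenerate (planar or collinear): cylinder axis undefined")
  }
  d0 <- eg$vectors[, 3]

  # orthonormal in-plane basis
  seed <- if (abs(d0[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- seed - sum(seed * d0) * d0
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d0[2] * e1[3] - d0[3] * e1[2],
          d0[3] * e1[1] - d0[1] * e1[3],
          d0[1] * e1[2] - d0[2] * e1[1])

  p0 <- colMeans(p)
  pc <- sweep(p, 2, p0, "-")
  x <- as.numeric(pc %*% e1)
  y <- as.numeric(pc %*% e2)
  # algebraic (Kasa) circle fit for the initial centre and radius
  ab <- tryCatch(
    qr.solve(cbind(2 * x, 2 * y, 1), x^2 + y^2),
    error = function(e) stop("surface is degenerate: circle fit failed")
  )
  r0 <- sqrt(max(ab[3] + ab[1]^2 + ab[2]^2, 1e-12))

  resid_fun <- function(par) {
    dir <- d0 + par[1] * e1 + par[2] * e2
    dir <- dir / sqrt(sum(dir^2))
    cpt <- p0 + par[3] * e1 + par[4] * e2
    rel <- sweep(p, 2, cpt, "-")
    ax <- as.numeric(rel %*% dir)
    rad2 <- rowSums(rel * rel) - ax^2
    sqrt(pmax(rad2, 0)) - par[5]
  }
  fit <- minpack.lm::nls.lm(par = c(0, 0, ab[1], ab[2], r0), fn = resid_fun,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!fit$info %in% 1:4) {
    stop(sprintf("cylinder fit did not converge (nls.lm info %d)", fit$info))
  }
  par <- fit$par
  dir <- d0 + par[1] * e1 + par[2] * e2
  dir <- dir / sqrt(sum(dir^2))
  if (sum(dir * reference_direction) < 0) dir <- -dir
  cpt <- p0 + par[3] * e1 + par[4] * e2
  rms <- sqrt(mean(resid_fun(par)^2))
  edem_log("debug", "cylinder fit: radius %.4f mm, radial RMS %.3e mm",
           par[5], rms)
  ax <- joint_axis(cpt, dir)
  attr(ax, "radius") <- par[5]
  attr(ax, "rms") <- rms
  ax
}

#' Orient one articular surface toward another
#'
#' Casts rays from up to `n_rays` triangle centroids along both the surface
#' normals and their opposites; if the flipped orientation hits the target
#' surface more often, the surface winding is reversed. Sampling is
#' deterministic (evenly spaced triangles).
#'
#' @param surface the surface whose normals should face `target`.
#' @param target the opposing [tri_surface()].
#' @param n_rays number of test rays.
#' @return `surface`, flipped if necessary.
#' @export
orient_facing <- function(surface, target, n_rays = 50L) {
  nf <- nrow(surface$faces)
  idx <- unique(round(seq(1L, nf, length.out = min(n_rays, nf))))
  fwd <- ray_mesh_nearest(surface$centroids[idx, , drop = FALSE],
                          surface$normals[idx, , drop = FALSE],
                          target$vertices, target$faces)
  bwd <- ray_mesh_nearest(surface$centroids[idx, , drop = FALSE],
                          -surface$normals[idx, , drop = FALSE],
                          target$vertices, target$faces)
  if (sum(!is.na(bwd$t)) > sum(!is.na(fwd$t))) {
    warning("surface normals point away from the opposing surface; flipping winding")
    return(flip_surface(surface))
  }
  surface
}
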