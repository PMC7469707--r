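# Independent oracles and small synthetic builders used across the suite.
# These deliberately re-derive results through different algorithms than the
# package (linear-system barycentric intersection instead of Moller-Trumbore;
# MASS::ginv instead of the package's eigen pseudo-inverse).

# Brute-force ray/mesh nearest-positive-hit: test every triangle by solving
# o + t d = v1 + b e1 + c e2 as a 3x3 linear system.
oracle_ray_lengths <- function(talus, tibia) {
  V <- tibia$vertices
  F <- tibia$faces
  n_rays <- nrow(talus$faces)
  out <- rep(NA_real_, n_rays)
  for (r in seq_len(n_rays)) {
    o <- talus$centroids[r, ]
    d <- talus$normals[r, ]
    best <- Inf
    for (i in seq_len(nrow(F))) {
      v1 <- V[F[i, 1], ]; e1 <- V[F[i, 2], ] - v1; e2 <- V[F[i, 3], ] - v1
      M <- cbind(d, -e1, -e2)
      x <- tryCatch(solve(M, v1 - o), error = function(e) NULL)
      if (is.null(x)) next
      if (x[2] >= -1e-9 && x[3] >= -1e-9 && x[2] + x[3] <= 1 + 1e-9 &&
          x[1] > 1e-12 && x[1] < best) {
        best <- x[1]
      }
    }
    if (is.finite(best)) out[r] <- best
  }
  out
}

# Naive re-implementation of the removal-only tension-release iteration on an
# explicit spring list (no ligaments): remove every non-compressed spring,
# re-solve with the Moore-Penrose inverse, repeat.
oracle_contact <- function(normals, k, fprev, F_applied) {
  S <- seq_len(nrow(normals))
  repeat {
    if (!length(S)) {
      return(list(active = integer(0), forces = numeric(0), liftoff = TRUE,
                  ill_posed = FALSE))
    }
    K <- matrix(0, 3, 3)
    rhs <- F_applied
    for (i in S) {
      K <- K + k[i] * tcrossprod(normals[i, ])
      rhs <- rhs - fprev[i] * normals[i, ]
    }
    u <- as.numeric(MASS::ginv(K) %*% rhs)
    f <- vapply(S, function(i) k[i] * sum(normals[i, ] * u) + fprev[i],
                numeric(1))
    if (all(f > 0)) {
      # a rank-deficient final set may leave part of the load unbalanced:
      # no equilibrium exists there and both routes must refuse
      resid <- F_applied
      for (j in seq_along(S)) resid <- resid - f[j] * normals[S[j], ]
      ill <- sqrt(sum(resid^2)) > 1e-8 * max(1, sqrt(sum(F_applied^2)))
      return(list(active = S, forces = f, u = u, liftoff = FALSE,
                  ill_posed = ill))
    }
    S <- S[f > 0]
  }
}

# Random well-posed spring system generator (normals in a +y hemisphere cap,
# mostly compressive load).
random_spring_system <- function(n_springs, with_state = FALSE) {
  repeat {
    v <- cbind(stats::runif(n_springs, -1, 1),
               stats::runif(n_springs, 0.35, 1),
               stats::runif(n_springs, -1, 1))
    nr <- sqrt(rowSums(v^2))
    normals <- v / nr
    if (all(is.finite(normals))) break
  }
  list(normals = normals,
       k = stats::runif(n_springs, 1, 10),
       fprev = if (with_state) stats::runif(n_springs, 0, 2) else numeric(n_springs),
       F_applied = c(stats::runif(1, -10, 10), stats::runif(1, 10, 50),
                     stats::runif(1, -10, 10)))
}

# Hand-built spring mattress for solver unit tests (areas in mm^2, k in N/mm).
synth_mattress <- function(normals, k, areas = rep(1, nrow(normals)),
                           lengths = rep(2, nrow(normals)),
                           material = material_params()) {
  n <- nrow(normals)
  structure(list(n = n, origin = matrix(0, n, 3), direction = normals,
                 area = areas, length = lengths, hit_tri = seq_len(n),
                 stiffness = k, stored_force = numeric(n),
                 status = rep("nominal", n), material = material),
            class = "spring_mattress")
}

# Thresholded + stiffened mattress for a joint in one call.
prepared_mattress <- function(joint, material = material_params()) {
  compute_stiffnesses(apply_length_threshold(
    cast_springs(joint$talus, joint$tibia, material)))
}

expect_balanced <- function(solution, mattress, bundles, F_applied,
                            u_total = solution$u_step) {
  springs <- if (length(solution$active_ids)) {
    colSums(as.numeric(solution$spring_forces) *
              mattress$direction[solution$active_ids, , drop = FALSE])
  } else c(0, 0, 0)
  lig <- if (is.null(bundles)) c(0, 0, 0) else {
    ligament_forces(bundles, u_total)$force
  }
  resid <- F_applied - springs + lig
  tol <- 1e-8 * max(1, sqrt(sum(F_applied^2)))
  expect_lt(sqrt(sum(resid^2)), tol + 1e-12)
  if (length(solution$active_ids)) {
    expect_gt(min(as.numeric(solution$spring_forces)), 0)
  }
  invisible(resid)
}
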