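# Contact equilibrium core.
#
# Translation-only force balance of the talus against the spring bed and the
# ligaments, with iterative release of non-compressed springs. Sign ledger
# (all conventions are pinned here):
#   * spring direction n_i points from the talus toward the tibia;
#   * a positive spring force f_i means compression: the spring pushes the
#     talus away from the tibia, i.e. exerts -f_i n_i on the talus;
#   * EDEM spring force: f_i = k_i (n_i . u) + f_prev_i, where u is the talus
#     translation increment of the current solve and f_prev_i the stored
#     push-back force from the previous time point (DEM: f_prev = 0);
#   * equilibrium of forces on the talus:
#       F_applied - sum_i f_i n_i + F_ligament(u_cum + u) = 0.

#' Solver parameters
#'
#' @param residual_tol convergence tolerance on the force residual (N);
#'   default `1e-8 * max(1, ||F_applied||)`, resolved at solve time.
#' @param max_active_set_iterations cap on tension-release iterations;
#'   default: the initial nominal spring count.
#' @param stiffness_update `"lagged"` (default) holds each spring stiffness at
#'   its start-of-time-point value during the solve; `"within_step"`
#'   recomputes it from the deformed gap each inner iteration.
#' @param removal_rule `"all_tensile"` (default) releases every non-compressed
#'   spring each iteration; `"most_tensile_only"` releases one per iteration.
#' @export
solver_params <- function(residual_tol = NULL,
                          max_active_set_iterations = NULL,
                          stiffness_update = c("lagged", "within_step"),
                          removal_rule = c("all_tensile", "most_tensile_only")) {
  if (!is.null(residual_tol)) stopifnot(residual_tol > 0)
  if (!is.null(max_active_set_iterations)) {
    stopifnot(max_active_set_iterations >= 1)
  }
  structure(list(residual_tol = residual_tol,
                 max_active_set_iterations = max_active_set_iterations,
                 stiffness_update = match.arg(stiffness_update),
                 removal_rule = match.arg(removal_rule)),
            class = "solver_params")
}

#' Solver state carried between EDEM time points
#'
#' @param n_springs number of talar triangles (spring slots).
#' @return list with `u_cum` (cumulative talus translation, mm, zero at t=0)
#'   and `stored_forces` (per-spring push-back forces, N, zero at t=0).
#' @export
solver_state <- function(n_springs) {
  structure(list(u_cum = c(0, 0, 0), stored_forces = numeric(n_springs)),
            class = "solver_state")
}

.norm3 <- function(x) sqrt(sum(x * x))

# Symmetric positive-semidefinite solve via eigen pseudo-inverse. Errors if b
# has a component outside the range of A larger than tol_rhs (the equilibrium
# is then under-constrained in that direction).
.psolve <- function(A, b, tol_rhs) {
  eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
  vmax <- max(eg$values, 0)
  keep <- eg$values > vmax * 1e-10
  if (!any(keep)) {
    if (.norm3(b) <= tol_rhs) return(c(0, 0, 0))
    stop("under-constrained equilibrium: stiffness matrix is zero")
  }
  Vk <- eg$vectors[, keep, drop = FALSE]
  coef <- crossprod(Vk, b)
  b_perp <- b - Vk %*% coef
  if (.norm3(b_perp) > max(tol_rhs, 1e-10 * .norm3(b))) {
    stop("under-constrained equilibrium: applied force has a component with no spring or ligament stiffness (fewer than 3 independent spring directions)")
  }
  as.numeric(Vk %*% (coef / eg$values[keep]))
}

.zero_lig <- list(force = c(0, 0, 0), K = matrix(0, 3, 3))

# Core active-set solve shared by EDEM and DEM.
#   mattress : thresholded, stiffness computed
#   stored   : per-slot push-back forces (length n)
#   u_base   : cumulative talus translation already applied to the geometry
#              (ligaments are evaluated at u_base + u)
.contact_core <- function(mattress, bundles, F_applied, stored, u_base,
                          params) {
  stopifnot(inherits(mattress, "spring_mattress"))
  F_applied <- as.numeric(F_applied)
  stopifnot(length(F_applied) == 3L, all(is.finite(F_applied)))
  Fn <- .norm3(F_applied)
  tol <- params$residual_tol %||% (1e-8 * max(1, Fn))
  nominal <- which(mattress$status == "nominal")
  if (length(nominal) && any(is.na(mattress$stiffness[nominal]))) {
    stop("spring stiffnesses not computed; call compute_stiffnesses() first")
  }
  maxit <- params$max_active_set_iterations %||% max(1L, length(nominal))
  Nmat <- mattress$direction
  have_lig <- !is.null(bundles) && length(bundles) > 0L
  lig_at <- function(u_tot) {
    if (have_lig) ligament_forces(bundles, u_tot) else .zero_lig
  }
  mk_sol <- function(active, released, forces, u, residual, iters) {
    structure(list(active_ids = active, released_ids = released,
                   spring_forces = setNames(forces, active),
                   pressures = setNames(forces / mattress$area[active], active),
                   u_step = u, residual = residual, iterations = iters,
                   n_nominal = length(nominal)),
              class = "contact_solution")
  }

  # Degenerate zero load: nothing stored, ligaments at rest -> zero solution.
  l0 <- lig_at(u_base)
  if (Fn == 0 && (!length(nominal) || all(stored[nominal] == 0)) &&
      .norm3(l0$force) == 0) {
    return(mk_sol(integer(0), integer(0), numeric(0), c(0, 0, 0), c(0, 0, 0), 0L))
  }

  s_nu_E <- poisson_factor(mattress$material$nu) * mattress$material$E_cartilage

  # Newton solve on a fixed active set S, starting from u_start.
  solve_on_set <- function(S, u_start) {
    u <- u_start
    NS <- Nmat[S, , drop = FALSE]
    kS <- mattress$stiffness[S]
    fS <- numeric(length(S))
    r <- c(Inf, Inf, Inf)
    for (newton in 1:100) {
      if (params$stiffness_update == "within_step" && length(S)) {
        h_def <- mattress$length[S] - as.numeric(NS %*% u)
        if (any(h_def <= .length_floor)) {
          stop("deformed gap fell below the length floor during within-step stiffness update")
        }
        kS <- s_nu_E * mattress$area[S] / h_def
      }
      lig <- lig_at(u_base + u)
      if (length(S)) {
        fS <- kS * as.numeric(NS %*% u) + stored[S]
        spring_sum <- colSums(fS * NS)
        Ks <- crossprod(NS * sqrt(kS))
      } else {
        spring_sum <- c(0, 0, 0)
        Ks <- matrix(0, 3, 3)
      }
      r <- F_applied - spring_sum + lig$force
      if (.norm3(r) <= tol) {
        return(list(u = u, f = fS, r = r, ok = TRUE))
      }
      J <- Ks + lig$K
      du <- if (have_lig) {
        # tension-only fibres can all fall slack mid-iteration, leaving J
        # momentarily rank-deficient; a damped step keeps the Newton moving
        # until they re-engage (a genuinely unbalanced load still fails the
        # convergence check below)
        tryCatch(.psolve(J, r, tol_rhs = tol), error = function(e) {
          as.numeric(solve(J + diag(3) * (1e-6 * max(1, max(abs(J)))), r))
        })
      } else {
        .psolve(J, r, tol_rhs = tol)
      }
      u <- u + du
    }
    list(u = u, f = fS, r = r, ok = .norm3(r) <= tol)
  }

  # Lift-off: no spring left; accept if the ligaments alone balance the load.
  liftoff <- function(u_last, released, iters) {
    for (cand in list(u_last, -u_base)) {
      lig <- lig_at(u_base + cand)
      r <- F_applied + lig$force
      if (.norm3(r) <= tol) {
        return(mk_sol(integer(0), released, numeric(0), cand, r, iters))
      }
    }
    if (have_lig) {
      u <- u_last
      for (newton in 1:100) {
        lig <- lig_at(u_base + u)
        r <- F_applied + lig$force
        if (.norm3(r) <= tol) {
          return(mk_sol(integer(0), released, numeric(0), u, r, iters))
        }
        J <- lig$K + diag(3) * (1e-8 * max(1, max(abs(diag(lig$K)))))
        u <- u + solve(J, r)
      }
    }
    stop("lift-off: all springs released and the remaining load is unbalanced")
  }

  S <- nominal
  released <- integer(0)
  u <- c(0, 0, 0)
  iters <- 0L
  repeat {
    iters <- iters + 1L
    if (iters > maxit) {
      stop(sprintf("active-set iteration cap reached (%d)", maxit))
    }
    if (!length(S)) {
      return(liftoff(u, released, iters))
    }
    sol <- solve_on_set(S, u)
    if (!sol$ok) {
      stop(sprintf("equilibrium Newton did not converge (residual %.3e N, tol %.3e N)",
                   .norm3(sol$r), tol))
    }
    u <- sol$u
    tens <- which(sol$f <= 0)
    if (!length(tens)) {
      edem_log("debug", "contact solve: %d active springs, %d iterations, residual %.3e N",
               length(S), iters, .norm3(sol$r))
      return(mk_sol(S, released, sol$f, u, sol$r, iters))
    }
    drop_idx <- if (params$removal_rule == "all_tensile") {
      tens
    } else {
      tens[which.min(sol$f[tens])]
    }
    released <- c(released, S[drop_idx])
    S <- S[-drop_idx]
  }
}

#' @export
print.contact_solution <- function(x, ...) {
  cat(sprintf("<contact_solution> %d/%d springs active, u_step (%.4g, %.4g, %.4g) mm, residual %.3e N, %d iterations\n",
              length(x$active_ids), x$n_nominal,
              x$u_step[1], x$u_step[2], x$u_step[3],
              .norm3(x$residual), x$iterations))
  invisible(x)
}

#' EDEM equilibrium solve (with push-back state)
#'
#' Finds the talus translation increment `u` balancing the applied joint
#' contact force against the spring bed (spring forces
#' `f_i = k_i (n_i . u) + f_prev_i`) and the ligaments evaluated at the
#' cumulative pose. Non-compressed springs (`f_i <= 0`) are released
#' iteratively until only compressed springs remain; the surviving set is the
#' active contact region. The returned state carries `u_cum + u` and the
#' stored push-back forces (active springs keep `f_i`; all others reset to 0).
#'
#' @param mattress a thresholded [spring_mattress] with stiffnesses computed.
#' @param bundles ligament bundles from [make_bundles()], or `NULL` to solve
#'   on springs alone.
#' @param F_applied applied joint contact force (N, length 3), acting on the
#'   talus.
#' @param state a [solver_state()] from the previous time point.
#' @param params a [solver_params()].
#' @return list with `solution` (a `contact_solution`) and `state` (the
#'   updated [solver_state()]).
#' @export
solve_equilibrium_edem <- function(mattress, bundles, F_applied, state,
                                   params = solver_params()) {
  stopifnot(inherits(state, "solver_state"),
            length(state$stored_forces) == mattress$n)
  if (any(state$stored_forces < 0)) stop("stored push-back forces must be >= 0")
  sol <- .contact_core(mattress, bundles, F_applied, state$stored_forces,
                       state$u_cum, params)
  state$u_cum <- state$u_cum + sol$u_step
  state$stored_forces <- numeric(mattress$n)
  state$stored_forces[sol$active_ids] <- as.numeric(sol$spring_forces)
  list(solution = sol, state = state)
}

#' Classical DEM equilibrium solve (stateless)
#'
#' Identical tension-release iteration with all stored forces zero
#' (`f_i = k_i (n_i . u)`); the displacement is relative to the reference
#' position and is not used to move the talus, so no state is produced.
#'
#' @inheritParams solve_equilibrium_edem
#' @return a `contact_solution`.
#' @export
solve_equilibrium_dem <- function(mattress, bundles, F_applied,
                                  params = solver_params()) {
  .contact_core(mattress, bundles, F_applied, numeric(mattress$n),
                c(0, 0, 0), params)
}

#' Per-triangle pressure field and contact summary
#'
#' Contact pressure is the (normal) spring force divided by the supporting
#' triangle area; non-active triangles have pressure 0. Active area is the
#' summed area of the active triangles, reported in cm^2.
#'
#' @param solution a `contact_solution`.
#' @param mattress the [spring_mattress] it was solved on.
#' @return list with `pressure` (MPa per talar triangle), `peak_mpa`,
#'   `active_area_cm2` and `active_ids`.
#' @export
pressure_map <- function(solution, mattress) {
  stopifnot(inherits(solution, "contact_solution"),
            inherits(mattress, "spring_mattress"))
  pressure <- numeric(mattress$n)
  pressure[solution$active_ids] <- as.numeric(solution$spring_forces) /
    mattress$area[solution$active_ids]
  list(pressure = pressure,
       peak_mpa = if (length(solution$active_ids)) max(pressure) else 0,
       active_area_cm2 = sum(mattress$area[solution$active_ids]) / 100,
       active_ids = solution$active_ids)
}

#' Advance the push-back state after an EDEM solve
#'
#' Stores the equilibrium force of every active spring for use at the next
#' time point and resets all other stored forces to zero; `u_cum` has already
#' been updated by [solve_equilibrium_edem()]. All springs become available
#' again for contact when the mattress is recast at the next time point.
#'
#' @param state a [solver_state()] (with `u_cum` already advanced).
#' @param solution the `contact_solution` of the step.
#' @param mattress the [spring_mattress] it was solved on.
#' @return the updated [solver_state()].
#' @export
advance_state <- function(state, solution, mattress) {
  stopifnot(inherits(state, "solver_state"),
            inherits(solution, "contact_solution"))
  state$stored_forces <- numeric(mattress$n)
  state$stored_forces[solution$active_ids] <- as.numeric(solution$spring_forces)
  state
}
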