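# Static equilibrium solve and moment-schedule sweep.

#' Load schedule of external moments
#'
#' @param moments ordered numeric vector of external moments, Nm. Must
#'   include 0. Default: -5 to +5 Nm in 11 equal 1 Nm steps. Negative moments
#'   drive dorsiflexion, positive moments plantarflexion.
#' @return an object of class `load_schedule`.
#' @export
load_schedule <- function(moments = seq(-5, 5, by = 1)) {
  stopifnot(is.numeric(moments), length(moments) >= 1, all(is.finite(moments)))
  if (!any(moments == 0)) {
    stop("load schedule must include the zero-load step", call. = FALSE)
  }
  if (anyDuplicated(moments)) {
    stop("load schedule has duplicated moments", call. = FALSE)
  }
  structure(list(moments = as.numeric(moments)), class = "load_schedule")
}

#' Solve one static equilibrium
#'
#' Finds the moving-body pose balancing the ligament, contact and external
#' loads by minimising the scaled residual in least squares with the
#' Levenberg-Marquardt algorithm ([minpack.lm::nls.lm()]). A solve is accepted
#' as converged only if the sum of absolute scaled residuals falls below
#' 1e-10; the final pose is returned either way.
#'
#' @param model a [joint_model()].
#' @param M_ext external moment, Nm.
#' @param initial_pose starting [pose2d()]; defaults to the model's reference
#'   pose.
#' @param control a [minpack.lm::nls.lm.control()] list. The defaults tighten
#'   the step and objective tolerances to machine precision so the solver can
#'   actually reach the 1e-10 acceptance condition.
#' @param engine `"cpp"` (compiled Levenberg-Marquardt fast path, default) or
#'   `"minpack"` (reference path through [minpack.lm::nls.lm()]).
#' @return list of class `equilibrium_state` with `pose`, `residual`
#'   (length 3), `residual_sum` and `converged`.
#' @export
solve_equilibrium <- function(model, M_ext, initial_pose = model$reference_pose,
                              control = solver_control(),
                              engine = c("cpp", "minpack")) {
  stopifnot(inherits(model, "joint_model"), inherits(initial_pose, "pose2d"))
  engine <- match.arg(engine)
  cache <- model$cache
  m_nmm <- M_ext * 1000
  par0 <- c(initial_pose$tx, initial_pose$ty, initial_pose$theta)

  r0 <- .residual_par(par0, cache, m_nmm)
  if (sum(abs(r0)) < RESIDUAL_TOL) {
    # already balanced (e.g. the zero-load reference configuration)
    return(structure(list(pose = initial_pose, residual = r0,
                          residual_sum = sum(abs(r0)), converged = TRUE),
                     class = "equilibrium_state"))
  }

  if (engine == "cpp") {
    sol <- .cpp_solve(cache, M_ext, par0, RESIDUAL_TOL, control$maxiter)
    par <- sol$par
    r <- .residual_par(par, cache, m_nmm)
    return(structure(list(pose = pose2d(par[1], par[2], par[3]),
                          residual = r, residual_sum = sum(abs(r)),
                          converged = isTRUE(sol$converged)),
                     class = "equilibrium_state"))
  }

  attempt <- function(par) {
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = par,
                           fn = function(p) .residual_par(p, cache, m_nmm),
                           control = control)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    par <- unname(fit$par)
    r <- .residual_par(par, cache, m_nmm)
    list(par = par, residual = r, rs = sum(abs(r)))
  }

  best <- list(par = par0, residual = r0, rs = sum(abs(r0)))
  # Attempt schedule: the warm start itself, a restart from its final
  # iterate (resets the LM damping), then restarts with the body rotated in
  # the direction of the unbalanced torque. The rotational nudges step the
  # iterate across any free-play arc in which every cable is slack and the
  # torque gradient vanishes, a configuration in which Levenberg-Marquardt
  # stalls on a flat residual.
  res <- attempt(par0)
  if (!is.null(res)) {
    if (res$rs < best$rs) best <- res
    if (res$rs >= RESIDUAL_TOL) {
      polish <- attempt(res$par)
      if (!is.null(polish) && polish$rs < best$rs) best <- polish
    }
  }
  if (best$rs >= RESIDUAL_TOL) {
    for (dth in c(0.035, 0.09, 0.18)) {
      nudge <- best$par + c(0, 0, sign(best$residual[3]) * dth)
      res <- attempt(nudge)
      if (!is.null(res) && res$rs < best$rs) best <- res
      if (best$rs < RESIDUAL_TOL) break
    }
  }
  structure(list(pose = pose2d(best$par[1], best$par[2], best$par[3]),
                 residual = best$residual, residual_sum = best$rs,
                 converged = best$rs < RESIDUAL_TOL),
            class = "equilibrium_state")
}

#' Levenberg-Marquardt control settings for the equilibrium solve
#'
#' @param maxiter iteration budget per solve.
#' @param ... further arguments to [minpack.lm::nls.lm.control()].
#' @return a control list.
#' @export
solver_control <- function(maxiter = 200, ...) {
  minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15, gtol = 0,
                             maxiter = maxiter, maxfev = 100 * (maxiter + 1), ...)
}

# Continuation solve: try the target moment directly from the warm-start
# pose; on failure bisect the load increment (up to `depth` levels) so the
# solver never has to jump across the slack-to-taut and contact-onset kinks
# in one step. Returns the equilibrium state at M_to.
.continuation_solve <- function(model, M_from, M_to, pose, control,
                                engine = "minpack", depth = 5) {
  st <- solve_equilibrium(model, M_to, pose, control, engine)
  if (st$converged || depth <= 0) {
    return(st)
  }
  mid <- (M_from + M_to) / 2
  st_mid <- .continuation_solve(model, M_from, mid, pose, control, engine,
                                depth - 1)
  .continuation_solve(model, mid, M_to, st_mid$pose, control, engine,
                      depth - 1)
}

#' Sweep a model over a schedule of external moments
#'
#' Solves the zero-load equilibrium first, starting from the reference pose,
#' then marches outward towards the positive and negative schedule extremes,
#' warm-starting every solve from the previous step's pose. If a step fails
#' the residual acceptance, the load increment is bisected adaptively (a
#' continuation strategy) before the step is declared failed. Angular
#' displacements are reported in degrees relative to the zero-load
#' equilibrium angle, so the displacement at 0 Nm is 0 by definition. A step
#' whose solve fails still contributes its pose as a warm start but
#' increments `not_passed`.
#'
#' @param model a [joint_model()].
#' @param schedule a [load_schedule()] (must include 0 Nm).
#' @param control solver control, see [solver_control()].
#' @param engine `"cpp"` (compiled fast path, default) or `"minpack"`
#'   (reference path through [minpack.lm::nls.lm()]); the two are
#'   cross-checked in the test suite.
#' @return an object of class `sweep_result`: list with `moments` (Nm,
#'   schedule order), `dtheta_deg`, `element_forces` (steps x 7 matrix:
#'   six ligaments then the contact pair, N), `converged` (logical) and
#'   `not_passed` (count of failed steps).
#' @export
sweep_loads <- function(model, schedule = load_schedule(),
                        control = solver_control(),
                        engine = c("cpp", "minpack")) {
  stopifnot(inherits(model, "joint_model"), inherits(schedule, "load_schedule"))
  engine <- match.arg(engine)
  moments <- schedule$moments
  n <- length(moments)
  ord <- order(moments)
  sorted <- moments[ord]
  i0 <- which(sorted == 0)

  if (engine == "cpp") {
    rp <- model$reference_pose
    sw <- .cpp_sweep(model$cache, sorted, i0, RESIDUAL_TOL, control$maxiter,
                     c(rp$tx, rp$ty, rp$theta))
    poses <- lapply(seq_len(n), function(i) {
      pose2d(sw$tx[i], sw$ty[i], sw$theta[i])
    })
    conv <- sw$converged
    theta <- sw$theta
    forces <- sw$forces
    colnames(forces) <- c(LIGAMENT_NAMES, "contact")
  } else {
    poses <- vector("list", n)
    conv <- logical(n)
    theta <- numeric(n)

    march <- function(indices, start_pose) {
      pose <- start_pose
      m_prev <- 0
      for (i in indices) {
        st <- .continuation_solve(model, m_prev, sorted[i], pose, control,
                                  engine)
        poses[[i]] <<- st$pose
        conv[i] <<- st$converged
        theta[i] <<- st$pose$theta
        pose <- st$pose
        m_prev <- sorted[i]
      }
    }
    st0 <- solve_equilibrium(model, 0, model$reference_pose, control, engine)
    poses[[i0]] <- st0$pose
    conv[i0] <- st0$converged
    theta[i0] <- st0$pose$theta
    if (i0 < n) march(seq(i0 + 1, n), st0$pose)
    if (i0 > 1) march(seq(i0 - 1, 1), st0$pose)

    forces <- matrix(NA_real_, n, 7,
                     dimnames = list(NULL, c(LIGAMENT_NAMES, "contact")))
    for (i in seq_len(n)) {
      p <- poses[[i]]
      for (j in 1:6) {
        forces[i, j] <- ligament_wrench(p, model$ligaments[[j]],
                                        model$reference_length[j])$magnitude
      }
      forces[i, 7] <- contact_wrench(p, model$contact)$magnitude
    }
  }

  dtheta <- (theta - theta[i0]) * 180 / pi
  back <- order(ord)  # restore the caller's schedule order
  structure(list(moments = moments,
                 dtheta_deg = dtheta[back],
                 element_forces = forces[back, , drop = FALSE],
                 converged = conv[back],
                 poses = poses[back],
                 not_passed = sum(!conv)),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d load steps, not_passed = %d\n",
              length(x$moments), x$not_passed))
  print(utils::head(as.data.frame(x), n = length(x$moments)))
  invisible(x)
}

#' Convert a sweep result to a data frame
#'
#' Columns follow the sweep CSV contract: `M_ext_Nm`, `dtheta_deg`, one force
#' column per ligament (`F_ATT_N`, ..., `F_PTF_N`), `F_contact_N`,
#' `converged`.
#'
#' @param x a `sweep_result`.
#' @param ... unused.
#' @export
as.data.frame.sweep_result <- function(x, ...) {
  df <- data.frame(M_ext_Nm = x$moments,
                   dtheta_deg = x$dtheta_deg)
  for (j in 1:6) {
    df[[paste0("F_", LIGAMENT_NAMES[j], "_N")]] <- x$element_forces[, j]
  }
  df$F_contact_N <- x$element_forces[, 7]
  df$converged <- x$converged
  df
}

#' Write a sweep result to CSV
#'
#' @param x a `sweep_result`.
#' @param path output file path.
#' @export
write_sweep_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
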