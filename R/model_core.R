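# Planar ligamentous joint model: rigid moving body (talus/calcaneus) against a
# fixed body (tibia/fibula), connected by six tension-only exponential cables
# (the ankle ligaments) and one conforming Hertzian sphere-sphere contact pair
# (the cartilage). Geometry is in mm, forces in N, external moments in Nm.

LIGAMENT_NAMES <- c("ATT", "TC", "PTT", "ATF", "CF", "PTF")

# Moment residuals (N*mm) are divided by this characteristic length (mm) so the
# three equilibrium residual components are commensurate; the 1e-10 convergence
# acceptance applies to the sum of absolute residuals in these scaled units.
MOMENT_SCALE_MM <- 10

RESIDUAL_TOL <- 1e-10

#' Planar pose of the moving body
#'
#' The moving body's configuration is a planar rigid transform: two
#' translations of the body frame origin (mm) and one rotation (rad). The
#' rotation is stored unwrapped, so angular displacement differences between
#' two poses are always well defined.
#'
#' @param tx,ty translation of the moving-body frame origin, mm.
#' @param theta rotation of the moving-body frame, rad (positive =
#'   plantarflexion under the sign convention used throughout).
#' @return an object of class `pose2d`.
#' @export
pose2d <- function(tx = 0, ty = 0, theta = 0) {
  stopifnot(is.numeric(tx), is.numeric(ty), is.numeric(theta),
            length(tx) == 1, length(ty) == 1, length(theta) == 1,
            is.finite(tx), is.finite(ty), is.finite(theta))
  structure(list(tx = tx, ty = ty, theta = theta), class = "pose2d")
}

#' @export
print.pose2d <- function(x, ...) {
  cat(sprintf("<pose2d> tx = %.4f mm, ty = %.4f mm, theta = %.6f rad (%.3f deg)\n",
              x$tx, x$ty, x$theta, x$theta * 180 / pi))
  invisible(x)
}

#' Apply a planar rigid transform to a point
#'
#' Rotates `p_local` by `pose$theta` and then translates by `(tx, ty)`.
#'
#' @param pose a [pose2d()].
#' @param p_local numeric length-2 point in the moving-body frame, mm.
#' @return numeric length-2 point in the global (fixed-body) frame, mm.
#' @export
transform_point <- function(pose, p_local) {
  stopifnot(inherits(pose, "pose2d"), is.numeric(p_local), length(p_local) == 2)
  ct <- cos(pose$theta)
  st <- sin(pose$theta)
  c(ct * p_local[1] - st * p_local[2] + pose$tx,
    st * p_local[1] + ct * p_local[2] + pose$ty)
}

#' Ligament cable specification
#'
#' One ankle ligament modelled as a tension-only cable with the two-parameter
#' exponential force law F = a (exp(b * strain) - 1) for positive strain and 0
#' otherwise. The slack reference length is not a free parameter: it is the
#' attachment distance at the owning model's reference pose, recomputed
#' whenever a model is built, so geometric perturbations change both the line
#' of action and the slack length.
#'
#' @param name one of `"ATT"`, `"TC"`, `"PTT"`, `"ATF"`, `"CF"`, `"PTF"`.
#' @param attach_moving length-2 attachment point in the moving-body frame, mm.
#' @param attach_fixed length-2 attachment point in the fixed-body (global)
#'   frame, mm.
#' @param stiffness_coeff exponential amplitude a, N. Must be positive.
#' @param shape_coeff exponential rate b, dimensionless. Must be positive.
#' @return an object of class `ligament_spec`.
#' @export
ligament_spec <- function(name, attach_moving, attach_fixed,
                          stiffness_coeff, shape_coeff) {
  if (!name %in% LIGAMENT_NAMES) {
    stop("unknown ligament name: ", name, call. = FALSE)
  }
  stopifnot(is.numeric(attach_moving), length(attach_moving) == 2,
            is.numeric(attach_fixed), length(attach_fixed) == 2)
  if (!is.finite(stiffness_coeff) || stiffness_coeff <= 0) {
    stop("stiffness_coeff must be positive", call. = FALSE)
  }
  if (!is.finite(shape_coeff) || shape_coeff <= 0) {
    stop("shape_coeff must be positive", call. = FALSE)
  }
  structure(
    list(name = name,
         attach_moving = as.numeric(attach_moving),
         attach_fixed = as.numeric(attach_fixed),
         stiffness_coeff = stiffness_coeff,
         shape_coeff = shape_coeff),
    class = "ligament_spec")
}

#' Conforming sphere-sphere contact pair specification
#'
#' The cartilage layer is modelled as one conforming (internal) Hertzian
#' contact pair: an inner sphere (talar dome) fixed to the moving body inside
#' an outer spherical socket on the fixed body, with outer radius
#' `radius_inner + clearance`. Contact engages when the centre-to-centre
#' distance exceeds the clearance. Both surfaces share one Young's modulus and
#' Poisson's ratio. The clearance is a fixed configuration constant, not one
#' of the free model parameters.
#'
#' @param center_moving inner-sphere centre in the moving frame, mm.
#' @param center_fixed outer-sphere centre in the global frame, mm.
#' @param radius_inner inner sphere radius, mm (> 0).
#' @param youngs_modulus cartilage Young's modulus, MPa (> 0).
#' @param poissons_ratio Poisson's ratio, in (0, 0.5).
#' @param clearance radial clearance between the spheres, mm (> 0,
#'   default 0.5).
#' @param mode `"internal"` (conforming, default) or `"external"` contact.
#' @return an object of class `contact_spec`.
#' @export
contact_spec <- function(center_moving, center_fixed, radius_inner,
                         youngs_modulus, poissons_ratio,
                         clearance = 0.5, mode = c("internal", "external")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(center_moving), length(center_moving) == 2,
            is.numeric(center_fixed), length(center_fixed) == 2)
  if (!is.finite(radius_inner) || radius_inner <= 0) {
    stop("radius_inner must be positive", call. = FALSE)
  }
  if (!is.finite(youngs_modulus) || youngs_modulus <= 0) {
    stop("youngs_modulus must be positive", call. = FALSE)
  }
  if (!is.finite(poissons_ratio) || poissons_ratio <= 0 || poissons_ratio >= 0.5) {
    stop("poissons_ratio must lie in (0, 0.5)", call. = FALSE)
  }
  if (!is.finite(clearance) || clearance <= 0) {
    stop("clearance must be positive", call. = FALSE)
  }
  structure(
    list(center_moving = as.numeric(center_moving),
         center_fixed = as.numeric(center_fixed),
         radius_inner = radius_inner,
         youngs_modulus = youngs_modulus,
         poissons_ratio = poissons_ratio,
         clearance = clearance,
         mode = mode),
    class = "contact_spec")
}

# Hertz stiffness constant K such that F = K * depth^(3/2), in N and mm.
# E* combines the two identical surfaces: 1/E* = 2 (1 - nu^2) / E.
hertz_constant <- function(contact) {
  e_star <- contact$youngs_modulus / (2 * (1 - contact$poissons_ratio^2))
  r_in <- contact$radius_inner
  r_out <- r_in + contact$clearance
  r_eff <- if (contact$mode == "internal") {
    r_in * r_out / (r_out - r_in)
  } else {
    r_in * r_out / (r_out + r_in)
  }
  (4 / 3) * e_star * sqrt(r_eff)
}

#' Assemble a planar joint model
#'
#' Combines six ligament cables, one contact pair and a reference pose into a
#' solvable joint model. The slack reference length of every ligament is
#' computed here as the attachment distance at `reference_pose`. The model's
#' free parameters flatten to a canonical 43-element vector (see
#' [flatten_model()]).
#'
#' @param ligaments list of 6 [ligament_spec()] objects, one per ligament name
#'   in the order ATT, TC, PTT, ATF, CF, PTF.
#' @param contact a [contact_spec()].
#' @param reference_pose the pose at which all ligaments are exactly slack;
#'   default identity.
#' @return an object of class `joint_model`.
#' @export
joint_model <- function(ligaments, contact, reference_pose = pose2d()) {
  stopifnot(is.list(ligaments), length(ligaments) == 6,
            inherits(contact, "contact_spec"),
            inherits(reference_pose, "pose2d"))
  nm <- vapply(ligaments, function(l) l$name, character(1))
  if (!identical(nm, LIGAMENT_NAMES)) {
    stop("ligaments must be given in the order ",
         paste(LIGAMENT_NAMES, collapse = ", "), call. = FALSE)
  }
  names(ligaments) <- nm
  ref_len <- vapply(ligaments, function(l) {
    g <- transform_point(reference_pose, l$attach_moving)
    sqrt(sum((l$attach_fixed - g)^2))
  }, numeric(1))
  if (any(ref_len < 1e-9)) {
    stop("singular geometry: coincident ligament attachment points (",
         paste(nm[ref_len < 1e-9], collapse = ", "), ")", call. = FALSE)
  }
  m <- structure(
    list(ligaments = ligaments,
         contact = contact,
         reference_pose = reference_pose,
         reference_length = ref_len),
    class = "joint_model")
  m$cache <- .model_cache(m)
  m
}

# Precomputed vectorised views of the model shared by the R and C++ residual
# evaluations.
.model_cache <- function(model) {
  lig <- model$ligaments
  ct <- model$contact
  list(
    mx = vapply(lig, function(l) l$attach_moving[1], numeric(1)),
    my = vapply(lig, function(l) l$attach_moving[2], numeric(1)),
    fx = vapply(lig, function(l) l$attach_fixed[1], numeric(1)),
    fy = vapply(lig, function(l) l$attach_fixed[2], numeric(1)),
    a = vapply(lig, function(l) l$stiffness_coeff, numeric(1)),
    b = vapply(lig, function(l) l$shape_coeff, numeric(1)),
    L0 = unname(model$reference_length),
    center_moving = ct$center_moving,
    center_fixed = ct$center_fixed,
    clearance = ct$clearance,
    internal_mode = as.integer(ct$mode == "internal"),
    K = hertz_constant(ct))
}

#' @export
print.joint_model <- function(x, ...) {
  cat("<joint_model> planar ankle: 6 exponential cables + 1 Hertzian contact pair\n")
  cat(sprintf("  reference lengths (mm): %s\n",
              paste(sprintf("%s=%.2f", LIGAMENT_NAMES, x$reference_length),
                    collapse = " ")))
  cat(sprintf("  contact: R_in = %.2f mm, clearance = %.2f mm, E = %.2f MPa, nu = %.3f\n",
              x$contact$radius_inner, x$contact$clearance,
              x$contact$youngs_modulus, x$contact$poissons_ratio))
  invisible(x)
}

#' Tension-only exponential ligament force law
#'
#' F = a (exp(b * strain) - 1) for positive strain; a slack cable (strain <= 0)
#' carries no load.
#'
#' @param strain engineering strain, dimensionless.
#' @param stiffness_coeff amplitude a, N (> 0).
#' @param shape_coeff rate b, dimensionless (> 0).
#' @return force magnitude, N (vectorised over `strain`).
#' @export
ligament_force_magnitude <- function(strain, stiffness_coeff, shape_coeff) {
  if (!is.finite(stiffness_coeff) || stiffness_coeff <= 0 ||
      !is.finite(shape_coeff) || shape_coeff <= 0) {
    stop("ligament coefficients must be positive", call. = FALSE)
  }
  ifelse(strain > 0, stiffness_coeff * (exp(shape_coeff * strain) - 1), 0)
}

#' Hertzian point-contact force law
#'
#' F = (4/3) E* sqrt(R_eff) depth^(3/2) for positive penetration depth, with
#' 1/E* = 2 (1 - nu^2) / E (both surfaces share E and nu); zero for separated
#' surfaces.
#'
#' @param depth penetration depth, mm.
#' @param E Young's modulus, MPa.
#' @param nu Poisson's ratio, in (0, 0.5).
#' @param R_eff effective contact radius, mm.
#' @return force, N (vectorised over `depth`).
#' @export
hertz_force_magnitude <- function(depth, E, nu, R_eff) {
  if (!is.finite(E) || E <= 0 || !is.finite(nu) || nu <= 0 || nu >= 0.5 ||
      !is.finite(R_eff) || R_eff <= 0) {
    stop("invalid Hertz material or geometry parameters", call. = FALSE)
  }
  e_star <- E / (2 * (1 - nu^2))
  ifelse(depth > 0, (4 / 3) * e_star * sqrt(R_eff) * depth^1.5, 0)
}

#' Contact penetration depth
#'
#' Distance between the two sphere centres in the global frame minus the
#' radial clearance (internal conforming contact); positive means the contact
#' is engaged.
#'
#' @param pose moving-body [pose2d()].
#' @param contact a [contact_spec()].
#' @return penetration depth, mm.
#' @export
contact_penetration <- function(pose, contact) {
  cm <- transform_point(pose, contact$center_moving)
  d <- sqrt(sum((cm - contact$center_fixed)^2))
  if (contact$mode == "internal") d - contact$clearance else -d
}

#' Wrench exerted by one ligament on the moving body
#'
#' The cable force acts along the line from the moving attachment (in the
#' global frame) towards the fixed attachment; the moment is taken about the
#' moving body's frame origin. A slack cable exerts a zero wrench. Strain is
#' (current length - reference length) / reference length.
#'
#' @param pose moving-body [pose2d()].
#' @param lig a [ligament_spec()].
#' @param reference_length slack length L0, mm (> 0).
#' @return list with `force` (N, length-2 global vector), `moment` (N*mm,
#'   about the moving origin), `length` (mm), `strain`, and `magnitude` (N).
#' @export
ligament_wrench <- function(pose, lig, reference_length) {
  stopifnot(reference_length > 0)
  gm <- transform_point(pose, lig$attach_moving)
  dvec <- lig$attach_fixed - gm
  len <- sqrt(sum(dvec^2))
  if (len < 1e-9) {
    stop("singular geometry: ligament ", lig$name,
         " has coincident attachment points", call. = FALSE)
  }
  strain <- (len - reference_length) / reference_length
  fmag <- ligament_force_magnitude(strain, lig$stiffness_coeff, lig$shape_coeff)
  force <- fmag * dvec / len
  r <- gm - c(pose$tx, pose$ty)
  list(force = force,
       moment = r[1] * force[2] - r[2] * force[1],
       length = len, strain = strain, magnitude = fmag)
}

#' Wrench exerted by the contact pair on the moving body
#'
#' For the conforming internal pair the restoring force pushes the moving
#' centre back towards the fixed centre once the centre distance exceeds the
#' clearance.
#'
#' @inheritParams contact_penetration
#' @return list with `force` (N, global), `moment` (N*mm about the moving
#'   origin), `depth` (mm) and `magnitude` (N).
#' @export
contact_wrench <- function(pose, contact) {
  cm <- transform_point(pose, contact$center_moving)
  dvec <- cm - contact$center_fixed
  d <- sqrt(sum(dvec^2))
  depth <- if (contact$mode == "internal") d - contact$clearance else -d
  if (depth <= 0 || d < 1e-12) {
    return(list(force = c(0, 0), moment = 0, depth = depth, magnitude = 0))
  }
  fmag <- hertz_constant(contact) * depth^1.5
  force <- -fmag * dvec / d
  r <- cm - c(pose$tx, pose$ty)
  list(force = force,
       moment = r[1] * force[2] - r[2] * force[1],
       depth = depth, magnitude = fmag)
}

# Fast vectorised residual working on par = c(tx, ty, theta) and the model
# cache. Returns c(Fx [N], Fy [N], Mz [N*mm] / MOMENT_SCALE_MM).
.residual_par <- function(par, cache, M_ext_Nmm) {
  ct <- cos(par[3]); st <- sin(par[3])
  gmx <- ct * cache$mx - st * cache$my + par[1]
  gmy <- st * cache$mx + ct * cache$my + par[2]
  dx <- cache$fx - gmx
  dy <- cache$fy - gmy
  len <- sqrt(dx^2 + dy^2)
  if (any(len < 1e-9)) {
    stop("singular geometry: coincident ligament attachment points",
         call. = FALSE)
  }
  strain <- (len - cache$L0) / cache$L0
  fmag <- ifelse(strain > 0, cache$a * (exp(cache$b * strain) - 1), 0)
  fx <- fmag * dx / len
  fy <- fmag * dy / len
  mz <- (gmx - par[1]) * fy - (gmy - par[2]) * fx

  cmx <- ct * cache$center_moving[1] - st * cache$center_moving[2] + par[1]
  cmy <- st * cache$center_moving[1] + ct * cache$center_moving[2] + par[2]
  ddx <- cmx - cache$center_fixed[1]
  ddy <- cmy - cache$center_fixed[2]
  d <- sqrt(ddx^2 + ddy^2)
  depth <- if (cache$internal_mode == 1L) d - cache$clearance else -d
  if (depth > 0 && d > 1e-12) {
    fc <- cache$K * depth^1.5
    fcx <- -fc * ddx / d
    fcy <- -fc * ddy / d
    mc <- (cmx - par[1]) * fcy - (cmy - par[2]) * fcx
  } else {
    fcx <- 0; fcy <- 0; mc <- 0
  }
  c(sum(fx) + fcx,
    sum(fy) + fcy,
    (sum(mz) + mc + M_ext_Nmm) / MOMENT_SCALE_MM)
}

#' Static equilibrium residual
#'
#' Sums the wrenches of all six ligaments and the contact pair on the moving
#' body together with the external moment, and returns the unbalanced net
#' load. Force residuals are in N; the moment residual (N*mm) is divided by a
#' characteristic length of 10 mm so that all three components share a common
#' force-equivalent magnitude, which is the scale on which the 1e-10 solver
#' acceptance condition operates.
#'
#' @param pose moving-body [pose2d()].
#' @param model a [joint_model()].
#' @param M_ext external moment, Nm (positive = plantarflexion).
#' @return numeric length-3 residual `(Fx, Fy, Mz_scaled)`.
#' @export
residual <- function(pose, model, M_ext) {
  stopifnot(inherits(pose, "pose2d"), inherits(model, "joint_model"))
  .residual_par(c(pose$tx, pose$ty, pose$theta), model$cache, M_ext * 1000)
}

#' Total elastic potential energy of the joint
#'
#' Strain energy stored in the stretched cables plus the Hertzian contact
#' energy, minus the work of the external moment. For the exponential cable
#' the closed-form energy is a (L0/b) (exp(b eps) - 1) - a (L - L0) for
#' positive strain and 0 otherwise; the contact contributes
#' (2/5) K depth^(5/2). Units: N*mm (millijoules). The scaled equilibrium
#' residual is the negative gradient of this function with respect to
#' (tx, ty, theta) (moment component divided by the 10 mm characteristic
#' length), which the test suite verifies by central finite differences.
#'
#' @inheritParams residual
#' @return scalar energy, N*mm.
#' @export
potential_energy <- function(pose, model, M_ext) {
  u <- 0
  for (i in seq_along(model$ligaments)) {
    l <- model$ligaments[[i]]
    L0 <- unname(model$reference_length[i])
    gm <- transform_point(pose, l$attach_moving)
    len <- sqrt(sum((l$attach_fixed - gm)^2))
    eps <- (len - L0) / L0
    if (eps > 0) {
      a <- l$stiffness_coeff; b <- l$shape_coeff
      u <- u + a * (L0 / b) * (exp(b * eps) - 1) - a * (len - L0)
    }
  }
  depth <- contact_penetration(pose, model$contact)
  if (depth > 0) {
    u <- u + (2 / 5) * hertz_constant(model$contact) * depth^2.5
  }
  u - M_ext * 1000 * pose$theta
}
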