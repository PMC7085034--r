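# Shared helpers: small factories and independent numerical oracles.

# Central finite-difference gradient of a scalar function of a pose.
fd_pose_gradient <- function(f, pose, h = 1e-6) {
  p0 <- c(pose$tx, pose$ty, pose$theta)
  vapply(1:3, function(j) {
    hp <- p0; hm <- p0
    hp[j] <- hp[j] + h
    hm[j] <- hm[j] - h
    (f(pose2d(hp[1], hp[2], hp[3])) - f(pose2d(hm[1], hm[2], hm[3]))) / (2 * h)
  }, numeric(1))
}

# Cable strain energy by numerical quadrature of the force law over length:
# independent of the closed-form energy used in the package.
cable_energy_quadrature <- function(len, L0, a, b) {
  if (len <= L0) return(0)
  stats::integrate(function(l) {
    ligament_force_magnitude((l - L0) / L0, a, b)
  }, lower = L0, upper = len, rel.tol = 1e-12)$value
}

# A hand-made sweep_result for statistics tests (no solver involved).
toy_sweep <- function(moments, dtheta, forces = NULL) {
  n <- length(moments)
  if (is.null(forces)) {
    forces <- matrix(0, n, 7)
  }
  colnames(forces) <- c("ATT", "TC", "PTT", "ATF", "CF", "PTF", "contact")
  structure(list(moments = moments, dtheta_deg = dtheta,
                 element_forces = forces,
                 converged = rep(TRUE, n), poses = NULL, not_passed = 0L),
            class = "sweep_result")
}

# 86-element decision vector holding two copies of a model.
duplicate_dv <- function(model) {
  rep(unname(flatten_model(model)), 2)
}

# A 43-vector with singular (coincident) ATT attachments: building it must
# fail, which the objective scores as all steps not passed.
degenerate_params <- function(model) {
  v <- unname(flatten_model(model))
  v[3:4] <- v[1:2]  # ATT fixed attachment == moving attachment
  v
}
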