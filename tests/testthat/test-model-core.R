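test_that("transform_point applies rotation then translation", {
  expect_equal(transform_point(pose2d(), c(3, 4)), c(3, 4))
  expect_equal(transform_point(pose2d(0, 0, pi / 2), c(1, 0)), c(0, 1))
  # hand evaluation: R(pi) (1,1) = (-1,-1); plus (1,2) = (0,1)
  expect_equal(transform_point(pose2d(1, 2, pi), c(1, 1)), c(0, 1))
})

test_that("exponential cable law is tension-only and matches the closed form", {
  expect_identical(ligament_force_magnitude(-0.05, 10, 20), 0)
  expect_identical(ligament_force_magnitude(0, 10, 20), 0)
  expect_equal(ligament_force_magnitude(0.1, 10, 20), 10 * (exp(2) - 1),
               tolerance = 1e-12)
  expect_error(ligament_force_magnitude(0.1, -1, 20), "positive")
  expect_error(ligament_force_magnitude(0.1, 10, 0), "positive")
})

test_that("Hertz law vanishes at separation and follows the 3/2 power", {
  expect_identical(hertz_force_magnitude(-0.1, 10, 0.4, 100), 0)
  expect_identical(hertz_force_magnitude(0, 10, 0.4, 100), 0)
  f1 <- hertz_force_magnitude(0.1, 10, 0.4, 100)
  f2 <- hertz_force_magnitude(0.2, 10, 0.4, 100)
  expect_equal(f2 / f1, 2^1.5, tolerance = 1e-12)
  # closed form: E* = 10 / (2 (1 - 0.4^2)), F = 4/3 E* sqrt(100) 0.1^1.5
  expect_equal(f1, 2.5097442, tolerance = 1e-6)
  expect_error(hertz_force_magnitude(0.1, 10, 0.6, 100), "invalid")
})

test_that("contact penetration is centre distance minus clearance", {
  ct <- contact_spec(c(0, 0), c(0, 0), 20, 10, 0.4, clearance = 0.5)
  expect_equal(contact_penetration(pose2d(), ct), -0.5)
  expect_equal(contact_penetration(pose2d(0, 0.5, 0), ct), 0)
  expect_equal(contact_penetration(pose2d(0.7, 0, 0), ct), 0.2)
})

test_that("ligament wrench is zero at the reference and matches the energy gradient", {
  lig <- ligament_spec("ATT", c(20, -8), c(15, 10), 10, 15)
  L0 <- sqrt(sum((c(15, 10) - c(20, -8))^2))
  w0 <- ligament_wrench(pose2d(), lig, L0)
  expect_equal(w0$force, c(0, 0))
  expect_equal(w0$moment, 0)
  expect_equal(w0$strain, 0)

  # stretched cable: wrench = -gradient of the cable's strain energy, with
  # the energy obtained by numerical quadrature of the force law
  pose <- pose2d(1.5, -2.0, -0.3)
  w <- ligament_wrench(pose, lig, L0)
  energy <- function(p) {
    g <- transform_point(p, lig$attach_moving)
    cable_energy_quadrature(sqrt(sum((lig$attach_fixed - g)^2)), L0, 10, 15)
  }
  g <- fd_pose_gradient(energy, pose)
  expect_gt(w$magnitude, 0)
  expect_equal(w$force, -g[1:2], tolerance = 1e-5)
  expect_equal(w$moment, -g[3], tolerance = 1e-5)
})

test_that("attachment on the line of action through the origin gives zero moment", {
  # both attachments on the x axis: force along x, lever arm zero
  lig <- ligament_spec("TC", c(10, 0), c(40, 0), 5, 10)
  w <- ligament_wrench(pose2d(5, 0, 0), lig, 20)  # stretched to length 25
  expect_gt(w$magnitude, 0)
  expect_equal(w$moment, 0, tolerance = 1e-12)
})

test_that("wrench reports singular geometry for coincident attachments", {
  lig <- ligament_spec("CF", c(3, 4), c(3, 4), 5, 10)
  expect_error(ligament_wrench(pose2d(), lig, 10), "singular")
})

test_that("residual is exactly zero with all elements slack and no load", {
  m <- default_ankle_fixture()
  expect_identical(residual(m$reference_pose, m, 0), c(0, 0, 0))
})

test_that("residual equals minus the scaled potential-energy gradient", {
  m <- default_ankle_fixture()
  set.seed(7)
  for (k in 1:20) {
    pose <- pose2d(runif(1, -1.5, 1.5), runif(1, -1.5, 1.5),
                   runif(1, -0.6, 0.6))
    M_ext <- runif(1, -5, 5)
    r <- residual(pose, m, M_ext)
    g <- fd_pose_gradient(function(p) potential_energy(p, m, M_ext), pose)
    expected <- -c(g[1], g[2], g[3] / 10)
    expect_equal(r, expected, tolerance = 1e-6)
  }
})

test_that("package energy matches the quadrature oracle for the cable terms", {
  m <- default_ankle_fixture()
  pose <- pose2d(0.3, -0.8, 0.4)
  u_quad <- 0
  for (i in 1:6) {
    l <- m$ligaments[[i]]
    g <- transform_point(pose, l$attach_moving)
    u_quad <- u_quad + cable_energy_quadrature(
      sqrt(sum((l$attach_fixed - g)^2)), m$reference_length[i],
      l$stiffness_coeff, l$shape_coeff)
  }
  depth <- contact_penetration(pose, m$contact)
  if (depth > 0) {
    k_h <- hertz_force_magnitude(1, m$contact$youngs_modulus,
                                 m$contact$poissons_ratio,
                                 20 * 20.5 / 0.5)
    u_quad <- u_quad + (2 / 5) * k_h * depth^2.5
  }
  expect_equal(potential_energy(pose, m, 0), u_quad, tolerance = 1e-8)
})

test_that("model parameter flattening is a 43-element bijection", {
  m <- default_ankle_fixture()
  v <- flatten_model(m)
  expect_length(v, 43)
  expect_identical(names(v), parameter_names())
  m2 <- unflatten_model(v, m)
  expect_equal(flatten_model(m2), v)
  expect_equal(m2$reference_length, m$reference_length)

  set.seed(3)
  jit <- unname(v)
  geo <- geometry_mask()
  jit[geo] <- jit[geo] + runif(29, -0.5, 0.5)
  jit[!geo] <- jit[!geo] * runif(14, 0.95, 1.05)
  expect_equal(unname(flatten_model(unflatten_model(jit, m))), jit)
  expect_error(unflatten_model(jit[-1], m), "43")
})

test_that("solved equilibria meet the residual acceptance condition", {
  m <- default_ankle_fixture()
  st0 <- solve_equilibrium(m, 0)
  expect_true(st0$converged)
  expect_lt(abs(st0$pose$theta) * 180 / pi, 1e-6)

  for (engine in c("cpp", "minpack")) {
    st <- solve_equilibrium(m, 1, engine = engine)
    expect_true(st$converged)
    expect_lt(st$residual_sum, 1e-10)
    expect_gt(st$pose$theta, 0)  # positive moment -> plantarflexion
  }
})

test_that("an exhausted iteration budget returns converged = FALSE, not an error", {
  m <- default_ankle_fixture()
  for (engine in c("cpp", "minpack")) {
    st <- solve_equilibrium(m, 3, control = solver_control(maxiter = 1),
                            engine = engine)
    expect_s3_class(st, "equilibrium_state")
    expect_false(st$converged)
  }
})

test_that("sweep honours the zero-load definition and is deterministic", {
  m <- default_ankle_fixture()
  sw0 <- sweep_loads(m, load_schedule(0))
  expect_equal(sw0$dtheta_deg, 0)
  expect_identical(sw0$not_passed, 0L)

  sw1 <- sweep_loads(m)
  sw2 <- sweep_loads(m)
  expect_identical(sw1$dtheta_deg, sw2$dtheta_deg)
  expect_identical(sw1$element_forces, sw2$element_forces)
})

test_that("fixture moment-rotation curve is monotonically non-decreasing", {
  m <- default_ankle_fixture()
  sw <- sweep_loads(m)
  expect_identical(sw$not_passed, 0L)
  expect_true(all(diff(sw$dtheta_deg[order(sw$moments)]) >= 0))
  expect_true(all(sw$element_forces >= 0))
})

test_that("sweep results do not depend on the schedule ordering", {
  m <- default_ankle_fixture()
  sched <- c(-5, -3, 0, 2, 5)
  sw_sorted <- sweep_loads(m, load_schedule(sched))
  sw_shuffled <- sweep_loads(m, load_schedule(c(2, -5, 0, 5, -3)))
  ord <- match(sched, sw_shuffled$moments)
  expect_equal(sw_shuffled$dtheta_deg[ord], sw_sorted$dtheta_deg)
  expect_equal(unname(sw_shuffled$element_forces[ord, ]),
               unname(sw_sorted$element_forces))
})

test_that("compiled and minpack sweep engines agree", {
  m <- default_ankle_fixture()
  sw_c <- sweep_loads(m, engine = "cpp")
  sw_r <- sweep_loads(m, engine = "minpack")
  expect_identical(sw_c$converged, sw_r$converged)
  expect_equal(sw_c$dtheta_deg, sw_r$dtheta_deg, tolerance = 1e-8)
  expect_equal(sw_c$element_forces, sw_r$element_forces, tolerance = 1e-6)
})

test_that("sweep data frame follows the CSV column contract", {
  m <- default_ankle_fixture()
  df <- as.data.frame(sweep_loads(m, load_schedule(c(-1, 0, 1))))
  expect_identical(names(df),
                   c("M_ext_Nm", "dtheta_deg", "F_ATT_N", "F_TC_N", "F_PTT_N",
                     "F_ATF_N", "F_CF_N", "F_PTF_N", "F_contact_N",
                     "converged"))
  expect_equal(df$dtheta_deg[df$M_ext_Nm == 0], 0)
})

test_that("load schedules are validated", {
  expect_error(load_schedule(c(-1, 1)), "zero")
  expect_error(load_schedule(c(0, 1, 1)), "duplicated")
  expect_equal(load_schedule()$moments, seq(-5, 5, by = 1))
})
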