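# Synthetic ankle fixture and random model generation.
#
# The reference parameter set the adversarial analysis perturbs is a
# documented synthetic ankle: coordinates follow the sagittal-plane anatomy
# of the talocrural joint (x anterior, y superior, mm; global frame fixed to
# the tibia/fibula, moving frame to the talus/calcaneus, coincident at the
# reference pose), and the cable stiffnesses are calibrated so the joint
# reproduces the qualitative regime of published planar ankle models: all 11
# load steps of the default +/-5 Nm schedule converge, the range of motion
# lies in the 40-80 deg band, and plantarflexion exceeds dorsiflexion in
# magnitude.

#' The default synthetic ankle model
#'
#' A fixed, versioned 43-parameter planar ankle. Anterior cables (ATT, ATF)
#' resist dorsiflexion, posterior cables (PTT, PTF) resist plantarflexion,
#' and the long vertical calcaneal cables (TC, CF) mainly stabilise
#' translation. The talar dome is a conforming Hertzian pair with coincident
#' centres at the reference pose, 20 mm inner radius, 0.5 mm clearance and
#' cartilage-like material (E = 10 MPa, nu = 0.4). Under the default
#' schedule the sweep converges at every step with roughly +37 deg of
#' plantarflexion and -22 deg of dorsiflexion.
#'
#' This parameter set is synthetic: it is the package's own calibrated
#' stand-in for a subject-specific ankle, not data from any measured
#' specimen.
#'
#' @return a [joint_model()].
#' @export
default_ankle_fixture <- function() {
  geom <- list(
    ATT = list(m = c(20, -8), f = c(15, 10)),
    TC = list(m = c(-8, -34), f = c(0, 12)),
    PTT = list(m = c(-18, -10), f = c(-12, 8)),
    ATF = list(m = c(24, -12), f = c(18, 5)),
    CF = list(m = c(-12, -30), f = c(-5, 6)),
    PTF = list(m = c(-22, -12), f = c(-15, 5)))
  a <- c(ATT = 3.0, TC = 5.0, PTT = 0.6, ATF = 2.2, CF = 5.0, PTF = 0.5)
  b <- c(ATT = 15, TC = 15, PTT = 15, ATF = 15, CF = 15, PTF = 15)
  ligs <- lapply(LIGAMENT_NAMES, function(nm) {
    ligament_spec(nm, geom[[nm]]$m, geom[[nm]]$f, a[[nm]], b[[nm]])
  })
  contact <- contact_spec(center_moving = c(0, 0), center_fixed = c(0, 0),
                          radius_inner = 20, youngs_modulus = 10,
                          poissons_ratio = 0.4, clearance = 0.5)
  joint_model(ligs, contact)
}

#' Metadata describing the shipped fixture
#'
#' @return list with the fixture name, a provenance note and the declared
#'   range-of-motion band (deg) its default sweep must fall into.
#' @export
fixture_metadata <- function() {
  list(name = "synthetic-ankle-v1",
       description = paste("Calibrated synthetic planar ankle:",
                           "6 exponential cables + conforming Hertzian pair"),
       expected_rom_band = c(40, 80),
       provenance = paste("Synthetic parameter set calibrated in-package;",
                          "not measured subject data"))
}

#' Randomly perturbed plausible ankle model
#'
#' Applies bounded uniform jitter to the default fixture: absolute jitter on
#' the 29 geometric parameters (mm) and relative jitter on the 14 material
#' parameters. Used by the property tests as a generator of plausible
#' models.
#'
#' @param geometry_jitter half-width of the geometric jitter, mm.
#' @param material_jitter half-width of the relative material jitter
#'   (0.05 = +/-5 percent).
#' @return a [joint_model()].
#' @export
random_plausible_model <- function(geometry_jitter = 0.5,
                                   material_jitter = 0.05) {
  stopifnot(geometry_jitter >= 0, material_jitter >= 0, material_jitter < 1)
  ref <- default_ankle_fixture()
  v <- flatten_model(ref)
  geo <- geometry_mask()
  v[geo] <- v[geo] + stats::runif(sum(geo), -geometry_jitter, geometry_jitter)
  v[!geo] <- v[!geo] * stats::runif(sum(!geo), 1 - material_jitter,
                                    1 + material_jitter)
  unflatten_model(v, ref)
}
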