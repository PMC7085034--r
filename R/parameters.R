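# Canonical 43-element flattening of the free model parameters.
#
# Order (geometry section first, then materials, mirroring the adversarial
# encoding):
#   1-24   per ligament (ATT, TC, PTT, ATF, CF, PTF):
#          attach_moving.x, attach_moving.y, attach_fixed.x, attach_fixed.y
#   25-29  contact: center_moving.x, center_moving.y,
#          center_fixed.x, center_fixed.y, radius_inner
#   30-41  per ligament: stiffness_coeff, shape_coeff
#   42-43  contact: youngs_modulus, poissons_ratio
#
# The clearance, contact mode and reference pose are fixed configuration,
# not free parameters. Indices 1-29 are geometric (absolute perturbation
# bounds, mm); 30-43 are material (relative bounds).

N_PARAMS <- 43L
N_GEOMETRY <- 29L

#' Canonical parameter names
#'
#' @return character vector of length 43 naming each entry of the canonical
#'   flattened parameter vector.
#' @export
parameter_names <- function() {
  geo <- unlist(lapply(LIGAMENT_NAMES, function(nm) {
    paste0(nm, c("_mov_x", "_mov_y", "_fix_x", "_fix_y"))
  }))
  mat <- unlist(lapply(LIGAMENT_NAMES, function(nm) {
    paste0(nm, c("_a", "_b"))
  }))
  c(geo,
    c("con_mov_x", "con_mov_y", "con_fix_x", "con_fix_y", "con_R_in"),
    mat,
    c("con_E", "con_nu"))
}

#' Logical mask of the geometric entries of the canonical vector
#'
#' @return logical length-43 vector, TRUE for the 29 geometric parameters
#'   (ligament attachment coordinates and contact geometry), FALSE for the 14
#'   material parameters.
#' @export
geometry_mask <- function() {
  c(rep(TRUE, N_GEOMETRY), rep(FALSE, N_PARAMS - N_GEOMETRY))
}

#' Flatten a joint model into the canonical 43-element vector
#'
#' @param model a [joint_model()].
#' @return named numeric vector of length 43 (see [parameter_names()]).
#' @export
flatten_model <- function(model) {
  stopifnot(inherits(model, "joint_model"))
  geo <- unlist(lapply(model$ligaments, function(l) {
    c(l$attach_moving, l$attach_fixed)
  }), use.names = FALSE)
  ct <- model$contact
  mat <- unlist(lapply(model$ligaments, function(l) {
    c(l$stiffness_coeff, l$shape_coeff)
  }), use.names = FALSE)
  v <- c(geo, ct$center_moving, ct$center_fixed, ct$radius_inner,
         mat, ct$youngs_modulus, ct$poissons_ratio)
  names(v) <- parameter_names()
  v
}

#' Rebuild a joint model from a canonical 43-element vector
#'
#' Fixed configuration (clearance, contact mode, reference pose) is taken
#' from `template`. Ligament reference lengths are recomputed from the new
#' geometry at the template's reference pose, so `unflatten_model` of a
#' perturbed vector yields a model whose cables are slack in the reference
#' configuration of that perturbed geometry.
#'
#' @param values numeric vector of length 43 in canonical order.
#' @param template a [joint_model()] supplying the fixed configuration.
#' @return a [joint_model()]. `flatten_model(unflatten_model(v, t))` is the
#'   identity on valid vectors.
#' @export
unflatten_model <- function(values, template) {
  stopifnot(inherits(template, "joint_model"))
  if (length(values) != N_PARAMS || !is.numeric(values) || any(!is.finite(values))) {
    stop("parameter vector must hold 43 finite numeric values", call. = FALSE)
  }
  values <- unname(values)
  ligs <- vector("list", 6)
  for (i in 1:6) {
    o <- (i - 1) * 4
    mo <- 24 + 5 + (i - 1) * 2
    ligs[[i]] <- ligament_spec(LIGAMENT_NAMES[i],
                               attach_moving = values[o + 1:2],
                               attach_fixed = values[o + 3:4],
                               stiffness_coeff = values[mo + 1],
                               shape_coeff = values[mo + 2])
  }
  tc <- template$contact
  contact <- contact_spec(center_moving = values[25:26],
                          center_fixed = values[27:28],
                          radius_inner = values[29],
                          youngs_modulus = values[42],
                          poissons_ratio = values[43],
                          clearance = tc$clearance,
                          mode = tc$mode)
  joint_model(ligs, contact, template$reference_pose)
}
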