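# Model file I/O. Models are stored as a structured YAML document with
# explicit units; reading validates the schema strictly and names the
# offending field in every error.

MODEL_SCHEMA_VERSION <- 1L

#' Write a joint model to a YAML file
#'
#' The file mirrors the model structure (ligaments with attachment points
#' and material coefficients, contact pair, reference pose) together with
#' the unit conventions and the schema version. [read_model()] restores it
#' losslessly.
#'
#' @param model a [joint_model()].
#' @param path output file path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "joint_model"))
  doc <- list(
    schema = "anklewc-joint-model",
    schema_version = MODEL_SCHEMA_VERSION,
    units = list(length = "mm", force = "N", pressure = "MPa",
                 angle = "rad"),
    reference_pose = list(tx = model$reference_pose$tx,
                          ty = model$reference_pose$ty,
                          theta = model$reference_pose$theta),
    ligaments = lapply(model$ligaments, function(l) {
      list(attach_moving = as.list(l$attach_moving),
           attach_fixed = as.list(l$attach_fixed),
           stiffness_coeff = l$stiffness_coeff,
           shape_coeff = l$shape_coeff)
    }),
    contact = list(center_moving = as.list(model$contact$center_moving),
                   center_fixed = as.list(model$contact$center_fixed),
                   radius_inner = model$contact$radius_inner,
                   youngs_modulus = model$contact$youngs_modulus,
                   poissons_ratio = model$contact$poissons_ratio,
                   clearance = model$contact$clearance,
                   mode = model$contact$mode))
  writeLines(yaml::as.yaml(doc, precision = 15), path)
  invisible(path)
}

.schema_check_keys <- function(x, expected, where) {
  missing <- setdiff(expected, names(x))
  if (length(missing) > 0) {
    stop(sprintf("model file schema error: missing field '%s' in %s",
                 missing[1], where), call. = FALSE)
  }
  extra <- setdiff(names(x), expected)
  if (length(extra) > 0) {
    stop(sprintf("model file schema error: unknown field '%s' in %s",
                 extra[1], where), call. = FALSE)
  }
}

.schema_point <- function(x, where) {
  if (!is.numeric(unlist(x)) || length(unlist(x)) != 2) {
    stop(sprintf("model file schema error: %s must be a 2-element numeric point",
                 where), call. = FALSE)
  }
  as.numeric(unlist(x))
}

.schema_scalar <- function(x, where) {
  v <- unlist(x)
  if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
    stop(sprintf("model file schema error: %s must be a finite numeric scalar",
                 where), call. = FALSE)
  }
  as.numeric(v)
}

#' Read a joint model from a YAML file
#'
#' Strict schema validation: missing fields, unknown extra fields, wrong
#' units or malformed values raise an error naming the field.
#'
#' @param path model file written by [write_model()] (or by hand in the same
#'   layout).
#' @return a [joint_model()].
#' @export
read_model <- function(path) {
  doc <- yaml::read_yaml(path)
  .schema_check_keys(doc, c("schema", "schema_version", "units",
                            "reference_pose", "ligaments", "contact"),
                     "the document root")
  if (!identical(doc$schema, "anklewc-joint-model")) {
    stop("model file schema error: field 'schema' must be 'anklewc-joint-model'",
         call. = FALSE)
  }
  if (!identical(as.integer(doc$schema_version), MODEL_SCHEMA_VERSION)) {
    stop("model file schema error: unsupported 'schema_version'",
         call. = FALSE)
  }
  .schema_check_keys(doc$units, c("length", "force", "pressure", "angle"),
                     "'units'")
  expected_units <- list(length = "mm", force = "N", pressure = "MPa",
                         angle = "rad")
  for (u in names(expected_units)) {
    if (!identical(doc$units[[u]], expected_units[[u]])) {
      stop(sprintf("model file schema error: unit '%s' must be '%s'",
                   u, expected_units[[u]]), call. = FALSE)
    }
  }
  .schema_check_keys(doc$reference_pose, c("tx", "ty", "theta"),
                     "'reference_pose'")
  pose <- pose2d(.schema_scalar(doc$reference_pose$tx, "reference_pose$tx"),
                 .schema_scalar(doc$reference_pose$ty, "reference_pose$ty"),
                 .schema_scalar(doc$reference_pose$theta,
                                "reference_pose$theta"))
  .schema_check_keys(doc$ligaments, LIGAMENT_NAMES, "'ligaments'")
  ligs <- lapply(LIGAMENT_NAMES, function(nm) {
    l <- doc$ligaments[[nm]]
    where <- sprintf("ligament '%s'", nm)
    .schema_check_keys(l, c("attach_moving", "attach_fixed",
                            "stiffness_coeff", "shape_coeff"), where)
    ligament_spec(nm,
                  .schema_point(l$attach_moving,
                                paste0(where, "$attach_moving")),
                  .schema_point(l$attach_fixed,
                                paste0(where, "$attach_fixed")),
                  .schema_scalar(l$stiffness_coeff,
                                 paste0(where, "$stiffness_coeff")),
                  .schema_scalar(l$shape_coeff,
                                 paste0(where, "$shape_coeff")))
  })
  ct <- doc$contact
  .schema_check_keys(ct, c("center_moving", "center_fixed", "radius_inner",
                           "youngs_modulus", "poissons_ratio", "clearance",
                           "mode"), "'contact'")
  if (!ct$mode %in% c("internal", "external")) {
    stop("model file schema error: contact$mode must be 'internal' or 'external'",
         call. = FALSE)
  }
  contact <- contact_spec(.schema_point(ct$center_moving,
                                        "contact$center_moving"),
                          .schema_point(ct$center_fixed,
                                        "contact$center_fixed"),
                          .schema_scalar(ct$radius_inner,
                                         "contact$radius_inner"),
                          .schema_scalar(ct$youngs_modulus,
                                         "contact$youngs_modulus"),
                          .schema_scalar(ct$poissons_ratio,
                                         "contact$poissons_ratio"),
                          .schema_scalar(ct$clearance, "contact$clearance"),
                          ct$mode)
  joint_model(ligs, contact, pose)
}
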