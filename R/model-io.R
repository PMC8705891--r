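# Human-readable model serialization. The YAML schema lists every segment
# with its parent, joint origin, degrees of freedom (name, type, axis,
# bounds, locked) and model-fixed marker positions, plus the model-level
# audit fields; a read of a written file reproduces the model exactly.

#' Write a skeletal model to a YAML file
#'
#' The file documents the laboratory frame convention (X progression,
#' Y left, Z up; metres and radians) and is loss-free under
#' [read_model_yaml()].
#'
#' @param model a `skeletal_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_yaml <- function(model, path) {
  segs <- lapply(model$segments, function(seg) {
    list(parent = if (is.na(seg$parent)) NULL else seg$parent,
         joint_origin_in_parent = as.numeric(seg$origin),
         dofs = lapply(seg$dofs, function(d) {
           list(name = d$name, type = d$type, axis = as.numeric(d$axis),
                bounds = as.numeric(d$bounds), locked = d$locked,
                value = d$value)
         }),
         markers = lapply(seg$markers, as.numeric))
  })
  doc <- list(
    format = "gaitprofile_skeletal_model",
    version = 1L,
    frame_convention = "X = walking progression, Y = left, Z = up; metres, radians",
    anthropometry = unclass(model$anthropometry),
    knee_axis_correction_deg = as.list(model$knee_axis_correction_deg),
    marker_radius = model$marker_radius,
    geometry = lapply(model$geometry, function(g)
      if (is.null(names(g))) as.numeric(g) else as.list(g)),
    segments = segs)
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Read a skeletal model from its YAML serialization
#'
#' @param path a file written by [write_model_yaml()].
#' @return a validated `skeletal_model`.
#' @export
read_model_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  assert_that(identical(doc$format, "gaitprofile_skeletal_model"),
              "not a gaitprofile skeletal model file: %s", path)
  segments <- list()
  for (nm in names(doc$segments)) {
    s <- doc$segments[[nm]]
    segments[[nm]] <- list(
      name = nm,
      parent = s$parent %||% NA_character_,
      origin = as.numeric(s$joint_origin_in_parent),
      dofs = lapply(s$dofs, function(d) {
        list(name = d$name, type = d$type, axis = as.numeric(d$axis),
             bounds = as.numeric(d$bounds), locked = isTRUE(d$locked),
             value = d$value %||% 0)
      }),
      markers = lapply(s$markers, as.numeric))
  }
  geometry <- doc$geometry
  for (g in c("femur_length", "tibia_length", "ankle_height", "foot_length")) {
    geometry[[g]] <- unlist(geometry[[g]])
  }
  model <- structure(list(
    segments = segments,
    anthropometry = validate_anthropometry(doc$anthropometry),
    knee_axis_correction_deg = unlist(doc$knee_axis_correction_deg),
    marker_radius = doc$marker_radius,
    geometry = geometry), class = "skeletal_model")
  validate_model(model)
}
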