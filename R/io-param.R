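#' Save and load parameterizations as JSON
#'
#' The JSON holds the centerline knots and control points, the wall basis
#' metadata and coefficient matrix, so `read_param(write_param(p))` restores
#' the parameterization exactly.
#'
#' @param param an `aorta_param`.
#' @param path JSON file path.
#' @export
write_param <- function(param, path) {
  obj <- list(
    centerline = list(knots = param$centerline$knots,
                      coef = param$centerline$coef,
                      degree = param$centerline$degree,
                      n_ctrl = param$centerline$n_ctrl,
                      residual = param$centerline$residual,
                      length = param$centerline$length),
    wall = list(knots = param$wall$knots, mode = param$wall$mode,
                n_s = param$wall$n_s, n_theta = param$wall$n_theta,
                coef = param$wall$coef, residual = param$wall$residual,
                seam_gap = param$wall$seam_gap))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_param
#' @export
read_param <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  cl <- structure(list(knots = o$centerline$knots,
                       coef = as.matrix(o$centerline$coef),
                       degree = as.integer(o$centerline$degree),
                       n_ctrl = as.integer(o$centerline$n_ctrl),
                       residual = o$centerline$residual,
                       length = o$centerline$length),
                  class = "centerline_spline")
  wall <- structure(list(knots = o$wall$knots, mode = o$wall$mode,
                         n_s = as.integer(o$wall$n_s),
                         n_theta = as.integer(o$wall$n_theta),
                         coef = as.matrix(o$wall$coef),
                         residual = o$wall$residual,
                         seam_gap = o$wall$seam_gap),
                    class = "wall_model")
  structure(list(centerline = cl, wall = wall, meta = list(from = path)),
            class = "aorta_param")
}
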