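#' Camera geometry of the tilted-bracket imaging platform
#'
#' Parameters of the pixel-to-millimetre mapping: the camera looks straight
#' down from height `h_mm` above the reference origin, and the wrist bracket
#' is tilted by `alpha_deg` about the transverse axis, which makes near
#' objects appear wide and far objects narrow (trapezoid distortion). The
#' equations use two pixel axes: the *tilt axis* (extent `height_px`, half
#' field angle `theta_deg`) along which the bracket rises, and the
#' *transverse axis* (extent `width_px`, half field angle `beta_deg`).
#' In wrist images where the arm runs along image columns, the tilt axis is
#' the column axis (see [map_guan()]).
#'
#' @param theta_deg half field angle of the tilt axis, degrees.
#' @param beta_deg half field angle of the transverse axis, degrees.
#' @param h_mm camera-to-bracket distance, perpendicular to the horizontal
#'   plane, mm.
#' @param alpha_deg bracket tilt angle, degrees; must satisfy
#'   `0 <= alpha < 90 - theta` so the mapping stays nondegenerate.
#' @param height_px,width_px pixel extents of the tilt and transverse axes.
#' @return An object of class `camera_geometry`.
#' @export
camera_geometry <- function(theta_deg, beta_deg, h_mm, alpha_deg = 0,
                            height_px, width_px) {
  if (theta_deg <= 0 || theta_deg >= 90) guan_abort("guan_param_error", "need 0 < theta < 90")
  if (beta_deg <= 0 || beta_deg >= 90) guan_abort("guan_param_error", "need 0 < beta < 90")
  if (alpha_deg < 0 || alpha_deg >= 90 - theta_deg) {
    guan_abort("guan_param_error", "need 0 <= alpha < 90 - theta")
  }
  if (h_mm <= 0) guan_abort("guan_param_error", "need h_mm > 0")
  if (height_px < 2 || width_px < 2) guan_abort("guan_param_error", "pixel extents too small")
  structure(
    list(theta_deg = theta_deg, beta_deg = beta_deg, h_mm = h_mm,
         alpha_deg = alpha_deg, height_px = height_px, width_px = width_px),
    class = "camera_geometry"
  )
}

#' @export
print.camera_geometry <- function(x, ...) {
  cat(sprintf(
    "<camera_geometry> theta %.1f deg, beta %.1f deg, h %.0f mm, alpha %.1f deg, %d x %d px\n",
    x$theta_deg, x$beta_deg, x$h_mm, x$alpha_deg, x$height_px, x$width_px))
  invisible(x)
}

deg2rad <- function(d) d * pi / 180

#' Step angle of a pixel on the tilt axis
#'
#' The view angle of a pixel offset `X` from the tilt-axis center is
#' proportional to the offset: `dtheta = X / (height_px / 2) * theta`, so
#' the frame edge maps to the full half field angle.
#'
#' @param X signed pixel offset from the tilt-axis center; positive toward
#'   the far (narrow) end.
#' @param geom a [camera_geometry].
#' @return Signed step angle in degrees.
#' @export
step_angle_vertical <- function(X, geom) {
  half <- geom$height_px / 2
  if (any(abs(X) > half + 1e-9)) {
    guan_abort("guan_geometry_error", "pixel offset outside the frame")
  }
  X / half * geom$theta_deg
}

#' Map a tilt-axis pixel offset to the along-bracket world coordinate
#'
#' Sine-theorem solution of the side-view triangle formed by the camera, the
#' bracket origin and the target point. The sign of `X` selects the case:
#' `X < 0` lies on the `x_P = -HP` side of the origin (denominator
#' `sin(90 - dtheta - alpha)`), `X > 0` on the `x_P = +HP` side
#' (denominator `sin(90 - dtheta + alpha)`). The slant range `AP` to the
#' point's side-view position is returned alongside for the transverse
#' mapping.
#'
#' @inheritParams step_angle_vertical
#' @return Named numeric vector `c(x_mm, AP_mm)`.
#' @export
pixel_to_world_x <- function(X, geom) {
  dth <- deg2rad(abs(step_angle_vertical(X, geom)))
  al <- deg2rad(geom$alpha_deg)
  h <- geom$h_mm
  # sin(90 - u) written as cos(u)
  den <- if (X < 0) cos(dth + al) else cos(dth - al)
  if (den <= 1e-9) guan_abort("guan_geometry_error", "degenerate viewing geometry")
  HP <- sin(dth) * h * cos(al) / den
  AP <- cos(al) * h / den
  c(x_mm = if (X < 0) -HP else HP, AP_mm = AP)
}

#' Map a transverse pixel offset to the cross world coordinate
#'
#' `dbeta = |Y| / (width_px / 2) * beta`, `PQ = AP * tan(dbeta)`, with the
#' sign of `Y` restored by the sign function.
#'
#' @param Y signed pixel offset from the transverse-axis center.
#' @param AP slant range from [pixel_to_world_x()], mm.
#' @param geom a [camera_geometry].
#' @return Signed transverse coordinate in mm.
#' @export
pixel_to_world_y <- function(Y, AP, geom) {
  half <- geom$width_px / 2
  if (any(abs(Y) > half + 1e-9)) {
    guan_abort("guan_geometry_error", "pixel offset outside the frame")
  }
  if (AP <= 0) guan_abort("guan_geometry_error", "slant range AP must be positive")
  db <- deg2rad(abs(Y) / half * geom$beta_deg)
  if (db >= pi / 2) guan_abort("guan_geometry_error", "transverse step angle >= 90 degrees")
  AP * tan(db) * sign(Y)
}

#' Map a pixel-space localization to world millimetres
#'
#' Converts the GUAN pixel coordinates (and the crease reference column, if
#' present) to millimetres on the bracket plane. With
#' `tilt_axis = "columns"` (the default, matching wrist images where the arm
#' runs along image columns) the column offset feeds the tilt-axis equations
#' and the row offset the transverse equation; `geom$height_px` must then
#' equal the image width and `geom$width_px` the image height.
#' Offsets are measured from the pixel-center of the frame, `(extent+1)/2`.
#'
#' @param result a [guan_result] with pixel coordinates set.
#' @param geom a [camera_geometry].
#' @param tilt_axis `"columns"` or `"rows"`: which image axis runs along the
#'   tilted bracket.
#' @return The result with `x_world_mm`, `y_world_mm` (and `x_distance_mm`
#'   when a crease reference is present) filled in; slant range and step
#'   angles are added to diagnostics.
#' @export
map_guan <- function(result, geom, tilt_axis = c("columns", "rows")) {
  tilt_axis <- match.arg(tilt_axis)
  if (tilt_axis == "columns") {
    X <- result$x0_px - (geom$height_px + 1) / 2
    Y <- result$y0_px - (geom$width_px + 1) / 2
  } else {
    X <- result$y0_px - (geom$height_px + 1) / 2
    Y <- result$x0_px - (geom$width_px + 1) / 2
  }
  wx <- pixel_to_world_x(X, geom)
  wy <- pixel_to_world_y(Y, wx["AP_mm"], geom)
  result$x_world_mm <- unname(wx["x_mm"])
  result$y_world_mm <- unname(wy)
  result$diagnostics$AP_mm <- unname(wx["AP_mm"])
  result$diagnostics$dtheta_deg <- step_angle_vertical(X, geom)
  if (!is.null(result$crease_x_px)) {
    if (tilt_axis != "columns") {
      guan_abort("guan_geometry_error",
                 "crease distance mapping requires tilt_axis = 'columns'")
    }
    Xc <- result$crease_x_px - (geom$height_px + 1) / 2
    wc <- pixel_to_world_x(Xc, geom)
    result$x_distance_mm <- abs(unname(wc["x_mm"]) - result$x_world_mm)
    result$diagnostics$crease_x_world_mm <- unname(wc["x_mm"])
  }
  result
}
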