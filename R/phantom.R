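#' Synthetic thermal-wrist phantom specification
#'
#' Parameters of the phantom generator, which emulates a thermal wrist image
#' as acquired on the positioning platform: a warm forearm band on a cool
#' background entering the frame from the left with the hand at the right,
#' a radial-styloid protrusion (Gaussian bump) on the upper contour with a
#' concave recess on its proximal side, a warmer radial-artery stripe inside
#' the band, a cold square marker at the wrist crease near the right image
#' edge (mirroring an aluminum-sheet reference), Gaussian sensor noise, and
#' optional rigid acquisition jitter across repeated acquisitions.
#'
#' Intensities are abstract 8-bit-like units (the pipeline is invariant to
#' affine intensity rescaling). All defaults are the study conditions used
#' throughout the package's tests; see the methods vignette for how they
#' were chosen.
#'
#' @param height_px,width_px image size (rows x columns).
#' @param background_temp,forearm_temp,artery_temp intensity levels; must
#'   increase in that order.
#' @param marker_temp,marker_size_px,marker_row cold crease-marker intensity,
#'   side length and center row.
#' @param contour_base_row,contour_taper_px upper-contour baseline: row
#'   `contour_base_row + contour_taper_px * ((c-1)/(W-1) - 1/2)`.
#' @param lower_row lower contour row (straight).
#' @param bump_amplitude_px,bump_sigma_px styloid protrusion height and
#'   width at `salient_col`.
#' @param recess_depth_px,recess_sigma_px,recess_offset_px concave recess at
#'   `salient_col - recess_offset_px`; the offset must stay under 100 px
#'   (one finger width).
#' @param salient_col styloid bump center column.
#' @param artery_row,artery_slope,artery_width_px artery centerline row at
#'   the image center column, its slope, and full stripe width.
#' @param artery_cols,artery_taper_px column extent of the visible stripe
#'   and the taper length at its ends.
#' @param crease_col wrist-crease reference column (near the right edge).
#' @param noise_sigma Gaussian sensor noise standard deviation.
#' @param jitter list of acquisition-jitter half-ranges for repeated
#'   acquisitions: `dx_px` (along-arm translation), `dy_px` (cross-arm
#'   translation), `rot_deg` (rotation about the image center), `amp_frac`
#'   (relative styloid-bump amplitude variation).
#' @param seed integer seed; a fixed spec generates a byte-identical image.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height_px = 240L, width_px = 320L,
                         background_temp = 90, forearm_temp = 170, artery_temp = 196,
                         marker_temp = 60, marker_size_px = 8L, marker_row = 140L,
                         contour_base_row = 96, contour_taper_px = 14,
                         lower_row = 226,
                         bump_amplitude_px = 12, bump_sigma_px = 8,
                         recess_depth_px = 7, recess_sigma_px = 7, recess_offset_px = 70,
                         salient_col = 250L,
                         artery_row = 162, artery_slope = 0.05, artery_width_px = 8,
                         artery_cols = c(130L, 290L), artery_taper_px = 20,
                         crease_col = 296L,
                         noise_sigma = 2,
                         jitter = list(dx_px = 3, dy_px = 1, rot_deg = 1, amp_frac = 0.1),
                         seed = 1L) {
  spec <- structure(as.list(environment()), class = "phantom_spec")
  if (!(artery_temp > forearm_temp && forearm_temp > background_temp)) {
    guan_abort("guan_spec_error", "need artery_temp > forearm_temp > background_temp")
  }
  if (recess_offset_px <= 0 || recess_offset_px >= 100) {
    guan_abort("guan_spec_error", "recess_offset_px must lie in (0, 100)")
  }
  hw <- artery_width_px / 2
  u_max <- contour_base_row + contour_taper_px / 2 + recess_depth_px
  if (artery_row - hw - 4 < u_max || artery_row + hw + 4 > lower_row) {
    guan_abort("guan_spec_error", "artery stripe does not fit inside the forearm band")
  }
  if (marker_row - marker_size_px / 2 < u_max || marker_row + marker_size_px / 2 > lower_row) {
    guan_abort("guan_spec_error", "crease marker does not lie inside the forearm band")
  }
  jd <- list(dx_px = 3, dy_px = 1, rot_deg = 1, amp_frac = 0.1)
  jd[names(jitter)] <- jitter
  spec$jitter <- jd
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %d x %d px, salient col %d, crease col %d, seed %d\n",
              x$height_px, x$width_px, x$salient_col, x$crease_col, x$seed))
  invisible(x)
}

#' Default camera geometry of the phantom's world model
#'
#' The phantom places the arm along image columns, so the tilt axis of the
#' geometry is the column axis: extent 320 px with half field angle 20
#' degrees, transverse extent 240 px with half angle 25 degrees, camera
#' height 300 mm, bracket tilt 10 degrees.
#'
#' @return A [camera_geometry].
#' @export
phantom_geometry <- function() {
  camera_geometry(theta_deg = 20, beta_deg = 25, h_mm = 300, alpha_deg = 10,
                  height_px = 320L, width_px = 240L)
}

# Analytic anatomy of a phantom in nominal (untransformed) coordinates.
# Returns closed-form component functions of continuous (col, row).
phantom_anatomy <- function(spec, amp_scale = 1) {
  W <- spec$width_px
  upper <- function(c0) {
    spec$contour_base_row + spec$contour_taper_px * ((c0 - 1) / (W - 1) - 0.5) -
      amp_scale * spec$bump_amplitude_px *
        exp(-(c0 - spec$salient_col)^2 / (2 * spec$bump_sigma_px^2)) +
      spec$recess_depth_px *
        exp(-(c0 - (spec$salient_col - spec$recess_offset_px))^2 / (2 * spec$recess_sigma_px^2))
  }
  artery_center <- function(c0) {
    spec$artery_row + spec$artery_slope * (c0 - (W + 1) / 2)
  }
  list(upper = upper, artery_center = artery_center, lower = function(c0) rep(spec$lower_row, length(c0)))
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Render the phantom intensity field (no noise) for pixel coordinate
# matrices c0, r0 given in nominal anatomy coordinates.
render_anatomy <- function(spec, anat, c0, r0) {
  u <- anat$upper(c0)
  l <- anat$lower(c0)
  cov <- clamp01(r0 - u + 0.5) * clamp01(l - r0 + 0.5)
  I <- spec$background_temp + (spec$forearm_temp - spec$background_temp) * cov
  hw <- spec$artery_width_px / 2
  stripe <- clamp01(hw - abs(r0 - anat$artery_center(c0)) + 0.5)
  tp <- spec$artery_taper_px
  taper <- clamp01((c0 - spec$artery_cols[1L]) / tp) * clamp01((spec$artery_cols[2L] - c0) / tp)
  I <- I + (spec$artery_temp - spec$forearm_temp) * stripe * taper * cov
  ms <- spec$marker_size_px / 2
  mcov <- clamp01(ms - abs(c0 - spec$crease_col) + 0.5) *
    clamp01(ms - abs(r0 - spec$marker_row) + 0.5)
  I - (spec$forearm_temp - spec$marker_temp) * mcov * cov
}

# Rigid acquisition transform: anatomy -> image. A nominal point p is imaged
# at q = R(rot) (p - ctr) + ctr + (dx, dy). fwd/inv operate on (col,row)
# matrices.
make_transform <- function(spec, dx = 0, dy = 0, rot_deg = 0) {
  ctr <- c((spec$width_px + 1) / 2, (spec$height_px + 1) / 2)
  th <- deg2rad(rot_deg)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  list(
    fwd = function(p) sweep(sweep(p, 2, ctr) %*% t(R), 2, ctr + c(dx, dy), `+`),
    inv = function(q) sweep(sweep(q, 2, ctr + c(dx, dy)) %*% R, 2, ctr, `+`),
    rot_deg = rot_deg, dx = dx, dy = dy
  )
}

with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Ground-truth landmark of the (transformed) analytic contour: sample the
# contour densely, map to image coordinates, reduce to one row per column,
# then apply the same smoothing + curvature + salient/recess rule the
# pipeline uses. Returns list(salient_col, x0) or NULL when the rule finds
# no landmark (e.g. ablated bump).
truth_landmark <- function(spec, anat, trf) {
  W <- spec$width_px
  c_dense <- seq(1, W, by = 0.25)
  pts <- trf$fwd(cbind(c_dense, anat$upper(c_dense)))
  ord <- order(pts[, 1L])
  cols <- seq_len(W)
  rows <- stats::approx(pts[ord, 1L], pts[ord, 2L], xout = cols, rule = 2)$y
  prof <- tryCatch(
    find_salient(curvature_profile(outline_profile(cols, rows), side = "upper")),
    guan_error = function(e) NULL
  )
  if (is.null(prof)) return(NULL)
  x0 <- tryCatch(locate_x(prof), guan_error = function(e) NULL)
  if (is.null(x0)) return(NULL)
  list(salient_col = prof$salient_x, x0 = x0)
}

#' Generate a synthetic thermal wrist image with ground truth
#'
#' Renders the phantom described by `spec` (deterministically for a fixed
#' spec, including its `seed`) and records the ground truth *before* noise:
#' the styloid salient column, the GUAN landmark obtained by applying the
#' contour rule to the noise-free analytic outline, the artery centerline,
#' the crease reference column, and the world-space GUAN under `geometry`.
#'
#' @param spec a [phantom_spec].
#' @param jitter_draw optional list `(dx, dy, rot_deg, amp_scale)` applying
#'   a rigid acquisition transform; used by [acquire_series()].
#' @param geometry a [camera_geometry] for the world-truth mapping, or NULL.
#' @return List with `image` (a [thermal_image]) and `truth` (class
#'   `phantom_truth`: `guan_px`, `crease_col`, `salient_col`, `artery_line`,
#'   `world_guan`).
#' @export
generate_phantom <- function(spec, jitter_draw = NULL, geometry = phantom_geometry()) {
  stopifnot(inherits(spec, "phantom_spec"))
  jd <- jitter_draw %||% list(dx = 0, dy = 0, rot_deg = 0, amp_scale = 1)
  anat <- phantom_anatomy(spec, amp_scale = jd$amp_scale)
  trf <- make_transform(spec, jd$dx, jd$dy, jd$rot_deg)
  H <- spec$height_px; W <- spec$width_px
  q <- cbind(rep(seq_len(W), each = H), rep(seq_len(H), W))  # (col,row) of each pixel
  p0 <- trf$inv(q)
  I <- matrix(render_anatomy(spec, anat, p0[, 1L], p0[, 2L]), H, W)
  if (spec$noise_sigma > 0) {
    I <- I + with_local_seed(spec$seed, matrix(stats::rnorm(H * W, 0, spec$noise_sigma), H, W))
    I <- pmax(I, 0)
  }
  lm <- truth_landmark(spec, anat, trf)
  # artery line in image coordinates
  cmid <- (W + 1) / 2
  pline <- trf$fwd(rbind(c(cmid, anat$artery_center(cmid)),
                         c(cmid + 1, anat$artery_center(cmid + 1))))
  slope_t <- (pline[2L, 2L] - pline[1L, 2L]) / (pline[2L, 1L] - pline[1L, 1L])
  intercept_t <- pline[1L, 2L] - slope_t * pline[1L, 1L]
  crease_t <- trf$fwd(cbind(spec$crease_col, spec$marker_row))[1L, 1L]
  truth <- list(
    salient_col = if (is.null(lm)) NA_real_ else lm$salient_col,
    guan_px = if (is.null(lm)) c(NA_real_, NA_real_) else
      c(lm$x0, round_half_away(slope_t * lm$x0 + intercept_t)),
    crease_col = crease_t,
    artery_line = c(slope = slope_t, intercept = intercept_t),
    world_guan = NULL,
    jitter_draw = jd
  )
  if (!is.null(geometry) && !is.null(lm)) {
    r <- guan_result(truth$guan_px[1L], truth$guan_px[2L], crease_x_px = crease_t)
    r <- map_guan(r, geometry, tilt_axis = "columns")
    truth$world_guan <- c(x_mm = r$x_world_mm, y_mm = r$y_world_mm)
    truth$x_distance_mm <- r$x_distance_mm
  }
  class(truth) <- "phantom_truth"
  list(image = thermal_image(I, source = "phantom"), truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> GUAN (col %.0f, row %.0f), salient %.0f, crease col %.1f\n",
              x$guan_px[1L], x$guan_px[2L], x$salient_col, x$crease_col))
  invisible(x)
}

#' Acquire a series of jittered phantom images
#'
#' Emulates repeated acquisitions of the same anatomy under residual posture
#' variation: each repeat draws an independent rigid jitter (along-arm and
#' cross-arm translation, small rotation, styloid-bump amplitude scaling)
#' from the ranges in `spec$jitter`, plus fresh sensor noise; ground truths
#' are transformed consistently.
#'
#' @param spec a [phantom_spec].
#' @param n_repeats number of acquisitions (>= 2).
#' @param seed seed for the jitter and noise draws.
#' @param geometry a [camera_geometry] used for the world truths.
#' @return List of `n_repeats` elements, each as from [generate_phantom()].
#' @export
acquire_series <- function(spec, n_repeats = 10L, seed = 1L, geometry = phantom_geometry()) {
  if (n_repeats < 2) guan_abort("guan_param_error", "`n_repeats` must be at least 2")
  jr <- spec$jitter
  draws <- with_local_seed(seed, {
    lapply(seq_len(n_repeats), function(i) {
      list(
        dx = stats::runif(1, -jr$dx_px, jr$dx_px),
        dy = stats::runif(1, -jr$dy_px, jr$dy_px),
        rot_deg = stats::runif(1, -jr$rot_deg, jr$rot_deg),
        amp_scale = 1 + stats::runif(1, -jr$amp_frac, jr$amp_frac),
        noise_seed = as.integer(stats::runif(1, 1, 2^30))
      )
    })
  })
  lapply(draws, function(d) {
    sp <- spec
    sp$seed <- d$noise_seed
    generate_phantom(sp, jitter_draw = d, geometry = geometry)
  })
}
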