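#' Gaussian-derivative gradient magnitude
#'
#' Per-pixel gradient magnitude from first-derivative-of-Gaussian filtering
#' at scale `sigma`, the singularity-detection front end of the
#' arbitrary-angle edge detector. Filtering is separable (Gaussian along one
#' axis, Gaussian derivative along the other, correlation form) with
#' half-sample symmetric (reflective) boundary handling; the kernel radius is
#' `ceiling(3.5 * sigma)`.
#'
#' @param image a [thermal_image] or numeric matrix.
#' @param sigma Gaussian scale in pixels, > 0.
#' @return Numeric matrix of gradient magnitudes, same shape as the image.
#' @export
gaussian_gradient <- function(image, sigma = 2) {
  gaussian_gradient_xy(image, sigma)$mag
}

# Gradient components (gx across columns, gy across rows) and magnitude.
gaussian_gradient_xy <- function(image, sigma = 2) {
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) || sigma <= 0) {
    guan_abort("guan_param_error", "`sigma` must be a positive number")
  }
  px <- if (inherits(image, "thermal_image")) image$pixels else image
  r <- ceiling(3.5 * sigma)
  u <- seq(-r, r)
  g <- exp(-u^2 / (2 * sigma^2)); g <- g / sum(g)
  dg <- -(u / sigma^2) * g
  Kg_row <- conv_band_matrix(nrow(px), g)
  Kd_row <- conv_band_matrix(nrow(px), dg)
  Kg_col <- conv_band_matrix(ncol(px), g)
  Kd_col <- conv_band_matrix(ncol(px), dg)
  gy <- Kd_row %*% (px %*% t(Kg_col))  # derivative across rows
  gx <- Kg_row %*% (px %*% t(Kd_col))  # derivative across columns
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

# Dense banded matrix M such that (M %*% x)[i] = sum_o k[o] * x[reflect(i+o)]
# (correlation with half-sample symmetric boundary). Kernel k has odd length.
conv_band_matrix <- function(n, k) {
  r <- (length(k) - 1L) / 2L
  M <- matrix(0, n, n)
  i <- seq_len(n)
  for (o in seq(-r, r)) {
    j <- i + o
    j <- ifelse(j < 1L, 1L - j, j)
    j <- ifelse(j > n, 2L * n + 1L - j, j)
    M[cbind(i, j)] <- M[cbind(i, j)] + k[o + r + 1L]
  }
  M
}

#' Decompose an image grid into digital pixel lines at an angle
#'
#' Partitions every pixel of an `height x width` grid into digital straight
#' lines at `angle_deg` (measured from the row direction, rising toward
#' smaller row indices as the column increases). Two pixel-combination rules
#' are provided: `"compact"` uses symmetric rounding of the ideal line offset
#' (Bresenham-style), `"sparse"` uses the floor of the offset so diagonal
#' steps are taken as late as possible. Under both rules the lines partition
#' the grid exactly and consecutive pixels within a line are 8-connected.
#'
#' @param shape integer vector `c(height, width)`.
#' @param angle_deg detection angle in degrees, in `[0, 45]`; other angles
#'   are reached through the symmetry expansion in [detect_edges()].
#' @param connection `"compact"` or `"sparse"`.
#' @return List of pixel lines; each line is a list with `coords` (an `n x 2`
#'   integer matrix with columns `col`, `row`, ordered by increasing column)
#'   and `angle_deg`.
#' @export
decompose_pixel_lines <- function(shape, angle_deg, connection = c("compact", "sparse")) {
  connection <- match.arg(connection)
  if (!is.numeric(angle_deg) || angle_deg < 0 || angle_deg > 45) {
    guan_abort("guan_param_error", "`angle_deg` must lie in [0, 45]")
  }
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  idx <- line_index(H, W, angle_deg, connection)
  ord <- order(idx$b, idx$col)
  ids <- idx$b[ord]
  split_points <- c(0L, which(diff(ids) != 0L), length(ids))
  lines <- vector("list", length(split_points) - 1L)
  for (k in seq_along(lines)) {
    sel <- ord[(split_points[k] + 1L):split_points[k + 1L]]
    lines[[k]] <- list(
      coords = cbind(col = idx$col[sel], row = idx$row[sel]),
      angle_deg = angle_deg
    )
  }
  lines
}

# Line membership index: pixel (col,row) belongs to line b = row + s(col),
# where s is the (rounded or floored) rise of the ideal line over col-1 steps.
line_index <- function(H, W, angle_deg, connection) {
  m <- tan(angle_deg * pi / 180)
  s <- switch(connection,
    compact = as.integer(round(m * (seq_len(W) - 1L))),
    sparse  = as.integer(floor(m * (seq_len(W) - 1L) + 1e-9))
  )
  col <- rep(seq_len(W), each = H)
  row <- rep(seq_len(H), W)
  list(col = col, row = row, b = row + s[col])
}

#' Non-maximum suppression along pixel lines
#'
#' Marks a pixel iff its response is a strict local maximum along its pixel
#' line (strictly greater than both line neighbours) and at least
#' `threshold`. Line endpoints have a single neighbour and are never marked.
#'
#' @param response numeric response matrix.
#' @param lines pixel lines from [decompose_pixel_lines()] covering the
#'   response grid.
#' @param threshold response floor; maxima below it are suppressed.
#' @return An `edge_map`: list with logical `mask` (same shape as
#'   `response`) and `angles_used`.
#' @export
nms_along_lines <- function(response, lines, threshold = 0) {
  H <- nrow(response); W <- ncol(response)
  col <- unlist(lapply(lines, function(l) l$coords[, 1L]), use.names = FALSE)
  row <- unlist(lapply(lines, function(l) l$coords[, 2L]), use.names = FALSE)
  id <- rep(seq_along(lines), vapply(lines, function(l) nrow(l$coords), integer(1)))
  if (any(col < 1L | col > W | row < 1L | row > H)) {
    guan_abort("guan_validation_error", "line coordinates outside the response grid")
  }
  v <- response[cbind(row, col)]
  n <- length(v)
  first <- c(TRUE, id[-1L] != id[-n])
  last <- c(first[-1L], TRUE)
  mark <- !first & !last &
    v > c(-Inf, v[-n]) & v > c(v[-1L], -Inf) &
    v >= threshold
  mask <- matrix(FALSE, H, W)
  mask[cbind(row[mark], col[mark])] <- TRUE
  edge_map(mask, angles_used = unique(vapply(lines, `[[`, numeric(1), "angle_deg")))
}

edge_map <- function(mask, angles_used = numeric()) {
  structure(list(mask = mask, angles_used = angles_used), class = "edge_map")
}

#' @export
print.edge_map <- function(x, ...) {
  cat(sprintf("<edge_map> %d x %d, %d edge pixels, %d detection angles\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), length(x$angles_used)))
  invisible(x)
}

# Fast equivalent of nms_along_lines for one angle family, without building
# the explicit line list (used by detect_edges; agreement with the explicit
# path is asserted in the test suite). `eligible`, if given, additionally
# restricts which pixels may be marked.
nms_at_angle <- function(response, angle_deg, threshold, connection, eligible = NULL) {
  H <- nrow(response); W <- ncol(response)
  idx <- line_index(H, W, angle_deg, connection)
  ord <- order(idx$b, idx$col)
  lin <- (idx$col[ord] - 1L) * H + idx$row[ord]
  v <- as.vector(response)[lin]
  n <- length(v)
  ids <- idx$b[ord]
  first <- c(TRUE, ids[-1L] != ids[-n])
  last <- c(first[-1L], TRUE)
  mark <- !first & !last & v > c(-Inf, v[-n]) & v > c(v[-1L], -Inf) & v >= threshold
  if (!is.null(eligible)) mark <- mark & as.vector(eligible)[lin]
  out <- logical(H * W)
  out[lin[mark]] <- TRUE
  matrix(out, H, W)
}

# The 4 grid symmetries that extend detection directions from [0, 45] deg to
# the full half-turn [0, 180) (directions d and d+180 share scan lines, so 4
# of the 8 dihedral symmetries suffice): identity (d), transpose (90 - d),
# column flip (180 - d), transpose-of-flip (90 + d). `dir` gives the
# original-frame (col, row) direction of a scan line at angle a (radians) in
# the transformed frame.
grid_symmetries <- function() {
  flip <- function(x) x[, rev(seq_len(ncol(x))), drop = FALSE]
  list(
    list(fwd = identity, inv = identity,
         dir = function(a) c(cos(a), -sin(a))),
    list(fwd = t, inv = t,
         dir = function(a) c(-sin(a), cos(a))),
    list(fwd = flip, inv = flip,
         dir = function(a) c(-cos(a), -sin(a))),
    list(fwd = function(x) t(flip(x)), inv = function(x) flip(t(x)),
         dir = function(a) c(sin(a), cos(a)))
  )
}

#' Arbitrary-angle edge detection
#'
#' Three-step detector: (1) Gaussian-derivative gradient magnitude at scale
#' `sigma`; (2) decomposition of the grid into digital pixel lines at
#' `n_angles` equally spaced angles in `[0, 45]` degrees with per-line
#' non-maximum suppression above a global response threshold; (3) extension
#' of the `[0, 45]` degree machinery to all directions through the symmetries
#' of the square grid, with the per-angle edge maps superimposed (logical OR)
#' into the final edge image. The threshold is the `threshold_quantile`
#' quantile of the positive response values, so detection is invariant to
#' affine intensity rescaling.
#'
#' Each scan family only suppresses pixels whose local gradient lies within
#' `grad_tol_deg` of the scan direction: a scan line running *along* an edge
#' rasterizes into horizontal runs with occasional jogs whose sampled
#' response is a sawtooth, and its spurious maxima would otherwise deposit
#' marks throughout the response skirt parallel to the true edge. With the
#' default tolerance of 45 degrees every gradient orientation is still
#' covered by several scan families.
#'
#' @inheritParams gaussian_gradient
#' @param n_angles number of detection angles in `[0, 45]` degrees (>= 2).
#' @param threshold_quantile quantile of positive responses used as the NMS
#'   floor, in (0, 1).
#' @param connection pixel-combination rule, see [decompose_pixel_lines()].
#' @param grad_tol_deg maximum angle between a pixel's gradient and a scan
#'   family's line direction for the pixel to participate in that family;
#'   `90` disables the gating.
#' @return An `edge_map`. A constant image yields an empty mask.
#' @export
detect_edges <- function(image, sigma = 2, n_angles = 8, threshold_quantile = 0.9,
                         connection = c("compact", "sparse"), grad_tol_deg = 45) {
  connection <- match.arg(connection)
  if (n_angles < 2) guan_abort("guan_param_error", "`n_angles` must be at least 2")
  if (threshold_quantile <= 0 || threshold_quantile >= 1) {
    guan_abort("guan_param_error", "`threshold_quantile` must lie in (0, 1)")
  }
  px <- if (inherits(image, "thermal_image")) image$pixels else image
  gr <- gaussian_gradient_xy(px, sigma)
  resp <- gr$mag
  # responses at rounding level relative to the intensity scale are noise
  floor_resp <- 1e-10 * max(abs(px), 1)
  angles <- seq(0, 45, length.out = n_angles)
  if (max(resp) <= floor_resp) {
    return(edge_map(matrix(FALSE, nrow(px), ncol(px)), angles_used = angles))
  }
  # quantile over the full response field (flat regions included), floored
  # above rounding level: behaves continuously as the sensor noise vanishes
  thr <- max(stats::quantile(resp, threshold_quantile, names = FALSE), floor_resp)
  gate <- grad_tol_deg < 90
  cos_tol <- cos(deg2rad(grad_tol_deg))
  mask <- matrix(FALSE, nrow(px), ncol(px))
  for (sym in grid_symmetries()) {
    rs <- sym$fwd(resp)
    for (a in angles) {
      eligible <- NULL
      if (gate) {
        v <- sym$dir(a * pi / 180)
        # |cos(angle between gradient and scan direction)| >= cos(tol);
        # zero-gradient pixels are below threshold anyway
        eligible <- sym$fwd(abs(gr$gx * v[1L] + gr$gy * v[2L]) >= cos_tol * resp)
      }
      mask <- mask | sym$inv(nms_at_angle(rs, a, thr, connection, eligible))
    }
  }
  edge_map(mask, angles_used = angles)
}
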