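#' Neighbourhood intensity statistics at edge points
#'
#' Establishes a `size x size` pixel region at each edge point of the edge
#' image and computes the intensity mean and population standard deviation
#' of each region. The even-size window is anchored so that a region at
#' `(col, row)` spans rows `[row - size/2, row + size/2 - 1]` and columns
#' `[col - size/2, col + size/2 - 1]`; edge points whose window would leave
#' the image are skipped.
#'
#' @param image a [thermal_image].
#' @param edges an `edge_map` over the same grid.
#' @param size region side length in pixels (even, >= 4).
#' @return A data frame with one row per interior edge point: `col`, `row`,
#'   `mean`, `std`.
#' @export
region_stats <- function(image, edges, size = 10L) {
  if (size %% 2 != 0 || size < 4) {
    guan_abort("guan_param_error", "`size` must be even and at least 4")
  }
  px <- image$pixels
  H <- nrow(px); W <- ncol(px)
  if (!identical(dim(edges$mask), dim(px))) {
    guan_abort("guan_validation_error", "edge map shape does not match the image")
  }
  h <- size %/% 2L
  pts <- mask_coords(edges$mask)
  if (nrow(pts) > 0) {
    interior <- pts[, 2L] - h >= 1L & pts[, 2L] + h - 1L <= H &
      pts[, 1L] - h >= 1L & pts[, 1L] + h - 1L <= W
    pts <- pts[interior, , drop = FALSE]
  }
  if (nrow(pts) == 0) {
    return(data.frame(col = integer(), row = integer(), mean = numeric(), std = numeric()))
  }
  # integral images with a leading zero row/column for O(1) window sums
  S <- matrix(0, H + 1L, W + 1L); S[-1L, -1L] <- apply(apply(px, 2L, cumsum), 1L, cumsum) |> t()
  S2 <- matrix(0, H + 1L, W + 1L); S2[-1L, -1L] <- apply(apply(px^2, 2L, cumsum), 1L, cumsum) |> t()
  r1 <- pts[, 2L] - h; r2 <- pts[, 2L] + h - 1L
  c1 <- pts[, 1L] - h; c2 <- pts[, 1L] + h - 1L
  win_sum <- function(M) {
    M[cbind(r2 + 1L, c2 + 1L)] - M[cbind(r1, c2 + 1L)] -
      M[cbind(r2 + 1L, c1)] + M[cbind(r1, c1)]
  }
  n <- size^2
  mu <- win_sum(S) / n
  v <- pmax(win_sum(S2) / n - mu^2, 0)
  data.frame(col = pts[, 1L], row = pts[, 2L], mean = mu, std = sqrt(v))
}

# Otsu's threshold on a numeric sample: the split maximizing between-class
# variance; returns the midpoint between the two boundary values
# (shift-equivariant).
otsu_split <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 2L || x[n] - x[1L] <= 0) return(NA_real_)
  csum <- cumsum(x)
  k <- seq_len(n - 1L)
  mu0 <- csum[k] / k
  mu1 <- (csum[n] - csum[k]) / (n - k)
  bcv <- k * (n - k) * (mu0 - mu1)^2
  k_best <- which.max(bcv)
  (x[k_best] + x[k_best + 1L]) / 2
}

# Robust image noise estimate: scaled median absolute first difference
# (dominated by locally flat regions).
estimate_noise <- function(px) {
  d <- c(diff(px), diff(t(px)))
  stats::median(abs(d)) / (sqrt(2) * stats::qnorm(0.75))
}

#' Derive mean/std gating thresholds for artery-region selection
#'
#' The radial artery is segmented by gating the per-region intensity mean
#' and standard deviation. `method = "adaptive"` (default) derives the gates
#' from the image's gray histogram: foreground pixels are split off by an
#' Otsu threshold, the forearm skin level is their median and the artery
#' level their upper tail, and the mean floor is placed between the two,
#' nearer the artery (the artery is the warmest structure, so regions
#' straddling its boundary have means around the midpoint of the two
#' levels). The std floor is three times a robust estimate of the image
#' noise, rejecting flat regions (background speckle and saturated stripe
#' interiors) whatever their temperature. When the histogram shows no
#' distinct hot structure the mean floor falls back to an Otsu split of the
#' warm half of the region means. `method = "percentile"` instead uses
#' fixed percentile windows of the region statistics (`mean_pct`,
#' `std_pct`).
#'
#' @param image the [thermal_image] the statistics came from.
#' @param stats data frame from [region_stats()] (>= 10 rows).
#' @param method `"adaptive"` or `"percentile"`.
#' @param mean_pct,std_pct lower/upper percentiles (in percent) for the
#'   percentile method.
#' @return Named list `mean_min`, `mean_max`, `std_min`, `std_max`.
#' @export
derive_thresholds <- function(image, stats, method = c("adaptive", "percentile"),
                              mean_pct = c(70, 99.5), std_pct = c(40, 98)) {
  method <- match.arg(method)
  if (nrow(stats) < 10L) {
    guan_abort("guan_threshold_error",
               sprintf("need at least 10 regions to derive thresholds (got %d)", nrow(stats)))
  }
  m <- stats$mean; s <- stats$std
  if (diff(range(m)) <= .Machine$double.eps * max(1, abs(m[1L])) &&
      diff(range(s)) <= .Machine$double.eps) {
    guan_abort("guan_threshold_error", "degenerate region statistics: all regions identical")
  }
  if (method == "adaptive") {
    px <- image$pixels
    sigma <- estimate_noise(px)
    fg_split <- otsu_split(as.vector(px))
    mean_min <- NA_real_
    if (!is.na(fg_split)) {
      fg <- px[px >= fg_split]
      skin_level <- stats::median(fg)          # forearm skin dominates the foreground
      hot_level <- stats::quantile(fg, 0.999, names = FALSE)  # artery stripe
      if (hot_level - skin_level > 3 * sigma) {
        # gate between the skin level and the artery level, nearer the artery
        mean_min <- skin_level + 0.4 * (hot_level - skin_level)
      }
    }
    if (is.na(mean_min)) {
      # no distinct hot structure in the intensity histogram: fall back to a
      # split of the warm half of the region means
      warm <- m[m >= stats::median(m)]
      mean_min <- otsu_split(warm)
      if (is.na(mean_min)) mean_min <- (stats::median(m) + max(m)) / 2
    }
    list(mean_min = mean_min, mean_max = max(m),
         std_min = 3 * sigma, std_max = max(s))
  } else {
    qm <- stats::quantile(m, mean_pct / 100, names = FALSE)
    qs <- stats::quantile(s, std_pct / 100, names = FALSE)
    list(mean_min = qm[1L], mean_max = qm[2L], std_min = qs[1L], std_max = qs[2L])
  }
}

#' Select radial-artery pixels and per-column centroids
#'
#' Regions whose mean and standard deviation both satisfy the threshold
#' windows are selected; the union of their pixels composes the partial
#' radial-artery image, and the mean row of the selected pixels in each
#' column is recorded for the centerline fit.
#'
#' @param image a [thermal_image].
#' @param stats data frame from [region_stats()].
#' @param thresholds list from [derive_thresholds()].
#' @param size region side length (must match the one used for `stats`).
#' @param band_cols optional `c(first, last)` column window to restrict the
#'   selected regions to (by region center column).
#' @return An `artery_model`: list with `pixels` (unique `(col,row)` matrix),
#'   `columns`, `col_means`, `slope`, `intercept` (NA until fitted).
#' @export
select_artery_pixels <- function(image, stats, thresholds, size = 10L, band_cols = NULL) {
  th <- thresholds
  keep <- stats$mean >= th$mean_min & stats$mean <= th$mean_max &
    stats$std >= th$std_min & stats$std <= th$std_max
  if (!is.null(band_cols)) {
    keep <- keep & stats$col >= band_cols[1L] & stats$col <= band_cols[2L]
  }
  sel <- stats[keep, , drop = FALSE]
  H <- img_height(image)
  h <- size %/% 2L
  if (nrow(sel) > 0) {
    doff <- seq(-h, h - 1L)
    cc <- rep(sel$col, each = size^2) + rep(rep(doff, each = size), nrow(sel))
    rr <- rep(sel$row, each = size^2) + rep(doff, size * nrow(sel))
    key <- unique((cc - 1L) * H + rr)
    col <- ((key - 1L) %/% H) + 1L
    row <- ((key - 1L) %% H) + 1L
  } else {
    col <- integer(0); row <- integer(0)
  }
  cols_with <- sort(unique(col))
  if (length(cols_with) < 2L) {
    guan_abort("guan_artery_error",
               sprintf("artery not found: %d distinct columns selected", length(cols_with)),
               data = list(thresholds = th, n_regions = nrow(sel)))
  }
  cm <- tapply(row, col, mean)
  structure(
    list(pixels = cbind(col = col, row = row),
         columns = cols_with,
         col_means = as.numeric(cm[as.character(cols_with)]),
         slope = NA_real_, intercept = NA_real_),
    class = "artery_model"
  )
}

#' @export
print.artery_model <- function(x, ...) {
  cat(sprintf("<artery_model> %d px over %d columns", nrow(x$pixels), length(x$columns)))
  if (!is.na(x$slope)) cat(sprintf(", line row = %.4f col + %.2f", x$slope, x$intercept))
  cat("\n")
  invisible(x)
}

#' Fit the radial-artery centerline by least squares
#'
#' Ordinary least squares of the per-column mean rows on the column indices.
#'
#' @param model an `artery_model` from [select_artery_pixels()].
#' @return The model with `slope` and `intercept` filled in.
#' @export
fit_artery_line <- function(model) {
  if (length(unique(model$columns)) < 2L) {
    guan_abort("guan_fit_error", "need at least 2 distinct columns to fit the artery line")
  }
  fit <- stats::lm.fit(cbind(1, model$columns), model$col_means)
  model$intercept <- unname(fit$coefficients[1L])
  model$slope <- unname(fit$coefficients[2L])
  model
}

#' Locate the GUAN y coordinate
#'
#' Evaluates the fitted artery line at the GUAN column and rounds
#' half-away-from-zero to a pixel row; the unrounded row is attached as
#' attribute `y_raw` for the millimetre mapping.
#'
#' @param model a fitted `artery_model`.
#' @param x0 GUAN column.
#' @param img_height image height in rows; the result must fall inside.
#' @return Integer row `y0` with attribute `y_raw`.
#' @export
locate_y <- function(model, x0, img_height = Inf) {
  if (is.na(model$slope)) guan_abort("guan_fit_error", "artery line not fitted")
  y_raw <- model$slope * x0 + model$intercept
  y0 <- round_half_away(y_raw)
  if (y0 < 1 || y0 > img_height) {
    guan_abort("guan_localization_error",
               sprintf("predicted row %s lies outside the image", y0),
               data = list(y_raw = y_raw))
  }
  structure(as.integer(y0), y_raw = y_raw)
}
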