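# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# 8-connected components by explicit flood fill (queue-based).
flood_fill_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  labels <- matrix(0L, H, W)
  cur <- 0L
  for (c0 in seq_len(W)) for (r0 in seq_len(H)) {
    if (!mask[r0, c0] || labels[r0, c0] > 0L) next
    cur <- cur + 1L
    queue <- list(c(r0, c0))
    labels[r0, c0] <- cur
    while (length(queue) > 0) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1L] + dr; cc <- p[2L] + dc
        if (r >= 1 && r <= H && cc >= 1 && cc <= W && mask[r, cc] && labels[r, cc] == 0L) {
          labels[r, cc] <- cur
          queue[[length(queue) + 1L]] <- c(r, cc)
        }
      }
    }
  }
  labels
}

# Direct dense correlation with separable Gaussian / Gaussian-derivative
# kernels and half-sample symmetric boundary, evaluated pixel by pixel.
dense_dog_magnitude <- function(px, sigma) {
  r <- ceiling(3.5 * sigma)
  u <- seq(-r, r)
  g <- exp(-u^2 / (2 * sigma^2)); g <- g / sum(g)
  dg <- -(u / sigma^2) * g
  H <- nrow(px); W <- ncol(px)
  reflect <- function(i, n) {
    i <- ifelse(i < 1, 1 - i, i)
    ifelse(i > n, 2 * n + 1 - i, i)
  }
  val <- function(rr, cc) px[reflect(rr, H), reflect(cc, W)]
  gx <- gy <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    sx <- 0; sy <- 0
    for (a in u) for (b in u) {
      v <- val(i + a, j + b)
      sx <- sx + g[a + r + 1] * dg[b + r + 1] * v
      sy <- sy + dg[a + r + 1] * g[b + r + 1] * v
    }
    gx[i, j] <- sx; gy[i, j] <- sy
  }
  sqrt(gx^2 + gy^2)
}

# Strict-local-maximum scan along one ordered value sequence.
brute_line_maxima <- function(v, threshold) {
  n <- length(v)
  out <- logical(n)
  if (n >= 3) for (i in 2:(n - 1)) {
    out[i] <- v[i] > v[i - 1] && v[i] > v[i + 1] && v[i] >= threshold
  }
  out
}

# Windowed mean / population std by direct summation.
brute_region_stats <- function(px, pts, size) {
  h <- size / 2
  out <- NULL
  for (k in seq_len(nrow(pts))) {
    cc <- pts[k, 1]; rr <- pts[k, 2]
    r1 <- rr - h; r2 <- rr + h - 1; c1 <- cc - h; c2 <- cc + h - 1
    if (r1 < 1 || c1 < 1 || r2 > nrow(px) || c2 > ncol(px)) next
    w <- px[r1:r2, c1:c2]
    out <- rbind(out, data.frame(col = cc, row = rr, mean = mean(w),
                                 std = sqrt(mean((w - mean(w))^2))))
  }
  out
}

# Closed-form normal-equations straight-line fit.
normal_equations_fit <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  den <- n * sxx - sx^2
  c(slope = (n * sxy - sx * sy) / den, intercept = (sxx * sy - sx * sxy) / den)
}

# Pinhole ray / tilted-plane intersection: camera at origin looking straight
# down, bracket plane through (0, 0, -h) with z = -h + x * tan(alpha). Ray
# angles proportional to pixel offsets as in the camera model. Returns the
# horizontal along-tilt coordinate and the transverse coordinate of the
# intersection point, in mm.
ray_plane_world <- function(X, Y, geom) {
  dth <- abs(X) / (geom$height_px / 2) * geom$theta_deg * pi / 180
  dbe <- abs(Y) / (geom$width_px / 2) * geom$beta_deg * pi / 180
  al <- geom$alpha_deg * pi / 180
  sx <- sign(X)
  d <- c(sx * sin(dth), sign(Y) * tan(dbe), -cos(dth))
  t_hit <- geom$h_mm / (cos(dth) + sx * sin(dth) * tan(al))
  p <- t_hit * d
  c(x_mm = p[1], y_mm = p[2])
}
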