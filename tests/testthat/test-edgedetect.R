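test_that("gaussian gradient vanishes on constant images and peaks on a step", {
  expect_lt(max(gaussian_gradient(matrix(7, 32, 32), 2)), 1e-12)
  step <- cbind(matrix(0, 32, 16), matrix(1, 32, 16))
  resp <- gaussian_gradient(step, 2)
  # response is maximal at the step columns and symmetric about the boundary
  expect_true(all(resp[, 16] == apply(resp, 1, max) | resp[, 17] == apply(resp, 1, max)))
  for (k in 0:5) expect_equal(resp[, 16 - k], resp[, 17 + k], tolerance = 1e-12)
  expect_error(gaussian_gradient(step, -1), class = "guan_param_error")
})

test_that("gaussian gradient matches a dense convolution oracle", {
  set.seed(42)
  ramp <- outer(seq_len(16), seq_len(16), function(r, c) 0.7 * c + 0.2 * r)
  expect_equal(gaussian_gradient(ramp, 1.5), dense_dog_magnitude(ramp, 1.5),
               tolerance = 1e-10)
  rnd <- matrix(runif(256), 16, 16)
  expect_equal(gaussian_gradient(rnd, 2), dense_dog_magnitude(rnd, 2),
               tolerance = 1e-10)
})

test_that("pixel lines partition the grid at every angle and stay 8-connected", {
  for (conn in c("compact", "sparse")) {
    for (ang in c(0, 10, 22.5, 30, 45)) {
      lines <- decompose_pixel_lines(c(8, 8), ang, conn)
      coords <- do.call(rbind, lapply(lines, `[[`, "coords"))
      keys <- paste(coords[, 1], coords[, 2])
      expect_length(keys, 64)
      expect_false(any(duplicated(keys)))
      for (l in lines) {
        cc <- l$coords
        if (nrow(cc) > 1) {
          d <- abs(diff(cc))
          expect_true(all(d <= 1), info = sprintf("angle %s conn %s", ang, conn))
        }
      }
    }
  }
  expect_error(decompose_pixel_lines(c(8, 8), 60), class = "guan_param_error")
})

test_that("angle 0 gives rows and angle 45 gives all diagonals", {
  l0 <- decompose_pixel_lines(c(4, 4), 0)
  expect_length(l0, 4)
  expect_true(all(vapply(l0, function(l) nrow(l$coords) == 4 &&
                           length(unique(l$coords[, 2])) == 1, logical(1))))
  l45 <- decompose_pixel_lines(c(4, 4), 45)
  expect_length(l45, 7)
  expect_equal(sum(vapply(l45, function(l) nrow(l$coords), integer(1))), 16)
})

test_that("NMS marks exactly the strict local maxima at or above threshold", {
  # monotone response: endpoints are never marked, so nothing is marked
  resp <- matrix(seq_len(5), 1, 5)
  lines <- decompose_pixel_lines(c(1, 5), 0)
  expect_equal(sum(nms_along_lines(resp, lines, 0)$mask), 0)

  resp <- matrix(c(0, 1, 3, 1, 0), 1, 5)
  m <- nms_along_lines(resp, lines, 0.5)$mask
  expect_identical(which(m), 3L)
  # threshold above the peak suppresses it
  expect_equal(sum(nms_along_lines(resp, lines, 3.5)$mask), 0)
})

test_that("NMS agrees with a brute-force per-line scan on random grids", {
  set.seed(7)
  for (rep in 1:5) {
    H <- sample(6:16, 1); W <- sample(6:16, 1)
    resp <- matrix(runif(H * W), H, W)
    thr <- runif(1, 0.2, 0.6)
    for (ang in c(0, 17, 45)) {
      lines <- decompose_pixel_lines(c(H, W), ang)
      got <- nms_along_lines(resp, lines, thr)$mask
      want <- matrix(FALSE, H, W)
      for (l in lines) {
        v <- resp[cbind(l$coords[, 2], l$coords[, 1])]
        mk <- brute_line_maxima(v, thr)
        want[cbind(l$coords[mk, 2], l$coords[mk, 1])] <- TRUE
      }
      expect_identical(got, want, info = sprintf("angle %d, %dx%d", ang, H, W))
    }
  }
})

test_that("the fast per-angle path equals the explicit line-list path", {
  set.seed(8)
  resp <- matrix(runif(20 * 24), 20, 24)
  for (ang in c(0, 6.4, 30, 45)) {
    lines <- decompose_pixel_lines(c(20, 24), ang)
    expect_identical(
      guanloc:::nms_at_angle(resp, ang, 0.5, "compact"),
      nms_along_lines(resp, lines, 0.5)$mask
    )
  }
})

test_that("detect_edges returns an empty map on constant images", {
  img <- thermal_image(matrix(3, 48, 48))
  expect_equal(sum(detect_edges(img)$mask), 0)
})

test_that("a bright disk yields a ring of edge pixels on the circle", {
  H <- 64; W <- 64; R <- 20
  d <- sqrt(outer((seq_len(H) - 32.5)^2, (seq_len(W) - 32.5)^2, `+`))
  px <- matrix(10 + 90 * pmax(0, pmin(1, R + 0.5 - d)), H, W)  # anti-aliased disk
  e <- detect_edges(thermal_image(px), threshold_quantile = 0.9)
  pts <- which(e$mask, arr.ind = TRUE)
  expect_gt(nrow(pts), 40)
  dist_to_circle <- abs(sqrt((pts[, 1] - 32.5)^2 + (pts[, 2] - 32.5)^2) - R)
  expect_gte(mean(dist_to_circle <= 2), 0.95)
})

test_that("edge detection commutes with 90-degree rotation for symmetric angle sets", {
  set.seed(9)
  K <- guanloc:::conv_band_matrix(24, rep(1 / 5, 5))
  img <- K %*% (matrix(runif(24 * 24, 0, 50), 24, 24) %*% t(K)) + 30
  rot90 <- function(m) t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
  m1 <- detect_edges(img, n_angles = 2, threshold_quantile = 0.8)$mask
  m2 <- detect_edges(rot90(img), n_angles = 2, threshold_quantile = 0.8)$mask
  expect_identical(m2, rot90(m1))
})

test_that("the phantom edge map traces the wrist outline across the image", {
  e <- default_edges()
  comp <- max_connected_domain(e)
  expect_true(isTRUE(attr(comp, "border_to_border")))
  expect_gte(diff(range(comp$coords[, 1])), 0.8 * ncol(e$mask))
})
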