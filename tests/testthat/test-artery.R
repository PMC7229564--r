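mask_at <- function(H, W, pts) {
  m <- matrix(FALSE, H, W)
  m[cbind(pts[, 2], pts[, 1])] <- TRUE
  guanloc:::edge_map(m)
}

test_that("region statistics match direct summation", {
  # constant image: zero std everywhere
  img <- thermal_image(matrix(5, 40, 40))
  st <- region_stats(img, mask_at(40, 40, cbind(c(10, 20), c(15, 25))))
  expect_equal(st$mean, c(5, 5))
  expect_equal(st$std, c(0, 0))

  # a 10x10 window holding the values 0..99
  px <- matrix(200, 40, 40)
  px[6:15, 6:15] <- matrix(0:99, 10, 10)
  img2 <- thermal_image(px)
  st2 <- region_stats(img2, mask_at(40, 40, cbind(11, 11)))
  expect_equal(st2$mean, 49.5)
  expect_equal(st2$std, sqrt(mean((0:99 - 49.5)^2)))
  expect_equal(st2$std, 28.86607, tolerance = 1e-5)

  # centers too close to a border are skipped
  st3 <- region_stats(img, mask_at(40, 40, cbind(3, 20)))
  expect_equal(nrow(st3), 0)
  expect_error(region_stats(img, mask_at(40, 40, cbind(20, 20)), size = 7),
               class = "guan_param_error")
})

test_that("region statistics equal the brute-force oracle on random images", {
  set.seed(31)
  px <- matrix(runif(32 * 32, 0, 255), 32, 32)
  img <- thermal_image(px)
  pts <- unique(cbind(sample(6:27, 12, TRUE), sample(6:27, 12, TRUE)))
  got <- region_stats(img, mask_at(32, 32, pts))
  want <- brute_region_stats(px, pts, 10)
  got <- got[order(got$col * 100 + got$row), ]
  want <- want[order(want$col * 100 + want$row), ]
  expect_equal(got$mean, want$mean, tolerance = 1e-9)
  expect_equal(got$std, want$std, tolerance = 1e-9)
})

# cool background with a warm stripe: the classic bimodal fixture
bimodal_fixture <- function(noise = 0.5) {
  set.seed(5)
  px <- matrix(20, 60, 60) + matrix(rnorm(3600, 0, noise), 60, 60)
  px[25:32, ] <- px[25:32, ] + 100
  img <- thermal_image(pmax(px, 0))
  pts <- rbind(cbind(6:55, 25), cbind(6:55, 32), cbind(6:55, 10))
  list(img = img, edges = mask_at(60, 60, pts))
}

test_that("threshold derivation separates the modes of bimodal region statistics", {
  fx <- bimodal_fixture()
  st <- region_stats(fx$img, fx$edges)
  cool <- st$mean[st$mean < 60]; warm <- st$mean[st$mean > 60]
  for (method in c("adaptive", "percentile")) {
    th <- derive_thresholds(fx$img, st, method = method)
    expect_gt(th$mean_min, mean(cool))
    expect_lt(th$mean_min, max(warm))
  }
})

test_that("degenerate statistics raise a threshold error", {
  img <- thermal_image(matrix(50, 40, 40))
  st <- region_stats(img, mask_at(40, 40, cbind(sample(10:30, 12), sample(10:30, 12))))
  expect_error(derive_thresholds(img, st), class = "guan_threshold_error")
  expect_error(derive_thresholds(img, st[0, ]), class = "guan_threshold_error")
})

test_that("thresholds are equivariant under intensity shifts", {
  fx <- bimodal_fixture()
  st <- region_stats(fx$img, fx$edges)
  th <- derive_thresholds(fx$img, st)
  img_up <- thermal_image(fx$img$pixels + 37)
  st_up <- region_stats(img_up, fx$edges)
  th_up <- derive_thresholds(img_up, st_up)
  expect_equal(th_up$mean_min, th$mean_min + 37, tolerance = 1e-6)
  expect_equal(th_up$mean_max, th$mean_max + 37, tolerance = 1e-6)
  expect_equal(th_up$std_min, th$std_min, tolerance = 1e-6)
  expect_equal(th_up$std_max, th$std_max, tolerance = 1e-6)
})

test_that("artery pixel selection composes qualifying regions and their column means", {
  img <- thermal_image(matrix(100, 60, 60))
  st <- data.frame(col = c(20, 40), row = c(25, 25), mean = c(150, 80), std = c(10, 10))
  th <- list(mean_min = 120, mean_max = 200, std_min = 0, std_max = 50)
  model <- select_artery_pixels(img, st, th)
  # only the first region qualifies: rows 20..29, columns 15..24
  expect_equal(model$columns, 15:24)
  expect_true(all(model$col_means == 24.5))
  expect_equal(nrow(model$pixels), 100)

  th_none <- list(mean_min = 500, mean_max = 600, std_min = 0, std_max = 50)
  expect_error(select_artery_pixels(img, st, th_none), class = "guan_artery_error")
})

test_that("the centerline fit is exact least squares", {
  m <- list(columns = c(0, 10, 20), col_means = 0.5 * c(0, 10, 20) + 10,
            pixels = cbind(col = 1, row = 1))
  class(m) <- "artery_model"
  fit <- fit_artery_line(m)
  expect_equal(fit$slope, 0.5, tolerance = 1e-9)
  expect_equal(fit$intercept, 10, tolerance = 1e-9)

  m2 <- m; m2$columns <- c(0, 1, 2); m2$col_means <- c(1, 2, 2)
  fit2 <- fit_artery_line(m2)
  expect_equal(fit2$slope, 0.5, tolerance = 1e-12)
  expect_equal(fit2$intercept, 7 / 6, tolerance = 1e-12)

  set.seed(17)
  m3 <- m; m3$columns <- runif(50, 0, 300); m3$col_means <- runif(50, 0, 200)
  fit3 <- fit_artery_line(m3)
  want <- normal_equations_fit(m3$columns, m3$col_means)
  expect_equal(fit3$slope, unname(want["slope"]), tolerance = 1e-9)
  expect_equal(fit3$intercept, unname(want["intercept"]), tolerance = 1e-9)

  m1col <- m; m1col$columns <- 5; m1col$col_means <- 12
  expect_error(fit_artery_line(m1col), class = "guan_fit_error")
})

test_that("locate_y evaluates the line and validates the image bounds", {
  m <- list(columns = 1:2, col_means = c(33, 33), slope = 0, intercept = 33)
  class(m) <- "artery_model"
  expect_equal(as.integer(locate_y(m, 57, 240)), 33)
  m$slope <- 0.5; m$intercept <- 10
  y <- locate_y(m, 100, 240)
  expect_equal(as.integer(y), 60)
  expect_equal(attr(y, "y_raw"), 60)
  expect_error(locate_y(m, 1000, 240), class = "guan_localization_error")
})

test_that("selection is invariant under a constant intensity shift of the phantom", {
  ph <- default_phantom()
  cfg <- guan_config()
  res1 <- locate_guan(ph$image)
  res2 <- locate_guan(thermal_image(ph$image$pixels + 25))
  expect_equal(res2$x0_px, res1$x0_px)
  expect_equal(res2$y0_px, res1$y0_px)
  expect_equal(res2$diagnostics$n_artery_px, res1$diagnostics$n_artery_px)
})

test_that("the phantom artery is segmented along most of the stripe with accurate slope", {
  for (sl in c(-0.2, 0, 0.2)) {
    sp <- phantom_spec(artery_slope = sl)
    ph <- generate_phantom(sp)
    res <- locate_guan(ph$image)
    cols <- res$diagnostics$n_artery_cols
    stripe_extent <- diff(sp$artery_cols)
    expect_gte(cols, 0.6 * stripe_extent)
    expect_lte(abs(res$diagnostics$artery_slope - ph$truth$artery_line[["slope"]]), 0.05)
    expect_lte(abs(res$y0_px - ph$truth$guan_px[2]), 3)
  }
})
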