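mask_from_coords <- function(H, W, coords) {
  m <- matrix(FALSE, H, W)
  m[cbind(coords[, 2], coords[, 1])] <- TRUE
  m
}

path_key <- function(coords) sort(paste(coords[, 1], coords[, 2]))

test_that("max_connected_domain picks the largest component and flags borders", {
  m <- matrix(FALSE, 10, 20)
  m[2, 3:12] <- TRUE          # 10 px
  m[8, 4:6] <- TRUE           # 3 px
  p <- max_connected_domain(guanloc:::edge_map(m))
  expect_equal(nrow(p$coords), 10)
  expect_false(isTRUE(attr(p, "border_to_border")))

  m2 <- matrix(FALSE, 10, 20)
  m2[5, ] <- TRUE
  p2 <- max_connected_domain(guanloc:::edge_map(m2))
  expect_true(isTRUE(attr(p2, "border_to_border")))

  expect_error(max_connected_domain(guanloc:::edge_map(matrix(FALSE, 5, 5))),
               class = "guan_no_edge_error")
})

test_that("max_connected_domain agrees with a flood-fill oracle on random masks", {
  set.seed(13)
  for (rep in 1:6) {
    n <- sample(c(20, 24), 1)
    m <- matrix(runif(n * n) < 0.25, n, n)
    if (!any(m)) next
    lbl <- flood_fill_components(m)
    sizes <- table(lbl[lbl > 0])
    if (sum(sizes == max(sizes)) > 1) next  # ambiguous winner: skip draw
    want <- which(lbl == as.integer(names(which.max(sizes))), arr.ind = TRUE)
    got <- max_connected_domain(guanloc:::edge_map(m))$coords
    expect_identical(path_key(got), path_key(want[, c(2, 1)]))
  }
})

test_that("connect_breakpoints bridges small gaps into a border-to-border edge", {
  # two horizontal segments, one missing pixel between them
  m <- matrix(FALSE, 9, 20)
  m[5, 1:10] <- TRUE
  m[5, 12:20] <- TRUE
  comp <- max_connected_domain(guanloc:::edge_map(m))
  merged <- connect_breakpoints(guanloc:::edge_map(m), comp)
  expect_true(isTRUE(attr(merged, "border_to_border")))
  expect_equal(nrow(merged$coords), 10 + 9 + 1)
  lbl <- flood_fill_components(mask_from_coords(9, 20, merged$coords))
  expect_equal(max(lbl), 1)

  # three collinear fragments with 2-px gaps
  m3 <- matrix(FALSE, 9, 24)
  m3[4, 1:7] <- TRUE; m3[4, 9:15] <- TRUE; m3[4, 17:24] <- TRUE
  comp3 <- max_connected_domain(guanloc:::edge_map(m3))
  merged3 <- connect_breakpoints(guanloc:::edge_map(m3), comp3)
  expect_true(isTRUE(attr(merged3, "border_to_border")))
  lbl3 <- flood_fill_components(mask_from_coords(9, 24, merged3$coords))
  expect_equal(max(lbl3), 1)

  # a component already spanning both borders is returned unchanged
  mfull <- matrix(FALSE, 9, 20); mfull[3, ] <- TRUE
  compf <- max_connected_domain(guanloc:::edge_map(mfull))
  expect_identical(connect_breakpoints(guanloc:::edge_map(mfull), compf)$coords,
                   compf$coords)

  # nothing within range: the stuck endpoint is reported
  miso <- matrix(FALSE, 9, 20); miso[5, 8:12] <- TRUE
  compi <- max_connected_domain(guanloc:::edge_map(miso))
  err <- tryCatch(connect_breakpoints(guanloc:::edge_map(miso), compi),
                  guan_connection_error = function(e) e)
  expect_s3_class(err, "guan_connection_error")
  expect_equal(unname(err$data$stuck[1]), 8)
})

test_that("cut_branches removes short spurs and keeps long arms", {
  # straight line: unchanged
  line <- pixel_path(cbind(1:20, rep(5, 20)))
  expect_identical(cut_branches(line, 8)$coords, line$coords)

  # T-shape: 20-px horizontal line with a 4-px vertical spur
  tee <- pixel_path(rbind(cbind(1:20, 10), cbind(8, 11:14)))
  cut <- cut_branches(tee, 8)
  expect_equal(nrow(cut$coords), 20)
  expect_true(all(cut$coords[, 2] == 10))

  # plus-shape: long horizontal through-arm, two short vertical spurs
  plus <- pixel_path(rbind(cbind(3:28, 15), cbind(15, 11:14), cbind(15, 16:20)))
  cutp <- cut_branches(plus, 8)
  expect_equal(nrow(cutp$coords), 26)
  expect_true(all(cutp$coords[, 2] == 15))

  # every surviving pixel has at most 2 neighbours
  cc <- cutp$coords
  for (i in seq_len(nrow(cc))) {
    nb <- sum(abs(cc[, 1] - cc[i, 1]) <= 1 & abs(cc[, 2] - cc[i, 2]) <= 1) - 1
    expect_lte(nb, 2)
  }
})

test_that("to_outline reduces paths to one row per column with small-gap interpolation", {
  stair <- pixel_path(cbind(1:10, 1:10))
  o <- to_outline(stair)
  expect_equal(o$rows, 1:10)

  multi <- pixel_path(rbind(cbind(1:5, 10), c(3, 30)))
  expect_equal(to_outline(multi, "upper")$rows, rep(10, 5))
  o_low <- to_outline(multi, "lower")
  expect_equal(o_low$rows[3], 30)

  # a 2-column gap is linearly interpolated
  gap2 <- pixel_path(cbind(c(1, 2, 5, 6), c(10, 10, 16, 16)))
  expect_equal(to_outline(gap2)$rows, c(10, 10, 12, 14, 16, 16))

  gap3 <- pixel_path(cbind(c(1, 2, 6, 7), c(10, 10, 16, 16)))
  expect_error(to_outline(gap3), class = "guan_outline_error")
})

test_that("the extracted phantom outline matches the analytic contour within 1 px RMS", {
  ph <- noiseless_phantom()
  e <- detect_edges(ph$image)
  comp <- cut_branches(max_connected_domain(e))
  o <- to_outline(comp)
  anat <- guanloc:::phantom_anatomy(phantom_spec(noise_sigma = 0))
  err <- o$rows - anat$upper(o$columns)
  expect_lt(sqrt(mean(err^2)), 1)
})
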