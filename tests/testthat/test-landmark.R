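freq_response <- function(b, a, f, fs) {
  w <- 2 * pi * f / fs
  z <- exp(-1i * w * (seq_along(b) - 1))
  abs(sum(b * z) / sum(a * exp(-1i * w * (seq_along(a) - 1))))
}

test_that("the designed low-pass meets its specification", {
  spec <- filter_spec()
  d <- design_lowpass(spec)
  expect_gte(d$order, 1)
  # unit DC gain
  expect_equal(freq_response(d$b, d$a, 0, 70), 1, tolerance = 1e-9)
  # <= 3 dB loss at the passband corner, >= 30 dB at the stopband corner
  expect_gte(freq_response(d$b, d$a, 2, 70), 10^(-3 / 20) * (1 - 1e-6))
  expect_lte(freq_response(d$b, d$a, 3, 70), 10^(-30 / 20))
  expect_error(filter_spec(passband_hz = 5, stopband_hz = 3), class = "guan_param_error")
})

test_that("zero-phase smoothing preserves constants and is symmetric under reversal", {
  x <- rep(42.5, 200)
  expect_lt(max(abs(smooth_outline(x) - 42.5)), 1e-9)

  set.seed(21)
  y <- cumsum(rnorm(300)) / 5 + 100
  expect_equal(rev(smooth_outline(rev(y))), smooth_outline(y), tolerance = 1e-9)

  expect_error(smooth_outline(rep(1, 10)), class = "guan_length_error")
})

test_that("a stopband sinusoid is attenuated by at least the one-pass specification", {
  n <- 0:499
  x <- 100 + sin(2 * pi * 3 / 70 * n)
  y <- smooth_outline(x)
  expect_lte(max(abs(y[100:400] - 100)), 10^(-30 / 20))
})

test_that("smoothing reduces the second differences of a pixel staircase", {
  stair <- 50 + floor(seq(0, 12, length.out = 120))
  sw <- smooth_outline(stair)
  expect_lt(max(abs(diff(sw, differences = 2))),
            max(abs(diff(stair, differences = 2))))
})

test_that("curvature matches closed forms for lines, circles and parabolas", {
  x <- seq_len(100)
  expect_lt(max(abs(curvature(3 + 0.7 * x, x))), 1e-9)

  # circle of radius 50: |kappa| = 1/50 within 2% away from the arc ends
  xs <- seq(-30, 30)
  arc <- 50 - sqrt(50^2 - xs^2)
  k <- curvature(arc, xs)
  interior <- 10:52
  expect_true(all(abs(abs(k[interior]) - 1 / 50) <= 0.02 / 50))

  # parabola y = x^2 at x = 0 has kappa = 2 (0.01 sampling, within 1e-3)
  xp <- seq(-0.5, 0.5, by = 0.01)
  kp <- curvature(xp^2, xp)
  expect_equal(kp[which(xp == 0)], 2, tolerance = 1e-3)

  expect_error(curvature(1:4), class = "guan_length_error")
})

make_outline <- function(rows) outline_profile(seq_along(rows), rows)

two_bump_rows <- function(n = 320, sal = 220, sal_amp = 10, sal_sig = 10,
                          rec = 160, rec_amp = 3, rec_sig = 6, base = 100) {
  cols <- seq_len(n)
  base - sal_amp * exp(-(cols - sal)^2 / (2 * sal_sig^2)) -
    rec_amp * exp(-(cols - rec)^2 / (2 * rec_sig^2))
}

test_that("find_salient returns the apex of the sharpest protrusion", {
  prof <- curvature_profile(make_outline(two_bump_rows()), side = "upper")
  prof <- find_salient(prof)
  expect_lte(abs(prof$salient_x - 220), 1)

  # second bump sharper: it wins the global curvature maximum
  rows2 <- two_bump_rows(sal_amp = 6, sal_sig = 14, rec = 120, rec_amp = 6, rec_sig = 4)
  prof2 <- find_salient(curvature_profile(make_outline(rows2), side = "upper"))
  expect_lte(abs(prof2$salient_x - 120), 1)
  # brute-force confirmation on this profile
  expect_equal(prof2$salient_x, prof2$columns[which.max(prof2$cc)])

  flat <- curvature_profile(make_outline(rep(80, 200)), side = "upper")
  expect_error(find_salient(flat), class = "guan_no_salient_error")
})

test_that("locate_x finds the recess-edge maximum nearest the salient", {
  prof <- find_salient(curvature_profile(make_outline(two_bump_rows()), side = "upper"))
  x0 <- locate_x(prof)
  # the smaller bump lies 60 px left of the salient; its apex is the landmark
  expect_lte(abs(x0 - 160), 2)

  # brute-force scan oracle: nearest strict cc maximum with rising approach
  cc <- prof$cc; cols <- prof$columns
  cand <- rev((prof$salient_x - 99):(prof$salient_x - 1))
  brute <- NA
  for (cx in cand) {
    i <- match(cx, cols)
    up <- mean(prof$up_slope[max(1, i - 5):i])
    if (cc[i] > cc[i - 1] && cc[i] > cc[i + 1] && up > 0) { brute <- cx; break }
  }
  expect_equal(x0, brute)
})

test_that("locate_x honours the half-open finger-width window", {
  # qualifying bump exactly 100 px left of the salient: excluded
  rows <- two_bump_rows(sal = 240, rec = 140)
  prof <- find_salient(curvature_profile(make_outline(rows), side = "upper"))
  expect_equal(prof$salient_x, 240)
  expect_error(locate_x(prof, window_px = 100L), class = "guan_no_guan_x_error")
  expect_lte(abs(locate_x(prof, window_px = 110L) - 140), 2)
})

test_that("locate_x is translation-equivariant", {
  rows <- two_bump_rows()
  shift <- 25
  rows_sh <- two_bump_rows(sal = 220 + shift, rec = 160 + shift)
  x0 <- locate_x(find_salient(curvature_profile(make_outline(rows), side = "upper")))
  x0s <- locate_x(find_salient(curvature_profile(make_outline(rows_sh), side = "upper")))
  # exact up to one pixel: the shifted profile differs near the array ends
  expect_lte(abs(x0s - (x0 + shift)), 1)
})

test_that("both scan orders are available and leftmost differs when two candidates exist", {
  rows <- 100 - 10 * exp(-(seq_len(320) - 250)^2 / 200) -
    3 * exp(-(seq_len(320) - 190)^2 / 72) -
    3 * exp(-(seq_len(320) - 165)^2 / 72)
  prof <- find_salient(curvature_profile(make_outline(rows), side = "upper"))
  near <- locate_x(prof, scan_order = "nearest")
  left <- locate_x(prof, scan_order = "leftmost")
  expect_gte(near, left)
})

test_that("the landmark column is recovered on the phantom within 3 px", {
  ph <- default_phantom()
  res <- locate_guan(ph$image)
  expect_lte(abs(res$x0_px - ph$truth$guan_px[1]), 3)
})
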