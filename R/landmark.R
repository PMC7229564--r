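#' Low-pass filter specification for outline smoothing
#'
#' The raw wrist outline contains one-pixel steps from adjacent rows which
#' corrupt its curvature, so it is smoothed with a minimum-order Butterworth
#' low-pass filter before curvature analysis. One outline column is treated
#' as one sample at `sample_rate` pseudo-Hz, so the default passband corner
#' of 2 Hz at a 70 Hz sample rate corresponds to a spatial cutoff of about
#' 2/70 cycles per pixel (features wider than ~35 px pass).
#'
#' @param sample_rate samples per second equivalent (one column = one sample).
#' @param passband_hz passband corner frequency.
#' @param stopband_hz stopband corner frequency.
#' @param passband_ripple_db maximum passband ripple, dB.
#' @param stopband_atten_db minimum stopband attenuation, dB.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(sample_rate = 70, passband_hz = 2, stopband_hz = 3,
                        passband_ripple_db = 3, stopband_atten_db = 30) {
  if (!(passband_hz < stopband_hz && stopband_hz < sample_rate / 2)) {
    guan_abort("guan_param_error",
               "need passband_hz < stopband_hz < sample_rate / 2")
  }
  structure(
    list(sample_rate = sample_rate, passband_hz = passband_hz,
         stopband_hz = stopband_hz, passband_ripple_db = passband_ripple_db,
         stopband_atten_db = stopband_atten_db),
    class = "filter_spec"
  )
}

#' Design the minimum-order Butterworth low-pass meeting a filter_spec
#'
#' @param spec a [filter_spec].
#' @return List with numerator `b`, denominator `a` and the design `order`.
#' @export
design_lowpass <- function(spec = filter_spec()) {
  nyq <- spec$sample_rate / 2
  ord <- signal::buttord(spec$passband_hz / nyq, spec$stopband_hz / nyq,
                         spec$passband_ripple_db, spec$stopband_atten_db)
  flt <- signal::butter(ord)
  # renormalize the numerator so the DC gain is exactly 1 (the high-order
  # transfer-function coefficients otherwise carry ~1e-9 rounding)
  b <- flt$b * sum(flt$a) / sum(flt$b)
  list(b = b, a = flt$a, order = ord$n)
}

# Zero-phase IIR filtering, exactly symmetric under time reversal: the
# forward-backward result is averaged with the backward-forward result
# computed on the reversed signal, so filtering commutes with reversal by
# construction and landmark columns are not shifted.
zero_phase_filter <- function(b, a, x) {
  (zero_phase_once(b, a, x) + rev(zero_phase_once(b, a, rev(x)))) / 2
}

# One forward-backward pass over an odd-reflection padded signal, each pass
# started from matched initial conditions (the standard filtfilt
# construction), so a constant signal is reproduced exactly.
zero_phase_once <- function(b, a, x) {
  # filter about the signal mean: with exact unit DC gain this makes
  # constant signals pass through unchanged regardless of the conditioning
  # of the initial-state solve
  m <- mean(x)
  m + zero_phase_core(b, a, x - m)
}

zero_phase_core <- function(b, a, x) {
  nfilt <- max(length(a), length(b))
  b <- c(b, rep(0, nfilt - length(b)))
  a <- c(a, rep(0, nfilt - length(a)))
  nfact <- 3L * (nfilt - 1L)
  n <- length(x)
  if (n <= nfact) {
    guan_abort("guan_length_error",
               sprintf("signal of length %d too short for filter of order %d", n, nfilt - 1L))
  }
  # steady-state initial conditions (unit-step matched)
  m <- nfilt - 1L
  A <- diag(1, m) - cbind(-a[2:nfilt], rbind(diag(1, m - 1L), rep(0, m - 1L)))
  zi <- solve(A, b[2:nfilt] - b[1L] * a[2:nfilt])
  xext <- c(2 * x[1L] - x[(nfact + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - nfact)])
  y <- df2t_filter(b, a, xext, zi * xext[1L])
  y <- rev(df2t_filter(b, a, rev(y), zi * y[length(y)]))
  y[(nfact + 1L):(nfact + n)]
}

# Direct-form II transposed IIR filter with explicit initial state.
df2t_filter <- function(b, a, x, zi) {
  n <- length(x)
  m <- length(zi)
  y <- numeric(n)
  z <- zi
  for (i in seq_len(n)) {
    xi <- x[i]
    yi <- b[1L] * xi + z[1L]
    if (m > 1L) {
      z[1:(m - 1L)] <- b[2:m] * xi + z[2:m] - a[2:m] * yi
    }
    z[m] <- b[m + 1L] * xi - a[m + 1L] * yi
    y[i] <- yi
  }
  y
}

#' Smooth a wrist outline with the specified low-pass filter
#'
#' Applies the minimum-order Butterworth design meeting `spec` in zero-phase
#' (forward-backward) form, so the smoothed outline `sw(x)` is not shifted
#' relative to the raw outline and the landmark columns stay put. Output has
#' the same length as the input.
#'
#' @param outline an [outline_profile] (or a numeric vector of row values).
#' @param spec a [filter_spec].
#' @return Numeric vector of smoothed outline values.
#' @export
smooth_outline <- function(outline, spec = filter_spec()) {
  x <- if (inherits(outline, "outline_profile")) outline$rows else as.numeric(outline)
  d <- design_lowpass(spec)
  if (length(x) < 3L * d$order) {
    guan_abort("guan_length_error",
               sprintf("outline length %d is shorter than 3 x filter order (%d)",
                       length(x), 3L * d$order))
  }
  zero_phase_filter(d$b, d$a, x)
}

#' Signed curvature of a sampled plane curve
#'
#' Computes `kappa(x) = s'' / (1 + s'^2)^(3/2)` by central finite differences
#' (one-sided at the endpoints) for a single-valued profile sampled at unit
#' column spacing. With row values as input, a protrusion of the upper
#' outline (a bump toward smaller rows) is a local minimum of the profile
#' and therefore has positive curvature.
#'
#' @param sw_values smoothed outline values.
#' @param columns sample positions (uniform spacing; unit spacing for image
#'   columns).
#' @return Numeric vector of curvature values, same length as the input.
#' @export
curvature <- function(sw_values, columns = seq_along(sw_values)) {
  s <- as.numeric(sw_values)
  n <- length(s)
  if (n < 5L) guan_abort("guan_length_error", "need at least 5 points for curvature")
  h <- if (length(columns) == n) mean(diff(columns)) else 1
  d1 <- numeric(n); d2 <- numeric(n)
  d1[2:(n - 1L)] <- (s[3:n] - s[1:(n - 2L)]) / (2 * h)
  d1[1L] <- (s[2L] - s[1L]) / h
  d1[n] <- (s[n] - s[n - 1L]) / h
  d2[2:(n - 1L)] <- (s[3:n] - 2 * s[2:(n - 1L)] + s[1:(n - 2L)]) / h^2
  d2[1L] <- (s[3L] - 2 * s[2L] + s[1L]) / h^2
  d2[n] <- (s[n] - 2 * s[n - 1L] + s[n - 2L]) / h^2
  d2 / (1 + d1^2)^1.5
}

#' Curvature profile of a smoothed outline
#'
#' Convenience constructor: smooths the outline, computes its curvature
#' `cc(x)` in the orientation-normalized frame (protrusions positive for the
#' chosen side) and the outward slope used by the landmark gate.
#'
#' @param outline an [outline_profile].
#' @param spec a [filter_spec].
#' @param side which outline the profile describes; `"upper"` means the
#'   radial side lies on top of the image (smaller rows).
#' @return An object of class `curvature_profile` with fields `columns`,
#'   `sw` (smoothed row values), `cc`, `up_slope` (outward slope of `sw`)
#'   and `salient_x` (NA until [find_salient()] is run).
#' @export
curvature_profile <- function(outline, spec = filter_spec(), side = c("upper", "lower")) {
  side <- match.arg(side)
  sw <- smooth_outline(outline, spec)
  f <- if (side == "upper") sw else -sw
  cc <- curvature(f, outline$columns)
  n <- length(f)
  d1 <- numeric(n)
  d1[2:(n - 1L)] <- (f[3:n] - f[1:(n - 2L)]) / 2
  d1[1L] <- f[2L] - f[1L]; d1[n] <- f[n] - f[n - 1L]
  structure(
    list(columns = outline$columns, sw = sw, cc = cc,
         up_slope = -d1,  # outward (toward the protrusion side) slope
         side = side, salient_x = NA_integer_),
    class = "curvature_profile"
  )
}

#' @export
print.curvature_profile <- function(x, ...) {
  cat(sprintf("<curvature_profile> cols %d..%d, side %s, salient %s\n",
              x$columns[1], x$columns[length(x$columns)], x$side,
              ifelse(is.na(x$salient_x), "not located", x$salient_x)))
  invisible(x)
}

#' Find the styloid salient on a curvature profile
#'
#' The salient is the most convex point of the outline - the column of the
#' global maximum of positive curvature, the radial styloid protrusion.
#' Ties go to the smallest column.
#'
#' @param profile a `curvature_profile`.
#' @return The profile with `salient_x` set.
#' @export
find_salient <- function(profile) {
  cc <- profile$cc
  if (!any(cc > 0)) {
    guan_abort("guan_no_salient_error", "no positive-curvature point on the outline")
  }
  profile$salient_x <- profile$columns[which.max(cc)]
  profile
}

#' Locate the GUAN x coordinate
#'
#' Scans the curvature curve within one finger width (default 100 px) to the
#' left of the styloid salient and returns the first column that is a strict
#' local maximum of `cc(x)` with positive outward slope of `sw(x)` - the
#' recess-edge bump adjoining the styloid. `scan_order = "nearest"` (default)
#' scans from the salient leftward so the recess feature nearest the salient
#' is found first; `"leftmost"` scans rightward from the window start. The
#' window is open at both ends: the salient column itself and the column
#' exactly `window_px` away are excluded.
#'
#' @param profile a `curvature_profile` with `salient_x` set (see
#'   [find_salient()]).
#' @param window_px finger-width search window in pixels.
#' @param scan_order `"nearest"` or `"leftmost"`.
#' @return The x0 column index.
#' @export
locate_x <- function(profile, window_px = 100L, scan_order = c("nearest", "leftmost")) {
  scan_order <- match.arg(scan_order)
  sal <- profile$salient_x
  if (is.na(sal)) guan_abort("guan_no_salient_error", "salient not located; run find_salient()")
  cols <- profile$columns
  lo <- max(cols[1L] + 1L, sal - window_px + 1L)
  hi <- sal - 1L
  if (hi < lo) {
    guan_abort("guan_no_guan_x_error", "search window left of the salient is empty",
               data = list(salient_x = sal))
  }
  cand <- lo:hi
  if (scan_order == "nearest") cand <- rev(cand)
  ix <- match(cand, cols)
  cc <- profile$cc
  # The slope gate is evaluated as the mean outward slope over the columns
  # leading into the candidate from the left: at the apex of a small
  # recess-edge bump the pointwise central difference is zero by symmetry,
  # while the approach from the recess side is what the rule requires to
  # rise.
  gate_slope <- function(i) {
    mean(profile$up_slope[max(1L, i - 5L):i])
  }
  for (k in seq_along(cand)) {
    i <- ix[k]
    if (is.na(i) || i <= 1L || i >= length(cc)) next
    if (cc[i] > cc[i - 1L] && cc[i] > cc[i + 1L] && gate_slope(i) > 0) {
      return(cand[k])
    }
  }
  win <- match(lo:hi, cols)
  guan_abort(
    "guan_no_guan_x_error",
    sprintf("no strict curvature maximum with positive slope within %d px left of the salient",
            window_px),
    data = list(salient_x = sal, window_columns = lo:hi,
                cc = cc[win], up_slope = profile$up_slope[win])
  )
}
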