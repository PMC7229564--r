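#' @keywords internal
#' Signal a structured guanloc error.
#'
#' All pipeline failures carry a subclass (e.g. "guan_no_edge_error") so
#' callers and the stage wrapper in [locate_guan()] can react to the failure
#' mode, plus a `data` list with diagnostic payload.
#' @noRd
guan_abort <- function(class, message, data = list()) {
  cond <- structure(
    class = c(class, "guan_error", "error", "condition"),
    list(message = message, call = sys.call(-1), data = data)
  )
  stop(cond)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero to an integer.
#'
#' Pixel coordinates are reported as whole pixels; `round()` in R rounds half
#' to even, which would make the reported row depend on the parity of the
#' neighbour. Half-away-from-zero is used instead and the unrounded value is
#' kept in diagnostics.
#' @noRd
round_half_away <- function(x) trunc(x + 0.5 * sign(x))
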