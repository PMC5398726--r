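#' Round half away from zero
#'
#' Commercial rounding (0.5 always rounds up in magnitude), used for the
#' integer percentages reported in the coverage, overlap and dosimetry tables;
#' base `round()` rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
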