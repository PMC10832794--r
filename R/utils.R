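# Shared small helpers.

deg2rad <- function(x) x * pi / 180

#' Normalise a relative azimuth to [0, 180] degrees
#'
#' The kernel-driven BRDF model and the two-leaf mixture depend on the
#' sun-sensor azimuth difference only through its absolute value folded
#' into [0, 180].
#'
#' @param phi_v,phi_s View and solar azimuth in degrees.
#' @return Relative azimuth in degrees, in [0, 180].
#' @export
relative_azimuth <- function(phi_v, phi_s) {
  d <- abs((phi_v - phi_s) %% 360)
  ifelse(d > 180, 360 - d, d)
}

stopifnot_finite <- function(x, name) {
  if (!all(is.finite(x))) {
    stop(sprintf("non-finite values in %s", name), call. = FALSE)
  }
}

# Sample standard deviation, NA-tolerant.
sd_na <- function(x) stats::sd(x, na.rm = TRUE)
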