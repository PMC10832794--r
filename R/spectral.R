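# Spectral retrieval: whiteboard-corrected reflectance, PRI, and
# 3FLD-retrieved SIF from per-angle radiance/irradiance spectra.

#' Construct a spectrum
#'
#' A light container for a single hyperspectral measurement: reflected
#' canopy radiance (W m-2 um-1 sr-1), downwelling irradiance
#' (W m-2 um-1), or a derived reflectance.
#'
#' @param wavelengths Strictly increasing wavelength grid in nm.
#' @param values Spectral values, finite, same length as `wavelengths`.
#' @param kind One of `"reflected"`, `"downwelling"`, `"reflectance"`.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(wavelengths, values,
                     kind = c("reflected", "downwelling", "reflectance")) {
  kind <- match.arg(kind)
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  if (length(wavelengths) != length(values)) {
    stop("wavelengths and values must have equal length", call. = FALSE)
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  stopifnot_finite(values, "spectrum values")
  if (kind == "reflectance" && any(values < 0 | values > 1.5)) {
    stop("reflectance values outside [0, 1.5]; check calibration",
         call. = FALSE)
  }
  structure(list(wavelengths = wavelengths, values = values, kind = kind),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d samples, %.0f-%.0f nm>\n",
              x$kind, length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Whiteboard calibration pair
#'
#' Holds the reference-panel reflected radiance L' and synchronous
#' downwelling irradiance E' used by the whiteboard correction.
#'
#' @param wavelengths Wavelength grid in nm, strictly increasing.
#' @param board_reflected Panel reflected radiance L', all > 0.
#' @param board_downwelling Panel downwelling irradiance E', all > 0.
#' @return An object of class `whiteboard_calibration`.
#' @export
whiteboard_calibration <- function(wavelengths, board_reflected,
                                   board_downwelling) {
  wavelengths <- as.numeric(wavelengths)
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (length(board_reflected) != length(wavelengths) ||
      length(board_downwelling) != length(wavelengths)) {
    stop("calibration vectors must match the wavelength grid", call. = FALSE)
  }
  if (any(board_reflected <= 0) || any(board_downwelling <= 0)) {
    stop("calibration values must be strictly positive", call. = FALSE)
  }
  structure(list(wavelengths = wavelengths,
                 board_reflected = as.numeric(board_reflected),
                 board_downwelling = as.numeric(board_downwelling)),
            class = "whiteboard_calibration")
}

#' Identity whiteboard calibration
#'
#' A calibration with L' = E' = 1 on the given grid, under which the
#' whiteboard correction reduces to R = L / E. Used for pre-calibrated
#' instruments and by the synthetic generator.
#'
#' @param wavelengths Wavelength grid in nm.
#' @return A `whiteboard_calibration`.
#' @export
identity_calibration <- function(wavelengths) {
  whiteboard_calibration(wavelengths, rep(1, length(wavelengths)),
                         rep(1, length(wavelengths)))
}

# Grids must agree sample-by-sample to within 0.5 nm; coarser mismatch
# is an error, never an interpolation.
check_grid <- function(a, b, what) {
  if (length(a) != length(b) || any(abs(a - b) > 0.5)) {
    stop(sprintf("wavelength grid mismatch between %s", what), call. = FALSE)
  }
}

#' Retrieve reflectance by whiteboard correction
#'
#' Computes canopy reflectance from reflected radiance L and downwelling
#' irradiance E with the reference-panel pair (L', E') as
#' R = (L * L') / (E * E'), evaluated elementwise. Values outside
#' \[0, 1\] are flagged in the attached QC mask, not clipped.
#'
#' @param reflected `spectrum` of kind `"reflected"`.
#' @param downwelling `spectrum` of kind `"downwelling"`, values > 0.
#' @param cal A `whiteboard_calibration` on the same grid.
#' @return A `spectrum` of kind `"reflectance"` with attribute
#'   `qc_out_of_range` (logical mask of samples outside \[0, 1\]).
#' @export
calibrate_reflectance <- function(reflected, downwelling, cal) {
  stopifnot(inherits(reflected, "spectrum"), inherits(downwelling, "spectrum"),
            inherits(cal, "whiteboard_calibration"))
  check_grid(reflected$wavelengths, downwelling$wavelengths,
             "reflected and downwelling spectra")
  check_grid(reflected$wavelengths, cal$wavelengths,
             "spectra and calibration")
  if (any(downwelling$values <= 0)) {
    stop("downwelling irradiance must be strictly positive", call. = FALSE)
  }
  r <- (reflected$values * cal$board_reflected) /
    (downwelling$values * cal$board_downwelling)
  out <- structure(list(wavelengths = reflected$wavelengths, values = r,
                        kind = "reflectance"),
                   class = "spectrum")
  attr(out, "qc_out_of_range") <- r < 0 | r > 1
  out
}

# Mean of all grid samples within +/- bandwidth nm of a band center.
band_mean <- function(wavelengths, values, center, bandwidth) {
  idx <- which(abs(wavelengths - center) <= bandwidth)
  if (length(idx) == 0L) {
    stop(sprintf("no grid samples within %.2f nm of %.1f nm",
                 bandwidth, center), call. = FALSE)
  }
  mean(values[idx])
}

#' PRI band configuration
#'
#' @param lambda_531,lambda_570 Band centers in nm (defaults 531 and 570).
#' @param bandwidth Half-width in nm for band averaging (default 1).
#' @return A `pri_band_config` list.
#' @export
pri_band_config <- function(lambda_531 = 531, lambda_570 = 570,
                            bandwidth = 1) {
  if (lambda_531 < 350 || lambda_531 > 800 ||
      lambda_570 < 350 || lambda_570 > 800) {
    stop("PRI bands must lie inside the 350-800 nm spectrometer range",
         call. = FALSE)
  }
  structure(list(lambda_531 = lambda_531, lambda_570 = lambda_570,
                 bandwidth = bandwidth), class = "pri_band_config")
}

#' Photochemical reflectance index
#'
#' PRI = (R531 - R570) / (R531 + R570), where R531 and R570 are the mean
#' reflectance within the configured half-width of each band center.
#'
#' @param reflectance A `spectrum` of kind `"reflectance"`.
#' @param cfg A [pri_band_config()].
#' @return PRI, a scalar in \[-1, 1\].
#' @export
compute_pri <- function(reflectance, cfg = pri_band_config()) {
  stopifnot(inherits(reflectance, "spectrum"))
  if (reflectance$kind != "reflectance") {
    stop("compute_pri requires a reflectance spectrum", call. = FALSE)
  }
  r531 <- band_mean(reflectance$wavelengths, reflectance$values,
                    cfg$lambda_531, cfg$bandwidth)
  r570 <- band_mean(reflectance$wavelengths, reflectance$values,
                    cfg$lambda_570, cfg$bandwidth)
  if (r531 + r570 == 0) {
    stop("undefined PRI: R531 + R570 = 0", call. = FALSE)
  }
  (r531 - r570) / (r531 + r570)
}

#' FLD band configuration for the O2-A feature
#'
#' Defaults place the absorption-line center at 762 nm with outer bands
#' at 758 and 769 nm.
#'
#' @param lambda_in Absorption-line center, nm.
#' @param lambda_left,lambda_right Outer band centers, nm.
#' @param bandwidth Half-width in nm for band averaging (default 1).
#' @return An `fld_band_config` list.
#' @export
fld_band_config <- function(lambda_in = 762, lambda_left = 758,
                            lambda_right = 769, bandwidth = 1) {
  if (!(lambda_left < lambda_in && lambda_in < lambda_right)) {
    stop("require lambda_left < lambda_in < lambda_right", call. = FALSE)
  }
  structure(list(lambda_in = lambda_in, lambda_left = lambda_left,
                 lambda_right = lambda_right, bandwidth = bandwidth),
            class = "fld_band_config")
}

#' 3FLD outer-band weights
#'
#' The two outer bands are combined with weights proportional to the
#' spectral distance of the opposite band from the line center:
#' w_left = (lambda_right - lambda_in) / (lambda_right - lambda_left),
#' w_right = 1 - w_left.
#'
#' @param cfg An [fld_band_config()].
#' @return Named numeric vector `c(w_left =, w_right =)` summing to 1.
#' @export
fld_weights <- function(cfg = fld_band_config()) {
  span <- cfg$lambda_right - cfg$lambda_left
  if (span == 0) stop("degenerate band: lambda_right = lambda_left",
                      call. = FALSE)
  w_left <- (cfg$lambda_right - cfg$lambda_in) / span
  c(w_left = w_left, w_right = 1 - w_left)
}

#' Retrieve SIF by three-band Fraunhofer Line Discrimination
#'
#' Exploits the O2-A absorption dip: inside the line the reflected
#' signal is dominated relatively more by fluorescence than outside.
#' With band means L_in, E_in at the line center and weighted averages
#' L_out, E_out of the two outer bands,
#' SIF = (E_out * L_in - E_in * L_out) / (E_out - E_in).
#' The retrieval is exact when reflectance and fluorescence are
#' spectrally constant across the three bands. Negative retrievals are
#' returned with a QC flag, not clipped.
#'
#' @param reflected `spectrum` of kind `"reflected"` (canopy radiance).
#' @param downwelling `spectrum` of kind `"downwelling"`.
#' @param cfg An [fld_band_config()].
#' @return SIF in the radiance units of `reflected`, with attribute
#'   `qc_negative` (TRUE when the retrieval is negative).
#' @export
retrieve_sif_3fld <- function(reflected, downwelling,
                              cfg = fld_band_config()) {
  stopifnot(inherits(reflected, "spectrum"), inherits(downwelling, "spectrum"))
  check_grid(reflected$wavelengths, downwelling$wavelengths,
             "reflected and downwelling spectra")
  w <- fld_weights(cfg)
  wl <- reflected$wavelengths
  l_in <- band_mean(wl, reflected$values, cfg$lambda_in, cfg$bandwidth)
  e_in <- band_mean(wl, downwelling$values, cfg$lambda_in, cfg$bandwidth)
  l_out <- w[["w_left"]] *
    band_mean(wl, reflected$values, cfg$lambda_left, cfg$bandwidth) +
    w[["w_right"]] *
    band_mean(wl, reflected$values, cfg$lambda_right, cfg$bandwidth)
  e_out <- w[["w_left"]] *
    band_mean(wl, downwelling$values, cfg$lambda_left, cfg$bandwidth) +
    w[["w_right"]] *
    band_mean(wl, downwelling$values, cfg$lambda_right, cfg$bandwidth)
  if (abs(e_out - e_in) <= 1e-9 * max(abs(e_out), abs(e_in))) {
    stop("no absorption contrast: E_out equals E_in", call. = FALSE)
  }
  sif <- (e_out * l_in - e_in * l_out) / (e_out - e_in)
  attr(sif, "qc_negative") <- sif < 0
  sif
}

#' Process one multi-angle scan into per-direction indices
#'
#' Applies whiteboard correction, PRI, and 3FLD SIF retrieval to every
#' directional record of a half-hour angular scan, and extracts the
#' red-band reflectance used downstream as the sunlit-fraction input.
#'
#' @param scan Long-format data frame with columns `timestamp`,
#'   `record_id`, `view_zenith_deg`, `view_azimuth_deg`,
#'   `solar_zenith_deg`, `solar_azimuth_deg`, `wavelength_nm`,
#'   `reflected_radiance`, `downwelling_irradiance` (one row per record
#'   per wavelength).
#' @param cal A `whiteboard_calibration`; defaults to the identity
#'   calibration on the scan's grid.
#' @param pri_cfg A [pri_band_config()].
#' @param fld_cfg An [fld_band_config()].
#' @param lambda_pt Wavelength (nm) at which per-angle reflectance is
#'   extracted for the two-leaf sunlit fraction (default 670).
#' @return Data frame with one row per directional record: timestamp,
#'   geometry columns, `pri`, `sif`, `refl_670`, `qc_negative_sif`,
#'   `qc_reflectance_range`.
#' @export
process_angular_scan <- function(scan, cal = NULL,
                                 pri_cfg = pri_band_config(),
                                 fld_cfg = fld_band_config(),
                                 lambda_pt = 670) {
  needed <- c("timestamp", "record_id", "view_zenith_deg", "view_azimuth_deg",
              "solar_zenith_deg", "solar_azimuth_deg", "wavelength_nm",
              "reflected_radiance", "downwelling_irradiance")
  if (!all(needed %in% names(scan))) {
    stop("scan is missing required columns: ",
         paste(setdiff(needed, names(scan)), collapse = ", "), call. = FALSE)
  }
  if (nrow(scan) == 0L) stop("empty scan", call. = FALSE)

  ids <- unique(scan$record_id)
  grid <- sort(unique(scan$wavelength_nm))
  if (is.null(cal)) cal <- identity_calibration(grid)

  rows <- lapply(ids, function(id) {
    rec <- scan[scan$record_id == id, , drop = FALSE]
    rec <- rec[order(rec$wavelength_nm), , drop = FALSE]
    refl <- spectrum(rec$wavelength_nm, rec$reflected_radiance, "reflected")
    down <- spectrum(rec$wavelength_nm, rec$downwelling_irradiance,
                     "downwelling")
    r <- calibrate_reflectance(refl, down, cal)
    sif <- retrieve_sif_3fld(refl, down, fld_cfg)
    data.frame(
      timestamp = rec$timestamp[1],
      record_id = id,
      view_zenith_deg = rec$view_zenith_deg[1],
      view_azimuth_deg = rec$view_azimuth_deg[1],
      solar_zenith_deg = rec$solar_zenith_deg[1],
      solar_azimuth_deg = rec$solar_azimuth_deg[1],
      pri = compute_pri(r, pri_cfg),
      sif = as.numeric(sif),
      refl_670 = band_mean(r$wavelengths, r$values, lambda_pt,
                           pri_cfg$bandwidth),
      qc_negative_sif = isTRUE(attr(sif, "qc_negative")),
      qc_reflectance_range = any(attr(r, "qc_out_of_range")),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
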