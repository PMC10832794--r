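# Two-leaf decomposition: split each angular PRI/SIF field into sunlit
# and shaded leaf components and form the LAI-weighted canopy total.

#' Two-leaf model configuration
#'
#' @param omega Leaf clumping index, in (0, 1\]; default 0.9.
#' @param leaf_reflectance_670 Leaf-level reflectance at `lambda_pt`
#'   (supplied externally, e.g. from a PROSPECT run; default 0.05, a
#'   typical red-band value for healthy rice leaves).
#' @param lambda_pt Wavelength (nm) at which the sunlit fraction is
#'   computed from the canopy/leaf reflectance ratio; default 670.
#' @param clamp_negative_sif Clamp negative SIF component solutions to 0
#'   (with a QC flag)? Default TRUE. PRI components are never clamped.
#' @return A `two_leaf_config` list.
#' @export
two_leaf_config <- function(omega = 0.9, leaf_reflectance_670 = 0.05,
                            lambda_pt = 670, clamp_negative_sif = TRUE) {
  if (omega <= 0 || omega > 1) stop("omega must be in (0, 1]", call. = FALSE)
  if (leaf_reflectance_670 <= 0 || leaf_reflectance_670 >= 1) {
    stop("leaf reflectance must be in (0, 1)", call. = FALSE)
  }
  structure(list(omega = omega,
                 leaf_reflectance_670 = leaf_reflectance_670,
                 lambda_pt = lambda_pt,
                 clamp_negative_sif = clamp_negative_sif),
            class = "two_leaf_config")
}

#' Background (non-leaf) fraction seen at a view zenith
#'
#' Gap-fraction form P_VG = exp(-0.5 * omega * LAI / cos theta): the
#' probability of seeing through the canopy to the background at view
#' zenith theta.
#'
#' @param lai Leaf area index, >= 0.
#' @param theta_v View zenith, degrees, < 90.
#' @param cfg A [two_leaf_config()].
#' @return P_VG in \[0, 1\]. Vectorised over `lai` and `theta_v`.
#' @export
background_fraction <- function(lai, theta_v, cfg = two_leaf_config()) {
  if (any(theta_v >= 90) || any(theta_v < 0)) {
    stop("view zenith must be in [0, 90) degrees", call. = FALSE)
  }
  if (any(lai < 0)) stop("LAI must be nonnegative", call. = FALSE)
  exp(-0.5 * cfg$omega * lai / cos(deg2rad(theta_v)))
}

#' Sunlit-leaf fraction from the red-band reflectance ratio
#'
#' P_T = R_canopy(670) / R_leaf(670), clamped into \[0, 1 - P_VG\] so
#' the fractions can close. Clamping is recorded in the
#' `clamped` attribute.
#'
#' @param canopy_refl_670 Per-angle canopy reflectance at the
#'   configured wavelength.
#' @param p_vg Background fraction at the same angle.
#' @param cfg A [two_leaf_config()].
#' @return P_T, vectorised, with logical attribute `clamped`.
#' @export
sunlit_fraction <- function(canopy_refl_670, p_vg, cfg = two_leaf_config()) {
  if (cfg$leaf_reflectance_670 <= 0) {
    stop("leaf reflectance must be positive", call. = FALSE)
  }
  raw <- canopy_refl_670 / cfg$leaf_reflectance_670
  p_t <- pmin(pmax(raw, 0), 1 - p_vg)
  attr(p_t, "clamped") <- raw != p_t
  p_t
}

#' Shaded-leaf fraction by closure
#'
#' P_S = 1 - P_T - P_VG.
#'
#' @param p_t Sunlit fraction.
#' @param p_vg Background fraction.
#' @return P_S >= 0, vectorised.
#' @export
shaded_fraction <- function(p_t, p_vg) {
  if (any(p_t + p_vg > 1 + 1e-12)) {
    stop("p_t + p_vg exceeds 1; clamp the sunlit fraction first",
         call. = FALSE)
  }
  pmax(1 - p_t - p_vg, 0)
}

#' Sunlit and shaded leaf area
#'
#' L_sun = 2 cos theta (1 - exp(-0.5 omega LAI / cos theta)),
#' L_sh = LAI - L_sun, with theta the solar zenith angle.
#'
#' @param lai Leaf area index, >= 0.
#' @param theta_s Solar zenith, degrees, < 90.
#' @param cfg A [two_leaf_config()].
#' @return Named list `l_sun`, `l_sh`; their sum equals `lai` exactly.
#' @export
sunlit_shaded_lai <- function(lai, theta_s, cfg = two_leaf_config()) {
  if (any(theta_s >= 90) || any(theta_s < 0)) {
    stop("solar zenith must be in [0, 90) degrees", call. = FALSE)
  }
  if (any(lai < 0)) stop("LAI must be nonnegative", call. = FALSE)
  ct <- cos(deg2rad(theta_s))
  l_sun <- 2 * ct * (1 - exp(-0.5 * cfg$omega * lai / ct))
  # Saturating canopies: the projected sunlit area cannot exceed LAI.
  l_sun <- pmin(l_sun, lai)
  list(l_sun = l_sun, l_sh = lai - l_sun)
}

#' Solve the sunlit/shaded component values for one angular scan
#'
#' Least-squares solution (no intercept) of the per-direction mixture
#' rho_obs = P_T * rho_sun + P_S * rho_sh over all directions of one
#' rotation cycle.
#'
#' @param rho Per-direction index values (PRI or SIF).
#' @param p_t,p_s Per-direction sunlit and shaded fractions.
#' @return List `rho_sun`, `rho_sh`, `residual_rms`,
#'   `condition_number`, `n_obs`.
#' @export
solve_sun_shade <- function(rho, p_t, p_s) {
  keep <- is.finite(rho) & is.finite(p_t) & is.finite(p_s)
  rho <- rho[keep]; p_t <- p_t[keep]; p_s <- p_s[keep]
  if (length(rho) < 2) {
    stop("need at least 2 directional observations", call. = FALSE)
  }
  x <- cbind(p_t, p_s)
  cond <- kappa(x, exact = TRUE)
  if (qr(x)$rank < 2 || cond > 1e10) {
    stop("sunlit/shaded fractions are collinear across angles",
         call. = FALSE)
  }
  fit <- stats::lm.fit(x, rho)
  list(rho_sun = unname(fit$coefficients[1]),
       rho_sh = unname(fit$coefficients[2]),
       residual_rms = sqrt(mean(fit$residuals^2)),
       condition_number = cond, n_obs = length(rho))
}

#' LAI-weighted total-canopy index
#'
#' rho_tot = (L_sun / LAI) rho_sun + (L_sh / LAI) rho_sh — a convex
#' combination, so the total always lies between the two components.
#'
#' @param rho_sun,rho_sh Component index values.
#' @param l_sun,l_sh Sunlit and shaded LAI.
#' @return rho_tot.
#' @export
total_canopy_index <- function(rho_sun, rho_sh, l_sun, l_sh) {
  lai <- l_sun + l_sh
  if (any(lai <= 0)) stop("total LAI must be positive", call. = FALSE)
  (l_sun / lai) * rho_sun + (l_sh / lai) * rho_sh
}

#' Two-leaf decomposition for every half-hour group
#'
#' For each group: per-angle component fractions from the red-band
#' reflectance ratio and the gap fraction, least-squares solve of the
#' sunlit/shaded component values for PRI and SIF, sunlit/shaded LAI at
#' the group's solar zenith, and the LAI-weighted canopy totals.
#'
#' @param index_table Per-direction table with geometry, `pri`, `sif`,
#'   `refl_670`, and `timestamp` group identifier.
#' @param lai_by_group Named numeric: LAI per timestamp (character
#'   names matching `timestamp`), or a single value recycled.
#' @param cfg A [two_leaf_config()].
#' @return Data frame, one row per (timestamp, index): `rho_sun`,
#'   `rho_sh`, `l_sun`, `l_sh`, `rho_tot`, `residual_rms`,
#'   `condition_number`, `n_obs`, `qc_clamped_sif`.
#' @export
process_two_leaf <- function(index_table, lai_by_group,
                             cfg = two_leaf_config()) {
  groups <- split(index_table, index_table$timestamp)
  single_lai <- length(lai_by_group) == 1L && is.null(names(lai_by_group))
  rows <- lapply(groups, function(g) {
    ts <- as.character(g$timestamp[1])
    lai <- if (single_lai) lai_by_group else unname(lai_by_group[[ts]])
    if (is.null(lai) || !is.finite(lai)) {
      stop(sprintf("no LAI available for group %s", ts), call. = FALSE)
    }
    p_vg <- background_fraction(lai, g$view_zenith_deg, cfg)
    p_t <- sunlit_fraction(g$refl_670, p_vg, cfg)
    p_s <- shaded_fraction(p_t, p_vg)
    theta_s <- mean(g$solar_zenith_deg)
    l <- sunlit_shaded_lai(lai, theta_s, cfg)
    per_index <- lapply(c("pri", "sif"), function(w) {
      sol <- solve_sun_shade(g[[w]], p_t, p_s)
      clamped <- FALSE
      if (w == "sif" && cfg$clamp_negative_sif) {
        if (sol$rho_sun < 0) { sol$rho_sun <- 0; clamped <- TRUE }
        if (sol$rho_sh < 0) { sol$rho_sh <- 0; clamped <- TRUE }
      }
      data.frame(timestamp = g$timestamp[1], index_name = w,
                 rho_sun = sol$rho_sun, rho_sh = sol$rho_sh,
                 l_sun = l$l_sun, l_sh = l$l_sh,
                 rho_tot = total_canopy_index(sol$rho_sun, sol$rho_sh,
                                              l$l_sun, l$l_sh),
                 residual_rms = sol$residual_rms,
                 condition_number = sol$condition_number,
                 n_obs = sol$n_obs, qc_clamped_sif = clamped,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_index)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Linearly interpolate sparse LAI measurements to target dates
#'
#' Field LAI is measured about every 7 days; intermediate dates are
#' linearly interpolated (constant extrapolation at the ends).
#'
#' @param lai_doy,lai Measurement days of year and LAI values.
#' @param target_doy Days to interpolate to.
#' @return Numeric LAI at `target_doy`.
#' @export
interpolate_lai <- function(lai_doy, lai, target_doy) {
  stats::approx(lai_doy, lai, xout = target_doy, rule = 2)$y
}
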