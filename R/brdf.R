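# Kernel-driven BRDF model (Ross-Thick + Li-Sparse) for per-group
# angular PRI/SIF fields, and hotspot extraction.

#' Kernel shape parameters
#'
#' Crown relative height (h/b) and crown relative shape (b/r) of the
#' Li-Sparse geometric kernel. Defaults h/b = 2, b/r = 1 are the
#' conventional values for crop canopies.
#'
#' @param h_over_b Crown center height over vertical crown radius, > 0.
#' @param b_over_r Vertical over horizontal crown radius, > 0.
#' @return A `kernel_params` list.
#' @export
kernel_params <- function(h_over_b = 2, b_over_r = 1) {
  if (h_over_b <= 0 || b_over_r <= 0) {
    stop("kernel parameters must be positive", call. = FALSE)
  }
  structure(list(h_over_b = h_over_b, b_over_r = b_over_r),
            class = "kernel_params")
}

check_geometry <- function(theta_v, theta_s) {
  if (any(theta_v < 0 | theta_v >= 90) || any(theta_s < 0 | theta_s >= 90)) {
    stop("zenith angles must lie in [0, 90) degrees", call. = FALSE)
  }
}

#' Ross-Thick volumetric scattering kernel
#'
#' K_R = ((pi/2 - xi) cos xi + sin xi) / (cos theta_s + cos theta_v)
#' - pi/4, with xi the phase angle between sun and view directions.
#' Vectorised over geometry.
#'
#' @param theta_v,theta_s View and solar zenith, degrees.
#' @param delta_phi Relative azimuth, degrees.
#' @return Kernel value(s).
#' @export
ross_thick_kernel <- function(theta_v, theta_s, delta_phi) {
  check_geometry(theta_v, theta_s)
  tv <- deg2rad(theta_v); ts <- deg2rad(theta_s); dp <- deg2rad(delta_phi)
  cos_xi <- cos(ts) * cos(tv) + sin(ts) * sin(tv) * cos(dp)
  cos_xi <- pmin(pmax(cos_xi, -1), 1)
  xi <- acos(cos_xi)
  ((pi / 2 - xi) * cos_xi + sin(xi)) / (cos(ts) + cos(tv)) - pi / 4
}

#' Li-Sparse geometric scattering kernel
#'
#' Non-reciprocal Wanner form: zeniths are transformed to equivalent
#' angles through b/r, the crown overlap is computed through h/b, and
#' K_L = O - sec theta_s' - sec theta_v'
#' + 0.5 (1 + cos xi') sec theta_v'. Vectorised over geometry.
#'
#' @inheritParams ross_thick_kernel
#' @param p A [kernel_params()].
#' @return Kernel value(s).
#' @export
li_sparse_kernel <- function(theta_v, theta_s, delta_phi,
                             p = kernel_params()) {
  check_geometry(theta_v, theta_s)
  dp <- deg2rad(delta_phi)
  tv <- atan(p$b_over_r * tan(deg2rad(theta_v)))
  ts <- atan(p$b_over_r * tan(deg2rad(theta_s)))
  sec_v <- 1 / cos(tv); sec_s <- 1 / cos(ts)
  cos_xi <- cos(ts) * cos(tv) + sin(ts) * sin(tv) * cos(dp)
  cos_xi <- pmin(pmax(cos_xi, -1), 1)
  d2 <- tan(ts)^2 + tan(tv)^2 - 2 * tan(ts) * tan(tv) * cos(dp)
  cos_t <- p$h_over_b *
    sqrt(pmax(d2, 0) + (tan(ts) * tan(tv) * sin(dp))^2) / (sec_s + sec_v)
  cos_t <- pmin(pmax(cos_t, -1), 1)
  t <- acos(cos_t)
  overlap <- (1 / pi) * (t - sin(t) * cos_t) * (sec_s + sec_v)
  overlap - sec_s - sec_v + 0.5 * (1 + cos_xi) * sec_v
}

#' Fit the kernel-driven BRDF model to a multi-angle index field
#'
#' Ordinary least squares of the per-direction index (PRI or SIF) on
#' \[1, K_L, K_R\], giving the isotropic, geometric, and volumetric
#' scattering coefficients (k_i, k_g, k_v). One fit per half-hour group
#' per index.
#'
#' @param indices Data frame with columns `view_zenith_deg`,
#'   `view_azimuth_deg`, `solar_zenith_deg`, `solar_azimuth_deg`, and
#'   the index column named by `which`. Rows with `qc_negative_sif`
#'   TRUE are excluded when fitting SIF (if present).
#' @param which `"pri"` or `"sif"`.
#' @param p A [kernel_params()].
#' @param min_obs Minimum observations for a quality-passing fit
#'   (default 30; fewer than 3 is an error).
#' @param max_condition Condition-number ceiling for a quality-passing
#'   fit (default 1e6).
#' @return A `brdf_fit` list: `k_i`, `k_g`, `k_v`, `residual_rms`,
#'   `n_obs`, `condition_number`, `which`, `params`, `qc_pass`.
#' @export
fit_brdf <- function(indices, which = c("pri", "sif"), p = kernel_params(),
                     min_obs = 30, max_condition = 1e6) {
  which <- match.arg(which)
  if (which == "sif" && "qc_negative_sif" %in% names(indices)) {
    indices <- indices[!indices$qc_negative_sif, , drop = FALSE]
  }
  y <- indices[[which]]
  keep <- is.finite(y)
  indices <- indices[keep, , drop = FALSE]
  y <- y[keep]
  n <- length(y)
  if (n < 3) stop("fewer than 3 usable directional observations",
                  call. = FALSE)
  dp <- relative_azimuth(indices$view_azimuth_deg, indices$solar_azimuth_deg)
  kl <- li_sparse_kernel(indices$view_zenith_deg, indices$solar_zenith_deg,
                         dp, p)
  kr <- ross_thick_kernel(indices$view_zenith_deg, indices$solar_zenith_deg,
                          dp)
  x <- cbind(1, kl, kr)
  geom_distinct <- nrow(unique(round(
    cbind(indices$view_zenith_deg, indices$view_azimuth_deg, dp), 6)))
  if (geom_distinct < 3) {
    stop("need at least 3 distinct view geometries", call. = FALSE)
  }
  cond <- kappa(x, exact = TRUE)
  if (cond > 1e12 || qr(x)$rank < 3) {
    stop("rank-deficient kernel design matrix", call. = FALSE)
  }
  fit <- stats::lm.fit(x, y)
  co <- fit$coefficients
  structure(list(
    k_i = unname(co[1]), k_g = unname(co[2]), k_v = unname(co[3]),
    residual_rms = sqrt(mean(fit$residuals^2)),
    n_obs = n, condition_number = cond, which = which, params = p,
    qc_pass = n >= min_obs && cond <= max_condition
  ), class = "brdf_fit")
}

#' Evaluate a BRDF fit at the hotspot geometry
#'
#' The hotspot is the sun-view coincident direction (theta_v = theta_s,
#' delta_phi = 0), where shadows are hidden from the sensor. Warns when
#' the solar zenith exceeds the 60-degree measured vertical range, since
#' the value is then an extrapolation of the fitted model.
#'
#' @param fit A `brdf_fit`.
#' @param theta_s Solar zenith in degrees.
#' @return The fitted index value at the hotspot.
#' @export
hotspot_value <- function(fit, theta_s) {
  stopifnot(inherits(fit, "brdf_fit"))
  if (theta_s > 60) {
    warning("hotspot zenith exceeds the 60-degree measured range; ",
            "value is an extrapolation", call. = FALSE)
  }
  kl <- li_sparse_kernel(theta_s, theta_s, 0, fit$params)
  kr <- ross_thick_kernel(theta_s, theta_s, 0)
  fit$k_i + fit$k_g * kl + fit$k_v * kr
}

#' Hotspot PRI and SIF for every half-hour group
#'
#' Fits the kernel-driven model per group and index and evaluates it at
#' the group's hotspot geometry (the mean solar zenith of the group).
#'
#' @param index_table Per-direction index table (rows from
#'   [process_angular_scan()] or the synthetic generator) with a
#'   `timestamp` column identifying groups.
#' @param p A [kernel_params()].
#' @param min_obs,max_condition Quality screen passed to [fit_brdf()].
#' @return Data frame: one row per (timestamp, index) with k
#'   coefficients, `hotspot_value`, `residual_rms`, `condition_number`,
#'   `n_obs`, `qc_pass`.
#' @export
process_brdf <- function(index_table, p = kernel_params(),
                         min_obs = 30, max_condition = 1e6) {
  groups <- split(index_table, index_table$timestamp)
  rows <- lapply(groups, function(g) {
    theta_s <- mean(g$solar_zenith_deg)
    per_index <- lapply(c("pri", "sif"), function(w) {
      fit <- fit_brdf(g, w, p, min_obs, max_condition)
      data.frame(timestamp = g$timestamp[1], index_name = w,
                 k_i = fit$k_i, k_g = fit$k_g, k_v = fit$k_v,
                 hotspot_value = hotspot_value(fit, theta_s),
                 residual_rms = fit$residual_rms,
                 condition_number = fit$condition_number,
                 n_obs = fit$n_obs, qc_pass = fit$qc_pass,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_index)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
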