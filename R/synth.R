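# Synthetic campaign generator: angular spectral scans with injected
# fluorescence and kernel-driven anisotropy, component-mixed index
# fields, and coupled eddy-covariance flux series — all with known
# ground truth so every inversion in the pipeline is verifiable by
# parameter recovery.

#' Campaign ground truth
#'
#' Collects every knob of the synthetic campaign: the observation
#' calendar, site coordinates, LAI seasonal curve, angular sampling
#' design, per-index truth models, flux-model parameters, the
#' SIF/PRI-to-GPP coupling, and noise levels. Regeneration from the
#' same truth and seed is bit-identical.
#'
#' @param seed Integer seed; every generator call derives its RNG
#'   stream from it.
#' @param mode Forward model for the angular index fields:
#'   `"twoleaf-exact"` (sunlit/shaded mixture is exactly true; the
#'   default), `"brdf-exact"` (kernel superposition exactly true), or
#'   `"mixed"` (average of both, realistic for qualitative end-to-end
#'   checks).
#' @param doys 25 campaign days of year (must include the validation
#'   days 224, 251, 271 for the standard split).
#' @param slots Decimal hours of the half-hour groups (default 13
#'   slots, 09:00-15:00).
#' @param n_reps Grid repetitions per scan; the 31 x 7 directional grid
#'   times 7 repetitions gives ~1,500 records per group.
#' @param noise_index Additive noise sd on per-angle PRI/SIF (0 =
#'   noiseless forward model).
#' @param noise_nee Additive noise sd on half-hourly NEE,
#'   mg CO2 m-2 s-1.
#' @param noise_gpp Additive noise sd on the coupled GPP target.
#' @param a_sif,a_pri,c_gpp GPP coupling: GPP = a_sif * SIF_tot +
#'   a_pri * PRI_tot + c_gpp + noise (mg CO2 m-2 s-1 scale).
#' @param re_ref,b_resp Van't Hoff respiration truth (defaults 0.22 and
#'   0.1235, the field-campaign fit).
#' @param frac_low_ustar Fraction of night half-hours with friction
#'   velocity below the 0.13 m s-1 screen.
#' @param p_rain_day Probability a day contains a rainfall event.
#' @param p_spike,p_missing Per-record probabilities of an
#'   out-of-range spike and of a missing slot.
#' @param dip_depth Fractional depth of the O2-A irradiance dip.
#' @param omega,leaf_reflectance_670 Two-leaf structural truth.
#' @return A `campaign_truth` list.
#' @export
campaign_truth <- function(seed = 1,
                           mode = c("twoleaf-exact", "brdf-exact", "mixed"),
                           doys = c(215, 217, 220, 222, 224, 227, 230, 233,
                                    235, 238, 241, 243, 246, 248, 251, 254,
                                    256, 259, 262, 264, 267, 269, 271, 274,
                                    277),
                           slots = seq(9, 15, by = 0.5),
                           n_reps = 7,
                           noise_index = 0.002,
                           noise_nee = 0.01,
                           noise_gpp = 0.03,
                           a_sif = 6, a_pri = -5, c_gpp = 0.15,
                           re_ref = 0.22, b_resp = 0.1235,
                           frac_low_ustar = 0.3,
                           p_rain_day = 0.15,
                           p_spike = 0.01, p_missing = 0.02,
                           dip_depth = 0.35,
                           omega = 0.9, leaf_reflectance_670 = 0.05) {
  mode <- match.arg(mode)
  structure(list(
    seed = as.integer(seed), mode = mode, doys = doys, slots = slots,
    n_reps = n_reps, lat = 32.43, lon = 116.78,
    view_zeniths = seq(0, 60, by = 10),
    view_azimuths = seq(-150, 150, by = 10),
    jitter_deg = 0.8,
    noise_index = noise_index, noise_nee = noise_nee,
    noise_gpp = noise_gpp,
    a_sif = a_sif, a_pri = a_pri, c_gpp = c_gpp,
    re_ref = re_ref, b_resp = b_resp, t_ref = 25,
    frac_low_ustar = frac_low_ustar, p_rain_day = p_rain_day,
    p_spike = p_spike, p_missing = p_missing,
    dip_depth = dip_depth, omega = omega,
    leaf_reflectance_670 = leaf_reflectance_670,
    wavelengths = seq(350, 800, by = 1),
    par_max = 2200
  ), class = "campaign_truth")
}

# Derive a reproducible sub-seed for a named stream; kept below 2^31.
sub_seed <- function(truth, ...) {
  key <- paste(c(truth$seed, ...), collapse = "/")
  v <- utf8ToInt(key)
  as.integer((sum(v * seq_along(v)) * 2654435 + truth$seed) %% 2147483647)
}

#' Seasonal LAI of the synthetic rice canopy
#'
#' Rises to a peak of 7.7 at DOY 224 (heading), then declines through
#' ripening; asymmetric Gaussian in DOY.
#'
#' @param doy Day of year.
#' @return LAI, vectorised.
#' @export
synth_lai <- function(doy) {
  sigma <- ifelse(doy <= 224, 14, 38)
  pmax(7.7 * exp(-((doy - 224)^2) / (2 * sigma^2)), 0.3)
}

#' Low-precision solar position for the synthetic site
#'
#' Declination/hour-angle formula at the site coordinates (32.43 N,
#' 116.78 E), local solar time. Adequate for generating plausible
#' geometry; the pipeline itself takes angles as data.
#'
#' @param doy Day of year.
#' @param hour Local solar decimal hour.
#' @param lat Latitude, degrees (default the site's).
#' @return List `zenith`, `azimuth` in degrees (zenith > 90 at night).
#' @export
solar_position <- function(doy, hour, lat = 32.43) {
  decl <- 23.45 * sin(2 * pi * (284 + doy) / 365)
  h <- deg2rad(15 * (hour - 12))
  phi <- deg2rad(lat); d <- deg2rad(decl)
  cos_z <- sin(phi) * sin(d) + cos(phi) * cos(d) * cos(h)
  cos_z <- pmin(pmax(cos_z, -1), 1)
  z <- acos(cos_z)
  az <- atan2(sin(h), cos(h) * sin(phi) - tan(d) * cos(phi))
  list(zenith = z * 180 / pi, azimuth = (az * 180 / pi + 180) %% 360)
}

# Per-day cloudiness factor in (0, 1]; a minority of days are cloudy.
day_cloud_factor <- function(truth, doy) {
  set.seed(sub_seed(truth, "cloud", doy))
  if (stats::runif(1) < 0.2) stats::runif(1, 0.25, 0.45)
  else stats::runif(1, 0.85, 1.0)
}

# Deterministic physiological truth for one half-hour group: solar
# geometry, PAR, LAI, component index values, and the implied totals.
group_truth <- function(truth, doy, slot) {
  sp <- solar_position(doy, slot, truth$lat)
  lai <- synth_lai(doy)
  par <- max(0, truth$par_max * cos(deg2rad(min(sp$zenith, 90)))) *
    day_cloud_factor(truth, doy)
  rel_par <- par / 2000
  canopy <- lai / (lai + 2)
  # Independent per-group physiological variability (light-use
  # efficiency and xanthophyll state are not deterministic functions of
  # PAR and LAI in the field); deterministic given (truth, group).
  set.seed(sub_seed(truth, "phys", doy, slot))
  u_sif <- exp(stats::rnorm(1, 0, 0.15))
  u_pri <- stats::rnorm(1, 0, 0.01)
  sif_sun <- 0.25 * rel_par * canopy * u_sif
  sif_sh <- 0.10 * sqrt(rel_par) * canopy * u_sif
  pri_sun <- -0.02 - 0.06 * rel_par + u_pri
  pri_sh <- -0.02 - 0.03 * sqrt(rel_par) + u_pri
  cfg <- two_leaf_config(truth$omega, truth$leaf_reflectance_670)
  l <- sunlit_shaded_lai(lai, min(sp$zenith, 89), cfg)
  sif_tot <- total_canopy_index(sif_sun, sif_sh, l$l_sun, l$l_sh)
  pri_tot <- total_canopy_index(pri_sun, pri_sh, l$l_sun, l$l_sh)
  list(doy = doy, slot = slot, theta_s = sp$zenith, phi_s = sp$azimuth,
       lai = lai, par = par,
       sif_sun = sif_sun, sif_sh = sif_sh, sif_tot = sif_tot,
       pri_sun = pri_sun, pri_sh = pri_sh, pri_tot = pri_tot,
       l_sun = l$l_sun, l_sh = l$l_sh,
       # Kernel truth for the brdf-exact forward model, on the same
       # magnitude scale as the component values.
       k_pri = c(k_i = pri_tot, k_g = 0.15 * abs(pri_tot),
                 k_v = -0.3 * abs(pri_tot)),
       k_sif = c(k_i = sif_tot, k_g = -0.1 * sif_tot, k_v = 0.35 * sif_tot))
}

# Angular sampling design for one scan: the 31 x 7 grid repeated
# n_reps times with small pointing jitter.
scan_geometry <- function(truth, doy, slot) {
  base <- expand.grid(view_zenith_deg = truth$view_zeniths,
                      view_azimuth_deg = truth$view_azimuths)
  g <- base[rep(seq_len(nrow(base)), truth$n_reps), , drop = FALSE]
  set.seed(sub_seed(truth, "geom", doy, slot))
  if (truth$n_reps > 1) {
    g$view_zenith_deg <- pmax(0, pmin(89,
      g$view_zenith_deg + stats::rnorm(nrow(g), 0, truth$jitter_deg)))
    g$view_azimuth_deg <- g$view_azimuth_deg +
      stats::rnorm(nrow(g), 0, truth$jitter_deg)
  }
  rownames(g) <- NULL
  g
}

#' Forward-model per-angle indices for one half-hour group
#'
#' Generates the per-direction PRI, SIF, and red-band reflectance of
#' one angular scan from the configured forward model
#' (sunlit/shaded mixture, kernel superposition, or their average),
#' plus the truth columns needed for recovery checks.
#'
#' @param truth A [campaign_truth()].
#' @param doy,slot Campaign day of year and decimal hour.
#' @return Data frame: timestamp, doy, slot, geometry, `pri`, `sif`,
#'   `refl_670`, and truth fractions `p_t`, `p_s`, `p_vg`.
#' @export
synth_group_indices <- function(truth, doy, slot) {
  gt <- group_truth(truth, doy, slot)
  g <- scan_geometry(truth, doy, slot)
  n <- nrow(g)
  dp <- relative_azimuth(g$view_azimuth_deg, gt$phi_s)
  theta_s <- min(gt$theta_s, 89)

  cfg <- two_leaf_config(truth$omega, truth$leaf_reflectance_670)
  p_vg <- background_fraction(gt$lai, g$view_zenith_deg, cfg)
  # Sunlit fraction rises towards the hotspot (sun-view coincidence).
  cos_xi <- cos(deg2rad(theta_s)) * cos(deg2rad(g$view_zenith_deg)) +
    sin(deg2rad(theta_s)) * sin(deg2rad(g$view_zenith_deg)) *
      cos(deg2rad(dp))
  hot <- (1 + pmin(pmax(cos_xi, -1), 1)) / 2
  p_t <- (1 - p_vg) * (0.35 + 0.3 * hot)
  p_s <- 1 - p_t - p_vg

  tl_pri <- p_t * gt$pri_sun + p_s * gt$pri_sh
  tl_sif <- p_t * gt$sif_sun + p_s * gt$sif_sh
  kl <- li_sparse_kernel(g$view_zenith_deg, theta_s, dp)
  kr <- ross_thick_kernel(g$view_zenith_deg, theta_s, dp)
  kb_pri <- gt$k_pri[["k_i"]] + gt$k_pri[["k_g"]] * kl +
    gt$k_pri[["k_v"]] * kr
  kb_sif <- gt$k_sif[["k_i"]] + gt$k_sif[["k_g"]] * kl +
    gt$k_sif[["k_v"]] * kr

  pri <- switch(truth$mode,
                "twoleaf-exact" = tl_pri,
                "brdf-exact" = kb_pri,
                "mixed" = 0.5 * (tl_pri + kb_pri))
  sif <- switch(truth$mode,
                "twoleaf-exact" = tl_sif,
                "brdf-exact" = kb_sif,
                "mixed" = 0.5 * (tl_sif + kb_sif))
  set.seed(sub_seed(truth, "idxnoise", doy, slot))
  if (truth$noise_index > 0) {
    pri <- pri + stats::rnorm(n, 0, truth$noise_index)
    sif <- sif + stats::rnorm(n, 0, truth$noise_index)
  }

  data.frame(
    timestamp = doy * 86400 + slot * 3600,
    doy = doy, slot = slot,
    view_zenith_deg = g$view_zenith_deg,
    view_azimuth_deg = g$view_azimuth_deg,
    solar_zenith_deg = theta_s, solar_azimuth_deg = gt$phi_s,
    pri = pri, sif = sif,
    refl_670 = truth$leaf_reflectance_670 * p_t,
    p_t = p_t, p_s = p_s, p_vg = p_vg,
    stringsAsFactors = FALSE
  )
}

#' Synthetic downwelling solar irradiance with the O2-A dip
#'
#' Smooth envelope on the 350-800 nm grid with a Gaussian absorption
#' dip centered at 762 nm of fractional depth `dip_depth` (sd 1.2 nm,
#' so the 758/769 nm outer bands sit essentially outside the dip).
#'
#' @param wavelengths Wavelength grid, nm.
#' @param dip_depth Fractional dip depth in (0, 1); 0 disables the dip.
#' @param scale Envelope scale (irradiance units).
#' @return A `spectrum` of kind `"downwelling"`.
#' @export
synth_solar_spectrum <- function(wavelengths = seq(350, 800, by = 1),
                                 dip_depth = 0.35, scale = 1) {
  envelope <- scale * (1.1 - 0.0006 * (wavelengths - 350))
  dip <- 1 - dip_depth * exp(-((wavelengths - 762)^2) / (2 * 1.2^2))
  spectrum(wavelengths, envelope * dip, "downwelling")
}

# Vegetation-like baseline reflectance with flat windows at every band
# the pipeline reads, so band means are exact.
synth_reflectance_curve <- function(wavelengths, r531, r570, r670,
                                    r_nir = 0.45) {
  r <- 0.05 + 0.45 / (1 + exp(-(wavelengths - 715) / 12))  # red edge
  r[wavelengths >= 500 & wavelengths < 600] <- 0.08
  r[wavelengths >= 525 & wavelengths <= 537] <- r531
  r[wavelengths >= 564 & wavelengths <= 576] <- r570
  r[wavelengths >= 660 & wavelengths <= 680] <- r670
  r[wavelengths >= 745 & wavelengths <= 785] <- r_nir
  r
}

#' Synthesize one full spectral angular scan
#'
#' Long-format per-record spectra for one half-hour group. Each
#' record's reflectance encodes its forward-model PRI (via the
#' 531/570 nm bands) and sunlit fraction (via the 670 nm band), and its
#' radiance adds the forward-model SIF as a spectrally flat emission
#' across the O2-A window, so the retrieval chain inverts the
#' generator exactly.
#'
#' @param truth A [campaign_truth()].
#' @param doy,slot Group identifier.
#' @return List: `scan` (long data frame for
#'   [process_angular_scan()]), `indices` (the per-angle forward truth
#'   from [synth_group_indices()]), `irradiance` (the group's
#'   downwelling `spectrum`).
#' @export
synth_angular_scan <- function(truth, doy, slot) {
  idx <- synth_group_indices(truth, doy, slot)
  wl <- truth$wavelengths
  gt <- group_truth(truth, doy, slot)
  e <- synth_solar_spectrum(wl, truth$dip_depth,
                            scale = max(0.2, gt$par / 2000))
  n_wl <- length(wl)
  n_rec <- nrow(idx)
  r570 <- 0.08
  rows <- vector("list", n_rec)
  for (i in seq_len(n_rec)) {
    pri <- idx$pri[i]
    r531 <- r570 * (1 + pri) / (1 - pri)
    r <- synth_reflectance_curve(wl, r531, r570, idx$refl_670[i])
    l <- r * e$values
    fl_window <- wl >= 745 & wl <= 785
    l[fl_window] <- l[fl_window] + idx$sif[i]
    rows[[i]] <- data.frame(
      timestamp = idx$timestamp[i], record_id = i,
      view_zenith_deg = idx$view_zenith_deg[i],
      view_azimuth_deg = idx$view_azimuth_deg[i],
      solar_zenith_deg = idx$solar_zenith_deg[i],
      solar_azimuth_deg = idx$solar_azimuth_deg[i],
      wavelength_nm = wl,
      reflected_radiance = l,
      downwelling_irradiance = e$values,
      stringsAsFactors = FALSE
    )
  }
  list(scan = do.call(rbind, rows), indices = idx, irradiance = e)
}

#' Synthesize one day of half-hourly flux records
#'
#' 48 half-hours: diurnal temperature and VPD, solar-geometry-shaped
#' PAR, Van't Hoff respiration, light-response GPP scaled by LAI (or
#' the coupled GPP override for the scan slots), NEE = Re - GPP +
#' noise, plus injected rainfall events, low-u* nights, out-of-range
#' spikes, and missing slots.
#'
#' @param truth A [campaign_truth()].
#' @param doy Day of year.
#' @param gpp_override Optional named numeric: GPP truth for specific
#'   decimal hours (names = hour as character), used by
#'   [synth_campaign()] to couple GPP to the index truth.
#' @return Data frame of 48 `FluxRecord` rows, plus truth columns
#'   `gpp_true` and `re_true`.
#' @export
synth_flux_day <- function(truth, doy, gpp_override = NULL) {
  hours <- seq(0, 23.5, by = 0.5)
  sp <- solar_position(doy, hours, truth$lat)
  cloud <- day_cloud_factor(truth, doy)
  par <- pmax(0, truth$par_max * cos(deg2rad(pmin(sp$zenith, 90)))) * cloud
  tmean <- 27 - 0.08 * (doy - 215)
  t_air <- tmean + 5 * cos(2 * pi * (hours - 15) / 24)
  es <- 0.6108 * exp(17.27 * t_air / (t_air + 237.3))
  vpd <- pmax(0.05, es * (0.2 + 0.45 * par / 2000))
  lai <- synth_lai(doy)
  re_true <- truth$re_ref * exp(truth$b_resp * (t_air - truth$t_ref))
  gpp_true <- ifelse(par > 0,
                     (0.002 * par * 1.2 / (0.002 * par + 1.2)) * (lai / 7.7),
                     0)
  if (!is.null(gpp_override)) {
    hit <- match(as.character(hours), names(gpp_override))
    gpp_true <- ifelse(is.na(hit), gpp_true, gpp_override[hit])
  }
  set.seed(sub_seed(truth, "flux", doy))
  nee <- re_true - gpp_true +
    (if (truth$noise_nee > 0) stats::rnorm(48, 0, truth$noise_nee) else 0)

  rain_flag <- rep(FALSE, 48)
  if (stats::runif(1) < truth$p_rain_day) {
    start <- sample(seq_len(44), 1)
    rain_flag[start:(start + sample(2:4, 1))] <- TRUE
  }
  night <- par < 5
  ustar <- numeric(48)
  low <- stats::runif(48) < truth$frac_low_ustar
  ustar[night & low] <- stats::runif(sum(night & low), 0.04, 0.125)
  ustar[night & !low] <- stats::runif(sum(night & !low), 0.14, 0.45)
  ustar[!night] <- stats::runif(sum(!night), 0.2, 0.6)
  range_ok <- stats::runif(48) >= truth$p_spike
  nee[!range_ok] <- sign(nee[!range_ok] + 1e-9) * 10
  nee[stats::runif(48) < truth$p_missing] <- NA_real_

  data.frame(
    timestamp = doy * 86400 + hours * 3600,
    doy = doy, hour = hours,
    nee = nee, t_air = t_air, vpd = vpd, par = par, ustar = ustar,
    rain_flag = rain_flag, range_ok = range_ok,
    gpp_true = gpp_true, re_true = re_true,
    stringsAsFactors = FALSE
  )
}

#' Synthesize the full 25-day campaign
#'
#' 25 days x 13 half-hour groups (09:00-15:00) of per-angle index
#' fields plus matching flux days. The flux GPP of the scan slots is
#' coupled to the truth SIF_tot and PRI_tot via
#' GPP = a_sif * SIF_tot + a_pri * PRI_tot + c + noise, so the
#' end-to-end pipeline has a known regression target.
#'
#' @param truth A [campaign_truth()].
#' @return List: `index_table` (per-angle rows, all groups),
#'   `group_truth` (one row per group with every truth quantity),
#'   `flux` (25 x 48 half-hour records), `lai_measured` (sparse 7-day
#'   LAI table), `truth`.
#' @export
synth_campaign <- function(truth = campaign_truth()) {
  groups <- expand.grid(slot = truth$slots, doy = truth$doys)
  idx_list <- vector("list", nrow(groups))
  gt_rows <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    doy <- groups$doy[i]; slot <- groups$slot[i]
    idx_list[[i]] <- synth_group_indices(truth, doy, slot)
    gt <- group_truth(truth, doy, slot)
    set.seed(sub_seed(truth, "gppnoise", doy, slot))
    gpp <- truth$a_sif * gt$sif_tot + truth$a_pri * gt$pri_tot +
      truth$c_gpp +
      (if (truth$noise_gpp > 0) stats::rnorm(1, 0, truth$noise_gpp) else 0)
    gt_rows[[i]] <- data.frame(
      timestamp = doy * 86400 + slot * 3600, doy = doy, slot = slot,
      theta_s = gt$theta_s, lai = gt$lai, par = gt$par,
      sif_sun = gt$sif_sun, sif_sh = gt$sif_sh, sif_tot = gt$sif_tot,
      pri_sun = gt$pri_sun, pri_sh = gt$pri_sh, pri_tot = gt$pri_tot,
      gpp_true = gpp, stringsAsFactors = FALSE
    )
  }
  group_truth_df <- do.call(rbind, gt_rows)

  flux <- do.call(rbind, lapply(truth$doys, function(doy) {
    g <- group_truth_df[group_truth_df$doy == doy, ]
    ov <- stats::setNames(g$gpp_true, as.character(g$slot))
    synth_flux_day(truth, doy, gpp_override = ov)
  }))

  lai_doys <- seq(min(truth$doys), max(truth$doys), by = 7)
  list(index_table = do.call(rbind, idx_list),
       group_truth = group_truth_df,
       flux = flux,
       lai_measured = data.frame(doy = lai_doys, lai = synth_lai(lai_doys)),
       truth = truth)
}
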