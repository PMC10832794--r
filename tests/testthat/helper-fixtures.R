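# Shared fixtures, all built in code.

# The six-record screening fixture: one clean daytime record, one
# night record with negative NEE, one rainy record (rule c removes the
# event and its 1-h window; records are spaced 2 h apart so only the
# event itself falls in the window), one calm night (low u*), one
# instrument-range failure, one clean night.
toy_flux_fixture <- function() {
  ts0 <- 230 * 86400
  data.frame(
    timestamp = ts0 + 7200 * (0:5),
    nee = c(-0.6, -0.1, 0.2, 0.15, 0.5, 0.18),
    t_air = c(28, 20, 27, 19, 27, 21),
    vpd = rep(1.5, 6),
    par = c(1500, 0, 1400, 0, 1300, 0),
    ustar = c(0.40, 0.30, 0.35, 0.10, 0.30, 0.25),
    rain_flag = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    range_ok = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE)
  )
}

# Synthetic nighttime respiration records for Van't Hoff recovery.
vant_hoff_nights <- function(n = 60, re_ref = 0.22, b = 0.1235,
                             noise = 0, seed = 1, t_min = 14, t_max = 28) {
  set.seed(seed)
  t_air <- seq(t_min, t_max, length.out = n)
  nee <- re_ref * exp(b * (t_air - 25)) +
    (if (noise > 0) rnorm(n, 0, noise) else 0)
  data.frame(
    timestamp = 230 * 86400 + 1800 * seq_len(n),
    nee = nee, t_air = t_air, vpd = 0.5,
    par = 0, ustar = 0.3, rain_flag = FALSE, range_ok = TRUE
  )
}

# A small angular design (no repetitions) for kernel-fit tests.
toy_geometry <- function(theta_s = 30, phi_s = 180) {
  g <- expand.grid(view_zenith_deg = seq(0, 60, by = 15),
                   view_azimuth_deg = seq(-150, 150, by = 30))
  g$solar_zenith_deg <- theta_s
  g$solar_azimuth_deg <- phi_s
  g
}

# Forward-model a kernel index field on a geometry table.
forward_brdf <- function(g, k, p = kernel_params()) {
  dp <- relative_azimuth(g$view_azimuth_deg, g$solar_azimuth_deg)
  k[1] + k[2] * li_sparse_kernel(g$view_zenith_deg, g$solar_zenith_deg,
                                 dp, p) +
    k[3] * ross_thick_kernel(g$view_zenith_deg, g$solar_zenith_deg, dp)
}
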