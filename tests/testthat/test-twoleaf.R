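test_that("gap-fraction background matches the closed form", {
  cfg <- two_leaf_config(omega = 0.9)
  expect_equal(background_fraction(0, 0, cfg), 1)
  expect_equal(background_fraction(7.7, 0, cfg), exp(-0.5 * 0.9 * 7.7),
               tolerance = 1e-12)
  expect_equal(background_fraction(7.7, 0, cfg), 0.0313, tolerance = 1e-3)
  # strictly decreasing in view zenith
  p <- background_fraction(3, seq(0, 80, by = 10), cfg)
  expect_true(all(diff(p) < 0))
  expect_error(background_fraction(3, 95, cfg), "zenith")
})

test_that("component fractions close to one and clamp at the boundary", {
  cfg <- two_leaf_config(leaf_reflectance_670 = 0.05)
  expect_equal(as.numeric(sunlit_fraction(0.05, 0, cfg)), 1)
  expect_equal(as.numeric(sunlit_fraction(0.03, 0.1, cfg)), 0.6)
  clamped <- sunlit_fraction(0.0495, 0.05, cfg)  # ratio 0.99, cap 0.95
  expect_equal(as.numeric(clamped), 0.95)
  expect_true(attr(clamped, "clamped"))

  expect_equal(shaded_fraction(0.6, 0.1), 0.3)
  expect_equal(shaded_fraction(0.9, 0.1), 0)
  expect_error(shaded_fraction(0.95, 0.1), "exceeds")

  set.seed(9)
  for (i in 1:30) {
    lai <- runif(1, 0.5, 8); tv <- runif(1, 0, 60)
    p_vg <- background_fraction(lai, tv, cfg)
    p_t <- sunlit_fraction(runif(1, 0.005, 0.049), p_vg, cfg)
    p_s <- shaded_fraction(as.numeric(p_t), p_vg)
    expect_equal(as.numeric(p_t) + p_s + p_vg, 1, tolerance = 1e-12)
  }
})

test_that("sunlit/shaded LAI follows the closed form and closes exactly", {
  cfg <- two_leaf_config(omega = 0.9)
  expect_equal(sunlit_shaded_lai(0, 30, cfg), list(l_sun = 0, l_sh = 0))
  l <- sunlit_shaded_lai(7.7, 0, cfg)
  expect_equal(l$l_sun, 2 * (1 - exp(-0.5 * 0.9 * 7.7)), tolerance = 1e-12)
  expect_equal(l$l_sun, 1.9374, tolerance = 1e-4)
  expect_equal(l$l_sh, 7.7 - l$l_sun)
  set.seed(2)
  for (i in 1:30) {
    lai <- runif(1, 0, 9); th <- runif(1, 0, 75)
    ll <- sunlit_shaded_lai(lai, th, cfg)
    expect_equal(ll$l_sun + ll$l_sh, lai)
    expect_gte(ll$l_sh, 0)
  }
  # saturation: as LAI grows, L_sun -> 2 cos(theta)
  big <- sunlit_shaded_lai(500, 40, cfg)
  expect_equal(big$l_sun, 2 * cos(40 * pi / 180), tolerance = 1e-6)
})

test_that("the sunlit/shaded solve recovers forward mixtures exactly", {
  set.seed(5)
  p_t <- runif(40, 0.2, 0.7)
  p_vg <- runif(40, 0.02, 0.2)
  p_s <- 1 - p_t - p_vg
  rho <- p_t * (-0.02) + p_s * (-0.06)
  sol <- solve_sun_shade(rho, p_t, p_s)
  expect_equal(sol$rho_sun, -0.02, tolerance = 1e-8)
  expect_equal(sol$rho_sh, -0.06, tolerance = 1e-8)
  expect_lt(sol$residual_rms, 1e-12)

  # equal components with zero background: any observation equals c
  p_t2 <- runif(20, 0.1, 0.9); p_s2 <- 1 - p_t2
  sol2 <- solve_sun_shade(p_t2 * 0.04 + p_s2 * 0.04, p_t2, p_s2)
  expect_equal(sol2$rho_sun, 0.04, tolerance = 1e-8)
  expect_equal(sol2$rho_sh, 0.04, tolerance = 1e-8)

  # symmetric noise leaves the estimator unbiased
  est <- replicate(200, {
    s <- solve_sun_shade(rho + rnorm(40, 0, 0.005), p_t, p_s)
    c(s$rho_sun, s$rho_sh)
  })
  expect_lt(max(abs(rowMeans(est) - c(-0.02, -0.06))), 0.001)

  expect_error(solve_sun_shade(c(1, 2), c(0.5, 0.5), c(0.25, 0.25)),
               "collinear")
})

test_that("the canopy total is the LAI-weighted convex combination", {
  expect_equal(total_canopy_index(0.1, 0.04, 1.9374, 5.7626), 0.0551,
               tolerance = 1e-3)
  expect_equal(total_canopy_index(0.07, 0.07, 2, 5), 0.07)
  expect_equal(total_canopy_index(0.1, 0.04, 2, 0), 0.1)
  expect_error(total_canopy_index(0.1, 0.04, 0, 0), "positive")
  set.seed(8)
  for (i in 1:20) {
    rs <- runif(1, -0.1, 0.2); rh <- runif(1, -0.1, 0.2)
    tot <- total_canopy_index(rs, rh, runif(1, 0.1, 2), runif(1, 0.1, 6))
    expect_gte(tot, min(rs, rh) - 1e-12)
    expect_lte(tot, max(rs, rh) + 1e-12)
  }
})

test_that("per-group decomposition inverts the synthetic mixture", {
  truth <- campaign_truth(seed = 6, mode = "twoleaf-exact", noise_index = 0,
                          n_reps = 1)
  idx <- synth_group_indices(truth, 224, 12)
  lai <- synth_lai(224)
  tab <- process_two_leaf(idx, stats::setNames(lai, unique(idx$timestamp)),
                          two_leaf_config(0.9, truth$leaf_reflectance_670))
  gt <- canopyGPP:::group_truth(truth, 224, 12)
  sif_row <- tab[tab$index_name == "sif", ]
  pri_row <- tab[tab$index_name == "pri", ]
  expect_equal(sif_row$rho_sun, gt$sif_sun, tolerance = 1e-6)
  expect_equal(sif_row$rho_sh, gt$sif_sh, tolerance = 1e-6)
  expect_equal(pri_row$rho_sun, gt$pri_sun, tolerance = 1e-6)
  expect_equal(pri_row$rho_tot, gt$pri_tot, tolerance = 1e-6)
  expect_equal(sif_row$l_sun + sif_row$l_sh, lai)
})

test_that("sparse LAI interpolates linearly with constant extrapolation", {
  doys <- c(210, 217, 224)
  lai <- c(2, 4, 7)
  expect_equal(interpolate_lai(doys, lai, 220.5), 4 + 3 * 3.5 / 7)
  expect_equal(interpolate_lai(doys, lai, 205), 2)
  expect_equal(interpolate_lai(doys, lai, 230), 7)
})
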