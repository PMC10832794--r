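test_that("whiteboard correction evaluates R = L*L'/(E*E') elementwise", {
  wl <- c(500, 600, 700)
  cal <- whiteboard_calibration(wl, c(1, 1, 1), c(0.5, 1, 1))
  refl <- spectrum(wl, c(0.2, 0, 0.3), "reflected")
  down <- spectrum(wl, c(1, 1, 1), "downwelling")
  r <- calibrate_reflectance(refl, down, cal)
  expect_equal(r$values, c(0.4, 0, 0.3))
  expect_equal(r$kind, "reflectance")

  # identity: L = E and L' = E' gives R = 1 everywhere
  cal1 <- identity_calibration(wl)
  same <- spectrum(wl, c(0.7, 0.8, 0.9), "reflected")
  same_e <- spectrum(wl, c(0.7, 0.8, 0.9), "downwelling")
  expect_equal(calibrate_reflectance(same, same_e, cal1)$values, rep(1, 3))
})

test_that("calibration flags out-of-range values and rejects bad inputs", {
  wl <- c(500, 600)
  cal <- identity_calibration(wl)
  r <- calibrate_reflectance(spectrum(wl, c(1.2, 0.1), "reflected"),
                             spectrum(wl, c(1, 1), "downwelling"), cal)
  expect_equal(attr(r, "qc_out_of_range"), c(TRUE, FALSE))
  expect_equal(r$values[1], 1.2)  # flagged, not clipped

  expect_error(
    calibrate_reflectance(spectrum(c(500, 601), c(1, 1), "reflected"),
                          spectrum(wl, c(1, 1), "downwelling"), cal),
    "grid mismatch")
  expect_error(
    calibrate_reflectance(spectrum(wl, c(1, 1), "reflected"),
                          spectrum(wl, c(1, 0), "downwelling"), cal),
    "positive")
  expect_error(whiteboard_calibration(wl, c(1, -1), c(1, 1)), "positive")
})

test_that("PRI matches hand arithmetic and is antisymmetric in its bands", {
  wl <- seq(520, 580, by = 1)
  mk <- function(r531, r570) {
    v <- rep(0.05, length(wl))
    v[abs(wl - 531) <= 2] <- r531
    v[abs(wl - 570) <= 2] <- r570
    spectrum(wl, v, "reflectance")
  }
  expect_equal(compute_pri(mk(0.04, 0.05)), (0.04 - 0.05) / 0.09)
  expect_equal(compute_pri(mk(0.07, 0.07)), 0)
  expect_equal(compute_pri(mk(0.03, 0)), 1)

  set.seed(42)
  for (i in 1:20) {
    a <- runif(1, 0.01, 0.2); b <- runif(1, 0.01, 0.2)
    expect_equal(compute_pri(mk(a, b)), -compute_pri(mk(b, a)))
    expect_lte(abs(compute_pri(mk(a, b))), 1)
  }
  expect_error(compute_pri(mk(0, 0)), "undefined")
})

test_that("3FLD weights follow the band spacing and sum to one", {
  w <- fld_weights(fld_band_config(762, 758, 769))
  expect_equal(unname(w), c(7 / 11, 4 / 11))
  expect_equal(unname(fld_weights(fld_band_config(760, 755, 765))),
               c(0.5, 0.5))
  set.seed(7)
  for (i in 1:20) {
    left <- runif(1, 750, 758); right <- runif(1, 765, 775)
    mid <- runif(1, left + 0.5, right - 0.5)
    expect_equal(sum(fld_weights(fld_band_config(mid, left, right))), 1)
  }
  expect_error(fld_band_config(762, 769, 758), "lambda_left")
})

test_that("3FLD is exact for spectrally constant reflectance and SIF", {
  wl <- seq(740, 790, by = 1)
  # worked case: flat r = 0.5, F = 0.02, outer E = 1, in-band E = 0.3
  e_v <- rep(1, length(wl)); e_v[abs(wl - 762) <= 1] <- 0.3
  e <- spectrum(wl, e_v, "downwelling")
  l <- spectrum(wl, 0.5 * e_v + 0.02, "reflected")
  expect_equal(as.numeric(retrieve_sif_3fld(l, e)), 0.02, tolerance = 1e-12)

  # zero fluorescence retrieves zero
  l0 <- spectrum(wl, 0.5 * e_v, "reflected")
  expect_equal(as.numeric(retrieve_sif_3fld(l0, e)), 0, tolerance = 1e-12)

  # doubling the reflected term at fixed F leaves the retrieval fixed
  l2 <- spectrum(wl, 2 * 0.5 * e_v + 0.02, "reflected")
  expect_equal(as.numeric(retrieve_sif_3fld(l2, e)), 0.02,
               tolerance = 1e-12)

  # no dip -> no contrast error
  flat <- spectrum(wl, rep(1, length(wl)), "downwelling")
  lf <- spectrum(wl, 0.5 * rep(1, length(wl)) + 0.02, "reflected")
  expect_error(retrieve_sif_3fld(lf, flat), "contrast")

  # negative retrievals are flagged, not clipped
  ln <- spectrum(wl, 0.5 * e_v - 0.01, "reflected")
  sif <- retrieve_sif_3fld(ln, e)
  expect_lt(as.numeric(sif), 0)
  expect_true(attr(sif, "qc_negative"))
})

test_that("processing an angular scan inverts the generator's forward model", {
  truth <- campaign_truth(seed = 5, mode = "twoleaf-exact",
                          noise_index = 0, n_reps = 1)
  sc <- synth_angular_scan(truth, 224, 12)
  out <- process_angular_scan(sc$scan)
  expect_equal(nrow(out), nrow(sc$indices))  # row count preserved
  expect_equal(out$pri, sc$indices$pri, tolerance = 1e-10)
  expect_equal(out$sif, sc$indices$sif, tolerance = 1e-10)
  expect_equal(out$refl_670, sc$indices$refl_670, tolerance = 1e-10)
  expect_error(process_angular_scan(sc$scan[0, ]), "empty")
})
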