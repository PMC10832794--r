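make_samples <- function(n_days = 25, slots = seq(9, 15, by = 0.5),
                         seed = 1) {
  doys <- c(215, 217, 220, 222, 224, 227, 230, 233, 235, 238, 241, 243,
            246, 248, 251, 254, 256, 259, 262, 264, 267, 269, 271, 274,
            277)[seq_len(n_days)]
  set.seed(seed)
  g <- expand.grid(slot = slots, doy = doys)
  g$timestamp <- g$doy * 86400 + g$slot * 3600
  g$sif_tot <- runif(nrow(g), 0.02, 0.18)
  g$pri_tot <- runif(nrow(g), -0.1, -0.02)
  g$sif_hs <- g$sif_tot * 0.8 + rnorm(nrow(g), 0, 0.01)
  g$pri_hs <- g$pri_tot + rnorm(nrow(g), 0, 0.01)
  g$lai <- synth_lai(g$doy)
  g$t_air <- runif(nrow(g), 20, 34)
  g$vpd <- runif(nrow(g), 0.5, 3.5)
  g$par <- runif(nrow(g), 300, 2000)
  g$gpp <- 118.06 * g$sif_tot - 130.47 * g$pri_tot - 5.29
  g
}

test_that("the DOY split reproduces the 286/39 campaign partition", {
  samples <- make_samples()
  sp <- split_dataset(samples, c(224, 251, 271))
  expect_equal(nrow(sp$modeling), 286)
  expect_equal(nrow(sp$validation), 39)
  expect_equal(nrow(sp$modeling) + nrow(sp$validation), nrow(samples))
  expect_length(intersect(sp$modeling$timestamp, sp$validation$timestamp), 0)
  expect_error(split_dataset(samples, integer(0)), "nonempty")
  expect_error(split_dataset(samples, c(1, 2)), "empty")
  expect_error(split_dataset(samples, unique(samples$doy)), "modeling")
})

test_that("regression recovers an exact linear GPP law", {
  samples <- make_samples()
  fit <- fit_gpp_model(samples, c("pri", "sif"), "tot")
  expect_equal(unname(fit$coefficients),
               c(-5.29, -130.47, 118.06), tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_lt(fit$rmse, 1e-8)

  # permutation invariance
  fit2 <- fit_gpp_model(samples[sample(nrow(samples)), ],
                        c("pri", "sif"), "tot")
  expect_equal(fit$coefficients, fit2$coefficients, tolerance = 1e-10)

  # degenerate inputs
  const <- samples; const$sif_tot <- 0.1
  expect_error(fit_gpp_model(const, "sif", "tot"), "constant")
  flat <- samples; flat$gpp <- 5
  expect_equal(fit_gpp_model(flat, "sif", "tot")$r2, 0, tolerance = 1e-10)
})

test_that("validation metrics follow the RMSE and RPD definitions", {
  obs <- c(1, 2, 3); pred <- c(2, 2, 2)
  rmse <- sqrt(mean((obs - pred)^2))
  expect_equal(rmse, sqrt(2 / 3))
  expect_equal(sd(obs) / rmse, sqrt(3 / 2))

  samples <- make_samples()
  sp <- split_dataset(samples)
  fit <- fit_gpp_model(sp$modeling, "sif", "tot")
  ev <- evaluate_model(fit, sp$validation)
  # RPD * RMSE = SD identity
  expect_equal(ev$rpd * ev$rmse, ev$sd_validation, tolerance = 1e-12)
  expect_equal(ev$n_validation, 39)

  # perfect predictions give zero RMSE and infinite RPD
  perfect <- fit_gpp_model(sp$modeling, c("pri", "sif"), "tot")
  evp <- evaluate_model(perfect, sp$validation)
  expect_lt(evp$rmse, 1e-8)
  expect_equal(evp$r2, 1, tolerance = 1e-8)

  expect_error(evaluate_model(fit, sp$validation[1, ]), "fewer than 2")
})

test_that("adding a predictor never lowers the in-sample R2", {
  samples <- make_samples(seed = 3)
  samples$gpp <- samples$gpp + rnorm(nrow(samples), 0, 2)
  r_pri <- fit_gpp_model(samples, "pri", "tot")$r2
  r_sif <- fit_gpp_model(samples, "sif", "tot")$r2
  r_both <- fit_gpp_model(samples, c("pri", "sif"), "tot")$r2
  expect_gte(r_both, max(r_pri, r_sif))
})

test_that("stratified R2 reflects per-bin signal-to-noise", {
  set.seed(6)
  n <- 300
  lai <- runif(n, 3, 9)
  sif <- runif(n, 0.02, 0.2)
  noise_sd <- ifelse(lai > 7, 0.2, ifelse(lai > 6, 1.5, 6))
  d <- data.frame(lai = lai, sif_tot = sif,
                  gpp = 100 * sif + rnorm(n, 0, noise_sd))
  tab <- stratified_r2(d, "sif_tot", "lai", c(6, 7))
  expect_equal(nrow(tab), 3)
  expect_true(all(diff(tab$r2) > 0))  # monotone with construction
  expect_equal(tab$stars[3], "**")

  # identical data in all bins gives identical R2
  d2 <- rbind(transform(d, lai = 5), transform(d, lai = 6.5),
              transform(d, lai = 8))
  tab2 <- stratified_r2(d2, "sif_tot", "lai", c(6, 7))
  expect_equal(tab2$r2, rep(tab2$r2[1], 3), tolerance = 1e-12)

  # single point in a bin: undefined, not an error
  d3 <- d[d$lai > 7, ][1, ]
  tab3 <- stratified_r2(d3, "sif_tot", "lai", c(6, 7))
  expect_true(is.na(tab3$r2[3]))
  expect_error(stratified_r2(d, "sif_tot", "lai", c(7, 6)), "increasing")
})

test_that("daily aggregation computes means, errors, and sky class", {
  samples <- make_samples(n_days = 3)
  daily <- aggregate_daily(samples)
  expect_equal(nrow(daily), 3)
  expect_equal(daily$n, rep(13, 3))

  # a constant day has SE zero and mean equal to the value
  one <- samples[samples$doy == 215, ]
  one$gpp <- 7; one$par <- 999
  d1 <- aggregate_daily(one)
  expect_equal(d1$gpp_mean, 7)
  expect_equal(d1$gpp_se, 0)
  expect_equal(d1$sky, "cloudy")
  one$par <- 1001
  expect_equal(aggregate_daily(one)$sky, "clear")
})
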