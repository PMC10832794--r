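# End-to-end orchestration: synthetic campaign -> angular indices ->
# BRDF hotspot -> two-leaf totals -> flux partitioning -> GPP models.

pipeline_defaults <- function() {
  list(
    seed = 1,
    mode = "twoleaf-exact",
    validation_doys = c(224, 251, 271),
    noise_index = 0.002, noise_nee = 0.01, noise_gpp = 0.03,
    omega = 0.9, leaf_reflectance_670 = 0.05,
    h_over_b = 2, b_over_r = 1, min_obs = 30, max_condition = 1e6,
    ustar_threshold = 0.13, night_par_threshold = 5,
    nee_range = 3, diurnal_window_days = 7,
    run_twoleaf = TRUE, run_brdf = TRUE,
    out_dir = NULL
  )
}

#' Build and validate a pipeline configuration
#'
#' Merges user settings over the defaults; unknown keys are rejected.
#' Can read a YAML file.
#'
#' @param config Named list of settings, or a path to a YAML file.
#' @return Validated configuration list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown pipeline config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  utils::modifyList(defaults, config)
}

#' Merge per-group indices with partitioned fluxes into matched samples
#'
#' One row per half-hour group carrying GPP, the four index variants
#' (hotspot and total-canopy PRI/SIF), LAI, and the meteorology — the
#' sample table the regression stage consumes.
#'
#' @param brdf_table Output of [process_brdf()] (or NULL).
#' @param twoleaf_table Output of [process_two_leaf()] (or NULL).
#' @param flux_records Partitioned flux table (with `gpp`).
#' @param lai_by_group Named numeric LAI per group timestamp.
#' @return Matched-sample data frame with columns `timestamp`, `doy`,
#'   `gpp`, `pri_hs`, `sif_hs`, `pri_tot`, `sif_tot`, `lai`, `t_air`,
#'   `vpd`, `par`.
#' @export
build_matched_samples <- function(brdf_table, twoleaf_table, flux_records,
                                  lai_by_group) {
  stamps <- sort(unique(c(brdf_table$timestamp, twoleaf_table$timestamp)))
  wide <- data.frame(timestamp = stamps)
  pick <- function(tab, index, col) {
    m <- tab[tab$index_name == index, , drop = FALSE]
    m[[col]][match(stamps, m$timestamp)]
  }
  if (!is.null(brdf_table)) {
    wide$pri_hs <- pick(brdf_table, "pri", "hotspot_value")
    wide$sif_hs <- pick(brdf_table, "sif", "hotspot_value")
  }
  if (!is.null(twoleaf_table)) {
    wide$pri_tot <- pick(twoleaf_table, "pri", "rho_tot")
    wide$sif_tot <- pick(twoleaf_table, "sif", "rho_tot")
  }
  fi <- match(wide$timestamp, as.numeric(flux_records$timestamp))
  wide$gpp <- flux_records$gpp[fi]
  # Gap-filled NEE is an interpolation, not a measurement; samples for
  # the regression carry only measured GPP (the filled series remains
  # in the flux table for budgets and diurnal summaries).
  if ("qc" %in% names(flux_records)) {
    wide$gpp_measured <- flux_records$qc[fi] == "pass"
    wide$gpp[!wide$gpp_measured] <- NA_real_
  }
  wide$t_air <- flux_records$t_air[fi]
  wide$vpd <- if ("vpd" %in% names(flux_records))
    flux_records$vpd[fi] else NA_real_
  wide$par <- flux_records$par[fi]
  wide$doy <- floor(wide$timestamp / 86400)
  wide$lai <- unname(lai_by_group[as.character(wide$timestamp)])
  wide
}

#' Run the full pipeline on a synthetic campaign
#'
#' Generates the campaign for the configured seed, retrieves per-group
#' hotspot and total-canopy PRI/SIF, screens and partitions the flux
#' series, merges matched samples, splits by validation DOY, fits the
#' six GPP model forms, and computes stratified and daily summaries.
#' Deterministic for a fixed config.
#'
#' @param config A list or YAML path accepted by [pipeline_config()].
#' @return List: `samples`, `models` (the six-model table), `split`,
#'   `stratified` (per-factor tables), `daily`, `flux_fit`,
#'   `campaign`, `manifest`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- pipeline_config(config)
  truth <- campaign_truth(seed = cfg$seed, mode = cfg$mode,
                          noise_index = cfg$noise_index,
                          noise_nee = cfg$noise_nee,
                          noise_gpp = cfg$noise_gpp,
                          omega = cfg$omega,
                          leaf_reflectance_670 = cfg$leaf_reflectance_670)
  campaign <- synth_campaign(truth)
  idx <- campaign$index_table

  lai_daily <- interpolate_lai(campaign$lai_measured$doy,
                               campaign$lai_measured$lai,
                               sort(unique(idx$doy)))
  names(lai_daily) <- as.character(sort(unique(idx$doy)))
  lai_by_group <- stats::setNames(
    lai_daily[as.character(floor(unique(idx$timestamp) / 86400))],
    as.character(unique(idx$timestamp)))

  brdf_tab <- NULL
  if (cfg$run_brdf) {
    brdf_tab <- process_brdf(idx, kernel_params(cfg$h_over_b, cfg$b_over_r),
                             min_obs = cfg$min_obs,
                             max_condition = cfg$max_condition)
  }
  tl_tab <- NULL
  if (cfg$run_twoleaf) {
    tl_cfg <- two_leaf_config(cfg$omega, cfg$leaf_reflectance_670)
    tl_tab <- process_two_leaf(idx, lai_by_group, tl_cfg)
  }

  fl_cfg <- flux_config(ustar_threshold = cfg$ustar_threshold,
                        night_par_threshold = cfg$night_par_threshold,
                        nee_range = cfg$nee_range,
                        diurnal_window_days = cfg$diurnal_window_days)
  flux <- process_flux(campaign$flux, fl_cfg)

  samples <- build_matched_samples(brdf_tab, tl_tab, flux$records,
                                   lai_by_group)
  split <- split_dataset(samples, cfg$validation_doys)
  variants <- c(if (cfg$run_brdf) "hs", if (cfg$run_twoleaf) "tot")
  models <- model_table_variants(split$modeling, split$validation, variants)

  strat_col <- if (cfg$run_twoleaf) "sif_tot" else "sif_hs"
  strat <- list(
    lai = stratified_r2(samples, strat_col, "lai", c(6, 7)),
    t_air = stratified_r2(samples, strat_col, "t_air", c(25, 30)),
    vpd = stratified_r2(samples, strat_col, "vpd", c(2, 3))
  )
  daily <- aggregate_daily(samples)

  manifest <- list(
    seed = cfg$seed, mode = cfg$mode,
    config_hash = sum(utf8ToInt(jsonlite::toJSON(cfg, auto_unbox = TRUE))),
    n_groups = length(unique(idx$timestamp)),
    n_angular_records = nrow(idx),
    n_samples = nrow(samples),
    n_modeling = nrow(split$modeling),
    n_validation = nrow(split$validation),
    flux_qc = table(flux$records$qc)
  )
  list(samples = samples, models = models, split = split,
       stratified = strat, daily = daily, flux_fit = flux$fit,
       campaign = campaign, manifest = manifest)
}

# model_table restricted to the variants whose stage ran.
model_table_variants <- function(modeling, validation, variants) {
  forms <- list("pri", "sif", c("pri", "sif"))
  rows <- list()
  for (variant in variants) {
    for (p in forms) {
      fit <- fit_gpp_model(modeling, p, variant)
      ev <- evaluate_model(fit, validation)
      co <- fit$coefficients
      rows[[length(rows) + 1L]] <- data.frame(
        model = paste0(paste(toupper(p), collapse = "+"), "_", variant),
        intercept = unname(co["(Intercept)"]),
        coef_pri = if ("pri" %in% p)
          unname(co[predictor_columns("pri", variant)]) else NA_real_,
        coef_sif = if ("sif" %in% p)
          unname(co[predictor_columns("sif", variant)]) else NA_real_,
        r2 = fit$r2, rmse = fit$rmse, f_stat = fit$f_stat, n = fit$n,
        val_r2 = ev$r2, val_rmse = ev$rmse, val_rpd = ev$rpd,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
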