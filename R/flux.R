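# Eddy-covariance flux processing: quality screening, Van't Hoff
# respiration fit, gap filling, and NEE -> Re/GPP partitioning.
#
# Sign convention: NEE negative = net uptake. GPP = Re - NEE, so a
# strongly negative daytime NEE yields a large positive GPP.

#' Flux processing configuration
#'
#' @param ustar_threshold Nighttime friction-velocity threshold,
#'   m s-1; records below it at night are discarded (default 0.13).
#' @param night_par_threshold PAR (umol m-2 s-1) below which a
#'   half-hour counts as night (default 5).
#' @param nee_range Plausibility window on |NEE| in mg CO2 m-2 s-1;
#'   the "out of device range" screen (default 3).
#' @param rain_window_hours Exclusion window around rainfall events,
#'   hours on each side (default 1).
#' @param diurnal_window_days Half-width in days of the mean-diurnal
#'   gap-filling window (default 7).
#' @param t_ref Reference temperature for the respiration model, deg C
#'   (default 25).
#' @return A `flux_config` list.
#' @export
flux_config <- function(ustar_threshold = 0.13, night_par_threshold = 5,
                        nee_range = 3, rain_window_hours = 1,
                        diurnal_window_days = 7, t_ref = 25) {
  structure(list(ustar_threshold = ustar_threshold,
                 night_par_threshold = night_par_threshold,
                 nee_range = nee_range,
                 rain_window_hours = rain_window_hours,
                 diurnal_window_days = diurnal_window_days,
                 t_ref = t_ref),
            class = "flux_config")
}

check_flux_table <- function(records) {
  needed <- c("timestamp", "nee", "t_air", "par", "ustar", "rain_flag",
              "range_ok")
  if (!all(needed %in% names(records))) {
    stop("flux table is missing columns: ",
         paste(setdiff(needed, names(records)), collapse = ", "),
         call. = FALSE)
  }
  ts <- as.numeric(records$timestamp)
  if (is.unsorted(ts, strictly = TRUE)) {
    stop("flux records must be strictly time-ordered without duplicates",
         call. = FALSE)
  }
  invisible(records)
}

#' Screen half-hourly flux records
#'
#' Applies the four invalid-data standards: (a) out of instrument
#' range, (b) negative NEE at night, (c) within the exclusion window
#' before/after a rainfall event, (d) nighttime friction velocity below
#' the u* threshold. Records are kept in the table; failures get their
#' rule letter in `qc` and their NEE masked to NA in `nee_screened`.
#' Survivors are unchanged.
#'
#' @param records Half-hourly flux data frame with columns `timestamp`
#'   (POSIXct or numeric seconds), `nee`, `t_air`, `par`, `ustar`,
#'   `rain_flag`, `range_ok` (and optionally `vpd`).
#' @param cfg A [flux_config()].
#' @return The table with added columns `is_night`, `qc` ("pass" or the
#'   rule letter, first failing rule in a-d order), `nee_screened`.
#' @export
apply_quality_filters <- function(records, cfg = flux_config()) {
  check_flux_table(records)
  ts <- as.numeric(records$timestamp)
  night <- records$par < cfg$night_par_threshold
  qc <- rep("pass", nrow(records))

  miss <- !is.finite(records$nee)
  rule_a <- !records$range_ok |
    (!miss & abs(records$nee) > cfg$nee_range)
  rule_b <- night & !miss & records$nee < 0
  rain_ts <- ts[records$rain_flag]
  rule_c <- rep(FALSE, nrow(records))
  if (length(rain_ts) > 0) {
    win <- cfg$rain_window_hours * 3600
    for (rt in rain_ts) rule_c <- rule_c | (ts >= rt - win & ts <= rt + win)
  }
  rule_d <- night & records$ustar < cfg$ustar_threshold

  # Tag each removal with the first failing rule, in a-d order.
  qc[rule_d] <- "d"
  qc[rule_c] <- "c"
  qc[rule_b] <- "b"
  qc[rule_a] <- "a"
  qc[miss & qc == "pass"] <- "m"

  records$is_night <- night
  records$qc <- qc
  records$nee_screened <- ifelse(qc == "pass", records$nee, NA_real_)
  records
}

#' Fit the Van't Hoff respiration model to screened nighttime NEE
#'
#' Nighttime NEE is taken as ecosystem respiration and fitted with
#' Re = Re_ref * exp(B (T - T_ref)), T_ref fixed at 25 deg C, by
#' untransformed nonlinear least squares (Levenberg-Marquardt).
#'
#' @param records Output of [apply_quality_filters()].
#' @param cfg A [flux_config()].
#' @return A `vant_hoff_fit` list: `re_ref` (mg CO2 m-2 s-1 at T_ref),
#'   `b` (per deg C), `t_ref`, `n_fit`, `rss`.
#' @export
fit_vant_hoff <- function(records, cfg = flux_config()) {
  night <- records[records$is_night & records$qc == "pass" &
                     is.finite(records$nee_screened) &
                     is.finite(records$t_air), , drop = FALSE]
  if (nrow(night) < 10) {
    stop("fewer than 10 screened nighttime records", call. = FALSE)
  }
  if (diff(range(night$t_air)) < 5) {
    stop("nighttime temperature spread below 5 deg C: ",
         "respiration sensitivity is unidentifiable", call. = FALSE)
  }
  df <- data.frame(nee = night$nee_screened,
                   dt = night$t_air - cfg$t_ref)
  fit <- minpack.lm::nlsLM(
    nee ~ re_ref * exp(b * dt), data = df,
    start = list(re_ref = max(mean(df$nee), 1e-3), b = 0.1),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  co <- stats::coef(fit)
  structure(list(re_ref = unname(co["re_ref"]), b = unname(co["b"]),
                 t_ref = cfg$t_ref, n_fit = nrow(df),
                 rss = sum(stats::resid(fit)^2)),
            class = "vant_hoff_fit")
}

#' Predict ecosystem respiration from air temperature
#'
#' @param fit A `vant_hoff_fit`.
#' @param t_air Air temperature, deg C.
#' @return Re in mg CO2 m-2 s-1, vectorised.
#' @export
predict_re <- function(fit, t_air) {
  fit$re_ref * exp(fit$b * (t_air - fit$t_ref))
}

#' Fill screened/missing half-hours
#'
#' Daytime gaps are filled with the mean diurnal course: the mean of
#' the same half-hour slot on days within the configured window.
#' Nighttime gaps are filled with the fitted respiration model at the
#' record's temperature. Unfillable slots (no donors, missing T) are
#' flagged, not errors. Non-missing records are never changed.
#'
#' @param records Output of [apply_quality_filters()].
#' @param fit A `vant_hoff_fit`.
#' @param cfg A [flux_config()].
#' @return The table with `nee_filled`, `filled` (logical), and
#'   `unfillable` (logical) columns.
#' @export
fill_gaps <- function(records, fit, cfg = flux_config()) {
  ts <- as.numeric(records$timestamp)
  day_index <- floor(ts / 86400)
  slot <- round((ts %% 86400) / 1800)
  filled <- records$nee_screened
  was_gap <- !is.finite(filled)
  unfillable <- rep(FALSE, nrow(records))

  for (i in which(was_gap)) {
    if (records$is_night[i]) {
      if (is.finite(records$t_air[i])) {
        filled[i] <- predict_re(fit, records$t_air[i])
      } else {
        unfillable[i] <- TRUE
      }
    } else {
      donors <- which(!was_gap & slot == slot[i] &
                        abs(day_index - day_index[i]) <=
                        cfg$diurnal_window_days &
                        seq_along(ts) != i)
      if (length(donors) > 0) {
        filled[i] <- mean(records$nee_screened[donors])
      } else {
        unfillable[i] <- TRUE
      }
    }
  }
  records$nee_filled <- filled
  records$filled <- was_gap & !unfillable
  records$unfillable <- unfillable
  records
}

#' Partition NEE into respiration and GPP
#'
#' Re is the Van't Hoff model at each record's temperature; GPP = Re -
#' NEE. Nighttime GPP is set to 0 by definition (no photosynthetically
#' active radiation).
#'
#' @param records Output of [fill_gaps()] (or of
#'   [apply_quality_filters()]; then `nee_screened` is used).
#' @param fit A `vant_hoff_fit`.
#' @return The table with `re` and `gpp` columns.
#' @export
partition_gpp <- function(records, fit) {
  nee <- if ("nee_filled" %in% names(records)) records$nee_filled
         else records$nee_screened
  re <- ifelse(is.finite(records$t_air), predict_re(fit, records$t_air),
               NA_real_)
  gpp <- re - nee
  gpp[records$is_night] <- 0
  records$re <- re
  records$gpp <- gpp
  records
}

#' Run the full flux chain
#'
#' Screen, fit respiration, gap-fill, and partition in one call.
#'
#' @param records Raw half-hourly flux table.
#' @param cfg A [flux_config()].
#' @return List `records` (processed table) and `fit` (the
#'   `vant_hoff_fit`).
#' @export
process_flux <- function(records, cfg = flux_config()) {
  screened <- apply_quality_filters(records, cfg)
  fit <- fit_vant_hoff(screened, cfg)
  filled <- fill_gaps(screened, fit, cfg)
  list(records = partition_gpp(filled, fit), fit = fit)
}
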