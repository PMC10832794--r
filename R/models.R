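# GPP regression models: dataset split, the six PRI/SIF model forms,
# validation metrics (RMSE, RPD), environmental stratification, and
# daily aggregation.

#' Split matched samples into modeling and validation sets by DOY
#'
#' Whole days are held out: rows whose day of year falls in
#' `validation_doys` form the validation set. The split is a partition.
#'
#' @param samples Data frame with a `doy` column (one row per matched
#'   half-hour group).
#' @param validation_doys Integer days of year to hold out (the field
#'   campaign used 224, 251, and 271 — tassel, filling, maturity).
#' @return List `modeling`, `validation`.
#' @export
split_dataset <- function(samples, validation_doys = c(224, 251, 271)) {
  if (length(validation_doys) == 0) {
    stop("validation_doys must be nonempty", call. = FALSE)
  }
  in_val <- samples$doy %in% validation_doys
  if (!any(in_val)) stop("validation set is empty", call. = FALSE)
  if (all(in_val)) stop("modeling set is empty", call. = FALSE)
  list(modeling = samples[!in_val, , drop = FALSE],
       validation = samples[in_val, , drop = FALSE])
}

predictor_columns <- function(predictors, variant) {
  stopifnot(all(predictors %in% c("pri", "sif")),
            variant %in% c("hs", "tot"))
  paste0(predictors, "_", variant)
}

#' Fit a PRI/SIF GPP estimation model
#'
#' Ordinary least squares of GPP on the chosen predictor set (PRI, SIF,
#' or both; hotspot or total-canopy variant) with intercept. Reports
#' the in-sample coefficient of determination, RMSE (divisor n), and
#' the regression F statistic.
#'
#' @param modeling Data frame with `gpp` and the predictor columns
#'   (`pri_hs`, `pri_tot`, `sif_hs`, `sif_tot`).
#' @param predictors Character subset of `c("pri", "sif")`.
#' @param variant `"hs"` (hotspot) or `"tot"` (total canopy).
#' @return A `gpp_model_fit`: `coefficients` (named, incl.
#'   `(Intercept)`), `r2`, `rmse`, `f_stat`, `n`, `predictors`,
#'   `variant`.
#' @export
fit_gpp_model <- function(modeling, predictors = c("pri", "sif"),
                          variant = c("tot", "hs")) {
  variant <- match.arg(variant)
  cols <- predictor_columns(predictors, variant)
  keep <- stats::complete.cases(modeling[, c("gpp", cols), drop = FALSE])
  d <- modeling[keep, , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 complete rows", call. = FALSE)
  for (cc in cols) {
    if (stats::sd(d[[cc]]) == 0) {
      stop(sprintf("predictor %s is constant", cc), call. = FALSE)
    }
  }
  fml <- stats::as.formula(paste("gpp ~", paste(cols, collapse = " + ")))
  fit <- stats::lm(fml, data = d)
  n <- nrow(d); p <- length(cols)
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((d$gpp - mean(d$gpp))^2)
  r2 <- if (tss == 0) 0 else max(0, min(1, 1 - rss / tss))
  f_stat <- if (tss == 0) NA_real_
            else if (rss == 0) Inf
            else ((tss - rss) / p) / (rss / (n - p - 1))
  structure(list(
    coefficients = stats::coef(fit),
    r2 = r2,
    rmse = sqrt(rss / n),
    f_stat = f_stat,
    n = n, predictors = predictors, variant = variant,
    lm = fit
  ), class = "gpp_model_fit")
}

#' Predict GPP from a fitted model
#'
#' @param object A `gpp_model_fit`.
#' @param newdata Data frame with the model's predictor columns.
#' @param ... Unused.
#' @return Predicted GPP.
#' @export
predict.gpp_model_fit <- function(object, newdata, ...) {
  unname(stats::predict(object$lm, newdata = newdata))
}

#' Evaluate a GPP model on a validation set
#'
#' Out-of-sample metrics: R2 (squared Pearson correlation of observed
#' and predicted), RMSE with divisor n, and the relative prediction
#' deviation RPD = SD(observed) / RMSE, with SD the sample (n-1)
#' standard deviation of the validation GPP. RPD > 2 marks an
#' excellent model, RPD < 1.5 a model without predictive power.
#'
#' @param fit A `gpp_model_fit`.
#' @param validation Data frame with `gpp` and the predictor columns.
#' @return An `evaluation_report`: `r2`, `rmse`, `rpd`,
#'   `sd_validation`, `n_validation`. RPD is `Inf` when RMSE is 0.
#' @export
evaluate_model <- function(fit, validation) {
  cols <- predictor_columns(fit$predictors, fit$variant)
  keep <- stats::complete.cases(validation[, c("gpp", cols), drop = FALSE])
  d <- validation[keep, , drop = FALSE]
  if (nrow(d) < 2) {
    stop("validation standard deviation undefined with fewer than 2 rows",
         call. = FALSE)
  }
  pred <- predict(fit, d)
  rmse <- sqrt(mean((d$gpp - pred)^2))
  sdv <- stats::sd(d$gpp)
  structure(list(
    r2 = if (stats::sd(pred) == 0) 0 else stats::cor(d$gpp, pred)^2,
    rmse = rmse,
    rpd = if (rmse == 0) Inf else sdv / rmse,
    sd_validation = sdv, n_validation = nrow(d)
  ), class = "evaluation_report")
}

#' Fit and evaluate the six standard model forms
#'
#' PRI-only, SIF-only, and PRI+SIF, each in the hotspot and
#' total-canopy variants.
#'
#' @param modeling,validation Matched-sample data frames.
#' @return Data frame, one row per model: predictor set, variant,
#'   coefficients, in-sample R2/RMSE/F, validation R2/RMSE/RPD.
#' @export
model_table <- function(modeling, validation) {
  model_table_variants(modeling, validation, c("hs", "tot"))
}

#' Stratified univariate R2 between GPP and one index
#'
#' Bins the samples by an environmental factor (LAI, temperature, or
#' VPD) and reports the per-bin R2 of the univariate regression of GPP
#' on the index, with significance stars from the regression F test
#' (* p < 0.05, ** p < 0.01). Bins with fewer than 3 rows get NA.
#'
#' @param samples Matched-sample data frame.
#' @param index_name Column to regress GPP on (e.g. `"sif_tot"`).
#' @param factor_name Column to bin by (e.g. `"lai"`, `"t_air"`,
#'   `"vpd"`).
#' @param breaks Strictly increasing inner bin edges; default LAI-style
#'   `c(6, 7)` giving bins (-Inf,6\], (6,7\], (7,Inf).
#' @return Data frame: bin label, n, r2, p_value, stars.
#' @export
stratified_r2 <- function(samples, index_name, factor_name,
                          breaks = c(6, 7)) {
  if (any(diff(breaks) <= 0)) {
    stop("bin edges must be strictly increasing", call. = FALSE)
  }
  edges <- c(-Inf, breaks, Inf)
  bins <- cut(samples[[factor_name]], edges)
  out <- lapply(levels(bins), function(b) {
    d <- samples[!is.na(bins) & bins == b, , drop = FALSE]
    d <- d[stats::complete.cases(d[, c("gpp", index_name)]), , drop = FALSE]
    if (nrow(d) < 3 || stats::sd(d[[index_name]]) == 0 ||
        stats::sd(d$gpp) == 0) {
      return(data.frame(bin = b, n = nrow(d), r2 = NA_real_,
                        p_value = NA_real_, stars = "",
                        stringsAsFactors = FALSE))
    }
    fit <- stats::lm(d$gpp ~ d[[index_name]])
    sm <- summary(fit)
    p <- stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                   lower.tail = FALSE)
    data.frame(bin = b, n = nrow(d), r2 = sm$r.squared, p_value = unname(p),
               stars = if (p < 0.01) "**" else if (p < 0.05) "*" else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Aggregate matched half-hourly samples to daily values
#'
#' Per-day mean and standard error of GPP, the four indices, and PAR,
#' plus a sky class: "cloudy" when the daily mean PAR is below
#' 1,000 umol m-2 s-1, else "clear".
#'
#' @param samples Matched-sample data frame with `doy` and the value
#'   columns.
#' @param par_cloudy_threshold Daily-mean PAR threshold (default 1000).
#' @return Data frame, one row per day: means, standard errors, `n`,
#'   `sky`.
#' @export
aggregate_daily <- function(samples, par_cloudy_threshold = 1000) {
  value_cols <- intersect(c("gpp", "pri_hs", "pri_tot", "sif_hs", "sif_tot",
                            "par"), names(samples))
  days <- split(samples, samples$doy)
  rows <- lapply(days, function(d) {
    out <- data.frame(doy = d$doy[1], n = nrow(d))
    for (cc in value_cols) {
      v <- d[[cc]][is.finite(d[[cc]])]
      out[[paste0(cc, "_mean")]] <- mean(v)
      out[[paste0(cc, "_se")]] <- if (length(v) > 1)
        stats::sd(v) / sqrt(length(v)) else 0
    }
    out$sky <- if (out$par_mean < par_cloudy_threshold) "cloudy" else "clear"
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$doy), , drop = FALSE]
}
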