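#' Linear volume calibration from band signals
#'
#' Fits a least-squares affine map from the rib-cage and abdomen band
#' signals to a reference volume signal and returns the calibrated
#' volume. This is a deliberately simple calibration model: tidal volume
#' is reconstructed as `a*ribcage + b*abdomen + c`, which is adequate for
#' the simulator's linear band mixing and keeps the calibration step
#' transparent and testable.
#'
#' @param ribcage,abdomen,volume_ref equal-length numeric vectors
#'   (>= 100 samples); `volume_ref` in liters.
#' @return A list: `coefficients` (intercept, ribcage, abdomen),
#'   `volume` (fitted volume series), `r_squared`.
#' @export
calibrate_volume <- function(ribcage, abdomen, volume_ref) {
  n <- length(volume_ref)
  if (length(ribcage) != n || length(abdomen) != n) {
    stop("band and reference signals must have equal length", call. = FALSE)
  }
  if (n < 100) stop("need at least 100 samples for calibration", call. = FALSE)
  if (stats::sd(volume_ref) == 0) {
    stop("volume_ref is constant; cannot calibrate", call. = FALSE)
  }
  if (stats::sd(ribcage) == 0 && stats::sd(abdomen) == 0) {
    stop("both band signals are constant; calibration is rank-deficient",
         call. = FALSE)
  }
  fit <- stats::lm(volume_ref ~ ribcage + abdomen)
  vol <- as.numeric(stats::fitted(fit))
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((volume_ref - mean(volume_ref))^2)
  list(coefficients = stats::coef(fit),
       volume = breath_series(vol, unit = "liters", index_kind = "time"),
       r_squared = r2)
}

#' Detect breath peaks in a volume waveform
#'
#' Finds local maxima of the calibrated volume signal subject to a
#' minimum peak separation and a minimum prominence expressed as a
#' fraction of the signal SD. Defaults (1 s separation, 0.5 SD
#' prominence) sit below the physiologic minimum inter-breath interval
#' and are robust to asymmetric breath lobes.
#'
#' @param volume numeric vector or time-indexed `breath_series`.
#' @param fs sampling rate, Hz.
#' @param min_separation minimum time between accepted peaks, seconds.
#' @param min_prominence minimum peak prominence as a multiple of the
#'   signal SD.
#' @return A data.frame with columns `peak_time_s` and `peak_volume_L`.
#' @export
detect_breaths <- function(volume, fs, min_separation = 1,
                           min_prominence = 0.5) {
  v <- as_values(volume)
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  if (length(v) < 3) stop("waveform too short", call. = FALSE)
  s <- stats::sd(v)
  if (s == 0) stop("no peaks found: signal is flat", call. = FALSE)
  pk <- pracma::findpeaks(v,
                          minpeakdistance = max(1L, round(min_separation * fs)),
                          minpeakheight = min(v) + min_prominence * s)
  if (is.null(pk) || nrow(pk) == 0L) {
    stop("no peaks found with the given thresholds", call. = FALSE)
  }
  ord <- order(pk[, 2])
  data.frame(peak_time_s = pk[ord, 2] / fs,
             peak_volume_L = pk[ord, 1])
}

#' Breath-indexed series from a breath table
#'
#' Converts detected peaks to the two analysis series: peak-to-peak
#' intervals form the inter-breath interval (IBI) series (length n - 1)
#' and peak amplitudes form the lung volume (LV) series (length n).
#'
#' @param breaths data.frame with `peak_time_s` (strictly increasing)
#'   and `peak_volume_L` columns.
#' @return A list with `ibi` (seconds) and `lv` (liters) series.
#' @export
series_from_breaths <- function(breaths) {
  tt <- breaths$peak_time_s
  vv <- breaths$peak_volume_L
  if (length(tt) < 2) stop("need at least 2 peaks", call. = FALSE)
  if (any(diff(tt) <= 0)) {
    stop("peak times must be strictly increasing", call. = FALSE)
  }
  list(ibi = breath_series(diff(tt), unit = "seconds"),
       lv = breath_series(vv, unit = "liters"))
}

#' Remove artifactual breaths from an IBI series
#'
#' Drops values outside physiologic bounds and, after that, values more
#' than `z_limit` robust SDs (median absolute deviation) from the
#' median. The bounds rule runs first so that an isolated spike in an
#' otherwise constant series is still caught when the MAD is zero.
#' Artifact criteria in ambulatory recordings are ultimately a judgment
#' call; both rules are configurable and every removal is logged.
#'
#' @param series numeric vector or `breath_series`.
#' @param ibi_bounds length-2 numeric, admissible interval in the
#'   series' unit (default 0.5 to 15 s).
#' @param z_limit robust z-score limit (default 5).
#' @return A list: `series` (cleaned), `removed` (data.frame of index,
#'   value, rule), `warning_high_removal` (TRUE when > 20% removed).
#' @export
remove_artifacts <- function(series, ibi_bounds = c(0.5, 15), z_limit = 5) {
  x <- as_values(series)
  if (length(x) == 0L) stop("empty series", call. = FALSE)
  out_bounds <- which(x < ibi_bounds[1] | x > ibi_bounds[2])
  keep <- setdiff(seq_along(x), out_bounds)
  med <- stats::median(x[keep])
  rsd <- stats::mad(x[keep])
  out_z <- if (rsd > 0) {
    keep[abs(x[keep] - med) / rsd > z_limit]
  } else integer(0)
  removed_idx <- sort(c(out_bounds, out_z))
  log <- data.frame(
    index = removed_idx,
    value = x[removed_idx],
    rule = ifelse(removed_idx %in% out_bounds, "bounds", "robust_z"))
  kept <- x[setdiff(seq_along(x), removed_idx)]
  frac <- length(removed_idx) / length(x)
  res <- list(series = breath_series(kept,
                                     unit = series_unit(series),
                                     meta = list(removed = length(removed_idx))),
              removed = log,
              warning_high_removal = frac > 0.2)
  if (res$warning_high_removal) {
    warning(sprintf("%.0f%% of values flagged as artifacts", 100 * frac),
            call. = FALSE)
  }
  res
}

#' Z-normalize a series
#'
#' Centers and scales so the output has mean 0 and sample SD exactly 1
#' (n - 1 denominator). All complexity indices are computed on
#' normalized series so that subjects with different absolute rates and
#' volumes are comparable and the entropy tolerance `r` reads as a
#' fraction of SD.
#'
#' @param series numeric vector or `breath_series`, length >= 2,
#'   non-constant.
#' @return A dimensionless `breath_series` with mean 0 and sample SD 1.
#' @export
znormalize <- function(series) {
  x <- as_values(series)
  if (length(x) < 2) stop("need at least 2 values", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) stop("constant series cannot be normalized", call. = FALSE)
  breath_series((x - mean(x)) / s, unit = "dimensionless",
                meta = attr(series, "meta") %||% list())
}

#' Mean and coefficient of variation
#'
#' @param series numeric vector or `breath_series`, length >= 2.
#' @return A list with `mean`, `sd` (sample SD) and `cv` (SD/mean; `NaN`
#'   with a flag when the mean is zero).
#' @export
summary_stats <- function(series) {
  x <- as_values(series)
  if (length(x) < 2) stop("need at least 2 values", call. = FALSE)
  m <- mean(x)
  s <- stats::sd(x)
  list(mean = m, sd = s,
       cv = if (m == 0) NaN else s / m,
       cv_defined = m != 0)
}
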