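#' Colored (power-law) noise by spectral synthesis
#'
#' Generates a zero-mean, unit-SD series whose power spectral density is
#' proportional to \eqn{1/f^\beta}. Fourier amplitudes are set to
#' \eqn{f^{-\beta/2}} with independent Gaussian real/imaginary parts and
#' the result is inverse-transformed and standardized. For such a signal
#' the expected detrended-fluctuation scaling exponent is
#' \eqn{\alpha = (\beta + 1)/2}: white noise (\eqn{\beta = 0}) gives
#' \eqn{\alpha = 0.5}, 1/f noise gives \eqn{\alpha = 1}, Brownian noise
#' (\eqn{\beta = 2}) gives \eqn{\alpha = 1.5}.
#'
#' @param n series length (>= 64).
#' @param beta spectral exponent in `[0, 3]`.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return A dimensionless `breath_series` of length `n` with mean 0 and
#'   sample SD 1.
#' @examples
#' x <- colored_noise(1024, beta = 1, seed = 42)
#' dfa(x)$alpha  # close to 1
#' @export
colored_noise <- function(n, beta, seed = NULL) {
  if (n < 64) stop("n must be at least 64", call. = FALSE)
  if (!is.finite(beta) || beta < 0 || beta > 3) {
    stop("beta must be finite and in [0, 3]", call. = FALSE)
  }
  x <- with_seed(seed, {
    nfft <- n
    nf <- nfft %/% 2L
    f <- seq_len(nf) / nfft
    amp <- f^(-beta / 2)
    re <- stats::rnorm(nf) * amp
    im <- stats::rnorm(nf) * amp
    spec <- complex(real = re, imaginary = im)
    # Hermitian-symmetric spectrum -> real signal; for even n the
    # Nyquist bin is kept real and mirrored bins exclude it.
    mirror <- if (nfft %% 2L == 0L) {
      spec[nf] <- complex(real = re[nf], imaginary = 0)
      seq_len(nf - 1L)
    } else {
      seq_len(nf)
    }
    full <- c(complex(real = 0, imaginary = 0), spec,
              Conj(rev(spec[mirror])))
    Re(stats::fft(full, inverse = TRUE)) / nfft
  })
  x <- (x - mean(x)) / stats::sd(x)
  breath_series(x, unit = "dimensionless",
                meta = list(generator = "colored_noise", beta = beta,
                            seed = seed))
}

#' Logistic-map series
#'
#' Iterates \eqn{x_{t+1} = r x_t (1 - x_t)} from `x0`, discarding
#' `burn_in` initial iterates. At `r = 4` the map is fully chaotic with
#' analytic Lyapunov exponent \eqn{\ln 2 \approx 0.693} per iteration;
#' this series is the standard positive control for Lyapunov-exponent
#' estimators.
#'
#' @param n number of values returned.
#' @param r map parameter in `(0, 4]`.
#' @param x0 initial value in `(0, 1)`.
#' @param burn_in iterations discarded before recording (>= 0).
#' @return A dimensionless `breath_series` of length `n`.
#' @examples
#' logistic_series(3, r = 4, x0 = 0.2)  # 0.2, 0.64, 0.9216
#' @export
logistic_series <- function(n, r = 4, x0 = 0.2, burn_in = 0L) {
  if (x0 <= 0 || x0 >= 1) stop("x0 must lie in (0, 1)", call. = FALSE)
  if (r <= 0 || r > 4) stop("r must lie in (0, 4]", call. = FALSE)
  if (burn_in < 0) stop("burn_in must be >= 0", call. = FALSE)
  total <- n + burn_in
  x <- numeric(total)
  x[1L] <- x0
  for (t in seq_len(total - 1L)) x[t + 1L] <- r * x[t] * (1 - x[t])
  breath_series(x[(burn_in + 1L):total], unit = "dimensionless",
                meta = list(generator = "logistic", r = r, x0 = x0))
}

#' Noisy periodic series
#'
#' A unit-amplitude sinusoid of the given period plus iid Gaussian noise.
#' With `noise_sd = 0` the output is exactly periodic (and the seed is
#' irrelevant); sample entropy of the clean sinusoid is far below the
#' iid-noise value, and grows toward it as `noise_sd` increases.
#'
#' @param n series length.
#' @param period period in samples (>= 2).
#' @param noise_sd SD of the additive Gaussian noise.
#' @param seed integer seed.
#' @return A dimensionless `breath_series`.
#' @export
periodic_series <- function(n, period, noise_sd = 0, seed = NULL) {
  if (period < 2) stop("period must be >= 2", call. = FALSE)
  x <- sin(2 * pi * seq_len(n) / period)
  if (noise_sd > 0) {
    x <- x + with_seed(seed, stats::rnorm(n, sd = noise_sd))
  }
  breath_series(x, unit = "dimensionless",
                meta = list(generator = "periodic", period = period,
                            noise_sd = noise_sd, seed = seed))
}

#' Pair of series with a controlled common driver
#'
#' Two zero-mean unit-SD series sharing a common driver with correlation
#' `coupling`. `coupling = 1` returns two identical series; `coupling =
#' 0` returns independent ones. Used to validate that cross-sample
#' entropy decreases as synchronization strengthens. The drivers are
#' colored noise with spectral exponent `beta`; the default (`beta = 1`)
#' gives temporally correlated, physiologically plausible signals, for
#' which synchronization shifts the template-match statistics of O(n^2)
#' series pairs. With white drivers (`beta = 0`) only the n aligned
#' pairs feel the coupling, so the cross-entropy of a weakly coupled
#' white pair is indistinguishable from independence at realistic n --
#' use `beta = 0` when the target is the iid reference value itself.
#'
#' @param n series length (>= 64).
#' @param coupling correlation of the two drivers, in `[-1, 1]`.
#' @param beta spectral exponent of the drivers (0 = white).
#' @param seed integer seed.
#' @return A list with elements `a` and `b`, each a `breath_series`.
#' @export
coupled_pair <- function(n, coupling, beta = 1, seed = NULL) {
  if (abs(coupling) > 1) stop("|coupling| must be <= 1", call. = FALSE)
  z <- as_values(colored_noise(n, beta, seed = seed))
  e <- as_values(colored_noise(n, beta,
                               seed = if (is.null(seed)) NULL
                                      else seed + 5000L))
  b <- coupling * z + sqrt(1 - coupling^2) * e
  std <- function(v) (v - mean(v)) / stats::sd(v)
  list(a = breath_series(std(z)), b = breath_series(std(b)))
}

#' Specification of one subject's breathing pattern
#'
#' Parameters for the breath-by-breath simulator: mean and coefficient of
#' variation of the inter-breath interval (IBI) and lung volume (LV)
#' series, the spectral exponents of their fluctuation drivers (which set
#' the long-range-correlation structure, hence the DFA exponent
#' \eqn{\alpha \approx (\beta+1)/2}), the correlation between the two
#' drivers (IBI-LV coupling), and the recording duration. Defaults are
#' the healthy-adult values: mean IBI 3.51 s with CV 0.13, mean tidal
#' volume 0.64 L with CV 0.27, 60-min recording, 1/f fluctuations.
#'
#' @param mean_ibi mean inter-breath interval, seconds (> 0).
#' @param cv_ibi coefficient of variation of the IBI series (>= 0).
#' @param mean_lv mean breath amplitude, liters (> 0).
#' @param cv_lv coefficient of variation of the LV series (>= 0).
#' @param beta_ibi,beta_lv spectral exponents of the fluctuation drivers.
#' @param coupling correlation between IBI and LV drivers, `[-1, 1]`.
#' @param duration recording duration, seconds.
#' @param seed integer seed.
#' @return A list of class `breath_spec`.
#' @export
breath_spec <- function(mean_ibi = 3.51, cv_ibi = 0.13,
                        mean_lv = 0.64, cv_lv = 0.27,
                        beta_ibi = 1, beta_lv = 1,
                        coupling = 0.2, duration = 3600, seed = NULL) {
  if (mean_ibi <= 0 || mean_lv <= 0) {
    stop("mean_ibi and mean_lv must be positive", call. = FALSE)
  }
  if (cv_ibi < 0 || cv_lv < 0) stop("cv values must be >= 0", call. = FALSE)
  if (abs(coupling) > 1) stop("|coupling| must be <= 1", call. = FALSE)
  structure(list(mean_ibi = mean_ibi, cv_ibi = cv_ibi,
                 mean_lv = mean_lv, cv_lv = cv_lv,
                 beta_ibi = beta_ibi, beta_lv = beta_lv,
                 coupling = coupling, duration = duration, seed = seed),
            class = "breath_spec")
}

# Draw per-breath interval and amplitude sequences from correlated
# colored-noise drivers. The CV is imposed through a lognormal link on
# the driver, which is clipped at +/- 4 SD so intervals stay positive
# even at the largest observed CV (0.51).
draw_breath_sequences <- function(spec, n_breaths) {
  n <- max(64L, as.integer(n_breaths))
  u_ibi <- as_values(colored_noise(n, spec$beta_ibi, seed = spec$seed))
  seed_lv <- if (is.null(spec$seed)) NULL else spec$seed + 10000L
  u_ind <- as_values(colored_noise(n, spec$beta_lv, seed = seed_lv))
  rho <- spec$coupling
  u_lv <- rho * u_ibi + sqrt(1 - rho^2) * u_ind
  if (stats::sd(u_lv) > 0) u_lv <- (u_lv - mean(u_lv)) / stats::sd(u_lv)
  link <- function(u, m, cv) {
    if (cv == 0) return(rep(m, length(u)))
    s <- sqrt(log1p(cv^2))
    u <- pmin(pmax(u, -4), 4)
    m * exp(s * u - s^2 / 2)
  }
  list(ibi = link(u_ibi, spec$mean_ibi, spec$cv_ibi)[seq_len(n_breaths)],
       lv = link(u_lv, spec$mean_lv, spec$cv_lv)[seq_len(n_breaths)])
}

# Per-subject breath-indexed series without waveform rendering.
simulate_breath_series <- function(spec) {
  n_breaths <- max(8L, ceiling(spec$duration / spec$mean_ibi))
  seqs <- draw_breath_sequences(spec, n_breaths)
  list(ibi = breath_series(seqs$ibi, unit = "seconds",
                           meta = list(spec = unclass(spec))),
       lv = breath_series(seqs$lv, unit = "liters",
                          meta = list(spec = unclass(spec))))
}

#' Simulate a two-band plethysmography recording
#'
#' Renders a breathing-movement waveform from a [breath_spec()]:
#' per-breath intervals and amplitudes are drawn from correlated
#' colored-noise drivers, each breath is rendered as a half-sine volume
#' lobe centred on its peak, and the lobe is split across rib-cage and
#' abdomen channels with fixed 60/40 mixing weights (so that
#' `0.6 * ribcage + 0.4 * abdomen` reconstructs the volume signal
#' exactly). The drawn peak times and amplitudes are returned as the
#' ground-truth breath table, so peak detection can be validated against
#' what the renderer actually consumed.
#'
#' @param spec a [breath_spec()].
#' @param fs sampling rate in Hz (>= 10; recordings are digitized at
#'   1 kHz, but lower rates are adequate for simulation).
#' @return A list with elements `waveform` (list: `fs`, `ribcage`,
#'   `abdomen`, `volume_ref`, `duration`) and `breaths` (data.frame:
#'   `peak_time_s`, `peak_volume_L`).
#' @export
breath_waveform <- function(spec, fs = 50) {
  stopifnot(inherits(spec, "breath_spec"))
  if (fs < 10) stop("fs must be >= 10 Hz", call. = FALSE)
  if (spec$duration < 3 * spec$mean_ibi) {
    stop("duration must cover at least 3 mean breaths", call. = FALSE)
  }
  n_breaths <- ceiling(spec$duration / spec$mean_ibi) + 8L
  seqs <- draw_breath_sequences(spec, n_breaths)
  peak_times <- cumsum(seqs$ibi)
  keep <- peak_times <= spec$duration - spec$mean_ibi / 2
  peak_times <- peak_times[keep]
  amps <- seqs$lv[keep]
  n_samp <- round(fs * spec$duration)
  t <- seq_len(n_samp) / fs
  volume <- numeric(n_samp)
  gaps <- diff(c(0, peak_times, spec$duration))
  for (k in seq_along(peak_times)) {
    half_width <- 0.45 * min(gaps[k], gaps[k + 1L])
    idx <- which(abs(t - peak_times[k]) <= half_width)
    volume[idx] <- volume[idx] +
      amps[k] * cos(pi * (t[idx] - peak_times[k]) / (2 * half_width))
  }
  # Band-specific wiggle that cancels in the 60/40 weighted sum, so the
  # two channels differ while 0.6*rib + 0.4*abd stays equal to volume.
  wiggle <- with_seed(if (is.null(spec$seed)) NULL else spec$seed + 20000L,
                      stats::rnorm(n_samp, sd = 0.02 * max(amps)))
  ribcage <- volume + 0.4 * wiggle
  abdomen <- volume - 0.6 * wiggle
  list(waveform = list(fs = fs, ribcage = ribcage, abdomen = abdomen,
                       volume_ref = volume, duration = spec$duration),
       breaths = data.frame(peak_time_s = peak_times,
                            peak_volume_L = amps))
}

#' Default four-group synthetic cohort specification
#'
#' Group-level simulator settings emulating a 4 x 10 design: healthy
#' controls plus controlled atopic (CAA), uncontrolled atopic (UAA) and
#' uncontrolled non-atopic (UNAA) asthma. Mean and CV of the IBI and LV
#' series are set to the published cohort descriptive statistics; the
#' spectral exponents and coupling values are synthetic defaults chosen
#' so that long-range correlation decreases, regularity increases and
#' IBI-LV synchronization strengthens from health to uncontrolled
#' disease -- the qualitative ordering the complexity indices are
#' expected to resolve. They are not estimates of any patient cohort.
#'
#' @param n_per_group subjects per group.
#' @param duration recording duration per subject, seconds.
#' @return A named list of group parameter lists, usable as the `groups`
#'   argument of [simulate_cohort()].
#' @export
cohort_groups_default <- function(n_per_group = 10L, duration = 3600) {
  mk <- function(...) c(list(...), list(duration = duration,
                                        n_subjects = n_per_group))
  list(
    Healthy = mk(mean_ibi = 3.51, cv_ibi = 0.13, mean_lv = 0.64,
                 cv_lv = 0.27, beta_ibi = 1.00, beta_lv = 1.00,
                 coupling = 0.30),
    CAA = mk(mean_ibi = 2.90, cv_ibi = 0.22, mean_lv = 0.66,
             cv_lv = 0.61, beta_ibi = 0.70, beta_lv = 0.75,
             coupling = 0.80),
    UAA = mk(mean_ibi = 3.47, cv_ibi = 0.26, mean_lv = 0.76,
             cv_lv = 0.63, beta_ibi = 0.45, beta_lv = 0.55,
             coupling = 0.97),
    UNAA = mk(mean_ibi = 4.03, cv_ibi = 0.51, mean_lv = 0.77,
              cv_lv = 0.66, beta_ibi = 0.25, beta_lv = 0.40,
              coupling = 0.99)
  )
}

#' Simulate a labelled cohort
#'
#' Two modes. `mode = "series"` simulates per-subject IBI/LV series from
#' each group's [breath_spec()] parameters and computes the seven
#' complexity indices per subject with [complexity_profile()].
#' `mode = "features"` skips the time-series stage and draws the feature
#' matrix directly from per-group Gaussian mean/SD tables (useful when
#' only the classifier/evaluation stages are under study).
#'
#' @param groups named list of group parameter lists. In `"series"` mode
#'   each entry holds `n_subjects` plus [breath_spec()] arguments (see
#'   [cohort_groups_default()]). In `"features"` mode each entry holds
#'   `n_subjects`, `mean` (named numeric vector of feature means) and
#'   `sd` (matching SDs).
#' @param seed integer seed; subject-level seeds are derived from it.
#' @param mode `"series"` or `"features"`.
#' @param config analysis configuration (see [default_config()]), used
#'   in `"series"` mode.
#' @return A list of class `cohort_dataset`: `features` (subjects x
#'   features matrix), `labels` (factor), `subject_ids`, `feature_names`.
#' @export
simulate_cohort <- function(groups = cohort_groups_default(),
                            seed = 1L,
                            mode = c("series", "features"),
                            config = default_config()) {
  mode <- match.arg(mode)
  if (length(groups) == 0L) stop("no groups supplied", call. = FALSE)
  if (is.null(names(groups)) || anyDuplicated(names(groups))) {
    stop("groups must be uniquely named", call. = FALSE)
  }
  rows <- list()
  labels <- character(0)
  ids <- character(0)
  subj <- 0L
  for (g in names(groups)) {
    par <- groups[[g]]
    n_sub <- par$n_subjects
    if (is.null(n_sub) || n_sub < 1L) {
      stop(sprintf("group '%s' must have n_subjects >= 1", g), call. = FALSE)
    }
    for (i in seq_len(n_sub)) {
      subj <- subj + 1L
      sseed <- as.integer(seed) + 1009L * subj
      if (mode == "series") {
        spec_args <- par[setdiff(names(par), "n_subjects")]
        spec_args$seed <- sseed
        spec <- do.call(breath_spec, spec_args)
        ser <- simulate_breath_series(spec)
        prof <- complexity_profile(ser$ibi, ser$lv, config = config)
        rows[[subj]] <- prof$indices
      } else {
        mu <- par$mean
        sdv <- par$sd
        if (is.null(mu) || is.null(sdv) || is.null(names(mu))) {
          stop("'features' mode needs named `mean` and `sd` vectors",
               call. = FALSE)
        }
        rows[[subj]] <- with_seed(sseed, {
          stats::setNames(stats::rnorm(length(mu), mu, sdv), names(mu))
        })
      }
      labels <- c(labels, g)
      ids <- c(ids, sprintf("S%03d", subj))
    }
  }
  features <- do.call(rbind, rows)
  rownames(features) <- ids
  structure(list(features = features,
                 labels = factor(labels, levels = names(groups)),
                 subject_ids = ids,
                 feature_names = colnames(features),
                 seed = seed, mode = mode),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d subjects x %d features\n",
              nrow(x$features), ncol(x$features)))
  print(table(x$labels))
  invisible(x)
}
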