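#' Largest Lyapunov exponent (Rosenstein algorithm)
#'
#' Estimates the rate at which nearby phase-space trajectories diverge,
#' following the mean-log-divergence procedure designed for small data
#' sets: the series is delay-embedded, each embedded point is paired
#' with its nearest neighbor outside a Theiler exclusion window, the
#' log distance between each pair is tracked over `i = 1, 2, ...` steps,
#' and the exponent is the least-squares slope of the averaged
#' log-divergence curve over `fit_range` (the divergence model is
#' `d(i) = d(0) exp(LLE * i)`, with one step per breath index).
#' Positive values indicate sensitive dependence on initial conditions;
#' values near zero indicate regular dynamics.
#'
#' @param series numeric vector or `breath_series`.
#' @param dim embedding dimension; `NULL` selects it by false nearest
#'   neighbors ([fnn_dimension()]).
#' @param tau embedding delay; `NULL` selects it by average mutual
#'   information ([ami_delay()]).
#' @param theiler exclusion window in samples; `NULL` uses the series'
#'   dominant period estimated from the periodogram peak.
#' @param fit_range steps of the divergence curve used for the slope
#'   fit (default 1:10).
#' @param max_steps steps tracked.
#' @return A list of class `lle_result`: `lle`, `divergence_curve`
#'   (mean log-separation per step), `fit_range`, `dim`, `tau`,
#'   `theiler`, `n_pairs`.
#' @examples
#' x <- logistic_series(2000, r = 4, x0 = 0.3, burn_in = 100)
#' largest_lyapunov(x)$lle  # near log(2)
#' @export
largest_lyapunov <- function(series, dim = NULL, tau = NULL,
                             theiler = NULL, fit_range = 1:10,
                             max_steps = max(fit_range) + 5L) {
  x <- as_values(series)
  if (is.null(tau)) {
    tau <- tryCatch(as.integer(ami_delay(x)), error = function(e) 1L)
  }
  if (is.null(dim)) {
    # keep >= 100 embedded vectors, so the candidate dimension is
    # capped for short breath series
    cap <- max(1L, 1L + (length(x) - 100L) %/% tau)
    dim <- tryCatch(
      as.integer(fnn_dimension(x, tau = tau, max_dim = min(6L, cap))),
      error = function(e) min(3L, cap))
  }
  if (is.null(theiler)) theiler <- dominant_period(x)
  emb <- delay_embed(x, dim, tau)
  n_vec <- nrow(emb)
  if (n_vec < 100L) {
    stop("series too short: fewer than 100 embedded vectors",
         call. = FALSE)
  }
  usable <- n_vec - max_steps  # pairs must be trackable for max_steps
  nn <- nearest_neighbors(emb[seq_len(usable), , drop = FALSE],
                          theiler = as.integer(theiler))
  i <- which(nn$index > 0 & is.finite(nn$distance) & nn$distance > 0)
  j <- nn$index[i]
  if (length(i) == 0L) stop("no valid neighbor pairs", call. = FALSE)
  curve <- vapply(seq_len(max_steps), function(k) {
    d <- sqrt(rowSums((emb[i + k, , drop = FALSE] -
                         emb[j + k, , drop = FALSE])^2))
    pos <- d > 0
    if (!any(pos)) return(NA_real_)
    mean(log(d[pos]))
  }, numeric(1))
  steps <- fit_range[fit_range <= max_steps]
  ok <- is.finite(curve[steps])
  fit <- stats::lm(curve[steps][ok] ~ steps[ok])
  structure(list(lle = unname(stats::coef(fit)[2L]),
                 divergence_curve = curve,
                 fit_range = steps,
                 dim = dim, tau = tau, theiler = theiler,
                 n_pairs = length(i)),
            class = "lle_result")
}

# Dominant period in samples from the periodogram peak; used as the
# default Theiler window so neighbors on the same oscillation cycle are
# not paired.
dominant_period <- function(x) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x))[2:(n %/% 2)])^2
  f <- (seq_along(sp)) / n
  per <- 1 / f[which.max(sp)]
  max(1L, min(as.integer(round(per)), n %/% 10L))
}

#' @export
print.lle_result <- function(x, ...) {
  cat(sprintf(
    "LLE = %.4f per step (dim = %d, tau = %d, theiler = %d, %d pairs)\n",
    x$lle, x$dim, x$tau, x$theiler, x$n_pairs))
  invisible(x)
}
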