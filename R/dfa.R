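#' Detrended fluctuation analysis
#'
#' Quantifies long-range correlations in a series. The mean-subtracted
#' series is integrated, partitioned into non-overlapping boxes of size
#' `n`, the local polynomial trend (default linear, i.e. DFA-1) is
#' subtracted in each box, and the root-mean-square fluctuation F(n) is
#' recorded per box size. The scaling exponent `alpha` is the slope of
#' the least-squares line of log F(n) against log n. Benchmarks:
#' `alpha = 0.5` for white (uncorrelated) noise, `alpha = 1` for 1/f
#' fractal dynamics, `alpha = 1.5` for Brownian noise (integrated random
#' walk).
#'
#' @param series numeric vector or `breath_series`; non-constant, and at
#'   least 64 points when `box_sizes` is automatic.
#' @param box_sizes integer vector of box sizes, or `NULL` for ~15
#'   log-spaced sizes from 4 to N/4.
#' @param order detrending polynomial order (default 1).
#' @return A list of class `dfa_result`: `alpha`, `box_sizes`,
#'   `fluctuations`, `r_squared`.
#' @examples
#' x <- colored_noise(2048, beta = 0, seed = 1)
#' dfa(x)$alpha  # about 0.5
#' @export
dfa <- function(series, box_sizes = NULL, order = 1L) {
  x <- as_values(series)
  n_len <- length(x)
  if (stats::sd(x) == 0) stop("constant series", call. = FALSE)
  if (is.null(box_sizes)) {
    if (n_len < 64) stop("need >= 64 points for automatic box sizes",
                         call. = FALSE)
    box_sizes <- dfa_boxes(n_len)
  }
  box_sizes <- sort(unique(as.integer(box_sizes)))
  box_sizes <- box_sizes[box_sizes >= order + 2 & box_sizes <= n_len %/% 2]
  if (length(box_sizes) < 4) stop("fewer than 4 usable box sizes",
                                  call. = FALSE)
  y <- cumsum(x - mean(x))
  fl <- vapply(box_sizes, function(bn) dfa_fluct(y, bn, order), numeric(1))
  fit <- stats::lm(log(fl) ~ log(box_sizes))
  list(alpha = unname(stats::coef(fit)[2L]),
       box_sizes = box_sizes,
       fluctuations = fl,
       r_squared = summary(fit)$r.squared) |>
    structure(class = "dfa_result")
}

# ~15 log-spaced integer box sizes from 4 to N/4, duplicates dropped.
dfa_boxes <- function(n_len, n_sizes = 15L) {
  unique(round(exp(seq(log(4), log(n_len %/% 4), length.out = n_sizes))))
}

# RMS fluctuation at one box size: partition the profile into
# floor(N/bn) non-overlapping boxes and detrend each with a polynomial
# fit of the given order (vectorized across boxes via a shared design
# matrix projection).
dfa_fluct <- function(y, bn, order) {
  nbox <- length(y) %/% bn
  ymat <- matrix(y[seq_len(nbox * bn)], nrow = bn)
  X <- stats::poly(seq_len(bn), degree = order, raw = TRUE)
  X <- cbind(1, X)
  hat <- X %*% solve(crossprod(X), t(X))
  resid <- ymat - hat %*% ymat
  sqrt(mean(resid^2))
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf("DFA: alpha = %.3f (R^2 = %.4f, %d box sizes %d..%d)\n",
              x$alpha, x$r_squared, length(x$box_sizes),
              min(x$box_sizes), max(x$box_sizes)))
  invisible(x)
}
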