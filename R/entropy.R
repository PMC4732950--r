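#' Sample entropy
#'
#' The negative natural logarithm of the conditional probability that
#' two sequences similar for `m` points remain similar at the next
#' point, within tolerance `r`, self-matches excluded. Template
#' similarity uses the Chebyshev (maximum-coordinate) distance and the
#' tolerance is `r` times the sample SD of the series, so the statistic
#' is invariant under affine rescaling of the input. Lower values
#' indicate a more regular series. Defaults `m = 2`, `r = 0.2`.
#'
#' @param series numeric vector or `breath_series`; non-constant, length
#'   >= m + 2.
#' @param m template length (>= 1).
#' @param r tolerance as a fraction of the series SD (> 0).
#' @return Sample entropy in nats. When no (m+1)-template pair matches,
#'   returns `Inf` with attribute `no_matches = TRUE` rather than
#'   erroring, so batch runs over short regular series survive.
#' @examples
#' sample_entropy(periodic_series(300, period = 10))
#' @export
sample_entropy <- function(series, m = 2L, r = 0.2) {
  x <- as_values(series)
  n <- length(x)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  if (r <= 0) stop("r must be positive", call. = FALSE)
  if (n < m + 2) stop("series too short for the given m", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) stop("constant series has undefined sample entropy",
                   call. = FALSE)
  cnt <- sampen_counts(x, as.integer(m), r * s)
  entropy_from_counts(cnt[["A"]], cnt[["B"]])
}

#' Cross-sample entropy of two series
#'
#' Measures the asynchrony of two interacting series: templates of
#' length `m` drawn from `a` are matched against `b` (there is no
#' self-match concept across distinct series), and the statistic is
#' `-ln(A/B)` with A and B the (m+1)- and m-match counts. Lower values
#' indicate stronger synchronization. The tolerance is `r` times the
#' pooled SD of the two series, which equals `r` itself when both
#' inputs are z-normalized. The statistic is direction-dependent;
#' `symmetrize = TRUE` averages the two directions and the direction
#' used is recorded in the result's attributes.
#'
#' @param a,b numeric vectors or `breath_series` of equal length, both
#'   non-constant.
#' @param m template length.
#' @param r tolerance as a fraction of the pooled SD.
#' @param symmetrize average the a-to-b and b-to-a statistics.
#' @return Cross-sample entropy in nats (`Inf` with `no_matches`
#'   attribute when A = 0).
#' @export
cross_sample_entropy <- function(a, b, m = 2L, r = 0.2,
                                 symmetrize = FALSE) {
  x <- as_values(a)
  y <- as_values(b)
  if (length(x) != length(y)) {
    stop("series must have equal length (align first)", call. = FALSE)
  }
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  if (r <= 0) stop("r must be positive", call. = FALSE)
  if (length(x) < m + 2) stop("series too short", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input series", call. = FALSE)
  }
  tol <- r * sqrt((stats::var(x) + stats::var(y)) / 2)
  cnt <- cross_sampen_counts(x, y, as.integer(m), tol)
  v <- entropy_from_counts(cnt[["A"]], cnt[["B"]])
  if (symmetrize) {
    cnt2 <- cross_sampen_counts(y, x, as.integer(m), tol)
    v2 <- entropy_from_counts(cnt2[["A"]], cnt2[["B"]])
    v <- structure((v + v2) / 2, direction = "symmetric")
  } else {
    attr(v, "direction") <- "a_to_b"
  }
  v
}

entropy_from_counts <- function(A, B) {
  if (B == 0) {
    return(structure(Inf, no_matches = TRUE, A = A, B = B))
  }
  if (A == 0) {
    return(structure(Inf, no_matches = TRUE, A = A, B = B))
  }
  structure(-log(A / B), A = A, B = B)
}
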