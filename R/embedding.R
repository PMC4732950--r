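# Delay embedding: rows are vectors (x_i, x_{i+tau}, ..., x_{i+(d-1)tau}).
delay_embed <- function(x, dim, tau) {
  n <- length(x) - (dim - 1L) * tau
  if (n < 2L) stop("series too short for this embedding", call. = FALSE)
  idx <- outer(seq_len(n), (seq_len(dim) - 1L) * tau, `+`)
  matrix(x[idx], nrow = n)
}

#' Embedding delay by average mutual information
#'
#' Computes the histogram-based mutual information between the series
#' and its lagged copy for lags 1..`max_lag` and selects the delay as
#' the first local minimum of the mutual-information curve. When the
#' curve has no local minimum in range, the fallback is the first lag at
#' which the information drops below I(1)/e; failing that, lag 1.
#'
#' Computes the histogram-based mutual information between the series
#' and its lagged copy for lags 1..`max_lag` and selects the delay as
#' the curve's first qualifying interior local minimum (one followed by
#' a genuine rise, not a wiggle in the estimator's noise floor); when
#' no such minimum exists, the first lag at which the information
#' decays below 1/e of its lag-0 (self) value; failing both, lag 1.
#' A guard runs first: a series that is already linearly decorrelated
#' at lag 1 (|lag-1 autocorrelation| < 1/e -- iid noise, but also
#' white-spectrum chaotic maps) gets `tau = 1` directly, because every
#' feature of its AMI curve beyond lag 1 is either estimator noise or
#' the signature of the iterated map, and larger delays only degrade
#' the embedding.
#'
#' @param series numeric vector or `breath_series`, length >= 10 *
#'   `max_lag`.
#' @param max_lag largest lag scanned (>= 2).
#' @param bins number of equal-width histogram bins per axis.
#' @return Integer delay, with attributes `ami` (the I(lag) curve,
#'   lag-0 value first), and `method` (`"decorrelated"`, `"local_min"`,
#'   `"e_decay"` or `"fallback_lag1"`).
#' @export
ami_delay <- function(series, max_lag = 20L, bins = 16L) {
  x <- as_values(series)
  if (max_lag < 2) stop("max_lag must be >= 2", call. = FALSE)
  if (length(x) < 10 * max_lag) {
    stop("series too short for the requested max_lag", call. = FALSE)
  }
  i0 <- mutual_information(x, x, bins)
  ami <- vapply(seq_len(max_lag), function(lag) {
    mutual_information(x[seq_len(length(x) - lag)],
                       x[(lag + 1L):length(x)], bins)
  }, numeric(1))
  n <- length(x)
  acf1 <- abs(stats::cor(x[-n], x[-1L]))
  if (acf1 < exp(-1)) {
    return(structure(1L, ami = c(i0, ami), method = "decorrelated"))
  }
  cand_min <- NA_integer_
  for (lag in 2:(max_lag - 1L)) {
    if (ami[lag] < ami[lag - 1L] && ami[lag] <= ami[lag + 1L] &&
        max(ami[(lag + 1L):max_lag]) > ami[lag] +
          0.1 * (ami[1L] - ami[lag])) {
      cand_min <- lag
      break
    }
  }
  if (!is.na(cand_min)) {
    return(structure(as.integer(cand_min), ami = c(i0, ami),
                     method = "local_min"))
  }
  cand_decay <- which(ami < i0 / exp(1))[1L]
  if (!is.na(cand_decay)) {
    return(structure(as.integer(cand_decay), ami = c(i0, ami),
                     method = "e_decay"))
  }
  structure(1L, ami = c(i0, ami), method = "fallback_lag1")
}

mutual_information <- function(u, v, bins) {
  cu <- cut(u, breaks = bins, labels = FALSE)
  cv <- cut(v, breaks = bins, labels = FALSE)
  joint <- table(cu, cv) / length(u)
  pu <- rowSums(joint)
  pv <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(pu, pv)[nz]))
}

#' Embedding dimension by false nearest neighbors
#'
#' For each candidate dimension d the series is delay-embedded, each
#' point's nearest neighbor is found, and the neighbor is declared false
#' when adding the (d+1)-th coordinate inflates the pair distance by
#' more than `rtol`, or pushes it beyond `atol` times the series SD
#' (the attractor-size criterion). The selected dimension is the
#' smallest d whose false-neighbor fraction falls below `threshold`;
#' when no dimension qualifies (as for stochastic signals, whose
#' false-neighbor fraction stays high at any dimension) the cap
#' `max_dim` is returned with attribute `saturated = TRUE`.
#'
#' @param series numeric vector or `breath_series`.
#' @param tau embedding delay in samples.
#' @param max_dim largest dimension tried (default 10).
#' @param rtol relative distance-growth criterion (default 15).
#' @param atol attractor-size criterion in SD multiples (default 2).
#' @param threshold admissible false-neighbor fraction (default 0.01).
#' @return Integer dimension with attributes `fnn_fraction` (per
#'   dimension) and `saturated`.
#' @export
fnn_dimension <- function(series, tau = 1L, max_dim = 10L,
                          rtol = 15, atol = 2, threshold = 0.01) {
  x <- as_values(series)
  s <- stats::sd(x)
  fractions <- rep(NA_real_, max_dim)
  for (d in seq_len(max_dim)) {
    n_vec <- length(x) - d * tau  # need the (d+1)-th coordinate too
    if (n_vec < 20L) break
    emb <- delay_embed(x[seq_len(length(x) - tau)], d, tau)[seq_len(n_vec), ,
                                                            drop = FALSE]
    nn <- nearest_neighbors(emb, theiler = 0L)
    i <- seq_len(n_vec)
    j <- nn$index
    ok <- j > 0 & is.finite(nn$distance)
    extra <- abs(x[i + d * tau] - x[j + d * tau])
    rd <- nn$distance
    # distance floor: neighbors coincident to machine precision (exact
    # recurrences of a periodic orbit) must not trip the ratio test
    rd_floor <- 1e-8 * s
    false_rel <- ok & rd > rd_floor & (extra / rd) > rtol
    new_d <- sqrt(rd^2 + extra^2)
    false_abs <- ok & new_d > atol * s
    fractions[d] <- mean((false_rel | false_abs)[ok])
    if (fractions[d] < threshold) {
      return(structure(as.integer(d), fnn_fraction = fractions[seq_len(d)],
                       saturated = FALSE))
    }
  }
  structure(as.integer(max_dim), fnn_fraction = fractions, saturated = TRUE)
}
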