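# Independent brute-force oracles. These deliberately share no code
# with the package: plain loops and direct definitions only.

# Sample-entropy pair counting: templates i = 1..N-m (so each template
# has a continuation), unordered pairs i < j, Chebyshev distance.
oracle_sampen <- function(x, m, r) {
  n <- length(x)
  tol <- r * sd(x)
  nt <- n - m
  A <- 0L
  B <- 0L
  for (i in seq_len(nt - 1L)) {
    for (j in (i + 1L):nt) {
      if (max(abs(x[i:(i + m - 1L)] - x[j:(j + m - 1L)])) <= tol) {
        B <- B + 1L
        if (abs(x[i + m] - x[j + m]) <= tol) A <- A + 1L
      }
    }
  }
  list(A = A, B = B,
       value = if (A == 0 || B == 0) Inf else -log(A / B))
}

# Cross-sample entropy: ordered template pairs from x matched in y,
# tolerance r times the pooled SD.
oracle_cross_sampen <- function(x, y, m, r) {
  n <- length(x)
  tol <- r * sqrt((var(x) + var(y)) / 2)
  nt <- n - m
  A <- 0L
  B <- 0L
  for (i in seq_len(nt)) {
    for (j in seq_len(nt)) {
      if (max(abs(x[i:(i + m - 1L)] - y[j:(j + m - 1L)])) <= tol) {
        B <- B + 1L
        if (abs(x[i + m] - y[j + m]) <= tol) A <- A + 1L
      }
    }
  }
  list(A = A, B = B,
       value = if (A == 0 || B == 0) Inf else -log(A / B))
}

# DFA fluctuation function by explicit per-box arithmetic.
oracle_dfa_fluct <- function(x, box_sizes, order = 1L) {
  y <- cumsum(x - mean(x))
  vapply(box_sizes, function(bn) {
    nbox <- length(y) %/% bn
    sq <- 0
    for (b in seq_len(nbox)) {
      seg <- y[((b - 1L) * bn + 1L):(b * bn)]
      t <- seq_len(bn)
      fit <- lm(seg ~ poly(t, degree = order, raw = TRUE))
      sq <- sq + sum(resid(fit)^2)
    }
    sqrt(sq / (nbox * bn))
  }, numeric(1))
}

# AUC by exhaustive concordant/discordant/tied pair counting.
oracle_auc <- function(scores, is_case) {
  pos <- scores[is_case]
  neg <- scores[!is_case]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
  }
  tot / (length(pos) * length(neg))
}

# Analytic Lyapunov exponent of the logistic map: orbit average of
# log|r (1 - 2 x_t)|.
oracle_logistic_lyap <- function(r, x0, n = 5000L, burn_in = 100L) {
  x <- x0
  for (k in seq_len(burn_in)) x <- r * x * (1 - x)
  acc <- 0
  for (k in seq_len(n)) {
    acc <- acc + log(abs(r * (1 - 2 * x)))
    x <- r * x * (1 - x)
  }
  acc / n
}

# Histogram mutual information, written directly from the definition.
oracle_mi <- function(u, v, bins) {
  cu <- cut(u, bins, labels = FALSE)
  cv <- cut(v, bins, labels = FALSE)
  p <- table(cu, cv) / length(u)
  pu <- rowSums(p)
  pv <- colSums(p)
  tot <- 0
  for (a in seq_len(nrow(p))) {
    for (b in seq_len(ncol(p))) {
      if (p[a, b] > 0) tot <- tot + p[a, b] * log(p[a, b] / (pu[a] * pv[b]))
    }
  }
  unname(tot)
}

# Nearest-centroid classifier used as an agreement oracle for the
# sparse-representation classifier on well-separated data.
oracle_nearest_centroid <- function(train, labels, test_row) {
  cents <- vapply(split(seq_len(nrow(train)), labels), function(ix) {
    colMeans(train[ix, , drop = FALSE])
  }, numeric(ncol(train)))
  names(which.min(colSums((cents - test_row)^2)))
}

with_fixed_seed <- function(seed, expr) {
  set.seed(seed)
  expr
}
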