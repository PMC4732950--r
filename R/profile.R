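#' Per-subject complexity profile
#'
#' Computes the seven nonlinear indices used to characterize one
#' subject's breathing pattern: the DFA scaling exponent, sample
#' entropy, and largest Lyapunov exponent of the inter-breath interval
#' (IBI) and lung volume (LV) series, plus the cross-sample entropy
#' between them. Both series are z-normalized first; cross-sample
#' entropy templates are drawn from the IBI series and matched in the
#' LV series, whose first element is dropped so the (n-1)-long IBI
#' series aligns with the volume of the breath it leads into.
#' Summary statistics (mean, CV) of the raw series are recorded
#' alongside.
#'
#' @param ibi inter-breath interval series, seconds.
#' @param lv lung volume (peak amplitude) series, liters; length may
#'   exceed `ibi` by one (the usual n vs n-1 peak bookkeeping).
#' @param config analysis parameters, see [default_config()].
#' @return A list of class `complexity_profile`: `indices` (named
#'   numeric vector `DFA_IBI`, `DFA_LV`, `SampEn_IBI`, `SampEn_LV`,
#'   `LLE_IBI`, `LLE_LV`, `CrossSampEn_IBI_LV`), `summary` (mean/CV of
#'   each raw series) and `parameters` (embedding choices per series).
#' @export
complexity_profile <- function(ibi, lv, config = default_config()) {
  ibi_v <- as_values(ibi)
  lv_v <- as_values(lv)
  if (length(lv_v) == length(ibi_v) + 1L) lv_v <- lv_v[-1L]
  if (length(lv_v) != length(ibi_v)) {
    lag <- length(lv_v) - length(ibi_v)
    stop(sprintf("IBI and LV lengths differ by %d; expected 0 or 1", lag),
         call. = FALSE)
  }
  m <- config$entropy$m
  r <- config$entropy$r
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", label, conditionMessage(e)), call. = FALSE)
    })
  }
  zi <- as_values(stage("normalize_ibi", znormalize(ibi_v)))
  zl <- as_values(stage("normalize_lv", znormalize(lv_v)))
  dfa_i <- stage("dfa_ibi", dfa(zi, order = config$dfa$order))
  dfa_l <- stage("dfa_lv", dfa(zl, order = config$dfa$order))
  lle_i <- stage("lle_ibi", largest_lyapunov(
    zi, fit_range = config$lle$fit_range))
  lle_l <- stage("lle_lv", largest_lyapunov(
    zl, fit_range = config$lle$fit_range))
  idx <- c(
    DFA_IBI = dfa_i$alpha,
    DFA_LV = dfa_l$alpha,
    SampEn_IBI = as.numeric(stage("sampen_ibi", sample_entropy(zi, m, r))),
    SampEn_LV = as.numeric(stage("sampen_lv", sample_entropy(zl, m, r))),
    LLE_IBI = lle_i$lle,
    LLE_LV = lle_l$lle,
    CrossSampEn_IBI_LV = as.numeric(stage(
      "cross_sampen", cross_sample_entropy(zi, zl, m, r)))
  )
  structure(list(
    indices = idx,
    summary = list(ibi = summary_stats(ibi_v), lv = summary_stats(lv_v)),
    parameters = list(
      entropy = list(m = m, r = r),
      ibi_embedding = list(dim = lle_i$dim, tau = lle_i$tau),
      lv_embedding = list(dim = lle_l$dim, tau = lle_l$tau))),
    class = "complexity_profile")
}

#' @export
print.complexity_profile <- function(x, ...) {
  cat("Complexity profile:\n")
  print(round(x$indices, 4))
  invisible(x)
}
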