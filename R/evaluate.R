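#' ROC analysis of a single index
#'
#' Builds the ROC curve for one complexity index against a binary label,
#' sweeping all observed thresholds. The area under the curve is the
#' trapezoidal area (equivalently the Mann-Whitney concordance
#' probability with ties counted half), its standard error follows
#' Hanley and McNeil, the 95% CI is the normal interval clipped to
#' [0, 1], and the p-value tests AUC = 0.5 on the same SE. The curve
#' orientation is chosen automatically so AUC >= 0.5 and is recorded.
#' The reported cut-off maximizes the Youden index (Se + Sp - 1), ties
#' resolved toward higher specificity; sensitivity and specificity at
#' the cut-off carry exact binomial (Clopper-Pearson) CIs.
#'
#' @param scores numeric vector of index values, one per subject.
#' @param labels binary factor/vector; `positive` names the case class.
#' @param positive positive (case) class; default = first factor level.
#' @param conf confidence level (default 0.95).
#' @return A list of class `roc_result`: `auc`, `se_auc`, `ci95`,
#'   `p_value`, `direction`, `best_cutoff`, `se_at_cutoff`,
#'   `sp_at_cutoff` (each with CI), `curve` (data.frame threshold /
#'   tpr / fpr), `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(scores, labels, positive = NULL, conf = 0.95) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2) {
    stop("labels must contain exactly 2 classes", call. = FALSE)
  }
  labels <- droplevels(labels)
  pos <- positive %||% levels(labels)[1L]
  neg <- setdiff(levels(labels), pos)
  resp <- factor(ifelse(labels == pos, "case", "control"),
                 levels = c("control", "case"))
  roc <- pROC::roc(response = resp, predictor = as.numeric(scores),
                   levels = c("control", "case"), direction = "<",
                   quiet = TRUE)
  if (as.numeric(pROC::auc(roc)) < 0.5) {
    # flip orientation so the reported area is always >= 0.5
    roc <- pROC::roc(response = resp, predictor = as.numeric(scores),
                     levels = c("control", "case"), direction = ">",
                     quiet = TRUE)
  }
  auc <- as.numeric(pROC::auc(roc))
  n1 <- sum(resp == "case")
  n0 <- sum(resp == "control")
  se <- hanley_mcneil_se(auc, n1, n0)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- c(max(0, auc - z * se), min(1, auc + z * se))
  p <- if (se == 0) {
    if (auc == 0.5) 1 else 0
  } else {
    2 * stats::pnorm(-abs(auc - 0.5) / se)
  }
  co <- pROC::coords(roc, x = "all", ret = c("threshold", "sensitivity",
                                             "specificity"),
                     transpose = FALSE)
  youden <- co$sensitivity + co$specificity - 1
  best <- which(youden >= max(youden) - 1e-12)
  if (length(best) > 1L) best <- best[which.max(co$specificity[best])]
  se_ci <- clopper_pearson(round(co$sensitivity[best] * n1), n1, conf)
  sp_ci <- clopper_pearson(round(co$specificity[best] * n0), n0, conf)
  structure(list(
    auc = auc, se_auc = se, ci95 = ci, p_value = p,
    direction = roc$direction,
    best_cutoff = co$threshold[best],
    se_at_cutoff = list(estimate = 100 * co$sensitivity[best], ci = se_ci),
    sp_at_cutoff = list(estimate = 100 * co$specificity[best], ci = sp_ci),
    curve = data.frame(threshold = co$threshold,
                       tpr = co$sensitivity,
                       fpr = 1 - co$specificity),
    n_pos = n1, n_neg = n0),
    class = "roc_result")
}

hanley_mcneil_se <- function(auc, n1, n0) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
          (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.2f (%.0f%% CI %.2f-%.2f), SE = %.2f, p = %.4g\n",
              x$auc, 95, x$ci95[1], x$ci95[2], x$se_auc, x$p_value))
  cat(sprintf("cut-off %.3g: Se %.1f%% (%.0f-%.0f), Sp %.1f%% (%.0f-%.0f)\n",
              x$best_cutoff,
              x$se_at_cutoff$estimate, x$se_at_cutoff$ci[1],
              x$se_at_cutoff$ci[2],
              x$sp_at_cutoff$estimate, x$sp_at_cutoff$ci[1],
              x$sp_at_cutoff$ci[2]))
  invisible(x)
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' Exact interval for a binomial proportion, in percent. Chosen because
#' reported intervals for 100% sensitivity/specificity in small
#' diagnostic samples (e.g. 88-100 at k = n = 30, 69-100 at k = n = 10)
#' are exact-binomial bounds.
#'
#' @param k number of successes (0..n).
#' @param n number of trials (>= 1).
#' @param conf confidence level.
#' @return Length-2 numeric, interval endpoints in percent.
#' @examples
#' clopper_pearson(30, 30)  # c(88.4, 100)
#' @export
clopper_pearson <- function(k, n, conf = 0.95) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (k < 0 || k > n) stop("k must lie in 0..n", call. = FALSE)
  ci <- stats::binom.test(k, n, conf.level = conf)$conf.int
  100 * as.numeric(ci)
}

#' Diagnostic metrics from a 2x2 confusion table
#'
#' Sensitivity, specificity, predictive values and likelihood ratios
#' with confidence intervals: exact binomial intervals for the
#' proportions, log-method intervals for the likelihood ratios.
#' Division by zero follows the usual diagnostic-table conventions:
#' LR+ is `Inf` when specificity is 100%, LR- is 0 when sensitivity is
#' 100% (with an undefined `NaN` upper CI bound when its SE is
#' undefined).
#'
#' @param tp,fp,fn,tn nonnegative confusion-table counts.
#' @param conf confidence level.
#' @return A list of class `diag_metrics` with elements `se`, `sp`,
#'   `ppv`, `npv` (percent, each with `ci`), `lr_pos`, `lr_neg` (each
#'   with `ci`), and the input `counts`.
#' @export
diagnostic_metrics <- function(tp, fp, fn, tn, conf = 0.95) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (sum(counts) == 0) stop("all-zero confusion table", call. = FALSE)
  prop <- function(k, n) {
    if (n == 0) return(list(estimate = NaN, ci = c(NaN, NaN)))
    list(estimate = 100 * k / n, ci = clopper_pearson(k, n, conf))
  }
  se <- prop(tp, tp + fn)
  sp <- prop(tn, tn + fp)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  lr_ci <- function(lr, a, n1, b, n0) {
    # log-method CI for a ratio of two proportions a/n1 over b/n0
    if (!is.finite(lr) || lr == 0 || a == 0 || b == 0) return(c(NaN, NaN))
    s <- sqrt(1 / a - 1 / n1 + 1 / b - 1 / n0)
    exp(log(lr) + c(-z, z) * s)
  }
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  lr_pos <- if (spec == 1) Inf else sens / (1 - spec)
  lr_neg <- if (spec == 0) NaN else (1 - sens) / spec
  lrp_ci <- lr_ci(lr_pos, tp, tp + fn, fp, fp + tn)
  lrn_ci <- if (is.finite(lr_neg) && lr_neg == 0) {
    c(0, NaN)  # 100% sensitivity: point LR- of 0, undefined upper bound
  } else {
    lr_ci(lr_neg, fn, tp + fn, tn, fp + tn)
  }
  structure(list(se = se, sp = sp,
                 ppv = prop(tp, tp + fp), npv = prop(tn, tn + fn),
                 lr_pos = list(estimate = lr_pos, ci = lrp_ci),
                 lr_neg = list(estimate = lr_neg, ci = lrn_ci),
                 counts = counts),
            class = "diag_metrics")
}

#' @export
print.diag_metrics <- function(x, ...) {
  fmt <- function(nm, v) {
    cat(sprintf("%-4s %.1f%% (%.0f-%.0f)\n", nm, v$estimate,
                v$ci[1], v$ci[2]))
  }
  fmt("Se", x$se); fmt("Sp", x$sp); fmt("PPV", x$ppv); fmt("NPV", x$npv)
  cat(sprintf("LR+  %s\nLR-  %s\n",
              format(x$lr_pos$estimate, digits = 3),
              format(x$lr_neg$estimate, digits = 3)))
  invisible(x)
}

#' Compare a complexity index across groups
#'
#' One-way comparison with automatic method choice: when every group
#' passes a Shapiro-Wilk normality check (and has enough observations
#' to run one), a one-way ANOVA with Bonferroni-adjusted pairwise
#' t-tests (pooled SD) is used; otherwise a Kruskal-Wallis test with
#' Dunn's rank-based post-test (Bonferroni-adjusted z-statistics on
#' mean ranks, with tie correction).
#'
#' @param values numeric vector, one value per subject.
#' @param groups factor of group labels (>= 2 groups, >= 2 values each).
#' @param method `"auto"`, `"anova_bonferroni"` or `"kruskal_dunn"`.
#' @param alpha significance level for pairwise flags.
#' @return A list of class `group_comparison`: `method`, `statistic`,
#'   `p_value`, `pairwise` (data.frame: group1, group2, p_adjusted,
#'   significant).
#' @export
group_compare <- function(values, groups,
                          method = c("auto", "anova_bonferroni",
                                     "kruskal_dunn"),
                          alpha = 0.05) {
  method <- match.arg(method)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) {
    stop("every group needs >= 2 values", call. = FALSE)
  }
  lv0 <- levels(groups)
  if (stats::sd(values) == 0) {
    # all observations identical: no evidence of any difference
    pairs0 <- utils::combn(lv0, 2)
    return(structure(list(method = if (method == "auto") "kruskal_dunn"
                          else method,
                          statistic = 0, p_value = 1,
                          pairwise = data.frame(group1 = pairs0[1, ],
                                                group2 = pairs0[2, ],
                                                p_adjusted = 1,
                                                significant = FALSE)),
                     class = "group_comparison"))
  }
  if (method == "auto") {
    normal <- vapply(split(values, groups), function(v) {
      if (length(v) < 3 || stats::sd(v) == 0) return(FALSE)
      stats::shapiro.test(v)$p.value > 0.05
    }, logical(1))
    method <- if (all(normal)) "anova_bonferroni" else "kruskal_dunn"
  }
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  if (method == "anova_bonferroni") {
    fit <- stats::aov(values ~ groups)
    an <- summary(fit)[[1L]]
    statistic <- an[["F value"]][1L]
    p_global <- an[["Pr(>F)"]][1L]
    pt <- stats::pairwise.t.test(values, groups,
                                 p.adjust.method = "bonferroni",
                                 pool.sd = TRUE)
    # pairwise.t.test stores p[level_j, level_i] for i < j
    p_adj <- apply(pairs, 2L, function(pr) pt$p.value[pr[2], pr[1]])
  } else {
    kw <- stats::kruskal.test(values ~ groups)
    statistic <- unname(kw$statistic)
    p_global <- kw$p.value
    p_adj <- dunn_posthoc(values, groups)[
      paste(pairs[1, ], pairs[2, ], sep = "|")]
  }
  structure(list(method = method,
                 statistic = statistic,
                 p_value = p_global,
                 pairwise = data.frame(group1 = pairs[1, ],
                                       group2 = pairs[2, ],
                                       p_adjusted = unname(p_adj),
                                       significant = unname(p_adj) < alpha)),
            class = "group_comparison")
}

# Dunn's post-test: z-statistics on mean ranks with tie correction,
# Bonferroni-adjusted over all pairs.
dunn_posthoc <- function(values, groups) {
  n <- length(values)
  rk <- rank(values)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_rank <- tapply(rk, groups, mean)
  counts <- table(groups)
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  n_pairs <- ncol(pairs)
  p <- apply(pairs, 2L, function(pr) {
    se <- sqrt((n * (n + 1) / 12 - tie_corr) *
                 (1 / counts[[pr[1]]] + 1 / counts[[pr[2]]]))
    z <- (mean_rank[[pr[1]]] - mean_rank[[pr[2]]]) / se
    min(1, 2 * stats::pnorm(-abs(z)) * n_pairs)
  })
  stats::setNames(p, paste(pairs[1, ], pairs[2, ], sep = "|"))
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.3f, p = %.4g\n", x$method, x$statistic,
              x$p_value))
  print(x$pairwise)
  invisible(x)
}
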