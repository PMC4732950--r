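#' Minkowski distance weights for sparse representation
#'
#' Weight vector used by the weighted sparse representation classifier:
#' the Minkowski distance of order `p` between the test vector and each
#' training column, rescaled to `[eps, 1]` by division by the maximum.
#' Nearer training samples get smaller weights, hence a smaller sparsity
#' penalty, so the representation prefers geometrically close samples.
#'
#' @param y test feature vector (length = rows of `A`).
#' @param A training matrix, features x samples.
#' @param p Minkowski order (>= 1; default 2).
#' @param eps floor for the rescaled weights.
#' @return Numeric weight vector, one entry per training sample.
#' @export
minkowski_weights <- function(y, A, p = 2, eps = 1e-6) {
  if (p < 1) stop("p must be >= 1", call. = FALSE)
  if (length(y) != nrow(A)) {
    stop("dimension mismatch between y and A", call. = FALSE)
  }
  d <- apply(abs(A - y), 2L, function(v) sum(v^p))^(1 / p)
  mx <- max(d)
  if (mx == 0) return(rep(eps, ncol(A)))
  pmax(d / mx, eps)
}

#' Weighted sparse representation fit and class prediction
#'
#' Represents a test sample as a sparse linear combination of training
#' samples, with per-sample weights penalizing geometrically distant
#' samples, and assigns the class whose coefficients reconstruct the
#' sample with the smallest residual. The weighted L0 objective is
#' solved by greedy matching pursuit: at each step the column
#' maximizing |correlation with the residual| / weight joins the
#' support, the coefficients are refit by least squares on the support,
#' and selection stops at `budget` atoms or when the residual is
#' negligible. Class residuals are `||y - A delta_c(x)||_2` using only
#' class-c coefficients; ties go to the class with larger total
#' absolute coefficient mass, then to the earlier class label.
#'
#' @param A training matrix, features x samples (columns standardized
#'   with training statistics by the caller; [loocv_wsrc()] does this).
#' @param labels factor or vector of class labels, one per column.
#' @param y test feature vector.
#' @param budget maximum support size; default `min(10, ceiling(n/4))`.
#' @param p Minkowski order for the weights.
#' @param weights optional precomputed weight vector (equal weights
#'   reduce the method to unweighted sparse representation).
#' @return A list of class `sparse_fit`: `coefficients`, `weights`,
#'   `support`, `residuals` (named per class), `predicted`.
#' @export
wsrc_fit_predict <- function(A, labels, y, budget = NULL, p = 2,
                             weights = NULL) {
  A <- as.matrix(A)
  n <- ncol(A)
  labels <- as.factor(labels)
  if (length(labels) != n) stop("one label per training column",
                                call. = FALSE)
  if (all(y == 0)) stop("all-zero test vector", call. = FALSE)
  if (is.null(budget)) budget <- min(10L, ceiling(n / 4))
  if (budget < 1 || budget > n) {
    stop("budget must be between 1 and the number of training samples",
         call. = FALSE)
  }
  if (is.null(weights)) weights <- minkowski_weights(y, A, p = p)
  col_norm <- sqrt(colSums(A^2))
  col_norm[col_norm == 0] <- 1
  An <- sweep(A, 2L, col_norm, "/")
  support <- integer(0)
  coef_sup <- numeric(0)
  resid <- y
  y_norm <- sqrt(sum(y^2))
  for (step in seq_len(budget)) {
    score <- abs(drop(crossprod(An, resid))) / weights
    score[support] <- -Inf
    k <- which.max(score)
    support <- c(support, k)
    sub <- A[, support, drop = FALSE]
    coef_sup <- drop(qr.coef(qr(sub), y))
    coef_sup[is.na(coef_sup)] <- 0
    resid <- y - drop(sub %*% coef_sup)
    if (sqrt(sum(resid^2)) < 1e-8 * max(y_norm, 1)) break
  }
  x_full <- numeric(n)
  x_full[support] <- coef_sup
  classes <- levels(labels)
  residuals <- vapply(classes, function(cl) {
    xc <- x_full
    xc[labels != cl] <- 0
    sqrt(sum((y - drop(A %*% xc))^2))
  }, numeric(1))
  # argmin residual; ties -> larger coefficient mass, then label order
  best <- min(residuals)
  cand <- which(residuals <= best + 1e-12)
  if (length(cand) > 1L) {
    mass <- vapply(classes[cand], function(cl) {
      sum(abs(x_full[labels == cl]))
    }, numeric(1))
    cand <- cand[order(-mass, cand)][1L]
  }
  structure(list(coefficients = x_full,
                 weights = weights,
                 support = support,
                 residuals = residuals,
                 predicted = classes[cand[1L]]),
            class = "sparse_fit")
}

#' Leave-one-out cross-validated WSRC
#'
#' Classifies every subject with the weighted sparse representation
#' classifier trained on the remaining subjects. Features are
#' standardized per fold using training-fold statistics only (no test
#' leakage), each held-out subject is predicted, and the accumulated
#' confusion matrix is summarized. For binary tasks the diagnostic
#' metrics of [diagnostic_metrics()] are attached for the designated
#' positive class.
#'
#' @param data a `cohort_dataset` (see [simulate_cohort()]).
#' @param task optional label regrouping, see [task_labels()]; `NULL`
#'   uses the dataset's labels as-is.
#' @param features character vector of feature names or a preset name
#'   (see [feature_presets()]); `NULL` uses every feature.
#' @param positive positive class for diagnostic metrics (binary tasks);
#'   default = first level.
#' @param budget,p passed to [wsrc_fit_predict()].
#' @param conf confidence level for metric CIs.
#' @return A list of class `loocv_result`: `confusion`, `accuracy`,
#'   `predicted`, `truth`, `metrics` (binary tasks), `warnings`.
#' @export
loocv_wsrc <- function(data, task = NULL, features = NULL,
                       positive = NULL, budget = NULL, p = 2,
                       conf = 0.95) {
  X <- data$features
  labels <- data$labels
  if (!is.null(task)) {
    mapped <- task_labels(labels, task)
    keep <- !is.na(mapped)
    X <- X[keep, , drop = FALSE]
    labels <- droplevels(mapped[keep])
  }
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stop("need at least 2 classes", call. = FALSE)
  if (!is.null(features)) {
    features <- resolve_features(features, colnames(X))
    X <- X[, features, drop = FALSE]
  }
  n <- nrow(X)
  warn <- character(0)
  if (any(table(labels) < 2)) {
    warn <- c(warn, "a class has a single member; its LOOCV fold lacks it")
    warning(warn[length(warn)], call. = FALSE)
  }
  pred <- character(n)
  for (i in seq_len(n)) {
    tr <- X[-i, , drop = FALSE]
    mu <- colMeans(tr)
    sdv <- apply(tr, 2L, stats::sd)
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    A <- t(sweep(sweep(tr, 2L, mu), 2L, sdv, "/"))
    yv <- (X[i, ] - mu) / sdv
    fit <- wsrc_fit_predict(A, droplevels(labels[-i]), yv,
                            budget = budget, p = p)
    pred[i] <- fit$predicted
  }
  pred <- factor(pred, levels = levels(labels))
  confusion <- table(truth = labels, predicted = pred)
  acc <- mean(pred == labels)
  metrics <- NULL
  if (nlevels(labels) == 2L) {
    pos <- positive %||% levels(labels)[1L]
    neg <- setdiff(levels(labels), pos)
    tp <- sum(labels == pos & pred == pos)
    fn <- sum(labels == pos & pred != pos)
    tn <- sum(labels == neg & pred == neg)
    fp <- sum(labels == neg & pred != neg)
    metrics <- diagnostic_metrics(tp = tp, fp = fp, fn = fn, tn = tn,
                                  conf = conf)
  }
  structure(list(confusion = confusion, accuracy = acc,
                 predicted = pred, truth = labels,
                 metrics = metrics, warnings = warn),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("LOOCV-WSRC accuracy: %.1f%%\n", 100 * x$accuracy))
  print(x$confusion)
  invisible(x)
}

#' Sequential forward feature selection
#'
#' Greedy wrapper selection: starting from the empty set, repeatedly
#' adds the feature whose addition maximizes LOOCV-WSRC accuracy, until
#' all features are included. The full trajectory is returned so
#' overfitting (accuracy declining as weak features join) is visible.
#'
#' @inheritParams loocv_wsrc
#' @return A list of class `sfs_result`: `order` (features in selection
#'   order), `accuracy` (per step), `best_subset`, `best_accuracy`.
#' @export
sequential_forward_selection <- function(data, task = NULL,
                                         budget = NULL, p = 2) {
  all_feats <- data$feature_names
  if (length(all_feats) < 2) stop("need at least 2 features", call. = FALSE)
  chosen <- character(0)
  acc_path <- numeric(0)
  remaining <- all_feats
  while (length(remaining)) {
    step_acc <- vapply(remaining, function(f) {
      loocv_wsrc(data, task = task, features = c(chosen, f),
                 budget = budget, p = p)$accuracy
    }, numeric(1))
    best <- remaining[which.max(step_acc)]
    chosen <- c(chosen, best)
    acc_path <- c(acc_path, max(step_acc))
    remaining <- setdiff(remaining, best)
  }
  k <- which.max(acc_path)
  structure(list(order = chosen, accuracy = acc_path,
                 best_subset = chosen[seq_len(k)],
                 best_accuracy = acc_path[k]),
            class = "sfs_result")
}

#' Binary task label maps
#'
#' Regroups the four cohort labels into the three binary diagnostic
#' tasks: all asthma (CAA, UAA, UNAA) vs healthy; uncontrolled (UAA,
#' UNAA) vs controlled (CAA) asthma; non-atopic (UNAA) vs atopic (CAA,
#' UAA) asthma. Subjects outside a task (e.g. healthy controls in the
#' controlled/uncontrolled contrast) map to `NA` and are dropped.
#'
#' @param labels factor with levels among Healthy, CAA, UAA, UNAA.
#' @param task one of `"asthma_vs_healthy"`,
#'   `"uncontrolled_vs_controlled"`, `"nonatopic_vs_atopic"`.
#' @return Factor of task labels (positive class first) with `NA` for
#'   excluded subjects.
#' @export
task_labels <- function(labels,
                        task = c("asthma_vs_healthy",
                                 "uncontrolled_vs_controlled",
                                 "nonatopic_vs_atopic")) {
  task <- match.arg(task)
  l <- as.character(labels)
  out <- switch(task,
    asthma_vs_healthy = ifelse(l %in% c("CAA", "UAA", "UNAA"), "Asthma",
                               ifelse(l == "Healthy", "Healthy", NA)),
    uncontrolled_vs_controlled = ifelse(l %in% c("UAA", "UNAA"),
                                        "Uncontrolled",
                                        ifelse(l == "CAA", "Controlled", NA)),
    nonatopic_vs_atopic = ifelse(l == "UNAA", "NonAtopic",
                                 ifelse(l %in% c("CAA", "UAA"), "Atopic", NA)))
  first <- c(asthma_vs_healthy = "Asthma",
             uncontrolled_vs_controlled = "Uncontrolled",
             nonatopic_vs_atopic = "NonAtopic")[[task]]
  factor(out, levels = c(first, setdiff(unique(stats::na.omit(out)), first)))
}

#' Named feature combinations
#'
#' The index combinations routinely reported: all three IBI indices,
#' all three LV indices, and the pairwise DFA / SampEn / LLE sets.
#'
#' @return Named list of character vectors of feature names.
#' @export
feature_presets <- function() {
  list(ibi_all = c("DFA_IBI", "SampEn_IBI", "LLE_IBI"),
       lv_all = c("DFA_LV", "SampEn_LV", "LLE_LV"),
       dfa_both = c("DFA_IBI", "DFA_LV"),
       sampen_both = c("SampEn_IBI", "SampEn_LV"),
       lle_both = c("LLE_IBI", "LLE_LV"),
       all = c("DFA_IBI", "DFA_LV", "SampEn_IBI", "SampEn_LV",
               "LLE_IBI", "LLE_LV", "CrossSampEn_IBI_LV"))
}

resolve_features <- function(features, available) {
  if (length(features) == 1L && grepl("^preset:", features)) {
    name <- sub("^preset:", "", features)
    presets <- feature_presets()
    if (!name %in% names(presets)) {
      stop(sprintf("unknown feature preset '%s'; valid presets: %s",
                   name, paste(names(presets), collapse = ", ")),
           call. = FALSE)
    }
    features <- presets[[name]]
  }
  missing <- setdiff(features, available)
  if (length(missing)) {
    stop("unknown features: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  features
}
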