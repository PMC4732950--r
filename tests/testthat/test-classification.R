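test_that("Minkowski weights follow hand-computed distances", {
  A <- cbind(c(3, 4), c(0, 1))
  y <- c(0, 0)
  w <- minkowski_weights(y, A, p = 2)
  # raw distances 5 and 1, rescaled by the maximum
  expect_equal(w, c(1, 0.2))
  # a test vector equal to a training column gets the floor weight
  A2 <- cbind(c(1, 2), c(5, 5))
  expect_equal(minkowski_weights(c(1, 2), A2)[1], 1e-6)
  # p = 1 and p = 2 agree in ordering on axis-aligned configurations
  A3 <- cbind(c(1, 0), c(2, 0), c(4, 0))
  expect_equal(order(minkowski_weights(c(0, 0), A3, p = 1)),
               order(minkowski_weights(c(0, 0), A3, p = 2)))
  expect_error(minkowski_weights(c(0, 0), A, p = 0.5), "p must be")
  expect_error(minkowski_weights(c(0, 0, 0), A), "dimension")
})

test_that("a test sample equal to a training column is reconstructed
           exactly", {
  A <- cbind(c(1, 2, 3), c(-1, 0.5, 2))
  fit <- wsrc_fit_predict(A, c("a", "b"), y = c(1, 2, 3), budget = 2)
  expect_equal(fit$predicted, "a")
  expect_equal(unname(fit$residuals["a"]), 0, tolerance = 1e-10)
  expect_error(wsrc_fit_predict(A, c("a", "b"), y = c(0, 0, 0)),
               "zero")
  expect_error(wsrc_fit_predict(A, c("a", "b"), y = c(1, 2, 3),
                                budget = 5), "budget")
})

test_that("well-separated clusters are classified like nearest centroid", {
  set.seed(11)
  tr <- rbind(matrix(rnorm(10 * 3), 10), matrix(rnorm(10 * 3) + 10, 10))
  labels <- rep(c("A", "B"), each = 10)
  for (k in 1:5) {
    y <- rnorm(3) + if (k %% 2) 0 else 10
    fit <- wsrc_fit_predict(t(tr), labels, y)
    expect_equal(fit$predicted, oracle_nearest_centroid(tr, labels, y))
  }
})

test_that("equal weights reduce WSRC to unweighted sparse representation", {
  set.seed(12)
  A <- matrix(rnorm(4 * 12), 4)
  y <- rnorm(4)
  labs <- rep(c("a", "b"), 6)
  f_eq <- wsrc_fit_predict(A, labs, y, weights = rep(1, 12), budget = 3)
  # independent unweighted matching-pursuit support oracle
  An <- sweep(A, 2, sqrt(colSums(A^2)), "/")
  supp <- integer(0)
  resid <- y
  for (s in 1:3) {
    sc <- abs(drop(crossprod(An, resid)))
    sc[supp] <- -Inf
    supp <- c(supp, which.max(sc))
    cf <- qr.coef(qr(A[, supp, drop = FALSE]), y)
    resid <- y - drop(A[, supp, drop = FALSE] %*% cf)
  }
  expect_equal(f_eq$support, supp)
})

test_that("duplicate-column ties resolve deterministically", {
  col <- c(1, 1)
  A <- cbind(col, col, col, col)
  fits <- replicate(5, wsrc_fit_predict(A, c("a", "a", "b", "b"),
                                        y = c(1, 1), budget = 1)$predicted)
  expect_equal(length(unique(fits)), 1L)
  # tie on residuals goes to the class holding more coefficient mass;
  # here one class has zero mass, so prediction is the supported class
  f <- wsrc_fit_predict(A, c("a", "a", "b", "b"), y = c(1, 1), budget = 1)
  expect_equal(f$predicted, levels(factor(c("a", "b")))[
    which.max(c(sum(abs(f$coefficients[1:2])),
                sum(abs(f$coefficients[3:4]))))])
})

test_that("residual invariants hold on random instances", {
  set.seed(13)
  for (k in 1:10) {
    A <- matrix(rnorm(5 * 16), 5)
    y <- rnorm(5)
    fit <- wsrc_fit_predict(A, rep(c("a", "b"), 8), y, budget = 4)
    expect_true(all(fit$residuals >= 0))
    expect_lte(min(fit$residuals), sqrt(sum(y^2)) + 1e-9)
  }
})

test_that("LOOCV is perfect on separation and at chance under permutation", {
  apart <- list(
    A = list(n_subjects = 10, mean = c(f1 = 0, f2 = 0, f3 = 0),
             sd = rep(0.5, 3)),
    B = list(n_subjects = 10, mean = c(f1 = 8, f2 = 8, f3 = 8),
             sd = rep(0.5, 3)))
  co <- simulate_cohort(apart, seed = 7, mode = "features")
  res <- loocv_wsrc(co)
  expect_equal(res$accuracy, 1)
  expect_equal(res$metrics$lr_neg$estimate, 0)
  # permuted 4-class labels: accuracy near 25%
  four <- lapply(c(A = 0, B = 1, C = 2, D = 3), function(mu) {
    list(n_subjects = 10, mean = c(f1 = mu, f2 = -mu), sd = c(1, 1))
  })
  co4 <- simulate_cohort(four, seed = 8, mode = "features")
  accs <- vapply(1:20, function(k) {
    perm <- co4
    perm$labels <- with_fixed_seed(900 + k, sample(co4$labels))
    loocv_wsrc(perm)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.25), 0.10)
})

test_that("LOOCV predictions are invariant to feature scaling", {
  set.seed(14)
  base <- list(
    A = list(n_subjects = 6, mean = c(f1 = 0, f2 = 1), sd = c(1, 1)),
    B = list(n_subjects = 6, mean = c(f1 = 2, f2 = -1), sd = c(1, 1)))
  co <- simulate_cohort(base, seed = 9, mode = "features")
  res1 <- loocv_wsrc(co)
  co$features[, 1] <- co$features[, 1] * 1000
  co$features[, 2] <- co$features[, 2] / 50 + 3
  res2 <- loocv_wsrc(co)
  expect_equal(res1$predicted, res2$predicted)
})

test_that("two-subject LOOCV degenerates gracefully", {
  tiny <- list(A = list(n_subjects = 1, mean = c(f1 = 0, f2 = 0),
                        sd = c(1, 1)),
               B = list(n_subjects = 1, mean = c(f1 = 5, f2 = 5),
                        sd = c(1, 1)))
  co <- simulate_cohort(tiny, seed = 10, mode = "features")
  expect_warning(res <- loocv_wsrc(co), "single member")
  expect_true(res$accuracy %in% c(0, 0.5, 1))
})

test_that("forward selection ranks an informative feature first", {
  set.seed(15)
  informative <- c(rnorm(10), rnorm(10) + 6)
  X <- cbind(sig = informative, n1 = rnorm(20), n2 = rnorm(20))
  co <- structure(list(features = X,
                       labels = factor(rep(c("A", "B"), each = 10)),
                       subject_ids = sprintf("S%02d", 1:20),
                       feature_names = colnames(X)),
                  class = "cohort_dataset")
  sfs <- sequential_forward_selection(co)
  expect_equal(sfs$order[1], "sig")
  expect_length(sfs$accuracy, 3L)
  expect_equal(sfs$best_accuracy, max(sfs$accuracy))
  # identical copies: accuracy trajectory is flat after the first pick
  X2 <- cbind(a = informative, b = informative, c = informative)
  co2 <- co
  co2$features <- X2
  co2$feature_names <- colnames(X2)
  sfs2 <- sequential_forward_selection(co2)
  expect_equal(sfs2$accuracy, rep(sfs2$accuracy[1], 3))
})

test_that("task label maps implement the three binary groupings", {
  l <- factor(c("Healthy", "CAA", "UAA", "UNAA"),
              levels = c("Healthy", "CAA", "UAA", "UNAA"))
  expect_equal(as.character(task_labels(l, "asthma_vs_healthy")),
               c("Healthy", "Asthma", "Asthma", "Asthma"))
  expect_equal(as.character(task_labels(l, "uncontrolled_vs_controlled")),
               c(NA, "Controlled", "Uncontrolled", "Uncontrolled"))
  expect_equal(as.character(task_labels(l, "nonatopic_vs_atopic")),
               c(NA, "Atopic", "Atopic", "NonAtopic"))
  expect_error(resolve_features <- respvar:::resolve_features(
    "preset:bogus", c("DFA_IBI")), "valid presets")
})
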