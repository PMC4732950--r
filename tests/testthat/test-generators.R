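test_that("generators are deterministic in their seed", {
  expect_equal(as.numeric(colored_noise(256, 1, seed = 7)),
               as.numeric(colored_noise(256, 1, seed = 7)))
  expect_false(isTRUE(all.equal(as.numeric(colored_noise(256, 1, seed = 7)),
                                as.numeric(colored_noise(256, 1, seed = 8)))))
  p1 <- coupled_pair(128, 0.5, seed = 3)
  p2 <- coupled_pair(128, 0.5, seed = 3)
  expect_equal(as.numeric(p1$b), as.numeric(p2$b))
  w1 <- breath_waveform(breath_spec(duration = 120, seed = 4), fs = 20)
  w2 <- breath_waveform(breath_spec(duration = 120, seed = 4), fs = 20)
  expect_identical(w1$breaths, w2$breaths)
  expect_equal(w1$waveform$ribcage, w2$waveform$ribcage)
})

test_that("colored noise is standardized and has the right spectral slope", {
  for (beta in c(0.5, 1.5)) {
    x <- as.numeric(colored_noise(2^14, beta, seed = 11))
    expect_equal(mean(x), 0, tolerance = 1e-10)
    expect_equal(sd(x), 1, tolerance = 1e-10)
    # periodogram slope on log-log axes approximates -beta
    pg <- Mod(fft(x)[2:(2^13)])^2
    f <- (1:(2^13 - 1)) / 2^14
    slope <- coef(lm(log(pg) ~ log(f)))[2]
    expect_lt(abs(slope + beta), 0.15)
  }
  expect_error(colored_noise(32, 1), "at least 64")
  expect_error(colored_noise(128, NaN), "beta")
  # odd lengths must not lose a sample to the Hermitian mirror
  expect_length(as.numeric(colored_noise(179, 1, seed = 1)), 179)
})

test_that("logistic map iterates exactly and settles to its fixed point", {
  expect_equal(as.numeric(logistic_series(3, r = 4, x0 = 0.2)),
               c(0.2, 0.64, 0.9216))
  x <- as.numeric(logistic_series(50, r = 2.5, x0 = 0.37, burn_in = 500))
  expect_equal(x, rep(1 - 1 / 2.5, 50), tolerance = 1e-8)
  expect_error(logistic_series(10, r = 4, x0 = 1.2), "x0")
})

test_that("periodic series: clean sinusoid is far more regular than noise", {
  clean <- periodic_series(1000, period = 10)
  expect_equal(as.numeric(clean), as.numeric(periodic_series(1000, 10)))
  noisy <- periodic_series(1000, period = 10, noise_sd = 10, seed = 2)
  se_clean <- sample_entropy(clean)
  se_noisy <- sample_entropy(noisy)
  iid <- sample_entropy(with_fixed_seed(3, rnorm(1000)))
  expect_lt(se_clean, 0.5 * iid)
  expect_gt(se_noisy, 0.8 * iid)
})

test_that("coupled pair honors its coupling contract", {
  p <- coupled_pair(256, 1, seed = 5)
  expect_equal(as.numeric(p$a), as.numeric(p$b))
  expect_error(coupled_pair(256, 1.4, seed = 1), "coupling")
  # driver correlation is recovered approximately
  p2 <- coupled_pair(4096, 0.8, seed = 6)
  expect_equal(cor(as.numeric(p2$a), as.numeric(p2$b)), 0.8,
               tolerance = 0.1)
})

test_that("waveform generator recovers the prescribed breath statistics", {
  spec <- breath_spec(duration = 1200, seed = 9)
  w <- breath_waveform(spec, fs = 25)
  ser <- series_from_breaths(w$breaths)
  st <- summary_stats(ser$ibi)
  expect_equal(st$mean, spec$mean_ibi, tolerance = 0.05 * spec$mean_ibi)
  expect_equal(st$cv, spec$cv_ibi, tolerance = 0.35 * spec$cv_ibi)
  stl <- summary_stats(ser$lv)
  expect_equal(stl$mean, spec$mean_lv, tolerance = 0.05 * spec$mean_lv)
  # breath count tracks duration / mean interval
  expect_equal(nrow(w$breaths), 1200 / spec$mean_ibi, tolerance = 0.03)
  # ground-truth intervals are exactly the rendered peak-to-peak gaps
  expect_equal(as.numeric(ser$ibi), diff(w$breaths$peak_time_s))
})

test_that("zero-CV spec renders perfectly regular breathing", {
  spec <- breath_spec(cv_ibi = 0, cv_lv = 0, duration = 120, seed = 2)
  w <- breath_waveform(spec, fs = 20)
  expect_equal(diff(w$breaths$peak_time_s),
               rep(spec$mean_ibi, nrow(w$breaths) - 1L))
  expect_equal(w$breaths$peak_volume_L,
               rep(spec$mean_lv, nrow(w$breaths)))
})

test_that("cohort simulation has the right shape and labelling", {
  groups <- cohort_groups_default(n_per_group = 2L, duration = 400)
  co <- simulate_cohort(groups, seed = 3)
  expect_s3_class(co, "cohort_dataset")
  expect_equal(dim(co$features), c(8L, 7L))
  expect_equal(levels(co$labels), c("Healthy", "CAA", "UAA", "UNAA"))
  expect_equal(as.vector(table(co$labels)), rep(2L, 4))
  expect_true(all(is.finite(co$features)))
  # determinism
  co2 <- simulate_cohort(groups, seed = 3)
  expect_equal(co$features, co2$features)
})

test_that("feature-mode cohorts drive downstream stages as constructed", {
  # identical groups: discrimination is at chance
  same <- list(
    A = list(n_subjects = 12, mean = c(f1 = 0, f2 = 0), sd = c(1, 1)),
    B = list(n_subjects = 12, mean = c(f1 = 0, f2 = 0), sd = c(1, 1)))
  co <- simulate_cohort(same, seed = 4, mode = "features")
  auc <- oracle_auc(co$features[, "f1"], co$labels == "A")
  expect_lt(abs(auc - 0.5), 0.2)
  # non-overlapping groups: LOOCV is perfect
  apart <- list(
    A = list(n_subjects = 8, mean = c(f1 = 0, f2 = 0), sd = c(0.5, 0.5)),
    B = list(n_subjects = 8, mean = c(f1 = 10, f2 = 10), sd = c(0.5, 0.5)))
  co2 <- simulate_cohort(apart, seed = 5, mode = "features")
  expect_equal(loocv_wsrc(co2)$accuracy, 1)
})
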