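# synthetic Gaussian marker matrix: `signal` controls how far pain-day
# rows shift in the first marker
mk_gauss_data <- function(n_groups = 12, days_per_class = 8, p = 20,
                          signal = 0, seed = 1) {
  set.seed(seed)
  n <- n_groups * days_per_class * 2
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("marker_", seq_len(p))))
  y <- rep(rep(c("pain", "pain_free"), each = days_per_class), n_groups)
  X[y == "pain", 1] <- X[y == "pain", 1] + signal
  g <- rep(sprintf("E%02d", seq_len(n_groups)),
           each = 2 * days_per_class)
  mk_feature_matrix(X, y, g)
}

test_that("group-aware folds never split a group and balance classes", {
  d <- mk_gauss_data()
  folds <- make_group_folds(d$groups, 3, seed = 5)
  expect_setequal(unique(folds), 1:3)
  # no group straddles folds (the leakage canary)
  expect_true(all(tapply(folds, d$groups,
                         function(f) length(unique(f))) == 1))
  # every fold sees both classes
  for (f in 1:3)
    expect_setequal(unique(as.character(d$y[folds == f])),
                    c("pain", "pain_free"))
  expect_error(make_group_folds(rep("G1", 10), 3), "at least 3")
})

test_that("classifier is at chance on null data, perfect under separation", {
  null <- mk_gauss_data(signal = 0, seed = 2)   # 384 rows
  r0 <- train_classifier_cv(null, n_trees = 100, seed = 3)
  expect_lt(abs(r0$accuracy - 0.5), 0.1)
  expect_lt(abs(r0$auroc - 0.5), 0.12)

  sep <- mk_gauss_data(signal = 20, seed = 4)
  r1 <- train_classifier_cv(sep, n_trees = 100, seed = 3)
  expect_equal(r1$accuracy, 1.0)
  expect_equal(r1$auroc, 1.0)
  expect_equal(r1$auprc, 1.0)

  # single-class input is degenerate
  one <- mk_gauss_data()
  one$y <- factor(rep("pain", length(one$y)),
                  levels = c("pain_free", "pain"))
  expect_error(train_classifier_cv(one), "degenerate")
})

test_that("reported metrics agree with the stored confusion matrix", {
  d <- mk_gauss_data(signal = 1.5, seed = 6)
  r <- train_classifier_cv(d, seed = 7)
  cm <- r$confusion
  expect_equal(r$accuracy, (cm[1, 1] + cm[2, 2]) / sum(cm))
  expect_equal(r$sensitivity, cm[1, 1] / (cm[1, 1] + cm[2, 1]))
  expect_equal(r$specificity, cm[2, 2] / (cm[2, 2] + cm[1, 2]))
  # metrics from pooled out-of-fold predictions match the vectors
  expect_equal(r$accuracy, mean(r$predictions == r$y))
})

test_that("regression-tree correlation tracks the class signal", {
  expect_lt(abs(fit_regression_correlation(mk_gauss_data(signal = 0,
                                                         seed = 8),
                                           seed = 1)), 0.15)
  expect_gt(fit_regression_correlation(mk_gauss_data(signal = 20,
                                                     seed = 9),
                                       seed = 1), 0.95)
})

test_that("isolation forest flags constructed outliers and misses inliers", {
  # pain days are scattered extremes in the single relevant marker ->
  # anomaly coincides with class and accuracy is (near) perfect
  d <- mk_gauss_data(n_groups = 6, p = 1, signal = 0, seed = 10)
  set.seed(10)
  d$X[d$y == "pain", 1] <- sample(c(-1, 1), sum(d$y == "pain"),
                                  replace = TRUE) *
    runif(sum(d$y == "pain"), 20, 500)
  out <- iforest_baseline(d, seed = 2)
  expect_gt(out$baseline_accuracy, 0.9)
  expect_equal(out$contamination, 0.5)

  # pain days sit in the middle of a routine shell -> at or below chance
  set.seed(11)
  n <- 120
  X <- matrix(rnorm(n * 5, sd = 0.05), n, 5,
              dimnames = list(NULL, paste0("m", 1:5)))
  shell <- seq_len(n) %% 2 == 0
  X[shell, ] <- X[shell, ] + sign(matrix(rnorm(sum(shell) * 5),
                                         sum(shell), 5)) * 3
  y <- ifelse(shell, "pain_free", "pain")
  d2 <- mk_feature_matrix(X, y, rep(sprintf("E%02d", 1:10), each = 12))
  out2 <- iforest_baseline(d2, seed = 3)
  expect_lte(out2$baseline_accuracy, 0.5)
})

test_that("information gain ranks a clean split at full label entropy", {
  d <- mk_gauss_data(n_groups = 6, signal = 0, seed = 12)
  X <- d$X
  X[, 1] <- ifelse(d$y == "pain", 1, 0)     # perfect split
  X[, 2] <- 7                               # constant
  d$X <- X
  rk <- rank_markers_information_gain(d)
  expect_equal(rk$marker[1], "marker_1")
  expect_equal(rk$gain[1], 1.0)              # H(y) = 1 bit at balance
  expect_equal(rk$gain[rk$marker == "marker_2"], 0)
  expect_true(all(diff(rk$gain) <= 0))
  expect_true(all(rk$gain >= 0))
  expect_equal(rk$direction[1], 1)
})

test_that("paired permutation test behaves at its extremes", {
  y <- rep(c("pain", "pain_free"), 50)
  same <- y
  expect_equal(compare_guided_vs_unguided(same, same, y, 1000, seed = 1),
               1.0)
  wrong <- ifelse(y == "pain", "pain_free", "pain")
  p <- compare_guided_vs_unguided(same, wrong, y, 10000, seed = 1)
  expect_lte(p, 0.001)
  # symmetry under swapping the two methods
  p2 <- compare_guided_vs_unguided(wrong, same, y, 10000, seed = 1)
  expect_equal(p, p2)
  expect_error(compare_guided_vs_unguided(same[-1], wrong, y),
               "length mismatch")
})

test_that("guided accuracy responds monotonically to the injected effect", {
  accs <- vapply(c(1.0, 0.8, 0.6), function(m) {
    pert <- function(ty) pain_perturbation(
      ty, activity_rate_multiplier = m,
      extra_bed_toilet_transitions_per_night = 0,
      transition_duration_multiplier = 1,
      favorite_chair_added_minutes = 0,
      out_of_home_probability_multiplier = 1,
      grooming_skip_probability = 0, sleep_shift_minutes = 0,
      nap_probability = NA, visitor_burst_probability = NA)
    sp <- cohort_spec(n_participants = 3L, monitoring_days = 70L,
                      n_pain_events = 6L, master_seed = 99L,
                      acute_perturbation = pert("acute"),
                      flare_perturbation = pert("flare"))
    co <- generate_cohort(sp)
    fm <- feature_matrix(cohort_feature_matrix(co))
    train_classifier_cv(fm, seed = 5)$accuracy
  }, 0)
  expect_true(all(diff(accs) >= -0.05))
  expect_gt(accs[3], accs[1])
})
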