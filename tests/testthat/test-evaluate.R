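random_fm <- function(n_subj = 4, per_subj = 20, d = 3, seed = 1,
                      labels = NULL) {
  set.seed(seed)
  n <- n_subj * per_subj
  if (is.null(labels)) labels <- sample(c("normal", "fatigue"), n, replace = TRUE)
  feature_matrix(matrix(stats::rnorm(n * d), ncol = d),
                 sprintf("f%d", seq_len(d)), labels,
                 rep(sprintf("S%d", seq_len(n_subj)), each = per_subj))
}

test_that("LOSO folds partition the rows exactly", {
  fm <- random_fm(n_subj = 6, per_subj = 10)
  splits <- loso_splits(fm)
  expect_length(splits, 6)
  test_all <- sort(unlist(lapply(splits, `[[`, "test_idx")))
  expect_identical(test_all, seq_len(60))
  for (sp in splits) {
    expect_false(sp$test_subject %in% sp$train_ids)
    expect_length(intersect(sp$test_idx, sp$train_idx), 0)
    expect_length(sp$test_idx, 10)
    expect_length(sp$train_idx, 50)
  }
  expect_length(loso_splits(random_fm(n_subj = 2)), 2)
  expect_error(loso_splits(random_fm(n_subj = 1)),
               class = "fatigueEEG_parameter_error")
})

test_that("accuracy arithmetic and its binomial null", {
  expect_equal(accuracy(c(1, 0, 1, 0), c(1, 1, 1, 1)), 50)
  expect_equal(accuracy(letters[1:4], letters[1:4]), 100)
  expect_error(accuracy(1:3, 1:4), class = "fatigueEEG_parameter_error")
  set.seed(20)
  acc <- replicate(100, accuracy(sample(0:1, 1000, TRUE), sample(0:1, 1000, TRUE)))
  expect_lt(abs(mean(acc) - 50), 5)
})

test_that("paired t-test matches the closed-form Student oracle", {
  r <- paired_t_test(c(1, 2, 3, 4, 5, 6) + 10, rep(10, 6))
  expect_equal(r$mean, 3.5, tolerance = 1e-4)
  expect_equal(r$sd, 1.8708, tolerance = 1e-4)
  expect_equal(r$t, 4.5826, tolerance = 1e-4)
  expect_equal(r$df, 5)
  expect_equal(round(r$p, 4), 0.0059)

  # independent oracle: stats::t.test on random pairs
  set.seed(21)
  a <- stats::rnorm(8, 70, 5); b <- stats::rnorm(8, 65, 5)
  r2 <- paired_t_test(a, b)
  tt <- stats::t.test(a, b, paired = TRUE)
  expect_equal(r2$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(r2$p, tt$p.value, tolerance = 1e-10)
  expect_equal(c(r2$ci_lo, r2$ci_hi), as.numeric(tt$conf.int), tolerance = 1e-10)

  # degenerate and antisymmetry
  expect_true(paired_t_test(a, a)$degenerate)
  r3 <- paired_t_test(b, a)
  expect_equal(r3$mean, -r2$mean)
  expect_equal(r3$t, -r2$t)
  expect_equal(r3$p, r2$p)
})

test_that("report averages equal the means of its own cells", {
  fm <- tiny_features_psd()
  rep_ <- run_experiment(fm, classifiers = list(
    knn = function(x, y, seed) knn_train(x, y),
    elm = function(x, y, seed) elm_train(x, y, seed = seed)), seed = 2)
  expect_equal(rep_$averages, rowMeans(rep_$per_cell), tolerance = 1e-12)
  expect_true(all(rep_$per_cell >= 0 & rep_$per_cell <= 100))
})

test_that("permuted labels drive LOSO accuracy to chance", {
  accs <- numeric(10)
  for (s in 1:10) {
    set.seed(600 + s)
    fm <- tiny_features_psd()
    fm$labels <- sample(fm$labels)
    rep_ <- run_experiment(fm, classifiers = list(
      knn = function(x, y, seed) knn_train(x, y)), seed = s)
    accs[s] <- rep_$averages[["knn"]]
  }
  expect_lt(abs(mean(accs) - 50), 10)
})

test_that("EMD features classify at least as well as band power (within 5 points)", {
  fm_emd <- tiny_features_emd()
  fm_psd <- tiny_features_psd()
  cls <- list(knn = function(x, y, seed) knn_train(x, y),
              svm = function(x, y, seed) svm_train(x, y))
  mean_acc <- function(fm, s) mean(run_experiment(fm, classifiers = cls,
                                                  seed = s)$averages)
  a_emd <- vapply(1:10, function(s) mean_acc(fm_emd, s), 0)
  a_psd <- vapply(1:10, function(s) mean_acc(fm_psd, s), 0)
  expect_gte(mean(a_emd), mean(a_psd) - 5)
})

test_that("the full pipeline is deterministic end to end", {
  recs <- tiny_dataset()[1:4]                  # 2 subjects x 2 states
  run <- function() run_experiment(
    recs, "psd", classifiers = list(
      knn = function(x, y, seed) knn_train(x, y),
      elm = function(x, y, seed) elm_train(x, y, seed = seed)),
    seed = 7, denoise = threshold_params(), ttest_reference = "elm")
  r1 <- run(); r2 <- run()
  expect_identical(r1$per_cell, r2$per_cell)
  expect_identical(r1$features$values, r2$features$values)
  expect_identical(r1$ttests, r2$ttests)
})

test_that("classifier failures become missing cells, not fatal errors", {
  fm <- random_fm(n_subj = 3, per_subj = 8, seed = 3)
  boom <- function(x, y, seed) stop("deliberate failure")
  expect_message(
    rep_ <- run_experiment(fm, classifiers = list(
      knn = function(x, y, seed) knn_train(x, y), broken = boom), seed = 1),
    "failed")
  expect_true(all(is.na(rep_$per_cell["broken", ])))
  expect_true(all(!is.na(rep_$per_cell["knn", ])))
  expect_equal(rep_$n_missing, 3)
  expect_false(is.na(rep_$averages[["knn"]]))
})

test_that("reports serialize to JSON", {
  fm <- random_fm(seed = 5)
  rep_ <- run_experiment(fm, classifiers = list(
    knn = function(x, y, seed) knn_train(x, y)), seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep_, path)
  parsed <- jsonlite::read_json(path)
  expect_named(parsed$averages, "knn")
})
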