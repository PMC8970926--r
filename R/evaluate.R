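#' Leave-one-subject-out split plans
#'
#' One plan per subject: that subject's rows form the test fold, everyone
#' else trains. Folds partition the rows exactly.
#'
#' @param fm A [feature_matrix()].
#' @return List of `split_plan` objects with `test_subject`, `train_ids`,
#'   `test_idx`, `train_idx`.
#' @export
loso_splits <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  subjects <- unique(fm$subject_ids)
  if (length(subjects) < 2)
    stop_param("leave-one-subject-out needs at least 2 subjects")
  lapply(subjects, function(s) {
    structure(list(test_subject = s,
                   train_ids = setdiff(subjects, s),
                   test_idx = which(fm$subject_ids == s),
                   train_idx = which(fm$subject_ids != s)),
              class = "split_plan")
  })
}

#' Classification accuracy in percent
#'
#' @param pred,truth Equal-length label vectors.
#' @return `100 * matches / total`.
#' @export
accuracy <- function(pred, truth) {
  if (length(pred) == 0 || length(pred) != length(truth))
    stop_param("pred and truth must be non-empty and of equal length")
  100 * mean(as.character(pred) == as.character(truth))
}

#' Paired t-test row
#'
#' For accuracy vectors `a` and `b` over the same subjects, computes the
#' paired differences `d = a - b` and returns mean, sd (n-1 denominator),
#' standard error, 95% confidence interval (Student t, df = n-1), t
#' statistic and two-sided p value. Zero-variance differences are flagged
#' degenerate with `t`/`p` omitted.
#'
#' @param a,b Numeric vectors of equal length (>= 2).
#' @return A one-row data frame: `mean`, `sd`, `se`, `ci_lo`, `ci_hi`,
#'   `t`, `df`, `p`, `degenerate`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2)
    stop_param("a and b must have equal length >= 2")
  d <- a - b
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  df <- n - 1
  if (s == 0) {
    return(data.frame(mean = m, sd = 0, se = 0, ci_lo = m, ci_hi = m,
                      t = NA_real_, df = df, p = NA_real_, degenerate = TRUE))
  }
  se <- s / sqrt(n)
  tcrit <- stats::qt(0.975, df)
  tstat <- m / se
  data.frame(mean = m, sd = s, se = se,
             ci_lo = m - tcrit * se, ci_hi = m + tcrit * se,
             t = tstat, df = df,
             p = 2 * stats::pt(-abs(tstat), df), degenerate = FALSE)
}

default_classifiers <- function() {
  list(
    knn = function(x, y, seed) knn_train(x, y, k = 5),
    svm = function(x, y, seed) svm_train(x, y),
    elm = function(x, y, seed) elm_train(x, y, seed = seed),
    helm = function(x, y, seed) helm_train(x, y, seed = seed))
}

#' Run the leave-one-subject-out experiment
#'
#' End-to-end harness: preprocess the recordings (downsample, bandpass,
#' epoch), optionally wavelet-denoise every epoch channel, extract
#' features, then for every LOSO fold train each classifier on the
#' training subjects and score it on the held-out subject. Averages are
#' the exact arithmetic means of the per-subject cells; classifier
#' failures are recorded as missing cells, not fatal. Optionally appends
#' paired t-test rows comparing a reference classifier against the others.
#'
#' @param recordings List of [eeg_recording()] objects spanning >= 2
#'   subjects and both states, or a ready-made [feature_matrix()] (in
#'   which case preprocessing/feature arguments are ignored).
#' @param feature_method `"emd"` or `"psd"`.
#' @param classifiers Named list of trainer functions `f(x, y, seed)`
#'   returning a model with a `predict` method; default KNN, SVM, ELM,
#'   H-ELM.
#' @param seed Integer seed; per-fold classifier seeds derive from it.
#' @param target_rate,band,epoch_s Preprocessing settings, see
#'   [preprocess_dataset()].
#' @param denoise `NULL` to skip, or a [threshold_params()] applied to
#'   every epoch channel.
#' @param wavelet,J Wavelet settings for denoising.
#' @param n_imfs IMF layers for `"emd"` features.
#' @param ttest_reference Name of the classifier to compare against the
#'   others with [paired_t_test()], or `NULL` for none.
#' @param ... Further arguments to the feature extractor.
#' @return An `eval_report`: `per_cell` (classifier x subject accuracy
#'   matrix, %), `averages`, `ttests`, `n_missing`, `features` (the
#'   feature matrix used).
#' @export
run_experiment <- function(recordings, feature_method = c("emd", "psd"),
                           classifiers = default_classifiers(), seed = 1,
                           target_rate = 200, band = c(0.1, 50), epoch_s = 10,
                           denoise = threshold_params(), wavelet = "db4", J = 3,
                           n_imfs = 3, ttest_reference = NULL, ...) {
  feature_method <- match.arg(feature_method)
  if (is.null(names(classifiers)) || any(!nzchar(names(classifiers))))
    stop_param("classifiers must be a named list")

  if (inherits(recordings, "feature_matrix")) {
    fm <- recordings
  } else {
    states <- vapply(recordings, `[[`, "", "state")
    if (length(unique(states)) < 2)
      stop_param("dataset must contain both states")
    es <- preprocess_dataset(recordings, target_rate = target_rate,
                             band = band, epoch_s = epoch_s)
    if (!is.null(denoise)) es <- denoise_epochs(es, denoise, wavelet, J)
    fm <- if (feature_method == "emd")
      extract_features(es, "emd", n_imfs = n_imfs, ...)
    else extract_features(es, "psd", ...)
  }

  splits <- loso_splits(fm)
  subjects <- vapply(splits, `[[`, "", "test_subject")
  per_cell <- matrix(NA_real_, nrow = length(classifiers), ncol = length(subjects),
                     dimnames = list(names(classifiers), subjects))
  for (si in seq_along(splits)) {
    sp <- splits[[si]]
    x_tr <- fm$values[sp$train_idx, , drop = FALSE]
    y_tr <- fm$labels[sp$train_idx]
    x_te <- fm$values[sp$test_idx, , drop = FALSE]
    y_te <- fm$labels[sp$test_idx]
    for (ci in seq_along(classifiers)) {
      cl_seed <- derive_seed(seed, names(classifiers)[ci], sp$test_subject)
      fit <- tryCatch(classifiers[[ci]](x_tr, y_tr, cl_seed),
                      error = function(e) NULL)
      if (is.null(fit)) next
      pred <- tryCatch(predict(fit, x_te), error = function(e) NULL)
      if (is.null(pred)) next
      per_cell[ci, si] <- accuracy(pred, y_te)
    }
  }
  n_missing <- sum(is.na(per_cell))
  if (n_missing > 0)
    message(sprintf("%d classifier cell(s) failed and are excluded from averages", n_missing))
  averages <- rowMeans(per_cell, na.rm = TRUE)

  ttests <- NULL
  if (!is.null(ttest_reference)) {
    if (!ttest_reference %in% rownames(per_cell))
      stop_param("ttest_reference must name a classifier")
    others <- setdiff(rownames(per_cell), ttest_reference)
    rows <- lapply(others, function(o) {
      ok <- !is.na(per_cell[ttest_reference, ]) & !is.na(per_cell[o, ])
      if (sum(ok) < 2) return(NULL)
      cbind(pair = paste0(ttest_reference, "-", o),
            paired_t_test(per_cell[ttest_reference, ok], per_cell[o, ok]))
    })
    ttests <- do.call(rbind, Filter(Negate(is.null), rows))
  }

  structure(list(per_cell = per_cell, averages = averages, ttests = ttests,
                 n_missing = n_missing, features = fm, seed = seed),
            class = "eval_report")
}

#' Wavelet-denoise every channel of every epoch
#'
#' @param es An [eeg_epoch_set()].
#' @param params A [threshold_params()].
#' @param wavelet,J Wavelet settings.
#' @return The denoised [eeg_epoch_set()].
#' @export
denoise_epochs <- function(es, params = threshold_params(), wavelet = "db4", J = 3) {
  stopifnot(inherits(es, "eeg_epoch_set"))
  es$epochs <- lapply(es$epochs, function(ep) {
    for (ch in seq_len(nrow(ep$data)))
      ep$data[ch, ] <- denoise_signal(ep$data[ch, ], params, wavelet, J)$signal
    ep
  })
  es
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> per-subject accuracy (%):\n")
  print(round(x$per_cell, 2))
  cat("averages (%):\n")
  print(round(x$averages, 2))
  if (!is.null(x$ttests)) {
    cat("paired t-tests:\n")
    print(cbind(x$ttests[, "pair", drop = FALSE],
                round(x$ttests[, c("mean", "sd", "se", "ci_lo", "ci_hi", "t")], 3),
                df = x$ttests$df, p = signif(x$ttests$p, 3)))
  }
  invisible(x)
}

#' Export an evaluation report as JSON
#'
#' @param report An `eval_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  out <- list(per_cell = as.data.frame(report$per_cell),
              averages = as.list(report$averages),
              n_missing = report$n_missing, seed = report$seed)
  if (!is.null(report$ttests)) out$ttests <- report$ttests
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
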