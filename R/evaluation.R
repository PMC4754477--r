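#' Confusion counts from decisions and labels
#'
#' Tallies true/false positives and negatives. (Named `confusion_counts`
#' rather than `tally` to avoid colliding with the dplyr verb in tidy
#' pipelines.)
#'
#' @param decisions Logical vector: `TRUE` = segment confirmed as the
#'   hypothesized class (CHF).
#' @param labels Logical vector: `TRUE` = segment truly is the
#'   hypothesized class.
#' @return A one-row tibble with integer columns `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(decisions, labels) {
  decisions <- as.logical(decisions)
  labels <- as.logical(labels)
  stopifnot(length(decisions) == length(labels),
            !anyNA(decisions), !anyNA(labels))
  tibble::tibble(
    tp = sum(decisions & labels),
    tn = sum(!decisions & !labels),
    fp = sum(decisions & !labels),
    fn = sum(!decisions & labels)
  )
}

#' Sensitivity, specificity, positive predictivity and recognition rate
#'
#' From confusion counts:
#' sensitivity `= 100 * TP/(TP+FN)`, specificity `= 100 * TN/(TN+FP)`,
#' positive predictivity `= 100 * TP/(TP+FP)`, and the recognition rate is
#' the arithmetic mean of the three.
#'
#' @param counts A one-row data frame (or named list/vector) with `tp`,
#'   `tn`, `fp`, `fn`; alternatively the four counts as named arguments.
#' @return A one-row tibble: `tp`, `tn`, `fp`, `fn`, `sensitivity`,
#'   `specificity`, `positive_predictivity`, `recognition_rate` (all rates
#'   in percent).
#' @examples
#' classification_metrics(list(tn = 123, tp = 130, fn = 27, fp = 20))
#' @export
classification_metrics <- function(counts) {
  cn <- as.list(counts)
  tp <- as.numeric(cn$tp); tn <- as.numeric(cn$tn)
  fp <- as.numeric(cn$fp); fn <- as.numeric(cn$fn)
  stopifnot(length(tp) == 1, length(tn) == 1, length(fp) == 1,
            length(fn) == 1)
  if (tp + fn == 0) stop("sensitivity undefined: TP + FN = 0", call. = FALSE)
  if (tn + fp == 0) stop("specificity undefined: TN + FP = 0", call. = FALSE)
  if (tp + fp == 0) {
    stop("positive predictivity undefined: TP + FP = 0", call. = FALSE)
  }
  se <- 100 * tp / (tp + fn)
  sp <- 100 * tn / (tn + fp)
  pp <- 100 * tp / (tp + fp)
  tibble::tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    sensitivity = se, specificity = sp, positive_predictivity = pp,
    recognition_rate = (se + sp + pp) / 3
  )
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps a decision threshold over all distinct score values (plus
#' infinite endpoints), classifying `score >= threshold` as positive, and
#' integrates the area under the TPR-vs-FPR curve by the trapezoidal rule.
#' The AUC equals the normalized Mann-Whitney U statistic (ties counted
#' one half).
#'
#' @param scores Numeric decision scores (higher = more positive-like; the
#'   package's confirmation score is `-ldsr`).
#' @param labels Logical (or 0/1) true-class labels.
#' @return A tibble of class `ecg_roc` with columns `threshold`, `tpr`,
#'   `fpr`, running from (0,0) to (1,1), and attribute `auc`.
#' @examples
#' rc <- roc_curve(c(3, 2.5, 1, 0.5, -1, -2), c(1, 1, 0, 1, 0, 0))
#' attr(rc, "auc")
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("roc_curve: need at least one positive and one negative label",
         call. = FALSE)
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / n_neg,
                numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  out <- tibble::tibble(threshold = thr, tpr = tpr, fpr = fpr)
  class(out) <- c("ecg_roc", class(out))
  attr(out, "auc") <- auc
  attr(out, "n_pos") <- n_pos
  attr(out, "n_neg") <- n_neg
  out
}

#' Area under an ROC curve
#' @param x An `ecg_roc` from [roc_curve()].
#' @return Scalar AUC in \[0, 1\].
#' @export
auc <- function(x) {
  stopifnot(inherits(x, "ecg_roc"))
  attr(x, "auc")
}

#' End-to-end synthetic recognition benchmark
#'
#' Reproduces the study design on generated data: the first
#' `n_model` segments of each class build the hypothesized (CHF) and
#' background models; the remaining segments are test segments (never the
#' model-building ones). Optionally, white Gaussian noise at `snr_db` is
#' injected into the raw test segments before preprocessing. Every test
#' segment is scored by the three confirmation functions against the two
#' models; decisions are tallied into the four rates, and the continuous
#' score (`-ldsr`) is swept into an ROC curve. Fully reproducible from
#' `seed`.
#'
#' @param background_class Background rhythm class (`"NSR"`, `"AF"` or
#'   `"PEB"`); the hypothesized class is always `"CHF"`.
#' @param n_model Model-building segments per class (default 15).
#' @param n_test Test segments per class (default 150).
#' @param snr_db SNR of noise injected into test segments (`Inf` = clean,
#'   the default).
#' @param seed Integer seed driving segment generation and noise.
#' @param wavelet_cfg A [wavelet_config()].
#' @param preprocess_cfg A [preprocess_config()].
#' @param extractor Feature extractor (see [extract_features()]).
#' @param duration_s,fs Segment duration and sampling rate.
#' @return An object of class `wafe_benchmark`: list with `report` (the
#'   one-row metrics tibble), `roc` (an `ecg_roc`), `results` (per-segment
#'   confirmation tibble), and the call parameters.
#' @examples
#' \donttest{
#' bm <- run_benchmark(n_test = 20, seed = 1)
#' bm$report$recognition_rate
#' }
#' @export
run_benchmark <- function(background_class = "NSR", n_model = 15L,
                          n_test = 150L, snr_db = Inf, seed = 1L,
                          wavelet_cfg = wavelet_config(),
                          preprocess_cfg = preprocess_config(),
                          extractor = "wafe", duration_s = 10, fs = 250) {
  stopifnot(background_class %in% c("NSR", "AF", "PEB"), n_model >= 1L,
            n_test >= 1L)
  classes <- c(background_class, "CHF")
  data <- synth_ecg_dataset(classes, n_per_class = n_model + n_test,
                            duration_s = duration_s, fs = fs, seed = seed)
  data$role <- unlist(lapply(classes, function(cl) {
    c(rep("model", n_model), rep("test", n_test))
  }))

  is_test <- data$role == "test"
  if (is.finite(snr_db)) {
    noise_seeds <- derive_seeds(seed, sum(is_test), salt = 7919L)
    data$segment[is_test] <- Map(function(s, sd) add_awgn(s, snr_db, sd),
                                 data$segment[is_test], noise_seeds)
  }
  data <- preprocess_segments(data, preprocess_cfg)
  feats <- extract_features(data, extractor = extractor, cfg = wavelet_cfg)
  feats$role <- data$role

  mx <- build_model(feats[feats$role == "model" & feats$label == "CHF", ],
                    class_label = "CHF")
  mb <- build_model(
    feats[feats$role == "model" & feats$label == background_class, ],
    class_label = background_class
  )
  test_feats <- feats[feats$role == "test", ]
  results <- confirm_segments(test_feats, mx, mb)
  counts <- confusion_counts(results$confirmed, results$label == "CHF")
  report <- classification_metrics(counts)
  roc <- roc_curve(results$score, results$label == "CHF")
  structure(
    list(report = report, roc = roc, results = results,
         model_x = mx, model_b = mb,
         params = list(background_class = background_class,
                       n_model = n_model, n_test = n_test, snr_db = snr_db,
                       seed = seed, extractor = extractor,
                       wavelet_cfg = wavelet_cfg,
                       preprocess_cfg = preprocess_cfg,
                       duration_s = duration_s, fs = fs)),
    class = "wafe_benchmark"
  )
}

#' @export
print.wafe_benchmark <- function(x, ...) {
  p <- x$params
  cat(sprintf("<wafe_benchmark> CHF vs %s, %s features, %d+%d test segments%s\n",
              p$background_class, toupper(p$extractor), p$n_test, p$n_test,
              if (is.finite(p$snr_db)) sprintf(", AWGN %g dB", p$snr_db)
              else ""))
  r <- x$report
  cat(sprintf("  sensitivity %.2f%%  specificity %.2f%%  pos. predictivity %.2f%%\n",
              r$sensitivity, r$specificity, r$positive_predictivity))
  cat(sprintf("  recognition rate %.2f%%  AUC %.4f\n",
              r$recognition_rate, auc(x$roc)))
  invisible(x)
}

# Derive n child seeds (31-bit) from a parent seed, decorrelated by a salt.
derive_seeds <- function(seed, n, salt = 1L) {
  (as.double(seed) * 48271 + salt * 95783 + 1e4 * seq_len(n)) %% 2147483629
}
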