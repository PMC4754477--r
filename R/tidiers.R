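#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a class model
#'
#' One row per terminal node with the model's mean feature value.
#'
#' @param x An `arrhythmia_model`.
#' @param ... Unused.
#' @return A tibble with columns `node`, `value`, `class_label`.
#' @export
tidy.arrhythmia_model <- function(x, ...) {
  tibble::tibble(
    node = seq_along(x$mean_vector),
    value = x$mean_vector,
    class_label = x$class_label
  )
}

#' @rdname tidy.arrhythmia_model
#' @return `glance()` returns a one-row summary (class, extractor, Q,
#'   training count).
#' @export
glance.arrhythmia_model <- function(x, ...) {
  tibble::tibble(
    class_label = x$class_label,
    extractor = x$extractor %||% NA_character_,
    q = length(x$mean_vector),
    n_training = x$n_training
  )
}

#' Tidy an ROC curve
#'
#' @param x An `ecg_roc` from [roc_curve()].
#' @param ... Unused.
#' @return `tidy()`: the sweep points (`threshold`, `tpr`, `fpr`);
#'   `glance()`: one row with `auc`, `n_pos`, `n_neg`.
#' @export
tidy.ecg_roc <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("threshold", "tpr", "fpr")])
}

#' @rdname tidy.ecg_roc
#' @export
glance.ecg_roc <- function(x, ...) {
  tibble::tibble(auc = attr(x, "auc"), n_pos = attr(x, "n_pos"),
                 n_neg = attr(x, "n_neg"))
}

#' Tidy a benchmark run
#'
#' @param x A `wafe_benchmark` from [run_benchmark()].
#' @param ... Unused.
#' @return `tidy()`: the per-segment confirmation results;
#'   `glance()`: one row with the four rates, AUC and run parameters.
#' @export
tidy.wafe_benchmark <- function(x, ...) x$results

#' @rdname tidy.wafe_benchmark
#' @export
glance.wafe_benchmark <- function(x, ...) {
  dplyr::bind_cols(
    x$report,
    tibble::tibble(
      auc = auc(x$roc),
      background_class = x$params$background_class,
      extractor = x$params$extractor,
      snr_db = x$params$snr_db,
      seed = x$params$seed
    )
  )
}
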