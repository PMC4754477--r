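#' Build a rhythm-class model by feature averaging
#'
#' A class model is the element-wise arithmetic mean of the feature vectors
#' of (typically fifteen) segments of that class. The model for the
#' hypothesized rhythm (CHF) and a background model for an opposing rhythm
#' (NSR, AF or PEB) are the two references every tested segment is scored
#' against.
#'
#' @param features A feature tibble from [extract_features()] (rows of one
#'   class), or a list of `feature_vector`s.
#' @param class_label Rhythm label for the model; defaults to the single
#'   label present in `features`.
#' @return An object of class `arrhythmia_model` with fields
#'   `mean_vector`, `class_label`, `n_training`, `config`, `extractor`.
#' @examples
#' feats <- synth_ecg_dataset("CHF", n_per_class = 15, seed = 1) |>
#'   preprocess_segments() |>
#'   extract_features()
#' build_model(feats)
#' @export
build_model <- function(features, class_label = NULL) {
  if (is.data.frame(features)) {
    mat <- feature_matrix(features)
    cfg <- attr(features, "wavelet_config")
    extractor <- attr(features, "extractor")
    labels <- unique(features$label)
  } else {
    exts <- unique(vapply(features, function(f) f$extractor, character(1)))
    lens <- unique(vapply(features, function(f) length(f$values), integer(1)))
    if (length(exts) != 1L || length(lens) != 1L) {
      stop("incompatible feature vectors: mixed extractors (",
           paste(exts, collapse = ", "), ") or lengths (",
           paste(lens, collapse = ", "), ")", call. = FALSE)
    }
    mat <- do.call(rbind, lapply(features, feature_values))
    cfg <- features[[1]]$config
    extractor <- exts
    labels <- unique(vapply(features, function(f) f$label, character(1)))
  }
  if (nrow(mat) < 1L) stop("build_model: no feature vectors", call. = FALSE)
  if (is.null(class_label)) {
    if (length(labels) != 1L) {
      stop("build_model: features carry multiple labels (",
           paste(labels, collapse = ", "),
           "); pass class_label explicitly", call. = FALSE)
    }
    class_label <- labels
  }
  structure(
    list(mean_vector = colMeans(mat), class_label = class_label,
         n_training = nrow(mat), config = cfg, extractor = extractor),
    class = "arrhythmia_model"
  )
}

#' @export
print.arrhythmia_model <- function(x, ...) {
  cat(sprintf("<arrhythmia_model> class %s, %s features, Q = %d, averaged over %d segments\n",
              x$class_label, x$extractor %||% "?", length(x$mean_vector),
              x$n_training))
  invisible(x)
}

#' Save / load a class model as JSON
#'
#' @param model An `arrhythmia_model`.
#' @param path JSON file path.
#' @return `read_model()` returns the model; `write_model()` returns
#'   `path` invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "arrhythmia_model"))
  obj <- list(
    class_label = model$class_label, n_training = model$n_training,
    extractor = model$extractor,
    config = model$config[c("wavelet_name", "level", "n_frames",
                            "node_order", "boundary_mode")],
    mean_vector = model$mean_vector
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- wavelet_config(obj$config$wavelet_name, obj$config$level,
                        obj$config$n_frames, obj$config$node_order,
                        obj$config$boundary_mode)
  structure(
    list(mean_vector = as.numeric(obj$mean_vector),
         class_label = obj$class_label,
         n_training = as.integer(obj$n_training),
         config = cfg, extractor = obj$extractor),
    class = "arrhythmia_model"
  )
}

#' Percentage root-mean-square difference score
#'
#' `100 * sqrt(sum((y - m)^2) / sum(y^2))`: the normalized Euclidean
#' distance (in percent) between a tested feature vector and a class
#' model. Zero iff `y == m`; equals 100 when `m` is the zero vector or
#' `m = 2 y`.
#'
#' @param y Tested feature vector (`feature_vector` or numeric).
#' @param m Class model (`arrhythmia_model`, `feature_vector` or numeric).
#' @return Scalar percentage, `>= 0`.
#' @export
prds <- function(y, m) {
  yv <- feature_values(y)
  mv <- feature_values(m)
  stopifnot(length(yv) == length(mv))
  denom <- sum(yv^2)
  if (denom == 0) {
    stop("prds: tested vector is identically zero", call. = FALSE)
  }
  100 * sqrt(sum((yv - mv)^2) / denom)
}

#' Log distance-ratio score
#'
#' Natural log of the ratio of squared distances from the tested vector to
#' the hypothesized model versus the background model,
#' `log((||y - mx||^2 + eps) / (||y - mb||^2 + eps))` with
#' `eps = 1e-12` guarding against log(0). Negative values mean `y` lies
#' closer to the hypothesized model; the confirmation threshold is
#' `ldsr <= 0`. Antisymmetric under model swap.
#'
#' @param y Tested feature vector.
#' @param mx Hypothesized-class model.
#' @param mb Background-class model.
#' @param eps Guard added to each squared distance (default `1e-12`).
#' @return Scalar, in log-units.
#' @export
ldsr <- function(y, mx, mb, eps = 1e-12) {
  yv <- feature_values(y)
  dx <- sum((yv - feature_values(mx))^2)
  db <- sum((yv - feature_values(mb))^2)
  if (dx < eps && db < eps) {
    stop("ldsr: tested vector equals both models; ratio undefined",
         call. = FALSE)
  }
  log((dx + eps) / (db + eps))
}

#' Correlation-coefficient ratio
#'
#' Pearson correlation of the tested vector with the hypothesized model
#' divided by its correlation with the background model. The confirmation
#' threshold is `ccr > 1`. When the background correlation is exactly zero
#' the ratio is the signed-infinity sentinel (sign of the numerator).
#'
#' @inheritParams ldsr
#' @return Scalar ratio (dimensionless, possibly `+-Inf`).
#' @export
ccr <- function(y, mx, mb) {
  yv <- feature_values(y)
  xv <- feature_values(mx)
  bv <- feature_values(mb)
  for (v in list(yv, xv, bv)) {
    if (stats::sd(v) == 0) {
      stop("ccr: zero-variance vector; correlation undefined", call. = FALSE)
    }
  }
  cx <- stats::cor(yv, xv)
  cb <- stats::cor(yv, bv)
  if (cb == 0) {
    return(sign(cx) * Inf)
  }
  cx / cb
}

#' Three-function CHF confirmation for one feature vector
#'
#' Scores a tested feature vector against the hypothesized (`mx`) and
#' background (`mb`) models with all three confirmation functions and
#' combines them by the AND rule: the segment is confirmed as the
#' hypothesized class only if
#' `prds(y, mx) / prds(y, mb) < 1` AND `ldsr <= 0` AND `ccr > 1`
#' (boundary ties on the PRDS and CCR ratios do not confirm). A continuous
#' decision score `score = -ldsr` (higher = more hypothesized-class-like)
#' is attached for ROC sweeping.
#'
#' @inheritParams ldsr
#' @return A one-row tibble with columns `prds_x`, `prds_b`, `prds_ratio`,
#'   `ldsr`, `cc_x`, `cc_b`, `ccr`, `confirm_prds`, `confirm_ldsr`,
#'   `confirm_ccr`, `confirmed`, `score`.
#' @export
confirm_vector <- function(y, mx, mb) {
  yv <- feature_values(y)
  px <- prds(yv, mx)
  pb <- prds(yv, mb)
  pr <- if (pb == 0) Inf else px / pb
  ld <- ldsr(yv, mx, mb)
  cx <- stats::cor(yv, feature_values(mx))
  cb <- stats::cor(yv, feature_values(mb))
  cr <- if (is.na(cx) || is.na(cb)) NA_real_
        else if (cb == 0) sign(cx) * Inf
        else cx / cb
  c_prds <- pr < 1
  c_ldsr <- ld <= 0
  c_ccr <- !is.na(cr) && cr > 1
  tibble::tibble(
    prds_x = px, prds_b = pb, prds_ratio = pr, ldsr = ld,
    cc_x = cx, cc_b = cb, ccr = cr,
    confirm_prds = c_prds, confirm_ldsr = c_ldsr, confirm_ccr = c_ccr,
    confirmed = c_prds && c_ldsr && c_ccr,
    score = -ld
  )
}

#' Confirm every segment of a feature table
#'
#' Tibble-level verb applying [confirm_vector()] to each row of a feature
#' table (wide `node_*` columns) against a hypothesized and a background
#' model.
#'
#' @param features Feature tibble from [extract_features()].
#' @param model_x Hypothesized-class `arrhythmia_model`.
#' @param model_b Background-class `arrhythmia_model`.
#' @return `features`' identifier columns (`source_id`, `label`) joined
#'   with the per-row confirmation scores and decisions.
#' @examples
#' data <- synth_ecg_dataset(c("NSR", "CHF"), n_per_class = 4, seed = 1) |>
#'   preprocess_segments()
#' feats <- extract_features(data)
#' mx <- build_model(dplyr::filter(feats, label == "CHF"))
#' mb <- build_model(dplyr::filter(feats, label == "NSR"))
#' confirm_segments(feats, mx, mb)
#' @export
confirm_segments <- function(features, model_x, model_b) {
  mat <- feature_matrix(features)
  rows <- lapply(seq_len(nrow(mat)), function(i) {
    confirm_vector(mat[i, ], model_x, model_b)
  })
  dplyr::bind_cols(
    features[, intersect(c("source_id", "label"), names(features))],
    dplyr::bind_rows(rows)
  )
}
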