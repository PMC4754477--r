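#' Frame boundaries for subsignal framing
#'
#' Each full-length terminal subsignal is cut into `Z` equal,
#' non-overlapping frames; remainder samples beyond `Z * floor(n/Z)` are
#' dropped.
#' @keywords internal
#' @noRd
frame_index_set <- function(n, z, n_frames) {
  len <- n %/% n_frames
  if (len < 1L) {
    stop("cannot cut ", n, " samples into ", n_frames, " frames",
         call. = FALSE)
  }
  ((z - 1L) * len + 1L):(z * len)
}

#' Per-node percentage energy of one frame
#'
#' For frame `z` of the framed terminal subsignals, returns the length-Q
#' vector whose entry `q` is 100 times the energy of node `q`'s frame
#' divided by the total energy of that frame across all nodes. Entries are
#' nonnegative and sum to 100.
#'
#' @param subsignals A `wpt_subsignals` object from [wpt_decompose()].
#' @param frame_index Frame number `z` in `1..Z` (Z from the config used at
#'   decomposition, overridable via `n_frames`).
#' @param n_frames Number of frames; defaults to the decomposition
#'   config's `n_frames`.
#' @return Numeric vector of length Q summing to 100.
#' @export
percentage_energy <- function(subsignals, frame_index,
                              n_frames = subsignals$config$n_frames) {
  stopifnot(inherits(subsignals, "wpt_subsignals"))
  z <- as.integer(frame_index)
  if (z < 1L || z > n_frames) {
    stop("frame_index must be in 1..", n_frames, call. = FALSE)
  }
  idx <- frame_index_set(subsignals$n, z, n_frames)
  e <- colSums(subsignals$subsignals[idx, , drop = FALSE]^2)
  tot <- sum(e)
  if (tot == 0) {
    stop("degenerate frame: zero energy across all nodes in frame ", z,
         call. = FALSE)
  }
  100 * e / tot
}

new_feature_vector <- function(values, extractor, config, source_id = "",
                               label = "unknown") {
  structure(
    list(values = as.numeric(values), extractor = extractor,
         config = config, source_id = source_id, label = label),
    class = "feature_vector"
  )
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %s, Q = %d (%s level %d, Z = %d)%s\n",
              x$extractor, length(x$values), x$config$wavelet_name,
              x$config$level, x$config$n_frames,
              if (nzchar(x$source_id)) paste0(", source ", x$source_id) else ""))
  print(utils::head(round(x$values, 4), 8))
  invisible(x)
}

#' Feature values as a plain numeric vector
#' @param x A `feature_vector`, `arrhythmia_model`, or numeric vector.
#' @return Numeric vector of length Q.
#' @export
feature_values <- function(x) {
  if (inherits(x, "feature_vector")) x$values
  else if (inherits(x, "arrhythmia_model")) x$mean_vector
  else as.numeric(x)
}

#' Average-framing percentage-energy features (WAFE)
#'
#' The package's central extractor. The segment is decomposed into the
#' `Q = 2^level` terminal wavelet-packet subsignals; each subsignal is cut
#' into `Z` equal frames; within every frame the per-node percentage
#' energies (summing to 100) are computed; and the `Z` percentage vectors
#' are averaged element-wise. The result is a length-Q vector that is
#' nonnegative, sums to 100, and is invariant to amplitude scaling of the
#' input.
#'
#' @param seg A preprocessed [ecg_segment] (or numeric vector).
#' @param cfg A [wavelet_config()].
#' @return A `feature_vector` with `extractor = "WAFE"`.
#' @examples
#' seg <- preprocess(synth_ecg_segment(rhythm_preset("NSR"), seed = 3))
#' fv <- extract_afe(seg)
#' sum(fv$values)      # 100
#' @export
extract_afe <- function(seg, cfg = wavelet_config()) {
  wp <- wpt_decompose(seg, cfg)
  z_all <- vapply(seq_len(cfg$n_frames), function(z) {
    percentage_energy(wp, z)
  }, numeric(n_terminal_nodes(cfg)))
  new_feature_vector(rowMeans(z_all), "WAFE", cfg,
                     source_id = if (inherits(seg, "ecg_segment")) seg$source_id else "",
                     label = if (inherits(seg, "ecg_segment")) seg$label else "unknown")
}

#' Entropy of one coefficient/sample block
#'
#' The three wavelet-toolbox entropy definitions used by the comparison
#' extractors, applied to a numeric block `c`:
#' * `shannon`: \eqn{-\sum_i p_i \log p_i} with \eqn{p_i = c_i^2 / \sum c^2}
#'   and \eqn{0 \log 0 := 0};
#' * `log_energy`: \eqn{\sum_i \log(c_i^2)} with a floor of `1e-12` on
#'   \eqn{c_i^2};
#' * `sure`: \eqn{\sum_i \min(c_i^2, \tau^2)} with
#'   \eqn{\tau = \sqrt{2 \log(n \log_2 n)}}, `n = length(c)`.
#'
#' @param c_block Numeric block.
#' @param kind `"shannon"`, `"log_energy"` or `"sure"`.
#' @return Scalar entropy value.
#' @export
node_entropy <- function(c_block, kind = c("shannon", "log_energy", "sure")) {
  kind <- match.arg(kind)
  c2 <- c_block^2
  switch(kind,
    shannon = {
      tot <- sum(c2)
      if (tot == 0) return(0)
      p <- c2 / tot
      p <- p[p > 0]
      -sum(p * log(p))
    },
    log_energy = sum(log(pmax(c2, 1e-12))),
    sure = {
      n <- length(c_block)
      tau2 <- 2 * log(n * log2(max(n, 2)))
      sum(pmin(c2, tau2))
    }
  )
}

#' Wavelet-packet entropy features (comparison extractors)
#'
#' WPSE (Shannon), WPLE (log-energy) and WPSUE (SURE) comparison
#' extractors: per terminal node, the chosen entropy is computed on each of
#' the `Z` frames of the node's reconstructed subsignal and frame-averaged,
#' exactly like the WAFE framing.
#'
#' @inheritParams extract_afe
#' @param kind `"shannon"`, `"log_energy"` or `"sure"`.
#' @return A `feature_vector` with extractor `"WPSE"`, `"WPLE"` or
#'   `"WPSUE"`.
#' @export
extract_entropy_features <- function(seg, cfg = wavelet_config(),
                                     kind = c("shannon", "log_energy", "sure")) {
  kind <- match.arg(kind)
  wp <- wpt_decompose(seg, cfg)
  q <- n_terminal_nodes(cfg)
  vals <- matrix(0, q, cfg$n_frames)
  for (z in seq_len(cfg$n_frames)) {
    idx <- frame_index_set(wp$n, z, cfg$n_frames)
    fr <- wp$subsignals[idx, , drop = FALSE]
    vals[, z] <- apply(fr, 2L, node_entropy, kind = kind)
  }
  lab <- c(shannon = "WPSE", log_energy = "WPLE", sure = "WPSUE")[[kind]]
  new_feature_vector(rowMeans(vals), lab, cfg,
                     source_id = if (inherits(seg, "ecg_segment")) seg$source_id else "",
                     label = if (inherits(seg, "ecg_segment")) seg$label else "unknown")
}

# Hann-window Welch power spectral density (one-sided, density scaling).
welch_psd <- function(x, fs, nperseg = 256L, overlap = 0.5) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1L, floor(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  scale <- fs * sum(w^2)
  nf <- nperseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)] * w
    p <- abs(stats::fft(seg))^2 / scale
    p <- p[seq_len(nf)]
    p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]
    acc <- acc + p
  }
  list(freq = (seq_len(nf) - 1L) * fs / nperseg, psd = acc / length(starts))
}

#' Mean Welch-PSD features (comparison extractor WPAP)
#'
#' Per terminal subsignal, the mean of its Welch power-spectral-density
#' estimate (segment length 256, 50% overlap, Hann window), computed on
#' each of the `Z` frames and frame-averaged like WAFE. Values scale with
#' the square of the input amplitude.
#'
#' @inheritParams extract_afe
#' @return A `feature_vector` with `extractor = "WPAP"`.
#' @export
extract_wpap <- function(seg, cfg = wavelet_config()) {
  fs <- if (inherits(seg, "ecg_segment")) seg$fs else 250
  samples <- if (inherits(seg, "ecg_segment")) seg$samples else as.numeric(seg)
  if (all(samples == 0)) {
    stop("degenerate signal: all-zero input to extract_wpap", call. = FALSE)
  }
  wp <- wpt_decompose(samples, cfg)
  q <- n_terminal_nodes(cfg)
  vals <- matrix(0, q, cfg$n_frames)
  for (z in seq_len(cfg$n_frames)) {
    idx <- frame_index_set(wp$n, z, cfg$n_frames)
    fr <- wp$subsignals[idx, , drop = FALSE]
    vals[, z] <- apply(fr, 2L, function(u) mean(welch_psd(u, fs)$psd))
  }
  new_feature_vector(rowMeans(vals), "WPAP", cfg,
                     source_id = if (inherits(seg, "ecg_segment")) seg$source_id else "",
                     label = if (inherits(seg, "ecg_segment")) seg$label else "unknown")
}

#' Descriptive statistics of a feature vector
#'
#' Population statistics (divisor Q, not Q-1) over the Q entries: standard
#' deviation, median, maximum and variance.
#'
#' @param fv A `feature_vector` or numeric vector.
#' @return A one-row tibble with columns `std`, `median`, `max`, `var`.
#' @export
feature_statistics <- function(fv) {
  v <- feature_values(fv)
  va <- mean((v - mean(v))^2)
  tibble::tibble(std = sqrt(va), median = stats::median(v),
                 max = max(v), var = va)
}

#' Extract features for every segment of a dataset
#'
#' Tibble-level verb: maps the chosen extractor over a `segment`
#' list-column and returns one row per segment with the Q feature values in
#' wide columns `node_01 .. node_Q`. The wavelet config and extractor name
#' travel as attributes (`"wavelet_config"`, `"extractor"`).
#'
#' @param data A tibble with a `segment` list-column of preprocessed
#'   [ecg_segment]s (e.g. from [synth_ecg_dataset()] piped through
#'   [preprocess_segments()]), or a bare list of segments.
#' @param extractor `"wafe"`, `"wpse"`, `"wple"`, `"wpsue"` or `"wpap"`.
#' @param cfg A [wavelet_config()].
#' @return A tibble with columns `source_id`, `label` and `node_*`.
#' @examples
#' synth_ecg_dataset(c("NSR", "CHF"), n_per_class = 2, seed = 1) |>
#'   preprocess_segments() |>
#'   extract_features()
#' @export
extract_features <- function(data, extractor = c("wafe", "wpse", "wple",
                                                 "wpsue", "wpap"),
                             cfg = wavelet_config()) {
  extractor <- match.arg(extractor)
  segs <- if (is.data.frame(data)) data$segment else data
  if (is.null(segs)) {
    stop("extract_features: 'data' has no 'segment' list-column",
         call. = FALSE)
  }
  fun <- switch(extractor,
    wafe = function(s) extract_afe(s, cfg),
    wpse = function(s) extract_entropy_features(s, cfg, "shannon"),
    wple = function(s) extract_entropy_features(s, cfg, "log_energy"),
    wpsue = function(s) extract_entropy_features(s, cfg, "sure"),
    wpap = function(s) extract_wpap(s, cfg)
  )
  fvs <- lapply(segs, fun)
  q <- n_terminal_nodes(cfg)
  mat <- do.call(rbind, lapply(fvs, feature_values))
  colnames(mat) <- sprintf("node_%02d", seq_len(q))
  out <- tibble::tibble(
    source_id = vapply(fvs, function(f) f$source_id, character(1)),
    label = vapply(fvs, function(f) f$label, character(1))
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(mat))
  attr(out, "extractor") <- fvs[[1]]$extractor
  attr(out, "wavelet_config") <- cfg
  out
}

#' Preprocess every segment of a dataset
#'
#' Tibble-level companion of [preprocess()]: conditions each segment in the
#' `segment` list-column.
#'
#' @param data A tibble with a `segment` list-column.
#' @param cfg A [preprocess_config()].
#' @return `data` with the `segment` column replaced by conditioned
#'   segments.
#' @export
preprocess_segments <- function(data, cfg = preprocess_config()) {
  stopifnot(is.data.frame(data), !is.null(data$segment))
  data$segment <- lapply(data$segment, preprocess, cfg = cfg)
  data
}

# Feature-matrix helper: rows of node_* columns as a plain matrix.
feature_matrix <- function(features) {
  cols <- grep("^node_\\d+$", names(features), value = TRUE)
  if (length(cols) == 0L) {
    stop("no 'node_*' feature columns found", call. = FALSE)
  }
  as.matrix(features[, cols])
}
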