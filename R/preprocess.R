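#' Preprocessing configuration
#'
#' Parameters of the conditioning step every segment passes through before
#' feature extraction. The confirmation scores compare feature vectors
#' across recordings, so all segments must share a sampling rate, be free
#' of baseline wander and out-of-band noise, and sit at a common amplitude
#' level; this config fixes how that is achieved.
#'
#' @param target_fs Common sampling rate in Hz (default 250, the rate of
#'   typical ambulatory CHF recordings).
#' @param hp_cutoff High-pass corner in Hz removing baseline wander
#'   (default 0.5, the standard clinical-monitor corner).
#' @param lp_cutoff Low-pass corner in Hz (default 40, the upper edge of
#'   the ambulatory recording bandwidth).
#' @param filter_order Butterworth order for each band edge (default 4).
#' @param normalize If `TRUE` (default), divide by the maximum absolute
#'   amplitude so the peak is exactly 1.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_fs = 250, hp_cutoff = 0.5,
                              lp_cutoff = 40, filter_order = 4L,
                              normalize = TRUE) {
  stopifnot(filter_order >= 1L)
  if (!(0 < hp_cutoff && hp_cutoff < lp_cutoff && lp_cutoff < target_fs / 2)) {
    stop("preprocess_config: need 0 < hp_cutoff < lp_cutoff < target_fs/2",
         call. = FALSE)
  }
  structure(
    list(target_fs = target_fs, hp_cutoff = hp_cutoff,
         lp_cutoff = lp_cutoff, filter_order = as.integer(filter_order),
         normalize = isTRUE(normalize)),
    class = "preprocess_config"
  )
}

#' @export
print.preprocess_config <- function(x, ...) {
  cat(sprintf("<preprocess_config> fs -> %g Hz, band-pass [%g, %g] Hz (order %d), normalize = %s\n",
              x$target_fs, x$hp_cutoff, x$lp_cutoff, x$filter_order,
              x$normalize))
  invisible(x)
}

# Zero-phase Butterworth band-pass, realized spectrally: the squared
# magnitude response of an order-`order` Butterworth high-pass at
# `hp`Hz cascaded with a low-pass at `lp` Hz is applied circularly via the
# FFT. This is exactly the response a forward-backward (filtfilt) pass has
# in steady state, but with no start-up transients: the operator is
# diagonal in frequency, so repeated application only touches the
# transition bands (which is what makes preprocessing idempotent in
# practice), and the zero bin is nulled exactly (zero mean out).
zero_phase_bandpass <- function(x, fs, hp, lp, order) {
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  h2 <- 1 / (1 + (hp / pmax(f, .Machine$double.eps))^(2 * order)) /
    (1 + (f / lp)^(2 * order))
  Re(stats::fft(stats::fft(x) * h2, inverse = TRUE)) / n
}

#' Condition a segment for feature extraction
#'
#' Resamples to the common rate, removes baseline wander and out-of-band
#' noise with a zero-phase Butterworth band-pass, and peak-normalizes.
#' After this step the segment satisfies the comparability conditions the
#' confirmation scores assume: common `fs`, near-zero mean, peak amplitude
#' exactly 1.
#'
#' @param seg An [ecg_segment].
#' @param cfg A [preprocess_config()].
#' @return The conditioned [ecg_segment].
#' @examples
#' raw <- synth_ecg_segment(rhythm_preset("CHF"), seed = 2)
#' seg <- preprocess(raw)
#' max(abs(seg$samples))   # exactly 1
#' @export
preprocess <- function(seg, cfg = preprocess_config()) {
  stopifnot(inherits(seg, "ecg_segment"))
  if (seg$fs < 2 * cfg$lp_cutoff) {
    stop("preprocess: fs = ", seg$fs, " Hz cannot represent the ",
         cfg$lp_cutoff, " Hz band edge", call. = FALSE)
  }
  x <- seg$samples
  fs <- seg$fs
  if (abs(fs - cfg$target_fs) > 1e-9) {
    frac <- rational_approx(cfg$target_fs / fs)
    x <- signal::resample(x, frac[1], frac[2])
    fs <- cfg$target_fs
  }
  in_peak <- max(abs(x))
  x <- zero_phase_bandpass(x, fs, cfg$hp_cutoff, cfg$lp_cutoff,
                           cfg$filter_order)
  if (cfg$normalize) {
    peak <- max(abs(x))
    # a pure-DC/out-of-band input leaves only FFT round-off behind
    if (peak == 0 || !is.finite(peak) || peak < 1e-8 * in_peak) {
      stop("preprocess: degenerate signal (all zero after filtering), ",
           "cannot normalize", call. = FALSE)
    }
    x <- x / peak
  }
  ecg_segment(x, fs = fs, lead = seg$lead, label = seg$label,
              source_id = seg$source_id)
}

rational_approx <- function(r, max_den = 1000L) {
  best <- c(round(r), 1L)
  best_err <- abs(r - best[1])
  for (q in seq_len(max_den)) {
    p <- round(r * q)
    err <- abs(r - p / q)
    if (err < best_err - 1e-15) {
      best <- c(p, q)
      best_err <- err
    }
    if (best_err < 1e-12) break
  }
  as.integer(best)
}

#' Add white Gaussian noise at an exact signal-to-noise ratio
#'
#' Adds zero-mean Gaussian noise whose variance is set from the clean
#' segment's mean-square power so that
#' `10*log10(P_signal / P_noise) = snr_db`. Noise is injected into the raw
#' segment (before preprocessing) when emulating noisy acquisition.
#' Deterministic for a fixed `seed`; `snr_db = Inf` disables the noise and
#' returns the input unchanged.
#'
#' @param seg An [ecg_segment] with nonzero power.
#' @param snr_db Target SNR in decibels (`Inf` = no noise).
#' @param seed Integer seed for the noise realization.
#' @return The noisy [ecg_segment].
#' @examples
#' seg <- synth_ecg_segment(rhythm_preset("NSR"), seed = 1)
#' noisy <- add_awgn(seg, snr_db = 5, seed = 99)
#' @export
add_awgn <- function(seg, snr_db, seed = 1L) {
  stopifnot(inherits(seg, "ecg_segment"))
  if (is.infinite(snr_db) && snr_db > 0) {
    return(seg)
  }
  p_sig <- mean(seg$samples^2)
  if (p_sig == 0) {
    stop("add_awgn: degenerate segment (zero power)", call. = FALSE)
  }
  p_noise <- p_sig / 10^(snr_db / 10)
  noise <- with_local_seed(seed, stats::rnorm(length(seg$samples)))
  # rescale the realization to the exact target power, so the injected SNR
  # is exact rather than exact-in-expectation
  noise <- noise * sqrt(p_noise / mean(noise^2))
  ecg_segment(seg$samples + noise, fs = seg$fs, lead = seg$lead,
              label = seg$label, source_id = seg$source_id)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
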