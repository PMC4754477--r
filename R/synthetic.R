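#' Rhythm-class presets for the synthetic generator
#'
#' Parameter bundles from which labelled single-lead segments are
#' generated. Each beat is a sum of Gaussian bumps (P, Q, R, S, T) placed
#' at physiological offsets inside one RR interval; RR intervals are drawn
#' lognormal. The presets are artifact choices that give the four classes
#' distinct rhythm statistics and morphology (hence distinct subband
#' energy profiles); they are not claims about clinical waveform shape:
#'
#' * `NSR` — 72 bpm, tight RR (cv 0.03), full PQRST.
#' * `CHF` — 88 bpm, irregular RR (cv 0.12), attenuated R (0.55) and P
#'   (0.06), QRS broadened 1.9x, flattened T.
#' * `AF` — 95 bpm, grossly irregular RR (cv 0.25), no P wave, 8-12 Hz
#'   fibrillatory baseline oscillation (amplitude 0.12).
#' * `PEB` — NSR base with probability 0.15 per beat of a premature,
#'   wide (2.5x), tall (1.4), P-less ectopic beat.
#'
#' @param class_label `"NSR"`, `"CHF"`, `"AF"` or `"PEB"`.
#' @param ... Named overrides of preset fields (`mean_hr`, `rr_jitter_cv`,
#'   `wave_amplitudes`, `wave_widths`, `p_wave_present`,
#'   `fibrillatory_amp`, `ectopic_rate`, `noise_floor_snr_db`).
#' @return An object of class `rhythm_preset`.
#' @examples
#' rhythm_preset("CHF")
#' rhythm_preset("NSR", mean_hr = 60)
#' @export
rhythm_preset <- function(class_label = c("NSR", "CHF", "AF", "PEB"), ...) {
  class_label <- match.arg(class_label)
  base <- list(
    class_label = class_label,
    mean_hr = 72, rr_jitter_cv = 0.03,
    wave_amplitudes = c(P = 0.15, Q = -0.10, R = 1.00, S = -0.20, T = 0.30),
    wave_widths = c(P = 0.025, Q = 0.010, R = 0.013, S = 0.012, T = 0.055),
    wave_offsets = c(P = -0.17, Q = -0.032, R = 0.000, S = 0.030, T = 0.28),
    p_wave_present = TRUE,
    fibrillatory_amp = 0,
    ectopic_rate = 0,
    noise_floor_snr_db = 30
  )
  tweak <- switch(class_label,
    NSR = list(),
    CHF = list(
      mean_hr = 88, rr_jitter_cv = 0.12,
      wave_amplitudes = c(P = 0.06, Q = -0.06, R = 0.55, S = -0.12,
                          T = 0.15),
      wave_widths = c(P = 0.030, Q = 0.019, R = 0.025, S = 0.023, T = 0.065)
    ),
    AF = list(mean_hr = 95, rr_jitter_cv = 0.25, p_wave_present = FALSE,
              fibrillatory_amp = 0.12),
    PEB = list(rr_jitter_cv = 0.05, ectopic_rate = 0.15)
  )
  preset <- utils::modifyList(base, tweak)
  preset <- utils::modifyList(preset, list(...))
  stopifnot(preset$mean_hr >= 30, preset$mean_hr <= 220,
            preset$rr_jitter_cv >= 0,
            all(is.finite(preset$wave_amplitudes)))
  structure(preset, class = "rhythm_preset")
}

#' @export
print.rhythm_preset <- function(x, ...) {
  cat(sprintf("<rhythm_preset> %s: %g bpm, RR cv %g, P wave %s%s%s\n",
              x$class_label, x$mean_hr, x$rr_jitter_cv,
              if (x$p_wave_present) "present" else "absent",
              if (x$fibrillatory_amp > 0)
                sprintf(", fibrillatory amp %g", x$fibrillatory_amp) else "",
              if (x$ectopic_rate > 0)
                sprintf(", ectopic rate %g", x$ectopic_rate) else ""))
  invisible(x)
}

#' Synthesize one beat
#'
#' One RR interval's waveform: a sum of Gaussian bumps for P (if present),
#' Q, R, S and T at fixed offsets (seconds) around the R wave, which sits
#' 35% into the interval. Length is `round(rr * fs)` samples.
#'
#' @param preset A [rhythm_preset()].
#' @param rr RR interval in seconds.
#' @param fs Sampling rate in Hz.
#' @param ectopic If `TRUE`, render the beat as a premature ectopic one:
#'   no P, amplitude 1.4x, width 2.5x.
#' @return Numeric waveform of length `round(rr * fs)`.
#' @export
synth_beat <- function(preset, rr, fs, ectopic = FALSE) {
  n <- round(rr * fs)
  t <- (seq_len(n) - 1) / fs
  t_r <- 0.35 * rr
  amps <- preset$wave_amplitudes
  wids <- preset$wave_widths
  offs <- preset$wave_offsets
  waves <- names(amps)
  if (!preset$p_wave_present || ectopic) waves <- setdiff(waves, "P")
  if (ectopic) {
    amps <- amps * 1.4
    wids <- wids * 2.5
  }
  y <- numeric(n)
  for (w in waves) {
    y <- y + amps[[w]] * exp(-(t - t_r - offs[[w]])^2 / (2 * wids[[w]]^2))
  }
  y
}

#' Synthesize a labelled ECG segment
#'
#' Concatenates beats with lognormal RR intervals (mean `60/mean_hr`,
#' coefficient of variation `rr_jitter_cv`), applies the class-specific
#' structure (fibrillatory baseline for AF, random ectopic beats for PEB),
#' and adds measurement noise at `noise_floor_snr_db`. Deterministic per
#' `seed`.
#'
#' @param preset A [rhythm_preset()].
#' @param duration_s Segment duration in seconds (default 10).
#' @param fs Sampling rate in Hz (default 250).
#' @param seed Integer seed.
#' @return An [ecg_segment] labelled with the preset's class.
#' @examples
#' seg <- synth_ecg_segment(rhythm_preset("AF"), seed = 4)
#' seg
#' @export
synth_ecg_segment <- function(preset, duration_s = 10, fs = 250, seed = 1L) {
  stopifnot(inherits(preset, "rhythm_preset"))
  n_target <- round(duration_s * fs)
  samples <- with_local_seed(seed, {
    m <- 60 / preset$mean_hr
    cv <- preset$rr_jitter_cv
    sdlog <- sqrt(log(1 + cv^2))
    meanlog <- log(m) - sdlog^2 / 2
    y <- numeric(0)
    while (length(y) < n_target + fs) {
      rr <- if (cv > 0) stats::rlnorm(1, meanlog, sdlog) else m
      ect <- preset$ectopic_rate > 0 &&
        stats::runif(1) < preset$ectopic_rate
      if (ect) rr <- 0.7 * rr
      y <- c(y, synth_beat(preset, rr, fs, ectopic = ect))
    }
    y <- y[seq_len(n_target)]
    if (preset$fibrillatory_amp > 0) {
      f_fib <- stats::runif(1, 8, 12)
      phi <- stats::runif(1, 0, 2 * pi)
      tt <- (seq_len(n_target) - 1) / fs
      y <- y + preset$fibrillatory_amp * sin(2 * pi * f_fib * tt + phi)
    }
    if (is.finite(preset$noise_floor_snr_db)) {
      p_sig <- mean(y^2)
      sd_n <- sqrt(p_sig / 10^(preset$noise_floor_snr_db / 10))
      y <- y + stats::rnorm(n_target, sd = sd_n)
    }
    y
  })
  ecg_segment(samples, fs = fs, lead = "synthetic",
              label = preset$class_label,
              source_id = sprintf("synth-%s-%d", preset$class_label,
                                  as.integer(seed)))
}

#' Synthesize a labelled dataset of segments
#'
#' Generates `n_per_class` segments per class with per-segment seeds
#' derived from `seed`; ordering (all segments of the first class, then
#' the second, ...) and content are reproducible.
#'
#' @param classes Character vector of class labels, or a list of
#'   [rhythm_preset()]s.
#' @param n_per_class Segments per class.
#' @param duration_s,fs Segment duration and sampling rate.
#' @param seed Integer master seed.
#' @return A tibble with columns `source_id`, `label` and list-column
#'   `segment` (raw, unpreprocessed segments).
#' @examples
#' synth_ecg_dataset(c("NSR", "CHF"), n_per_class = 3, seed = 1)
#' @export
synth_ecg_dataset <- function(classes = c("NSR", "CHF"), n_per_class = 10L,
                              duration_s = 10, fs = 250, seed = 1L) {
  presets <- if (is.list(classes) && inherits(classes[[1]], "rhythm_preset")) {
    classes
  } else {
    lapply(classes, rhythm_preset)
  }
  segs <- list()
  for (i in seq_along(presets)) {
    seeds <- derive_seeds(seed, n_per_class, salt = i)
    segs <- c(segs, lapply(seeds, function(s) {
      synth_ecg_segment(presets[[i]], duration_s = duration_s, fs = fs,
                        seed = s)
    }))
  }
  tibble::tibble(
    source_id = vapply(segs, function(s) s$source_id, character(1)),
    label = vapply(segs, function(s) s$label, character(1)),
    segment = segs
  )
}
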