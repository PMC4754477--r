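test_that("a lone R bump peaks at the R offset with unit amplitude", {
  preset <- rhythm_preset("NSR",
                          wave_amplitudes = c(P = 0, Q = 0, R = 1, S = 0,
                                              T = 0))
  beat <- synth_beat(preset, rr = 0.8, fs = 250)
  expect_length(beat, 200)
  expect_equal(max(beat), 1, tolerance = 1e-6)
  expect_equal(which.max(beat), round(0.35 * 0.8 * 250) + 1, tolerance = 1)
})

test_that("suppressing the P wave only changes the P window", {
  p_on <- rhythm_preset("NSR")
  p_off <- rhythm_preset("NSR", p_wave_present = FALSE)
  b_on <- synth_beat(p_on, rr = 0.8, fs = 250)
  b_off <- synth_beat(p_off, rr = 0.8, fs = 250)
  d <- abs(b_on - b_off)
  t <- (seq_along(d) - 1) / 250
  t_p <- 0.35 * 0.8 - 0.17
  inside <- abs(t - t_p) < 0.12
  expect_gt(max(d[inside]), 0.1)
  expect_lt(max(d[!inside]), 1e-5)   # Gaussian tail beyond +-~5 sigma
})

test_that("beat energy matches the closed-form Gaussian integral", {
  preset <- rhythm_preset("NSR")
  fs <- 2000                              # fine grid: discretization << 2%
  beat <- synth_beat(preset, rr = 1.0, fs = fs)
  # analytic: int a^2 exp(-(t-mu)^2/s^2) dt = a^2 s sqrt(pi); cross terms
  # negligible for well-separated waves except Q/R/S, so integrate the
  # pairwise sum exactly
  a <- preset$wave_amplitudes
  s <- preset$wave_widths
  mu <- 0.35 + preset$wave_offsets
  waves <- names(a)
  analytic <- 0
  for (i in waves) {
    for (j in waves) {
      analytic <- analytic + a[[i]] * a[[j]] *
        sqrt(2 * pi * s[[i]]^2 * s[[j]]^2 / (s[[i]]^2 + s[[j]]^2)) *
        exp(-(mu[[i]] - mu[[j]])^2 / (2 * (s[[i]]^2 + s[[j]]^2)))
    }
  }
  expect_equal(sum(beat^2) / fs, analytic, tolerance = 0.02)
})

test_that("NSR segments hold about twelve beats in ten seconds", {
  for (s in 1:10) {
    seg <- synth_ecg_segment(rhythm_preset("NSR"), seed = 100 + s)
    expect_length(seg$samples, 2500)
    n_peaks <- count_r_peaks(seg$samples, seg$fs)
    expect_gte(n_peaks, 10)
    expect_lte(n_peaks, 14)
  }
})

test_that("AF rhythm is far more irregular than NSR", {
  rr_spread <- function(preset, seeds) {
    vapply(seeds, function(s) {
      seg <- synth_ecg_segment(preset, seed = s)
      x <- seg$samples
      thr <- 0.5 * max(x)
      idx <- which(x > thr &
                     x >= c(-Inf, x[-length(x)]) & x >= c(x[-1], -Inf))
      idx <- idx[c(TRUE, diff(idx) > 0.3 * seg$fs)]
      stats::var(diff(idx) / seg$fs)
    }, numeric(1))
  }
  seeds <- 200 + 1:20
  v_af <- rr_spread(rhythm_preset("AF"), seeds)
  v_nsr <- rr_spread(rhythm_preset("NSR"), seeds)
  expect_gte(mean(v_af, na.rm = TRUE), 3 * mean(v_nsr, na.rm = TRUE))
})

test_that("segments are deterministic per seed and labelled by preset", {
  a <- synth_ecg_segment(rhythm_preset("PEB"), seed = 7)
  b <- synth_ecg_segment(rhythm_preset("PEB"), seed = 7)
  c <- synth_ecg_segment(rhythm_preset("PEB"), seed = 8)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples, c$samples))
  expect_identical(a$label, "PEB")
  expect_identical(synth_ecg_segment(rhythm_preset("AF"), seed = 1)$label,
                   "AF")
})

test_that("datasets have the requested size, ordering, and distinct segments", {
  data <- synth_ecg_dataset(c("NSR", "CHF"), n_per_class = 8, seed = 9)
  expect_identical(nrow(data), 16L)
  expect_identical(sum(data$label == "NSR"), 8L)
  expect_identical(data$label, rep(c("NSR", "CHF"), each = 8))
  sigs <- vapply(data$segment, function(s) paste(head(s$samples, 50),
                                                 collapse = ","),
                 character(1))
  expect_identical(anyDuplicated(sigs), 0L)
  # regenerating reproduces the collection exactly
  again <- synth_ecg_dataset(c("NSR", "CHF"), n_per_class = 8, seed = 9)
  expect_identical(data$segment[[3]]$samples, again$segment[[3]]$samples)
})

test_that("all presets survive preprocessing and satisfy segment invariants", {
  for (cl in c("NSR", "CHF", "AF", "PEB")) {
    seg <- synth_ecg_segment(rhythm_preset(cl), seed = 11)
    expect_true(all(is.finite(seg$samples)))
    pp <- preprocess(seg)
    expect_equal(max(abs(pp$samples)), 1, tolerance = 1e-9)
    expect_lt(abs(mean(pp$samples)), 0.05)
  }
})

test_that("NSR and CHF feature clouds are well separated", {
  data <- synth_ecg_dataset(c("NSR", "CHF"), n_per_class = 20, seed = 12) |>
    preprocess_segments()
  feats <- extract_features(data)
  mat <- wafecg:::feature_matrix(feats)
  lab <- feats$label
  pairdist <- function(a, b) {
    d <- numeric(0)
    for (i in seq_len(nrow(a))) {
      for (j in seq_len(nrow(b))) {
        if (!identical(a, b) || j > i) {
          d <- c(d, sqrt(sum((a[i, ] - b[j, ])^2)))
        }
      }
    }
    d
  }
  within_d <- c(pairdist(mat[lab == "NSR", ], mat[lab == "NSR", ]),
                pairdist(mat[lab == "CHF", ], mat[lab == "CHF", ]))
  between_d <- pairdist(mat[lab == "NSR", ], mat[lab == "CHF", ])
  expect_gt(mean(between_d), 2 * mean(within_d))

  # linear separability along the first principal direction
  pc1 <- stats::prcomp(mat, center = TRUE, scale. = FALSE)$x[, 1]
  best <- max(vapply(pc1, function(thr) {
    max(mean((pc1 >= thr) == (lab == "CHF")),
        mean((pc1 < thr) == (lab == "CHF")))
  }, numeric(1)))
  expect_gte(best, 0.9)
})
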