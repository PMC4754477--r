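test_that("per-frame percentage energies are a partition of 100", {
  set.seed(50)
  wp <- wpt_decompose(rnorm(2496), wavelet_config())
  for (z in 1:5) {
    pe <- percentage_energy(wp, z)
    expect_length(pe, 32)
    expect_true(all(pe >= 0))
    expect_equal(sum(pe), 100, tolerance = 1e-6)
  }
  expect_error(percentage_energy(wp, 6), "frame_index")
  # scale invariance: ratio of quadratic forms
  wp2 <- wpt_decompose(2 * wp$subsignals %*% rep(1, 32), wavelet_config())
  expect_equal(percentage_energy(wp2, 3), percentage_energy(wp, 3),
               tolerance = 1e-9)
})

test_that("WAFE vectors are nonnegative, sum to 100, and ignore amplitude", {
  set.seed(51)
  cfg <- wavelet_config()
  for (i in 1:25) {
    x <- if (i %% 2) rnorm(512) else {
      preprocess(synth_ecg_segment(rhythm_preset("CHF"), seed = i))$samples
    }
    fv <- extract_afe(x, cfg)
    expect_length(fv$values, 32)
    expect_true(all(fv$values >= 0))
    expect_equal(sum(fv$values), 100, tolerance = 1e-6)
    for (s in c(1e-3, 1e3)) {
      expect_lt(max(abs(extract_afe(s * x, cfg)$values - fv$values)), 1e-9)
    }
  }
})

test_that("WAFE with Z=1 equals the coefficient-energy percentages (Parseval)", {
  set.seed(52)
  x <- rnorm(2496)
  fv <- extract_afe(x, wavelet_config(n_frames = 1))
  wp <- wpt_decompose(x, wavelet_config())
  direct <- 100 * colSums(wp$coefficients^2) / sum(wp$coefficients^2)
  expect_equal(fv$values, unname(direct), tolerance = 1e-6)
})

test_that("frame symmetry: duplicated half-signals give the frame's own vector", {
  set.seed(53)
  half <- rnorm(1248)
  x <- c(half, half)
  fv2 <- extract_afe(x, wavelet_config(n_frames = 2))
  wp <- wpt_decompose(x, wavelet_config(n_frames = 2))
  expect_equal(fv2$values, unname(percentage_energy(wp, 1)),
               tolerance = 1e-6)
})

test_that("WAFE matches an independently coded straight-line oracle", {
  set.seed(54)
  h <- wafecg:::.db_scaling_filters$db5
  for (n in c(256, 512)) {
    x <- rnorm(n)
    for (zf in c(1, 5)) {
      got <- extract_afe(x, wavelet_config(level = 3, n_frames = zf))$values
      ref <- naive_afe(x, h, 3, zf)
      expect_equal(got, ref, tolerance = 1e-9)
    }
  }
})

test_that("node entropies match their defining sums", {
  one_hot <- c(rep(0, 15), 3)
  expect_equal(node_entropy(one_hot, "shannon"), 0)
  uniform <- rep(0.5, 16)
  expect_equal(node_entropy(uniform, "shannon"), log(16), tolerance = 1e-12)
  set.seed(55)
  for (i in 1:10) {
    c_block <- rnorm(78)
    expect_equal(node_entropy(c_block, "shannon"), naive_shannon(c_block),
                 tolerance = 1e-9)
    expect_equal(node_entropy(c_block, "log_energy"),
                 naive_log_energy(c_block), tolerance = 1e-9)
    expect_equal(node_entropy(c_block, "sure"), naive_sure(c_block),
                 tolerance = 1e-9)
  }
})

test_that("entropy extractors return length-Q frame-averaged vectors", {
  seg <- preprocess(synth_ecg_segment(rhythm_preset("NSR"), seed = 56))
  for (kind in c("shannon", "log_energy", "sure")) {
    fv <- extract_entropy_features(seg, wavelet_config(), kind)
    expect_length(fv$values, 32)
    expect_true(all(is.finite(fv$values)))
  }
  expect_identical(extract_entropy_features(seg, kind = "shannon")$extractor,
                   "WPSE")
  expect_identical(
    extract_entropy_features(seg, kind = "log_energy")$extractor, "WPLE")
  expect_identical(extract_entropy_features(seg, kind = "sure")$extractor,
                   "WPSUE")
})

test_that("WPAP scales quadratically, is flat for white noise, rejects zeros", {
  set.seed(57)
  x <- rnorm(2500)
  cfg <- wavelet_config()
  f1 <- extract_wpap(x, cfg)$values
  f2 <- extract_wpap(2 * x, cfg)$values
  expect_equal(f2, 4 * f1, tolerance = 1e-9)
  expect_lt(max(f1) / min(f1), 3)        # flat spectrum across nodes
  expect_error(extract_wpap(rep(0, 2500), cfg), "degenerate")
})

test_that("feature statistics agree with their textbook formulas", {
  const <- rep(7, 32)
  st <- feature_statistics(const)
  expect_equal(st$std, 0)
  expect_equal(st$var, 0)
  expect_equal(st$median, 7)
  expect_equal(st$max, 7)

  one_hot <- c(rep(0, 31), 100)
  st2 <- feature_statistics(one_hot)
  expect_equal(st2$max, 100)
  expect_equal(st2$median, 0)

  set.seed(58)
  v <- runif(32, 0, 10)
  st3 <- feature_statistics(v)
  mu <- sum(v) / 32
  va <- sum((v - mu)^2) / 32
  expect_equal(st3$var, va, tolerance = 1e-12)
  expect_equal(st3$std^2, st3$var, tolerance = 1e-12)
  expect_gte(st3$max, st3$median)
})

test_that("the tidy extraction verb returns one labelled row per segment", {
  data <- synth_ecg_dataset(c("NSR", "CHF"), n_per_class = 3, seed = 59) |>
    preprocess_segments()
  feats <- extract_features(data)
  expect_identical(nrow(feats), 6L)
  expect_identical(sum(feats$label == "CHF"), 3L)
  expect_length(grep("^node_", names(feats)), 32)
  expect_identical(attr(feats, "extractor"), "WAFE")
  expect_equal(unname(rowSums(wafecg:::feature_matrix(feats))),
               rep(100, 6), tolerance = 1e-6)
})
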