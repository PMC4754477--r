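random_wafe <- function(n = 1, q = 32) {
  m <- matrix(stats::rexp(n * q), n, q)
  100 * m / rowSums(m)
}

test_that("model building is the element-wise mean and validates inputs", {
  set.seed(60)
  feats <- synth_ecg_dataset("CHF", n_per_class = 15, seed = 60) |>
    preprocess_segments() |>
    extract_features()
  m <- build_model(feats)
  expect_identical(m$n_training, 15L)
  expect_identical(m$class_label, "CHF")
  expect_equal(m$mean_vector,
               colMeans(wafecg:::feature_matrix(feats)), tolerance = 1e-12)
  expect_equal(sum(m$mean_vector), 100, tolerance = 1e-6)

  one <- build_model(feats[3, ])
  expect_equal(one$mean_vector,
               unname(unlist(feats[3, grep("^node_", names(feats))])),
               ignore_attr = TRUE, tolerance = 1e-12)

  # fifteen copies of one vector average to that vector
  rep15 <- feats[rep(2, 15), ]
  attr(rep15, "wavelet_config") <- attr(feats, "wavelet_config")
  attr(rep15, "extractor") <- attr(feats, "extractor")
  m15 <- build_model(rep15, class_label = "CHF")
  expect_equal(m15$mean_vector, build_model(feats[2, ])$mean_vector,
               tolerance = 1e-12)
})

test_that("mixed extractors or lengths are rejected", {
  seg <- preprocess(synth_ecg_segment(rhythm_preset("NSR"), seed = 61))
  fv_a <- extract_afe(seg)
  fv_b <- extract_entropy_features(seg, kind = "shannon")
  expect_error(build_model(list(fv_a, fv_b)), "incompatible")
})

test_that("models survive a JSON round-trip", {
  feats <- synth_ecg_dataset("CHF", n_per_class = 4, seed = 62) |>
    preprocess_segments() |>
    extract_features()
  m <- build_model(feats)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(back$mean_vector, unname(m$mean_vector), tolerance = 1e-12)
  expect_identical(back$class_label, "CHF")
  expect_identical(back$n_training, 15L - 11L)
  expect_identical(back$config$wavelet_name, "db5")
})

test_that("prds identities hold exactly", {
  set.seed(63)
  y <- as.numeric(random_wafe())
  expect_equal(prds(y, y), 0)
  expect_equal(prds(y, 2 * y), 100, tolerance = 1e-12)
  expect_equal(prds(c(3, 4), c(0, 0)), 100, tolerance = 1e-12)
  expect_gte(prds(y, as.numeric(random_wafe())), 0)
  expect_error(prds(rep(0, 32), y), "zero")
})

test_that("ldsr is antisymmetric under model swap and confirms at the limit", {
  set.seed(64)
  for (i in 1:20) {
    y <- as.numeric(random_wafe())
    mx <- as.numeric(random_wafe())
    mb <- as.numeric(random_wafe())
    expect_equal(ldsr(y, mx, mb), -ldsr(y, mb, mx), tolerance = 1e-12)
  }
  y <- as.numeric(random_wafe())
  mb <- as.numeric(random_wafe())
  expect_lt(ldsr(y, y, mb), log(1e-11 / sum((y - mb)^2)))
  expect_error(ldsr(y, y, y), "both models")
  # equidistant case: zero
  d <- stats::rnorm(32)
  expect_equal(ldsr(y, y + d, y - d), 0, tolerance = 1e-12)
})

test_that("ccr matches the textbook Pearson ratio and handles edge cases", {
  set.seed(65)
  for (i in 1:20) {
    y <- stats::rnorm(32)
    mx <- stats::rnorm(32)
    mb <- stats::rnorm(32)
    pearson <- function(a, b) {
      am <- a - mean(a); bm <- b - mean(b)
      sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
    }
    expect_equal(ccr(y, mx, mb), pearson(y, mx) / pearson(y, mb),
                 tolerance = 1e-12)
  }
  m <- as.numeric(random_wafe())
  expect_equal(ccr(m, m, m), 1)          # identical models never confirm
  expect_error(ccr(rep(1, 32), m, m), "zero-variance")
})

test_that("perfect match confirms, perfect mismatch rejects", {
  set.seed(66)
  mx <- as.numeric(random_wafe())
  mb <- as.numeric(random_wafe())
  hit <- confirm_vector(mx, mx, mb)
  expect_true(hit$confirm_prds && hit$confirm_ldsr && hit$confirm_ccr)
  expect_true(hit$confirmed)
  miss <- confirm_vector(mb, mx, mb)
  expect_gt(miss$prds_ratio, 1)
  expect_gt(miss$ldsr, 0)
  expect_lt(miss$ccr, 1)
  expect_false(miss$confirmed)
  expect_equal(hit$score, -hit$ldsr)
})

test_that("the AND rule agrees with a brute-force equation-level oracle", {
  set.seed(67)
  for (i in 1:200) {
    y <- as.numeric(random_wafe())
    mx <- as.numeric(random_wafe())
    mb <- as.numeric(random_wafe())
    got <- confirm_vector(y, mx, mb)
    ref <- naive_confirm(y, mx, mb)
    expect_equal(got$prds_ratio, ref$prds_ratio, tolerance = 1e-9)
    expect_equal(got$ldsr, ref$ldsr, tolerance = 1e-9)
    expect_equal(got$ccr, ref$ccr, tolerance = 1e-9)
    expect_identical(got$confirmed, ref$confirmed)
  }
})

test_that("all three scores are invariant to a common positive rescaling", {
  set.seed(68)
  y <- as.numeric(random_wafe())
  mx <- as.numeric(random_wafe())
  mb <- as.numeric(random_wafe())
  base <- confirm_vector(y, mx, mb)
  for (s in c(1e-3, 0.7, 42)) {
    sc <- confirm_vector(s * y, s * mx, s * mb)
    expect_lt(abs(sc$prds_ratio - base$prds_ratio), 1e-9)
    expect_lt(abs(sc$ldsr - base$ldsr), 1e-9)
    expect_lt(abs(sc$ccr - base$ccr), 1e-9)
  }
})

test_that("moving the tested vector from background toward hypothesis drives ldsr down", {
  set.seed(69)
  for (i in 1:100) {
    mx <- stats::rnorm(32)
    mb <- stats::rnorm(32)
    vals <- vapply(seq(0, 1, length.out = 11), function(a) {
      ldsr((1 - a) * mb + a * mx, mx, mb)
    }, numeric(1))
    expect_true(all(diff(vals) < 0))
  }
})

test_that("confirm_segments scores every row against the two models", {
  data <- synth_ecg_dataset(c("NSR", "CHF"), n_per_class = 4, seed = 70) |>
    preprocess_segments()
  feats <- extract_features(data)
  mx <- build_model(feats[feats$label == "CHF", ], "CHF")
  mb <- build_model(feats[feats$label == "NSR", ], "NSR")
  res <- confirm_segments(feats, mx, mb)
  expect_identical(nrow(res), 8L)
  expect_true(all(c("prds_ratio", "ldsr", "ccr", "confirmed", "score")
                  %in% names(res)))
  expect_identical(res$confirmed,
                   res$confirm_prds & res$confirm_ldsr & res$confirm_ccr)
})
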