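# Independent, deliberately naive reference implementations used as test
# oracles. These are scalar-loop, straight-from-the-definition codings kept
# free of the package's vectorized implementation machinery.

# -- naive periodized wavelet-packet transform ------------------------------

naive_qmf <- function(h) rev(h) * (-1)^(seq_along(h) - 1)

naive_analysis <- function(v, f) {
  n <- length(v)
  out <- numeric(n %/% 2)
  for (k in seq_along(out)) {
    acc <- 0
    for (m in seq_along(f)) {
      acc <- acc + f[m] * v[(2 * (k - 1) + m - 1) %% n + 1]
    }
    out[k] <- acc
  }
  out
}

naive_synthesis <- function(a, f) {
  l <- length(a)
  n <- 2 * l
  out <- numeric(n)
  for (k in seq_len(l)) {
    for (m in seq_along(f)) {
      i <- (2 * (k - 1) + m - 1) %% n + 1
      out[i] <- out[i] + f[m] * a[k]
    }
  }
  out
}

# terminal coefficient blocks in natural order, as a list
naive_wpt_coefs <- function(x, h, level) {
  g <- naive_qmf(h)
  nodes <- list(x)
  for (lev in seq_len(level)) {
    nxt <- list()
    for (v in nodes) {
      nxt <- c(nxt, list(naive_analysis(v, h)), list(naive_analysis(v, g)))
    }
    nodes <- nxt
  }
  nodes
}

# full-length reconstruction of terminal node q (1-based, natural order)
naive_wpt_subsignal <- function(coefs, q, h, level) {
  g <- naive_qmf(h)
  v <- coefs[[q]]
  idx <- q - 1L
  for (lev in seq_len(level)) {
    f <- if (idx %% 2L == 0L) h else g
    v <- naive_synthesis(v, f)
    idx <- idx %/% 2L
  }
  v
}

# straight-line WAFE: decompose -> frame -> normalize per frame -> average
naive_afe <- function(x, h, level, n_frames) {
  n <- (length(x) %/% 2^level) * 2^level
  x <- x[seq_len(n)]
  coefs <- naive_wpt_coefs(x, h, level)
  q <- 2^level
  subs <- matrix(0, n, q)
  for (j in seq_len(q)) subs[, j] <- naive_wpt_subsignal(coefs, j, h, level)
  flen <- n %/% n_frames
  acc <- numeric(q)
  for (z in seq_len(n_frames)) {
    rows <- ((z - 1) * flen + 1):(z * flen)
    e <- numeric(q)
    for (j in seq_len(q)) e[j] <- sum(subs[rows, j]^2)
    acc <- acc + 100 * e / sum(e)
  }
  acc / n_frames
}

# -- entropies, straight off the definitions --------------------------------

naive_shannon <- function(c) {
  tot <- sum(c^2)
  if (tot == 0) return(0)
  s <- 0
  for (ci in c) {
    p <- ci^2 / tot
    if (p > 0) s <- s - p * log(p)
  }
  s
}

naive_log_energy <- function(c) {
  s <- 0
  for (ci in c) s <- s + log(max(ci^2, 1e-12))
  s
}

naive_sure <- function(c) {
  n <- length(c)
  tau2 <- 2 * log(n * log2(max(n, 2)))
  s <- 0
  for (ci in c) s <- s + min(ci^2, tau2)
  s
}

# -- confirmation scores, straight off the equations ------------------------

naive_confirm <- function(y, mx, mb) {
  prds_x <- 100 * sqrt(sum((y - mx)^2) / sum(y^2))
  prds_b <- 100 * sqrt(sum((y - mb)^2) / sum(y^2))
  ld <- log((sum((y - mx)^2) + 1e-12) / (sum((y - mb)^2) + 1e-12))
  pearson <- function(a, b) {
    am <- a - mean(a); bm <- b - mean(b)
    sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
  }
  cc <- pearson(y, mx) / pearson(y, mb)
  confirmed <- (prds_x / prds_b < 1) && (ld <= 0) && (cc > 1)
  list(prds_ratio = prds_x / prds_b, ldsr = ld, ccr = cc,
       confirmed = confirmed)
}

# -- Mann-Whitney U by brute-force pair counting ----------------------------

naive_auc_u <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  u <- 0
  for (p in pos) {
    for (q in neg) {
      u <- u + (p > q) + 0.5 * (p == q)
    }
  }
  u / (length(pos) * length(neg))
}

# -- crude R-peak counter (threshold + refractory) --------------------------

count_r_peaks <- function(x, fs, thresh_frac = 0.5, refractory_s = 0.3) {
  thr <- thresh_frac * max(x)
  n <- length(x)
  peaks <- 0L
  last <- -Inf
  for (i in 2:(n - 1)) {
    if (x[i] > thr && x[i] >= x[i - 1] && x[i] >= x[i + 1] &&
        (i - last) / fs > refractory_s) {
      peaks <- peaks + 1L
      last <- i
    }
  }
  peaks
}

# segments used across feature tests: a mix of white noise and generator
# output
make_test_signals <- function(n_random, n_synth, seed = 42) {
  set.seed(seed)
  sigs <- lapply(seq_len(n_random), function(i) rnorm(512))
  classes <- c("NSR", "CHF", "AF", "PEB")
  synth <- lapply(seq_len(n_synth), function(i) {
    preprocess(synth_ecg_segment(rhythm_preset(classes[(i %% 4) + 1]),
                                 seed = 1000 + i))$samples
  })
  c(sigs, synth)
}
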