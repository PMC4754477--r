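#' Daubechies scaling filters
#'
#' Orthonormal scaling (low-pass analysis) filter coefficients for the
#' Daubechies family, db1 (Haar) through db8. These are the standard
#' published values; orthonormality of the induced filter bank is what makes
#' the energy-conservation (Parseval) contract of [wpt_decompose()] exact
#' under periodized boundaries.
#'
#' @keywords internal
#' @noRd
.db_scaling_filters <- list(
  db1 = c(0.70710678118654757, 0.70710678118654757),
  db2 = c(-0.12940952255126037, 0.22414386804201339, 0.83651630373780794,
          0.48296291314453416),
  db3 = c(0.035226291885709533, -0.085441273882026658, -0.13501102001025458,
          0.45987750211849154, 0.80689150931109255, 0.33267055295008263),
  db4 = c(-0.010597401785069032, 0.032883011666885197, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.63088076792985892,
          0.71484657055291567, 0.23037781330889651),
  db5 = c(0.0033357252854737712, -0.012580751999081999, -0.0062414902127982744,
          0.077571493840045719, -0.032244869584638375, -0.24229488706638203,
          0.13842814590132074, 0.72430852843777294, 0.60382926979718965,
          0.16010239797419293),
  db6 = c(-0.0010773010853084796, 0.0047772575109455108, 0.00055384220116149613,
          -0.03158203931748603, 0.027522865530305727, 0.097501605587323043,
          -0.12976686756726194, -0.22626469396543983, 0.31525035170919763,
          0.75113390802109536, 0.49462389039845306, 0.11154074335010947),
  db7 = c(0.00035371379997452024, -0.0018016407040474908, 0.00042957797292136651,
          0.01255099855609984, -0.016574541630666881, -0.038029936935014413,
          0.080612609151083078, 0.071309219266830259, -0.22403618499387498,
          -0.14390600392856498, 0.46978228740519312, 0.72913209084623509,
          0.39653931948191729, 0.077852054085009184),
  db8 = c(-0.00011747678412476953, 0.00067544940645056933,
          -0.00039174037337694705, -0.0048703529934515741,
          0.0087460940474057766, 0.013981027917398282, -0.044088253930794755,
          -0.017369301001807547, 0.12874742662047847, 0.00047248457391328279,
          -0.28401554296154691, -0.015829105256349306, 0.58535468365420673,
          0.67563073629728976, 0.31287159091429995, 0.054415842243104008)
)

#' Analysis filter pair for a named wavelet
#'
#' @param wavelet_name one of `"db1"` .. `"db8"`.
#' @return list with elements `lo` and `hi`, the low-pass and high-pass
#'   analysis filters (quadrature mirror pair).
#' @keywords internal
#' @noRd
wavelet_filters <- function(wavelet_name) {
  h <- .db_scaling_filters[[wavelet_name]]
  if (is.null(h)) {
    stop("unknown wavelet '", wavelet_name, "'; available: ",
         paste(names(.db_scaling_filters), collapse = ", "), call. = FALSE)
  }
  m <- length(h)
  # quadrature mirror: g[k] = (-1)^k h[M-1-k] (0-based)
  g <- rev(h) * (-1)^(seq_len(m) - 1)
  list(lo = h, hi = g)
}

#' Wavelet-packet configuration
#'
#' Bundles the parameters of the wavelet-packet feature extraction: the
#' mother wavelet, the decomposition depth, the number of frames each
#' terminal subsignal is cut into before energies are averaged, and the
#' ordering of the terminal nodes.
#'
#' @param wavelet_name Mother wavelet (`"db1"`..`"db8"`). Default `"db5"`,
#'   the Daubechies order-5 wavelet.
#' @param level Decomposition depth `L`; the tree has `Q = 2^L` terminal
#'   subband nodes. Default 5 (32 nodes).
#' @param n_frames Number `Z` of equal non-overlapping frames per terminal
#'   subsignal over which percentage energies are averaged. Default 5
#'   (2-second frames on a 10-second segment).
#' @param node_order `"natural"` (filter-bank / Paley order, default) or
#'   `"frequency"` (nodes permuted so subband centre frequencies increase).
#'   Ordering only permutes feature vectors; all vectors that are compared
#'   must share it.
#' @param boundary_mode Boundary extension; only `"periodization"` is
#'   implemented (it makes the orthonormal filter bank exactly
#'   energy-preserving, which the package's contracts rely on).
#' @return An object of class `wavelet_config`.
#' @examples
#' wavelet_config()
#' wavelet_config(level = 3, n_frames = 1)
#' @export
wavelet_config <- function(wavelet_name = "db5", level = 5L, n_frames = 5L,
                           node_order = c("natural", "frequency"),
                           boundary_mode = "periodization") {
  node_order <- match.arg(node_order)
  level <- as.integer(level)
  n_frames <- as.integer(n_frames)
  stopifnot(level >= 1L, n_frames >= 1L)
  if (!identical(boundary_mode, "periodization")) {
    stop("only boundary_mode = 'periodization' is supported", call. = FALSE)
  }
  wavelet_filters(wavelet_name)  # validates the name
  structure(
    list(wavelet_name = wavelet_name, level = level, n_frames = n_frames,
         node_order = node_order, boundary_mode = boundary_mode),
    class = "wavelet_config"
  )
}

#' @export
print.wavelet_config <- function(x, ...) {
  cat(sprintf("<wavelet_config> %s, level %d (Q = %d nodes), Z = %d frames, %s order\n",
              x$wavelet_name, x$level, 2L^x$level, x$n_frames, x$node_order))
  invisible(x)
}

n_terminal_nodes <- function(cfg) 2L^cfg$level

# One periodized analysis step applied column-wise: each column of `x`
# (even length n) is split into low-pass and high-pass halves of length n/2.
# Returns list(lo =, hi =) of (n/2 x ncol) matrices.
wp_analysis_step <- function(x, filt) {
  n <- nrow(x)
  half <- n %/% 2L
  lo <- matrix(0, half, ncol(x))
  hi <- matrix(0, half, ncol(x))
  base_idx <- 2L * (seq_len(half) - 1L)
  for (m in seq_along(filt$lo)) {
    idx <- (base_idx + (m - 1L)) %% n + 1L
    xm <- x[idx, , drop = FALSE]
    lo <- lo + filt$lo[m] * xm
    hi <- hi + filt$hi[m] * xm
  }
  list(lo = lo, hi = hi)
}

# Transpose (synthesis) of wp_analysis_step for a single branch: takes
# coefficients `a` (l x C) and a filter vector, returns (2l x C).
wp_synthesis_step <- function(a, f) {
  l <- nrow(a)
  n <- 2L * l
  out <- matrix(0, n, ncol(a))
  base_idx <- 2L * (seq_len(l) - 1L)
  for (m in seq_along(f)) {
    idx <- (base_idx + (m - 1L)) %% n + 1L
    out[idx, ] <- out[idx, , drop = FALSE] + f[m] * a
  }
  out
}

# Permutation mapping natural (Paley) node order to frequency order:
# returns an integer vector p such that nodes[, p] are in increasing
# subband-frequency order. Gray-code relationship between the two orders.
wp_frequency_order <- function(level) {
  q <- 2L^level
  nat <- 0:(q - 1L)
  freq <- integer(q)
  for (i in seq_along(nat)) {
    b <- nat[i]
    # accumulate path bits MSB-first, flipping branch sense whenever the
    # previous accumulated bit was 1 (high-pass halves reverse frequency order)
    f <- 0L
    prev <- 0L
    for (k in seq_len(level)) {
      bit <- bitwAnd(bitwShiftR(b, level - k), 1L)
      eff <- bitwXor(bit, prev)
      f <- bitwOr(bitwShiftL(f, 1L), eff)
      prev <- eff
    }
    freq[i] <- f
  }
  order(freq)
}

#' Wavelet-packet decomposition into terminal subsignals
#'
#' Decomposes a signal with a periodized orthonormal wavelet-packet filter
#' bank down to `cfg$level`, and reconstructs each of the `Q = 2^level`
#' terminal nodes back to the time domain with all other nodes zeroed. The
#' terminal subsignals sum to the analyzed signal exactly (perfect
#' reconstruction) and their energies sum to its energy (Parseval), both up
#' to numerical round-off.
#'
#' Periodization requires the analyzed length to be a multiple of
#' `2^level`; inputs whose length is not are truncated to the longest such
#' prefix (at most `2^level - 1` trailing samples dropped) and the analyzed
#' length is recorded in the result.
#'
#' @param x An [ecg_segment] or numeric vector.
#' @param cfg A [wavelet_config()].
#' @return An object of class `wpt_subsignals`: a list with `subsignals`
#'   (n x Q matrix, one column per terminal node in `cfg$node_order`),
#'   `coefficients` (n/Q x Q matrix of terminal coefficient blocks, same
#'   column order), `total_energy` (sum of squared coefficients), `n` (the
#'   analyzed length) and `config`.
#' @examples
#' seg <- synth_ecg_segment(rhythm_preset("NSR"), seed = 1)
#' wp <- wpt_decompose(seg, wavelet_config())
#' ncol(wp$subsignals)                       # 32 terminal nodes
#' max(abs(rowSums(wp$subsignals) - seg$samples[seq_len(wp$n)]))
#' @export
wpt_decompose <- function(x, cfg = wavelet_config()) {
  samples <- if (inherits(x, "ecg_segment")) x$samples else as.numeric(x)
  q <- n_terminal_nodes(cfg)
  if (length(samples) < q) {
    stop("signal of length ", length(samples),
         " is too short for a level-", cfg$level,
         " decomposition (needs at least ", q, " samples)", call. = FALSE)
  }
  n <- as.integer((length(samples) %/% q) * q)
  samples <- samples[seq_len(n)]
  filt <- wavelet_filters(cfg$wavelet_name)

  # analysis: matrix columns are current-level nodes in natural order
  coef <- matrix(samples, ncol = 1L)
  for (lev in seq_len(cfg$level)) {
    st <- wp_analysis_step(coef, filt)
    nc <- ncol(coef)
    out <- matrix(0, nrow(coef) %/% 2L, 2L * nc)
    out[, 2L * seq_len(nc) - 1L] <- st$lo
    out[, 2L * seq_len(nc)] <- st$hi
    coef <- out
  }

  # per-node reconstruction: carry every node up separately (zero siblings),
  # batching the low- and high-branch synthesis at each level
  recon <- coef
  node <- 0:(q - 1L)
  for (lev in seq_len(cfg$level)) {
    is_hi <- node %% 2L == 1L
    up <- matrix(0, 2L * nrow(recon), q)
    if (any(!is_hi)) {
      up[, !is_hi] <- wp_synthesis_step(recon[, !is_hi, drop = FALSE], filt$lo)
    }
    if (any(is_hi)) {
      up[, is_hi] <- wp_synthesis_step(recon[, is_hi, drop = FALSE], filt$hi)
    }
    recon <- up
    node <- node %/% 2L
  }

  if (cfg$node_order == "frequency") {
    perm <- wp_frequency_order(cfg$level)
    coef <- coef[, perm, drop = FALSE]
    recon <- recon[, perm, drop = FALSE]
  }

  structure(
    list(subsignals = recon, coefficients = coef,
         total_energy = sum(coef^2), n = n, config = cfg),
    class = "wpt_subsignals"
  )
}

#' @export
print.wpt_subsignals <- function(x, ...) {
  cat(sprintf("<wpt_subsignals> %d terminal nodes x %d samples (%s, level %d), total energy %.4g\n",
              ncol(x$subsignals), x$n, x$config$wavelet_name,
              x$config$level, x$total_energy))
  invisible(x)
}
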