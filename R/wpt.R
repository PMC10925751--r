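# Wavelet packet engine: full binary filter-bank decomposition with
# periodized boundary handling, frequency-ordered terminal sub-band energies.

# One periodized analysis step: circular correlation with the taps followed
# by dyadic downsampling. For output index i (0-based) the window starts at
# 2*i + 1 - L/2 (mod n), with the taps applied time-reversed — the convention
# of the standard reference implementations, so coefficient arrays are
# directly comparable.
.wp_step <- function(x, taps) {
  n <- length(x)
  L <- length(taps)
  half <- n %/% 2L
  f <- rev(taps)
  out <- numeric(half)
  i0 <- seq_len(half) - 1L
  start <- 2L * i0 + 1L - L %/% 2L
  for (k in seq_len(L)) {
    out <- out + f[k] * x[((start + (k - 1L)) %% n) + 1L]
  }
  out
}

#' Natural-to-frequency ordering of wavelet packet nodes
#'
#' The terminal nodes of a wavelet packet tree in natural (filter-path)
#' order are not sorted by physical frequency: below every high-pass branch
#' the spectrum is mirrored, so the children of such branches appear swapped.
#' The fix is the Gray-code permutation: reading the path bits
#' (0 = low-pass, 1 = high-pass) from the root, each output bit is the
#' running XOR of the path bits. The map is a bijection on
#' `0 ... 2^level - 1`; without it, "band index times bandwidth" would not be
#' a frequency.
#'
#' @param natural_index 0-based node index (or vector of indices) in natural
#'   order, `0 <= natural_index < 2^level`.
#' @param level Decomposition level (>= 0).
#' @return The 0-based frequency-ordered position(s).
#' @examples
#' frequency_order(0:3, 2) # 0 1 3 2
#' @export
frequency_order <- function(natural_index, level) {
  if (level < 0) stop("frequency_order: level must be >= 0")
  natural_index <- as.integer(natural_index)
  if (any(natural_index < 0L) || any(natural_index >= 2^level))
    stop("frequency_order: index out of range [0, 2^level)")
  vapply(natural_index, function(b) {
    f <- 0L
    acc <- 0L
    for (pos in seq_len(level)) {
      bit <- bitwAnd(bitwShiftR(b, level - pos), 1L)
      acc <- bitwXor(acc, bit)
      f <- bitwOr(bitwShiftL(f, 1L), acc)
    }
    f
  }, integer(1))
}

#' Frequency range of a terminal sub-band
#'
#' Band `j` (0-based, frequency-ordered) at decomposition level `level`
#' covers the half-open interval `[j * df, (j + 1) * df)` with
#' `df = fs / 2^(level + 1)`; the `2^level` bands tile `[0, fs/2)` exactly.
#' At `fs = 5000` Hz and level 9 each band is 2500/512 = 4.88 Hz wide.
#'
#' @param j 0-based band index (vectorised), `0 <= j < 2^level`.
#' @param level Decomposition level.
#' @param fs Sampling frequency in Hz.
#' @return A list with numeric vectors `low` and `high` (Hz).
#' @export
band_range <- function(j, level, fs) {
  if (fs <= 0) stop("band_range: fs must be > 0")
  if (any(j < 0) || any(j >= 2^level))
    stop("band_range: band index out of range [0, 2^level)")
  df <- fs / 2^(level + 1)
  list(low = j * df, high = (j + 1) * df)
}

#' Wavelet packet decomposition with sub-band energies
#'
#' Decomposes an acceleration signal down a full wavelet packet tree of the
#' given depth, using periodized (circular) convolution at every split — the
#' boundary mode under which the transform is exactly orthogonal, so the sum
#' of terminal sub-band energies equals the signal energy `sum(x^2)` to
#' machine precision (Parseval). The signal is zero-padded at the tail to the
#' next multiple of `2^levels` (tail zeros change neither `sum(x^2)` nor the
#' energy budget). Terminal nodes are re-ordered from natural (filter-path)
#' order to physical frequency order via [frequency_order()] before energies
#' are reported; the energy of band `j` is the sum of squared coefficients of
#' that node, and the total energy is the sum over all bands.
#'
#' @param signal An [accel_signal()].
#' @param levels Decomposition depth `i >= 0`; the spectrum has `2^i` bands.
#' @param filters A [qmf_pair()]; defaults to [build_sym2()].
#' @param max_nodes Safety cap on `2^levels` (default `2^16`).
#' @return An object of class `wp_spectrum`: list with `level`, `energies`
#'   (length `2^levels`, frequency-ordered), `band_width` (Hz), `fs` (Hz),
#'   `total_energy`, `coefs` (matrix, one row per frequency-ordered band),
#'   `n_orig` and `n_padded` sample counts, `unit`, `label`.
#' @examples
#' fs <- 5000
#' sig <- accel_signal(sin(2 * pi * 250 * (0:4095) / fs), dt = 1 / fs)
#' sp <- wp_decompose(sig, levels = 9)
#' sp
#' @export
wp_decompose <- function(signal, levels = 9L, filters = build_sym2(),
                         max_nodes = 2^16) {
  stopifnot(inherits(signal, "accel_signal"), inherits(filters, "qmf_pair"))
  levels <- as.integer(levels)
  if (levels < 0L) stop("wp_decompose: levels must be >= 0")
  if (2^levels > max_nodes)
    stop("wp_decompose: 2^levels exceeds the configured cap (", max_nodes, ")")
  x <- signal$values
  n <- length(x)
  block <- 2^levels
  n_pad <- max(block, as.integer(ceiling(n / block)) * block)
  if (n_pad > n) x <- c(x, numeric(n_pad - n))

  nodes <- list(x)
  if (levels > 0L) {
    for (lev in seq_len(levels)) {
      nxt <- vector("list", 2L * length(nodes))
      for (i in seq_along(nodes)) {
        nxt[[2L * i - 1L]] <- .wp_step(nodes[[i]], filters$h)
        nxt[[2L * i]] <- .wp_step(nodes[[i]], filters$g)
      }
      nodes <- nxt
    }
  }

  perm <- frequency_order(seq_along(nodes) - 1L, levels) + 1L
  coefs <- matrix(0, nrow = length(nodes), ncol = n_pad / block)
  for (i in seq_along(nodes)) coefs[perm[i], ] <- nodes[[i]]
  energies <- rowSums(coefs^2)

  structure(
    list(level = levels,
         energies = energies,
         band_width = (1 / signal$dt) / 2^(levels + 1),
         fs = 1 / signal$dt,
         total_energy = sum(energies),
         coefs = coefs,
         n_orig = n, n_padded = n_pad,
         unit = signal$unit, label = signal$label),
    class = "wp_spectrum"
  )
}

#' @export
print.wp_spectrum <- function(x, ...) {
  cat(sprintf(
    "<wp_spectrum> %s: level %d, %d bands x %.4g Hz, fs = %.6g Hz\n",
    if (nzchar(x$label)) x$label else "(unlabelled)",
    x$level, length(x$energies), x$band_width, x$fs))
  jmax <- which.max(x$energies) - 1L
  br <- band_range(jmax, x$level, x$fs)
  cat(sprintf(
    "  total energy %.6g %s^2; peak band %d [%.4g, %.4g) Hz (%.1f%% of total)\n",
    x$total_energy, if (x$unit == "g") "g" else "(m/s^2)",
    jmax, br$low, br$high, 100 * x$energies[jmax + 1L] / x$total_energy))
  invisible(x)
}

#' @export
as.data.frame.wp_spectrum <- function(x, ...) {
  j <- seq_along(x$energies) - 1L
  br <- band_range(j, x$level, x$fs)
  data.frame(band_index = j, f_low_hz = br$low, f_high_hz = br$high,
             energy = x$energies)
}

#' @export
plot.wp_spectrum <- function(x, xlim = NULL, ...) {
  df <- as.data.frame(x)
  graphics::plot((df$f_low_hz + df$f_high_hz) / 2, df$energy, type = "h",
                 xlab = "frequency (Hz)", ylab = "sub-band energy",
                 main = x$label, xlim = xlim, ...)
  invisible(x)
}

#' Write a sub-band energy spectrum to CSV
#'
#' Columns: `band_index`, `f_low_hz`, `f_high_hz`, `energy`.
#'
#' @param spectrum A `wp_spectrum`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "wp_spectrum"))
  utils::write.csv(as.data.frame(spectrum), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
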