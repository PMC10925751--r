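#' Frequency-domain injury indicators
#'
#' From a sub-band energy spectrum, computes the three frequency-domain
#' indicators used to characterise head response to blunt impact:
#' * `e_max` — the energy of the most energetic sub-band (signal-unit
#'   squared), reflecting the strength of the response in that band;
#' * `band_index` — the 0-based, frequency-ordered position of that band
#'   (its physical range is `band_index * band_width` to
#'   `(band_index + 1) * band_width` Hz, reported as `band_low_hz` /
#'   `band_high_hz`);
#' * `proportion` — `e_max / total_energy`, the concentration of the signal
#'   energy in its dominant band, in `[1/2^level, 1]`.
#'
#' Ties in the maximal energy are broken towards the lowest band index, so
#' the result is deterministic.
#'
#' @param spectrum A [wp_decompose()] result with positive total energy.
#' @return An object of class `freq_indicators`: list with `e_max`,
#'   `band_index`, `band_low_hz`, `band_high_hz`, `proportion`, `level`,
#'   `label`.
#' @export
compute_indicators <- function(spectrum) {
  stopifnot(inherits(spectrum, "wp_spectrum"))
  if (spectrum$total_energy <= 0)
    stop("compute_indicators: degenerate signal (total energy is zero)")
  j <- which.max(spectrum$energies) - 1L  # which.max takes the first max
  br <- band_range(j, spectrum$level, spectrum$fs)
  structure(
    list(e_max = spectrum$energies[j + 1L],
         band_index = j,
         band_low_hz = br$low,
         band_high_hz = br$high,
         proportion = spectrum$energies[j + 1L] / spectrum$total_energy,
         level = spectrum$level,
         label = spectrum$label),
    class = "freq_indicators"
  )
}

#' @export
print.freq_indicators <- function(x, ...) {
  cat(sprintf("<freq_indicators> %s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)"))
  cat(sprintf("  peak sub-band energy  %.6g\n", x$e_max))
  cat(sprintf("  peak band             %d  [%.4g, %.4g) Hz\n",
              x$band_index, x$band_low_hz, x$band_high_hz))
  cat(sprintf("  energy proportion     %.4f\n", x$proportion))
  invisible(x)
}

#' @export
as.data.frame.freq_indicators <- function(x, ...) {
  data.frame(signal_label = x$label, e_max = x$e_max,
             band_index = x$band_index, f_low_hz = x$band_low_hz,
             f_high_hz = x$band_high_hz, proportion = x$proportion)
}
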