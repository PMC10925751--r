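#' Uniformly sampled acceleration signal
#'
#' Container for a scalar acceleration trace sampled at a fixed interval.
#' This is the universal input of the analysis pipeline: wavelet packet
#' decomposition, the frequency-domain indicators and the HIC all consume an
#' `accel_signal`.
#'
#' @param values Numeric vector of acceleration samples (length >= 2, all
#'   finite), in the unit given by `unit`.
#' @param dt Sampling interval in seconds (> 0). Sample `k` (1-based) is at
#'   time `(k - 1) * dt`.
#' @param unit Either `"g"` or `"m_per_s2"`.
#' @param label Free-text label carried through to result tables.
#' @return An object of class `accel_signal`: a list with elements `values`,
#'   `dt`, `unit`, `label`.
#' @examples
#' sig <- accel_signal(sin(2 * pi * 50 * seq(0, 0.1, by = 2e-4)), dt = 2e-4)
#' print(sig)
#' @export
accel_signal <- function(values, dt, unit = c("m_per_s2", "g"), label = "") {
  unit <- match.arg(unit)
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("accel_signal: length >= 2 violated (got ", length(values), " sample)")
  if (!all(is.finite(values)))
    stop("accel_signal: non-finite samples (NaN/Inf) present")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("accel_signal: dt must be a single finite value > 0")
  structure(
    list(values = values, dt = as.numeric(dt), unit = unit,
         label = as.character(label)),
    class = "accel_signal"
  )
}

#' @export
print.accel_signal <- function(x, ...) {
  cat(sprintf(
    "<accel_signal> %s: %d samples @ %.6g s (fs = %.6g Hz), unit = %s\n",
    if (nzchar(x$label)) x$label else "(unlabelled)",
    length(x$values), x$dt, 1 / x$dt, x$unit))
  cat(sprintf("  duration %.4g s, peak |a| = %.4g %s\n",
              (length(x$values) - 1) * x$dt, max(abs(x$values)),
              if (x$unit == "g") "g" else "m/s^2"))
  invisible(x)
}

#' @export
plot.accel_signal <- function(x, ...) {
  t <- (seq_along(x$values) - 1) * x$dt
  graphics::plot(t, x$values, type = "l", xlab = "time (s)",
                 ylab = paste0("acceleration (",
                               if (x$unit == "g") "g" else "m/s^2", ")"),
                 main = x$label, ...)
  invisible(x)
}

#' Sampling frequency of a signal
#' @param signal An `accel_signal`.
#' @return Sampling frequency in Hz (`1 / dt`).
#' @export
sampling_rate <- function(signal) {
  stopifnot(inherits(signal, "accel_signal"))
  1 / signal$dt
}

#' Read an acceleration signal from CSV
#'
#' Reads a two-column plain CSV (header row required, comma separator, '.'
#' decimal) holding one uniformly sampled acceleration trace. The sampling
#' interval is inferred as the median successive time difference; the file is
#' rejected if any successive difference deviates from that median by more
#' than 0.1% (relative), which tolerates the slight time jitter of
#' finite-element solver output while catching genuinely non-uniform traces.
#'
#' @param path Path to the CSV file.
#' @param time_col,accel_col Column names for time (seconds) and acceleration.
#' @param unit Unit of the acceleration column: `"m_per_s2"` or `"g"`.
#' @param label Label for the signal; defaults to the file name.
#' @return An [accel_signal()].
#' @export
load_signal <- function(path, time_col = "time_s", accel_col = "accel",
                        unit = c("m_per_s2", "g"), label = NULL) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("load_signal: file not found: ", path)
  df <- utils::read.csv(path, header = TRUE)
  for (col in c(time_col, accel_col)) {
    if (!col %in% names(df))
      stop("load_signal: missing column '", col, "' in ", path)
    if (!is.numeric(df[[col]]))
      stop("load_signal: column '", col, "' is not numeric in ", path)
  }
  tm <- df[[time_col]]
  a <- df[[accel_col]]
  if (length(tm) < 2L)
    stop("load_signal: length >= 2 violated (", length(tm), " row)")
  if (anyNA(a) || !all(is.finite(a)))
    stop("load_signal: NaN/Inf acceleration samples in ", path)
  if (anyNA(tm) || !all(is.finite(tm)))
    stop("load_signal: NaN/Inf time stamps in ", path)
  dts <- diff(tm)
  if (any(dts <= 0))
    stop("load_signal: non-monotone time column in ", path)
  dt <- stats::median(dts)
  if (any(abs(dts - dt) / dt > 1e-3))
    stop("load_signal: non-uniform sampling in ", path,
         " (successive time step deviates > 0.1% from the median)")
  accel_signal(a, dt = dt, unit = unit,
               label = if (is.null(label)) basename(path) else label)
}

#' Write an acceleration signal to CSV
#'
#' Inverse of [load_signal()]: writes columns `time_s`, `accel` at full
#' double precision so that a load/write round trip reproduces the signal.
#'
#' @param signal An `accel_signal`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(signal, path) {
  stopifnot(inherits(signal, "accel_signal"))
  t <- (seq_along(signal$values) - 1) * signal$dt
  df <- data.frame(time_s = sprintf("%.17g", t),
                   accel = sprintf("%.17g", signal$values))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# standard gravity, m/s^2 per g
.g0 <- 9.80665

#' Convert acceleration units
#'
#' Converts between g and m/s^2 using the standard-gravity constant
#' 9.80665 m/s^2. Idempotent when the target equals the current unit; length
#' and sampling interval are preserved exactly.
#'
#' @param signal An `accel_signal`.
#' @param target `"g"` or `"m_per_s2"`.
#' @return The converted `accel_signal`.
#' @export
convert_units <- function(signal, target = c("g", "m_per_s2")) {
  stopifnot(inherits(signal, "accel_signal"))
  target <- match.arg(target)
  if (!signal$unit %in% c("g", "m_per_s2"))
    stop("convert_units: unknown unit tag '", signal$unit, "'")
  if (signal$unit == target) return(signal)
  values <- if (target == "g") signal$values / .g0 else signal$values * .g0
  accel_signal(values, dt = signal$dt, unit = target, label = signal$label)
}
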