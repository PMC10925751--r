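#' Head Injury Criterion
#'
#' Computes `HIC = max over windows (t2 - t1) * [ mean a(t) over (t1, t2) ]^2.5`
#' with acceleration in g, searching every pair of sample-aligned window
#' endpoints whose width does not exceed `max_window`. The running integral
#' is a cumulative trapezoid, so the search is a vectorised sweep over window
#' widths rather than an O(n^2) double loop. The default 15 ms cap is the
#' HIC15 variant; set `max_window = 0.036` for HIC36.
#'
#' The signal is converted to g internally (the criterion is defined on g).
#' By default the signed samples are used as given; a window whose mean
#' acceleration is negative contributes `|mean|^2.5` and, if it is the
#' maximizing window, a warning is issued. Set `rectify = TRUE` to take the
#' absolute value of the samples before integration instead.
#'
#' @param signal An [accel_signal()] (any unit; converted to g).
#' @param max_window Maximum window width `t2 - t1` in seconds (> `dt`).
#' @param rectify If `TRUE`, rectify the signal to its magnitude first.
#' @return An object of class `hic_result`: list with `value`, `t1`, `t2`
#'   (seconds, on sample boundaries), `max_window`.
#' @examples
#' # constant 100 g for >= 15 ms: HIC15 = 0.015 * 100^2.5 = 1500
#' sig <- accel_signal(rep(100, 101), dt = 2e-4, unit = "g")
#' compute_hic(sig)$value
#' @export
compute_hic <- function(signal, max_window = 0.015, rectify = FALSE) {
  stopifnot(inherits(signal, "accel_signal"))
  if (max_window <= signal$dt)
    stop("compute_hic: max_window must exceed the sampling interval dt")
  sig <- convert_units(signal, "g")
  a <- sig$values
  if (rectify) a <- abs(a)
  n <- length(a)
  dt <- sig$dt

  # cumulative trapezoidal integral of a(t): ct[k] = integral to sample k
  ct <- c(0, cumsum((a[-n] + a[-1]) / 2 * dt))
  wmax <- as.integer(floor(max_window / dt + 1e-9))
  wmax <- min(wmax, n - 1L)

  best <- -Inf; best_d <- 1L; best_i <- 1L; best_signed <- 0
  for (d in seq_len(wmax)) {
    integ <- ct[(1L + d):n] - ct[1L:(n - d)]
    i <- which.max(abs(integ))
    cand <- abs(integ[i])^2.5 / (d * dt)^1.5
    if (cand > best) {
      best <- cand
      best_d <- d
      best_i <- i
      best_signed <- integ[i]
    }
  }
  if (best_signed < 0)
    warning("compute_hic: maximizing window has negative mean acceleration; ",
            "HIC computed from its magnitude")
  structure(
    list(value = if (is.finite(best)) best else 0,
         t1 = (best_i - 1L) * dt,
         t2 = (best_i - 1L + best_d) * dt,
         max_window = max_window),
    class = "hic_result"
  )
}

#' @export
print.hic_result <- function(x, ...) {
  cat(sprintf("<hic_result> HIC = %.4g over [%.4g, %.4g] s (window cap %g ms)\n",
              x$value, x$t1, x$t2, 1000 * x$max_window))
  invisible(x)
}

#' Join externally computed brain strain (MPS) onto a results table
#'
#' Maximum principal strain of brain tissue comes from finite-element
#' post-processing and is accepted only as an external CSV with columns
#' `scenario_id` and `mps`. Rows of the results table without a matching
#' scenario id are flagged in the `mps_matched` column.
#'
#' @param table A `factorial_result` data frame (see [run_matrix()]).
#' @param mps_file CSV path with columns `scenario_id`, `mps`.
#' @return `table` with columns `mps` and `mps_matched` appended.
#' @export
attach_external_mps <- function(table, mps_file) {
  stopifnot(is.data.frame(table), "scenario_id" %in% names(table))
  mps <- utils::read.csv(mps_file, header = TRUE)
  if (!all(c("scenario_id", "mps") %in% names(mps)))
    stop("attach_external_mps: file must have columns scenario_id, mps")
  if (anyDuplicated(mps$scenario_id))
    stop("attach_external_mps: duplicate keys in ", mps_file)
  idx <- match(table$scenario_id, mps$scenario_id)
  if (all(is.na(idx)))
    stop("attach_external_mps: no overlap between table and ", mps_file)
  table$mps <- mps$mps[idx]
  table$mps_matched <- !is.na(idx)
  table
}
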