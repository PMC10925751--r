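#' Quadrature mirror filter pair
#'
#' Analysis filter pair for an orthogonal two-channel filter bank. The
#' high-pass taps are the alternating flip of the low-pass taps,
#' `g_k = (-1)^(k+1) h_(L-1-k)` (0-based), the standard sign/shift convention
#' of the quadrature-mirror relation; any other valid convention differs only
#' by an overall sign and an even circular shift and yields identical
#' sub-band energies.
#'
#' Validated invariants (all to 1e-12):
#' * `sum(h) = sqrt(2)` and `sum(h^2) = 1` (orthonormal scaling filter);
#' * double-shift orthogonality `sum(h_k h_(k+2m)) = 0` for `m != 0`;
#' * `sum(g) = 0`, `sum(g^2) = 1`, and cross-orthogonality
#'   `sum(h_k g_(k+2m)) = 0` for all `m`.
#'
#' @param h Numeric vector of low-pass analysis taps (even length).
#' @param name Filter name, e.g. `"sym2"`.
#' @return An object of class `qmf_pair`: list with `h`, `g`, `name`.
#' @seealso [build_sym2()]
#' @export
qmf_pair <- function(h, name = "custom") {
  h <- as.numeric(h)
  L <- length(h)
  if (L < 2L || L %% 2L != 0L)
    stop("qmf_pair: filter length must be even and >= 2")
  tol <- 1e-12
  if (abs(sum(h) - sqrt(2)) > tol)
    stop("qmf_pair: sum(h) != sqrt(2); not a valid orthogonal scaling filter")
  if (abs(sum(h^2) - 1) > tol)
    stop("qmf_pair: sum(h^2) != 1; taps are not orthonormal")
  for (m in seq_len(L / 2 - 1)) {
    ip <- sum(h[seq_len(L - 2 * m)] * h[seq_len(L - 2 * m) + 2 * m])
    if (abs(ip) > tol)
      stop("qmf_pair: double-shift orthogonality violated at shift ", 2 * m)
  }
  # alternating flip: g_k = (-1)^(k+1) h_{L-1-k}  (0-based k)
  k <- seq_len(L) - 1L
  g <- (-1)^(k + 1) * rev(h)
  structure(list(h = h, g = g, name = name), class = "qmf_pair")
}

#' @export
print.qmf_pair <- function(x, ...) {
  cat(sprintf("<qmf_pair> %s (%d taps)\n", x$name, length(x$h)))
  cat("  h:", format(x$h, digits = 10), "\n")
  cat("  g:", format(x$g, digits = 10), "\n")
  invisible(x)
}

#' Symlet-2 analysis filter pair
#'
#' The 4-tap Symlet-2 orthogonal wavelet filter, computed from its exact
#' closed form `(1 - sqrt(3), 3 - sqrt(3), 3 + sqrt(3), 1 + sqrt(3)) /
#' (4 sqrt(2))`, which reproduces the standard published decomposition
#' low-pass table at full double precision. A compactly supported orthogonal
#' filter with low regularity, suited to short transient impact signals.
#'
#' @return A [qmf_pair()] named `"sym2"`.
#' @examples
#' f <- build_sym2()
#' sum(f$h)   # sqrt(2)
#' sum(f$h^2) # 1
#' @export
build_sym2 <- function() {
  s3 <- sqrt(3)
  h <- c(1 - s3, 3 - s3, 3 + s3, 1 + s3) / (4 * sqrt(2))
  qmf_pair(h, name = "sym2")
}
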