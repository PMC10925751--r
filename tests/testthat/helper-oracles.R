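# Independent oracles and shared fixtures for the test suite.

# --- brute-force HIC oracle: direct trapezoid over every (t1, t2) pair ----
brute_hic <- function(a_g, dt, max_window = 0.015) {
  n <- length(a_g)
  best <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      w <- (j - i) * dt
      if (w > max_window + 1e-12) break
      integ <- sum((a_g[i:(j - 1)] + a_g[(i + 1):j]) / 2) * dt
      cand <- w * (abs(integ) / w)^2.5
      if (cand > best) best <- cand
    }
  }
  best
}

# --- Fourier oracle: frequency-ordered band holding the spectral peak -----
dft_peak_band <- function(x, fs, level) {
  n <- length(x)
  mag <- Mod(stats::fft(x))[1:(n %/% 2)]
  f_peak <- (which.max(mag) - 1) * fs / n
  as.integer(floor(f_peak / (fs / 2^(level + 1))))
}

# --- reference wavelet library oracle (PyWavelets, sym2/periodization) ----
# Batched: one python invocation computes terminal frequency-ordered
# coefficients for every (signal file, level) pair found in `dir`.
pywt_reference_coefs <- function(signals, levels, dir = tempfile("pywt")) {
  dir.create(dir)
  for (nm in names(signals)) {
    writeLines(sprintf("%.17g", signals[[nm]]), file.path(dir, paste0("x_", nm, ".txt")))
  }
  script <- file.path(dir, "ref.py")
  writeLines(c(
    "import sys, glob, os",
    "import numpy as np",
    "import pywt",
    "d = sys.argv[1]",
    "levels = [int(v) for v in sys.argv[2].split(',')]",
    "for f in sorted(glob.glob(os.path.join(d, 'x_*.txt'))):",
    "    name = os.path.basename(f)[2:-4]",
    "    x = np.loadtxt(f)",
    "    for lev in levels:",
    "        wp = pywt.WaveletPacket(data=x, wavelet='sym2', mode='periodization', maxlevel=lev)",
    "        nodes = wp.get_level(lev, order='freq')",
    "        arr = np.vstack([n.data for n in nodes])",
    "        np.savetxt(os.path.join(d, 'coefs_%s_%d.txt' % (name, lev)), arr, fmt='%.17g')"
  ), script)
  status <- system2("python", c(script, dir, paste(levels, collapse = ",")),
                    stdout = FALSE, stderr = FALSE)
  stopifnot(status == 0)
  out <- list()
  for (nm in names(signals)) {
    for (lev in levels) {
      m <- as.matrix(utils::read.table(
        file.path(dir, sprintf("coefs_%s_%d.txt", nm, lev))))
      dimnames(m) <- NULL
      out[[sprintf("%s_%d", nm, lev)]] <- m
    }
  }
  out
}

# --- shared factorial matrix (computed once per test run) -----------------
.matrix_cache <- new.env(parent = emptyenv())
default_matrix <- function() {
  if (is.null(.matrix_cache$res)) {
    .matrix_cache$res <- run_matrix(generate_matrix(master_seed = 1L))
  }
  .matrix_cache$res
}

# quick tone fixture
tone_signal <- function(freq, fs = 5000, n = 4096, amp = 1) {
  accel_signal(amp * sin(2 * pi * freq * (0:(n - 1)) / fs), dt = 1 / fs,
               label = sprintf("tone_%g", freq))
}
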