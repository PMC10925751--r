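---
title: "Methods: wavelet-packet frequency response of blunt head impacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet-packet frequency response of blunt head impacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(impactwave)
```

## The analysis

`impactwave` characterises the frequency content of blunt-impact head
acceleration signals. A signal `x(t)`, uniformly sampled at `fs` Hz, is
pushed down a full wavelet packet tree: at every node the coefficient
sequence is split by a low-pass/high-pass quadrature-mirror pair followed
by dyadic downsampling, and *both* children are split again, so depth `i`
yields `2^i` terminal nodes of equal nominal bandwidth `fs / 2^(i+1)`.
The energy of terminal node `(i, j)` is the sum of its squared
coefficients, and — because the filter pair is orthogonal and the
convolution periodized — the node energies sum exactly to the signal
energy `sum(x_k^2)` (Parseval). Three indicators summarise the spectrum:
the peak sub-band energy, the frequency-ordered index of the peak band,
and the peak's share of the total energy. The Head Injury Criterion is
computed from the same trace for comparison with time-domain practice.

### The filter pair

The basis is the 4-tap Symlet-2 wavelet: compact support (4 samples) and
orthogonality suit short, non-stationary impact transients, at the cost of
poor frequency selectivity (discussed under *Limitations*). The taps are
computed from the exact closed form
`(1 - sqrt(3), 3 - sqrt(3), 3 + sqrt(3), 1 + sqrt(3)) / (4 sqrt(2))` and
validated at construction against the orthonormal-filter identities
(`sum h = sqrt(2)`, `sum h^2 = 1`, double-shift orthogonality, all to
1e-12). The high-pass taps are the alternating flip
`g_k = (-1)^(k+1) h_(L-1-k)` — the convention of the widely used reference
implementations, so coefficient arrays are directly comparable with them;
the other textbook sign/shift conventions of the quadrature-mirror
relation differ only by an overall sign and an even circular shift and
give identical sub-band energies.

### Numerical choices

* **Boundary handling** is periodized (circular) convolution inside the
  filter bank. It is the only extension mode under which the discrete
  transform is exactly orthogonal, which is what makes the
  energy-conservation invariant hold to machine precision rather than
  approximately.
* **Padding**: signals are zero-padded at the tail to the next multiple of
  `2^levels` (an impact window at 5000 Hz is often shorter than 512
  samples). Tail zeros leave `sum(x^2)` unchanged, so the energy budget is
  unaffected; they do interact with the circular boundary, which is one
  reason coefficient-level agreement with a reference library is part of
  the test suite.
* **Node ordering**: the natural (filter-path) order of terminal nodes is
  converted to frequency order with the Gray-code permutation (the
  spectrum is mirrored below every high-pass branch). Band indexing is
  0-based with half-open intervals `[j*df, (j+1)*df)`, so "index times
  bandwidth" is the band's lower edge. The published description of the
  peak-band indicator does not fix 0- vs 1-based indexing or the node
  ordering; the frequency-ordered, 0-based convention adopted here is the
  one under which the index maps to a physical frequency band.
* **Tie-break**: equal maximal band energies resolve to the lowest band
  index — arbitrary but deterministic; ties do not arise in practice.
* **Degenerate inputs**: an all-zero spectrum raises an explicit
  degenerate-signal error rather than returning 0/0; signals must have at
  least 2 finite samples and a strictly positive sampling interval; CSV
  input is rejected when successive time stamps deviate more than 0.1%
  (relative) from the median step — loose enough for solver output jitter,
  tight enough to catch resampled or event-based traces.

### HIC

`compute_hic()` searches every sample-aligned window of width up to the
cap (default 15 ms, i.e. HIC15; 36 ms is a flag away — the variant used in
the source literature is not stated, and no published HIC value depends on
the choice here) using a cumulative trapezoidal integral, after converting
to g (the criterion is defined on g). Signed samples are used as given;
a maximizing window with negative mean contributes through its magnitude
with a warning, and a rectify flag is available. Windows are not optimised
below the sampling interval; at 5000 Hz the induced error is negligible
relative to the 2.5-power amplification of the mean.

## The synthetic impact study

No public data accompany the source analysis, so the factorial study runs
on a lumped-parameter surrogate of the finite-element setup: a rigid
cylindrical impactor of the design's material and size strikes a two-mass
skull–brain model through a unilateral (compression-only) linear contact
spring, the skull being weakly grounded to represent the occipital
fixation.

The design factors are the full 3×3×3×3 factorial: position
(right/front/top), material (rubber/glass/steel, with density 1.829e-6 /
2.5e-6 / 7.8e-6 kg/mm³, Young's modulus 4 / 70000 / 210000 MPa, Poisson's
ratio 0.45 / 0.23 / 0.3), velocity (2/6/10 m/s) and block size (12.5, 25,
37.5 mm diameter × 12 mm thickness — the size labels are read as
diameter × thickness; a radius reading would change areas fourfold and is
stated nowhere).

Parameter choices, with rationale:

* **Head masses**: skull 1.5 kg + brain 3.0 kg ≈ 4.5 kg total, an adult
  head.
* **Skull–brain coupling** `k_sb = 2.5e4` N/m puts the coupled mode at
  ~25 Hz, inside the 14–35 Hz fundamental-frequency range reported for the
  human head; damping `c_sb = 63` N·s/m gives damping ratio ≈ 0.2,
  under-damped as the literature describes.
* **Occipital grounding** `1e4` N/m: a weak constraint that returns the
  head to rest without adding a stiff mode.
* **Contact stiffness**: the block's axial stiffness `E·A/t` (monotone in
  modulus and face area) is scaled by 0.01 — local indentation of a curved
  skull engages far less compliance than uniform axial compression of the
  whole cylinder — and combined in series with a 6e5 N/m scalp stiffness.
  These two constants were chosen once so that the surrogate shows the
  qualitative pattern expected of the real system: a soft slow impact
  (rubber, 2 m/s) concentrates its energy below 100 Hz, while a stiff fast
  one (steel, 10 m/s) produces a short pulse whose energy sits well above
  it; they also keep every contact-pulse frequency inside the 2500 Hz
  analyzable band.
* **Position factors** 0.9/1.0/1.1 on contact stiffness
  (right/front/top): a deliberately weak, sub-rank-resolution effect —
  impact position is the factor the analysis should find non-significant.
* **Integration**: fixed-step classical Runge–Kutta 4 with step at most
  `1/(50·f_max)` for the stiffest undamped mode `f_max` of the engaged
  system, followed by an energy audit over the whole trace (undamped runs
  must conserve mechanical energy to 0.1%; damped runs must never gain
  more than 1%); audit failure aborts with advice to reduce the step.
* **Noise**: additive white Gaussian noise at a configurable SNR is
  available but off by default — the emulated solver outputs are
  noiseless. Noise seeds derive per scenario from the master seed, and the
  generator restores the caller's RNG state.

### What the surrogate does and does not emulate

It reproduces the *structure* of the study — amplitude and frequency
content varying with velocity, material, size and (weakly) position, an
under-damped low-frequency head mode, impulse-like loading — and is
therefore suitable for testing that the analysis pipeline recovers such
structure: monotone velocity and material orderings of peak energy and
HIC, their significance pattern, and the correlation of peak energy (but
not peak position or proportion) with HIC. It does **not** emulate
finite-element specifics: no distributed skull modes, no CSF layer, no
rotational kinematics, no tissue strain — so maximum principal strain is
accepted only as an externally supplied column (`attach_external_mps()`),
and the surrogate's absolute energy and HIC magnitudes, and the specific
multi-region energy-concentration patterns of a full head model, carry no
biofidelic meaning. Passing tests show the pipeline recovers imposed
structure, not that the surrogate predicts real head response.

## Statistics

Factor influence is tested marginally — each factor's three groups pool
the 27 combinations of the other factors — with the Kruskal–Wallis rank
test (the appropriate non-parametric test for 3+ independent groups; the
source analysis names no specific test). P-values are reported raw, one
per factor × indicator cell, without multiplicity correction, mirroring
tabulated per-cell practice; the output schema flags this. Responses are
min–max normalized to [0, 1] for distribution plots (z-scoring behind a
flag); constant columns are rejected. Indicator-vs-criterion association
uses ordinary least squares with `R² = 1 - SS_res/SS_tot`; a constant
response returns R² = 0 with a degenerate-fit warning.

## Problem sizes in the test suite

The suite exercises: energy conservation on 100 random signals of 300–5000
samples across depths 1–9; coefficient-level agreement with an independent
reference wavelet library on lengths 512/1024/4096 at depths 1/2/5/9 (to
1e-10); 20 random tones against a Fourier-peak oracle; 50 random pulses of
HIC against an exhaustive brute-force window search (to 1e-9 relative);
the 81-scenario factorial at 0.2 s × 5000 Hz; and 200 null replicates of
the rank test (3 groups × 20) for its type-I error. These sizes make the
properties sharp while keeping a full run to well under a minute per
module.

## Known limitations

* **Frequency selectivity of sym2.** A 4-tap filter has wide, overlapping
  band responses. Within roughly ±50 Hz of the *coarse* dyadic split
  frequencies (multiples of `fs/16`, most visibly around `fs/4` =
  1250 Hz), spectral leakage can place a pure tone's argmax band several
  terminal bands away from the band nominally containing the tone — about
  1–2% of the frequency axis at the default settings, and identically so
  in the reference library, since it is a property of the basis, not of
  the implementation. Away from those neighbourhoods, localization is
  within one band of the Fourier prediction. Peak-band *indices* near
  coarse split edges should therefore be read with that leakage in mind.
* The HIC window variant (15 vs 36 ms) is a configuration choice, as the
  source literature leaves it unstated.
* The surrogate's contact model is linear and unilateral, not Hertzian;
  its constants are tuning choices documented above, not measured head
  properties, and are not claimed to reproduce any finite-element model.
* The pipeline analyzes a scalar acceleration channel; whether that
  channel is a resultant magnitude or a single component is left to the
  data producer.
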