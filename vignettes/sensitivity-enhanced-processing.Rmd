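---
title: "Sensitivity-enhanced high-dimensional NMR: model, processing and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sensitivity-enhanced high-dimensional NMR: model, processing and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdnmr)
```

## The problem

Proton-detected magic-angle-spinning solid-state NMR resolves the backbone
resonances of large proteins by spreading correlations into four- and
five-dimensional chemical-shift space. The price is sensitivity: every
phase-sensitive indirect dimension that is encoded with a conventional
cross-polarization (CP) transfer keeps only one of the two transverse
magnetization components, losing a factor of sqrt(2) in SNR per dimension,
and the sheer number of time increments forces non-uniform sampling (NUS)
with its signal-dependent point-spread-function (PSF) artifacts.

Preserved-pathway transfers (transverse-mixing optimal-control pulses)
carry *both* components through a transfer at some bulk efficiency `b`
relative to the CP version, encoded echo-antiecho. `hdnmr` implements the
computational side of this methodology as a desk-scale simulator: the
hypercomplex data model and quadrature processing, a transfer-amplitude
signal model, NUS with direct nuFT and PSF computation, a generic
iterative-thresholding reconstruction, the plane-based SNR estimator, and
the closed-form enhancement calculus. Everything the package claims
numerically is computed by the test suite or by `scripts/acceptance.R`.

## Signal model

The simulator abstracts the transfer physics to amplitude bookkeeping. For
a resonance with per-dimension offset `Omega` (Hz), amplitude `a` and decay
`R` (1/s), each component FID is a separable product over dimensions:

* direct dimension: `a * exp(i 2 pi Omega t - R t)`;
* CP/States dimension: `cos(2 pi Omega t) e^(-R t)` or `sin(...) e^(-R t)`
  (one retained component, unit relative amplitude; States-TPPI adds the
  `(-1)^k` alternation that shifts apparent frequencies by half a spectral
  width);
* preserved-pathway dimension: `b * exp(+/- i 2 pi Omega t - R t)` for the
  echo/antiecho component.

Independent complex Gaussian noise of standard deviation `sigma` is added
to every recorded point of every component FID; thermal noise is
receiver-determined, so the same `sigma` applies to the enhanced and the
conventional experiment of equal duration. No spin dynamics, pulse
imperfections or water-suppression effects are modelled: the enhancement
calculus and the NUS phenomenology studied here depend only on the bulk
amplitude `b`, the component count, and the noise, which is exactly what
the amplitude model carries. Consequences: simulated lineshapes are ideal
zero-phase Lorentzians; site-specific transfer variation can only be
mimicked by per-resonance amplitudes; and passing tests validate the
processing chain and the statistical claims, not any particular pulse
implementation.

## Quadrature conventions

The package fixes one Rance-Kay convention and records it in all
provenance: echo is the `+Omega` (p-type) pathway, the cosine component is
`(E + A)/2`, and the sine component `(E - A)/(2i)` (the division by `i` is
the 90-degree zero-order phase). With this scaling a noiseless
echo-antiecho data set recombines to *exactly* the States encoding of the
same resonances, which turns the States-equivalence check into an exact
oracle, and the sqrt(2) gain appears purely through noise propagation: two
components with independent noise `sigma` combine to components with noise
`sigma/sqrt(2)`.

Axes are reported in ppm via `ppm = carrier + offset_Hz / observe_MHz`,
increasing, with 0-based time indices and the carrier at the centre of the
spectral width. Hypercomplex data are stored as a single real array,
component axes first; the hypercomplex Fourier transform is a per-dimension
complex FT pairing that dimension's two components, which keeps the
operator invertible (needed by the reconstruction) and yields the purely
absorptive spectrum as the all-real component — equal, for zero-phase
signals, to conventional sequential real-part processing. Echo-antiecho
dimensions must be recombined before their Fourier transform or any
reconstruction; the processing functions refuse to continue otherwise,
since silent processing of unrecombined data is the classic failure mode
of this workflow. Recombination is a per-increment linear operation, so it
commutes with sampling masks and with transforms of other dimensions;
States and echo-antiecho dimensions can therefore be processed in any
order, and a property test asserts the resulting spectra are identical.

## Processing defaults

Default processing is deterministic and minimal: no apodization,
zero-filling x2, no first-order phase, no first-point scaling. Exponential
and half-cosine windows are available where tests need leakage control.
Exactness-oriented tests (States equivalence, PSF convolution, nuFT
identities) use zero-fill x1 and on-grid frequencies so that the discrete
identities hold to rounding error rather than to leakage level.

## Non-uniform sampling

A schedule is a subset of the indirect time grid; one sampled point means
all `2^n` hypercomplex components of that increment. The origin is always
kept. Generators: `uniform_random` and `exponential_biased` (weights
`exp(-sum(bias_i k_i / N_i))`, default decay 2 per dimension), both seeded
and reproducible; schedules are exchanged as plain text, one 0-based
multi-index per line. The reference material for this methodology does not
specify its schedule generator or densities, so these defaults are the
package's own choice and are logged with every run; NUS-dependent results
are therefore asserted as stochastic trends, not as point values.

The PSF is the Fourier transform of the schedule's indicator mask,
normalized to 1 at zero frequency, real part retained to match the
real-part processing chain. For a single masked indirect dimension the
convolution identity is exact and tested at 1e-10: the nuFT spectrum of an
on-grid noiseless resonance is its height times the circularly shifted
PSF.

## Iterative-thresholding reconstruction

The in-repo reconstruction is a deliberately generic iterative hard/soft
thresholding stage: transform the current residual (zeros at unsampled
increments), move the part of every spectrum point above
`threshold * current max` into an accumulating model, and restore the
measured values at sampled increments of the residual; the final residual
spectrum is added back to the model. Design choices worth noting:

* *Residual re-insertion* makes the full-sampling case exactly equal to
  the plain FT regardless of iteration count, and keeps the returned model
  exactly data-consistent at sampled points.
* *Thresholds* act on the hypercomplex point magnitude (root sum of
  squares over the `2^n` components), which is invariant under frequency
  shifts and phase conventions. They are computed per direct-dimension
  plane by default (`per_plane`), matching how high-dimensional spectra
  are reconstructed as stacks of planes.
* *Zero-filled points are treated as measured zeros*, so zero-filling
  commutes with reconstruction and the full-sampling identity holds at any
  zero-fill.
* Defaults (`n_iterations = 100`, `threshold_start = 0.98`, constant
  threshold) favour safety on noisy data; the sparse noiseless oracle
  fixtures in the tests use a lower threshold (0.9) and more iterations,
  where the algorithm recovers on-grid peak sets to numerical precision.
  Truncated, unapodized decaying signals are *not* sparse (their
  sinc-skirts carry significant energy), and reconstruction quality
  degrades accordingly — the reason the artifact-suppression oracle uses
  on-grid non-decaying peaks.

No parity with any external reconstruction program is claimed; the stage
exists so that reconstruction-dependent claims can be exercised
reproducibly in-repo.

## SNR estimation

`plane_snr` implements the robust plane-based estimator: `n_points = 100`
random grid points (without replacement, seeded) outside an exclusion
rectangle around the peak (default half-widths 1.0 ppm on an amide-proton
axis and 2.5 ppm on a nitrogen axis, generalized to arbitrary per-axis
widths); the mean of the sampled values is subtracted from the peak
intensity, the noise level is their standard deviation, and
`snr = corrected intensity / noise level`. Mean subtraction makes the
estimate exactly invariant under constant offsets; a zero-variance plane
raises an error rather than returning infinity. The noise statistic is
taken to be the standard deviation throughout, including in the
pre/post-reconstruction noise comparison, where the reference material
leaves the exact statistic open. On crowded synthetic planes the Monte
Carlo tests additionally exclude the other known peaks
(`exclude_other_peaks`), since with only a handful of strong synthetic
resonances a single contaminated noise point biases the estimate in a way
that real, peak-dense spectra average out.

## Enhancement calculus

For `n` enhanced indirect dimensions at bulk `b`, the expected enhancement
is `E = b * 2^(n/2)`; the break-even bulk is `2^(-n/2)`; the time to reach
the conventional experiment's SNR is the fraction `1/E^2`. The
measurement-time multiple relative to the 2D amide reference experiment
(hNH) is `2^(n_indirect - 1) / (s E)^2`, where `s` is the first-FID signal
as a fraction of the hNH and `2^(n_indirect - 1)` counts hypercomplex FIDs
per sampled increment relative to the hNH's single indirect dimension.
This last formula is a reconstruction by the package authors — it is
validated by reproducing every printed cell of the reference panel before
being frozen, and lives in a single documented function.

Rounding: all intermediates stay unrounded; reported values are rounded at
the last step (two significant figures for `E`, two decimals for time
fractions, per-row printed precision for the hNH multiples — two
significant figures except one row conventionally printed at three). The
well-known "7.8-fold" time saving of a triple enhancement arises from
squaring the already-rounded 2.8 rather than the exact `2^3 = 8`; both
conventions are implemented (`time_saving_factor`) and the one used is
attached as an attribute.

## The non-linearity study

`nonlinearity_study` reproduces, as a simulation, the mechanism by which
reconstruction makes enhancement *more* than multiplicative: sampling
artifacts are proportional to peak intensity while thermal noise is not,
and thresholding algorithms remove artifacts the better the higher the
per-peak SNR. The study uses a 2D system of three on-grid, non-decaying
resonances (so every off-peak amplitude is either thermal noise or a
sampling artifact), one enhanced dimension at `b = 1`, 40 % uniform
sampling, and a ladder of noise levels spanning buried-in-noise to
artifact-limited peaks (default `sigma` 6, 1.5, 0.4, 0.1 against a unit
amplitude; 20 seeds per level in the acceptance suite). Reported per
level: the enhanced/conventional effective-noise ratio before (nuFT) and
after reconstruction, and their quotient, the extra gain. The asserted
facts are trends — the extra gain grows along the ladder, the
post-reconstruction ratio beats the nuFT ratio at high SNR, and the extra
gain is absent (within 0.15 of 1) at the lowest SNR. Absolute magnitudes
measured on real deposited spectra are out of scope, as they depend on the
actual schedules, lineshapes and reconstruction software used there.

Note one scaling difference from figures produced with spectra scaled to a
common noise level: in this package's unscaled simulation the enhanced
spectrum's thermal noise is *lower* (by `sqrt(2)` per dimension) at equal
artifact level, so the pre-reconstruction noise ratio sits below 1 in the
thermal-dominated regime and approaches 1 as artifacts dominate. The extra
gain, being a ratio of ratios, is invariant to this convention.

## Problem sizes and determinism

All shipped fixtures run end-to-end in seconds: the 2D fixtures use 16
indirect x 64 direct points, the 3D fixtures 12 x 12 x 48, the 4D and 5D
fixtures 8 and 6 points per indirect dimension. The Monte Carlo checks use
200 realizations (2D, sqrt(2) recovery), 60 (3D, factor-2 recovery) and
4 x 20 (non-linearity ladder); these sizes put the standard errors well
inside the asserted tolerances while keeping the whole suite under a
minute of compute. Every stochastic element — noise, schedules, noise-point
sampling, fixture peak placement — is seeded, and derived seeds are
reported in every run summary, so identical configurations reproduce
bit-identical outputs including the JSON summaries.

## Known limitations

* The transfer model is amplitude bookkeeping; no spin dynamics, phase
  errors, or site-specific transfer profiles (beyond per-resonance
  amplitudes).
* The reconstruction is a generic IST; quantitative agreement with
  dedicated reconstruction packages is not claimed, and heavily
  non-sparse (truncated, unapodized) signals reconstruct poorly.
* The native spectrum container is package-specific (binary array + JSON
  sidecar with a bit-exact round trip); no external spectrum format is
  written.
* Water suppression interacts with preserved-pathway encoding only as an
  ordering constraint in real experiments; it is documented here but has
  no computational counterpart.
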