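---
title: "Time-frequency nonlinear Granger causality with wavelet packets and polynomial NARX models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-frequency nonlinear Granger causality with wavelet packets and polynomial NARX models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wptgc)
```

## The problem

Corticomuscular coupling -- the directed functional connection between the
sensorimotor cortex (observed through EEG) and the active muscle (observed
through surface EMG) -- is band-specific, bidirectional, nonlinear and
non-stationary. Coherence-style measures give no direction; classical
linear Granger causality misses quadratic interactions; and whole-segment
estimates hide the evolution of coupling across movement preparation and
execution. `wptgc` implements an analysis that addresses all three at
once:

1. each signal is split into narrow, uniform frequency bands by a
   wavelet packet transform (WPT);
2. within each band, a polynomial (linear + quadratic) NARX model is
   identified in short sliding windows by forward-regression orthogonal
   least squares (FROLS);
3. directed Granger causality (GC) is computed per band and per window as
   a log ratio of restricted-to-full model prediction-error variances,
   giving one time-frequency causality map per direction.

## The statistic

For series $x(t), y(t)$, a restricted model predicts $y(t)$ from its own
past only, and a full model also uses the past of $x$:

$$G_{X \to Y} = \ln \frac{\operatorname{var}(Y \mid Y^-)}
                         {\operatorname{var}(Y \mid Y^-, X^-)} .$$

Both models are polynomial autoregressions with all lags $1..p$ (own) and
$1..q$ (input) as linear terms plus all unordered pairwise lag products
(quadratic terms). With the defaults $p = q = 5$ the restricted dictionary
has 20 candidate terms and the full one 65. The population value of
$G_{X \to Y}$ is non-negative; negative finite-sample estimates are
clamped to zero in maps and summaries, with the raw value retained in the
result object.

## Model identification

FROLS selects terms greedily: each remaining candidate is orthogonalized
(classical Gram-Schmidt) against the already-selected regressors, its
error reduction ratio (ERR, the fraction of target energy it explains) is
computed on the orthogonalized version, and the best candidate is taken.
Parameters come from the unit-upper-triangular system by back-substitution
and are then refit by ordinary least squares on the selected columns
(refit is the default; the orthogonal-stage estimates are also available).

**Stopping rule.** The literature often stops when the unexplained energy
fraction drops below a fixed threshold $\rho$. That rule fails across the
dynamic range this package must cover: a narrowband (sub-Hz) signal is
more than 99% predictable from its own past, so a fixed target is reached
by own-past terms alone and genuinely informative input terms are frozen
out, while on noisy windows the same rule lets junk terms accumulate. The
operative default here is instead a *relative, selection-aware* rule: a
term is accepted only if its ERR exceeds

$$\frac{\log N + 2\log M}{N} \times (\text{energy still unexplained}),$$

a BIC-type penalty inflated by $2\log M$ because the term is the best of
$M$ candidates (the expected maximum ERR of a pure-noise candidate is of
order $2\log M/N$ of the remaining energy). The classical $\rho$ rule and
the hard cap `n_max` (default 10) remain available; `rho = 0` disables
the former by default.

**Fair nesting.** The full model's FROLS run starts from the restricted
model's selected terms (forced in) and continues over the full dictionary.
This guarantees $\operatorname{var}(Y|Y^-,X^-) \le
\operatorname{var}(Y|Y^-)$ up to rounding -- so clamping only ever removes
estimation noise -- and it lets input terms compete for the energy the own
terms leave unexplained rather than for a share of the total. Without
forced nesting, independent selections can produce spuriously negative GC,
and on nearly deterministic band signals the full model never admits an
input term at all.

## The wavelet packet front end

The WPT is a full binary filter-bank tree: unlike the plain wavelet
transform it also splits the highpass branch, so depth $j$ tiles
$[0, f_s/2)$ with $2^j$ bands of uniform width $f_s/2^{j+1}$ -- at
$f_s = 250$ Hz and $j = 7$, 128 bands of 0.9766 Hz (nominally "1 Hz").
Three implementation choices matter:

* **Coiflet order.** The family member is configurable; the default is
  `coif5`, whose 30-tap filters give the sharpest band edges in the
  family. Filter coefficients are embedded constants.
* **Periodized boundaries.** The signal is zero-padded to the next
  multiple of $2^j$ and each analysis step uses circular convolution, so
  the whole transform is an orthogonal matrix: coefficient energy equals
  signal energy and the summed terminal-band reconstruction differs from
  the input only by floating-point rounding (MSE $\approx 10^{-31}$,
  comfortably below the $10^{-20}$ acceptance bound). Symmetric or
  zero-padding extension would break exactness.
* **Sequency ordering.** The natural (filter-tree) node order is not
  frequency order: every highpass split mirrors its branch spectrum.
  Ascending frequency corresponds to the binary-reflected Gray-code
  permutation of the natural index. Skipping this permutation silently
  selects wrong bands above the first level; the mapping is verified in
  the tests by maximum-energy localization of pure tones.

Band extraction reconstructs a single terminal node to full length with
all other nodes zeroed. A frequency $f$ selects the node whose half-open
interval $[k\,\Delta f, (k+1)\Delta f)$ contains it.

**What a band can and cannot carry.** Two caveats are inherent to the
method, not to this implementation. First, a critically sampled WPT is
shift-variant: the band image of a delayed signal is not the delayed band
image, which caps the attainable cross-band correspondence between two
independently decomposed signals (empirically, lagged correlations of
about 0.5 for strongly coupled narrowband pairs). Second, a mid-band pure
tone keeps only about 75% of its energy in its own 0.98 Hz band with
`coif5` at depth 7 -- the rest leaks through the filter transition bands
into the neighbours. The maximum-energy band is still always the correct
one; claims of near-total energy concentration at this resolution are not
achievable with compactly supported filters.

## Time variation

Time-varying coefficients are handled by the short-time-invariance
assumption: within a window of length $\Delta t$ centred at $t_n$ the
model is treated as constant, fitted from scratch (including term
selection), and the window slides by `step`. Defaults are $\Delta t = 1$ s
and step 0.1 s at 250 Hz, giving about 250 samples per window for a
65-term dictionary.

**Time-bandwidth warning.** For *band-limited* inputs the effective
sample count per window is roughly $2 \times \text{bandwidth} \times
\Delta t$ -- about 2 for a 1 Hz band in a 1 s window. Windowed GC at full
band resolution is therefore statistically vacuous; the window must scale
with the reciprocal bandwidth. The frequency-localization acceptance test
consequently uses the whole segment as a single window (to which the
sliding-window estimator exactly reduces), and broadband step-tracking
uses 1 s windows. This trade-off is intrinsic to any time-frequency
causality method and is the main practical limitation of the approach.

## Significance and statistics

Per-cell significance uses circular-shift surrogates of the putative
cause: shifting by a random offset destroys causal alignment while
preserving marginal and spectral structure; the threshold is the
$\lceil(1-\alpha)(n_{\text{surr}}+1)\rceil$-th order statistic (with 19
surrogates and $\alpha = 0.05$, the surrogate maximum). Under sparse
selection the GC estimate has an atom at exactly zero, which makes the
test conservative (observed false-positive rates near zero); setting
`err_min_frac = 0` forces every fit to its full term budget, restoring a
continuous statistic with exact nominal calibration, at the cost of a
higher overfitting floor. Both modes are exposed and tested.

Group comparisons follow a gate: Shapiro-Wilk normality per group and
Brown-Forsythe (median-centred Levene) homogeneity at 0.05 route the data
to one-way ANOVA when both pass and to Kruskal-Wallis otherwise. The gate
tests are a documented choice; the source analysis names the gate but not
the tests.

## Preprocessing chain

`preprocess_chain()` runs common-average referencing (multi-channel EEG
only), zero-phase 1-60 Hz Butterworth bandpass (4th-order prototype per
pass, applied forward-backward through second-order sections -- expanded
polynomial forms of narrowband filters are numerically unusable),
anti-aliased integer decimation to 250 Hz, segmentation into 3 s
preparation + 4 s execution trials around supplied onsets, baseline
correction by the preparation-window mean, per-channel z-scoring over the
concatenated segment, and trial averaging. Baseline correction precedes
normalization; this order is a convention of this package, not a datum.
Artifact removal (ICA, component classification, line-noise cleaning) is
out of scope: the chain expects cleaned signals.

## Synthetic ground truth

The generator family covers every tested behaviour with known truth:

* `linear_unidirectional`: $y(t) = 0.8y(t-1) + 0.5x(t-1) + e$ with unit
  white noise; the restricted innovation variance is $1 + 0.25$, so the
  true GC is $\ln 1.25 \approx 0.223$ in one direction and 0 in the other.
* `quadratic_unidirectional`: $y(t) = 0.5y(t-1) + 0.6x(t-1)^2 + e$;
  invisible to a degree-1 dictionary because all odd moments vanish.
* `step_coupling`: the cross-term switched on at the midpoint of a 10 s
  segment.
* `banded_20hz`: AR(2) resonators (pole radius 0.97) at 20 Hz (x) and
  10 Hz (y's own rhythm) with lagged 20 Hz coupling, plus broadband
  floors. Within a ~1 Hz band a signal is almost perfectly predictable
  from its own past, so the detectable band-level GC is of order
  $\ln(1 + \text{band innovation}/\text{in-band broadband power})$ --
  small (0.01-0.05) even for strong coupling; the generator keeps the
  broadband floor in $y$ low (sd 0.2) so the coupled band dominates.
* `null_pair`: independent AR(1) processes for floors and calibration.

Innovations are Gaussian, seeds are explicit everywhere, burn-in is 500
samples, and generation aborts if any sample exceeds $10^6$. What the
generators do *not* emulate: volume conduction, electrode artifacts,
nonstationary noise floors, or multi-channel structure -- a green test
establishes correctness of the estimator on its stated model class, not
field performance on raw recordings.

## Numerical choices

* Variance normalizer: residual variances divide by the number of
  predicted samples ($N - \max(p,q)$), the count of residuals that exist.
* Degenerate candidates (orthogonalized norm below $10^{-12}$ of the
  original) are skipped; a re-orthogonalization pass runs when loss of
  orthogonality against the selected set exceeds $10^{-8}$.
* The GC log ratio refuses full-model variances below $10^{-15}$.
* No intercept term: inputs are z-normalized upstream (an optional
  intercept would be identically confounded with the quadratic terms'
  means on short windows).
* Filter initial conditions use steady-state states per second-order
  section with odd-reflection padding of one low-edge period.

## Known limitations

* Bivariate only: no conditional/multivariate GC, no spectral (Geweke)
  decomposition.
* Quadratic polynomial ceiling; no cubic terms or basis-expanded
  time-varying coefficients.
* Integer-factor resampling only.
* Shift-variance of the critically sampled WPT bounds cross-band model
  fit quality (see above); an undecimated transform would remove this at
  8x the cost and is not implemented.
* The surrogate test with the sparse default statistic is conservative,
  not exact.
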