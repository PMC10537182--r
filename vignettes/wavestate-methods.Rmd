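---
title: "Ensemble wavelet decomposition for EEG mental-state detection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble wavelet decomposition for EEG mental-state detection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavestate)
```

## The problem

Brain-computer interfaces for safety-critical settings (driving, train and
flight operation) need to tell whether an operator is focused, unfocused or
drowsy from scalp EEG. `wavestate` implements a complete detection pipeline
for this three-state problem: multichannel recordings (the reference
configuration is a 14-channel consumer headset at 128 Hz, band-limited
0.2-43 Hz on the device) are cut into 30 s non-overlapping segments of
3840 samples, each segment is decomposed per channel by three different
wavelet filter banks, 27 statistical and nonlinear features are computed per
subband signal, features are ranked by minimum-redundancy maximum-relevance
(mRMR) and fused across the transforms, and an optimizable ensemble
classifier is evaluated under holdout (80:20), five-fold and ten-fold
cross-validation, optionally followed by iterative majority voting (IMV)
over repeated ten-fold rounds.

Using three filter banks at once is the point of the design: the dyadic
MDWT, the tunable Q-factor transform (TQWT) and the flexible analytic
wavelet transform (FAWT) tile the time-frequency plane differently, so their
subband features carry complementary information, and fusing the top-ranked
features from each is more accurate than any single transform.

## The three filter banks

**MDWT.** A classical orthogonal cascade: each level splits the current
approximation with a pair of quadrature-mirror filters and downsamples by
two. Defaults are the `db2` wavelet and 4 levels, which at 128 Hz maps the
five subbands onto the five classical EEG rhythms (SB-1 = 32-64 Hz gamma
range down to SB-5 = 0-4 Hz delta). Boundary handling is half-sample
symmetric extension with full-length coefficient retention, so the cascade
inverts to machine precision (the round-trip error tolerance used in the
tests is 1e-8). Daubechies scaling coefficients db1-db10 are built in.

**TQWT.** An oversampled two-channel bank parameterized by a quality factor
`q` (default 2), an oversampling rate `R` (default 5) and `B` levels
(default 7). The derived factors are `beta = 2/(q+1)` (high-pass band
fraction) and `a = 1 - beta/R` (low-pass shrinkage per level); for the
defaults `beta = 2/3` and `a = 13/15` exactly. We implement it directly in
the DFT domain: at each level the spectrum is split by complementary
windows, with the transition shaped by the 2-vanishing-moment Daubechies
frequency response `theta(w) = (1 + cos w) sqrt(2 - cos w) / 2`. Because
`theta(w)^2 + theta(pi - w)^2 = 1`, the analysis/synthesis pair is a tight
frame and reconstruction is exact up to floating-point rounding. Ideal
subband lengths are rounded to the nearest even integer; the synthesis bank
uses the stored actual lengths.

**FAWT.** A rational-rate bank: the low-pass channel resamples by `p/q`
(defaults 3/5) and the high-pass channel by `r/s` (defaults 2/3), with
*analytic* (one-sided, complex) high-pass atoms. The band edges follow

```
wp = ((1-beta) pi + eps)/p    ws = pi/q
w0 = ((1-beta) pi + eps)/r    w1 = p pi/(q r)
w2 = (pi - eps)/r             w3 = (pi + eps)/r
```

and the constructor validates `wp < ws` and `w0 <= w1 <= w2 < w3`. The
factors `beta` and `eps` are tied to perfect reconstruction but their values
are a design choice; we default to `beta = r/s` and
`eps = ((q - p)/(q + p)) pi`, both overridable. Implementation is again
per-bin in the DFT domain: the low/high crossover shares a Daubechies
transition, and the analytic band's upper taper is mirrored across the
Nyquist bin (which, being self-mirrored, keeps full weight) so that squared
window weights sum to one on every bin. Band edges are snapped to each
level's DFT grid; reconstruction in practice reaches machine precision and
is tested against a 1e-6 tolerance that allows for the rational-resampling
rounding. Each high-pass subband is delivered as a real signal (twice the
real part of the analytic subband); the complex form is kept internally and
used for reconstruction.

Subband indexing is uniform: SB-1 is the highest-frequency band, the final
subband is the low-pass residue, and `levels + 1` subbands are produced by
every transform. Reference material on this family of methods does not pin
down an indexing convention, so ours is stated explicitly and carried in
`subband_rhythm_map()`, which reports each subband's nominal Hz span.

## The 27 features

The feature list mixes amplitude statistics (standard deviation, IQR,
trimean, peak/minimum/peak-to-peak, V-order), energy measures (average,
absolute, simple square integral, log energy, fractional-power sums),
difference-based waveform complexity (wavelength, DASDV, normalized
first/second differences, difference variance, slope-sign changes,
zero-crossing rate, Hjorth mobility), shape moments (skewness, kurtosis) and
nonlinear dynamics (Hurst exponent, Higuchi fractal dimension, largest
Lyapunov exponent). The exact formulas are fixed in the documentation of
`compute_feature()`; choices worth calling out:

- **Hurst exponent**: rescaled-range analysis over logarithmically spaced
  window sizes in `[10, N/2]`, with the Anis-Lloyd-Peters finite-sample
  correction applied by default. The raw R/S slope is biased upward by
  roughly 0.05 at these lengths (white noise estimates near 0.55); the
  corrected estimator is centred at 0.5, which is what the white-noise
  sanity checks assert. `corrected = FALSE` restores the raw slope.
- **Largest Lyapunov exponent**: the Rosenstein nearest-neighbour
  divergence method with embedding dimension 10, unit delay, a Theiler
  window of one mean period (from zero crossings) and a fit over the first
  20 divergence steps, reported in nats per sample. For long signals at
  most `max_ref = 512` reference points (evenly strided) are used; the
  neighbour search itself is exact (a sorted projection bound prunes it
  without changing the result).
- **Higuchi fractal dimension** with `kmax = 10`.
- Fractional powers act on `|x|` (the features are defined through absolute
  values and would otherwise be undefined for negative samples), and
  `log energy` carries a `1e-12` additive floor.
- Degenerate inputs are mapped to defined values instead of NaN: on a
  constant signal the sigma-normalized differences return 0 with a warning,
  and the Lyapunov exponent returns 0.
- The printed feature list of this family of pipelines contains "peak
  amplitude" twice; we resolve the duplicate as maximum, minimum and
  peak-to-peak, which keeps 27 distinct columns.

Every estimator parameter (`v`, `kmax`, embedding settings, the exponential
root power) is overridable per `FeatureSpec`. A 14-channel segment yields
`14 x 27 = 378` columns per subband.

## Ranking and fusion

Relevance and redundancy are mutual information estimates after
equal-frequency discretization into 10 bins (MI is computed in nats and
reported in bits). Ranking granularity is the feature *type*: a type's
relevance is the mean MI with the class over its channel columns, and
redundancy between two types is the mean MI over channel-matched column
pairs. The greedy scheme is MID (difference): the first pick maximizes
relevance; each later pick maximizes relevance minus mean redundancy with
the already-selected types. MID rather than the quotient variant (MIQ) is
the standard default and is stable when redundancy is near zero; ties break
by the canonical feature-list order, constant columns get relevance 0 and
rank last. Column-level ranking is available behind
`granularity = "column"`.

`select_top(fm, ranking, k)` keeps all channels of the `k` best types;
`fuse_features()` concatenates the per-transform selections (so three
14-channel matrices at `k = 4` give 168 columns). The fusion default in the
pipeline uses each transform's best subband; with `subbands$mode = "auto"`
the best subband is discovered by a per-subband cross-validated screen with
a fixed bagged-tree ensemble, and with `"fixed"` (the default) the
configured indices are used — SB-1 for MDWT and TQWT and the final subband
for FAWT, the combination reported as strongest for the reference dataset.

## Ensemble classification and evaluation

Five ensemble methods share a majority-vote interface: bagged trees
(bootstrap resamples of full training size; degenerate single-class
resamples are redrawn), boosted trees (multiclass SAMME with a
learning-rate shrinkage), RUSBoost (the same boosting loop with the
majority classes randomly under-sampled to the minority count each round,
weighted by the current boosting weights), random-subspace k-NN and
random-subspace linear discriminant. Trees are `rpart` with `cp = 0` and a
depth cap equivalent to the requested split budget; k-NN and LDA come from
`class` and `MASS`. The "optimizable ensemble" is a seeded random search
across the five methods with log-uniform draws for ensemble size
`[10, 500]`, learning rate `[1e-3, 1]` and split budget `[1, n-1]`, and
uniform draws for subspace dimension `[1, d/2]` and `k in [1, 20]`;
the objective is cross-validated accuracy and the full search history is
returned. A black-box hyper-parameter optimizer could substitute for the
random search, but random search with a stated budget is reproducible and
easy to audit.

Evaluation pools out-of-fold predictions (stratified folds by default;
fold assignment cycles across class strata so fold sizes stay within one
segment even for small classes) and reports one-vs-rest confusion counts
per class. The conventional metric definitions are used — recall on the
positive class, specificity on the negatives — because the widely printed
variant of these formulas swaps the roles of Tp and Tn; that printed
variant is available behind `paper_eq11 = TRUE` for comparability. IMV runs
ten-fold CV for `rounds` seeds and reports the best overall and the best
single-fold accuracy; 10 rounds is the package default. Subject-grouped
folding is deliberately not the default: the reported tables of this
pipeline family imply segment-pooled folds, and pooled stratified folding
is what `cv_scheme()` produces.

## The synthetic generator

`generate_recording()` builds each channel as a sum of band-limited
Gaussian noise components — one per classical rhythm (delta 0.5-4, theta
4-8, alpha 8-13, beta 13-30, gamma 30-43 Hz), synthesized in the frequency
domain with random phases and exactly shaped magnitude — plus a `1/f` pink
floor, all scaled by a per-subject log-normal gain (SD 0.1). Sub-stream
seeds are derived from the master seed and a stable hash of
(subject, session, state), so datasets are reproducible and extensible.

The default profiles encode the physiological expectations the detection
problem rests on (relative band variances):

| state | delta | theta | alpha | beta | gamma | pink |
|---|---|---|---|---|---|---|
| focused | 0.6 | 0.7 | 1.0 | 2.5 | 0.8 | 0.8 |
| unfocused | 1.0 | 1.0 | 1.0 | 1.0 | 0.6 | 0.6 |
| drowsy | 1.6 | 2.3 | 2.0 | 0.5 | 0.2 | 0.2 |

i.e. focus is beta-dominant, drowsiness is slow-wave dominant with a 4:1
alpha-to-beta ratio, and the unfocused state is spectrally flat. The exact
ratios are package choices; `null_profiles()` gives every state the same
flat spectrum for negative controls. What the generator does **not**
emulate: ocular/muscle artifacts, volume conduction and inter-channel
covariance, non-stationarity within a state block. Passing the pipeline's
recovery tests on this data therefore shows that the machinery extracts
genuinely present rhythm-power differences; it does not certify performance
on artifact-laden real recordings.

## Numerical choices and problem sizes

- Odd-length inputs to the DFT-domain transforms are zero-padded by one
  sample and trimmed after reconstruction; the padding is recorded.
- TQWT/FAWT validity requires every subband to keep at least ~8 samples;
  too-deep decompositions of short signals fail with an explicit error.
- Equal-frequency discretization can produce fewer than 10 distinct bins
  for heavily tied columns; duplicate quantile breaks are collapsed.
- Majority-vote ties break to the first class level, deterministically.
- The verification suite exercises the end-to-end claim at 60 segments per
  class (3 subjects x 10 min per state) for the separable dataset and 120
  segments per class for the null control, with a search budget of 8
  candidates; these sizes give stable Monte-Carlo behaviour (the chance
  band for 360 null segments is about +-5 percentage points at two
  standard errors) while keeping a full run in the minutes range on one
  core.

## Known limitations

- The EDF reader covers plain 16-bit EDF without annotation channels.
- Boosted ensembles stop early when the weighted error leaves the SAMME
  validity range, so the effective member count can be below `L`.
- mRMR scores are the greedy criterion at selection time; they are
  monotone evidence for the selection order, not an absolute importance
  scale (a late-selected duplicate's score is diluted by the mean over many
  selected types).
- Subject-grouped cross-validation is available only by manual fold
  construction; the packaged schemes pool segments.
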