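---
title: "Measuring streetscape complexity from local contrast and spatial frequency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring streetscape complexity from local contrast and spatial frequency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viscomplex)
```

## The measurement model

Perceived visual complexity in street scenes correlates with two low-level
image properties: the presence of objects that create strong local luminance
contrast against their surroundings, and the presence of regions whose
spatial frequency is lower than the scene average (roads, sky, large smooth
facades). `viscomplex` turns both properties into dense maps over the image
and summarises them into a single scalar.

For every neighborhood $N_{i,j}$ of $s \times s$ pixels (default $s = 16$)
around each pixel of a grayscale image $I$, vectorised column-major into
$\mathbf{x}$:

* the **contrast map** records the RMS contrast
  $C(i,j) = \sqrt{\tfrac{1}{n}\sum_k (x_k - \bar{x})^2}$, the population
  standard deviation of the neighborhood's luminance values;

* the **kurtosis map** records the Pearson kurtosis
  $K(i,j) = m_4 / m_2^2$ of the response vector
  $a_k = \mathbf{w}_k^\top \ell(\mathbf{x})$ of a bank of learned
  independent-component (IC) filters $\mathbf{w}_k$ applied to the
  log-transformed neighborhood $\ell(\mathbf{x})$. Because the learned
  filters concentrate at high spatial frequencies, a low-frequency
  neighborhood excites only a few of them — a sparse response vector with
  *high* kurtosis — while a high-frequency neighborhood excites many,
  giving dense responses and *low* kurtosis. The map therefore segments
  local spatial frequency without any explicit frequency analysis.

Four population statistics summarise the maps: the mean $\mu_C$ and standard
deviation $\sigma_C$ of the contrast map, and the skewness $S_K$ and
kurtosis $K_K$ of the kurtosis-map values. The combined measure is

$$M = \frac{\mu_C \, \sigma_C \, S_K}{K_K}.$$

$\mu_C$ grows with the number of high-contrast regions; $\sigma_C$ captures
contrast variety; $S_K > 0$ indicates an asymmetry of the kurtosis-map
distribution towards values above its mean, i.e. towards regions of
lower-than-average spatial frequency; and $K_K$, which flags outliers in
that distribution, divides the product so that skewness inflated by a few
outlying neighborhoods does not inflate $M$. Since $K_K \ge 1$ always (the
Pearson bound, attained by a balanced two-point distribution), the
denominator never vanishes. $M$ carries the sign of $S_K$.

The exact algebraic combination of the four statistics is the one point of
the procedure where we had to commit to a functional form; the product-over-
kurtosis form above is the minimal combination in which each numerator
statistic contributes positively and the outlier diagnostic compensates in
the denominator. It is isolated in `complexity_measure()` so an alternative
form is a one-line change, and all four statistics are always reported
alongside $M$.

### Choices fixed by the procedure

* **Population moments** (divisor $n$) everywhere, including skewness and
  kurtosis; the sample-moment variant of `rms_contrast()` sits behind a
  flag.
* **Non-excess kurtosis** in both the response kurtosis and $K_K$, which
  keeps the denominator of $M$ positive.
* **Log transform** $\ell(v) = \ln v$ for $v > 0$, $\ell(0) = 0$, applied
  elementwise before filtering; it compresses large luminance differences
  between image parts. The zero case keeps 8-bit black pixels finite.
* **DC response constant** $c = 0$: the learned DC (mean-luminance) filter's
  response is pinned to a constant, and since any constant only shifts the
  response sample by one entry, the least informative choice is 0
  (configurable in the bank object). Response kurtosis is invariant to a
  common affine rescaling of the responses, so filter sign and scale
  conventions do not affect the maps.
* **Stride**: the maps are defined around every pixel of the valid region
  (stride 1, no padding). A configurable stride is provided purely for
  speed; every documented result states its stride, and the map values at
  the sampled positions are identical to the stride-1 values there. Map
  computation is required (and tested) to agree with direct per-neighborhood
  evaluation to $10^{-9}$ regardless of the internal matrix strategy.
* **Undefined entries**: a neighborhood whose response variance is below
  $10^{-12}$ (e.g. a perfectly flat region) has no defined kurtosis; such
  entries are masked and excluded from the map statistics, and the masked
  fraction is reported.

## Learning the filter bank

The filters are learned by symmetric FastICA with the hyperbolic-tangent
nonlinearity, 200 iterations maximum (convergence tolerance $10^{-4}$), and
no dimension reduction, on 16×16-pixel patches drawn non-overlapping from a
training corpus — so 256 components are learned, of which one is the DC
component and 255 are wavelet-like oriented filters. Patches keep their
per-patch mean (only the global per-dimension mean is removed before
whitening); removing per-patch means would prevent the DC component from
being learned at all. The DC filter is identified as the component whose
amplitude spectrum is most concentrated at zero frequency; every other
filter is normalised to unit norm, residual-mean-removed, and sign-oriented
so its central weight is nonnegative.

Each non-DC filter is characterised by a least-squares 2-D Gabor fit
(Levenberg–Marquardt, initialised from the filter's spectral peak and
envelope centroid, carrier frequency bounded by the diagonal Nyquist limit
$0.5\sqrt{2}$ cycles/pixel). The half-amplitude spatial-frequency bandwidth
follows in closed form: a Gaussian envelope of s.d. $\sigma$ along the
carrier has spectral s.d. $\sigma_f = 1/(2\pi\sigma)$, so
$\mathrm{bw} = \log_2\frac{f + \sigma_f\sqrt{2\ln 2}}{f - \sigma_f\sqrt{2\ln 2}}$
octaves. Banks learned from textured corpora put most filters above
0.25 cycles/pixel with a bandwidth histogram peaking between 0.3 and 0.5
octaves.

## What the synthetic corpus emulates

Without shipping a photographic database, `make_texture_corpus()` generates
images reproducing the two statistical properties of natural scenes that the
learning stage actually consumes:

1. a roughly $1/f$ amplitude spectrum (measured radially averaged
   log-amplitude slopes near $-0.7$, within the range reported for natural
   scenes), and
2. sparse, non-Gaussian structure: occluding edges from a dead-leaves
   background with a scale-invariant disc-size distribution, and localized
   oriented texture from a sparse field of Gabor-shaped wave elements.

A Gaussian $1/f$ noise floor plus a weak white-noise component fill the
spectral regions the sparse components leave empty (the lowest frequencies
and the corner beyond the element band); being Gaussian, they contribute no
independent-component structure of their own, only a realistic background
against which the sparse structure is learned. Each image is contrast-
normalised before 8-bit quantisation so that no component's amplitude is
distorted by clipping. It matters that Gaussian fields *alone* are not a
usable corpus: ICA finds no preferred directions in Gaussian data, and a
bank learned from pure $1/f$ noise is unstructured noise itself — the
sparse dead-leaves and wave-element components are what make the corpus
learnable.

The element design matters and is worth recording. Element centre
frequencies are drawn with density $\propto f^2$, i.e. uniform coverage of
the two-dimensional frequency plane, which is what makes the number of
filters responding to a grating grow smoothly with its frequency — the
mechanism behind the monotone frequency segmentation of the kurtosis map.
Envelopes extend about 1.4 carrier periods along the oscillation (setting
the learned filters' half-octave-scale bandwidth) but only ~2 pixels across
it, which makes individual elements — and hence the learned filters —
orientation-broadband, so the segmentation does not depend on a grating's
orientation happening to match some filter's. ICA on this corpus recovers
essentially the generating element family, which is the intended analogy to
how ICA on natural images recovers V1-like Gabor filters.

What the corpus does **not** emulate: photometric nonlinearities of real
cameras, occlusion relationships beyond simple layering, scene-scale
structure (horizons, perspective), and chromatic content. Tests passing on
this corpus therefore demonstrate the mechanics of the measure — learning,
segmentation, statistics — not its empirical correlation with human
judgments of real streetscapes, which requires real photographs and real
rankings.

`make_surrogate_scene()` plays the role of a streetscape with a known
ground-truth construction: a textured mid-gray canvas, a chosen fraction of
smooth low-frequency area (elliptical patches of low-frequency surface) and
a chosen number of high-contrast rectangles. Object count drives $\mu_C$ up;
smooth-area fraction drives $S_K$ up; their sum serves as the construction
complexity parameter against which $M$ is validated (Spearman rank
correlation across seeded scenes).

One behaviour of $S_K$ deserves a note because it follows from what
skewness *is*: adding smooth low-frequency regions raises $S_K$ while those
regions form a minority of the scene — a right tail of high kurtosis-map
values. Once they approach half the area the distribution turns bimodal and
skewness falls again even though low-frequency content keeps growing. In
real streetscapes roads and sky are a minority of the image, which is the
regime the measure was designed for; the tests exercise that regime, and
scenes dominated by smooth area are a documented boundary of the
statistic's interpretability.

## Subjective rankings

Each participant partitions the items into *simple*, *ordinary* and
*complex* groups and sorts within groups; the two group boundaries are
materialised as two extra rank positions (74 items yield 76 positions: if
the simple group holds ten items, the first division occupies position 11).
Across subjects each item induces a distribution over positions with mean
$\mu = \sum_r r\, p(r)$; items *and* divisions sort by $\mu$, and the
divisions' positions in the sorted order induce the final three-group
partition. Ties in $\mu$ break by item identifier — the protocol does not
specify a rule, and a stable deterministic one keeps reruns identical.
Objective measures are compared against $\mu$ by Pearson correlation with
the two-sided $p$-value from the $t$-distribution on $n - 2$ degrees of
freedom; the significance criterion defaults to $p < 0.001$. The rank-file
dialect (one CSV row per subject, `|` tokens at the divisions) is this
package's own, defined in `write_rankings()`.

`make_participants()` simulates the protocol with Gaussian rank jitter
around a true order. At the study's scale (74 items, 40 subjects, jitter
s.d. 2 positions) aggregation recovers the true order to Kendall
$\tau \ge 0.9$.

## Preprocessing

Display presentation requires downsampling; `decimate()` implements the
classic anti-aliased scheme: a zero-phase (forward–backward) eighth-order
Chebyshev Type I low-pass, applied separably with mirror-reflect padding,
then subsampling. The normalized cutoff defaults to $0.8/\mathrm{factor}$ of
Nyquist with 0.05 dB passband ripple — the standard decimation design —
and both are configurable. The order-8 design attenuates Nyquist by far
more than 40 dB, and DC is preserved up to the (doubled, zero-phase)
passband ripple. Quantization to 8 bits maps the source bit-depth range
linearly onto $[0, 255]$, rounds half-to-even and clips, making outputs
bit-exact across platforms. Colour collapses to the unweighted channel mean
by default (the minimal reading of "collapsing" RGB); Rec. 601 luminance
weights are available behind a flag.

Two helpers document the presentation geometry: `nyquist_cpd()` (half the
pixel count per degree of visual angle) and `visual_angle_deg()` (from pixel
pitch and viewing distance). For a 2144×1424 image spanning 37° × 25.12°
these give ≈28.97 and ≈28.34 cycles/degree; 1424 pixels of 0.2505 mm pitch
at 80 cm subtend ≈25.15°.

## Baseline clutter measures

Four conventional measures are implemented for comparison, each deterministic
given its configuration and each at its minimum on a constant image:

* **Perimeter length** — edge-pixel count of a Canny map (Gaussian
  $\sigma = 1$; hysteresis thresholds default to fixed fractions 0.10/0.20
  of the maximal Sobel magnitude on the 8-bit scale). Fixed thresholds were
  a deliberate design choice over per-image gradient-percentile thresholds:
  percentile thresholds adapt to each image, so an object-free textured
  scene can count *more* edge pixels than a cluttered one, which destroys
  cross-image comparability (and the strong rank-agreement with JPEG file
  size that edge counting is known for). The percentile rule remains
  available as `threshold_mode = "quantile"` for within-image salience
  analysis.
* **JPEG file size** — in-memory encoded byte count at quality 75,
  grayscale, no metadata.
* **Subband entropy** — mean Shannon entropy (base 2, 255 bins) of the
  subbands of a 3-level orthogonal 2-D Haar decomposition, luminance only.
  This is a deliberate simplification of the steerable-pyramid construction
  used in the clutter literature; the Haar basis keeps the decomposition
  orthogonal and dependency-free.
* **Näsänen's measure** — effective image area × median radial frequency of
  the DC-excluded amplitude spectrum. "Effective area" is interpreted as the
  product of $4\times$ the s.d. of the marginal spatial distributions of
  $|I - \bar I|$ along each axis, a second-moment spread definition recorded
  here because the source literature does not pin one down.

The Rosenholtz feature-congestion measure is deliberately out of scope (its
colour-opponent covariance machinery is a method of its own); the report
schema reserves a `feature_congestion` column.

## Problem sizes and numerical notes

The package's own test suite learns its banks from 10,000 patches (16×16)
drawn from 40 corpus images of 256×256 — enough for the filter properties
above to be stable — and computes maps on 64–128-pixel images at strides 1–4.
The acceptance script learns from 50,000 patches of a 135-image corpus at
320×320. Whitening uses a full eigendecomposition (no dimension reduction);
a patch covariance with an eigenvalue below $10^{-12}$ of the maximum is
rejected as rank-deficient rather than silently truncated. FastICA uses
symmetric decorrelation, so no component ordering is implied; determinism is
guaranteed by seeding the initial unmixing matrix, and the sampling,
learning and fixture stages restore the caller's RNG state.

## Known limitations

* The measure is purely photometric: no contrast-response saturation,
  thresholds, or contrast-sensitivity weighting — physiological refinements
  explicitly left outside the measure.
* Filter banks and neighborhoods are single-scale (one patch size).
* The synthetic corpus validates mechanics, not human correlation; learned
  filter properties quoted here are properties of banks trained on this
  corpus, and a photographic corpus (e.g. a calibrated natural-image
  database) can be dropped in through `sample_patches()` unchanged.
* Canny parameters, JPEG quality and wavelet settings for the baselines are
  package defaults, not values fixed by the comparison literature; every one
  is exposed as an argument.
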