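# viscomplex

Objective measurement of the visual complexity of streetscape images from
the statistics of local contrast and local spatial frequency.

People judge street scenes as more complex when the scenes contain objects
that contrast strongly with their surroundings and large regions whose
spatial frequency is lower than the scene average (roads, sky, smooth
facades). `viscomplex` operationalises both cues. For every 16×16-pixel
neighborhood **x** of a grayscale image it computes

* a **contrast map** `C(i,j) = sd(x)` — the RMS contrast (population
  standard deviation of the neighborhood's luminance values), and
* a **kurtosis map** `K(i,j) = kurt(a)`, the Pearson kurtosis of the
  response vector `a_k = w_k' · log(x)` of a bank of independent-component
  (IC) filters learned by FastICA from image patches. The learned filters
  concentrate at high spatial frequencies, so low-frequency neighborhoods
  excite few filters (sparse responses, high kurtosis) and high-frequency
  neighborhoods excite many (dense responses, low kurtosis): the map
  segments local spatial frequency.

Four population statistics summarise the maps — the mean and standard
deviation of the contrast map (`mu_C`, `sigma_C`) and the skewness and
kurtosis of the kurtosis-map values (`S_K`, `K_K`) — and combine into the
single measure

```
M = mu_C * sigma_C * S_K / K_K
```

The package also provides the anti-aliased decimation used to prepare
images for display presentation, aggregation of per-subject grouped
complexity rankings into a mean-rank order with correlation reports, four
conventional clutter baselines (Canny edge-perimeter length, JPEG file
size, wavelet subband entropy, Näsänen's area × median-frequency measure),
and a synthetic fixture generator (edge and grating control stimuli,
streetscape surrogate scenes with known construction complexity, ICA
training textures, simulated participants).

## Worked example

```r
library(viscomplex)

## learn an IC filter bank from the synthetic texture corpus
corpus <- make_texture_corpus(40, size = 256, seed = 101)
patches <- sample_patches(corpus, 10000, patch_size = 16, seed = 202)
bank <- learn_filters(patches, seed = 303)
print(bank)
#> Independent-component filter bank
#>   256 filters on 16x16 patches (255 non-DC + 1 DC, dc_index = 25)
#>   learning: 92 iterations, converged (seed 303)

## measure two surrogate scenes of known construction complexity
simple_scene <- make_surrogate_scene(n_objects = 1, smooth_fraction = 0.1,
                                     size = 128, seed = 1)
busy_scene <- make_surrogate_scene(n_objects = 12, smooth_fraction = 0.5,
                                   size = 128, seed = 1)
measure_image(busy_scene, bank, stride = 4)
#> Visual complexity statistics (neighborhood 16x16, stride 4)
#>   mu_C    = 29.82   (mean local RMS contrast)
#>   sigma_C = 23.73   (s.d. of local contrast)
#>   S_K     = 1.119   (skewness of kurtosis map)
#>   K_K     = 3.855   (kurtosis of kurtosis map)
#>   M       = 205.3
measure_image(simple_scene, bank, stride = 4)$M
#> [1] 23.9965
```

`mu_C` is the mean local RMS contrast in 8-bit luminance levels; `sigma_C`
is the contrast variety; `S_K > 0` says the kurtosis-map distribution leans
towards values above its mean, i.e. the scene carries regions of
lower-than-average spatial frequency; `K_K` (≥ 1 by construction) discounts
skewness driven by a few outlying neighborhoods. The busy scene — more
high-contrast objects, more smooth low-frequency area — scores nearly an order of
magnitude higher than the sparse one. (Numbers above are what the code
prints for these exact calls; they are deterministic given the seeds.)

A thin command-line wrapper over the same functions is installed at
`inst/scripts/viscomplex.R` with `learn-filters`, `measure` and
`make-fixtures` subcommands, and `run_pipeline()` runs
preprocess → maps → measure (optionally + baselines) end to end with
provenance hashes.

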