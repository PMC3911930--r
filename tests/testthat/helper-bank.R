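## Shared fixtures, built once per test run. The filter bank is the
## expensive piece (FastICA on 10,000 16x16 patches); every test that needs
## a learned natural-texture bank reuses it.
vx_cache <- new.env(parent = emptyenv())

vx_corpus <- function() {
  if (is.null(vx_cache$corpus)) {
    vx_cache$corpus <- make_texture_corpus(40, size = 256, seed = 101)
  }
  vx_cache$corpus
}

vx_bank <- function() {
  if (is.null(vx_cache$bank)) {
    P <- sample_patches(vx_corpus(), 10000, 16, seed = 202)
    vx_cache$bank <- learn_filters(P, seed = 303)
  }
  vx_cache$bank
}

## Small 8x8 bank for fast structural tests.
vx_bank8 <- function() {
  if (is.null(vx_cache$bank8)) {
    P <- sample_patches(vx_corpus(), 2000, 8, seed = 404)
    vx_cache$bank8 <- learn_filters(P, seed = 505)
  }
  vx_cache$bank8
}

## Population moments by definition, used as the brute-force oracle.
oracle_moments <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  list(mean = mu, sd = sqrt(m2), skew = m3 / m2^1.5, kurt = m4 / m2^2)
}
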