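#' Two-level edge control stimulus
#'
#' A square patch whose upper half holds a luminance value `delta` levels
#' above its lower half, centred in `[0, 255]`. Considered as one
#' neighborhood, its RMS contrast is exactly `delta / 2`.
#'
#' @param size Patch side length (default 16; must be even).
#' @param delta Luminance difference between upper and lower halves, in
#'   `[0, 255]`.
#' @return `size x size` integer-valued matrix with attribute `delta`.
#' @export
make_edge <- function(size = 16L, delta) {
  stopifnot(size %% 2L == 0L, delta >= 0, delta <= 255)
  base <- round((255 - delta) / 2)
  m <- matrix(base, size, size)
  m[seq_len(size %/% 2L), ] <- base + delta
  structure(m, delta = delta)
}

#' Two-dimensional cosine grating control stimulus
#'
#' A `cos(2 pi f (u + v))` pattern with equal horizontal and vertical
#' frequency components (a 45-degree oriented grating), scaled from
#' `[-1, 1]` to `[0, 255]` and rounded to integers.
#'
#' @param size Patch side length (default 16).
#' @param frequency Frequency of each component in cycles/pixel,
#'   `0 < frequency <= 0.5`.
#' @return `size x size` integer-valued matrix with attribute `frequency`.
#' @export
make_grating <- function(size = 16L, frequency) {
  stopifnot(frequency > 0, frequency <= 0.5)
  u <- 0:(size - 1L)
  g <- cos(2 * pi * frequency * outer(u, u, "+"))
  structure(round((g + 1) / 2 * 255), frequency = frequency)
}

## Low-frequency random surface: sum of a few low-frequency cosines with
## random phases/orientations, normalised to unit amplitude range.
smooth_surface <- function(H, W, n_comp = 3L) {
  u <- matrix(seq_len(H), H, W)
  v <- matrix(rep(seq_len(W), each = H), H, W)
  s <- matrix(0, H, W)
  for (k in seq_len(n_comp)) {
    f <- stats::runif(1, 0.004, 0.02)
    th <- stats::runif(1, 0, pi)
    ph <- stats::runif(1, 0, 2 * pi)
    s <- s + cos(2 * pi * f * (u * sin(th) + v * cos(th)) + ph)
  }
  s / max(abs(s))
}

## Band-pass noise texture around a centre frequency (cycles/pixel),
## unit-variance.
bandpass_noise <- function(H, W, f0, bw = 0.08) {
  z <- matrix(stats::rnorm(H * W), H, W)
  Fz <- stats::fft(z)
  fy <- c(0:(H %/% 2), -((H - H %/% 2 - 1L):1)) / H
  fx <- c(0:(W %/% 2), -((W - W %/% 2 - 1L):1)) / W
  fr <- sqrt(outer(fy^2, fx^2, "+"))
  mask <- exp(-(fr - f0)^2 / (2 * bw^2))
  out <- Re(stats::fft(Fz * mask, inverse = TRUE)) / (H * W)
  out / stats::sd(out)
}

#' Synthetic streetscape surrogate scene
#'
#' A controllable stand-in for a streetscape photograph: a mid-gray canvas
#' carrying a high-frequency texture, a chosen fraction of smooth
#' low-spatial-frequency area (road/sky-like regions, rendered as random
#' low-frequency surfaces inside elliptical patches), and a chosen number of
#' high-contrast rectangular objects (signage/window-like). The construction
#' parameters define a ground-truth complexity ordering: more objects raise
#' the mean local contrast, and more smooth area skews the kurtosis map
#' towards high (low-frequency) values.
#'
#' @param n_objects Number of high-contrast rectangles.
#' @param smooth_fraction Approximate fraction of the canvas covered by
#'   smooth low-frequency regions, in `[0, 1]`.
#' @param texture_freq Centre frequency of the background texture in
#'   cycles/pixel (default 0.35).
#' @param size Canvas side length (default 128).
#' @param seed Integer seed; the scene is deterministic given the seed.
#' @return `size x size` integer matrix in `[0, 255]` with attributes
#'   `n_objects`, `smooth_fraction`, `texture_freq`, `seed`, and
#'   `complexity_param` (`n_objects + smooth_fraction`, the construction
#'   complexity parameter).
#' @export
make_surrogate_scene <- function(n_objects, smooth_fraction,
                                 texture_freq = 0.35, size = 128L,
                                 seed = 1L) {
  stopifnot(n_objects >= 0, smooth_fraction >= 0, smooth_fraction <= 1)
  img <- with_seed(seed, {
    canvas <- matrix(128, size, size)
    if (smooth_fraction < 1) {
      canvas <- canvas + 12 * bandpass_noise(size, size, texture_freq)
    }
    ## smooth low-frequency regions: elliptical patches until the target
    ## area fraction is covered
    if (smooth_fraction > 0) {
      covered <- matrix(FALSE, size, size)
      u <- matrix(seq_len(size), size, size)
      v <- matrix(rep(seq_len(size), each = size), size, size)
      target <- smooth_fraction * size^2
      tries <- 0L
      while (sum(covered) < target && tries < 200L) {
        tries <- tries + 1L
        cx <- stats::runif(1, 1, size); cy <- stats::runif(1, 1, size)
        rx <- stats::runif(1, size / 12, size / 6)
        ry <- stats::runif(1, size / 12, size / 6)
        inside <- ((u - cy) / ry)^2 + ((v - cx) / rx)^2 <= 1
        covered <- covered | inside
      }
      sm <- 128 + 35 * smooth_surface(size, size)
      canvas[covered] <- sm[covered]
    }
    if (n_objects > 0) {
      for (k in seq_len(n_objects)) {
        h <- sample(8:20, 1L); w <- sample(8:20, 1L)
        r0 <- sample.int(size - h, 1L); c0 <- sample.int(size - w, 1L)
        val <- if (stats::runif(1) < 0.5) 0 else 255
        canvas[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- val
      }
    }
    canvas
  })
  img <- pmin(pmax(round(img), 0), 255)
  structure(img, n_objects = n_objects, smooth_fraction = smooth_fraction,
            texture_freq = texture_freq, seed = seed,
            complexity_param = n_objects + smooth_fraction)
}

#' Simulated participant rankings
#'
#' Generates per-subject rankings around a known true complexity order: each
#' subject's ordering is the true order perturbed by Gaussian rank jitter of
#' s.d. `noise_sigma` positions, then partitioned into simple/ordinary/
#' complex groups at the given quantiles, with division markers inserted.
#'
#' @param true_order Character vector of item identifiers in true increasing
#'   complexity.
#' @param noise_sigma Rank jitter s.d. in positions (default 2).
#' @param n_subjects Number of simulated subjects (default 40).
#' @param group_quantiles Two fractions at which the groups split (default
#'   `c(1/3, 2/3)`).
#' @param seed Integer seed.
#' @return Named list of `length(true_order) + 2` position sequences, one
#'   per subject.
#' @export
make_participants <- function(true_order, noise_sigma = 2, n_subjects = 40L,
                              group_quantiles = c(1 / 3, 2 / 3), seed = 1L) {
  stopifnot(n_subjects >= 1L, length(group_quantiles) == 2L,
            all(diff(group_quantiles) >= 0))
  n <- length(true_order)
  n1 <- round(group_quantiles[1] * n)
  n2 <- round(group_quantiles[2] * n)
  with_seed(seed, {
    out <- lapply(seq_len(n_subjects), function(s) {
      scores <- seq_len(n) + stats::rnorm(n, 0, noise_sigma)
      ord <- true_order[order(scores)]
      insert_divisions(list(
        simple = ord[seq_len(n1)],
        ordinary = ord[seq_len(n2 - n1) + n1],
        complex = ord[seq_len(n - n2) + n2]
      ))
    })
    names(out) <- sprintf("subject_%02d", seq_len(n_subjects))
    out
  })
}

#' Synthetic texture corpus for ICA learning
#'
#' Photographic-surrogate images for learning the IC filter bank without an
#' external image database. Each image combines the two kinds of structure
#' that drive independent-component learning on natural scenes:
#' a dead-leaves background (occluding discs of random luminance with a
#' scale-invariant size distribution), which supplies piecewise-smooth
#' regions, edges and the low-frequency content, and a sparse field of
#' oriented wave elements (Gabor-shaped texture patches) standing in for
#' natural texture. Element centre frequencies are drawn with density
#' proportional to `f^2` (uniform coverage density over the 2-D frequency
#' plane), their envelopes extend `cycles_sigma / f` pixels along the
#' oscillation and `sigma_perp` pixels across it, and element amplitudes
#' fall off as `f^-amp_slope`, which together give the corpus an
#' approximately 1/f amplitude spectrum. Output is quantised to the 8-bit
#' range, so a fixed seed yields byte-identical images on every platform.
#'
#' @param n_images Number of images.
#' @param size Image side length in pixels (default 128).
#' @param seed Integer seed.
#' @param freq_range Range of element centre frequencies in cycles/pixel.
#' @param coverage Expected total element area as a multiple of the image
#'   area (elements overlap; default 2.5).
#' @param cycles_sigma Envelope s.d. along the oscillation in carrier
#'   periods (default 1.36, about a half-octave element).
#' @param sigma_perp Envelope s.d. across the oscillation in pixels
#'   (default 1.8; small values make elements orientation-broadband).
#' @param amp_slope Spectral amplitude fall-off exponent (default 0.5,
#'   which yields an approximately 1/f ensemble amplitude spectrum).
#' @param n_leaves Number of background discs (default 60).
#' @param leaf_amp Half-range of disc luminance about mid-gray (default 60).
#' @return List of `size x size` integer matrices in `[0, 255]`.
#' @export
make_texture_corpus <- function(n_images, size = 128L, seed = 1L,
                                freq_range = c(0.05, 0.45), coverage = 2.5,
                                cycles_sigma = 1.36, sigma_perp = 1.8,
                                amp_slope = 0.5, n_leaves = 60L,
                                leaf_amp = 60) {
  stopifnot(n_images >= 1L, freq_range[1] > 0, freq_range[2] <= 0.5)
  with_seed(seed, {
    u0 <- matrix(seq_len(size), size, size)
    v0 <- matrix(rep(seq_len(size), each = size), size, size)
    a3 <- freq_range[1]^3; b3 <- freq_range[2]^3
    mean_inv_f <- 3 * (freq_range[2]^2 - freq_range[1]^2) / (2 * (b3 - a3))
    mean_area <- 2 * pi * cycles_sigma * sigma_perp * mean_inv_f
    n_el <- round(coverage * size^2 / mean_area)
    lapply(seq_len(n_images), function(k) {
      img <- matrix(stats::runif(1, 80, 175), size, size)
      a <- 8^-2; b <- (size / 2)^-2
      for (s in seq_len(n_leaves)) {
        r <- (a - stats::runif(1) * (a - b))^-0.5   # p(r) ~ r^-3
        cx <- stats::runif(1, 1, size); cy <- stats::runif(1, 1, size)
        inside <- (u0 - cy)^2 + (v0 - cx)^2 <= r^2
        img[inside] <- 128 + leaf_amp * (stats::runif(1) - 0.5) * 2
      }
      for (e in seq_len(n_el)) {
        f0 <- (stats::runif(1, a3, b3))^(1 / 3)     # density ~ f^2
        sp <- cycles_sigma / f0
        half <- ceiling(2.5 * sp)
        xs <- (-half):half
        th <- stats::runif(1, 0, pi)
        ph <- stats::runif(1, 0, 2 * pi)
        amp <- 40 * (f0 / freq_range[2])^-amp_slope * stats::rexp(1)
        xr <- outer(xs, xs, function(r, cc) cc * cos(th) + r * sin(th))
        yr <- outer(xs, xs, function(r, cc) -cc * sin(th) + r * cos(th))
        blob <- exp(-(xr^2 / (2 * sp^2) + yr^2 / (2 * sigma_perp^2))) *
          cos(2 * pi * f0 * xr + ph)
        cy <- sample.int(size, 1L); cx <- sample.int(size, 1L)
        rr <- (cy - half):(cy + half); cc <- (cx - half):(cx + half)
        ok_r <- rr >= 1 & rr <= size; ok_c <- cc >= 1 & cc <= size
        img[rr[ok_r], cc[ok_c]] <- img[rr[ok_r], cc[ok_c]] +
          amp * blob[ok_r, ok_c]
      }
      pmin(pmax(round(img), 0), 255)
    })
  })
}
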