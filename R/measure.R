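pop_moments <- function(x) {
  mu <- mean(x)
  xc <- x - mu
  list(mean = mu, m2 = mean(xc^2), m3 = mean(xc^3), m4 = mean(xc^4))
}

#' Contrast-map statistics
#'
#' Population mean and standard deviation of all contrast-map entries — the
#' two contrast statistics entering the complexity measure. The mean grows
#' with the number of high-contrast regions; the standard deviation captures
#' the contrast "variety" of the scene.
#'
#' @param cmap A `contrast_map` (or any numeric matrix/vector), at least 2
#'   values.
#' @return Named numeric vector `c(mu_C, sigma_C)`, in luminance levels.
#' @export
contrast_statistics <- function(cmap) {
  x <- as.vector(cmap)
  x <- x[!is.na(x)]
  if (length(x) < 2L) {
    stop("contrast map must contain at least 2 values", call. = FALSE)
  }
  m <- pop_moments(x)
  c(mu_C = m$mean, sigma_C = sqrt(m$m2))
}

#' Kurtosis-map statistics
#'
#' Population skewness (third standardised moment) and Pearson kurtosis
#' (fourth standardised moment) of the defined (unmasked) kurtosis-map
#' entries. Positive skewness marks an asymmetry towards kurtosis values
#' above the map mean, i.e. towards regions of lower-than-average spatial
#' frequency; the kurtosis of the map flags outliers in that distribution.
#'
#' @param kmap A `kurtosis_map` (or numeric matrix/vector); at least 4
#'   defined values, not all equal.
#' @return Named numeric vector `c(S_K, K_K)`, unitless.
#' @export
kurtosis_statistics <- function(kmap) {
  x <- as.vector(kmap)
  x <- x[!is.na(x)]
  if (length(x) < 4L) {
    stop("kurtosis map must contain at least 4 defined values", call. = FALSE)
  }
  m <- pop_moments(x)
  if (m$m2 < .Machine$double.eps * max(1, m$mean^2)) {
    stop("degenerate kurtosis map: zero variance across defined entries",
         call. = FALSE)
  }
  c(S_K = m$m3 / m$m2^1.5, K_K = m$m4 / m$m2^2)
}

#' The combined complexity measure M
#'
#' Combines the four map statistics into the single objective measure
#' `M = mu_C * sigma_C * S_K / K_K`: the product of the three statistics that
#' grow with perceived complexity (mean local contrast, contrast variety, and
#' skewness towards low spatial frequencies), divided by the kurtosis of the
#' kurtosis-map distribution, which compensates skewness values inflated by
#' outliers. `M` carries the sign of `S_K`.
#'
#' @param mu_C,sigma_C Mean and s.d. of the contrast map (luminance levels).
#' @param S_K,K_K Skewness and kurtosis of the kurtosis-map values; `K_K`
#'   must be at least 1 (the Pearson lower bound), so the denominator never
#'   vanishes.
#' @return The scalar measure `M`.
#' @export
complexity_measure <- function(mu_C, sigma_C, S_K, K_K) {
  if (any(!is.finite(c(mu_C, sigma_C, S_K, K_K)))) {
    stop("undefined inputs to the complexity measure: mu_C = ", mu_C,
         ", sigma_C = ", sigma_C, ", S_K = ", S_K, ", K_K = ", K_K,
         call. = FALSE)
  }
  if (K_K < 1) {
    stop("K_K = ", K_K, " violates the Pearson kurtosis lower bound of 1",
         call. = FALSE)
  }
  mu_C * sigma_C * S_K / K_K
}

#' Measure the visual complexity of one image
#'
#' End-to-end composition: contrast map and kurtosis map over sliding
#' neighborhoods, their four statistics, and the combined measure `M`.
#'
#' @param img Grayscale matrix (8-bit luminance scale).
#' @param bank An `ic_filter_bank` for the kurtosis map.
#' @param size Neighborhood side length (defaults to the bank's patch size).
#' @param stride Step between neighborhood anchors (default 1; larger strides
#'   trade map density for speed).
#' @return An object of class `complexity_stats`: list with `mu_C`,
#'   `sigma_C`, `S_K`, `K_K`, `M`, the fraction of masked kurtosis entries
#'   `masked_fraction`, and the `size`/`stride` used.
#' @examples
#' \donttest{
#' corpus <- make_texture_corpus(8, size = 96, seed = 1)
#' bank <- learn_filters(sample_patches(corpus, 300, 8, seed = 1), seed = 1)
#' scene <- make_surrogate_scene(n_objects = 6, smooth_fraction = 0.3, seed = 2)
#' measure_image(scene, bank, stride = 4)
#' }
#' @export
measure_image <- function(img, bank, size = bank$patch_size, stride = 1L) {
  cmap <- contrast_map(img, size = size, stride = stride)
  kmap <- kurtosis_map(img, bank, size = size, stride = stride)
  cs <- contrast_statistics(cmap)
  ks <- kurtosis_statistics(kmap)
  structure(
    list(mu_C = unname(cs["mu_C"]), sigma_C = unname(cs["sigma_C"]),
         S_K = unname(ks["S_K"]), K_K = unname(ks["K_K"]),
         M = complexity_measure(cs["mu_C"], cs["sigma_C"],
                                ks["S_K"], ks["K_K"]),
         masked_fraction = mean(is.na(kmap)),
         size = as.integer(size), stride = as.integer(stride)),
    class = "complexity_stats"
  )
}

#' @export
print.complexity_stats <- function(x, digits = 4, ...) {
  cat("Visual complexity statistics (neighborhood ", x$size, "x", x$size,
      ", stride ", x$stride, ")\n", sep = "")
  cat(sprintf("  mu_C    = %.*g   (mean local RMS contrast)\n", digits, x$mu_C))
  cat(sprintf("  sigma_C = %.*g   (s.d. of local contrast)\n", digits,
              x$sigma_C))
  cat(sprintf("  S_K     = %.*g   (skewness of kurtosis map)\n", digits,
              x$S_K))
  cat(sprintf("  K_K     = %.*g   (kurtosis of kurtosis map)\n", digits,
              x$K_K))
  cat(sprintf("  M       = %.*g\n", digits, x$M))
  if (x$masked_fraction > 0) {
    cat(sprintf("  (%.1f%% of kurtosis entries undefined and excluded)\n",
                100 * x$masked_fraction))
  }
  invisible(x)
}

#' @export
as.data.frame.complexity_stats <- function(x, ...) {
  data.frame(mu_C = x$mu_C, sigma_C = x$sigma_C, S_K = x$S_K, K_K = x$K_K,
             M = unname(x$M), masked_fraction = x$masked_fraction,
             size = x$size, stride = x$stride)
}
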