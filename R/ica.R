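## Seed handling: run `code` under a fixed RNG state and restore the caller's
## state afterwards, so fixture/learning determinism never leaks into user RNG.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Sample non-overlapping image patches
#'
#' Extracts square patches from a non-overlapping grid laid over each image,
#' sampling grid cells uniformly at random across the pooled grid of all
#' images until `n_patches` are drawn. Patches are vectorised column-major
#' (top-to-bottom, then left-to-right).
#'
#' @param images List of grayscale matrices, each at least `patch_size` in
#'   both dimensions.
#' @param n_patches Number of patches to draw.
#' @param patch_size Patch side length in pixels (default 16).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return An `n_patches x patch_size^2` numeric matrix, one patch per row.
#' @export
sample_patches <- function(images, n_patches, patch_size = 16L, seed = 1L) {
  if (!is.list(images)) images <- list(images)
  patch_size <- as.integer(patch_size)
  d <- patch_size^2
  if (n_patches == 0L) return(matrix(numeric(0), 0L, d))
  grids <- lapply(images, function(im) {
    dm <- dim(im)
    if (any(dm < patch_size)) {
      stop("every image must be at least patch_size in both dimensions",
           call. = FALSE)
    }
    c(dm[1] %/% patch_size, dm[2] %/% patch_size)
  })
  capacity <- sum(vapply(grids, prod, numeric(1)))
  if (n_patches > capacity) {
    stop("requested ", n_patches, " patches but only ", capacity,
         " non-overlapping grid cells are available", call. = FALSE)
  }
  cells <- do.call(rbind, lapply(seq_along(images), function(k) {
    g <- grids[[k]]
    cbind(k, rep(seq_len(g[1]), times = g[2]),
          rep(seq_len(g[2]), each = g[1]))
  }))
  pick <- with_seed(seed, sample.int(nrow(cells), n_patches))
  out <- matrix(0, n_patches, d)
  for (i in seq_len(n_patches)) {
    cc <- cells[pick[i], ]
    im <- images[[cc[1]]]
    r0 <- (cc[2] - 1L) * patch_size
    c0 <- (cc[3] - 1L) * patch_size
    out[i, ] <- as.vector(im[(r0 + 1L):(r0 + patch_size),
                             (c0 + 1L):(c0 + patch_size)])
  }
  attr(out, "patch_size") <- patch_size
  out
}

## Symmetric-orthogonalisation helper: W <- (W W^T)^{-1/2} W
sym_decorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, .Machine$double.eps))) %*%
    t(e$vectors) %*% W
}

## Flag the filter whose amplitude spectrum is most concentrated at zero
## frequency: maximise |F(0,0)| / sum |F|.
find_dc_index <- function(filters, patch_size) {
  ratios <- apply(filters, 1L, function(w) {
    Fm <- Mod(stats::fft(matrix(w, patch_size, patch_size)))
    Fm[1, 1] / sum(Fm)
  })
  which.max(ratios)
}

#' Learn an independent-component filter bank from image patches
#'
#' Runs symmetric FastICA on vectorised image patches and returns the learned
#' filters (rows of the unmixing matrix mapped back to pixel space). Patches
#' are centred globally (per-dimension mean over patches) and whitened by
#' eigendecomposition of their covariance; no dimension reduction is applied,
#' so the number of filters equals the patch dimensionality (256 for 16 x 16
#' patches). Per-patch mean luminance is deliberately not removed, which lets
#' a DC (mean-luminance) component emerge as one of the learned filters; it is
#' identified spectrally and flagged. All other filters are unit-norm,
#' zero-mean, and sign-oriented so the weight at the patch centre is
#' nonnegative.
#'
#' @param patches `n_patches x d` matrix from [sample_patches()]
#'   (`n_patches >= d`).
#' @param iterations Maximum FastICA iterations (default 200).
#' @param nonlinearity Contrast nonlinearity; only `"tanh"` is implemented.
#' @param seed Seed for the random orthonormal initialisation.
#' @param tol Convergence tolerance on the per-component change in direction
#'   (default 1e-4).
#' @return An object of class `ic_filter_bank`: list with `filters`
#'   (`d x d`, one filter per row), `dc_index`, `patch_size`,
#'   `dc_constant` (response constant for the DC filter, default 0),
#'   `iterations_run`, `converged`, `seed`.
#' @seealso [fit_gabor()], [characterize_bank()], [kurtosis_map()]
#' @export
learn_filters <- function(patches, iterations = 200L,
                          nonlinearity = c("tanh"), seed = 1L, tol = 1e-4) {
  nonlinearity <- match.arg(nonlinearity)
  patch_size <- attr(patches, "patch_size")
  d <- ncol(patches)
  if (is.null(patch_size)) patch_size <- as.integer(round(sqrt(d)))
  if (patch_size^2 != d) {
    stop("patch dimensionality ", d, " is not a square", call. = FALSE)
  }
  n <- nrow(patches)
  if (n < d) {
    stop("need at least as many patches (", n, ") as dimensions (", d, ")",
         call. = FALSE)
  }
  X <- t(patches)                       # d x n
  X <- X - rowMeans(X)
  CV <- tcrossprod(X) / n
  e <- eigen(CV, symmetric = TRUE)
  if (max(e$values) <= 0 || min(e$values) < 1e-12 * max(e$values)) {
    stop("patch covariance is rank deficient; supply more or more varied ",
         "patches", call. = FALSE)
  }
  K <- diag(1 / sqrt(e$values)) %*% t(e$vectors)  # whitening, d x d
  Z <- K %*% X
  W <- with_seed(seed, matrix(stats::rnorm(d * d), d, d))
  W <- sym_decorrelate(W)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(iterations)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    W1 <- tcrossprod(G, Z) / n - (rowMeans(1 - G^2)) * W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  filters <- W %*% K                    # rows act on raw (centred) patches
  filters <- filters / sqrt(rowSums(filters^2))
  dc_index <- find_dc_index(filters, patch_size)
  ## remove residual mean from non-DC filters, renormalise, fix sign
  ctr <- (ceiling(patch_size / 2) - 1L) * patch_size + ceiling(patch_size / 2)
  for (k in seq_len(d)) {
    if (k == dc_index) {
      if (sum(filters[k, ]) < 0) filters[k, ] <- -filters[k, ]
      next
    }
    w <- filters[k, ] - mean(filters[k, ])
    w <- w / sqrt(sum(w^2))
    s <- if (w[ctr] != 0) sign(w[ctr]) else sign(w[which.max(abs(w))])
    filters[k, ] <- s * w
  }
  structure(
    list(filters = filters, dc_index = dc_index, patch_size = patch_size,
         dc_constant = 0, iterations_run = it, converged = converged,
         seed = seed),
    class = "ic_filter_bank"
  )
}

#' @export
print.ic_filter_bank <- function(x, ...) {
  cat("Independent-component filter bank\n")
  cat(sprintf("  %d filters on %dx%d patches (%d non-DC + 1 DC, dc_index = %d)\n",
              nrow(x$filters), x$patch_size, x$patch_size,
              nrow(x$filters) - 1L, x$dc_index))
  cat(sprintf("  learning: %d iterations, %s (seed %s)\n", x$iterations_run,
              if (isTRUE(x$converged)) "converged" else "iteration cap reached",
              format(x$seed)))
  invisible(x)
}

#' @export
plot.ic_filter_bank <- function(x, n = 25L, ...) {
  n <- min(n, nrow(x$filters))
  side <- ceiling(sqrt(n))
  op <- graphics::par(mfrow = c(side, side), mar = c(0.2, 0.2, 0.2, 0.2))
  on.exit(graphics::par(op))
  idx <- setdiff(seq_len(nrow(x$filters)), x$dc_index)[seq_len(n)]
  for (k in idx) {
    m <- matrix(x$filters[k, ], x$patch_size, x$patch_size)
    graphics::image(t(m[nrow(m):1, ]), col = grDevices::gray.colors(64),
                    axes = FALSE, asp = 1)
  }
  invisible(x)
}

#' Persist / restore a filter bank
#'
#' Writes the bank as portable JSON (filters plus metadata) and reads it back.
#'
#' @param bank An `ic_filter_bank`.
#' @param path File path.
#' @return `read_filter_bank()` returns an `ic_filter_bank`.
#' @export
write_filter_bank <- function(bank, path) {
  stopifnot(inherits(bank, "ic_filter_bank"))
  obj <- list(
    filters = bank$filters, dc_index = bank$dc_index,
    patch_size = bank$patch_size, dc_constant = bank$dc_constant,
    iterations_run = bank$iterations_run, converged = bank$converged,
    seed = bank$seed, filters_digest = digest::digest(round(bank$filters, 12))
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_filter_bank
#' @export
read_filter_bank <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(filters = as.matrix(obj$filters), dc_index = as.integer(obj$dc_index),
         patch_size = as.integer(obj$patch_size),
         dc_constant = obj$dc_constant,
         iterations_run = obj$iterations_run, converged = obj$converged,
         seed = obj$seed),
    class = "ic_filter_bank"
  )
}
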