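#' Division marker identifiers
#'
#' Internal identifiers for the two group-division markers inserted between
#' the simple/ordinary and ordinary/complex groups of a subject's ranking.
#' @format Character scalars.
#' @export
DIV1 <- "<div1>"
#' @rdname DIV1
#' @export
DIV2 <- "<div2>"

#' Insert group-division markers into a grouped ranking
#'
#' A subject partitions the items into three groups — simple, ordinary,
#' complex — each sorted in increasing complexity. The two divisions between
#' groups are represented as two additional rank positions: if the simple
#' group holds ten items, the first division occupies position 11, the
#' ordinary items start at position 12, and so on, so `n` items yield a
#' sequence of `n + 2` positions (76 for 74 items).
#'
#' @param ranking List with character vectors `simple`, `ordinary`,
#'   `complex` (some possibly empty) covering every item exactly once.
#' @return Character vector of length `n_items + 2` with [DIV1] and [DIV2]
#'   at the group boundaries.
#' @export
insert_divisions <- function(ranking) {
  stopifnot(is.list(ranking),
            all(c("simple", "ordinary", "complex") %in% names(ranking)))
  items <- c(ranking$simple, ranking$ordinary, ranking$complex)
  if (anyDuplicated(items)) {
    stop("items appear more than once across groups", call. = FALSE)
  }
  c(as.character(ranking$simple), DIV1,
    as.character(ranking$ordinary), DIV2,
    as.character(ranking$complex))
}

#' Rank-position distribution of one item
#'
#' Counts, over all subjects' sequences, how often the item (or division
#' marker) occupies each rank position, and derives the probability mass
#' `p(r) = n_r / n_subjects`, the mean rank `mu = sum(r * p(r))` and its
#' standard deviation.
#'
#' @param sequences List (optionally named by subject) of equal-length
#'   character sequences as produced by [insert_divisions()].
#' @param item Item (or [DIV1]/[DIV2]) identifier.
#' @return Object of class `rank_distribution`: list with `item`, `counts`
#'   (length = number of positions), `p`, `mu`, `sigma`, `n_subjects`.
#' @export
rank_distribution <- function(sequences, item) {
  stopifnot(length(sequences) >= 1L)
  R <- length(sequences[[1]])
  pos <- vapply(seq_along(sequences), function(s) {
    seqs <- sequences[[s]]
    if (length(seqs) != R) {
      stop("subject ", names(sequences)[s] %||% s,
           " has a sequence of different length", call. = FALSE)
    }
    p <- match(item, seqs)
    if (is.na(p)) {
      stop("item '", item, "' missing from the sequence of subject ",
           names(sequences)[s] %||% s, call. = FALSE)
    }
    p
  }, integer(1))
  counts <- tabulate(pos, nbins = R)
  p <- counts / length(sequences)
  mu <- sum(seq_len(R) * p)
  sigma <- sqrt(sum((seq_len(R) - mu)^2 * p))
  structure(list(item = item, counts = counts, p = p, mu = mu, sigma = sigma,
                 n_subjects = length(sequences)),
            class = "rank_distribution")
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) != 1L || is.na(a)) b else a
}

#' @export
print.rank_distribution <- function(x, ...) {
  cat(sprintf("Rank distribution for '%s' over %d positions (%d subjects)\n",
              x$item, length(x$counts), x$n_subjects))
  cat(sprintf("  mean rank mu = %.3f, sigma = %.3f\n", x$mu, x$sigma))
  invisible(x)
}

#' Aggregate subject rankings into the final complexity rank
#'
#' Sorts items (and the two division markers, which are ranked like items) by
#' ascending mean rank `mu`; ties are broken by item identifier. The
#' positions of the division markers in the sorted order induce the final
#' simple/ordinary/complex partition.
#'
#' @param distributions List of `rank_distribution` objects covering every
#'   item and both division markers.
#' @return Data frame (one row per entry, divisions included) with columns
#'   `item`, `mu`, `sigma`, `group` (`"simple"`, `"ordinary"`, `"complex"`,
#'   or `"division"`), in final rank order.
#' @export
aggregate_rank <- function(distributions) {
  ids <- vapply(distributions, `[[`, character(1), "item")
  if (!all(c(DIV1, DIV2) %in% ids)) {
    stop("distributions must include both division markers", call. = FALSE)
  }
  df <- data.frame(
    item = ids,
    mu = vapply(distributions, `[[`, numeric(1), "mu"),
    sigma = vapply(distributions, `[[`, numeric(1), "sigma"),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$mu, df$item), , drop = FALSE]
  ndiv <- cumsum(df$item %in% c(DIV1, DIV2))
  group <- c("simple", "ordinary", "complex")[ndiv -
            (df$item %in% c(DIV1, DIV2)) + 1L]
  group[df$item %in% c(DIV1, DIV2)] <- "division"
  df$group <- group
  rownames(df) <- NULL
  df
}

#' Correlate an objective measure with the subjective rank
#'
#' Pearson correlation between measure values and mean subjective ranks over
#' an optional subset, with the two-sided p-value from the t-distribution on
#' `n - 2` degrees of freedom and the first-order least-squares fit.
#'
#' @param measure_values Numeric vector of objective scores.
#' @param mu_ranks Numeric vector of mean subjective ranks (same length).
#' @param subset Optional logical mask selecting the streetscape type
#'   (all/dayscapes/nightscapes/...).
#' @param label Subset label carried into the report.
#' @param alpha Significance criterion (default 0.001, the table-footnote
#'   convention).
#' @return Object of class `correlation_report`: list with `label`, `n`,
#'   `R`, `p_value`, `slope`, `intercept`, `significant`.
#' @export
correlate <- function(measure_values, mu_ranks, subset = NULL, label = "all",
                      alpha = 0.001) {
  stopifnot(length(measure_values) == length(mu_ranks))
  if (!is.null(subset)) {
    measure_values <- measure_values[subset]
    mu_ranks <- mu_ranks[subset]
  }
  n <- length(measure_values)
  if (n < 3L) {
    stop("need at least 3 paired values in the subset, got ", n,
         call. = FALSE)
  }
  if (stats::sd(measure_values) == 0 || stats::sd(mu_ranks) == 0) {
    stop("undefined correlation: zero variance in subset '", label, "'",
         call. = FALSE)
  }
  x <- mu_ranks; y <- measure_values
  R <- stats::cor(x, y)
  tt <- R * sqrt((n - 2) / max(1 - R^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  slope <- stats::cov(x, y) / stats::var(x)
  structure(list(label = label, n = n, R = R, p_value = p, slope = slope,
                 intercept = mean(y) - slope * mean(x),
                 significant = p < alpha, alpha = alpha),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("Correlation report [%s], n = %d\n", x$label, x$n))
  cat(sprintf("  R = %.3f, p = %.3g%s\n", x$R, x$p_value,
              if (x$significant) sprintf("  (significant at p < %g)", x$alpha)
              else ""))
  cat(sprintf("  fit: y = %.4g x + %.4g\n", x$slope, x$intercept))
  invisible(x)
}

#' Read / write ranking files
#'
#' The rank-file dialect is one line per subject: comma-separated item
#' identifiers in rank order with a literal `|` token at each of the two
#' group divisions. On reading, the two `|` tokens become [DIV1] and [DIV2].
#'
#' @param sequences Named list of sequences (from [insert_divisions()] or
#'   [make_participants()]).
#' @param path File path.
#' @return `read_rankings()` returns a named list of character sequences.
#' @export
write_rankings <- function(sequences, path) {
  lines <- vapply(sequences, function(s) {
    s[s %in% c(DIV1, DIV2)] <- "|"
    paste(s, collapse = ",")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_rankings
#' @export
read_rankings <- function(path) {
  lines <- readLines(path)
  out <- lapply(lines, function(ln) {
    s <- strsplit(ln, ",", fixed = TRUE)[[1]]
    div <- which(s == "|")
    if (length(div) != 2L) {
      stop("each subject line must contain exactly two '|' division tokens",
           call. = FALSE)
    }
    s[div] <- c(DIV1, DIV2)
    s
  })
  names(out) <- sprintf("subject_%02d", seq_along(out))
  out
}
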