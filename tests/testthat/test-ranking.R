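test_that("division markers occupy the documented positions", {
  items <- sprintf("img%02d", 1:74)
  r <- list(simple = items[1:10], ordinary = items[11:40],
            complex = items[41:74])
  s <- insert_divisions(r)
  expect_length(s, 76)
  expect_identical(s[11], DIV1)
  expect_identical(s[12], "img11")
  expect_identical(s[42], DIV2)
  ## empty simple group puts the first division at position 1
  s0 <- insert_divisions(list(simple = character(0), ordinary = "a",
                              complex = "b"))
  expect_identical(s0[1], DIV1)
  expect_error(insert_divisions(list(simple = "a", ordinary = "a",
                                     complex = "b")), "more than once")
})

test_that("rank distributions count positions and average per the weighted mean", {
  items <- letters[1:4]
  mk <- function(ord) insert_divisions(list(simple = ord[1], ordinary = ord[2:3],
                                            complex = ord[4]))
  ## all subjects agree -> degenerate distribution
  seqs <- replicate(40, mk(items), simplify = FALSE)
  d <- rank_distribution(seqs, "b")
  expect_equal(d$mu, 3)      # a | b c | d  -> b at position 3
  expect_equal(d$sigma, 0)
  expect_equal(sum(d$counts), 40)
  expect_equal(sum(d$p), 1)
  ## half at one position, half at another: mu is the midpoint
  seqs2 <- c(replicate(20, mk(c("a", "b", "c", "d")), simplify = FALSE),
             replicate(20, mk(c("b", "c", "d", "a")), simplify = FALSE))
  expect_equal(rank_distribution(seqs2, "d")$mu, (6 + 4) / 2)
  expect_error(rank_distribution(seqs, "zz"), "missing")
})

test_that("the weighted-mean rank equals brute force on random counts", {
  set.seed(41)
  for (i in 1:20) {
    R <- 76
    counts <- rmultinom(1, 40, runif(R))[, 1]
    positions <- rep(seq_len(R), counts)
    mu_brute <- sum(positions) / 40
    p <- counts / 40
    mu_eq <- sum(seq_len(R) * p)
    expect_equal(mu_eq, mu_brute, tolerance = 1e-12)
  }
})

test_that("aggregation sorts by mean rank and classifies by the divisions", {
  mkdist <- function(item, mu) {
    structure(list(item = item, counts = NULL, p = NULL, mu = mu, sigma = 0,
                   n_subjects = 1), class = "rank_distribution")
  }
  dists <- list(mkdist("x", 7.0), mkdist("y", 3.0), mkdist(DIV1, 4.5),
                mkdist(DIV2, 8.5), mkdist("z", 9.1))
  agg <- aggregate_rank(dists)
  expect_identical(agg$item, c("y", DIV1, "x", DIV2, "z"))
  expect_identical(agg$group, c("simple", "division", "ordinary",
                                "division", "complex"))
  ## ties broken by item identifier
  dists2 <- list(mkdist("b", 2), mkdist("a", 2), mkdist(DIV1, 1),
                 mkdist(DIV2, 3))
  expect_identical(aggregate_rank(dists2)$item[2:3], c("a", "b"))
})

test_that("aggregation is invariant to subject order and exact at zero noise", {
  items <- sprintf("s%02d", 1:20)
  seqs <- make_participants(items, noise_sigma = 0, n_subjects = 15, seed = 2)
  dists <- lapply(c(items, DIV1, DIV2), rank_distribution, sequences = seqs)
  agg <- aggregate_rank(dists)
  expect_identical(agg$item[agg$group != "division"], items)
  ## permuting subjects leaves the aggregate unchanged
  dists_p <- lapply(c(items, DIV1, DIV2), rank_distribution,
                    sequences = rev(seqs))
  expect_identical(aggregate_rank(dists_p), agg)
})

test_that("noisy synthetic participants still recover the true order", {
  items <- sprintf("img%02d", 1:74)
  seqs <- make_participants(items, noise_sigma = 2, n_subjects = 40,
                            seed = 314)
  expect_true(all(lengths(seqs) == 76))
  dists <- lapply(c(items, DIV1, DIV2), rank_distribution, sequences = seqs)
  agg <- aggregate_rank(dists)
  rec <- agg$item[agg$group != "division"]
  tau <- stats::cor(match(items, rec), seq_along(items), method = "kendall")
  expect_gte(tau, 0.9)
})

test_that("correlation reports match closed-form regression and cor.test", {
  x <- c(1, 2, 3, 4, 5)
  r <- correlate(2 * x + 1, x)
  expect_equal(r$R, 1)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)
  set.seed(43)
  xs <- rnorm(30); ys <- 0.6 * xs + rnorm(30)
  got <- correlate(ys, xs)
  ref <- stats::cor.test(xs, ys)
  expect_equal(got$R, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
  expect_error(correlate(c(1, 2), c(1, 2)), "at least 3")
  expect_error(correlate(rep(1, 5), 1:5), "zero variance")
  ## subset mask restricts the pairs
  sub <- correlate(ys, xs, subset = seq_along(xs) <= 10, label = "first10")
  expect_equal(sub$n, 10)
})

test_that("null correlations at n = 74 stay below the 5% critical value", {
  ## |R| < ~0.23 for ~95% of independent draws at n = 74
  set.seed(44)
  rs <- replicate(400, stats::cor(rnorm(74), rnorm(74)))
  crit <- 1.993 / sqrt(72 + 1.993^2)    # t-based critical value, alpha 0.05
  expect_equal(crit, 0.229, tolerance = 0.01)
  expect_gt(mean(abs(rs) < 0.23), 0.92)
})

test_that("t-based p-values agree with a permutation test", {
  set.seed(45)
  for (i in 1:3) {
    x <- rnorm(20)
    y <- 0.4 * x + rnorm(20)
    r <- correlate(y, x)
    robs <- abs(stats::cor(x, y))
    perm <- replicate(1e4, abs(stats::cor(x, sample(y))))
    p_perm <- (1 + sum(perm >= robs)) / (1e4 + 1)
    se <- sqrt(p_perm * (1 - p_perm) / 1e4)
    expect_lt(abs(r$p_value - p_perm), max(6 * se, 0.005))
  }
})

test_that("ranking files round-trip through the CSV dialect", {
  items <- letters[1:8]
  seqs <- make_participants(items, noise_sigma = 1, n_subjects = 5, seed = 6)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_rankings(seqs, tmp)
  back <- read_rankings(tmp)
  expect_identical(unname(back), unname(seqs))
  expect_identical(readLines(tmp)[1],
                   gsub("<div[12]>", "|", paste(seqs[[1]], collapse = ",")))
})
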