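# Brute-force oracles: two-pass min/max standardization, double-loop
# squared differences, and naive histogram binning.

standardizeOracle <- function(x) {
  mn <- Inf; mx <- -Inf
  for (v in x) { if (v < mn) mn <- v; if (v > mx) mx <- v }
  if (mx == mn) return(x * 0)
  out <- x
  for (i in seq_along(x)) out[i] <- (x[i] - mn) / (mx - mn)
  out
}

colorDiffOracle <- function(x, y, c) {
  acc <- 0; n <- 0
  for (i in seq_len(dim(x)[1])) for (j in seq_len(dim(x)[2])) {
    acc <- acc + (x[i, j, c] - y[i, j, c])^2
    n <- n + 1
  }
  acc / n
}

histOracle <- function(img, bins) {
  counts <- matrix(0L, bins, 3)
  for (c in 1:3) for (v in img[, , c]) {
    b <- min(floor(v * bins), bins - 1) + 1
    counts[b, c] <- counts[b, c] + 1L
  }
  counts
}

test_that("standardization maps global extremes to 0 and 1", {
  expect_equal(standardizeImage(matrix(c(0, 4, 2, 8), 2)),
               matrix(c(0, 0.5, 0.25, 1), 2))
  const <- array(0.7, c(3, 3, 3))
  expect_equal(standardizeImage(const), const * 0)
  x <- seededImage(4, 4, 10)
  s <- standardizeImage(x)
  expect_equal(s, standardizeOracle(x), tolerance = 1e-14)
  expect_equal(min(s), 0)
  expect_equal(max(s), 1)
  # idempotent once the input spans [0,1]
  expect_equal(standardizeImage(s), s, tolerance = 1e-14)
  expect_error(standardizeImage(numeric(0)), "empty")
})

test_that("the difference image standardizes the subtraction", {
  x <- round(seededImage(6, 6, 11) * 64) / 64   # dyadic grid: exact shifts
  expect_equal(imageDiff(x, x), x * 0)
  expect_equal(imageDiff(x, x + 0.25), x * 0)   # constant offset
  x <- seededImage(6, 6, 11)
  y <- seededImage(6, 6, 12)
  expect_equal(imageDiff(x, y), standardizeOracle(x - y), tolerance = 1e-14)
  expect_true(all(imageDiff(x, y) >= 0 & imageDiff(x, y) <= 1))
  expect_error(imageDiff(x, seededImage(5, 6, 1)), "shape")
})

test_that("per-channel colour difference is the mean squared plane difference", {
  x <- seededImage(8, 8, 13)
  expect_equal(colorDiff(x, x, 1), 0)
  y <- x; y[, , 2] <- pmin(y[, , 2] + 0.1, 2)
  expect_equal(colorDiff(x, y, 2), 0.01, tolerance = 1e-12)
  z <- seededImage(8, 8, 14)
  for (c in 1:3)
    expect_equal(colorDiff(x, z, c), colorDiffOracle(x, z, c),
                 tolerance = 1e-14)
  expect_equal(colorDiff(x, z, 1, aggregate = "sum"),
               64 * colorDiffOracle(x, z, 1), tolerance = 1e-12)
  expect_error(colorDiff(x, z, 4), "channel")
})

test_that("benchmark value is the root of summed channel differences", {
  x <- seededImage(8, 8, 15)
  expect_equal(benchmarkValue(x, x), 0)
  y <- x + 0.1  # uniform offset on all channels
  expect_equal(benchmarkValue(x, y), sqrt(3) * 0.1, tolerance = 1e-12)
  z <- seededImage(8, 8, 16)
  expect_equal(benchmarkValue(x, z),
               sqrt(sum(vapply(1:3, function(c) colorDiffOracle(x, z, c),
                               numeric(1)))),
               tolerance = 1e-14)
  expect_equal(benchmarkValue(x, z), benchmarkValue(z, x))
  expect_lte(benchmarkValue(array(0, c(4, 4, 3)), array(1, c(4, 4, 3))),
             sqrt(3))
})

test_that("channel histograms bin [0,1] values with 1.0 in the last bin", {
  zero <- array(0, c(4, 5, 3))
  h <- channelHistograms(zero, 256)
  expect_equal(h@counts[1, ], rep(20L, 3))
  expect_equal(colSums(h@counts), rep(20, 3))
  one <- array(1, c(4, 5, 3))
  h1 <- channelHistograms(one, 16)
  expect_equal(h1@counts[16, ], rep(20L, 3))
  img <- seededImage(8, 8, 17)
  h2 <- channelHistograms(img, 32)
  expect_equal(h2@counts, histOracle(img, 32))
  expect_equal(colSums(h2@counts), rep(64, 3))
  expect_error(channelHistograms(img, 1), "bins")
})

test_that("pooled histogram statistics match direct formulas", {
  mk <- function(counts) new("ChannelHistogram", bins = length(counts),
                             counts = cbind(counts, counts, counts))
  flat <- new("ChannelHistogram", bins = 4L,
              counts = matrix(c(10L, 10L, 10L, 10L), 4, 1))
  s <- histogramStats(flat)
  expect_equal(s@stdDev, 0); expect_equal(s@scale, 0); expect_equal(s@cov, 0)

  two <- new("ChannelHistogram", bins = 2L, counts = matrix(c(0L, 100L), 2, 1))
  s2 <- histogramStats(two)
  expect_equal(s2@min, 0); expect_equal(s2@max, 100)
  expect_equal(s2@scale, 100); expect_equal(s2@stdDev, 50)
  expect_equal(s2@cov, 1)

  hists <- lapply(1:5, function(i) channelHistograms(seededImage(8, 8, i), 16))
  pooled <- unlist(lapply(hists, function(h) as.vector(h@counts)))
  s3 <- histogramStats(hists)
  expect_equal(s3@min, min(pooled))
  expect_equal(s3@max, max(pooled))
  expect_equal(s3@scale, max(pooled) - min(pooled))
  expect_equal(s3@stdDev, sqrt(mean((pooled - mean(pooled))^2)))
  expect_equal(s3@cov, s3@stdDev / mean(pooled))
  expect_error(histogramStats(list()), "at least one")
})
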