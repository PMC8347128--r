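# Independent oracles used here: nested-loop bilinear interpolation and a
# direct brute-force enhancement (brightness, contrast, 3x3 kernel with
# zero padding), written against the documented conventions only.

bilinearOracle <- function(img, target) {
  n <- dim(img)[1]
  out <- array(0, dim = c(target, target, dim(img)[3]))
  for (c in seq_len(dim(img)[3])) for (i in seq_len(target))
    for (j in seq_len(target)) {
      sy <- min(max((i - 0.5) * n / target - 0.5, 0), n - 1)
      sx <- min(max((j - 0.5) * n / target - 0.5, 0), n - 1)
      y0 <- floor(sy); x0 <- floor(sx)
      wy <- sy - y0; wx <- sx - x0
      y1 <- min(y0 + 1, n - 1); x1 <- min(x0 + 1, n - 1)
      out[i, j, c] <-
        (1 - wy) * ((1 - wx) * img[y0 + 1, x0 + 1, c] +
                    wx * img[y0 + 1, x1 + 1, c]) +
        wy * ((1 - wx) * img[y1 + 1, x0 + 1, c] +
              wx * img[y1 + 1, x1 + 1, c])
    }
  pmin(pmax(out, 0), 1)
}

enhanceOracle <- function(img, bf, cf, kernel) {
  clip <- function(x) pmin(pmax(x, 0), 1)
  out <- clip(img * bf)
  for (c in 1:3) {
    m <- mean(out[, , c])
    out[, , c] <- (out[, , c] - m) * cf + m
  }
  out <- clip(out)
  H <- dim(out)[1]; W <- dim(out)[2]
  conv <- out
  for (c in 1:3) for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      v <- if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        out[ii, jj, c] else 0
      acc <- acc + v * kernel[di + 2, dj + 2]
    }
    conv[i, j, c] <- acc
  }
  clip(conv)
}

test_that("square padding centres content in a zero square of side max(H,W)", {
  crop <- seededImage(100, 60, 1)
  out <- squarePad(crop)
  expect_equal(dim(out), c(100L, 100L, 3L))
  expect_equal(out[, 21:80, ], crop)
  expect_true(all(out[, c(1:20, 81:100), ] == 0))

  sq <- seededImage(50, 50, 2)
  expect_identical(squarePad(sq), sq)

  wide <- seededImage(3, 7, 3)
  out <- squarePad(wide)
  expect_equal(dim(out), c(7L, 7L, 3L))
  expect_equal(out[3:5, , ], wide)          # offset floor((7-3)/2) = 2
  expect_true(all(out[c(1:2, 6:7), , ] == 0))
  expect_error(squarePad(array(0, c(0, 3, 3))), "non-empty")
})

test_that("pad-then-crop recovers the original bit-exactly", {
  for (dims in list(c(5, 9), c(9, 5), c(8, 8), c(1, 4))) {
    crop <- seededImage(dims[1], dims[2], sum(dims))
    padded <- squarePad(crop)
    S <- max(dims)
    r0 <- floor((S - dims[1]) / 2); c0 <- floor((S - dims[2]) / 2)
    back <- padded[(r0 + 1):(r0 + dims[1]), (c0 + 1):(c0 + dims[2]), ,
                   drop = FALSE]
    expect_identical(back, crop)
  }
})

test_that("bilinear resize matches a nested-loop oracle and fixes edge cases", {
  img <- seededImage(32, 32, 4)
  expect_identical(resizeImage(img, 32), img)

  const <- array(0.37, c(5, 5, 3))
  expect_equal(resizeImage(const, 9), array(0.37, c(9, 9, 3)))

  checker <- array(0, c(2, 2, 3))
  checker[1, 2, ] <- 1; checker[2, 1, ] <- 1
  expect_equal(resizeImage(checker, 4), bilinearOracle(checker, 4),
               tolerance = 1e-12)

  rnd <- seededImage(6, 6, 5)
  expect_equal(resizeImage(rnd, 10), bilinearOracle(rnd, 10),
               tolerance = 1e-12)
  expect_equal(resizeImage(rnd, 3), bilinearOracle(rnd, 3),
               tolerance = 1e-12)
  expect_error(resizeImage(rnd, 0), "target")
})

test_that("enhancement follows brightness, contrast, kernel order exactly", {
  const <- array(0.2, c(6, 6, 3))
  cfg9 <- enhanceConfig(brightnessFactor = 1, contrastFactor = 1,
                        kernelCenter = 9)
  out <- enhanceImage(const, cfg9)       # kernel sums to 1
  expect_equal(out[3, 3, 1], 0.2, tolerance = 1e-12)
  cfg11 <- enhanceConfig(brightnessFactor = 1, contrastFactor = 1,
                         kernelCenter = 11)
  out <- enhanceImage(const, cfg11)      # kernel sums to 3
  expect_equal(out[3, 3, 2], 0.6, tolerance = 1e-12)

  rnd <- seededImage(8, 8, 6)
  cfg <- enhanceConfig()                 # reference defaults: 2 / 0.6 / 11
  expect_equal(enhanceImage(rnd, cfg),
               enhanceOracle(rnd, 2, 0.6, cfg$kernel), tolerance = 1e-12)

  ident <- matrix(0, 3, 3); ident[2, 2] <- 1
  cfgI <- enhanceConfig(brightnessFactor = 1, contrastFactor = 1,
                        kernel = ident)
  expect_equal(enhanceImage(rnd, cfgI), rnd, tolerance = 1e-12)
  expect_error(enhanceImage(rnd, list(brightnessFactor = 1,
                                      contrastFactor = 1,
                                      kernel = matrix(0, 2, 2))), "3x3")
})

test_that("augmentation count is (1 + shifts) x (360 / step)", {
  img <- seededImage(16, 16, 7)
  expect_length(augmentImage(img, augmentConfig(rotationStep = 45)), 8L)
  expect_length(augmentImage(img, augmentConfig(
    rotationStep = 45,
    shifts = list(c(2, 0), c(0, 2), c(-2, -2)))), 32L)
  const <- array(0.5, c(8, 8, 3))
  out <- augmentImage(const, augmentConfig(rotationStep = 90))
  expect_length(out, 4L)
  for (o in out) expect_equal(o, const)
  expect_error(augmentImage(seededImage(4, 6, 1), augmentConfig()),
               "square")
  expect_error(augmentConfig(rotationStep = 50), "divisible")
})

test_that("rotations at multiples of 90 degrees are exact permutations", {
  img <- seededImage(9, 9, 8)
  r90 <- rotateImage(img, 90)
  expect_identical(rotateImage(r90, 270), img)
  expect_identical(rotateImage(rotateImage(r90, 90), 180), img)
  expect_identical(rotateImage(img, 360), img)
  # content is preserved exactly (pure permutation, no resampling)
  expect_equal(sort(as.vector(r90)), sort(as.vector(img)))
})

test_that("quality filter drops near-constant frames and keeps real crops", {
  const <- array(0.4, c(12, 12, 3))
  crops <- makeDataset(10, sceneParams(12, 12, nFish = 1L,
                                       contrastDelta = 0.3, seed = 31L))$frames
  res <- qualityFilter(c(crops, rep(list(const), 5)), tau = 0.02)
  expect_length(res$kept, 10L)
  expect_length(res$dropped, 5L)
  res0 <- qualityFilter(c(crops, list(const)), tau = 0)
  expect_length(res0$kept, 11L)
  expect_error(qualityFilter(crops, tau = -1), "tau")
})

test_that("the preprocessing pipeline produces the expected outputs deterministically", {
  src <- withr::local_tempdir()
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  writeScenes(10, sceneParams(20, 20, nFish = 1L, contrastDelta = 0.3,
                              seed = 41L), src)
  m1 <- preprocessPipeline(src, out1, augment = augmentConfig(45),
                           target = 16L)
  expect_equal(m1$n_output, 80L)      # 10 crops x 8 rotations
  expect_length(list.files(out1, pattern = "\\.png$"), 80L)
  m2 <- preprocessPipeline(src, out2, augment = augmentConfig(45),
                           target = 16L)
  expect_equal(m1$outputs, m2$outputs)
  f <- list.files(out1, pattern = "\\.png$")[1]
  expect_identical(readBin(file.path(out1, f), "raw", 1e6),
                   readBin(file.path(out2, f), "raw", 1e6))
  empty <- withr::local_tempdir()
  expect_error(preprocessPipeline(empty, out1), "no PNG")
})
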