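# Closed forms used throughout: dense n_in*n_out + n_out;
# conv/transposed conv 9*c_in*c_out + c_out; pooling/up-sampling 0.

test_that("architecture strings parse into validated specs", {
  sp <- parseModelSpec("256-64", "mlp")
  expect_equal(sp@stages, c(256L, 64L))
  expect_equal(aquae:::specLatentShape(sp), 64L)

  sc <- parseModelSpec("64-32-16", "cnn", 256)
  expect_equal(aquae:::specLatentShape(sc), c(32L, 32L, 16L))
  s5 <- parseModelSpec("512-256-128-64-32", "cnn", 256)
  expect_equal(aquae:::specLatentShape(s5), c(8L, 8L, 32L))

  expect_error(parseModelSpec("256-x-64", "mlp"), "positive integers")
  expect_error(parseModelSpec("256-0-64", "mlp"), "strictly positive")
  expect_error(parseModelSpec("8-8-8-8", "cnn", 100), "divisible")
})

test_that("MLP builder reproduces the baseline per-layer accounting", {
  m <- buildMLP(parseModelSpec("256-128-64", "mlp", 256))
  df <- modelSummary(m)
  expect_equal(df$params,
               c(0L, 50331904L, 32896L, 8256L, 8320L, 33024L, 50528256L))
  expect_equal(df$output_shape,
               c("(None, 196608)", "(None, 256)", "(None, 128)",
                 "(None, 64)", "(None, 128)", "(None, 256)",
                 "(None, 196608)"))
  expect_equal(df$name[4], "latent")
  expect_equal(df$activation[7], "Sigmoid")
  expect_equal(countParams(m), sum(df$params))
})

test_that("CNN builder reproduces the baseline per-layer accounting", {
  m <- buildCNN(parseModelSpec("256-128-64", "cnn", 256))
  df <- modelSummary(m)
  expect_equal(df$params,
               c(0L, 7168L, 0L, 295040L, 0L, 73792L, 0L, 36928L, 0L,
                 73856L, 0L, 295168L, 0L, 6915L))
  expect_equal(df$output_shape[c(1, 2, 7, 8, 13, 14)],
               c("(None, 256, 256, 3)", "(None, 256, 256, 256)",
                 "(None, 32, 32, 64)", "(None, 32, 32, 64)",
                 "(None, 256, 256, 256)", "(None, 256, 256, 3)"))
  expect_equal(latentShape(m), c(32L, 32L, 64L))
  expect_equal(df$name[7], "latent")
})

test_that("parameter counts obey the dense and convolution closed forms", {
  # single dense stage on a 2x2x3 input: (12*1+1) + (1*12+12) = 37
  m1 <- buildMLP(parseModelSpec("1", "mlp", 2))
  expect_equal(countParams(m1), 37L)
  # one conv stage with 4 filters on RGB: 9*3*4+4 = 112 for the encoder conv
  m2 <- buildCNN(parseModelSpec("4", "cnn", 4))
  expect_equal(modelSummary(m2)$params[2], 112L)
  # property: totals match the closed form for assorted specs
  for (txt in c("32-16", "64-32-16", "16-8-4-2")) {
    spm <- parseModelSpec(txt, "mlp", 16)
    w <- c(16^2 * 3, spm@stages, rev(spm@stages[-length(spm@stages)]),
           16^2 * 3)
    expect_equal(countParams(buildMLP(spm)),
                 sum(w[-length(w)] * w[-1] + w[-1]))
    spc <- parseModelSpec(txt, "cnn", 16)
    ch <- c(3L, spc@stages, rev(spc@stages), 3L)
    expect_equal(countParams(buildCNN(spc)),
                 sum(9L * ch[-length(ch)] * ch[-1] + ch[-1]))
  }
})

test_that("decoder mirrors the encoder stages in reverse", {
  m <- buildCNN(parseModelSpec("64-32-16", "cnn", 64))
  enc <- vapply(Filter(function(l) l$type == "Conv2D" && l$name != "output",
                       m@layers), function(l) ncol(l$W), integer(1))
  dec <- vapply(Filter(function(l) l$type == "Conv2DTranspose", m@layers),
                function(l) ncol(l$W), integer(1))
  expect_equal(dec, rev(enc))
  mm <- buildMLP(parseModelSpec("64-32-16", "mlp", 16))
  widths <- vapply(mm@layers, function(l) ncol(l$W), integer(1))
  expect_equal(widths, c(64L, 32L, 16L, 32L, 64L, 16L^2 * 3L))
})

test_that("encode and decode preserve the declared shapes for all table specs", {
  img32 <- seededImage(32, 32, 20)
  for (txt in c("64-32-16", "128-64-32", "256-64")) {
    m <- buildMLP(parseModelSpec(txt, "mlp", 32))
    lat <- encode(m, img32)
    expect_length(lat, m@latentShape)
    rec <- decode(m, lat)
    expect_equal(dim(rec), dim(img32))
    expect_true(all(rec >= 0 & rec <= 1))
  }
  for (txt in c("64-32-16", "128-64-32", "256-128-64-32",
                "512-256-128-64-32")) {
    m <- buildCNN(parseModelSpec(txt, "cnn", 32))
    lat <- encode(m, img32)
    expect_equal(dim(lat), as.integer(latentShape(m)))
    rec <- decode(m, lat)
    expect_equal(dim(rec), dim(img32))
    expect_true(all(rec >= 0 & rec <= 1))
  }
  expect_error(encode(buildMLP(parseModelSpec("8", "mlp", 16)), img32),
               "shape")
})

test_that("zero weights give a zero latent and a flat 0.5 reconstruction", {
  m <- buildCNN(parseModelSpec("4-2", "cnn", 16), seed = 5)
  zero <- aquae:::setParams(m, lapply(aquae:::getParams(m), function(p) p * 0))
  img <- seededImage(16, 16, 21)
  lat <- encode(zero, img)
  expect_true(all(lat == 0))
  rec <- decode(zero, lat)
  expect_equal(rec, array(0.5, dim(img)))
})

test_that("weight initialization is reproducible from the seed", {
  a <- buildCNN(parseModelSpec("8-4", "cnn", 16), seed = 7)
  b <- buildCNN(parseModelSpec("8-4", "cnn", 16), seed = 7)
  expect_identical(aquae:::getParams(a), aquae:::getParams(b))
  img <- seededImage(16, 16, 22)
  expect_identical(encode(a, img), encode(a, img))
  c2 <- buildCNN(parseModelSpec("8-4", "cnn", 16), seed = 8)
  expect_false(identical(aquae:::getParams(a), aquae:::getParams(c2)))
})

test_that("backpropagated gradients match finite differences", {
  img <- seededImage(8, 8, 23)
  m <- buildCNN(parseModelSpec("4-3", "cnn", 8), seed = 3)
  fw <- aquae:::cnnForward(m@layers, img)
  gr <- aquae:::cnnBackward(m@layers, fw$caches,
                            aquae:::lossAndGrad(fw$out, img, "mse")$dZ)
  lossAt <- function(model) {
    a <- aquae:::cnnForward(model@layers, img)$out
    mean((a - img)^2)
  }
  set.seed(1)
  for (li in c(1, 3, 5, 7, 9)) for (k in 1:3) {
    i <- sample(length(m@layers[[li]]$W), 1)
    eps <- 1e-6
    up <- m; up@layers[[li]]$W[i] <- up@layers[[li]]$W[i] + eps
    dn <- m; dn@layers[[li]]$W[i] <- dn@layers[[li]]$W[i] - eps
    num <- (lossAt(up) - lossAt(dn)) / (2 * eps)
    expect_equal(gr[[li]]$dW[i], num, tolerance = 1e-4)
  }

  mm <- buildMLP(parseModelSpec("16-8", "mlp", 8), seed = 4)
  X <- matrix(runif(2 * 192), 2, 192)
  fw <- aquae:::mlpForward(mm@layers, X)
  gr <- aquae:::mlpBackward(mm@layers, fw$caches,
                            aquae:::lossAndGrad(fw$out, X, "bce")$dZ)
  lossAtM <- function(model) {
    a <- aquae:::mlpForward(model@layers, X)$out
    a <- pmin(pmax(a, 1e-7), 1 - 1e-7)
    -mean(X * log(a) + (1 - X) * log(1 - a))
  }
  for (li in 1:4) for (k in 1:3) {
    i <- sample(length(mm@layers[[li]]$W), 1)
    eps <- 1e-6
    up <- mm; up@layers[[li]]$W[i] <- up@layers[[li]]$W[i] + eps
    dn <- mm; dn@layers[[li]]$W[i] <- dn@layers[[li]]$W[i] - eps
    num <- (lossAtM(up) - lossAtM(dn)) / (2 * eps)
    expect_equal(gr[[li]]$dW[i], num, tolerance = 1e-4)
  }
})
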