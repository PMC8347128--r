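# Shared fixtures: seeded random images and small scene parameter sets.

seededImage <- function(h, w, seed, channels = 3L) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  array(runif(h * w * channels), dim = c(h, w, channels))
}

quietParams <- function(h = 16, w = 16, seed = 1L, ...) {
  sceneParams(h, w, nFish = 0L, contrastDelta = 0.1, noiseSigma = 0,
              gradientStrength = 0, clutterDensity = 0, seed = seed, ...)
}

# small CNN trained for a handful of epochs on tiny scenes; memoised per
# test file run
tinyTrainedCNN <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    ds <- makeDataset(16, sceneParams(32, 32, nFish = 1L, seed = 11))
    m <- buildCNN(parseModelSpec("8-4", "cnn", 32), seed = 2)
    m <- fitAutoencoder(m, ds$frames,
                        trainConfig(epochs = 4, seed = 2, patience = 10))
    cache <<- list(model = m, data = ds)
    cache
  }
})
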