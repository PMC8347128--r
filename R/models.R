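# Symmetric autoencoder builders with exact parameter accounting, plus
# the forward/backward machinery the trainer uses. Dense layers run as
# batched matrix products; convolutional layers run per image through
# the compiled kernels in src/.

#' Parse a dash-separated architecture string
#'
#' Row labels like \code{"256-64"} (MLP dense widths ending at the latent
#' length) or \code{"256-128-64"} (CNN filter counts per
#' convolution+pooling block) become a validated [ModelSpec-class].
#'
#' @param text dash-separated positive integers, e.g. \code{"256-64"}.
#' @param family "mlp" or "cnn".
#' @param inputSide input image side in pixels (default 256). For the
#'   CNN family it must be divisible by \code{2^nstages}.
#' @param channels colour channels (default 3).
#' @return a [ModelSpec-class].
#' @examples
#' parseModelSpec("256-128-64", "cnn")   # latent (32, 32, 64)
#' @export
parseModelSpec <- function(text, family = c("mlp", "cnn"),
                           inputSide = 256L, channels = 3L) {
  family <- match.arg(family)
  toks <- strsplit(text, "-", fixed = TRUE)[[1]]
  if (length(toks) == 0L || !all(grepl("^[0-9]+$", toks)))
    stop("spec must be dash-separated positive integers, got '", text, "'")
  stages <- as.integer(toks)
  if (any(stages == 0L)) stop("stage widths must be strictly positive")
  new("ModelSpec", family = family, stages = stages,
      inputSide = as.integer(inputSide), channels = as.integer(channels))
}

specLatentShape <- function(spec) {
  if (spec@family == "mlp") {
    spec@stages[length(spec@stages)]
  } else {
    side <- spec@inputSide %/% 2L^length(spec@stages)
    c(side, side, spec@stages[length(spec@stages)])
  }
}

# index of the layer whose output is the latent code
latentIndex <- function(spec) {
  if (spec@family == "mlp") length(spec@stages)
  else 2L * length(spec@stages)
}

denseLayer <- function(nIn, nOut, act, name) {
  lim <- sqrt(1 / nIn)
  list(kind = "dense", type = "Dense",
       W = matrix(runif(nIn * nOut, -lim, lim), nIn, nOut),
       b = numeric(nOut), act = act, name = name)
}

convLayer <- function(cIn, cOut, act, name, type = "Conv2D") {
  fanIn <- 9L * cIn
  lim <- sqrt(1 / fanIn)
  list(kind = "conv", type = type,
       W = matrix(runif(fanIn * cOut, -lim, lim), fanIn, cOut),
       b = numeric(cOut), act = act, name = name)
}

#' Build a symmetric MLP autoencoder
#'
#' The flattened input (side^2 x channels) passes through the dense
#' encoder stages (rectifier activations) down to the latent layer (the
#' last stage width); the decoder mirrors the remaining stages in
#' reverse and a final dense layer with sigmoid activation restores the
#' flattened image, so reconstructions always lie in [0,1]. Every dense
#' layer carries a bias.
#'
#' @param spec an mlp-family [ModelSpec-class].
#' @param seed integer seed for weight initialization (uniform, scaled
#'   by 1/sqrt(fan-in); biases zero).
#' @return an [Autoencoder-class].
#' @export
buildMLP <- function(spec, seed = 1L) {
  stopifnot(is(spec, "ModelSpec"))
  if (spec@family != "mlp") stop("buildMLP needs an mlp-family spec")
  validObject(spec)
  nIn <- spec@inputSide^2L * spec@channels
  k <- length(spec@stages)
  withSceneSeed(seed, {
    layers <- list()
    prev <- nIn
    for (i in seq_len(k)) {
      nm <- if (i == k) "latent" else paste0("encoded_", spec@stages[i])
      layers[[length(layers) + 1L]] <-
        denseLayer(prev, spec@stages[i], "relu", nm)
      prev <- spec@stages[i]
    }
    if (k > 1L) for (w in rev(spec@stages[-k])) {
      layers[[length(layers) + 1L]] <-
        denseLayer(prev, w, "relu", paste0("decoded_", w))
      prev <- w
    }
    layers[[length(layers) + 1L]] <-
      denseLayer(prev, nIn, "sigmoid", "output")
    new("Autoencoder", spec = spec, layers = layers,
        latentShape = as.integer(specLatentShape(spec)), history = list())
  })
}

#' Build a symmetric CNN autoencoder
#'
#' Each encoder stage is a 3x3 stride-1 same-padded convolution
#' (rectifier) followed by 2x2 max pooling; the latent code is the final
#' pooled tensor. The decoder mirrors the stages in reverse with 3x3
#' transposed convolutions (stride 1, realized as same-padded
#' convolutions, which they equal at stride 1) and 2x2 nearest-neighbour
#' up-sampling. The output head is a 3x3 convolution onto 3 channels
#' with sigmoid activation — a per-pixel dense head could not account
#' for the parameter budget this architecture carries, a 3x3 head does
#' exactly.
#'
#' @inheritParams buildMLP
#' @param spec a cnn-family [ModelSpec-class].
#' @return an [Autoencoder-class].
#' @export
buildCNN <- function(spec, seed = 1L) {
  stopifnot(is(spec, "ModelSpec"))
  if (spec@family != "cnn") stop("buildCNN needs a cnn-family spec")
  validObject(spec)
  k <- length(spec@stages)
  withSceneSeed(seed, {
    layers <- list()
    prev <- spec@channels
    for (i in seq_len(k)) {
      f <- spec@stages[i]
      layers[[length(layers) + 1L]] <-
        convLayer(prev, f, "relu", paste0("Conv2D_", f))
      poolName <- if (i == k) "latent" else paste0("MaxPooling_", f)
      layers[[length(layers) + 1L]] <-
        list(kind = "pool", type = "MaxPooling2D", name = poolName)
      prev <- f
    }
    for (f in rev(spec@stages)) {
      layers[[length(layers) + 1L]] <-
        convLayer(prev, f, "relu", paste0("Conv2DT_", f),
                  type = "Conv2DTranspose")
      layers[[length(layers) + 1L]] <-
        list(kind = "up", type = "UpSampling2D",
             name = paste0("UpSampling2D_", f))
      prev <- f
    }
    layers[[length(layers) + 1L]] <-
      convLayer(prev, spec@channels, "sigmoid", "output")
    new("Autoencoder", spec = spec, layers = layers,
        latentShape = as.integer(specLatentShape(spec)), history = list())
  })
}

#' Build an autoencoder from its spec
#'
#' Dispatches to [buildMLP()] or [buildCNN()] by family.
#'
#' @inheritParams buildMLP
#' @return an [Autoencoder-class].
#' @export
buildAutoencoder <- function(spec, seed = 1L) {
  if (spec@family == "mlp") buildMLP(spec, seed) else buildCNN(spec, seed)
}

actFun <- function(z, act) {
  switch(act,
         relu = pmax(z, 0),
         sigmoid = 1 / (1 + exp(-z)),
         linear = z,
         stop("unknown activation ", act))
}

# ---- dense (batched) forward/backward -------------------------------

mlpForward <- function(layers, X, from = 1L, to = length(layers)) {
  caches <- vector("list", length(layers))
  for (i in seq(from, to)) {
    ly <- layers[[i]]
    Z <- X %*% ly$W
    Z <- sweep(Z, 2L, ly$b, "+")
    A <- actFun(Z, ly$act)
    caches[[i]] <- list(X = X, A = A)
    X <- A
  }
  list(out = X, caches = caches)
}

# dOut is the gradient w.r.t. the PRE-activation of the last layer (the
# loss functions fold the output activation's derivative in)
mlpBackward <- function(layers, caches, dZ) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    cache <- caches[[i]]
    grads[[i]] <- list(dW = crossprod(cache$X, dZ), db = colSums(dZ))
    if (i > 1L) {
      dA <- dZ %*% t(ly$W)
      prev <- layers[[i - 1L]]
      dZ <- switch(prev$act,
                   relu = dA * (caches[[i - 1L]]$A > 0),
                   sigmoid = dA * caches[[i - 1L]]$A *
                     (1 - caches[[i - 1L]]$A),
                   dA)
    }
  }
  grads
}

# ---- convolutional (per-image) forward/backward ---------------------

cnnForward <- function(layers, x, from = 1L, to = length(layers)) {
  caches <- vector("list", length(layers))
  for (i in seq(from, to)) {
    ly <- layers[[i]]
    if (ly$kind == "conv") {
      Z <- conv2d_fw(x, ly$W, ly$b, 3L)
      A <- actFun(Z, ly$act)
      caches[[i]] <- list(X = x, A = A)
      x <- A
    } else if (ly$kind == "pool") {
      res <- maxpool2_fw(x)
      caches[[i]] <- list(idx = res$idx, H = dim(x)[1], W = dim(x)[2])
      x <- res$Y
    } else {  # up
      x <- upsample2_fw(x)
    }
  }
  list(out = x, caches = caches)
}

cnnBackward <- function(layers, caches, dZ) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    if (ly$kind == "conv") {
      cache <- caches[[i]]
      bw <- conv2d_bw(cache$X, ly$W, dZ, 3L)
      grads[[i]] <- list(dW = bw$dW, db = as.numeric(bw$db))
      dA <- bw$dX
    } else if (ly$kind == "pool") {
      cache <- caches[[i]]
      dA <- maxpool2_bw(caches[[i]]$idx, dZ, cache$H, cache$W)
    } else {
      dA <- upsample2_bw(dZ)
    }
    if (i > 1L) {
      prev <- layers[[i - 1L]]
      dZ <- if (prev$kind == "conv") {
        switch(prev$act,
               relu = dA * (caches[[i - 1L]]$A > 0),
               sigmoid = dA * caches[[i - 1L]]$A *
                 (1 - caches[[i - 1L]]$A),
               dA)
      } else dA
    }
  }
  grads
}

#' @describeIn encode latent code of one image (vector for MLP, array
#'   for CNN).
#' @export
setMethod("encode", "Autoencoder", function(object, x) {
  spec <- object@spec
  li <- latentIndex(spec)
  expected <- c(spec@inputSide, spec@inputSide, spec@channels)
  if (!identical(dim(x), as.integer(expected)))
    stop("input shape ", paste(dim(x), collapse = "x"),
         " does not match model input ", paste(expected, collapse = "x"))
  if (spec@family == "mlp") {
    out <- mlpForward(object@layers, matrix(as.vector(x), nrow = 1L),
                      to = li)$out
    as.numeric(out)
  } else {
    cnnForward(object@layers, x, to = li)$out
  }
})

#' @describeIn decode reconstructs an image from a latent code.
#' @export
setMethod("decode", "Autoencoder", function(object, x) {
  spec <- object@spec
  li <- latentIndex(spec)
  ls <- object@latentShape
  if (spec@family == "mlp") {
    if (length(x) != ls) stop("latent length must be ", ls)
    out <- mlpForward(object@layers, matrix(as.numeric(x), nrow = 1L),
                      from = li + 1L)$out
    array(as.numeric(out), dim = c(spec@inputSide, spec@inputSide,
                                   spec@channels))
  } else {
    if (!identical(dim(x), as.integer(ls)))
      stop("latent shape must be ", paste(ls, collapse = "x"))
    cnnForward(object@layers, x, from = li + 1L)$out
  }
})

#' Reconstruct an image through the full autoencoder
#'
#' @param model a built [Autoencoder-class].
#' @param img image array matching the model input shape.
#' @return reconstruction of the same shape, values in [0,1].
#' @export
reconstructImage <- function(model, img) {
  decode(model, encode(model, img))
}

#' @describeIn countParams sums weights and biases over all layers.
#' @export
setMethod("countParams", "Autoencoder", function(object) {
  sum(vapply(object@layers, function(ly)
    if (is.null(ly$W)) 0L else length(ly$W) + length(ly$b), integer(1)))
})

#' @describeIn latentShape latent dimensions of a built model.
#' @export
setMethod("latentShape", "Autoencoder", function(object) object@latentShape)

#' @describeIn trainHistory training record of a fitted model.
#' @export
setMethod("trainHistory", "Autoencoder", function(object) object@history)

#' @describeIn modelSummary layer table with output shapes and exact
#'   parameter counts.
#' @export
setMethod("modelSummary", "Autoencoder", function(object) {
  spec <- object@spec
  li <- latentIndex(spec)
  rows <- list()
  if (spec@family == "mlp") {
    nIn <- spec@inputSide^2L * spec@channels
    rows[[1]] <- data.frame(
      name = "input", type = "InputLayer",
      output_shape = sprintf("(None, %d)", nIn),
      activation = "", params = 0L, stringsAsFactors = FALSE)
    for (ly in object@layers)
      rows[[length(rows) + 1L]] <- data.frame(
        name = ly$name, type = ly$type,
        output_shape = sprintf("(None, %d)", ncol(ly$W)),
        activation = if (ly$act == "relu") "ReLU" else "Sigmoid",
        params = length(ly$W) + length(ly$b), stringsAsFactors = FALSE)
  } else {
    side <- spec@inputSide
    ch <- spec@channels
    rows[[1]] <- data.frame(
      name = "input", type = "InputLayer",
      output_shape = sprintf("(None, %d, %d, %d)", side, side, ch),
      activation = "", params = 0L, stringsAsFactors = FALSE)
    for (ly in object@layers) {
      if (ly$kind == "conv") {
        ch <- ncol(ly$W)
        p <- length(ly$W) + length(ly$b)
        a <- if (ly$act == "relu") "ReLU" else "Sigmoid"
      } else if (ly$kind == "pool") {
        side <- side %/% 2L
        p <- 0L; a <- ""
      } else {
        side <- side * 2L
        p <- 0L; a <- ""
      }
      rows[[length(rows) + 1L]] <- data.frame(
        name = ly$name, type = ly$type,
        output_shape = sprintf("(None, %d, %d, %d)", side, side, ch),
        activation = a, params = p, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
})

#' @describeIn modelSummary printed layer table in the conventional
#'   summary layout.
#' @param object an \code{Autoencoder}.
#' @export
setMethod("show", "Autoencoder", function(object) {
  cat(sprintf("Symmetric %s autoencoder | spec %s | input %dx%dx%d\n",
              toupper(object@spec@family),
              paste(object@spec@stages, collapse = "-"),
              object@spec@inputSide, object@spec@inputSide,
              object@spec@channels))
  cat(sprintf("latent shape: (%s) | trainable params: %s\n",
              paste(object@latentShape, collapse = ", "),
              format(countParams(object), big.mark = ",")))
  df <- modelSummary(object)
  df$params <- format(df$params, big.mark = ",")
  print(df, right = FALSE)
  if (length(object@history))
    cat(sprintf("fitted: %d epochs, best epoch %d\n",
                length(object@history$loss), object@history$bestEpoch))
})

# flat parameter access for the optimizer
getParams <- function(model) {
  out <- list()
  for (i in seq_along(model@layers)) {
    ly <- model@layers[[i]]
    if (!is.null(ly$W)) {
      out[[paste0("W", i)]] <- ly$W
      out[[paste0("b", i)]] <- ly$b
    }
  }
  out
}

setParams <- function(model, params) {
  for (i in seq_along(model@layers)) {
    if (!is.null(model@layers[[i]]$W)) {
      model@layers[[i]]$W <- params[[paste0("W", i)]]
      model@layers[[i]]$b <- params[[paste0("b", i)]]
    }
  }
  model
}
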