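# Self-supervised training: seeded 80/20 partition, Adam minibatch
# optimization with early stopping and best-weight restoration, and
# benchmark-based evaluation of a fitted model.

#' Create a training configuration
#'
#' Defaults follow the reference operating point: Adam with step size
#' 0.001 and moment decays 0.9/0.999, batch size 8, up to 512 epochs,
#' an 80/20 train/test partition, and the family-default loss (binary
#' cross-entropy for MLP, mean squared error for CNN), averaged per
#' pixel. Convergence is operationalized as early stopping: training
#' halts after \code{patience} epochs without validation improvement
#' and the best-epoch weights are restored.
#'
#' @param epochs maximum epochs (>= 1).
#' @param batchSize minibatch size.
#' @param lr,beta1,beta2,epsilon Adam hyperparameters.
#' @param loss "bce", "mse", or "" for the family default.
#' @param splitFraction train fraction in (0,1).
#' @param seed seed for weight updates' minibatch order.
#' @param patience epochs without improvement before stopping.
#' @return a [TrainConfig-class].
#' @export
trainConfig <- function(epochs = 512L, batchSize = 8L, lr = 0.001,
                        beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                        loss = "", splitFraction = 0.8, seed = 1L,
                        patience = 32L) {
  new("TrainConfig", epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), lr = lr, beta1 = beta1,
      beta2 = beta2, epsilon = epsilon, loss = loss,
      splitFraction = splitFraction, seed = as.integer(seed),
      patience = as.integer(patience))
}

#' Randomly partition a dataset
#'
#' Disjoint, exhaustive, seeded shuffle; the training half holds
#' \code{round(fraction * N)} items.
#'
#' @param items a list (or vector) of at least 2 items.
#' @param fraction train fraction in (0,1), default 0.8.
#' @param seed integer seed.
#' @return list with \code{train} and \code{test} subsets.
#' @export
splitDataset <- function(items, fraction = 0.8, seed = 1L) {
  n <- length(items)
  if (n < 2L) stop("splitDataset needs at least 2 items")
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1")
  withSceneSeed(seed, {
    idx <- sample.int(n)
    nTrain <- round(fraction * n)
    list(train = items[idx[seq_len(nTrain)]],
         test = items[idx[-seq_len(nTrain)]])
  })
}

.EPS <- 1e-7  # clamp for the cross-entropy logs

# loss value and gradient w.r.t. the output PRE-activation (sigmoid
# derivative folded in), both averaged per pixel
lossAndGrad <- function(a, y, loss) {
  P <- length(a)
  if (loss == "bce") {
    ac <- pmin(pmax(a, .EPS), 1 - .EPS)
    list(loss = -sum(y * log(ac) + (1 - y) * log(1 - ac)) / P,
         dZ = (a - y) / P)
  } else {
    d <- a - y
    list(loss = sum(d * d) / P, dZ = 2 * d / P * a * (1 - a))
  }
}

evalLoss <- function(model, data, loss) {
  spec <- model@spec
  if (spec@family == "mlp") {
    X <- t(vapply(data, as.vector, numeric(length(data[[1]]))))
    a <- mlpForward(model@layers, X)$out
    if (loss == "bce") {
      ac <- pmin(pmax(a, .EPS), 1 - .EPS)
      -mean(X * log(ac) + (1 - X) * log(1 - ac))
    } else mean((a - X)^2)
  } else {
    mean(vapply(data, function(img) {
      a <- cnnForward(model@layers, img)$out
      lossAndGrad(a, img, loss)$loss
    }, numeric(1)))
  }
}

#' Fit an autoencoder to reconstruct its inputs
#'
#' Self-supervised training (input = target) with Adam. Minibatch order
#' is drawn from the configuration seed, so two runs with the same
#' seed, data and initial weights produce identical loss curves in
#' single-threaded mode. When a validation set is supplied, its loss is
#' recorded each epoch and drives early stopping; otherwise the
#' training loss does.
#'
#' @param model a built [Autoencoder-class].
#' @param data list of image arrays matching the model input shape,
#'   values in [0,1].
#' @param cfg a [TrainConfig-class].
#' @param validation optional list of image arrays.
#' @return the fitted [Autoencoder-class]; retrieve the per-epoch
#'   record with [trainHistory()].
#' @export
fitAutoencoder <- function(model, data, cfg = trainConfig(),
                           validation = NULL) {
  stopifnot(is(model, "Autoencoder"), is(cfg, "TrainConfig"))
  validObject(cfg)
  if (length(data) == 0L) stop("no training data supplied")
  spec <- model@spec
  expected <- as.integer(c(spec@inputSide, spec@inputSide, spec@channels))
  for (img in data)
    if (!identical(dim(img), expected))
      stop("training image shape does not match the model input")
  loss <- if (nzchar(cfg@loss)) cfg@loss
          else if (spec@family == "mlp") "bce" else "mse"
  params <- getParams(model)
  mState <- lapply(params, function(p) p * 0)
  vState <- lapply(params, function(p) p * 0)
  tStep <- 0L
  n <- length(data)
  histLoss <- numeric(0)
  histVal <- numeric(0)
  bestMonitor <- Inf
  bestParams <- params
  bestEpoch <- 0L
  badEpochs <- 0L
  stoppedEarly <- FALSE
  isMLP <- spec@family == "mlp"
  if (isMLP)
    Xall <- t(vapply(data, as.vector, numeric(length(data[[1]]))))
  withSceneSeed(cfg@seed, {
    for (epoch in seq_len(cfg@epochs)) {
      ord <- sample.int(n)
      epochLoss <- 0
      for (b0 in seq(1L, n, by = cfg@batchSize)) {
        # the shuffle decides batch composition; members are processed in
        # index order so the accumulated loss is independent of the
        # within-batch permutation (which is mathematically irrelevant)
        idx <- sort(ord[b0:min(b0 + cfg@batchSize - 1L, n)])
        B <- length(idx)
        if (isMLP) {
          Xb <- Xall[idx, , drop = FALSE]
          fw <- mlpForward(model@layers, Xb)
          lg <- lossAndGrad(fw$out, Xb, loss)
          lg$loss <- lg$loss  # per-pixel mean over the whole batch
          grads <- mlpBackward(model@layers, fw$caches, lg$dZ)
          batchLoss <- lg$loss
        } else {
          grads <- NULL
          batchLoss <- 0
          for (j in idx) {
            fw <- cnnForward(model@layers, data[[j]])
            lg <- lossAndGrad(fw$out, data[[j]], loss)
            batchLoss <- batchLoss + lg$loss / B
            g <- cnnBackward(model@layers, fw$caches, lg$dZ / B)
            if (is.null(grads)) grads <- g
            else for (i in seq_along(g)) if (!is.null(g[[i]])) {
              grads[[i]]$dW <- grads[[i]]$dW + g[[i]]$dW
              grads[[i]]$db <- grads[[i]]$db + g[[i]]$db
            }
          }
        }
        if (!is.finite(batchLoss))
          stop("non-finite training loss at epoch ", epoch,
               "; inputs must lie in [0,1]")
        # Adam update
        tStep <- tStep + 1L
        bc1 <- 1 - cfg@beta1^tStep
        bc2 <- 1 - cfg@beta2^tStep
        for (i in seq_along(model@layers)) {
          if (is.null(grads[[i]])) next
          for (part in c("W", "b")) {
            key <- paste0(part, i)
            g <- if (part == "W") grads[[i]]$dW else grads[[i]]$db
            mState[[key]] <- cfg@beta1 * mState[[key]] + (1 - cfg@beta1) * g
            vState[[key]] <- cfg@beta2 * vState[[key]] +
              (1 - cfg@beta2) * g * g
            step <- cfg@lr * (mState[[key]] / bc1) /
              (sqrt(vState[[key]] / bc2) + cfg@epsilon)
            if (part == "W") model@layers[[i]]$W <- model@layers[[i]]$W - step
            else model@layers[[i]]$b <- model@layers[[i]]$b - step
          }
        }
        epochLoss <- epochLoss + batchLoss * B / n
      }
      histLoss <- c(histLoss, epochLoss)
      valLoss <- if (!is.null(validation))
        evalLoss(model, validation, loss) else NA_real_
      histVal <- c(histVal, valLoss)
      monitor <- if (!is.null(validation)) valLoss else epochLoss
      if (monitor < bestMonitor) {
        bestMonitor <- monitor
        bestParams <- getParams(model)
        bestEpoch <- epoch
        badEpochs <- 0L
      } else {
        badEpochs <- badEpochs + 1L
        if (badEpochs >= cfg@patience) {
          stoppedEarly <- TRUE
          break
        }
      }
    }
  })
  model <- setParams(model, bestParams)
  model@history <- list(loss = histLoss, valLoss = histVal,
                        bestEpoch = bestEpoch,
                        stoppedEarly = stoppedEarly, lossName = loss)
  model
}

#' Evaluate a fitted autoencoder on a test set
#'
#' Computes the per-image benchmark value ([benchmarkValue()]) between
#' each source and its reconstruction.
#'
#' @param model a fitted [Autoencoder-class].
#' @param testset non-empty list of image arrays.
#' @return a list with \code{records} (data.frame, one row per image),
#'   \code{mean}, \code{sd}, and a \code{"mean±sd"} \code{summary}
#'   string.
#' @export
evaluateModel <- function(model, testset) {
  if (length(testset) == 0L) stop("empty test set")
  bench <- vapply(testset, function(img)
    benchmarkValue(img, reconstructImage(model, img)), numeric(1))
  m <- mean(bench)
  s <- if (length(bench) > 1L) stats::sd(bench) else 0
  list(records = data.frame(image = seq_along(bench), benchmark = bench),
       mean = m, sd = s,
       summary = sprintf("%.8f±%.9f", m, s))
}
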