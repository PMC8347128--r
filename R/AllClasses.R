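#' @import methods
NULL

#' Synthetic scene parameters
#'
#' Controls for the murky-aquarium scene generator. Scenes are H x W x 3
#' RGB arrays in [0,1] built from a base murk colour, a left-to-right
#' illumination falloff (brightest at column 1), semi-transparent clutter
#' (a metal bar and elliptical reflections), additive Gaussian pixel noise,
#' and low-contrast fusiform foreground subjects.
#'
#' @slot height,width frame dimensions in pixels.
#' @slot nFish number of foreground subjects (>= 0).
#' @slot contrastDelta foreground-background intensity offset in [0,1].
#'   The default 0.1 is a deliberate calibration of "low contrast":
#'   subjects sit well inside the background noise band.
#' @slot noiseSigma standard deviation of additive Gaussian noise on the
#'   [0,1] intensity scale (>= 0).
#' @slot gradientStrength left-to-right illumination falloff in [0,1];
#'   0 means flat lighting, 1 means the rightmost column is fully dark.
#' @slot clutterDensity fraction in [0,1] scaling the number of clutter
#'   elements drawn behind the subjects.
#' @slot seed integer seed; identical parameters (including the seed)
#'   produce bit-identical frames.
#'
#' @seealso [sceneParams()], [makeBackground()], [composeScene()]
#' @export
setClass("SceneParams", representation(
  height = "integer", width = "integer", nFish = "integer",
  contrastDelta = "numeric", noiseSigma = "numeric",
  gradientStrength = "numeric", clutterDensity = "numeric",
  seed = "integer"
))

setValidity("SceneParams", function(object) {
  msgs <- character()
  if (object@height < 1L || object@width < 1L)
    msgs <- c(msgs, "height and width must be positive")
  if (object@nFish < 0L) msgs <- c(msgs, "nFish must be >= 0")
  if (object@contrastDelta < 0 || object@contrastDelta > 1)
    msgs <- c(msgs, "contrastDelta must lie in [0,1]")
  if (object@noiseSigma < 0) msgs <- c(msgs, "noiseSigma must be >= 0")
  if (object@gradientStrength < 0 || object@gradientStrength > 1)
    msgs <- c(msgs, "gradientStrength must lie in [0,1]")
  if (object@clutterDensity < 0 || object@clutterDensity > 1)
    msgs <- c(msgs, "clutterDensity must lie in [0,1]")
  if (length(msgs)) msgs else TRUE
})

#' Declarative autoencoder architecture
#'
#' Describes a symmetric autoencoder by its encoder stage widths. For the
#' MLP family the stages are dense unit counts ending at the latent length
#' (e.g. \code{c(256, 64)}); for the CNN family they are convolution filter
#' counts per block (e.g. \code{c(256, 128, 64)}), each block being a 3x3
#' stride-1 convolution followed by 2x2 max pooling, so the input side must
#' be divisible by \code{2^length(stages)}.
#'
#' @slot family "mlp" or "cnn".
#' @slot stages integer vector of encoder stage widths, strictly positive.
#' @slot inputSide input image side length in pixels.
#' @slot channels number of colour channels (3 for RGB).
#'
#' @seealso [parseModelSpec()], [buildAutoencoder()]
#' @export
setClass("ModelSpec", representation(
  family = "character", stages = "integer",
  inputSide = "integer", channels = "integer"
))

setValidity("ModelSpec", function(object) {
  msgs <- character()
  if (!object@family %in% c("mlp", "cnn"))
    msgs <- c(msgs, "family must be 'mlp' or 'cnn'")
  if (length(object@stages) == 0L || any(object@stages < 1L))
    msgs <- c(msgs, "stages must be non-empty and strictly positive")
  if (object@inputSide < 1L) msgs <- c(msgs, "inputSide must be positive")
  if (object@family == "cnn" &&
      object@inputSide %% 2L^length(object@stages) != 0L)
    msgs <- c(msgs, sprintf(
      "inputSide %d is not divisible by 2^%d (one halving per CNN stage)",
      object@inputSide, length(object@stages)))
  if (length(msgs)) msgs else TRUE
})

#' Symmetric autoencoder model
#'
#' A built encoder/decoder pair. Layers are held as a flat list of weight
#' arrays plus structural markers; the decoder mirrors the encoder stages
#' in reverse, and the output head applies a sigmoid so reconstructions
#' stay in [0,1].
#'
#' @slot spec the [ModelSpec-class] the model was built from.
#' @slot layers list of layer descriptors (weights, biases, activations).
#' @slot latentShape integer dimensions of the latent code: a length for
#'   the MLP family, (side, side, filters) for the CNN family.
#' @slot history per-epoch training record, empty until fitted; see
#'   [fitAutoencoder()] and [trainHistory()].
#'
#' @export
setClass("Autoencoder", representation(
  spec = "ModelSpec", layers = "list", latentShape = "integer",
  history = "list"
))

#' Training configuration
#'
#' Hyperparameters for self-supervised reconstruction training: Adam with
#' step size 0.001 and moment decays 0.9/0.999, batch size 8, and binary
#' cross-entropy (MLP) or mean-squared-error (CNN) loss, each averaged per
#' pixel. Early stopping watches the validation loss with the given
#' patience and restores the best-epoch weights.
#'
#' @slot epochs maximum number of epochs (>= 1).
#' @slot batchSize minibatch size.
#' @slot lr,beta1,beta2,epsilon Adam hyperparameters.
#' @slot loss "bce" or "mse"; the empty string picks the family default.
#' @slot splitFraction train fraction for [splitDataset()], in (0,1).
#' @slot seed integer seed controlling weight updates' minibatch order.
#' @slot patience epochs without validation improvement before stopping.
#'
#' @export
setClass("TrainConfig", representation(
  epochs = "integer", batchSize = "integer", lr = "numeric",
  beta1 = "numeric", beta2 = "numeric", epsilon = "numeric",
  loss = "character", splitFraction = "numeric", seed = "integer",
  patience = "integer"
))

setValidity("TrainConfig", function(object) {
  msgs <- character()
  if (object@epochs < 1L) msgs <- c(msgs, "epochs must be >= 1")
  if (object@batchSize < 1L) msgs <- c(msgs, "batchSize must be >= 1")
  if (object@splitFraction <= 0 || object@splitFraction >= 1)
    msgs <- c(msgs, "splitFraction must lie strictly between 0 and 1")
  if (!object@loss %in% c("", "bce", "mse"))
    msgs <- c(msgs, "loss must be '', 'bce' or 'mse'")
  if (object@patience < 1L) msgs <- c(msgs, "patience must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Per-channel histogram of an RGB image
#'
#' @slot bins number of equal-width bins spanning [0,1]; 1.0 falls in the
#'   last bin.
#' @slot counts bins x 3 integer matrix; each column sums to the pixel
#'   count.
#' @export
setClass("ChannelHistogram", representation(
  bins = "integer", counts = "matrix"
))

#' Pooled histogram summary statistics
#'
#' Distinguishability summary of one or more channel histograms: all count
#' vectors are pooled into one sequence and its minimum, maximum,
#' population standard deviation, scale (max - min) and coefficient of
#' variation (std dev / mean) are reported.
#'
#' @slot min,max,stdDev,scale,cov numeric summaries of the pooled counts.
#' @export
setClass("HistogramStats", representation(
  min = "numeric", max = "numeric", stdDev = "numeric",
  scale = "numeric", cov = "numeric"
))

#' Quantized latent-space record
#'
#' A latent code quantized to one byte per element by a linear map from its
#' observed [qmin, qmax] range onto 0..255, together with capture metadata.
#' Serialized as Base64 text inside a single JSON document.
#'
#' @slot shape integer latent dimensions; \code{prod(shape)} equals the
#'   payload length.
#' @slot payload raw vector, one byte per latent element.
#' @slot qmin,qmax dequantization range endpoints.
#' @slot meta list with capture timestamp (\code{ts}, ISO-8601),
#'   \code{source} id, optional \code{bbox}, and \code{model} id.
#' @export
setClass("LatentRecord", representation(
  shape = "integer", payload = "raw", qmin = "numeric", qmax = "numeric",
  meta = "list"
))

setValidity("LatentRecord", function(object) {
  if (length(object@payload) != prod(object@shape))
    return("payload length must equal prod(shape)")
  TRUE
})

#' File-backed latent store
#'
#' Key-value store filing one JSON document per latent record under a
#' \code{date/hour/source-sequence} key layout, the contract a document
#' database would satisfy.
#'
#' @slot path root directory of the store.
#' @export
setClass("LatentStore", representation(path = "character"))

#' Observation panel: source, reconstruction, DIFF, DIFF2
#'
#' One frame's denoising panel: the source, its autoencoder
#' reconstruction, the standardized difference image (DIFF) and its
#' Sobel treatment (DIFF2), plus the reconstruction benchmark value.
#'
#' @slot source,reconstructed,diff,diff2 H x W x 3 arrays in [0,1].
#' @slot benchmarkValue root-summed per-channel mean squared difference
#'   between source and reconstruction (see [benchmarkValue()]).
#' @export
setClass("DiffPanel", representation(
  source = "array", reconstructed = "array", diff = "array",
  diff2 = "array", benchmarkValue = "numeric"
))

setValidity("DiffPanel", function(object) {
  d <- dim(object@source)
  for (s in c("reconstructed", "diff", "diff2"))
    if (!identical(dim(slot(object, s))[1:2], d[1:2]))
      return("all panel images must share spatial dimensions")
  TRUE
})
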