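#' Encode an image to its latent code
#'
#' @param object a built [Autoencoder-class].
#' @param x an image array matching the model's input shape.
#' @return the latent code: a numeric vector (MLP) or a 3-d array (CNN).
#' @export
setGeneric("encode", function(object, x) standardGeneric("encode"))

#' Decode a latent code back to an image
#'
#' @param object a built [Autoencoder-class].
#' @param x a latent code matching the model's latent shape.
#' @return an image array of the model's input shape with values in [0,1].
#' @export
setGeneric("decode", function(object, x) standardGeneric("decode"))

#' Total trainable parameter count
#'
#' @param object a built [Autoencoder-class].
#' @return exact integer count of weights plus biases.
#' @export
setGeneric("countParams", function(object) standardGeneric("countParams"))

#' Latent code dimensions
#'
#' @param object a built [Autoencoder-class].
#' @return integer vector: latent length (MLP) or (side, side, filters)
#'   (CNN).
#' @export
setGeneric("latentShape", function(object) standardGeneric("latentShape"))

#' Per-epoch training record
#'
#' @param object a fitted [Autoencoder-class].
#' @return a list with per-epoch \code{loss} and \code{valLoss} vectors,
#'   \code{bestEpoch} and \code{stoppedEarly}; empty list if never fitted.
#' @export
setGeneric("trainHistory", function(object) standardGeneric("trainHistory"))

#' Layer-by-layer architecture summary
#'
#' @param object a built [Autoencoder-class].
#' @return a data.frame with one row per layer: id, name, type, output
#'   shape, activation and parameter count.
#' @export
setGeneric("modelSummary", function(object) standardGeneric("modelSummary"))
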