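# Latent-space persistence: one-byte-per-element quantization, Base64
# serialization, and a file-backed key-value store filing one JSON
# document per record under date/hour sub-folders — the contract a
# document database would satisfy, with no server dependency.

#' Quantize a latent tensor to one byte per element
#'
#' Linear map of the observed \code{[qmin, qmax]} range onto 0..255
#' with round-half-up. A (32, 32, 64) latent therefore occupies exactly
#' 65,536 bytes = 64 KB. A constant tensor quantizes to an all-zero
#' payload with \code{qmin == qmax}. Dequantization recovers every
#' element to within \code{0.5/255 * (qmax - qmin)}.
#'
#' @param latent numeric array or vector with finite values.
#' @return list with \code{payload} (raw), \code{qmin}, \code{qmax}.
#' @seealso [dequantizeLatent()]
#' @export
quantizeLatent <- function(latent) {
  if (any(!is.finite(latent))) stop("latent contains non-finite values")
  qmin <- min(latent); qmax <- max(latent)
  if (qmax == qmin) {
    q <- integer(length(latent))
  } else {
    q <- floor((as.vector(latent) - qmin) / (qmax - qmin) * 255 + 0.5)
  }
  list(payload = as.raw(q), qmin = qmin, qmax = qmax)
}

#' Dequantize a byte payload back to a numeric array
#'
#' @param payload raw vector.
#' @param qmin,qmax range recorded at quantization time.
#' @param shape optional integer dimensions to restore.
#' @return numeric vector or array.
#' @export
dequantizeLatent <- function(payload, qmin, qmax, shape = NULL) {
  x <- qmin + as.integer(payload) / 255 * (qmax - qmin)
  if (!is.null(shape) && length(shape) > 1L) dim(x) <- shape
  x
}

#' Base64 text encoding
#'
#' Standard alphabet with padding, no line wrapping; the encoded length
#' is exactly \code{4 * ceiling(n / 3)} characters, so a 64 KB payload
#' serializes to 87,384 characters (just over 85 KB).
#'
#' @param payload raw vector.
#' @return single Base64 string.
#' @export
toBase64 <- function(payload) {
  if (length(payload) == 0L) return("")
  gsub("[\r\n]", "", jsonlite::base64_enc(payload))
}

#' @rdname toBase64
#' @param text Base64 string.
#' @return \code{fromBase64}: the decoded raw vector.
#' @export
fromBase64 <- function(text) {
  if (!nzchar(text)) return(raw(0))
  if (grepl("[^A-Za-z0-9+/=\r\n ]", text)) stop("malformed Base64 text")
  jsonlite::base64_dec(text)
}

#' Create a latent record
#'
#' Quantizes a latent code and attaches capture metadata.
#'
#' @param latent numeric latent array (or vector).
#' @param ts capture timestamp, ISO-8601 (e.g.
#'   \code{"2021-04-20T14:03:55"}).
#' @param source source/camera identifier.
#' @param model model identifier.
#' @param bbox optional length-4 box of the encoded subject.
#' @return a [LatentRecord-class].
#' @export
latentRecord <- function(latent, ts, source, model, bbox = NULL) {
  q <- quantizeLatent(latent)
  shape <- if (is.null(dim(latent))) length(latent) else dim(latent)
  new("LatentRecord", shape = as.integer(shape), payload = q$payload,
      qmin = q$qmin, qmax = q$qmax,
      meta = list(ts = ts, source = source,
                  bbox = if (is.null(bbox)) NULL else as.integer(bbox),
                  model = model))
}

#' @describeIn latentRecord display of shape, range and key metadata.
#' @param object a \code{LatentRecord}.
#' @export
setMethod("show", "LatentRecord", function(object) {
  cat(sprintf(
    "LatentRecord (%s) | %d bytes | range [%.4g, %.4g] | %s @ %s\n",
    paste(object@shape, collapse = ", "), length(object@payload),
    object@qmin, object@qmax, object@meta$source, object@meta$ts))
})

#' Open (or create) a file-backed latent store
#'
#' @param path root directory; created if missing.
#' @return a [LatentStore-class].
#' @export
latentStore <- function(path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  new("LatentStore", path = path)
}

recordKey <- function(store, record) {
  ts <- record@meta$ts
  date <- substr(ts, 1L, 10L)
  hour <- substr(ts, 12L, 13L)
  dir <- file.path(store@path, date, hour)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prefix <- paste0(record@meta$source, "-")
  existing <- list.files(dir, pattern = paste0("^", prefix, "[0-9]+\\.json$"))
  seqno <- length(existing) + 1L
  file.path(date, hour, sprintf("%s%06d", prefix, seqno))
}

#' Persist a latent record
#'
#' Files the record as one JSON document under the key
#' \code{date/hour/source-sequence} derived from its timestamp; two
#' records in the same hour get distinct sequence suffixes, so listing
#' by date prefix enumerates records in timestamp order.
#'
#' @param store a [LatentStore-class].
#' @param record a [LatentRecord-class].
#' @return the key the record was filed under.
#' @export
putRecord <- function(store, record) {
  stopifnot(is(store, "LatentStore"), is(record, "LatentRecord"))
  validObject(record)
  key <- recordKey(store, record)
  doc <- list(shape = record@shape, qmin = record@qmin,
              qmax = record@qmax, b64 = toBase64(record@payload),
              meta = list(ts = record@meta$ts,
                          source = record@meta$source,
                          bbox = record@meta$bbox,
                          model = record@meta$model))
  jsonlite::write_json(doc, file.path(store@path, paste0(key, ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  key
}

#' Retrieve a latent record by key
#'
#' @param store a [LatentStore-class].
#' @param key key returned by [putRecord()].
#' @return the byte-identical [LatentRecord-class].
#' @export
getRecord <- function(store, key) {
  path <- file.path(store@path, paste0(key, ".json"))
  if (!file.exists(path)) stop("no record under key '", key, "'")
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("corrupted record under key '", key, "': ",
                         conditionMessage(e)))
  need <- c("shape", "qmin", "qmax", "b64", "meta")
  if (!all(need %in% names(doc)))
    stop("corrupted record under key '", key, "': missing fields")
  payload <- fromBase64(doc$b64)
  if (length(payload) != prod(doc$shape))
    stop("corrupted record under key '", key, "': payload length ",
         length(payload), " != prod(shape)")
  new("LatentRecord", shape = as.integer(doc$shape), payload = payload,
      qmin = as.numeric(doc$qmin), qmax = as.numeric(doc$qmax),
      meta = list(ts = doc$meta$ts, source = doc$meta$source,
                  bbox = if (is.null(doc$meta$bbox)) NULL
                         else as.integer(doc$meta$bbox),
                  model = doc$meta$model))
}

#' List stored keys by prefix
#'
#' @param store a [LatentStore-class].
#' @param prefix key prefix, e.g. a date \code{"2021-04-20"} or
#'   \code{""} for everything.
#' @return sorted character vector of keys.
#' @export
listKeys <- function(store, prefix = "") {
  files <- list.files(store@path, pattern = "\\.json$", recursive = TRUE)
  keys <- sub("\\.json$", "", files)
  sort(keys[startsWith(keys, prefix)])
}

#' Reconstruct an image from a stored record
#'
#' get -> Base64 decode -> dequantize -> decode: the full retrieval
#' path from the archive back to a viewable image.
#'
#' @param store a [LatentStore-class].
#' @param key record key.
#' @param model the [Autoencoder-class] that produced the latent.
#' @return image array in [0,1].
#' @export
reconstructFromStore <- function(store, key, model) {
  rec <- getRecord(store, key)
  latent <- dequantizeLatent(rec@payload, rec@qmin, rec@qmax, rec@shape)
  if (length(rec@shape) == 1L) latent <- as.numeric(latent)
  decode(model, latent)
}
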