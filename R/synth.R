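# Synthetic murky-aquarium scene generator. Every downstream stage of the
# package is testable against these scenes because they come with exact
# ground-truth subject boxes and are bit-reproducible from their seed.

#' Create synthetic scene parameters
#'
#' @param height,width frame dimensions in pixels.
#' @param nFish number of foreground subjects.
#' @param contrastDelta foreground-background intensity offset in [0,1];
#'   the default 0.1 keeps subjects near the edge of visibility, which is
#'   the regime the toolkit targets.
#' @param noiseSigma additive Gaussian noise standard deviation on the
#'   [0,1] scale; the default 0.02 is typical sensor noise.
#' @param gradientStrength left-to-right illumination falloff in [0,1]
#'   (brightest at the left edge).
#' @param clutterDensity in [0,1], scales the number of semi-transparent
#'   clutter elements (a metal bar plus elliptical reflections).
#' @param seed integer seed; identical parameters give bit-identical
#'   scenes.
#' @return a validated [SceneParams-class] object.
#' @examples
#' p <- sceneParams(64, 64, nFish = 2, seed = 7)
#' sc <- composeScene(p)
#' dim(sc$image)
#' @export
sceneParams <- function(height, width, nFish = 3L, contrastDelta = 0.1,
                        noiseSigma = 0.02, gradientStrength = 0.5,
                        clutterDensity = 0.3, seed = 1L) {
  if (length(height) != 1L || length(width) != 1L ||
      !is.finite(height) || !is.finite(width) ||
      height < 1 || width < 1)
    stop("height and width must be positive integers")
  new("SceneParams",
      height = as.integer(height), width = as.integer(width),
      nFish = as.integer(nFish), contrastDelta = contrastDelta,
      noiseSigma = noiseSigma, gradientStrength = gradientStrength,
      clutterDensity = clutterDensity, seed = as.integer(seed))
}

#' @describeIn sceneParams compact display of the scene controls.
#' @param object a \code{SceneParams} object.
#' @export
setMethod("show", "SceneParams", function(object) {
  cat(sprintf(
    "SceneParams %dx%d | fish=%d delta=%.3g noise=%.3g grad=%.3g clutter=%.3g seed=%d\n",
    object@height, object@width, object@nFish, object@contrastDelta,
    object@noiseSigma, object@gradientStrength, object@clutterDensity,
    object@seed))
})

# run expr under a private RNG stream so scene generation never disturbs
# (nor is disturbed by) the caller's RNG state
withSceneSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# base murk colour of the water column (teal-grey)
.murk <- c(0.30, 0.42, 0.45)

# Draws the deterministic parts of the background (murk + illumination +
# clutter) and then adds pixel noise. All RNG draws happen in a fixed
# order so the fish geometry drawn afterwards by composeScene() is
# independent of noise/clutter settings only through the stream position;
# clutter and noise draws are consumed even when their amplitude is zero.
backgroundCore <- function(params) {
  H <- params@height; W <- params@width
  img <- array(rep(.murk, each = H * W), dim = c(H, W, 3L))
  # illumination: brightest at column 1, fading to the right
  tcol <- if (W > 1L) (seq_len(W) - 1) / (W - 1) else 0
  illum <- 1 - params@gradientStrength * tcol
  img <- img * array(rep(illum, each = H), dim = c(H, W, 3L))
  # clutter: one horizontal metal bar plus elliptical reflections,
  # alpha-blended at low opacity
  nClutter <- as.integer(round(params@clutterDensity * 12))
  if (nClutter > 0L) {
    xs <- matrix(rep(seq_len(W), each = H), H, W)
    ys <- matrix(rep(seq_len(H), times = W), H, W)
    for (k in seq_len(nClutter)) {
      shade <- runif(1, -0.25, 0.25)
      alpha <- runif(1, 0.15, 0.35)
      if (k == 1L) {
        y0 <- runif(1, 0.1, 0.9) * H
        hh <- max(1, 0.03 * H)
        mask <- ys >= y0 - hh & ys <= y0 + hh
      } else if (k %% 2L == 0L) {
        cx <- runif(1, 1, W); cy <- runif(1, 1, H)
        rx <- runif(1, 0.05, 0.2) * W; ry <- runif(1, 0.05, 0.2) * H
        mask <- ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1
      } else {
        cx <- runif(1, 1, W); cy <- runif(1, 1, H)
        rx <- runif(1, 0.03, 0.15) * W; ry <- runif(1, 0.03, 0.15) * H
        mask <- abs(xs - cx) <= rx & abs(ys - cy) <= ry
      }
      for (c in 1:3)
        img[, , c][mask] <- (1 - alpha) * img[, , c][mask] +
          alpha * pmin(pmax(.murk[c] + shade, 0), 1)
    }
  }
  noise <- array(rnorm(H * W * 3L, sd = params@noiseSigma),
                 dim = c(H, W, 3L))
  clip01(img + noise)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Generate a background-only murky scene
#'
#' Base murk colour, left-to-right illumination gradient (brightest at
#' column 1), semi-transparent clutter and additive Gaussian noise,
#' clipped to [0,1].
#'
#' @param params a [SceneParams-class] object.
#' @return an H x W x 3 array in [0,1].
#' @export
makeBackground <- function(params) {
  stopifnot(is(params, "SceneParams"))
  validObject(params)
  withSceneSeed(params@seed, backgroundCore(params))
}

# fusiform subject: a body ellipse plus a smaller tail ellipse, rotated.
# Returns a logical H x W mask; NULL when the shape cannot fit.
fishMask <- function(H, W, cx, cy, len, aspect, angle) {
  a <- len / 2; b <- a * aspect
  ext <- a * 1.4  # the tail ellipse reaches u = -1.35 a
  if (cx - ext < 1 || cx + ext > W || cy - ext < 1 || cy + ext > H)
    return(NULL)
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), times = W), H, W)
  ca <- cos(angle); sa <- sin(angle)
  u <- (xs - cx) * ca + (ys - cy) * sa
  v <- -(xs - cx) * sa + (ys - cy) * ca
  body <- (u / a)^2 + (v / b)^2 <= 1
  # tail: smaller ellipse trailing the body along its axis
  tu <- u + 0.9 * a
  tail <- (tu / (0.45 * a))^2 + (v / (0.6 * b))^2 <= 1
  body | tail
}

#' Compose a full synthetic scene with subjects
#'
#' Places \code{nFish} low-contrast fusiform subjects on the generated
#' background. Each subject brightens the underlying (noisy) background
#' by \code{contrastDelta}, so its visibility is controlled exactly;
#' subjects may overlap one another, as they do in real footage.
#'
#' @param params a [SceneParams-class] object.
#' @return a list with \code{image} (H x W x 3 array in [0,1]) and
#'   \code{boxes}, an nFish x 4 integer matrix of 0-based half-open
#'   bounding boxes with columns \code{x0, y0, x1, y1} (x along width).
#' @export
composeScene <- function(params) {
  stopifnot(is(params, "SceneParams"))
  validObject(params)
  withSceneSeed(params@seed, {
    img <- backgroundCore(params)
    H <- params@height; W <- params@width
    boxes <- matrix(integer(0), nrow = 0L, ncol = 4L,
                    dimnames = list(NULL, c("x0", "y0", "x1", "y1")))
    if (params@nFish > 0L) {
      for (i in seq_len(params@nFish)) {
        mask <- NULL
        for (attempt in 1:50) {
          len <- runif(1, 0.12, 0.25) * min(H, W)
          aspect <- runif(1, 0.3, 0.5)
          angle <- runif(1, 0, pi)
          cx <- runif(1, 1, W); cy <- runif(1, 1, H)
          mask <- fishMask(H, W, cx, cy, len, aspect, angle)
          if (!is.null(mask) && any(mask)) break
          mask <- NULL
        }
        if (is.null(mask))
          stop("subject placement failed: frame too small for the ",
               "requested number of subjects")
        for (c in 1:3)
          img[, , c][mask] <- img[, , c][mask] + params@contrastDelta
        cols <- which(apply(mask, 2, any))
        rows <- which(apply(mask, 1, any))
        boxes <- rbind(boxes, c(min(cols) - 1L, min(rows) - 1L,
                                max(cols), max(rows)))
      }
      img <- clip01(img)
    }
    list(image = img, boxes = boxes)
  })
}

#' Generate a reproducible dataset of scenes
#'
#' Scene \code{i} uses seed \code{params@seed + i - 1}, so any subset of
#' the dataset can be regenerated independently.
#'
#' @param nScenes number of scenes (>= 1).
#' @param params a [SceneParams-class] template.
#' @return list with \code{frames} (list of H x W x 3 arrays) and
#'   \code{boxes} (list of per-scene box matrices).
#' @export
makeDataset <- function(nScenes, params) {
  if (nScenes < 1L) stop("nScenes must be >= 1")
  stopifnot(is(params, "SceneParams"))
  frames <- vector("list", nScenes)
  boxes <- vector("list", nScenes)
  for (i in seq_len(nScenes)) {
    p <- params
    p@seed <- params@seed + i - 1L
    sc <- composeScene(p)
    frames[[i]] <- sc$image
    boxes[[i]] <- sc$boxes
  }
  list(frames = frames, boxes = boxes)
}

#' Write scenes as PNG frames with JSON sidecars
#'
#' Each frame \code{frame_NNNN.png} gets a sidecar
#' \code{frame_NNNN.json} recording its boxes, seed and parameters.
#'
#' @param nScenes number of scenes.
#' @param params a [SceneParams-class] template.
#' @param dir output directory, created if missing.
#' @return invisibly, the vector of PNG paths written.
#' @export
writeScenes <- function(nScenes, params, dir) {
  ds <- makeDataset(nScenes, params)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nScenes)
  for (i in seq_len(nScenes)) {
    base <- file.path(dir, sprintf("frame_%04d", i))
    paths[i] <- paste0(base, ".png")
    png::writePNG(ds$frames[[i]], paths[i])
    sidecar <- list(
      boxes = unname(apply(ds$boxes[[i]], 1, as.integer, simplify = FALSE)),
      seed = params@seed + i - 1L,
      params = list(height = params@height, width = params@width,
                    n_fish = params@nFish,
                    contrast_delta = params@contrastDelta,
                    noise_sigma = params@noiseSigma,
                    gradient_strength = params@gradientStrength,
                    clutter_density = params@clutterDensity))
    jsonlite::write_json(sidecar, paste0(base, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}
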