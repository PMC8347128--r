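# Denoised observation of aquatic subjects: standardized difference
# images (DIFF) and their Sobel treatment (DIFF2), which suppress the
# reconstructed background and leave the subject contours.

#' Standardized difference image of a frame and its reconstruction
#'
#' \code{imageDiff(src, reconstruction)}: the reconstruction captures
#' what the model has learned of the background, so the standardized
#' difference reveals the subjects far more clearly than the murky
#' source does.
#'
#' @param src image array matching the model input shape.
#' @param model a fitted [Autoencoder-class].
#' @return array of the same shape with values in [0,1].
#' @export
differenceImage <- function(src, model) {
  imageDiff(src, reconstructImage(model, src))
}

.sobelX <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # d/dx, x = cols
.sobelY <- t(.sobelX)
.lumaWeights <- c(0.299, 0.587, 0.114)

#' Sobel treatment of an image
#'
#' Converts to luminance (0.299 R + 0.587 G + 0.114 B), applies the
#' horizontal and vertical 3x3 Sobel operators with edge-replicated
#' borders, takes the gradient magnitude \code{sqrt(gx^2 + gy^2)} and
#' min-max standardizes the result. Edge replication (rather than zero
#' padding) keeps a constant image at exactly zero response and avoids
#' a spurious high-gradient ring along the frame border. The
#' single-channel edge map is replicated to RGB for panel display.
#'
#' @param img H x W x 3 array.
#' @return H x W x 3 array in [0,1] (three identical channels).
#' @export
sobelTreatment <- function(img) {
  d <- dim(img)
  H <- d[1]; W <- d[2]
  lum <- img[, , 1] * .lumaWeights[1] + img[, , 2] * .lumaWeights[2] +
    img[, , 3] * .lumaWeights[3]
  pad <- lum[c(1L, seq_len(H), H), c(1L, seq_len(W), W)]
  gx <- matrix(0, H, W)
  gy <- matrix(0, H, W)
  for (di in -1:1) for (dj in -1:1) {
    kx <- .sobelX[di + 2L, dj + 2L]
    ky <- .sobelY[di + 2L, dj + 2L]
    if (kx == 0 && ky == 0) next
    block <- pad[seq_len(H) + 1L + di, seq_len(W) + 1L + dj]
    if (kx != 0) gx <- gx + kx * block
    if (ky != 0) gy <- gy + ky * block
  }
  mag <- standardizeImage(sqrt(gx^2 + gy^2))
  array(rep(mag, 3L), dim = d)
}

#' Observe frames through a fitted model
#'
#' Builds one [DiffPanel-class] per frame: source, reconstruction,
#' DIFF (standardized difference) and DIFF2 (Sobel treatment of DIFF),
#' with the reconstruction benchmark value.
#'
#' @param frames list of image arrays matching the model input shape.
#' @param model a fitted [Autoencoder-class].
#' @return list of [DiffPanel-class] objects.
#' @export
observeFrames <- function(frames, model) {
  lapply(frames, function(src) {
    rec <- reconstructImage(model, src)
    dif <- imageDiff(src, rec)
    new("DiffPanel", source = src, reconstructed = rec, diff = dif,
        diff2 = sobelTreatment(dif),
        benchmarkValue = benchmarkValue(src, rec))
  })
}

#' @describeIn observeFrames display of a single panel.
#' @param object a \code{DiffPanel}.
#' @export
setMethod("show", "DiffPanel", function(object) {
  d <- dim(object@source)
  cat(sprintf("DiffPanel %dx%d | benchmark %.6f\n", d[1], d[2],
              object@benchmarkValue))
})

#' Write observation panels as side-by-side PNG strips
#'
#' Each panel becomes one PNG: source | reconstructed | DIFF | DIFF2.
#'
#' @param panels list of [DiffPanel-class] objects.
#' @param dir output directory, created if missing.
#' @return invisibly, the written paths.
#' @export
writePanels <- function(panels, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(panels))
  for (i in seq_along(panels)) {
    p <- panels[[i]]
    strip <- abind3(p@source, p@reconstructed, p@diff, p@diff2)
    paths[i] <- file.path(dir, sprintf("panel_%04d.png", i))
    png::writePNG(strip, paths[i])
  }
  invisible(paths)
}

# column-bind H x W x 3 arrays into one strip
abind3 <- function(...) {
  parts <- list(...)
  H <- dim(parts[[1]])[1]
  Wtot <- sum(vapply(parts, function(p) dim(p)[2], integer(1)))
  out <- array(0, dim = c(H, Wtot, 3L))
  at <- 0L
  for (p in parts) {
    w <- dim(p)[2]
    out[, (at + 1L):(at + w), ] <- p
    at <- at + w
  }
  out
}

#' Standardized latent-space visualization
#'
#' Min-max standardizes the latent code of one image and lays it out as
#' a square grey image: the MLP latent vector fills a
#' \code{ceiling(sqrt(L))} square grid (trailing cells zero when L is
#' not a perfect square); the CNN latent tensor is averaged over
#' channels.
#'
#' @param model a built [Autoencoder-class].
#' @param img image array matching the model input shape.
#' @return a square H x W x 3 array in [0,1] (three identical
#'   channels).
#' @export
latentImage <- function(model, img) {
  lat <- encode(model, img)
  if (model@spec@family == "mlp") {
    side <- ceiling(sqrt(length(lat)))
    cells <- numeric(side * side)
    cells[seq_along(lat)] <- standardizeImage(lat)
    grid <- matrix(cells, side, side, byrow = TRUE)
  } else {
    grid <- standardizeImage(apply(lat, c(1, 2), mean))
  }
  array(rep(grid, 3L), dim = c(dim(grid), 3L))
}

#' DIFF2 salience inside ground-truth boxes
#'
#' Mean DIFF2 intensity inside the union of the supplied boxes divided
#' by the mean outside — the quantitative surrogate for "the subject
#' shapes stand out from the suppressed background". Values well above
#' 1 indicate the Sobel-treated difference image concentrates its
#' energy on the subjects.
#'
#' @param panel a [DiffPanel-class].
#' @param boxes n x 4 matrix of 0-based half-open boxes
#'   (\code{x0, y0, x1, y1}, x along width).
#' @return list with \code{inside}, \code{outside} mean intensities and
#'   their \code{ratio}.
#' @export
diff2Salience <- function(panel, boxes) {
  d <- dim(panel@diff2)
  mask <- matrix(FALSE, d[1], d[2])
  for (i in seq_len(nrow(boxes))) {
    b <- boxes[i, ]
    mask[(b[2] + 1):b[4], (b[1] + 1):b[3]] <- TRUE
  }
  v <- panel@diff2[, , 1]
  inside <- mean(v[mask])
  outside <- mean(v[!mask])
  list(inside = inside, outside = outside,
       ratio = if (outside == 0) Inf else inside / outside)
}
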