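# Image preprocessing: quality filtering, brightness/contrast/kernel
# enhancement, rotation/shift augmentation, square zero-padding and
# bilinear resizing, plus the directory-level pipeline with a manifest.

#' Enhancement configuration
#'
#' Brightness is a multiplicative factor on pixel values; contrast scales
#' each channel around its mean; the 3x3 kernel is then applied per
#' channel, unnormalized, with zero border padding. The default kernel
#' (all eight neighbours -1, centre 11, sum 3) intentionally amplifies —
#' values are clipped to [0,1] after every step. A centre of 9 (sum 1)
#' gives the sharpening variant that preserves constants.
#'
#' @param brightnessFactor multiplicative brightness factor (default 2).
#' @param contrastFactor scale around the per-channel mean (default 0.6).
#' @param kernelCenter centre weight of the default kernel (default 11).
#' @param kernel optional explicit 3x3 matrix overriding
#'   \code{kernelCenter}.
#' @return a list with elements \code{brightnessFactor},
#'   \code{contrastFactor} and \code{kernel}.
#' @export
enhanceConfig <- function(brightnessFactor = 2, contrastFactor = 0.6,
                          kernelCenter = 11, kernel = NULL) {
  if (is.null(kernel)) {
    kernel <- matrix(-1, 3, 3)
    kernel[2, 2] <- kernelCenter
  }
  if (!is.matrix(kernel) || !all(dim(kernel) == c(3L, 3L)))
    stop("kernel must be exactly 3x3")
  list(brightnessFactor = brightnessFactor,
       contrastFactor = contrastFactor, kernel = kernel)
}

#' Augmentation configuration
#'
#' @param rotationStep rotation step in degrees; 360 must be divisible by
#'   it (default 45, i.e. eight rotations).
#' @param shifts list of integer \code{c(dx, dy)} pixel offsets; each
#'   shifted variant is rotated through the full set of angles in
#'   addition to the unshifted image.
#' @param fillValue value for pixels exposed by shifts/rotations
#'   (default 0, black).
#' @return a list with elements \code{rotationStep}, \code{shifts},
#'   \code{fillValue}.
#' @export
augmentConfig <- function(rotationStep = 45, shifts = list(),
                          fillValue = 0) {
  if (rotationStep <= 0 || 360 %% rotationStep != 0)
    stop("360 must be divisible by rotationStep")
  shifts <- lapply(shifts, function(s) {
    if (length(s) != 2L) stop("each shift must be c(dx, dy)")
    as.integer(round(s))
  })
  list(rotationStep = rotationStep, shifts = shifts,
       fillValue = fillValue)
}

#' Embed a crop in a zero-filled square
#'
#' Pads an H x W x 3 crop to S x S x 3 with S = max(H, W), content
#' centred (offset \code{floor((S - dim) / 2)}), padding black. This
#' preserves the subject's aspect ratio exactly before resizing.
#'
#' @param crop non-empty H x W x 3 array.
#' @return S x S x 3 array.
#' @export
squarePad <- function(crop) {
  d <- dim(crop)
  if (is.null(d) || length(d) != 3L || d[1] < 1L || d[2] < 1L)
    stop("squarePad needs a non-empty H x W x 3 array")
  H <- d[1]; W <- d[2]
  S <- max(H, W)
  if (H == W) return(crop)
  out <- array(0, dim = c(S, S, d[3]))
  r0 <- floor((S - H) / 2)
  c0 <- floor((S - W) / 2)
  out[(r0 + 1):(r0 + H), (c0 + 1):(c0 + W), ] <- crop
  out
}

# bilinear weight matrix mapping n source samples onto m targets;
# source coordinate of target i is (i - 0.5) * n/m - 0.5 (0-based,
# pixel-centre convention), edge-clamped
bilinearWeights <- function(n, m) {
  A <- matrix(0, m, n)
  s <- (seq_len(m) - 0.5) * n / m - 0.5
  s <- pmin(pmax(s, 0), n - 1)
  s0 <- floor(s)
  w <- s - s0
  i0 <- pmin(s0, n - 1) + 1
  i1 <- pmin(s0 + 1, n - 1) + 1
  for (i in seq_len(m)) {
    A[i, i0[i]] <- A[i, i0[i]] + (1 - w[i])
    A[i, i1[i]] <- A[i, i1[i]] + w[i]
  }
  A
}

#' Bilinear resize of a square image
#'
#' Pixel-centre bilinear interpolation (separable; edge clamped), output
#' clipped to [0,1]. Resizing to the input side returns the input
#' unchanged.
#'
#' @param img S x S x 3 array.
#' @param target output side in pixels (>= 1).
#' @return target x target x 3 array.
#' @export
resizeImage <- function(img, target) {
  d <- dim(img)
  if (length(d) != 3L || d[1] != d[2])
    stop("resizeImage expects a square H x H x 3 image")
  if (target < 1) stop("target must be >= 1")
  target <- as.integer(target)
  if (target == d[1]) return(img)
  A <- bilinearWeights(d[1], target)
  out <- array(0, dim = c(target, target, d[3]))
  for (c in seq_len(d[3]))
    out[, , c] <- A %*% img[, , c] %*% t(A)
  clip01(out)
}

# 3x3 kernel applied per channel as a sliding dot product with zero
# border padding (the kernels used here are symmetric, so correlation
# and convolution coincide)
applyKernel3 <- function(img, kernel) {
  d <- dim(img)
  W <- matrix(as.vector(kernel), ncol = 1L)
  out <- img
  for (c in seq_len(d[3])) {
    ch <- array(img[, , c], dim = c(d[1], d[2], 1L))
    out[, , c] <- conv2d_fw(ch, W, 0, 3L)[, , 1L]
  }
  out
}

#' Enhance an image
#'
#' Applies, in order: brightness (multiplicative), contrast (scaling
#' around the per-channel mean of the brightened image), and the 3x3
#' kernel (per channel, zero-padded borders); values are clipped to
#' [0,1] after each step.
#'
#' @param img H x W x 3 array in [0,1].
#' @param cfg an [enhanceConfig()] list.
#' @return array of the same shape in [0,1].
#' @export
enhanceImage <- function(img, cfg = enhanceConfig()) {
  if (!is.matrix(cfg$kernel) || !all(dim(cfg$kernel) == c(3L, 3L)))
    stop("kernel must be exactly 3x3")
  out <- clip01(img * cfg$brightnessFactor)
  for (c in seq_len(dim(out)[3])) {
    m <- mean(out[, , c])
    out[, , c] <- (out[, , c] - m) * cfg$contrastFactor + m
  }
  out <- clip01(out)
  clip01(applyKernel3(out, cfg$kernel))
}

#' Shift an image by whole pixels
#'
#' @param img H x W x C array.
#' @param dx,dy shift in pixels along width (positive = right) and
#'   height (positive = down).
#' @param fill value for exposed pixels.
#' @return array of the same shape.
#' @export
shiftImage <- function(img, dx, dy, fill = 0) {
  d <- dim(img)
  out <- array(fill, dim = d)
  src_r <- seq_len(d[1]) - dy
  src_c <- seq_len(d[2]) - dx
  ok_r <- which(src_r >= 1 & src_r <= d[1])
  ok_c <- which(src_c >= 1 & src_c <= d[2])
  if (length(ok_r) && length(ok_c))
    out[ok_r, ok_c, ] <- img[src_r[ok_r], src_c[ok_c], , drop = FALSE]
  out
}

#' Rotate a square image about its centre
#'
#' Bilinear inverse-mapped rotation with zero fill for exposed corners.
#' Multiples of 90 degrees are exact index permutations (no
#' interpolation).
#'
#' @param img S x S x C array.
#' @param degrees rotation angle, counterclockwise.
#' @param fill value for pixels mapped from outside the frame.
#' @return array of the same shape.
#' @export
rotateImage <- function(img, degrees, fill = 0) {
  d <- dim(img)
  if (length(d) != 3L || d[1] != d[2])
    stop("rotateImage expects a square image")
  S <- d[1]
  degrees <- degrees %% 360
  if (degrees == 0) return(img)
  ctr <- (S + 1) / 2
  theta <- degrees * pi / 180
  co <- cos(theta); si <- sin(theta)
  dxm <- matrix(rep(seq_len(S) - ctr, each = S), S, S)   # x offset (cols)
  dym <- matrix(rep(seq_len(S) - ctr, times = S), S, S)  # y offset (rows)
  sx <- ctr + dxm * co + dym * si
  sy <- ctr - dxm * si + dym * co
  out <- array(fill, dim = d)
  if (degrees %% 90 == 0) {
    ri <- round(sy); ci <- round(sx)
    idx <- cbind(as.vector(ri), as.vector(ci))
    for (c in seq_len(d[3]))
      out[, , c] <- matrix(img[, , c][idx], S, S)
    return(out)
  }
  x0 <- floor(sx); y0 <- floor(sy)
  wx <- sx - x0; wy <- sy - y0
  gather <- function(ch, r, cc) {
    v <- matrix(fill, S, S)
    ok <- r >= 1 & r <= S & cc >= 1 & cc <= S
    v[ok] <- ch[cbind(r[ok], cc[ok])]
    v
  }
  for (c in seq_len(d[3])) {
    ch <- img[, , c]
    v00 <- gather(ch, y0, x0)
    v01 <- gather(ch, y0, x0 + 1)
    v10 <- gather(ch, y0 + 1, x0)
    v11 <- gather(ch, y0 + 1, x0 + 1)
    out[, , c] <- (1 - wy) * ((1 - wx) * v00 + wx * v01) +
      wy * ((1 - wx) * v10 + wx * v11)
  }
  out
}

#' Augment a square image by shifting and rotating
#'
#' Returns every rotation (360 / step of them) of the unshifted image and
#' of each shifted variant: \code{(1 + length(shifts)) * (360 / step)}
#' images in all.
#'
#' @param img S x S x 3 array.
#' @param cfg an [augmentConfig()] list.
#' @return list of arrays, all the same shape as \code{img}.
#' @export
augmentImage <- function(img, cfg = augmentConfig()) {
  d <- dim(img)
  if (length(d) != 3L || d[1] != d[2])
    stop("augmentImage expects a square image (rotation preserves the frame)")
  variants <- c(list(img),
                lapply(cfg$shifts, function(s)
                  shiftImage(img, s[1], s[2], cfg$fillValue)))
  angles <- seq(0, 360 - cfg$rotationStep, by = cfg$rotationStep)
  out <- vector("list", length(variants) * length(angles))
  k <- 1L
  for (v in variants) {
    for (a in angles) {
      out[[k]] <- rotateImage(v, a, cfg$fillValue)
      k <- k + 1L
    }
  }
  out
}

#' Drop exceptionally low-quality images
#'
#' An image is kept when the maximum of its per-channel standard
#' deviations reaches \code{tau}; near-constant ("blank") frames, in
#' which the subject has blended entirely into the background, are
#' dropped. Order is preserved.
#'
#' @param imgs list of H x W x 3 arrays.
#' @param tau variability threshold (>= 0); 0 keeps everything.
#' @return list with \code{kept} and \code{dropped} sublists.
#' @export
qualityFilter <- function(imgs, tau = 0.02) {
  if (tau < 0) stop("tau must be >= 0")
  keep <- vapply(imgs, function(im) {
    max(vapply(seq_len(dim(im)[3]), function(c) stats::sd(im[, , c]),
               numeric(1))) >= tau
  }, logical(1))
  list(kept = imgs[keep], dropped = imgs[!keep])
}

#' Read an RGB image file
#'
#' @param path PNG file path.
#' @return H x W x 3 array in [0,1] (grayscale replicated, alpha
#'   dropped).
#' @export
readImageFile <- function(path) {
  img <- png::readPNG(path)
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Full preprocessing pipeline over a directory
#'
#' Loads every PNG in \code{srcDir} (sorted by name), then applies
#' quality filtering, enhancement, square zero-padding, augmentation and
#' resizing, writing each output as an 8-bit PNG plus a JSON manifest
#' recording the provenance of every output image. Padding precedes
#' augmentation so rotations act on square frames.
#'
#' @param srcDir directory of source PNG frames or crops.
#' @param outDir output directory, created if missing.
#' @param enhance an [enhanceConfig()] list, or NULL to skip enhancement.
#' @param augment an [augmentConfig()] list.
#' @param target output side in pixels (default 256).
#' @param tau quality-filter threshold.
#' @return invisibly, the manifest as a list.
#' @export
preprocessPipeline <- function(srcDir, outDir, enhance = enhanceConfig(),
                               augment = augmentConfig(), target = 256L,
                               tau = 0.02) {
  files <- sort(list.files(srcDir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L)
    stop("no PNG images found in ", srcDir)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  imgs <- lapply(files, readImageFile)
  sds <- vapply(imgs, function(im)
    max(vapply(seq_len(dim(im)[3]), function(c) stats::sd(im[, , c]),
               numeric(1))), numeric(1))
  keep <- sds >= tau
  entries <- list()
  n_out <- 0L
  angles <- seq(0, 360 - augment$rotationStep, by = augment$rotationStep)
  n_var <- 1L + length(augment$shifts)
  for (i in seq_along(files)) {
    if (!keep[i]) next
    im <- imgs[[i]]
    if (!is.null(enhance)) im <- enhanceImage(im, enhance)
    im <- squarePad(im)
    aug <- augmentImage(im, augment)
    stem <- sub("\\.png$", "", basename(files[i]))
    for (k in seq_along(aug)) {
      outName <- sprintf("%s_a%03d.png", stem, k)
      png::writePNG(resizeImage(aug[[k]], target),
                    file.path(outDir, outName))
      v <- (k - 1L) %/% length(angles)
      entries[[length(entries) + 1L]] <- list(
        source = basename(files[i]),
        shift = if (v == 0L) c(0L, 0L) else augment$shifts[[v]],
        rotation = angles[(k - 1L) %% length(angles) + 1L],
        enhanced = !is.null(enhance),
        output = outName)
      n_out <- n_out + 1L
    }
  }
  manifest <- list(
    n_source = length(files), n_kept = sum(keep), n_output = n_out,
    tau = tau, target = as.integer(target),
    rotation_step = augment$rotationStep,
    n_shifts = length(augment$shifts),
    dropped = basename(files)[!keep],
    outputs = entries)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
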