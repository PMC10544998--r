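## Image preprocessing and training-time augmentation. Decoding and file
## resizing go through png/EBImage; augmentation operates on numeric
## arrays shaped (channels, height, width) in the model's input space.

## read any supported image into an (H, W, C) numeric array in [0,1]
.readImageHWC <- function(path) {
    if (!file.exists(path)) stop("cannot read image file: ", path)
    ext <- tolower(tools::file_ext(path))
    a <- if (ext == "png") {
        png::readPNG(path)
    } else {
        img <- EBImage::readImage(path)
        d <- EBImage::imageData(img)
        ## EBImage stores (x, y, channel); transpose to (row, col, channel)
        if (length(dim(d)) == 2) t(d) else aperm(d, c(2, 1, 3))
    }
    if (length(dim(a)) == 2) a <- array(a, dim = c(dim(a), 1))
    if (dim(a)[3] == 4) a <- a[, , 1:3, drop = FALSE]  # drop alpha
    a
}

.toChannels <- function(hwc, channels) {
    have <- dim(hwc)[3]
    if (have == channels) return(hwc)
    if (channels == 1L && have == 3L) {
        y <- 0.299 * hwc[, , 1] + 0.587 * hwc[, , 2] + 0.114 * hwc[, , 3]
        array(y, dim = c(dim(hwc)[1:2], 1))
    } else if (channels == 3L && have == 1L) {
        array(rep(hwc, 3), dim = c(dim(hwc)[1:2], 3))
    } else stop("cannot convert ", have, " channels to ", channels)
}

#' Preprocess an image into a model input tensor
#'
#' Decodes (if given a path), resizes bilinearly to the configured square
#' size, converts to the configured channel count (RGB by default, or
#' luminance grayscale), scales pixel values to [0,1] and applies the
#' per-channel normalization.
#'
#' @param image a file path (PNG/JPEG) or an (H, W, C) numeric array in
#'   [0,1].
#' @param config an [AugmentConfig-class] (its targetSize, channels and
#'   normalization are used).
#' @return Numeric array (channels, targetSize, targetSize).
#' @export
preprocessImage <- function(image, config = AugmentConfig()) {
    stopifnot(is(config, "AugmentConfig"))
    hwc <- if (is.character(image)) .readImageHWC(image) else {
        a <- image
        if (length(dim(a)) == 2) a <- array(a, dim = c(dim(a), 1))
        a
    }
    if (any(dim(hwc)[1:2] < 2)) stop("degenerate image (smaller than 2x2)")
    ts <- config@targetSize
    if (!all(dim(hwc)[1:2] == c(ts, ts))) {
        ## EBImage works on (x, y, channel); transpose in and out
        img <- EBImage::Image(aperm(hwc, c(2, 1, 3)),
                              colormode = if (dim(hwc)[3] == 3) "Color"
                                          else "Grayscale")
        rs <- EBImage::resize(img, w = ts, h = ts)
        d <- EBImage::imageData(rs)
        if (length(dim(d)) == 2) d <- array(d, dim = c(dim(d), 1))
        hwc <- aperm(d, c(2, 1, 3))
    }
    hwc <- .toChannels(hwc, config@channels)
    hwc[hwc < 0] <- 0; hwc[hwc > 1] <- 1
    chw <- aperm(hwc, c(3, 1, 2))
    (chw - config@normMean) / config@normStd
}

## sample a crop window: retained side fractions guaranteeing that at most
## maxCropFraction of the area is removed. Exposed internally so the
## Monte-Carlo bound check can exercise the sampler cheaply.
.sampleCropWindow <- function(h, w, maxCropFraction) {
    u <- stats::runif(1, 0, maxCropFraction)
    a <- 1 - u
    ch <- min(h, ceiling(h * sqrt(a)))
    cw <- min(w, ceiling(w * sqrt(a)))
    oy <- if (h > ch) sample.int(h - ch + 1L, 1L) else 1L
    ox <- if (w > cw) sample.int(w - cw + 1L, 1L) else 1L
    list(ch = ch, cw = cw, oy = oy, ox = ox)
}

#' Randomly augment an image tensor
#'
#' Applies, each with its own random draw: horizontal flip, vertical flip,
#' a random crop removing at most `maxCropFraction` of the area (the result
#' is resized back to the input size), and a random edge-padded translation
#' of up to `maxTranslateFraction` of the side length per axis. Intended
#' for the training split only. With all probabilities and fractions 0 the
#' output is pixel-identical to the input.
#'
#' @param x numeric array (channels, height, width).
#' @param config an [AugmentConfig-class].
#' @return Augmented array of identical shape.
#' @export
augmentArray <- function(x, config = AugmentConfig()) {
    stopifnot(is(config, "AugmentConfig"))
    d <- dim(x)
    if (length(d) != 3 || d[2] < 2 || d[3] < 2)
        stop("'x' must be a (channels, H, W) array of at least 2x2 pixels")
    h <- d[2]; w <- d[3]
    if (stats::runif(1) < config@horizontalFlip)
        x <- x[, , w:1, drop = FALSE]
    if (stats::runif(1) < config@verticalFlip)
        x <- x[, h:1, , drop = FALSE]
    if (config@maxCropFraction > 0) {
        cw <- .sampleCropWindow(h, w, config@maxCropFraction)
        if (cw$ch < h || cw$cw < w) {
            crop <- x[, cw$oy:(cw$oy + cw$ch - 1L),
                      cw$ox:(cw$ox + cw$cw - 1L), drop = FALSE]
            dim(crop) <- c(d[1], cw$ch, cw$cw, 1)
            x <- array(bilinearResize(crop, h, w)$out, dim = d)
        }
    }
    f <- config@maxTranslateFraction
    if (f > 0) {
        dy <- sample.int(2L * floor(f * h) + 1L, 1L) - floor(f * h) - 1L
        dx <- sample.int(2L * floor(f * w) + 1L, 1L) - floor(f * w) - 1L
        if (dy != 0 || dx != 0) {
            yi <- pmin(pmax(seq_len(h) - dy, 1L), h)
            xi <- pmin(pmax(seq_len(w) - dx, 1L), w)
            x <- x[, yi, xi, drop = FALSE]
        }
    }
    dim(x) <- d
    x
}

#' Load and preprocess every image of a manifest split into a batch tensor
#'
#' @param manifest a [DatasetManifest-class] (typically one split, see
#'   [manifestSplit()]).
#' @param config an [AugmentConfig-class] used by [preprocessImage()].
#' @return list with `x` (array channels x size x size x N) and `y`
#'   (integer class indices in vocabulary order).
#' @export
loadSplitTensors <- function(manifest, config = AugmentConfig()) {
    stopifnot(is(manifest, "DatasetManifest"))
    s <- manifest@samples
    n <- nrow(s)
    if (!n) stop("manifest split is empty")
    ts <- config@targetSize
    x <- array(0, dim = c(config@channels, ts, ts, n))
    for (i in seq_len(n))
        x[, , , i] <- preprocessImage(s$path[i], config)
    y <- match(s$label, manifest@classes)
    list(x = x, y = as.integer(y))
}
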