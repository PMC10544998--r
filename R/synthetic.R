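## Synthetic severely-imbalanced 5-class image generator. Emulates only the
## statistical structure the training framework needs — class-discriminative
## color/texture plus the reference cohort's class skew — not histological
## realism. Fully deterministic given the seed.

## largest-remainder apportionment of `total` among positive proportions
propCounts <- function(proportions, total) {
    p <- proportions / sum(proportions)
    exact <- p * total
    base <- floor(exact)
    rem <- exact - base
    short <- total - sum(base)
    if (short > 0) {
        ord <- order(rem, decreasing = TRUE)
        base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
    }
    as.integer(base)
}

#' Construct a synthetic dataset configuration
#'
#' Defaults emulate the reference cohort: 5 classes with the severe
#' 41 : 1317 : 196 : 121 : 546 imbalance, 300 images total at 64x64 —
#' large enough to train the miniature backbones meaningfully, small
#' enough for minutes-scale CPU runs. Each class has a distinct background
#' hue, blob (cell-cluster) appearance, line-structure count and noise
#' level; `difficulty` interpolates all class parameter sets toward their
#' mean (1 collapses the classes entirely).
#'
#' @param imageSize square image side (default 64).
#' @param classProportions positive per-class proportions.
#' @param totalImages total number of images (default 300).
#' @param classes class names.
#' @param difficulty numeric in [0,1] (default 0).
#' @param seed integer seed.
#' @param baseColor,blobColor 3 x C matrices of RGB values in [0,1].
#' @param blobDensity blobs per 1000 px^2, per class.
#' @param blobRadius 2 x C min/max blob radii (pixels).
#' @param veinCount line structures per image, per class.
#' @param noiseSd additive Gaussian pixel noise sd, per class.
#' @return A [SyntheticConfig-class].
#' @export
SyntheticConfig <- function(imageSize = 64L,
                            classProportions = c(41, 1317, 196, 121, 546),
                            totalImages = 300L,
                            classes = c("Grade1", "Grade2", "Grade3",
                                        "AIS", "MIA"),
                            difficulty = 0, seed = 1L,
                            baseColor = NULL, blobColor = NULL,
                            blobDensity = c(1.5, 3.0, 4.5, 2.0, 3.5),
                            blobRadius = NULL,
                            veinCount = c(2, 4, 6, 1, 3),
                            noiseSd = c(0.03, 0.05, 0.04, 0.03, 0.06)) {
    C <- length(classes)
    if (is.null(baseColor))
        baseColor <- matrix(c(0.85, 0.55, 0.55,
                              0.75, 0.45, 0.75,
                              0.45, 0.45, 0.80,
                              0.50, 0.75, 0.50,
                              0.85, 0.75, 0.45), 3, C)
    if (is.null(blobColor))
        blobColor <- matrix(c(0.55, 0.15, 0.25,
                              0.40, 0.10, 0.45,
                              0.15, 0.15, 0.50,
                              0.15, 0.45, 0.20,
                              0.60, 0.45, 0.10), 3, C)
    if (is.null(blobRadius))
        blobRadius <- rbind(c(2, 3, 2, 4, 3), c(5, 7, 5, 9, 8))
    new("SyntheticConfig", imageSize = as.integer(imageSize),
        classProportions = as.numeric(classProportions),
        totalImages = as.integer(totalImages), classes = classes,
        baseColor = baseColor, blobColor = blobColor,
        blobDensity = as.numeric(blobDensity), blobRadius = blobRadius,
        veinCount = as.numeric(veinCount), noiseSd = as.numeric(noiseSd),
        difficulty = as.numeric(difficulty), seed = as.integer(seed))
}

## per-class parameter list after difficulty interpolation toward the mean
.interpParams <- function(config) {
    d <- config@difficulty
    mix <- function(m) {
        if (is.matrix(m)) (1 - d) * m + d * rowMeans(m)
        else (1 - d) * m + d * mean(m)
    }
    list(baseColor = mix(config@baseColor), blobColor = mix(config@blobColor),
         blobDensity = mix(config@blobDensity),
         blobRadius = mix(config@blobRadius),
         veinCount = mix(config@veinCount), noiseSd = mix(config@noiseSd))
}

## draw one synthetic image for class k; (H, W, 3) array in [0,1]
.drawSynthetic <- function(config, pars, k) {
    S <- config@imageSize
    xg <- matrix(rep(seq_len(S), each = S), S, S)   # column index
    yg <- matrix(rep(seq_len(S), times = S), S, S)  # row index
    img <- array(0, dim = c(S, S, 3))
    grad <- 0.06 * (yg / S - 0.5)
    for (ch in 1:3) img[, , ch] <- pars$baseColor[ch, k] + grad
    nBlob <- max(0L, round(pars$blobDensity[k] * S * S / 1000))
    for (i in seq_len(nBlob)) {
        cx <- stats::runif(1, 1, S); cy <- stats::runif(1, 1, S)
        r <- stats::runif(1, pars$blobRadius[1, k], pars$blobRadius[2, k])
        asp <- stats::runif(1, 0.5, 1)
        th <- stats::runif(1, 0, pi)
        dx <- xg - cx; dy <- yg - cy
        u <- dx * cos(th) + dy * sin(th)
        v <- -dx * sin(th) + dy * cos(th)
        mask <- (u / r)^2 + (v / (r * asp))^2 <= 1
        alpha <- 0.85
        for (ch in 1:3)
            img[, , ch][mask] <- (1 - alpha) * img[, , ch][mask] +
                alpha * pars$blobColor[ch, k]
    }
    nVein <- max(0L, round(pars$veinCount[k]))
    for (i in seq_len(nVein)) {
        p1 <- stats::runif(2, 1, S); p2 <- stats::runif(2, 1, S)
        thick <- stats::runif(1, 0.6, 1.4)
        v <- p2 - p1
        len2 <- sum(v^2) + 1e-9
        tproj <- ((xg - p1[1]) * v[1] + (yg - p1[2]) * v[2]) / len2
        tproj <- pmin(pmax(tproj, 0), 1)
        distx <- xg - (p1[1] + tproj * v[1])
        disty <- yg - (p1[2] + tproj * v[2])
        mask <- distx^2 + disty^2 <= thick^2
        for (ch in 1:3)
            img[, , ch][mask] <- 0.5 * img[, , ch][mask] +
                0.5 * 0.5 * pars$blobColor[ch, k]
    }
    img <- img + array(stats::rnorm(S * S * 3, sd = pars$noiseSd[k]),
                       dim = dim(img))
    img[img < 0] <- 0; img[img > 1] <- 1
    img
}

#' Generate a synthetic imbalanced image dataset
#'
#' Writes `totalImages` PNG files into one subfolder per class under
#' `outputDir` (per-class counts follow the configured proportions by
#' largest-remainder rounding) and returns the corresponding manifest.
#' Byte-identical output for identical configuration and seed.
#'
#' @param config a [SyntheticConfig-class].
#' @param outputDir writable output directory (created if missing).
#' @return A [DatasetManifest-class] of the written images (split
#'   unassigned).
#' @examples
#' \donttest{
#' cfg <- SyntheticConfig(totalImages = 300L, seed = 7L)
#' m <- generateDataset(cfg, file.path(tempdir(), "synth"))
#' classCounts(m)  # 6 178 26 16 74
#' }
#' @export
generateDataset <- function(config, outputDir) {
    stopifnot(is(config, "SyntheticConfig"))
    ok <- dir.exists(outputDir) ||
        dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || file.access(outputDir, 2) != 0)
        stop("output directory is not writable: ", outputDir)
    counts <- propCounts(config@classProportions, config@totalImages)
    pars <- .interpParams(config)
    set.seed(config@seed)
    rows <- list()
    for (k in seq_along(config@classes)) {
        cls <- config@classes[k]
        dir.create(file.path(outputDir, cls), showWarnings = FALSE)
        for (i in seq_len(counts[k])) {
            img <- .drawSynthetic(config, pars, k)
            path <- file.path(outputDir, cls,
                              sprintf("%s_%04d.png", cls, i))
            png::writePNG(img, path)
            rows[[length(rows) + 1]] <- data.frame(path = path, label = cls)
        }
    }
    DatasetManifest(do.call(rbind, rows), config@classes)
}

#' Expected class separability of a synthetic configuration
#'
#' A cheap proxy in [0,1]: the mean pairwise Euclidean distance between the
#' per-class appearance parameter vectors (colors, blob density and radius,
#' line count, noise sd; each dimension standardized by its across-class
#' spread at difficulty 0), normalized by its value at difficulty 0. Since
#' difficulty interpolates parameters linearly toward their mean, the proxy
#' is monotonically non-increasing in difficulty and reaches 0 when the
#' classes collapse.
#'
#' @param config a [SyntheticConfig-class].
#' @return Numeric in [0,1].
#' @export
expectedSeparability <- function(config) {
    stopifnot(is(config, "SyntheticConfig"))
    featMatrix <- function(pars) {
        rbind(pars$baseColor, pars$blobColor, pars$blobDensity,
              colMeans(pars$blobRadius), pars$veinCount, pars$noiseSd)
    }
    base <- config
    base@difficulty <- 0
    F0 <- featMatrix(.interpParams(base))       # features x classes
    Fd <- featMatrix(.interpParams(config))
    sdv <- apply(F0, 1, stats::sd)
    keep <- sdv > 0
    if (!any(keep)) return(0)
    F0 <- F0[keep, , drop = FALSE] / sdv[keep]
    Fd <- Fd[keep, , drop = FALSE] / sdv[keep]
    meanDist <- function(M) mean(stats::dist(t(M)))
    d0 <- meanDist(F0)
    if (d0 == 0) return(0)
    min(1, max(0, meanDist(Fd) / d0))
}
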