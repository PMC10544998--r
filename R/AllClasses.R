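#' @import methods
NULL

#' Loss-combination weights
#'
#' Holds the coefficients of the combined distillation objective
#' \deqn{L = \alpha L_{feat} + (1-\alpha) L_{soft} + \beta L_{focal}}
#' together with the distillation temperature applied to both teacher and
#' student logits before the soft-label cross-entropy.
#'
#' @slot alpha numeric in [0,1]; weight of the feature-matching term (the
#'   soft-label term receives 1 - alpha).
#' @slot beta nonnegative numeric; weight of the focal (hard-label) term.
#' @slot temperature positive numeric; softmax temperature T. Larger T
#'   yields smoother teacher distributions carrying more inter-class
#'   information.
#' @slot tsquare logical; if TRUE the soft-label loss is rescaled by T^2
#'   (the classic gradient-magnitude correction). Default FALSE: the
#'   combined objective is taken literally, without the correction.
#' @export
setClass("LossWeights", representation(
    alpha = "numeric", beta = "numeric",
    temperature = "numeric", tsquare = "logical"
))

setValidity("LossWeights", function(object) {
    msg <- character()
    if (length(object@alpha) != 1 || is.na(object@alpha) ||
        object@alpha < 0 || object@alpha > 1)
        msg <- c(msg, "'alpha' must be a single value in [0, 1]")
    if (length(object@beta) != 1 || is.na(object@beta) || object@beta < 0)
        msg <- c(msg, "'beta' must be a single nonnegative value")
    if (length(object@temperature) != 1 || is.na(object@temperature) ||
        object@temperature <= 0)
        msg <- c(msg, "'temperature' must be a single positive value")
    if (length(msg)) msg else TRUE
})

#' Construct loss-combination weights
#'
#' Defaults are the reference protocol: alpha = 0.5 and beta = 1 balance the
#' three loss terms; T = 4 is a conventional distillation temperature (the
#' reference protocol does not state one).
#'
#' @param alpha weight in [0,1] of the feature-matching loss.
#' @param beta nonnegative weight of the focal loss.
#' @param temperature positive softmax temperature.
#' @param tsquare logical, apply the optional T^2 rescaling to the
#'   soft-label loss (default FALSE).
#' @return A [LossWeights-class] object.
#' @examples
#' LossWeights(alpha = 0.5, beta = 1, temperature = 4)
#' @export
LossWeights <- function(alpha = 0.5, beta = 1, temperature = 4,
                        tsquare = FALSE) {
    new("LossWeights", alpha = as.numeric(alpha), beta = as.numeric(beta),
        temperature = as.numeric(temperature), tsquare = isTRUE(tsquare))
}

#' Focal-loss parameters
#'
#' @slot gamma nonnegative focusing exponent; gamma = 0 reduces the focal
#'   loss to (weighted) cross-entropy.
#' @slot classWeights positive per-class weights (the alpha_t factor);
#'   typically inverse class frequencies normalized to mean 1, see
#'   [classWeights()].
#' @export
setClass("FocalParams", representation(
    gamma = "numeric", classWeights = "numeric"
))

setValidity("FocalParams", function(object) {
    msg <- character()
    if (length(object@gamma) != 1 || is.na(object@gamma) || object@gamma < 0)
        msg <- c(msg, "'gamma' must be a single nonnegative value")
    if (length(object@classWeights) < 2 || any(!is.finite(object@classWeights)) ||
        any(object@classWeights <= 0))
        msg <- c(msg, "'classWeights' must be >= 2 positive finite values")
    if (length(msg)) msg else TRUE
})

#' Construct focal-loss parameters
#'
#' @param gamma nonnegative focusing exponent (default 2, the conventional
#'   value; the reference protocol does not state one).
#' @param classWeights positive per-class weight vector.
#' @return A [FocalParams-class] object.
#' @examples
#' FocalParams(gamma = 2, classWeights = rep(1, 5))
#' @export
FocalParams <- function(gamma = 2, classWeights = rep(1, 5)) {
    new("FocalParams", gamma = as.numeric(gamma),
        classWeights = as.numeric(classWeights))
}

#' Labelled image manifest
#'
#' The unit of data exchange between pipeline stages: an ordered table of
#' image records (path, class label, optional lesion id, split tag) plus
#' the class vocabulary.
#'
#' @slot samples data.frame with columns `path`, `label`, `lesion_id`,
#'   `split` (split is one of train/val/test/unassigned).
#' @slot classes character vector, the class vocabulary in fixed order.
#' @export
setClass("DatasetManifest", representation(
    samples = "data.frame", classes = "character"
))

setValidity("DatasetManifest", function(object) {
    msg <- character()
    need <- c("path", "label", "lesion_id", "split")
    if (!all(need %in% names(object@samples)))
        msg <- c(msg, paste("samples must have columns:",
                            paste(need, collapse = ", ")))
    else {
        bad <- setdiff(unique(object@samples$label), object@classes)
        if (length(bad))
            msg <- c(msg, paste("labels outside vocabulary:",
                                paste(bad, collapse = ", ")))
        badsplit <- setdiff(unique(object@samples$split),
                            c("train", "val", "test", "unassigned"))
        if (length(badsplit))
            msg <- c(msg, paste("invalid split tags:",
                                paste(badsplit, collapse = ", ")))
    }
    if (!length(object@classes) || anyDuplicated(object@classes))
        msg <- c(msg, "class vocabulary must be nonempty and unique")
    if (length(msg)) msg else TRUE
})

#' Augmentation and preprocessing configuration
#'
#' @slot horizontalFlip probability of a horizontal flip.
#' @slot verticalFlip probability of a vertical flip.
#' @slot maxCropFraction maximum fraction of image area removed by the
#'   random crop, at most 0.1 (the 10 percent cap of the reference
#'   augmentation recipe).
#' @slot maxTranslateFraction maximum translation per axis as a fraction of
#'   the image side (default 0.1).
#' @slot targetSize side length of the square model input (default 224).
#' @slot channels 1 (grayscale) or 3 (RGB, default).
#' @slot normMean,normStd per-channel normalization applied after scaling
#'   pixel values to [0,1].
#' @export
setClass("AugmentConfig", representation(
    horizontalFlip = "numeric", verticalFlip = "numeric",
    maxCropFraction = "numeric", maxTranslateFraction = "numeric",
    targetSize = "integer", channels = "integer",
    normMean = "numeric", normStd = "numeric"
))

setValidity("AugmentConfig", function(object) {
    msg <- character()
    p <- c(object@horizontalFlip, object@verticalFlip)
    if (any(p < 0 | p > 1)) msg <- c(msg, "flip probabilities must be in [0,1]")
    if (object@maxCropFraction < 0 || object@maxCropFraction > 0.1)
        msg <- c(msg, "'maxCropFraction' must be in [0, 0.1]")
    if (object@maxTranslateFraction < 0 || object@maxTranslateFraction > 1)
        msg <- c(msg, "'maxTranslateFraction' must be in [0, 1]")
    if (object@targetSize < 2) msg <- c(msg, "'targetSize' must be >= 2")
    if (!object@channels %in% c(1L, 3L)) msg <- c(msg, "'channels' must be 1 or 3")
    if (length(object@normMean) != object@channels ||
        length(object@normStd) != object@channels)
        msg <- c(msg, "normMean/normStd must have one entry per channel")
    if (any(object@normStd <= 0)) msg <- c(msg, "'normStd' must be positive")
    if (length(msg)) msg else TRUE
})

#' Construct an augmentation/preprocessing configuration
#'
#' Defaults follow the reference recipe: random horizontal and vertical
#' flips, random cropping removing at most 10 percent of the area, random
#' translation up to 10 percent per axis, then resizing to a square input.
#'
#' @param horizontalFlip,verticalFlip flip probabilities (default 0.5).
#' @param maxCropFraction maximum cropped-away area fraction, <= 0.1.
#' @param maxTranslateFraction maximum per-axis translation fraction.
#' @param targetSize square input side length (default 224).
#' @param channels 1 or 3 (default 3; source images are color photographs,
#'   a grayscale mode is available).
#' @param normMean,normStd per-channel normalization (defaults 0 and 1,
#'   i.e. plain [0,1] scaling).
#' @return An [AugmentConfig-class] object.
#' @examples
#' AugmentConfig(targetSize = 64)
#' @export
AugmentConfig <- function(horizontalFlip = 0.5, verticalFlip = 0.5,
                          maxCropFraction = 0.1, maxTranslateFraction = 0.1,
                          targetSize = 224L, channels = 3L,
                          normMean = rep(0, channels),
                          normStd = rep(1, channels)) {
    new("AugmentConfig",
        horizontalFlip = as.numeric(horizontalFlip),
        verticalFlip = as.numeric(verticalFlip),
        maxCropFraction = as.numeric(maxCropFraction),
        maxTranslateFraction = as.numeric(maxTranslateFraction),
        targetSize = as.integer(targetSize), channels = as.integer(channels),
        normMean = as.numeric(normMean), normStd = as.numeric(normStd))
}

#' Synthetic imbalanced image dataset configuration
#'
#' Parameterizes the generator of histology-like synthetic images: per class
#' a base background hue, elliptical "cell cluster" blobs, line "veins" and
#' additive Gaussian pixel noise. `difficulty` linearly interpolates every
#' class parameter set toward the across-class mean, so difficulty 1
#' collapses all classes to a common appearance.
#'
#' @slot imageSize square image side in pixels.
#' @slot classProportions positive class proportions (default the reference
#'   cohort's severe 41 : 1317 : 196 : 121 : 546 imbalance).
#' @slot totalImages total images to generate.
#' @slot classes class names.
#' @slot baseColor 3 x C matrix of per-class background RGB in [0,1].
#' @slot blobColor 3 x C matrix of per-class blob RGB in [0,1].
#' @slot blobDensity per-class blob count per 1000 px^2.
#' @slot blobRadius 2 x C matrix, min/max blob radius in pixels.
#' @slot veinCount per-class number of line structures.
#' @slot noiseSd per-class additive Gaussian noise standard deviation.
#' @slot difficulty numeric in [0,1].
#' @slot seed integer random seed.
#' @export
setClass("SyntheticConfig", representation(
    imageSize = "integer", classProportions = "numeric",
    totalImages = "integer", classes = "character",
    baseColor = "matrix", blobColor = "matrix",
    blobDensity = "numeric", blobRadius = "matrix",
    veinCount = "numeric", noiseSd = "numeric",
    difficulty = "numeric", seed = "integer"
))

setValidity("SyntheticConfig", function(object) {
    msg <- character()
    C <- length(object@classes)
    if (C < 2) msg <- c(msg, "need at least 2 classes")
    if (length(object@classProportions) != C ||
        any(object@classProportions <= 0))
        msg <- c(msg, "'classProportions' must be positive, one per class")
    if (object@imageSize < 8) msg <- c(msg, "'imageSize' must be >= 8")
    if (object@totalImages < 1) msg <- c(msg, "'totalImages' must be >= 1")
    if (object@difficulty < 0 || object@difficulty > 1)
        msg <- c(msg, "'difficulty' must be in [0, 1]")
    if (!all(dim(object@baseColor) == c(3, C)) ||
        !all(dim(object@blobColor) == c(3, C)))
        msg <- c(msg, "color matrices must be 3 x C")
    if (!all(dim(object@blobRadius) == c(2, C)))
        msg <- c(msg, "'blobRadius' must be 2 x C")
    if (length(object@blobDensity) != C || length(object@veinCount) != C ||
        length(object@noiseSd) != C)
        msg <- c(msg, "per-class parameter vectors must have length C")
    cnt <- propCounts(object@classProportions, object@totalImages)
    if (any(cnt < 5))
        msg <- c(msg, "every class must receive >= 5 images after rounding; increase 'totalImages'")
    if (length(msg)) msg else TRUE
})

#' Training configuration for the distillation engine
#'
#' Defaults equal the reference training protocol: AdamW with learning rate
#' 0.001, first-moment decay 0.9, weight decay 5e-4, 100 epochs, batch size
#' 32, five repeats, best-on-validation checkpoint selection.
#'
#' @slot mode one of "plain", "logits", "feature", "full".
#' @slot lossWeights a [LossWeights-class].
#' @slot focal a [FocalParams-class].
#' @slot learningRate positive step size.
#' @slot weightDecay decoupled weight-decay coefficient.
#' @slot momentumBeta1 first-moment decay coefficient of AdamW.
#' @slot epochs,batchSize positive integers.
#' @slot seed integer seed; repeats use seed, seed+1, ...
#' @slot nRepeats number of independent repeats.
#' @slot freezeAllButHead if TRUE only head parameters are optimized
#'   (the pure transfer-learning baseline); default FALSE so feature
#'   distillation can reach the trunk.
#' @slot warmupEpochs feature-matching-only warm-up epochs preceding joint
#'   optimization (default 0).
#' @export
setClass("DistillConfig", representation(
    mode = "character", lossWeights = "LossWeights", focal = "FocalParams",
    learningRate = "numeric", weightDecay = "numeric",
    momentumBeta1 = "numeric", epochs = "integer", batchSize = "integer",
    seed = "integer", nRepeats = "integer", freezeAllButHead = "logical",
    warmupEpochs = "integer"
))

setValidity("DistillConfig", function(object) {
    msg <- character()
    if (!object@mode %in% c("plain", "logits", "feature", "full"))
        msg <- c(msg, "'mode' must be one of plain/logits/feature/full")
    if (object@learningRate <= 0) msg <- c(msg, "'learningRate' must be > 0")
    if (object@weightDecay < 0) msg <- c(msg, "'weightDecay' must be >= 0")
    if (object@momentumBeta1 < 0 || object@momentumBeta1 >= 1)
        msg <- c(msg, "'momentumBeta1' must be in [0, 1)")
    if (object@epochs < 1) msg <- c(msg, "'epochs' must be >= 1")
    if (object@batchSize < 1) msg <- c(msg, "'batchSize' must be >= 1")
    if (object@nRepeats < 1) msg <- c(msg, "'nRepeats' must be >= 1")
    if (object@warmupEpochs < 0) msg <- c(msg, "'warmupEpochs' must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Construct a training configuration
#'
#' @param mode training mode: "plain" (focal loss only), "logits" (adds the
#'   temperature-scaled soft-label loss), "feature" (adds the stage-wise
#'   feature-matching loss), or "full" (all three terms).
#' @param lossWeights a [LossWeights-class] (default [LossWeights()]).
#' @param focal a [FocalParams-class] (default [FocalParams()]).
#' @param learningRate,weightDecay,momentumBeta1,epochs,batchSize,seed,nRepeats
#'   optimizer/protocol settings; defaults are the reference protocol.
#' @param freezeAllButHead optimize head parameters only (default FALSE).
#' @param warmupEpochs feature-only warm-up epochs (default 0).
#' @return A [DistillConfig-class] object.
#' @examples
#' DistillConfig(mode = "full", epochs = 5L, batchSize = 16L)
#' @export
DistillConfig <- function(mode = "full", lossWeights = LossWeights(),
                          focal = FocalParams(), learningRate = 0.001,
                          weightDecay = 5e-4, momentumBeta1 = 0.9,
                          epochs = 100L, batchSize = 32L, seed = 1L,
                          nRepeats = 5L, freezeAllButHead = FALSE,
                          warmupEpochs = 0L) {
    new("DistillConfig", mode = mode, lossWeights = lossWeights,
        focal = focal, learningRate = as.numeric(learningRate),
        weightDecay = as.numeric(weightDecay),
        momentumBeta1 = as.numeric(momentumBeta1),
        epochs = as.integer(epochs), batchSize = as.integer(batchSize),
        seed = as.integer(seed), nRepeats = as.integer(nRepeats),
        freezeAllButHead = isTRUE(freezeAllButHead),
        warmupEpochs = as.integer(warmupEpochs))
}

#' A classifier network partitioned into 4 ordered stage blocks
#'
#' Wraps an ordered sequence of layer blocks cut into exactly four stages
#' plus a classification head, exposing intermediate stage outputs for
#' feature distillation. The composed staged forward pass reproduces the
#' unpartitioned network's logits exactly.
#'
#' @slot stages list of 4 stage blocks (each an ordered list of layers).
#' @slot head the classification head (global average pool + linear).
#' @slot descriptor data.frame with one row per stage: output `channels`
#'   and cumulative `downsample` factor.
#' @slot nClasses number of output classes.
#' @slot inChannels number of input image channels.
#' @export
setClass("StagedBackbone", representation(
    stages = "list", head = "list", descriptor = "data.frame",
    nClasses = "integer", inChannels = "integer"
))

setValidity("StagedBackbone", function(object) {
    msg <- character()
    if (length(object@stages) != 4)
        msg <- c(msg, "a staged backbone must have exactly 4 stages")
    if (nrow(object@descriptor) != 4 ||
        !all(c("channels", "downsample") %in% names(object@descriptor)))
        msg <- c(msg, "descriptor must have 4 rows with channels/downsample")
    if (length(msg)) msg else TRUE
})

#' Per-stage channel-projection adapters
#'
#' Four learnable pointwise (1x1) projections mapping student stage-k
#' feature channels into the teacher's stage-k channel space. Trained
#' jointly with the student; the teacher side is the identity.
#'
#' @slot adapters list of 4 lists with elements `W` (teacherC x studentC
#'   matrix) and `b` (length teacherC bias).
#' @export
setClass("AdapterBank", representation(adapters = "list"))

setValidity("AdapterBank", function(object) {
    if (length(object@adapters) != 4)
        return("an adapter bank must hold exactly 4 adapters")
    ok <- vapply(object@adapters, function(a)
        is.matrix(a$W) && is.numeric(a$b) && length(a$b) == nrow(a$W),
        logical(1))
    if (!all(ok)) return("each adapter needs a W matrix and matching bias")
    TRUE
})

#' Training history and checkpoints
#'
#' @slot history data.frame with one row per epoch: epoch, loss1 (feature),
#'   loss2 (soft label), loss3 (focal), total, val_accuracy.
#' @slot bestEpoch epoch with the highest validation accuracy seen.
#' @slot bestValAccuracy the corresponding validation accuracy.
#' @slot bestModel the best-on-validation student checkpoint.
#' @slot bestAdapters adapter checkpoint matching `bestModel` (may be NULL).
#' @slot finalModel the student after the last epoch.
#' @slot finalAdapters adapters after the last epoch (may be NULL).
#' @slot config the [DistillConfig-class] used.
#' @export
setClass("TrainingState", representation(
    history = "data.frame", bestEpoch = "integer", bestValAccuracy = "numeric",
    bestModel = "ANY", bestAdapters = "ANY", finalModel = "ANY",
    finalAdapters = "ANY", config = "DistillConfig"
))

#' Confusion matrix
#'
#' Rows are true classes, columns predicted classes (the dominant ecosystem
#' convention; a transposed display is available via `show`'s `transpose`
#' counterpart [printTransposed()]).
#'
#' @slot counts C x C nonnegative integer matrix, rows = truth.
#' @slot classes class vocabulary.
#' @export
setClass("ConfusionMatrix", representation(
    counts = "matrix", classes = "character"
))

setValidity("ConfusionMatrix", function(object) {
    msg <- character()
    C <- length(object@classes)
    if (!all(dim(object@counts) == c(C, C)))
        msg <- c(msg, "counts must be C x C for C classes")
    if (any(object@counts < 0) || any(object@counts != round(object@counts)))
        msg <- c(msg, "counts must be nonnegative integers")
    if (length(msg)) msg else TRUE
})

#' Classification metrics report
#'
#' Accuracy plus per-class and macro-averaged precision, recall and F1.
#' Two macro-F1 variants are computed: `macroF1` is the unweighted mean of
#' per-class F1 scores; `macroF1Paper` applies the harmonic-mean formula
#' F1 = 2PR/(P+R) to the macro precision and macro recall (the variant that
#' reproduces the reference result tables).
#'
#' @slot accuracy overall accuracy in [0,1].
#' @slot macroPrecision,macroRecall unweighted means of per-class values.
#' @slot macroF1 mean of per-class F1.
#' @slot macroF1Paper harmonic mean of macro precision and macro recall.
#' @slot perClass data.frame: class, precision, recall, f1, support,
#'   undefined (TRUE when the class received no predictions).
#' @slot nUndefined number of classes with undefined precision (reported
#'   as 0).
#' @export
setClass("MetricsReport", representation(
    accuracy = "numeric", macroPrecision = "numeric", macroRecall = "numeric",
    macroF1 = "numeric", macroF1Paper = "numeric", perClass = "data.frame",
    nUndefined = "integer"
))
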