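## The distillation training loop: joint optimization of the combined
## objective over student + adapter parameters with AdamW (decoupled weight
## decay; no decay on biases), constant learning rate, best-on-validation
## checkpoint selection. The teacher is frozen and used in inference mode
## throughout.

## chain rule softmax -> probabilities gradient to logits:
## dz_i = p_i * (g_i - sum_j g_j p_j)
.probGradToLogits <- function(dprobs, probs) {
    s <- rowSums(dprobs * probs)
    probs * (dprobs - s)
}

.newOptState <- function(model, adapters, reg) {
    lapply(reg, function(e) {
        p <- .getParam(model, adapters, e)
        list(m = p * 0, v = p * 0)   # zero state, same shape/class as p
    })
}

.adamwStep <- function(model, adapters, reg, grads, adapterGrads, opt, t,
                       lr, wd, beta1, beta2 = 0.999, eps = 1e-8) {
    for (j in seq_along(reg)) {
        e <- reg[[j]]
        g <- .getGrad(grads, adapterGrads, e)
        if (is.null(g)) next
        p <- .getParam(model, adapters, e)
        opt[[j]]$m <- beta1 * opt[[j]]$m + (1 - beta1) * g
        opt[[j]]$v <- beta2 * opt[[j]]$v + (1 - beta2) * g^2
        mhat <- opt[[j]]$m / (1 - beta1^t)
        vhat <- opt[[j]]$v / (1 - beta2^t)
        upd <- mhat / (sqrt(vhat) + eps)
        if (e$decay && wd > 0) upd <- upd + wd * p
        p <- p - lr * upd
        r <- .setParam(model, adapters, e, p)
        model <- r$model; adapters <- r$adapters
    }
    list(model = model, adapters = adapters, opt = opt)
}

#' Train a student network, optionally under a frozen teacher
#'
#' Runs the staged distillation training protocol in one of four modes:
#' \describe{
#'   \item{plain}{focal loss only (no teacher).}
#'   \item{logits}{(1-alpha) * soft-label loss + beta * focal loss.}
#'   \item{feature}{alpha * feature-matching loss + beta * focal loss.}
#'   \item{full}{alpha * L1 + (1-alpha) * L2 + beta * L3 (the combined
#'     objective).}
#' }
#' All modes record the three loss components per epoch so the weighted
#' decomposition can be verified externally; absent terms are logged as
#' zero. The student and (in feature-bearing modes) the stage adapters are
#' optimized jointly with AdamW; the teacher's parameters are never
#' touched. The checkpoint with the highest validation accuracy seen so far
#' is retained. An optional warm-up of feature-matching-only epochs can
#' precede the joint optimization (default 0).
#'
#' @param student a [StagedBackbone-class] to train.
#' @param teacher a frozen [StagedBackbone-class]; required for every mode
#'   except "plain" (ignored in "plain").
#' @param trainData,valData lists with `x` (array channels x H x W x N) and
#'   `y` (integer labels 1..C).
#' @param config a [DistillConfig-class].
#' @param augmentConfig optional [AugmentConfig-class] applied to training
#'   batches only (validation is evaluated on unaugmented inputs).
#' @param adapters optional pre-built [AdapterBank-class]; built
#'   automatically (seeded from `config@seed`) when needed.
#' @param verbose print per-epoch progress.
#' @return A [TrainingState-class].
#' @export
trainModel <- function(student, teacher = NULL, trainData, valData,
                       config = DistillConfig(), augmentConfig = NULL,
                       adapters = NULL, verbose = FALSE) {
    stopifnot(is(student, "StagedBackbone"), is(config, "DistillConfig"))
    mode <- config@mode
    needTeacher <- mode != "plain"
    if (needTeacher && is.null(teacher))
        stop("mode '", mode, "' requires a teacher network")
    if (is.null(trainData$x) || length(trainData$y) == 0)
        stop("empty training data")
    if (dim(trainData$x)[4] != length(trainData$y))
        stop("trainData: batch dimension does not match labels")
    useFeat <- mode %in% c("feature", "full")
    useSoft <- mode %in% c("logits", "full")
    lw <- config@lossWeights
    if (length(config@focal@classWeights) != student@nClasses)
        stop("focal class weights must have one entry per class")
    set.seed(config@seed)
    if (useFeat && is.null(adapters))
        adapters <- buildAdapters(student, teacher, seed = config@seed)
    if (!useFeat) adapters <- NULL
    reg <- .paramRegistry(student, adapters,
                          headOnly = config@freezeAllButHead)
    opt <- .newOptState(student, adapters, reg)
    nTrain <- length(trainData$y)
    bs <- min(config@batchSize, nTrain)
    hist <- vector("list", config@epochs)
    best <- list(acc = -Inf, epoch = 0L, model = student,
                 adapters = adapters)
    stepCount <- 0L
    for (epoch in seq_len(config@epochs)) {
        warm <- epoch <= config@warmupEpochs && useFeat
        ord <- sample.int(nTrain)
        nb <- ceiling(nTrain / bs)
        sums <- c(l1 = 0, l2 = 0, l3 = 0, total = 0)
        for (bi in seq_len(nb)) {
            idx <- ord[((bi - 1) * bs + 1):min(bi * bs, nTrain)]
            xb <- trainData$x[, , , idx, drop = FALSE]
            if (!is.null(augmentConfig))
                for (n in seq_along(idx))
                    xb[, , , n] <- augmentArray(
                        array(xb[, , , n], dim = dim(xb)[1:3]),
                        augmentConfig)
            yb <- trainData$y[idx]
            fwd <- .stagedForwardTrain(student, xb)
            tFwd <- if (needTeacher) forwardWithFeatures(teacher, xb)
                    else NULL
            probs <- temperedSoftmax(fwd$logits, 1)
            l3 <- focalLoss(probs, yb, config@focal, grad = TRUE)
            dprobs <- attr(l3, "gradient")
            dLogits3 <- .probGradToLogits(dprobs, probs)
            l2 <- 0; dLogits2 <- 0
            if (useSoft) {
                l2 <- softTargetLoss(fwd$logits, tFwd$logits,
                                     lw@temperature, tsquare = lw@tsquare,
                                     grad = TRUE)
                dLogits2 <- attr(l2, "gradient")
            }
            l1 <- 0; dFeatures <- NULL; adapterGrads <- NULL
            if (useFeat) {
                l1 <- featureMatchLoss(fwd$features, tFwd$features,
                                       adapters, grad = TRUE)
                fg <- attr(l1, "gradient")
                dFeatures <- lapply(fg$features, function(g) g * lw@alpha)
                adapterGrads <- lapply(fg$adapters, function(g)
                    list(dW = g$dW * lw@alpha, db = g$db * lw@alpha))
            }
            total <- totalLoss(as.numeric(l1), as.numeric(l2),
                               as.numeric(l3), lw)
            if (warm) {
                dLogits <- matrix(0, nrow(fwd$logits), ncol(fwd$logits))
            } else {
                dLogits <- lw@beta * dLogits3
                if (useSoft) dLogits <- dLogits + (1 - lw@alpha) * dLogits2
            }
            grads <- .stagedBackward(student, fwd, dLogits, dFeatures)
            stepCount <- stepCount + 1L
            st <- .adamwStep(student, adapters, reg, grads, adapterGrads,
                             opt, stepCount, config@learningRate,
                             config@weightDecay, config@momentumBeta1)
            student <- st$model; adapters <- st$adapters; opt <- st$opt
            w <- length(idx) / nTrain
            sums <- sums + w * c(as.numeric(l1), as.numeric(l2),
                                 as.numeric(l3), total)
        }
        valAcc <- NA_real_
        if (!is.null(valData$x) && length(valData$y) > 0) {
            pred <- predictClasses(student, valData$x)
            valAcc <- mean(pred == valData$y)
        }
        hist[[epoch]] <- data.frame(
            epoch = epoch, loss1 = sums[1], loss2 = sums[2],
            loss3 = sums[3], total = sums[4], val_accuracy = valAcc,
            row.names = NULL)
        if (!is.na(valAcc) && valAcc > best$acc) {
            best <- list(acc = valAcc, epoch = epoch, model = student,
                         adapters = adapters)
        }
        if (verbose)
            message(sprintf(
                "epoch %3d  L1 %.4f  L2 %.4f  L3 %.4f  total %.4f  val %.3f",
                epoch, sums[1], sums[2], sums[3], sums[4], valAcc))
    }
    history <- do.call(rbind, hist)
    rownames(history) <- NULL
    if (!is.finite(best$acc))
        best <- list(acc = NA_real_, epoch = config@epochs, model = student,
                     adapters = adapters)
    new("TrainingState", history = history,
        bestEpoch = as.integer(best$epoch),
        bestValAccuracy = as.numeric(best$acc),
        bestModel = best$model, bestAdapters = best$adapters,
        finalModel = student, finalAdapters = adapters, config = config)
}

#' Export a training history as CSV
#'
#' Columns: epoch, loss1 (feature), loss2 (soft label), loss3 (focal),
#' total, val_accuracy.
#'
#' @param state a [TrainingState-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
exportHistory <- function(state, path) {
    stopifnot(is(state, "TrainingState"))
    utils::write.csv(state@history, path, row.names = FALSE)
    invisible(path)
}
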