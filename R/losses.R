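## Loss terms of the combined distillation objective.
## Batches of logits/probabilities are N x C matrices (rows = samples).
## Each loss has an analytic gradient helper used by the training engine;
## gradients flow only to the student side.

.asLogitMatrix <- function(x, what = "logits") {
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    x <- as.matrix(x)
    if (ncol(x) < 2)
        stop("'", what, "' must have at least 2 classes")
    if (!all(is.finite(x)))
        stop("'", what, "' must be finite (no NaN/Inf)")
    x
}

#' Temperature-scaled softmax
#'
#' Computes p_i = exp(z_i / T) / sum_j exp(z_j / T) with max-subtraction for
#' numerical stability. Larger temperatures yield smoother distributions,
#' which is what lets a teacher's soft labels carry inter-class information
#' about rare categories.
#'
#' @param logits numeric vector of length C, or an N x C matrix (row-wise).
#' @param temperature positive softmax temperature T.
#' @return Probabilities with the same shape as `logits`; rows sum to 1.
#' @examples
#' temperedSoftmax(c(1, 2, 3), temperature = 1)
#' temperedSoftmax(c(1, 2, 3), temperature = 2)  # smoother
#' @export
temperedSoftmax <- function(logits, temperature = 1) {
    if (!is.numeric(temperature) || length(temperature) != 1 ||
        is.na(temperature) || temperature <= 0)
        stop("'temperature' must be a single positive number")
    vec <- is.null(dim(logits))
    z <- .asLogitMatrix(logits)
    z <- z / temperature
    z <- z - apply(z, 1, max)
    e <- exp(z)
    p <- e / rowSums(e)
    if (vec) drop(p) else p
}

#' Soft-target distillation loss
#'
#' Cross-entropy between the teacher's and the student's temperature-scaled
#' softmax distributions, averaged over the batch:
#' \deqn{L_2 = \frac{1}{N}\sum_n \sum_i -p_i(z_t^{(n)}; T)\,
#'   \log p_i(z_s^{(n)}; T).}
#' The teacher logits are treated as constants (no gradient flows to the
#' teacher). By default no T^2 rescaling is applied; `tsquare = TRUE`
#' multiplies loss and gradient by T^2 (the classic correction keeping
#' gradient magnitudes comparable across temperatures).
#'
#' @param studentLogits,teacherLogits N x C matrices (or length-C vectors)
#'   of identical shape.
#' @param temperature positive temperature T.
#' @param tsquare logical, apply T^2 rescaling (default FALSE).
#' @param grad logical; if TRUE the gradient with respect to the student
#'   logits is attached as attribute "gradient".
#' @return Nonnegative scalar loss (>= the tempered teacher entropy, by
#'   Gibbs' inequality).
#' @examples
#' softTargetLoss(c(0, 0), c(0, 0), temperature = 1)  # log(2)
#' @export
softTargetLoss <- function(studentLogits, teacherLogits, temperature = 1,
                           tsquare = FALSE, grad = FALSE) {
    zs <- .asLogitMatrix(studentLogits, "studentLogits")
    zt <- .asLogitMatrix(teacherLogits, "teacherLogits")
    if (!all(dim(zs) == dim(zt)))
        stop("student and teacher logits must have identical shapes")
    ps <- temperedSoftmax(zs, temperature)
    pt <- temperedSoftmax(zt, temperature)
    n <- nrow(zs)
    ## log softmax computed stably from the logits themselves
    a <- zs / temperature
    lse <- apply(a, 1, function(r) { m <- max(r); m + log(sum(exp(r - m))) })
    logps <- a - lse
    loss <- -sum(pt * logps) / n
    scale <- if (isTRUE(tsquare)) temperature^2 else 1
    loss <- loss * scale
    if (grad)
        attr(loss, "gradient") <- (ps - pt) / (n * temperature) * scale
    loss
}

#' Focal loss
#'
#' Class-weighted focal loss against hard labels, averaged over the batch:
#' \deqn{L_3 = \frac{1}{N}\sum_n -\alpha_{y_n} (1 - p_{y_n})^{\gamma}
#'   \log p_{y_n},}
#' where p_y is the predicted probability of the true class. The modulating
#' factor (1-p)^gamma down-weights easy examples; the per-class weights
#' alpha_t up-weight rare classes. p is clamped below at 1e-12 before the
#' logarithm.
#'
#' @param studentProbs N x C matrix of predicted class probabilities (rows
#'   sum to 1), or a length-C vector for a single sample.
#' @param labels integer true-class indices in 1..C (or a factor with the
#'   same level order as the columns).
#' @param params a [FocalParams-class] with gamma and per-class weights.
#' @param grad logical; if TRUE the gradient with respect to
#'   `studentProbs` is attached as attribute "gradient" (nonzero only at
#'   the true-class entries).
#' @return Nonnegative scalar loss.
#' @examples
#' focalLoss(matrix(c(0.5, 0.5), 1), 1L,
#'           FocalParams(gamma = 0, classWeights = c(1, 1)))  # log(2)
#' @export
focalLoss <- function(studentProbs, labels, params = FocalParams(),
                      grad = FALSE) {
    if (is.null(dim(studentProbs))) studentProbs <- matrix(studentProbs, 1)
    p <- as.matrix(studentProbs)
    C <- ncol(p)
    if (is.factor(labels)) labels <- as.integer(labels)
    labels <- as.integer(labels)
    if (nrow(p) != length(labels))
        stop("'labels' must have one entry per row of 'studentProbs'")
    if (any(is.na(labels)) || any(labels < 1L) || any(labels > C))
        stop("labels out of range 1..", C)
    if (length(params@classWeights) != C)
        stop("'classWeights' length must equal the number of classes")
    n <- nrow(p)
    idx <- cbind(seq_len(n), labels)
    pt <- pmax(p[idx], 1e-12)
    at <- params@classWeights[labels]
    g <- params@gamma
    loss <- mean(-at * (1 - pt)^g * log(pt))
    if (grad) {
        gr <- matrix(0, n, C)
        modgrad <- if (g == 0) 0 else g * (1 - pt)^(g - 1) * log(pt)
        gr[idx] <- (at * modgrad - at * (1 - pt)^g / pt) / n
        attr(loss, "gradient") <- gr
    }
    loss
}

#' Stage-wise feature-matching loss
#'
#' For each of the 4 corresponding stages, the student feature map is
#' projected into the teacher's channel space by the learnable 1x1 adapter,
#' bilinearly resized to the teacher map's spatial size if the sizes differ,
#' and compared to the (untransformed) teacher map by mean squared error.
#' The returned loss is the mean over the 4 stages, which keeps its
#' magnitude independent of feature-map size so the combination weight
#' alpha transfers across backbones.
#'
#' @param studentFeats,teacherFeats lists of 4 arrays with dimensions
#'   (channels, height, width, batch), ordered shallow to deep; batch sizes
#'   must agree (channel counts may differ).
#' @param adapters an [AdapterBank-class] mapping student channels to
#'   teacher channels per stage.
#' @param grad logical; if TRUE attaches attribute "gradient": a list with
#'   `features` (per-stage gradients w.r.t. the student features) and
#'   `adapters` (per-stage list of dW, db). No gradient flows to the
#'   teacher features.
#' @return Nonnegative scalar loss; 0 iff every adapted student map equals
#'   the corresponding teacher map.
#' @export
featureMatchLoss <- function(studentFeats, teacherFeats, adapters,
                             grad = FALSE) {
    if (!is.list(studentFeats) || length(studentFeats) != 4 ||
        !is.list(teacherFeats) || length(teacherFeats) != 4)
        stop("feature sets must be lists of exactly 4 stage arrays")
    stopifnot(is(adapters, "AdapterBank"))
    nb <- vapply(c(studentFeats, teacherFeats),
                 function(f) dim(f)[4], numeric(1))
    if (length(unique(nb)) != 1)
        stop("all stages must share one batch size")
    total <- 0
    gfeat <- vector("list", 4)
    gadap <- vector("list", 4)
    for (k in 1:4) {
        s <- studentFeats[[k]]; t <- teacherFeats[[k]]
        A <- adapters@adapters[[k]]$W; b <- adapters@adapters[[k]]$b
        ds <- dim(s); dt <- dim(t)
        if (ncol(A) != ds[1] || nrow(A) != dt[1])
            stop("adapter ", k, " does not map student channels (", ds[1],
                 ") to teacher channels (", dt[1], ")")
        sm <- matrix(s, nrow = ds[1])            # Cs x (H*W*N)
        am <- A %*% sm + b                       # Ct x (H*W*N)
        aarr <- array(am, dim = c(dt[1], ds[2], ds[3], ds[4]))
        resized <- !all(ds[2:3] == dt[2:3])
        if (resized) {
            rz <- bilinearResize(aarr, dt[2], dt[3], adjointReady = grad)
            aarr2 <- rz$out
        } else aarr2 <- aarr
        diff <- aarr2 - t
        m <- length(diff)
        total <- total + sum(diff^2) / m
        if (grad) {
            dA2 <- 2 * diff / m / 4              # d stage-loss / d adapted
            if (resized) dA1 <- bilinearResizeAdjoint(dA2, rz)
            else dA1 <- dA2
            dAm <- matrix(dA1, nrow = dt[1])
            gfeat[[k]] <- array(crossprod(A, dAm), dim = ds)
            gadap[[k]] <- list(dW = dAm %*% t(sm), db = rowSums(dAm))
        }
    }
    loss <- total / 4
    if (grad)
        attr(loss, "gradient") <- list(features = gfeat, adapters = gadap)
    loss
}

#' Combined distillation objective
#'
#' Weighted combination of the three loss terms:
#' total = alpha * loss1 + (1 - alpha) * loss2 + beta * loss3, with loss1
#' the feature-matching loss, loss2 the soft-target loss and loss3 the
#' focal loss. The reference coefficients are alpha = 0.5, beta = 1.
#'
#' @param loss1,loss2,loss3 finite scalars.
#' @param weights a [LossWeights-class].
#' @return The weighted total.
#' @examples
#' totalLoss(2, 4, 1, LossWeights(alpha = 0.5, beta = 1))  # 4
#' @export
totalLoss <- function(loss1, loss2, loss3, weights = LossWeights()) {
    stopifnot(is(weights, "LossWeights"))
    vals <- c(loss1, loss2, loss3)
    if (length(vals) != 3 || !all(is.finite(vals)))
        stop("loss terms must be three finite scalars")
    weights@alpha * loss1 + (1 - weights@alpha) * loss2 +
        weights@beta * loss3
}

#' Shannon entropy of a probability vector
#'
#' Convenience used by the soft-target lower-bound property: the
#' soft-target loss can never fall below the tempered teacher entropy.
#'
#' @param p probability vector (or N x C matrix, row-wise).
#' @return Entropy in nats.
#' @export
shannonEntropy <- function(p) {
    if (is.null(dim(p))) p <- matrix(p, 1)
    drop(-rowSums(ifelse(p > 0, p * log(p), 0)))
}
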