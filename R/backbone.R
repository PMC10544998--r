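## Miniature staged CNN backbones and the 4-stage partitioning contract.
## A "flat" network is an ordered list of named layer blocks plus a head;
## partitionBackbone() cuts it into the 4 stages required by stage-wise
## feature distillation. The staged forward composes to exactly the flat
## forward (same operations, same order), which the tests check bitwise.

.heInitConv <- function(cOut, cIn, k) {
    fanIn <- cIn * k * k
    array(stats::rnorm(cOut * cIn * k * k, sd = sqrt(2 / fanIn)),
          dim = c(cOut, cIn, k, k))
}

.convLayer <- function(cOut, cIn, k, stride, pad) {
    list(type = "conv", W = .heInitConv(cOut, cIn, k),
         b = numeric(cOut), stride = stride, pad = pad)
}

#' Build a miniature 4-stage CNN classifier
#'
#' A small ConvNeXt-like staged network: a 4x4 stride-4 patchify stem, then
#' three 3x3 stride-2 downsampling blocks, each stage followed by a 3x3
#' stride-1 mixing convolution with ReLU activations, closed by a global
#' average pool and a linear classifier. Cumulative downsampling is
#' 4/8/16/32, the schedule shared by the reference teacher and student
#' architectures, so corresponding stages have matching spatial sizes.
#'
#' The result is a "flat" network (ordered named blocks + head) meant to be
#' cut into 4 stages with [partitionBackbone()]. Roughly 7e4 parameters at
#' the default widths: trainable on one CPU in seconds per epoch.
#'
#' @param channels integer vector of 4 stage widths (output channels).
#' @param nClasses number of output classes.
#' @param inChannels input image channels (3 for RGB).
#' @param seed integer seed controlling the (He-normal) initialization.
#' @return A flat network object (class "flatNetwork") with blocks
#'   `s1_down, s1_mix, ..., s4_down, s4_mix` and a head.
#' @examples
#' net <- miniatureBackbone(c(8, 16, 32, 64), nClasses = 5, seed = 1)
#' names(net$blocks)
#' @export
miniatureBackbone <- function(channels = c(8L, 16L, 32L, 64L), nClasses = 5L,
                              inChannels = 3L, seed = 1L) {
    stopifnot(length(channels) == 4, all(channels >= 1))
    set.seed(as.integer(seed))
    blocks <- list()
    cin <- inChannels
    for (k in 1:4) {
        cOut <- channels[k]
        down <- if (k == 1)
            list(.convLayer(cOut, cin, 4, stride = 4, pad = 0),
                 list(type = "relu"))
        else
            list(.convLayer(cOut, cin, 3, stride = 2, pad = 1),
                 list(type = "relu"))
        mix <- list(.convLayer(cOut, cOut, 3, stride = 1, pad = 1),
                    list(type = "relu"))
        blocks[[paste0("s", k, "_down")]] <- down
        blocks[[paste0("s", k, "_mix")]] <- mix
        cin <- cOut
    }
    head <- list(type = "head",
                 W = matrix(stats::rnorm(nClasses * channels[4],
                                         sd = sqrt(1 / channels[4])),
                            nClasses, channels[4]),
                 b = numeric(nClasses))
    structure(list(blocks = blocks, head = head,
                   channels = as.integer(channels),
                   downsample = c(4L, 8L, 16L, 32L),
                   nClasses = as.integer(nClasses),
                   inChannels = as.integer(inChannels)),
              class = "flatNetwork")
}

.blockForward <- function(block, x, keepCache = FALSE) {
    caches <- if (keepCache) vector("list", length(block)) else NULL
    for (i in seq_along(block)) {
        layer <- block[[i]]
        r <- switch(layer$type,
                    conv = convForward(x, layer, keepCache),
                    relu = reluForward(x, keepCache),
                    stop("unknown layer type: ", layer$type))
        x <- r$y
        if (keepCache) caches[[i]] <- r$cache
    }
    list(y = x, caches = caches)
}

#' Forward pass of an unpartitioned flat network
#'
#' Runs all blocks in order followed by the head. Used as the reference
#' against which the staged forward is checked for exact (bitwise) identity.
#'
#' @param network a flat network from [miniatureBackbone()].
#' @param x input batch, array (channels, height, width, batch).
#' @return N x C matrix of logits.
#' @export
flatForward <- function(network, x) {
    for (block in network$blocks) x <- .blockForward(block, x)$y
    t(headForward(x, network$head)$y)
}

#' Partition a network into 4 corresponding stage blocks
#'
#' Cuts a flat network at 4 named block boundaries into the four ordered
#' stages used for stage-wise feature distillation. The composed staged
#' forward reproduces the unpartitioned forward exactly. The final boundary
#' must be the network's last block (everything before the head belongs to
#' some stage).
#'
#' @param network a flat network (see [miniatureBackbone()]).
#' @param stageBoundaries character vector of exactly 4 block names, in
#'   increasing network order; stage k ends immediately after the named
#'   block.
#' @return A [StagedBackbone-class].
#' @examples
#' net <- miniatureBackbone(seed = 1)
#' sb <- partitionBackbone(net, c("s1_mix", "s2_mix", "s3_mix", "s4_mix"))
#' stageDescriptor(sb)
#' @export
partitionBackbone <- function(network,
                              stageBoundaries = c("s1_mix", "s2_mix",
                                                  "s3_mix", "s4_mix")) {
    if (!inherits(network, "flatNetwork"))
        stop("'network' must be a flat network (see miniatureBackbone)")
    if (length(stageBoundaries) != 4)
        stop("exactly 4 stage boundaries are required, got ",
             length(stageBoundaries))
    nm <- names(network$blocks)
    pos <- match(stageBoundaries, nm)
    if (anyNA(pos))
        stop("unknown block label(s): ",
             paste(stageBoundaries[is.na(pos)], collapse = ", "))
    if (any(diff(pos) <= 0))
        stop("stage boundaries must be strictly increasing network order")
    if (pos[4] != length(nm))
        stop("the 4th boundary must be the final block ('", nm[length(nm)],
             "') so every block belongs to a stage")
    starts <- c(1, pos[-4] + 1)
    stages <- vector("list", 4)
    for (k in 1:4) {
        blk <- network$blocks[starts[k]:pos[k]]
        stages[[k]] <- unlist(blk, recursive = FALSE, use.names = FALSE)
    }
    channels <- vapply(stages, function(st) {
        convs <- Filter(function(l) l$type == "conv", st)
        as.integer(dim(convs[[length(convs)]]$W)[1])
    }, integer(1))
    downs <- integer(4)
    cum <- 1L
    for (k in 1:4) {
        for (l in stages[[k]]) if (l$type == "conv") cum <- cum * l$stride
        downs[k] <- cum
    }
    new("StagedBackbone", stages = stages, head = network$head,
        descriptor = data.frame(stage = 1:4, channels = channels,
                                downsample = downs),
        nClasses = network$nClasses, inChannels = network$inChannels)
}

#' Stage descriptor of a partitioned backbone
#'
#' @param backbone a [StagedBackbone-class].
#' @return data.frame with per-stage output channel counts and cumulative
#'   downsampling factors.
#' @export
stageDescriptor <- function(backbone) {
    stopifnot(is(backbone, "StagedBackbone"))
    backbone@descriptor
}

#' Forward pass capturing the 4 stage feature maps
#'
#' Runs the staged forward and returns the final logits together with the
#' four intermediate stage outputs (shallow to deep), captured without
#' altering the forward result.
#'
#' @param model a [StagedBackbone-class].
#' @param batch input array (channels, height, width, batch).
#' @return list with `logits` (N x C matrix) and `features` (list of 4
#'   arrays shaped (channels_k, height_k, width_k, batch)).
#' @export
forwardWithFeatures <- function(model, batch) {
    stopifnot(is(model, "StagedBackbone"))
    if (length(dim(batch)) != 4 || dim(batch)[1] != model@inChannels)
        stop("batch must be (", model@inChannels, ", H, W, N)")
    feats <- vector("list", 4)
    x <- batch
    for (k in 1:4) {
        x <- .blockForward(model@stages[[k]], x)$y
        feats[[k]] <- x
    }
    logits <- t(headForward(x, model@head)$y)
    list(logits = logits, features = feats)
}

## forward keeping every layer cache, for backprop
.stagedForwardTrain <- function(model, batch) {
    feats <- vector("list", 4)
    caches <- vector("list", 4)
    x <- batch
    for (k in 1:4) {
        r <- .blockForward(model@stages[[k]], x, keepCache = TRUE)
        x <- r$y
        feats[[k]] <- x
        caches[[k]] <- r$caches
    }
    hr <- headForward(x, model@head, keepCache = TRUE)
    list(logits = t(hr$y), features = feats, caches = caches,
         headCache = hr$cache)
}

## backprop through head and stages; dFeatures injects the feature-matching
## gradient at each stage output (or NULL). Returns grads mirroring the
## model structure.
.stagedBackward <- function(model, fwd, dLogits, dFeatures = NULL) {
    hb <- headBackward(model@head, fwd$headCache, t(dLogits))
    gHead <- list(dW = hb$dW, db = hb$db)
    dx <- hb$dx
    gStages <- vector("list", 4)
    for (k in 4:1) {
        if (!is.null(dFeatures) && !is.null(dFeatures[[k]]))
            dx <- dx + dFeatures[[k]]
        st <- model@stages[[k]]
        gLayers <- vector("list", length(st))
        for (i in rev(seq_along(st))) {
            layer <- st[[i]]
            if (layer$type == "conv") {
                cb <- convBackward(layer, fwd$caches[[k]][[i]], dx)
                gLayers[[i]] <- list(dW = cb$dW, db = cb$db)
                dx <- cb$dx
            } else if (layer$type == "relu") {
                dx <- reluBackward(fwd$caches[[k]][[i]], dx)
                gLayers[i] <- list(NULL)   # keep positions aligned
            }
        }
        gStages[[k]] <- gLayers
    }
    list(stages = gStages, head = gHead)
}

#' Build per-stage 1x1 channel adapters between a student and a teacher
#'
#' Creates the 4 learnable pointwise projections mapping the student's
#' stage-k output channels to the teacher's stage-k channel count, with
#' channel counts read from the two stage descriptors. Initialization is
#' He-normal and deterministic given the seed. Adapters are created (and
#' remain learnable) even when the channel counts already match.
#'
#' @param student,teacher [StagedBackbone-class] objects.
#' @param seed integer seed for the deterministic initialization.
#' @return An [AdapterBank-class].
#' @export
buildAdapters <- function(student, teacher, seed = 1L) {
    stopifnot(is(student, "StagedBackbone"), is(teacher, "StagedBackbone"))
    set.seed(as.integer(seed))
    adapters <- vector("list", 4)
    for (k in 1:4) {
        cs <- student@descriptor$channels[k]
        ct <- teacher@descriptor$channels[k]
        adapters[[k]] <- list(
            W = matrix(stats::rnorm(ct * cs, sd = sqrt(2 / cs)), ct, cs),
            b = numeric(ct))
    }
    new("AdapterBank", adapters = adapters)
}

#' Apply a stage adapter to a student feature map
#'
#' @param adapters an [AdapterBank-class].
#' @param k stage index 1..4.
#' @param feat array (channels, height, width, batch).
#' @return Array with the teacher's channel count.
#' @export
applyAdapter <- function(adapters, k, feat) {
    stopifnot(is(adapters, "AdapterBank"), k %in% 1:4)
    A <- adapters@adapters[[k]]$W
    b <- adapters@adapters[[k]]$b
    d <- dim(feat)
    if (ncol(A) != d[1])
        stop("adapter ", k, " expects ", ncol(A), " channels, got ", d[1])
    m <- A %*% matrix(feat, d[1]) + b
    array(m, dim = c(nrow(A), d[2], d[3], d[4]))
}

#' Predict class indices
#'
#' Softmax argmax per image; ties are broken toward the lowest class index.
#' (The argmax is invariant to any positive rescaling of the logits, so the
#' inference temperature is irrelevant.)
#'
#' @param model a [StagedBackbone-class].
#' @param images input array (channels, height, width, batch).
#' @return Integer vector of 1-based class indices.
#' @export
predictClasses <- function(model, images) {
    logits <- forwardWithFeatures(model, images)$logits
    max.col(logits, ties.method = "first")
}

#' Save / load a model checkpoint
#'
#' Checkpoints are RDS files (R's standard serialization) holding the
#' student, optional adapters, and the training configuration.
#'
#' @param model a [StagedBackbone-class].
#' @param path file path ending in .rds.
#' @param adapters optional [AdapterBank-class].
#' @param config optional [DistillConfig-class].
#' @return `saveCheckpoint` returns `path` invisibly; `loadCheckpoint`
#'   returns a list with `model`, `adapters`, `config`.
#' @export
saveCheckpoint <- function(model, path, adapters = NULL, config = NULL) {
    stopifnot(is(model, "StagedBackbone"))
    saveRDS(list(model = model, adapters = adapters, config = config), path)
    invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
    if (!file.exists(path)) stop("checkpoint not found: ", path)
    readRDS(path)
}

## flatten all trainable parameters into an indexed registry so a generic
## AdamW step can walk student + adapters uniformly
.paramRegistry <- function(model, adapters = NULL, headOnly = FALSE) {
    reg <- list()
    if (!headOnly) {
        for (k in 1:4) for (i in seq_along(model@stages[[k]]))
            if (model@stages[[k]][[i]]$type == "conv") {
                reg[[length(reg) + 1]] <- list(where = "stage", k = k, i = i,
                                               name = "W", decay = TRUE)
                reg[[length(reg) + 1]] <- list(where = "stage", k = k, i = i,
                                               name = "b", decay = FALSE)
            }
    }
    reg[[length(reg) + 1]] <- list(where = "head", name = "W", decay = TRUE)
    reg[[length(reg) + 1]] <- list(where = "head", name = "b", decay = FALSE)
    if (!is.null(adapters))
        for (k in 1:4) {
            reg[[length(reg) + 1]] <- list(where = "adapter", k = k,
                                           name = "W", decay = TRUE)
            reg[[length(reg) + 1]] <- list(where = "adapter", k = k,
                                           name = "b", decay = FALSE)
        }
    reg
}

.getParam <- function(model, adapters, e) {
    switch(e$where,
           stage = model@stages[[e$k]][[e$i]][[e$name]],
           head = model@head[[e$name]],
           adapter = adapters@adapters[[e$k]][[e$name]])
}

.setParam <- function(model, adapters, e, value) {
    switch(e$where,
           stage = model@stages[[e$k]][[e$i]][[e$name]] <- value,
           head = model@head[[e$name]] <- value,
           adapter = adapters@adapters[[e$k]][[e$name]] <- value)
    list(model = model, adapters = adapters)
}

.getGrad <- function(grads, adapterGrads, e) {
    switch(e$where,
           stage = grads$stages[[e$k]][[e$i]][[paste0("d", e$name)]],
           head = grads$head[[paste0("d", e$name)]],
           adapter = adapterGrads[[e$k]][[paste0("d", e$name)]])
}

## collect every parameter of a model (and optional adapters) into one
## numeric vector; used for the frozen-teacher bitwise check
#' Concatenate all parameters of a model into one vector
#'
#' Useful for checking that a teacher is bitwise untouched by training.
#'
#' @param model a [StagedBackbone-class].
#' @param adapters optional [AdapterBank-class] appended at the end.
#' @return Numeric vector of all parameter values.
#' @export
parameterVector <- function(model, adapters = NULL) {
    reg <- .paramRegistry(model, adapters)
    unlist(lapply(reg, function(e) as.numeric(.getParam(model, adapters, e))))
}
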