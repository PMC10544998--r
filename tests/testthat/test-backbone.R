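test_that("staged forward reproduces the unpartitioned forward bitwise", {
    set.seed(1)
    for (seed in c(1L, 2L)) {
        net <- miniatureBackbone(c(4, 8, 12, 16), nClasses = 5, seed = seed)
        sb <- partitionBackbone(net)
        x <- array(rnorm(3 * 32 * 32 * 2), dim = c(3, 32, 32, 2))
        expect_identical(flatForward(net, x), forwardWithFeatures(sb, x)$logits)
    }
})

test_that("partitioning validates its boundaries", {
    net <- miniatureBackbone(seed = 1)
    expect_error(partitionBackbone(net, c("s1_mix", "s2_mix", "s4_mix")),
                 "exactly 4")
    expect_error(partitionBackbone(net, c("s1_mix", "s2_mix", "s3_mix",
                                          "s4_mix", "s4_down")), "exactly 4")
    expect_error(partitionBackbone(net, c("s1_mix", "s2_mix", "nope",
                                          "s4_mix")), "unknown block")
    expect_error(partitionBackbone(net, c("s2_mix", "s1_mix", "s3_mix",
                                          "s4_mix")), "increasing")
    expect_error(partitionBackbone(net, c("s1_mix", "s2_mix", "s3_mix",
                                          "s4_down")), "final block")
})

test_that("stage descriptor reports the configured widths and 4/8/16/32 schedule", {
    sb <- partitionBackbone(miniatureBackbone(c(16, 32, 64, 128), seed = 1))
    d <- stageDescriptor(sb)
    expect_equal(d$channels, c(16, 32, 64, 128))
    expect_equal(d$downsample, c(4, 8, 16, 32))
    fw <- forwardWithFeatures(sb, array(0, dim = c(3, 64, 64, 2)))
    dims <- vapply(fw$features, dim, numeric(4))
    expect_equal(dims[1, ], c(16, 32, 64, 128))
    expect_equal(dims[2, ], 64 / c(4, 8, 16, 32))
    expect_equal(dims[4, ], rep(2, 4))
})

test_that("captured stage features equal an independent truncated forward", {
    sb <- tinyStudent(seed = 4)
    x <- array(rnorm(3 * 32 * 32 * 2), dim = c(3, 32, 32, 2))
    fw <- forwardWithFeatures(sb, x)
    run <- x
    for (k in 1:4) {
        run <- kdistill:::.blockForward(sb@stages[[k]], run)$y
        expect_identical(fw$features[[k]], run)
    }
    ## logits equal head applied to the stage-4 output
    expect_identical(fw$logits, t(kdistill:::headForward(run, sb@head)$y))
})

test_that("adapter construction reads descriptors and is seed-deterministic", {
    s <- partitionBackbone(miniatureBackbone(c(16, 32, 64, 128), seed = 1))
    t <- partitionBackbone(miniatureBackbone(c(24, 48, 96, 192), seed = 2))
    ad <- buildAdapters(s, t, seed = 9)
    for (k in 1:4) {
        expect_equal(dim(ad@adapters[[k]]$W),
                     c(c(24, 48, 96, 192)[k], c(16, 32, 64, 128)[k]))
        expect_equal(length(ad@adapters[[k]]$b), c(24, 48, 96, 192)[k])
    }
    ad2 <- buildAdapters(s, t, seed = 9)
    expect_identical(ad@adapters, ad2@adapters)
    ad3 <- buildAdapters(s, t, seed = 10)
    expect_false(identical(ad@adapters, ad3@adapters))
    ## equal channel counts still yield learnable (non-identity) adapters
    adEq <- buildAdapters(s, s, seed = 1)
    expect_equal(dim(adEq@adapters[[1]]$W), c(16, 16))
    expect_false(isTRUE(all.equal(adEq@adapters[[1]]$W, diag(16))))
})

test_that("prediction takes the argmax with lowest-index tie-breaking", {
    sb <- tinyStudent(seed = 6)
    ## zero the head weights so logits equal the bias for every image:
    ## classes 2 and 3 tie at the maximum -> class 2 must win
    sb@head$W[] <- 0
    sb@head$b <- c(0, 3, 3, 1, 0)
    x <- array(rnorm(3 * 32 * 32 * 3), dim = c(3, 32, 32, 3))
    expect_equal(predictClasses(sb, x), rep(2L, 3))
    ## argmax is invariant to positive rescaling of the logits
    sb@head$b <- c(0.1, 0.9, 0.2, 0.1, 0.1)
    p1 <- predictClasses(sb, x)
    sb@head$b <- 10 * sb@head$b
    expect_equal(predictClasses(sb, x), p1)
    expect_equal(p1, rep(2L, 3))
})

test_that("checkpoints round-trip through RDS", {
    sb <- tinyStudent(seed = 8)
    ad <- buildAdapters(sb, tinyTeacher(seed = 9), seed = 1)
    path <- tempfile(fileext = ".rds")
    saveCheckpoint(sb, path, adapters = ad, config = DistillConfig())
    ck <- loadCheckpoint(path)
    expect_identical(parameterVector(ck$model, ck$adapters),
                     parameterVector(sb, ad))
    expect_error(loadCheckpoint(tempfile()), "not found")
})

test_that("model gradients match finite differences end to end", {
    set.seed(15)
    sb <- partitionBackbone(miniatureBackbone(c(2, 3, 4, 5), seed = 3))
    x <- array(rnorm(3 * 32 * 32 * 2), dim = c(3, 32, 32, 2))
    y <- c(2L, 5L)
    fpars <- FocalParams(2, rep(1, 5))
    lossAt <- function(model) {
        p <- temperedSoftmax(forwardWithFeatures(model, x)$logits, 1)
        as.numeric(focalLoss(p, y, fpars))
    }
    fwd <- kdistill:::.stagedForwardTrain(sb, x)
    p0 <- temperedSoftmax(fwd$logits, 1)
    l3 <- focalLoss(p0, y, fpars, grad = TRUE)
    dl <- kdistill:::.probGradToLogits(attr(l3, "gradient"), p0)
    g <- kdistill:::.stagedBackward(sb, fwd, dl, NULL)
    eps <- 1e-5
    for (k in 1:4) {
        ii <- which(vapply(sb@stages[[k]], function(l) l$type == "conv",
                           logical(1)))[1]
        for (j in sample(length(sb@stages[[k]][[ii]]$W), 3)) {
            mp <- sb; mp@stages[[k]][[ii]]$W[j] <-
                sb@stages[[k]][[ii]]$W[j] + eps
            mm <- sb; mm@stages[[k]][[ii]]$W[j] <-
                sb@stages[[k]][[ii]]$W[j] - eps
            num <- (lossAt(mp) - lossAt(mm)) / (2 * eps)
            expect_lt(maxRelErr(g$stages[[k]][[ii]]$dW[j], num), 1e-3)
        }
    }
})
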