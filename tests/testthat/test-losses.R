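test_that("tempered softmax matches direct evaluation and is symmetric", {
    expect_equal(temperedSoftmax(c(3, 3, 3), 2.5), rep(1 / 3, 3))
    expect_equal(temperedSoftmax(c(1, 2, 3), 1),
                 c(0.09003057, 0.24472847, 0.66524096), tolerance = 1e-6)
    expect_equal(temperedSoftmax(c(1, 2, 3), 2),
                 c(0.18632372, 0.30719589, 0.50648039), tolerance = 1e-6)
    expect_error(temperedSoftmax(c(1, 2), 0), "positive")
    expect_error(temperedSoftmax(c(1, NaN), 1), "finite")
})

test_that("tempered softmax sums to 1 and its entropy grows with T", {
    set.seed(101)
    for (i in 1:100) {
        z <- rnorm(5, sd = runif(1, 0.1, 10))
        temps <- c(1, 2, 4, 8)
        for (Tv in c(temps, 1e4))
            expect_equal(sum(temperedSoftmax(z, Tv)), 1, tolerance = 1e-6)
        ent <- vapply(temps, function(Tv)
            shannonEntropy(temperedSoftmax(z, Tv)), numeric(1))
        expect_true(all(diff(ent) >= -1e-12))
    }
})

test_that("soft-target loss reproduces worked values and the Gibbs bound", {
    expect_equal(as.numeric(softTargetLoss(c(0, 0), c(0, 0), 1)), log(2),
                 tolerance = 1e-10)
    expect_equal(as.numeric(softTargetLoss(c(0, 10), c(10, 0), 1)), 10,
                 tolerance = 1e-2)
    set.seed(7)
    for (i in 1:50) {
        zt <- matrix(rnorm(4 * 5, sd = 3), 4, 5)
        zs <- matrix(rnorm(4 * 5, sd = 3), 4, 5)
        Tv <- runif(1, 0.5, 8)
        lo <- as.numeric(softTargetLoss(zs, zt, Tv))
        entT <- mean(shannonEntropy(temperedSoftmax(zt, Tv)))
        expect_gte(lo, entT - 1e-10)
        ## equality iff the student logits are a per-sample shift of the
        ## teacher's
        shift <- zt + rnorm(4)   # per-sample constant offset
        expect_equal(as.numeric(softTargetLoss(shift, zt, Tv)), entT,
                     tolerance = 1e-8)
    }
    expect_error(softTargetLoss(matrix(0, 2, 3), matrix(0, 2, 4)),
                 "identical shape")
})

test_that("T^2 rescaling flag scales the soft-target loss and gradient", {
    zs <- matrix(rnorm(10), 2, 5); zt <- matrix(rnorm(10), 2, 5)
    l0 <- softTargetLoss(zs, zt, 4, grad = TRUE)
    l2 <- softTargetLoss(zs, zt, 4, tsquare = TRUE, grad = TRUE)
    expect_equal(as.numeric(l2), 16 * as.numeric(l0), tolerance = 1e-12)
    expect_equal(attr(l2, "gradient"), 16 * attr(l0, "gradient"),
                 tolerance = 1e-12)
})

test_that("focal loss worked examples and limiting cases hold", {
    ## gamma = 0, unit weight: plain cross-entropy
    expect_equal(as.numeric(focalLoss(matrix(c(0.5, 0.5), 1), 1L,
                                      FocalParams(0, c(1, 1)))),
                 log(2), tolerance = 1e-10)
    ## direct evaluation: 0.25 * (1-0.9)^2 * -log(0.9)
    expect_equal(as.numeric(focalLoss(matrix(c(0.9, 0.1), 1), 1L,
                                      FocalParams(2, c(0.25, 1)))),
                 2.634013e-4, tolerance = 1e-6)
    ## perfect prediction: zero for any parameters
    expect_equal(as.numeric(focalLoss(matrix(c(1, 0), 1), 1L,
                                      FocalParams(3.7, c(5, 1)))), 0)
    expect_error(focalLoss(matrix(c(0.5, 0.5), 1), 3L, FocalParams(2, c(1, 1))),
                 "out of range")
})

test_that("focal loss with gamma 0 equals cross-entropy on random batches", {
    set.seed(21)
    for (i in 1:20) {
        p <- matrix(runif(8 * 5, 0.01, 1), 8, 5)
        p <- p / rowSums(p)
        y <- sample(5, 8, replace = TRUE)
        ce <- -mean(log(p[cbind(1:8, y)]))
        expect_equal(as.numeric(focalLoss(p, y, FocalParams(0, rep(1, 5)))),
                     ce, tolerance = 1e-8)
    }
})

test_that("focal loss is strictly decreasing in the true-class probability", {
    pts <- seq(0.05, 0.95, by = 0.05)
    vals <- vapply(pts, function(pt)
        as.numeric(focalLoss(matrix(c(pt, 1 - pt), 1), 1L,
                             FocalParams(2, c(1, 1)))), numeric(1))
    expect_true(all(diff(vals) < 0))
})

test_that("feature-matching loss: identity, hand example, homogeneity", {
    set.seed(3)
    fp <- randomFeaturePair()
    ## make adapted student equal teacher at every stage -> loss 0
    tf <- lapply(1:4, function(k)
        applyAdapter(fp$adapters, k, fp$student[[k]]))
    expect_equal(featureMatchLoss(fp$student, tf, fp$adapters), 0,
                 tolerance = 1e-12)
    ## hand example: one 1x1x2x2 stage off by 1 everywhere, rest identical
    idAd <- new("AdapterBank", adapters = replicate(4, list(
        W = matrix(1, 1, 1), b = 0), simplify = FALSE))
    sf <- replicate(4, array(0, dim = c(1, 2, 2, 1)), simplify = FALSE)
    tf2 <- sf
    sf[[1]] <- array(1, dim = c(1, 2, 2, 1))
    expect_equal(featureMatchLoss(sf, tf2, idAd), 0.25, tolerance = 1e-12)
    ## quadratic homogeneity: scaling the difference by c scales loss by c^2
    l1 <- featureMatchLoss(sf, tf2, idAd)
    sf3 <- lapply(sf, function(x) 3 * x)
    expect_equal(featureMatchLoss(sf3, tf2, idAd), 9 * l1, tolerance = 1e-12)
    expect_error(featureMatchLoss(sf[1:3], tf2, idAd), "4 stage")
})

test_that("feature-matching loss resizes mismatched stages bilinearly", {
    set.seed(9)
    fp <- randomFeaturePair()
    ## shrink the teacher's stage-1 spatial size: loss must still evaluate,
    ## and downscaling a spatially constant map must be lossless
    fp$teacher[[1]] <- array(rnorm(3 * 4 * 4 * 2), dim = c(3, 4, 4, 2))
    l <- featureMatchLoss(fp$student, fp$teacher, fp$adapters)
    expect_true(is.finite(l) && l > 0)
    ## constant-map invariance: adapted student constant c, teacher constant
    ## c at a different size -> exactly zero
    sfc <- replicate(4, array(2, dim = c(1, 4, 4, 1)), simplify = FALSE)
    tfc <- replicate(4, array(2, dim = c(1, 2, 2, 1)), simplify = FALSE)
    idAd <- new("AdapterBank", adapters = replicate(4, list(
        W = matrix(1, 1, 1), b = 0), simplify = FALSE))
    expect_equal(featureMatchLoss(sfc, tfc, idAd), 0, tolerance = 1e-12)
})

test_that("all losses agree with independent scalar-loop oracles", {
    set.seed(42)
    for (i in 1:100) {
        n <- sample(1:8, 1)
        Tv <- runif(1, 0.5, 8)
        z <- rnorm(5, sd = 4)
        expect_lt(max(abs(temperedSoftmax(z, Tv) - oracleSoftmax(z, Tv))),
                  1e-6)
        zs <- matrix(rnorm(n * 5, sd = 3), n, 5)
        zt <- matrix(rnorm(n * 5, sd = 3), n, 5)
        expect_equal(as.numeric(softTargetLoss(zs, zt, Tv)),
                     oracleSoftTarget(zs, zt, Tv), tolerance = 1e-6)
        p <- matrix(runif(n * 5, 1e-3, 1), n, 5); p <- p / rowSums(p)
        y <- sample(5, n, replace = TRUE)
        g <- runif(1, 0, 4); w <- runif(5, 0.2, 5)
        expect_equal(as.numeric(focalLoss(p, y, FocalParams(g, w))),
                     oracleFocal(p, y, g, w), tolerance = 1e-6)
    }
    set.seed(43)
    for (i in 1:20) {
        fp <- randomFeaturePair(batch = sample(1:3, 1))
        expect_equal(featureMatchLoss(fp$student, fp$teacher, fp$adapters),
                     oracleFeatureMatch(fp$student, fp$teacher,
                                        fp$adapterList),
                     tolerance = 1e-6)
    }
    expect_equal(totalLoss(2, 4, 1, LossWeights(alpha = 0.5, beta = 1)), 4)
    expect_equal(totalLoss(2, 4, 1, LossWeights(alpha = 1, beta = 0)), 2)
    expect_equal(totalLoss(2, 4, 1, LossWeights(alpha = 0, beta = 0)), 4)
})

test_that("analytic loss gradients match central finite differences", {
    set.seed(77)
    ## soft-target loss wrt student logits; teacher side carries no gradient
    zs <- matrix(rnorm(3 * 5), 3, 5); zt <- matrix(rnorm(3 * 5), 3, 5)
    Tv <- 3
    l <- softTargetLoss(zs, zt, Tv, grad = TRUE)
    num <- numericGradient(function(v)
        as.numeric(softTargetLoss(matrix(v, 3, 5), zt, Tv)), as.numeric(zs))
    expect_lt(maxRelErr(as.numeric(attr(l, "gradient")), num), 1e-4)
    expect_named(attributes(l), c("gradient"))
    ## focal loss wrt probabilities
    p <- matrix(runif(4 * 5, 0.05, 1), 4, 5); p <- p / rowSums(p)
    y <- c(1L, 3L, 5L, 2L)
    fpars <- FocalParams(2, runif(5, 0.5, 3))
    lf <- focalLoss(p, y, fpars, grad = TRUE)
    numf <- numericGradient(function(v)
        as.numeric(focalLoss(matrix(v, 4, 5), y, fpars)), as.numeric(p))
    expect_lt(maxRelErr(as.numeric(attr(lf, "gradient")), numf), 1e-4)
    ## feature-matching loss wrt student features and adapter weights,
    ## including a stage that needs bilinear resizing
    fp <- randomFeaturePair(batch = 2L)
    fp$teacher[[2]] <- array(rnorm(4 * 3 * 3 * 2), dim = c(4, 3, 3, 2))
    lm <- featureMatchLoss(fp$student, fp$teacher, fp$adapters, grad = TRUE)
    gr <- attr(lm, "gradient")
    for (k in c(1, 2)) {
        numk <- numericGradient(function(v) {
            sf <- fp$student
            sf[[k]] <- array(v, dim = dim(fp$student[[k]]))
            featureMatchLoss(sf, fp$teacher, fp$adapters)
        }, as.numeric(fp$student[[k]]))
        expect_lt(maxRelErr(as.numeric(gr$features[[k]]), numk), 1e-4)
        numA <- numericGradient(function(v) {
            ad <- fp$adapters
            ad@adapters[[k]]$W <- matrix(v, nrow(ad@adapters[[k]]$W))
            featureMatchLoss(fp$student, fp$teacher, ad)
        }, as.numeric(fp$adapters@adapters[[k]]$W))
        expect_lt(maxRelErr(as.numeric(gr$adapters[[k]]$dW), numA), 1e-4)
    }
})
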