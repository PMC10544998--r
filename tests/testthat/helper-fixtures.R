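## Programmatic fixtures: tiny image trees, miniature backbones and small
## in-memory datasets, all generated at test time.

fiveClasses <- c("Grade1", "Grade2", "Grade3", "AIS", "MIA")

## write a tiny class-per-subfolder image tree; counts named by class
writeImageTree <- function(dir, counts, size = 8L) {
    for (cls in names(counts)) {
        d <- file.path(dir, cls)
        dir.create(d, recursive = TRUE, showWarnings = FALSE)
        for (i in seq_len(counts[[cls]])) {
            img <- array(runif(size * size * 3), dim = c(size, size, 3))
            png::writePNG(img, file.path(d, sprintf("%s_%03d.png", cls, i)))
        }
    }
    dir
}

## manifest with the reference cohort's per-class totals (paths are
## placeholders; splitting never touches the files)
table1Manifest <- function() {
    counts <- c(Grade1 = 41, Grade2 = 1317, Grade3 = 196, AIS = 121,
                MIA = 546)
    DatasetManifest(
        data.frame(path = sprintf("img_%04d.png", seq_len(sum(counts))),
                   label = rep(names(counts), counts)),
        classes = names(counts))
}

## small backbone pair for engine tests (32x32 inputs keep them fast)
tinyStudent <- function(seed = 1L, nClasses = 5L)
    partitionBackbone(miniatureBackbone(c(4L, 8L, 12L, 16L),
                                        nClasses = nClasses, seed = seed))

tinyTeacher <- function(seed = 2L, nClasses = 5L)
    partitionBackbone(miniatureBackbone(c(6L, 10L, 14L, 20L),
                                        nClasses = nClasses, seed = seed))

## balanced 5-class synthetic dataset at 32x32, loaded into tensors once
tinyTrainingData <- local({
    cache <- NULL
    function() {
        if (!is.null(cache)) return(cache)
        dir <- file.path(tempdir(), "kdistill_tiny_ds")
        if (!dir.exists(dir)) {
            cfg <- SyntheticConfig(imageSize = 32L,
                                   classProportions = rep(1, 5),
                                   totalImages = 50L, difficulty = 0,
                                   seed = 11L)
            generateDataset(cfg, dir)
        }
        manifest <- splitDataset(loadManifest(dir), seed = 5L)
        aug <- AugmentConfig(targetSize = 32L)
        all <- kdistill:::.loadAllTensors(manifest, aug)
        cache <<- list(
            manifest = manifest,
            train = kdistill:::.splitTensors(all, manifest, "train"),
            val = kdistill:::.splitTensors(all, manifest, "val"),
            test = kdistill:::.splitTensors(all, manifest, "test"),
            weights = classWeights(classCounts(manifestSplit(manifest,
                                                             "train"))),
            aug = aug)
        cache
    }
})

## random stage feature sets with matching spatial sizes
randomFeaturePair <- function(batch = 2L, sCh = c(2L, 3L, 4L, 5L),
                              tCh = c(3L, 4L, 5L, 6L), sizes = c(8, 4, 2, 1)) {
    sf <- list(); tf <- list(); ad <- list()
    for (k in 1:4) {
        sf[[k]] <- array(rnorm(sCh[k] * sizes[k]^2 * batch),
                         dim = c(sCh[k], sizes[k], sizes[k], batch))
        tf[[k]] <- array(rnorm(tCh[k] * sizes[k]^2 * batch),
                         dim = c(tCh[k], sizes[k], sizes[k], batch))
        ad[[k]] <- list(W = matrix(rnorm(tCh[k] * sCh[k]), tCh[k], sCh[k]),
                        b = rnorm(tCh[k]))
    }
    list(student = sf, teacher = tf,
         adapters = new("AdapterBank", adapters = ad), adapterList = ad)
}
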