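test_that("confusion matrices count true x predicted pairs", {
    cm <- confusionMatrix(1:5, 1:5, classes = fiveClasses)
    expect_equal(unname(diag(cm@counts)), rep(1L, 5))
    expect_equal(sum(cm@counts), 5)
    set.seed(1)
    tr <- sample(5, 200, replace = TRUE)
    pr <- sample(5, 200, replace = TRUE)
    cm2 <- confusionMatrix(tr, pr, fiveClasses)
    ## marginal conservation: row i sums to #(true == i)
    expect_equal(unname(rowSums(cm2@counts)),
                 as.integer(table(factor(tr, levels = 1:5))))
    expect_error(confusionMatrix(1:3, 1:2, fiveClasses), "equal length")
    expect_error(confusionMatrix(c("a"), c("b"), fiveClasses), "vocabulary")
})

test_that("a single dominant class reproduces the Grade-2 worked example", {
    ## all 122 true Grade-2 images predicted Grade 2, plus 12 false
    ## positives from other classes -> precision 122/134, recall 1
    true <- c(rep("Grade2", 122), rep(c("Grade3", "MIA"), each = 6))
    pred <- rep("Grade2", 134)
    cm <- confusionMatrix(true, pred, fiveClasses)
    expect_equal(cm@counts["Grade2", "Grade2"], 122L)
    rep <- perClassReport(cm)
    g2 <- rep[rep$class == "Grade2", ]
    expect_equal(round(g2$precision, 4), 0.9104)
    expect_equal(g2$recall, 1)
    ## only-one-class case: a single cell holds all 122 counts
    cmOne <- confusionMatrix(rep("Grade2", 122), rep("Grade2", 122),
                             fiveClasses)
    expect_equal(sum(cmOne@counts), 122)
    expect_equal(cmOne@counts["Grade2", "Grade2"], 122L)
})

test_that("metrics agree with a scalar-loop oracle on random matrices", {
    set.seed(12)
    for (i in 1:100) {
        counts <- matrix(rpois(25, 6), 5, 5,
                         dimnames = list(fiveClasses, fiveClasses))
        if (sum(counts) == 0) counts[1, 1] <- 1
        cm <- new("ConfusionMatrix", counts = counts, classes = fiveClasses)
        got <- metricsFromConfusion(cm)
        want <- oracleMetrics(counts)
        expect_equal(got@accuracy, want$accuracy, tolerance = 1e-12)
        expect_equal(got@perClass$precision, unname(want$precision),
                     tolerance = 1e-12)
        expect_equal(got@perClass$recall, unname(want$recall),
                     tolerance = 1e-12)
        expect_equal(got@macroF1, want$macroF1, tolerance = 1e-12)
        expect_equal(got@macroF1Paper, want$macroF1Paper, tolerance = 1e-12)
    }
})

test_that("outputs are invariant to sample order", {
    set.seed(4)
    tr <- sample(5, 120, replace = TRUE)
    pr <- sample(5, 120, replace = TRUE)
    perm <- sample(120)
    m1 <- metricsFromConfusion(confusionMatrix(tr, pr, fiveClasses))
    m2 <- metricsFromConfusion(confusionMatrix(tr[perm], pr[perm],
                                               fiveClasses))
    expect_equal(m1@accuracy, m2@accuracy)
    expect_equal(m1@perClass, m2@perClass)
})

test_that("classes without predictions are zeroed and flagged, not NaN", {
    ## class 5 absent from both truth and predictions
    cm <- confusionMatrix(c(1, 2, 3, 4), c(1, 2, 3, 4), fiveClasses)
    r <- metricsFromConfusion(cm)
    expect_equal(r@nUndefined, 1L)
    mia <- r@perClass[r@perClass$class == "MIA", ]
    expect_equal(mia$precision, 0)
    expect_equal(mia$recall, 0)
    expect_true(mia$undefined)
    expect_true(all(is.finite(c(r@macroPrecision, r@macroRecall,
                                r@macroF1))))
    empty <- new("ConfusionMatrix", counts = matrix(0L, 5, 5),
                 classes = fiveClasses)
    expect_error(metricsFromConfusion(empty), "all zero")
})

test_that("the two macro-F1 variants are both reported and differ in general", {
    counts <- matrix(c(50, 10, 0, 30, 5, 5, 0, 2, 20), 3, 3,
                     dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
    cm <- new("ConfusionMatrix", counts = counts, classes = c("a", "b", "c"))
    r <- metricsFromConfusion(cm)
    expect_false(isTRUE(all.equal(r@macroF1, r@macroF1Paper)))
    expect_equal(r@macroF1Paper,
                 f1FromPrecisionRecall(r@macroPrecision, r@macroRecall))
})

test_that("reports are exported consistently across formats", {
    set.seed(5)
    tr <- sample(5, 80, replace = TRUE)
    pr <- ifelse(runif(80) < 0.7, tr, sample(5, 80, replace = TRUE))
    cm <- confusionMatrix(tr, pr, fiveClasses)
    r <- metricsFromConfusion(cm)
    dir <- file.path(tempdir(), "kdistill_report")
    paths <- writeMetricsReport(r, cm, dir)
    expect_true(all(file.exists(paths)))
    j <- jsonlite::read_json(paths[1])
    expect_equal(j$accuracy, r@accuracy, tolerance = 1e-12)
    cmCsv <- read.csv(paths[3], row.names = 1)
    expect_equal(sum(diag(as.matrix(cmCsv))) / sum(cmCsv), r@accuracy,
                 tolerance = 1e-12)
    ## transposed display swaps the axes
    tc <- printTransposed(cm)
    expect_identical(unname(tc), unname(t(cm@counts)))
})
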