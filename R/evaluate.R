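## Confusion matrix and the macro-averaged metric suite. One-vs-rest
## definitions: per class c, TP = cm[c,c], FP = colsum - TP, FN = rowsum -
## TP; accuracy = trace/total; macro values are unweighted means of the
## per-class values ("calculated first and then averaged").

#' Build a confusion matrix
#'
#' counts[i, j] = number of samples with true class i predicted as class j.
#'
#' @param true,predicted equal-length label vectors (character, factor, or
#'   1-based integer indices into `classes`).
#' @param classes class vocabulary fixing the row/column order.
#' @return A [ConfusionMatrix-class].
#' @examples
#' confusionMatrix(c(1, 2, 2), c(1, 2, 1), classes = c("a", "b"))
#' @export
confusionMatrix <- function(true, predicted, classes) {
    if (length(true) != length(predicted))
        stop("'true' and 'predicted' must have equal length")
    toIdx <- function(x) {
        if (is.numeric(x)) {
            x <- as.integer(x)
            if (any(x < 1L | x > length(classes)))
                stop("integer labels out of range 1..", length(classes))
            x
        } else {
            i <- match(as.character(x), classes)
            if (anyNA(i))
                stop("label(s) outside vocabulary: ",
                     paste(unique(as.character(x)[is.na(i)]), collapse = ", "))
            i
        }
    }
    ti <- toIdx(true); pr <- toIdx(predicted)
    C <- length(classes)
    counts <- matrix(0L, C, C, dimnames = list(true = classes,
                                               predicted = classes))
    for (n in seq_along(ti))
        counts[ti[n], pr[n]] <- counts[ti[n], pr[n]] + 1L
    new("ConfusionMatrix", counts = counts, classes = classes)
}

#' Harmonic mean of precision and recall
#'
#' F1 = 2 P R / (P + R); 0 when both are 0. Applied to macro precision and
#' macro recall this is the "paper-style" macro F1 that reproduces the
#' reference result tables from their printed precision/recall columns.
#'
#' @param precision,recall values in [0,1] (vectorized).
#' @return F1 score(s).
#' @examples
#' f1FromPrecisionRecall(0.7988, 0.7464)  # 0.7717
#' @export
f1FromPrecisionRecall <- function(precision, recall) {
    s <- precision + recall
    ifelse(s > 0, 2 * precision * recall / s, 0)
}

#' Compute the metric suite from a confusion matrix
#'
#' Per class: precision = TP/(TP+FP) (0, flagged, when the class received
#' no predictions), recall = TP/(TP+FN), F1 the harmonic mean. Accuracy =
#' trace/total. Macro values are unweighted means across classes. Two
#' macro-F1 variants are reported: the mean of per-class F1 (`macroF1`)
#' and the harmonic mean of macro precision and macro recall
#' (`macroF1Paper`); they generally differ.
#'
#' @param cm a [ConfusionMatrix-class].
#' @return A [MetricsReport-class].
#' @export
metricsFromConfusion <- function(cm) {
    stopifnot(is(cm, "ConfusionMatrix"))
    m <- cm@counts
    total <- sum(m)
    if (total == 0) stop("confusion matrix is all zero")
    tp <- diag(m)
    fp <- colSums(m) - tp
    fn <- rowSums(m) - tp
    precDen <- tp + fp
    prec <- ifelse(precDen > 0, tp / precDen, 0)
    recDen <- tp + fn
    rec <- ifelse(recDen > 0, tp / recDen, 0)
    f1 <- f1FromPrecisionRecall(prec, rec)
    undef <- precDen == 0
    perClass <- data.frame(class = cm@classes, precision = as.numeric(prec),
                           recall = as.numeric(rec), f1 = as.numeric(f1),
                           support = as.integer(rowSums(m)),
                           undefined = as.logical(undef),
                           row.names = NULL)
    mp <- mean(prec); mr <- mean(rec)
    new("MetricsReport", accuracy = sum(tp) / total,
        macroPrecision = mp, macroRecall = mr,
        macroF1 = mean(f1), macroF1Paper = f1FromPrecisionRecall(mp, mr),
        perClass = perClass, nUndefined = as.integer(sum(undef)))
}

#' Per-class precision/recall report
#'
#' One row per vocabulary class with precision and recall as defined by
#' [metricsFromConfusion()].
#'
#' @param cm a [ConfusionMatrix-class].
#' @return data.frame with columns class, precision, recall, support,
#'   undefined.
#' @export
perClassReport <- function(cm) {
    rep <- metricsFromConfusion(cm)@perClass
    rep[, c("class", "precision", "recall", "support", "undefined")]
}

#' Print a confusion matrix with predicted classes as rows
#'
#' The internal convention is rows = true, columns = predicted; some
#' reports display the transpose. Cosmetic only.
#'
#' @param cm a [ConfusionMatrix-class].
#' @return The transposed counts matrix, invisibly (after printing).
#' @export
printTransposed <- function(cm) {
    stopifnot(is(cm, "ConfusionMatrix"))
    tc <- t(cm@counts)
    names(dimnames(tc)) <- c("predicted", "true")
    print(tc)
    invisible(tc)
}

#' Write an evaluation report to files
#'
#' Emits the metrics as JSON, the per-class table as CSV, and the confusion
#' matrix as CSV.
#'
#' @param report a [MetricsReport-class].
#' @param cm the matching [ConfusionMatrix-class].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix (default "metrics").
#' @return Character vector of the written paths, invisibly.
#' @export
writeMetricsReport <- function(report, cm, dir, prefix = "metrics") {
    stopifnot(is(report, "MetricsReport"), is(cm, "ConfusionMatrix"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    jsonPath <- file.path(dir, paste0(prefix, ".json"))
    jsonlite::write_json(list(
        accuracy = report@accuracy,
        macro_precision = report@macroPrecision,
        macro_recall = report@macroRecall,
        macro_f1 = report@macroF1,
        macro_f1_paper_style = report@macroF1Paper,
        n_undefined = report@nUndefined), jsonPath,
        auto_unbox = TRUE, digits = NA)
    perClassPath <- file.path(dir, paste0(prefix, "_per_class.csv"))
    utils::write.csv(report@perClass, perClassPath, row.names = FALSE)
    cmPath <- file.path(dir, paste0(prefix, "_confusion.csv"))
    utils::write.csv(as.data.frame(cm@counts), cmPath)
    invisible(c(jsonPath, perClassPath, cmPath))
}
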