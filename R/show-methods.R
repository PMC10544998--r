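#' @describeIn DatasetManifest-class compact summary with per-class and
#'   per-split counts.
#' @param object object to display.
#' @export
setMethod("show", "DatasetManifest", function(object) {
    cat("DatasetManifest with", nrow(object@samples), "samples,",
        length(object@classes), "classes\n")
    print(splitCounts(object))
    invisible(NULL)
})

#' @describeIn StagedBackbone-class stage descriptor summary.
#' @param object object to display.
#' @export
setMethod("show", "StagedBackbone", function(object) {
    cat("StagedBackbone:", object@nClasses, "classes,",
        object@inChannels, "input channels\n")
    print(object@descriptor, row.names = FALSE)
    invisible(NULL)
})

#' @describeIn ConfusionMatrix-class prints the counts (rows = true).
#' @param object object to display.
#' @export
setMethod("show", "ConfusionMatrix", function(object) {
    cat("ConfusionMatrix (rows = true, cols = predicted),",
        sum(object@counts), "samples\n")
    print(object@counts)
    invisible(NULL)
})

#' @describeIn MetricsReport-class accuracy, macro metrics and the
#'   per-class table.
#' @param object object to display.
#' @export
setMethod("show", "MetricsReport", function(object) {
    cat(sprintf(
        "MetricsReport: accuracy %.4f | macro P %.4f R %.4f F1 %.4f (paper-style %.4f)\n",
        object@accuracy, object@macroPrecision, object@macroRecall,
        object@macroF1, object@macroF1Paper))
    if (object@nUndefined > 0)
        cat(object@nUndefined, "class(es) with undefined precision\n")
    print(object@perClass, row.names = FALSE, digits = 4)
    invisible(NULL)
})

#' @describeIn TrainingState-class best-epoch summary and history tail.
#' @param object object to display.
#' @export
setMethod("show", "TrainingState", function(object) {
    cat(sprintf(
        "TrainingState: %d epochs, mode '%s'; best val accuracy %.4f at epoch %d\n",
        nrow(object@history), object@config@mode, object@bestValAccuracy,
        object@bestEpoch))
    print(utils::tail(object@history, 3), row.names = FALSE, digits = 4)
    invisible(NULL)
})
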