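## Manifest construction, deterministic stratified 8:1:1 splitting and
## inverse-frequency class weights.

.IMG_EXT <- c("png", "jpg", "jpeg")

.isReadableImage <- function(path) {
    hdr <- tryCatch(readBin(path, "raw", n = 8), error = function(e) raw(0))
    if (length(hdr) < 3) return(FALSE)
    pngMagic <- as.raw(c(0x89, 0x50, 0x4e, 0x47))
    jpgMagic <- as.raw(c(0xff, 0xd8, 0xff))
    identical(hdr[1:4], pngMagic) || identical(hdr[1:3], jpgMagic)
}

#' Construct a DatasetManifest
#'
#' @param samples data.frame with at least `path` and `label`; optional
#'   `lesion_id` and `split` columns are filled with NA/"unassigned".
#' @param classes class vocabulary; defaults to the sorted unique labels.
#' @return A [DatasetManifest-class].
#' @export
DatasetManifest <- function(samples, classes = NULL) {
    samples <- as.data.frame(samples)
    if (is.null(classes)) classes <- sort(unique(as.character(samples$label)))
    if (!"lesion_id" %in% names(samples)) samples$lesion_id <- NA_character_
    if (!"split" %in% names(samples)) samples$split <- "unassigned"
    samples$path <- as.character(samples$path)
    samples$label <- as.character(samples$label)
    samples$lesion_id <- as.character(samples$lesion_id)
    samples$split <- as.character(samples$split)
    new("DatasetManifest",
        samples = samples[, c("path", "label", "lesion_id", "split")],
        classes = as.character(classes))
}

#' Load a dataset manifest from a directory tree or manifest file
#'
#' Directory layout: one subfolder per class containing PNG/JPEG images.
#' Manifest file: delimited text (CSV) with a header row and columns
#' `path,label[,lesion_id,split]`. Images whose header bytes are not a
#' valid PNG/JPEG signature are skipped with a warning reporting the count.
#'
#' @param source directory or manifest file path.
#' @param classes optional class vocabulary (defaults to the subfolder
#'   names / sorted unique labels).
#' @return A [DatasetManifest-class].
#' @export
loadManifest <- function(source, classes = NULL) {
    if (dir.exists(source)) {
        dirs <- list.dirs(source, recursive = FALSE)
        if (!length(dirs)) stop("no class subfolders found in ", source)
        labs <- basename(dirs)
        if (is.null(classes)) classes <- sort(labs)
        unknown <- setdiff(labs, classes)
        if (length(unknown))
            stop("unknown label folder(s): ", paste(unknown, collapse = ", "))
        rows <- lapply(dirs, function(d) {
            files <- list.files(d, full.names = TRUE,
                                pattern = paste0("\\.(",
                                                 paste(.IMG_EXT, collapse = "|"),
                                                 ")$"), ignore.case = TRUE)
            if (!length(files)) return(NULL)
            data.frame(path = files, label = basename(d))
        })
        samples <- do.call(rbind, rows)
        if (is.null(samples) || !nrow(samples))
            stop("empty dataset: no images found under ", source)
        ok <- vapply(samples$path, .isReadableImage, logical(1))
        if (any(!ok))
            warning(sum(!ok), " unreadable image(s) skipped")
        samples <- samples[ok, , drop = FALSE]
        if (!nrow(samples)) stop("empty dataset: no readable images")
        DatasetManifest(samples, classes)
    } else if (file.exists(source)) {
        samples <- utils::read.csv(source, stringsAsFactors = FALSE)
        if (!all(c("path", "label") %in% names(samples)))
            stop("manifest file needs 'path' and 'label' columns (with header)")
        if (!nrow(samples)) stop("empty dataset: manifest has no rows")
        if (is.null(classes)) classes <- sort(unique(samples$label))
        bad <- which(!samples$label %in% classes)
        if (length(bad))
            stop("unknown label(s) in manifest rows: ",
                 paste(utils::head(bad, 10), collapse = ", "))
        DatasetManifest(samples, classes)
    } else stop("no such file or directory: ", source)
}

#' Write a manifest to a delimited file
#'
#' @param manifest a [DatasetManifest-class].
#' @param path output CSV path (UTF-8, header row).
#' @return `path`, invisibly.
#' @export
writeManifest <- function(manifest, path) {
    stopifnot(is(manifest, "DatasetManifest"))
    utils::write.csv(manifest@samples, path, row.names = FALSE)
    invisible(path)
}

#' Per-class and per-split sample counts
#'
#' @param manifest a [DatasetManifest-class].
#' @return `classCounts`: named integer vector in vocabulary order.
#'   `splitCounts`: class x split table of counts.
#' @export
classCounts <- function(manifest) {
    stopifnot(is(manifest, "DatasetManifest"))
    cnt <- table(factor(manifest@samples$label, levels = manifest@classes))
    stats::setNames(as.integer(cnt), manifest@classes)
}

#' @rdname classCounts
#' @export
splitCounts <- function(manifest) {
    stopifnot(is(manifest, "DatasetManifest"))
    table(factor(manifest@samples$label, levels = manifest@classes),
          factor(manifest@samples$split,
                 levels = c("train", "val", "test", "unassigned")))
}

#' Deterministic stratified train/val/test split
#'
#' Within each class, samples are shuffled with the seed and assigned to
#' train/val/test. The training share is rounded to nearest
#' (train_c = round(r_train * n_c)), the rule that reproduces the reference
#' cohort's published per-class training counts; every nonempty class
#' contributes at least one training sample. Of the held-out remainder,
#' validation receives floor(valFraction * n_c) and test the rest. The
#' default valFraction = 0.1065 reproduces the reference cohort's
#' validation/test totals (234/209 on class sizes 41/1317/196/121/546); a
#' class of 10 still splits exactly 8/1/1.
#'
#' With `stratify = FALSE` a single pooled shuffle is cut at the global
#' round(r * N) boundaries instead. When a `lesion_id` column is present
#' and `groupByLesion = TRUE`, all images of a lesion are kept in one split
#' to prevent leakage (assignment then follows the lesion's class).
#'
#' @param manifest a [DatasetManifest-class].
#' @param ratios length-3 positive ratios summing to 1 (default 0.8/0.1/0.1).
#' @param seed integer seed; the assignment is deterministic given it.
#' @param valFraction fraction of each class assigned to validation
#'   (applied as floor(valFraction * n_c)).
#' @param stratify per-class (TRUE, default) or pooled splitting.
#' @param groupByLesion keep all images of a lesion in one split.
#' @return The manifest with the `split` column filled.
#' @export
splitDataset <- function(manifest, ratios = c(0.8, 0.1, 0.1), seed = 1L,
                         valFraction = 0.1065, stratify = TRUE,
                         groupByLesion = FALSE) {
    stopifnot(is(manifest, "DatasetManifest"))
    if (length(ratios) != 3 || any(ratios < 0) ||
        abs(sum(ratios) - 1) > 1e-8)
        stop("'ratios' must be three nonnegative values summing to 1")
    s <- manifest@samples
    set.seed(as.integer(seed))
    assignGroup <- function(n) {
        ## returns a character vector of split tags for n units of one class
        tr <- round(ratios[1] * n)
        if (n >= 1 && tr < 1) tr <- 1
        if (tr > n) tr <- n
        rem <- n - tr
        va <- min(rem, floor(valFraction * n))
        te <- rem - va
        c(rep("train", tr), rep("val", va), rep("test", te))
    }
    if (groupByLesion && any(!is.na(s$lesion_id))) {
        s$split <- NA_character_
        for (cl in manifest@classes) {
            rows <- which(s$label == cl)
            if (!length(rows)) next
            les <- unique(s$lesion_id[rows])
            les <- les[sample.int(length(les))]
            tags <- assignGroup(length(les))
            for (i in seq_along(les))
                s$split[rows[s$lesion_id[rows] == les[i]]] <- tags[i]
        }
    } else if (stratify) {
        s$split <- NA_character_
        for (cl in manifest@classes) {
            rows <- which(s$label == cl)
            if (!length(rows)) next
            rows <- rows[sample.int(length(rows))]
            s$split[rows] <- assignGroup(length(rows))
        }
    } else {
        n <- nrow(s)
        ord <- sample.int(n)
        tr <- round(ratios[1] * n)
        va <- floor(valFraction * n)
        tags <- c(rep("train", tr), rep("val", min(va, n - tr)),
                  rep("test", max(0, n - tr - min(va, n - tr))))
        s$split <- NA_character_
        s$split[ord] <- tags
    }
    DatasetManifest(s, manifest@classes)
}

#' Subset a manifest to one split
#'
#' @param manifest a [DatasetManifest-class].
#' @param split one of "train", "val", "test", "unassigned".
#' @return A [DatasetManifest-class] with only that split's samples.
#' @export
manifestSplit <- function(manifest, split = c("train", "val", "test",
                                              "unassigned")) {
    split <- match.arg(split)
    s <- manifest@samples[manifest@samples$split == split, , drop = FALSE]
    DatasetManifest(s, manifest@classes)
}

#' Inverse-frequency class weights
#'
#' Returns w_c = N / (C * n_c) normalized to mean 1 across classes, the
#' default per-class alpha_t weights of the focal loss: rare classes get
#' proportionally larger weight, and w_c * n_c is constant across classes.
#'
#' @param manifest a [DatasetManifest-class], or a numeric vector of class
#'   counts.
#' @return Named numeric weight vector with mean 1.
#' @examples
#' classWeights(c(a = 10, b = 10, c = 10))  # all 1
#' @export
classWeights <- function(manifest) {
    counts <- if (is(manifest, "DatasetManifest")) classCounts(manifest)
              else manifest
    if (any(counts <= 0))
        stop("every class must have at least one sample; empty: ",
             paste(names(counts)[counts <= 0], collapse = ", "))
    w <- 1 / counts
    w <- w / mean(w)
    w
}
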