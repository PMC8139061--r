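#' Construct an AsvExperiment
#'
#' @param counts integer matrix of read counts, ASVs as rows and samples as
#'   columns, with unique dimnames.
#' @param sampleData data.frame or DataFrame of per-sample metadata, one row
#'   per column of \code{counts} (same order or matching rownames).
#' @param sequences optional named character vector or [Biostrings::DNAStringSet]
#'   of ASV sequences; stored in \code{rowData(x)$sequence} after
#'   normalization (uppercase, U to T).
#'
#' @return a validated [AsvExperiment-class] object.
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L, 1L, 9L), nrow = 3,
#'             dimnames = list(paste0("ASV", 1:3), c("s1", "s2")))
#' ae <- AsvExperiment(m)
#' sampleDepth(ae)
#' @export
AsvExperiment <- function(counts, sampleData = NULL, sequences = NULL) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("counts need ASV and sample ids as dimnames")
    storage.mode(counts) <- "integer"
    if (is.null(sampleData))
        sampleData <- DataFrame(row.names = colnames(counts))
    else {
        sampleData <- as(sampleData, "DataFrame")
        if (!is.null(rownames(sampleData)) &&
            !identical(rownames(sampleData), colnames(counts))) {
            if (!all(colnames(counts) %in% rownames(sampleData)))
                stop("sampleData rownames do not cover all sample ids")
            sampleData <- sampleData[colnames(counts), , drop = FALSE]
        }
    }
    se <- SummarizedExperiment(assays = SimpleList(counts = counts),
                               colData = sampleData)
    obj <- new("AsvExperiment", se)
    if (!is.null(sequences)) asvSequences(obj) <- sequences
    obj
}

#' @describeIn AsvExperiment read counts (ASVs x samples)
#' @param object,x an AsvExperiment
#' @export
setMethod("counts", "AsvExperiment", function(object) assay(object, "counts"))

#' Per-sample sequencing depth
#'
#' Column sums of the count assay. Every sample in a valid experiment used
#' for relative-abundance work must have depth > 0.
#' @param x an AsvExperiment
#' @return named integer vector, one entry per sample.
#' @export
setMethod("sampleDepth", "AsvExperiment", function(x) colSums(counts(x)))

#' Relative abundances
#'
#' Counts divided by per-sample depth, so each sample (column) sums to 1.
#' This is the within-sample proportion basis used throughout the community
#' statistics and the percentile-threshold source partitioner.
#'
#' @param x an AsvExperiment (or a counts matrix, taxa x samples).
#' @param ... unused.
#' @return numeric matrix, same dimensions and dimnames as the counts, each
#'   column summing to 1.
#' @examples
#' m <- matrix(c(1L, 2L, 1L), ncol = 1,
#'             dimnames = list(paste0("a", 1:3), "s1"))
#' relAbund(AsvExperiment(m))[, 1]   # 0.25 0.50 0.25
#' @export
setMethod("relAbund", "AsvExperiment", function(x, ...)
    relAbund(counts(x)))

#' @rdname relAbund-AsvExperiment-method
#' @export
setMethod("relAbund", "matrix", function(x, ...) {
    depth <- colSums(x)
    if (any(depth <= 0))
        stop("zero-depth sample(s): ",
             paste(colnames(x)[depth <= 0], collapse = ", "))
    sweep(x, 2L, depth, "/")
})

#' ASV sequences stored on an experiment
#' @param x an AsvExperiment
#' @return a [Biostrings::DNAStringSet] named by ASV id, or NULL if absent.
#' @export
setMethod("asvSequences", "AsvExperiment", function(x) {
    if (!"sequence" %in% colnames(rowData(x))) return(NULL)
    DNAStringSet(structure(rowData(x)$sequence, names = rownames(x)))
})

#' @rdname asvSequences-AsvExperiment-method
#' @param value named character vector or DNAStringSet covering all ASV ids
#' @export
setReplaceMethod("asvSequences", "AsvExperiment", function(x, value) {
    nm <- names(value)
    value <- vapply(as.character(value), normalizeSequence, character(1),
                    USE.NAMES = FALSE)
    names(value) <- nm
    if (is.null(names(value)) || !all(rownames(x) %in% names(value)))
        stop("sequences must be named and cover every ASV id")
    rowData(x)$sequence <- unname(value[rownames(x)])
    validObject(x)
    x
})

setMethod("show", "AsvExperiment", function(object) {
    cat("AsvExperiment:", nrow(object), "ASVs x", ncol(object), "samples\n")
    cat("  depth:", paste(range(sampleDepth(object)), collapse = "-"), "\n")
    if ("sequence" %in% colnames(rowData(object)))
        cat("  sequences: lengths",
            paste(range(nchar(rowData(object)$sequence)), collapse = "-"), "\n")
    if (ncol(colData(object)))
        cat("  sample metadata:", paste(colnames(colData(object)),
                                        collapse = ", "), "\n")
})
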