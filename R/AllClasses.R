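#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData rowData<- colData<-
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet width
NULL

#' ASV count experiment
#'
#' Container for a samples-by-ASVs amplicon survey, stored Bioconductor-style
#' with ASVs as rows and samples as columns. The \code{"counts"} assay holds
#' non-negative integer read counts; sample metadata (collection date, site,
#' wastewater temperature, chemistry, marker concentrations) lives in
#' \code{colData}, and per-ASV information (nucleotide sequence, ground-truth
#' labels for simulated data) in \code{rowData}.
#'
#' Validity requires unique ASV and sample identifiers, at least one of each,
#' and counts that are non-negative whole numbers.
#'
#' @seealso [AsvExperiment()] for construction, [relAbund()],
#'   [sampleDepth()], [asvSequences()]
#' @export
setClass("AsvExperiment", contains = "SummarizedExperiment")

setValidity("AsvExperiment", function(object) {
    msg <- NULL
    if (nrow(object) < 1L || ncol(object) < 1L)
        msg <- c(msg, "need at least 1 ASV and 1 sample")
    if (!"counts" %in% names(assays(object)))
        msg <- c(msg, "assay 'counts' is required")
    else {
        m <- assay(object, "counts")
        if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
            msg <- c(msg, "counts must be non-negative whole numbers")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "ASV ids must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be present and unique")
    if (is.null(msg)) TRUE else msg
})

#' Reduced human-microbiome reference set
#'
#' Dereplicated reference sequences with the metadata needed by the source
#' partitioner: per-sequence occurrence counts, subject and sample id sets,
#' body-site occurrence tallies, and a per-sequence relative-abundance matrix
#' across reference samples (zeros where a sequence is absent from a sample).
#' Sequences are normalized (uppercase, U converted to T) and unique.
#'
#' @slot sequences character vector of normalized, unique sequences.
#' @slot occurrence integer occurrence count per sequence (>= the reduction
#'   threshold used at construction).
#' @slot subjectIds,sampleIds lists of id sets per sequence.
#' @slot bodySiteCounts list of named integer vectors tallying raw body-site
#'   labels per sequence.
#' @slot refAbund numeric matrix, sequences x reference samples, each column
#'   summing to 1: within-reference-sample relative abundances.
#' @seealso [buildReducedReference()]
#' @export
setClass("ReferenceSet", representation(
    sequences = "character",
    occurrence = "integer",
    subjectIds = "list",
    sampleIds = "list",
    bodySiteCounts = "list",
    refAbund = "matrix"
))

setValidity("ReferenceSet", function(object) {
    msg <- NULL
    n <- length(object@sequences)
    if (n < 1L) msg <- c(msg, "reference set is empty")
    if (anyDuplicated(object@sequences))
        msg <- c(msg, "sequences must be unique after normalization")
    if (length(object@occurrence) != n || any(object@occurrence < 1L))
        msg <- c(msg, "each sequence needs an occurrence count >= 1")
    if (length(object@subjectIds) != n || length(object@sampleIds) != n ||
        length(object@bodySiteCounts) != n)
        msg <- c(msg, "metadata lists must parallel the sequences")
    if (n >= 1L && (any(lengths(object@subjectIds) < 1L) ||
                    any(lengths(object@sampleIds) < 1L)))
        msg <- c(msg, "each retained record needs >= 1 subject and sample id")
    if (nrow(object@refAbund) != n)
        msg <- c(msg, "refAbund must have one row per sequence")
    if (is.null(msg)) TRUE else msg
})

#' Human/sewer source partition of an ASV table
#'
#' One row per ASV of the wastewater table: final source label
#' (\code{"human"} or \code{"sewer"}), whether the ASV matched the reference
#' by exact sequence identity, whether a matched ASV was reclassified to
#' sewer by the percentile rule, the body-site bin (majority bin for human
#' ASVs, \code{NA} otherwise), and the two percentile values compared.
#'
#' Invariants: every ASV is labeled exactly once; \code{reclassified} implies
#' \code{matched}; unmatched ASVs are labeled sewer.
#'
#' @slot table a [S4Vectors::DataFrame] with columns \code{asv_id},
#'   \code{label}, \code{matched}, \code{reclassified}, \code{body_site},
#'   \code{ww_qlow}, \code{ref_qhigh}, \code{ref_index}.
#' @slot qLow,qHigh the percentiles used (defaults 5 and 95).
#' @seealso [partitionSources()], [humanFraction()], [binBodySites()]
#' @export
setClass("PartitionResult", representation(
    table = "DataFrame", qLow = "numeric", qHigh = "numeric"
))

setValidity("PartitionResult", function(object) {
    msg <- NULL
    tb <- object@table
    need <- c("asv_id", "label", "matched", "reclassified", "body_site",
              "ww_qlow", "ref_qhigh", "ref_index")
    if (!all(need %in% colnames(tb)))
        msg <- c(msg, "partition table is missing required columns")
    else {
        if (anyDuplicated(tb$asv_id)) msg <- c(msg, "duplicate ASV ids")
        if (!all(tb$label %in% c("human", "sewer")))
            msg <- c(msg, "labels must be 'human' or 'sewer'")
        if (any(tb$reclassified & !tb$matched))
            msg <- c(msg, "reclassified implies matched")
        if (any(!tb$matched & tb$label != "sewer"))
            msg <- c(msg, "unmatched ASVs must be labeled sewer")
    }
    if (!(object@qLow > 0 && object@qHigh < 100 && object@qLow < object@qHigh))
        msg <- c(msg, "percentiles must satisfy 0 < qLow < qHigh < 100")
    if (is.null(msg)) TRUE else msg
})

#' Principal coordinates ordination
#'
#' Result of classical multidimensional scaling (PCoA) of a dissimilarity
#' matrix: sample coordinates on axes with positive eigenvalues, the full
#' eigenvalue spectrum, and the proportion of (positive) eigenvalue mass
#' explained per retained axis.
#'
#' @slot coordinates numeric matrix, samples x retained axes, axes ordered by
#'   decreasing eigenvalue.
#' @slot eigenvalues all eigenvalues, decreasing (possibly negative tail).
#' @slot propExplained proportion explained per retained axis, computed over
#'   positive eigenvalues only.
#' @seealso [pcoa()]
#' @export
setClass("Ordination", representation(
    coordinates = "matrix", eigenvalues = "numeric", propExplained = "numeric"
))

setValidity("Ordination", function(object) {
    msg <- NULL
    if (is.unsorted(rev(object@eigenvalues)))
        msg <- c(msg, "eigenvalues must be in decreasing order")
    if (ncol(object@coordinates) != length(object@propExplained))
        msg <- c(msg, "one proportion-explained entry per retained axis")
    if (length(object@propExplained) && sum(object@propExplained) > 1 + 1e-8)
        msg <- c(msg, "proportions explained must sum to <= 1")
    if (is.null(rownames(object@coordinates)))
        msg <- c(msg, "coordinates need sample ids as rownames")
    if (is.null(msg)) TRUE else msg
})
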