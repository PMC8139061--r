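#' @importFrom stats quantile
NULL

#' Normalize a nucleotide sequence for exact-identity matching
#'
#' Uppercases and converts U to T. Ambiguity codes and gap characters are an
#' error: the exact matcher is defined only over unambiguous A/C/G/T.
#'
#' @param raw a single sequence string.
#' @return the normalized string.
#' @examples
#' normalizeSequence("acgu")  # "ACGT"
#' @export
normalizeSequence <- function(raw) {
    s <- chartr("acgtu", "ACGTT", as.character(raw))
    s <- chartr("U", "T", s)
    if (grepl("[^ACGT]", s))
        stop("sequence contains non-ACGT characters (ambiguity codes or gaps)")
    s
}

#' Build a reduced reference set from raw per-occurrence records
#'
#' Dereplicates raw reference entries by normalized sequence, then drops
#' sequences occurring fewer than \code{minOccurrence} times or lacking a
#' subject or sample id. Within-reference-sample relative abundances are
#' computed per sample (occurrence counts over the sample's total retained
#' and unretained occurrences) and collected into a sequences-by-samples
#' matrix.
#'
#' @param records data.frame with columns \code{sequence}, \code{subject_id},
#'   \code{sample_id}, \code{body_site}; one row per occurrence.
#' @param minOccurrence minimum total occurrences for a sequence to be
#'   retained (default 10, boundary inclusive).
#' @return a [ReferenceSet-class].
#' @export
buildReducedReference <- function(records, minOccurrence = 10L) {
    need <- c("sequence", "subject_id", "sample_id", "body_site")
    if (!all(need %in% colnames(records)))
        stop("records need columns: ", paste(need, collapse = ", "))
    if (nrow(records) < 1L) stop("no reference records")
    seqn <- vapply(records$sequence, normalizeSequence, character(1),
                   USE.NAMES = FALSE)

    ## per-reference-sample totals use every occurrence, before reduction
    sampleTotals <- table(records$sample_id)
    occ <- table(seqn)

    keepSeq <- names(occ)[occ >= minOccurrence]
    ok <- seqn %in% keepSeq &
        !is.na(records$subject_id) & nzchar(records$subject_id) &
        !is.na(records$sample_id) & nzchar(records$sample_id)
    if (!any(ok)) stop("no sequences survive the reduction filter")
    rec <- records[ok, , drop = FALSE]
    sq <- seqn[ok]

    uniq <- unique(sq)
    idx <- split(seq_along(sq), factor(sq, levels = uniq))
    sampleLevels <- names(sampleTotals)
    ab <- matrix(0, length(uniq), length(sampleLevels),
                 dimnames = list(uniq, sampleLevels))
    cnt <- table(factor(sq, levels = uniq), factor(rec$sample_id,
                                                   levels = sampleLevels))
    ab[] <- sweep(unclass(cnt), 2L, as.numeric(sampleTotals), "/")

    new("ReferenceSet",
        sequences = uniq,
        occurrence = as.integer(occ[uniq]),
        subjectIds = lapply(idx, function(i) unique(rec$subject_id[i])),
        sampleIds = lapply(idx, function(i) unique(rec$sample_id[i])),
        bodySiteCounts = lapply(idx, function(i) {
            tb <- table(rec$body_site[i])
            structure(as.integer(tb), names = names(tb))
        }),
        refAbund = ab)
}

setMethod("show", "ReferenceSet", function(object) {
    cat("ReferenceSet:", length(object@sequences), "unique sequences,",
        ncol(object@refAbund), "reference samples\n")
    cat("  occurrence range:", paste(range(object@occurrence), collapse = "-"),
        "\n")
})

#' Exact-identity matching of ASVs against a reference
#'
#' An ASV matches iff its normalized sequence is string-identical to a
#' reference sequence; no partial or mismatch-tolerant hits.
#'
#' @param asvSeqs named character vector of ASV sequences.
#' @param reference a [ReferenceSet-class].
#' @return data.frame with \code{asv_id}, logical \code{matched}, and
#'   \code{ref_index} (row into the reference, NA if unmatched).
#' @export
matchExact <- function(asvSeqs, reference) {
    if (length(asvSeqs) < 1L) stop("no ASV sequences")
    norm <- vapply(asvSeqs, normalizeSequence, character(1))
    hit <- match(norm, reference@sequences)
    data.frame(asv_id = names(asvSeqs), matched = !is.na(hit),
               ref_index = hit, stringsAsFactors = FALSE)
}

## linear interpolation between order statistics (R's default quantile
## estimator); zeros for samples lacking the ASV are part of the vector
percentileOf <- function(x, p) unname(quantile(x, p / 100, type = 7L))

#' Partition ASVs into human-associated and sewer-resident sources
#'
#' Implements the percentile-threshold classifier. Each ASV matched to the
#' human-microbiome reference by exact identity is compared on two numbers:
#' the \code{qLow}th percentile (default 5th, a robust minimum) of its
#' relative abundance across wastewater samples, zeros included, and the
#' \code{qHigh}th percentile (default 95th, a robust maximum) of its
#' relative abundance across reference samples. If the wastewater low
#' percentile strictly exceeds the reference high percentile the ASV is too
#' consistently abundant in sewage to be explained by human input and is
#' reclassified to sewer; otherwise it stays human. Unmatched ASVs are
#' sewer-resident by definition. Ties (exact equality) stay human, since
#' reclassification requires strict exceedance.
#'
#' @param x an [AsvExperiment-class] or relative-abundance matrix
#'   (taxa x samples, columns summing to 1).
#' @param reference a [ReferenceSet-class].
#' @param matches optional result of [matchExact()]; computed from
#'   \code{asvSequences(x)} when omitted.
#' @param qLow,qHigh percentiles in (0, 100), \code{qLow < qHigh}.
#' @param schema body-site schema, see [defaultBodySiteSchema()].
#' @return a [PartitionResult-class].
#' @export
partitionSources <- function(x, reference, matches = NULL,
                             qLow = 5, qHigh = 95,
                             schema = defaultBodySiteSchema()) {
    if (!(qLow > 0 && qHigh < 100)) stop("percentiles must lie in (0, 100)")
    if (qLow >= qHigh) stop("qLow must be < qHigh")
    rel <- if (is(x, "AsvExperiment")) relAbund(x) else x
    if (is.null(matches)) {
        if (!is(x, "AsvExperiment") || is.null(asvSequences(x)))
            stop("provide 'matches' or an experiment carrying sequences")
        matches <- matchExact(vapply(as.character(asvSequences(x)),
                                     identity, character(1)), reference)
    }
    if (!setequal(matches$asv_id, rownames(rel)))
        stop("matches and table cover different ASV ids")
    matches <- matches[match(rownames(rel), matches$asv_id), ]

    n <- nrow(rel)
    label <- rep("sewer", n)
    reclass <- rep(FALSE, n)
    wwQ <- refQ <- rep(NA_real_, n)
    for (i in which(matches$matched)) {
        wwQ[i] <- percentileOf(rel[i, ], qLow)
        refQ[i] <- percentileOf(reference@refAbund[matches$ref_index[i], ],
                                qHigh)
        if (wwQ[i] > refQ[i]) {
            label[i] <- "sewer"; reclass[i] <- TRUE
        } else label[i] <- "human"
    }

    bin <- rep(NA_character_, n)
    hum <- which(label == "human")
    if (length(hum)) {
        bin[hum] <- vapply(hum, function(i) {
            tb <- reference@bodySiteCounts[[matches$ref_index[i]]]
            bins <- applySchema(names(tb), schema)
            agg <- tapply(as.numeric(tb), bins, sum)
            names(agg)[which.max(agg)]
        }, character(1))
    }

    res <- new("PartitionResult",
               table = DataFrame(asv_id = rownames(rel), label = label,
                                 matched = matches$matched,
                                 reclassified = reclass, body_site = bin,
                                 ww_qlow = wwQ, ref_qhigh = refQ,
                                 ref_index = matches$ref_index),
               qLow = qLow, qHigh = qHigh)
    message("partition: ", sum(matches$matched), " matched, ",
            sum(reclass), " reclassified, ", sum(label == "human"),
            " human / ", sum(label == "sewer"), " sewer")
    res
}

#' @describeIn PartitionResult the per-ASV table as a DataFrame
#' @param x a PartitionResult
#' @export
partitionTable <- function(x) x@table

setMethod("show", "PartitionResult", function(object) {
    tb <- object@table
    cat("PartitionResult:", nrow(tb), "ASVs (",
        sum(tb$label == "human"), "human /", sum(tb$label == "sewer"),
        "sewer );", sum(tb$matched), "matched,",
        sum(tb$reclassified), "reclassified\n")
    cat("  percentiles:", object@qLow, "(wastewater) vs",
        object@qHigh, "(reference)\n")
})

#' Default schema mapping raw body-site labels to bins
#'
#' Maps common human-microbiome body-site descriptions onto the six bins
#' used for summarising human read provenance: stool, oral, skin, airways,
#' urogenital, other. Unmapped labels fall into \code{other} with a warning
#' at use time.
#' @return named character vector: raw label -> bin.
#' @export
defaultBodySiteSchema <- function() c(
    stool = "stool", feces = "stool", gut = "stool",
    tongue_dorsum = "oral", buccal_mucosa = "oral", saliva = "oral",
    supragingival_plaque = "oral", subgingival_plaque = "oral",
    hard_palate = "oral", palatine_tonsils = "oral", throat = "oral",
    keratinized_gingiva = "oral", oral = "oral",
    anterior_nares = "airways", airways = "airways", nostril = "airways",
    retroauricular_crease = "skin", antecubital_fossa = "skin", skin = "skin",
    vaginal_introitus = "urogenital", mid_vagina = "urogenital",
    posterior_fornix = "urogenital", urogenital = "urogenital",
    other = "other")

applySchema <- function(labels, schema) {
    out <- unname(schema[labels])
    if (anyNA(out)) {
        warning("unmapped body-site label(s) assigned to 'other': ",
                paste(unique(labels[is.na(out)]), collapse = ", "))
        out[is.na(out)] <- "other"
    }
    out
}

#' Per-sample human read fraction
#'
#' Sum of relative abundances of human-labeled ASVs in each sample.
#' @param x an [AsvExperiment-class] or relative-abundance matrix.
#' @param partition a [PartitionResult-class] covering the same ASVs.
#' @param ... unused.
#' @return named numeric vector in [0, 1], one entry per sample.
#' @export
setMethod("humanFraction", "ANY", function(x, partition, ...) {
    rel <- if (is(x, "AsvExperiment")) relAbund(x) else x
    tb <- partitionTable(partition)
    if (!setequal(tb$asv_id, rownames(rel)))
        stop("partition and table cover different ASV ids")
    hum <- tb$asv_id[tb$label == "human"]
    colSums(rel[hum, , drop = FALSE])
})

#' Per-sample read fractions by human body-site bin
#'
#' Splits each human-labeled ASV's read mass across body-site bins in
#' proportion to its reference records' occurrence counts per site, then
#' sums per sample. Bins partition the human-labeled reads, so per-sample
#' bin fractions sum to the sample's human fraction.
#'
#' @param x an [AsvExperiment-class] or relative-abundance matrix.
#' @param partition a [PartitionResult-class].
#' @param reference the [ReferenceSet-class] used for partitioning.
#' @param schema raw-label to bin mapping, default [defaultBodySiteSchema()].
#' @return matrix of fractions, bins x samples.
#' @export
binBodySites <- function(x, partition, reference,
                         schema = defaultBodySiteSchema()) {
    rel <- if (is(x, "AsvExperiment")) relAbund(x) else x
    tb <- partitionTable(partition)
    bins <- sort(unique(unname(schema)))
    out <- matrix(0, length(bins), ncol(rel),
                  dimnames = list(bins, colnames(rel)))
    for (i in which(tb$label == "human")) {
        siteCnt <- reference@bodySiteCounts[[tb$ref_index[i]]]
        siteBins <- applySchema(names(siteCnt), schema)
        w <- tapply(as.numeric(siteCnt), factor(siteBins, levels = bins), sum)
        w[is.na(w)] <- 0
        w <- w / sum(w)
        out <- out + outer(as.numeric(w), rel[tb$asv_id[i], ])
    }
    out
}
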