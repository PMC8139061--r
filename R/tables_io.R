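#' @importFrom utils read.delim write.table read.csv
#' @importFrom stats median
NULL

## round-half-away-from-zero; base round() is banker's rounding
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Read an ASV count table
#'
#' Reads the tab-separated on-disk convention for amplicon count tables:
#' first column the ASV id, remaining columns per-sample read counts.
#'
#' @param path path to a TSV file with a header row.
#' @return an [AsvExperiment-class]; ASV and sample order as in the file.
#' @export
readAsvTable <- function(path) {
    df <- read.delim(path, header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
    if (nrow(df) < 1L || ncol(df) < 2L) stop("empty ASV table: ", path)
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids))
        stop("duplicate ASV id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m) || any(is.na(m)) || any(m < 0) || any(m != round(m)))
        stop("counts must be non-negative integers")
    rownames(m) <- ids
    message("read ASV table: ", nrow(m), " ASVs x ", ncol(m), " samples")
    AsvExperiment(m)
}

#' Write an ASV count table
#'
#' @param x an AsvExperiment
#' @param path output TSV path (ASVs as rows, samples as columns).
#' @return \code{path}, invisibly.
#' @export
writeAsvTable <- function(x, path) {
    df <- data.frame(asv_id = rownames(x), counts(x), check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read sample metadata
#'
#' CSV with a header; must contain \code{sample_id} and \code{date}
#' (ISO-8601) columns. A \code{month} column (1-12) is derived from the
#' date; all other columns are kept as-is (missing values stay NA and are
#' dropped pairwise by downstream fits).
#'
#' @param path CSV path.
#' @return a [S4Vectors::DataFrame] with rownames = sample ids.
#' @export
readSampleMetadata <- function(path) {
    df <- read.csv(path, header = TRUE, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "date") %in% colnames(df)))
        stop("metadata needs 'sample_id' and 'date' columns")
    if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
    d <- as.Date(df$date)
    if (any(is.na(d))) stop("unparseable date(s) in metadata")
    df$month <- as.integer(format(d, "%m"))
    out <- DataFrame(df[, setdiff(colnames(df), "sample_id"), drop = FALSE],
                     row.names = df$sample_id)
    message("read metadata: ", nrow(out), " samples, ",
            ncol(out), " variables")
    out
}

#' Read sequences from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet] that normalizes to
#' uppercase T-form and checks id uniqueness.
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
readSequences <- function(path) {
    ss <- readDNAStringSet(path)
    if (anyDuplicated(names(ss))) stop("duplicate sequence ids in ", path)
    seqs <- vapply(as.character(ss), normalizeSequence, character(1))
    message("read ", length(seqs), " sequences from ", basename(path))
    seqs
}

#' Write sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSequences <- function(seqs, path) {
    writeXStringSet(DNAStringSet(seqs), path)
    invisible(path)
}

#' Length-filter sequences around their median length
#'
#' Keeps sequences whose length falls inside the inclusive window
#' \code{[round(m * (1 - fraction)), round(m * (1 + fraction))]} where
#' \code{m} is the median sequence length (mean of the middle two for an
#' even count) and rounding is half-away-from-zero. With the default 5%
#' fraction, a median length of 374 bases gives the window 355-393.
#'
#' @param seqs named character vector of sequences (at least one).
#' @param fraction half-width of the window as a proportion of the median.
#' @return list with \code{kept} (the surviving sequences) and
#'   \code{bounds} (integer lower/upper bound).
#' @examples
#' s <- c(a = strrep("A", 374), b = strrep("C", 350))
#' lengthFilter(s)$bounds
#' @export
lengthFilter <- function(seqs, fraction = 0.05) {
    if (length(seqs) < 1L) stop("no sequences to filter")
    if (fraction < 0) stop("fraction must be >= 0")
    len <- nchar(seqs)
    m <- median(len)
    bounds <- as.integer(c(roundHalfAway(m * (1 - fraction)),
                           roundHalfAway(m * (1 + fraction))))
    keep <- len >= bounds[1L] & len <= bounds[2L]
    message("length filter: median ", m, ", window [", bounds[1L], ", ",
            bounds[2L], "], kept ", sum(keep), "/", length(seqs))
    list(kept = seqs[keep], bounds = bounds)
}
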