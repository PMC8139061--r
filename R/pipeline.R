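#' @importFrom tools md5sum
#' @importFrom utils write.csv
NULL

writeTsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> source partition -> community
#' statistics -> seasonal dynamics, writing plain-text TSV/CSV outputs and
#' a manifest recording parameters, per-stage seeds, and md5 checksums of
#' every output. A single master seed fans out deterministically to stages
#' via [deriveSeed()], so a rerun with the same configuration reproduces
#' every checksum.
#'
#' @param outDir output directory (created if needed).
#' @param config a [simulationConfig()] describing the synthetic study, or
#'   \code{NULL} with \code{asvTable}/\code{metadata}/\code{asvFasta}/
#'   \code{referenceRecords} paths supplied instead.
#' @param asvTable,metadata,asvFasta,referenceRecords optional input paths
#'   (TSV counts, CSV metadata, FASTA sequences, TSV per-occurrence
#'   reference records) used when \code{config} is NULL.
#' @param seed master seed; overrides \code{config$seed} when given.
#' @param nPerm permutations for PERMANOVA/envfit/indicators.
#' @param qLow,qHigh partition percentiles.
#' @param minOccurrence reference reduction threshold.
#' @param maxAbundMin indicator screen threshold.
#' @param alpha indicator significance level.
#' @param maxLag autocorrelation lags.
#' @param verbose print stage progress.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest data.frame.
#' @export
runPipeline <- function(outDir, config = simulationConfig(),
                        asvTable = NULL, metadata = NULL, asvFasta = NULL,
                        referenceRecords = NULL,
                        seed = NULL, nPerm = 999L, qLow = 5, qHigh = 95,
                        minOccurrence = 10L, maxAbundMin = 0.01,
                        alpha = 0.05, maxLag = 60L, verbose = TRUE) {
    say <- function(...) if (verbose) message("[pipeline] ", ...)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    outputs <- character(0)
    keep <- function(p) { outputs <<- c(outputs, p); p }

    ## ---- stage: inputs -------------------------------------------------
    if (!is.null(config)) {
        if (!is.null(seed)) config$seed <- as.integer(seed)
        say("simulate: seed ", config$seed)
        study <- simulateStudy(config)
        ae <- study$experiment
        refRecords <- study$referenceRecords
        truth <- study$truth
        keep(writeAsvTable(ae, file.path(outDir, "asv_table.tsv")))
        keep(writeSequences(as.character(asvSequences(ae)),
                            file.path(outDir, "asv_seqs.fasta")))
        md <- data.frame(sample_id = colnames(ae),
                         as.data.frame(colData(ae)))
        write.csv(md, keep(file.path(outDir, "sample_metadata.csv")),
                  row.names = FALSE, quote = FALSE)
        keep(writeTsv(refRecords, file.path(outDir, "reference_records.tsv")))
        keep(writeTsv(truth$taxa, file.path(outDir, "truth_taxa.tsv")))
    } else {
        for (p in c(asvTable, metadata, asvFasta, referenceRecords))
            if (!file.exists(p)) stop("input path does not exist: ", p)
        if (is.null(seed)) seed <- 1L
        config <- list(seed = as.integer(seed))
        say("load inputs")
        ae <- readAsvTable(asvTable)
        cd <- readSampleMetadata(metadata)
        colData(ae) <- cbind(colData(ae), cd[colnames(ae), , drop = FALSE])
        asvSequences(ae) <- readSequences(asvFasta)
        refRecords <- read.delim(referenceRecords, stringsAsFactors = FALSE)
        truth <- NULL
    }

    ## ---- stage: partition ----------------------------------------------
    say("partition: reduce reference (min occurrence ", minOccurrence, ")")
    reference <- buildReducedReference(refRecords, minOccurrence)
    part <- partitionSources(ae, reference, qLow = qLow, qHigh = qHigh)
    keep(writeTsv(as.data.frame(partitionTable(part)),
                  file.path(outDir, "partition.tsv")))
    hf <- humanFraction(ae, part)
    bins <- binBodySites(ae, part, reference)
    keep(writeTsv(data.frame(sample_id = names(hf), human_fraction = hf,
                             t(bins)),
                  file.path(outDir, "human_fraction.tsv")))

    ## ---- stage: community statistics ------------------------------------
    say("stats: diversity, Bray-Curtis, PCoA, PERMANOVA, envfit")
    rel <- relAbund(ae)
    H <- shannonDiversity(rel)
    d <- brayCurtis(rel)
    ord <- pcoa(d)
    month <- colData(ae)$month
    season <- assignSeason(month)
    perma <- permanova(d, season, nPerm = nPerm,
                       seed = deriveSeed(config$seed, "permanova"))
    ef <- envFit(ord, colData(ae)$temperature, nPerm = nPerm,
                 seed = deriveSeed(config$seed, "envfit"))
    keep(writeTsv(data.frame(sample_id = names(H), shannon = H,
                             season = season,
                             axis1 = ordCoordinates(ord)[, 1],
                             axis2 = ordCoordinates(ord)[, 2]),
                  file.path(outDir, "community_stats.tsv")))
    keep(writeTsv(data.frame(test = c("permanova_F", "permanova_R2",
                                      "permanova_p", "envfit_temperature_R2",
                                      "envfit_temperature_p"),
                             value = c(perma$F, perma$R2, perma$p,
                                       ef$R2, ef$p)),
                  file.path(outDir, "tests.tsv")))

    ## ---- stage: seasonal dynamics ---------------------------------------
    say("seasonal: indicator screen, ACF, clustering")
    ind <- indicatorScreen(ae, month = month, maxAbundMin = maxAbundMin,
                           nPerm = nPerm, alpha = alpha,
                           seed = deriveSeed(config$seed, "indicators"))
    keep(writeTsv(ind, file.path(outDir, "indicators.tsv")))
    screened <- ind$asv_id
    acfTab <- do.call(rbind, lapply(screened, function(a) {
        r <- seasonalAcf(rel[a, ], monthIndex = colData(ae)$month_index %||%
                             seq_len(ncol(ae)), maxLag = maxLag)
        data.frame(asv_id = a, lag = r$lag, acf = r$acf, bound = r$bound)
    }))
    keep(writeTsv(acfTab, file.path(outDir, "acf.tsv")))
    cl <- zscoreCluster(rel[screened, , drop = FALSE])
    keep(writeTsv(data.frame(order = seq_along(cl$leafOrder),
                             asv_id = cl$leafOrder),
                  file.path(outDir, "cluster_order.tsv")))

    ## ---- manifest --------------------------------------------------------
    manifest <- data.frame(
        file = basename(outputs),
        md5 = unname(md5sum(outputs)),
        stringsAsFactors = FALSE)
    params <- data.frame(
        parameter = c("seed", "n_perm", "q_low", "q_high", "min_occurrence",
                      "max_abund_min", "alpha", "max_lag"),
        value = c(config$seed, nPerm, qLow, qHigh, minOccurrence,
                  maxAbundMin, alpha, maxLag))
    writeTsv(params, file.path(outDir, "manifest_params.tsv"))
    writeTsv(manifest, file.path(outDir, "manifest_checksums.tsv"))
    say("done: ", length(outputs), " outputs in ", outDir)

    invisible(list(experiment = ae, reference = reference, partition = part,
                   humanFraction = hf, bodySites = bins, shannon = H,
                   distance = d, ordination = ord, permanova = perma,
                   envfit = ef, indicators = ind, acf = acfTab,
                   cluster = cl, truth = truth, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
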