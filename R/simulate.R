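#' @importFrom stats rnorm rlnorm rgamma rmultinom rpois
NULL

#' Derive a stage seed from a master seed
#'
#' Deterministically maps (master seed, stage name) to an integer seed below
#' 2^31 so pipeline stages can be rerun independently while a single
#' run-level seed governs all randomness.
#'
#' @param seed integer master seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
deriveSeed <- function(seed, stage) {
    h <- 0
    for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
    as.integer(((abs(as.numeric(seed)) %% 2147483647) * 48271 + h) %%
                   2147483647)
}

#' Simulation configuration for the synthetic sewer time series
#'
#' Defines the study conditions emulated by the generator: a five-year
#' monthly influent series whose resident-sewer taxa respond log-linearly
#' to a sinusoidal wastewater temperature cycle (annual mean 14 deg C,
#' amplitude 4 deg C, peak in October, so roughly 10 deg C in April and
#' 18 deg C in October), while human-associated taxa are aseasonal. The
#' human read fraction defaults to 0.11 as observed at treatment plants;
#' use 0.36 for neighborhood-sewer scenarios. Counts are drawn
#' Dirichlet-multinomial for amplicon-typical overdispersion.
#'
#' @param nMonths number of monthly time points (default 60).
#' @param samplesPerMonth replicate samples per month (default 1).
#' @param depth sequencing depth per sample (default 20000, min 1000).
#' @param nWarm,nCold,nAseasonal,nHuman,nTrap taxon counts per class:
#'   warm-peaking seasonal sewer, cold-peaking seasonal sewer, aseasonal
#'   sewer, human-associated, and "trap" taxa (sewer residents that also
#'   occur in the human reference and must be reclassified by the
#'   percentile rule).
#' @param tempMean,tempAmplitude,tempPeakMonth,tempNoiseSd wastewater
#'   temperature model (deg C; peak calendar month; Gaussian noise sd).
#' @param tempSlope per-degree log-linear abundance response of seasonal
#'   taxa (sign set by class).
#' @param humanFraction target human read fraction per sample, in (0, 1).
#' @param noiseSd sd of the per-sample lognormal multiplicative noise on
#'   taxon intensities.
#' @param concentration Dirichlet-multinomial concentration (larger = less
#'   overdispersed).
#' @param seqLength amplicon length for simulated sequences (default 374).
#' @param nRefSamples,nRefOnly reference-panel size and number of
#'   reference-only sequences absent from wastewater.
#' @param missingMonths integer month indices (1..nMonths) dropped from the
#'   series, emulating unsampled months.
#' @param seed integer master seed.
#' @return validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(nMonths = 60L, samplesPerMonth = 1L,
                             depth = 20000L,
                             nWarm = 15L, nCold = 15L, nAseasonal = 120L,
                             nHuman = 80L, nTrap = 10L,
                             tempMean = 14, tempAmplitude = 4,
                             tempPeakMonth = 10L, tempNoiseSd = 0.3,
                             tempSlope = 0.25,
                             humanFraction = 0.11, noiseSd = 0.3,
                             concentration = 500,
                             seqLength = 374L, nRefSamples = 50L,
                             nRefOnly = 50L,
                             missingMonths = integer(0), seed = 1L) {
    cfg <- list(nMonths = as.integer(nMonths),
                samplesPerMonth = as.integer(samplesPerMonth),
                depth = as.integer(depth), nWarm = as.integer(nWarm),
                nCold = as.integer(nCold), nAseasonal = as.integer(nAseasonal),
                nHuman = as.integer(nHuman), nTrap = as.integer(nTrap),
                tempMean = tempMean, tempAmplitude = tempAmplitude,
                tempPeakMonth = as.integer(tempPeakMonth),
                tempNoiseSd = tempNoiseSd, tempSlope = tempSlope,
                humanFraction = humanFraction, noiseSd = noiseSd,
                concentration = concentration,
                seqLength = as.integer(seqLength),
                nRefSamples = as.integer(nRefSamples),
                nRefOnly = as.integer(nRefOnly),
                missingMonths = as.integer(missingMonths),
                seed = as.integer(seed))
    stopifnot(cfg$nMonths >= 1L, cfg$samplesPerMonth >= 1L,
              cfg$depth >= 1000L, cfg$nHuman >= 1L, cfg$nAseasonal >= 1L,
              cfg$nWarm >= 0L, cfg$nCold >= 0L, cfg$nTrap >= 0L,
              cfg$tempAmplitude >= 0,
              cfg$humanFraction > 0, cfg$humanFraction < 1,
              cfg$concentration > 0, cfg$seqLength >= 20L,
              all(cfg$missingMonths >= 1L & cfg$missingMonths <= cfg$nMonths))
    structure(cfg, class = "SimulationConfig")
}

#' @export
print.SimulationConfig <- function(x, ...) {
    cat("SimulationConfig:", x$nMonths, "months x", x$samplesPerMonth,
        "sample(s), depth", x$depth, "\n  taxa:", x$nWarm, "warm /",
        x$nCold, "cold /", x$nAseasonal, "aseasonal sewer /",
        x$nTrap, "trap /", x$nHuman, "human\n  temperature:",
        x$tempMean, "+/-", x$tempAmplitude, "C, peak month",
        x$tempPeakMonth, "; human fraction", x$humanFraction,
        "; seed", x$seed, "\n")
    invisible(x)
}

#' Simulated wastewater temperature series
#'
#' \eqn{T(t) = mean + amplitude \cdot \cos(2\pi (m_t - peak)/12) + noise},
#' with \eqn{m_t} the calendar month. Defaults peak near October and bottom
#' near April with an annual range of about 8 deg C, mirroring the roughly
#' three-month lag of sewer temperature behind air temperature.
#'
#' @param config a [simulationConfig()].
#' @param seed seed (default derived from the config's master seed).
#' @return numeric vector of monthly temperatures, length \code{nMonths}.
#' @export
temperatureSeries <- function(config, seed = deriveSeed(config$seed,
                                                        "temperature")) {
    t <- seq_len(config$nMonths)
    m <- (t - 1L) %% 12L + 1L
    set.seed(seed)
    config$tempMean + config$tempAmplitude *
        cos(2 * pi * (m - config$tempPeakMonth) / 12) +
        rnorm(config$nMonths, 0, config$tempNoiseSd)
}

taxonClasses <- function(config) {
    cls <- rep(c("warm", "cold", "aseasonal", "trap", "human"),
               c(config$nWarm, config$nCold, config$nAseasonal,
                 config$nTrap, config$nHuman))
    data.frame(asv_id = sprintf("ASV%04d", seq_along(cls)), class = cls,
               stringsAsFactors = FALSE)
}

#' Simulate a monthly wastewater ASV community
#'
#' Expected per-taxon intensities: seasonal sewer taxa are log-linear in
#' wastewater temperature (positive slope for the warm class, negative for
#' the cold class); aseasonal sewer, trap, and human taxa have constant
#' means; all receive per-sample lognormal multiplicative noise. Each
#' sample's composition is renormalized so the human-class expected read
#' fraction equals the configured target; counts are then drawn
#' Dirichlet-multinomial at the configured depth and concentration. Fully
#' seeded: the same (config, seed) give bit-identical output.
#'
#' @param config a [simulationConfig()].
#' @return list with \code{experiment} (an [AsvExperiment-class] with
#'   month, date, season and temperature in \code{colData}) and
#'   \code{truth} (per-ASV class/slope table, temperature series, target
#'   human fraction, config).
#' @export
simulateCommunity <- function(config) {
    temp <- temperatureSeries(config)
    months <- setdiff(seq_len(config$nMonths), config$missingMonths)
    cls <- taxonClasses(config)
    nT <- nrow(cls)

    set.seed(deriveSeed(config$seed, "community"))
    ## trap taxa emulate resident organisms that are consistently present in
    ## wastewater (like the ~1% reclassified exemplars); their base abundance
    ## must keep the 5th-percentile wastewater abundance strictly positive
    baseMeanlog <- c(warm = log(4), cold = log(4), aseasonal = 0,
                     trap = log(4), human = 0)
    baseSd <- c(warm = 1, cold = 1, aseasonal = 1, trap = 0.2, human = 0.5)
    b <- rlnorm(nT, baseMeanlog[cls$class], baseSd[cls$class])
    slope <- ifelse(cls$class == "warm", config$tempSlope,
             ifelse(cls$class == "cold", -config$tempSlope, 0))

    sampleIds <- character(0); sampleMonth <- integer(0)
    counts <- NULL
    human <- cls$class == "human"
    for (t in months) {
        for (r in seq_len(config$samplesPerMonth)) {
            eps <- rlnorm(nT, 0, config$noiseSd)
            w <- b * exp(slope * (temp[t] - config$tempMean)) * eps
            p <- numeric(nT)
            p[human] <- config$humanFraction * w[human] / sum(w[human])
            p[!human] <- (1 - config$humanFraction) * w[!human] /
                sum(w[!human])
            lam <- rgamma(nT, shape = p * config$concentration, rate = 1)
            counts <- cbind(counts,
                            rmultinom(1, config$depth, lam / sum(lam)))
            sampleIds <- c(sampleIds, sprintf("S%03d%s", t,
                           if (config$samplesPerMonth > 1)
                               paste0(".", r) else ""))
            sampleMonth <- c(sampleMonth, t)
        }
    }
    rownames(counts) <- cls$asv_id
    colnames(counts) <- sampleIds
    calMonth <- (sampleMonth - 1L) %% 12L + 1L
    dates <- seq(as.Date("2013-01-15"), by = "month",
                 length.out = config$nMonths)[sampleMonth]
    set.seed(deriveSeed(config$seed, "covariates"))
    cd <- DataFrame(
        date = as.character(dates), month = calMonth,
        month_index = sampleMonth,
        season = assignSeason(calMonth),
        temperature = temp[sampleMonth],
        air_temperature = config$tempMean + 6 *
            cos(2 * pi * (calMonth - (config$tempPeakMonth - 3L)) / 12) +
            rnorm(length(sampleMonth), 0, 1),
        flow = rlnorm(length(sampleMonth), log(150), 0.2),
        row.names = sampleIds)
    ae <- AsvExperiment(counts, cd)
    rowData(ae)$class <- cls$class
    list(experiment = ae,
         truth = list(taxa = cbind(cls, slope = slope, base = b),
                      temperature = temp,
                      humanFractionTarget = config$humanFraction,
                      config = config))
}

randomSequences <- function(n, len) {
    repeat {
        s <- vapply(seq_len(n), function(i)
            paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                  collapse = ""), character(1))
        if (!anyDuplicated(s)) return(s)
    }
}

#' Simulate ASV sequences and a raw human-microbiome reference
#'
#' Gives every wastewater ASV a random sequence of the configured length.
#' Human-class and trap-class ASVs get per-occurrence reference records
#' (occurrence >= 10, with subject/sample ids and body-site labels) so they
#' match by exact identity; sewer classes are absent from the reference.
#' Human sequences are spread over many reference samples, so their robust
#' maximum (95th-percentile) reference abundance is positive; each trap
#' sequence is confined to two reference samples, so its 95th-percentile
#' reference abundance is zero while it remains consistently present in
#' wastewater -- guaranteeing reclassification by the percentile rule.
#' A configurable number of reference-only sequences is added.
#'
#' @param config a [simulationConfig()].
#' @return list with \code{asvSeqs} (named vector over all ASV ids),
#'   \code{records} (raw per-occurrence reference data.frame), and
#'   \code{truth} (per-ASV class and in-reference flag).
#' @export
simulateReference <- function(config) {
    cls <- taxonClasses(config)
    set.seed(deriveSeed(config$seed, "reference"))
    asvSeqs <- structure(randomSequences(nrow(cls), config$seqLength),
                         names = cls$asv_id)
    refOnly <- randomSequences(config$nRefOnly, config$seqLength)

    sites <- c("stool", "tongue_dorsum", "buccal_mucosa", "anterior_nares",
               "retroauricular_crease", "posterior_fornix")
    siteProb <- c(0.55, 0.12, 0.08, 0.1, 0.1, 0.05)
    refSamples <- sprintf("HMPS%03d", seq_len(config$nRefSamples))
    subjects <- sprintf("SUBJ%03d", seq_len(max(2L, config$nRefSamples %/% 2L)))

    ## a trap sequence must have zero 95th-percentile reference abundance:
    ## confine its records to the largest number of reference samples whose
    ## occupancy still leaves the interpolated 95th percentile at zero
    kConf <- config$nRefSamples -
        ceiling(1 + 0.95 * (config$nRefSamples - 1))
    if (config$nTrap > 0L && kConf < 1L)
        stop("reference panel too small for trap construction; ",
             "increase nRefSamples (>= 21)")

    mkRecords <- function(seqs, confined) {
        do.call(rbind, lapply(seqs, function(s) {
            occ <- 10L + rpois(1L, 10L)
            sampPool <- if (confined) sample(refSamples, kConf) else refSamples
            data.frame(sequence = s,
                       subject_id = sample(subjects, occ, replace = TRUE),
                       sample_id = sample(sampPool, occ, replace = TRUE),
                       body_site = sample(sites, occ, replace = TRUE,
                                          prob = siteProb),
                       stringsAsFactors = FALSE)
        }))
    }
    records <- rbind(
        mkRecords(asvSeqs[cls$class == "human"], confined = FALSE),
        mkRecords(asvSeqs[cls$class == "trap"], confined = TRUE),
        mkRecords(refOnly, confined = FALSE))
    rownames(records) <- NULL
    truth <- cbind(cls, inReference = cls$class %in% c("human", "trap"))
    list(asvSeqs = asvSeqs, records = records, truth = truth)
}

#' Simulate a full study: community, sequences, and reference
#'
#' Convenience wrapper running [simulateCommunity()] and
#' [simulateReference()] under one config, attaching sequences to the
#' experiment.
#'
#' @param config a [simulationConfig()].
#' @return list with \code{experiment}, \code{referenceRecords},
#'   \code{truth} (community truth plus reference truth merged).
#' @export
simulateStudy <- function(config = simulationConfig()) {
    com <- simulateCommunity(config)
    ref <- simulateReference(config)
    ae <- com$experiment
    asvSequences(ae) <- ref$asvSeqs
    com$truth$inReference <- ref$truth$inReference
    list(experiment = ae, referenceRecords = ref$records,
         truth = com$truth)
}
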