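test_that("sequence normalization uppercases and converts U to T", {
    expect_identical(normalizeSequence("acgu"), "ACGT")
    expect_identical(normalizeSequence("ACGT"), "ACGT")
    expect_error(normalizeSequence("ACGN"), "non-ACGT")
    expect_error(normalizeSequence("AC-GT"), "non-ACGT")
})

rawRecords <- function(seqs, occs, site = "stool") {
    do.call(rbind, Map(function(s, n) data.frame(
        sequence = rep(s, n),
        subject_id = paste0("subj", seq_len(n)),
        sample_id = paste0("samp", rep_len(1:3, n)),
        body_site = site, stringsAsFactors = FALSE), seqs, occs))
}

test_that("reference reduction applies the inclusive >= 10 occurrence filter", {
    recs <- rawRecords(c("ACGTACGT", "TTTTCCCC", "GGGGAAAA"), c(9, 10, 25))
    ref <- buildReducedReference(recs)
    expect_setequal(ref@sequences, c("TTTTCCCC", "GGGGAAAA"))
    expect_identical(ref@occurrence[ref@sequences == "TTTTCCCC"], 10L)
})

test_that("dereplication merges case/U variants of the same sequence", {
    recs <- rawRecords(c("ACGTACGT", "acguacgu"), c(6, 6))
    ref <- buildReducedReference(recs)
    expect_identical(ref@sequences, "ACGTACGT")
    expect_identical(ref@occurrence, 12L)

    expect_error(buildReducedReference(rawRecords("ACGT", 3)), "survive")
})

test_that("reference relative abundances are per-sample fractions", {
    ## samp1 holds 4 of seqA + 4 of seqB; fractions 0.5 each
    recs <- rbind(rawRecords("ACGTACGTAC", 10), rawRecords("TTTTCCCCTT", 10))
    ref <- buildReducedReference(recs)
    expect_equal(colSums(ref@refAbund), rep(1, 3), ignore_attr = TRUE)
    expect_equal(unname(ref@refAbund[, "samp1"]), c(0.5, 0.5))
})

test_that("exact matching requires string identity", {
    ref <- buildReducedReference(rawRecords(c("ACGTACGT", "GGGGAAAA"),
                                            c(10, 10)))
    asvs <- c(a1 = "ACGTACGT", a2 = "ACGTACGA", a3 = "TTTTTTTT")
    m <- matchExact(asvs, ref)
    expect_identical(m$matched, c(TRUE, FALSE, FALSE))
    expect_identical(ref@sequences[m$ref_index[1]], "ACGTACGT")
    expect_true(all(!matchExact(c(z = "CCCCCCCC"), ref)$matched))
})

## hand-built scenario exercising the percentile rule both ways
percentileFixture <- function() {
    ## wastewater: 3 ASVs x 4 samples of relative abundance
    rel <- rbind(
        hi = c(0.02, 0.03, 0.025, 0.04),   # ww 5th pct = 0.02075 > ref
        lo = c(0.001, 0.002, 0.001, 0.001),# ww 5th pct = 0.001 < ref
        un = c(0.979, 0.968, 0.974, 0.959))
    colnames(rel) <- paste0("s", 1:4)
    refAb <- rbind(rep(0.01, 5), rep(0.01, 5))  # ref 95th pct = 0.01
    ref <- tinyReference(c("AAAACCCC", "GGGGTTTT"), refAb,
                         list(c(stool = 2L), c(stool = 2L)))
    matches <- data.frame(asv_id = c("hi", "lo", "un"),
                          matched = c(TRUE, TRUE, FALSE),
                          ref_index = c(1L, 2L, NA))
    list(rel = rel, ref = ref, matches = matches)
}

test_that("percentile rule reclassifies abundant matches and keeps rare ones", {
    fx <- percentileFixture()
    pr <- suppressMessages(
        partitionSources(fx$rel, fx$ref, matches = fx$matches))
    tb <- partitionTable(pr)
    expect_identical(tb$label, c("sewer", "human", "sewer"))
    expect_identical(tb$reclassified, c(TRUE, FALSE, FALSE))
    expect_identical(tb$matched, c(TRUE, TRUE, FALSE))
    ## percentile values recorded with the rule's orientation
    expect_gt(tb$ww_qlow[1], tb$ref_qhigh[1])
    expect_lt(tb$ww_qlow[2], tb$ref_qhigh[2])
})

test_that("exact percentile ties stay human (rule requires strict exceedance)", {
    rel <- rbind(tie = rep(0.01, 4), rest = rep(0.99, 4))
    colnames(rel) <- paste0("s", 1:4)
    ref <- tinyReference("AAAACCCC", matrix(0.01, 1, 5),
                         list(c(stool = 1L)))
    matches <- data.frame(asv_id = c("tie", "rest"),
                          matched = c(TRUE, FALSE), ref_index = c(1L, NA))
    tb <- partitionTable(suppressMessages(
        partitionSources(rel, ref, matches = matches)))
    expect_identical(tb$label[tb$asv_id == "tie"], "human")
})

test_that("invalid percentile parameters are rejected", {
    fx <- percentileFixture()
    expect_error(partitionSources(fx$rel, fx$ref, matches = fx$matches,
                                  qLow = 0), "percentiles")
    expect_error(partitionSources(fx$rel, fx$ref, matches = fx$matches,
                                  qLow = 95, qHigh = 5), "qLow")
})

test_that("labels always cover every ASV and sewer count is monotone in thresholds", {
    set.seed(11)
    rel <- randomRelTable(12, 10, seed = 11)
    refAb <- matrix(rgamma(6 * 8, 1), 6, 8)
    refAb <- sweep(refAb, 2, colSums(refAb), "/")
    ref <- tinyReference(paste0(strrep("A", 7), c("A","C","G","T","AA","CC")),
                         refAb, rep(list(c(stool = 1L)), 6))
    matched <- rep(c(TRUE, FALSE), 6)
    refIndex <- rep(NA_integer_, 12)
    refIndex[matched] <- 1:6
    matches <- data.frame(asv_id = rownames(rel), matched = matched,
                          ref_index = refIndex)

    prev <- -1L
    for (q in c(2, 5, 10, 20, 40)) {
        tb <- partitionTable(suppressMessages(
            partitionSources(rel, ref, matches = matches, qLow = q)))
        expect_identical(nrow(tb), 12L)
        expect_identical(sum(tb$label == "human") + sum(tb$label == "sewer"),
                         12L)
        nSewer <- sum(tb$label == "sewer")
        expect_gte(nSewer, prev)   # raising qLow never un-reclassifies
        prev <- nSewer
    }
    prev <- -1L
    for (qh in c(98, 95, 80, 60, 50)) {   # decreasing qHigh
        tb <- partitionTable(suppressMessages(
            partitionSources(rel, ref, matches = matches, qHigh = qh)))
        nSewer <- sum(tb$label == "sewer")
        expect_gte(nSewer, prev)   # lowering qHigh never decreases sewer count
        expect_gte(nSewer, sum(tb$reclassified))
        prev <- nSewer
    }
})

test_that("human fraction sums human-labeled relative abundance per sample", {
    rel <- randomRelTable(4, 3, seed = 2)
    mkpart <- function(labels) {
        new("PartitionResult",
            table = DataFrame(asv_id = rownames(rel), label = labels,
                              matched = labels == "human",
                              reclassified = FALSE,
                              body_site = ifelse(labels == "human", "stool", NA),
                              ww_qlow = NA_real_, ref_qhigh = NA_real_,
                              ref_index = NA_integer_),
            qLow = 5, qHigh = 95)
    }
    expect_equal(unname(humanFraction(rel, mkpart(rep("human", 4)))),
                 rep(1, 3))
    expect_equal(unname(humanFraction(rel, mkpart(rep("sewer", 4)))),
                 rep(0, 3))
    half <- mkpart(c("human", "human", "sewer", "sewer"))
    expect_equal(unname(humanFraction(rel, half)),
                 unname(colSums(rel[1:2, ])))
})

test_that("body-site binning splits multi-site matches by occurrence counts", {
    ## ASV 'hs' matches a reference sequence seen 3x in stool, 1x oral
    rel <- rbind(hs = c(0.4, 0.2), other = c(0.6, 0.8))
    colnames(rel) <- c("s1", "s2")
    ref <- tinyReference("ACACACAC", matrix(0.2, 1, 5),
                         list(c(stool = 3L, tongue_dorsum = 1L)))
    part <- new("PartitionResult",
                table = DataFrame(asv_id = c("hs", "other"),
                                  label = c("human", "sewer"),
                                  matched = c(TRUE, FALSE),
                                  reclassified = FALSE,
                                  body_site = c("stool", NA),
                                  ww_qlow = NA_real_, ref_qhigh = NA_real_,
                                  ref_index = c(1L, NA)),
                qLow = 5, qHigh = 95)
    bins <- binBodySites(rel, part, ref)
    ## hand computation: 0.4 read mass -> 0.75 stool, 0.25 oral
    expect_equal(bins["stool", "s1"], 0.3)
    expect_equal(bins["oral", "s1"], 0.1)
    expect_equal(bins["stool", "s2"], 0.15)
    expect_equal(colSums(bins), unname(humanFraction(rel, part)),
                 ignore_attr = TRUE)
    expect_true(all(bins[c("skin", "airways", "urogenital"), ] == 0))

    ## no human ASVs -> all-zero bins
    part@table$label <- c("sewer", "sewer")
    part@table$matched <- c(TRUE, FALSE)
    part@table$body_site <- NA_character_
    expect_true(all(binBodySites(rel, part, ref) == 0))

    ## unmapped site labels warn and fall into 'other'
    refU <- tinyReference("ACACACAC", matrix(0.2, 1, 5),
                          list(c(mystery_site = 2L)))
    part@table$label <- c("human", "sewer")
    part@table$matched <- c(TRUE, FALSE)
    expect_warning(binsU <- binBodySites(rel, part, refU), "unmapped")
    expect_equal(binsU["other", "s1"], 0.4)
})
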