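#' @importFrom stats sd hclust dist cor.test qnorm as.dendrogram order.dendrogram
NULL

#' Assign calendar months to seasonal community-state groups
#'
#' February-June form the spring steady state, August-December the fall
#' steady state; January and July are transition ("mix") months between the
#' two community configurations.
#'
#' @param month integer vector of calendar months (1-12).
#' @return factor with levels spring, fall, mix.
#' @examples
#' assignSeason(c(4, 10, 7))   # spring fall mix
#' @export
assignSeason <- function(month) {
    month <- as.integer(month)
    if (any(is.na(month)) || any(month < 1L | month > 12L))
        stop("months must be integers in 1..12")
    lab <- ifelse(month >= 2L & month <= 6L, "spring",
           ifelse(month >= 8L & month <= 12L, "fall", "mix"))
    factor(lab, levels = c("spring", "fall", "mix"))
}

#' The twelve consecutive three-month windows
#'
#' All windows of exactly three consecutive calendar months, wrapping the
#' year boundary (Dec-Jan-Feb and Nov-Dec-Jan included), so each month
#' appears in exactly three windows.
#'
#' @return named list of integer month triples; names like \code{"Sep-Oct-Nov"}.
#' @export
monthWindows <- function() {
    out <- lapply(1:12, function(m) ((m - 1L):(m + 1L) - 1L) %% 12L + 1L)
    names(out) <- vapply(out, function(w)
        paste(month.abb[w], collapse = "-"), character(1))
    out
}

#' Indicator value of an ASV for a group of samples
#'
#' IndVal for a one-vs-rest split: specificity
#' \eqn{A = \bar{x}_{in} / (\bar{x}_{in} + \bar{x}_{out})} (mean relative
#' abundance inside the group against the mean outside), fidelity
#' \eqn{B} = fraction of in-group samples where the ASV is present, and
#' statistic \eqn{\sqrt{A B}}. Significance permutes the group labels
#' (upper tail, +1 convention).
#'
#' @param abundance numeric vector of the ASV's relative abundance per sample.
#' @param inGroup logical vector, TRUE for in-group samples; both the group
#'   and its complement must be non-empty.
#' @param nPerm label permutations (0 skips the test, p = NA).
#' @param seed integer seed.
#' @return list with \code{A}, \code{B}, \code{stat}, \code{p}.
#' @export
indVal <- function(abundance, inGroup, nPerm = 999L, seed = 1L) {
    if (length(abundance) != length(inGroup))
        stop("abundance and inGroup lengths differ")
    if (!any(inGroup) || all(inGroup))
        stop("group and complement must both be non-empty")
    if (all(abundance == 0)) stop("ASV absent everywhere: IndVal undefined")
    stat1 <- function(g) {
        mIn <- mean(abundance[g]); mOut <- mean(abundance[!g])
        if (mIn + mOut == 0) return(0)
        sqrt(mIn / (mIn + mOut) * mean(abundance[g] > 0))
    }
    mIn <- mean(abundance[inGroup]); mOut <- mean(abundance[!inGroup])
    A <- if (mIn + mOut == 0) 0 else mIn / (mIn + mOut)
    B <- mean(abundance[inGroup] > 0)
    s <- sqrt(A * B)
    p <- NA_real_
    if (nPerm > 0L) {
        set.seed(seed)
        exceed <- sum(vapply(seq_len(nPerm), function(b)
            stat1(sample(inGroup)) >= s, logical(1)))
        p <- (1 + exceed) / (1 + nPerm)
    }
    list(A = A, B = B, stat = s, p = p)
}

## vectorized IndVal statistics for a matrix (ASVs x samples)
indValStatMatrix <- function(rel, inGroup) {
    mIn <- rowMeans(rel[, inGroup, drop = FALSE])
    mOut <- rowMeans(rel[, !inGroup, drop = FALSE])
    A <- ifelse(mIn + mOut == 0, 0, mIn / (mIn + mOut))
    B <- rowMeans(rel[, inGroup, drop = FALSE] > 0)
    cbind(A = A, B = B, stat = sqrt(A * B))
}

#' Screen ASVs for three-month indicator windows
#'
#' Tests every ASV passing the maximum-relative-abundance screen (default:
#' max across samples >= 1%) against each of the twelve consecutive
#' three-month windows, one window vs all other months. For each ASV the
#' best window (largest IndVal statistic) is reported. Because the best
#' window is selected from twelve overlapping candidates, its p-value is
#' computed against the permutation null of the *maximum* statistic over
#' all windows (the same label permutations evaluated on every window), so
#' an aseasonal ASV is flagged at rate alpha rather than inflated by the
#' twelve-fold selection. Per-window uncorrected p-values are attached as
#' \code{attr(, "all_windows")}.
#'
#' @param x an [AsvExperiment-class] or relative-abundance matrix.
#' @param month integer calendar month (1-12) per sample; taken from
#'   \code{colData(x)$month} when missing.
#' @param maxAbundMin screen threshold on each ASV's maximum relative
#'   abundance (default 0.01).
#' @param nPerm label permutations (shared across windows).
#' @param seed integer seed.
#' @param alpha significance level for the \code{significant} flag.
#' @return data.frame (one row per screened ASV): \code{asv_id},
#'   \code{window}, \code{A}, \code{B}, \code{stat}, \code{p}
#'   (selection-corrected), \code{significant}; attribute
#'   \code{"all_windows"} holds the full window-by-ASV grid.
#' @export
indicatorScreen <- function(x, month = NULL, maxAbundMin = 0.01,
                            nPerm = 999L, seed = 1L, alpha = 0.05) {
    rel <- if (is(x, "AsvExperiment")) relAbund(x) else x
    if (is.null(month)) {
        if (!is(x, "AsvExperiment") || !"month" %in% colnames(colData(x)))
            stop("supply 'month' or an experiment with colData month")
        month <- colData(x)$month
    }
    month <- as.integer(month)
    dropped <- rownames(rel)[apply(rel, 1L, max) < maxAbundMin]
    if (length(dropped))
        message("indicator screen: ", length(dropped),
                " ASV(s) below the ", maxAbundMin, " max-abundance screen")
    rel <- rel[!rownames(rel) %in% dropped, , drop = FALSE]
    if (!nrow(rel)) stop("no ASVs pass the abundance screen")
    absent <- rowSums(rel) == 0
    if (any(absent)) {
        message("indicator screen: skipping ", sum(absent),
                " ASV(s) absent everywhere")
        rel <- rel[!absent, , drop = FALSE]
    }

    wins <- monthWindows()
    nA <- nrow(rel)
    nS <- ncol(rel)
    inGrid <- vapply(wins, function(w) month %in% w, logical(nS))

    obsStat <- vapply(seq_along(wins), function(w)
        indValStatMatrix(rel, inGrid[, w]), matrix(0, nA, 3))
    dimnames(obsStat) <- list(rownames(rel), c("A", "B", "stat"), names(wins))
    obsMax <- apply(obsStat[, "stat", , drop = FALSE], 1L, max)

    set.seed(seed)
    exceedWin <- matrix(0L, nA, length(wins))
    exceedMax <- integer(nA)
    for (b in seq_len(nPerm)) {
        ord <- sample.int(nS)
        permStat <- vapply(seq_along(wins), function(w)
            indValStatMatrix(rel, inGrid[ord, w])[, "stat"], numeric(nA))
        exceedWin <- exceedWin + (permStat >= obsStat[, "stat", ])
        exceedMax <- exceedMax +
            (apply(permStat, 1L, max) >= obsMax)
    }

    allw <- do.call(rbind, lapply(seq_along(wins), function(w)
        data.frame(asv_id = rownames(rel), window = names(wins)[w],
                   A = obsStat[, "A", w], B = obsStat[, "B", w],
                   stat = obsStat[, "stat", w],
                   p = (1 + exceedWin[, w]) / (1 + nPerm),
                   row.names = NULL)))
    bestIdx <- apply(obsStat[, "stat", , drop = FALSE], 1L, which.max)
    best <- data.frame(
        asv_id = rownames(rel),
        window = names(wins)[bestIdx],
        A = obsStat[cbind(seq_len(nA), 1L, bestIdx)],
        B = obsStat[cbind(seq_len(nA), 2L, bestIdx)],
        stat = obsMax,
        p = (1 + exceedMax) / (1 + nPerm),
        row.names = NULL)
    best$significant <- best$p <= alpha
    attr(best, "all_windows") <- allw
    best
}

#' z-score normalization and hierarchical clustering of ASV series
#'
#' Each ASV's relative-abundance series is relativized to itself:
#' \eqn{z = (x - \bar{x}) / s} across samples. ASVs with constant series
#' are excluded with a message. Clustering is agglomerative (average
#' linkage) on Euclidean distances between z-series, with a deterministic
#' leaf order.
#'
#' @param x an [AsvExperiment-class] or relative-abundance matrix
#'   (ASVs x samples); at least 2 non-constant ASVs.
#' @param linkage agglomeration method for [stats::hclust].
#' @return list with \code{z} (z-scored matrix), \code{hclust}, and
#'   \code{leafOrder} (ASV ids in dendrogram order).
#' @export
zscoreCluster <- function(x, linkage = "average") {
    rel <- if (is(x, "AsvExperiment")) relAbund(x) else x
    sds <- apply(rel, 1L, sd)
    if (any(sds == 0)) {
        message("zscoreCluster: excluding ", sum(sds == 0),
                " constant ASV(s)")
        rel <- rel[sds > 0, , drop = FALSE]
        sds <- sds[sds > 0]
    }
    if (nrow(rel) < 2L) stop("need at least 2 non-constant ASVs")
    z <- (rel - rowMeans(rel)) / sds
    hc <- hclust(dist(z), method = linkage)
    list(z = z, hclust = hc, leafOrder = rownames(z)[hc$order])
}

#' Autocorrelation of a monthly series with explicit gaps
#'
#' The series is placed on a complete monthly grid; missing months stay NA.
#' For lag k, \eqn{r_k = \sum (x_t - \bar{x})(x_{t+k} - \bar{x}) / \sum
#' (x_t - \bar{x})^2}, the numerator over pairs where both points are
#' observed and the mean and denominator over all observed points. The
#' large-lag significance bound is \eqn{1.96/\sqrt{n}} with n the number of
#' observed points; for a complete 60-month series this is 0.253, matching
#' the conventional printed ~0.26 level at p = 0.05.
#'
#' @param values numeric observations.
#' @param monthIndex integer time index (months since series start, 1-based,
#'   strictly increasing; gaps allowed). Default: 1..length(values).
#' @param maxLag largest lag to compute (default 60).
#' @return list with \code{lag} (0..maxLag), \code{acf}, \code{bound},
#'   \code{n} (observed points), class \code{"acfResult"}.
#' @export
seasonalAcf <- function(values, monthIndex = seq_along(values),
                        maxLag = 60L) {
    monthIndex <- as.integer(monthIndex)
    if (length(values) != length(monthIndex))
        stop("values and monthIndex lengths differ")
    if (is.unsorted(monthIndex, strictly = TRUE))
        stop("monthIndex must be strictly increasing")
    grid <- rep(NA_real_, max(monthIndex))
    grid[monthIndex] <- values
    obs <- !is.na(grid)
    n <- sum(obs)
    if (n < 3L) stop("need at least 3 observed points")
    xbar <- mean(grid[obs])
    cent <- grid - xbar
    denom <- sum(cent[obs]^2)
    if (denom == 0) stop("constant series: autocorrelation undefined")
    Tn <- length(grid)
    maxLag <- min(maxLag, Tn - 1L)
    r <- vapply(0:maxLag, function(k) {
        t1 <- seq_len(Tn - k)
        prod <- cent[t1] * cent[t1 + k]
        sum(prod, na.rm = TRUE) / denom
    }, numeric(1))
    structure(list(lag = 0:maxLag, acf = r,
                   bound = qnorm(0.975) / sqrt(n), n = n),
              class = "acfResult")
}

#' @export
print.acfResult <- function(x, ...) {
    cat(sprintf("ACF over %d lags (n = %d, bound = %.3f); lag-12 r = %.3f\n",
                max(x$lag), x$n, x$bound,
                if (12 %in% x$lag) x$acf[x$lag == 12] else NA))
    invisible(x)
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of mid-ranks (ties averaged); the
#' two-sided p-value uses the t approximation.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with \code{rho} and \code{p}.
#' @examples
#' spearmanRho(1:4, c(1, 3, 2, 4))$rho   # 0.8
#' @export
spearmanRho <- function(x, y) {
    if (length(x) != length(y) || length(x) < 3L)
        stop("need equal-length vectors of length >= 3")
    if (sd(x) == 0 || sd(y) == 0) stop("constant input")
    ct <- suppressWarnings(
        cor.test(x, y, method = "spearman", exact = FALSE))
    list(rho = unname(ct$estimate), p = ct$p.value)
}
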