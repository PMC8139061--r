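#' @importFrom stats wilcox.test lm.fit cor complete.cases
NULL

#' Shannon diversity per sample
#'
#' \eqn{H = -\sum_{p_i > 0} p_i \ln p_i}, in natural-log units (nats),
#' computed on within-sample relative abundances without rarefaction.
#'
#' @param x an [AsvExperiment-class] or relative-abundance matrix
#'   (taxa x samples, columns summing to 1).
#' @param ... unused.
#' @return named numeric vector of H per sample.
#' @examples
#' p <- matrix(rep(0.25, 4), ncol = 1, dimnames = list(letters[1:4], "s"))
#' shannonDiversity(p)   # log(4)
#' @export
setMethod("shannonDiversity", "ANY", function(x, ...) {
    rel <- if (is(x, "AsvExperiment")) relAbund(x) else x
    if (any(abs(colSums(rel) - 1) > 1e-9))
        stop("columns must be relative abundances summing to 1")
    apply(rel, 2L, function(p) {
        p <- p[p > 0]
        -sum(p * log(p))
    })
})

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{BC(j,k) = \sum_i |x_{ij} - x_{ik}| / \sum_i (x_{ij} + x_{ik})}
#' between all sample pairs. On relative abundances the denominator is 2 and
#' values lie in [0, 1]: 0 for identical compositions, 1 for disjoint ones.
#'
#' @param x an [AsvExperiment-class] or abundance matrix (taxa x samples).
#' @param ... unused.
#' @return symmetric matrix, samples x samples, zero diagonal.
#' @export
setMethod("brayCurtis", "ANY", function(x, ...) {
    m <- if (is(x, "AsvExperiment")) relAbund(x) else x
    n <- ncol(m)
    if (n < 2L) stop("need at least 2 samples")
    if (any(colSums(m) == 0)) stop("all-zero sample: Bray-Curtis undefined")
    d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
    for (j in seq_len(n - 1L)) {
        xj <- m[, j]
        for (k in (j + 1L):n) {
            xk <- m[, k]
            d[j, k] <- d[k, j] <- sum(abs(xj - xk)) / sum(xj + xk)
        }
    }
    d
})

#' Principal coordinates analysis (classical MDS)
#'
#' Gower double-centering of \eqn{-d^2/2} followed by a symmetric
#' eigendecomposition. Coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues; axes with eigenvalues at or below
#' a relative tolerance are dropped from the coordinates but their
#' eigenvalues are still reported. No correction is applied for negative
#' eigenvalues; proportion explained is over positive eigenvalues only.
#' Axis signs are fixed so each axis's largest-magnitude loading is
#' positive, making results deterministic.
#'
#' @param d symmetric dissimilarity matrix with zero diagonal and sample
#'   ids as dimnames.
#' @param tol relative eigenvalue tolerance for axis retention.
#' @return an [Ordination-class].
#' @export
pcoa <- function(d, tol = 1e-9) {
    d <- as.matrix(d)
    n <- nrow(d)
    if (n < 2L) stop("need at least 2 samples")
    if (max(abs(d - t(d))) > 1e-8 || any(diag(d) != 0))
        stop("d must be symmetric with zero diagonal")
    B <- -0.5 * d^2
    ## sequential row/column sweeps give B - rowmean - colmean + grand mean
    B <- sweep(B, 1L, rowMeans(B))
    B <- sweep(B, 2L, colMeans(B))
    e <- eigen((B + t(B)) / 2, symmetric = TRUE)
    lam <- e$values
    keep <- lam > max(abs(lam)) * tol
    coords <- e$vectors[, keep, drop = FALSE] %*%
        diag(sqrt(lam[keep]), sum(keep))
    for (a in seq_len(ncol(coords))) {
        i <- which.max(abs(coords[, a]))
        if (coords[i, a] < 0) coords[, a] <- -coords[, a]
    }
    rownames(coords) <- rownames(d)
    colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
    pos <- lam[lam > 0]
    new("Ordination", coordinates = coords, eigenvalues = lam,
        propExplained = lam[keep] / sum(pos))
}

#' @describeIn Ordination sample coordinates (samples x axes)
#' @param x an Ordination
#' @export
ordCoordinates <- function(x) x@coordinates

#' @describeIn Ordination the eigenvalue spectrum
#' @export
ordEigenvalues <- function(x) x@eigenvalues

#' @describeIn Ordination proportion of positive eigenvalue mass per axis
#' @export
ordPropExplained <- function(x) x@propExplained

setMethod("show", "Ordination", function(object) {
    cat("Ordination:", nrow(object@coordinates), "samples,",
        ncol(object@coordinates), "axes\n")
    if (length(object@propExplained))
        cat("  proportion explained:",
            paste(sprintf("%.1f%%", 100 * utils::head(object@propExplained, 3)),
                  collapse = ", "), "...\n")
})

#' Mann-Whitney U test (two-sided, non-paired)
#'
#' Exact p by enumeration when the pooled size is at most 12 and there are
#' no ties; otherwise the tie-corrected normal approximation with
#' continuity correction. If every value in both samples is identical the
#' test is degenerate: U is its null mean and p = 1, with a warning.
#'
#' @param a,b numeric samples.
#' @return list with \code{U} (statistic for sample \code{a}) and \code{p}.
#' @export
mannWhitneyU <- function(a, b) {
    if (!length(a) || !length(b)) stop("both samples must be non-empty")
    if (length(unique(c(a, b))) == 1L) {
        warning("all values identical; U test degenerate")
        return(list(U = length(a) * length(b) / 2, p = 1))
    }
    ties <- anyDuplicated(c(a, b)) > 0L
    exact <- (length(a) + length(b) <= 12L) && !ties
    wt <- suppressWarnings(
        wilcox.test(a, b, exact = exact, correct = TRUE,
                    alternative = "two.sided"))
    list(U = unname(wt$statistic), p = wt$p.value)
}

permanovaStats <- function(d2, groups) {
    n <- length(groups)
    g <- nlevels(groups)
    ssTotal <- sum(d2[upper.tri(d2)]) / n
    ssWithin <- 0
    for (lv in levels(groups)) {
        idx <- which(groups == lv)
        if (length(idx) > 1L) {
            sub <- d2[idx, idx, drop = FALSE]
            ssWithin <- ssWithin + sum(sub[upper.tri(sub)]) / length(idx)
        }
    }
    ssAmong <- ssTotal - ssWithin
    list(F = (ssAmong / (g - 1)) / (ssWithin / (n - g)),
         R2 = ssAmong / ssTotal)
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Partitions the total sum of squared dissimilarities among and within
#' groups: \eqn{SS_{total} = \sum_{j<k} d_{jk}^2 / n},
#' \eqn{SS_{within} = \sum_g \sum_{j<k \in g} d_{jk}^2 / n_g},
#' pseudo-\eqn{F = (SS_{among}/(g-1)) / (SS_{within}/(n-g))},
#' \eqn{R^2 = SS_{among}/SS_{total}}. The p-value permutes group labels,
#' with the +1 numerator/denominator convention so p is never 0 and has
#' resolution 1/(nPerm + 1).
#'
#' @param d dissimilarity matrix with sample ids.
#' @param groups factor (or coercible) of group membership per sample.
#' @param nPerm number of label permutations.
#' @param seed integer seed for the permutations.
#' @return list with \code{F}, \code{R2}, \code{p}, \code{nPerm},
#'   \code{seed}, of class \code{"permanovaResult"}.
#' @export
permanova <- function(d, groups, nPerm = 9999L, seed = 1L) {
    d <- as.matrix(d)
    groups <- droplevels(factor(groups))
    n <- nrow(d)
    if (length(groups) != n) stop("one group label per sample required")
    g <- nlevels(groups)
    if (g < 2L) stop("need at least 2 groups")
    if (g >= n) stop("no residual degrees of freedom (g >= n)")
    d2 <- d^2
    obs <- permanovaStats(d2, groups)
    set.seed(seed)
    exceed <- 0L
    for (b in seq_len(nPerm)) {
        fp <- permanovaStats(d2, sample(groups))$F
        if (fp >= obs$F) exceed <- exceed + 1L
    }
    structure(list(F = obs$F, R2 = obs$R2,
                   p = (1 + exceed) / (1 + nPerm),
                   nPerm = nPerm, seed = seed),
              class = "permanovaResult")
}

#' @export
print.permanovaResult <- function(x, ...) {
    cat(sprintf("PERMANOVA: pseudo-F = %.3f, R2 = %.3f, p = %.4g (%d permutations)\n",
                x$F, x$R2, x$p, x$nPerm))
    invisible(x)
}

#' Fit an environmental variable onto ordination axes
#'
#' Least-squares fit of a numeric variable onto the first \code{nAxes}
#' ordination coordinates. \eqn{R^2} is the squared multiple correlation;
#' the direction is the unit vector of regression coefficients on the axes
#' (the arrow of the fit); significance is by permutation of the variable
#' with the +1 convention. Missing values are dropped with a message.
#'
#' @param ord an [Ordination-class].
#' @param variable numeric vector, one value per ordination sample (NAs
#'   allowed, dropped).
#' @param nAxes number of leading axes to fit onto (default 2).
#' @param nPerm permutations for the p-value.
#' @param seed integer seed.
#' @return list with \code{R2}, \code{direction} (unit vector over axes),
#'   \code{p}, \code{nUsed}, class \code{"envFitResult"}.
#' @export
envFit <- function(ord, variable, nAxes = 2L, nPerm = 999L, seed = 1L) {
    sc <- ordCoordinates(ord)
    nAxes <- min(nAxes, ncol(sc))
    sc <- sc[, seq_len(nAxes), drop = FALSE]
    if (length(variable) != nrow(sc))
        stop("variable length must equal the number of ordination samples")
    ok <- !is.na(variable)
    if (sum(!ok)) message("envFit: dropping ", sum(!ok), " missing value(s)")
    v <- variable[ok]
    sc <- sc[ok, , drop = FALSE]
    if (length(v) < 3L) stop("need at least 3 complete cases")
    if (length(unique(v)) == 1L) stop("variable is constant")

    fitR2 <- function(y) {
        f <- lm.fit(cbind(1, sc), y)
        1 - sum(f$residuals^2) / sum((y - mean(y))^2)
    }
    r2 <- fitR2(v)
    beta <- lm.fit(cbind(1, sc), v)$coefficients[-1L]
    dir <- beta / sqrt(sum(beta^2))
    set.seed(seed)
    exceed <- sum(vapply(seq_len(nPerm),
                         function(b) fitR2(sample(v)) >= r2, logical(1)))
    structure(list(R2 = r2, direction = dir,
                   p = (1 + exceed) / (1 + nPerm), nUsed = length(v),
                   nPerm = nPerm, seed = seed),
              class = "envFitResult")
}

#' @export
print.envFitResult <- function(x, ...) {
    cat(sprintf("envFit: R2 = %.3f, p = %.4g (n = %d, %d permutations)\n",
                x$R2, x$p, x$nUsed, x$nPerm))
    invisible(x)
}
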