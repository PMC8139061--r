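## Independent brute-force oracles: coded from the definitions with plain
## loops, deliberately not sharing code paths with the package.

oracleBray <- function(m) {
    n <- ncol(m)
    d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
    for (j in seq_len(n)) for (k in seq_len(n)) {
        num <- 0; den <- 0
        for (i in seq_len(nrow(m))) {
            num <- num + abs(m[i, j] - m[i, k])
            den <- den + m[i, j] + m[i, k]
        }
        d[j, k] <- num / den
    }
    diag(d) <- 0
    d
}

oracleIndval <- function(x, g) {
    mIn <- sum(x[g]) / sum(g)
    mOut <- sum(x[!g]) / sum(!g)
    A <- mIn / (mIn + mOut)
    B <- sum(x[g] > 0) / sum(g)
    sqrt(A * B)
}

oraclePermanovaF <- function(d, groups) {
    groups <- as.character(groups)
    n <- length(groups)
    ssT <- 0
    for (j in seq_len(n - 1)) for (k in (j + 1):n) ssT <- ssT + d[j, k]^2
    ssT <- ssT / n
    ssW <- 0
    for (lv in unique(groups)) {
        idx <- which(groups == lv)
        s <- 0
        if (length(idx) > 1)
            for (a in seq_len(length(idx) - 1))
                for (b in (a + 1):length(idx))
                    s <- s + d[idx[a], idx[b]]^2
        ssW <- ssW + s / length(idx)
    }
    g <- length(unique(groups))
    ((ssT - ssW) / (g - 1)) / (ssW / (n - g))
}

## exact PERMANOVA p by enumerating every labeling (small n only)
oraclePermanovaExactP <- function(d, groups) {
    n <- length(groups)
    perms <- gtoolsPerms(n)
    fObs <- oraclePermanovaF(d, groups)
    fAll <- apply(perms, 1L, function(ix) oraclePermanovaF(d, groups[ix]))
    mean(fAll >= fObs - 1e-12)
}

## all permutations of 1..n without external packages
gtoolsPerms <- function(n) {
    if (n == 1L) return(matrix(1L, 1, 1))
    sub <- gtoolsPerms(n - 1L)
    out <- NULL
    for (i in seq_len(n)) {
        rest <- seq_len(n)[-i]
        out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
    }
    unname(out)
}

oracleAcf <- function(x, maxLag) {
    n <- length(x)
    xbar <- mean(x)
    den <- sum((x - xbar)^2)
    sapply(0:maxLag, function(k) {
        s <- 0
        for (t in seq_len(n - k)) s <- s + (x[t] - xbar) * (x[t + k] - xbar)
        s / den
    })
}

## Procrustes error after optimal translation/rotation/reflection
procrustesError <- function(A, B) {
    Ac <- scale(A, scale = FALSE); Bc <- scale(B, scale = FALSE)
    sv <- svd(t(Bc) %*% Ac)
    R <- sv$v %*% t(sv$u)
    s <- sum(sv$d) / sum(Ac^2)
    max(abs(s * Ac %*% R - Bc))
}

## tiny deterministic relative-abundance fixture
randomRelTable <- function(nTaxa, nSamples, seed) {
    set.seed(seed)
    m <- matrix(rgamma(nTaxa * nSamples, 1), nTaxa, nSamples,
                dimnames = list(paste0("t", seq_len(nTaxa)),
                                paste0("s", seq_len(nSamples))))
    sweep(m, 2, colSums(m), "/")
}

## hand-built two-record reference for body-site splitting tests
tinyReference <- function(seqs, refAbund, bodySiteCounts) {
    new("ReferenceSet", sequences = seqs,
        occurrence = rep(10L, length(seqs)),
        subjectIds = rep(list("subj1"), length(seqs)),
        sampleIds = rep(list("samp1"), length(seqs)),
        bodySiteCounts = bodySiteCounts,
        refAbund = refAbund)
}
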