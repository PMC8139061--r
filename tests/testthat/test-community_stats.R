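test_that("Shannon diversity matches closed forms and vegan", {
    mk <- function(p) matrix(p, ncol = 1,
                             dimnames = list(paste0("a", seq_along(p)), "s"))
    expect_equal(unname(shannonDiversity(mk(rep(0.25, 4)))), log(4))
    expect_equal(unname(shannonDiversity(mk(1))), 0)
    expect_equal(unname(shannonDiversity(mk(c(0.5, 0.25, 0.25)))),
                 -(0.5 * log(0.5) + 0.5 * log(0.25)), tolerance = 1e-12)

    rel <- randomRelTable(8, 5, seed = 3)
    expect_equal(unname(shannonDiversity(rel)),
                 unname(vegan::diversity(t(rel), index = "shannon")),
                 tolerance = 1e-12)
})

test_that("Bray-Curtis handles identical, disjoint, and mixed profiles", {
    m <- cbind(s1 = c(0.5, 0, 0.5), s2 = c(0.5, 0, 0.5),
               s3 = c(0, 1, 0))
    rownames(m) <- paste0("a", 1:3)
    d <- brayCurtis(m)
    expect_equal(d["s1", "s2"], 0)
    expect_equal(d["s1", "s3"], 1)
    ## x=(1,0,1), y=(0,1,1) as fractions of 2
    m2 <- cbind(x = c(0.5, 0, 0.5), y = c(0, 0.5, 0.5))
    expect_equal(brayCurtis(m2)["x", "y"], 0.5)
    expect_error(brayCurtis(cbind(a = c(0, 0), b = c(1, 0))), "all-zero")
})

test_that("Bray-Curtis agrees with a brute-force oracle and vegan to 1e-12", {
    for (seed in 1:3) {
        rel <- randomRelTable(8, 5, seed = seed)
        d <- brayCurtis(rel)
        expect_equal(d, oracleBray(rel), tolerance = 1e-12)
        expect_equal(d[lower.tri(d)],
                     as.vector(vegan::vegdist(t(rel), "bray")),
                     tolerance = 1e-12)
        expect_equal(d, t(d))
        expect_true(all(diag(d) == 0))
    }
})

test_that("PCoA geometry: two points, simplex, duplicates", {
    d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
    ord <- pcoa(d2)
    expect_equal(sort(ordCoordinates(ord)[, 1]), c(-1.5, 1.5),
                 ignore_attr = TRUE)

    ## three equidistant samples: two equal positive eigenvalues
    d3 <- matrix(1, 3, 3) - diag(3)
    dimnames(d3) <- list(letters[1:3], letters[1:3])
    ev <- ordEigenvalues(pcoa(d3))
    expect_equal(ev[1], ev[2], tolerance = 1e-10)
    expect_gt(ev[1], 0)

    ## duplicated sample lands on identical coordinates
    d4 <- as.matrix(dist(c(0, 0, 2, 5)))
    dimnames(d4) <- list(paste0("s", 1:4), paste0("s", 1:4))
    co <- ordCoordinates(pcoa(d4))
    expect_equal(co["s1", ], co["s2", ], tolerance = 1e-10)
    expect_error(pcoa(matrix(0, 1, 1)), "at least 2")
})

test_that("PCoA of Euclidean distances recovers the configuration", {
    set.seed(9)
    pts <- cbind(rnorm(12), rnorm(12))
    rownames(pts) <- paste0("s", 1:12)
    d <- as.matrix(dist(pts))
    ord <- pcoa(d)
    co <- ordCoordinates(ord)[, 1:2]
    expect_lt(procrustesError(co, pts), 1e-8)
    ## cross-check eigenvalues against ape
    ap <- ape::pcoa(d)
    expect_equal(ordEigenvalues(ord)[1:2], unname(ap$values$Eigenvalues[1:2]),
                 tolerance = 1e-8)
    expect_lte(sum(ordPropExplained(ord)), 1 + 1e-12)
})

test_that("Mann-Whitney U: exact enumeration, degenerate, and shifted cases", {
    r <- mannWhitneyU(c(1, 2), c(3, 4))
    expect_equal(r$U, 0)
    expect_equal(r$p, 1 / 3, tolerance = 1e-12)   # 2/C(4,2)

    expect_warning(rd <- mannWhitneyU(c(5, 5), c(5, 5)), "identical")
    expect_equal(rd$p, 1)

    set.seed(4)
    rs <- mannWhitneyU(rnorm(40), rnorm(40) + 2)
    expect_lt(rs$p, 0.05)
    expect_error(mannWhitneyU(numeric(0), 1), "non-empty")
})

test_that("PERMANOVA matches vegan and full enumeration on small designs", {
    set.seed(21)
    rel <- randomRelTable(10, 8, seed = 21)
    d <- brayCurtis(rel)
    g <- rep(c("A", "B"), each = 4)
    res <- permanova(d, g, nPerm = 199, seed = 1)
    dd <- as.dist(d)
    ad <- vegan::adonis2(dd ~ g, data = data.frame(g = g),
                         permutations = 199)
    expect_equal(res$F, ad$F[1], tolerance = 1e-10)
    expect_equal(res$R2, ad$R2[1], tolerance = 1e-10)
    expect_equal(res$F, oraclePermanovaF(d, g), tolerance = 1e-12)

    ## n = 4, 2+2: permutation p approaches the exact enumerated value
    d4 <- as.matrix(dist(c(0, 0.1, 5, 5.2)))
    dimnames(d4) <- list(paste0("s", 1:4), paste0("s", 1:4))
    g4 <- c("A", "A", "B", "B")
    exact <- oraclePermanovaExactP(d4, g4)
    res4 <- permanova(d4, g4, nPerm = 1999, seed = 2)
    expect_equal(res4$F, oraclePermanovaF(d4, g4), tolerance = 1e-12)
    expect_lt(abs(res4$p - exact), 0.05)
})

test_that("PERMANOVA null structure, separation floor, and invariances", {
    ## identical within/between distances: R2 ~ 0, p ~ 1
    dEq <- matrix(1, 6, 6) - diag(6)
    dimnames(dEq) <- list(paste0("s", 1:6), paste0("s", 1:6))
    g <- rep(c("A", "B"), 3)
    rEq <- permanova(dEq, g, nPerm = 99, seed = 1)
    expect_equal(rEq$F, 1, tolerance = 1e-12)   # no group structure at all
    expect_lt(rEq$R2, 0.25)                     # at its null expectation
    expect_equal(rEq$p, 1)                      # every permutation ties F

    ## perfectly separated clusters hit the resolution floor
    pts <- c(seq(0, 0.09, by = 0.01), seq(10, 10.09, by = 0.01))
    dSep <- as.matrix(dist(pts))
    dimnames(dSep) <- list(paste0("s", 1:20), paste0("s", 1:20))
    gs <- rep(c("A", "B"), each = 10)
    rSep <- permanova(dSep, gs, nPerm = 199, seed = 3)
    expect_equal(rSep$p, 1 / 200)

    ## R2 invariant to consistent relabeling of samples
    perm <- sample(20)
    r2a <- permanova(dSep, gs, nPerm = 9, seed = 1)$R2
    r2b <- permanova(dSep[perm, perm], gs[perm], nPerm = 9, seed = 1)$R2
    expect_equal(r2a, r2b, tolerance = 1e-12)

    expect_error(permanova(dSep, seq_len(20), nPerm = 9), "residual")
    expect_error(permanova(dSep, rep("A", 20), nPerm = 9), "2 groups")
})

test_that("envfit recovers exact linear structure and matches vegan R2", {
    set.seed(31)
    pts <- cbind(rnorm(15), rnorm(15))
    rownames(pts) <- paste0("s", 1:15)
    ord <- pcoa(as.matrix(dist(pts)))
    ax <- ordCoordinates(ord)

    r1 <- envFit(ord, ax[, 1], nPerm = 99, seed = 1)
    expect_equal(r1$R2, 1, tolerance = 1e-10)
    r12 <- envFit(ord, ax[, 1] + ax[, 2], nPerm = 99, seed = 1)
    expect_equal(r12$R2, 1, tolerance = 1e-10)
    expect_equal(sum(r12$direction^2), 1, tolerance = 1e-12)

    v <- ax[, 1] * 2 + rnorm(15)
    rv <- envFit(ord, v, nPerm = 99, seed = 1)
    vg <- vegan::envfit(ax[, 1:2], data.frame(v = v), permutations = 0)
    expect_equal(unname(rv$R2), unname(vg$vectors$r["v"]), tolerance = 1e-8)

    expect_error(envFit(ord, rep(1, 15)), "constant")
    vNA <- v; vNA[1:13] <- NA
    expect_error(suppressMessages(envFit(ord, vNA)), "complete cases")
})
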