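## small deterministic fixture: 2 families x 4 RILs
handCase <- function() {
    fams <- rep(c("f1", "f2"), each = 4)
    marker <- c(0, 0, 2, 2, 0, 2, 0, 2)
    y <- c(1.0, 1.2, 3.1, 2.9, 0.4, 1.9, 0.6, 2.1)
    names(y) <- sprintf("l%d", 1:8)
    list(y = y, fams = fams,
         markers = matrix(marker, 8, 1, dimnames = list(names(y), "m1")))
}

test_that("nested marker F equals a from-scratch normal-equations fit", {
    hc <- handCase()
    res <- nestedMarkerTest(hc$y, hc$fams, hc$markers[, 1])
    ## direct lm: family means + per-family slopes
    d <- data.frame(y = hc$y, fam = hc$fams, m = hc$markers[, 1])
    fit0 <- lm(y ~ fam, data = d)
    fit1 <- lm(y ~ fam + fam:m, data = d)
    a <- anova(fit0, fit1)
    expect_equal(res$F, a$F[2], tolerance = 1e-10)
    expect_equal(res$p, a$`Pr(>F)`[2], tolerance = 1e-10)
    expect_equal(res$df1, 2L)
    ## marker monomorphic everywhere is skipped
    skip_ <- nestedMarkerTest(hc$y, hc$fams, rep(0, 8))
    expect_true(skip_$skipped)
})

test_that("fast scan reproduces the direct nested test", {
    set.seed(6)
    n <- 120
    fams <- rep(c("a", "b", "c"), each = 40)
    mk <- matrix(sample(c(0L, 2L, NA), n * 8, TRUE, prob = c(.45, .45, .1)),
                 n, 8, dimnames = list(sprintf("l%03d", 1:n),
                                       paste0("m", 1:8)))
    y <- rnorm(n) + 0.8 * ifelse(is.na(mk[, 3]), 1, mk[, 3])
    names(y) <- rownames(mk)
    prep <- nambin:::.jlPrep(fams, mk)
    yc <- nambin:::.centerWithin(y, prep$famIdx)
    P <- nambin:::.scanNestedP(prep$M, prep$famIdx, yc, p0 = 3, n = n)[, 1]
    for (j in c(1, 3, 5)) {
        ## mean-impute within family exactly as the scan does
        mcol <- mk[, j]
        for (f in unique(fams)) {
            rows <- fams == f
            mu <- mean(mcol[rows], na.rm = TRUE)
            mcol[rows][is.na(mcol[rows])] <- mu
        }
        direct <- nestedMarkerTest(y, fams, mcol)
        expect_equal(P[j], direct$p, tolerance = 1e-8, label = paste("m", j))
    }
})

test_that("a perfectly fitting marker underflows to the minimum P", {
    hc <- handCase()
    y <- as.numeric(hc$markers[, 1]) * 2 + rep(c(0, 5), each = 4)
    names(y) <- names(hc$y)
    res <- nestedMarkerTest(y, hc$fams, hc$markers[, 1])
    expect_lt(res$p, 1e-12)
})

test_that("permutation threshold approximates Sidak for independent markers", {
    set.seed(11)
    n <- 300; K <- 40
    fams <- rep(c("f1", "f2", "f3"), each = 100)
    mk <- matrix(sample(c(0L, 2L), n * K, TRUE), n, K,
                 dimnames = list(sprintf("l%03d", 1:n), paste0("m", 1:K)))
    y <- rnorm(n); names(y) <- rownames(mk)
    thr <- permutationThreshold(y, fams, mk, alpha = 0.05, n_perm = 400,
                                seed = 13)
    sidak <- 1 - (1 - 0.05)^(1 / K)
    ## Monte-Carlo agreement within a factor ~2 on the log scale
    expect_gt(thr$p_enter, sidak / 3)
    expect_lt(thr$p_enter, sidak * 3)
    ## alpha = 1 returns the largest recorded minimum
    thr1 <- permutationThreshold(y, fams, mk, alpha = 1, n_perm = 400,
                                 seed = 13)
    expect_equal(thr1$p_enter, max(thr1$minP))
    ## determinism under a fixed seed
    thr2 <- permutationThreshold(y, fams, mk, alpha = 0.05, n_perm = 400,
                                 seed = 13)
    expect_identical(thr$p_enter, thr2$p_enter)
    expect_error(permutationThreshold(y, fams, mk, n_perm = 10), "100")
})

test_that("stepwise selection agrees with best subset on a strong toy", {
    set.seed(21)
    n <- 240
    fams <- rep(c("f1", "f2"), each = 120)
    mk <- matrix(sample(c(0L, 2L), n * 6, TRUE), n, 6,
                 dimnames = list(sprintf("l%03d", 1:n), paste0("m", 1:6)))
    y <- rnorm(n, sd = 0.5) + 2 * mk[, 2] + 1.5 * mk[, 5]
    names(y) <- rownames(mk)
    fit <- stepwiseSelect(y, fams, mk, threshold = 1e-4)
    expect_setequal(fit$selected, c("m2", "m5"))
    ## exhaustive best subset of size 2 (by RSS) picks the same pair
    best <- NULL; bestRSS <- Inf
    for (i in 1:5) for (j in (i + 1):6) {
        d <- data.frame(y = y, fam = fams, a = mk[, i], b = mk[, j])
        rss <- sum(resid(lm(y ~ fam + fam:a + fam:b, data = d))^2)
        if (rss < bestRSS) { bestRSS <- rss; best <- c(i, j) }
    }
    expect_setequal(paste0("m", best), fit$selected)
    ## family terms always survive
    expect_true(all(paste0("fam:", c(1, 2)) %in% colnames(fit$X) |
                    any(grepl("^fam:", colnames(fit$X)))))
})

test_that("LOD follows (n/2) log10(RSS ratio) and profiles peak correctly", {
    set.seed(31)
    bp <- binPanel(2, 120, 40, LcM = 100, seed = 31)
    g <- bp$genotypes
    y <- 60 + 1.5 * g[, 20] + rnorm(nrow(g), 0, 1)
    names(y) <- rownames(g)
    fit <- stepwiseSelect(y, bp$families, g, threshold = 1e-3)
    expect_true("bin0020" %in% fit$selected ||
                any(fit$selected %in% c("bin0019", "bin0021")))
    qtl <- fit$selected[1]
    pr <- lodProfile(fit, qtl, g, bp$map)
    ## hand-recompute one LOD value
    others <- setdiff(fit$selected, qtl)
    d <- data.frame(y = y, fam = bp$families)
    rss0 <- sum(resid(lm(y ~ fam, data = d))^2)
    cand <- pr$marker[1]
    d$m <- g[, cand]
    rss1 <- sum(resid(lm(y ~ fam + fam:m, data = d))^2)
    if (!length(others))
        expect_equal(pr$LOD[1], (length(y) / 2) * log10(rss0 / rss1),
                     tolerance = 1e-8)
    expect_gte(min(pr$LOD), 0)
    ## peak at the selected marker
    expect_equal(pr$marker[which.max(pr$LOD)], qtl)
})

test_that("the 2-LOD interval rule matches its worked examples", {
    prof <- data.frame(marker = c("a", "b", "c"), chrom = "chr1",
                       pos = c(100, 200, 300), cM = c(0, 1, 2),
                       LOD = c(3, 8, 3))
    ci <- ci2Lod(prof)
    expect_equal(ci$lo, 1)
    expect_equal(ci$hi, 3)
    expect_equal(ci$bp, c(100, 300))
    expect_false(ci$truncated)
    ## peak-only window degenerates to a single marker
    one <- ci2Lod(prof[2, ])
    expect_equal(one$lo, 1)
    expect_equal(one$hi, 1)
    expect_true(one$truncated)
    ## flat profile: full window, truncated
    flat <- prof; flat$LOD <- c(5, 5, 5)
    cf <- ci2Lod(flat)
    expect_equal(c(cf$lo, cf$hi), c(1, 3))
    expect_true(cf$truncated)
})

test_that("allele effects recover a noiseless per-family effect exactly", {
    set.seed(41)
    n <- 200
    fams <- rep(c("f1", "f2"), each = 100)
    mk <- matrix(sample(c(0L, 2L), n * 3, TRUE), n, 3,
                 dimnames = list(sprintf("l%03d", 1:n), paste0("m", 1:3)))
    y <- 10 + 1.0 * mk[, 2] * (fams == "f1")     # +1 day/allele in f1 only
    names(y) <- rownames(mk)
    fit <- stepwiseSelect(y, fams, mk, threshold = 1e-3)
    eff <- alleleEffects(fit)
    e1 <- eff$effect[eff$marker == "m2" & eff$family == "f1"]
    e2 <- eff$effect[eff$marker == "m2" & eff$family == "f2"]
    expect_equal(e1, 1.0, tolerance = 1e-8)
    expect_equal(e2, 0.0, tolerance = 1e-8)
})

test_that("null responses rarely enter the model (type-I control)", {
    bp <- binPanel(3, 60, 50, LcM = 100, seed = 51)
    hits <- 0
    for (r in 1:12) {
        set.seed(300 + r)
        y <- rnorm(nrow(bp$genotypes), 60, 2)
        names(y) <- rownames(bp$genotypes)
        thr <- permutationThreshold(y, bp$families, bp$genotypes,
                                    n_perm = 200, seed = r)
        f <- stepwiseSelect(y, bp$families, bp$genotypes, thr)
        hits <- hits + (length(f$selected) > 0)
    }
    ## ~5% true rate: 12 draws should almost never produce 3+ hits
    expect_lte(hits, 2)
})
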