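test_that("blocks and breakpoints follow the midpoint rule", {
    cb <- callBlocks(c(0L, 0L, 2L), c(100, 200, 300))
    expect_equal(cb$blocks$start, c(100, 300))
    expect_equal(cb$blocks$end, c(200, 300))
    expect_equal(cb$blocks$genotype, c(0L, 2L))
    expect_equal(cb$breakpoints, 250)
    ## single state: one block, no breakpoints
    cb2 <- callBlocks(rep(2L, 5), 1:5 * 100)
    expect_equal(nrow(cb2$blocks), 1)
    expect_length(cb2$breakpoints, 0)
    ## NA does not interrupt a run
    cb3 <- callBlocks(c(0L, NA, 0L, 2L), c(10, 20, 30, 40))
    expect_equal(nrow(cb3$blocks), 2)
    expect_equal(cb3$blocks$n_snps, c(2L, 1L))
})

test_that("block count equals transitions + 1 on random instances", {
    for (seed in 1:10) {
        set.seed(seed)
        st <- sample(c(0L, 2L, NA), 60, TRUE)
        pos <- sort(sample.int(1e6, 60))
        cb <- callBlocks(st, pos)
        inf <- st[!is.na(st)]
        if (!length(inf)) {
            expect_equal(nrow(cb$blocks), 0)
        } else {
            expect_equal(nrow(cb$blocks), sum(diff(inf) != 0) + 1)
            expect_equal(length(cb$breakpoints), nrow(cb$blocks) - 1)
        }
    }
})

test_that("the short-block mask is a strict conjunction", {
    mk <- function(len, nsnps, geno = 2L)
        data.frame(start = 1e7, end = 1e7 + len - 1, genotype = geno,
                   n_snps = nsnps)
    blocks <- rbind(mk(5e6, 50, 0L),
                    data.frame(start = 1.6e7, end = 1.6e7 + 1.4e6 - 1,
                               genotype = 2L, n_snps = 4),   # masked
                    data.frame(start = 1.8e7, end = 3e7, genotype = 0L,
                               n_snps = 60))
    out <- maskShortBlocks(blocks)
    expect_equal(nrow(out), 1)            # flanks re-merged (same genotype)
    expect_equal(out$n_snps, 110L)
    ## 1,600 kb with 3 SNPs survives (length clears the bar)
    b2 <- rbind(mk(5e6, 50, 0L),
                data.frame(start = 1.6e7, end = 1.6e7 + 1.6e6 - 1,
                           genotype = 2L, n_snps = 3),
                data.frame(start = 1.9e7, end = 3e7, genotype = 0L,
                           n_snps = 60))
    expect_equal(nrow(maskShortBlocks(b2)), 3)
    ## 1,400 kb with 6 SNPs survives (support clears the bar)
    b3 <- rbind(mk(5e6, 50, 0L),
                data.frame(start = 1.6e7, end = 1.6e7 + 1.4e6 - 1,
                           genotype = 2L, n_snps = 6),
                data.frame(start = 1.8e7, end = 3e7, genotype = 0L,
                           n_snps = 60))
    expect_equal(nrow(maskShortBlocks(b3)), 3)
})

test_that("two RILs with breakpoints at 250 and 750 give three bins", {
    pos <- c(100, 200, 300, 500, 700, 800)
    decoded <- rbind(r1 = c(0L, 0L, 2L, 2L, 2L, 2L),
                     r2 = c(0L, 0L, 0L, 0L, 0L, 2L))
    bm <- buildFamilyBins(decoded, pos, "chr1", 1000, "famX",
                          min_bp = 0, min_snps = 0)
    bins <- binRanges(bm)
    expect_length(bins, 3)
    expect_equal(start(bins), c(1, 251, 751))
    expect_equal(end(bins), c(250, 750, 1000))
    expect_identical(unname(binGenotypes(bm)["r1", ]), c(0L, 2L, 2L))
    expect_identical(unname(binGenotypes(bm)["r2", ]), c(0L, 0L, 2L))
})

test_that("identical RILs collapse to one bin per chromosome", {
    decoded <- rbind(r1 = rep(0L, 5), r2 = rep(0L, 5))
    bm <- buildFamilyBins(decoded, 1:5 * 1000, "chr1", 10000, "famX")
    expect_length(binRanges(bm), 1)
    expect_equal(width(binRanges(bm)), 10000)
    expect_error(buildFamilyBins(decoded[1, , drop = FALSE], 1:5 * 1000,
                                 "chr1", 10000, "famX"), "2 RILs")
})

test_that("bin expansion reproduces the post-mask decoded genotypes", {
    sp <- smallPanel()
    panel <- sp$panel
    gf <- prefilterFamilySites(
        panel$geno[familyOf(panel$geno) == "fam02", ])
    asg <- refineByResampling(gf, inferAssignmentParsimony(gf), 100)
    bm <- familyBinMap(gf, asg, c(chr1 = 1e8), c(chr1 = 1e-6))
    dec <- attr(bm, "decoded")
    pos <- start(siteRanges(gf))[attr(bm, "sites")]
    exp <- expandBinsToSites(bm, pos, "chr1")
    ## every decoded (post-mask) non-NA site genotype is reproduced
    cmp <- is.na(dec) | exp == dec
    expect_gte(mean(cmp, na.rm = TRUE), 0.9999)
})

test_that("small bins merge into the next bin (strict < 5 kb)", {
    bm <- binMap(data.frame(chrom = "chr1", start = c(1, 3001, 103001),
                            end = c(3000, 103000, 200000)),
                 rbind(r1 = c(0L, 0L, 2L), r2 = c(2L, 0L, 2L)),
                 "famX")
    out <- mergeSmallBins(bm)
    expect_length(binRanges(out), 2)
    expect_equal(start(binRanges(out)), c(1, 103001))
    ## r1 agrees across constituents; r2 conflicts (2 vs 0) -> NA
    expect_identical(unname(binGenotypes(out)[, 1]), c(0L, NA))
    ## exactly 5 kb is kept
    bm2 <- binMap(data.frame(chrom = "chr1", start = c(1, 5001),
                             end = c(5000, 20000)),
                  rbind(r1 = c(0L, 2L), r2 = c(2L, 0L)), "famX")
    expect_length(binRanges(mergeSmallBins(bm2)), 2)
    ## a tiny final bin merges backward
    bm3 <- binMap(data.frame(chrom = "chr1", start = c(1, 98001),
                             end = c(98000, 100000)),
                  rbind(r1 = c(0L, 0L), r2 = c(2L, 2L)), "famX")
    out3 <- mergeSmallBins(bm3)
    expect_length(binRanges(out3), 1)
    expect_equal(end(binRanges(out3)), 100000)
})

test_that("transition imputation fills NA by flanks or posterior", {
    bm <- binMap(data.frame(chrom = "chr1",
                            start = c(1, 10001, 20001, 30001, 40001),
                            end = c(10000, 20000, 30000, 40000, 50000)),
                 rbind(r1 = c(0L, NA, 0L, NA, 2L),
                       r2 = c(2L, 2L, 2L, 2L, 2L)),
                 "famX")
    out <- imputeTransitionBins(bm, cm_per_bp = 1e-5)
    g <- binGenotypes(out)
    expect_identical(unname(g["r1", 2]), 0L)       # agreeing flanks
    expect_false(anyNA(g))
    ## disagreeing flanks: the HMM assigns the nearer state; position 4 is
    ## 10 bins... compare against the brute-force posterior
    v <- c(0L, NA, 0L, NA, 2L)
    mids <- (c(1, 10001, 20001, 30001, 40001) +
             c(10000, 20000, 30000, 40000, 50000)) / 2 * 1e-5
    bf <- bruteForcePosterior(v, mids, hmmParams(p_min = 0.5))
    expect_identical(unname(g["r1", 4]),
                     if (bf[4, "common"] >= 0.5) 0L else 2L)
    ## identity on complete input
    expect_identical(binGenotypes(imputeTransitionBins(out)),
                     binGenotypes(out))
    ## an all-NA line is reported, not fabricated
    bm2 <- binMap(data.frame(chrom = "chr1", start = c(1, 10001),
                             end = c(10000, 20000)),
                  rbind(r1 = c(NA_integer_, NA_integer_),
                        r2 = c(0L, 2L)), "famX")
    out2 <- imputeTransitionBins(bm2)
    expect_identical(attr(out2, "unimputed"), "r1")
    expect_true(all(is.na(binGenotypes(out2)["r1", ])))
})

test_that("breakpoint recovery metrics match a hand-checked case", {
    bm <- binMap(data.frame(chrom = "chr1",
                            start = c(1, 1001, 2001, 3001),
                            end = c(1000, 2000, 3000, 4000)),
                 rbind(r1 = c(0L, 0L, 2L, 2L), r2 = c(0L, 2L, 2L, 0L)),
                 "famX")
    pred <- predictedBreakpoints(bm)
    expect_equal(nrow(pred), 3)
    truth <- new("TruthSet",
                 segments = GRanges("chr1", IRanges(1, 4000), ril = "r1",
                                    family = "famX", parent = "common"),
                 breakpoints = data.frame(ril = c("r1", "r2"),
                                          family = "famX", chrom = "chr1",
                                          pos = c(2100, 950)),
                 founders = list(), qtl = data.frame())
    rec <- breakpointRecovery(bm, pred, truth)
    ## r1's true 2100 matches the predicted 2000.5 boundary; r2's 950
    ## matches 1000.5; r2's second prediction (3000.5) is spurious
    expect_equal(rec$nRecovered, 2)
    expect_equal(rec$recall, 1)
    expect_equal(rec$spuriousRate, 0.5)
})
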