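test_that("family prefilter removes low-MAF and same-tag sites", {
    calls <- rbind(c("A", "A", "B", "A"),
                   c("B", "B", "A", "A"),
                   c("A", NA,  "B", "A"),
                   c("B", "B", NA,  "A"))
    rownames(calls) <- paste0("r", 1:4)
    colnames(calls) <- paste0("s", 1:4)
    ## sites 1,2 are 50 bp apart (same tag); site 4 is monomorphic-ish
    gm <- genotypeMatrix(calls,
                         data.frame(chrom = "chr1",
                                    pos = c(100, 150, 300, 400),
                                    alleleA = "A", alleleB = "C"), "f")
    out <- prefilterFamilySites(gm)
    ## s1 has call rate 1 > s2 (0.75): keep s1; s4 MAF 0 removed
    expect_identical(names(siteRanges(out)), c("s1", "s3"))
    ## sites 100 bp apart are both kept
    gm2 <- gm[, c(1, 3)]
    expect_length(siteRanges(prefilterFamilySites(gm2)), 2)
})

test_that("MAF 0.04 sites are removed and 0.06 kept by the prefilter", {
    nl <- 50
    calls <- cbind(rep(c("A", "B"), c(48, 2)),   # MAF 0.04 -> removed
                   rep(c("A", "B"), c(47, 3)),   # MAF 0.06 -> kept
                   rep(c("A", "B"), c(25, 25)))
    rownames(calls) <- sprintf("r%02d", 1:nl)
    colnames(calls) <- c("low", "ok", "good")
    gm <- genotypeMatrix(calls,
                         data.frame(chrom = "chr1", pos = c(1e3, 1e4, 1e5),
                                    alleleA = "A", alleleB = "C"), "f")
    expect_identical(names(siteRanges(prefilterFamilySites(gm))),
                     c("ok", "good"))
})

test_that("parsimony DP equals the exhaustive minimum on small instances", {
    for (seed in 1:25) {
        set.seed(seed)
        k <- sample(2:12, 1)
        n <- sample(1:6, 1)
        m <- matrix(sample(c(0, 1, NA), n * k, TRUE, prob = c(.4, .4, .2)),
                    n, k)
        keep <- colSums(!is.na(m)) > 0
        m <- m[, keep, drop = FALSE]
        if (ncol(m) < 2) next
        calls <- ifelse(is.na(m), NA, ifelse(m == 0, "A", "B"))
        colnames(calls) <- paste0("s", seq_len(ncol(calls)))
        rownames(calls) <- paste0("r", seq_len(nrow(calls)))
        asg <- inferAssignmentParsimony(calls, margin = 0)
        expect_equal(asg$switches, bruteForceParsimony(m),
                     label = paste("seed", seed))
    }
})

test_that("a single RIL's minimum equals its observed transition count", {
    calls <- matrix(c("A", "B", "B", NA, "A"), 1,
                    dimnames = list("r1", paste0("s", 1:5)))
    asg <- inferAssignmentParsimony(calls, margin = 0)
    expect_equal(asg$switches, 0)   # a free assignment absorbs every switch
    m <- nambin:::.ab01(calls)
    expect_equal(bruteForceParsimony(m), 0)
})

test_that("assignment is invariant to global allele relabeling (sign)", {
    sp <- smallPanel()
    gf <- prefilterFamilySites(
        sp$panel$geno[familyOf(sp$panel$geno) == "fam01", ])
    calls <- genoCalls(gf)
    asg1 <- inferAssignmentParsimony(calls)
    swapped <- calls
    swapped[calls == "A"] <- "B"
    swapped[calls == "B"] <- "A"
    asg2 <- inferAssignmentParsimony(swapped)
    both <- !is.na(asg1$assignment) & !is.na(asg2$assignment)
    agree <- mean(asg1$assignment[both] == (1L - asg2$assignment[both]))
    expect_gte(max(agree, 1 - agree), 0.999)
})

test_that("noiseless simulation assigns every retained site correctly", {
    sp <- smallPanel()
    panel <- sp$panel
    gf <- panel$trueGeno[familyOf(panel$trueGeno) == "fam01", ]
    gf <- prefilterFamilySites(gf)
    asg <- inferAssignmentParsimony(gf)
    idx <- match(names(siteRanges(gf)), names(panel$founders$sites))
    trueA <- ifelse(panel$founders$commonAllele[idx] == "A", 0L, 1L)
    keep <- !is.na(asg$assignment)
    agree <- mean(asg$assignment[keep] == trueA[keep])
    expect_gte(max(agree, 1 - agree), 1)
})

test_that("anchoring to known common-parent calls fixes the global sign", {
    sp <- smallPanel()
    panel <- sp$panel
    gf <- prefilterFamilySites(
        panel$geno[familyOf(panel$geno) == "fam01", ])
    idx <- match(names(siteRanges(gf)), names(panel$founders$sites))
    trueCommon <- ifelse(panel$founders$commonAllele[idx] == "A", "A", "B")
    anchor <- setNames(trueCommon[1:50], names(siteRanges(gf))[1:50])
    asg <- inferAssignmentParsimony(gf, anchor = anchor)
    trueA <- ifelse(trueCommon == "A", 0L, 1L)
    keep <- !is.na(asg$assignment)
    expect_gte(mean(asg$assignment[keep] == trueA[keep]), 0.99)
})

test_that("resampling keeps clean sites and drops a noise column", {
    sp <- smallPanel()
    panel <- sp$panel
    gf <- panel$trueGeno[familyOf(panel$trueGeno) == "fam01", ]
    gf <- prefilterFamilySites(gf)
    gf <- gf[, 1:120]
    asg <- inferAssignmentParsimony(gf)
    ## noiseless data: everything confident, nothing dropped
    ref <- refineByResampling(gf, asg, n_resamples = 100)
    expect_true(all(ref$q[!is.na(ref$assignment)] >= 0.9))
    expect_length(ref$dropped, 0)
    ## corrupt one column into pure noise: its q collapses
    calls <- genoCalls(gf)
    set.seed(5)
    calls[, 60] <- sample(c("A", "B"), nrow(calls), TRUE)
    asg2 <- inferAssignmentParsimony(calls, margin = 0)
    ref2 <- refineByResampling(calls, asg2, n_resamples = 200)
    expect_lt(ref2$q[60], 0.9)
    expect_true(names(ref2$q)[60] %in% ref2$dropped)
    ## precondition: too few resamples is an error
    expect_error(refineByResampling(calls, asg2, n_resamples = 0),
                 "at least 100")
})

test_that("origin encoding maps calls through the assignment", {
    calls <- matrix(c("A", "B", "H", NA), 1,
                    dimnames = list("r", paste0("s", 1:4)))
    asg <- structure(list(assignment = setNames(c(0L, 1L, 0L, 0L),
                                                colnames(calls))),
                     class = "ParentalAssignment")
    enc <- encodeOrigins(calls, asg)
    ## s1: A with "A common" -> 0; s2: B with "B common" -> 0;
    ## s3: H -> NA; s4: missing -> NA
    expect_identical(unname(enc$origins[1, ]), c(0L, 0L, NA, NA))
})

test_that("het-region masking removes undercalled runs, keeps clean data", {
    set.seed(2)
    calls <- matrix(sample(c("A", "B"), 300, TRUE), 2, 150,
                    dimnames = list(c("r1", "r2"), NULL))
    expect_identical(maskHetRegions(calls), calls)   # no H anywhere
    calls2 <- calls
    calls2[1, 60:80] <- sample(c("A", "B", "H"), 21, TRUE,
                               prob = c(.25, .25, .5))
    masked <- maskHetRegions(calls2)
    expect_true(all(is.na(masked[1, 62:78])))
    expect_identical(masked[2, ], calls2[2, ])
})
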