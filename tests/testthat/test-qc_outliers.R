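test_that("site filter applies strict thresholds and matches a recount", {
    ## MAF exactly at the threshold is removed (strict ">")
    calls <- rbind(matrix("A", 99, 3), matrix("B", 1, 3))
    rownames(calls) <- sprintf("l%03d", 1:100)
    gm <- genotypeMatrix(calls,
                         data.frame(chrom = "chr1", pos = c(10, 20, 30),
                                    alleleA = "A", alleleB = "C"), "f")
    expect_warning(out <- filterSites(gm, siteFilter(min_maf = 0.01)),
                   "all sites removed")
    expect_length(siteRanges(out), 0)
    kept <- filterSites(gm, siteFilter(min_maf = 0.0099))
    expect_length(siteRanges(kept), 3)
    ## with zero thresholds, polymorphic sites survive but a monomorphic
    ## one (MAF 0, not > 0) does not
    gm2 <- tinyGM()
    keptIds <- names(siteRanges(filterSites(gm2, siteFilter(0, 0, 0))))
    expect_identical(keptIds, c("s1", "s2"))
    ## independent recount oracle on a random matrix
    gm3 <- randomGM(20, 100, seed = 44)
    flt <- siteFilter(0.5, 0.2, 0.6)
    res <- filterSites(gm3, flt)
    c3 <- genoCalls(gm3)
    nA <- colSums(c3 == "A", na.rm = TRUE) * 2 + colSums(c3 == "H", na.rm = TRUE)
    nB <- colSums(c3 == "B", na.rm = TRUE) * 2 + colSums(c3 == "H", na.rm = TRUE)
    maf <- pmin(nA, nB) / (nA + nB)
    keepS <- maf > 0.2 & colMeans(!is.na(c3)) > 0.6
    keepL <- rowMeans(!is.na(c3)) > 0.5
    expect_identical(names(siteRanges(res)), colnames(c3)[keepS])
    expect_identical(lineNames(res), rownames(c3)[keepL])
})

test_that("excess-het scan flags strictly above 10% on retained sites", {
    ## 100 fully observed, balanced sites; one line with 15 hets
    set.seed(7)
    calls <- matrix(sample(c("A", "B"), 20 * 100, TRUE), 20, 100,
                    dimnames = list(sprintf("l%02d", 1:20), NULL))
    calls["l01", 1:15] <- "H"     # ratio 0.15
    calls["l02", 1:10] <- "H"     # ratio exactly 0.10 -> not flagged
    gm <- genotypeMatrix(calls,
                         data.frame(chrom = "chr1", pos = seq_len(100) * 10,
                                    alleleA = "A", alleleB = "C"), "f")
    rep <- excessHetScan(gm, min_site_coverage = 0, min_maf = 0)
    flagged <- rep$line[rep$reason == "excess_het"]
    expect_true("l01" %in% flagged)
    expect_false("l02" %in% flagged)
    expect_false("l03" %in% flagged)   # zero hets
})

test_that("contaminant scan flags cross-family copies, spares honest lines", {
    cfg <- simConfig(n_families = 3, rils_per_family = 50,
                     chromosomes = data.frame(chrom = c("chr1", "chr2"),
                                              length_bp = c(1e8, 8e7),
                                              length_cM = c(100, 80)),
                     n_sites = 2000, seed = 17)
    panel <- simulateNAMPanel(cfg)
    inj <- injectOutliers(panel$geno, n_contaminants = 8, n_excess_het = 0,
                          seed = 18)
    parents <- founderGenotypes(panel$founders)
    fams <- unique(familyOf(panel$geno))
    parentOf <- setNames(paste0(fams, "_parent"), fams)
    scan <- njContaminantScan(filterSites(inj$geno), parents, parentOf)
    flagged <- scan$line[scan$reason == "contaminant"]
    labs <- inj$labels
    ## only contaminants that actually carry non-parental alleles are
    ## detectable: require >= 10% foreign-diverse genome in the source
    seg <- trueSegments(panel$truth)
    divFrac <- vapply(labs$source, function(s) {
        ss <- seg[seg$ril == s]
        sum(width(ss)[ss$parent == "diverse"]) / sum(width(ss))
    }, 0)
    detectable <- labs$line[divFrac >= 0.10]
    expect_gte(mean(detectable %in% flagged), 0.95)
    falseFlags <- setdiff(flagged, labs$line)
    expect_lte(length(falseFlags), ceiling(0.01 * length(lineNames(panel$geno))))
})

test_that("NJ trees are built per chromosome and export as Newick", {
    sp <- smallPanel()
    gm <- filterSites(sp$panel$geno[1:20, ])
    parents <- founderGenotypes(sp$panel$founders)
    parentOf <- setNames(paste0(c("fam01", "fam02"), "_parent"),
                         c("fam01", "fam02"))
    scan <- njContaminantScan(gm, parents, parentOf, buildTrees = TRUE)
    trees <- attr(scan, "trees")
    expect_named(trees, "chr1")
    expect_s3_class(trees$chr1, "phylo")
    ## lines cluster with their own family's parent: the tree distance
    ## from a fam01 RIL to fam01_parent is below that to fam02_parent
    d <- ape::cophenetic.phylo(trees$chr1)
    ## lines that inherited a clear majority of their genome from their
    ## diverse parent must sit nearer that parent on the review tree
    ## (mostly-common-parent lines are legitimately equidistant)
    seg <- trueSegments(sp$panel$truth)
    divFrac <- vapply(rownames(d)[grep("^fam01_r", rownames(d))],
                      function(l) {
                          s <- seg[seg$ril == l]
                          sum(width(s)[s$parent == "diverse"]) / sum(width(s))
                      }, 0)
    strong <- names(divFrac)[divFrac > 0.6]
    expect_gt(length(strong), 0)
    expect_true(all(d[strong, "fam01_parent"] < d[strong, "fam02_parent"]))
    dir <- withr::local_tempdir()
    paths <- writeNJTrees(scan, dir)
    expect_true(file.exists(paths[["chr1"]]))
    expect_s3_class(ape::read.tree(paths[["chr1"]]), "phylo")
})

test_that("removing a flagged line leaves other families' flags intact", {
    sp <- smallPanel()
    gm <- sp$panel$geno
    inj <- injectOutliers(gm, 2, 2, seed = 3)
    rep1 <- excessHetScan(inj$geno)
    flagged1 <- rep1$line[rep1$reason == "excess_het"]
    drop1 <- flagged1[1]
    dropFam <- familyOf(inj$geno)[[drop1]]
    rest <- inj$geno[lineNames(inj$geno) != drop1, ]
    rep2 <- excessHetScan(rest)
    flagged2 <- rep2$line[rep2$reason == "excess_het"]
    otherFams <- names(familyOf(inj$geno))[familyOf(inj$geno) != dropFam]
    expect_setequal(intersect(flagged1, otherFams),
                    intersect(flagged2, otherFams))
})
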