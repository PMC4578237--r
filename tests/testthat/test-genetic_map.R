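test_that("Haldane-Waddington correction and map function closed forms", {
    r0 <- rfBetweenBins(rep(c(0, 2), 20), rep(c(0, 2), 20), min_shared = 30)
    expect_equal(r0$R, 0)
    expect_equal(r0$d_cM, 0)
    ## R = 1/3 -> r = 0.25 -> d = 34.657 cM
    g1 <- rep(0L, 60)
    g2 <- c(rep(2L, 20), rep(0L, 40))
    rf <- rfBetweenBins(g1, g2)
    expect_equal(rf$R, 1 / 3)
    expect_equal(rf$r, 0.25)
    expect_equal(rf$d_cM, -50 * log(0.5), tolerance = 1e-9)
    expect_equal(round(rf$d_cM, 3), 34.657)
    ## R = 0.5 is the unlinked fixed point
    g3 <- rep(c(0L, 2L), 30)
    g4 <- c(rep(c(0L, 2L), 15), rep(c(2L, 0L), 15))
    expect_true(rfBetweenBins(g3, g4)$unlinked)
    ## round trip d(r(d)) to 1e-9
    d <- c(0.01, 1, 10, 49.9, 120)
    expect_equal(haldane_cM(haldane_r(d)), d, tolerance = 1e-9)
    expect_error(rfBetweenBins(c(0, 2, NA), c(0, 2, 0)), "need")
})

test_that("family map length recovers the simulated truth within 10%", {
    sp <- smallPanel()
    panel <- sp$panel
    gf <- prefilterFamilySites(
        panel$geno[familyOf(panel$geno) == "fam01", ])
    asg <- refineByResampling(gf, inferAssignmentParsimony(gf), 100)
    bm <- familyBinMap(gf, asg, c(chr1 = 1e8), c(chr1 = 1e-6))
    gmap <- buildFamilyMap(bm)
    expect_lt(abs(mapLength(gmap) - 100) / 100, 0.10)
    tab <- markerTable(gmap)
    expect_true(all(diff(tab$cM) >= 0))
    ## a one-bin chromosome has length zero
    one <- binMap(data.frame(chrom = "chr9", start = 1, end = 1e6),
                  matrix(rep(c(0L, 2L), 20), ncol = 1,
                         dimnames = list(sprintf("r%02d", 1:40), NULL)),
                  "famX")
    expect_equal(mapLength(buildFamilyMap(one)), 0)
})

test_that("composite marker selection honors the strict family threshold", {
    set.seed(9)
    mk <- function(polyIn, nfam = 4, nril = 10, nsites = 6) {
        lapply(seq_len(nfam), function(f) {
            m <- matrix(NA_integer_, nril, nsites)
            for (j in seq_len(nsites))
                if (f %in% polyIn[[j]])
                    m[, j] <- sample(c(0L, 2L), nril, TRUE)
                else m[, j] <- 0L
            m
        }) |> setNames(paste0("fam", seq_len(nfam)))
    }
    polyIn <- list(1:4, 1:2, 1:3, 2:4, 1, 2:3)
    ol <- mk(polyIn)
    sel <- selectCompositeMarkers(ol, min_families = 2)
    ## markers polymorphic in exactly 2 families are excluded ("more than")
    expect_setequal(sel$markers, which(lengths(polyIn) > 2))
    ## recount oracle
    polyCount <- vapply(seq_len(6), function(j)
        sum(vapply(ol, function(m) length(unique(m[, j])) > 1, TRUE)), 0)
    expect_setequal(sel$markers, which(polyCount > 2))
    ## encoding: 1 = common allele (origin 0), NA where monomorphic
    expect_true(all(is.na(sel$encoding[1:10, which(sel$markers == 4)[0]])))
    j3 <- match(3, sel$markers)
    expect_setequal(unique(sel$encoding[1:10, j3]), c(0L, 1L))  # fam1 segregates
    j4 <- match(4, sel$markers)
    expect_true(all(is.na(sel$encoding[1:10, j4])))             # fam1 monomorphic
})

test_that("segregation test matches chi-square closed forms", {
    even <- segregationTest(rep(c(0, 2), 50))
    expect_equal(even$chisq, 0)
    expect_equal(even$p, 1)
    expect_false(even$distorted)
    skewed <- segregationTest(rep(c(0, 2), c(70, 30)))
    expect_equal(skewed$chisq, 16)
    expect_equal(skewed$p, 6.3e-5, tolerance = 0.01)
    expect_true(skewed$distorted)
    mild <- segregationTest(rep(c(0, 2), c(55, 45)))
    expect_equal(mild$chisq, 1)
    expect_false(mild$distorted)
    expect_error(segregationTest(c(NA, NA)), "no informative")
})

test_that("composite bins merge identical columns and small bins", {
    enc <- rbind(r1 = c(1L, 1L, 0L, 0L),
                 r2 = c(0L, 0L, 0L, 1L))
    sites <- GRanges("chr1", IRanges(c(1000, 2000, 50000, 90000), width = 1))
    bm <- compositeBins(enc, sites, c("f1", "f1"),
                        c(chr1 = 100000), min_bp = 500)
    ## columns 1-2 identical -> merged; cuts at midpoints
    expect_length(binRanges(bm), 3)
    expect_equal(start(binRanges(bm)), c(1, 26001, 70001))
    ## lossless expansion: each original site falls in a bin whose stored
    ## column doubles its encoding
    exp <- expandBinsToSites(bm, start(sites), "chr1")
    expect_identical(unname(exp), unname(enc * 2L))
})

test_that("composite map keeps physical order and flags distortion", {
    bp <- binPanel(3, 80, 60, LcM = 150, seed = 21)
    g <- bp$genotypes
    bm <- binMap(data.frame(chrom = "chr1",
                            start = c(1, head(bp$map$pos, -1) + 1),
                            end = c(bp$map$pos)),
                 g, bp$families)
    cmap <- assembleCompositeMap(bm, maxPairwise = 100)
    tab <- markerTable(cmap)
    ## physical order preserved, cM monotone
    expect_true(all(diff(tab$pos) > 0))
    expect_true(all(diff(tab$cM) >= -1e-9))
    expect_false(any(tab$framework & tab$distorted))
    ## noise-free segregation: ~5% distorted by chance
    expect_lt(mean(tab$distorted), 0.2)
    ## with the finite-generation RIL correction the composite length
    ## recovers the simulated 150 cM
    expect_lt(abs(mapLength(cmap) - 150) / 150, 0.12)
})

test_that("a badly mis-genotyped marker is excluded from the composite map", {
    bp <- binPanel(3, 80, 40, LcM = 150, seed = 22)
    g <- bp$genotypes
    set.seed(1)
    flip <- runif(nrow(g)) < 0.45
    bad <- ifelse(flip, 2L - g[, 20], g[, 20])
    ## also distort it so it enters through the insertion path
    bad[1:120] <- 2L
    g[, 20] <- bad
    bm <- binMap(data.frame(chrom = "chr1",
                            start = c(1, head(bp$map$pos, -1) + 1),
                            end = bp$map$pos),
                 g, bp$families)
    cmap <- assembleCompositeMap(bm, maxPairwise = 100)
    expect_true(colnames(g)[20] %in% attr(cmap, "excluded"))
})

test_that("two unlinked chromosomes give two linkage groups at LOD 10", {
    cfg <- simConfig(n_families = 2, rils_per_family = 80,
                     chromosomes = data.frame(chrom = c("chr1", "chr2"),
                                              length_bp = c(1e8, 1e8),
                                              length_cM = c(100, 100)),
                     n_sites = 10, seed = 12)
    pos <- round(seq(1e6, 9.9e7, length.out = 25))
    sim <- simulateBinGenotypes(cfg, data.frame(
        chrom = rep(c("chr1", "chr2"), each = 25), pos = rep(pos, 2)))
    grp <- nambin:::.linkageGroups(sim$genotypes, lod_group = 10,
                                   maxPairwise = 100)
    expect_equal(length(unique(grp)), 2)
    expect_length(unique(grp[1:25]), 1)
    expect_length(unique(grp[26:50]), 1)
})
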