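test_that("simConfig validates rates, lengths and the mandatory seed", {
    expect_error(simConfig(), "seed")
    expect_error(simConfig(missing_rate = 1.2, seed = 1), "rates")
    expect_error(simConfig(chromosomes = data.frame(chrom = "c",
                                                    length_bp = -5,
                                                    length_cM = 100),
                           seed = 1), "positive")
})

test_that("founders are deterministic and polymorphism follows 2p(1-p)", {
    cfg <- simConfig(n_families = 4, n_sites = 1000, maf_spectrum = 0.5,
                     seed = 5)
    f1 <- simulateFounders(cfg)
    f2 <- simulateFounders(cfg)
    expect_identical(f1, f2)
    ## MAF fixed at 0.5 -> P(polymorphic in a family) = 0.5
    nPoly <- colSums(f1$differs)
    expect_true(all(abs(nPoly - 500) < 5 * sqrt(1000 * 0.25)))
    expect_false(any(f1$commonAllele %in% c(NA, "")))
})

test_that("gametes have Poisson crossovers strictly inside the chromosome", {
    h1 <- list(origin0 = 0, switches = numeric(0))
    h2 <- list(origin0 = 1, switches = numeric(0))
    set.seed(1)
    g0 <- simulateGamete(h1, h2, 1e8, 0)
    expect_length(g0$crossovers, 0)
    nXO <- replicate(4000, length(simulateGamete(h1, h2, 1e8, 200)$crossovers))
    ## mean 2.0, tolerance 5 SE
    expect_lt(abs(mean(nXO) - 2), 5 * sd(nXO) / sqrt(length(nXO)))
    xo <- simulateGamete(h1, h2, 1e8, 500)$crossovers
    expect_identical(xo, sort(xo))
    expect_true(all(xo > 0 & xo < 1e8))
})

test_that("F7 SSD junction density and residual het match theory", {
    ## independent-oracle value: grid-based Monte-Carlo of F7 selfing gives
    ## 1.857 junctions per Morgan (SE 0.011) for the homozygous consensus
    cfg <- simConfig(n_families = 1, rils_per_family = 400,
                     chromosomes = data.frame(chrom = "chr1",
                                              length_bp = 2e8,
                                              length_cM = 200),
                     n_sites = 10, seed = 31)
    f <- simulateFounders(cfg)
    sim <- simulateSSDFamily(f, "fam01", cfg)
    perRIL <- table(factor(sim$breakpoints$ril,
                           levels = unique(sim$segments$ril)))
    se <- sd(perRIL) / sqrt(length(perRIL))
    expect_lt(abs(mean(perRIL) - 2 * 1.857), 5 * se)
    ## marginal residual heterozygosity ~ (1/2)^6 after six selfings
    seHet <- sd(sim$hetFraction) / sqrt(length(sim$hetFraction))
    expect_lt(abs(mean(sim$hetFraction) - 0.5^6), 5 * seHet)
    ## segments tile the chromosome; breakpoints are internal boundaries
    segs <- sim$segments
    for (r in unique(segs$ril)[1:10]) {
        s <- segs[segs$ril == r, ]
        expect_equal(s$start[1], 1)
        expect_equal(s$end[nrow(s)], 2e8)
        if (nrow(s) > 1)
            expect_equal(s$start[-1], s$end[-nrow(s)] + 1)
    }
})

test_that("generation F1 is fully heterozygous at polymorphic sites", {
    cfg <- simConfig(n_families = 1, rils_per_family = 5,
                     chromosomes = data.frame(chrom = "chr1",
                                              length_bp = 1e7,
                                              length_cM = 10),
                     n_sites = 100, generations = 1, seed = 3)
    f <- simulateFounders(cfg)
    sim <- simulateSSDFamily(f, "fam01", cfg)
    poly <- f$differs[, "fam01"]
    expect_true(all(sim$calls[, poly] == "H"))
    expect_true(all(sim$calls[, !poly] != "H"))
})

test_that("GBS noise hits the configured rates", {
    cfg0 <- simConfig(missing_rate = 0, error_rate = 0,
                      het_undercall_rate = 0, seed = 1)
    calls <- matrix(sample(c("A", "B", "H"), 1e5, TRUE), 200, 500)
    expect_identical(applyGBSNoise(calls, cfg0, "A", "B"), calls)
    cfgAll <- simConfig(missing_rate = 1, seed = 1)
    expect_true(all(is.na(applyGBSNoise(calls, cfgAll, "A", "B"))))
    cfg <- simConfig(missing_rate = 0.3, error_rate = 0.02,
                     het_undercall_rate = 0.5, seed = 9)
    noisy <- applyGBSNoise(calls, cfg, "A", "B")
    missFrac <- mean(is.na(noisy))
    expect_lt(abs(missFrac - 0.3), 5 * sqrt(0.3 * 0.7 / 1e5))
    ## flips among surviving homozygotes
    hom <- !is.na(noisy) & calls != "H"
    flip <- mean(noisy[hom] != calls[hom])
    expect_lt(abs(flip - 0.02), 5 * sqrt(0.02 * 0.98 / sum(hom)))
    ## determinism
    expect_identical(noisy, applyGBSNoise(calls, cfg, "A", "B"))
})

test_that("phenotypes follow the 0/2 genotype coding exactly", {
    sp <- smallPanel()
    truth <- sp$panel$truth
    fams <- c("fam01", "fam02")
    ## zero effects, zero noise -> every line sits at its family mean
    ph0 <- simulatePhenotype(truth, qtl = data.frame(), h2 = NULL,
                             sigma_e = 0, n_env = 2, n_rep = 1, seed = 4)
    g0 <- attr(ph0, "geneticValues")
    expect_true(all(g0 == 60))
    ## one QTL, effect 1 day/allele, no noise -> classes 2 days apart
    qtl <- data.frame(chrom = "chr1", pos = 5e7, fam01 = 1, fam02 = 1)
    ph1 <- simulatePhenotype(truth, qtl, h2 = NULL, sigma_e = 0,
                             n_env = 1, n_rep = 1, seed = 4)
    g1 <- attr(ph1, "geneticValues")
    expect_setequal(unique(g1), c(60, 62))
    ## determinism
    ph2 <- simulatePhenotype(truth, qtl, h2 = NULL, sigma_e = 0,
                             n_env = 1, n_rep = 1, seed = 4)
    expect_identical(ph1, ph2)
    ## QTL outside the genome is rejected
    expect_error(simulatePhenotype(truth,
                                   data.frame(chrom = "chr1", pos = 9e9,
                                              fam01 = 1, fam02 = 1)),
                 "outside")
})

test_that("realized line-mean heritability lands near the target", {
    sp <- smallPanel()
    qtl <- data.frame(chrom = "chr1", pos = 5e7, fam01 = 0.8, fam02 = 0.5)
    ph <- simulatePhenotype(sp$panel$truth, qtl, h2 = 0.9, n_env = 6,
                            n_rep = 2, seed = 8)
    comp <- estimateComponents(ph)
    expect_lt(abs(h2MeanBasis(comp) - 0.9), 0.05)
})

test_that("outlier injection is labelled, disjoint and above threshold", {
    sp <- smallPanel()
    gm <- sp$panel$geno
    same <- injectOutliers(gm, 0, 0)
    expect_identical(genoCalls(same$geno), genoCalls(gm))
    inj <- injectOutliers(gm, 3, 2, seed = 10)
    expect_length(intersect(inj$labels$line, lineNames(gm)), 0)
    expect_equal(nrow(inj$labels), 5)
    hets <- inj$labels$line[inj$labels$type == "excess_het"]
    calls <- genoCalls(inj$geno)
    for (l in hets) {
        ratio <- mean(calls[l, !is.na(calls[l, ])] == "H")
        expect_gt(ratio, 0.10)
    }
    gm1 <- gm[familyOf(gm) == "fam01", ]
    expect_error(injectOutliers(gm1, 1, 0), "2 families")
})
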