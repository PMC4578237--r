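## Shared fixtures, built once per test run.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(withr)
})

## tiny hand-constructed GenotypeMatrix: 2 lines x 3 sites
tinyGM <- function() {
    calls <- matrix(c("A", "B", NA,
                      "B", "H", "A"), nrow = 2, byrow = TRUE,
                    dimnames = list(c("ril1", "ril2"), c("s1", "s2", "s3")))
    genotypeMatrix(calls,
                   data.frame(chrom = "chr1", pos = c(100, 200, 300),
                              alleleA = c("A", "C", "G"),
                              alleleB = c("T", "G", "A")),
                   family = "fam1")
}

## moderate simulated panel reused by several test files
.panelCache <- new.env()
smallPanel <- function() {
    if (is.null(.panelCache$panel)) {
        cfg <- simConfig(n_families = 2, rils_per_family = 60,
                         chromosomes = data.frame(chrom = "chr1",
                                                  length_bp = 1e8,
                                                  length_cM = 100),
                         n_sites = 3000, seed = 2024)
        .panelCache$panel <- simulateNAMPanel(cfg)
        .panelCache$config <- cfg
    }
    list(panel = .panelCache$panel, config = .panelCache$config)
}

## random GenotypeMatrix for round-trip property tests
randomGM <- function(nLines, nSites, seed) {
    set.seed(seed)
    pos <- sort(sample.int(1e6, nSites))
    bases <- c("A", "C", "G", "T")
    a <- sample(bases, nSites, replace = TRUE)
    b <- vapply(a, function(x) sample(setdiff(bases, x), 1), "")
    calls <- matrix(sample(c("A", "B", "H", NA), nLines * nSites, TRUE,
                           prob = c(0.35, 0.35, 0.1, 0.2)),
                    nLines, nSites,
                    dimnames = list(sprintf("l%02d", seq_len(nLines)),
                                    sprintf("s%03d", seq_len(nSites))))
    sites <- data.frame(chrom = "chr1", pos = pos, alleleA = a,
                        alleleB = unname(b))
    genotypeMatrix(calls, sites,
                   sample(c("famA", "famB"), nLines, TRUE))
}

## brute-force posterior of the two-state origin HMM by path enumeration
bruteForcePosterior <- function(obs, pos_cM, params) {
    k <- length(obs)
    eps <- params$epsilon
    trans <- (1 - exp(-2 * params$rho * diff(pos_cM))) / 2
    paths <- as.matrix(expand.grid(rep(list(c(0L, 2L)), k)))
    emit <- function(state, o) {
        if (is.na(o)) return(1)
        if (o == state) 1 - eps else eps
    }
    pp <- apply(paths, 1, function(path) {
        p <- 0.5 * emit(path[1], obs[1])
        if (k > 1) for (j in 2:k) {
            t <- trans[j - 1]
            p <- p * (if (path[j] == path[j - 1]) 1 - t else t) *
                emit(path[j], obs[j])
        }
        p
    })
    post <- vapply(seq_len(k), function(j)
        sum(pp[paths[, j] == 0]) / sum(pp), 0)
    cbind(common = post, diverse = 1 - post)
}

## brute-force parsimony: exhaustive minimum over all 2^k assignments of
## the pairwise-adjacent switch count
bruteForceParsimony <- function(m01) {
    k <- ncol(m01)
    best <- Inf
    for (mask in 0:(2^k - 1)) {
        a <- as.integer(intToBits(mask))[seq_len(k)]
        tot <- 0
        for (j in seq_len(k - 1)) {
            L <- m01[, j]; R <- m01[, j + 1]
            both <- !is.na(L) & !is.na(R)
            oL <- (L + a[j]) %% 2
            oR <- (R + a[j + 1]) %% 2
            tot <- tot + sum(both & (oL != oR))
        }
        best <- min(best, tot)
    }
    best
}

## noise-free bin-level NAM marker panel for joint-linkage tests
binPanel <- function(nfam, nril, nbins, LcM = 200, Lbp = 2e8, seed = 1) {
    cfg <- simConfig(n_families = nfam, rils_per_family = nril,
                     chromosomes = data.frame(chrom = "chr1",
                                              length_bp = Lbp,
                                              length_cM = LcM),
                     n_sites = 10, seed = seed)
    pos <- round(seq(Lbp / nbins / 2, Lbp - Lbp / nbins / 2,
                     length.out = nbins))
    simulateBinGenotypes(cfg, pos)
}
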