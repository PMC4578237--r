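## NAM-panel simulator with full ground truth.
##
## The design emulated: several F7 RIL families derived by single seed
## descent from crosses of diverse founders onto one shared common parent,
## genotyped by low-coverage GBS (missing calls, allele-call errors,
## heterozygote undercalls).  Meiosis has no crossover interference
## (Poisson crossovers on the cM scale), matching the Haldane map function
## used downstream.  One master seed drives named sub-streams so that any
## family or stage can be regenerated on its own.

#' Simulation configuration for a synthetic NAM panel
#'
#' @param n_families number of RIL families (each shares the common parent).
#' @param rils_per_family RILs per family.
#' @param chromosomes data.frame with columns \code{chrom},
#'   \code{length_bp}, \code{length_cM}; the cM<->bp relation is uniform
#'   within a chromosome.
#' @param n_sites total SNP sites across the genome (shared site list; each
#'   site is polymorphic in a family only when that family's diverse parent
#'   differs from the common parent there).
#' @param maf_spectrum founder minor-allele frequency: a single number or a
#'   function(n) returning per-site MAFs.  A diverse parent differs from the
#'   common parent at a site with probability 2 maf (1 - maf).
#' @param generations inbreeding generation reached by single seed descent
#'   (7 = F7, i.e. an F1 followed by 6 selfing generations).
#' @param missing_rate per-call probability of a missing genotype.
#' @param error_rate per-call probability that a surviving homozygote is
#'   reported as the opposite homozygote.
#' @param het_undercall_rate probability that a surviving heterozygote is
#'   reported as a random homozygote (low-coverage GBS samples one allele).
#' @param seed master seed (mandatory; all randomness derives from it).
#' @return A validated list of class \code{SimConfig}.
#' @examples
#' cfg <- simConfig(n_families = 2, rils_per_family = 50, n_sites = 500,
#'                  seed = 1)
#' @export
simConfig <- function(n_families = 2, rils_per_family = 200,
                      chromosomes = data.frame(chrom = "chr1",
                                               length_bp = 2e8,
                                               length_cM = 200),
                      n_sites = 10000, maf_spectrum = 0.5,
                      generations = 7, missing_rate = 0.3,
                      error_rate = 0.01, het_undercall_rate = 0.5,
                      seed) {
    if (missing(seed)) .stopf("a seed is mandatory for reproducibility")
    rates <- c(missing_rate, error_rate, het_undercall_rate)
    if (any(rates < 0 | rates > 1)) .stopf("rates must lie in [0, 1]")
    if (any(chromosomes$length_bp <= 0) || any(chromosomes$length_cM < 0))
        .stopf("chromosome lengths must be positive")
    if (generations < 1) .stopf("generations must be >= 1")
    structure(list(n_families = n_families,
                   rils_per_family = rils_per_family,
                   chromosomes = chromosomes, n_sites = n_sites,
                   maf_spectrum = maf_spectrum, generations = generations,
                   missing_rate = missing_rate, error_rate = error_rate,
                   het_undercall_rate = het_undercall_rate,
                   seed = as.integer(seed)),
              class = "SimConfig")
}

#' Simulate founder genotypes for a NAM panel
#'
#' Sites are laid down uniformly at random along each chromosome.  The
#' common parent carries one of the two alleles at every site; each
#' family's diverse parent differs from it at a site with probability
#' 2 maf (1 - maf), which makes the site polymorphic (segregating) in that
#' family.
#'
#' @param config a [simConfig()].
#' @return List with \code{sites} (GRanges with alleleA/alleleB),
#'   \code{commonAllele} ("A"/"B" per site) and \code{differs} (site x
#'   family logical matrix: diverse parent differs from common parent).
#' @export
simulateFounders <- function(config) {
    .withSeed(.childSeed(config$seed, "founders"), {
        chroms <- config$chromosomes
        nPer <- .splitSites(config$n_sites, chroms$length_bp)
        posL <- lapply(seq_len(nrow(chroms)), function(i) {
            if (nPer[i] == 0) return(integer(0))
            sort(sample.int(chroms$length_bp[i] - 2L, nPer[i])) + 1L
        })
        sites <- GRanges(rep(chroms$chrom, lengths(posL)),
                         IRanges(unlist(posL), width = 1L))
        n <- length(sites)
        bases <- c("A", "C", "G", "T")
        a1 <- sample(bases, n, replace = TRUE)
        a2 <- vapply(a1, function(x) sample(setdiff(bases, x), 1), "")
        mcols(sites)$alleleA <- unname(a1)
        mcols(sites)$alleleB <- unname(a2)
        names(sites) <- sprintf("s%05d", seq_len(n))
        maf <- if (is.function(config$maf_spectrum))
            config$maf_spectrum(n) else rep(config$maf_spectrum, n)
        commonAllele <- ifelse(runif(n) < 0.5, "A", "B")
        pPoly <- 2 * maf * (1 - maf)
        differs <- matrix(runif(n * config$n_families) <
                              rep(pPoly, config$n_families),
                          nrow = n,
                          dimnames = list(names(sites),
                                          .famNames(config$n_families)))
        list(sites = sites, commonAllele = commonAllele, differs = differs)
    })
}

.famNames <- function(k) sprintf("fam%02d", seq_len(k))

.splitSites <- function(n, lengths) {
    raw <- n * lengths / sum(lengths)
    out <- floor(raw)
    rem <- n - sum(out)
    if (rem > 0) {
        o <- order(raw - out, decreasing = TRUE)
        out[o[seq_len(rem)]] <- out[o[seq_len(rem)]] + 1
    }
    as.integer(out)
}

## A haplotype is a step function of parental origin along one chromosome:
## `origin0` (0 common / 1 diverse) before the first switch point, switch
## positions in bp strictly inside (0, length_bp).
.haplotype <- function(origin0, switches = numeric(0))
    list(origin0 = origin0, switches = switches)

.originAt <- function(hap, pos) {
    k <- findInterval(pos, hap$switches)
    (hap$origin0 + k) %% 2
}

#' Simulate one gamete from a diplotype
#'
#' Crossover count is Poisson with mean length_cM / 100 (no interference);
#' crossover positions are uniform on the genetic scale and mapped to bp by
#' the chromosome's uniform cM<->bp relation.
#'
#' @param hap1,hap2 the parent's two haplotypes (internal step-function
#'   representation as produced during [simulateSSDFamily()]).
#' @param length_bp,length_cM chromosome lengths.
#' @return List with the gamete haplotype and the crossover positions (bp).
#' @export
simulateGamete <- function(hap1, hap2, length_bp, length_cM) {
    nXO <- rpois(1, length_cM / 100)
    xo <- sort(runif(nXO, 0, length_cM)) / max(length_cM, 1e-12) * length_bp
    start <- sample(0:1, 1)
    grid <- sort(unique(c(0, hap1$switches, hap2$switches, xo, length_bp)))
    mids <- (grid[-1] + grid[-length(grid)]) / 2
    active <- (start + findInterval(mids, xo)) %% 2      # 0 = hap1, 1 = hap2
    orig <- ifelse(active == 0, .originAt(hap1, mids), .originAt(hap2, mids))
    sw <- grid[-c(1, length(grid))][diff(orig) != 0]
    list(haplotype = .haplotype(orig[1], sw), crossovers = xo)
}

#' Simulate one F7 single-seed-descent family
#'
#' Starts from the F1 of common x diverse parent and selfs for
#' \code{generations - 1} rounds, keeping a single offspring each round.
#'
#' @param founders output of [simulateFounders()].
#' @param family family id (a column of \code{founders$differs}).
#' @param config a [simConfig()].
#' @return List with \code{calls} (noise-free RIL x site calls on the
#'   A/B/H alphabet), \code{segments}/\code{breakpoints} (ground truth;
#'   heterozygous residual intervals are split at their midpoint between
#'   the flanking homozygous states), \code{hetFraction} (per-RIL fraction
#'   of the genome still heterozygous) and the per-RIL diplotypes.
#' @export
simulateSSDFamily <- function(founders, family, config) {
    if (!any(founders$differs[, family]))
        .stopf("family %s has no polymorphic site", family)
    chroms <- config$chromosomes
    sites <- founders$sites
    .withSeed(.childSeed(config$seed, "ssd", family), {
        nR <- config$rils_per_family
        rilIds <- sprintf("%s_r%03d", family, seq_len(nR))
        calls <- matrix(NA_character_, nR, length(sites),
                        dimnames = list(rilIds, names(sites)))
        segL <- list(); bpL <- list()
        hetBp <- numeric(nR)
        for (ci in seq_len(nrow(chroms))) {
            Lbp <- chroms$length_bp[ci]; LcM <- chroms$length_cM[ci]
            onChr <- which(as.character(seqnames(sites)) == chroms$chrom[ci])
            pos <- start(sites)[onChr]
            for (ri in seq_len(nR)) {
                dip <- list(.haplotype(0), .haplotype(1))   # the F1
                for (g in seq_len(config$generations - 1L)) {
                    g1 <- simulateGamete(dip[[1]], dip[[2]], Lbp, LcM)
                    g2 <- simulateGamete(dip[[1]], dip[[2]], Lbp, LcM)
                    dip <- list(g1$haplotype, g2$haplotype)
                }
                o1 <- .originAt(dip[[1]], pos); o2 <- .originAt(dip[[2]], pos)
                tot <- o1 + o2                                # 0 / 1 / 2
                cl <- ifelse(tot == 0, "A", ifelse(tot == 2, "B", "H"))
                poly <- founders$differs[onChr, family]
                common <- founders$commonAllele[onChr]
                out <- character(length(pos))
                ## polymorphic site: common origin -> common allele
                comCall <- common
                divCall <- ifelse(common == "A", "B", "A")
                out[poly] <- ifelse(cl[poly] == "H", "H",
                                    ifelse(cl[poly] == "A", comCall[poly],
                                           divCall[poly]))
                out[!poly] <- comCall[!poly]                  # monomorphic
                calls[ri, onChr] <- out
                cons <- .consensusSegments(dip[[1]], dip[[2]], Lbp)
                hetBp[ri] <- hetBp[ri] + cons$hetBp
                if (nrow(cons$segments)) {
                    s <- cons$segments
                    segL[[length(segL) + 1L]] <- data.frame(
                        chrom = chroms$chrom[ci], start = s$start,
                        end = s$end, ril = rilIds[ri], family = family,
                        parent = s$parent)
                    bp <- s$start[-1] - 0.5
                    if (length(bp))
                        bpL[[length(bpL) + 1L]] <- data.frame(
                            ril = rilIds[ri], family = family,
                            chrom = chroms$chrom[ci], pos = bp)
                }
            }
        }
        segs <- do.call(rbind, segL)
        bps <- if (length(bpL)) do.call(rbind, bpL) else
            data.frame(ril = character(0), family = character(0),
                       chrom = character(0), pos = numeric(0))
        list(calls = calls, segments = segs, breakpoints = bps,
             hetFraction = hetBp / sum(chroms$length_bp))
    })
}

## Collapse a diplotype to common/diverse consensus segments tiling
## [1, length_bp]; residual-het stretches are split at their midpoint
## between the flanking homozygous states (terminal het stretches join
## their single neighbour).  Returns the het bp total for bookkeeping.
.consensusSegments <- function(hap1, hap2, length_bp) {
    grid <- sort(unique(c(0, hap1$switches, hap2$switches, length_bp)))
    mids <- (grid[-1] + grid[-length(grid)]) / 2
    state <- .originAt(hap1, mids) + .originAt(hap2, mids)  # 0 hom-C,1 het,2 hom-D
    segS <- grid[-length(grid)]; segE <- grid[-1]
    hetBp <- sum((segE - segS)[state == 1])
    keep <- state != 1
    if (!any(keep)) {
        ## fully heterozygous chromosome: assign to haplotype 1's origin
        par <- if (.originAt(hap1, length_bp / 2) == 0) "common" else "diverse"
        return(list(segments = data.frame(start = 1, end = length_bp,
                                          parent = par), hetBp = hetBp))
    }
    ## absorb het stretches: split at midpoint between flanking hom states
    homIdx <- which(keep)
    bounds <- numeric(0); pars <- character(0)
    cur <- 0
    for (k in seq_along(homIdx)) {
        i <- homIdx[k]
        nxt <- if (k < length(homIdx)) homIdx[k + 1] else NA
        endAt <- if (is.na(nxt)) length_bp else {
            if (state[nxt] == state[i]) segS[nxt] else (segE[i] + segS[nxt]) / 2
        }
        pars <- c(pars, if (state[i] == 0) "common" else "diverse")
        bounds <- rbind(bounds, c(cur, endAt))
        cur <- endAt
    }
    ## integerize to 1-based inclusive segments tiling [1, length_bp]
    cut <- floor(bounds[, 2])
    cut[length(cut)] <- round(length_bp)
    ok <- c(cut[1] >= 1, diff(cut) >= 1)        # drop sub-bp slivers
    cut <- cut[ok]; pars <- pars[ok]
    r <- rle(pars)                               # re-merge same-parent runs
    ends <- cut[cumsum(r$lengths)]
    starts <- c(1, head(ends, -1) + 1)
    list(segments = data.frame(start = starts, end = ends,
                               parent = r$values),
         hetBp = hetBp)
}

#' Overlay low-coverage GBS noise on noise-free calls
#'
#' Each call is independently set missing with probability
#' \code{missing_rate}; a surviving homozygote is flipped to the opposite
#' homozygote with probability \code{error_rate}; a surviving heterozygote
#' is reported as a random homozygote with probability
#' \code{het_undercall_rate}.
#'
#' @param calls character matrix of noise-free calls (allele symbols or
#'   A/B/H coding; "H" rows are treated as heterozygous either way).
#' @param config a [simConfig()] carrying the three rates and the seed.
#' @param alleleA,alleleB per-site allele symbols (needed to flip
#'   homozygotes when calls are raw allele symbols).
#' @param stream seed sub-stream label (change to draw independent noise).
#' @return Matrix of the same shape with noise applied.
#' @export
applyGBSNoise <- function(calls, config, alleleA, alleleB,
                          stream = "noise") {
    alleleA <- rep(alleleA, length.out = ncol(calls))
    alleleB <- rep(alleleB, length.out = ncol(calls))
    .withSeed(.childSeed(config$seed, stream), {
        n <- length(calls)
        out <- calls
        miss <- runif(n) < config$missing_rate
        out[miss] <- NA_character_
        A <- matrix(rep(alleleA, each = nrow(calls)), nrow(calls))
        B <- matrix(rep(alleleB, each = nrow(calls)), nrow(calls))
        isHet <- !is.na(out) & out == "H"
        isHomA <- !is.na(out) & out == A
        isHomB <- !is.na(out) & out == B
        flip <- runif(n) < config$error_rate
        out[isHomA & flip] <- B[isHomA & flip]
        out[isHomB & flip] <- A[isHomB & flip]
        under <- runif(n) < config$het_undercall_rate
        toHom <- isHet & under
        pickA <- runif(n) < 0.5
        out[toHom & pickA] <- A[toHom & pickA]
        out[toHom & !pickA] <- B[toHom & !pickA]
        out
    })
}

#' Simulate a complete NAM panel with ground truth
#'
#' Runs [simulateFounders()], [simulateSSDFamily()] per family and
#' [applyGBSNoise()], and assembles the observed \linkS4class{GenotypeMatrix}
#' (calls recoded to A/B/H relative to alleleA/alleleB), the noise-free
#' matrix, and the \linkS4class{TruthSet}.
#'
#' @param config a [simConfig()].
#' @param qtl optional data.frame of true QTL (chrom, pos, one effect
#'   column per family) stored in the TruthSet.
#' @return List with \code{geno} (noisy GenotypeMatrix), \code{trueGeno}
#'   (noise-free), \code{truth} (TruthSet), \code{founders} and
#'   \code{hetFraction}.
#' @export
simulateNAMPanel <- function(config, qtl = NULL) {
    founders <- simulateFounders(config)
    sites <- founders$sites
    fams <- colnames(founders$differs)
    callL <- list(); segL <- list(); bpL <- list(); hetL <- list()
    for (f in fams) {
        sim <- simulateSSDFamily(founders, f, config)
        callL[[f]] <- sim$calls
        segL[[f]] <- sim$segments
        bpL[[f]] <- sim$breakpoints
        hetL[[f]] <- sim$hetFraction
    }
    allCalls <- do.call(rbind, callL)
    famVec <- rep(fams, vapply(callL, nrow, 0L))
    ## family calls are already on the A/B/H label alphabet
    noisy <- applyGBSNoise(allCalls, config, "A", "B")
    segs <- do.call(rbind, segL)
    truth <- new("TruthSet",
        segments = GRanges(segs$chrom, IRanges(segs$start, segs$end),
                           ril = segs$ril, family = segs$family,
                           parent = segs$parent),
        breakpoints = do.call(rbind, bpL),
        founders = lapply(fams, function(f) founders$differs[, f]) |>
            setNames(fams),
        qtl = if (is.null(qtl)) data.frame() else qtl)
    list(geno = genotypeMatrix(noisy, sites, famVec),
         trueGeno = genotypeMatrix(allCalls, sites, famVec),
         truth = truth, founders = founders,
         hetFraction = unlist(hetL))
}

## allele-symbol matrix -> A/B/H coding relative to alleleA/alleleB
.toABH <- function(calls, alleleA, alleleB) {
    A <- matrix(rep(alleleA, each = nrow(calls)), nrow(calls))
    B <- matrix(rep(alleleB, each = nrow(calls)), nrow(calls))
    out <- matrix(NA_character_, nrow(calls), ncol(calls),
                  dimnames = dimnames(calls))
    out[!is.na(calls) & calls == A] <- "A"
    out[!is.na(calls) & calls == B] <- "B"
    out[!is.na(calls) & calls == "H"] <- "H"
    out
}

#' Simulate RIL genotypes directly at marker (bin) positions
#'
#' Runs the F7 single-seed-descent machinery per family and evaluates the
#' consensus parental origin at the supplied positions -- a fast route to
#' noise-free bin-level marker matrices for QTL experiments, skipping SNP
#' sampling and GBS noise.
#'
#' @param config a [simConfig()] (n_sites is ignored).
#' @param positions data.frame (chrom, pos) of marker positions, or a
#'   numeric vector of positions on the first configured chromosome.
#' @return List: \code{genotypes} (lines x markers, 0 = common / 2 =
#'   diverse), \code{families} (per line), \code{map} (marker, chrom,
#'   pos, cM under the uniform cM<->bp relation), \code{truth}
#'   (\linkS4class{TruthSet} of segments/breakpoints).
#' @export
simulateBinGenotypes <- function(config, positions) {
    chroms <- config$chromosomes
    if (!is.data.frame(positions))
        positions <- data.frame(chrom = chroms$chrom[1], pos = positions)
    founders <- simulateFounders(config)
    fams <- .famNames(config$n_families)
    gL <- list(); segL <- list(); bpL <- list()
    for (f in fams) {
        sim <- simulateSSDFamily(founders, f, config)
        segs <- sim$segments
        rils <- unique(segs$ril)
        g <- matrix(NA_integer_, length(rils), nrow(positions),
                    dimnames = list(rils, NULL))
        for (ch in unique(positions$chrom)) {
            pj <- which(positions$chrom == ch)
            sub <- segs[segs$chrom == ch, , drop = FALSE]
            for (i in seq_along(rils)) {
                s <- sub[sub$ril == rils[i], , drop = FALSE]
                k <- findInterval(positions$pos[pj], s$start)
                g[i, pj] <- ifelse(s$parent[pmax(k, 1)] == "common", 0L, 2L)
            }
        }
        gL[[f]] <- g
        segL[[f]] <- segs
        bpL[[f]] <- sim$breakpoints
    }
    g <- do.call(rbind, gL)
    colnames(g) <- sprintf("bin%04d", seq_len(ncol(g)))
    cmPerBp <- setNames(chroms$length_cM / chroms$length_bp, chroms$chrom)
    segs <- do.call(rbind, segL)
    truth <- new("TruthSet",
        segments = GRanges(segs$chrom, IRanges(segs$start, segs$end),
                           ril = segs$ril, family = segs$family,
                           parent = segs$parent),
        breakpoints = do.call(rbind, bpL),
        founders = list(), qtl = data.frame())
    list(genotypes = g,
         families = rep(fams, vapply(gL, nrow, 0L)),
         map = data.frame(marker = colnames(g), chrom = positions$chrom,
                          pos = positions$pos,
                          cM = positions$pos *
                              cmPerBp[as.character(positions$chrom)]),
         truth = truth)
}

#' Founder genotypes as a GenotypeMatrix
#'
#' One row for the common parent ("common") plus one per diverse parent
#' ("<family>_parent"), on the A/B/H coding of [simulateNAMPanel()].
#'
#' @param founders output of [simulateFounders()].
#' @return A \linkS4class{GenotypeMatrix} (family slot set to "founder").
#' @export
founderGenotypes <- function(founders) {
    common <- ifelse(founders$commonAllele == "A", "A", "B")
    fams <- colnames(founders$differs)
    rows <- rbind(common,
                  t(vapply(fams, function(f)
                      ifelse(founders$differs[, f],
                             ifelse(common == "A", "B", "A"), common),
                      character(length(common)))))
    rownames(rows) <- c("common", paste0(fams, "_parent"))
    genotypeMatrix(rows, founders$sites, "founder")
}

#' Parental-origin genotype of each line at arbitrary positions
#'
#' Looks the positions up in the true segments: 0 = common, 2 = diverse
#' (residual-het intervals were already resolved by the simulator).
#'
#' @param truth a \linkS4class{TruthSet}.
#' @param chrom,pos vectors of query positions.
#' @return Integer matrix lines x positions with values 0/2.
#' @export
trueOriginAt <- function(truth, chrom, pos) {
    seg <- trueSegments(truth)
    rils <- unique(seg$ril)
    out <- matrix(NA_integer_, length(rils), length(pos),
                  dimnames = list(rils, NULL))
    q <- GRanges(chrom, IRanges(round(pos), width = 1L))
    for (i in seq_along(rils)) {
        s <- seg[seg$ril == rils[i]]
        hit <- GenomicRanges::findOverlaps(q, s, select = "first")
        out[i, ] <- ifelse(s$parent[hit] == "common", 0L, 2L)
    }
    out
}

#' Simulate multi-environment phenotypes from true QTL
#'
#' \code{value = family mean + sum(effect_qf * x_q) + env effect + noise},
#' with \code{x_q} the 0/2-coded parental-origin genotype at the QTL (so an
#' "additive allele effect" of e days separates the two homozygous classes
#' by 2 e days).
#'
#' @param truth a \linkS4class{TruthSet} (provides genotypes at QTL
#'   positions).
#' @param qtl data.frame with columns chrom, pos and one effect column per
#'   family (named as the families; effects in trait units per allele).
#' @param familyMeans named numeric, one per family (default 60 for all,
#'   a typical days-to-tasseling baseline).
#' @param n_env,n_rep environments and replicates per environment.
#' @param h2 target broad-sense heritability on a line-mean basis; the
#'   residual standard deviation is solved from the realized genetic
#'   variance ( \code{NULL} = use \code{sigma_e} directly).
#' @param sigma_e residual SD when \code{h2} is NULL.
#' @param envEffects optional numeric vector of environment main effects.
#' @param seed seed for the phenotype stream.
#' @return A phenotype data.frame (line, env, rep, value) plus attributes
#'   \code{geneticValues} and \code{sigma_e}.
#' @export
simulatePhenotype <- function(truth, qtl, familyMeans = NULL,
                              n_env = 6, n_rep = 2, h2 = 0.9,
                              sigma_e = 1, envEffects = NULL, seed = 1) {
    seg <- trueSegments(truth)
    fams <- unique(seg$family)
    rils <- unique(seg$ril)
    famOf <- setNames(seg$family[match(rils, seg$ril)], rils)
    if (is.null(familyMeans))
        familyMeans <- setNames(rep(60, length(fams)), fams)
    ## check QTL fall inside the simulated genome
    chromEnd <- tapply(end(seg), as.character(seqnames(seg)), max)
    if (nrow(qtl)) {
        bad <- qtl$pos < 1 | qtl$pos > chromEnd[as.character(qtl$chrom)]
        if (any(bad | is.na(bad)))
            .stopf("QTL at %s:%s lies outside the simulated bins",
                   qtl$chrom[which(bad)[1]], qtl$pos[which(bad)[1]])
    }
    g <- familyMeans[famOf[rils]]
    names(g) <- rils
    if (nrow(qtl)) {
        x <- trueOriginAt(truth, qtl$chrom, qtl$pos)[rils, , drop = FALSE]
        for (q in seq_len(nrow(qtl))) {
            eff <- unlist(qtl[q, fams])
            g <- g + eff[famOf[rils]] * x[, q]
        }
    }
    .withSeed(.childSeed(seed, "phenotype"), {
        if (!is.null(h2)) {
            vg <- var(g)
            sigma_e <- if (vg == 0 || h2 <= 0) 0 else
                sqrt(max(vg * (1 - h2) / h2 * n_env * n_rep, 0))
        }
        if (is.null(envEffects)) envEffects <- rnorm(n_env, 0, 1)
        tab <- expand.grid(line = rils, env = paste0("env", seq_len(n_env)),
                           rep = seq_len(n_rep), stringsAsFactors = FALSE,
                           KEEP.OUT.ATTRS = FALSE)
        ei <- as.integer(sub("env", "", tab$env))
        tab$value <- g[tab$line] + envEffects[ei] +
            rnorm(nrow(tab), 0, sigma_e)
        rownames(tab) <- NULL
        attr(tab, "geneticValues") <- g
        attr(tab, "sigma_e") <- sigma_e
        tab
    })
}

#' Inject known outlier lines into a genotype matrix
#'
#' Contaminants are copies of a line from a different family, relabelled
#' into the target family; excess-het lines are copies with enough calls
#' forced heterozygous to push the het ratio above 10 %.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param n_contaminants,n_excess_het how many of each to add.
#' @param het_target het ratio forced on excess-het lines (default 0.2).
#' @param seed RNG seed.
#' @return List: \code{geno} (augmented matrix) and \code{labels}
#'   (data.frame line, type, source describing the injections).
#' @export
injectOutliers <- function(gm, n_contaminants, n_excess_het,
                           het_target = 0.2, seed = 1) {
    fam <- familyOf(gm)
    fams <- unique(fam)
    if (n_contaminants > 0 && length(fams) < 2)
        .stopf("contamination needs at least 2 families")
    .withSeed(.childSeed(seed, "outliers"), {
        calls <- genoCalls(gm)
        labels <- data.frame(line = character(0), type = character(0),
                             source = character(0))
        addCalls <- NULL; addFam <- character(0)
        if (n_contaminants > 0) {
            for (i in seq_len(n_contaminants)) {
                target <- sample(fams, 1)
                donorFam <- sample(setdiff(fams, target), 1)
                donor <- sample(names(fam)[fam == donorFam], 1)
                id <- sprintf("contam_%02d", i)
                addCalls <- rbind(addCalls,
                                  matrix(calls[donor, ], 1,
                                         dimnames = list(id, NULL)))
                addFam <- c(addFam, target)
                labels <- rbind(labels, data.frame(line = id,
                                                   type = "contaminant",
                                                   source = donor))
            }
        }
        if (n_excess_het > 0) {
            for (i in seq_len(n_excess_het)) {
                donor <- sample(rownames(calls), 1)
                row <- calls[donor, ]
                obs <- which(!is.na(row))
                k <- ceiling(het_target * length(obs))
                row[sample(obs, min(k, length(obs)))] <- "H"
                id <- sprintf("exhet_%02d", i)
                addCalls <- rbind(addCalls,
                                  matrix(row, 1, dimnames = list(id, NULL)))
                addFam <- c(addFam, fam[donor])
                labels <- rbind(labels, data.frame(line = id,
                                                   type = "excess_het",
                                                   source = donor))
            }
        }
        if (is.null(addCalls))
            return(list(geno = gm, labels = labels))
        allCalls <- rbind(calls, addCalls)
        list(geno = genotypeMatrix(allCalls, siteRanges(gm),
                                   c(fam, setNames(addFam,
                                                   rownames(addCalls)))),
             labels = labels)
    })
}
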