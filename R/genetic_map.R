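## Genetic maps from recombination bins.  Distances use the observed
## discordance R between bin genotype columns, corrected for selfed-RIL
## map expansion (Haldane-Waddington: R = 2r / (1 + 2r), so
## r = R / (2 - 2R)) and converted to cM with the Haldane map function
## d = -50 ln(1 - 2r).  Composite maps are ordered by physical position
## (marker coordinates are anchored to the reference genome); likelihood
## enters only through the distances.

#' Recombination fraction and map distance between two bin columns
#'
#' @param g1,g2 genotype columns coded 0/2 (or 0/1) with NA; only lines
#'   observed in both contribute.
#' @param min_shared minimum jointly observed lines (default 30).
#' @param generations inbreeding generation used for the selfed-RIL
#'   correction: \code{Inf} (default) applies the classical
#'   Haldane-Waddington r = R / (2 - 2R); a finite value (e.g. 7 for F7
#'   populations) inverts the exact finite-generation discordance of
#'   [selfedDiscordance()], which removes the ~7% map deflation the
#'   infinite-generation shortcut causes on partially inbred lines.
#' @return List: \code{R} (observed discordance), \code{r} (meiotic
#'   recombination fraction after selfed-RIL correction), \code{d_cM}
#'   (Haldane distance; \code{Inf} and \code{unlinked = TRUE} when the
#'   corrected r reaches 0.5), \code{n} (lines used).
#' @examples
#' rfBetweenBins(c(0, 0, 2, 2), c(0, 2, 2, 2), min_shared = 1)
#' @export
rfBetweenBins <- function(g1, g2, min_shared = 30, generations = Inf) {
    use <- !is.na(g1) & !is.na(g2)
    n <- sum(use)
    if (n < min_shared)
        .stopf("only %d lines observed in both bins (need %d)", n, min_shared)
    R <- mean(g1[use] != g2[use])
    .haldaneFromR(R, n, generations)
}

.haldaneFromR <- function(R, n, generations = Inf) {
    r <- if (is.finite(generations)) .invertSelfedR(R, generations) else
        R / (2 - 2 * R)
    unlinked <- r >= 0.5
    r <- min(max(r, 0), 0.5 - 1e-12)
    d <- if (unlinked) Inf else -50 * log(1 - 2 * r)
    list(R = R, r = if (unlinked) 0.5 else r, d_cM = d,
         unlinked = unlinked, n = n)
}

#' Expected discordance between two loci in selfed RILs at generation t
#'
#' Exact two-locus computation for single-seed descent: an F1 in coupling
#' is selfed for \code{generations - 1} rounds; the returned value is the
#' probability that a line homozygous at both loci carries a recombinant
#' haplotype.  As \code{generations} grows this converges to the classical
#' Haldane-Waddington 2r / (1 + 2r).
#'
#' @param r meiotic recombination fraction (vectorized).
#' @param generations inbreeding generation (7 = F7).
#' @return Expected observed discordance R.
#' @export
selfedDiscordance <- function(r, generations = 7) {
    vapply(r, function(rr) {
        ## haplotypes 1..4 = AB, Ab, aB, ab; genotype = ordered pair
        gamProb <- function(i, j, rr) {
            p <- numeric(4)
            p[i] <- p[i] + (1 - rr) / 2
            p[j] <- p[j] + (1 - rr) / 2
            a <- c(1, 1, 2, 2)[c(i, j)]   # allele index at locus A (1=A,2=a)
            b <- c(1, 2, 1, 2)[c(i, j)]   # allele index at locus B
            hap <- function(ai, bi) (ai - 1) * 2 + bi
            p[hap(a[1], b[2])] <- p[hap(a[1], b[2])] + rr / 2
            p[hap(a[2], b[1])] <- p[hap(a[2], b[1])] + rr / 2
            p
        }
        ## genotype distribution over ordered haplotype pairs (16 states)
        v <- matrix(0, 4, 4)
        v[1, 4] <- 1                       # F1: AB / ab
        for (g in seq_len(max(generations - 1, 0))) {
            nv <- matrix(0, 4, 4)
            for (i in 1:4) for (j in 1:4) {
                if (v[i, j] == 0) next
                gp <- gamProb(i, j, rr)
                nv <- nv + v[i, j] * outer(gp, gp)
            }
            v <- nv
        }
        conc <- v[1, 1] + v[4, 4]
        disc <- v[2, 2] + v[3, 3]
        if (conc + disc == 0) 0 else disc / (conc + disc)
    }, 0)
}

## numeric inverse of selfedDiscordance in r, cached per generation
.selfedInvCache <- new.env()
.invertSelfedR <- function(R, generations) {
    key <- as.character(generations)
    if (is.null(.selfedInvCache[[key]])) {
        grid <- seq(0, 0.5, length.out = 201)
        .selfedInvCache[[key]] <-
            list(r = grid, R = selfedDiscordance(grid, generations))
    }
    tab <- .selfedInvCache[[key]]
    if (R >= max(tab$R)) return(0.5)
    if (R <= 0) return(0)
    stats::approx(tab$R, tab$r, xout = R, ties = "ordered")$y
}

#' Haldane map function and its inverse
#'
#' \code{haldane_cM(r)} = -50 ln(1 - 2r); \code{haldane_r(d)} is the
#' inverse (1 - exp(-d/50)) / 2.
#' @param r recombination fraction in [0, 0.5).
#' @param d_cM map distance in cM.
#' @return Numeric vector.
#' @export
haldane_cM <- function(r) -50 * log(1 - 2 * r)

#' @rdname haldane_cM
#' @export
haldane_r <- function(d_cM) (1 - exp(-d_cM / 50)) / 2

#' Build a per-family genetic map from an imputed bin map
#'
#' Markers (bins) stay in physical order; cM positions are the cumulative
#' sum of adjacent-bin Haldane distances.  Unlinked adjacent bins get a
#' capped distance and are recorded in the \code{"capped"} attribute.
#'
#' @param bm an imputed \linkS4class{BinMap}.
#' @param min_shared passed to [rfBetweenBins()].
#' @param cap_cM distance used when adjacent bins appear unlinked
#'   (default 50).
#' @param generations inbreeding generation for the RIL correction
#'   (default 7: the F7 single-seed-descent populations this package
#'   targets; see [rfBetweenBins()]).
#' @return A \linkS4class{GeneticMap}.
#' @export
buildFamilyMap <- function(bm, min_shared = 30, cap_cM = 50,
                           generations = 7) {
    bins <- binRanges(bm)
    g <- binGenotypes(bm)
    chroms <- as.character(seqnames(bins))
    rows <- list(); capped <- character(0)
    for (ch in unique(chroms)) {
        ix <- which(chroms == ch)
        cm <- numeric(length(ix))
        if (length(ix) > 1) for (k in 2:length(ix)) {
            rf <- rfBetweenBins(g[, ix[k - 1]], g[, ix[k]], min_shared,
                                generations)
            d <- rf$d_cM
            if (rf$unlinked || d > cap_cM) {
                if (rf$unlinked)
                    capped <- c(capped, names(bins)[ix[k]])
                d <- min(d, cap_cM)
            }
            cm[k] <- cm[k - 1] + d
        }
        rows[[ch]] <- data.frame(marker = names(bins)[ix], chrom = ch,
                                 pos = round((start(bins)[ix] +
                                              end(bins)[ix]) / 2),
                                 cM = cm)
    }
    out <- geneticMap(do.call(rbind, rows))
    attr(out, "capped") <- capped
    out
}

#' Select markers for the composite map and encode them across families
#'
#' A marker is eligible when it is polymorphic (segregating) in strictly
#' more than \code{min_families} families.  Eligible markers are encoded
#' per RIL: 1 = common-parent allele, 0 = diverse-parent allele, NA for
#' heterozygous or missing calls and for all RILs of families in which the
#' marker is monomorphic.
#'
#' @param originList named list (per family) of lines x sites matrices of
#'   origin-coded calls (0 common / 2 diverse / NA), all on the same
#'   site set; a site is polymorphic in a family when its column there
#'   has at least one 0 and one 2.
#' @param min_families threshold: keep markers polymorphic in more than
#'   this many families (default 2, i.e. at least 3).
#' @return List: \code{markers} (kept site indices) and \code{encoding}
#'   (all-lines x kept-sites matrix over \{1, 0, NA\}).
#' @export
selectCompositeMarkers <- function(originList, min_families = 2) {
    polyBy <- vapply(originList, function(m)
        colSums(m == 0L, na.rm = TRUE) > 0 & colSums(m == 2L, na.rm = TRUE) > 0,
        logical(ncol(originList[[1]])))
    keep <- which(rowSums(polyBy) > min_families)
    enc <- do.call(rbind, lapply(names(originList), function(f) {
        m <- originList[[f]][, keep, drop = FALSE]
        e <- matrix(NA_integer_, nrow(m), ncol(m), dimnames = dimnames(m))
        e[m == 0L] <- 1L                      # common-parent allele
        e[m == 2L] <- 0L                      # diverse allele
        e[, !polyBy[keep, f]] <- NA_integer_  # monomorphic in this family
        e
    }))
    list(markers = keep, encoding = enc)
}

#' Build joint recombination bins from a composite encoding
#'
#' Consecutive sites whose encoded columns are identical across all RILs
#' (NA treated as a value) collapse into one bin; bins smaller than
#' \code{min_bp} are merged into the next.
#'
#' @param encoding lines x markers matrix from [selectCompositeMarkers()].
#' @param sites GRanges of the encoded markers (width-1 positions).
#' @param family family id per line.
#' @param chromLengths named vector of chromosome lengths (bins tile the
#'   chromosome).
#' @param min_bp small-bin merge threshold (default 5000).
#' @return A \linkS4class{BinMap} whose genotypes use the composite coding
#'   \{0 = diverse, 2 = common, NA\} re-expressed as 0/2 with 2 = common
#'   allele code 1 doubled; see Details.
#' @details The composite encoding is 1/0/NA; to reuse the BinMap
#'   container (which stores 0/2/NA) code 1 is stored as 2.  Column-level
#'   semantics are unchanged.
#' @export
compositeBins <- function(encoding, sites, family, chromLengths,
                          min_bp = 5000) {
    chroms <- as.character(seqnames(sites))
    pos <- start(sites)
    stored <- encoding * 2L                  # 1 -> 2, 0 -> 0
    binsL <- list(); gL <- list()
    for (ch in unique(chroms)) {
        ix <- which(chroms == ch)
        sub <- stored[, ix, drop = FALSE]
        key <- apply(sub, 2, function(col)
            paste(ifelse(is.na(col), ".", col), collapse = ""))
        grp <- cumsum(c(TRUE, key[-1] != key[-length(key)]))
        first <- which(!duplicated(grp))
        last <- which(!duplicated(grp, fromLast = TRUE))
        p <- pos[ix]
        cut <- if (length(first) > 1)
            floor((p[last[-length(last)]] + p[first[-1]]) / 2) else numeric(0)
        bs <- c(1, cut + 1); be <- c(cut, chromLengths[[ch]])
        binsL[[ch]] <- GRanges(ch, IRanges(bs, be))
        gL[[ch]] <- sub[, first, drop = FALSE]
    }
    bins <- do.call(c, unname(binsL))
    names(bins) <- sprintf("%s_jbin%04d", as.character(seqnames(bins)),
                           unlist(lapply(binsL, seq_along)))
    g <- do.call(cbind, gL)
    colnames(g) <- names(bins)
    mergeSmallBins(binMap(bins, g, family), min_bp)
}

#' Chi-square test for segregation distortion of one marker
#'
#' 1-df chi-square of the observed counts of the two homozygous codes
#' against the 1:1 expectation of a RIL family; distorted iff P < alpha.
#'
#' @param column genotype codes (0/2 or 0/1) with NA.
#' @param alpha significance level (default 0.05).
#' @return List: chisq, p, distorted, n.
#' @examples
#' segregationTest(rep(c(0, 2), c(70, 30)))   # chisq 16, P ~ 6.3e-5
#' @export
segregationTest <- function(column, alpha = 0.05) {
    v <- column[!is.na(column)]
    if (!length(v)) .stopf("no informative calls")
    lev <- sort(unique(v))
    n1 <- sum(v == lev[1])
    n <- length(v)
    chisq <- (n1 - n / 2)^2 / (n / 2) + ((n - n1) - n / 2)^2 / (n / 2)
    p <- pchisq(chisq, df = 1, lower.tail = FALSE)
    list(chisq = chisq, p = p, distorted = p < alpha, n = n)
}

## pooled across-family discordance between two columns: families weighted
## by their informative RIL count (both markers observed)
.pooledRF <- function(g1, g2, fam, generations = 7) {
    use <- !is.na(g1) & !is.na(g2)
    n <- sum(use)
    if (n == 0) return(list(R = NA_real_, r = 0.5, d_cM = Inf,
                            unlinked = TRUE, n = 0))
    R <- mean(g1[use] != g2[use])
    .haldaneFromR(R, n, generations)
}

## two-point linkage LOD for RIL-coded columns under r = R vs r = 0.5
.linkageLOD <- function(g1, g2) {
    use <- !is.na(g1) & !is.na(g2)
    n <- sum(use)
    if (n == 0) return(0)
    k <- sum(g1[use] != g2[use])
    R <- k / n
    if (R >= 0.5) return(0)
    ll <- k * log10(max(R, 1e-12)) + (n - k) * log10(1 - R)
    ll0 <- n * log10(0.5)
    ll - ll0
}

#' Assemble the composite genetic map
#'
#' Linkage groups are formed by single-linkage clustering of markers at a
#' pairwise linkage LOD of at least \code{lod_group}; a group spanning two
#' chromosomes signals upstream contamination and raises an error.  The
#' framework map consists of the non-distorted markers in physical order
#' with cM from pooled across-family recombination fractions.  Distorted
#' markers are then inserted at their physical rank; an inserted marker
#' whose distances to its flanking framework markers are inconsistent
#' with the framework interval (genetic position conflicting with
#' physical order) is excluded.
#'
#' @param bm composite \linkS4class{BinMap} from [compositeBins()].
#' @param alpha distortion significance level (default 0.05).
#' @param lod_group linkage-group LOD threshold (default 10).
#' @param slack_cM tolerance when checking a distorted marker's placement
#'   (default 5 cM).
#' @param maxPairwise compute the full pairwise linkage-group check only
#'   up to this marker count (quadratic cost); above it adjacent-marker
#'   chaining is used.
#' @param generations inbreeding generation for the RIL correction
#'   (default 7).
#' @return A \linkS4class{GeneticMap}; excluded markers are listed in the
#'   \code{"excluded"} attribute.
#' @export
assembleCompositeMap <- function(bm, alpha = 0.05, lod_group = 10,
                                 slack_cM = 5, maxPairwise = 800,
                                 generations = 7) {
    bins <- binRanges(bm)
    g <- binGenotypes(bm)
    fam <- familyOf(bm)
    chroms <- as.character(seqnames(bins))
    m <- length(bins)
    ## segregation distortion per marker
    distorted <- vapply(seq_len(m), function(j) {
        col <- g[, j]
        if (all(is.na(col))) TRUE else segregationTest(col, alpha)$distorted
    }, logical(1))
    ## linkage groups
    groups <- .linkageGroups(g, lod_group, maxPairwise)
    for (grp in unique(groups)) {
        if (length(unique(chroms[groups == grp])) > 1)
            .stopf("linkage group spans two chromosomes (group %s)", grp)
    }
    rows <- list(); excluded <- character(0)
    for (ch in unique(chroms)) {
        ix <- which(chroms == ch)
        fw <- ix[!distorted[ix]]
        if (!length(fw)) { excluded <- c(excluded, names(bins)[ix]); next }
        ## framework cM by cumulative pooled distances, physical order
        cm <- numeric(length(fw))
        if (length(fw) > 1) for (k in 2:length(fw)) {
            rf <- .pooledRF(g[, fw[k - 1]], g[, fw[k]], fam, generations)
            cm[k] <- cm[k - 1] + min(rf$d_cM, 50)
        }
        cmOf <- setNames(cm, names(bins)[fw])
        keepDist <- integer(0); distCM <- numeric(0)
        for (j in ix[distorted[ix]]) {
            posj <- start(bins)[j]
            li <- which(start(bins)[fw] < posj)
            ri <- which(start(bins)[fw] > posj)
            if (!length(li) || !length(ri)) {
                ## terminal insertion: distance to the single neighbour
                nb <- if (length(li)) fw[max(li)] else fw[min(ri)]
                d <- .pooledRF(g[, j], g[, nb], fam, generations)$d_cM
                if (!is.finite(d) || d > 50) {
                    excluded <- c(excluded, names(bins)[j]); next
                }
                distCM <- c(distCM, if (length(li)) cmOf[[length(cmOf)]] + d
                            else -d)
                keepDist <- c(keepDist, j)
                next
            }
            L <- fw[max(li)]; Rr <- fw[min(ri)]
            dL <- .pooledRF(g[, j], g[, L], fam, generations)$d_cM
            dR <- .pooledRF(g[, j], g[, Rr], fam, generations)$d_cM
            span <- cmOf[[match(Rr, fw)]] - cmOf[[match(L, fw)]]
            if (!is.finite(dL) || !is.finite(dR) ||
                dL > span + slack_cM || dR > span + slack_cM) {
                excluded <- c(excluded, names(bins)[j])
            } else {
                keepDist <- c(keepDist, j)
                distCM <- c(distCM,
                            cmOf[[match(L, fw)]] +
                                (dL + (span - dR)) / 2)
            }
        }
        tab <- data.frame(marker = c(names(bins)[fw], names(bins)[keepDist]),
                          chrom = ch,
                          pos = start(bins)[c(fw, keepDist)],
                          cM = c(cm, distCM),
                          distorted = c(rep(FALSE, length(fw)),
                                        rep(TRUE, length(keepDist))),
                          framework = c(rep(TRUE, length(fw)),
                                        rep(FALSE, length(keepDist))))
        tab <- tab[order(tab$pos), ]
        ## monotone regularization: any residual order conflict from the
        ## insertion step is resolved by excluding the conflicting marker
        while (nrow(tab) > 1 && any(diff(tab$cM) < -1e-9)) {
            bad <- which(diff(tab$cM) < -1e-9)[1] + 1
            excluded <- c(excluded, tab$marker[bad])
            tab <- tab[-bad, ]
        }
        tab$cM <- tab$cM - min(tab$cM)
        rows[[ch]] <- tab
    }
    out <- geneticMap(do.call(rbind, rows))
    attr(out, "excluded") <- excluded
    out
}

.linkageGroups <- function(g, lod_group, maxPairwise) {
    m <- ncol(g)
    if (m <= 1) return(rep(1L, m))
    if (m <= maxPairwise) {
        M0 <- (!is.na(g)) & g == 0; storage.mode(M0) <- "double"
        M2 <- (!is.na(g)) & g == 2; storage.mode(M2) <- "double"
        obs <- M0 + M2
        n <- crossprod(obs)
        k <- crossprod(M0, M2) + crossprod(M2, M0)
        R <- ifelse(n > 0, k / n, 0.5)
        lod <- k * log10(pmax(R, 1e-12)) + (n - k) * log10(pmax(1 - R, 1e-12)) -
            n * log10(0.5)
        lod[R >= 0.5 | n == 0] <- 0
        parent <- seq_len(m)
        find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
        edges <- which(lod >= lod_group & upper.tri(lod), arr.ind = TRUE)
        for (e in seq_len(nrow(edges))) {
            ri <- find(edges[e, 1]); rj <- find(edges[e, 2])
            if (ri != rj) parent[rj] <- ri
        }
        vapply(seq_len(m), find, 0L)
    } else {
        ## adjacent chaining (markers are in physical order)
        grp <- integer(m); grp[1] <- 1L
        for (j in 2:m)
            grp[j] <- if (.linkageLOD(g[, j - 1], g[, j]) >= lod_group)
                grp[j - 1] else grp[j - 1] + 1L
        grp
    }
}
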