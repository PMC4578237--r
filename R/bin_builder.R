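## From decoded per-site origins to blocks, breakpoints and family-level
## recombination bins.
##
## Conventions: a block spans the first to the last informative site of a
## run of identical decoded states; a breakpoint sits at the midpoint
## between the last site of one block and the first site of the next; bins
## tile the whole chromosome (first bin starts at 1, last ends at the
## chromosome length); the short-block mask is the conjunction
## (length < 1,500 kb) AND (supporting SNPs < 5).

#' Call genotype blocks and breakpoints for one RIL
#'
#' Maximal runs of identical non-NA decoded states become blocks; missing
#' sites do not interrupt a run.  A breakpoint is placed at the midpoint
#' between the last site of one block and the first site of the next.
#'
#' @param states integer vector of decoded origins (0/2/NA) along one
#'   chromosome.
#' @param pos physical positions (bp) of the sites, increasing.
#' @return List: \code{blocks} (data.frame start, end, genotype, n_snps)
#'   and \code{breakpoints} (numeric positions).
#' @export
callBlocks <- function(states, pos) {
    inf <- which(!is.na(states))
    if (!length(inf))
        return(list(blocks = data.frame(start = numeric(0), end = numeric(0),
                                        genotype = integer(0),
                                        n_snps = integer(0)),
                    breakpoints = numeric(0)))
    s <- states[inf]; p <- pos[inf]
    r <- rle(s)
    ends <- cumsum(r$lengths)
    starts <- c(1L, head(ends, -1) + 1L)
    blocks <- data.frame(start = p[starts], end = p[ends],
                         genotype = r$values, n_snps = r$lengths)
    bp <- if (nrow(blocks) > 1)
        (blocks$end[-nrow(blocks)] + blocks$start[-1]) / 2 else numeric(0)
    list(blocks = blocks, breakpoints = bp)
}

#' Mask short, weakly supported blocks
#'
#' A block is masked (treated as missing) if and only if its physical
#' length is below \code{min_bp} AND it is supported by fewer than
#' \code{min_snps} sequenced SNPs -- short well-supported and long
#' weakly-supported blocks survive.  Flanking blocks with the same
#' genotype are re-merged after masking.
#'
#' @param blocks data.frame from [callBlocks()].
#' @param min_bp,min_snps mask thresholds (defaults 1,500 kb and 5).
#' @return data.frame of retained blocks with re-computed breakpoints as
#'   attribute \code{"breakpoints"}.
#' @export
maskShortBlocks <- function(blocks, min_bp = 1.5e6, min_snps = 5) {
    blocks$n_snps <- as.integer(blocks$n_snps)
    if (nrow(blocks)) {
        len <- blocks$end - blocks$start + 1
        masked <- len < min_bp & blocks$n_snps < min_snps
        blocks <- blocks[!masked, , drop = FALSE]
    }
    if (nrow(blocks) > 1) {
        r <- rle(blocks$genotype)
        ends <- cumsum(r$lengths)
        starts <- c(1L, head(ends, -1) + 1L)
        blocks <- data.frame(start = blocks$start[starts],
                             end = blocks$end[ends],
                             genotype = r$values,
                             n_snps = vapply(seq_along(starts), function(i)
                                 sum(blocks$n_snps[starts[i]:ends[i]]), 0L))
    }
    rownames(blocks) <- NULL
    bp <- if (nrow(blocks) > 1)
        (blocks$end[-nrow(blocks)] + blocks$start[-1]) / 2 else numeric(0)
    attr(blocks, "breakpoints") <- bp
    blocks
}

## Per-RIL genotype lookup for arbitrary intervals, given masked blocks.
## Returns the block genotype when the interval holds informative sites or
## its centre lies within a block's site span; genotype extends to the
## chromosome ends beyond the terminal blocks; transition gaps are NA.
.genotypeAtBins <- function(blocks, binStart, binEnd, sitePos, siteState) {
    nb <- length(binStart)
    out <- rep(NA_integer_, nb)
    if (!nrow(blocks)) return(out)
    ## informative sites voting
    inf <- which(!is.na(siteState))
    if (length(inf)) {
        idx <- findInterval(sitePos[inf], binStart)
        firstOfBin <- !duplicated(idx)
        out[idx[firstOfBin]] <- siteState[inf][firstOfBin]
    }
    ## remaining bins: locate centre relative to block site spans
    rest <- which(is.na(out))
    if (length(rest)) {
        c_ <- (binStart[rest] + binEnd[rest]) / 2
        lower <- findInterval(c_, blocks$start)       # last block starting <= c
        g <- rep(NA_integer_, length(rest))
        inSpan <- lower >= 1 & c_ <= blocks$end[pmax(lower, 1)]
        g[inSpan] <- blocks$genotype[lower[inSpan]]
        g[lower == 0] <- blocks$genotype[1]           # before first block
        beyond <- c_ > blocks$end[nrow(blocks)]
        g[beyond] <- blocks$genotype[nrow(blocks)]
        out[rest] <- g
    }
    out
}

#' Build the family-level recombination bin map
#'
#' The chromosome is partitioned at the union of all RILs' breakpoints;
#' adjacent intervals whose genotype columns are identical across every
#' RIL (treating NA as a value) are merged into one bin.  Per-RIL bin
#' genotypes come from the masked blocks; bins falling in a RIL's
#' transition gap (between two different-genotype blocks) are NA, to be
#' filled by [imputeTransitionBins()].
#'
#' @param decoded lines x sites matrix of decoded origins (0/2/NA) for one
#'   chromosome; rownames are RIL ids.
#' @param pos site positions (bp).
#' @param chrom chromosome id.
#' @param chromLength chromosome length in bp.
#' @param family family id for the lines.
#' @param min_bp,min_snps mask thresholds passed to [maskShortBlocks()].
#' @return A \linkS4class{BinMap} whose bins tile [1, chromLength].
#' @export
buildFamilyBins <- function(decoded, pos, chrom, chromLength, family,
                            min_bp = 1.5e6, min_snps = 5) {
    if (nrow(decoded) < 2) .stopf("a family needs at least 2 RILs")
    nR <- nrow(decoded)
    blocksL <- vector("list", nR)
    cuts <- numeric(0)
    for (r in seq_len(nR)) {
        cb <- callBlocks(decoded[r, ], pos)
        mb <- maskShortBlocks(cb$blocks, min_bp, min_snps)
        blocksL[[r]] <- mb
        cuts <- c(cuts, attr(mb, "breakpoints"))
    }
    cutInt <- sort(unique(floor(cuts)))
    cutInt <- cutInt[cutInt >= 1 & cutInt < chromLength]
    binStart <- c(1, cutInt + 1)
    binEnd <- c(cutInt, chromLength)
    ## post-mask per-site states (sites inside masked regions become NA)
    g <- matrix(NA_integer_, nR, length(binStart),
                dimnames = list(rownames(decoded), NULL))
    for (r in seq_len(nR)) {
        mb <- blocksL[[r]]
        maskedStates <- .maskStates(decoded[r, ], pos, mb)
        g[r, ] <- .genotypeAtBins(mb, binStart, binEnd, pos, maskedStates)
    }
    ## merge adjacent identical columns (NA treated as a value)
    key <- apply(g, 2, function(col) paste(ifelse(is.na(col), ".", col),
                                           collapse = ""))
    grp <- cumsum(c(TRUE, key[-1] != key[-length(key)]))
    first <- !duplicated(grp)
    last <- !duplicated(grp, fromLast = TRUE)
    bins <- GRanges(chrom, IRanges(binStart[first], binEnd[last]))
    names(bins) <- sprintf("%s_bin%04d", chrom, seq_along(bins))
    gm <- g[, first, drop = FALSE]
    colnames(gm) <- names(bins)
    binMap(bins, gm, family)
}

## site states restricted to the retained blocks (masked regions -> NA)
.maskStates <- function(states, pos, blocks) {
    out <- rep(NA_integer_, length(states))
    if (!nrow(blocks)) return(out)
    idx <- findInterval(pos, blocks$start)
    ok <- idx >= 1 & pos <= blocks$end[pmax(idx, 1)] & !is.na(states)
    ## a site keeps its state only if it lies in a block of that state
    ok <- ok & states == blocks$genotype[pmax(idx, 1)]
    out[ok] <- states[ok]
    out
}

#' Merge bins smaller than a minimum physical size
#'
#' A bin strictly smaller than \code{min_bp} is merged into the next bin
#' on the chromosome (into the previous one if it is last).  The merged
#' genotype column starts from the larger constituent; cells where the two
#' constituents disagree (both non-NA) become NA, cells missing in the
#' larger are filled from the smaller.
#'
#' @param bm a \linkS4class{BinMap}.
#' @param min_bp minimum bin width in bp (default 5000; strict "<").
#' @return A \linkS4class{BinMap} with all bins at least \code{min_bp}
#'   wide (unless a whole chromosome is shorter).
#' @export
mergeSmallBins <- function(bm, min_bp = 5000) {
    bins <- binRanges(bm)
    g <- binGenotypes(bm)
    chroms <- as.character(seqnames(bins))
    outBins <- list(); outG <- list()
    for (ch in unique(chroms)) {
        ix <- which(chroms == ch)
        s <- start(bins)[ix]; e <- end(bins)[ix]
        gg <- g[, ix, drop = FALSE]
        repeat {
            w <- e - s + 1
            small <- which(w < min_bp)
            if (!length(small) || length(s) == 1) break
            i <- small[1]
            j <- if (i < length(s)) i + 1L else i - 1L
            a <- min(i, j); b <- max(i, j)
            wi <- e[i] - s[i] + 1; wj <- e[j] - s[j] + 1
            big <- if (wj >= wi) gg[, j] else gg[, i]
            sml <- if (wj >= wi) gg[, i] else gg[, j]
            merged <- big
            conflict <- !is.na(big) & !is.na(sml) & big != sml
            merged[conflict] <- NA
            fill <- is.na(big) & !is.na(sml)
            merged[fill] <- sml[fill]
            s <- s[-b]; eNew <- e; eNew[a] <- e[b]; e <- eNew[-b]
            gg[, a] <- merged
            gg <- gg[, -b, drop = FALSE]
        }
        outBins[[ch]] <- GRanges(ch, IRanges(s, e))
        outG[[ch]] <- gg
    }
    allBins <- do.call(c, unname(outBins))
    names(allBins) <- sprintf("%s_bin%04d", as.character(seqnames(allBins)),
                              unlist(lapply(outBins, seq_along)))
    gAll <- do.call(cbind, unname(outG))
    colnames(gAll) <- names(allBins)
    binMap(allBins, gAll, familyOf(bm))
}

#' Impute missing bin genotypes at transition regions
#'
#' NA bins flanked by two agreeing non-NA bins of the same RIL take that
#' value; otherwise the RIL's whole bin sequence is decoded with the
#' two-state origin HMM at the bin midpoints and the posterior-argmax
#' state fills the gap.  RILs with an all-NA chromosome are left NA and
#' reported in the \code{"unimputed"} attribute.
#'
#' @param bm a \linkS4class{BinMap}.
#' @param cm_per_bp genetic-to-physical scaling used for the HMM
#'   transition distances (single value or named per chromosome).
#' @param params [hmmParams()] for the fill (the posterior threshold is
#'   ignored here: every NA receives the argmax state).
#' @return A \linkS4class{BinMap} without NA (except reported RILs).
#' @export
imputeTransitionBins <- function(bm, cm_per_bp = 1e-6,
                                 params = hmmParams()) {
    bins <- binRanges(bm)
    g <- binGenotypes(bm)
    chroms <- as.character(seqnames(bins))
    unimputed <- character(0)
    for (ch in unique(chroms)) {
        ix <- which(chroms == ch)
        scale <- if (length(cm_per_bp) > 1) cm_per_bp[[ch]] else cm_per_bp
        mid_cM <- (start(bins)[ix] + end(bins)[ix]) / 2 * scale
        sub <- g[, ix, drop = FALSE]
        naRow <- apply(sub, 1, anyNA)
        for (r in which(naRow)) {
            v <- sub[r, ]
            if (all(is.na(v))) {
                unimputed <- c(unimputed, rownames(g)[r])
                next
            }
            v <- .fillRun(v, mid_cM, params)
            sub[r, ] <- v
        }
        g[, ix] <- sub
    }
    out <- binMap(bins, g, familyOf(bm))
    attr(out, "unimputed") <- unique(unimputed)
    out
}

## fill NA runs in one RIL's bin sequence
.fillRun <- function(v, mid_cM, params) {
    na <- is.na(v)
    idx <- which(na)
    obs <- which(!na)
    for (i in idx) {
        left <- obs[obs < i]
        right <- obs[obs > i]
        lv <- if (length(left)) v[max(left)] else NA
        rv <- if (length(right)) v[min(right)] else NA
        if (!is.na(lv) && !is.na(rv) && lv == rv) v[i] <- lv
        else if (is.na(lv)) v[i] <- rv
        else if (is.na(rv)) v[i] <- lv
    }
    if (!anyNA(v)) return(v)
    ## disagreeing flanks: HMM posterior over the full bin sequence
    post <- decodeRIL(v, mid_cM,
                      hmmParams(params$epsilon, params$rho, p_min = 0.5),
                      returnPosterior = TRUE)$posterior
    p1 <- if (is.null(dim(post))) post[1] else post[, 1]
    fill <- ifelse(p1 >= 0.5, 0L, 2L)
    v[is.na(v)] <- fill[is.na(v)]
    v
}

#' Predicted breakpoints of a bin map
#'
#' Transitions between consecutive bins with different non-NA genotypes;
#' each breakpoint is reported at the boundary between the two bins.
#'
#' @param bm a \linkS4class{BinMap} (ideally after
#'   [imputeTransitionBins()]).
#' @return data.frame (ril, chrom, pos, leftBin, rightBin).
#' @export
predictedBreakpoints <- function(bm) {
    bins <- binRanges(bm)
    g <- binGenotypes(bm)
    chroms <- as.character(seqnames(bins))
    out <- list()
    for (ch in unique(chroms)) {
        ix <- which(chroms == ch)
        if (length(ix) < 2) next
        sub <- g[, ix, drop = FALSE]
        bound <- (end(bins)[ix][-length(ix)] + start(bins)[ix][-1]) / 2
        for (r in seq_len(nrow(sub))) {
            v <- sub[r, ]
            d <- which(!is.na(v[-length(v)]) & !is.na(v[-1]) &
                       v[-length(v)] != v[-1])
            if (length(d))
                out[[length(out) + 1L]] <- data.frame(
                    ril = rownames(sub)[r], chrom = ch, pos = bound[d],
                    leftBin = names(bins)[ix][d],
                    rightBin = names(bins)[ix][d + 1])
        }
    }
    if (!length(out))
        return(data.frame(ril = character(0), chrom = character(0),
                          pos = numeric(0), leftBin = character(0),
                          rightBin = character(0)))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Compare predicted breakpoints against simulator truth
#'
#' A true breakpoint counts as recovered when the same RIL has a predicted
#' breakpoint within one bin boundary: the bin pair flanking the predicted
#' boundary must touch the bin holding the true position or one of its
#' immediate neighbours.  Matching is greedy one-to-one per RIL in order
#' of proximity; unmatched predictions are spurious.
#'
#' @param bm the \linkS4class{BinMap} used for prediction (provides the
#'   bin grid).
#' @param predicted output of [predictedBreakpoints()].
#' @param truth a \linkS4class{TruthSet}.
#' @return List: recall, spuriousRate (spurious / true count), counts.
#' @export
breakpointRecovery <- function(bm, predicted, truth) {
    bins <- binRanges(bm)
    tb <- trueBreakpoints(truth)
    chroms <- as.character(seqnames(bins))
    nTrue <- nrow(tb); nPred <- nrow(predicted)
    recovered <- 0; matchedPred <- 0
    for (ch in unique(c(tb$chrom, predicted$chrom))) {
        ix <- which(chroms == ch)
        bs <- start(bins)[ix]
        tSub <- tb[tb$chrom == ch, , drop = FALSE]
        pSub <- predicted[predicted$chrom == ch, , drop = FALSE]
        tBin <- findInterval(tSub$pos, bs)
        pBin <- findInterval(pSub$pos, bs)   # boundary sits at end of this bin
        for (ril in unique(tSub$ril)) {
            ti <- which(tSub$ril == ril)
            pi <- which(pSub$ril == ril)
            if (!length(ti) && !length(pi)) next
            usedP <- logical(length(pi))
            for (t in ti[order(tSub$pos[ti])]) {
                if (!length(pi)) break
                dlt <- abs(pBin[pi] - tBin[t])
                dlt2 <- abs(pBin[pi] + 1 - tBin[t])
                cand <- which(!usedP & pmin(dlt, dlt2) <= 1)
                if (length(cand)) {
                    best <- cand[which.min(abs(pSub$pos[pi[cand]] -
                                               tSub$pos[t]))]
                    usedP[best] <- TRUE
                    recovered <- recovered + 1
                }
            }
            matchedPred <- matchedPred + sum(usedP)
        }
    }
    list(recall = if (nTrue) recovered / nTrue else NA_real_,
         spuriousRate = if (nTrue) (nPred - matchedPred) / nTrue else
             NA_real_,
         nTrue = nTrue, nPredicted = nPred, nRecovered = recovered)
}

#' Expand a bin map back to SNP coordinates
#'
#' @param bm a \linkS4class{BinMap}.
#' @param pos site positions (bp) on \code{chrom}.
#' @param chrom chromosome of the sites.
#' @return lines x sites matrix: each site takes the genotype of the bin
#'   containing it.
#' @export
expandBinsToSites <- function(bm, pos, chrom) {
    bins <- binRanges(bm)
    ix <- which(as.character(seqnames(bins)) == chrom)
    idx <- findInterval(pos, start(bins)[ix])
    binGenotypes(bm)[, ix[idx], drop = FALSE]
}
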