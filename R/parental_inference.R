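## Per-family inference of which observed allele came from the common
## parent, by minimizing the recombinations implied across RILs, followed
## by a resampling-agreement score that drops unstable sites.
##
## Observed heterozygotes are ignored (treated as missing) throughout:
## the downstream HMM works on the two homozygous origin states only.

## calls (lines x sites, "A"/"B"/"H"/NA) -> 0/1/NA numeric (H -> NA)
.ab01 <- function(calls) {
    m <- matrix(NA_real_, nrow(calls), ncol(calls), dimnames = dimnames(calls))
    m[!is.na(calls) & calls == "A"] <- 0
    m[!is.na(calls) & calls == "B"] <- 1
    m
}

#' Pre-filter sites of one family before parental inference
#'
#' Removes sites with family MAF below 0.05 and, among sites closer than
#' \code{tag_bp} (a proxy for SNPs on the same sequencing tag), keeps only
#' the one with the highest call rate.
#'
#' @param gm a \linkS4class{GenotypeMatrix} restricted to one family.
#' @param min_maf sites with MAF strictly below this are removed.
#' @param tag_bp sites whose positions differ by less than this many bp are
#'   treated as same-tag (chained: a run of closely spaced sites forms one
#'   group).
#' @return The reduced \linkS4class{GenotypeMatrix}.
#' @export
prefilterFamilySites <- function(gm, min_maf = 0.05, tag_bp = 64) {
    calls <- genoCalls(gm)
    keep <- .siteMAF(calls) >= min_maf
    gm2 <- gm[, keep]
    sites <- siteRanges(gm2)
    if (!length(sites)) return(gm2)
    callRate <- .siteCallRate(genoCalls(gm2))
    chrom <- as.character(seqnames(sites))
    pos <- start(sites)
    grp <- cumsum(c(TRUE, !(chrom[-1] == chrom[-length(chrom)] &
                            diff(pos) < tag_bp)))
    best <- vapply(split(seq_along(grp), grp), function(ix)
        ix[which.max(callRate[ix])], 0L)
    gm2[, sort(best)]
}

#' Infer per-site parental assignment by maximum parsimony
#'
#' Chooses, for every site, whether allele A or allele B came from the
#' common parent, minimizing the total number of parent-origin switches
#' implied between consecutive sites across all RILs (counted over RILs
#' with non-missing calls at both sites of each adjacent pair).  The
#' optimum is found exactly by a two-state shortest path along the sites;
#' ties break toward keeping the previous site's assignment, then toward
#' "allele A is common".
#'
#' The global sign is unidentifiable from RIL data alone: it is anchored
#' to known common-parent calls when supplied, otherwise to the majority
#' allele of the first informative site.
#'
#' @param gm \linkS4class{GenotypeMatrix} of one family (or a calls
#'   matrix).  Heterozygous calls are ignored.
#' @param anchor optional named character vector (site id -> "A"/"B") of
#'   known common-parent calls.
#' @param margin sites whose agree/disagree margin with both neighbours
#'   is below \code{margin * sqrt(n)} carry no linkage information (they
#'   are typically monomorphic sites surviving the MAF filter on call
#'   errors); they are excluded before the shortest path, because a
#'   single such site would let the path flip the parity of everything
#'   beyond it at negligible cost.  Set to 0 to disable.
#' @return Object of class \code{ParentalAssignment}: list with
#'   \code{assignment} (named integer, 0 = allele A is common-parent,
#'   1 = allele B is; NA for sites with no informative calls or excluded
#'   as unlinked), \code{q} (confidence, NA until
#'   [refineByResampling()]), and \code{switches} (the minimized switch
#'   count).
#' @export
inferAssignmentParsimony <- function(gm, anchor = NULL, margin = 4) {
    calls <- if (is(gm, "GenotypeMatrix")) genoCalls(gm) else gm
    m <- .ab01(calls)
    if (nrow(m) < 1) .stopf("need at least one RIL with calls")
    informative <- which(colSums(!is.na(m)) > 0)
    ids <- colnames(m)
    if (is.null(ids)) ids <- paste0("s", seq_len(ncol(m)))
    if (margin > 0 && length(informative) > 2)
        informative <- informative[
            .stronglyLinked(m[, informative, drop = FALSE], margin)]
    mi <- m[, informative, drop = FALSE]
    k <- ncol(mi)
    assign <- rep(NA_integer_, ncol(m))
    names(assign) <- ids
    if (k > 0) {
        sol <- .parsimonyDP(mi)
        a <- sol$assignment
        ## global sign
        flip <- if (!is.null(anchor)) {
            anchIdx <- match(names(anchor), ids[informative])
            ok <- !is.na(anchIdx)
            if (any(ok)) {
                implied <- ifelse(anchor[ok] == "A", 0L, 1L)
                mean(a[anchIdx[ok]] == implied) < 0.5
            } else FALSE
        } else {
            ## majority allele of the first informative site = common parent
            first <- mi[, 1]
            majority <- if (mean(first, na.rm = TRUE) > 0.5) 1L else 0L
            a[1] != majority
        }
        if (flip) a <- 1L - a
        assign[informative] <- a
        switches <- sol$cost
    } else switches <- 0
    structure(list(assignment = assign,
                   q = setNames(rep(NA_real_, length(assign)), ids),
                   switches = switches),
              class = "ParentalAssignment")
}

## Iteratively drop sites with no statistically strong link (margin
## |agree - disagree| >= margin * sqrt(n)) to either current neighbour.
## Returns indices (into the supplied matrix) of the retained backbone.
.stronglyLinked <- function(mi, margin) {
    keep <- seq_len(ncol(mi))
    repeat {
        k <- length(keep)
        if (k < 3) break
        sub <- mi[, keep, drop = FALSE]
        L <- sub[, -k, drop = FALSE]; R <- sub[, -1, drop = FALSE]
        both <- !is.na(L) & !is.na(R)
        dis <- colSums(both & (L != R), na.rm = TRUE)
        agr <- colSums(both & (L == R), na.rm = TRUE)
        n <- dis + agr
        strong <- n > 0 & abs(agr - dis) >= margin * sqrt(pmax(n, 1))
        siteStrong <- c(strong[1],
                        strong[seq_len(k - 2)] | strong[seq_len(k - 2) + 1],
                        strong[k - 1])
        if (all(siteStrong)) break
        keep <- keep[siteStrong]
    }
    keep
}

## Exact 2-state shortest path.  mi: RILs x sites 0/1/NA, all sites
## informative.  Pair costs: same assignment -> # discordant RIL pairs,
## different assignment -> # concordant pairs.
.parsimonyDP <- function(mi) {
    k <- ncol(mi)
    if (k == 1)
        return(list(assignment = 0L, cost = 0))
    L <- mi[, -k, drop = FALSE]; R <- mi[, -1, drop = FALSE]
    both <- !is.na(L) & !is.na(R)
    dis <- colSums(both & (L != R), na.rm = TRUE)
    agr <- colSums(both & (L == R), na.rm = TRUE)
    f <- matrix(Inf, k, 2)
    back <- matrix(0L, k, 2)
    f[1, ] <- 0
    for (j in 2:k) {
        for (s in 0:1) {
            stay <- f[j - 1, s + 1] + dis[j - 1]
            switch_ <- f[j - 1, 2 - s] + agr[j - 1]
            if (stay <= switch_) {           # tie -> keep previous state
                f[j, s + 1] <- stay; back[j, s + 1] <- s
            } else {
                f[j, s + 1] <- switch_; back[j, s + 1] <- 1L - s
            }
        }
    }
    last <- if (f[k, 1] <= f[k, 2]) 0L else 1L   # tie -> 0
    a <- integer(k)
    a[k] <- last
    for (j in k:2) a[j - 1] <- back[j, a[j] + 1]
    list(assignment = a, cost = min(f[k, ]))
}

#' Refine a parental assignment by resampling; drop unstable sites
#'
#' For each of \code{n_resamples} bootstrap draws of RILs (with
#' replacement), the parsimony inference is rerun on overlapping windows
#' of \code{window} sites (stride window/2); each window's sign is aligned
#' to the full-data assignment and the per-site agreement is recorded.
#' \code{q_j} is the fraction of (resample, window) runs in which site j's
#' assignment reproduces the full-data one; sites with \code{q_j < q_min}
#' are dropped.
#'
#' @param gm \linkS4class{GenotypeMatrix} (or calls matrix) of the family,
#'   same sites as used for \code{assignment}.
#' @param assignment a \code{ParentalAssignment} from
#'   [inferAssignmentParsimony()].
#' @param n_resamples bootstrap draws (at least 100).
#' @param window window width in sites (a window larger than the site
#'   count collapses to a single window).
#' @param q_min sites with agreement below this are removed.
#' @return A \code{ParentalAssignment} whose \code{assignment} has
#'   low-confidence and uninformative sites set NA and whose \code{q}
#'   carries the agreement scores.
#' @export
refineByResampling <- function(gm, assignment, n_resamples = 200,
                               window = 15, q_min = 0.9) {
    if (n_resamples < 100)
        .stopf("n_resamples must be at least 100 (got %d)", n_resamples)
    calls <- if (is(gm, "GenotypeMatrix")) genoCalls(gm) else gm
    m <- .ab01(calls)
    full <- assignment$assignment
    informative <- which(!is.na(full))
    mi <- m[, informative, drop = FALSE]
    k <- ncol(mi); nR <- nrow(mi)
    if (k == 0) return(assignment)
    w <- min(window, k)
    starts <- unique(c(seq(1, max(k - w + 1, 1), by = max(ceiling(w / 2), 1)),
                       max(k - w + 1, 1)))
    ## per-adjacent-pair indicator matrices (pairs x RILs) for weighted counts
    if (k > 1) {
        L <- t(mi[, -k, drop = FALSE]); R <- t(mi[, -1, drop = FALSE])
        both <- !is.na(L) & !is.na(R)
        DIS <- both & (L != R); AGR <- both & (L == R)
        storage.mode(DIS) <- "double"; storage.mode(AGR) <- "double"
    }
    agreeCnt <- numeric(k); totCnt <- numeric(k)
    fullI <- full[informative]
    for (r in seq_len(n_resamples)) {
        wts <- tabulate(sample.int(nR, nR, replace = TRUE), nbins = nR)
        if (k > 1) {
            disW <- as.vector(DIS %*% wts)
            agrW <- as.vector(AGR %*% wts)
        }
        for (st in starts) {
            en <- st + w - 1
            a <- if (en == st) 0L else
                .parsimonyDPCosts(disW[st:(en - 1)], agrW[st:(en - 1)])
            ref <- fullI[st:en]
            if (mean(a == ref) < 0.5) a <- 1L - a
            idx <- st:en
            agreeCnt[idx] <- agreeCnt[idx] + (a == ref)
            totCnt[idx] <- totCnt[idx] + 1
        }
    }
    q <- ifelse(totCnt > 0, agreeCnt / totCnt, NA_real_)
    qAll <- setNames(rep(NA_real_, length(full)), names(full))
    qAll[informative] <- q
    newAssign <- full
    drop <- informative[!is.na(q) & q < q_min]
    newAssign[drop] <- NA_integer_
    structure(list(assignment = newAssign, q = qAll,
                   switches = assignment$switches,
                   dropped = names(full)[drop]),
              class = "ParentalAssignment")
}

## DP given precomputed weighted pair costs
.parsimonyDPCosts <- function(dis, agr) {
    k <- length(dis) + 1
    f <- matrix(Inf, k, 2); back <- matrix(0L, k, 2)
    f[1, ] <- 0
    for (j in 2:k) {
        for (s in 0:1) {
            stay <- f[j - 1, s + 1] + dis[j - 1]
            sw <- f[j - 1, 2 - s] + agr[j - 1]
            if (stay <= sw) { f[j, s + 1] <- stay; back[j, s + 1] <- s }
            else { f[j, s + 1] <- sw; back[j, s + 1] <- 1L - s }
        }
    }
    a <- integer(k)
    a[k] <- if (f[k, 1] <= f[k, 2]) 0L else 1L
    for (j in k:2) a[j - 1] <- back[j, a[j] + 1]
    a
}

#' Mask residual-heterozygosity regions of each line
#'
#' In an F7 line a heterozygous residual region shows a characteristic
#' local signature: about half of its surviving calls are observed "H"
#' and the rest are undercalled random homozygotes.  Those random
#' homozygote runs would otherwise be decoded as short false blocks
#' (spurious double recombination).  This screen slides a window over
#' each line's observed calls and sets the whole window missing wherever
#' it contains \code{min_h} or more H calls.
#'
#' @param calls lines x sites character matrix on the A/B/H alphabet.
#' @param window window width in observed (non-missing) calls.
#' @param min_h H calls within a window that trigger masking.
#' @return The calls matrix with het-region calls set NA.
#' @export
maskHetRegions <- function(calls, window = 7, min_h = 2) {
    half <- window %/% 2
    for (r in seq_len(nrow(calls))) {
        obs <- which(!is.na(calls[r, ]))
        if (length(obs) < window) next
        h <- as.numeric(calls[r, obs] == "H")
        cnt <- as.numeric(stats::filter(h, rep(1, window), sides = 2))
        ## filter leaves NA at the edges; use one-sided counts there
        k <- length(h)
        edge <- c(seq_len(half), k - seq_len(half) + 1)
        cnt[edge] <- vapply(edge, function(i)
            sum(h[max(1, i - half):min(k, i + half)]), 0)
        bad <- which(cnt >= min_h)
        if (length(bad)) {
            ## mask every observed call inside a triggering window
            maskIdx <- unique(unlist(lapply(bad, function(i)
                max(1, i - half):min(k, i + half))))
            calls[r, obs[maskIdx]] <- NA_character_
        }
    }
    calls
}

#' Recode observed calls to parental origin
#'
#' Applies a \code{ParentalAssignment}: a homozygous call equal to the
#' common-parent allele becomes 0 (common origin), the other homozygote 2
#' (diverse origin); heterozygotes and calls at unassigned sites become NA.
#'
#' @param gm \linkS4class{GenotypeMatrix} (or calls matrix) of the family.
#' @param assignment a \code{ParentalAssignment}.
#' @param dropUnassigned drop columns whose assignment is NA (default TRUE).
#' @return List: \code{origins} (lines x sites integer matrix over
#'   \{0, 2, NA\}) and \code{sites} (kept site indices).
#' @export
encodeOrigins <- function(gm, assignment, dropUnassigned = TRUE) {
    calls <- if (is(gm, "GenotypeMatrix")) genoCalls(gm) else gm
    m <- .ab01(calls)
    a <- assignment$assignment
    keep <- if (dropUnassigned) which(!is.na(a)) else seq_along(a)
    mi <- m[, keep, drop = FALSE]
    ai <- matrix(a[keep], nrow(mi), length(keep), byrow = TRUE)
    orig <- (mi != ai) * 2
    storage.mode(orig) <- "integer"
    list(origins = orig, sites = keep)
}
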