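## Outlier screens: contaminated lines (non-parental genomes) and lines
## retaining excess heterozygosity.  Both operate on the unimputed calls.

#' Site/line filter thresholds (strict inequalities)
#'
#' @param min_taxa_coverage minimum per-line call-rate (kept lines have
#'   call rate strictly greater).
#' @param min_maf minimum minor allele frequency per site (strict).
#' @param min_site_coverage minimum per-site call rate (strict).
#' @return A list of class \code{SiteFilter}.
#' @export
siteFilter <- function(min_taxa_coverage = 0.10, min_maf = 0.01,
                       min_site_coverage = 0.20) {
    v <- c(min_taxa_coverage, min_maf, min_site_coverage)
    if (any(v < 0 | v > 1)) .stopf("filter thresholds must lie in [0, 1]")
    structure(list(min_taxa_coverage = min_taxa_coverage,
                   min_maf = min_maf,
                   min_site_coverage = min_site_coverage),
              class = "SiteFilter")
}

#' Filter SNP sites and lines by coverage and MAF
#'
#' Kept sites have MAF strictly above \code{min_maf} (heterozygotes
#' contribute one count to each allele) and call rate strictly above
#' \code{min_site_coverage}; kept lines have call rate strictly above
#' \code{min_taxa_coverage}.  All statistics are computed on the input
#' matrix, so the keep decision for one site/line never depends on which
#' others are removed.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param filter a [siteFilter()].
#' @return The reduced \linkS4class{GenotypeMatrix} (with a warning, not an
#'   error, if nothing survives).
#' @export
filterSites <- function(gm, filter = siteFilter()) {
    calls <- genoCalls(gm)
    keepSite <- .siteMAF(calls) > filter$min_maf &
        .siteCallRate(calls) > filter$min_site_coverage
    keepLine <- .lineCallRate(calls) > filter$min_taxa_coverage
    if (!any(keepSite)) .warnf("all sites removed by filter")
    if (!any(keepLine)) .warnf("all lines removed by filter")
    gm[keepLine, keepSite]
}

## numeric dosage coding for IBS: A=0, H=1, B=2, NA stays NA
.dosage <- function(calls) {
    d <- matrix(NA_real_, nrow(calls), ncol(calls), dimnames = dimnames(calls))
    d[!is.na(calls) & calls == "A"] <- 0
    d[!is.na(calls) & calls == "H"] <- 1
    d[!is.na(calls) & calls == "B"] <- 2
    d
}

## Mean IBS distance between rows of X and rows of Y: mean(|x - y|) / 2
## over shared non-missing calls; heterozygote vs homozygote counts as a
## half mismatch.  Returns list(dist, nShared).
.ibsCross <- function(X, Y) {
    ind <- function(M, v) {
        Z <- (!is.na(M)) & (M == v)
        storage.mode(Z) <- "double"
        Z
    }
    X0 <- ind(X, 0); X1 <- ind(X, 1); X2 <- ind(X, 2)
    Y0 <- ind(Y, 0); Y1 <- ind(Y, 1); Y2 <- ind(Y, 2)
    tY0 <- t(Y0); tY1 <- t(Y1); tY2 <- t(Y2)
    absSum <- X0 %*% tY1 + X1 %*% tY0 + X1 %*% tY2 + X2 %*% tY1 +
        2 * (X0 %*% tY2 + X2 %*% tY0)
    n <- (X0 + X1 + X2) %*% t(Y0 + Y1 + Y2)
    list(dist = ifelse(n > 0, absSum / (2 * n), NA_real_), nShared = n)
}

#' Neighbor-joining contamination scan
#'
#' Builds a neighbor-joining tree per chromosome from pairwise IBS
#' distances over all lines plus the founder genotypes (for manual review;
#' Newick strings are attached as an attribute), and flags a line as a
#' contaminant when, on a majority of chromosomes, some other family's
#' diverse parent is closer by IBS than the line's own diverse parent by
#' more than \code{ibs_margin} -- i.e. the line clusters with another
#' family.  The margin guards lines whose genome is mostly common-parent
#' (all diverse founders then sit at the same IBS distance up to noise).
#' Ties (no majority) break toward "not flagged".
#'
#' @param gm a \linkS4class{GenotypeMatrix} of RILs.
#' @param parents a \linkS4class{GenotypeMatrix} of founder genotypes (the
#'   common parent plus one diverse parent per family).
#' @param parentOf named character vector: family id -> row name of that
#'   family's diverse parent in \code{parents}.
#' @param commonParent row name of the common parent in \code{parents}.
#' @param ibs_margin minimum IBS-similarity advantage of a foreign founder
#'   over the line's own diverse parent for a chromosome to vote "foreign"
#'   (default 0.05).
#' @param buildTrees also compute NJ trees (set \code{FALSE} to skip the
#'   O(lines^2) distance matrix when only flags are needed).
#' @return data.frame (line, reason, evidence, detail): one row per flagged
#'   or unevaluable line; evidence is the fraction of chromosomes voting
#'   "foreign".  Attribute \code{"trees"}: named list of
#'   \link[ape]{phylo} objects per chromosome when \code{buildTrees}.
#' @export
njContaminantScan <- function(gm, parents, parentOf,
                              commonParent = "common", ibs_margin = 0.05,
                              buildTrees = FALSE) {
    calls <- .dosage(genoCalls(gm))
    ## align founder columns to the (possibly filtered) RIL site set
    pIdx <- match(names(siteRanges(gm)), names(siteRanges(parents)))
    if (anyNA(pIdx))
        .stopf("parents matrix lacks %d of the RIL sites", sum(is.na(pIdx)))
    pcalls <- .dosage(genoCalls(parents)[, pIdx, drop = FALSE])
    fam <- familyOf(gm)
    chroms <- as.character(seqnames(siteRanges(gm)))
    chromIds <- unique(chroms)
    diverse <- setdiff(rownames(pcalls), commonParent)
    votes <- matrix(NA, nrow(calls), length(chromIds),
                    dimnames = list(rownames(calls), chromIds))
    trees <- list()
    for (ch in chromIds) {
        j <- chroms == ch
        cr <- .ibsCross(calls[, j, drop = FALSE],
                        pcalls[diverse, j, drop = FALSE])
        d <- cr$dist
        evaluable <- rowSums(cr$nShared > 0) > 0
        own <- unname(parentOf[fam])
        ownD <- d[cbind(seq_len(nrow(d)), match(own, diverse))]
        foreign <- d
        foreign[cbind(seq_len(nrow(d)), match(own, diverse))] <- NA
        bestForeign <- apply(foreign, 1, function(r)
            if (all(is.na(r))) NA_real_ else min(r, na.rm = TRUE))
        ## +1: a foreign founder clearly closer; -1: own parent clearly
        ## closer; NA: chromosome uninformative (e.g. all common-parent)
        delta <- ownD - bestForeign
        v <- rep(NA_real_, nrow(d))
        v[!is.na(delta) & delta > ibs_margin] <- 1
        v[!is.na(delta) & delta < -ibs_margin] <- -1
        v[!evaluable] <- NA
        votes[, ch] <- v
        if (buildTrees) {
            all <- rbind(calls[, j, drop = FALSE], pcalls[, j, drop = FALSE])
            D <- .ibsCross(all, all)$dist
            diag(D) <- 0
            D[is.na(D)] <- max(D, na.rm = TRUE)
            trees[[ch]] <- ape::nj(as.dist(D))
        }
    }
    foreignVotes <- rowSums(votes == 1, na.rm = TRUE)
    ownVotes <- rowSums(votes == -1, na.rm = TRUE)
    nEval <- rowSums(!is.na(votes))
    unevaluable <- rowSums(!is.na(calls)) == 0
    flagged <- !unevaluable & foreignVotes > ownVotes
    voteFrac <- ifelse(nEval > 0, foreignVotes / pmax(nEval, 1), NA_real_)
    out <- rbind(
        if (any(flagged)) data.frame(line = rownames(calls)[flagged],
                                     reason = "contaminant",
                                     evidence = voteFrac[flagged],
                                     detail = "foreign founder closer on majority of informative chromosomes"),
        if (any(unevaluable)) data.frame(line = rownames(calls)[unevaluable],
                                         reason = "unevaluable",
                                         evidence = NA_real_,
                                         detail = "no overlapping calls with any founder"))
    if (is.null(out))
        out <- data.frame(line = character(0), reason = character(0),
                          evidence = numeric(0), detail = character(0))
    rownames(out) <- NULL
    attr(out, "trees") <- trees
    out
}

#' Export NJ trees from a contamination scan as Newick
#'
#' @param report output of [njContaminantScan()] run with
#'   \code{buildTrees = TRUE}.
#' @param dir output directory; one \code{<chrom>.nwk} file per chromosome.
#' @return Paths written, invisibly.
#' @export
writeNJTrees <- function(report, dir) {
    trees <- attr(report, "trees")
    if (is.null(trees) || !length(trees))
        .stopf("report carries no trees; rerun with buildTrees = TRUE")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- vapply(names(trees), function(ch) {
        p <- file.path(dir, paste0(ch, ".nwk"))
        ape::write.tree(trees[[ch]], p)
        p
    }, "")
    invisible(paths)
}

#' Excess-heterozygosity scan
#'
#' Per family, sites are first filtered to call rate strictly above
#' \code{min_site_coverage} and family MAF strictly above \code{min_maf};
#' a line whose heterozygosity ratio (H calls / non-missing calls on the
#' retained sites) is strictly above \code{threshold} is flagged.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param min_site_coverage,min_maf per-family site filters (defaults 0.66
#'   and 0.25).
#' @param threshold het-ratio cutoff (default 0.10, strict).
#' @return data.frame (line, reason, evidence, detail); evidence is the
#'   het ratio.  Lines with no retained calls are reported "unevaluable".
#' @export
excessHetScan <- function(gm, min_site_coverage = 0.66, min_maf = 0.25,
                          threshold = 0.10) {
    fam <- familyOf(gm)
    calls <- genoCalls(gm)
    out <- list()
    for (f in unique(fam)) {
        sub <- calls[fam == f, , drop = FALSE]
        keep <- .siteMAF(sub) > min_maf &
            .siteCallRate(sub) > min_site_coverage
        sub <- sub[, keep, drop = FALSE]
        nObs <- rowSums(!is.na(sub))
        hetRatio <- rowSums(sub == "H", na.rm = TRUE) /
            ifelse(nObs == 0, NA_real_, nObs)
        hi <- !is.na(hetRatio) & hetRatio > threshold
        if (any(hi))
            out[[length(out) + 1L]] <- data.frame(
                line = rownames(sub)[hi], reason = "excess_het",
                evidence = hetRatio[hi],
                detail = sprintf("het ratio on %d retained sites", ncol(sub)))
        if (any(nObs == 0))
            out[[length(out) + 1L]] <- data.frame(
                line = rownames(sub)[nObs == 0], reason = "unevaluable",
                evidence = NA_real_, detail = "no retained calls")
    }
    if (!length(out))
        return(data.frame(line = character(0), reason = character(0),
                          evidence = numeric(0), detail = character(0)))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
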