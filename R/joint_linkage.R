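## Joint-linkage QTL mapping across NAM families: family main effects are
## always in the model; marker effects are nested within families (one
## allele-substitution slope per family in which the marker segregates);
## entry/exit thresholds come from within-family permutations; each
## selected QTL gets a LOD profile over its four flanking markers per side
## and a 2-LOD support interval.
##
## Design note: every model column (family indicator or family-nested
## marker) is supported on a single family, so the design is block
## diagonal by family.  Residualizing against the current model therefore
## acts within families, and candidate nested columns for different
## families stay mutually orthogonal -- the F-test of a candidate marker
## decomposes into per-family projections.  The scan exploits this;
## `nestedMarkerTest` is the direct (slow) reference implementation of
## the same test.

## Build per-family centered, mean-imputed marker codes.
## markers: lines x m with 0/2/NA.  Returns list(M (centered, NA->0),
## seg (m x nfam logical), famIdx, famLevels).
.jlPrep <- function(families, markers) {
    famLevels <- unique(families)
    famIdx <- match(families, famLevels)
    M <- markers
    seg <- matrix(FALSE, ncol(markers), length(famLevels),
                  dimnames = list(colnames(markers), famLevels))
    for (f in seq_along(famLevels)) {
        rows <- famIdx == f
        sub <- markers[rows, , drop = FALSE]
        has0 <- colSums(!is.na(sub) & sub == 0) > 0
        has2 <- colSums(!is.na(sub) & sub == 2) > 0
        seg[, f] <- has0 & has2
        mu <- colMeans(sub, na.rm = TRUE)
        cen <- sweep(sub, 2, mu, "-")
        cen[is.na(cen)] <- 0
        cen[, !seg[, f]] <- 0            # monomorphic in f: no column
        M[rows, ] <- cen
    }
    storage.mode(M) <- "double"
    list(M = M, seg = seg, famIdx = famIdx, famLevels = famLevels)
}

## family-wise sums of z*y and z*z for every marker; Y may be a matrix
## (columns = permutations).  Returns list(num [m x k], den [m]).
.famProjections <- function(M, famIdx, Y) {
    if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1)
    m <- ncol(M)
    num2 <- matrix(0, m, ncol(Y))
    den <- numeric(m)
    for (f in unique(famIdx)) {
        rows <- famIdx == f
        Mf <- M[rows, , drop = FALSE]
        df <- colSums(Mf^2)
        nf <- crossprod(Mf, Y[rows, , drop = FALSE])     # m x k
        ok <- df > 1e-10
        num2[ok, ] <- num2[ok, ] + nf[ok, , drop = FALSE]^2 / df[ok]
        den <- den + ok
    }
    list(delta = num2, q = den)
}

#' F-test of one family-nested marker against a current model
#'
#' Adds one allele-substitution slope per family in which the marker
#' segregates (both homozygous codes present) to the current model and
#' tests the joint addition with an F-test.  Direct implementation via
#' QR of the augmented design; used as the reference for the fast scan.
#'
#' @param y named numeric response (e.g. line BLUPs).
#' @param families family id per line.
#' @param marker genotype codes 0/2/NA per line.
#' @param covariates optional matrix of extra forced columns (e.g. other
#'   selected QTL terms).
#' @return List: F, p, df1 (segregating families), df2.
#' @export
nestedMarkerTest <- function(y, families, marker, covariates = NULL) {
    prep <- .jlPrep(families, matrix(marker, ncol = 1))
    if (sum(prep$seg) == 0)
        return(list(F = NA_real_, p = NA_real_, df1 = 0L, df2 = NA_integer_,
                    skipped = TRUE))
    famF <- factor(families)
    X0 <- model.matrix(~famF)
    if (!is.null(covariates)) X0 <- cbind(X0, covariates)
    Z <- sapply(which(prep$seg[1, ]), function(f)
        prep$M[, 1] * (prep$famIdx == f))
    X1 <- cbind(X0, Z)
    q0 <- qr(X0); q1 <- qr(X1)
    rss0 <- sum(qr.resid(q0, y)^2)
    rss1 <- sum(qr.resid(q1, y)^2)
    df1 <- q1$rank - q0$rank
    df2 <- length(y) - q1$rank
    if (df1 == 0 || df2 <= 0)
        return(list(F = NA_real_, p = NA_real_, df1 = df1, df2 = df2,
                    skipped = TRUE))
    Fv <- ((rss0 - rss1) / df1) / (rss1 / df2)
    list(F = Fv, p = pf(Fv, df1, df2, lower.tail = FALSE), df1 = df1,
         df2 = df2, skipped = FALSE)
}

## Fast nested-marker scan against the family-means model (optionally with
## current nested terms already swept out).  yres: within-family-residual
## response (vector or matrix of permutations); Mres: residualized marker
## codes; p0: columns already in the model.  Returns m x k matrix of P.
.scanNestedP <- function(Mres, famIdx, yres, p0, n) {
    pr <- .famProjections(Mres, famIdx, yres)
    if (is.null(dim(yres))) yres <- matrix(yres, ncol = 1)
    rss0 <- colSums(yres^2)
    P <- matrix(NA_real_, nrow(pr$delta), ncol(yres))
    for (k in seq_len(ncol(yres))) {
        delta <- pr$delta[, k]
        q <- pr$q
        rss1 <- pmax(rss0[k] - delta, 1e-300)
        df2 <- n - p0 - q
        Fv <- (delta / pmax(q, 1)) / (rss1 / pmax(df2, 1))
        p <- pf(Fv, pmax(q, 1), pmax(df2, 1), lower.tail = FALSE)
        p[q == 0 | df2 <= 0] <- NA_real_
        P[, k] <- p
    }
    P
}

#' Permutation-calibrated entry threshold for the nested-marker scan
#'
#' The response is shuffled within families (preserving the forced family
#' structure); for each permutation the minimum nested-marker P over all
#' markers is recorded, and the empirical alpha-quantile of these minima
#' becomes the entry threshold.
#'
#' @param y response per line.
#' @param families family id per line.
#' @param markers lines x markers matrix of 0/2/NA codes.
#' @param alpha genome-wide type-I error rate (default 0.05).
#' @param n_perm permutations (default 1000).
#' @param seed RNG seed.
#' @return List of class \code{SelectionThreshold}: p_enter, alpha,
#'   n_perm, minP (the recorded minima).
#' @export
permutationThreshold <- function(y, families, markers, alpha = 0.05,
                                 n_perm = 1000, seed = 1) {
    if (n_perm < 100) .stopf("n_perm must be at least 100")
    prep <- .jlPrep(families, markers)
    famIdx <- prep$famIdx
    yc <- .centerWithin(y, famIdx)
    n <- length(y)
    Y <- .withSeed(.childSeed(seed, "permutations"), {
        vapply(seq_len(n_perm), function(k) {
            out <- yc
            for (f in unique(famIdx)) {
                rows <- which(famIdx == f)
                out[rows] <- yc[rows][sample.int(length(rows))]
            }
            out
        }, numeric(n))
    })
    P <- .scanNestedP(prep$M, famIdx, Y, p0 = length(prep$famLevels), n = n)
    minP <- apply(P, 2, min, na.rm = TRUE)
    structure(list(p_enter = unname(quantile(minP, alpha, type = 1)),
                   alpha = alpha, n_perm = n_perm, minP = minP),
              class = "SelectionThreshold")
}

.centerWithin <- function(y, famIdx) {
    mu <- tapply(y, famIdx, mean)
    as.numeric(y - mu[as.character(famIdx)])
}

## Build the design matrix for a set of selected markers.
## Returns matrix of nested columns with names "<marker>:<family>".
.nestedDesign <- function(prep, selected) {
    cols <- list()
    for (j in selected) {
        for (f in which(prep$seg[j, ])) {
            nm <- paste0(rownames(prep$seg)[j], ":", prep$famLevels[f])
            cols[[nm]] <- prep$M[, j] * (prep$famIdx == f)
        }
    }
    if (!length(cols)) return(NULL)
    do.call(cbind, cols)
}

#' Stepwise selection of family-nested marker effects
#'
#' Forward selection enters the smallest-P marker while its P is below
#' \code{p_enter}; after each entry a backward pass drops any selected
#' marker whose removal P exceeds \code{p_exit}; iterated to a fixed
#' point.  Family main effects are always retained.  Markers whose
#' residualized codes are collinear with the current model are skipped
#' (logged in the result).
#'
#' @param y response per line (named by line).
#' @param families family id per line.
#' @param markers lines x markers 0/2/NA codes (colnames = marker ids).
#' @param threshold a \code{SelectionThreshold} or a numeric p_enter.
#' @param p_exit removal threshold (default = p_enter).
#' @param max_steps safety cap on forward steps.
#' @return List: selected (marker ids), prep internals, qr of the final
#'   design, rss, n, p0; input to [lodProfile()] / [alleleEffects()].
#' @export
stepwiseSelect <- function(y, families, markers, threshold,
                           p_exit = NULL, max_steps = 50) {
    p_enter <- if (is.list(threshold)) threshold$p_enter else threshold
    if (is.null(p_exit)) p_exit <- p_enter
    prep <- .jlPrep(families, markers)
    famIdx <- prep$famIdx
    n <- length(y)
    nfam <- length(prep$famLevels)
    yc <- .centerWithin(y, famIdx)
    selected <- integer(0)
    skipped <- character(0)
    repeat {
        ## residualize candidates and response against current model
        Xsel <- .nestedDesign(prep, selected)
        if (is.null(Xsel)) {
            Mres <- prep$M; yres <- yc; p0 <- nfam
        } else {
            qx <- qr(Xsel)
            Mres <- qr.resid(qx, prep$M)
            yres <- qr.resid(qx, yc)
            p0 <- nfam + qx$rank
        }
        P <- .scanNestedP(Mres, famIdx, yres, p0 = p0, n = n)[, 1]
        P[selected] <- NA
        if (all(is.na(P))) break
        j <- which.min(P)
        if (is.na(P[j]) || P[j] >= p_enter) break
        selected <- c(selected, j)
        ## backward pass
        repeat {
            if (length(selected) < 2) break
            dropP <- vapply(seq_along(selected), function(i)
                .dropPValue(prep, yc, selected, selected[i], nfam, n), 0)
            worst <- which.max(dropP)
            if (dropP[worst] > p_exit) selected <- selected[-worst]
            else break
        }
        if (length(selected) >= max_steps) break
    }
    Xsel <- .nestedDesign(prep, selected)
    famMM <- stats::model.matrix(~0 + factor(famIdx))
    colnames(famMM) <- paste0("fam:", prep$famLevels)
    X <- if (is.null(Xsel)) famMM else cbind(famMM, Xsel)
    qx <- qr(X)
    rss <- sum(qr.resid(qx, y)^2)
    list(selected = colnames(markers)[selected], selectedIdx = selected,
         prep = prep, X = X, qr = qx, rss = rss, n = n, p0 = qx$rank,
         y = y, yc = yc, famIdx = famIdx, p_enter = p_enter,
         p_exit = p_exit, skipped = skipped)
}

## P-value for removing one selected marker's nested terms
.dropPValue <- function(prep, yc, selected, dropJ, nfam, n) {
    Xfull <- .nestedDesign(prep, selected)
    Xred <- .nestedDesign(prep, setdiff(selected, dropJ))
    qf <- qr(Xfull)
    rssF <- sum(qr.resid(qf, yc)^2)
    rkF <- qf$rank
    if (is.null(Xred)) { rssR <- sum(yc^2); rkR <- 0 }
    else { qr_ <- qr(Xred); rssR <- sum(qr.resid(qr_, yc)^2); rkR <- qr_$rank }
    df1 <- rkF - rkR
    df2 <- n - nfam - rkF
    if (df1 <= 0 || df2 <= 0) return(0)
    Fv <- ((rssR - rssF) / df1) / (rssF / df2)
    pf(Fv, df1, df2, lower.tail = FALSE)
}

#' LOD profile of one selected QTL over its flanking markers
#'
#' Candidate positions are the QTL's own marker and up to \code{flank}
#' adjacent markers on each side (map order, same chromosome).  For each
#' candidate, the QTL's nested term is swapped for the candidate's while
#' all other selected QTL stay in the model as covariates;
#' \code{LOD = (n/2) log10(RSS_without / RSS_with)}, where RSS_without is
#' the model with the QTL's term removed entirely.
#'
#' @param fit result of [stepwiseSelect()].
#' @param qtlMarker marker id of the selected QTL to profile.
#' @param markers the full marker matrix used in the scan.
#' @param map data.frame (marker, chrom, pos, cM) covering the markers.
#' @param flank markers per side (default 4).
#' @return data.frame (marker, chrom, pos, cM, LOD).
#' @export
lodProfile <- function(fit, qtlMarker, markers, map, flank = 4) {
    prep <- fit$prep
    allIds <- colnames(markers)
    jq <- match(qtlMarker, allIds)
    others <- setdiff(fit$selectedIdx, jq)
    mrow <- map[match(qtlMarker, map$marker), ]
    onChr <- map[map$chrom == mrow$chrom, ]
    onChr <- onChr[order(onChr$cM, onChr$pos), ]
    at <- match(qtlMarker, onChr$marker)
    cand <- onChr$marker[max(1, at - flank):min(nrow(onChr), at + flank)]
    candIdx <- match(cand, allIds)
    Xother <- .nestedDesign(prep, others)
    famMM <- stats::model.matrix(~0 + factor(prep$famIdx))
    Xbase <- if (is.null(Xother)) famMM else cbind(famMM, Xother)
    qb <- qr(Xbase)
    rssWithout <- sum(qr.resid(qb, fit$y)^2)
    n <- fit$n
    lod <- vapply(candIdx, function(j) {
        Zc <- .nestedDesign(prep, j)
        if (is.null(Zc)) return(0)
        qw <- qr(cbind(Xbase, Zc))
        rssWith <- sum(qr.resid(qw, fit$y)^2)
        (n / 2) * log10(rssWithout / max(rssWith, 1e-300))
    }, 0)
    out <- data.frame(marker = cand,
                      chrom = mrow$chrom,
                      pos = onChr$pos[match(cand, onChr$marker)],
                      cM = onChr$cM[match(cand, onChr$marker)],
                      LOD = lod)
    rownames(out) <- NULL
    out
}

#' 2-LOD support interval from a LOD profile
#'
#' Starting at the profile peak, the interval extends in both directions
#' over markers whose LOD stays above peak - drop and includes the first
#' marker at or below the drop as its edge; if the drop is not reached
#' within the profiled window the interval is truncated at the window and
#' flagged.
#'
#' @param profile data.frame from [lodProfile()].
#' @param drop LOD drop defining the support interval (default 2).
#' @return List: peakMarker, lo/hi (row indices), interval bp and cM
#'   bounds, truncated flag.
#' @export
ci2Lod <- function(profile, drop = 2) {
    lod <- profile$LOD
    peak <- which.max(lod)
    cutoff <- lod[peak] - drop
    lo <- peak
    truncated <- FALSE
    while (lo > 1) {
        lo <- lo - 1
        if (lod[lo] <= cutoff) break
    }
    if (lod[lo] > cutoff) truncated <- TRUE
    hi <- peak
    while (hi < length(lod)) {
        hi <- hi + 1
        if (lod[hi] <= cutoff) break
    }
    if (lod[hi] > cutoff) truncated <- TRUE
    list(peakMarker = profile$marker[peak], lo = lo, hi = hi,
         bp = c(profile$pos[lo], profile$pos[hi]),
         cM = c(profile$cM[lo], profile$cM[hi]),
         truncated = truncated)
}

#' Per-family allele effects of the final QTL model
#'
#' Effects are the family-nested slopes on the 0/2 origin coding, i.e.
#' trait units per allele substitution relative to the common-parent
#' allele; significance is an (uncorrected) t-test of each slope against
#' the reference allele effect of zero.
#'
#' @param fit result of [stepwiseSelect()].
#' @return data.frame (marker, family, effect, se, t, p); families in
#'   which a marker is monomorphic are absent.
#' @export
alleleEffects <- function(fit) {
    X <- fit$X
    qx <- fit$qr
    n <- fit$n
    dfres <- n - qx$rank
    coefs <- qr.coef(qx, fit$y)
    sigma2 <- fit$rss / dfres
    R <- qr.R(qx)
    piv <- qx$pivot[seq_len(qx$rank)]
    XtXinv <- chol2inv(R[seq_len(qx$rank), seq_len(qx$rank), drop = FALSE])
    se <- rep(NA_real_, ncol(X))
    se[piv] <- sqrt(pmax(diag(XtXinv) * sigma2, 0))
    names(se) <- colnames(X)
    nested <- grep(":", names(coefs), value = TRUE)
    nested <- setdiff(nested, grep("^fam:", names(coefs), value = TRUE))
    if (!length(nested))
        return(data.frame(marker = character(0), family = character(0),
                          effect = numeric(0), se = numeric(0),
                          t = numeric(0), p = numeric(0)))
    parts <- strsplit(nested, ":", fixed = TRUE)
    eff <- coefs[nested]
    s <- se[nested]
    tv <- eff / s
    out <- data.frame(marker = vapply(parts, `[`, "", 1),
                      family = vapply(parts, `[`, "", 2),
                      effect = unname(eff), se = unname(s),
                      t = unname(tv),
                      p = unname(2 * pt(abs(tv), dfres, lower.tail = FALSE)))
    rownames(out) <- NULL
    out
}

#' Full joint-linkage QTL scan
#'
#' Convenience wrapper: permutation threshold, stepwise selection, LOD
#' profiles, 2-LOD intervals and allele effects, assembled into a
#' \linkS4class{QTLModel}.
#'
#' @param y response per line (named numeric, e.g. BLUPs).
#' @param families family per line.
#' @param markers lines x markers matrix of 0/2/NA codes.
#' @param map data.frame (marker, chrom, pos, cM).
#' @param alpha genome-wide type-I error (default 0.05).
#' @param n_perm permutations for the threshold (default 1000).
#' @param seed RNG seed for the permutations.
#' @param flank profile width per side (default 4).
#' @param threshold optional precomputed \code{SelectionThreshold} (skips
#'   the permutations).
#' @return A \linkS4class{QTLModel}.
#' @export
jointLinkageScan <- function(y, families, markers, map, alpha = 0.05,
                             n_perm = 1000, seed = 1, flank = 4,
                             threshold = NULL) {
    stopifnot(length(y) == nrow(markers), length(families) == length(y))
    if (is.null(threshold))
        threshold <- permutationThreshold(y, families, markers, alpha,
                                          n_perm, seed)
    fit <- stepwiseSelect(y, families, markers, threshold)
    profiles <- list(); qtlRows <- list()
    for (mk in fit$selected) {
        pr <- lodProfile(fit, mk, markers, map, flank)
        ci <- ci2Lod(pr)
        profiles[[mk]] <- pr
        at <- match(mk, pr$marker)
        qtlRows[[mk]] <- data.frame(
            marker = mk, chrom = pr$chrom[1], pos = pr$pos[at],
            cM = pr$cM[at], lod = pr$LOD[at],
            ci_lo_bp = ci$bp[1], ci_hi_bp = ci$bp[2],
            ci_lo_cM = ci$cM[1], ci_hi_cM = ci$cM[2],
            truncated = ci$truncated)
    }
    eff <- alleleEffects(fit)
    qtl <- if (length(qtlRows)) do.call(rbind, qtlRows) else
        data.frame(marker = character(0), chrom = character(0),
                   pos = numeric(0), cM = numeric(0), lod = numeric(0),
                   ci_lo_bp = numeric(0), ci_hi_bp = numeric(0),
                   ci_lo_cM = numeric(0), ci_hi_cM = numeric(0),
                   truncated = logical(0))
    rownames(qtl) <- NULL
    new("QTLModel", qtl = qtl, effects = eff, profiles = profiles,
        fit = list(threshold = threshold, selected = fit$selected,
                   rss = fit$rss, n = fit$n, p0 = fit$p0))
}
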