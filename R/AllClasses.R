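#' @importFrom GenomicRanges GRanges seqnames start end width mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors Rle runValue
NULL

.CALL_ALPHABET <- c("A", "B", "H")

#' GenotypeMatrix: RIL x SNP genotype calls with physical coordinates
#'
#' Container for the unimputed genotype calls of one or more RIL families.
#' Calls are stored on a four-state alphabet: \code{"A"} (homozygous for
#' allele A), \code{"B"} (homozygous for allele B), \code{"H"}
#' (heterozygous) and \code{NA} (missing).  SNP sites carry physical
#' coordinates (1-based bp) and the two allele symbols; every line belongs
#' to exactly one family.
#'
#' @slot calls character matrix, lines x sites.
#' @slot sites \link[GenomicRanges]{GRanges} of width-1 positions, one per
#'   column of \code{calls}, with metadata columns \code{alleleA},
#'   \code{alleleB}; positions are strictly increasing within a chromosome.
#' @slot family named character vector, one family id per line.
#'
#' @seealso [genotypeMatrix()] for construction, [readGenotypes()] to read
#'   from disk.
#' @export
setClass("GenotypeMatrix",
    representation(calls = "matrix", sites = "GRanges", family = "character"))

setValidity("GenotypeMatrix", function(object) {
    msg <- NULL
    calls <- object@calls
    sites <- object@sites
    if (!is.character(calls))
        msg <- c(msg, "'calls' must be a character matrix")
    if (ncol(calls) != length(sites))
        msg <- c(msg, "ncol(calls) must equal length(sites)")
    if (is.null(rownames(calls)) && nrow(calls) > 0)
        msg <- c(msg, "'calls' must have line ids as rownames")
    bad <- setdiff(unique(as.vector(calls)), c(.CALL_ALPHABET, NA))
    if (length(bad))
        msg <- c(msg, paste0("invalid call symbols: ",
                             paste(bad, collapse = ", ")))
    if (length(object@family) != nrow(calls))
        msg <- c(msg, "'family' must have one entry per line")
    if (nrow(calls) > 0 && !identical(names(object@family), rownames(calls)))
        msg <- c(msg, "names(family) must match rownames(calls)")
    if (length(sites)) {
        if (any(width(sites) != 1L))
            msg <- c(msg, "sites must be width-1 positions")
        if (!all(c("alleleA", "alleleB") %in% colnames(mcols(sites))))
            msg <- c(msg, "sites must carry alleleA/alleleB metadata")
        byChr <- split(start(sites), as.character(seqnames(sites)))
        if (any(vapply(byChr, function(p) any(diff(p) <= 0), logical(1))))
            msg <- c(msg,
                "site positions must be strictly increasing within chromosome")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a GenotypeMatrix
#'
#' @param calls character matrix (lines x sites) over \{"A","B","H",NA\};
#'   rownames are line ids.
#' @param sites either a \code{GRanges} (width 1, mcols alleleA/alleleB) or a
#'   data.frame with columns \code{chrom}, \code{pos}, \code{alleleA},
#'   \code{alleleB}.
#' @param family character vector of family ids, one per line (recycled if
#'   length 1).
#' @return A validated \linkS4class{GenotypeMatrix}.
#' @examples
#' calls <- matrix(c("A", "B", "A", NA, "H", "B"), nrow = 2, byrow = TRUE,
#'                 dimnames = list(c("ril1", "ril2"), NULL))
#' sites <- data.frame(chrom = "chr1", pos = c(100, 200, 300),
#'                     alleleA = "A", alleleB = "C")
#' gm <- genotypeMatrix(calls, sites, family = "fam1")
#' @export
genotypeMatrix <- function(calls, sites, family) {
    if (is.data.frame(sites)) {
        sites <- GRanges(sites$chrom, IRanges(sites$pos, width = 1L),
                         alleleA = as.character(sites$alleleA),
                         alleleB = as.character(sites$alleleB))
    }
    if (is.null(names(sites)) && !is.null(colnames(calls)))
        names(sites) <- colnames(calls)
    if (length(family) == 1L) family <- rep(family, nrow(calls))
    new("GenotypeMatrix", calls = calls, sites = sites,
        family = setNames(as.character(family), rownames(calls)))
}

#' @rdname lineNames
#' @export
setMethod("lineNames", "GenotypeMatrix", function(x) rownames(x@calls))

#' @rdname familyOf
#' @export
setMethod("familyOf", "GenotypeMatrix",
          function(x) setNames(x@family, rownames(x@calls)))

#' @rdname genoCalls
#' @export
setMethod("genoCalls", "GenotypeMatrix", function(x) x@calls)

#' @rdname siteRanges
#' @export
setMethod("siteRanges", "GenotypeMatrix", function(x) x@sites)

setMethod("show", "GenotypeMatrix", function(object) {
    cat("GenotypeMatrix:", nrow(object@calls), "lines x",
        ncol(object@calls), "sites\n")
    cat("  families:", paste(unique(object@family), collapse = ", "), "\n")
    cat("  chromosomes:",
        paste(unique(as.character(seqnames(object@sites))), collapse = ", "),
        "\n")
    miss <- mean(is.na(object@calls))
    cat(sprintf("  missing: %.1f%%  het: %.1f%%\n", 100 * miss,
                100 * mean(object@calls == "H", na.rm = TRUE) * (1 - miss)))
})

#' Subset a GenotypeMatrix by lines and/or sites
#'
#' @param x a GenotypeMatrix.
#' @param i line index (logical, integer or character).
#' @param j site index.
#' @param ... ignored.
#' @param drop ignored; subsetting always returns a GenotypeMatrix.
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
    if (missing(i)) i <- seq_len(nrow(x@calls))
    if (missing(j)) j <- seq_len(ncol(x@calls))
    new("GenotypeMatrix", calls = x@calls[i, j, drop = FALSE],
        sites = x@sites[j], family = x@family[i])
})

#' BinMap: recombination bins with per-RIL parental-origin genotypes
#'
#' A partition of each chromosome into recombination bins, plus a lines x
#' bins genotype matrix coded 0 (common-parent origin), 2 (diverse-parent
#' origin) or \code{NA}.  Bin intervals are 1-based inclusive and
#' non-overlapping, sorted within chromosome.
#'
#' @slot bins \link[GenomicRanges]{GRanges} of bin intervals, named by bin id.
#' @slot genotypes integer matrix lines x bins in \{0, 2, NA\}.
#' @slot family named character vector of family ids per line.
#' @export
setClass("BinMap",
    representation(bins = "GRanges", genotypes = "matrix",
                   family = "character"))

setValidity("BinMap", function(object) {
    msg <- NULL
    if (ncol(object@genotypes) != length(object@bins))
        msg <- c(msg, "ncol(genotypes) must equal number of bins")
    vals <- unique(as.vector(object@genotypes))
    if (length(setdiff(vals, c(0L, 2L, NA))))
        msg <- c(msg, "bin genotypes must be 0, 2 or NA")
    if (length(object@bins) > 1) {
        byChr <- split(object@bins, as.character(seqnames(object@bins)))
        for (gr in byChr) {
            if (length(gr) < 2) next
            s <- start(gr); e <- end(gr)
            if (any(diff(s) <= 0))
                msg <- c(msg, "bins must be sorted within chromosome")
            if (any(s[-1] <= e[-length(e)]))
                msg <- c(msg, "bins must not overlap")
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a BinMap
#'
#' @param bins GRanges of bin intervals (1-based inclusive) or data.frame
#'   with columns chrom, start, end.
#' @param genotypes integer matrix lines x bins over \{0, 2, NA\}.
#' @param family family id per line (recycled if length 1).
#' @return A validated \linkS4class{BinMap}.
#' @export
binMap <- function(bins, genotypes, family) {
    if (is.data.frame(bins))
        bins <- GRanges(bins$chrom, IRanges(bins$start, bins$end))
    if (is.null(names(bins)) && length(bins))
        names(bins) <- sprintf("bin%04d", seq_along(bins))
    storage.mode(genotypes) <- "integer"
    if (length(family) == 1L) family <- rep(family, nrow(genotypes))
    names(family) <- rownames(genotypes)
    new("BinMap", bins = bins, genotypes = genotypes, family = family)
}

#' @rdname binRanges
#' @export
setMethod("binRanges", "BinMap", function(x) x@bins)

#' @rdname binGenotypes
#' @export
setMethod("binGenotypes", "BinMap", function(x) x@genotypes)

#' @rdname lineNames
#' @export
setMethod("lineNames", "BinMap", function(x) rownames(x@genotypes))

#' @rdname familyOf
#' @export
setMethod("familyOf", "BinMap", function(x) x@family)

setMethod("show", "BinMap", function(object) {
    cat("BinMap:", nrow(object@genotypes), "lines x",
        length(object@bins), "bins\n")
    if (length(object@bins)) {
        w <- width(object@bins)
        cat(sprintf("  bin width: median %.0f kb (range %.1f kb - %.1f Mb)\n",
                    median(w) / 1e3, min(w) / 1e3, max(w) / 1e6))
    }
    cat(sprintf("  missing genotypes: %.2f%%\n",
                100 * mean(is.na(object@genotypes))))
})

#' TruthSet: simulator ground truth for one NAM panel
#'
#' @slot segments \link[GenomicRanges]{GRanges} of true parental-origin
#'   segments with metadata columns \code{ril}, \code{family} and
#'   \code{parent} ("common"/"diverse"); the segments of one RIL tile each
#'   chromosome exactly.
#' @slot breakpoints data.frame (ril, family, chrom, pos) of true breakpoint
#'   positions, i.e. the internal segment boundaries.
#' @slot founders list, per family: logical vector over sites, TRUE where
#'   the diverse parent differs from the common parent (the site is
#'   polymorphic in that family).
#' @slot qtl data.frame of true QTL: chrom, pos, then one effect column per
#'   family (additive effect in trait units).
#' @export
setClass("TruthSet",
    representation(segments = "GRanges", breakpoints = "data.frame",
                   founders = "list", qtl = "data.frame"))

setValidity("TruthSet", function(object) {
    msg <- NULL
    need <- c("ril", "family", "parent")
    if (length(object@segments) &&
        !all(need %in% colnames(mcols(object@segments))))
        msg <- c(msg, "segments need ril/family/parent metadata")
    if (nrow(object@breakpoints) &&
        !all(c("ril", "chrom", "pos") %in% colnames(object@breakpoints)))
        msg <- c(msg, "breakpoints need ril/chrom/pos columns")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "TruthSet", function(object) {
    cat("TruthSet:", length(unique(object@segments$ril)), "RILs,",
        nrow(object@breakpoints), "true breakpoints,",
        nrow(object@qtl), "QTL\n")
})

#' True breakpoints of a TruthSet
#' @param x a TruthSet.
#' @return data.frame (ril, family, chrom, pos).
#' @export
trueBreakpoints <- function(x) x@breakpoints

#' True parental-origin segments of a TruthSet
#' @param x a TruthSet.
#' @return GRanges with ril/family/parent metadata.
#' @export
trueSegments <- function(x) x@segments

#' True QTL table of a TruthSet
#' @param x a TruthSet.
#' @return data.frame (chrom, pos, one effect column per family).
#' @export
trueQTL <- function(x) x@qtl

#' GeneticMap: ordered markers with genetic positions
#'
#' @slot markers data.frame with columns \code{marker}, \code{chrom},
#'   \code{pos} (bp), \code{cM}, \code{distorted} (logical),
#'   \code{framework} (logical).  cM is non-decreasing within chromosome
#'   and framework markers are never distorted.
#' @export
setClass("GeneticMap", representation(markers = "data.frame"))

setValidity("GeneticMap", function(object) {
    m <- object@markers
    msg <- NULL
    need <- c("marker", "chrom", "pos", "cM", "distorted", "framework")
    if (!all(need %in% colnames(m)))
        msg <- c(msg, paste("markers must have columns:",
                            paste(need, collapse = ", ")))
    else {
        if (any(vapply(split(m$cM, m$chrom),
                       function(x) any(diff(x) < -1e-9), logical(1))))
            msg <- c(msg, "cM must be non-decreasing within chromosome")
        if (any(m$framework & m$distorted))
            msg <- c(msg, "framework markers must not be distorted")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a GeneticMap
#' @param markers data.frame with columns marker, chrom, pos, cM and
#'   optionally distorted, framework (default FALSE / !distorted).
#' @return A \linkS4class{GeneticMap}.
#' @export
geneticMap <- function(markers) {
    if (is.null(markers$distorted)) markers$distorted <- FALSE
    if (is.null(markers$framework)) markers$framework <- !markers$distorted
    new("GeneticMap", markers = markers)
}

#' @rdname markerTable
#' @export
setMethod("markerTable", "GeneticMap", function(x) x@markers)

setMethod("show", "GeneticMap", function(object) {
    m <- object@markers
    len <- sum(vapply(split(m$cM, m$chrom), function(x) max(x) - min(x),
                      numeric(1)))
    cat("GeneticMap:", nrow(m), "markers on",
        length(unique(m$chrom)), "chromosome(s),",
        sprintf("%.2f cM total", len), "\n")
    cat(sprintf("  distorted: %d  framework: %d\n",
                sum(m$distorted), sum(m$framework)))
})

#' Total genetic length of a map (cM)
#' @param x a GeneticMap.
#' @return Numeric, summed over chromosomes.
#' @export
mapLength <- function(x) {
    m <- markerTable(x)
    sum(vapply(split(m$cM, m$chrom), function(v) max(v) - min(v), numeric(1)))
}

#' QTLModel: result of a joint-linkage stepwise QTL scan
#'
#' @slot qtl data.frame, one row per selected QTL: marker, chrom, pos,
#'   peak LOD, 2-LOD interval bounds in bp and cM, truncation flag.
#' @slot effects data.frame of per-family allele effects: marker, family,
#'   effect (trait units per allele substitution), se, t, p.
#' @slot profiles named list of per-QTL LOD profiles (data.frame marker,
#'   pos, cM, LOD).
#' @slot fit list with fit internals (terms, residual df, RSS, threshold).
#' @export
setClass("QTLModel",
    representation(qtl = "data.frame", effects = "data.frame",
                   profiles = "list", fit = "list"))

setValidity("QTLModel", function(object) {
    msg <- NULL
    if (nrow(object@qtl) && !all(object@qtl$marker %in% names(object@profiles)))
        msg <- c(msg, "every selected QTL must have a LOD profile")
    if (is.null(msg)) TRUE else msg
})

#' @rdname qtlTable
#' @export
setMethod("qtlTable", "QTLModel", function(x) x@qtl)

#' Per-family allele effects of a fitted QTL model
#' @param x a QTLModel.
#' @return data.frame (marker, family, effect, se, t, p).
#' @export
alleleEffectTable <- function(x) x@effects

#' LOD profiles of a fitted QTL model
#' @param x a QTLModel.
#' @return Named list of data.frames (marker, pos, cM, LOD).
#' @export
lodProfiles <- function(x) x@profiles

setMethod("show", "QTLModel", function(object) {
    cat("QTLModel:", nrow(object@qtl), "QTL selected\n")
    if (nrow(object@qtl)) {
        print(object@qtl[, c("marker", "chrom", "pos", "lod")])
    }
})
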