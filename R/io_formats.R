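## Readers/writers for every external table the pipeline touches.
##
## Dialects:
##  * Genotypes, HapMap-like: tab-delimited; columns rs#, alleles ("A/C"),
##    chrom, pos, then one column per line.  Homozygotes are written as the
##    allele base; heterozygotes as the IUPAC ambiguity code of the allele
##    pair (or "X/Y" when no code exists); missing as "N".  The reader also
##    accepts "NA", "./." and "XY" two-letter diplotypes.
##  * Genotypes, minimal VCF v4.2: GT field only, unphased or phased.
##  * Bin maps: one tab-delimited table; coordinates on disk are BED-style
##    0-based half-open, internal coordinates 1-based inclusive.
##  * Phenotypes and genetic maps: plain CSV.
## Families travel in a separate two-column table (line, family) because
## neither HapMap nor VCF has a slot for them.

.IUPAC_HET <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

.hetCode <- function(a, b) {
    pair <- paste0(sort(c(a, b)), collapse = "")
    code <- names(.IUPAC_HET)[match(pair, .IUPAC_HET)]
    if (is.na(code)) paste0(a, "/", b) else code
}

.normalizeCall <- function(raw, a, b, siteLabel) {
    out <- rep(NA_character_, length(raw))
    raw <- toupper(raw)
    miss <- is.na(raw) | raw %in% c("N", "NA", "./.", ".", "NN", "")
    hetStrings <- c(.hetCode(a, b), paste0(a, "/", b), paste0(b, "/", a),
                    paste0(a, b), paste0(b, a),
                    paste0(a, "|", b), paste0(b, "|", a))
    out[raw == a | raw == paste0(a, a) | raw %in% paste0(a, c("/", "|"), a)] <- "A"
    out[raw == b | raw == paste0(b, b) | raw %in% paste0(b, c("/", "|"), b)] <- "B"
    out[raw %in% hetStrings] <- "H"
    unknown <- !miss & is.na(out)
    if (any(unknown))
        .stopf("unknown allele symbol '%s' at site %s (alleles %s/%s)",
               raw[which(unknown)[1]], siteLabel, a, b)
    out
}

#' Read a genotype matrix from disk
#'
#' @param path path to the genotype file.
#' @param format \code{"hapmap"} (tab-delimited, rs#/alleles/chrom/pos then
#'   one column per line) or \code{"vcf"} (minimal VCF v4.2, GT only; needs
#'   the vcfR package).
#' @param families data.frame with columns \code{line}, \code{family}, a
#'   named character vector, or a path to a two-column CSV.  Lines absent
#'   from the table are assigned family \code{"fam1"}.
#' @return A \linkS4class{GenotypeMatrix}.  Heterozygote encodings (IUPAC
#'   codes, \code{"A/C"}, \code{"AC"}) are normalized to \code{"H"};
#'   \code{"N"}, \code{"NA"} and \code{"./."} to \code{NA}.
#' @seealso [writeGenotypes()]
#' @export
readGenotypes <- function(path, format = c("hapmap", "vcf"), families = NULL) {
    format <- match.arg(format)
    fam <- .readFamilies(families)
    gm <- if (format == "hapmap") .readHapmap(path) else .readVcfMinimal(path)
    lines <- rownames(gm@calls)
    f <- if (is.null(fam)) rep("fam1", length(lines)) else {
        out <- unname(fam[lines])
        out[is.na(out)] <- "fam1"
        out
    }
    genotypeMatrix(gm@calls, gm@sites, f)
}

.readFamilies <- function(families) {
    if (is.null(families)) return(NULL)
    if (is.character(families) && length(families) == 1 && file.exists(families))
        families <- read.csv(families, stringsAsFactors = FALSE)
    if (is.data.frame(families))
        return(setNames(as.character(families$family),
                        as.character(families$line)))
    families
}

.checkDupPositions <- function(chrom, pos) {
    key <- paste(chrom, pos)
    if (anyDuplicated(key))
        .stopf("duplicate position: %s", key[duplicated(key)][1])
}

.readHapmap <- function(path) {
    if (!file.exists(path)) .stopf("file not found: %s", path)
    tab <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE,
                      comment.char = "")
    meta <- c("rs#", "alleles", "chrom", "pos")
    if (!all(meta %in% colnames(tab)[1:4]))
        .stopf("HapMap-like header must start with: %s",
               paste(meta, collapse = ", "))
    .checkDupPositions(tab$chrom, tab$pos)
    al <- strsplit(tab$alleles, "/", fixed = TRUE)
    a <- toupper(vapply(al, `[`, "", 1))
    b <- toupper(vapply(al, `[`, "", 2))
    lineCols <- setdiff(colnames(tab), meta)
    calls <- matrix(NA_character_, nrow = length(lineCols), ncol = nrow(tab),
                    dimnames = list(lineCols, tab[["rs#"]]))
    for (j in seq_len(nrow(tab)))
        calls[, j] <- .normalizeCall(as.character(unlist(tab[j, lineCols])),
                                     a[j], b[j],
                                     paste0(tab$chrom[j], ":", tab$pos[j]))
    ord <- order(tab$chrom, tab$pos)
    sites <- GRanges(tab$chrom[ord], IRanges(tab$pos[ord], width = 1L),
                     alleleA = a[ord], alleleB = b[ord])
    names(sites) <- tab[["rs#"]][ord]
    genotypeMatrix(calls[, ord, drop = FALSE], sites, "fam1")
}

.readVcfMinimal <- function(path) {
    if (!requireNamespace("vcfR", quietly = TRUE))
        .stopf("reading VCF requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fx <- v@fix
    .checkDupPositions(fx[, "CHROM"], fx[, "POS"])
    gt <- vcfR::extract.gt(v, element = "GT")
    a <- toupper(fx[, "REF"]); b <- toupper(fx[, "ALT"])
    calls <- matrix(NA_character_, nrow = ncol(gt), ncol = nrow(gt),
                    dimnames = list(colnames(gt), rownames(gt)))
    for (j in seq_len(nrow(gt))) {
        g <- gsub("|", "/", gt[j, ], fixed = TRUE)
        cj <- rep(NA_character_, length(g))
        cj[g %in% "0/0"] <- "A"
        cj[g %in% "1/1"] <- "B"
        cj[g %in% c("0/1", "1/0")] <- "H"
        unknown <- !is.na(g) & !(g %in% c("0/0", "1/1", "0/1", "1/0", "./."))
        if (any(unknown))
            .stopf("unknown GT '%s' at site %s:%s", g[which(unknown)[1]],
                   fx[j, "CHROM"], fx[j, "POS"])
        calls[, j] <- cj
    }
    pos <- as.integer(fx[, "POS"])
    ord <- order(fx[, "CHROM"], pos)
    sites <- GRanges(fx[ord, "CHROM"], IRanges(pos[ord], width = 1L),
                     alleleA = a[ord], alleleB = b[ord])
    names(sites) <- if (all(is.na(fx[, "ID"]))) {
        paste0("s", seq_along(sites))
    } else fx[ord, "ID"]
    genotypeMatrix(calls[, ord, drop = FALSE], sites, "fam1")
}

#' Write a genotype matrix to disk
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param path output file.
#' @param format \code{"hapmap"} or \code{"vcf"} (minimal, GT-only,
#'   uncompressed).
#' @return \code{path}, invisibly.
#' @export
writeGenotypes <- function(x, path, format = c("hapmap", "vcf")) {
    format <- match.arg(format)
    sites <- siteRanges(x)
    a <- mcols(sites)$alleleA; b <- mcols(sites)$alleleB
    calls <- genoCalls(x)
    if (format == "hapmap") {
        enc <- matrix("N", nrow = nrow(calls), ncol = ncol(calls))
        for (j in seq_len(ncol(calls))) {
            cj <- calls[, j]
            ej <- rep("N", length(cj))
            ej[cj %in% "A"] <- a[j]
            ej[cj %in% "B"] <- b[j]
            ej[cj %in% "H"] <- .hetCode(a[j], b[j])
            enc[, j] <- ej
        }
        ids <- names(sites)
        if (is.null(ids)) ids <- paste0("s", seq_along(sites))
        tab <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
            `rs#` = ids, alleles = paste0(a, "/", b),
            chrom = as.character(seqnames(sites)), pos = start(sites))
        tab <- cbind(tab, as.data.frame(t(enc), stringsAsFactors = FALSE,
                                        optional = TRUE))
        colnames(tab)[-(1:4)] <- rownames(calls)
        write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
        con <- file(path, "w")
        on.exit(close(con))
        writeLines(c("##fileformat=VCFv4.2",
                     '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                     paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                             "FILTER", "INFO", "FORMAT", rownames(calls)),
                           collapse = "\t")), con)
        gtmap <- c(A = "0/0", B = "1/1", H = "0/1")
        for (j in seq_along(sites)) {
            g <- gtmap[calls[, j]]
            g[is.na(g)] <- "./."
            writeLines(paste(c(as.character(seqnames(sites))[j],
                               start(sites)[j], names(sites)[j], a[j], b[j],
                               ".", "PASS", ".", "GT", g),
                             collapse = "\t"), con)
        }
    }
    invisible(path)
}

#' Write a bin map (BED-style coordinates plus genotype matrix)
#'
#' One tab-delimited table: columns chrom, start, end (0-based half-open),
#' bin, then one genotype column per line.  A comment line carries family
#' assignments so that [readBinMap()] round-trips exactly.
#'
#' @param x a \linkS4class{BinMap}; bins must be sorted and non-overlapping
#'   (enforced by the class).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeBinMap <- function(x, path) {
    bins <- binRanges(x)
    g <- binGenotypes(x)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#family\t",
                      paste(rownames(g), familyOf(x), sep = "=",
                            collapse = "\t")), con)
    writeLines(paste(c("#chrom", "start", "end", "bin", rownames(g)),
                     collapse = "\t"), con)
    if (length(bins)) {
        bed <- .toBed(start(bins), end(bins))
        body <- cbind(as.character(seqnames(bins)), bed$start, bed$end,
                      names(bins), t(g))
        writeLines(apply(body, 1, paste, collapse = "\t"), con)
    }
    invisible(path)
}

#' Read a bin map written by [writeBinMap()]
#'
#' @param path file written by [writeBinMap()].
#' @return A \linkS4class{BinMap} (coordinates converted back to 1-based
#'   inclusive).
#' @export
readBinMap <- function(path) {
    lines <- readLines(path)
    famLine <- sub("^#family\t", "", lines[1])
    kv <- strsplit(strsplit(famLine, "\t")[[1]], "=", fixed = TRUE)
    fam <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
    header <- strsplit(sub("^#", "", lines[2]), "\t")[[1]]
    rils <- header[-(1:4)]
    body <- lines[-(1:2)]
    if (!length(body)) {
        return(binMap(GRanges(), matrix(integer(0), nrow = length(rils),
                                        ncol = 0,
                                        dimnames = list(rils, NULL)),
                      unname(fam[rils])))
    }
    parts <- do.call(rbind, strsplit(body, "\t"))
    conv <- .fromBed(as.integer(parts[, 2]), as.integer(parts[, 3]))
    bins <- GRanges(parts[, 1], IRanges(conv$start, conv$end))
    names(bins) <- parts[, 4]
    ## rows on disk are bins; internal layout is lines x bins
    g <- matrix(suppressWarnings(as.integer(parts[, -(1:4), drop = FALSE])),
                nrow = nrow(parts))
    g <- t(g)
    dimnames(g) <- list(rils, parts[, 4])
    binMap(bins, g, unname(fam[rils]))
}

#' Read / write multi-environment phenotype tables
#'
#' CSV with columns \code{line}, \code{env}, \code{rep}, \code{value}.
#' Duplicate (line, env, rep) keys and non-finite values are rejected.
#'
#' @param path CSV path.
#' @return data.frame with the four columns above.
#' @export
readPhenotypes <- function(path) {
    ph <- read.csv(path, stringsAsFactors = FALSE)
    validatePhenotypes(ph)
    ph
}

#' @rdname readPhenotypes
#' @param ph phenotype data.frame to write / validate.
#' @export
writePhenotypes <- function(ph, path) {
    validatePhenotypes(ph)
    write.csv(ph, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname readPhenotypes
#' @export
validatePhenotypes <- function(ph) {
    need <- c("line", "env", "rep", "value")
    if (!all(need %in% colnames(ph)))
        .stopf("phenotypes need columns: %s", paste(need, collapse = ", "))
    key <- paste(ph$line, ph$env, ph$rep)
    if (anyDuplicated(key))
        .stopf("duplicate phenotype record: %s", key[duplicated(key)][1])
    if (any(!is.finite(ph$value)))
        .stopf("non-finite phenotype values present")
    invisible(ph)
}

#' Write / read a genetic map as CSV
#'
#' Columns: marker, chrom, pos (bp), cM, distorted, framework.
#' @param x a \linkS4class{GeneticMap}.
#' @param path CSV path.
#' @return \code{path} (writer) or a \linkS4class{GeneticMap} (reader).
#' @export
writeGeneticMap <- function(x, path) {
    write.csv(markerTable(x), path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeGeneticMap
#' @export
readGeneticMap <- function(path) {
    geneticMap(read.csv(path, stringsAsFactors = FALSE))
}

#' Export simulator ground truth (JSON plus BED of true segments)
#'
#' @param truth a \linkS4class{TruthSet}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeTruthSet <- function(truth, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    seg <- trueSegments(truth)
    bedPath <- file.path(dir, "true_segments.bed")
    bed <- .toBed(start(seg), end(seg))
    write.table(data.frame(chrom = as.character(seqnames(seg)),
                           start = bed$start, end = bed$end,
                           name = paste(seg$ril, seg$parent, sep = "|")),
                bedPath, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    jsonPath <- file.path(dir, "truth.json")
    jsonlite::write_json(list(breakpoints = trueBreakpoints(truth),
                              qtl = trueQTL(truth)),
                         jsonPath, digits = NA, auto_unbox = TRUE)
    invisible(c(bed = bedPath, json = jsonPath))
}
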