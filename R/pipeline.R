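## End-to-end orchestration: simulate -> qc -> parental inference ->
## HMM decode -> bins -> maps -> BLUP -> joint QTL, from a single
## validated config, with per-stage outputs and truth-comparison metrics.

.PIPE_STAGES <- c("simulate", "qc", "binmap", "map", "blup", "jointqtl")

#' Validate a pipeline configuration
#'
#' @param config a named list (or path to a YAML file) with any of the
#'   keys: \code{seed} (required), \code{out_dir} (required),
#'   \code{stages} (subset of simulate/qc/binmap/map/blup/jointqtl),
#'   \code{sim} (arguments for [simConfig()]), \code{qtl} (true-QTL
#'   data.frame: chrom, pos, one effect column per family),
#'   \code{phenotype} (n_env, n_rep, h2), \code{hmm} (epsilon, rho,
#'   p_min), \code{binning} (mask_bp, mask_snps, merge_bp),
#'   \code{jointqtl} (alpha, n_perm, flank), \code{qc}
#'   (run_nj: logical).  Unknown keys are rejected.
#' @return The completed config list.
#' @export
pipelineConfig <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    known <- c("seed", "out_dir", "stages", "sim", "qtl", "phenotype",
               "hmm", "binning", "jointqtl", "qc")
    unknown <- setdiff(names(config), known)
    if (length(unknown))
        .stopf("unknown config keys: %s", paste(unknown, collapse = ", "))
    if (is.null(config$seed)) .stopf("config$seed is required")
    if (is.null(config$out_dir)) .stopf("config$out_dir is required")
    config$stages <- if (is.null(config$stages)) .PIPE_STAGES else
        match.arg(config$stages, .PIPE_STAGES, several.ok = TRUE)
    defaults <- list(phenotype = list(n_env = 6, n_rep = 2, h2 = 0.9),
                     hmm = list(epsilon = 0.01, rho = 0.02, p_min = 0.99),
                     binning = list(mask_bp = 1.5e6, mask_snps = 5,
                                    merge_bp = 5000),
                     jointqtl = list(alpha = 0.05, n_perm = 200, flank = 4),
                     qc = list(run_nj = TRUE))
    for (k in names(defaults))
        config[[k]] <- utils::modifyList(defaults[[k]],
                                         if (is.null(config[[k]])) list()
                                         else config[[k]])
    config
}

## combine per-chromosome BinMaps of the same lines
.combineBinMaps <- function(bmList) {
    bins <- do.call(c, unname(lapply(bmList, binRanges)))
    g <- do.call(cbind, lapply(bmList, binGenotypes))
    colnames(g) <- names(bins)
    binMap(bins, g, familyOf(bmList[[1]]))
}

#' Error-corrected bin map for one family
#'
#' Chains residual-het masking ([maskHetRegions()]), origin encoding, HMM
#' decoding, block/bin calling, small-bin merging and transition
#' imputation over all chromosomes of one family.
#'
#' @param gm \linkS4class{GenotypeMatrix} of one family (prefiltered).
#' @param assignment a \code{ParentalAssignment} for its sites.
#' @param chromLengths named vector, chromosome -> length bp.
#' @param cm_per_bp named vector, chromosome -> cM per bp.
#' @param params [hmmParams()].
#' @param mask_bp,mask_snps,merge_bp binning thresholds.
#' @param het_window,het_min residual-het screen (see [maskHetRegions()]).
#' @return An imputed \linkS4class{BinMap}, with the decoded (post-mask)
#'   site states in attribute \code{"decoded"} and kept site indices in
#'   \code{"sites"}.
#' @export
familyBinMap <- function(gm, assignment, chromLengths, cm_per_bp,
                         params = hmmParams(), mask_bp = 1.5e6,
                         mask_snps = 5, merge_bp = 5000,
                         het_window = 7, het_min = 2) {
    masked <- maskHetRegions(genoCalls(gm), het_window, het_min)
    enc <- encodeOrigins(masked, assignment)
    sites <- siteRanges(gm)[enc$sites]
    chroms <- as.character(seqnames(sites))
    fam <- unique(familyOf(gm))
    if (length(fam) != 1) .stopf("familyBinMap expects a single family")
    bmL <- list()
    decoded <- matrix(NA_integer_, nrow(enc$origins), ncol(enc$origins),
                      dimnames = dimnames(enc$origins))
    for (ch in unique(chroms)) {
        ix <- which(chroms == ch)
        pos <- start(sites)[ix]
        st <- decodeRIL(enc$origins[, ix, drop = FALSE],
                        pos * cm_per_bp[[ch]], params)
        decoded[, ix] <- st
        bmL[[ch]] <- buildFamilyBins(st, pos, ch, chromLengths[[ch]], fam,
                                     mask_bp, mask_snps)
    }
    bm <- mergeSmallBins(.combineBinMaps(bmL), merge_bp)
    out <- imputeTransitionBins(bm, cm_per_bp, params)
    attr(out, "decoded") <- decoded
    attr(out, "sites") <- enc$sites
    out
}

## Re-genotype joint composite bins from the families' imputed bin maps.
## Cells of a family in which a joint bin was structurally missing in the
## encoding (marker monomorphic there: the family's whole column is NA)
## remain NA; everything else takes the imputed family-bin genotype at
## the joint bin midpoint.
.compositeGenotypes <- function(comp, famBinMaps) {
    bins <- binRanges(comp)
    enc <- binGenotypes(comp)
    fam <- familyOf(comp)
    chroms <- as.character(seqnames(bins))
    mids <- (start(bins) + end(bins)) / 2
    g <- matrix(NA_integer_, nrow(enc), ncol(enc), dimnames = dimnames(enc))
    for (f in names(famBinMaps)) {
        bmf <- famBinMaps[[f]]
        fbins <- binRanges(bmf)
        fchrom <- as.character(seqnames(fbins))
        fg <- binGenotypes(bmf)
        rows <- which(fam == f)
        lineIdx <- match(rownames(enc)[rows], rownames(fg))
        for (ch in unique(chroms)) {
            jc <- which(chroms == ch)
            fc <- which(fchrom == ch)
            if (!length(fc)) next
            k <- findInterval(mids[jc], start(fbins)[fc])
            ok <- k >= 1
            g[rows, jc[ok]] <- fg[lineIdx, fc[k[ok]], drop = FALSE]
        }
        ## structural NA: the family's encoding column entirely missing
        structNA <- colSums(!is.na(enc[rows, , drop = FALSE])) == 0
        g[rows, structNA] <- NA_integer_
    }
    binMap(bins, g, fam)
}

#' Run the full pipeline from a config
#'
#' Executes the configured stages in order, writing every stage's outputs
#' under \code{out_dir} and, because the simulator provides ground truth,
#' a \code{metrics.json} with breakpoint precision/recall, parental
#' assignment accuracy, map-length error and QTL power/coverage.
#' A stage failure stops with the failing stage named.
#'
#' @param config list or YAML path accepted by [pipelineConfig()].
#' @return Invisibly, a list with the main artifacts (panel, bin maps,
#'   maps, blups, qtl model, metrics).
#' @export
runPipeline <- function(config) {
    cfg <- pipelineConfig(config)
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    logFile <- file.path(cfg$out_dir, "pipeline.log")
    logmsg <- function(fmt, ...)
        cat(sprintf(paste0("[%s] ", fmt, "\n"),
                    format(Sys.time(), "%H:%M:%S"), ...),
            file = logFile, append = TRUE)
    stage <- function(name, expr) {
        logmsg("stage %s: start", name)
        r <- tryCatch(force(expr), error = function(e)
            .stopf("stage '%s' failed: %s", name, conditionMessage(e)))
        logmsg("stage %s: done", name)
        r
    }
    res <- list()
    simArgs <- cfg$sim
    simArgs$seed <- cfg$seed
    scfg <- do.call(simConfig, simArgs)
    chroms <- scfg$chromosomes
    chromLengths <- setNames(chroms$length_bp, chroms$chrom)
    cmPerBp <- setNames(chroms$length_cM / chroms$length_bp, chroms$chrom)
    qtl <- if (!is.null(cfg$qtl)) as.data.frame(cfg$qtl) else NULL

    panel <- stage("simulate", {
        p <- simulateNAMPanel(scfg, qtl = qtl)
        writeGenotypes(p$geno, file.path(cfg$out_dir, "genotypes.hmp.txt"))
        write.csv(data.frame(line = lineNames(p$geno),
                             family = familyOf(p$geno)),
                  file.path(cfg$out_dir, "families.csv"), row.names = FALSE)
        writeTruthSet(p$truth, file.path(cfg$out_dir, "truth"))
        p
    })
    res$panel <- panel
    geno <- panel$geno

    if ("qc" %in% cfg$stages) {
        geno <- stage("qc", {
            filtered <- filterSites(geno)
            het <- excessHetScan(filtered)
            contam <- if (isTRUE(cfg$qc$run_nj))
                njContaminantScan(filtered, founderGenotypes(panel$founders),
                                  setNames(paste0(unique(familyOf(geno)),
                                                  "_parent"),
                                           unique(familyOf(geno))))
            else data.frame(line = character(0), reason = character(0),
                            evidence = numeric(0), detail = character(0))
            report <- rbind(het, contam)
            write.csv(report, file.path(cfg$out_dir, "qc_report.csv"),
                      row.names = FALSE)
            bad <- unique(report$line[report$reason != "unevaluable"])
            filtered[!(lineNames(filtered) %in% bad), ]
        })
    }

    binMaps <- NULL
    if ("binmap" %in% cfg$stages) {
        binMaps <- stage("binmap", {
            hp <- hmmParams(cfg$hmm$epsilon, cfg$hmm$rho, cfg$hmm$p_min)
            out <- list()
            for (f in unique(familyOf(geno))) {
                gf <- geno[familyOf(geno) == f, ]
                gf <- prefilterFamilySites(gf)
                asg <- inferAssignmentParsimony(gf)
                asg <- refineByResampling(gf, asg)
                bm <- familyBinMap(gf, asg, chromLengths, cmPerBp, hp,
                                   cfg$binning$mask_bp, cfg$binning$mask_snps,
                                   cfg$binning$merge_bp)
                writeBinMap(bm, file.path(cfg$out_dir,
                                          sprintf("binmap_%s.tsv", f)))
                out[[f]] <- list(binMap = bm, assignment = asg, geno = gf)
            }
            out
        })
        res$binMaps <- binMaps
    }

    if ("map" %in% cfg$stages && !is.null(binMaps)) {
        res$maps <- stage("map", {
            fmaps <- lapply(binMaps, function(b)
                buildFamilyMap(b$binMap,
                               min_shared = min(30, nrow(binGenotypes(b$binMap)))))
            for (f in names(fmaps))
                writeGeneticMap(fmaps[[f]],
                                file.path(cfg$out_dir,
                                          sprintf("map_%s.csv", f)))
            ## composite from per-family decoded origins on shared sites
            originList <- lapply(binMaps, function(b) {
                d <- attr(b$binMap, "decoded")
                full <- matrix(NA_integer_, nrow(d), length(siteRanges(geno)),
                               dimnames = list(rownames(d), NULL))
                idx <- match(names(siteRanges(b$geno))[attr(b$binMap, "sites")],
                             names(siteRanges(geno)))
                full[, idx] <- d
                full
            })
            sel <- selectCompositeMarkers(originList,
                                          min_families = min(2, length(originList) - 1))
            comp <- compositeBins(sel$encoding, siteRanges(geno)[sel$markers],
                                  rep(names(binMaps),
                                      vapply(originList, nrow, 0L)),
                                  chromLengths)
            ## genotype the joint bins from the imputed family bin maps
            ## (the raw encoding is NA exactly at transition regions, which
            ## would hide recombinations from the distance estimates);
            ## family-monomorphic cells stay structurally NA
            comp <- .compositeGenotypes(comp,
                                        lapply(binMaps, `[[`, "binMap"))
            cmap <- assembleCompositeMap(comp)
            writeGeneticMap(cmap, file.path(cfg$out_dir, "composite_map.csv"))
            list(family = fmaps, composite = cmap, compositeBins = comp)
        })
    }

    if ("blup" %in% cfg$stages) {
        res$blup <- stage("blup", {
            ph <- simulatePhenotype(panel$truth,
                                    qtl = if (is.null(qtl)) data.frame()
                                    else qtl,
                                    n_env = cfg$phenotype$n_env,
                                    n_rep = cfg$phenotype$n_rep,
                                    h2 = cfg$phenotype$h2, seed = cfg$seed)
            writePhenotypes(ph, file.path(cfg$out_dir, "phenotypes.csv"))
            comp <- estimateComponents(ph)
            bl <- blupLines(ph, comp)
            write.csv(bl, file.path(cfg$out_dir, "blups.csv"),
                      row.names = FALSE)
            list(phenotypes = ph, components = comp,
                 h2 = h2MeanBasis(comp), blups = bl)
        })
    }

    if ("jointqtl" %in% cfg$stages && !is.null(res$maps) &&
        !is.null(res$blup)) {
        res$qtlModel <- stage("jointqtl", {
            comp <- res$maps$compositeBins
            g <- binGenotypes(comp)
            bl <- res$blup$blups
            keep <- intersect(rownames(g), bl$line)
            y <- setNames(bl$blup[match(keep, bl$line)], keep)
            mk <- g[keep, , drop = FALSE]
            mapTab <- markerTable(res$maps$composite)
            mk <- mk[, intersect(colnames(mk), mapTab$marker), drop = FALSE]
            model <- jointLinkageScan(y, familyOf(comp)[keep], mk, mapTab,
                                      alpha = cfg$jointqtl$alpha,
                                      n_perm = cfg$jointqtl$n_perm,
                                      seed = cfg$seed,
                                      flank = cfg$jointqtl$flank)
            write.csv(qtlTable(model), file.path(cfg$out_dir, "qtl.csv"),
                      row.names = FALSE)
            jsonlite::write_json(list(qtl = qtlTable(model),
                                      effects = alleleEffectTable(model)),
                                 file.path(cfg$out_dir, "qtl_model.json"),
                                 digits = NA, auto_unbox = TRUE)
            model
        })
    }

    res$metrics <- stage("metrics", {
        m <- pipelineMetrics(res, panel, chromLengths, cmPerBp)
        jsonlite::write_json(m, file.path(cfg$out_dir, "metrics.json"),
                             digits = NA, auto_unbox = TRUE)
        m
    })
    invisible(res)
}

#' Truth-comparison metrics for a pipeline run
#'
#' @param res partial pipeline results (as built by [runPipeline()]).
#' @param panel the simulated panel (with truth).
#' @param chromLengths,cmPerBp chromosome geometry.
#' @return List of metrics (breakpoint recall/spurious rate, assignment
#'   accuracy, map-length error, QTL detection, per family where
#'   applicable).
#' @export
pipelineMetrics <- function(res, panel, chromLengths, cmPerBp) {
    out <- list()
    truth <- panel$truth
    if (!is.null(res$binMaps)) {
        bp <- lapply(names(res$binMaps), function(f) {
            b <- res$binMaps[[f]]
            pred <- predictedBreakpoints(b$binMap)
            tb <- trueBreakpoints(truth)
            tSub <- truth
            tSub@breakpoints <- tb[tb$family == f, , drop = FALSE]
            rec <- breakpointRecovery(b$binMap, pred, tSub)
            acc <- .assignmentAccuracy(b, panel)
            c(recall = rec$recall, spurious = rec$spuriousRate,
              assignment = acc, nBins = length(binRanges(b$binMap)))
        })
        names(bp) <- names(res$binMaps)
        out$binmap <- bp
    }
    if (!is.null(res$maps)) {
        trueLen <- sum(attr(cmPerBp, "trueLen") %||%
                       (cmPerBp * chromLengths))
        out$map <- list(
            familyLengths = lapply(res$maps$family, mapLength),
            trueLength_cM = trueLen,
            compositeLength_cM = mapLength(res$maps$composite))
    }
    if (!is.null(res$blup)) out$h2 <- res$blup$h2
    if (!is.null(res$qtlModel)) {
        qt <- qtlTable(res$qtlModel)
        tq <- trueQTL(truth)
        covered <- if (nrow(tq) && nrow(qt))
            vapply(seq_len(nrow(tq)), function(i)
                any(qt$chrom == tq$chrom[i] &
                    qt$ci_lo_bp <= tq$pos[i] & qt$ci_hi_bp >= tq$pos[i]),
                logical(1))
        else logical(0)
        out$qtl <- list(nSelected = nrow(qt), nTrue = nrow(tq),
                        ciCoverage = if (length(covered)) mean(covered)
                        else NA_real_)
    }
    out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## fraction of retained sites assigned to the true common parent
## (max over global sign)
.assignmentAccuracy <- function(b, panel) {
    asg <- b$assignment$assignment
    keep <- !is.na(asg)
    if (!any(keep)) return(NA_real_)
    ids <- names(siteRanges(b$geno))[keep]
    idx <- match(ids, names(panel$founders$sites))
    trueA <- ifelse(panel$founders$commonAllele[idx] == "A", 0L, 1L)
    agree <- mean(asg[keep] == trueA)
    max(agree, 1 - agree)
}
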