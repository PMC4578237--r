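#' @import methods
#' @importFrom stats pchisq pf pt qf quantile rbinom rnorm rpois runif sd var
#'   aggregate setNames complete.cases lm anova
#' @importFrom utils read.table write.table write.csv read.csv head tail
NULL

#' Line (RIL) identifiers of an object
#'
#' @param x a \linkS4class{GenotypeMatrix} or \linkS4class{BinMap}.
#' @return Character vector of line identifiers.
#' @export
setGeneric("lineNames", function(x) standardGeneric("lineNames"))

#' Family membership of each line
#'
#' @param x a \linkS4class{GenotypeMatrix} or \linkS4class{BinMap}.
#' @return Named character vector mapping line id to family id.
#' @export
setGeneric("familyOf", function(x) standardGeneric("familyOf"))

#' Raw genotype calls
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @return Character matrix, lines x sites, with values \code{"A"},
#'   \code{"B"}, \code{"H"} or \code{NA}.
#' @export
setGeneric("genoCalls", function(x) standardGeneric("genoCalls"))

#' SNP site coordinates
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @return A \link[GenomicRanges]{GRanges} of width-1 SNP positions with
#'   metadata columns \code{alleleA} and \code{alleleB}.
#' @export
setGeneric("siteRanges", function(x) standardGeneric("siteRanges"))

#' Recombination bin intervals
#'
#' @param x a \linkS4class{BinMap}.
#' @return A \link[GenomicRanges]{GRanges} of bin intervals (1-based,
#'   inclusive), named by bin id.
#' @export
setGeneric("binRanges", function(x) standardGeneric("binRanges"))

#' Per-line bin genotypes
#'
#' @param x a \linkS4class{BinMap}.
#' @return Integer matrix, lines x bins; 0 = common-parent genotype,
#'   2 = diverse-parent genotype, \code{NA} = missing.
#' @export
setGeneric("binGenotypes", function(x) standardGeneric("binGenotypes"))

#' Marker table of a genetic map
#'
#' @param x a \linkS4class{GeneticMap}.
#' @return data.frame with columns marker, chrom, pos, cM, distorted,
#'   framework.
#' @export
setGeneric("markerTable", function(x) standardGeneric("markerTable"))

#' QTL summary table
#'
#' @param x a \linkS4class{QTLModel}.
#' @return data.frame with one row per selected QTL.
#' @export
setGeneric("qtlTable", function(x) standardGeneric("qtlTable"))
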