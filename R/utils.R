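## Internal helpers: hierarchical RNG streams and coordinate conversions.

## Derive a child seed from a master seed and a string key, so that each
## simulation sub-stream (founders, family 3, noise, ...) is reproducible on
## its own.  Plain multiplicative hash; stays inside 32-bit integer range.
.childSeed <- function(seed, ...) {
    key <- paste(c(...), collapse = "/")
    h <- as.double(seed %% 2147483647L)
    for (k in utf8ToInt(key)) h <- (h * 31 + k) %% 2147483629
    as.integer(h)
}

.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    force(expr)
}

## 1-based inclusive [start, end] <-> BED 0-based half-open [start0, end0)
.toBed <- function(start, end) data.frame(start = start - 1L, end = end)
.fromBed <- function(start0, end0) data.frame(start = start0 + 1L, end = end0)

## Origin coding used throughout: 0 = common parent, 2 = diverse parent.
.ORIGIN_COMMON <- 0L
.ORIGIN_DIVERSE <- 2L

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Per-site minor allele frequency on a calls matrix (lines x sites).
## Hets contribute one count to each allele; homozygotes two to theirs.
.siteMAF <- function(calls) {
    nA <- colSums(calls == "A", na.rm = TRUE) * 2 +
          colSums(calls == "H", na.rm = TRUE)
    nB <- colSums(calls == "B", na.rm = TRUE) * 2 +
          colSums(calls == "H", na.rm = TRUE)
    tot <- nA + nB
    maf <- pmin(nA, nB) / ifelse(tot == 0, NA_real_, tot)
    maf[tot == 0] <- 0
    maf
}

.siteCallRate <- function(calls) colMeans(!is.na(calls))
.lineCallRate <- function(calls) rowMeans(!is.na(calls))
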