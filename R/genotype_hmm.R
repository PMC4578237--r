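## Two-state hidden Markov model over parental origin along a chromosome.
## States: common-parent origin (0) and diverse-parent origin (2);
## heterozygous observations were set missing upstream, so no het state
## is needed.  Decoding is by forward-backward posterior rather than
## Viterbi, so that sites whose posterior is ambiguous can be left NA and
## later treated as transition-region missing data.

#' HMM parameters for origin decoding
#'
#' @param epsilon emission error: probability that an observed call shows
#'   the wrong parental origin (must lie in (0, 0.5)).
#' @param rho junction rate per cM; 0.02 (= 2 junctions per Morgan)
#'   reflects the two-fold map expansion of selfed RILs.
#' @param p_min posterior threshold: sites whose maximum posterior falls
#'   below this are decoded NA.
#' @return List of class \code{HMMParams}.
#' @export
hmmParams <- function(epsilon = 0.01, rho = 0.02, p_min = 0.99) {
    if (epsilon <= 0 || epsilon >= 0.5) .stopf("epsilon must be in (0, 0.5)")
    if (rho <= 0) .stopf("rho must be positive")
    structure(list(epsilon = epsilon, rho = rho, p_min = p_min),
              class = "HMMParams")
}

## transition probability between adjacent sites d cM apart
.hmmTrans <- function(d_cM, rho) pmin((1 - exp(-2 * rho * d_cM)) / 2, 0.5)

## Vectorized forward-backward over many RILs at once.
## origins: lines x sites in {0, 2, NA}; pos_cM increasing.
## Returns posterior array [lines, sites, 2] (state 1 = common, 2 = diverse).
.posteriorMatrix <- function(origins, pos_cM, params) {
    if (any(diff(pos_cM) <= 0))
        .stopf("site positions must be strictly increasing")
    n <- nrow(origins); k <- ncol(origins)
    eps <- params$epsilon
    ## emission likelihood per state
    E1 <- matrix(1, n, k); E2 <- matrix(1, n, k)
    obs0 <- !is.na(origins) & origins == 0L
    obs2 <- !is.na(origins) & origins == 2L
    E1[obs0] <- 1 - eps; E1[obs2] <- eps
    E2[obs0] <- eps;     E2[obs2] <- 1 - eps
    tr <- .hmmTrans(diff(pos_cM), params$rho)
    a1 <- 0.5 * E1[, 1]; a2 <- 0.5 * E2[, 1]
    sc <- a1 + a2
    A1 <- matrix(0, n, k); A2 <- matrix(0, n, k)
    A1[, 1] <- a1 / sc; A2[, 1] <- a2 / sc
    for (j in seq_len(k - 1) + 1) {
        t <- tr[j - 1]
        p1 <- (1 - t) * A1[, j - 1] + t * A2[, j - 1]
        p2 <- t * A1[, j - 1] + (1 - t) * A2[, j - 1]
        a1 <- p1 * E1[, j]; a2 <- p2 * E2[, j]
        sc <- a1 + a2
        A1[, j] <- a1 / sc; A2[, j] <- a2 / sc
    }
    B1 <- matrix(1, n, k); B2 <- matrix(1, n, k)
    if (k > 1) for (j in (k - 1):1) {
        t <- tr[j]
        b1n <- B1[, j + 1] * E1[, j + 1]
        b2n <- B2[, j + 1] * E2[, j + 1]
        b1 <- (1 - t) * b1n + t * b2n
        b2 <- t * b1n + (1 - t) * b2n
        sc <- b1 + b2
        B1[, j] <- b1 / sc; B2[, j] <- b2 / sc
    }
    g1 <- A1 * B1; g2 <- A2 * B2
    tot <- g1 + g2
    array(c(g1 / tot, g2 / tot), dim = c(n, k, 2))
}

#' Decode a RIL's parental origin along one chromosome
#'
#' Posterior (forward-backward) decoding of the two-state origin HMM.
#' The transition probability between adjacent sites d cM apart is
#' \code{(1 - exp(-2 rho d)) / 2}, capped at 0.5; emissions show the true
#' origin with probability \code{1 - epsilon}; missing sites emit nothing.
#' Sites whose maximum posterior is below \code{p_min} are decoded NA.
#'
#' @param origins integer vector (or lines x sites matrix) of origin-coded
#'   observations: 0 = common, 2 = diverse, NA = missing (hets were set
#'   missing upstream).
#' @param pos_cM genetic positions of the sites, strictly increasing.
#' @param params an [hmmParams()].
#' @param returnPosterior also return the posterior array.
#' @return Decoded states in \{0, 2, NA\}, same shape as the input; with
#'   \code{returnPosterior}, a list(states, posterior).
#' @export
decodeRIL <- function(origins, pos_cM, params = hmmParams(),
                      returnPosterior = FALSE) {
    vec <- is.null(dim(origins))
    m <- if (vec) matrix(origins, nrow = 1) else origins
    post <- .posteriorMatrix(m, pos_cM, params)
    p1 <- post[, , 1, drop = FALSE][, , 1]
    if (is.null(dim(p1))) p1 <- matrix(p1, nrow = nrow(m))
    states <- matrix(NA_integer_, nrow(m), ncol(m), dimnames = dimnames(m))
    states[p1 >= params$p_min] <- 0L
    states[(1 - p1) >= params$p_min] <- 2L
    if (vec) {
        states <- states[1, ]
        post <- post[1, , , drop = TRUE]
    }
    if (returnPosterior) list(states = states, posterior = post) else states
}

#' Estimate the emission error from decoded vs observed calls
#'
#' The mismatch fraction between confidently decoded states and the
#' non-missing observed calls estimates the per-call origin error.  With
#' fewer than \code{min_calls} usable calls the prior epsilon is kept.
#'
#' @param observed,decoded origin-coded matrices/vectors (\{0, 2, NA\}).
#' @param params an [hmmParams()]; its epsilon is the fallback prior.
#' @param min_calls minimum usable (both non-NA) calls (default 1000).
#' @return Updated \code{HMMParams} with the estimated epsilon and an
#'   attribute \code{"n"} giving the calls used.
#' @export
fitEpsilon <- function(observed, decoded, params = hmmParams(),
                       min_calls = 1000) {
    use <- !is.na(observed) & !is.na(decoded)
    n <- sum(use)
    if (n < min_calls) {
        attr(params, "n") <- n
        return(params)
    }
    eps <- mean(observed[use] != decoded[use])
    out <- hmmParams(epsilon = min(max(eps, 1e-6), 0.499),
                     rho = params$rho, p_min = params$p_min)
    attr(out, "n") <- n
    out
}
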