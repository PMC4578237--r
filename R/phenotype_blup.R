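## Cross-environment BLUPs and broad-sense heritability on a line-mean
## basis.  Variance components come from the ANOVA expected mean squares
## (method of moments); environments are fixed, lines random.  Exact REML
## (e.g. via lme4) gives the same answers on balanced data and can be used
## as an external cross-check.

#' Estimate variance components from a multi-environment trial
#'
#' Method-of-moments solution of the two-way (line x environment, with
#' replicates) ANOVA expected mean squares:
#' \code{sigma2_e = MS_error}, \code{sigma2_ge = (MS_LE - MS_error) / R},
#' \code{sigma2_g = (MS_L - MS_LE) / (E R)}.  Negative estimates are
#' truncated at zero.  With a single unreplicated environment the
#' line-by-environment and residual variances are confounded; the
#' confounded residual is returned in \code{sigma2_e} with a warning.
#'
#' @param ph phenotype data.frame (line, env, rep, value).
#' @return List of class \code{VarianceComponents}: sigma2_g, sigma2_ge,
#'   sigma2_e, E (environments), R (mean replicates per line-environment
#'   cell), grandMean.
#' @export
estimateComponents <- function(ph) {
    validatePhenotypes(ph)
    ph$line <- as.character(ph$line); ph$env <- as.character(ph$env)
    E <- length(unique(ph$env))
    cellN <- table(ph$line, ph$env)
    R <- mean(cellN[cellN > 0])
    if (length(unique(ph$line)) < 2)
        .stopf("need at least 2 lines")
    if (E < 2) {
        .warnf("single environment: line x env and residual variances are confounded")
        fit <- lm(value ~ line, data = ph)
        a <- suppressWarnings(anova(fit))
        msL <- a["line", "Mean Sq"]
        mse <- a["Residuals", "Mean Sq"]
        s2g <- max((msL - mse) / R, 0)
        return(structure(list(sigma2_g = s2g, sigma2_ge = NA_real_,
                              sigma2_e = mse, E = E, R = R,
                              grandMean = mean(ph$value)),
                         class = "VarianceComponents"))
    }
    replicated <- any(cellN > 1)
    if (replicated) {
        fit <- lm(value ~ env + line + env:line, data = ph)
        a <- suppressWarnings(anova(fit))   # mean squares only; the F-tests are unused
        msL <- a["line", "Mean Sq"]
        msLE <- a["env:line", "Mean Sq"]
        mse <- if ("Residuals" %in% rownames(a) &&
                   a["Residuals", "Df"] > 0) a["Residuals", "Mean Sq"] else 0
    } else {
        fit <- lm(value ~ env + line, data = ph)
        a <- suppressWarnings(anova(fit))
        msL <- a["line", "Mean Sq"]
        msLE <- a["Residuals", "Mean Sq"]
        mse <- 0
    }
    s2e <- max(mse, 0)
    s2ge <- max((msLE - s2e) / R, 0)
    s2g <- max((msL - msLE) / (E * R), 0)
    structure(list(sigma2_g = s2g, sigma2_ge = s2ge, sigma2_e = s2e,
                   E = E, R = R, grandMean = mean(ph$value)),
              class = "VarianceComponents")
}

#' Broad-sense heritability on a line-mean basis
#'
#' \code{H2 = sigma2_g / (sigma2_g + sigma2_ge / E + sigma2_e / (E R))}.
#'
#' @param comp a \code{VarianceComponents} (or list with the same fields).
#' @param E,R override the environments / replicates stored in
#'   \code{comp}.
#' @return H-squared in [0, 1].
#' @examples
#' h2MeanBasis(list(sigma2_g = 4, sigma2_ge = 1, sigma2_e = 2), E = 6,
#'             R = 2)   # 0.923
#' @export
h2MeanBasis <- function(comp, E = comp$E, R = comp$R) {
    ge <- if (is.null(comp$sigma2_ge) || is.na(comp$sigma2_ge)) 0 else
        comp$sigma2_ge
    denom <- comp$sigma2_g + ge / E + comp$sigma2_e / (E * R)
    if (denom <= 0) .stopf("zero total variance: H2 undefined")
    comp$sigma2_g / denom
}

#' Line BLUPs across environments
#'
#' Model: value = mu + environment (fixed) + line (random) + error.  Each
#' line's BLUP is the environment-adjusted line mean shrunk toward the
#' grand mean by \code{sigma2_g / (sigma2_g + v_i)}, where \code{v_i =
#' sigma2_ge / E_i + sigma2_e / n_i} is the sampling variance of line i's
#' adjusted mean given its own environment count \code{E_i} and
#' observation count \code{n_i} (per-line effective replication handles
#' unbalanced data).
#'
#' @param ph phenotype data.frame (line, env, rep, value).
#' @param comp optional precomputed \code{VarianceComponents}.
#' @return data.frame (line, blup, n_obs, n_env); lines with no
#'   observations are absent.  Attribute \code{"grandMean"}.
#' @export
blupLines <- function(ph, comp = NULL) {
    validatePhenotypes(ph)
    if (is.null(comp)) comp <- estimateComponents(ph)
    ph$line <- as.character(ph$line); ph$env <- as.character(ph$env)
    envMean <- tapply(ph$value, ph$env, mean)
    mu <- mean(ph$value)
    adj <- ph$value - (envMean[ph$env] - mu)      # environment-adjusted
    lineMean <- tapply(adj, ph$line, mean)
    nObs <- tapply(adj, ph$line, length)
    nEnv <- tapply(ph$env, ph$line, function(e) length(unique(e)))
    ge <- if (is.null(comp$sigma2_ge) || is.na(comp$sigma2_ge)) 0 else
        comp$sigma2_ge
    v <- ge / nEnv + comp$sigma2_e / nObs
    shrink <- if (comp$sigma2_g <= 0) rep(0, length(v)) else
        comp$sigma2_g / (comp$sigma2_g + v)
    out <- data.frame(line = names(lineMean),
                      blup = mu + shrink * (lineMean - mu),
                      n_obs = as.integer(nObs), n_env = as.integer(nEnv))
    rownames(out) <- NULL
    attr(out, "grandMean") <- mu
    out
}
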