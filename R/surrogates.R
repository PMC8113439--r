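#' @include AllClasses.R scoring.R
NULL

# standardize each column to zero mean, unit sample variance
.standardizeColumns <- function(m) {
    m <- scale(m)
    bad <- attr(m, "scaled:scale") == 0
    if (any(bad)) stop("cannot standardize a constant map")
    attr(m, "scaled:center") <- attr(m, "scaled:scale") <- NULL
    m
}

#' Generate an ensemble of independent random phenotype maps (SBP-random)
#'
#' Each surrogate assigns an independent standard-normal value to every
#' region; columns are then standardized to zero mean and unit variance.
#' With a fixed seed the ensemble is regenerated bit-identically.
#'
#' @param regionIds character region identifiers.
#' @param nNull number of surrogate maps (>= 1).
#' @param seed integer RNG seed stored in the ensemble spec.
#' @return A \linkS4class{NullPhenotypeEnsemble}.
#' @export
generateRandomMaps <- function(regionIds, nNull, seed = 1L) {
    if (nNull < 1L) stop("nNull must be >= 1")
    regionIds <- as.character(regionIds)
    n <- length(regionIds)
    if (n < 2L) stop("at least 2 regions required")
    set.seed(seed)
    maps <- .standardizeColumns(matrix(stats::rnorm(n * nNull), n, nNull))
    rownames(maps) <- regionIds
    new("NullPhenotypeEnsemble", regionIds = regionIds, maps = maps,
        spec = list(kind = "random", nNull = as.integer(nNull),
                    seed = as.integer(seed)))
}

# spatial-lag weight matrix: exponential kernel, zero diagonal, rows
# normalized to unit sum (guarantees invertibility of I - rho W for rho < 1)
.spatialLagW <- function(d, d0) {
    W <- exp(-d / d0)
    diag(W) <- 0
    rs <- rowSums(W)
    if (any(rs == 0)) stop("isolated region: zero spatial weights")
    W / rs
}

#' Generate spatially autocorrelated surrogate maps (SBP-spatial)
#'
#' Draws maps from the spatial-lag (simultaneous autoregressive) model
#' \eqn{u = (I - \rho W)^{-1}\epsilon} with i.i.d. standard-normal
#' \eqn{\epsilon}, where \eqn{W_{ij} = \exp(-d_{ij}/d_0)} for \eqn{i \ne j},
#' zero diagonal, rows normalized to unit sum. \eqn{\rho} controls the
#' autocorrelation strength relative to noise (default 0.8) and \eqn{d_0}
#' the characteristic spatial scale (mm). Columns are standardized.
#'
#' @param distances a \linkS4class{DistanceMatrix}.
#' @param d0 characteristic length scale in mm (> 0); typically estimated
#'   from the expression data with [fitSpatialScale()].
#' @param rho autocorrelation strength in [0, 1); default 0.8.
#' @param nNull number of maps.
#' @param seed integer RNG seed.
#' @param standardize standardize each map column (default TRUE); disable
#'   to inspect raw draws, whose covariance is [spatialLagCovariance()].
#' @return A \linkS4class{NullPhenotypeEnsemble}.
#' @export
generateSpatialLagMaps <- function(distances, d0, rho = 0.8, nNull,
                                   seed = 1L, standardize = TRUE) {
    stopifnot(is(distances, "DistanceMatrix"))
    if (d0 <= 0) stop("d0 must be positive")
    if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
    if (nNull < 1L) stop("nNull must be >= 1")
    d <- distances@d
    n <- nrow(d)
    W <- .spatialLagW(d, d0)
    A <- diag(n) - rho * W
    set.seed(seed)
    eps <- matrix(stats::rnorm(n * nNull), n, nNull)
    maps <- tryCatch(solve(A, eps), error = function(e)
        stop("singular (I - rho W) at rho = ", rho, ": ",
             conditionMessage(e)))
    if (standardize) maps <- .standardizeColumns(maps)
    rownames(maps) <- distances@regionIds
    new("NullPhenotypeEnsemble", regionIds = distances@regionIds,
        maps = maps,
        spec = list(kind = "spatial_lag", nNull = as.integer(nNull),
                    seed = as.integer(seed), rho = rho, d0 = d0))
}

#' Regenerate an ensemble from its stored specification
#'
#' @param spec an ensemble spec list (see
#'   \linkS4class{NullPhenotypeEnsemble}).
#' @param regionIds region ids for a random ensemble.
#' @param distances a \linkS4class{DistanceMatrix} for a spatial_lag
#'   ensemble.
#' @return A \linkS4class{NullPhenotypeEnsemble} bit-identical to the
#'   original.
#' @export
regenerateEnsemble <- function(spec, regionIds = NULL, distances = NULL) {
    if (spec$kind == "random") {
        if (is.null(regionIds)) stop("regionIds required for a random spec")
        generateRandomMaps(regionIds, spec$nNull, spec$seed)
    } else {
        if (is.null(distances)) stop("distances required for a spatial spec")
        generateSpatialLagMaps(distances, d0 = spec$d0, rho = spec$rho,
                               nNull = spec$nNull, seed = spec$seed)
    }
}

#' Analytic covariance of the spatial-lag model
#'
#' \eqn{(I - \rho W)^{-1} (I - \rho W^{T})^{-1}}: the exact covariance of
#' the surrogate maps before column standardization. Used as an independent
#' oracle for validating generated ensembles on small instances.
#'
#' @inheritParams generateSpatialLagMaps
#' @return The n x n covariance matrix.
#' @export
spatialLagCovariance <- function(distances, d0, rho = 0.8) {
    stopifnot(is(distances, "DistanceMatrix"))
    n <- nrow(distances@d)
    A <- diag(n) - rho * .spatialLagW(distances@d, d0)
    Ai <- solve(A)
    Ai %*% t(Ai)
}

#' Estimate the characteristic spatial scale d0 of an expression atlas
#'
#' Computes correlated gene expression across \emph{all} genes for every
#' region pair (Pearson), fits the three-parameter exponential
#' \eqn{CGE(d) = A\exp(-d/\lambda) + B}, and returns the fitted length scale
#' \eqn{d_0 := \lambda}. A weak fit (low \eqn{R^2}) indicates little
#' distance-dependent structure; the full fit object is returned so callers
#' can check.
#'
#' @param atlas an \linkS4class{ExpressionAtlas}.
#' @param distances a \linkS4class{DistanceMatrix}.
#' @return list(d0, fit) where fit is the \linkS4class{ExpDecayFit}.
#' @export
fitSpatialScale <- function(atlas, distances) {
    cge <- categoryCGE(atlas, geneIds(atlas), distances)
    if (length(unique(cge$d)) < 4L)
        stop("need >= 4 distinct inter-region distances")
    fit <- fitExpDecay(cge$d, cge$cge)
    if (!is.finite(fit@lambda) || fit@lambda <= 0)
        stop("degenerate spatial-scale fit (lambda = ", fit@lambda,
             ", R2 = ", fit@r2, ")")
    list(d0 = fit@lambda, fit = fit)
}
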