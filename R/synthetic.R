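#' @include surrogates.R
NULL

#' Specification for a synthetic spatial expression atlas
#'
#' Collects and validates the generator parameters: region and gene counts,
#' the edge length of the cubic domain region centroids are drawn in (mm),
#' per-category size / coexpression weight w / optional spatial
#' autocorrelation length ell (mm), the idiosyncratic noise level, the
#' strength of one shared dominant expression gradient, and the seed.
#'
#' @param nRegions,nGenes atlas dimensions.
#' @param coordinateBox cube edge length in mm for uniform random centroids.
#' @param categories list of lists with elements \code{size}, \code{w}
#'   (coexpression weight in [0, 1]) and optional \code{ell}
#'   (autocorrelation length in mm) per engineered category.
#' @param noiseSd standard deviation of each gene's idiosyncratic noise.
#' @param gradientStrength coefficient (>= 0) of the shared smooth gradient
#'   added to every gene.
#' @param seed integer seed.
#' @return A validated list of class \code{"SyntheticAtlasSpec"}.
#' @export
syntheticAtlasSpec <- function(nRegions = 100L, nGenes = 2000L,
                               coordinateBox = 40, categories = list(),
                               noiseSd = 1, gradientStrength = 0,
                               seed = 1L) {
    stopifnot(nRegions >= 3L, nGenes >= 1L, coordinateBox > 0,
              noiseSd > 0, gradientStrength >= 0)
    for (c in categories) {
        if (is.null(c$size) || c$size < 2L || c$size > nGenes)
            stop("category size must lie in [2, nGenes]")
        if (is.null(c$w) || c$w < 0 || c$w > 1)
            stop("coexpression weight w must lie in [0, 1]")
        if (!is.null(c$ell) && c$ell <= 0)
            stop("autocorrelation length ell must be positive")
    }
    if (sum(vapply(categories, function(c) c$size, numeric(1L))) > nGenes)
        stop("total category sizes exceed nGenes")
    structure(list(nRegions = as.integer(nRegions),
                   nGenes = as.integer(nGenes),
                   coordinateBox = coordinateBox, categories = categories,
                   noiseSd = noiseSd, gradientStrength = gradientStrength,
                   seed = as.integer(seed)),
              class = "SyntheticAtlasSpec")
}

# zero-mean unit-variance Gaussian field with correlation exp(-d / ell);
# the Cholesky factor can be precomputed and reused across draws
.grfChol <- function(d, ell) chol(exp(-d / ell) + diag(1e-8, nrow(d)))
.grfMap <- function(cholFactor)
    as.numeric(crossprod(cholFactor, stats::rnorm(nrow(cholFactor))))

#' Generate a synthetic expression atlas with engineered categories
#'
#' Region centroids are placed uniformly in a cube. Each engineered category
#' gets a latent spatial map \eqn{L} and member gene profiles
#' \eqn{g = w L + \sqrt{1 - w^2}\,\sigma_{noise} z}, giving (at
#' \code{noiseSd = 1}) a population pairwise within-category correlation of
#' \eqn{w^2}. By default \eqn{L} and the idiosyncratic components \eqn{z}
#' are i.i.d. across regions; when an autocorrelation length \eqn{\ell} is
#' set, both are drawn as Gaussian random fields with inter-region
#' correlation \eqn{\exp(-d/\ell)}, so every member gene is a smooth spatial
#' map and the category's correlated gene expression decays with distance as
#' \eqn{\exp(-d/\ell)} (gene-level heterogeneity, not only the shared
#' latent, carries the spatial structure, as in real transcriptomes). A
#' shared smooth gradient (linear in a random direction) can be added to
#' every gene; filler genes are noise plus gradient. All gene profiles are
#' standardized across regions.
#'
#' @param spec a [syntheticAtlasSpec()].
#' @return list with elements \code{atlas} (\linkS4class{ExpressionAtlas}
#'   with coordinates), \code{categories} (\linkS4class{CategoryTable} over
#'   the engineered categories), \code{gradient} (the shared gradient map)
#'   and \code{latents} (region x category latent matrix), the last two for
#'   validation against the generating truth.
#' @export
makeSyntheticAtlas <- function(spec) {
    stopifnot(inherits(spec, "SyntheticAtlasSpec"))
    set.seed(spec$seed)
    n <- spec$nRegions
    xy <- matrix(stats::runif(n * 3L, 0, spec$coordinateBox), n, 3L)
    regions <- sprintf("R%03d", seq_len(n))
    rownames(xy) <- regions
    d <- as.matrix(stats::dist(xy))
    u <- stats::rnorm(3L)
    G <- as.numeric(scale(xy %*% (u / sqrt(sum(u^2)))))
    genes <- sprintf("g%05d", seq_len(spec$nGenes))
    m <- matrix(NA_real_, n, spec$nGenes, dimnames = list(regions, genes))
    nc <- length(spec$categories)
    latents <- matrix(NA_real_, n, nc)
    sets <- vector("list", nc)
    nxt <- 1L
    chols <- list()                 # cache one Cholesky factor per ell
    for (i in seq_len(nc)) {
        cc <- spec$categories[[i]]
        draw <- if (is.null(cc$ell)) {
            function() stats::rnorm(n)
        } else {
            key <- as.character(cc$ell)
            if (is.null(chols[[key]]))
                chols[[key]] <- .grfChol(d, cc$ell)
            local({ cf <- chols[[key]]; function() .grfMap(cf) })
        }
        L <- as.numeric(scale(draw()))
        latents[, i] <- L
        members <- nxt:(nxt + cc$size - 1L)
        nxt <- nxt + cc$size
        for (j in members)
            m[, j] <- cc$w * L +
                sqrt(1 - cc$w^2) * spec$noiseSd * draw()
        sets[[i]] <- genes[members]
    }
    if (nxt <= spec$nGenes)
        for (j in nxt:spec$nGenes)
            m[, j] <- spec$noiseSd * stats::rnorm(n)
    if (spec$gradientStrength > 0)
        m <- m + spec$gradientStrength * G
    m <- apply(m, 2L, function(x) as.numeric(scale(x)))
    rownames(m) <- regions
    atlas <- ExpressionAtlas(m, coordinates = xy)
    categories <- if (nc)
        CategoryTable(categoryId = sprintf("SYN:%04d", seq_len(nc)),
                      genes = sets,
                      categoryName = vapply(seq_len(nc), function(i)
                          sprintf("synthetic w=%.2f s=%d%s",
                                  spec$categories[[i]]$w,
                                  spec$categories[[i]]$size,
                                  if (is.null(spec$categories[[i]]$ell)) ""
                                  else sprintf(" ell=%.1f",
                                               spec$categories[[i]]$ell)),
                          character(1L)))
    else CategoryTable(character(), list(), character())
    list(atlas = atlas, categories = categories, gradient =
             stats::setNames(G, regions), latents = latents, spec = spec)
}

#' Construct categories of randomly assigned genes
#'
#' Random gene sets with sizes drawn uniformly from a range; the synthetic
#' analogue of a GO category table for calibration audits, where category
#' membership carries no signal by construction.
#'
#' @param geneIds measured gene universe.
#' @param nCategories number of categories.
#' @param sizeRange inclusive integer size bounds (default c(10, 200)).
#' @param seed integer seed.
#' @return A \linkS4class{CategoryTable}.
#' @export
makeRandomCategories <- function(geneIds, nCategories,
                                 sizeRange = c(10L, 200L), seed = 1L) {
    geneIds <- as.character(geneIds)
    if (sizeRange[2L] > length(geneIds))
        stop("sizeRange exceeds the gene universe")
    set.seed(seed)
    sizes <- sample.int(sizeRange[2L] - sizeRange[1L] + 1L, nCategories,
                        replace = TRUE) + sizeRange[1L] - 1L
    sets <- lapply(sizes, function(s) sample(geneIds, s))
    CategoryTable(categoryId = sprintf("RND:%05d", seq_len(nCategories)),
                  genes = sets)
}

#' Phenotype aligned with the dominant expression gradient
#'
#' Returns the leading spatial principal component of the expression matrix
#' (the first left singular vector of the gene-centered region x gene
#' matrix) as a phenotype map, optionally with added noise. The sign is
#' fixed by orienting the component to correlate positively with its
#' top-loading gene.
#'
#' @param atlas an \linkS4class{ExpressionAtlas} (>= 3 regions).
#' @param noiseSd standard deviation of optional additive noise.
#' @param seed seed for the noise draw.
#' @return A \linkS4class{PhenotypeMap}.
#' @export
makeGradientAlignedPhenotype <- function(atlas, noiseSd = 0, seed = 1L) {
    m <- exprValues(atlas)
    if (nrow(m) < 3L) stop("need >= 3 regions")
    if (anyNA(m)) stop("gradient extraction requires complete data")
    mc <- scale(m, center = TRUE, scale = FALSE)
    sv <- svd(mc, nu = 1L, nv = 0L)
    if (sv$d[1L] < 1e-10 * nrow(m)) stop("degenerate (rank-deficient) atlas")
    pc <- sv$u[, 1L] * sv$d[1L]
    loading <- as.numeric(crossprod(mc, pc))
    top <- which.max(abs(loading))
    if (loading[top] < 0) pc <- -pc
    v <- as.numeric(scale(pc))
    if (noiseSd > 0) {
        set.seed(seed)
        v <- v + stats::rnorm(length(v), 0, noiseSd)
    }
    PhenotypeMap(regionIds = rownames(m), values = v)
}
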