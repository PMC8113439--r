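#' @include AllClasses.R scoring.R surrogates.R
NULL

# row standard deviations (denominator n - 1)
.rowSds <- function(m) {
    n <- ncol(m)
    mu <- rowMeans(m)
    sqrt(rowSums((m - mu)^2) / (n - 1L))
}

# gene x k matrix of correlations between every atlas gene and every map
# column; maps rows must be named by region id. Fast crossprod path when the
# data are complete, pairwise-complete cor() otherwise.
.scoreMatrix <- function(atlas, maps, method = "pearson") {
    X <- exprValues(atlas)                       # region x gene
    common <- intersect(rownames(X), rownames(maps))
    if (length(common) < 3L)
        stop("atlas and maps share fewer than 3 regions")
    X <- X[common, , drop = FALSE]
    Y <- maps[common, , drop = FALSE]
    if (method == "spearman") {
        X <- apply(X, 2L, rank, na.last = "keep")
        Y <- apply(Y, 2L, rank, na.last = "keep")
    }
    if (!anyNA(X) && !anyNA(Y)) {
        n <- nrow(X)
        Xs <- scale(X); Ys <- scale(Y)
        sdx <- attr(Xs, "scaled:scale")
        S <- crossprod(Xs, Ys) / (n - 1L)
        S[sdx == 0, ] <- NA_real_               # constant genes: undefined
        S
    } else {
        suppressWarnings(stats::cor(X, Y, use = "pairwise.complete.obs"))
    }
}

# sparse category x gene membership matrix, rows normalized to row means
.membershipMatrix <- function(categories, geneIds) {
    sets <- geneSets(categories)
    idx <- lapply(sets, function(g) match(intersect(g, geneIds), geneIds))
    len <- lengths(idx)
    if (any(len == 0L))
        stop("category with no scored member gene: ",
             paste(categoryIds(categories)[len == 0L], collapse = ", "))
    M <- Matrix::sparseMatrix(
        i = rep(seq_along(idx), len), j = unlist(idx),
        x = rep(1 / len, len),
        dims = c(length(idx), length(geneIds)),
        dimnames = list(categoryIds(categories), geneIds))
    M
}

#' Build random-gene null models for category mean scores
#'
#' For each category size \eqn{s}, forms the null distribution of the mean
#' of \eqn{s} gene scores drawn uniformly without replacement from the
#' scored-gene pool, and fits a Gaussian (mean and standard deviation of the
#' resampled means). The default is 40,000 resamples per size. With
#' \code{exact = TRUE} the Gaussian moments are computed in closed form from
#' the finite-population formulas (the limit the sampled fit converges to):
#' \eqn{\mu = \bar{x}} and
#' \eqn{\sigma^2 = \frac{S^2}{s}\left(1 - \frac{s}{N}\right)} for a pool of
#' \eqn{N} scores with sample variance \eqn{S^2}.
#'
#' @param scores a \linkS4class{GeneScoreTable}; the resampling pool.
#' @param sizes integer vector of category sizes needed.
#' @param nSamples resamples per size (default 40000).
#' @param seed RNG seed.
#' @param transform \code{"raw"} or \code{"absolute"}; must match the
#'   aggregation transform the null will be evaluated against.
#' @param exact use closed-form moments instead of resampling.
#' @param keepSamples retain the raw resampled means for empirical p-values
#'   (ignored when \code{exact}).
#' @return A \linkS4class{CategoryNullBank} keyed by size.
#' @export
buildRandomGeneNull <- function(scores, sizes, nSamples = 40000L, seed = 1L,
                                transform = c("raw", "absolute"),
                                exact = FALSE, keepSamples = FALSE) {
    transform <- match.arg(transform)
    stopifnot(is(scores, "GeneScoreTable"))
    pool <- scores@scores
    if (transform == "absolute") pool <- abs(pool)
    N <- length(pool)
    sizes <- sort(unique(as.integer(sizes)))
    if (max(sizes) > N)
        stop("category size ", max(sizes), " exceeds the score pool (", N,
             " genes)")
    if (!exact && nSamples < 100L) stop("nSamples must be >= 100")
    samp <- NULL
    if (exact) {
        mu <- rep(mean(pool), length(sizes))
        S2 <- stats::var(pool)
        sigma <- sqrt(S2 / sizes * (1 - sizes / N))
        n <- rep(Inf, length(sizes))
    } else {
        set.seed(seed)
        ms <- lapply(sizes, function(s)
            vapply(seq_len(nSamples), function(i)
                mean(pool[sample.int(N, s, useHash = TRUE)]), numeric(1L)))
        mu <- vapply(ms, mean, numeric(1L))
        sigma <- vapply(ms, stats::sd, numeric(1L))
        n <- rep(as.integer(nSamples), length(sizes))
        if (keepSamples) {
            samp <- do.call(rbind, ms)
            rownames(samp) <- as.character(sizes)
        }
    }
    new("CategoryNullBank",
        table = data.frame(key = as.character(sizes), size = sizes,
                           mu = mu, sigma = sigma, n = n,
                           stringsAsFactors = FALSE),
        nullKind = "random_gene", keyedBy = "size",
        scoreConfig = list(method = scores@method, transform = transform),
        samples = if (is.null(samp)) matrix(numeric(), 0L, 0L) else samp)
}

#' Build ensemble null models for category mean scores
#'
#' Scores every gene against every surrogate map of a phenotype ensemble and
#' aggregates per category, yielding one null category score per map; a
#' Gaussian is then fitted per category. Unlike the random-gene null this
#' null preserves each category's gene-gene coexpression (and, for
#' spatial-lag ensembles, generic spatial autocorrelation), so categories of
#' strongly coexpressed genes get wider nulls. The bank is independent of
#' any observed phenotype: it is a one-off computation that can be cached
#' and reused for any phenotype scored with the same configuration.
#'
#' @param atlas an \linkS4class{ExpressionAtlas}.
#' @param categories a \linkS4class{CategoryTable}.
#' @param ensemble a \linkS4class{NullPhenotypeEnsemble} whose regions all
#'   occur in the atlas.
#' @param method,transform gene-scoring configuration (recorded in the bank
#'   and enforced when the bank is evaluated).
#' @param keepSamples retain the raw per-category null scores (category x
#'   n_null matrix) for empirical p-values.
#' @param chunkSize surrogate maps are processed in chunks of this many
#'   columns to bound memory.
#' @return A \linkS4class{CategoryNullBank} keyed by category id.
#' @export
buildEnsembleNull <- function(atlas, categories, ensemble,
                              method = c("pearson", "spearman"),
                              transform = c("raw", "absolute"),
                              keepSamples = FALSE, chunkSize = 2000L) {
    method <- match.arg(method)
    transform <- match.arg(transform)
    stopifnot(is(atlas, "ExpressionAtlas"), is(categories, "CategoryTable"),
              is(ensemble, "NullPhenotypeEnsemble"))
    if (!all(ensemble@regionIds %in% regionIds(atlas)))
        stop("ensemble regions are not all present in the atlas")
    maps <- ensembleMaps(ensemble)
    nNull <- ncol(maps)
    M <- .membershipMatrix(categories, geneIds(atlas))
    starts <- seq(1L, nNull, by = chunkSize)
    C <- matrix(NA_real_, length(categories), nNull,
                dimnames = list(categoryIds(categories), NULL))
    for (st in starts) {
        en <- min(st + chunkSize - 1L, nNull)
        S <- .scoreMatrix(atlas, maps[, st:en, drop = FALSE], method)
        if (transform == "absolute") S <- abs(S)
        if (anyNA(S)) {
            ok <- !is.na(S)
            S0 <- ifelse(ok, S, 0)
            num <- (M > 0) %*% S0
            den <- (M > 0) %*% ok
            C[, st:en] <- as.matrix(num / den)
        } else {
            C[, st:en] <- as.matrix(M %*% S)
        }
    }
    sigma <- .rowSds(C)
    if (any(sigma == 0))
        stop("degenerate (zero-variance) null for category: ",
             paste(categoryIds(categories)[sigma == 0], collapse = ", "))
    new("CategoryNullBank",
        table = data.frame(key = categoryIds(categories),
                           size = unname(Matrix::rowSums(M > 0)),
                           mu = unname(rowMeans(C)), sigma = unname(sigma),
                           n = rep(nNull, length(categories)),
                           stringsAsFactors = FALSE),
        nullKind = paste0("ensemble_", ensembleSpec(ensemble)$kind),
        keyedBy = "category",
        scoreConfig = list(method = method, transform = transform,
                           ensemble = ensembleSpec(ensemble)),
        samples = if (keepSamples) C else matrix(numeric(), 0L, 0L))
}

#' Gaussian-estimated p-value of a category score
#'
#' Right tail: \eqn{p = 1 - \Phi((x - \hat\mu)/\hat\sigma)}; two-sided
#' doubles the smaller tail. p is floored at the smallest positive
#' representable double and capped at 1.
#'
#' @param score numeric score(s).
#' @param mu,sigma fitted Gaussian null parameters (sigma > 0).
#' @param tail \code{"right"} (default) or \code{"two_sided"}.
#' @return p-value(s) in (0, 1].
#' @export
gaussianP <- function(score, mu, sigma, tail = c("right", "two_sided")) {
    tail <- match.arg(tail)
    if (any(!is.finite(score))) stop("non-finite score")
    if (any(sigma <= 0)) stop("sigma must be positive")
    z <- (score - mu) / sigma
    p <- if (tail == "right") stats::pnorm(z, lower.tail = FALSE)
         else 2 * stats::pnorm(abs(z), lower.tail = FALSE)
    pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Empirical permutation p-value from raw null samples
#'
#' \eqn{p = (1 + \#\{x_{null} \ge x\}) / (n + 1)} for the right tail; the
#' two-sided value doubles the smaller tail (capped at 1).
#'
#' @param score observed score.
#' @param nullSamples numeric vector of null scores.
#' @param tail \code{"right"} or \code{"two_sided"}.
#' @export
empiricalP <- function(score, nullSamples, tail = c("right", "two_sided")) {
    tail <- match.arg(tail)
    if (!is.finite(score)) stop("non-finite score")
    n <- length(nullSamples)
    pr <- (1 + sum(nullSamples >= score)) / (n + 1)
    if (tail == "right") return(min(pr, 1))
    pl <- (1 + sum(nullSamples <= score)) / (n + 1)
    min(2 * min(pr, pl), 1)
}

#' Benjamini-Hochberg adjusted values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement
#' (delegates to \code{stats::p.adjust}).
#'
#' @param p vector of p-values in (0, 1].
#' @return adjusted q-values.
#' @export
bhFDR <- function(p) {
    if (!length(p)) stop("empty p-value vector")
    if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
        stop("p-values must lie in (0, 1]")
    stats::p.adjust(p, method = "BH")
}
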