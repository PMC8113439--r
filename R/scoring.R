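#' @include AllClasses.R atlas-io.R
NULL

#' Score every gene against a spatial phenotype
#'
#' Computes, for each gene, the spatial correlation between the phenotype map
#' and that gene's expression profile across regions, using pairwise-complete
#' observations. Genes with fewer than 3 complete pairs, or with constant
#' expression over the overlap, are dropped with a reported count.
#'
#' @param atlas an \linkS4class{ExpressionAtlas}.
#' @param phenotype a \linkS4class{PhenotypeMap}; aligned to the atlas by
#'   region id (row order in files is irrelevant).
#' @param method correlation type, \code{"pearson"} (default) or
#'   \code{"spearman"} (average ranks for ties).
#' @return A \linkS4class{GeneScoreTable}.
#' @export
scoreGenes <- function(atlas, phenotype, method = c("pearson", "spearman")) {
    method <- match.arg(method)
    al <- .alignPhenotype(atlas, phenotype)
    X <- exprValues(atlas)[al$regions, , drop = FALSE]
    y <- al$values
    if (stats::sd(y) == 0) stop("constant phenotype: undefined correlation")
    r <- suppressWarnings(
        stats::cor(X, y, use = "pairwise.complete.obs", method = method))[, 1L]
    nUsed <- colSums(!is.na(X) & is.finite(y))
    keep <- !is.na(r) & nUsed >= 3L
    if (!any(keep)) stop("no gene with >= 3 complete observations")
    if (any(!keep))
        message("scoreGenes: dropped ", sum(!keep),
                " gene(s) with undefined scores or < 3 complete pairs")
    new("GeneScoreTable", geneIds = colnames(X)[keep],
        scores = unname(r[keep]), nUsed = as.integer(unname(nUsed[keep])),
        method = method)
}

#' Aggregate gene scores per category (mean-score agglomeration)
#'
#' The category-level statistic is the arithmetic mean of its member gene
#' scores, optionally after taking absolute values. Members without a score
#' are dropped and the size recomputed; categories with no scored member are
#' excluded with a warning.
#'
#' @param scores a \linkS4class{GeneScoreTable}.
#' @param categories a \linkS4class{CategoryTable}.
#' @param transform \code{"raw"} (signed scores, default) or
#'   \code{"absolute"}.
#' @return data.frame with columns category_id, name, size, score.
#' @export
aggregateCategoryScores <- function(scores, categories,
                                    transform = c("raw", "absolute")) {
    transform <- match.arg(transform)
    stopifnot(is(scores, "GeneScoreTable"), is(categories, "CategoryTable"))
    v <- geneScores(scores)
    if (transform == "absolute") v <- abs(v)
    sets <- geneSets(categories)
    res <- lapply(seq_along(categories), function(i) {
        g <- intersect(sets[[i]], names(v))
        if (!length(g)) return(NULL)
        data.frame(category_id = categories@categoryId[i],
                   name = categories@categoryName[i],
                   size = length(g), score = mean(v[g]),
                   stringsAsFactors = FALSE)
    })
    dropped <- vapply(res, is.null, logical(1L))
    if (any(dropped))
        warning("aggregateCategoryScores: excluded ", sum(dropped),
                " category(ies) with no scored member gene")
    out <- do.call(rbind, res[!dropped])
    if (is.null(out)) stop("no category with scored members")
    rownames(out) <- NULL
    out
}

#' Within-category coexpression score
#'
#' Mean of the unique (upper-diagonal) entries of the gene x gene Spearman
#' coexpression matrix of a category's member genes, computed over
#' pairwise-complete regions.
#'
#' @param atlas an \linkS4class{ExpressionAtlas}.
#' @param genes character vector of member gene ids (>= 2 present in the
#'   atlas).
#' @return The scalar mean pairwise coexpression.
#' @export
withinCategoryCoexpression <- function(atlas, genes) {
    genes <- intersect(unique(genes), geneIds(atlas))
    if (length(genes) < 2L)
        stop("coexpression needs >= 2 measured member genes")
    X <- exprValues(atlas)[, genes, drop = FALSE]
    C <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs",
                                     method = "spearman"))
    mean(C[upper.tri(C)], na.rm = TRUE)
}

#' Correlated gene expression (CGE) of a category across region pairs
#'
#' For each unordered pair of regions, the Pearson correlation between the
#' two regions' expression values across the category's genes, paired with
#' the inter-region distance.
#'
#' @param atlas an \linkS4class{ExpressionAtlas}.
#' @param genes member gene ids (>= 3 measured genes required; with fewer
#'   genes a per-pair correlation is meaningless).
#' @param distances a \linkS4class{DistanceMatrix} covering the atlas
#'   regions.
#' @return data.frame with columns region_i, region_j, d, cge; one row per
#'   region pair. Pairs involving a region with no observed category
#'   expression are dropped.
#' @export
categoryCGE <- function(atlas, genes, distances) {
    stopifnot(is(distances, "DistanceMatrix"))
    genes <- intersect(unique(genes), geneIds(atlas))
    if (length(genes) < 3L) stop("CGE needs >= 3 measured member genes")
    regions <- intersect(regionIds(atlas), distances@regionIds)
    if (length(regions) < 2L) stop("atlas and distances share < 2 regions")
    X <- exprValues(atlas)[regions, genes, drop = FALSE]
    R <- suppressWarnings(stats::cor(t(X), use = "pairwise.complete.obs"))
    D <- distances@d[regions, regions]
    ut <- which(upper.tri(R), arr.ind = TRUE)
    out <- data.frame(region_i = regions[ut[, 1L]],
                      region_j = regions[ut[, 2L]],
                      d = D[ut], cge = R[ut], stringsAsFactors = FALSE)
    out[!is.na(out$cge), , drop = FALSE]
}

#' Fit the three-parameter exponential decay CGE(d) = A exp(-d/lambda) + B
#'
#' Nonlinear least squares via Levenberg-Marquardt. The first start is
#' A0 = max(y) - min(y), lambda0 = median(d), B0 = min(y); if that start
#' converges poorly, additional starts over distance quantiles are tried and
#' the best sum of squares kept (fast exponential decays are easily missed
#' from a single long-length start). Returns the goodness of fit
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} and the fit-free alternative statistic
#' \eqn{-\rho_{Spearman}(y, d)}.
#'
#' @param d numeric distances (mm).
#' @param y numeric CGE (or other decaying quantity) per distance.
#' @return An \linkS4class{ExpDecayFit}. Non-convergence is flagged rather
#'   than raised; the best iterate's parameters and R2 are reported.
#' @export
fitExpDecay <- function(d, y) {
    ok <- is.finite(d) & is.finite(y)
    d <- d[ok]; y <- y[ok]
    if (length(unique(d)) < 4L)
        stop("exponential fit needs >= 4 distinct distances")
    sstot <- sum((y - mean(y))^2)
    resid <- function(p) y - (p[1L] * exp(-d / p[2L]) + p[3L])
    lam0 <- unique(c(stats::median(d),
                     unname(stats::quantile(d, c(0.05, 0.1, 0.25, 0.75))),
                     diff(range(d))))
    lam0 <- lam0[lam0 > 0]
    best <- NULL
    for (l0 in lam0) {
        f <- try(minpack.lm::nls.lm(
            par = c(A = max(y) - min(y), lambda = l0, B = min(y)),
            fn = resid, lower = c(-Inf, 1e-8, -Inf),
            control = minpack.lm::nls.lm.control(maxiter = 1000L)),
            silent = TRUE)
        if (inherits(f, "try-error")) next
        if (is.null(best) || sum(f$fvec^2) < sum(best$fvec^2)) best <- f
    }
    if (is.null(best)) stop("exponential fit failed from every start")
    ssres <- sum(best$fvec^2)
    r2 <- if (sstot > 0) 1 - ssres / sstot else NA_real_
    conv <- best$info %in% 1:4
    altS <- -suppressWarnings(stats::cor(y, d, method = "spearman"))
    new("ExpDecayFit", A = unname(best$par[1L]),
        lambda = unname(best$par[2L]), B = unname(best$par[3L]),
        r2 = r2, altSpearman = altS, converged = conv,
        n = length(y))
}

#' Per-gene differential expression between two region classes
#'
#' Two-sided Wilcoxon rank-sum test per gene comparing expression between the
#' two region classes (e.g. cortex vs non-cortex), with Benjamini-Hochberg
#' adjusted q-values.
#'
#' @param atlas an \linkS4class{ExpressionAtlas}.
#' @param classLabels optional two-level labels per region (named by region
#'   id); defaults to \code{regionClass(atlas)}.
#' @return data.frame with columns gene_id, statistic, p, q. Genes fully
#'   missing in one class are excluded with a reported count.
#' @export
regionClassDifferential <- function(atlas, classLabels = NULL) {
    if (is.null(classLabels)) classLabels <- regionClass(atlas)
    if (is.null(classLabels)) stop("no region class labels available")
    if (!is.null(names(classLabels)))
        classLabels <- classLabels[regionIds(atlas)]
    lv <- unique(stats::na.omit(as.character(classLabels)))
    if (length(lv) != 2L) stop("exactly two region classes are required")
    g1 <- which(classLabels == lv[1L]); g2 <- which(classLabels == lv[2L])
    if (length(g1) < 2L || length(g2) < 2L)
        stop("both classes need >= 2 regions")
    X <- exprValues(atlas)
    res <- lapply(seq_len(ncol(X)), function(j) {
        a <- X[g1, j]; b <- X[g2, j]
        a <- a[!is.na(a)]; b <- b[!is.na(b)]
        if (!length(a) || !length(b)) return(NULL)
        w <- suppressWarnings(stats::wilcox.test(a, b,
                                                 alternative = "two.sided"))
        data.frame(gene_id = colnames(X)[j], statistic = unname(w$statistic),
                   p = w$p.value, stringsAsFactors = FALSE)
    })
    dropped <- vapply(res, is.null, logical(1L))
    if (any(dropped))
        message("regionClassDifferential: excluded ", sum(dropped),
                " gene(s) fully missing in one class")
    out <- do.call(rbind, res[!dropped])
    if (is.null(out)) stop("no testable gene")
    out$q <- stats::p.adjust(out$p, method = "BH")
    rownames(out) <- NULL
    out
}

#' Per-category diagnostics: coexpression and spatial autocorrelation scores
#'
#' For each category computes the within-category coexpression score and,
#' when a distance matrix is supplied, the distance-CGE exponential fit
#' (A, lambda, B, R2) and its Spearman alternative.
#'
#' @param atlas an \linkS4class{ExpressionAtlas}.
#' @param categories a \linkS4class{CategoryTable}.
#' @param distances optional \linkS4class{DistanceMatrix}.
#' @return data.frame with columns category_id, size, mean_coexpression and,
#'   with distances, A, lambda_mm, B, r2_exp, alt_spearman_stat.
#' @export
categoryDiagnostics <- function(atlas, categories, distances = NULL) {
    stopifnot(is(categories, "CategoryTable"))
    sets <- geneSets(categories)
    rows <- lapply(seq_along(categories), function(i) {
        g <- intersect(sets[[i]], geneIds(atlas))
        row <- data.frame(category_id = categories@categoryId[i],
                          size = length(g),
                          mean_coexpression =
                              if (length(g) >= 2L)
                                  withinCategoryCoexpression(atlas, g)
                              else NA_real_,
                          stringsAsFactors = FALSE)
        if (!is.null(distances)) {
            fit <- if (length(g) >= 3L) {
                cge <- categoryCGE(atlas, g, distances)
                if (length(unique(cge$d)) >= 4L)
                    fitExpDecay(cge$d, cge$cge) else NULL
            } else NULL
            row$A <- if (is.null(fit)) NA_real_ else fit@A
            row$lambda_mm <- if (is.null(fit)) NA_real_ else fit@lambda
            row$B <- if (is.null(fit)) NA_real_ else fit@B
            row$r2_exp <- if (is.null(fit)) NA_real_ else fit@r2
            row$alt_spearman_stat <-
                if (is.null(fit)) NA_real_ else fit@altSpearman
        }
        row
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' @rdname categoryDiagnostics
#' @param x a diagnostics data.frame.
#' @param path output TSV path.
#' @export
writeDiagnostics <- function(x, path) {
    data.table::fwrite(x, path, sep = "\t", quote = FALSE)
    invisible(path)
}
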