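#' @include nulls.R
NULL

#' Run gene category enrichment analysis
#'
#' End-to-end gene-score-resampling GCEA: scores every gene against the
#' phenotype, aggregates scores per category as the mean, evaluates each
#' category against the requested null model, and applies
#' Benjamini-Hochberg FDR. The full table is always returned (never only the
#' significant rows).
#'
#' Null models:
#' \describe{
#'   \item{random_gene}{mean of \eqn{s} scores resampled without replacement
#'     from this phenotype's gene-score pool (the conventional null; built
#'     on the fly, 40,000 resamples per size by default).}
#'   \item{ensemble}{per-category null scores against a bank of surrogate
#'     phenotypes (SBP-random or SBP-spatial); pass a prebuilt
#'     \code{nullBank} from [buildEnsembleNull()] (cached banks are reusable
#'     across phenotypes) or an \code{ensemble} to build one.}
#' }
#'
#' @param atlas an \linkS4class{ExpressionAtlas}.
#' @param phenotype a \linkS4class{PhenotypeMap}.
#' @param categories a \linkS4class{CategoryTable}.
#' @param null \code{"random_gene"} or \code{"ensemble"}.
#' @param nullBank optional prebuilt \linkS4class{CategoryNullBank}; its
#'   recorded scoring configuration must match \code{method}/
#'   \code{transform} or an error is raised.
#' @param ensemble optional \linkS4class{NullPhenotypeEnsemble} used to
#'   build an ensemble bank when none is supplied.
#' @param method gene scoring correlation, \code{"pearson"} (default) or
#'   \code{"spearman"}.
#' @param transform \code{"raw"} signed scores (default) or
#'   \code{"absolute"}.
#' @param tail \code{"right"} (default; tests for categories scoring higher
#'   than the null) or \code{"two_sided"}.
#' @param nSamples resamples per size for the random-gene null.
#' @param exactNull use closed-form Gaussian moments for the random-gene
#'   null instead of resampling (see [buildRandomGeneNull()]).
#' @param pMode \code{"gaussian"} (default: p from the fitted Gaussian,
#'   \eqn{p_Z}) or \code{"empirical"} (permutation p from the raw null
#'   samples; needs a bank with retained samples).
#' @param alphaFdr FDR significance threshold recorded in the output
#'   (default 0.05).
#' @param seed RNG seed for null resampling.
#' @return data.frame sorted by increasing p with columns category_id, name,
#'   size, score, p, q, null_kind, significant, and a \code{"config"}
#'   attribute holding the full run configuration.
#' @export
runGCEA <- function(atlas, phenotype, categories,
                    null = c("random_gene", "ensemble"),
                    nullBank = NULL, ensemble = NULL,
                    method = c("pearson", "spearman"),
                    transform = c("raw", "absolute"),
                    tail = c("right", "two_sided"),
                    nSamples = 40000L, exactNull = FALSE,
                    pMode = c("gaussian", "empirical"),
                    alphaFdr = 0.05, seed = 1L) {
    null <- match.arg(null)
    method <- match.arg(method)
    transform <- match.arg(transform)
    tail <- match.arg(tail)
    pMode <- match.arg(pMode)
    scores <- withCallingHandlers(
        scoreGenes(atlas, phenotype, method),
        error = function(e) stop("scoring stage: ", conditionMessage(e)))
    agg <- tryCatch(
        aggregateCategoryScores(scores, categories, transform),
        error = function(e) stop("aggregation stage: ",
                                 conditionMessage(e)))
    if (null == "random_gene") {
        if (is.null(nullBank))
            nullBank <- buildRandomGeneNull(
                scores, sizes = unique(agg$size), nSamples = nSamples,
                seed = seed, transform = transform, exact = exactNull,
                keepSamples = pMode == "empirical")
        keys <- as.character(agg$size)
    } else {
        if (is.null(nullBank)) {
            if (is.null(ensemble))
                stop("ensemble null requires a nullBank or an ensemble")
            nullBank <- buildEnsembleNull(atlas, categories, ensemble,
                                          method = method,
                                          transform = transform,
                                          keepSamples = pMode == "empirical")
        }
        keys <- agg$category_id
    }
    cfg <- nullBank@scoreConfig
    if (!identical(cfg$method, method) ||
        !identical(cfg$transform, transform))
        stop("null bank was built with scoring configuration ", cfg$method,
             "/", cfg$transform, " but ", method, "/", transform,
             " was requested")
    idx <- match(keys, nullBank@table$key)
    if (anyNA(idx))
        stop("null stage: no null model for ",
             paste(utils::head(keys[is.na(idx)], 5L), collapse = ", "))
    if (pMode == "gaussian") {
        p <- gaussianP(agg$score, nullBank@table$mu[idx],
                       nullBank@table$sigma[idx], tail = tail)
    } else {
        if (!nrow(nullBank@samples))
            stop("empirical p-values need a bank built with keepSamples")
        p <- vapply(seq_len(nrow(agg)), function(i)
            empiricalP(agg$score[i],
                       nullBank@samples[nullBank@table$key[idx[i]], ],
                       tail = tail), numeric(1L))
    }
    out <- data.frame(category_id = agg$category_id, name = agg$name,
                      size = agg$size, score = agg$score, p = p,
                      q = bhFDR(p),
                      null_kind = nullBank@nullKind,
                      stringsAsFactors = FALSE)
    out$significant <- out$q < alphaFdr
    out <- out[order(out$p, out$category_id), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "config") <- list(
        null = nullBank@nullKind, method = method, transform = transform,
        tail = tail, p_mode = pMode, n_samples =
            if (null == "random_gene" && exactNull) "exact" else
                max(nullBank@table$n),
        alpha_fdr = alphaFdr, seed = seed,
        n_regions = length(regionIds(atlas)),
        n_genes = length(scores),
        ensemble_spec = if (null == "ensemble")
            nullBank@scoreConfig$ensemble else NULL)
    out
}
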