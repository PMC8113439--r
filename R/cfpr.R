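#' @include gcea.R
NULL

#' Independently randomize each gene's expression profile
#'
#' Permutes every gene's values across regions with an independent
#' permutation per gene, preserving each gene's missingness pattern
#' (observed values are shuffled among observed positions). This destroys
#' gene-gene coexpression and spatial structure while keeping every gene's
#' value multiset, giving the reference condition for false-positive-rate
#' audits.
#'
#' @param atlas an \linkS4class{ExpressionAtlas}.
#' @param seed RNG seed.
#' @return A randomized \linkS4class{ExpressionAtlas}.
#' @export
referenceRandomize <- function(atlas, seed = 1L) {
    m <- exprValues(atlas)
    set.seed(seed)
    for (j in seq_len(ncol(m))) {
        obs <- which(!is.na(m[, j]))
        if (length(obs) > 1L)
            m[obs, j] <- m[obs[sample.int(length(obs))], j]
    }
    co <- regionCoords(atlas)
    rc <- regionClass(atlas)
    ExpressionAtlas(m, coordinates = co, regionClass = rc)
}

#' Per-category false-positive rate under a phenotype ensemble
#'
#' Runs GCEA once per surrogate phenotype in the ensemble and reports, for
#' every category, the percentage of phenotypes for which it was called
#' significant (\eqn{q_{FDR} < \alpha}). The inner GCEA defaults to the
#' conventional random-gene null, since the CFPR is defined as the
#' conventional method's false-positive rate; auditing an ensemble-null
#' GCEA (expected to stay near the nominal rate) is supported by passing
#' \code{null = "ensemble"} with a prebuilt bank.
#'
#' With \code{exactNull = TRUE} (default) the random-gene Gaussian null uses
#' closed-form moments, making large audits tractable; the per-phenotype
#' loop is then fully vectorized. \code{exactNull = FALSE} falls back to a
#' literal per-phenotype [runGCEA()] loop with resampled nulls.
#'
#' @param atlas an \linkS4class{ExpressionAtlas}.
#' @param categories a \linkS4class{CategoryTable}.
#' @param ensemble a \linkS4class{NullPhenotypeEnsemble} of audit
#'   phenotypes (full-scale audits typically use 10,000).
#' @param alphaFdr significance threshold on q (default 0.05).
#' @param method,transform,tail inner GCEA scoring configuration.
#' @param null inner null model, \code{"random_gene"} (default) or
#'   \code{"ensemble"}.
#' @param nullBank prebuilt \linkS4class{CategoryNullBank} (required for
#'   \code{null = "ensemble"}).
#' @param nSamples,exactNull random-gene null configuration.
#' @param condition label stored in the output; defaults to
#'   \code{"sbp_random"}/\code{"sbp_spatial"} from the ensemble kind. Use
#'   \code{"reference"} when the atlas has been through
#'   [referenceRandomize()].
#' @param chunkSize phenotypes processed per block.
#' @param seed seed for resampled nulls (fallback path only).
#' @return data.frame with columns category_id, condition, n_phenotypes,
#'   n_significant, cfpr_percent and a \code{"config"} attribute.
#' @export
computeCFPR <- function(atlas, categories, ensemble, alphaFdr = 0.05,
                        method = c("pearson", "spearman"),
                        transform = c("raw", "absolute"),
                        tail = c("right", "two_sided"),
                        null = c("random_gene", "ensemble"),
                        nullBank = NULL, nSamples = 40000L,
                        exactNull = TRUE, condition = NULL,
                        chunkSize = 500L, seed = 1L) {
    method <- match.arg(method)
    transform <- match.arg(transform)
    tail <- match.arg(tail)
    null <- match.arg(null)
    stopifnot(is(ensemble, "NullPhenotypeEnsemble"))
    if (!all(ensemble@regionIds %in% regionIds(atlas)))
        stop("ensemble regions are not all present in the atlas")
    if (is.null(condition))
        condition <- switch(ensembleSpec(ensemble)$kind,
                            random = "sbp_random",
                            spatial_lag = "sbp_spatial")
    if (null == "ensemble") {
        if (is.null(nullBank))
            stop("auditing the ensemble null requires a prebuilt nullBank")
        cfg <- nullBank@scoreConfig
        if (!identical(cfg$method, method) ||
            !identical(cfg$transform, transform))
            stop("null bank scoring configuration mismatch")
    }
    maps <- ensembleMaps(ensemble)
    nPheno <- ncol(maps)
    ids <- categoryIds(categories)
    nsig <- stats::setNames(integer(length(ids)), ids)

    if (null == "random_gene" && !exactNull) {
        # literal loop with resampled nulls; slow, small audits only
        for (k in seq_len(nPheno)) {
            ph <- PhenotypeMap(ensemble@regionIds, maps[, k])
            res <- suppressWarnings(suppressMessages(
                runGCEA(atlas, ph, categories, null = "random_gene",
                        method = method, transform = transform, tail = tail,
                        nSamples = nSamples, alphaFdr = alphaFdr,
                        seed = seed + k)))
            hit <- res$category_id[res$significant]
            nsig[hit] <- nsig[hit] + 1L
        }
    } else {
        # vectorized audit; identical decisions to the per-phenotype loop
        keep <- .scorableGenes(atlas)
        M <- .membershipMatrix(categories, keep)
        sizes <- unname(Matrix::rowSums(M > 0))
        starts <- seq(1L, nPheno, by = chunkSize)
        for (st in starts) {
            en <- min(st + chunkSize - 1L, nPheno)
            S <- .scoreMatrix(atlas, maps[, st:en, drop = FALSE], method)
            S <- S[keep, , drop = FALSE]
            if (transform == "absolute") S <- abs(S)
            C <- as.matrix(M %*% S)
            if (null == "random_gene") {
                N <- nrow(S)
                muPool <- colMeans(S)
                sdPool <- sqrt(.colVars(S))
                f <- sqrt((1 - sizes / N) / sizes)
                Z <- sweep(C, 2L, muPool) / (f %o% sdPool)
            } else {
                idx <- match(ids, nullBank@table$key)
                if (anyNA(idx)) stop("null bank is missing categories")
                Z <- (C - nullBank@table$mu[idx]) / nullBank@table$sigma[idx]
            }
            P <- if (tail == "right")
                     stats::pnorm(Z, lower.tail = FALSE)
                 else 2 * stats::pnorm(abs(Z), lower.tail = FALSE)
            P <- pmin(pmax(P, .Machine$double.xmin), 1)
            Q <- apply(P, 2L, stats::p.adjust, method = "BH")
            if (!is.matrix(Q)) Q <- matrix(Q, nrow = nrow(P))
            nsig <- nsig + rowSums(Q < alphaFdr)
        }
    }
    out <- data.frame(category_id = ids, condition = condition,
                      n_phenotypes = nPheno,
                      n_significant = as.integer(nsig),
                      cfpr_percent = 100 * nsig / nPheno,
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "config") <- list(
        null = null, method = method, transform = transform, tail = tail,
        alpha_fdr = alphaFdr, exact_null = exactNull,
        n_samples = nSamples, ensemble_spec = ensembleSpec(ensemble))
    out
}

# genes usable for scoring: non-constant with >= 3 observed regions
.scorableGenes <- function(atlas) {
    m <- exprValues(atlas)
    nobs <- colSums(!is.na(m))
    sds <- apply(m, 2L, stats::sd, na.rm = TRUE)
    colnames(m)[nobs >= 3L & !is.na(sds) & sds > 0]
}

.colVars <- function(m) {
    n <- nrow(m)
    mu <- colMeans(m)
    colSums(sweep(m, 2L, mu)^2) / (n - 1L)
}

#' Summarize CFPR tables across conditions and category properties
#'
#' Produces (i) mean CFPR per condition with pairwise fold changes,
#' (ii) equiprobable CFPR bins (bin sizes differing by at most one
#' category) with per-bin mean coexpression, spatial-autocorrelation score
#' and, when supplied, the proportion of literature-reported categories
#' falling in each bin, and (iii) the per-category CFPR change between the
#' sbp_random and sbp_spatial conditions when both are present.
#'
#' @param tables a named list of CFPR tables from [computeCFPR()] (names
#'   default to each table's condition), or a single table.
#' @param diagnostics optional data.frame from [categoryDiagnostics()].
#' @param literatureLabels optional per-category report counts: a
#'   data.frame (category_id, n_reports) or a character vector of reported
#'   category ids.
#' @param nBins number of equiprobable bins (default 8).
#' @param binOn condition whose CFPR defines the binning; defaults to
#'   \code{"sbp_random"} when present, else the first table.
#' @return list(mean_cfpr, fold_change, bins, delta).
#' @export
summarizeCFPR <- function(tables, diagnostics = NULL,
                          literatureLabels = NULL, nBins = 8L,
                          binOn = NULL) {
    if (is.data.frame(tables)) tables <- list(tables)
    if (is.null(names(tables)) || any(!nzchar(names(tables))))
        names(tables) <- vapply(tables, function(t) t$condition[1L],
                                character(1L))
    if (nBins < 2L) stop("nBins must be >= 2")
    meanC <- vapply(tables, function(t) mean(t$cfpr_percent), numeric(1L))
    fold <- outer(meanC, meanC, function(a, b) a / b)
    dimnames(fold) <- list(names(tables), names(tables))

    if (is.null(binOn))
        binOn <- if ("sbp_random" %in% names(tables)) "sbp_random"
                 else names(tables)[1L]
    tb <- tables[[binOn]]
    if (nrow(tb) < nBins) stop("fewer categories than bins")
    ord <- order(tb$cfpr_percent, tb$category_id)
    binId <- integer(nrow(tb))
    binId[ord] <- rep(seq_len(nBins),
                      times = diff(floor(seq(0, nrow(tb), length.out =
                                                 nBins + 1L))))
    if (is.character(literatureLabels))
        literatureLabels <- data.frame(category_id = literatureLabels,
                                       n_reports = 1L)
    rep_count <- rep(0, nrow(tb))
    if (!is.null(literatureLabels)) {
        idx <- match(tb$category_id, literatureLabels$category_id)
        rep_count <- ifelse(is.na(idx), 0,
                            literatureLabels$n_reports[idx])
    }
    coex <- r2 <- rep(NA_real_, nrow(tb))
    if (!is.null(diagnostics)) {
        idx <- match(tb$category_id, diagnostics$category_id)
        coex <- diagnostics$mean_coexpression[idx]
        if ("r2_exp" %in% colnames(diagnostics))
            r2 <- diagnostics$r2_exp[idx]
    }
    bins <- do.call(rbind, lapply(seq_len(nBins), function(b) {
        sel <- binId == b
        data.frame(bin = b, n = sum(sel),
                   cfpr_lo = min(tb$cfpr_percent[sel]),
                   cfpr_hi = max(tb$cfpr_percent[sel]),
                   cfpr_mid = (min(tb$cfpr_percent[sel]) +
                               max(tb$cfpr_percent[sel])) / 2,
                   mean_cfpr = mean(tb$cfpr_percent[sel]),
                   mean_coexpression = mean(coex[sel], na.rm = TRUE),
                   mean_r2_exp = mean(r2[sel], na.rm = TRUE),
                   prop_reported = if (sum(rep_count) > 0)
                       sum(rep_count[sel]) / sum(rep_count) else NA_real_)
    }))

    delta <- NULL
    if (all(c("sbp_random", "sbp_spatial") %in% names(tables))) {
        a <- tables[["sbp_random"]]; b <- tables[["sbp_spatial"]]
        idx <- match(a$category_id, b$category_id)
        delta <- data.frame(category_id = a$category_id,
                            cfpr_random = a$cfpr_percent,
                            cfpr_spatial = b$cfpr_percent[idx],
                            delta = b$cfpr_percent[idx] - a$cfpr_percent,
                            stringsAsFactors = FALSE)
    }
    list(mean_cfpr = meanC, fold_change = fold, bins = bins, delta = delta)
}

#' @rdname computeCFPR
#' @param x a CFPR table.
#' @param path output TSV path.
#' @export
writeCFPRTable <- function(x, path) {
    data.table::fwrite(x, path, sep = "\t", quote = FALSE)
    invisible(path)
}
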