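#' @include AllGenerics.R
NULL

#' @rdname atlas-accessors
#' @export
setMethod("regionIds", "ExpressionAtlas", function(x) colnames(x))

#' @rdname atlas-accessors
#' @export
setMethod("regionIds", "PhenotypeMap", function(x) x@regionIds)

#' @rdname atlas-accessors
#' @export
setMethod("regionIds", "DistanceMatrix", function(x) x@regionIds)

#' @rdname atlas-accessors
#' @export
setMethod("regionIds", "NullPhenotypeEnsemble", function(x) x@regionIds)

#' @rdname atlas-accessors
#' @export
setMethod("geneIds", "ExpressionAtlas", function(x) rownames(x))

#' @rdname atlas-accessors
#' @export
setMethod("geneIds", "GeneScoreTable", function(x) x@geneIds)

#' @rdname atlas-accessors
#' @export
setMethod("exprValues", "ExpressionAtlas", function(x)
    t(SummarizedExperiment::assay(x, "expr")))

#' @rdname atlas-accessors
#' @export
setMethod("regionCoords", "ExpressionAtlas", function(x) {
    cd <- SummarizedExperiment::colData(x)
    if (!all(c("x", "y", "z") %in% colnames(cd))) return(NULL)
    m <- cbind(x = cd$x, y = cd$y, z = cd$z)
    rownames(m) <- colnames(x)
    m
})

#' @rdname atlas-accessors
#' @export
setMethod("regionCoords<-", "ExpressionAtlas", function(x, value) {
    value <- as.matrix(value)
    if (nrow(value) != ncol(x))
        stop("coordinates must have one row per region")
    if (!is.null(rownames(value)))
        value <- value[colnames(x), , drop = FALSE]
    cd <- SummarizedExperiment::colData(x)
    cd$x <- value[, 1L]; cd$y <- value[, 2L]; cd$z <- value[, 3L]
    SummarizedExperiment::colData(x) <- cd
    validObject(x)
    x
})

#' @rdname atlas-accessors
#' @export
setMethod("regionClass", "ExpressionAtlas", function(x) {
    cd <- SummarizedExperiment::colData(x)
    if (!"region_class" %in% colnames(cd)) return(NULL)
    stats::setNames(cd$region_class, colnames(x))
})

#' @rdname atlas-accessors
#' @export
setMethod("phenotypeValues", "PhenotypeMap", function(x)
    stats::setNames(x@values, x@regionIds))

#' @rdname atlas-accessors
#' @export
setMethod("distanceValues", "DistanceMatrix", function(x) x@d)

#' @rdname category-accessors
#' @export
setMethod("categoryIds", "CategoryTable", function(x) x@categoryId)

#' @rdname category-accessors
#' @export
setMethod("categoryNames", "CategoryTable", function(x) x@categoryName)

#' @rdname category-accessors
#' @export
setMethod("categorySizes", "CategoryTable", function(x)
    stats::setNames(unname(lengths(x@genes)), x@categoryId))

#' @rdname category-accessors
#' @export
setMethod("geneSets", "CategoryTable", function(x) x@genes)

#' @rdname score-accessors
#' @export
setMethod("geneScores", "GeneScoreTable", function(x)
    stats::setNames(x@scores, x@geneIds))

#' @rdname ensemble-accessors
#' @export
setMethod("ensembleMaps", "NullPhenotypeEnsemble", function(x) x@maps)

#' @rdname ensemble-accessors
#' @export
setMethod("ensembleSpec", "NullPhenotypeEnsemble", function(x) x@spec)

#' @rdname nullbank-accessors
#' @export
setMethod("nullParameters", "CategoryNullBank", function(x) x@table)

#' @rdname nullbank-accessors
#' @export
setMethod("nullKind", "CategoryNullBank", function(x) x@nullKind)

#' @rdname fit-accessors
#' @export
setMethod("decayLength", "ExpDecayFit", function(x) x@lambda)

#' @rdname fit-accessors
#' @export
setMethod("fitR2", "ExpDecayFit", function(x) x@r2)
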