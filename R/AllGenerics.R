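#' @include AllClasses.R
NULL

#' Accessors for atlas-like objects
#'
#' \code{regionIds} and \code{geneIds} return the identifier vectors;
#' \code{exprValues} returns the expression matrix in the region x gene
#' orientation; \code{regionCoords} returns the region x 3 coordinate matrix
#' (mm) or \code{NULL}; \code{regionClass} returns the per-region class
#' labels or \code{NULL}.
#'
#' @param x an object with regions (and genes).
#' @param value replacement value.
#' @return See the individual descriptions.
#' @name atlas-accessors
NULL

#' @rdname atlas-accessors
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))

#' @rdname atlas-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname atlas-accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname atlas-accessors
#' @export
setGeneric("regionCoords", function(x) standardGeneric("regionCoords"))

#' @rdname atlas-accessors
#' @export
setGeneric("regionCoords<-", function(x, value)
    standardGeneric("regionCoords<-"))

#' @rdname atlas-accessors
#' @export
setGeneric("regionClass", function(x) standardGeneric("regionClass"))

#' @rdname atlas-accessors
#' @export
setGeneric("phenotypeValues", function(x) standardGeneric("phenotypeValues"))

#' @rdname atlas-accessors
#' @export
setGeneric("distanceValues", function(x) standardGeneric("distanceValues"))

#' Category accessors
#'
#' \code{categoryIds} returns category accessions, \code{categorySizes} the
#' per-category gene counts (symbol \eqn{s}), \code{geneSets} the member
#' gene-id sets as a \link[IRanges]{CharacterList}.
#'
#' @param x a \linkS4class{CategoryTable}.
#' @name category-accessors
NULL

#' @rdname category-accessors
#' @export
setGeneric("categoryIds", function(x) standardGeneric("categoryIds"))

#' @rdname category-accessors
#' @export
setGeneric("categoryNames", function(x) standardGeneric("categoryNames"))

#' @rdname category-accessors
#' @export
setGeneric("categorySizes", function(x) standardGeneric("categorySizes"))

#' @rdname category-accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' Score accessors
#'
#' @param x a \linkS4class{GeneScoreTable}.
#' @name score-accessors
NULL

#' @rdname score-accessors
#' @export
setGeneric("geneScores", function(x) standardGeneric("geneScores"))

#' Ensemble accessors
#'
#' \code{ensembleMaps} returns the region x n_null surrogate matrix,
#' \code{ensembleSpec} its generator specification.
#'
#' @param x a \linkS4class{NullPhenotypeEnsemble}.
#' @name ensemble-accessors
NULL

#' @rdname ensemble-accessors
#' @export
setGeneric("ensembleMaps", function(x) standardGeneric("ensembleMaps"))

#' @rdname ensemble-accessors
#' @export
setGeneric("ensembleSpec", function(x) standardGeneric("ensembleSpec"))

#' Null-bank accessors
#'
#' @param x a \linkS4class{CategoryNullBank}.
#' @name nullbank-accessors
NULL

#' @rdname nullbank-accessors
#' @export
setGeneric("nullParameters", function(x) standardGeneric("nullParameters"))

#' @rdname nullbank-accessors
#' @export
setGeneric("nullKind", function(x) standardGeneric("nullKind"))

#' Fit accessors
#'
#' \code{decayLength} extracts the fitted length scale \eqn{\lambda} (mm);
#' \code{fitR2} the exponential goodness of fit.
#'
#' @param x an \linkS4class{ExpDecayFit}.
#' @name fit-accessors
NULL

#' @rdname fit-accessors
#' @export
setGeneric("decayLength", function(x) standardGeneric("decayLength"))

#' @rdname fit-accessors
#' @export
setGeneric("fitR2", function(x) standardGeneric("fitR2"))
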