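#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges CharacterList
#' @importClassesFrom IRanges CharacterList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData colData<-
#' @importFrom stats rnorm runif pnorm p.adjust cor sd var dist median quantile setNames wilcox.test na.omit
#' @importFrom utils head
NULL

#' ExpressionAtlas: a region x gene expression matrix with spatial metadata
#'
#' Thin extension of \linkS4class{SummarizedExperiment} holding normalized
#' expression values for a set of brain regions. Internally the assay is
#' stored gene x region (features x samples, the SummarizedExperiment
#' convention); user-facing accessors present the matrix in the
#' region x gene orientation used throughout the enrichment pipeline.
#' Region centroid coordinates (mm) and an optional two-level region class
#' (e.g. cortex / non-cortex) live in \code{colData}.
#'
#' @slot .. inherits all slots from SummarizedExperiment.
#' @seealso [ExpressionAtlas()], [exprValues()], [regionCoords()]
#' @export
setClass("ExpressionAtlas", contains = "SummarizedExperiment")

setValidity("ExpressionAtlas", function(object) {
    msg <- character()
    if (is.null(rownames(object)) || is.null(colnames(object)))
        msg <- c(msg, "gene and region identifiers are required (dimnames)")
    if (!is.null(colnames(object)) && anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate region identifiers")
    if (!is.null(rownames(object)) && anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene identifiers")
    cd <- SummarizedExperiment::colData(object)
    if (all(c("x", "y", "z") %in% colnames(cd))) {
        if (any(!vapply(as.list(cd[, c("x", "y", "z")]), is.numeric,
                        logical(1L))))
            msg <- c(msg, "coordinates must be numeric")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionAtlas
#'
#' @param values numeric region x gene matrix with region ids as rownames and
#'   gene ids as colnames; missing entries as \code{NA}.
#' @param coordinates optional region x 3 numeric matrix of centroid
#'   coordinates (mm), rows aligned to (or named by) the regions.
#' @param regionClass optional character/factor label per region, e.g.
#'   \code{"cortex"} / \code{"non-cortex"}.
#' @return An \linkS4class{ExpressionAtlas}.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(paste0("R", 1:3), paste0("g", 1:2)))
#' ExpressionAtlas(m)
#' @export
ExpressionAtlas <- function(values, coordinates = NULL, regionClass = NULL) {
    values <- as.matrix(values)
    if (is.null(rownames(values)) || is.null(colnames(values)))
        stop("'values' needs region rownames and gene colnames")
    storage.mode(values) <- "double"
    cd <- S4Vectors::DataFrame(row.names = rownames(values))
    if (!is.null(coordinates)) {
        coordinates <- as.matrix(coordinates)
        if (nrow(coordinates) != nrow(values))
            stop("'coordinates' must have one row per region")
        if (ncol(coordinates) != 3L)
            stop("'coordinates' must have three columns (x, y, z in mm)")
        if (!is.null(rownames(coordinates))) {
            if (!setequal(rownames(coordinates), rownames(values)))
                stop("coordinate region ids do not match the expression matrix")
            coordinates <- coordinates[rownames(values), , drop = FALSE]
        }
        cd$x <- coordinates[, 1L]
        cd$y <- coordinates[, 2L]
        cd$z <- coordinates[, 3L]
    }
    if (!is.null(regionClass)) {
        if (length(regionClass) != nrow(values))
            stop("'regionClass' must have one label per region")
        cd$region_class <- as.character(regionClass)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(expr = t(values)), colData = cd)
    new("ExpressionAtlas", se)
}

#' PhenotypeMap: one value per brain region
#'
#' A spatial brain phenotype (SBP): a single real value assigned to each
#' region of an atlas (cell density, connectivity degree, ...). Units are
#' arbitrary; enrichment only uses spatial correlations.
#'
#' @slot regionIds character region identifiers.
#' @slot values numeric phenotype values, parallel to \code{regionIds}.
#' @export
setClass("PhenotypeMap",
         representation(regionIds = "character", values = "numeric"))

setValidity("PhenotypeMap", function(object) {
    if (length(object@regionIds) != length(object@values))
        return("regionIds and values lengths differ")
    if (anyDuplicated(object@regionIds))
        return("duplicate region identifiers")
    TRUE
})

#' @param regionIds character region ids, or a named numeric vector when
#'   \code{values} is missing.
#' @param values numeric phenotype values.
#' @rdname PhenotypeMap-class
#' @export
PhenotypeMap <- function(regionIds, values) {
    if (missing(values)) {
        values <- unname(regionIds)
        regionIds <- names(regionIds)
        if (is.null(regionIds))
            stop("a single-argument call requires a named numeric vector")
    }
    new("PhenotypeMap", regionIds = as.character(regionIds),
        values = as.numeric(values))
}

setMethod("show", "PhenotypeMap", function(object) {
    cat("PhenotypeMap with", length(object@regionIds), "regions\n")
    n <- min(5L, length(object@values))
    if (n > 0L)
        cat("  ", paste(sprintf("%s=%.3g", object@regionIds[seq_len(n)],
                                object@values[seq_len(n)]),
                        collapse = ", "),
            if (length(object@values) > n) "..." else "", "\n")
})

#' DistanceMatrix: symmetric region x region Euclidean distances (mm)
#'
#' @slot regionIds character region identifiers.
#' @slot d symmetric nonnegative numeric matrix with zero diagonal.
#' @export
setClass("DistanceMatrix",
         representation(regionIds = "character", d = "matrix"))

setValidity("DistanceMatrix", function(object) {
    d <- object@d
    msg <- character()
    if (nrow(d) != length(object@regionIds) || ncol(d) != nrow(d))
        msg <- c(msg, "distance matrix dimensions do not match regionIds")
    else {
        if (any(abs(diag(d)) > 1e-12)) msg <- c(msg, "diagonal must be zero")
        if (any(d < 0)) msg <- c(msg, "distances must be nonnegative")
        if (max(abs(d - t(d))) > 1e-8) msg <- c(msg, "matrix must be symmetric")
    }
    if (length(msg)) msg else TRUE
})

#' @param regionIds character region ids.
#' @param d numeric symmetric distance matrix (mm).
#' @rdname DistanceMatrix-class
#' @export
DistanceMatrix <- function(regionIds, d) {
    d <- as.matrix(d)
    dimnames(d) <- list(regionIds, regionIds)
    new("DistanceMatrix", regionIds = as.character(regionIds), d = d)
}

setMethod("show", "DistanceMatrix", function(object) {
    cat("DistanceMatrix:", length(object@regionIds), "regions, range [",
        sprintf("%.3g, %.3g", min(object@d), max(object@d)), "] mm\n")
})

#' OntologyGraph: GO terms and their is_a hierarchy
#'
#' Directed child-to-parent structure parsed from an OBO file. Obsolete
#' terms are retained but flagged and never traversed during annotation
#' propagation.
#'
#' @slot terms data.frame with columns term_id, name, namespace, obsolete.
#' @slot edges data.frame with columns child, parent, relation (only
#'   \code{is_a} edges are created by [parseOBO()] unless part_of capture is
#'   requested).
#' @export
setClass("OntologyGraph",
         representation(terms = "data.frame", edges = "data.frame"))

setValidity("OntologyGraph", function(object) {
    msg <- character()
    if (anyDuplicated(object@terms$term_id))
        msg <- c(msg, "duplicate term ids")
    known <- object@terms$term_id
    if (nrow(object@edges) &&
        !all(c(object@edges$child, object@edges$parent) %in% known))
        msg <- c(msg, "edge endpoint not present in terms")
    if (length(msg)) msg else TRUE
})

setMethod("show", "OntologyGraph", function(object) {
    cat("OntologyGraph:", nrow(object@terms), "terms (",
        sum(object@terms$obsolete), "obsolete ),",
        nrow(object@edges), "edges\n")
})

#' AnnotationSet: gene-to-term annotations
#'
#' Annotation records after exclusion filtering (rows whose qualifier
#' contains NOT, or whose evidence code is ND, are never admitted).
#'
#' @slot annotations data.frame with columns gene_id, term_id, qualifier,
#'   evidence, aspect.
#' @export
setClass("AnnotationSet", representation(annotations = "data.frame"))

setValidity("AnnotationSet", function(object) {
    a <- object@annotations
    need <- c("gene_id", "term_id", "qualifier", "evidence", "aspect")
    if (!all(need %in% colnames(a)))
        return(paste("annotations must have columns",
                     paste(need, collapse = ", ")))
    if (any(grepl("NOT", a$qualifier, fixed = TRUE)))
        return("NOT-qualified annotations are not allowed")
    if (any(a$evidence == "ND"))
        return("ND-evidence annotations are not allowed")
    TRUE
})

setMethod("show", "AnnotationSet", function(object) {
    cat("AnnotationSet:", nrow(object@annotations), "annotations,",
        length(unique(object@annotations$gene_id)), "genes,",
        length(unique(object@annotations$term_id)), "terms\n")
})

#' CategoryTable: gene-category definitions for enrichment
#'
#' Propagated, universe-intersected gene sets. Category size \eqn{s} is
#' always the number of member genes after intersection with the measured
#' gene universe, i.e. the size of the resampling pool the null models see.
#'
#' @slot categoryId character category accessions (unique).
#' @slot categoryName character display names, parallel to categoryId.
#' @slot genes a \link[IRanges]{CharacterList} of member gene ids.
#' @export
setClass("CategoryTable",
         representation(categoryId = "character", categoryName = "character",
                        genes = "CharacterList"))

setValidity("CategoryTable", function(object) {
    msg <- character()
    n <- length(object@categoryId)
    if (length(object@categoryName) != n || length(object@genes) != n)
        msg <- c(msg, "slot lengths differ")
    if (anyDuplicated(object@categoryId))
        msg <- c(msg, "duplicate category ids")
    if (n && any(vapply(object@genes, anyDuplicated, integer(1L)) > 0L))
        msg <- c(msg, "duplicate gene ids within a category")
    if (length(msg)) msg else TRUE
})

#' @param categoryId character accessions.
#' @param categoryName character names (defaults to the accessions).
#' @param genes list (or CharacterList) of member gene-id vectors.
#' @rdname CategoryTable-class
#' @export
CategoryTable <- function(categoryId, genes, categoryName = categoryId) {
    genes <- IRanges::CharacterList(lapply(genes, function(g)
        unique(as.character(g))))
    names(genes) <- categoryId
    new("CategoryTable", categoryId = as.character(categoryId),
        categoryName = as.character(categoryName), genes = genes)
}

setMethod("show", "CategoryTable", function(object) {
    s <- lengths(object@genes)
    cat("CategoryTable:", length(object@categoryId), "categories")
    if (length(s))
        cat(", sizes", min(s), "-", max(s))
    cat("\n")
})

setMethod("length", "CategoryTable", function(x) length(x@categoryId))

setMethod("names", "CategoryTable", function(x) x@categoryId)

setMethod("[", "CategoryTable", function(x, i, j, ..., drop = TRUE) {
    if (is.character(i)) i <- match(i, x@categoryId)
    new("CategoryTable", categoryId = x@categoryId[i],
        categoryName = x@categoryName[i], genes = x@genes[i])
})

#' @export
#' @method as.data.frame CategoryTable
as.data.frame.CategoryTable <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
    data.frame(category_id = x@categoryId, name = x@categoryName,
               size = unname(lengths(x@genes)), stringsAsFactors = FALSE)
}

#' GeneScoreTable: one spatial correlation score per gene
#'
#' @slot geneIds character gene identifiers.
#' @slot scores numeric correlation of each gene's expression pattern with
#'   the phenotype (in [-1, 1]).
#' @slot nUsed integer number of complete region pairs used per gene.
#' @slot method "pearson" or "spearman".
#' @export
setClass("GeneScoreTable",
         representation(geneIds = "character", scores = "numeric",
                        nUsed = "integer", method = "character"))

setValidity("GeneScoreTable", function(object) {
    msg <- character()
    n <- length(object@geneIds)
    if (length(object@scores) != n || length(object@nUsed) != n)
        msg <- c(msg, "slot lengths differ")
    if (n && (min(object@scores) < -1 - 1e-8 || max(object@scores) > 1 + 1e-8))
        msg <- c(msg, "scores must lie in [-1, 1]")
    if (n && min(object@nUsed) < 3L)
        msg <- c(msg, "retained genes need >= 3 complete observations")
    if (!object@method %in% c("pearson", "spearman"))
        msg <- c(msg, "method must be pearson or spearman")
    if (length(msg)) msg else TRUE
})

setMethod("show", "GeneScoreTable", function(object) {
    cat("GeneScoreTable:", length(object@geneIds), "genes (",
        object@method, "), score range [",
        sprintf("%.3f, %.3f", min(object@scores), max(object@scores)), "]\n")
})

setMethod("length", "GeneScoreTable", function(x) length(x@geneIds))

#' NullPhenotypeEnsemble: a bank of surrogate phenotype maps
#'
#' Each column is one surrogate map, standardized to zero mean and unit
#' variance across regions. The generator specification (kind, parameters,
#' seed) is carried along so any ensemble can be regenerated bit-identically.
#'
#' @slot regionIds character region ids (rows of \code{maps}).
#' @slot maps numeric region x n_null matrix.
#' @slot spec list with elements kind ("random" or "spatial_lag"), nNull,
#'   seed and, for spatial_lag, rho and d0.
#' @export
setClass("NullPhenotypeEnsemble",
         representation(regionIds = "character", maps = "matrix",
                        spec = "list"))

setValidity("NullPhenotypeEnsemble", function(object) {
    msg <- character()
    if (nrow(object@maps) != length(object@regionIds))
        msg <- c(msg, "maps must have one row per region")
    if (!object@spec$kind %in% c("random", "spatial_lag"))
        msg <- c(msg, "spec$kind must be random or spatial_lag")
    if (length(msg)) msg else TRUE
})

setMethod("show", "NullPhenotypeEnsemble", function(object) {
    cat("NullPhenotypeEnsemble:", ncol(object@maps), "maps x",
        nrow(object@maps), "regions, kind =", object@spec$kind)
    if (object@spec$kind == "spatial_lag")
        cat(sprintf(" (rho = %.3g, d0 = %.3g mm)",
                    object@spec$rho, object@spec$d0))
    cat(", seed =", object@spec$seed, "\n")
})

#' CategoryNullBank: fitted Gaussian null models for category scores
#'
#' For the random-gene null the bank is keyed by category size \eqn{s}; for
#' ensemble nulls it is keyed by category id. The gene-scoring configuration
#' used to build the bank is recorded and enforced at evaluation time.
#'
#' @slot table data.frame with columns key, size, mu, sigma, n.
#' @slot nullKind one of "random_gene", "ensemble_random",
#'   "ensemble_spatial_lag".
#' @slot keyedBy "size" or "category".
#' @slot scoreConfig list(method, transform).
#' @slot samples optional matrix of raw null samples (one row per key) for
#'   empirical p-value estimation; may be a 0 x 0 matrix when not kept.
#' @export
setClass("CategoryNullBank",
         representation(table = "data.frame", nullKind = "character",
                        keyedBy = "character", scoreConfig = "list",
                        samples = "matrix"))

setValidity("CategoryNullBank", function(object) {
    msg <- character()
    need <- c("key", "size", "mu", "sigma", "n")
    if (!all(need %in% colnames(object@table)))
        msg <- c(msg, paste("table must have columns",
                            paste(need, collapse = ", ")))
    else if (nrow(object@table) && any(object@table$sigma <= 0))
        msg <- c(msg, "all null standard deviations must be positive")
    if (!object@keyedBy %in% c("size", "category"))
        msg <- c(msg, "keyedBy must be size or category")
    if (length(msg)) msg else TRUE
})

setMethod("show", "CategoryNullBank", function(object) {
    cat("CategoryNullBank (", object@nullKind, "): ", nrow(object@table),
        " entries keyed by ", object@keyedBy, ", n = ",
        if (nrow(object@table)) max(object@table$n) else 0L,
        " null samples each\n  scoring: ", object@scoreConfig$method, " / ",
        object@scoreConfig$transform,
        if (nrow(object@samples)) "; raw samples retained" else "",
        "\n", sep = "")
})

#' ExpDecayFit: three-parameter exponential fit of CGE against distance
#'
#' Model: \eqn{CGE(d) = A \exp(-d/\lambda) + B}. \code{r2} is
#' \eqn{1 - SS_{res}/SS_{tot}}; \code{altSpearman} is \eqn{-\rho} of the
#' Spearman correlation between CGE and distance, a fit-free alternative
#' statistic.
#'
#' @slot A,lambda,B fitted parameters (lambda in mm, > 0).
#' @slot r2 goodness of fit.
#' @slot altSpearman numeric, minus the Spearman correlation of y with d.
#' @slot converged logical convergence flag from the optimizer.
#' @slot n number of (d, y) pairs used.
#' @export
setClass("ExpDecayFit",
         representation(A = "numeric", lambda = "numeric", B = "numeric",
                        r2 = "numeric", altSpearman = "numeric",
                        converged = "logical", n = "integer"))

setValidity("ExpDecayFit", function(object) {
    if (length(object@lambda) == 1L && is.finite(object@lambda) &&
        object@lambda <= 0)
        return("lambda must be positive")
    TRUE
})

setMethod("show", "ExpDecayFit", function(object) {
    cat(sprintf(
        "ExpDecayFit: A = %.4g, lambda = %.4g mm, B = %.4g, R2 = %.4f%s\n",
        object@A, object@lambda, object@B, object@r2,
        if (!object@converged) " (NOT converged)" else ""))
})
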