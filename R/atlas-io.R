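#' @include AllClasses.R
NULL

.readDelim <- function(path) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    dt <- data.table::fread(path, sep = sep, header = TRUE,
                            data.table = FALSE, na.strings = c("", "NA"),
                            fill = FALSE, check.names = FALSE)
    dt
}

#' Load a region x gene expression matrix
#'
#' Expected layout: first column region identifier, header row gene
#' identifiers, one row per region; empty cells are treated as missing.
#' Identifier order is preserved as in the file.
#'
#' @param path TSV (or CSV, by extension) file path.
#' @param coordinates optional path to a region coordinate table with
#'   columns region id, x, y, z (mm), or a region x 3 matrix.
#' @return An \linkS4class{ExpressionAtlas}.
#' @export
loadExpression <- function(path, coordinates = NULL) {
    df <- .readDelim(path)
    if (ncol(df) < 2L) stop("expression file needs an id column and genes")
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids)) stop("duplicate region identifiers in ", path)
    genes <- colnames(df)[-1L]
    if (anyDuplicated(genes)) stop("duplicate gene identifiers in ", path)
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    if (!is.null(coordinates) && is.character(coordinates))
        coordinates <- loadCoordinates(coordinates)
    ExpressionAtlas(m, coordinates = coordinates)
}

#' @rdname loadExpression
#' @param atlas an \linkS4class{ExpressionAtlas} to serialize.
#' @export
writeExpression <- function(atlas, path) {
    m <- exprValues(atlas)
    df <- data.frame(region_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    data.table::fwrite(df, path, sep = "\t", na = "", quote = FALSE)
    invisible(path)
}

#' Load region centroid coordinates
#'
#' @param path TSV with columns region id, x, y, z (header required).
#' @return A numeric region x 3 matrix with region-id rownames.
#' @export
loadCoordinates <- function(path) {
    df <- .readDelim(path)
    if (ncol(df) < 4L) stop("coordinate file needs id, x, y, z columns")
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids)) stop("duplicate region identifiers in ", path)
    m <- as.matrix(df[, 2:4])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    colnames(m) <- c("x", "y", "z")
    m
}

#' Load / write a phenotype map
#'
#' A phenotype file is a two-column TSV (region id, value) with a header.
#'
#' @param path file path.
#' @return \code{loadPhenotype} returns a \linkS4class{PhenotypeMap}.
#' @export
loadPhenotype <- function(path) {
    df <- .readDelim(path)
    if (ncol(df) < 2L) stop("phenotype file needs id and value columns")
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids)) stop("duplicate region identifiers in ", path)
    PhenotypeMap(regionIds = ids, values = as.numeric(df[[2L]]))
}

#' @rdname loadPhenotype
#' @param phenotype a \linkS4class{PhenotypeMap} to serialize.
#' @export
writePhenotype <- function(phenotype, path) {
    data.table::fwrite(data.frame(region_id = phenotype@regionIds,
                                  value = phenotype@values),
                       path, sep = "\t", quote = FALSE)
    invisible(path)
}

#' Apply the 50\% quality threshold filter
#'
#' Removes genes with data in fewer than \code{geneThreshold} of regions,
#' \emph{then} removes regions with data in fewer than
#' \code{regionThreshold} of the remaining genes. The gene filter runs first;
#' with incomplete data the order changes the result.
#'
#' @param atlas an \linkS4class{ExpressionAtlas}.
#' @param geneThreshold,regionThreshold minimum fraction of non-missing
#'   entries required to keep a gene / region (defaults 0.5).
#' @return The filtered \linkS4class{ExpressionAtlas}.
#' @export
applyQualityFilter <- function(atlas, geneThreshold = 0.5,
                               regionThreshold = 0.5) {
    stopifnot(is(atlas, "ExpressionAtlas"),
              geneThreshold >= 0, geneThreshold <= 1,
              regionThreshold >= 0, regionThreshold <= 1)
    m <- exprValues(atlas)                       # region x gene
    okGene <- colMeans(!is.na(m)) >= geneThreshold
    if (!any(okGene)) stop("quality filter removed all genes")
    m <- m[, okGene, drop = FALSE]
    okRegion <- rowMeans(!is.na(m)) >= regionThreshold
    if (!any(okRegion)) stop("quality filter removed all regions")
    m <- m[okRegion, , drop = FALSE]
    co <- regionCoords(atlas)
    rc <- regionClass(atlas)
    ExpressionAtlas(m,
        coordinates = if (!is.null(co)) co[okRegion, , drop = FALSE],
        regionClass = if (!is.null(rc)) rc[okRegion])
}

#' Euclidean distance matrix between region centroids
#'
#' @param atlas an \linkS4class{ExpressionAtlas} with coordinates.
#' @return A \linkS4class{DistanceMatrix} (mm).
#' @export
computeDistanceMatrix <- function(atlas) {
    co <- regionCoords(atlas)
    if (is.null(co)) stop("atlas has no region coordinates")
    d <- as.matrix(stats::dist(co))
    if (any(d[upper.tri(d)] == 0))
        warning("regions with identical coordinates (zero distance)")
    DistanceMatrix(regionIds = rownames(co), d = d)
}

#' Load / write a distance matrix
#'
#' TSV layout: header of region ids, first column region ids, symmetric
#' numeric body (mm).
#'
#' @param path file path.
#' @export
loadDistanceMatrix <- function(path) {
    df <- .readDelim(path)
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    if (!identical(colnames(m), ids))
        stop("distance matrix header does not match its id column")
    DistanceMatrix(regionIds = ids, d = m)
}

#' @rdname loadDistanceMatrix
#' @param distances a \linkS4class{DistanceMatrix}.
#' @export
writeDistanceMatrix <- function(distances, path) {
    d <- distances@d
    df <- data.frame(region_id = distances@regionIds, d,
                     check.names = FALSE)
    colnames(df) <- c("region_id", distances@regionIds)
    data.table::fwrite(df, path, sep = "\t", quote = FALSE)
    invisible(path)
}

# align a phenotype to an atlas by region id; >= 3 finite overlaps required
.alignPhenotype <- function(atlas, phenotype) {
    stopifnot(is(atlas, "ExpressionAtlas"), is(phenotype, "PhenotypeMap"))
    common <- intersect(regionIds(atlas), phenotype@regionIds)
    v <- phenotypeValues(phenotype)[common]
    common <- common[is.finite(v)]
    if (length(common) < 3L)
        stop("fewer than 3 atlas regions with finite phenotype values")
    list(regions = common, values = phenotypeValues(phenotype)[common])
}

#' Write an enrichment result table with its JSON run record
#'
#' Writes the full result table as TSV (columns category_id, name, size,
#' score, p, q, null_kind), sorted by increasing p, plus a JSON sidecar
#' (\code{<path>.json}) holding the complete run configuration, including
#' seeds, so the run can be reproduced exactly.
#'
#' @param results a data.frame as returned by [runGCEA()].
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeEnrichmentTable <- function(results, path) {
    need <- c("category_id", "name", "size", "score", "p", "q", "null_kind")
    if (!all(need %in% colnames(results)))
        stop("results must have columns ", paste(need, collapse = ", "))
    out <- results[order(results$p), need, drop = FALSE]
    data.table::fwrite(out, path, sep = "\t", quote = FALSE)
    cfg <- attr(results, "config")
    if (!is.null(cfg))
        writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, pretty = TRUE,
                                    digits = NA, null = "null"),
                   paste0(path, ".json"))
    invisible(path)
}

#' @rdname writeEnrichmentTable
#' @export
readEnrichmentTable <- function(path) {
    df <- data.table::fread(path, sep = "\t", data.table = FALSE)
    cfgPath <- paste0(path, ".json")
    if (file.exists(cfgPath))
        attr(df, "config") <- jsonlite::fromJSON(cfgPath,
                                                 simplifyVector = TRUE)
    df
}
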