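#' @include AllClasses.R
NULL

#' Parse a Gene Ontology structure file (OBO 1.2)
#'
#' Reads \code{[Term]} stanzas and extracts, for each term, its accession,
#' name, namespace and obsolescence flag, together with the directed
#' child-to-parent \code{is_a} edges that define the hierarchy used for
#' annotation propagation. Other relationship types (\code{part_of},
#' \code{regulates}, ...) are ignored by default: only \code{is_a} is treated
#' as a parent-child relationship. \code{part_of} capture can be switched on,
#' in which case those edges are recorded with relation \code{"part_of"}.
#'
#' Edges whose endpoints are obsolete terms are dropped (obsolete terms are
#' kept in the term table, flagged, so annotations to them can be reported).
#' The resulting \code{is_a} graph must be acyclic.
#'
#' @param path path to an OBO 1.2 file.
#' @param includePartOf logical; also record \code{part_of} edges
#'   (default \code{FALSE}).
#' @return An \linkS4class{OntologyGraph}.
#' @export
parseOBO <- function(path, includePartOf = FALSE) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    in_term <- FALSE
    cur <- NULL
    terms <- list()
    edges <- list()
    flush_term <- function(cur) {
        if (is.null(cur$id))
            stop("malformed stanza ending near line ", cur$start,
                 ": missing id")
        terms[[length(terms) + 1L]] <<- data.frame(
            term_id = cur$id,
            name = if (is.null(cur$name)) cur$id else cur$name,
            namespace = if (is.null(cur$namespace)) NA_character_
                        else cur$namespace,
            obsolete = isTRUE(cur$obsolete), stringsAsFactors = FALSE)
        for (p in cur$isa)
            edges[[length(edges) + 1L]] <<- c(cur$id, p, "is_a")
        if (includePartOf)
            for (p in cur$partof)
                edges[[length(edges) + 1L]] <<- c(cur$id, p, "part_of")
    }
    for (i in seq_along(lines)) {
        ln <- sub("\\s*!.*$", "", lines[i])   # trailing comments
        ln <- trimws(ln)
        if (ln == "") next
        if (grepl("^\\[", ln)) {
            if (in_term) flush_term(cur)
            in_term <- identical(ln, "[Term]")
            cur <- list(start = i, isa = character(), partof = character())
            next
        }
        if (!in_term) next
        m <- regmatches(ln, regexec("^([A-Za-z_]+):\\s*(.*)$", ln))[[1L]]
        if (length(m) < 3L)
            stop("malformed stanza at line ", i, ": '", lines[i], "'")
        key <- m[2L]; val <- m[3L]
        if (key == "id") cur$id <- val
        else if (key == "name") cur$name <- val
        else if (key == "namespace") cur$namespace <- val
        else if (key == "is_obsolete") cur$obsolete <- identical(val, "true")
        else if (key == "is_a") cur$isa <- c(cur$isa, trimws(val))
        else if (key == "relationship") {
            rel <- strsplit(trimws(val), "\\s+")[[1L]]
            if (length(rel) >= 2L && rel[1L] == "part_of")
                cur$partof <- c(cur$partof, rel[2L])
        }
    }
    if (in_term) flush_term(cur)
    terms <- do.call(rbind, terms)
    if (is.null(terms)) stop("no [Term] stanzas found in ", path)
    if (anyDuplicated(terms$term_id))
        stop("duplicate term ids in ", path)
    if (length(edges)) {
        edges <- as.data.frame(do.call(rbind, edges),
                               stringsAsFactors = FALSE)
        colnames(edges) <- c("child", "parent", "relation")
        known <- terms$term_id
        bad <- !(edges$parent %in% known)
        if (any(bad)) {
            warning(sum(bad), " edge(s) to terms absent from the file; ",
                    "dropped")
            edges <- edges[!bad, , drop = FALSE]
        }
        obs <- terms$term_id[terms$obsolete]
        edges <- edges[!(edges$child %in% obs | edges$parent %in% obs),
                       , drop = FALSE]
        isa <- edges[edges$relation == "is_a", , drop = FALSE]
        if (nrow(isa)) {
            g <- igraph::graph_from_data_frame(isa[, c("child", "parent")],
                                               directed = TRUE)
            if (!igraph::is_dag(g))
                stop("cyclic is_a graph in ", path)
        }
    } else {
        edges <- data.frame(child = character(), parent = character(),
                            relation = character(), stringsAsFactors = FALSE)
    }
    rownames(edges) <- NULL
    new("OntologyGraph", terms = terms, edges = edges)
}

#' Parse a GO annotation file (GAF 2.x)
#'
#' Reads a 17-column tab-separated GAF file ('!' comment lines skipped) and
#' returns the gene-to-term annotation records, excluding NOT-qualified
#' annotations and annotations with the ND (no biological data) evidence
#' code. The number of excluded rows is reported via \code{message()}.
#'
#' @param path path to a GAF 2.1/2.2 file.
#' @param geneIdColumn which GAF field identifies the gene: \code{"id"}
#'   (column 2, the DB object id, e.g. an MGI accession) or \code{"symbol"}
#'   (column 3, the gene symbol, as used for human annotations).
#' @return An \linkS4class{AnnotationSet}.
#' @export
parseGAF <- function(path, geneIdColumn = c("id", "symbol")) {
    geneIdColumn <- match.arg(geneIdColumn)
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    keep <- !startsWith(lines, "!") & nzchar(lines)
    body <- lines[keep]
    if (!length(body)) {
        message("parseGAF: no annotation rows in ", path)
        return(new("AnnotationSet", annotations = data.frame(
            gene_id = character(), term_id = character(),
            qualifier = character(), evidence = character(),
            aspect = character(), stringsAsFactors = FALSE)))
    }
    # sentinel guards against strsplit dropping trailing empty fields
    fields <- strsplit(paste0(body, "\t\x1e"), "\t", fixed = TRUE)
    nf <- lengths(fields) - 1L
    if (any(nf != 17L)) {
        bad <- which(keep)[which(nf != 17L)[1L]]
        stop("GAF row at line ", bad, " has ", nf[which(nf != 17L)[1L]],
             " columns (expected 17)")
    }
    m <- do.call(rbind, fields)
    ann <- data.frame(gene_id = if (geneIdColumn == "id") m[, 2L] else m[, 3L],
                      term_id = m[, 5L], qualifier = m[, 4L],
                      evidence = m[, 7L], aspect = m[, 9L],
                      stringsAsFactors = FALSE)
    isNot <- grepl("NOT", ann$qualifier, fixed = TRUE)
    isND <- ann$evidence == "ND"
    if (any(isNot | isND))
        message("parseGAF: excluded ", sum(isNot), " NOT-qualified and ",
                sum(isND & !isNot), " ND-evidence annotation(s)")
    ann <- ann[!(isNot | isND), , drop = FALSE]
    rownames(ann) <- NULL
    new("AnnotationSet", annotations = ann)
}

# transitive is_a ancestors (term itself excluded) for each requested term
.ancestorSets <- function(graph, termIds) {
    isa <- graph@edges[graph@edges$relation == "is_a", , drop = FALSE]
    if (!nrow(isa))
        return(stats::setNames(rep(list(character()), length(termIds)),
                               termIds))
    g <- igraph::graph_from_data_frame(
        isa[, c("child", "parent")], directed = TRUE,
        vertices = data.frame(name = graph@terms$term_id))
    out <- lapply(termIds, function(t) {
        anc <- igraph::subcomponent(g, t, mode = "out")$name
        setdiff(anc, t)
    })
    stats::setNames(out, termIds)
}

#' Propagate annotations up the is_a hierarchy
#'
#' Adds, for each (gene, term) record, one record per transitive \code{is_a}
#' ancestor of the term, then deduplicates, producing the fully propagated
#' annotation set. Ancestors reachable along multiple paths (diamonds)
#' contribute a single record. Annotations to terms missing from the graph
#' are dropped with a warning; annotations to obsolete terms are dropped
#' likewise (obsolete terms take no part in propagation).
#'
#' @param graph an \linkS4class{OntologyGraph}.
#' @param annotations an \linkS4class{AnnotationSet}.
#' @return A fully propagated \linkS4class{AnnotationSet}; records created
#'   by propagation inherit the originating record's
#'   qualifier/evidence/aspect.
#' @export
propagateAnnotations <- function(graph, annotations) {
    stopifnot(is(graph, "OntologyGraph"), is(annotations, "AnnotationSet"))
    ann <- annotations@annotations
    if (!nrow(ann)) return(annotations)
    live <- graph@terms$term_id[!graph@terms$obsolete]
    unknown <- !(ann$term_id %in% live)
    if (any(unknown)) {
        warning("propagateAnnotations: dropped ", sum(unknown),
                " annotation(s) to unknown or obsolete terms")
        ann <- ann[!unknown, , drop = FALSE]
        if (!nrow(ann)) return(new("AnnotationSet", annotations = ann))
    }
    anc <- .ancestorSets(graph, unique(ann$term_id))
    reps <- lengths(anc[ann$term_id])
    extra <- ann[rep(seq_len(nrow(ann)), reps), , drop = FALSE]
    extra$term_id <- unlist(anc[ann$term_id], use.names = FALSE)
    out <- rbind(ann, extra)
    out <- out[!duplicated(out[, c("gene_id", "term_id")]), , drop = FALSE]
    out <- out[order(out$term_id, out$gene_id), , drop = FALSE]
    rownames(out) <- NULL
    new("AnnotationSet", annotations = out)
}

#' Build the filtered category table used for enrichment
#'
#' Turns a fully propagated annotation set into gene categories: optionally
#' maps gene identifiers through a static two-column join table, intersects
#' each category's gene set with the measured-gene universe, and then filters
#' by size. The size filter is applied \emph{after} universe intersection, so
#' a category's size \eqn{s} always equals the number of measured genes the
#' null models can resample.
#'
#' @param annotations a propagated \linkS4class{AnnotationSet}.
#' @param universe character vector of measured gene ids.
#' @param namespace GO namespace to keep; matched against the GAF aspect
#'   codes (P/F/C) or full namespace names. Default biological_process.
#'   Use \code{NA} to keep all namespaces.
#' @param sizeMin,sizeMax inclusive size bounds (default 10 and 200).
#' @param mapping optional two-column data.frame mapping annotation gene ids
#'   (first column) to universe ids (second column); duplicated source ids
#'   are an error, unmapped genes are dropped with a reported count.
#' @param graph optional \linkS4class{OntologyGraph} supplying category
#'   display names.
#' @return A \linkS4class{CategoryTable}.
#' @export
buildCategoryTable <- function(annotations, universe,
                               namespace = "biological_process",
                               sizeMin = 10L, sizeMax = 200L,
                               mapping = NULL, graph = NULL) {
    stopifnot(is(annotations, "AnnotationSet"))
    universe <- unique(as.character(universe))
    if (!length(universe)) stop("empty measured-gene universe")
    if (sizeMin < 1L || sizeMax < sizeMin)
        stop("invalid size bounds")
    ann <- annotations@annotations
    if (!is.na(namespace)) {
        aspect <- c(biological_process = "P", molecular_function = "F",
                    cellular_component = "C")
        want <- if (namespace %in% names(aspect)) aspect[[namespace]]
                else namespace
        ann <- ann[ann$aspect %in% c(want, namespace), , drop = FALSE]
    }
    if (!is.null(mapping)) {
        mapping <- as.data.frame(mapping)
        if (ncol(mapping) < 2L) stop("mapping must have two columns")
        if (anyDuplicated(mapping[[1L]]))
            stop("mapping has duplicate source ids")
        idx <- match(ann$gene_id, as.character(mapping[[1L]]))
        unmapped <- is.na(idx)
        if (any(unmapped))
            message("buildCategoryTable: dropped ", sum(unmapped),
                    " annotation(s) for unmapped genes")
        ann <- ann[!unmapped, , drop = FALSE]
        ann$gene_id <- as.character(mapping[[2L]])[idx[!unmapped]]
    }
    ann <- ann[ann$gene_id %in% universe, , drop = FALSE]
    sets <- split(ann$gene_id, ann$term_id)
    sets <- lapply(sets, function(g) sort(unique(g)))
    s <- lengths(sets)
    sets <- sets[s >= sizeMin & s <= sizeMax]
    ids <- sort(names(sets))
    sets <- sets[ids]
    nm <- ids
    if (!is.null(graph)) {
        hit <- match(ids, graph@terms$term_id)
        nm <- ifelse(is.na(hit), ids, graph@terms$name[hit])
    }
    CategoryTable(categoryId = ids, genes = sets, categoryName = nm)
}

#' Read and write category tables
#'
#' \code{writeCategoryTable} serializes a \linkS4class{CategoryTable} either
#' as JSON (array of objects with category_id, name, gene_ids) or in the GMT
#' tab-separated gene-set format (id, name, genes...). \code{readGMT} reads
#' the GMT form back.
#'
#' @param x a \linkS4class{CategoryTable}.
#' @param path output (input) file path.
#' @param format "json" or "gmt".
#' @return \code{writeCategoryTable} returns \code{path} invisibly;
#'   \code{readGMT} returns a \linkS4class{CategoryTable}.
#' @export
writeCategoryTable <- function(x, path, format = c("json", "gmt")) {
    format <- match.arg(format)
    stopifnot(is(x, "CategoryTable"))
    if (format == "json") {
        obj <- lapply(seq_along(x), function(i) list(
            category_id = x@categoryId[i], name = x@categoryName[i],
            gene_ids = as.character(x@genes[[i]])))
        writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE),
                   path)
    } else {
        lines <- vapply(seq_along(x), function(i) paste(
            c(x@categoryId[i], x@categoryName[i],
              as.character(x@genes[[i]])), collapse = "\t"), character(1L))
        writeLines(lines, path)
    }
    invisible(path)
}

#' @rdname writeCategoryTable
#' @export
readGMT <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < 3L))
        stop("GMT rows need at least id, name and one gene")
    CategoryTable(categoryId = vapply(fields, `[[`, character(1L), 1L),
                  genes = lapply(fields, function(f) f[-(1:2)]),
                  categoryName = vapply(fields, `[[`, character(1L), 2L))
}
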