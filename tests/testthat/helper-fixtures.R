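# shared fixture builders; everything is generated in code at test time

makeToyAtlas <- function(nRegions = 20L, nGenes = 30L, seed = 1L,
                         coordinates = TRUE, box = 20) {
    set.seed(seed)
    m <- matrix(rnorm(nRegions * nGenes), nRegions, nGenes,
                dimnames = list(sprintf("R%02d", seq_len(nRegions)),
                                sprintf("g%03d", seq_len(nGenes))))
    co <- if (coordinates)
        matrix(runif(nRegions * 3, 0, box), nRegions, 3,
               dimnames = list(rownames(m), c("x", "y", "z")))
    ExpressionAtlas(m, coordinates = co)
}

writeToyOBO <- function(lines, path = tempfile(fileext = ".obo")) {
    writeLines(lines, path)
    path
}

# three-term is_a chain: GO:3 is_a GO:2 is_a GO:1
oboChain3 <- function() c(
    "format-version: 1.2",
    "",
    "[Term]", "id: GO:0000001", "name: root",
    "namespace: biological_process",
    "",
    "[Term]", "id: GO:0000002", "name: mid",
    "namespace: biological_process", "is_a: GO:0000001 ! root",
    "",
    "[Term]", "id: GO:0000003", "name: leaf",
    "namespace: biological_process", "is_a: GO:0000002 ! mid")

# one 17-column GAF row
gafRow <- function(gene, term, qualifier = "", evidence = "IDA",
                   aspect = "P") {
    paste(c("DB", gene, toupper(gene), qualifier, term, "REF", evidence,
            "", aspect, "desc", "", "protein", "taxon:10090", "20190417",
            "DB", "", ""), collapse = "\t")
}

writeToyGAF <- function(rows, path = tempfile(fileext = ".gaf")) {
    writeLines(c("!gaf-version: 2.1", rows), path)
    path
}

makeAnnotationSet <- function(gene, term, aspect = "P") {
    new("AnnotationSet", annotations = data.frame(
        gene_id = gene, term_id = term, qualifier = "", evidence = "IDA",
        aspect = aspect, stringsAsFactors = FALSE))
}

# brute-force transitive reachability on an edge list (child -> parent):
# iterated relaxation, independent of the igraph-based implementation
bruteForceAncestors <- function(edges, term) {
    anc <- character()
    frontier <- term
    repeat {
        nxt <- unique(edges$parent[edges$child %in% frontier])
        nxt <- setdiff(nxt, c(anc, term))
        if (!length(nxt)) break
        anc <- c(anc, nxt)
        frontier <- nxt
    }
    sort(anc)
}

# random DAG over nTerms: edges only from higher to lower index
randomDagGraph <- function(nTerms, pEdge = 0.25, seed = 1L) {
    set.seed(seed)
    ids <- sprintf("GO:%07d", seq_len(nTerms))
    edges <- do.call(rbind, lapply(seq_len(nTerms), function(i) {
        parents <- which(runif(nTerms) < pEdge & seq_len(nTerms) < i)
        if (!length(parents)) return(NULL)
        data.frame(child = ids[i], parent = ids[parents],
                   relation = "is_a", stringsAsFactors = FALSE)
    }))
    if (is.null(edges))
        edges <- data.frame(child = character(), parent = character(),
                            relation = character())
    new("OntologyGraph",
        terms = data.frame(term_id = ids, name = ids,
                           namespace = "biological_process",
                           obsolete = FALSE, stringsAsFactors = FALSE),
        edges = edges)
}

expect_no_diff <- function(a, b, tol = 1e-12) {
    testthat::expect_lt(max(abs(a - b)), tol)
}
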