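test_that("parseOBO transcribes terms and is_a edges, ignoring part_of", {
    p <- writeToyOBO(oboChain3())
    g <- parseOBO(p)
    expect_s4_class(g, "OntologyGraph")
    expect_equal(nrow(g@terms), 3L)
    expect_equal(nrow(g@edges), 2L)
    expect_setequal(g@edges$child, c("GO:0000002", "GO:0000003"))

    # part_of-only relationship creates no is_a edge by default
    p2 <- writeToyOBO(c(
        "[Term]", "id: GO:0000010", "name: a",
        "",
        "[Term]", "id: GO:0000011", "name: b",
        "relationship: part_of GO:0000010"))
    g2 <- parseOBO(p2)
    expect_equal(nrow(g2@edges), 0L)
    g2b <- parseOBO(p2, includePartOf = TRUE)
    expect_equal(g2b@edges$relation, "part_of")
})

test_that("obsolete terms are flagged and excluded from the hierarchy", {
    p <- writeToyOBO(c(
        oboChain3(),
        "",
        "[Term]", "id: GO:0000004", "name: dead", "is_obsolete: true",
        "is_a: GO:0000001"))
    g <- parseOBO(p)
    expect_true(g@terms$obsolete[g@terms$term_id == "GO:0000004"])
    # obsolete term present but contributes no edges
    expect_false("GO:0000004" %in% g@edges$child)
    ann <- makeAnnotationSet("geneA", "GO:0000004")
    expect_warning(out <- propagateAnnotations(g, ann), "obsolete")
    expect_equal(nrow(out@annotations), 0L)
})

test_that("parseOBO rejects malformed stanzas and cyclic is_a graphs", {
    p <- writeToyOBO(c("[Term]", "id: GO:0000001", "not a field line"))
    expect_error(parseOBO(p), "line 3")
    p2 <- writeToyOBO(c(
        "[Term]", "id: GO:0000001", "is_a: GO:0000002",
        "",
        "[Term]", "id: GO:0000002", "is_a: GO:0000001"))
    expect_error(parseOBO(p2), "cyclic")
})

test_that("parseGAF excludes NOT and ND rows and keeps the rest", {
    p <- writeToyGAF(c(gafRow("g1", "GO:0000001"),
                       gafRow("g2", "GO:0000001", qualifier = "NOT"),
                       gafRow("g3", "GO:0000002")))
    expect_message(a <- parseGAF(p), "1 NOT")
    expect_equal(nrow(a@annotations), 2L)
    expect_setequal(a@annotations$gene_id, c("g1", "g3"))

    p2 <- writeToyGAF(gafRow("g1", "GO:0000001", evidence = "ND"))
    expect_message(a2 <- parseGAF(p2), "ND-evidence")
    expect_equal(nrow(a2@annotations), 0L)

    # header-only file is fine
    p3 <- writeToyGAF(character())
    expect_message(a3 <- parseGAF(p3), "no annotation rows")
    expect_equal(nrow(a3@annotations), 0L)

    # wrong column count is a parse error naming the row
    p4 <- tempfile(); writeLines(c("!gaf", "a\tb\tc"), p4)
    expect_error(parseGAF(p4), "line 2")
})

test_that("annotations propagate transitively and deduplicate", {
    g <- parseOBO(writeToyOBO(oboChain3()))
    ann <- makeAnnotationSet("geneA", "GO:0000003")
    out <- propagateAnnotations(g, ann)
    expect_setequal(out@annotations$term_id,
                    c("GO:0000001", "GO:0000002", "GO:0000003"))
    # annotating both a term and its ancestor stays one record per term
    ann2 <- makeAnnotationSet(c("geneA", "geneA"),
                              c("GO:0000003", "GO:0000002"))
    out2 <- propagateAnnotations(g, ann2)
    expect_equal(nrow(out2@annotations), 3L)
})

test_that("diamond hierarchies contribute each ancestor exactly once", {
    # L is_a M1, L is_a M2, M1 and M2 is_a R
    g <- new("OntologyGraph",
             terms = data.frame(term_id = c("GO:L", "GO:M1", "GO:M2",
                                            "GO:R"),
                                name = "t", namespace = "biological_process",
                                obsolete = FALSE, stringsAsFactors = FALSE),
             edges = data.frame(child = c("GO:L", "GO:L", "GO:M1", "GO:M2"),
                                parent = c("GO:M1", "GO:M2", "GO:R",
                                           "GO:R"),
                                relation = "is_a", stringsAsFactors = FALSE))
    out <- propagateAnnotations(g, makeAnnotationSet("geneA", "GO:L"))
    expect_equal(sum(out@annotations$term_id == "GO:R"), 1L)
    expect_equal(sort(out@annotations$term_id),
                 sort(c("GO:L", "GO:M1", "GO:M2", "GO:R")))
    expect_equal(bruteForceAncestors(g@edges, "GO:L"),
                 sort(c("GO:M1", "GO:M2", "GO:R")))
})

test_that("propagation matches brute-force reachability on random DAGs", {
    for (seed in 1:5) {
        g <- randomDagGraph(12L, pEdge = 0.3, seed = seed)
        leaf <- g@terms$term_id[nrow(g@terms)]
        out <- propagateAnnotations(g, makeAnnotationSet("geneA", leaf))
        expect_equal(sort(setdiff(out@annotations$term_id, leaf)),
                     bruteForceAncestors(g@edges, leaf),
                     info = paste("seed", seed))
    }
})

test_that("propagation closure: category gene sets are nested under is_a", {
    set.seed(42)
    g <- randomDagGraph(10L, pEdge = 0.35, seed = 7L)
    genes <- sprintf("gene%02d", 1:25)
    ann <- makeAnnotationSet(sample(genes, 60, replace = TRUE),
                             sample(g@terms$term_id, 60, replace = TRUE))
    ann@annotations <- unique(ann@annotations)
    out <- propagateAnnotations(g, ann)
    tab <- buildCategoryTable(out, universe = genes, sizeMin = 1L,
                              sizeMax = 1000L)
    sets <- as.list(geneSets(tab))
    for (i in seq_len(nrow(g@edges))) {
        ch <- g@edges$child[i]; pa <- g@edges$parent[i]
        if (!is.null(sets[[ch]]) && !is.null(sets[[pa]]))
            expect_true(all(sets[[ch]] %in% sets[[pa]]),
                        info = paste(ch, "->", pa))
    }
})

test_that("category sizes are computed after universe intersection", {
    ann <- makeAnnotationSet(sprintf("gene%02d", 1:12),
                             rep("GO:0000001", 12))
    # 12 annotated genes, 9 measured: excluded at bounds [10, 200]
    tab <- buildCategoryTable(ann, universe = sprintf("gene%02d", 1:9))
    expect_equal(length(tab), 0L)
    # with 10 measured genes the category enters at s = 10, not 12
    tab2 <- buildCategoryTable(ann, universe = sprintf("gene%02d", 1:10))
    expect_equal(unname(categorySizes(tab2)), 10L)
    # no filtering at bounds [1, Inf)
    tab3 <- buildCategoryTable(makeAnnotationSet("gene01", "GO:0000001"),
                               universe = "gene01", sizeMin = 1L,
                               sizeMax = .Machine$integer.max)
    expect_equal(unname(categorySizes(tab3)), 1L)
})

test_that("buildCategoryTable filters namespace, maps ids and validates", {
    ann <- new("AnnotationSet", annotations = data.frame(
        gene_id = c("a", "b", "c"), term_id = c("GO:1", "GO:1", "GO:2"),
        qualifier = "", evidence = "IDA", aspect = c("P", "P", "F"),
        stringsAsFactors = FALSE))
    tab <- buildCategoryTable(ann, universe = c("a", "b", "c"),
                              sizeMin = 1L, sizeMax = 10L)
    expect_equal(categoryIds(tab), "GO:1")   # F-aspect term filtered

    map <- data.frame(from = c("a", "b"), to = c("A", "B"))
    expect_message(
        tabm <- buildCategoryTable(ann, universe = c("A", "B"),
                                   sizeMin = 1L, sizeMax = 10L,
                                   mapping = map, namespace = NA),
        "unmapped")
    expect_setequal(unlist(geneSets(tabm)), c("A", "B"))

    badmap <- data.frame(from = c("a", "a"), to = c("A", "B"))
    expect_error(buildCategoryTable(ann, universe = "A", mapping = badmap),
                 "duplicate source")
    expect_error(buildCategoryTable(ann, universe = character()), "empty")
})

test_that("category tables serialize deterministically and round-trip", {
    ann <- makeAnnotationSet(c("g2", "g1", "g3", "g1"),
                             c("GO:1", "GO:1", "GO:2", "GO:2"))
    tab <- buildCategoryTable(ann, universe = c("g1", "g2", "g3"),
                              sizeMin = 1L, sizeMax = 10L)
    f1 <- tempfile(); f2 <- tempfile()
    writeCategoryTable(tab, f1, format = "json")
    writeCategoryTable(buildCategoryTable(ann,
                                          universe = c("g1", "g2", "g3"),
                                          sizeMin = 1L, sizeMax = 10L),
                       f2, format = "json")
    expect_identical(readLines(f1), readLines(f2))

    fg <- tempfile()
    writeCategoryTable(tab, fg, format = "gmt")
    back <- readGMT(fg)
    expect_equal(categoryIds(back), categoryIds(tab))
    expect_equal(as.list(geneSets(back)), as.list(geneSets(tab)))
})
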