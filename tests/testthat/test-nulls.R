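makeScorePool <- function(n = 400L, seed = 90L) {
    set.seed(seed)
    r <- tanh(rnorm(n, 0, 0.3))
    new("GeneScoreTable", geneIds = sprintf("g%04d", seq_len(n)),
        scores = r, nUsed = rep(20L, n), method = "pearson")
}

test_that("random-gene nulls centre on the pool mean and tighten with s", {
    sc <- makeScorePool()
    pool <- geneScores(sc)
    bank <- buildRandomGeneNull(sc, sizes = c(10L, 100L), nSamples = 4000L,
                                seed = 1)
    tab <- nullParameters(bank)
    # mean of resampled means equals the pool mean within 4 SE
    for (i in 1:2) {
        se <- tab$sigma[i] / sqrt(tab$n[i])
        expect_lt(abs(tab$mu[i] - mean(pool)), 4 * se)
    }
    # null variance decreases with s and matches the finite-population
    # formula var(pool) / s * (1 - s/N)
    expect_lt(tab$sigma[tab$size == 100], tab$sigma[tab$size == 10])
    N <- length(pool)
    for (i in 1:2) {
        s <- tab$size[i]
        expect_equal(tab$sigma[i],
                     sqrt(var(pool) / s * (1 - s / N)),
                     tolerance = 0.06)
    }
    # closed-form moments are the resampling limit
    ex <- nullParameters(buildRandomGeneNull(sc, sizes = c(10L, 100L),
                                             exact = TRUE))
    expect_equal(ex$mu, rep(mean(pool), 2))
    expect_equal(ex$sigma,
                 sqrt(var(pool) / ex$size * (1 - ex$size / N)))
    expect_error(buildRandomGeneNull(sc, sizes = 1000L), "exceeds")
})

test_that("gaussian p-values follow the standard normal tail", {
    expect_equal(gaussianP(0.3, mu = 0.3, sigma = 0.1), 0.5)
    expect_equal(gaussianP(0.3 + 1.6449 * 0.1, mu = 0.3, sigma = 0.1),
                 0.05, tolerance = 1e-3)
    expect_equal(gaussianP(0, 0, 1, tail = "two_sided"), 1)
    expect_gt(gaussianP(1e3, 0, 1e-3), 0)          # floored, never 0
    expect_error(gaussianP(NA_real_, 0, 1), "non-finite")
    expect_error(gaussianP(1, 0, 0), "sigma")
})

test_that("gaussian and empirical p-values agree in rank on a simulated
           null", {
    set.seed(101)
    nullSamples <- rnorm(10000, 0.02, 0.15)
    probes <- seq(-0.4, 0.55, length.out = 100)
    pg <- gaussianP(probes, mean(nullSamples), sd(nullSamples))
    pe <- vapply(probes, empiricalP, numeric(1),
                 nullSamples = nullSamples)
    expect_gt(cor(pg, pe, method = "spearman"), 0.99)
})

test_that("BH adjustment equals the brute-force step-up rule", {
    expect_equal(bhFDR(0.037), 0.037)
    expect_equal(bhFDR(rep(1, 5)), rep(1, 5))
    expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.5)),
                 c(0.04, 0.04, 0.04, 0.5))
    # brute-force step-up on random vectors
    set.seed(102)
    for (i in 1:5) {
        p <- runif(20)
        o <- order(p)
        m <- length(p)
        stepup <- rev(cummin(rev(p[o] * m / seq_len(m))))
        stepup <- pmin(stepup, 1)
        q <- numeric(m); q[o] <- stepup
        expect_equal(bhFDR(p), q)
    }
    expect_error(bhFDR(numeric()), "empty")
    expect_error(bhFDR(c(0.5, 0)), "0, 1")
})

test_that("ensemble nulls are phenotype independent and cacheable", {
    syn <- makeSyntheticAtlas(syntheticAtlasSpec(
        nRegions = 40, nGenes = 200,
        categories = list(list(size = 15L, w = 0.8),
                          list(size = 15L, w = 0)),
        seed = 111))
    ens <- generateRandomMaps(regionIds(syn$atlas), 600, seed = 112)
    bank <- buildEnsembleNull(syn$atlas, syn$categories, ens)
    before <- nullParameters(bank)

    ph1 <- PhenotypeMap(setNames(rnorm(40), regionIds(syn$atlas)))
    ph2 <- PhenotypeMap(setNames(rnorm(40), regionIds(syn$atlas)))
    r1 <- runGCEA(syn$atlas, ph1, syn$categories, null = "ensemble",
                  nullBank = bank)
    r2 <- runGCEA(syn$atlas, ph2, syn$categories, null = "ensemble",
                  nullBank = bank)
    expect_identical(nullParameters(bank), before)   # bank untouched
    expect_false(identical(r1$p, r2$p))

    # the bank is never rebuilt when supplied
    local_mocked_bindings(
        buildEnsembleNull = function(...) stop("bank rebuilt"),
        .package = "ensembleGCEA")
    expect_silent(suppressMessages(
        runGCEA(syn$atlas, ph1, syn$categories, null = "ensemble",
                nullBank = bank)))
})

test_that("ensemble null means vanish for iid categories and variances
           inflate for coexpressed categories", {
    set.seed(120)
    musd <- replicate(10, {
        syn <- makeSyntheticAtlas(syntheticAtlasSpec(
            nRegions = 50, nGenes = 120,
            categories = list(list(size = 20L, w = 0.9),
                              list(size = 20L, w = 0)),
            seed = sample.int(1e6, 1)))
        ens <- generateRandomMaps(regionIds(syn$atlas), 400,
                                  seed = sample.int(1e6, 1))
        bank <- buildEnsembleNull(syn$atlas, syn$categories, ens)
        ph <- PhenotypeMap(setNames(rnorm(50), regionIds(syn$atlas)))
        sc <- scoreGenes(syn$atlas, ph)
        rg <- buildRandomGeneNull(sc, sizes = 20L, exact = TRUE)
        c(nullParameters(bank)$mu,            # mu (coexpr), mu (iid)
          nullParameters(bank)$sigma,         # sigma ens
          nullParameters(rg)$sigma)           # sigma random-gene
    })
    # iid-noise category: ensemble-null mean within 4 SE of zero
    muIid <- musd[2, ]
    se <- musd[4, ] / sqrt(400)
    expect_true(all(abs(muIid) < 4 * se))
    # coexpressed category: ensemble sigma exceeds random-gene sigma at
    # equal size, in every one of the 10 paired replicates
    expect_true(all(musd[3, ] > musd[5, ]))
})

test_that("empirical p-values are uniform when the data match the null", {
    # iid expression, random phenotypes, random-gene resampling null:
    # the generating process equals the null, so p should be uniform
    set.seed(160)
    nR <- 30L; nG <- 250L
    m <- matrix(rnorm(nR * nG), nR, nG,
                dimnames = list(sprintf("R%02d", 1:nR),
                                sprintf("g%03d", 1:nG)))
    atlas <- ExpressionAtlas(m)
    cats <- CategoryTable("C1", list(sample(colnames(m), 15)))
    ps <- vapply(seq_len(500), function(i) {
        ph <- PhenotypeMap(setNames(rnorm(nR), rownames(m)))
        sc <- scoreGenes(atlas, ph)
        agg <- aggregateCategoryScores(sc, cats)
        bank <- buildRandomGeneNull(sc, sizes = 15L, nSamples = 1000L,
                                    seed = i, keepSamples = TRUE)
        empiricalP(agg$score, bank@samples["15", ])
    }, numeric(1))
    ks <- suppressWarnings(ks.test(ps, "punif"))
    expect_gt(ks$p.value, 0.01)
})

test_that("score configuration mismatches are refused at evaluation", {
    syn <- makeSyntheticAtlas(syntheticAtlasSpec(
        nRegions = 30, nGenes = 60,
        categories = list(list(size = 10L, w = 0.5)), seed = 131))
    ens <- generateRandomMaps(regionIds(syn$atlas), 100, seed = 132)
    bank <- buildEnsembleNull(syn$atlas, syn$categories, ens,
                              method = "pearson", transform = "raw")
    ph <- PhenotypeMap(setNames(rnorm(30), regionIds(syn$atlas)))
    expect_error(runGCEA(syn$atlas, ph, syn$categories, null = "ensemble",
                         nullBank = bank, method = "spearman"),
                 "configuration")
    expect_error(runGCEA(syn$atlas, ph, syn$categories, null = "ensemble",
                         nullBank = bank, transform = "absolute"),
                 "configuration")
})

test_that("runGCEA ranks an engineered phenotype-matched category first
           and is deterministic", {
    syn <- makeSyntheticAtlas(syntheticAtlasSpec(
        nRegions = 50, nGenes = 300,
        categories = list(list(size = 20L, w = 0.9),
                          list(size = 20L, w = 0.2),
                          list(size = 20L, w = 0)),
        seed = 141))
    atlas <- syn$atlas
    # phenotype = the first category's mean expression map
    target <- as.list(geneSets(syn$categories))[[1]]
    ph <- PhenotypeMap(setNames(
        rowMeans(exprValues(atlas)[, target]), regionIds(atlas)))
    res <- runGCEA(atlas, ph, syn$categories, null = "random_gene",
                   nSamples = 2000L, seed = 7)
    expect_equal(res$category_id[1], categoryIds(syn$categories)[1])
    expect_true(res$significant[1])
    expect_equal(nrow(res), 3L)     # full table, never only significant

    res2 <- runGCEA(atlas, ph, syn$categories, null = "random_gene",
                    nSamples = 2000L, seed = 7)
    expect_identical(res, res2)

    # empirical p mode tracks the gaussian mode
    rese <- runGCEA(atlas, ph, syn$categories, null = "random_gene",
                    nSamples = 2000L, seed = 7, pMode = "empirical")
    expect_equal(rese$category_id[1], categoryIds(syn$categories)[1])
})

test_that("run records make results reproducible byte for byte", {
    syn <- makeSyntheticAtlas(syntheticAtlasSpec(
        nRegions = 30, nGenes = 80,
        categories = list(list(size = 10L, w = 0.6)), seed = 151))
    ph <- PhenotypeMap(setNames(rnorm(30), regionIds(syn$atlas)))
    res <- runGCEA(syn$atlas, ph, syn$categories, nSamples = 500L,
                   seed = 3)
    f1 <- tempfile(fileext = ".tsv")
    writeEnrichmentTable(res, f1)
    cfg <- jsonlite::fromJSON(paste0(f1, ".json"))
    res2 <- runGCEA(syn$atlas, ph, syn$categories,
                    null = "random_gene",
                    method = cfg$method, transform = cfg$transform,
                    tail = cfg$tail, nSamples = cfg$n_samples,
                    alphaFdr = cfg$alpha_fdr, seed = cfg$seed)
    f2 <- tempfile(fileext = ".tsv")
    writeEnrichmentTable(res2, f2)
    expect_identical(readLines(f1), readLines(f2))
})
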