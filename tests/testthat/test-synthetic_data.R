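test_that("generator parameters validate their design constraints", {
    expect_error(generatorParams(are_by_family = c(MAPK = 13L, MAPKK = 4L,
                                                   MAPKKK = 54L)),
                 "exceeds the MAPK family size")
    expect_error(generatorParams(hse_total = 200L), "exceeds")
    expect_error(generatorParams(cold_up = 30L, cold_down = 30L,
                                 cold_full = 40L), "cold design")
    expect_error(generatorParams(pair_dnds = 0), "positive")
    expect_error(generatorParams(ct_replicates = 1L), "replicates")
    expect_error(generatorParams(pair_counts = c(MAPK = 7L, MAPKKK = 19L)),
                 "too many duplicate pairs")
})

test_that("the proteome generator is deterministic and composition-exact", {
    p <- smallProteomeParams()
    a <- generateProteome(p)
    b <- generateProteome(p)
    expect_identical(as.character(a$proteome), as.character(b$proteome))
    expect_identical(as.character(a$cds), as.character(b$cds))

    expect_equal(length(a$proteome), 82L + 4L)
    expect_equal(sum(a$truth$proteins$family == "MAPK"), 12L)
    expect_equal(sum(a$truth$proteins$family == "MAPKK"), 5L)
    expect_equal(sum(a$truth$proteins$family == "MAPKKK"), 65L)
    expect_equal(unname(table(a$truth$proteins$subfamily)[c("MEKK", "RAF", "ZIK")]),
                 c(16L, 40L, 9L), ignore_attr = TRUE)
    expect_equal(nrow(a$truth$pairs), 22L)

    noDecoys <- generateProteome(generatorParams(decoy_count = 0L, seed = 3L))
    expect_equal(length(noDecoys$proteome), 82L)
})

test_that("hard decoys carry a bare TEY but never classify", {
    p <- generatorParams(decoy_count = 2L, hard_decoy_count = 3L, seed = 12L)
    prot <- generateProteome(p)
    hd <- as.character(prot$proteome)[grep("^HDECOY", names(prot$proteome))]
    expect_equal(length(hd), 3L)
    expect_true(all(grepl("TEY", hd)))
    cls <- classifyProteins(Biostrings::AAStringSet(hd))
    expect_true(all(cls$family == "none"))
})

test_that("every CDS translates to its protein", {
    corpus <- defaultCorpus()
    cds <- as.character(cdsSeqs(corpus))
    prots <- as.character(proteome(corpus))
    for (g in names(cds)[seq(1, length(cds), by = 9)]) {
        expect_equal(mapkcascade:::translateCds(cds[[g]]), prots[[g]],
                     info = g)
    }
})

test_that("truth-table marginals equal the generator parameters", {
    corpus <- defaultCorpus()
    p <- corpusParams(corpus)
    tr <- corpusTruth(corpus)
    expect_equal(sum(tr$proteins$family == "MAPK"), sum(p$mapk_groups))
    expect_equal(sum(tr$proteins$family == "decoy"), p$decoy_count)
    expect_equal(nrow(tr$pairs),
                 sum(p$pair_counts[["MAPK"]], p$pair_counts[["MAPKKK"]]))
    expect_equal(length(tr$expression$cold_up), p$cold_up)
    expect_equal(length(tr$expression$tissue_silent), p$tissue_silent)
    hse <- tr$promoters$element_counts
    expect_equal(sum(hse$count[hse$element == "HSE"] >= 1), p$hse_total)
})

test_that("tandem pairs share a linkage group within 50 kb by construction", {
    corpus <- defaultCorpus()
    tr <- corpusTruth(corpus)
    anchors <- anchorTable(corpus)
    for (k in seq_len(nrow(tr$pairs))) {
        a <- anchors[anchors$gene_id == tr$pairs$member[k], ]
        b <- anchors[anchors$gene_id == tr$pairs$partner[k], ]
        expect_equal(a$linkage_group, b$linkage_group)
        expect_lte(abs(a$position - b$position), 5e4)
    }
})

test_that("the corpus round-trips through its on-disk public form", {
    corpus <- defaultCorpus()
    dir <- withr::local_tempdir()
    writeCorpus(corpus, dir)
    expect_true(file.exists(file.path(dir, "truth", "proteins.tsv")))

    back <- readCorpus(dir)
    expect_identical(as.character(proteome(back)),
                     as.character(proteome(corpus)))
    expect_identical(as.character(genomeSeqs(back)),
                     as.character(genomeSeqs(corpus)))
    expect_equal(length(corpusTruth(back)), 0L)   # truth never re-read
    expect_equal(anchorTable(back)$gene_id, anchorTable(corpus)$gene_id)
    expect_equal(unname(tissueCounts(back)), unname(tissueCounts(corpus)))
    m1 <- geneModels(back); m2 <- geneModels(corpus)
    expect_equal(m1$genes$gene_id, m2$genes$gene_id)
    expect_equal(lapply(m2$exons, GenomicRanges::start),
                 lapply(m1$exons, GenomicRanges::start)[names(m2$exons)])
})

test_that("planted Ct tables have the configured replication and noise scale", {
    corpus <- defaultCorpus()
    ct <- ctTable(corpus)
    reps <- table(ct$gene, ct$condition)
    expect_true(all(reps == corpusParams(corpus)$ct_replicates))
    ## reference channel sits near 20 cycles with sub-cycle noise
    expect_lt(max(abs(ct$ct_reference - 20)), 1)
})
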