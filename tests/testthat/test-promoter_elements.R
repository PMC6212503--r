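test_that("upstream extraction follows strand and truncation contracts", {
    contig <- paste(rep("ACGT", 1000), collapse = "")  # 4000 bp
    genome <- Biostrings::DNAStringSet(c(LG1 = contig))

    plus <- list(seqid = "LG1", strand = "+", start = 2001, end = 2500)
    prom <- extractUpstream(plus, genome, 1500)
    expect_equal(nchar(prom), 1500L)
    expect_equal(prom, substr(contig, 501, 2000), ignore_attr = TRUE)
    expect_false(attr(prom, "truncated"))

    minus <- list(seqid = "LG1", strand = "-", start = 100, end = 600)
    promM <- extractUpstream(minus, genome, 1500)
    expect_equal(promM, as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(substr(contig, 601, 2100)))),
        ignore_attr = TRUE)

    shortGene <- list(seqid = "LG1", strand = "+", start = 401, end = 900)
    promS <- extractUpstream(shortGene, genome, 1500)
    expect_equal(nchar(promS), 400L)
    expect_true(attr(promS, "truncated"))

    expect_error(extractUpstream(plus, genome["LG1"][0], 1500), "contig")
})

test_that("element scanning counts planted instances on both strands", {
    dict <- defaultElementDictionary()
    hse <- dict$consensus[dict$name == "HSE"]
    bg <- strrep("C", 200)
    prom <- paste0(substr(bg, 1, 50), hse, strrep("C", 60), hse,
                   strrep("C", 200))
    scan <- scanElements(prom, dict)
    expect_equal(unname(scan$counts["HSE"]), 2L)
    expect_true(scan$presence[["HSE"]])

    ## reverse-strand planting is found, with the strand recorded
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(hse)))
    promRc <- paste0(strrep("C", 80), rc, strrep("C", 80))
    scanRc <- scanElements(promRc, dict)
    expect_equal(unname(scanRc$counts["HSE"]), 1L)
    expect_equal(scanRc$positions$strand[scanRc$positions$element == "HSE"],
                 "-")

    ## IUPAC degeneracy expands; both strands are scanned (GCA matches RYN
    ## forward, AGC matches its reverse complement NRY)
    deg <- readElementDictionaryFromRows(
        data.frame(name = "DEG", consensus = "RYN",
                   annotation = "degenerate test element"))
    expect_equal(unname(scanElements("AAGCAA", deg)$counts["DEG"]), 2L)

    ## a palindromic consensus is counted once per position
    pal <- readElementDictionaryFromRows(
        data.frame(name = "PAL", consensus = "GAATTC",
                   annotation = "palindromic test element"))
    expect_equal(unname(scanElements("CCGAATTCCC", pal)$counts["PAL"]), 1L)
})

test_that("scanning the reverse complement mirrors counts", {
    dict <- defaultElementDictionary()
    corpus <- defaultCorpus()
    models <- geneModels(corpus)
    prom <- extractUpstream(models$genes[5], genomeSeqs(corpus), 1500)
    fwd <- scanElements(prom, dict)
    rev <- scanElements(as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(prom))), dict)
    expect_equal(fwd$counts, rev$counts)
})

test_that("presence matrix marginals equal recomputation from raw scans", {
    corpus <- defaultCorpus()
    scans <- defaultPromoterScan()
    pm <- presenceMatrix(scans, truthFamilies(corpus))
    manual <- vapply(scans, function(s) s$presence, logical(nrow(
        defaultElementDictionary())))
    expect_equal(unname(colSums(pm$presence)), unname(rowSums(manual)))
    prevHse <- pm$prevalence[pm$prevalence$element == "HSE", ]
    expect_equal(sum(prevHse$genes_with_element),
                 sum(pm$presence[, "HSE"]))

    ## empty dictionary gives an all-zero matrix
    emptyDict <- defaultElementDictionary()[0, ]
    emptyScan <- lapply(1:3, function(i) scanElements("ACGTACGT", emptyDict))
    names(emptyScan) <- paste0("g", 1:3)
    pm0 <- presenceMatrix(emptyScan)
    expect_equal(ncol(pm0$presence), 0L)
})

test_that("generated promoters scan back to exactly the planted counts", {
    corpus <- defaultCorpus()
    tr <- corpusTruth(corpus)
    scans <- defaultPromoterScan()
    planted <- tr$promoters$element_counts
    for (g in unique(planted$gene_id)[seq(1, 82, by = 7)]) {
        want <- planted[planted$gene_id == g, ]
        got <- scans[[g]]$counts[want$element]
        expect_equal(unname(got), want$count, info = g)
    }
})
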