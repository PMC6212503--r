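test_that("back-translation maps residues to codons and validates frames", {
    cds <- c(p1 = "ATGAAATGA", p2 = "ATGGGATGA")  # M K / M G (+ stop)
    msa <- c(p1 = "MK", p2 = "MG")
    cod <- backtranslateAlignment(msa, cds)
    expect_equal(unname(cod["p1"]), "ATGAAA")
    expect_equal(unname(cod["p2"]), "ATGGGA")

    gapped <- c(p1 = "MK-", p2 = "MKG")
    cds2 <- c(p1 = "ATGAAATGA", p2 = "ATGAAAGGATGA")
    cod2 <- backtranslateAlignment(gapped, cds2)
    expect_equal(unname(cod2["p1"]), "ATGAAA---")
    expect_equal(unname(nchar(cod2["p1"])), 3L * 3L)

    ## translation mismatch is reported with the offending codon
    expect_error(backtranslateAlignment(c(p1 = "MM"), c(p1 = "ATGAAATGA")),
                 "translation mismatch.*codon 2")
    expect_error(backtranslateAlignment(c(p1 = "MK"), c(p1 = "ATGAAAT")),
                 "multiple of 3")
})

test_that("NG86 handles identical, single-change and gapped pairs", {
    same <- ng86KaKs("ATGAAA", "ATGAAA")
    expect_equal(same$ka, 0)
    expect_equal(same$ks, 0)
    expect_true(is.na(same$ratio))
    expect_match(same$flags, "undefined_ratio")

    ## one nonsynonymous difference only: Ks = 0, ratio undefined
    one <- ng86KaKs("ATGAAA", "ATGGAA")  # K -> E
    expect_equal(one$ks, 0)
    expect_gt(one$ka, 0)
    expect_true(is.na(one$ratio))

    ## gapped codon columns are excluded from all counts
    gap <- ng86KaKs("ATGAAA---", "ATGAAAGGG")
    expect_equal(gap$codons, 2L)
    expect_equal(gap$n + gap$s, 6, tolerance = 1e-9)

    expect_error(ng86KaKs("---", "GGG"), "no gap-free")
})

test_that("NG86 is symmetric and conserves sites", {
    set.seed(13)
    codons <- senseSample <- sample(setdiff(names(Biostrings::GENETIC_CODE),
                                            c("TAA", "TAG", "TGA")), 30)
    a <- paste(codons[1:15], collapse = "")
    b <- paste(codons[16:30], collapse = "")
    ab <- ng86KaKs(a, b)
    ba <- ng86KaKs(b, a)
    expect_equal(ab$nd, ba$nd)
    expect_equal(ab$sd, ba$sd)
    expect_equal(ab$n, ba$n)
    expect_equal(ab$s, ba$s)
    expect_equal(ab$n + ab$s, 3 * ab$codons, tolerance = 1e-9)
})

test_that("per-codon differences match the pathway-enumeration oracle (sampled)", {
    sense <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
    set.seed(8)
    picks <- expand.grid(a = sample(sense, 12), b = sample(sense, 12),
                         stringsAsFactors = FALSE)
    for (k in seq_len(nrow(picks))) {
        got <- codonDifferences(picks$a[k], picks$b[k])
        want <- oracleCodonNdSd(picks$a[k], picks$b[k])
        expect_equal(unname(got), unname(want), tolerance = 1e-12,
                     info = paste(picks$a[k], picks$b[k]))
    }
})

test_that("codon evolution is purifying below dN/dS 1 and neutral at 1", {
    set.seed(19)
    prot <- randomPeptide(220)
    cds <- paste(vapply(strsplit(prot, "")[[1]], function(aa) {
        opts <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == aa]
        sample(opts, 1)
    }, character(1)), collapse = "")
    cds <- paste0(cds, "TAA")

    pur <- evolveDuplicatePair(cds, dnds = 0.2, targetIdentity = 0.85)
    neu <- evolveDuplicatePair(cds, dnds = 1.0, targetIdentity = 0.85)
    ## purifying: realized nonsyn/syn acceptance ratio well below neutral
    expect_lt(pur$n_nonsyn / pur$n_syn, neu$n_nonsyn / neu$n_syn)
    expect_lte(pur$protein_identity, 0.86)

    ## estimated Ka/Ks separates the two regimes with margin
    kaksOf <- function(ev) {
        aln <- nwAlign(translateCds(cds), translateCds(ev$cds))
        cod <- backtranslateAlignment(
            stats::setNames(c(aln$alignedA, aln$alignedB), c("a", "b")),
            c(a = cds, b = ev$cds))
        ng86KaKs(cod[["a"]], cod[["b"]])$ratio
    }
    translateCds <- mapkcascade:::translateCds
    rPur <- kaksOf(pur); rNeu <- kaksOf(neu)
    expect_lt(rPur, 0.6)
    expect_gt(rNeu, 0.6)

    expect_error(evolveDuplicatePair(cds, dnds = 0), "positive")
})

test_that("duplicate pair criteria and tandem rule behave on a toy family", {
    set.seed(23)
    base <- randomPeptide(150)
    ch <- strsplit(base, "")[[1]]
    idx <- sample(seq_along(ch), 15)                 # ~90% identical
    for (i in idx) ch[i] <- sample(setdiff(c("A", "G", "K"), ch[i]), 1)
    close <- paste(ch, collapse = "")
    far <- randomPeptide(150)                        # unrelated
    prots <- c(g1 = base, g2 = close, g3 = far)
    fams <- c(g1 = "MAPK", g2 = "MAPK", g3 = "MAPK")
    anchors <- data.frame(gene_id = c("g1", "g2", "g3"),
                          linkage_group = c("LG1", "LG1", "LG2"),
                          position = c(1000, 45000, 5000))
    pairs <- findDuplicatePairs(prots, fams, anchors)
    expect_equal(nrow(pairs), 1L)
    expect_equal(c(pairs$gene1, pairs$gene2), c("g1", "g2"))
    expect_true(pairs$tandem)

    expect_true(classifyTandem(c("g1", "g2"), anchors, 1e5))
    expect_false(classifyTandem(c("g1", "g3"), anchors, 1e5))  # different LG
    expect_false(classifyTandem(c("g1", "missing"), anchors, 1e5))

    ## empty pair list propagates to an empty Ka/Ks table
    none <- findDuplicatePairs(c(a = base, b = far),
                               c(a = "MAPK", b = "MAPK"), anchors)
    expect_equal(nrow(none), 0L)
    rep <- pairKaksReport(none, prots, character(0))
    expect_equal(nrow(rep), 0L)
    expect_true(all(c("ka", "ks", "ka_ks") %in% names(rep)))
})

test_that("tightly linked qualifying chains collapse to one event", {
    set.seed(29)
    base <- randomPeptide(150)
    tweak <- function(s, n) {
        ch <- strsplit(s, "")[[1]]
        idx <- sample(seq_along(ch), n)
        for (i in idx) ch[i] <- sample(setdiff(c("A", "G", "K", "W"), ch[i]), 1)
        paste(ch, collapse = "")
    }
    trio <- c(g1 = base, g2 = tweak(base, 8), g3 = tweak(base, 8))
    fams <- stats::setNames(rep("MAPKKK", 3), names(trio))
    anchors <- data.frame(gene_id = names(trio), linkage_group = "LG1",
                          position = c(1000, 20000, 40000))
    pairs <- findDuplicatePairs(trio, fams, anchors)
    ## three pairwise-qualifying tightly linked genes -> one event
    expect_equal(nrow(pairs), 1L)
})
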