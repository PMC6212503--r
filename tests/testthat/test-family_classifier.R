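test_that("degenerate motif expressions compile and match as specified", {
    mekk <- motifPattern("MEKK", "G(T/S)Px(W/Y/F)MAPEV")
    hit <- matchMotif("AAGTPAWMAPEVAA", mekk)
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$start, 3L)  # 1-based
    expect_equal(hit$match, "GTPAWMAPEV")

    zik <- motifPattern("ZIK", "GTPEEMAPE(L/V/M)(Y/F/L)")
    expect_equal(nrow(matchMotif("GTPEEMAPELY", zik)), 1L)

    expect_equal(nrow(matchMotif("AAAAAA", mekk)), 0L)

    gap <- motifPattern("st", "(S/T)x{3,5}(S/T)")
    expect_equal(matchMotif("AASAAAATAA", gap)$match, "SAAAAT")

    expect_error(motifPattern("bad", "G(T/S"), "unbalanced")
    expect_error(motifPattern("bad", "G?"), "unexpected character")
})

test_that("family rules require the full motif context", {
    g <- motifGrammar()
    ## a bare TEY without the RWYRAPE context never qualifies as MAPK
    seq <- paste0(strrep("A", 120), "TEY", strrep("G", 120))
    cls <- classifyProtein(seq)
    expect_equal(cls$family, "none")

    ## full activation-loop context qualifies, loop type read from position 2
    ctx <- paste0(strrep("A", 120), "TDYVQTRWYRAPEL", strrep("G", 120))
    cls <- classifyProtein(ctx)
    expect_equal(cls$family, "MAPK")
    expect_equal(cls$loop_type, "TDY")

    ## MAPKK needs all three motifs
    part <- paste0(strrep("A", 100), "VGTQQYMSPER", strrep("G", 100))
    expect_equal(classifyProtein(part)$family, "none")
    full <- paste0(strrep("A", 80), "DLK", strrep("A", 20), "VGTQQYMSPER",
                   strrep("G", 60), "SAAAAAT", strrep("G", 60))
    expect_equal(classifyProtein(full)$family, "MAPKK")

    ## RAF signature places the protein in MAPKKK / RAF
    raf <- paste0(strrep("A", 150), "GTQQWMAPE", strrep("G", 100))
    cls <- classifyProtein(raf)
    expect_equal(cls$family, "MAPKKK")
    expect_equal(cls$subfamily, "RAF")

    ## sequences shorter than the kinase-domain proxy are never classified
    shortSeq <- paste0("TDYVQTRWYRAPEL", strrep("G", 50))
    expect_equal(classifyProtein(shortSeq)$family, "none")
})

test_that("every motif match is recorded even when another family wins", {
    ## a sequence with both a MAPK context and a RAF signature: MAPK wins by
    ## priority, the RAF match is still present, and the row is flagged
    seq <- paste0(strrep("A", 100), "TEYVQTRWYRAPEL", strrep("G", 60),
                  "GTQQWMAPE", strrep("A", 60))
    cls <- classifyProtein(seq)
    expect_equal(cls$family, "MAPK")
    expect_match(cls$motifs, "raf:")
    expect_match(cls$flags, "ambiguous_family")
})

test_that("CD domain detection is restricted to the C-terminal half", {
    cterm <- paste0(strrep("A", 200), "LHDAAEEPKC")
    expect_true(detectCdDomain(cterm)$present)
    nterm <- paste0("LHDAAEEPKC", strrep("A", 200))
    expect_false(detectCdDomain(nterm)$present)
})

test_that("planted group-C MAPKs carry the CD domain and other groups do not", {
    corpus <- defaultCorpus()
    cls <- defaultClassification()
    tr <- corpusTruth(corpus)$proteins
    mapk <- tr[tr$family == "MAPK", ]
    got <- cls[match(mapk$gene_id, cls$id), ]
    expect_true(all(got$cd_domain[mapk$group == "C"]))
    expect_false(any(got$cd_domain[mapk$group != "C"]))
    ## TEY in groups A-C, TDY in group D
    expect_true(all(got$loop_type[mapk$group == "D"] == "TDY"))
    expect_true(all(got$loop_type[mapk$group != "D"] == "TEY"))
})

test_that("group assignment uses TDY shortcut, tree placement, and tie rule", {
    expect_equal(assignGroup("ACDEF", references = NULL, refGroups = NULL,
                             loopType = "TDY"), "D")

    set.seed(11)
    anc <- vapply(1:4, function(i) randomPeptide(80), character(1))
    refs <- stats::setNames(anc, paste0("R", 1:4))
    mutate <- function(s, k) {
        ch <- strsplit(s, "")[[1]]
        idx <- sample(seq_along(ch), k)
        for (i in idx) ch[i] <- sample(setdiff(LETTERS[LETTERS %in% ch], ch[i]), 1)
        paste(ch, collapse = "")
    }
    cand <- mutate(anc[3], 8L)
    expect_equal(assignGroup(cand, refs, c("A", "B", "C", "D")), "C")

    ## a candidate whose sister clade holds two equally-supported labels is
    ## unassigned: A and B references identical, candidate a few steps away
    twin <- refs
    twin["R2"] <- refs[["R1"]]
    g <- assignGroup(mutate(refs[["R1"]], 5L), twin, c("A", "B", "C", "D"))
    expect_equal(g, "unassigned")

    expect_error(assignGroup(cand, refs[1:3], c("A", "B", "C")),
                 "missing reference group")
})

test_that("identity screen keeps true relatives and drops random decoys", {
    set.seed(5)
    ref <- randomPeptide(120)
    near <- paste0(substr(ref, 1, 100), randomPeptide(20))  # >80% identical
    decoy <- randomPeptide(120)
    refs <- c(R = ref)
    out <- identityScreen(c(a = ref, b = near, c = decoy), refs,
                          threshold = 50)
    expect_equal(names(out), c("a", "b"))
    ## identical survives at any threshold; one mismatch fails 100%
    oneOff <- paste0("A", substr(ref, 2, 120))
    if (substr(ref, 1, 1) == "A") oneOff <- paste0("C", substr(ref, 2, 120))
    expect_equal(names(identityScreen(c(x = ref), refs, 100)), "x")
    expect_equal(length(identityScreen(c(x = oneOff), refs, 100)), 0L)
    expect_error(identityScreen(c(x = ref), character(0)), "empty reference")
})

test_that("redundancy removal keeps the longest with lexicographic ties", {
    set.seed(9)
    s <- randomPeptide(150)
    recs <- c(b = s, a = s, c = paste0(s, "A"))
    out <- removeRedundant(recs)
    expect_equal(names(out), "c")  # longest of the redundant cluster

    recs2 <- c(zz = s, aa = s)
    expect_equal(names(removeRedundant(recs2)), "aa")  # tie -> smallest id

    ## an 85%-identical pair is below the 99% cutoff: both kept
    ch <- strsplit(s, "")[[1]]
    idx <- sample(seq_along(ch), 22)
    for (i in idx) ch[i] <- sample(setdiff(c("A", "G", "K", "W"), ch[i]), 1)
    par <- paste(ch, collapse = "")
    expect_equal(length(removeRedundant(c(a = s, b = par))), 2L)
})

test_that("molecular weight and isoelectric point match their oracles", {
    gg <- computeProperties("GG")
    expect_equal(gg$mw, 132.12, tolerance = 1e-4)

    ## Mw additivity up to one water mass
    s1 <- "MKTAYW"; s2 <- "GGLLP"
    expect_equal(computeProperties(paste0(s1, s2))$mw,
                 computeProperties(s1)$mw + computeProperties(s2)$mw - 18.01524,
                 tolerance = 1e-9)

    expect_gt(computeProperties("KKKKKKKK")$pi, 9)
    expect_lt(computeProperties("DDDDDDDD")$pi, 5)

    ## bisection agrees with a fine-grid scan of the charge curve
    set.seed(31)
    for (k in 1:40) {
        pep <- randomPeptide(sample(10:60, 1))
        expect_lt(abs(computeProperties(pep)$pi - gridPi(pep)), 0.01)
    }
})

test_that("classifier counts on the default corpus equal the planted counts", {
    corpus <- defaultCorpus()
    cls <- classifyProteins(proteome(corpus))
    fams <- truthFamilies(corpus)
    for (fam in c("MAPK", "MAPKK", "MAPKKK")) {
        expect_setequal(cls$id[cls$family == fam],
                        names(fams)[fams == fam])
    }
    decoys <- names(fams)[fams == "decoy"]
    expect_true(all(cls$family[cls$id %in% decoys] == "none"))
})
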