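test_that("global alignment handles forced and degenerate cases", {
    a <- nwAlign("MKTAYW", "MKTAYW")
    expect_equal(a$identity, 100)
    expect_equal(a$coverage, 100)
    expect_false(grepl("-", a$alignedA, fixed = TRUE))

    m <- substitutionMatrix(match = 1, mismatch = -1)
    forced <- nwAlign("A", "G", m, gapOpen = 2, gapExtend = 0)
    expect_equal(forced$score, -1)
    expect_equal(nchar(forced$alignedA), 1L)

    expect_error(nwAlign("", "A"), "non-empty")
})

test_that("alignment scores equal brute-force enumeration over all alignments", {
    m <- substitutionMatrix(match = 2, mismatch = -1,
                            alphabet = c("A", "C", "G", "T"))
    ## exhaustive over all pairs up to length 3
    alphabets <- c("A", "C", "G", "T")
    shortSeqs <- unlist(lapply(1:3, function(L)
        apply(expand.grid(rep(list(alphabets), L)), 1, paste, collapse = "")))
    set.seed(2)
    shortSeqs <- sample(shortSeqs, 12)
    for (a in shortSeqs) for (b in shortSeqs) {
        expect_equal(nwAlign(a, b, m, gapOpen = 3, gapExtend = 1)$score,
                     bruteForceNwScore(a, b, m, 3, 1),
                     info = paste(a, b))
    }
    ## random pairs up to length 6, two gap-penalty regimes
    for (k in 1:60) {
        a <- paste(sample(alphabets, sample(1:6, 1), TRUE), collapse = "")
        b <- paste(sample(alphabets, sample(1:6, 1), TRUE), collapse = "")
        go <- sample(c(2, 5), 1); ge <- sample(c(0.5, 1), 1)
        expect_equal(nwAlign(a, b, m, gapOpen = go, gapExtend = ge)$score,
                     bruteForceNwScore(a, b, m, go, ge),
                     info = paste(a, b, go, ge))
    }
})

test_that("progressive alignment reduces to pairwise and aligns planted motifs", {
    two <- progressiveAlign(c(x = "MKTAYW", y = "MKAYW"))
    pw <- nwAlign("MKTAYW", "MKAYW")
    expect_equal(unname(two["x"]), pw$alignedA)
    expect_equal(unname(two["y"]), pw$alignedB)

    three <- progressiveAlign(c(a = "MKTAYW", b = "MKTAYW", c = "MKTAYW"))
    expect_true(all(!grepl("-", three, fixed = TRUE)))

    one <- progressiveAlign(c(solo = "MKTAYW"))
    expect_equal(unname(one), "MKTAYW")

    ## family members sharing a planted motif put its residues in the same
    ## columns
    set.seed(21)
    motif <- "TEYVQTRWYRAPEL"
    seqs <- vapply(1:4, function(i)
        paste0(randomPeptide(sample(20:30, 1)), motif,
               randomPeptide(sample(20:30, 1))), character(1))
    names(seqs) <- paste0("s", 1:4)
    msa <- progressiveAlign(seqs)
    starts <- regexpr(motif, gsub("-", "", msa), fixed = TRUE)
    ## locate the motif column-wise: the aligned column of the motif's first
    ## residue must coincide across sequences
    colOfResidue <- function(aln, k) {
        ## column index of the k-th non-gap character
        which(cumsum(strsplit(aln, "")[[1]] != "-") == k &
              strsplit(aln, "")[[1]] != "-")[1]
    }
    cols <- vapply(seq_along(msa), function(i)
        colOfResidue(msa[[i]], as.integer(starts[i])), numeric(1))
    expect_equal(length(unique(cols)), 1L)
})

test_that("p-distance counts mismatches over comparable sites", {
    msa <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAA")
    expect_equal(pDistance(msa)["a", "b"], 0)

    msa2 <- c(a = "AAAAAAAAAA", b = "CCAAAAAAAA")
    expect_equal(pDistance(msa2)["a", "b"], 0.2)

    msa3 <- c(a = "AAAA", b = "CCCC")
    d <- pDistance(msa3, correction = "poisson")
    expect_true(is.infinite(d["a", "b"]))
    expect_true(isTRUE(attr(d, "saturated")))

    expect_error(pDistance(c(a = "A---", b = "-CCC")), "no comparable sites")
})

test_that("neighbor joining recovers additive trees exactly", {
    ## a hand-built quartet: ((A,B),(C,D)) with branch lengths 1,2,3,4 and
    ## internal branch 1 gives an additive matrix NJ must invert exactly
    d <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                         c("A", "B", "C", "D")))
    d["A", "B"] <- d["B", "A"] <- 3          # 1 + 2
    d["A", "C"] <- d["C", "A"] <- 5          # 1 + 1 + 3
    d["A", "D"] <- d["D", "A"] <- 6          # 1 + 1 + 4
    d["B", "C"] <- d["C", "B"] <- 6
    d["B", "D"] <- d["D", "B"] <- 7
    d["C", "D"] <- d["D", "C"] <- 7
    tree <- njTree(d)
    expect_s3_class(tree, "phylo")
    pat <- ape::cophenetic.phylo(tree)[rownames(d), colnames(d)]
    expect_equal(unname(pat), unname(d), tolerance = 1e-10)
    ## AB|CD is the only internal split
    splits <- ape::prop.part(tree)
    expect_equal(ape::Ntip(tree), 4L)

    ## n = 3 has the closed-form star resolution
    d3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
                 dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
    t3 <- njTree(d3)
    pat3 <- ape::cophenetic.phylo(t3)[rownames(d3), colnames(d3)]
    expect_equal(unname(pat3), unname(d3), tolerance = 1e-10)

    expect_error(njTree(matrix(c(0, 1, 2, 0), 2, 2)), "at least 3")
    bad <- d; bad["A", "B"] <- 99
    expect_error(njTree(bad), "not symmetric")
})

test_that("NJ recovery holds for random additive trees and label permutations", {
    set.seed(17)
    for (rep in 1:50) {
        n <- sample(4:8, 1)
        ref <- ape::rtree(n, rooted = FALSE)
        ref$edge.length <- runif(length(ref$edge.length), 0.1, 2)
        d <- ape::cophenetic.phylo(ref)
        tree <- njTree(d)
        expect_equal(ape::dist.topo(ape::unroot(ref), tree), 0,
                     ignore_attr = TRUE)
        pat <- ape::cophenetic.phylo(tree)[rownames(d), colnames(d)]
        expect_equal(unname(pat), unname(d), tolerance = 1e-8)
    }
    ## permuting the input labels yields an isomorphic tree
    ref <- ape::rtree(6, rooted = FALSE)
    ref$edge.length <- runif(length(ref$edge.length), 0.1, 2)
    d <- ape::cophenetic.phylo(ref)
    perm <- sample(rownames(d))
    t1 <- njTree(d)
    t2 <- njTree(d[perm, perm])
    expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
})

test_that("bootstrap supports are reproducible and separate planted clades", {
    set.seed(3)
    cladeA <- randomPeptide(60)
    cladeB <- randomPeptide(60)
    jitter <- function(s, k) {
        ch <- strsplit(s, "")[[1]]
        idx <- sample(seq_along(ch), k)
        for (i in idx) ch[i] <- randomPeptide(1)
        paste(ch, collapse = "")
    }
    msa <- c(a1 = jitter(cladeA, 2), a2 = jitter(cladeA, 2),
             b1 = jitter(cladeB, 2), b2 = jitter(cladeB, 2))
    t1 <- bootstrapSupport(msa, nReps = 100, seed = 42)
    t2 <- bootstrapSupport(msa, nReps = 100, seed = 42)
    expect_equal(t1$node.label, t2$node.label)
    ## the single internal split separating the two planted clades is
    ## essentially always recovered
    expect_true(max(t1$node.label, na.rm = TRUE) >= 0.95)

    single <- bootstrapSupport(msa, nReps = 1, seed = 1)
    expect_true(all(single$node.label %in% c(0, 1)))
    expect_error(bootstrapSupport(msa, nReps = 0), "at least 1")
})
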