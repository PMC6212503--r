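mkCounts <- function(counts, lengths) {
    m <- matrix(counts, nrow = length(lengths))
    rownames(m) <- names(lengths)
    colnames(m) <- paste0("s", seq_len(ncol(m)))
    m
}

test_that("FPKM follows its formula and scale invariance", {
    lens <- c(g1 = 1000)
    m <- mkCounts(10, lens)
    expect_equal(unname(fpkm(m, lens, libSizes = 1e6)[1, 1]), 10)
    expect_equal(unname(fpkm(mkCounts(0, lens), lens, libSizes = 1e6)[1, 1]), 0)

    lens2 <- c(g1 = 500, g2 = 2000)
    m2 <- mkCounts(c(7, 40), lens2)
    f1 <- fpkm(m2, lens2, libSizes = sum(m2))
    f2 <- fpkm(2 * m2, lens2, libSizes = 2 * sum(m2))
    expect_equal(f1, f2)
    expect_error(fpkm(m2, lens2, libSizes = 0), "positive")
})

test_that("TPM normalizes columns to one million", {
    lens <- c(g1 = 1000, g2 = 2000)
    m <- mkCounts(c(10, 10), lens)
    got <- tpm(m, lens)
    expect_equal(unname(got[, 1]), c(666666.67, 333333.33), tolerance = 1e-6)

    set.seed(4)
    lens3 <- stats::setNames(sample(500:3000, 20), paste0("g", 1:20))
    m3 <- mkCounts(rpois(60, 50), lens3)
    expect_equal(unname(colSums(tpm(m3, lens3))), rep(1e6, 3),
                 tolerance = 1e-6)

    eq <- mkCounts(rep(5, 8), stats::setNames(rep(1000, 8), paste0("g", 1:8)))
    expect_equal(unname(tpm(eq, stats::setNames(rep(1000, 8),
                                                paste0("g", 1:8)))[, 1]),
                 rep(1e6 / 8, 8))

    zero <- mkCounts(rep(0, 4), stats::setNames(rep(1000, 4), paste0("g", 1:4)))
    expect_error(tpm(zero, stats::setNames(rep(1000, 4), paste0("g", 1:4))),
                 "all-zero")

    ## FPKM and TPM agree on within-sample ranking
    f <- fpkm(m3, lens3, libSizes = colSums(m3))
    t <- tpm(m3, lens3)
    for (j in 1:3) expect_equal(order(f[, j]), order(t[, j]))
})

test_that("detection flags and summaries follow the floor", {
    expr <- matrix(c(5, 0, 2, 7, 0, 0.5), nrow = 3,
                   dimnames = list(c("a", "b", "c"), c("s1", "s2")))
    det <- detectExpressed(expr, floor = 1)
    expect_equal(det$in_all, "a")
    expect_equal(det$in_none, "b")
    expect_equal(det$in_some, "c")

    det0 <- detectExpressed(abs(expr) + 0.01, floor = 0)
    expect_equal(length(det0$in_all), 3L)
})

test_that("Audic-Claverie probabilities and tails match direct evaluation", {
    expect_equal(acTest(0, 0, 1e6, 1e6), 0.5)

    ## symmetric inputs give a symmetric two-sided p
    expect_equal(acTest(7, 19, 1e6, 1e6), acTest(19, 7, 1e6, 1e6))
    expect_equal(acTest(3, 40, 1e6, 1e6), acTest(40, 3, 1e6, 1e6))

    ## point probabilities and the left tail match brute-force summation
    for (x in c(0, 3, 17, 50)) for (y in c(0, 5, 28, 50)) {
        direct <- sum(vapply(0:y, function(yy)
            oracleAcProb(x, yy, 1.2e6, 0.8e6), numeric(1)))
        left <- sum(exp(vapply(0:y, function(yy)
            mapkcascade:::acLogProb(x, yy, 1.2e6, 0.8e6), numeric(1))))
        expect_equal(left, direct, tolerance = 1e-10)
    }
    expect_error(acTest(-1, 0, 1e6, 1e6), "nonnegative")
})

test_that("differential calls require all time points and match planted labels", {
    corpus <- defaultCorpus()
    res <- callDifferential(coldCounts(corpus), baseline = "t0",
                            libSizes = librarySizes(corpus)[
                                colnames(coldCounts(corpus))])
    tr <- corpusTruth(corpus)$expression
    expect_setequal(names(res$calls)[res$calls == "up"], tr$cold_up)
    expect_setequal(names(res$calls)[res$calls == "down"], tr$cold_down)
    ## adjusted p never below raw p
    expect_true(all(res$table$padj >= res$table$p - 1e-12))
    ## BH output is monotone in raw-p rank within each comparison
    for (cc in unique(res$table$comparison)) {
        sub <- res$table[res$table$comparison == cc, ]
        ord <- order(sub$p)
        expect_true(all(diff(sub$padj[ord]) >= -1e-12))
    }

    ## a flat gene with equal counts is never called
    flat <- matrix(c(50, 50, 50, 50), 1,
                   dimnames = list("g", c("t0", "t12", "t24", "t48")))
    resF <- callDifferential(flat, baseline = "t0",
                             libSizes = rep(1e6, 4))
    expect_equal(unname(resF$calls), "flat")

    expect_error(callDifferential(flat, baseline = "t0", compare = "t96"),
                 "missing compared")
})

test_that("type-I error of the tag-count test is controlled under the null", {
    set.seed(1234)
    n <- 2000
    x <- rpois(n, 100); y <- rpois(n, 100)
    p <- vapply(seq_len(n), function(i) acTest(x[i], y[i], 1e6, 1e6),
                numeric(1))
    reject <- mean(p < 0.05)
    expect_lte(reject, 0.07)
})

test_that("heatmap profiles cluster by correlation with an oracle check", {
    a <- c(1, 2, 3, 4)
    expr <- rbind(a = a, b = (a + 1) * 4 - 1,   # identical log2(x+1) shape
                  c = c(9, 7, 5, 3), d = c(5, 5, 5, 5))
    colnames(expr) <- paste0("s", 1:4)
    hp <- heatmapProfile(expr)
    expect_equal(hp$flat_genes, "d")
    expect_equal(unname(hp$profile["d", ]), rep(0, 4))
    ## perfectly correlated genes merge at height ~0 and sit adjacent
    ord <- hp$order
    expect_equal(abs(which(ord == "a") - which(ord == "b")), 1L)
    expect_equal(min(hp$hclust$height), 0, tolerance = 1e-9)

    ## anti-correlated log-profiles sit at distance 2
    expr2 <- rbind(u = 2^c(1, 2, 3, 4) - 1, v = 2^c(4, 3, 2, 1) - 1)
    colnames(expr2) <- paste0("s", 1:4)
    hp2 <- heatmapProfile(expr2)
    expect_equal(max(hp2$hclust$height), 2, tolerance = 1e-9)

    ## merge heights match a brute-force average-linkage oracle
    set.seed(6)
    m <- matrix(rpois(36, 40), 6, dimnames = list(paste0("g", 1:6),
                                                  paste0("s", 1:6)))
    hp3 <- heatmapProfile(m)
    lg <- log2(m + 1)
    d <- 1 - suppressWarnings(stats::cor(t(lg)))
    diag(d) <- 0
    expect_equal(hp3$hclust$height, bruteForceAverageLinkage(d),
                 tolerance = 1e-9)
})

test_that("2^-ddCt quantification matches its arithmetic", {
    fx <- ctFoldFixture()
    res <- ddct(fx, control = "control")
    trt <- res[res$condition == "treated", ]
    expect_equal(trt$ddct, -5.6187)
    expect_equal(trt$fold, 49.13, tolerance = 0.01)
    expect_match(trt$flags, "zero_variance")

    ## identical treated and control -> fold 1, no stars
    ct <- data.frame(gene = "g", condition = rep(c("ctl", "trt"), each = 3),
                     replicate = rep(1:3, 2),
                     ct_target = c(24.1, 24.0, 23.9, 24.1, 24.0, 23.9),
                     ct_reference = rep(20, 6))
    res2 <- ddct(ct, control = "ctl")
    expect_equal(res2$fold[res2$condition == "trt"], 1, tolerance = 1e-9)
    expect_equal(res2$stars[res2$condition == "trt"], "")

    ## ddCt of -1 doubles expression
    ct3 <- ct
    ct3$ct_target[ct3$condition == "trt"] <-
        ct3$ct_target[ct3$condition == "trt"] - 1
    res3 <- ddct(ct3, control = "ctl")
    expect_equal(res3$fold[res3$condition == "trt"], 2, tolerance = 1e-9)

    expect_error(ddct(ct[ct$replicate == 1, ], control = "ctl"),
                 "fewer than 2")
})
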