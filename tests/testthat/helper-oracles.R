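## Independent oracles, kept deliberately separate from the implementation
## paths they check.

## --- global alignment: exhaustive enumeration over all alignments ---------
## An alignment is a string of ops: D (pair), U (gap in b), L (gap in a).
## Cost model: substitution scores summed over D columns; every maximal gap
## run of length k costs gapOpen + k * gapExtend.
bruteForceNwScore <- function(a, b, S, gapOpen, gapExtend) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    best <- -Inf
    recurse <- function(i, j, ops) {
        if (i > length(ca) && j > length(cb)) {
            score <- 0
            ai <- 1L; bi <- 1L
            for (op in ops) {
                if (op == "D") {
                    score <- score + S[ca[ai], cb[bi]]
                    ai <- ai + 1L; bi <- bi + 1L
                } else if (op == "U") ai <- ai + 1L
                else bi <- bi + 1L
            }
            runs <- rle(ops)
            gapRuns <- runs$lengths[runs$values != "D"]
            score <- score - sum(gapOpen + gapRuns * gapExtend)
            best <<- max(best, score)
            return(invisible())
        }
        if (i <= length(ca) && j <= length(cb)) recurse(i + 1L, j + 1L, c(ops, "D"))
        if (i <= length(ca)) recurse(i + 1L, j, c(ops, "U"))
        if (j <= length(cb)) recurse(i, j + 1L, c(ops, "L"))
    }
    recurse(1L, 1L, character(0))
    best
}

## --- NG86 per-codon differences: depth-first pathway enumeration ----------
oracleCodonNdSd <- function(c1, c2) {
    gc <- Biostrings::GENETIC_CODE
    paths <- list()
    dfs <- function(cur, target, sd, nd) {
        if (identical(cur, target)) {
            paths[[length(paths) + 1L]] <<- c(sd = sd, nd = nd)
            return(invisible())
        }
        for (site in which(cur != target)) {
            nxt <- cur; nxt[site] <- target[site]
            aaN <- gc[[paste(nxt, collapse = "")]]
            if (aaN == "*") next
            aaC <- gc[[paste(cur, collapse = "")]]
            if (aaC == aaN) dfs(nxt, target, sd + 1, nd)
            else dfs(nxt, target, sd, nd + 1)
        }
    }
    a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
    dfs(a, b, 0, 0)
    if (!length(paths)) return(c(sd = 0, nd = sum(a != b)))
    ## weight pathways so that each ordering of the differing sites counts
    ## once: a DFS path that fixes k sites in some order corresponds to one
    ## ordering, so equal weight over completed paths matches the k!-average
    ## with blocked orderings excluded
    m <- do.call(rbind, paths)
    c(sd = mean(m[, "sd"]), nd = mean(m[, "nd"]))
}

## --- Audic-Claverie point probability, direct arithmetic ------------------
oracleAcProb <- function(x, y, n1, n2) {
    r <- n2 / n1
    exp(y * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
        (x + y + 1) * log(1 + r))
}

## --- average-linkage agglomeration, brute force ----------------------------
## returns the merge heights in order, for comparison with hclust$height
bruteForceAverageLinkage <- function(d) {
    n <- nrow(d)
    clusters <- as.list(seq_len(n))
    active <- rep(TRUE, length(clusters))
    heights <- numeric(0)
    clusterDist <- function(ci, cj)
        mean(d[clusters[[ci]], clusters[[cj]]])
    while (sum(active) > 1L) {
        idx <- which(active)
        best <- c(NA, NA); bestD <- Inf
        for (i in idx) for (j in idx) {
            if (i >= j) next
            dd <- clusterDist(i, j)
            if (dd < bestD) { bestD <- dd; best <- c(i, j) }
        }
        heights <- c(heights, bestD)
        clusters[[length(clusters) + 1L]] <-
            c(clusters[[best[1]]], clusters[[best[2]]])
        active[best] <- FALSE
        active[length(clusters)] <- TRUE
    }
    heights
}

## --- fine-grid isoelectric point -------------------------------------------
gridPi <- function(sequence, step = 0.001) {
    ph <- seq(0, 14, by = step)
    q <- peptideCharge(sequence, ph)
    ph[which.min(abs(q))]
}

randomPeptide <- function(n) paste(sample(c("A", "C", "D", "E", "F", "G", "H",
                                            "I", "K", "L", "M", "N", "P", "Q",
                                            "R", "S", "T", "V", "W", "Y"),
                                          n, replace = TRUE), collapse = "")
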