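## Global pairwise alignment, progressive multiple alignment, distance
## matrices, neighbor-joining trees and bootstrap support -- the engine
## behind group assignment, the identity screen and duplicate detection.

.alnEnv <- new.env(parent = emptyenv())

#' The BLOSUM62 substitution matrix
#'
#' Loaded from the scoring matrices shipped with Biostrings and cached.
#'
#' @return A numeric matrix with amino-acid row/column names.
#' @export
blosum62Matrix <- function() {
    if (is.null(.alnEnv$blosum62)) {
        e <- new.env()
        utils::data("BLOSUM62", package = "Biostrings", envir = e)
        .alnEnv$blosum62 <- e$BLOSUM62
    }
    .alnEnv$blosum62
}

#' Build a simple match/mismatch substitution matrix
#'
#' @param match,mismatch Scores for identical and differing symbols.
#' @param alphabet Symbols the matrix covers.
#' @return A square numeric matrix.
#' @export
substitutionMatrix <- function(match = 1, mismatch = -1,
                               alphabet = c("A", "C", "G", "T")) {
    n <- length(alphabet)
    m <- matrix(mismatch, n, n, dimnames = list(alphabet, alphabet))
    diag(m) <- match
    m
}

## pairwise position-score matrix, unknown symbols scoring 0
pairScoreMatrix <- function(a, b, S) {
    alpha <- rownames(S)
    K <- length(alpha)
    Spad <- matrix(0, K + 1L, K + 1L)
    Spad[seq_len(K), seq_len(K)] <- S
    ia <- match(strsplit(a, "")[[1]], alpha)
    ib <- match(strsplit(b, "")[[1]], alpha)
    if (anyNA(ia) || anyNA(ib))
        mcLog("nwAlign: residues outside the scoring matrix treated as unknown (score 0)")
    ia[is.na(ia)] <- K + 1L
    ib[is.na(ib)] <- K + 1L
    Spad[ia, ib, drop = FALSE]
}

#' Global pairwise alignment with affine gaps (Needleman-Wunsch/Gotoh)
#'
#' A gap run of length k costs `gapOpen + k * gapExtend`. Tie-breaks during
#' traceback are deterministic: diagonal, then up (gap in `b`), then left
#' (gap in `a`). Residues absent from the scoring matrix are treated as
#' unknown and score 0.
#'
#' @param a,b Sequences (character strings).
#' @param substitution Substitution matrix; defaults to BLOSUM62.
#' @param gapOpen,gapExtend Nonnegative gap penalties.
#' @return A list of class `mapk_alignment`: `alignedA`, `alignedB` (equal
#'   length, gap `-`), `score`, `identity` (% of alignment columns that
#'   match, dual-gap columns excluded) and `coverage` (% of the longer
#'   sequence covered by columns aligning residue to residue).
#' @examples
#' nwAlign("HEAGAWGHEE", "PAWHEAE")$score
#' @export
nwAlign <- function(a, b, substitution = blosum62Matrix(),
                    gapOpen = 10, gapExtend = 0.5) {
    a <- toupper(as.character(a)); b <- toupper(as.character(b))
    if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
    sm <- pairScoreMatrix(a, b, substitution)
    dp <- .nw_dp(sm, gapOpen, gapExtend)
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    alnA <- ifelse(dp$a == 0L, "-", ca[pmax(dp$a, 1L)])
    alnB <- ifelse(dp$b == 0L, "-", cb[pmax(dp$b, 1L)])
    both <- dp$a > 0L & dp$b > 0L
    ident <- 100 * sum(both & alnA == alnB) / length(alnA)
    cov <- 100 * sum(both) / max(nchar(a), nchar(b))
    structure(list(alignedA = paste(alnA, collapse = ""),
                   alignedB = paste(alnB, collapse = ""),
                   score = dp$score, identity = ident, coverage = cov),
              class = "mapk_alignment")
}

#' @export
print.mapk_alignment <- function(x, ...) {
    cat("global alignment  score ", format(x$score), ", identity ",
        sprintf("%.1f%%", x$identity), ", coverage ",
        sprintf("%.1f%%", x$coverage), "\n", sep = "")
    cat(" ", x$alignedA, "\n ", x$alignedB, "\n", sep = "")
    invisible(x)
}

## column frequency profile of an aligned block (rows: alphabet, cols: columns)
profileFreq <- function(seqs, alpha) {
    mat <- do.call(rbind, strsplit(seqs, ""))
    K <- length(alpha)
    F <- matrix(0, K, ncol(mat))
    for (k in seq_len(K)) F[k, ] <- colSums(mat == alpha[k])
    nz <- colSums(F)
    list(F = F, nz = nz)
}

mergeProfiles <- function(seqsA, seqsB, S, gapOpen, gapExtend) {
    alpha <- rownames(S)
    pa <- profileFreq(seqsA, alpha)
    pb <- profileFreq(seqsB, alpha)
    M <- t(pa$F) %*% S %*% pb$F / outer(pmax(pa$nz, 1), pmax(pb$nz, 1))
    dp <- .nw_dp(M, gapOpen, gapExtend)
    la <- nchar(seqsA[1L]); lb <- nchar(seqsB[1L])
    chA <- lapply(strsplit(seqsA, ""), identity)
    chB <- lapply(strsplit(seqsB, ""), identity)
    outA <- matrix("-", length(seqsA), length(dp$a))
    outB <- matrix("-", length(seqsB), length(dp$a))
    for (k in seq_along(dp$a)) {
        if (dp$a[k] > 0L) for (s in seq_along(chA)) outA[s, k] <- chA[[s]][dp$a[k]]
        if (dp$b[k] > 0L) for (s in seq_along(chB)) outB[s, k] <- chB[[s]][dp$b[k]]
    }
    c(stats::setNames(apply(outA, 1L, paste, collapse = ""), names(seqsA)),
      stats::setNames(apply(outB, 1L, paste, collapse = ""), names(seqsB)))
}

#' Progressive multiple alignment
#'
#' Builds a guide tree by average-linkage clustering of pairwise global-
#' alignment distances (1 - identity), then merges profiles in guide-tree
#' order with profile-to-profile Needleman-Wunsch (column scores are the
#' mean substitution score over residue pairs). Columns consisting only of
#' gaps are removed.
#'
#' @param seqs Named character vector or `AAStringSet` (>= 1 sequence).
#' @inheritParams nwAlign
#' @return Named character vector of aligned sequences (equal length), in
#'   the input order.
#' @export
progressiveAlign <- function(seqs, substitution = blosum62Matrix(),
                             gapOpen = 10, gapExtend = 0.5) {
    seqs <- asNamedChar(seqs)
    if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
        stop("sequences must have unique names")
    n <- length(seqs)
    if (n == 1L) return(seqs)
    if (n == 2L) {
        aln <- nwAlign(seqs[1L], seqs[2L], substitution, gapOpen, gapExtend)
        return(stats::setNames(c(aln$alignedA, aln$alignedB), names(seqs)))
    }
    d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        aln <- nwAlign(seqs[i], seqs[j], substitution, gapOpen, gapExtend)
        d[i, j] <- d[j, i] <- 1 - aln$identity / 100
    }
    hc <- hclust(stats::as.dist(d), method = "average")
    profiles <- vector("list", nrow(hc$merge))
    getProf <- function(k) {
        if (k < 0L) stats::setNames(seqs[-k], names(seqs)[-k]) else profiles[[k]]
    }
    for (m in seq_len(nrow(hc$merge))) {
        A <- getProf(hc$merge[m, 1L]); B <- getProf(hc$merge[m, 2L])
        profiles[[m]] <- mergeProfiles(A, B, substitution, gapOpen, gapExtend)
    }
    res <- profiles[[nrow(hc$merge)]]
    ## drop all-gap columns (defensive; cannot arise from profile merging)
    mat <- do.call(rbind, strsplit(res, ""))
    rownames(mat) <- names(res)
    keep <- colSums(mat != "-") > 0L
    res <- apply(mat[, keep, drop = FALSE], 1L, paste, collapse = "")
    res[names(seqs)]
}

#' Pairwise distance matrix from a multiple alignment
#'
#' p-distance: mismatches over compared sites, ignoring columns where either
#' sequence has a gap. An optional Poisson correction `-ln(1 - p)` is
#' available; pairs with p = 1 are flagged infinite under the correction.
#'
#' @param msa Named character vector of equal-length aligned sequences.
#' @param correction `"none"` (default) or `"poisson"`.
#' @return Symmetric numeric matrix with zero diagonal and sequence names as
#'   labels; when the Poisson correction saturates, entries are `Inf` and
#'   `attr(x, "saturated")` is `TRUE`.
#' @export
pDistance <- function(msa, correction = c("none", "poisson")) {
    correction <- match.arg(correction)
    msa <- asNamedChar(msa)
    if (length(unique(nchar(msa))) != 1L)
        stop("aligned sequences must have equal length")
    mat <- do.call(rbind, strsplit(msa, ""))
    n <- length(msa)
    d <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        ok <- mat[i, ] != "-" & mat[j, ] != "-"
        if (!any(ok))
            stop("no comparable sites between '", names(msa)[i], "' and '",
                 names(msa)[j], "'")
        p <- sum(mat[i, ok] != mat[j, ok]) / sum(ok)
        d[i, j] <- d[j, i] <- if (correction == "poisson") {
            if (p >= 1) Inf else -log(1 - p)
        } else p
    }
    if (any(is.infinite(d))) attr(d, "saturated") <- TRUE
    d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration; exact for additive distance matrices. Negative
#' branch-length estimates are clamped to zero and flagged.
#'
#' @param d Symmetric numeric matrix (zero diagonal, labels on both
#'   dimensions) for n >= 3 taxa.
#' @return An unrooted [ape::read.tree()]-style `phylo` object;
#'   `attr(tree, "clamped")` gives the number of negative branch lengths
#'   clamped to zero.
#' @export
njTree <- function(d) {
    d <- as.matrix(d)
    if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
    if (is.null(rownames(d))) stop("distance matrix must be labeled")
    if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
    if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
    tree <- ape::nj(d)
    neg <- tree$edge.length < 0
    if (any(neg)) tree$edge.length[neg] <- 0
    attr(tree, "clamped") <- sum(neg)
    tree
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Alignment columns are resampled with replacement `nReps` times; each
#' replicate alignment yields a p-distance NJ tree, and support for every
#' internal edge of the original tree is the fraction of replicate trees
#' containing the same bipartition.
#'
#' @param msa Named character vector of aligned sequences.
#' @param nReps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; resampling is reproducible.
#' @param correction Distance correction passed to [pDistance()].
#' @return The NJ tree of the full alignment with `node.label` set to the
#'   support fractions.
#' @export
bootstrapSupport <- function(msa, nReps = 100, seed = 1L,
                             correction = "none") {
    if (nReps < 1L) stop("nReps must be at least 1")
    msa <- asNamedChar(msa)
    mat <- do.call(rbind, strsplit(msa, ""))
    rownames(mat) <- names(msa)
    orig <- njTree(pDistance(msa, correction))
    set.seed(as.integer(seed))
    trees <- vector("list", nReps)
    for (r in seq_len(nReps)) {
        cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
        rep_msa <- apply(mat[, cols, drop = FALSE], 1L, paste, collapse = "")
        trees[[r]] <- njTree(pDistance(rep_msa, correction))
    }
    counts <- ape::prop.clades(orig, trees, rooted = FALSE)
    counts[is.na(counts)] <- 0L
    orig$node.label <- counts / nReps
    orig
}

## tips reachable below `node` in a rooted tree
tipsUnder <- function(tree, node) {
    nTips <- length(tree$tip.label)
    todo <- node
    tips <- integer(0)
    while (length(todo)) {
        cur <- todo[1L]; todo <- todo[-1L]
        if (cur <= nTips) tips <- c(tips, cur)
        else todo <- c(todo, tree$edge[tree$edge[, 1L] == cur, 2L])
    }
    tree$tip.label[tips]
}

#' Assign a classified MAPK/MAPKK to a phylogenetic group
#'
#' MAPKs whose activation loop is TDY are assigned to group D directly. All
#' other candidates are joined to the labeled reference panel, aligned
#' progressively, and placed on a p-distance NJ tree; the candidate takes
#' the majority group label of its sister clade (the tree is rooted at the
#' reference farthest from the candidate). Ties yield `"unassigned"`.
#'
#' @param candidate Candidate sequence (character or `AAString`).
#' @param references Named references, one or more per group.
#' @param refGroups Character vector of group labels (`A`-`D`), parallel to
#'   `references`.
#' @param loopType Optional activation-loop type of the candidate (`"TEY"`,
#'   `"TDY"`); `"TDY"` short-circuits to group D.
#' @inheritParams nwAlign
#' @return A group label `"A"`, `"B"`, `"C"`, `"D"`, or `"unassigned"`.
#' @export
assignGroup <- function(candidate, references, refGroups, loopType = NULL,
                        substitution = blosum62Matrix(),
                        gapOpen = 10, gapExtend = 0.5) {
    if (!is.null(loopType) && !is.na(loopType) && loopType == "TDY")
        return("D")
    refs <- asNamedChar(references)
    if (is.null(names(refs))) names(refs) <- paste0("ref", seq_along(refs))
    if (length(refGroups) != length(refs))
        stop("refGroups must parallel references")
    missing <- setdiff(c("A", "B", "C", "D"), refGroups)
    if (length(missing))
        stop("missing reference group(s): ", paste(missing, collapse = ", "))
    qid <- "query.candidate"
    seqs <- c(stats::setNames(as.character(candidate)[1L], qid), refs)
    msa <- progressiveAlign(seqs, substitution, gapOpen, gapExtend)
    tree <- njTree(pDistance(msa))
    pat <- ape::cophenetic.phylo(tree)
    far <- names(which.max(pat[qid, setdiff(colnames(pat), qid)]))
    rooted <- ape::root(tree, outgroup = far, resolve.root = TRUE)
    qtip <- which(rooted$tip.label == qid)
    parent <- rooted$edge[rooted$edge[, 2L] == qtip, 1L]
    sibs <- setdiff(tipsUnder(rooted, parent), qid)
    labs <- refGroups[match(sibs, names(refs))]
    tab <- sort(table(labs), decreasing = TRUE)
    if (length(tab) == 0L) return("unassigned")
    if (length(tab) > 1L && tab[1L] == tab[2L]) return("unassigned")
    names(tab)[1L]
}
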