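## Count normalization (FPKM / TPM), detection flags, tag-count differential
## expression with BH FDR, heatmap profiles, and qRT-PCR 2^-ddCt analysis.

checkCounts <- function(counts, lengths, libSizes) {
    if (!is.matrix(counts)) stop("counts must be a matrix")
    if (any(counts < 0)) stop("counts must be nonnegative")
    if (is.null(rownames(counts))) stop("counts must have gene rownames")
    lengths <- lengths[rownames(counts)]
    if (anyNA(lengths) || any(lengths <= 0))
        stop("every gene needs a positive effective length")
    if (is.null(libSizes)) libSizes <- colSums(counts)
    if (length(libSizes) != ncol(counts))
        stop("one library size per sample required")
    list(lengths = as.numeric(lengths), libSizes = as.numeric(libSizes))
}

#' FPKM normalization
#'
#' `FPKM = count * 1e9 / (librarySize * length)`.
#'
#' @param counts Gene x sample matrix of nonnegative counts with gene
#'   rownames.
#' @param lengths Named numeric of effective transcript lengths (bp).
#' @param libSizes Per-sample library sizes; defaults to column sums.
#' @return Matrix of FPKM values with a `"unit"` attribute.
#' @export
fpkm <- function(counts, lengths, libSizes = NULL) {
    ck <- checkCounts(counts, lengths, libSizes)
    if (any(ck$libSizes <= 0)) stop("library sizes must be positive")
    out <- counts * 1e9 / (rep(ck$libSizes, each = nrow(counts)) * ck$lengths)
    attr(out, "unit") <- "FPKM"
    out
}

#' TPM normalization
#'
#' Per-sample length-normalized rates rescaled to one million:
#' `r_g = count_g / length_g; TPM_g = r_g * 1e6 / sum(r)`. Every column of
#' the result sums to 1e6.
#'
#' @inheritParams fpkm
#' @return Matrix of TPM values with a `"unit"` attribute.
#' @export
tpm <- function(counts, lengths) {
    ck <- checkCounts(counts, lengths, NULL)
    rate <- counts / ck$lengths
    tot <- colSums(rate)
    if (any(tot == 0)) stop("all-zero sample column: TPM undefined")
    out <- sweep(rate, 2L, tot, "/") * 1e6
    attr(out, "unit") <- "TPM"
    out
}

#' Detection flags and summaries
#'
#' A gene is detected in a sample when its normalized value reaches the
#' floor.
#'
#' @param expr Normalized expression matrix (genes x samples).
#' @param floor Detection floor (default 1, FPKM units).
#' @return A list: `detected` (logical matrix), `in_all`, `in_some`,
#'   `in_none` (character vectors of gene ids) and `summary` (named counts).
#' @export
detectExpressed <- function(expr, floor = 1) {
    det <- expr >= floor
    nDet <- rowSums(det)
    inAll <- rownames(expr)[nDet == ncol(expr)]
    inNone <- rownames(expr)[nDet == 0L]
    inSome <- setdiff(rownames(expr), c(inAll, inNone))
    mcLog("detectExpressed: floor %g -> %d in all, %d in some, %d in no sample",
          floor, length(inAll), length(inSome), length(inNone))
    list(detected = det, in_all = inAll, in_some = inSome, in_none = inNone,
         summary = c(all = length(inAll), some = length(inSome),
                     none = length(inNone)))
}

#' Audic-Claverie tag-count test
#'
#' For counts x and y of one gene in two libraries of sizes N1 and N2, the
#' conditional probability of y given x is
#' `p(y|x) = (N2/N1)^y (x+y)! / (x! y! (1+N2/N1)^(x+y+1))`,
#' evaluated in log space. The two-sided p-value doubles the smaller of the
#' two directional tails -- the lower tail `P(Y <= y | x)` and, in the
#' mirrored orientation, `P(X <= x | y)` -- and counts the observed point
#' probability once: `p = min(1, max(p(y|x), 2 min(L, R) - p(y|x)))`. With
#' equal libraries the statistic is symmetric in (x, y), and for
#' x = y = 0 it equals 0.5, the conditional probability itself.
#'
#' @param x,y Nonnegative integer counts.
#' @param n1,n2 Library sizes.
#' @return Two-sided p-value.
#' @examples
#' acTest(0, 0, 1e6, 1e6)  # 0.5
#' @export
acTest <- function(x, y, n1, n2) {
    if (x < 0 || y < 0) stop("counts must be nonnegative")
    if (n1 <= 0 || n2 <= 0) stop("library sizes must be positive")
    pPoint <- exp(acLogProb(x, y, n1, n2))
    left <- sum(exp(vapply(0:y, function(yy) acLogProb(x, yy, n1, n2),
                           numeric(1))))
    right <- sum(exp(vapply(0:x, function(xx) acLogProb(y, xx, n2, n1),
                            numeric(1))))
    left <- min(1, left); right <- min(1, right)
    min(1, max(pPoint, 2 * min(left, right) - pPoint))
}

## log p(y | x) for the Audic-Claverie model
acLogProb <- function(x, y, n1, n2) {
    r <- n2 / n1
    y * log(r) + lchoose(x + y, y) - (x + y + 1) * log1p(r)
}

#' Differential expression calls between a baseline and later time points
#'
#' For every gene and every compared column, the Audic-Claverie test is
#' applied to the baseline and treatment counts, p-values are Benjamini-
#' Hochberg adjusted across genes within each comparison, and the log2 fold
#' change of library-size-normalized rates is computed. A gene is called
#' `up` when the adjusted p-value is below `alpha` and log2FC >= `lfc` at
#' every compared time point; `down` symmetrically; otherwise `flat`.
#'
#' @param counts Gene x sample count matrix (integer), first-listed column
#'   the baseline.
#' @param baseline Column name of the baseline (default first column).
#' @param compare Column names to compare against the baseline (default all
#'   other columns).
#' @param libSizes Per-sample library sizes (defaults to column sums).
#' @param lfc log2 fold-change cutoff (default 1).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @return A list: `table` (per gene x comparison rows: `gene`,
#'   `comparison`, `log2fc`, `p`, `padj`, `direction`) and `calls` (named
#'   vector, `up`/`down`/`flat` per gene).
#' @export
callDifferential <- function(counts, baseline = colnames(counts)[1L],
                             compare = setdiff(colnames(counts), baseline),
                             libSizes = NULL, lfc = 1, alpha = 0.05) {
    if (!baseline %in% colnames(counts)) stop("baseline column not found")
    if (!all(compare %in% colnames(counts)))
        stop("missing compared time point(s): ",
             paste(setdiff(compare, colnames(counts)), collapse = ", "))
    if (is.null(libSizes)) libSizes <- colSums(counts)
    if (is.null(names(libSizes))) names(libSizes) <- colnames(counts)
    genes <- rownames(counts)
    tabs <- list()
    upMat <- matrix(FALSE, length(genes), length(compare),
                    dimnames = list(genes, compare))
    downMat <- upMat
    for (cc in compare) {
        x <- counts[, baseline]; y <- counts[, cc]
        n1 <- libSizes[[baseline]]; n2 <- libSizes[[cc]]
        p <- vapply(seq_along(genes), function(g) acTest(x[g], y[g], n1, n2),
                    numeric(1))
        padj <- p.adjust(p, method = "BH")
        l2fc <- log2((y / n2) / (x / n1))
        l2fc[x == 0 & y == 0] <- 0
        upMat[, cc] <- padj < alpha & l2fc >= lfc
        downMat[, cc] <- padj < alpha & l2fc <= -lfc
        dir <- ifelse(upMat[, cc], "up", ifelse(downMat[, cc], "down", "flat"))
        tabs[[cc]] <- data.frame(gene = genes, comparison = cc, log2fc = l2fc,
                                 p = p, padj = padj, direction = dir,
                                 stringsAsFactors = FALSE)
    }
    calls <- ifelse(rowSums(upMat) == length(compare), "up",
                    ifelse(rowSums(downMat) == length(compare), "down", "flat"))
    names(calls) <- genes
    mcLog("callDifferential: %s vs (%s): %d up, %d down at |log2FC| >= %g, BH alpha %g",
          baseline, paste(compare, collapse = ","), sum(calls == "up"),
          sum(calls == "down"), lfc, alpha)
    list(table = do.call(rbind, tabs), calls = calls)
}

#' Normalized expression profiles and clustering order for heatmaps
#'
#' Profiles are `log2(x + 1)` followed by a per-gene z-score; genes are
#' ordered by average-linkage hierarchical clustering on the correlation
#' distance `1 - Pearson r`. Zero-variance genes get an all-zero profile,
#' are flagged, and sit at correlation distance 1 from everything.
#'
#' @param expr Normalized expression matrix (genes x samples).
#' @return A list: `profile` (z-scored matrix), `order` (gene ids in leaf
#'   order), `hclust` (the clustering object) and `flat_genes` (zero-
#'   variance gene ids).
#' @export
heatmapProfile <- function(expr) {
    lg <- log2(expr + 1)
    mu <- rowMeans(lg)
    sd <- apply(lg, 1L, stats::sd)
    flat <- rownames(expr)[sd == 0]
    z <- (lg - mu) / ifelse(sd == 0, 1, sd)
    cormat <- suppressWarnings(stats::cor(t(lg)))
    cormat[is.na(cormat)] <- 0
    d <- 1 - cormat
    diag(d) <- 0
    hc <- hclust(stats::as.dist(d), method = "average")
    list(profile = z, order = rownames(expr)[hc$order], hclust = hc,
         flat_genes = flat)
}

## ---------------------------------------------------------------------------
## qRT-PCR

#' Relative expression by the 2^-ddCt method
#'
#' Per replicate, `dCt = Ct_target - Ct_reference`; per condition,
#' `ddCt = mean dCt(condition) - mean dCt(control)` and the fold change is
#' `2^-ddCt`. Significance versus the control is a paired two-sided t-test
#' on the replicate dCt values, starred at p < 0.05 (`*`) and p < 0.01
#' (`**`). When the replicate dCt differences have zero variance the t-test
#' is undefined and p is `NA` (flagged).
#'
#' @param ct data.frame with columns `gene`, `condition`, `replicate`,
#'   `ct_target`, `ct_reference`.
#' @param control Name of the control condition.
#' @return data.frame with one row per gene x condition: `gene`,
#'   `condition`, `mean_dct`, `ddct`, `fold`, `p`, `stars`, `flags`.
#' @export
ddct <- function(ct, control) {
    need <- c("gene", "condition", "replicate", "ct_target", "ct_reference")
    if (!all(need %in% names(ct)))
        stop("Ct table needs columns: ", paste(need, collapse = ", "))
    if (!control %in% ct$condition)
        stop("control condition not present: ", control)
    ct$dct <- ct$ct_target - ct$ct_reference
    out <- list()
    for (g in unique(ct$gene)) {
        sub <- ct[ct$gene == g, , drop = FALSE]
        ctrl <- sub[sub$condition == control, , drop = FALSE]
        ctrl <- ctrl[order(ctrl$replicate), ]
        if (nrow(ctrl) < 2L)
            stop("gene ", g, ": fewer than 2 control replicates")
        for (cond in unique(sub$condition)) {
            trt <- sub[sub$condition == cond, , drop = FALSE]
            trt <- trt[order(trt$replicate), ]
            if (nrow(trt) < 2L)
                stop("gene ", g, ", condition ", cond,
                     ": fewer than 2 replicates")
            dd <- mean(trt$dct) - mean(ctrl$dct)
            flags <- character(0)
            p <- NA_real_
            if (cond != control) {
                if (nrow(trt) != nrow(ctrl)) {
                    flags <- c(flags, "unpaired")
                } else {
                    diffs <- trt$dct - ctrl$dct
                    if (stats::sd(diffs) == 0) {
                        flags <- c(flags, "zero_variance")
                    } else {
                        p <- t.test(trt$dct, ctrl$dct, paired = TRUE)$p.value
                    }
                }
            }
            stars <- if (is.na(p)) "" else if (p < 0.01) "**"
                     else if (p < 0.05) "*" else ""
            out[[length(out) + 1L]] <- data.frame(
                gene = g, condition = cond, mean_dct = mean(trt$dct),
                ddct = dd, fold = 2^(-dd), p = p, stars = stars,
                flags = paste(flags, collapse = ","),
                stringsAsFactors = FALSE)
        }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
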