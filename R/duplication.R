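## Duplicate gene pair detection, tandem classification, codon alignments
## and Nei-Gojobori (1986) Ka/Ks estimation.

.codonEnv <- new.env(parent = emptyenv())

geneticCode <- function() Biostrings::GENETIC_CODE

translateCodon <- function(codon) {
    aa <- geneticCode()[codon]
    if (is.na(aa)) stop("invalid codon: ", codon)
    unname(aa)
}

senseCodons <- function() {
    gc <- geneticCode()
    names(gc)[gc != "*"]
}

#' Synonymous site fractions of a codon
#'
#' For each codon position, the fraction of the three possible nucleotide
#' changes that are synonymous. Changes creating a stop codon count as
#' nonsynonymous, so every codon contributes exactly 3 sites and the
#' invariant N + S = 3 x codons holds exactly.
#'
#' @param codon A sense codon string.
#' @return Numeric of length 3 (per-position synonymous fractions).
#' @export
codonSynFraction <- function(codon) {
    key <- paste0("syn_", codon)
    cached <- .codonEnv[[key]]
    if (!is.null(cached)) return(cached)
    gc <- geneticCode()
    aa <- gc[[codon]]
    if (is.na(aa) || aa == "*") stop("not a sense codon: ", codon)
    nt <- c("A", "C", "G", "T")
    chars <- strsplit(codon, "")[[1]]
    out <- vapply(1:3, function(pos) {
        alts <- setdiff(nt, chars[pos])
        syn <- vapply(alts, function(x) {
            mut <- chars; mut[pos] <- x
            mutAa <- gc[[paste(mut, collapse = "")]]
            !is.na(mutAa) && mutAa != "*" && mutAa == aa
        }, logical(1))
        sum(syn) / 3
    }, numeric(1))
    .codonEnv[[key]] <- out
    out
}

#' Synonymous/nonsynonymous differences between two codons
#'
#' All minimal substitution pathways between the codons are enumerated (k!
#' orderings of the k differing positions); pathways passing through a stop
#' codon are excluded, and the synonymous/nonsynonymous step counts are
#' averaged over the remaining pathways with equal weight.
#'
#' @param c1,c2 Sense codon strings.
#' @return Numeric of length 2: `c(sd, nd)`, the average synonymous and
#'   nonsynonymous difference counts.
#' @export
codonDifferences <- function(c1, c2) {
    key <- paste0("diff_", c1, "_", c2)
    cached <- .codonEnv[[key]]
    if (!is.null(cached)) return(cached)
    gc <- geneticCode()
    if (is.na(gc[c1]) || gc[[c1]] == "*") stop("not a sense codon: ", c1)
    if (is.na(gc[c2]) || gc[[c2]] == "*") stop("not a sense codon: ", c2)
    a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
    pos <- which(a != b)
    k <- length(pos)
    if (k == 0L) {
        out <- c(sd = 0, nd = 0)
        .codonEnv[[key]] <- out
        return(out)
    }
    perms <- if (k == 1L) list(pos) else {
        idx <- seq_len(k)
        ords <- list()
        permute <- function(v, acc) {
            if (!length(v)) { ords[[length(ords) + 1L]] <<- acc; return(invisible()) }
            for (q in seq_along(v)) permute(v[-q], c(acc, v[q]))
        }
        permute(idx, integer(0))
        lapply(ords, function(o) pos[o])
    }
    sdnd <- matrix(NA_real_, length(perms), 2L)
    for (p in seq_along(perms)) {
        cur <- a
        sdp <- 0; ndp <- 0; blocked <- FALSE
        for (site in perms[[p]]) {
            nxt <- cur; nxt[site] <- b[site]
            aaCur <- gc[[paste(cur, collapse = "")]]
            aaNxt <- gc[[paste(nxt, collapse = "")]]
            if (aaNxt == "*") { blocked <- TRUE; break }
            if (aaCur == aaNxt) sdp <- sdp + 1 else ndp <- ndp + 1
            cur <- nxt
        }
        if (!blocked) sdnd[p, ] <- c(sdp, ndp)
    }
    ok <- !is.na(sdnd[, 1L])
    if (!any(ok)) {
        ## every minimal pathway runs through a stop; count all steps as
        ## nonsynonymous (conservative; cannot occur between close paralogs)
        out <- c(sd = 0, nd = k)
    } else {
        out <- c(sd = mean(sdnd[ok, 1L]), nd = mean(sdnd[ok, 2L]))
    }
    .codonEnv[[key]] <- out
    out
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each aligned residue is replaced by its codon from the matching CDS, and
#' each protein gap by `---`. Every CDS must be exactly 3x the ungapped
#' protein length (a trailing stop codon is tolerated and dropped) and must
#' translate to the protein; the first discordant codon is reported
#' otherwise.
#'
#' @param msa Named character vector of aligned protein sequences.
#' @param cds Named character vector or [Biostrings::DNAStringSet] of coding
#'   sequences covering every name in `msa`.
#' @return Named character vector of codon-aligned nucleotide sequences.
#' @export
backtranslateAlignment <- function(msa, cds) {
    msa <- asNamedChar(msa)
    cds <- asNamedChar(cds)
    if (is.null(names(msa))) stop("protein alignment must be named")
    miss <- setdiff(names(msa), names(cds))
    if (length(miss)) stop("no CDS for: ", paste(miss, collapse = ", "))
    gc <- geneticCode()
    out <- vapply(names(msa), function(id) {
        prot <- gsub("-", "", msa[[id]])
        dna <- cds[[id]]
        nCod <- nchar(dna) %/% 3
        if (nchar(dna) %% 3 != 0)
            stop("CDS length of ", id, " is not a multiple of 3")
        codons <- substring(dna, 3 * seq_len(nCod) - 2, 3 * seq_len(nCod))
        if (nCod == nchar(prot) + 1L && gc[[codons[nCod]]] == "*")
            codons <- codons[-nCod]
        if (length(codons) != nchar(prot))
            stop("CDS of ", id, " has ", length(codons),
                 " codons but the protein has ", nchar(prot), " residues")
        aas <- unname(gc[codons])
        res <- strsplit(prot, "")[[1]]
        bad <- which(aas != res)
        if (length(bad))
            stop("translation mismatch for ", id, " at codon ", bad[1L],
                 " (", codons[bad[1L]], " -> ", aas[bad[1L]], ", expected ",
                 res[bad[1L]], ")")
        ci <- 0L
        aligned <- vapply(strsplit(msa[[id]], "")[[1]], function(ch) {
            if (ch == "-") return("---")
            ci <<- ci + 1L
            codons[ci]
        }, character(1))
        paste(aligned, collapse = "")
    }, character(1))
    stats::setNames(out, names(msa))
}

#' Nei-Gojobori (1986) Ka/Ks for a codon-aligned pair
#'
#' Synonymous site fractions are averaged over the two sequences; multi-
#' substitution codons are averaged over all minimal substitution pathways
#' (stop-codon pathways excluded); proportions are Jukes-Cantor corrected,
#' `d = -(3/4) ln(1 - (4/3) p)`. Codon columns containing a gap in either
#' sequence are excluded from all counts.
#'
#' @param codonA,codonB Codon-aligned nucleotide strings of equal length
#'   (multiple of 3; gaps as `---`).
#' @return A list: `ka`, `ks`, `ratio` (NA when undefined), site counts `n`
#'   and `s`, difference counts `nd` and `sd`, `codons` compared, and
#'   `flags`.
#' @export
ng86KaKs <- function(codonA, codonB) {
    codonA <- toupper(as.character(codonA))
    codonB <- toupper(as.character(codonB))
    if (nchar(codonA) != nchar(codonB))
        stop("codon alignments must have equal length")
    if (nchar(codonA) %% 3 != 0) stop("alignment length must be a multiple of 3")
    nCod <- nchar(codonA) %/% 3
    ca <- substring(codonA, 3 * seq_len(nCod) - 2, 3 * seq_len(nCod))
    cb <- substring(codonB, 3 * seq_len(nCod) - 2, 3 * seq_len(nCod))
    hasGap <- grepl("-", ca, fixed = TRUE) | grepl("-", cb, fixed = TRUE)
    ca <- ca[!hasGap]; cb <- cb[!hasGap]
    if (length(ca) == 0L) stop("no gap-free codon columns to compare")

    S <- 0; Nd <- 0; Sd <- 0
    for (k in seq_along(ca)) {
        S <- S + (sum(codonSynFraction(ca[k])) + sum(codonSynFraction(cb[k]))) / 2
        d <- codonDifferences(ca[k], cb[k])
        Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
    }
    N <- 3 * length(ca) - S
    pN <- Nd / N; pS <- Sd / S

    flags <- character(0)
    jc <- function(p) {
        if (p >= 0.75) return(NA_real_)
        -0.75 * log(1 - 4 * p / 3)
    }
    ka <- jc(pN); ks <- jc(pS)
    if (is.na(ka) || is.na(ks)) flags <- c(flags, "saturated")
    ratio <- NA_real_
    if (!is.na(ka) && !is.na(ks)) {
        if (ks == 0) flags <- c(flags, "undefined_ratio")
        else ratio <- ka / ks
    }
    list(ka = ka, ks = ks, ratio = ratio, n = N, s = S, nd = unname(Nd),
         sd = unname(Sd), codons = length(ca),
         flags = paste(flags, collapse = ","))
}

## ---------------------------------------------------------------------------
## Duplicate pair detection

#' Detect duplicate gene pairs within families
#'
#' All-vs-all global alignment within each family; a pair qualifies when the
#' residue-to-residue aligned span exceeds `dup_coverage` percent of the
#' longer sequence and the alignment identity exceeds `dup_identity` percent
#' (both strict, defaults 70/70). Chains of qualifying pairs among tightly
#' linked genes (same linkage group, within the tandem distance) are
#' collapsed to single best-partner events, greedily by identity with a
#' deterministic lexicographic tie-break, so one local duplication is
#' reported once.
#'
#' @param proteins Named `AAStringSet` or character vector.
#' @param families Named character vector of family labels (only members of
#'   the same family are compared; label `"none"` is skipped).
#' @param anchors Anchor table (`gene_id`, `linkage_group`, `position`) or
#'   `NULL`; genes missing from the table get `same_chromosome = NA`.
#' @param config See [defaultConfig()].
#' @return data.frame with one row per duplicate pair: `gene1`, `gene2`
#'   (lexicographic order), `family`, `identity`, `coverage`,
#'   `same_chromosome`, `distance_bp`, `tandem`.
#' @export
findDuplicatePairs <- function(proteins, families, anchors = NULL,
                               config = defaultConfig()) {
    seqs <- asNamedChar(proteins)
    if (is.null(names(seqs))) stop("proteins must be named")
    families <- families[names(seqs)]
    rows <- list()
    for (fam in setdiff(unique(families), c(NA, "none"))) {
        ids <- names(seqs)[!is.na(families) & families == fam]
        if (length(ids) < 2L) next
        for (i in seq_len(length(ids) - 1L)) for (j in (i + 1L):length(ids)) {
            aln <- nwAlign(seqs[[ids[i]]], seqs[[ids[j]]],
                           gapOpen = config$gap_open,
                           gapExtend = config$gap_extend)
            if (aln$coverage > config$dup_coverage &&
                aln$identity > config$dup_identity) {
                pair <- sort(c(ids[i], ids[j]))
                rows[[length(rows) + 1L]] <- data.frame(
                    gene1 = pair[1L], gene2 = pair[2L], family = fam,
                    identity = aln$identity, coverage = aln$coverage,
                    stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(rows)) {
        out <- data.frame(gene1 = character(0), gene2 = character(0),
                          family = character(0), identity = numeric(0),
                          coverage = numeric(0), same_chromosome = logical(0),
                          distance_bp = numeric(0), tandem = logical(0))
        return(out)
    }
    pairs <- do.call(rbind, rows)

    loc <- locateGenes(unique(c(pairs$gene1, pairs$gene2)), anchors)
    pairs$same_chromosome <- loc$lg[pairs$gene1] == loc$lg[pairs$gene2]
    pairs$distance_bp <- ifelse(isTRUE_vec(pairs$same_chromosome),
                                abs(loc$pos[pairs$gene1] - loc$pos[pairs$gene2]),
                                NA_real_)

    ## collapse tightly linked chains to one event per local cluster
    tight <- !is.na(pairs$same_chromosome) & pairs$same_chromosome &
        !is.na(pairs$distance_bp) &
        pairs$distance_bp <= config$tandem_max_distance
    keep <- rep(TRUE, nrow(pairs))
    if (any(tight)) {
        tp <- which(tight)
        ord <- tp[order(-pairs$identity[tp], pairs$gene1[tp], pairs$gene2[tp])]
        used <- character(0)
        for (k in ord) {
            g <- c(pairs$gene1[k], pairs$gene2[k])
            if (any(g %in% used)) keep[k] <- FALSE
            else used <- c(used, g)
        }
    }
    dropped <- sum(!keep)
    if (dropped)
        mcLog("findDuplicatePairs: collapsed %d tightly linked pair(s) into best-partner events",
              dropped)
    pairs <- pairs[keep, , drop = FALSE]
    pairs$tandem <- vapply(seq_len(nrow(pairs)), function(k)
        classifyTandem(c(pairs$gene1[k], pairs$gene2[k]), anchors,
                       config$tandem_max_distance), logical(1))
    rownames(pairs) <- NULL
    mcLog("findDuplicatePairs: %d pair(s) pass coverage > %g%% and identity > %g%%",
          nrow(pairs), config$dup_coverage, config$dup_identity)
    pairs
}

isTRUE_vec <- function(x) !is.na(x) & x

locateGenes <- function(ids, anchors) {
    lg <- stats::setNames(rep(NA_character_, length(ids)), ids)
    pos <- stats::setNames(rep(NA_real_, length(ids)), ids)
    if (!is.null(anchors)) {
        hit <- match(ids, anchors$gene_id)
        lg[!is.na(hit)] <- anchors$linkage_group[hit[!is.na(hit)]]
        pos[!is.na(hit)] <- anchors$position[hit[!is.na(hit)]]
        if (anyNA(hit))
            mcLog("locateGenes: %d gene(s) missing from the anchor table",
                  sum(is.na(hit)))
    }
    list(lg = lg, pos = pos)
}

#' Classify a duplicate pair as tandem
#'
#' Tandem iff both genes anchor to the same linkage group within
#' `maxDistance` base pairs (default 100 kb). Pairs with unknown location
#' are classified `FALSE`.
#'
#' @param pair Character vector of two gene ids.
#' @param anchors Anchor table.
#' @param maxDistance Maximum separation in bp.
#' @return Logical scalar.
#' @export
classifyTandem <- function(pair, anchors, maxDistance = 1e5) {
    loc <- locateGenes(pair, anchors)
    if (anyNA(loc$lg)) return(FALSE)
    loc$lg[[1L]] == loc$lg[[2L]] && abs(loc$pos[[1L]] - loc$pos[[2L]]) <= maxDistance
}

#' Ka/Ks report for detected duplicate pairs
#'
#' For every pair the two proteins are globally aligned, the alignment is
#' back-translated to codons, and NG86 Ka/Ks is computed. Ratios are `NA`
#' (never infinite sentinels) when Ks = 0 or the correction saturates.
#'
#' @param pairs data.frame from [findDuplicatePairs()].
#' @param proteins Named proteins covering all pair members.
#' @param cds Named CDS sequences covering all pair members.
#' @param config See [defaultConfig()].
#' @return `pairs` extended with `ka`, `ks`, `ka_ks`, `purifying` and
#'   `kaks_flags` columns.
#' @export
pairKaksReport <- function(pairs, proteins, cds, config = defaultConfig()) {
    if (nrow(pairs) == 0L) {
        pairs$ka <- numeric(0); pairs$ks <- numeric(0)
        pairs$ka_ks <- numeric(0); pairs$purifying <- logical(0)
        pairs$kaks_flags <- character(0)
        return(pairs)
    }
    seqs <- asNamedChar(proteins)
    cds <- asNamedChar(cds)
    res <- lapply(seq_len(nrow(pairs)), function(k) {
        g1 <- pairs$gene1[k]; g2 <- pairs$gene2[k]
        aln <- nwAlign(seqs[[g1]], seqs[[g2]],
                       gapOpen = config$gap_open, gapExtend = config$gap_extend)
        msa <- stats::setNames(c(aln$alignedA, aln$alignedB), c(g1, g2))
        cod <- backtranslateAlignment(msa, cds[c(g1, g2)])
        ng86KaKs(cod[[1L]], cod[[2L]])
    })
    pairs$ka <- vapply(res, `[[`, numeric(1), "ka")
    pairs$ks <- vapply(res, `[[`, numeric(1), "ks")
    pairs$ka_ks <- vapply(res, `[[`, numeric(1), "ratio")
    pairs$purifying <- isTRUE_vec(pairs$ka_ks < 1)
    pairs$kaks_flags <- vapply(res, `[[`, character(1), "flags")
    pairs
}
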