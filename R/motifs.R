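## Motif grammar and family classification
##
## The three-tier kinase families are defined by short degenerate motifs:
## MAPKs by the dual-phosphorylation activation loop in its full context
## -T(E/D)YVxTRWYRAPE(L/V)-, MAPKKs by the catalytic site -VGTxxYMSPER-
## together with the active site -D(L/I/V)K- and the phosphorylation target
## -(S/T)xxxxx(S/T)-, and MAPKKKs by exactly one of the MEKK / RAF / ZIK
## subfamily signatures.

#' Compile a degenerate amino-acid motif expression
#'
#' The expression language: plain residue letters match themselves, `x`
#' matches any residue, `(A/B/C)` matches one of the alternatives, and
#' `x{m,n}` is a bounded gap of m to n arbitrary residues. Leading/trailing
#' dashes are decorative and ignored. Compilation errors are raised at
#' construction, not at match time.
#'
#' @param name Motif name.
#' @param expression Degenerate expression, e.g. `"G(T/S)Px(W/Y/F)MAPEV"`.
#' @return A `motif_pattern` object (name, expression, compiled regex).
#' @examples
#' p <- motifPattern("MEKK", "G(T/S)Px(W/Y/F)MAPEV")
#' matchMotif("AAGTPAWMAPEVAA", p)
#' @export
motifPattern <- function(name, expression) {
    expr <- gsub("^-+|-+$", "", expression)
    chars <- strsplit(expr, "")[[1]]
    out <- character(0)
    i <- 1L
    while (i <= length(chars)) {
        ch <- chars[i]
        if (ch == "(") {
            j <- i
            while (j <= length(chars) && chars[j] != ")") j <- j + 1L
            if (j > length(chars))
                stop("motif '", name, "': unbalanced parenthesis in ", expression)
            alt <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
            res <- strsplit(alt, "/", fixed = TRUE)[[1]]
            if (!all(res %in% AA_ALPHABET20))
                stop("motif '", name, "': bad alternative block (", alt, ")")
            out <- c(out, paste0("[", paste(res, collapse = ""), "]"))
            i <- j + 1L
        } else if (ch == "x") {
            if (i < length(chars) && chars[i + 1L] == "{") {
                j <- i + 1L
                while (j <= length(chars) && chars[j] != "}") j <- j + 1L
                if (j > length(chars))
                    stop("motif '", name, "': unbalanced brace in ", expression)
                bound <- paste(chars[(i + 2L):(j - 1L)], collapse = "")
                if (!grepl("^[0-9]+(,[0-9]+)?$", bound))
                    stop("motif '", name, "': bad gap bound {", bound, "}")
                out <- c(out, paste0(".{", bound, "}"))
                i <- j + 1L
            } else {
                out <- c(out, ".")
                i <- i + 1L
            }
        } else if (ch %in% AA_ALPHABET20) {
            out <- c(out, ch)
            i <- i + 1L
        } else {
            stop("motif '", name, "': unexpected character '", ch, "'")
        }
    }
    regex <- paste(out, collapse = "")
    ## validate the regex compiles
    tryCatch(grepl(regex, "A", perl = TRUE),
             error = function(e) stop("motif '", name, "' failed to compile: ",
                                      conditionMessage(e)))
    structure(list(name = name, expression = expression, regex = regex),
              class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
    cat("motif_pattern ", x$name, ": ", x$expression, "  /", x$regex, "/\n",
        sep = "")
    invisible(x)
}

#' The family-defining motif grammar
#'
#' @return A named list of [motifPattern()] objects: the MAPK activation-loop
#'   context, the three MAPKK motifs, the three MAPKKK subfamily signatures
#'   and the C-terminal common-docking (CD) domain.
#' @export
motifGrammar <- function() {
    list(
        mapk_tloop  = motifPattern("mapk_tloop",  "T(E/D)YVxTRWYRAPE(L/V)"),
        mapkk_cat   = motifPattern("mapkk_cat",   "VGTxxYMSPER"),
        mapkk_act   = motifPattern("mapkk_act",   "D(L/I/V)K"),
        mapkk_st    = motifPattern("mapkk_st",    "(S/T)xxxxx(S/T)"),
        mekk        = motifPattern("mekk",        "G(T/S)Px(W/Y/F)MAPEV"),
        raf         = motifPattern("raf",         "GTxx(W/Y)MAPE"),
        zik         = motifPattern("zik",         "GTPEEMAPE(L/V/M)(Y/F/L)"),
        cd_domain   = motifPattern("cd_domain",   "LHDxx(E/D)EPxC")
    )
}

#' Match a motif pattern against a sequence
#'
#' Returns all leftmost non-overlapping matches.
#'
#' @param sequence Uppercase amino-acid string.
#' @param pattern A [motifPattern()].
#' @return data.frame with columns `start`, `end` (1-based, inclusive) and
#'   `match`; zero rows when the motif is absent.
#' @export
matchMotif <- function(sequence, pattern) {
    stopifnot(inherits(pattern, "motif_pattern"))
    assertAaString(sequence)
    hits <- gregexpr(pattern$regex, sequence, perl = TRUE)[[1]]
    if (hits[1] == -1L)
        return(data.frame(start = integer(0), end = integer(0),
                          match = character(0), stringsAsFactors = FALSE))
    len <- attr(hits, "match.length")
    data.frame(start = as.integer(hits),
               end = as.integer(hits) + len - 1L,
               match = substring(sequence, hits, hits + len - 1L),
               stringsAsFactors = FALSE)
}

#' Detect the C-terminal common-docking (CD) domain
#'
#' True only when the -LHDxx(E/D)EPxC- motif occurs in the C-terminal half of
#' the sequence, where the docking site of classified MAPKs resides.
#'
#' @param sequence Uppercase amino-acid string.
#' @param grammar A motif grammar, see [motifGrammar()].
#' @return A list with `present` (logical) and `start` (position or `NA`).
#' @export
detectCdDomain <- function(sequence, grammar = motifGrammar()) {
    m <- matchMotif(sequence, grammar$cd_domain)
    half <- nchar(sequence) / 2
    keep <- m$start > half
    if (!any(keep)) return(list(present = FALSE, start = NA_integer_))
    list(present = TRUE, start = m$start[keep][1L])
}

## which families does a sequence qualify for, under the full rules?
qualifyFamilies <- function(matches) {
    fam <- character(0)
    if (nrow(matches$mapk_tloop)) fam <- c(fam, "MAPK")
    if (nrow(matches$mapkk_cat) && nrow(matches$mapkk_act) &&
        nrow(matches$mapkk_st)) fam <- c(fam, "MAPKK")
    if (nrow(matches$mekk) || nrow(matches$raf) || nrow(matches$zik))
        fam <- c(fam, "MAPKKK")
    fam
}

#' Classify one protein by the motif grammar
#'
#' Families are tested in priority order MAPK, MAPKK, MAPKKK; all motif
#' matches are recorded even when another family wins, and multi-family hits
#' are flagged ambiguous rather than discarded. MAPKKK subfamily signatures
#' are resolved in specificity order MEKK, ZIK, RAF (the RAF consensus is the
#' least specific of the three and is matched by some MEKK instances). A
#' minimum length of 200 aa is enforced as a proxy for the 200-300 aa kinase
#' domain every true family member carries.
#'
#' @param sequence Uppercase amino-acid string (or `AAString`).
#' @param id Identifier used in the result row.
#' @param grammar See [motifGrammar()].
#' @param minLength Minimum sequence length in residues.
#' @return One-row data.frame: `id`, `family` (`MAPK`/`MAPKK`/`MAPKKK`/
#'   `none`), `subfamily` (`MEKK`/`RAF`/`ZIK` or `NA`), `group` (filled by
#'   [assignGroup()]), `loop_type` (`TEY`/`TDY` or `NA`), `cd_domain`,
#'   `length`, `motifs` (collapsed `name:start-end` list) and `flags`.
#' @export
classifyProtein <- function(sequence, id = "query", grammar = motifGrammar(),
                            minLength = 200) {
    sequence <- toupper(as.character(sequence))
    assertAaString(sequence)

    matches <- lapply(grammar, function(p) matchMotif(sequence, p))
    motifStr <- paste(unlist(lapply(names(matches), function(nm) {
        m <- matches[[nm]]
        if (!nrow(m)) return(character(0))
        paste0(nm, ":", m$start, "-", m$end)
    })), collapse = ";")

    flags <- character(0)
    family <- "none"; subfamily <- NA_character_
    loop <- NA_character_; cd <- NA

    if (nchar(sequence) < minLength) {
        flags <- c(flags, "short")
    } else {
        qual <- qualifyFamilies(matches)
        if (length(qual) > 1L) flags <- c(flags, "ambiguous_family")
        if (length(qual)) {
            family <- qual[1L]  # priority MAPK > MAPKK > MAPKKK
            if (family == "MAPK") {
                inst <- matches$mapk_tloop$match[1L]
                loop <- if (substr(inst, 2L, 2L) == "E") "TEY" else "TDY"
                cdHit <- detectCdDomain(sequence, grammar)
                cd <- cdHit$present
            } else if (family == "MAPKKK") {
                subOrder <- c("mekk", "zik", "raf")
                hit <- subOrder[vapply(subOrder,
                                       function(s) nrow(matches[[s]]) > 0L,
                                       logical(1))]
                subfamily <- c(mekk = "MEKK", zik = "ZIK", raf = "RAF")[[hit[1L]]]
                ## a MEKK-signature instance may also satisfy the generic RAF
                ## consensus at the same site; only flag when distinct sites hit
                if (length(hit) > 1L) {
                    starts <- lapply(hit, function(s) matches[[s]]$start)
                    if (length(Reduce(union, starts)) > length(starts[[1L]]))
                        flags <- c(flags, "ambiguous_subfamily")
                }
            }
        }
    }
    data.frame(id = id, family = family, subfamily = subfamily,
               group = "unassigned", loop_type = loop, cd_domain = cd,
               length = nchar(sequence), motifs = motifStr,
               flags = paste(flags, collapse = ","),
               stringsAsFactors = FALSE)
}

#' Classify a set of proteins
#'
#' @param proteins An [Biostrings::AAStringSet] (named) or named character
#'   vector.
#' @inheritParams classifyProtein
#' @return An [S4Vectors::DataFrame] with one row per protein (see
#'   [classifyProtein()] for columns).
#' @export
classifyProteins <- function(proteins, grammar = motifGrammar(),
                             minLength = 200) {
    seqs <- asNamedChar(proteins)
    if (is.null(names(seqs))) stop("proteins must be named")
    rows <- lapply(names(seqs), function(id)
        classifyProtein(seqs[[id]], id = id, grammar = grammar,
                        minLength = minLength))
    out <- S4Vectors::DataFrame(do.call(rbind, rows))
    mcLog("classifyProteins: %d sequences -> %d MAPK, %d MAPKK, %d MAPKKK (min length %d aa)",
          length(seqs), sum(out$family == "MAPK"), sum(out$family == "MAPKK"),
          sum(out$family == "MAPKKK"), minLength)
    out
}

## ---------------------------------------------------------------------------
## Redundancy removal and reference identity screen

#' Remove redundant sequences
#'
#' Among any set of records with pairwise identity and mutual coverage at or
#' above the cutoffs, only the longest is kept (ties broken by lexicographic
#' id). A length prefilter exploits the coverage requirement: two sequences
#' can only be redundant when their lengths differ by at most
#' `100 - coverage` percent.
#'
#' @param records A named [Biostrings::AAStringSet] or character vector.
#' @param identity Percent identity cutoff (default 99).
#' @param coverage Percent mutual coverage cutoff (default 99).
#' @return The deduplicated `AAStringSet`.
#' @export
removeRedundant <- function(records, identity = 99, coverage = 99) {
    seqs <- asNamedChar(records)
    ids <- names(seqs)
    n <- length(seqs)
    if (n < 2L) return(Biostrings::AAStringSet(seqs))
    len <- nchar(seqs)
    parent <- seq_len(n)
    findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    ord <- order(len)
    for (a in seq_len(n - 1L)) {
        i <- ord[a]
        for (b in (a + 1L):n) {
            j <- ord[b]
            if (len[j] * coverage / 100 > len[i]) break  # prefilter on length
            aln <- nwAlign(seqs[[i]], seqs[[j]])
            if (aln$identity >= identity && aln$coverage >= coverage) {
                ri <- findRoot(i); rj <- findRoot(j)
                if (ri != rj) parent[ri] <- rj
            }
        }
    }
    roots <- vapply(seq_len(n), findRoot, integer(1))
    keep <- vapply(split(seq_len(n), roots), function(members) {
        best <- members[len[members] == max(len[members])]
        best[order(ids[best])][1L]
    }, integer(1))
    keep <- sort(unname(keep))
    mcLog("removeRedundant: %d -> %d records (identity >= %g%%, coverage >= %g%%)",
          n, length(keep), identity, coverage)
    out <- Biostrings::AAStringSet(seqs[keep])
    names(out) <- ids[keep]
    out
}

#' Screen candidates by best identity against a reference panel
#'
#' A candidate survives iff its best global-alignment identity against any
#' reference reaches the threshold. Identity is matches over alignment
#' columns (dual-gap columns excluded).
#'
#' @param candidates,references Named [Biostrings::AAStringSet] or character
#'   vectors.
#' @param threshold Percent identity in (0, 100]; default 50.
#' @return The surviving candidates as an `AAStringSet`, with the per-
#'   candidate best identity attached as `metadata(x)$best_identity`.
#' @export
identityScreen <- function(candidates, references, threshold = 50) {
    if (length(references) == 0L) stop("empty reference set")
    if (threshold <= 0 || threshold > 100) stop("threshold must be in (0, 100]")
    cand <- asNamedChar(candidates)
    refs <- asNamedChar(references)
    best <- vapply(cand, function(s) {
        top <- 0
        for (r in refs) {
            top <- max(top, nwAlign(s, r)$identity)
            if (top >= 100) break
        }
        top
    }, numeric(1))
    keep <- best >= threshold
    mcLog("identityScreen: %d candidates, %d survive at >= %g%% identity vs %d references",
          length(cand), sum(keep), threshold, length(refs))
    out <- Biostrings::AAStringSet(cand[keep])
    names(out) <- names(cand)[keep]
    S4Vectors::metadata(out)$best_identity <- best
    out
}

## ---------------------------------------------------------------------------
## Physicochemical properties

.aaMassEnv <- new.env(parent = emptyenv())

aaMassTable <- function() {
    if (is.null(.aaMassEnv$mass)) {
        tab <- readTable(system.file("extdata", "aa_masses.tsv",
                                     package = "mapkcascade"))
        .aaMassEnv$mass <- stats::setNames(tab$average_mass, tab$residue)
    }
    .aaMassEnv$mass
}

pkaTable <- function() {
    if (is.null(.aaMassEnv$pka)) {
        .aaMassEnv$pka <- readTable(system.file("extdata", "pka_bjellqvist.tsv",
                                                package = "mapkcascade"))
    }
    .aaMassEnv$pka
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch over the termini and the ionizable side chains
#' (D, E, C, Y, H, K, R) with the packaged Bjellqvist pKa set.
#'
#' @param sequence Amino-acid string.
#' @param pH pH value(s).
#' @return Net charge (vectorized over `pH`).
#' @export
peptideCharge <- function(sequence, pH) {
    sequence <- toupper(as.character(sequence))
    counts <- table(strsplit(sequence, "")[[1]])
    pka <- pkaTable()
    vapply(pH, function(p) {
        q <- 0
        for (k in seq_len(nrow(pka))) {
            grp <- pka$group[k]
            n <- if (grp == "Nterm" || grp == "Cterm") 1L
                 else as.integer(counts[grp])
            if (is.na(n) || n == 0L) next
            if (pka$sign[k] > 0) q <- q + n / (1 + 10^(p - pka$pka[k]))
            else q <- q - n / (1 + 10^(pka$pka[k] - p))
        }
        q
    }, numeric(1))
}

#' Molecular weight and isoelectric point
#'
#' Mw is the sum of average residue masses plus one water mass; pI is the pH
#' at which the net charge crosses zero, located by bisection to 0.01 pH
#' units. Unknown residues (X) contribute the mean residue mass to Mw and
#' are ignored for pI.
#'
#' @param sequence Amino-acid string.
#' @return A list: `length` (residues), `mw` (Da), `pi` (pH units).
#' @examples
#' computeProperties("GG")$mw  # 132.12 Da
#' @export
computeProperties <- function(sequence) {
    sequence <- toupper(as.character(sequence))
    assertAaString(sequence)
    mass <- aaMassTable()
    res <- strsplit(sequence, "")[[1]]
    if (any(res == "X"))
        mcLog("computeProperties: sequence contains X; mean residue mass used for Mw, ignored for pI")
    mw <- sum(mass[res]) + 18.01524
    piSeq <- paste(res[res != "X"], collapse = "")
    lo <- 0; hi <- 14
    while (hi - lo > 1e-3) {
        mid <- (lo + hi) / 2
        if (peptideCharge(piSeq, mid) > 0) lo <- mid else hi <- mid
    }
    list(length = length(res), mw = unname(mw), pi = (lo + hi) / 2)
}
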