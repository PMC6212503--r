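## Promoter extraction and cis-element scanning.
##
## Promoters are the 1.5 kb of genomic sequence immediately upstream of the
## translation start (ATG), on the coding strand. Scanning is dictionary
## based: each element is a named IUPAC consensus, matched exactly (with
## IUPAC expansion) on both strands.

#' Read a cis-element dictionary
#'
#' @param path TSV with columns `name`, `consensus`, `annotation`. Names
#'   must be unique and consensus strings drawn from the IUPAC nucleotide
#'   alphabet.
#' @return A data.frame of class `element_dictionary`.
#' @export
readElementDictionary <- function(path) {
    tab <- readTable(path)
    need <- c("name", "consensus", "annotation")
    if (!all(need %in% names(tab)))
        stop("element dictionary needs columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(tab$name)) stop("element names must be unique")
    tab$consensus <- toupper(tab$consensus)
    bad <- grepl("[^ACGTRYSWKMBDHVN]", tab$consensus)
    if (any(bad))
        stop("non-IUPAC consensus for element(s): ",
             paste(tab$name[bad], collapse = ", "))
    class(tab) <- c("element_dictionary", "data.frame")
    tab
}

#' The packaged cis-element dictionary
#'
#' Consensus strings for the stress- and hormone-responsive elements the
#' pipeline reports (HSE, ARE, LTR, ABRE, CGTCA-motif, TGACG-motif, ERE,
#' TCA-element, W-box, TC-rich repeats), shipped as an editable TSV under
#' `inst/extdata`. Note that the CGTCA- and TGACG-motifs are reverse
#' complements of one another, so a double-strand scan reports both at every
#' occurrence of either, mirroring how plant promoter databases report this
#' element pair.
#'
#' @return A data.frame of class `element_dictionary`.
#' @export
defaultElementDictionary <- function() {
    readElementDictionary(system.file("extdata", "cis_elements.tsv",
                                      package = "mapkcascade"))
}

#' Extract the upstream promoter region of a gene
#'
#' Returns the `length` bases 5' of the translation start on the coding
#' strand: for plus-strand genes the sequence immediately left of the gene
#' start; for minus-strand genes the reverse complement of the flank right
#' of the gene end. Regions running off the contig edge are truncated and
#' the realized length flagged.
#'
#' @param gene A single-range [GenomicRanges::GRanges] (strand set) or a
#'   list with `seqid`, `strand`, `start`, `end`.
#' @param genome A named [Biostrings::DNAStringSet].
#' @param length Promoter length in bp (default 1500).
#' @return A character scalar; `attr(x, "truncated")` is TRUE when the
#'   contig edge cut the window short.
#' @export
extractUpstream <- function(gene, genome, length = 1500) {
    if (methods::is(gene, "GRanges")) {
        seqid <- as.character(GenomicRanges::seqnames(gene))[1L]
        strand <- as.character(GenomicRanges::strand(gene))[1L]
        gstart <- GenomicRanges::start(gene)[1L]
        gend <- GenomicRanges::end(gene)[1L]
    } else {
        seqid <- gene$seqid; strand <- gene$strand
        gstart <- gene$start; gend <- gene$end
    }
    if (!seqid %in% names(genome)) stop("contig not in genome: ", seqid)
    contig <- genome[[seqid]]
    clen <- Biostrings::nchar(contig)
    if (strand == "-") {
        from <- gend + 1L
        to <- min(clen, gend + length)
        if (to < from) seq <- Biostrings::DNAString("")
        else seq <- Biostrings::reverseComplement(
            Biostrings::subseq(contig, from, to))
    } else {
        to <- gstart - 1L
        from <- max(1L, gstart - length)
        if (to < from) seq <- Biostrings::DNAString("")
        else seq <- Biostrings::subseq(contig, from, to)
    }
    out <- as.character(seq)
    attr(out, "truncated") <- nchar(out) < length
    if (nchar(out) < length)
        mcLog("extractUpstream: promoter truncated to %d bp at contig edge",
              nchar(out))
    out
}

#' Scan a promoter against a cis-element dictionary
#'
#' Every occurrence of each consensus (IUPAC-expanded) is counted on both
#' strands, one count per distinct (element, start, strand). A palindromic
#' consensus matching the same position on both strands is counted once.
#'
#' @param promoter Nucleotide string.
#' @param dictionary An element dictionary, see [defaultElementDictionary()].
#' @return A list: `counts` (named integer per element), `presence` (named
#'   logical), `positions` (data.frame `element`, `start`, `strand`;
#'   1-based starts on the forward promoter coordinate), and
#'   `promoter_length`.
#' @export
scanElements <- function(promoter, dictionary = defaultElementDictionary()) {
    promoter <- toupper(as.character(promoter))
    n <- nrow(dictionary)
    counts <- stats::setNames(integer(n), dictionary$name)
    posRows <- list()
    if (nzchar(promoter) && n > 0L) {
        subject <- Biostrings::DNAString(promoter)
        for (k in seq_len(n)) {
            pat <- Biostrings::DNAString(dictionary$consensus[k])
            fwd <- Biostrings::start(
                Biostrings::matchPattern(pat, subject, fixed = FALSE))
            rcp <- Biostrings::reverseComplement(pat)
            rev <- Biostrings::start(
                Biostrings::matchPattern(rcp, subject, fixed = FALSE))
            if (as.character(rcp) == as.character(pat)) rev <- integer(0)
            if (length(fwd))
                posRows[[length(posRows) + 1L]] <- data.frame(
                    element = dictionary$name[k], start = fwd, strand = "+",
                    stringsAsFactors = FALSE)
            if (length(rev))
                posRows[[length(posRows) + 1L]] <- data.frame(
                    element = dictionary$name[k], start = rev, strand = "-",
                    stringsAsFactors = FALSE)
            counts[k] <- length(fwd) + length(rev)
        }
    }
    positions <- if (length(posRows)) do.call(rbind, posRows)
    else data.frame(element = character(0), start = integer(0),
                    strand = character(0), stringsAsFactors = FALSE)
    list(counts = counts, presence = counts >= 1L, positions = positions,
         promoter_length = nchar(promoter))
}

#' Scan all gene promoters of a genome
#'
#' @param models Gene models (list with `genes`), e.g. from
#'   [readGff3GeneModels()] or [geneModels()].
#' @param genome Named [Biostrings::DNAStringSet].
#' @param dictionary Element dictionary.
#' @param length Promoter length in bp.
#' @return Named list of [scanElements()] results, one per gene.
#' @export
scanAllPromoters <- function(models, genome,
                             dictionary = defaultElementDictionary(),
                             length = 1500) {
    genes <- models$genes
    out <- lapply(seq_along(genes), function(k) {
        prom <- extractUpstream(genes[k], genome, length)
        scanElements(prom, dictionary)
    })
    names(out) <- genes$gene_id
    mcLog("scanAllPromoters: %d promoters x %d elements (window %d bp)",
          length(out), nrow(dictionary), length)
    out
}

#' Presence matrix and per-family prevalence of cis-elements
#'
#' @param scans Named list of [scanElements()] results.
#' @param familyLabels Named character vector of family labels per gene;
#'   genes without a label are summarized in an `"unassigned"` stratum.
#' @return A list: `presence` (genes x elements logical matrix), `counts`
#'   (genes x elements integer matrix) and `prevalence` (data.frame
#'   `family`, `element`, `genes_with_element`, `family_size`).
#' @export
presenceMatrix <- function(scans, familyLabels = NULL) {
    if (!length(scans))
        stop("no scan results supplied")
    elements <- names(scans[[1L]]$counts)
    counts <- t(vapply(scans, function(s) s$counts[elements],
                       numeric(length(elements))))
    if (is.null(dim(counts)))
        counts <- matrix(counts, nrow = length(scans), byrow = TRUE,
                         dimnames = list(names(scans), elements))
    colnames(counts) <- elements
    rownames(counts) <- names(scans)
    presence <- counts >= 1L
    fams <- rep("unassigned", length(scans))
    names(fams) <- names(scans)
    if (!is.null(familyLabels)) {
        hit <- intersect(names(scans), names(familyLabels))
        fams[hit] <- familyLabels[hit]
        fams[is.na(fams)] <- "unassigned"
    }
    prev <- if (length(elements) == 0L) {
        data.frame(family = character(0), element = character(0),
                   genes_with_element = integer(0),
                   family_size = integer(0), stringsAsFactors = FALSE)
    } else do.call(rbind, lapply(unique(fams), function(f) {
        rows <- presence[fams == f, , drop = FALSE]
        data.frame(family = f, element = elements,
                   genes_with_element = colSums(rows),
                   family_size = nrow(rows), stringsAsFactors = FALSE)
    }))
    rownames(prev) <- NULL
    list(presence = presence, counts = counts, prevalence = prev)
}
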