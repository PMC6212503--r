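#' Read a protein FASTA into an AAStringSet
#'
#' Sequences are uppercased on read; duplicate identifiers and empty
#' sequences are rejected, and the alphabet is restricted to the 20 standard
#' residues plus X.
#'
#' @param path Path to a FASTA file.
#' @return An [Biostrings::AAStringSet] named by the first whitespace-
#'   delimited token of each header; full headers are kept in
#'   `metadata(x)$description`.
#' @export
readProteinFasta <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop("FASTA file contains no records: ", path)
    desc <- names(set)
    ids <- vapply(strsplit(desc, "\\s+"), `[`, character(1), 1L)
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
        stop("duplicate sequence id(s) in ", path, ": ", paste(dup, collapse = ", "))
    seqs <- toupper(as.character(set))
    if (any(!nzchar(seqs))) {
        bad <- ids[!nzchar(seqs)]
        stop("empty sequence for record(s): ", paste(bad, collapse = ", "))
    }
    badChar <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), seqs)
    if (any(badChar))
        stop("non amino-acid characters in record(s): ",
             paste(ids[badChar], collapse = ", "))
    out <- Biostrings::AAStringSet(seqs)
    names(out) <- ids
    S4Vectors::metadata(out)$description <- stats::setNames(desc, ids)
    out
}

#' Read a nucleotide FASTA into a DNAStringSet
#'
#' @inheritParams readProteinFasta
#' @return A [Biostrings::DNAStringSet]; sequences uppercased, duplicate ids
#'   rejected.
#' @export
readDnaFasta <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop("FASTA file contains no records: ", path)
    ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
        stop("duplicate sequence id(s) in ", path, ": ", paste(dup, collapse = ", "))
    seqs <- toupper(as.character(set))
    if (any(!nzchar(seqs))) stop("empty sequence in ", path)
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- ids
    out
}

#' Write sequences to FASTA
#'
#' @param x An `XStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path) {
    Biostrings::writeXStringSet(x, filepath = path)
    invisible(path)
}

## ---------------------------------------------------------------------------
## Gene models (GFF3)

#' Read GFF3 gene models
#'
#' Parses gene/mRNA/exon features into one gene model per mRNA. Coordinates
#' follow the GFF3 convention (1-based, inclusive) throughout the package;
#' minus-strand genes keep ascending genomic coordinates with the strand
#' recorded separately. Exons are validated to lie within their parent gene
#' span and to be non-overlapping.
#'
#' @param path Path to a GFF3 file.
#' @return A list with elements `genes` (a [GenomicRanges::GRanges] with one
#'   range per mRNA, metadata columns `gene_id` and `mrna_id`) and `exons`
#'   (a [GenomicRanges::GRangesList] named by `gene_id`, exons sorted in
#'   genomic order).
#' @export
readGff3GeneModels <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    gr <- rtracklayer::import(path, format = "gff3")
    geneModelsFromGRanges(gr)
}

geneModelsFromGRanges <- function(gr) {
    type <- as.character(gr$type)
    genes <- gr[type == "gene"]
    mrnas <- gr[type == "mRNA"]
    exons <- gr[type == "exon"]
    if (length(genes) == 0L) stop("GFF3 contains no gene features")
    if (length(mrnas) == 0L) stop("GFF3 contains no mRNA features")
    mrnaParent <- vapply(mrnas$Parent, function(p) {
        if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
    }, character(1))
    if (anyNA(mrnaParent)) stop("mRNA feature without Parent attribute")
    exonParent <- vapply(exons$Parent, function(p) {
        if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
    }, character(1))
    if (anyNA(exonParent)) stop("exon feature without Parent attribute")

    geneIds <- as.character(genes$ID)
    geneIdx <- stats::setNames(seq_along(genes), geneIds)
    out <- GenomicRanges::GRanges()
    exonList <- list()
    for (k in seq_along(mrnas)) {
        gid <- mrnaParent[k]
        if (!gid %in% geneIds) stop("mRNA Parent not found among genes: ", gid)
        g <- genes[geneIdx[[gid]]]
        mid <- as.character(mrnas$ID[k])
        ex <- exons[exonParent == mid]
        if (length(ex) == 0L) stop("mRNA without exons: ", mid)
        ex <- GenomicRanges::sort(ex)
        if (any(GenomicRanges::start(ex) < GenomicRanges::start(g)) ||
            any(GenomicRanges::end(ex) > GenomicRanges::end(g)))
            stop("exon outside parent gene span for gene ", gid)
        if (length(ex) > 1L) {
            s <- GenomicRanges::start(ex); e <- GenomicRanges::end(ex)
            if (any(s[-1L] <= e[-length(e)]))
                stop("overlapping exons for gene ", gid)
        }
        rng <- GenomicRanges::GRanges(
            GenomicRanges::seqnames(g),
            IRanges::IRanges(GenomicRanges::start(g), GenomicRanges::end(g)),
            strand = GenomicRanges::strand(g))
        rng$gene_id <- gid
        rng$mrna_id <- mid
        out <- c(out, rng)
        GenomicRanges::mcols(ex) <- NULL
        exonList[[gid]] <- ex
    }
    list(genes = out, exons = GenomicRanges::GRangesList(exonList))
}

#' Write gene models to GFF3
#'
#' @param models A gene-model list as returned by [readGff3GeneModels()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGff3GeneModels <- function(models, path) {
    genes <- models$genes
    feats <- GenomicRanges::GRanges()
    for (k in seq_along(genes)) {
        g <- genes[k]
        gid <- g$gene_id
        mid <- g$mrna_id
        ex <- models$exons[[gid]]
        gene <- GenomicRanges::granges(g)
        gene$type <- "gene"; gene$ID <- gid
        gene$Parent <- IRanges::CharacterList(character(0))
        mrna <- GenomicRanges::granges(g)
        mrna$type <- "mRNA"; mrna$ID <- mid
        mrna$Parent <- IRanges::CharacterList(gid)
        exf <- GenomicRanges::granges(ex)
        GenomicRanges::strand(exf) <- GenomicRanges::strand(g)
        exf$type <- "exon"
        exf$ID <- paste0(mid, ".exon", seq_along(exf))
        exf$Parent <- IRanges::CharacterList(as.list(rep(mid, length(exf))))
        feats <- c(feats, gene, mrna, exf)
    }
    feats$type <- factor(feats$type, levels = c("gene", "mRNA", "exon"))
    rtracklayer::export(feats, path, format = "gff3")
    invisible(path)
}

## ---------------------------------------------------------------------------
## Tables

#' Read / write tabular results
#'
#' Deterministic column order, UTF-8, tab- or comma-separated. Written files
#' round-trip through the matching reader.
#'
#' @param rows A data.frame.
#' @param path File path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return `writeTable` returns `path` invisibly; `readTable` returns a
#'   data.frame.
#' @export
writeTable <- function(rows, path, format = c("tsv", "csv")) {
    format <- match.arg(format)
    if (!is.data.frame(rows)) stop("rows must be a data.frame")
    sep <- if (format == "tsv") "\t" else ","
    write.table(rows, path, sep = sep, quote = FALSE,
                row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
    invisible(path)
}

#' @rdname writeTable
#' @export
readTable <- function(path, format = c("tsv", "csv")) {
    format <- match.arg(format)
    sep <- if (format == "tsv") "\t" else ","
    read.delim(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE,
               fileEncoding = "UTF-8")
}

#' Read a gene anchor table
#'
#' The anchor table places each gene on a linkage group at a base-pair
#' position; one row per gene.
#'
#' @param path Path to a TSV with columns `gene_id`, `linkage_group`,
#'   `position`.
#' @return A data.frame.
#' @export
readAnchorTable <- function(path) {
    tab <- readTable(path)
    need <- c("gene_id", "linkage_group", "position")
    if (!all(need %in% names(tab)))
        stop("anchor table must have columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(tab$gene_id))
        stop("anchor table has duplicated gene_id rows")
    tab$position <- as.numeric(tab$position)
    tab
}

## ---------------------------------------------------------------------------
## Interval convention conversion

#' Convert between 1-based inclusive ranges and BED-style intervals
#'
#' Internally all coordinates are GFF3-style (1-based, inclusive).
#' `toBedFrame` exports 0-based half-open intervals; `fromBedFrame` converts
#' back.
#'
#' @param gr A [GenomicRanges::GRanges].
#' @param df A data.frame with columns `chrom`, `start`, `end`, and
#'   optionally `name`, `strand`.
#' @return `toBedFrame` returns a data.frame; `fromBedFrame` a `GRanges`.
#' @export
toBedFrame <- function(gr) {
    data.frame(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr) - 1L,
        end = GenomicRanges::end(gr),
        name = if (!is.null(gr$gene_id)) gr$gene_id else
            if (!is.null(names(gr))) names(gr) else rep(".", length(gr)),
        strand = as.character(GenomicRanges::strand(gr)),
        stringsAsFactors = FALSE)
}

#' @rdname toBedFrame
#' @export
fromBedFrame <- function(df) {
    gr <- GenomicRanges::GRanges(
        df$chrom,
        IRanges::IRanges(df$start + 1L, df$end),
        strand = if ("strand" %in% names(df)) df$strand else "*")
    if ("name" %in% names(df)) gr$gene_id <- df$name
    gr
}
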