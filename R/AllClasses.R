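#' MapkCorpus: a self-contained miniature study
#'
#' An S4 container holding everything the pipeline consumes for one study:
#' the candidate proteome (planted family members plus decoys), the labeled
#' reference panel, coding sequences, the genome with gene models and anchor
#' table, tissue and cold-stress count matrices with declared library sizes,
#' and a qRT-PCR Ct table. The generator's planted labels live in the
#' `truth` slot; analysis stages take only the public slots, and
#' [writeCorpus()] writes the truth to a separate file that no reader of the
#' public corpus touches.
#'
#' @slot proteome [Biostrings::AAStringSet] of candidate proteins.
#' @slot referencePanel [Biostrings::AAStringSet] of labeled references
#'   (names of the form `REF_<FAMILY>_<GROUP>`).
#' @slot cds [Biostrings::DNAStringSet] of coding sequences (stop codon
#'   included) for the family genes.
#' @slot genome [Biostrings::DNAStringSet] of linkage-group sequences.
#' @slot genes [GenomicRanges::GRanges], one range per gene.
#' @slot exons [GenomicRanges::GRangesList] of exons per gene.
#' @slot anchors data.frame with `gene_id`, `linkage_group`, `position`.
#' @slot tissueCounts integer matrix, genes x tissues.
#' @slot coldCounts integer matrix, genes x cold time points.
#' @slot geneLengths named numeric, effective transcript length (bp).
#' @slot librarySize named numeric, declared library size per sample.
#' @slot ctTable data.frame of qRT-PCR Ct values.
#' @slot truth list of planted labels (never read by analysis stages).
#' @slot params the [generatorParams()] list that produced the corpus.
#'
#' @aliases MapkCorpus
#' @name MapkCorpus-class
#' @export
setClass("MapkCorpus", representation(
    proteome = "AAStringSet",
    referencePanel = "AAStringSet",
    cds = "DNAStringSet",
    genome = "DNAStringSet",
    genes = "GRanges",
    exons = "GRangesList",
    anchors = "data.frame",
    tissueCounts = "matrix",
    coldCounts = "matrix",
    geneLengths = "numeric",
    librarySize = "numeric",
    ctTable = "data.frame",
    truth = "list",
    params = "list"
))

setValidity("MapkCorpus", function(object) {
    msgs <- character(0)
    if (anyDuplicated(names(object@proteome)))
        msgs <- c(msgs, "duplicated protein ids")
    gids <- object@genes$gene_id
    if (length(gids) && !all(gids %in% names(object@proteome)))
        msgs <- c(msgs, "gene models name proteins absent from the proteome")
    if (length(object@cds) && !all(names(object@cds) %in% names(object@proteome)))
        msgs <- c(msgs, "CDS ids absent from the proteome")
    if (nrow(object@tissueCounts) &&
        !all(rownames(object@tissueCounts) %in% names(object@proteome)))
        msgs <- c(msgs, "tissue count rows absent from the proteome")
    if (length(msgs)) msgs else TRUE
})

#' @describeIn MapkCorpus-class Candidate proteome.
#' @param x,object A `MapkCorpus`.
#' @export
setGeneric("proteome", function(x) standardGeneric("proteome"))
#' @export
setMethod("proteome", "MapkCorpus", function(x) x@proteome)

#' @describeIn MapkCorpus-class Labeled reference panel.
#' @export
setGeneric("referencePanel", function(x) standardGeneric("referencePanel"))
#' @export
setMethod("referencePanel", "MapkCorpus", function(x) x@referencePanel)

#' @describeIn MapkCorpus-class Coding sequences.
#' @export
setGeneric("cdsSeqs", function(x) standardGeneric("cdsSeqs"))
#' @export
setMethod("cdsSeqs", "MapkCorpus", function(x) x@cds)

#' @describeIn MapkCorpus-class Linkage-group sequences.
#' @export
setGeneric("genomeSeqs", function(x) standardGeneric("genomeSeqs"))
#' @export
setMethod("genomeSeqs", "MapkCorpus", function(x) x@genome)

#' @describeIn MapkCorpus-class Gene models (list with `genes` and `exons`).
#' @export
setGeneric("geneModels", function(x) standardGeneric("geneModels"))
#' @export
setMethod("geneModels", "MapkCorpus", function(x)
    list(genes = x@genes, exons = x@exons))

#' @describeIn MapkCorpus-class Gene anchor table.
#' @export
setGeneric("anchorTable", function(x) standardGeneric("anchorTable"))
#' @export
setMethod("anchorTable", "MapkCorpus", function(x) x@anchors)

#' @describeIn MapkCorpus-class Tissue count matrix.
#' @export
setGeneric("tissueCounts", function(x) standardGeneric("tissueCounts"))
#' @export
setMethod("tissueCounts", "MapkCorpus", function(x) x@tissueCounts)

#' @describeIn MapkCorpus-class Cold-stress count matrix.
#' @export
setGeneric("coldCounts", function(x) standardGeneric("coldCounts"))
#' @export
setMethod("coldCounts", "MapkCorpus", function(x) x@coldCounts)

#' @describeIn MapkCorpus-class Effective transcript lengths (bp).
#' @export
setGeneric("geneLengths", function(x) standardGeneric("geneLengths"))
#' @export
setMethod("geneLengths", "MapkCorpus", function(x) x@geneLengths)

#' @describeIn MapkCorpus-class Declared per-sample library sizes.
#' @export
setGeneric("librarySizes", function(x) standardGeneric("librarySizes"))
#' @export
setMethod("librarySizes", "MapkCorpus", function(x) x@librarySize)

#' @describeIn MapkCorpus-class qRT-PCR Ct table.
#' @export
setGeneric("ctTable", function(x) standardGeneric("ctTable"))
#' @export
setMethod("ctTable", "MapkCorpus", function(x) x@ctTable)

#' @describeIn MapkCorpus-class Planted truth labels. Test/audit use only:
#'   analysis stages must not consume this.
#' @export
setGeneric("corpusTruth", function(x) standardGeneric("corpusTruth"))
#' @export
setMethod("corpusTruth", "MapkCorpus", function(x) x@truth)

#' @describeIn MapkCorpus-class Generator parameters used to build the corpus.
#' @export
setGeneric("corpusParams", function(x) standardGeneric("corpusParams"))
#' @export
setMethod("corpusParams", "MapkCorpus", function(x) x@params)

setMethod("show", "MapkCorpus", function(object) {
    cat("MapkCorpus\n")
    cat("  proteome:       ", length(object@proteome), " proteins (",
        length(object@cds), " with CDS)\n", sep = "")
    cat("  reference panel:", length(object@referencePanel), "sequences\n")
    cat("  genome:         ", length(object@genome), " linkage groups, ",
        sum(Biostrings::width(object@genome)), " bp\n", sep = "")
    cat("  gene models:    ", length(object@genes), "genes\n")
    cat("  expression:     ", nrow(object@tissueCounts), " genes x ",
        ncol(object@tissueCounts), " tissues; ",
        ncol(object@coldCounts), " cold time points\n", sep = "")
    cat("  qRT-PCR:        ", nrow(object@ctTable), "Ct rows\n")
    invisible(object)
})
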