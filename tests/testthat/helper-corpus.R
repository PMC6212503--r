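## Shared fixtures: the default synthetic corpus and the pipeline results on
## it are expensive, so they are built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

defaultCorpus <- function() {
    if (is.null(.fixtures$corpus))
        .fixtures$corpus <- generateCorpus(generatorParams())
    .fixtures$corpus
}

defaultClassification <- function() {
    if (is.null(.fixtures$cls)) {
        corpus <- defaultCorpus()
        .fixtures$cls <- runClassification(proteome(corpus),
                                           referencePanel(corpus))
    }
    .fixtures$cls
}

defaultDuplication <- function() {
    if (is.null(.fixtures$dup)) {
        corpus <- defaultCorpus()
        .fixtures$dup <- runDuplicationAnalysis(
            defaultClassification(), proteome(corpus), cdsSeqs(corpus),
            anchorTable(corpus))
    }
    .fixtures$dup
}

defaultPromoterScan <- function() {
    if (is.null(.fixtures$prom)) {
        corpus <- defaultCorpus()
        .fixtures$prom <- scanAllPromoters(geneModels(corpus),
                                           genomeSeqs(corpus))
    }
    .fixtures$prom
}

## a small corpus for structural tests that do not need the full study
smallProteomeParams <- function(seed = 7L)
    generatorParams(decoy_count = 4L, seed = seed)

readElementDictionaryFromRows <- function(df) {
    df$consensus <- toupper(df$consensus)
    class(df) <- c("element_dictionary", "data.frame")
    df
}

truthFamilies <- function(corpus) {
    tr <- corpusTruth(corpus)$proteins
    stats::setNames(tr$family, tr$gene_id)
}
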