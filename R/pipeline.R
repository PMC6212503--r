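## End-to-end pipeline stages over a public corpus (files or MapkCorpus).

parseRefLabels <- function(references) {
    ids <- names(references)
    parts <- strsplit(ids, "_", fixed = TRUE)
    data.frame(id = ids,
               family = vapply(parts, `[`, character(1), 2L),
               label = vapply(parts, `[`, character(1), 3L),
               stringsAsFactors = FALSE)
}

#' Run the full identification and classification stage
#'
#' Mirrors the reference workflow: redundancy removal, the reference-panel
#' identity screen, motif-grammar classification, phylogenetic group
#' assignment for MAPKs/MAPKKs (TDY activation loops go to group D
#' directly), and molecular weight / isoelectric point calculation.
#' Proteins removed by a filter stay in the output with family `none` and
#' an explanatory flag, so every decision is auditable.
#'
#' @param proteins Named `AAStringSet` or character vector (the candidate
#'   proteome).
#' @param references Labeled reference panel named `REF_<FAMILY>_<LABEL>`
#'   (labels A-D for MAPK/MAPKK; subfamily names for MAPKKK).
#' @param config See [defaultConfig()].
#' @return An [S4Vectors::DataFrame], one row per input protein: the
#'   [classifyProtein()] columns plus `mw`, `pi` and `best_ref_identity`.
#' @export
runClassification <- function(proteins, references, config = defaultConfig()) {
    seqs <- asNamedChar(proteins)
    mcLog("runClassification: %d candidate proteins", length(seqs))
    kept <- removeRedundant(Biostrings::AAStringSet(seqs),
                            identity = config$redundancy_identity,
                            coverage = config$redundancy_coverage)
    survivors <- identityScreen(kept, references,
                                threshold = config$identity_screen)
    bestId <- S4Vectors::metadata(survivors)$best_identity

    cls <- classifyProteins(survivors, minLength = config$min_protein_length)

    ## group assignment for MAPK / MAPKK via the labeled panel
    refTab <- parseRefLabels(references)
    refSeqs <- asNamedChar(references)
    for (fam in c("MAPK", "MAPKK")) {
        famRefs <- refTab[refTab$family == fam &
                          refTab$label %in% c("A", "B", "C", "D"), ]
        if (!nrow(famRefs)) next
        rows <- which(cls$family == fam)
        for (r in rows) {
            cls$group[r] <- assignGroup(
                seqs[[cls$id[r]]],
                stats::setNames(refSeqs[famRefs$id], famRefs$id),
                famRefs$label,
                loopType = cls$loop_type[r],
                gapOpen = config$gap_open, gapExtend = config$gap_extend)
        }
    }

    props <- lapply(cls$id, function(id) computeProperties(seqs[[id]]))
    cls$mw <- vapply(props, `[[`, numeric(1), "mw")
    cls$pi <- vapply(props, `[[`, numeric(1), "pi")
    cls$best_ref_identity <- unname(bestId[cls$id])

    ## reinstate filtered proteins as unclassified, flagged rows
    dropped <- setdiff(names(seqs), cls$id)
    if (length(dropped)) {
        reason <- ifelse(dropped %in% names(kept), "screened_out", "redundant")
        extra <- S4Vectors::DataFrame(
            id = dropped, family = "none", subfamily = NA_character_,
            group = "unassigned", loop_type = NA_character_,
            cd_domain = NA, length = nchar(seqs[dropped]), motifs = "",
            flags = reason, mw = NA_real_, pi = NA_real_,
            best_ref_identity = NA_real_)
        cls <- rbind(cls, extra)
    }
    cls <- cls[match(names(seqs), cls$id), ]
    mcLog("runClassification: %d MAPK, %d MAPKK, %d MAPKKK",
          sum(cls$family == "MAPK"), sum(cls$family == "MAPKK"),
          sum(cls$family == "MAPKKK"))
    cls
}

#' Family label lookup from a classification table
#'
#' @param classification Output of [runClassification()].
#' @return Named character vector of family labels for classified proteins.
#' @export
familyLabels <- function(classification) {
    keep <- classification$family != "none"
    stats::setNames(classification$family[keep], classification$id[keep])
}

#' Run duplicate-pair detection and Ka/Ks analysis
#'
#' @param classification Output of [runClassification()].
#' @param proteins Named proteome.
#' @param cds Named CDS set covering the classified family genes.
#' @param anchors Anchor table (or `NULL`).
#' @param config See [defaultConfig()].
#' @return data.frame of duplicate pairs with tandem flags and NG86
#'   Ka/Ks columns (see [pairKaksReport()]).
#' @export
runDuplicationAnalysis <- function(classification, proteins, cds,
                                   anchors = NULL, config = defaultConfig()) {
    fams <- familyLabels(classification)
    fams <- fams[names(fams) %in% names(asNamedChar(cds))]
    pairs <- findDuplicatePairs(proteins, fams, anchors, config)
    pairKaksReport(pairs, proteins, cds, config)
}

#' Run the promoter cis-element stage
#'
#' @param models Gene models (list with `genes`).
#' @param genome Named `DNAStringSet`.
#' @param classification Output of [runClassification()] (for the family
#'   strata of the prevalence summary); may be `NULL`.
#' @param dictionary Element dictionary.
#' @param config See [defaultConfig()].
#' @return A list: `scans` (per-gene [scanElements()] results) and the
#'   [presenceMatrix()] components.
#' @export
runPromoterAnalysis <- function(models, genome, classification = NULL,
                                dictionary = defaultElementDictionary(),
                                config = defaultConfig()) {
    scans <- scanAllPromoters(models, genome, dictionary,
                              length = config$promoter_length)
    labels <- if (!is.null(classification)) familyLabels(classification)
    pm <- presenceMatrix(scans, labels)
    c(list(scans = scans), pm)
}
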