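## Synthetic study generator.
##
## Builds a miniature genome-wide study with planted signals: a proteome
## whose family members carry exactly the motifs their family requires, a
## genome with gene models, promoters carrying planted cis-elements, tandem
## duplicate pairs evolved under a chosen dN/dS, tissue and cold-stress
## count matrices, and replicate qRT-PCR Ct tables. Planted labels are kept
## in a truth table that analysis stages never read.

NT <- c("A", "C", "G", "T")

randomAa <- function(n) paste(sample(AA_ALPHABET20, n, replace = TRUE),
                              collapse = "")
randomDna <- function(n) paste(sample(NT, n, replace = TRUE), collapse = "")

mutateAa <- function(seq, rate) {
    chars <- strsplit(seq, "")[[1]]
    hit <- which(runif(length(chars)) < rate)
    for (i in hit) chars[i] <- sample(setdiff(AA_ALPHABET20, chars[i]), 1L)
    paste(chars, collapse = "")
}

overwriteAt <- function(seq, piece, at) {
    paste0(substr(seq, 1L, at - 1L), piece,
           substr(seq, at + nchar(piece), nchar(seq)))
}

#' Parameters for the synthetic study generator
#'
#' Defaults encode the reference study composition: 12 MAPKs (groups
#' A/B/C/D = 1/1/5/5), 5 MAPKKs (1/1/1/2), 65 MAPKKKs (16 MEKK, 40 RAF,
#' 9 ZIK), 100 motif-free decoys, 22 tandem duplicate pairs (3 MAPK, 19
#' MAPKKK) evolved at dN/dS 0.2 to ~85\% protein identity, 1.5 kb promoters
#' with a heat-shock element in 66 of 82, anaerobic elements in 8/12, 4/5
#' and 54/65 per family, low-temperature elements in 5/12, 2/5 and 22/65,
#' one designated promoter totalling 27 scanned elements, 74/82 genes
#' detected in all three tissues (5 partial, 3 silent), 33/82 genes nonzero
#' at every cold time point with 10 up- and 11 down-regulated, and
#' triplicate Ct tables with N(0, 0.1) cycle noise.
#'
#' @param ... Named overrides.
#' @return A validated parameter list of class `generator_params`.
#' @export
generatorParams <- function(...) {
    p <- list(
        mapk_groups = c(A = 1L, B = 1L, C = 5L, D = 5L),
        mapkk_groups = c(A = 1L, B = 1L, C = 1L, D = 2L),
        mapkkk_subfamilies = c(MEKK = 16L, RAF = 40L, ZIK = 9L),
        decoy_count = 100L,
        hard_decoy_count = 0L,
        pair_counts = c(MAPK = 3L, MAPKKK = 19L),
        pair_target_identity = 0.85,
        pair_dnds = 0.2,
        member_divergence = 0.25,   # per-site substitution prob from ancestor
        promoter_length = 1500L,
        hse_total = 66L,
        are_by_family = c(MAPK = 8L, MAPKK = 4L, MAPKKK = 54L),
        ltr_by_family = c(MAPK = 5L, MAPKK = 2L, MAPKKK = 22L),
        designated_total = 27L,
        tissue_partial = 5L,
        tissue_silent = 3L,
        cold_full = 33L,
        cold_up = 10L,
        cold_down = 11L,
        library_size = 1e6,
        n_linkage_groups = 11L,
        ct_replicates = 3L,
        ct_noise_sd = 0.1,
        seed = 42L
    )
    dots <- list(...)
    if (length(dots)) {
        unknown <- setdiff(names(dots), names(p))
        if (length(unknown))
            stop("unknown generator parameter(s): ",
                 paste(unknown, collapse = ", "))
        p[names(dots)] <- dots
    }
    validateGeneratorParams(p)
    class(p) <- c("generator_params", "list")
    p
}

familySizes <- function(p) {
    c(MAPK = sum(p$mapk_groups), MAPKK = sum(p$mapkk_groups),
      MAPKKK = sum(p$mapkkk_subfamilies))
}

validateGeneratorParams <- function(p) {
    sizes <- familySizes(p)
    total <- sum(sizes)
    if (p$hse_total > total)
        stop("HSE prevalence exceeds the number of family genes")
    for (f in names(p$are_by_family))
        if (p$are_by_family[[f]] > sizes[[f]])
            stop("ARE prevalence exceeds the ", f, " family size")
    for (f in names(p$ltr_by_family))
        if (p$ltr_by_family[[f]] > sizes[[f]])
            stop("LTR prevalence exceeds the ", f, " family size")
    if (p$tissue_partial + p$tissue_silent > total)
        stop("tissue design counts exceed the number of family genes")
    if (p$cold_full > total || p$cold_up + p$cold_down > p$cold_full)
        stop("cold design counts exceed the number of family genes")
    if (p$pair_dnds <= 0) stop("pair dN/dS must be positive")
    if (p$pair_target_identity <= 0 || p$pair_target_identity >= 1)
        stop("pair target identity must be in (0, 1)")
    if (p$ct_replicates < 2L) stop("at least 2 qRT replicates required")
    for (f in names(p$pair_counts)) {
        need <- 2L * p$pair_counts[[f]]
        if (need > sizes[[f]])
            stop("too many duplicate pairs for the ", f, " family")
    }
    invisible(p)
}

## ---------------------------------------------------------------------------
## Motif instance builders (the generator's side of the motif grammar)

motifInstances <- list(
    mapk = function(loop) paste0("T", if (loop == "TDY") "D" else "E", "YV",
                                 sample(AA_ALPHABET20, 1L), "TRWYRAPE",
                                 sample(c("L", "V"), 1L)),
    cd = function() paste0("LHD", randomAa(2L), sample(c("E", "D"), 1L),
                           "EP", sample(AA_ALPHABET20, 1L), "C"),
    mapkk_cat = function() paste0("VGT", randomAa(2L), "YMSPER"),
    mapkk_act = function() paste0("D", sample(c("L", "I", "V"), 1L), "K"),
    mapkk_st = function() paste0(sample(c("S", "T"), 1L), randomAa(5L),
                                 sample(c("S", "T"), 1L)),
    ## MEKK instances use the S / F alternatives so the generic RAF consensus
    ## -GTxx(W/Y)MAPE- cannot also match them
    mekk = function() paste0("GSP", sample(AA_ALPHABET20, 1L), "F", "MAPEV"),
    raf = function() paste0("GT", sample(AA_ALPHABET20, 1L),
                            sample(setdiff(AA_ALPHABET20, "P"), 1L),
                            sample(c("W", "Y"), 1L), "MAPE"),
    zik = function() paste0("GTPEEMAPE", sample(c("L", "V", "M"), 1L),
                            sample(c("Y", "F", "L"), 1L))
)

## planted-motif layout for one protein; returns list(pieces, at) in residues
motifLayout <- function(family, subfamily, group, loop, len) {
    if (family == "MAPK") {
        pieces <- list(motifInstances$mapk(loop))
        at <- as.integer(round(0.55 * len))
        if (!is.na(group) && group == "C") {
            pieces <- c(pieces, motifInstances$cd())
            at <- c(at, len - 20L)
        }
    } else if (family == "MAPKK") {
        pieces <- list(motifInstances$mapkk_act(), motifInstances$mapkk_cat(),
                       motifInstances$mapkk_st())
        at <- as.integer(round(c(0.40, 0.55, 0.66) * len))
    } else {
        fn <- switch(subfamily, MEKK = motifInstances$mekk,
                     ZIK = motifInstances$zik, RAF = motifInstances$raf)
        pieces <- list(fn())
        at <- as.integer(round(if (subfamily == "RAF") 0.80 * len
                               else 0.45 * len))
    }
    list(pieces = pieces, at = at)
}

plantMotifs <- function(seq, layout) {
    for (k in seq_along(layout$pieces))
        seq <- overwriteAt(seq, layout$pieces[[k]], layout$at[k])
    seq
}

motifFootprintCodons <- function(layout) {
    unlist(lapply(seq_along(layout$pieces), function(k)
        seq(layout$at[k], layout$at[k] + nchar(layout$pieces[[k]]) - 1L)))
}

## expected classification of a planted protein, checked by the classifier's
## own rules (rejection sampling)
classifiesAsPlanted <- function(seq, family, subfamily, group, loop) {
    cls <- classifyProtein(seq)
    if (cls$family != family) return(FALSE)
    if (nzchar(cls$flags)) return(FALSE)
    if (family == "MAPK") {
        if (!identical(cls$loop_type, loop)) return(FALSE)
        wantCd <- !is.na(group) && group == "C"
        if (!identical(as.logical(cls$cd_domain), wantCd)) return(FALSE)
    }
    if (family == "MAPKKK" && !identical(cls$subfamily, subfamily))
        return(FALSE)
    TRUE
}

## ---------------------------------------------------------------------------
## Gene plan: ids, groups, pairs

planGenes <- function(p) {
    rows <- list()
    addRow <- function(id, family, subfamily, group, loop)
        rows[[length(rows) + 1L]] <<- data.frame(
            gene_id = id, family = family, subfamily = subfamily,
            group = group, loop_type = loop, stringsAsFactors = FALSE)
    i <- 0L
    for (g in names(p$mapk_groups)) for (k in seq_len(p$mapk_groups[[g]])) {
        i <- i + 1L
        addRow(sprintf("MAPK%02d", i), "MAPK", NA_character_, g,
               if (g == "D") "TDY" else "TEY")
    }
    i <- 0L
    for (g in names(p$mapkk_groups)) for (k in seq_len(p$mapkk_groups[[g]])) {
        i <- i + 1L
        addRow(sprintf("MAPKK%02d", i), "MAPKK", NA_character_, g,
               NA_character_)
    }
    i <- 0L
    for (s in names(p$mapkkk_subfamilies))
        for (k in seq_len(p$mapkkk_subfamilies[[s]])) {
            i <- i + 1L
            addRow(sprintf("MAPKKK%02d", i), "MAPKKK", s, NA_character_,
                   NA_character_)
        }
    plan <- do.call(rbind, rows)
    plan$pair_id <- NA_character_
    plan$pair_role <- NA_character_

    ## duplicate pairs: within-group (MAPK) / within-subfamily (MAPKKK)
    pairNo <- 0L
    assignPairs <- function(plan, family, nPairs) {
        strata <- if (family == "MAPK") plan$group else plan$subfamily
        idx <- which(plan$family == family)
        quota <- if (family == "MAPK") nPairs else {
            sizes <- p$mapkkk_subfamilies
            apportion(nPairs, sizes)
        }
        if (family == "MAPK") {
            ## fill from the largest groups first
            sizes <- sort(table(strata[idx]), decreasing = TRUE)
            quota <- apportion(nPairs, stats::setNames(as.integer(sizes),
                                                       names(sizes)))
        }
        for (st in names(quota)) {
            avail <- idx[strata[idx] == st & is.na(plan$pair_id[idx])]
            need <- quota[[st]]
            if (2L * need > length(avail))
                stop("cannot place ", need, " pairs in stratum ", st)
            for (q in seq_len(need)) {
                pairNo <<- pairNo + 1L
                pid <- sprintf("PAIR%02d", pairNo)
                take <- avail[1:2]; avail <- avail[-(1:2)]
                plan$pair_id[take] <- pid
                plan$pair_role[take] <- c("member", "partner")
            }
        }
        plan
    }
    for (f in names(p$pair_counts))
        if (p$pair_counts[[f]] > 0L)
            plan <- assignPairs(plan, f, p$pair_counts[[f]])
    plan
}

## largest-remainder apportionment of n among strata with given sizes
apportion <- function(n, sizes) {
    share <- n * sizes / sum(sizes)
    base <- floor(share)
    rem <- n - sum(base)
    if (rem > 0) {
        extra <- order(share - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1L
    }
    ## never ask a stratum for more pairs than it can hold
    over <- base > floor(sizes / 2)
    while (any(over)) {
        surplus <- sum(base[over] - floor(sizes[over] / 2))
        base[over] <- floor(sizes[over] / 2)
        room <- which(!over & base < floor(sizes / 2))
        for (k in room) {
            if (surplus == 0) break
            base[k] <- base[k] + 1L; surplus <- surplus - 1L
        }
        over <- base > floor(sizes / 2)
        if (surplus == 0) break
    }
    stats::setNames(as.integer(base), names(sizes))
}

## ---------------------------------------------------------------------------
## Proteome

#' Generate the synthetic proteome
#'
#' Family members are 250-700 aa kinase-like scaffolds derived from a shared
#' per-group (or per-subfamily) ancestor by point substitution, carrying
#' exactly the motif instances their family requires; the ancestors
#' themselves are emitted as the labeled reference panel. Decoys are random
#' kinase-like sequences rejection-sampled against the classifier's own
#' rules so that none qualifies for any family; an optional harder decoy
#' tier carries a bare TEY tripeptide without its activation-loop context.
#' Duplicate-pair partners are produced by codon-level evolution of the
#' member CDS (see [evolveDuplicatePair()]) with the motif footprint masked
#' against nonsynonymous change.
#'
#' @param p Generator parameters, see [generatorParams()].
#' @return A list: `proteome` (`AAStringSet`, planted members then decoys),
#'   `references` (`AAStringSet` named `REF_<FAMILY>_<GROUP>`), `cds`
#'   (`DNAStringSet` for the family genes, stop codon included), `plan`
#'   (gene table with planted labels) and `truth` (planted labels plus
#'   realized pair divergence).
#' @export
generateProteome <- function(p = generatorParams()) {
    set.seed(as.integer(p$seed))
    plan <- planGenes(p)

    ## ancestors: one per MAPK/MAPKK group and per MAPKKK subfamily
    strata <- unique(data.frame(
        family = plan$family,
        stratum = ifelse(plan$family == "MAPKKK", plan$subfamily, plan$group),
        stringsAsFactors = FALSE))
    ancestors <- list()
    for (k in seq_len(nrow(strata))) {
        fam <- strata$family[k]; st <- strata$stratum[k]
        loop <- if (fam == "MAPK") (if (st == "D") "TDY" else "TEY") else NA
        len <- sample(340:620, 1L)
        repeat {
            layout <- motifLayout(fam, st, st, loop, len)
            seq <- plantMotifs(randomAa(len), layout)
            if (classifiesAsPlanted(seq, fam,
                                    if (fam == "MAPKKK") st else NA,
                                    if (fam != "MAPKKK") st else NA, loop))
                break
        }
        ancestors[[paste(fam, st, sep = "_")]] <-
            list(seq = seq, len = len, layout = layout)
    }

    ## members (pair partners are evolved later, at the CDS level)
    seqs <- character(0)
    layouts <- list()
    for (k in seq_len(nrow(plan))) {
        fam <- plan$family[k]
        st <- if (fam == "MAPKKK") plan$subfamily[k] else plan$group[k]
        anc <- ancestors[[paste(fam, st, sep = "_")]]
        if (!is.na(plan$pair_role[k]) && plan$pair_role[k] == "partner") {
            seqs[plan$gene_id[k]] <- NA_character_  # filled after evolution
            next
        }
        repeat {
            layout <- motifLayout(fam, plan$subfamily[k], plan$group[k],
                                  plan$loop_type[k], anc$len)
            seq <- plantMotifs(mutateAa(anc$seq, p$member_divergence), layout)
            if (classifiesAsPlanted(seq, fam, plan$subfamily[k],
                                    plan$group[k], plan$loop_type[k])) break
        }
        seqs[plan$gene_id[k]] <- seq
        layouts[[plan$gene_id[k]]] <- layout
    }

    ## CDS for generated members; partners by codon evolution from the member
    cds <- character(0)
    divergence <- list()
    for (k in which(!is.na(plan$pair_id) & plan$pair_role == "member")) {
        gid <- plan$gene_id[k]
        cds[gid] <- backtranslate(seqs[[gid]])
        partnerK <- which(plan$pair_id == plan$pair_id[k] &
                          plan$pair_role == "partner")
        pid <- plan$gene_id[partnerK]
        mask <- motifFootprintCodons(layouts[[gid]])
        repeat {
            ev <- evolveDuplicatePair(cds[[gid]], dnds = p$pair_dnds,
                                      targetIdentity = p$pair_target_identity,
                                      maskCodons = mask)
            prot <- translateCds(ev$cds)
            if (classifiesAsPlanted(prot, plan$family[k], plan$subfamily[k],
                                    plan$group[k], plan$loop_type[k])) {
                cds[pid] <- ev$cds
                seqs[pid] <- prot
                layouts[[pid]] <- layouts[[gid]]
                divergence[[plan$pair_id[k]]] <- data.frame(
                    pair_id = plan$pair_id[k], member = gid, partner = pid,
                    n_syn = ev$n_syn, n_nonsyn = ev$n_nonsyn,
                    protein_identity = ev$protein_identity,
                    dnds = p$pair_dnds, stringsAsFactors = FALSE)
                break
            }
        }
    }
    for (k in which(is.na(plan$pair_id))) {
        gid <- plan$gene_id[k]
        cds[gid] <- backtranslate(seqs[[gid]])
    }
    cds <- cds[plan$gene_id]

    ## decoys: kinase-like but carrying no qualifying motif combination
    decoys <- character(0)
    nDec <- p$decoy_count + p$hard_decoy_count
    if (nDec > 0L) {
        for (d in seq_len(nDec)) {
            hard <- d > p$decoy_count
            repeat {
                seq <- randomAa(sample(250:700, 1L))
                if (hard)  # bare TEY without the activation-loop context
                    seq <- overwriteAt(seq, "TEY",
                                       as.integer(nchar(seq) / 2))
                cls <- classifyProtein(seq)
                if (cls$family == "none" &&
                    (!hard || grepl("TEY", seq, fixed = TRUE))) break
            }
            decoys[sprintf(if (hard) "HDECOY%03d" else "DECOY%03d",
                           if (hard) d - p$decoy_count else d)] <- seq
        }
    }

    refs <- vapply(ancestors, `[[`, character(1), "seq")
    names(refs) <- paste0("REF_", names(ancestors))

    proteome <- Biostrings::AAStringSet(c(seqs[plan$gene_id], decoys))
    truth <- plan
    truth$is_decoy <- FALSE
    if (length(decoys)) {
        decoyTruth <- data.frame(
            gene_id = names(decoys), family = "decoy",
            subfamily = NA_character_, group = NA_character_,
            loop_type = NA_character_, pair_id = NA_character_,
            pair_role = NA_character_, is_decoy = TRUE,
            stringsAsFactors = FALSE)
        truth <- rbind(truth, decoyTruth)
    }
    pairDf <- if (length(divergence)) do.call(rbind, divergence)
    else data.frame(pair_id = character(0), member = character(0),
                    partner = character(0), n_syn = integer(0),
                    n_nonsyn = integer(0), protein_identity = numeric(0),
                    dnds = numeric(0))
    mcLog("generateProteome: %d planted + %d decoys, %d references, %d pairs",
          nrow(plan), length(decoys), length(refs), nrow(pairDf))
    list(proteome = proteome,
         references = Biostrings::AAStringSet(refs),
         cds = Biostrings::DNAStringSet(cds),
         plan = plan,
         truth = list(proteins = truth, pairs = pairDf),
         layouts = layouts)
}

## uniform synonymous back-translation; appends a TAA stop
backtranslate <- function(protein) {
    gc <- geneticCode()
    byAa <- split(names(gc), gc)
    codons <- vapply(strsplit(protein, "")[[1]], function(aa) {
        opts <- byAa[[aa]]
        if (is.null(opts)) stop("cannot back-translate residue ", aa)
        if (length(opts) == 1L) opts else sample(opts, 1L)
    }, character(1))
    paste0(paste(codons, collapse = ""), "TAA")
}

translateCds <- function(cds) {
    n <- nchar(cds) %/% 3
    codons <- substring(cds, 3 * seq_len(n) - 2, 3 * seq_len(n))
    aa <- geneticCode()[codons]
    if (aa[n] == "*") aa <- aa[-n]
    if (any(aa == "*")) stop("internal stop codon")
    paste(aa, collapse = "")
}

#' Evolve a duplicate-pair partner CDS under a target dN/dS
#'
#' Random codon-wise point substitutions are proposed; substitutions
#' creating stop codons are rejected, synonymous substitutions are always
#' accepted, and nonsynonymous substitutions are accepted with probability
#' equal to the `dnds` parameter (purifying when < 1, neutral at 1).
#' Evolution stops when the translated protein identity to the original
#' falls to `targetIdentity`.
#'
#' @param cds Coding sequence (stop codon allowed at the end; never
#'   mutated).
#' @param dnds Nonsynonymous acceptance probability (> 0; values >= 1 make
#'   acceptance independent of substitution type).
#' @param targetIdentity Protein identity in (0, 1) at which to stop.
#' @param maskCodons Integer codon indices protected from nonsynonymous
#'   change (synonymous change still allowed).
#' @param maxProposals Safety cap on proposal count.
#' @return A list: `cds` (evolved sequence), `n_syn`, `n_nonsyn` (accepted
#'   substitution counts) and `protein_identity` (realized).
#' @export
evolveDuplicatePair <- function(cds, dnds, targetIdentity = 0.85,
                                maskCodons = integer(0),
                                maxProposals = 1e6) {
    if (dnds <= 0) stop("dN/dS must be positive")
    gc <- geneticCode()
    chars <- strsplit(cds, "")[[1]]
    nCodon <- length(chars) %/% 3
    lastIsStop <- gc[[paste(chars[(3 * nCodon - 2):(3 * nCodon)],
                            collapse = "")]] == "*"
    mutable <- if (lastIsStop) 3L * (nCodon - 1L) else 3L * nCodon
    orig <- translateCds(cds)
    origChars <- strsplit(orig, "")[[1]]
    nAa <- length(origChars)
    nSyn <- 0L; nNonsyn <- 0L
    identity <- 1
    proposals <- 0L
    while (identity > targetIdentity && proposals < maxProposals) {
        proposals <- proposals + 1L
        pos <- sample.int(mutable, 1L)
        ci <- (pos - 1L) %/% 3L + 1L
        lo <- 3L * ci - 2L
        cod <- chars[lo:(lo + 2L)]
        alt <- sample(setdiff(NT, chars[pos]), 1L)
        newCod <- cod; newCod[pos - lo + 1L] <- alt
        aaOld <- gc[[paste(cod, collapse = "")]]
        aaNew <- gc[[paste(newCod, collapse = "")]]
        if (aaNew == "*") next
        syn <- aaNew == aaOld
        if (!syn) {
            if (ci %in% maskCodons) next
            if (dnds < 1 && runif(1) > dnds) next
            nNonsyn <- nNonsyn + 1L
        } else nSyn <- nSyn + 1L
        chars[pos] <- alt
        if (!syn || proposals %% 25L == 0L) {
            cur <- vapply(seq_len(nAa), function(k)
                gc[[paste(chars[(3 * k - 2):(3 * k)], collapse = "")]],
                character(1))
            identity <- mean(cur == origChars)
        }
    }
    list(cds = paste(chars, collapse = ""), n_syn = nSyn,
         n_nonsyn = nNonsyn, protein_identity = identity)
}
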