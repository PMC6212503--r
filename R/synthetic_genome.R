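## Synthetic genome, promoters, expression and Ct tables; corpus assembly.

IUPAC_MAP <- list(A = "A", C = "C", G = "G", T = "T",
                  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                  B = c("C", "G", "T"), D = c("A", "G", "T"),
                  H = c("A", "C", "T"), V = c("A", "C", "G"),
                  N = c("A", "C", "G", "T"))

concretize <- function(consensus) {
    paste(vapply(strsplit(consensus, "")[[1]],
                 function(ch) sample(IUPAC_MAP[[ch]], 1L), character(1)),
          collapse = "")
}

revcompChr <- function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

## map of elements that are exact reverse complements of each other; a
## double-strand scan reports the partner at every planted occurrence
dualPartners <- function(dictionary) {
    rc <- vapply(dictionary$consensus, revcompChr, character(1))
    out <- stats::setNames(rep(NA_character_, nrow(dictionary)),
                           dictionary$name)
    for (k in seq_len(nrow(dictionary))) {
        hit <- which(dictionary$consensus == rc[k] &
                     dictionary$name != dictionary$name[k])
        if (length(hit)) out[k] <- dictionary$name[hit[1L]]
    }
    out
}

## fixed composition of the designated maximum-element promoter (planted
## instances; the double-strand scan adds one dual count per CGTCA-motif)
designatedComposition <- function() {
    c(HSE = 2L, ARE = 2L, LTR = 1L, ABRE = 4L, `CGTCA-motif` = 3L,
      ERE = 3L, `TCA-element` = 3L, `W-box` = 3L, `TC-rich` = 3L)
}

expectedScanCounts <- function(planted, dictionary) {
    duals <- dualPartners(dictionary)
    exp <- stats::setNames(integer(nrow(dictionary)), dictionary$name)
    for (e in names(planted)) {
        exp[e] <- exp[e] + planted[[e]]
        if (!is.na(duals[[e]]))
            exp[duals[[e]]] <- exp[duals[[e]]] + planted[[e]]
    }
    exp
}

## element-free background of the requested length
cleanBackground <- function(len, dictionary, maxIter = 500L) {
    seq <- randomDna(len)
    for (it in seq_len(maxIter)) {
        scan <- scanElements(seq, dictionary)
        if (!nrow(scan$positions)) return(seq)
        widths <- nchar(dictionary$consensus)[match(scan$positions$element,
                                                    dictionary$name)]
        for (h in seq_len(nrow(scan$positions))) {
            s <- scan$positions$start[h]
            e <- min(len, s + widths[h] - 1L)
            seq <- overwriteAt(seq, randomDna(e - s + 1L), s)
        }
    }
    stop("could not generate an element-free promoter background")
}

## plant the requested element instances into a clean background; the
## finished promoter is rescanned and must show exactly the expected counts
plantPromoter <- function(planted, len, dictionary, maxTries = 60L) {
    expected <- expectedScanCounts(planted, dictionary)
    widths <- stats::setNames(nchar(dictionary$consensus), dictionary$name)
    instances <- rep(names(planted), planted)
    for (try in seq_len(maxTries)) {
        bg <- cleanBackground(len, dictionary)
        occupied <- logical(len)
        ok <- TRUE
        rows <- list()
        for (e in instances) {
            w <- widths[[e]]
            placed <- FALSE
            for (att in seq_len(200L)) {
                s <- sample.int(len - w + 1L, 1L)
                if (any(occupied[s:(s + w - 1L)])) next
                strand <- sample(c("+", "-"), 1L)
                inst <- concretize(dictionary$consensus[dictionary$name == e])
                if (strand == "-") inst <- revcompChr(inst)
                bg <- overwriteAt(bg, inst, s)
                occupied[s:(s + w - 1L)] <- TRUE
                rows[[length(rows) + 1L]] <- data.frame(
                    element = e, start = s, strand = strand,
                    stringsAsFactors = FALSE)
                placed <- TRUE
                break
            }
            if (!placed) { ok <- FALSE; break }
        }
        if (!ok) next
        scan <- scanElements(bg, dictionary)
        if (identical(unname(scan$counts[names(expected)]),
                      as.integer(unname(expected))) ||
            all(scan$counts[names(expected)] == expected)) {
            return(list(seq = bg,
                        planted = if (length(rows)) do.call(rbind, rows)
                                  else data.frame(element = character(0),
                                                  start = integer(0),
                                                  strand = character(0)),
                        expected_counts = expected))
        }
    }
    stop("could not place promoter elements without overlap")
}

#' Generate promoters with planted cis-elements
#'
#' Each gene receives an element-free random background of the configured
#' length into which exact consensus instances are planted at random
#' non-overlapping positions on either strand: a heat-shock element in
#' `hse_total` genes, anaerobic and low-temperature elements at the per-
#' family prevalences, a fixed 27-element composition in the designated
#' promoter (a MAPKK, mirroring the most element-rich promoter of the
#' reference study), and a small random complement of hormone-responsive
#' elements elsewhere.
#'
#' @param p Generator parameters.
#' @param plan Gene table from [generateProteome()].
#' @param dictionary Element dictionary.
#' @return A list: `promoters` (named character), `truth` (per-gene planted
#'   element counts as scanned on both strands, the planted positions, and
#'   the designated gene id).
#' @export
generatePromoters <- function(p, plan, dictionary = defaultElementDictionary()) {
    genes <- plan$gene_id
    fam <- stats::setNames(plan$family, genes)
    mapkk <- genes[fam == "MAPKK"]
    designated <- if (length(mapkk) >= 3L) mapkk[3L] else mapkk[1L]

    pickWithDesignated <- function(pool, n) {
        if (designated %in% pool && n >= 1L)
            c(designated, sample(setdiff(pool, designated), n - 1L))
        else sample(pool, n)
    }
    hseSet <- pickWithDesignated(genes, p$hse_total)
    areSet <- unlist(lapply(names(p$are_by_family), function(f)
        pickWithDesignated(genes[fam == f], p$are_by_family[[f]])))
    ltrSet <- unlist(lapply(names(p$ltr_by_family), function(f)
        pickWithDesignated(genes[fam == f], p$ltr_by_family[[f]])))

    extras <- c("ABRE", "ERE", "TCA-element", "W-box", "TC-rich",
                "CGTCA-motif", "TGACG-motif")
    extras <- intersect(extras, dictionary$name)

    promoters <- character(0)
    truthRows <- list()
    posRows <- list()
    for (g in genes) {
        if (g == designated) {
            planted <- designatedComposition()
            planted <- planted[names(planted) %in% dictionary$name]
        } else {
            planted <- integer(0)
            if (g %in% hseSet) planted["HSE"] <- 1L
            if (g %in% areSet) planted["ARE"] <- 1L
            if (g %in% ltrSet) planted["LTR"] <- 1L
            nExtra <- sample(0:3, 1L)
            if (nExtra > 0L) {
                ex <- table(sample(extras, nExtra, replace = TRUE))
                for (e in names(ex))
                    planted[e] <- (if (is.na(planted[e])) 0L else planted[e]) +
                        as.integer(ex[[e]])
            }
            planted <- planted[!is.na(planted) & planted > 0L]
        }
        res <- plantPromoter(planted, p$promoter_length, dictionary)
        promoters[g] <- res$seq
        truthRows[[g]] <- data.frame(gene_id = g,
                                     element = names(res$expected_counts),
                                     count = as.integer(res$expected_counts),
                                     stringsAsFactors = FALSE)
        if (nrow(res$planted)) {
            res$planted$gene_id <- g
            posRows[[g]] <- res$planted
        }
    }
    counts <- do.call(rbind, truthRows)
    rownames(counts) <- NULL
    mcLog("generatePromoters: %d promoters, designated max-element promoter %s",
          length(promoters), designated)
    list(promoters = promoters,
         truth = list(element_counts = counts,
                      positions = do.call(rbind, posRows),
                      designated = designated))
}

## ---------------------------------------------------------------------------
## Gene structure and genome assembly

exonCountFor <- function(family, subfamily, group) {
    if (family == "MAPK") {
        switch(group, A = 18L, B = 3L, C = sample(6:7, 1L),
               D = sample(10:12, 1L))
    } else if (family == "MAPKK") {
        switch(group, A = 8L, B = 10L, C = 12L, D = 1L)
    } else {
        switch(subfamily, MEKK = sample(1:17, 1L), RAF = sample(3:17, 1L),
               ZIK = sample(3:9, 1L))
    }
}

## split a CDS of cdsLen bp into k exon widths of at least 3 bp each
splitExons <- function(cdsLen, k) {
    if (k == 1L) return(cdsLen)
    base <- rep(3L, k)
    rest <- cdsLen - 3L * k
    if (rest < 0L) stop("CDS too short for ", k, " exons")
    extra <- as.integer(stats::rmultinom(1L, rest, rep(1 / k, k)))
    base + extra
}

#' Generate the synthetic genome, gene models and anchor table
#'
#' Every planted gene receives a coding region split into a family- and
#' group-specific number of exons (one RAF gene carries 51 exons, the
#' structural outlier of the reference study), separated by short GT..AG
#' introns, preceded by its planted promoter, and placed on one of the
#' synthetic linkage groups. Duplicate pairs are placed adjacently on the
#' same linkage group (well under 50 kb apart), making every planted pair
#' tandem by construction. Roughly a third of genes are placed on the minus
#' strand.
#'
#' @param p Generator parameters.
#' @param prot Result of [generateProteome()].
#' @param promoters Named promoter sequences from [generatePromoters()].
#' @return A list: `genome` (`DNAStringSet` of linkage groups), `genes`
#'   (`GRanges`), `exons` (`GRangesList`), `anchors` (data.frame) and
#'   `truth` (per-gene exon counts and placement).
#' @export
generateGenomeAndModels <- function(p, prot, promoters) {
    plan <- prot$plan
    cds <- as.character(prot$cds)

    ## exon counts: drawn per gene; partners copy their pair member
    exonN <- stats::setNames(integer(nrow(plan)), plan$gene_id)
    for (k in seq_len(nrow(plan))) {
        if (!is.na(plan$pair_role[k]) && plan$pair_role[k] == "partner") next
        exonN[plan$gene_id[k]] <- exonCountFor(plan$family[k],
                                               plan$subfamily[k],
                                               plan$group[k])
    }
    for (k in which(!is.na(plan$pair_role) & plan$pair_role == "partner")) {
        member <- plan$gene_id[which(plan$pair_id == plan$pair_id[k] &
                                     plan$pair_role == "member")]
        exonN[plan$gene_id[k]] <- exonN[[member]]
    }
    ## the structural outlier: one 51-exon RAF gene, never a pair member
    rafSingles <- plan$gene_id[plan$family == "MAPKKK" &
                               plan$subfamily == "RAF" & is.na(plan$pair_id)]
    if (length(rafSingles)) {
        outlier <- rafSingles[length(rafSingles) - 2L]
        if (is.na(outlier)) outlier <- rafSingles[length(rafSingles)]
        if (nchar(cds[[outlier]]) >= 51L * 3L) exonN[outlier] <- 51L
    }

    ## placement: pairs stay together; units shuffled across linkage groups
    units <- list()
    done <- character(0)
    for (k in seq_len(nrow(plan))) {
        g <- plan$gene_id[k]
        if (g %in% done) next
        if (!is.na(plan$pair_id[k])) {
            mates <- plan$gene_id[which(plan$pair_id == plan$pair_id[k])]
            units[[length(units) + 1L]] <- mates
            done <- c(done, mates)
        } else {
            units[[length(units) + 1L]] <- g
            done <- c(done, g)
        }
    }
    units <- units[sample.int(length(units))]
    lgOf <- rep(seq_len(p$n_linkage_groups), length.out = length(units))

    lgSeq <- stats::setNames(rep("", p$n_linkage_groups),
                             sprintf("LG%d", seq_len(p$n_linkage_groups)))
    geneRows <- list()
    exonList <- list()
    anchorRows <- list()
    planIdx <- stats::setNames(seq_len(nrow(plan)), plan$gene_id)

    for (u in seq_along(units)) {
        lg <- sprintf("LG%d", lgOf[u])
        for (g in units[[u]]) {
            k <- planIdx[[g]]
            dna <- cds[[g]]
            widths <- splitExons(nchar(dna), exonN[[g]])
            offs <- cumsum(c(0L, utils::head(widths, -1L)))
            exonSeqs <- substring(dna, offs + 1L, offs + widths)
            nEx <- length(widths)
            introns <- if (nEx > 1L)
                vapply(seq_len(nEx - 1L), function(i)
                    paste0("GT", randomDna(sample(66:146, 1L)), "AG"),
                    character(1))
            else character(0)
            body <- paste0(paste0(exonSeqs[-nEx], introns, collapse = ""),
                           exonSeqs[nEx])
            ## transcript-space exon bounds within the body
            intW <- c(0L, nchar(introns))
            bStart <- integer(nEx); pos <- 1L
            for (i in seq_len(nEx)) {
                pos <- pos + (if (i > 1L) intW[i] else 0L)
                bStart[i] <- pos
                pos <- pos + widths[i]
            }
            bEnd <- bStart + widths - 1L
            strand <- sample(c("+", "+", "-"), 1L)
            spacer <- randomDna(sample(800:2000, 1L))
            cur <- nchar(lgSeq[[lg]])
            if (strand == "+") {
                block <- paste0(spacer, promoters[[g]], body)
                gStart <- cur + nchar(spacer) + nchar(promoters[[g]]) + 1L
                gEnd <- gStart + nchar(body) - 1L
                exStart <- gStart + bStart - 1L
                exEnd <- gStart + bEnd - 1L
            } else {
                block <- paste0(spacer, revcompChr(paste0(promoters[[g]], body)))
                gStart <- cur + nchar(spacer) + 1L
                gEnd <- gStart + nchar(body) - 1L
                exStart <- gEnd - bEnd + 1L
                exEnd <- gEnd - bStart + 1L
                ord <- order(exStart)
                exStart <- exStart[ord]; exEnd <- exEnd[ord]
            }
            lgSeq[[lg]] <- paste0(lgSeq[[lg]], block)
            geneRows[[g]] <- data.frame(gene_id = g, seqid = lg,
                                        strand = strand, start = gStart,
                                        end = gEnd, n_exons = nEx,
                                        stringsAsFactors = FALSE)
            exonList[[g]] <- GenomicRanges::GRanges(
                lg, IRanges::IRanges(exStart, exEnd))
            anchorRows[[g]] <- data.frame(gene_id = g, linkage_group = lg,
                                          position = gStart,
                                          stringsAsFactors = FALSE)
        }
    }
    lgSeq <- vapply(lgSeq, function(s) paste0(s, randomDna(500L)),
                    character(1))
    geneTab <- do.call(rbind, geneRows)[plan$gene_id, ]
    genes <- GenomicRanges::GRanges(
        geneTab$seqid, IRanges::IRanges(geneTab$start, geneTab$end),
        strand = geneTab$strand)
    genes$gene_id <- geneTab$gene_id
    genes$mrna_id <- paste0(geneTab$gene_id, ".t1")
    anchors <- do.call(rbind, anchorRows)[plan$gene_id, ]
    rownames(anchors) <- NULL
    mcLog("generateGenomeAndModels: %d genes on %d linkage groups",
          length(genes), p$n_linkage_groups)
    list(genome = Biostrings::DNAStringSet(lgSeq),
         genes = genes,
         exons = GenomicRanges::GRangesList(exonList[plan$gene_id]),
         anchors = anchors,
         truth = data.frame(gene_id = plan$gene_id,
                            n_exons = unname(exonN[plan$gene_id]),
                            linkage_group = geneTab$seqid,
                            strand = geneTab$strand,
                            stringsAsFactors = FALSE))
}

## ---------------------------------------------------------------------------
## Expression

#' Generate tissue and cold-stress count matrices
#'
#' Detected genes receive Poisson counts whose FPKM (at the declared library
#' size) is comfortably above the detection floor; undetected cells are
#' exactly zero. In the cold time course, up-regulated genes rise five-fold
#' over baseline at every later time point, down-regulated genes drop
#' five-fold, fully-expressed flat genes stay level, and every gene outside
#' the fully-expressed set is zeroed at exactly one later time point.
#'
#' @param p Generator parameters.
#' @param geneIds Character vector of the planted family gene ids.
#' @param lengths Named effective transcript lengths (bp).
#' @return A list: `tissue` and `cold` count matrices, `librarySize`
#'   (named, all samples) and `truth` (detection and regulation labels).
#' @export
generateExpression <- function(p, geneIds, lengths) {
    n <- length(geneIds)
    tissues <- c("leaf", "root", "seed")
    timepts <- c("t0", "t12", "t24", "t48")

    silent <- sample(geneIds, p$tissue_silent)
    partial <- sample(setdiff(geneIds, silent), p$tissue_partial)
    detectedAll <- setdiff(geneIds, c(silent, partial))

    tissue <- matrix(0L, n, length(tissues),
                     dimnames = list(geneIds, tissues))
    for (g in detectedAll) {
        lam <- runif(1, 50, 500)
        tissue[g, ] <- rpois(length(tissues), lam)
    }
    for (g in partial) {
        lam <- runif(1, 50, 500)
        zero <- sample(seq_along(tissues), sample(1:2, 1L))
        cnt <- rpois(length(tissues), lam)
        cnt[zero] <- 0L
        tissue[g, ] <- cnt
    }

    full <- sample(geneIds, p$cold_full)
    up <- sample(full, p$cold_up)
    down <- sample(setdiff(full, up), p$cold_down)
    flat <- setdiff(full, c(up, down))
    rest <- setdiff(geneIds, full)

    cold <- matrix(0L, n, length(timepts), dimnames = list(geneIds, timepts))
    for (g in up) {
        lam0 <- runif(1, 40, 80)
        cold[g, ] <- rpois(length(timepts), c(lam0, rep(5 * lam0, 3)))
    }
    for (g in down) {
        lam0 <- runif(1, 200, 400)
        cold[g, ] <- rpois(length(timepts), c(lam0, rep(lam0 / 5, 3)))
    }
    for (g in flat) {
        lam <- runif(1, 60, 150)
        cold[g, ] <- rpois(length(timepts), lam)
    }
    zeroPick <- rep(2:4, length.out = length(rest))
    for (i in seq_along(rest)) {
        g <- rest[i]
        lam <- runif(1, 20, 40)
        cnt <- rpois(length(timepts), lam)
        cnt[zeroPick[i]] <- 0L
        cold[g, ] <- cnt
    }
    ## Poisson draws at these rates are essentially never zero, but the
    ## design is exact by construction: enforce strict positivity where the
    ## truth says "expressed"
    for (g in full) cold[g, cold[g, ] == 0L] <- 1L
    for (i in seq_along(rest)) {
        g <- rest[i]
        nz <- setdiff(seq_along(timepts), zeroPick[i])
        cold[g, nz][cold[g, nz] == 0L] <- 1L
    }
    for (g in detectedAll) tissue[g, tissue[g, ] == 0L] <- 1L
    for (g in partial) {
        nz <- tissue[g, ] > 0L
        if (!any(nz)) tissue[g, sample(seq_along(tissues), 1L)] <- 1L
    }

    libs <- stats::setNames(rep(p$library_size, length(tissues) + length(timepts)),
                            c(tissues, timepts))
    mcLog("generateExpression: %d/%d detected in all tissues; %d fully cold-expressed (%d up, %d down)",
          length(detectedAll), n, length(full), length(up), length(down))
    list(tissue = tissue, cold = cold, librarySize = libs,
         truth = list(tissue_all = detectedAll, tissue_partial = partial,
                      tissue_silent = silent, cold_full = full,
                      cold_up = up, cold_down = down, cold_flat = flat))
}

## ---------------------------------------------------------------------------
## qRT-PCR Ct tables

#' Generate replicate qRT-PCR Ct tables
#'
#' Three replicates per gene and condition; replicate noise is
#' N(0, `ct_noise_sd`) cycles on both the target and the reference channel.
#' Up-regulated genes carry 2- to 50-fold induction relative to the
#' control at each cold time point, down-regulated genes 0.1-0.6-fold.
#'
#' @param p Generator parameters.
#' @param exprTruth Truth list from [generateExpression()].
#' @return A list: `ct` (data.frame `gene`, `condition`, `replicate`,
#'   `ct_target`, `ct_reference`) and `truth` (the planted fold changes).
#' @export
generateCtTables <- function(p, exprTruth) {
    if (p$ct_replicates < 2L) stop("at least 2 replicates required")
    genes <- c(exprTruth$cold_up, exprTruth$cold_down)
    conds <- c("control", "cold_0.5h", "cold_3h", "cold_12h", "cold_24h",
               "cold_48h")
    rows <- list()
    foldRows <- list()
    for (g in genes) {
        isUp <- g %in% exprTruth$cold_up
        dctControl <- runif(1, 3, 8)
        for (cond in conds) {
            fold <- if (cond == "control") 1
                    else if (isUp) runif(1, 2, 50) else runif(1, 0.1, 0.6)
            foldRows[[length(foldRows) + 1L]] <- data.frame(
                gene = g, condition = cond, fold = fold,
                stringsAsFactors = FALSE)
            for (r in seq_len(p$ct_replicates)) {
                ref <- 20 + rnorm(1, 0, p$ct_noise_sd)
                tgt <- ref + dctControl - log2(fold) +
                    rnorm(1, 0, p$ct_noise_sd)
                rows[[length(rows) + 1L]] <- data.frame(
                    gene = g, condition = cond, replicate = r,
                    ct_target = tgt, ct_reference = ref,
                    stringsAsFactors = FALSE)
            }
        }
    }
    list(ct = do.call(rbind, rows), truth = do.call(rbind, foldRows))
}

#' Packaged worked-example Ct fixture
#'
#' Exact Ct values (treated target/reference 20.000/20.000; control
#' 25.6187/20.000, three replicates each) whose delta-delta-Ct is -5.6187,
#' i.e. a 49.13-fold induction.
#'
#' @return A Ct data.frame in the [ddct()] input layout.
#' @export
ctFoldFixture <- function() {
    readTable(system.file("extdata", "qrt_fold_fixture.tsv",
                          package = "mapkcascade"))
}

## ---------------------------------------------------------------------------
## Corpus assembly and serialization

#' Generate a complete synthetic corpus
#'
#' Runs every generator stage under a single seed: proteome and duplicate
#' pairs, promoters, genome with gene models and anchors, expression
#' matrices, and Ct tables. The result is byte-deterministic for a fixed
#' parameter set and seed.
#'
#' @param p Generator parameters, see [generatorParams()].
#' @return A [MapkCorpus-class] object.
#' @examples
#' \donttest{
#' corpus <- generateCorpus(generatorParams(decoy_count = 5L))
#' corpus
#' }
#' @export
generateCorpus <- function(p = generatorParams()) {
    prot <- generateProteome(p)  # seeds the RNG stream
    prom <- generatePromoters(p, prot$plan)
    gen <- generateGenomeAndModels(p, prot, prom$promoters)
    lens <- stats::setNames(nchar(as.character(prot$cds)),
                            names(prot$cds))
    expr <- generateExpression(p, prot$plan$gene_id, lens)
    qrt <- generateCtTables(p, expr$truth)
    methods::new("MapkCorpus",
        proteome = prot$proteome,
        referencePanel = prot$references,
        cds = prot$cds,
        genome = gen$genome,
        genes = gen$genes,
        exons = gen$exons,
        anchors = gen$anchors,
        tissueCounts = expr$tissue,
        coldCounts = expr$cold,
        geneLengths = lens,
        librarySize = expr$librarySize,
        ctTable = qrt$ct,
        truth = list(proteins = prot$truth$proteins,
                     pairs = prot$truth$pairs,
                     promoters = prom$truth,
                     structure = gen$truth,
                     expression = expr$truth,
                     qrt_folds = qrt$truth),
        params = unclass(p))
}

#' Write a corpus to disk
#'
#' Public files (FASTA, GFF3, TSV, YAML parameters) go to `dir`; the truth
#' table is written separately under `dir/truth/` and is never read by any
#' analysis stage or by [readCorpus()].
#'
#' @param corpus A [MapkCorpus-class].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCorpus <- function(corpus, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeFasta(corpus@proteome, file.path(dir, "proteome.fasta"))
    writeFasta(corpus@referencePanel, file.path(dir, "references.fasta"))
    writeFasta(corpus@cds, file.path(dir, "cds.fasta"))
    writeFasta(corpus@genome, file.path(dir, "genome.fasta"))
    writeGff3GeneModels(list(genes = corpus@genes, exons = corpus@exons),
                        file.path(dir, "genes.gff3"))
    writeTable(corpus@anchors, file.path(dir, "anchors.tsv"))
    writeCountsTsv(corpus@tissueCounts, file.path(dir, "tissue_counts.tsv"))
    writeCountsTsv(corpus@coldCounts, file.path(dir, "cold_counts.tsv"))
    writeTable(data.frame(gene_id = names(corpus@geneLengths),
                          length = unname(corpus@geneLengths)),
               file.path(dir, "gene_lengths.tsv"))
    writeTable(data.frame(sample = names(corpus@librarySize),
                          library_size = unname(corpus@librarySize)),
               file.path(dir, "library_sizes.tsv"))
    writeTable(corpus@ctTable, file.path(dir, "ct_table.tsv"))
    yaml::write_yaml(corpus@params, file.path(dir, "params.yaml"))
    tdir <- file.path(dir, "truth")
    dir.create(tdir, showWarnings = FALSE)
    writeTable(corpus@truth$proteins, file.path(tdir, "proteins.tsv"))
    writeTable(corpus@truth$pairs, file.path(tdir, "pairs.tsv"))
    writeTable(corpus@truth$promoters$element_counts,
               file.path(tdir, "promoter_elements.tsv"))
    writeTable(corpus@truth$structure, file.path(tdir, "gene_structure.tsv"))
    yaml::write_yaml(list(designated_promoter = corpus@truth$promoters$designated,
                          expression = corpus@truth$expression),
                     file.path(tdir, "design.yaml"))
    invisible(dir)
}

writeCountsTsv <- function(mat, path) {
    df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                     stringsAsFactors = FALSE)
    writeTable(df, path)
}

readCountsTsv <- function(path) {
    df <- readTable(path)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    m
}

#' Read the public part of a corpus from disk
#'
#' Reconstructs a [MapkCorpus-class] from the files written by
#' [writeCorpus()], leaving the truth slot empty: analyses on a re-read
#' corpus are blind to the planted labels by construction.
#'
#' @param dir Directory written by [writeCorpus()].
#' @return A [MapkCorpus-class] with an empty `truth` slot.
#' @export
readCorpus <- function(dir) {
    models <- readGff3GeneModels(file.path(dir, "genes.gff3"))
    lens <- readTable(file.path(dir, "gene_lengths.tsv"))
    libs <- readTable(file.path(dir, "library_sizes.tsv"))
    methods::new("MapkCorpus",
        proteome = readProteinFasta(file.path(dir, "proteome.fasta")),
        referencePanel = readProteinFasta(file.path(dir, "references.fasta")),
        cds = readDnaFasta(file.path(dir, "cds.fasta")),
        genome = readDnaFasta(file.path(dir, "genome.fasta")),
        genes = models$genes,
        exons = models$exons,
        anchors = readAnchorTable(file.path(dir, "anchors.tsv")),
        tissueCounts = readCountsTsv(file.path(dir, "tissue_counts.tsv")),
        coldCounts = readCountsTsv(file.path(dir, "cold_counts.tsv")),
        geneLengths = stats::setNames(lens$length, lens$gene_id),
        librarySize = stats::setNames(libs$library_size, libs$sample),
        ctTable = readTable(file.path(dir, "ct_table.tsv")),
        truth = list(),
        params = yaml::read_yaml(file.path(dir, "params.yaml")))
}
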