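#' Default run configuration
#'
#' A single configuration list drives a pipeline run. The defaults reproduce
#' the thresholds used for the reference analysis: a 50\% reference-identity
#' screen, duplicate pairs called at >70\% coverage of the longer sequence
#' and >70\% identity, tandem pairs at most 100 kb apart on the same linkage
#' group, an FPKM detection floor of 1, a |log2 fold-change| cutoff of 1 with
#' Benjamini-Hochberg FDR at 0.05, and 1.5 kb promoter windows upstream of
#' the translation start.
#'
#' @param ... Named overrides for individual fields.
#' @return A named list of class `mapk_config`.
#' @examples
#' cfg <- defaultConfig(identity_screen = 40)
#' cfg$identity_screen
#' @export
defaultConfig <- function(...) {
    cfg <- list(
        identity_screen      = 50,     # % identity vs reference panel
        min_protein_length   = 200,    # aa, kinase-domain proxy
        redundancy_identity  = 99,     # % identity for redundancy removal
        redundancy_coverage  = 99,     # % mutual coverage for redundancy removal
        dup_coverage         = 70,     # % of longer sequence
        dup_identity         = 70,     # % identity
        tandem_max_distance  = 1e5,    # bp
        detection_floor      = 1,      # FPKM
        fold_change_cutoff   = 1,      # log2 units
        fdr_alpha            = 0.05,
        promoter_length      = 1500,   # bp upstream of ATG
        gap_open             = 10,
        gap_extend           = 0.5,
        codon_table          = "standard",
        seed                 = 42L
    )
    dots <- list(...)
    if (length(dots)) {
        unknown <- setdiff(names(dots), names(cfg))
        if (length(unknown))
            stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
        cfg[names(dots)] <- dots
    }
    validateConfig(cfg)
    class(cfg) <- c("mapk_config", "list")
    cfg
}

validateConfig <- function(cfg) {
    pct <- c("identity_screen", "redundancy_identity", "redundancy_coverage",
             "dup_coverage", "dup_identity")
    for (f in pct) {
        v <- cfg[[f]]
        if (!is.numeric(v) || length(v) != 1L || v <= 0 || v > 100)
            stop("configuration field '", f, "' must be in (0, 100]")
    }
    if (cfg$tandem_max_distance <= 0) stop("tandem_max_distance must be positive")
    if (cfg$detection_floor < 0) stop("detection_floor must be nonnegative")
    if (cfg$fdr_alpha <= 0 || cfg$fdr_alpha >= 1) stop("fdr_alpha must be in (0, 1)")
    if (cfg$fold_change_cutoff < 0) stop("fold_change_cutoff must be nonnegative")
    if (cfg$promoter_length <= 0) stop("promoter_length must be positive")
    if (cfg$min_protein_length < 0) stop("min_protein_length must be nonnegative")
    invisible(cfg)
}

#' Read / write a run configuration
#'
#' Configurations serialize to YAML and round-trip losslessly.
#'
#' @param path File path.
#' @param cfg A configuration list from [defaultConfig()].
#' @return `readConfig` returns the configuration list; `writeConfig` returns
#'   `path` invisibly.
#' @export
readConfig <- function(path) {
    raw <- yaml::read_yaml(path)
    do.call(defaultConfig, raw)
}

#' @rdname readConfig
#' @export
writeConfig <- function(cfg, path) {
    stopifnot(inherits(cfg, "mapk_config"))
    yaml::write_yaml(unclass(cfg), path)
    invisible(path)
}
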