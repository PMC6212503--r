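#' @useDynLib mapkcascade, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats cor cutree dist hclust p.adjust rbinom rnorm rpois runif t.test var setNames
#' @importFrom utils read.delim write.table combn head tail
NULL

# Stage logging: every pipeline stage reports input counts, survivors and the
# active thresholds so printed counts can be audited from the log. Controlled
# by options(mapkcascade.verbose = TRUE/FALSE).
mcLog <- function(...) {
    if (isTRUE(getOption("mapkcascade.verbose", FALSE)))
        message("[mapkcascade] ", sprintf(...))
    invisible(NULL)
}

#' Enable or disable pipeline stage logging
#'
#' When enabled, every pipeline stage logs its input counts, filter survivors
#' and the thresholds in force.
#'
#' @param on Logical; turn logging on or off.
#' @return The previous setting, invisibly.
#' @export
mapkVerbose <- function(on = TRUE) {
    old <- getOption("mapkcascade.verbose", FALSE)
    options(mapkcascade.verbose = isTRUE(on))
    invisible(old)
}

## amino-acid alphabet used throughout (20 residues + X for unknown)
AA_ALPHABET20 <- c("A","C","D","E","F","G","H","I","K","L",
                   "M","N","P","Q","R","S","T","V","W","Y")
AA_ALPHABET <- c(AA_ALPHABET20, "X")

assertAaString <- function(x, what = "sequence") {
    if (length(x) != 1L || is.na(x) || !nzchar(x))
        stop(what, " must be a single non-empty string")
    bad <- setdiff(strsplit(x, "")[[1]], AA_ALPHABET)
    if (length(bad))
        stop(what, " contains residues outside the amino-acid alphabet: ",
             paste(unique(bad), collapse = ", "))
    invisible(x)
}

# draw a seed below 2^31 derived from the session RNG
deriveSeed <- function() sample.int(2147483646L, 1L)

# character coercion that keeps names (base as.character drops them)
asNamedChar <- function(x) {
    nm <- names(x)
    out <- as.character(x)
    if (!is.null(nm)) names(out) <- nm
    out
}
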