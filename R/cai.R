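# Codon adaptation index.  Weights are relative adaptiveness values from a
# published highly-expressed reference set; they ship as a TSV so the code
# never hardcodes them.

#' Load CAI relative-adaptiveness weights
#'
#' Reads a two-column TSV (\code{codon}, \code{weight}).  The packaged
#' default is the S. cerevisiae relative adaptiveness table of Sharp & Li
#' (1987), in which the preferred codon of every amino acid has weight 1.
#'
#' @param path weights TSV; defaults to the packaged Sharp & Li table
#' @param provenance provenance string stored in the object
#' @return a \linkS4class{CaiWeights}
#' @export
loadCaiWeights <- function(path = system.file(
                               "extdata", "cai_weights_sharp_li_1987_sc.tsv",
                               package = "antisenseMotifs"),
                           provenance = "Sharp & Li (1987), S. cerevisiae") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (!all(c("codon", "weight") %in% names(tab)))
        stop("weights table must have columns 'codon' and 'weight'")
    methods::new("CaiWeights",
                 weights = stats::setNames(tab$weight, toupper(tab$codon)),
                 provenance = provenance)
}

#' Codon adaptation index of a coding sequence
#'
#' Geometric mean of the relative adaptiveness weights over the CDS's
#' codons.  Following the Sharp & Li convention, termination codons and the
#' two non-degenerate codons ATG (Met) and TGG (Trp) are excluded from the
#' mean.  Weights must be positive for every remaining codon.
#'
#' @param cds coding sequence(s): character vector or DNAStringSet, each of
#'   length divisible by 3
#' @param w a \linkS4class{CaiWeights} (default: packaged Sharp & Li table)
#' @return numeric vector of CAI values in (0, 1]
#' @examples
#' cai("ATGGCAGCA")  # two non-preferred Ala codons, CAI well below 1
#' @export
cai <- function(cds, w = loadCaiWeights()) {
    if (is(w, "CaiWeights")) w <- adaptiveness(w)
    if (any(w <= 0)) stop("CAI weights must be positive")
    gc <- Biostrings::GENETIC_CODE
    singlet <- names(gc)[gc %in% names(table(gc))[table(gc) == 1L] &
                             gc != "*"]
    excluded <- c(names(gc)[gc == "*"], singlet)
    cds <- asDNAStringSet(cds)
    vapply(seq_along(cds), function(i) {
        codons <- splitCodons(as.character(cds[[i]]))
        codons <- codons[!codons %in% excluded]
        if (!length(codons))
            stop("no scoreable codons in ", names(cds)[i])
        wi <- w[codons]
        if (anyNA(wi))
            stop("weights missing for codon(s): ",
                 paste(unique(codons[is.na(wi)]), collapse = ", "))
        exp(mean(log(wi)))
    }, numeric(1L))
}
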