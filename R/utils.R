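# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs \code{expr} with the global RNG seeded at \code{seed} and restores the
#' caller's RNG state afterwards, so package functions never leak random state.
#'
#' @param seed single integer seed
#' @param expr expression to evaluate
#' @return the value of \code{expr}
#' @keywords internal
withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("'seed' must be a single non-missing number")
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed)
        old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
        if (has_seed)
            assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# message-based logging with a level prefix; verbosity controlled by option
# 'antisenseMotifs.verbose' (default TRUE for INFO and above).
asmLog <- function(..., level = "INFO") {
    if (isFALSE(getOption("antisenseMotifs.verbose", TRUE)) && level == "INFO")
        return(invisible(NULL))
    message("[", level, "] ", ...)
}

# reverse complement for plain character vectors of DNA strings
revComp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# coerce character / DNAString / DNAStringSet input to a named DNAStringSet
asDNAStringSet <- function(x) {
    if (is(x, "DNAStringSet")) {
        ss <- x
    } else if (is(x, "DNAString")) {
        ss <- Biostrings::DNAStringSet(list(x))
    } else if (is.character(x)) {
        ss <- Biostrings::DNAStringSet(toupper(x))
    } else {
        stop("cannot interpret object of class '", class(x)[1L],
             "' as DNA sequence(s)")
    }
    if (is.null(names(ss)))
        names(ss) <- paste0("seq", seq_along(ss))
    ss
}

# split a CDS string into codons; error on frame violations
splitCodons <- function(cds) {
    cds <- toupper(as.character(cds))
    n <- nchar(cds)
    if (n %% 3L != 0L)
        stop("CDS length (", n, ") is not divisible by 3")
    substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

# translate codons to one-letter symbols with "*" for termination codons
codonToSymbol <- function(codons) {
    gc <- Biostrings::GENETIC_CODE
    sym <- unname(gc[codons])
    if (anyNA(sym))
        stop("unrecognised codon(s): ",
             paste(unique(codons[is.na(sym)]), collapse = ", "))
    sym
}

# package-level cache (motif site-count lookup tables etc.)
.asmCache <- new.env(parent = emptyenv())
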