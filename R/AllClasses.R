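#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom Biostrings DNAStringSet
NULL

#' MotifSet: consensus binding-site sequences for one RNA-binding protein
#'
#' A set of short RNA consensus motifs (written as DNA on the transcribed
#' strand) recognised by an RNA-binding protein such as Nrd1 or Nab3.  The
#' default sets are the tetramer/pentamer consensus sequences UGUA, GUAG,
#' UGUAG (Nrd1) and UCUU, CUUG, UCUUG (Nab3).
#'
#' @slot protein protein name, e.g. \code{"Nrd1"}
#' @slot motifs character vector of DNA motifs (4 or 5 nt, alphabet ACGT)
#' @export
setClass("MotifSet",
    representation(protein = "character", motifs = "character"))

setValidity("MotifSet", function(object) {
    msg <- NULL
    if (length(object@protein) != 1L || is.na(object@protein) ||
        !nzchar(object@protein))
        msg <- c(msg, "'protein' must be a single non-empty string")
    if (length(object@motifs) == 0L)
        msg <- c(msg, "motif set must contain at least one motif")
    if (any(!grepl("^[ACGT]+$", object@motifs)))
        msg <- c(msg, "motifs must be DNA strings over {A,C,G,T}")
    if (any(!nchar(object@motifs) %in% c(4L, 5L)))
        msg <- c(msg, "motifs must be 4 or 5 nt long")
    if (anyDuplicated(object@motifs))
        msg <- c(msg, "duplicated motifs in set")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "MotifSet", function(object) {
    cat("MotifSet for", object@protein, ":",
        paste(object@motifs, collapse = ", "), "\n")
})

#' BinnedProfile: metagene profile anchored at a codon
#'
#' Average per-bin signal (predicted-site density or expression-normalised
#' PAR-CLIP occupancy) around the start or stop codon of a set of ORFs,
#' binned in fixed windows.  Each bin carries the denominator: the number of
#' ORFs long enough (coding region for body bins, chromosome for flank bins)
#' to contribute.
#'
#' @slot kind \code{"density"} or \code{"occupancy"}
#' @slot anchor \code{"start_codon"} or \code{"stop_codon"}
#' @slot direction \code{"sense"} or \code{"antisense"}
#' @slot bins data.frame with columns \code{bin_start}, \code{bin_end},
#'   \code{value}, \code{denominator} (bin coordinates are relative to the
#'   anchor, half-open)
#' @slot nTranscripts number of ORFs the profile was built from
#' @export
setClass("BinnedProfile",
    representation(kind = "character", anchor = "character",
                   direction = "character", bins = "data.frame",
                   nTranscripts = "integer"))

setValidity("BinnedProfile", function(object) {
    msg <- NULL
    need <- c("bin_start", "bin_end", "value", "denominator")
    if (!all(need %in% names(object@bins)))
        msg <- c(msg, paste("bins must have columns",
                            paste(need, collapse = ", ")))
    else {
        v <- object@bins$value
        if (any(v[!is.na(v)] < 0))
            msg <- c(msg, "profile values must be non-negative")
        if (any(!is.finite(v) & !is.na(v)))
            msg <- c(msg, "profile values must be finite or NA")
    }
    if (!object@kind %in% c("density", "occupancy"))
        msg <- c(msg, "kind must be 'density' or 'occupancy'")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "BinnedProfile", function(object) {
    cat("BinnedProfile (", object@kind, "), anchor=", object@anchor,
        ", direction=", object@direction, ", ", nrow(object@bins),
        " bins over ", object@nTranscripts, " transcripts\n", sep = "")
    v <- object@bins$value
    cat("  mean value: ", signif(mean(v, na.rm = TRUE), 4), "\n", sep = "")
})

#' CodonUsageModel: class-conditional synonymous codon-combination usage
#'
#' Frequencies of codon combinations for every observed amino-acid pair
#' (adjacent codons, termination symbol allowed in either slot) and
#' motif-eligible triplet (middle residue Leu/Val for sense pentamers,
#' Lys/Tyr for antisense pentamers), fitted from the coding sequences of one
#' ORF class, together with the derived per-key probability that a
#' combination encodes an Nrd1/Nab3 motif in sense or antisense.
#'
#' @slot classLabel label of the ORF class the model was fitted from
#' @slot method \code{"pair"} (adjacent-codon combinations) or
#'   \code{"single"} (independent per-codon marginals)
#' @slot pairUsage data.frame key/combo/count/freq for amino-acid pairs
#' @slot tripletUsage data.frame key/combo/count/freq for triplets
#' @slot pairP matrix (keys x c(sense, antisense)) of expected motif sites
#'   per pair occurrence
#' @slot tripletP matrix (keys x c(sense, antisense)) for triplets
#' @slot nOrfs number of coding sequences used in the fit
#' @export
setClass("CodonUsageModel",
    representation(classLabel = "character", method = "character",
                   pairUsage = "data.frame", tripletUsage = "data.frame",
                   pairP = "matrix", tripletP = "matrix", nOrfs = "integer"))

setValidity("CodonUsageModel", function(object) {
    msg <- NULL
    if (!object@method %in% c("pair", "single"))
        msg <- c(msg, "method must be 'pair' or 'single'")
    if (nrow(object@pairUsage)) {
        s <- tapply(object@pairUsage$freq, object@pairUsage$key, sum)
        if (any(abs(s - 1) > 1e-8))
            msg <- c(msg, "pair combination frequencies must sum to 1 per key")
    }
    if (length(object@pairP) && (any(object@pairP < 0)))
        msg <- c(msg, "motif probabilities must be non-negative")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "CodonUsageModel", function(object) {
    cat("CodonUsageModel [", object@method, "] for class '",
        object@classLabel, "': ", length(unique(object@pairUsage$key)),
        " pair keys, ", length(unique(object@tripletUsage$key)),
        " triplet keys, fitted from ", object@nOrfs, " CDSs\n", sep = "")
})

#' CaiWeights: relative adaptiveness weights for CAI
#'
#' Per-codon relative adaptiveness values w in (0, 1] used by the codon
#' adaptation index, together with a provenance string naming the reference
#' set they were derived from.
#'
#' @slot weights named numeric vector, names are sense codons
#' @slot provenance free-text provenance of the reference set
#' @export
setClass("CaiWeights",
    representation(weights = "numeric", provenance = "character"))

setValidity("CaiWeights", function(object) {
    msg <- NULL
    w <- object@weights
    if (is.null(names(w)) || any(!grepl("^[ACGT]{3}$", names(w))))
        msg <- c(msg, "weights must be named by 3-letter DNA codons")
    if (any(w <= 0) || any(w > 1))
        msg <- c(msg, "weights must lie in (0, 1]")
    gc <- Biostrings::GENETIC_CODE
    aa <- gc[names(w)]
    if (!anyNA(aa)) {
        mx <- tapply(w, aa, max)
        if (any(abs(mx - 1) > 1e-6))
            msg <- c(msg, "the preferred codon of every amino acid must have weight 1")
    }
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "CaiWeights", function(object) {
    cat("CaiWeights:", length(object@weights), "codons;",
        object@provenance, "\n")
})

#' GeneratorConfig: parameters of the synthetic-data generator
#'
#' Everything the generator needs to emit a genome, transcript annotation,
#' expression track, PAR-CLIP-like read midpoints and ground truth.  The
#' defaults describe the simulation conditions used throughout the package's
#' validation: 300/150/150 CLEAR/CUT/SUT-like ORFs with class-specific
#' synonymous codon usage, yeast-like protein lengths and GC content.
#'
#' @slot seed integer; fixes every random choice
#' @slot nClear,nCut,nSut ORFs per class
#' @slot proteinLenMeanLog,proteinLenSdLog lognormal protein length (codons)
#' @slot proteinLenMin,proteinLenMax clamp on protein length
#' @slot utr5Range,utr3Range,gapRange,overlapRange,ncExtensionRange
#'   uniform sampling ranges (bp)
#' @slot gcContent background GC fraction of non-coding sequence
#' @slot aaFreqs named amino-acid sampling frequencies
#' @slot usageClear,usageCut,usageSut per-amino-acid codon probability lists
#' @slot pairCoupling named multipliers (CLEAR, CUT, SUT) applied to
#'   candidate codons whose junction with the previous codon hosts an
#'   antisense motif; 1 = independent codons, > 1 favours antisense motif
#'   encoding, < 1 avoids it while leaving sense encoding and the protein
#'   sequence essentially untouched
#' @slot exprMeanLog,exprSdLog lognormal sense expression
#' @slot antiExprMeanLog,antiExprSdLog lognormal antisense expression for
#'   CUT/SUT-overlapped ORFs
#' @slot baselineExpr expression floor used outside transcripts and for the
#'   antisense strand of CLEAR ORFs
#' @slot exprWindow expression track window size (bp)
#' @slot readRate coefficient linking expression x site density to the
#'   Poisson midpoint rate per 10 bp bin
#' @export
setClass("GeneratorConfig",
    representation(seed = "numeric",
                   nClear = "integer", nCut = "integer", nSut = "integer",
                   proteinLenMeanLog = "numeric", proteinLenSdLog = "numeric",
                   proteinLenMin = "integer", proteinLenMax = "integer",
                   utr5Range = "numeric", utr3Range = "numeric",
                   gapRange = "numeric", overlapRange = "numeric",
                   ncExtensionRange = "numeric",
                   gcContent = "numeric", aaFreqs = "numeric",
                   usageClear = "list", usageCut = "list", usageSut = "list",
                   pairCoupling = "numeric",
                   exprMeanLog = "numeric", exprSdLog = "numeric",
                   antiExprMeanLog = "numeric", antiExprSdLog = "numeric",
                   baselineExpr = "numeric", exprWindow = "integer",
                   readRate = "numeric"))

setValidity("GeneratorConfig", function(object) {
    msg <- NULL
    for (nm in c("usageClear", "usageCut", "usageSut")) {
        u <- slot(object, nm)
        bad <- vapply(u, function(p) abs(sum(p) - 1) > 1e-8 || any(p < 0),
                      logical(1L))
        if (any(bad))
            msg <- c(msg, paste0(nm, ": codon probabilities must be ",
                                 "non-negative and sum to 1 per amino acid"))
    }
    if (abs(sum(object@aaFreqs) - 1) > 1e-6)
        msg <- c(msg, "amino-acid frequencies must sum to 1")
    if (object@gcContent <= 0 || object@gcContent >= 1)
        msg <- c(msg, "gcContent must be in (0, 1)")
    rng <- c("utr5Range", "utr3Range", "gapRange", "overlapRange",
             "ncExtensionRange")
    for (nm in rng) {
        r <- slot(object, nm)
        if (length(r) != 2L || any(r <= 0) || r[2L] < r[1L])
            msg <- c(msg, paste0(nm, " must be an increasing positive pair"))
    }
    if (object@readRate < 0)
        msg <- c(msg, "readRate must be non-negative")
    if (length(object@pairCoupling) != 3L ||
        !identical(names(object@pairCoupling), c("CLEAR", "CUT", "SUT")) ||
        any(object@pairCoupling <= 0))
        msg <- c(msg, paste0("pairCoupling must be positive and named ",
                             "CLEAR, CUT, SUT"))
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "GeneratorConfig", function(object) {
    cat("GeneratorConfig: seed=", object@seed, "; ORFs ",
        object@nClear, "/", object@nCut, "/", object@nSut,
        " (CLEAR/CUT/SUT); pairCoupling=",
        paste(signif(object@pairCoupling, 3), collapse = "/"),
        "; readRate=", object@readRate, "\n", sep = "")
})

#' SyntheticDataset: generated genome, annotation, signal and ground truth
#'
#' Container for one synthetic dataset: the genome sequence, the transcript
#' annotation (ORFs plus antisense CUT/SUT ncRNAs), a strand-resolved
#' expression track in fixed windows, simulated PAR-CLIP read midpoints and
#' the per-ORF ground truth the generator committed to.
#'
#' @slot genome DNAStringSet
#' @slot transcripts GRanges with mcols id, ttype, cds_start, cds_end
#' @slot expression GRanges (5 bp windows) with mcols value
#' @slot midpoints GRanges (width-1 read midpoints)
#' @slot truth data.frame of per-ORF ground truth
#' @slot config the GeneratorConfig that produced the dataset
#' @export
setClass("SyntheticDataset",
    representation(genome = "DNAStringSet", transcripts = "GRanges",
                   expression = "GRanges", midpoints = "GRanges",
                   truth = "data.frame", config = "GeneratorConfig"))

setMethod("show", "SyntheticDataset", function(object) {
    cat("SyntheticDataset:", sum(width(object@genome)), "bp genome,",
        length(object@transcripts), "transcripts,",
        length(object@midpoints), "read midpoints,",
        nrow(object@truth), "ORFs with ground truth\n")
})
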