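#' Construct a motif set
#'
#' @param protein protein name
#' @param motifs character vector of 4/5-nt DNA motifs (sense-strand RNA
#'   motifs written as DNA)
#' @return a \linkS4class{MotifSet}
#' @export
motifSet <- function(protein, motifs) {
    methods::new("MotifSet", protein = protein,
                 motifs = toupper(unique(motifs)))
}

#' Default Nrd1 consensus motifs (UGUA, GUAG, UGUAG as DNA)
#'
#' A variant set replacing GUAG with GAUG circulates in parts of the
#' literature; the canonical set used here is GUAG, and any alternative can
#' be built with \code{\link{motifSet}}.
#'
#' @return a \linkS4class{MotifSet}
#' @export
nrd1Motifs <- function() motifSet("Nrd1", c("TGTA", "GTAG", "TGTAG"))

#' Default Nab3 consensus motifs (UCUU, CUUG, UCUUG as DNA)
#' @return a \linkS4class{MotifSet}
#' @export
nab3Motifs <- function() motifSet("Nab3", c("TCTT", "CTTG", "TCTTG"))

#' Both default motif sets
#' @return list of \linkS4class{MotifSet} (Nrd1, Nab3)
#' @export
defaultMotifSets <- function() list(nrd1Motifs(), nab3Motifs())

# find all exact occurrences of 'motif' on the plus strand of one sequence
.motifStarts <- function(seq, motif) {
    Biostrings::start(Biostrings::matchPattern(motif, seq, fixed = TRUE))
}

# longest-match suppression: a 4-mer occurrence is dropped iff its span lies
# within a reported 5-mer occurrence of the same motif set.  In genomic
# coordinates a length-4 span [s, s+3] is contained in a length-5 span
# [t, t+4] iff s == t or s == t + 1, on either strand.
.suppress4 <- function(starts4, starts5) {
    if (!length(starts4) || !length(starts5)) return(starts4)
    starts4[!(starts4 %in% starts5 | (starts4 - 1L) %in% starts5)]
}

#' Scan sequences for predicted Nrd1/Nab3 binding sites
#'
#' Finds every occurrence of the motifs in each set on the requested
#' strand(s), applying the longest-match rule: a 4-nt occurrence is
#' suppressed if and only if its span is contained within a reported 5-nt
#' occurrence of the same set; partially overlapping occurrences are all
#' reported.  Minus-strand sites are found by matching the
#' reverse-complemented motifs, so their coordinates stay in the frame of
#' the input sequence.  \code{N} never matches.
#'
#' @param subject DNAStringSet / DNAString / character vector of sequences
#' @param msets list of \linkS4class{MotifSet}s (default: Nrd1 and Nab3)
#' @param strand \code{"both"} (default), \code{"+"} or \code{"-"}
#' @return GRanges of sites with metadata columns \code{protein} and
#'   \code{motif} (the matched motif in its sense orientation)
#' @examples
#' sites <- scanMotifs("TGTAGTAG", strand = "+")
#' # two partially overlapping Nrd1 sites: TGTAG at 1 and GTAG at 5
#' start(sites)
#' @export
scanMotifs <- function(subject, msets = defaultMotifSets(),
                       strand = c("both", "+", "-")) {
    strand <- match.arg(strand)
    if (is(msets, "MotifSet")) msets <- list(msets)
    if (!length(msets) || !all(vapply(msets, is, logical(1L), "MotifSet")))
        stop("'msets' must be a non-empty list of MotifSet objects")
    subject <- asDNAStringSet(subject)
    strands <- if (strand == "both") c("+", "-") else strand

    recs <- list(); k <- 0L
    for (i in seq_along(subject)) {
        sq <- subject[[i]]
        for (ms in msets) {
            mot <- motifs(ms)
            for (st in strands) {
                pat <- if (st == "+") mot else revComp(mot)
                hits <- lapply(pat, .motifStarts, seq = sq)
                len <- nchar(mot)
                s5 <- unlist(hits[len == 5L], use.names = FALSE)
                keep <- hits
                for (j in which(len == 4L))
                    keep[[j]] <- .suppress4(hits[[j]], s5)
                n <- lengths(keep)
                if (sum(n) == 0L) next
                k <- k + 1L
                recs[[k]] <- data.frame(
                    seqnames = names(subject)[i],
                    start = unlist(keep, use.names = FALSE),
                    width = rep(len, n),
                    strand = st,
                    protein = protein(ms),
                    motif = rep(mot, n),
                    stringsAsFactors = FALSE)
            }
        }
    }
    if (!k) {
        gr <- GenomicRanges::GRanges()
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            protein = character(), motif = character())
        return(gr)
    }
    df <- do.call(rbind, recs)
    gr <- GenomicRanges::GRanges(
        seqnames = df$seqnames,
        ranges = IRanges::IRanges(start = df$start, width = df$width),
        strand = df$strand)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(protein = df$protein,
                                                 motif = df$motif)
    BiocGenerics::sort(gr, ignore.strand = TRUE)
}

#' Scan the antisense strand only
#'
#' Equivalent to scanning the reverse complement of the input and mapping
#' the coordinates back to the input frame.
#'
#' @inheritParams scanMotifs
#' @return GRanges of minus-strand sites
#' @export
scanAntisense <- function(subject, msets = defaultMotifSets()) {
    scanMotifs(subject, msets, strand = "-")
}

# the 5'-most base of each site in the strand of its scan: start on '+',
# end on '-'.  Used to assign sites to windows and bins unambiguously.
siteAnchorPos <- function(sites) {
    ifelse(as.character(GenomicRanges::strand(sites)) == "+",
           GenomicRanges::start(sites), GenomicRanges::end(sites))
}

# genomic window of length 'span' adjacent to an anchor, per transcript,
# in transcript orientation.  Returns start/end vectors plus a length check.
.anchorWindow <- function(tx, anchor, span) {
    m <- S4Vectors::mcols(tx)
    st <- as.character(GenomicRanges::strand(tx))
    if (anchor %in% c("start_codon", "stop_codon") &&
        any(is.na(m$cds_start)))
        stop("codon anchor requested for transcript(s) without a CDS: ",
             paste(m$id[is.na(m$cds_start)], collapse = ", "))
    txs <- GenomicRanges::start(tx); txe <- GenomicRanges::end(tx)
    res <- switch(anchor,
        tss = {
            len <- GenomicRanges::width(tx)
            ws <- ifelse(st == "+", txs, txe - span + 1L)
            we <- ifelse(st == "+", txs + span - 1L, txe)
            list(ws = ws, we = we, len = len)
        },
        start_codon = {
            len <- m$cds_end - m$cds_start + 1L
            ws <- ifelse(st == "+", m$cds_start, m$cds_end - span + 1L)
            we <- ifelse(st == "+", m$cds_start + span - 1L, m$cds_end)
            list(ws = ws, we = we, len = len)
        },
        stop_codon = {
            len <- m$cds_end - m$cds_start + 1L
            ws <- ifelse(st == "+", m$cds_end - span + 1L, m$cds_start)
            we <- ifelse(st == "+", m$cds_end, m$cds_start + span - 1L)
            list(ws = ws, we = we, len = len)
        },
        stop("unknown anchor: ", anchor))
    res
}

#' Count predicted sites in an anchored window per transcript
#'
#' Counts the predicted Nrd1+Nab3 sites whose 5'-most base falls in the
#' \code{span}-bp stretch of the transcript adjacent to the anchor (first
#' \code{span} bp after the TSS or start codon; last \code{span} bp before
#' the stop codon), on the sense or antisense strand of the transcript.
#' Transcripts (or coding regions) shorter than \code{span} get \code{NA}:
#' truncated windows are not comparable across transcripts.
#'
#' @param tx GRanges of transcripts (codon anchors require CDS columns)
#' @param genome DNAStringSet (used when \code{sites} is NULL)
#' @param anchor \code{"tss"}, \code{"start_codon"} or \code{"stop_codon"}
#' @param direction \code{"sense"} or \code{"antisense"}
#' @param span window length in bp (default 400)
#' @param msets motif sets (default Nrd1 + Nab3, pooled)
#' @param sites optional precomputed GRanges from \code{\link{scanMotifs}}
#'   over the genome (saves rescanning in repeated calls)
#' @return named integer vector of counts (NA where the window does not fit)
#' @export
countWindow <- function(tx, genome = NULL,
                        anchor = c("tss", "start_codon", "stop_codon"),
                        direction = c("sense", "antisense"),
                        span = 400L, msets = defaultMotifSets(),
                        sites = NULL) {
    anchor <- match.arg(anchor)
    direction <- match.arg(direction)
    if (is.null(sites)) {
        if (is.null(genome))
            stop("either 'genome' or precomputed 'sites' must be supplied")
        sites <- scanMotifs(genome, msets, strand = "both")
    }
    w <- .anchorWindow(tx, anchor, span)
    ok <- w$len >= span
    st <- as.character(GenomicRanges::strand(tx))
    want <- if (direction == "sense") st else c("+" = "-", "-" = "+")[st]
    pos <- siteAnchorPos(sites)
    posGR <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(sites),
        IRanges::IRanges(start = pos, width = 1L),
        strand = GenomicRanges::strand(sites))
    win <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(tx),
        IRanges::IRanges(start = pmax(1L, w$ws), end = w$we),
        strand = want)
    n <- GenomicRanges::countOverlaps(win, posGR, ignore.strand = FALSE)
    n[!ok] <- NA_integer_
    stats::setNames(as.integer(n), S4Vectors::mcols(tx)$id)
}

#' Count predicted sites in control regions
#'
#' Pools both strands and both motif sets, as for the intergenic control
#' distributions shown alongside transcript counts.
#'
#' @param regions GRanges from \code{\link{intergenicRegions}}
#' @param genome DNAStringSet
#' @param msets motif sets
#' @param sites optional precomputed genome scan
#' @return integer vector, one count per region
#' @export
intergenicSiteCounts <- function(regions, genome = NULL,
                                 msets = defaultMotifSets(), sites = NULL) {
    if (is.null(sites)) {
        if (is.null(genome))
            stop("either 'genome' or 'sites' must be supplied")
        sites <- scanMotifs(genome, msets, strand = "both")
    }
    pos <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(sites),
        IRanges::IRanges(start = siteAnchorPos(sites), width = 1L))
    GenomicRanges::countOverlaps(regions, pos, ignore.strand = TRUE)
}

#' Two-sided Wilcoxon rank-sum comparison of site counts
#'
#' Standard plumbing around \code{\link[stats]{wilcox.test}} (normal
#' approximation with continuity correction, as conventional for tied count
#' data).  Degenerate all-tied input returns p = 1 with a warning instead
#' of erroring.
#'
#' @param countsA,countsB numeric vectors of per-transcript site counts
#' @return the \code{htest} object (or a degenerate stand-in with
#'   \code{p.value = 1} for all-tied input)
#' @export
compareSiteCounts <- function(countsA, countsB) {
    countsA <- countsA[!is.na(countsA)]
    countsB <- countsB[!is.na(countsB)]
    if (!length(countsA) || !length(countsB))
        stop("both samples must be non-empty")
    if (length(unique(c(countsA, countsB))) == 1L) {
        warning("all observations tied; returning p = 1")
        return(structure(list(statistic = c(W = NA_real_), p.value = 1,
                              method = "Wilcoxon rank sum test (degenerate)",
                              data.name = "countsA and countsB"),
                         class = "htest"))
    }
    stats::wilcox.test(countsA, countsB, alternative = "two.sided",
                       exact = FALSE, correct = TRUE)
}
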