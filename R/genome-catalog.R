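#' Load a genome from a FASTA file
#'
#' Reads all records, upper-cases the sequences and validates the alphabet
#' (\code{A,C,G,T,N}).
#'
#' @param path FASTA file
#' @return a named \link[Biostrings]{DNAStringSet} with one entry per
#'   chromosome
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chrI", "acgtACGT"), fa)
#' loadGenome(fa)
#' @export
loadGenome <- function(path) {
    # read as raw strings first: the DNA reader silently drops characters
    # outside its alphabet, which would hide corrupt records
    raw <- tryCatch(
        Biostrings::readBStringSet(path, format = "fasta"),
        error = function(e) stop("malformed FASTA '", path, "': ",
                                 conditionMessage(e), call. = FALSE))
    if (length(raw) == 0L)
        stop("FASTA '", path, "' contains no records")
    # first whitespace-delimited token of the header is the chromosome name
    names(raw) <- sub("\\s.*$", "", names(raw))
    up <- toupper(as.character(raw))
    bad <- grepl("[^ACGTN]", up)
    if (any(bad))
        stop("record(s) with characters outside {A,C,G,T,N}: ",
             paste(names(raw)[bad], collapse = ", "))
    Biostrings::DNAStringSet(stats::setNames(up, names(raw)))
}

#' Load a transcript annotation table
#'
#' Reads a BED-like TSV with header columns \code{chrom start end id ttype
#' strand} and optional \code{cds_start cds_end} (required for ORFs).  The
#' native dialect is BED (0-based half-open); 1-based closed tables are
#' converted on load with \code{coords = "onebased"}.  Returned coordinates
#' follow the GenomicRanges convention (1-based closed).
#'
#' ORFs whose CDS length is not divisible by 3, or (when a genome is given)
#' whose CDS does not begin with ATG in transcript orientation, are retained
#' for interval-level analyses but flagged \code{cds_ok = FALSE} so codon
#' analyses can drop them.
#'
#' @param path TSV file with a header line
#' @param genome optional \code{DNAStringSet}; when given, coordinates are
#'   validated against chromosome bounds and start codons are checked
#' @param coords input coordinate dialect, \code{"bed"} (default) or
#'   \code{"onebased"}
#' @return a \link[GenomicRanges]{GRanges} with metadata columns \code{id},
#'   \code{ttype}, \code{cds_start}, \code{cds_end} (1-based, NA for
#'   ncRNAs), \code{cds_ok}
#' @export
loadTranscripts <- function(path, genome = NULL,
                            coords = c("bed", "onebased")) {
    coords <- match.arg(coords)
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, comment.char = "#")
    need <- c("chrom", "start", "end", "id", "ttype", "strand")
    if (!all(need %in% names(tab)))
        stop("transcript table must have columns: ",
             paste(need, collapse = ", "))
    if (anyDuplicated(tab$id))
        stop("duplicate transcript id(s): ",
             paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
    if (!all(tab$ttype %in% c("ORF", "CUT", "SUT")))
        stop("ttype must be one of ORF, CUT, SUT")
    if (!all(tab$strand %in% c("+", "-")))
        stop("strand must be '+' or '-'")
    has_cds <- all(c("cds_start", "cds_end") %in% names(tab))
    if (!has_cds && any(tab$ttype == "ORF"))
        stop("ORF rows require cds_start/cds_end columns")
    if (coords == "bed") {
        tab$start <- tab$start + 1L
        if (has_cds) tab$cds_start <- tab$cds_start + 1L
    }
    if (any(tab$end < tab$start))
        stop("transcript with end < start: ",
             paste(tab$id[tab$end < tab$start], collapse = ", "))
    if (!has_cds)
        tab$cds_start <- tab$cds_end <- NA_integer_
    is_orf <- tab$ttype == "ORF"
    tab$cds_start[!is_orf] <- NA_integer_
    tab$cds_end[!is_orf] <- NA_integer_
    if (any(is_orf & (is.na(tab$cds_start) | is.na(tab$cds_end))))
        stop("ORF rows with missing CDS coordinates: ",
             paste(tab$id[is_orf & is.na(tab$cds_start)], collapse = ", "))
    bad_cds <- is_orf & (tab$cds_start < tab$start | tab$cds_end > tab$end)
    if (any(bad_cds))
        stop("CDS outside transcript interval for: ",
             paste(tab$id[bad_cds], collapse = ", "))

    gr <- GenomicRanges::GRanges(
        seqnames = tab$chrom,
        ranges = IRanges::IRanges(start = tab$start, end = tab$end),
        strand = tab$strand)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        id = tab$id, ttype = tab$ttype,
        cds_start = as.integer(tab$cds_start),
        cds_end = as.integer(tab$cds_end))

    cds_ok <- rep(TRUE, length(gr))
    cds_len <- tab$cds_end - tab$cds_start + 1L
    off_frame <- is_orf & (cds_len %% 3L != 0L)
    if (any(off_frame)) {
        cds_ok[off_frame] <- FALSE
        asmLog("excluding from codon analyses (CDS length not divisible ",
               "by 3): ", paste(tab$id[off_frame], collapse = ", "))
    }
    if (!is.null(genome)) {
        if (!all(tab$chrom %in% names(genome)))
            stop("chromosome(s) absent from genome: ",
                 paste(setdiff(tab$chrom, names(genome)), collapse = ", "))
        lens <- Biostrings::width(genome)[match(tab$chrom, names(genome))]
        if (any(tab$end > lens))
            stop("transcript(s) beyond chromosome end: ",
                 paste(tab$id[tab$end > lens], collapse = ", "))
        chk <- which(is_orf & cds_ok)
        if (length(chk)) {
            first <- cdsSequence(gr[chk], genome)
            no_atg <- !startsWith(as.character(Biostrings::subseq(
                first, 1L, pmin(Biostrings::width(first), 3L))), "ATG")
            if (any(no_atg)) {
                cds_ok[chk[no_atg]] <- FALSE
                asmLog("excluding from codon analyses (CDS does not begin ",
                       "with ATG): ",
                       paste(tab$id[chk[no_atg]], collapse = ", "))
            }
        }
        lens_all <- stats::setNames(Biostrings::width(genome), names(genome))
        GenomeInfoDb::seqlengths(gr) <-
            lens_all[GenomeInfoDb::seqlevels(gr)]
    }
    S4Vectors::mcols(gr)$cds_ok <- cds_ok
    gr
}

#' Extract CDS sequences in transcript orientation
#'
#' @param orfs GRanges of ORF transcripts with \code{cds_start}/\code{cds_end}
#' @param genome DNAStringSet
#' @return DNAStringSet, one CDS per ORF, reverse-complemented for minus-strand
#'   ORFs, named by transcript id
#' @export
cdsSequence <- function(orfs, genome) {
    m <- S4Vectors::mcols(orfs)
    if (any(is.na(m$cds_start)))
        stop("cdsSequence() requires CDS coordinates on every input range")
    seqs <- Biostrings::DNAStringSet(vapply(seq_along(orfs), function(i) {
        chr <- as.character(GenomicRanges::seqnames(orfs)[i])
        s <- as.character(Biostrings::subseq(genome[[chr]],
                                             m$cds_start[i], m$cds_end[i]))
        s
    }, character(1L)))
    neg <- as.character(GenomicRanges::strand(orfs)) == "-"
    if (any(neg))
        seqs[neg] <- Biostrings::reverseComplement(seqs[neg])
    names(seqs) <- m$id
    seqs
}

#' Drop transcripts shorter than a minimum length
#'
#' @param tx GRanges from \code{\link{loadTranscripts}}
#' @param minLen minimum transcript length in bp (default 200)
#' @return the surviving GRanges; removal counts per transcript type are
#'   logged
#' @export
filterMinLength <- function(tx, minLen = 200L) {
    keep <- GenomicRanges::width(tx) >= minLen
    if (any(!keep)) {
        drop <- table(S4Vectors::mcols(tx)$ttype[!keep])
        asmLog("filterMinLength: removed ",
               paste(paste0(drop, " ", names(drop)), collapse = ", "),
               " (< ", minLen, " bp)")
    }
    tx[keep]
}

# maximum single-transcript antisense overlap (bp) of each ORF with a set of
# ncRNAs; 0 when there is none
.maxAntisenseOverlap <- function(orfs, nc) {
    out <- integer(length(orfs))
    if (length(nc) == 0L) return(out)
    hits <- GenomicRanges::findOverlaps(orfs, nc, ignore.strand = TRUE)
    if (length(hits) == 0L) return(out)
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    anti <- as.character(GenomicRanges::strand(orfs))[q] !=
        as.character(GenomicRanges::strand(nc))[s]
    q <- q[anti]; s <- s[anti]
    if (!length(q)) return(out)
    ov <- pmin(GenomicRanges::end(orfs)[q], GenomicRanges::end(nc)[s]) -
        pmax(GenomicRanges::start(orfs)[q], GenomicRanges::start(nc)[s]) + 1L
    mx <- tapply(ov, q, max)
    out[as.integer(names(mx))] <- as.integer(mx)
    out
}

#' Classify ORFs by antisense CUT/SUT overlap
#'
#' Assigns each ORF to \code{ORF_CUT} (antisense CUT overlap of at least
#' \code{minOverlap} bp and no such SUT overlap), \code{ORF_SUT}
#' (symmetric), \code{EXCLUDED} (both a CUT and a SUT overlap of at least
#' \code{minOverlap} bp) or \code{ORF_CLEAR} (everything else, including
#' antisense overlaps below the threshold).  When one ORF has several
#' antisense ncRNAs of a type, the overlap is the maximum single-transcript
#' overlap.  ORFs overlapping another ORF by more than \code{orfOrfMax} bp
#' (any strand), or flagged \code{cds_ok = FALSE} on load, are additionally
#' marked ineligible for codon-usage and PAR-CLIP analyses.
#'
#' @param tx GRanges of length-filtered transcripts (ORFs + ncRNAs)
#' @param minOverlap minimum antisense overlap in bp (default 100)
#' @param orfOrfMax maximum tolerated ORF-ORF overlap in bp (default 10)
#' @return data.frame with columns \code{orf_id}, \code{label},
#'   \code{antisense_overlap_bp}, \code{cut_overlap_bp},
#'   \code{sut_overlap_bp}, \code{orf_overlap_bp}, \code{codon_eligible}
#' @export
classifyOrfs <- function(tx, minOverlap = 100L, orfOrfMax = 10L) {
    m <- S4Vectors::mcols(tx)
    orfs <- tx[m$ttype == "ORF"]
    cuts <- tx[m$ttype == "CUT"]
    suts <- tx[m$ttype == "SUT"]
    if (length(orfs) == 0L)
        stop("no ORF transcripts to classify")
    cutOv <- .maxAntisenseOverlap(orfs, cuts)
    sutOv <- .maxAntisenseOverlap(orfs, suts)
    label <- rep("ORF_CLEAR", length(orfs))
    label[cutOv >= minOverlap & sutOv < minOverlap] <- "ORF_CUT"
    label[sutOv >= minOverlap & cutOv < minOverlap] <- "ORF_SUT"
    label[cutOv >= minOverlap & sutOv >= minOverlap] <- "EXCLUDED"

    # ORF-ORF overlap (any strand), max over partners
    orfOv <- integer(length(orfs))
    if (length(orfs) > 1L) {
        hits <- GenomicRanges::findOverlaps(orfs, ignore.strand = TRUE,
                                            drop.self = TRUE)
        if (length(hits)) {
            q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
            ov <- pmin(GenomicRanges::end(orfs)[q],
                       GenomicRanges::end(orfs)[s]) -
                pmax(GenomicRanges::start(orfs)[q],
                     GenomicRanges::start(orfs)[s]) + 1L
            mx <- tapply(ov, q, max)
            orfOv[as.integer(names(mx))] <- as.integer(mx)
        }
    }
    eligible <- orfOv <= orfOrfMax & S4Vectors::mcols(orfs)$cds_ok
    data.frame(orf_id = S4Vectors::mcols(orfs)$id,
               label = label,
               antisense_overlap_bp = pmax(cutOv, sutOv),
               cut_overlap_bp = cutOv,
               sut_overlap_bp = sutOv,
               orf_overlap_bp = orfOv,
               codon_eligible = eligible,
               stringsAsFactors = FALSE)
}

#' Orientation of adjacent non-overlapping ORF pairs
#'
#' Labels each adjacent, non-overlapping pair of ORF transcripts on a
#' chromosome as \code{tandem} (same strand), \code{divergent} (5' ends
#' facing: left on minus, right on plus) or \code{convergent} (3' ends
#' facing: left on plus, right on minus).
#'
#' @param tx GRanges of transcripts; only ORFs are considered
#' @return data.frame with columns \code{left_id}, \code{right_id},
#'   \code{orientation}
#' @export
neighborOrientation <- function(tx) {
    orfs <- tx[S4Vectors::mcols(tx)$ttype == "ORF"]
    res <- list()
    for (chr in unique(as.character(GenomicRanges::seqnames(orfs)))) {
        o <- orfs[as.character(GenomicRanges::seqnames(orfs)) == chr]
        o <- o[order(GenomicRanges::start(o), GenomicRanges::end(o))]
        if (length(o) < 2L) next
        left <- o[-length(o)]; right <- o[-1L]
        nonov <- GenomicRanges::start(right) > GenomicRanges::end(left)
        if (!any(nonov)) next
        ls <- as.character(GenomicRanges::strand(left))[nonov]
        rs <- as.character(GenomicRanges::strand(right))[nonov]
        orient <- ifelse(ls == rs, "tandem",
                         ifelse(ls == "-" & rs == "+", "divergent",
                                "convergent"))
        res[[chr]] <- data.frame(
            left_id = S4Vectors::mcols(left)$id[nonov],
            right_id = S4Vectors::mcols(right)$id[nonov],
            orientation = orient, stringsAsFactors = FALSE)
    }
    if (!length(res))
        return(data.frame(left_id = character(), right_id = character(),
                          orientation = character()))
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Intergenic control regions
#'
#' Finds maximal regions covered by no transcript on either strand and takes
#' the centered \code{window}-bp interval from every gap at least
#' \code{window} bp wide, one control region per gap.
#'
#' @param genome DNAStringSet (defines chromosome lengths)
#' @param tx GRanges of transcripts
#' @param window control window size in bp (default 400)
#' @return GRanges of strand-less control windows
#' @export
intergenicRegions <- function(genome, tx, window = 400L) {
    out <- list()
    for (chr in names(genome)) {
        len <- Biostrings::width(genome)[match(chr, names(genome))]
        sel <- tx[as.character(GenomicRanges::seqnames(tx)) == chr]
        cov <- IRanges::reduce(IRanges::IRanges(
            start = GenomicRanges::start(sel), end = GenomicRanges::end(sel)))
        gaps <- IRanges::setdiff(IRanges::IRanges(1L, len), cov)
        gaps <- gaps[IRanges::width(gaps) >= window]
        if (length(gaps) == 0L) next
        mid <- IRanges::start(gaps) +
            (IRanges::width(gaps) - window) %/% 2L
        out[[chr]] <- GenomicRanges::GRanges(
            chr, IRanges::IRanges(start = mid, width = window), strand = "*")
    }
    if (!length(out)) return(GenomicRanges::GRanges())
    unname(do.call(c, unname(out)))
}
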