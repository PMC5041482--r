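# Metagene binning shared by site-density and PAR-CLIP occupancy profiles.
#
# Relative coordinate convention: for the start-codon anchor, r = 0 is the
# first CDS base, so bins [0, flank) lie in the coding region and
# [-flank, 0) in the upstream genomic flank.  For the stop-codon anchor,
# r = 0 is the first base after the CDS, so bins [-flank, 0) are the last
# flank bp of the coding region and [0, flank) the downstream flank.
# A transcript contributes to a body bin only if its coding region covers
# the whole bin, and to a flank bin only if the chromosome does; the
# per-bin denominator records how many transcripts contribute.

.anchorPointRel <- function(tx, anchor) {
    m <- S4Vectors::mcols(tx)
    if (any(is.na(m$cds_start)))
        stop("metagene anchors require CDS coordinates on every transcript")
    st <- as.character(GenomicRanges::strand(tx))
    a <- if (anchor == "start_codon")
        ifelse(st == "+", m$cds_start, m$cds_end)
    else  # stop_codon: first position after the CDS, in orientation
        ifelse(st == "+", m$cds_end + 1L, m$cds_start - 1L)
    list(a = as.numeric(a), st = st,
         cdslen = as.numeric(m$cds_end - m$cds_start + 1L))
}

# logical nOrf x nBin matrix saying which ORF contributes to which bin
.contributionMatrix <- function(tx, anchor, flank, bin) {
    ap <- .anchorPointRel(tx, anchor)
    binStarts <- seq(-flank, flank - bin, by = bin)
    chrlen <- GenomeInfoDb::seqlengths(tx)[
        as.character(GenomicRanges::seqnames(tx))]
    if (anyNA(chrlen))
        stop("transcripts must carry seqlengths (load with a genome)")
    contrib <- matrix(FALSE, length(tx), length(binStarts))
    for (j in seq_along(binStarts)) {
        b <- binStarts[j]
        body <- if (anchor == "start_codon") b >= 0 else b < 0
        if (body) {
            need <- if (anchor == "start_codon") b + bin else -b
            contrib[, j] <- ap$cdslen >= need
        } else {
            # flank bin: both genomic ends of the bin must be on-chromosome
            r1 <- b; r2 <- b + bin - 1L
            p1 <- ifelse(ap$st == "+", ap$a + r1, ap$a - r1)
            p2 <- ifelse(ap$st == "+", ap$a + r2, ap$a - r2)
            lo <- pmin(p1, p2); hi <- pmax(p1, p2)
            contrib[, j] <- lo >= 1 & hi <= chrlen
        }
    }
    list(contrib = contrib, binStarts = binStarts, ap = ap)
}

# core metagene aggregation over genomic point positions (site anchors or
# read midpoints).  'weight' is a per-transcript multiplier (1 for density,
# 1/expression for occupancy).
.metageneProfile <- function(tx, posGR, anchor, direction, flank, bin,
                             weight = rep(1, length(tx))) {
    cm <- .contributionMatrix(tx, anchor, flank, bin)
    binStarts <- cm$binStarts
    st <- cm$ap$st
    want <- if (direction == "sense") st else c("+" = "-", "-" = "+")[st]
    win <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(tx),
        IRanges::IRanges(
            start = pmax(1, ifelse(st == "+", cm$ap$a - flank,
                                   cm$ap$a - flank + 1)),
            end = ifelse(st == "+", cm$ap$a + flank - 1, cm$ap$a + flank)))
    hits <- GenomicRanges::findOverlaps(win, posGR, ignore.strand = TRUE)
    num <- numeric(length(binStarts))
    if (length(hits)) {
        q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
        okStrand <- as.character(GenomicRanges::strand(posGR))[s] == want[q]
        q <- q[okStrand]; s <- s[okStrand]
        if (length(q)) {
            p <- GenomicRanges::start(posGR)[s]
            r <- ifelse(st[q] == "+", p - cm$ap$a[q], cm$ap$a[q] - p)
            j <- (r + flank) %/% bin + 1L
            keep <- r >= -flank & r < flank
            keep[keep] <- cm$contrib[cbind(q[keep], j[keep])]
            if (any(keep)) {
                agg <- tapply(weight[q[keep]], j[keep], sum)
                num[as.integer(names(agg))] <- agg
            }
        }
    }
    denom <- colSums(cm$contrib)
    value <- ifelse(denom > 0, num / denom, NA_real_)
    data.frame(bin_start = binStarts, bin_end = binStarts + bin,
               value = value, denominator = denom)
}

#' Metagene density profile of predicted binding sites
#'
#' Average number of predicted Nrd1+Nab3 sites per contributing ORF in
#' fixed bins around the start or stop codon, on the sense or antisense
#' strand.  Sites are assigned to bins by their 5'-most base; each bin is
#' normalised by the number of ORFs whose coding region (body bins) or
#' chromosome (flank bins) covers the bin.
#'
#' @param orfs GRanges of ORFs of one class (with CDS columns and
#'   seqlengths)
#' @param genome DNAStringSet (used when \code{sites} is NULL)
#' @param anchor \code{"start_codon"} or \code{"stop_codon"}
#' @param direction \code{"sense"} or \code{"antisense"}
#' @param flank half-width of the profiled window in bp (default 400)
#' @param bin bin width in bp (default 10)
#' @param msets motif sets (default Nrd1 + Nab3, pooled)
#' @param sites optional precomputed genome-wide site GRanges
#' @return a \linkS4class{BinnedProfile} of kind \code{"density"}
#' @export
densityProfile <- function(orfs, genome = NULL,
                           anchor = c("start_codon", "stop_codon"),
                           direction = c("sense", "antisense"),
                           flank = 400L, bin = 10L,
                           msets = defaultMotifSets(), sites = NULL) {
    anchor <- match.arg(anchor)
    direction <- match.arg(direction)
    if (length(orfs) == 0L)
        stop("'orfs' is empty")
    if (is.null(sites)) {
        if (is.null(genome))
            stop("either 'genome' or 'sites' must be supplied")
        sites <- scanMotifs(genome, msets, strand = "both")
    }
    posGR <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(sites),
        IRanges::IRanges(start = siteAnchorPos(sites), width = 1L),
        strand = GenomicRanges::strand(sites))
    bins <- .metageneProfile(orfs, posGR, anchor, direction, flank, bin)
    methods::new("BinnedProfile", kind = "density", anchor = anchor,
                 direction = direction, bins = bins,
                 nTranscripts = length(orfs))
}

#' Write a profile to a TSV file
#'
#' @param profile a \linkS4class{BinnedProfile}
#' @param path output file
#' @export
writeProfile <- function(profile, path) {
    utils::write.table(profileBins(profile), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
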