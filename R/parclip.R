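# PAR-CLIP occupancy: read midpoints, expression normalisation, metagene
# occupancy profiles.  Upstream read cleaning and mapping are out of scope;
# this module consumes already-aligned reads (BED6 of alignments, or BAM
# when Rsamtools is available).

#' Load aligned-read midpoints
#'
#' Computes one midpoint per alignment, \code{floor((start0 + end0) / 2)}
#' in 0-based terms (reported 1-based in the returned GRanges).  BED6 input
#' is native; \code{.bam} files are read through Rsamtools when installed,
#' skipping unmapped records with a logged count.
#'
#' @param path BED6 file (chrom, start, end, name, score, strand) or BAM
#' @return GRanges of width-1 midpoints with alignment strand
#' @export
loadMidpoints <- function(path) {
    if (grepl("\\.bam$", path, ignore.case = TRUE)) {
        if (!requireNamespace("Rsamtools", quietly = TRUE))
            stop("BAM input requires the Rsamtools package")
        p <- Rsamtools::ScanBamParam(what = c("rname", "pos", "qwidth",
                                              "strand", "flag"))
        b <- Rsamtools::scanBam(path, param = p)[[1L]]
        mapped <- !bitwAnd(b$flag, 4L)
        if (any(!mapped))
            asmLog("loadMidpoints: skipped ", sum(!mapped),
                   " unmapped record(s)")
        start1 <- b$pos[mapped]
        end1 <- start1 + b$qwidth[mapped] - 1L
        chrom <- as.character(b$rname)[mapped]
        strand <- as.character(b$strand)[mapped]
    } else {
        tab <- utils::read.table(path, header = FALSE, sep = "\t",
                                 stringsAsFactors = FALSE)
        if (ncol(tab) < 6L)
            stop("alignment BED must have at least 6 columns")
        chrom <- tab[[1L]]
        start1 <- tab[[2L]] + 1L   # BED is 0-based half-open
        end1 <- tab[[3L]]
        strand <- tab[[6L]]
    }
    if (!length(chrom))
        return(GenomicRanges::GRanges())
    # midpoint in 0-based coords is floor((start0+end0)/2); +1 for 1-based
    mid1 <- ((start1 - 1L) + end1) %/% 2L + 1L
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start = mid1, width = 1L),
                           strand = strand)
}

#' Load a strand-resolved expression track
#'
#' BedGraph-like TSV with header \code{chrom start end value strand} on a
#' fixed window grid (the replicate-averaged tiling values; the
#' conventional grid is 5 bp).  BED-dialect (0-based half-open) starts.
#'
#' @param path TSV file
#' @return GRanges with metadata column \code{value}
#' @export
loadExpressionTrack <- function(path) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "value", "strand")
    if (!all(need %in% names(tab)))
        stop("expression track must have columns: ",
             paste(need, collapse = ", "))
    if (any(tab$value < 0))
        stop("expression values must be non-negative")
    gr <- GenomicRanges::GRanges(
        tab$chrom,
        IRanges::IRanges(start = tab$start + 1L, end = tab$end),
        strand = tab$strand)
    S4Vectors::mcols(gr)$value <- tab$value
    gr
}

#' Sense and antisense expression level of ORFs
#'
#' The mean of the track-window values overlapping the ORF interval, per
#' strand (sense = the ORF's strand).
#'
#' @param orfs GRanges of ORFs
#' @param track GRanges from \code{\link{loadExpressionTrack}}
#' @return data.frame with columns \code{id}, \code{sense},
#'   \code{antisense}
#' @export
orfExpression <- function(orfs, track) {
    st <- as.character(GenomicRanges::strand(orfs))
    tst <- as.character(GenomicRanges::strand(track))
    val <- S4Vectors::mcols(track)$value
    hits <- GenomicRanges::findOverlaps(orfs, track, ignore.strand = TRUE)
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    same <- tst[s] == st[q]
    mean_by <- function(idx, vals) {
        out <- rep(NA_real_, length(orfs))
        if (length(idx)) {
            m <- tapply(vals, idx, mean)
            out[as.integer(names(m))] <- as.numeric(m)
        }
        out
    }
    sense <- mean_by(q[same], val[s[same]])
    anti <- mean_by(q[!same], val[s[!same]])
    nocov <- is.na(sense) & is.na(anti)
    if (any(nocov))
        stop("no expression coverage for ORF(s): ",
             paste(S4Vectors::mcols(orfs)$id[nocov], collapse = ", "))
    data.frame(id = S4Vectors::mcols(orfs)$id, sense = sense,
               antisense = anti, stringsAsFactors = FALSE)
}

#' Expression-normalised PAR-CLIP occupancy profile
#'
#' Bins read midpoints around the start or stop codon exactly as
#' \code{\link{densityProfile}} bins predicted sites, divides each ORF's
#' binned counts by its strand-appropriate expression level, and averages
#' over the ORFs contributing to each bin.  ORFs whose expression on the
#' required strand is missing or below \code{exprFloor} are skipped with a
#' logged reason (unbounded ratios are worse than a smaller class).
#'
#' @param orfs GRanges of ORFs of one class
#' @param midpoints GRanges from \code{\link{loadMidpoints}}
#' @param track GRanges from \code{\link{loadExpressionTrack}}
#' @param anchor \code{"start_codon"} or \code{"stop_codon"}
#' @param direction \code{"sense"} or \code{"antisense"}
#' @param flank,bin window geometry in bp (defaults 400 / 10)
#' @param exprFloor minimum usable expression (default 1e-6)
#' @return a \linkS4class{BinnedProfile} of kind \code{"occupancy"}
#' @export
occupancyProfile <- function(orfs, midpoints, track,
                             anchor = c("start_codon", "stop_codon"),
                             direction = c("sense", "antisense"),
                             flank = 400L, bin = 10L, exprFloor = 1e-6) {
    anchor <- match.arg(anchor)
    direction <- match.arg(direction)
    if (length(orfs) == 0L) stop("'orfs' is empty")
    ex <- orfExpression(orfs, track)
    lev <- if (direction == "sense") ex$sense else ex$antisense
    usable <- !is.na(lev) & lev >= exprFloor
    if (any(!usable))
        asmLog("occupancyProfile: skipped ", sum(!usable), " ORF(s) with ",
               direction, " expression below ", exprFloor)
    if (!any(usable))
        stop("no ORF with usable ", direction, " expression")
    orfs <- orfs[usable]
    bins <- .metageneProfile(orfs, midpoints, anchor, direction, flank, bin,
                             weight = 1 / lev[usable])
    methods::new("BinnedProfile", kind = "occupancy", anchor = anchor,
                 direction = direction, bins = bins,
                 nTranscripts = length(orfs))
}

#' Mean expression-normalised occupancy of intergenic control regions
#'
#' Strand-pooled midpoint counts per region divided by the region's
#' strand-pooled mean expression, averaged over regions.  Regions with
#' pooled expression below \code{exprFloor} are dropped.
#'
#' @param regions GRanges from \code{\link{intergenicRegions}}
#' @param midpoints GRanges of read midpoints
#' @param track expression GRanges
#' @param exprFloor minimum usable expression
#' @return single numeric value (0 when there are no reads)
#' @export
intergenicOccupancy <- function(regions, midpoints, track,
                                exprFloor = 1e-6) {
    if (length(regions) == 0L) stop("'regions' is empty")
    cnt <- GenomicRanges::countOverlaps(regions, midpoints,
                                        ignore.strand = TRUE)
    hits <- GenomicRanges::findOverlaps(regions, track, ignore.strand = TRUE)
    expr <- rep(NA_real_, length(regions))
    if (length(hits)) {
        m <- tapply(S4Vectors::mcols(track)$value[
            S4Vectors::subjectHits(hits)], S4Vectors::queryHits(hits), mean)
        expr[as.integer(names(m))] <- as.numeric(m)
    }
    ok <- !is.na(expr) & expr >= exprFloor
    if (!any(ok)) stop("no control region with usable expression")
    mean(cnt[ok] / expr[ok])
}
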