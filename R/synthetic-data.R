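# Seeded generator for genomes, annotations, expression tracks and
# PAR-CLIP-like read midpoints with full ground truth.  The generator
# emulates the statistical structure the analysis assumes -- class-specific
# synonymous codon usage inside ORFs, antisense CUT/SUT annotations
# overlapping ORF 3' ends by at least the classification threshold, and
# read midpoints Poisson-distributed at a rate proportional to expression
# times (1 + local antisense site count).

#' Packaged yeast-like amino-acid frequencies
#'
#' Approximate S. cerevisiae proteome amino-acid frequencies used as the
#' default protein model of the generator (shipped as a TSV).
#'
#' @return named numeric vector over the 20 amino acids, summing to 1
#' @export
yeastAminoAcidFreqs <- function() {
    tab <- utils::read.table(
        system.file("extdata", "aa_frequencies_scerevisiae.tsv",
                    package = "antisenseMotifs"),
        header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    v <- stats::setNames(tab$freq, tab$aa)
    v / sum(v)
}

# codons whose presence at a pair junction tends to create antisense
# Nrd1/Nab3 motifs on the template strand (e.g. CTA-AGA -> TCTTAG in
# antisense); boosting or suppressing them shifts antisense motif encoding
# without touching the protein sequence
.ANTI_PRONE <- c("CTA", "TTA", "TAC", "AAG", "ACT", "AGA")

#' Per-amino-acid synonymous codon sampling probabilities
#'
#' \code{"uniform"} spreads mass equally over synonymous codons;
#' \code{"antisense-rich"} multiplies the weight of codons prone to create
#' antisense motifs at pair junctions by \code{strength};
#' \code{"antisense-poor"} divides it.  The amino-acid sequence
#' distribution is unaffected, isolating the codon-usage effect.
#'
#' @param bias usage flavour
#' @param strength multiplicative bias (default 4)
#' @return named list: symbol (incl. \code{"*"}) -> codon probability vector
#' @export
codonUsageParams <- function(bias = c("uniform", "antisense-rich",
                                      "antisense-poor"), strength = 4) {
    bias <- match.arg(bias)
    cb <- .codonsBySymbol()
    lapply(cb, function(codons) {
        w <- rep(1, length(codons))
        if (bias != "uniform") {
            hit <- codons %in% .ANTI_PRONE
            w[hit] <- if (bias == "antisense-rich") w[hit] * strength
                      else w[hit] / strength
        }
        stats::setNames(w / sum(w), codons)
    })
}

#' Build a generator configuration
#'
#' Defaults describe the package's standard simulation: 300/150/150
#' CLEAR/CUT/SUT-like ORFs sharing one protein model (yeast-like amino-acid
#' frequencies, lognormal lengths around ~330 codons) and uniform
#' synonymous marginals, with the class difference carried by the junction
#' coupling: CUT-like ORFs favour (x3) and SUT-like ORFs avoid (x1/3)
#' codon choices whose junction with the previous codon creates an
#' antisense Nrd1/Nab3 motif.  Acting on junctions rather than marginals
#' shifts antisense motif encoding while leaving sense encoding and the
#' amino-acid spectrum essentially unchanged -- the configuration the
#' analysis is meant to detect.  38\% GC intergenic sequence, antisense
#' ncRNA overlaps of 100-250 bp, lognormal expression and a read rate of
#' 0.03 midpoints per expression unit per 10 bp bin (about 4e4 reads at
#' the default ORF counts).
#'
#' @param seed integer seed fixing every random choice
#' @param nClear,nCut,nSut ORFs per class
#' @param proteinLenMeanLog,proteinLenSdLog,proteinLenMin,proteinLenMax
#'   protein length model (codons)
#' @param utr5Range,utr3Range,gapRange,overlapRange,ncExtensionRange
#'   uniform sampling ranges in bp
#' @param gcContent background GC fraction
#' @param aaFreqs amino-acid frequencies (default packaged yeast table)
#' @param usageClear,usageCut,usageSut codon usage per class (default
#'   uniform synonymous marginals for all three)
#' @param pairCoupling named junction coupling multipliers per class
#' @param exprMeanLog,exprSdLog,antiExprMeanLog,antiExprSdLog lognormal
#'   expression models
#' @param baselineExpr floor expression outside transcripts / antisense of
#'   CLEAR ORFs
#' @param exprWindow expression grid in bp (default 5)
#' @param readRate Poisson coefficient per 10 bp bin
#' @return a \linkS4class{GeneratorConfig}
#' @export
generatorConfig <- function(seed = 1L,
                            nClear = 300L, nCut = 150L, nSut = 150L,
                            proteinLenMeanLog = log(330),
                            proteinLenSdLog = 0.45,
                            proteinLenMin = 80L, proteinLenMax = 1200L,
                            utr5Range = c(20, 100), utr3Range = c(50, 150),
                            gapRange = c(250, 600),
                            overlapRange = c(100, 250),
                            ncExtensionRange = c(100, 200),
                            gcContent = 0.38,
                            aaFreqs = yeastAminoAcidFreqs(),
                            usageClear = codonUsageParams("uniform"),
                            usageCut = codonUsageParams("uniform"),
                            usageSut = codonUsageParams("uniform"),
                            pairCoupling = c(CLEAR = 1, CUT = 3,
                                             SUT = 1 / 3),
                            exprMeanLog = log(10), exprSdLog = 0.7,
                            antiExprMeanLog = log(5), antiExprSdLog = 0.7,
                            baselineExpr = 0.5, exprWindow = 5L,
                            readRate = 0.03) {
    methods::new("GeneratorConfig", seed = as.numeric(seed),
                 nClear = as.integer(nClear), nCut = as.integer(nCut),
                 nSut = as.integer(nSut),
                 proteinLenMeanLog = proteinLenMeanLog,
                 proteinLenSdLog = proteinLenSdLog,
                 proteinLenMin = as.integer(proteinLenMin),
                 proteinLenMax = as.integer(proteinLenMax),
                 utr5Range = utr5Range, utr3Range = utr3Range,
                 gapRange = gapRange, overlapRange = overlapRange,
                 ncExtensionRange = ncExtensionRange,
                 gcContent = gcContent, aaFreqs = aaFreqs,
                 usageClear = usageClear, usageCut = usageCut,
                 usageSut = usageSut, pairCoupling = pairCoupling,
                 exprMeanLog = exprMeanLog, exprSdLog = exprSdLog,
                 antiExprMeanLog = antiExprMeanLog,
                 antiExprSdLog = antiExprSdLog,
                 baselineExpr = baselineExpr,
                 exprWindow = as.integer(exprWindow),
                 readRate = readRate)
}

#' Configuration for validating expression normalization
#'
#' A dedicated generator configuration for checking that the
#' expression-normalised occupancy profile recovers the predicted-site
#' density profile.  Correlation-based validation needs the density
#' landscape to stand out from counting noise, so this configuration uses
#' one strongly antisense-enriched class (300 CUT-like ORFs, junction
#' coupling 8), expression on a common scale inside and outside
#' transcripts (so normalisation is linear across the whole metagene
#' window), moderate expression spread and a deep read library (~4e5
#' midpoints).  The qualitative read law is unchanged: Poisson midpoints
#' at rate proportional to expression, with site-driven reads piling up on
#' the predicted sites.
#'
#' @param seed integer seed
#' @return a \linkS4class{GeneratorConfig}
#' @export
occupancyValidationConfig <- function(seed = 1L) {
    generatorConfig(seed = seed, nClear = 0L, nCut = 300L, nSut = 0L,
                    pairCoupling = c(CLEAR = 1, CUT = 8, SUT = 1),
                    exprSdLog = 0.3, antiExprMeanLog = log(10),
                    antiExprSdLog = 0.2, baselineExpr = 10,
                    readRate = 0.3)
}

# Metropolis synonymous re-sampling toward a target distribution
# proportional to coupling^(antisense motif count), restricted to moves
# that leave every sense motif count (pair junctions and triplet cores)
# unchanged.  Proposals are uniform over synonyms, so the stationary law
# within each sense-preserving stratum stays uniform apart from the
# antisense tilt.
.tiltAntisense <- function(codons, coupling, sweeps = 4L) {
    n <- length(codons)
    if (n < 2L) return(codons)
    codons64 <- names(Biostrings::GENETIC_CODE)
    ci <- match(codons, codons64)
    synIdx <- lapply(.codonsBySymbol()[codonToSymbol(codons64)],
                     match, table = codons64)
    names(synIdx) <- codons64
    # .pairSiteLookup is ordered as.vector(outer(codons, codons, paste0)),
    # i.e. column-major with the FIRST codon varying fastest, so the
    # default matrix fill puts sMat[c1, c2] at the 6-mer paste0(c1, c2)
    sMat <- matrix(.pairSiteLookup("sense"), 64L, 64L)
    aMat <- matrix(.pairSiteLookup("antisense"), 64L, 64L)
    baseIdx <- function(b) match(b, c("A", "C", "G", "T"))
    lastI <- baseIdx(substr(codons64, 3L, 3L))
    firstI <- baseIdx(substr(codons64, 1L, 1L))
    coreArr <- function(hits) {
        arr <- array(FALSE, c(4L, 64L, 4L))
        bases <- c("A", "C", "G", "T")
        for (l in 1:4) for (f in 1:4) {
            core <- paste0(bases[l], codons64, bases[f])
            arr[l, , f] <- hits(core)
        }
        arr
    }
    sCore <- coreArr(function(core) core %in% .SENSE5)
    aCore <- coreArr(function(core) core %in% .ANTI5_ON_SENSE)

    # (sense pair, sense core, antisense pair, antisense core) counts over
    # the junctions and triplet cores a swap at position i can touch
    localCounts <- function(i, c_i) {
        sp <- sc <- ap <- ac <- 0
        if (i > 1L) {
            sp <- sp + sMat[ci[i - 1L], c_i]
            ap <- ap + aMat[ci[i - 1L], c_i]
        }
        if (i < n) {
            sp <- sp + sMat[c_i, ci[i + 1L]]
            ap <- ap + aMat[c_i, ci[i + 1L]]
        }
        for (m in (i - 1L):(i + 1L)) {
            if (m < 2L || m > n - 1L) next
            l <- if (m - 1L == i) lastI[c_i] else lastI[ci[m - 1L]]
            md <- if (m == i) c_i else ci[m]
            f <- if (m + 1L == i) firstI[c_i] else firstI[ci[m + 1L]]
            sc <- sc + sCore[l, md, f]
            ac <- ac + aCore[l, md, f]
        }
        c(sp, sc, ap, ac)
    }
    for (sw in seq_len(sweeps)) {
        for (i in 2:n) {
            alts <- synIdx[[ci[i]]]
            if (length(alts) < 2L) next
            cand <- alts[sample.int(length(alts), 1L)]
            if (cand == ci[i]) next
            old <- localCounts(i, ci[i])
            new <- localCounts(i, cand)
            # never touch sense encoding: both the pair-level and the
            # triplet-core sense counts must survive unchanged
            if (new[1L] != old[1L] || new[2L] != old[2L]) next
            # tilt on the net scanned antisense count (a core adds one
            # pentamer but suppresses its two pair-counted tetramers)
            d <- (new[3L] - new[4L]) - (old[3L] - old[4L])
            if (d == 0 || stats::runif(1L) < min(1, coupling^d))
                ci[i] <- cand
        }
    }
    codons64[ci]
}

# random background DNA with the configured GC content
.randomDNA <- function(n, gc) {
    if (n <= 0L) return("")
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
}

#' Sample one coding sequence from a codon-usage model
#'
#' Draws a protein of the given length (leading Met fixed, remaining
#' residues i.i.d. from \code{aaFreqs}), chooses synonymous codons from
#' \code{usage}, and appends a termination codon.  With
#' \code{pairCoupling != 1} the baseline codons are then re-sampled by
#' Metropolis synonymous swaps targeting antisense motif counts: a swap
#' changing the number of antisense junction/triplet motifs by d is
#' accepted with probability \code{min(1, pairCoupling^d)}, and any swap
#' that would change a SENSE motif count at an affected junction or
#' triplet core is rejected outright.  Sense motif encoding is therefore
#' preserved exactly while antisense encoding is enriched
#' (\code{pairCoupling > 1}) or depleted (\code{< 1}).  Consumes the
#' caller's RNG stream (seed management is the caller's job;
#' \code{\link{makeDataset}} routes everything through one seed).
#'
#' @param proteinLength number of residues including the leading Met
#' @param usage named list of codon probability vectors (see
#'   \code{\link{codonUsageParams}})
#' @param aaFreqs amino-acid frequencies
#' @param pairCoupling junction coupling multiplier
#' @return list with \code{protein}, \code{codons}, \code{cds} (the CDS
#'   includes the termination codon)
#' @export
sampleCds <- function(proteinLength, usage,
                      aaFreqs = yeastAminoAcidFreqs(), pairCoupling = 1) {
    if (proteinLength < 1L) stop("proteinLength must be >= 1")
    aa <- c("M", if (proteinLength > 1L)
        sample(names(aaFreqs), proteinLength - 1L, replace = TRUE,
               prob = aaFreqs))
    sym <- c(aa, "*")
    n <- length(sym)
    codons <- character(n)
    for (s in unique(sym)) {
        idx <- which(sym == s)
        p <- usage[[s]]
        codons[idx] <- names(p)[sample.int(length(p), length(idx),
                                           replace = TRUE, prob = p)]
    }
    codons[1L] <- "ATG"
    if (pairCoupling != 1)
        codons <- .tiltAntisense(codons, pairCoupling)
    list(protein = paste(aa, collapse = ""), codons = codons,
         cds = paste(codons, collapse = ""))
}

#' Generate a complete synthetic dataset
#'
#' Assembles one chromosome of interleaved ORFs (classes shuffled along the
#' chromosome, random strand), places an antisense CUT or SUT over the 3'
#' end of every CUT/SUT-class ORF with an overlap drawn from
#' \code{overlapRange} (always at least the 100 bp classification
#' threshold) extending into the flanking gap, builds a strand-resolved
#' expression track on the \code{exprWindow} grid, and draws read
#' midpoints per 10 bp bin from a Poisson law with rate \code{readRate *
#' expression} on the sense strand and \code{readRate * expression * (1 +
#' antisense site count in the bin)} on the antisense strand.  The same
#' seed reproduces the dataset byte-identically.
#'
#' @param cfg a \linkS4class{GeneratorConfig}
#' @param dir optional directory; when given, the dataset is also written
#'   as \code{genome.fa}, \code{transcripts.tsv}, \code{expression.tsv},
#'   \code{midpoints.bed} and \code{truth.tsv}
#' @return a \linkS4class{SyntheticDataset}
#' @export
makeDataset <- function(cfg, dir = NULL) {
    ds <- withSeed(cfg@seed, .makeDatasetImpl(cfg))
    if (!is.null(dir)) writeDataset(ds, dir)
    ds
}

.makeDatasetImpl <- function(cfg) {
    classes <- sample(c(rep("CLEAR", cfg@nClear), rep("CUT", cfg@nCut),
                        rep("SUT", cfg@nSut)))
    nOrf <- length(classes)
    usageOf <- list(CLEAR = cfg@usageClear, CUT = cfg@usageCut,
                    SUT = cfg@usageSut)
    runifInt <- function(r) as.integer(round(stats::runif(1L, r[1L], r[2L])))

    pieces <- character(0)
    cursor <- 0L            # length of assembled sequence so far
    pendingGapMin <- 0L     # room a previous ncRNA claimed in the next gap
    txRows <- list()
    truthRows <- list()
    for (i in seq_len(nOrf)) {
        gap <- max(runifInt(cfg@gapRange), pendingGapMin)
        pendingGapMin <- 0L
        pieces <- c(pieces, .randomDNA(gap, cfg@gcContent))
        cursor <- cursor + gap

        plen <- as.integer(round(stats::rlnorm(1L, cfg@proteinLenMeanLog,
                                               cfg@proteinLenSdLog)))
        plen <- min(max(plen, cfg@proteinLenMin), cfg@proteinLenMax)
        smp <- sampleCds(plen, usageOf[[classes[i]]], cfg@aaFreqs,
                         cfg@pairCoupling[[classes[i]]])
        utr5 <- runifInt(cfg@utr5Range)
        utr3 <- runifInt(cfg@utr3Range)
        strand <- sample(c("+", "-"), 1L)
        txSeq <- paste0(.randomDNA(utr5, cfg@gcContent), smp$cds,
                        .randomDNA(utr3, cfg@gcContent))
        txLen <- nchar(txSeq)
        insert <- if (strand == "+") txSeq else revComp(txSeq)
        txStart <- cursor + 1L
        txEnd <- cursor + txLen
        pieces <- c(pieces, insert)
        cursor <- txEnd
        cdsLen <- nchar(smp$cds)
        if (strand == "+") {
            cdsStart <- txStart + utr5; cdsEnd <- cdsStart + cdsLen - 1L
        } else {
            cdsStart <- txStart + utr3; cdsEnd <- cdsStart + cdsLen - 1L
        }
        orfId <- sprintf("ORF%04d", i)
        txRows[[length(txRows) + 1L]] <- data.frame(
            chrom = "chrS", start = txStart, end = txEnd, id = orfId,
            ttype = "ORF", strand = strand, cds_start = cdsStart,
            cds_end = cdsEnd, stringsAsFactors = FALSE)

        exprSense <- stats::rlnorm(1L, cfg@exprMeanLog, cfg@exprSdLog)
        exprAnti <- if (classes[i] == "CLEAR") cfg@baselineExpr
                    else stats::rlnorm(1L, cfg@antiExprMeanLog,
                                       cfg@antiExprSdLog)
        if (classes[i] != "CLEAR") {
            ov <- min(runifInt(cfg@overlapRange), txLen)
            ext <- runifInt(cfg@ncExtensionRange)
            if (strand == "+") {
                # 3' end is the genomic right end; extend into the next gap
                ncStart <- txEnd - ov + 1L; ncEnd <- txEnd + ext
                ncStrand <- "-"
                pendingGapMin <- ext + 50L
            } else {
                # 3' end is the genomic left end; extend into this gap
                ext <- min(ext, gap - 50L)
                ncStart <- txStart - ext; ncEnd <- txStart + ov - 1L
                ncStrand <- "+"
            }
            if (ncStart < 1L)
                stop("cannot place antisense ncRNA before chromosome start")
            txRows[[length(txRows) + 1L]] <- data.frame(
                chrom = "chrS", start = ncStart, end = ncEnd,
                id = sprintf("%s%04d", classes[i], i), ttype = classes[i],
                strand = ncStrand, cds_start = NA_integer_,
                cds_end = NA_integer_, stringsAsFactors = FALSE)
        }
        truthRows[[length(truthRows) + 1L]] <- data.frame(
            id = orfId, class = classes[i], strand = strand,
            tx_start = txStart, tx_end = txEnd,
            cds_start = cdsStart, cds_end = cdsEnd,
            protein = smp$protein, cds = smp$cds,
            expr_sense = exprSense, expr_anti = exprAnti,
            stringsAsFactors = FALSE)
    }
    gap <- runifInt(cfg@gapRange) + max(pendingGapMin, 0L)
    pieces <- c(pieces, .randomDNA(gap, cfg@gcContent))
    cursor <- cursor + gap

    genome <- Biostrings::DNAStringSet(
        stats::setNames(paste(pieces, collapse = ""), "chrS"))
    txDf <- do.call(rbind, txRows)
    truth <- do.call(rbind, truthRows)
    tx <- GenomicRanges::GRanges(
        txDf$chrom, IRanges::IRanges(txDf$start, txDf$end),
        strand = txDf$strand)
    S4Vectors::mcols(tx) <- S4Vectors::DataFrame(
        id = txDf$id, ttype = txDf$ttype, cds_start = txDf$cds_start,
        cds_end = txDf$cds_end, cds_ok = TRUE)
    GenomeInfoDb::seqlengths(tx) <- c(chrS = cursor)

    expr <- .buildExpressionTrack(cfg, cursor, truth)
    mids <- .simulateMidpoints(cfg, genome, truth)
    methods::new("SyntheticDataset", genome = genome, transcripts = tx,
                 expression = expr, midpoints = mids, truth = truth,
                 config = cfg)
}

# strand-resolved expression on the fixed window grid: baseline everywhere,
# each ORF's interval carries its sense value on the ORF strand and its
# antisense value on the other strand
.buildExpressionTrack <- function(cfg, chrLen, truth) {
    wlen <- cfg@exprWindow
    nWin <- chrLen %/% wlen
    plus <- rep(cfg@baselineExpr, nWin)
    minus <- rep(cfg@baselineExpr, nWin)
    for (i in seq_len(nrow(truth))) {
        w1 <- (truth$tx_start[i] - 1L) %/% wlen + 1L
        w2 <- min((truth$tx_end[i] - 1L) %/% wlen + 1L, nWin)
        idx <- w1:w2
        if (truth$strand[i] == "+") {
            plus[idx] <- truth$expr_sense[i]
            minus[idx] <- truth$expr_anti[i]
        } else {
            minus[idx] <- truth$expr_sense[i]
            plus[idx] <- truth$expr_anti[i]
        }
    }
    starts <- seq(1L, by = wlen, length.out = nWin)
    gr <- GenomicRanges::GRanges(
        "chrS",
        IRanges::IRanges(start = c(starts, starts),
                         width = wlen),
        strand = rep(c("+", "-"), each = nWin))
    S4Vectors::mcols(gr)$value <- c(plus, minus)
    gr
}

# Poisson read midpoints in one genome-wide pass over a fixed 10 bp grid.
# On each strand the rate in a bin is readRate x expression x (1 + number
# of predicted sites on that strand in the bin): the emulated RNA-binding
# proteins crosslink wherever their sites are transcribed, so reads
# antisense to an ORF follow expression x (1 + antisense site count).  A
# single pass means no position is generated twice even where metagene
# windows of neighbouring ORFs would overlap.
.simulateMidpoints <- function(cfg, genome, truth, bin = 10L) {
    if (cfg@readRate <= 0)
        return(GenomicRanges::GRanges())
    chrLen <- Biostrings::width(genome)[1L]
    nb <- chrLen %/% bin
    binOf <- function(p) (p - 1L) %/% bin + 1L
    # per-bin expression per strand (bin value = ORF value inside ORFs,
    # baseline elsewhere, mirroring the emitted track)
    exprP <- rep(cfg@baselineExpr, nb); exprM <- rep(cfg@baselineExpr, nb)
    for (i in seq_len(nrow(truth))) {
        idx <- binOf(truth$tx_start[i]):min(binOf(truth$tx_end[i]), nb)
        if (truth$strand[i] == "+") {
            exprP[idx] <- truth$expr_sense[i]
            exprM[idx] <- truth$expr_anti[i]
        } else {
            exprM[idx] <- truth$expr_sense[i]
            exprP[idx] <- truth$expr_anti[i]
        }
    }
    sites <- scanMotifs(genome, strand = "both")
    sitePos <- siteAnchorPos(sites)
    siteStrand <- as.character(GenomicRanges::strand(sites))
    posOut <- integer(0); strandOut <- character(0)
    binStart <- seq(1L, by = bin, length.out = nb)
    for (st in c("+", "-")) {
        expr <- if (st == "+") exprP else exprM
        # expression background: uniform within each bin
        n <- stats::rpois(nb, cfg@readRate * expr)
        tot <- sum(n)
        if (tot > 0L) {
            off <- sample.int(bin, tot, replace = TRUE) - 1L
            posOut <- c(posOut, rep(binStart, n) + off)
            strandOut <- c(strandOut, rep(st, tot))
        }
        # site-driven reads: crosslinks pile up at the site itself
        sel <- siteStrand == st & sitePos <= nb * bin
        sp <- sitePos[sel]
        ns <- stats::rpois(length(sp), cfg@readRate * expr[binOf(sp)])
        if (sum(ns) > 0L) {
            posOut <- c(posOut, rep(sp, ns))
            strandOut <- c(strandOut, rep(st, sum(ns)))
        }
    }
    if (!length(posOut)) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges("chrS",
                           IRanges::IRanges(start = posOut, width = 1L),
                           strand = strandOut)
}

#' Write a synthetic dataset to disk
#'
#' Emits exactly the formats the pipeline consumes: \code{genome.fa},
#' \code{transcripts.tsv} (BED-dialect starts), \code{expression.tsv},
#' \code{midpoints.bed} (BED6) and \code{truth.tsv}.
#'
#' @param ds a \linkS4class{SyntheticDataset}
#' @param dir output directory (created if missing)
#' @return the directory, invisibly
#' @export
writeDataset <- function(ds, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    Biostrings::writeXStringSet(genomeSeq(ds), file.path(dir, "genome.fa"))
    tx <- transcriptAnnotation(ds)
    m <- S4Vectors::mcols(tx)
    txDf <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(tx)),
        start = GenomicRanges::start(tx) - 1L,  # BED dialect
        end = GenomicRanges::end(tx),
        id = m$id, ttype = m$ttype,
        strand = as.character(GenomicRanges::strand(tx)),
        cds_start = ifelse(is.na(m$cds_start), NA, m$cds_start - 1L),
        cds_end = m$cds_end)
    utils::write.table(txDf, file.path(dir, "transcripts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ex <- expressionTrack(ds)
    exDf <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(ex)),
        start = GenomicRanges::start(ex) - 1L,
        end = GenomicRanges::end(ex),
        value = S4Vectors::mcols(ex)$value,
        strand = as.character(GenomicRanges::strand(ex)))
    utils::write.table(exDf, file.path(dir, "expression.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    mp <- readMidpoints(ds)
    mpDf <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(mp)),
        start = GenomicRanges::start(mp) - 1L,
        end = GenomicRanges::end(mp),
        name = sprintf("read%06d", seq_along(mp)),
        score = 0L,
        strand = as.character(GenomicRanges::strand(mp)))
    utils::write.table(mpDf, file.path(dir, "midpoints.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(groundTruth(ds), file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(dir)
}
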