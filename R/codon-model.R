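# Codon-combination universes, motif-encoding enumeration and the
# class-conditional codon-usage expectation model.
#
# Symbols are the 20 amino acids in one-letter code plus "*" for a
# termination codon.  An adjacent-codon pair reads 6 nt of coding sequence;
# a motif occurrence that spans two codons is credited to the pair term and
# one that spans three codons (only possible for the pentamers, with the
# middle codon equal to the motif's central trinucleotide) to the triplet
# term.  Within a 6-mer the longest-match rule of the scanner applies: a
# tetramer occurrence contained in a pentamer occurrence of the same set is
# counted once, as the pentamer.

.SENSE5 <- c("TGTAG", "TCTTG")
.ANTI5_ON_SENSE <- c("CTACA", "CAAGA")  # reverse complements of .SENSE5

.aaSymbols <- function() {
    gc <- Biostrings::GENETIC_CODE
    c(sort(unique(unname(gc[gc != "*"]))), "*")
}

.codonsBySymbol <- function() {
    gc <- Biostrings::GENETIC_CODE
    split(names(gc), unname(gc))
}

#' The amino-acid pair universe
#'
#' All ordered pairs over the 20 amino acids plus a termination symbol in
#' either (but not both) positions: 400 + 40 = 440 keys.
#'
#' @return data.frame with columns \code{sym1}, \code{sym2}, \code{key}
#' @export
pairUniverse <- function() {
    syms <- .aaSymbols()
    u <- expand.grid(sym2 = syms, sym1 = syms, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)[, c("sym1", "sym2")]
    u <- u[!(u$sym1 == "*" & u$sym2 == "*"), , drop = FALSE]
    rownames(u) <- NULL
    u$key <- paste(u$sym1, u$sym2, sep = "|")
    u
}

#' The amino-acid triplet universe
#'
#' Triplets (sym1, mid, sym3) where the middle residue is one that a
#' three-codon-spanning pentamer can pass through -- leucine or valine for
#' the sense motifs (central codons CTT, GTA) and lysine or tyrosine for
#' the antisense motifs (central codons AAG, TAC) -- and (sym1, sym3) runs
#' over the 440-pair universe: 4 x 440 = 1760 keys.
#'
#' @return data.frame with columns \code{sym1}, \code{mid}, \code{sym3},
#'   \code{key}
#' @export
tripletUniverse <- function() {
    p <- pairUniverse()
    mids <- c("L", "V", "K", "Y")
    out <- do.call(rbind, lapply(mids, function(m)
        data.frame(sym1 = p$sym1, mid = m, sym3 = p$sym2,
                   stringsAsFactors = FALSE)))
    out$key <- paste(out$sym1, out$mid, out$sym3, sep = "|")
    rownames(out) <- NULL
    out
}

# number of surviving motif sites fully contained in a vector of 6-mers,
# per motif set, after within-6-mer longest-match suppression
.siteCount6 <- function(s6, msets = defaultMotifSets()) {
    if (!length(s6)) return(numeric(0))
    total <- numeric(length(s6))
    for (ms in msets) {
        mot <- motifs(ms)
        m5 <- mot[nchar(mot) == 5L]; m4 <- mot[nchar(mot) == 4L]
        hit5 <- sapply(1:2, function(o) substr(s6, o, o + 4L) %in% m5)
        hit4 <- sapply(1:3, function(o) substr(s6, o, o + 3L) %in% m4)
        if (length(s6) == 1L) { hit5 <- rbind(hit5); hit4 <- rbind(hit4) }
        # 4-mer at offset o is suppressed by a 5-mer at offset o or o-1
        sup <- cbind(hit5[, 1L],
                     hit5[, 1L] | hit5[, 2L],
                     hit5[, 2L])
        total <- total + rowSums(hit5) + rowSums(hit4 & !sup)
    }
    total
}

# cached site counts for all 4096 codon-pair 6-mers, by direction
.pairSiteLookup <- function(direction) {
    key <- paste0("pair6_", direction)
    if (!is.null(.asmCache[[key]])) return(.asmCache[[key]])
    codons <- names(Biostrings::GENETIC_CODE)
    all6 <- as.vector(outer(codons, codons, paste0))
    s <- if (direction == "sense") all6 else revComp(all6)
    v <- stats::setNames(.siteCount6(s), all6)
    .asmCache[[key]] <- v
    v
}

# does the core of a codon-triplet 9-mer (last base of codon 1 + codon 2 +
# first base of codon 3) host a three-codon-spanning pentamer?
.tripletCoreHit <- function(core5, direction) {
    if (direction == "sense") core5 %in% .SENSE5
    else core5 %in% .ANTI5_ON_SENSE
}

# Net effect of one three-codon-spanning pentamer on the scanned site
# count.  The pentamer itself is one site, but under the longest-match
# rule it suppresses its two flanking tetramers -- and both of those are
# always counted by the adjacent pair terms: for each consensus pentamer
# the prefix/suffix tetramers lie at 6-mer offsets (3 and 1) where no
# same-set pentamer can contain them within the 6-mer.  The triplet term
# therefore contributes 1 - 2 = -1 per core occurrence, which makes the
# pair + triplet decomposition equal the scanner's count exactly.
.TRIPLET_NET <- -1

# all codon combinations for a pair key, as two codon vectors
.pairCombos <- function(sym1, sym2) {
    cb <- .codonsBySymbol()
    c1 <- rep(cb[[sym1]], each = length(cb[[sym2]]))
    c2 <- rep(cb[[sym2]], times = length(cb[[sym1]]))
    list(c1 = c1, c2 = c2, combo = paste0(c1, c2))
}

#' Motif-encoding amino-acid pairs
#'
#' Enumerates, for every pair key, the codon combinations whose 6-mer
#' contains at least one (surviving) Nrd1/Nab3 motif in the requested
#' direction, by looping over every synonymous combination.
#'
#' @param direction \code{"sense"} or \code{"antisense"} (antisense tests
#'   the reverse complement of the 6-mer)
#' @param msets motif sets (default Nrd1 + Nab3)
#' @return data.frame with one row per motif-bearing combination: columns
#'   \code{key}, \code{sym1}, \code{sym2}, \code{codon1}, \code{codon2},
#'   \code{combo}, \code{nSites}
#' @export
motifEncodingPairs <- function(direction = c("sense", "antisense"),
                               msets = defaultMotifSets()) {
    direction <- match.arg(direction)
    u <- pairUniverse()
    rows <- vector("list", nrow(u))
    for (i in seq_len(nrow(u))) {
        pc <- .pairCombos(u$sym1[i], u$sym2[i])
        s <- if (direction == "sense") pc$combo else revComp(pc$combo)
        n <- .siteCount6(s, msets)
        hit <- n > 0
        if (!any(hit)) next
        rows[[i]] <- data.frame(
            key = u$key[i], sym1 = u$sym1[i], sym2 = u$sym2[i],
            codon1 = pc$c1[hit], codon2 = pc$c2[hit],
            combo = pc$combo[hit], nSites = n[hit],
            stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
    rownames(out) <- NULL
    out
}

#' Motif-encoding amino-acid triplets
#'
#' Enumerates the codon assignments of each triplet key whose 9-mer hosts a
#' pentamer spanning all three codons (last base of codon one, all of codon
#' two, first base of codon three) in the requested direction.
#'
#' @inheritParams motifEncodingPairs
#' @return data.frame with columns \code{key}, \code{sym1}, \code{mid},
#'   \code{sym3}, \code{codon1}, \code{codon2}, \code{codon3},
#'   \code{combo}, \code{core}
#' @export
motifEncodingTriplets <- function(direction = c("sense", "antisense")) {
    direction <- match.arg(direction)
    u <- tripletUniverse()
    cb <- .codonsBySymbol()
    rows <- vector("list", nrow(u))
    for (i in seq_len(nrow(u))) {
        c1 <- cb[[u$sym1[i]]]; c2 <- cb[[u$mid[i]]]; c3 <- cb[[u$sym3[i]]]
        g <- expand.grid(c3 = c3, c2 = c2, c1 = c1,
                         stringsAsFactors = FALSE)[, c("c1", "c2", "c3")]
        core <- paste0(substr(g$c1, 3L, 3L), g$c2, substr(g$c3, 1L, 1L))
        hit <- .tripletCoreHit(core, direction)
        if (!any(hit)) next
        rows[[i]] <- data.frame(
            key = u$key[i], sym1 = u$sym1[i], mid = u$mid[i],
            sym3 = u$sym3[i], codon1 = g$c1[hit], codon2 = g$c2[hit],
            codon3 = g$c3[hit], combo = paste0(g$c1, g$c2, g$c3)[hit],
            core = core[hit], stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
    rownames(out) <- NULL
    out
}

#' Middle codons permitting a three-codon-spanning pentamer
#'
#' @param direction \code{"sense"} or \code{"antisense"}
#' @return character vector of central codons, derived from the triplet
#'   enumeration (GTA/CTT i.e. Val/Leu in sense; TAC/AAG i.e. Tyr/Lys in
#'   antisense)
#' @export
middleCodons <- function(direction = c("sense", "antisense")) {
    direction <- match.arg(direction)
    sort(unique(motifEncodingTriplets(direction)$codon2))
}

#' Summary of the combinatorial enumeration
#'
#' Sizes of the pair and triplet universes and the motif-encoding counts.
#' Pairs are reported the way they are conventionally quoted: sense-only,
#' antisense-only and both-capable counts (the raw capability counts are
#' included as well); the triplet sense/antisense sets do not intersect.
#'
#' @return data.frame with columns \code{quantity} and \code{value}
#' @export
enumerationSummary <- function() {
    sp <- unique(motifEncodingPairs("sense")$key)
    ap <- unique(motifEncodingPairs("antisense")$key)
    stx <- unique(motifEncodingTriplets("sense")$key)
    atx <- unique(motifEncodingTriplets("antisense")$key)
    both <- intersect(sp, ap)
    data.frame(
        quantity = c("pairs_total", "pairs_sense", "pairs_antisense",
                     "pairs_both", "pairs_sense_capable",
                     "pairs_antisense_capable", "triplets_total",
                     "triplets_sense", "triplets_antisense"),
        value = c(nrow(pairUniverse()),
                  length(setdiff(sp, both)), length(setdiff(ap, both)),
                  length(both), length(sp), length(ap),
                  nrow(tripletUniverse()), length(stx), length(atx)))
}

# validated codon/symbol decomposition of one CDS; NULL (with a logged
# reason) when the CDS cannot enter codon analyses
.cdsCodons <- function(cds, id = "cds") {
    codons <- splitCodons(cds)
    sym <- codonToSymbol(codons)
    n <- length(sym)
    if (codons[1L] != "ATG") {
        asmLog("skipping ", id, ": CDS does not begin with ATG")
        return(NULL)
    }
    if (n > 1L && any(sym[-n] == "*")) {
        asmLog("skipping ", id, ": internal termination codon")
        return(NULL)
    }
    list(codons = codons, sym = sym)
}

# uniform-synonymous-usage probabilities for every key, used as the
# fallback prior for keys unobserved in a fitted class model
.uniformPairP <- function(direction) {
    key <- paste0("unifPair_", direction)
    if (!is.null(.asmCache[[key]])) return(.asmCache[[key]])
    u <- pairUniverse()
    look <- .pairSiteLookup(direction)
    p <- vapply(seq_len(nrow(u)), function(i) {
        pc <- .pairCombos(u$sym1[i], u$sym2[i])
        mean(look[pc$combo])
    }, numeric(1L))
    v <- stats::setNames(p, u$key)
    .asmCache[[key]] <- v
    v
}

.uniformTripletP <- function(direction) {
    key <- paste0("unifTrip_", direction)
    if (!is.null(.asmCache[[key]])) return(.asmCache[[key]])
    u <- tripletUniverse()
    cb <- .codonsBySymbol()
    p <- vapply(seq_len(nrow(u)), function(i) {
        c1 <- cb[[u$sym1[i]]]; c2 <- cb[[u$mid[i]]]; c3 <- cb[[u$sym3[i]]]
        core <- as.vector(outer(as.vector(outer(
            substr(c1, 3L, 3L), c2, paste0)), substr(c3, 1L, 1L), paste0))
        .TRIPLET_NET * mean(.tripletCoreHit(core, direction))
    }, numeric(1L))
    v <- stats::setNames(p, u$key)
    .asmCache[[key]] <- v
    v
}

#' Fit a class-conditional codon-usage model
#'
#' Counts the codon combinations of every adjacent amino-acid pair
#' (including the terminal residue-termination pair) and of every
#' motif-eligible triplet over all coding sequences of one ORF class, and
#' derives the per-key expected number of motif sites in sense and
#' antisense.  CDSs with an internal termination codon, a length not
#' divisible by 3 or a missing ATG start are excluded with a logged reason.
#'
#' @param cds DNAStringSet (or character vector) of coding sequences in
#'   reading frame, or a GRanges of ORFs if \code{genome} is given
#' @param genome optional DNAStringSet to extract CDS from a GRanges input
#' @param classLabel label stored in the model
#' @param msets motif sets used for the site-count lookup
#' @return a \linkS4class{CodonUsageModel}
#' @export
fitCodonUsage <- function(cds, genome = NULL, classLabel = "class",
                          msets = defaultMotifSets()) {
    if (is(cds, "GRanges")) {
        if (is.null(genome))
            stop("a GRanges input requires 'genome'")
        cds <- cdsSequence(cds, genome)
    }
    cds <- asDNAStringSet(cds)
    pairKey <- character(0); pairCombo <- character(0)
    tripKey <- character(0); tripCombo <- character(0)
    used <- 0L
    eligibleMid <- c("L", "V", "K", "Y")
    for (i in seq_along(cds)) {
        cc <- tryCatch(.cdsCodons(as.character(cds[[i]]), names(cds)[i]),
                       error = function(e) {
                           asmLog("skipping ", names(cds)[i], ": ",
                                  conditionMessage(e))
                           NULL
                       })
        if (is.null(cc)) next
        used <- used + 1L
        n <- length(cc$sym)
        if (n >= 2L) {
            i1 <- seq_len(n - 1L)
            pairKey <- c(pairKey,
                         paste(cc$sym[i1], cc$sym[i1 + 1L], sep = "|"))
            pairCombo <- c(pairCombo,
                           paste0(cc$codons[i1], cc$codons[i1 + 1L]))
        }
        if (n >= 3L) {
            i2 <- seq_len(n - 2L)
            mid_ok <- cc$sym[i2 + 1L] %in% eligibleMid
            if (any(mid_ok)) {
                i2 <- i2[mid_ok]
                tripKey <- c(tripKey, paste(cc$sym[i2], cc$sym[i2 + 1L],
                                            cc$sym[i2 + 2L], sep = "|"))
                tripCombo <- c(tripCombo, paste0(
                    cc$codons[i2], cc$codons[i2 + 1L], cc$codons[i2 + 2L]))
            }
        }
    }
    if (used == 0L)
        stop("no usable coding sequences")

    .usageTable <- function(keys, combos) {
        if (!length(keys))
            return(data.frame(key = character(), combo = character(),
                              count = integer(), freq = numeric()))
        tab <- table(paste(keys, combos, sep = "\r"))
        parts <- strsplit(names(tab), "\r", fixed = TRUE)
        df <- data.frame(key = vapply(parts, `[`, "", 1L),
                         combo = vapply(parts, `[`, "", 2L),
                         count = as.integer(tab), stringsAsFactors = FALSE)
        tot <- tapply(df$count, df$key, sum)
        df$freq <- df$count / as.numeric(tot[df$key])
        df[order(df$key, df$combo), ]
    }
    pu <- .usageTable(pairKey, pairCombo)
    tu <- .usageTable(tripKey, tripCombo)

    pkeys <- unique(pu$key)
    pairP <- matrix(0, length(pkeys), 2L,
                    dimnames = list(pkeys, c("sense", "antisense")))
    for (dir in c("sense", "antisense")) {
        look <- .pairSiteLookup(dir)
        contrib <- pu$freq * look[pu$combo]
        agg <- tapply(contrib, pu$key, sum)
        pairP[names(agg), dir] <- as.numeric(agg)
    }
    tkeys <- unique(tu$key)
    tripP <- matrix(0, length(tkeys), 2L,
                    dimnames = list(tkeys, c("sense", "antisense")))
    if (nrow(tu)) {
        core <- substr(tu$combo, 3L, 7L)
        for (dir in c("sense", "antisense")) {
            contrib <- .TRIPLET_NET * tu$freq *
                as.numeric(.tripletCoreHit(core, dir))
            agg <- tapply(contrib, tu$key, sum)
            tripP[names(agg), dir] <- as.numeric(agg)
        }
    }
    methods::new("CodonUsageModel", classLabel = classLabel,
                 method = "pair", pairUsage = pu, tripletUsage = tu,
                 pairP = pairP, tripletP = tripP, nOrfs = used)
}

#' Fit the independent single-codon usage model
#'
#' The discarded-comparator model: per-amino-acid marginal codon
#' frequencies with independence between adjacent codons.  Expected pair
#' and triplet motif probabilities are the product-marginal analogues of
#' \code{\link{fitCodonUsage}}, computed over the full 440-pair and
#' 1760-triplet universes.
#'
#' @inheritParams fitCodonUsage
#' @return a \linkS4class{CodonUsageModel} with \code{method = "single"}
#' @export
fitSingleCodonUsage <- function(cds, genome = NULL, classLabel = "class") {
    if (is(cds, "GRanges")) {
        if (is.null(genome))
            stop("a GRanges input requires 'genome'")
        cds <- cdsSequence(cds, genome)
    }
    cds <- asDNAStringSet(cds)
    codAll <- character(0); used <- 0L
    for (i in seq_along(cds)) {
        cc <- tryCatch(.cdsCodons(as.character(cds[[i]]), names(cds)[i]),
                       error = function(e) NULL)
        if (is.null(cc)) next
        used <- used + 1L
        codAll <- c(codAll, cc$codons)
    }
    if (used == 0L) stop("no usable coding sequences")
    sym <- codonToSymbol(codAll)
    tab <- table(sym, codAll)
    marg <- lapply(rownames(tab), function(s) {
        v <- tab[s, ]; v <- v[v > 0]; v / sum(v)
    })
    names(marg) <- rownames(tab)

    margP <- function(s) {
        if (is.null(marg[[s]])) {
            # symbol unseen in this class: uniform over its codons
            cb <- .codonsBySymbol()[[s]]
            stats::setNames(rep(1 / length(cb), length(cb)), cb)
        } else marg[[s]]
    }
    u <- pairUniverse()
    pairP <- matrix(0, nrow(u), 2L,
                    dimnames = list(u$key, c("sense", "antisense")))
    for (dir in c("sense", "antisense")) {
        look <- .pairSiteLookup(dir)
        pairP[, dir] <- vapply(seq_len(nrow(u)), function(i) {
            f1 <- margP(u$sym1[i]); f2 <- margP(u$sym2[i])
            w <- as.vector(outer(f1, f2))
            combos <- as.vector(outer(names(f1), names(f2), paste0))
            sum(w * look[combos])
        }, numeric(1L))
    }
    ut <- tripletUniverse()
    tripP <- matrix(0, nrow(ut), 2L,
                    dimnames = list(ut$key, c("sense", "antisense")))
    for (dir in c("sense", "antisense")) {
        tripP[, dir] <- vapply(seq_len(nrow(ut)), function(i) {
            f1 <- margP(ut$sym1[i]); f2 <- margP(ut$mid[i])
            f3 <- margP(ut$sym3[i])
            core <- as.vector(outer(as.vector(outer(
                substr(names(f1), 3L, 3L), names(f2), paste0)),
                substr(names(f3), 1L, 1L), paste0))
            w <- as.vector(outer(as.vector(outer(f1, f2)), f3))
            .TRIPLET_NET * sum(w * as.numeric(.tripletCoreHit(core, dir)))
        }, numeric(1L))
    }
    pu <- data.frame(key = rep(names(marg), lengths(marg)),
                     combo = unlist(lapply(marg, names), use.names = FALSE),
                     count = NA_integer_,
                     freq = unlist(marg, use.names = FALSE))
    methods::new("CodonUsageModel", classLabel = classLabel,
                 method = "single", pairUsage = pu,
                 tripletUsage = data.frame(key = character(),
                                           combo = character(),
                                           count = integer(),
                                           freq = numeric()),
                 pairP = pairP, tripletP = tripP, nOrfs = used)
}

#' Expected number of predicted sites in a CDS under a usage model
#'
#' Sums, over the CDS's adjacent amino-acid pairs and motif-eligible
#' triplets, the model's per-key expected number of motif sites in the
#' requested direction.  Pair terms count motifs fully contained in the
#' 6-mer (two-codon span, longest match within the 6-mer); triplet terms
#' carry the net effect of a three-codon-spanning pentamer (+1 site, -2
#' for the flanking tetramers it suppresses in the scanner), so the sum
#' reproduces the scanner's longest-match count without double counting.
#' Keys unobserved in the fitted model fall back to the
#' uniform-synonymous-usage prior (counted and logged).
#'
#' @param cds DNAStringSet/character of coding sequences, or GRanges with
#'   \code{genome}
#' @param usage a \linkS4class{CodonUsageModel}
#' @param direction \code{"sense"} or \code{"antisense"}
#' @param genome optional DNAStringSet for GRanges input
#' @return named numeric vector of expected counts (NA for CDSs excluded
#'   from codon analyses)
#' @export
expectedSites <- function(cds, usage, direction = c("sense", "antisense"),
                          genome = NULL) {
    direction <- match.arg(direction)
    if (is(cds, "GRanges")) {
        if (is.null(genome))
            stop("a GRanges input requires 'genome'")
        cds <- cdsSequence(cds, genome)
    }
    cds <- asDNAStringSet(cds)
    pv <- usage@pairP[, direction]
    tv <- usage@tripletP[, direction]
    upv <- .uniformPairP(direction)
    utv <- .uniformTripletP(direction)
    eligibleMid <- c("L", "V", "K", "Y")
    nMissing <- 0L
    out <- vapply(seq_along(cds), function(i) {
        cc <- tryCatch(.cdsCodons(as.character(cds[[i]]), names(cds)[i]),
                       error = function(e) NULL)
        if (is.null(cc)) return(NA_real_)
        n <- length(cc$sym)
        tot <- 0
        if (n >= 2L) {
            keys <- paste(cc$sym[-n], cc$sym[-1L], sep = "|")
            p <- pv[keys]
            miss <- is.na(p)
            if (any(miss)) {
                p[miss] <- upv[keys[miss]]
                nMissing <<- nMissing + sum(miss)
            }
            tot <- tot + sum(p)
        }
        if (n >= 3L) {
            i2 <- which(cc$sym[seq(2L, n - 1L)] %in% eligibleMid) + 1L
            if (length(i2)) {
                keys <- paste(cc$sym[i2 - 1L], cc$sym[i2], cc$sym[i2 + 1L],
                              sep = "|")
                p <- tv[keys]
                miss <- is.na(p)
                if (any(miss)) {
                    p[miss] <- utv[keys[miss]]
                    nMissing <<- nMissing + sum(miss)
                }
                tot <- tot + sum(p)
            }
        }
        tot
    }, numeric(1L))
    if (nMissing > 0L)
        asmLog(nMissing, " pair/triplet occurrences used the uniform prior ",
               "(key absent from the fitted '", usage@classLabel,
               "' model)")
    stats::setNames(out, names(cds))
}

#' Observed number of predicted sites in a CDS
#'
#' Scans each coding sequence with the longest-match rule and counts sites
#' on the coding strand (sense) or its reverse complement (antisense).
#'
#' @inheritParams expectedSites
#' @param msets motif sets
#' @return named integer vector
#' @export
observedSites <- function(cds, direction = c("sense", "antisense"),
                          genome = NULL, msets = defaultMotifSets()) {
    direction <- match.arg(direction)
    if (is(cds, "GRanges")) {
        if (is.null(genome))
            stop("a GRanges input requires 'genome'")
        cds <- cdsSequence(cds, genome)
    }
    cds <- asDNAStringSet(cds)
    st <- if (direction == "sense") "+" else "-"
    sites <- scanMotifs(cds, msets, strand = st)
    cnt <- table(factor(as.character(GenomicRanges::seqnames(sites)),
                        levels = names(cds)))
    stats::setNames(as.integer(cnt), names(cds))
}

#' Observed/expected site counts and residuals per ORF
#'
#' @inheritParams expectedSites
#' @param msets motif sets for the observed scan
#' @return data.frame with columns \code{id}, \code{direction},
#'   \code{observed}, \code{expected}, \code{residual}
#' @export
siteResiduals <- function(cds, usage, direction = c("sense", "antisense"),
                          genome = NULL, msets = defaultMotifSets()) {
    direction <- match.arg(direction)
    if (is(cds, "GRanges")) {
        if (is.null(genome))
            stop("a GRanges input requires 'genome'")
        cds <- cdsSequence(cds, genome)
    }
    cds <- asDNAStringSet(cds)
    obs <- observedSites(cds, direction, msets = msets)
    exp <- expectedSites(cds, usage, direction)
    data.frame(id = names(cds), direction = direction,
               observed = as.integer(obs), expected = as.numeric(exp),
               residual = as.integer(obs) - as.numeric(exp),
               stringsAsFactors = FALSE)
}

#' Codon-usage impact relative to the background class
#'
#' For each ORF, the difference between the expected number of predicted
#' sites under its own class's codon usage and under the background
#' (ORF_CLEAR) usage.  Positive values mean the class's synonymous-codon
#' choices make motifs more likely than the background usage would.
#'
#' @inheritParams expectedSites
#' @param usageOwn model fitted from the ORF's own class
#' @param usageClear model fitted from the background class
#' @return named numeric vector of differences
#' @export
deltaExpected <- function(cds, usageOwn, usageClear,
                          direction = c("sense", "antisense"),
                          genome = NULL) {
    direction <- match.arg(direction)
    expectedSites(cds, usageOwn, direction, genome = genome) -
        expectedSites(cds, usageClear, direction, genome = genome)
}

#' Anderson-Darling normality check on residuals
#'
#' @param residuals numeric vector, n >= 8
#' @return the \code{htest} from \code{\link[nortest]{ad.test}}
#' @export
residualNormality <- function(residuals) {
    residuals <- residuals[!is.na(residuals)]
    if (length(residuals) < 8L)
        stop("Anderson-Darling test requires at least 8 observations")
    if (stats::sd(residuals) == 0)
        stop("residuals are constant; normality test undefined")
    nortest::ad.test(residuals)
}
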