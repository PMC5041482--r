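# Independent oracles, written against base R string handling only, so they
# share no code path with the package implementation.

options(antisenseMotifs.verbose = FALSE)

oracleRevComp <- function(s) {
    vapply(s, function(x) {
        paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1L]]),
              collapse = "")
    }, character(1L), USE.NAMES = FALSE)
}

# every (possibly overlapping) occurrence of a fixed pattern
oracleFindAll <- function(pattern, subject) {
    out <- integer(0)
    from <- 1L
    repeat {
        i <- regexpr(pattern, substring(subject, from), fixed = TRUE)
        if (i < 0L) break
        out <- c(out, from + i - 1L)
        from <- from + i
    }
    out
}

# naive all-occurrence scan + containment suppression for one motif set on
# the plus strand of 'seq'; returns data.frame(start, width)
oracleScanSet <- function(seq, motifs) {
    len <- nchar(motifs)
    hits <- lapply(motifs, oracleFindAll, subject = seq)
    s5 <- sort(unique(unlist(hits[len == 5L])))
    out <- data.frame(start = s5, width = rep(5L, length(s5)))
    for (j in which(len == 4L)) {
        s4 <- hits[[j]]
        s4 <- s4[!(s4 %in% s5 | (s4 - 1L) %in% s5)]
        if (length(s4))
            out <- rbind(out, data.frame(start = s4, width = 4L))
    }
    out[order(out$start, out$width), , drop = FALSE]
}

# both-strand oracle scan; minus-strand coordinates mapped back to 'seq'
oracleScanBoth <- function(seq, motifs) {
    plus <- oracleScanSet(seq, motifs)
    plus$strand <- if (nrow(plus)) "+" else character(0)
    rcHits <- oracleScanSet(oracleRevComp(seq), motifs)
    L <- nchar(seq)
    minus <- data.frame(start = L - (rcHits$start + rcHits$width - 1L) + 1L,
                        width = rcHits$width,
                        strand = rep("-", nrow(rcHits)))
    out <- rbind(plus, minus)
    out[order(out$start, out$width, out$strand), , drop = FALSE]
}

ALL_MOTIFS <- c("TGTA", "GTAG", "TGTAG", "TCTT", "CTTG", "TCTTG")

# brute-force count of surviving motif sites fully inside a 6-mer
# (longest-match within each protein's set), matching the scanner contract
oracleSite6 <- function(s6, direction = "sense") {
    if (direction == "antisense") s6 <- oracleRevComp(s6)
    total <- 0L
    for (set in list(c("TGTA", "GTAG", "TGTAG"),
                     c("TCTT", "CTTG", "TCTTG"))) {
        hits <- oracleScanSet(s6, set)
        total <- total + nrow(hits)
    }
    total
}

# full brute-force enumeration of the pair/triplet motif-encoding universes
oracleEnumeration <- function() {
    gc <- Biostrings::GENETIC_CODE
    cb <- split(names(gc), unname(gc))
    syms <- c(sort(setdiff(names(cb), "*")), "*")
    pairSense <- character(0); pairAnti <- character(0); nPairs <- 0L
    for (a in syms) for (b in syms) {
        if (a == "*" && b == "*") next
        nPairs <- nPairs + 1L
        combos <- as.vector(outer(cb[[a]], cb[[b]], paste0))
        hasS <- hasA <- FALSE
        for (cc in combos) {
            if (!hasS && any(vapply(ALL_MOTIFS, grepl, TRUE, x = cc,
                                    fixed = TRUE))) hasS <- TRUE
            if (!hasA && any(vapply(ALL_MOTIFS, grepl, TRUE,
                                    x = oracleRevComp(cc),
                                    fixed = TRUE))) hasA <- TRUE
            if (hasS && hasA) break
        }
        key <- paste(a, b, sep = "|")
        if (hasS) pairSense <- c(pairSense, key)
        if (hasA) pairAnti <- c(pairAnti, key)
    }
    tripSense <- tripAnti <- 0L; nTrip <- 0L
    midSense <- midAnti <- character(0)
    pent <- c("TGTAG", "TCTTG")
    for (m in c("L", "V", "K", "Y")) for (a in syms) for (b in syms) {
        if (a == "*" && b == "*") next
        nTrip <- nTrip + 1L
        core <- as.vector(outer(as.vector(outer(
            substr(cb[[a]], 3L, 3L), cb[[m]], paste0)),
            substr(cb[[b]], 1L, 1L), paste0))
        sHit <- core %in% pent
        aHit <- oracleRevComp(core) %in% pent
        if (any(sHit)) {
            tripSense <- tripSense + 1L
            midSense <- union(midSense, substr(core[sHit], 2L, 4L))
        }
        if (any(aHit)) {
            tripAnti <- tripAnti + 1L
            midAnti <- union(midAnti, substr(core[aHit], 2L, 4L))
        }
    }
    list(nPairs = nPairs, pairSense = pairSense, pairAnti = pairAnti,
         nTriplets = nTrip, tripSense = tripSense, tripAnti = tripAnti,
         midSense = sort(midSense), midAnti = sort(midAnti))
}

randomDna <- function(n, alphabet = c("A", "C", "G", "T")) {
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
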