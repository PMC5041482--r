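test_that("scanner applies the longest-match rule and counts partial overlaps", {
    s <- scanMotifs("TGTAG", strand = "+")
    expect_length(s, 1L)
    expect_equal(GenomicRanges::width(s), 5L)

    # two partially overlapping occurrences are both reported
    s2 <- scanMotifs("TGTAGTAG", strand = "+")
    expect_equal(GenomicRanges::start(s2), c(1L, 5L))
    expect_equal(S4Vectors::mcols(s2)$motif, c("TGTAG", "GTAG"))

    expect_length(scanMotifs("AAAAAA", strand = "+"), 0L)
    # N never matches
    expect_length(scanMotifs("TGTNG", strand = "+"), 0L)
    expect_error(scanMotifs("TGTAG", msets = list()), "non-empty")
})

test_that("antisense scanning equals scanning the reverse complement", {
    s <- scanAntisense("CTACA")
    expect_length(s, 1L)
    expect_equal(S4Vectors::mcols(s)$motif, "TGTAG")
    expect_length(scanAntisense("TGTAG"), 0L)

    set.seed(31)
    for (i in 1:10) {
        seq <- randomDna(400)
        anti <- scanMotifs(seq, strand = "-")
        sense_of_rc <- scanMotifs(oracleRevComp(seq), strand = "+")
        expect_equal(length(anti), length(sense_of_rc))
        # coordinates map back through the mirror
        expect_equal(sort(400L - GenomicRanges::end(anti) + 1L),
                     sort(GenomicRanges::start(sense_of_rc)))
    }
})

test_that("scanner equals the naive all-occurrence oracle on random sequences", {
    set.seed(101)
    msets <- defaultMotifSets()
    for (i in 1:40) {
        seq <- randomDna(600)
        for (ms in msets) {
            got <- scanMotifs(seq, list(ms), strand = "both")
            df <- data.frame(start = GenomicRanges::start(got),
                             width = GenomicRanges::width(got),
                             strand = as.character(
                                 GenomicRanges::strand(got)))
            df <- df[order(df$start, df$width, df$strand), ]
            ora <- oracleScanBoth(seq, motifs(ms))
            expect_equal(unname(as.matrix(df)), unname(as.matrix(ora)),
                         ignore_attr = TRUE)
        }
    }
})

test_that("site counts are additive over a window partition by site start", {
    set.seed(7)
    seq <- randomDna(1000)
    sites <- scanMotifs(seq, strand = "both")
    pos <- antisenseMotifs:::siteAnchorPos(sites)
    total <- length(sites)
    cuts <- c(0L, sort(sample(1:999, 7)), 1000L)
    partSum <- sum(vapply(seq_len(length(cuts) - 1L), function(k)
        sum(pos > cuts[k] & pos <= cuts[k + 1L]), integer(1L)))
    expect_equal(partSum, total)
})

test_that("window counts find planted motifs and respect anchors and length", {
    # ORF with CDS of 600 bp: TGTAG planted 50 bp into the CDS (sense),
    # CAAGA planted 100 bp before the stop codon (an antisense Nab3 site)
    g <- rep("A", 2000)
    g[401:403] <- c("A", "T", "G")
    g[451:455] <- c("T", "G", "T", "A", "G")
    g[901:905] <- c("C", "A", "A", "G", "A")
    genome <- Biostrings::DNAStringSet(c(c = paste(g, collapse = "")))
    tx <- makeTx(data.frame(chrom = "c", start = 301L, end = 1200L,
                            id = "orf1", ttype = "ORF", strand = "+",
                            cds_start = 401L, cds_end = 1000L),
                 c(c = 2000L))
    expect_equal(unname(countWindow(tx, genome, anchor = "start_codon",
                                    direction = "sense", span = 400L)), 1L)
    expect_equal(unname(countWindow(tx, genome, anchor = "stop_codon",
                                    direction = "antisense", span = 400L)),
                 1L)
    expect_equal(unname(countWindow(tx, genome, anchor = "tss",
                                    direction = "sense", span = 400L)), 1L)
    # all-A window holds nothing
    expect_equal(unname(countWindow(tx, genome, anchor = "stop_codon",
                                    direction = "sense", span = 400L)), 0L)
    # window longer than the CDS is not comparable
    expect_true(is.na(countWindow(tx, genome, anchor = "start_codon",
                                  direction = "sense", span = 700L)))
    # codon anchors require a CDS
    cut <- makeTx(data.frame(chrom = "c", start = 1L, end = 300L,
                             id = "cut1", ttype = "CUT", strand = "-"),
                  c(c = 2000L))
    expect_error(countWindow(cut, genome, anchor = "start_codon",
                             direction = "sense"), "without a CDS")
})

test_that("density profiles place sites in bins and use per-bin denominators", {
    g <- rep("A", 3000)
    g[1001:1003] <- c("A", "T", "G")
    g[1051:1055] <- c("T", "G", "T", "A", "G")  # 50 bp into the CDS
    genome <- Biostrings::DNAStringSet(c(c = paste(g, collapse = "")))
    tx <- makeTx(data.frame(chrom = "c", start = 901L, end = 1700L,
                            id = "orf1", ttype = "ORF", strand = "+",
                            cds_start = 1001L, cds_end = 1600L),
                 c(c = 3000L))
    pr <- densityProfile(tx, genome, anchor = "start_codon",
                         direction = "sense")
    b <- profileBins(pr)
    expect_equal(b$value[b$bin_start == 50], 1.0)
    expect_equal(sum(b$value), 1.0)

    # a second, shorter ORF cannot contribute to distal bins, so a distal
    # site is averaged over a denominator of one
    g2 <- g
    g2[1901:1903] <- c("A", "T", "G")  # short ORF, CDS 30 bp
    genome2 <- Biostrings::DNAStringSet(c(c = paste(g2, collapse = "")))
    tx2 <- makeTx(data.frame(
        chrom = "c", start = c(901L, 1851L), end = c(1700L, 2100L),
        id = c("orf1", "orf2"), ttype = "ORF", strand = "+",
        cds_start = c(1001L, 1901L), cds_end = c(1600L, 1930L)),
        c(c = 3000L))
    pr2 <- densityProfile(tx2, genome2, anchor = "start_codon",
                          direction = "sense")
    b2 <- profileBins(pr2)
    expect_equal(b2$denominator[b2$bin_start == 50], 1L)
    expect_equal(b2$value[b2$bin_start == 50], 1.0)
    expect_equal(b2$denominator[b2$bin_start == 10], 2L)
    # denominator never increases deeper into the body
    body <- b2[b2$bin_start >= 0, ]
    expect_true(all(diff(body$denominator) <= 0L))
})

test_that("profile values match brute-force per-window counting on random data", {
    set.seed(55)
    g <- randomDna(20000)
    genome <- Biostrings::DNAStringSet(c(c = g))
    starts <- seq(1000L, 19000L, by = 1500L)[1:10]
    cdsLen <- 300L + 30L * (0:9)
    df <- data.frame(chrom = "c", start = starts, end = starts + 900L,
                     id = paste0("o", 1:10), ttype = "ORF",
                     strand = rep(c("+", "-"), 5),
                     cds_start = starts + 100L,
                     cds_end = starts + 100L + cdsLen - 1L)
    tx <- makeTx(df, c(c = 20000L))
    pr <- densityProfile(tx, genome, anchor = "start_codon",
                         direction = "antisense", flank = 200L, bin = 10L)
    b <- profileBins(pr)
    # oracle: per ORF, count oracle-scan sites by 5'-most base per bin
    allSites <- do.call(rbind, lapply(defaultMotifSets(), function(ms)
        oracleScanBoth(g, motifs(ms))))
    anchorPos <- ifelse(allSites$strand == "+", allSites$start,
                        allSites$start + allSites$width - 1L)
    for (bs in c(-200L, -50L, 0L, 100L, 190L)) {
        num <- 0L; den <- 0L
        for (i in 1:10) {
            st <- df$strand[i]
            a <- if (st == "+") df$cds_start[i] else df$cds_end[i]
            contrib <- if (bs >= 0) cdsLen[i] >= bs + 10L else TRUE
            if (!contrib) next
            den <- den + 1L
            want <- if (st == "+") "-" else "+"
            r <- if (st == "+") anchorPos - a else a - anchorPos
            num <- num + sum(allSites$strand == want & r >= bs &
                             r < bs + 10L)
        }
        expect_equal(b$value[b$bin_start == bs], num / den)
        expect_equal(b$denominator[b$bin_start == bs], den)
    }
})

test_that("sense and antisense swap roles under genome reverse complement", {
    set.seed(13)
    g <- randomDna(4000)
    genome <- Biostrings::DNAStringSet(c(c = g))
    tx <- makeTx(data.frame(chrom = "c", start = 1001L, end = 1900L,
                            id = "o1", ttype = "ORF", strand = "+",
                            cds_start = 1101L, cds_end = 1700L),
                 c(c = 4000L))
    mirrorGenome <- Biostrings::DNAStringSet(c(c = oracleRevComp(g)))
    tx_m <- makeTx(data.frame(chrom = "c",
                              start = 4000L - 1900L + 1L,
                              end = 4000L - 1001L + 1L,
                              id = "o1", ttype = "ORF", strand = "-",
                              cds_start = 4000L - 1700L + 1L,
                              cds_end = 4000L - 1101L + 1L),
                   c(c = 4000L))
    for (dirn in c("sense", "antisense")) {
        p1 <- profileBins(densityProfile(tx, genome, "start_codon", dirn))
        p2 <- profileBins(densityProfile(tx_m, mirrorGenome,
                                         "start_codon", dirn))
        expect_equal(p1$value, p2$value)
    }
})

test_that("rank-sum comparison behaves at the extremes and holds its size", {
    expect_warning(p <- compareSiteCounts(rep(3, 10), rep(3, 8)), "tied")
    expect_equal(p$p.value, 1)
    expect_lt(compareSiteCounts(1:20, 101:120)$p.value, 0.001)
    expect_error(compareSiteCounts(numeric(0), 1:3), "non-empty")

    set.seed(99)
    rej <- mean(replicate(1000, {
        compareSiteCounts(rpois(15, 5), rpois(15, 5))$p.value < 0.05
    }))
    expect_gt(rej, 0.02)
    expect_lt(rej, 0.09)
})
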