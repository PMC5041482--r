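writeMidBed <- function(df, path = tempfile(fileext = ".bed")) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    path
}

test_that("midpoints are the floor of the alignment centre", {
    # a read spanning [100, 130) in 0-based terms has midpoint 115
    # (position 116 in 1-based coordinates)
    bed <- writeMidBed(data.frame(chrom = "c", start = 100L, end = 130L,
                                  name = "r1", score = 0L, strand = "+"))
    mp <- loadMidpoints(bed)
    expect_length(mp, 1L)
    expect_equal(GenomicRanges::start(mp), 116L)

    empty <- tempfile(fileext = ".bed")
    file.create(empty)
    expect_error(loadMidpoints(empty))  # nothing to read is an error

    n <- 1000L
    bed2 <- writeMidBed(data.frame(chrom = "c", start = 1:n,
                                   end = 1:n + 30L, name = paste0("r", 1:n),
                                   score = 0L,
                                   strand = rep(c("+", "-"), n / 2)))
    expect_length(loadMidpoints(bed2), n)
})

test_that("BAM input yields the same midpoints and skips unmapped records", {
    seq30 <- strrep("A", 30)
    qual <- strrep("I", 30)
    sam <- c("@HD\tVN:1.6\tSO:coordinate",
             "@SQ\tSN:chrS\tLN:2000",
             paste("r1", 0, "chrS", 101, 60, "30M", "*", 0, 0, seq30, qual,
                   sep = "\t"),
             paste("r2", 16, "chrS", 201, 60, "30M", "*", 0, 0, seq30,
                   qual, sep = "\t"),
             paste("r3", 4, "*", 0, 0, "*", "*", 0, 0, seq30, qual,
                   sep = "\t"))
    samfile <- tempfile(fileext = ".sam")
    writeLines(sam, samfile)
    bamfile <- suppressMessages(
        Rsamtools::asBam(samfile, tempfile(), overwrite = TRUE))
    mp <- suppressMessages(loadMidpoints(bamfile))
    expect_length(mp, 2L)
    expect_equal(GenomicRanges::start(mp), c(116L, 216L))
    expect_equal(as.character(GenomicRanges::strand(mp)), c("+", "-"))
})

test_that("ORF expression is the mean of overlapping windows per strand", {
    track <- GenomicRanges::GRanges(
        "c", IRanges::IRanges(start = seq(1, 96, by = 5), width = 5),
        strand = "+")
    S4Vectors::mcols(track)$value <- rep(2, 20)
    orfs <- makeTx(data.frame(chrom = "c", start = 11L, end = 60L,
                              id = "o1", ttype = "ORF", strand = "+",
                              cds_start = 11L, cds_end = 60L),
                   c(c = 100L))
    ex <- orfExpression(orfs, track)
    expect_equal(ex$sense, 2)
    expect_true(is.na(ex$antisense))

    # two windows with values 1 and 3 average to 2
    tr2 <- GenomicRanges::GRanges(
        "c", IRanges::IRanges(start = c(11L, 16L), width = 5),
        strand = "+")
    S4Vectors::mcols(tr2)$value <- c(1, 3)
    orfs2 <- makeTx(data.frame(chrom = "c", start = 11L, end = 20L,
                               id = "o1", ttype = "ORF", strand = "+",
                               cds_start = 11L, cds_end = 20L),
                    c(c = 100L))
    expect_equal(orfExpression(orfs2, tr2)$sense, 2)

    # randomized track matches a brute-force per-window average
    set.seed(17)
    vals <- runif(40, 0, 5)
    win <- seq(1, 96, by = 5)  # the same 20-window grid on both strands
    tr3 <- GenomicRanges::GRanges(
        "c", IRanges::IRanges(start = c(win, win), width = 5),
        strand = rep(c("+", "-"), each = 20))
    S4Vectors::mcols(tr3)$value <- vals
    orfs3 <- makeTx(data.frame(chrom = "c", start = 23L, end = 71L,
                               id = "o1", ttype = "ORF", strand = "-",
                               cds_start = 23L, cds_end = 71L),
                    c(c = 200L))
    ex3 <- orfExpression(orfs3, tr3)
    hitP <- which(win <= 71 & win + 4 >= 23)          # plus-strand windows
    hitM <- hitP + 20L                                # minus-strand windows
    expect_equal(ex3$sense, mean(vals[hitM]))      # ORF is on the minus strand
    expect_equal(ex3$antisense, mean(vals[hitP]))

    out <- makeTx(data.frame(chrom = "c", start = 181L, end = 199L,
                             id = "nocov", ttype = "ORF", strand = "+",
                             cds_start = 181L, cds_end = 199L),
                  c(c = 200L))
    expect_error(orfExpression(out, track), "nocov")
})

test_that("occupancy divides binned counts by expression and scales out", {
    # one ORF, four midpoints in the first CDS bin, sense expression 2
    orfs <- makeTx(data.frame(chrom = "c", start = 501L, end = 1100L,
                              id = "o1", ttype = "ORF", strand = "+",
                              cds_start = 601L, cds_end = 1000L),
                   c(c = 2000L))
    track <- GenomicRanges::GRanges(
        "c", IRanges::IRanges(start = seq(1, 1996, 5), width = 5),
        strand = "+")
    S4Vectors::mcols(track)$value <- rep(2, length(track))
    mids <- GenomicRanges::GRanges(
        "c", IRanges::IRanges(start = c(602L, 604L, 607L, 609L),
                              width = 1), strand = "+")
    pr <- occupancyProfile(orfs, mids, track, anchor = "start_codon",
                           direction = "sense")
    b <- profileBins(pr)
    expect_equal(b$value[b$bin_start == 0], 2)   # 4 reads / expression 2
    expect_equal(sum(b$value, na.rm = TRUE), 2)

    # joint scaling of reads and expression leaves the profile unchanged
    S4Vectors::mcols(track)$value <- rep(6, length(track))
    pr3 <- occupancyProfile(orfs, c(mids, mids, mids), track,
                            anchor = "start_codon", direction = "sense")
    expect_equal(profileBins(pr3)$value, b$value)

    # an ORF without usable expression on the required strand is skipped
    expect_error(suppressMessages(
        occupancyProfile(orfs, mids, track, direction = "antisense")),
        "usable")
})

test_that("intergenic occupancy pools strands and matches brute force", {
    regions <- GenomicRanges::GRanges(
        "c", IRanges::IRanges(start = c(1L, 501L), width = 400L))
    track <- GenomicRanges::GRanges(
        "c", IRanges::IRanges(start = seq(1, 996, 5), width = 5),
        strand = rep(c("+", "-"), each = 100))
    S4Vectors::mcols(track)$value <- rep(2, length(track))
    none <- GenomicRanges::GRanges()
    expect_equal(intergenicOccupancy(regions, none, track), 0)

    set.seed(9)
    mids <- GenomicRanges::GRanges(
        "c", IRanges::IRanges(start = sample(1:1000, 200, TRUE),
                              width = 1),
        strand = sample(c("+", "-"), 200, TRUE))
    got <- intergenicOccupancy(regions, mids, track)
    cnt <- vapply(1:2, function(i) {
        s <- GenomicRanges::start(regions)[i]
        sum(GenomicRanges::start(mids) >= s &
                GenomicRanges::start(mids) <= s + 399L)
    }, integer(1))
    expect_equal(got, mean(cnt / 2))
})

test_that("binned midpoint totals are conserved within a window", {
    set.seed(12)
    orfs <- makeTx(data.frame(chrom = "c", start = 901L, end = 1500L,
                              id = "o1", ttype = "ORF", strand = "+",
                              cds_start = 1001L, cds_end = 1400L),
                   c(c = 3000L))
    track <- GenomicRanges::GRanges(
        "c", IRanges::IRanges(start = seq(1, 2996, 5), width = 5),
        strand = "+")
    S4Vectors::mcols(track)$value <- rep(1, length(track))
    pos <- sample(700:1700, 300, replace = TRUE)
    mids <- GenomicRanges::GRanges(
        "c", IRanges::IRanges(start = pos, width = 1), strand = "+")
    pr <- occupancyProfile(orfs, mids, track, anchor = "start_codon",
                           direction = "sense")
    b <- profileBins(pr)
    inWindow <- sum(pos >= 1001 - 400 & pos < 1001 + 400)
    expect_equal(sum(b$value * b$denominator), inWindow)
})
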