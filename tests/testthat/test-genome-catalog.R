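test_that("loadGenome reads, upper-cases and validates FASTA records", {
    fa <- writeFasta(list(c1 = "acgt"))
    g <- loadGenome(fa)
    expect_equal(names(g), "c1")
    expect_equal(as.character(g[[1]]), "ACGT")
    expect_equal(Biostrings::width(g), 4L)

    fa2 <- writeFasta(list("chrI extra description" = "ACGTN"))
    expect_equal(names(loadGenome(fa2)), "chrI")

    bad <- writeFasta(list(cx = "ACGX"))
    expect_error(loadGenome(bad), "cx")
    expect_error(loadGenome(tempfile()), "FASTA")
})

test_that("loadTranscripts enforces schema, coordinate dialects and CDS contracts", {
    fx <- classificationFixture()
    fa <- writeFasta(list(chrT = as.character(fx$genome[[1]])))
    genome <- loadGenome(fa)

    path <- writeTxTsv(fx$df, coords = "bed")
    tx <- loadTranscripts(path, genome = genome)
    expect_length(tx, 12L)
    expect_equal(S4Vectors::mcols(tx)$id, fx$df$id)
    expect_equal(GenomicRanges::start(tx), fx$df$start)

    # 1-based dialect converts to identical internal coordinates
    path1 <- writeTxTsv(fx$df, coords = "onebased")
    tx1 <- loadTranscripts(path1, genome = genome, coords = "onebased")
    expect_equal(GenomicRanges::start(tx1), GenomicRanges::start(tx))

    dup <- fx$df
    dup$id[2] <- dup$id[1]
    expect_error(loadTranscripts(writeTxTsv(dup), genome = genome),
                 "duplicate")

    noCds <- fx$df[, !(names(fx$df) %in% c("cds_start", "cds_end"))]
    expect_error(loadTranscripts(writeTxTsv(noCds), genome = genome),
                 "cds_start")

    # an ORF whose CDS does not start with ATG is kept for interval work
    # but flagged ineligible for codon analyses
    shifted <- fx$df
    shifted$cds_start[1] <- shifted$cds_start[1] + 3L
    shifted$cds_end[1] <- shifted$cds_end[1] + 3L
    tx2 <- suppressMessages(
        loadTranscripts(writeTxTsv(shifted), genome = genome))
    expect_length(tx2, 12L)
    expect_false(S4Vectors::mcols(tx2)$cds_ok[1])
    expect_true(all(S4Vectors::mcols(tx2)$cds_ok[-1]))

    # CDS length not divisible by 3: flagged, not dropped
    off <- fx$df
    off$cds_end[1] <- off$cds_end[1] + 1L
    tx3 <- suppressMessages(
        loadTranscripts(writeTxTsv(off), genome = genome))
    expect_false(S4Vectors::mcols(tx3)$cds_ok[1])
})

test_that("filterMinLength keeps the 200 bp boundary inclusive", {
    tx <- makeTx(data.frame(
        chrom = "c", start = c(1L, 301L), end = c(199L, 500L),
        id = c("short", "exact"), ttype = "ORF", strand = "+",
        cds_start = c(1L, 301L), cds_end = c(198L, 500L)),
        c(c = 1000L))
    out <- suppressMessages(filterMinLength(tx, 200L))
    expect_equal(S4Vectors::mcols(out)$id, "exact")
})

test_that("classification follows the overlap rules on the hand-built fixture", {
    fx <- classificationFixture()
    fa <- writeFasta(list(chrT = as.character(fx$genome[[1]])))
    tx <- loadTranscripts(writeTxTsv(fx$df), genome = loadGenome(fa))
    tx <- suppressMessages(filterMinLength(tx))
    expect_false("O7" %in% S4Vectors::mcols(tx)$id)  # 199 bp removed

    cls <- classifyOrfs(tx)
    lab <- setNames(cls$label, cls$orf_id)
    expect_equal(lab[c("O1", "O2", "O3", "O4", "O5", "O6")],
                 c(O1 = "ORF_CLEAR", O2 = "ORF_CUT", O3 = "ORF_CLEAR",
                   O4 = "EXCLUDED", O5 = "ORF_CLEAR", O6 = "ORF_SUT"))
    ov <- setNames(cls$antisense_overlap_bp, cls$orf_id)
    expect_equal(unname(ov[c("O2", "O3", "O6")]), c(150L, 99L, 100L))
    elig <- setNames(cls$codon_eligible, cls$orf_id)
    expect_false(elig[["O5"]])   # 11 bp ORF-ORF overlap
    expect_false(elig[["O6"]])
    expect_true(all(elig[c("O1", "O2", "O3")]))
})

test_that("classification is order-independent and partitions the ORF set", {
    fx <- classificationFixture()
    fa <- writeFasta(list(chrT = as.character(fx$genome[[1]])))
    genome <- loadGenome(fa)
    base <- classifyOrfs(suppressMessages(filterMinLength(
        loadTranscripts(writeTxTsv(fx$df), genome = genome))))
    set.seed(5)
    for (i in 1:5) {
        perm <- fx$df[sample.int(nrow(fx$df)), ]
        cls <- classifyOrfs(suppressMessages(filterMinLength(
            loadTranscripts(writeTxTsv(perm), genome = genome))))
        cls <- cls[match(base$orf_id, cls$orf_id), ]
        expect_equal(cls$label, base$label)
        expect_equal(cls$antisense_overlap_bp, base$antisense_overlap_bp)
    }
    expect_true(all(base$label %in%
                    c("ORF_CLEAR", "ORF_CUT", "ORF_SUT", "EXCLUDED")))
    expect_equal(sum(table(base$label)), nrow(base))
})

test_that("overlap lengths agree with per-base brute force on random layouts", {
    set.seed(77)
    for (rep in 1:4) {
        n <- 14L
        start <- sort(sample.int(4000L, n)) * 2L
        width <- sample(200:600, n, replace = TRUE)
        ttype <- sample(c("ORF", "CUT", "SUT"), n, replace = TRUE,
                        prob = c(0.5, 0.25, 0.25))
        if (!any(ttype == "ORF")) ttype[1] <- "ORF"
        df <- data.frame(chrom = "c", start = start, end = start + width,
                         id = paste0("t", seq_len(n)), ttype = ttype,
                         strand = sample(c("+", "-"), n, replace = TRUE),
                         cds_start = start, cds_end = start + width)
        tx <- makeTx(df, c(c = 20000L))
        cls <- classifyOrfs(tx, minOverlap = 100L)
        # per-base brute force
        for (i in which(df$ttype == "ORF")) {
            for (what in c("CUT", "SUT")) {
                best <- 0L
                for (j in which(df$ttype == what &
                                df$strand != df$strand[i])) {
                    cover <- length(intersect(df$start[i]:df$end[i],
                                              df$start[j]:df$end[j]))
                    best <- max(best, cover)
                }
                got <- cls[cls$orf_id == df$id[i],
                           paste0(tolower(what), "_overlap_bp")]
                expect_equal(got, best)
            }
        }
    }
})

test_that("neighbour orientation labels follow the strand definitions", {
    df <- data.frame(
        chrom = "c",
        start = c(100L, 600L, 1200L, 1800L),
        end = c(400L, 900L, 1500L, 2100L),
        id = c("a", "b", "c", "d"), ttype = "ORF",
        strand = c("+", "+", "-", "+"),
        cds_start = NA_integer_, cds_end = NA_integer_)
    out <- neighborOrientation(makeTx(df, c(c = 5000L)))
    expect_equal(out$orientation, c("tandem", "convergent", "divergent"))
})

test_that("intergenic control regions come from gaps of at least the window", {
    # three transcripts leaving a 399 bp gap and a 400 bp gap
    df <- data.frame(chrom = "c",
                     start = c(1L, 600L, 1301L),
                     end = c(200L, 900L, 1500L),
                     id = c("a", "b", "cc"), ttype = "SUT", strand = "+",
                     cds_start = NA_integer_, cds_end = NA_integer_)
    genome <- Biostrings::DNAStringSet(c(c = paste(rep("A", 1500),
                                                   collapse = "")))
    tx <- makeTx(df, c(c = 1500L))
    expect_length(intergenicRegions(genome, tx, window = 400L), 1L)

    # random layouts: one region per gap >= window, verified by interval
    # subtraction
    set.seed(21)
    for (rep in 1:3) {
        s <- sort(sample(seq(100L, 9000L, by = 50L), 8L))
        df <- data.frame(chrom = "c", start = s, end = s + 280L,
                         id = paste0("t", 1:8), ttype = "SUT",
                         strand = "+", cds_start = NA_integer_,
                         cds_end = NA_integer_)
        genome <- Biostrings::DNAStringSet(c(c = paste(
            rep("A", 10000), collapse = "")))
        tx <- makeTx(df, c(c = 10000L))
        covered <- rep(FALSE, 10000L)
        for (i in 1:8) covered[df$start[i]:df$end[i]] <- TRUE
        runs <- rle(covered)
        gapLens <- runs$lengths[!runs$values]
        expect_length(intergenicRegions(genome, tx, 400L),
                      sum(gapLens >= 400L))
    }
})
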