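# Fixture builders: everything is generated in code at test time.

writeFasta <- function(seqs, path = tempfile(fileext = ".fa")) {
    lines <- unlist(lapply(names(seqs), function(n) c(paste0(">", n),
                                                      seqs[[n]])))
    writeLines(lines, path)
    path
}

# build a transcript GRanges directly (1-based closed coordinates), with
# seqlengths attached; df columns: chrom start end id ttype strand
# [cds_start cds_end]
makeTx <- function(df, seqlens) {
    gr <- GenomicRanges::GRanges(
        df$chrom, IRanges::IRanges(df$start, df$end), strand = df$strand)
    if (is.null(df$cds_start)) df$cds_start <- NA_integer_
    if (is.null(df$cds_end)) df$cds_end <- NA_integer_
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        id = df$id, ttype = df$ttype,
        cds_start = as.integer(df$cds_start),
        cds_end = as.integer(df$cds_end),
        cds_ok = TRUE)
    GenomeInfoDb::seqlengths(gr) <- seqlens[GenomeInfoDb::seqlevels(gr)]
    gr
}

writeTxTsv <- function(df, path = tempfile(fileext = ".tsv"),
                       coords = "bed") {
    out <- df
    if (coords == "bed") {
        out$start <- out$start - 1L
        if (!is.null(out$cds_start))
            out$cds_start <- ifelse(is.na(out$cds_start), NA,
                                    out$cds_start - 1L)
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}

# Twelve-transcript toy exercising every classification rule.  The genome
# is mostly A with ATG planted at CDS starts (strand-aware) so start-codon
# validation passes.
classificationFixture <- function() {
    L <- 7000L
    g <- rep("A", L)
    orf <- function(s, e, cs, ce, strand) {
        if (strand == "+") g[cs:(cs + 2L)] <<- c("A", "T", "G")
        else g[(ce - 2L):ce] <<- c("C", "A", "T")  # revcomp(ATG)
        NULL
    }
    tx <- list()
    add <- function(...) tx[[length(tx) + 1L]] <<- data.frame(...)
    # O1: clear, no antisense neighbour
    orf(1001, 1800, 1101, 1700, "+")
    add(chrom = "chrT", start = 1001, end = 1800, id = "O1", ttype = "ORF",
        strand = "+", cds_start = 1101, cds_end = 1700)
    # O2 + antisense CUT overlapping 150 bp -> ORF_CUT
    orf(2001, 2800, 2101, 2700, "+")
    add(chrom = "chrT", start = 2001, end = 2800, id = "O2", ttype = "ORF",
        strand = "+", cds_start = 2101, cds_end = 2700)
    add(chrom = "chrT", start = 2651, end = 2950, id = "CUTa",
        ttype = "CUT", strand = "-", cds_start = NA, cds_end = NA)
    # O3 + antisense SUT overlapping 99 bp -> ORF_CLEAR
    orf(3001, 3800, 3101, 3700, "+")
    add(chrom = "chrT", start = 3001, end = 3800, id = "O3", ttype = "ORF",
        strand = "+", cds_start = 3101, cds_end = 3700)
    add(chrom = "chrT", start = 3702, end = 3950, id = "SUTb",
        ttype = "SUT", strand = "-", cds_start = NA, cds_end = NA)
    # O4 + both a CUT and a SUT overlapping >= 100 bp -> EXCLUDED
    orf(4001, 4800, 4101, 4700, "+")
    add(chrom = "chrT", start = 4001, end = 4800, id = "O4", ttype = "ORF",
        strand = "+", cds_start = 4101, cds_end = 4700)
    add(chrom = "chrT", start = 4681, end = 4900, id = "CUTc",
        ttype = "CUT", strand = "-", cds_start = NA, cds_end = NA)
    add(chrom = "chrT", start = 3901, end = 4105, id = "SUTd",
        ttype = "SUT", strand = "-", cds_start = NA, cds_end = NA)
    # O5/O6: ORF-ORF overlap of 11 bp (> 10) -> both codon-ineligible;
    # O6 additionally has an antisense SUT overlapping exactly 100 bp
    orf(5001, 5600, 5101, 5499, "+")
    add(chrom = "chrT", start = 5001, end = 5600, id = "O5", ttype = "ORF",
        strand = "+", cds_start = 5101, cds_end = 5499)
    orf(5590, 6200, 5690, 6100, "+")
    add(chrom = "chrT", start = 5590, end = 6200, id = "O6", ttype = "ORF",
        strand = "+", cds_start = 5690, cds_end = 6100)
    add(chrom = "chrT", start = 6101, end = 6400, id = "SUTe",
        ttype = "SUT", strand = "-", cds_start = NA, cds_end = NA)
    # O7: 199 bp transcript, removed by the length filter
    orf(6500, 6698, 6520, 6618, "+")
    add(chrom = "chrT", start = 6500, end = 6698, id = "O7", ttype = "ORF",
        strand = "+", cds_start = 6520, cds_end = 6618)
    df <- do.call(rbind, tx)
    stopifnot(nrow(df) == 12L)
    genome <- Biostrings::DNAStringSet(c(chrT = paste(g, collapse = "")))
    list(genome = genome, df = df)
}

# one small shared synthetic dataset for integration-style unit tests
smallDataset <- local({
    cache <- NULL
    function() {
        if (is.null(cache))
            cache <<- makeDataset(generatorConfig(
                seed = 11, nClear = 10, nCut = 5, nSut = 5,
                proteinLenMeanLog = log(120), proteinLenMin = 80,
                proteinLenMax = 250))
        cache
    }
})
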