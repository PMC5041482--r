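# End-to-end orchestration.  The exported functions are the primary
# interface; inst/scripts/antisense-pipeline.R is a thin shell wrapper
# around runPipeline() for command-line use.

.defaultRunConfig <- function() {
    list(minLen = 200, minOverlap = 100, orfOrfMax = 10,
         flank = 400, bin = 10, span = 400, exprWindow = 5,
         exprFloor = 1e-6, seed = 1,
         nClear = 300, nCut = 150, nSut = 150,
         dataDir = ".", outDir = ".",
         genome = "genome.fa", transcripts = "transcripts.tsv",
         expression = "expression.tsv", midpoints = "midpoints.bed")
}

#' Read a flat key=value run-configuration file
#'
#' One \code{key=value} per line; blank lines and \code{#} comments are
#' ignored; values that parse as numbers are converted.  Keys mirror the
#' arguments of \code{\link{runPipeline}}; explicit \code{config} entries
#' passed to \code{runPipeline} override file values.
#'
#' @param path configuration file
#' @return named list
#' @export
readRunConfig <- function(path) {
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    kv <- regmatches(lines, regexpr("=", lines, fixed = TRUE),
                     invert = TRUE)
    bad <- lengths(kv) != 2L
    if (any(bad))
        stop("malformed config line(s): ",
             paste(lines[bad], collapse = "; "))
    keys <- trimws(vapply(kv, `[`, "", 1L))
    vals <- trimws(vapply(kv, `[`, "", 2L))
    out <- lapply(vals, function(v) {
        n <- suppressWarnings(as.numeric(v))
        if (!is.na(n)) n else v
    })
    stats::setNames(out, keys)
}

.resolveConfig <- function(config) {
    cfg <- .defaultRunConfig()
    if (!is.null(config$configFile)) {
        fromFile <- readRunConfig(config$configFile)
        cfg[names(fromFile)] <- fromFile
        config$configFile <- NULL
    }
    cfg[names(config)] <- config
    cfg
}

.loadInputs <- function(cfg, what = c("genome", "transcripts")) {
    out <- list()
    p <- function(f) file.path(cfg$dataDir, f)
    if ("genome" %in% what) out$genome <- loadGenome(p(cfg$genome))
    if ("transcripts" %in% what) {
        out$tx <- loadTranscripts(p(cfg$transcripts), genome = out$genome)
        out$tx <- filterMinLength(out$tx, cfg$minLen)
    }
    if ("expression" %in% what)
        out$track <- loadExpressionTrack(p(cfg$expression))
    if ("midpoints" %in% what)
        out$mids <- loadMidpoints(p(cfg$midpoints))
    out
}

# ORFs of one classified class that are eligible for codon/PAR-CLIP work
.classOrfs <- function(tx, cls, label, eligibleOnly = TRUE) {
    ids <- cls$orf_id[cls$label == label &
                          (!eligibleOnly | cls$codon_eligible)]
    tx[S4Vectors::mcols(tx)$id %in% ids]
}

#' Run one pipeline stage
#'
#' Subcommands: \code{simulate} (emit a synthetic dataset),
#' \code{classify} (ORF classification TSV), \code{scan} (genome-wide site
#' BED6), \code{profile} (per-class density profile TSVs),
#' \code{codon-model} (per-ORF observed/expected/residual/delta TSV),
#' \code{parclip} (occupancy profile TSVs), \code{enumerate}
#' (pair/triplet universe summary) and \code{report} (per-class summary
#' TSV + JSON).  \code{config} is a flat list of overrides; defaults are
#' the standard thresholds (200 bp minimum transcript length, 100 bp
#' antisense overlap, 10 bp ORF-ORF tolerance, 400 bp flank, 10 bp bins,
#' 5 bp expression windows).  A \code{configFile} entry points at a
#' \code{key=value} file; explicit entries override it.  The resolved
#' configuration is logged.
#'
#' @param subcommand one of the stage names above
#' @param config named list of overrides (see \code{\link{readRunConfig}})
#' @return stage-dependent value, invisibly where the product is a file
#' @export
runPipeline <- function(subcommand = c("simulate", "classify", "scan",
                                       "profile", "codon-model", "parclip",
                                       "enumerate", "report"),
                        config = list()) {
    subcommand <- match.arg(subcommand)
    cfg <- .resolveConfig(config)
    asmLog("resolved config: ",
           paste(names(cfg), vapply(cfg, function(x)
               paste(format(x), collapse = ","), ""),
               sep = "=", collapse = "; "))
    if (!dir.exists(cfg$outDir)) dir.create(cfg$outDir, recursive = TRUE)
    out <- function(f) file.path(cfg$outDir, f)

    if (subcommand == "enumerate") {
        res <- enumerationSummary()
        utils::write.table(res, out("enumeration.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        return(res)
    }
    if (subcommand == "simulate") {
        gen <- generatorConfig(seed = cfg$seed, nClear = cfg$nClear,
                               nCut = cfg$nCut, nSut = cfg$nSut)
        ds <- makeDataset(gen, dir = cfg$outDir)
        return(invisible(ds))
    }
    if (subcommand == "classify") {
        inp <- .loadInputs(cfg)
        cls <- classifyOrfs(inp$tx, cfg$minOverlap, cfg$orfOrfMax)
        utils::write.table(
            cls[, c("orf_id", "label", "antisense_overlap_bp")],
            out("classification.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
        return(invisible(cls))
    }
    if (subcommand == "scan") {
        inp <- .loadInputs(cfg, "genome")
        sites <- scanMotifs(inp$genome)
        bed <- data.frame(
            chrom = as.character(GenomicRanges::seqnames(sites)),
            start = GenomicRanges::start(sites) - 1L,
            end = GenomicRanges::end(sites),
            name = paste(S4Vectors::mcols(sites)$protein,
                         S4Vectors::mcols(sites)$motif, sep = ":"),
            score = GenomicRanges::width(sites),
            strand = as.character(GenomicRanges::strand(sites)))
        utils::write.table(bed, out("sites.bed"), sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
        return(invisible(sites))
    }

    inp <- .loadInputs(cfg)
    cls <- classifyOrfs(inp$tx, cfg$minOverlap, cfg$orfOrfMax)
    labels <- c("ORF_CLEAR", "ORF_CUT", "ORF_SUT")

    if (subcommand == "profile") {
        sites <- scanMotifs(inp$genome)
        for (lb in labels) {
            orfs <- .classOrfs(inp$tx, cls, lb, eligibleOnly = FALSE)
            if (!length(orfs)) next
            for (anch in c("start_codon", "stop_codon"))
                for (dirn in c("sense", "antisense")) {
                    pr <- densityProfile(orfs, anchor = anch,
                                         direction = dirn,
                                         flank = cfg$flank, bin = cfg$bin,
                                         sites = sites)
                    writeProfile(pr, out(sprintf("density_%s_%s_%s.tsv",
                                                 lb, anch, dirn)))
                }
        }
        return(invisible(NULL))
    }
    if (subcommand == "parclip") {
        inp2 <- .loadInputs(cfg, c("expression", "midpoints"))
        for (lb in labels) {
            orfs <- .classOrfs(inp$tx, cls, lb)
            if (!length(orfs)) next
            for (anch in c("start_codon", "stop_codon"))
                for (dirn in c("sense", "antisense")) {
                    pr <- occupancyProfile(orfs, inp2$mids, inp2$track,
                                           anchor = anch, direction = dirn,
                                           flank = cfg$flank,
                                           bin = cfg$bin,
                                           exprFloor = cfg$exprFloor)
                    writeProfile(pr, out(sprintf("occupancy_%s_%s_%s.tsv",
                                                 lb, anch, dirn)))
                }
        }
        return(invisible(NULL))
    }
    if (subcommand == "codon-model") {
        res <- .codonModelTable(inp$genome, inp$tx, cls)
        utils::write.table(res, out("codon_model.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        return(invisible(res))
    }
    # report
    rep <- pipelineReport(inp$genome, inp$tx, cls, span = cfg$span)
    utils::write.table(rep$classes, out("report_classes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(rep, out("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(rep)
}

# per-ORF observed/expected/residual/delta, both directions, all classes
.codonModelTable <- function(genome, tx, cls) {
    labels <- c("ORF_CLEAR", "ORF_CUT", "ORF_SUT")
    cdsOf <- lapply(labels, function(lb)
        cdsSequence(.classOrfs(tx, cls, lb), genome))
    names(cdsOf) <- labels
    models <- lapply(labels, function(lb)
        fitCodonUsage(cdsOf[[lb]], classLabel = lb))
    names(models) <- labels
    out <- list()
    for (lb in labels)
        for (dirn in c("sense", "antisense")) {
            r <- siteResiduals(cdsOf[[lb]], models[[lb]], dirn)
            r$class <- lb
            r$delta <- if (lb == "ORF_CLEAR") 0 else
                as.numeric(deltaExpected(cdsOf[[lb]], models[[lb]],
                                         models$ORF_CLEAR, dirn))
            out[[paste(lb, dirn)]] <- r
        }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res[, c("class", "id", "direction", "observed", "expected",
            "residual", "delta")]
}

#' Aggregate per-class summaries
#'
#' Class sizes, mean sense/antisense site counts in the anchored windows,
#' and moments of the codon-usage delta distributions, in one structure
#' suitable for TSV/JSON export.
#'
#' @param genome DNAStringSet
#' @param tx filtered transcript GRanges
#' @param cls classification from \code{\link{classifyOrfs}}
#' @param span boxplot window span in bp
#' @return list with elements \code{classes} (data.frame) and
#'   \code{deltas} (list of moment vectors)
#' @export
pipelineReport <- function(genome, tx, cls, span = 400L) {
    labels <- c("ORF_CLEAR", "ORF_CUT", "ORF_SUT")
    sites <- scanMotifs(genome)
    tab <- .codonModelTable(genome, tx, cls)
    rows <- list(); deltas <- list()
    for (lb in labels) {
        orfs <- .classOrfs(tx, cls, lb, eligibleOnly = FALSE)
        senseFirst <- countWindow(orfs, anchor = "start_codon",
                                  direction = "sense", span = span,
                                  sites = sites)
        antiLast <- countWindow(orfs, anchor = "stop_codon",
                                direction = "antisense", span = span,
                                sites = sites)
        sel <- tab$class == lb & tab$direction == "antisense"
        rows[[lb]] <- data.frame(
            class = lb, n = length(orfs),
            n_codon_eligible = sum(cls$label == lb & cls$codon_eligible),
            mean_sense_first = mean(senseFirst, na.rm = TRUE),
            mean_antisense_last = mean(antiLast, na.rm = TRUE),
            delta_antisense_mean = mean(tab$delta[sel]),
            delta_antisense_sd = stats::sd(tab$delta[sel]))
        for (dirn in c("sense", "antisense")) {
            d <- tab$delta[tab$class == lb & tab$direction == dirn]
            deltas[[paste(lb, dirn, sep = "_")]] <-
                c(mean = mean(d), sd = stats::sd(d))
        }
    }
    list(classes = do.call(rbind, rows), deltas = deltas)
}
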