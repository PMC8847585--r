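# Readers and writers for the standard plain-text interchange formats.

#' @importFrom utils read.delim write.table head
#' @importFrom rtracklayer import export
NULL

#' Read gene models from BED6
#'
#' @param path BED6 file (chrom, start, end, name, score, strand).
#' @return named \code{GRanges}.
#' @export
readGeneBed <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    names(gr) <- gr$name
    gr
}

#' Read a bedGraph signal track
#'
#' @param path bedGraph file.
#' @return \code{GRanges} with a \code{score} column, sorted.
#' @export
readBedGraph <- function(path) {
    sort(rtracklayer::import(path, format = "bedGraph"))
}

#' Read a CpG methylation table
#'
#' @param path TSV with columns chrom, pos0 (0-based), meth, total.
#' @return \code{GRanges} with \code{meth} and \code{total} columns.
#' @export
readCpgTable <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    GRanges(df$chrom, IRanges(start = df$pos0 + 1L, width = 1L),
            meth = df$meth, total = df$total)
}

#' Read a gene x sample count matrix
#'
#' @param path TSV whose first column holds gene ids and whose header
#'   holds sample ids.
#' @return integer matrix with gene rownames.
#' @export
readCountMatrix <- function(path) {
    df <- read.delim(path, row.names = 1, check.names = FALSE)
    as.matrix(df)
}

#' Read a cohort expression matrix
#'
#' @param path TSV, rows samples, columns genes, values log2(RPM); the
#'   first column holds sample ids.
#' @param marker designated marker gene id.
#' @return a \code{\linkS4class{CohortMatrix}}.
#' @export
readCohortMatrix <- function(path, marker) {
    df <- read.delim(path, row.names = 1, check.names = FALSE)
    new("CohortMatrix", expr = as.matrix(df), marker = marker)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, tab-separated genes).
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    sets <- lapply(parts, function(x) unique(x[-(1:2)]))
    names(sets) <- vapply(parts, `[`, character(1), 1L)
    sets
}

#' Write all artifacts of a simulated study to plain-text files
#'
#' Emits BED6 gene models, one bedGraph per mark, the CpG TSV, control
#' and treated count TSVs, spike-in statistics TSV, the cohort TSV and a
#' ground-truth JSON into \code{outdir}.
#'
#' @param sim a \code{\linkS4class{PrcSimulation}}.
#' @param outdir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
writeSimulation <- function(sim, outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- c()
    genes <- sim@genes
    bed <- genes
    bed$name <- names(genes)
    bed$score <- 0L
    p <- file.path(outdir, "genes.bed")
    rtracklayer::export(bed, p, format = "BED")
    paths["genes"] <- p
    for (mark in names(sim@tracks)) {
        p <- file.path(outdir, paste0(mark, ".bedGraph"))
        rtracklayer::export(sim@tracks[[mark]], p, format = "bedGraph")
        paths[mark] <- p
    }
    cpg <- sim@cpg
    p <- file.path(outdir, "cpg.tsv")
    write.table(data.frame(chrom = as.character(seqnames(cpg)),
                           pos0 = start(cpg) - 1L,
                           meth = cpg$meth, total = cpg$total),
                p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths["cpg"] <- p
    counts <- assay(sim@counts, "counts")
    cond <- sim@counts$condition
    for (arm in levels(cond)) {
        m <- counts[, cond == arm, drop = FALSE]
        p <- file.path(outdir, paste0("counts_", arm, ".tsv"))
        write.table(data.frame(gene_id = rownames(m), m,
                               check.names = FALSE),
                    p, sep = "\t", quote = FALSE, row.names = FALSE)
        paths[paste0("counts_", arm)] <- p
    }
    p <- file.path(outdir, "spikein.tsv")
    write.table(as.data.frame.SpikeInStats(metadata(sim@counts)$spikein),
                p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths["spikein"] <- p
    expr <- cohortExpr(sim@cohort)
    p <- file.path(outdir, "cohort.tsv")
    write.table(data.frame(sample_id = rownames(expr), expr,
                           check.names = FALSE),
                p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths["cohort"] <- p
    p <- file.path(outdir, "truth.json")
    jsonlite::write_json(as.list(archetypeTruth(sim)), p,
                         auto_unbox = TRUE)
    paths["truth"] <- p
    invisible(paths)
}
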