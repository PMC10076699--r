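#' Read a FASTA file
#'
#' @param path FASTA file (wrapped or unwrapped, multi-record).
#' @return `DNAStringSet`.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write sequences to FASTA
#'
#' @param x `DNAStringSet` or named character vector.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @export
write_fasta <- function(x, path, width = 60L) {
    if (!methods::is(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
    Biostrings::writeXStringSet(x, path, width = width)
    invisible(path)
}

#' Read a FASTQ file (Sanger Phred+33)
#'
#' @param path FASTQ file.
#' @return List with `reads` (named character) and `quality` (named
#'   character).
#' @export
read_fastq <- function(path) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    q <- as.character(S4Vectors::mcols(x)$qualities)
    list(reads = setNames(as.character(x), names(x)),
         quality = setNames(q, names(x)))
}

#' Write reads to FASTQ (Sanger Phred+33)
#'
#' @param reads Named character vector of read sequences.
#' @param path Output path.
#' @param quality Quality string(s): a single string recycled to all reads
#'   (each read's length must match) or a vector parallel to `reads`.
#' @export
write_fastq <- function(reads, path, quality = NULL) {
    dss <- Biostrings::DNAStringSet(unname(reads))
    names(dss) <- names(reads)
    if (is.null(quality)) quality <- strrep("I", max(nchar(reads), 0L))
    if (length(quality) == 1L) quality <- rep(quality, length(reads))
    Biostrings::writeXStringSet(dss, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quality))
    invisible(path)
}

#' Write a data frame as TSV with a provenance header
#'
#' Provenance lines are written as leading `#` comments (inputs, parameters,
#' seed, package version); missing values are written as ".".
#'
#' @param df data.frame.
#' @param path Output path.
#' @param provenance Character vector of provenance strings (one per line).
#' @export
write_tsv <- function(df, path, provenance = character(0)) {
    con <- file(path, "w")
    on.exit(close(con))
    hdr <- c(provenance,
             paste("generated by isoswitchr",
                   as.character(utils::packageVersion("isoswitchr"))))
    writeLines(paste("#", hdr), con)
    df[] <- lapply(df, function(col) {
        col[is.na(col)] <- if (is.character(col)) "." else NA
        col
    })
    suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE, na = "."))
    invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path Input path.
#' @return data.frame (comment lines skipped, "." read as NA).
#' @export
read_tsv <- function(path) {
    read.delim(path, sep = "\t", comment.char = "#", na.strings = ".",
               stringsAsFactors = FALSE)
}

#' Write labeled feature intervals as BED
#'
#' BED uses the same 0-based half-open convention as the package internals,
#' so coordinates pass through unchanged; the feature label goes in the name
#' column.
#'
#' @param features data.frame with columns `chrom`, `start`, `end`, `strand`
#'   and a label column (`record`, `feature_id` or `label`).
#' @param path Output path.
#' @export
write_feature_bed <- function(features, path) {
    lab <- intersect(c("record", "feature_id", "label"), colnames(features))
    if (length(lab) == 0) stop("no label column found")
    bed <- data.frame(features$chrom, features$start, features$end,
                      features[[lab[1]]], 0L, features$strand)
    write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' Write one fixture sample as FASTQ plus truth TSV
#'
#' @param fixture A [make_study_fixture()] result.
#' @param sample_id One of `fixture$samples$sample`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_sample_fastq <- function(fixture, sample_id, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    sim <- simulate_sample_reads(fixture, sample_id)
    fq <- file.path(dir, paste0(sample_id, ".fastq"))
    tt <- file.path(dir, paste0(sample_id, ".truth.tsv"))
    write_fastq(sim$reads, fq, quality = sim$quality)
    write_tsv(sim$truth, tt,
              provenance = paste("sample:", sample_id))
    invisible(c(fastq = fq, truth = tt))
}
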