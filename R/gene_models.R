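#' Parse a GTF gene annotation into gene models
#'
#' Reads a GTF file (1-based, inclusive coordinates) and returns one gene
#' model per `gene_id`. Exons are grouped by transcript and ordered 5' to 3'
#' according to strand; coordinates are converted to the package-internal
#' 0-based half-open convention at this boundary.
#'
#' Transcripts may carry an optional `isoform` attribute naming the promoter
#' isoform they belong to; transcripts without one are treated as their own
#' isoform (label = transcript_id).
#'
#' @param gtf Path to a GTF file, or a character vector of GTF lines.
#' @return A list of `GeneModel` objects (one per gene), each a list with
#'   elements `gene_id`, `span` (data.frame: chrom, start, end, strand,
#'   0-based half-open) and `transcripts`, a list of lists with
#'   `transcript_id`, `isoform_label` and `exons` (data.frame of 0-based
#'   half-open intervals in 5'->3' transcript order).
#' @export
parse_gene_annotation <- function(gtf) {
    if (length(gtf) == 1L && !grepl("\n", gtf) && file.exists(gtf)) {
        lines <- readLines(gtf)
        path <- gtf
        cleanup <- FALSE
    } else {
        lines <- unlist(strsplit(as.character(gtf), "\n", fixed = TRUE))
        path <- tempfile(fileext = ".gtf")
        writeLines(lines, path)
        cleanup <- TRUE
    }
    if (cleanup) on.exit(unlink(path), add = TRUE)

    body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
    for (i in body) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
        if (length(f) < 9L)
            stop("GTF parse error at line ", i, ": expected 9 tab-separated ",
                 "fields, found ", length(f))
        type <- f[3L]
        attrs <- f[9L]
        if (!grepl("gene_id", attrs, fixed = TRUE))
            stop("GTF parse error at line ", i, ": missing gene_id attribute")
        if (type %in% c("exon", "transcript") &&
            !grepl("transcript_id", attrs, fixed = TRUE))
            stop("GTF parse error at line ", i,
                 ": missing transcript_id attribute")
    }

    gr <- rtracklayer::import(path, format = "gtf")
    md <- S4Vectors::mcols(gr)
    exon <- gr[md$type == "exon"]
    if (length(exon) == 0L) stop("annotation contains no exon features")
    em <- S4Vectors::mcols(exon)

    # transcripts declared but without exons are invalid
    declared <- unique(md$transcript_id[md$type == "transcript"])
    declared <- declared[!is.na(declared)]
    missing_tx <- setdiff(declared, unique(em$transcript_id))
    if (length(missing_tx) > 0L)
        stop("transcript with zero exons: ", paste(missing_tx, collapse = ", "))

    exon_df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(exon)),
        start = GenomicRanges::start(exon) - 1L, # to 0-based half-open
        end = GenomicRanges::end(exon),
        strand = as.character(GenomicRanges::strand(exon)),
        gene_id = em$gene_id,
        transcript_id = em$transcript_id,
        isoform = if ("isoform" %in% colnames(em)) em$isoform else NA_character_,
        stringsAsFactors = FALSE
    )
    lapply(split(exon_df, exon_df$gene_id), .build_gene_model)
}

.build_gene_model <- function(df) {
    transcripts <- lapply(split(df, df$transcript_id), function(tx) {
        strand <- tx$strand[1L]
        ord <- order(tx$start, decreasing = (strand == "-"))
        tx <- tx[ord, , drop = FALSE]
        exons <- data.frame(
            chrom = tx$chrom, start = tx$start, end = tx$end,
            strand = tx$strand,
            exon_id = sprintf("%s.e%d", tx$transcript_id[1L], seq_len(nrow(tx))),
            stringsAsFactors = FALSE
        )
        label <- tx$isoform[1L]
        if (is.na(label)) label <- tx$transcript_id[1L]
        list(transcript_id = tx$transcript_id[1L],
             isoform_label = label, exons = exons)
    })
    span <- data.frame(
        chrom = df$chrom[1L], start = min(df$start), end = max(df$end),
        strand = df$strand[1L], stringsAsFactors = FALSE
    )
    structure(list(gene_id = df$gene_id[1L], span = span,
                   transcripts = unname(transcripts)),
              class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
    cat("GeneModel", x$gene_id, "|", length(x$transcripts), "transcript(s) |",
        x$span$chrom, sprintf("[%d,%d)", x$span$start, x$span$end),
        x$span$strand, "\n")
    invisible(x)
}

#' Classify the exons of a gene as isoform-specific or common
#'
#' An exon interval is specific to isoform i when it intersects exons of
#' transcripts of exactly one isoform label, and common when it intersects
#' exons of two or more isoform labels. Identity is by genomic-interval
#' intersection, not exact coordinate equality, so partially overlapping
#' exon variants from different isoforms are both classified common.
#'
#' @param gene A `GeneModel` from [parse_gene_annotation()].
#' @return An `ExonClassification`: list with `exons` (data.frame of distinct
#'   exon intervals with a `label` column, `"common"` or the isoform label)
#'   and `specific_counts` (named integer, specific exons per isoform).
#' @export
classify_exons <- function(gene) {
    stopifnot(inherits(gene, "GeneModel"))
    all_ex <- do.call(rbind, lapply(gene$transcripts, function(tx) {
        cbind(tx$exons, isoform = tx$isoform_label, stringsAsFactors = FALSE)
    }))
    key <- paste(all_ex$chrom, all_ex$start, all_ex$end, all_ex$strand)
    distinct <- all_ex[!duplicated(key), c("chrom", "start", "end", "strand"),
                       drop = FALSE]
    # which isoform labels touch each distinct interval (nonzero intersection)
    ir_d <- IRanges::IRanges(start = distinct$start + 1L, end = distinct$end)
    ir_a <- IRanges::IRanges(start = all_ex$start + 1L, end = all_ex$end)
    ov <- IRanges::findOverlaps(ir_d, ir_a)
    same_chrom <- distinct$chrom[S4Vectors::queryHits(ov)] ==
        all_ex$chrom[S4Vectors::subjectHits(ov)]
    ov <- ov[same_chrom]
    labs <- split(all_ex$isoform[S4Vectors::subjectHits(ov)],
                  S4Vectors::queryHits(ov))
    isoforms <- unique(all_ex$isoform)
    label <- character(nrow(distinct))
    for (i in seq_len(nrow(distinct))) {
        touching <- unique(labs[[as.character(i)]])
        label[i] <- if (length(touching) == 1L) touching else "common"
    }
    distinct$label <- label
    counts <- setNames(integer(length(isoforms)), isoforms)
    tab <- table(label[label != "common"])
    counts[names(tab)] <- as.integer(tab)
    structure(list(exons = distinct, specific_counts = counts),
              class = "ExonClassification")
}

#' Extract feature sequences from a genome
#'
#' Features are labeled sets of genomic intervals (0-based half-open); rows
#' sharing a `feature_id` are concatenated in row order (transcript order),
#' and minus-strand intervals are reverse-complemented so every returned
#' sequence is in sense (mRNA) orientation.
#'
#' @param genome Named `DNAStringSet` (or named character vector) of
#'   chromosome sequences.
#' @param features data.frame with columns `feature_id`, `chrom`, `start`,
#'   `end`, `strand`.
#' @return `DNAStringSet` named by feature_id.
#' @export
extract_feature_sequences <- function(genome, features) {
    if (!methods::is(genome, "DNAStringSet"))
        genome <- Biostrings::DNAStringSet(genome)
    need <- c("feature_id", "chrom", "start", "end", "strand")
    stopifnot(all(need %in% colnames(features)))
    chunks <- character(nrow(features))
    for (i in seq_len(nrow(features))) {
        f <- features[i, ]
        if (!f$chrom %in% names(genome))
            stop("unknown chromosome '", f$chrom, "' for feature ",
                 f$feature_id)
        L <- length(genome[[f$chrom]])
        if (f$start < 0 || f$end > L || f$start >= f$end)
            stop("interval out of bounds for feature ", f$feature_id,
                 sprintf(" ([%d,%d) on %s of length %d)",
                         f$start, f$end, f$chrom, L))
        s <- Biostrings::subseq(genome[[f$chrom]], f$start + 1L, f$end)
        if (f$strand == "-") s <- Biostrings::reverseComplement(s)
        chunks[i] <- as.character(s)
    }
    ids <- unique(features$feature_id)
    out <- vapply(ids, function(id) {
        paste(chunks[features$feature_id == id], collapse = "")
    }, character(1))
    Biostrings::DNAStringSet(setNames(out, ids))
}

#' Translate the longest ATG-initiated open reading frame
#'
#' Scans the forward strand for ATG-initiated ORFs terminated by an in-frame
#' stop codon and translates the longest one (ties broken by leftmost start).
#' The stop codon is excluded from the residue count. Codons containing N
#' translate to X and cannot serve as stops.
#'
#' @param cdna A `DNAString`, `DNAStringSet` of length 1, or single character
#'   string over A,C,G,T,N.
#' @return List with `found` (logical), `protein` (character, "" when no ORF),
#'   `n_residues` (integer) and `start` (0-based position of the ATG, NA when
#'   no ORF).
#' @export
translate_longest_orf <- function(cdna) {
    if (methods::is(cdna, "DNAStringSet")) cdna <- cdna[[1L]]
    s <- toupper(as.character(cdna))
    if (!nzchar(s)) stop("empty sequence")
    if (grepl("[^ACGTN]", s)) stop("sequence must be over A,C,G,T,N")
    n <- nchar(s)
    atg <- gregexpr("ATG", s, fixed = TRUE)[[1L]]
    if (atg[1L] == -1L)
        return(list(found = FALSE, protein = "", n_residues = 0L,
                    start = NA_integer_))
    codon_at <- function(p) substr(s, p, p + 2L)
    stops <- c("TAA", "TAG", "TGA")
    # in-frame stop positions per frame (1-based codon starts)
    stop_pos <- lapply(0:2, function(f) {
        p <- seq.int(f + 1L, n - 2L, by = 3L)
        if (length(p) == 0L) return(integer(0))
        p[vapply(p, function(q) codon_at(q) %in% stops, logical(1))]
    })
    best_len <- -1L
    best_start <- NA_integer_
    best_end <- NA_integer_
    for (p in atg) {
        f <- (p - 1L) %% 3L
        sp <- stop_pos[[f + 1L]]
        sp <- sp[sp > p]
        if (length(sp) == 0L) next
        q <- sp[1L]
        len <- (q - p) %/% 3L # residues, stop excluded
        if (len > best_len) {
            best_len <- len
            best_start <- p
            best_end <- q
        }
    }
    if (best_len < 0L)
        return(list(found = FALSE, protein = "", n_residues = 0L,
                    start = NA_integer_))
    coding <- Biostrings::DNAString(substr(s, best_start, best_end - 1L))
    prot <- as.character(Biostrings::translate(coding, if.fuzzy.codon = "X"))
    list(found = TRUE, protein = prot, n_residues = best_len,
         start = best_start - 1L)
}
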