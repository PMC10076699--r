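#' Build a k-mer feature index
#'
#' Maps every length-k word of every record to the set of feature classes
#' containing it. Words containing N (or any non-ACGT base) are skipped.
#' Records are grouped into classes by the `classes` vector; several records
#' may share a class (e.g. the four isoform-1-specific exons as
#' separate-but-co-classed records). Supports k up to 31 and up to 32 classes.
#'
#' @param records `DNAStringSet` or named character vector of feature
#'   sequences (sense orientation).
#' @param classes Character vector, one class label per record. Defaults to
#'   the record names (one class per record).
#' @param k k-mer length (default 21, shorter than a 50-base read, long
#'   enough for uniqueness in toy genomes).
#' @param specific Character vector naming the classes that are
#'   isoform-specific (used by the junction rule in [assign_reads()]).
#'   Default: all classes except any named "common".
#' @param concatenate If TRUE, records of a class are concatenated into a
#'   single sequence before indexing (adds junction k-mers between co-classed
#'   records); default FALSE keeps them as separate records.
#' @return A `FeatureIndex` object.
#' @export
build_feature_index <- function(records, classes = NULL, k = 21L,
                                specific = NULL, concatenate = FALSE) {
    if (methods::is(records, "DNAStringSet")) {
        seqs <- as.character(records)
    } else {
        seqs <- as.character(records)
        names(seqs) <- names(records)
    }
    if (is.null(classes)) {
        if (is.null(names(seqs))) stop("records must be named or classes given")
        classes <- names(seqs)
    }
    stopifnot(length(classes) == length(seqs))
    k <- as.integer(k)
    if (k < 1L) stop("k must be >= 1")
    class_levels <- unique(classes)
    if (concatenate) {
        seqs <- vapply(class_levels, function(cl) {
            paste(seqs[classes == cl], collapse = "")
        }, character(1))
        classes <- class_levels
    }
    if (all(nchar(seqs) < k))
        stop("empty index: k (", k, ") exceeds every record length")
    if (is.null(specific)) specific <- setdiff(class_levels, "common")
    class_lengths <- vapply(class_levels, function(cl) {
        sum(nchar(seqs[classes == cl]))
    }, numeric(1))
    ptr <- .kmer_index_build(unname(seqs),
                             match(classes, class_levels) - 1L,
                             k, length(class_levels))
    structure(list(
        k = k,
        classes = class_levels,
        specific = intersect(specific, class_levels),
        class_lengths = class_lengths,
        n_records = length(seqs),
        n_kmers = .kmer_index_size(ptr),
        records = seqs,
        record_classes = classes,
        ptr = ptr
    ), class = "FeatureIndex")
}

# external pointers do not survive serialization; rebuild transparently
.index_ptr <- function(index) {
    p <- index$ptr
    if (!.ptr_is_null(p)) return(p)
    .kmer_index_build(unname(index$records),
                      match(index$record_classes, index$classes) - 1L,
                      index$k, length(index$classes))
}

#' @export
print.FeatureIndex <- function(x, ...) {
    cat("FeatureIndex: k =", x$k, "|", length(x$classes), "classes |",
        x$n_records, "records |", format(x$n_kmers, big.mark = ","),
        "distinct k-mers\n")
    cat("  classes:", paste(x$classes, collapse = ", "), "\n")
    invisible(x)
}

#' Query the class sets of k-mer words
#'
#' @param index A `FeatureIndex`.
#' @param words Character vector of length-k words.
#' @return List of character vectors: the feature classes containing each
#'   word (empty when absent from the index).
#' @export
query_kmer_classes <- function(index, words) {
    stopifnot(inherits(index, "FeatureIndex"))
    hits <- .kmer_index_query(.index_ptr(index), as.character(words))
    lapply(hits, function(h) index$classes[h])
}

#' Assign reads to feature classes by unique k-mer membership
#'
#' For each read, all distinct k-mers present in the index are collected.
#' A read is `assigned` to class c when every matched k-mer maps only to c
#' and at least `min_hits` distinct k-mers match; reads whose matches span
#' two or more classes are `ambiguous`, except that a read touching exactly
#' one isoform-specific class plus common (non-specific) classes is assigned
#' to the specific class when it carries at least `min_hits` k-mers unique
#' to it (junction rule, favoring isoform evidence). Reads with no matching
#' k-mer — or matching fewer than `min_hits` k-mers of a single class — are
#' `unassigned`; reads shorter than k are unassigned with zero hits.
#'
#' @param index A `FeatureIndex`.
#' @param reads Character vector (or `DNAStringSet`) of read sequences.
#' @param min_hits Minimum number of distinct matching k-mers required for
#'   assignment (default 2, suppressing single-k-mer error hits).
#' @return data.frame with columns `read` (names or index), `outcome`
#'   (factor: unassigned/assigned/ambiguous), `class` (assigned class or NA)
#'   and `n_hits` (distinct matched k-mers).
#' @export
assign_reads <- function(index, reads, min_hits = 2L) {
    stopifnot(inherits(index, "FeatureIndex"))
    if (methods::is(reads, "DNAStringSet")) reads <- as.character(reads)
    ids <- names(reads)
    if (is.null(ids)) ids <- as.character(seq_along(reads))
    spec_mask <- sum(2^(match(index$specific, index$classes) - 1L))
    res <- .assign_reads_cpp(.index_ptr(index), unname(reads),
                             as.integer(min_hits), spec_mask)
    data.frame(
        read = ids,
        outcome = factor(c("unassigned", "assigned", "ambiguous")[res$outcome + 1L],
                         levels = c("unassigned", "assigned", "ambiguous")),
        class = ifelse(is.na(res$class), NA_character_,
                       index$classes[res$class]),
        n_hits = res$n_hits,
        stringsAsFactors = FALSE
    )
}

#' Assign a single read
#'
#' Convenience wrapper around [assign_reads()] for one read.
#'
#' @inheritParams assign_reads
#' @param read Single read sequence.
#' @return One-row data.frame as in [assign_reads()].
#' @export
assign_read <- function(read, index, min_hits = 2L) {
    assign_reads(index, read, min_hits = min_hits)
}
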