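#' Counts per million
#'
#' `count / library_size * 1e6`. The denominator is the total number of
#' reads in the sample's library (not the number of assigned reads), which
#' stays well-defined for small feature sets.
#'
#' @param count Read count(s).
#' @param library_size Total reads in the library (> 0).
#' @return CPM value(s).
#' @export
cpm <- function(count, library_size) {
    if (any(library_size <= 0)) stop("library size must be > 0")
    count / library_size * 1e6
}

#' Effective feature length
#'
#' Number of read start positions a feature admits:
#' `length - read_length + 1`, floored at 1.
#'
#' @param length Feature length(s) in bases.
#' @param read_length Read length in bases.
#' @return Effective length(s).
#' @export
effective_length <- function(length, read_length) {
    pmax(length - read_length + 1, 1)
}

#' Transcripts per million
#'
#' Length-normalized read rates rescaled to sum to 1e6 over the quantified
#' feature set: `rate_f = count_f / effective_length_f`,
#' `TPM_f = rate_f / sum(rate) * 1e6`.
#'
#' @param counts Named non-negative counts per feature.
#' @param effective_lengths Positive effective lengths per feature (same
#'   order/names).
#' @return Named TPM vector summing to 1e6 (all zero, with a warning, when
#'   all counts are zero).
#' @export
tpm <- function(counts, effective_lengths) {
    stopifnot(length(counts) == length(effective_lengths))
    if (any(effective_lengths <= 0)) stop("effective lengths must be > 0")
    rate <- counts / effective_lengths
    total <- sum(rate)
    if (total == 0) {
        warning("all counts zero; TPM undefined, returning zeros")
        return(setNames(rep(0, length(counts)), names(counts)))
    }
    setNames(rate / total * 1e6, names(counts))
}

#' Quantify one sample against a feature index
#'
#' Assigns every read with [assign_reads()] and tallies assigned reads per
#' feature class; ambiguous and unassigned reads are tallied separately and
#' excluded from all feature counts. Library size is the total number of
#' input reads.
#'
#' @param reads Character vector / `DNAStringSet` of read sequences (may be
#'   empty).
#' @param index A `FeatureIndex`.
#' @param min_hits Minimum distinct matching k-mers for assignment.
#' @param assignments If TRUE, also return the per-read assignment table.
#' @return List with `counts` (named integer per class), `ambiguous`,
#'   `unassigned`, `library_size`, and optionally `assignments`.
#' @export
quantify_sample <- function(reads, index, min_hits = 2L,
                            assignments = FALSE) {
    stopifnot(inherits(index, "FeatureIndex"))
    n <- length(reads)
    if (n == 0L) {
        out <- list(counts = setNames(integer(length(index$classes)),
                                      index$classes),
                    ambiguous = 0L, unassigned = 0L, library_size = 0L)
        if (assignments) out$assignments <- data.frame(
            read = character(0), outcome = factor(character(0),
                levels = c("unassigned", "assigned", "ambiguous")),
            class = character(0), n_hits = integer(0))
        return(out)
    }
    asg <- assign_reads(index, reads, min_hits = min_hits)
    tab <- table(factor(asg$class[asg$outcome == "assigned"],
                        levels = index$classes))
    out <- list(counts = setNames(as.integer(tab), index$classes),
                ambiguous = sum(asg$outcome == "ambiguous"),
                unassigned = sum(asg$outcome == "unassigned"),
                library_size = n)
    if (assignments) out$assignments <- asg
    out
}

#' Whole-gene quantification
#'
#' Builds (or reuses) a single-class index covering the union of all exons
#' of all isoforms of a gene and counts reads against it — the standard
#' whole-gene reference that cannot separate promoter isoforms, used to
#' demonstrate how total-gene counts mask an isoform switch.
#'
#' @param reads Read sequences.
#' @param index A single-class `FeatureIndex` over all exons of the gene
#'   (e.g. from [build_study_indices()]).
#' @param min_hits Minimum distinct matching k-mers.
#' @return As [quantify_sample()].
#' @export
whole_gene_quantify <- function(reads, index, min_hits = 2L) {
    stopifnot(inherits(index, "FeatureIndex"))
    if (length(index$classes) != 1L)
        stop("whole-gene index must have exactly one class")
    quantify_sample(reads, index, min_hits = min_hits)
}

#' Build the study's feature indices from a fixture
#'
#' Returns the isoform-resolved index (classes: the isoform-specific exon
#' sets, the common exons, and each housekeeping gene) and the whole-gene
#' index (one class over the union of all target-gene exons). Isoform-1's
#' four specific exons enter the index as separate-but-co-classed records.
#'
#' @param fixture A [make_study_fixture()] result.
#' @param k k-mer length.
#' @return List with `isoform` and `whole_gene` `FeatureIndex` objects.
#' @export
build_study_indices <- function(fixture, k = 21L) {
    stopifnot(inherits(fixture, "StudyFixture"))
    feats <- fixture$features
    recs <- extract_feature_sequences(
        fixture$genome,
        data.frame(feature_id = feats$record, chrom = feats$chrom,
                   start = feats$start, end = feats$end,
                   strand = feats$strand, stringsAsFactors = FALSE))
    iso_index <- build_feature_index(
        recs, classes = feats$class, k = k,
        specific = c("iso1_specific", "iso2_specific"))
    target <- feats[feats$class %in% c("iso1_specific", "iso2_specific",
                                       "common"), ]
    wg_recs <- extract_feature_sequences(
        fixture$genome,
        data.frame(feature_id = target$record, chrom = target$chrom,
                   start = target$start, end = target$end,
                   strand = target$strand, stringsAsFactors = FALSE))
    wg_index <- build_feature_index(wg_recs,
                                    classes = rep("tgene_whole", nrow(target)),
                                    k = k, specific = character(0))
    list(isoform = iso_index, whole_gene = wg_index)
}

#' Quantify every sample of a study fixture
#'
#' Runs the full quantification stage: per sample, simulate the reads,
#' assign them against the isoform-resolved index and the whole-gene index,
#' and collect counts and CPM values. Reads are generated and discarded one
#' sample at a time.
#'
#' @param fixture A [make_study_fixture()] result.
#' @param k k-mer length for the indices.
#' @param min_hits Minimum distinct matching k-mers for assignment.
#' @param keep_truth If TRUE (default), per-sample true counts are retained.
#' @param verbose Print one progress line per sample.
#' @return A `StudyQuantification` list: `counts` (long data.frame: sample,
#'   class, count, library_size), `cpm` (matrix, feature classes x samples,
#'   whole-gene class included as its own row), `samples` (the fixture's
#'   sample design), `ambiguous`/`unassigned` per sample, `true_counts`
#'   (matrix of simulated per-transcript read counts), and `indices`.
#' @export
quantify_study <- function(fixture, k = 21L, min_hits = 2L,
                           keep_truth = TRUE, verbose = FALSE) {
    stopifnot(inherits(fixture, "StudyFixture"))
    idx <- build_study_indices(fixture, k = k)
    classes <- idx$isoform$classes
    samples <- fixture$samples$sample
    cpm_mat <- matrix(0, nrow = length(classes) + 1L, ncol = length(samples),
                      dimnames = list(c(classes, "tgene_whole"), samples))
    counts_long <- vector("list", length(samples))
    ambiguous <- unassigned <- setNames(integer(length(samples)), samples)
    true_counts <- NULL
    for (i in seq_along(samples)) {
        sm <- samples[i]
        sim <- simulate_sample_reads(fixture, sm)
        qi <- quantify_sample(sim$reads, idx$isoform, min_hits = min_hits)
        qw <- whole_gene_quantify(sim$reads, idx$whole_gene,
                                  min_hits = min_hits)
        lib <- qi$library_size
        counts_long[[i]] <- data.frame(
            sample = sm, class = c(classes, "tgene_whole"),
            count = c(qi$counts, qw$counts), library_size = lib,
            stringsAsFactors = FALSE)
        cpm_mat[, i] <- if (lib > 0)
            cpm(c(qi$counts, qw$counts), lib) else 0
        ambiguous[i] <- qi$ambiguous
        unassigned[i] <- qi$unassigned
        if (keep_truth) {
            if (is.null(true_counts))
                true_counts <- matrix(0L, nrow = length(sim$counts),
                                      ncol = length(samples),
                                      dimnames = list(names(sim$counts),
                                                      samples))
            true_counts[names(sim$counts), i] <- sim$counts
        }
        if (verbose)
            message(sprintf("%s: %d reads, %d assigned isoform-resolved",
                            sm, lib, sum(qi$counts)))
    }
    structure(list(
        counts = do.call(rbind, counts_long), cpm = cpm_mat,
        samples = fixture$samples, ambiguous = ambiguous,
        unassigned = unassigned, true_counts = true_counts,
        indices = idx, min_hits = min_hits
    ), class = "StudyQuantification")
}
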