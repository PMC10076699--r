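# Shared fixtures and independent brute-force oracles.

# Minimal two-isoform GTF mirroring the study gene structure: isoform 1 with
# four specific 5' exons, isoform 2 with one, five shared 3' exons.
thrb_like_gtf <- function() {
    ex <- function(start1, end1, tx, iso) {
        sprintf(paste0("chr1\ttest\texon\t%d\t%d\t.\t+\t.\t",
                       'gene_id "g1"; transcript_id "%s"; isoform "%s";'),
                start1, end1, tx, iso)
    }
    shared <- list(c(12001, 12300), c(12601, 12880), c(13201, 13490),
                   c(13901, 14230), c(14501, 14753))
    c(
        ex(1001, 1180, "t1", "iso1"), ex(2001, 2120, "t1", "iso1"),
        ex(3001, 3090, "t1", "iso1"), ex(4001, 4093, "t1", "iso1"),
        vapply(shared, function(s) ex(s[1], s[2], "t1", "iso1"), character(1)),
        ex(5001, 5378, "t2", "iso2"),
        vapply(shared, function(s) ex(s[1], s[2], "t2", "iso2"), character(1))
    )
}

# Brute-force longest-ORF oracle: enumerate every ATG, scan codons for the
# first in-frame stop, translate by direct genetic-code lookup.
bf_longest_orf <- function(s) {
    s <- toupper(s)
    n <- nchar(s)
    stops <- c("TAA", "TAG", "TGA")
    best_len <- -1L
    best_start <- NA_integer_
    best_end <- NA_integer_
    p <- 1L
    while (p + 2L <= n) {
        if (substr(s, p, p + 2L) == "ATG") {
            q <- p
            found <- FALSE
            repeat {
                q <- q + 3L
                if (q + 2L > n) break
                if (substr(s, q, q + 2L) %in% stops) { found <- TRUE; break }
            }
            if (found) {
                len <- (q - p) %/% 3L
                if (len > best_len) {
                    best_len <- len; best_start <- p; best_end <- q
                }
            }
        }
        p <- p + 1L
    }
    if (best_len < 0L)
        return(list(found = FALSE, protein = "", n_residues = 0L))
    gc <- Biostrings::GENETIC_CODE
    codons <- substring(s, seq(best_start, best_end - 3L, by = 3L),
                        seq(best_start + 2L, best_end - 1L, by = 3L))
    aa <- unname(gc[codons])
    aa[is.na(aa)] <- "X"
    list(found = TRUE, protein = paste(aa, collapse = ""),
         n_residues = best_len, start = best_start - 1L)
}

# Brute-force read assignment over index records by substring enumeration
# (independent of the packed-hash implementation): applies the documented
# rule — single-class reads need >= min_hits distinct matching k-mers; reads
# spanning one specific class plus non-specific classes are assigned to the
# specific class when it has >= min_hits unique k-mers; anything else
# spanning two classes is ambiguous.
bf_assign_read <- function(read, records, record_classes, k, min_hits,
                           specific) {
    if (nchar(read) < k)
        return(list(outcome = "unassigned", class = NA_character_, n_hits = 0L))
    kmers_of <- function(s) {
        n <- nchar(s)
        if (n < k) return(character(0))
        w <- substring(s, 1:(n - k + 1), k:n)
        w[!grepl("[^ACGT]", w)]
    }
    class_kmers <- lapply(split(seq_along(records), record_classes),
                          function(ix) unique(unlist(lapply(records[ix],
                                                            kmers_of))))
    rk <- unique(kmers_of(read))
    hit_classes <- lapply(rk, function(w)
        names(class_kmers)[vapply(class_kmers, function(ck) w %in% ck,
                                  logical(1))])
    matched <- lengths(hit_classes) > 0
    n_hits <- sum(matched)
    if (n_hits == 0L)
        return(list(outcome = "unassigned", class = NA_character_,
                    n_hits = 0L))
    union_classes <- unique(unlist(hit_classes[matched]))
    uniq_counts <- table(unlist(hit_classes[matched][
        lengths(hit_classes[matched]) == 1L]))
    if (length(union_classes) == 1L) {
        c1 <- union_classes
        nh <- if (c1 %in% names(uniq_counts)) uniq_counts[[c1]] else 0L
        if (nh >= min_hits)
            return(list(outcome = "assigned", class = c1, n_hits = n_hits))
        return(list(outcome = "unassigned", class = NA_character_,
                    n_hits = n_hits))
    }
    spec_in <- intersect(union_classes, specific)
    if (length(spec_in) == 1L) {
        nh <- if (spec_in %in% names(uniq_counts)) uniq_counts[[spec_in]] else 0L
        if (nh >= min_hits)
            return(list(outcome = "assigned", class = spec_in,
                        n_hits = n_hits))
    }
    list(outcome = "ambiguous", class = NA_character_, n_hits = n_hits)
}

# Small deterministic random DNA helper for tests
rand_dna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A small three-class index fixture (two specific classes + common) with
# known record sequences.
small_index_fixture <- function(seed = 42, k = 21) {
    withr::with_seed(seed, {
        recs <- c(specA = rand_dna(120), specB = rand_dna(130),
                  common1 = rand_dna(140), common2 = rand_dna(110))
        classes <- c("specA", "specB", "common", "common")
        idx <- build_feature_index(recs, classes, k = k,
                                   specific = c("specA", "specB"))
        list(records = recs, classes = classes, index = idx, k = k)
    })
}
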