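#' Parametric developmental expression trajectory
#'
#' Three shapes cover the study design: `early_peak` is a Gaussian bump
#' `A * exp(-(t - t0)^2 / (2 sigma^2))` (embryonic-high isoform that declines
#' postnatally), `late_plateau` is a logistic rise `A / (1 + exp(-(t - t50)/s))`
#' (postnatal isoform that plateaus), and `constant` returns `A`
#' (housekeeping genes). Ages `t` are in postnatal days (embryonic ages map
#' to negative values).
#'
#' @param shape One of "early_peak", "late_plateau", "constant".
#' @param A Amplitude, expression units (CPM scale); A >= 0.
#' @param t0 Peak age (early_peak).
#' @param sigma Peak width in age units, > 0 (early_peak).
#' @param t50 Midpoint age (late_plateau).
#' @param s Rise slope in age units, > 0 (late_plateau).
#' @return A `TrajectorySpec` object.
#' @export
trajectory_spec <- function(shape = c("early_peak", "late_plateau", "constant"),
                            A, t0 = NULL, sigma = NULL, t50 = NULL, s = NULL) {
    shape <- match.arg(shape)
    stopifnot(is.numeric(A), A >= 0)
    if (shape == "early_peak") {
        stopifnot(is.numeric(t0), is.numeric(sigma), sigma > 0)
    } else if (shape == "late_plateau") {
        stopifnot(is.numeric(t50), is.numeric(s), s > 0)
    }
    structure(list(shape = shape, A = A, t0 = t0, sigma = sigma,
                   t50 = t50, s = s), class = "TrajectorySpec")
}

#' Evaluate a trajectory at given ages
#'
#' @param spec A [trajectory_spec()].
#' @param t Numeric vector of ages.
#' @return Expected expression at each age (same length as `t`).
#' @export
trajectory_value <- function(spec, t) {
    stopifnot(inherits(spec, "TrajectorySpec"))
    switch(spec$shape,
        early_peak = spec$A * exp(-(t - spec$t0)^2 / (2 * spec$sigma^2)),
        late_plateau = spec$A / (1 + exp(-(t - spec$t50) / spec$s)),
        constant = rep(spec$A, length(t))
    )
}

#' Age at which two trajectories cross
#'
#' Finds the age where a rising trajectory first equals a falling one, by
#' root-finding on their difference over the given interval.
#'
#' @param rising,falling [trajectory_spec()] objects.
#' @param interval Numeric length-2 search interval (ages).
#' @return The crossing age, or NA when no sign change exists in the interval.
#' @export
trajectory_crossing <- function(rising, falling, interval) {
    f <- function(t) trajectory_value(rising, t) - trajectory_value(falling, t)
    lo <- f(interval[1]); hi <- f(interval[2])
    if (is.na(lo) || is.na(hi) || sign(lo) == sign(hi)) return(NA_real_)
    stats::uniroot(f, interval, tol = 1e-8)$root
}

#' Default developmental ages
#'
#' Twelve retinal ages from embryonic day 14 to postnatal day 60, mapped to
#' numeric positions on a postnatal-day axis (E14 -> -5, E17 -> -2, P1 -> 1,
#' ..., P60 -> 60).
#'
#' @return Named numeric vector of age positions.
#' @export
default_ages <- function() {
    c(E14 = -5, E17 = -2, P1 = 1, P3 = 3, P6 = 6, P10 = 10,
      P14 = 14, P17 = 17, P21 = 21, P28 = 28, P45 = 45, P60 = 60)
}

#' Simulation configuration
#'
#' Study-scale defaults: 12 developmental ages with 3 replicates each,
#' 200,000 single-end 50-base reads per sample (a desk-scale stand-in for
#' deep sequencing), per-base substitution error rate 0.001,
#' negative-binomial overdispersion 0.05, an embryonic-peaking isoform-2
#' trajectory, a postnatally plateauing isoform-1 trajectory, and six
#' constant housekeeping genes.
#'
#' @param ages Named numeric vector of age positions (labels are group
#'   names).
#' @param replicates Replicates per age (>= 1).
#' @param reads_per_sample Target read depth per sample.
#' @param read_length Read length in bases.
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param dispersion Negative-binomial overdispersion of transcript counts
#'   (0 gives Poisson noise).
#' @param seed Master seed; all randomness in the fixture flows from it.
#' @param iso1,iso2 [trajectory_spec()] for the two promoter isoforms.
#' @param housekeeping Named numeric vector of constant housekeeping
#'   expression levels.
#' @return A `SimulationConfig` list.
#' @export
sim_config <- function(ages = default_ages(),
                       replicates = 3L,
                       reads_per_sample = 200000L,
                       read_length = 50L,
                       error_rate = 0.001,
                       dispersion = 0.05,
                       seed = 1L,
                       iso1 = trajectory_spec("late_plateau", A = 50,
                                              t50 = 8, s = 3),
                       iso2 = trajectory_spec("early_peak", A = 60,
                                              t0 = -5, sigma = 8),
                       housekeeping = c(hk1 = 150, hk2 = 220, hk3 = 300,
                                        hk4 = 180, hk5 = 260, hk6 = 120)) {
    stopifnot(replicates >= 1L, read_length >= 1L,
              error_rate >= 0, error_rate < 1, dispersion >= 0,
              length(ages) >= 1L, !is.null(names(ages)))
    structure(list(ages = ages, replicates = as.integer(replicates),
                   reads_per_sample = as.integer(reads_per_sample),
                   read_length = as.integer(read_length),
                   error_rate = error_rate, dispersion = dispersion,
                   seed = as.integer(seed), iso1 = iso1, iso2 = iso2,
                   housekeeping = housekeeping),
              class = "SimulationConfig")
}

.random_dna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# UTR sequence free of ATG trinucleotides, first and last base fixed to C so
# that no ATG can arise across exon junctions either
.random_utr <- function(n) {
    s <- .random_dna(n)
    while (grepl("ATG", s, fixed = TRUE))
        s <- gsub("ATG", "ACG", s, fixed = TRUE)
    if (n >= 2) {
        substr(s, 1L, 1L) <- "C"
        substr(s, n, n) <- "C"
    }
    s
}

.STOPS <- c("TAA", "TAG", "TGA")

# n_codons sense codons with no stop codon
.random_cds <- function(n_codons) {
    all64 <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                   paste0), c("A", "C", "G", "T"), paste0))
    sense <- setdiff(all64, .STOPS)
    paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

#' Draw per-transcript read counts for one sample
#'
#' Counts are negative-binomial with mean proportional to
#' `expected * length` (depth-normalized so means sum to `depth`); a
#' dispersion of 0 gives Poisson draws. Transcripts with zero expected
#' expression always get zero counts. A fixed seed reproduces the draw
#' exactly.
#'
#' @param expected Non-negative expected expression per transcript.
#' @param lengths Per-transcript (effective) lengths in bases, used to weight
#'   read counts.
#' @param depth Total expected reads for the sample.
#' @param dispersion Negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2); 0 = Poisson.
#' @param seed Optional integer seed (RNG state restored afterwards).
#' @return Integer vector of read counts, named like `expected`.
#' @export
simulate_sample_counts <- function(expected, lengths, depth,
                                   dispersion = 0.05, seed = NULL) {
    stopifnot(length(expected) == length(lengths), all(expected >= 0),
              all(lengths > 0))
    draw <- function() {
        w <- expected * lengths
        if (sum(w) == 0) return(setNames(integer(length(w)), names(expected)))
        mu <- depth * w / sum(w)
        counts <- if (dispersion > 0) {
            rnbinom(length(mu), mu = mu, size = 1 / dispersion)
        } else {
            rpois(length(mu), mu)
        }
        counts[expected == 0] <- 0L
        setNames(as.integer(counts), names(expected))
    }
    if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate single-end reads from transcript sequences
#'
#' Each transcript emits the requested number of reads with uniformly random
#' start positions such that the full read length fits; per-base substitution
#' errors are applied at the configured rate; all reads share a constant
#' quality string (Phred 40, "I"). A truth table records each read's source
#' transcript and 0-based start position.
#'
#' @param transcripts `DNAStringSet` or named character vector of transcript
#'   (sense) sequences.
#' @param counts Named integer vector of reads per transcript.
#' @param read_length Read length in bases.
#' @param error_rate Per-base substitution probability.
#' @param seed Optional integer seed.
#' @param id_prefix Prefix for generated read ids.
#' @return List with `reads` (named character vector), `truth` (data.frame:
#'   read_id, transcript_id, pos) and `quality` (the constant quality
#'   string).
#' @export
simulate_reads <- function(transcripts, counts, read_length = 50L,
                           error_rate = 0, seed = NULL, id_prefix = "r") {
    if (methods::is(transcripts, "DNAStringSet"))
        transcripts <- setNames(as.character(transcripts), names(transcripts))
    stopifnot(!is.null(names(counts)), all(names(counts) %in% names(transcripts)))
    active <- names(counts)[counts > 0]
    short <- active[nchar(transcripts[active]) < read_length]
    if (length(short) > 0)
        stop("transcript shorter than read length: ",
             paste(short, collapse = ", "))
    gen <- function() {
        seqs <- character(0)
        src <- character(0)
        pos <- integer(0)
        for (tx in active) {
            L <- nchar(transcripts[[tx]])
            n <- counts[[tx]]
            starts0 <- sample.int(L - read_length + 1L, n, replace = TRUE) - 1L
            seqs <- c(seqs, substring(transcripts[[tx]], starts0 + 1L,
                                      starts0 + read_length))
            src <- c(src, rep(tx, n))
            pos <- c(pos, starts0)
        }
        seqs <- .inject_errors(seqs, read_length, error_rate)
        ids <- sprintf("%s%06d", id_prefix, seq_along(seqs))
        list(reads = setNames(seqs, ids),
             truth = data.frame(read_id = ids, transcript_id = src, pos = pos,
                                stringsAsFactors = FALSE),
             quality = strrep("I", read_length))
    }
    if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

.inject_errors <- function(reads, read_length, rate) {
    if (rate <= 0 || length(reads) == 0) return(reads)
    nerr <- rbinom(length(reads), read_length, rate)
    bases <- c("A", "C", "G", "T")
    for (i in which(nerr > 0)) {
        r <- strsplit(reads[i], "", fixed = TRUE)[[1]]
        for (p in sample.int(read_length, nerr[i]))
            r[p] <- sample(setdiff(bases, r[p]), 1)
        reads[i] <- paste(r, collapse = "")
    }
    reads
}

# Genomic layout of the toy study locus (0-based half-open, plus strand).
# Two-isoform target gene on chrT: isoform 1 has four specific 5' exons
# (two non-coding, two coding), isoform 2 a single specific exon; both share
# five common 3' exons lying > 6 kb downstream of the specific exons. The
# isoform cDNAs are built to encode proteins of 461 (isoform 1) and 476
# (isoform 2) residues. Six housekeeping genes sit on chrH (hk6 on the minus
# strand).
.fixture_layout <- function() {
    iso1 <- data.frame(
        exon = c("iso1_e1", "iso1_e2", "iso1_e3", "iso1_e4"),
        start = c(1000L, 2000L, 3000L, 4000L),
        end = c(1180L, 2120L, 3090L, 4093L),
        kind = c("utr", "utr", "cds", "cds"),
        stringsAsFactors = FALSE
    )
    iso2 <- data.frame(exon = "iso2_e1", start = 5000L, end = 5378L,
                       kind = "mixed", stringsAsFactors = FALSE)
    common <- data.frame(
        exon = paste0("common_e", 1:5),
        start = c(12000L, 12600L, 13200L, 13900L, 14500L),
        end = c(12300L, 12880L, 13490L, 14230L, 14753L),
        stringsAsFactors = FALSE
    )
    hk <- data.frame(
        gene = paste0("hk", 1:6),
        start = c(1000L, 4000L, 7000L, 10000L, 13000L, 16000L),
        end = c(2000L, 5000L, 8000L, 11000L, 14000L, 17000L),
        strand = c("+", "+", "+", "+", "+", "-"),
        stringsAsFactors = FALSE
    )
    list(iso1 = iso1, iso2 = iso2, common = common, hk = hk,
         chrT_len = 16000L, chrH_len = 18000L,
         iso2_utr = 150L, # iso2 exon = 150 nt UTR + 228 nt CDS
         common_cds = 1200L) # then TAA stop, then 250 nt 3' UTR
}

#' Generate the toy two-isoform study fixture
#'
#' Builds a deterministic desk-scale emulation of the study design: a toy
#' genome carrying a two-isoform target gene (four isoform-1-specific 5'
#' exons, one isoform-2-specific exon, shared common 3' exons more than
#' 6 kb downstream) plus constant housekeeping genes; a GTF annotation;
#' biphasic expression trajectories (early-peaking isoform 2,
#' late-plateauing isoform 1); and per-sample expected read fractions.
#' The two isoform cDNAs encode open reading frames of 461 and 476
#' residues, mirroring the reported isoform protein lengths. Reads for a
#' sample are generated on demand by [simulate_sample_reads()] so the
#' fixture itself stays small.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, writes `genome.fa`,
#'   `annotation.gtf`, `truth_expected.tsv` and `config.json` there.
#' @return A `StudyFixture` list: `config`, `genome` (DNAStringSet), `gtf`
#'   (character lines), `gene` (GeneModel of the target gene), `features`
#'   (data.frame of index records: record, class, chrom, start, end,
#'   strand), `transcripts` (DNAStringSet of all mRNAs), `samples`
#'   (data.frame: sample, age_label, age, replicate, seed), `truth`
#'   (data.frame of per-sample expected expression and read fractions per
#'   transcript) and `trajectories`.
#' @export
make_study_fixture <- function(config = sim_config(), out_dir = NULL) {
    stopifnot(inherits(config, "SimulationConfig"))
    lay <- .fixture_layout()
    built <- withr::with_seed(config$seed, {
        # designed transcript pieces
        utr1a <- .random_utr(1180L - 1000L)
        utr1b <- .random_utr(2120L - 2000L)
        cds1 <- paste0("ATG", .random_cds((90L + 93L) / 3L - 1L))
        utr2 <- .random_utr(lay$iso2_utr)
        cds2 <- paste0("ATG", .random_cds((5378L - 5000L - lay$iso2_utr) / 3L - 1L))
        cds_common <- .random_cds(lay$common_cds / 3L)
        utr3p <- .random_utr(sum(lay$common$end - lay$common$start) -
                             lay$common_cds - 3L)
        common_seq <- paste0(cds_common, "TAA", utr3p)
        chrT <- .random_dna(lay$chrT_len)
        put <- function(chrom, start, end, s) {
            stopifnot(nchar(s) == end - start)
            substr(chrom, start + 1L, end) <- s
            chrom
        }
        chrT <- put(chrT, 1000L, 1180L, utr1a)
        chrT <- put(chrT, 2000L, 2120L, utr1b)
        chrT <- put(chrT, 3000L, 3090L, substr(cds1, 1L, 90L))
        chrT <- put(chrT, 4000L, 4093L, substr(cds1, 91L, 183L))
        chrT <- put(chrT, 5000L, 5378L, paste0(utr2, cds2))
        off <- 0L
        for (i in seq_len(nrow(lay$common))) {
            w <- lay$common$end[i] - lay$common$start[i]
            chrT <- put(chrT, lay$common$start[i], lay$common$end[i],
                        substr(common_seq, off + 1L, off + w))
            off <- off + w
        }
        hk_tx <- vapply(seq_len(nrow(lay$hk)), function(i) {
            .random_dna(lay$hk$end[i] - lay$hk$start[i])
        }, character(1))
        names(hk_tx) <- lay$hk$gene
        chrH <- .random_dna(lay$chrH_len)
        for (i in seq_len(nrow(lay$hk))) {
            genomic <- if (lay$hk$strand[i] == "-") {
                as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(hk_tx[i])))
            } else hk_tx[i]
            chrH <- put(chrH, lay$hk$start[i], lay$hk$end[i], genomic)
        }
        n_samples <- length(config$ages) * config$replicates
        sample_seeds <- sample.int(2147483000L, n_samples)
        list(chrT = chrT, chrH = chrH, hk_tx = hk_tx,
             sample_seeds = sample_seeds)
    })

    genome <- Biostrings::DNAStringSet(c(chrT = built$chrT, chrH = built$chrH))
    gtf <- .fixture_gtf(lay)
    gene <- parse_gene_annotation(gtf)[["tgene"]]

    features <- rbind(
        data.frame(record = lay$iso1$exon, class = "iso1_specific",
                   chrom = "chrT", start = lay$iso1$start,
                   end = lay$iso1$end, strand = "+",
                   stringsAsFactors = FALSE),
        data.frame(record = lay$iso2$exon, class = "iso2_specific",
                   chrom = "chrT", start = lay$iso2$start,
                   end = lay$iso2$end, strand = "+",
                   stringsAsFactors = FALSE),
        data.frame(record = lay$common$exon, class = "common",
                   chrom = "chrT", start = lay$common$start,
                   end = lay$common$end, strand = "+",
                   stringsAsFactors = FALSE),
        data.frame(record = lay$hk$gene, class = lay$hk$gene,
                   chrom = "chrH", start = lay$hk$start, end = lay$hk$end,
                   strand = lay$hk$strand, stringsAsFactors = FALSE)
    )

    tx_feats <- rbind(
        data.frame(feature_id = "tgene_iso1", chrom = "chrT",
                   start = c(lay$iso1$start, lay$common$start),
                   end = c(lay$iso1$end, lay$common$end), strand = "+",
                   stringsAsFactors = FALSE),
        data.frame(feature_id = "tgene_iso2", chrom = "chrT",
                   start = c(lay$iso2$start, lay$common$start),
                   end = c(lay$iso2$end, lay$common$end), strand = "+",
                   stringsAsFactors = FALSE),
        data.frame(feature_id = lay$hk$gene, chrom = "chrH",
                   start = lay$hk$start, end = lay$hk$end,
                   strand = lay$hk$strand, stringsAsFactors = FALSE)
    )
    transcripts <- extract_feature_sequences(genome, tx_feats)

    ages <- config$ages
    samples <- data.frame(
        sample = paste0(rep(names(ages), each = config$replicates), "_r",
                        rep(seq_len(config$replicates), length(ages))),
        age_label = rep(names(ages), each = config$replicates),
        age = rep(unname(ages), each = config$replicates),
        replicate = rep(seq_len(config$replicates), length(ages)),
        seed = built$sample_seeds,
        stringsAsFactors = FALSE
    )

    trajectories <- c(list(tgene_iso1 = config$iso1, tgene_iso2 = config$iso2),
                      lapply(config$housekeeping, function(a)
                          trajectory_spec("constant", A = a)))
    tx_names <- names(transcripts)
    eff_len <- pmax(Biostrings::width(transcripts) - config$read_length + 1L, 1L)
    names(eff_len) <- tx_names
    truth <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i) {
        expr <- vapply(tx_names, function(tx)
            trajectory_value(trajectories[[tx]], samples$age[i]), numeric(1))
        w <- expr * eff_len[tx_names]
        frac <- if (sum(w) > 0) w / sum(w) else w
        data.frame(sample = samples$sample[i], transcript_id = tx_names,
                   expected_expression = unname(expr),
                   true_fraction = unname(frac), stringsAsFactors = FALSE)
    }))

    fixture <- structure(list(
        config = config, genome = genome, gtf = gtf, gene = gene,
        features = features, transcripts = transcripts,
        effective_lengths = eff_len, samples = samples, truth = truth,
        trajectories = trajectories
    ), class = "StudyFixture")

    if (!is.null(out_dir)) {
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        Biostrings::writeXStringSet(genome, file.path(out_dir, "genome.fa"))
        writeLines(gtf, file.path(out_dir, "annotation.gtf"))
        write_tsv(truth, file.path(out_dir, "truth_expected.tsv"),
                  provenance = c(paste("seed:", config$seed)))
        jsonlite::write_json(
            list(ages = as.list(ages), replicates = config$replicates,
                 reads_per_sample = config$reads_per_sample,
                 read_length = config$read_length,
                 error_rate = config$error_rate,
                 dispersion = config$dispersion, seed = config$seed),
            file.path(out_dir, "config.json"), auto_unbox = TRUE, digits = NA)
    }
    fixture
}

.fixture_gtf <- function(lay) {
    attr_str <- function(gene, tx = NULL, iso = NULL) {
        a <- sprintf('gene_id "%s";', gene)
        if (!is.null(tx)) a <- paste(a, sprintf('transcript_id "%s";', tx))
        if (!is.null(iso)) a <- paste(a, sprintf('isoform "%s";', iso))
        a
    }
    line <- function(chrom, type, start0, end0, strand, attrs) {
        paste(chrom, "isoswitchr", type, start0 + 1L, end0, ".", strand, ".",
              attrs, sep = "\t")
    }
    out <- character(0)
    # target gene: exon lines 1-based inclusive in the GTF
    tg_span <- c(min(lay$iso1$start), max(lay$common$end))
    out <- c(out, line("chrT", "gene", tg_span[1], tg_span[2], "+",
                       attr_str("tgene")))
    for (tx in c("tgene_iso1", "tgene_iso2")) {
        iso <- if (tx == "tgene_iso1") "iso1" else "iso2"
        ex <- if (tx == "tgene_iso1") {
            rbind(lay$iso1[, c("start", "end")], lay$common[, c("start", "end")])
        } else {
            rbind(lay$iso2[, c("start", "end")], lay$common[, c("start", "end")])
        }
        out <- c(out, line("chrT", "transcript", min(ex$start), max(ex$end),
                           "+", attr_str("tgene", tx, iso)))
        for (i in seq_len(nrow(ex)))
            out <- c(out, line("chrT", "exon", ex$start[i], ex$end[i], "+",
                               attr_str("tgene", tx, iso)))
    }
    for (i in seq_len(nrow(lay$hk))) {
        g <- lay$hk$gene[i]
        st <- lay$hk$strand[i]
        out <- c(out, line("chrH", "gene", lay$hk$start[i], lay$hk$end[i], st,
                           attr_str(g)))
        out <- c(out, line("chrH", "transcript", lay$hk$start[i],
                           lay$hk$end[i], st, attr_str(g, paste0(g, "_t1"))))
        out <- c(out, line("chrH", "exon", lay$hk$start[i], lay$hk$end[i], st,
                           attr_str(g, paste0(g, "_t1"))))
    }
    out
}

#' Simulate the reads of one fixture sample
#'
#' Draws per-transcript counts (negative binomial, seeded per sample from
#' the fixture's master seed) and emits the sample's reads with a truth
#' table. Deterministic per sample: the same fixture yields byte-identical
#' reads on rerun.
#'
#' @param fixture A [make_study_fixture()] result.
#' @param sample_id One of `fixture$samples$sample`.
#' @return As [simulate_reads()], plus `counts` (true per-transcript read
#'   counts).
#' @export
simulate_sample_reads <- function(fixture, sample_id) {
    stopifnot(inherits(fixture, "StudyFixture"))
    row <- fixture$samples[fixture$samples$sample == sample_id, ]
    if (nrow(row) != 1L) stop("unknown sample: ", sample_id)
    cfg <- fixture$config
    tr <- fixture$truth[fixture$truth$sample == sample_id, ]
    expr <- setNames(tr$expected_expression, tr$transcript_id)
    counts <- simulate_sample_counts(
        expr, fixture$effective_lengths[names(expr)],
        depth = cfg$reads_per_sample, dispersion = cfg$dispersion,
        seed = row$seed)
    out <- simulate_reads(fixture$transcripts, counts,
                          read_length = cfg$read_length,
                          error_rate = cfg$error_rate, seed = row$seed + 1L,
                          id_prefix = paste0(sample_id, ":r"))
    out$counts <- counts
    out
}
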