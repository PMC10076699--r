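test_that("reads are assigned by unique k-mer class membership", {
    fx <- small_index_fixture()
    # read wholly inside a specific record
    r_spec <- substr(fx$records[["specA"]], 10, 59)
    a <- assign_read(r_spec, fx$index)
    expect_equal(as.character(a$outcome), "assigned")
    expect_equal(a$class, "specA")
    # read wholly inside a common record, index containing specific classes:
    # assigned to common, never to an isoform
    r_common <- substr(fx$records[["common1"]], 20, 69)
    b <- assign_read(r_common, fx$index)
    expect_equal(as.character(b$outcome), "assigned")
    expect_equal(b$class, "common")
    # random sequence absent from the index
    withr::with_seed(1, {
        c_ <- assign_read(rand_dna(50), fx$index)
        expect_equal(as.character(c_$outcome), "unassigned")
        expect_equal(c_$n_hits, 0L)
    })
    # read shorter than k: unassigned with zero hits
    d <- assign_read("ACGTACG", fx$index)
    expect_equal(as.character(d$outcome), "unassigned")
    expect_equal(d$n_hits, 0L)
})

test_that("junction reads follow the specific-evidence rule", {
    fx <- small_index_fixture()
    half <- function(rec, n, from_end = FALSE) {
        s <- fx$records[[rec]]
        if (from_end) substr(s, nchar(s) - n + 1, nchar(s)) else substr(s, 1, n)
    }
    # 25 bases of specA + 25 of common1: 5 k-mers unique to specA -> assigned
    jread <- paste0(half("specA", 25, from_end = TRUE), half("common1", 25))
    a <- assign_read(jread, fx$index)
    expect_equal(a$class, "specA")
    # same read but min_hits above the 5 unique k-mers -> ambiguous
    b <- assign_read(jread, fx$index, min_hits = 6)
    expect_equal(as.character(b$outcome), "ambiguous")
    # specific/specific junction is always ambiguous
    c_ <- assign_read(paste0(half("specA", 25, from_end = TRUE),
                             half("specB", 25)), fx$index)
    expect_equal(as.character(c_$outcome), "ambiguous")
    # only 21 bases in the specific part: a single unique k-mer, ambiguous
    d <- assign_read(paste0(half("specA", 21, from_end = TRUE),
                            half("common1", 29)), fx$index)
    expect_equal(as.character(d$outcome), "ambiguous")
})

test_that("assignment agrees with brute-force substring enumeration", {
    fx <- small_index_fixture()
    reads <- withr::with_seed(55, {
        mk <- function(n) vapply(seq_len(n), function(i) {
            rec <- sample(names(fx$records), 1)
            s <- fx$records[[rec]]
            p <- sample.int(nchar(s) - 49, 1)
            substr(s, p, p + 49)
        }, character(1))
        junc <- vapply(1:20, function(i) {
            pair <- sample(names(fx$records), 2)
            n1 <- sample(5:45, 1)
            s1 <- fx$records[[pair[1]]]; s2 <- fx$records[[pair[2]]]
            paste0(substr(s1, nchar(s1) - n1 + 1, nchar(s1)),
                   substr(s2, 1, 50 - n1))
        }, character(1))
        noise <- vapply(1:10, function(i) rand_dna(50), character(1))
        c(mk(40), junc, noise)
    })
    got <- assign_reads(fx$index, reads, min_hits = 2)
    for (i in seq_along(reads)) {
        ref <- bf_assign_read(reads[i], fx$records, fx$classes, fx$k,
                              min_hits = 2, specific = c("specA", "specB"))
        expect_equal(as.character(got$outcome[i]), ref$outcome, info = reads[i])
        expect_equal(got$class[i], ref$class, info = reads[i])
        expect_equal(got$n_hits[i], ref$n_hits, info = reads[i])
    }
})

test_that("CPM and TPM follow their definitions", {
    expect_identical(cpm(10, 1e6), 10)
    expect_identical(cpm(0, 1e6), 0)
    expect_equal(cpm(500, 2e7), 25)
    expect_error(cpm(1, 0), "library size")
    # equal counts, equal lengths: symmetric 250,000 each
    expect_equal(unname(tpm(rep(5, 4), rep(100, 4))), rep(250000, 4))
    # hand computation: counts (10,10), effective lengths (100,200)
    v <- tpm(c(10, 10), c(100, 200))
    expect_equal(unname(v), c(2e6 / 3, 1e6 / 3), tolerance = 0.01 / 333333)
    expect_equal(sum(v), 1e6)
    expect_warning(z <- tpm(c(0, 0), c(10, 10)), "all counts zero")
    expect_true(all(z == 0))
})

test_that("cpm is linear in counts; tpm invariant to uniform scaling", {
    withr::with_seed(2, {
        counts <- rpois(6, 50)
        lens <- sample(100:500, 6)
        expect_equal(cpm(3 * counts, 1e5), 3 * cpm(counts, 1e5))
        expect_equal(tpm(counts * 7, lens), tpm(counts, lens))
    })
})

test_that("empty input yields a zero count row with zero library size", {
    fx <- small_index_fixture()
    q <- quantify_sample(character(0), fx$index)
    expect_true(all(q$counts == 0L))
    expect_equal(q$library_size, 0L)
})

test_that("quantification is additive over merged read sets", {
    fx <- small_index_fixture()
    withr::with_seed(77, {
        r1 <- vapply(1:30, function(i) {
            s <- fx$records[[sample(names(fx$records), 1)]]
            p <- sample.int(nchar(s) - 49, 1); substr(s, p, p + 49)
        }, character(1))
        r2 <- vapply(1:20, function(i) {
            s <- fx$records[[sample(names(fx$records), 1)]]
            p <- sample.int(nchar(s) - 49, 1); substr(s, p, p + 49)
        }, character(1))
    })
    qa <- quantify_sample(r1, fx$index)
    qb <- quantify_sample(r2, fx$index)
    qm <- quantify_sample(c(r1, r2), fx$index)
    expect_equal(qm$counts, qa$counts + qb$counts)
    expect_equal(qm$library_size, qa$library_size + qb$library_size)
})

quant_cfg <- sim_config(ages = c(E14 = -5, P6 = 6, P28 = 28),
                        replicates = 2L, reads_per_sample = 5000L,
                        error_rate = 0, seed = 314L)

test_that("error-free counts match truth-table brute force per class", {
    fx <- make_study_fixture(quant_cfg)
    idx <- build_study_indices(fx)
    sm <- fx$samples$sample[1] # embryonic sample, isoform 2 high
    sim <- simulate_sample_reads(fx, sm)
    q <- quantify_sample(sim$reads, idx$isoform, assignments = TRUE)
    # transcript-coordinate boundary between specific 5' block and common
    spec_len <- c(tgene_iso1 = 180L + 120L + 90L + 93L, tgene_iso2 = 378L)
    truth <- sim$truth
    contained <- function(class) {
        if (class == "iso1_specific") {
            sum(truth$transcript_id == "tgene_iso1" &
                truth$pos + 50 <= spec_len["tgene_iso1"])
        } else if (class == "iso2_specific") {
            sum(truth$transcript_id == "tgene_iso2" &
                truth$pos + 50 <= spec_len["tgene_iso2"])
        } else if (class == "common") {
            sum(truth$transcript_id %in% names(spec_len) &
                truth$pos >= spec_len[truth$transcript_id])
        } else {
            sum(truth$transcript_id == class)
        }
    }
    asg_class <- q$assignments$class[match(truth$read_id, q$assignments$read)]
    for (cl in c("iso1_specific", "iso2_specific", "common",
                 paste0("hk", 1:6))) {
        n_cont <- contained(cl)
        # every fully contained read is assigned to its class...
        is_cont <- if (cl == "iso1_specific") {
            truth$transcript_id == "tgene_iso1" & truth$pos + 50 <= 483
        } else if (cl == "iso2_specific") {
            truth$transcript_id == "tgene_iso2" & truth$pos + 50 <= 378
        } else if (cl == "common") {
            truth$transcript_id %in% names(spec_len) &
                truth$pos >= spec_len[truth$transcript_id]
        } else truth$transcript_id == cl
        expect_true(all(asg_class[is_cont] == cl), info = cl)
        # ...and junction reads only ever add to the specific classes
        expect_gte(q$counts[[cl]], n_cont)
    }
    # junction reads resolved per the documented rule: totals reconcile
    n_junction_assigned <- sum(q$counts[c("iso1_specific", "iso2_specific")]) -
        contained("iso1_specific") - contained("iso2_specific")
    expect_gte(n_junction_assigned, 0L)
    expect_equal(sum(q$counts) + q$ambiguous + q$unassigned, q$library_size)
})

test_that("no cross-isoform misassignment at zero error rate", {
    fx <- make_study_fixture(quant_cfg)
    idx <- build_study_indices(fx)
    for (sm in fx$samples$sample) {
        sim <- simulate_sample_reads(fx, sm)
        q <- quantify_sample(sim$reads, idx$isoform, assignments = TRUE)
        cls <- q$assignments$class[match(sim$truth$read_id,
                                         q$assignments$read)]
        expect_equal(sum(sim$truth$transcript_id == "tgene_iso2" &
                         cls == "iso1_specific", na.rm = TRUE), 0L)
        expect_equal(sum(sim$truth$transcript_id == "tgene_iso1" &
                         cls == "iso2_specific", na.rm = TRUE), 0L)
    }
})

test_that("whole-gene counts equal total target-gene reads when error-free", {
    fx <- make_study_fixture(quant_cfg)
    idx <- build_study_indices(fx)
    sm <- fx$samples$sample[3]
    sim <- simulate_sample_reads(fx, sm)
    qw <- whole_gene_quantify(sim$reads, idx$whole_gene)
    n_target <- sum(sim$truth$transcript_id %in%
                    c("tgene_iso1", "tgene_iso2"))
    expect_equal(unname(qw$counts["tgene_whole"]), n_target)
    expect_error(whole_gene_quantify(sim$reads, idx$isoform),
                 "exactly one class")
})

test_that("whole-gene count equals the single expressed isoform's reads", {
    cfg <- sim_config(ages = c(P28 = 28), replicates = 1L,
                      reads_per_sample = 2000L, error_rate = 0, seed = 9L,
                      iso2 = trajectory_spec("constant", A = 0))
    fx <- make_study_fixture(cfg)
    idx <- build_study_indices(fx)
    sim <- simulate_sample_reads(fx, fx$samples$sample[1])
    expect_equal(unname(sim$counts["tgene_iso2"]), 0L)
    qw <- whole_gene_quantify(sim$reads, idx$whole_gene)
    expect_equal(unname(qw$counts["tgene_whole"]),
                 unname(sim$counts["tgene_iso1"]))
    # the unexpressed isoform's specific class stays at zero
    qi <- quantify_sample(sim$reads, idx$isoform)
    expect_equal(unname(qi$counts["iso2_specific"]), 0L)
})
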