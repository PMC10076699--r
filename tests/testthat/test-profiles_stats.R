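mk_design <- function(samples, groups) {
    data.frame(sample = samples, group = groups, stringsAsFactors = FALSE)
}

test_that("group summaries give sample mean and n-1 SD per group", {
    m <- matrix(c(4, 6, 2, 2, 9, 9), nrow = 1,
                dimnames = list("f", paste0("s", 1:6)))
    d <- mk_design(paste0("s", 1:6), rep(c("g1", "g2", "g3"), each = 2))
    gs <- group_summary(m, d)
    expect_equal(gs$mean, c(5, 2, 9))
    expect_equal(gs$sd, c(sqrt(2), 0, 0))
    expect_equal(gs$n, rep(2L, 3))
    # single-sample group: mean = value, SD flagged and set to 0
    m1 <- matrix(7, nrow = 1, dimnames = list("f", "s1"))
    gs1 <- group_summary(m1, mk_design("s1", "only"))
    expect_equal(gs1$mean, 7)
    expect_equal(gs1$sd, 0)
    expect_true(gs1$sd_undefined)
    expect_error(group_summary(m, rbind(d, mk_design("s7", "g4"))), "s7")
})

test_that("group means are invariant to sample order; log SD shift-invariant", {
    withr::with_seed(10, {
        m <- matrix(rexp(24, 0.1), nrow = 4,
                    dimnames = list(paste0("f", 1:4), paste0("s", 1:6)))
        d <- mk_design(paste0("s", 1:6), rep(c("a", "b"), each = 3))
        perm <- sample(6)
        gs1 <- group_summary(m, d)
        gs2 <- group_summary(m[, perm], d)
        expect_equal(gs1$mean, gs2$mean)
        expect_equal(gs1$sd, gs2$sd)
        # affine contract: adding a constant on the log scale shifts the
        # mean and leaves the SD unchanged (not so on the raw scale)
        x <- log2(m[1, 1:3] + 1)
        expect_equal(sd(x + 5), sd(x))
    })
})

test_that("mean-CPM filtering is boundary-inclusive", {
    m <- rbind(at_cut = c(8, 12, 10, 10), below = c(9.9, 9.9, 9.9, 9.9),
               above = c(10.1, 10.1, 10.1, 10.1), zero = c(0, 0, 0, 0))
    colnames(m) <- paste0("s", 1:4)
    kept <- filter_mean_expression(m, cutoff = 10)
    expect_setequal(rownames(kept), c("at_cut", "above"))
    expect_equal(nrow(filter_mean_expression(m, cutoff = 0.1)), 3L)
})

test_that("PCA explained-variance fractions behave as eigenvalue ratios", {
    # rank-1 data: samples on a line
    m <- outer(c(1, 2, 3), c(0, 1, 2, 3))
    dimnames(m) <- list(paste0("f", 1:3), paste0("s", 1:4))
    p <- pca_explained_variance(m, transform = "none")
    expect_equal(p$fractions[1], 1)
    # fractions sum to 1 and descend for a random 10 x 6 matrix
    withr::with_seed(4, {
        r <- matrix(rexp(60, 0.05), nrow = 10,
                    dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
        pr <- pca_explained_variance(r)
        expect_equal(sum(pr$fractions), 1, tolerance = 1e-9)
        expect_true(all(diff(pr$fractions) <= 1e-12))
        # invariant to feature reordering
        pr2 <- pca_explained_variance(r[sample(10), ])
        expect_equal(pr$fractions, pr2$fractions, tolerance = 1e-9)
    })
    # hand eigendecomposition: sample covariance diag(2, 1) -> (2/3, 1/3)
    f1 <- c(-sqrt(2), 0, sqrt(2))
    f2 <- c(1, -2, 1) / sqrt(3)
    m2 <- rbind(f1 = f1, f2 = f2)
    colnames(m2) <- paste0("s", 1:3)
    p2 <- pca_explained_variance(m2, transform = "none")
    expect_equal(unname(p2$fractions), c(2 / 3, 1 / 3), tolerance = 1e-9)
    expect_error(pca_explained_variance(matrix(1, 2, 3), transform = "none"),
                 "constant")
})

test_that("duplicating a dominant feature pulls variance toward it", {
    withr::with_seed(6, {
        m <- rbind(big = c(0, 10, 20, 30, 40, 50) + rnorm(6, 0, 0.1),
                   small = rnorm(6))
        colnames(m) <- paste0("s", 1:6)
        p1 <- pca_explained_variance(m, transform = "none")
        p2 <- pca_explained_variance(rbind(m, big2 = m["big", ]),
                                     transform = "none")
        expect_gt(p2$fractions[1], p1$fractions[1])
    })
})

test_that("log t-test follows the pooled-variance Student definition", {
    same <- log_ttest(c(1, 2, 3), c(1, 2, 3), log_transform = FALSE)
    expect_equal(same$t, 0)
    expect_equal(same$p, 1)
    ab <- log_ttest(c(1, 2, 3), c(2, 3, 4), log_transform = FALSE)
    ba <- log_ttest(c(2, 3, 4), c(1, 2, 3), log_transform = FALSE)
    expect_equal(ab$t, -ba$t)
    expect_equal(ab$p, ba$p)
    ref <- stats::t.test(c(1, 2, 3), c(2, 3, 4), var.equal = TRUE)
    expect_equal(ab$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ab$p, ref$p.value, tolerance = 1e-9)
    # degenerate: zero variance, unequal means
    expect_error(log_ttest(c(2, 2), c(3, 3), log_transform = FALSE),
                 "zero pooled variance")
})

test_that("Student and Welch variants match the reference implementation", {
    withr::with_seed(2024, {
        for (i in 1:100) {
            a <- rexp(sample(2:8, 1), 0.2)
            b <- rexp(sample(2:8, 1), 0.2)
            got_s <- log_ttest(a, b)
            ref_s <- stats::t.test(log2(a + 1), log2(b + 1), var.equal = TRUE)
            expect_equal(got_s$t, unname(ref_s$statistic), tolerance = 1e-9)
            expect_equal(got_s$p, ref_s$p.value, tolerance = 1e-9)
            got_w <- log_ttest(a, b, welch = TRUE)
            ref_w <- stats::t.test(log2(a + 1), log2(b + 1))
            expect_equal(got_w$t, unname(ref_w$statistic), tolerance = 1e-9)
            expect_equal(got_w$p, ref_w$p.value, tolerance = 1e-9)
            expect_equal(got_w$df, unname(ref_w$parameter), tolerance = 1e-9)
        }
    })
})

qpcr_plate <- function() {
    data.frame(
        sample = rep(c("c1", "c2", "t1", "t2"), each = 2),
        group = rep(c("calib", "calib", "treat", "treat"), each = 2),
        gene = rep(c("target", "ref"), 4),
        ct = c(20, 18, 20, 18, 22, 18, 22, 18),
        stringsAsFactors = FALSE
    )
}

test_that("2^-ddCt quantification matches hand computation", {
    res <- ddct(qpcr_plate(), reference = "ref", calibrator = "calib")
    per <- res$per_sample
    treat <- per[per$group == "treat", ]
    expect_equal(treat$ddct, c(2, 2))
    expect_equal(treat$rel_expr, c(0.25, 0.25), tolerance = 1e-12)
    # ddCt = 0 -> relative expression exactly 1
    calib <- per[per$group == "calib", ]
    expect_equal(calib$rel_expr, c(1, 1))
    # calibrator group mean dCt gives relative expression exactly 1
    expect_identical(2^(-(mean(calib$dct) - res$calibrator_mean_dct[["target"]])),
                     1)
    # lowering a test sample's target Ct by one cycle doubles its expression
    p2 <- qpcr_plate()
    p2$ct[p2$sample == "t1" & p2$gene == "target"] <- 21
    res2 <- ddct(p2, reference = "ref", calibrator = "calib")
    expect_equal(res2$per_sample$rel_expr[res2$per_sample$sample == "t1"],
                 2 * 0.25)
})

test_that("ddct validates its plate", {
    p <- qpcr_plate()
    p <- p[!(p$sample == "t2" & p$gene == "ref"), ]
    expect_error(ddct(p, reference = "ref", calibrator = "calib"), "t2")
    bad <- qpcr_plate(); bad$ct[1] <- -1
    expect_error(ddct(bad, reference = "ref", calibrator = "calib"),
                 "finite")
})

test_that("regional comparison detects opsin-like counter-gradients", {
    withr::with_seed(123, {
        n <- 4
        sup <- paste0("sup", 1:n); inf <- paste0("inf", 1:n)
        m <- rbind(
            m_opsin = c(rnorm(n, 400, 20), rnorm(n, 100, 5)),
            s_opsin = c(rnorm(n, 100, 5), rnorm(n, 400, 20))
        )
        colnames(m) <- c(sup, inf)
        d <- data.frame(sample = c(sup, inf),
                        region = rep(c("superior", "inferior"), each = n))
        res <- regional_comparison(m, d)
        expect_true(res$t[res$gene == "m_opsin"] > 0)
        expect_true(res$t[res$gene == "s_opsin"] < 0)
        expect_equal(sign(res$t), sign(log(res$fold)))
        # known 4-fold difference, low noise: estimated fold in [3.5, 4.5]
        expect_true(res$fold[res$gene == "m_opsin"] > 3.5 &&
                    res$fold[res$gene == "m_opsin"] < 4.5)
    })
    # identical regional values: fold 1, p 1
    m0 <- matrix(5, 1, 4, dimnames = list("g", paste0("s", 1:4)))
    d0 <- data.frame(sample = paste0("s", 1:4),
                     region = rep(c("superior", "inferior"), each = 2))
    r0 <- regional_comparison(m0, d0)
    expect_equal(r0$fold, 1)
    expect_equal(r0$p, 1)
    expect_error(regional_comparison(m0, d0, regions = c("superior", "nasal")),
                 "nasal")
})

test_that("switch report finds the crossing age and flags degeneracy", {
    ages <- c(E14 = -5, P1 = 1, P10 = 10, P28 = 28)
    rep1 <- switch_report(iso1 = c(1, 5, 20, 40), iso2 = c(50, 30, 8, 1),
                          whole_gene = c(51, 35, 28, 41), ages = ages,
                          truth = list(iso1 = c(1, 5, 20, 40),
                                       iso2 = c(50, 30, 8, 1)))
    expect_true(rep1$crossing_age$found)
    expect_equal(rep1$crossing_age$age_label, "P10")
    expect_true(all(rep1$masked))
    # identical profiles never strictly cross: none, per the tie rule
    rep2 <- switch_report(iso1 = c(1, 2, 3), iso2 = c(1, 2, 3),
                          ages = ages[1:3])
    expect_false(rep2$crossing_age$found)
    # monotone single-isoform data: masking diagnostic degenerate, flagged
    rep3 <- switch_report(iso1 = c(1, 5, 20, 40), iso2 = c(0, 0, 0, 0),
                          whole_gene = c(1, 5, 20, 40), ages = ages,
                          truth = list(iso1 = c(1, 5, 20, 40),
                                       iso2 = c(0, 0, 0, 0)))
    expect_true(rep3$degenerate[["iso2"]])
})

test_that("plateau midpoint is recovered from clean profile data", {
    ages <- unname(default_ages())
    spec <- trajectory_spec("late_plateau", A = 50, t50 = 8, s = 3)
    y <- trajectory_value(spec, ages)
    fit <- fit_plateau_midpoint(ages, y)
    expect_equal(fit$t50, 8, tolerance = 1e-4)
    expect_equal(fit$A, 50, tolerance = 1e-3)
    withr::with_seed(5, {
        noisy <- y * exp(rnorm(length(y), 0, 0.1))
        fit2 <- fit_plateau_midpoint(ages, noisy)
        expect_lt(abs(fit2$t50 - 8), 1)
    })
})
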