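#' Per-group mean and standard deviation profiles
#'
#' Summarizes an expression matrix (features x samples) into per-feature,
#' per-group sample mean and sample SD (n - 1 denominator). Single-sample
#' groups get SD 0 with a flag.
#'
#' @param matrix Numeric matrix, features in rows, samples in columns.
#' @param design data.frame with columns `sample` and `group` (optionally
#'   `position` for group ordering); every sample must be a column of
#'   `matrix`, every sample belongs to exactly one group.
#' @return data.frame: feature, group, mean, sd, n, sd_undefined (TRUE when
#'   n = 1).
#' @export
group_summary <- function(matrix, design) {
    stopifnot(all(c("sample", "group") %in% colnames(design)))
    if (anyDuplicated(design$sample))
        stop("each sample must appear in exactly one group")
    missing <- setdiff(design$sample, colnames(matrix))
    if (length(missing) > 0)
        stop("samples absent from matrix: ", paste(missing, collapse = ", "))
    groups <- unique(design$group)
    out <- do.call(rbind, lapply(groups, function(g) {
        cols <- design$sample[design$group == g]
        if (length(cols) == 0L) stop("group with zero samples: ", g)
        sub <- matrix[, cols, drop = FALSE]
        n <- length(cols)
        data.frame(
            feature = rownames(matrix),
            group = g,
            mean = rowMeans(sub),
            sd = if (n == 1L) 0 else apply(sub, 1L, sd),
            n = n,
            sd_undefined = n == 1L,
            stringsAsFactors = FALSE
        )
    }))
    rownames(out) <- NULL
    out
}

#' Filter features by grand-mean expression
#'
#' Retains features whose mean across all samples is at least `cutoff`
#' (boundary inclusive) — the CPM cutoff used before heatmap display.
#'
#' @param matrix Numeric matrix (CPM units), features in rows.
#' @param cutoff Grand-mean CPM threshold (default 10).
#' @return The filtered matrix (possibly zero rows).
#' @export
filter_mean_expression <- function(matrix, cutoff = 10) {
    matrix[rowMeans(matrix) >= cutoff, , drop = FALSE]
}

#' PCA explained-variance fractions over samples
#'
#' Transforms the expression matrix (default log2(x + 1)), treats samples as
#' observations and features as variables, centers per feature (no
#' unit-variance scaling) and reports the fraction of variance explained by
#' each principal component.
#'
#' @param matrix Numeric matrix, features x samples (>= 2 samples).
#' @param transform "log2p1" (default) or "none".
#' @param center Center per feature (default TRUE).
#' @return A `PcaResult` list: `fractions` (descending, summing to 1) and
#'   `scores` (samples x components).
#' @export
pca_explained_variance <- function(matrix, transform = c("log2p1", "none"),
                                   center = TRUE) {
    transform <- match.arg(transform)
    if (ncol(matrix) < 2L) stop("PCA requires at least 2 samples")
    x <- if (transform == "log2p1") log2(matrix + 1) else matrix
    X <- t(x) # samples as observations
    if (all(apply(X, 2L, var) < .Machine$double.eps))
        stop("constant matrix: explained variance undefined")
    p <- prcomp(X, center = center, scale. = FALSE)
    ev <- p$sdev^2
    structure(list(fractions = ev / sum(ev), scores = p$x),
              class = "PcaResult")
}

#' Unpaired two-tailed t-test on log-transformed expression
#'
#' Applies log2(x + pseudocount) (optional) and computes the pooled-variance
#' (equal-variance) Student t statistic with a two-sided p-value from the t
#' distribution with n_a + n_b - 2 degrees of freedom. A Welch
#' (unequal-variance) variant is available behind `welch = TRUE`.
#'
#' @param group_a,group_b Numeric vectors (n >= 2 each).
#' @param log_transform Apply log2(x + pseudocount) first (default TRUE).
#' @param pseudocount Added before the log (default 1).
#' @param welch Use the Welch unequal-variance statistic instead.
#' @return A `TestResult` list: `t`, `p`, `df`, `mean_a`, `mean_b` (log
#'   scale when transformed), `n_a`, `n_b`, `log_transform`, `pseudocount`,
#'   `method`.
#' @export
log_ttest <- function(group_a, group_b, log_transform = TRUE,
                      pseudocount = 1, welch = FALSE) {
    na <- length(group_a); nb <- length(group_b)
    if (na < 2L || nb < 2L) stop("each group needs at least 2 values")
    a <- if (log_transform) log2(group_a + pseudocount) else group_a
    b <- if (log_transform) log2(group_b + pseudocount) else group_b
    ma <- mean(a); mb <- mean(b)
    va <- var(a); vb <- var(b)
    if (welch) {
        se2 <- va / na + vb / nb
        if (se2 == 0) {
            if (ma == mb) {
                tstat <- 0; df <- na + nb - 2
            } else stop("zero variance with unequal means: t undefined")
        } else {
            tstat <- (ma - mb) / sqrt(se2)
            df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
        }
        method <- "welch"
    } else {
        df <- na + nb - 2
        sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
        if (sp2 == 0) {
            if (ma == mb) tstat <- 0
            else stop("zero pooled variance with unequal means: t undefined")
        } else {
            tstat <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
        }
        method <- "student"
    }
    p <- if (tstat == 0) 1 else 2 * pt(-abs(tstat), df)
    list(t = tstat, p = p, df = df, mean_a = ma, mean_b = mb,
         n_a = na, n_b = nb, log_transform = log_transform,
         pseudocount = pseudocount, method = method)
}

#' 2^-ddCt relative qPCR quantification
#'
#' Per sample: dCt = Ct_target - Ct_reference; ddCt = dCt minus the mean dCt
#' of the calibrator group; relative expression = 2^-ddCt. The calibrator
#' group's relative expression, computed from its group-mean dCt, is exactly
#' 1.
#'
#' @param plate data.frame with columns `sample`, `group`, `gene`, `ct`.
#' @param target Target gene name(s); default: every gene except the
#'   reference.
#' @param reference Reference (internal control) gene name, present for
#'   every sample.
#' @param calibrator Calibrator group label.
#' @return A `DdctResult` list: `per_sample` (data.frame: sample, group,
#'   target, dct, ddct, rel_expr) and `calibrator_mean_dct` per target.
#' @export
ddct <- function(plate, target = NULL, reference, calibrator) {
    stopifnot(all(c("sample", "group", "gene", "ct") %in% colnames(plate)))
    if (any(!is.finite(plate$ct)) || any(plate$ct <= 0))
        stop("Ct values must be finite and > 0")
    if (is.null(target)) target <- setdiff(unique(plate$gene), reference)
    if (!calibrator %in% plate$group)
        stop("calibrator group not present: ", calibrator)
    ref <- plate[plate$gene == reference, ]
    samples <- unique(plate$sample)
    no_ref <- setdiff(samples, ref$sample)
    if (length(no_ref) > 0)
        stop("missing reference Ct for sample: ",
             paste(no_ref, collapse = ", "))
    ref_ct <- setNames(ref$ct, ref$sample)
    per <- do.call(rbind, lapply(target, function(tg) {
        sub <- plate[plate$gene == tg, ]
        dct <- sub$ct - ref_ct[sub$sample]
        cal_mean <- mean(dct[sub$group == calibrator])
        if (is.nan(cal_mean))
            stop("calibrator group has no measurements for target ", tg)
        ddct_v <- dct - cal_mean
        data.frame(sample = sub$sample, group = sub$group, target = tg,
                   dct = unname(dct), ddct = unname(ddct_v),
                   rel_expr = 2^(-unname(ddct_v)), stringsAsFactors = FALSE)
    }))
    cal <- vapply(target, function(tg) {
        sub <- per[per$target == tg, ]
        mean(sub$dct[sub$group == calibrator])
    }, numeric(1))
    structure(list(per_sample = per, calibrator_mean_dct = cal,
                   reference = reference, calibrator = calibrator),
              class = "DdctResult")
}

#' Regional (superior vs inferior) expression comparison
#'
#' For each gene, runs the log-transformed unpaired t-test between the two
#' regions and reports the ratio of (raw-scale) group means.
#'
#' @param matrix Numeric matrix, genes x samples.
#' @param design data.frame with columns `sample` and `region`.
#' @param genes Genes to test (default: all rows).
#' @param regions Length-2 character: the regions compared, numerator first
#'   (default c("superior", "inferior")).
#' @param welch Use Welch's t instead of Student's.
#' @return data.frame: gene, t, p, fold (mean ratio numerator/denominator),
#'   mean_1, mean_2.
#' @export
regional_comparison <- function(matrix, design, genes = rownames(matrix),
                                regions = c("superior", "inferior"),
                                welch = FALSE) {
    stopifnot(all(c("sample", "region") %in% colnames(design)),
              length(regions) == 2L)
    for (r in regions)
        if (!r %in% design$region) stop("region absent from design: ", r)
    s1 <- design$sample[design$region == regions[1]]
    s2 <- design$sample[design$region == regions[2]]
    out <- do.call(rbind, lapply(genes, function(g) {
        a <- matrix[g, s1]; b <- matrix[g, s2]
        tt <- log_ttest(a, b, welch = welch)
        data.frame(gene = g, t = tt$t, p = tt$p,
                   fold = mean(a) / mean(b),
                   mean_1 = mean(a), mean_2 = mean(b),
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

.spearman <- function(x, y) {
    suppressWarnings(stats::cor(x, y, method = "spearman"))
}

#' Isoform-switch report and whole-gene masking diagnostic
#'
#' Identifies the first age at which the isoform-1 group-mean profile
#' strictly exceeds the isoform-2 profile (the developmental switch), and,
#' when true trajectories are supplied, quantifies how whole-gene
#' quantification masks the switch: for each isoform, the Spearman
#' correlation of the whole-gene profile with the true trajectory is
#' compared against the isoform's own estimated-vs-true (self-recovery)
#' correlation.
#'
#' @param iso1,iso2 Numeric vectors of per-age group means (isoform 1 and
#'   2), one value per age, same order as `ages`.
#' @param whole_gene Per-age whole-gene group means (optional, needed for
#'   the masking diagnostic).
#' @param ages Named numeric vector of age positions (>= 3 ages).
#' @param truth Optional list with elements `iso1` and `iso2`: the true
#'   trajectory values at `ages`.
#' @return A `SwitchReport` list: `crossing_age` (name and position, NA when
#'   no crossing), and when truth and whole_gene are given, `self_corr`,
#'   `whole_gene_corr` and `masked` (logical per isoform; TRUE when the
#'   whole-gene profile tracks the isoform's truth strictly worse than the
#'   isoform's own estimate does), plus `degenerate` flags for constant
#'   profiles.
#' @export
switch_report <- function(iso1, iso2, whole_gene = NULL, ages,
                          truth = NULL) {
    stopifnot(length(ages) >= 3L,
              length(iso1) == length(ages), length(iso2) == length(ages))
    ord <- order(ages)
    iso1 <- iso1[ord]; iso2 <- iso2[ord]; ages <- ages[ord]
    if (!is.null(whole_gene)) whole_gene <- whole_gene[ord]
    cross_idx <- which(iso1 > iso2)[1L] # tie-break: first strict inequality
    crossing <- if (is.na(cross_idx)) {
        list(age_label = NA_character_, age = NA_real_, found = FALSE)
    } else {
        list(age_label = names(ages)[cross_idx],
             age = unname(ages[cross_idx]), found = TRUE)
    }
    out <- list(crossing_age = crossing, ages = ages,
                profiles = list(iso1 = iso1, iso2 = iso2,
                                whole_gene = whole_gene))
    if (!is.null(truth) && !is.null(whole_gene)) {
        tr1 <- truth$iso1[ord]; tr2 <- truth$iso2[ord]
        degenerate <- c(
            iso1 = sd(iso1) == 0 || sd(tr1) == 0,
            iso2 = sd(iso2) == 0 || sd(tr2) == 0,
            whole_gene = sd(whole_gene) == 0
        )
        self_corr <- c(iso1 = .spearman(iso1, tr1),
                       iso2 = .spearman(iso2, tr2))
        wg_corr <- c(iso1 = .spearman(whole_gene, tr1),
                     iso2 = .spearman(whole_gene, tr2))
        out$self_corr <- self_corr
        out$whole_gene_corr <- wg_corr
        out$masked <- wg_corr < self_corr
        out$degenerate <- degenerate
    }
    structure(out, class = "SwitchReport")
}

#' @export
print.SwitchReport <- function(x, ...) {
    if (x$crossing_age$found) {
        cat("Isoform switch: isoform 1 first exceeds isoform 2 at",
            x$crossing_age$age_label,
            sprintf("(age position %g)\n", x$crossing_age$age))
    } else {
        cat("Isoform switch: no crossing detected\n")
    }
    if (!is.null(x$self_corr)) {
        cat(sprintf("  self-recovery Spearman: iso1 %.3f, iso2 %.3f\n",
                    x$self_corr["iso1"], x$self_corr["iso2"]))
        cat(sprintf("  whole-gene vs truth:    iso1 %.3f, iso2 %.3f\n",
                    x$whole_gene_corr["iso1"], x$whole_gene_corr["iso2"]))
        cat("  masking:", if (all(x$masked))
            "whole-gene profile tracks neither isoform as well as its own estimate"
            else "not demonstrated", "\n")
    }
    invisible(x)
}

#' Fit the logistic plateau midpoint from a developmental profile
#'
#' Least-squares fit of `A / (1 + exp(-(t - t50)/s))` to per-age expression
#' means, recovering the plateau midpoint t50 (and A, s) of a
#' late-plateau trajectory.
#'
#' @param ages Numeric age positions.
#' @param values Expression means at those ages.
#' @param start Optional named list of starting values (A, t50, s).
#' @return List with `A`, `t50`, `s` and the `fit` object.
#' @export
fit_plateau_midpoint <- function(ages, values, start = NULL) {
    stopifnot(length(ages) == length(values), length(ages) >= 4L)
    if (is.null(start)) {
        A0 <- max(values)
        half <- A0 / 2
        t50_0 <- ages[which.min(abs(values - half))]
        start <- list(A = A0, t50 = t50_0, s = diff(range(ages)) / 10)
    }
    df <- data.frame(t = ages, y = values)
    fit <- minpack.lm::nlsLM(
        y ~ A / (1 + exp(-(t - t50) / s)), data = df, start = start,
        lower = c(A = 0, t50 = min(ages) - 10, s = 1e-3),
        upper = c(A = Inf, t50 = max(ages) + 10, s = diff(range(ages))),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    co <- stats::coef(fit)
    list(A = unname(co["A"]), t50 = unname(co["t50"]), s = unname(co["s"]),
         fit = fit)
}
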