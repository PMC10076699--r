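#!/usr/bin/env Rscript
# Stage 4: downstream assays emulated at desk scale — 2^-ddCt qPCR
# quantification of the two isoforms against a constant reference gene, and
# a superior/inferior regional comparison of opsin-like counter-gradients.

suppressPackageStartupMessages(library(isoswitchr))
set.seed(4L)

out <- "results/qpcr"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## ---- qPCR: isoform trajectories as Ct values ----
# Ct falls by one cycle per doubling of template: Ct = offset - log2(expr).
cfg <- sim_config(seed = 1L)
ages <- c(E17 = -2, P10 = 10, P60 = 60)
plate <- do.call(rbind, lapply(names(ages), function(a) {
    t <- ages[[a]]
    do.call(rbind, lapply(1:3, function(rep) {
        s <- sprintf("%s_q%d", a, rep)
        noise <- function() rnorm(1, 0, 0.15)
        data.frame(
            sample = s, group = a,
            gene = c("iso1", "iso2", "ref"),
            ct = c(30 - log2(trajectory_value(cfg$iso1, t) + 0.05) + noise(),
                   30 - log2(trajectory_value(cfg$iso2, t) + 0.05) + noise(),
                   18 + noise()))
    }))
}))
write_tsv(plate, file.path(out, "plate.tsv"), provenance = "seed: 4")

res <- ddct(plate, reference = "ref", calibrator = "E17")
write_tsv(res$per_sample, file.path(out, "ddct.tsv"),
          provenance = c("reference: ref", "calibrator: E17"))
fold <- tapply(res$per_sample$rel_expr,
               list(res$per_sample$group, res$per_sample$target), mean)
cat("Mean 2^-ddCt fold change vs E17 calibrator:\n")
print(round(fold[names(ages), ], 3))
cat("Isoform 1 rises and isoform 2 collapses by P60, as in the RNA-seq\n")
cat("profiles; the reciprocal pattern is the promoter switch.\n\n")

## ---- regional comparison: opsin-like counter-gradient ----
n <- 4
m <- rbind(m_opsin = c(rnorm(n, 400, 30), rnorm(n, 100, 10)),
           s_opsin = c(rnorm(n, 100, 10), rnorm(n, 400, 30)))
colnames(m) <- c(paste0("sup", 1:n), paste0("inf", 1:n))
design <- data.frame(sample = colnames(m),
                     region = rep(c("superior", "inferior"), each = n))
reg <- regional_comparison(m, design)
write_tsv(reg, file.path(out, "regional_ttests.tsv"),
          provenance = "log2(x+1) Student t, superior vs inferior")
cat("Regional t-tests (superior vs inferior):\n")
print(reg, digits = 3)
cat("Opposite-signed t statistics capture the M/S opsin counter-gradient.\n")
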