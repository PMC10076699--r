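#!/usr/bin/env Rscript
# Stage 3: developmental-profile statistics on the quantified study
# (run 02_quantify_isoforms.R first): CPM-cutoff filtering, per-age
# mean +/- SD profiles, plateau-midpoint recovery, and the contrast between
# isoform-resolved and whole-gene trajectories.

suppressPackageStartupMessages(library(isoswitchr))

study <- "results/study"
out <- "results/profiles"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cpm_df <- read_tsv(file.path(study, "cpm_matrix.tsv"))
mat <- as.matrix(cpm_df[, -1])
rownames(mat) <- cpm_df$feature

kept <- filter_mean_expression(mat, cutoff = 10)
cat("CPM filter (grand mean >= 10):", nrow(kept), "of", nrow(mat),
    "features retained\n")

ages <- default_ages()
age_label <- sub("_r[0-9]+$", "", colnames(mat))
design <- data.frame(sample = colnames(mat), group = age_label)
prof <- group_summary(mat, design)
write_tsv(prof, file.path(out, "profiles_mean_sd.tsv"),
          provenance = "groups: developmental ages, n = 3")

pick <- function(f) {
    s <- prof[prof$feature == f, ]
    setNames(s$mean[match(names(ages), s$group)], names(ages))
}
iso1 <- pick("iso1_specific"); iso2 <- pick("iso2_specific")
wg <- pick("tgene_whole")

cfg <- sim_config(seed = 1L) # the study conditions 02 ran under
rep <- switch_report(iso1, iso2, wg, ages,
                     truth = list(iso1 = trajectory_value(cfg$iso1, ages),
                                  iso2 = trajectory_value(cfg$iso2, ages)))
print(rep)

fit <- fit_plateau_midpoint(unname(ages), unname(iso1))
cat(sprintf("Fitted isoform-1 plateau midpoint t50 = %.2f (simulated: %g)\n",
            fit$t50, cfg$iso1$t50))
write_tsv(data.frame(parameter = c("A", "t50", "s"),
                     fitted = c(fit$A, fit$t50, fit$s),
                     simulated = c(cfg$iso1$A, cfg$iso1$t50, cfg$iso1$s)),
          file.path(out, "plateau_fit.tsv"))

cat("The whole-gene profile is near-flat across the switch: its Spearman\n")
cat("correlation with each true isoform trajectory is",
    sprintf("%.2f / %.2f,", rep$whole_gene_corr["iso1"],
            rep$whole_gene_corr["iso2"]),
    "\nversus self-recovery",
    sprintf("%.2f / %.2f.", rep$self_corr["iso1"], rep$self_corr["iso2"]), "\n")
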