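# isoswitchr

Isoform-resolved quantification of alternative-promoter switches in
short-read RNA-seq, with a deterministic simulator and the downstream
developmental-profile statistics.

## The problem

Genes with alternative promoters express isoforms that differ only in their
5' exons. The motivating case is the thyroid hormone receptor beta gene,
whose two receptor isoforms share the exons encoding the DNA-binding and
ligand-binding domains but start from distinct promoters. During retinal
development the two isoforms switch: one is high embryonically and declines
after birth, the other rises postnatally to a plateau. Whole-gene read
counting sums both and yields a near-flat profile — the switch is masked.
Counting reads against the isoform-specific 5' exons resolves it.

`isoswitchr` implements this as an explicit k-mer assignment rule rather
than a black-box aligner. Feature classes (isoform-specific exon sets, the
common exons, a whole-gene union) are indexed by their k-mers (default
k = 21); a read is assigned to a class when all of its matched k-mers are
unique to that class and at least `min_hits` (default 2) distinct k-mers
match. Reads spanning a specific/common junction count toward the specific
class when they carry enough k-mers unique to it; anything spanning two
classes otherwise is ambiguous and excluded. Normalization is

- CPM: `count / library_size * 1e6` (library size = all reads in the sample),
- TPM: `rate_f / sum(rate) * 1e6` with `rate_f = count_f / effective_length_f`
  and effective length `len - read_length + 1`.

Downstream statistics follow the conventions of developmental expression
studies: per-age mean ± SD profiles, a grand-mean CPM ≥ 10 heatmap filter,
PCA explained variance on log2(CPM + 1) (centered, unscaled), unpaired
two-tailed Student t-tests on log2(x + 1) (Welch behind a flag), 2^−ΔΔCt
qPCR quantification against a reference gene and calibrator group, and
superior/inferior regional comparisons.

The simulator generates the entire study from one seed: a toy genome with a
two-isoform gene (four isoform-1-specific 5' exons, one isoform-2-specific
exon, common exons > 6 kb downstream; the two cDNAs encode 461- and
476-residue ORFs), six housekeeping genes, biphasic trajectories across 12
ages (E14 → P60) with 3 replicates, and 50-base single-end reads with a
truth table (negative-binomial counts, uniform start positions, per-base
substitution errors).

## Worked example

The numbered scripts under `analysis/` run the study end to end
(`Rscript analysis/01_simulate_study.R`, then 02–04). The core of it in a
session:

```r
library(isoswitchr)
run <- run_study_pipeline(sim_config(seed = 1L), out_dir = "results/study")
print(run$report)
```

which prints (seed 1):

```
Isoform switch: isoform 1 first exceeds isoform 2 at P10 (age position 10)
  self-recovery Spearman: iso1 0.979, iso2 0.991
  whole-gene vs truth:    iso1 0.524, iso2 -0.524
  masking: whole-gene profile tracks neither isoform as well as its own estimate
```

Reading: the estimated CPM trajectories of the two isoform-specific exon
classes track their true simulated trajectories almost perfectly (Spearman
0.98/0.99), the isoform-1-over-isoform-2 crossing is detected at P10 (the
first sampled age after the analytic crossing of the true curves at ~6.8),
while the whole-gene profile correlates only weakly — and with opposite
signs — with the two true trajectories: whole-gene counting cannot reveal
the switch. `analysis/03_developmental_profiles.R` additionally recovers the
simulated plateau midpoint (t50 = 8) from the estimated profile by
least-squares fit (7.81 at seed 1), and `analysis/04_qpcr_and_regions.R`
shows the same reciprocal pattern in 2^−ΔΔCt fold changes and opsin-like
regional counter-gradients.

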