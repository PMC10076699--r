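---
title: "Quantifying an alternative-promoter isoform switch from short RNA-seq reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying an alternative-promoter isoform switch from short RNA-seq reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Many genes express several protein isoforms from alternative promoters. The
thyroid hormone receptor beta gene is the motivating case: its two receptor
isoforms differ only in N-terminal exons driven by separate promoters, while
the downstream exons encoding the DNA-binding and ligand-binding domains are
shared. Standard gene-level RNA-seq quantification sums reads over all exons
of the gene, so two isoforms with reciprocal developmental trajectories — one
high embryonically and declining after birth, the other rising postnatally to
a plateau — can produce a nearly flat total-gene profile. The switch is
invisible unless reads are counted against the isoform-specific 5' exons
themselves.

`isoswitchr` implements that counting strategy as an explicit, testable rule,
together with everything needed to exercise it end to end at desk scale: a
deterministic read simulator with a truth table, CPM/TPM normalization, and
the downstream developmental statistics (group summaries, CPM-cutoff
filtering, PCA explained variance, log-transformed t-tests, 2^-ddCt qPCR
quantification, regional comparisons).

## Feature classes and the assignment rule

Exons of a two-isoform gene fall into three classes. An exon is *specific* to
an isoform when it intersects exons of transcripts of exactly one isoform
label, and *common* when it intersects exons of two or more
(`classify_exons()`; identity is by genomic-interval intersection, not exact
coordinate equality, because near-identical exon variants should not be
called specific on a technicality). The gene emulated here has four
isoform-1-specific 5' exons (two coding, two non-coding) and a single
isoform-2-specific exon, with the common exons several kilobases downstream.

`build_feature_index()` maps every k-mer of every feature sequence to the set
of classes containing it (default k = 21: comfortably shorter than a 50-base
read, and long enough that chance matches are negligible in toy genomes;
k ≤ 31 and ≤ 32 classes are supported by the 2-bit packed implementation).
Co-classed features — the four isoform-1 exons — are indexed as separate
records by default, so no artificial junction k-mers arise; a `concatenate`
flag exists for the alternative convention.

`assign_reads()` then applies the rule that replaces a full aligner:

* a read is **assigned** to class *c* when every matched k-mer maps only to
  *c* and at least `min_hits` distinct k-mers match (default 2, so a single
  spurious k-mer hit from a sequencing error cannot assign a read);
* a read whose matches span one *specific* class plus common classes is
  assigned to the specific class when it has ≥ `min_hits` k-mers unique to it
  — the junction rule, which deliberately favors isoform evidence because
  specific-exon/common-exon junction reads are genuine isoform evidence;
* any other multi-class pattern is **ambiguous**; no matches (or a
  single-class match below `min_hits`) is **unassigned**. Ambiguous and
  unassigned reads are tallied but never counted toward features.

Mismatch tolerance is implicit — a k-mer containing an error simply fails to
match — and there is no indel handling, no expectation–maximization
redistribution and no paired-end logic, which matches the short single-end
library design being emulated.

CPM uses the total number of reads in the sample as denominator, not the
number of assigned reads: "per million reads" stays well-defined when only a
handful of features are quantified. TPM divides counts by effective length
(feature length − read length + 1, floored at 1) before rescaling to 10^6.

## What the simulator emulates — and what it does not

`make_study_fixture()` generates the whole study in a few seconds: a toy
genome with the two-isoform target gene (specific 5' exons placed > 6 kb
upstream of the shared exons), six constant housekeeping genes (one on the
minus strand, exercising strand handling), a GTF annotation, and 12
developmental ages from E14 to P60 (mapped to a postnatal-day axis:
E14 → −5, E17 → −2, P1 → 1, … P60 → 60) with 3 replicates each. The two
isoform cDNAs are constructed so that their longest open reading frames
encode 461 and 476 residues — the protein lengths of the receptor isoforms
being emulated — which gives `translate_longest_orf()` a realistic target.

Expression follows parametric trajectories: isoform 2 is an early Gaussian
peak (A = 60, t0 = −5, σ = 8 age units: high embryonically, near zero by
P21), isoform 1 a logistic rise (A = 50, t50 = 8, s = 3: low embryonically,
plateau around P15). These values were chosen once to reproduce the
qualitative design — an embryonic isoform-2 peak, a postnatal isoform-1
plateau, and a crossing between them in the P6–P10 window — at amplitudes
comparable to the housekeeping background.

Counts per transcript are negative binomial with mean proportional to
expected expression × effective length (dispersion 0.05, a typical
low-replicate bulk RNA-seq value; 0 gives Poisson), read start positions are
uniform over admissible sites, substitution errors are applied per base
(default 0.001), and qualities are a constant Phred-40 "I" since nothing
downstream consumes them. Depth is 200,000 reads per sample — a deliberate
desk-scale stand-in for ~20 million-read libraries that keeps a full 36-sample
study under two minutes while leaving hundreds of reads on the rarer isoform
at its low ages.

The simulator does **not** model GC or positional bias, PCR duplicates,
indels, strandedness ambiguity (reads are sense-strand), intron signal or
genome-scale alignment ambiguity. Passing tests therefore demonstrate that
the assignment rule and statistics are correct under clean sampling
assumptions, not that the pipeline is robust to every artifact of real
libraries.

All randomness flows from one master seed: the fixture draws one sub-seed per
sample, so any sample's reads are reproducible in isolation and byte-identical
across reruns.

## The switch report and the masking diagnostic

`switch_report()` takes the per-age group means. The crossing age is the
first age at which the isoform-1 mean strictly exceeds the isoform-2 mean
(ties therefore do not declare a crossing); on the default fixture this lands
on the first sampled age after the analytic crossing of the true
trajectories, i.e. within one age step of it. The masking diagnostic computes
Spearman correlations of the whole-gene profile against each true trajectory
and compares them with each isoform's own estimated-vs-true correlation: on
biphasic data the whole-gene profile, being approximately the sum of an
early-declining and a late-rising component, correlates weakly (and with
opposite signs) with the two trajectories while the isoform-resolved
estimates track them almost perfectly. Degenerate inputs (a constant profile,
a single expressed isoform) are flagged rather than scored.

`fit_plateau_midpoint()` closes the loop on parameter recovery: a
Levenberg–Marquardt least-squares fit of the logistic to the estimated
isoform-1 means recovers the simulated t50 to within one age unit at
default depth.

## Statistical conventions

* **t-tests** are pooled-variance Student tests on log2(x + 1) values — the
  named test of the study design — with Welch available behind a flag since
  the equal-variance label cannot be verified; the pseudocount and base are
  recorded in the result.
* **PCA** is computed on log2(CPM + 1), samples as observations, centered per
  feature, no unit-variance scaling; explained-variance fractions are
  eigenvalues over their sum. On the default fixture the first component
  carries the large majority of variance and orders samples by age.
* **2^-ddCt** normalizes the target Ct to a reference gene per sample and to
  the calibrator group's mean ΔCt; by construction the calibrator group's
  relative expression, computed from its group-mean ΔCt, is exactly 1.
* **No multiple-testing correction** is applied by default, matching the
  per-gene α = 0.05 convention of the emulated analyses; a
  Benjamini–Hochberg-adjusted column can be added by the caller via
  `p.adjust`.
* The CPM **heatmap cutoff** retains features with grand mean ≥ 10 CPM,
  boundary inclusive.

## Numerical and degenerate-input choices

Internal coordinates are 0-based half-open, converted at the GTF boundary
(1-based inclusive) only. K-mers containing N are skipped at indexing and at
query. A library of zero reads quantifies to a zero row with library size 0;
`cpm()` refuses a zero library size. All-zero counts give all-zero TPM with a
warning. Zero pooled variance with equal means yields t = 0, p = 1; with
unequal means it is an error rather than an infinite statistic. Single-sample
groups report SD 0 with an explicit flag. Crossing ties resolve to "no
crossing" because strict inequality is required.

## Interface

The package is organized as an analysis workflow: the numbered scripts under
`analysis/` (simulate → quantify → profiles → qPCR/regional) are thin
narrative drivers over the exported functions, writing their tables under
`results/`, and `run_study_pipeline()` executes the whole chain in one call.
`scripts/acceptance.R --seed N --out F` recomputes the headline quantities
from scratch and writes them as JSON.

```{r example}
library(isoswitchr)
run <- run_study_pipeline(sim_config(seed = 1L), out_dir = "results/study")
print(run$report)
```

## Known limitations

Class count is capped at 32 and k at 31 by the packed-hash design — ample for
a single locus plus controls, not for transcriptome-scale indices. The
assignment rule has no error model beyond k-mer mismatch-as-miss, so at high
error rates sensitivity decays (reads become unassigned, never misassigned —
the specificity tests show zero cross-isoform assignments at error rate 0).
The CPM scale in the toy world is inflated relative to real transcriptomes
because only ten features absorb the library; comparisons and correlations
are unaffected, but absolute CPM values should not be read as biological.
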