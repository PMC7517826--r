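---
title: "Methods and design notes for amlscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for amlscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

amlscape implements the computational core of a single-cell AML hierarchy
analysis: preprocessing of microwell 3' UMI data, discovery of malignant
transcriptional programs shared across patients, pseudo-cell correlation
mapping against reference atlases, hurdle-model differential expression,
regulon inference with attractor transcription-factor selection,
mitochondrial clone tracing from barcoded targeted long reads, and type
I/II prognosis classification. This vignette records the models, the
parameters that matter, and the design choices made where the procedure was
genuinely open — in enough detail that a maintainer can defend or revisit
each one.

## Preprocessing

Quality control keeps cells with strictly more than `min_transcripts`
(default 500) UMIs and mitochondrial fraction at most `max_mito_frac`. A
"high proportion" of mitochondrial reads is not a universal constant; 0.2
is the default because dying cells in marrow preparations typically sit
well above it while intact myeloid cells sit below, and it is an explicit
argument everywhere.

Normalization is `log2(count / nUMI * 1e4 + 1)`, i.e. log2(TP10K + 1).
There is no transcript-length correction: with 3' UMI chemistry each
molecule is counted once regardless of length, so counts-per-million-style
scaling is the correct "TPM" reading. Zeros map to zeros, so sparsity is
preserved, and the transform is invariant to per-cell count rescaling.

Highly variable genes are ranked by the residual of log1p(variance/mean)
from a loess trend over the per-gene mean (span 0.3, degree 1, symmetric
family). An earlier design used z-scores within equal-frequency mean bins;
it has a failure mode worth recording: a block of co-varying genes with
similar means can occupy an entire bin and z-score itself toward zero. The
trend residual judges each gene against the genome-wide mean–dispersion
relationship and does not have that trap.

Covariate regression is ordinary least squares per gene (one shared QR
decomposition), residuals centered, unit-scaled and clipped to ±10.
Residual standard deviations below `sqrt(.Machine$double.eps)` are treated
as zero so that perfectly fitted genes stay at zero instead of having
rounding noise amplified to unit variance. Collinear covariate columns are
dropped with a warning (QR rank detection). Two covariate conventions
coexist deliberately: scaling regresses nUMI + mitochondrial fraction
(optionally a patient indicator), while the hurdle model uses the
detected-gene count nGene — each matching the convention of the analysis it
serves.

Clustering is PCA (up to 50 components; the number of retained PCs defaults
to the largest drop in explained variance with a floor of 10 — an
automated, reproducible stand-in for interactive elbow/permutation
inspection), a k-nearest-neighbour graph (k = 20) with Jaccard
shared-neighbour edge weights pruned below 1/15, and Louvain community
detection (igraph) at the requested resolution. Labels are 0-based, ordered
by cluster size, and deterministic under a fixed seed. Note one honest
limit: "resolution → 0 gives one cluster" holds per connected graph
component; two blobs with no cross edges can never merge.

## Shared-program discovery

Malignant cells' expression is largely set by patient-specific factors, so
pooled clustering of malignant cells recovers patients, not programs. The
discovery pipeline:

1. **Per-patient subclustering** at high resolution (default 3.0) into many
   small subgroups; patients with fewer than `min_cells` (50) malignant
   cells are excluded. Subgroups cannot span patients by construction.
2. **Subgroup profiles**: the arithmetic mean log expression of member
   cells over the highly variable genes.
3. **Ward modules**: Ward.D2 clustering of profiles on Euclidean distance.
   Profiles are first centered within each patient (`center_patients =
   TRUE`). This mirrors the linear batch-effect regression used before
   pooled maps, and it is load-bearing: without it, the between-patient
   shift dominates the distance and every Ward module is one patient's
   subgroups, which the next rule then discards. The number of modules is
   chosen by maximum mean silhouette over k in [2, 12] unless fixed.
   Modules contributed by a single patient are discarded (reason
   "single-patient"), as are modules named in an analyst exclusion list
   (reason "excluded") — the generalization of a curated removal whose
   criterion is otherwise unstated.
4. **Signatures**: per kept module, one-vs-rest Wilcoxon over member cells
   against the other malignant cells. Only genes with BH FDR < `sig_fdr`
   (0.05) may enter a signature. This filter is the package's specificity
   valve: in batch-only null cohorts, weak but reproducible library-depth
   structure otherwise yields consistently ranked (though insignificant)
   "markers" and therefore spuriously stable modules. The pooled signature
   takes up to `n_total` (500) unique genes with per-module quotas
   proportional to module size, topped up round-robin; it may legitimately
   fall short of 500 when fewer genes are significant. Whether the 500 are
   per-module or pooled was an open reading; pooled-with-quota was chosen
   and the per-module tables are returned for sensitivity checks.
5. **Reclustering** of all malignant cells pooled across patients on the
   signature genes, after rescaling with a patient indicator included
   (`regress_patient = TRUE`), at moderate resolution (0.5).

Stability across seeds (`program_stability`) reruns stages 1–4 under two
seeds and matches kept modules by Jaccard overlap of their top 100
significant markers; a module is "stable" at Jaccard ≥ 0.5. Real planted
programs reappear at Jaccard ≈ 1; noise modules either lose their
significance or their gene lists.

Cluster phenotyping scores each shared cluster as the mean over member
cells of the mean log expression of a gene set, flagging clusters more than
`sd_mult` (default 1) SD above the cluster-score mean. With very few
clusters the SD rule is conservative (with two clusters no score can exceed
mean + 1 SD); lower `sd_mult` when the shared landscape has under ~5
clusters. Group assignment is arg-max over the four set scores with the
fixed tie priority RP > neutrophil > monocyte > myeloid, and an RP-high
flag always wins — it is the prognostic category.

The malignant mask is the caller's choice: either truth/annotation, or
operationally the cells whose best reference correlation falls below the
unmatched threshold of `map_cells`.

## Pseudo-cells and correlation analyses

Pseudo-cells average `k` cells of one cluster: `random` mode partitions a
seeded shuffle into groups of k (20 is the convention for random
averaging), `top_detected` takes consecutive groups of the k cells with
most detected genes (50 is the convention there). The terminal remainder
keeps its own pseudo-cell when it holds at least k/2 cells and is dropped
otherwise; clusters below k/2 are skipped with a warning. The size-weighted
mean of pseudo-cell profiles equals the mean of the used member cells.

Correlation networks use Pearson r on profiles with a strict threshold
(r > 0.65 for cell–cell networks); a value exactly at the threshold is
excluded, and zero-variance profiles are dropped with a warning because
their correlations are undefined. Expression for these analyses is
normalized to counts per 100,000 (optionally log1p); whether mapping should
run on log or linear scale is exposed through which matrix the caller
passes, with log1p(CPM×1e5) the default used by `build_reference`.

Reference atlases take the union of each type's top 20 one-vs-rest Wilcoxon
markers as the gene panel and the per-type mean expression over that panel
as profiles. `map_cells` correlates each query cell with each type profile
over the shared panel (error below 5 shared genes) and flags cells
"unmatched" below max-r 0.6 — a configurable operational proxy for a
malignant state that matches no normal type; no universal numeric criterion
exists for that judgement.

Cross-batch similarity follows the neighbour-voting idea: batch-B cells are
ranked by mean correlation to a batch-A type over the variable genes, and
the AUROC of each B type against that ranking (Mann–Whitney U with
mid-ranks) is reported; pairs at AUROC ≥ 0.7 form the linkage table. The
implementation is a single fold with mean-correlation ranking — the
cited methodology's spirit without its cross-validation machinery, which the
source does not parameterize.

The specificity screen removes from a ranked disease marker list every gene
found in any reference type's top-marker list. The gene–gene network first
removes genes expressed in fewer than 3 profiles, then takes each seed
gene's `top_m` partners by |r|.

## Hurdle differential expression

For gene expression y (log2(TP10K+1)) with group indicator and nGene
covariate: a logistic model for P(y > 0) and a Gaussian model for y given
y > 0, each tested against its group-free null by a likelihood-ratio
statistic (1 df each); the combined statistic is their sum with df = number
of components actually fitted (a component is dropped when it is degenerate:
no zeros, under 3 positive cells, or a constant group among positives).
The Gaussian LRT is n·log(RSS0/RSS1). The reported log2FC is the difference
of group means including zeros, matching the volcano-axis convention; the
discrete and continuous coefficients are also returned, and the combined p
is the default ranking.

Numerical choices: nGene is standardized before fitting; a constant nGene
column is dropped rather than fitted (a silently singular design would
otherwise zero the statistic). Perfect separation in the logistic part is
detected (fitted probabilities at the boundary or runaway coefficients) and
handled by an IRLS refit with a small ridge penalty (1e-4) on non-intercept
coefficients, flagged per gene. Variance shrinkage / empirical Bayes is
deliberately out of scope: the hurdle structure, not moderation, is the
method here.

`de_test` downsamples each group evenly to at most `max_cells` (10,000)
with the given seed, applies the fit gene-wise, and BH-adjusts over tested
genes. `common_unique` intersects significant genes by direction across two
comparisons and sub-flags a supplied ribosomal-protein list.

## Regulons and attractor TFs

Mutual information uses equal-frequency binning on mid-ranks (default 8
bins) and the plug-in estimator in nats; it is symmetric by construction.
The plug-in estimator's positive bias is shared by the permutation null, so
the default edge threshold — the 99th percentile of MI between permuted
gene pairs (500 draws, seeded) — is bias-matched; a fixed `mi_threshold`
can be supplied instead. DPI then marks, in every triangle whose three
edges exist (which requires two TFs), the weakest edge as indirect when it
is below both others by more than `dpi_epsilon` (0 = classic rule); marks
are applied after the scan, so the strongest edge of a triangle is never
removed. Edge sign is the Spearman correlation sign; weight is the MI rank
normalized within each TF's regulon. Bootstrapping and adaptive
partitioning of the full network-reconstruction machinery are omitted —
at pseudo-cell scale (tens to hundreds of profiles, ≤ ~2,000 genes) the
binned estimator with a permutation threshold is adequate and transparent.

Enrichment of a regulon against a DE z-score signature is
`NES = Σ w·m·z / sqrt(Σ w²)`; for independent standard-normal z this is
exactly standard normal, giving the two-sided p, with BH over TFs. TFs
with fewer than 5 usable targets are skipped.

Target pruning removes targets with DE FDR strictly above 0.05 (0.05
itself is kept, matching the stated removal rule); it is idempotent.
Attractor selection takes candidates with enrichment FDR < 0.05 and
NES > 0, computes the gene score `|log2FC|·(−log10 FDR)` (FDR floored at
1e-300 before the log), and keeps a TF iff its pruned targets' scores are
significantly higher than all other DEGs' scores by one-sided Wilcoxon at
α = 0.05 — the significance level is unstated in the source and exposed as
a parameter. The Wilcoxon p is computed by complete enumeration of
rank assignments when both groups have ≤ 8 observations (exact under ties),
and by the tie-corrected normal approximation with continuity correction
otherwise; TFs with fewer than 3 target DEGs are flagged unselectable. The
attractor network is pairwise Pearson r over pseudo-cells among selected
TFs with strict r > 0.3.

## Long-read clone tracing

Reads below predicted CCS accuracy 0.9 (strict) are removed; reads lacking
the accuracy tag pass with a warning, assuming instrument-filtered input.

Parsing scans the forward strand then the reverse complement for
`ACGT + CB1(6) + linker1(15) + CB2(6) + linker2(15) + CB3(6) + UMI(6) +
polyT(12)`; the 12-nt block between linker2 and the polyT is read as
CB3 + UMI per the three-segment barcode + 6-nt UMI design. Candidate
anchors are every exact `ACGT` occurrence plus always the read start, and
the anchor itself may carry one mismatch: consensus long reads still carry
residual errors, and an exact 4-mer anchor requirement would reject about
1 − 0.98⁴ ≈ 8% of reads at a 2% error rate for no downstream benefit. Each
linker tolerates `max_mm` (2) mismatches, and at least 8 of the 12 polyT
positions must be T (tolerating sequencing error in the tail). The leftmost
passing window wins; rejections carry a reason code (linker1, linker2,
polyT, no-anchor, too-short).

Barcode correction is per 6-nt segment against the whitelist's segment sets:
a unique nearest segment within `max_seg_mm` (1) is accepted; ties at the
minimal distance yield no correction. With segment sets at pairwise Hamming
distance ≥ 4 (as designed bead barcode sets are), any read segment with at
most 2 errors either corrects to the true segment or is rejected — it can
never correct to a wrong one.

Alignment of the cDNA to the single-gene target is k-mer seeded (k = 12,
seeds every 8 bases) gapless extension on both strands, scoring the full
overlap along each candidate diagonal; "well-mapped" means aligned fraction
≥ 0.8 of the cDNA and identity ≥ 0.9. Gapless is a deliberate fit to
consensus reads whose residual errors are substitutions; indel-rich reads
should come in through the external-alignment import (SAM/PAF) instead.

Variant calling is a transparent, deterministic pileup replacing a
black-box somatic caller: reads sharing (cell, UMI) are collapsed to a
majority consensus base per position (ties → N, ignored), then per cell a
site is reported when UMI depth ≥ 20, alternate count ≥ 3 and alternate
fraction ≥ 0.05; heteroplasmy is alt/depth. Before clone assignment,
`filter_variant_calls` keeps sites called in ≥ 3 cells with mean
heteroplasmy ≥ 0.2 and drops per-cell calls below heteroplasmy 0.1. This
separation step matters quantitatively: at 2% substitution error and ~50
UMIs per cell, the per-cell thresholds alone admit a few sporadic
error-driven calls per cell across a ~600-base target, which would fragment
every clone's variant pattern; clone-defining heteroplasmy recurs across
cells at high fractions and survives the filter, sequencing error does not.

Clones are the distinct observed variant-presence patterns (the
intersection patterns of an UpSet tabulation); patterns below `min_cells`
(3) merge into "unassigned", and the variant-free pattern is the wild-type
clone. Clone–phenotype association is Cramér's V of the clone × cluster
table with a permutation p = (1 + #{V_perm ≥ V_obs}) / (1 + n_perm).
Coordinates are 0-based half-open internally; exported variant tables are
1-based.

## Prognosis

Type I means the progenitor cluster holds strictly more than 50% of a
patient's cells; exactly 50% is type II. Remission rates are
CR / (CR + non-CR) per type with patients lost to follow-up excluded,
reported as percentages rounded half-up to two decimals (half-up, not
banker's rounding, reproduces two-decimal clinical reporting: 5/9 →
55.56%, 16/19 → 84.21%). The hypergeometric test is the exact one-sided
lower tail for the CR count among type I patients given the margins — the
natural alternative is a remission deficit in the high-progenitor-burden
group. The tail is computed by direct summation of the point masses and is
checked against complete enumeration in the tests; at the 5/9 vs 16/19
margins this exact tail is 0.123, and the package reports what it computes.
Dominant phenotype groups per patient are plurality votes over progenitor
cells with the RP > neutrophil > monocyte > myeloid tie rule, summarized as
a 2×2 (RP-high dominant vs other) × (CR vs non-CR) table with Fisher's
exact and hypergeometric p-values.

## The synthetic-data generator

`simulate_bmmc` draws counts from a gamma–Poisson (negative binomial)
model: per-gene log2 abundances are normal (SD 1.5), lineage markers add
`marker_log2fc` (3) in exactly one lineage, malignant cells carry a
dampened HSPC-like identity (half marker effect, emulating a progenitor
state) plus one of `n_programs` (2) shared programs at `program_log2fc`
(2) over `program_size` (100) genes; the ribosomal-protein-like module
(`rp_size` 50, log2FC 2) rides on program 1. The patient batch effect is a
per-patient per-gene log-normal factor (`batch_sd` 0.5) — the simplest
structure that makes naive pooled clustering split by patient, which the
discovery pipeline must overcome. Library sizes are log-normal
(median 2,500 UMIs); rates are renormalized per cell, so planted effects
are relative abundances and pseudo-bulk ratios should be read after
median-of-ratios centering. A small fraction (2%) of cells is simulated as
dying (15% depth, 8× mitochondrial leakage) to give QC something real to
remove, and ~10 `MT-` genes carry ~5% of counts. Mitochondrial clones
(3 per patient, uneven sizes) are assigned to malignant cells independently
of the expression program, emulating the observed decoupling of genetic
subclones from phenotype.

`simulate_long_reads` builds each read as the barcode layout above plus the
reverse-complemented target cDNA, plants each clone variant on each
molecule independently at its heteroplasmy fraction, applies i.i.d.
substitution errors, and flips a configurable fraction of whole reads to
the opposite strand. Barcode segments come from the hexacode — the
[6,3,4] linear code over GF(4), 64 words at pairwise Hamming distance ≥ 4 —
because that is what a designed bead barcode set looks like and because a
greedy random sampler cannot reach usable set sizes at that separation.
PolyT length is fixed at 12 to match the written pattern.

What the generator does **not** emulate — and what passing tests therefore
do not demonstrate about real data: doublets, ambient RNA, indel sequencing
errors (substitutions only; the alignment import path exists for indel-rich
data), transcript-length effects, cell-cycle structure, continuous
differentiation trajectories (lineages are discrete), and realistic
gene–gene correlation beyond the planted blocks. Clone heteroplasmies are
planted at 0.5–0.9 in the end-to-end checks; much lower-heteroplasmy
variants would need deeper UMI coverage or laxer thresholds than the
defaults.

## Problem sizes and determinism

Every stochastic operation takes an explicit seed and is bit-reproducible
under it. The shipped checks run the discovery pipeline on 3 patients ×
1,000 cells (≈1,500 malignant) with 2,000 genes, the null-specificity sweep
on twenty 3×400-cell batch-only cohorts, hurdle calibration on 2,000 null
genes at 200+200 cells, and clone tracing on 200 cells × 50 reads over a
600-base target at 2% substitution error — sizes chosen so the full suite
exercises every stage of the method at statistically meaningful scale on a
single CPU in minutes.

## Known limitations

- Louvain clustering depends on graph connectivity; cluster-count limits
  hold per connected component.
- The marker scan's normal-approximation Wilcoxon is asymptotic; exact
  enumeration is used only in the attractor selection (small groups).
- The Gaussian LRT uses the ML variance; calibration is asymptotic and was
  verified at the 200+200 scale, not for very small groups.
- The MI estimator is the plug-in; absolute MI values are biased upward and
  only comparisons against the matched permutation null are meaningful.
- `align_target` is gapless; use external aligners (via `read_alignments`)
  for indel-bearing reads.
- The hypergeometric remission test is one-sided in the deficit direction;
  other constructions of "the" test on the same margins give other values.
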