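---
title: "Models and methods behind embryolin"
author: "embryolin maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind embryolin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models, parameter choices and numerical
conventions of the package, in the order the pipeline runs them, and
states what the synthetic-data generator does and does not emulate.
Every empirical number referenced here is computed by the test suite or
by `scripts/acceptance.R`; nothing is asserted beyond what those runs
measure.

## The data model

The central container, `EmbryoExpression`, extends
`SingleCellExperiment`: a gene-by-cell RPKM matrix, gene annotation
(chromosome, 1-based start, length, spike-in flag) and cell metadata
(embryo, embryonic day 3–7, sex, QC flag). All correlation, PCA,
embedding and clustering work uses `log2(RPKM + 1)`; Spearman-based
steps are unaffected by this monotone transform, and the pseudo-count
keeps zeros finite. Allele-level data live in `AlleleCounts`: one row
per (cell, SNV) with reference/alternative read counts. Reference and
alternative are arbitrary labels — parental phase is unknown — so every
allelic statistic is phase-free.

## Quality control and sex

A cell passes QC when its maximum Spearman correlation to any other
cell (spike-ins excluded) reaches `rhoMin = 0.63`. Spike-ins carry no
biological signal and are excluded from all downstream biology; their
only role is the technical-noise fit. Sex is classified from the sum of
Y-gene RPKM: below 50 female, above 100 male, between unknown; embryo
sex is a majority vote with a conflict flag. Cells of unknown sex are
excluded from sex-stratified analyses but retained for lineage work.

## Technical noise and variable genes

Spike-in squared coefficients of variation are regressed on inverse
mean, CV² = a₁/μ + α₀, by ordinary least squares; a negative slope is
clamped to zero (technical variance cannot decrease with 1/mean). A
gene's variability score is the ratio of its observed CV² to the
expected CV² at its mean, a₁/μ + α₀ + CV²_bio with a baseline
biological CV of 0.5; a one-sided F-type tail probability accompanies
the ratio, genes rank by descending ratio with lexicographic ID
tie-breaks, and only genes expressed (RPKM ≥ 1) in at least 5% of the
cells are scored. The pipeline uses the top 500 genes globally and the
top 250 within a day.

## Pseudo-time

Cells are embedded in two dimensions and a Hastie–Stuetzle principal
curve is fitted: iterate projection onto the current polyline and
per-coordinate spline smoothing against arc length, at most 50
iterations, converged when the mean projection displacement falls below
10⁻⁴ of the coordinate range. Numerical conventions: the spline uses
4–8 effective degrees of freedom depending on cell count; degenerate
(coincident) inputs are an error; when the smoother fails on
near-degenerate scatter a cubic polynomial fit substitutes. Because the
iteration can settle on a curve that threads the cloud orthogonally to
developmental time, the fit is started from both principal-axis
initializations and the curve whose arc-length positions correlate best
with the day labels is kept — the day labels already define the curve's
orientation, so using them to pick the initialization introduces no new
information. Positions are finally rescaled so per-embryo means regress
on day with slope 2.5 and intercept 0; on this clock 12.5 corresponds
to day 5 and is the default pre-lineage gate. This scale is a
reconstruction: it gives the gate an operational meaning ("embryos
younger than mid-E5") rather than reproducing any published unit.

The pipeline's default embedding for pseudo-time is PCA rather than
t-SNE. At a few hundred cells a t-SNE layout folds locally and the
principal curve can thread it out of developmental order, while the
PCA and diffusion alternates order cells by day equivalently; t-SNE
remains available (`embed2D(..., "tsne")`, perplexity 30, fixed seed).
Epiblast/primitive-endoderm cells sit on side branches and project
onto the branch junction, so cell-level pseudo-time is meaningful for
non-ICM cells, and branch cells are timed at the embryo level (the
mean over member cells) — this is also why `assignPseudotime` accepts
an exclusion mask for the curve fit.

## Lineage classification

Per day d ∈ {5, 6, 7}, cells of embryos past the pseudo-time gate are
split by PAM (k-medoids, deterministic greedy build initialization) on
the first two principal components of the day's top 250 variable
genes, and the two clusters are labeled TE versus ICM by marker panels
with weights +1/−1 (panels ship as an editable YAML in
`inst/extdata/`); ICM cells are split again into EPI versus PE with
variable genes recomputed among them; TE cells of days 6–7 are split
into polar versus mural, labeled by the polar-gene z-score. Days 3–4
are always pre-lineage.

Two design choices deserve emphasis:

* **The no-split gate is 0.45 mean silhouette.** A forced two-way PAM
  split of genuinely unstructured cells in a 2-PC space does not score
  near zero: on simulated pre-lineage days the average silhouette is
  roughly 0.28–0.41, while genuine lineage splits score about
  0.6–0.85. The gate is placed between those two regimes and is
  config-exposed; the test suite measures the false-split rate over 20
  simulated null days.
* **Sex chromosomes are excluded from split-defining gene pools.** All
  X-linked genes shift coordinately ~2-fold between sexes before
  compensation, which in a 2,000-gene panel forms a bimodal axis that
  can out-compete the lineage axis in a k = 2 clustering (a 15,000-gene
  transcriptome dilutes it). Marker scoring and all expression
  statistics still use every gene; the exclusion (config-exposed)
  applies only to the variable-gene pools that define splits.

## Lineage-specific genes

Differential expression is a two-sided Wilcoxon rank-sum test per gene
on log2(RPKM + 1) — chosen over a parametric single-cell error model
because it is robust, dependency-free, and the downstream consumers
(rankings and recalls) are insensitive to the engine; the test function
is a config hook. Genes expressed in fewer than 10% of both groups are
not tested; fold-changes use pseudo-count 1. Signed Z scores are
combined by Stouffer's method, Σz/√k: within a day (one lineage against
each of the other two) and then across days E5–E7 ("maintained" genes),
with BH FDR ≤ 5% at each level. The two within-day contrasts share the
reference lineage's cells, so the combined scores are mildly
anti-conservative; at small, sex-imbalanced strata this admits some
X-linked genes into the lists, which shrinks with cohort size.

Within-embryo variability is the squared CV of log2(RPKM + 1) across an
embryo's cells, computed only where the embryo expresses the gene (mean
RPKM ≥ 2): the CV of a barely detected gene measures dropout noise, not
regulation, and otherwise dominates every peak-time estimate. The score
is regressed on embryo pseudo-time by OLS; genes scored in fewer than
three embryos are missing.

## Segregation scoring

A diffusion map (Gaussian kernel; bandwidth = median pairwise distance,
which is parameter-free and deterministic; symmetrized normalization;
sign fixed by the largest-magnitude loading) embeds cells on the
lineage-specific genes — in the pipeline, the E5 FDR ≤ 5% set, whose
size on real data need not match any fixed count. A linear soft-margin
SVM (C = 1) on the matured cells defines the decision surface;
coordinates are first divided by the square root of their mean
per-component variance, so distances are in normalized component units
and rigid rotations leave them unchanged. Segregation versus time uses
per-embryo mean |distance|, a least-squares one-step changepoint (the
reported changepoint is the midpoint between the flanking embryos, with
the 90%-of-plateau crossing reported alongside). Because commitment
unfolds over an activation ramp rather than instantaneously, the
changepoint localizes the rise to within about a day — the test asserts
that precision, not a sharper one. Uncommitted cells already co-express
early program genes, so matured cells sit roughly 2–3× (not 10×)
further from the boundary than pre-lineage cells.

## X-dosage statistics

Per-gene female:male ratios use (mean_F + c)/(mean_M + c) over
transcribed genes (mean RPKM ≥ 1 in at least one sex). The pseudo-count
default is c = 0.5: with transcribed-gene means of order 10–20 RPKM, a
pseudo-count of 1 biases the chrX median ratio downward by several
percent — enough to corrupt the recovery of a dampening factor as
d̂ = ratio/2 — while 0.5 keeps the estimator nearly unbiased yet still
stabilizes lowly expressed genes. Moving-average tracks use the 25
positionally nearest expressed genes, truncated symmetrically at
chromosome ends; the implementation is tested against an O(n·w)
brute-force oracle for exact equality. The X0 screen compares an
embryo's chrX track with same-day female and male references and flags
a sex-called-female embryo whose profile is closer to the male
reference over ≥ 80% of positions; flagged embryos should be excluded
from dosage analyses only.

## Allelic classification

With total reads t = ref + alt: t < 3 is undetected; otherwise the
site is biallelic iff the minor allele has ≥ 2 reads and ≥ 10% of t.
These cutoffs are reconstructions (robust to sequencing noise,
validated on simulated truth) and config-exposed; the
dampening-versus-XCI discrimination holds across a minor-fraction grid
of 0.05–0.2. The per-cell relative biallelic ratio divides the chrX
biallelic fraction by the autosomal one, each requiring ≥ 25 detected
SNVs; per-chromosome variants of the autosomal reference (chr1–3)
serve as negative controls. Group comparisons of biallelic proportions
use Fisher's exact test.

## The synthetic-data generator

`simulateExperiment` draws expression as Gamma–Poisson: spike-ins
exactly satisfy CV² = a₁/μ + α₀ (default a₁ = 5, α₀ = 0.1) via a scaled
negative binomial with no dropout; biological genes add a gamma burst
factor (dispersion 0.25, i.e. biological CV 0.5) and mean-dependent
logistic dropout. Reference conditions: 6/6/8/8/8 embryos for days
E3–E7 with 8–16 cells each (~430 cells — a deliberate scale-down of a
full study, sized so the complete suite runs in minutes); 2,000 genes
plus 60 spike-ins; 160 X-linked genes; lineage programs of 100 genes
each with early/mid/late activation waves; 60 polar-TE genes; 250
temporally trending genes (±0.3–1.0 log2/day, reflecting that most
between-day contrasts in real data carry large gene sets); 50 decaying
maternal transcripts. Trophectoderm folds (2^3.5–2^5.5) deliberately
exceed EPI/PE folds (2^2.8–2^4.2), mirroring the much stronger TE–ICM
divergence seen in real blastocysts; this also makes the first k = 2
split merge EPI with PE rather than pairing arbitrarily.

Commitment is at day 4.75 (blastocyst formation begins late E4/early
E5, so most E5 embryos carry lineages); committed waves activate along
logistic ramps (scale 0.25 day), while the uncommitted co-expression
state rises slowly and *uniformly* (scale 0.7 day) at 50% of the
committed level — the pre-lineage state is homogeneous within a day,
heterogeneity appears only at commitment, and consequently forced
splits of pre-lineage days find no structure. Y genes are male-only at
30% of their mature level on E3 (incomplete genome activation) —
enough to classify sex, low enough to show the E3→E4 activation jump.
XIST ramps up in females from E4 and escapes dampening; under XCI it is
expressed from the silenced X.

X dosage: each female cell carries (maternal, paternal) activity
factors — (1, 1) for two active X; (d, d) under dampening with a
non-increasing per-day schedule reaching d = 0.55 at E7 (~70–85%
compensation); under XCI one whole allele per affected cell is zeroed
with a non-decreasing completion schedule. Allele reads are Poisson in
the cell's expression value and split beta-binomially (concentration
20) around the allele-activity ratio; per-embryo phase is randomized.
Lingering maternal transcripts make 30% of male E3 chrX reads derive
from the second allele, which vanishes from E4.

What the generator does **not** emulate: read-level data (no FASTQ/BAM;
RPKM-like values are drawn directly), batch and plate effects, embryo
ploidy abnormalities beyond the optional X0 embryos, gene-length biases
in dropout, linked SNV haplotype blocks (one SNV per gene by default),
strand-resolved loci (the XIST/TSIX overlap cannot be represented at
matrix level), and real marker-gene co-regulation — marker names are
attached to simulated program genes so the default panels apply, but
their correlation structure is the program's, not the genome's.
Passing tests therefore demonstrate that the machinery recovers truth
under these idealized conditions, not that it is robust to every
artifact of real embryo data.

## Known limitations

* Cell-level pseudo-time is undefined on lineage branches (ICM cells
  project onto the junction); use embryo-level times there.
* The Stouffer combinations assume independent contrasts; shared
  reference cells make the maintained lists mildly anti-conservative.
* The silhouette gate is calibrated for two-way splits in a 2-PC
  space; other dimensionalities need recalibration (it is
  config-exposed).
* The segregation changepoint has ~1-day resolution because commitment
  itself is gradual.
* All allelic thresholds are reconstructions; sensitivity to them is
  tested but values on real data may need revisiting.
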