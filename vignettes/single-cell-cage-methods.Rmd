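---
title: "Models and methods behind sccage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sccage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sccage)
```

This vignette is the package's account of its science: the generative
model behind the synthetic data, the statistics each processing stage
computes, the numerical conventions, and the places where the design was
genuinely open and a choice had to be made.

## 1. The generative model

A synthetic experiment is a grid of `n_runs` microfluidic runs ×
`timepoints` × `cells_per_run_per_timepoint` capture chambers. Each
chamber is empty (`empty_rate`, default 4%), a doublet (`doublet_rate`,
3%) or a singlet; doublets pool two independently drawn cells, empty
chambers receive only the spike-in mix (the spikes ride in the reagents,
which is also why empty chambers show an extreme spike proportion and are
caught by QC).

**Bursty expression.** For feature *f* in cell *c* at timepoint *t*, the
feature fires a burst with probability π (`burst_prob`, default 0.3),
modulated per feature and timepoint by a logit-normal factor
(`timepoint_effect_sd`, default 0.5 on the log-odds scale) so that
timepoints carry reproducible biological signal. Given a burst, the
molecule count is negative binomial with mean μ (`burst_size_mean`,
default 20 molecules) and dispersion φ (`burst_size_dispersion`, 0.5;
variance μ + φμ²). This Bernoulli-gate × negative-binomial model is the
simplest one that reproduces the hallmark of single-cell 5′ data — high
expression in few cells — without claiming mechanistic detail.

**Enhancers.** Each enhancer locus carries `allele_count` alleles
(default 2). Every allele gates and bursts independently, picks the plus
strand with probability θ (`enhancer_strand_prob`, 0.5) and commits *all*
of its molecules to that strand. Strand exclusivity is therefore a
per-allele property: a single cell shows a mixed-strand locus only when
both alleles fire and disagree (probability π²·2θ(1−θ) ≈ 4.5% at the
defaults), which is what keeps within-cell bidirectionality scores near 1
while the pool is balanced. θ is exposed rather than fixed because
per-locus strand bias of real enhancers is not established.

**Batch effect.** Each run shifts burst sizes additively on the log2
scale (`run_batch_shift`, defaults 0, +0.75, −0.75) — a strong,
correctable run-level effect.

**Tag emission.** A molecule is captured with probability *p*
(`capture_prob`, 0.5) and then emits exactly one tag pair. Its 5′ end
falls on the feature's first base with probability *q*
(`first_base_prob`, 0.8); otherwise it is shifted downstream, in strand
sense, by 1 + a geometric offset with mean `offset_mean` (10 nt),
truncated at 50 nt — a sharp first-base mode with a short tail. With
probability `invasion_rate` (0.1) the captured molecule is emitted
instead as a strand-invasion artifact at a planted site (below).
Fragment ends are drawn *distinct within each (cell, chromosome, strand,
5′ position) group*, so coordinate-based duplicate collapse never merges
two genuine molecules; this makes molecule-count recovery exactly
testable and mirrors the low per-position collision probability of real
fragmentation at these depths.

**Planted artifacts.** The toy genome is generated free of `GGG`/`CCC`
trimers; artifact sites, in a reserved zone of each chromosome away from
all features, then get the linker trimer written immediately upstream (in
read-strand sense). Consequently the upstream-linker filter can be
benchmarked at exact recall *and* precision — every flagged tag is a
planted artifact and vice versa. With `invasion_exact = FALSE` the
planted context carries one mismatch, for exercising mismatch-tolerant
matching (exact precision is then no longer guaranteed, since one-off
contexts occur naturally).

**Fluorescence.** Each (run, timepoint) gets a color code in
{G, R, GR} by a rotated (Latin-square) design: a seed-permuted base order
shifted by one position per run. Independently random per-run
permutations can make stain collinear with timepoint — the batch
detrending step then rightly refuses — so the rotation is part of the
design, exactly as permuting dye combinations across replicates is the
point of color multiplexing. Stained channels read
`fluor_signal_mean` (1000 a.u.) plus Gaussian noise
(`fluor_noise_sd` = 50), unstained ones `fluor_background_mean`
(100 a.u.); at these defaults the channels are ~9 SD apart and
demultiplexing is essentially error-free.

**Spike-ins.** The bundled design has 92 species in four subgroups of 23
with mix1:mix2 input ratios 4, 1, 2/3 and 1/2; within a subgroup,
concentrations are log-uniform over 3.5 decades. Two choices are
deliberate: (i) subgroup scale factors (1, 1, 0.5, 0.5) make the two
mixes *equal in total input*, so per-library depth scaling leaves
relative fold changes unbiased; (ii) the default `spike_dilution = 1`
puts ~3,000 molecules in a chamber — desk scale — while the
mix1-versus-mix2 fold-change comparison, which emulates a *library pair*
rather than a chamber, is run at `spike_dilution = 10` (~31,000
molecules, ~6,000 captured reads per library at p = 0.2). At
single-chamber depth the subgroup-median species has only a few reads
and any zero-guard inflates toward the pseudocount; the library scale is
the regime the fold-change figure describes.

## 2. Processing stages and their statistics

**Tag processing.** Pairs sharing cell, chromosome, strand and full
fragment coordinates collapse to one (first occurrence kept). A tag is a
strand invader iff the `nchar(linker)` genomic bases immediately
upstream of its 5′ end, reverse-complemented for minus-strand tags,
match the linker (`GGG`) with at most `max_mismatch` (0) mismatches;
tags lacking upstream context are left unflagged and tallied. Invaders
are removed before counting by default (a switch retains them, flagged,
since quantifying rather than removing is also defensible). Promoter
intervals are subtracted from enhancer intervals (pieces keep their
locus id; empty results are dropped). Masked tags are removed strand-
insensitively. Counting is by the 5′ base only, half-open intervals:
promoters/mitochondrial/spike rows require strand match; enhancer counts
split into `locus:+` / `locus:−` rows by *tag* strand. Per cell,
`counted + unannotated + masked + invaders + duplicates = input` — an
accounting identity asserted in the tests.

**Demultiplexing.** Per channel, an exhaustive Otsu-style threshold
splits intensities in two; the decision boundary is the midpoint of the
two class means. Codes map through the run's design row; chambers coded
`none` or curated empty/dead/doublet stay unassigned. Curation is taken
from the chamber table, never computed from images.

**Cell QC.** A cell fails if `log2(library size)` or
`log2(feature count + 1)` is more than 3 MADs (1.4826 consistency
constant) below the median, or mitochondrial/spike proportion more than
3 MADs above. Sizes are filtered on the log scale, proportions raw. The
inequality is strict — a cell exactly at the boundary passes. A metric
with zero MAD filters nothing. Features expressed in fewer than 2 cells
or with mean count below 0.3 (strictly) across QC-passing cells are
dropped; the mean is over passing cells because the filters apply in
that order.

**Normalization and batch detrending.** Size factors are library sizes
over their geometric mean, rescaled to mean 1; values are
`log2(count/sf + 1)`. Library-size factors replace pooling-deconvolution
estimators deliberately: under the generator's balanced design,
composition bias is absent and depth factors are exact; a hook
(`normalize_counts` being a plain function returning the factors) lets an
alternative estimator be substituted. Batch detrending is per-feature
least squares on run (and optionally stain) indicators with timepoint as
a protected covariate, via `limma::removeBatchEffect`; a rank check
refuses designs where batch is confounded with the protected covariate.
High-variance features are those whose variance exceeds a running-median
mean–variance trend by more than the 75th percentile of the positive
excesses; no significance step is attached (a deliberate simplification —
see limitations).

**Spike metrics.** Accuracy is the Pearson correlation of observed
counts with input molecules, both `log2(x+1)` by default (the linear
option is kept for sensitivity checks; on log scale the
concentration-versus-molecules distinction is a constant and cancels).
The detection limit comes from a per-cell binomial-family logistic fit
of detected on log10(molecules): `limit50 = 10^(−β₀/β₁)`. Cells with
complete separation get the geometric midpoint of the separating gap and
a flag; all-detected / none-detected cells are censored; a non-positive
slope is flagged non-identifiable. Fold-change recovery scales the two
libraries to a common depth, computes per-species log2 ratios with a
*zero-guard* pseudocount (0.5 added to both scaled counts only for
species with a zero count — unconditional addition shrinks every
detected species' ratio toward zero and biases the subgroup median
noticeably at desk-scale depth), summarizes subgroups by the median
member ratio, and reports R² of observed on expected log2 ratios.

**Enhancer analysis.** Scores, selection (`≤ 0.5` pooled score — the
inclusive convention was adopted since both strict and inclusive
phrasings are in circulation; a `strict` flag flips it — with ≥ 10
strand-summed reads in ≥ 5 cells), per-cell scores for any cell with ≥ 1
locus read (unweighted mean across cells; no depth weighting), and
depth-matched references by hypergeometric draws without replacement
from the pooled strand multiset (100 replicates) — "downsampling a
pooled set" means sampling from that fixed multiset, hence without
replacement. Gini uses the sorted closed form of the pairwise
mean-absolute-difference definition on `log2(count+1)` (identical to the
O(n²) definition to 1e−12; the +1 keeps values nonnegative as Gini
requires); all-zero vectors are undefined. The promoter-versus-enhancer
Gini comparison uses the two-sample KS test, exact when either side has
fewer than 30 values and asymptotic otherwise. Detection-by-stratum bins
features within class into quantile bins of pooled ("bulk") expression
and reports each cell's detected fraction per bin.

## 3. Numerical conventions and degenerate inputs

* Coordinates are 0-based half-open (BED) everywhere in memory; the 5′
  end of a minus-strand record is `frag_end − 1`. 1-based arithmetic
  exists only inside GRanges conversions and string indexing.
* Zero-read loci have undefined (NA) bidirectionality; zero-variance
  vectors make correlations and R² NA rather than 0.
* Overlapping same-class regions (impossible for generated annotation,
  possible for user input) assign a tag to the first region in sorted
  order, with a warning.
* All stage seeds derive deterministically from one master seed and the
  stage name (`stage_seed`), so stages rerun in isolation reproduce the
  pipeline; identical configuration implies byte-identical outputs.
* Default problem sizes: unit tests run 2 runs × 2 timepoints × 5
  chambers with ~35 features; the study-scale checks run the full
  default configuration — 3 runs × 3 timepoints × 30 chambers, 500
  endogenous features, ~800k tags — once and complete in about a minute.

## 4. What passing tests do and do not show

The generator provides exact ground truth, so the suite can assert exact
duplicate-collapse behavior, exact artifact recall/precision, exact
count conservation, and calibration of capture and first-base rates.
What it cannot show: robustness to sequencing error, quality-score
handling, UMI behavior (UMIs are deliberately not used for counting;
deduplication is coordinate-based), realistic fragment-length
distributions, composition bias between cells (library-size factors are
exact here but not in general), image segmentation, or any property of
real genomes (repeats, nucleotide composition, overlapping annotation).
Mitochondrial features are ordinary bursty features tagged `mito` purely
to exercise the QC metric.

## 5. Known limitations

* **Logistic detection limit is biased against the binomial-capture
  closed form.** If detection truly follows 1 − (1−p)ⁿ, the 50% point is
  ln(0.5)/ln(1−p); but that curve is complementary-log-log-shaped, and
  the logistic fit's 50% crossing lands systematically ~15–18% low for
  any log-uniform molecule design (measured asymptotically on several
  grids). This is a property of the standard estimator, not of the
  implementation; limits from logistic fits should be compared only with
  limits fitted the same way.
* **No FDR step in high-variance selection**; the quantile rule alone
  over-selects relative to a significance-controlled rule.
* **Library-size factors instead of pooling-deconvolution**; exact under
  the generator, optimistic for real data with composition effects.
* **PCA denoising is out of scope**; batch handling is the linear-model
  step only.
* The fold-change zero-guard pseudocount makes ratio estimates of
  sparsely detected species depend on the guard value; subgroup medians
  are robust to this, per-species ratios of near-zero species are not.
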