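---
title: "Enhancing GWAS signals with a deep neural network: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enhancing GWAS signals with a deep neural network: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genome-wide association studies (GWAS) test millions of variants one at a
time and call a variant significant at the conventional threshold
p < 5×10⁻⁸. Sample size is the dominant driver of power, and for many
phenotypes — neuropsychiatric disorders in particular — collecting another
order of magnitude of cases is impractical. Yet a standard GWAS treats all
variants as a priori exchangeable, ignoring decades of accumulated evidence
that trait-associated variants concentrate in regulatory sequence, in
conserved positions, and in linkage disequilibrium (LD) with one another.

`gwasdnn` treats signal enhancement as a supervised learning problem on the
variant level. Each variant is represented by a 33-dimensional feature
vector X combining its summary statistics, population-genetic context and
functional annotations. A deep fully connected network F is trained so that
P̂ = F(X) approximates the probability that the variant is truly associated;
the binary training label Y comes from a larger, better-powered study of the
same trait. Applied back to a study's features, variants with P̂ at or above
a threshold (default 0.5) but p ≥ 5×10⁻⁸ in the study itself are *enhanced*
— candidate associations recovered without new samples. The network is
trained by minimising the binary cross-entropy

  −(1/n) Σᵢ [ Yᵢ log F(Xᵢ) + (1 − Yᵢ) log(1 − F(Xᵢ)) ].

## The feature representation

Five statistical features are computed per variant:

* `neglog10_p` — −log₁₀ of the study p-value, capped at 320 so p-values that
  underflow double precision stay finite;
* `odds_ratio` — the effect size (beta inputs are converted via OR = exp β);
* `maf` — minor allele frequency, min(f, 1−f) of the alternate-allele
  frequency in a matched-ancestry reference panel;
* `ld_score_overall` — Σ r² between the variant and every panel variant
  within 1 Mb. Following the usual LD-score convention the self term is
  included, so the floor is 1; the convention is a flag (`include_self`)
  because either reading is defensible, and tests pin the default;
* `ld_score_known` — the same sum restricted to variants that are
  genome-wide significant in the input study, the self term counting only
  when the variant is itself significant. This feature lets the model
  recognise sub-threshold variants sitting in LD with established signal.

r² is the squared Pearson correlation of allele counts across panel
individuals (computed on genotypes, not phased haplotypes, so any VCF
works). Pairs involving a monomorphic variant have undefined correlation and
contribute 0. Panel variants with more than 10% missing genotypes are
excluded at load; remaining missingness is handled pairwise-complete.

The remaining 28 slots are annotations: one eQTL membership indicator
(a variant qualifies when any of its eQTL associations has nominal
p < 10⁻⁶, strictly), three continuous pathogenicity scores (phyloP,
Fathmm-XF, CADD-phred; missing values filled by 0 or the track median), and
24 binary interval indicators (open chromatin, FIREs and super FIREs,
selective sweeps, cCRE marks, 11 data-driven meta-annotations, one free
slot). Interval tracks use BED conventions (0-based half-open); a 1-based
variant position p overlaps [start, end) iff start < p ≤ end. The schema is
configuration, not code: the published feature list is partly in
supplementary material we do not reproduce, so any schema is accepted as
long as its length matches the network's input width.

Meta-annotations compress a redundant collection of epigenomic tracks:
pairwise similarity is the Jaccard index (intersection bp / union bp after
merging each track to disjoint intervals), and average-linkage hierarchical
clustering on 1 − Jaccard is cut at a fixed number of groups (default 11),
each meta-annotation being the base-pair union of its members. Only the
similarity measure and the group count are externally given; the linkage
and the fixed-count cut are this package's choices. Tracks are sorted by
name before clustering so the result is invariant to input order.

## Building the training set

Labels are Y = 1 iff the label study's p-value is strictly below 5×10⁻⁸.
GWAS tables are extremely imbalanced (typically well under 1% positive), and
a network trained on the raw table collapses to the trivial all-negative
solution, so non-significant variants are under-sampled: every positive is
kept and ⌈ratio × #positives⌉ negatives are drawn uniformly without
replacement (default ratio 10:1 — the published value is in unavailable
supplementary material, so the ratio is exposed and fixed explicitly in the
tests). Negatives are drawn genome-wide without MAF or LD matching, since no
matching is described. Features are z-scored with mean and variance fit on
the training rows only and stored in the model, so prediction takes raw
features and no test-set statistics leak into training; constant columns
pass through unscaled.

## The network and its training

The default architecture is the 14-layer fully connected stack
33–256–256–128–128–128–64–64–64–32–32–16–8–1: an input layer, twelve
rectified-linear hidden layers, and one logistic output unit. Only the
layer count and input width are externally fixed; widths, activation and
dropout (default 0.1, training only) are configuration.

Weights are initialised with variance-scaled uniform draws matched to the
activation: He scaling (±√(6/fan_in)) for rectifier networks, Glorot
scaling for tanh. The distinction matters here — with Glorot initialisation
a 12-hidden-layer ReLU stack attenuates the forward signal by roughly √2
per layer, and in early experiments the output saturated below the 0.5
call threshold for some seeds; He scaling removes the pathology and also
improves the best validation loss.

Training is mini-batch Adam (β₁ = 0.9, β₂ = 0.999) on the binary
cross-entropy, with probabilities clipped to [10⁻¹², 1 − 10⁻¹²] inside the
loss so log 0 never occurs. A label-stratified random 10% split monitors
validation loss; training stops when it has not improved for `patience`
epochs and the best-validation weights are returned. Every stochastic
element (initialisation, shuffling, dropout, the split) derives from one
seed, so runs replay exactly. Gradient correctness of the full
backpropagation is verified against central finite differences in the test
suite. Inference runs with dropout off and is deterministic; transfer to
another trait applies the frozen network (the tests check the weights are
byte-identical before and after) to a feature matrix built with the
identical schema and standardised with the stored training parameters.

## Baselines

Two comparators consume the same features: maximum-likelihood logistic
regression (logit P̂ = β₀ + Σ βᵢXᵢ, via IRLS; under perfect separation the
fit is ridge-stabilised with λ = 10⁻⁶ and flagged rather than failing, so
comparisons always complete) and gradient-boosted trees (xgboost, logistic
objective, at most 50 boosting rounds, RMSLE evaluation metric,
`scale_pos_weight` defaulting to #negatives/#positives). Each baseline is
fit both on the full variant table and on exactly the network's
under-sampled subset (`_subset` variants, sharing the identical mask).

## Evaluation

The field evaluates at two levels. At the variant level the package reports
confusion counts at a threshold, the true-positive rate, precision, and
F1 = TP / (TP + ½(FP + FN)), plus full ROC and precision–recall curves by
sweeping every distinct score (AUROC by trapezoid integration, which the
tests check against the concordance-pair statistic). One ambiguity in the
source material — a metric abbreviated "CPR" that is never defined — is
resolved by reporting precision (positive predictive value) in its place.

Loci are built by single-linkage merging: consecutive called variants at
most 250 kb apart join one locus (a pair exactly 250 kb apart merges), and
the index variant is the member with the highest score (−log₁₀ p for input
loci, P̂ for predicted loci). The merge distance and the matching slack
(a locus matches another set if its span ±250 kb overlaps a span there) are
this package's choices — the evaluation literature rarely states its locus
algorithm — and both are configurable. A truth locus matched by any
predicted locus is a locus-level true positive; unmatched predicted loci
are false positives.

Enhanced variants are those with P̂ ≥ threshold but input p ≥ 5×10⁻⁸, so the
enhanced set and the input-significant set are disjoint by construction.
Enhanced loci are predicted-significant loci that neither contain an
input-significant member nor overlap any input-study locus: novelty is
judged against the input study's loci, which do not depend on the
probability threshold. The complementary "anti-enhanced" set — input
significant loci whose members all fall below the threshold — captures the
model's ability to flag likely false positives of the input study.

The threshold sweep (0.50 to 0.95 in steps of 0.05) treats stringency as a
filter: locus boundaries are fixed at the lowest threshold and a locus
survives a stricter threshold iff its index probability reaches it. This
makes the per-threshold counts nested and monotone non-increasing, which
matches how the counts are reasoned about; recomputing locus boundaries at
every threshold can otherwise split a merged locus in two and produce a
spurious increase. Validation binning groups enhanced loci by index-variant
probability (bins of width 0.05 on [0.5, 1]) and reports, per bin, the
proportion matched by at least one independent study and the distribution
of how many studies validate each locus.

## The synthetic benchmark

No public desk-scale dataset exercises the full pipeline with known ground
truth, so the package generates one. The generator's defaults *are* the
study conditions of the benchmark; they were fixed once, before the
acceptance results were produced, and are not tuned.

* **Panel.** 20,000 variants in 40 blocks of 500, positions ~5 kb apart
  with >1 Mb gaps between blocks so an LD window never straddles two blocks
  (the LD code does not rely on this; it handles arbitrary layouts).
  Within a block, two latent exchangeable Gaussians per individual
  (correlation ρ = 0.5) are thresholded at the variant's MAF (drawn from
  [0.05, 0.5]) and summed to Hardy–Weinberg genotypes for a panel of 200
  individuals — comparable to the European subset of a public reference
  panel. Thresholding attenuates the latent correlation, giving realistic
  genotype r² well below 1 within blocks and ≈ 1/n between.
* **Truth.** 36 causal variants (fraction 0.0018) clustered into 12 causal
  loci, each holding at least one causal variant; standardized effects
  a ~ N(0, 0.03²). The effect scale was chosen so the per-variant power at
  the three sample sizes brackets the regime the method targets: marginal
  z-scores at causal variants have sd √(1 + n·σₐ²) ≈ 4.4, 7.4 and 10.4 at
  n = 20k, 60k and 120k, i.e. the feature study detects a minority of causal
  variants, the label study roughly half, and the validation study most.
* **Studies.** Marginal z-scores per block follow the standard
  summary-statistic model z ~ N(√n R a, R) with R the block's panel
  correlation matrix (ridge-repaired with 10⁻⁶ if Cholesky fails);
  p = 2Φ(−|z|), se = 1/√n, and OR = exp(z·se) on the standardized scale (a
  convenience: the model uses OR magnitude, not its epidemiological
  meaning). Studies of the same trait share R and a and differ only in n
  and the noise seed. Individual-level phenotypes are never simulated;
  the multivariate-normal model is faster and exercises every pipeline
  stage.
* **Annotations.** Each binary track covers causal variants at rate e·q and
  others at q (defaults e = 5, q = 0.05, echoing the observed enrichment of
  GWAS signal in regulatory annotation); score tracks are standard normal
  noise plus a +1 shift at causal variants; the eQTL table contains causal
  variants below the 10⁻⁶ filter at rate 0.4 versus 0.02 for the rest, plus
  sub-threshold rows the strict filter must drop.
* **Related trait.** For transfer experiments a second trait draws fresh
  causal variants preferentially from the annotated regions (weight
  (1 + coverage)²), so the annotation-to-causality structure is shared
  while the causal variants differ.

What the generator does *not* emulate: coalescent LD patterns, population
structure and admixture, case-control ascertainment, MAF-dependent effect
sizes, tissue specificity of annotations, and cross-study heterogeneity.
Passing benchmarks therefore demonstrates that the machinery is correct and
that the method recovers planted signal under idealised conditions — not
performance on real cohorts.

## Benchmark protocol and sizes

The enhancement benchmark mirrors the three-study design: the small study
(n = 20k) contributes features, the large study (n = 60k) contributes
labels, the trained model is applied to the large study's features, and the
largest study (n = 120k) serves as independent truth. With the default
configuration a run takes under a minute on one CPU; the acceptance tests
aggregate five master seeds (medians) for the recovery, null-safety and
transfer checks. The harness trains with learning rate 2×10⁻³, batch 512,
at most 60 epochs and patience 8 — a schedule sized once for the few
thousand training rows the under-sampled benchmark produces; the exported
defaults (10⁻³/512/200/20) remain the general-purpose setting.

On a null benchmark (effect sd 0) the label study almost surely contains no
genome-wide-significant variant, so no model can be trained; the pipeline
then reports zero predicted and enhanced loci rather than inventing signal
from noise, and the null acceptance check asserts exactly that.

## Numerical choices and degenerate inputs

* Probabilities are clipped to [10⁻¹², 1 − 10⁻¹²] in the loss and to
  [10⁻¹⁵, 1 − 10⁻¹⁵] at the network output, keeping them in the open
  interval.
* −log₁₀ p is capped at 320; p-values are required in (0, 1] at parse time
  and rows violating that are dropped and counted, never silently fixed.
* Duplicate variant keys are dropped (first kept) with a warning; the
  handling of multi-allelic records is not specified by the source
  material, and dropping is the conservative choice.
* A/T and C/G variants are matched by position and allele pair without
  strand flipping; a mismatched pair is reported, not resolved.
* Effect-allele flips invert the odds ratio (OR → 1/OR); harmonisation is
  idempotent, and all retained effects refer to the panel's alternate
  allele.
* Monomorphic variants contribute r² = 0; all-missing genotype vectors are
  an error for MAF.
* Clustering ties are broken by lexicographic track name; locus calling on
  an empty input returns an empty locus set, and one-class truth vectors
  yield missing (NA) ROC summaries rather than errors.

## Known limitations

The published architecture's exact widths and optimizer settings are not in
the source text, so the defaults here are reasonable stand-ins exposed as
configuration; no attempt is made to reproduce released model weights. The
locus definitions, the under-sampling ratio, and the composition of the 28
annotation slots are likewise documented choices where the original is
silent or relies on unavailable supplementary material. LD computation is
windowed and desk-scale; biobank-scale streaming LD is out of scope, as are
genotype QC, imputation, meta-analysis and annotation liftover.
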