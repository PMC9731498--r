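---
title: "Detecting genomic instability in F2 hybrid embryos: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting genomic instability in F2 hybrid embryos: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridscar)
library(dplyr)
```

## The problem

Embryos from an intercross of two F1 hybrids of inbred mouse strains
(C57BL/6 as the reference strain, 129/Sv as the alternate) carry genomes
that are recombinant mosaics of the two parental haplotypes. At the tens of
thousands of exome positions where the strains carry fixed different
alleles — the *strain catalog* — the variant allele fraction (VAF, alternate
reads over total reads) reads out both local ancestry and allelic copy
state: about 0 in segments homozygous for the reference strain, about 1 in
segments homozygous for the alternate strain, and 0.5 in heterozygous
segments of a balanced diploid genome.

That last number is the lever. In DNA-repair-deficient embryos, lesions
arising in utero — copy-neutral loss of heterozygosity (LOH), focal
deletions and duplications, whole-chromosome gains and losses — pull
heterozygous-site VAFs away from 0.5. `hybridscar` packages the full chain
needed to exploit this: a synthetic F2-cross simulator, VCF/catalog
handling, a germline/somatic triage rule on ranked VAFs, strain-origin
segmentation with allelic-imbalance scoring, a panel-of-normals copy-ratio
workflow, and the organism-level statistics of such a cross (segregation
distortion, Mendelian goodness of fit, limiting-dilution stem-cell
frequencies).

Because no embryo sequencing data are deposited for this design, the
simulator is a first-class module: every downstream method is exercised
against synthetic data with known truth.

## The synthetic F2 cross

**Recombination.** An F1 gamete is an alternating two-strain mosaic per
chromosome. Crossover counts are Poisson with mean equal to the genetic map
length in Morgans, positions uniform, starting strain a fair coin, and no
crossover interference. Interference changes breakpoint spacing slightly
but none of the downstream readouts depend on it; the Poisson model is the
simplest one that produces the long strain-origin segments these analyses
rest on. The default genome (`genome_model()`) is deliberately compact —
five 100 Mb chromosomes of 1 Morgan each — so that simulations carry
multiple independently segregating chromosomes and tens-of-megabase
segments without mouse-genome runtimes; all sizes are parameters.

**Litters.** Each embryo draws two independent gametes and, independently,
genotypes at two unlinked knockout loci with Mendelian 1:2:1 probabilities.
All embryos are alive at midgestation (E12.5); survival to weaning is
Bernoulli with a genotype-keyed death probability. The default kills half
of the double knockouts, reproducing the observation that the double
knockout is present at the Mendelian ratio at E12.5 but halved among weaned
pups.

**Instability events.** Events are intervals with a kind (`CN_LOH`,
`DELETION`, `DUPLICATION`, `CHR_GAIN`, `CHR_LOSS`), a retained (or gained)
haplotype identified by strain, and a cell fraction. Expected per-strain
allele copy numbers are transformed per event and mixed linearly across the
cell fraction — the standard bulk-sequencing assumption. Overlapping events
compose sequentially on the mixed copy numbers, with decrements clamped at
zero (one cannot delete more copies than remain). In a region homozygous
for the *other* strain, a dosage event still applies to the resident
haplotype (a deletion removes a copy whatever its ancestry), while CN-LOH
is a no-op there (already homozygous, copy neutral).

**Reads.** At a site with expected total copies $c$ and expected VAF $v$
(including a base error rate $e$, which cancels exactly at balanced
heterozygous sites), depth is Poisson with mean $\bar d \, c / 2$ —
negative binomial when `depth_dispersion > 0`, since real exome depth is
overdispersed — and the alternate count is Binomial(depth, $v$). All
randomness flows from one seed through named substreams (gametes, litters,
reads), so each stage is independently reproducible; coordinates are
1-based at the VCF surface and half-open `[start, end)` internally.

## Germline/somatic triage

For each called variant, rank its VAFs across embryos, $v_1 \ge v_2$.
The rule: if $v_1 \le 0.05$ the variant is excluded as noise; else if
$v_2 > 0.4\,v_1$ it is shared and labeled germline-or-false; else it is
somatic. Both boundaries are strict (a top VAF of exactly 0.05 is excluded;
a second VAF of exactly 40% of the top is somatic) — "above" and "more
than" are read as strict inequalities; both thresholds are configurable
for sensitivity analysis. A sample with zero depth contributes VAF 0 to the ranking — the
rule is stated purely on VAFs, and absence of reads is treated as absence
of evidence for the variant. Known catalog sites are pre-labeled
germline-or-false and bypass the rule; applying the catalog exemption
before the ranked-VAF rule is a design choice of this package (the reverse
order would differ only for catalog sites private to one embryo).

The follow-up cluster filter formalizes what is otherwise a manual visual
step: somatic calls that appear in clusters in only one embryo are almost
always residual germline haplotype variation. Any run of at least
`cluster_min_count` (default 3) somatic sites sharing the same single
carrier embryo within a `cluster_window_bp` (default 1 Mb) window is
relabeled `CLUSTER_REMOVED`. Sites whose top VAF is tied between two
embryos have no single carrier and are never removed. The defaults are this
package's declared values, not recovered ones.

## Strain-origin segmentation and the instability score

Per sample, catalog sites are decoded into `HOM_REF` / `HET` / `HOM_ALT`
by most-probable-path (Viterbi) dynamic programming over a three-state
model: binomial emissions with success probabilities $e$, $0.5$, $1-e$
($e$ defaults to 0.005, absorbing sequencing error and stray mismapped
reads) and a distance-scaled switch probability $1-(1-t)^{\text{gap}}$
with $t = 10^{-7}$ per bp, which prices a state switch at roughly one
recombination per 100 Mb. Segmentation was chosen over per-site
thresholding to reproduce the segment-level picture; ties in the decoder
are broken deterministically toward the lower-indexed state, and the path
equals exhaustive enumeration on small instances (tested).

The instability readout is computed over *heterozygous territory* at sites
meeting a depth floor (default 10, below which binomial noise swamps the
signal):

* `mad_score`: mean absolute deviation of VAF from 0.5, in $[0, 0.5]$;
* `outlier_fraction`: fraction of sites with $|{\rm VAF} - 0.5| > \delta$,
  $\delta$ defaulting to 0.15.

Both are reported so neither is privileged; a VAF scatter displays this
deviation only visually, and these two statistics are this package's
formalizations of it. Even a perfectly euploid genome has a positive `mad_score`
baseline — the exact binomial expectation
$\sum_k |k/d - 1/2|\binom{d}{k}2^{-d}$ at depth $d$, about 0.045 at depth
80 — so scores are interpreted against matched controls, not against zero.

One subtlety matters for clonal events. With cell fraction 1, CN-LOH pushes
heterozygous-site VAFs to 0 or 1, and a read-based decoder will correctly
call those segments homozygous — thereby excluding exactly the deviating
sites from a HET-restricted score. `instability_score()` therefore takes
the state track as an explicit argument: in simulations with clonal events,
pass the germline truth track (`ancestry_track()`); with mosaic events
(cell fraction below roughly 0.8 at depth 80) the embryo's own
`assign_states()` track keeps the affected segments HET and suffices. On
real data the analogous choice is a track from a matched control or an
external genotype source.

## Panel-of-normals copy ratios

Depths over exome targets are normalized to per-sample fractions (columns
sum to 1, so library size drops out). The panel of normals is the
per-target median fraction across designated wild-type samples; with the
two-normal panels of small embryo studies the median is the mean of the
two, which is the honest denominator at that panel size — no PCA-style
denoising is attempted, a deliberate simplification at two normals. Targets
with panel median below a mask threshold are excluded. A sample's copy
ratio is its fraction over the panel median, median-centred so the euploid
expectation is exactly 1.

Segmentation runs per chromosome on the log2 scale (reporting is linear):
exact optimal partitioning minimizing within-segment squared error with a
fixed per-breakpoint penalty, hence deterministic. The default penalty is
$3\hat\sigma^2\log n$, with $\hat\sigma$ a robust
(median-absolute-deviation) estimate from successive differences. A
BIC-type $\hat\sigma^2\log n$ was evaluated and rejected: the maximal
spurious-split gain of pure noise at these track lengths has median about
$4\hat\sigma^2$ and 99th percentile about $12.5\hat\sigma^2$, so the
smaller penalty oversplits roughly half of all flat chromosomes, while the
factor-3 form clears the 99th percentile. The penalty is exposed as an
argument.

## Organism-level statistics

* **Segregation distortion** (`mendelian_breed_test()`): each breed's
  double-knockout count among weaned pups is tested against the null
  proportion 1/16 with a two-sided *exact* binomial test — the exact test
  is the only reading consistent with also reporting exact 95% confidence
  intervals; a normal-approximation variant is retained behind
  `method = "normal"` for comparison. Two-sidedness uses the
  minimum-likelihood convention (sum of all outcome probabilities no larger
  than the observed one, with a $1+10^{-7}$ relative tolerance for
  floating-point ties), stated explicitly because at least three two-sided
  conventions exist. Intervals are Clopper–Pearson from Beta quantiles;
  p-values are Bonferroni-multiplied across breeds.
* **Mendelian goodness of fit** (`mendelian_gof()`): chi-square against the
  9-class $\{1,2,1\}\otimes\{1,2,1\}/16$ expectation, falling back to a
  seeded Monte-Carlo multinomial p-value whenever any expected count drops
  below 5 — routine for midgestation litters — with the method recorded.
* **Limiting dilution** (`fit_single_hit()`, `lrt_compare()`): under the
  single-hit Poisson model the probability a recipient shows no engraftment
  at dose $d$ is $e^{-fd}$. $f$ is estimated by direct 1-D maximum
  likelihood on $\log f$ (equivalent to the single-parameter
  complementary-log-log regression and simpler to verify against the
  one-dose closed form $-\log(k/n)/d$), with a Wald interval on the log
  scale; all-negative or all-positive assays return a boundary estimate
  flagged non-identifiable. Group comparison is the likelihood-ratio test
  against the pooled fit with the asymptotic $\chi^2_1$ approximation,
  Bonferroni-adjusted across multiple pairwise comparisons via
  `bonferroni()`.

## What the simulations do and do not show

The generator reproduces the features the methods rely on: recombinant
ancestry mosaics, binomial read counts at Poisson/negative-binomial depth,
linear mixing of lesion cell fractions, Mendelian segregation with
genotype-dependent lethality, shared capture bias across samples. It does
not model alignment or calling artifacts (mapping bias at divergent sites,
strand bias, caller-specific filters), GC-dependent coverage waves,
contamination, or subclonal structure beyond a single cell fraction per
event. Green tests therefore certify the statistical machinery and its
calibration on clean data honoring the stated models — not robustness to
every artifact of real exomes, which is what the triage rule's thresholds
must absorb when applied to real call sets.

Problem sizes used by the test suite and the acceptance script — 20,000
catalog sites at mean depth 80 for VAF calibration, 2,000 exome targets
against a two-normal panel, 100 paired replicates for the instability
contrast, 500 simulated assays for frequency recovery, 2,000 replicates for
test size — are the package's chosen desk-scale study conditions, stated
here once.

## A worked pass through the pipeline

```{r pipeline, eval = FALSE}
genome <- genome_model()
catalog <- simulate_catalog(genome, 20000, seed = 1)
cfg <- sim_config(mean_depth = 80)

litter <- simulate_litter(genome, 6, cfg, seed = 1) |>
  add_instability_event("embryo03", "CN_LOH", "chr2", 1, 5e7,
                        retained_haplotype = "S", cell_fraction = 0.6)
ad <- sample_reads(litter, catalog, cfg, seed = 1)

# triage, segmentation, scoring
labels <- classify_all(ad, catalog = catalog)
track <- assign_states(ad, sample = "embryo03")
instability_score(filter(ad, sample == "embryo03"), track) |> glance()

# copy ratios against a wild-type panel
depths <- simulate_target_depths(genome, 2000,
                                 c("wt1", "wt2", "embryo03"), seed = 1)
norm <- normalize_coverage(depths)
pon <- build_pon(norm, c("wt1", "wt2"))
denoise(norm, pon, "embryo03") |> segment_copy_ratios()
```
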