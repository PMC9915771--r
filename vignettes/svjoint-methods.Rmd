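---
title: "Models and methods behind svjoint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind svjoint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svjoint)
```

## The problem

Population-scale structural-variant (SV) call sets are built in two
phases: per-sample discovery produces noisy, breakpoint-imprecise calls
for each genome, and a joint step turns them into one genotyped,
quality-controlled population resource. svjoint implements the joint
phase for deletions (DEL), duplications (DUP) and inversions (INV):

1. **merge** per-sample calls into candidate sites,
2. **jointly genotype** every candidate across all samples from
   pileup-summary evidence,
3. **filter** low-confidence duplications and chromosome-X calls,
4. **evaluate** the call set with pedigree and population statistics.

Because real cohorts of this kind are restricted-access, the package
ships a first-class synthetic-cohort generator whose generative model is
exactly the statistical structure the genotyper assumes. Every stage is
tested against that generator's truth.

## The evidence model and the synthetic cohort

For each candidate site and sample the pipeline consumes a pileup
summary: counts of discordant read pairs, split reads and soft-clipped
reads (jointly, the *alignment support*), the mean read depth across the
event, mean/SD of the depth in the flanks before and after the event,
and the GC fraction of the region. Genome-wide 100-bp interval depths
per sample support GC-curve estimation, and mean chrX/chrY depths
support sex inference.

`simulate_cohort()` generates these quantities under the model:

* **Allele frequencies.** Per-site ancestral frequency `p ~ Beta(0.5, 4.5)`
  by default — a rare-skewed spectrum (mean AF 0.1) resembling what large
  cohorts observe for SVs. With several populations and a divergence
  parameter `F`, population frequencies follow a Balding–Nichols draw
  `Beta(p(1-F)/F, (1-p)(1-F)/F)`, so mean Hudson FST rises monotonically
  with `F`.
* **Pedigrees.** Trios are father/mother/child with alleles transmitted
  uniformly; duos mask the father. Families share a population. Sex is
  assigned 50:50; fathers are male, mothers female.
* **Depth.** Sample mean diploid depth 30× (±5% across samples). An
  event with copy number `c` has normalized depth expectation `c/2`;
  observed depth is `sample_depth × gc_bias(gc) × max(0, c/2 + ε)`,
  `ε ~ N(0, 0.1)` — Gaussian noise truncated at zero, the same SD for
  every genotype (homoscedastic). The GC bias is a smooth per-sample
  quadratic in GC fraction with sample-specific amplitude (up to 0.2),
  so curve estimation is non-trivial.
* **Support.** Counts are Poisson with mean `λ × a`, where `a` is the
  number of alternate alleles (extra copies for DUP) and `λ = 15` per
  allele by default; an overdispersion option switches to negative
  binomial. The Poisson choice is a modeling decision — pileup tools do
  not document a count distribution — and is the simplest law matching
  the mixture assumptions the genotyper fits.
* **Breakpoints.** Per-sample calls jitter the true breakpoints by
  `N(0, 50 bp)`, emulating caller imprecision well inside the 1 kbp merge
  wobble.
* **Artifacts.** A configurable fraction of sites are *false
  candidates*: no true carriers, but ~8% of samples show spurious
  support, a mild depth shift (+0.15 for DUP-like artifacts) and 3×
  noisier flanks. These enter the candidate list through spurious calls
  and are what the duplication prefilter and SVM are trained to remove.
* **Chromosome X.** Males carry one X haplotype (base copy number 1,
  X depth 0.5, Y depth 0.5 of the autosomal mean); females two. Default
  pseudoautosomal regions span the first 2% and last 1% of the simulated
  chrX.

What the generator does **not** emulate: read-level artifacts (mapping
ambiguity, segmental duplications, reference errors), LD between SVs and
nearby SNPs, overlapping/nested complex events, breakpoint-sequence
effects on support, and batch effects across sequencing centers. Passing
tests therefore demonstrate correctness of the algorithms under the
stated statistical model, not robustness to everything real genomes do.

## Merging calls into candidates

Two calls are linked when they share chromosome and SV type and both
breakpoints agree within the wobble distance (default 1 kbp):
`|Δstart| ≤ w` **and** `|Δend| ≤ w`. Candidate sites are the connected
components (single linkage) of this relation; the transitive chaining
mirrors the behavior of standard SV merging tools. Implementation:
calls are sorted canonically, grouped by (chromosome, type), and linked
with a union-find over a sliding start-coordinate window, which makes
the result independent of input order and `O(n·k)` rather than `O(n²)`.
The tests compare it against an exhaustive quadratic oracle on hundreds
of random call sets. Consensus breakpoints are member medians (lower
median on ties, so consensus coordinates are always observed values).
Whether the wobble applies jointly to both breakpoints or to either
alone is not fixed by merging conventions; the joint form is used, being
the stricter reading.

Truth matching (`match_to_truth()`) uses the standard benchmarking
rules: type equality, breakpoint distance `max(|Δstart|, |Δend|) ≤ 500`,
size ratio `min/max ≥ 0.5`, calls under 10 bp unscored, and a truth
entry may satisfy any number of calls.

## GC correction and normalized depth

Per sample, expected depth per GC bin (width 0.025, 40 bins) is the 10%
trimmed mean of the 100-bp interval depths in the bin; bins with fewer
than 50 intervals are interpolated linearly from their neighbors
(constant extrapolation at the ends). Normalized depth is
`depth_raw / curve(gc)`, putting diploid at 1.0, a heterozygous deletion
at 0.5, a CN3 duplication at 1.5. The trimmed mean keeps carrier
intervals and outliers from biasing the curve; bin width and trim are
tunable but were fixed once and never revisited.

## The mixture-model genotyper

Deletions and duplications are genotyped with a Gaussian mixture over
the two-dimensional evidence `(normalized depth, pooled support)`.
Components are **anchored at the genotype expectations**: depth
`1, 0.5, 0` for DEL copy numbers `2, 1, 0`; depth `1, 1.5, 2, …` for DUP
copy numbers `2, 3, 4, …` (the class list extends to the 99.5th depth
percentile, capped at CN 8, making multi-allelic duplications first-class);
support mean `λ̂ × a` with `λ̂` estimated deterministically as the median
positive support among depth-defined putative carriers. EM refines
means, variances and weights from this anchored start — never from a
random one — so genotyping is fully deterministic and component labels
never need to be disambiguated.

Numerical choices that matter:

* **Shared depth variance.** The depth dimension uses one pooled
  variance across components. Log-posterior differences between classes
  are then linear in depth, so the class boundaries are monotone: at a
  deletion site, lowering a sample's depth can only move its call away
  from reference. (The generator's truncated-Gaussian noise is
  homoscedastic, so nothing is lost.) Support variances are
  per-component with a floor of 0.25, since Poisson variance scales with
  the mean.
* **Minimum effective membership.** A component whose responsibility sums
  to fewer than 2 samples keeps its anchor parameters for that
  iteration. This prevents an empty class from collapsing onto a single
  reference-tail outlier at null sites, and pins rare classes (e.g. a
  singleton heterozygote) at their expected location.
* **Convergence** at relative log-likelihood change `< 1e-6` or 200
  iterations; depth variance floor `1e-4`.
* **Pruning and assignment.** Components with weight `< 1/(2n)` are
  pruned; samples take the maximum-posterior class, with posteriors of
  same-class components pooled. A posterior below 0.5 is a no-call.
* **Mode selection.** Inversions are copy-neutral and always use a
  support-only 1-D mixture. DEL/DUP sites whose putative carriers (by
  depth) average less than 2 supporting reads — the complex-breakpoint
  signature — fall back to a depth-only 1-D mixture, as does any site
  where the 2-D EM fails to converge. The mode is recorded per site
  (`GT2D`/`GTDP`/`GTSUP`).
* **Site quality.** A site PASSes when call rate ≥ 0.9 and adjacent
  components are at least 2 Mahalanobis units apart; otherwise it is
  flagged `LowQual`.

## Chromosome X

Sex is inferred from autosome-normalized X and Y depths (male:
X < 0.75 and Y > 0.25; female: X ≥ 0.75 and Y < 0.15; anything else is
flagged ambiguous and excluded). Sites intersecting pseudoautosomal
regions are skipped entirely. Male normalized depths are increased by
0.5 before the mixture fit so male and female clusters coincide; male
calls are then reported hemizygously (present/absent, one allele in
AC/AN accounting) because a diploid heterozygote is undefined on a
single-copy chromosome.

## Duplication and chrX filters

The rule-based prefilter flags a DUP when (a) its carriers' mean
normalized depth is more than 0.25 from the copy-number expectation, or
(b) it overlaps another DUP reciprocally ≥ 50% with carrier-genotype
concordance ≥ 95% — then the lower-quality member (lower call rate,
ties by shorter length, then coordinate order) is flagged. The two
conditions are applied disjunctively: either signature alone marks a
redundant or non-conforming site, and the thresholds are configurable
precisely because "aberrant" and "significant" are cohort-dependent.

The trainable filter is an RBF-kernel SVM over five cohort-level site
features for DUPs (normalized flank depth mean/SD before and after the
event, plus GC fraction) or six for chrX (depth mean/SD, female−male AF
difference, male−female call-rate difference, split- and clip-support
indicators). Hyper-parameters come from a deterministic 5-fold
cross-validated grid search (cost × gamma); scores are oriented so
higher is better and sites under a user-chosen threshold become
`LowQual`. In this package the training labels come from simulation
truth; flags only ever change FILTER status, never genotypes. A sex
with no called genotypes contributes allele frequency 0 to the AF
difference, keeping the features finite while the call-rate feature
carries the missingness signal.

## Pedigree QC

* **Mendelian error rate**: inconsistent triples over (site, family)
  pairs where all members are genotyped and at least one is
  non-reference. Biallelic consistency uses the exhaustive 3×3×3
  transmission table; multi-allelic duplications use copy-number
  arithmetic (`0 ≤ c−2 ≤ (p1−2)+(p2−2)`); chrX sons are checked against
  the mother only, daughters receive the father's hemizygous allele;
  duos are checked against the single typed parent. The denominator
  counts site×family pairs (not sites), which keeps the estimate a
  per-genotype error rate; an aggregation over families would mix
  family counts into the unit.
* **De novo (novel HET) rate**: HET children of REF×REF genotyped
  parents, over all genotyped HET children (trios only).
* **Allelic balance**: among REF×HET parental pairs, the REF:HET split
  of the children, expected 50:50 under unbiased calling.
* **Het/hom ratio** per sample over PASS biallelic sites, with infinite
  ratios flagged and excluded from the cohort mean.

`expected_mendelian_error_rate()` is the calibration oracle: under
Hardy–Weinberg parents, exact transmission, and a channel replacing each
genotype with probability `e` by a uniformly chosen different one, it
enumerates all 27 observed triples and returns the expected
inconsistency rate with the estimator's own denominator. The estimator
on error-injected simulated trios must land within binomial noise of
this closed-form value.

## Population statistics

* **Frequencies** from called genotypes only; `singleton` is AC == 1,
  `rare` is AF < 1%.
* **Hudson FST** per site:
  `[(p1−p2)² − p1(1−p1)/(n1−1) − p2(1−p2)/(n2−1)] / [p1(1−p2) + p2(1−p1)]`,
  with the cohort rules applied first: populations under 1,000 samples
  are refused, populations over 7,000 are randomly subset (seeded), and
  combined-AC-1 singletons are excluded. Identically fixed sites have a
  zero denominator and are skipped with a flag. The mean is the
  ratio-of-averages form.
* **LD**: squared Pearson correlation of dosages between an SV and SNPs
  within ±1 Mbp over samples non-missing in both, with MAF ≥ 0.001 and
  an r² reporting floor of 0.05; zero-variance vectors are skipped.
  Founder restriction is the caller's responsibility (founders are
  PED rows without parents).
* **Window scan**: disjoint 100-kb windows, exclusion regions removed,
  SVs ≥ 50 bp counted in every window their span touches; hotspots are
  counts above mean + 3 SD of the retained windows (SD genome-wide —
  per-chromosome SD would make thresholds incomparable across
  chromosomes), deserts are zero-count windows.
* **Catalog overlap**: a query is known when a same-type catalog entry
  overlaps ≥ 70% — reciprocally by default, with a query-fraction mode
  since catalog conventions differ.

## Determinism and problem sizes

Every stochastic step (simulation, error injection, SVM folds, FST
subsampling) is driven by explicit seeds, and the genotyper contains no
randomness at all, so the full pipeline is byte-identical across reruns
of one configuration. The shipped tests exercise: genotype recovery on
1,000 samples × 350 sites (concordance ≥ 99% DEL / 95% DUP / 98% INV);
error-rate calibration and allelic balance on 500 trios; the merge
oracle on 500 random call sets; FST and LD against independent formula
oracles at 1e-12; and the window scan, truth matcher and chrX contract
on constructed fixtures. These sizes were chosen to estimate each rate
with comfortable binomial resolution.

## Known limitations

* Genotype quality is a class posterior under the fitted mixture, not a
  calibrated phred-scaled likelihood.
* Support counts enter the mixture raw; per-sample normalization (for
  heterogeneous coverage cohorts) is not implemented.
* Chromosome Y is not genotyped; breakpoints are not refined after
  merging; phasing is out of scope.
* The strict linear separability of evidence clusters degrades with
  cohort size at fixed noise (extreme order statistics eventually
  cross); the genotyper's accuracy does not, because the mixture model
  weighs the whole clusters rather than their extremes.
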