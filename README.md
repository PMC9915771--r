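# svjoint

Population-scale **structural-variant (SV) joint genotyping and quality
control** in R, for cohorts where per-sample deletion (DEL), duplication
(DUP) and inversion (INV) calls must be turned into one genotyped,
filtered population call set. It is aimed at statistical-genetics and
sequencing-informatics groups building SV resources from short-read
cohorts, and at methodologists who need a fully synthetic, truth-bearing
test bed for joint-genotyping machinery.

## What it does

* **Candidate merging** — per-sample calls are clustered into population
  candidate sites by single-linkage with a breakpoint *wobble*: calls
  link when they share chromosome and SV type and both
  `|Δstart| ≤ w` and `|Δend| ≤ w` (default `w` = 1 kbp). Consensus
  breakpoints are member medians.
* **Joint genotyping** — every candidate is genotyped across all samples
  by a Gaussian mixture model over the per-sample evidence
  `(s, d)` = (alignment support, GC-corrected normalized depth), with
  components anchored at the genotype expectations

  | genotype | depth mean | support mean |
  |---|---|---|
  | DEL CN 2 / 1 / 0 | 1.0 / 0.5 / 0.0 | 0 / λ / 2λ |
  | DUP CN 2 / 3 / 4… | 1.0 / 1.5 / 2.0… | 0 / λ / 2λ… |

  EM refines the fit deterministically (no random initialization);
  depth-only and support-only 1-D modes handle complex-breakpoint
  DEL/DUP sites and copy-neutral inversions. Chromosome X is genotyped
  with inferred sex, male normalized depth compensated by +0.5,
  pseudoautosomal regions excluded, and hemizygous male reporting.
* **Filtering** — a rule-based duplication prefilter (depth-conformance
  and concordant-overlap redundancy → `PreFiltered`) plus an RBF-SVM
  site classifier over flank-depth/GC features (DUPs) or per-sex
  AF/call-rate features (chrX) → `LowQual`.
* **Pedigree QC** — Mendelian error rate (site × family denominator,
  copy-number arithmetic for multi-allelic DUPs, chrX-aware), de novo
  (novel-HET) rate, REF:HET allelic balance (expected 50:50), het/hom
  ratios, and a closed-form enumeration oracle for calibrating the
  error-rate estimator.
* **Population statistics** — allele-frequency spectrum with
  singleton/rare classes; per-site Hudson FST
  `[(p₁−p₂)² − p₁(1−p₁)/(n₁−1) − p₂(1−p₂)/(n₂−1)] / [p₁(1−p₂) + p₂(1−p₁)]`
  with singleton exclusion and 7,000-sample subsetting; SV–SNP LD r²
  within ±1 Mbp; 100-kb hotspot (mean + 3 SD) / desert window scans; and
  ≥70%-overlap catalog novelty classification.
* **Synthetic cohorts** — `simulate_cohort()` generates truth genotypes
  (Beta-distributed allele frequencies, Balding–Nichols population
  divergence, Mendelian trios/duos), genotype-proportional depth with
  per-sample GC bias, Poisson support counts, jittered per-sample calls,
  artifact sites, and chrX structure — so the entire pipeline is
  testable without access data.

## Worked example

```r
library(svjoint)

cfg <- sim_config(n_samples = 300, n_trios = 50, n_del = 30, n_dup = 15,
                  n_inv = 8, n_chrx = 4, false_candidate_rate = 0.1,
                  seed = 1)
res <- run_sv_pipeline(cfg)

head(res$candidates, 3)
#>      site_id chrom   start     end svtype n_members n_supporting_samples
#> 1 CAND000001  chr1 1103596 1104887    DEL       173                  173
#> 2 CAND000002  chr1 2937558 2942959    DEL        38                   38
#> 3 CAND000003  chr1 3527736 3528716    DUP       124                  124

genotype_concordance(res$genotypes, res$sim$truth)
#>   svtype n_genotypes concordance
#> 1    DEL        8700   0.9998851
#> 2    DUP        3600   0.9988889
#> 3    INV        1800   0.9955556

res$qc$mendelian
#>   svtype n_inconsistent n_informative       rate undefined
#> 1    DEL              0           506 0.00000000     FALSE
#> 2    DUP              0           167 0.00000000     FALSE
#> 3    INV              3            65 0.04615385     FALSE

res$qc$allelic_balance
#>   svtype n_ref n_het  pct_ref  pct_het undefined
#> 1    DEL   183   184 49.86376 50.13624     FALSE
#> 2    DUP    45    47 48.91304 51.08696     FALSE
#> 3    INV    23    12 65.71429 34.28571     FALSE
```

Reading the output: 173 of 300 samples carry the first deletion, whose
consensus breakpoints sit within the 50-bp simulated jitter of the true
locus. Genotype concordance against the simulated truth exceeds 99% for
every SV type. The error-free trios show zero Mendelian inconsistency
for the biallelic deletions and duplications, a small inversion
inconsistency rate driven by the handful of support-only genotyping
errors, and REF:HET transmission balance statistically compatible with
the unbiased 50:50 expectation (the INV row counts only 35
transmissions, so its swing is sampling noise).

A thin command-line front end covers the file-based workflow:

```sh
svjoint simulate --seed 3 --out cohort/ --n-samples 100 --n-trios 15
svjoint merge    --calls cohort/calls.tsv --out cohort/candidates.tsv
svjoint genotype --candidates cohort/candidates.tsv \
                 --evidence cohort/evidence.tsv \
                 --intervals cohort/intervals.tsv \
                 --registry cohort/truth_sites.tsv --out cohort/geno.vcf
svjoint qc-pedigree --vcf cohort/geno.vcf --ped cohort/cohort.ped \
                 --out cohort/qc.tsv
```

## Documentation

The methods vignette (`vignettes/svjoint-methods.Rmd`) describes the
generative model and its defaults, the mixture-model genotyper and its
numerical safeguards, the filter thresholds, the pedigree and population
statistics, and the package's known limitations.
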