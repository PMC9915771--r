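#' Configuration for the synthetic SV cohort generator
#'
#' Builds and validates the parameter set that [simulate_cohort()] consumes.
#' The defaults describe a cohort whose evidence has the statistical
#' structure the joint genotyper assumes: genotype-dependent normalized-depth
#' clusters (1.0 / 0.5 / 0.0 for deletions, 1.0 / 1.5 / 2.0+ for
#' duplications), Poisson-distributed alignment-support counts proportional
#' to the number of alternate alleles, a smooth per-sample GC depth bias,
#' and trio pedigrees with Mendelian-consistent transmission.
#'
#' @param n_samples Number of samples in the cohort.
#' @param n_trios Number of father/mother/child trios (uses `3 * n_trios`
#'   samples; the remainder are unrelated founders).
#' @param n_duos Number of mother/child duos (father missing from the
#'   pedigree but not simulated; uses `2 * n_duos` further samples).
#' @param populations Data frame with columns `label` and `fraction`
#'   (fractions sum to 1). Samples (and whole families) are assigned to
#'   populations by these fractions.
#' @param af_shape1,af_shape2 Beta-distribution shape parameters for the
#'   per-site ancestral allele-frequency draw. The defaults give a
#'   rare-skewed site-frequency spectrum (mean AF 0.1).
#' @param divergence Balding-Nichols fixation parameter F in `[0, 1)`.
#'   With more than one population, per-population allele frequencies are
#'   drawn from `Beta(p(1-F)/F, (1-p)(1-F)/F)` around the ancestral
#'   frequency `p`; `0` means all populations share the drawn frequency.
#' @param af_fixed Optional fixed allele frequency (single value or one per
#'   site), overriding the Beta draw. Used for controlled experiments.
#' @param n_del,n_dup,n_inv Number of autosomal deletion / duplication /
#'   inversion sites.
#' @param n_chrx Number of chromosome-X deletion sites (males simulated
#'   with a single X copy).
#' @param n_dup_overlap_pairs Number of injected pairs of heavily
#'   overlapping duplications with identical carrier genotypes, exercising
#'   the concordant-overlap prefilter.
#' @param genome_length Autosome ("chr1") length in bp.
#' @param chrx_length Chromosome X length in bp.
#' @param sv_len_range Length range (bp) for simulated SVs; lengths are
#'   drawn log-uniformly.
#' @param depth_mean Mean diploid sequencing depth (reads per base).
#' @param sample_depth_sd Relative SD of per-sample mean depth.
#' @param depth_noise_sd SD of the per-observation depth noise on the
#'   normalized (diploid = 1.0) scale; Gaussian truncated at 0.
#' @param gc_amplitude Maximum amplitude of the per-sample quadratic GC
#'   depth-bias curve (each sample draws an amplitude in
#'   `[0.5, 1] * gc_amplitude`).
#' @param support_lambda Expected alignment-support count (discordant pairs
#'   + split reads + soft clips) per alternate allele.
#' @param support_overdispersion Overdispersion `phi` of support counts:
#'   variance is `mu * (1 + phi * mu)`; `0` gives Poisson counts.
#' @param breakpoint_jitter_sd SD (bp) of per-sample breakpoint jitter in
#'   emitted calls.
#' @param false_candidate_rate Fraction of sites that are artifacts: no
#'   true carriers, but a small set of samples shows spurious support,
#'   mildly shifted event depth and noisy flanks, so the sites enter the
#'   candidate list and exercise the duplication filters.
#' @param dup_allele2_frac Fraction of duplication alternate alleles that
#'   carry two extra copies (making some DUP sites multi-allelic, CN > 4).
#' @param n_intervals Number of 100-bp genomic intervals per sample emitted
#'   for GC-curve estimation.
#' @param n_snps Number of biallelic SNPs (HWE, independent of the SVs)
#'   simulated for linkage-disequilibrium analyses.
#' @param seed Integer seed; identical configurations reproduce identical
#'   cohorts byte for byte.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_samples = 100,
                       n_trios = 0,
                       n_duos = 0,
                       populations = data.frame(label = "POP1", fraction = 1),
                       af_shape1 = 0.5,
                       af_shape2 = 4.5,
                       divergence = 0,
                       af_fixed = NULL,
                       n_del = 20,
                       n_dup = 10,
                       n_inv = 5,
                       n_chrx = 0,
                       n_dup_overlap_pairs = 0,
                       genome_length = 1e8,
                       chrx_length = 5e7,
                       sv_len_range = c(300, 20000),
                       depth_mean = 30,
                       sample_depth_sd = 0.05,
                       depth_noise_sd = 0.1,
                       gc_amplitude = 0.2,
                       support_lambda = 15,
                       support_overdispersion = 0,
                       breakpoint_jitter_sd = 50,
                       false_candidate_rate = 0,
                       dup_allele2_frac = 0.15,
                       n_intervals = 4000,
                       n_snps = 0,
                       seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_trios = as.integer(n_trios),
    n_duos = as.integer(n_duos), populations = populations,
    af_shape1 = af_shape1, af_shape2 = af_shape2,
    divergence = divergence, af_fixed = af_fixed,
    n_del = as.integer(n_del), n_dup = as.integer(n_dup),
    n_inv = as.integer(n_inv), n_chrx = as.integer(n_chrx),
    n_dup_overlap_pairs = as.integer(n_dup_overlap_pairs),
    genome_length = genome_length, chrx_length = chrx_length,
    sv_len_range = sv_len_range,
    depth_mean = depth_mean, sample_depth_sd = sample_depth_sd,
    depth_noise_sd = depth_noise_sd, gc_amplitude = gc_amplitude,
    support_lambda = support_lambda,
    support_overdispersion = support_overdispersion,
    breakpoint_jitter_sd = breakpoint_jitter_sd,
    false_candidate_rate = false_candidate_rate,
    dup_allele2_frac = dup_allele2_frac,
    n_intervals = as.integer(n_intervals), n_snps = as.integer(n_snps),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_samples < 1L) stopf("n_samples must be positive")
  if (cfg$n_trios * 3L + cfg$n_duos * 2L > cfg$n_samples) {
    stopf("pedigree needs %d samples but n_samples is %d",
          cfg$n_trios * 3L + cfg$n_duos * 2L, cfg$n_samples)
  }
  pops <- cfg$populations
  if (!all(c("label", "fraction") %in% names(pops))) {
    stopf("populations must have columns 'label' and 'fraction'")
  }
  if (abs(sum(pops$fraction) - 1) > 1e-8) {
    stopf("population fractions must sum to 1 (got %g)", sum(pops$fraction))
  }
  for (f in c("divergence", "false_candidate_rate", "dup_allele2_frac")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stopf("%s must be in [0, 1]", f)
  }
  if (cfg$depth_mean <= 0) stopf("depth_mean must be positive")
  if (cfg$depth_noise_sd < 0) stopf("depth_noise_sd must be non-negative")
  if (cfg$support_lambda < 0) stopf("support_lambda must be non-negative")
  if (cfg$breakpoint_jitter_sd < 0) stopf("breakpoint_jitter_sd must be non-negative")
  if (cfg$genome_length <= 2 * max(cfg$sv_len_range)) {
    stopf("genome_length must exceed twice the maximum SV length")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  samples: %d (%d trios, %d duos)\n",
              x$n_samples, x$n_trios, x$n_duos))
  cat(sprintf("  sites: %d DEL, %d DUP, %d INV, %d chrX\n",
              x$n_del, x$n_dup, x$n_inv, x$n_chrx))
  cat(sprintf("  populations: %s\n",
              paste(sprintf("%s (%.2f)", x$populations$label,
                            x$populations$fraction), collapse = ", ")))
  cat(sprintf("  depth %g, support lambda %g, seed %d\n",
              x$depth_mean, x$support_lambda, x$seed))
  invisible(x)
}

## Default pseudoautosomal regions for the simulated chrX: the first 2% and
## final 1% of the chromosome, mirroring PAR1/PAR2 placement.
default_par_regions <- function(chrx_length) {
  data.frame(
    chrom = "chrX",
    start = c(0, round(0.99 * chrx_length)),
    end = c(round(0.02 * chrx_length), chrx_length)
  )
}
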