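#' Genotype matrix container
#'
#' The common result object for the joint genotyper and the input to the
#' filtering, pedigree-QC and population-genetics modules. Holds per-site
#' x per-sample genotype calls (dosage 0/1/2 for biallelic sites; 0/1 for
#' hemizygous male chromosome X), integer copy number, and the posterior
#' probability of the assigned class, plus per-site summaries (genotyping
#' mode, call rate, allele count/number/frequency, FILTER status).
#'
#' @param sites Data frame with at least `site_id`, `chrom`, `start`,
#'   `end`, `svtype`.
#' @param samples Character vector of sample identifiers.
#' @param gt Integer matrix (sites x samples) of genotype dosages; `NA` for
#'   no-calls.
#' @param cn Integer matrix of copy numbers (same shape).
#' @param qual Numeric matrix of assignment posteriors in `[0, 1]`.
#' @param mode Per-site genotyping mode label (`GT2D`, `GTDP`, `GTSUP`,
#'   `TRUTH`, ...).
#' @param sex Optional per-sample `"male"`/`"female"` labels; male samples
#'   contribute one allele on chrX sites.
#' @return An object of class `sv_genotypes`.
#' @export
new_sv_genotypes <- function(sites, samples, gt, cn, qual,
                             mode = "GT2D", sex = NULL) {
  stopifnot(nrow(gt) == nrow(sites), ncol(gt) == length(samples))
  dimnames(gt) <- dimnames(cn) <- dimnames(qual) <-
    list(sites$site_id, samples)
  st <- genotype_site_stats(sites, gt, samples, sex)
  sites$mode <- rep_len(mode, nrow(sites))
  sites$call_rate <- st$call_rate
  sites$AC <- st$AC
  sites$AN <- st$AN
  sites$AF <- st$AF
  if (is.null(sites$filter)) sites$filter <- "PASS"
  structure(list(sites = sites, samples = samples, sex = sex,
                 gt = gt, cn = cn, qual = qual),
            class = "sv_genotypes")
}

## AC/AN/AF from called genotypes only; on chrX males are hemizygous
## (1 allele), so AF = AC / (2 females + males called).
genotype_site_stats <- function(sites, gt, samples, sex) {
  male <- if (is.null(sex)) rep(FALSE, length(samples)) else sex == "male"
  is_x <- sites$chrom == "chrX"
  called <- !is.na(gt)
  ploidy <- matrix(2L, nrow(gt), ncol(gt))
  if (any(is_x)) ploidy[is_x, male] <- 1L
  an <- rowSums(called * ploidy)
  ac <- rowSums(gt * called, na.rm = TRUE)
  list(call_rate = rowMeans(called),
       AC = as.integer(ac), AN = as.integer(an),
       AF = ifelse(an > 0, ac / an, NA_real_))
}

#' @export
print.sv_genotypes <- function(x, ...) {
  cat(sprintf("<sv_genotypes> %d sites x %d samples\n",
              nrow(x$sites), length(x$samples)))
  cat(sprintf("  FILTER: %s\n",
              paste(sprintf("%d %s", table(x$sites$filter),
                            names(table(x$sites$filter))), collapse = ", ")))
  invisible(x)
}

#' Build an `sv_genotypes` object from simulated truth
#'
#' Wraps the true dosage/copy-number matrices of a simulated cohort in the
#' standard genotype container so that the pedigree-QC and popgen modules
#' can be run directly on truth (e.g. to calibrate error-rate estimators
#' against injected errors).
#'
#' @param truth A `sv_cohort_truth` object.
#' @return An `sv_genotypes` object with unit quality and mode `TRUTH`.
#' @export
truth_genotype_matrix <- function(truth) {
  qual <- matrix(1, nrow(truth$sites), nrow(truth$samples))
  new_sv_genotypes(truth$sites, truth$samples$sample,
                   gt = truth$dosage, cn = truth$cn, qual = qual,
                   mode = "TRUTH", sex = truth$samples$sex)
}
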