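#' Run the full joint-genotyping pipeline on a simulated cohort
#'
#' Chains every stage end to end: simulate the cohort, merge the
#' per-sample calls into candidate sites (1 kbp wobble, type-matched),
#' map candidates back to the evidence registry, fit per-sample GC
#' curves and normalize the evidence, infer sex and jointly genotype all
#' candidates (chrX handled with male depth compensation and PAR
#' exclusion), apply the duplication prefilter and (optionally) the
#' truth-trained SVM filter, and compute pedigree QC and population
#' summaries. Every stochastic step derives from `config$seed`, so two
#' runs with the same configuration produce byte-identical outputs.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory: when given, writes
#'   `genotypes.vcf`, `cohort.ped`, `frequencies.tsv`, `qc_mendelian.tsv`,
#'   `qc_allelic_balance.tsv` and `windows.tsv` there.
#' @param svm_filter Train the duplication SVM on simulation-truth labels
#'   and flag low-scoring DUP sites `LowQual` (requires both true and
#'   artifact DUP sites in the cohort).
#' @param wobble,refdist Merge wobble and candidate-to-registry matching
#'   distance (bp).
#' @return List: `sim`, `candidates`, `genotypes` (`sv_genotypes`),
#'   `qc`, `frequencies`, `windows`, `sex`, and the candidate/registry
#'   `matching`.
#' @export
run_sv_pipeline <- function(config, out_dir = NULL, svm_filter = FALSE,
                            wobble = 1000, refdist = 1000) {
  sim <- simulate_cohort(config)
  truth <- sim$truth

  candidates <- merge_calls(sim$calls, wobble = wobble)
  matching <- match_to_truth(candidates, truth$sites, refdist = refdist,
                             pctsize = 0.5, sizemin = 10)
  mc <- matching$calls
  hit <- mc[mc$matched, , drop = FALSE]
  hit <- hit[!duplicated(hit$truth_idx), , drop = FALSE]
  if (nrow(hit) < nrow(candidates)) {
    log_msg("pipeline: %d candidate(s) without evidence registry match dropped",
            nrow(candidates) - nrow(hit))
  }
  ## candidate coordinates, registry identity (the evidence key)
  sites <- data.frame(site_id = truth$sites$site_id[hit$truth_idx],
                      chrom = hit$chrom, start = hit$start, end = hit$end,
                      svtype = hit$svtype, stringsAsFactors = FALSE)
  sites <- sites[order(sites$chrom, sites$start, sites$end), ]
  rownames(sites) <- NULL

  curves <- fit_gc_curves(sim$interval_depths)
  ev <- normalize_evidence(sim$evidence, curves)
  sex <- infer_sex(sim$sex_depths)
  par <- default_par_regions(config$chrx_length)

  gtm <- genotype_cohort(sites, ev, sex = sex, par_regions = par)
  gtm <- prefilter_dups(gtm, ev)

  if (svm_filter) {
    dup <- gtm$sites$svtype == "DUP" & gtm$sites$filter != "PreFiltered"
    if (sum(dup) >= 10L) {
      feats <- extract_dup_features(gtm$sites[dup, , drop = FALSE], ev)
      labels <- !truth$sites$is_false[match(gtm$sites$site_id[dup],
                                            truth$sites$site_id)]
      if (length(unique(labels)) == 2L) {
        clf <- train_dup_classifier(feats, labels, seed = config$seed)
        res <- apply_dup_classifier(clf, feats, threshold = 0)
        gtm$sites$filter[which(dup)[res$low_qual]] <- "LowQual"
      }
    }
  }

  qc <- pedigree_qc(gtm, truth$pedigree)
  pops <- stats::setNames(truth$samples$population, truth$samples$sample)
  freqs <- compute_frequencies(gtm, pops)
  genome <- data.frame(chrom = c("chr1", "chrX"),
                       length = c(config$genome_length, config$chrx_length))
  windows <- window_scan(gtm$sites, genome, exclude = par)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_population_vcf(gtm, file.path(out_dir, "genotypes.vcf"))
    write_ped(truth, file.path(out_dir, "cohort.ped"))
    wtsv <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wtsv(freqs, "frequencies.tsv")
    wtsv(qc$mendelian, "qc_mendelian.tsv")
    wtsv(qc$allelic_balance, "qc_allelic_balance.tsv")
    wtsv(windows, "windows.tsv")
  }

  list(sim = sim, candidates = candidates, matching = matching,
       genotypes = gtm, sex = sex, qc = qc, frequencies = freqs,
       windows = windows)
}

#' Genotype concordance against simulation truth
#'
#' Compares called genotypes with the simulated truth per SV type:
#' deletions and inversions on allele dosage, duplications on integer
#' copy number. No-calls count as discordant.
#'
#' @param gtm An `sv_genotypes` whose `site_id`s are registry (truth) ids.
#' @param truth A `sv_cohort_truth`.
#' @return Data frame per SV type: `n_genotypes`, `concordance`.
#' @export
genotype_concordance <- function(gtm, truth) {
  idx <- match(gtm$sites$site_id, truth$sites$site_id)
  if (anyNA(idx)) stopf("genotype sites missing from truth registry")
  samp <- match(gtm$samples, truth$samples$sample)
  types <- sort(unique(gtm$sites$svtype))
  out <- lapply(types, function(tp) {
    rows <- which(gtm$sites$svtype == tp)
    called <- if (tp == "DUP") gtm$cn[rows, , drop = FALSE] else
      gtm$gt[rows, , drop = FALSE]
    true <- if (tp == "DUP") truth$cn[idx[rows], samp, drop = FALSE] else
      truth$dosage[idx[rows], samp, drop = FALSE]
    ok <- !is.na(called) & called == true
    data.frame(svtype = tp, n_genotypes = length(true),
               concordance = mean(ok))
  })
  do.call(rbind, out)
}
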