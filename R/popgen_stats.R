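## Population-level summaries: allele-frequency spectrum and rarity
## classes, Hudson FST with cohort sampling rules, SV-SNP linkage
## disequilibrium, hotspot/desert window scans, and cross-catalog overlap
## classification.

#' Site frequencies and rarity classes
#'
#' Computes AC/AN/AF per site from called genotypes only (missing calls
#' leave AN), plus per-population frequencies, and classifies every site
#' as `singleton` (AC == 1), `rare` (AF < 1%, AC > 1) or `common`.
#'
#' @param gtm An `sv_genotypes` object.
#' @param population_labels Per-sample population labels aligned with
#'   `gtm$samples` (named or positional).
#' @return Data frame per site: `site_id`, `svtype`, `AC`, `AN`, `AF`,
#'   `class`, and `AC_`/`AN_`/`AF_` columns per population.
#' @export
compute_frequencies <- function(gtm, population_labels = NULL) {
  if (length(gtm$samples) == 0L) stopf("empty cohort")
  s <- gtm$sites
  out <- data.frame(site_id = s$site_id, svtype = s$svtype,
                    AC = s$AC, AN = s$AN, AF = s$AF,
                    stringsAsFactors = FALSE)
  out$class <- ifelse(out$AC == 1L, "singleton",
                      ifelse(out$AF < 0.01, "rare", "common"))
  out$class[out$AC == 0L] <- "monomorphic"
  if (!is.null(population_labels)) {
    labs <- if (!is.null(names(population_labels)))
      unname(population_labels[gtm$samples]) else population_labels
    for (pop in sort(unique(labs))) {
      cols <- labs == pop
      sub <- gtm$gt[, cols, drop = FALSE]
      st <- genotype_site_stats(s, sub, gtm$samples[cols],
                                if (is.null(gtm$sex)) NULL else gtm$sex[cols])
      out[[paste0("AC_", pop)]] <- st$AC
      out[[paste0("AN_", pop)]] <- st$AN
      out[[paste0("AF_", pop)]] <- st$AF
    }
  }
  out
}

#' Per-site Hudson FST between two populations
#'
#' The Hudson estimator with finite-sample correction:
#' `[(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)] /
#'  [p1(1-p2) + p2(1-p1)]`
#' with `p` the allele frequency and `n` the allele number in each
#' population. Sites where the denominator is zero (both populations
#' identically fixed) are returned as `NA` and flagged.
#'
#' @param ac1,an1 Allele counts and numbers in population 1 (vectors).
#' @param ac2,an2 Same for population 2.
#' @return List: `fst` (per-site; `NA` where undefined), `skipped`
#'   (logical), `mean` (ratio of averages over defined sites).
#' @export
hudson_fst <- function(ac1, an1, ac2, an2) {
  p1 <- ac1 / an1
  p2 <- ac2 / an2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (an1 - 1) - p2 * (1 - p2) / (an2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  skipped <- !is.finite(den) | den == 0
  fst <- ifelse(skipped, NA_real_, num / den)
  list(fst = fst,
       skipped = skipped,
       mean = sum(num[!skipped]) / sum(den[!skipped]))
}

#' Cohort FST scan with the population sampling rules
#'
#' Applies the cohort rules before the per-site Hudson estimator: both
#' populations must have at least `min_samples` members (else an error),
#' populations larger than `max_samples` are randomly subset to
#' `max_samples` with the given seed, and sites with combined allele
#' count of 1 (singletons) are excluded.
#'
#' @param gtm An `sv_genotypes` object.
#' @param population_labels Per-sample labels aligned with `gtm$samples`.
#' @param pop1,pop2 Labels of the two populations compared.
#' @param min_samples Minimum population size, default 1000.
#' @param max_samples Subsampling cap, default 7000.
#' @param seed Seed for the subsampling draw.
#' @return Data frame per retained site (`site_id`, `svtype`, `af1`,
#'   `af2`, `fst`) with the ratio-of-averages mean in
#'   `attr(, "mean_fst")`.
#' @export
fst_scan <- function(gtm, population_labels, pop1, pop2,
                     min_samples = 1000, max_samples = 7000, seed = 1L) {
  labs <- if (!is.null(names(population_labels)))
    unname(population_labels[gtm$samples]) else population_labels
  take <- function(pop) {
    i <- which(labs == pop)
    if (length(i) < min_samples) {
      stopf("population %s has %d samples; minimum is %d",
            pop, length(i), min_samples)
    }
    if (length(i) > max_samples) {
      set.seed(seed)
      i <- sort(sample(i, max_samples))
    }
    i
  }
  i1 <- take(pop1); i2 <- take(pop2)
  stats_for <- function(i) {
    genotype_site_stats(gtm$sites, gtm$gt[, i, drop = FALSE],
                        gtm$samples[i],
                        if (is.null(gtm$sex)) NULL else gtm$sex[i])
  }
  s1 <- stats_for(i1); s2 <- stats_for(i2)
  keep <- (s1$AC + s2$AC) != 1L & s1$AN > 1 & s2$AN > 1
  h <- hudson_fst(s1$AC[keep], s1$AN[keep], s2$AC[keep], s2$AN[keep])
  out <- data.frame(site_id = gtm$sites$site_id[keep],
                    svtype = gtm$sites$svtype[keep],
                    af1 = s1$AC[keep] / s1$AN[keep],
                    af2 = s2$AC[keep] / s2$AN[keep],
                    fst = h$fst, stringsAsFactors = FALSE)
  attr(out, "mean_fst") <- h$mean
  out
}

#' SV-SNP linkage disequilibrium
#'
#' Squared Pearson correlation of allele dosages between one SV and every
#' SNP within a window of its breakpoints, over samples non-missing in
#' both vectors. Pairs where either vector has minor allele frequency
#' below `maf_min`, zero variance, or `r^2` below `min_r2` are omitted.
#'
#' @param sv_dosage Dosage vector (0/1/2) of the SV over the analysis
#'   samples (typically founders).
#' @param sv_pos SV midpoint or breakpoint position (bp).
#' @param snp_dosage SNP x sample dosage matrix over the same samples.
#' @param snp_pos Per-SNP positions (bp).
#' @param window Maximum distance (bp), default 1 Mbp.
#' @param min_r2 Reporting floor, default 0.05.
#' @param maf_min Minor-allele-frequency floor, default 0.001.
#' @return Data frame: `snp` (row index or name), `distance`, `r2`.
#' @export
ld_r2 <- function(sv_dosage, sv_pos, snp_dosage, snp_pos,
                  window = 1e6, min_r2 = 0.05, maf_min = 0.001) {
  in_win <- which(abs(snp_pos - sv_pos) <= window)
  ids <- rownames(snp_dosage) %||% as.character(seq_len(nrow(snp_dosage)))
  rows <- lapply(in_win, function(j) {
    snp <- snp_dosage[j, ]
    ok <- !is.na(sv_dosage) & !is.na(snp)
    x <- sv_dosage[ok]; y <- snp[ok]
    if (length(x) < 2L) return(NULL)
    maf <- function(v) {
      p <- mean(v) / 2
      min(p, 1 - p)
    }
    if (maf(x) < maf_min || maf(y) < maf_min) return(NULL)
    if (stats::var(x) == 0 || stats::var(y) == 0) return(NULL)
    r2 <- stats::cor(x, y)^2
    if (r2 < min_r2) return(NULL)
    data.frame(snp = ids[j], distance = abs(snp_pos[j] - sv_pos), r2 = r2,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(snp = character(), distance = numeric(),
                      r2 = numeric()))
  }
  do.call(rbind, rows)
}

#' Genome window scan for SV hotspots and deserts
#'
#' Splits each chromosome into disjoint windows (100 kb by default),
#' removes windows overlapping the exclusion regions (e.g. centromeres
#' and assembly gaps), drops SVs shorter than `min_len`, counts each SV
#' in every window its span intersects, and classifies windows: hotspots
#' have counts above `mean + k_sd * SD` of the retained window counts,
#' deserts have zero SVs.
#'
#' @param sites SV site table (`chrom`, `start`, `end`).
#' @param genome Data frame `chrom`, `length`.
#' @param exclude Optional exclusion region table (`chrom`, `start`,
#'   `end`).
#' @param window Window size (bp), default 100 kb.
#' @param min_len Minimum SV length counted, default 50 bp.
#' @param k_sd Hotspot threshold in SDs above the mean, default 3.
#' @return Data frame per retained window: `chrom`, `start`, `end`,
#'   `sv_count`, `classification` (`hotspot`/`desert`/`neither`), with
#'   the count mean/SD in attributes.
#' @export
window_scan <- function(sites, genome, exclude = NULL, window = 1e5,
                        min_len = 50, k_sd = 3) {
  sites <- sites[(sites$end - sites$start) >= min_len, , drop = FALSE]
  wins <- do.call(rbind, lapply(seq_len(nrow(genome)), function(g) {
    starts <- seq(0, genome$length[g] - 1, by = window)
    data.frame(chrom = genome$chrom[g], start = starts,
               end = pmin(starts + window, genome$length[g]),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    drop <- vapply(seq_len(nrow(wins)), function(i) {
      any(overlaps_region_set(wins$chrom[i], wins$start[i], wins$end[i],
                              exclude))
    }, logical(1))
    wins <- wins[!drop, , drop = FALSE]
  }
  wins$sv_count <- vapply(seq_len(nrow(wins)), function(i) {
    sel <- sites$chrom == wins$chrom[i]
    sum(interval_overlap(sites$start[sel], sites$end[sel],
                         wins$start[i], wins$end[i]) > 0)
  }, numeric(1))
  m <- mean(wins$sv_count); sdev <- stats::sd(wins$sv_count)
  wins$classification <- ifelse(
    wins$sv_count == 0, "desert",
    ifelse(wins$sv_count > m + k_sd * sdev, "hotspot", "neither"))
  rownames(wins) <- NULL
  attr(wins, "count_mean") <- m
  attr(wins, "count_sd") <- sdev
  wins
}

#' Classify query SVs as known or novel against a catalog
#'
#' A query is `known` when some same-type catalog entry overlaps it by at
#' least `threshold` — reciprocally by default (the overlap must be at
#' least that fraction of *both* SV lengths), or of the query length only
#' with `mode = "query"`.
#'
#' @param query,catalog Site tables (`chrom`, `start`, `end`, `svtype`).
#' @param threshold Overlap fraction, default 0.70.
#' @param mode `"reciprocal"` (default) or `"query"`.
#' @return The query table with a logical `known` column; novelty
#'   fractions (overall and per type) in `attr(, "novelty")`.
#' @export
overlap_classify <- function(query, catalog, threshold = 0.70,
                             mode = c("reciprocal", "query")) {
  mode <- match.arg(mode)
  known <- vapply(seq_len(nrow(query)), function(i) {
    sel <- catalog$svtype == query$svtype[i] &
      catalog$chrom == query$chrom[i]
    if (!any(sel)) return(FALSE)
    ov <- interval_overlap(query$start[i], query$end[i],
                           catalog$start[sel], catalog$end[sel])
    q_frac <- ov / (query$end[i] - query$start[i])
    c_frac <- ov / (catalog$end[sel] - catalog$start[sel])
    if (mode == "reciprocal") any(q_frac >= threshold & c_frac >= threshold)
    else any(q_frac >= threshold)
  }, logical(1))
  query$known <- known
  novelty <- c(overall = mean(!known),
               tapply(!known, query$svtype, mean))
  attr(query, "novelty") <- novelty
  query
}
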