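## Post-genotyping duplication and chromosome-X filters. Rule-based
## prefiltering flags depth-nonconforming and redundant duplications;
## an SVM over cohort-level site features flags the remainder. Flags only
## ever touch the FILTER status, never the genotypes.

#' Rule-based duplication prefilter
#'
#' Flags a duplication as `PreFiltered` when either (a) its carriers'
#' mean normalized depth deviates from the copy-number expectation
#' (`CN / 2`) by more than `depth_tol`, or (b) it overlaps another
#' duplication reciprocally by at least `overlap_min` with carrier
#' genotype concordance of at least `concord_min`, in which case the
#' lower-quality member of the pair (lower call rate; ties broken by
#' smaller length, then by coordinate order) is flagged.
#'
#' @param gtm An `sv_genotypes` object.
#' @param evidence Normalized evidence table (provides per-sample `ndepth`).
#' @param depth_tol Depth-aberrance threshold, default 0.25.
#' @param overlap_min Reciprocal-overlap threshold, default 0.5.
#' @param concord_min Genotype-concordance threshold, default 0.95.
#' @return The `sv_genotypes` object with updated FILTER; the logical flag
#'   vector (all sites) is attached as `attr(, "prefiltered")`.
#' @export
prefilter_dups <- function(gtm, evidence, depth_tol = 0.25,
                           overlap_min = 0.5, concord_min = 0.95) {
  s <- gtm$sites
  dup <- which(s$svtype == "DUP")
  flag <- rep(FALSE, nrow(s))
  if (length(dup) == 0L) {
    attr(gtm, "prefiltered") <- flag
    return(gtm)
  }
  nd <- evidence_ndepth_matrix(evidence, s$site_id, gtm$samples)

  ## (a) depth conformance of carriers
  for (i in dup) {
    carrier <- which(!is.na(gtm$gt[i, ]) & gtm$gt[i, ] > 0L)
    if (!length(carrier)) next
    expected <- mean(gtm$cn[i, carrier], na.rm = TRUE) / 2
    observed <- mean(nd[i, carrier])
    if (is.finite(expected) && abs(observed - expected) > depth_tol) {
      flag[i] <- TRUE
    }
  }

  ## (b) concordant genotypes on heavily overlapping duplications
  for (ai in seq_along(dup)) {
    i <- dup[ai]
    for (bi in seq_len(ai - 1L)) {
      j <- dup[bi]
      if (s$chrom[i] != s$chrom[j]) next
      ov <- interval_overlap(s$start[i], s$end[i], s$start[j], s$end[j])
      len_i <- s$end[i] - s$start[i]; len_j <- s$end[j] - s$start[j]
      if (ov / len_i < overlap_min || ov / len_j < overlap_min) next
      conc <- carrier_concordance(gtm$cn[i, ], gtm$cn[j, ])
      if (is.na(conc) || conc < concord_min) next
      flag[pick_lower_quality(s, i, j)] <- TRUE
    }
  }
  gtm$sites$filter[flag] <- "PreFiltered"
  attr(gtm, "prefiltered") <- flag
  gtm
}

## Genotype concordance over the union of carriers of two sites, using
## samples called at both; NA when no carrier is shared-callable.
carrier_concordance <- function(cn_a, cn_b) {
  called <- !is.na(cn_a) & !is.na(cn_b)
  carrier <- called & (cn_a != 2L | cn_b != 2L)
  if (!any(carrier)) return(NA_real_)
  mean(cn_a[carrier] == cn_b[carrier])
}

pick_lower_quality <- function(s, i, j) {
  if (s$call_rate[i] != s$call_rate[j]) {
    return(if (s$call_rate[i] < s$call_rate[j]) i else j)
  }
  len_i <- s$end[i] - s$start[i]; len_j <- s$end[j] - s$start[j]
  if (len_i != len_j) return(if (len_i < len_j) i else j)
  if (s$start[i] != s$start[j]) return(if (s$start[i] > s$start[j]) i else j)
  max(i, j)
}

evidence_ndepth_matrix <- function(evidence, site_ids, samples) {
  nd <- matrix(NA_real_, length(site_ids), length(samples),
               dimnames = list(site_ids, samples))
  idx <- cbind(match(evidence$site_id, site_ids),
               match(evidence$sample_id, samples))
  keep <- !is.na(idx[, 1]) & !is.na(idx[, 2])
  nd[idx[keep, , drop = FALSE]] <- evidence$ndepth[keep]
  nd
}

#' Extract duplication filter features
#'
#' Cohort-level feature vector per duplication site: means over samples of
#' the normalized flank depth statistics before (`pre_mean`, `pre_sd`) and
#' after (`post_mean`, `post_sd`) the event, plus the site GC fraction.
#'
#' @param sites Site table (`site_id`, used for row order).
#' @param evidence Normalized evidence table.
#' @return Data frame of five features, one row per site in `sites`.
#' @export
extract_dup_features <- function(sites, evidence) {
  rows <- split(seq_len(nrow(evidence)), evidence$site_id)
  feat <- t(vapply(sites$site_id, function(id) {
    r <- rows[[id]]
    if (is.null(r)) stopf("no evidence for site %s", id)
    ev <- evidence[r, ]
    c(pre_mean = mean(ev$pre_mean_n), pre_sd = mean(ev$pre_sd_n),
      post_mean = mean(ev$post_mean_n), post_sd = mean(ev$post_sd_n),
      gc_frac = ev$gc_frac[1])
  }, numeric(5)))
  as.data.frame(feat)
}

#' Extract chromosome-X filter features
#'
#' Per-site features for chrX SVM filtering: cohort mean and SD of the
#' normalized event depth, the difference in allele frequency between
#' female and male samples, the difference in call rate between male and
#' female samples, and indicators for the presence of split-read and
#' soft-clip breakpoint support.
#'
#' @param gtm An `sv_genotypes` object restricted to (or containing) chrX
#'   sites.
#' @param evidence Normalized evidence table.
#' @param sex Per-sample sex labels aligned with `gtm$samples`.
#' @return Data frame of six features, one row per site of `gtm`.
#' @export
extract_chrx_features <- function(gtm, evidence, sex) {
  male <- sex == "male"; female <- sex == "female"
  if (!any(male, na.rm = TRUE) || !any(female, na.rm = TRUE)) {
    stopf("chrX features need both sexes in the cohort")
  }
  rows <- split(seq_len(nrow(evidence)), evidence$site_id)
  out <- lapply(seq_len(nrow(gtm$sites)), function(i) {
    id <- gtm$sites$site_id[i]
    r <- rows[[id]]
    if (is.null(r)) stopf("no evidence for site %s", id)
    ev <- evidence[r, ]
    gt <- gtm$gt[i, ]
    af_f <- sex_af(gt[female], ploidy = 2L)
    af_m <- sex_af(gt[male], ploidy = 1L)
    carrier_samples <- gtm$samples[!is.na(gt) & gt > 0L]
    evc <- ev[ev$sample_id %in% carrier_samples, , drop = FALSE]
    data.frame(
      depth_mean = mean(ev$ndepth), depth_sd = stats::sd(ev$ndepth),
      af_sex_diff = af_f - af_m,
      callrate_sex_diff = mean(!is.na(gt[male])) - mean(!is.na(gt[female])),
      has_split_support = as.integer(sum(evc$n_split) > 0),
      has_clip_support = as.integer(sum(evc$n_clip) > 0)
    )
  })
  do.call(rbind, out)
}

## A sex with no called genotypes contributes frequency 0; the call-rate
## difference feature carries the missingness signal, keeping features
## finite as the classifier requires.
sex_af <- function(gt, ploidy) {
  called <- !is.na(gt)
  if (!any(called)) return(0)
  sum(gt[called]) / (ploidy * sum(called))
}

#' Train an SVM site filter
#'
#' Fits an RBF-kernel support vector machine separating true from
#' artifact sites on cohort-level features, with hyper-parameters chosen
#' by grid search over a small fixed (cost, gamma) grid using
#' deterministic 5-fold cross-validated accuracy. Scores are oriented so
#' that higher means more likely a true site.
#'
#' @param features Data frame of numeric features.
#' @param labels Logical (or coercible) vector: `TRUE` for true sites,
#'   `FALSE` for artifacts. Both classes must be present.
#' @param seed Integer seed controlling fold assignment.
#' @param cost_grid,gamma_grid Hyper-parameter grids.
#' @return Object of class `sv_svm`.
#' @export
train_dup_classifier <- function(features, labels, seed = 1L,
                                 cost_grid = c(0.5, 1, 5, 10),
                                 gamma_grid = c(0.05, 0.2, 1)) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L) {
    stopf("classifier training needs both classes present")
  }
  x <- as.matrix(features)
  y <- factor(ifelse(labels, "true", "false"), levels = c("false", "true"))
  set.seed(seed)
  folds <- sample(rep_len(1:5, nrow(x)))
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    mean(vapply(1:5, function(f) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2L) return(NA_real_)
      m <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                      cost = grid$cost[g], gamma = grid$gamma[g])
      mean(stats::predict(m, x[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  best <- which.max(acc)
  model <- e1071::svm(x, y, kernel = "radial", cost = grid$cost[best],
                      gamma = grid$gamma[best])
  dv <- attr(stats::predict(model, x, decision.values = TRUE),
             "decision.values")[, 1]
  orient <- if (mean(dv[labels]) >= mean(dv[!labels])) 1 else -1
  structure(list(model = model, orientation = orient,
                 features = colnames(x),
                 cost = grid$cost[best], gamma = grid$gamma[best],
                 cv_accuracy = acc[best]),
            class = "sv_svm")
}

#' @export
print.sv_svm <- function(x, ...) {
  cat(sprintf("<sv_svm> RBF, cost %g gamma %g, CV accuracy %.3f\n",
              x$cost, x$gamma, x$cv_accuracy))
  invisible(x)
}

#' Score sites with a trained SVM filter
#'
#' @param classifier An `sv_svm` from [train_dup_classifier()].
#' @param features Feature data frame with the training columns.
#' @param threshold Score cutoff: sites scoring below it are flagged
#'   `LowQual`. `-Inf` flags nothing.
#' @return List: `score` (higher = more likely true) and logical
#'   `low_qual`.
#' @export
apply_dup_classifier <- function(classifier, features, threshold = 0) {
  x <- as.matrix(features[, classifier$features, drop = FALSE])
  dv <- attr(stats::predict(classifier$model, x, decision.values = TRUE),
             "decision.values")[, 1]
  score <- unname(classifier$orientation * dv)
  list(score = score, low_qual = score < threshold)
}

#' SVM-based chromosome-X site filter
#'
#' Extracts the chrX feature set, scores it with a classifier trained by
#' [train_dup_classifier()] on labeled chrX sites, and flags failing
#' sites `LowQual`.
#'
#' @param gtm An `sv_genotypes` object with chrX sites.
#' @param evidence Normalized evidence table.
#' @param sex Per-sample sex labels aligned with `gtm$samples`.
#' @param classifier A trained `sv_svm`.
#' @param threshold Score cutoff (as in [apply_dup_classifier()]).
#' @return The `sv_genotypes` with updated FILTER; scores attached as
#'   `attr(, "chrx_scores")`.
#' @export
filter_chrx <- function(gtm, evidence, sex, classifier, threshold = 0) {
  feats <- extract_chrx_features(gtm, evidence, sex)
  res <- apply_dup_classifier(classifier, feats, threshold)
  flag <- res$low_qual & gtm$sites$filter != "PreFiltered"
  gtm$sites$filter[flag] <- "LowQual"
  attr(gtm, "chrx_scores") <- res$score
  gtm
}
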