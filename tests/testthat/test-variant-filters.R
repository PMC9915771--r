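## A small genotyped cohort with one conforming DUP, one depth-aberrant
## DUP, and one concordant overlapping DUP pair.
dup_fixture <- function(seed = 20) {
  set.seed(seed)
  n <- 60
  samples <- sprintf("S%03d", seq_len(n))
  carriers <- 1:12
  gt <- matrix(0L, 4, n, dimnames = list(NULL, samples))
  gt[, carriers] <- 1L
  cn <- gt + 2L
  sites <- data.frame(
    site_id = c("D1", "D2", "D3", "D4"),
    chrom = "chr1",
    start = c(10000L, 50000L, 90000L, 90500L),
    end = c(20000L, 60000L, 100000L, 100000L),
    svtype = "DUP", stringsAsFactors = FALSE
  )
  gtm <- new_sv_genotypes(sites, samples, gt = gt, cn = cn,
                          qual = matrix(1, 4, n), mode = "GT2D")
  nd_for <- function(expected_het) {
    nd <- rnorm(n, 1, 0.03)
    nd[carriers] <- rnorm(length(carriers), expected_het, 0.03)
    nd
  }
  ev <- rbind(
    toy_site_evidence(nd_for(1.5), rpois(n, 3), "D1"),
    toy_site_evidence(nd_for(1.05), rpois(n, 3), "D2"),  # aberrant depth
    toy_site_evidence(nd_for(1.5), rpois(n, 3), "D3"),
    toy_site_evidence(nd_for(1.5), rpois(n, 3), "D4")
  )
  list(gtm = gtm, ev = ev)
}

test_that("the prefilter flags depth-aberrant and redundant duplications", {
  f <- dup_fixture()
  out <- prefilter_dups(f$gtm, f$ev)
  flt <- setNames(out$sites$filter, out$sites$site_id)
  expect_equal(unname(flt["D1"]), "PASS")          # conforming carriers
  expect_equal(unname(flt["D2"]), "PreFiltered")   # carriers at depth 1.05
  ## of the 90%-overlap concordant pair, exactly the shorter one goes
  expect_equal(unname(flt["D3"]), "PASS")
  expect_equal(unname(flt["D4"]), "PreFiltered")
  ## genotypes are untouched
  expect_identical(out$gt, f$gtm$gt)
})

test_that("prefiltering an all-PASS or empty DUP set changes nothing", {
  f <- dup_fixture()
  solo <- f$gtm
  solo$sites <- solo$sites[1, , drop = FALSE]
  solo$gt <- solo$gt[1, , drop = FALSE]
  solo$cn <- solo$cn[1, , drop = FALSE]
  solo$qual <- solo$qual[1, , drop = FALSE]
  out <- prefilter_dups(solo, f$ev)
  expect_equal(out$sites$filter, "PASS")
  none <- toy_genotypes(matrix(0L, 2, 10), svtype = "DEL")
  expect_equal(prefilter_dups(none, f$ev)$sites$filter, rep("PASS", 2))
})

test_that("duplication features equal their brute-force recomputation", {
  f <- dup_fixture()
  feats <- extract_dup_features(f$gtm$sites, f$ev)
  for (i in 1:4) {
    rows <- f$ev$site_id == f$gtm$sites$site_id[i]
    expect_equal(feats$pre_mean[i], mean(f$ev$pre_mean_n[rows]))
    expect_equal(feats$post_sd[i], mean(f$ev$post_sd_n[rows]))
    expect_equal(feats$gc_frac[i], f$ev$gc_frac[rows][1])
  }
})

test_that("the SVM separates separable features and honors the threshold", {
  set.seed(22)
  n <- 80
  feats <- data.frame(
    pre_mean = c(rnorm(n / 2, 1, 0.02), rnorm(n / 2, 1, 0.02)),
    pre_sd = c(rnorm(n / 2, 0.05, 0.005), rnorm(n / 2, 0.30, 0.02)),
    post_mean = rnorm(n, 1, 0.02),
    post_sd = c(rnorm(n / 2, 0.05, 0.005), rnorm(n / 2, 0.30, 0.02)),
    gc_frac = runif(n, 0.3, 0.6)
  )
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  clf <- train_dup_classifier(feats, labels, seed = 1)
  res <- apply_dup_classifier(clf, feats, threshold = 0)
  expect_equal(res$low_qual, !labels)          # 100% training separation
  expect_false(any(apply_dup_classifier(clf, feats, -Inf)$low_qual))
  ## retraining with the same seed is bit-reproducible
  clf2 <- train_dup_classifier(feats, labels, seed = 1)
  expect_identical(apply_dup_classifier(clf2, feats, 0)$score, res$score)
  expect_error(train_dup_classifier(feats, rep(TRUE, n), seed = 1),
               "both classes")
})

test_that("SVM filtering of simulated artifact DUPs raises PPV and keeps most true DUPs", {
  cfg <- sim_config(n_samples = 300, n_del = 0, n_dup = 60, n_inv = 0,
                    false_candidate_rate = 0.25, af_shape1 = 2,
                    af_shape2 = 3, seed = 23)
  sim <- simulate_cohort(cfg)
  curves <- fit_gc_curves(sim$interval_depths)
  ev <- normalize_evidence(sim$evidence, curves)
  gtm <- genotype_cohort(sim$truth$sites, ev)
  is_true <- !sim$truth$sites$is_false
  feats <- extract_dup_features(gtm$sites, ev)
  clf <- train_dup_classifier(feats, is_true, seed = 5)
  res <- apply_dup_classifier(clf, feats, threshold = 0)
  kept <- !res$low_qual
  ppv_before <- mean(is_true)
  ppv_after <- mean(is_true[kept])
  expect_gt(ppv_after, ppv_before)
  expect_lt(mean(res$low_qual[is_true]), 0.30)   # < 30% true DUPs lost
})

test_that("chrX features match per-sex recomputation and flag sex artifacts", {
  set.seed(24)
  n <- 80
  sex <- rep(c("male", "female"), each = n / 2)
  male <- sex == "male"
  gt <- matrix(0L, 2, n, dimnames = list(NULL, sprintf("S%03d", 1:n)))
  gt[1, c(1:4, 41:48)] <- 1L       # site 1: called in both sexes
  gt[2, male] <- NA_integer_       # site 2: genotyped only in females
  gt[2, 41:44] <- 1L
  sites <- data.frame(site_id = c("X1", "X2"), chrom = "chrX",
                      start = c(2e6, 3e6), end = c(2.1e6, 3.1e6),
                      svtype = "DEL", stringsAsFactors = FALSE)
  gtm <- new_sv_genotypes(sites, colnames(gt), gt,
                          cn = 2L - ifelse(is.na(gt), 0L, gt),
                          qual = matrix(1, 2, n), mode = "GT2D", sex = sex)
  ev <- rbind(toy_site_evidence(rnorm(n, 1, 0.05), rpois(n, 2), "X1"),
              toy_site_evidence(rnorm(n, 1, 0.05), rpois(n, 2), "X2"))
  feats <- extract_chrx_features(gtm, ev, sex)
  ## brute-force per-sex recomputation for site 1
  af_f <- sum(gt[1, !male]) / (2 * sum(!male))
  af_m <- sum(gt[1, male]) / sum(male)
  expect_equal(feats$af_sex_diff[1], af_f - af_m)
  expect_equal(feats$callrate_sex_diff[1], 0)
  expect_equal(feats$callrate_sex_diff[2], -1)   # males all missing
  expect_error(extract_chrx_features(gtm, ev, rep("female", n)),
               "both sexes")

  ## a classifier trained on such labels separates the artifact site
  many <- do.call(rbind, lapply(1:30, function(k) {
    jitter <- rnorm(6, 0, 0.01)
    rbind(feats[1, ] + jitter, feats[2, ] + jitter)
  }))
  labels <- rep(c(TRUE, FALSE), 30)
  clf <- train_dup_classifier(many, labels, seed = 2)
  gtm2 <- filter_chrx(gtm, ev, sex, clf, threshold = 0)
  expect_equal(gtm2$sites$filter, c("PASS", "LowQual"))
})
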