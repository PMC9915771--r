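test_that("frequencies and rarity classes follow their definitions", {
  gt <- matrix(0L, 3, 100, dimnames = list(NULL, sprintf("S%03d", 1:100)))
  gt[1, 1] <- 1L                       # singleton
  gt[2, 1:30] <- 1L                    # common
  gtm <- toy_genotypes(gt)
  fr <- compute_frequencies(gtm)
  expect_equal(fr$AC, c(1L, 30L, 0L))
  expect_equal(fr$AN, rep(200L, 3))
  expect_equal(fr$class, c("singleton", "common", "monomorphic"))
  ## missing genotypes leave AN
  gt[3, 1:10] <- NA_integer_
  fr2 <- compute_frequencies(toy_genotypes(gt))
  expect_equal(fr2$AN[3], 180L)
})

test_that("per-population frequencies equal brute-force counting", {
  cfg <- sim_config(
    n_samples = 300, n_del = 20,
    populations = data.frame(label = c("A", "B"), fraction = c(0.5, 0.5)),
    divergence = 0.05, seed = 33)
  sim <- simulate_cohort(cfg)
  gtm <- truth_genotype_matrix(sim$truth)
  pops <- setNames(sim$truth$samples$population, sim$truth$samples$sample)
  fr <- compute_frequencies(gtm, pops)
  a <- sim$truth$samples$population == "A"
  for (i in c(1, 7, 20)) {
    expect_equal(fr$AC_A[i], sum(sim$truth$dosage[i, a]))
    expect_equal(fr$AN_A[i], 2L * sum(a))
  }
  expect_error(compute_frequencies(toy_genotypes(matrix(0L, 1, 0))),
               "empty")
})

test_that("Hudson FST matches the formula oracle to 1e-12", {
  set.seed(34)
  n <- 2000
  an1 <- sample(500:4000, n, replace = TRUE)
  an2 <- sample(500:4000, n, replace = TRUE)
  ac1 <- rbinom(n, an1, runif(n, 0.01, 0.99))
  ac2 <- rbinom(n, an2, runif(n, 0.01, 0.99))
  h <- hudson_fst(ac1, an1, ac2, an2)
  oracle <- oracle_hudson_fst(ac1 / an1, an1, ac2 / an2, an2)
  expect_lt(max(abs(h$fst - oracle), na.rm = TRUE), 1e-12)
  ## symmetry under population swap
  h2 <- hudson_fst(ac2, an2, ac1, an1)
  expect_equal(h$fst, h2$fst, tolerance = 1e-14)
  ## fixed difference gives exactly 1; equal frequencies at most 0
  expect_equal(hudson_fst(1000, 1000, 0, 1000)$fst, 1)
  expect_lte(hudson_fst(300, 1000, 300, 1000)$fst, 0)
  ## both populations identically fixed -> undefined, skipped
  h3 <- hudson_fst(c(1000, 5), 1000, c(1000, 7), 1000)
  expect_true(h3$skipped[1])
  expect_false(h3$skipped[2])
})

test_that("the FST scan enforces size rules, subsampling and singleton exclusion", {
  n_per <- 1200
  gt <- matrix(0L, 3, 2 * n_per,
               dimnames = list(NULL, sprintf("S%05d", 1:(2 * n_per))))
  gt[1, 1:600] <- 1L                  # differentiated in pop A
  gt[2, 1] <- 1L                      # cohort singleton -> excluded
  gt[3, c(5, 2000)] <- 1L             # AC 2, retained
  gtm <- toy_genotypes(gt)
  pops <- rep(c("A", "B"), each = n_per)
  fst <- fst_scan(gtm, pops, "A", "B", min_samples = 1000,
                  max_samples = 7000, seed = 2)
  expect_setequal(fst$site_id, gtm$sites$site_id[c(1, 3)])
  expect_gt(fst$fst[fst$site_id == gtm$sites$site_id[1]], 0.1)
  expect_error(fst_scan(gtm, pops, "A", "B", min_samples = 5000),
               "minimum")
  ## subsampling cap applies and is seed-deterministic
  fst_a <- fst_scan(gtm, pops, "A", "B", max_samples = 1000, seed = 9)
  fst_b <- fst_scan(gtm, pops, "A", "B", max_samples = 1000, seed = 9)
  expect_identical(fst_a, fst_b)
})

test_that("mean FST rises with simulated population divergence", {
  means <- vapply(c(0.01, 0.05, 0.15), function(f) {
    cfg <- sim_config(
      n_samples = 2400, n_del = 40, n_dup = 0, n_inv = 0,
      populations = data.frame(label = c("A", "B"), fraction = c(0.5, 0.5)),
      divergence = f, af_shape1 = 2, af_shape2 = 2, n_intervals = 100,
      seed = 35)
    sim <- simulate_cohort(cfg)
    gtm <- truth_genotype_matrix(sim$truth)
    pops <- setNames(sim$truth$samples$population,
                     sim$truth$samples$sample)
    attr(fst_scan(gtm, pops, "A", "B", seed = 1), "mean_fst")
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("r2 equals the dosage-correlation oracle and its invariances", {
  set.seed(36)
  n <- 500
  sv <- rbinom(n, 2, 0.3)
  snps <- rbind(sv, rbinom(n, 2, 0.4), rbinom(n, 2, 0.25))
  rownames(snps) <- c("self", "x1", "x2")
  ld <- ld_r2(sv, 5e5, snps, c(5e5, 6e5, 9e5), min_r2 = 0, maf_min = 0)
  expect_equal(ld$r2[ld$snp == "self"], 1)
  for (s in c("x1", "x2")) {
    expect_equal(ld$r2[ld$snp == s],
                 stats::cor(sv, snps[s, ])^2, tolerance = 1e-12)
  }
  ## allele-label flip leaves r2 unchanged
  ld_f <- ld_r2(2 - sv, 5e5, snps, c(5e5, 6e5, 9e5), min_r2 = 0,
                maf_min = 0)
  expect_equal(ld_f$r2, ld$r2, tolerance = 1e-12)
  ## window, MAF floor and zero-variance skipping
  far <- ld_r2(sv, 5e5, snps, c(5e5, 6e5, 2e6), min_r2 = 0, maf_min = 0)
  expect_false("x2" %in% far$snp)
  mono <- rbind(rep(0, n)); rownames(mono) <- "m"
  expect_equal(nrow(ld_r2(sv, 1, mono, 1, min_r2 = 0, maf_min = 0)), 0)
})

test_that("independent SV/SNP pairs rarely exceed the r2 floor", {
  set.seed(37)
  n <- 3000
  sv <- rbinom(n, 2, 0.3)
  snps <- matrix(rbinom(200 * n, 2, 0.3), nrow = 200)
  r2 <- apply(snps, 1, function(s) stats::cor(sv, s)^2)
  ld <- ld_r2(sv, 0, snps, rep(0, 200), min_r2 = 0.05, maf_min = 0.001)
  expect_equal(nrow(ld), sum(r2 >= 0.05))
  expect_gte(mean(r2 < 0.05), 0.99)
})

test_that("window scan finds injected hotspots, deserts and conserves counts", {
  genome <- data.frame(chrom = "chr1", length = 3e6)   # 30 x 100 kb
  set.seed(38)
  ## background: ~5 SVs per window; one empty window; one cluster of 50
  bg_start <- sort(sample(setdiff(0:(3e6 - 200), c(10e5:11e5, 20e5:21e5)),
                          150))
  bg_start <- bg_start[!(bg_start >= 9.98e5 & bg_start < 11e5) &
                         !(bg_start >= 19.98e5 & bg_start < 21e5)]
  cluster_start <- sample(20e5:(20.9e5), 50)
  sites <- data.frame(
    chrom = "chr1",
    start = c(bg_start, cluster_start),
    end = c(bg_start, cluster_start) + 100,
    svtype = "DEL", stringsAsFactors = FALSE)
  w <- window_scan(sites, genome, window = 1e5, min_len = 50, k_sd = 3)
  expect_equal(nrow(w), 30)
  hot <- w[w$classification == "hotspot", ]
  expect_true(any(hot$start == 20e5))
  expect_equal(w$classification[w$start == 10e5], "desert")
  ## conservation: summed window counts equal SV-window incidences
  incidences <- sum(vapply(seq_len(nrow(sites)), function(i) {
    sum(sites$start[i] < w$end & sites$end[i] > w$start)
  }, numeric(1)))
  expect_equal(sum(w$sv_count), incidences)
  ## SVs under the length floor are ignored
  tiny <- sites; tiny$end <- tiny$start + 20
  expect_equal(sum(window_scan(tiny, genome)$sv_count), 0)
})

test_that("excluded windows are absent and spans count in every window hit", {
  genome <- data.frame(chrom = "chr1", length = 1e6)
  excl <- data.frame(chrom = "chr1", start = 3e5, end = 4e5)
  sites <- data.frame(chrom = "chr1", start = 150000, end = 250001,
                      svtype = "DEL")   # spans windows 2 and 3
  w <- window_scan(sites, genome, exclude = excl)
  expect_equal(nrow(w), 9)
  expect_false(any(w$start == 3e5))
  expect_equal(sum(w$sv_count), 2)
})

test_that("overlap classification honors the 70% rule, boundaries and types", {
  catalog <- data.frame(chrom = "chr1", start = c(0, 5000),
                        end = c(700, 6000), svtype = c("DEL", "DUP"))
  q <- data.frame(chrom = "chr1",
                  start = c(0, 0, 5000, 0),
                  end = c(700, 1000, 6000, 1000),
                  svtype = c("DEL", "DEL", "DEL", "DEL"))
  res <- overlap_classify(q, catalog, threshold = 0.70)
  expect_true(res$known[1])            # identical interval
  expect_true(res$known[2])            # boundary: min ratio exactly 0.70
  res_q <- overlap_classify(q, catalog, threshold = 0.70, mode = "query")
  expect_true(res_q$known[2])
  expect_false(res$known[3])           # type mismatch at same interval
  nov <- attr(res, "novelty")
  expect_equal(unname(nov["overall"]), mean(!res$known))
})
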