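trio_ped <- function(n) {
  data.frame(family_id = sprintf("F%03d", seq_len(n)),
             child = sprintf("C%03d", seq_len(n)),
             father = sprintf("P%03d", seq_len(n)),
             mother = sprintf("M%03d", seq_len(n)),
             stringsAsFactors = FALSE)
}

## gt rows: sites; columns ordered father, mother, child per family
trio_gt <- function(triples, svtype = "DEL") {
  n_fam <- length(triples[[1]]) / 3
  gt <- do.call(rbind, lapply(triples, function(x) as.integer(x)))
  cols <- as.vector(vapply(seq_len(n_fam), function(k)
    c(sprintf("P%03d", k), sprintf("M%03d", k), sprintf("C%03d", k)),
    character(3)))
  colnames(gt) <- cols
  toy_genotypes(gt, svtype = svtype)
}

test_that("the biallelic consistency check equals allele-pair enumeration", {
  for (p1 in 0:2) for (p2 in 0:2) for (ch in 0:2) {
    expect_equal(
      svjoint:::BIALLELIC_OK[ch + 1L, p1 + 1L, p2 + 1L],
      oracle_mendel_consistent(ch, p1, p2),
      info = sprintf("child %d from %d x %d", ch, p1, p2))
  }
})

test_that("impossible transmissions are counted and denominators are right", {
  ## family 1: HET x REF -> HOM (impossible); family 2: all REF (not
  ## informative); family 3: HET x HET -> HET (fine)
  gtm <- trio_gt(list(c(1, 0, 2,   0, 0, 0,   1, 1, 1)))
  mer <- mendelian_error_rate(gtm, trio_ped(3))
  expect_equal(mer$n_informative, 2)
  expect_equal(mer$n_inconsistent, 1)
  expect_equal(mer$rate, 0.5)
})

test_that("an all-reference cohort reports rate 0 with the undefined flag", {
  gtm <- trio_gt(list(rep(0, 9)))
  mer <- mendelian_error_rate(gtm, trio_ped(3))
  expect_equal(mer$rate, 0)
  expect_true(mer$undefined)
  expect_error(mendelian_error_rate(gtm, trio_ped(0)), "empty pedigree")
})

test_that("duos are evaluated against the single typed parent", {
  ## child HOM with typed parent REF is impossible regardless of the
  ## missing parent; child HET is always possible
  ped <- data.frame(family_id = c("D1", "D2"), child = c("C001", "C002"),
                    father = NA_character_,
                    mother = c("M001", "M002"), stringsAsFactors = FALSE)
  gt <- matrix(c(2L, 0L, 1L, 0L), nrow = 1,
               dimnames = list(NULL, c("C001", "M001", "C002", "M002")))
  gtm <- toy_genotypes(gt)
  mer <- mendelian_error_rate(gtm, ped)
  expect_equal(mer$n_informative, 2)
  expect_equal(mer$n_inconsistent, 1)
})

test_that("multi-allelic duplication copy numbers use CN arithmetic", {
  ## CN 6 child from CN 3 x CN 3 parents: 4 extra copies from 1 + 1 -> bad
  ## CN 4 child from CN 3 x CN 3 parents: 2 extra from 1 + 1 -> fine
  gtm <- trio_gt(list(c(3, 3, 6) - 2L, c(3, 3, 4) - 2L), svtype = "DUP")
  ## toy_genotypes stores dosage; rebuild cn as the real CN values
  gtm$cn <- matrix(c(3L, 3L, 6L, 3L, 3L, 4L), nrow = 2, byrow = TRUE,
                   dimnames = dimnames(gtm$cn))
  mer <- mendelian_error_rate(gtm, trio_ped(1))
  expect_equal(mer$n_inconsistent, 1)
  expect_equal(mer$n_informative, 2)
})

test_that("chrX sons are checked against the mother only", {
  ped <- trio_ped(1)
  sex <- c(P001 = "male", M001 = "female", C001 = "male")
  ## son carrier (gt 1) with REF mother and carrier father: impossible
  gt <- matrix(c(1L, 0L, 1L), nrow = 1,
               dimnames = list(NULL, c("P001", "M001", "C001")))
  gtm <- toy_genotypes(gt, chrom = "chrX", sex = unname(sex[colnames(gt)]))
  mer <- mendelian_error_rate(gtm, ped)
  expect_equal(mer$n_inconsistent, 1)
  ## same genotypes but HET mother: possible
  gt2 <- matrix(c(1L, 1L, 1L), nrow = 1, dimnames = dimnames(gt))
  gtm2 <- toy_genotypes(gt2, chrom = "chrX", sex = unname(sex[colnames(gt)]))
  expect_equal(mendelian_error_rate(gtm2, ped)$n_inconsistent, 0)
})

test_that("estimates are invariant to sample and family order", {
  cfg <- sim_config(n_samples = 90, n_trios = 25, n_del = 15, n_dup = 5,
                    n_inv = 3, seed = 26)
  sim <- simulate_cohort(cfg)
  truth <- inject_genotype_errors(sim$truth, 0.05, seed = 3)
  gtm <- truth_genotype_matrix(truth)
  ped <- sim$truth$pedigree
  a <- mendelian_error_rate(gtm, ped)
  b <- mendelian_error_rate(gtm, ped[rev(seq_len(nrow(ped))), ])
  expect_equal(a, b)
})

test_that("injected uniform errors calibrate against the enumeration oracle", {
  cfg <- sim_config(n_samples = 600, n_trios = 200, n_del = 25, n_dup = 0,
                    n_inv = 0, seed = 27)
  sim <- simulate_cohort(cfg)
  rate <- 0.02
  truth <- inject_genotype_errors(sim$truth, rate, seed = 11)
  gtm <- truth_genotype_matrix(truth)
  mer <- mendelian_error_rate(gtm, sim$truth$pedigree)
  expected <- expected_mendelian_error_rate(sim$truth$af[, 1], rate)
  se <- sqrt(expected * (1 - expected) / mer$n_informative)
  expect_lt(abs(mer$rate - expected), 3 * se)
})

test_that("de novo events are REF x REF parents with a HET child", {
  gtm <- trio_gt(list(c(0, 0, 1,   1, 0, 1,   0, 0, 0)))
  dn <- de_novo_rate(gtm, trio_ped(3))
  expect_equal(dn$n_de_novo, 1)       # family 1 only
  expect_equal(dn$n_child_het, 2)     # families 1 and 2
  expect_equal(dn$rate, 0.5)
})

test_that("allelic balance counts REF x HET transmissions", {
  ## three informative trios; children REF, HET, HET -> 33.3 : 66.7
  gtm <- trio_gt(list(c(0, 1, 0,   1, 0, 1,   0, 1, 1)))
  ab <- allelic_balance(gtm, trio_ped(3))
  expect_equal(ab$n_ref, 1)
  expect_equal(ab$n_het, 2)
  expect_equal(ab$pct_ref, 100 / 3, tolerance = 1e-12)
  expect_equal(ab$pct_ref + ab$pct_het, 100)
  ## no informative family -> flagged undefined
  gtm0 <- trio_gt(list(c(2, 2, 2)))
  expect_true(allelic_balance(gtm0, trio_ped(1))$undefined)
})

test_that("reference-biased errors shift the allelic balance toward REF", {
  cfg <- sim_config(n_samples = 600, n_trios = 200, n_del = 30, n_dup = 0,
                    n_inv = 0, af_shape1 = 2, af_shape2 = 2, seed = 28)
  sim <- simulate_cohort(cfg)
  clean <- allelic_balance(truth_genotype_matrix(sim$truth),
                           sim$truth$pedigree)
  n <- clean$n_ref + clean$n_het
  expect_lt(abs(clean$pct_ref / 100 - 0.5), 3 * sqrt(0.25 / n))
  biased <- inject_genotype_errors(sim$truth, 0.2, seed = 4,
                                   mode = "ref_bias")
  ab <- allelic_balance(truth_genotype_matrix(biased), sim$truth$pedigree)
  expect_gt(ab$pct_ref / 100, 0.5 + 3 * sqrt(0.25 / (ab$n_ref + ab$n_het)))
})

test_that("het/hom ratios follow arithmetic and the HWE closed form", {
  gt <- matrix(c(rep(1L, 10), rep(2L, 5), rep(0L, 5)), ncol = 1)
  colnames(gt) <- "S1"
  expect_equal(het_hom_ratio(toy_genotypes(gt))$ratio, 2)
  gt0 <- matrix(c(1L, 1L, 0L), ncol = 1, dimnames = list(NULL, "S1"))
  r <- het_hom_ratio(toy_genotypes(gt0))
  expect_true(is.infinite(r$ratio))
  expect_true(is.nan(attr(r, "cohort_mean")))

  ## Hardy-Weinberg cohort at fixed AF q: E[het]/E[hom] = 2(1-q)/q
  q <- 0.4
  cfg <- sim_config(n_samples = 400, n_del = 60, n_dup = 0, n_inv = 0,
                    af_fixed = q, seed = 29)
  sim <- simulate_cohort(cfg)
  r <- het_hom_ratio(truth_genotype_matrix(sim$truth))
  expected <- 2 * (1 - q) / q
  ratios <- r$ratio[is.finite(r$ratio)]
  se <- stats::sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(attr(r, "cohort_mean") - expected), 3 * se + 0.05)
})
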