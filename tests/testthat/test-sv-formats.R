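write_test_vcf <- function(records, path = tempfile(fileext = ".vcf")) {
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
               "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
               "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"l\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO"), collapse = "\t"),
               records), path)
  path
}

test_that("VCF coordinates convert to 0-based half-open", {
  p <- write_test_vcf("chr1\t101\tsv1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=200")
  calls <- read_sv_vcf(p)
  expect_equal(calls$start, 100)
  expect_equal(calls$end, 200)
  expect_equal(calls$svlen, 100)
})

test_that("non-DEL/DUP/INV records are skipped and counted", {
  p <- write_test_vcf(c(
    "chr1\t101\tsv1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=200",
    "chr1\t500\tbnd1\tN\tN[chr2:100[\t.\tPASS\tSVTYPE=BND",
    "chr1\t900\tsv2\tN\t<INV>\t.\tPASS\tSVTYPE=INV;SVLEN=300"))
  calls <- suppressMessages(read_sv_vcf(p))
  expect_equal(nrow(calls), 2)
  expect_equal(attr(calls, "n_skipped"), 1L)
  expect_equal(calls$end[2], 899 + 300)
})

test_that("records with neither END nor SVLEN are rejected by name", {
  p <- write_test_vcf("chr1\t101\tbad1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL")
  expect_warning(calls <- read_sv_vcf(p), "bad1")
  expect_equal(nrow(calls), 0)
})

test_that("an empty VCF body yields an empty call set without error", {
  p <- write_test_vcf(character())
  calls <- read_sv_vcf(p)
  expect_equal(nrow(calls), 0)
})

test_that("population VCF round-trips sites, genotypes and filters", {
  gt <- matrix(c(0L, 1L, 2L,
                 0L, 0L, 1L), nrow = 2, byrow = TRUE,
               dimnames = list(NULL, c("A", "B", "C")))
  gtm <- toy_genotypes(gt, svtype = "DEL")
  gtm$sites$filter <- c("PASS", "LowQual")
  p <- tempfile(fileext = ".vcf")
  write_population_vcf(gtm, p)
  back <- read_population_vcf(p)
  expect_equal(back$sites$site_id, gtm$sites$site_id)
  expect_equal(back$sites$start, gtm$sites$start)
  expect_equal(back$sites$end, gtm$sites$end)
  expect_equal(back$sites$filter, c("PASS", "LowQual"))
  expect_equal(unname(back$gt), unname(gtm$gt))
  expect_equal(unname(back$cn), unname(gtm$cn))
  ## site list also readable through the plain SV reader
  sv <- read_sv_vcf(p)
  expect_equal(sv$start, gtm$sites$start)
})

test_that("chrX male genotypes are written and read hemizygously", {
  gt <- matrix(c(0L, 1L, 1L), nrow = 1,
               dimnames = list(NULL, c("M1", "M2", "F1")))
  sex <- c("male", "male", "female")
  gtm <- toy_genotypes(gt, svtype = "DEL", chrom = "chrX", sex = sex)
  p <- tempfile(fileext = ".vcf")
  write_population_vcf(gtm, p)
  raw <- readLines(p)
  body <- strsplit(raw[length(raw)], "\t")[[1]]
  expect_match(body[10], "^0:")     # male REF: single allele
  expect_match(body[11], "^1:")     # male carrier
  expect_match(body[12], "^0/1:")   # female heterozygote
  back <- read_population_vcf(p, sex = sex)
  expect_equal(unname(back$gt), unname(gt))
  expect_equal(back$sites$AN, 4L)   # 2 males x 1 + 1 female x 2
})

test_that("PED files parse trios, duos and reject self-parentage", {
  p <- tempfile()
  writeLines(c("F1\tC1\tP1\tP2\t1\t-9",
               "F1\tP1\t0\t0\t1\t-9",
               "F1\tP2\t0\t0\t2\t-9",
               "D1\tC2\t0\tP3\t2\t-9",
               "D1\tP3\t0\t0\t2\t-9"), p)
  ped <- read_ped(p)
  expect_equal(nrow(ped), 2)
  expect_true(is.na(ped$father[ped$child == "C2"]))
  expect_equal(ped$mother[ped$child == "C2"], "P3")
  writeLines("F1\tA\tA\t0\t1\t-9", p)
  expect_error(read_ped(p), "own parent")
})

test_that("PED writing round-trips a simulated pedigree", {
  cfg <- sim_config(n_samples = 30, n_trios = 5, n_duos = 2, n_del = 2,
                    seed = 8)
  sim <- simulate_cohort(cfg)
  p <- tempfile()
  write_ped(sim$truth, p)
  ped <- read_ped(p)
  expect_setequal(ped$child, sim$truth$pedigree$child)
  s <- attr(ped, "samples")
  expect_equal(s$sex[match(sim$truth$samples$sample, s$sample)],
               sim$truth$samples$sex)
})

test_that("BED intervals are half-open and malformed lines are located", {
  p <- tempfile()
  writeLines("chr1\t0\t100000", p)
  bed <- read_bed(p)
  expect_equal(bed$end - bed$start, 100000)
  writeLines(c("chr1\t0\t100", "chr1\t50\tx"), p)
  expect_error(read_bed(p), "line 2")
})

test_that("evidence TSV round-trips and rejects negative depths", {
  cfg <- sim_config(n_samples = 10, n_del = 3, seed = 4)
  sim <- simulate_cohort(cfg)
  p <- tempfile()
  write_evidence(sim$evidence, p)
  back <- read_evidence(p)
  expect_equal(nrow(back), nrow(sim$evidence))
  expect_equal(back$n_disc, sim$evidence$n_disc)
  bad <- sim$evidence
  bad$depth_raw[5] <- -1
  write_evidence(bad, p)
  expect_error(read_evidence(p), "line 6")
})
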