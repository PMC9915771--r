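## Readers and writers for the formats shared by all pipeline stages.
## Internal coordinates are 0-based half-open everywhere; the 1-based
## inclusive VCF convention is converted exactly at the I/O boundary.

SV_TYPES <- c("DEL", "DUP", "INV")

## vcfR returns a bare named vector for single-record files
vcf_fix_df <- function(v) {
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)
  as.data.frame(fix, stringsAsFactors = FALSE)
}

#' Read structural-variant records from a VCF
#'
#' Parses a (single- or multi-sample) VCF with `SVTYPE` and `END`/`SVLEN`
#' INFO fields into the internal call table. Types other than DEL, DUP and
#' INV (e.g. translocation `BND` records) are skipped and counted; records
#' missing both `END` and `SVLEN` are dropped with a warning naming the
#' site. VCF `POS` (1-based, base before the event) becomes 0-based
#' `start`; `END` is taken as the half-open end.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @return Data frame with columns `sample`, `chrom`, `start`, `end`,
#'   `svtype`, `svlen`. The number of type-skipped records is attached as
#'   `attr(, "n_skipped")`.
#' @export
read_sv_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf_fix_df(v)
  n_in <- nrow(fix)
  sample_name <- if (ncol(v@gt) >= 2L) colnames(v@gt)[2L] else NA_character_
  if (n_in == 0L) {
    out <- data.frame(sample = character(), chrom = character(),
                      start = integer(), end = integer(),
                      svtype = character(), svlen = integer())
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  svtype <- vcfR::extract.info(v, "SVTYPE")
  end_i <- suppressWarnings(as.integer(vcfR::extract.info(v, "END")))
  svlen <- suppressWarnings(as.integer(vcfR::extract.info(v, "SVLEN")))
  keep_type <- !is.na(svtype) & svtype %in% SV_TYPES
  n_skipped <- sum(!keep_type)
  if (n_skipped > 0) {
    log_msg("read_sv_vcf: skipped %d record(s) with SVTYPE outside %s",
            n_skipped, paste(SV_TYPES, collapse = "/"))
  }
  start <- as.integer(fix$POS) - 1L
  no_span <- keep_type & is.na(end_i) & is.na(svlen)
  for (i in which(no_span)) {
    warning(sprintf("record %s:%s (%s) has neither END nor SVLEN; rejected",
                    fix$CHROM[i], fix$POS[i],
                    ifelse(is.na(fix$ID[i]), ".", fix$ID[i])), call. = FALSE)
  }
  end <- ifelse(!is.na(end_i), end_i, start + abs(svlen))
  keep <- keep_type & !no_span
  out <- data.frame(
    sample = rep(sample_name, sum(keep)),
    chrom = fix$CHROM[keep], start = start[keep],
    end = end[keep], svtype = svtype[keep],
    svlen = end[keep] - start[keep], stringsAsFactors = FALSE
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

vcf_header_lines <- function(samples = character()) {
  c("##fileformat=VCFv4.2",
    "##source=svjoint",
    sprintf("##ALT=<ID=%s,Description=\"%s\">",
            SV_TYPES, c("Deletion", "Duplication", "Inversion")),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position (1-based inclusive)\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency\">",
    "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Allele count\">",
    "##INFO=<ID=MODE,Number=1,Type=String,Description=\"Genotyping mode (GT2D/GTDP/GTSUP)\">",
    "##INFO=<ID=PRE,Number=2,Type=Float,Description=\"Cohort mean,SD of normalized depth before the event\">",
    "##INFO=<ID=POST,Number=2,Type=Float,Description=\"Cohort mean,SD of normalized depth after the event\">",
    "##FILTER=<ID=PreFiltered,Description=\"Duplication failing depth-conformance or concordant-overlap prefilter\">",
    "##FILTER=<ID=LowQual,Description=\"Flagged by quality evaluation or SVM filter\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=CN,Number=1,Type=Integer,Description=\"Integer copy number\">",
    "##FORMAT=<ID=PQ,Number=1,Type=Float,Description=\"Posterior probability of assigned class\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples)) c("FORMAT", samples)), collapse = "\t"))
}

gt_string <- function(dosage, hemi) {
  out <- rep("./.", length(dosage))
  dip <- c("0/0", "0/1", "1/1")
  ok <- !is.na(dosage)
  out[ok & !hemi] <- dip[dosage[ok & !hemi] + 1L]
  out[ok & hemi] <- as.character(dosage[ok & hemi])
  out
}

#' Write a genotyped population VCF
#'
#' Emits a multi-sample VCF 4.2 with `SVTYPE`/`END`/`SVLEN`/`AF`/`AC` (and,
#' when present in the site table, genotyping `MODE` and `PRE`/`POST` flank
#' summaries) in INFO, per-sample `GT:CN:PQ` genotypes, and the FILTER
#' column carrying `PASS`/`PreFiltered`/`LowQual`. Male chromosome-X
#' genotypes are written hemizygously (`0`/`1`).
#'
#' @param gtm An `sv_genotypes` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_population_vcf <- function(gtm, path) {
  stopifnot(inherits(gtm, "sv_genotypes"))
  s <- gtm$sites
  male <- if (is.null(gtm$sex)) rep(FALSE, length(gtm$samples)) else gtm$sex == "male"
  info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d;AF=%s;AC=%d;MODE=%s",
                  s$svtype, s$end, s$end - s$start,
                  formatC(s$AF, format = "g", digits = 6), s$AC, s$mode)
  if (!is.null(s$pre_mean)) {
    info <- sprintf("%s;PRE=%.4f,%.4f;POST=%.4f,%.4f", info,
                    s$pre_mean, s$pre_sd, s$post_mean, s$post_sd)
  }
  gt_cols <- vapply(seq_len(nrow(s)), function(i) {
    hemi <- male & s$chrom[i] == "chrX"
    paste(sprintf("%s:%s:%s",
                  gt_string(gtm$gt[i, ], hemi),
                  ifelse(is.na(gtm$cn[i, ]), ".", gtm$cn[i, ]),
                  ifelse(is.na(gtm$qual[i, ]), ".",
                         formatC(gtm$qual[i, ], format = "f", digits = 4))),
          collapse = "\t")
  }, character(1))
  body <- paste(s$chrom, s$start + 1L, s$site_id, "N",
                sprintf("<%s>", s$svtype), ".", s$filter, info,
                "GT:CN:PQ", gt_cols, sep = "\t")
  writeLines(c(vcf_header_lines(gtm$samples), body), path)
  invisible(path)
}

#' Read a genotyped population VCF back into an `sv_genotypes` object
#'
#' Inverse of [write_population_vcf()] (up to numeric formatting of the
#' quality field).
#'
#' @param path Path to a population VCF written by this package.
#' @param sex Optional per-sample sex labels (needed to interpret chrX
#'   hemizygous genotypes' allele numbers).
#' @return An `sv_genotypes` object.
#' @export
read_population_vcf <- function(path, sex = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf_fix_df(v)
  samples <- colnames(v@gt)[-1L]
  sites <- data.frame(
    site_id = fix$ID, chrom = fix$CHROM,
    start = as.integer(fix$POS) - 1L,
    end = as.integer(vcfR::extract.info(v, "END")),
    svtype = vcfR::extract.info(v, "SVTYPE"),
    filter = fix$FILTER, stringsAsFactors = FALSE
  )
  gt_raw <- vcfR::extract.gt(v, "GT")
  cn <- suppressWarnings(apply(vcfR::extract.gt(v, "CN"), 2, as.integer))
  pq <- suppressWarnings(apply(vcfR::extract.gt(v, "PQ"), 2, as.numeric))
  dos <- matrix(NA_integer_, nrow(sites), length(samples))
  dos[gt_raw %in% c("0/0", "0")] <- 0L
  dos[gt_raw %in% c("0/1", "1")] <- 1L
  dos[gt_raw == "1/1"] <- 2L
  mode <- vcfR::extract.info(v, "MODE")
  if (!is.matrix(cn)) cn <- matrix(cn, nrow = nrow(sites))
  if (!is.matrix(pq)) pq <- matrix(pq, nrow = nrow(sites))
  new_sv_genotypes(sites, samples, gt = dos, cn = cn, qual = pq,
                   mode = mode %||% "GT2D", sex = sex)
}

#' Write one SV VCF per sample
#'
#' Emits the per-sample call lists of a simulated cohort as single-sample
#' VCFs (the input format of the merge stage).
#'
#' @param calls Call table (`sample`, `chrom`, `start`, `end`, `svtype`).
#' @param dir Output directory (created if missing).
#' @return Character vector of the files written, invisibly.
#' @export
write_sample_vcfs <- function(calls, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(split(calls, calls$sample), function(cc) {
    p <- file.path(dir, paste0(cc$sample[1], ".vcf"))
    body <- paste(cc$chrom, cc$start + 1L,
                  sprintf("%s_%d", cc$sample[1], seq_len(nrow(cc))),
                  "N", sprintf("<%s>", cc$svtype), ".", "PASS",
                  sprintf("SVTYPE=%s;END=%d;SVLEN=%d",
                          cc$svtype, cc$end, cc$end - cc$start),
                  "GT", "0/1", sep = "\t")
    writeLines(c(vcf_header_lines(cc$sample[1]), body), p)
    p
  }, character(1))
  invisible(paths)
}

#' Read a 6-column PED pedigree file
#'
#' @param path Path to a whitespace-delimited PED file
#'   (family, individual, father, mother, sex, phenotype); `0` denotes a
#'   missing parent.
#' @return Data frame of child records (`family_id`, `child`, `father`,
#'   `mother`; `NA` for missing parents) with a per-sample sex table in
#'   `attr(, "samples")`.
#' @export
read_ped <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(fields) < 6L)
  if (length(bad)) stopf("malformed PED line %d: expected 6 fields", bad[1])
  m <- do.call(rbind, fields)
  samples <- data.frame(
    sample = m[, 2],
    sex = c("male", "female", NA)[match(m[, 5], c("1", "2"))],
    stringsAsFactors = FALSE
  )
  if (any(m[, 2] == m[, 3] | m[, 2] == m[, 4])) {
    stopf("PED line %d: sample is its own parent",
          which(m[, 2] == m[, 3] | m[, 2] == m[, 4])[1])
  }
  is_child <- m[, 3] != "0" | m[, 4] != "0"
  fam <- data.frame(
    family_id = m[is_child, 1],
    child = m[is_child, 2],
    father = ifelse(m[is_child, 3] == "0", NA_character_, m[is_child, 3]),
    mother = ifelse(m[is_child, 4] == "0", NA_character_, m[is_child, 4]),
    stringsAsFactors = FALSE
  )
  known <- m[, 2]
  unresolved <- setdiff(stats::na.omit(c(fam$father, fam$mother)), known)
  if (length(unresolved)) {
    stopf("PED parent id(s) not present as samples: %s",
          paste(unresolved, collapse = ", "))
  }
  attr(fam, "samples") <- samples
  fam
}

#' Write a PED file for a simulated cohort
#' @param truth A `sv_cohort_truth` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(truth, path) {
  s <- truth$samples
  ped <- truth$pedigree
  father <- stats::setNames(ped$father, ped$child)
  mother <- stats::setNames(ped$mother, ped$child)
  fa <- father[s$sample]; mo <- mother[s$sample]
  lines <- paste(
    ifelse(is.na(s$family_id), s$sample, s$family_id), s$sample,
    ifelse(is.na(fa), "0", fa), ifelse(is.na(mo), "0", mo),
    ifelse(s$sex == "male", 1L, 2L), -9L, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED3 file into a region table
#' @param path Path to a tab-delimited BED file (0-based half-open).
#' @return Data frame `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t")
  out <- data.frame(chrom = character(length(fields)),
                    start = integer(length(fields)),
                    end = integer(length(fields)))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3L) stopf("malformed BED line %d: fewer than 3 fields", i)
    st <- suppressWarnings(as.integer(f[2])); en <- suppressWarnings(as.integer(f[3]))
    if (is.na(st) || is.na(en) || en <= st || st < 0) {
      stopf("malformed BED line %d: invalid interval [%s, %s)", i, f[2], f[3])
    }
    out$chrom[i] <- f[1]; out$start[i] <- st; out$end[i] <- en
  }
  out
}

#' Write / read the evidence table
#'
#' The evidence TSV is the pileup-summary contract between the simulator
#' (or an external pileup tool) and the joint genotyper: one row per
#' (site, sample) with discordant-pair/split-read/soft-clip counts, raw
#' event depth, flanking depth statistics and the site GC fraction.
#'
#' @param evidence Evidence data frame.
#' @param path File path.
#' @return `read_evidence`: the validated evidence data frame.
#' @export
write_evidence <- function(evidence, path) {
  cols <- evidence_columns()
  utils::write.table(evidence[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

evidence_columns <- function() {
  c("site_id", "sample_id", "n_disc", "n_split", "n_clip", "depth_raw",
    "depth_pre_mean", "depth_pre_sd", "depth_post_mean", "depth_post_sd",
    "gc_frac")
}

#' @rdname write_evidence
#' @export
read_evidence <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(evidence_columns(), names(ev))
  if (length(missing_cols)) {
    stopf("evidence file lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  counts <- c("n_disc", "n_split", "n_clip")
  depths <- c("depth_raw", "depth_pre_mean", "depth_pre_sd",
              "depth_post_mean", "depth_post_sd")
  for (col in c(counts, depths)) {
    bad <- which(!is.finite(ev[[col]]) | ev[[col]] < 0)
    if (length(bad)) {
      stopf("evidence line %d: negative or non-finite %s", bad[1] + 1L, col)
    }
  }
  bad_gc <- which(ev$gc_frac < 0 | ev$gc_frac > 1)
  if (length(bad_gc)) stopf("evidence line %d: gc_frac outside [0, 1]",
                            bad_gc[1] + 1L)
  ev
}

#' Read a genome table (chromosome lengths)
#' @param path Tab-delimited file with columns chromosome and length.
#' @return Data frame `chrom`, `length`.
#' @export
read_genome_table <- function(path) {
  g <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)[, 1:2]
  names(g) <- c("chrom", "length")
  g$length <- as.numeric(g$length)
  if (any(is.na(g$length) | g$length <= 0)) stopf("invalid chromosome length")
  g
}
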