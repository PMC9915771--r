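## Independent oracles and small fixture builders used across the suite.
## Each oracle is written as directly as possible (exhaustive pairs,
## explicit allele enumeration, textbook formulas) and never shares code
## with the implementation it checks.

## Exhaustive O(n^2) single-linkage clustering of SV calls: build the full
## adjacency matrix, then take connected components by BFS.
oracle_single_linkage <- function(calls, wobble = 1000, type_match = TRUE) {
  n <- nrow(calls)
  if (n == 0L) return(list())
  adj <- outer(calls$chrom, calls$chrom, "==") &
    abs(outer(calls$start, calls$start, "-")) <= wobble &
    abs(outer(calls$end, calls$end, "-")) <= wobble
  if (type_match) adj <- adj & outer(calls$svtype, calls$svtype, "==")
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

## Canonical signature of a partition of calls: a sorted list of sorted
## member-key sets, independent of cluster labels and call order.
partition_signature <- function(calls, comp) {
  keys <- paste(calls$chrom, calls$svtype, calls$start, calls$end,
                calls$sample, sep = "|")
  sets <- unname(lapply(split(keys, comp), function(k) sort(unname(k))))
  sets[order(vapply(sets, `[`, character(1), 1))]
}

## Signature of a merge_calls() result via its membership table.
merge_signature <- function(merged) {
  mem <- attr(merged, "membership")
  partition_signature(mem, mem$site_id)
}

random_call_set <- function(n, chroms = c("chr1", "chr2"),
                            types = c("DEL", "DUP", "INV"),
                            span = 50000) {
  start <- sort(sample.int(span, n, replace = TRUE))
  len <- sample(100:5000, n, replace = TRUE)
  data.frame(
    sample = sprintf("S%03d", sample.int(20, n, replace = TRUE)),
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + len,
    svtype = sample(types, n, replace = TRUE),
    svlen = len, stringsAsFactors = FALSE
  )
}

## Hudson FST, written straight from the estimator definition.
oracle_hudson_fst <- function(p1, n1, p2, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  num / den
}

## Mendelian consistency by explicit allele-pair enumeration (independent
## of the package's transmission-set formulation): parents' genotypes are
## expanded into allele pairs and every child allele combination tried.
oracle_mendel_consistent <- function(child, p1, p2) {
  alleles <- function(g) switch(g + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L))
  ap1 <- alleles(p1); ap2 <- alleles(p2)
  for (a in ap1) for (b in ap2) if (a + b == child) return(TRUE)
  FALSE
}

## A tiny hand-built genotype object: biallelic sites from a dosage matrix.
toy_genotypes <- function(gt, svtype = "DEL", chrom = "chr1", sex = NULL,
                          filter = "PASS") {
  n_sites <- nrow(gt); n_samp <- ncol(gt)
  samples <- colnames(gt) %||% sprintf("S%03d", seq_len(n_samp))
  sites <- data.frame(
    site_id = sprintf("T%03d", seq_len(n_sites)),
    chrom = rep_len(chrom, n_sites),
    start = seq_len(n_sites) * 10000L,
    end = seq_len(n_sites) * 10000L + 1000L,
    svtype = rep_len(svtype, n_sites), stringsAsFactors = FALSE
  )
  cn <- gt
  del <- sites$svtype == "DEL"
  cn[del, ] <- 2L - gt[del, , drop = FALSE]
  dup <- sites$svtype == "DUP"
  cn[dup, ] <- 2L + gt[dup, , drop = FALSE]
  cn[sites$svtype == "INV", ] <- 2L
  if (!is.null(sex)) {
    male <- sex == "male"
    is_x <- sites$chrom == "chrX"
    cn[is_x, male] <- pmax(cn[is_x, male, drop = FALSE] - 1L, 0L)
  }
  g <- new_sv_genotypes(sites, samples, gt = gt, cn = cn,
                        qual = matrix(1, n_sites, n_samp),
                        mode = "TRUTH", sex = sex)
  g$sites$filter <- rep_len(filter, n_sites)
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Synthetic single-site evidence with the genotyper's expected structure.
toy_site_evidence <- function(ndepth, support, site_id = "T001",
                              gc = 0.45) {
  n <- length(ndepth)
  data.frame(
    site_id = site_id, sample_id = sprintf("S%03d", seq_len(n)),
    n_disc = floor(support * 0.5), n_split = floor(support * 0.3),
    n_clip = support - floor(support * 0.5) - floor(support * 0.3),
    depth_raw = ndepth * 30, depth_pre_mean = 30, depth_pre_sd = 1.5,
    depth_post_mean = 30, depth_post_sd = 1.5, gc_frac = gc,
    ndepth = ndepth, pre_mean_n = 1, pre_sd_n = 0.05,
    post_mean_n = 1, post_sd_n = 0.05, stringsAsFactors = FALSE
  )
}
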