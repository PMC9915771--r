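#' Merge per-sample SV calls into population candidate sites
#'
#' Collapses calls by breakpoint-proximity clustering: two calls are linked
#' when they lie on the same chromosome, have the same SV type (unless
#' `type_match = FALSE`), and both breakpoints agree within the wobble
#' distance (`|start_a - start_b| <= wobble` and `|end_a - end_b| <=
#' wobble`). Candidate sites are the connected components of this relation
#' (single linkage), with consensus breakpoints at the member medians
#' (lower median for even member counts). The result is independent of the
#' input order.
#'
#' @param calls Call table with columns `sample`, `chrom`, `start`, `end`,
#'   `svtype` (0-based half-open).
#' @param wobble Maximum breakpoint displacement (bp) for linking two
#'   calls; default 1 kbp.
#' @param type_match Require identical SV type for linking (default TRUE).
#' @return Data frame of candidate sites (`site_id`, `chrom`, `start`,
#'   `end`, `svtype`, `n_members`, `n_supporting_samples`), sorted by
#'   position, with the member call table attached as
#'   `attr(, "membership")` (column `site_id` joins the two).
#' @export
merge_calls <- function(calls, wobble = 1000, type_match = TRUE) {
  if (wobble < 0) stopf("wobble must be non-negative, got %g", wobble)
  if (nrow(calls) == 0L) {
    out <- data.frame(site_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      svtype = character(), n_members = integer(),
                      n_supporting_samples = integer())
    attr(out, "membership") <- cbind(calls, site_id = character(0))
    return(out)
  }
  ## canonical order makes the clustering permutation-invariant
  calls <- calls[order(calls$chrom, calls$svtype, calls$start, calls$end,
                       calls$sample), , drop = FALSE]
  rownames(calls) <- NULL
  key <- if (type_match) paste(calls$chrom, calls$svtype) else calls$chrom
  comp <- integer(nrow(calls))
  n_comp <- 0L
  for (idx in split(seq_len(nrow(calls)), key)) {
    labels <- uf_cluster(calls$start[idx], calls$end[idx], wobble)
    comp[idx] <- labels + n_comp
    n_comp <- n_comp + max(labels)
  }
  groups <- split(seq_len(nrow(calls)), comp)
  sites <- do.call(rbind, lapply(groups, function(g) {
    data.frame(chrom = calls$chrom[g[1]],
               start = lower_median(calls$start[g]),
               end = lower_median(calls$end[g]),
               svtype = calls$svtype[g[1]],
               n_members = length(g),
               n_supporting_samples = length(unique(calls$sample[g])),
               stringsAsFactors = FALSE)
  }))
  ord <- order(sites$chrom, sites$start, sites$end, sites$svtype)
  sites <- sites[ord, , drop = FALSE]
  sites$site_id <- sprintf("CAND%06d", seq_len(nrow(sites)))
  rownames(sites) <- NULL
  site_of_call <- sites$site_id[match(comp, as.integer(names(groups))[ord])]
  membership <- cbind(calls, site_id = site_of_call)
  out <- sites[, c("site_id", "chrom", "start", "end", "svtype",
                   "n_members", "n_supporting_samples")]
  attr(out, "membership") <- membership
  out
}

## Single-linkage connected components over calls already restricted to one
## (chromosome, type) group; calls arrive sorted by start, so only pairs
## within the wobble window on start need end comparison. Union-find with
## path compression.
uf_cluster <- function(start, end, wobble) {
  n <- length(start)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n)) {
    j <- i + 1L
    while (j <= n && start[j] - start[i] <= wobble) {
      if (abs(end[j] - end[i]) <= wobble) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
      j <- j + 1L
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Match a call set against a truth set
#'
#' Benchmarks candidate sites against a truth list with the comparison
#' rules of assembly-based SV benchmarking: a call matches a truth entry
#' when the types agree, both breakpoints are within `refdist`, and the
#' length ratio `min/max` is at least `pctsize`. A truth entry may satisfy
#' any number of calls (multi-match). Calls (and truth entries, for
#' recall) shorter than `sizemin` are excluded from scoring.
#'
#' @param calls,truth Site tables (`chrom`, `start`, `end`, `svtype`).
#' @param refdist Maximum breakpoint distance (bp), default 500.
#' @param pctsize Minimum size ratio, default 0.5.
#' @param sizemin Minimum SV length scored, default 10.
#' @return List: `calls` (input plus `scored`, `matched`, `truth_idx`),
#'   `ppv` (matched / scored calls), `recall` (`NA` with
#'   `recall_undefined = TRUE` when the truth set is empty), and counts.
#' @export
match_to_truth <- function(calls, truth, refdist = 500, pctsize = 0.5,
                           sizemin = 10) {
  len_c <- calls$end - calls$start
  len_t <- truth$end - truth$start
  scored <- len_c >= sizemin
  matched <- rep(FALSE, nrow(calls))
  truth_idx <- rep(NA_integer_, nrow(calls))
  truth_hit <- rep(FALSE, nrow(truth))
  for (i in which(scored)) {
    cand <- which(truth$svtype == calls$svtype[i] &
                    truth$chrom == calls$chrom[i])
    if (!length(cand)) next
    d <- pmax(abs(truth$start[cand] - calls$start[i]),
              abs(truth$end[cand] - calls$end[i]))
    ratio <- pmin(len_c[i], len_t[cand]) / pmax(len_c[i], len_t[cand])
    ok <- d <= refdist & ratio >= pctsize
    if (any(ok)) {
      matched[i] <- TRUE
      best <- cand[ok][which.min(d[ok])]
      truth_idx[i] <- best
      truth_hit[cand[ok]] <- TRUE
    }
  }
  n_scored <- sum(scored)
  truth_scored <- len_t >= sizemin
  calls$scored <- scored
  calls$matched <- matched
  calls$truth_idx <- truth_idx
  list(
    calls = calls,
    ppv = if (n_scored > 0) sum(matched) / n_scored else NA_real_,
    recall = if (sum(truth_scored) > 0)
      sum(truth_hit & truth_scored) / sum(truth_scored) else NA_real_,
    recall_undefined = sum(truth_scored) == 0L,
    n_scored = n_scored,
    n_truth_scored = sum(truth_scored)
  )
}
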