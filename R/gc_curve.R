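#' Fit a per-sample GC depth-bias curve
#'
#' Estimates the expected raw depth as a function of GC fraction from
#' genome-wide 100-bp interval depths: intervals are binned by GC fraction
#' (bin width 0.025 by default, 40 bins over `[0, 1]`) and each occupied
#' bin's expected depth is the 10% trimmed mean of its interval depths.
#' Bins with fewer than `min_per_bin` intervals borrow strength from their
#' neighbors by linear interpolation (constant extrapolation at the ends).
#' Dividing raw depths by this curve removes the GC bias and puts diploid
#' depth at 1.0.
#'
#' @param depth Numeric vector of interval depths for one sample.
#' @param gc GC fraction of each interval, in `[0, 1]`.
#' @param bin_width GC bin width, default 0.025.
#' @param trim Trim fraction for the per-bin trimmed mean, default 0.1.
#' @param min_per_bin Minimum intervals for a bin to be estimated directly,
#'   default 50.
#' @return Object of class `gc_curve`: per-bin expected depths (defined on
#'   every bin), bin midpoints, per-bin counts and the sample mean diploid
#'   depth.
#' @export
fit_gc_curve <- function(depth, gc, bin_width = 0.025, trim = 0.1,
                         min_per_bin = 50) {
  stopifnot(length(depth) == length(gc))
  if (all(depth == 0)) stopf("all interval depths are zero")
  n_bins <- ceiling(1 / bin_width)
  bin <- pmin(pmax(floor(gc / bin_width) + 1L, 1L), n_bins)
  mids <- (seq_len(n_bins) - 0.5) * bin_width
  counts <- tabulate(bin, n_bins)
  est <- rep(NA_real_, n_bins)
  for (b in which(counts >= min_per_bin)) {
    est[b] <- mean(depth[bin == b], trim = trim)
  }
  if (!any(!is.na(est))) stopf("no GC bin has >= %d intervals", min_per_bin)
  occupied <- which(!is.na(est))
  filled <- stats::approx(mids[occupied], est[occupied], xout = mids,
                          rule = 2)$y
  structure(list(bin_width = bin_width, mids = mids, expected = filled,
                 n_per_bin = counts,
                 sample_mean = mean(depth, trim = trim)),
            class = "gc_curve")
}

#' @export
print.gc_curve <- function(x, ...) {
  cat(sprintf("<gc_curve> %d bins (width %g), sample mean depth %.2f\n",
              length(x$expected), x$bin_width, x$sample_mean))
  invisible(x)
}

gc_curve_value <- function(curve, gc_frac) {
  n_bins <- length(curve$expected)
  bin <- pmin(pmax(floor(gc_frac / curve$bin_width) + 1L, 1L), n_bins)
  curve$expected[bin]
}

#' GC-correct a raw depth to the normalized (diploid = 1) scale
#'
#' @param depth_raw Raw mean depth over an event.
#' @param gc_frac GC fraction of the event region.
#' @param curve A [fit_gc_curve()] result for the sample.
#' @return Normalized depth with expectation 1.0 at copy number 2, 0.5 at
#'   CN 1, 1.5 at CN 3.
#' @export
normalize_depth <- function(depth_raw, gc_frac, curve) {
  expected <- gc_curve_value(curve, gc_frac)
  if (any(expected <= 0)) stopf("GC curve value is zero at gc=%g",
                                gc_frac[which(expected <= 0)[1]])
  depth_raw / expected
}

#' Fit GC curves for every sample of a simulated cohort
#' @param interval_depths The `interval_depths` element of a
#'   [simulate_cohort()] result (`gc` vector plus interval x sample depth
#'   matrix).
#' @param ... Passed to [fit_gc_curve()].
#' @return Named list of `gc_curve` objects, one per sample.
#' @export
fit_gc_curves <- function(interval_depths, ...) {
  samples <- colnames(interval_depths$depth)
  stats::setNames(lapply(samples, function(s) {
    fit_gc_curve(interval_depths$depth[, s], interval_depths$gc, ...)
  }), samples)
}

#' Add GC-normalized depth columns to an evidence table
#'
#' Computes `ndepth` (event depth / per-sample GC curve value) and
#' normalized flank statistics (`pre_mean_n`, `pre_sd_n`, `post_mean_n`,
#' `post_sd_n`, scaled by the sample mean diploid depth) for every
#' evidence row.
#'
#' @param evidence Evidence table (see [read_evidence()]).
#' @param curves Named list of `gc_curve` objects covering every sample.
#' @return The evidence table with normalized columns appended.
#' @export
normalize_evidence <- function(evidence, curves) {
  missing_s <- setdiff(unique(evidence$sample_id), names(curves))
  if (length(missing_s)) {
    stopf("no GC curve for sample(s): %s",
          paste(utils::head(missing_s, 3), collapse = ", "))
  }
  expected <- numeric(nrow(evidence))
  smean <- numeric(nrow(evidence))
  for (s in unique(evidence$sample_id)) {
    rows <- evidence$sample_id == s
    expected[rows] <- gc_curve_value(curves[[s]], evidence$gc_frac[rows])
    smean[rows] <- curves[[s]]$sample_mean
  }
  evidence$ndepth <- evidence$depth_raw / expected
  evidence$pre_mean_n <- evidence$depth_pre_mean / smean
  evidence$pre_sd_n <- evidence$depth_pre_sd / smean
  evidence$post_mean_n <- evidence$depth_post_mean / smean
  evidence$post_sd_n <- evidence$depth_post_sd / smean
  evidence
}
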