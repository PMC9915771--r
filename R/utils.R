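## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Lower median: for even n, take the lower of the two central order
## statistics, so consensus breakpoints are always observed coordinates.
lower_median <- function(x) {
  x <- sort(x)
  x[(length(x) + 1L) %/% 2L]
}

## Overlap length of [s1, e1) and [s2, e2); 0 when disjoint.
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

## Does any interval in (s, e) [vectors] overlap any row of `regions`
## (data.frame chrom/start/end) on the given chromosome?
overlaps_region_set <- function(chrom, start, end, regions) {
  if (is.null(regions) || nrow(regions) == 0L) {
    return(rep(FALSE, length(start)))
  }
  vapply(seq_along(start), function(i) {
    r <- regions[regions$chrom == chrom[i], , drop = FALSE]
    if (nrow(r) == 0L) return(FALSE)
    any(interval_overlap(start[i], end[i], r$start, r$end) > 0)
  }, logical(1))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

log_msg <- function(...) message("[svjoint] ", sprintf(...))
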