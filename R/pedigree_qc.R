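## Genotype-quality evaluation from family structure: Mendelian error
## rate, de novo (novel HET) rate, allelic balance of REF x HET
## transmissions, and per-sample het/hom ratios.

## 3x3x3 lookup: is child dosage c consistent with parent dosages p1, p2
## under biallelic transmission? Transmitted-allele sets: REF -> {0},
## HET -> {0, 1}, HOM -> {1}.
transmit_set <- list(`0` = 0L, `1` = 0:1, `2` = 1L)

biallelic_consistency_table <- function() {
  arr <- array(FALSE, c(3, 3, 3))
  for (p1 in 0:2) for (p2 in 0:2) for (ch in 0:2) {
    ok <- any(outer(transmit_set[[p1 + 1L]], transmit_set[[p2 + 1L]],
                    "+") == ch)
    arr[ch + 1L, p1 + 1L, p2 + 1L] <- ok
  }
  arr
}
BIALLELIC_OK <- biallelic_consistency_table()

## Duo (one typed parent): consistent iff some transmitted allele of the
## typed parent plus a free allele {0, 1} gives the child dosage.
duo_consistent <- function(child, parent) {
  vapply(seq_along(child), function(i) {
    any(outer(transmit_set[[parent[i] + 1L]], 0:1, "+") == child[i])
  }, logical(1))
}

#' Mendelian error rate from trio and duo genotypes
#'
#' The denominator counts (site, family) pairs where every family member
#' is genotyped and at least one member carries a non-reference genotype;
#' the numerator counts those where the child genotype is impossible
#' under transmission from the parents. Biallelic sites (DEL, INV, and
#' duplications treated on allele dosage where CN <= 4 is unambiguous)
#' use the exhaustive 3x3x3 transmission table; multi-allelic
#' duplications use copy-number arithmetic (child CN `c` is consistent
#' iff `0 <= c - 2 <= (p1 - 2) + (p2 - 2)`). On chromosome X, sons are
#' checked against the mother only and daughters receive the father's
#' hemizygous allele. Duos are checked against the single typed parent.
#'
#' @param gtm An `sv_genotypes` object.
#' @param pedigree Pedigree table (`child`, `father`, `mother`; `NA` for a
#'   missing parent), e.g. from [read_ped()].
#' @return Data frame per SV type: `n_inconsistent`, `n_informative`
#'   (denominator), `rate` (0 with `undefined = TRUE` when the
#'   denominator is empty).
#' @export
mendelian_error_rate <- function(gtm, pedigree) {
  if (nrow(pedigree) == 0L) stopf("empty pedigree")
  per_family <- family_consistency(gtm, pedigree)
  agg <- function(sv) {
    rows <- per_family$svtype == sv
    n_inf <- sum(per_family$informative[rows])
    n_bad <- sum(per_family$inconsistent[rows])
    data.frame(svtype = sv, n_inconsistent = n_bad, n_informative = n_inf,
               rate = if (n_inf > 0) n_bad / n_inf else 0,
               undefined = n_inf == 0L)
  }
  do.call(rbind, lapply(sort(unique(gtm$sites$svtype)), agg))
}

## One row per (site, family): was the triple informative (all called,
## >= 1 non-REF) and was it inconsistent?
family_consistency <- function(gtm, pedigree) {
  s <- gtm$sites
  male <- if (is.null(gtm$sex)) rep(FALSE, length(gtm$samples)) else
    gtm$sex == "male"
  idx <- function(id) match(id, gtm$samples)
  out <- vector("list", nrow(pedigree))
  for (k in seq_len(nrow(pedigree))) {
    ci <- idx(pedigree$child[k])
    fi <- if (!is.na(pedigree$father[k])) idx(pedigree$father[k]) else NA
    mi <- if (!is.na(pedigree$mother[k])) idx(pedigree$mother[k]) else NA
    gt_c <- gtm$gt[, ci]
    cn_c <- gtm$cn[, ci]
    gt_f <- if (!is.na(fi)) gtm$gt[, fi] else rep(NA_integer_, nrow(s))
    cn_f <- if (!is.na(fi)) gtm$cn[, fi] else rep(NA_integer_, nrow(s))
    gt_m <- if (!is.na(mi)) gtm$gt[, mi] else rep(NA_integer_, nrow(s))
    cn_m <- if (!is.na(mi)) gtm$cn[, mi] else rep(NA_integer_, nrow(s))
    has_f <- !is.na(fi); has_m <- !is.na(mi)

    called <- !is.na(gt_c) &
      (!has_f | !is.na(gt_f)) & (!has_m | !is.na(gt_m))
    nonref <- (gt_c > 0) |
      (has_f & !is.na(gt_f) & gt_f > 0) | (has_m & !is.na(gt_m) & gt_m > 0)
    informative <- called & ifelse(is.na(nonref), FALSE, nonref)

    consistent <- rep(TRUE, nrow(s))
    for (i in which(informative)) {
      consistent[i] <- triple_consistent(
        svtype = s$svtype[i], chrx = s$chrom[i] == "chrX",
        child_male = male[ci],
        gt_c = gt_c[i], cn_c = cn_c[i],
        gt_f = if (has_f) gt_f[i] else NA, cn_f = if (has_f) cn_f[i] else NA,
        gt_m = if (has_m) gt_m[i] else NA, cn_m = if (has_m) cn_m[i] else NA)
    }
    out[[k]] <- data.frame(svtype = s$svtype, informative = informative,
                           inconsistent = informative & !consistent)
  }
  do.call(rbind, out)
}

triple_consistent <- function(svtype, chrx, child_male, gt_c, cn_c,
                              gt_f, cn_f, gt_m, cn_m) {
  if (svtype == "DUP" && !chrx) {
    ## copy-number transmission: child extra copies must be expressible as
    ## a sum of one per-parent haplotype contribution
    e_c <- cn_c - 2L
    e_f <- if (is.na(cn_f)) NA else cn_f - 2L
    e_m <- if (is.na(cn_m)) NA else cn_m - 2L
    if (is.na(e_f) || is.na(e_m)) return(e_c >= 0L)  # duo: untyped parent free
    return(e_c >= 0L && e_c <= e_f + e_m)
  }
  if (chrx) {
    if (child_male) {
      if (is.na(gt_m)) return(TRUE)                  # X comes from mother
      return(gt_c %in% transmit_set[[gt_m + 1L]])
    }
    pat <- if (is.na(gt_f)) 0:1 else gt_f            # father's hemizygous allele
    mat <- if (is.na(gt_m)) 0:1 else transmit_set[[gt_m + 1L]]
    return(any(outer(pat, mat, "+") == gt_c))
  }
  if (is.na(gt_f)) return(duo_consistent(gt_c, gt_m))
  if (is.na(gt_m)) return(duo_consistent(gt_c, gt_f))
  BIALLELIC_OK[gt_c + 1L, gt_f + 1L, gt_m + 1L]
}

#' De novo (novel heterozygote) rate
#'
#' Fraction of heterozygous child genotypes whose parents are both
#' genotyped homozygous reference. Duos are excluded (a single typed
#' parent cannot establish a de novo event).
#'
#' @inheritParams mendelian_error_rate
#' @return Data frame per SV type: `n_de_novo`, `n_child_het`, `rate`.
#' @export
de_novo_rate <- function(gtm, pedigree) {
  if (nrow(pedigree) == 0L) stopf("empty pedigree")
  trios <- pedigree[!is.na(pedigree$father) & !is.na(pedigree$mother), ]
  s <- gtm$sites
  n_dn <- n_het <- stats::setNames(rep(0L, length(unique(s$svtype))),
                                   sort(unique(s$svtype)))
  for (k in seq_len(nrow(trios))) {
    ci <- match(trios$child[k], gtm$samples)
    fi <- match(trios$father[k], gtm$samples)
    mi <- match(trios$mother[k], gtm$samples)
    het <- !is.na(gtm$gt[, ci]) & gtm$gt[, ci] == 1L &
      !is.na(gtm$gt[, fi]) & !is.na(gtm$gt[, mi])
    dn <- het & gtm$gt[, fi] == 0L & gtm$gt[, mi] == 0L
    t_het <- tapply(het, s$svtype, sum)
    t_dn <- tapply(dn, s$svtype, sum)
    n_het[names(t_het)] <- n_het[names(t_het)] + t_het
    n_dn[names(t_dn)] <- n_dn[names(t_dn)] + t_dn
  }
  data.frame(svtype = names(n_het), n_de_novo = as.integer(n_dn),
             n_child_het = as.integer(n_het),
             rate = ifelse(n_het > 0, n_dn / n_het, 0),
             row.names = NULL)
}

#' Allelic balance of REF x HET transmissions
#'
#' Over (site, family) pairs where one parent is homozygous reference and
#' the other heterozygous (the informative configuration), tabulates
#' whether the child received the reference or the alternate allele.
#' Unbiased genotyping gives a 50:50 REF:HET split.
#'
#' @inheritParams mendelian_error_rate
#' @return Data frame per SV type: `n_ref`, `n_het`, `pct_ref`, `pct_het`
#'   (percentages summing to 100; `NA` with `undefined = TRUE` when no
#'   informative family exists).
#' @export
allelic_balance <- function(gtm, pedigree) {
  if (nrow(pedigree) == 0L) stopf("empty pedigree")
  trios <- pedigree[!is.na(pedigree$father) & !is.na(pedigree$mother), ]
  s <- gtm$sites
  types <- sort(unique(s$svtype))
  n_ref <- n_het <- stats::setNames(rep(0L, length(types)), types)
  for (k in seq_len(nrow(trios))) {
    ci <- match(trios$child[k], gtm$samples)
    fi <- match(trios$father[k], gtm$samples)
    mi <- match(trios$mother[k], gtm$samples)
    gf <- gtm$gt[, fi]; gm <- gtm$gt[, mi]; gc <- gtm$gt[, ci]
    informative <- !is.na(gf) & !is.na(gm) & !is.na(gc) &
      ((gf == 0L & gm == 1L) | (gf == 1L & gm == 0L)) & gc %in% 0:1
    t_ref <- tapply(informative & gc == 0L, s$svtype, sum)
    t_het <- tapply(informative & gc == 1L, s$svtype, sum)
    n_ref[names(t_ref)] <- n_ref[names(t_ref)] + t_ref
    n_het[names(t_het)] <- n_het[names(t_het)] + t_het
  }
  tot <- n_ref + n_het
  data.frame(svtype = types, n_ref = as.integer(n_ref),
             n_het = as.integer(n_het),
             pct_ref = ifelse(tot > 0, 100 * n_ref / tot, NA_real_),
             pct_het = ifelse(tot > 0, 100 * n_het / tot, NA_real_),
             undefined = tot == 0L, row.names = NULL)
}

#' Per-sample heterozygous/homozygous-alternate ratio
#'
#' Counts HET and HOM-alt calls per sample across PASS biallelic sites
#' (chrX male hemizygous calls are excluded). Samples without a HOM call
#' get an infinite ratio and are excluded from the cohort mean.
#'
#' @param gtm An `sv_genotypes` object.
#' @return Data frame per sample (`n_het`, `n_hom`, `ratio`) with the
#'   cohort mean over finite ratios in `attr(, "cohort_mean")`.
#' @export
het_hom_ratio <- function(gtm) {
  s <- gtm$sites
  keep <- s$filter == "PASS" & s$svtype %in% c("DEL", "INV")
  male <- if (is.null(gtm$sex)) rep(FALSE, length(gtm$samples)) else
    gtm$sex == "male"
  gt <- gtm$gt[keep, , drop = FALSE]
  is_x <- s$chrom[keep] == "chrX"
  if (any(is_x) && any(male)) gt[is_x, male] <- NA_integer_
  n_het <- colSums(gt == 1L, na.rm = TRUE)
  n_hom <- colSums(gt == 2L, na.rm = TRUE)
  out <- data.frame(sample = gtm$samples, n_het = n_het, n_hom = n_hom,
                    ratio = ifelse(n_hom > 0, n_het / n_hom, Inf),
                    row.names = NULL)
  attr(out, "cohort_mean") <- mean(out$ratio[is.finite(out$ratio)])
  out
}

#' Expected Mendelian inconsistency rate under uniform genotype errors
#'
#' Enumeration oracle for calibrating [mendelian_error_rate()]: for
#' biallelic sites with the given allele frequencies, assumes
#' Hardy-Weinberg parents, exact transmission to the child, and an error
#' channel that replaces each of the three genotypes independently with
#' probability `error_rate` by one of the two other genotypes uniformly.
#' Enumerates all 27 observed parent/parent/child combinations and
#' returns the expected inconsistency rate with the estimator's
#' denominator (triples with at least one non-reference observed
#' genotype), pooled across sites.
#'
#' @param af Per-site allele frequencies.
#' @param error_rate Uniform-replacement error probability.
#' @return Expected inconsistency rate (scalar in `[0, 1]`).
#' @export
expected_mendelian_error_rate <- function(af, error_rate) {
  e <- error_rate
  channel <- matrix(e / 2, 3, 3)
  diag(channel) <- 1 - e
  num <- den <- 0
  for (p in af) {
    g <- c((1 - p)^2, 2 * p * (1 - p), p^2)     # HWE genotype probabilities
    ## P(child | p1, p2) from Mendelian transmission
    ptrans <- function(gt) c(`0` = mean(transmit_set[[gt + 1L]] == 0L),
                             `1` = mean(transmit_set[[gt + 1L]] == 1L))
    for (p1 in 0:2) for (p2 in 0:2) {
      t1 <- ptrans(p1); t2 <- ptrans(p2)
      pc <- c(t1[1] * t2[1], t1[1] * t2[2] + t1[2] * t2[1], t1[2] * t2[2])
      for (ch in 0:2) {
        p_true <- g[p1 + 1L] * g[p2 + 1L] * pc[ch + 1L]
        if (p_true == 0) next
        for (o1 in 0:2) for (o2 in 0:2) for (oc in 0:2) {
          p_obs <- p_true * channel[p1 + 1L, o1 + 1L] *
            channel[p2 + 1L, o2 + 1L] * channel[ch + 1L, oc + 1L]
          if (o1 + o2 + oc > 0) {
            den <- den + p_obs
            if (!BIALLELIC_OK[oc + 1L, o1 + 1L, o2 + 1L]) num <- num + p_obs
          }
        }
      }
    }
  }
  if (den == 0) return(0)
  num / den
}

#' Full pedigree QC report
#'
#' Convenience wrapper running [mendelian_error_rate()], [de_novo_rate()],
#' [allelic_balance()] and [het_hom_ratio()] on one genotype set.
#'
#' @inheritParams mendelian_error_rate
#' @return List with elements `mendelian`, `de_novo`, `allelic_balance`,
#'   `het_hom`.
#' @export
pedigree_qc <- function(gtm, pedigree) {
  list(mendelian = mendelian_error_rate(gtm, pedigree),
       de_novo = de_novo_rate(gtm, pedigree),
       allelic_balance = allelic_balance(gtm, pedigree),
       het_hom = het_hom_ratio(gtm))
}
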