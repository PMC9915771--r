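## Joint genotyping of candidate SV sites by Gaussian mixture models over
## pooled per-sample evidence. Deletions and duplications use a 2-D model
## on (alignment support, normalized depth); sites lacking support fall
## back to a depth-only model; inversions (copy-neutral) use a
## support-only model. EM is initialized at the anchored genotype
## expectations, never randomly, so genotyping is fully deterministic.

GT_QUAL_MIN <- 0.5      # below this posterior a genotype is a no-call
EM_TOL <- 1e-6
EM_MAX_ITER <- 200L
DEPTH_VAR_FLOOR <- 1e-4
SUPPORT_VAR_FLOOR <- 0.25

## ---- EM core --------------------------------------------------------------

## x: n x d matrix; mu0: K x d anchor means; shared dims use one pooled
## variance across components (homoscedastic), which keeps the class
## boundaries monotone along that dimension. Components that lose all
## responsibility keep their anchor parameters and weight ~0.
em_fit <- function(x, mu0, var0, shared = rep(FALSE, ncol(x)),
                   floors = rep(1e-4, ncol(x)),
                   max_iter = EM_MAX_ITER, tol = EM_TOL) {
  n <- nrow(x); d <- ncol(x); K <- nrow(mu0)
  mu <- mu0
  v <- var0
  ## initial hard assignment by scaled distance to the anchors sets the
  ## starting weights to the apparent class proportions
  d2 <- sapply(seq_len(K), function(k)
    rowSums(sweep(x, 2, mu[k, ])^2 / rep(pmax(v[k, ], floors), each = n)))
  if (n == 1L) d2 <- matrix(d2, nrow = 1L)
  hard <- max.col(-d2, ties.method = "first")
  w <- pmax(tabulate(hard, K) / n, 1e-8)
  w <- w / sum(w)

  loglik <- -Inf; converged <- FALSE; iter <- 0L
  logdens <- matrix(0, n, K)
  while (iter < max_iter) {
    iter <- iter + 1L
    for (k in seq_len(K)) {
      logdens[, k] <- log(w[k]) +
        rowSums(stats::dnorm(x, mean = rep(mu[k, ], each = n),
                             sd = rep(sqrt(v[k, ]), each = n), log = TRUE))
    }
    m <- apply(logdens, 1, max)
    lse <- m + log(rowSums(exp(logdens - m)))
    ll <- sum(lse)
    resp <- exp(logdens - lse)
    nk <- colSums(resp)
    ## location/scale updates need effective membership of >= 2 samples;
    ## below that a component keeps its anchor instead of collapsing onto
    ## a stray outlier, which also pins rare genotype classes in place
    live <- nk >= 2
    w <- pmax(nk, 1e-10) / sum(pmax(nk, 1e-10))
    for (k in which(live)) {
      mu[k, ] <- colSums(resp[, k] * x) / nk[k]
      v[k, ] <- colSums(resp[, k] * sweep(x, 2, mu[k, ])^2) / nk[k]
    }
    v <- sweep(pmax(v, 0), 2, floors, pmax)
    if (any(live)) {
      for (j in which(shared)) {
        pooled <- sum(nk[live] * v[live, j]) / sum(nk[live])
        v[, j] <- max(pooled, floors[j])
      }
    }
    if (is.finite(loglik) && abs(ll - loglik) <= tol * (abs(loglik) + 1)) {
      loglik <- ll; converged <- TRUE
      break
    }
    loglik <- ll
  }
  list(mu = mu, var = v, w = w, loglik = loglik,
       converged = converged, n_iter = iter)
}

new_mixture_fit <- function(em, classes, dims, mode) {
  comp <- data.frame(class = classes, weight = em$w)
  for (j in seq_along(dims)) {
    comp[[paste0("mu_", dims[j])]] <- em$mu[, j]
    comp[[paste0("var_", dims[j])]] <- em$var[, j]
  }
  structure(list(components = comp, dims = dims, mode = mode,
                 loglik = em$loglik, converged = em$converged,
                 n_iter = em$n_iter),
            class = "sv_mixture_fit")
}

#' @export
print.sv_mixture_fit <- function(x, ...) {
  cat(sprintf("<sv_mixture_fit> mode %s, %d components, loglik %.2f (%s, %d iter)\n",
              x$mode, nrow(x$components), x$loglik,
              if (x$converged) "converged" else "not converged", x$n_iter))
  print(x$components, digits = 3)
  invisible(x)
}

#' Assign genotype classes under a fitted mixture
#'
#' Computes per-sample class posteriors under a fitted site model and
#' assigns each sample its maximum-posterior class; posteriors of
#' components mapped to the same class are pooled. Samples whose best
#' posterior falls below the no-call threshold are set to `NA`.
#'
#' @param fit An `sv_mixture_fit`.
#' @param depth,support Per-sample normalized depth / pooled support count
#'   (whichever dimensions the fit uses).
#' @param qual_min No-call posterior threshold, default 0.5.
#' @return List with integer `class` (copy-number class or allele dosage,
#'   `NA` for no-calls) and `qual` (posterior of the assigned class).
#' @export
assign_genotypes <- function(fit, depth = NULL, support = NULL,
                             qual_min = GT_QUAL_MIN) {
  comp <- fit$components
  x <- cbind(depth = depth, support = support)[, fit$dims, drop = FALSE]
  n <- nrow(x)
  K <- nrow(comp)
  logdens <- matrix(-Inf, n, K)
  for (k in seq_len(K)) {
    if (comp$weight[k] <= 1e-9) next
    mu <- unlist(comp[k, paste0("mu_", fit$dims)])
    v <- unlist(comp[k, paste0("var_", fit$dims)])
    logdens[, k] <- log(comp$weight[k]) +
      rowSums(stats::dnorm(x, mean = rep(mu, each = n),
                           sd = rep(sqrt(v), each = n), log = TRUE))
  }
  m <- apply(logdens, 1, max)
  post <- exp(logdens - (m + log(rowSums(exp(logdens - m)))))
  classes <- sort(unique(comp$class))
  class_post <- sapply(classes, function(cl)
    rowSums(post[, comp$class == cl, drop = FALSE]))
  if (n == 1L) class_post <- matrix(class_post, nrow = 1L)
  best <- max.col(class_post, ties.method = "first")
  qual <- class_post[cbind(seq_len(n), best)]
  cls <- classes[best]
  cls[qual < qual_min] <- NA_integer_
  list(class = as.integer(cls), qual = qual)
}

## Deterministic estimate of the per-allele support rate from samples that
## look like carriers on the depth axis (or, failing that, any supported
## sample); the EM refines it.
estimate_lambda <- function(support, putative) {
  s <- support[putative & support > 0]
  if (!length(s)) s <- support[support > 0]
  if (!length(s)) return(10)
  max(2, stats::median(s))
}

anchor_set <- function(svtype, ndepth, lambda) {
  if (svtype == "DEL") {
    list(classes = 2:0,                    # copy number
         depth = c(1, 0.5, 0), units = 0:2)
  } else {
    cn_max <- 4L
    if (length(ndepth)) {
      q <- stats::quantile(ndepth, 0.995, names = FALSE)
      cn_max <- max(4L, min(8L, as.integer(ceiling(2 * q))))
    }
    cls <- 2:cn_max
    list(classes = cls, depth = cls / 2, units = pmin(cls - 2L, 4L))
  }
}

## ---- per-site genotypers --------------------------------------------------

#' Genotype one site from two-dimensional evidence
#'
#' Fits a Gaussian mixture over (normalized depth, pooled alignment
#' support) with components anchored at the genotype expectations —
#' deletions at depth 1.0 / 0.5 / 0.0 and duplications at 1.0 / 1.5 /
#' 2.0 and beyond for multi-allelic copy numbers — and support means
#' proportional to the alternate-allele count. The depth dimension uses a
#' pooled variance so class boundaries are monotone in depth. Components
#' with weight below `1 / (2n)` are pruned before assignment.
#'
#' @param ndepth Per-sample GC-normalized event depth.
#' @param support Per-sample pooled support count
#'   (`n_disc + n_split + n_clip`).
#' @param svtype `"DEL"` or `"DUP"`.
#' @return List: `fit` (`sv_mixture_fit`), `class` (copy number), `gt`
#'   (allele dosage), `cn`, `qual`.
#' @export
genotype_site_2d <- function(ndepth, support, svtype = c("DEL", "DUP")) {
  svtype <- match.arg(svtype)
  n <- length(ndepth)
  if (n < 20L) stopf("2-D genotyping needs >= 20 samples, got %d", n)
  anc <- anchor_set(svtype, ndepth, NA)
  putative <- if (svtype == "DEL") ndepth < 0.75 else ndepth > 1.25
  lambda <- estimate_lambda(support, putative)
  mu0 <- cbind(anc$depth, anc$units * lambda)
  var0 <- cbind(rep(0.01, length(anc$depth)),
                pmax(anc$units * lambda, 1))
  em <- em_fit(cbind(ndepth, support), mu0, var0,
               shared = c(TRUE, FALSE),
               floors = c(DEPTH_VAR_FLOOR, SUPPORT_VAR_FLOOR))
  finalize_site_fit(em, anc, dims = c("depth", "support"), mode = "GT2D",
                    svtype = svtype, ndepth = ndepth, support = support)
}

#' Genotype one site from depth only
#'
#' Fallback for deletions/duplications with complex breakpoints whose
#' alignment support is absent but whose depth signal is clear: a 1-D
#' Gaussian mixture on normalized depth with the same anchored components
#' and assignment rule as the 2-D model.
#'
#' @inheritParams genotype_site_2d
#' @return As [genotype_site_2d()], with mode `GTDP`.
#' @export
genotype_site_depth_only <- function(ndepth, svtype = c("DEL", "DUP")) {
  svtype <- match.arg(svtype)
  anc <- anchor_set(svtype, ndepth, NA)
  mu0 <- cbind(anc$depth)
  var0 <- cbind(rep(0.01, length(anc$depth)))
  em <- em_fit(cbind(ndepth), mu0, var0, shared = TRUE,
               floors = DEPTH_VAR_FLOOR)
  finalize_site_fit(em, anc, dims = "depth", mode = "GTDP",
                    svtype = svtype, ndepth = ndepth, support = NULL)
}

#' Genotype one site from alignment support only
#'
#' Used for inversions, which are copy-neutral: a 1-D mixture on the
#' pooled support count with components at 0, lambda and 2*lambda support
#' for reference, heterozygous and homozygous samples.
#'
#' @param support Per-sample pooled support count.
#' @return As [genotype_site_2d()], with mode `GTSUP`; classes are allele
#'   dosages 0/1/2.
#' @export
genotype_site_support_only <- function(support) {
  if (all(support == 0)) {
    n <- length(support)
    fit <- new_mixture_fit(
      list(mu = cbind(0), var = cbind(SUPPORT_VAR_FLOOR), w = 1,
           loglik = 0, converged = TRUE, n_iter = 0L),
      classes = 0L, dims = "support", mode = "GTSUP")
    return(list(fit = fit, class = rep(0L, n), gt = rep(0L, n),
                cn = rep(2L, n), qual = rep(1, n)))
  }
  lambda <- estimate_lambda(support, support > 0)
  anc <- list(classes = 0:2, depth = NULL, units = 0:2)
  mu0 <- cbind(anc$units * lambda)
  var0 <- cbind(pmax(anc$units * lambda, 1))
  em <- em_fit(cbind(support), mu0, var0, shared = FALSE,
               floors = SUPPORT_VAR_FLOOR)
  fit <- new_mixture_fit(em, classes = anc$classes, dims = "support",
                         mode = "GTSUP")
  fit <- prune_components(fit, length(support))
  asn <- assign_genotypes(fit, support = support)
  list(fit = fit, class = asn$class, gt = asn$class,
       cn = rep(2L, length(support)), qual = asn$qual)
}

## Map EM components back to genotype classes (labels never swap because
## each component keeps its anchor identity), prune empty components, and
## translate copy-number classes into dosage calls.
finalize_site_fit <- function(em, anc, dims, mode, svtype, ndepth, support) {
  fit <- new_mixture_fit(em, classes = anc$classes, dims = dims, mode = mode)
  n <- length(ndepth %||% support)
  fit <- prune_components(fit, n)
  asn <- assign_genotypes(fit, depth = ndepth, support = support)
  cn <- asn$class
  gt <- if (svtype == "DEL") 2L - cn else pmin(pmax(cn - 2L, 0L), 2L)
  list(fit = fit, class = asn$class, gt = as.integer(gt), cn = cn,
       qual = asn$qual)
}

prune_components <- function(fit, n) {
  keep <- fit$components$weight >= 1 / (2 * n)
  if (!any(keep)) keep <- fit$components$weight == max(fit$components$weight)
  fit$components <- fit$components[keep, , drop = FALSE]
  fit$components$weight <- fit$components$weight / sum(fit$components$weight)
  fit
}

## Minimum separation between adjacent retained components (diagonal
## Mahalanobis with averaged variances); used by the PASS criterion.
min_component_separation <- function(fit) {
  comp <- fit$components
  if (nrow(comp) < 2L) return(Inf)
  mu <- as.matrix(comp[, paste0("mu_", fit$dims), drop = FALSE])
  v <- as.matrix(comp[, paste0("var_", fit$dims), drop = FALSE])
  ord <- order(comp$class)
  mu <- mu[ord, , drop = FALSE]; v <- v[ord, , drop = FALSE]
  min(vapply(seq_len(nrow(mu) - 1L), function(i) {
    sqrt(sum((mu[i + 1L, ] - mu[i, ])^2 / ((v[i + 1L, ] + v[i, ]) / 2)))
  }, numeric(1)))
}

## ---- cohort-level driver --------------------------------------------------

#' Jointly genotype candidate sites across a cohort
#'
#' Runs the per-site mixture genotypers over every candidate site:
#' inversions with the support-only model, deletions/duplications with the
#' 2-D model, falling back to depth-only when the putative carriers'
#' pooled mean support is below `support_sparsity` (complex breakpoints)
#' or when the 2-D EM fails to converge. Sites on chromosome X are
#' delegated to [genotype_chrx()] when sex labels are supplied, and
#' dropped with a message otherwise. A site PASSes when its call rate is
#' at least `min_call_rate` and adjacent mixture components are separated
#' by a Mahalanobis distance of at least `min_separation`; other sites are
#' flagged `LowQual`.
#'
#' @param sites Candidate site table (`site_id`, `chrom`, `start`, `end`,
#'   `svtype`).
#' @param evidence Evidence table with GC-normalized columns (see
#'   [normalize_evidence()]) covering every (site, sample) pair.
#' @param sex Optional per-sample sex labels (named or in sample order)
#'   for chromosome-X genotyping.
#' @param par_regions Optional pseudoautosomal region table
#'   (`chrom`/`start`/`end`) excluded from chrX genotyping.
#' @param support_sparsity Mean carrier support below which a DEL/DUP site
#'   is genotyped depth-only; default 2.
#' @param min_call_rate,min_separation PASS thresholds (0.9 and 2).
#' @return An `sv_genotypes` object; per-site fits are attached as
#'   `attr(, "fits")`.
#' @export
genotype_cohort <- function(sites, evidence, sex = NULL, par_regions = NULL,
                            support_sparsity = 2, min_call_rate = 0.9,
                            min_separation = 2) {
  samples <- sort(unique(evidence$sample_id))
  ev_rows <- split(seq_len(nrow(evidence)), evidence$site_id)
  is_x <- sites$chrom == "chrX"

  auto <- genotype_site_block(sites[!is_x, , drop = FALSE], evidence,
                              ev_rows, samples, male = NULL,
                              support_sparsity = support_sparsity)
  res <- auto
  if (any(is_x)) {
    if (is.null(sex)) {
      log_msg("no sex labels: dropping %d chrX site(s)", sum(is_x))
    } else {
      xres <- genotype_chrx(sites[is_x, , drop = FALSE], evidence, sex,
                            par_regions = par_regions,
                            support_sparsity = support_sparsity)
      res <- list(sites = rbind(auto$sites, xres$sites),
                  gt = rbind(auto$gt, xres$gt),
                  cn = rbind(auto$cn, xres$cn),
                  qual = rbind(auto$qual, xres$qual),
                  fits = c(auto$fits, xres$fits),
                  mode = c(auto$mode, xres$mode))
    }
  }
  sex_vec <- align_sex(sex, samples)
  gtm <- new_sv_genotypes(res$sites, samples, res$gt, res$cn, res$qual,
                          mode = res$mode, sex = sex_vec)
  gtm$sites$filter <- ifelse(
    gtm$sites$call_rate >= min_call_rate &
      vapply(res$fits, min_component_separation, numeric(1)) >= min_separation,
    "PASS", "LowQual")
  attr(gtm, "fits") <- res$fits
  gtm
}

align_sex <- function(sex, samples) {
  if (is.null(sex)) return(NULL)
  if (!is.null(names(sex))) return(unname(sex[samples]))
  sex
}

genotype_site_block <- function(sites, evidence, ev_rows, samples,
                                male = NULL, depth_shift = 0,
                                support_sparsity = 2) {
  n_sites <- nrow(sites); n_samp <- length(samples)
  gt <- cn <- matrix(NA_integer_, n_sites, n_samp)
  qual <- matrix(NA_real_, n_sites, n_samp)
  fits <- vector("list", n_sites)
  mode <- character(n_sites)
  pre <- matrix(NA_real_, n_sites, 4)

  for (i in seq_len(n_sites)) {
    rows <- ev_rows[[sites$site_id[i]]]
    if (is.null(rows)) stopf("no evidence for site %s", sites$site_id[i])
    ev <- evidence[rows, , drop = FALSE]
    ev <- ev[match(samples, ev$sample_id), , drop = FALSE]
    support <- ev$n_disc + ev$n_split + ev$n_clip
    ndepth <- ev$ndepth
    if (!is.null(male) && any(male)) ndepth[male] <- ndepth[male] + depth_shift
    svtype <- sites$svtype[i]

    if (svtype == "INV") {
      r <- genotype_site_support_only(support)
    } else {
      putative <- if (svtype == "DEL") ndepth < 0.75 else ndepth > 1.25
      sparse <- any(putative) && mean(support[putative]) < support_sparsity
      r <- NULL
      if (!sparse) {
        r <- genotype_site_2d(ndepth, support, svtype)
        if (!r$fit$converged) r <- NULL
      }
      if (is.null(r)) r <- genotype_site_depth_only(ndepth, svtype)
    }
    if (!is.null(male)) {
      ## hemizygous reporting: any carrier class collapses to one allele
      carrier <- !is.na(r$gt) & r$gt > 0L
      r$gt[male & carrier] <- 1L
      if (svtype == "DEL") r$cn[male] <- 1L - r$gt[male]
      if (svtype == "DUP") r$cn[male & !is.na(r$cn)] <-
          pmax(r$cn[male & !is.na(r$cn)] - 1L, 0L)
    }
    gt[i, ] <- r$gt; cn[i, ] <- r$cn; qual[i, ] <- r$qual
    fits[[i]] <- r$fit; mode[i] <- r$fit$mode
    pre[i, ] <- c(mean(ev$pre_mean_n), mean(ev$pre_sd_n),
                  mean(ev$post_mean_n), mean(ev$post_sd_n))
  }
  sites$pre_mean <- pre[, 1]; sites$pre_sd <- pre[, 2]
  sites$post_mean <- pre[, 3]; sites$post_sd <- pre[, 4]
  list(sites = sites, gt = gt, cn = cn, qual = qual, fits = fits,
       mode = mode)
}

#' Infer sample sex from chromosome X and Y depths
#'
#' Thresholds the autosome-normalized X and Y depths: one X copy and
#' substantial Y coverage give male, two X copies and near-zero Y give
#' female. Samples between the thresholds are returned as `NA` and should
#' be excluded from chrX genotyping.
#'
#' @param sex_depths Data frame with `sample`, `x_depth`, `y_depth`,
#'   `autosome_depth`.
#' @return Named character vector (`"male"`/`"female"`/`NA`).
#' @export
infer_sex <- function(sex_depths) {
  xn <- sex_depths$x_depth / sex_depths$autosome_depth
  yn <- sex_depths$y_depth / sex_depths$autosome_depth
  out <- rep(NA_character_, nrow(sex_depths))
  out[xn < 0.75 & yn > 0.25] <- "male"
  out[xn >= 0.75 & yn < 0.15] <- "female"
  n_amb <- sum(is.na(out))
  if (n_amb > 0) log_msg("infer_sex: %d sample(s) ambiguous, excluded", n_amb)
  stats::setNames(out, sex_depths$sample)
}

#' Genotype chromosome-X candidate sites
#'
#' Sites intersecting pseudoautosomal regions are skipped entirely. Male
#' samples' normalized depths are increased by 0.5 before the mixture fit
#' so that male and female evidence clusters coincide; male calls are then
#' reported hemizygously (absent/present, one allele each), female calls
#' as diploid genotypes. Unknown-sex samples are excluded (no-call) with a
#' logged count.
#'
#' @param sites chrX candidate site table.
#' @param evidence Normalized evidence table.
#' @param sex Per-sample sex labels (named by sample or in sorted-sample
#'   order); `NA` = unknown.
#' @param par_regions Pseudoautosomal region table (`chrom`, `start`,
#'   `end`); sites overlapping any interval are skipped.
#' @param support_sparsity As in [genotype_cohort()].
#' @return List (site block) used by [genotype_cohort()]; skipped PAR site
#'   ids are attached as `attr(, "skipped_par")`.
#' @export
genotype_chrx <- function(sites, evidence, sex, par_regions = NULL,
                          support_sparsity = 2) {
  samples <- sort(unique(evidence$sample_id))
  sex <- align_sex(sex, samples)
  in_par <- overlaps_region_set(sites$chrom, sites$start, sites$end,
                                par_regions)
  if (any(in_par)) {
    log_msg("genotype_chrx: %d site(s) inside PARs skipped", sum(in_par))
  }
  keep <- sites[!in_par, , drop = FALSE]
  male <- !is.na(sex) & sex == "male"
  unknown <- is.na(sex)
  if (any(unknown)) {
    log_msg("genotype_chrx: %d unknown-sex sample(s) excluded", sum(unknown))
  }
  ev_rows <- split(seq_len(nrow(evidence)), evidence$site_id)
  res <- genotype_site_block(keep, evidence, ev_rows, samples,
                             male = male, depth_shift = 0.5,
                             support_sparsity = support_sparsity)
  res$gt[, unknown] <- NA_integer_
  res$cn[, unknown] <- NA_integer_
  res$qual[, unknown] <- NA_real_
  attr(res, "skipped_par") <- sites$site_id[in_par]
  res
}
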