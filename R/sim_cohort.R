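#' Simulate a synthetic SV cohort with evidence, calls and truth
#'
#' Generates a complete cohort under the generative model the joint
#' genotyper assumes: per-site allele frequencies drawn from a Beta
#' distribution (optionally diverged between populations under a
#' Balding-Nichols model), Mendelian transmission within trios and duos,
#' genotype-proportional normalized read depth with truncated-Gaussian
#' noise and a per-sample quadratic GC bias, Poisson (optionally
#' overdispersed) alignment-support counts, per-sample SV calls with
#' jittered breakpoints, 100-bp interval depths for GC-curve estimation,
#' and chromosome X/Y mean depths for sex inference.
#'
#' Artifact ("false candidate") sites have no true carriers but show
#' spurious support and mildly non-conforming depth in a small random set
#' of samples, so they enter the candidate list and exercise the
#' duplication and chrX filters exactly where the real pipeline needs them.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements:
#'   \describe{
#'     \item{truth}{`sv_cohort_truth`: samples, pedigree, site registry,
#'       true copy-number and dosage matrices, per-population allele
#'       frequencies, and the generating config.}
#'     \item{calls}{Per-sample SV calls (data frame: `sample`, `chrom`,
#'       `start`, `end`, `svtype`, `svlen`), 0-based half-open.}
#'     \item{evidence}{Long-format evidence table, one row per
#'       (site, sample): support counts, raw event depth, flank depth
#'       statistics and site GC fraction.}
#'     \item{interval_depths}{List with `gc` (per-interval GC fraction) and
#'       `depth` (interval x sample raw depth matrix) for GC-curve fitting.}
#'     \item{sex_depths}{Per-sample mean depths of chrX, chrY and autosomes.}
#'     \item{snps}{If `n_snps > 0`: SNP positions, allele frequencies and a
#'       SNP x sample dosage matrix (HWE, independent of the SVs).}
#'   }
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)

  samples <- sim_samples(config)
  sites <- sim_site_registry(config)
  af <- sim_allele_freqs(config, sites)
  geno <- sim_genotypes(config, samples, sites, af)
  per_sample_depth <- config$depth_mean *
    pmax(0.2, 1 + stats::rnorm(config$n_samples, 0, config$sample_depth_sd))
  gc_amp <- config$gc_amplitude * stats::runif(config$n_samples, 0.5, 1)
  ## generating parameters are part of the truth record
  samples$mean_depth <- per_sample_depth
  samples$gc_amplitude <- gc_amp

  evidence <- sim_evidence(config, samples, sites, geno,
                           per_sample_depth, gc_amp)
  calls <- sim_calls(config, samples, sites, geno)
  intervals <- sim_interval_depths(config, per_sample_depth, gc_amp)
  sexd <- sim_sex_depths(samples, per_sample_depth)
  snps <- if (config$n_snps > 0) sim_snps(config, samples) else NULL

  truth <- structure(list(
    config = config,
    samples = samples,
    pedigree = sim_pedigree_table(samples),
    sites = sites,
    af = af,
    dosage = geno$dosage,
    cn = geno$cn
  ), class = "sv_cohort_truth")

  list(truth = truth, calls = calls, evidence = evidence,
       interval_depths = intervals, sex_depths = sexd, snps = snps)
}

#' @export
print.sv_cohort_truth <- function(x, ...) {
  cat(sprintf("<sv_cohort_truth> %d samples, %d sites (%s)\n",
              nrow(x$samples), nrow(x$sites),
              paste(sprintf("%d %s", table(x$sites$svtype),
                            names(table(x$sites$svtype))), collapse = ", ")))
  invisible(x)
}

## ---- samples, pedigree ----------------------------------------------------

sim_samples <- function(cfg) {
  n <- cfg$n_samples
  id <- sprintf("S%05d", seq_len(n))
  sex <- sample(c("male", "female"), n, replace = TRUE)
  family_id <- rep(NA_character_, n)
  role <- rep("founder", n)
  i <- 1L
  if (cfg$n_trios > 0) {
    for (k in seq_len(cfg$n_trios)) {
      fam <- sprintf("F%04d", k)
      family_id[i:(i + 2L)] <- fam
      role[i:(i + 2L)] <- c("father", "mother", "child")
      sex[i] <- "male"; sex[i + 1L] <- "female"
      i <- i + 3L
    }
  }
  if (cfg$n_duos > 0) {
    for (k in seq_len(cfg$n_duos)) {
      fam <- sprintf("D%04d", k)
      family_id[i:(i + 1L)] <- fam
      role[i:(i + 1L)] <- c("mother", "child")
      sex[i] <- "female"
      i <- i + 1L + 1L
    }
  }
  ## population assigned per family unit so relatives share ancestry
  unit <- ifelse(is.na(family_id), id, family_id)
  units <- unique(unit)
  pop_of_unit <- sample(cfg$populations$label, length(units),
                        replace = TRUE, prob = cfg$populations$fraction)
  names(pop_of_unit) <- units
  data.frame(sample = id, sex = sex, population = unname(pop_of_unit[unit]),
             family_id = family_id, role = role, stringsAsFactors = FALSE)
}

sim_pedigree_table <- function(samples) {
  fams <- unique(stats::na.omit(samples$family_id))
  if (length(fams) == 0L) {
    return(data.frame(family_id = character(), child = character(),
                      father = character(), mother = character()))
  }
  do.call(rbind, lapply(fams, function(f) {
    m <- samples[!is.na(samples$family_id) & samples$family_id == f, ]
    data.frame(
      family_id = f,
      child = m$sample[m$role == "child"],
      father = if (any(m$role == "father")) m$sample[m$role == "father"] else NA_character_,
      mother = m$sample[m$role == "mother"],
      stringsAsFactors = FALSE
    )
  }))
}

## ---- site registry --------------------------------------------------------

sim_site_registry <- function(cfg) {
  draw_sites <- function(n, svtype, chrom, chrom_len) {
    if (n == 0L) return(NULL)
    len <- round(exp(stats::runif(n, log(cfg$sv_len_range[1]),
                                  log(cfg$sv_len_range[2]))))
    start <- floor(stats::runif(n, 0, chrom_len - len))
    data.frame(chrom = chrom, start = start, end = start + len,
               svtype = svtype, stringsAsFactors = FALSE)
  }
  sites <- rbind(
    draw_sites(cfg$n_del, "DEL", "chr1", cfg$genome_length),
    draw_sites(cfg$n_dup, "DUP", "chr1", cfg$genome_length),
    draw_sites(cfg$n_inv, "INV", "chr1", cfg$genome_length),
    draw_sites(cfg$n_chrx, "DEL", "chrX", cfg$chrx_length)
  )
  ## injected concordant overlap pairs: second member shifted and slightly
  ## shorter, so the prefilter tie-break is deterministic
  if (cfg$n_dup_overlap_pairs > 0) {
    a <- draw_sites(cfg$n_dup_overlap_pairs, "DUP", "chr1", cfg$genome_length)
    len <- a$end - a$start
    b <- data.frame(chrom = a$chrom,
                    start = a$start + round(0.05 * len),
                    end = a$start + round(0.05 * len) + round(0.9 * len),
                    svtype = "DUP", stringsAsFactors = FALSE)
    a$overlap_pair <- seq_len(nrow(a)); b$overlap_pair <- seq_len(nrow(b))
    sites$overlap_pair <- NA_integer_
    sites <- rbind(sites, a, b)
  } else {
    sites$overlap_pair <- NA_integer_
  }
  n <- nrow(sites)
  sites$is_false <- FALSE
  if (cfg$false_candidate_rate > 0) {
    eligible <- which(is.na(sites$overlap_pair) & sites$chrom == "chr1")
    n_false <- round(cfg$false_candidate_rate * n)
    sites$is_false[sample(eligible, min(n_false, length(eligible)))] <- TRUE
  }
  sites$gc_frac <- round(stats::runif(n, 0.3, 0.6), 4)
  ord <- order(sites$chrom, sites$start, sites$end)
  sites <- sites[ord, , drop = FALSE]
  sites$site_id <- sprintf("SV%05d", seq_len(n))
  rownames(sites) <- sites$site_id
  sites[, c("site_id", "chrom", "start", "end", "svtype", "gc_frac",
            "is_false", "overlap_pair")]
}

sim_allele_freqs <- function(cfg, sites) {
  n <- nrow(sites)
  pops <- cfg$populations$label
  if (!is.null(cfg$af_fixed)) {
    p <- rep_len(cfg$af_fixed, n)
  } else {
    p <- stats::rbeta(n, cfg$af_shape1, cfg$af_shape2)
  }
  p <- pmin(pmax(p, 1e-4), 0.999)
  af <- matrix(p, nrow = n, ncol = length(pops),
               dimnames = list(sites$site_id, pops))
  if (length(pops) > 1 && cfg$divergence > 0) {
    f <- cfg$divergence
    for (j in seq_along(pops)) {
      af[, j] <- stats::rbeta(n, p * (1 - f) / f, (1 - p) * (1 - f) / f)
    }
    af <- pmin(pmax(af, 0), 1)
  }
  af[sites$is_false, ] <- 0
  ## overlap-pair second members reuse the first member's genotypes later
  af
}

## ---- genotypes ------------------------------------------------------------

## Haplotype allele values: 0 = reference; DEL/INV alternate = 1;
## DUP alternate = number of extra copies (1 or 2). Males carry a single
## X haplotype (a2 = NA on chrX).
sim_genotypes <- function(cfg, samples, sites, af) {
  n_sites <- nrow(sites); n_samp <- nrow(samples)
  a1 <- matrix(0L, n_sites, n_samp,
               dimnames = list(sites$site_id, samples$sample))
  a2 <- a1
  is_x <- sites$chrom == "chrX"
  male <- samples$sex == "male"
  pop_idx <- match(samples$population, colnames(af))

  draw_allele <- function(i, p_alt) {
    alt <- stats::rbinom(length(p_alt), 1L, p_alt)
    if (sites$svtype[i] == "DUP") {
      two <- stats::rbinom(length(p_alt), 1L, cfg$dup_allele2_frac)
      alt <- alt * (1L + two)
    }
    alt
  }

  founder <- samples$role != "child"
  for (i in seq_len(n_sites)) {
    p <- af[i, pop_idx]
    a1[i, founder] <- draw_allele(i, p[founder])
    a2[i, founder] <- draw_allele(i, p[founder])
  }

  ## children inherit one haplotype per parent; chrX sons are maternal-only
  ped <- sim_pedigree_table(samples)
  si <- stats::setNames(seq_len(n_samp), samples$sample)
  for (k in seq_len(nrow(ped))) {
    ch <- si[ped$child[k]]
    mo <- si[ped$mother[k]]
    fa <- if (!is.na(ped$father[k])) si[ped$father[k]] else NA_integer_
    pick_m <- stats::rbinom(n_sites, 1L, 0.5) == 1L
    mat <- ifelse(pick_m, a1[, mo], a2[, mo])
    if (is.na(fa)) {
      ## unsimulated father: draw from the family's population frequencies
      pat <- vapply(seq_len(n_sites), function(i)
        draw_allele(i, af[i, pop_idx[ch]]), integer(1))
    } else {
      pick_f <- stats::rbinom(n_sites, 1L, 0.5) == 1L
      pat <- ifelse(pick_f, a1[, fa], a2[, fa])
      if (any(is_x)) pat[is_x] <- a1[is_x, fa]  # father's single X
    }
    a1[, ch] <- pat
    a2[, ch] <- mat
    if (any(is_x) && male[ch]) a1[is_x, ch] <- NA_integer_  # maternal X only
  }
  if (any(is_x) && any(male & founder)) {
    a2[is_x, male & founder] <- NA_integer_  # single X haplotype
  }

  ## injected overlap pairs share one set of carrier genotypes
  for (k in unique(stats::na.omit(sites$overlap_pair))) {
    rows <- which(sites$overlap_pair == k)
    if (length(rows) == 2L) {
      a1[rows[2], ] <- a1[rows[1], ]
      a2[rows[2], ] <- a2[rows[1], ]
    }
  }

  sim_genotype_matrices(sites, a1, a2)
}

sim_genotype_matrices <- function(sites, a1, a2) {
  present <- function(a) ifelse(is.na(a), 0L, a)
  carried <- function(a) ifelse(is.na(a), 0L, as.integer(a > 0L))
  n_hap <- (!is.na(a1)) + (!is.na(a2))
  dosage <- carried(a1) + carried(a2)
  extra <- present(a1) + present(a2)
  is_dup <- sites$svtype == "DUP"
  is_del <- sites$svtype == "DEL"
  cn <- n_hap                 # base copy number = haplotype count
  cn[is_dup, ] <- n_hap[is_dup, , drop = FALSE] + extra[is_dup, , drop = FALSE]
  cn[is_del, ] <- n_hap[is_del, , drop = FALSE] - dosage[is_del, , drop = FALSE]
  ## INV is copy-neutral: cn stays at the haplotype count
  list(a1 = a1, a2 = a2, dosage = dosage, cn = cn)
}

## ---- evidence -------------------------------------------------------------

gc_bias_mult <- function(gc, amplitude) {
  pmax(0.2, 1 + amplitude * (gc - 0.45) - 2 * amplitude * (gc - 0.45)^2)
}

rsupport <- function(n, mu, phi) {
  out <- numeric(length(mu))
  pos <- mu > 0
  if (!any(pos)) return(out)
  if (phi > 0) {
    out[pos] <- stats::rnbinom(sum(pos), size = 1 / phi, mu = mu[pos])
  } else {
    out[pos] <- stats::rpois(sum(pos), mu[pos])
  }
  out
}

sim_evidence <- function(cfg, samples, sites, geno, sample_depth, gc_amp) {
  n_sites <- nrow(sites); n_samp <- nrow(samples)
  male <- samples$sex == "male"
  rows <- vector("list", n_sites)
  pseudo_all <- matrix(FALSE, n_sites, n_samp,
                       dimnames = list(sites$site_id, samples$sample))

  for (i in seq_len(n_sites)) {
    gc <- sites$gc_frac[i]
    gmult <- gc_bias_mult(gc, gc_amp)
    is_x <- sites$chrom[i] == "chrX"
    cn <- geno$cn[i, ]
    dos <- geno$dosage[i, ]
    svtype <- sites$svtype[i]

    ## normalized-depth expectation: diploid = 1.0; INV copy-neutral
    nd_exp <- if (svtype == "INV") {
      ifelse(is_x & male, 0.5, 1.0)
    } else {
      cn / 2
    }
    units <- if (svtype == "DUP") pmax(cn - 2L, 0L) else dos

    if (sites$is_false[i]) {
      pseudo <- stats::runif(n_samp) < 0.08
      pseudo_all[i, ] <- pseudo
      units <- as.integer(pseudo)
      shift <- if (svtype == "DEL") -0.15 else if (svtype == "DUP") 0.15 else 0
      nd_exp <- nd_exp + shift * pseudo
    }

    depth_raw <- sample_depth * gmult *
      pmax(0, nd_exp + stats::rnorm(n_samp, 0, cfg$depth_noise_sd))
    total <- rsupport(n_samp, cfg$support_lambda * units,
                      cfg$support_overdispersion)
    n_disc <- stats::rbinom(n_samp, total, 0.5)
    n_split <- stats::rbinom(n_samp, total - n_disc, 0.6)
    n_clip <- total - n_disc - n_split

    flank_exp <- sample_depth * gmult * ifelse(is_x & male, 0.5, 1.0)
    sd_scale <- if (sites$is_false[i]) 3 else 1
    mean_jit <- if (sites$is_false[i]) 0.10 else 0.02
    pre_mean <- flank_exp * (1 + stats::rnorm(n_samp, 0, mean_jit))
    post_mean <- flank_exp * (1 + stats::rnorm(n_samp, 0, mean_jit))
    pre_sd <- sample_depth * 0.05 * sd_scale *
      (1 + abs(stats::rnorm(n_samp, 0, 0.3)))
    post_sd <- sample_depth * 0.05 * sd_scale *
      (1 + abs(stats::rnorm(n_samp, 0, 0.3)))

    rows[[i]] <- data.frame(
      site_id = sites$site_id[i], sample_id = samples$sample,
      n_disc = n_disc, n_split = n_split, n_clip = n_clip,
      depth_raw = depth_raw,
      depth_pre_mean = pre_mean, depth_pre_sd = pre_sd,
      depth_post_mean = post_mean, depth_post_sd = post_sd,
      gc_frac = gc, stringsAsFactors = FALSE
    )
  }
  ev <- do.call(rbind, rows)
  rownames(ev) <- NULL
  attr(ev, "pseudo_carriers") <- pseudo_all
  ev
}

## ---- per-sample calls -----------------------------------------------------

sim_calls <- function(cfg, samples, sites, geno) {
  carrier <- geno$dosage > 0
  rows <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    who <- which(carrier[i, ])
    if (length(who) == 0L) next
    jit_s <- round(stats::rnorm(length(who), 0, cfg$breakpoint_jitter_sd))
    jit_e <- round(stats::rnorm(length(who), 0, cfg$breakpoint_jitter_sd))
    st <- pmax(0, sites$start[i] + jit_s)
    en <- pmax(st + 50, sites$end[i] + jit_e)
    rows[[i]] <- data.frame(
      sample = samples$sample[who], chrom = sites$chrom[i],
      start = st, end = en, svtype = sites$svtype[i],
      svlen = en - st, stringsAsFactors = FALSE
    )
  }
  calls <- do.call(rbind, rows)
  if (is.null(calls)) {
    calls <- data.frame(sample = character(), chrom = character(),
                        start = integer(), end = integer(),
                        svtype = character(), svlen = integer())
  }
  calls <- calls[order(calls$sample, calls$chrom, calls$start), ]
  rownames(calls) <- NULL
  calls
}

## ---- auxiliary depth tables ----------------------------------------------

sim_interval_depths <- function(cfg, sample_depth, gc_amp) {
  gc <- round(stats::runif(cfg$n_intervals, 0.25, 0.65), 4)
  depth <- vapply(seq_along(sample_depth), function(s) {
    sample_depth[s] * gc_bias_mult(gc, gc_amp[s]) *
      pmax(0, 1 + stats::rnorm(cfg$n_intervals, 0, cfg$depth_noise_sd))
  }, numeric(cfg$n_intervals))
  colnames(depth) <- sprintf("S%05d", seq_along(sample_depth))
  list(gc = gc, depth = depth)
}

sim_sex_depths <- function(samples, sample_depth) {
  male <- samples$sex == "male"
  data.frame(
    sample = samples$sample,
    x_depth = sample_depth * ifelse(male, 0.5, 1.0) *
      (1 + stats::rnorm(nrow(samples), 0, 0.02)),
    y_depth = sample_depth * ifelse(male, 0.5, 0.01) *
      (1 + stats::rnorm(nrow(samples), 0, 0.02)),
    autosome_depth = sample_depth * (1 + stats::rnorm(nrow(samples), 0, 0.01)),
    stringsAsFactors = FALSE
  )
}

sim_snps <- function(cfg, samples) {
  n <- cfg$n_snps
  af <- stats::rbeta(n, 2, 5)
  pos <- sort(floor(stats::runif(n, 0, cfg$genome_length)))
  dosage <- vapply(seq_len(nrow(samples)), function(s)
    stats::rbinom(n, 2L, af), integer(n))
  colnames(dosage) <- samples$sample
  rownames(dosage) <- sprintf("SNP%06d", seq_len(n))
  list(chrom = rep("chr1", n), pos = pos, af = af, dosage = dosage)
}

#' Inject genotyping errors into a simulated truth set
#'
#' Replaces genotypes independently with probability `rate`. In `uniform`
#' mode the replacement is a uniformly chosen *different* genotype (dosage
#' 0/1/2 for biallelic sites, 0/1 for hemizygous male chrX, copy number
#' 2..6 for duplications), the error channel assumed by the
#' Mendelian-error calibration oracle. In `ref_bias` mode heterozygous
#' genotypes are converted to homozygous reference with probability
#' `rate`, producing the reference bias that allelic-balance QC detects.
#'
#' @param truth A `sv_cohort_truth` object from [simulate_cohort()].
#' @param rate Per-genotype error probability in `[0, 1]`.
#' @param seed Integer seed for the error draw.
#' @param mode `"uniform"` or `"ref_bias"`.
#' @return The modified `sv_cohort_truth`; the number of changed entries is
#'   available as `attr(, "n_changed")`.
#' @export
inject_genotype_errors <- function(truth, rate, seed = 1L,
                                   mode = c("uniform", "ref_bias")) {
  mode <- match.arg(mode)
  if (rate < 0 || rate > 1) stopf("rate must be in [0, 1], got %g", rate)
  set.seed(seed)
  sites <- truth$sites
  dosage <- truth$dosage
  cn <- truth$cn
  male <- truth$samples$sex == "male"
  is_x <- sites$chrom == "chrX"
  is_dup <- sites$svtype == "DUP"
  n_changed <- 0L

  if (rate > 0) {
    hit <- matrix(stats::runif(length(dosage)) < rate,
                  nrow(dosage), ncol(dosage))
    if (mode == "ref_bias") {
      hit <- hit & dosage == 1L
      dosage[hit] <- 0L
      cn <- coherent_cn(sites, dosage, cn, male, hit)
      n_changed <- sum(hit)
    } else {
      for (i in seq_len(nrow(dosage))) {
        idx <- which(hit[i, ])
        if (length(idx) == 0L) next
        if (is_dup[i]) {
          space <- 2:6
          old <- cn[i, idx]
          cn[i, idx] <- vapply(old, function(g)
            sample(setdiff(space, g), 1L), numeric(1))
          dosage[i, idx] <- pmin(cn[i, idx] - 2L, 2L)
        } else {
          hemi <- is_x[i] & male[idx]
          old <- dosage[i, idx]
          newg <- integer(length(idx))
          for (j in seq_along(idx)) {
            space <- if (hemi[j]) 0:1 else 0:2
            newg[j] <- sample(setdiff(space, old[j]), 1L)
          }
          dosage[i, idx] <- newg
          if (sites$svtype[i] == "DEL") {
            base <- ifelse(hemi, 1L, 2L)
            cn[i, idx] <- base - newg
          }
        }
        n_changed <- n_changed + length(idx)
      }
    }
  }
  truth$dosage <- dosage
  truth$cn <- cn
  attr(truth, "n_changed") <- n_changed
  truth
}

coherent_cn <- function(sites, dosage, cn, male, hit) {
  for (i in seq_len(nrow(dosage))) {
    idx <- which(hit[i, ])
    if (length(idx) == 0L) next
    base <- ifelse(sites$chrom[i] == "chrX" & male[idx], 1L, 2L)
    cn[i, idx] <- switch(sites$svtype[i],
      DEL = base - dosage[i, idx],
      DUP = base + dosage[i, idx],
      base)
  }
  cn
}
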