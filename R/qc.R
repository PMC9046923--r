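#' QC thresholds
#'
#' Filter thresholds mirroring the semantics of PLINK-style genotype QC:
#' markers are removed when MAF < `maf_min`, marker call rate <
#' `marker_call_rate_min`, or exact Hardy-Weinberg p-value < `hwe_p_min`;
#' samples are removed first when their call rate is below
#' `sample_call_rate_min` (if given).
#'
#' @param maf_min minimum minor allele frequency.
#' @param marker_call_rate_min minimum per-marker call rate.
#' @param hwe_p_min minimum exact-HWE p-value.
#' @param sample_call_rate_min minimum per-sample call rate, or `NULL` to
#'   skip sample filtering.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0, marker_call_rate_min = 0,
                          hwe_p_min = 0, sample_call_rate_min = NULL) {
  vals <- c(maf_min, marker_call_rate_min, hwe_p_min, sample_call_rate_min)
  if (any(vals < 0 | vals > 1)) stop("thresholds must be in [0, 1]")
  structure(list(maf_min = maf_min,
                 marker_call_rate_min = marker_call_rate_min,
                 hwe_p_min = hwe_p_min,
                 sample_call_rate_min = sample_call_rate_min),
            class = "qc_thresholds")
}

#' Preset QC thresholds for the panel tiers
#'
#' Named presets for the QC regimes applied to whole-genome sequence data
#' (`"wgs"`: MAF < 0.01, call rate < 0.80, HWE < 1e-8), imputed sequence data
#' (`"imputed_wgs"`: MAF < 0.05, HWE < 1e-8) and the low/mid-density SNP
#' panels (`"panel"`: MAF < 0.01, call rate < 0.70, HWE < 1e-6, sample call
#' rate < 0.70).
#'
#' @param name one of "wgs", "imputed_wgs", "panel".
#' @return A [qc_thresholds()] object.
#' @export
qc_preset <- function(name = c("wgs", "imputed_wgs", "panel")) {
  switch(match.arg(name),
    wgs = qc_thresholds(maf_min = 0.01, marker_call_rate_min = 0.80,
                        hwe_p_min = 1e-8),
    imputed_wgs = qc_thresholds(maf_min = 0.05, marker_call_rate_min = 0,
                                hwe_p_min = 1e-8),
    panel = qc_thresholds(maf_min = 0.01, marker_call_rate_min = 0.70,
                          hwe_p_min = 1e-6, sample_call_rate_min = 0.70)
  )
}

#' Per-marker minor allele frequency
#'
#' Computed over non-missing entries only. A monomorphic marker has MAF 0;
#' an all-missing marker gets `NA` (it is caught by the call-rate filter).
#'
#' @param geno a [genotypes()] object or allele-count matrix.
#' @return Named numeric vector in \[0, 0.5\].
#' @export
compute_maf <- function(geno) {
  g <- if (inherits(geno, "genotypes")) geno$geno else geno
  p <- colMeans(g, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA_real_
  pmin(p, 1 - p)
}

#' Per-marker and per-sample call rates
#'
#' @param geno a [genotypes()] object or allele-count matrix.
#' @return A list with `marker` and `sample` proportions of non-missing
#'   entries.
#' @export
call_rates <- function(geno) {
  g <- if (inherits(geno, "genotypes")) geno$geno else geno
  if (length(g) == 0) stop("empty genotype matrix")
  obs <- !is.na(g)
  list(marker = colMeans(obs), sample = rowMeans(obs))
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact test p-value obtained by enumerating every heterozygote count
#' compatible with the observed allele counts (conditional distribution of
#' heterozygotes given allele counts) and summing the probabilities of all
#' configurations no more probable than the observed one.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return p-value in (0, 1\].
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("negative genotype counts")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("need at least one genotyped sample")
  n_minor <- 2 * min(n_AA, n_aa) + n_Aa  # minor allele count
  # heterozygote counts share the parity of the minor allele count
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  if (length(hets) <= 1) return(1)
  # log P(het = h | allele counts) up to a constant:
  # n! / (n_AA! n_Aa! n_aa!) * 2^h  with homozygote counts implied by h
  logp <- vapply(hets, function(h) {
    hom_minor <- (n_minor - h) / 2
    hom_major <- n - h - hom_minor
    h * log(2) - lfactorial(h) - lfactorial(hom_minor) - lfactorial(hom_major)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- which(hets == n_Aa)
  min(1, sum(prob[prob <= prob[obs] * (1 + 1e-12)]))
}

#' Apply marker and sample quality control
#'
#' Samples failing `sample_call_rate_min` are removed first; markers are then
#' removed in the fixed attribution order MAF, call rate, HWE - a marker
#' failing several filters is counted once, at the first failing filter, so
#' the report's removal counts partition the removed markers. (Removal counts
#' therefore depend on this order; tools with a different internal order will
#' report different per-filter counts for the same final set.)
#'
#' @param geno a [genotypes()] object.
#' @param thresholds a [qc_thresholds()] object.
#' @return A list with `genotypes` (filtered) and `report`, a one-row tibble
#'   with columns `initial_samples`, `initial_snps`, `removed_by_maf`,
#'   `removed_by_call_rate`, `removed_by_hwe`, `final_samples`, `final_snps`.
#' @export
apply_qc <- function(geno, thresholds) {
  stopifnot(inherits(geno, "genotypes"), inherits(thresholds, "qc_thresholds"))
  g <- geno$geno
  init_samples <- nrow(g)
  init_snps <- ncol(g)

  if (!is.null(thresholds$sample_call_rate_min)) {
    sr <- rowMeans(!is.na(g))
    keep <- sr >= thresholds$sample_call_rate_min
    g <- g[keep, , drop = FALSE]
  }
  if (nrow(g) == 0) stop("all samples removed by sample call-rate filter")

  maf <- compute_maf(g)
  cr <- colMeans(!is.na(g))
  fail_maf <- !is.na(maf) & maf < thresholds$maf_min
  fail_cr <- !fail_maf & (cr < thresholds$marker_call_rate_min | is.na(maf))
  hwe_p <- rep(NA_real_, ncol(g))
  cand <- which(!fail_maf & !fail_cr)
  if (thresholds$hwe_p_min > 0 && length(cand) > 0) {
    hwe_p[cand] <- vapply(cand, function(j) {
      x <- g[, j]
      x <- x[!is.na(x) & x %in% c(0, 1, 2)]
      if (length(x) == 0) return(1)
      hwe_test(sum(x == 0), sum(x == 1), sum(x == 2))
    }, numeric(1))
  }
  fail_hwe <- !fail_maf & !fail_cr & !is.na(hwe_p) & hwe_p < thresholds$hwe_p_min

  keep <- !(fail_maf | fail_cr | fail_hwe)
  if (!any(keep)) warning("all markers removed by QC")
  out <- genotypes(g[, keep, drop = FALSE], geno$map[keep, , drop = FALSE])
  for (a in c("chrom_lengths", "chrom_morgans")) {
    attr(out$map, a) <- attr(geno$map, a)
  }
  report <- tibble::tibble(
    initial_samples = init_samples,
    initial_snps = init_snps,
    removed_by_maf = sum(fail_maf),
    removed_by_call_rate = sum(fail_cr),
    removed_by_hwe = sum(fail_hwe),
    final_samples = nrow(g),
    final_snps = sum(keep)
  )
  list(genotypes = out, report = report)
}
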