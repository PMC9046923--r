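#' Back-solve SNP effects from genomic breeding values
#'
#' Recovers allele-substitution effects from the GEBV of genotyped animals:
#' `a_hat = D Mc' G^-1 u_hat / k` with `k = 2 sum_j p_j (1 - p_j) w_j`, where
#' `Mc`, the frequencies and `k` are those the (unblended, weighted) `G` was
#' built with. When `G` is invertible the round trip `Mc a_hat = u_hat` is
#' exact; a singular `G` falls back to the Moore-Penrose pseudo-inverse with a
#' warning (the round trip then holds in the projected space).
#'
#' @param gebv named numeric vector of breeding values for the genotyped
#'   animals (names = ids), or a tibble with columns `id`, `ebv`.
#' @param geno the [genotypes()] object `G` was built from.
#' @param weights the per-marker weights used to build `G` (default all 1).
#' @param G_unblended the unblended weighted [build_G()] matrix.
#' @return A SNP-effect tibble: `marker`, `chrom`, `pos`, `freq`, `effect`,
#'   `weight`.
#' @export
backsolve_snp_effects <- function(gebv, geno, weights = NULL, G_unblended) {
  stopifnot(inherits(geno, "genotypes"))
  if (is.data.frame(gebv)) gebv <- setNames(gebv$ebv, gebv$id)
  markers <- attr(G_unblended, "markers")
  p <- attr(G_unblended, "freq")
  k <- attr(G_unblended, "scale")
  if (is.null(markers) || is.null(p) || is.null(k)) {
    stop("G_unblended must come from build_G() (freq/scale attributes missing)")
  }
  if (is.null(weights)) weights <- setNames(rep(1, ncol(geno$geno)),
                                            colnames(geno$geno))
  if (is.null(names(weights))) names(weights) <- colnames(geno$geno)
  w <- weights[markers]
  ids <- rownames(G_unblended)
  u <- gebv[ids]
  if (anyNA(u)) stop("gebv missing for some genotyped animals")
  g <- geno$geno[ids, markers, drop = FALSE]
  if (anyNA(g)) {
    na_idx <- which(is.na(g), arr.ind = TRUE)
    g[na_idx] <- 2 * p[na_idx[, 2]]
  }
  Mc <- sweep(g, 2, 2 * p)
  Ginv_u <- tryCatch(solve(G_unblended, u), error = function(e) NULL)
  if (is.null(Ginv_u)) {
    warning("unblended G is singular; using pseudo-inverse for the backsolve")
    sv <- svd(G_unblended)
    pos <- sv$d > max(sv$d) * 1e-10
    Ginv_u <- sv$v[, pos] %*% ((crossprod(sv$u[, pos], u)) / sv$d[pos])
  }
  a_hat <- drop(w * crossprod(Mc, Ginv_u)) / k
  map <- geno$map[match(markers, geno$map$marker), ]
  tibble::tibble(marker = markers, chrom = map$chrom, pos = map$pos,
                 freq = unname(p), effect = unname(a_hat),
                 weight = unname(w))
}

#' Percentage of additive genetic variance per SNP
#'
#' `pct_j = 100 * 2 p_j (1 - p_j) a_hat_j^2 / sigma2_a`.
#'
#' @param effects SNP-effect tibble from [backsolve_snp_effects()] (needs
#'   `freq` and `effect`).
#' @param sigma2_a additive genetic variance (> 0), typically the REML
#'   estimate of the model the effects came from.
#' @return The tibble with a `pct_var` column appended.
#' @export
snp_variance_explained <- function(effects, sigma2_a) {
  if (sigma2_a <= 0) stop("sigma2_a must be positive")
  dplyr::mutate(effects,
                pct_var = 100 * 2 * .data$freq * (1 - .data$freq) *
                  .data$effect^2 / sigma2_a)
}

#' Update SNP weights from estimated effects
#'
#' Raw weights are the per-marker variances `2 p (1 - p) a_hat^2`, floored at
#' `1e-8` of their mean (so one iteration cannot permanently zero a marker)
#' and normalized to mean 1 (keeping the sigma2_a interpretation stable
#' across iterations).
#'
#' @param effects SNP-effect tibble with `marker`, `freq`, `effect`.
#' @return Named numeric weight vector with mean 1.
#' @export
update_weights <- function(effects) {
  raw <- 2 * effects$freq * (1 - effects$freq) * effects$effect^2
  m <- mean(raw)
  if (m == 0) {
    warning("all SNP effects are zero; weights reset to 1")
    return(setNames(rep(1, nrow(effects)), effects$marker))
  }
  raw <- pmax(raw, 1e-8 * m)
  setNames(raw / mean(raw), effects$marker)
}

#' Weighted single-step GBLUP GWAS
#'
#' Iterative wssGBLUP: iteration 1 fits the animal model with all marker
#' weights 1 (plain single-step GBLUP), back-solves SNP effects from the
#' genotyped animals' GEBV, and converts effects to per-marker weights;
#' iteration 2 refits with the weighted `G` and re-backsolves. The final SNP
#' effect table is the last iteration's (two iterations by default). The
#' model fit uses a blended `G` (for invertibility of the H-inverse block);
#' the backsolve deliberately uses the unblended weighted `G` so the
#' round-trip identity `Mc a_hat = u_hat` is exact.
#'
#' @param geno post-QC [genotypes()] object (genotyped animals).
#' @param phenotypes phenotype tibble (`id`, trait, fixed effects,
#'   covariates).
#' @param pedigree pedigree tibble (all animals, topologically ordered).
#' @param spec a [model_spec()].
#' @param n_iterations number of wssGBLUP iterations (1 = ssGBLUP).
#' @param alpha blending proportion of A22 in G (see [blend_G()]).
#' @return A list of class `wssgblup_fit` with elements `iterations` (one
#'   SNP-effect tibble per iteration, each with `pct_var` and an `iteration`
#'   column), `effects` (final iteration), `vc` (list of [reml_estimate()]
#'   fits), `solutions` (final [solve_mme()] solutions).
#' @export
run_wssgblup <- function(geno, phenotypes, pedigree, spec = model_spec(),
                         n_iterations = 2, alpha = 0.05) {
  stopifnot(inherits(geno, "genotypes"), n_iterations >= 1)
  ids_all <- as.character(pedigree$id)
  genotyped <- rownames(geno$geno)
  A <- build_A(pedigree)
  A_inv <- build_A_inverse(pedigree)
  A22 <- extract_A22(A, genotyped)
  A22_inv <- kinship_inverse(A22)
  des <- build_design(phenotypes, spec, ids_all)

  w <- setNames(rep(1, ncol(geno$geno)), colnames(geno$geno))
  iterations <- vector("list", n_iterations)
  vcs <- vector("list", n_iterations)
  sol <- NULL
  for (it in seq_len(n_iterations)) {
    Gw <- build_G(geno, unname(w))
    Gb <- blend_G(Gw, A22, alpha)
    Gb_inv <- kinship_inverse(Gb)
    H_inv <- build_H_inverse(A_inv, A22_inv, Gb_inv, genotyped)
    H <- kinship_inverse(H_inv)
    vc <- reml_estimate(des$y, des$X, des$Z, H)
    if (!vc$converged && vc$sigma2_a <= 1e-8 * var(des$y)) {
      stop("REML failed at wssGBLUP iteration ", it,
           " (additive variance collapsed)")
    }
    sol <- solve_mme(des$y, des$X, des$Z, H_inv, vc)
    u_g <- setNames(sol$ebv$ebv, sol$ebv$id)[genotyped]
    eff <- backsolve_snp_effects(u_g, geno, w, Gw)
    eff <- snp_variance_explained(eff, vc$sigma2_a)
    eff$iteration <- it
    iterations[[it]] <- eff
    vcs[[it]] <- vc
    if (it < n_iterations) {
      wn <- update_weights(eff)
      w[names(wn)] <- wn  # markers excluded from G keep their old weight
    }
  }
  structure(list(iterations = iterations,
                 effects = iterations[[n_iterations]],
                 vc = vcs, solutions = sol),
            class = "wssgblup_fit")
}

#' @export
print.wssgblup_fit <- function(x, ...) {
  cat(sprintf("<wssgblup_fit> %d iteration(s), %d markers; final h2 = %.3f\n",
              length(x$iterations), nrow(x$effects),
              x$vc[[length(x$vc)]]$h2))
  invisible(x)
}

#' @export
tidy.wssgblup_fit <- function(x, iteration = length(x$iterations), ...) {
  x$iterations[[iteration]]
}

#' @export
glance.wssgblup_fit <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$vc), function(i) {
    dplyr::mutate(glance(x$vc[[i]]), iteration = i, .before = 1)
  }))
}

#' Select lead SNPs by variance explained
#'
#' Orders markers by decreasing `pct_var` (ties broken by ascending
#' chromosome then position - a stable total order) and keeps the top `k`,
#' attaching the 100 kb up/downstream candidate-gene window clipped at
#' chromosome bounds.
#'
#' @param effects SNP-effect tibble with `marker`, `chrom`, `pos`,
#'   `pct_var`.
#' @param k number of lead SNPs (k > markers returns all).
#' @param window_bp flanking distance on each side (default 100 kb).
#' @param chrom_lengths optional named vector of chromosome lengths for
#'   clipping the upper window bound.
#' @return Tibble of the `k` leads with `window_start`, `window_end`.
#' @export
select_lead_snps <- function(effects, k = 5, window_bp = 1e5,
                             chrom_lengths = NULL) {
  if (nrow(effects) == 0) stop("empty SNP effect table")
  if (k < 1) stop("k must be >= 1")
  out <- effects %>%
    dplyr::arrange(dplyr::desc(.data$pct_var), .data$chrom, .data$pos) %>%
    head(min(k, nrow(effects))) %>%
    dplyr::mutate(window_start = pmax(1, .data$pos - window_bp),
                  window_end = .data$pos + window_bp)
  if (!is.null(chrom_lengths)) {
    len <- unname(chrom_lengths[out$chrom])
    out$window_end <- ifelse(is.na(len), out$window_end,
                             pmin(out$window_end, len))
  }
  out
}

#' Candidate genes in lead-SNP windows
#'
#' Intersects each lead SNP's flanking window with gene intervals (1-based,
#' closed): a gene overlaps when its interval touches the window, boundary
#' included. Genes containing the SNP itself are flagged `in_gene`
#' (exon/intron resolution is out of scope).
#'
#' @param leads tibble from [select_lead_snps()].
#' @param annotation tibble with columns `chrom`, `start`, `end`, `gene`
#'   (see [read_annotation()]).
#' @return One row per lead-gene overlap (leads without genes keep one row
#'   with `gene = NA`), with a logical `in_gene` column.
#' @export
gene_window_lookup <- function(leads, annotation) {
  stopifnot(all(c("chrom", "start", "end", "gene") %in% names(annotation)))
  if (length(intersect(unique(leads$chrom), unique(annotation$chrom))) == 0) {
    stop("annotation chromosome names match no lead-SNP chromosomes; ",
         "annotation has: ",
         paste(head(unique(annotation$chrom), 5), collapse = ", "),
         " vs leads: ",
         paste(head(unique(leads$chrom), 5), collapse = ", "))
  }
  hits <- leads %>%
    dplyr::left_join(annotation, by = "chrom",
                     relationship = "many-to-many") %>%
    dplyr::filter(is.na(.data$gene) |
                    (.data$start <= .data$window_end &
                       .data$end >= .data$window_start))
  # keep leads with no overlapping gene as single NA-gene rows
  no_hit <- dplyr::anti_join(leads, hits, by = "marker")
  if (nrow(no_hit) > 0) {
    no_hit$gene <- NA_character_
    no_hit$start <- NA_real_
    no_hit$end <- NA_real_
    hits <- dplyr::bind_rows(hits, no_hit)
  }
  hits %>%
    dplyr::mutate(in_gene = !is.na(.data$gene) &
                    .data$pos >= .data$start & .data$pos <= .data$end) %>%
    dplyr::rename(gene_start = "start", gene_end = "end") %>%
    dplyr::arrange(dplyr::desc(.data$pct_var), .data$chrom, .data$pos)
}
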