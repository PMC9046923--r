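#' LD pruning of a marker set
#'
#' Greedy sliding-window pruning: within each window of `window_bp`
#' (advanced `step` markers at a time along each chromosome), while any
#' surviving pair of markers has squared genotype correlation above
#' `r2_max`, the member with the lower MAF is removed (ties: the later
#' position). Deterministic given the input.
#'
#' @param geno a [genotypes()] object with markers sorted by (chrom, pos).
#' @param window_bp window size in bp (default 40 kb).
#' @param step window advance in markers (default 1).
#' @param r2_max maximum tolerated r-squared; a single value or a named
#'   per-chromosome vector.
#' @return Character vector of surviving marker ids.
#' @export
ld_prune <- function(geno, window_bp = 4e4, step = 1, r2_max = 0.5) {
  stopifnot(inherits(geno, "genotypes"))
  if (window_bp <= 0 || step < 1) stop("prune parameters must be positive")
  map <- geno$map
  if (is.unsorted(order(map$chrom, map$pos)) ||
      any(unlist(tapply(map$pos, map$chrom, is.unsorted)))) {
    stop("marker map must be sorted by (chrom, pos)")
  }
  g <- geno$geno
  maf <- compute_maf(g)
  keep <- rep(TRUE, ncol(g))
  # mean-impute once for correlation computation
  if (anyNA(g)) {
    p <- colMeans(g, na.rm = TRUE)
    na_idx <- which(is.na(g), arr.ind = TRUE)
    g[na_idx] <- p[na_idx[, 2]]
  }
  for (cc in unique(map$chrom)) {
    idx <- which(map$chrom == cc)
    thr <- if (length(r2_max) > 1) r2_max[[cc]] else r2_max
    s <- 1
    while (s <= length(idx)) {
      j0 <- idx[s]
      win <- idx[map$pos[idx] >= map$pos[j0] &
                   map$pos[idx] <= map$pos[j0] + window_bp]
      alive <- win[keep[win]]
      if (length(alive) > 1) {
        r2 <- suppressWarnings(cor(g[, alive, drop = FALSE]))^2
        diag(r2) <- 0
        r2[is.na(r2)] <- 0
        while (any(r2 > thr)) {
          hit <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
          pair <- alive[hit]
          drop_one <- if (maf[pair[1]] < maf[pair[2]]) 1L
                      else if (maf[pair[2]] < maf[pair[1]]) 2L
                      else which.max(map$pos[pair])
          gone <- pair[drop_one]
          keep[gone] <- FALSE
          at <- which(alive == gone)
          r2[at, ] <- 0
          r2[, at] <- 0
        }
      }
      s <- s + step
    }
  }
  map$marker[keep]
}

#' Repeated k-fold cross-validation scheme
#'
#' Within each repetition animals are partitioned into `n_folds` near-equal
#' folds (sizes differ by at most one). Repetitions use distinct seeds
#' derived from the master seed by fixed offsets.
#'
#' @param ids animal ids.
#' @param n_folds folds per repetition (>= 2).
#' @param n_repetitions number of repetitions.
#' @param seed master seed.
#' @return Tibble with columns `rep`, `fold`, `id`.
#' @export
make_cv_scheme <- function(ids, n_folds = 5, n_repetitions = 5, seed = 1L) {
  ids <- as.character(ids)
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (n_folds > length(ids)) stop("more folds than animals")
  purrr::map_dfr(seq_len(n_repetitions), function(r) {
    set.seed(seed + 1000L * r)
    fold <- sample(rep_len(seq_len(n_folds), length(ids)))
    tibble::tibble(rep = r, fold = fold, id = ids)
  })
}

#' Preselect top SNPs by GWAS within the training set
#'
#' Runs the wssGBLUP GWAS using only training-fold phenotypes (validation
#' phenotypes are excluded before any fitting, so selection cannot leak
#' validation information) and returns the `k` markers explaining the most
#' genetic variance, ranked with the [select_lead_snps()] ordering.
#'
#' @param geno [genotypes()] for all genotyped animals.
#' @param train_phenotypes phenotype tibble restricted to training animals.
#' @param pedigree full pedigree.
#' @param k number of markers to keep; `k >=` markers returns all with a
#'   warning.
#' @param spec a [model_spec()].
#' @param n_iterations wssGBLUP iterations for the selection GWAS.
#' @param alpha blending proportion.
#' @return Character vector of selected marker ids.
#' @export
preselect_top_snps <- function(geno, train_phenotypes, pedigree, k,
                               spec = model_spec(), n_iterations = 2,
                               alpha = 0.05) {
  m <- ncol(geno$geno)
  if (k >= m) {
    if (k > m) warning("k exceeds available markers; returning all")
    return(colnames(geno$geno))
  }
  fit <- run_wssgblup(geno, train_phenotypes, pedigree, spec,
                      n_iterations = n_iterations, alpha = alpha)
  select_lead_snps(fit$effects, k = k)$marker
}

#' Prediction accuracy from validation correlation
#'
#' `accuracy = r / sqrt(h2)`: the correlation between (G)EBV and phenotype in
#' the validation set, rescaled by the square root of heritability. May
#' exceed 1 in small samples; reported as-is.
#'
#' @param r correlation between predictions and phenotypes.
#' @param h2 heritability in (0, 1].
#' @return The accuracy.
#' @export
accuracy <- function(r, h2) {
  if (any(h2 <= 0)) stop("h2 must be positive")
  r / sqrt(h2)
}

#' Evaluate one cross-validation split
#'
#' Masks the validation animals' phenotypes, fits REML and the mixed-model
#' equations on the training records (with the relationship matrix spanning
#' all animals, so validation animals are predicted through kinship), and
#' returns the Pearson correlation between validation (G)EBV and validation
#' phenotypes pre-adjusted for the training-estimated fixed effects and
#' covariates.
#'
#' @param phenotypes full phenotype tibble.
#' @param validation_ids animal ids whose phenotypes are masked.
#' @param K relationship matrix over all animals (A for PBLUP, G or H for
#'   genomic methods).
#' @param spec a [model_spec()].
#' @param vc optional pre-estimated variance components; when `NULL`, REML is
#'   run on the training records.
#' @return A list with `r` (validation correlation), `vc`, `solutions`.
#' @export
evaluate_split <- function(phenotypes, validation_ids, K,
                           spec = model_spec(), vc = NULL) {
  validation_ids <- as.character(validation_ids)
  ids_all <- rownames(K)
  train <- phenotypes[!as.character(phenotypes$id) %in% validation_ids, ]
  val <- phenotypes[as.character(phenotypes$id) %in% validation_ids, ]
  if (nrow(train) == 0 || nrow(val) == 0) {
    stop("both training and validation sets must be non-empty")
  }
  des <- build_design(train, spec, ids_all)
  if (is.null(vc)) vc <- reml_estimate(des$y, des$X, des$Z, K)
  if (vc$sigma2_a <= 1e-6 * var(des$y)) {
    # additive variance collapsed: all breeding values shrink to zero
    warning("zero-variance predictions (sigma2_a ~ 0); correlation set to 0")
    return(list(r = 0, vc = vc, solutions = NULL))
  }
  K_inv <- kinship_inverse(K)
  sol <- solve_mme(des$y, des$X, des$Z, K_inv, vc)
  # adjust validation phenotypes by training-estimated fixed effects
  des_val <- build_design(val, spec, ids_all)
  bmap <- match(colnames(des_val$X), colnames(des$X))
  if (anyNA(bmap)) stop("validation design has levels unseen in training")
  beta <- setNames(sol$fixed$estimate, sol$fixed$term)[colnames(des$X)]
  y_adj <- des_val$y - drop(des_val$X %*% beta[colnames(des_val$X)])
  pred <- setNames(sol$ebv$ebv, sol$ebv$id)[as.character(des_val$data$id)]
  if (sd(pred) == 0 || sd(y_adj) == 0) {
    warning("zero-variance predictions or phenotypes; correlation set to 0")
    r <- 0
  } else {
    r <- cor(pred, y_adj)
  }
  list(r = r, vc = vc, solutions = sol)
}

#' Cross-validated genomic-prediction comparison across marker scenarios
#'
#' Runs the marker-density experiment: for each repetition x fold split,
#' evaluates pedigree BLUP and GBLUP under each scenario - all markers
#' (`"wgs"`), an LD-pruned subset (`"pruned"`), and GWAS-preselected top-k
#' subsets (`"top_k"`, selection re-done within every training fold with
#' validation phenotypes masked). Accuracy divides each validation
#' correlation by the square root of the full-data heritability of the
#' matching method: the pedigree h2 for PBLUP and the full-density genomic
#' h2 for every GBLUP scenario. A single denominator per method keeps
#' scenario accuracies comparable; re-estimating h2 from a preselected
#' marker subset would inflate the denominator by the selection itself.
#'
#' @param geno post-QC [genotypes()] of the genotyped animals.
#' @param phenotypes phenotype tibble for the genotyped animals.
#' @param pedigree full pedigree.
#' @param scenarios list of scenario descriptions; each is a list with
#'   `name`, and for `top_k` scenarios `k` (plus optional `n_iterations`),
#'   for `pruned` optional `window_bp`, `step`, `r2_max`.
#' @param spec a [model_spec()].
#' @param n_folds,n_repetitions,seed cross-validation layout.
#' @param alpha blending proportion for genomic matrices.
#' @return A list of class `cv_result`: `splits` (tibble `rep`, `fold`,
#'   `scenario`, `method`, `r`, `accuracy`), `h2` (per scenario), `markers`
#'   (selected marker ids per scenario/split, for audit), `scheme`.
#' @export
run_prediction_cv <- function(geno, phenotypes, pedigree,
                              scenarios = list(list(name = "wgs")),
                              spec = model_spec(),
                              n_folds = 5, n_repetitions = 5, seed = 1L,
                              alpha = 0.05) {
  genotyped <- rownames(geno$geno)
  # prediction models are fitted/validated on the genotyped cohort; the
  # preselection GWAS is single-step and uses every phenotyped animal
  # (genotyped or not), with validation-fold phenotypes masked
  ph_gwas <- phenotypes
  ph <- phenotypes[as.character(phenotypes$id) %in% genotyped, ]
  scheme <- make_cv_scheme(intersect(genotyped, as.character(ph$id)),
                           n_folds, n_repetitions, seed)
  A <- build_A(pedigree)
  A_g <- extract_A22(A, genotyped)

  # full-data h2 per method/scenario (Eq-4 denominators)
  des_full <- build_design(ph, spec, genotyped)
  h2_tab <- list()
  vc_p <- reml_estimate(des_full$y, des_full$X, des_full$Z, A_g)
  h2_tab[["PBLUP"]] <- vc_p$h2

  # one genomic h2 denominator, from the full-density G
  G_full <- blend_G(build_G(geno), A_g, alpha)
  h2_genomic <- reml_estimate(des_full$y, des_full$X, des_full$Z, G_full)$h2

  scen_G <- list()
  static_markers <- list()
  for (sc in scenarios) {
    if (sc$name == "pruned") {
      kept <- ld_prune(geno,
                       window_bp = sc$window_bp %||% 4e4,
                       step = sc$step %||% 1,
                       r2_max = sc$r2_max %||% 0.5)
      static_markers[[sc$name]] <- kept
      Gs <- blend_G(build_G(subset_genotypes(geno, markers = kept)),
                    A_g, alpha)
    } else if (sc$name == "wgs") {
      static_markers[[sc$name]] <- colnames(geno$geno)
      Gs <- G_full
    } else {
      h2_tab[[sc$name]] <- h2_genomic
      next  # top_k scenarios build per-split G
    }
    scen_G[[sc$name]] <- Gs
    h2_tab[[sc$name]] <- h2_genomic
  }

  audit <- list()
  rows <- list()
  for (r_i in seq_len(n_repetitions)) {
    for (f_i in seq_len(n_folds)) {
      val_ids <- scheme$id[scheme$rep == r_i & scheme$fold == f_i]
      train_ph <- ph_gwas[!as.character(ph_gwas$id) %in% val_ids, ]
      ev <- evaluate_split(ph, val_ids, A_g, spec)
      rows[[length(rows) + 1]] <- tibble::tibble(
        rep = r_i, fold = f_i, scenario = "PBLUP", method = "PBLUP",
        r = ev$r, accuracy = accuracy(ev$r, h2_tab[["PBLUP"]]))
      for (sc in scenarios) {
        if (sc$name %in% names(scen_G)) {
          Gs <- scen_G[[sc$name]]
          h2_s <- h2_tab[[sc$name]]
        } else {
          k <- sc$k
          sel <- preselect_top_snps(geno, train_ph, pedigree, k, spec,
                                    n_iterations = sc$n_iterations %||% 2,
                                    alpha = alpha)
          audit[[paste(sc$name, r_i, f_i, sep = "_")]] <- sel
          Gs <- blend_G(build_G(subset_genotypes(geno, markers = sel)),
                        A_g, alpha)
          h2_s <- h2_tab[[sc$name]]
        }
        ev_s <- evaluate_split(ph, val_ids, Gs, spec)
        rows[[length(rows) + 1]] <- tibble::tibble(
          rep = r_i, fold = f_i, scenario = sc$name, method = "GBLUP",
          r = ev_s$r, accuracy = accuracy(ev_s$r, h2_s))
      }
    }
  }
  structure(list(splits = dplyr::bind_rows(rows),
                 h2 = tibble::tibble(scenario = names(h2_tab),
                                     h2 = unlist(h2_tab)),
                 markers = c(lapply(static_markers, identity), audit),
                 scheme = scheme),
            class = "cv_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cv_result <- function(x, ...) {
  print(compare_scenarios(x))
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) x$splits

#' Summarize scenario accuracies against the pedigree baseline
#'
#' Means and SDs over splits (both pooled over all splits and averaging
#' folds within repetition first), plus the relative accuracy gain
#' `100 (acc - acc_PBLUP) / acc_PBLUP`.
#'
#' @param result a `cv_result` from [run_prediction_cv()] or its `splits`
#'   tibble.
#' @return Tibble: `scenario`, `method`, `mean_r`, `mean_accuracy`,
#'   `sd_accuracy`, `mean_accuracy_by_rep`, `relative_gain_pct`.
#' @export
compare_scenarios <- function(result) {
  splits <- if (inherits(result, "cv_result")) result$splits else result
  if (!"PBLUP" %in% splits$scenario) stop("PBLUP baseline missing")
  by_rep <- splits %>%
    dplyr::group_by(.data$scenario, .data$method, .data$rep) %>%
    dplyr::summarise(acc = mean(.data$accuracy), .groups = "drop") %>%
    dplyr::group_by(.data$scenario, .data$method) %>%
    dplyr::summarise(mean_accuracy_by_rep = mean(.data$acc), .groups = "drop")
  out <- splits %>%
    dplyr::group_by(.data$scenario, .data$method) %>%
    dplyr::summarise(mean_r = mean(.data$r),
                     mean_accuracy = mean(.data$accuracy),
                     sd_accuracy = sd(.data$accuracy), .groups = "drop") %>%
    dplyr::left_join(by_rep, by = c("scenario", "method"))
  base <- out$mean_accuracy[out$scenario == "PBLUP"]
  out$relative_gain_pct <- 100 * (out$mean_accuracy - base) / base
  out
}
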