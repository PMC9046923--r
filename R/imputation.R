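#' Masking cross-validation scheme for imputation accuracy
#'
#' Splits the fully genotyped panel animals into `n_folds` validation sets;
#' within a fold the validation animals keep only the low-density markers
#' (everything else masked) while the remaining animals serve as the
#' full-density reference.
#'
#' @param panel a full-density [genotypes()] object.
#' @param lowdensity_markers marker ids retained on the low-density chip.
#' @param n_folds number of folds.
#' @param seed seed for the random fold assignment.
#' @return A list of class `mask_scheme`: `folds` (tibble `fold`, `id`),
#'   `lowdensity_markers`, `panel_markers`.
#' @export
make_mask_cv <- function(panel, lowdensity_markers, n_folds = 5, seed = 1L) {
  stopifnot(inherits(panel, "genotypes"))
  bad <- setdiff(lowdensity_markers, colnames(panel$geno))
  if (length(bad) > 0) {
    stop("low-density markers absent from panel: ",
         paste(head(bad, 5), collapse = ", "))
  }
  ids <- rownames(panel$geno)
  if (n_folds > length(ids)) stop("a fold would have no validation animals")
  set.seed(seed)
  fold <- sample(rep_len(seq_len(n_folds), length(ids)))
  structure(list(folds = tibble::tibble(fold = fold, id = ids),
                 lowdensity_markers = lowdensity_markers,
                 panel_markers = colnames(panel$geno)),
            class = "mask_scheme")
}

#' Apply one fold's masking
#'
#' @param panel full-density [genotypes()].
#' @param scheme a [make_mask_cv()] scheme.
#' @param fold fold index.
#' @return List with `masked` (all animals; validation animals keep only
#'   low-density markers), `reference` (full-density non-validation animals),
#'   `validation_ids`, and `masked_entries` (logical matrix of entries that
#'   were knocked out).
#' @export
mask_fold <- function(panel, scheme, fold) {
  stopifnot(inherits(scheme, "mask_scheme"))
  val_ids <- scheme$folds$id[scheme$folds$fold == fold]
  if (length(val_ids) == 0) stop("fold ", fold, " has no validation animals")
  g <- panel$geno
  masked_entries <- matrix(FALSE, nrow(g), ncol(g), dimnames = dimnames(g))
  hi <- !(colnames(g) %in% scheme$lowdensity_markers)
  masked_entries[val_ids, hi] <- !is.na(g[val_ids, hi])
  g[masked_entries] <- NA_real_
  list(masked = genotypes(g, panel$map),
       reference = subset_genotypes(panel, ids = setdiff(rownames(g), val_ids)),
       validation_ids = val_ids,
       masked_entries = masked_entries)
}

#' Naive family-and-frequency imputer
#'
#' A documented baseline imputer defining the harness interface: each missing
#' entry is filled with the Mendelian-certain genotype when both parents'
#' genotypes at the marker are known (among observed/reference animals) and
#' jointly determine the offspring (0x0 -> 0, 2x2 -> 2, 0x2 -> 1); otherwise
#' with the reference-panel mean allele dosage `2p` (possibly non-integer).
#' Observed entries are never altered.
#'
#' @param masked [genotypes()] with missing entries to fill.
#' @param reference full-density [genotypes()] of reference animals.
#' @param pedigree pedigree tibble (for the Mendelian rule); `NULL` skips it.
#' @return A [genotypes()] object with no missing entries at markers present
#'   in the reference.
#' @export
naive_impute <- function(masked, reference, pedigree = NULL) {
  stopifnot(inherits(masked, "genotypes"), inherits(reference, "genotypes"))
  absent <- setdiff(colnames(masked$geno), colnames(reference$geno))
  if (length(absent) > 0) {
    stop("markers absent from reference: ",
         paste(head(absent, 5), collapse = ", "))
  }
  g <- masked$geno
  markers <- colnames(g)
  ref <- reference$geno[, markers, drop = FALSE]
  p_ref <- colMeans(ref, na.rm = TRUE) / 2
  p_ref[is.nan(p_ref)] <- 0.5

  na_idx <- which(is.na(g), arr.ind = TRUE)
  fill <- p_ref[na_idx[, 2]] * 2
  if (!is.null(pedigree) && nrow(na_idx) > 0) {
    # observed genotypes across masked + reference animals, by id
    all_ids <- union(rownames(g), rownames(ref))
    O <- matrix(NA_real_, length(all_ids), length(markers),
                dimnames = list(all_ids, markers))
    O[rownames(ref), ] <- ref
    tmp <- O[rownames(g), , drop = FALSE]
    obs <- !is.na(g)
    tmp[obs] <- g[obs]
    O[rownames(g), ] <- tmp
    pid <- as.character(pedigree$id)
    norm <- function(x) {
      x <- as.character(x); x[x %in% c("0", "", "NA")] <- NA_character_; x
    }
    sire_of <- setNames(norm(pedigree$sire), pid)
    dam_of <- setNames(norm(pedigree$dam), pid)
    ids_here <- rownames(g)[na_idx[, 1]]
    s_row <- match(sire_of[ids_here], all_ids)
    d_row <- match(dam_of[ids_here], all_ids)
    ok <- !is.na(s_row) & !is.na(d_row)
    gs <- gd <- rep(NA_real_, nrow(na_idx))
    gs[ok] <- O[cbind(s_row[ok], na_idx[ok, 2])]
    gd[ok] <- O[cbind(d_row[ok], na_idx[ok, 2])]
    det <- !is.na(gs) & !is.na(gd) & (gs %in% c(0, 2)) & (gd %in% c(0, 2))
    fill[det] <- (gs[det] + gd[det]) / 2
  }
  g[na_idx] <- fill
  genotypes(g, masked$map)
}

#' Imputation accuracy (per-marker squared correlation)
#'
#' For each marker, the squared Pearson correlation between true and imputed
#' allele counts over the masked entries only. Markers with zero variance in
#' either vector get r2 = 0 by convention; markers with no masked entries are
#' skipped (with a note in the output).
#'
#' @param true,imputed [genotypes()] objects of identical dimensions.
#' @param masked_entries logical matrix marking the masked entries (from
#'   [mask_fold()]).
#' @return A list of class `imputation_accuracy`: `per_marker` (tibble
#'   `marker`, `n_masked`, `r2`), `mean_r2` (over markers with masked
#'   entries), `n_skipped`.
#' @export
imputation_r2 <- function(true, imputed, masked_entries) {
  gt <- if (inherits(true, "genotypes")) true$geno else true
  gi <- if (inherits(imputed, "genotypes")) imputed$geno else imputed
  if (!identical(dim(gt), dim(gi)) || !identical(dim(gt), dim(masked_entries))) {
    stop("true, imputed and masked_entries must have identical dimensions")
  }
  m <- ncol(gt)
  r2 <- rep(NA_real_, m)
  n_masked <- colSums(masked_entries)
  for (j in which(n_masked > 0)) {
    sel <- masked_entries[, j]
    x <- gt[sel, j]
    y <- gi[sel, j]
    if (length(x) < 2 || sd(x) == 0 || sd(y) == 0 || anyNA(x)) {
      r2[j] <- 0
    } else {
      r2[j] <- cor(x, y)^2
    }
  }
  per_marker <- tibble::tibble(marker = colnames(gt),
                               n_masked = unname(n_masked), r2 = r2)
  structure(list(per_marker = per_marker,
                 mean_r2 = mean(r2[n_masked > 0]),
                 n_skipped = sum(n_masked == 0)),
            class = "imputation_accuracy")
}

#' @export
print.imputation_accuracy <- function(x, ...) {
  cat(sprintf("<imputation_accuracy> mean r2 = %.3f over %d markers (%d skipped)\n",
              x$mean_r2, sum(x$per_marker$n_masked > 0), x$n_skipped))
  invisible(x)
}

#' @export
tidy.imputation_accuracy <- function(x, ...) x$per_marker

#' Filter markers by imputation accuracy
#'
#' Strictly-greater-than threshold on per-marker r2.
#'
#' @param acc an [imputation_r2()] result.
#' @param threshold retain markers with `r2 > threshold`.
#' @return Character vector of retained marker ids.
#' @export
filter_by_r2 <- function(acc, threshold = 0.8) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  pm <- acc$per_marker
  pm$marker[!is.na(pm$r2) & pm$r2 > threshold]
}

#' Run the masking cross-validation and summarize imputation accuracy
#'
#' For each fold, masks the validation animals down to the low-density chip,
#' imputes with `imputer`, and pools the masked entries over folds (each
#' animal is validation exactly once) before computing per-marker r2.
#'
#' @param panel full-density [genotypes()].
#' @param lowdensity_markers marker ids of the low-density chip.
#' @param pedigree pedigree (passed to the imputer).
#' @param n_folds,seed cross-validation layout.
#' @param imputer function `(masked, reference, pedigree) -> genotypes`;
#'   default [naive_impute()].
#' @param r2_threshold retention threshold for the summary.
#' @return A list: `accuracy` ([imputation_r2()] result over pooled masked
#'   entries), `retained` (markers with r2 > threshold), `scheme`.
#' @export
run_imputation_cv <- function(panel, lowdensity_markers, pedigree = NULL,
                              n_folds = 5, seed = 1L,
                              imputer = naive_impute, r2_threshold = 0.8) {
  scheme <- make_mask_cv(panel, lowdensity_markers, n_folds, seed)
  imputed_all <- panel$geno
  masked_all <- matrix(FALSE, nrow(panel$geno), ncol(panel$geno),
                       dimnames = dimnames(panel$geno))
  for (f in seq_len(n_folds)) {
    mf <- mask_fold(panel, scheme, f)
    imp <- imputer(mf$masked, mf$reference, pedigree)
    sel <- mf$masked_entries
    imputed_all[sel] <- imp$geno[sel]
    masked_all <- masked_all | sel
  }
  acc <- imputation_r2(panel, genotypes(imputed_all, panel$map), masked_all)
  list(accuracy = acc,
       retained = filter_by_r2(acc, r2_threshold),
       scheme = scheme)
}

#' Stepwise low-to-high density imputation
#'
#' Sequentially imputes an ordered series of panels: each step's output
#' becomes the next step's low-density input, and each step's reference is a
#' set of animals genotyped at that step's target density. Densities must be
#' strictly increasing.
#'
#' @param steps list of steps, each a list with `masked` ([genotypes()] to
#'   fill at this step's density) and `reference` (full [genotypes()] at the
#'   target density).
#' @param pedigree pedigree passed to the imputer.
#' @param imputer imputation function (default [naive_impute()]).
#' @return The final imputed [genotypes()]; per-step outputs in attribute
#'   `steps`.
#' @export
stepwise_impute <- function(steps, pedigree = NULL, imputer = naive_impute) {
  dens <- vapply(steps, function(s) ncol(s$reference$geno), numeric(1))
  if (any(diff(dens) <= 0)) {
    stop("step target densities must be strictly increasing")
  }
  current <- NULL
  outs <- list()
  for (i in seq_along(steps)) {
    st <- steps[[i]]
    low <- st$masked
    if (!is.null(current)) {
      # carry forward previous step's imputed animals, lifted to this density
      tmpl <- st$reference$map
      g <- matrix(NA_real_, nrow(current$geno), nrow(tmpl),
                  dimnames = list(rownames(current$geno), tmpl$marker))
      shared <- intersect(colnames(current$geno), tmpl$marker)
      g[, shared] <- current$geno[, shared]
      extra_ids <- if (is.null(low)) character(0)
                   else setdiff(rownames(low$geno), rownames(g))
      if (length(extra_ids) > 0) {
        g2 <- matrix(NA_real_, length(extra_ids), ncol(g),
                     dimnames = list(extra_ids, colnames(g)))
        shared2 <- intersect(colnames(low$geno), colnames(g))
        g2[, shared2] <- low$geno[extra_ids, shared2]
        g <- rbind(g, g2)
      }
      low <- genotypes(g, tmpl)
    }
    current <- imputer(low, st$reference, pedigree)
    outs[[i]] <- current
  }
  attr(current, "steps") <- outs
  current
}
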