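#' Pedigree additive relationship matrix (tabular method)
#'
#' Recursive tabular construction: `a(i,i) = 1 + a(s,d)/2` and
#' `a(i,j) = (a(j,s) + a(j,d))/2`, with unknown parents contributing zero.
#' Requires a topologically ordered pedigree (parents before offspring).
#'
#' @param pedigree tibble with columns `id`, `sire`, `dam` (`NA` or 0 for
#'   unknown), parents preceding offspring.
#' @return Symmetric numeric matrix with dimnames the animal ids.
#' @export
build_A <- function(pedigree) {
  ped <- .check_pedigree(pedigree)
  n <- nrow(ped)
  A <- matrix(0, n, n)
  s <- ped$sire_row
  d <- ped$dam_row
  for (i in seq_len(n)) {
    if (i > 1) {
      j <- seq_len(i - 1)
      as <- if (is.na(s[i])) 0 else A[j, s[i]]
      ad <- if (is.na(d[i])) 0 else A[j, d[i]]
      A[j, i] <- A[i, j] <- (as + ad) / 2
    }
    A[i, i] <- 1 + if (is.na(s[i]) || is.na(d[i])) 0 else A[s[i], d[i]] / 2
  }
  dimnames(A) <- list(ped$id, ped$id)
  A
}

# normalize pedigree: character ids, NA for unknown, parent-row indices,
# ordering check
.check_pedigree <- function(pedigree) {
  stopifnot(is.data.frame(pedigree),
            all(c("id", "sire", "dam") %in% names(pedigree)))
  id <- as.character(pedigree$id)
  if (anyDuplicated(id)) stop("duplicated animal ids in pedigree")
  norm <- function(x) {
    x <- as.character(x)
    x[x %in% c("0", "", "NA")] <- NA_character_
    x
  }
  sire <- norm(pedigree$sire)
  dam <- norm(pedigree$dam)
  row_of <- setNames(seq_along(id), id)
  s_row <- unname(row_of[sire])
  d_row <- unname(row_of[dam])
  if (any(!is.na(sire) & is.na(s_row)) || any(!is.na(dam) & is.na(d_row))) {
    stop("pedigree refers to parents not present as animals")
  }
  bad <- which(s_row >= seq_along(id) | d_row >= seq_along(id))
  if (length(bad) > 0) {
    stop("pedigree not topologically ordered: offspring ",
         paste(head(id[bad], 5), collapse = ", "), " precede a parent")
  }
  tibble::tibble(id = id, sire_row = s_row, dam_row = d_row)
}

#' Inbreeding coefficients by the Meuwissen-Luo algorithm
#'
#' Computes each animal's inbreeding coefficient F without forming the full A
#' matrix, via the L-and-D decomposition recursion.
#'
#' @inheritParams build_A
#' @return Named numeric vector of F, one per animal.
#' @export
inbreeding_ml <- function(pedigree) {
  ped <- .check_pedigree(pedigree)
  n <- nrow(ped)
  s <- ped$sire_row
  d <- ped$dam_row
  f <- numeric(n)     # F
  diagA <- numeric(n) # 1 + F
  for (i in seq_len(n)) {
    if (is.na(s[i]) && is.na(d[i])) {
      diagA[i] <- 1
      f[i] <- 0
      next
    }
    # Mendelian sampling variances of processed animals
    dvec <- numeric(i)
    L <- numeric(i)
    anc <- logical(i)
    L[i] <- 1
    anc[i] <- TRUE
    aii <- 0
    for (j in i:1) {
      if (!anc[j] || L[j] == 0) next
      sj <- s[j]; dj <- d[j]
      dv <- 0.5 - 0.25 * ((if (is.na(sj)) -1 else f[min(sj, i)]) +
                          (if (is.na(dj)) -1 else f[min(dj, i)]))
      if (j == i) {
        # own Mendelian term uses parents' F (already known, parents < i)
        dv <- if (is.na(sj) && is.na(dj)) 1
              else 0.5 - 0.25 * (f[sj] + f[dj])
      }
      aii <- aii + L[j]^2 * dv
      if (!is.na(sj)) { L[sj] <- L[sj] + 0.5 * L[j]; anc[sj] <- TRUE }
      if (!is.na(dj)) { L[dj] <- L[dj] + 0.5 * L[j]; anc[dj] <- TRUE }
    }
    diagA[i] <- aii
    f[i] <- aii - 1
  }
  setNames(f, ped$id)
}

#' Inverse of the pedigree relationship matrix (Henderson's rules)
#'
#' Builds A-inverse directly from Mendelian sampling variances, with
#' inbreeding accounted for through [inbreeding_ml()] coefficients.
#'
#' @inheritParams build_A
#' @return Symmetric numeric matrix, the inverse of [build_A()]'s output.
#' @export
build_A_inverse <- function(pedigree) {
  ped <- .check_pedigree(pedigree)
  n <- nrow(ped)
  f <- unname(inbreeding_ml(pedigree))
  Ainv <- matrix(0, n, n)
  s <- ped$sire_row
  d <- ped$dam_row
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    mend <- if (is.na(si) && is.na(di)) 1
            else if (is.na(si)) 0.75 - 0.25 * f[di]
            else if (is.na(di)) 0.75 - 0.25 * f[si]
            else 0.5 - 0.25 * (f[si] + f[di])
    alpha <- 1 / mend
    Ainv[i, i] <- Ainv[i, i] + alpha
    for (p in c(si, di)) {
      if (is.na(p)) next
      Ainv[i, p] <- Ainv[p, i] <- Ainv[p, i] - alpha / 2
      Ainv[p, p] <- Ainv[p, p] + alpha / 4
    }
    if (!is.na(si) && !is.na(di)) {
      Ainv[si, di] <- Ainv[di, si] <- Ainv[di, si] + alpha / 4
    }
  }
  dimnames(Ainv) <- list(ped$id, ped$id)
  Ainv
}

#' Extract the genotyped-animal block of a relationship matrix
#'
#' @param A relationship matrix with animal-id dimnames.
#' @param genotyped_ids ids of genotyped animals, in the desired order.
#' @return The principal submatrix of `A` on `genotyped_ids`.
#' @export
extract_A22 <- function(A, genotyped_ids) {
  ids <- as.character(genotyped_ids)
  missing_ids <- setdiff(ids, rownames(A))
  if (length(missing_ids) > 0) {
    stop("ids not in relationship matrix: ",
         paste(head(missing_ids, 5), collapse = ", "))
  }
  A[ids, ids, drop = FALSE]
}

#' Genomic relationship matrix (VanRaden method 1, optionally weighted)
#'
#' `G = Mc D Mc' / (2 * sum_j p_j (1 - p_j) w_j)` where `Mc` is the
#' allele-count matrix centered by twice the observed allele frequencies and
#' `D = diag(w)` holds per-marker weights (all 1 recovers the plain VanRaden
#' G). Missing entries are mean-imputed per marker before centering;
#' monomorphic markers are excluded with a warning.
#'
#' @param geno a [genotypes()] object or allele-count matrix.
#' @param weights per-marker non-negative weights (default all 1).
#' @return Symmetric matrix with animal-id dimnames; attributes `freq`
#'   (allele frequencies used), `scale` (the denominator `k`), and `markers`.
#' @export
build_G <- function(geno, weights = NULL) {
  g <- if (inherits(geno, "genotypes")) geno$geno else geno
  m <- ncol(g)
  if (is.null(weights)) weights <- rep(1, m)
  if (length(weights) != m) stop("need one weight per marker")
  if (any(weights < 0)) stop("weights must be non-negative")
  p <- colMeans(g, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("all markers monomorphic; G undefined")
  if (any(!poly)) {
    warning(sum(!poly), " monomorphic or all-missing marker(s) excluded from G")
  }
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  w <- weights[poly]
  # mean imputation preserves the observed allele frequency
  if (anyNA(g)) {
    na_idx <- which(is.na(g), arr.ind = TRUE)
    g[na_idx] <- 2 * p[na_idx[, 2]]
  }
  Mc <- sweep(g, 2, 2 * p)
  k <- 2 * sum(p * (1 - p) * w)
  G <- tcrossprod(sweep(Mc, 2, w, `*`), Mc) / k
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(g), rownames(g))
  attr(G, "freq") <- p
  attr(G, "scale") <- k
  attr(G, "markers") <- colnames(g)
  G
}

#' Blend a genomic relationship matrix with its pedigree counterpart
#'
#' `(1 - alpha) G + alpha A22`; a small `alpha` guarantees invertibility when
#' `A22` is positive definite.
#'
#' @param G,A22 relationship matrices on the same animals (same id order).
#' @param alpha blending proportion in \[0, 1).
#' @return Blended relationship matrix.
#' @export
blend_G <- function(G, A22, alpha = 0.05) {
  if (alpha < 0 || alpha >= 1) stop("alpha must be in [0, 1)")
  if (!identical(dim(G), dim(A22)) ||
      !identical(rownames(G), rownames(A22))) {
    stop("G and A22 must be indexed by the same animals in the same order")
  }
  out <- (1 - alpha) * G + alpha * A22
  attributes(out)[c("freq", "scale", "markers")] <-
    attributes(G)[c("freq", "scale", "markers")]
  out
}

#' Single-step combined relationship matrix inverse
#'
#' `H^-1 = A^-1 + [[0, 0], [0, G^-1 - A22^-1]]`, the correction block acting
#' on the genotyped animals.
#'
#' @param A_inv inverse pedigree relationship matrix (all animals).
#' @param A22_inv inverse of the genotyped-block pedigree matrix.
#' @param G_inv inverse (blended) genomic relationship matrix.
#' @param genotyped_ids ids of genotyped animals, matching the order of
#'   `G_inv` and `A22_inv`.
#' @return Symmetric matrix, same dimnames as `A_inv`.
#' @export
build_H_inverse <- function(A_inv, A22_inv, G_inv, genotyped_ids) {
  ids <- as.character(genotyped_ids)
  if (length(ids) == 0) return(A_inv)
  if (!identical(dim(G_inv), dim(A22_inv)) ||
      any(dim(G_inv) != length(ids))) {
    stop("G_inv and A22_inv must both be ", length(ids), " x ", length(ids))
  }
  missing_ids <- setdiff(ids, rownames(A_inv))
  if (length(missing_ids) > 0) {
    stop("genotyped ids absent from A_inv: ",
         paste(head(missing_ids, 5), collapse = ", "))
  }
  H_inv <- A_inv
  H_inv[ids, ids] <- H_inv[ids, ids] + (G_inv - A22_inv)
  (H_inv + t(H_inv)) / 2
}

#' Invert a symmetric positive-definite relationship matrix
#'
#' Cholesky-based inverse with a clear error when the matrix is not positive
#' definite (advising blending for singular G).
#'
#' @param K symmetric matrix.
#' @return The inverse, dimnames preserved.
#' @export
kinship_inverse <- function(K) {
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) {
    stop("relationship matrix is not positive definite; ",
         "blend with A22 (see blend_G) before inverting")
  }
  out <- chol2inv(ch)
  dimnames(out) <- dimnames(K)
  out
}

#' Write / read a relationship matrix as an id-pair triplet TSV
#'
#' Lower triangle (including diagonal) as `id_i`, `id_j`, `value`.
#'
#' @param K relationship matrix with id dimnames.
#' @param path output TSV path.
#' @return `write_grm` invisibly returns `path`; `read_grm` returns the
#'   symmetric matrix.
#' @export
write_grm <- function(K, path) {
  idx <- which(lower.tri(K, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(id_i = rownames(K)[idx[, 1]],
                   id_j = colnames(K)[idx[, 2]],
                   value = K[idx])
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    id_i = readr::col_character(), id_j = readr::col_character(),
    value = readr::col_double()))
  ids <- unique(c(df$id_i, df$id_j))
  K <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  K[cbind(df$id_i, df$id_j)] <- df$value
  K[cbind(df$id_j, df$id_i)] <- df$value
  K
}
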