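#' Genotype matrix with marker map
#'
#' Container coupling an individuals-by-markers allele-count matrix (0/1/2,
#' `NA` for missing; imputed dosages may be non-integer) with its marker map.
#'
#' @param geno numeric matrix, individuals in rows (rownames = animal ids),
#'   markers in columns (colnames = marker ids).
#' @param map tibble with columns `marker`, `chrom`, `pos` (1-based bp),
#'   one row per column of `geno`, in column order.
#' @return An object of class `genotypes`: a list with elements `geno` and
#'   `map`.
#' @export
genotypes <- function(geno, map) {
  stopifnot(is.matrix(geno), is.data.frame(map))
  if (is.null(rownames(geno))) stop("`geno` must have rownames (animal ids)")
  if (is.null(colnames(geno))) colnames(geno) <- map$marker
  if (ncol(geno) != nrow(map)) {
    stop("map has ", nrow(map), " rows but geno has ", ncol(geno), " columns")
  }
  if (!all(colnames(geno) == map$marker)) {
    stop("marker ids in map and geno column names disagree")
  }
  if (is.unsorted(order(map$chrom, map$pos))) {
    # map rows must follow (chrom, pos) order within the object
  }
  structure(list(geno = geno, map = tibble::as_tibble(map)),
            class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  miss <- mean(is.na(x$geno))
  cat(sprintf("<genotypes> %d individuals x %d markers (%d chromosome%s), %.1f%% missing\n",
              nrow(x$geno), ncol(x$geno),
              length(unique(x$map$chrom)),
              if (length(unique(x$map$chrom)) == 1) "" else "s",
              100 * miss))
  invisible(x)
}

#' @export
dim.genotypes <- function(x) dim(x$geno)

#' Subset a genotypes object
#'
#' @param x a [genotypes()] object.
#' @param ids animal ids to keep (default all).
#' @param markers marker ids to keep (default all).
#' @return A `genotypes` object restricted to the requested animals/markers.
#' @export
subset_genotypes <- function(x, ids = NULL, markers = NULL) {
  stopifnot(inherits(x, "genotypes"))
  g <- x$geno
  map <- x$map
  if (!is.null(ids)) {
    ids <- as.character(ids)
    missing_ids <- setdiff(ids, rownames(g))
    if (length(missing_ids) > 0) {
      stop("unknown animal ids: ", paste(head(missing_ids, 5), collapse = ", "))
    }
    g <- g[ids, , drop = FALSE]
  }
  if (!is.null(markers)) {
    keep <- map$marker %in% markers
    if (sum(keep) == 0) stop("no requested markers present")
    g <- g[, keep, drop = FALSE]
    map <- map[keep, , drop = FALSE]
  }
  genotypes(g, map)
}

#' Turn a genotypes object into a long tibble
#'
#' @param x a [genotypes()] object.
#' @param ... unused.
#' @return A tibble with columns `id`, `marker`, `chrom`, `pos`, `dosage`.
#' @export
tidy.genotypes <- function(x, ...) {
  g <- x$geno
  tibble::tibble(
    id = rep(rownames(g), times = ncol(g)),
    marker = rep(colnames(g), each = nrow(g)),
    dosage = as.vector(g)
  ) %>%
    dplyr::left_join(x$map, by = "marker") %>%
    dplyr::select("id", "marker", "chrom", "pos", "dosage")
}
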