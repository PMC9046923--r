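#' Write / read a pedigree as 3-column TSV
#'
#' Columns `id`, `sire`, `dam`; 0 encodes an unknown parent.
#'
#' @param pedigree pedigree tibble (`id`, `sire`, `dam`, extra columns kept
#'   on write only if `extra = TRUE`).
#' @param path file path.
#' @param extra also write any additional pedigree columns.
#' @return `write_pedigree` invisibly returns `path`; `read_pedigree`
#'   returns a tibble with `NA` for unknown parents.
#' @export
write_pedigree <- function(pedigree, path, extra = FALSE) {
  df <- if (extra) pedigree else pedigree[, c("id", "sire", "dam")]
  df$sire[is.na(df$sire)] <- 0
  df$dam[is.na(df$dam)] <- 0
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols())
  df$sire[df$sire == 0] <- NA
  df$dam[df$dam == 0] <- NA
  tibble::as_tibble(df)
}

#' Write / read phenotypes as CSV
#'
#' Header `id,trait,tank,covariate,age` (plus any extra columns).
#'
#' @param phenotypes phenotype tibble.
#' @param path file path.
#' @return `write_phenotypes` invisibly returns `path`; `read_phenotypes`
#'   a tibble.
#' @export
write_phenotypes <- function(phenotypes, path) {
  readr::write_csv(phenotypes, path)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  readr::read_csv(path, col_types = readr::cols())
}

#' Write genotypes as a minimal VCF
#'
#' Biallelic sites with alleles A (REF) / B (ALT), GT-only FORMAT, `./.` for
#' missing; non-integer dosages are rounded to the nearest genotype.
#'
#' @param geno a [genotypes()] object.
#' @param path output path (plain text).
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "genotypes"))
  g <- round(geno$geno)
  ids <- rownames(g)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(g)), function(j) {
    gt <- gt_code[as.character(g[, j])]
    gt[is.na(gt)] <- "./."
    paste(c(geno$map$chrom[j], geno$map$pos[j], geno$map$marker[j],
            "A", "B", ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Uses vcfR; only biallelic rows are accepted (multiallelic rows abort with
#' a message). Genotypes become allele counts of the ALT allele; `./.`
#' becomes `NA`.
#'
#' @param path VCF path.
#' @return A [genotypes()] object.
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  if (any(grepl(",", alt))) {
    stop("multiallelic rows present; only biallelic SNPs are supported")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  count <- function(x) {
    x[x %in% c("./.", ".|.", ".")] <- NA
    a <- strsplit(gsub("\\|", "/", x), "/")
    vapply(a, function(al) {
      if (length(al) != 2 || anyNA(al)) return(NA_real_)
      sum(al == "1")
    }, numeric(1))
  }
  g <- vapply(seq_len(nrow(gt)), function(i) count(gt[i, ]),
              numeric(ncol(gt)))
  g <- matrix(g, nrow = ncol(gt), dimnames = list(colnames(gt), NULL))
  fix <- vcfR::getFIX(v)
  map <- tibble::tibble(marker = fix[, "ID"], chrom = fix[, "CHROM"],
                        pos = as.numeric(fix[, "POS"]))
  bad_id <- is.na(map$marker)
  map$marker[bad_id] <- paste0(map$chrom[bad_id], "_", map$pos[bad_id])
  colnames(g) <- map$marker
  genotypes(g, map)
}

#' Write / read genotypes in PLINK ped/map text format
#'
#' `write_plink` writes `<prefix>.ped` (family id = individual id, parents 0,
#' sex 0, phenotype -9; alleles A/B, missing `0 0`) and `<prefix>.map`
#' (chrom, marker, 0 cM, bp).
#'
#' @param geno a [genotypes()] object.
#' @param prefix path prefix for the `.ped`/`.map` pair.
#' @return `write_plink` invisibly returns `prefix`; `read_plink` a
#'   [genotypes()] object.
#' @export
write_plink <- function(geno, prefix) {
  stopifnot(inherits(geno, "genotypes"))
  g <- round(geno$geno)
  allele <- function(x) {
    out <- matrix("0", length(x), 2)
    out[!is.na(x) & x == 0, ] <- "A"
    out[!is.na(x) & x == 2, ] <- "B"
    het <- !is.na(x) & x == 1
    out[het, 1] <- "A"
    out[het, 2] <- "B"
    out
  }
  ped_rows <- vapply(seq_len(nrow(g)), function(i) {
    al <- t(allele(g[i, ]))
    paste(c(rownames(g)[i], rownames(g)[i], 0, 0, 0, -9, as.vector(al)),
          collapse = " ")
  }, character(1))
  writeLines(ped_rows, paste0(prefix, ".ped"))
  readr::write_tsv(
    tibble::tibble(chrom = geno$map$chrom, marker = geno$map$marker,
                   cm = 0, pos = geno$map$pos),
    paste0(prefix, ".map"), col_names = FALSE)
  invisible(prefix)
}

#' @rdname write_plink
#' @export
read_plink <- function(prefix) {
  map <- readr::read_tsv(paste0(prefix, ".map"), col_names = FALSE,
                         col_types = "ccdd")
  map <- tibble::tibble(marker = map[[2]], chrom = map[[1]], pos = map[[4]])
  lines <- readLines(paste0(prefix, ".ped"))
  parts <- strsplit(lines, " +")
  m <- nrow(map)
  g <- matrix(NA_real_, length(parts), m)
  ids <- character(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    ids[i] <- p[2]
    al <- matrix(p[-(1:6)], ncol = 2, byrow = TRUE)
    known <- al[, 1] != "0" & al[, 2] != "0"
    g[i, known] <- (al[known, 1] == "B") + (al[known, 2] == "B")
  }
  rownames(g) <- ids
  colnames(g) <- map$marker
  genotypes(g, map)
}

#' Read gene annotation from GFF3 or BED
#'
#' GFF3: 1-based inclusive `gene` features (falls back to all features if
#' none are typed `gene`); BED: 0-based half-open, converted to 1-based
#' inclusive. Reading goes through rtracklayer.
#'
#' @param path annotation file (`.gff`, `.gff3`, `.bed`).
#' @param format "auto" (from extension), "gff3" or "bed".
#' @return Tibble with columns `chrom`, `start`, `end`, `gene`.
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "bed")) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading annotation files requires the rtracklayer package")
  }
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF")
  df <- as.data.frame(gr)
  if (format == "gff3") {
    if ("type" %in% names(df) && any(df$type == "gene")) {
      df <- df[df$type == "gene", ]
    }
    nm <- if ("Name" %in% names(df) && !all(is.na(df$Name))) df$Name
          else if ("ID" %in% names(df)) df$ID else NA_character_
  } else {
    nm <- if ("name" %in% names(df)) df$name else NA_character_
  }
  tibble::tibble(chrom = as.character(df$seqnames),
                 start = df$start, end = df$end,
                 gene = as.character(nm))
}

#' Write simulated study files to a directory
#'
#' Convenience writer producing the interchange files for one simulated
#' population: `pedigree.tsv`, `phenotypes.csv`, `genotypes.vcf` and a PLINK
#' `genotypes.ped/.map` pair.
#'
#' @param pedigree,phenotypes,geno simulated objects.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_simulation <- function(pedigree, phenotypes, geno, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_pedigree(pedigree, file.path(dir, "pedigree.tsv"))
  write_phenotypes(phenotypes, file.path(dir, "phenotypes.csv"))
  write_vcf(geno, file.path(dir, "genotypes.vcf"))
  write_plink(geno, file.path(dir, "genotypes"))
  invisible(dir)
}
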