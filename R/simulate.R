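#' Simulation configuration for a breeding-nucleus population
#'
#' Bundles every knob of the synthetic-population generator. Defaults emulate
#' a rainbow-trout breeding nucleus: 36 sires and 66 dams producing 119
#' full-sib families averaging 15 offspring (range 12-16), offspring reared
#' in three tanks, and a polygenic growth trait with heritability 0.4 on a
#' unit-phenotypic-variance scale.
#'
#' @param n_sires,n_dams number of male/female founders used as parents.
#' @param n_families number of full-sib families per generation.
#' @param offspring_per_family target mean family size; total offspring per
#'   generation is `n_families * offspring_per_family`.
#' @param family_size_range integer range family sizes are drawn from
#'   (uniformly) before trimming to the target total; set equal to
#'   `offspring_per_family` (both ends) for constant family sizes.
#' @param n_generations number of offspring generations (0 = founders only).
#' @param n_chromosomes,chrom_length_bp,chrom_length_morgans genome layout:
#'   number of chromosomes, physical length (bp) and genetic length (Morgans)
#'   per chromosome (scalars recycled).
#' @param n_markers,n_qtl total marker count and number of causal loci
#'   (QTL are sampled among the markers).
#' @param founder_maf_range interval in (0, 0.5] founder allele frequencies
#'   are drawn from.
#' @param h2_target narrow-sense heritability of the simulated trait; the
#'   generator rescales true breeding values so the generating-model
#'   heritability equals this exactly.
#' @param n_tanks number of rearing tanks (fixed effect levels).
#' @param tank_effects numeric vector of tank effects (trait units, one per
#'   tank); default centers `n_tanks` effects 0.25 trait-SD apart.
#' @param covariate_slope regression of the trait on the initial body-size
#'   covariate (trait units per covariate SD).
#' @param intercept trait intercept (default 3.4, an average-daily-gain-like
#'   scale in g/day).
#' @param genotyping_error_rate probability an allele count is replaced by a
#'   random resample (default 0: no genotyping error).
#' @param seed integer master seed; every generator operation derives its own
#'   stream from it, so equal seeds give byte-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_sires = 36, n_dams = 66, n_families = 119,
                       offspring_per_family = 15,
                       family_size_range = c(12, 16),
                       n_generations = 1,
                       n_chromosomes = 30, chrom_length_bp = 5e7,
                       chrom_length_morgans = 1,
                       n_markers = 5000, n_qtl = 300,
                       founder_maf_range = c(0.05, 0.5),
                       h2_target = 0.4,
                       n_tanks = 3, tank_effects = NULL,
                       covariate_slope = 0.2,
                       intercept = 3.4,
                       genotyping_error_rate = 0,
                       seed = 1L) {
  counts <- c(n_sires = n_sires, n_dams = n_dams, n_families = n_families,
              offspring_per_family = offspring_per_family,
              n_chromosomes = n_chromosomes, n_markers = n_markers,
              n_tanks = n_tanks)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("configuration error: counts must be positive integers (",
         paste(names(counts)[counts < 1 | counts != round(counts)],
               collapse = ", "), ")")
  }
  if (n_generations < 0) stop("configuration error: n_generations must be >= 0")
  if (n_qtl < 0 || n_qtl > n_markers) {
    stop("configuration error: need 0 <= n_qtl <= n_markers")
  }
  if (h2_target < 0 || h2_target > 1) {
    stop("configuration error: h2_target must be in [0, 1]")
  }
  if (length(founder_maf_range) != 2 || founder_maf_range[1] <= 0 ||
      founder_maf_range[2] > 0.5 || founder_maf_range[1] > founder_maf_range[2]) {
    stop("configuration error: founder_maf_range must lie within (0, 0.5]")
  }
  if (any(chrom_length_bp <= 0)) stop("configuration error: zero-length chromosome")
  if (any(chrom_length_morgans < 0)) {
    stop("configuration error: negative genetic length")
  }
  if (is.null(tank_effects)) {
    tank_effects <- 0.25 * (seq_len(n_tanks) - (n_tanks + 1) / 2)
  }
  if (length(tank_effects) != n_tanks) {
    stop("configuration error: tank_effects must have length n_tanks")
  }
  if (genotyping_error_rate < 0 || genotyping_error_rate > 1) {
    stop("configuration error: genotyping_error_rate must be in [0, 1]")
  }
  structure(list(
    n_sires = as.integer(n_sires), n_dams = as.integer(n_dams),
    n_families = as.integer(n_families),
    offspring_per_family = as.integer(offspring_per_family),
    family_size_range = as.integer(family_size_range),
    n_generations = as.integer(n_generations),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = rep_len(chrom_length_bp, n_chromosomes),
    chrom_length_morgans = rep_len(chrom_length_morgans, n_chromosomes),
    n_markers = as.integer(n_markers), n_qtl = as.integer(n_qtl),
    founder_maf_range = founder_maf_range,
    h2_target = h2_target,
    n_tanks = as.integer(n_tanks), tank_effects = tank_effects,
    covariate_slope = covariate_slope, intercept = intercept,
    genotyping_error_rate = genotyping_error_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Derived, operation-specific RNG stream (kept below 2^31).
.sim_seed <- function(config, offset) {
  (config$seed %% 1000000L) * 1000L + offset
}

#' Simulate a full-sib family pedigree
#'
#' Founders (sires then dams) come first with unknown parents; each offspring
#' generation consists of `n_families` sire-dam matings with family sizes
#' drawn uniformly from `family_size_range` and trimmed so the generation
#' totals `n_families * offspring_per_family` animals. The returned tibble is
#' topologically ordered (parents precede offspring).
#'
#' @param config a [sim_config()].
#' @return A tibble with columns `id`, `sire`, `dam` (`NA` = unknown),
#'   `generation`, `sex` ("M"/"F") and `family` (`NA` for founders).
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.sim_seed(config, 1L))
  n_found <- config$n_sires + config$n_dams
  ped <- tibble::tibble(
    id = seq_len(n_found),
    sire = NA_integer_, dam = NA_integer_,
    generation = 0L,
    sex = c(rep("M", config$n_sires), rep("F", config$n_dams)),
    family = NA_integer_
  )
  if (config$n_generations == 0) return(ped)
  next_id <- n_found + 1L
  fam_counter <- 0L
  for (g in seq_len(config$n_generations)) {
    prev <- ped[ped$generation == g - 1L, ]
    sires <- prev$id[prev$sex == "M"]
    dams <- prev$id[prev$sex == "F"]
    if (length(sires) < 1 || length(dams) < 1) {
      stop("generation ", g - 1L, " has no available sires or dams")
    }
    n_use_s <- min(config$n_sires, length(sires))
    n_use_d <- min(config$n_dams, length(dams))
    sires <- sample(sires, n_use_s)
    dams <- sample(dams, n_use_d)
    fam_sire <- sample(rep_len(sires, config$n_families))
    fam_dam <- sample(rep_len(dams, config$n_families))
    # re-draw dams for duplicated pairs so families are distinct matings
    for (tries in 1:20) {
      dup <- duplicated(paste(fam_sire, fam_dam))
      if (!any(dup) || length(dams) == 1) break
      fam_dam[dup] <- sample(dams, sum(dup), replace = TRUE)
    }
    sizes <- .draw_family_sizes(config)
    fam_ids <- fam_counter + seq_len(config$n_families)
    fam_counter <- fam_counter + config$n_families
    off <- tibble::tibble(
      id = next_id - 1L + seq_len(sum(sizes)),
      sire = rep(fam_sire, sizes),
      dam = rep(fam_dam, sizes),
      generation = g,
      sex = sample(c("M", "F"), sum(sizes), replace = TRUE),
      family = rep(fam_ids, sizes)
    )
    next_id <- next_id + sum(sizes)
    ped <- dplyr::bind_rows(ped, off)
  }
  ped
}

.draw_family_sizes <- function(config) {
  target <- config$n_families * config$offspring_per_family
  lo <- config$family_size_range[1]
  hi <- config$family_size_range[2]
  if (lo == hi) return(rep(lo, config$n_families))
  sizes <- sample(lo:hi, config$n_families, replace = TRUE)
  # trim/grow randomly chosen families (within range) to hit the exact total
  while (sum(sizes) != target) {
    if (sum(sizes) > target) {
      i <- sample(which(sizes > lo), 1)
      sizes[i] <- sizes[i] - 1L
    } else {
      i <- sample(which(sizes < hi), 1)
      sizes[i] <- sizes[i] + 1L
    }
  }
  sizes
}

#' Simulate a marker map
#'
#' Markers are allotted to chromosomes proportionally to physical length
#' (largest-remainder rounding) and placed at distinct uniform positions,
#' strictly increasing within chromosome, 1-based.
#'
#' @param config a [sim_config()].
#' @return A tibble with columns `marker`, `chrom`, `pos`, plus attributes
#'   `chrom_lengths` (bp) and `chrom_morgans`.
#' @export
simulate_marker_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_markers < config$n_chromosomes) {
    stop("need n_markers >= n_chromosomes")
  }
  set.seed(.sim_seed(config, 2L))
  len <- config$chrom_length_bp
  frac <- len / sum(len) * config$n_markers
  cnt <- floor(frac)
  rem <- config$n_markers - sum(cnt)
  if (rem > 0) {
    cnt[order(frac - cnt, decreasing = TRUE)[seq_len(rem)]] <-
      cnt[order(frac - cnt, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  chroms <- sprintf("Omy%02d", seq_len(config$n_chromosomes))
  pos <- lapply(seq_len(config$n_chromosomes), function(k) {
    if (cnt[k] == 0) return(numeric(0))
    sort(sample.int(len[k], cnt[k]))
  })
  map <- tibble::tibble(
    chrom = rep(chroms, cnt),
    pos = unlist(pos)
  )
  map <- tibble::tibble(
    marker = sprintf("snp%06d", seq_len(nrow(map))),
    chrom = map$chrom, pos = map$pos
  )
  attr(map, "chrom_lengths") <- setNames(len, chroms)
  attr(map, "chrom_morgans") <- setNames(config$chrom_length_morgans, chroms)
  map
}

#' Drop genotypes through a pedigree
#'
#' Founder haplotypes are drawn independently per locus at founder allele
#' frequencies sampled within `founder_maf_range`; gametes are formed with
#' Haldane (no-interference) recombination - crossover counts Poisson with
#' mean the chromosome's genetic length - and Mendelian transmission.
#'
#' @param pedigree tibble from [simulate_pedigree()].
#' @param map tibble from [simulate_marker_map()].
#' @param config a [sim_config()].
#' @return A [genotypes()] object for all pedigree animals; allele counts in
#'   0/1/2. Attribute `founder_freq` holds the founder allele frequencies.
#' @export
gene_drop_genotypes <- function(pedigree, map, config) {
  stopifnot(inherits(config, "sim_config"))
  one_parent <- xor(is.na(pedigree$sire), is.na(pedigree$dam))
  if (any(one_parent)) {
    stop("animal with exactly one known parent: ",
         paste(head(pedigree$id[one_parent], 5), collapse = ", "))
  }
  set.seed(.sim_seed(config, 3L))
  m <- nrow(map)
  n <- nrow(pedigree)
  freq <- runif(m, config$founder_maf_range[1], config$founder_maf_range[2])
  chroms <- unique(map$chrom)
  chrom_idx <- lapply(chroms, function(cc) which(map$chrom == cc))
  chrom_pos <- lapply(chrom_idx, function(ii) map$pos[ii])
  chrom_len <- attr(map, "chrom_lengths")[chroms]
  chrom_mor <- attr(map, "chrom_morgans")[chroms]

  H1 <- matrix(0L, n, m)
  H2 <- matrix(0L, n, m)
  row_of <- setNames(seq_len(n), as.character(pedigree$id))
  founder <- is.na(pedigree$sire)
  nf <- sum(founder)
  H1[founder, ] <- matrix(rbinom(nf * m, 1L, rep(freq, each = nf)), nf, m)
  H2[founder, ] <- matrix(rbinom(nf * m, 1L, rep(freq, each = nf)), nf, m)

  gamete <- function(prow) {
    out <- integer(m)
    for (k in seq_along(chroms)) {
      ii <- chrom_idx[[k]]
      n_co <- rpois(1L, chrom_mor[k])
      if (n_co == 0) {
        src <- rep(sample(1:2, 1L), length(ii))
      } else {
        breaks <- sort(runif(n_co, 0, chrom_len[k]))
        seg <- findInterval(chrom_pos[[k]], breaks)
        src <- (sample(0:1, 1L) + seg) %% 2L + 1L
      }
      out[ii] <- ifelse(src == 1L, H1[prow, ii], H2[prow, ii])
    }
    out
  }

  for (i in which(!founder)) {
    H1[i, ] <- gamete(row_of[as.character(pedigree$sire[i])])
    H2[i, ] <- gamete(row_of[as.character(pedigree$dam[i])])
  }

  g <- H1 + H2
  if (config$genotyping_error_rate > 0) {
    err <- matrix(runif(n * m) < config$genotyping_error_rate, n, m)
    g[err] <- sample(0:2, sum(err), replace = TRUE)
  }
  storage.mode(g) <- "double"
  rownames(g) <- as.character(pedigree$id)
  colnames(g) <- map$marker
  out <- genotypes(g, map)
  attr(out, "founder_freq") <- setNames(freq, map$marker)
  out
}

#' Simulate phenotypes with a polygenic architecture
#'
#' Samples `n_qtl` causal markers, draws additive allele-substitution effects,
#' and rescales true breeding values (TBV) so the generating-model
#' heritability is exactly `h2_target` on a unit-phenotypic-variance scale
#' (residual variance `1 - h2_target`). Phenotype = intercept + tank effect +
#' `covariate_slope` x covariate + TBV + normal residual. The initial-size
#' covariate is simulated standard normal, independent of TBV. Only
#' non-founder animals (generation >= 1) receive phenotypes; tanks are
#' assigned round-robin within family so every family is represented in every
#' tank.
#'
#' @param geno a [genotypes()] object from [gene_drop_genotypes()].
#' @param pedigree tibble from [simulate_pedigree()].
#' @param config a [sim_config()].
#' @return A list with `phenotypes` (tibble `id`, `trait`, `tank`,
#'   `covariate`, `age`) and `tgv` (tibble `animal_id`, `tbv` for every
#'   animal, with attributes `qtl_markers`, `qtl_genotypes`, `sigma2_e`,
#'   `h2_target`).
#' @export
simulate_phenotypes <- function(geno, pedigree, config) {
  stopifnot(inherits(geno, "genotypes"), inherits(config, "sim_config"))
  if (config$h2_target > 0 && config$n_qtl == 0) {
    stop("configuration error: h2_target > 0 requires n_qtl >= 1")
  }
  set.seed(.sim_seed(config, 4L))
  n <- nrow(pedigree)
  ids <- as.character(pedigree$id)
  m <- ncol(geno$geno)

  pheno_rows <- which(pedigree$generation >= 1L)
  if (length(pheno_rows) == 0) pheno_rows <- seq_len(n)

  if (config$h2_target == 0 || config$n_qtl == 0) {
    tbv <- rep(0, n)
    qtl_markers <- character(0)
    Q <- matrix(0, n, 0)
    sigma2_e <- 1
  } else {
    qtl_cols <- sort(sample.int(m, config$n_qtl))
    qtl_markers <- colnames(geno$geno)[qtl_cols]
    Q <- geno$geno[ids, qtl_cols, drop = FALSE]
    a <- rnorm(config$n_qtl)
    tbv <- unname(drop(Q %*% a))
    # exact rescaling on the phenotyped cohort: its realized genetic variance
    # is h2 and sigma2_e = 1 - h2, so the generating-model heritability of
    # the analyzed animals equals h2_target to machine precision
    v <- var(tbv[pheno_rows])
    if (v <= 0) stop("QTL genotypes carry no variance; increase n_qtl or MAF")
    tbv <- tbv * sqrt(config$h2_target / v)
    tbv <- tbv - mean(tbv[pheno_rows])
    sigma2_e <- 1 - config$h2_target
  }
  np <- length(pheno_rows)
  fam <- pedigree$family[pheno_rows]
  fam[is.na(fam)] <- 0L
  tank <- integer(np)
  for (f in unique(fam)) {
    w <- which(fam == f)
    tank[w] <- 1L + (sample(seq_along(w)) - 1L) %% config$n_tanks
  }
  covariate <- rnorm(np)
  resid <- if (sigma2_e > 0) rnorm(np, 0, sqrt(sigma2_e)) else rep(0, np)
  trait <- config$intercept + config$tank_effects[tank] +
    config$covariate_slope * covariate + tbv[pheno_rows] + resid

  phenotypes <- tibble::tibble(
    id = pedigree$id[pheno_rows],
    trait = trait,
    tank = paste0("T", tank),
    covariate = covariate,
    age = as.integer(round(rnorm(np, 540, 8)))
  )
  tgv <- tibble::tibble(animal_id = pedigree$id, tbv = tbv)
  attr(tgv, "qtl_markers") <- qtl_markers
  attr(tgv, "qtl_genotypes") <- Q
  attr(tgv, "sigma2_e") <- sigma2_e
  attr(tgv, "h2_target") <- config$h2_target
  list(phenotypes = phenotypes, tgv = tgv)
}

#' Thin a genotype matrix to a lower-density panel
#'
#' Keeps an evenly spaced subset of markers (every `m/panel_size`-th marker in
#' map order) and, optionally, knocks entries out at random to emulate
#' missingness.
#'
#' @param geno a [genotypes()] object.
#' @param panel_size number of markers to retain (1..m).
#' @param missing_rate per-entry missingness probability.
#' @param seed integer seed for the missingness draw.
#' @return A [genotypes()] object with `panel_size` markers.
#' @export
degrade_to_panel <- function(geno, panel_size, missing_rate = 0, seed = 1L) {
  stopifnot(inherits(geno, "genotypes"))
  m <- ncol(geno$geno)
  if (panel_size < 1 || panel_size > m) {
    stop("panel_size must be in 1..", m)
  }
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate must be in [0,1]")
  idx <- unique(ceiling(seq_len(panel_size) * m / panel_size))
  g <- geno$geno[, idx, drop = FALSE]
  map <- geno$map[idx, , drop = FALSE]
  if (missing_rate > 0) {
    set.seed(seed)
    g[matrix(runif(length(g)) < missing_rate, nrow(g), ncol(g))] <- NA_real_
  }
  for (a in c("chrom_lengths", "chrom_morgans")) {
    attr(map, a) <- attr(geno$map, a)
  }
  genotypes(g, map)
}
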