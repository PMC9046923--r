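# Small simulated populations shared across tests.

quick_config <- function(seed = 1, ...) {
  defaults <- list(n_sires = 6, n_dams = 12, n_families = 15,
                   offspring_per_family = 10,
                   family_size_range = c(10, 10),
                   n_chromosomes = 3, chrom_length_bp = 4e7,
                   chrom_length_morgans = 1,
                   n_markers = 150, n_qtl = 20, h2_target = 0.4,
                   seed = seed)
  args <- utils::modifyList(defaults, list(...))
  if (args$n_qtl > args$n_markers) args$n_qtl <- max(1, args$n_markers %/% 3)
  do.call(sim_config, args)
}

quick_population <- function(seed = 1, ...) {
  cfg <- quick_config(seed, ...)
  ped <- simulate_pedigree(cfg)
  map <- simulate_marker_map(cfg)
  geno <- gene_drop_genotypes(ped, map, cfg)
  sim <- simulate_phenotypes(geno, ped, cfg)
  list(cfg = cfg, ped = ped, map = map, geno = geno,
       phenotypes = sim$phenotypes, tgv = sim$tgv)
}

# genotypes object from a bare matrix on one chromosome
toy_genotypes <- function(g, pos = NULL, chrom = "Omy01") {
  if (is.null(rownames(g))) rownames(g) <- paste0("a", seq_len(nrow(g)))
  m <- ncol(g)
  if (is.null(pos)) pos <- seq_len(m) * 1000
  map <- tibble::tibble(marker = paste0("m", seq_len(m)),
                        chrom = chrom, pos = pos)
  colnames(g) <- map$marker
  genotypes(g, map)
}

# random valid pedigree for property tests (single founder generation plus
# offspring, some matings between relatives in later layers)
random_pedigree <- function(n_founders, n_offspring, seed) {
  set.seed(seed)
  n <- n_founders + n_offspring
  id <- seq_len(n)
  sire <- rep(NA_integer_, n)
  dam <- rep(NA_integer_, n)
  for (i in (n_founders + 1):n) {
    pair <- sample(seq_len(i - 1), 2)
    sire[i] <- pair[1]
    dam[i] <- pair[2]
  }
  tibble::tibble(id = id, sire = sire, dam = dam)
}
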