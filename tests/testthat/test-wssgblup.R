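# Table of the five strongest ADG/BL/BW association signals as printed in the
# source population's GWAS, used to exercise ranking and window logic.
adg_table <- tibble::tibble(
  marker = c("s1", "s2", "s3", "s4", "s5"),
  chrom = c("Omy07", "Omy06", "Omy07", "Omy01", "Omy25"),
  pos = c(62669267, 25326130, 62654174, 59530229, 40665614),
  pct_var = c(0.1382, 0.1162, 0.0901, 0.0824, 0.0823)
)

test_that("backsolved SNP effects reproduce GEBV exactly (round trip)", {
  # GEBV of genotyped animals live in the column space of G (observed-
  # frequency centering makes 1'G = 0, so G is PSD with one null direction);
  # the round trip is exact for any u in col(G)
  set.seed(41)
  g <- matrix(sample(0:2, 4 * 3, TRUE), 4, 3,
              dimnames = list(paste0("a", 1:4), NULL))
  g[1, 1] <- 0; g[2, 1] <- 2  # ensure polymorphism
  geno <- toy_genotypes(g)
  G <- build_G(geno)
  u <- drop(G %*% rnorm(nrow(g)))
  names(u) <- rownames(g)
  eff <- suppressWarnings(
    backsolve_snp_effects(u, geno, G_unblended = G))
  p <- attr(G, "freq")
  Mc <- sweep(geno$geno[, attr(G, "markers"), drop = FALSE], 2, 2 * p)
  expect_equal(unname(drop(Mc %*% eff$effect)), unname(u), tolerance = 1e-8)
  # zero GEBV -> zero effects
  eff0 <- suppressWarnings(backsolve_snp_effects(
    setNames(rep(0, nrow(g)), rownames(g)), geno, G_unblended = G))
  expect_true(all(eff0$effect == 0))
})

test_that("round trip holds across random instances", {
  ok <- 0
  for (s in 1:100) {
    set.seed(500 + s)
    n <- sample(5:10, 1)
    m <- n + sample(5:15, 1)
    g <- matrix(rbinom(n * m, 2, runif(m, 0.2, 0.8)[rep(1:m, each = n)]),
                n, m, dimnames = list(paste0("a", 1:n), NULL))
    geno <- toy_genotypes(g)
    w <- setNames(runif(m, 0.5, 2), paste0("m", 1:m))
    G <- suppressWarnings(build_G(geno, weights = unname(w)))
    u <- drop(G %*% rnorm(n))
    names(u) <- rownames(g)
    eff <- suppressWarnings(
      backsolve_snp_effects(u, geno, weights = w, G_unblended = G))
    p <- attr(G, "freq")
    Mc <- sweep(geno$geno[, attr(G, "markers"), drop = FALSE], 2, 2 * p)
    if (max(abs(drop(Mc %*% eff$effect) - u)) < 1e-6) ok <- ok + 1
  }
  expect_gt(ok, 90)
})

test_that("per-SNP variance percentages follow 2p(1-p)a^2 / sigma2_a", {
  eff <- tibble::tibble(marker = "m", chrom = "Omy01", pos = 1,
                        freq = 0.5, effect = 1, weight = 1)
  out <- snp_variance_explained(eff, sigma2_a = 50)
  expect_equal(out$pct_var, 100 * 0.5 * 1 / 50)  # = 1%
  expect_equal(snp_variance_explained(dplyr::mutate(eff, effect = 0),
                                      1)$pct_var, 0)
  expect_error(snp_variance_explained(eff, 0), "positive")
})

test_that("weight updates are floored and mean-normalized", {
  eff <- tibble::tibble(marker = paste0("m", 1:4), freq = rep(0.3, 4),
                        effect = rep(2, 4))
  w <- update_weights(eff)
  expect_equal(unname(w), rep(1, 4))  # constant raw weights normalize to 1
  eff2 <- dplyr::mutate(eff, effect = c(5, 0, 0, 0))
  w2 <- update_weights(eff2)
  expect_equal(mean(w2), 1, tolerance = 1e-12)
  expect_equal(unname(w2[1]), 4, tolerance = 1e-6)  # one signal among 4
  expect_true(all(w2[-1] > 0))                      # floor keeps them positive
  expect_warning(w0 <- update_weights(dplyr::mutate(eff, effect = 0)), "zero")
  expect_equal(unname(w0), rep(1, 4))
})

test_that("one wssGBLUP iteration is the plain ssGBLUP path and is reproducible", {
  pop <- quick_population(seed = 43, n_markers = 120, n_qtl = 15)
  off <- as.character(pop$ped$id[pop$ped$generation == 1])
  geno <- subset_genotypes(pop$geno, ids = off)
  f1 <- suppressWarnings(run_wssgblup(geno, pop$phenotypes, pop$ped,
                                      n_iterations = 1))
  f2 <- suppressWarnings(run_wssgblup(geno, pop$phenotypes, pop$ped,
                                      n_iterations = 2))
  expect_identical(f1$effects$effect, f2$iterations[[1]]$effect)
  expect_true(all(f2$iterations[[1]]$weight == 1))
  expect_false(all(f2$iterations[[2]]$weight == 1))
  # bitwise reproducibility
  f1b <- suppressWarnings(run_wssgblup(geno, pop$phenotypes, pop$ped,
                                       n_iterations = 1))
  expect_identical(f1$effects, f1b$effects)
  # variance-decomposition sanity: percentages are bounded
  expect_true(all(f2$effects$pct_var >= 0))
  expect_lt(sum(f2$effects$pct_var), 100 * (1 + 1e-6) + 100)
})

test_that("a major QTL is recovered as the top association signal", {
  hits <- vapply(1:5, function(s) {
    pop <- quick_population(seed = 700 + s, n_markers = 200, n_qtl = 1,
                            h2_target = 0.4, n_families = 30,
                            offspring_per_family = 12,
                            family_size_range = c(12, 12),
                            n_sires = 10, n_dams = 20)
    off <- as.character(pop$ped$id[pop$ped$generation == 1])
    geno <- subset_genotypes(pop$geno, ids = off)
    fit <- suppressWarnings(run_wssgblup(geno, pop$phenotypes, pop$ped,
                                         n_iterations = 2))
    qtl <- attr(pop$tgv, "qtl_markers")
    qtl_pos <- pop$map$pos[pop$map$marker == qtl]
    qtl_chrom <- pop$map$chrom[pop$map$marker == qtl]
    top <- select_lead_snps(fit$effects, k = 5)
    any(top$chrom == qtl_chrom & abs(top$pos - qtl_pos) < 5e6)
  }, logical(1))
  expect_gte(sum(hits), 4)
})

test_that("polygenic architecture spreads variance thinly", {
  pop <- quick_population(seed = 46, n_markers = 300, n_qtl = 150,
                          n_families = 30, offspring_per_family = 12,
                          family_size_range = c(12, 12),
                          n_sires = 10, n_dams = 20)
  off <- as.character(pop$ped$id[pop$ped$generation == 1])
  geno <- subset_genotypes(pop$geno, ids = off)
  fit <- suppressWarnings(run_wssgblup(geno, pop$phenotypes, pop$ped,
                                       n_iterations = 2))
  expect_lt(max(fit$effects$pct_var), 15)
})

test_that("lead-SNP selection reproduces the printed ranking and tie rules", {
  shuffled <- adg_table[c(3, 5, 1, 4, 2), ]
  top <- select_lead_snps(shuffled, k = 5)
  expect_equal(top$pos, c(62669267, 25326130, 62654174, 59530229, 40665614))
  expect_equal(top$chrom, c("Omy07", "Omy06", "Omy07", "Omy01", "Omy25"))
  # stable under shuffling
  top2 <- select_lead_snps(adg_table[sample(1:5), ], k = 5)
  expect_equal(top2$marker, top$marker)
  # k = 1 with unique maximum
  expect_equal(select_lead_snps(adg_table, k = 1)$marker, "s1")
  # ties break by (chrom, pos) ascending
  tied <- tibble::tibble(marker = c("x", "y"), chrom = c("Omy02", "Omy01"),
                         pos = c(5, 10), pct_var = c(0.5, 0.5))
  expect_equal(select_lead_snps(tied, k = 2)$marker, c("y", "x"))
  # windows are clipped at 1
  near_edge <- tibble::tibble(marker = "z", chrom = "Omy01", pos = 50,
                              pct_var = 1)
  expect_equal(select_lead_snps(near_edge, k = 1)$window_start, 1)
  expect_error(select_lead_snps(adg_table[0, ], 5), "empty")
})

test_that("gene windows use closed-interval overlap at exactly 100 kb", {
  leads <- select_lead_snps(
    tibble::tibble(marker = "m", chrom = "Omy01", pos = 500000, pct_var = 1),
    k = 1)
  ann <- tibble::tibble(
    chrom = "Omy01",
    start = c(300000, 100000, 499000, 550000),
    end = c(400000, 399999, 501000, 560000),  # 2nd ends 1 bp short of window
    gene = c("at_boundary", "too_far", "contains_snp", "inside_window"))
  out <- gene_window_lookup(leads, ann)
  expect_setequal(out$gene[!is.na(out$gene)],
                  c("at_boundary", "contains_snp", "inside_window"))
  expect_true(out$in_gene[out$gene == "contains_snp"])
  expect_false(any(out$in_gene[out$gene != "contains_snp"], na.rm = TRUE))
  # leads with no nearby gene keep a row
  far <- select_lead_snps(
    tibble::tibble(marker = "f", chrom = "Omy01", pos = 9e6, pct_var = 1),
    k = 1)
  out2 <- gene_window_lookup(far, ann)
  expect_true(is.na(out2$gene[out2$marker == "f"]))
  # disjoint chromosome naming is an error
  ann_bad <- dplyr::mutate(ann, chrom = "chr1")
  expect_error(gene_window_lookup(leads, ann_bad), "chromosome names")
})

test_that("GBLUP breeding values are order-equivariant", {
  pop <- quick_population(seed = 47)
  off <- as.character(pop$ped$id[pop$ped$generation == 1])
  geno <- subset_genotypes(pop$geno, ids = off)
  G <- blend_G(build_G(geno), extract_A22(build_A(pop$ped), off), 0.05)
  spec <- model_spec()
  ph <- pop$phenotypes[as.character(pop$phenotypes$id) %in% off, ]
  des <- build_design(ph, spec, off)
  vc <- list(sigma2_a = 0.4, sigma2_e = 0.6)
  sol <- solve_mme(des$y, des$X, des$Z, kinship_inverse(G), vc)
  perm <- rev(off)
  Gp <- G[perm, perm]
  desp <- build_design(ph, spec, perm)
  solp <- solve_mme(desp$y, desp$X, desp$Z, kinship_inverse(Gp), vc)
  e1 <- setNames(sol$ebv$ebv, sol$ebv$id)
  e2 <- setNames(solp$ebv$ebv, solp$ebv$id)
  expect_equal(e1[off], e2[off], tolerance = 1e-8)
})
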