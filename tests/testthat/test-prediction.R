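# independent pruning oracle: exhaustive repeated scan over all pairs within
# the bp window, dropping the lower-MAF member until no violating pair remains
prune_oracle <- function(geno, window_bp, r2_max) {
  g <- geno$geno
  map <- geno$map
  maf <- compute_maf(g)
  alive <- rep(TRUE, ncol(g))
  repeat {
    worst <- NULL
    worst_r2 <- r2_max
    idx <- which(alive)
    for (a in idx) for (b in idx[idx > a]) {
      if (map$chrom[a] != map$chrom[b]) next
      if (abs(map$pos[b] - map$pos[a]) > window_bp) next
      r2 <- suppressWarnings(cor(g[, a], g[, b]))^2
      if (!is.na(r2) && r2 > worst_r2) {
        worst_r2 <- r2
        worst <- c(a, b)
      }
    }
    if (is.null(worst)) break
    drop <- if (maf[worst[1]] < maf[worst[2]]) worst[1]
            else if (maf[worst[2]] < maf[worst[1]]) worst[2]
            else worst[which.max(map$pos[worst])]
    alive[drop] <- FALSE
  }
  map$marker[alive]
}

test_that("LD pruning removes one of each violating pair", {
  g <- cbind(a = c(0, 1, 2, 0, 1, 2), b = c(0, 1, 2, 0, 1, 2),
             c = c(2, 0, 1, 2, 0, 1))
  rownames(g) <- paste0("s", 1:6)
  geno <- toy_genotypes(g, pos = c(1000, 2000, 3000))
  kept <- ld_prune(geno, window_bp = 5000, r2_max = 0.5)
  expect_equal(length(kept), 2)        # identical pair collapsed
  expect_true("m3" %in% kept)
  # nothing removed when all r2 below threshold
  set.seed(51)
  g2 <- matrix(rbinom(8 * 6, 2, 0.5), 8, 6,
               dimnames = list(paste0("s", 1:8), NULL))
  geno2 <- toy_genotypes(g2, pos = (1:6) * 1e6)  # far apart: no window pairs
  expect_equal(ld_prune(geno2, window_bp = 1000, r2_max = 0.01),
               geno2$map$marker)
  expect_error(ld_prune(toy_genotypes(g, pos = c(3, 2, 1))), "sorted")
})

test_that("pruning matches the exhaustive-pair oracle on toys", {
  for (s in 1:8) {
    set.seed(60 + s)
    n <- 12
    base <- rbinom(n, 2, 0.5)
    g <- cbind(base,
               ifelse(runif(n) < 0.15, sample(0:2, n, TRUE), base),
               rbinom(n, 2, 0.3),
               ifelse(runif(n) < 0.2, sample(0:2, n, TRUE), base),
               rbinom(n, 2, 0.4))
    rownames(g) <- paste0("s", 1:n)
    geno <- toy_genotypes(g, pos = c(1000, 1500, 2000, 2500, 3000))
    expect_equal(sort(ld_prune(geno, window_bp = 4000, step = 1,
                               r2_max = 0.4)),
                 sort(prune_oracle(geno, 4000, 0.4)),
                 label = paste("seed", s))
  }
})

test_that("CV scheme partitions animals into near-equal folds", {
  ids <- paste0("a", 1:805)
  scheme <- make_cv_scheme(ids, n_folds = 5, n_repetitions = 5, seed = 7)
  for (r in 1:5) {
    sub <- scheme[scheme$rep == r, ]
    expect_setequal(sub$id, ids)             # exact partition
    expect_equal(unname(table(sub$fold)), rep(161L, 5), ignore_attr = TRUE)
  }
  # determinism and cross-repetition variety
  scheme2 <- make_cv_scheme(ids, 5, 5, seed = 7)
  expect_identical(scheme, scheme2)
  expect_false(identical(scheme$fold[scheme$rep == 1],
                         scheme$fold[scheme$rep == 2]))
  small <- make_cv_scheme(paste0("b", 1:10), 5, 1, seed = 1)
  expect_equal(unname(table(small$fold)), rep(2L, 5), ignore_attr = TRUE)
  expect_error(make_cv_scheme(paste0("c", 1:3), 5, 1, 1), "folds")
})

test_that("accuracy is r over sqrt(h2) and scale invariant", {
  expect_equal(accuracy(0.3, 0.36), 0.5)
  expect_equal(accuracy(sqrt(0.4), 0.4), 1)
  expect_equal(accuracy(0, 0.99), 0)
  expect_error(accuracy(0.5, 0), "positive")
  # scale invariance of the underlying correlation
  set.seed(52)
  pred <- rnorm(50); obs <- pred + rnorm(50)
  expect_equal(accuracy(cor(10 * pred, 10 * obs), 0.4),
               accuracy(cor(pred, obs), 0.4))
})

test_that("split evaluation predicts validation animals without their phenotypes", {
  pop <- quick_population(seed = 53, n_families = 25,
                          offspring_per_family = 12,
                          family_size_range = c(12, 12),
                          n_sires = 8, n_dams = 16)
  off <- as.character(pop$ped$id[pop$ped$generation == 1])
  ph <- pop$phenotypes[as.character(pop$phenotypes$id) %in% off, ]
  A22 <- extract_A22(build_A(pop$ped), off)
  val <- off[1:60]
  ev <- evaluate_split(ph, val, A22)
  expect_true(is.finite(ev$r) && abs(ev$r) <= 1)
  # genetic signal should produce positive validation correlation
  expect_gt(ev$r, 0)
  # pure noise phenotypes give |r| near zero
  ph0 <- ph
  set.seed(2)
  ph0$trait <- rnorm(nrow(ph0))
  ev0 <- evaluate_split(ph0, val, A22,
                        vc = list(sigma2_a = 0.2, sigma2_e = 0.8,
                                  converged = TRUE))
  expect_lt(abs(ev0$r), 0.25)
})

test_that("training-fold selection and solutions ignore validation phenotypes", {
  pop <- quick_population(seed = 54, n_markers = 100, n_qtl = 10)
  off <- as.character(pop$ped$id[pop$ped$generation == 1])
  geno <- subset_genotypes(pop$geno, ids = off)
  ph <- pop$phenotypes[as.character(pop$phenotypes$id) %in% off, ]
  val <- off[1:50]
  train_ph <- ph[!as.character(ph$id) %in% val, ]
  sel1 <- suppressWarnings(preselect_top_snps(geno, train_ph, pop$ped, k = 20,
                                              n_iterations = 1))
  # permute validation phenotypes: training rows untouched
  ph_perm <- ph
  set.seed(3)
  vrows <- as.character(ph_perm$id) %in% val
  ph_perm$trait[vrows] <- sample(ph_perm$trait[vrows])
  train_ph2 <- ph_perm[!as.character(ph_perm$id) %in% val, ]
  sel2 <- suppressWarnings(preselect_top_snps(geno, train_ph2, pop$ped, k = 20,
                                              n_iterations = 1))
  expect_identical(sel1, sel2)
  # training solutions are hash-identical too
  A22 <- extract_A22(build_A(pop$ped), off)
  ev1 <- evaluate_split(ph, val, A22)
  ev2 <- evaluate_split(ph_perm, val, A22)
  expect_identical(ev1$solutions$ebv, ev2$solutions$ebv)
  expect_identical(ev1$solutions$fixed, ev2$solutions$fixed)
})

test_that("scenario comparison computes relative gains against PBLUP", {
  splits <- tibble::tibble(
    rep = rep(1:2, each = 4), fold = rep(1:2, 4),
    scenario = rep(c("PBLUP", "PBLUP", "wgs", "wgs"), 2),
    method = rep(c("PBLUP", "PBLUP", "GBLUP", "GBLUP"), 2),
    r = c(0.3, 0.3, 0.33, 0.33, 0.3, 0.3, 0.33, 0.33),
    accuracy = c(0.5, 0.5, 0.55, 0.55, 0.5, 0.5, 0.55, 0.55))
  out <- compare_scenarios(splits)
  expect_equal(out$relative_gain_pct[out$scenario == "wgs"], 10)
  expect_equal(out$relative_gain_pct[out$scenario == "PBLUP"], 0)
  expect_equal(out$mean_accuracy_by_rep, out$mean_accuracy)
  expect_error(compare_scenarios(splits[splits$scenario != "PBLUP", ]),
               "baseline")
})

test_that("the CV driver produces a complete, ordered experiment", {
  pop <- quick_population(seed = 55, n_markers = 120, n_qtl = 12)
  off <- as.character(pop$ped$id[pop$ped$generation == 1])
  geno <- subset_genotypes(pop$geno, ids = off)
  ph <- pop$phenotypes[as.character(pop$phenotypes$id) %in% off, ]
  cv <- suppressWarnings(run_prediction_cv(
    geno, ph, pop$ped,
    scenarios = list(list(name = "wgs"),
                     list(name = "top_k", k = 40, n_iterations = 1)),
    n_folds = 3, n_repetitions = 1, seed = 9))
  expect_equal(nrow(cv$splits), 3 * 3)  # PBLUP + 2 scenarios x 3 folds
  expect_setequal(unique(cv$splits$scenario), c("PBLUP", "wgs", "top_k"))
  expect_true(all(is.finite(cv$splits$accuracy)))
  # per-split audit of preselected markers exists and has size k
  audit <- cv$markers[grepl("top_k", names(cv$markers))]
  expect_equal(length(audit), 3)
  expect_true(all(vapply(audit, length, numeric(1)) == 40))
  summary <- compare_scenarios(cv)
  expect_true("relative_gain_pct" %in% names(summary))
})

test_that("k covering all markers reduces preselection to the full panel", {
  pop <- quick_population(seed = 56, n_markers = 60)
  off <- as.character(pop$ped$id[pop$ped$generation == 1])
  geno <- subset_genotypes(pop$geno, ids = off)
  ph <- pop$phenotypes[as.character(pop$phenotypes$id) %in% off, ]
  sel <- preselect_top_snps(geno, ph, pop$ped, k = ncol(geno$geno))
  expect_setequal(sel, colnames(geno$geno))
  expect_warning(
    sel2 <- preselect_top_snps(geno, ph, pop$ped, k = 10000), "all")
  expect_setequal(sel2, colnames(geno$geno))
})
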