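test_that("screen PCA separates constructed clouds and reconstructs the input", {
  set.seed(31)
  base <- matrix(rnorm(50 * 8, 0, 0.2), 50, 8)
  m <- toy_matrix(cbind(base, base + 3), lines = paste0("s", 1:16))
  pc <- pca_screens(m)
  # PC1 separates the two screen groups
  expect_true(all(pc$coords[1:8, 1] * pc$coords[9:16, 1] < 0) ||
              all(sign(pc$coords[1:8, 1]) != sign(pc$coords[9:16, 1])))
  # reconstruction identity from all components
  centered <- scale(t(m), center = TRUE, scale = FALSE)
  rec <- pc$coords %*% t(pc$loadings)
  expect_lt(max(abs(rec - centered)), 1e-8)
  # orthonormal loadings
  k <- ncol(pc$loadings)
  expect_lt(max(abs(crossprod(pc$loadings) - diag(k))), 1e-8)
  expect_equal(sum(pc$var_explained), 1)
  expect_error(pca_screens(m[, 1:2]), ">= 3")
})

test_that("loading enrichment p equals the closed-form hypergeometric tail", {
  # k = 5 of a 10-gene set in a 20-gene list from a 100-gene universe
  manual <- sum(vapply(5:10, function(i)
    choose(10, i) * choose(90, 20 - i) / choose(100, 20), numeric(1)))
  expect_equal(hypergeom_test(5, 10, 20, 100), manual)
  set.seed(32)
  loadings <- matrix(rnorm(200), 100, 2,
                     dimnames = list(sprintf("g%03d", 1:100), c("PC1", "PC2")))
  # a set fully inside the extreme tail of PC1 gets the minimal p
  tail_genes <- rownames(loadings)[order(loadings[, 1])][1:5]
  sets <- list(planted = tail_genes,
               random = sample(rownames(loadings), 10))
  enr <- loading_enrichment(loadings, sets, components = 1, top_frac = 0.05)
  p_planted <- enr$p[enr$set == "planted"]
  expect_equal(p_planted, hypergeom_test(5, 5, 10, 100))
  expect_lt(p_planted, enr$p[enr$set == "random"])
})

test_that("loading enrichment p-values are calibrated under random sets", {
  set.seed(33)
  loadings <- matrix(rnorm(1000), 500, 2,
                     dimnames = list(sprintf("g%03d", 1:500), c("PC1", "PC2")))
  sets <- lapply(1:300, function(i) sample(rownames(loadings), 25))
  names(sets) <- paste0("s", 1:300)
  enr <- loading_enrichment(loadings, sets, components = 1, top_frac = 0.05)
  # discrete p-values are stochastically >= uniform; check no inflation
  expect_gt(suppressWarnings(ks.test(enr$p, "punif", alternative = "greater"))$p.value, 0.01)
})

test_that("co-targeting correlations behave at the extremes", {
  set.seed(34)
  profile <- rnorm(50)
  fa <- toy_matrix(rbind(profile, profile, rnorm(50), rnorm(50)),
                   genes = c("gA_1", "gA_2", "gB_1", "gB_2"),
                   lines = paste0("l", 1:50))
  fb <- toy_matrix(rbind(profile + rnorm(50, 0, 0.1), rnorm(50)),
                   genes = c("hA_1", "hB_1"), lines = paste0("l", 1:50))
  map_a <- data.frame(sgrna = rownames(fa), gene = c("G", "G", "H", "H"),
                      library = "A")
  map_b <- data.frame(sgrna = rownames(fb), gene = c("G", "H"), library = "B")
  cc <- cotargeting_correlations(fa, fb, map_a, map_b)
  g <- cc[cc$gene == "G", ]
  expect_equal(g$within_a, 1) # duplicated identical guides
  expect_gt(g$between, 0.9)
  h <- cc[cc$gene == "H", ]
  expect_lt(abs(h$within_a), 0.35) # independent noise guides
  expect_true(is.na(g$within_b))   # single guide per gene in study B
})

test_that("MESE is the per-gene per-library median efficacy", {
  map <- data.frame(sgrna = paste0("s", 1:6),
                    gene = c("G", "G", "G", "H", "G", "H"),
                    library = c("A", "A", "A", "A", "B", "B"),
                    efficacy = c(0.2, 0.6, 0.9, 0.5, 0.7, NA))
  m <- mese(map)
  expect_equal(m$mese[m$gene == "G" & m$library == "A"], 0.6)
  expect_equal(m$mese[m$gene == "H" & m$library == "A"], 0.5)
  expect_equal(m$mese[m$gene == "G" & m$library == "B"], 0.7)
  expect_true(is.na(m$mese[m$gene == "H" & m$library == "B"]))
})

test_that("efficacy-difference filter removes outlying exclusive genes", {
  set.seed(35)
  genes <- sprintf("g%03d", 1:100)
  eff_a <- setNames(runif(100, 0.5, 0.9), genes)
  eff_b <- eff_a + rnorm(100, 0, 0.02)
  excl_a <- genes[1:6]; excl_b <- genes[7:12]
  eff_b[genes[1]] <- eff_a[genes[1]] - 0.5 # planted 3-sigma-plus outlier
  res <- efficacy_difference_filter(eff_a, eff_b, excl_a, excl_b)
  expect_false(genes[1] %in% res$exclusive_a)
  expect_true(genes[1] %in% res$removed)
  # brute-force recomputation
  diffs <- eff_a - eff_b
  null <- diffs[setdiff(genes, c(excl_a, excl_b))]
  keep_a <- excl_a[abs(diffs[excl_a] - mean(null)) <= 2 * sd(null)]
  expect_setequal(res$exclusive_a, keep_a)
  # identical efficacies are always retained
  res2 <- efficacy_difference_filter(eff_a, eff_a, excl_a, excl_b)
  expect_setequal(res2$exclusive_a, excl_a)
})

test_that("exclusive-dependency enrichment flags the planted late set", {
  set.seed(36)
  genes <- sprintf("g%03d", 1:120)
  late <- genes[1:20]
  lines <- paste0("l", 1:8)
  ca <- matrix(runif(120 * 8) < 0.1, 120, 8, dimnames = list(genes, lines))
  cb <- ca
  cb[late, ] <- TRUE # study-B-exclusive late dependencies
  ca[late, ] <- FALSE
  sets <- list(late_set = late, other = genes[50:70])
  res <- exclusive_dependency_enrichment(ca, cb, sets)
  summ <- res$summary
  frac <- summ$frac_lines_enriched[summ$study == "B" & summ$set == "late_set"]
  expect_gt(frac, 0.9)
  # identical calls produce no exclusive genes at all
  res2 <- exclusive_dependency_enrichment(cb, cb, sets)
  expect_equal(nrow(res2$tests), 0)
  # empty overlap gives p = 1
  res3 <- exclusive_dependency_enrichment(ca, cb, list(off = "not_a_gene"))
  expect_equal(nrow(res3$tests), 0)
})

test_that("resampling test recovers planted time-point effects", {
  set.seed(37)
  genes <- sprintf("g%04d", 1:600)
  means_a <- setNames(rnorm(600, -0.2, 0.2), genes)
  means_b <- means_a + rnorm(600, 0, 0.05)
  late <- genes[1:30]; early <- genes[31:120]
  means_b[late] <- means_b[late] - 0.4
  lt <- early_late_resampling_test(means_a, means_b, late, n_perm = 2000)
  et <- early_late_resampling_test(means_a, means_b, early, n_perm = 2000)
  expect_lt(lt$p_gaussian, 1e-3)
  expect_lt(lt$p_empirical, 2 / 2000)
  expect_gt(et$p_gaussian, 0.05)
  expect_equal(lt$delta,
               median(means_a[late]) - median(means_b[late]))
  # identical studies: delta 0, p near 1
  same <- early_late_resampling_test(means_a, means_a, late, n_perm = 500)
  expect_equal(same$delta, 0)
  expect_gt(same$p_empirical, 0.5)
  expect_error(early_late_resampling_test(means_a, means_b, "nope"), "absent")
})

test_that("gaussian and empirical resampling p agree for moderate effects", {
  set.seed(38)
  genes <- sprintf("g%04d", 1:500)
  means_a <- setNames(rnorm(500, 0, 0.3), genes)
  means_b <- means_a + rnorm(500, 0, 0.1)
  agree <- 0
  for (i in 1:12) {
    set <- sample(genes, 25)
    r <- early_late_resampling_test(means_a, means_b, set, n_perm = 2000)
    if (r$p_empirical > 0.01 && r$p_empirical < 0.5) {
      ratio <- r$p_gaussian / r$p_empirical
      expect_gt(ratio, 0.5 * 0.8)
      expect_lt(ratio, 2 / 0.8)
    }
  }
})

test_that("condition difference profiles are single-condition and anti-symmetric", {
  set.seed(39)
  genes <- sprintf("g%02d", 1:40)
  m <- toy_matrix(matrix(rnorm(40 * 5), 40, 5), genes = genes,
                  lines = c("s1", "s2", "s3", "s4", "s5"))
  meta <- data.frame(screen = colnames(m),
                     cell_line = c("HT29", "HT29", "HT29", "HT29", "JIMT1"),
                     library = c("KY", "AV", "KY", "AV", "KY"),
                     timepoint = c(14, 14, 21, 14, 14),
                     clone = "c1", site = "here")
  res <- condition_difference_analysis(m, meta)
  # valid contrasts: s1-s2 (library), s1-s3 (timepoint), s2-s4 identical
  # screens differ in nothing -> excluded; s5 differs in cell line -> excluded
  expect_true(all(res$contrasts$condition %in% c("library", "timepoint")))
  expect_false(any(res$contrasts$cell_line == "JIMT1"))
  lib_contrast <- res$profiles[, res$contrasts$condition == "library", drop = FALSE]
  expect_equal(lib_contrast[, 1], m[, "s1"] - m[, "s2"]) # KY minus AV (sorted levels)
  # identical screens give a zero profile and zero variance vs reference
  m2 <- toy_matrix(cbind(m[, 1], m[, 1]), genes = genes, lines = c("x", "y"))
  meta2 <- data.frame(screen = c("x", "y"), cell_line = "HT29",
                      library = c("KY", "AV"), timepoint = 14,
                      clone = "c1", site = "here")
  res2 <- condition_difference_analysis(m2, meta2, reference = "x")
  expect_equal(unname(res2$profiles[, 1]), rep(0, 40))
  expect_equal(res2$detrending$sd_difference, 0)
  expect_error(condition_difference_analysis(m[, 4:5], meta[4:5, ]), "no screen pairs")
})
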