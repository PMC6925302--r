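test_that("feature prevalence filter keeps the documented boundaries", {
  f <- toy_matrix(rbind(c(1, 1, 0, 0, 0, 0), c(1, 1, 1, 0, 0, 0),
                        c(1, 1, 1, 1, 1, 0), c(1, 1, 1, 1, 1, 1)),
                  genes = c("two", "three", "five", "six"))
  kept <- filter_features(f, min_pos = 3, max_pos = 6)
  expect_setequal(rownames(kept), c("three", "five"))
  expect_error(filter_features(f * 2), "binary")
})

test_that("differential dependency matches the equal-variance t-test", {
  set.seed(23)
  scores <- toy_matrix(matrix(rnorm(3 * 12), 3, 12), genes = paste0("G", 1:3))
  feats <- toy_matrix(rbind(rep(c(1, 0), c(5, 7)), rep(c(0, 1), c(8, 4))),
                      genes = c("F1", "F2"), lines = colnames(scores))
  tab <- differential_dependency(scores, feats)
  for (i in seq_len(nrow(tab))) {
    pos <- feats[tab$feature[i], ] == 1
    tt <- t.test(scores[tab$gene[i], pos], scores[tab$gene[i], !pos],
                 var.equal = TRUE)
    expect_equal(tab$t[i], unname(tt$statistic))
    expect_equal(tab$p[i], tt$p.value)
    # Cohen's delta from the textbook pooled-SD formula
    n1 <- sum(pos); n0 <- sum(!pos)
    sp <- sqrt(((n1 - 1) * var(scores[tab$gene[i], pos]) +
                (n0 - 1) * var(scores[tab$gene[i], !pos])) / (n1 + n0 - 2))
    expect_equal(tab$dfc[i],
                 (mean(scores[tab$gene[i], pos]) -
                  mean(scores[tab$gene[i], !pos])) / sp)
  }
  expect_equal(tab$fdr, p.adjust(tab$p, "BH"))
})

test_that("a clean separation is significant and identical groups are not", {
  set.seed(24)
  lines <- paste0("l", 1:12)
  sep <- toy_matrix(matrix(c(rep(-2, 4), rep(0, 8)) + rnorm(12, 0, 0.01), 1, 12),
                    genes = "G", lines = lines)
  feats <- toy_matrix(matrix(rep(c(1, 0), c(4, 8)), 1), genes = "F",
                      lines = lines)
  tab <- differential_dependency(sep, feats)
  expect_lt(tab$p, 1e-10)
  expect_lt(tab$dfc, -1.9 / 0.011 * 0.001) # strongly negative
  expect_true(tab$significant)
  same <- toy_matrix(matrix(rnorm(12), 1, 12), genes = "G", lines = lines)
  tab2 <- differential_dependency(same, feats)
  expect_gt(abs(tab2$dfc), 0) # finite, small
  expect_false(tab2$significant && tab2$dfc < -1 && tab2$p < 1e-4)
})

test_that("expression-dependency correlation uses the n-2 df t mapping", {
  set.seed(25)
  n <- 20
  dep <- toy_matrix(matrix(rnorm(n), 1, n), genes = "SSD1")
  expr <- toy_matrix(rbind(dep[1, ] * 2 + 3, rnorm(n)),
                     genes = c("per", "rand"), lines = colnames(dep))
  tab <- expression_dependency_correlation(expr, dep)
  perfect <- tab[tab$expr_gene == "per", ]
  expect_equal(perfect$r, 1)
  expect_lt(perfect$p, 1e-12)
  rnd <- tab[tab$expr_gene == "rand", ]
  r <- cor(expr["rand", ], dep[1, ])
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(rnd$p, 2 * pt(-abs(tstat), n - 2))
  # documented mapping at r = 0.5, n = 147
  r <- 0.5; n2 <- 147
  expect_equal(r * sqrt((n2 - 2) / (1 - r^2)), 0.5 * sqrt(145 / 0.75))
})

test_that("q-values are monotone in p order and bounded", {
  set.seed(26)
  p <- c(runif(900), rbeta(100, 0.2, 8))
  q <- qvalue_storey(p)
  expect_true(all(q >= 0 & q <= 1))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  # q-values shrink p toward the estimated null fraction: under a dense
  # signal, q < BH-adjusted p
  expect_true(mean(q[o][1:100] <= p.adjust(p, "BH")[o][1:100]) == 1)
})

test_that("variable-expression selection intersects per-study top-k sets", {
  set.seed(27)
  e <- toy_matrix(matrix(rnorm(200), 20, 10),
                  genes = sprintf("E%02d", 1:20))
  expect_length(select_variable_expression(e, e, k = 5), 5)
  expect_setequal(select_variable_expression(e, e, k = 30), rownames(e))
  # disjoint variability gives a small intersection
  e2 <- e
  v <- apply(e, 1, var)
  top <- names(sort(v, decreasing = TRUE))[1:5]
  e2[top, ] <- matrix(rnorm(50, 0, 1e-3), 5, 10)
  expect_lt(length(select_variable_expression(e, e2, k = 5)), 5)
})

test_that("planted biomarker and expression correlates are recovered", {
  sim <- small_sim()
  truth <- sim$truth
  sc <- score_matrix(sim_scores(sim, "study_a"))
  feats <- filter_features(sim$features, 3, ncol(sc) - 3)
  tab <- differential_dependency(sc[truth$ssd_genes, , drop = FALSE], feats)
  for (g in truth$ssd_genes) {
    hit <- tab[tab$feature == paste0("F_", g) & tab$gene == g, ]
    expect_true(hit$significant)
  }
  ec <- expression_dependency_correlation(sim$expression$A,
                                          sc[truth$ssd_genes, , drop = FALSE])
  for (g in truth$ssd_expression_genes) {
    hit <- ec[ec$expr_gene == g & ec$dep_gene == g, ]
    expect_lt(hit$q, 0.05)
    # a positive planted sign means expression tracks the dependency score
    expect_equal(sign(hit$r), unname(truth$ssd_expression_sign[g]))
  }
})

test_that("cross-study recovery is perfect for identical tables, chance for noise", {
  set.seed(28)
  n <- 400
  tab <- data.frame(feature = rep(sprintf("F%02d", 1:20), each = 20),
                    gene = rep(sprintf("G%02d", 1:20), times = 20),
                    p = runif(n))
  tab$p[1:30] <- tab$p[1:30] / 1e4
  tab$fdr <- p.adjust(tab$p, "BH")
  rec <- cross_study_recovery(tab, tab)
  for (q in rec$a_to_b) {
    expect_equal(q$auroc, 1)
    expect_equal(q$curve$precision[q$n_pos], 1)
  }
  # independent p-values: AUROC near 0.5
  tab2 <- tab; tab2$p <- runif(n); tab2$fdr <- p.adjust(tab2$p, "BH")
  rec2 <- cross_study_recovery(tab, tab2)
  expect_gt(rec2$a_to_b$q100$auroc, 0.35)
  expect_lt(rec2$a_to_b$q100$auroc, 0.65)
  # correlated studies: the most significant associations are the most
  # recoverable, so stricter quantiles do at least as well
  tab3 <- tab
  tab3$p <- pmin(1, tab$p * exp(rnorm(n, 0, 1)))
  tab3$fdr <- p.adjust(tab3$p, "BH")
  rec3 <- cross_study_recovery(tab, tab3)
  expect_gte(rec3$a_to_b$q20$auroc, rec3$a_to_b$q100$auroc - 0.05)
})
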