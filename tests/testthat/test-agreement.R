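test_that("correlation suite recovers exact relationships", {
  set.seed(14)
  a <- toy_matrix(matrix(rnorm(40), 4, 10))
  cs <- correlation_suite(a, a)
  expect_equal(cs$overall_pearson, 1)
  expect_equal(cs$overall_spearman, 1)
  expect_equal(cs$per_gene$r, rep(1, 4))
  expect_equal(cs$gene_mean_pearson, 1)
  expect_equal(correlation_suite(a, -a)$overall_pearson, -1)
  # per-gene correlations against the closed-form Pearson
  b <- toy_matrix(matrix(rnorm(40), 4, 10), genes = rownames(a))
  pg <- correlation_suite(a, b)$per_gene$r
  manual <- vapply(1:4, function(i) {
    x <- a[i, ]; y <- b[i, ]
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }, numeric(1))
  expect_equal(pg, manual)
  # constant profile reported as missing
  a2 <- a; a2[2, ] <- 1
  expect_true(is.na(correlation_suite(a2, b)$per_gene$r[2]))
})

test_that("kappa matches the hand-computed 2x2 example and brute force", {
  # table [[20,5],[3,72]]: p_o = 0.92, p_e = 0.635, kappa = 0.781
  x <- rep(c(TRUE, TRUE, FALSE, FALSE), c(20, 5, 3, 72))
  y <- rep(c(TRUE, FALSE, TRUE, FALSE), c(20, 5, 3, 72))
  expect_equal(cohens_kappa(x, y), (0.92 - 0.635) / (1 - 0.635))
  expect_equal(round(cohens_kappa(x, y), 3), 0.781)
  expect_equal(cohens_kappa(x, x), 1)
  expect_true(is.na(cohens_kappa(rep(TRUE, 5), rep(TRUE, 5))))
  # brute force from the definition on random vectors
  set.seed(15)
  for (i in 1:25) {
    x <- runif(40) < 0.4; y <- runif(40) < 0.4
    p_o <- mean(x == y)
    p_e <- mean(x) * mean(y) + mean(!x) * mean(!y)
    expect_equal(cohens_kappa(x, y), (p_o - p_e) / (1 - p_e))
  }
})

test_that("two-sided Fisher p matches exhaustive table enumeration", {
  # [[2,0],[0,2]] -> 1/3 by direct enumeration of fixed-margin tables
  ca <- toy_matrix(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  cb <- toy_matrix(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  expect_equal(binarized_agreement(ca, cb, per_gene = FALSE)$fisher_p, 1 / 3)
  enumerate_p <- function(tab) {
    rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
    probs <- vapply(max(0, rs[1] + cs[1] - n):min(rs[1], cs[1]), function(a) {
      choose(cs[1], a) * choose(cs[2], rs[1] - a) / choose(n, rs[1])
    }, numeric(1))
    obs <- choose(cs[1], tab[1, 1]) * choose(cs[2], tab[1, 2]) / choose(n, rs[1])
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
  set.seed(16)
  for (i in 1:25) {
    va <- runif(30) < 0.3; vb <- runif(30) < 0.3
    tab <- table(factor(va, c(TRUE, FALSE)), factor(vb, c(TRUE, FALSE)))
    got <- binarized_agreement(matrix(va, 5), matrix(vb, 5),
                               per_gene = FALSE)$fisher_p
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      expect_equal(got, 1)
    } else {
      expect_equal(got, enumerate_p(tab), tolerance = 1e-7)
    }
  }
})

test_that("AUROC equals the brute-force pairwise probability", {
  set.seed(17)
  for (i in 1:25) {
    scores <- round(rnorm(30), 1) # ties on purpose
    labels <- runif(30) < 0.4
    if (!any(labels) || all(labels)) next
    pos <- scores[labels]; neg <- scores[!labels]
    brute <- mean(outer(pos, neg, function(p, q) (p < q) + 0.5 * (p == q)))
    expect_equal(auroc(scores, labels), brute)
  }
})

test_that("binarized agreement reports precision/recall and AUROC", {
  ca <- toy_matrix(matrix(c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE), 3, 2))
  m <- binarized_agreement(ca, ca)
  expect_equal(m$kappa, 1)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  sc <- toy_matrix(matrix(c(-2, -1.5, 0.2, 0.4, -1.2, 0.5), 3, 2))
  m2 <- binarized_agreement(ca, ca, scores_a = sc)
  expect_equal(m2$auroc_a_predicts_b, 1) # calls exactly the lowest scores
})

test_that("counterpart recall is exact for identical studies and ~0.5 when shuffled", {
  set.seed(18)
  a <- toy_matrix(matrix(rnorm(300), 15, 20))
  rc <- knn_recall_nauc(a, a)
  expect_equal(rc$recall[1], 100)
  expect_equal(rc$nauc, 1)
  expect_equal(rc$top1, 40)
  expect_true(all(diff(rc$recall) >= 0))
  expect_equal(rc$recall[length(rc$recall)], 100)
  # destroy the counterpart structure: study b is unrelated noise
  b <- toy_matrix(matrix(rnorm(300), 15, 20))
  rc2 <- knn_recall_nauc(a, b)
  # counterpart ranks are then uniform on 1..2n-1: nAUC ~ 0.5
  expect_gt(rc2$nauc, 0.35); expect_lt(rc2$nauc, 0.65)
  expect_error(knn_recall_nauc(a, b[, c(1, 1:19)]), "duplicate|aligned")
})

test_that("nAUC is invariant to profile order", {
  set.seed(19)
  a <- toy_matrix(matrix(rnorm(200), 10, 20))
  b <- a + toy_matrix(matrix(rnorm(200, 0, 0.5), 10, 20))
  perm <- sample(20)
  rc1 <- knn_recall_nauc(a, b)
  rc2 <- knn_recall_nauc(a[, perm], b[, perm])
  expect_equal(rc2$nauc, rc1$nauc)
})

test_that("per-line Jaccard follows the set formula", {
  genes <- c("a", "b", "c", "d")
  ca <- toy_matrix(matrix(c(TRUE, TRUE, TRUE, FALSE), 4, 1), genes = genes)
  cb <- toy_matrix(matrix(c(FALSE, TRUE, TRUE, TRUE), 4, 1), genes = genes)
  j <- per_line_jaccard(ca, cb)
  expect_equal(j$jaccard, 0.5) # {a,b,c} vs {b,c,d}
  expect_equal(per_line_jaccard(ca, ca)$jaccard, 1)
  cc <- toy_matrix(matrix(c(FALSE, FALSE, FALSE, TRUE), 4, 1), genes = genes)
  cd <- toy_matrix(matrix(c(TRUE, TRUE, FALSE, FALSE), 4, 1), genes = genes)
  expect_equal(per_line_jaccard(cc, cd)$jaccard, 0)
  empty <- toy_matrix(matrix(FALSE, 4, 1), genes = genes)
  expect_warning(je <- per_line_jaccard(empty, empty), "no calls")
  expect_equal(je$jaccard, 1)
  expect_true(je$both_empty)
})

test_that("quality-agreement regression matches closed-form OLS", {
  tpr_a <- c(l1 = 0.5, l2 = 0.6, l3 = 0.7, l4 = 0.8, l5 = 0.9)
  tpr_b <- c(l1 = 0.5, l2 = 0.7, l3 = 0.6, l4 = 0.9, l5 = 0.8)
  agreement <- c(l1 = 0.31, l2 = 0.42, l3 = 0.38, l4 = 0.55, l5 = 0.58)
  res <- quality_vs_agreement(tpr_a, tpr_b, agreement)
  x <- (tpr_a + tpr_b) / 2
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% agreement)
  expect_equal(res$slope, beta[2], ignore_attr = TRUE)
  resid <- agreement - X %*% beta
  s2 <- sum(resid^2) / 3
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  expect_equal(res$p, 2 * pt(-abs(beta[2] / se), df = 3), ignore_attr = TRUE)
  # exact linear relationship gives adjusted R-squared 1
  res2 <- suppressWarnings(quality_vs_agreement(tpr_a, tpr_b, 0.2 + 0.5 * x))
  expect_equal(res2$adj_r_squared, 1)
  const <- setNames(rep(0.5, 5), names(tpr_a))
  expect_error(quality_vs_agreement(const, const, agreement), "constant")
})
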