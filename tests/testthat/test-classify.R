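make_groups <- function(n_per = 4, k = 3, p = 3, sep = 10, sd = 1, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(k * p, 0, sep), k, p)
  X <- do.call(rbind, lapply(seq_len(k), function(g) {
    sweep(matrix(rnorm(n_per * p, 0, sd), n_per, p), 2, centers[g, ], "+")
  }))
  rownames(X) <- sprintf("G%02d", seq_len(nrow(X)))
  colnames(X) <- paste0("t", seq_len(p))
  list(X = X, labels = rep(paste0("C", seq_len(k)), each = n_per))
}

test_that("well-separated groups are recovered exactly by Ward clustering", {
  gr <- make_groups(n_per = 4, k = 5, p = 4, sep = 10, sd = 1, seed = 2)
  colnames(gr$X)[1] <- "GY"
  cl <- ward_cluster(gr$X, k = 5)
  expect_equal(rand_adjusted(cl$cluster, gr$labels), 1)
  # category naming is a bijection ordered by the yield column
  expect_setequal(unique(cl$category), c("HT", "T", "M", "S", "HS"))
  cat_means <- tapply(gr$X[, "GY"], cl$category, mean)
  expect_equal(names(sort(cat_means, decreasing = TRUE)),
               c("HT", "T", "M", "S", "HS"))
  # standardized matrix has unit columns; heatmap export is clipped
  expect_equal(unname(colMeans(cl$z)), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(apply(cl$z, 2, sd)), rep(1, 4), tolerance = 1e-10)
  expect_true(all(abs(cl$heatmap) <= 3))
  # row order invariance of the partition
  perm <- sample(nrow(gr$X))
  cl2 <- ward_cluster(gr$X[perm, ], k = 5)
  expect_equal(rand_adjusted(cl2$category[rownames(gr$X)], cl$category), 1)
})

test_that("duplicated rows merge at height zero", {
  gr <- make_groups(n_per = 3, k = 2, p = 3, seed = 3)
  X <- rbind(gr$X, dup = gr$X[1, ])
  tree <- hclust(dist(scale(X)), method = "ward.D2")
  expect_equal(min(tree$height), 0)
})

test_that("LDA separates distant groups and yields coherent posteriors", {
  gr <- make_groups(n_per = 5, k = 2, p = 1, sep = 10, sd = 1, seed = 4)
  fit <- lda_fit(gr$X, gr$labels)
  res <- lda_classify(fit, gr$X, prior_labels = gr$labels)
  expect_equal(attr(res, "percent_correct"), 100)
  P <- as.matrix(res[, fit$levels])
  expect_equal(unname(rowSums(P)), rep(1, 10), tolerance = 1e-10)
  expect_equal(res$posterior,
               fit$levels[max.col(P, ties.method = "first")])
  # an observation at a group mean with equal priors belongs to that group
  fit_eq <- lda_fit(gr$X, gr$labels, prior = "equal")
  at_mean <- matrix(fit_eq$means["C1", ], 1)
  expect_equal(lda_classify(fit_eq, at_mean)$posterior, "C1")
})

test_that("identical group distributions give posteriors near the priors", {
  post <- matrix(0, 200, 2)
  for (s in 1:200) {
    set.seed(700 + s)
    X <- matrix(rnorm(30), 30, 1, dimnames = list(NULL, "t"))
    labels <- rep(c("A", "B"), c(20, 10))
    fit <- lda_fit(X, labels)
    res <- lda_classify(fit, X)
    post[s, ] <- colMeans(as.matrix(res[, c("A", "B")]))
  }
  expect_equal(colMeans(post), c(2 / 3, 1 / 3), tolerance = 0.05)
})

test_that("a wide trait panel is handled by the pseudo-inverse at full agreement", {
  # 20 predictors, 20 observations, 5 groups: the pooled covariance is
  # singular, yet resubstitution should be perfect for separated groups
  gr <- make_groups(n_per = 4, k = 5, p = 20, sep = 5, sd = 1, seed = 5)
  expect_message(fit <- lda_fit(gr$X, gr$labels), "pseudo-inverse")
  expect_true(fit$pseudo_inverse)
  res <- lda_classify(fit, gr$X, prior_labels = gr$labels)
  expect_equal(attr(res, "percent_correct"), 100)
})

test_that("LDA decisions are invariant to affine predictor transformations", {
  gr <- make_groups(n_per = 6, k = 3, p = 3, sep = 3, sd = 1, seed = 6)
  fit1 <- lda_fit(gr$X, gr$labels)
  A <- matrix(c(2, 0.5, 0, 0, 1, 0.3, 0, 0, 1.5), 3, 3)
  Xt <- gr$X %*% A + matrix(rep(c(5, -2, 1), each = nrow(gr$X)), ncol = 3)
  colnames(Xt) <- colnames(gr$X)
  fit2 <- lda_fit(Xt, gr$labels)
  expect_equal(lda_classify(fit2, Xt)$posterior,
               lda_classify(fit1, gr$X)$posterior)
})

test_that("leave-one-out matches a brute-force refit loop and the optimism property", {
  gr <- make_groups(n_per = 4, k = 5, p = 3, sep = 2.5, sd = 1, seed = 7)
  loo <- lda_loo(gr$X, gr$labels)
  # brute-force oracle: explicit refit per fold
  manual <- vapply(seq_len(nrow(gr$X)), function(i) {
    fit <- lda_fit(gr$X[-i, ], gr$labels[-i])
    lda_classify(fit, gr$X[i, , drop = FALSE])$posterior
  }, "")
  expect_equal(loo$posterior, manual)

  # independent oracle for resubstitution: MASS::lda on the same data
  fit <- lda_fit(gr$X, gr$labels)
  res <- lda_classify(fit, gr$X, prior_labels = gr$labels)
  mass <- MASS::lda(gr$X, grouping = factor(gr$labels))
  expect_equal(res$posterior,
               as.character(predict(mass, gr$X)$class))

  # LOO accuracy does not beat resubstitution on average
  deltas <- vapply(1:40, function(s) {
    g2 <- make_groups(n_per = 4, k = 3, p = 2, sep = 1.5, sd = 1,
                      seed = 900 + s)
    r <- lda_classify(lda_fit(g2$X, g2$labels), g2$X,
                      prior_labels = g2$labels)
    l <- lda_loo(g2$X, g2$labels)
    attr(r, "percent_correct") - attr(l, "percent_correct")
  }, 0)
  expect_gte(mean(deltas), 0)

  # perfectly separable and well-replicated: LOO equals resubstitution
  g3 <- make_groups(n_per = 10, k = 3, p = 2, sep = 20, sd = 1, seed = 8)
  r3 <- lda_classify(lda_fit(g3$X, g3$labels), g3$X, prior_labels = g3$labels)
  l3 <- lda_loo(g3$X, g3$labels)
  expect_equal(attr(l3, "percent_correct"), attr(r3, "percent_correct"))
})

test_that("randomized labels score near the largest-group frequency", {
  gr <- make_groups(n_per = 5, k = 2, p = 2, sep = 4, sd = 1, seed = 9)
  labels <- rep(c("A", "B"), c(7, 3))
  acc <- vapply(1:200, function(s) {
    set.seed(1500 + s)
    shuf <- sample(labels)
    r <- lda_classify(lda_fit(gr$X, shuf), gr$X, prior_labels = shuf)
    attr(r, "percent_correct")
  }, 0)
  expect_lt(abs(mean(acc) - 70), 12)
})

test_that("agreement tables count moves and reproduce the published misfits", {
  expect_equal(agreement_table(c("A", "B"), c("A", "B"))$percent_correct, 100)
  a <- agreement_table(rep("A", 20), c(rep("A", 19), "B"))
  expect_equal(a$percent_correct, 95)
  expect_error(agreement_table("A", c("A", "B")),
               class = "stressmet_format_error")

  lab <- reference_table("lda_labels")
  ag <- agreement_table(lab$prior, lab$posterior, labels = lab$genotype)
  expect_equal(ag$percent_correct, 75)
  expect_setequal(ag$moved$label, c("G04", "G07", "G12", "G17", "G20"))
})
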