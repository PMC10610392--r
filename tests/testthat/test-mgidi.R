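test_that("rescaling is a sense-oriented linear map onto 0..100", {
  X <- cbind(a = c(1, 2, 3), b = c(1, 2, 3))
  senses <- c(a = "increase", b = "decrease")
  R <- rescale_traits(X, senses)
  expect_equal(unname(R[, "a"]), c(0, 50, 100))
  expect_equal(unname(R[, "b"]), c(100, 50, 0))
  # idempotent on already-rescaled increase-sense data
  R2 <- rescale_traits(R, c(a = "increase", b = "increase"))
  expect_equal(unname(R2), unname(R), ignore_attr = TRUE)
  # constant columns are dropped with a warning
  X2 <- cbind(a = c(1, 2, 3), c = c(5, 5, 5))
  expect_warning(R3 <- rescale_traits(X2, c(a = "increase", c = "increase")),
                 "constant")
  expect_equal(colnames(R3), "a")
})

test_that("factor analysis retains Kaiser factors and recovers planted blocks", {
  # two orthogonal planted factors over six traits
  set.seed(5)
  n <- 60
  f1 <- rnorm(n); f2 <- rnorm(n)
  X <- cbind(t1 = f1 + rnorm(n, 0, 0.3), t2 = f1 + rnorm(n, 0, 0.3),
             t3 = f1 + rnorm(n, 0, 0.3), t4 = f2 + rnorm(n, 0, 0.3),
             t5 = f2 + rnorm(n, 0, 0.3), t6 = f2 + rnorm(n, 0, 0.3))
  m <- trait_factor_analysis(X)
  expect_equal(m$n_factors, 2)
  expect_equal(m$communality + m$uniqueness, rep(1, 6),
               tolerance = 1e-6, ignore_attr = TRUE)
  L <- abs(m$loadings)
  block1 <- apply(L[1:3, ], 1, which.max)
  block2 <- apply(L[4:6, ], 1, which.max)
  expect_equal(length(unique(block1)), 1)
  expect_equal(length(unique(block2)), 1)
  expect_false(block1[1] == block2[1])
  # cross-loadings stay small
  for (i in 1:6) expect_lt(min(L[i, ]), 0.2)
})

test_that("retention follows the eigenvalue > 1 rule on the published spectra", {
  ev <- reference_table("fa_eigenvalues")
  expect_equal(sum(ev$eigenvalue[ev$panel == "gy_panel"] > 1), 2)
  expect_equal(sum(ev$eigenvalue[ev$panel == "all_traits"] > 1), 8)
  # the rule as implemented: planted one-factor data retain one factor
  set.seed(6)
  f <- rnorm(40)
  X1 <- cbind(a = f + rnorm(40, 0, .2), b = f + rnorm(40, 0, .2),
              c = f + rnorm(40, 0, .2))
  expect_equal(trait_factor_analysis(X1)$n_factors, 1)
})

test_that("the ideotype is at distance zero and selection size follows the intensity", {
  # one genotype holds the best value of every trait
  set.seed(8)
  X <- matrix(runif(20 * 5, 10, 20), 20, 5,
              dimnames = list(sprintf("G%02d", 1:20), paste0("t", 1:5)))
  X[7, ] <- 21
  senses <- setNames(rep("increase", 5), colnames(X))
  R <- rescale_traits(X, senses)
  m <- trait_factor_analysis(R)
  res <- mgidi_index(m, intensity = 0.2)
  expect_equal(res$table$mgidi[7], 0, tolerance = 1e-8)
  expect_equal(res$table$rank[7], 1)
  expect_equal(sum(res$table$selected), 4)  # 20 genotypes at 20%
  expect_true("G07" %in% res$selected)
  # distances match the Euclidean norm of the score gaps
  gaps <- sweep(m$scores, 2, res$ideotype_scores)
  expect_equal(res$table$mgidi, unname(sqrt(rowSums(gaps^2))))
})

test_that("MGIDI ranking is invariant to per-trait affine rescaling of the input", {
  set.seed(9)
  X <- matrix(rnorm(15 * 4, 50, 10), 15, 4,
              dimnames = list(sprintf("G%02d", 1:15), paste0("t", 1:4)))
  senses <- setNames(rep(c("increase", "decrease"), 2), colnames(X))
  r1 <- mgidi_index(trait_factor_analysis(rescale_traits(X, senses)))
  X2 <- sweep(sweep(X, 2, c(2, 0.5, 10, 1), "*"), 2, c(3, -7, 0, 100), "+")
  r2 <- mgidi_index(trait_factor_analysis(rescale_traits(X2, senses)))
  expect_equal(r2$table$mgidi, r1$table$mgidi, tolerance = 1e-8)
  expect_equal(r2$table$rank, r1$table$rank)
})

test_that("a planted globally superior genotype is almost always ranked first", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    X <- matrix(rnorm(12 * 4, 50, 5), 12, 4,
                dimnames = list(sprintf("G%02d", 1:12), paste0("t", 1:4)))
    X[3, ] <- X[3, ] + 12   # ~2.4 SD better on every trait
    senses <- setNames(rep("increase", 4), colnames(X))
    res <- mgidi_index(trait_factor_analysis(rescale_traits(X, senses)))
    if (res$table$rank[3] == 1) hits <- hits + 1L
  }
  expect_gte(hits, 95)
})

test_that("selection gains follow the differential times heritability", {
  means <- cbind(a = c(10, 12, 14, 16), b = c(8, 6, 4, 2))
  rownames(means) <- paste0("G", 1:4)
  senses <- c(a = "increase", b = "decrease")
  h2 <- c(a = 1, b = 0.5)
  # selecting everyone: zero differential
  g_all <- selection_gains(means, paste0("G", 1:4), h2, senses)
  expect_equal(g_all$SD, c(0, 0))
  # h2 = 1 and a 10% better selected mean: gain 10%
  g <- selection_gains(means, c("G3", "G4"), c(a = 1, b = 1), senses)
  expect_equal(g$SG_pct[g$trait == "a"],
               100 * (15 - 13) / 13, tolerance = 1e-10)
  # decrease-sense trait with negative differential is a desired gain
  expect_true(g$desired[g$trait == "b"])
  expect_lt(attr(g, "totals")[["decrease"]], 0)
})

test_that("factor contributions are squared-gap shares summing to one", {
  set.seed(10)
  X <- matrix(runif(10 * 6, 0, 100), 10, 6,
              dimnames = list(paste0("G", 1:10), paste0("t", 1:6)))
  m <- trait_factor_analysis(X)
  res <- mgidi_index(m)
  contrib <- factor_contributions(res)
  tot <- tapply(contrib$share, contrib$genotype, sum)
  expect_equal(as.numeric(tot), rep(1, 10), tolerance = 1e-10)
  # shares proportional to squared gaps
  g1 <- contrib[contrib$genotype == "G1", ]
  expect_equal(g1$share[order(g1$factor)],
               unname(res$gaps["G1", ]^2 / sum(res$gaps["G1", ]^2)),
               tolerance = 1e-10)
})

test_that("the full MGIDI workflow selects the planted tolerant group", {
  groups <- list(HT = c(drought = 0.95, heat = 0.92),
                 S = c(drought = 0.70, heat = 0.64))
  cfg <- sim_config(n_genotypes = 10, n_reps = 2,
                    traits = quiet_traits(4), group_effects = groups,
                    group_of = rep(c("HT", "S"), each = 5),
                    tol_sd = 0.01, tol_gei_sd = 0.01, seed = 33)
  d <- generate_met(cfg)
  idx <- build_index_environments(d)
  traits <- unique(idx$trait)
  gmeans <- sapply(traits, function(tr) {
    tapply(idx$index[idx$trait == tr], idx$genotype[idx$trait == tr], mean)
  })
  senses <- setNames(rep("increase", length(traits)), traits)
  mg <- run_mgidi(gmeans, senses, intensity = 0.2,
                  h2mg = setNames(rep(0.8, length(traits)), traits))
  expect_true(all(mg$index$selected %in% sprintf("G%02d", 1:5)))
  expect_true(all(mg$gains$desired))
})
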