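test_that("joint ANOVA reproduces the factorial degrees of freedom and SS additivity", {
  tab <- simulate_index_table(g = 20, e = 6, r = 3, seed = 4)
  a <- joint_anova(tab, "GY")
  expect_equal(a$df[a$source == "GEN"], 19)
  expect_equal(a$df[a$source == "GEN:ENV"], 95)
  expect_equal(a$df[a$source == "Residuals"], 228)
  expect_equal(a$df[a$source == "ENV"], 5)
  expect_equal(a$df[a$source == "REP(ENV)"], 12)
  expect_equal(sum(a$df), 20 * 6 * 3 - 1)
  total_ss <- sum((tab$index - mean(tab$index))^2)
  expect_equal(sum(a$ss), total_ss, tolerance = 1e-8)
})

test_that("pure-noise data give genotype F statistics near 1 on average", {
  fs <- vapply(1:200, function(s) {
    tab <- simulate_index_table(g = 10, e = 4, r = 2, sd_g = 0, sd_e = 0,
                                sd_rep = 0, sd_ge = 0, sd_eps = 1, seed = s,
                                ge_mat = matrix(0, 10, 4))
    a <- joint_anova(tab, "GY")
    a$f[a$source == "GEN"]
  }, 0)
  # E[F(9, m)] = m/(m-2) with m = 30 residual df here, i.e. ~1.07
  expect_lt(abs(mean(fs) - 1), 0.15)
})

test_that("additive zero-noise data have zero interaction SS", {
  tab <- simulate_index_table(g = 8, e = 4, r = 2, sd_ge = 0, sd_eps = 0,
                              sd_rep = 0, seed = 2,
                              ge_mat = matrix(0, 8, 4))
  a <- joint_anova(tab, "GY")
  expect_equal(a$ss[a$source == "GEN:ENV"], 0, tolerance = 1e-20)
})

test_that("variance components follow the expected-mean-square solution", {
  # published grain-yield mean squares
  a <- tibble::tibble(
    source = c("ENV", "REP(ENV)", "GEN", "GEN:ENV", "Residuals"),
    df = c(5, 12, 19, 95, 228),
    ms = c(0.162, 0.0026, 0.117, 0.0217, 0.0027))
  a$ss <- a$ms * a$df; a$f <- NA; a$p <- NA
  vc <- variance_components(a, g = 20, e = 6, r = 3)
  expect_equal(vc$sigma2_g, (0.117 - 0.0217) / 18, tolerance = 1e-12)
  expect_equal(vc$sigma2_ge, 0.0063, tolerance = 0.01)
  expect_equal(vc$sigma2_e, 0.0027)
  expect_equal(vc$sigma2_p, vc$sigma2_g + vc$sigma2_ge + vc$sigma2_e)

  # MS_GE equal to MS_res forces a zero interaction component
  a2 <- a; a2$ms[4] <- a2$ms[5]
  expect_equal(variance_components(a2, 20, 6, 3)$sigma2_ge, 0)

  # negative solutions are truncated and flagged
  a3 <- a; a3$ms[4] <- 2; a3$ms[3] <- 1
  vc3 <- variance_components(a3, 20, 6, 3)
  expect_equal(vc3$sigma2_g, 0)
  expect_true("sigma2_g" %in% vc3$truncated)
})

test_that("genetic parameters match the reference yield-index values and limits", {
  vc <- list(sigma2_g = 0.0073, sigma2_ge = 0.0063, sigma2_e = 0.0007,
             sigma2_p = 0.0143)
  gp <- genetic_parameters(vc, e = 6, r = 3, grand_mean = 0.885)
  expect_equal(gp$H2, 0.51, tolerance = 0.02)
  expect_equal(gp$R2gei, 0.441, tolerance = 0.012)
  expect_equal(gp$As, sqrt(gp$h2mg))
  expect_equal(gp$CV_ratio, gp$CVg / gp$CVr)

  # noise-free limit
  gp0 <- genetic_parameters(list(sigma2_g = 1, sigma2_ge = 0, sigma2_e = 0,
                                 sigma2_p = 1), e = 6, r = 3, grand_mean = 1)
  expect_equal(gp0$H2, 1)
  expect_equal(gp0$h2mg, 1)
  expect_equal(gp0$As, 1)
})

test_that("variance components and h2mg are recovered from planted simulations", {
  planted <- c(g = 4, ge = 2, eps = 1)
  rel_err <- sapply(1:100, function(s) {
    tab <- simulate_index_table(g = 50, e = 6, r = 3, mu = 10,
                                sd_g = 2, sd_ge = sqrt(2), sd_eps = 1,
                                sd_e = 0.5, sd_rep = 0.1, seed = 1000 + s)
    a <- joint_anova(tab, "GY")
    vc <- variance_components(a)
    c(abs(vc$sigma2_g - 4) / 4, abs(vc$sigma2_ge - 2) / 2,
      abs(vc$sigma2_e - 1) / 1)
  })
  expect_lt(median(rel_err[1, ]), 0.25)
  expect_lt(median(rel_err[2, ]), 0.25)
  expect_lt(median(rel_err[3, ]), 0.25)

  # h2mg recovered within 0.05 of the planted-component value
  h2_planted <- 4 / (4 + 2 / 6 + 1 / 18)
  tab <- simulate_index_table(g = 50, e = 6, r = 3, mu = 10, sd_g = 2,
                              sd_ge = sqrt(2), sd_eps = 1, seed = 77)
  a <- joint_anova(tab, "GY")
  gp <- genetic_parameters(variance_components(a), e = 6, r = 3,
                           grand_mean = attr(a, "grand_mean"))
  expect_lt(abs(gp$h2mg - h2_planted), 0.05)
})

test_that("pre-tests behave under the null and under planted heteroscedasticity", {
  # null: normal residuals rarely rejected
  ps <- vapply(1:100, function(s) {
    tab <- simulate_index_table(g = 10, e = 6, r = 2, sd_eps = 1,
                                seed = 500 + s)
    index_pretests(tab, "GY")$shapiro_p
  }, 0)
  expect_gte(mean(ps > 0.05), 0.90)

  # one environment with 10x the noise: Bartlett must flag it
  tab <- simulate_index_table(g = 20, e = 6, r = 3, sd_eps = 0.3, seed = 9)
  blow <- tab$env == "E1"
  set.seed(10)
  tab$index[blow] <- tab$index[blow] + rnorm(sum(blow), 0, 3)
  expect_lt(index_pretests(tab, "GY")$bartlett_p, 0.01)

  # constant data: degenerate, skipped with a warning
  tab0 <- simulate_index_table(g = 4, e = 2, r = 2, sd_g = 0, sd_e = 0,
                               sd_rep = 0, sd_ge = 0, sd_eps = 0, seed = 1,
                               ge_mat = matrix(0, 4, 2))
  expect_warning(res <- index_pretests(tab0, "GY"), "constant")
  expect_true(res$degenerate)
})

test_that("BLUPs shrink toward zero and vanish for identical genotypes", {
  tab <- simulate_index_table(g = 12, e = 6, r = 3, seed = 31)
  b <- fit_blup(tab, "GY")
  cellm <- tapply(tab$index, list(tab$genotype, tab$env), mean)
  raw_g <- rowMeans(cellm) - mean(cellm)
  expect_true(all(abs(b$genotype_blup) <= abs(raw_g) + 1e-10))
  expect_lt(abs(sum(b$genotype_blup)), 1e-6 * max(abs(b$genotype_blup)))
  expect_equal(dim(b$ge_blup), c(12, 6))

  # no genetic signal: all genotype BLUPs 0
  tab0 <- simulate_index_table(g = 8, e = 4, r = 3, sd_g = 0, sd_ge = 0,
                               seed = 3, ge_mat = matrix(0, 8, 4))
  b0 <- fit_blup(tab0, "GY")
  expect_lt(max(abs(b0$genotype_blup)), 0.05)
})

test_that("zero-noise BLUP equals the centered interaction table exactly", {
  tab <- simulate_index_table(g = 10, e = 5, r = 2, sd_eps = 0, sd_rep = 0,
                              seed = 13)
  b <- fit_blup(tab, "GY")
  cellm <- tapply(tab$index, list(tab$genotype, tab$env), mean)
  centered <- sweep(sweep(cellm, 1, rowMeans(cellm)), 2, colMeans(cellm)) +
    mean(cellm)
  expect_equal(unname(b$ge_blup), unname(centered), tolerance = 1e-8)
})

test_that("a planted interaction is recovered by the BLUP matrix", {
  set.seed(42)
  u <- rnorm(50); u <- u - mean(u); u <- u / sqrt(sum(u^2))
  v <- rnorm(6); v <- v - mean(v); v <- v / sqrt(sum(v^2))
  ge <- 8 * u %*% t(v)
  tab <- simulate_index_table(g = 50, e = 6, r = 3, sd_eps = 0.3,
                              ge_mat = ge, seed = 15)
  b <- fit_blup(tab, "GY")
  expect_gt(cor(as.vector(b$ge_blup), as.vector(ge)), 0.9)
})

test_that("method-of-moments and REML components agree on balanced data", {
  diffs <- vapply(1:50, function(s) {
    tab <- simulate_index_table(g = 50, e = 6, r = 2, sd_g = 2,
                                sd_ge = sqrt(2), sd_eps = 1, mu = 10,
                                seed = 2000 + s)
    a <- joint_anova(tab, "GY")
    vc <- variance_components(a)
    dd <- data.frame(y = tab$index, GEN = tab$genotype, ENV = tab$env,
                     REP = factor(tab$rep))
    fit <- suppressMessages(lme4::lmer(
      y ~ 1 + (1 | GEN) + (1 | ENV) + (1 | ENV:REP) + (1 | GEN:ENV),
      data = dd))
    vcr <- as.data.frame(lme4::VarCorr(fit))
    reml_g <- vcr$vcov[vcr$grp == "GEN"]
    reml_ge <- vcr$vcov[vcr$grp == "GEN:ENV"]
    max(abs(vc$sigma2_g - reml_g) / reml_g,
        abs(vc$sigma2_ge - reml_ge) / reml_ge)
  }, 0)
  expect_lt(median(diffs), 0.10)
})
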