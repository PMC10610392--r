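# small deterministic configurations used across the suite

# a single-trait spec with everything off unless asked for
quiet_trait <- function(name = "GY", mean = 6, sense = "increase", ...) {
  trait_spec(name, mean = mean, sense = sense, ...)
}

# n_tr noise-free traits
quiet_traits <- function(n_tr = 2, names = NULL) {
  if (is.null(names)) {
    names <- c("GY", if (n_tr > 1) paste0("T", seq_len(n_tr - 1)))
  }
  lst <- lapply(seq_len(n_tr), function(i) {
    quiet_trait(names[i], mean = 5 + i)
  })
  setNames(lst, names)
}

# flat stress response (factor 1 everywhere): indices identically 1
flat_groups <- function(conditions = c("drought", "heat")) {
  list(ALL = setNames(rep(1, length(conditions)), conditions))
}

# small fully-quiet config: deterministic values equal to the trait means
quiet_config <- function(n_genotypes = 6, n_reps = 2, n_tr = 2,
                         seasons = c("s1", "s2"), seed = 7, ...) {
  sim_config(n_genotypes = n_genotypes, seasons = seasons,
             conditions = c("optimal", "drought", "heat"), n_reps = n_reps,
             traits = quiet_traits(n_tr),
             group_effects = flat_groups(),
             tol_sd = 0, tol_gei_sd = 0, seed = seed, ...)
}

# simulate a balanced replicate-level index table directly:
# y = mu + g_i + e_j + r_k(j) + ge_ij + eps, all components returned
simulate_index_table <- function(g = 20, e = 6, r = 3, mu = 1,
                                 sd_g = 0.1, sd_e = 0.1, sd_rep = 0.02,
                                 sd_ge = 0.1, sd_eps = 0.05, seed = 1,
                                 trait = "GY", ge_mat = NULL) {
  set.seed(seed)
  gen <- sprintf("G%02d", seq_len(g))
  env <- sprintf("E%d", seq_len(e))
  g_eff <- rnorm(g, 0, sd_g); g_eff <- g_eff - mean(g_eff)
  e_eff <- rnorm(e, 0, sd_e); e_eff <- e_eff - mean(e_eff)
  if (is.null(ge_mat)) {
    ge_mat <- matrix(rnorm(g * e, 0, sd_ge), g, e)
    ge_mat <- sweep(sweep(ge_mat, 1, rowMeans(ge_mat)), 2, colMeans(ge_mat))
  }
  rep_eff <- matrix(rnorm(e * r, 0, sd_rep), e, r)
  rows <- expand.grid(gi = seq_len(g), ej = seq_len(e), rk = seq_len(r))
  y <- mu + g_eff[rows$gi] + e_eff[rows$ej] +
    rep_eff[cbind(rows$ej, rows$rk)] + ge_mat[cbind(rows$gi, rows$ej)] +
    rnorm(nrow(rows), 0, sd_eps)
  tab <- tibble::tibble(genotype = gen[rows$gi], env = env[rows$ej],
                        rep = rows$rk, trait = trait, index = y)
  attr(tab, "components") <- list(mu = mu, g = g_eff, e = e_eff,
                                  ge = ge_mat, rep = rep_eff,
                                  sd = c(g = sd_g, ge = sd_ge, eps = sd_eps))
  tab
}

# adjusted Rand index between two partitions
rand_adjusted <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n2
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}
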