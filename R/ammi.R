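#' Genotype-by-environment means table for one trait
#'
#' @param index_table Output of [build_index_environments()].
#' @param trait Trait name.
#' @return A g x e numeric matrix of replicate means, genotypes in rows,
#'   index environments in columns, with attribute `r` (replicates per cell).
#' @export
two_way_means <- function(index_table, trait) {
  d <- one_trait(index_table, trait)
  gen <- sort(unique(d$genotype)); env <- sort(unique(d$env))
  counts <- table(factor(d$genotype, gen), factor(d$env, env))
  if (any(counts == 0) || length(unique(as.vector(counts))) != 1) {
    bad <- which(counts < max(counts), arr.ind = TRUE)[1, ]
    stop_stressmet(sprintf("missing or incomplete cell: genotype %s, environment %s",
                           gen[bad[1]], env[bad[2]]),
                   "stressmet_balance_error")
  }
  M <- tapply(d$index, list(factor(d$genotype, gen), factor(d$env, env)), mean)
  M <- matrix(M, nrow = length(gen), dimnames = list(gen, env))
  attr(M, "r") <- as.integer(counts[1, 1])
  M
}

#' AMMI decomposition of a two-way table
#'
#' Additive main effects and multiplicative interaction: the table is
#' double-centered to the interaction matrix
#' \eqn{GEI_{ij} = \bar y_{ij} - \bar y_{i.} - \bar y_{.j} + \mu}, which is
#' factorized by singular value decomposition. Scores are symmetric-scaled
#' (both sides carry \eqn{\sqrt\lambda}), so per axis the genotype and
#' environment score vectors have equal sums of squares \eqn{\lambda_k}.
#' Sign convention: the largest-magnitude environment loading of each axis
#' is made positive.
#'
#' @param table A complete g x e numeric matrix (means table, or an already
#'   centered interaction matrix such as a BLUP matrix; centering is
#'   idempotent).
#' @return An `ammi_decomposition` list: `grand_mean`, `gen_means`,
#'   `env_means`, `gei` (centered matrix), `lambda` (singular values),
#'   `gen_scores` and `env_scores` (g x k and e x k matrices), `proportion`
#'   and `accumulated` (percent of interaction sum of squares per axis).
#' @export
ammi_decompose <- function(table) {
  M <- as.matrix(table)
  if (anyNA(M)) {
    stop_stressmet("two-way table has missing cells",
                   "stressmet_balance_error")
  }
  g <- nrow(M); e <- ncol(M)
  mu <- mean(M)
  gm <- rowMeans(M); em <- colMeans(M)
  gei <- sweep(sweep(M, 1, gm), 2, em) + mu
  k <- min(g - 1, e - 1)
  s <- svd(gei, nu = k, nv = k)
  lambda <- s$d[seq_len(k)]
  U <- s$u; V <- s$v
  # sign: largest-magnitude environment loading per axis positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(V[, j]))
    if (V[i_max, j] < 0) { V[, j] <- -V[, j]; U[, j] <- -U[, j] }
  }
  sq <- sqrt(lambda)
  gs <- U %*% diag(sq, k); es <- V %*% diag(sq, k)
  dimnames(gs) <- list(rownames(M), paste0("IPC", seq_len(k)))
  dimnames(es) <- list(colnames(M), paste0("IPC", seq_len(k)))
  ss <- lambda^2
  prop <- if (sum(ss) > 0) 100 * ss / sum(ss) else rep(0, k)
  structure(list(grand_mean = mu,
                 gen_means = gm, env_means = em, gei = gei,
                 lambda = lambda, gen_scores = gs, env_scores = es,
                 proportion = prop, accumulated = cumsum(prop)),
            class = "ammi_decomposition")
}

#' AMMI ANOVA with Gollob tests of the multiplicative axes
#'
#' Extends the joint ANOVA with one row per interaction principal component
#' axis: Gollob degrees of freedom \eqn{df_k = g + e - 1 - 2k}, sum of
#' squares on the replicate scale \eqn{SS_k = r\lambda_k^2}, F against the
#' replicate-level residual mean square.
#'
#' @param decomp An [ammi_decompose()] result computed from the means table
#'   of the same data as `anova_tab`.
#' @param anova_tab Output of [joint_anova()].
#' @param r Replicates per cell (default from the ANOVA table).
#' @return Tibble: the five ANOVA sources, then `IPC1..IPCk` rows with
#'   `df, ss, ms, f, p, proportion, accumulated`.
#' @export
ammi_anova <- function(decomp, anova_tab, r = attr(anova_tab, "r")) {
  g <- length(decomp$gen_means); e <- length(decomp$env_means)
  if (!is.null(attr(anova_tab, "g")) &&
      (attr(anova_tab, "g") != g || attr(anova_tab, "e") != e)) {
    stop_stressmet("decomposition and ANOVA table sizes disagree",
                   "stressmet_format_error")
  }
  df_ge <- anova_tab$df[anova_tab$source == "GEN:ENV"]
  if (df_ge != (g - 1) * (e - 1)) {
    stop_stressmet("GEN:ENV degrees of freedom inconsistent with the table",
                   "stressmet_format_error")
  }
  k <- length(decomp$lambda)
  df_k <- gollob_df(g, e, seq_len(k))
  ss_k <- r * decomp$lambda^2
  ms_res <- anova_tab$ms[anova_tab$source == "Residuals"]
  df_res <- anova_tab$df[anova_tab$source == "Residuals"]
  ms_k <- ss_k / df_k
  f_k <- ms_k / ms_res
  p_k <- pf(f_k, df_k, df_res, lower.tail = FALSE)
  ipc <- tibble(source = paste0("IPC", seq_len(k)), df = df_k, ss = ss_k,
                ms = ms_k, f = f_k, p = p_k,
                proportion = decomp$proportion,
                accumulated = decomp$accumulated)
  base <- anova_tab
  base$proportion <- NA_real_; base$accumulated <- NA_real_
  out <- bind_rows(base[base$source != "Residuals", ], ipc,
                   base[base$source == "Residuals", ])
  attr(out, "g") <- g; attr(out, "e") <- e; attr(out, "r") <- r
  out
}

#' Gollob degrees of freedom for multiplicative axes
#'
#' @param g,e Table dimensions.
#' @param k Axis number(s).
#' @return `g + e - 1 - 2k`.
#' @export
gollob_df <- function(g, e, k) g + e - 1 - 2 * k

#' Predict the two-way table from the first n multiplicative terms
#'
#' \deqn{\hat y_{ij} = \mu + (\bar y_{i.} - \mu) + (\bar y_{.j} - \mu) +
#'   \sum_{k \le n} g_{ik} e_{jk}}
#' `n_terms = 0` is the purely additive (AMMI0) fit; the full rank
#' reproduces the observed means exactly.
#'
#' @param decomp An [ammi_decompose()] result.
#' @param n_terms Number of multiplicative terms, `0..min(g-1, e-1)`.
#' @return The predicted g x e matrix.
#' @export
ammi_predict <- function(decomp, n_terms) {
  k_max <- length(decomp$lambda)
  if (length(n_terms) != 1 || n_terms < 0 || n_terms > k_max) {
    stop_stressmet(sprintf("`n_terms` must be in 0..%d", k_max),
                   "stressmet_argument_error")
  }
  add <- outer(decomp$gen_means, decomp$env_means, "+") - decomp$grand_mean
  if (n_terms > 0) {
    idx <- seq_len(n_terms)
    add <- add + decomp$gen_scores[, idx, drop = FALSE] %*%
      t(decomp$env_scores[, idx, drop = FALSE])
  }
  add
}

#' Biplot coordinates and environment-vector angles
#'
#' Genotype and environment scores on two axes, plus the pairwise angles
#' between environment vectors: angles below 90 degrees read as positively
#' correlated interaction patterns, above 90 degrees as negatively
#' correlated.
#'
#' @param decomp An [ammi_decompose()] result.
#' @param axes Two axis numbers (default first two).
#' @return List with `points` (tibble `label, type, x, y`) and `angles`
#'   (tibble `env_a, env_b, angle_deg`).
#' @export
ammi_biplot_coords <- function(decomp, axes = c(1, 2)) {
  k_max <- length(decomp$lambda)
  if (any(axes < 1) || any(axes > k_max) || length(axes) != 2) {
    stop_stressmet(sprintf("`axes` must be two values in 1..%d", k_max),
                   "stressmet_argument_error")
  }
  gs <- decomp$gen_scores[, axes, drop = FALSE]
  es <- decomp$env_scores[, axes, drop = FALSE]
  pts <- bind_rows(
    tibble(label = rownames(gs), type = "genotype",
           x = gs[, 1], y = gs[, 2]),
    tibble(label = rownames(es), type = "environment",
           x = es[, 1], y = es[, 2])
  )
  envs <- rownames(es)
  pairs <- t(combn(length(envs), 2))
  ang <- apply(pairs, 1, function(ij) {
    a <- es[ij[1], ]; b <- es[ij[2], ]
    den <- sqrt(sum(a^2)) * sqrt(sum(b^2))
    if (den == 0) return(NA_real_)
    acos(pmin(1, pmax(-1, sum(a * b) / den))) * 180 / pi
  })
  list(points = pts,
       angles = tibble(env_a = envs[pairs[, 1]], env_b = envs[pairs[, 2]],
                       angle_deg = ang))
}
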