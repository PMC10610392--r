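#' Sense-oriented 0-100 rescaling of a genotype x trait matrix
#'
#' Each trait column is mapped linearly so that the most desirable observed
#' value becomes 100 and the least desirable 0: the identity orientation for
#' `"increase"` traits, reversed for `"decrease"` traits. Constant columns
#' carry no ranking information and are dropped with a warning.
#'
#' @param X g x t numeric matrix (genotypes in rows).
#' @param senses Named character vector (`"increase"`/`"decrease"`) covering
#'   every column of `X`.
#' @return Matrix with attribute `senses` (for the retained columns) and
#'   `dropped` (names of constant columns removed).
#' @export
rescale_traits <- function(X, senses) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    stop_stressmet("`X` must have trait column names", "stressmet_format_error")
  }
  if (!all(colnames(X) %in% names(senses))) {
    stop_stressmet(paste("missing sense for:",
                         paste(setdiff(colnames(X), names(senses)),
                               collapse = ", ")),
                   "stressmet_format_error")
  }
  keep <- apply(X, 2, function(v) max(v) - min(v) > 0)
  if (any(!keep)) {
    warn(paste("constant trait columns dropped:",
               paste(colnames(X)[!keep], collapse = ", ")))
  }
  X <- X[, keep, drop = FALSE]
  out <- X
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    r <- 100 * (v - min(v)) / (max(v) - min(v))
    if (senses[[colnames(X)[j]]] == "decrease") r <- 100 - r
    out[, j] <- r
  }
  attr(out, "senses") <- senses[colnames(X)]
  attr(out, "dropped") <- colnames(X)[!keep]
  out
}

#' Exploratory factor analysis of the rescaled trait matrix
#'
#' Principal-component extraction from the trait correlation matrix, Kaiser
#' retention (eigenvalue strictly greater than 1), loadings
#' \eqn{L = V \sqrt{\Lambda}} varimax-rotated with Kaiser normalization, and
#' factor scores by the regression method
#' \eqn{F = Z R^{-1} L}. A singular correlation matrix receives a `1e-8`
#' ridge (reported via a message).
#'
#' @param X Rescaled g x t matrix from [rescale_traits()] (any numeric
#'   matrix with named columns works).
#' @param n_factors Override for the retained factor count (default Kaiser).
#' @return List: `eigenvalues`, `n_factors`, `loadings` (t x f, rotated),
#'   `communality`, `uniqueness`, `scores` (g x f), `center`, `scale` (the
#'   standardization used, so new rows can be projected), `rotmat`.
#' @export
trait_factor_analysis <- function(X, n_factors = NULL) {
  X <- as.matrix(X)
  t_n <- ncol(X)
  Z <- scale(X)
  R <- cor(X)
  ev <- eigen(R, symmetric = TRUE)
  eigenvalues <- ev$values
  nf <- if (is.null(n_factors)) max(1L, sum(eigenvalues > 1)) else
    as.integer(n_factors)
  if (nrow(X) <= nf) {
    stop_stressmet("more retained factors than genotypes",
                   "stressmet_argument_error")
  }
  L <- ev$vectors[, seq_len(nf), drop = FALSE] %*%
    diag(sqrt(pmax(eigenvalues[seq_len(nf)], 0)), nf)
  rownames(L) <- colnames(X)
  if (nf > 1) {
    rot <- varimax(L, normalize = TRUE, eps = 1e-6)
    L_rot <- L %*% rot$rotmat
    rotmat <- rot$rotmat
  } else {
    L_rot <- L
    rotmat <- diag(1)
  }
  colnames(L_rot) <- paste0("FA", seq_len(nf))
  comm <- rowSums(L_rot^2)
  Ri <- tryCatch(solve(R), error = function(e) {
    inform("singular trait correlation matrix: 1e-8 ridge added")
    solve(R + diag(1e-8, t_n))
  })
  B <- Ri %*% L_rot            # regression-method score weights
  scores <- Z %*% B
  colnames(scores) <- colnames(L_rot)
  list(eigenvalues = eigenvalues, n_factors = nf, loadings = L_rot,
       communality = comm, uniqueness = 1 - comm, scores = scores,
       center = attr(Z, "scaled:center"), scale = attr(Z, "scaled:scale"),
       score_weights = B, rotmat = rotmat)
}

project_scores <- function(model, newrow) {
  z <- (newrow - model$center) / model$scale
  as.vector(z %*% model$score_weights)
}

#' Multi-trait genotype-ideotype distance index
#'
#' The ideotype holds the rescaled optimum (100) for every trait; it is
#' projected through the same factor-score equation as the genotypes, and
#' each genotype's MGIDI is its Euclidean distance to the ideotype in factor
#' space:
#' \deqn{MGIDI_i = \sqrt{\sum_f (F_{if} - F_f^{ideo})^2}}
#' Lower is closer to the ideal. The selected set holds the
#' `max(1, round(alpha * g))` lowest distances (ties resolved by rank then
#' label).
#'
#' @param model A [trait_factor_analysis()] fit on the rescaled matrix.
#' @param intensity Selection intensity `alpha` in (0, 1]; the reference
#'   workflow uses ~0.20.
#' @return List: `table` (tibble `genotype, mgidi, rank, selected`),
#'   `ideotype_scores`, `selected` (labels), `model`.
#' @export
mgidi_index <- function(model, intensity = 0.20) {
  if (intensity <= 0 || intensity > 1) {
    stop_stressmet("`intensity` must be in (0, 1]", "stressmet_argument_error")
  }
  ideo <- project_scores(model, rep(100, length(model$center)))
  gaps <- sweep(model$scores, 2, ideo)
  d <- sqrt(rowSums(gaps^2))
  g <- length(d)
  ord <- order(d, names(d))
  rk <- integer(g); rk[ord] <- seq_len(g)
  n_sel <- max(1L, round(intensity * g))
  sel <- rownames(model$scores)[ord][seq_len(n_sel)]
  tab <- tibble(genotype = rownames(model$scores), mgidi = unname(d),
                rank = rk, selected = rownames(model$scores) %in% sel)
  list(table = tab, ideotype_scores = ideo, selected = sel, model = model,
       gaps = gaps)
}

#' Per-factor contribution to each genotype's distance
#'
#' \deqn{share_{if} = (F_{if} - F^{ideo}_f)^2 / \sum_f (F_{if} - F^{ideo}_f)^2}
#' Shares sum to 1 per genotype; a factor with a large share is the
#' genotype's main weakness. Genotypes at zero distance get uniform shares
#' (flagged).
#'
#' @param result A [mgidi_index()] result.
#' @return Tibble `genotype, factor, share, zero_distance`.
#' @export
factor_contributions <- function(result) {
  sq <- result$gaps^2
  tot <- rowSums(sq)
  zero <- tot == 0
  shares <- sq
  shares[!zero, ] <- sq[!zero, , drop = FALSE] / tot[!zero]
  if (any(zero)) {
    warn("zero-distance genotype(s): uniform factor shares assigned")
    shares[zero, ] <- 1 / ncol(sq)
  }
  out <- as_tibble(shares, rownames = "genotype") %>%
    pivot_longer(-"genotype", names_to = "factor", values_to = "share")
  out$zero_distance <- out$genotype %in% rownames(sq)[zero]
  out
}

#' Predicted selection gains of a selected set
#'
#' For each trait: original-population mean `Xo`, selected-set mean `Xs`,
#' selection differential `SD = Xs - Xo`, and the predicted gain
#' \eqn{SG\% = 100 \times SD \times h^2_{mg} / Xo} using the genotype-mean
#' heritability as multiplier. A gain is "desired" when its sign matches the
#' trait's sense.
#'
#' @param means g x t matrix of raw (unrescaled) genotype means.
#' @param selected Character vector of selected genotype labels.
#' @param h2mg Named numeric vector of mean-basis heritabilities per trait.
#' @param senses Named character vector of trait senses.
#' @param factors Optional named factor assignment per trait (for reporting).
#' @return Tibble `factor, trait, Xo, Xs, SD, SG_pct, sense, desired`, with
#'   attribute `totals` (summed `SG_pct` over increase- and decrease-sense
#'   traits).
#' @export
selection_gains <- function(means, selected, h2mg, senses, factors = NULL) {
  means <- as.matrix(means)
  if (!length(selected) || !all(selected %in% rownames(means))) {
    stop_stressmet("`selected` must name rows of `means`",
                   "stressmet_argument_error")
  }
  traits <- colnames(means)
  Xo <- colMeans(means)
  Xs <- colMeans(means[selected, , drop = FALSE])
  SD <- Xs - Xo
  undef <- Xo == 0
  if (any(undef)) warn(paste("zero population mean; gain undefined for:",
                             paste(traits[undef], collapse = ", ")))
  SG <- ifelse(undef, NA_real_, 100 * SD * h2mg[traits] / Xo)
  sense <- unname(unlist(senses[traits]))
  desired <- (SG > 0 & sense == "increase") | (SG < 0 & sense == "decrease")
  out <- tibble(
    factor = if (is.null(factors)) NA_character_ else unname(factors[traits]),
    trait = traits, Xo = unname(Xo), Xs = unname(Xs), SD = unname(SD),
    SG_pct = unname(SG), sense = sense, desired = unname(desired))
  attr(out, "totals") <- c(
    increase = sum(out$SG_pct[out$sense == "increase"], na.rm = TRUE),
    decrease = sum(out$SG_pct[out$sense == "decrease"], na.rm = TRUE))
  attr(out, "heritability_basis") <- "h2mg (genotype-mean basis)"
  out
}

#' Full MGIDI workflow from genotype means
#'
#' Rescales, factor-analyses, and ranks genotypes by ideotype distance. The
#' standard input is the matrix of BLUP-based genotype means per trait
#' (raw means are accepted).
#'
#' @param means g x t matrix of genotype means.
#' @param senses Named sense vector.
#' @param intensity Selection intensity.
#' @param h2mg Optional heritabilities for the gains block.
#' @return List: `rescaled`, `model`, `index` ([mgidi_index()] result),
#'   `contributions`, and (if `h2mg` given) `gains`.
#' @export
run_mgidi <- function(means, senses, intensity = 0.20, h2mg = NULL) {
  resc <- rescale_traits(means, senses)
  model <- trait_factor_analysis(resc)
  idx <- mgidi_index(model, intensity)
  contrib <- factor_contributions(idx)
  fct <- colnames(model$loadings)[apply(abs(model$loadings), 1, which.max)]
  names(fct) <- rownames(model$loadings)
  out <- list(rescaled = resc, model = model, index = idx,
              contributions = contrib, trait_factor = fct)
  if (!is.null(h2mg)) {
    out$gains <- selection_gains(means[, colnames(resc), drop = FALSE],
                                 idx$selected, h2mg,
                                 attr(resc, "senses"), factors = fct)
  }
  out
}
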