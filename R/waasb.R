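#' Proportion-weighted average of absolute scores
#'
#' The elementary WAASB computation: given a matrix of IPCA scores (rows =
#' genotypes or environments) and the per-axis explained proportions, return
#' \eqn{\sum_k |score_k| EP_k / \sum_k EP_k} per row. Exposed so published
#' score tables can be re-weighted directly.
#'
#' @param scores Numeric matrix, one column per axis.
#' @param proportions Non-negative axis weights (percent or fractions).
#' @return Named numeric vector.
#' @export
waasb_weighted <- function(scores, proportions) {
  scores <- as.matrix(scores)
  if (ncol(scores) != length(proportions)) {
    stop_stressmet("one proportion per score column required",
                   "stressmet_argument_error")
  }
  if (any(proportions < 0) || sum(proportions) <= 0) {
    stop_stressmet("proportions must be >= 0 with positive sum",
                   "stressmet_argument_error")
  }
  setNames(as.vector(abs(scores) %*% proportions) / sum(proportions),
           rownames(scores))
}

#' WAASB stability scores
#'
#' Weighted average of absolute scores: for each genotype (and, symmetrically,
#' each environment),
#' \deqn{WAASB_i = \frac{\sum_k |score_{ik}| \times EP_k}{\sum_k EP_k}}
#' where \eqn{EP_k} is the percentage of interaction sum of squares explained
#' by axis \eqn{k}. Lower values mean the genotype contributes less
#' interaction, i.e. is more stable. Computed on the decomposition of the
#' BLUP interaction matrix in the standard workflow (see
#' [waasb_from_blup()]), but accepts any [ammi_decompose()] result.
#'
#' @param decomp An [ammi_decompose()] result.
#' @param n_axes Number of leading axes to include, or `"all"` (default).
#' @param means Optional named performance means attached to the output (for
#'   genotypes, e.g. BLUP-based genotype means); defaults to the
#'   decomposition's marginal means.
#' @return List of two tibbles, `genotypes` and `environments`, each with
#'   `label, Y, waasb, rank` (rank ascending, ties broken by label), plus
#'   `proportion` (the axis weights used).
#' @export
waasb_scores <- function(decomp, n_axes = "all", means = NULL) {
  k_max <- length(decomp$lambda)
  k <- if (identical(n_axes, "all")) k_max else as.integer(n_axes)
  if (k < 1 || k > k_max) {
    stop_stressmet(sprintf("`n_axes` must be in 1..%d or \"all\"", k_max),
                   "stressmet_argument_error")
  }
  ep <- decomp$proportion[seq_len(k)]
  if (sum(ep) <= 0) {
    stop_stressmet("no interaction variance: WAASB is undefined",
                   "stressmet_degenerate_error")
  }
  one_side <- function(S, Y) {
    w <- unname(waasb_weighted(S[, seq_len(k), drop = FALSE], ep))
    ord <- order(w, rownames(S))
    rk <- integer(length(w)); rk[ord] <- seq_along(w)
    tibble(label = rownames(S), Y = Y, waasb = w, rank = rk)
  }
  g_means <- decomp$gen_means
  if (!is.null(means)) g_means <- means[rownames(decomp$gen_scores)]
  list(genotypes = one_side(decomp$gen_scores, unname(g_means)),
       environments = one_side(decomp$env_scores,
                               unname(decomp$env_means)),
       proportion = ep)
}

#' WAASB from the BLUP interaction matrix
#'
#' The standard stability workflow: decompose the genotype-by-environment
#' BLUP matrix of [fit_blup()] and weight the absolute scores, attaching the
#' BLUP-based genotype means as the performance column.
#'
#' @param blup Output of [fit_blup()].
#' @param n_axes Passed to [waasb_scores()].
#' @return As [waasb_scores()].
#' @export
waasb_from_blup <- function(blup, n_axes = "all") {
  decomp <- ammi_decompose(blup$ge_blup)
  waasb_scores(decomp, n_axes = n_axes,
               means = blup$genotype_mean)
}

#' Joint performance-stability index (WAASBY)
#'
#' Performance is rescaled to `0..100` (100 = best, respecting `sense`) and
#' stability likewise (100 = lowest WAASB); the index is their weighted
#' average \eqn{(r_Y\theta_Y + r_W\theta_S)/(\theta_Y+\theta_S)}.
#'
#' @param waasb A [waasb_scores()] result (the `genotypes` block is used).
#' @param theta_Y,theta_S Non-negative weights for performance and
#'   stability (default 50/50).
#' @param sense `"increase"` if larger performance means better.
#' @return Tibble `label, Y, waasb, rY, rW, waasby, rank` (rank descending
#'   in `waasby`, ties broken by label).
#' @export
waasby <- function(waasb, theta_Y = 50, theta_S = 50,
                   sense = c("increase", "decrease")) {
  sense <- match.arg(sense)
  if (theta_Y < 0 || theta_S < 0 || theta_Y + theta_S == 0) {
    stop_stressmet("weights must be >= 0 and not both 0",
                   "stressmet_argument_error")
  }
  d <- waasb$genotypes
  resc <- function(x, best_high) {
    rng <- max(x) - min(x)
    if (rng == 0) {
      warn("constant values: rescaled to 100 for all")
      return(rep(100, length(x)))
    }
    out <- 100 * (x - min(x)) / rng
    if (best_high) out else 100 - out
  }
  rY <- resc(d$Y, best_high = sense == "increase")
  rW <- resc(d$waasb, best_high = FALSE)
  sc <- (rY * theta_Y + rW * theta_S) / (theta_Y + theta_S)
  ord <- order(-sc, d$label)
  rk <- integer(length(sc)); rk[ord] <- seq_along(sc)
  tibble(label = d$label, Y = d$Y, waasb = d$waasb, rY = rY, rW = rW,
         waasby = sc, rank = rk)
}

#' Quadrant classification of the performance x WAASB biplot
#'
#' Quadrant I: below the performance cut, above the stability cut (unstable,
#' low performing); II: above/above (productive but unstable); III:
#' below/below (stable, low performing); IV: above the performance cut and
#' below the WAASB cut -- the productive, stable corner.
#'
#' @param means Named numeric vector of performance values.
#' @param waasb Named numeric vector of WAASB values (same names).
#' @param x_cut Performance cut (default mean of `means`).
#' @param y_cut WAASB cut (default mean of `waasb`).
#' @return Tibble `label, Y, waasb, quadrant, on_cut` (items lying exactly on
#'   a cut are assigned to the lower quadrant and flagged).
#' @export
classify_quadrants <- function(means, waasb, x_cut = mean(means),
                               y_cut = mean(waasb)) {
  if (!is.finite(x_cut) || !is.finite(y_cut)) {
    stop_stressmet("cut points must be finite", "stressmet_argument_error")
  }
  stopifnot(length(means) == length(waasb))
  high_y <- means > x_cut
  low_w <- waasb < y_cut
  quad <- ifelse(high_y,
                 ifelse(low_w, "IV", "II"),
                 ifelse(low_w, "III", "I"))
  tibble(label = names(means), Y = unname(means), waasb = unname(waasb),
         quadrant = unname(quad),
         on_cut = unname(means == x_cut | waasb == y_cut))
}
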