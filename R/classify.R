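#' Ward clustering of genotypes into tolerance categories
#'
#' Trait columns are z-scored, genotypes clustered on Euclidean distance
#' with Ward linkage (`ward.D2`: squared distances in the merge objective,
#' heights on the distance scale), and the tree cut at `k` groups. Clusters
#' are named by descending mean of the orientation trait (grain-yield index
#' by default): `HT` (highly tolerant) down to `HS` (highly sensitive) for
#' the default `k = 5`.
#'
#' @param means g x t matrix of genotype index means (named rows/columns).
#' @param k Number of categories (default 5).
#' @param gy_trait Column used to order the category names.
#' @param category_names Names assigned in descending `gy_trait` order.
#' @param clip Display clip for the exported heatmap z-matrix (computation
#'   never uses the clipped values).
#' @return List: `tree` (`hclust`), `cluster` (integer vector),
#'   `category` (named character vector per genotype), `z` (standardized
#'   matrix), `heatmap` (z clipped to `[-clip, clip]`, rows/cols in
#'   dendrogram order), `cluster_gy` (per-cluster mean of the orientation
#'   trait).
#' @export
ward_cluster <- function(means, k = 5, gy_trait = "GY",
                         category_names = c("HT", "T", "M", "S", "HS"),
                         clip = 3) {
  means <- as.matrix(means)
  g <- nrow(means)
  if (g <= k) {
    stop_stressmet("need more genotypes than clusters",
                   "stressmet_argument_error")
  }
  if (!gy_trait %in% colnames(means)) {
    stop_stressmet(sprintf("orientation trait '%s' not in matrix", gy_trait),
                   "stressmet_format_error")
  }
  if (length(category_names) < k) {
    stop_stressmet("need at least k category names",
                   "stressmet_argument_error")
  }
  z <- scale(means)
  z[, attr(z, "scaled:scale") == 0] <- 0
  tree <- hclust(dist(z, method = "euclidean"), method = "ward.D2")
  cl <- cutree(tree, k = k)
  if (length(unique(cl)) < k) {
    stop_stressmet("duplicate rows collapse below k clusters",
                   "stressmet_degenerate_error")
  }
  cl_gy <- tapply(means[, gy_trait], cl, mean)
  ord <- order(-cl_gy)
  name_of <- setNames(category_names[seq_len(k)], names(cl_gy)[ord])
  category <- setNames(name_of[as.character(cl)], rownames(means))
  hm <- pmin(pmax(unclass(z), -clip), clip)
  hm <- hm[tree$order, , drop = FALSE]
  list(tree = tree, cluster = cl, category = category, z = unclass(z),
       heatmap = hm, cluster_gy = cl_gy)
}

#' Fit a pooled-covariance linear discriminant model
#'
#' Gaussian classifier with a common within-group covariance matrix, the
#' classical LDA model behind posterior membership probabilities. When the
#' pooled covariance is singular (more predictors than residual degrees of
#' freedom), the Moore-Penrose pseudo-inverse is used (reported via a
#' message), so wide trait panels can still be scored.
#'
#' @param X n x p predictor matrix.
#' @param labels Group label per row.
#' @param prior `"frequency"` (group frequencies, default) or `"equal"`, or
#'   a named numeric vector summing to 1.
#' @return `stressmet_lda` list: `means` (group x p), `cov_inv`, `prior`,
#'   `levels`, `pseudo_inverse` flag.
#' @export
lda_fit <- function(X, labels, prior = c("frequency", "equal")) {
  X <- as.matrix(X)
  f <- factor(labels)
  lev <- levels(f)
  if (length(lev) < 2) {
    stop_stressmet("need at least two groups", "stressmet_argument_error")
  }
  n <- nrow(X); p <- ncol(X); k <- length(lev)
  if (any(table(f) == 1) && p > 1) {
    warn("single-member group(s): covariance pooled across groups")
  }
  mns <- matrix(NA_real_, k, p, dimnames = list(lev, colnames(X)))
  for (g in lev) mns[g, ] <- colMeans(X[f == g, , drop = FALSE])
  W <- matrix(0, p, p)
  for (g in lev) {
    Xi <- X[f == g, , drop = FALSE]
    Xi <- sweep(Xi, 2, colMeans(Xi))
    W <- W + crossprod(Xi)
  }
  S <- W / max(1, n - k)
  pseudo <- FALSE
  Si <- tryCatch({
    if (rcond_ok(S)) solve(S) else stop("ill-conditioned")
  }, error = function(e) {
    pseudo <<- TRUE
    inform("singular pooled covariance: Moore-Penrose pseudo-inverse used")
    MASS::ginv(S)
  })
  pr <- if (is.numeric(prior)) {
    if (!all(lev %in% names(prior))) {
      stop_stressmet("numeric prior must name every group",
                     "stressmet_argument_error")
    }
    prior[lev] / sum(prior[lev])
  } else {
    prior <- match.arg(prior)
    if (prior == "frequency") as.vector(table(f)) / n else rep(1 / k, k)
  }
  structure(list(means = mns, cov_inv = Si, prior = setNames(pr, lev),
                 levels = lev, pseudo_inverse = pseudo, p = p),
            class = "stressmet_lda")
}

rcond_ok <- function(S) is.finite(rcond(S)) && rcond(S) > 1e-12

#' Classify observations with a fitted discriminant model
#'
#' Posterior membership probabilities proportional to
#' `prior * exp(-Mahalanobis^2 / 2)`; the posterior label is the argmax.
#'
#' @param model A [lda_fit()] result.
#' @param X Predictor matrix (same columns as the fit).
#' @param prior_labels Optional true/prior labels; if given, agreement
#'   statistics are attached.
#' @return Tibble `label, prior, posterior`, one probability column per
#'   group; attributes `percent_correct` and `misclassified` when
#'   `prior_labels` is supplied.
#' @export
lda_classify <- function(model, X, prior_labels = NULL) {
  X <- as.matrix(X)
  if (ncol(X) != model$p) {
    stop_stressmet("predictor count differs from the fitted model",
                   "stressmet_format_error")
  }
  lev <- model$levels
  D2 <- vapply(lev, function(g) {
    v <- sweep(X, 2, model$means[g, ])
    rowSums((v %*% model$cov_inv) * v)
  }, numeric(nrow(X)))
  D2 <- matrix(D2, nrow = nrow(X), dimnames = list(NULL, lev))
  lp <- sweep(-D2 / 2, 2, log(model$prior), "+")
  lp <- lp - apply(lp, 1, max)
  P <- exp(lp); P <- P / rowSums(P)
  post <- lev[max.col(P, ties.method = "first")]
  labs <- if (!is.null(rownames(X))) rownames(X) else
    as.character(seq_len(nrow(X)))
  out <- tibble(label = labs,
                prior = if (is.null(prior_labels)) NA_character_ else
                  as.character(prior_labels),
                posterior = post)
  for (g in lev) out[[g]] <- P[, g]
  if (!is.null(prior_labels)) {
    ok <- post == as.character(prior_labels)
    attr(out, "percent_correct") <- 100 * mean(ok)
    attr(out, "misclassified") <- labs[!ok]
  }
  out
}

#' Leave-one-out cross-validated discriminant classification
#'
#' Refits the model excluding each observation in turn and classifies the
#' held-out row. A fold whose exclusion would empty a group is flagged and
#' classified among the remaining groups.
#'
#' @inheritParams lda_fit
#' @return As [lda_classify()], with agreement statistics against `labels`
#'   and a `flagged_folds` attribute.
#' @export
lda_loo <- function(X, labels, prior = c("frequency", "equal")) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  n <- nrow(X)
  rows <- vector("list", n)
  flagged <- character(0)
  labs <- if (!is.null(rownames(X))) rownames(X) else as.character(seq_len(n))
  for (i in seq_len(n)) {
    keep <- setdiff(seq_len(n), i)
    li <- labels[keep]
    if (!labels[i] %in% li) flagged <- c(flagged, labs[i])
    m <- suppressMessages(lda_fit(X[keep, , drop = FALSE], li, prior = prior))
    rows[[i]] <- lda_classify(m, X[i, , drop = FALSE])
  }
  lev <- sort(unique(labels))
  out <- bind_rows(lapply(seq_len(n), function(i) {
    r <- rows[[i]]
    r$label <- labs[i]; r$prior <- labels[i]
    for (g in setdiff(lev, names(r))) r[[g]] <- 0
    r[, c("label", "prior", "posterior", lev)]
  }))
  ok <- out$posterior == out$prior
  attr(out, "percent_correct") <- 100 * mean(ok)
  attr(out, "misclassified") <- out$label[!ok]
  attr(out, "flagged_folds") <- flagged
  out
}

#' Agreement between prior and posterior category assignments
#'
#' @param prior,posterior Equal-length label vectors.
#' @param labels Optional item names for the moved list.
#' @return List: `confusion` (table), `percent_correct`, `moved` (tibble
#'   `label, from, to`).
#' @export
agreement_table <- function(prior, posterior, labels = NULL) {
  prior <- as.character(prior); posterior <- as.character(posterior)
  if (length(prior) != length(posterior)) {
    stop_stressmet("prior and posterior must have equal length",
                   "stressmet_format_error")
  }
  if (is.null(labels)) labels <- as.character(seq_along(prior))
  lev <- sort(unique(c(prior, posterior)))
  conf <- table(factor(prior, lev), factor(posterior, lev),
                dnn = c("prior", "posterior"))
  moved <- prior != posterior
  list(confusion = conf,
       percent_correct = 100 * mean(!moved),
       moved = tibble(label = labels[moved], from = prior[moved],
                      to = posterior[moved]))
}
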