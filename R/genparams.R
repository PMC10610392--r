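one_trait <- function(index_table, trait) {
  d <- index_table[index_table$trait == trait, ]
  if (!nrow(d)) {
    stop_stressmet(sprintf("trait '%s' not present in the index table", trait),
                   "stressmet_format_error")
  }
  d
}

#' Distributional pre-tests on one trait's indices
#'
#' Shapiro-Wilk normality of the residuals of the joint ANOVA model and
#' Bartlett homogeneity of variances across the index environments. Both are
#' reported, never enforced: they inform whether the downstream F-tests can
#' be read at face value.
#'
#' @param index_table Output of [build_index_environments()].
#' @param trait Trait name.
#' @return List with `shapiro_p`, `bartlett_p` and `degenerate` (`TRUE` when
#'   the data are constant and the tests are skipped).
#' @export
index_pretests <- function(index_table, trait) {
  d <- one_trait(index_table, trait)
  if (var(d$index) < 1e-12) {
    warn(sprintf("trait '%s': constant indices, pre-tests skipped", trait))
    return(list(shapiro_p = NA_real_, bartlett_p = NA_real_,
                degenerate = TRUE))
  }
  fit <- lm(index ~ factor(env) + factor(env):factor(rep) + factor(genotype) +
              factor(genotype):factor(env), data = d)
  res <- resid(fit)
  sw <- if (length(res) >= 3 && length(res) <= 5000) {
    tryCatch(shapiro.test(res)$p.value, error = function(e) NA_real_)
  } else NA_real_
  env_var <- tapply(d$index, d$env, var)
  bt <- if (all(env_var > 1e-14)) {
    bartlett.test(d$index, d$env)$p.value
  } else NA_real_
  list(shapiro_p = sw, bartlett_p = bt, degenerate = FALSE)
}

#' Joint ANOVA of one trait's tolerance indices
#'
#' Full factorial decomposition of the replicate-level index values:
#' \deqn{y_{ijk} = \mu + G_i + E_j + R_{k(j)} + GE_{ij} + \epsilon_{ijk}}
#' with genotype, environment, replicate-within-environment and interaction
#' strata. F for genotype and interaction is taken against the residual mean
#' square; F for environment against the replicate-within-environment mean
#' square, as usual for a randomized-complete-block series.
#'
#' @param index_table Output of [build_index_environments()].
#' @param trait Trait name.
#' @return Tibble with one row per source (`ENV`, `REP(ENV)`, `GEN`,
#'   `GEN:ENV`, `Residuals`): `df`, `ss`, `ms`, `f`, `p`, plus attributes
#'   `g`, `e`, `r`, `grand_mean`.
#' @export
joint_anova <- function(index_table, trait) {
  d <- one_trait(index_table, trait)
  g <- length(unique(d$genotype)); e <- length(unique(d$env))
  r <- length(unique(d$rep))
  if (nrow(d) != g * e * r) {
    stop_stressmet(sprintf(
      "trait '%s': expected %d rows for a balanced g x e x r layout, found %d",
      trait, g * e * r, nrow(d)), "stressmet_balance_error")
  }
  d$GEN <- factor(d$genotype); d$ENV <- factor(d$env); d$REP <- factor(d$rep)
  fit <- aov(index ~ ENV + ENV:REP + GEN + GEN:ENV, data = d)
  # F ratios are rebuilt below against the design-appropriate error strata;
  # anova()'s own (and its perfect-fit warnings) are discarded
  a <- suppressWarnings(anova(fit))
  rn <- trimws(rownames(a))
  rn[rn == "ENV:GEN"] <- "GEN:ENV"
  rn[rn == "REP:ENV"] <- "ENV:REP"
  rownames(a) <- rn
  a <- a[c("ENV", "ENV:REP", "GEN", "GEN:ENV", "Residuals"), ]
  tab <- tibble(
    source = c("ENV", "REP(ENV)", "GEN", "GEN:ENV", "Residuals"),
    df = a$Df, ss = a$`Sum Sq`, ms = a$`Mean Sq`
  )
  ms_res <- tab$ms[tab$source == "Residuals"]
  ms_rep <- tab$ms[tab$source == "REP(ENV)"]
  f <- rep(NA_real_, 5); p <- rep(NA_real_, 5)
  f[1] <- tab$ms[1] / ms_rep
  p[1] <- pf(f[1], tab$df[1], tab$df[2], lower.tail = FALSE)
  f[2] <- ms_rep / ms_res
  p[2] <- pf(f[2], tab$df[2], tab$df[5], lower.tail = FALSE)
  for (i in 3:4) {
    f[i] <- tab$ms[i] / ms_res
    p[i] <- pf(f[i], tab$df[i], tab$df[5], lower.tail = FALSE)
  }
  tab$f <- f; tab$p <- p
  attr(tab, "g") <- g; attr(tab, "e") <- e; attr(tab, "r") <- r
  attr(tab, "grand_mean") <- mean(d$index)
  attr(tab, "trait") <- trait
  tab
}

#' Variance components from the expected mean squares
#'
#' Method-of-moments solution treating genotype as random:
#' \eqn{\sigma^2_\epsilon = MS_{res}},
#' \eqn{\sigma^2_{ge} = (MS_{GE} - MS_{res})/r},
#' \eqn{\sigma^2_g = (MS_G - MS_{GE})/(re)}. Negative solutions are truncated
#' at 0 and flagged so the downstream heritability ratios stay in `[0, 1]`.
#'
#' @param anova_tab Output of [joint_anova()].
#' @param g,e,r Numbers of genotypes, environments, replicates (defaults are
#'   read from the table's attributes).
#' @return List `sigma2_g`, `sigma2_ge`, `sigma2_e`, `sigma2_p`,
#'   `truncated` (character vector of truncated components).
#' @export
variance_components <- function(anova_tab, g = attr(anova_tab, "g"),
                                e = attr(anova_tab, "e"),
                                r = attr(anova_tab, "r")) {
  ms <- setNames(anova_tab$ms, anova_tab$source)
  s2e <- ms[["Residuals"]]
  s2ge <- (ms[["GEN:ENV"]] - ms[["Residuals"]]) / r
  s2g <- (ms[["GEN"]] - ms[["GEN:ENV"]]) / (r * e)
  truncated <- character(0)
  if (s2ge < 0) { truncated <- c(truncated, "sigma2_ge"); s2ge <- 0 }
  if (s2g < 0) { truncated <- c(truncated, "sigma2_g"); s2g <- 0 }
  list(sigma2_g = s2g, sigma2_ge = s2ge, sigma2_e = s2e,
       sigma2_p = s2g + s2ge + s2e, truncated = truncated)
}

#' Quantitative-genetic parameters from variance components
#'
#' Broad-sense heritability on a plot basis \eqn{H^2 = \sigma^2_g/\sigma^2_p},
#' the interaction determination \eqn{R^2_{gei} = \sigma^2_{ge}/\sigma^2_p},
#' heritability on a genotype-mean basis
#' \eqn{h^2_{mg} = \sigma^2_g / (\sigma^2_g + \sigma^2_{ge}/e +
#' \sigma^2_\epsilon/(er))}, selection accuracy \eqn{A_s = \sqrt{h^2_{mg}}},
#' genotype-environment correlation
#' \eqn{r_{ge} = \sigma^2_{ge}/(\sigma^2_{ge} + \sigma^2_\epsilon)}, and the
#' genotypic and residual coefficients of variation with their ratio.
#'
#' @param vc Output of [variance_components()].
#' @param e,r Numbers of environments and replicates.
#' @param grand_mean Grand mean of the trait's indices (> 0).
#' @return List of the parameters above; entries are `NA` (with an
#'   `undefined` flag listing them) where a zero denominator makes the ratio
#'   meaningless.
#' @export
genetic_parameters <- function(vc, e, r, grand_mean) {
  if (!is.finite(grand_mean) || grand_mean <= 0) {
    stop_stressmet("`grand_mean` must be > 0", "stressmet_domain_error")
  }
  undef <- character(0)
  ratio <- function(num, den, name) {
    if (den <= 0) { undef <<- c(undef, name); return(NA_real_) }
    num / den
  }
  H2 <- ratio(vc$sigma2_g, vc$sigma2_p, "H2")
  R2gei <- ratio(vc$sigma2_ge, vc$sigma2_p, "R2gei")
  h2mg <- ratio(vc$sigma2_g,
                vc$sigma2_g + vc$sigma2_ge / e + vc$sigma2_e / (e * r),
                "h2mg")
  As <- if (is.na(h2mg)) NA_real_ else sqrt(h2mg)
  rge <- ratio(vc$sigma2_ge, vc$sigma2_ge + vc$sigma2_e, "rge")
  CVg <- 100 * sqrt(vc$sigma2_g) / grand_mean
  CVr <- 100 * sqrt(vc$sigma2_e) / grand_mean
  CVratio <- if (CVr > 0) CVg / CVr else { undef <- c(undef, "CV_ratio"); NA_real_ }
  list(H2 = H2, R2gei = R2gei, h2mg = h2mg, As = As, rge = rge,
       CVg = CVg, CVr = CVr, CV_ratio = CVratio, undefined = undef)
}

#' BLUPs of genotype and interaction effects for one trait
#'
#' Fits the linear mixed model with random genotype, environment,
#' replicate-within-environment and genotype-by-environment effects by REML
#' (via \pkg{lme4}) and returns the shrunken genotype effects and the
#' genotype-by-environment interaction BLUP matrix that feeds the
#' stability analysis. If REML fails (or the fit is degenerate, e.g.
#' noise-free data), a method-of-moments shrinkage fallback is used:
#' each raw centered effect is multiplied by
#' \eqn{\sigma^2/(\sigma^2 + \sigma^2_{err})} with the components taken from
#' [variance_components()]; with zero residual variance this reproduces the
#' raw centered table exactly.
#'
#' @param index_table Output of [build_index_environments()].
#' @param trait Trait name.
#' @return List with `genotype_blup` (named vector), `ge_blup` (g x e
#'   matrix), `genotype_mean` (BLUP-based genotype means,
#'   grand mean + genotype BLUP), `grand_mean`, and `method` (`"reml"` or
#'   `"moments"`).
#' @export
fit_blup <- function(index_table, trait) {
  d <- one_trait(index_table, trait)
  gen <- sort(unique(d$genotype)); env <- sort(unique(d$env))
  g <- length(gen); e <- length(env); r <- length(unique(d$rep))
  mu <- mean(d$index)
  cellm <- tapply(d$index, list(factor(d$genotype, gen), factor(d$env, env)),
                  mean)
  gm <- rowMeans(cellm); em <- colMeans(cellm)
  raw_g <- gm - mu
  raw_ge <- sweep(sweep(cellm, 1, gm), 2, em) + mu
  anova_tab <- joint_anova(index_table, trait)
  ms_res <- anova_tab$ms[anova_tab$source == "Residuals"]
  moments <- function() {
    vc <- variance_components(anova_tab)
    sh_g <- if (vc$sigma2_g + vc$sigma2_ge / e + vc$sigma2_e / (e * r) > 0) {
      vc$sigma2_g / (vc$sigma2_g + vc$sigma2_ge / e + vc$sigma2_e / (e * r))
    } else 0
    sh_ge <- if (vc$sigma2_ge + vc$sigma2_e / r > 0) {
      vc$sigma2_ge / (vc$sigma2_ge + vc$sigma2_e / r)
    } else 0
    list(genotype_blup = raw_g * sh_g, ge_blup = raw_ge * sh_ge,
         method = "moments")
  }
  res <- if (var(d$index) < 1e-12) {
    list(genotype_blup = raw_g * 0, ge_blup = raw_ge * 0, method = "moments")
  } else if (ms_res < 1e-10 * var(d$index)) {
    # residual variance numerically zero: REML is degenerate, the
    # method-of-moments shrinkage is exact here
    moments()
  } else {
    tryCatch({
      dd <- data.frame(y = d$index, GEN = factor(d$genotype, gen),
                       ENV = factor(d$env, env), REP = factor(d$rep))
      fit <- suppressMessages(suppressWarnings(
        lme4::lmer(y ~ 1 + (1 | GEN) + (1 | ENV) + (1 | ENV:REP) +
                     (1 | GEN:ENV), data = dd,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))
      ))
      re <- lme4::ranef(fit)
      gb <- setNames(re$GEN[[1]], rownames(re$GEN))[gen]
      ge_tab <- re$`GEN:ENV`
      keys <- strsplit(rownames(ge_tab), ":", fixed = TRUE)
      M <- matrix(0, g, e, dimnames = list(gen, env))
      for (i in seq_along(keys)) {
        M[keys[[i]][1], keys[[i]][2]] <- ge_tab[[1]][i]
      }
      list(genotype_blup = gb, ge_blup = M, method = "reml")
    }, error = function(err) {
      inform(sprintf("fit_blup('%s'): REML failed (%s); method-of-moments shrinkage used",
                     trait, conditionMessage(err)))
      moments()
    })
  }
  list(genotype_blup = res$genotype_blup,
       ge_blup = res$ge_blup,
       genotype_mean = mu + res$genotype_blup,
       grand_mean = mu,
       method = res$method)
}
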