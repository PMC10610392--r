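#' Specify one simulated trait
#'
#' Builds the per-trait block of a [sim_config()]. Each trait is simulated on
#' its own measurement scale as
#' \deqn{y = (\mu + g_i + e_j + r_{k(j)} + \sum_m \lambda_m u_{im} v_{jm} +
#'   \varepsilon) \times f_{c(i)}}
#' where \eqn{g_i}, \eqn{e_j}, \eqn{r_{k(j)}} and \eqn{\varepsilon} are
#' independent zero-mean Gaussians, the bilinear term is a planted
#' genotype-by-environment interaction of configured rank and singular values,
#' and \eqn{f} is the multiplicative stress-response factor of the genotype's
#' tolerance group (1 under optimal conditions).
#'
#' @param name Trait label.
#' @param mean Grand mean on the trait's measurement scale; must be positive
#'   (all traits are ratio-bound).
#' @param sd_g Genotypic standard deviation.
#' @param sd_env Environment (condition-by-season trial) standard deviation.
#' @param sd_block Block (replicate-within-trial) standard deviation.
#' @param sd_res Residual plot-level standard deviation.
#' @param gei_rank Rank of the planted interaction (0 for purely additive).
#' @param gei_sv Singular values of the planted interaction, length
#'   `gei_rank`, in descending order.
#' @param sense `"increase"` if larger values are agronomically better (e.g.
#'   grain yield), `"decrease"` otherwise (e.g. canopy temperature).
#' @param stress_inverts If `TRUE` the group stress factor is applied as its
#'   reciprocal, so stress raises rather than lowers the trait (canopy
#'   temperature behaves this way).
#' @param unit Measurement unit label carried through the dataset.
#' @return A `trait_spec` list.
#' @export
trait_spec <- function(name, mean, sd_g = 0, sd_env = 0, sd_block = 0,
                       sd_res = 0,
                       gei_rank = 0, gei_sv = numeric(0),
                       sense = c("increase", "decrease"),
                       stress_inverts = FALSE, unit = "") {
  sense <- match.arg(sense)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_stressmet("`name` must be a non-empty string", "stressmet_config_error")
  }
  if (mean <= 0) {
    stop_stressmet(sprintf("trait '%s': `mean` must be > 0", name),
                   "stressmet_config_error")
  }
  for (f in c("sd_g", "sd_env", "sd_block", "sd_res")) {
    v <- get(f)
    if (length(v) != 1L || !is.finite(v) || v < 0) {
      stop_stressmet(sprintf("trait '%s': `%s` must be a single value >= 0",
                             name, f), "stressmet_config_error")
    }
  }
  gei_rank <- as.integer(gei_rank)
  if (gei_rank < 0) {
    stop_stressmet(sprintf("trait '%s': `gei_rank` must be >= 0", name),
                   "stressmet_config_error")
  }
  if (length(gei_sv) != gei_rank || any(gei_sv < 0)) {
    stop_stressmet(
      sprintf("trait '%s': `gei_sv` must have length gei_rank with values >= 0",
              name), "stressmet_config_error")
  }
  structure(list(name = name, mean = mean, sd_g = sd_g, sd_env = sd_env,
                 sd_block = sd_block, sd_res = sd_res, gei_rank = gei_rank,
                 gei_sv = as.numeric(gei_sv), sense = sense,
                 stress_inverts = stress_inverts, unit = unit),
            class = "trait_spec")
}

#' Default trait panel for the simulated wheat trial
#'
#' Twenty physio-morphological and agronomic traits with plausible means,
#' coefficients of variation and interaction structure for a winter-wheat
#' stress trial: phenology (DH, DM, GFD), canopy and leaf traits (PH, FLA,
#' GLA, LAI, LWC, RWC, CT), gas exchange (Pn, Gs, E), antioxidant enzymes
#' (POD, PPO, CAT) and yield components (NS, NKS, TKW, GY).
#'
#' @return A named list of [trait_spec()] objects.
#' @export
default_trait_specs <- function() {
  spec <- function(name, mean, cv_g, cv_res, unit, sense = "increase",
                   stress_inverts = FALSE) {
    sg <- mean * cv_g / 100
    trait_spec(name, mean = mean, sd_g = sg, sd_env = sg / 2,
               sd_block = sg / 4, sd_res = mean * cv_res / 100,
               gei_rank = 2, gei_sv = c(1.2, 0.5) * sg, sense = sense,
               stress_inverts = stress_inverts, unit = unit)
  }
  lst <- list(
    spec("DH",  95,   2, 1.5, "day", sense = "decrease"),
    spec("DM",  140,  2, 1.5, "day", sense = "decrease"),
    spec("GFD", 42,   5, 4,   "day", sense = "decrease"),
    spec("NS",  350,  7, 7,   "spike m-2", sense = "decrease"),
    spec("PH",  95,   4, 4,   "cm", sense = "decrease"),
    spec("FLA", 32,   8, 6,   "cm2"),
    spec("GLA", 180, 10, 8,   "cm2"),
    spec("LAI", 3.6, 12, 6,   "m2 m-2"),
    spec("LWC", 74,   3, 3,   "%"),
    spec("RWC", 85,   3, 5,   "%"),
    spec("NKS", 52,   5, 6,   "kernel spike-1"),
    spec("TKW", 44,   5, 6,   "g"),
    spec("CT",  24,   4, 2,   "deg C", sense = "decrease",
         stress_inverts = TRUE),
    spec("Pn",  21,   9, 8,   "umol CO2 m-2 s-1"),
    spec("Gs",  0.42, 15, 7,  "mol H2O m-2 s-1"),
    spec("E",   5.8, 12, 8,   "mmol H2O m-2 s-1"),
    spec("POD", 38,  25, 7,   "U mg-1 protein"),
    spec("PPO", 24,  22, 6,   "U mg-1 protein"),
    spec("CAT", 11,  20, 3,   "U mg-1 protein"),
    spec("GY",  6.4, 10, 7,   "t ha-1")
  )
  setNames(lst, vapply(lst, `[[`, "", "name"))
}

#' Default tolerance-group stress responses
#'
#' Five tolerance groups, from highly tolerant (HT) to highly sensitive (HS),
#' each with a multiplicative response factor per stress condition: the
#' fraction of the optimal-condition value retained under stress. Tolerant
#' groups retain more; heat is slightly more damaging than drought.
#'
#' @return Named list: per group, a named numeric vector of factors keyed by
#'   stress condition.
#' @export
default_group_effects <- function() {
  list(
    HT = c(drought = 0.92, heat = 0.89),
    T  = c(drought = 0.86, heat = 0.83),
    M  = c(drought = 0.79, heat = 0.76),
    S  = c(drought = 0.72, heat = 0.68),
    HS = c(drought = 0.64, heat = 0.59)
  )
}

#' Configure a synthetic multi-environment stress trial
#'
#' The default configuration mirrors the reference design: 20 genotypes
#' evaluated under optimal, drought and heat conditions over three winter
#' seasons in randomized complete blocks with three replicates, on a panel of
#' 20 traits.
#'
#' @param n_genotypes Number of genotypes (>= 2).
#' @param seasons Character vector of season labels, chronological order.
#' @param conditions Character vector of conditions; must contain
#'   `"optimal"` plus at least one stress condition.
#' @param n_reps Replicates per trial (>= 2).
#' @param traits List of [trait_spec()] objects.
#' @param group_effects Named list of per-group stress factors, see
#'   [default_group_effects()].
#' @param group_of Optional character vector (length `n_genotypes`) assigning
#'   each genotype to a tolerance group; defaults to cycling through the
#'   groups.
#' @param tol_sd Relative spread of individual genotype tolerance around the
#'   group factor (a genotype's own stress response is
#'   `group factor * (1 + N(0, tol_sd))`, drawn once per condition). This is
#'   what makes genotypes within a group distinguishable on the index scale.
#' @param tol_gei_sd Relative season-to-season variability of each
#'   genotype's stress response; this is the planted genotype-by-environment
#'   interaction of the tolerance indices.
#' @param seed Integer seed; the generator is byte-reproducible under it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genotypes = 20,
                       seasons = c("2018/19", "2019/20", "2020/21"),
                       conditions = c("optimal", "drought", "heat"),
                       n_reps = 3,
                       traits = default_trait_specs(),
                       group_effects = default_group_effects(),
                       group_of = NULL,
                       tol_sd = 0.04,
                       tol_gei_sd = 0.05,
                       seed = 1L) {
  if (n_genotypes < 2) {
    stop_stressmet("`n_genotypes` must be >= 2", "stressmet_config_error")
  }
  if (n_reps < 2) {
    stop_stressmet("`n_reps` must be >= 2", "stressmet_config_error")
  }
  if (!"optimal" %in% conditions || length(conditions) < 2) {
    stop_stressmet(
      "`conditions` must include 'optimal' and at least one stress condition",
      "stressmet_config_error")
  }
  if (length(seasons) < 1 || anyDuplicated(seasons)) {
    stop_stressmet("`seasons` must be distinct labels",
                   "stressmet_config_error")
  }
  if (!length(traits)) {
    stop_stressmet("`traits` must contain at least one trait_spec",
                   "stressmet_config_error")
  }
  n_env <- length(conditions) * length(seasons)
  for (tr in traits) {
    if (!inherits(tr, "trait_spec")) {
      stop_stressmet("every element of `traits` must be a trait_spec",
                     "stressmet_config_error")
    }
    if (tr$gei_rank >= min(n_genotypes, n_env)) {
      stop_stressmet(
        sprintf("trait '%s': `gei_rank` must be < min(n_genotypes, n_environments) = %d",
                tr$name, min(n_genotypes, n_env)),
        "stressmet_config_error")
    }
  }
  groups <- names(group_effects)
  stress <- setdiff(conditions, "optimal")
  for (g in groups) {
    if (!all(stress %in% names(group_effects[[g]]))) {
      stop_stressmet(
        sprintf("`group_effects` for group '%s' must name every stress condition", g),
        "stressmet_config_error")
    }
  }
  if (is.null(group_of)) {
    group_of <- rep(groups, length.out = n_genotypes)
  }
  if (length(group_of) != n_genotypes || !all(group_of %in% groups)) {
    stop_stressmet(
      "`group_of` must assign each genotype a group named in `group_effects`",
      "stressmet_config_error")
  }
  if (tol_sd < 0 || tol_gei_sd < 0) {
    stop_stressmet("`tol_sd` and `tol_gei_sd` must be >= 0",
                   "stressmet_config_error")
  }
  structure(list(n_genotypes = as.integer(n_genotypes), seasons = seasons,
                 conditions = conditions, n_reps = as.integer(n_reps),
                 traits = traits, group_effects = group_effects,
                 group_of = group_of, tol_sd = tol_sd,
                 tol_gei_sd = tol_gei_sd, seed = as.integer(seed)),
            class = "sim_config")
}

# run expr under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# zero-mean, unit-norm columns orthogonal to each other and to the intercept,
# so the planted bilinear term survives double-centering unchanged
orthonormal_scores <- function(n, rank) {
  if (rank == 0) return(matrix(0, n, 0))
  M <- matrix(rnorm(n * rank), n, rank)
  M <- sweep(M, 2, colMeans(M))
  qr.Q(qr(M))[, seq_len(rank), drop = FALSE]
}

#' Generate a balanced synthetic multi-environment trial
#'
#' Simulates replicate-level trait values for every genotype x condition x
#' season x replicate cell, with known (recorded) genotype effects, trial
#' effects, low-rank genotype-by-environment interaction and tolerance-group
#' stress responses. Ratio-bound traits are truncated at `1e-6` if a draw
#' falls non-positive (a message reports how many cells were affected).
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `genotype`, `condition`, `season`, `rep`,
#'   `trait`, `value`, `unit` (one row per cell per trait) and attributes
#'   `planted` (the simulated effect components per trait), `group_of` and
#'   `config`.
#' @export
generate_met <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop_stressmet("`config` must be a sim_config object",
                   "stressmet_config_error")
  }
  gen <- sprintf("G%02d", seq_len(config$n_genotypes))
  env <- expand.grid(condition = config$conditions, season = config$seasons,
                     stringsAsFactors = FALSE)
  env$label <- paste(env$condition, env$season, sep = "|")
  n_g <- length(gen); n_e <- nrow(env); n_r <- config$n_reps
  stress <- setdiff(config$conditions, "optimal")
  with_seed(config$seed, {
    planted <- list()
    rows <- vector("list", length(config$traits))
    n_trunc <- 0L
    for (ti in seq_along(config$traits)) {
      tr <- config$traits[[ti]]
      g_eff <- rnorm(n_g, 0, tr$sd_g)
      e_eff <- rnorm(n_e, 0, tr$sd_env)
      r_eff <- matrix(rnorm(n_e * n_r, 0, tr$sd_block), n_e, n_r)
      U <- orthonormal_scores(n_g, tr$gei_rank)
      V <- orthonormal_scores(n_e, tr$gei_rank)
      gei <- if (tr$gei_rank > 0) {
        U %*% diag(tr$gei_sv, tr$gei_rank) %*% t(V)
      } else matrix(0, n_g, n_e)
      # genotype-specific stress response: group factor, a per-genotype
      # tolerance deviation (constant over seasons), and a per-season
      # deviation -- the planted interaction of the tolerance indices
      delta <- matrix(rnorm(n_g * length(stress), 0, config$tol_sd),
                      n_g, length(stress), dimnames = list(gen, stress))
      eta <- array(rnorm(n_g * length(stress) * length(config$seasons),
                         0, config$tol_gei_sd),
                   dim = c(n_g, length(stress), length(config$seasons)),
                   dimnames = list(gen, stress, config$seasons))
      fmat <- matrix(1, n_g, n_e)
      for (j in seq_len(n_e)) {
        cond <- env$condition[j]
        if (cond == "optimal") next
        gf <- vapply(config$group_of,
                     function(gr) config$group_effects[[gr]][[cond]], 0)
        f <- gf * (1 + delta[, cond]) *
          (1 + eta[, cond, env$season[j]])
        f <- pmax(f, 0.05)
        fmat[, j] <- if (tr$stress_inverts) 1 / f else f
      }
      base <- tr$mean + outer(g_eff, e_eff, "+") + gei   # n_g x n_e
      idx <- expand.grid(i = seq_len(n_g), j = seq_len(n_e),
                         k = seq_len(n_r))
      eps <- rnorm(nrow(idx), 0, tr$sd_res)
      val <- (base[cbind(idx$i, idx$j)] + r_eff[cbind(idx$j, idx$k)] + eps) *
        fmat[cbind(idx$i, idx$j)]
      low <- val <= 0
      if (any(low)) {
        n_trunc <- n_trunc + sum(low)
        val[low] <- 1e-6
      }
      rows[[ti]] <- tibble(
        genotype = gen[idx$i],
        condition = env$condition[idx$j],
        season = env$season[idx$j],
        rep = idx$k,
        trait = tr$name,
        value = val,
        unit = tr$unit
      )
      dimnames(gei) <- list(gen, env$label)
      planted[[tr$name]] <- list(
        mean = tr$mean, genotype = setNames(g_eff, gen),
        environment = setNames(e_eff, env$label),
        block = r_eff, gei = gei, singular_values = tr$gei_sv,
        stress_factor = `dimnames<-`(fmat, list(gen, env$label)),
        sense = tr$sense
      )
    }
    if (n_trunc > 0) {
      inform(sprintf("generate_met: %d non-positive draws truncated at 1e-6",
                     n_trunc))
    }
    out <- bind_rows(rows)
    out <- out[order(match(out$trait, names(config$traits)), out$genotype,
                     match(out$condition, config$conditions),
                     match(out$season, config$seasons), out$rep), ]
    attr(out, "planted") <- planted
    attr(out, "group_of") <- setNames(config$group_of, gen)
    attr(out, "config") <- config
    out
  })
}

#' Check that a trial dataset is fully balanced
#'
#' Every genotype x condition x season x replicate x trait combination must
#' occur exactly once and every value must be finite.
#'
#' @param data A long-format trial tibble as produced by [generate_met()] or
#'   [read_met_csv()].
#' @return `data`, invisibly, if valid; otherwise an error of class
#'   `stressmet_balance_error` listing the offending cells.
#' @export
validate_met <- function(data) {
  need <- c("genotype", "condition", "season", "rep", "trait", "value")
  if (!all(need %in% names(data))) {
    stop_stressmet(paste("missing columns:",
                         paste(setdiff(need, names(data)), collapse = ", ")),
                   "stressmet_format_error")
  }
  if (!all(is.finite(data$value))) {
    stop_stressmet("non-finite trait values present", "stressmet_format_error")
  }
  full <- expand.grid(genotype = unique(data$genotype),
                      condition = unique(data$condition),
                      season = unique(data$season),
                      rep = unique(data$rep),
                      trait = unique(data$trait),
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$genotype, d$condition, d$season, d$rep, d$trait,
                           sep = "/")
  have <- key(data)
  if (anyDuplicated(have)) {
    stop_stressmet(paste("duplicated cells:",
                         paste(head(unique(have[duplicated(have)]), 5),
                               collapse = "; ")),
                   "stressmet_balance_error")
  }
  missing <- setdiff(key(full), have)
  if (length(missing)) {
    stop_stressmet(paste0("unbalanced dataset; missing cells (",
                          length(missing), "): ",
                          paste(head(missing, 5), collapse = "; ")),
                   "stressmet_balance_error")
  }
  invisible(data)
}

#' Write / read a trial dataset as CSV
#'
#' Long format, UTF-8, header row, fixed column order
#' `genotype,condition,season,rep,trait,value,unit`. Reading validates
#' balance and round-trips [write_met_csv()] output identically.
#'
#' @param data Trial tibble.
#' @param path File path.
#' @return `write_met_csv()` returns `path` invisibly; `read_met_csv()`
#'   returns the validated tibble.
#' @export
write_met_csv <- function(data, path) {
  validate_met(data)
  cols <- c("genotype", "condition", "season", "rep", "trait", "value", "unit")
  if (!"unit" %in% names(data)) data$unit <- ""
  write.csv(as.data.frame(data)[, cols], path, row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_met_csv
#' @export
read_met_csv <- function(path) {
  if (!file.exists(path)) {
    stop_stressmet(paste("file not found:", path), "stressmet_format_error")
  }
  d <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                colClasses = c(genotype = "character", condition = "character",
                               season = "character", trait = "character",
                               unit = "character"))
  d <- as_tibble(d)
  validate_met(d)
  d
}
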