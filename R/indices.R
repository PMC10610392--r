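#' Stress tolerance index of one observation
#'
#' The drought (DTI) and heat (HTI) tolerance indices are the ratio of a
#' trait's value under stress to its value under optimal conditions in the
#' same season: values near 1 mean the genotype held its performance under
#' stress.
#'
#' @param x_stress Trait value under the stress condition.
#' @param x_optimal Trait value under the optimal condition (> 0).
#' @param where Optional label (genotype/trait/cell) used in error messages.
#' @return `x_stress / x_optimal`.
#' @export
tolerance_index <- function(x_stress, x_optimal, where = NULL) {
  bad <- !is.finite(x_optimal) | x_optimal <= 0
  if (any(bad)) {
    lab <- if (is.null(where)) which(bad)[1] else where[bad][1]
    stop_stressmet(
      sprintf("optimal-condition value must be > 0 (first offending cell: %s)",
              lab),
      "stressmet_domain_error")
  }
  x_stress / x_optimal
}

#' Build the tolerance index environments
#'
#' Converts a raw trial into the derived "index environments": one per
#' (stress condition, season) pair, coded `E1, E2, ...` with seasons in
#' chronological order and drought before heat within a season (three seasons
#' by two stresses give E1-E6). The index is formed per replicate, pairing
#' stress block `k` with optimal block `k` of the same season, so the joint
#' ANOVA of the indices keeps a replicate-within-environment stratum.
#'
#' @param data Balanced trial tibble (must contain the `optimal` condition
#'   and at least one stress condition in every season).
#' @param stress_order Order in which stress conditions are assigned codes
#'   within a season; defaults to the order of appearance with `"drought"`
#'   first if present.
#' @return A tibble `genotype, env, rep, trait, index` with attribute
#'   `env_map` (tibble `env, condition, season`). Sense metadata on the
#'   input, if present, is carried through.
#' @export
build_index_environments <- function(data, stress_order = NULL) {
  validate_met(data)
  conds <- unique(data$condition)
  if (!"optimal" %in% conds) {
    stop_stressmet("dataset has no 'optimal' condition",
                   "stressmet_balance_error")
  }
  stress <- setdiff(conds, "optimal")
  if (!length(stress)) {
    stop_stressmet("dataset has no stress condition",
                   "stressmet_balance_error")
  }
  if (is.null(stress_order)) {
    stress_order <- c(intersect("drought", stress),
                      setdiff(stress, "drought"))
  }
  seasons <- sort(unique(data$season))
  env_map <- expand.grid(condition = stress_order, season = seasons,
                         stringsAsFactors = FALSE)
  env_map <- env_map[order(env_map$season,
                           match(env_map$condition, stress_order)), ]
  env_map$env <- sprintf("E%d", seq_len(nrow(env_map)))
  opt <- data %>%
    filter(.data$condition == "optimal") %>%
    select("genotype", "season", "rep", "trait", x_optimal = "value")
  str_d <- data %>%
    filter(.data$condition != "optimal") %>%
    left_join(env_map, by = c("condition", "season"))
  joined <- left_join(str_d, opt, by = c("genotype", "season", "rep", "trait"))
  if (anyNA(joined$x_optimal)) {
    miss <- joined[is.na(joined$x_optimal), ]
    stop_stressmet(
      paste("missing optimal counterpart for:",
            paste(head(paste(miss$genotype, miss$season, miss$rep, miss$trait,
                             sep = "/"), 5), collapse = "; ")),
      "stressmet_balance_error")
  }
  out <- joined %>%
    mutate(index = tolerance_index(
      .data$value, .data$x_optimal,
      where = paste(.data$genotype, .data$env, .data$rep, .data$trait,
                    sep = "/"))) %>%
    select("genotype", "env", "rep", "trait", "index") %>%
    arrange(match(.data$trait, unique(data$trait)), .data$genotype,
            .data$env, .data$rep)
  attr(out, "env_map") <- as_tibble(env_map[, c("env", "condition", "season")])
  out
}

#' Export the index-environment code map as JSON
#'
#' @param index_table Result of [build_index_environments()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_env_map_json <- function(index_table, path) {
  m <- attr(index_table, "env_map")
  if (is.null(m)) {
    stop_stressmet("index table carries no env_map attribute",
                   "stressmet_format_error")
  }
  jsonlite::write_json(m, path, dataframe = "rows", pretty = TRUE)
  invisible(path)
}
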