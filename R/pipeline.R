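#' Configure a full analysis run
#'
#' @param input Path to a long-format trial CSV (see [read_met_csv()]), or
#'   `NULL` to simulate.
#' @param sim A [sim_config()] used when `input` is `NULL`.
#' @param senses Named trait sense vector; defaults to the senses of the
#'   simulation's trait specs (required for CSV input).
#' @param gy_trait Name of the yield trait that orients selection.
#' @param mgidi_intensity Selection intensity for [mgidi_index()].
#' @param theta_Y,theta_S WAASBY weights.
#' @param alpha_enter,alpha_remove Stepwise thresholds.
#' @param smlr_mode `"pooled"` regresses on the genotype-by-environment mean
#'   rows; `"genotype"` on the genotype means.
#' @param cluster_k Number of tolerance categories.
#' @param lda_prior `"frequency"` or `"equal"`.
#' @param out_dir Output directory (`NULL` for no files).
#' @param seed Seed for any simulation.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, sim = sim_config(seed = seed),
                            senses = NULL, gy_trait = "GY",
                            mgidi_intensity = 0.20,
                            theta_Y = 50, theta_S = 50,
                            alpha_enter = 0.05, alpha_remove = 0.10,
                            smlr_mode = c("pooled", "genotype"),
                            cluster_k = 5,
                            lda_prior = c("frequency", "equal"),
                            out_dir = NULL, seed = 1L) {
  smlr_mode <- match.arg(smlr_mode)
  lda_prior <- match.arg(lda_prior)
  if (mgidi_intensity <= 0 || mgidi_intensity > 1) {
    stop_stressmet("`mgidi_intensity` must be in (0, 1]",
                   "stressmet_config_error")
  }
  if (is.null(input)) {
    if (is.null(senses)) {
      senses <- vapply(sim$traits, `[[`, "", "sense")
      names(senses) <- names(sim$traits)
    }
  } else if (is.null(senses)) {
    stop_stressmet("`senses` is required for CSV input",
                   "stressmet_config_error")
  }
  structure(list(input = input, sim = sim, senses = senses,
                 gy_trait = gy_trait, mgidi_intensity = mgidi_intensity,
                 theta_Y = theta_Y, theta_S = theta_S,
                 alpha_enter = alpha_enter, alpha_remove = alpha_remove,
                 smlr_mode = smlr_mode, cluster_k = cluster_k,
                 lda_prior = lda_prior, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; a `sim`
#' block, if present, is passed to [sim_config()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  if (!file.exists(path)) {
    stop_stressmet(paste("config file not found:", path),
                   "stressmet_config_error")
  }
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), "sim")]
  if (!is.null(y$sim)) {
    args$sim <- do.call(sim_config, y$sim)
  }
  if (!is.null(args$senses)) args$senses <- unlist(args$senses)
  do.call(pipeline_config, args)
}

#' Run the full ideotype-identification analysis
#'
#' Executes the stages in order: tolerance index construction; per-trait
#' joint ANOVA, variance components, genetic parameters and BLUPs; AMMI
#' decomposition and Gollob tests of the yield index; WAASB/WAASBY stability
#' with quadrant classification; MGIDI ideotype selection with selection
#' gains; stepwise regression of the yield index on the other trait indices;
#' Ward clustering into tolerance categories with LDA validation
#' (resubstitution and leave-one-out). A consensus summary lists the
#' genotypes appearing in the MGIDI selected set, the stable-productive
#' WAASB quadrant (IV), and the LDA-confirmed tolerant categories, plus
#' their intersection.
#'
#' If `out_dir` is set, every stage table is written as CSV along with a
#' JSON manifest recording the configuration, seed and per-file MD5
#' checksums; re-running with the same config and seed reproduces identical
#' checksums.
#'
#' @param config A [pipeline_config()].
#' @return A `report_bundle` list with elements `data`, `index_table`,
#'   `env_map`, `anova`, `parameters`, `blup`, `ammi`, `waasb`, `waasby`,
#'   `quadrants`, `mgidi`, `smlr`, `classify`, `consensus`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop_stressmet("`config` must be a pipeline_config",
                   "stressmet_config_error")
  }
  log_stage <- function(stage, ...) {
    inform(sprintf("[%s] %s", stage, sprintf(...)))
  }
  data <- if (is.null(config$input)) {
    generate_met(config$sim)
  } else {
    read_met_csv(config$input)
  }
  traits <- unique(data$trait)
  gy <- config$gy_trait
  if (!gy %in% traits) {
    stop_stressmet(sprintf("yield trait '%s' not in the data", gy),
                   "stressmet_config_error")
  }
  missing_sense <- setdiff(traits, names(config$senses))
  if (length(missing_sense)) {
    stop_stressmet(paste("no sense configured for:",
                         paste(missing_sense, collapse = ", ")),
                   "stressmet_config_error")
  }
  log_stage("indices", "input: %d rows, %d traits", nrow(data),
            length(traits))
  idx <- build_index_environments(data)

  log_stage("genparams", "%d traits x %d index rows", length(traits),
            nrow(idx))
  anova_list <- list(); param_rows <- list(); blups <- list()
  h2mg <- setNames(numeric(length(traits)), traits)
  for (tr in traits) {
    a <- joint_anova(idx, tr)
    vc <- variance_components(a)
    gp <- genetic_parameters(vc, e = attr(a, "e"), r = attr(a, "r"),
                             grand_mean = attr(a, "grand_mean"))
    anova_list[[tr]] <- a
    param_rows[[tr]] <- tibble(
      trait = tr, sigma2_g = vc$sigma2_g, sigma2_ge = vc$sigma2_ge,
      sigma2_e = vc$sigma2_e, sigma2_p = vc$sigma2_p, H2 = gp$H2,
      R2gei = gp$R2gei, h2mg = gp$h2mg, As = gp$As, rge = gp$rge,
      CVg = gp$CVg, CVr = gp$CVr, CV_ratio = gp$CV_ratio)
    blups[[tr]] <- fit_blup(idx, tr)
    h2mg[tr] <- if (is.na(gp$h2mg)) 0 else gp$h2mg
  }
  params <- bind_rows(param_rows)

  log_stage("ammi", "decomposing '%s' means table", gy)
  means_gy <- two_way_means(idx, gy)
  decomp <- ammi_decompose(means_gy)
  ammi_tab <- ammi_anova(decomp, anova_list[[gy]])
  biplot <- ammi_biplot_coords(decomp)

  log_stage("waasb", "BLUP-based stability for '%s'", gy)
  wa <- waasb_from_blup(blups[[gy]])
  wy <- waasby(wa, config$theta_Y, config$theta_S,
               sense = unname(config$senses[gy]))
  quad <- classify_quadrants(setNames(wa$genotypes$Y, wa$genotypes$label),
                             setNames(wa$genotypes$waasb,
                                      wa$genotypes$label))

  log_stage("mgidi", "intensity %.2f", config$mgidi_intensity)
  gmeans <- vapply(traits, function(tr) blups[[tr]]$genotype_mean,
                   numeric(length(blups[[gy]]$genotype_mean)))
  rownames(gmeans) <- names(blups[[gy]]$genotype_mean)
  mg <- run_mgidi(gmeans, config$senses, intensity = config$mgidi_intensity,
                  h2mg = h2mg)

  log_stage("smlr", "mode '%s'", config$smlr_mode)
  if (config$smlr_mode == "pooled") {
    wide <- idx %>%
      group_by(.data$genotype, .data$env, .data$trait) %>%
      summarise(index = mean(.data$index), .groups = "drop") %>%
      pivot_wider(names_from = "trait", values_from = "index")
    Xs <- as.matrix(wide[, setdiff(traits, gy)])
    ys <- wide[[gy]]
    sm_labels <- paste(wide$genotype, wide$env, sep = ":")
  } else {
    Xs <- gmeans[, setdiff(traits, gy), drop = FALSE]
    ys <- gmeans[, gy]
    sm_labels <- rownames(gmeans)
  }
  sm <- stepwise_fit(Xs, ys, config$alpha_enter, config$alpha_remove)
  sm_report <- predict_report(sm, Xs, ys, labels = sm_labels)
  # per-genotype diagnostics are reported on genotype means in either mode
  sm_gen_report <- predict_report(
    sm, gmeans[, setdiff(traits, gy), drop = FALSE], gmeans[, gy],
    labels = rownames(gmeans))

  log_stage("classify", "Ward k=%d + LDA (%s priors)", config$cluster_k,
            config$lda_prior)
  cl <- ward_cluster(gmeans, k = config$cluster_k, gy_trait = gy)
  ld <- lda_fit(gmeans, cl$category, prior = config$lda_prior)
  ld_res <- lda_classify(ld, gmeans, prior_labels = cl$category)
  ld_loo <- lda_loo(gmeans, cl$category, prior = config$lda_prior)

  tolerant <- c("HT", "T")
  lda_confirmed <- ld_res$label[ld_res$prior %in% tolerant &
                                  ld_res$posterior == ld_res$prior]
  consensus <- list(
    mgidi_selected = mg$index$selected,
    waasb_quadrant_iv = quad$label[quad$quadrant == "IV"],
    lda_confirmed_tolerant = lda_confirmed)
  consensus$intersection <- Reduce(intersect, consensus)
  log_stage("consensus", "intersection: %s",
            paste(consensus$intersection, collapse = ", "))

  bundle <- list(data = data, index_table = idx,
                 env_map = attr(idx, "env_map"),
                 anova = anova_list, parameters = params, blup = blups,
                 ammi = list(means = means_gy, decomposition = decomp,
                             anova = ammi_tab, biplot = biplot),
                 waasb = wa, waasby = wy, quadrants = quad, mgidi = mg,
                 smlr = list(model = sm, report = sm_report,
                             genotype_report = sm_gen_report),
                 classify = list(cluster = cl, lda = ld,
                                 resubstitution = ld_res, loo = ld_loo),
                 consensus = consensus, config = config)
  if (!is.null(config$out_dir)) {
    bundle$manifest <- write_bundle(bundle, config$out_dir)
  }
  class(bundle) <- "report_bundle"
  bundle
}

write_tab <- function(x, dir, name) {
  p <- file.path(dir, paste0(name, ".csv"))
  write.csv(as.data.frame(x), p, row.names = FALSE)
  p
}

#' Write a report bundle's tables and manifest to disk
#'
#' @param bundle A [run_pipeline()] result (pre-manifest).
#' @param dir Output directory, created if needed.
#' @return The manifest list, invisibly written to `manifest.json`.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    write_tab(bundle$index_table, dir, "index_table"),
    write_tab(bundle$env_map, dir, "env_map"),
    write_tab(bind_rows(lapply(names(bundle$anova), function(tr) {
      a <- bundle$anova[[tr]]; a$trait <- tr; a
    })), dir, "anova"),
    write_tab(bundle$parameters, dir, "parameters"),
    write_tab(bundle$ammi$anova, dir, "ammi_anova"),
    write_tab(bundle$ammi$biplot$points, dir, "ammi_biplot"),
    write_tab(bundle$waasb$genotypes, dir, "waasb_genotypes"),
    write_tab(bundle$waasb$environments, dir, "waasb_environments"),
    write_tab(bundle$waasby, dir, "waasby"),
    write_tab(bundle$quadrants, dir, "quadrants"),
    write_tab(bundle$mgidi$index$table, dir, "mgidi"),
    write_tab(bundle$mgidi$contributions, dir, "mgidi_contributions"),
    write_tab(if (!is.null(bundle$mgidi$gains)) bundle$mgidi$gains else
      tibble(), dir, "mgidi_gains"),
    write_tab(bundle$smlr$model$coefficients, dir, "smlr_coefficients"),
    write_tab(bundle$smlr$genotype_report, dir, "smlr_report"),
    write_tab(tibble(genotype = names(bundle$classify$cluster$category),
                     category = unname(bundle$classify$cluster$category)),
              dir, "cluster_categories"),
    write_tab(bundle$classify$resubstitution, dir, "lda_resubstitution"),
    write_tab(bundle$classify$loo, dir, "lda_loo")
  )
  manifest <- list(
    package = "stressmet",
    version = as.character(utils::packageVersion("stressmet")),
    seed = bundle$config$seed,
    config = bundle$config[setdiff(names(bundle$config),
                                   c("sim", "out_dir"))],
    consensus = bundle$consensus,
    checksums = as.list(setNames(unname(tools::md5sum(files)),
                                 basename(files))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}
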