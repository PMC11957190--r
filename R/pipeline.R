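#' End-to-end pipeline orchestration
#'
#' Runs simulate -> distribution selection -> screens -> validation ->
#' enrichment from a single configuration, writing every table plus a
#' reproducibility manifest.  The numbered scripts under `analysis/` are
#' thin drivers over the same stage functions.
#'
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' All analysis thresholds surfaced as keys with their study defaults:
#' FDR 0.1, binding-score cutoff 80, CPM filter (1 CPM in >= 50% of
#' samples), 10-fold CV, 1000 bootstrap replicates.
#'
#' @param seed Master seed.
#' @param ... Overrides for [sim_config()] fields.
#' @return Nested list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L, ...) {
  list(seed = as.integer(seed),
       simulate = list(...),
       filter = list(min_cpm = 1, min_fraction = 0.5),
       distfit = list(bootstrap_B = 1000L,
                      family_a = "negative_binomial", family_b = "gamma"),
       screen = list(fdr = 0.1,
                     adversities = ADVERSITIES,
                     pairings = list(discovery = c(expr = 2L, outcome = 3L),
                                     validation = c(expr = 4L, outcome = 4L))),
       validate = list(k = 10L),
       enrich = list(score_cutoff = 80, fdr = 0.1))
}

#' Read and validate a pipeline configuration from YAML
#'
#' @param path YAML file; must contain a `seed` key.
#' @return Validated config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg Config list to validate.
#' @export
validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$seed))
    stop("config_error: missing required field 'seed'", call. = FALSE)
  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed))
    stop("config_error: 'seed' must be an integer", call. = FALSE)
  base <- default_pipeline_config(seed = cfg$seed)
  for (k in setdiff(names(base), "seed"))
    if (!is.null(cfg[[k]]))
      base[[k]][names(cfg[[k]])] <- cfg[[k]]
  for (k in c("fdr")) {
    v <- base$screen[[k]]
    if (!is.numeric(v) || v <= 0 || v > 1)
      stop("config_error: screen.", k, " must lie in (0, 1]", call. = FALSE)
  }
  base
}

stage_log <- function(stage, msg, ...) {
  message(sprintf("[%s] %s", stage, sprintf(msg, ...)))
}

#' Run the full pipeline
#'
#' Stages run in dependency order; each stage records row counts and its
#' analytic decisions in the manifest.  Statistical outputs are a pure
#' function of the configuration and seed.
#'
#' @param config Config list (see [default_pipeline_config()]) or a path
#'   to a YAML file.
#' @param out_dir Output directory for the artifact tree.
#' @return Invisibly, a list with every stage's in-memory result plus the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  else config <- validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(tool_version = as.character(utils::packageVersion("mirmod")),
                   seed = config$seed,
                   stages = list())
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  manifest$config_hash <- unname(tools::md5sum(cfg_path))

  ## -- simulate ------------------------------------------------------
  sim_args <- c(list(seed = config$seed), config$simulate)
  scfg <- do.call(sim_config, sim_args)
  bundle <- gen_dataset(scfg, out_dir = file.path(out_dir, "data"))
  stage_log("simulate", "n=%d participants, m=%d miRNAs",
            scfg$n_participants, scfg$n_mirnas)
  manifest$stages$simulate <- list(
    n_participants = scfg$n_participants, n_mirnas = scfg$n_mirnas,
    planted_modifiers = nrow(bundle$ground_truth$modifiers))

  ## -- distribution selection ---------------------------------------
  ptss3 <- bundle$phenotype$ptss[bundle$phenotype$wave == 3]
  # gamma/Weibull need y > 0; shift only when a zero actually occurs
  eps_shift <- any(ptss3 == 0)
  ranking <- select_distribution(ptss3, epsilon_shift = eps_shift)
  boot <- bootstrap_bic_compare(ptss3, config$distfit$family_a,
                                config$distfit$family_b,
                                B = config$distfit$bootstrap_B,
                                seed = config$seed + 7L,
                                epsilon_shift = eps_shift)
  utils::write.table(ranking$table,
                     file.path(out_dir, "distribution_ranking.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(boot[c("mean_delta", "p", "B", "n_failed")],
                       file.path(out_dir, "bootstrap_bic.json"),
                       auto_unbox = TRUE, digits = NA)
  stage_log("distfit", "best family: %s (bootstrap p=%.3f)",
            ranking$table$family[1], boot$p)
  manifest$stages$distfit <- list(best_family = ranking$table$family[1],
                                  bootstrap_p = boot$p,
                                  B = config$distfit$bootstrap_B,
                                  epsilon_shift = eps_shift)

  ## -- screens -------------------------------------------------------
  filt2 <- filter_low_expression(bundle$counts$wave2,
                                 config$filter$min_cpm,
                                 config$filter$min_fraction)
  filt4 <- filter_low_expression(bundle$counts$wave4,
                                 config$filter$min_cpm,
                                 config$filter$min_fraction)
  norm2 <- cpm_log_normalize(filt2)
  norm4 <- cpm_log_normalize(filt4)
  pairings <- config$screen$pairings
  screens <- list()
  for (pn in names(pairings)) {
    pr <- pairings[[pn]]
    norm <- if (pr[["expr"]] == 2) norm2 else norm4
    main <- main_effect_screen(norm, bundle$phenotype, pr[["expr"]],
                               pr[["outcome"]],
                               fdr_threshold = config$screen$fdr)
    write_screen_records(main,
                         file.path(out_dir,
                                   sprintf("screen_%s_main.tsv", pn)))
    screens[[pn]] <- list(main = main)
    for (adv in config$screen$adversities) {
      rec <- interaction_screen(norm, bundle$phenotype, adv, pr[["expr"]],
                                pr[["outcome"]],
                                fdr_threshold = config$screen$fdr)
      write_screen_records(rec,
                           file.path(out_dir,
                                     sprintf("screen_%s_%s.tsv", pn, adv)))
      screens[[pn]][[adv]] <- rec
      stage_log("screen", "%s/%s: %d hits (FDR<%.2g) of %d estimable",
                pn, adv, nrow(significant_hits(rec, config$screen$fdr)),
                config$screen$fdr, sum(rec$estimable))
    }
  }
  manifest$stages$screen <- list(
    fdr_family = "BH within each (adversity, wave-pair) screen",
    fdr_threshold = config$screen$fdr,
    link = "log",
    mirnas_tested = c(discovery = nrow(norm2), validation = nrow(norm4)))

  ## -- validation ----------------------------------------------------
  pr <- pairings$discovery
  aligned <- align_samples(norm2, bundle$phenotype, pr[["expr"]],
                           pr[["outcome"]])
  X <- build_design(aligned$data, ADVERSITIES)
  cv <- kfold_cv_spearman(aligned$data$ptss, X, k = config$validate$k,
                          seed = config$seed + 11L)
  stage_log("validate", "%d-fold CV Spearman of the adversity model: %.3f",
            cv$k, cv$mean_rho)

  target_adv <- unique(bundle$ground_truth$modifiers$adversity)
  if (length(target_adv) == 0) target_adv <- "trauma_lifetime"
  disc <- screens$discovery[[target_adv[1]]]
  val <- screens$validation[[target_adv[1]]]
  hits <- significant_hits(disc, config$screen$fdr)$mirna_id
  crosswave <- NULL
  shared <- intersect(val$mirna_id[val$estimable], hits)
  if (length(shared) > 0 &&
      length(shared) < sum(val$estimable)) {
    scores <- stats::setNames(val$score[val$estimable],
                              val$mirna_id[val$estimable])
    crosswave <- cross_wave_consistency(scores, shared)
    stage_log("validate", "cross-wave consistency: W=%.1f, p=%.3g",
              crosswave$W, crosswave$p)
  } else {
    stage_log("validate",
              "cross-wave consistency skipped (no usable hit set)")
  }
  jsonlite::write_json(
    list(cv = list(k = cv$k, mean_rho = cv$mean_rho,
                   per_fold_rho = cv$per_fold_rho),
         crosswave = crosswave),
    file.path(out_dir, "validation.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  manifest$stages$validate <- list(cv_mean_rho = cv$mean_rho,
                                   crosswave_p = if (is.null(crosswave))
                                     NA else crosswave$p)

  ## -- enrichment ----------------------------------------------------
  enrich_tab <- NULL
  if (length(hits) > 0) {
    td <- gen_target_data(rownames(bundle$counts$wave2),
                          signal_mirnas = bundle$ground_truth$modifier_ids,
                          seed = config$seed)
    gmt_path <- file.path(out_dir, "data", "pathways_synthetic.gmt")
    writeLines(td$gmt_lines, gmt_path)
    tt_path <- file.path(out_dir, "data", "targets_synthetic.tsv")
    utils::write.table(td$targets, tt_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    targets <- read_target_table(tt_path,
                                 score_cutoff = config$enrich$score_cutoff)
    sets <- read_gmt(gmt_path)
    usable <- intersect(hits, unique(targets$mirna))
    if (length(usable)) {
      enrich_tab <- enrich_all(usable, targets, sets,
                               fdr_threshold = config$enrich$fdr)
      utils::write.table(enrich_tab, file.path(out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      stage_log("enrich", "%d/%d pathways significant at adjusted p<%.2g",
                sum(enrich_tab$significant), nrow(enrich_tab),
                config$enrich$fdr)
    }
  }
  manifest$stages$enrich <- list(
    score_cutoff = config$enrich$score_cutoff,
    fdr_threshold = config$enrich$fdr,
    universe = "filtered target genes union pathway genes",
    n_significant = if (is.null(enrich_tab)) 0L
                    else sum(enrich_tab$significant))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(bundle = bundle, ranking = ranking, bootstrap = boot,
                 screens = screens, cv = cv, crosswave = crosswave,
                 enrichment = enrich_tab, manifest = manifest))
}
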