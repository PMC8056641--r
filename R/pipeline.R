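#' Default pipeline configuration
#'
#' Settings for [run_pipeline()]: a simulated cohort, clock-training
#' options, and evaluation options. Any subset can be overridden via a YAML
#' file or an override list; unknown keys are an error.
#'
#' @param overrides named list (possibly nested) of settings to replace.
#' @return A nested configuration list.
#' @export
pipeline_config <- function(overrides = list()) {
  cfg <- list(
    seed = 42L,
    simulation = list(n_samples = 600L, n_probes = 4000L, n_active = 30L,
                      signal_fraction = 0.8, noise_sd = 0.3,
                      art_fraction = 0.45, icsi_fraction = 0.5,
                      frozen_fraction = 0.25, gaa_shift_days = 0,
                      missing_rate = 0.01),
    annotation = list(frac_450k = 0.6, frac_cross_reactive = 0.05,
                      frac_snp = 0.02, frac_non_autosomal = 0.03),
    train = list(n_folds = 10L, lambda_rule = "min", train_fraction = 0.8),
    evaluate = list(n_boot = 500L, ci_level = 0.95)
  )
  merge_config(cfg, overrides)
}

merge_config <- function(base, overrides) {
  for (nm in names(overrides)) {
    if (!nm %in% names(base)) {
      stop("unknown configuration key: ", nm, call. = FALSE)
    }
    if (is.list(base[[nm]]) && is.list(overrides[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], overrides[[nm]])
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  base
}

#' Run the full clock workflow on a simulated cohort
#'
#' Executes, with counts logged at each stage: cohort simulation; probe
#' filtering; ETD annotation; a train/test split of the non-ART samples; a
#' second split of the ART samples; training of three clocks (the main
#' clock on non-ART training samples against ultrasound GA, a
#' platform-overlap clock restricted to 450K probes, and an ETD-trained
#' clock on ART training samples); prediction on the non-ART test set;
#' MM-robust evaluation of each clock; paired-bootstrap comparisons against
#' the main clock; and the GAA association analysis (ART vs non-ART, plus
#' ICSI-vs-IVF and frozen-vs-fresh subgroup contrasts). All randomness
#' derives from `config$seed`, so two runs with the same configuration are
#' identical.
#'
#' @param config a [pipeline_config()] list, or a path to a YAML file of
#'   overrides.
#' @param out_dir optional directory; when given, clock coefficient CSVs,
#'   prediction CSVs and JSON reports (each embedding the seed and a
#'   configuration hash) are written there.
#' @param quiet suppress progress messages.
#' @return A list with elements `clocks`, `predictions`, `evaluations`,
#'   `comparisons`, `gaa`, `filter_report`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  if (is.character(config)) {
    config <- pipeline_config(yaml::read_yaml(config))
  } else if (!identical(names(config), names(pipeline_config()))) {
    config <- pipeline_config(config)
  }
  tf <- config$train$train_fraction
  if (tf <= 0 || tf >= 1) {
    stop("train.train_fraction must lie strictly between 0 and 1",
         call. = FALSE)
  }
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- as.integer(config$seed)
  stamp <- list(seed = seed, config_hash = rlang::hash(config))

  say("simulate: n = %d samples, p = %d probes",
      config$simulation$n_samples, config$simulation$n_probes)
  scfg <- do.call(sim_config, c(config$simulation, list(seed = seed)))
  cohort <- simulate_cohort(scfg)
  ann <- do.call(make_probe_annotation, c(list(cfg = scfg), config$annotation))

  filt <- filter_probes(cohort$beta, ann)
  say("filter: %d -> %d probes", nrow(cohort$beta), nrow(filt$beta))
  beta <- filt$beta

  sheet <- annotate_etd(cohort$samples)
  say("etd: %d ART records annotated", sum(!is.na(sheet$ga_etd_days)))

  non_art <- sheet$sample_id[!sheet$art]
  art <- sheet$sample_id[sheet$art]
  split_na <- split_train_test(non_art, tf, seed = derive_seed(seed, 11L))
  split_art <- split_train_test(art, tf, seed = derive_seed(seed, 12L))
  say("split: non-ART %d/%d, ART %d/%d", length(split_na$train),
      length(split_na$test), length(split_art$train), length(split_art$test))

  tcfg <- train_config(n_folds = config$train$n_folds,
                       lambda_rule = config$train$lambda_rule,
                       train_fraction = tf, seed = derive_seed(seed, 13L))
  bm_train <- subset_beta(beta, samples = split_na$train)
  clock_main <- train_clock(bm_train, sheet, tcfg)
  say("train main clock: %d CpGs at lambda = %.4g",
      length(clock_main$coefficients), clock_main$lambda)

  overlap_ids <- ann$probe_id[ann$on_450k]
  clock_overlap <- train_clock(restrict_to_platform(bm_train, overlap_ids),
                               sheet, tcfg)
  say("train overlap clock: %d CpGs", length(clock_overlap$coefficients))

  bm_art_train <- subset_beta(beta, samples = split_art$train)
  clock_etd <- train_clock(bm_art_train, sheet, tcfg, ga_source = "etd")
  say("train ETD clock: %d CpGs", length(clock_etd$coefficients))

  bm_test <- subset_beta(beta, samples = split_na$test)
  clocks <- list(main = clock_main, overlap = clock_overlap, etd = clock_etd)
  preds <- purrr::map(clocks, ~ predict_ga(bm_test, .x))
  obs_test <- sheet$ga_ultrasound_days[match(split_na$test, sheet$sample_id)]

  evals <- purrr::map(preds, ~ compute_metrics(obs_test, .x))
  for (nm in names(evals)) {
    say("evaluate %s clock: R2 = %.3f, SE = %.2f, MAD = %.2f", nm,
        evals[[nm]]$r2, evals[[nm]]$se, evals[[nm]]$mad_days)
  }

  comparisons <- list(
    overlap_vs_main = bootstrap_compare(
      obs_test, preds$overlap, preds$main, n_boot = config$evaluate$n_boot,
      seed = derive_seed(seed, 14L), ci_level = config$evaluate$ci_level),
    etd_vs_main = bootstrap_compare(
      obs_test, preds$etd, preds$main, n_boot = config$evaluate$n_boot,
      seed = derive_seed(seed, 15L), ci_level = config$evaluate$ci_level)
  )

  # GAA on everything the main clock was not trained on
  gaa_ids <- c(split_na$test, art)
  bm_gaa <- subset_beta(beta, samples = gaa_ids)
  pred_gaa <- predict_ga(bm_gaa, clock_main)
  sheet_gaa <- sheet[match(gaa_ids, sheet$sample_id), ]
  gaa <- compute_gaa(pred_gaa, sheet_gaa$ga_ultrasound_days)
  gaa_art <- test_gaa_association(gaa, sheet_gaa$art)
  say("gaa: ART coefficient %.4f per day, p = %.3g", gaa_art$logit_coef,
      gaa_art$p_value)
  in_art <- sheet_gaa$art
  gaa_tests <- list(
    art_vs_non_art = gaa_art,
    icsi_vs_ivf = test_gaa_association(gaa[in_art],
                                       sheet_gaa$procedure[in_art] == "ICSI"),
    frozen_vs_fresh = test_gaa_association(
      gaa[in_art], sheet_gaa$embryo_state[in_art] == "frozen")
  )

  result <- list(clocks = clocks, predictions = preds, evaluations = evals,
                 comparisons = comparisons, gaa = gaa_tests,
                 filter_report = filt$report, config = config,
                 truth = cohort$truth)
  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir, stamp, say)
  invisible(result)
}

write_pipeline_artifacts <- function(result, out_dir, stamp, say) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(result$clocks)) {
    write_clock_file(result$clocks[[nm]],
                     file.path(out_dir, paste0("clock_", nm, ".csv")))
  }
  for (nm in names(result$predictions)) {
    readr::write_csv(result$predictions[[nm]],
                     file.path(out_dir, paste0("predictions_", nm, ".csv")),
                     progress = FALSE)
  }
  report <- c(stamp, list(
    filter = result$filter_report,
    evaluations = purrr::map(result$evaluations, glance),
    comparisons = purrr::map(result$comparisons, tidy),
    gaa = purrr::map(result$gaa, glance)
  ))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  say("artifacts written to %s", out_dir)
  invisible(out_dir)
}
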