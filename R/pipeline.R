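#' Run the full analysis pipeline on a synthetic study
#'
#' Ties every stage together: simulate (or accept) a study, decode each
#' participant with the nested-LOO ridge decoder, code the behavioral
#' indicators, build the mismatched-pairing null and test the observed
#' accuracy against it, reduce the full factorial mixed model stepwise, and —
#' when both mind-wandering levels are populated — fit the per-level
#' follow-up models. Deterministic under a fixed config seed.
#'
#' @param config A [sim_config()]; its `seed` drives every random draw.
#' @param study Optional pre-generated study (a `list(trials, truth)` as from
#'   [simulate_study()]); when supplied, `config` is only used for decoding
#'   parameters.
#' @param t_min,t_max,lambda_grid Decoder settings (see
#'   [nested_loo_decode()]).
#' @param alpha_random,alpha_fixed Stepwise thresholds.
#' @param n_permutations Mismatched pairings per subject for the null.
#' @param out_dir Optional directory; when given, the per-epoch results CSV,
#'   elimination table CSV, group-summary CSV and a machine-readable summary
#'   JSON are written there, each file naming the config hash and seed.
#' @return A list of class `musetrack_run`: `records` (coded per-epoch
#'   results), `null_comparison`, `stepwise`, `best_model`, `follow_up` (or
#'   NULL), `agreement`, `config`, `config_hash`.
#' @export
run_pipeline <- function(config, study = NULL,
                         t_min = -0.2, t_max = 0.35,
                         lambda_grid = 10^(-6:6),
                         alpha_random = 0.1, alpha_fixed = 0.05,
                         n_permutations = 50, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(study)) study <- simulate_study(config)
  decoded <- decode_study(study$trials, t_min = t_min, t_max = t_max,
                          fs = config$fs, lambda_grid = lambda_grid)
  records <- code_indicators(decoded)
  null_tbl <- null_distribution(records, n_permutations = n_permutations,
                                seed = derive_seed(config$seed, 77L))
  null_cmp <- compare_to_null(null_tbl)
  sw <- stepwise_backward(records, alpha_random = alpha_random,
                          alpha_fixed = alpha_fixed)
  follow <- if (nlevels(droplevels(records$coded_mw_group)) == 2) {
    follow_up_by_level(records)
  }
  agreement <- familiarity_agreement(records, study$truth$designed)
  run <- structure(
    list(records = records %>% select(-dplyr::any_of(c("eeg", "model"))),
         null_table = null_tbl, null_comparison = null_cmp,
         stepwise = sw, best_model = sw$fit, follow_up = follow,
         agreement = agreement, config = config,
         config_hash = config_hash(config)),
    class = "musetrack_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

config_hash <- function(config) {
  substr(rlang::hash(unclass(config)), 1, 8)
}

#' Write a pipeline run to disk
#'
#' Emits the per-epoch results CSV (metadata and accuracies; array columns
#' are dropped), the elimination-table CSV, a Figure-style group-summary CSV
#' of cell means and standard errors, a frozen copy of the configuration and
#' a machine-readable summary JSON. Every file name carries the config hash
#' and seed that produced it.
#'
#' @param run A `musetrack_run` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tag <- sprintf("%s_seed%d", run$config_hash, run$config$seed)
  paths <- c(
    results = file.path(out_dir, paste0("results_", tag, ".csv")),
    elimination = file.path(out_dir, paste0("elimination_", tag, ".csv")),
    cells = file.path(out_dir, paste0("group_summary_", tag, ".csv")),
    config = file.path(out_dir, paste0("config_", tag, ".json")),
    summary = file.path(out_dir, paste0("summary_", tag, ".json"))
  )
  utils::write.csv(flatten_records(run$records), paths["results"],
                   row.names = FALSE)
  utils::write.csv(run$stepwise$elimination, paths["elimination"],
                   row.names = FALSE)
  utils::write.csv(group_summary(run$records), paths["cells"],
                   row.names = FALSE)
  cfg <- unclass(run$config)
  jsonlite::write_json(cfg, paths["config"], auto_unbox = TRUE, digits = NA)
  smry <- list(
    config_hash = run$config_hash, seed = run$config$seed,
    n_subjects = length(unique(run$records$subject_id)),
    n_epochs = nrow(run$records),
    null_comparison = as.list(run$null_comparison),
    reduced_formula = deparse(run$stepwise$reduced_formula),
    best_model = as.list(glance(run$best_model)),
    coefficients = run$best_model$coefficients
  )
  jsonlite::write_json(smry, paths["summary"], auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(paths)
}

flatten_records <- function(records) {
  records %>%
    select(dplyr::where(~ !is.list(.x))) %>%
    as.data.frame()
}

#' Cell means and standard errors of reconstruction accuracy
#'
#' Group summary in the style of a familiarity-by-mind-wandering figure:
#' per-cell mean accuracy and standard error of the mean over subjects'
#' cell means.
#'
#' @param records Coded records with `accuracy`.
#' @return A tibble with one row per (familiarity, mind-wandering) cell.
#' @export
group_summary <- function(records) {
  records %>%
    group_by(.data$subject_id, .data$coded_familiarity,
             .data$coded_mw_group) %>%
    summarise(subject_mean = mean(.data$accuracy), .groups = "drop") %>%
    group_by(.data$coded_familiarity, .data$coded_mw_group) %>%
    summarise(mean_r = mean(.data$subject_mean),
              sem = sd(.data$subject_mean) / sqrt(dplyr::n()),
              n_subjects = dplyr::n(), .groups = "drop")
}

#' Miniature study for fast experimentation and testing
#'
#' Three subjects, two stimuli presented twice, 10-s trials equal to the
#' epoch length (so four epochs per subject), six channels — a seconds-scale
#' study exercising every code path of the full design.
#'
#' @param seed Integer seed.
#' @param snr_map Optional SNR map (defaults to the package default).
#' @return A `list(trials, truth)` as from [simulate_study()].
#' @export
make_fixtures <- function(seed = 1L, snr_map = default_snr_map()) {
  cfg <- sim_config(n_subjects = 3, n_stimuli = 2, n_presentations = 2,
                    trial_duration = 10, epoch_duration = 10,
                    n_channels = 6, fs = 64, snr_map = snr_map, seed = seed)
  simulate_study(cfg)
}

#' Round-trip the per-epoch results table through CSV
#'
#' @param records Coded records (list-columns are dropped on write).
#' @param path CSV path.
#' @return `write_records` returns `path` invisibly; `read_records` returns a
#'   tibble with the coded factors restored.
#' @export
write_records <- function(records, path) {
  utils::write.csv(flatten_records(records), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- as_tibble(df)
  if ("coded_familiarity" %in% names(out)) {
    out$coded_familiarity <- factor(out$coded_familiarity,
                                    levels = c("Low", "High"))
  }
  if ("coded_mw_group" %in% names(out)) {
    out$coded_mw_group <- factor(out$coded_mw_group,
                                 levels = c("Low", "High"))
  }
  if ("coded_repetition" %in% names(out)) {
    out$coded_repetition <- factor(out$coded_repetition,
                                   levels = c("First", "Second"))
  }
  out
}

#' @export
print.musetrack_run <- function(x, ...) {
  cat("musetrack pipeline run  [config", x$config_hash, "seed",
      x$config$seed, "]\n")
  cat(sprintf("  %d subjects, %d epochs\n",
              length(unique(x$records$subject_id)), nrow(x$records)))
  cat("Null comparison:\n"); print(x$null_comparison)
  cat("Reduced model:", deparse(x$stepwise$reduced_formula), "\n")
  invisible(x)
}
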