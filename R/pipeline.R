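#' Run the full analysis pipeline
#'
#' Orchestrates every stage on one dataset: read or simulate trials, exclude
#' below-chance participants, aggregate counts, build the descriptive
#' proportion table and scaled-difference matrix, run the Bayes factor model
#' comparison, and run the legacy 2 x 2 ANOVAs for old items and lures.
#' Exactly one of `input` and `scenario` must be given.
#'
#' @param input A path to a delimited trials file, or an in-memory data frame
#'   of trials.
#' @param scenario A scenario name or [synthetic_config()] object to simulate
#'   from instead of reading data.
#' @param participants,items Size overrides when simulating.
#' @param dialect Column/label mapping for file input; see [rkn_dialect()].
#' @param exclusion_threshold Accuracy threshold for
#'   [exclude_below_chance()].
#' @param models Model registry for [compare_models()].
#' @param prior Prior and sampler settings from [g_prior()].
#' @param seed Integer seed; required. Governs simulation and posterior
#'   sampling, making the whole report reproducible.
#' @param out_dir Optional directory; if given, [write_report()] is called.
#' @return An `rkn_report` list: `n_trials`, `exclusions`, `proportions`,
#'   `scaled_differences`, `bf` (an `rkn_bf`), `anova_old`, `anova_new`,
#'   `config`, and `config_hash`.
#' @export
analyze_experiment <- function(input = NULL, scenario = NULL,
                               participants = NULL, items = NULL,
                               dialect = rkn_dialect(),
                               exclusion_threshold = 0.5,
                               models = rkn_models(), prior = g_prior(),
                               seed, out_dir = NULL) {
  if (missing(seed)) abort("A seed is required.")
  if (is.null(input) == is.null(scenario)) {
    abort("Give exactly one of `input` (data) or `scenario` (simulate).")
  }
  config <- list(
    input = if (is.character(input)) input else if (!is.null(input)) "<data frame>" else NULL,
    scenario = if (is.character(scenario)) scenario
               else if (!is.null(scenario)) scenario$name else NULL,
    participants = participants, items = items,
    exclusion_threshold = exclusion_threshold,
    models = names(models) %||% vapply(models, `[[`, "", "name"),
    prior = unclass(prior), seed = as.integer(seed)
  )
  trials <- if (!is.null(scenario)) {
    generate_experiment(scenario, participants = participants, items = items,
                        seed = seed)
  } else if (is.character(input)) {
    read_trials(input, dialect)
  } else {
    as_trials(input, dialect)
  }
  counts <- aggregate_counts(trials)
  counts <- exclude_below_chance(counts, exclusion_threshold)
  props <- proportion_table(counts)
  sd_long <- scaled_differences(counts)
  Y <- scaled_difference_matrix(counts)
  bf <- compare_models(Y, models, prior, seed = seed)
  report <- structure(
    list(
      n_trials = nrow(trials),
      exclusions = exclusion_report(counts),
      proportions = props,
      scaled_differences = sd_long,
      bf = bf,
      anova_old = rm_anova_2x2(counts, "old"),
      anova_new = rm_anova_2x2(counts, "new"),
      config = config,
      config_hash = rlang::hash(config)
    ),
    class = "rkn_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.rkn_report <- function(x, ...) {
  n_excl <- sum(x$exclusions$excluded)
  cat("Recognition-memory analysis report (config ", x$config_hash, ")\n",
      x$n_trials, " trials; ", n_excl, " participant(s) excluded below chance\n\n",
      sep = "")
  cat("Response proportions and scaled differences:\n")
  print(as.data.frame(x$proportions[, 1:7]), digits = 2, row.names = FALSE)
  cat("\n")
  print(x$bf)
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits machine-readable outputs: TSV tables for the proportion summary,
#' scaled differences, Bayes factor comparison and both ANOVAs; a JSON blob
#' with everything including the configuration and its hash (timestamps are
#' kept out of the JSON so identical runs are byte-identical); and a
#' plain-text run log.
#'
#' @param report An `rkn_report` from [analyze_experiment()].
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, nm) readr::write_tsv(x, file.path(dir, nm), progress = FALSE)
  tsv(report$proportions, "proportions.tsv")
  tsv(report$scaled_differences, "scaled_differences.tsv")
  tsv(tidy(report$bf), "bayes_factors.tsv")
  tsv(tibble::as_tibble(report$anova_old), "anova_old.tsv")
  tsv(tibble::as_tibble(report$anova_new), "anova_new.tsv")
  json <- list(
    config = report$config, config_hash = report$config_hash,
    n_trials = report$n_trials,
    exclusions = report$exclusions,
    proportions = report$proportions,
    bayes_factors = tidy(report$bf),
    winner = report$bf$winner,
    anova_old = tibble::as_tibble(report$anova_old),
    anova_new = tibble::as_tibble(report$anova_new)
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(
    c(
      paste0("run at: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
      paste0("config hash: ", report$config_hash),
      paste0("seed: ", report$config$seed),
      paste0("R version: ", R.version.string),
      paste0("rknbayes version: ",
             as.character(utils::packageVersion("rknbayes"))),
      paste0("winner: ", report$bf$winner)
    ),
    file.path(dir, "run.log")
  )
  invisible(dir)
}
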