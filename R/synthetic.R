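#' Configure a synthetic recognition experiment
#'
#' Defines the generative conditions for trial-level synthetic data: the
#' baseline (remember, know, new) response probabilities per condition, and
#' strong between-participant heterogeneity in remember-vs-know preference.
#' Each participant draws a single preference shift on the log-odds scale,
#' applied to the remember-vs-know split in every condition (the new-response
#' mass is untouched). Sharing one shift across conditions induces the
#' positive cross-condition correlation of individual scaled differences seen
#' in real data, where some participants respond almost exclusively
#' *remember* and others almost exclusively *know*.
#'
#' @param probs A 4-by-3 numeric matrix (or list of 4 length-3 vectors) of
#'   response probabilities, rows in canonical condition order (old word, old
#'   nonword, new word, new nonword), columns (remember, know, new). Rows are
#'   renormalized to sum to one.
#' @param participants Number of participants `I`.
#' @param items_per_condition Items tested per participant in each condition.
#' @param heterogeneity_sd SD of the participant preference shift (log-odds
#'   scale). The default 1.5 puts about 5% of participants beyond 20:1
#'   response odds — near-exclusive use of one option.
#' @param name Optional scenario name.
#' @return An object of class `rkn_scenario`.
#' @export
synthetic_config <- function(probs, participants = 53L,
                             items_per_condition = 30L,
                             heterogeneity_sd = 1.5, name = "custom") {
  if (is.list(probs)) probs <- do.call(rbind, probs)
  probs <- as.matrix(probs)
  if (!all(dim(probs) == c(4, 3)) || any(probs < 0)) {
    abort("`probs` must be a 4 x 3 matrix of non-negative probabilities.")
  }
  if (any(rowSums(probs) == 0)) abort("Each condition needs positive total probability.")
  probs <- probs / rowSums(probs)
  dimnames(probs) <- list(rkn_conditions()$label, c("remember", "know", "new"))
  stopifnot(participants >= 1, items_per_condition >= 1, heterogeneity_sd >= 0)
  structure(
    list(
      name = name, probs = probs,
      participants = as.integer(participants),
      items_per_condition = as.integer(items_per_condition),
      heterogeneity_sd = heterogeneity_sd
    ),
    class = "rkn_scenario"
  )
}

#' @export
print.rkn_scenario <- function(x, ...) {
  cat("<rkn_scenario> ", x$name, ": I = ", x$participants, ", ",
      x$items_per_condition, " items/condition, heterogeneity SD = ",
      x$heterogeneity_sd, "\n", sep = "")
  print(round(x$probs, 3))
  invisible(x)
}

# Offset c such that E[plogis(qlogis(p) + c + b)] = p for b ~ N(0, sd^2):
# without it, averaging the logistic over the preference distribution shrinks
# every remember share towards 1/2 and the condition-level mean proportions
# (and mean scaled differences) would drift from the configured baselines.
calibrate_offset <- function(p, sd) {
  if (sd == 0 || p <= 0 || p >= 1) return(0)
  z <- stats::qnorm((seq_len(201) - 0.5) / 201) * sd
  lo <- stats::qlogis(p)
  stats::uniroot(function(cc) mean(plogis(lo + cc + z)) - p,
                 c(-15, 15), tol = 1e-10)$root
}

# apply a lexicality tilt to the remember-vs-know log odds of a prob matrix
tilt_probs <- function(probs, tilt) {
  cond <- rkn_conditions()
  for (j in 1:4) {
    delta <- tilt[[cond$lexicality[j]]] %||% 0
    mass <- probs[j, 1] + probs[j, 2]
    if (mass > 0 && delta != 0) {
      lo <- stats::qlogis(probs[j, 1] / mass) + delta
      probs[j, 1] <- mass * plogis(lo)
      probs[j, 2] <- mass - probs[j, 1]
    }
  }
  probs
}

#' Named generator scenarios
#'
#' Loads the shipped scenario library: `gardiner_java` (the original crossover
#' pattern), `null_lexicality` (no lexicality effect, the single-process
#' pattern), and `word_bias` / `nonword_bias` (a global lexicality bias in
#' either direction, matching the two ordered models). See the packaged
#' `extdata/scenarios.yaml` for the probability values.
#'
#' @param file Path to a scenario YAML file; defaults to the shipped library.
#' @return A named list of [synthetic_config()] objects.
#' @export
rkn_scenarios <- function(file = system.file("extdata", "scenarios.yaml",
                                             package = "rknbayes")) {
  raw <- yaml::read_yaml(file)
  purrr::imap(raw, function(sc, nm) {
    probs <- do.call(rbind, sc$probs[c("old_word", "old_nonword",
                                       "new_word", "new_nonword")])
    if (!is.null(sc$tilt)) probs <- tilt_probs(probs / rowSums(probs), sc$tilt)
    synthetic_config(
      probs,
      heterogeneity_sd = sc$heterogeneity_sd %||% 1.5,
      name = nm
    )
  })
}

#' Generate a synthetic trial-level dataset
#'
#' Simulates one full experiment under a scenario: each participant receives
#' a preference shift drawn once from \eqn{N(0, sd^2)}, the shift tilts the
#' remember-vs-know log odds in every condition, and item responses are then
#' independent categorical draws. The output has exactly
#' `participants x 4 x items` rows and is reproducible under `seed`.
#'
#' @param config An [rkn_scenario] from [synthetic_config()] or
#'   [rkn_scenarios()], or a scenario name from the shipped library.
#' @param participants,items Optional overrides of the scenario's size.
#' @param seed Integer seed; required.
#' @return A trials tibble (`participant`, `lexicality`, `status`,
#'   `response`) in the canonical format consumed by [aggregate_counts()].
#' @export
generate_experiment <- function(config, participants = NULL, items = NULL,
                                seed) {
  if (missing(seed)) abort("A seed is required to generate data.")
  if (is.character(config)) {
    lib <- rkn_scenarios()
    if (!config %in% names(lib)) {
      abort(paste0("Unknown scenario \"", config, "\". Available: ",
                   paste(names(lib), collapse = ", "), "."))
    }
    config <- lib[[config]]
  }
  stopifnot(inherits(config, "rkn_scenario"))
  I <- as.integer(participants %||% config$participants)
  n_items <- as.integer(items %||% config$items_per_condition)
  stopifnot(I >= 1, n_items >= 1)
  cond <- rkn_conditions()
  offsets <- vapply(1:4, function(j) {
    mass <- sum(config$probs[j, 1:2])
    if (mass == 0) return(0)
    calibrate_offset(config$probs[j, 1] / mass, config$heterogeneity_sd)
  }, numeric(1))
  set.seed(as.integer(seed))
  shift <- rnorm(I, 0, config$heterogeneity_sd)
  rows <- vector("list", I)
  resp_lev <- rkn_response_levels()
  for (i in seq_len(I)) {
    counts <- matrix(0L, 4, 3)
    for (j in 1:4) {
      p <- config$probs[j, ]
      mass <- p[1] + p[2]
      if (mass > 0 && p[1] > 0 && p[2] > 0) {
        lo <- stats::qlogis(p[1] / mass) + offsets[j] + shift[i]
        p[1] <- mass * plogis(lo)
        p[2] <- mass - p[1]
      }
      counts[j, ] <- stats::rmultinom(1, n_items, p)
    }
    rows[[i]] <- tibble::tibble(
      participant = sprintf("p%03d", i),
      condition = rep(1:4, times = rowSums(counts)),
      response = rep(rep(resp_lev, 4), times = as.integer(t(counts)))
    )
  }
  purrr::list_rbind(rows) |>
    dplyr::inner_join(cond, by = "condition") |>
    dplyr::select("participant", "lexicality", "status", "response")
}

#' Model-recovery simulation
#'
#' Repeatedly generates data under each scenario, runs the full model
#' comparison, and tabulates how often each model wins. This is the package's
#' main calibration tool: it shows, at a given sample size, how reliably the
#' comparison identifies the data-generating pattern.
#'
#' @param scenarios A named list of [rkn_scenario] objects (or scenario
#'   names). Default: the null-lexicality and crossover scenarios.
#' @param reps Replicates per scenario and sample size.
#' @param participants Integer vector of sample sizes to simulate.
#' @param items Items per condition.
#' @param models Model registry; default [rkn_models()].
#' @param prior Prior/sampler settings. The default uses a reduced sampler
#'   (2 chains of 5,000 iterations) appropriate for a simulation with
#'   hundreds of fits; single-dataset analyses use the larger [g_prior()]
#'   defaults.
#' @param seed Integer seed; one sub-seed per run is drawn from it.
#' @return An `rkn_recovery` object; `tidy()` returns recovery rates per
#'   scenario, sample size and winning model, and `$runs` holds one row per
#'   simulated dataset.
#' @export
model_recovery <- function(scenarios = rkn_scenarios()[c("null_lexicality",
                                                         "gardiner_java")],
                           reps = 100L, participants = 50L, items = 25L,
                           models = rkn_models(),
                           prior = g_prior(iterations = 5000L, warmup = 500L,
                                           chains = 2L),
                           seed) {
  if (missing(seed)) abort("A seed is required for model recovery.")
  if (reps < 1) abort("`reps` must be at least 1.")
  if (is.character(scenarios)) scenarios <- rkn_scenarios()[scenarios]
  grid <- tidyr::expand_grid(
    scenario = names(scenarios),
    I = as.integer(participants),
    rep = seq_len(reps)
  )
  set.seed(as.integer(seed))
  grid$run_seed <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  runs <- purrr::pmap(grid, function(scenario, I, rep, run_seed) {
    trials <- generate_experiment(scenarios[[scenario]], participants = I,
                                  items = items, seed = run_seed)
    Y <- scaled_difference_matrix(aggregate_counts(trials))
    # per-fit advisories (e.g. a hopeless model's posterior constraint
    # probability hitting 0 on decisive data) are expected in bulk and not
    # actionable per run
    cmp <- suppressWarnings(compare_models(Y, models, prior, seed = run_seed))
    tibble::tibble(
      scenario = scenario, I = I, rep = rep,
      winner = cmp$winner, log_bf_winner = cmp$results$log_bf[1]
    )
  }) |> purrr::list_rbind()
  rates <- runs |>
    dplyr::count(.data$scenario, .data$I, .data$winner, name = "wins") |>
    dplyr::group_by(.data$scenario, .data$I) |>
    dplyr::mutate(rate = .data$wins / sum(.data$wins)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$scenario, .data$I, dplyr::desc(.data$rate))
  structure(
    list(runs = runs, rates = rates, reps = reps, items = items,
         seed = as.integer(seed)),
    class = "rkn_recovery"
  )
}

#' @export
print.rkn_recovery <- function(x, ...) {
  cat("Model recovery (", x$reps, " replicates/scenario, ", x$items,
      " items/condition)\n", sep = "")
  print(as.data.frame(x$rates), digits = 3, row.names = FALSE)
  invisible(x)
}

#' @rdname model_recovery
#' @param x An `rkn_recovery` object.
#' @param ... Unused.
#' @export
tidy.rkn_recovery <- function(x, ...) x$rates
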