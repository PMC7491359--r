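#' Aggregate trials into per-participant condition counts
#'
#' Tabulates remember/know/new response counts for every participant in each
#' of the four conditions (old word, old nonword, new word, new nonword). The
#' total number of responses is conserved: the `r + k + n` cells sum to the
#' number of input trials.
#'
#' @param trials A trials tibble from [as_trials()], [read_trials()] or
#'   [generate_experiment()].
#' @return A tibble with columns `participant`, `condition` (1--4 in the
#'   canonical order), `status`, `lexicality`, `r`, `k`, `n`, and `total`.
#'   Participants lacking trials in some condition trigger a warning and have
#'   no row for that condition.
#' @export
aggregate_counts <- function(trials) {
  if (nrow(trials) == 0) abort("No trials to aggregate.")
  cond <- rkn_conditions()
  counts <- trials |>
    dplyr::count(.data$participant, .data$status, .data$lexicality, .data$response) |>
    tidyr::pivot_wider(
      names_from = "response", values_from = "n",
      values_fill = 0L
    )
  for (resp in rkn_response_levels()) {
    if (is.null(counts[[resp]])) counts[[resp]] <- 0L
  }
  out <- counts |>
    dplyr::inner_join(cond, by = c("status", "lexicality")) |>
    dplyr::transmute(
      .data$participant, .data$condition, .data$status, .data$lexicality,
      r = .data$remember, k = .data$know, n = .data$new,
      total = .data$remember + .data$know + .data$new
    ) |>
    dplyr::arrange(.data$participant, .data$condition)
  incomplete <- out |>
    dplyr::count(.data$participant) |>
    dplyr::filter(.data$n < 4L)
  if (nrow(incomplete) > 0) {
    warn(paste0(
      nrow(incomplete), " participant(s) have no trials in some condition: ",
      paste(head(incomplete$participant, 5), collapse = ", ")
    ))
  }
  out
}

validate_counts <- function(counts) {
  needed <- c("participant", "condition", "status", "lexicality", "r", "k", "n")
  missing_cols <- setdiff(needed, names(counts))
  if (length(missing_cols) > 0) {
    abort(paste0("Count table lacks column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  if (any(counts$r < 0 | counts$k < 0 | counts$n < 0)) {
    abort("Counts must be non-negative.")
  }
  invisible(counts)
}

#' Exclude participants performing below chance
#'
#' Overall accuracy pools all of a participant's trials: *remember* and *know*
#' both count as an "old" answer, so hits are old-item trials answered
#' remember-or-know and correct rejections are new-item trials answered new.
#' Participants whose accuracy is strictly below the threshold are removed
#' (the boundary case, exactly at threshold, is retained).
#'
#' @param counts A count table from [aggregate_counts()].
#' @param threshold Accuracy threshold; default `0.5` (chance for the
#'   old/new decision).
#' @return The retained count table. The full per-participant accuracy table,
#'   with an `excluded` flag and the threshold used, is attached as attribute
#'   `"exclusions"` and can be read with [exclusion_report()].
#' @export
exclude_below_chance <- function(counts, threshold = 0.5) {
  validate_counts(counts)
  acc <- counts |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(
      correct = sum(ifelse(.data$status == "old", .data$r + .data$k, .data$n)),
      trials = sum(.data$r + .data$k + .data$n),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      accuracy = .data$correct / .data$trials,
      excluded = .data$accuracy < threshold
    )
  keep <- acc$participant[!acc$excluded]
  if (length(keep) == 0) {
    abort("All participants fall below the accuracy threshold; nothing to analyse.")
  }
  out <- dplyr::filter(counts, .data$participant %in% keep)
  attr(out, "exclusions") <- structure(
    acc[, c("participant", "accuracy", "excluded")],
    threshold = threshold
  )
  out
}

#' @rdname exclude_below_chance
#' @param x A count table returned by [exclude_below_chance()].
#' @export
exclusion_report <- function(x) {
  rep <- attr(x, "exclusions")
  if (is.null(rep)) abort("No exclusion report attached; run exclude_below_chance() first.")
  rep
}

#' Condition-level response proportions and scaled differences
#'
#' The descriptive summary reported for each experiment: per condition, the
#' mean proportion of remember, know and new responses across participants
#' (the three sum to one before rounding), the mean scaled difference
#' (computed per participant from raw counts, then averaged), and the
#' between-participant standard deviation of each proportion.
#'
#' @inheritParams exclude_below_chance
#' @return A tibble with one row per condition: `condition`, `status`,
#'   `lexicality`, `remember`, `know`, `new`, `scaled_difference`,
#'   `remember_sd`, `know_sd`, `new_sd`.
#' @export
proportion_table <- function(counts) {
  validate_counts(counts)
  if (nrow(counts) == 0) abort("Empty count table.")
  counts |>
    dplyr::mutate(
      p_r = .data$r / (.data$r + .data$k + .data$n),
      p_k = .data$k / (.data$r + .data$k + .data$n),
      p_n = .data$n / (.data$r + .data$k + .data$n),
      y = scaled_difference(.data$r, .data$k, .data$n)
    ) |>
    dplyr::group_by(.data$condition, .data$status, .data$lexicality) |>
    dplyr::summarise(
      remember = mean(.data$p_r),
      know = mean(.data$p_k),
      new = mean(.data$p_n),
      scaled_difference = mean(.data$y),
      remember_sd = sd(.data$p_r),
      know_sd = sd(.data$p_k),
      new_sd = sd(.data$p_n),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$condition)
}
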