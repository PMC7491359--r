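#' Scaled difference between remember and know responses
#'
#' The composite measure analysed throughout the package,
#' \deqn{Y = (r - k) / (r + k + n),}
#' where `r`, `k`, and `n` are the numbers of *remember*, *know* and *new*
#' responses a participant gave in one condition. The value lies in
#' \eqn{[-1, 1]}: negative when *know* responses are preferred, positive when
#' *remember* responses are preferred, zero when they are equally frequent.
#' Because the measure is a single number per participant and condition, it
#' sidesteps the built-in negative correlation between remember and know
#' response rates that compromises treating them as a factor in an ANOVA.
#'
#' The inputs need not be integer counts: response *proportions* scaled by any
#' common total give the same value (the statistic is invariant to multiplying
#' all three arguments by a positive constant).
#'
#' @param r,k,n Non-negative counts (or proportions) of remember, know and new
#'   responses. Vectors are recycled to a common length.
#' @return A numeric vector of scaled differences in \eqn{[-1, 1]}.
#' @examples
#' scaled_difference(0.28, 0.16, 0.56)  # 0.12, a remember preference
#' scaled_difference(0.19, 0.30, 0.51)  # -0.11, a know preference
#' @seealso [scaled_differences()] for the per-participant table.
#' @export
scaled_difference <- function(r, k, n) {
  if (any(r < 0 | k < 0 | n < 0, na.rm = TRUE)) {
    abort("Counts `r`, `k`, `n` must be non-negative.")
  }
  total <- r + k + n
  if (any(total == 0, na.rm = TRUE)) {
    abort("Scaled difference is undefined when r + k + n = 0.")
  }
  (r - k) / total
}

#' Per-participant scaled differences
#'
#' Computes the scaled difference for every participant-by-condition cell of a
#' count table, always from raw counts (never from rounded proportions).
#' Participants missing one of the four conditions cannot enter the
#' condition-means model and are dropped with a warning.
#'
#' @param counts A count table from [aggregate_counts()].
#' @return A tibble with columns `participant`, `condition`, `status`,
#'   `lexicality`, and `y` (the scaled difference), one row per cell, complete
#'   in all four conditions for every retained participant.
#' @export
scaled_differences <- function(counts) {
  validate_counts(counts)
  zero <- counts$r + counts$k + counts$n == 0
  if (any(zero)) {
    bad <- counts[zero, c("participant", "condition")]
    abort(paste0(
      "Scaled difference undefined (no responses) for participant ",
      bad$participant[1], ", condition ", bad$condition[1], "."
    ))
  }
  out <- counts |>
    dplyr::mutate(y = scaled_difference(.data$r, .data$k, .data$n)) |>
    dplyr::select("participant", "condition", "status", "lexicality", "y")
  n_cond <- out |>
    dplyr::count(.data$participant) |>
    dplyr::filter(.data$n < 4L)
  if (nrow(n_cond) > 0) {
    warn(paste0(
      "Dropping ", nrow(n_cond),
      " participant(s) without observations in all 4 conditions: ",
      paste(head(n_cond$participant, 5), collapse = ", ")
    ))
    out <- dplyr::anti_join(out, n_cond, by = "participant")
  }
  out
}

#' Scaled-difference matrix
#'
#' The participants-by-conditions matrix of scaled differences consumed by the
#' model-comparison machinery: one row per participant, four columns in the
#' canonical condition order (old word, old nonword, new word, new nonword).
#'
#' @inheritParams scaled_differences
#' @return A numeric matrix, `I` participants by 4 conditions, with participant
#'   ids as row names.
#' @export
scaled_difference_matrix <- function(counts) {
  long <- scaled_differences(counts)
  wide <- long |>
    dplyr::select("participant", "condition", "y") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "y") |>
    dplyr::arrange(.data$participant)
  m <- as.matrix(wide[, as.character(1:4)])
  rownames(m) <- wide$participant
  colnames(m) <- rkn_conditions()$label
  m
}
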