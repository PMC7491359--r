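#' Classic 2 x 2 repeated-measures ANOVA on response frequencies
#'
#' The legacy analysis applied to this paradigm: a within-subjects ANOVA with
#' factors item type (word vs. nonword) and response type (remember vs. know)
#' on the response frequencies, run separately for old items and for lures.
#' Each participant contributes four cells. Model fitting goes through
#' [stats::aov()] with participant error strata; the table adds the
#' Greenhouse-Geisser-corrected degrees of freedom (both factors have two
#' levels, so every effect has a single numerator df and the correction is
#' the identity, \eqn{\epsilon = 1}) and generalized eta squared
#' \deqn{\hat\eta^2_G = SS_{effect} / (SS_{effect} + SS_{subjects} +
#'   \textstyle\sum SS_{error}),}
#' the recommended effect size for fully within designs.
#'
#' Treating remember and know as a factor is statistically problematic —
#' the two response rates are negatively correlated by construction, which is
#' what the scaled-difference analysis avoids — but the table allows direct
#' comparison with analyses in the older literature.
#'
#' @param counts A count table from [aggregate_counts()].
#' @param status Which items to analyse: `"old"` or `"new"` (lures).
#' @param measure `"frequency"` (raw counts, the classic choice) or
#'   `"proportion"` (counts divided by the items tested in the cell).
#' @return An `rkn_anova` object: a tibble with one row per effect (`item`,
#'   `response`, `item:response`) and columns `F`, `df1`, `df2` (GG-corrected),
#'   `mse`, `p`, `eta_sq_g`, `epsilon`.
#' @export
rm_anova_2x2 <- function(counts, status = c("old", "new"),
                         measure = c("frequency", "proportion")) {
  status <- match.arg(status)
  measure <- match.arg(measure)
  validate_counts(counts)
  cells <- counts |>
    dplyr::filter(.data$status == !!status) |>
    tidyr::pivot_longer(c("r", "k"), names_to = "resp", values_to = "freq") |>
    dplyr::mutate(
      value = if (measure == "proportion") .data$freq / .data$total else .data$freq,
      item = factor(.data$lexicality, levels = c("word", "nonword")),
      resp = factor(.data$resp, levels = c("r", "k"),
                    labels = c("remember", "know")),
      participant = factor(.data$participant)
    )
  if (dplyr::n_distinct(cells$participant) < 2) {
    abort("At least 2 participants are required for the ANOVA.")
  }
  if (nrow(cells) != 4 * dplyr::n_distinct(cells$participant)) {
    abort("Each participant must contribute exactly 4 cells (2 items x 2 responses).")
  }
  fit <- stats::aov(value ~ item * resp + Error(participant / (item * resp)),
                    data = cells)
  strata <- summary(fit)
  # effect rows and residuals from their error strata
  pull_stratum <- function(nm) as.data.frame(strata[[nm]][[1]])
  s_item <- pull_stratum("Error: participant:item")
  s_resp <- pull_stratum("Error: participant:resp")
  s_int <- pull_stratum("Error: participant:item:resp")
  s_subj <- pull_stratum("Error: participant")
  ss_error_all <- sum(
    s_subj[["Sum Sq"]][nrow(s_subj)],
    s_item[["Sum Sq"]][2], s_resp[["Sum Sq"]][2], s_int[["Sum Sq"]][2]
  )
  one_effect <- function(s, label) {
    tibble::tibble(
      effect = label,
      F = s$`F value`[1],
      # both factors are two-level: epsilon is exactly 1, the GG correction
      # leaves the single-df effects untouched
      epsilon = 1,
      df1 = s$Df[1] * 1,
      df2 = s$Df[2] * 1,
      mse = s$`Mean Sq`[2],
      p = s$`Pr(>F)`[1],
      eta_sq_g = s$`Sum Sq`[1] / (s$`Sum Sq`[1] + ss_error_all)
    )
  }
  out <- dplyr::bind_rows(
    one_effect(s_item, "item"),
    one_effect(s_resp, "response"),
    one_effect(s_int, "item:response")
  )
  structure(out, class = c("rkn_anova", class(out)),
            status = status, measure = measure,
            n_participants = dplyr::n_distinct(cells$participant))
}

#' @export
print.rkn_anova <- function(x, ...) {
  cat("2 x 2 repeated-measures ANOVA (", attr(x, "status"), " items, ",
      attr(x, "measure"), ", n = ", attr(x, "n_participants"), ")\n", sep = "")
  NextMethod()
}

#' @rdname rm_anova_2x2
#' @param x An `rkn_anova` object.
#' @param ... Unused.
#' @export
tidy.rkn_anova <- function(x, ...) {
  tibble::tibble(
    term = x$effect, statistic = x$F, df = x$df1, df.residual = x$df2,
    mse = x$mse, p.value = x$p, eta_sq_g = x$eta_sq_g
  )
}

#' @rdname rm_anova_2x2
#' @export
glance.rkn_anova <- function(x, ...) {
  tibble::tibble(
    status = attr(x, "status"), measure = attr(x, "measure"),
    n_participants = attr(x, "n_participants")
  )
}
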