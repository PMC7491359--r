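test_that("results agree with the independent sums-of-squares oracle", {
  for (seed in c(9, 23)) {
    tr <- generate_experiment("gardiner_java", participants = 18, items = 20,
                              seed = seed)
    cts <- aggregate_counts(tr)
    for (st in c("old", "new")) {
      fit <- rm_anova_2x2(cts, st)
      orc <- oracle_anova_2x2(anova_cell_matrix(cts, st))
      orc_rows <- list(orc$item, orc$response, orc$interaction)
      for (i in 1:3) {
        expect_equal(fit$F[i], orc_rows[[i]]$F, tolerance = 1e-8)
        expect_equal(fit$df1[i], orc_rows[[i]]$df1)
        expect_equal(fit$df2[i], orc_rows[[i]]$df2)
        expect_equal(fit$mse[i], orc_rows[[i]]$mse, tolerance = 1e-8)
        expect_equal(fit$p[i], orc_rows[[i]]$p, tolerance = 1e-8)
        expect_equal(fit$eta_sq_g[i], orc_rows[[i]]$eta_sq_g, tolerance = 1e-8)
      }
    }
  }
})

test_that("a pure response-preference signal loads on the response effect only", {
  # every participant: remember exceeds know by 4 in both item types;
  # participant baselines vary
  set.seed(31)
  n <- 12
  base <- sample(3:8, n, replace = TRUE)
  cts <- tidyr::expand_grid(
    participant = sprintf("s%02d", 1:n),
    condition = 1:2
  ) |>
    dplyr::mutate(
      status = "old",
      lexicality = ifelse(condition == 1, "word", "nonword"),
      r = base[match(participant, sprintf("s%02d", 1:n))] + 4L,
      k = base[match(participant, sprintf("s%02d", 1:n))],
      n = 30L - r - k,
      total = 30L
    )
  fit <- rm_anova_2x2(cts, "old")
  expect_gt(fit$F[fit$effect == "response"], 100)
  # item and interaction carry no signal: their sums of squares vanish
  # (F itself is 0/0 in this exactly degenerate design)
  expect_lt(fit$eta_sq_g[fit$effect == "item"], 1e-12)
  expect_lt(fit$eta_sq_g[fit$effect == "item:response"], 1e-12)
  expect_gt(fit$p[fit$effect == "item:response"], 0.1)
})

test_that("permuting participant order changes nothing", {
  tr <- generate_experiment("null_lexicality", participants = 10, items = 15,
                            seed = 55)
  cts <- aggregate_counts(tr)
  perm <- dplyr::arrange(cts, dplyr::desc(participant), condition)
  expect_equal(tibble::as_tibble(rm_anova_2x2(perm, "old")),
               tibble::as_tibble(rm_anova_2x2(cts, "old")))
})

test_that("interaction F ignores participant-specific constants; eta_G ignores relabeling", {
  tr <- generate_experiment("gardiner_java", participants = 10, items = 15,
                            seed = 77)
  cts <- aggregate_counts(tr)
  fit <- rm_anova_2x2(cts, "old", measure = "proportion")
  # add a participant constant to all four cells (proportions scale allows it)
  shifted <- cts |>
    dplyr::group_by(participant) |>
    dplyr::mutate(shift = match(participant[1], unique(cts$participant)) / 10) |>
    dplyr::ungroup()
  cells_fit <- rm_anova_2x2(
    dplyr::mutate(shifted, r = r + shift * total, k = k + shift * total),
    "old", measure = "proportion"
  )
  expect_equal(cells_fit$F[3], fit$F[3], tolerance = 1e-8)
  # swapping the factor labels permutes rows but leaves eta_G values intact
  relab <- dplyr::mutate(cts,
                         lexicality = ifelse(lexicality == "word",
                                             "nonword", "word"))
  fit_rel <- rm_anova_2x2(relab, "old", measure = "proportion")
  expect_equal(sort(fit_rel$eta_sq_g), sort(fit$eta_sq_g), tolerance = 1e-10)
})

test_that("degenerate inputs are rejected", {
  cts <- aggregate_counts(trials_from_counts(matrix(3L, 4, 3)))
  expect_error(rm_anova_2x2(cts, "old"), "At least 2 participants")
})
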