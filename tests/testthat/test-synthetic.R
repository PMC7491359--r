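test_that("the generator emits the exact trial count of the study design", {
  tr <- generate_experiment("gardiner_java", participants = 53, items = 30,
                            seed = 1)
  expect_equal(nrow(tr), 6360)
  expect_equal(dplyr::n_distinct(tr$participant), 53)
  counts <- aggregate_counts(tr)
  expect_true(all(counts$total == 30))
  tiny <- generate_experiment("gardiner_java", participants = 1, items = 1,
                              seed = 1)
  expect_equal(nrow(tiny), 4)
})

test_that("generation is reproducible under a seed and scenario names are checked", {
  a <- generate_experiment("null_lexicality", participants = 5, items = 10,
                           seed = 99)
  b <- generate_experiment("null_lexicality", participants = 5, items = 10,
                           seed = 99)
  expect_identical(a, b)
  expect_error(generate_experiment("no_such_scenario", seed = 1),
               "Unknown scenario.*gardiner_java")
})

test_that("without heterogeneity, uniform probabilities give uniform proportions", {
  cfg <- synthetic_config(matrix(1 / 3, 4, 3), heterogeneity_sd = 0)
  tr <- generate_experiment(cfg, participants = 3, items = 10000, seed = 5)
  pt <- proportion_table(aggregate_counts(tr))
  expect_true(all(abs(pt$remember - 1 / 3) < 0.02))
  expect_true(all(abs(pt$know - 1 / 3) < 0.02))
  expect_true(all(abs(pt$new - 1 / 3) < 0.02))
})

test_that("long-run mean scaled differences converge to the crossover pattern", {
  tr <- generate_experiment("gardiner_java", participants = 1000, items = 30,
                            seed = 12)
  pt <- proportion_table(aggregate_counts(tr))
  expect_true(all(abs(pt$scaled_difference -
                        c(0.12, -0.11, -0.07, -0.09)) < 0.01))
})

test_that("generated data satisfy the count-table invariants by construction", {
  tr <- generate_experiment("word_bias", participants = 20, items = 25,
                            seed = 8)
  cts <- aggregate_counts(tr)
  expect_equal(nrow(cts), 80)
  expect_true(all(cts$r + cts$k + cts$n == cts$total))
  expect_true(all(cts$r >= 0 & cts$k >= 0 & cts$n >= 0))
})

test_that("cross-condition correlation of scaled differences rises with heterogeneity", {
  base <- rkn_scenarios()$null_lexicality
  cors <- vapply(c(0, 0.75, 1.5, 3), function(s) {
    cfg <- synthetic_config(base$probs, heterogeneity_sd = s)
    tr <- generate_experiment(cfg, participants = 150, items = 30, seed = 61)
    Y <- scaled_difference_matrix(aggregate_counts(tr))
    stats::cor(Y[, 1], Y[, 2])
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
  expect_lt(abs(cors[1]), 0.2)   # no shared preference, no correlation
  expect_gt(cors[4], 0.7)
})

test_that("strong heterogeneity spreads old-item scaled differences across both signs", {
  tr <- generate_experiment("null_lexicality", participants = 100, items = 30,
                            seed = 44)
  Y <- scaled_difference_matrix(aggregate_counts(tr))
  expect_gt(mean(Y[, 1] > 0), 0.2)
  expect_gt(mean(Y[, 1] < 0), 0.2)
  expect_gt(max(Y[, 1]), 0.4)
  expect_lt(min(Y[, 1]), -0.4)
})

test_that("model recovery tabulates winners deterministically", {
  sc <- rkn_scenarios()["null_lexicality"]
  rec <- model_recovery(sc, reps = 2, participants = 20, items = 15,
                        prior = quick_prior(1500, 300, 1), seed = 3)
  expect_equal(nrow(rec$runs), 2)
  expect_true(all(rec$runs$winner %in% names(rkn_models())))
  expect_equal(sum(tidy(rec)$rate), 1)
  rec2 <- model_recovery(sc, reps = 2, participants = 20, items = 15,
                         prior = quick_prior(1500, 300, 1), seed = 3)
  expect_identical(rec$runs, rec2$runs)
  expect_error(model_recovery(sc, reps = 0, seed = 1), "at least 1")
})
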