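test_that("prior constraint probabilities are exact for disjoint pairs", {
  expect_equal(as.numeric(prior_constraint_probability(list(c(1L, 2L)))), 0.5)
  expect_equal(attr(prior_constraint_probability(list(c(1L, 2L))), "mc_error"), 0)
  expect_equal(
    as.numeric(prior_constraint_probability(list(c(1L, 2L), c(3L, 4L)))), 0.25
  )
  # an equality on an unrelated pair leaves a single inequality at 1/2
  expect_equal(
    as.numeric(prior_constraint_probability(list(c(1L, 2L)),
                                            equalities = list(c(3L, 4L)))), 0.5
  )
  expect_equal(as.numeric(prior_constraint_probability(list())), 1)
})

test_that("overlapping constraints fall back to Monte Carlo near the exact value", {
  set.seed(10)
  # mu1 > mu2 > mu3: probability 1/6 among exchangeable effects
  p <- prior_constraint_probability(list(c(1L, 2L), c(2L, 3L)))
  expect_gt(attr(p, "mc_error"), 0)
  expect_lt(abs(as.numeric(p) - 1 / 6), 5 * attr(p, "mc_error"))
})

test_that("contradictory constraints are rejected", {
  expect_error(prior_constraint_probability(list(c(1L, 2L), c(2L, 1L))),
               "Contradictory")
  expect_error(
    prior_constraint_probability(list(c(1L, 2L)), equalities = list(c(1L, 2L))),
    "contradictory"
  )
  expect_error(rkn_model("bad", equalities = list(c(1L, 2L)),
                         inequalities = list(c(2L, 1L))),
               "both equal and ordered")
})

test_that("the registry encodes the five standard models", {
  reg <- rkn_models()
  expect_named(reg, c("M_u", "M_*", "M_1", "M_2", "M_3"))
  expect_length(reg$M_u$equalities, 0)
  expect_length(reg$M_u$inequalities, 0)
  expect_equal(reg[["M_*"]]$equalities, list(c(3L, 4L)))
  expect_equal(reg[["M_*"]]$inequalities, list(c(1L, 2L)))
  expect_equal(reg$M_1$equalities, list(c(1L, 2L), c(3L, 4L)))
  expect_equal(reg$M_2$inequalities, list(c(1L, 2L), c(3L, 4L)))
  expect_equal(reg$M_3$inequalities, list(c(2L, 1L), c(4L, 3L)))
})

test_that("inequality Bayes factors never exceed the encompassing bound", {
  set.seed(11)
  reg <- rkn_models()
  for (rep in 1:5) {
    Y <- matrix(rnorm(60, rep(rnorm(4, 0, 0.2), each = 15), 0.3), 15, 4)
    for (m in c("M_2", "M_3")) {
      # a posterior constraint probability of exactly 0 still satisfies the
      # bound (BF 0); silence its advisory warning
      res <- suppressWarnings(
        bf_constrained(Y, reg[[m]], quick_prior(3000, 500), seed = rep)
      )
      expect_lte(res$bf, 1 / res$prior_prob + 1e-9)
    }
  }
})

test_that("a model against itself and pure-equality results are exact", {
  set.seed(12)
  Y <- matrix(rnorm(80, 0, 0.3), 20, 4)
  res <- bf_constrained(Y, rkn_models()$M_1, quick_prior(), seed = 1)
  # quadrature only: rerunning reproduces the value exactly, no MC error
  res2 <- bf_constrained(Y, rkn_models()$M_1, quick_prior(), seed = 99)
  expect_identical(res$log_bf, res2$log_bf)
  expect_equal(res$mc_error, 0)
  # any model relative to itself has BF 1 (log-BF difference 0)
  expect_equal(res$log_bf - res2$log_bf, 0)
})

test_that("pairwise Bayes factors are transitive within Monte-Carlo error", {
  set.seed(13)
  Y <- matrix(rnorm(120, rep(c(0.02, 0, 0.01, -0.01), each = 30), 0.3), 30, 4)
  reg <- rkn_models()
  r2 <- bf_constrained(Y, reg$M_2, quick_prior(20000, 2000), seed = 21)
  r3 <- bf_constrained(Y, reg$M_3, quick_prior(20000, 2000), seed = 22)
  # direct route: ratio of posterior odds under the shared M_u posterior
  smp <- sample_posterior(Y, prior = quick_prior(20000, 2000), seed = 23)
  i2 <- smp$mu_1 > smp$mu_2 & smp$mu_3 > smp$mu_4
  i3 <- smp$mu_2 > smp$mu_1 & smp$mu_4 > smp$mu_3
  direct <- log(mean(i2)) - log(mean(i3))
  chained <- r2$log_bf - r3$log_bf
  # autocorrelation-aware (batch-means) error for the direct route as well
  se2 <- rknbayes:::batch_se(i2, 2) / mean(i2)
  se3 <- rknbayes:::batch_se(i3, 2) / mean(i3)
  mc <- 2 * sqrt(r2$mc_error^2 + r3$mc_error^2 + se2^2 + se3^2)
  expect_lt(abs(chained - direct), mc)
})

test_that("compare_models ranks, reports winner ratios, and is reproducible", {
  set.seed(14)
  Y <- matrix(rnorm(120, rep(c(0.15, -0.1, 0, 0), each = 30), 0.3), 30, 4)
  # M_3 points against a strong signal here: its posterior constraint
  # probability is legitimately 0 and its advisory warning expected
  cmp <- suppressWarnings(compare_models(Y, prior = quick_prior(), seed = 5))
  res <- tidy(cmp)
  expect_equal(nrow(res), 5)
  expect_true(!is.unsorted(rev(res$log_bf)))
  expect_equal(res$bf_winner_vs_model[1], 1)
  expect_true(all(res$bf_winner_vs_model >= 1))
  expect_equal(res$log_bf[res$model == "M_u"], 0)
  cmp2 <- suppressWarnings(compare_models(Y, prior = quick_prior(), seed = 5))
  expect_identical(tidy(cmp), tidy(cmp2))
  expect_equal(glance(cmp)$winner, cmp$winner)
})

test_that("a single-model registry yields a table of one", {
  set.seed(15)
  Y <- matrix(rnorm(40, 0, 0.3), 10, 4)
  cmp <- compare_models(Y, models = rkn_models()["M_1"],
                        prior = quick_prior(1000, 100), seed = 1)
  expect_equal(nrow(tidy(cmp)), 1)
  expect_equal(tidy(cmp)$bf_winner_vs_model, 1)
})
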