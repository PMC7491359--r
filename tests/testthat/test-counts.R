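test_that("aggregation conserves trials and counts cells additively", {
  cmat <- matrix(c(1L, 0L, 0L,
                   0L, 0L, 1L,
                   0L, 1L, 0L,
                   1L, 1L, 1L), 4, 3, byrow = TRUE)
  tr <- trials_from_counts(cmat, participants = 3)
  cts <- aggregate_counts(tr)
  expect_equal(sum(cts$r + cts$k + cts$n), nrow(tr))
  cell <- dplyr::filter(cts, participant == "s01", condition == 1)
  expect_equal(c(cell$r, cell$k, cell$n), c(1, 0, 0))
  # additivity: duplicating every trial doubles every cell
  cts2 <- aggregate_counts(dplyr::bind_rows(tr, tr))
  expect_equal(cts2$r, 2 * cts$r)
  expect_equal(cts2$n, 2 * cts$n)
})

test_that("aggregation warns when a participant misses a condition", {
  tr <- trials_from_counts(matrix(2L, 4, 3), participants = 2)
  tr_missing <- dplyr::filter(tr, !(participant == "s02" & status == "new" &
                                      lexicality == "nonword"))
  expect_warning(aggregate_counts(tr_missing), "no trials in some condition")
})

test_that("below-chance exclusion is strict at the boundary and removes whole participants", {
  # accuracy = (old answered old + new answered new) / total
  perfect <- matrix(c(10L, 0L, 0L, 0L, 10L, 0L, 0L, 0L, 10L, 0L, 0L, 10L),
                    4, 3, byrow = TRUE)              # accuracy 1
  at_chance <- matrix(c(5L, 0L, 5L, 0L, 5L, 5L, 5L, 0L, 5L, 0L, 5L, 5L),
                      4, 3, byrow = TRUE)            # accuracy exactly 0.5
  below <- matrix(c(0L, 0L, 10L, 0L, 0L, 10L, 10L, 0L, 0L, 9L, 0L, 1L),
                  4, 3, byrow = TRUE)                # accuracy 1/40 < 0.5
  tr <- dplyr::bind_rows(
    dplyr::mutate(trials_from_counts(perfect), participant = "good"),
    dplyr::mutate(trials_from_counts(at_chance), participant = "boundary"),
    dplyr::mutate(trials_from_counts(below), participant = "bad")
  )
  cts <- aggregate_counts(tr)
  kept <- exclude_below_chance(cts)
  rep <- exclusion_report(kept)
  expect_setequal(unique(kept$participant), c("good", "boundary"))
  expect_equal(rep$accuracy[rep$participant == "boundary"], 0.5)
  expect_false(rep$excluded[rep$participant == "boundary"])
  expect_true(rep$excluded[rep$participant == "bad"])
  expect_equal(attr(rep, "threshold"), 0.5)
  # whole participants only: the kept table still has 4 conditions each
  expect_equal(nrow(kept), 8)
})

test_that("exclusion keeps everyone when all are accurate, errors when none are", {
  perfect <- matrix(c(10L, 0L, 0L, 0L, 10L, 0L, 0L, 0L, 10L, 0L, 0L, 10L),
                    4, 3, byrow = TRUE)
  cts <- aggregate_counts(trials_from_counts(perfect, participants = 3))
  kept <- exclude_below_chance(cts)
  expect_false(any(exclusion_report(kept)$excluded))
  wrong <- matrix(c(0L, 0L, 10L, 0L, 0L, 10L, 10L, 0L, 0L, 0L, 10L, 0L),
                  4, 3, byrow = TRUE)
  cts_bad <- aggregate_counts(trials_from_counts(wrong))
  expect_error(exclude_below_chance(cts_bad), "below the accuracy threshold")
})

test_that("proportion rows sum to one exactly and match homogeneous input", {
  cmat <- matrix(c(7L, 3L, 10L), 4, 3, byrow = TRUE)
  cts <- aggregate_counts(trials_from_counts(cmat, participants = 6))
  pt <- proportion_table(cts)
  expect_equal(pt$remember + pt$know + pt$new, rep(1, 4))
  expect_equal(pt$remember, rep(0.35, 4))
  expect_equal(pt$know, rep(0.15, 4))
  expect_equal(pt$new, rep(0.50, 4))
  expect_equal(pt$scaled_difference, rep(0.2, 4))
  expect_equal(pt$know_sd, rep(0, 4))
})

test_that("proportion SDs measure between-participant spread", {
  # two participants with opposite remember/know preferences
  a <- matrix(c(9L, 1L, 10L), 4, 3, byrow = TRUE)
  b <- matrix(c(1L, 9L, 10L), 4, 3, byrow = TRUE)
  tr <- dplyr::bind_rows(
    dplyr::mutate(trials_from_counts(a), participant = "pro_remember"),
    dplyr::mutate(trials_from_counts(b), participant = "pro_know")
  )
  pt <- proportion_table(aggregate_counts(tr))
  expect_equal(pt$remember, rep(0.25, 4))
  expect_equal(pt$know_sd, rep(sd(c(0.05, 0.45)), 4))
})
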