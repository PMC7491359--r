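#' Posterior samples under an equality structure
#'
#' Draws from the posterior of the one-way g-prior model with the condition
#' means collapsed according to `equalities`, via a Gibbs cycle over the fully
#' conjugate conditionals (means given variance and g; error variance; g).
#' The draws drive the encompassing step of [bf_constrained()]: the posterior
#' probability of a set of order constraints is the fraction of draws
#' satisfying them.
#'
#' With `fixed_g` set, g is frozen at that value (a degenerate prior), in
#' which case tail probabilities of mean contrasts have a closed scaled-t
#' form — useful for validation.
#'
#' @inheritParams marginal_loglik
#' @param seed Integer seed; required, so every pipeline run is reproducible.
#' @param fixed_g Optional positive value freezing g.
#' @return An object of class `rkn_posterior`: a tibble of draws with columns
#'   `chain`, `iteration`, `mu_1`..`mu_4` (condition means; collapsed
#'   conditions share a column value), `sigma2`, `g`, carrying the grouping,
#'   prior settings, seed and split-\eqn{\hat R} diagnostics as attributes.
#' @export
sample_posterior <- function(Y, equalities = list(), prior = g_prior(),
                             seed, fixed_g = NULL) {
  if (missing(seed)) abort("A seed is required for posterior sampling.")
  st <- group_stats(Y, equalities)
  keep <- prior$iterations - prior$warmup
  set.seed(as.integer(seed))
  if (st$G == 1) {
    # intercept-only model: draw directly from the exact conjugate posterior
    ybar <- st$ytot / st$N
    S0 <- st$yty - st$ytot^2 / st$N
    draws_l <- lapply(seq_len(prior$chains), function(ch) {
      sigma2 <- 0.5 * S0 / stats::rgamma(keep, 0.5 * (st$N - 1))
      mu <- rnorm(keep, ybar, sqrt(sigma2 / st$N))
      cbind(mu, sigma2, g = NA_real_)
    })
  } else {
    Q <- sum_to_zero_basis(st$G)
    grp_obs <- rep(st$grp, each = nrow(Y)) - 1L  # 0-based, column-major of Y
    draws_l <- lapply(seq_len(prior$chains), function(ch) {
      gibbs_gprior(
        as.numeric(Y), as.integer(grp_obs), st$G, Q, prior$scale,
        prior$iterations, prior$warmup, ifelse(is.null(fixed_g), -1, fixed_g)
      )
    })
  }
  # expand group means to the four condition columns
  to_tbl <- function(m, ch) {
    G <- st$G
    mu <- m[, st$grp, drop = FALSE]
    colnames(mu) <- paste0("mu_", 1:4)
    tibble::as_tibble(mu) |>
      dplyr::mutate(
        sigma2 = m[, G + 1], g = m[, G + 2],
        chain = ch, iteration = seq_len(nrow(m)), .before = 1
      )
  }
  draws <- purrr::list_rbind(purrr::imap(draws_l, \(m, ch) to_tbl(m, ch)))
  rhat <- vapply(
    c(paste0("mu_", unique(st$grp)), "sigma2"),
    function(v) split_rhat(matrix(draws[[v]], nrow = keep)),
    numeric(1)
  )
  if (any(rhat > 1.01, na.rm = TRUE)) {
    warn(paste0(
      "Possible non-convergence: split-Rhat up to ",
      format(max(rhat, na.rm = TRUE), digits = 4),
      "; consider more iterations."
    ))
  }
  structure(
    draws,
    class = c("rkn_posterior", class(draws)),
    grp = st$grp, equalities = equalities, prior = prior,
    seed = as.integer(seed), fixed_g = fixed_g, rhat = rhat
  )
}

# split-half Rhat; x is an iterations x chains matrix
split_rhat <- function(x) {
  n <- nrow(x)
  half <- floor(n / 2)
  if (half < 2) return(NA_real_)
  seqs <- cbind(x[seq_len(half), , drop = FALSE],
                x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(seqs)
  means <- colMeans(seqs)
  vars <- apply(seqs, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' @export
print.rkn_posterior <- function(x, ...) {
  cat("<rkn_posterior> ", nrow(x), " draws (",
      attr(x, "prior")$chains, " chains), max split-Rhat ",
      format(max(attr(x, "rhat"), na.rm = TRUE), digits = 4), "\n", sep = "")
  NextMethod()
}

#' @rdname sample_posterior
#' @param x An `rkn_posterior` object.
#' @param ... Unused.
#' @export
tidy.rkn_posterior <- function(x, ...) {
  pars <- c(paste0("mu_", 1:4), "sigma2", "g")
  purrr::map(pars, function(v) {
    tibble::tibble(
      term = v,
      estimate = mean(x[[v]]),
      std.error = sd(x[[v]]),
      conf.low = unname(stats::quantile(x[[v]], 0.025, na.rm = TRUE)),
      conf.high = unname(stats::quantile(x[[v]], 0.975, na.rm = TRUE))
    )
  }) |> purrr::list_rbind()
}

#' @rdname sample_posterior
#' @export
glance.rkn_posterior <- function(x, ...) {
  tibble::tibble(
    draws = nrow(x),
    chains = attr(x, "prior")$chains,
    max_rhat = max(attr(x, "rhat"), na.rm = TRUE),
    seed = attr(x, "seed")
  )
}
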