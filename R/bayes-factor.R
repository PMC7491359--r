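# Monte-Carlo standard error of a posterior probability via batch means:
# robust to the autocorrelation of Gibbs draws.
batch_se <- function(ind, chains, n_batches = 50L) {
  per_chain <- split(ind, rep(seq_len(chains), each = length(ind) / chains))
  bm <- unlist(lapply(per_chain, function(x) {
    nb <- min(n_batches, floor(length(x) / 10))
    if (nb < 2) return(mean(x))
    size <- floor(length(x) / nb)
    vapply(seq_len(nb), function(b) mean(x[((b - 1) * size + 1):(b * size)]),
           numeric(1))
  }))
  sd(bm) / sqrt(length(bm))
}

constraint_indicator <- function(draws, inequalities) {
  ok <- rep(TRUE, nrow(draws))
  for (p in inequalities) {
    ok <- ok & (draws[[paste0("mu_", p[1])]] > draws[[paste0("mu_", p[2])]])
  }
  ok
}

#' Bayes factor of a constrained model against the unconstrained model
#'
#' Combines the two ingredients of the package's model comparison. The
#' equality part of the model is handled analytically by quadrature marginal
#' likelihoods ([bf_equality()]). The inequality part is handled by the
#' encompassing approach: the Bayes factor of the order-constrained model
#' against its equality-restricted encompassing model is the ratio of the
#' posterior to the prior probability that the constraints hold, estimated
#' from Gibbs draws and computed analytically, respectively. On the log
#' scale,
#' \deqn{\log BF = \log BF_{eq} + \log \Pr(\text{order} \mid data, eq)
#'   - \log \Pr(\text{order} \mid prior).}
#'
#' Because posterior probabilities cannot exceed one, the Bayes factor of a
#' pure-inequality model can never exceed the reciprocal of its prior
#' constraint probability (2 for one inequality, 4 for two); this bound is
#' asserted on every run.
#'
#' @inheritParams marginal_loglik
#' @param model An [rkn_model()].
#' @param seed Integer seed for the posterior sampling step.
#' @param samples Optional pre-computed [sample_posterior()] draws under the
#'   model's equality structure (reused by [compare_models()]).
#' @return A one-row tibble: `model`, `log_bf` (vs `M_u`), `bf`, `post_prob`,
#'   `prior_prob`, `mc_error` (Monte-Carlo standard error of `log_bf`; 0 for
#'   pure-equality models, which are quadrature-only).
#' @export
bf_constrained <- function(Y, model, prior = g_prior(), seed, samples = NULL) {
  log_bf_eq <- if (length(model$equalities) > 0) {
    marginal_loglik(Y, model$equalities, prior) - marginal_loglik(Y, list(), prior)
  } else 0
  if (length(model$inequalities) == 0) {
    return(tibble::tibble(
      model = model$name, log_bf = log_bf_eq, bf = exp(log_bf_eq),
      post_prob = 1, prior_prob = 1, mc_error = 0
    ))
  }
  p_prior <- prior_constraint_probability(model$inequalities, model$equalities)
  if (is.null(samples)) {
    samples <- sample_posterior(Y, model$equalities, prior, seed = seed)
  }
  ind <- constraint_indicator(samples, model$inequalities)
  p_post <- mean(ind)
  if (p_post == 0) {
    warn(paste0("Posterior constraint probability for ", model$name,
                " estimated as 0; log BF is -Inf. Increase iterations."))
    return(tibble::tibble(
      model = model$name, log_bf = -Inf, bf = 0,
      post_prob = 0, prior_prob = as.numeric(p_prior), mc_error = NA_real_
    ))
  }
  se_post <- batch_se(ind, attr(samples, "prior")$chains)
  mc_error <- sqrt((se_post / p_post)^2 +
                     (attr(p_prior, "mc_error") / as.numeric(p_prior))^2)
  log_bf <- log_bf_eq + log(p_post) - log(as.numeric(p_prior))
  stopifnot(exp(log_bf) <= exp(log_bf_eq) / as.numeric(p_prior) * (1 + 1e-12))
  tibble::tibble(
    model = model$name, log_bf = log_bf, bf = exp(log_bf),
    post_prob = p_post, prior_prob = as.numeric(p_prior), mc_error = mc_error
  )
}

#' Competitive comparison of constrained models
#'
#' Runs [bf_constrained()] for every model in the registry against the
#' unconstrained model and ranks them. Posterior draws are shared between
#' models with the same equality structure (e.g. `M_2` and `M_3` both use the
#' unconstrained posterior). Pairwise Bayes factors against the winner are
#' formed by subtracting log Bayes factors, reported in the winner's
#' "X-to-1" orientation.
#'
#' @inheritParams bf_constrained
#' @param models A named list of [rkn_model()] objects; default [rkn_models()].
#' @return An object of class `rkn_bf` whose `tidy()` method returns the
#'   ranked table with columns `model`, `log_bf`, `bf`, `bf_winner_vs_model`
#'   (the winner's Bayes factor against each model), `post_prob`,
#'   `prior_prob`, `mc_error`.
#' @export
compare_models <- function(Y, models = rkn_models(), prior = g_prior(), seed) {
  if (length(models) < 1) abort("At least one model is required.")
  if (missing(seed)) abort("A seed is required for model comparison.")
  cache <- new.env(parent = emptyenv())
  cache$n_sampled <- 0L
  get_samples <- function(equalities) {
    key <- paste0("s", paste(equality_groups(equalities), collapse = ""))
    if (is.null(cache[[key]])) {
      # distinct, deterministic seed per equality structure
      cache$n_sampled <- cache$n_sampled + 1L
      cache[[key]] <- sample_posterior(Y, equalities, prior,
                                       seed = as.integer(seed) + cache$n_sampled)
    }
    cache[[key]]
  }
  rows <- purrr::map(unname(models), function(m) {
    if (length(m$inequalities) == 0) {
      bf_constrained(Y, m, prior, seed = seed)
    } else {
      bf_constrained(Y, m, prior, seed = seed, samples = get_samples(m$equalities))
    }
  })
  res <- purrr::list_rbind(rows) |>
    dplyr::arrange(dplyr::desc(.data$log_bf)) |>
    dplyr::mutate(bf_winner_vs_model = exp(.data$log_bf[1] - .data$log_bf))
  structure(
    list(results = res, winner = res$model[1], prior = prior,
         seed = as.integer(seed), n = nrow(Y)),
    class = "rkn_bf"
  )
}

#' @export
print.rkn_bf <- function(x, ...) {
  cat("Bayes factor model comparison (", x$n, " participants)\n", sep = "")
  cat("Winner: ", x$winner, "\n\n", sep = "")
  print(as.data.frame(x$results), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @rdname compare_models
#' @param x An `rkn_bf` object.
#' @param ... Unused.
#' @export
tidy.rkn_bf <- function(x, ...) x$results

#' @rdname compare_models
#' @export
glance.rkn_bf <- function(x, ...) {
  second <- if (nrow(x$results) > 1) x$results$bf_winner_vs_model[2] else NA_real_
  tibble::tibble(
    winner = x$winner,
    log_bf_winner = x$results$log_bf[1],
    bf_vs_runner_up = second,
    n_models = nrow(x$results),
    n_participants = x$n,
    seed = x$seed
  )
}
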