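# Marginal likelihood of the one-way g-prior model for a given equality
# structure on the condition means.
#
# Model, with conditions collapsed into G groups:
#   y_n = mu0 + theta_{group(n)} + e_n,  e_n ~ N(0, sigma^2)
#   theta = Q alpha, Q an orthonormal basis of the sum-to-zero space (p = G-1)
#   alpha | g, sigma^2 ~ N(0, g sigma^2 I_p),  pi(mu0) flat,  pi(sigma^2) ~ 1/sigma^2
#   g ~ InvGamma(1/2, r^2/2)   (the mixture representation of a Cauchy(r)
#                               prior on standardized effects)
# mu0, alpha and sigma^2 integrate analytically; g is handled by trapezoid
# quadrature on the log scale. With G = 1 there is no effect term and the
# marginal is fully closed-form.

sum_to_zero_basis <- function(G) {
  # orthonormal columns spanning {x : sum(x) = 0}; any such basis gives the
  # same marginal because the effect prior is isotropic
  C <- diag(G) - 1 / G
  e <- eigen(C, symmetric = TRUE)
  e$vectors[, e$values > 0.5, drop = FALSE]
}

# sufficient statistics of y under a grouping of the 4 conditions
group_stats <- function(Y, equalities) {
  if (!is.matrix(Y) || ncol(Y) != 4) abort("Y must be an I x 4 matrix.")
  if (any(!is.finite(Y))) abort("Y contains non-finite values.")
  grp <- equality_groups(equalities)
  G <- max(grp)
  n_g <- as.numeric(nrow(Y) * tabulate(grp, G))
  s_g <- as.numeric(tapply(colSums(Y), grp, sum))
  if (any(n_g < 2)) abort("Fewer than 2 observations in some condition group.")
  list(
    grp = grp, G = G, n = n_g, s = s_g,
    N = length(Y), yty = sum(Y^2), ytot = sum(Y)
  )
}

# log p(y | g) after integrating mu0 (flat), alpha (Gaussian), sigma^2 (Jeffreys)
loglik_given_g <- function(g, st, Q) {
  p <- ncol(Q)
  XtX <- crossprod(Q, st$n * Q)         # Q' diag(n) Q
  tvec <- drop(crossprod(Q, st$s))      # X*'y
  uvec <- drop(crossprod(Q, st$n))      # X*'1
  A <- XtX + diag(1 / g, p)
  Ai <- solve(A)
  ySy <- st$yty - drop(crossprod(tvec, Ai %*% tvec))
  oSo <- st$N - drop(crossprod(uvec, Ai %*% uvec))
  oSy <- st$ytot - drop(crossprod(uvec, Ai %*% tvec))
  S <- ySy - oSy^2 / oSo
  logdet <- determinant(diag(p) + g * XtX, logarithm = TRUE)$modulus
  lgamma((st$N - 1) / 2) - ((st$N - 1) / 2) * log(pi * S) -
    0.5 * as.numeric(logdet) - 0.5 * log(oSo)
}

log_prior_g <- function(g, scale) {
  0.5 * log(scale^2 / 2) - lgamma(0.5) - 1.5 * log(g) - scale^2 / (2 * g)
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Log marginal likelihood of an equality structure
#'
#' Integrates the one-way normal model over the grand mean (flat prior), the
#' sum-to-zero condition effects (g-prior), the error variance (Jeffreys
#' prior) and g itself (the default heavy-tailed prior set by [g_prior()]),
#' for the condition-mean equality structure given. The g integral uses
#' trapezoid quadrature on \eqn{\log g} over a wide grid centred on the prior
#' scale; everything else is analytic, so the result is deterministic.
#'
#' @param Y A participants-by-4 scaled-difference matrix from
#'   [scaled_difference_matrix()].
#' @param equalities A list of condition pairs constrained equal (see
#'   [rkn_model()]); `list()` gives the unconstrained model.
#' @param prior Settings from [g_prior()].
#' @return The log marginal likelihood (a scalar).
#' @export
marginal_loglik <- function(Y, equalities = list(), prior = g_prior()) {
  st <- group_stats(Y, equalities)
  if (st$G == 1) {
    # intercept-only model: no effects, no g
    S0 <- st$yty - st$ytot^2 / st$N
    return(lgamma((st$N - 1) / 2) - ((st$N - 1) / 2) * log(pi * S0) -
             0.5 * log(st$N))
  }
  Q <- sum_to_zero_basis(st$G)
  u <- log(prior$scale^2) + seq(log(1e-6), log(1e6), length.out = prior$nodes)
  du <- u[2] - u[1]
  logf <- vapply(u, function(ui) {
    g <- exp(ui)
    loglik_given_g(g, st, Q) + log_prior_g(g, prior$scale) + ui
  }, numeric(1))
  w <- rep(du, length(u))
  w[c(1, length(u))] <- du / 2
  logsumexp(logf + log(w))
}

#' Bayes factor of an equality structure against the unconstrained model
#'
#' Compares a model containing only equality constraints (e.g. the
#' single-process model `M_1`) to the unconstrained model `M_u` by the ratio
#' of quadrature marginal likelihoods. Deterministic: no Monte Carlo error.
#'
#' @inheritParams marginal_loglik
#' @param model An [rkn_model()]; only its equality part is used (its
#'   inequality part, if any, is handled by [bf_constrained()]).
#' @return A one-row tibble with columns `model`, `log_bf` (vs `M_u`), `bf`,
#'   `post_prob`, `prior_prob` (both 1 here) and `mc_error` (0).
#' @export
bf_equality <- function(Y, model, prior = g_prior()) {
  log_bf <- marginal_loglik(Y, model$equalities, prior) -
    marginal_loglik(Y, list(), prior)
  tibble::tibble(
    model = model$name, log_bf = log_bf, bf = exp(log_bf),
    post_prob = 1, prior_prob = 1, mc_error = 0
  )
}
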