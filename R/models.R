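#' Define an equality/order-constrained model of the condition means
#'
#' A model constrains the four condition means \eqn{\mu_1, \ldots, \mu_4} of
#' the scaled differences (conditions in the canonical order old word, old
#' nonword, new word, new nonword) by equalities \eqn{\mu_j = \mu_{j'}} and/or
#' inequalities \eqn{\mu_j > \mu_{j'}}.
#'
#' @param name Model name used in output tables.
#' @param equalities A list of length-2 integer vectors `c(j, jp)`, each
#'   imposing \eqn{\mu_j = \mu_{j'}}.
#' @param inequalities A list of length-2 integer vectors `c(j, jp)`, each
#'   imposing \eqn{\mu_j > \mu_{j'}}.
#' @return An object of class `rkn_model`.
#' @seealso [rkn_models()] for the standard registry.
#' @export
rkn_model <- function(name, equalities = list(), inequalities = list()) {
  chk_pair <- function(p, what) {
    if (length(p) != 2 || !all(p %in% 1:4) || p[1] == p[2]) {
      abort(paste0("Each ", what, " must be a pair of distinct condition indices in 1..4."))
    }
    as.integer(p)
  }
  equalities <- lapply(equalities, chk_pair, what = "equality")
  inequalities <- lapply(inequalities, chk_pair, what = "inequality")
  unord <- function(p) paste(sort(p), collapse = "-")
  if (length(intersect(vapply(equalities, unord, ""),
                       vapply(inequalities, unord, ""))) > 0) {
    abort("A pair of conditions cannot be constrained both equal and ordered.")
  }
  ord <- vapply(inequalities, paste, "", collapse = ">")
  rev_ord <- vapply(inequalities, function(p) paste(rev(p), collapse = ">"), "")
  if (length(intersect(ord, rev_ord)) > 0) {
    abort("Contradictory inequality constraints.")
  }
  structure(
    list(name = name, equalities = equalities, inequalities = inequalities),
    class = "rkn_model"
  )
}

#' @export
print.rkn_model <- function(x, ...) {
  eq <- vapply(x$equalities, function(p) sprintf("mu%d = mu%d", p[1], p[2]), "")
  iq <- vapply(x$inequalities, function(p) sprintf("mu%d > mu%d", p[1], p[2]), "")
  cons <- c(eq, iq)
  cat("<rkn_model> ", x$name, ": ",
      if (length(cons) == 0) "unconstrained" else paste(cons, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' The standard model registry
#'
#' The five competing accounts of the condition means compared in the package:
#' * `M_u` — unconstrained: each condition has its own mean.
#' * `M_*` — the dual-process (replication) pattern: more remember responses
#'   for old words than old nonwords (\eqn{\mu_1 > \mu_2}) with no lexicality
#'   effect for new items (\eqn{\mu_3 = \mu_4}).
#' * `M_1` — single-process criterion shift: no lexicality effect at all
#'   (\eqn{\mu_1 = \mu_2}, \eqn{\mu_3 = \mu_4}).
#' * `M_2` — words promote remember responses regardless of study status
#'   (\eqn{\mu_1 > \mu_2}, \eqn{\mu_3 > \mu_4}).
#' * `M_3` — the opposite: nonwords promote remember responses
#'   (\eqn{\mu_1 < \mu_2}, \eqn{\mu_3 < \mu_4}).
#'
#' @return A named list of [rkn_model()] objects.
#' @export
rkn_models <- function() {
  list(
    M_u = rkn_model("M_u"),
    "M_*" = rkn_model("M_*",
      equalities = list(c(3L, 4L)),
      inequalities = list(c(1L, 2L))
    ),
    M_1 = rkn_model("M_1", equalities = list(c(1L, 2L), c(3L, 4L))),
    M_2 = rkn_model("M_2", inequalities = list(c(1L, 2L), c(3L, 4L))),
    M_3 = rkn_model("M_3", inequalities = list(c(2L, 1L), c(4L, 3L)))
  )
}

#' Default g-prior and sampler settings
#'
#' Settings for the default-prior Bayes factor machinery. Condition effects
#' (sum-to-zero contrasts of the collapsed condition means) receive a joint
#' g-prior \eqn{N(0, g\sigma^2)} with \eqn{g} given the scaled
#' inverse-chi-square distribution implied by a Cauchy prior of scale `scale`
#' on the standardized effects; the grand mean has a flat prior and
#' \eqn{\sigma^2} the Jeffreys prior. Bayes factors are therefore invariant to
#' location and scale changes of the data.
#'
#' @param scale Prior scale on standardized effects; default
#'   \eqn{\sqrt{2}/2 \approx 0.707}, the conventional default for this class
#'   of priors.
#' @param nodes Number of quadrature nodes for the one-dimensional integral
#'   over \eqn{\log g}.
#' @param iterations,warmup,chains Gibbs sampler settings used by the
#'   encompassing step (posterior probability of the order constraints).
#' @return An object of class `rkn_prior`.
#' @export
g_prior <- function(scale = sqrt(2) / 2, nodes = 401L,
                    iterations = 20000L, warmup = 2000L, chains = 4L) {
  stopifnot(scale > 0, nodes >= 51, iterations > warmup, warmup >= 0, chains >= 1)
  structure(
    list(
      scale = scale, nodes = as.integer(nodes),
      iterations = as.integer(iterations), warmup = as.integer(warmup),
      chains = as.integer(chains)
    ),
    class = "rkn_prior"
  )
}

# Partition {1..4} into equality groups; returns integer group id per condition,
# groups numbered in order of first appearance.
equality_groups <- function(equalities) {
  g <- 1:4
  for (p in equalities) {
    old <- g[p[2]]
    g[g == old] <- g[p[1]]
  }
  match(g, unique(g))
}

#' Prior probability that order constraints hold
#'
#' Under the g-prior the (collapsed) condition effects are exchangeable and
#' symmetrically distributed, so the prior probability of a set of pairwise
#' order constraints on disjoint pairs is \eqn{(1/2)^m} exactly. Constraints
#' sharing a condition are evaluated by Monte Carlo over the exchangeable
#' effect prior, with the standard error of the estimate attached.
#'
#' @param inequalities A list of ordered pairs `c(j, jp)` meaning
#'   \eqn{\mu_j > \mu_{j'}}.
#' @param equalities Equality constraints active in the same model; an
#'   inequality between two conditions collapsed to the same group is
#'   contradictory and raises an error.
#' @param mc_draws Number of Monte Carlo draws for the non-disjoint case.
#' @return The prior constraint probability, with attribute `mc_error`
#'   (0 for the analytic case).
#' @export
prior_constraint_probability <- function(inequalities, equalities = list(),
                                         mc_draws = 1e5) {
  if (length(inequalities) == 0) {
    return(structure(1, mc_error = 0))
  }
  grp <- equality_groups(equalities)
  pairs <- lapply(inequalities, function(p) c(grp[p[1]], grp[p[2]]))
  for (p in pairs) {
    if (p[1] == p[2]) {
      abort("Inequality between conditions constrained equal is contradictory.")
    }
  }
  key_ord <- vapply(pairs, paste, "", collapse = ">")
  key_rev <- vapply(pairs, function(p) paste(rev(p), collapse = ">"), "")
  if (length(intersect(key_ord, key_rev)) > 0) {
    abort("Contradictory inequality constraints.")
  }
  pairs <- pairs[!duplicated(key_ord)]
  members <- unlist(pairs)
  if (anyDuplicated(members) == 0) {
    # disjoint pairs of exchangeable effects: each ordering has probability 1/2
    return(structure(0.5^length(pairs), mc_error = 0))
  }
  ngrp <- max(grp)
  z <- matrix(rnorm(mc_draws * ngrp), mc_draws, ngrp)
  ok <- rep(TRUE, mc_draws)
  for (p in pairs) ok <- ok & (z[, p[1]] > z[, p[2]])
  p_hat <- mean(ok)
  structure(p_hat, mc_error = sqrt(p_hat * (1 - p_hat) / mc_draws))
}
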