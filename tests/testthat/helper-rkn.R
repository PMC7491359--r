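# Fixture builders and independent oracles used across the suite.

# a trials tibble from explicit per-cell counts: counts is a 4 x 3 matrix
# (conditions x remember/know/new) used for every participant
trials_from_counts <- function(counts, participants = 1) {
  cond <- tibble::tibble(
    condition = 1:4,
    status = c("old", "old", "new", "new"),
    lexicality = c("word", "nonword", "word", "nonword")
  )
  resp <- c("remember", "know", "new")
  purrr::map(seq_len(participants), function(i) {
    tibble::tibble(
      participant = sprintf("s%02d", i),
      condition = rep(1:4, times = rowSums(counts)),
      response = rep(rep(resp, 4), times = as.integer(t(counts)))
    )
  }) |>
    purrr::list_rbind() |>
    dplyr::inner_join(cond, by = "condition") |>
    dplyr::select(participant, lexicality, status, response)
}

# printed condition-level response proportions: original study (old) and the
# four replication experiments; columns remember, know, new, scaled difference
table_original <- matrix(
  c(0.28, 0.16, 0.56, 0.12,
    0.19, 0.30, 0.51, -0.11,
    0.04, 0.11, 0.85, -0.07,
    0.03, 0.12, 0.85, -0.09),
  nrow = 4, byrow = TRUE
)

table_replications <- list(
  exp1 = matrix(c(0.35, 0.30, 0.35, 0.05,
                  0.36, 0.28, 0.37, 0.08,
                  0.20, 0.18, 0.61, 0.02,
                  0.20, 0.15, 0.64, 0.05), 4, byrow = TRUE),
  exp2 = matrix(c(0.35, 0.31, 0.35, 0.04,
                  0.32, 0.32, 0.36, 0.00,
                  0.08, 0.23, 0.69, -0.16,
                  0.07, 0.15, 0.78, -0.09), 4, byrow = TRUE),
  exp3 = matrix(c(0.46, 0.19, 0.35, 0.28,
                  0.45, 0.19, 0.35, 0.26,
                  0.18, 0.16, 0.66, 0.01,
                  0.13, 0.17, 0.70, -0.04), 4, byrow = TRUE),
  exp4 = matrix(c(0.35, 0.29, 0.35, 0.06,
                  0.42, 0.26, 0.32, 0.15,
                  0.10, 0.16, 0.74, -0.07,
                  0.13, 0.17, 0.70, -0.04), 4, byrow = TRUE)
)

# ---- independent marginal-likelihood oracle -------------------------------
# Dense 2-D trapezoid integration over (g, sigma^2) with the conditionally
# Gaussian layer (grand mean and effects) integrated by generic N x N linear
# algebra -- a different computational route from the package's analytic
# sigma^2 integral + Woodbury identities.
oracle_marginal_grid <- function(Y, equalities = list(), scale = sqrt(2) / 2,
                                 n_g = 401, n_s = 401) {
  grp <- rknbayes:::equality_groups(equalities)
  G <- max(grp)
  stopifnot(G >= 2)  # the G = 1 case is closed-form in both routes
  y <- as.numeric(Y)
  N <- length(y)
  X <- outer(rep(grp, each = nrow(Y)), seq_len(G), `==`) * 1
  C <- diag(G) - 1 / G
  e <- eigen(C, symmetric = TRUE)
  Q <- e$vectors[, e$values > 0.5, drop = FALSE]
  Xs <- X %*% Q
  ones <- rep(1, N)

  log_pg <- function(g) 0.5 * log(scale^2 / 2) - lgamma(0.5) - 1.5 * log(g) -
    scale^2 / (2 * g)
  log_ps <- function(s2) -log(s2)

  ug <- log(scale^2) + seq(log(1e-6), log(1e6), length.out = n_g)
  v0 <- sum((y - mean(y))^2) / N
  us <- log(v0) + seq(log(1e-5), log(1e5), length.out = n_s)
  s2v <- exp(us)
  lf <- matrix(NA_real_, n_g, n_s)
  for (a in seq_len(n_g)) {
    g <- exp(ug[a])
    Sg <- diag(N) + g * tcrossprod(Xs)   # N x N, generic route
    Si <- solve(Sg)
    S <- drop(t(y) %*% Si %*% y -
                (t(ones) %*% Si %*% y)^2 / (t(ones) %*% Si %*% ones))
    base <- -0.5 * as.numeric(determinant(Sg)$modulus) -
      0.5 * log(drop(t(ones) %*% Si %*% ones)) + log_pg(g) + ug[a]
    lf[a, ] <- base - 0.5 * (N - 1) * log(2 * pi * s2v) - S / (2 * s2v) +
      log_ps(s2v) + us
  }
  wg <- rep(ug[2] - ug[1], n_g); wg[c(1, n_g)] <- wg[1] / 2
  ws <- rep(us[2] - us[1], n_s); ws[c(1, n_s)] <- ws[1] / 2
  lw <- outer(log(wg), log(ws), `+`)
  m <- max(lf + lw)
  m + log(sum(exp(lf + lw - m)))
}

# ---- closed-form fixed-g contrast tail ------------------------------------
# With g fixed, the posterior of a contrast of condition means is scaled-t
# with N - 1 df; returns Pr(mu_a > mu_b | data).
oracle_fixed_g_tail <- function(Y, a, b, g) {
  y <- as.numeric(Y)
  N <- length(y)
  I <- nrow(Y)
  grp <- rep(1:4, each = I)
  X <- outer(grp, 1:4, `==`) * 1
  C <- diag(4) - 1 / 4
  e <- eigen(C, symmetric = TRUE)
  Q <- e$vectors[, e$values > 0.5, drop = FALSE]
  Xf <- cbind(1, X %*% Q)
  D <- diag(c(0, rep(1 / g, 3)))
  B <- solve(crossprod(Xf) + D)
  m <- B %*% crossprod(Xf, y)
  S <- drop(crossprod(y) - t(crossprod(Xf, y)) %*% m)
  cvec <- c(0, Q[a, ] - Q[b, ])
  mc <- drop(t(cvec) %*% m)
  s2c <- (S / (N - 1)) * drop(t(cvec) %*% B %*% cvec)
  stats::pt(mc / sqrt(s2c), df = N - 1)
}

# ---- 2 x 2 fully-within ANOVA oracle --------------------------------------
# Textbook sums-of-squares route (no model-fitting machinery). `m` is an
# n x 4 matrix of cell values, columns in the order
# (item1:resp1, item1:resp2, item2:resp1, item2:resp2).
oracle_anova_2x2 <- function(m) {
  n <- nrow(m)
  gm <- mean(m)
  subj <- rowMeans(m)                                   # y_i..
  A_subj <- cbind(rowMeans(m[, 1:2]), rowMeans(m[, 3:4]))  # y_ij. (item)
  B_subj <- cbind(rowMeans(m[, c(1, 3)]), rowMeans(m[, c(2, 4)]))  # y_i.k
  A_mean <- colMeans(A_subj)
  B_mean <- colMeans(B_subj)
  cell_mean <- colMeans(m)
  ss_total <- sum((m - gm)^2)
  ss_S <- 4 * sum((subj - gm)^2)
  ss_A <- 2 * n * sum((A_mean - gm)^2)
  ss_B <- 2 * n * sum((B_mean - gm)^2)
  ab_resid <- cell_mean - A_mean[c(1, 1, 2, 2)] - B_mean[c(1, 2, 1, 2)] + gm
  ss_AB <- n * sum(ab_resid^2)
  dev_AS <- sweep(sweep(A_subj, 1, subj - gm), 2, A_mean) # y_ij. - y_i.. - y_.j. + y
  ss_AS <- 2 * sum(dev_AS^2)
  dev_BS <- sweep(sweep(B_subj, 1, subj - gm), 2, B_mean)
  ss_BS <- 2 * sum(dev_BS^2)
  ss_ABS <- ss_total - ss_S - ss_A - ss_B - ss_AB - ss_AS - ss_BS
  df_err <- n - 1
  eff <- function(ss_eff, ss_err) {
    F <- (ss_eff / 1) / (ss_err / df_err)
    list(
      F = F, df1 = 1, df2 = df_err, mse = ss_err / df_err,
      p = stats::pf(F, 1, df_err, lower.tail = FALSE),
      eta_sq_g = ss_eff / (ss_eff + ss_S + ss_AS + ss_BS + ss_ABS)
    )
  }
  list(
    item = eff(ss_A, ss_AS),
    response = eff(ss_B, ss_BS),
    interaction = eff(ss_AB, ss_ABS)
  )
}

# n x 4 cell matrix (word:remember, word:know, nonword:remember, nonword:know)
# for a given status, from a count table
anova_cell_matrix <- function(counts, status = "old") {
  d <- counts[counts$status == status, ]
  wide <- tidyr::pivot_wider(
    d[, c("participant", "lexicality", "r", "k")],
    names_from = "lexicality", values_from = c("r", "k")
  )
  as.matrix(wide[, c("r_word", "k_word", "r_nonword", "k_nonword")])
}

# reduced sampler settings for tests
quick_prior <- function(it = 6000, wu = 1000, ch = 2) {
  g_prior(iterations = it, warmup = wu, chains = ch)
}
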