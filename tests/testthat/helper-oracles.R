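# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: normal equations instead of lm.fit, all-pairs
# counting instead of rank sums, hypergeometric enumeration instead of
# fisher.test.

# OLS via normal equations; t-test p for each coefficient.
ols_oracle <- function(y, X) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% beta
  df <- length(y) - ncol(X)
  s2 <- sum(resid^2) / df
  se <- sqrt(diag(solve(XtX)) * s2)
  tval <- beta / se
  list(beta = drop(beta), se = se, p = 2 * pt(-abs(tval), df))
}

# AUC by brute-force pair counting (concordant + half ties) on the
# risk-oriented scale (larger risk = positive class expected larger).
auc_pairs_oracle <- function(risk, positive) {
  pos <- risk[positive]
  neg <- risk[!positive]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Two-sided Fisher exact p by full enumeration of tables with fixed margins.
fisher_enum_oracle <- function(tbl) {
  a <- tbl[1, 1]
  r1 <- sum(tbl[1, ]); r2 <- sum(tbl[2, ])
  c1 <- sum(tbl[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tbl[, 2]) == 0) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(ks, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Youden scan by exhaustive threshold enumeration (lower score = positive).
youden_scan_oracle <- function(score, positive) {
  best <- -Inf
  for (t in sort(unique(score))) {
    pred <- score <= t
    j <- sum(pred & positive) / sum(positive) +
      sum(!pred & !positive) / sum(!positive) - 1
    if (j > best) best <- j
  }
  best
}

# A tiny deterministic cohort for IO and pipeline tests.
small_cohort <- function(n = 24, seed = 11) {
  simulate_cohort(sim_config(n_subjects = n, seed = seed,
                             discovery_fraction = 0.75))
}

# Config with every genetic and covariate effect switched off.
null_sim_config <- function(...) {
  vs <- default_variant_specs()
  vs$effect_model <- "null"
  vs$effect_size <- 0
  sd <- default_star_variant_defs()
  sd$effect_size <- 0
  sim_config(variant_specs = vs, star_variant_defs = sd, ...)
}
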