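#' Code raw genotypes under a genetic model
#'
#' @param genotype Integer vector of alt-allele counts (0/1/2, `NA` allowed).
#' @param model One of `"additive"` (0/1/2 -> 0/1/2), `"dominant"`
#'   (1 or 2 -> 1) or `"recessive"` (2 -> 1, else 0).
#' @return Numeric coded vector, `NA` preserved.
#' @export
code_genotype <- function(genotype,
                          model = c("additive", "dominant", "recessive")) {
  model <- match.arg(model)
  assert_genotype_values(genotype)
  switch(model,
    additive  = as.numeric(genotype),
    dominant  = as.numeric(genotype >= 1L),
    recessive = as.numeric(genotype == 2L)
  )
}

# Least-squares fit of y ~ [1, covariates..., x]; returns beta/se/p for the
# last column. Complete cases are assumed; used on hot paths (variant scans).
.ols_last_coef <- function(y, X) {
  fit <- lm.fit(X, y)
  k <- ncol(X)
  df <- length(y) - fit$rank
  rss <- sum(fit$residuals^2)
  R <- qr.R(fit$qr)
  XtX_inv <- chol2inv(R)
  se <- unname(sqrt(rss / df * XtX_inv[k, k]))
  beta <- unname(fit$coefficients[k])
  tval <- beta / se
  list(beta = beta, se = se, p = 2 * pt(-abs(tval), df), df = df)
}

#' Age- and sex-adjusted linear regression of DIP on a coded genotype
#'
#' Fits ordinary least squares `dip ~ intercept + genotype_code + age + sex`
#' and reports the genotype coefficient (DIP units per coded-genotype unit)
#' with its two-sided t-test p-value. Subjects with any missing field are
#' dropped; `n_used` reports the remainder. If the coded genotype is constant
#' after the drop (e.g. a recessive coding with no homozygote) the test is
#' marked not applicable.
#'
#' @param dip Numeric DIP vector (percentage of planned dose).
#' @param genotype_code Coded genotype vector (see [code_genotype()]).
#' @param age Numeric age in years.
#' @param sex Sex vector, `"male"`/`"female"` or 0/1 (male = 1).
#' @return One-row tibble: `beta`, `se`, `p_value`, `n_used`, `applicable`.
#' @export
adjusted_regression <- function(dip, genotype_code, age, sex) {
  n <- length(dip)
  stopifnot(length(genotype_code) == n, length(age) == n, length(sex) == n)
  sex_num <- if (is.character(sex) || is.factor(sex)) {
    as.numeric(as.character(sex) == "male")
  } else as.numeric(sex)

  ok <- complete.cases(dip, genotype_code, age, sex_num)
  y <- dip[ok]; g <- genotype_code[ok]; a <- age[ok]; s <- sex_num[ok]
  if (length(y) < 5L || length(unique(g)) < 2L) {
    return(tibble(beta = NA_real_, se = NA_real_, p_value = NA_real_,
                  n_used = length(y), applicable = FALSE))
  }
  X <- cbind(1, a, s, g)
  # drop constant covariate columns (keeps the fit full-rank; equals the
  # unadjusted regression when age and sex carry no information)
  keep <- c(TRUE, length(unique(a)) > 1L, length(unique(s)) > 1L, TRUE)
  fit <- .ols_last_coef(y, X[, keep, drop = FALSE])
  tibble(beta = fit$beta, se = fit$se, p_value = fit$p,
         n_used = length(y), applicable = TRUE)
}

#' Association scan over a genotype table
#'
#' Runs [adjusted_regression()] for every variant column under one genetic
#' model, complete-case per variant.
#'
#' @param genotypes Wide genotype tibble (`subject_id` + one column per
#'   variant).
#' @param subjects Subject tibble with `subject_id`, `age`, `sex`, `dip`.
#' @param model Genetic model passed to [code_genotype()].
#' @return Tibble: `variant_id`, `model`, `beta`, `se`, `p_value`, `n_used`,
#'   `applicable`.
#' @export
assoc_scan <- function(genotypes, subjects, model = "additive") {
  stopifnot(identical(genotypes$subject_id, subjects$subject_id))
  vids <- setdiff(names(genotypes), "subject_id")
  res <- map(vids, function(v) {
    adjusted_regression(subjects$dip,
                        code_genotype(genotypes[[v]], model),
                        subjects$age, subjects$sex)
  })
  bind_cols(tibble(variant_id = vids, model = model), list_rbind(res))
}

#' One-way ANOVA of DIP across genotype groups
#'
#' Fixed-effects one-way ANOVA F-test of the DIP phenotype across raw
#' genotype groups 0/1/2.
#'
#' @param dip Numeric DIP vector.
#' @param genotype Raw genotype vector (0/1/2, `NA` dropped).
#' @return One-row tibble: `statistic` (F), `p_value`, `n_used`, `applicable`.
#' @export
anova_by_genotype <- function(dip, genotype) {
  ok <- complete.cases(dip, genotype)
  y <- dip[ok]; g <- factor(genotype[ok])
  counts <- table(g)
  if (sum(counts >= 2L) < 2L || nlevels(droplevels(g)) < 2L) {
    return(tibble(statistic = NA_real_, p_value = NA_real_,
                  n_used = length(y), applicable = FALSE))
  }
  a <- anova(lm(y ~ g))
  tibble(statistic = a[["F value"]][1], p_value = a[["Pr(>F)"]][1],
         n_used = length(y), applicable = TRUE)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value obtained by summing the hypergeometric
#' probabilities of all tables (with the observed margins) no more probable
#' than the observed one. A table with a zero margin is uninformative and
#' returns p = 1.
#'
#' @param counts 2x2 matrix of nonnegative integer counts.
#' @return Two-sided p-value.
#' @export
#' @examples
#' fisher_2x2(matrix(c(5, 0, 0, 5), 2))
fisher_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(identical(dim(counts), c(2L, 2L)))
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be nonnegative integers", class = "gvb_data_error")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) return(1)
  stats::fisher.test(counts)$p.value
}

#' Cochran-Armitage trend test across genotype classes
#'
#' Score-form trend test of case proportions across the three genotype
#' columns with weights 0, 1, 2 and no continuity correction; two-sided
#' p-value from the standard-normal reference.
#'
#' @param counts 2x3 matrix: rows cases/controls, columns genotypes 0/1/2.
#' @return One-row tibble: `statistic` (Z), `p_value`, `applicable`.
#' @export
cochran_armitage_trend <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(identical(dim(counts), c(2L, 3L)))
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be nonnegative integers", class = "gvb_data_error")
  }
  if (any(rowSums(counts) == 0) || sum(counts) == 0) {
    return(tibble(statistic = NA_real_, p_value = NA_real_, applicable = FALSE))
  }
  w <- c(0, 1, 2)
  n_i <- colSums(counts)
  r_i <- counts[1, ]
  N <- sum(n_i); R <- sum(r_i); p <- R / N
  num <- sum(w * r_i) - p * sum(w * n_i)
  v <- p * (1 - p) * (sum(w^2 * n_i) - sum(w * n_i)^2 / N)
  if (v <= 0) {
    return(tibble(statistic = NA_real_, p_value = NA_real_, applicable = FALSE))
  }
  z <- num / sqrt(v)
  tibble(statistic = z, p_value = 2 * pnorm(-abs(z)), applicable = TRUE)
}

#' DIP toxicity group scheme
#'
#' The nested severity groups used in the categorical analyses: the control
#' group G0 holds subjects with DIP > 70%, and G1..G6 hold subjects at or
#' below decreasing DIP thresholds (G6 alone uses a strict `<`).
#'
#' @return Tibble with `group`, `threshold`, `strict` columns.
#' @export
dip_group_scheme <- function() {
  tibble(
    group = paste0("G", 1:6),
    threshold = c(70, 60, 45, 35, 25, 15),
    strict = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  )
}

#' Assign subjects to DIP severity groups
#'
#' Groups are nested, not a partition: G1 contains G2 contains ... G6. G0 is
#' the complement of G1 (DIP strictly above 70%).
#'
#' @param subjects Subject tibble with `subject_id` and `dip`.
#' @param scheme A [dip_group_scheme()]-shaped tibble.
#' @return Long tibble: `group`, `subject_id`.
#' @export
dip_groups <- function(subjects, scheme = dip_group_scheme()) {
  stopifnot(!any(is.na(subjects$dip)))
  rows <- list(tibble(group = "G0",
                      subject_id = subjects$subject_id[subjects$dip > 70]))
  for (i in seq_len(nrow(scheme))) {
    inn <- if (scheme$strict[i]) subjects$dip < scheme$threshold[i]
           else subjects$dip <= scheme$threshold[i]
    rows[[i + 1L]] <- tibble(group = scheme$group[i],
                             subject_id = subjects$subject_id[inn])
  }
  list_rbind(rows)
}

#' Discovery-phase variant screen
#'
#' Additive-model adjusted regression of every variant against DIP in the
#' supplied (discovery) subjects; variants reaching `p < p_max` are then
#' passed through the SIFT/CADD deleteriousness filter to form the candidate
#' list. The full per-variant screen table (before the deleteriousness
#' filter) is attached as attribute `"screen"` so funnel counts can be
#' reported.
#'
#' @param variants Annotated variant tibble (already restricted to
#'   strong-effect consequences).
#' @param genotypes Wide genotype tibble for the same subjects.
#' @param subjects Discovery-cohort subject tibble.
#' @param p_max Discovery significance cutoff, default 0.01 (strict `<`).
#' @param sift_max,cadd_min Deleteriousness thresholds, defaults 0.05 / 25.
#' @return Candidate tibble: variant annotation joined with the additive
#'   association result.
#' @export
discovery_screen <- function(variants, genotypes, subjects,
                             p_max = 0.01, sift_max = 0.05, cadd_min = 25) {
  if (nrow(subjects) == 0L) {
    out <- variants[0, ]
    attr(out, "screen") <- tibble()
    return(out)
  }
  scan <- assoc_scan(genotypes[, c("subject_id", variants$variant_id)],
                     subjects, model = "additive")
  hits <- scan$variant_id[scan$applicable & !is.na(scan$p_value) &
                            scan$p_value < p_max]
  cand <- filter_deleterious(variants[variants$variant_id %in% hits, ],
                             sift_max = sift_max, cadd_min = cadd_min)
  out <- left_join(cand, scan, by = "variant_id")
  attr(out, "screen") <- scan
  out
}

#' Replication of candidate variants
#'
#' Refits each candidate in the replication cohort under both the additive
#' and recessive models. A candidate replicates when any applicable model
#' reaches `p < p_max`; the recessive model is not applicable when the
#' replication data contain no homozygote.
#'
#' @param candidates Candidate tibble (needs `variant_id`).
#' @param genotypes Wide genotype tibble for the replication subjects.
#' @param subjects Replication-cohort subject tibble.
#' @param p_max Replication cutoff, default 0.05 (strict `<`).
#' @return Tibble: per candidate, both models' results and a `replicated`
#'   flag.
#' @export
replicate_candidates <- function(candidates, genotypes, subjects,
                                 p_max = 0.05) {
  res <- map(candidates$variant_id, function(v) {
    if (!v %in% names(genotypes)) {
      return(tibble(variant_id = v,
                    beta_additive = NA_real_, p_additive = NA_real_,
                    beta_recessive = NA_real_, p_recessive = NA_real_,
                    recessive_applicable = FALSE, n_used = 0L,
                    replicated = FALSE))
    }
    g <- genotypes[[v]]
    add <- adjusted_regression(subjects$dip, code_genotype(g, "additive"),
                               subjects$age, subjects$sex)
    rec <- adjusted_regression(subjects$dip, code_genotype(g, "recessive"),
                               subjects$age, subjects$sex)
    ps <- c(if (add$applicable) add$p_value, if (rec$applicable) rec$p_value)
    tibble(variant_id = v,
           beta_additive = add$beta, p_additive = add$p_value,
           beta_recessive = rec$beta, p_recessive = rec$p_value,
           recessive_applicable = rec$applicable, n_used = add$n_used,
           replicated = length(ps) > 0 && any(ps < p_max))
  })
  list_rbind(res)
}
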