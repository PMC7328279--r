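#' Confusion-matrix metrics
#'
#' Sensitivity, specificity, positive and negative predictive values and
#' accuracy from 2x2 counts. Condition positive means intolerant (DIP at or
#' below the cutoff); test positive means predicted intolerant. A metric
#' whose defining denominator is zero is reported as `NA` (undefined), never
#' as 0.
#'
#' @param tp,fp,fn,tn Nonnegative integer counts.
#' @return One-row tibble with the counts, `total`, and the five metrics.
#' @export
#' @examples
#' confusion_metrics(tp = 5, fp = 7, fn = 16, tn = 212)
confusion_metrics <- function(tp, fp, fn, tn) {
  counts <- c(tp, fp, fn, tn)
  if (any(counts < 0) || any(counts != round(counts)) || any(is.na(counts))) {
    abort("counts must be nonnegative integers", class = "gvb_data_error")
  }
  total <- tp + fp + fn + tn
  stopifnot(total > 0)
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble(
    tp = tp, fp = fp, fn = fn, tn = tn, total = total,
    sensitivity = div(tp, tp + fn),
    specificity = div(tn, tn + fp),
    ppv = div(tp, tp + fp),
    npv = div(tn, tn + fn),
    accuracy = (tp + tn) / total
  )
}

#' Build a confusion table from logical vectors
#'
#' @param condition Logical: truly intolerant.
#' @param predicted Logical: predicted intolerant.
#' @return One-row metrics tibble (see [confusion_metrics()]).
#' @export
confusion_from_labels <- function(condition, predicted) {
  stopifnot(length(condition) == length(predicted),
            !any(is.na(condition)), !any(is.na(predicted)))
  confusion_metrics(
    tp = sum(condition & predicted),
    fp = sum(!condition & predicted),
    fn = sum(condition & !predicted),
    tn = sum(!condition & !predicted)
  )
}

# Risk-oriented score: larger = more at risk. GVB is a "lower = worse" scale.
.risk_score <- function(score, direction) {
  if (direction == "lower") -score else score
}

#' ROC curve and AUC for a risk score
#'
#' The AUC is the tie-corrected Mann-Whitney probability that a positive
#' subject's risk-oriented score exceeds a negative subject's (ties count
#' half). For GVB scores use `direction = "lower"` (lower burden score means
#' higher risk). The confidence interval is a stratified bootstrap
#' percentile interval (cases and controls resampled separately) under a
#' fixed seed; set `boot_n = 0` to skip it.
#'
#' @param score Numeric score vector.
#' @param positive Logical condition-positive labels.
#' @param direction `"lower"` if a lower score indicates the positive
#'   (at-risk) class, `"higher"` otherwise.
#' @param boot_n Bootstrap resamples for the CI (default 2000).
#' @param conf Confidence level (default 0.95).
#' @param seed Seed for the bootstrap, default 1.
#' @return A `gvb_roc` object: list with `points` (tibble `threshold`, `fpr`,
#'   `tpr`), `auc`, `ci_low`, `ci_high`, `n_pos`, `n_neg`, `direction`.
#' @export
roc_auc <- function(score, positive, direction = c("lower", "higher"),
                    boot_n = 2000, conf = 0.95, seed = 1L) {
  direction <- match.arg(direction)
  stopifnot(length(score) == length(positive), !any(is.na(score)),
            !any(is.na(positive)))
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) {
    abort("both classes must be nonempty to compute an AUC",
          class = "gvb_degenerate_error")
  }
  risk <- .risk_score(score, direction)
  auc_of <- function(r, pos) {
    rk <- rank(r)
    (sum(rk[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
  }
  auc <- auc_of(risk, positive)

  # ROC points: sweep thresholds over unique risk values, predict positive
  # when risk >= threshold
  thr <- sort(unique(risk), decreasing = TRUE)
  pts <- tibble(
    threshold = c(Inf, thr),
    tpr = c(0, map_dbl(thr, ~ sum(risk >= .x & positive) / n1)),
    fpr = c(0, map_dbl(thr, ~ sum(risk >= .x & !positive) / n0))
  )

  ci <- c(NA_real_, NA_real_)
  if (boot_n > 0) {
    ip <- which(positive); ineg <- which(!positive)
    boots <- withr::with_seed(seed, {
      vapply(seq_len(boot_n), function(i) {
        bp <- sample(ip, n1, replace = TRUE)
        bn <- sample(ineg, n0, replace = TRUE)
        r <- risk[c(bp, bn)]
        auc_of(r, c(rep(TRUE, n1), rep(FALSE, n0)))
      }, numeric(1))
    })
    alpha <- (1 - conf) / 2
    ci <- unname(quantile(boots, c(alpha, 1 - alpha), type = 7))
  }
  structure(
    list(points = pts, auc = auc, ci_low = ci[1], ci_high = ci[2],
         n_pos = n1, n_neg = n0, direction = direction),
    class = "gvb_roc"
  )
}

#' @export
print.gvb_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f", x$auc))
  if (!is.na(x$ci_low)) cat(sprintf(" [%.3f, %.3f]", x$ci_low, x$ci_high))
  cat(sprintf(" (%d positive / %d negative)\n", x$n_pos, x$n_neg))
  invisible(x)
}

#' Youden-optimal classification cutoff
#'
#' Scans every observed score as a candidate threshold and returns the one
#' maximizing Youden's J = sensitivity + specificity - 1. Ties are broken
#' toward the threshold that classifies more subjects as positive (higher
#' sensitivity), the conservative choice for a toxicity screen.
#'
#' @inheritParams roc_auc
#' @return One-row tibble: `threshold`, `j_statistic`, `sensitivity`,
#'   `specificity`.
#' @export
youden_cutoff <- function(score, positive, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) {
    abort("both classes must be nonempty", class = "gvb_degenerate_error")
  }
  cand <- sort(unique(score))
  stats_at <- function(t) {
    pred <- if (direction == "lower") score <= t else score >= t
    c(sens = sum(pred & positive) / n1, spec = sum(!pred & !positive) / n0)
  }
  m <- vapply(cand, stats_at, numeric(2))
  j <- m["sens", ] + m["spec", ] - 1
  best_j <- max(j)
  ties <- which(j >= best_j - 1e-12)
  # more-positive threshold: larger for "lower" direction, smaller otherwise
  pick <- if (direction == "lower") ties[which.max(cand[ties])]
          else ties[which.min(cand[ties])]
  tibble(threshold = cand[pick], j_statistic = unname(j[pick]),
         sensitivity = unname(m["sens", pick]),
         specificity = unname(m["spec", pick]))
}

#' Classify subjects by a GVB threshold
#'
#' Predicted intolerant iff the score is at or below the threshold
#' (inclusive boundary).
#'
#' @param score Numeric GVB scores.
#' @param threshold Finite threshold.
#' @return Logical vector of predicted-intolerant flags.
#' @export
classify_by_gvb <- function(score, threshold) {
  stopifnot(is.finite(threshold))
  score <= threshold
}

#' Compare the star-allele classifier with GVB models
#'
#' The machine twin of the star-allele vs GVB comparison tables: for the
#' CPIC-style PM+IM/NM classifier and each requested GVB column (at its
#' Youden-optimal cutoff determined on the full table), emits the confusion
#' counts, derived metrics, and AUC per cohort and combined, at one DIP
#' cutoff.
#'
#' @param subjects Subject tibble (`subject_id`, `cohort`, `dip`).
#' @param profiles GVB profile tibble from [profile_cohort()].
#' @param risk Combined risk calls from [combined_risk()].
#' @param gvb_columns Names of the score columns in `profiles` to evaluate.
#' @param dip_cutoff Condition-positive cutoff in DIP % (positive iff
#'   `dip <= dip_cutoff`), default 25.
#' @param boot_n Bootstrap resamples for AUC CIs (0 to skip).
#' @param seed Seed for the bootstrap.
#' @return Tidy tibble: one row per predictor x cohort with threshold,
#'   counts, metrics, `auc`, `ci_low`, `ci_high`.
#' @export
compare_models <- function(subjects, profiles, risk,
                           gvb_columns = c("NUDT15,TPMT",
                                           "NUDT15,TPMT,CRIM1"),
                           dip_cutoff = 25, boot_n = 0, seed = 1L) {
  dat <- subjects |>
    left_join(risk, by = "subject_id") |>
    left_join(profiles, by = "subject_id")
  if (any(is.na(dat$risk)) ||
      any(vapply(gvb_columns, function(cn) any(is.na(dat[[cn]])), logical(1)))) {
    bad <- dat$subject_id[is.na(dat$risk)]
    abort(paste("missing predictor for subject(s):",
                paste(utils::head(bad, 5L), collapse = ", ")),
          class = "gvb_data_error")
  }
  cond <- dat$dip <= dip_cutoff
  cohorts <- c(unique(dat$cohort), "combined")

  preds <- list(list(name = "CPIC NUDT15/TPMT metabolizer",
                     predicted = dat$risk == "PM+IM",
                     score = as.numeric(dat$risk == "NM"), # 0 = risk arm
                     threshold = NA_real_))
  for (cn in gvb_columns) {
    yj <- youden_cutoff(dat[[cn]], cond, direction = "lower")
    preds <- c(preds, list(list(
      name = paste0("GVB ", cn),
      predicted = classify_by_gvb(dat[[cn]], yj$threshold),
      score = dat[[cn]],
      threshold = yj$threshold)))
  }

  rows <- list()
  for (p in preds) {
    for (co in cohorts) {
      idx <- if (co == "combined") rep(TRUE, nrow(dat)) else dat$cohort == co
      cm <- confusion_from_labels(cond[idx], p$predicted[idx])
      auc <- ci_lo <- ci_hi <- NA_real_
      if (sum(cond[idx]) > 0 && sum(!cond[idx]) > 0) {
        r <- roc_auc(p$score[idx], cond[idx], direction = "lower",
                     boot_n = boot_n, seed = seed)
        auc <- r$auc; ci_lo <- r$ci_low; ci_hi <- r$ci_high
      }
      rows[[length(rows) + 1L]] <- bind_cols(
        tibble(predictor = p$name, cohort = co, dip_cutoff = dip_cutoff,
               threshold = p$threshold),
        cm, tibble(auc = auc, ci_low = ci_lo, ci_high = ci_hi))
    }
  }
  list_rbind(rows)
}

#' Single-gene predictive contribution after controlling for the other genes
#'
#' Measures the ROC performance of one gene's GVB score on the subset of
#' subjects in whom the other two genes are uninformative: for CRIM1 the
#' both-wildtype (NUDT15 and TPMT NM) subjects; for NUDT15 the TPMT-wildtype
#' subjects who are not homozygous for the masked CRIM1 variant; for TPMT
#' the NUDT15-wildtype non-homozygote subjects.
#'
#' @param subjects Subject tibble.
#' @param profiles GVB profiles containing a column per gene.
#' @param phenotypes Per-gene metabolizer calls from [assign_phenotype()].
#' @param genotypes Wide genotype tibble (needed for the masked-variant
#'   homozygosity rule).
#' @param gene One of `"CRIM1"`, `"NUDT15"`, `"TPMT"`.
#' @param masked_variant Variant id whose homozygotes define CRIM1 burden,
#'   default `"rs3821169"`.
#' @param dip_cutoffs DIP cutoffs (in %) to evaluate.
#' @param boot_n,seed Bootstrap controls for the AUC CI.
#' @return Tibble: `gene`, `dip_cutoff`, `n`, `n_pos`, `auc`, `ci_low`,
#'   `ci_high` (AUC columns `NA` when a class is empty).
#' @export
single_gene_contribution <- function(subjects, profiles, phenotypes,
                                     genotypes, gene,
                                     masked_variant = "rs3821169",
                                     dip_cutoffs = c(15, 25, 35, 45, 60, 80, 100),
                                     boot_n = 0, seed = 1L) {
  stopifnot(gene %in% c("CRIM1", "NUDT15", "TPMT"))
  wt <- function(g) {
    ph <- phenotypes[phenotypes$gene == g, ]
    ph$subject_id[ph$phenotype == "NM"]
  }
  non_hom <- if (masked_variant %in% names(genotypes)) {
    genotypes$subject_id[is.na(genotypes[[masked_variant]]) |
                           genotypes[[masked_variant]] != 2L]
  } else genotypes$subject_id
  keep_ids <- switch(gene,
    CRIM1  = intersect(wt("NUDT15"), wt("TPMT")),
    NUDT15 = intersect(wt("TPMT"), non_hom),
    TPMT   = intersect(wt("NUDT15"), non_hom)
  )
  dat <- subjects |>
    filter(.data$subject_id %in% keep_ids) |>
    left_join(profiles[, c("subject_id", gene)], by = "subject_id")
  if (nrow(dat) == 0L) {
    warn(sprintf("empty subset for gene %s after exclusions", gene))
    return(tibble(gene = character(), dip_cutoff = numeric(), n = integer(),
                  n_pos = integer(), auc = numeric(), ci_low = numeric(),
                  ci_high = numeric()))
  }
  rows <- map(dip_cutoffs, function(ct) {
    cond <- dat$dip <= ct
    if (sum(cond) == 0L || sum(!cond) == 0L) {
      return(tibble(gene = gene, dip_cutoff = ct, n = nrow(dat),
                    n_pos = sum(cond), auc = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_))
    }
    r <- roc_auc(dat[[gene]], cond, direction = "lower",
                 boot_n = boot_n, seed = seed)
    tibble(gene = gene, dip_cutoff = ct, n = nrow(dat), n_pos = sum(cond),
           auc = r$auc, ci_low = r$ci_low, ci_high = r$ci_high)
  })
  list_rbind(rows)
}
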