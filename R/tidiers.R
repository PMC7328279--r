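#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an ROC result into its curve points
#'
#' @param x A `gvb_roc` from [roc_auc()].
#' @param ... Unused.
#' @return Tibble of `threshold`, `fpr`, `tpr` points.
#' @method tidy gvb_roc
#' @export
tidy.gvb_roc <- function(x, ...) x$points

#' One-row summary of an ROC result
#'
#' @param x A `gvb_roc` from [roc_auc()].
#' @param ... Unused.
#' @return One-row tibble: `auc`, `ci_low`, `ci_high`, `n_pos`, `n_neg`.
#' @method glance gvb_roc
#' @export
glance.gvb_roc <- function(x, ...) {
  tibble(auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
         n_pos = x$n_pos, n_neg = x$n_neg)
}

#' One-row summary of a synthetic cohort
#'
#' @param x A `gvb_cohort` from [simulate_cohort()].
#' @param ... Unused.
#' @return One-row tibble with cohort sizes, variant count and DIP summary.
#' @method glance gvb_cohort
#' @export
glance.gvb_cohort <- function(x, ...) {
  tibble(
    n_subjects = nrow(x$subjects),
    n_discovery = sum(x$subjects$cohort == "discovery"),
    n_replication = sum(x$subjects$cohort == "replication"),
    n_variants = nrow(x$variants),
    dip_mean = mean(x$subjects$dip),
    dip_sd = stats::sd(x$subjects$dip)
  )
}

#' Tidy a synthetic cohort into its subject table
#'
#' @param x A `gvb_cohort`.
#' @param ... Unused.
#' @return The subject tibble.
#' @method tidy gvb_cohort
#' @export
tidy.gvb_cohort <- function(x, ...) x$subjects
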