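#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_abline geom_point
#'   geom_jitter geom_boxplot labs theme_minimal coord_equal
#' @export
ggplot2::autoplot

#' Plot an ROC curve
#'
#' @param object A `gvb_roc` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gvb_roc
#' @export
autoplot.gvb_roc <- function(object, ...) {
  lab <- sprintf("AUC = %.3f", object$auc)
  if (!is.na(object$ci_low)) {
    lab <- sprintf("%s [%.3f, %.3f]", lab, object$ci_low, object$ci_high)
  }
  ggplot(object$points, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_step() +
    coord_equal() +
    labs(x = "False-positive rate", y = "True-positive rate",
         title = "ROC curve", subtitle = lab) +
    theme_minimal()
}

#' DIP distribution by genotype at one variant
#'
#' Box-and-jitter plot of the DIP phenotype across the 0/1/2 genotype groups
#' of a single variant, the usual visual companion to the per-variant
#' ANOVA/regression tests.
#'
#' @param subjects Subject tibble (`subject_id`, `dip`).
#' @param genotypes Wide genotype tibble.
#' @param variant_id Variant column to plot.
#' @return A ggplot.
#' @export
plot_dip_by_genotype <- function(subjects, genotypes, variant_id) {
  stopifnot(variant_id %in% names(genotypes))
  dat <- left_join(subjects, genotypes[, c("subject_id", variant_id)],
                   by = "subject_id")
  dat$genotype <- factor(dat[[variant_id]], levels = 0:2,
                         labels = c("0 (ref/ref)", "1 (het)", "2 (hom)"))
  dat <- dat[!is.na(dat$genotype), ]
  ggplot(dat, aes(x = .data$genotype, y = .data$dip)) +
    geom_boxplot(outlier.shape = NA) +
    geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    labs(x = paste0(variant_id, " genotype"), y = "Last-cycle 6-MP DIP (%)") +
    theme_minimal()
}

#' GVB score distribution by intolerance status
#'
#' @param profiles GVB profile tibble from [profile_cohort()].
#' @param subjects Subject tibble with `dip`.
#' @param score_column Which score column to plot.
#' @param dip_cutoff Intolerance cutoff in DIP %.
#' @return A ggplot.
#' @export
plot_gvb_by_status <- function(profiles, subjects,
                               score_column = "NUDT15,TPMT,CRIM1",
                               dip_cutoff = 25) {
  dat <- left_join(subjects, profiles, by = "subject_id")
  dat$status <- ifelse(dat$dip <= dip_cutoff,
                       sprintf("DIP ≤ %g%%", dip_cutoff),
                       sprintf("DIP > %g%%", dip_cutoff))
  ggplot(dat, aes(x = .data$status, y = .data[[score_column]])) +
    geom_boxplot(outlier.shape = NA) +
    geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    labs(x = NULL, y = paste0("GVB (", score_column, ")")) +
    theme_minimal()
}
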