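test_that("confusion metrics follow their definitions and flag undefined", {
  perfect <- confusion_metrics(tp = 10, fp = 0, fn = 0, tn = 10)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$ppv, 1)
  expect_equal(perfect$npv, 1)
  expect_equal(perfect$accuracy, 1)

  # zero denominators yield NA, never 0
  no_pos <- confusion_metrics(tp = 0, fp = 0, fn = 0, tn = 12)
  expect_true(is.na(no_pos$sensitivity))
  expect_true(is.na(no_pos$ppv))
  expect_equal(no_pos$accuracy, 1)

  expect_error(confusion_metrics(-1, 0, 0, 5), class = "gvb_data_error")

  # accuracy decomposes by prevalence
  withr::with_seed(3, {
    for (i in 1:20) {
      cm <- confusion_metrics(tp = rpois(1, 8) + 1, fp = rpois(1, 5) + 1,
                              fn = rpois(1, 6) + 1, tn = rpois(1, 20) + 1)
      prev <- (cm$tp + cm$fn) / cm$total
      expect_equal(cm$accuracy,
                   cm$sensitivity * prev + cm$specificity * (1 - prev))
    }
  })
})

test_that("AUC equals all-pairs counting and honors tie conventions", {
  # all scores identical -> 0.5
  expect_equal(roc_auc(rep(0.3, 10), c(rep(TRUE, 4), rep(FALSE, 6)),
                       boot_n = 0)$auc, 0.5)
  # perfect risk separation (lower score = positive) -> 1
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(TRUE, TRUE, FALSE, FALSE),
                       boot_n = 0)$auc, 1)
  # 6-subject hand case
  sc <- c(0.05, 0.2, 0.2, 0.5, 0.7, 0.9)
  lab <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  expect_equal(roc_auc(sc, lab, boot_n = 0)$auc,
               auc_pairs_oracle(-sc, lab))
  expect_error(roc_auc(1:5, rep(TRUE, 5)), class = "gvb_degenerate_error")
})

test_that("AUC matches the oracle, monotone transforms, and reversal", {
  withr::with_seed(41, {
    for (i in 1:25) {
      n <- sample(10:60, 1)
      sc <- round(runif(n), 2) # induces ties
      lab <- runif(n) < 0.4
      if (!any(lab) || all(lab)) next
      r <- roc_auc(sc, lab, boot_n = 0)
      expect_equal(r$auc, auc_pairs_oracle(-sc, lab))
      # strictly monotone transform leaves AUC unchanged
      expect_equal(roc_auc(sc^3 + 2 * sc, lab, boot_n = 0)$auc, r$auc)
      # direction reversal maps auc -> 1 - auc
      expect_equal(roc_auc(sc, lab, direction = "higher", boot_n = 0)$auc,
                   1 - r$auc)
      # ROC points are monotone nondecreasing
      expect_true(all(diff(r$points$tpr) >= 0))
      expect_true(all(diff(r$points$fpr) >= 0))
    }
  })
})

test_that("AUC and bootstrap CI agree with an independent implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(55, {
    sc <- runif(80)
    lab <- runif(80) < 0.35
    r <- roc_auc(sc, lab, boot_n = 500, seed = 9)
    p <- pROC::roc(response = lab, predictor = sc, direction = ">",
                   quiet = TRUE)
    expect_equal(r$auc, as.numeric(pROC::auc(p)))
    expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
    expect_lt(r$ci_high - r$ci_low, 0.5)
  })
})

test_that("Youden cutoff equals the exhaustive scan with the sensitivity tie rule", {
  # perfectly separated: J = 1, tie rule picks the most-positive threshold
  y <- youden_cutoff(c(0.1, 0.2, 0.8, 0.9), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(y$j_statistic, 1)
  expect_equal(y$threshold, 0.2) # largest separating observed score
  expect_equal(y$sensitivity, 1)

  withr::with_seed(61, {
    for (i in 1:25) {
      n <- sample(12:50, 1)
      sc <- round(runif(n), 2)
      lab <- runif(n) < 0.4
      if (!any(lab) || all(lab)) next
      y <- youden_cutoff(sc, lab)
      expect_equal(y$j_statistic, youden_scan_oracle(sc, lab))
      expect_equal(y$j_statistic, y$sensitivity + y$specificity - 1)
    }
    # independent labels: J near 0 at large n
    n <- 4000
    sc <- runif(n); lab <- runif(n) < 0.5
    expect_lt(youden_cutoff(sc, lab)$j_statistic, 0.12)
  })
})

test_that("GVB threshold classification uses an inclusive boundary", {
  expect_equal(classify_by_gvb(c(0.3, 0.30001, 0.1), 0.3),
               c(TRUE, FALSE, TRUE))
  expect_false(any(classify_by_gvb(c(0.001, 0.5), 0)))
  expect_true(all(classify_by_gvb(c(0.001, 0.5, 1), 1)))
})

test_that("compare_models emits the full predictor x cohort grid", {
  co <- simulate_cohort(sim_config(seed = 29))
  pr <- suppressMessages(profile_cohort(co$variants, co$genotypes))
  rk <- combined_risk(assign_phenotype(co$diplotypes))
  cmp <- compare_models(co$subjects, pr, rk, boot_n = 0)
  expect_equal(nrow(cmp), 9L) # 3 predictors x (2 cohorts + combined)
  expect_setequal(unique(cmp$cohort), c("discovery", "replication", "combined"))
  # combined counts are the sum of the cohort counts
  for (p in unique(cmp$predictor)) {
    sub <- cmp[cmp$predictor == p, ]
    expect_equal(sub$tp[sub$cohort == "combined"],
                 sum(sub$tp[sub$cohort != "combined"]))
    expect_equal(sub$total[sub$cohort == "combined"], 320)
  }
  # metrics reproducible from the counts alone
  row <- cmp[5, ]
  cm <- confusion_metrics(row$tp, row$fp, row$fn, row$tn)
  expect_equal(row$sensitivity, cm$sensitivity)
  expect_equal(row$accuracy, cm$accuracy)

  expect_error(compare_models(co$subjects, pr[-1, ], rk, boot_n = 0),
               class = "gvb_data_error")
})

test_that("a gene nobody carries leaves model ranking and AUC unchanged", {
  co <- simulate_cohort(sim_config(seed = 37))
  gt <- co$genotypes
  gt$rs3821169 <- 0L # nobody carries the CRIM1 variant
  pr <- suppressMessages(profile_cohort(co$variants, gt))
  expect_true(all(pr$CRIM1 == 1))
  # three-gene score is the cube-root rescaling of the two-gene score
  expect_equal(pr[["NUDT15,TPMT,CRIM1"]], pr[["NUDT15,TPMT"]]^(2 / 3))
  cond <- co$subjects$dip <= 25
  expect_equal(roc_auc(pr[["NUDT15,TPMT,CRIM1"]], cond, boot_n = 0)$auc,
               roc_auc(pr[["NUDT15,TPMT"]], cond, boot_n = 0)$auc)
})

test_that("single-gene contribution applies the exclusion subsets", {
  co <- simulate_cohort(sim_config(seed = 43))
  pr <- suppressMessages(profile_cohort(
    co$variants, co$genotypes,
    gene_sets = list("NUDT15", "TPMT", "CRIM1",
                     c("NUDT15", "TPMT"), c("NUDT15", "TPMT", "CRIM1"))))
  ph <- assign_phenotype(co$diplotypes)
  sg_crim1 <- single_gene_contribution(co$subjects, pr, ph, co$genotypes,
                                       "CRIM1", dip_cutoffs = c(25, 60))
  wt_n <- ph$subject_id[ph$gene == "NUDT15" & ph$phenotype == "NM"]
  wt_t <- ph$subject_id[ph$gene == "TPMT" & ph$phenotype == "NM"]
  expect_true(all(sg_crim1$n == length(intersect(wt_n, wt_t))))

  sg_nudt <- single_gene_contribution(co$subjects, pr, ph, co$genotypes,
                                      "NUDT15", dip_cutoffs = 25)
  non_hom <- co$genotypes$subject_id[co$genotypes$rs3821169 != 2L]
  expect_equal(sg_nudt$n, length(intersect(wt_t, non_hom)))

  # no CRIM1 homozygotes + all-WT NUDT15/TPMT -> NUDT15 subset = whole cohort
  gt2 <- co$genotypes
  gt2$rs3821169 <- pmin(gt2$rs3821169, 1L)
  ph_allwt <- ph
  ph_allwt$phenotype <- "NM"
  sg_all <- single_gene_contribution(co$subjects, pr, ph_allwt, gt2,
                                     "NUDT15", dip_cutoffs = 25)
  expect_equal(sg_all$n, nrow(co$subjects))
})

test_that("tidiers and plots expose the result objects", {
  r <- roc_auc(runif(30), rep(c(TRUE, FALSE), 15), boot_n = 50, seed = 2)
  td <- tidy(r)
  expect_true(all(c("threshold", "fpr", "tpr") %in% names(td)))
  gl <- glance(r)
  expect_equal(gl$auc, r$auc)
  pl <- ggplot2::autoplot(r)
  expect_s3_class(pl, "ggplot")
  co <- small_cohort()
  expect_equal(glance(co)$n_subjects, 24L)
  expect_s3_class(plot_dip_by_genotype(co$subjects, co$genotypes,
                                       "rs3821169"), "ggplot")
})
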