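test_that("adjusted regression matches the normal-equations oracle", {
  # 8-subject worked dataset
  dip <- c(90, 75, 60, 30, 85, 50, 20, 95)
  g <- c(0, 1, 1, 2, 0, 1, 2, 0)
  age <- c(5, 7, 9, 4, 6, 8, 10, 3)
  sex <- c("male", "female", "male", "male", "female", "female", "male",
           "female")
  r <- adjusted_regression(dip, g, age, sex)
  o <- ols_oracle(dip, cbind(1, age, as.numeric(sex == "male"), g))
  expect_equal(r$beta, unname(o$beta[4]))
  expect_equal(r$se, unname(o$se[4]))
  expect_equal(r$p_value, unname(o$p[4]))
  expect_equal(r$n_used, 8L)
})

test_that("noise-free recessive construction recovers beta = -21.09 exactly", {
  withr::with_seed(5, {
    g2 <- rbinom(60, 1, 0.2)
    age <- runif(60, 3, 12)
    sex <- sample(c("male", "female"), 60, replace = TRUE)
    dip <- 70 - 21.09 * g2 + 0 * age
    r <- adjusted_regression(dip, g2, age, sex)
    expect_equal(r$beta, -21.09)
    expect_lt(r$p_value, 1e-12)
  })
})

test_that("constant covariates reduce to the simple regression", {
  withr::with_seed(6, {
    g <- rbinom(50, 2, 0.3)
    dip <- 65 - 5 * g + rnorm(50, 0, 10)
    r <- adjusted_regression(dip, g, age = rep(7, 50), sex = rep("male", 50))
    f <- summary(lm(dip ~ g))
    expect_equal(r$beta, unname(coef(f)[2, 1]))
    expect_equal(r$p_value, unname(coef(f)[2, 4]))
  })
})

test_that("null genotypes give small beta and calibrated p-values", {
  withr::with_seed(7, {
    ps <- replicate(200, {
      n <- 150
      dip <- rnorm(n, 65, 25)
      g <- rbinom(n, 2, 0.3)
      adjusted_regression(dip, g, runif(n, 3, 12),
                          sample(c("male", "female"), n, TRUE))$p_value
    })
    expect_lt(abs(mean(ps < 0.1) - 0.1), 3 * sqrt(0.1 * 0.9 / 200))
  })
})

test_that("degenerate codings are flagged not applicable", {
  r <- adjusted_regression(c(50, 60, 70, 80, 90), rep(0, 5), 1:5,
                           rep("male", 5))
  expect_false(r$applicable)
  # recessive with no homozygote
  g <- c(0L, 1L, 1L, 0L, 1L, 0L)
  r2 <- adjusted_regression(runif(6, 40, 90), code_genotype(g, "recessive"),
                            1:6, rep(c("male", "female"), 3))
  expect_false(r2$applicable)
})

test_that("genetic model codings follow their definitions", {
  g <- c(0L, 1L, 2L, NA)
  expect_equal(code_genotype(g, "additive"), c(0, 1, 2, NA))
  expect_equal(code_genotype(g, "dominant"), c(0, 1, 1, NA))
  expect_equal(code_genotype(g, "recessive"), c(0, 0, 1, NA))
})

test_that("one-way ANOVA matches the sums-of-squares decomposition", {
  dip <- c(80, 75, 90, 60, 55, 65, 30, 25)
  g <- c(0, 0, 0, 1, 1, 1, 2, 2)
  a <- anova_by_genotype(dip, g)
  grand <- mean(dip)
  ssb <- sum(tapply(dip, g, function(x) length(x) * (mean(x) - grand)^2))
  ssw <- sum(tapply(dip, g, function(x) sum((x - mean(x))^2)))
  f_oracle <- (ssb / 2) / (ssw / 5)
  expect_equal(a$statistic, f_oracle)
  expect_equal(a$p_value, pf(f_oracle, 2, 5, lower.tail = FALSE))

  # two groups: F = t^2 and p equals the equal-variance t-test
  dip2 <- c(80, 75, 90, 62, 55, 65, 58)
  g2 <- c(0, 0, 0, 1, 1, 1, 1)
  a2 <- anova_by_genotype(dip2, g2)
  tt <- t.test(dip2[g2 == 0], dip2[g2 == 1], var.equal = TRUE)
  expect_equal(a2$statistic, unname(tt$statistic^2))
  expect_equal(a2$p_value, tt$p.value)

  # equal group means -> F = 0, p = 1
  a3 <- anova_by_genotype(c(50, 70, 50, 70, 50, 70), c(0, 0, 1, 1, 2, 2))
  expect_equal(a3$statistic, 0)
  expect_equal(a3$p_value, 1)

  expect_false(anova_by_genotype(c(1, 2, 3), c(0, 0, 0))$applicable)
})

test_that("Fisher 2x2 agrees with hypergeometric enumeration", {
  expect_equal(fisher_2x2(matrix(c(1, 1, 1, 1), 2)), 1)
  expect_equal(fisher_2x2(matrix(c(5, 0, 0, 5), 2)), 2 / choose(10, 5))
  expect_equal(fisher_2x2(matrix(c(0, 0, 3, 4), 2)), 1) # zero margin
  withr::with_seed(21, {
    for (i in 1:30) {
      tbl <- matrix(rpois(4, sample(1:8, 1)), 2)
      expect_equal(fisher_2x2(tbl), fisher_enum_oracle(tbl), tolerance = 1e-10)
      # row-swap symmetry
      expect_equal(fisher_2x2(tbl), fisher_2x2(tbl[2:1, ]))
    }
  })
})

test_that("Cochran-Armitage trend test matches the score formula", {
  # equal case fractions -> statistic 0, p = 1
  r0 <- cochran_armitage_trend(matrix(c(10, 20, 5, 10, 4, 8), 2))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  tbl <- matrix(c(5, 30, 12, 25, 9, 6), 2) # cases row 1, genotypes 0/1/2
  r <- cochran_armitage_trend(tbl)
  w <- 0:2; n_i <- colSums(tbl); r_i <- tbl[1, ]
  N <- sum(n_i); p <- sum(r_i) / N
  z_oracle <- (sum(w * r_i) - p * sum(w * n_i)) /
    sqrt(p * (1 - p) * (sum(w^2 * n_i) - sum(w * n_i)^2 / N))
  expect_equal(r$statistic, z_oracle)
  expect_equal(r$p_value, 2 * pnorm(-abs(z_oracle)))

  # the squared statistic equals the classic trend chi-square
  pt <- prop.trend.test(tbl[1, ], colSums(tbl), score = 0:2)
  expect_equal(r$statistic^2, unname(pt$statistic))

  # swapping rows flips only the sign
  r_swap <- cochran_armitage_trend(tbl[2:1, ])
  expect_equal(r_swap$statistic, -r$statistic)
  expect_equal(r_swap$p_value, r$p_value)

  # monotone enrichment of cases with genotype: positive statistic
  r_mono <- cochran_armitage_trend(matrix(c(2, 40, 10, 30, 20, 10), 2))
  expect_gt(r_mono$statistic, 0)
  expect_lt(pnorm(-r_mono$statistic), 0.5)

  # zero case margin -> not applicable
  expect_false(cochran_armitage_trend(matrix(c(0, 5, 0, 5, 0, 5), 2))$applicable)
})

test_that("DIP groups are nested with the printed boundary semantics", {
  subj <- tibble::tibble(subject_id = paste0("s", 1:8),
                         dip = c(120, 70.5, 70, 60, 45, 25, 15, 14.9))
  gr <- dip_groups(subj)
  member <- function(g) gr$subject_id[gr$group == g]
  expect_setequal(member("G0"), c("s1", "s2"))   # dip > 70
  expect_true("s3" %in% member("G1"))            # 70 is <= 70
  expect_false("s3" %in% member("G0"))
  expect_true("s7" %in% member("G5"))            # 15 <= 25
  expect_false("s7" %in% member("G6"))           # G6 strict < 15
  expect_true("s8" %in% member("G6"))
  # nesting G1 >= G2 >= ... >= G6
  sizes <- sapply(paste0("G", 1:6), function(g) length(member(g)))
  expect_true(all(diff(sizes) <= 0))
  # G0 and G1 partition the cohort
  expect_equal(length(member("G0")) + length(member("G1")), nrow(subj))
})

test_that("discovery screen finds a strong deleterious variant and respects p_max", {
  # plant a variant with a clear additive effect so the additive-model
  # screen has high power at n = 240
  vs <- default_variant_specs()
  vs$effect_model[vs$variant_id == "rs3821169"] <- "additive"
  co <- simulate_cohort(sim_config(seed = 77, n_subjects = 240,
                                   discovery_fraction = 1,
                                   variant_specs = vs))
  functional <- filter_functional(co$variants)
  cand <- suppressMessages(discovery_screen(functional, co$genotypes,
                                            co$subjects))
  expect_true("rs3821169" %in% cand$variant_id)
  screen <- attr(cand, "screen")
  expect_equal(nrow(screen), nrow(functional))
  # every candidate passed both gates
  expect_true(all(cand$p_value < 0.01))
  expect_true(all(cand$sift <= 0.05 & cand$cadd >= 25))

  empty <- suppressMessages(discovery_screen(functional, co$genotypes,
                                             co$subjects, p_max = 0))
  expect_equal(nrow(empty), 0L)
  none <- discovery_screen(functional, co$genotypes, co$subjects[0, ])
  expect_equal(nrow(none), 0L)
})

test_that("replication tests additive and recessive models per candidate", {
  co <- simulate_cohort(sim_config(seed = 13, n_subjects = 120,
                                   discovery_fraction = 0))
  cand <- tibble::tibble(variant_id = c("rs3821169", "rs746000108",
                                        "absent_variant"))
  rep <- replicate_candidates(cand, co$genotypes, co$subjects, p_max = 0.05)
  expect_equal(nrow(rep), 3L)
  crim <- rep[rep$variant_id == "rs3821169", ]
  expect_true(crim$recessive_applicable)
  expect_false(rep$replicated[rep$variant_id == "absent_variant"])
  # rare variant: no homozygote in 120 subjects -> recessive not applicable
  rare <- rep[rep$variant_id == "rs746000108", ]
  expect_false(rare$recessive_applicable)
  # p_max = 1 replicates every applicable candidate
  rep_all <- replicate_candidates(cand[1:2, ], co$genotypes, co$subjects,
                                  p_max = 1)
  applicable <- !is.na(rep_all$p_additive) | rep_all$recessive_applicable
  expect_true(all(rep_all$replicated[applicable]))
})
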