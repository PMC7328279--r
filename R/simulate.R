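#' Default variant panel for the synthetic cohort
#'
#' Twelve exome-screen candidate variants — the replicated CRIM1 rs3821169
#' (EAS T allele frequency 0.255, SIFT 0, CADD 25.3, recessive effect of
#' -21.09 DIP units in homozygotes) and eleven non-replicated candidates
#' carried at their reported East-Asian frequencies with null phenotype
#' effects — plus a handful of benign variants (synonymous, intronic, or
#' SIFT-tolerated) that exercise the consequence and deleteriousness
#' filters. Coordinates are representative.
#'
#' @return Tibble: `variant_id`, `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `consequence`, `sift`, `cadd`, `af`, `effect_model`, `effect_size`.
#' @export
default_variant_specs <- function() {
  tribble(
    ~variant_id,    ~chrom, ~pos,      ~ref, ~alt, ~gene,      ~consequence, ~sift, ~cadd, ~af,      ~effect_model, ~effect_size,
    "rs3821169",    "2",    36583758,  "C",  "T",  "CRIM1",    "missense",   0,     25.3,  0.255,    "recessive",   -21.09,
    "rs191083003",  "2",    186624000, "C",  "T",  "FSIP2",    "missense",   0.01,  26.7,  0.00346,  "null",        0,
    "rs67877771",   "3",    197717000, "A",  "G",  "IQCG",     "missense",   0.04,  26.2,  0.2155,   "null",        0,
    "rs200125400",  "5",    132370000, "G",  "A",  "SLC22A5",  "missense",   0,     32,    0.00239,  "null",        0,
    "rs141145196",  "8",    144400000, "G",  "A",  "TOP1MT",   "missense",   0.03,  27.1,  0.00476,  "null",        0,
    "rs61758536",   "9",    35810000,  "G",  "A",  "SPAG8",    "missense",   0,     26,    0.0522,   "null",        0,
    "rs181036640",  "9",    137100000, "G",  "A",  "DPP7",     "missense",   0,     28.7,  0.01,     "null",        0,
    "rs34337292",   "11",   57967000,  "G",  "C",  "OR9Q2",    "missense",   0,     25.9,  0.0684,   "null",        0,
    "rs200982819",  "11",   60972000,  "G",  "A",  "SLC15A3",  "missense",   0,     29.7,  0.028,    "null",        0,
    "rs144612495",  "12",   133030000, "C",  "T",  "GOLGA3",   "missense",   0.02,  25.7,  0.004,    "null",        0,
    "rs12587478",   "14",   20900000,  "G",  "T",  "KLHL33",   "missense",   0,     25,    0.0591,   "null",        0,
    "rs746000108",  "19",   7150000,   "C",  "T",  "INSR",     "missense",   0.01,  25,    0.000501, "null",        0,
    "syn_fsip2_1",  "2",    186625100, "T",  "C",  "FSIP2",    "synonymous", NA,    3.2,   0.30,     "null",        0,
    "mis_iqcg_1",   "3",    197718200, "C",  "G",  "IQCG",     "missense",   0.75,  8.9,   0.12,     "null",        0,
    "int_spag8_1",  "9",    35811500,  "A",  "T",  "SPAG8",    "intronic",   NA,    1.1,   0.22,     "null",        0,
    "mis_or9q2_1",  "11",   57967900,  "A",  "G",  "OR9Q2",    "missense",   0.4,   12,    0.09,     "null",        0
  )
}

#' Default star-allele defining variants
#'
#' One representative defining coding variant per no-function star allele of
#' NUDT15 and TPMT, used to translate simulated diplotypes into genotype
#' calls so that star-allele phenotyping and GVB scoring see a coherent
#' subject. The `effect_size` is the additive DIP shift per no-function
#' allele copy. These are synthetic stand-ins for unreleased study
#' genotypes; rsIDs and scores are representative, not authoritative.
#'
#' @return Tibble: `gene`, `allele`, `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `consequence`, `sift`, `cadd`, `effect_size`.
#' @export
default_star_variant_defs <- function() {
  tribble(
    ~gene,     ~allele, ~variant_id,   ~chrom, ~pos,     ~ref, ~alt, ~consequence, ~sift, ~cadd, ~effect_size,
    "NUDT15",  "*2",    "rs116855232", "13",   48045719, "C",  "T",  "missense",   0.001, 25.4,  -17,
    "NUDT15",  "*3",    "rs147390019", "13",   48037782, "G",  "A",  "missense",   0.01,  24.1,  -17,
    "NUDT15",  "*9",    "rs780144127", "13",   48037748, "A",  "G",  "missense",   0.02,  23.0,  -17,
    "TPMT",    "*2",    "rs1800462",   "6",    18143955, "C",  "G",  "missense",   0.01,  24.0,  -14,
    "TPMT",    "*3A",   "rs1800460",   "6",    18139228, "C",  "T",  "missense",   0.01,  25.0,  -14,
    "TPMT",    "*3C",   "rs1142345",   "6",    18130918, "T",  "C",  "missense",   0.02,  23.6,  -14
  )
}

#' Simulation configuration
#'
#' Defines the cohort-generating conditions: Hardy-Weinberg genotypes at the
#' panel allele frequencies, a Gaussian DIP model with per-variant genetic
#' effects (truncated below at 0, no upper cap), covariates, and star-allele
#' diplotype frequencies for NUDT15 and TPMT. The defaults emulate the
#' target study design: 320 East-Asian pediatric ALL subjects split 244/76
#' into discovery and replication cohorts, noncarrier DIP baseline
#' 71.99 +/- 27.0, age 7.0 +/- 4.5 years, and star-allele frequencies giving
#' an expected ~25% minority of non-normal metabolizers.
#'
#' @param n_subjects Cohort size (>= 2), default 320.
#' @param discovery_fraction Fraction assigned the discovery label.
#' @param seed Integer seed; every stochastic operation derives from it.
#' @param variant_specs Variant panel (see [default_variant_specs()]).
#' @param star_variant_defs Star-allele defining variants
#'   (see [default_star_variant_defs()]).
#' @param star_allele_freqs Named list (per gene) of named allele-frequency
#'   vectors, each summing to 1.
#' @param dip_baseline_mean,dip_baseline_sd DIP baseline (%) and residual SD.
#' @param age_mean,age_sd Age distribution (years).
#' @param male_fraction Bernoulli probability of male sex (coded male = 1).
#' @param age_effect,sex_effect DIP units per year of age / for male sex.
#' @param missing_rate Fraction of genotype calls set missing, default 0.
#' @return A validated `gvb_sim_config` list.
#' @export
sim_config <- function(n_subjects = 320L,
                       discovery_fraction = 244 / 320,
                       seed = 1L,
                       variant_specs = default_variant_specs(),
                       star_variant_defs = default_star_variant_defs(),
                       star_allele_freqs = list(
                         NUDT15 = c("*1" = 0.88, "*2" = 0.055,
                                    "*3" = 0.045, "*9" = 0.02),
                         TPMT = c("*1" = 0.98, "*3C" = 0.02)
                       ),
                       dip_baseline_mean = 71.99,
                       dip_baseline_sd = 27.0,
                       age_mean = 7.0, age_sd = 4.5,
                       male_fraction = 137 / 240,
                       age_effect = 0, sex_effect = 0,
                       missing_rate = 0) {
  if (n_subjects < 2L) abort("n_subjects must be >= 2", class = "gvb_config_error")
  if (dip_baseline_sd <= 0) abort("dip_baseline_sd must be > 0",
                                  class = "gvb_config_error")
  assert_prob(variant_specs$af, "variant allele frequency")
  assert_prob(c(male_fraction, missing_rate, discovery_fraction), "fraction")
  for (g in names(star_allele_freqs)) {
    fr <- star_allele_freqs[[g]]
    assert_prob(fr, sprintf("star-allele frequency (%s)", g))
    if (abs(sum(fr) - 1) > 1e-8) {
      abort(sprintf("star-allele frequencies for %s must sum to 1", g),
            class = "gvb_config_error")
    }
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         discovery_fraction = discovery_fraction, seed = seed,
         variant_specs = variant_specs,
         star_variant_defs = star_variant_defs,
         star_allele_freqs = star_allele_freqs,
         dip_baseline_mean = dip_baseline_mean,
         dip_baseline_sd = dip_baseline_sd,
         age_mean = age_mean, age_sd = age_sd,
         male_fraction = male_fraction,
         age_effect = age_effect, sex_effect = sex_effect,
         missing_rate = missing_rate),
    class = "gvb_sim_config"
  )
}

.with_optional_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

.subject_ids <- function(n) sprintf("S%04d", seq_len(n))

#' Simulate Hardy-Weinberg genotypes
#'
#' Draws each variant's genotypes independently as Binomial(2, af) — the
#' Hardy-Weinberg proportions — with no linkage disequilibrium.
#'
#' @param config A [sim_config()].
#' @param seed Seed (default the config's); `NULL` uses the current RNG
#'   stream.
#' @return Wide tibble: `subject_id` plus one integer column per variant.
#' @export
simulate_genotypes <- function(config, seed = config$seed) {
  spec <- config$variant_specs
  assert_prob(spec$af, "allele frequency")
  n <- config$n_subjects
  .with_optional_seed(seed, {
    g <- vapply(spec$af, function(p) rbinom(n, 2L, p), integer(n))
    colnames(g) <- spec$variant_id
    bind_cols(tibble(subject_id = .subject_ids(n)), as_tibble(g))
  })
}

#' Simulate star-allele diplotypes
#'
#' Draws two alleles per gene per subject independently from the configured
#' allele frequencies. Allele names must exist in the function table.
#'
#' @param config A [sim_config()].
#' @param fn_table Star-allele function table used to validate allele names.
#' @param seed Seed (default the config's).
#' @return Tibble: `subject_id`, `gene`, `allele1`, `allele2`.
#' @export
simulate_diplotypes <- function(config, fn_table = allele_function_table(),
                                seed = config$seed) {
  n <- config$n_subjects
  ids <- .subject_ids(n)
  for (g in names(config$star_allele_freqs)) {
    al <- names(config$star_allele_freqs[[g]])
    known <- fn_table$allele[fn_table$gene == g]
    bad <- setdiff(al, known)
    if (length(bad) > 0L) {
      abort(sprintf("allele(s) %s of gene %s absent from the function table",
                    paste(bad, collapse = ", "), g),
            class = "gvb_config_error")
    }
  }
  .with_optional_seed(seed, {
    rows <- imap(config$star_allele_freqs, function(fr, g) {
      a1 <- sample(names(fr), n, replace = TRUE, prob = fr)
      a2 <- sample(names(fr), n, replace = TRUE, prob = fr)
      tibble(subject_id = ids, gene = g, allele1 = a1, allele2 = a2)
    })
    list_rbind(unname(rows)) |> arrange(.data$subject_id, .data$gene)
  })
}

# Translate diplotypes into genotype calls at the star-defining variants.
star_genotypes <- function(diplotypes, star_defs, subject_ids) {
  out <- tibble(subject_id = subject_ids)
  for (i in seq_len(nrow(star_defs))) {
    d <- diplotypes[diplotypes$gene == star_defs$gene[i], ]
    d <- d[match(subject_ids, d$subject_id), ]
    out[[star_defs$variant_id[i]]] <-
      (d$allele1 == star_defs$allele[i]) + (d$allele2 == star_defs$allele[i])
  }
  out
}

# Per-variant effect table over all simulated variants (panel + star).
.effect_table <- function(config) {
  bind_rows(
    config$variant_specs |>
      select("variant_id", "effect_model", "effect_size"),
    config$star_variant_defs |>
      transmute(variant_id = .data$variant_id, effect_model = "additive",
                effect_size = .data$effect_size)
  )
}

#' Simulate the DIP phenotype
#'
#' DIP = baseline + age_effect * age + sex_effect * male + sum of per-variant
#' genetic effects + Gaussian noise, truncated below at 0 (the observed
#' scale has no upper cap). Each variant's contribution uses its configured
#' effect model: additive (0/1/2 copies), dominant (carrier), recessive
#' (homozygote only), or null. Missing genotypes contribute nothing.
#'
#' @param genotypes Wide genotype tibble (`subject_id` + variant columns).
#' @param covariates Tibble: `subject_id`, `age`, `sex`.
#' @param config A [sim_config()].
#' @param seed Seed (default the config's).
#' @return Tibble: `subject_id`, `dip`.
#' @export
simulate_dip <- function(genotypes, covariates, config, seed = config$seed) {
  if (!identical(sort(genotypes$subject_id), sort(covariates$subject_id))) {
    abort("genotype and covariate tables must cover the same subjects",
          class = "gvb_alignment_error")
  }
  covariates <- covariates[match(genotypes$subject_id, covariates$subject_id), ]
  eff <- .effect_table(config)
  eff <- eff[eff$variant_id %in% names(genotypes) & eff$effect_model != "null" &
               eff$effect_size != 0, ]
  n <- nrow(genotypes)
  genetic <- rep(0, n)
  for (i in seq_len(nrow(eff))) {
    g <- genotypes[[eff$variant_id[i]]]
    code <- code_genotype(g, eff$effect_model[i])
    code[is.na(code)] <- 0
    genetic <- genetic + eff$effect_size[i] * code
  }
  male <- as.numeric(covariates$sex == "male")
  .with_optional_seed(seed, {
    dip <- config$dip_baseline_mean +
      config$age_effect * covariates$age + config$sex_effect * male +
      genetic + rnorm(n, 0, config$dip_baseline_sd)
    tibble(subject_id = genotypes$subject_id, dip = pmax(dip, 0))
  })
}

#' Simulate a full synthetic cohort
#'
#' Generates subjects (age, sex, cohort label), star-allele diplotypes,
#' Hardy-Weinberg genotypes at the variant panel, genotype calls at the
#' star-defining variants consistent with the diplotypes, and the DIP
#' phenotype, all from a single seed.
#'
#' @param config A [sim_config()].
#' @param fn_table Star-allele function table for diplotype validation.
#' @return A `gvb_cohort` object: list with tibbles `subjects`, `variants`,
#'   `genotypes`, `diplotypes`, and `truth` (the effect parameters used).
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 40, seed = 7))
#' cohort
simulate_cohort <- function(config = sim_config(),
                            fn_table = allele_function_table()) {
  n <- config$n_subjects
  ids <- .subject_ids(n)
  withr::with_seed(config$seed, {
    n_disc <- round(n * config$discovery_fraction)
    subjects <- tibble(
      subject_id = ids,
      age = pmax(rnorm(n, config$age_mean, config$age_sd), 0.1),
      sex = ifelse(rbinom(n, 1L, config$male_fraction) == 1L, "male", "female"),
      cohort = rep(c("discovery", "replication"), c(n_disc, n - n_disc))
    )
    diplotypes <- simulate_diplotypes(config, fn_table, seed = NULL)
    genotypes <- simulate_genotypes(config, seed = NULL)
    genotypes <- left_join(genotypes,
                           star_genotypes(diplotypes,
                                          config$star_variant_defs, ids),
                           by = "subject_id")
    dip <- simulate_dip(genotypes, subjects, config, seed = NULL)
    subjects <- left_join(subjects, dip, by = "subject_id")
    if (config$missing_rate > 0) {
      vcols <- setdiff(names(genotypes), "subject_id")
      for (v in vcols) {
        miss <- runif(n) < config$missing_rate
        genotypes[[v]][miss] <- NA_integer_
      }
    }
    variants <- bind_rows(
      config$variant_specs |>
        select("variant_id", "chrom", "pos", "ref", "alt", "gene",
               "consequence", "sift", "cadd"),
      config$star_variant_defs |>
        select("variant_id", "chrom", "pos", "ref", "alt", "gene",
               "consequence", "sift", "cadd")
    )
    structure(
      list(subjects = subjects, variants = variants, genotypes = genotypes,
           diplotypes = diplotypes, truth = .effect_table(config)),
      class = "gvb_cohort"
    )
  })
}

#' @export
print.gvb_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects (%d discovery / %d replication), %d variants\n",
              nrow(x$subjects), sum(x$subjects$cohort == "discovery"),
              sum(x$subjects$cohort == "replication"), nrow(x$variants)))
  cat(sprintf("DIP: mean %.1f, sd %.1f\n",
              mean(x$subjects$dip), stats::sd(x$subjects$dip)))
  invisible(x)
}
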