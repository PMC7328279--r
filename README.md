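# gvburden

Pharmacogenomic prediction of thiopurine (6-mercaptopurine, 6-MP) toxicity
in pediatric acute lymphoblastic leukemia (ALL). During maintenance therapy
the tolerated 6-MP **dose intensity percentage (DIP)** — the administered
dose as a percentage of the protocol-planned dose over the last 12-week
cycle — is the clinical toxicity endpoint: a low DIP means the patient could
not tolerate the drug. The established genetic determinants are no-function
star alleles of *NUDT15* and *TPMT*, but many patients carrying wild-type
alleles of both genes still develop severe toxicity. This package implements
a quantitative, multigene alternative to categorical star-allele testing and
the full discovery/replication analysis around it, for statistical
geneticists and pharmacogenomics researchers.

## The gene-wise variant burden (GVB) score

For one individual and one gene *G*, with carried coding variants
*v₁, …, vₖ* whose SIFT scores satisfy *sᵢ* < 0.7,

```
GVB^G = ( ∏ᵢ max(sᵢ, 0.001) )^(1/k),        GVB^G = 1 if k = 0
```

i.e. the geometric mean of the SIFT scores of the carried deleterious
variants (SIFT is 0 for fully intolerant substitutions, hence the floor).
Scores live in (0, 1]; lower = higher predicted burden. Multigene scores
compose by a further geometric mean, e.g.
`GVB^{A,B} = sqrt(GVB^A · GVB^B)`. A designated common variant with a
recessive phenotype (default *CRIM1* rs3821169, East-Asian T allele
frequency 0.255) is **recessively masked**: heterozygotes contribute
nothing, only homozygotes count.

Around this core the package provides:

- **Synthetic cohorts** (`sim_config()`, `simulate_cohort()`,
  `write_cohort()`): Hardy–Weinberg genotypes, star-allele diplotypes, and
  a Gaussian DIP model with additive/dominant/recessive per-variant
  effects, emulating the statistical structure of a 320-subject
  discovery/replication study.
- **Variant IO and filtering** (`read_annotated_vcf()`,
  `filter_functional()`, `filter_deleterious()`): VCF 4.2 with
  GENE/CSQ/SIFT/CADD annotations; strong-effect consequence classes;
  SIFT ≤ 0.05 ∧ CADD ≥ 25.
- **Association testing** (`adjusted_regression()`, `assoc_scan()`,
  `discovery_screen()`, `replicate_candidates()`, `anova_by_genotype()`,
  `fisher_2x2()`, `cochran_armitage_trend()`, `dip_groups()`): age- and
  sex-adjusted linear models of DIP under additive/dominant/recessive
  codings, the p < 0.01 discovery → p < 0.05 replication funnel, and the
  categorical group analyses.
- **Star-allele phenotyping** (`assign_phenotype()`, `combined_risk()`,
  `select_both_wt()`): CPIC-style NM/IM/PM calls and the both-wildtype
  analysis subset.
- **Classifier evaluation** (`confusion_metrics()`, `roc_auc()`,
  `youden_cutoff()`, `compare_models()`, `single_gene_contribution()`):
  confusion-matrix metrics, tie-corrected Mann–Whitney AUC with stratified
  bootstrap CIs, Youden-optimal GVB cutoffs, and the star-allele vs GVB
  comparison across seven DIP cutoffs.
- **Orchestration** (`run_config()`, `run_pipeline()`): a seeded,
  manifest-writing end-to-end run.

## Worked example

```r
library(gvburden)
library(dplyr)

cohort <- simulate_cohort(sim_config(seed = 1))
glance(cohort)
#>   n_subjects n_discovery n_replication n_variants dip_mean dip_sd
#> 1        320         244            76         22     64.0   28.1

risk     <- combined_risk(assign_phenotype(cohort$diplotypes))
profiles <- profile_cohort(cohort$variants, cohort$genotypes)

compare_models(cohort$subjects, profiles, risk, dip_cutoff = 25,
               boot_n = 500, seed = 1) |>
  filter(cohort == "combined") |>
  select(predictor, threshold, sensitivity, specificity, accuracy, auc)
#>   predictor                  threshold sensitivity specificity accuracy   auc
#> 1 CPIC NUDT15/TPMT metabol…     NA           0.577       0.755    0.741 0.666
#> 2 GVB NUDT15,TPMT                0.141       0.577       0.755    0.741 0.658
#> 3 GVB NUDT15,TPMT,CRIM1          0.271       0.769       0.718    0.722 0.757
```

Reading the output: the condition is intolerance (DIP ≤ 25%); each
predictor flags subjects as at-risk (PM+IM metabolizer class, or GVB at or
below its Youden-optimal cutoff). On this simulated cohort the three-gene
burden score ranks intolerant subjects better than the two-gene score or
the categorical star-allele classes (AUC 0.757 vs 0.658/0.666) and finds
more of them (sensitivity 0.769 vs 0.577) — the behavior the score was
designed for: homozygotes of the masked *CRIM1* variant carry real risk
that two-gene testing cannot see. The recessive effect itself is recovered
by the adjusted regression:

```r
code <- code_genotype(cohort$genotypes$rs3821169, "recessive")
adjusted_regression(cohort$subjects$dip, code,
                    cohort$subjects$age, cohort$subjects$sex)
#>    beta    se   p_value n_used applicable
#>   -26.1  6.08 0.0000233    320 TRUE
```

a β̂ of −26.1 DIP units (simulated truth: −21.09, well within 2 SE).

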