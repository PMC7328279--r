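---
title: "Gene-wise variant burden scoring and multigene thiopurine toxicity prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-wise variant burden scoring and multigene thiopurine toxicity prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gvburden)
```

## The clinical problem

6-mercaptopurine (6-MP) is the backbone of maintenance chemotherapy in
pediatric acute lymphoblastic leukemia. Its hematological toxicity is
strongly genetic: no-function star alleles of *NUDT15* and *TPMT* force
dose reductions, and CPIC guidelines translate star-allele diplotypes into
categorical metabolizer phenotypes (normal, intermediate, poor: NM/IM/PM)
that guide dosing. The phenotype this package models is the **dose
intensity percentage (DIP)**: the 6-MP dose a patient actually tolerated
over the last 12-week maintenance cycle, as a percentage of the
protocol-planned dose. Low DIP = intolerance; DIP ≤ 25% is the usual
high-risk definition in East-Asian cohorts. The package's purpose is to
(i) score per-gene variant burden quantitatively instead of categorically,
(ii) screen coding variants for association with DIP in patients who are
wild type for both established genes, and (iii) evaluate single- and
multigene classifiers of intolerance systematically.

## The GVB model

For one individual and one gene, the gene-wise variant burden is the
geometric mean of the SIFT scores of the coding variants the individual
carries, restricted to SIFT < 0.7 (strict, as the inclusion rule is
printed in the pharmacogenomics literature this score comes from). An
individual with no qualifying variant scores exactly 1. Multigene scores
are geometric means of gene scores, so composition is associative and a
singleton set is the identity. Two numerical conventions matter:

- **SIFT = 0 floor.** Fully intolerant substitutions have SIFT exactly 0,
  and a literal geometric mean would collapse every carrier's score to 0,
  erasing the ordering among carriers and breaking any threshold rule.
  Scores are floored at 0.001 before averaging. The value is this
  package's documented choice; it keeps a single fully-deleterious variant
  (score 0.001) clearly below the clinically used cutoffs (≈0.3–0.45 on
  the multigene scale) while preserving strict monotonicity.
- **Recessive masking.** A common variant whose phenotype is recessive
  (default *CRIM1* rs3821169; ~47% of East Asians carry at least one T
  allele) would otherwise push nearly half the cohort's gene score down
  and destroy specificity. Masked variants contribute only when
  homozygous; heterozygous calls are ignored entirely, so toggling a
  masked genotype between 0 and 1 provably changes no score.

Zygosity is otherwise ignored: a carried site contributes its SIFT score
once whether heterozygous or homozygous. The source definition counts
"variants in the gene" without dosage weighting and gives no basis for
double-counting; `gvb_config(count_homozygous_twice = TRUE)` exposes the
alternative for sensitivity analyses.

## Association testing

The screen regresses DIP on a coded genotype with age and sex as
covariates, by ordinary least squares; the test is the two-sided t-test on
the genotype coefficient. Codings: additive 0/1/2, dominant carrier,
recessive homozygote. Conventions, each chosen once:

- Complete-case per variant: subjects missing a genotype are dropped for
  that variant only, and `n_used` reports the remainder. Imputation is out
  of scope.
- A coding that is constant after the drop (e.g. recessive with no
  homozygote) is reported `applicable = FALSE` rather than an error or a
  fabricated p-value — small replication cohorts routinely lack
  homozygotes at rare variants.
- The discovery funnel is: strong-effect consequences (missense, nonsense,
  splice-site, frameshift, in-frame indel) → additive-model p < 0.01 →
  SIFT ≤ 0.05 ∧ CADD ≥ 25 (boundaries inclusive as printed). No
  multiple-testing correction is applied at discovery: the design
  deliberately trades a lenient p cutoff plus orthogonal in-silico
  deleteriousness evidence plus independent replication (any applicable
  model p < 0.05) against full multiplicity control, which the sample
  sizes cannot support.
- Fisher's exact test uses the standard two-sided convention (sum of
  hypergeometric probabilities no larger than the observed table's); a
  zero margin returns p = 1. The Cochran–Armitage trend test is the
  classic score form with weights 0/1/2 and no continuity correction,
  referred to the standard normal. Both are oracle-tested against full
  enumeration / the direct formula.
- The DIP severity groups are nested, not a partition: G0 is DIP > 70%,
  G1..G5 are ≤ 70/60/45/35/25%, and G6 alone is strict < 15%. A DIP of
  exactly 15 therefore belongs to G1–G5 but not G6, and a DIP of exactly
  70 to G1 but not G0.

## Classifier evaluation

GVB is a lower-is-worse score, so ROC analysis orients risk as the
negative score; the condition is DIP ≤ cutoff and test positivity is score
≤ threshold (inclusive, matching how the clinical tables print "≤ 0.3"
risk rows). The AUC is the tie-corrected Mann–Whitney statistic — exactly
the probability that a random intolerant subject has higher risk than a
random tolerant one, ties counting half — computed from rank sums and
verified against all-pairs counting. Confidence intervals are stratified
bootstrap percentile intervals (cases and controls resampled separately,
2000 resamples, seeded); the interval method is this package's choice, as
the clinical tables print CIs without naming one. Youden's J is maximized
over the observed scores; ties break toward the threshold classifying more
subjects as positive, the conservative direction for a toxicity screen.
Metric displays round half-up at 3 decimals, matching the tables'
precision; raw values are retained everywhere internally. The evaluation
module applies "≤ cutoff" uniformly across its seven DIP cutoffs
(15–100%); the strict "< 15" boundary exists only in the association
module's G6 group, where it is printed that way.

The single-gene analysis measures each gene's contribution after removing
the others' signal by subsetting rather than modelling: *CRIM1* is
evaluated in both-wildtype (*NUDT15* and *TPMT* NM) subjects; *NUDT15* in
TPMT-wildtype subjects who are not homozygous for the masked *CRIM1*
variant; *TPMT* symmetrically.

## What the synthetic cohort emulates

No patient-level data accompany the study design this package analyzes
("available by request" only), so the generator is a first-class module
that reproduces the *statistical structure* the analysis assumes, with
defaults fixed once from the published summary statistics:

- 320 subjects split 244/76 into discovery and replication; age
  7.0 ± 4.5 years; male fraction 137/240.
- DIP = 71.99 + genetic effects + N(0, 27²), truncated below at 0 with no
  upper cap (the observed distribution has a > 100% stratum). Baseline and
  SD are the published noncarrier summary. Age and sex effects default to
  0 — the analysis adjusts for them, but no effect magnitude is published.
- *CRIM1* rs3821169 at allele frequency 0.255 (East-Asian) with a
  recessive effect of −21.09 DIP units, plus the eleven non-replicated
  screen candidates at their published East-Asian frequencies with null
  effects, plus four benign variants (synonymous/intronic/SIFT-tolerated)
  that exercise the filters.
- Star-allele frequencies NUDT15 \*1/\*2/\*3/\*9 = 0.88/0.055/0.045/0.02
  and TPMT \*1/\*3C = 0.98/0.02, chosen to be East-Asian-like and to give
  an expected ~26% of subjects carrying at least one no-function allele
  (the published cohort had 25%). Each no-function allele is tied to one
  representative defining coding variant (synthetic stand-ins for the
  unreleased genotypes) so that star-allele phenotyping and GVB scoring
  describe the same subject; the defining variants carry additive DIP
  effects of −17 (*NUDT15*) and −14 (*TPMT*) per copy, anchored to the
  published non-both-WT cohort means.
- Genotypes are drawn independently per variant under Hardy–Weinberg
  proportions; every stochastic draw descends from one seed, so a fixed
  seed reproduces the cohort bit-identically.

What the generator does **not** emulate — and therefore what passing tests
cannot show about real data: linkage disequilibrium and population
structure (variants are independent), haplotype phase (diplotypes are
drawn, not called), dosing feedback between toxicity and the recorded DIP,
missingness that depends on genotype or phenotype, and batch or
center effects between cohorts. Results on simulated cohorts validate the
machinery and its operating characteristics, not the clinical effect
sizes.

## Degenerate inputs and numerical choices

- Confusion-matrix metrics with a zero denominator are `NA` (explicitly
  undefined), never 0.
- An AUC with an empty class is an error, not 0.5; `compare_models()`
  reports `NA` for strata where a class is empty.
- Variants lacking a SIFT or CADD annotation fail the deleteriousness
  filter (logged), and carried variants without SIFT are skipped in GVB
  (logged) — a score cannot be invented for them.
- Consequence vocabularies are normalized through an editable synonym map
  (`consequence_synonyms()`), since annotation dialects differ; unknown
  terms class as `other` and are filtered out.
- Multi-allelic VCF records are decomposed before anything else; the
  genotype of a non-focal alternate allele counts 0 for the focal allele.
- Indeterminate metabolizer phenotypes (uncertain-function alleles) route
  to the PM+IM risk arm, logged — conservative toward toxicity.

## Problem sizes used by the test suite

The packaged tests exercise: distributional checks at n = 5,000–10,000
draws; parameter recovery over 200 replicates of n = 240 with 5%
homozygotes; null calibration over 200 simulated null screens of 100
variants × 188 subjects; the qualitative two- vs three-gene comparison
over 100 seeded cohorts of 320; and exact-oracle suites of 100–1,000
random instances for the GVB, ROC, Fisher and trend-test kernels. These
sizes give stable Monte-Carlo margins (3 binomial SEs on every stochastic
assertion) while keeping the whole suite around a minute on one CPU.

## Known limitations

The additive-model discovery screen has modest power against purely
recessive effects of the published magnitude (measured ≈30% at n = 240),
and a 52-subject replication cohort contains only ~3 homozygotes at allele
frequency 0.255, so single-seed screen outcomes vary; the package reports
funnel counts honestly rather than guaranteeing a rediscovery. Star-allele
*calling* from sequence is out of scope (diplotypes are inputs), as are
LD-aware burden scores, CADD-based GVB variants, and mixed-model or
kinship-corrected association.
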