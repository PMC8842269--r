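# ponvrisk

Pharmacogenetic risk analysis of postoperative nausea and vomiting (PONV).

About a third of surgical patients suffer nausea or vomiting within 24 h of
waking from anesthesia. Clinical risk scores such as the simplified Apfel
score (one point each for female sex, non-smoking status, previous PONV
history, and postoperative opioid use) guide antiemetic prophylaxis, but
their discrimination is limited. Variants in the type 3B serotonin receptor
gene (*HTR3B*) — in particular rs3782025 — modulate individual PONV
susceptibility, and genotyping medium-risk patients can sharpen the risk
stratification. `ponvrisk` implements the full analysis pipeline such a
study needs, for statisticians and pharmacogeneticists who want a tested,
reproducible reimplementation rather than a one-off script collection:

* **Genotype QC** — long-TSV and minimal-VCF readers, call rates, MAFs,
  Hardy–Weinberg testing (1-df chi-square and the exact conditional test on
  the heterozygote count, stratifiable by case/control status), and
  call-rate filtering.
* **CYP activity prediction** — star-allele diplotype assignment from an
  editable allele-definition table, additive activity scores (CYP1A2,
  CYP2B6, CYP2C19), the copy-number-aware CYP2D6 score, the combined
  CYP3A4/CYP3A5/CYP3A7 metabolizer group, the CYP2C9 reduced-allele count,
  and the ×1.5 CYP1A2 smoking-induction adjustment.
* **Genetic association** — logistic regression fitted from first
  principles by iteratively reweighted least squares, with the model

  `logit P(PONV) = β0 + β1·Gender + β2·Age + β3·PONVhistory + β4·Smoking +
  β5·Cannabis + β6·Volatile + β7·HighOpioid + β8·SurgeryType + β9·G`

  where each covariate is a dichotomized risk flag and `G` is the additive
  (0/1/2) minor-allele dosage — plus dominant/recessive/continuous
  encodings, Wald OR/CI/p, Bonferroni correction, variance inflation
  factors, and a marker-by-covariate confounding scan.
* **Haplotypes and LD** — EM haplotype-frequency estimation from unphased
  genotypes, pairwise `D`, `D′`, `r²`, greedy adjacent-`D′` block
  detection, and per-haplotype score tests of outcome association.
* **Risk modelling** — Apfel scoring, the rs3782025 genotype/age risk rule
  (`A/A = 0`, `G/G = 1`, `A/G = 1` only below age 50), genotyping models
  restricted to Apfel-category-2 women (< 50 y for Model 1, all for
  Model 2), closed-form sensitivity/specificity/accuracy, number needed to
  treat (`NNT = 1/Δrisk`), number needed to genotype (`NNG = NNT / group
  frequency`), and ROC/AUC by the Mann–Whitney statistic with DeLong or
  bootstrap intervals.
* **Synthetic cohorts** — a calibrated generator reproducing the covariate
  prevalences, allele frequencies, *HTR3B*/*HTR3A* LD blocks, and logistic
  outcome model of a 601-patient surgical cohort, so every stage is
  testable without patient data.

## Worked example

```r
library(ponvrisk)

sc <- generate_cohort(n = 3000, seed = 2026)   # synthetic study cohort
sc
#> synthetic_cohort: 3000 patients; PONV prevalence 43.5%
#> genotype_matrix: 3000 samples x 27 variants; 472 missing call(s)

compute_qc(sc$genotypes)
#> QC summary: 3000 samples, 27 variants
#>   mean sample call rate 99.42%; mean variant call rate 99.42%
#>   variants with HWE p < 0.001: 0

associate_marker("rs3782025", "occurrence", sc$cohort, sc$genotypes)
#>      marker encoding    outcome    n  maf  beta   or ci_low ci_high        p
#> 1 rs3782025 additive occurrence 2982 0.44 0.326 1.39   1.24    1.55 1.17e-08

em <- em_haplotype_frequencies(sc$genotypes, c("rs76124337", "rs3782025"))
em
#> haplotype_block rs76124337+rs3782025 : 2 loci, 2960 samples used; EM converged
#>  label      freq
#>    CAA 0.5603041
#>     -G 0.3293919
#>    CAG 0.1103041
ld_pairwise(em)        # D = 0.185, D' = 1.00, r2 = 0.63

risk_assessment(sc$cohort, sc$genotypes, model = 1)
#> genotyped 296 (flagged 201); PONV overall 51% (risk 55% / no-risk 43%)
#> ...
#> whole cohort (adjusted): AUC 0.655 [95% CI 0.636-0.674]
#> whole cohort (Apfel only): AUC 0.649 [95% CI 0.630-0.668]
```

Reading: the generator drew a cohort whose PONV prevalence (43.5%) matches
its calibration target; the covariate-adjusted additive fit recovers the
generating per-allele odds ratio of 1.40 for rs3782025 (estimate 1.39, CI
1.24–1.55); the EM re-estimates the simulated risk-haplotype frequency
(`-G`, truth 0.33) from unphased data; and genotyping Apfel-2 women under
50 nudges the whole-cohort discrimination of the adjusted category above
the plain Apfel score.

Closed-form evaluation of a published stratification works directly from
group sizes and risks:

```r
metrics_from_groups(n_risk = 51, n_norisk = 29, p_risk = 0.75, p_norisk = 0.44)
#> genotyped 80 (flagged 51); PONV overall 64% (risk 75% / no-risk 44%)
#> sensitivity 0.75  specificity 0.56  accuracy 0.68
#> NNT 3.23  NNG increased-risk 5  decreased-risk 9
```

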