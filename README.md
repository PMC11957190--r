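# mirmod

Statistical framework for identifying micro-RNAs that **modify** the
association between social adversity and post-traumatic stress symptom
severity (PTSS) in longitudinal cohort data — for biostatisticians and
psychiatric-genomics analysts working with bulk small-RNA expression and
survey phenotypes.

PTSS (the PCL-C sum of 17 symptoms, range 17-85) rises with exposure to
social adversity: cumulative trauma, financial problems, emotional
mistreatment, perceived discrimination, loneliness.  `mirmod` screens
every miRNA for a gene-environment interaction in a negative-binomial
regression,

```
log mu = a_j adv_j + b x + c (adv_j * x) + sum_{i != j} a_i adv_i,
y ~ NB(mu, theta),   Var(y) = mu + mu^2 / theta,
```

where `x` is the miRNA's log2(CPM+1) expression.  The **modulation
score** is the Wald statistic `z = c / SE(c)`: positive when higher
expression amplifies the adversity-PTSS association, negative when it
attenuates it.  Per-miRNA p-values are Benjamini-Hochberg adjusted
within each (adversity, wave-pair) screen and hits are declared at
FDR < 0.1.

Around that core the package provides outcome-distribution selection
(maximum-likelihood Poisson/gamma/NB/Weibull fits ranked by BIC, with a
bootstrap-over-individuals family comparison), a from-scratch NB-GLM
engine (IRLS + profile-likelihood dispersion, Wald and likelihood-ratio
tests, optional L1 penalty), 10-fold cross-validated Spearman model
comparison, a cross-wave rank-sum consistency test, hypergeometric
pathway enrichment over binding-score-filtered miRNA target genes, and
a synthetic cohort generator with planted effects and recorded ground
truth so every stage is testable end to end.

## Worked example

```r
library(mirmod)

cfg    <- sim_config(seed = 1)          # 600 participants, 200 miRNAs,
bundle <- gen_dataset(cfg)              # 10 planted trauma modifiers
norm   <- cpm_log_normalize(filter_low_expression(bundle$counts$wave2))
rec    <- interaction_screen(norm, bundle$phenotype, "trauma_lifetime",
                             expr_wave = 2, outcome_wave = 3)
head(significant_hits(rec)[, c("mirna_id", "estimate", "se",
                               "score", "p", "q")], 5)
#>  mirna_id estimate     se score        p        q
#>  mir_0001    0.128 0.0141  9.07 1.16e-19 1.33e-17
#>  mir_0011    0.125 0.0138  9.06 1.33e-19 1.33e-17
#>  mir_0009    0.108 0.0130  8.32 8.99e-17 5.99e-15
#>  mir_0003    0.110 0.0138  7.98 1.48e-15 7.40e-14
#>  mir_0013    0.102 0.0133  7.64 2.10e-14 8.39e-13
```

`estimate` is the interaction coefficient `c` on the raw
trauma-by-expression product (here about 0.08 was planted for the true
modifiers, i.e. 0.3 per trauma SD); `score` is the modulation score
`c/SE`; `q` the BH-adjusted p.  Nine of the ten planted modifiers are
recovered at FDR < 0.1 in this run, and the positive scores say the
trauma-PTSS slope steepens with expression.  Note the hit list is
longer than ten: when many true modifiers share one exposure,
one-at-a-time fits leave the remaining interaction terms out of every
model and null modulation scores inflate — measured and discussed in
`vignettes/modulation-screen.Rmd`.

The numbered drivers under `analysis/` narrate the full workflow on the
same synthetic cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # cohort + ground truth
Rscript analysis/02_distribution_fit.R  # BIC ranking + bootstrap
Rscript analysis/03_screen.R            # main-effect + interaction screens
Rscript analysis/04_validate.R          # 10-fold CV, cross-wave test
Rscript analysis/05_enrichment.R        # hypergeometric pathway table
```

`run_pipeline(default_pipeline_config(seed = 1), "results/run")` runs
the same stages in one call with a reproducibility manifest.

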