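#!/usr/bin/env Rscript

# Stage 4: model validation.  10-fold cross-validated Spearman correlation
# of the adversity-only NB regression (with an L1-penalized variant as a
# robustness check), and the cross-wave consistency test: do the
# discovery-wave trauma-modifier hits keep elevated modulation scores in
# the validation wave?

suppressMessages(library(mirmod))

pheno <- read_phenotype("results/data/phenotype.csv")
counts2 <- read_expression("results/data/counts_wave2.tsv")
norm2 <- cpm_log_normalize(filter_low_expression(counts2))
adversities <- c("trauma_lifetime", "financial_lifetime",
                 "emotional_lifetime", "discrimination", "loneliness")

aligned <- align_samples(norm2, pheno, 2, 3)
X <- build_design(aligned$data, adversities)
cv <- kfold_cv_spearman(aligned$data$ptss, X, k = 10L, seed = 12L)
message(sprintf("10-fold CV Spearman, adversity-only NB model: %.3f",
                cv$mean_rho))

# L1-penalized refit at a mild penalty: which adversities survive?
fit_l1 <- fit_nb_l1(aligned$data$ptss, X, lambda = 5)
kept <- names(which(abs(fit_l1$coefficients[-1]) > 1e-8))
message("L1 (lambda = 5) retains: ", paste(kept, collapse = ", "))

disc <- read_screen_records("results/screen_discovery_trauma_lifetime.tsv")
val <- read_screen_records("results/screen_validation_trauma_lifetime.tsv")
hits <- significant_hits(disc)$mirna_id
scores <- setNames(val$score[val$estimable], val$mirna_id[val$estimable])
cw <- cross_wave_consistency(scores, intersect(hits, names(scores)))
message(sprintf(
  "cross-wave consistency (discovery hits vs rest, one-sided rank-sum): W = %.0f, p = %.2g",
  cw$W, cw$p))

truth <- jsonlite::read_json("results/data/ground_truth.json",
                             simplifyVector = TRUE)
cw_true <- cross_wave_consistency(
  scores, intersect(truth$modifier_ids, names(scores)))
message(sprintf("same test on the planted modifiers only: p = %.2g",
                cw_true$p))

jsonlite::write_json(
  list(cv = list(k = cv$k, mean_rho = cv$mean_rho,
                 per_fold_rho = cv$per_fold_rho),
       l1_retained = kept,
       crosswave_hits = cw, crosswave_truth = cw_true),
  "results/validation.json", auto_unbox = TRUE, digits = NA)
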