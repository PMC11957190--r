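# Shared moderate-size cohorts so the screen tests stay fast.
null_bundle <- gen_dataset(sim_config(seed = 301, n_participants = 300,
                                      n_mirnas = 60, n_modifiers = 0))
null_norm <- cpm_log_normalize(filter_low_expression(null_bundle$counts$wave2))

test_that("modulation score and BH adjustment match their definitions", {
  expect_equal(modulation_score(0.4, 0.2), 2)
  expect_equal(modulation_score(0, 5), 0)
  expect_equal(modulation_score(-0.6, 0.3), -2)
  expect_error(modulation_score(1, 0), "positive")
  expect_error(modulation_score(1, -1), "positive")

  # worked step-up vectors
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.05, 1.0)), c(0.10, 1.0))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  # matches the hand formula on random vectors and is monotone
  withr::with_seed(17, {
    for (i in 1:10) {
      p <- runif(25)
      expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
    }
    p <- runif(40)
    p2 <- pmin(p + runif(40, 0, 0.2), 1)
    expect_true(all(bh_fdr(p2) - bh_fdr(p) >= -1e-12))
  })
})

test_that("median stratification: ties to low", {
  expect_equal(as.character(median_stratify(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_true(all(median_stratify(rep(2, 5)) == "low"))
  expect_equal(as.character(median_stratify(5)), "low")
})

test_that("significant hits: strict threshold and ordering", {
  rec <- data.frame(mirna_id = c("a", "b", "c"),
                    q = c(0.05, 0.1, 0.2),
                    score = c(1, 5, 2), estimable = TRUE)
  hits <- significant_hits(rec, 0.1)
  expect_equal(hits$mirna_id, "a")      # strict < at the boundary
  rec$q <- rep(0.5, 3)
  expect_equal(nrow(significant_hits(rec, 0.1)), 0)
  rec$q <- c(0.02, 0.02, 0.01)
  hits <- significant_hits(rec, 1.0)
  expect_equal(hits$mirna_id, c("c", "b", "a"))  # q, then |score| desc
})

test_that("main-effect screen: planted miRNA tops the ranking", {
  cfg <- sim_config(seed = 88, n_participants = 400, n_mirnas = 40,
                    n_modifiers = 0, b = c(mir_0005 = 0.4))
  b <- gen_dataset(cfg)
  norm <- cpm_log_normalize(filter_low_expression(b$counts$wave2))
  rec <- main_effect_screen(norm, b$phenotype, 2, 3)
  expect_equal(rec$mirna_id[which.min(rec$p)], "mir_0005")
  expect_gt(rec$estimate[rec$mirna_id == "mir_0005"], 0)
  expect_true(all(rec$adversity == "none"))
  # score * se recovers the estimate
  est <- rec$estimable
  expect_equal(rec$score[est] * rec$se[est], rec$estimate[est],
               tolerance = 1e-9)
})

test_that("constant-expression miRNA is flagged non-estimable, kept out of FDR", {
  norm2 <- null_norm
  norm2[3, ] <- 5  # constant profile
  rec <- main_effect_screen(norm2, null_bundle$phenotype, 2, 3)
  bad <- rec[3, ]
  expect_false(bad$estimable)
  expect_true(is.na(bad$p) && is.na(bad$q))
  expect_equal(sum(rec$estimable), nrow(norm2) - 1)
})

test_that("interaction screen: planted modifiers separate from nulls", {
  cfg <- sim_config(seed = 19, n_participants = 500, n_mirnas = 60,
                    n_modifiers = 6)
  b <- gen_dataset(cfg)
  norm <- cpm_log_normalize(filter_low_expression(b$counts$wave2))
  rec <- interaction_screen(norm, b$phenotype, "trauma_lifetime", 2, 3)
  planted <- rec$mirna_id %in% b$ground_truth$modifier_ids
  expect_gt(mean(rec$score[planted]), mean(rec$score[!planted]))
  expect_gte(sum(rec$estimate[planted] > 0), 5)  # >= 5 of 6 positive sign
  expect_true(all(rec$adversity == "trauma_lifetime"))
})

test_that("interaction estimate rescales with the adversity; score does not", {
  b <- null_bundle
  rec1 <- interaction_screen(null_norm, b$phenotype, "discrimination", 2, 3)
  ph2 <- b$phenotype
  ph2$discrimination <- ph2$discrimination * 4
  rec2 <- interaction_screen(null_norm, ph2, "discrimination", 2, 3)
  est <- rec1$estimable & rec2$estimable
  expect_equal(rec2$estimate[est], rec1$estimate[est] / 4,
               tolerance = 1e-5)
  expect_equal(rec2$score[est], rec1$score[est], tolerance = 1e-4)
  expect_equal(rec2$p[est], rec1$p[est], tolerance = 1e-4)
})

test_that("screens are invariant to a shared permutation of samples", {
  b <- null_bundle
  perm <- withr::with_seed(5, sample.int(ncol(null_norm)))
  norm_p <- null_norm[, perm]
  rec1 <- interaction_screen(null_norm, b$phenotype, "trauma_lifetime",
                             2, 3)
  rec2 <- interaction_screen(norm_p, b$phenotype, "trauma_lifetime", 2, 3)
  expect_equal(rec1$estimate, rec2$estimate, tolerance = 1e-6)
  expect_equal(rec1$q, rec2$q, tolerance = 1e-6)
})

test_that("screen records round-trip through TSV", {
  rec <- main_effect_screen(null_norm, null_bundle$phenotype, 2, 3)
  td <- withr::local_tempdir()
  path <- file.path(td, "rec.tsv")
  write_screen_records(rec, path)
  back <- read_screen_records(path)
  expect_equal(back$estimate, rec$estimate, tolerance = 1e-12)
  expect_equal(back$q, rec$q, tolerance = 1e-12)
  expect_equal(back$mirna_id, rec$mirna_id)
})

test_that("missing adversity column is an error", {
  ph <- null_bundle$phenotype
  ph$loneliness <- NULL
  expect_error(main_effect_screen(null_norm, ph, 2, 3), "loneliness")
})
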