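test_that("config validation catches invalid marginals and references", {
  expect_error(sim_config(n_mirnas = 0), "n_mirnas")
  expect_error(sim_config(financial_prev = 1.2), "financial_prev")
  expect_error(sim_config(theta = -1), "theta")
  expect_error(sim_config(copula_rho = 1), "copula_rho")
  expect_error(sim_config(b = c(mir_9999 = 0.4), n_mirnas = 10),
               "unknown miRNA")
  expect_error(sim_config(modifiers = data.frame(
    mirna = "mir_0001", adversity = "nope", effect = 0.3)),
    "unknown adversities")
})

test_that("adversity marginals match their configuration at scale", {
  cfg <- sim_config(n_participants = 10000L, n_mirnas = 5L, seed = 1)
  adv <- gen_adversities(cfg)
  expect_equal(mean(adv$financial_lifetime), 0.625, tolerance = 0.02)
  expect_equal(mean(adv$emotional_lifetime), 0.316, tolerance = 0.02)
  expect_equal(mean(adv$trauma_lifetime), 5.8, tolerance = 0.15)
  expect_equal(sd(adv$trauma_lifetime), sqrt(5.8 + 5.8^2 / 3.6),
               tolerance = 0.15)
  expect_equal(mean(adv$discrimination), 3.4, tolerance = 0.02)
  expect_equal(mean(adv$loneliness), 1.4, tolerance = 0.03)
  expect_true(all(adv$loneliness >= 0))

  # zero copula correlation decouples the columns
  cfg0 <- sim_config(n_participants = 10000L, n_mirnas = 5L, seed = 2,
                     copula_rho = 0)
  adv0 <- gen_adversities(cfg0)
  cors <- cor(adv0[, -1])
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.03)

  # positive copula correlation induces positive dependence
  expect_gt(cor(adv$trauma_lifetime, adv$discrimination), 0.1)

  # determinism
  expect_identical(gen_adversities(cfg), gen_adversities(cfg))
})

test_that("expression generator: libraries, dispersion limit, stability", {
  cfg <- sim_config(n_participants = 150L, n_mirnas = 120L, seed = 3)
  ex <- gen_expression(cfg)
  expect_equal(length(ex$counts), 2)
  expect_equal(dim(ex$counts[[1]]), c(120, 150))
  tot <- colSums(ex$counts[[1]])
  expect_true(all(tot > cfg$lib_size_range[1] * 0.5))
  expect_true(all(tot < cfg$lib_size_range[2] * 2))

  # near-Poisson limit: variance ~ mean per cell
  cfgp <- sim_config(n_participants = 400L, n_mirnas = 250L, seed = 4,
                     count_dispersion = 1e6,
                     participant_sd = 1e-3, wave_sd = 1e-3)
  cts <- gen_expression(cfgp, waves = 1L)$counts[[1]]
  cpm <- sweep(cts, 2, colSums(cts), "/") * 1e6
  rows <- which(rowMeans(cts) > 50)
  # library-size spread adds count variance, so assess on the CPM scale
  disp <- median(apply(cpm[rows, ], 1, function(v) var(v) / mean(v)^2))
  expect_lt(disp, 0.05)  # tiny squared CV in the Poisson-like limit

  # per-participant cross-wave Spearman of profiles is high
  rho <- vapply(seq_len(ncol(ex$counts[[1]])), function(j)
    cor(ex$counts[[1]][, j], ex$counts[[2]][, j], method = "spearman"), 0)
  expect_gt(median(rho), 0.75)

  # determinism
  ex2 <- gen_expression(cfg)
  expect_identical(ex$counts[[1]], ex2$counts[[1]])
})

test_that("PTSS generator obeys NB moment structure", {
  cfg <- sim_config(n_participants = 20000L, n_mirnas = 3L, seed = 6,
                    n_modifiers = 0L,
                    a = c(trauma_lifetime = 0), intercept = log(35),
                    theta = 5)
  adv <- gen_adversities(cfg)
  norm <- cpm_log_normalize(gen_expression(cfg, waves = 1L)$counts[[1]])
  out <- gen_ptss(adv, norm, cfg, seed = 99)
  expect_equal(mean(out$y), 35, tolerance = 1)
  expect_equal(var(out$y), 35 + 35^2 / 5, tolerance = 0.1 * (35 + 245))

  # dispersion cap: Poisson limit variance/mean -> 1
  cfgp <- sim_config(n_participants = 20000L, n_mirnas = 3L, seed = 6,
                     n_modifiers = 0L, a = c(trauma_lifetime = 0),
                     intercept = log(35), theta = 1e6)
  outp <- gen_ptss(adv, norm, cfgp, seed = 99)
  expect_equal(var(outp$y) / mean(outp$y), 1, tolerance = 0.05)

  # determinism
  expect_identical(out$y, gen_ptss(adv, norm, cfg, seed = 99)$y)
})

test_that("gen_dataset bundles a coherent two-wave cohort with truth", {
  cfg <- sim_config(seed = 11, n_participants = 120L, n_mirnas = 30L,
                    n_modifiers = 4L)
  b <- gen_dataset(cfg)
  expect_equal(nrow(b$phenotype), 360)          # 3 waves x participants
  expect_setequal(unique(b$phenotype$wave), c(2, 3, 4))
  expect_equal(nrow(b$ground_truth$modifiers), 4)
  expect_true(all(b$ground_truth$modifiers$mirna %in%
                    rownames(b$counts$wave2)))
  expect_equal(unname(b$ground_truth$c_raw),
               rep(0.3 / sd(b$phenotype$trauma_lifetime[b$phenotype$wave == 3]),
                   4), tolerance = 1e-10)

  # full determinism of the bundle under the master seed
  b2 <- gen_dataset(cfg)
  expect_identical(b$phenotype, b2$phenotype)
  expect_identical(b$counts, b2$counts)

  # on-disk round trip
  td <- withr::local_tempdir()
  gen_dataset(cfg, out_dir = td)
  expect_true(file.exists(file.path(td, "counts_wave2.tsv")))
  back <- read_expression(file.path(td, "counts_wave2.tsv"))
  expect_equal(back, b$counts$wave2)
  ph <- read_phenotype(file.path(td, "phenotype.csv"))
  expect_equal(ph$ptss, b$phenotype$ptss)
  gt <- jsonlite::read_json(file.path(td, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$seed, 11)
})

test_that("generated datasets feed the screens without manual edits", {
  cfg <- sim_config(seed = 21, n_participants = 150L, n_mirnas = 25L,
                    n_modifiers = 2L)
  b <- gen_dataset(cfg)
  norm <- cpm_log_normalize(filter_low_expression(b$counts$wave4))
  rec <- interaction_screen(norm, b$phenotype, "trauma_lifetime", 4, 4)
  expect_equal(nrow(rec), nrow(norm))
  expect_true(all(rec$estimable))
})
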