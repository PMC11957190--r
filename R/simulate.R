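#' Synthetic cohort generator
#'
#' Generates cohort datasets with the statistical structure the screens
#' assume: correlated social-adversity profiles with survey-like
#' marginals, miRNA count matrices with library-size variation and high
#' between-wave stability, and NB-distributed PTSS driven by a linear
#' predictor with planted main and interaction effects.  Every stage of
#' the pipeline is testable on its output, with the planted truth recorded
#' for recovery checks.
#'
#' Planted effect sizes are specified per standard deviation of the
#' adversity and per log2-CPM unit of mean-centred expression
#' (`eta += c * z(adv_j) * (x_m - mean(x_m))`).  Because the centring and
#' scaling differences are linear in terms the screens already include
#' (adversity and miRNA main effects, intercept), the screens' raw-product
#' interaction coefficient identifies `c / sd(adv_j)`, which the ground
#' truth records as `c_raw`.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defaults emulate the study conditions: ~600 usable participants, 200
#' miRNAs, lifetime-trauma counts with mean 5.8 and SD ~3.9, financial /
#' emotional stressor prevalences of 0.625 / 0.316, per-item
#' discrimination and loneliness scale scores of 3.4 (0.5) and 1.4 (0.5),
#' PTSS mean ~36.5 with dispersion giving SD ~15, and ten planted
#' trauma-modifier miRNAs at c = 0.3 (per-SD units).
#'
#' @param n_participants Cohort size.
#' @param n_mirnas Number of miRNAs.
#' @param seed Master seed; every byte of output is a function of it.
#' @param trauma_mean,trauma_theta NB marginal of lifetime trauma counts.
#' @param financial_prev,emotional_prev Bernoulli prevalences.
#' @param discrimination_mean,discrimination_sd,loneliness_mean,loneliness_sd
#'   Truncated-normal (at 0) scale marginals.
#' @param copula_rho Exchangeable Gaussian-copula correlation between
#'   adversities.
#' @param log2_abundance_range Range of per-miRNA baseline log2 CPM.
#' @param lib_size_range Per-sample library sizes, log-uniform.
#' @param count_dispersion NB size of the counts around their expected
#'   abundance.
#' @param participant_sd,wave_sd SDs (log2 units) of the per-participant
#'   latent abundance shared across waves and of the wave-specific
#'   fluctuation; their ratio sets the between-wave stability.
#' @param ptss_mean Target marginal mean of PTSS (intercept is solved for
#'   unless given explicitly in `intercept`).
#' @param intercept Optional explicit linear-predictor intercept.
#' @param a Named vector of adversity main effects (raw units).
#' @param b Named vector (miRNA id -> effect) of planted expression main
#'   effects, per log2-CPM of centred expression.
#' @param n_modifiers,modifier_adversity,modifier_effect Planted
#'   interaction block: how many miRNAs modify which adversity and how
#'   strongly (per-SD units).  Modifier miRNAs are the first
#'   `n_modifiers` ids whose baseline abundance is at or above the median
#'   (so they survive the low-expression filter).
#' @param modifiers Optional explicit data frame (mirna, adversity,
#'   effect) overriding the block above.
#' @param theta Outcome NB dispersion.
#' @param link Outcome link (`"log"`).
#' @return Classed list `"sim_config"`.
#' @export
sim_config <- function(n_participants = 600L, n_mirnas = 200L, seed = 1L,
                       trauma_mean = 5.8, trauma_theta = 3.6,
                       financial_prev = 0.625, emotional_prev = 0.316,
                       discrimination_mean = 3.4, discrimination_sd = 0.5,
                       loneliness_mean = 1.4, loneliness_sd = 0.5,
                       copula_rho = 0.2,
                       log2_abundance_range = c(2, 12),
                       lib_size_range = c(5e5, 2e6),
                       count_dispersion = 60,
                       participant_sd = 0.25, wave_sd = 0.15,
                       ptss_mean = 36.5, intercept = NULL,
                       a = c(trauma_lifetime = 0.02,
                             financial_lifetime = 0.15,
                             emotional_lifetime = 0.02,
                             discrimination = 0.10,
                             loneliness = 0.10),
                       b = numeric(),
                       n_modifiers = 10L,
                       modifier_adversity = "trauma_lifetime",
                       modifier_effect = 0.3,
                       modifiers = NULL,
                       theta = 12, link = "log") {
  cfg <- list(n_participants = as.integer(n_participants),
              n_mirnas = as.integer(n_mirnas), seed = as.integer(seed),
              trauma_mean = trauma_mean, trauma_theta = trauma_theta,
              financial_prev = financial_prev,
              emotional_prev = emotional_prev,
              discrimination_mean = discrimination_mean,
              discrimination_sd = discrimination_sd,
              loneliness_mean = loneliness_mean,
              loneliness_sd = loneliness_sd,
              copula_rho = copula_rho,
              log2_abundance_range = log2_abundance_range,
              lib_size_range = lib_size_range,
              count_dispersion = count_dispersion,
              participant_sd = participant_sd, wave_sd = wave_sd,
              ptss_mean = ptss_mean, intercept = intercept,
              a = a, b = b,
              n_modifiers = as.integer(n_modifiers),
              modifier_adversity = modifier_adversity,
              modifier_effect = modifier_effect,
              modifiers = modifiers,
              theta = theta, link = link)
  class(cfg) <- "sim_config"
  validate_config(cfg)
}

#' @rdname sim_config
#' @param cfg A `sim_config` to validate.
#' @export
validate_config <- function(cfg) {
  if (cfg$n_participants < 1) stop("n_participants must be >= 1",
                                   call. = FALSE)
  if (cfg$n_mirnas < 1) stop("n_mirnas must be >= 1", call. = FALSE)
  for (p in c("financial_prev", "emotional_prev"))
    if (cfg[[p]] <= 0 || cfg[[p]] >= 1)
      stop(p, " must lie in (0, 1)", call. = FALSE)
  for (p in c("trauma_mean", "trauma_theta", "discrimination_sd",
              "loneliness_sd", "count_dispersion", "participant_sd",
              "wave_sd", "theta"))
    if (cfg[[p]] <= 0) stop(p, " must be positive", call. = FALSE)
  if (abs(cfg$copula_rho) >= 1)
    stop("copula_rho must lie in (-1, 1)", call. = FALSE)
  if (!all(names(cfg$a) %in% ADVERSITIES))
    stop("unknown adversity in a: ",
         paste(setdiff(names(cfg$a), ADVERSITIES), collapse = ", "),
         call. = FALSE)
  if (!is.null(cfg$modifiers)) {
    if (!all(cfg$modifiers$adversity %in% ADVERSITIES))
      stop("modifiers reference unknown adversities", call. = FALSE)
    if (!all(cfg$modifiers$mirna %in% mirna_ids(cfg$n_mirnas)))
      stop("modifiers reference unknown miRNA ids", call. = FALSE)
  } else if (!cfg$modifier_adversity %in% ADVERSITIES) {
    stop("modifier_adversity must be one of: ",
         paste(ADVERSITIES, collapse = ", "), call. = FALSE)
  }
  if (length(cfg$b) && !all(names(cfg$b) %in% mirna_ids(cfg$n_mirnas)))
    stop("b references unknown miRNA ids", call. = FALSE)
  if (!cfg$link %in% c("log", "identity"))
    stop("link must be 'log' or 'identity'", call. = FALSE)
  cfg
}

mirna_ids <- function(m) sprintf("mir_%04d", seq_len(m))

## standard-normal quantile of a normal truncated below at 0
qtruncnorm0 <- function(u, mean, sd) {
  f0 <- stats::pnorm(0, mean, sd)
  stats::qnorm(f0 + u * (1 - f0), mean, sd)
}

#' Generate the social-adversity block
#'
#' Marginals per [sim_config()]; the five adversities are coupled through
#' an exchangeable Gaussian copula so they co-occur the way survey
#' adversities do.
#'
#' @param cfg A `sim_config`.
#' @param seed Seed (defaults to `cfg$seed`).
#' @return Data frame with `participant_id` and the five adversity
#'   columns.
#' @export
gen_adversities <- function(cfg, seed = cfg$seed) {
  validate_config(cfg)
  n <- cfg$n_participants
  R <- matrix(cfg$copula_rho, 5, 5); diag(R) <- 1
  U <- withr::with_seed(seed, {
    Z <- matrix(stats::rnorm(n * 5), n, 5) %*% chol(R)
    stats::pnorm(Z)
  })
  data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    trauma_lifetime = stats::qnbinom(U[, 1], mu = cfg$trauma_mean,
                                     size = cfg$trauma_theta),
    financial_lifetime = stats::qbinom(U[, 2], 1, cfg$financial_prev),
    emotional_lifetime = stats::qbinom(U[, 3], 1, cfg$emotional_prev),
    discrimination = qtruncnorm0(U[, 4], cfg$discrimination_mean,
                                 cfg$discrimination_sd),
    loneliness = qtruncnorm0(U[, 5], cfg$loneliness_mean,
                             cfg$loneliness_sd))
}

#' Generate miRNA count matrices for one or two waves
#'
#' Per-miRNA baseline abundances (log2 CPM uniform over the configured
#' range) are shared by all samples; each participant carries a latent
#' abundance deviation shared across waves, plus wave-specific
#' fluctuation; counts are NB around the library-scaled abundance.  With
#' the default latent/fluctuation SDs the per-participant cross-wave
#' Spearman correlation of profiles exceeds 0.75 for the large majority
#' of participants.
#'
#' @param cfg A `sim_config`.
#' @param seed Seed (defaults to `cfg$seed`).
#' @param waves 1 or 2 expression waves.
#' @param wave_labels Labels used in the sample ids (default 2 and 4).
#' @return List: `counts` (list of matrices, one per wave; columns
#'   `P####_w<label>`), `base_log2cpm` (named per-miRNA baseline).
#' @export
gen_expression <- function(cfg, seed = cfg$seed, waves = 2L,
                           wave_labels = c(2L, 4L)) {
  validate_config(cfg)
  stopifnot(waves %in% c(1L, 2L))
  n <- cfg$n_participants; m <- cfg$n_mirnas
  ids <- mirna_ids(m)
  out <- withr::with_seed(seed + 101L, {
    u <- stats::runif(m, cfg$log2_abundance_range[1],
                      cfg$log2_abundance_range[2])
    rel <- 2^u / sum(2^u)
    latent <- matrix(stats::rnorm(m * n, 0, cfg$participant_sd), m, n)
    counts <- vector("list", waves)
    for (w in seq_len(waves)) {
      lib <- exp(stats::runif(n, log(cfg$lib_size_range[1]),
                              log(cfg$lib_size_range[2])))
      eps <- matrix(stats::rnorm(m * n, 0, cfg$wave_sd), m, n)
      mu <- rel * 2^(latent + eps)
      mu <- sweep(mu, 2, lib / colSums(mu), "*")
      cts <- matrix(stats::rnbinom(m * n, mu = mu,
                                   size = cfg$count_dispersion), m, n)
      dimnames(cts) <- list(ids,
                            sprintf("P%04d_w%d", seq_len(n),
                                    wave_labels[w]))
      counts[[w]] <- cts
    }
    list(counts = counts, base_log2cpm = stats::setNames(u, ids))
  })
  out
}

## Resolve the planted interaction map for a config (needs abundances).
resolve_modifiers <- function(cfg, base_log2cpm) {
  if (!is.null(cfg$modifiers)) return(cfg$modifiers)
  if (cfg$n_modifiers == 0)
    return(data.frame(mirna = character(), adversity = character(),
                      effect = numeric()))
  eligible <- names(base_log2cpm)[base_log2cpm >=
                                    stats::median(base_log2cpm)]
  if (length(eligible) < cfg$n_modifiers)
    stop("not enough abundant miRNAs to plant ", cfg$n_modifiers,
         " modifiers", call. = FALSE)
  data.frame(mirna = eligible[seq_len(cfg$n_modifiers)],
             adversity = cfg$modifier_adversity,
             effect = cfg$modifier_effect)
}

#' Generate NB-distributed PTSS with planted effects
#'
#' Builds the linear predictor `eta = intercept + sum_i a_i adv_i +
#' sum_m b_m (x_m - mean) + sum_(m,j) c_mj z(adv_j) (x_m - mean)` and
#' draws `y ~ NB(exp(eta), theta)`.  The intercept is solved so the
#' marginal mean of PTSS matches `cfg$ptss_mean` unless given explicitly.
#' `eta` is clamped so means stay below 1e4 (clamp count recorded).
#'
#' @param adversities Data frame from [gen_adversities()].
#' @param norm Normalized (log2 CPM + 1) expression matrix whose columns
#'   align with the adversity rows.
#' @param cfg A `sim_config`.
#' @param modifiers Resolved modifier data frame (mirna, adversity,
#'   effect).
#' @param seed Seed for the outcome draw.
#' @return List: `y`, `eta`, `truth` (intercept, a, b, modifiers with
#'   `c_raw = effect / sd(adv)`, theta, clamped count).
#' @export
gen_ptss <- function(adversities, norm, cfg, modifiers = NULL,
                     seed = cfg$seed) {
  n <- nrow(adversities)
  stopifnot(ncol(norm) == n)
  if (is.null(modifiers))
    modifiers <- data.frame(mirna = character(), adversity = character(),
                            effect = numeric())
  eta <- rep(0, n)
  for (adv in names(cfg$a))
    eta <- eta + cfg$a[[adv]] * adversities[[adv]]
  b_raw <- cfg$b
  for (id in names(cfg$b)) {
    x <- as.numeric(norm[id, ])
    eta <- eta + cfg$b[[id]] * (x - mean(x))
  }
  modifiers$c_raw <- rep(NA_real_, nrow(modifiers))
  if (nrow(modifiers)) for (r in seq_len(nrow(modifiers))) {
    adv <- adversities[[modifiers$adversity[r]]]
    sd_a <- stats::sd(adv)
    x <- as.numeric(norm[modifiers$mirna[r], ])
    eta <- eta + modifiers$effect[r] * ((adv - mean(adv)) / sd_a) *
      (x - mean(x))
    modifiers$c_raw[r] <- modifiers$effect[r] / sd_a
  }
  intercept <- cfg$intercept
  if (is.null(intercept)) {
    intercept <- if (cfg$link == "log") log(cfg$ptss_mean) - log(mean(exp(eta)))
                 else cfg$ptss_mean - mean(eta)
  }
  eta <- eta + intercept
  clamped <- 0L
  if (cfg$link == "log") {
    hi <- log(9999)
    clamped <- sum(eta > hi)
    eta <- pmin(eta, hi)
    mu <- exp(eta)
  } else {
    mu <- eta
    if (any(mu <= 0))
      stop("identity link produced nonpositive means; use the log link",
           call. = FALSE)
    clamped <- sum(mu > 9999)
    mu <- pmin(mu, 9999)
  }
  y <- withr::with_seed(seed, stats::rnbinom(n, mu = mu, size = cfg$theta))
  list(y = y, eta = eta,
       truth = list(intercept = intercept, a = cfg$a, b = b_raw,
                    modifiers = modifiers, theta = cfg$theta,
                    link = cfg$link, clamped = clamped))
}

#' Generate a full synthetic cohort bundle
#'
#' Adversities, two expression waves (labelled 2 and 4), PTSS for outcome
#' waves 3 (driven by wave-2 expression) and 4 (wave-4 expression) from
#' the same planted coefficients, assembled into the standard phenotype
#' schema, plus the ground truth.  Optionally writes the standard file
#' formats (counts TSVs, phenotype CSV, ground-truth and manifest JSON).
#'
#' @param cfg A `sim_config`.
#' @param out_dir Optional output directory.
#' @return List: `phenotype`, `counts` (named list `wave2`, `wave4`),
#'   `ground_truth`, `config`.
#' @export
gen_dataset <- function(cfg, out_dir = NULL) {
  validate_config(cfg)
  adv <- gen_adversities(cfg)
  expr <- gen_expression(cfg)
  modifiers <- resolve_modifiers(cfg, expr$base_log2cpm)

  norm2 <- cpm_log_normalize(expr$counts[[1]])
  norm4 <- cpm_log_normalize(expr$counts[[2]])
  out3 <- gen_ptss(adv, norm2, cfg, modifiers, seed = cfg$seed + 202L)
  out4 <- gen_ptss(adv, norm4, cfg, modifiers, seed = cfg$seed + 303L)

  n <- cfg$n_participants
  row_block <- function(wave, sample_suffix, ptss) {
    data.frame(sample_id = if (is.null(sample_suffix)) sprintf("P%04d_s%d",
                 seq_len(n), wave)
               else sprintf("P%04d_w%d", seq_len(n), sample_suffix),
               participant_id = adv$participant_id,
               wave = wave, ptss = ptss,
               adv[ADVERSITIES], row.names = NULL)
  }
  pheno <- rbind(row_block(2L, 2L, NA_integer_),
                 row_block(3L, NULL, out3$y),
                 row_block(4L, 4L, out4$y))
  pheno <- validate_phenotype(pheno)

  modifiers <- out3$truth$modifiers  # carries c_raw
  truth <- list(seed = cfg$seed,
                modifiers = modifiers,
                modifier_ids = modifiers$mirna,
                intercept_wave3 = out3$truth$intercept,
                intercept_wave4 = out4$truth$intercept,
                a = cfg$a, b = cfg$b, theta = cfg$theta, link = cfg$link,
                clamped = c(wave3 = out3$truth$clamped,
                            wave4 = out4$truth$clamped),
                c_raw = stats::setNames(modifiers$c_raw, modifiers$mirna))

  bundle <- list(phenotype = pheno,
                 counts = list(wave2 = expr$counts[[1]],
                               wave4 = expr$counts[[2]]),
                 ground_truth = truth,
                 config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_expression(bundle$counts$wave2,
                     file.path(out_dir, "counts_wave2.tsv"))
    write_expression(bundle$counts$wave4,
                     file.path(out_dir, "counts_wave4.tsv"))
    write_phenotype(pheno, file.path(out_dir, "phenotype.csv"))
    jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(config = unclass(cfg), seed = cfg$seed),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  bundle
}

#' Generate a synthetic miRNA target table and pathway collection
#'
#' Companion generator for the enrichment stage: random target genes with
#' miRDB-style binding scores, where the target genes of the designated
#' signal miRNAs concentrate in a dedicated gene block that also forms
#' the first pathway — so that pathway is genuinely enriched in the
#' pooled targets of the signal miRNAs.
#'
#' @param mirnas All miRNA ids.
#' @param signal_mirnas Ids whose targets concentrate in the signal block.
#' @param seed Seed.
#' @param n_genes Universe size.
#' @param targets_per_mirna Targets drawn per miRNA.
#' @param n_pathways Number of pathways (>= 2).
#' @param pathway_size Genes per pathway.
#' @param signal_block Size of the signal gene block.
#' @param signal_prob Probability a signal miRNA's target falls in the
#'   block.
#' @return List: `targets` (data frame mirna/gene/score), `gmt_lines`
#'   (character vector of GMT lines).
#' @export
gen_target_data <- function(mirnas, signal_mirnas = character(), seed = 1L,
                            n_genes = 400L, targets_per_mirna = 20L,
                            n_pathways = 15L, pathway_size = 40L,
                            signal_block = 60L, signal_prob = 0.7) {
  stopifnot(n_pathways >= 2, signal_block <= n_genes,
            pathway_size <= n_genes)
  genes <- sprintf("G%04d", seq_len(n_genes))
  block <- genes[seq_len(signal_block)]
  withr::with_seed(seed + 404L, {
    rows <- lapply(mirnas, function(id) {
      k <- targets_per_mirna
      if (id %in% signal_mirnas) {
        nb <- stats::rbinom(1, k, signal_prob)
        g <- c(sample(block, min(nb, length(block))),
               sample(setdiff(genes, block), k - min(nb, length(block))))
      } else {
        g <- sample(genes, k)
      }
      data.frame(mirna = id, gene = g,
                 score = round(stats::runif(k, 50, 100), 1))
    })
    targets <- do.call(rbind, rows)
    pw <- vector("list", n_pathways)
    pw[[1]] <- block
    for (i in 2:n_pathways) pw[[i]] <- sample(genes, pathway_size)
    gmt_lines <- vapply(seq_len(n_pathways), function(i) {
      paste(c(sprintf("pathway_%02d", i),
              sprintf("synthetic pathway %d", i), pw[[i]]),
            collapse = "\t")
    }, "")
    list(targets = targets, gmt_lines = gmt_lines)
  })
}
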