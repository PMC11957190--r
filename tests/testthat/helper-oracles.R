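# Independent oracles and small fixture builders used across the suite.

# Brute-force maximizer of the joint NB log-likelihood over (beta, log
# theta) -- deliberately independent of the package's IRLS/profile path.
oracle_nb_fit <- function(y, X) {
  p <- ncol(X)
  nll <- function(par) {
    mu <- exp(drop(X %*% par[seq_len(p)]))
    v <- -sum(dnbinom(y, size = exp(par[p + 1]), mu = mu, log = TRUE))
    if (!is.finite(v)) 1e12 else v
  }
  start <- c(qr.coef(qr(X), log(y + 0.5)), 0)
  opt <- optim(start, nll, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-15))
  # restart from the incumbent to squeeze out the last digits
  opt <- optim(opt$par, nll, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-15))
  list(beta = opt$par[seq_len(p)], theta = exp(opt$par[p + 1]),
       loglik = -opt$value)
}

# Dense grid-search maximizer of a two-parameter positive-family
# likelihood (independent of optim): coarse log-grid, then two rounds of
# refinement around the incumbent.
oracle_grid_fit <- function(y, dens, shape_range, scale_range, n_grid = 60) {
  search <- function(sh_rng, sc_rng) {
    shapes <- exp(seq(log(sh_rng[1]), log(sh_rng[2]), length.out = n_grid))
    scales <- exp(seq(log(sc_rng[1]), log(sc_rng[2]), length.out = n_grid))
    best <- c(NA, NA, -Inf)
    for (sh in shapes) {
      ll <- vapply(scales,
                   function(sc) sum(dens(y, sh, scale = sc, log = TRUE)), 0)
      i <- which.max(ll)
      if (ll[i] > best[3]) best <- c(sh, scales[i], ll[i])
    }
    best
  }
  b <- search(shape_range, scale_range)
  for (w in c(0.5, 0.15, 0.03)) {  # shrinking log-window refinements
    b <- search(b[1] * c(1 / (1 + w), 1 + w), b[2] * c(1 / (1 + w), 1 + w))
  }
  list(shape = b[1], scale = b[2], loglik = b[3])
}

# Exhaustive-enumeration one-sided rank-sum p-value (hits greater).
oracle_wilcoxon_exact <- function(hits, others) {
  pooled <- c(hits, others)
  n <- length(pooled); m <- length(hits)
  obs <- sum(rank(pooled)[seq_len(m)])
  combs <- combn(n, m)
  stats <- apply(combs, 2, function(idx) sum(rank(pooled)[idx]))
  mean(stats >= obs)
}

# Exhaustive hypergeometric upper tail by enumerating all draws.
oracle_hypergeom <- function(N, K, n, k_obs) {
  draws <- combn(N, n)
  # successes are items 1..K
  overlaps <- apply(draws, 2, function(d) sum(d <= K))
  mean(overlaps >= k_obs)
}

# Hand BH step-up.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Small simulated regression fixture.
make_nb_data <- function(n, beta, theta, seed, design = NULL) {
  withr::with_seed(seed, {
    if (is.null(design)) {
      design <- cbind(`(Intercept)` = 1,
                      x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
      design <- design[, seq_along(beta), drop = FALSE]
    }
    mu <- exp(drop(design %*% beta))
    list(y = rnbinom(n, mu = mu, size = theta), X = design)
  })
}

# Tiny two-wave phenotype/expression fixture for alignment tests.
make_aligned_fixture <- function(seed = 42) {
  cfg <- sim_config(n_participants = 60L, n_mirnas = 20L, seed = seed,
                    n_modifiers = 0L)
  gen_dataset(cfg)
}
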