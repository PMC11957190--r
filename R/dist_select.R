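#' Outcome-distribution selection
#'
#' Maximum-likelihood fits of the four candidate outcome families
#' (Poisson, gamma, negative binomial, Weibull), ranking by BIC, and a
#' bootstrap-over-individuals comparison of two families.  Symptom-severity
#' sums are overdispersed counts, so the NB typically wins; the machinery
#' makes that an empirical decision rather than an assumption.
#'
#' @name dist_select
NULL

DIST_FAMILIES <- c("poisson", "gamma", "negative_binomial", "weibull")

#' Bayesian Information Criterion
#'
#' `k * ln(n) - 2 * loglik`; lower is better.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param n Number of observations.
#' @export
bic <- function(loglik, k, n) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (k < 0) stop("k must be >= 0", call. = FALSE)
  k * log(n) - 2 * loglik
}

#' Fit one outcome family by maximum likelihood
#'
#' Poisson and NB means have closed-form MLEs (the sample mean); the NB
#' dispersion is profiled; gamma and Weibull are maximized by quasi-Newton
#' on log-transformed parameters with multistart fallback.
#'
#' @param y Nonnegative outcome vector.  Poisson/NB require integer
#'   values; gamma/Weibull require strictly positive values (an
#'   `epsilon_shift` of +0.5 is available for integer outcomes that
#'   include zeros).
#' @param family One of `"poisson"`, `"gamma"`, `"negative_binomial"`,
#'   `"weibull"`.
#' @param epsilon_shift Add 0.5 to `y` before a gamma/Weibull fit.
#' @return List of class `"dist_fit"`: `family`, `params`, `loglik`, `n`,
#'   `k`, `bic`, `boundary`.
#' @export
fit_distribution <- function(y, family = DIST_FAMILIES,
                             epsilon_shift = FALSE) {
  family <- match.arg(family)
  if (length(y) < 2) stop("need at least 2 observations", call. = FALSE)
  if (any(!is.finite(y)) || any(y < 0))
    stop("y must be finite and nonnegative", call. = FALSE)
  n <- length(y)

  if (family %in% c("poisson", "negative_binomial")) {
    if (any(abs(y - round(y)) > 1e-8))
      stop(family, " requires integer-valued y", call. = FALSE)
    y <- round(y)
  } else {
    if (epsilon_shift) y <- y + 0.5
    if (any(y <= 0))
      stop(family, " requires strictly positive y ",
           "(epsilon_shift = TRUE shifts integer outcomes by +0.5)",
           call. = FALSE)
    if (stats::var(y) == 0)
      stop(family, " likelihood is unbounded for constant y", call. = FALSE)
  }

  res <- switch(family,
    poisson = {
      lambda <- mean(y)
      list(params = c(lambda = lambda),
           loglik = sum(stats::dpois(y, lambda, log = TRUE)),
           k = 1L, boundary = FALSE)
    },
    negative_binomial = {
      mu <- mean(y)
      theta <- profile_theta(y, rep(mu, n))
      list(params = c(mu = mu, theta = theta),
           loglik = sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE)),
           k = 2L, boundary = theta >= .THETA_CAP * 0.999)
    },
    gamma = fit_positive_family(y, stats::dgamma, shape_scale_start_gamma(y),
                                c("shape", "scale")),
    weibull = fit_positive_family(y, stats::dweibull,
                                  shape_scale_start_weibull(y),
                                  c("shape", "scale"))
  )

  structure(list(family = family, params = res$params, loglik = res$loglik,
                 n = n, k = res$k, bic = bic(res$loglik, res$k, n),
                 boundary = res$boundary),
            class = "dist_fit")
}

shape_scale_start_gamma <- function(y) {
  m <- mean(y); v <- stats::var(y)
  shape <- max(m^2 / v, 1e-2)
  c(log(shape), log(m / shape))
}

shape_scale_start_weibull <- function(y) {
  # Menon-style moment start: shape from log-variance, scale from mean
  sl <- stats::sd(log(y))
  shape <- if (is.finite(sl) && sl > 0) 1.2 / sl else 1
  c(log(shape), log(mean(y)))
}

## Generic 2-parameter positive-family MLE on log params, with multistart.
fit_positive_family <- function(y, dens, start, pnames) {
  nll <- function(lp) {
    v <- suppressWarnings(
      -sum(dens(y, exp(lp[1]), scale = exp(lp[2]), log = TRUE)))
    if (!is.finite(v)) 1e12 else v
  }
  starts <- list(start, start + c(0.5, -0.5), start + c(-0.5, 0.5))
  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      stats::optim(s, nll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value))
      best <- opt
  }
  if (is.null(best) || !is.finite(best$value))
    stop("maximum-likelihood fit failed", call. = FALSE)
  params <- exp(best$par)
  names(params) <- pnames
  list(params = params, loglik = -best$value, k = 2L, boundary = FALSE)
}

#' Fit all candidate families and rank by BIC
#'
#' @param y Outcome vector.
#' @param families Families to try (default all four).
#' @param epsilon_shift Passed to [fit_distribution()].
#' @return List of class `"dist_ranking"`: `fits` (ascending BIC),
#'   `table` (data frame family/loglik/k/bic), `failures` (named character
#'   vector of per-family failure reasons).
#' @export
select_distribution <- function(y, families = DIST_FAMILIES,
                                epsilon_shift = FALSE) {
  fits <- list(); failures <- character()
  for (fam in families) {
    f <- tryCatch(fit_distribution(y, fam, epsilon_shift = epsilon_shift),
                  error = function(e) conditionMessage(e))
    if (inherits(f, "dist_fit")) fits[[fam]] <- f
    else failures[[fam]] <- f
  }
  if (length(fits) == 0)
    stop("no candidate family could be fitted", call. = FALSE)
  ord <- order(vapply(fits, function(f) f$bic, 0))
  fits <- fits[ord]
  tab <- data.frame(
    family = vapply(fits, `[[`, "", "family"),
    loglik = vapply(fits, `[[`, 0, "loglik"),
    k = vapply(fits, `[[`, 0L, "k"),
    bic = vapply(fits, `[[`, 0, "bic"),
    boundary = vapply(fits, `[[`, FALSE, "boundary"),
    row.names = NULL)
  structure(list(fits = fits, table = tab, failures = failures),
            class = "dist_ranking")
}

#' @export
print.dist_ranking <- function(x, ...) {
  cat("Outcome-family ranking by BIC (lower is better):\n")
  print(x$table, row.names = FALSE)
  if (length(x$failures))
    cat("Not fittable:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}

#' Bootstrap BIC comparison of two families
#'
#' For each of `B` resamples of individuals (with replacement, size n),
#' both families are refitted and `dBIC = BIC_a - BIC_b` recorded.  The
#' summary p is the fraction of replicates with `dBIC > 0`, ties counted
#' one half — a symmetric convention: p near 0 favors family a, near 1
#' favors family b, near 0.5 means the families are interchangeable.
#'
#' @param y Outcome vector on which both families are fittable.
#' @param family_a,family_b Families to compare.
#' @param B Number of bootstrap replicates (>= 1).
#' @param seed RNG seed for the resampling.
#' @param epsilon_shift Passed to [fit_distribution()].
#' @return List: `delta_bic` (successful replicates), `mean_delta`, `p`,
#'   `B`, `n_failed`.
#' @export
bootstrap_bic_compare <- function(y, family_a, family_b, B = 1000L,
                                  seed = 1L, epsilon_shift = FALSE) {
  if (!is.numeric(B) || B < 1) stop("B must be >= 1", call. = FALSE)
  B <- as.integer(B)
  # both families must fit on the full data
  fit_distribution(y, family_a, epsilon_shift = epsilon_shift)
  fit_distribution(y, family_b, epsilon_shift = epsilon_shift)
  n <- length(y)
  delta <- rep(NA_real_, B)
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      yb <- y[sample.int(n, n, replace = TRUE)]
      fa <- tryCatch(fit_distribution(yb, family_a,
                                      epsilon_shift = epsilon_shift),
                     error = function(e) NULL)
      fb <- tryCatch(fit_distribution(yb, family_b,
                                      epsilon_shift = epsilon_shift),
                     error = function(e) NULL)
      if (!is.null(fa) && !is.null(fb)) delta[b] <- fa$bic - fb$bic
    }
  })
  n_failed <- sum(is.na(delta))
  if (n_failed > 0.1 * B)
    stop("more than 10% of bootstrap replicates failed to fit (",
         n_failed, "/", B, ")", call. = FALSE)
  d <- delta[!is.na(delta)]
  list(delta_bic = d,
       mean_delta = mean(d),
       p = mean(d > 0) + 0.5 * mean(d == 0),
       B = B,
       n_failed = n_failed)
}
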