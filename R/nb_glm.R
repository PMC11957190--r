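#' Negative-binomial GLM engine
#'
#' From-scratch negative-binomial (NB2) regression: coefficients by IRLS,
#' dispersion theta by profile maximum likelihood, alternated to joint
#' convergence.  The NB2 parameterization is mean \eqn{\mu} and dispersion
#' \eqn{\theta} with variance \eqn{\mu + \mu^2/\theta}; \eqn{\theta \to
#' \infty} recovers the Poisson.
#'
#' @name nb_glm
NULL

.THETA_CAP <- 1e6
.THETA_FLOOR <- 1e-3

nb_loglik <- function(y, mu, theta) {
  sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE))
}

## Profile MLE of theta given fitted means; golden-section on log(theta).
profile_theta <- function(y, mu, cap = .THETA_CAP) {
  f <- function(lt) nb_loglik(y, mu, exp(lt))
  opt <- stats::optimize(f, c(log(.THETA_FLOOR), log(cap)),
                         maximum = TRUE, tol = 1e-7)
  theta <- exp(opt$maximum)
  # snap to the cap when the profile is still rising there (Poisson limit)
  if (opt$maximum > log(cap) - 1e-3 || f(log(cap)) >= opt$objective - 1e-10) {
    if (f(log(cap)) >= opt$objective - 1e-10) theta <- cap
  }
  theta
}

check_design <- function(X, y) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != length(y))
    stop("nrow(X) must equal length(y)", call. = FALSE)
  if (length(y) <= ncol(X))
    stop("need more observations than predictors", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  X
}

#' Fit a negative-binomial GLM
#'
#' Coefficients and dispersion are estimated by alternating IRLS for the
#' regression coefficients (given theta) with profile maximum likelihood
#' for theta (given the fitted means), until the joint log-likelihood is
#' stable.  The covariance matrix is the inverse observed information for
#' the coefficient block at the optimum (the coefficient/dispersion
#' information is orthogonal in expectation for NB2).
#'
#' @param y Nonnegative integer outcome vector.
#' @param X Design matrix (include an intercept column yourself, e.g. via
#'   [build_design()]); must be full column rank.
#' @param link `"log"` (default, canonical-positive) or `"identity"`.
#' @param theta_cap Upper bound for the dispersion; fits hitting it are
#'   flagged `theta_boundary` (Poisson limit).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum outer (IRLS + profile) iterations.
#' @return An object of class `"nb_fit"`: `coefficients`, `covariance`,
#'   `standard_errors`, `theta`, `theta_boundary`, `loglik`, `converged`,
#'   `iterations`, `n_used`, `link`, `fitted`.
#' @examples
#' set.seed(1)
#' x <- rnorm(200)
#' y <- rnbinom(200, mu = exp(1 + 0.3 * x), size = 2)
#' fit <- fit_nb(y, cbind(`(Intercept)` = 1, x = x))
#' coef(fit)
#' @export
fit_nb <- function(y, X, link = c("log", "identity"),
                   theta_cap = .THETA_CAP, tol = 1e-8, max_iter = 100L) {
  link <- match.arg(link)
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8))
    stop("y must be a nonnegative integer vector", call. = FALSE)
  y <- as.numeric(round(y))
  X <- check_design(X, y)
  n <- length(y)
  p <- ncol(X)

  # moment start for theta
  m <- mean(y); v <- stats::var(y)
  theta <- if (is.finite(v) && v > m) min(max(m^2 / (v - m), 0.05), theta_cap)
           else theta_cap

  beta <- nb_irls_start(y, X, link)
  eta <- drop(X %*% beta)
  mu <- nb_linkinv(eta, link, y)
  ll <- nb_loglik(y, mu, theta)

  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    beta <- nb_irls(y, X, beta, theta, link)
    eta <- drop(X %*% beta)
    mu <- nb_linkinv(eta, link, y)
    theta <- profile_theta(y, mu, cap = theta_cap)
    ll_new <- nb_loglik(y, mu, theta)
    if (abs(ll_new - ll) < tol * (abs(ll) + 1e-8)) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }

  # Newton polish: a couple of scored steps sharpen the last digits on
  # flat likelihoods (small theta) at the cost of one solve each
  if (converged && link == "log") {
    for (polish in 1:2) {
      score <- drop(crossprod(X, theta * (y - mu) / (mu + theta)))
      info_p <- nb_obs_info(y, X, mu, theta, link)
      step <- tryCatch(solve(info_p, score), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) break
      beta_new <- beta + step
      mu_new <- exp(drop(X %*% beta_new))
      ll_new <- nb_loglik(y, mu_new, theta)
      if (!is.finite(ll_new) || ll_new < ll - 1e-8) break
      beta <- beta_new; mu <- mu_new; ll <- ll_new
    }
    theta <- profile_theta(y, mu, cap = theta_cap)
    ll <- nb_loglik(y, mu, theta)
  }

  info <- nb_obs_info(y, X, mu, theta, link)
  cov <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, p, p, dimnames = dimnames(info))
  })
  se <- sqrt(pmax(diag(cov), 0))
  names(beta) <- names(se) <- colnames(X)

  structure(list(
    coefficients = beta,
    covariance = cov,
    standard_errors = se,
    theta = theta,
    theta_boundary = theta >= theta_cap * 0.999,
    loglik = ll,
    converged = converged,
    iterations = iter,
    n_used = n,
    link = link,
    fitted = mu,
    terms = colnames(X)
  ), class = "nb_fit")
}

nb_linkinv <- function(eta, link, y) {
  if (link == "log") return(exp(eta))
  if (any(eta <= 0))
    stop("identity link produced nonpositive fitted means; use the log link",
         call. = FALSE)
  eta
}

nb_irls_start <- function(y, X, link) {
  z0 <- if (link == "log") log(y + 0.5) else y
  qr.coef(qr(X), z0)
}

## IRLS for beta at fixed theta (Fisher scoring).
nb_irls <- function(y, X, beta, theta, link, max_iter = 50L, tol = 1e-10) {
  eta <- drop(X %*% beta)
  mu <- nb_linkinv(eta, link, y)
  dev_old <- -2 * nb_loglik(y, mu, theta)
  for (i in seq_len(max_iter)) {
    if (link == "log") {
      w <- mu * theta / (mu + theta)           # expected info weight
      z <- eta + (y - mu) / mu
    } else {
      w <- theta / (mu * (mu + theta))
      z <- y
    }
    wv <- sqrt(w)
    fit <- qr.coef(qr(X * wv), z * wv)
    # step-halving if the likelihood degrades or means blow up
    step <- 1
    repeat {
      beta_new <- beta + step * (fit - beta)
      eta_new <- drop(X %*% beta_new)
      mu_new <- tryCatch(nb_linkinv(eta_new, link, y), error = function(e) NULL)
      ok <- !is.null(mu_new) && all(is.finite(mu_new)) && all(mu_new < 1e12)
      if (ok) {
        dev_new <- -2 * nb_loglik(y, mu_new, theta)
        if (is.finite(dev_new) && dev_new <= dev_old + 1e-8) break
      }
      step <- step / 2
      if (step < 1e-10) { beta_new <- beta; eta_new <- eta; mu_new <- mu
                          dev_new <- dev_old; break }
    }
    beta <- beta_new; eta <- eta_new; mu <- mu_new
    if (abs(dev_new - dev_old) < tol * (abs(dev_old) + 1e-8)) break
    dev_old <- dev_new
  }
  beta
}

## Observed information for the coefficient block.
nb_obs_info <- function(y, X, mu, theta, link) {
  if (link == "log") {
    w <- theta * mu * (theta + y) / (mu + theta)^2
  } else {
    w <- y / mu^2 - (y + theta) / (mu + theta)^2
  }
  info <- crossprod(X * sqrt(pmax(w, 0)))
  dimnames(info) <- list(colnames(X), colnames(X))
  info
}

#' @export
coef.nb_fit <- function(object, ...) object$coefficients

#' @export
logLik.nb_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 1L,
            class = "logLik")
}

#' @export
print.nb_fit <- function(x, ...) {
  cat("Negative-binomial GLM (", x$link, " link)\n", sep = "")
  cat("  n =", x$n_used, " theta =", format(x$theta, digits = 4),
      if (x$theta_boundary) "(at cap: Poisson limit)" else "", "\n")
  cat("  logLik =", format(x$loglik, digits = 8),
      " converged:", x$converged, "\n")
  print(cbind(estimate = x$coefficients, se = x$standard_errors))
  invisible(x)
}

#' Wald test for one coefficient
#'
#' @param fit An `nb_fit`.
#' @param term Name of the coefficient to test.
#' @return List with `z` (estimate/SE) and two-sided normal `p`.
#' @export
wald_test <- function(fit, term) {
  stopifnot(inherits(fit, "nb_fit"))
  if (!term %in% names(fit$coefficients))
    stop("term '", term, "' not in fit", call. = FALSE)
  se <- fit$standard_errors[[term]]
  if (!is.finite(se) || se <= 0)
    stop("standard error for '", term, "' is zero or undefined",
         call. = FALSE)
  z <- fit$coefficients[[term]] / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Likelihood-ratio test between nested NB fits
#'
#' Stand-in for an F test, which has no exact theory in the NB GLM: twice
#' the log-likelihood difference is referred to a chi-square with df equal
#' to the number of dropped columns.
#'
#' @param full,reduced `nb_fit` objects on the same rows; `reduced`'s
#'   predictors must be a strict subset of `full`'s.
#' @return List with `stat`, `df`, `p`.
#' @export
group_test <- function(full, reduced) {
  stopifnot(inherits(full, "nb_fit"), inherits(reduced, "nb_fit"))
  if (full$n_used != reduced$n_used)
    stop("fits use different numbers of rows", call. = FALSE)
  if (!all(reduced$terms %in% full$terms) ||
      length(reduced$terms) > length(full$terms))
    stop("models are not nested (reduced terms must be a subset of full)",
         call. = FALSE)
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  df <- length(full$terms) - length(reduced$terms)
  if (df == 0)
    return(list(stat = stat, df = 0L, p = 1))
  list(stat = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' L1-penalized negative-binomial GLM
#'
#' Maximizes `loglik - lambda * sum(|beta_j|)` over the non-intercept
#' coefficients by cyclic coordinate descent on the IRLS-weighted quadratic
#' approximation, alternated with profile-ML dispersion.  No covariance is
#' reported: Wald inference is not valid under the L1 penalty.
#'
#' @inheritParams fit_nb
#' @param lambda Nonnegative penalty on the absolute coefficients
#'   (log-likelihood scale, not divided by n).
#' @param penalize Logical vector over columns of `X`; defaults to
#'   penalizing everything except a column named `"(Intercept)"`.
#' @return An `nb_fit` with `covariance`/`standard_errors` set to `NA` and
#'   `lambda` recorded.
#' @export
fit_nb_l1 <- function(y, X, lambda, link = c("log", "identity"),
                      penalize = NULL, theta_cap = .THETA_CAP,
                      tol = 1e-8, max_iter = 100L) {
  link <- match.arg(link)
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0)
    stop("lambda must be a single nonnegative number", call. = FALSE)
  if (any(y < 0)) stop("y must be nonnegative", call. = FALSE)
  X <- check_design(X, y)
  p <- ncol(X)
  if (is.null(penalize)) penalize <- colnames(X) != "(Intercept)"
  stopifnot(length(penalize) == p)

  m <- mean(y); v <- stats::var(y)
  theta <- if (is.finite(v) && v > m) min(max(m^2 / (v - m), 0.05), theta_cap)
           else theta_cap
  beta <- rep(0, p)
  if (any(!penalize)) beta[!penalize][1] <- if (link == "log") log(m + 0.5) else m
  eta <- drop(X %*% beta)
  mu <- nb_linkinv(eta, link, y)
  pen_ll <- nb_loglik(y, mu, theta) - lambda * sum(abs(beta[penalize]))

  converged <- FALSE
  iter <- 0L
  xsq_cache <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    # quadratic approximation at current beta
    for (relin in 1:5) {
      if (link == "log") {
        w <- mu * theta / (mu + theta)
        z <- eta + (y - mu) / mu
      } else {
        w <- theta / (mu * (mu + theta))
        z <- y
      }
      beta <- l1_cd(z, X, w, beta, lambda, penalize)
      eta_new <- drop(X %*% beta)
      eta_new <- pmin(eta_new, 30)  # guard against overflow mid-path
      mu <- nb_linkinv(eta_new, link, y)
      if (max(abs(eta_new - eta)) < 1e-9) { eta <- eta_new; break }
      eta <- eta_new
    }
    theta <- profile_theta(y, mu, cap = theta_cap)
    pen_new <- nb_loglik(y, mu, theta) - lambda * sum(abs(beta[penalize]))
    if (abs(pen_new - pen_ll) < tol * (abs(pen_ll) + 1e-8)) {
      pen_ll <- pen_new; converged <- TRUE; break
    }
    pen_ll <- pen_new
  }

  names(beta) <- colnames(X)
  structure(list(
    coefficients = beta,
    covariance = NULL,
    standard_errors = rep(NA_real_, p),
    theta = theta,
    theta_boundary = theta >= theta_cap * 0.999,
    loglik = nb_loglik(y, mu, theta),
    penalized_loglik = pen_ll,
    lambda = lambda,
    converged = converged,
    iterations = iter,
    n_used = length(y),
    link = link,
    fitted = mu,
    terms = colnames(X)
  ), class = "nb_fit")
}

## one full pass of cyclic coordinate descent on
##   1/2 sum w (z - X b)^2 + lambda sum_{penalized} |b_j|
l1_cd <- function(z, X, w, beta, lambda, penalize, max_pass = 200L,
                  tol = 1e-10) {
  p <- ncol(X)
  r <- z - drop(X %*% beta)
  xsq <- colSums(w * X^2)
  for (pass in seq_len(max_pass)) {
    delta <- 0
    for (j in seq_len(p)) {
      bj_old <- beta[j]
      rho <- sum(w * X[, j] * r) + xsq[j] * bj_old
      bj <- if (penalize[j]) soft_threshold(rho, lambda) / xsq[j]
            else rho / xsq[j]
      if (bj != bj_old) {
        r <- r - X[, j] * (bj - bj_old)
        beta[j] <- bj
        delta <- max(delta, abs(bj - bj_old))
      }
    }
    if (delta < tol) break
  }
  beta
}

soft_threshold <- function(x, lambda) sign(x) * max(abs(x) - lambda, 0)

#' Build a design matrix from a phenotype data frame
#'
#' @param data Data frame of predictors.
#' @param predictors Character vector of column names.
#' @param intercept Include a leading `(Intercept)` column of ones.
#' @return Numeric matrix with named columns.
#' @export
build_design <- function(data, predictors, intercept = TRUE) {
  missing_cols <- setdiff(predictors, names(data))
  if (length(missing_cols))
    stop("missing predictor column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  X <- as.matrix(data[predictors])
  storage.mode(X) <- "double"
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  X
}
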