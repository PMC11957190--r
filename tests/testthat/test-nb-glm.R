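test_that("constant outcome: intercept is log-mean, dispersion at cap", {
  y <- rep(7L, 50)
  f <- fit_nb(y, matrix(1, 50, 1, dimnames = list(NULL, "(Intercept)")))
  expect_equal(unname(f$coefficients), log(7), tolerance = 1e-8)
  expect_true(f$theta_boundary)  # sample variance <= mean: Poisson limit
})

test_that("coefficients maximize the joint NB likelihood (oracle match)", {
  d <- make_nb_data(600, c(3.0, 0.25, -0.3), theta = 2, seed = 21)
  f <- fit_nb(d$y, d$X)
  o <- oracle_nb_fit(d$y, d$X)
  expect_lt(max(abs(f$coefficients - o$beta) / pmax(abs(o$beta), 1e-8)),
            1e-5)
  expect_lt(abs(f$theta - o$theta) / o$theta, 1e-4)
  expect_equal(f$loglik, o$loglik, tolerance = 1e-8)

  # local-optimum probe: perturbing any coefficient lowers the likelihood
  th <- f$theta
  ll_at <- function(b) sum(dnbinom(d$y, size = th,
                                   mu = exp(drop(d$X %*% b)), log = TRUE))
  for (j in seq_along(f$coefficients)) {
    for (s in c(-1, 1)) {
      b <- f$coefficients; b[j] <- b[j] + s * 0.01
      expect_gte(f$loglik, ll_at(b))
    }
  }

  # independent implementation cross-check
  skip_if_not_installed("MASS")
  g <- MASS::glm.nb(d$y ~ d$X[, 2] + d$X[, 3])
  expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-6)
  expect_equal(f$theta, g$theta, tolerance = 1e-4)
})

test_that("parameter recovery: estimates within 2 SE of the truth", {
  d <- make_nb_data(2000, c(3.0, 0.2), theta = 2, seed = 5)
  f <- fit_nb(d$y, d$X)
  expect_lt(abs(f$coefficients[1] - 3.0), 2 * f$standard_errors[1])
  expect_lt(abs(f$coefficients[2] - 0.2), 2 * f$standard_errors[2])
  expect_true(f$converged)
})

test_that("design validation names collinear columns and checks sizes", {
  d <- make_nb_data(100, c(2, 0.3), theta = 3, seed = 2)
  X <- cbind(d$X, dup = d$X[, 2] * 2)
  expect_error(fit_nb(d$y, X), "dup")
  expect_error(fit_nb(d$y[1:50], d$X), "nrow")
  expect_error(fit_nb(rep(2L, 2), d$X[1:2, ]), "more observations")
  expect_error(fit_nb(d$y - 10, d$X), "nonnegative")
})

test_that("Poisson limit: equidispersed data reproduce Poisson GLM", {
  withr::with_seed(8, {
    x <- rnorm(800)
    y <- rpois(800, exp(2 + 0.3 * x))
  })
  X <- cbind(`(Intercept)` = 1, x = x)
  f <- fit_nb(y, X)
  g <- glm(y ~ x, family = poisson())
  expect_true(f$theta_boundary)
  expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-4)
})

test_that("Wald test: closed form, symmetry, error on zero SE", {
  f <- structure(list(coefficients = c(a = 0.4, b = 0, c = -0.4),
                      standard_errors = c(a = 0.2, b = 0.1, c = 0.2)),
                 class = "nb_fit")
  wa <- wald_test(f, "a")
  expect_equal(wa$z, 2)
  expect_equal(wa$p, 2 * pnorm(-2), tolerance = 1e-10)
  expect_equal(wald_test(f, "b")$p, 1)
  expect_equal(wald_test(f, "c")$p, wa$p)
  f$standard_errors[["a"]] <- 0
  expect_error(wald_test(f, "a"), "zero")
  expect_error(wald_test(f, "nope"), "not in fit")
})

test_that("likelihood-ratio group test: nesting, null stat, equivalence", {
  d <- make_nb_data(400, c(3, 0.3, -0.2), theta = 3, seed = 31)
  full <- fit_nb(d$y, d$X)
  red <- fit_nb(d$y, d$X[, 1:2])
  gt <- group_test(full, red)
  expect_gte(gt$stat, 0)
  expect_equal(gt$df, 1)
  # identical model: stat ~ 0, p ~ 1
  self <- group_test(full, full)
  expect_lt(abs(self$stat), 1e-6)
  expect_equal(self$p, 1)
  # non-nested inputs rejected
  other <- fit_nb(d$y, cbind(d$X[, 1, drop = FALSE],
                             z = seq_len(400) / 400))
  expect_error(group_test(red, other), "not nested")

  # df=1: LRT statistic approximates squared Wald z on null data
  d0 <- make_nb_data(5000, c(3, 0.3, 0), theta = 3, seed = 77)
  f0 <- fit_nb(d0$y, d0$X)
  r0 <- fit_nb(d0$y, d0$X[, 1:2])
  lrt <- group_test(f0, r0)$stat
  wz <- wald_test(f0, colnames(d0$X)[3])$z
  expect_lt(abs(lrt - wz^2), 0.05 * max(wz^2, 0.5))
})

test_that("LRT has power against a planted covariate effect", {
  rej <- vapply(1:40, function(s) {
    d <- make_nb_data(1000, c(3, 0.2, 0.5), theta = 3, seed = 4000 + s)
    full <- fit_nb(d$y, d$X)
    red <- fit_nb(d$y, d$X[, 1:2])
    group_test(full, red)$p < 0.01
  }, TRUE)
  expect_gte(mean(rej), 0.95)
})

test_that("L1 fit: penalty-free limit, full shrinkage, selection order", {
  d <- make_nb_data(500, c(2.5, 0.4, -0.3), theta = 3, seed = 13)
  f0 <- fit_nb(d$y, d$X)
  fl0 <- fit_nb_l1(d$y, d$X, lambda = 0)
  expect_lt(max(abs(f0$coefficients - fl0$coefficients)), 1e-4)

  # huge penalty: slopes exactly zero, intercept = log mean
  fbig <- fit_nb_l1(d$y, d$X, lambda = 1e7)
  expect_equal(unname(fbig$coefficients[-1]), c(0, 0))
  expect_equal(unname(fbig$coefficients[1]), log(mean(d$y)),
               tolerance = 1e-6)
  expect_true(all(is.na(fbig$standard_errors)))  # no Wald inference

  # nulls leave the model before true predictors along the path
  withr::with_seed(99, {
    n <- 400
    X <- cbind(`(Intercept)` = 1,
               matrix(rnorm(n * 10), n,
                      dimnames = list(NULL, paste0("v", 1:10))))
    beta <- c(3, 0.5, -0.5, rep(0, 8))
    y <- rnbinom(n, mu = exp(drop(X %*% beta)), size = 5)
  })
  lams <- c(1, 5, 20, 60, 150)
  drop_lam <- function(j) {
    for (l in lams)
      if (fit_nb_l1(y, X, lambda = l)$coefficients[j] == 0) return(l)
    Inf
  }
  true_drop <- min(drop_lam("v1"), drop_lam("v2"))
  null_drop <- vapply(paste0("v", 3:10), drop_lam, 0)
  expect_gte(mean(null_drop < true_drop), 0.8)
})

test_that("identity link rejects nonpositive means and fits valid data", {
  withr::with_seed(55, {
    x <- runif(300, 0, 1)
    y <- rnbinom(300, mu = 10 + 5 * x, size = 4)
  })
  X <- cbind(`(Intercept)` = 1, x = x)
  f <- fit_nb(y, X, link = "identity")
  expect_true(f$converged)
  expect_lt(abs(f$coefficients[1] - 10), 3 * f$standard_errors[1])
  # a slope-only design that forces a negative fitted mean on one arm
  y2 <- c(rep(20L, 50), rep(1L, 50))
  X2 <- cbind(s = rep(c(1, -1), each = 50))
  expect_error(fit_nb(y2, X2, link = "identity"), "nonpositive")
  expect_s3_class(fit_nb(y2, cbind(`(Intercept)` = 1, X2)), "nb_fit")
})
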