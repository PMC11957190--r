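#' Model comparison and robustness checks
#'
#' 10-fold cross-validated Spearman correlation for comparing NB
#' regression feature sets, and the cross-wave consistency test: do the
#' miRNAs discovered in one wave retain elevated modulation scores in the
#' other wave?
#'
#' @name validate
NULL

#' Spearman rank correlation
#'
#' Average-rank tie handling; errors on constant input, where the rank
#' correlation is undefined.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation undefined for constant input", call. = FALSE)
  stats::cor(x, y, method = "spearman")
}

#' K-fold cross-validated Spearman correlation of an NB regression
#'
#' Samples are shuffled with the given seed and split into k contiguous
#' near-equal folds.  For each fold, the NB model is fitted (dispersion
#' re-profiled) on the remaining folds and held-out outcomes are compared
#' with predicted means by Spearman correlation.  Since Spearman is
#' invariant to the monotone log link, ranking by predicted mean equals
#' ranking by linear predictor.
#'
#' @param y Outcome vector.
#' @param X Design matrix (with intercept).
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold-assignment shuffle (mandatory for
#'   reproducibility).
#' @param link Passed to [fit_nb()].
#' @return List of class `"cv_result"`: `k`, `per_fold_rho`, `mean_rho`
#'   (over non-missing folds), `seed`, `model_spec`.
#' @export
kfold_cv_spearman <- function(y, X, k = 10L, seed, link = "log") {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  X <- check_design(X, y)
  n <- length(y)
  if (n < 2 * k) stop("need n >= 2k for ", k, "-fold CV", call. = FALSE)
  folds <- withr::with_seed(seed, {
    idx <- sample.int(n)
    split(idx, cut(seq_len(n), breaks = k, labels = FALSE))
  })
  rho <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    test <- folds[[f]]
    train <- setdiff(seq_len(n), test)
    fit <- fit_nb(y[train], X[train, , drop = FALSE], link = link)
    pred <- if (link == "log") exp(drop(X[test, , drop = FALSE] %*%
                                          fit$coefficients))
            else drop(X[test, , drop = FALSE] %*% fit$coefficients)
    if (stats::sd(y[test]) == 0 || stats::sd(pred) == 0) {
      warning("fold ", f, " has constant outcome or prediction; ",
              "excluded from the mean", call. = FALSE)
      next
    }
    rho[f] <- spearman(y[test], pred)
  }
  structure(list(k = k, per_fold_rho = rho,
                 mean_rho = mean(rho, na.rm = TRUE), seed = seed,
                 model_spec = colnames(X)),
            class = "cv_result")
}

#' Cross-wave consistency of modulation scores
#'
#' One-sided Wilcoxon rank-sum test that the discovery-wave hit miRNAs
#' have higher modulation scores in the validation wave than the remaining
#' miRNAs.  Exact enumeration when both groups have at most 10 members and
#' the scores are tie-free; normal approximation with tie correction
#' otherwise.
#'
#' @param scores_all Named numeric vector: validation-wave modulation
#'   score per miRNA.
#' @param hit_ids Character vector of discovery-wave hit miRNA ids; must
#'   be a nonempty strict subset of `names(scores_all)`.
#' @return List: `W` (rank-sum statistic), `p` (one-sided, hits greater),
#'   `method`.
#' @export
cross_wave_consistency <- function(scores_all, hit_ids) {
  if (is.null(names(scores_all)))
    stop("scores_all must be named by miRNA id", call. = FALSE)
  hit_ids <- unique(hit_ids)
  if (length(hit_ids) == 0) stop("hit set is empty", call. = FALSE)
  missing_ids <- setdiff(hit_ids, names(scores_all))
  if (length(missing_ids))
    stop("hit id(s) not scored: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  if (length(hit_ids) >= length(scores_all))
    stop("hit set must be strictly smaller than the full miRNA set",
         call. = FALSE)
  hits <- scores_all[hit_ids]
  others <- scores_all[setdiff(names(scores_all), hit_ids)]
  ties <- anyDuplicated(c(hits, others)) > 0
  exact <- !ties && length(hits) <= 10 && length(others) <= 10
  if (!ties || length(unique(c(hits, others))) > 1) {
    wt <- suppressWarnings(
      stats::wilcox.test(hits, others, alternative = "greater",
                         exact = exact, correct = !exact))
    p <- wt$p.value
    W <- unname(wt$statistic)
  } else {
    # all scores identical: zero rank variance, no separation
    W <- length(hits) * length(others) / 2
    p <- 0.5
  }
  if (!is.finite(p)) p <- 0.5
  list(W = W, p = p,
       method = if (exact) "exact" else "normal_approximation")
}
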