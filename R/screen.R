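#' Genome-wide main-effect and interaction screens
#'
#' Two screens over the miRNA axis, both NB regressions of PTSS on the
#' five lifetime social adversities:
#' \itemize{
#'   \item main effect: `PTSS ~ sum_i a_i adv_i + b miRNA`, testing b;
#'   \item interaction: `PTSS ~ sum_i a_i adv_i + b miRNA +
#'     c (adv_j * miRNA)`, testing c — the modulation model.
#' }
#' The modulation score is the Wald z of c (c divided by its standard
#' error); positive scores mean higher miRNA expression strengthens the
#' adversity-PTSS association, negative scores a protective attenuation.
#' P-values are BH-adjusted across miRNAs within each screen and hits are
#' declared at FDR strictly below the threshold (default 0.1).
#'
#' @name screen
NULL

#' Modulation score
#'
#' The interaction coefficient divided by its standard error (a Wald z).
#'
#' @param estimate Coefficient c.
#' @param se Its standard error (> 0).
#' @export
modulation_score <- function(estimate, se) {
  if (any(!is.finite(se)) || any(se <= 0))
    stop("se must be positive", call. = FALSE)
  estimate / se
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment `q_(i) = min_{j >= i} p_(j) m / j`, capped at 1.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted values in input order.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Median stratification of an expression profile
#'
#' Labels samples `high` when strictly above the median and `low`
#' otherwise (ties to low); used to draw stratified adversity-PTSS slopes.
#'
#' @param expr_row Numeric expression values for one miRNA.
#' @return Factor with levels `low`, `high`.
#' @export
median_stratify <- function(expr_row) {
  if (length(expr_row) == 0) stop("empty expression vector", call. = FALSE)
  factor(ifelse(expr_row > stats::median(expr_row), "high", "low"),
         levels = c("low", "high"))
}

#' Filter screen records to significant hits
#'
#' @param records A `screen_records` data frame.
#' @param fdr_threshold Strict FDR cutoff (default 0.1).
#' @return Rows with `q < fdr_threshold`, ordered by q then |score|
#'   descending.
#' @export
significant_hits <- function(records, fdr_threshold = 0.1) {
  hits <- records[!is.na(records$q) & records$q < fdr_threshold, ,
                  drop = FALSE]
  hits[order(hits$q, -abs(hits$score)), , drop = FALSE]
}

## Shared per-miRNA fitting loop.  `extra_cols` appends the miRNA (and
## optionally the product) column(s) to the adversity base design.
run_screen <- function(norm, pheno, adversity, expr_wave, outcome_wave,
                       covariates, fdr_threshold, standardize_expression) {
  aligned <- align_samples(norm, pheno, expr_wave, outcome_wave,
                           covariates = covariates)
  dat <- aligned$data
  ex <- aligned$expression
  y <- dat$ptss
  base <- build_design(dat, c(ADVERSITIES, covariates))

  interaction <- !identical(adversity, "none")
  adv_vec <- if (interaction) dat[[adversity]] else NULL

  mirnas <- rownames(ex)
  out <- vector("list", length(mirnas))
  for (i in seq_along(mirnas)) {
    x <- as.numeric(ex[i, ])
    if (standardize_expression && stats::sd(x) > 0)
      x <- (x - mean(x)) / stats::sd(x)
    rec <- list(mirna_id = mirnas[i],
                adversity = if (interaction) adversity else "none",
                expr_wave = expr_wave, outcome_wave = outcome_wave,
                estimate = NA_real_, se = NA_real_, score = NA_real_,
                p = NA_real_, q = NA_real_, n_used = length(y),
                converged = FALSE, estimable = FALSE)
    if (stats::sd(x) == 0) {
      out[[i]] <- rec
      next
    }
    X <- cbind(base, mirna = x)
    term <- "mirna"
    if (interaction) {
      X <- cbind(X, interaction = adv_vec * x)
      term <- "interaction"
    }
    fit <- tryCatch(fit_nb(y, X), error = function(e) NULL)
    if (is.null(fit)) { out[[i]] <- rec; next }
    rec$converged <- fit$converged
    se <- fit$standard_errors[[term]]
    if (fit$converged && is.finite(se) && se > 0) {
      w <- wald_test(fit, term)
      rec$estimate <- fit$coefficients[[term]]
      rec$se <- se
      rec$score <- w$z
      rec$p <- w$p
      rec$estimable <- TRUE
    }
    out[[i]] <- rec
  }
  records <- do.call(rbind, lapply(out, as.data.frame))
  # BH across the miRNA axis; non-estimable fits are excluded from the
  # denominator and carry no q
  est <- records$estimable
  records$q[est] <- bh_fdr(records$p[est])
  attr(records, "dropped") <- aligned$dropped
  attr(records, "fdr_threshold") <- fdr_threshold
  class(records) <- c("screen_records", "data.frame")
  records
}

#' Main-effect screen of miRNAs on PTSS
#'
#' Per miRNA, fits `PTSS ~ adversities + miRNA` by NB regression and Wald-
#' tests the miRNA coefficient b; BH-FDR across the miRNA axis.
#'
#' @param norm Normalized expression matrix (log2 CPM + 1), miRNA x
#'   sample.
#' @param pheno Phenotype table ([read_phenotype()] schema).
#' @param expr_wave,outcome_wave The (expression, outcome) wave pairing,
#'   e.g. 2 and 3.
#' @param covariates Optional covariate columns added to every model.
#' @param fdr_threshold Strict FDR cutoff used by [significant_hits()].
#' @param standardize_expression Z-score each miRNA across samples before
#'   fitting (changes coefficient units; off by default).
#' @return A `screen_records` data frame, one row per miRNA: `estimate`
#'   (b), `se`, `score`, `p`, `q`, `n_used`, `converged`, `estimable`.
#' @export
main_effect_screen <- function(norm, pheno, expr_wave, outcome_wave,
                               covariates = NULL, fdr_threshold = 0.1,
                               standardize_expression = FALSE) {
  run_screen(norm, pheno, "none", expr_wave, outcome_wave, covariates,
             fdr_threshold, standardize_expression)
}

#' Adversity-by-miRNA interaction screen
#'
#' Per miRNA, fits `PTSS ~ sum_i a_i adv_i + b miRNA + c (adv_j * miRNA)`
#' with all five adversities retained additively, and Wald-tests the
#' interaction coefficient c.  `estimate` is c and `score` is the
#' modulation score c/SE; BH-FDR across the miRNA axis within this
#' adversity.
#'
#' @inheritParams main_effect_screen
#' @param adversity Which adversity j forms the product term: one of
#'   `"trauma_lifetime"`, `"financial_lifetime"`, `"emotional_lifetime"`,
#'   `"discrimination"`, `"loneliness"`.
#' @return A `screen_records` data frame, one row per miRNA.
#' @export
interaction_screen <- function(norm, pheno, adversity, expr_wave,
                               outcome_wave, covariates = NULL,
                               fdr_threshold = 0.1,
                               standardize_expression = FALSE) {
  adversity <- match.arg(adversity, ADVERSITIES)
  run_screen(norm, pheno, adversity, expr_wave, outcome_wave, covariates,
             fdr_threshold, standardize_expression)
}

#' Write screen records to TSV
#' @param records A `screen_records` data frame.
#' @param path Output path.
#' @export
write_screen_records <- function(records, path) {
  utils::write.table(as.data.frame(records), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read screen records from TSV
#' @param path Input path.
#' @export
read_screen_records <- function(path) {
  records <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(records) <- c("screen_records", "data.frame")
  records
}
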