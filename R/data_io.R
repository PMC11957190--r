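#' Reading, writing, and survey aggregation
#'
#' Tabular I/O for the cohort inputs and the survey-aggregation arithmetic:
#' PCL-C symptom sums, lifetime adversity aggregation, CPM normalization,
#' low-expression filtering and expression/phenotype sample alignment.
#'
#' @name data_io
NULL

## Fixed phenotype schema.  One row per (participant, wave); the wave-2/4
## rows carry the biospecimen sample id matching an expression column.
PHENO_REQUIRED <- c("sample_id", "participant_id", "wave", "ptss",
                    "trauma_lifetime", "financial_lifetime",
                    "emotional_lifetime", "discrimination", "loneliness")

ADVERSITIES <- c("trauma_lifetime", "financial_lifetime",
                 "emotional_lifetime", "discrimination", "loneliness")

#' PCL-C symptom-severity sum
#'
#' PTSS is the sum of the 17 PCL-C symptom items, each scored 1-5, so the
#' total lies in \[17, 85\].
#'
#' @param items Integer vector of exactly 17 item scores in 1..5.
#' @return Integer sum.
#' @export
ptss_from_items <- function(items) {
  if (length(items) != 17)
    stop("PCL-C has 17 items; got ", length(items), call. = FALSE)
  if (any(!is.finite(items)) || any(items < 1 | items > 5) ||
      any(abs(items - round(items)) > 1e-8))
    stop("PCL-C items must be integers in 1..5", call. = FALSE)
  as.integer(sum(items))
}

#' Lifetime cumulative trauma
#'
#' Totals the trauma-event counts reported across all survey waves.
#'
#' @param per_wave_counts Nonnegative integer vector, one entry per wave.
#' @return Integer sum across waves.
#' @export
lifetime_trauma <- function(per_wave_counts) {
  if (length(per_wave_counts) == 0)
    stop("need at least one wave of trauma counts", call. = FALSE)
  if (any(!is.finite(per_wave_counts)) || any(per_wave_counts < 0))
    stop("trauma counts must be nonnegative", call. = FALSE)
  as.integer(sum(per_wave_counts))
}

#' Lifetime any-occurrence of a binary stressor
#'
#' Lifetime emotional mistreatment and financial problems are coded 1 if
#' the stressor was reported in any wave.
#'
#' @param per_wave_flags Vector of 0/1 flags, one per wave.
#' @return 0 or 1.
#' @export
lifetime_any <- function(per_wave_flags) {
  if (length(per_wave_flags) == 0)
    stop("need at least one wave of flags", call. = FALSE)
  if (!all(per_wave_flags %in% c(0, 1)))
    stop("flags must be 0 or 1", call. = FALSE)
  as.integer(any(per_wave_flags == 1))
}

#' Multi-item scale score
#'
#' Sum of the item responses of a fixed-length scale (9 items for the
#' Everyday Discrimination Scale, 3 for the loneliness scale).  `mean =
#' TRUE` averages instead, for surveys reported on the per-item scale.
#'
#' @param items Numeric item responses.
#' @param expected_len Required number of items.
#' @param mean Average instead of sum.
#' @return Numeric score.
#' @export
scale_score <- function(items, expected_len, mean = FALSE) {
  if (length(items) != expected_len)
    stop("expected ", expected_len, " items; got ", length(items),
         call. = FALSE)
  if (any(!is.finite(items)))
    stop("scale items must be finite", call. = FALSE)
  if (mean) base::mean(items) else sum(items)
}

#' Read a miRNA count matrix
#'
#' TSV with miRNA ids in the first column and one column per sample;
#' cells are nonnegative integer counts.
#'
#' @param path File path.
#' @return Integer matrix, rownames = miRNA ids, colnames = sample ids.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression TSV needs an id column plus samples",
                         call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicated miRNA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  m <- as.matrix(df[-1])
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < 0) || any(abs(m - round(m)) > 1e-8))
    stop("counts must be nonnegative integers", call. = FALSE)
  rownames(m) <- ids
  m
}

#' Write a miRNA count matrix
#' @param counts Matrix as returned by [read_expression()].
#' @param path Output TSV path.
#' @export
write_expression <- function(counts, path) {
  df <- data.frame(mirna_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the per-sample phenotype table
#'
#' CSV with the documented schema: `sample_id`, `participant_id`, `wave`,
#' `ptss`, the five lifetime adversities (`trauma_lifetime`,
#' `financial_lifetime`, `emotional_lifetime`, `discrimination`,
#' `loneliness`) and any number of optional numeric covariate columns
#' (age, sex, prs, cell-surrogate proportions).
#'
#' @param path File path.
#' @return Data frame, validated.
#' @export
read_phenotype <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_phenotype(df)
}

#' @rdname read_phenotype
#' @param pheno Phenotype data frame to validate in place.
#' @export
validate_phenotype <- function(pheno) {
  missing_cols <- setdiff(PHENO_REQUIRED, names(pheno))
  if (length(missing_cols))
    stop("phenotype table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(pheno$sample_id))
    stop("duplicated sample_id(s): ",
         paste(unique(pheno$sample_id[duplicated(pheno$sample_id)]),
               collapse = ", "), call. = FALSE)
  for (col in c("financial_lifetime", "emotional_lifetime")) {
    v <- pheno[[col]]
    if (!all(v[!is.na(v)] %in% c(0, 1)))
      stop(col, " must be 0/1", call. = FALSE)
  }
  ok <- is.na(pheno$ptss) | pheno$ptss >= 0
  if (!all(ok)) stop("ptss must be nonnegative", call. = FALSE)
  cell_cols <- grep("^cell_", names(pheno), value = TRUE)
  for (col in cell_cols) {
    v <- pheno[[col]]
    if (any(v[!is.na(v)] < 0 | v[!is.na(v)] > 1))
      stop(col, " proportions must lie in [0, 1]", call. = FALSE)
  }
  pheno
}

#' Write the phenotype table
#' @param pheno Phenotype data frame.
#' @param path Output CSV path.
#' @export
write_phenotype <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' log2 counts-per-million normalization
#'
#' `value[i, s] = log2(counts[i, s] / total_s * 1e6 + 1)`.  Invariant to
#' per-sample rescaling of the counts and monotone in counts within a
#' sample.
#'
#' @param counts Nonnegative count matrix (miRNA x sample).
#' @return Matrix of log2(CPM + 1) values, same dimnames.
#' @export
cpm_log_normalize <- function(counts) {
  totals <- colSums(counts)
  if (any(totals <= 0)) {
    bad <- colnames(counts)[totals <= 0]
    if (is.null(bad)) bad <- which(totals <= 0)
    stop("sample(s) with zero total count: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  log2(sweep(counts, 2, totals, "/") * 1e6 + 1)
}

#' Drop low-abundance miRNAs
#'
#' Retains miRNAs whose CPM is at least `min_cpm` in at least
#' `min_fraction` of samples.  The sample axis is unchanged.
#'
#' @param counts Count matrix.
#' @param min_cpm CPM floor (default 1).
#' @param min_fraction Required fraction of samples at or above the floor
#'   (default 0.5).
#' @return Filtered count matrix (possibly with zero rows).
#' @export
filter_low_expression <- function(counts, min_cpm = 1, min_fraction = 0.5) {
  if (min_fraction < 0 || min_fraction > 1)
    stop("min_fraction must lie in [0, 1]", call. = FALSE)
  cpm <- sweep(counts, 2, colSums(counts), "/") * 1e6
  keep <- rowMeans(cpm >= min_cpm) >= min_fraction
  counts[keep, , drop = FALSE]
}

#' Align expression samples with phenotype outcomes across waves
#'
#' Pairs the expression wave with the outcome wave (the study design pairs
#' wave-2 expression with wave-3 PTSS, and wave 4 with itself): expression
#' columns are matched to phenotype rows of `expr_wave` via their sample
#' id, then joined by participant to the outcome and lifetime-adversity
#' fields of the `outcome_wave` rows.  Complete cases only; every dropped
#' record is logged with a reason.
#'
#' @param expr Expression matrix (counts or normalized), columns = sample
#'   ids.
#' @param pheno Phenotype data frame ([read_phenotype()] schema).
#' @param expr_wave Wave of the expression samples.
#' @param outcome_wave Wave supplying PTSS.
#' @param covariates Optional covariate column names to carry through
#'   (complete-case over these too).
#' @return List: `data` (one row per retained participant: ids, ptss,
#'   adversities, covariates), `expression` (matrix subset, columns in row
#'   order of `data`), `dropped` (data frame sample_id/reason).
#' @export
align_samples <- function(expr, pheno, expr_wave, outcome_wave,
                          covariates = NULL) {
  pheno <- validate_phenotype(pheno)
  pe <- pheno[pheno$wave == expr_wave & !is.na(pheno$sample_id), ]
  po <- pheno[pheno$wave == outcome_wave, ]
  dropped <- list()
  note <- function(ids, reason) {
    if (length(ids))
      dropped[[length(dropped) + 1]] <<- data.frame(sample_id = ids,
                                                    reason = reason)
  }

  cols <- colnames(expr)
  in_pheno <- cols %in% pe$sample_id
  note(cols[!in_pheno], "no_phenotype_row_in_expression_wave")
  cols <- cols[in_pheno]
  if (anyDuplicated(pe$participant_id))
    stop("multiple biospecimens per participant in wave ", expr_wave,
         call. = FALSE)
  part <- pe$participant_id[match(cols, pe$sample_id)]

  out_row <- match(part, po$participant_id)
  note(cols[is.na(out_row)], "no_outcome_wave_record")
  keep <- !is.na(out_row)
  cols <- cols[keep]; part <- part[keep]; out_row <- out_row[keep]

  need <- c("ptss", ADVERSITIES, covariates)
  po_need <- po[out_row, need, drop = FALSE]
  complete <- stats::complete.cases(po_need)
  note(cols[!complete], "missing_required_field")
  cols <- cols[complete]; part <- part[complete]
  po_need <- po_need[complete, , drop = FALSE]

  if (length(cols) == 0)
    stop("no samples shared between expression wave ", expr_wave,
         " and outcome wave ", outcome_wave, call. = FALSE)

  data <- data.frame(participant_id = part, sample_id = cols,
                     po_need, row.names = NULL, check.names = FALSE)
  dropped <- if (length(dropped)) do.call(rbind, dropped)
             else data.frame(sample_id = character(), reason = character())
  list(data = data,
       expression = expr[, cols, drop = FALSE],
       dropped = dropped)
}

#' Write a dropped-record manifest
#' @param dropped Data frame (sample_id, reason) from [align_samples()].
#' @param path Output TSV path.
#' @export
write_dropped_manifest <- function(dropped, path) {
  utils::write.table(dropped, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
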