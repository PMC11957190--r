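#' Target-gene pathway enrichment
#'
#' Maps significant miRNAs to their predicted target genes (binding-score
#' filtered, miRDB-style), pools the targets per screen, and tests each
#' pathway gene set for over-representation with an upper-tail
#' hypergeometric test, BH-adjusted across pathways.
#'
#' @name enrichment
NULL

#' Read a miRNA target table
#'
#' TSV with columns `mirna`, `gene`, `score`.  Rows with a binding score
#' at or above the cutoff are retained (the cutoff is inclusive);
#' duplicate (mirna, gene) pairs collapse to their maximum score.
#'
#' @param path File path.
#' @param score_cutoff Minimum binding score kept (default 80).
#' @return Data frame of class `"target_table"` (mirna, gene, score).
#' @export
read_target_table <- function(path, score_cutoff = 80) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna", "gene", "score")
  if (!all(need %in% names(df)))
    stop("target table needs columns mirna, gene, score", call. = FALSE)
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$score))) |
                 is.na(df$mirna) | is.na(df$gene) |
                 df$mirna == "" | df$gene == "")
  if (length(bad))
    stop("malformed target-table row(s) at line(s): ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  df$score <- as.numeric(df$score)
  filter_target_table(df, score_cutoff)
}

#' @rdname read_target_table
#' @param targets In-memory data frame (mirna, gene, score) to filter.
#' @export
filter_target_table <- function(targets, score_cutoff = 80) {
  df <- targets[targets$score >= score_cutoff, , drop = FALSE]
  # collapse duplicates keeping the maximum score
  key <- paste(df$mirna, df$gene, sep = "\r")
  df <- df[order(key, -df$score), ]
  df <- df[!duplicated(paste(df$mirna, df$gene, sep = "\r")), ]
  rownames(df) <- NULL
  structure(df, class = c("target_table", "data.frame"))
}

#' Read a GMT gene-set file
#'
#' Standard gene-matrix-transposed format: one tab-separated line per set
#' (name, description, genes...).  Lines with no genes are skipped with a
#' warning; duplicated genes within a line are stored once.
#'
#' @param path File path.
#' @param universe Optional explicit gene universe (character vector);
#'   default is the union of all set genes.
#' @return List of class `"gene_set_collection"`: `sets` (named list of
#'   gene-id vectors), `names` (named descriptions), `universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty GMT file: ", path, call. = FALSE)
  sets <- list(); descs <- character()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    genes <- unique(parts[-(1:2)][nzchar(parts[-(1:2)])])
    if (length(parts) < 3 || length(genes) == 0) {
      warning("GMT set '", parts[1], "' has no genes; skipped",
              call. = FALSE)
      next
    }
    sets[[parts[1]]] <- genes
    descs[[parts[1]]] <- parts[2]
  }
  if (length(sets) == 0) stop("no usable gene sets in ", path, call. = FALSE)
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  structure(list(sets = sets, names = descs, universe = universe),
            class = "gene_set_collection")
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' `P(X >= overlap)` for X hypergeometric with population `N =
#' |universe|`, `K = |pathway|` successes, and `n = |targets in universe|`
#' draws.
#'
#' @param target_genes Character vector of target gene ids (the draw; its
#'   intersection with the universe is used).
#' @param pathway Character vector of pathway gene ids (must lie within
#'   the universe).
#' @param universe Character vector of background gene ids.
#' @export
hypergeom_enrich <- function(target_genes, pathway, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  pathway <- unique(pathway)
  if (length(setdiff(pathway, universe)))
    stop("pathway genes outside the universe", call. = FALSE)
  draw <- intersect(unique(target_genes), universe)
  k <- length(intersect(draw, pathway))
  stats::phyper(k - 1, length(pathway), length(universe) - length(pathway),
                length(draw), lower.tail = FALSE)
}

#' Enrichment of pooled miRNA target genes across all pathways
#'
#' The target genes of the hit miRNAs are pooled by set union (no
#' multiplicity weighting) and tested against every pathway; p-values are
#' BH-adjusted across pathways and rows with `q <` the threshold are
#' flagged significant.  The default universe is all genes in the filtered
#' target table together with all pathway genes — universe choice is the
#' dominant analytic degree of freedom, so it is returned with the table.
#'
#' @param hit_mirnas Character vector of significant miRNA ids.
#' @param targets A `target_table` (already score-filtered).
#' @param sets A `gene_set_collection`.
#' @param fdr_threshold Strict adjusted-p cutoff (default 0.1).
#' @param universe Optional explicit universe override.
#' @return Data frame: pathway_id, name, overlap, K, n, N, p, q,
#'   significant; attribute `"universe"` carries the universe used.
#' @export
enrich_all <- function(hit_mirnas, targets, sets, fdr_threshold = 0.1,
                       universe = NULL) {
  hit_mirnas <- unique(hit_mirnas)
  if (length(hit_mirnas) == 0) stop("no hit miRNAs supplied", call. = FALSE)
  no_targets <- setdiff(hit_mirnas, unique(targets$mirna))
  if (length(no_targets))
    stop("hit miRNA(s) with no retained targets: ",
         paste(no_targets, collapse = ", "), call. = FALSE)
  target_genes <- unique(targets$gene[targets$mirna %in% hit_mirnas])
  if (is.null(universe))
    universe <- sort(unique(c(targets$gene, unlist(sets$sets))))
  rows <- lapply(names(sets$sets), function(id) {
    pw <- intersect(sets$sets[[id]], universe)
    draw <- intersect(target_genes, universe)
    data.frame(pathway_id = id,
               name = unname(sets$names[id]),
               overlap = length(intersect(draw, pw)),
               K = length(pw), n = length(draw), N = length(universe),
               p = hypergeom_enrich(target_genes, pw, universe))
  })
  tab <- do.call(rbind, rows)
  tab$q <- bh_fdr(tab$p)
  tab$significant <- tab$q < fdr_threshold
  tab <- tab[order(tab$q, tab$p), ]
  rownames(tab) <- NULL
  attr(tab, "universe") <- universe
  tab
}
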