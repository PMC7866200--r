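# TFBS enrichment: per matrix, promoter-level binary occurrence in DEG vs
# reference promoters forms a 2x2 table tested one-sided by Fisher's exact
# test. The adjusted fold enrichment FE_adj is the lower bound of the
# Woolf 99% confidence interval of the odds ratio, with the
# Haldane-Anscombe +0.5 correction applied to all cells iff any cell is
# zero. FDR is Benjamini-Hochberg across the matrices of one analysis.

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up procedure with monotonicity enforcement, as in
#' [stats::p.adjust()]; inputs are validated to lie in (0, 1\].
#'
#' @param pvalues numeric vector of p-values in (0, 1\].
#' @return Adjusted p-values of the same length.
#' @export
fdr_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Enrichment of one matrix in DEG promoters versus reference promoters
#'
#' Counts promoters with >= 1 hit to form the 2x2 table
#' `a` (DEG with hit), `b` (DEG without), `c` (reference with hit),
#' `d` (reference without). One-sided Fisher exact test (enrichment);
#' `odds_ratio = (a*d)/(b*c)` and
#' `fe_adj = exp(ln OR - z_0.995 * sqrt(1/a + 1/b + 1/c + 1/d))`,
#' both on the +0.5-corrected table iff any raw cell is zero.
#'
#' @param deg_hits,ref_hits hit data.frames (as from [scan_sequences()])
#'   for one matrix on the DEG and reference promoter sets.
#' @param deg_promoters,ref_promoters character vectors of the promoter
#'   ids making up the two sets; hits outside them are an error.
#' @param matrix_id,tf_name annotation carried into the record (defaults
#'   taken from the hits when present).
#' @return One-row data.frame: `matrix_id, tf_name, a, b, c, d,
#'   odds_ratio, fe_adj, fisher_p`.
#' @export
enrich_matrix <- function(deg_hits, ref_hits, deg_promoters,
                          ref_promoters, matrix_id = NULL,
                          tf_name = NA_character_) {
  n_deg <- length(deg_promoters)
  n_ref <- length(ref_promoters)
  if (n_deg == 0L || n_ref == 0L)
    stop("both promoter sets must be non-empty", call. = FALSE)
  if (nrow(deg_hits) && !all(deg_hits$promoter_id %in% deg_promoters))
    stop("DEG hits reference promoters outside the declared DEG set",
         call. = FALSE)
  if (nrow(ref_hits) && !all(ref_hits$promoter_id %in% ref_promoters))
    stop("reference hits reference promoters outside the declared reference set",
         call. = FALSE)
  if (is.null(matrix_id))
    matrix_id <- if (nrow(deg_hits)) deg_hits$matrix_id[1]
                 else if (nrow(ref_hits)) ref_hits$matrix_id[1]
                 else NA_character_
  a <- length(unique(deg_hits$promoter_id))
  b <- n_deg - a
  c_ <- length(unique(ref_hits$promoter_id))
  d <- n_ref - c_
  fisher_p <- stats::fisher.test(matrix(c(a, b, c_, d), 2),
                                 alternative = "greater")$p.value
  cells <- c(a, b, c_, d)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  fe_adj <- exp(log(or) - stats::qnorm(0.995) * sqrt(sum(1 / cells)))
  data.frame(matrix_id = matrix_id, tf_name = tf_name, a = a, b = b,
             c = c_, d = d, odds_ratio = or, fe_adj = fe_adj,
             fisher_p = fisher_p, stringsAsFactors = FALSE)
}

#' Enrichment table for a whole matrix library
#'
#' Runs [enrich_matrix()] for every matrix id and applies
#' Benjamini-Hochberg FDR across the matrices of this analysis.
#'
#' @param deg_hits,ref_hits combined hit data.frames over all matrices.
#' @param deg_promoters,ref_promoters promoter id vectors of the two sets.
#' @param matrix_to_tf named character vector, matrix id -> TF name (see
#'   [matrix_tf_map()]); also fixes which matrices are scored (matrices
#'   with no hits anywhere still get a record).
#' @param fe_min,fe_high,fdr_max significance cutoffs (defaults 1.25, 1.5,
#'   0.05; strict inequalities on fe and fdr).
#' @return data.frame with one row per matrix: the [enrich_matrix()]
#'   columns plus `fdr`, `significant` (`fe_adj > fe_min & fdr < fdr_max`)
#'   and `highly_enriched` (`fe_adj > fe_high` and significant).
#' @export
enrich_library <- function(deg_hits, ref_hits, deg_promoters,
                           ref_promoters, matrix_to_tf,
                           fe_min = 1.25, fe_high = 1.5, fdr_max = 0.05) {
  ids <- names(matrix_to_tf)
  recs <- lapply(ids, function(id)
    enrich_matrix(deg_hits[deg_hits$matrix_id == id, , drop = FALSE],
                  ref_hits[ref_hits$matrix_id == id, , drop = FALSE],
                  deg_promoters, ref_promoters, matrix_id = id,
                  tf_name = matrix_to_tf[[id]]))
  out <- do.call(rbind, recs)
  out$fdr <- fdr_adjust(out$fisher_p)
  out$significant <- out$fe_adj > fe_min & out$fdr < fdr_max
  out$highly_enriched <- out$significant & out$fe_adj > fe_high
  out <- out[order(-out$fe_adj), ]
  rownames(out) <- NULL
  stage_log("enrich", matrices = nrow(out),
            significant = sum(out$significant))
  out
}

#' Collapse matrix-level enrichment records to one row per TF
#'
#' A TF may own several matrices; its summary takes the maximal `fe_adj`
#' over them (`best_matrix_id` records which), with the minimal FDR
#' recorded alongside. `significant` requires `fe_adj_max > fe_min` and
#' `fdr_min < fdr_max`; `highly_enriched` additionally `fe_adj_max >
#' fe_high`.
#'
#' @param records enrichment data.frame (from [enrich_library()], or any
#'   with columns `matrix_id, fe_adj, fdr`).
#' @param matrix_to_tf named character vector, matrix id -> TF name; every
#'   matrix in `records` must be mapped.
#' @param fe_min,fe_high,fdr_max cutoffs as in [enrich_library()].
#' @return data.frame with one row per TF: `tf_name, fe_adj_max,
#'   best_matrix_id, fdr_min, significant, highly_enriched`, ordered by
#'   decreasing `fe_adj_max`.
#' @export
collapse_to_tf <- function(records, matrix_to_tf, fe_min = 1.25,
                           fe_high = 1.5, fdr_max = 0.05) {
  unmapped <- setdiff(records$matrix_id, names(matrix_to_tf))
  if (length(unmapped))
    stop(sprintf("unmapped matrix id(s): %s",
                 paste(unmapped, collapse = ", ")), call. = FALSE)
  tf <- unname(matrix_to_tf[records$matrix_id])
  rows <- lapply(split(seq_len(nrow(records)), tf), function(i) {
    best <- i[which.max(records$fe_adj[i])]
    data.frame(tf_name = matrix_to_tf[[records$matrix_id[best]]],
               fe_adj_max = records$fe_adj[best],
               best_matrix_id = records$matrix_id[best],
               fdr_min = min(records$fdr[i]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$fe_adj_max > fe_min & out$fdr_min < fdr_max
  out$highly_enriched <- out$significant & out$fe_adj_max > fe_high
  out <- out[order(-out$fe_adj_max), ]
  rownames(out) <- NULL
  out
}
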