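# Per-study ingest: read differential-expression result tables, apply the
# platform-specific inclusion filter, and emit direction-specific ranked
# gene lists feeding the rank aggregation.

#' Biotypes counted as "translated" for the inclusion filter
#' @export
translated_biotypes <- c("protein_coding", "polymorphic_pseudogene",
                         "translated_processed_pseudogene",
                         "translated_unprocessed_pseudogene")

#' Construct a per-study result table
#'
#' @param df data.frame with columns `gene_id`, `fold_change` (linear
#'   ratio, > 0) and `padj` (in \[0, 1\]).
#' @param study_id study label.
#' @param platform one of `"rna-seq"`, `"microarray"`, `"cage"`.
#' @return An object of class `study_table`: list with `study_id`,
#'   `platform`, `table` and `measured_universe` (all gene ids present).
#' @export
study_table <- function(df, study_id, platform) {
  platform <- match.arg(platform, names(platform_padj_cutoffs))
  need <- c("gene_id", "fold_change", "padj")
  if (!all(need %in% names(df)))
    stop("table must have columns gene_id, fold_change, padj",
         call. = FALSE)
  if (nrow(df) == 0L) stop("empty study table", call. = FALSE)
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup))
    stop(sprintf("duplicate gene id(s) in study '%s': %s", study_id,
                 paste(utils::head(dup, 5), collapse = ", ")),
         call. = FALSE)
  bad <- df$padj < 0 | df$padj > 1 | df$fold_change <= 0
  if (any(bad)) {
    warning(sprintf("study '%s': dropping %d row(s) with out-of-range padj or non-positive fold change",
                    study_id, sum(bad)), call. = FALSE)
    df <- df[!bad, , drop = FALSE]
    if (nrow(df) == 0L) stop("empty study table after validation",
                             call. = FALSE)
  }
  structure(list(study_id = study_id, platform = platform,
                 table = df[need], measured_universe = df$gene_id),
            class = "study_table")
}

#' @export
print.study_table <- function(x, ...) {
  cat(sprintf("study_table '%s' (%s): %d genes measured\n",
              x$study_id, x$platform, length(x$measured_universe)))
  invisible(x)
}

#' Read a per-study differential-expression table from TSV
#'
#' Expects a header with at least `gene_id`, `fold_change`, `padj`. Rows
#' with missing fields are dropped with a logged count; rows violating the
#' domain (padj outside \[0, 1\], fold change <= 0) are dropped with a
#' warning; duplicated gene ids are an error.
#'
#' @param path TSV file path.
#' @param platform platform label (`"rna-seq"`, `"microarray"`, `"cage"`).
#' @return A `study_table`.
#' @export
read_study_table <- function(path, platform) {
  platform <- match.arg(platform, names(platform_padj_cutoffs))
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  df <- read_tsv(path)
  need <- c("gene_id", "fold_change", "padj")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  df$fold_change <- as.numeric(df$fold_change)
  df$padj <- as.numeric(df$padj)
  incomplete <- !stats::complete.cases(df[need]) | df$gene_id == ""
  if (any(incomplete))
    stage_log("ingest", study = basename(path),
              rows_dropped_incomplete = sum(incomplete))
  df <- df[!incomplete, , drop = FALSE]
  if (nrow(df) == 0L) stop(sprintf("%s: empty study table", path),
                           call. = FALSE)
  study_table(df, study_id = sub("\\.[^.]+$", "", basename(path)),
              platform = platform)
}

#' Filter a study table and rank retained genes per direction
#'
#' A gene is retained iff (i) |fold change| > `fc_min` on the symmetric
#' scale (up: FC > 1.25, down: FC < 1/1.25), (ii) its adjusted p is below
#' the platform cutoff (0.05 for RNA-seq and CAGE, 0.1 for microarray;
#' strict inequalities), and (iii) its biotype is translated (see
#' [translated_biotypes]). Genes missing from the biotype map are excluded
#' and counted. Retained genes are split by fold-change sign and ordered
#' by ascending adjusted p, ties broken by descending |log2 FC| then
#' lexicographic gene id. The normalized rank of a retained gene is its
#' position divided by the number of measured, biotype-eligible genes in
#' the study (the candidate universe of the rank aggregation); measured
#' genes not retained implicitly hold rank 1.
#'
#' @param study a `study_table`.
#' @param gene_biotypes named character vector (names = gene ids) or
#'   data.frame with columns `gene_id`, `biotype`.
#' @param fc_min linear fold-change threshold (default 1.25).
#' @return A list with `up` and `down`, each a `ranked_gene_list`: list
#'   with `study_id`, `direction`, `gene_id` (ordered), `normalized_rank`,
#'   `n_universe` and `universe` (the eligible measured gene ids).
#' @export
filter_and_rank <- function(study, gene_biotypes, fc_min = 1.25) {
  stopifnot(inherits(study, "study_table"))
  if (is.data.frame(gene_biotypes))
    gene_biotypes <- stats::setNames(gene_biotypes$biotype,
                                     gene_biotypes$gene_id)
  df <- study$table
  bt <- gene_biotypes[df$gene_id]
  uncovered <- is.na(bt)
  if (any(uncovered))
    stage_log("filter", study = study$study_id,
              genes_without_biotype = sum(uncovered))
  eligible <- !uncovered & bt %in% translated_biotypes
  cutoff <- platform_padj_cutoffs[[study$platform]]
  universe <- df$gene_id[eligible]
  n_universe <- length(universe)
  lfc <- log2(df$fold_change)
  pass <- eligible & abs(lfc) > log2(fc_min) & df$padj < cutoff

  one_direction <- function(direction) {
    idx <- which(pass & (if (direction == "up") lfc > 0 else lfc < 0))
    ord <- idx[order(df$padj[idx], -abs(lfc[idx]), df$gene_id[idx])]
    structure(list(study_id = study$study_id, direction = direction,
                   gene_id = df$gene_id[ord],
                   normalized_rank =
                     if (n_universe > 0) seq_along(ord) / n_universe
                     else numeric(0),
                   n_universe = n_universe, universe = universe),
              class = "ranked_gene_list")
  }
  res <- list(up = one_direction("up"), down = one_direction("down"))
  stage_log("filter", study = study$study_id, measured = nrow(df),
            eligible = n_universe, up = length(res$up$gene_id),
            down = length(res$down$gene_id))
  res
}

#' @export
print.ranked_gene_list <- function(x, ...) {
  cat(sprintf("ranked_gene_list '%s' [%s]: %d retained of %d eligible\n",
              x$study_id, x$direction, length(x$gene_id), x$n_universe))
  invisible(x)
}
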