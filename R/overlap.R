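# Heterodimer evidence: the fraction of a TF's motifs that are overlapped
# by a motif of a *different* TF on the same promoter by strictly more
# than half of the focal motif's own length. Intended for hits scanned at
# the sparse 1-per-50-kb calibration, where overlap is unlikely by chance.

#' Percent of each TF's motifs overlapped by another TF's motifs
#'
#' A motif of TF X counts as overlapped iff some motif of a different TF
#' on the same promoter overlaps it by strictly more than `min_fraction`
#' of X's own length (motif lengths differ between matrices, so the
#' criterion is asymmetric and per focal motif). TFs queried but owning
#' no motifs are reported with `NA` percent.
#'
#' @param hits_by_tf named list of hit data.frames keyed by TF (columns
#'   `promoter_id, start, end`), or a single data.frame with an
#'   additional `tf` column.
#' @param min_fraction overlap fraction threshold (default 0.5, strict
#'   `>`).
#' @param cross_tf_only if `TRUE` (default) overlaps between motifs of
#'   the same TF are ignored (self-overlap is no heterodimer evidence).
#' @return data.frame `tf, total_motifs, overlapped_motifs,
#'   percent_overlapped` (percent in \[0, 100\], `NA` when no motifs).
#' @export
overlap_percent <- function(hits_by_tf, min_fraction = 0.5,
                            cross_tf_only = TRUE) {
  if (is.data.frame(hits_by_tf)) {
    stopifnot("tf" %in% names(hits_by_tf))
    hits <- hits_by_tf
    tfs <- unique(hits$tf)
  } else {
    stopifnot(!is.null(names(hits_by_tf)))
    tfs <- names(hits_by_tf)
    hits <- do.call(rbind, lapply(tfs, function(tf) {
      h <- hits_by_tf[[tf]]
      if (is.null(h) || nrow(h) == 0L) return(NULL)
      cbind(h[c("promoter_id", "start", "end")], tf = tf)
    }))
  }
  if (is.null(hits)) hits <- data.frame(promoter_id = character(),
                                        start = integer(), end = integer(),
                                        tf = character())
  overlapped <- logical(nrow(hits))
  for (p in split(seq_len(nrow(hits)), hits$promoter_id)) {
    if (length(p) < 2L) next
    s <- hits$start[p]; e <- hits$end[p]; tf <- hits$tf[p]
    for (ii in seq_along(p)) {
      ov <- pmin(e[ii], e) - pmax(s[ii], s)
      other <- if (cross_tf_only) tf != tf[ii] else seq_along(p) != ii
      overlapped[p[ii]] <- any(other & ov > min_fraction * (e[ii] - s[ii]))
    }
  }
  out <- data.frame(tf = tfs, total_motifs = 0L, overlapped_motifs = 0L,
                    percent_overlapped = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(tfs)) {
    i <- hits$tf == tfs[k]
    out$total_motifs[k] <- sum(i)
    out$overlapped_motifs[k] <- sum(overlapped[i])
    if (out$total_motifs[k] > 0L)
      out$percent_overlapped[k] <-
        100 * out$overlapped_motifs[k] / out$total_motifs[k]
  }
  out
}
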