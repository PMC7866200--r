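# TSS selection from transcript abundances and strand-aware promoter
# extraction. Coordinates are 0-based half-open throughout. The promoter
# window spans -1500..+500 around the TSS in transcription coordinates:
# 1500 upstream bases + the TSS base (position 0) + 499 downstream bases
# = 2000 bp.

#' Select one TSS per gene from transcript abundances
#'
#' The transcript with maximal abundance wins. Ties are broken
#' deterministically: the 5'-most TSS on the gene's strand (smallest
#' coordinate on `+`, largest on `-`), then lexicographic transcript id.
#' Conflicting strands within a gene are an error.
#'
#' @param transcript_table data.frame with columns `gene_id,
#'   transcript_id, contig, tss_pos` (0-based), `strand` (`+`/`-`),
#'   `abundance` (non-negative).
#' @return data.frame with one row per gene: `gene_id, contig, tss_pos,
#'   strand, source_transcript, abundance`.
#' @export
select_tss <- function(transcript_table) {
  need <- c("gene_id", "transcript_id", "contig", "tss_pos", "strand",
            "abundance")
  if (!all(need %in% names(transcript_table)))
    stop("transcript table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(transcript_table$abundance < 0))
    stop("abundances must be non-negative", call. = FALSE)
  split_tab <- split(transcript_table, transcript_table$gene_id)
  bad <- names(split_tab)[vapply(split_tab, function(g)
    length(unique(g$strand)) > 1L, logical(1))]
  if (length(bad))
    stop(sprintf("conflicting strands within gene(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  rows <- lapply(split_tab, function(g) {
    five_prime <- if (g$strand[1] == "+") g$tss_pos else -g$tss_pos
    ord <- order(-g$abundance, five_prime, g$transcript_id)
    g[ord[1L], , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  data.frame(gene_id = out$gene_id, contig = out$contig,
             tss_pos = out$tss_pos, strand = out$strand,
             source_transcript = out$transcript_id,
             abundance = out$abundance, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Extract strand-aware promoter windows around TSSs
#'
#' For a `+` strand TSS at position `p` the window is
#' `[p - upstream, p + downstream)`; for a `-` strand TSS it is
#' `[p - downstream + 1, p + upstream + 1)` and the sequence is
#' reverse-complemented, so that in the emitted sequence position 0 is
#' always the most upstream base (-`upstream`) and the TSS sits at offset
#' `upstream`. Windows are clipped at contig edges and flagged.
#'
#' @param genome a named [Biostrings::DNAStringSet] (names = contigs) or a
#'   FASTA path.
#' @param tss data.frame as returned by [select_tss()].
#' @param upstream,downstream window extents in bp (defaults 1500 / 500).
#' @return A list of class `promoter_set`: `intervals` (data.frame
#'   `gene_id, contig, start, end, strand, clipped`, 0-based half-open)
#'   and `seqs` (a `DNAStringSet` named by gene, oriented 5'->3' relative
#'   to transcription).
#' @export
extract_promoters <- function(genome, tss, upstream = 1500L,
                              downstream = 500L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  stopifnot(methods::is(genome, "DNAStringSet"))
  names(genome) <- sub("\\s.*", "", names(genome))
  missing_contig <- setdiff(unique(tss$contig), names(genome))
  if (length(missing_contig))
    stop(sprintf("contig(s) absent from genome: %s",
                 paste(missing_contig, collapse = ", ")), call. = FALSE)
  n <- nrow(tss)
  start <- end <- integer(n)
  clipped <- logical(n)
  seqs <- character(n)
  for (i in seq_len(n)) {
    p <- tss$tss_pos[i]
    len <- Biostrings::width(genome[tss$contig[i]])
    if (tss$strand[i] == "+") {
      s <- p - upstream; e <- p + downstream
    } else {
      s <- p - downstream + 1L; e <- p + upstream + 1L
    }
    cs <- max(0L, s); ce <- min(len, e)
    if (ce <= cs)
      stop(sprintf("promoter window of gene '%s' falls outside contig",
                   tss$gene_id[i]), call. = FALSE)
    clipped[i] <- cs != s || ce != e
    sq <- Biostrings::subseq(genome[[tss$contig[i]]], cs + 1L, ce)
    if (tss$strand[i] == "-") sq <- Biostrings::reverseComplement(sq)
    start[i] <- cs; end[i] <- ce; seqs[i] <- as.character(sq)
  }
  out_seqs <- Biostrings::DNAStringSet(seqs)
  names(out_seqs) <- tss$gene_id
  if (any(clipped))
    stage_log("promoters", clipped = sum(clipped))
  structure(list(
    intervals = data.frame(gene_id = tss$gene_id, contig = tss$contig,
                           start = start, end = end, strand = tss$strand,
                           clipped = clipped, stringsAsFactors = FALSE),
    seqs = out_seqs), class = "promoter_set")
}

#' @export
print.promoter_set <- function(x, ...) {
  cat(sprintf("promoter_set: %d promoters (%d clipped)\n",
              nrow(x$intervals), sum(x$intervals$clipped)))
  invisible(x)
}

#' Sample the reference promoter set
#'
#' Uniform sample without replacement of `n` promoters, seed-reproducible,
#' optionally excluding a set of genes (typically the DEGs). If fewer than
#' `n` remain, all are returned with a warning.
#'
#' @param promoters a `promoter_set`.
#' @param n sample size (default 5000).
#' @param seed integer seed.
#' @param exclude gene ids to exclude before sampling (default none).
#' @return A `promoter_set` restricted to the sample.
#' @export
sample_reference_promoters <- function(promoters, n = 5000L, seed = 1L,
                                       exclude = character()) {
  stopifnot(inherits(promoters, "promoter_set"))
  pool <- setdiff(promoters$intervals$gene_id, exclude)
  if (length(pool) < n) {
    warning(sprintf("only %d promoters available, requested %d; taking all",
                    length(pool), n), call. = FALSE)
    chosen <- pool
  } else {
    chosen <- with_seed(derive_seed(seed, "refsample"),
                        sample(pool, n))
  }
  keep <- promoters$intervals$gene_id %in% chosen
  structure(list(intervals = promoters$intervals[keep, , drop = FALSE],
                 seqs = promoters$seqs[promoters$intervals$gene_id[keep]]),
            class = "promoter_set")
}

#' Write promoter intervals as BED6
#'
#' @param promoters a `promoter_set`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_promoter_bed <- function(promoters, path) {
  iv <- promoters$intervals
  bed <- data.frame(iv$contig, iv$start, iv$end, iv$gene_id, 0L, iv$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}
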