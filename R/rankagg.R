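# Robust rank aggregation across studies. A gene's normalized ranks
# r_(1) <= ... <= r_(m) across the n studies that measured it are scored
# by the order-statistic tail rho = min_k P(X >= k), X ~ Binomial(n, r_(k)):
# the probability that at least k of n uniform ranks fall at or below the
# k-th observed rank. The minimum over k is Bonferroni-bounded by n to give
# a valid p-value, then Benjamini-Hochberg adjusted across genes.

#' Upper tail of the binomial distribution
#'
#' Computes `P(X >= k)` for `X ~ Binomial(n, r)`, stably via the
#' regularized-incomplete-beta identity underlying [stats::pbinom()].
#'
#' @param k number of successes (0 <= k <= n); vectorised.
#' @param n number of trials.
#' @param r success probability in \[0, 1\]; vectorised.
#' @return `P(X >= k)`.
#' @export
binomial_tail <- function(k, n, r) {
  if (any(k < 0) || any(k > n)) stop("k must satisfy 0 <= k <= n",
                                     call. = FALSE)
  if (any(r < 0) || any(r > 1)) stop("r must lie in [0, 1]", call. = FALSE)
  if (n == 1)  # single uniform order statistic: tail is the rank itself
    return(ifelse(k == 0, 1, r))
  ifelse(k == 0, 1, stats::pbinom(k - 1, n, r, lower.tail = FALSE))
}

#' Rank-aggregation rho score of one gene
#'
#' `rho = min_k P(X >= k)` over the observed ranks, `X ~ Binomial(n,
#' r_(k))`. Ranks for studies that measured the gene but did not retain it
#' are 1 and can never attain the minimum, so only the retained ranks need
#' be supplied; `n` is the number of studies that measured the gene.
#'
#' @param sorted_ranks ascending normalized ranks in (0, 1\].
#' @param n number of studies measuring the gene (>= length of
#'   `sorted_ranks`).
#' @return The rho score in (0, 1\].
#' @export
rho_score <- function(sorted_ranks, n) {
  m <- length(sorted_ranks)
  if (m == 0L) return(1)
  if (is.unsorted(sorted_ranks))
    stop("ranks must be sorted ascending", call. = FALSE)
  if (any(sorted_ranks <= 0) || any(sorted_ranks > 1))
    stop("ranks must lie in (0, 1]", call. = FALSE)
  if (m > n) stop("more ranks than studies", call. = FALSE)
  min(binomial_tail(seq_len(m), n, sorted_ranks))
}

#' Aggregate ranked gene lists across studies into DEG calls
#'
#' Builds the gene-by-study rank matrix over the union of the studies'
#' eligible universes. Per gene, `n_eff` counts the studies whose universe
#' contains it (measured there); its rho score uses the normalized ranks
#' of the studies that retained it. The Bonferroni-bounded p-value is
#' `min(1, rho * n_eff)`; Benjamini-Hochberg adjustment across all
#' eligible genes gives `padj`, and `is_deg = (padj < padj_threshold)`.
#' Genes measured in fewer than `min_studies` studies are ineligible for a
#' meta-analytic call and are dropped (logged).
#'
#' @param lists list of `ranked_gene_list` objects, all of one direction.
#' @param direction optional direction check (`"up"`/`"down"`).
#' @param min_studies minimum number of studies measuring a gene
#'   (default 2; a meta-analysis claim from one study is degenerate).
#' @param padj_threshold DEG call threshold on `padj` (default 0.01,
#'   strict `<`).
#' @param adjust `"BH"` (default) adjusts the Bonferroni-bounded p-values
#'   across genes; `"bonferroni"` uses them directly as `padj`.
#' @return data.frame of class `aggregation_result` with columns
#'   `gene_id, direction, n_eff, n_retained, rho, p_bonf, padj, is_deg`,
#'   ordered by ascending `padj` then `rho`.
#' @export
aggregate_ranks <- function(lists, direction = NULL, min_studies = 2L,
                            padj_threshold = 0.01,
                            adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  if (!length(lists)) stop("need at least one ranked list", call. = FALSE)
  stopifnot(all(vapply(lists, inherits, logical(1), "ranked_gene_list")))
  dirs <- unique(vapply(lists, `[[`, character(1), "direction"))
  if (length(dirs) != 1L)
    stop("all lists must share one direction", call. = FALSE)
  if (!is.null(direction) && !identical(direction, dirs))
    stop(sprintf("lists are direction '%s', expected '%s'", dirs,
                 direction), call. = FALSE)

  genes <- sort(unique(unlist(lapply(lists, `[[`, "universe"))))
  if (!length(genes)) stop("union of study universes is empty",
                           call. = FALSE)
  gi <- stats::setNames(seq_along(genes), genes)
  n_eff <- integer(length(genes))
  ranks <- vector("list", length(genes))
  for (l in lists) {
    n_eff[gi[l$universe]] <- n_eff[gi[l$universe]] + 1L
    ret <- gi[l$gene_id]
    for (j in seq_along(ret))
      ranks[[ret[j]]] <- c(ranks[[ret[j]]], l$normalized_rank[j])
  }
  keep <- n_eff >= min_studies
  if (any(!keep))
    stage_log("aggregate", direction = dirs,
              ineligible_lt_min_studies = sum(!keep))
  rho <- vapply(which(keep), function(i)
    rho_score(sort(ranks[[i]]), n_eff[i]), numeric(1))
  p_bonf <- pmin(1, rho * n_eff[keep])
  padj <- if (adjust == "BH") stats::p.adjust(p_bonf, "BH") else p_bonf
  out <- data.frame(gene_id = genes[keep], direction = dirs,
                    n_eff = n_eff[keep],
                    n_retained = vapply(ranks[keep], length, integer(1)),
                    rho = rho, p_bonf = p_bonf, padj = padj,
                    is_deg = padj < padj_threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(out$padj, out$rho, out$gene_id), ]
  rownames(out) <- NULL
  stage_log("aggregate", direction = dirs, genes = nrow(out),
            degs = sum(out$is_deg))
  class(out) <- c("aggregation_result", "data.frame")
  out
}

#' Compare named DEG sets
#'
#' Exact set algebra over named gene-id sets: sizes, pairwise intersection
#' counts, and per-set unique counts (members of no other set).
#'
#' @param sets named list of character vectors (>= 2 sets).
#' @return A list with `sizes`, `intersections` (symmetric count matrix)
#'   and `unique_counts`.
#' @export
compare_deg_sets <- function(sets) {
  if (length(sets) < 2L || is.null(names(sets)))
    stop("need >= 2 named sets", call. = FALSE)
  sets <- lapply(sets, unique)
  nm <- names(sets)
  k <- length(sets)
  inter <- matrix(0L, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in seq_len(k))
    inter[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  uniq <- vapply(seq_len(k), function(i)
    length(setdiff(sets[[i]], unlist(sets[-i]))), integer(1))
  list(sizes = vapply(sets, length, integer(1)),
       intersections = inter,
       unique_counts = stats::setNames(uniq, nm))
}
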