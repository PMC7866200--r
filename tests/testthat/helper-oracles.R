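# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the code paths they check.

# P(X >= k), X ~ Binomial(n, r), by exhaustive enumeration over all 2^n
# outcomes (n small).
enum_binomial_tail <- function(k, n, r) {
  total <- 0
  for (mask in 0:(2^n - 1)) {
    bits <- sum(bitwAnd(mask, 2^(0:(n - 1))) != 0)
    if (bits >= k) total <- total + r^bits * (1 - r)^(n - bits)
  }
  total
}

# Naive per-window PWM scorer: double loop, string operations only.
naive_scan <- function(seq_str, lo, threshold) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  L <- nrow(lo)
  chars <- strsplit(seq_str, "")[[1]]
  score_window <- function(w) {
    s <- 0
    for (i in seq_len(L)) {
      b <- w[i]
      s <- s + if (b %in% c("A", "C", "G", "T"))
        lo[i, b] else 0
    }
    s
  }
  hits <- list()
  for (p in seq_len(length(chars) - L + 1)) {
    w <- chars[p:(p + L - 1)]
    sf <- score_window(w)
    wr <- rev(unname(comp[w]))
    wr[is.na(wr)] <- "N"
    sr <- score_window(wr)
    if (sf >= threshold)
      hits[[length(hits) + 1]] <- data.frame(start = p - 1L, score = sf,
                                             strand = "+")
    if (sr >= threshold)
      hits[[length(hits) + 1]] <- data.frame(start = p - 1L, score = sr,
                                             strand = "-")
  }
  if (length(hits)) do.call(rbind, hits)
  else data.frame(start = integer(0), score = numeric(0),
                  strand = character(0))
}

# One-sided (enrichment) Fisher p by hypergeometric enumeration with
# choose(); independent of stats::fisher.test and stats::phyper.
enum_fisher_greater <- function(a, b, c, d) {
  m <- a + b          # DEG promoters
  n <- c + d          # reference promoters
  k <- a + c          # promoters with a hit
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- vapply(lo:hi, function(x)
    choose(m, x) * choose(n, k - x) / choose(m + n, k), numeric(1))
  sum(probs[(lo:hi) >= a])
}

# A random iid DNA string.
random_dna <- function(n, gc = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Reverse complement on plain strings.
revcomp_str <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
}

# Minimal ranked_gene_list builder for aggregation tests.
make_ranked <- function(study_id, gene_id, rank, universe,
                        direction = "up") {
  structure(list(study_id = study_id, direction = direction,
                 gene_id = gene_id, normalized_rank = rank,
                 n_universe = length(universe), universe = universe),
            class = "ranked_gene_list")
}

# Connected components of an undirected edge list by union-find;
# independent oracle for clustering tests (the package's MCL extracts
# components of the converged flow matrix, not of the input graph).
graph_components <- function(edges, nodes) {
  parent <- stats::setNames(as.numeric(seq_along(nodes)), nodes)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (k in seq_len(nrow(edges))) {
    ra <- find(match(edges$node_a[k], nodes))
    rb <- find(match(edges$node_b[k], nodes))
    if (ra != rb) parent[rb] <- ra
  }
  stats::setNames(vapply(seq_along(nodes), find, numeric(1)), nodes)
}

# All-protein-coding biotype map over the simulator's gene naming.
sim_biotypes <- function(n_genes) {
  stats::setNames(rep("protein_coding", n_genes),
                  sprintf("gene%05d", seq_len(n_genes)))
}
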