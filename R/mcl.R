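# Markov clustering (MCL) of weighted undirected graphs, as used to group
# enriched transcription factors by their protein-protein interactions.
# A random-walk transition matrix with self-loops is alternately expanded
# (matrix squared) and inflated (elementwise power, columns renormalized)
# until it stops changing; clusters are the connected components of the
# converged matrix's support.

#' Markov clustering of a weighted undirected edge list
#'
#' @param edges data.frame with columns `node_a, node_b, weight`
#'   (weights > 0). An empty edge list yields singleton clusters over
#'   `nodes`.
#' @param nodes optional character vector of nodes to include even when
#'   isolated; defaults to the nodes appearing in `edges`.
#' @param inflation inflation exponent (default 2; larger values give
#'   finer clusters).
#' @param max_iter iteration cap (default 200).
#' @param tol convergence tolerance on the max absolute entry change
#'   (default 1e-6).
#' @param self_loop_weight weight of the added self-loops (default 1).
#' @param prune entries below this are zeroed each iteration for
#'   numerical stability (default 1e-10).
#' @return A list of class `cluster_partition`: `membership` (named
#'   integer vector node -> cluster id, clusters numbered by first node),
#'   `n_clusters`, `convergence_iterations`.
#' @export
mcl_cluster <- function(edges, nodes = NULL, inflation = 2,
                        max_iter = 200L, tol = 1e-6,
                        self_loop_weight = 1, prune = 1e-10) {
  if (inflation <= 1) stop("inflation must exceed 1", call. = FALSE)
  edge_nodes <- if (nrow(edges)) c(edges$node_a, edges$node_b)
                else character(0)
  nodes <- unique(c(nodes, edge_nodes))
  n <- length(nodes)
  if (n == 0L) stop("no nodes to cluster", call. = FALSE)
  if (nrow(edges)) {
    if (any(edges$weight <= 0)) stop("weights must be > 0", call. = FALSE)
    if (any(edges$node_a == edges$node_b))
      stop("graph must be simple (no self edges in input)", call. = FALSE)
  }
  idx <- stats::setNames(seq_len(n), nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    ia <- idx[edges$node_a]; ib <- idx[edges$node_b]
    A[cbind(ia, ib)] <- A[cbind(ia, ib)] + edges$weight
    A[cbind(ib, ia)] <- A[cbind(ia, ib)]
  }
  diag(A) <- self_loop_weight
  M <- sweep(A, 2, colSums(A), `/`)
  iters <- 0L
  repeat {
    iters <- iters + 1L
    M2 <- M %*% M          # expansion
    M2 <- M2^inflation     # inflation
    M2[M2 < prune] <- 0
    M2 <- sweep(M2, 2, colSums(M2), `/`)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol || iters >= max_iter) break
  }
  # clusters = connected components of the converged support
  supp <- (M > sqrt(prune)) | (t(M) > sqrt(prune))
  diag(supp) <- TRUE
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(supp[v, ] & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  structure(list(membership = stats::setNames(comp, nodes),
                 n_clusters = cid, convergence_iterations = iters),
            class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf("cluster_partition: %d nodes in %d clusters (%d iterations)\n",
              length(x$membership), x$n_clusters,
              x$convergence_iterations))
  invisible(x)
}
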