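# Off-diagonal absolute weights, as used by clustering / betweenness /
# eigenvector measures (their formulas presuppose non-negative weights; the
# signed matrix is preserved in the connectivity object itself).
abs_offdiag <- function(w) {
  a <- abs(as.matrix(w))
  diag(a) <- 0
  a
}

#' Weighted clustering coefficient (per node and global)
#'
#' Onnela-style local clustering of a weighted undirected graph: weights are
#' scaled by their maximum, and
#' `c_i = 2 / (d_i (d_i - 1)) * sum_jk (w_ij w_jk w_ki)^{1/3}` over the
#' geometric means of triangle weights, with `d_i` the number of neighbors.
#' Nodes with fewer than two neighbors get `c_i = 0`. The global coefficient
#' is the mean of the local values. Negative weights enter through their
#' absolute value.
#'
#' @param matrix A `connectivity_matrix` or symmetric weight matrix.
#' @return List with `local` (per-node vector) and `global` (mean).
#' @export
weighted_clustering <- function(matrix) {
  a <- abs_offdiag(matrix)
  mx <- max(a)
  if (mx == 0) return(list(local = rep(0, nrow(a)), global = 0))
  wt <- (a / mx)^(1 / 3)
  tri <- diag(wt %*% wt %*% wt) # 2x the weighted triangle sum per node
  d <- rowSums(a > 0)
  ci <- ifelse(d >= 2, tri / (d * (d - 1)), 0)
  list(local = as.numeric(ci), global = mean(ci))
}

#' Node strength
#'
#' Per-node sum of the (signed) weights of incident links, i.e. row sums of
#' the weight matrix excluding the diagonal.
#'
#' @param matrix A `connectivity_matrix` or symmetric weight matrix.
#' @return Numeric vector of strengths.
#' @export
strength <- function(matrix) {
  w <- as.matrix(matrix)
  diag(w) <- 0
  as.numeric(rowSums(w))
}

#' Betweenness centrality (per node and average)
#'
#' Fraction-of-shortest-paths betweenness on the weighted graph, with edge
#' lengths `1 / |w|` so that strong correlation means a short path (the
#' standard convention for correlation networks). Zero weights are absent
#' edges; on a disconnected graph paths are counted within components.
#'
#' @param matrix A `connectivity_matrix` or symmetric weight matrix.
#' @return List with `per_node` (vector) and `average` (scalar).
#' @export
betweenness <- function(matrix) {
  a <- abs_offdiag(matrix)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  lens <- 1 / igraph::E(g)$weight
  b <- igraph::betweenness(g, directed = FALSE, weights = lens)
  list(per_node = as.numeric(b), average = mean(b))
}

#' Leading eigenvalue and eigenvector centrality
#'
#' Dense symmetric eigendecomposition of the absolute weight matrix (taken
#' as given, including its diagonal). Returns the largest-magnitude
#' eigenvalue and the associated eigenvector normalized to unit norm with
#' non-negative orientation (Perron vector on a connected non-negative
#' graph).
#'
#' @param matrix A `connectivity_matrix` or symmetric weight matrix.
#' @return List with `centrality` (unit-norm vector) and `lambda_max`.
#' @export
eigen_features <- function(matrix) {
  a <- abs(as.matrix(matrix))
  e <- eigen(a, symmetric = TRUE)
  i <- which.max(abs(e$values))
  v <- e$vectors[, i]
  if (sum(v) < 0) v <- -v
  v <- v / sqrt(sum(v^2))
  list(centrality = as.numeric(v), lambda_max = e$values[i])
}

#' Full network feature vector of an epoch
#'
#' Builds the HVG degree-sequence connectivity matrix and concatenates all
#' five graph measure families: local clustering + global mean, strengths,
#' per-node betweenness + average, eigenvector centrality, and the largest
#' eigenvalue. For `n` channels this yields `4 n + 3` scalars (111 at
#' `n = 27`), deterministically named and ordered.
#'
#' @param epoch An `eeg_epoch`.
#' @param max_lag Maximum lag for [build_connectivity()].
#' @return Named numeric vector.
#' @export
extract_network_features <- function(epoch, max_lag = NULL) {
  w <- build_connectivity(epoch, max_lag)
  n <- nrow(w)
  cl <- weighted_clustering(w)
  st <- strength(w)
  bt <- betweenness(w)
  adj <- as.matrix(w)
  diag(adj) <- 0 # adjacency semantics: self-correlation carries no edge
  ei <- eigen_features(adj)
  out <- c(cl$local, cl$global, st, bt$per_node, bt$average,
           ei$centrality, ei$lambda_max)
  names(out) <- c(paste0("clust_", seq_len(n)), "clust_global",
                  paste0("strength_", seq_len(n)),
                  paste0("betw_", seq_len(n)), "betw_avg",
                  paste0("eigc_", seq_len(n)), "lambda_max")
  out
}
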