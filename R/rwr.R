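# Random walk with restart on a column-normalized adjacency matrix.
#
# The adjacency A (binary, undirected) is normalized per column,
# A'[i,j] = A[i,j] / sum_k A[k,j], so each column over a non-isolated node is
# a probability distribution over its neighbours. The walk iterates
#   P_{t+1} = (1 - r) A' P_t + r P_0
# from P_0 uniform over the seed genes until the L1 change falls below `tol`.

#' Column-normalized transition matrix of a gene network
#'
#' @param net igraph gene network (non-empty).
#' @return a `transition_matrix`: list with `matrix` (sparse, columns of
#'   non-isolated nodes sum to 1; isolated nodes have all-zero columns) and
#'   `node_order` (gene symbols fixing the row/column indices).
#' @export
normalize_adjacency <- function(net) {
  nodes <- network_genes(net)
  if (length(nodes) == 0) abort("empty network")
  A <- igraph::as_adjacency_matrix(net, type = "both", sparse = TRUE)
  A <- methods::as(A, "dMatrix")
  A@x[] <- 1  # unweighted topology even if edge attributes exist
  colsum <- Matrix::colSums(A)
  scale <- ifelse(colsum > 0, 1 / colsum, 0)
  Aprime <- A %*% Matrix::Diagonal(x = scale)
  structure(list(matrix = Aprime, node_order = nodes),
            class = "transition_matrix")
}

#' Random walk with restart to the fixed point
#'
#' Power iteration of `P_{t+1} = (1 - r) A' P_t + r P_0` with `P_0` uniform
#' over the seed genes. Seeds absent from the network are dropped with a
#' warning; it is an error if none remain. Columns of isolated nodes are all
#' zero and leak probability mass; the converged vector is renormalized to
#' sum 1 (rank order is unaffected) and the leaked fraction recorded.
#'
#' @param tm a `transition_matrix` from [normalize_adjacency()].
#' @param seeds character vector of seed genes.
#' @param r restart probability in (0, 1); default 0.5.
#' @param tol L1 convergence tolerance on successive iterates; default 1e-6.
#' @param max_iter iteration cap (safety valve; the map contracts at rate
#'   1 - r so convergence is fast).
#' @return an `rwr_profile`: list with `p` (named probability vector in
#'   `node_order`), `seeds` (seeds used), `r`, `iterations`, and
#'   `leaked` (mass renormalized away).
#' @export
rwr <- function(tm, seeds, r = 0.5, tol = 1e-6, max_iter = 10000) {
  stopifnot(inherits(tm, "transition_matrix"), r > 0, r < 1)
  nodes <- tm$node_order
  seeds <- unique(canonical_symbol(seeds))
  off <- setdiff(seeds, nodes)
  if (length(off) > 0) {
    warn(sprintf("dropping %d seed gene(s) not on the network", length(off)))
    seeds <- setdiff(seeds, off)
  }
  if (length(seeds) == 0) abort("no seed gene maps onto the network")
  n <- length(nodes)
  p0 <- numeric(n)
  p0[match(seeds, nodes)] <- 1 / length(seeds)
  A <- tm$matrix
  p <- p0
  iter <- 0L
  repeat {
    p_next <- as.numeric((1 - r) * (A %*% p)) + r * p0
    delta <- sum(abs(p_next - p))
    p <- p_next
    iter <- iter + 1L
    if (delta < tol) break
    if (iter >= max_iter) {
      abort(sprintf("RWR did not converge in %d iterations (last L1 residual %.3g)",
                    max_iter, delta))
    }
  }
  total <- sum(p)
  leaked <- 1 - total
  if (leaked > tol) {
    inform(sprintf("renormalizing RWR profile: %.3g probability mass leaked via isolated nodes",
                   leaked))
  }
  p <- p / total
  structure(list(p = setNames(p, nodes), seeds = seeds, r = r,
                 iterations = iter, leaked = leaked),
            class = "rwr_profile")
}

#' Rank genes by RWR probability
#'
#' @param profile an `rwr_profile`.
#' @param exclude genes to omit from the ranking (e.g. the seeds).
#' @return character vector of genes sorted by probability, descending; ties
#'   broken lexicographically on the symbol for reproducibility.
#' @export
rank_by_probability <- function(profile, exclude = character()) {
  p <- profile$p
  keep <- setdiff(names(p), canonical_symbol(exclude))
  p <- p[keep]
  names(p)[order(-p, names(p), method = "radix")]
}
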