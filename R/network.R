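# Data-driven DMN/TPN detection: modularity, seeded Louvain clustering,
# subject- and group-level consensus, and Dice overlap scoring.

#' Weighted graph for community detection
#'
#' Wraps a symmetric non-negative weight matrix. Negative weights (e.g.
#' anticorrelated Fisher-z edges) are set to zero, matching the positive-
#' weight modularity formulation; self-weights are removed.
#'
#' @param W symmetric numeric matrix of edge weights.
#' @param node_ids optional node identifiers (defaults to
#'   rownames/colnames or `node_1..n`).
#' @return object of class `weighted_graph`: list with `w` (matrix), `v`
#'   (total strength, both orderings counted), `s` (node strengths) and
#'   `node_ids`.
#' @export
weighted_graph <- function(W, node_ids = NULL) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stopf("weight matrix must be square")
  W[is.na(W)] <- 0
  if (max(abs(W - t(W))) > 1e-8) stopf("weight matrix must be symmetric")
  W <- (W + t(W)) / 2
  W[W < 0] <- 0
  diag(W) <- 0
  if (sum(W) <= 0) stopf("graph has zero total strength")
  ids <- node_ids %||% rownames(W) %||% sprintf("node_%d", seq_len(nrow(W)))
  dimnames(W) <- list(ids, ids)
  structure(list(w = W, v = sum(W), s = rowSums(W), node_ids = ids),
            class = "weighted_graph")
}

as_weighted_graph <- function(x) {
  if (inherits(x, "weighted_graph")) x else weighted_graph(x)
}

#' Modularity of a partition
#'
#' Exact evaluation of the positive-weight modularity
#' `Q = (1/v) * sum_ij (w_ij - gamma * s_i * s_j / v) * delta(M_i, M_j)`,
#' where v is the total strength (`sum_ij w_ij`, both orderings counted),
#' `s_i` the strength of node i, and the resolution `gamma` multiplies the
#' strength-product null term. The single-community partition has Q = 0 at
#' `gamma = 1`.
#'
#' @param graph a [weighted_graph()] (or a matrix coerced to one).
#' @param membership integer vector of community labels covering all
#'   nodes.
#' @param gamma resolution parameter (default 1).
#' @return the modularity Q.
#' @export
modularity <- function(graph, membership, gamma = 1) {
  g <- as_weighted_graph(graph)
  n <- length(g$node_ids)
  if (length(membership) != n || anyNA(membership)) {
    stopf("membership must label all %d nodes", n)
  }
  q <- 0
  for (c in unique(membership)) {
    idx <- which(membership == c)
    q <- q + sum(g$w[idx, idx]) - gamma * sum(g$s[idx])^2 / g$v
  }
  q / g$v
}

canonical_membership <- function(m) {
  match(m, unique(m))
}

#' Seeded Louvain community detection
#'
#' Greedy two-phase Louvain: local moving with best-gain moves over a
#' seeded-random node order, then community aggregation, repeated to
#' convergence. The returned partition never has Q below the trivial
#' single-community partition (Q = 0 at `gamma = 1`): if the greedy search
#' ends below that, the trivial partition is returned. Deterministic given
#' the seed.
#'
#' @inheritParams modularity
#' @param seed integer seed for the node-visiting order.
#' @return object of class `partition`: list with `membership` (named
#'   integer vector, consecutive labels), `Q`, `gamma`, `seed`.
#' @export
louvain_partition <- function(graph, gamma = 1, seed = 1L) {
  g <- as_weighted_graph(graph)
  memb <- canonical_membership(louvain_cpp(g$w, gamma, as.integer(seed)))
  q <- modularity(g, memb, gamma)
  q_triv <- modularity(g, rep(1L, length(memb)), gamma)
  if (q < q_triv) {
    memb <- rep(1L, length(memb))
    q <- q_triv
  }
  structure(
    list(membership = setNames(as.integer(memb), g$node_ids),
         Q = q, gamma = gamma, seed = as.integer(seed)),
    class = "partition"
  )
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("Partition: %d nodes, %d communities, Q = %.4f (gamma = %g)\n",
              length(x$membership), length(unique(x$membership)), x$Q,
              x$gamma))
  invisible(x)
}

#' Co-assignment agreement matrix
#'
#' Node-by-node proportion of partitions assigning both nodes to the same
#' community. From n identical partitions this is exactly the binary
#' co-assignment matrix.
#'
#' @param partitions list of `partition` objects (or membership vectors)
#'   over the same node set.
#' @return symmetric matrix with unit diagonal, entries in `[0, 1]`.
#' @export
agreement_matrix <- function(partitions) {
  membs <- lapply(partitions, function(p) {
    if (is.list(p)) p$membership else p
  })
  n <- length(membs[[1]])
  D <- matrix(0, n, n)
  for (m in membs) {
    if (length(m) != n) stopf("partitions cover different node sets")
    D <- D + outer(m, m, "==")
  }
  D <- D / length(membs)
  diag(D) <- 1
  D
}

#' Consensus clustering
#'
#' Runs [louvain_partition()] `n_iter` times with distinct sub-seeds,
#' builds the agreement matrix, zeroes entries strictly below `threshold`
#' (default 0.5, i.e. <50% agreement), and re-clusters the thresholded
#' agreement matrix with another `n_iter` Louvain runs, repeating until all
#' `n_iter` partitions of a round are identical. The first round clusters
#' the input graph at the requested `gamma`; re-clustering of agreement
#' matrices uses `gamma = 1` on the agreement weights directly.
#'
#' @inheritParams louvain_partition
#' @param n_iter Louvain runs per round (the emulated analysis used 1000).
#' @param threshold agreement proportion below which entries are zeroed.
#' @param max_rounds failure guard on the number of rounds (default 50).
#' @return a `partition`; its `Q` is evaluated on the *input* graph at the
#'   requested `gamma`, and `rounds` records the consensus rounds used.
#' @export
consensus_partition <- function(graph, n_iter = 1000L, threshold = 0.5,
                                gamma = 1, seed = 1L, max_rounds = 50L) {
  if (n_iter < 1L) stopf("n_iter must be >= 1")
  g <- as_weighted_graph(graph)
  current <- g
  for (round in seq_len(max_rounds)) {
    g_round <- if (round == 1L) gamma else 1
    parts <- lapply(seq_len(n_iter), function(i) {
      louvain_partition(current, g_round,
                        spawn_seed(seed, (round - 1L) * n_iter + i,
                                   "louvain"))
    })
    membs <- lapply(parts, function(p)
      canonical_membership(unname(p$membership)))
    if (all(vapply(membs, identical, logical(1), membs[[1]]))) {
      memb <- membs[[1]]
      return(structure(
        list(membership = setNames(as.integer(memb), g$node_ids),
             Q = modularity(g, memb, gamma), gamma = gamma,
             seed = as.integer(seed), rounds = round),
        class = "partition"
      ))
    }
    D <- agreement_matrix(membs)
    D[D < threshold] <- 0
    diag(D) <- 0
    if (sum(D) <= 0) {
      stopf("consensus failed: thresholded agreement matrix is empty at round %d",
            round)
    }
    current <- weighted_graph(D, node_ids = g$node_ids)
  }
  stopf(paste0(
    "consensus did not converge after %d rounds ",
    "(last-round mean off-diagonal agreement %.3f)"),
    max_rounds, mean(D[upper.tri(D)]))
}

#' Group-level consensus partition
#'
#' Averages the binary co-assignment matrices of the subject-level
#' partitions into a group agreement matrix, then applies the identical
#' consensus-clustering procedure to it.
#'
#' @param subject_partitions list of `partition` objects over the same
#'   node set.
#' @inheritParams consensus_partition
#' @return a `partition`.
#' @export
group_consensus <- function(subject_partitions, n_iter = 1000L,
                            threshold = 0.5, gamma = 1, seed = 1L,
                            max_rounds = 50L) {
  ids <- lapply(subject_partitions, function(p) names(p$membership))
  if (!all(vapply(ids, identical, logical(1), ids[[1]]))) {
    stopf("subject partitions cover different node sets")
  }
  D <- agreement_matrix(subject_partitions)
  diag(D) <- 0
  consensus_partition(weighted_graph(D, node_ids = ids[[1]]),
                      n_iter = n_iter, threshold = threshold,
                      gamma = gamma, seed = seed, max_rounds = max_rounds)
}

#' Sorensen-Dice overlap of two node sets
#'
#' `DSC = 2 |X intersect Y| / (|X| + |Y|)`; symmetric in its arguments.
#'
#' @param set_x,set_y vectors of node identifiers over a common universe.
#' @return object of class `overlap_result`: list with `dsc`, `size_x`,
#'   `size_y`, `intersection`.
#' @export
dice_overlap <- function(set_x, set_y) {
  set_x <- unique(set_x)
  set_y <- unique(set_y)
  if (length(set_x) == 0L && length(set_y) == 0L) {
    stopf("Dice overlap undefined for two empty sets")
  }
  inter <- length(intersect(set_x, set_y))
  structure(
    list(dsc = 2 * inter / (length(set_x) + length(set_y)),
         size_x = length(set_x), size_y = length(set_y),
         intersection = inter),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("DSC = %.3f (|X| = %d, |Y| = %d, |X n Y| = %d)\n",
              x$dsc, x$size_x, x$size_y, x$intersection))
  invisible(x)
}

#' Label detected communities as DMN or TPN
#'
#' Maps each empirical community to "DMN" or "TPN" by maximal Dice overlap
#' with the a-priori labels (a-priori DMN nodes vs a-priori task-positive
#' DAN + FPN nodes). The number of communities is not forced to two;
#' several communities may share a label. A community equally overlapping
#' both references is an error.
#'
#' @param partition a `partition`.
#' @param apriori data frame with columns `node_id` and `apriori_network`
#'   (`"DMN"`, `"DAN"`, `"FPN"`), as written by [node_labels()].
#' @return named character vector (`"DMN"`/`"TPN"`) per node, plus a
#'   `"dsc"` attribute with the per-network Dice overlap of the final
#'   empirical DMN/TPN node sets against the a-priori sets.
#' @export
label_networks <- function(partition, apriori) {
  memb <- partition$membership
  nodes <- names(memb)
  ref_dmn <- apriori$node_id[apriori$apriori_network == "DMN"]
  ref_tpn <- apriori$node_id[apriori$apriori_network != "DMN"]
  lab <- character(length(memb))
  for (c in unique(memb)) {
    set_c <- nodes[memb == c]
    d_dmn <- dice_overlap(set_c, ref_dmn)$dsc
    d_tpn <- dice_overlap(set_c, ref_tpn)$dsc
    if (d_dmn == d_tpn) {
      stopf("community %d overlaps DMN and TPN references equally (DSC %.3f)",
            c, d_dmn)
    }
    lab[memb == c] <- if (d_dmn > d_tpn) "DMN" else "TPN"
  }
  names(lab) <- nodes
  attr(lab, "dsc") <- c(
    dmn = dice_overlap(nodes[lab == "DMN"], ref_dmn)$dsc,
    tpn = dice_overlap(nodes[lab == "TPN"], ref_tpn)$dsc
  )
  lab
}
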