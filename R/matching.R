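#' Euclidean distance matrix between two batches
#'
#' Row i, column j is the Euclidean distance between source cell i and
#' target cell j in the shared gene space. Distances are computed on the
#' values as given (normally log-normalized expression); no internal
#' re-scaling is applied.
#'
#' @param A,B `expression_batch` objects (or bare matrices) with identical
#'   gene order.
#' @return An n x m numeric matrix, n = cells in `A`, m = cells in `B`.
#' @export
pairwise_distances <- function(A, B) {
  check_gene_space(A, B)
  X <- as_matrix(A); Y <- as_matrix(B)
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

new_pair_assignment <- function(source, target, strategy, params = list()) {
  structure(
    list(pairs = data.frame(source = as.integer(source),
                            target = as.integer(target)),
         strategy = strategy, params = params),
    class = "pair_assignment"
  )
}

#' @export
print.pair_assignment <- function(x, ...) {
  cat("pair_assignment (", x$strategy, "): ", nrow(x$pairs), " pairs\n",
      sep = "")
  invisible(x)
}

#' Classic closest-point assignment
#'
#' Every source cell is paired with its nearest target cell, the inner
#' minimization of the classic iterative-closest-point loss. Ties are
#' broken by the lowest target index.
#'
#' @param D Distance matrix from [pairwise_distances()].
#' @return A `pair_assignment` with exactly one pair per source cell.
#' @export
closest_match <- function(D) {
  D <- as.matrix(D)
  if (length(D) == 0) stop("empty distance matrix")
  j <- max.col(-D, ties.method = "first")
  new_pair_assignment(seq_len(nrow(D)), j, "closest")
}

#' Greedy partial assignment
#'
#' Sorts all n x m candidate edges by ascending distance and scans them,
#' accepting an edge when its source cell is still unmatched and its target
#' cell has been used fewer than `beta` times. Scanning stops once
#' `ceiling(alpha * n)` source cells are matched. `alpha` controls what
#' fraction of the source must be matched (partial assignment tolerates
#' non-overlapping cell types); `beta` caps how many sources may collapse
#' onto one target. Ties in distance are broken by (source index, target
#' index) so the scan is deterministic.
#'
#' If `ceiling(alpha * n) > beta * m` the request is infeasible; the
#' maximum feasible `beta * m` pairs are returned with a warning recording
#' the shortfall.
#'
#' @param D Distance matrix (n sources x m targets).
#' @param alpha Fraction of source cells that must be matched, in (0, 1].
#'   Default 0.5.
#' @param beta Maximum number of times a target cell may be matched.
#'   Default 2.
#' @return A `pair_assignment`.
#' @export
greedy_match <- function(D, alpha = 0.5, beta = 2) {
  D <- as.matrix(D)
  n <- nrow(D); m <- ncol(D)
  stopifnot(n >= 1, m >= 1, alpha > 0, alpha <= 1, beta >= 1)
  want <- ceiling(alpha * n)
  if (want > beta * m) {
    warning("infeasible alpha: requested ", want, " pairs but only ",
            beta * m, " are possible with beta = ", beta,
            "; matching ", beta * m, " pairs")
    want <- beta * m
  }
  iv <- as.vector(row(D)); jv <- as.vector(col(D)); dv <- as.vector(D)
  ord <- order(dv, iv, jv)
  src_used <- logical(n)
  tgt_count <- integer(m)
  src <- integer(want); tgt <- integer(want)
  got <- 0L
  for (e in ord) {
    i <- iv[e]; j <- jv[e]
    if (!src_used[i] && tgt_count[j] < beta) {
      src_used[i] <- TRUE
      tgt_count[j] <- tgt_count[j] + 1L
      got <- got + 1L
      src[got] <- i; tgt[got] <- j
      if (got == want) break
    }
  }
  new_pair_assignment(src[seq_len(got)], tgt[seq_len(got)], "greedy",
                      params = list(alpha = alpha, beta = beta))
}

#' Mutual nearest neighbour assignment
#'
#' Pair (i, j) is included iff target j is among the k nearest target
#' cells of source i AND source i is among the k nearest source cells of
#' target j (Euclidean distance both ways). Cells may appear in several
#' pairs; cells with no mutual neighbour appear in none. Ties at the k-th
#' neighbour are broken by index, making the output deterministic.
#'
#' @param A,B `expression_batch` objects (or matrices) sharing gene order.
#' @param k Neighbourhood size (default 10); must not exceed the number of
#'   cells in either batch.
#' @return A `pair_assignment`.
#' @export
mnn_match <- function(A, B, k = 10) {
  D <- pairwise_distances(A, B)
  mnn_match_from_distances(D, k = k)
}

mnn_match_from_distances <- function(D, k = 10) {
  n <- nrow(D); m <- ncol(D)
  if (k > n || k > m) {
    stop("k (", k, ") exceeds the number of cells in one of the batches (",
         n, ", ", m, ")")
  }
  # rank ties.method = "first" resolves equal distances by index
  src_nn <- t(apply(D, 1, rank, ties.method = "first")) <= k  # j in i's kNN
  tgt_nn <- apply(D, 2, rank, ties.method = "first") <= k     # i in j's kNN
  mutual <- src_nn & tgt_nn
  idx <- which(mutual, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  new_pair_assignment(idx[, 1], idx[, 2], "mnn", params = list(k = k))
}

#' Optimal partial matching by minimum-cost flow (test oracle)
#'
#' Finds the minimum-total-distance assignment of exactly `n_pairs` source
#' cells to distinct target cells (each cell used at most once), solved as
#' a min-cost flow on the bipartite graph: a super-source pushes `n_pairs`
#' units through unit-capacity cell nodes to a super-sink. This is the
#' exact reference the greedy scan is compared against; it is intended for
#' small instances only and is guarded to n * m <= 10000.
#'
#' @param D Distance matrix.
#' @param n_pairs Number of pairs to assign; at most `min(n, m)`.
#' @return A `pair_assignment` with attribute `total_cost`.
#' @export
optimal_partial_match <- function(D, n_pairs) {
  D <- as.matrix(D)
  n <- nrow(D); m <- ncol(D)
  if (n * m > 10000) {
    stop("optimal_partial_match is a small-instance oracle (n*m <= 10000)")
  }
  if (n_pairs < 1 || n_pairs > min(n, m)) {
    stop("n_pairs must be between 1 and min(n, m) = ", min(n, m))
  }
  # node ids: 1 = super source, 1+i = source cell i, 1+n+j = target cell j,
  # n+m+2 = super sink
  src_node <- 1L
  sink_node <- n + m + 2L
  from <- c(rep(src_node, n),
            rep(1L + seq_len(n), each = m),
            1L + n + seq_len(m))
  to <- c(1L + seq_len(n),
          rep(1L + n + seq_len(m), times = n),
          rep(sink_node, m))
  cost <- c(rep(0, n), as.vector(t(D)), rep(0, m))
  ne <- length(from)
  # forward edges then their residual reverses
  e_from <- c(from, to)
  e_to <- c(to, from)
  e_cost <- c(cost, -cost)
  e_cap <- c(rep(1L, ne), rep(0L, ne))
  rev_idx <- c(ne + seq_len(ne), seq_len(ne))
  nv <- sink_node
  pairs_src <- integer(0); pairs_tgt <- integer(0)
  total_cost <- 0
  for (unit in seq_len(n_pairs)) {
    # Bellman-Ford (vectorized edge relaxation) on the residual graph
    dist <- rep(Inf, nv); dist[src_node] <- 0
    pred_edge <- rep(NA_integer_, nv)
    act <- which(e_cap > 0L)
    af <- e_from[act]; at <- e_to[act]; ac <- e_cost[act]
    for (pass in seq_len(nv)) {
      cand <- dist[af] + ac
      better <- which(cand < dist[at] - 1e-12)
      if (length(better) == 0) break
      bt <- at[better]; bc <- cand[better]; be <- act[better]
      o <- order(bt, bc)
      first <- !duplicated(bt[o])
      sel <- o[first]
      dist[bt[sel]] <- bc[sel]
      pred_edge[bt[sel]] <- be[sel]
    }
    if (!is.finite(dist[sink_node])) stop("flow infeasible")
    # augment one unit along the shortest path
    v <- sink_node
    while (v != src_node) {
      e <- pred_edge[v]
      e_cap[e] <- e_cap[e] - 1L
      e_cap[rev_idx[e]] <- e_cap[rev_idx[e]] + 1L
      total_cost <- total_cost + e_cost[e]
      v <- e_from[e]
    }
  }
  # recover the matching from saturated source->target edges
  mid <- n + seq_len(n * m)  # indices of the bipartite edges
  used <- mid[e_cap[mid] == 0L]
  i <- (used - n - 1L) %/% m + 1L
  j <- (used - n - 1L) %% m + 1L
  out <- new_pair_assignment(i, j, "flow_oracle",
                             params = list(n_pairs = n_pairs))
  attr(out, "total_cost") <- total_cost
  out
}

# Total distance of an assignment under a distance matrix.
assignment_cost <- function(D, assignment) {
  sum(D[cbind(assignment$pairs$source, assignment$pairs$target)])
}
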