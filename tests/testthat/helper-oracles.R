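# Independent oracle implementations and fixture builders. Everything here
# is written as plain, direct computation so the tests never share code
# paths with the package internals they check.

# small random batch with iid Gaussian entries
random_batch <- function(n, d, label = "b", seed = 1, types = NULL) {
  set.seed(seed)
  expression_batch(matrix(rnorm(n * d), n, d,
                          dimnames = list(paste0(label, seq_len(n)),
                                          paste0("g", seq_len(d)))),
                   batch_label = label, cell_types = types)
}

# brute-force per-pair Euclidean distances
brute_distances <- function(X, Y) {
  out <- matrix(0, nrow(X), nrow(Y))
  for (i in seq_len(nrow(X))) {
    for (j in seq_len(nrow(Y))) {
      out[i, j] <- sqrt(sum((X[i, ] - Y[j, ])^2))
    }
  }
  out
}

# reference scan of the sorted edge list for greedy partial assignment
brute_greedy <- function(D, alpha, beta) {
  n <- nrow(D); m <- ncol(D)
  want <- min(ceiling(alpha * n), beta * m)
  edges <- expand.grid(i = seq_len(n), j = seq_len(m))
  edges$d <- D[cbind(edges$i, edges$j)]
  edges <- edges[order(edges$d, edges$i, edges$j), ]
  used_src <- logical(n); cnt_tgt <- integer(m)
  keep <- list()
  for (r in seq_len(nrow(edges))) {
    i <- edges$i[r]; j <- edges$j[r]
    if (!used_src[i] && cnt_tgt[j] < beta) {
      used_src[i] <- TRUE
      cnt_tgt[j] <- cnt_tgt[j] + 1L
      keep[[length(keep) + 1L]] <- c(i, j)
      if (length(keep) == want) break
    }
  }
  do.call(rbind, keep)
}

# exhaustive minimum-cost matching of np sources to distinct targets
brute_optimal_cost <- function(D, np) {
  n <- nrow(D); m <- ncol(D)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }))
  }
  best <- Inf
  for (ss in utils::combn(n, np, simplify = FALSE)) {
    for (ts in utils::combn(m, np, simplify = FALSE)) {
      for (p in perms(ts)) {
        best <- min(best, sum(D[cbind(ss, p)]))
      }
    }
  }
  best
}

# brute-force mutual k-nearest-neighbour pairs (ties by index)
brute_mnn <- function(X, Y, k) {
  D <- brute_distances(X, Y)
  n <- nrow(D); m <- ncol(D)
  pairs <- list()
  for (i in seq_len(n)) {
    nn_i <- order(D[i, ])[seq_len(k)]
    for (j in nn_i) {
      nn_j <- order(D[, j])[seq_len(k)]
      if (i %in% nn_j) pairs[[length(pairs) + 1L]] <- c(i, j)
    }
  }
  do.call(rbind, pairs)
}

# exact least-squares fit of Y ~ X W + b via the normal equations
normal_equations_fit <- function(X, Y) {
  Xa <- cbind(X, 1)
  theta <- solve(crossprod(Xa), crossprod(Xa, Y))
  d <- ncol(X)
  list(W = theta[seq_len(d), , drop = FALSE], b = as.numeric(theta[d + 1, ]))
}

scaled_mse_loss <- function(X, Y, W, b) {
  R <- X %*% W + matrix(b, nrow(X), ncol(X), byrow = TRUE) - Y
  mean(rowSums(R^2)) / ncol(X)
}

# independent per-cell LISI: neighbourhood of the 3*perplexity nearest
# cells, Gaussian kernel on squared distance, bandwidth solved with
# uniroot on the entropy, inverse Simpson over label probabilities
brute_lisi <- function(X, labels, perplexity) {
  n <- nrow(X)
  nn <- min(ceiling(3 * perplexity), n - 1)
  target_H <- log(min(perplexity, nn))
  out <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- colSums((t(X[-i, , drop = FALSE]) - X[i, ])^2)
    o <- order(d2)[seq_len(nn)]
    nd <- d2[o] - min(d2[o])
    nl <- labels[-i][o]
    H_of <- function(beta) {
      w <- exp(-beta * nd)
      P <- w / sum(w)
      P <- P[P > 0]
      -sum(P * log(P))
    }
    if (abs(H_of(1e-12) - target_H) < 1e-9) {
      beta <- 1e-12
    } else {
      beta <- stats::uniroot(function(b) H_of(b) - target_H,
                             lower = 1e-12, upper = 1e8,
                             tol = 1e-12)$root
    }
    w <- exp(-beta * nd)
    P <- w / sum(w)
    p <- vapply(unique(nl), function(l) sum(P[nl == l]), numeric(1))
    p <- p / sum(p)
    out[i] <- 1 / sum(p^2)
  }
  out
}
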