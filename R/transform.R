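#' Construct an affine transformation
#'
#' The map is f(x) = W'x + b for a column point x; applied to a cells x
#' genes matrix X row-wise this is `X %*% W + b`. `kind = "rigid"` asserts
#' that W is orthogonal (rotations and reflections; checked to 1e-8), the
#' restricted class used by classic point-cloud registration.
#'
#' @param W d x d numeric weight matrix.
#' @param b Numeric offset vector of length d.
#' @param kind "affine" or "rigid".
#' @return An `affine_transform` object.
#' @export
affine_transform <- function(W, b, kind = c("affine", "rigid")) {
  kind <- match.arg(kind)
  W <- unname(as.matrix(W))
  b <- unname(as.numeric(b))
  if (nrow(W) != ncol(W)) stop("W must be square")
  if (length(b) != nrow(W)) {
    stop("b has length ", length(b), " but W is ", nrow(W), " x ", ncol(W))
  }
  if (kind == "rigid") {
    dev <- max(abs(crossprod(W) - diag(nrow(W))))
    if (dev > 1e-8) {
      stop("kind = 'rigid' requires orthogonal W; max |W'W - I| = ",
           format(dev))
    }
  }
  structure(list(W = W, b = b, kind = kind), class = "affine_transform")
}

#' Identity transformation in d dimensions
#'
#' @param d Gene-space dimension.
#' @return An `affine_transform` with W = I, b = 0.
#' @export
identity_transform <- function(d) {
  stopifnot(d >= 1)
  affine_transform(diag(d), rep(0, d))
}

#' @export
print.affine_transform <- function(x, ...) {
  cat(x$kind, "transform in", length(x$b), "dimensions\n")
  invisible(x)
}

#' Apply a transformation to a matrix of cells
#'
#' @param transform An `affine_transform`.
#' @param X Cells x genes matrix (or `expression_batch`); its column count
#'   must equal the transform dimension.
#' @return Matrix of the same shape (an `expression_batch` in, an
#'   `expression_batch` out).
#' @export
apply_transform <- function(transform, X) {
  stopifnot(inherits(transform, "affine_transform"))
  if (inherits(X, "expression_batch")) {
    out <- X
    out$matrix <- apply_transform(transform, X$matrix)
    return(out)
  }
  X <- as.matrix(X)
  d <- length(transform$b)
  if (ncol(X) != d) {
    stop("X has ", ncol(X), " columns but the transform expects ", d)
  }
  dn <- dimnames(X)
  out <- X %*% transform$W +
    matrix(transform$b, nrow(X), d, byrow = TRUE)
  dimnames(out) <- dn
  out
}

#' Mean squared pair loss
#'
#' The registration objective: the mean over assigned pairs (i, j) of the
#' squared Euclidean distance between the transformed source cell and its
#' target, scaled by 1/d:
#' \deqn{L = \frac{1}{|S|}\sum_{(i,j)\in S}\frac{1}{d}\|W' A_i + b - B_j\|_2^2.}
#'
#' @param A,B Source and target matrices (or batches) with shared gene
#'   order.
#' @param S A `pair_assignment` over rows of `A` and `B`; must be
#'   non-empty.
#' @param transform An `affine_transform` (default: identity).
#' @return Non-negative scalar loss.
#' @export
pair_loss <- function(A, B, S, transform = NULL) {
  A <- as_matrix(A); B <- as_matrix(B)
  stopifnot(inherits(S, "pair_assignment"))
  if (nrow(S$pairs) == 0) stop("empty pair assignment")
  if (is.null(transform)) transform <- identity_transform(ncol(A))
  FA <- apply_transform(transform, A[S$pairs$source, , drop = FALSE])
  R <- FA - B[S$pairs$target, , drop = FALSE]
  mean(rowSums(R^2)) / ncol(A)
}

#' Gradient-descent settings
#'
#' Full-batch gradient descent on the pair loss. Plain gradient descent
#' ("sgd") is the default: on cluster-structured expression data it leaves
#' weakly determined weight directions near the identity initialization
#' instead of chasing them, which keeps the learned map close to a pure
#' batch correction. Adam is available for poorly scaled problems. W is
#' always initialized to the identity, so with coincident pairs the
#' gradient is zero at the start and the fit returns the identity.
#'
#' @param learning_rate Step size (default 0.002).
#' @param epochs Number of full-batch steps (default 100).
#' @param optimizer "sgd" (default) or "adam".
#' @param seed Integer seed recorded with the settings (the fit itself is
#'   deterministic; the seed is set for forward compatibility).
#' @return A `gd_settings` list.
#' @export
gd_settings <- function(learning_rate = 0.002, epochs = 100,
                        optimizer = c("sgd", "adam"), seed = 0) {
  optimizer <- match.arg(optimizer)
  stopifnot(learning_rate > 0, epochs >= 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 optimizer = optimizer, seed = as.integer(seed)),
            class = "gd_settings")
}

#' Fit an affine transformation to assigned pairs by gradient descent
#'
#' Minimizes [pair_loss()] over W and b, starting from the identity. The
#' exact minimizer is an ordinary least-squares solution, but in gene
#' space d is large and the d^3 solve is avoided; gradient descent
#' approximates it. The offset is profiled out analytically: at the
#' optimum b always equals `colMeans(Y) - colMeans(X) %*% W`, so descent
#' runs on W over the mean-centered pairs and b is recovered in closed
#' form. This is the same objective with fewer free parameters; in
#' particular a pure translation between the pair sets is absorbed
#' entirely by b and never distorts W. The per-epoch loss trace (length
#' epochs + 1, including the initial loss) is attached as attribute
#' `loss_trace`.
#'
#' @param A,B Source and target matrices (or batches), shared gene order.
#' @param S A non-empty `pair_assignment`.
#' @param settings A [gd_settings()] object.
#' @return An `affine_transform` with attribute `loss_trace`. Errors if
#'   the loss diverges (exceeds 10x its initial value or becomes
#'   non-finite), advising a smaller learning rate.
#' @export
fit_affine <- function(A, B, S, settings = gd_settings()) {
  A <- as_matrix(A); B <- as_matrix(B)
  stopifnot(inherits(S, "pair_assignment"), inherits(settings, "gd_settings"))
  if (nrow(S$pairs) == 0) stop("empty pair assignment")
  set.seed(settings$seed)
  X <- A[S$pairs$source, , drop = FALSE]
  Y <- B[S$pairs$target, , drop = FALSE]
  d <- ncol(X); ns <- nrow(X)
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  W <- diag(d)
  lr <- settings$learning_rate
  adam <- settings$optimizer == "adam"
  if (adam) {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    mW <- matrix(0, d, d); vW <- matrix(0, d, d)
  }
  trace <- numeric(settings$epochs + 1)
  loss_of <- function(W) mean(rowSums((Xc %*% W - Yc)^2)) / d
  trace[1] <- loss_of(W)
  for (t in seq_len(settings$epochs)) {
    gW <- 2 / (ns * d) * crossprod(Xc, Xc %*% W - Yc)
    if (adam) {
      mW <- b1 * mW + (1 - b1) * gW
      vW <- b2 * vW + (1 - b2) * gW^2
      W <- W - lr * (mW / (1 - b1^t)) / (sqrt(vW / (1 - b2^t)) + eps)
    } else {
      W <- W - lr * gW
    }
    trace[t + 1] <- loss_of(W)
    if (!is.finite(trace[t + 1]) || trace[t + 1] > 10 * (trace[1] + 1e-12)) {
      stop("gradient descent diverged at epoch ", t,
           " (loss ", format(trace[t + 1]),
           "); try a smaller learning_rate")
    }
  }
  b <- as.vector(my - mx %*% W)
  out <- affine_transform(W, b, kind = "affine")
  attr(out, "loss_trace") <- trace
  out
}

#' Fit a rigid transformation (orthogonal Procrustes with translation)
#'
#' Closed-form minimizer of [pair_loss()] restricted to orthogonal W
#' (rotations and reflections, det = +/-1) plus a translation: pair means
#' are removed, W = UV' from the SVD of the cross-covariance of the
#' centered pairs, and b realigns the means. If all source points in the
#' assignment coincide the rotation is undetermined and the identity is
#' returned with the exact translation.
#'
#' @inheritParams fit_affine
#' @return An `affine_transform` with `kind = "rigid"`.
#' @export
fit_rigid <- function(A, B, S) {
  A <- as_matrix(A); B <- as_matrix(B)
  stopifnot(inherits(S, "pair_assignment"))
  if (nrow(S$pairs) == 0) stop("empty pair assignment")
  X <- A[S$pairs$source, , drop = FALSE]
  Y <- B[S$pairs$target, , drop = FALSE]
  d <- ncol(X)
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  M <- crossprod(Xc, Yc)
  if (max(abs(M)) == 0) {
    W <- diag(d)
  } else {
    sv <- svd(M)
    W <- sv$u %*% t(sv$v)
  }
  b <- as.vector(my - mx %*% W)
  affine_transform(W, b, kind = "rigid")
}

#' Compose two transformations
#'
#' Returns the single transform equivalent to applying `first` and then
#' `second`: `apply(compose(first, second), x) == apply(second,
#' apply(first, x))`. In row convention W = W1 W2 and b = b1 W2 + b2. The
#' composition of affine maps is affine, which is what lets the iterative
#' registration collapse its per-iteration fits into one reusable map; the
#' composition of two rigid maps is rigid.
#'
#' @param first,second `affine_transform` objects of equal dimension.
#' @return An `affine_transform`.
#' @export
compose_transforms <- function(first, second) {
  stopifnot(inherits(first, "affine_transform"),
            inherits(second, "affine_transform"))
  if (length(first$b) != length(second$b)) {
    stop("transform dimensions differ: ", length(first$b), " vs ",
         length(second$b))
  }
  W <- first$W %*% second$W
  b <- as.vector(first$b %*% second$W) + second$b
  kind <- if (first$kind == "rigid" && second$kind == "rigid") "rigid"
          else "affine"
  affine_transform(W, b, kind = kind)
}
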