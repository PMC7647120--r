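test_that("identity and application behave as the map definition says", {
  id <- identity_transform(3)
  X <- random_batch(5, 3, seed = 40)$matrix
  expect_equal(apply_transform(id, X), X)
  # translation by 1 increments every entry
  tr <- affine_transform(diag(3), rep(1, 3))
  expect_equal(apply_transform(tr, X), X + 1)
  # scaling: W = 2I on (1, 2) gives (2, 4)
  sc <- affine_transform(2 * diag(2), c(0, 0))
  expect_equal(unname(apply_transform(sc, matrix(c(1, 2), 1, 2))[1, ]),
               c(2, 4))
  # random transform vs explicit per-row computation
  set.seed(41)
  W <- matrix(rnorm(9), 3, 3); b <- rnorm(3)
  t2 <- affine_transform(W, b)
  got <- apply_transform(t2, X)
  for (i in seq_len(nrow(X))) {
    expect_equal(got[i, ], as.vector(t(W) %*% X[i, ] + b),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  expect_error(apply_transform(t2, X[, 1:2]), "columns")
  expect_error(affine_transform(W, c(1, 2)), "length")
  expect_error(affine_transform(matrix(rnorm(9), 3, 3), rep(0, 3),
                                kind = "rigid"), "orthogonal")
})

test_that("pair loss equals the mean per-pair squared distance over d", {
  # coincident pairs at identity -> 0
  X <- random_batch(4, 3, seed = 42)$matrix
  S <- closest_match(pairwise_distances(X, X))
  expect_equal(pair_loss(X, X, S), 0)
  # single 1-d pair 0 vs 3 at identity -> 9
  S1 <- closest_match(matrix(1, 1, 1))
  expect_equal(pair_loss(matrix(0, 1, 1), matrix(3, 1, 1), S1), 9)
  # loss under identity equals mean squared pair distance / d
  Y <- random_batch(4, 3, label = "y", seed = 43)$matrix
  D <- pairwise_distances(X, Y)
  S2 <- closest_match(D)
  expect_equal(pair_loss(X, Y, S2),
               mean(D[cbind(S2$pairs$source, S2$pairs$target)]^2) / 3)
  # seeded random instance vs direct summation loop
  set.seed(44)
  W <- diag(3) + matrix(rnorm(9, sd = 0.1), 3, 3); b <- rnorm(3)
  tr <- affine_transform(W, b)
  acc <- 0
  for (r in seq_len(nrow(S2$pairs))) {
    fx <- as.vector(t(W) %*% X[S2$pairs$source[r], ] + b)
    acc <- acc + sum((fx - Y[S2$pairs$target[r], ])^2) / 3
  }
  expect_equal(pair_loss(X, Y, S2, tr), acc / nrow(S2$pairs),
               tolerance = 1e-12)
})

test_that("affine fit stays at identity when pairs already coincide", {
  X <- random_batch(10, 4, seed = 45)$matrix
  S <- closest_match(pairwise_distances(X, X))
  tr <- fit_affine(X, X, S)
  expect_lt(max(abs(tr$W - diag(4))), 1e-6)
  expect_lt(max(abs(tr$b)), 1e-6)
})

test_that("affine fit recovers a pure translation exactly", {
  X <- random_batch(30, 5, seed = 46)$matrix
  cvec <- c(2, -1, 0.5, 3, -0.25)
  Y <- X + matrix(cvec, 30, 5, byrow = TRUE)
  S <- closest_match(pairwise_distances(X, Y))
  S$pairs <- data.frame(source = 1:30, target = 1:30)  # true correspondences
  # independent check of what least squares would give on these pairs
  ls <- normal_equations_fit(X[S$pairs$source, ], Y[S$pairs$target, ])
  tr <- fit_affine(X, Y, S)
  expect_lt(max(abs(tr$b - cvec)), 1e-2)
  expect_lt(max(abs(tr$W - diag(5))), 1e-2)
  expect_lt(tail(attr(tr, "loss_trace"), 1), 1e-4)
  expect_lt(max(abs(ls$b - cvec)), 1e-8)  # oracle agrees on the optimum
})

test_that("affine fit approaches the normal-equations optimum", {
  set.seed(47)
  for (d in c(3, 5)) {
    n <- 40
    X <- matrix(rnorm(n * d), n, d)
    Wstar <- diag(d) + matrix(rnorm(d * d, sd = 0.2), d, d)
    Y <- X %*% Wstar + matrix(rnorm(d), n, d, byrow = TRUE) +
      matrix(rnorm(n * d, sd = 0.05), n, d)
    S <- closest_match(pairwise_distances(X, Y))
    S$pairs <- data.frame(source = seq_len(n), target = seq_len(n))
    ls <- normal_equations_fit(X, Y)
    opt <- scaled_mse_loss(X, Y, ls$W, ls$b)
    tr <- fit_affine(X, Y, S, gd_settings(learning_rate = 0.5, epochs = 2000))
    got <- scaled_mse_loss(X, Y, tr$W, tr$b)
    expect_lte(got, opt * 1.01 + 1e-12)
    expect_gte(got, opt - 1e-12)  # never below the true optimum
  }
})

test_that("loss trace is non-increasing and divergence fails loudly", {
  X <- random_batch(25, 4, seed = 48)$matrix
  Y <- X + matrix(c(1, -2, 0.5, 1), 25, 4, byrow = TRUE) +
    matrix(rnorm(100, sd = 0.1), 25, 4)
  S <- closest_match(pairwise_distances(X, Y))
  tr <- fit_affine(X, Y, S)
  trace <- attr(tr, "loss_trace")
  expect_equal(length(trace), 101)
  expect_true(all(diff(trace) <= 1e-8))
  expect_lte(tail(trace, 1), trace[1])
  expect_error(fit_affine(X, Y, S, gd_settings(learning_rate = 50)),
               "learning_rate")
})

test_that("rigid fit recovers rotations and translations in closed form", {
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  X <- random_batch(20, 2, seed = 49)$matrix
  Y <- X %*% R
  S <- closest_match(pairwise_distances(X, Y))
  S$pairs <- data.frame(source = 1:20, target = 1:20)
  tr <- fit_rigid(X, Y, S)
  expect_lt(max(abs(tr$W - R)), 1e-8)
  expect_lt(max(abs(tr$b)), 1e-8)
  expect_identical(tr$kind, "rigid")
  # pure translation: W = I, b = c
  cvec <- c(4, -3)
  Y2 <- X + matrix(cvec, 20, 2, byrow = TRUE)
  tr2 <- fit_rigid(X, Y2, S)
  expect_lt(max(abs(tr2$W - diag(2))), 1e-8)
  expect_lt(max(abs(tr2$b - cvec)), 1e-8)
  # degenerate: all source points identical -> identity rotation, exact b
  X0 <- matrix(1, 5, 2)
  Y0 <- matrix(c(3, 4), 5, 2, byrow = TRUE)
  S0 <- closest_match(pairwise_distances(X0, Y0))
  tr0 <- fit_rigid(X0, Y0, S0)
  expect_equal(tr0$W, diag(2))
  expect_equal(tr0$b, c(2, 3))
})

test_that("rigid fits are orthogonal and never beat the affine fit", {
  set.seed(50)
  for (trial in 1:5) {
    d <- sample(2:5, 1); n <- 30
    X <- matrix(rnorm(n * d), n, d)
    Y <- X %*% (diag(d) * runif(1, 0.5, 2)) + matrix(rnorm(n * d, sd = 0.2),
                                                     n, d)
    S <- closest_match(pairwise_distances(X, Y))
    S$pairs <- data.frame(source = seq_len(n), target = seq_len(n))
    rig <- fit_rigid(X, Y, S)
    expect_lt(max(abs(crossprod(rig$W) - diag(d))), 1e-8)
    aff <- fit_affine(X, Y, S, gd_settings(learning_rate = 0.5,
                                           epochs = 2000))
    expect_lte(pair_loss(X, Y, S, aff), pair_loss(X, Y, S, rig) + 1e-10)
  }
})

test_that("composition equals sequential application and is associative", {
  set.seed(51)
  mk <- function() affine_transform(diag(3) + matrix(rnorm(9, sd = 0.3), 3, 3),
                                    rnorm(3))
  t1 <- mk(); t2 <- mk(); t3 <- mk()
  id <- identity_transform(3)
  X <- matrix(rnorm(60), 20, 3)
  expect_equal(compose_transforms(id, t1)$W, t1$W)
  expect_equal(compose_transforms(t1, id)$b, t1$b)
  expect_equal(compose_transforms(id, id)$W, diag(3))
  # two translations add
  ta <- affine_transform(diag(3), c(1, 2, 3))
  tb <- affine_transform(diag(3), c(-1, 1, 0))
  expect_equal(compose_transforms(ta, tb)$b, c(0, 3, 3))
  # composed application == sequential application
  comp <- compose_transforms(t1, t2)
  expect_lt(max(abs(apply_transform(comp, X) -
                      apply_transform(t2, apply_transform(t1, X)))), 1e-10)
  # associativity
  left <- compose_transforms(compose_transforms(t1, t2), t3)
  right <- compose_transforms(t1, compose_transforms(t2, t3))
  expect_lt(max(abs(apply_transform(left, X) - apply_transform(right, X))),
            1e-9)
  expect_error(compose_transforms(t1, identity_transform(2)), "differ")
})
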