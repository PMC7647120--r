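# module-level fixture: the standard translation scenario
std_sim <- simulate_batches(simulation_spec(seed = 7))

test_that("fitting identical batches stays at the identity", {
  b <- random_batch(40, 6, seed = 60, types = rep(c("a", "b"), 20))
  # closest matching pairs every cell with itself: exact no-op
  mc <- scipr_fit(b, b, scipr_config(matching = "closest", iterations = 3))
  expect_lt(max(abs(mc$composite$W - diag(6))), 1e-12)
  expect_lt(max(abs(mc$composite$b)), 1e-12)
  expect_lt(mc$diagnostics$mean_distance[1], 1e-6)
  # MNN also pairs non-self mutual neighbours, so the fit wobbles within
  # the neighbourhood noise but stays near the identity
  m <- scipr_fit(b, b, scipr_config(matching = "mnn", k = 5, iterations = 3))
  expect_lt(max(abs(m$composite$W - diag(6))), 0.05)
  expect_lt(max(abs(m$composite$b)), 0.05)
})

test_that("iteration reduces matched distances and records diagnostics", {
  m <- scipr_fit(std_sim$source, std_sim$target, scipr_config())
  d <- m$diagnostics
  expect_true(all(diff(d$mean_distance) <= 0))
  expect_lte(nrow(d), 5)
  # converges to the aligned nearest-neighbour noise floor: well under the
  # initial batch gap, but bounded below by sigma * sqrt(2d) geometry
  expect_lt(tail(d$mean_distance, 1), 0.55 * d$mean_distance[1])
  expect_true(all(c("iteration", "n_pairs", "mean_distance", "final_loss")
                  %in% colnames(d)))
  # source input itself is never mutated
  expect_identical(std_sim$source$matrix,
                   simulate_batches(simulation_spec(seed = 7))$source$matrix)
})

test_that("composite application equals the sequential iteration loop", {
  m <- scipr_fit(std_sim$source, std_sim$target, scipr_config())
  seq_mat <- std_sim$source$matrix
  for (tr in m$transforms) seq_mat <- apply_transform(tr, seq_mat)
  comp_mat <- apply_transform(m$composite, std_sim$source$matrix)
  expect_lt(max(abs(seq_mat - comp_mat)), 1e-6)
  # scipr_transform on the training source reproduces the loop final state
  al <- scipr_transform(m, std_sim$source)
  expect_equal(al$matrix, comp_mat, tolerance = 1e-12)
  expect_identical(al$cell_ids, std_sim$source$cell_ids)
  expect_identical(al$gene_names, std_sim$source$gene_names)
})

test_that("fit is deterministic given the same inputs and seeds", {
  cfg <- scipr_config(matching = "greedy", iterations = 3)
  m1 <- scipr_fit(std_sim$source, std_sim$target, cfg)
  m2 <- scipr_fit(std_sim$source, std_sim$target, cfg)
  expect_identical(m1$composite$W, m2$composite$W)
  expect_identical(m1$composite$b, m2$composite$b)
  expect_identical(m1$diagnostics, m2$diagnostics)
})

test_that("transform validates gene order and honors the identity", {
  m <- scipr_fit(std_sim$source, std_sim$target,
                 scipr_config(iterations = 1))
  wrong <- std_sim$source
  wrong$gene_names <- rev(wrong$gene_names)
  colnames(wrong$matrix) <- wrong$gene_names
  expect_error(scipr_transform(m, wrong), "gene1")
  id_model <- m
  id_model$composite <- identity_transform(20)
  out <- scipr_transform(id_model, std_sim$source)
  expect_equal(out$matrix, std_sim$source$matrix)
})

test_that("early stop halts when matched distance stops improving", {
  # no batch effect: converged from the start, so iteration 2 cannot
  # improve by more than the tolerance
  sim0 <- simulate_batches(simulation_spec(seed = 8, batch_effect = "none"))
  m <- scipr_fit(sim0$source, sim0$target,
                 scipr_config(iterations = 5, tolerance = 0.05))
  expect_lt(nrow(m$diagnostics), 5)
})

test_that("a held-out source cell type is moved toward its target type", {
  sc <- simulate_scenario("source_holdout", simulation_spec(seed = 5))
  expect_false("type3" %in% sc$source$cell_types)
  expect_true(all(sc$held$cell_types == "type3"))
  m <- scipr_fit(sc$source, sc$target, scipr_config())
  held_al <- scipr_transform(m, sc$held)
  cen <- colMeans(sc$target$matrix[sc$target$cell_types == "type3", ,
                                   drop = FALSE])
  pre <- mean(sqrt(rowSums(sweep(sc$held$matrix, 2, cen)^2)))
  post <- mean(sqrt(rowSums(sweep(held_al$matrix, 2, cen)^2)))
  expect_lt(post, pre)
})

test_that("multi-batch alignment is independent pairwise fits", {
  ref <- simulate_batches(simulation_spec(seed = 31))$target
  srcs <- lapply(c(32, 33, 34), function(s) {
    b <- simulate_batches(simulation_spec(seed = s))$source
    b$batch_label <- paste0("src", s)
    b
  })
  models <- align_to_reference(srcs, ref, scipr_config(iterations = 3))
  expect_length(models, 3)
  expect_identical(names(models), c("src32", "src33", "src34"))
  for (i in seq_along(models)) {
    d <- models[[i]]$diagnostics
    expect_lt(tail(d$mean_distance, 1), d$mean_distance[1])
    # each model equals its own standalone pairwise fit
    solo <- scipr_fit(srcs[[i]], ref, scipr_config(iterations = 3))
    expect_identical(models[[i]]$composite$W, solo$composite$W)
  }
  # single source is identical to fit
  one <- align_to_reference(srcs[[1]], ref, scipr_config(iterations = 3))
  expect_identical(one[[1]]$composite$b, models[[1]]$composite$b)
})

test_that("gene ranking scores deviation from the identity map", {
  m <- scipr_fit(std_sim$source, std_sim$target,
                 scipr_config(iterations = 1))
  # identity composite -> all scores zero
  m0 <- m
  m0$composite <- identity_transform(20)
  rk0 <- rank_genes(m0)
  expect_true(all(rk0$score == 0))
  expect_identical(rk0$gene, sort(m$gene_names))  # alphabetical tie-break
  # offset on one gene alone puts it first
  m1 <- m0
  m1$composite$b[5] <- 3
  expect_identical(rank_genes(m1)$gene[1], m$gene_names[5])
  # rigid models are not gene-interpretable
  mr <- scipr_fit(std_sim$source, std_sim$target,
                  scipr_config(transform_kind = "rigid", iterations = 1))
  expect_error(rank_genes(mr), "affine")
})

test_that("empty matchings and empty batches error clearly", {
  empty <- expression_batch(matrix(numeric(0), 0, 3,
                                   dimnames = list(NULL, paste0("g", 1:3))))
  b <- random_batch(5, 3, seed = 61)
  expect_error(scipr_fit(empty, b), "non-empty")
})

test_that("pure-noise genes only mildly degrade the alignment", {
  base <- simulate_scenario("shared", simulation_spec(seed = 7))
  noisy <- simulate_scenario("extra_noise_genes", simulation_spec(seed = 7))
  expect_equal(ncol(noisy$source$matrix), 40)
  # first d genes identical to the shared scenario
  expect_identical(noisy$source$matrix[, 1:20], base$source$matrix)
  fit_eval <- function(sc) {
    m <- scipr_fit(sc$source, sc$target, scipr_config())
    ilisi_clisi(list(scipr_transform(m, sc$source), sc$target))$ilisi$median
  }
  expect_lt(fit_eval(base) - fit_eval(noisy), 0.3)
})
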