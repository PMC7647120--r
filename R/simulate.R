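#' Specification for a synthetic two-batch experiment
#'
#' The simulator emulates the situation the alignment method is built for:
#' several cell types shared (or partially shared) between two batches
#' that differ by an unknown affine batch effect plus noise. Per-type
#' centroids are drawn isotropically at scale `centroid_scale`; target
#' cells are centroid + Gaussian noise; source cells are independently
#' drawn same-centroid cells pushed through the batch effect. Because the
#' effect is known, the exact inverse map is returned as ground truth.
#'
#' Values are Gaussian log-scale expression rather than counts: the
#' alignment operates on log-normalized data, so Gaussian structure
#' exercises all of the math while dropout and library-size variation of
#' real counts are deliberately not modelled.
#'
#' @param n_types Number of cell types (default 3).
#' @param n_genes Gene-space dimension d (default 20).
#' @param cells_per_type Cells per type per batch; scalar or vector of
#'   length `n_types` (default 100).
#' @param batch_effect "translation", "affine" or "none".
#' @param offset Translation vector c (length `n_genes`). If NULL under
#'   "translation", a random direction of norm `offset_norm` is drawn.
#' @param offset_norm Norm of the default random translation (default 5).
#' @param effect_matrix Affine effect matrix W* (d x d, invertible). If
#'   NULL under "affine", a mild distortion of the identity is drawn
#'   (per-gene scale factors uniform in [0.6, 1.4] plus Gaussian shear of
#'   sd 0.1/sqrt(d)); its condition number is recorded.
#' @param effect_offset Affine effect offset b*; default a random vector
#'   of norm 2 under "affine", zero otherwise.
#' @param noise_sd Standard deviation of the isotropic per-cell noise
#'   (default 0.5).
#' @param centroid_scale Standard deviation of the centroid draw
#'   (default 5).
#' @param n_noise_genes Number of pure-noise genes (sd `noise_sd`, no type
#'   or batch structure) appended to both batches (default 0).
#' @param seed Integer seed; the same spec always yields identical output.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_types = 3, n_genes = 20, cells_per_type = 100,
                            batch_effect = c("translation", "affine", "none"),
                            offset = NULL, offset_norm = 5,
                            effect_matrix = NULL, effect_offset = NULL,
                            noise_sd = 0.5, centroid_scale = 5,
                            n_noise_genes = 0, seed = 1) {
  batch_effect <- match.arg(batch_effect)
  stopifnot(n_types >= 1, n_genes >= 1, all(cells_per_type >= 1),
            noise_sd >= 0, centroid_scale > 0, n_noise_genes >= 0)
  if (!length(cells_per_type) %in% c(1L, n_types)) {
    stop("cells_per_type must be a scalar or length n_types")
  }
  if (!is.null(offset) && length(offset) != n_genes) {
    stop("offset must have length n_genes")
  }
  if (!is.null(effect_matrix)) {
    effect_matrix <- as.matrix(effect_matrix)
    if (!all(dim(effect_matrix) == n_genes)) {
      stop("effect_matrix must be n_genes x n_genes")
    }
    sv <- svd(effect_matrix)$d
    if (min(sv) < 1e-10) stop("effect_matrix must be invertible")
  }
  structure(list(n_types = as.integer(n_types),
                 n_genes = as.integer(n_genes),
                 cells_per_type = rep(as.integer(cells_per_type),
                                      length.out = n_types),
                 batch_effect = batch_effect, offset = offset,
                 offset_norm = offset_norm, effect_matrix = effect_matrix,
                 effect_offset = effect_offset, noise_sd = noise_sd,
                 centroid_scale = centroid_scale,
                 n_noise_genes = as.integer(n_noise_genes),
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a source/target batch pair with known batch effect
#'
#' @param spec A [simulation_spec()].
#' @return List with `source` and `target` (`expression_batch` objects
#'   with type labels), `truth` (the `affine_transform` mapping source
#'   coordinates onto target coordinates, i.e. the exact inverse of the
#'   applied effect, extended by the identity over any noise genes) and
#'   `params` (the drawn effect parameters; for an affine effect the
#'   condition number of W* is included).
#' @export
simulate_batches <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  d <- spec$n_genes
  centroids <- matrix(stats::rnorm(spec$n_types * d, sd = spec$centroid_scale),
                      spec$n_types, d)
  draw_cells <- function() {
    do.call(rbind, lapply(seq_len(spec$n_types), function(ty) {
      nc <- spec$cells_per_type[ty]
      matrix(centroids[ty, ], nc, d, byrow = TRUE) +
        matrix(stats::rnorm(nc * d, sd = spec$noise_sd), nc, d)
    }))
  }
  types <- rep(paste0("type", seq_len(spec$n_types)),
               times = spec$cells_per_type)
  target_mat <- draw_cells()
  source_lat <- draw_cells()
  # batch-effect parameters (drawn after the cells so that specs differing
  # only in the effect share identical underlying draws)
  eff <- batch_effect_params(spec, d)
  source_mat <- source_lat %*% eff$W + matrix(eff$b, nrow(source_lat), d,
                                              byrow = TRUE)
  if (spec$n_noise_genes > 0) {
    ng <- spec$n_noise_genes
    target_mat <- cbind(target_mat,
                        matrix(stats::rnorm(nrow(target_mat) * ng,
                                            sd = spec$noise_sd),
                               nrow(target_mat), ng))
    source_mat <- cbind(source_mat,
                        matrix(stats::rnorm(nrow(source_mat) * ng,
                                            sd = spec$noise_sd),
                               nrow(source_mat), ng))
  }
  dtot <- d + spec$n_noise_genes
  genes <- c(paste0("gene", seq_len(d)),
             if (spec$n_noise_genes > 0) {
               paste0("noise", seq_len(spec$n_noise_genes))
             })
  Winv <- solve(eff$W)
  Wt <- diag(dtot); Wt[seq_len(d), seq_len(d)] <- Winv
  bt <- rep(0, dtot); bt[seq_len(d)] <- as.vector(-eff$b %*% Winv)
  truth <- affine_transform(Wt, bt)
  mk_batch <- function(mat, label, prefix) {
    expression_batch(mat,
                     cell_ids = paste0(prefix, "_", types, "_",
                                       sequence(spec$cells_per_type)),
                     gene_names = genes, batch_label = label,
                     cell_types = types)
  }
  params <- list(W = eff$W, b = eff$b, centroids = centroids)
  if (spec$batch_effect == "affine") {
    sv <- svd(eff$W)$d
    params$condition_number <- max(sv) / min(sv)
  }
  list(source = mk_batch(source_mat, "source", "src"),
       target = mk_batch(target_mat, "target", "tgt"),
       truth = truth, params = params, spec = spec)
}

batch_effect_params <- function(spec, d) {
  if (spec$batch_effect == "none") {
    return(list(W = diag(d), b = rep(0, d)))
  }
  if (spec$batch_effect == "translation") {
    b <- spec$offset
    if (is.null(b)) {
      u <- stats::rnorm(d)
      b <- u / sqrt(sum(u^2)) * spec$offset_norm
    }
    return(list(W = diag(d), b = as.numeric(b)))
  }
  # affine: a mild distortion of the identity (per-gene scaling plus
  # shear), the shape real batch effects take -- platforms rescale and mix
  # gene measurements, they do not arbitrarily rotate gene space
  W <- spec$effect_matrix
  if (is.null(W)) {
    W <- diag(stats::runif(d, 0.6, 1.4)) +
      matrix(stats::rnorm(d * d, sd = 0.1 / sqrt(d)), d, d)
  }
  b <- spec$effect_offset
  if (is.null(b)) {
    u <- stats::rnorm(d)
    b <- u / sqrt(sum(u^2)) * 2
  }
  list(W = W, b = as.numeric(b))
}

#' Build a named evaluation scenario
#'
#' Packages [simulate_batches()] output for the standard protocols:
#' \describe{
#'   \item{shared}{both batches contain every type.}
#'   \item{target_holdout}{one type is removed from the target; the source
#'     keeps all types (robustness to non-overlapping composition).}
#'   \item{source_holdout}{one type is removed from the source used for
#'     fitting; its cells are returned separately so a fitted model can be
#'     applied to them afterwards (generalization to unseen cells).}
#'   \item{extra_noise_genes}{the gene set is doubled with pure-noise
#'     genes; the first d genes are identical to the shared scenario for
#'     the same spec.}
#' }
#'
#' @param name Scenario name.
#' @param spec A [simulation_spec()]; hold-out scenarios need at least two
#'   types.
#' @param holdout_type Type to hold out (default: the last type).
#' @return List with `source`, `target`, `truth`, `params`, `held`
#'   (an `expression_batch` or NULL) and `scenario`.
#' @export
simulate_scenario <- function(name = c("shared", "target_holdout",
                                       "source_holdout",
                                       "extra_noise_genes"),
                              spec = simulation_spec(),
                              holdout_type = NULL) {
  name <- match.arg(name)
  if (name == "extra_noise_genes" && spec$n_noise_genes == 0) {
    spec$n_noise_genes <- spec$n_genes
  }
  sim <- simulate_batches(spec)
  held <- NULL
  if (name %in% c("target_holdout", "source_holdout")) {
    if (spec$n_types < 2) stop("hold-out scenarios need at least 2 types")
    if (is.null(holdout_type)) {
      holdout_type <- paste0("type", spec$n_types)
    }
    if (name == "target_holdout") {
      sp <- hold_out_type(sim$target, holdout_type)
      sim$target <- sp$retained
    } else {
      sp <- hold_out_type(sim$source, holdout_type)
      sim$source <- sp$retained
    }
    held <- sp$held
  }
  c(sim[c("source", "target", "truth", "params", "spec")],
    list(held = held, scenario = name))
}
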