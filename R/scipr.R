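#' Configuration for iterative registration
#'
#' Defaults follow the method's published settings: mutual nearest
#' neighbours with k = 10 (greedy matching uses alpha = 0.5, beta = 2), an
#' affine transform fitted by gradient descent, and at most 5 iterations.
#' MNN is the default strategy; greedy matching is recommended when the
#' user has prior expectations on what fraction of cells should match
#' (e.g. known missing cell types), since alpha/beta encode that belief.
#'
#' @param matching "mnn", "greedy" or "closest".
#' @param transform_kind "affine" (default) or "rigid".
#' @param iterations Maximum number of match/fit/apply iterations
#'   (default 5).
#' @param alpha,beta Greedy matching parameters (defaults 0.5 and 2).
#' @param k MNN neighbourhood size (default 10).
#' @param gd A [gd_settings()] object for the affine fit.
#' @param tolerance Relative improvement in mean matched-pair distance
#'   below which iteration stops early (default 1e-4).
#' @return A `scipr_config` list.
#' @export
scipr_config <- function(matching = c("mnn", "greedy", "closest"),
                         transform_kind = c("affine", "rigid"),
                         iterations = 5, alpha = 0.5, beta = 2, k = 10,
                         gd = gd_settings(), tolerance = 1e-4) {
  matching <- match.arg(matching)
  transform_kind <- match.arg(transform_kind)
  stopifnot(iterations >= 1, tolerance >= 0)
  if (!inherits(gd, "gd_settings")) gd <- do.call(gd_settings, gd)
  structure(list(matching = matching, transform_kind = transform_kind,
                 iterations = as.integer(iterations), alpha = alpha,
                 beta = as.integer(beta), k = as.integer(k), gd = gd,
                 tolerance = tolerance),
            class = "scipr_config")
}

#' Fit an iterative point-set registration model
#'
#' Each iteration (1) assigns pairs between the current, already-moved
#' source cells and the fixed target cells using the configured strategy,
#' (2) fits a fresh transform (from the identity) on the assigned pairs,
#' and (3) applies it to ALL current source cells, not just the matched
#' ones. Iteration stops after `config$iterations` rounds or as soon as
#' the mean matched-pair distance (measured before fitting) fails to
#' improve by more than `config$tolerance` relative to the previous
#' iteration. The final model is the ordered composition of the
#' per-iteration transforms: a single affine map that can be stored and
#' applied to unseen cells. The input batches are never mutated.
#'
#' @param source `expression_batch` to be moved onto `target`.
#' @param target Fixed reference `expression_batch`; must share the
#'   source's gene order.
#' @param config A [scipr_config()].
#' @return A `scipr_model`: list with `composite` (the fused
#'   `affine_transform`), `transforms` (per iteration), `config`,
#'   `diagnostics` (data frame: iteration, n_pairs, mean_distance,
#'   final_loss) and `gene_names`.
#' @export
scipr_fit <- function(source, target, config = scipr_config()) {
  stopifnot(inherits(source, "expression_batch"),
            inherits(target, "expression_batch"),
            inherits(config, "scipr_config"))
  check_gene_space(source, target)
  if (nrow(source$matrix) == 0 || nrow(target$matrix) == 0) {
    stop("source and target must be non-empty")
  }
  Amat <- source$matrix
  Bmat <- target$matrix
  transforms <- list()
  diag_rows <- list()
  prev_md <- Inf
  for (t in seq_len(config$iterations)) {
    D <- pairwise_distances(Amat, Bmat)
    S <- switch(config$matching,
      closest = closest_match(D),
      greedy = greedy_match(D, alpha = config$alpha, beta = config$beta),
      mnn = mnn_match_from_distances(D, k = config$k)
    )
    if (nrow(S$pairs) == 0) {
      stop("matching strategy '", config$matching, "' (",
           paste(names(S$params), unlist(S$params), sep = "=",
                 collapse = ", "),
           ") produced no pairs at iteration ", t)
    }
    md <- mean(D[cbind(S$pairs$source, S$pairs$target)])
    if (t > 1 && (prev_md - md) <= config$tolerance * prev_md) break
    tr <- if (config$transform_kind == "affine") {
      fit_affine(Amat, Bmat, S, settings = config$gd)
    } else {
      fit_rigid(Amat, Bmat, S)
    }
    Amat <- apply_transform(tr, Amat)
    transforms[[t]] <- tr
    final_loss <- if (config$transform_kind == "affine") {
      utils::tail(attr(tr, "loss_trace"), 1)
    } else {
      pair_loss(Amat, Bmat, S)  # rigid has no trace; loss after the move
    }
    diag_rows[[t]] <- data.frame(iteration = t, n_pairs = nrow(S$pairs),
                                 mean_distance = md, final_loss = final_loss)
    prev_md <- md
  }
  composite <- Reduce(compose_transforms, transforms)
  structure(
    list(composite = composite, transforms = transforms, config = config,
         diagnostics = do.call(rbind, diag_rows),
         gene_names = source$gene_names),
    class = "scipr_model"
  )
}

#' @export
print.scipr_model <- function(x, ...) {
  cat("scipr_model: ", x$config$matching, "/", x$config$transform_kind,
      ", ", nrow(x$diagnostics), " iteration(s), d = ",
      length(x$composite$b), "\n", sep = "")
  print(x$diagnostics, row.names = FALSE)
  invisible(x)
}

#' Apply a fitted model to a batch
#'
#' Transforms the expression matrix of `X` with the model's composite
#' affine map. Gene names must equal the model's training gene order; cell
#' ids, labels and gene semantics are untouched, which is what makes the
#' aligned output directly interpretable gene-by-gene and applicable to
#' cells never seen during fitting.
#'
#' @param model A `scipr_model`.
#' @param X An `expression_batch` (or bare matrix with matching columns).
#' @return The transformed batch (or matrix).
#' @export
scipr_transform <- function(model, X) {
  stopifnot(inherits(model, "scipr_model"))
  gx <- if (inherits(X, "expression_batch")) X$gene_names else colnames(X)
  if (!is.null(gx) && !identical(gx, model$gene_names)) {
    k <- min(length(gx), length(model$gene_names))
    idx <- which(gx[seq_len(k)] != model$gene_names[seq_len(k)])[1]
    if (is.na(idx)) idx <- k + 1
    stop("gene order does not match the model (first mismatch at ",
         "position ", idx, ": expected '",
         if (idx <= length(model$gene_names)) model$gene_names[idx]
         else "<absent>",
         "', got '", if (idx <= length(gx)) gx[idx] else "<absent>", "')")
  }
  apply_transform(model$composite, X)
}

#' Align several source batches to one reference
#'
#' Fits an independent pairwise registration of each source onto the same
#' fixed reference; the reference itself is never transformed. This is the
#' multi-batch strategy: choose the largest batch as the reference and map
#' every other batch onto it.
#'
#' @param sources List of `expression_batch` objects.
#' @param reference The fixed reference `expression_batch`.
#' @param config A [scipr_config()] used for every fit.
#' @return A named list of `scipr_model` objects (names from batch
#'   labels).
#' @export
align_to_reference <- function(sources, reference, config = scipr_config()) {
  if (inherits(sources, "expression_batch")) sources <- list(sources)
  models <- lapply(sources, scipr_fit, target = reference, config = config)
  names(models) <- vapply(sources, function(b) b$batch_label, character(1))
  models
}

#' Rank genes by their learned alignment coefficients
#'
#' A fitted affine map places weights on genes; genes the model had to
#' move (relative to leaving the data untouched) are the ones driving the
#' batch difference. The importance of gene g is the column-wise deviation
#' of the composite weight matrix from the identity plus the offset
#' magnitude:
#' \deqn{\mathrm{score}(g) = \sum_i |W_{ig} - I_{ig}| + |b_g|.}
#' Genes are returned in descending score order, ties broken
#' alphabetically.
#'
#' @param model A `scipr_model` fitted with `transform_kind = "affine"`.
#' @return A data frame with columns `gene` and `score`, highest first.
#' @export
rank_genes <- function(model) {
  stopifnot(inherits(model, "scipr_model"))
  if (model$composite$kind != "affine") {
    stop("gene ranking requires an affine model; rigid weights are not ",
         "gene-interpretable in the same way")
  }
  W <- model$composite$W
  score <- colSums(abs(W - diag(nrow(W)))) + abs(model$composite$b)
  genes <- model$gene_names
  ord <- order(-score, genes)
  data.frame(gene = genes[ord], score = unname(score[ord]),
             stringsAsFactors = FALSE)
}
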