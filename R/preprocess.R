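#' Library-size normalize and log-transform counts
#'
#' Each cell's counts are scaled so that they sum to `scale` (counts per
#' ten-thousand by default), then `log(1 + x)` is applied. Cells whose
#' total count is zero cannot be scaled and are removed; the number removed
#' is recorded in the `removed_cells` attribute and reported via a message.
#'
#' @param batch An `expression_batch` of raw, non-negative counts.
#' @param scale Positive total to which each cell is scaled (default 1e4).
#' @return A log-normalized `expression_batch`; attribute `removed_cells`
#'   holds the ids of any dropped zero-count cells.
#' @export
normalize_counts <- function(batch, scale = 1e4) {
  stopifnot(inherits(batch, "expression_batch"), scale > 0)
  if (any(batch$matrix < 0)) {
    stop("normalize_counts expects non-negative counts; found negative values")
  }
  totals <- rowSums(batch$matrix)
  keep <- totals > 0
  removed <- batch$cell_ids[!keep]
  if (length(removed) > 0) {
    message("removed ", length(removed), " cell(s) with zero total counts")
  }
  mat <- batch$matrix[keep, , drop = FALSE]
  mat <- log1p(mat / totals[keep] * scale)
  out <- expression_batch(mat, cell_ids = batch$cell_ids[keep],
                          gene_names = batch$gene_names,
                          batch_label = batch$batch_label,
                          cell_types = if (is.null(batch$cell_types)) NULL
                                       else batch$cell_types[keep])
  attr(out, "removed_cells") <- removed
  out
}

#' Select highly variable genes across batches
#'
#' Batches are first restricted to their common gene universe, then pooled
#' (rows concatenated), and each gene is scored by its dispersion
#' (variance / mean) of expression over all pooled cells. Genes with zero
#' mean score 0. The top `n_genes` by dispersion are returned, ties broken
#' alphabetically by gene name, so the selection is deterministic.
#'
#' Subsetting every batch to the returned list (see [subset_genes()])
#' leaves all batches with identical gene names in identical order.
#'
#' @param batches A single `expression_batch` or a list of them,
#'   typically log-normalized.
#' @param n_genes Number of genes to select.
#' @return Character vector of `n_genes` gene names, most dispersed first.
#' @export
select_hvg <- function(batches, n_genes) {
  if (inherits(batches, "expression_batch")) batches <- list(batches)
  stopifnot(length(batches) >= 1, n_genes >= 1)
  common <- Reduce(intersect, lapply(batches, function(b) b$gene_names))
  if (length(common) == 0) stop("batches share no genes")
  if (n_genes > length(common)) {
    stop("n_genes (", n_genes, ") exceeds the ", length(common),
         " genes common to all batches")
  }
  pooled <- do.call(rbind, lapply(batches, function(b) {
    b$matrix[, common, drop = FALSE]
  }))
  mu <- colMeans(pooled)
  v <- apply(pooled, 2, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  ord <- order(-disp, common)
  common[ord][seq_len(n_genes)]
}
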