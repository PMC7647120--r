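#' Local inverse Simpson's index (LISI)
#'
#' For each cell, the neighbourhood of its `3 * perplexity` nearest cells
#' (excluding itself) is weighted with a Gaussian kernel on squared
#' Euclidean distance whose bandwidth is calibrated per cell, by bisection,
#' so that the Shannon entropy of the weights equals log(perplexity)
#' (to 1e-10, at most 100 bisection steps). Kernel weights are summed by
#' label into probabilities p_l, and the score is the inverse Simpson
#' index 1 / sum(p_l^2): the effective number of labels in the local
#' neighbourhood. Scores lie in [1, L] where L is the number of distinct
#' labels; 1 means no local diversity.
#'
#' When fewer than `3 * perplexity` other cells exist, all other cells are
#' used and a message notes the shrunken neighbourhood.
#'
#' @param points Cells x genes numeric matrix (or `expression_batch`).
#' @param labels Character vector of per-cell labels.
#' @param perplexity Effective neighbourhood size parameter (default 30);
#'   must be smaller than the number of cells.
#' @return A `lisi_scores` object: list with `per_cell`, `median` and
#'   `label_kind` (NA unless set by the caller).
#' @export
lisi <- function(points, labels, perplexity = 30) {
  X <- as_matrix(points)
  n <- nrow(X)
  labels <- as.character(labels)
  if (n < 2) stop("LISI needs at least 2 cells")
  if (length(labels) != n) stop("labels length must equal the cell count")
  if (perplexity >= n) stop("perplexity must be smaller than the cell count")
  nn_size <- min(ceiling(3 * perplexity), n - 1)
  if (3 * perplexity > n - 1) {
    message("neighbourhood truncated to all ", n - 1,
            " other cells (3 * perplexity = ", 3 * perplexity, ")")
  }
  D2 <- pairwise_distances(X, X)^2
  log_u <- log(min(perplexity, nn_size))
  per_cell <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- D2[i, -i]
    nb <- order(d2)[seq_len(nn_size)]
    nd <- d2[nb]
    nl <- labels[-i][nb]
    P <- kernel_weights(nd, log_u)
    p <- tapply(P, nl, sum)
    p <- p / sum(p)
    per_cell[i] <- 1 / sum(p^2)
  }
  new_lisi_scores(per_cell)
}

# Gaussian kernel weights over squared distances with bandwidth (precision
# beta) calibrated so the weight entropy matches log_u. Bisection with
# expanding bounds; tolerance 1e-5 in entropy, at most 100 steps.
kernel_weights <- function(d2, log_u, tol = 1e-10, max_iter = 100) {
  d2 <- d2 - min(d2)  # shift for numerical stability; weights unchanged
  entropy_at <- function(beta) {
    w <- exp(-beta * d2)
    P <- w / sum(w)
    nzP <- P[P > 0]
    -sum(nzP * log(nzP))
  }
  beta <- 1
  lo <- 0; hi <- Inf
  for (iter in seq_len(max_iter)) {
    H <- entropy_at(beta)
    if (abs(H - log_u) < tol) break
    if (H > log_u) {       # too diffuse: sharpen
      lo <- beta
      beta <- if (is.finite(hi)) (lo + hi) / 2 else beta * 2
    } else {               # too sharp: widen
      hi <- beta
      beta <- (lo + hi) / 2
    }
  }
  w <- exp(-beta * d2)
  w / sum(w)
}

new_lisi_scores <- function(per_cell, label_kind = NA_character_) {
  structure(list(per_cell = per_cell,
                 median = stats::median(per_cell),
                 label_kind = label_kind),
            class = "lisi_scores")
}

#' @export
print.lisi_scores <- function(x, ...) {
  cat("lisi_scores", if (!is.na(x$label_kind)) paste0("(", x$label_kind, ")"),
      ": ", length(x$per_cell), " cells, median ",
      format(x$median, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Integration and cell-type LISI for a set of batches
#'
#' Concatenates the batches (which must share gene order) and computes
#' LISI twice: with the batch label (iLISI, higher = better batch mixing)
#' and with the cell-type label (cLISI, lower = better type separation).
#' If any batch lacks cell-type labels, cLISI is reported as unavailable
#' (`NULL`) with a warning, never silently as 1.
#'
#' @param batches List of `expression_batch` objects (typically target plus
#'   aligned sources).
#' @param perplexity Passed to [lisi()].
#' @return List with elements `ilisi` (`lisi_scores`), `clisi`
#'   (`lisi_scores` or NULL) and `clisi_available` (logical).
#' @export
ilisi_clisi <- function(batches, perplexity = 30) {
  if (inherits(batches, "expression_batch")) batches <- list(batches)
  pooled <- bind_batches(batches)
  il <- lisi(pooled$matrix, pooled$batch, perplexity = perplexity)
  il$label_kind <- "batch"
  if (is.null(pooled$cell_types)) {
    warning("cell-type labels missing in at least one batch; ",
            "cLISI unavailable")
    return(list(ilisi = il, clisi = NULL, clisi_available = FALSE))
  }
  cl <- lisi(pooled$matrix, pooled$cell_types, perplexity = perplexity)
  cl$label_kind <- "cell_type"
  list(ilisi = il, clisi = cl, clisi_available = TRUE)
}

#' Rank alignment results by difference of medians
#'
#' Orders result sets by median iLISI minus median cLISI, descending, so
#' that methods that both mix batches and keep cell types separate come
#' first. Ties are broken by name.
#'
#' @param results Data frame with columns `name`, `ilisi_median`,
#'   `clisi_median` (or a list of such rows).
#' @return The data frame with an added `score` column, ordered best
#'   first.
#' @export
rank_methods <- function(results) {
  if (!is.data.frame(results)) {
    results <- do.call(rbind, lapply(results, as.data.frame))
  }
  stopifnot(nrow(results) >= 1,
            all(c("name", "ilisi_median", "clisi_median") %in%
                  colnames(results)))
  results$score <- results$ilisi_median - results$clisi_median
  out <- results[order(-results$score, results$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split a batch by holding out one cell type
#'
#' Partitions the cells of `batch` into those not of `cell_type`
#' (retained) and those of it (held). Used for the hold-out protocols:
#' dropping a type from the target before fitting, or from the source and
#' transforming it only afterwards to test generalization.
#'
#' @param batch An `expression_batch` with cell-type labels.
#' @param cell_type The type to hold out; must be present.
#' @return List with `retained` and `held` `expression_batch` objects.
#' @export
hold_out_type <- function(batch, cell_type) {
  stopifnot(inherits(batch, "expression_batch"))
  if (is.null(batch$cell_types)) {
    stop("batch '", batch$batch_label, "' has no cell-type labels")
  }
  if (!cell_type %in% batch$cell_types) {
    stop("cell type '", cell_type, "' not found; available: ",
         paste(sort(unique(batch$cell_types)), collapse = ", "))
  }
  held_idx <- batch$cell_types == cell_type
  take <- function(keep) {
    expression_batch(batch$matrix[keep, , drop = FALSE],
                     cell_ids = batch$cell_ids[keep],
                     gene_names = batch$gene_names,
                     batch_label = batch$batch_label,
                     cell_types = batch$cell_types[keep])
  }
  list(retained = take(!held_idx), held = take(held_idx))
}

#' Write LISI score tables
#'
#' Writes a per-cell table (cell index, ilisi, clisi when available) and
#' appends a summary row of medians.
#'
#' @param scores Result of [ilisi_clisi()].
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
save_lisi_table <- function(scores, path) {
  n <- length(scores$ilisi$per_cell)
  df <- data.frame(cell = c(seq_len(n), "median"),
                   ilisi = c(scores$ilisi$per_cell, scores$ilisi$median))
  if (isTRUE(scores$clisi_available)) {
    df$clisi <- c(scores$clisi$per_cell, scores$clisi$median)
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
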