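#' Construct an expression batch
#'
#' An expression batch is the basic data container: a cells x genes numeric
#' matrix together with unique cell identifiers, unique gene names, a batch
#' label, and (optionally) a per-cell type annotation. All alignment
#' machinery operates on these objects; cells are points in d-dimensional
#' gene space.
#'
#' @param mat Numeric matrix, cells in rows and genes in columns. May not
#'   contain missing values.
#' @param cell_ids Character vector of unique cell identifiers
#'   (default: rownames of `mat`).
#' @param gene_names Character vector of unique gene names
#'   (default: colnames of `mat`).
#' @param batch_label Single string naming the batch.
#' @param cell_types Optional character vector of per-cell type labels.
#'
#' @return An object of class `expression_batch`: a list with elements
#'   `matrix`, `cell_ids`, `gene_names`, `batch_label`, `cell_types`.
#' @export
expression_batch <- function(mat, cell_ids = rownames(mat),
                             gene_names = colnames(mat),
                             batch_label = "batch", cell_types = NULL) {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop("`mat` must be a numeric matrix (cells x genes)")
  }
  if (is.null(cell_ids)) {
    cell_ids <- if (nrow(mat)) paste0("cell", seq_len(nrow(mat)))
                else character(0)
  }
  if (is.null(gene_names)) {
    gene_names <- if (ncol(mat)) paste0("gene", seq_len(ncol(mat)))
                  else character(0)
  }
  cell_ids <- as.character(cell_ids)
  gene_names <- as.character(gene_names)
  if (length(cell_ids) != nrow(mat)) {
    stop("number of cell_ids (", length(cell_ids),
         ") does not match matrix rows (", nrow(mat), ")")
  }
  if (length(gene_names) != ncol(mat)) {
    stop("number of gene_names (", length(gene_names),
         ") does not match matrix columns (", ncol(mat), ")")
  }
  if (anyDuplicated(cell_ids)) {
    stop("duplicate cell_ids: ", paste(unique(cell_ids[duplicated(cell_ids)]),
                                       collapse = ", "))
  }
  if (anyDuplicated(gene_names)) {
    stop("duplicate gene names: ",
         paste(unique(gene_names[duplicated(gene_names)]), collapse = ", "))
  }
  if (anyNA(mat)) stop("matrix contains missing values")
  if (!is.null(cell_types)) {
    cell_types <- as.character(cell_types)
    if (length(cell_types) != nrow(mat)) {
      stop("cell_types length must equal the number of cells")
    }
  }
  dimnames(mat) <- list(cell_ids, gene_names)
  structure(
    list(matrix = mat, cell_ids = cell_ids, gene_names = gene_names,
         batch_label = as.character(batch_label)[1], cell_types = cell_types),
    class = "expression_batch"
  )
}

#' @export
print.expression_batch <- function(x, ...) {
  cat("expression_batch '", x$batch_label, "': ",
      nrow(x$matrix), " cells x ", ncol(x$matrix), " genes",
      if (!is.null(x$cell_types)) {
        paste0(" (", length(unique(x$cell_types)), " cell types)")
      } else {
        " (no cell type labels)"
      },
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_batch <- function(x) dim(x$matrix)

#' Subset a batch to a given gene list, in the given order
#'
#' @param batch An `expression_batch`.
#' @param genes Character vector of gene names; all must be present in the
#'   batch. The result has exactly these genes in this order.
#' @return An `expression_batch` restricted to `genes`.
#' @export
subset_genes <- function(batch, genes) {
  stopifnot(inherits(batch, "expression_batch"))
  missing <- setdiff(genes, batch$gene_names)
  if (length(missing) > 0) {
    stop("genes not present in batch '", batch$batch_label, "': ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  expression_batch(batch$matrix[, genes, drop = FALSE],
                   cell_ids = batch$cell_ids, gene_names = genes,
                   batch_label = batch$batch_label,
                   cell_types = batch$cell_types)
}

#' Concatenate batches sharing a gene space
#'
#' Rows are stacked in input order; cell ids are prefixed with the batch
#' label when needed to keep them unique.
#'
#' @param batches List of `expression_batch` objects with identical
#'   `gene_names` in identical order.
#' @return A list with `matrix`, `batch` (per-cell batch label) and
#'   `cell_types` (per-cell, or NULL if any batch lacks them).
#' @keywords internal
bind_batches <- function(batches) {
  stopifnot(length(batches) >= 1)
  g <- batches[[1]]$gene_names
  for (b in batches) {
    if (!identical(b$gene_names, g)) {
      stop("all batches must share an identical gene order; batch '",
           b$batch_label, "' differs")
    }
  }
  mat <- do.call(rbind, lapply(batches, function(b) b$matrix))
  batch <- unlist(lapply(batches, function(b) {
    rep(b$batch_label, nrow(b$matrix))
  }), use.names = FALSE)
  has_types <- all(vapply(batches, function(b) !is.null(b$cell_types),
                          logical(1)))
  types <- if (has_types) {
    unlist(lapply(batches, function(b) b$cell_types), use.names = FALSE)
  } else {
    NULL
  }
  list(matrix = mat, batch = batch, cell_types = types)
}

# Shared helper: check two batches (or matrices) live in the same gene space.
check_gene_space <- function(A, B) {
  ga <- if (inherits(A, "expression_batch")) A$gene_names else colnames(A)
  gb <- if (inherits(B, "expression_batch")) B$gene_names else colnames(B)
  if (!is.null(ga) && !is.null(gb) && !identical(ga, gb)) {
    idx <- which(ga != gb)[1]
    stop("gene spaces differ (first mismatch at position ", idx, ": '",
         ga[idx], "' vs '", gb[idx], "')")
  }
  ma <- if (inherits(A, "expression_batch")) A$matrix else A
  mb <- if (inherits(B, "expression_batch")) B$matrix else B
  if (ncol(ma) != ncol(mb)) {
    stop("gene dimensions differ: ", ncol(ma), " vs ", ncol(mb))
  }
  invisible(TRUE)
}

as_matrix <- function(x) {
  if (inherits(x, "expression_batch")) x$matrix else x
}
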