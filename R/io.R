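#' Read an expression batch from disk
#'
#' Two formats are supported. `delimited`: a text table, cells in rows and
#' genes in columns, with a header row of gene names and the first column
#' holding cell identifiers; the separator is a comma by default, with tab
#' auto-detected from the header line. `mtx`: a Matrix Market coordinate
#' file `<stem>.mtx` with sidecar label files `<stem>_rows.txt` and
#' `<stem>_cols.txt` (one label per line). Rows are taken to be cells when
#' the sidecar lengths agree with the matrix dimensions; if the labels
#' match the transposed dimensions instead (a genes x cells file), the
#' matrix is transposed on load.
#'
#' If a sidecar file `<stem>_types.txt` exists (one label per cell), it is
#' read as the per-cell type annotation.
#'
#' @param path File path (for `mtx` either the `.mtx` file or its stem).
#' @param format "delimited" or "mtx".
#' @param batch_label Batch label to attach; defaults to the file stem.
#' @param impute_missing If TRUE, missing values in a delimited file are
#'   set to 0 (and a message records how many); if FALSE (default) missing
#'   values are an error.
#' @return An [expression_batch()].
#' @export
load_expression <- function(path, format = c("delimited", "mtx"),
                            batch_label = NULL, impute_missing = FALSE) {
  format <- match.arg(format)
  if (format == "mtx") {
    return(load_expression_mtx(path, batch_label))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "\"")
  mat <- as.matrix(df)
  if (!is.numeric(mat)) {
    bad <- which(!vapply(df, is.numeric, logical(1)))[1]
    stop("non-numeric entries in column '", colnames(df)[bad],
         "' of ", path)
  }
  if (anyNA(mat)) {
    if (impute_missing) {
      n_na <- sum(is.na(mat))
      mat[is.na(mat)] <- 0
      message("imputed ", n_na, " missing values to 0 in ", path)
    } else {
      stop("missing values in ", path,
           " (set impute_missing = TRUE to zero-fill)")
    }
  }
  if (is.null(batch_label)) batch_label <- file_stem(path)
  types <- read_types_sidecar(path, nrow(mat))
  expression_batch(mat, batch_label = batch_label, cell_types = types)
}

load_expression_mtx <- function(path, batch_label = NULL) {
  stem <- sub("\\.mtx$", "", path)
  mtx_path <- paste0(stem, ".mtx")
  if (!file.exists(mtx_path)) stop("file not found: ", mtx_path)
  rows_path <- paste0(stem, "_rows.txt")
  cols_path <- paste0(stem, "_cols.txt")
  if (!file.exists(rows_path) || !file.exists(cols_path)) {
    stop("MTX sidecar label files missing: expected ", rows_path,
         " and ", cols_path)
  }
  m <- as.matrix(Matrix::readMM(mtx_path))
  rl <- readLines(rows_path)
  cl <- readLines(cols_path)
  if (length(rl) == nrow(m) && length(cl) == ncol(m)) {
    cell_ids <- rl; gene_names <- cl
  } else if (length(rl) == ncol(m) && length(cl) == nrow(m)) {
    # genes x cells on disk: sidecars fit the transpose
    m <- t(m)
    cell_ids <- rl; gene_names <- cl
  } else {
    stop("sidecar label lengths (", length(rl), ", ", length(cl),
         ") do not match matrix dimensions ", nrow(m), " x ", ncol(m))
  }
  if (is.null(batch_label)) batch_label <- file_stem(mtx_path)
  types <- read_types_sidecar(mtx_path, length(cell_ids))
  expression_batch(m, cell_ids = cell_ids, gene_names = gene_names,
                   batch_label = batch_label, cell_types = types)
}

read_types_sidecar <- function(path, n_cells) {
  tp <- paste0(sub("\\.[^.]*$", "", path), "_types.txt")
  if (!file.exists(tp)) return(NULL)
  types <- readLines(tp)
  if (length(types) != n_cells) {
    stop("cell-type sidecar ", tp, " has ", length(types),
         " lines but the batch has ", n_cells, " cells")
  }
  types
}

file_stem <- function(path) sub("\\.[^.]*$", "", basename(path))

#' Write an expression batch to disk
#'
#' Inverse of [load_expression()]. For `delimited`, writes a CSV (or TSV if
#' `sep = "\t"`) with gene names in the header and cell ids in the first
#' column. For `mtx`, writes `<stem>.mtx` (cells x genes) plus
#' `<stem>_rows.txt` / `<stem>_cols.txt`. Cell types, when present, go to
#' `<stem>_types.txt` so a round trip preserves them.
#'
#' @param batch An `expression_batch`.
#' @param path Output path (for `mtx`, the `.mtx` path or stem).
#' @param format "delimited" or "mtx".
#' @param sep Field separator for the delimited format.
#' @return `path`, invisibly.
#' @export
save_expression <- function(batch, path, format = c("delimited", "mtx"),
                            sep = ",") {
  stopifnot(inherits(batch, "expression_batch"))
  format <- match.arg(format)
  if (format == "delimited") {
    df <- data.frame(cell_id = batch$cell_ids,
                     batch$matrix, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df) <- c("cell_id", batch$gene_names)
    utils::write.table(df, path, sep = sep, row.names = FALSE,
                       col.names = TRUE, quote = FALSE)
    stem_path <- path
  } else {
    stem <- sub("\\.mtx$", "", path)
    Matrix::writeMM(Matrix::Matrix(batch$matrix, sparse = TRUE),
                    paste0(stem, ".mtx"))
    writeLines(batch$cell_ids, paste0(stem, "_rows.txt"))
    writeLines(batch$gene_names, paste0(stem, "_cols.txt"))
    stem_path <- paste0(stem, ".mtx")
  }
  if (!is.null(batch$cell_types)) {
    writeLines(batch$cell_types,
               paste0(sub("\\.[^.]*$", "", stem_path), "_types.txt"))
  }
  invisible(path)
}

#' Export a pair assignment as a two-column table
#'
#' Writes `source_id` / `target_id` columns (cell identifiers when batches
#' are supplied, otherwise 1-based indices) for inspection of a matching.
#'
#' @param assignment A `pair_assignment`.
#' @param path Output path (tab-separated).
#' @param source,target Optional `expression_batch` objects supplying ids.
#' @return `path`, invisibly.
#' @export
save_pairs <- function(assignment, path, source = NULL, target = NULL) {
  stopifnot(inherits(assignment, "pair_assignment"))
  p <- assignment$pairs
  df <- data.frame(
    source_id = if (is.null(source)) p$source else source$cell_ids[p$source],
    target_id = if (is.null(target)) p$target else target$cell_ids[p$target]
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a fitted model to a JSON archive
#'
#' The archive stores the composite weight matrix and offset, the gene
#' order, the configuration, per-iteration transforms with their loss
#' traces, and the diagnostics table, at full floating-point precision so
#' that a reloaded model reproduces [apply_transform()] bit for bit.
#'
#' @param model A `scipr_model` from [scipr_fit()].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
save_scipr_model <- function(model, path) {
  stopifnot(inherits(model, "scipr_model"))
  obj <- list(
    format = "scipr_model",
    version = as.character(utils::packageVersion("scipr")),
    d = length(model$composite$b),
    gene_names = model$gene_names,
    composite = transform_to_list(model$composite),
    transforms = lapply(model$transforms, transform_to_list),
    config = local({
      cfg <- unclass(model$config)
      cfg$gd <- unclass(cfg$gd)
      cfg
    }),
    diagnostics = model$diagnostics
  )
  # digits = I(17): doubles survive the round trip bit for bit
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

transform_to_list <- function(tr) {
  list(W = lapply(seq_len(nrow(tr$W)), function(i) unname(tr$W[i, ])),
       b = unname(tr$b), kind = tr$kind,
       loss_trace = attr(tr, "loss_trace"))
}

transform_from_list <- function(x) {
  W <- do.call(rbind, lapply(x$W, function(r) as.numeric(unlist(r))))
  tr <- affine_transform(W, as.numeric(unlist(x$b)), kind = x$kind)
  if (!is.null(x$loss_trace)) {
    attr(tr, "loss_trace") <- as.numeric(unlist(x$loss_trace))
  }
  tr
}

#' Load a model archive written by [save_scipr_model()]
#'
#' @param path Path to the `.json` archive.
#' @return A `scipr_model`.
#' @export
load_scipr_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path)
  if (!identical(obj$format, "scipr_model")) {
    stop(path, " is not a scipr model archive")
  }
  cfg <- obj$config
  cfg$gd <- do.call(gd_settings, cfg$gd)
  cfg <- do.call(scipr_config, cfg[setdiff(names(cfg), character(0))])
  diag_df <- as.data.frame(
    do.call(rbind, lapply(obj$diagnostics, function(r) {
      data.frame(iteration = r$iteration, n_pairs = r$n_pairs,
                 mean_distance = r$mean_distance, final_loss = r$final_loss)
    }))
  )
  structure(
    list(composite = transform_from_list(obj$composite),
         transforms = lapply(obj$transforms, transform_from_list),
         config = cfg,
         diagnostics = diag_df,
         gene_names = unlist(obj$gene_names)),
    class = "scipr_model"
  )
}
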