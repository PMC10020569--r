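#' Construct a single expression batch
#'
#' An `ExpressionBatch` holds one batch's cells-by-genes expression matrix
#' together with per-cell identifiers, per-cell cell-type labels and the
#' batch identifier. Rows are cells, columns are genes; all downstream
#' modules assume this orientation.
#'
#' @param matrix Numeric cells x genes matrix with non-negative values.
#' @param gene_names Character vector of unique gene identifiers, one per
#'   column.
#' @param cell_ids Character vector of cell identifiers, one per row.
#' @param cell_types Character vector of per-cell cell-type labels.
#' @param batch_id Single string naming the batch.
#' @return An object of class `ExpressionBatch`.
#' @export
ExpressionBatch <- function(matrix, gene_names, cell_ids, cell_types, batch_id) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != length(cell_ids) || nrow(matrix) != length(cell_types))
    stop("row count of matrix must equal length(cell_ids) and length(cell_types)")
  if (ncol(matrix) != length(gene_names))
    stop("column count of matrix must equal length(gene_names)")
  if (anyDuplicated(gene_names))
    stop("gene_names must be unique within a batch")
  if (any(is.na(cell_types)) || any(cell_types == ""))
    stop("missing cell type labels in batch '", batch_id, "'")
  dimnames(matrix) <- list(cell_ids, gene_names)
  structure(list(
    matrix = matrix,
    gene_names = as.character(gene_names),
    cell_ids = as.character(cell_ids),
    cell_types = as.character(cell_types),
    batch_id = as.character(batch_id)
  ), class = "ExpressionBatch")
}

#' @export
print.ExpressionBatch <- function(x, ...) {
  cat(sprintf("ExpressionBatch '%s': %d cells x %d genes, %d cell types\n",
              x$batch_id, nrow(x$matrix), ncol(x$matrix),
              length(unique(x$cell_types))))
  invisible(x)
}

#' Construct a multi-batch data collection
#'
#' A `DataCollection` bundles several [ExpressionBatch] objects sharing a
#' gene universe, plus the raw-to-consolidated label mapping and the sorted
#' consolidated cell-type universe.
#'
#' @param batches List of [ExpressionBatch] objects with unique batch ids.
#' @param label_map Named character vector mapping raw labels to consolidated
#'   labels, or `NULL` if labels are already consolidated.
#' @return An object of class `DataCollection`.
#' @export
DataCollection <- function(batches, label_map = NULL) {
  if (!length(batches)) stop("a collection needs at least one batch")
  ok <- vapply(batches, inherits, logical(1), what = "ExpressionBatch")
  if (!all(ok)) stop("all elements of 'batches' must be ExpressionBatch objects")
  ids <- vapply(batches, `[[`, character(1), "batch_id")
  if (anyDuplicated(ids)) stop("batch ids must be unique")
  names(batches) <- ids
  universe <- sort(unique(unlist(lapply(batches, `[[`, "cell_types"))))
  structure(list(
    batches = batches,
    label_map = label_map,
    cell_type_universe = universe,
    preprocessed = FALSE
  ), class = "DataCollection")
}

#' @export
print.DataCollection <- function(x, ...) {
  cat(sprintf("DataCollection: %d batches, %d consolidated cell types%s\n",
              length(x$batches), length(x$cell_type_universe),
              if (isTRUE(x$preprocessed)) " (preprocessed)" else ""))
  for (b in x$batches) print(b)
  invisible(x)
}

#' Number of batches in a collection
#' @param collection A [DataCollection].
#' @return Integer batch count.
#' @export
n_batches <- function(collection) length(collection$batches)

batch_ids <- function(collection) names(collection$batches)

#' Consolidate heterogeneous cell-type vocabularies
#'
#' Different batches typically annotate the same cell type under different
#' names or granularities ("CD14 monocytes" vs "monocytes", "DCs" vs
#' "Dendritic Cells"). Consolidation rewrites every raw label through an
#' explicit user-supplied mapping to a common, most-general vocabulary.
#' The mapping must cover every raw label observed in the collection
#' (identity entries are allowed); the tool validates completeness rather
#' than guessing merges, so the manual harmonization step is reproducible.
#'
#' @param collection A [DataCollection].
#' @param label_map Named character vector: `names()` are raw labels, values
#'   are consolidated labels.
#' @return The collection with all batches relabeled, `label_map` stored and
#'   `cell_type_universe` recomputed. Matrix values and cell order are
#'   untouched. Idempotent when the map contains identity entries for its
#'   own values.
#' @export
consolidate_labels <- function(collection, label_map) {
  stopifnot(inherits(collection, "DataCollection"))
  if (is.null(names(label_map)) || any(names(label_map) == ""))
    stop("label_map must be a named character vector (raw -> consolidated)")
  missing <- lapply(collection$batches, function(b) {
    setdiff(unique(b$cell_types), names(label_map))
  })
  bad <- vapply(missing, length, integer(1)) > 0
  if (any(bad)) {
    msg <- vapply(which(bad), function(i) {
      sprintf("batch '%s': %s", names(collection$batches)[i],
              paste(sQuote(missing[[i]]), collapse = ", "))
    }, character(1))
    stop("unmapped raw labels found\n  ", paste(msg, collapse = "\n  "))
  }
  collection$batches <- lapply(collection$batches, function(b) {
    b$cell_types <- unname(label_map[b$cell_types])
    b
  })
  observed <- unlist(lapply(collection$batches, `[[`, "cell_types"))
  collection$label_map <- label_map
  collection$cell_type_universe <- sort(unique(observed))
  collection
}

#' Read a multi-batch collection from disk
#'
#' Each file (CSV/TSV) or directory (MatrixMarket triplet) becomes one
#' [ExpressionBatch]. The dense format is a delimited table whose header row
#' holds gene names, with `cell_id` and a label column among the columns.
#' The MTX format is a directory holding `matrix.mtx` (genes x cells, the
#' 10x convention), `barcodes.tsv`, `genes.tsv` and `labels.tsv`.
#'
#' @param paths Character vector of file (csv) or directory (mtx) paths.
#' @param format One of `"csv"` or `"mtx"`. (An HDF5-backed annotated-matrix
#'   reader is not provided; export such files to MTX or CSV first.)
#' @param label_field Name of the label column in the dense format / ignored
#'   for mtx (labels come from `labels.tsv`).
#' @param batch_ids Optional batch ids; defaults to basenames of `paths`.
#' @param sep Field separator for the dense format.
#' @return A [DataCollection].
#' @export
read_collection <- function(paths, format = c("csv", "mtx", "h5ad"),
                            label_field = "cell_type", batch_ids = NULL,
                            sep = ",") {
  format <- match.arg(format)
  if (format == "h5ad")
    stop("h5ad reading is not supported by this build; convert to MTX ",
         "(e.g. with scanpy/anndata) or dense CSV first")
  if (is.null(batch_ids)) {
    batch_ids <- sub("\\.(csv|tsv|txt)$", "", basename(paths))
  }
  if (length(batch_ids) != length(paths)) stop("one batch id per path required")
  batches <- Map(function(p, id) {
    if (format == "csv") read_batch_csv(p, id, label_field, sep)
    else read_batch_mtx(p, id)
  }, paths, batch_ids)
  DataCollection(unname(batches))
}

read_batch_csv <- function(path, batch_id, label_field, sep) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("cell_id", label_field)
  if (!all(meta_cols %in% names(df)))
    stop("file ", path, " lacks required column(s): ",
         paste(setdiff(meta_cols, names(df)), collapse = ", "))
  gene_cols <- setdiff(names(df), meta_cols)
  if (!length(gene_cols)) stop("file ", path, " contains no gene columns")
  m <- as.matrix(df[, gene_cols, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("non-numeric or missing expression values in ", path)
  ExpressionBatch(m, gene_cols, df$cell_id, df[[label_field]], batch_id)
}

read_batch_mtx <- function(dir, batch_id) {
  files <- file.path(dir, c("matrix.mtx", "barcodes.tsv", "genes.tsv", "labels.tsv"))
  miss <- files[!file.exists(files)]
  if (length(miss)) stop("missing MTX sidecar file(s): ", paste(miss, collapse = ", "))
  m <- Matrix::readMM(files[1])        # genes x cells (10x convention)
  barcodes <- readLines(files[2])
  genes <- readLines(files[3])
  labels <- readLines(files[4])
  if (ncol(m) != length(barcodes))
    stop("in ", dir, ": matrix has ", ncol(m), " cells but barcodes.tsv has ",
         length(barcodes), " entries")
  if (nrow(m) != length(genes))
    stop("in ", dir, ": matrix has ", nrow(m), " genes but genes.tsv has ",
         length(genes), " entries")
  if (length(labels) != length(barcodes))
    stop("in ", dir, ": labels.tsv has ", length(labels),
         " entries for ", length(barcodes), " cells")
  ExpressionBatch(t(as.matrix(m)), genes, barcodes, labels, batch_id)
}

#' Write a collection to disk
#'
#' Inverse of [read_collection()]; the write-read round trip is lossless up
#' to numeric formatting (full precision is kept for CSV via 17 significant
#' digits; MTX stores values verbatim).
#'
#' @param collection A [DataCollection].
#' @param dir Output directory (created if needed).
#' @param format `"csv"` or `"mtx"`.
#' @param label_field Label column name for the dense format.
#' @return Invisibly, the written paths.
#' @export
write_collection <- function(collection, dir, format = c("csv", "mtx"),
                             label_field = "cell_type") {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(collection$batches, function(b) {
    if (format == "csv") {
      p <- file.path(dir, paste0(b$batch_id, ".csv"))
      df <- data.frame(cell_id = b$cell_ids, check.names = FALSE,
                       stringsAsFactors = FALSE)
      df[[label_field]] <- b$cell_types
      em <- as.data.frame(b$matrix, check.names = FALSE)
      rownames(em) <- NULL
      df <- cbind(df, em)
      utils::write.table(format(df, digits = 17, scientific = FALSE,
                                trim = TRUE),
                         p, sep = ",", row.names = FALSE, quote = TRUE)
      p
    } else {
      p <- file.path(dir, b$batch_id)
      dir.create(p, showWarnings = FALSE)
      Matrix::writeMM(Matrix::Matrix(t(b$matrix), sparse = TRUE),
                      file.path(p, "matrix.mtx"))
      writeLines(b$cell_ids, file.path(p, "barcodes.tsv"))
      writeLines(b$gene_names, file.path(p, "genes.tsv"))
      writeLines(b$cell_types, file.path(p, "labels.tsv"))
      p
    }
  }, character(1))
  invisible(paths)
}

#' Write an integrated embedding to a delimited file
#'
#' @param embedding An [Embedding].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_embedding <- function(embedding, path) {
  stopifnot(inherits(embedding, "Embedding"))
  if (!nrow(embedding$coordinates)) stop("cannot write an empty embedding")
  df <- data.frame(cell_id = embedding$cell_ids,
                   batch_id = embedding$batch_ids,
                   cell_type = embedding$cell_types,
                   stringsAsFactors = FALSE, check.names = FALSE)
  co <- embedding$coordinates
  colnames(co) <- sprintf("dim%d", seq_len(ncol(co)))
  df <- cbind(df, as.data.frame(co, check.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an embedding written by [write_embedding()]
#' @param path TSV path.
#' @return An [Embedding].
#' @export
read_embedding <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("cell_id", "batch_id", "cell_type")
  if (!all(need %in% names(df))) stop("not an embedding table: ", path)
  co <- as.matrix(df[, setdiff(names(df), need), drop = FALSE])
  Embedding(co, df$cell_id, df$cell_type, df$batch_id)
}
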