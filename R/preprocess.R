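#' Restrict all batches to the shared gene set
#'
#' Genes not observed in every batch are removed and the surviving genes are
#' put in one canonical (alphabetically sorted) order across batches, so the
#' same column index refers to the same gene everywhere downstream.
#'
#' @param collection A [DataCollection] with at least two batches.
#' @return The collection with every batch restricted to the intersection.
#' @export
intersect_genes <- function(collection) {
  stopifnot(inherits(collection, "DataCollection"))
  if (n_batches(collection) < 2) stop("need at least two batches to intersect")
  shared <- Reduce(intersect, lapply(collection$batches, `[[`, "gene_names"))
  if (!length(shared)) stop("gene intersection across batches is empty")
  shared <- sort(shared)
  collection$batches <- lapply(collection$batches, function(b) {
    b$matrix <- b$matrix[, match(shared, b$gene_names), drop = FALSE]
    b$gene_names <- shared
    colnames(b$matrix) <- shared
    b
  })
  collection
}

#' Library-size normalization and log transform of one batch
#'
#' Each cell's counts are rescaled to sum to `scale` and then transformed
#' with `log(1 + x)`. The scale factor defaults to the conventional 10,000
#' counts per cell.
#'
#' @param batch An [ExpressionBatch] of raw non-negative counts.
#' @param scale Target library size per cell.
#' @param zero_cells `"error"` (default) or `"drop"`: what to do with cells
#'   whose library size is zero.
#' @return The batch with normalized, log-transformed values.
#' @export
normalize_log <- function(batch, scale = 1e4, zero_cells = c("error", "drop")) {
  stopifnot(inherits(batch, "ExpressionBatch"))
  zero_cells <- match.arg(zero_cells)
  if (any(batch$matrix < 0)) stop("negative expression values in batch '",
                                  batch$batch_id, "'")
  lib <- rowSums(batch$matrix)
  if (any(lib == 0)) {
    if (zero_cells == "error")
      stop("zero library size for cell(s) ",
           paste(sQuote(batch$cell_ids[lib == 0]), collapse = ", "),
           " in batch '", batch$batch_id, "'")
    keep <- lib > 0
    warning(sum(!keep), " zero-count cell(s) dropped from batch '",
            batch$batch_id, "'")
    batch$matrix <- batch$matrix[keep, , drop = FALSE]
    batch$cell_ids <- batch$cell_ids[keep]
    batch$cell_types <- batch$cell_types[keep]
    lib <- lib[keep]
  }
  batch$matrix <- log1p(batch$matrix / lib * scale)
  batch
}

#' Reduce each batch independently to its leading principal components
#'
#' PCA is fit per batch on that batch's own gene means (exact SVD via
#' [stats::prcomp], no unit-variance scaling), and the batch's cells are
#' projected onto its top `n_pcs` components. The per-batch coordinate
#' systems are deliberately NOT mutually aligned: aligning them is the
#' integration network's job. Component signs follow a deterministic
#' convention (largest-magnitude loading positive) for reproducibility.
#'
#' @param collection A [DataCollection] of normalized, log-transformed
#'   batches.
#' @param n_pcs Number of components to keep (default 50). Lowered globally
#'   with a warning when some batch is too small to support it.
#' @return A `PCView`: per-batch coordinates, loadings, centers and
#'   explained variances, with labels and batch ids carried over.
#' @export
pca_per_batch <- function(collection, n_pcs = 50) {
  stopifnot(inherits(collection, "DataCollection"))
  if (n_pcs < 1) stop("n_pcs must be >= 1")
  max_pcs <- min(vapply(collection$batches, function(b)
    min(nrow(b$matrix) - 1L, ncol(b$matrix)), integer(1)))
  if (n_pcs > max_pcs) {
    warning("n_pcs lowered from ", n_pcs, " to ", max_pcs,
            " (smallest batch limits the rank)")
    n_pcs <- max_pcs
  }
  views <- lapply(collection$batches, function(b) {
    pc <- stats::prcomp(b$matrix, center = TRUE, scale. = FALSE, rank. = n_pcs)
    # deterministic sign: largest-|loading| entry of each component positive
    flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
      v <- pc$rotation[, j]
      sign(v[which.max(abs(v))])
    }, numeric(1))
    flip[flip == 0] <- 1
    list(coords = sweep(pc$x, 2, flip, `*`),
         loadings = sweep(pc$rotation, 2, flip, `*`),
         center = pc$center,
         explained_var = pc$sdev[seq_len(n_pcs)]^2,
         cell_ids = b$cell_ids,
         cell_types = b$cell_types,
         batch_id = b$batch_id)
  })
  structure(list(batches = views, n_pcs = n_pcs,
                 cell_type_universe = collection$cell_type_universe),
            class = "PCView")
}

#' @export
print.PCView <- function(x, ...) {
  cat(sprintf("PCView: %d batches, %d PCs each\n", length(x$batches), x$n_pcs))
  for (b in x$batches)
    cat(sprintf("  '%s': %d cells\n", b$batch_id, nrow(b$coords)))
  invisible(x)
}

#' Run the full preprocessing pipeline on a raw collection
#'
#' Fixed order: gene intersection, library-size normalization, log
#' transform, per-batch PCA. The collection is flagged afterwards and
#' re-running the pipeline on an already-preprocessed collection raises:
#' normalization is only meaningful on raw counts.
#'
#' @param collection A raw [DataCollection].
#' @param n_pcs,scale,zero_cells Passed to the stages.
#' @return List with `collection` (intersected + normalized, gene space) and
#'   `pc_view` (the [pca_per_batch()] result).
#' @export
preprocess_collection <- function(collection, n_pcs = 50, scale = 1e4,
                                  zero_cells = "error") {
  stopifnot(inherits(collection, "DataCollection"))
  if (isTRUE(collection$preprocessed))
    stop("collection is already preprocessed; the pipeline requires raw counts")
  collection <- intersect_genes(collection)
  collection$batches <- lapply(collection$batches, normalize_log,
                               scale = scale, zero_cells = zero_cells)
  collection$preprocessed <- TRUE
  list(collection = collection,
       pc_view = pca_per_batch(collection, n_pcs = n_pcs))
}
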