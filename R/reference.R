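#' Find mutual-nearest-neighbor anchors against a target batch
#'
#' For every non-target batch, all cross-batch cell pairs that are mutually
#' within each other's `k_anchor` nearest neighbors in the integrated
#' embedding become anchors. Each anchor's score is the shared-neighbor
#' overlap: the fraction of the two cells' `k_anchor` nearest target-batch
#' neighborhoods that coincide (a simple surrogate for anchor confidence,
#' in `[0, 1]`).
#'
#' @param embedding An [Embedding].
#' @param target_batch Batch id to anchor against.
#' @param k_anchor Mutual-neighborhood size (default 5).
#' @return An `AnchorSet`: data frame `pairs` (other_batch, other_cell,
#'   target_cell, row indices into the embedding, score) plus
#'   `target_batch`, `k_anchor`.
#' @export
find_anchors <- function(embedding, target_batch, k_anchor = 5L) {
  stopifnot(inherits(embedding, "Embedding"))
  if (!target_batch %in% embedding$batch_ids)
    stop("target batch '", target_batch, "' not present in the embedding")
  co <- embedding$coordinates
  tgt_rows <- which(embedding$batch_ids == target_batch)
  others <- setdiff(unique(embedding$batch_ids), target_batch)
  if (!length(others)) stop("no non-target batches to anchor")
  tgt_co <- co[tgt_rows, , drop = FALSE]
  # within-target neighborhoods, used for the shared-neighbor score
  k_t <- min(k_anchor, length(tgt_rows) - 1L)
  tgt_self_nn <- RANN::nn2(tgt_co, tgt_co, k = k_t + 1L)$nn.idx[, -1, drop = FALSE]
  pairs <- lapply(others, function(ob) {
    o_rows <- which(embedding$batch_ids == ob)
    o_co <- co[o_rows, , drop = FALSE]
    k1 <- min(k_anchor, nrow(tgt_co))
    k2 <- min(k_anchor, nrow(o_co))
    o2t <- RANN::nn2(tgt_co, o_co, k = k1)$nn.idx   # for each other cell: target nbrs
    t2o <- RANN::nn2(o_co, tgt_co, k = k2)$nn.idx   # for each target cell: other nbrs
    hits <- which(vapply(seq_len(nrow(o_co)), function(i)
      any(i == t2o[o2t[i, ], , drop = FALSE]), logical(1)))
    res <- do.call(rbind, lapply(hits, function(i) {
      js <- o2t[i, ][vapply(o2t[i, ], function(j) i %in% t2o[j, ], logical(1))]
      data.frame(other_idx = o_rows[i], target_idx = tgt_rows[js],
                 other_local = i, target_local = js)
    }))
    if (is.null(res) || !nrow(res))
      stop("zero anchors between batch '", ob, "' and target '",
           target_batch, "'; cannot project it")
    res$score <- vapply(seq_len(nrow(res)), function(r) {
      a_nb <- o2t[res$other_local[r], ]
      b_nb <- tgt_self_nn[res$target_local[r], ]
      length(intersect(a_nb, b_nb)) / max(1L, k_anchor)
    }, numeric(1))
    res$other_batch <- ob
    res
  })
  pairs <- do.call(rbind, pairs)
  pairs$other_cell <- embedding$cell_ids[pairs$other_idx]
  pairs$target_cell <- embedding$cell_ids[pairs$target_idx]
  structure(list(pairs = pairs[, c("other_batch", "other_cell", "target_cell",
                                   "other_idx", "target_idx", "score")],
                 target_batch = target_batch, k_anchor = as.integer(k_anchor)),
            class = "AnchorSet")
}

#' @export
print.AnchorSet <- function(x, ...) {
  cat(sprintf("AnchorSet: %d anchors onto target '%s' (k_anchor = %d)\n",
              nrow(x$pairs), x$target_batch, x$k_anchor))
  invisible(x)
}

#' Back-project the integrated embedding into a target batch's gene space
#'
#' Each non-target cell's (normalized, log-scale) gene vector is corrected
#' by subtracting a weighted average of its nearest anchors' gene-space
#' differences (other-batch anchor cell minus target-batch anchor cell);
#' weights come from a Gaussian kernel on embedding-space distances to the
#' anchors. Target-batch cells pass through unchanged, so the corrected
#' collection resembles the target batch. A constant additive batch shift
#' is recovered exactly in the limit of correct anchors, since every anchor
#' difference then equals the shift.
#'
#' @param collection The preprocessed [DataCollection] (gene space) whose
#'   cells match the embedding.
#' @param embedding The integrated [Embedding].
#' @param anchors An `AnchorSet` from [find_anchors()].
#' @param n_weight Number of nearest anchors used per cell (default 10).
#' @return A `ReferencePanel`: corrected cells x genes matrix with labels,
#'   batch ids and provenance.
#' @export
project_to_gene_space <- function(collection, embedding, anchors,
                                  n_weight = 10L) {
  stopifnot(inherits(collection, "DataCollection"),
            inherits(embedding, "Embedding"),
            inherits(anchors, "AnchorSet"))
  genes <- collection$batches[[1]]$gene_names
  key <- paste(embedding$batch_ids, embedding$cell_ids, sep = "\r")
  gene_mat <- matrix(NA_real_, length(key), length(genes))
  for (b in collection$batches) {
    rows <- match(paste(b$batch_id, b$cell_ids, sep = "\r"), key)
    if (anyNA(rows)) stop("collection and embedding cells do not match")
    gene_mat[rows, ] <- b$matrix[, genes, drop = FALSE]
  }
  if (anyNA(gene_mat)) stop("embedding contains cells absent from the collection")
  co <- embedding$coordinates
  out <- gene_mat
  for (ob in unique(anchors$pairs$other_batch)) {
    ap <- anchors$pairs[anchors$pairs$other_batch == ob, ]
    D <- gene_mat[ap$other_idx, , drop = FALSE] -
         gene_mat[ap$target_idx, , drop = FALSE]
    cells <- which(embedding$batch_ids == ob)
    anchor_co <- co[ap$other_idx, , drop = FALSE]
    nw <- min(n_weight, nrow(ap))
    nn <- RANN::nn2(anchor_co, co[cells, , drop = FALSE], k = nw)
    for (r in seq_along(cells)) {
      d2 <- nn$nn.dists[r, ]^2
      sigma2 <- mean(d2)
      w <- if (sigma2 > 0) exp(-d2 / sigma2) else rep(1, nw)
      w <- w / sum(w)
      corr <- colSums(D[nn$nn.idx[r, ], , drop = FALSE] * w)
      out[cells[r], ] <- gene_mat[cells[r], ] - corr
    }
  }
  if (!all(is.finite(out))) stop("non-finite values after correction")
  colnames(out) <- genes
  structure(list(matrix = out, gene_names = genes,
                 cell_ids = embedding$cell_ids,
                 cell_types = embedding$cell_types,
                 batch_ids = embedding$batch_ids,
                 target_batch = anchors$target_batch),
            class = "ReferencePanel")
}

#' @export
print.ReferencePanel <- function(x, ...) {
  cat(sprintf("ReferencePanel: %d cells x %d genes in gene space of '%s'\n",
              nrow(x$matrix), length(x$gene_names), x$target_batch))
  invisible(x)
}

#' Use a single annotated batch directly as a reference panel
#' @param batch A normalized, log-transformed [ExpressionBatch].
#' @return A `ReferencePanel` wrapping the batch unchanged.
#' @export
as_reference_panel <- function(batch) {
  stopifnot(inherits(batch, "ExpressionBatch"))
  structure(list(matrix = batch$matrix, gene_names = batch$gene_names,
                 cell_ids = batch$cell_ids, cell_types = batch$cell_types,
                 batch_ids = rep(batch$batch_id, length(batch$cell_ids)),
                 target_batch = batch$batch_id),
            class = "ReferencePanel")
}

select_hvg <- function(mat, n_hvg, n_bins = 20L) {
  mu <- colMeans(mat)
  v <- apply(mat, 2, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  bins <- cut(rank(mu, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  z <- numeric(length(mu))
  for (b in unique(bins)) {
    i <- bins == b
    s <- stats::sd(disp[i])
    z[i] <- if (!is.na(s) && s > 0) (disp[i] - mean(disp[i])) / s else 0
  }
  order(z, decreasing = TRUE)[seq_len(min(n_hvg, ncol(mat)))]
}

#' Transfer cell-type labels from a reference panel to a query batch
#'
#' Highly variable genes are selected on the reference only (mean-dispersion
#' binning), PCA is fit on the reference HVG submatrix, the query is
#' projected into that PCA, and each query cell receives the majority label
#' of its `k_map` nearest reference cells (ties broken alphabetically).
#'
#' @param reference A `ReferencePanel`.
#' @param query A normalized, log-transformed [ExpressionBatch] sharing
#'   genes with the reference (intersected internally).
#' @param n_hvg Number of highly variable genes (default 2000).
#' @param n_pcs PCA dimensionality (default 50, capped by the data).
#' @param k_map Neighborhood size for the vote (default 15).
#' @return List with `predicted` labels and `accuracy` (against the query's
#'   own labels when present, otherwise `NA`).
#' @export
map_cell_types <- function(reference, query, n_hvg = 2000L, n_pcs = 50L,
                           k_map = 15L) {
  stopifnot(inherits(reference, "ReferencePanel"),
            inherits(query, "ExpressionBatch"))
  genes <- intersect(reference$gene_names, query$gene_names)
  if (!length(genes)) stop("reference and query share no genes")
  ref <- reference$matrix[, match(genes, reference$gene_names), drop = FALSE]
  qry <- query$matrix[, match(genes, query$gene_names), drop = FALSE]
  hvg <- select_hvg(ref, n_hvg)
  ref <- ref[, hvg, drop = FALSE]
  qry <- qry[, hvg, drop = FALSE]
  rank <- min(n_pcs, ncol(ref), nrow(ref) - 1L)
  pc <- stats::prcomp(ref, center = TRUE, scale. = FALSE, rank. = rank)
  ref_s <- pc$x
  qry_s <- sweep(qry, 2, pc$center) %*% pc$rotation
  k <- min(k_map, nrow(ref_s))
  nn <- RANN::nn2(ref_s, qry_s, k = k)$nn.idx
  pred <- vapply(seq_len(nrow(qry_s)), function(i) {
    names(which.max(table(reference$cell_types[nn[i, ]])))
  }, character(1))
  acc <- if (!is.null(query$cell_types)) mean(pred == query$cell_types) else NA_real_
  list(predicted = pred, accuracy = acc)
}

#' Leave-one-batch-out automated cell-type mapping
#'
#' Each batch in turn is held out as query; the remaining batches form the
#' reference. The `"individual"` baseline maps the query against each
#' retained batch alone; the `"sida"` method integrates the retained
#' batches, back-projects the embedding into each retained batch's gene
#' space via MNN anchors, and maps against each projected panel.
#'
#' @param collection A raw [DataCollection] with >= 3 batches (consolidated
#'   labels).
#' @param integrator `"sida"` or `"none"` (baseline only).
#' @param config A `SidaConfig` for the integration runs.
#' @param n_pcs Preprocessing PCA dimensionality.
#' @param n_hvg,k_map Passed to [map_cell_types()].
#' @param k_anchor,n_weight Passed to the anchor/projection steps.
#' @return Long-format data frame (left_out, method, target_space,
#'   accuracy), one row per (left-out batch, method, reference space).
#' @export
leave_one_out <- function(collection, integrator = c("sida", "none"),
                          config = sida_config(), n_pcs = 50L,
                          n_hvg = 2000L, k_map = 15L, k_anchor = 5L,
                          n_weight = 10L) {
  stopifnot(inherits(collection, "DataCollection"))
  integrator <- match.arg(integrator)
  ids <- names(collection$batches)
  if (length(ids) < 3) stop("leave-one-out needs at least three batches")
  rows <- list()
  for (q in ids) {
    retained <- DataCollection(unname(collection$batches[setdiff(ids, q)]))
    retained$cell_type_universe <-
      sort(unique(unlist(lapply(retained$batches, `[[`, "cell_types"))))
    prep <- preprocess_collection(retained, n_pcs = n_pcs)
    shared_genes <- prep$collection$batches[[1]]$gene_names
    query <- collection$batches[[q]]
    query$matrix <- query$matrix[, intersect(query$gene_names, shared_genes),
                                 drop = FALSE]
    query$gene_names <- colnames(query$matrix)
    query <- normalize_log(query)
    for (r in setdiff(ids, q)) {
      res <- map_cell_types(as_reference_panel(prep$collection$batches[[r]]),
                            query, n_hvg, n_pcs, k_map)
      rows[[length(rows) + 1L]] <- data.frame(
        left_out = q, method = "individual", target_space = r,
        accuracy = res$accuracy, stringsAsFactors = FALSE)
    }
    if (integrator == "sida") {
      sub <- subsample_cells(prep$pc_view, config$cells_per_type, config$seed)
      sched <- make_schedule(names(prep$pc_view$batches), config$seed)
      model <- sida_train(sub, sched, config)
      emb <- sida_embed(model, prep$pc_view)
      for (r in setdiff(ids, q)) {
        anchors <- find_anchors(emb, r, k_anchor)
        panel <- project_to_gene_space(prep$collection, emb, anchors, n_weight)
        res <- map_cell_types(panel, query, n_hvg, n_pcs, k_map)
        rows[[length(rows) + 1L]] <- data.frame(
          left_out = q, method = "sida", target_space = r,
          accuracy = res$accuracy, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
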