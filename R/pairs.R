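#' Subsample cells per (batch, cell type)
#'
#' Training uses a type-balanced subsample so abundant types do not dominate
#' the pair stream: within each batch, at most `cells_per_type` cells of
#' each type are kept, sampled without replacement. Sampling is
#' deterministic given the seed; shortfalls (types with fewer cells than
#' requested) keep all available cells.
#'
#' @param pc_view A `PCView` from [pca_per_batch()].
#' @param cells_per_type Maximum cells retained per type per batch.
#' @param seed Integer seed controlling the draw.
#' @return A `PCView` with subsampled rows (row order preserved).
#' @export
subsample_cells <- function(pc_view, cells_per_type, seed = 1L) {
  stopifnot(inherits(pc_view, "PCView"), cells_per_type >= 1)
  withr::with_seed(seed, {
    pc_view$batches <- lapply(pc_view$batches, function(b) {
      keep <- unlist(lapply(split(seq_along(b$cell_types), b$cell_types),
                            function(idx) {
        if (length(idx) <= cells_per_type) idx
        else sample(idx, cells_per_type)
      }), use.names = FALSE)
      keep <- sort(keep)
      b$coords <- b$coords[keep, , drop = FALSE]
      b$cell_ids <- b$cell_ids[keep]
      b$cell_types <- b$cell_types[keep]
      b
    })
  })
  pc_view
}

#' Build the rotated source/target batch schedule
#'
#' One cycle enumerates every ordered pair of distinct batches: first all
#' unordered pairs (i, j), i < j, with the lower-indexed batch as source,
#' then the same pairs reversed — for batches 1..3 the cycle is
#' (1,2), (1,3), (2,3), (2,1), (3,1), (3,2) — after which the schedule
#' rotates back to the start. Every batch therefore serves as source against
#' every other batch, which lets the classifier see all batches' cell types
#' even though it is attached to the source branch only.
#'
#' @param batch_ids Character vector of at least two batch ids.
#' @param seed Seed stored with the schedule for downstream pair drawing.
#' @return A `PairSchedule`: list with `cycle` (two-column character matrix
#'   source/target), `seed`.
#' @export
make_schedule <- function(batch_ids, seed = 1L) {
  if (length(batch_ids) < 2)
    stop("need at least two batches to integrate")
  idx <- utils::combn(seq_along(batch_ids), 2)
  fwd <- cbind(batch_ids[idx[1, ]], batch_ids[idx[2, ]])
  cycle <- rbind(fwd, fwd[, 2:1, drop = FALSE])
  colnames(cycle) <- c("source", "target")
  structure(list(cycle = cycle, seed = as.integer(seed)),
            class = "PairSchedule")
}

#' Draw one minibatch of cross-batch training pairs
#'
#' Pairs are stratified by cell type: a positive pair picks one of the
#' types shared by both batches, then one cell of that type from each
#' batch; a negative pair picks a source type and a different target type.
#' `round(size * pos_fraction)` positive pairs are drawn whenever shared
#' types exist (with a warning and all-negative output otherwise). Each
#' source cell carries its class index into `y_source` so batch-specific
#' types still train the classifier.
#'
#' Uses the current RNG state; seed once before iterating a schedule for a
#' reproducible stream.
#'
#' @param pc_view Subsampled `PCView`.
#' @param step Character vector `c(source_id, target_id)`.
#' @param size Number of pairs.
#' @param pos_fraction Fraction of same-type pairs (default 0.5).
#' @return A `PairBatch`: `x_source`, `x_target` (size x n_pcs matrices),
#'   `y_source` (integer class in 1..C, levels = cell_type_universe),
#'   `same_type` (logical), `source_batch`, `target_batch`.
#' @export
draw_pair_batch <- function(pc_view, step, size = 64L, pos_fraction = 0.5) {
  stopifnot(inherits(pc_view, "PCView"), length(step) == 2)
  universe <- pc_view$cell_type_universe
  src <- pc_view$batches[[step[1]]]
  tgt <- pc_view$batches[[step[2]]]
  if (is.null(src) || is.null(tgt)) stop("unknown batch id in step")
  src_by_type <- split(seq_along(src$cell_types), src$cell_types)
  tgt_by_type <- split(seq_along(tgt$cell_types), tgt$cell_types)
  shared <- intersect(names(src_by_type), names(tgt_by_type))
  n_pos <- round(size * pos_fraction)
  if (!length(shared) && pos_fraction > 0) {
    warning("no shared cell types between '", step[1], "' and '", step[2],
            "'; emitting negative pairs only")
    n_pos <- 0L
  }
  # a negative pair needs some (source type, different target type) combo
  can_neg <- length(unique(c(names(src_by_type), names(tgt_by_type)))) > 1
  n_neg <- size - n_pos
  if (n_neg > 0 && !can_neg) { n_pos <- size; n_neg <- 0L }

  pick <- function(v) v[sample.int(length(v), 1L)]
  si <- integer(size); ti <- integer(size)
  same <- logical(size)
  if (n_pos > 0) {
    types <- sample(shared, n_pos, replace = TRUE)
    si[seq_len(n_pos)] <- vapply(types, function(tp) pick(src_by_type[[tp]]),
                                 integer(1))
    ti[seq_len(n_pos)] <- vapply(types, function(tp) pick(tgt_by_type[[tp]]),
                                 integer(1))
    same[seq_len(n_pos)] <- TRUE
  }
  if (n_neg > 0) {
    for (i in n_pos + seq_len(n_neg)) {
      repeat {
        ts <- pick(names(src_by_type))
        tt <- pick(names(tgt_by_type))
        if (ts != tt) break
      }
      si[i] <- pick(src_by_type[[ts]])
      ti[i] <- pick(tgt_by_type[[tt]])
    }
  }
  structure(list(
    x_source = src$coords[si, , drop = FALSE],
    x_target = tgt$coords[ti, , drop = FALSE],
    y_source = match(src$cell_types[si], universe),
    same_type = same,
    source_cells = src$cell_ids[si],
    target_cells = tgt$cell_ids[ti],
    source_batch = step[1], target_batch = step[2]
  ), class = "PairBatch")
}
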