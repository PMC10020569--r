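# Integration-quality metrics. All kNN computations use Euclidean distance,
# exclude the cell itself, and break distance ties by cell index (stable).

#' k-nearest-neighbor indices
#'
#' Exact search (full distance matrix, ties broken by lower cell index) for
#' moderate n; kd-tree search via RANN above `exact_max` rows, where for
#' continuous embeddings exact ties have probability zero.
#'
#' @param coords Cells x d coordinate matrix.
#' @param k Neighbors per cell (capped at n - 1).
#' @param exact_max Largest n for the exact path.
#' @return n x k integer matrix of neighbor indices (self excluded).
#' @export
knn_indices <- function(coords, k, exact_max = 4000L) {
  n <- nrow(coords)
  if (k < 1) stop("k must be >= 1")
  k <- min(k, n - 1L)
  if (n <= exact_max) {
    D <- as.matrix(stats::dist(coords))
    t(vapply(seq_len(n), function(i) {
      ord <- order(D[i, ], seq_len(n))   # distance, then stable index
      ord <- ord[ord != i]
      ord[seq_len(k)]
    }, integer(k)))
  } else {
    nn <- RANN::nn2(coords, coords, k = k + 1L)$nn.idx
    t(vapply(seq_len(n), function(i) {
      row <- nn[i, ]
      row <- row[row != i]
      row[seq_len(k)]
    }, integer(k)))
  }
}

#' kNN positive rate (cell-type neighborhood purity)
#'
#' A cell is "positive" when at least `purity` (default 95%) of its `k`
#' (default 50) nearest neighbors share its cell type. The positive rate is
#' the fraction of positive cells.
#'
#' @param embedding An [Embedding].
#' @param k Neighborhood size.
#' @param purity Required same-type share.
#' @param nn Optional precomputed [knn_indices()] matrix.
#' @return List with `rate` and per-cell logical `flags`.
#' @export
positive_rate <- function(embedding, k = 50L, purity = 0.95, nn = NULL) {
  stopifnot(inherits(embedding, "Embedding"))
  n <- nrow(embedding$coordinates)
  if (n <= k) stop("need more than k = ", k, " cells")
  if (is.null(nn)) nn <- knn_indices(embedding$coordinates, k)
  types <- embedding$cell_types
  share <- vapply(seq_len(n), function(i)
    mean(types[nn[i, ]] == types[i]), numeric(1))
  flags <- share >= purity
  list(rate = mean(flags), flags = flags, k = ncol(nn), purity = purity)
}

#' kNN true-positive rate (batch mixing among positive cells)
#'
#' A positive cell of type t is a "true positive" when, for every batch i,
#' the number of its k neighbors drawn from batch i lies inside the
#' three-sigma binomial interval
#' `[max(0, k p_i - 3 sqrt(k p_i (1 - p_i))), k p_i + 3 sqrt(k p_i (1 - p_i))]`,
#' where `p_i` is batch i's share of all type-t cells. The rate keeps the
#' full cell count as denominator, so it never exceeds the positive rate.
#'
#' @param embedding An [Embedding].
#' @param positive_flags Per-cell flags from [positive_rate()] at the same k.
#' @param k Neighborhood size.
#' @param nn Optional precomputed neighbor matrix.
#' @return List with `rate` and per-cell logical `flags`.
#' @export
true_positive_rate <- function(embedding, positive_flags, k = 50L, nn = NULL) {
  stopifnot(inherits(embedding, "Embedding"))
  n <- nrow(embedding$coordinates)
  if (is.null(nn)) nn <- knn_indices(embedding$coordinates, k)
  k <- ncol(nn)
  types <- embedding$cell_types
  batches <- factor(embedding$batch_ids)
  B <- nlevels(batches)
  # per-type batch composition p_i
  comp <- table(types, batches)
  p <- comp / rowSums(comp)
  flags <- logical(n)
  for (i in which(positive_flags)) {
    pi <- p[types[i], ]
    Mi <- tabulate(as.integer(batches[nn[i, ]]), nbins = B)
    sig <- 3 * sqrt(k * pi * (1 - pi))
    lo <- pmax(0, k * pi - sig)
    hi <- k * pi + sig
    flags[i] <- all(Mi >= lo & Mi <= hi)
  }
  list(rate = sum(flags) / n, flags = flags)
}

#' kBET: k-nearest-neighbor batch-effect test score
#'
#' For a 10% sample of cells, each sampled cell's kNN batch composition is
#' compared to the global batch proportions with a Pearson chi-squared
#' goodness-of-fit test (df = number of batches - 1, no continuity
#' correction). The score is 1 minus the rejection rate at level `alpha`:
#' close to 1 when batches are locally well mixed.
#'
#' Comparing each neighborhood to proportions estimated from the same
#' finite label population makes the test slightly conservative (the
#' deflation is roughly `1 - k/n`); supply `global_props` when the null
#' composition is known exogenously, e.g. in calibration studies.
#'
#' @param embedding An [Embedding] with at least two batches.
#' @param k Neighborhood size.
#' @param sample_fraction Fraction of cells tested.
#' @param alpha Test level.
#' @param seed Seed for the cell sample.
#' @param nn Optional precomputed neighbor matrix.
#' @param global_props Optional named vector of expected batch proportions
#'   (must cover every batch and sum to 1); default: the embedding's own
#'   batch composition.
#' @return List with `score` (1 - rejection rate), `rejection_rate`,
#'   per-sampled-cell `stats` and `p_values`.
#' @export
kbet <- function(embedding, k = 50L, sample_fraction = 0.10, alpha = 0.05,
                 seed = 1L, nn = NULL, global_props = NULL) {
  stopifnot(inherits(embedding, "Embedding"))
  batches <- factor(embedding$batch_ids)
  B <- nlevels(batches)
  if (B < 2) stop("kBET needs at least two batches")
  n <- nrow(embedding$coordinates)
  m <- max(1L, round(n * sample_fraction))
  if (is.null(nn)) nn <- knn_indices(embedding$coordinates, k)
  k <- ncol(nn)
  f <- if (is.null(global_props)) as.numeric(table(batches)) / n
  else {
    if (!all(levels(batches) %in% names(global_props)))
      stop("global_props must name every batch")
    p <- as.numeric(global_props[levels(batches)])
    if (abs(sum(p) - 1) > 1e-8) stop("global_props must sum to 1")
    p
  }
  idx <- withr::with_seed(seed, sample.int(n, m))
  stats <- vapply(idx, function(i) {
    O <- tabulate(as.integer(batches[nn[i, ]]), nbins = B)
    E <- k * f
    sum((O - E)^2 / E)
  }, numeric(1))
  pv <- stats::pchisq(stats, df = B - 1, lower.tail = FALSE)
  rej <- mean(pv < alpha)
  list(score = 1 - rej, rejection_rate = rej, stats = stats, p_values = pv,
       sampled = idx, k = k, alpha = alpha)
}

#' Local inverse Simpson's index (LISI)
#'
#' For each cell, neighbor weights are given by a Gaussian kernel on squared
#' Euclidean distance whose bandwidth is calibrated by bisection so that the
#' weight distribution has the requested perplexity; the cell's score is the
#' inverse Simpson's index `1 / sum_b p(b)^2` of the weighted category
#' composition of its neighborhood. The score ranges from 1 (one category)
#' to the number of categories (uniform mixture). With batch labels this is
#' iLISI (higher = better mixing); with cell-type labels, cLISI (lower =
#' better separation).
#'
#' @param embedding An [Embedding].
#' @param labels Per-cell category labels.
#' @param perplexity Effective neighborhood size (default 30).
#' @return Per-cell numeric vector of inverse Simpson's indices.
#' @export
lisi <- function(embedding, labels, perplexity = 30) {
  stopifnot(inherits(embedding, "Embedding"))
  coords <- embedding$coordinates
  n <- nrow(coords)
  if (perplexity >= n) stop("perplexity must be smaller than the cell count")
  labels <- factor(labels)
  B <- nlevels(labels)
  if (B < 2) stop("LISI needs at least two categories")
  k <- min(n - 1L, as.integer(ceiling(3 * perplexity)))
  nn <- knn_indices(coords, k)
  d2 <- t(vapply(seq_len(n), function(i) {
    colSums((t(coords[nn[i, ], , drop = FALSE]) - coords[i, ])^2)
  }, numeric(k)))
  target <- log(perplexity)
  vapply(seq_len(n), function(i) {
    di <- d2[i, ]
    lo <- 0; hi <- Inf; beta <- 1
    w <- NULL
    for (iter in 1:64) {
      w <- exp(-beta * (di - min(di)))
      sw <- sum(w)
      H <- log(sw) + beta * sum(w * (di - min(di))) / sw
      if (abs(H - target) < 1e-7) break
      if (H > target) {                 # too diffuse -> increase beta
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- (lo + beta) / 2
      }
    }
    w <- w / sum(w)
    p <- vapply(split(w, labels[nn[i, ]]), sum, numeric(1))
    1 / sum(p^2)
  }, numeric(1))
}

#' Combine iLISI and cLISI into the F1 LISI score
#'
#' Raw scores are first rescaled to `[0, 1]` via `(LISI - 1) / (B - 1)`
#' (B = number of categories on that axis; the raw index lives in `[1, B]`),
#' then combined as `2 (1 - cLISI) iLISI / (1 - cLISI + iLISI)`.
#'
#' @param ilisi_raw,clisi_raw Mean raw LISI on the batch / cell-type axis.
#' @param n_batches,n_types Category counts used for rescaling.
#' @return List with `f1`, `ilisi` and `clisi` (rescaled means).
#' @export
f1_lisi <- function(ilisi_raw, clisi_raw, n_batches, n_types) {
  i01 <- (ilisi_raw - 1) / (n_batches - 1)
  c01 <- if (n_types > 1) (clisi_raw - 1) / (n_types - 1) else 0
  i01 <- min(max(i01, 0), 1); c01 <- min(max(c01, 0), 1)
  den <- (1 - c01) + i01
  list(f1 = if (den > 0) 2 * (1 - c01) * i01 / den else 0,
       ilisi = i01, clisi = c01)
}

#' Average silhouette width
#'
#' Mean silhouette `s = (b - a) / max(a, b)` over cells (Euclidean
#' distance), where `a` is the mean distance to the cell's own cluster and
#' `b` the mean distance to the nearest other cluster; singleton clusters
#' score 0.
#'
#' @param embedding An [Embedding].
#' @param labels Per-cell cluster labels (>= 2 distinct).
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
asw <- function(embedding, labels) {
  stopifnot(inherits(embedding, "Embedding"))
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("silhouette needs at least two labels")
  sil <- cluster::silhouette(as.integer(labels),
                             stats::dist(embedding$coordinates))
  mean(sil[, "sil_width"])
}

#' Combine batch and cell-type silhouettes into the F1 ASW score
#'
#' Raw silhouettes (in `[-1, 1]`) are rescaled to `[0, 1]` via
#' `(s + 1) / 2`, then combined as
#' `2 (1 - ASW_batch) ASW_celltype / (1 - ASW_batch + ASW_celltype)`.
#'
#' @param asw_batch,asw_celltype Raw mean silhouettes by batch / cell type.
#' @return List with `f1`, `asw_batch`, `asw_celltype` (rescaled).
#' @export
f1_asw <- function(asw_batch, asw_celltype) {
  b01 <- (asw_batch + 1) / 2
  c01 <- (asw_celltype + 1) / 2
  den <- (1 - b01) + c01
  list(f1 = if (den > 0) 2 * (1 - b01) * c01 / den else 0,
       asw_batch = b01, asw_celltype = c01)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement under the permutation model;
#' 1 for identical partitions (up to relabeling), about 0 for independent
#' ones.
#'
#' @param a,b Two label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
ari_score <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  sa <- sum(ch2(rowSums(tab)))
  sb <- sum(ch2(colSums(tab)))
  np <- ch2(length(a))
  expected <- sa * sb / np
  mx <- (sa + sb) / 2
  if (mx == expected) return(1)  # both partitions trivial
  (sij - expected) / (mx - expected)
}

#' k-means based ARI scores and their F1 combination
#'
#' Cells are clustered by k-means in the embedding with k equal to the
#' number of unique cell types (seeded, 10 restarts, best inertia kept).
#' `ARI_celltype` compares the clustering to the true cell types (higher =
#' better separation); `ARI_batch` compares it to the batch labels (lower =
#' better mixing). Both are clamped at 0 (chance-level ARI can be slightly
#' negative) and combined as
#' `2 (1 - ARI_batch) ARI_celltype / (1 - ARI_batch + ARI_celltype)`.
#'
#' @param embedding An [Embedding] with >= 2 cell types.
#' @param seed Seed for k-means restarts.
#' @param nstart Number of k-means restarts.
#' @return List with `f1`, `ari_batch`, `ari_celltype`, `clusters`.
#' @export
ari <- function(embedding, seed = 1L, nstart = 10L) {
  stopifnot(inherits(embedding, "Embedding"))
  C <- length(unique(embedding$cell_types))
  if (C < 2) stop("ARI clustering needs at least two cell types")
  n <- nrow(embedding$coordinates)
  if (n < C) stop("fewer cells than cell types")
  km <- withr::with_seed(seed,
    stats::kmeans(embedding$coordinates, centers = C, nstart = nstart,
                  iter.max = 100))
  a_ct <- max(0, ari_score(km$cluster, embedding$cell_types))
  a_b <- max(0, ari_score(km$cluster, embedding$batch_ids))
  den <- (1 - a_b) + a_ct
  list(f1 = if (den > 0) 2 * (1 - a_b) * a_ct / den else 0,
       ari_batch = a_b, ari_celltype = a_ct, clusters = km$cluster)
}

#' Evaluate all six integration metrics
#'
#' Computes the kNN positive and true-positive rates, kBET, and the F1
#' combinations of LISI, ASW and ARI on one integrated embedding; all
#' headline scores lie in `[0, 1]` and higher is better.
#'
#' @param embedding An [Embedding] with >= 2 batches and cell-type labels.
#' @param k kNN size for the positive/true-positive rates and kBET.
#' @param purity Same-type share defining a positive cell.
#' @param sample_fraction,alpha kBET parameters.
#' @param perplexity LISI perplexity.
#' @param seed Seed for kBET sampling and k-means.
#' @return A `MetricsReport` with the six headline scores, raw sub-scores
#'   and the parameters used.
#' @export
evaluate_all <- function(embedding, k = 50L, purity = 0.95,
                         sample_fraction = 0.10, alpha = 0.05,
                         perplexity = 30, seed = 1L) {
  stopifnot(inherits(embedding, "Embedding"))
  nn <- knn_indices(embedding$coordinates, k)
  pos <- positive_rate(embedding, k, purity, nn = nn)
  tp <- true_positive_rate(embedding, pos$flags, k, nn = nn)
  kb <- kbet(embedding, k, sample_fraction, alpha, seed, nn = nn)
  B <- length(unique(embedding$batch_ids))
  C <- length(unique(embedding$cell_types))
  il <- mean(lisi(embedding, embedding$batch_ids, perplexity))
  cl <- if (C > 1) mean(lisi(embedding, embedding$cell_types, perplexity)) else 1
  fl <- f1_lisi(il, cl, B, C)
  ab <- asw(embedding, embedding$batch_ids)
  ac <- asw(embedding, embedding$cell_types)
  fa <- f1_asw(ab, ac)
  fr <- ari(embedding, seed)
  structure(list(
    positive_rate = pos$rate,
    true_positive_rate = tp$rate,
    kbet = kb$score,
    f1_lisi = fl$f1,
    f1_asw = fa$f1,
    f1_ari = fr$f1,
    sub = list(ilisi_raw = il, clisi_raw = cl,
               ilisi = fl$ilisi, clisi = fl$clisi,
               asw_batch_raw = ab, asw_celltype_raw = ac,
               asw_batch = fa$asw_batch, asw_celltype = fa$asw_celltype,
               ari_batch = fr$ari_batch, ari_celltype = fr$ari_celltype,
               kbet_rejection = kb$rejection_rate),
    params = list(k = k, purity = purity, sample_fraction = sample_fraction,
                  alpha = alpha, perplexity = perplexity, seed = seed)
  ), class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat("Integration metrics:\n")
  for (f in c("positive_rate", "true_positive_rate", "kbet",
              "f1_lisi", "f1_asw", "f1_ari"))
    cat(sprintf("  %-18s %.4f\n", f, x[[f]]))
  invisible(x)
}

#' Flatten a MetricsReport to a one-row data frame
#' @param report A `MetricsReport`.
#' @return One-row data frame of the six headline scores.
#' @export
metrics_row <- function(report) {
  stopifnot(inherits(report, "MetricsReport"))
  as.data.frame(report[c("positive_rate", "true_positive_rate", "kbet",
                         "f1_lisi", "f1_asw", "f1_ari")])
}
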