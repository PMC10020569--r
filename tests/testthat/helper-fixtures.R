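# Fixture builders and independent brute-force oracles used across tests.
# Oracles are deliberately naive (full loops / O(n^2) scans) and share no
# code with the package implementation.

rand_embedding <- function(n, d = 5, n_types = 3, n_batches = 2, seed = 1) {
  withr::with_seed(seed, {
    Embedding(matrix(rnorm(n * d), n, d),
              sprintf("c%03d", seq_len(n)),
              sample(sprintf("type%d", seq_len(n_types)), n, replace = TRUE),
              sample(sprintf("batch%d", seq_len(n_batches)), n, replace = TRUE))
  })
}

# blobs: one Gaussian blob per row of `centers`; types/batches recycled
blob_embedding <- function(centers, n_per, types, batches, sd = 0.1, seed = 1) {
  withr::with_seed(seed, {
    co <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
      matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
        rep(centers[i, ], each = n_per)))
    Embedding(co, sprintf("c%04d", seq_len(nrow(co))),
              rep(types, each = n_per)[seq_len(nrow(co))],
              rep(batches, each = n_per)[seq_len(nrow(co))])
  })
}

# well-mixed fixture: types separated, batch labels shuffled within type
mixed_embedding <- function(n_types = 3, n_batches = 2, n_per = 120, d = 4,
                            sep = 20, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    centers <- matrix(0, n_types, d)
    for (i in seq_len(n_types)) centers[i, ((i - 1) %% d) + 1] <- i * sep
    co <- do.call(rbind, lapply(seq_len(n_types), function(i)
      matrix(rnorm(n_per * d, sd = sd), n_per) + rep(centers[i, ], each = n_per)))
    Embedding(co, sprintf("c%04d", seq_len(nrow(co))),
              rep(sprintf("type%d", seq_len(n_types)), each = n_per),
              sample(sprintf("batch%d", seq_len(n_batches)), n_types * n_per,
                     replace = TRUE))
  })
}

oracle_knn <- function(coords, k) {
  n <- nrow(coords)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- sqrt(sum((coords[i, ] - coords[j, ])^2))
  t(sapply(seq_len(n), function(i) {
    cand <- setdiff(seq_len(n), i)
    cand[order(D[i, cand], cand)][seq_len(min(k, n - 1))]
  }))
}

oracle_positive <- function(emb, k, purity) {
  nn <- oracle_knn(emb$coordinates, k)
  flags <- sapply(seq_len(nrow(nn)), function(i)
    sum(emb$cell_types[nn[i, ]] == emb$cell_types[i]) / ncol(nn) >= purity)
  list(rate = mean(flags), flags = flags)
}

oracle_tpr <- function(emb, flags, k) {
  nn <- oracle_knn(emb$coordinates, k)
  bl <- unique(emb$batch_ids)
  ok <- logical(length(flags))
  for (i in which(flags)) {
    tt <- emb$cell_types[i]
    Nt <- sapply(bl, function(b) sum(emb$cell_types == tt & emb$batch_ids == b))
    p <- Nt / sum(Nt)
    M <- sapply(bl, function(b) sum(emb$batch_ids[nn[i, ]] == b))
    good <- TRUE
    for (j in seq_along(bl)) {
      s <- 3 * sqrt(k * p[j] * (1 - p[j]))
      if (M[j] < max(0, k * p[j] - s) || M[j] > k * p[j] + s) good <- FALSE
    }
    ok[i] <- good
  }
  sum(ok) / length(flags)
}

oracle_chisq <- function(obs, expected) sum((obs - expected)^2 / expected)

oracle_silhouette <- function(coords, labels) {
  n <- nrow(coords)
  D <- as.matrix(dist(coords))
  mean(sapply(seq_len(n), function(i) {
    own <- which(labels == labels[i])
    if (length(own) == 1) return(0)
    a <- mean(D[i, setdiff(own, i)])
    b <- min(sapply(setdiff(unique(labels), labels[i]), function(l)
      mean(D[i, labels == l])))
    (b - a) / max(a, b)
  }))
}

oracle_mutual_knn <- function(co_a, co_b, k) {
  # all (i in a, j in b) mutually within each other's k nearest cross-set nbrs
  da <- function(i) sqrt(colSums((t(co_b) - co_a[i, ])^2))
  db <- function(j) sqrt(colSums((t(co_a) - co_b[j, ])^2))
  out <- NULL
  for (i in seq_len(nrow(co_a))) {
    nb_i <- order(da(i))[seq_len(min(k, nrow(co_b)))]
    for (j in nb_i) {
      nb_j <- order(db(j))[seq_len(min(k, nrow(co_a)))]
      if (i %in% nb_j) out <- rbind(out, c(i, j))
    }
  }
  out
}

# tiny already-consolidated collection built by hand (not via the simulator)
toy_collection <- function(n_genes = 30, n_per = 8, seed = 42) {
  withr::with_seed(seed, {
    genes <- sprintf("g%02d", seq_len(n_genes))
    mk <- function(bid, types) {
      lab <- rep(types, each = n_per)
      m <- matrix(rpois(length(lab) * n_genes, lambda = 5), length(lab))
      m[lab == types[1], 1:5] <- m[lab == types[1], 1:5] + 30
      ExpressionBatch(m, genes, sprintf("%s_c%02d", bid, seq_along(lab)),
                      lab, bid)
    }
    DataCollection(list(mk("b1", c("alpha", "beta")),
                        mk("b2", c("alpha", "beta"))))
  })
}
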