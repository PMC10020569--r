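test_that("positive rate is 1 on pure far-apart blobs and 0 on shuffled labels", {
  centers <- rbind(c(0, 0), c(100, 0))
  emb <- blob_embedding(centers, 60, c("t1", "t2"), c("b1", "b1"), seed = 1)
  expect_equal(positive_rate(emb, k = 50)$rate, 1.0)
  # random 2-type labels in one blob: 95% purity unreachable near 50/50
  emb2 <- withr::with_seed(2, Embedding(matrix(rnorm(240), 120),
                                        sprintf("c%d", 1:120),
                                        sample(c("a", "b"), 120, replace = TRUE),
                                        rep("b1", 120)))
  expect_equal(positive_rate(emb2, k = 50)$rate, 0)
  expect_error(positive_rate(emb2, k = 0), "k")
  expect_error(positive_rate(emb2, k = 200), "more than")
})

test_that("kNN metrics equal brute-force oracles on random embeddings", {
  for (seed in 1:3) {
    emb <- rand_embedding(120, d = 4, n_types = 3, n_batches = 3, seed = seed)
    k <- 15
    expect_identical(knn_indices(emb$coordinates, k),
                     unname(oracle_knn(emb$coordinates, k)))
    pos <- positive_rate(emb, k, purity = 0.4)
    orc <- oracle_positive(emb, k, purity = 0.4)
    expect_equal(pos$rate, orc$rate, tolerance = 1e-12)
    expect_equal(pos$flags, orc$flags)
    tp <- true_positive_rate(emb, pos$flags, k)
    expect_equal(tp$rate, oracle_tpr(emb, orc$flags, k), tolerance = 1e-12)
    expect_lte(tp$rate, pos$rate)
    expect_equal(asw(emb, emb$cell_types),
                 oracle_silhouette(emb$coordinates, emb$cell_types),
                 tolerance = 1e-9)
  }
})

test_that("three-sigma true-positive intervals match the printed formula", {
  # two batches, p = (1/2, 1/2), k = 50: bounds ~ [14.39, 35.61] per batch
  k <- 50; p <- 0.5
  lo <- max(0, k * p - 3 * sqrt(k * p * (1 - p)))
  hi <- k * p + 3 * sqrt(k * p * (1 - p))
  expect_equal(lo, 14.3934, tolerance = 1e-4)
  expect_equal(hi, 35.6066, tolerance = 1e-4)
  # build a positive cell with a (20, 30) split -> true positive,
  # and one with (10, 40) -> not
  # cell 1 plus 50 tight neighbors with an (n1, 50 - n1) batch split; a far
  # blob balances the global composition to exactly (1/2, 1/2)
  mk <- function(n1) {
    co <- rbind(matrix(rnorm(102, sd = 1e-3), 51),
                matrix(rnorm(198, sd = 1e-3), 99) + 500)
    batches <- c("b1", rep(c("b1", "b2"), c(n1, 50 - n1)),
                 rep(c("b1", "b2"), c(74 - n1, 25 + n1)))
    Embedding(co, sprintf("c%d", 1:150), rep("t", 150), batches)
  }
  emb_ok <- withr::with_seed(4, mk(20))
  flags <- rep(FALSE, 150); flags[1] <- TRUE
  expect_equal(true_positive_rate(emb_ok, flags, k = 50)$rate, 1 / 150)
  emb_bad <- withr::with_seed(4, mk(10))
  expect_equal(true_positive_rate(emb_bad, flags, k = 50)$rate, 0)
})

test_that("a single batch makes every positive cell a true positive", {
  emb <- rand_embedding(80, n_batches = 1, seed = 5)
  pos <- positive_rate(emb, k = 10, purity = 0.2)
  tp <- true_positive_rate(emb, pos$flags, k = 10)
  expect_equal(tp$rate, pos$rate)
})

test_that("kBET chi-squared statistics match hand computation", {
  emb <- rand_embedding(150, d = 3, n_batches = 3, seed = 6)
  kb <- kbet(emb, k = 20, sample_fraction = 0.2, seed = 9)
  nn <- knn_indices(emb$coordinates, 20)
  f <- table(emb$batch_ids) / 150
  for (r in seq_along(kb$sampled)) {
    i <- kb$sampled[r]
    O <- sapply(names(f), function(b) sum(emb$batch_ids[nn[i, ]] == b))
    expect_equal(kb$stats[r], oracle_chisq(O, 20 * as.numeric(f)),
                 tolerance = 1e-10)
  }
  # a printed toy neighborhood: counts (10, 5, 5) vs uniform expectation
  expect_equal(oracle_chisq(c(10, 5, 5), c(20 / 3, 20 / 3, 20 / 3)),
               (10 - 20 / 3)^2 / (20 / 3) * 1 + (5 - 20 / 3)^2 / (20 / 3) * 2)
})

test_that("kBET hits its extremes on disjoint vs shuffled batches", {
  far <- blob_embedding(rbind(c(0, 0), c(1000, 0)), 100, c("t", "t"),
                        c("b1", "b2"), seed = 7)
  expect_lte(kbet(far, k = 50)$score, 0.05)
  mixed <- mixed_embedding(n_types = 2, n_batches = 2, n_per = 150, seed = 8)
  expect_gte(kbet(mixed, k = 50)$score, 0.8)
})

test_that("LISI attains its endpoint values and rescales into the F1", {
  one <- blob_embedding(rbind(c(0, 0), c(1000, 0)), 80, c("t1", "t2"),
                        c("b1", "b2"), seed = 9)
  cl <- lisi(one, one$cell_types, perplexity = 20)
  expect_true(all(cl < 1.02))          # single-category neighborhoods -> 1
  mixed <- mixed_embedding(n_types = 2, n_batches = 3, n_per = 200, seed = 10)
  il <- lisi(mixed, mixed$batch_ids, perplexity = 30)
  expect_gte(mean(il), 2.6)            # near the maximum B = 3
  expect_lte(max(il), 3 + 1e-9)
  # F1 endpoints
  expect_equal(f1_lisi(2, 1, 2, 2)$f1, 1)     # iLISI max, cLISI min
  expect_equal(f1_lisi(1.5, 3, 2, 3)$f1, 0)   # cLISI at its worst
  expect_error(lisi(mixed, rep("x", 600)), "two categories")
  expect_error(lisi(mixed, mixed$batch_ids, perplexity = 1000), "perplexity")
})

test_that("silhouette behaves at ideal separation and at the boundary", {
  far <- blob_embedding(rbind(c(0, 0), c(500, 0)), 50, c("t1", "t2"),
                        c("b", "b"), sd = 0.01, seed = 11)
  expect_gt(asw(far, far$cell_types), 0.99)
  # a point equidistant between its own cluster and the other scores ~0
  co <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1), c(5, 0.5))
  emb <- Embedding(co, paste0("c", 1:5), rep("t", 5),
                   c("a", "a", "b", "b", "a"))
  sil <- cluster::silhouette(c(1, 1, 2, 2, 1), dist(co))
  a <- mean(sqrt(colSums((t(co[1:2, ]) - co[5, ])^2)))
  b <- mean(sqrt(colSums((t(co[3:4, ]) - co[5, ])^2)))
  expect_equal(a, b, tolerance = 1e-9)
  expect_equal(unname(sil[5, "sil_width"]), 0, tolerance = 1e-9)
  expect_error(asw(far, rep("one", 100)), "two labels")
})

test_that("ARI matches hand pair-counting and an independent implementation", {
  expect_equal(ari_score(c(1, 1, 2, 2), c(1, 2, 2, 2)), 0)  # closed form
  expect_equal(ari_score(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)  # relabeling
  withr::with_seed(12, {
    for (rep in 1:10) {
      a <- sample(4, 60, replace = TRUE)
      b <- sample(3, 60, replace = TRUE)
      expect_equal(ari_score(a, b), mclust::adjustedRandIndex(a, b),
                   tolerance = 1e-12)
    }
    perm <- sample(4)
    a <- sample(4, 60, replace = TRUE)
    expect_equal(ari_score(a, perm[a]), 1)
  })
})

test_that("k-means ARI scores recognize a perfectly clustered embedding", {
  mixed <- mixed_embedding(n_types = 3, n_batches = 2, n_per = 80, seed = 13)
  res <- ari(mixed, seed = 1)
  expect_equal(res$ari_celltype, 1)
  expect_lt(res$ari_batch, 0.05)
  expect_gt(res$f1, 0.95)
  expect_error(ari(blob_embedding(rbind(c(0, 0)), 10, "t", "b"), 1),
               "two cell types")
})

test_that("evaluate_all populates a complete report within [0, 1]", {
  mixed <- mixed_embedding(n_types = 3, n_batches = 2, n_per = 70, seed = 14)
  rep1 <- evaluate_all(mixed, k = 30)
  scores <- unlist(metrics_row(rep1))
  expect_true(all(scores >= 0 & scores <= 1))
  expect_lte(rep1$true_positive_rate, rep1$positive_rate)
  expect_true(all(c("ilisi_raw", "asw_batch_raw", "ari_batch") %in%
                    names(rep1$sub)))
  # near-optimal on the well-mixed fixture
  expect_gte(rep1$positive_rate, 0.95)
  expect_gte(rep1$f1_ari, 0.9)
  # disjoint batch blobs: mixing scores collapse
  far <- blob_embedding(rbind(c(0, 0), c(800, 0)), 120,
                        c("t1", "t1"), c("b1", "b2"), seed = 15)
  expect_lte(kbet(far, k = 50)$score, 0.05)
  il <- mean(lisi(far, far$batch_ids, perplexity = 30))
  expect_lte((il - 1) / (2 - 1), 0.05)
})

test_that("metrics are invariant to rigid motion and uniform scaling", {
  emb <- mixed_embedding(n_types = 2, n_batches = 2, n_per = 60, seed = 16)
  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta), 0, 0),
             c(sin(theta), cos(theta), 0, 0),
             c(0, 0, 1, 0), c(0, 0, 0, 1))
  tr <- function(emb, f) {
    e <- emb; e$coordinates <- f(e$coordinates); e
  }
  variants <- list(tr(emb, function(x) x %*% R),
                   tr(emb, function(x) sweep(x, 2, c(5, -3, 2, 0), `+`)),
                   tr(emb, function(x) x * 3.7))
  base <- evaluate_all(emb, k = 20)
  for (v in variants) {
    m <- evaluate_all(v, k = 20)
    expect_equal(m$positive_rate, base$positive_rate, tolerance = 1e-12)
    expect_equal(m$true_positive_rate, base$true_positive_rate,
                 tolerance = 1e-12)
    expect_equal(m$kbet, base$kbet, tolerance = 1e-12)
    expect_equal(m$f1_lisi, base$f1_lisi, tolerance = 1e-6)
  }
  # ASW is rigid-motion and scale invariant too
  expect_equal(asw(variants[[3]], emb$cell_types), asw(emb, emb$cell_types),
               tolerance = 1e-9)
})
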