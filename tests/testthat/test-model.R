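naive_sa <- function(gs, gt, same, squared = FALSE) {
  vals <- c()
  for (i in which(same)) {
    d <- sqrt(sum((gs[i, ] - gt[i, ])^2))
    vals <- c(vals, if (squared) 0.5 * d^2 else 0.5 * d)
  }
  if (is.null(vals)) 0 else mean(vals)
}

naive_sep <- function(gs, gt, same, m) {
  vals <- c()
  for (i in which(!same)) {
    d <- sqrt(sum((gs[i, ] - gt[i, ])^2))
    vals <- c(vals, 0.5 * max(0, m - d)^2)
  }
  if (is.null(vals)) 0 else mean(vals)
}

naive_ce <- function(logits, y) {
  mean(sapply(seq_along(y), function(i) {
    p <- exp(logits[i, ]) / sum(exp(logits[i, ]))
    -log(p[y[i]])
  }))
}

test_that("loss components match their closed forms", {
  # alignment: coincident pairs give exactly zero; one pair at distance 2
  g1 <- rbind(c(1, 2), c(3, 4))
  expect_equal(semantic_alignment_loss(g1, g1, c(TRUE, TRUE)), 0)
  gs <- rbind(c(0, 0)); gt <- rbind(c(2, 0))
  expect_equal(semantic_alignment_loss(gs, gt, TRUE), 1.0, tolerance = 1e-9)
  expect_equal(semantic_alignment_loss(gs, gt, TRUE, sa_squared = TRUE), 2.0,
               tolerance = 1e-9)
  # separation: inactive beyond the margin, m^2/2 at distance zero
  expect_equal(separation_loss(gs, gt, FALSE, margin = 1), 0)
  expect_equal(separation_loss(rbind(c(1, 1)), rbind(c(1, 1)), FALSE,
                               margin = 1), 0.5, tolerance = 1e-9)
  expect_equal(separation_loss(rbind(c(0, 0)), rbind(c(1, 0)), FALSE,
                               margin = 2), 0.5, tolerance = 1e-9)
  # cross entropy: log C for uniform logits, ~0 for a confident classifier
  expect_equal(classification_loss(matrix(0, 3, 4), c(1, 2, 3)), log(4),
               tolerance = 1e-9)
  hot <- matrix(-50, 2, 3); hot[cbind(1:2, c(2, 3))] <- 50
  expect_lt(classification_loss(hot, c(2, 3)), 1e-6)
  expect_equal(classification_loss(matrix(1, 5, 1), rep(1, 5)), 0)
  expect_error(classification_loss(matrix(0, 2, 3), c(0, 1)), "labels")
})

test_that("losses equal naive loop recomputation on random pair batches", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      n <- 40
      gs <- matrix(rnorm(n * 6), n)
      gt <- matrix(rnorm(n * 6), n)
      same <- sample(c(TRUE, FALSE), n, replace = TRUE)
      m <- runif(1, 0.5, 3)
      expect_equal(semantic_alignment_loss(gs, gt, same),
                   naive_sa(gs, gt, same), tolerance = 1e-12)
      expect_equal(semantic_alignment_loss(gs, gt, same, sa_squared = TRUE),
                   naive_sa(gs, gt, same, squared = TRUE), tolerance = 1e-12)
      expect_equal(separation_loss(gs, gt, same, m),
                   naive_sep(gs, gt, same, m), tolerance = 1e-12)
      logits <- matrix(rnorm(n * 4), n)
      y <- sample(4, n, replace = TRUE)
      expect_equal(classification_loss(logits, y), naive_ce(logits, y),
                   tolerance = 1e-12)
    }
  })
})

test_that("degenerate pair batches warn and return zero", {
  g <- matrix(rnorm(10), 5)
  expect_warning(v <- semantic_alignment_loss(g, g, rep(FALSE, 5)),
                 "no positive")
  expect_equal(v, 0)
  expect_warning(v2 <- separation_loss(g, g, rep(TRUE, 5)), "no negative")
  expect_equal(v2, 0)
})

test_that("separation loss stays within [0, m^2/2]", {
  withr::with_seed(3, {
    for (rep in 1:20) {
      gs <- matrix(rnorm(20), 10); gt <- matrix(rnorm(20), 10)
      m <- runif(1, 0.1, 4)
      v <- separation_loss(gs, gt, rep(FALSE, 10), m)
      expect_gte(v, 0); expect_lte(v, m^2 / 2)
    }
  })
})

test_that("analytic gradients match finite differences, incl. the hinge cutoff", {
  withr::with_seed(31, {
    n <- 6; d <- 4
    gs <- matrix(rnorm(n * d), n); gt <- matrix(rnorm(n * d), n)
    same <- c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE)
    eps <- 1e-6
    for (fn in list(
      function(a, b) sida:::sa_loss_grad(a, b, same, FALSE),
      function(a, b) sida:::sa_loss_grad(a, b, same, TRUE),
      function(a, b) sida:::sep_loss_grad(a, b, same, 1.5))) {
      an <- fn(gs, gt)
      for (probe in 1:10) {
        i <- sample(n, 1); j <- sample(d, 1)
        gp <- gs; gp[i, j] <- gp[i, j] + eps
        gm <- gs; gm[i, j] <- gm[i, j] - eps
        num <- (fn(gp, gt)$value - fn(gm, gt)$value) / (2 * eps)
        expect_equal(an$dgs[i, j], num, tolerance = 1e-4)
      }
    }
    # hinge gradient vanishes for negative pairs beyond the margin
    far <- matrix(rnorm(n * d), n) + 10
    an <- sida:::sep_loss_grad(far, -far, same, 1.5)
    expect_true(all(an$dgs[!same, ] == 0))
    # cross-entropy gradient
    logits <- matrix(rnorm(n * 3), n); y <- sample(3, n, replace = TRUE)
    an <- sida:::ce_loss_grad(logits, y)
    for (probe in 1:10) {
      i <- sample(n, 1); j <- sample(3, 1)
      lp <- logits; lp[i, j] <- lp[i, j] + eps
      lm <- logits; lm[i, j] <- lm[i, j] - eps
      num <- (sida:::ce_loss_grad(lp, y)$value -
                sida:::ce_loss_grad(lm, y)$value) / (2 * eps)
      expect_equal(an$grad[i, j], num, tolerance = 1e-4)
    }
  })
})

test_that("network backpropagation matches finite differences end to end", {
  withr::with_seed(41, {
    layers <- sida:::init_layers(list(
      list(type = "conv", cout = 2, k = 3, act = "relu"),
      list(type = "dense", n_out = 3, act = "linear")), 10)
    x <- matrix(rnorm(5 * 10), 5)
    tgt <- matrix(rnorm(5 * 3), 5)
    loss_of <- function(ly) sum((sida:::nn_forward(ly, x)$out - tgt)^2)
    fw <- sida:::nn_forward(layers, x)
    bw <- sida:::nn_backward(layers, fw$caches, 2 * (fw$out - tgt))
    eps <- 1e-6
    for (li in seq_along(layers)) {
      field <- if (layers[[li]]$type == "dense") "W" else "Wk"
      for (probe in 1:6) {
        idx <- sample(length(layers[[li]][[field]]), 1)
        lp <- layers; lp[[li]][[field]][idx] <- lp[[li]][[field]][idx] + eps
        lm <- layers; lm[[li]][[field]][idx] <- lm[[li]][[field]][idx] - eps
        num <- (loss_of(lp) - loss_of(lm)) / (2 * eps)
        expect_equal(bw$grads[[li]]$W[idx], num, tolerance = 1e-3)
      }
    }
  })
})

test_that("the conv layer equals a naive sliding-window convolution", {
  withr::with_seed(51, {
    ly <- sida:::init_conv(L = 12, cin = 1, cout = 3, k = 3, act = "linear")
    x <- matrix(rnorm(4 * 12), 4)
    out <- sida:::layer_forward(ly, x)$out
    for (i in 1:4) for (co in 1:3) for (p in 1:10) {
      naive <- sum(x[i, p:(p + 2)] * ly$Wk[1:3, co]) + ly$b[co]
      expect_equal(out[i, (co - 1) * 10 + p], naive, tolerance = 1e-12)
    }
  })
})

test_that("total_loss is the weighted sum of its components", {
  fx <- smoke_fixture("tiny", batch_magnitude = 1, seed = 3)
  col <- consolidate_labels(fx$collection, fx$truth$label_map)
  pv <- preprocess_collection(col, n_pcs = 10)$pc_view
  cfg <- sida_config(steps = 5L, weights = c(2, 3, 0.5), seed = 7)
  sched <- make_schedule(names(pv$batches), 7)
  model <- sida_train(subsample_cells(pv, 30, 7), sched, cfg)
  pb <- withr::with_seed(8, draw_pair_batch(pv, c("batch1", "batch2"), 32))
  tl <- total_loss(pb, model, cfg)
  expect_equal(tl$total, 2 * tl$sa + 3 * tl$s + 0.5 * tl$c, tolerance = 1e-12)
})

test_that("weight sharing: both branches are the same map at all times", {
  fx <- smoke_fixture("tiny", batch_magnitude = 1, seed = 4)
  col <- consolidate_labels(fx$collection, fx$truth$label_map)
  pv <- preprocess_collection(col, n_pcs = 10)$pc_view
  model <- sida_train(subsample_cells(pv, 30, 1),
                      make_schedule(names(pv$batches), 1),
                      sida_config(steps = 40L, seed = 1))
  x <- pv$batches[[1]]$coords[1:7, ] / model$input_scale
  expect_identical(sida:::nn_forward(model$g, x)$out,
                   sida:::nn_forward(model$g, x)$out)
  # a pair of identical cells across branches has zero alignment distance
  gs <- sida:::nn_forward(model$g, x)$out
  expect_equal(semantic_alignment_loss(gs, gs, rep(TRUE, 7)), 0)
})

test_that("training is deterministic and contracts positive pairs", {
  fx <- smoke_fixture("tiny", batch_magnitude = 2, seed = 5)
  col <- consolidate_labels(fx$collection, fx$truth$label_map)
  pv <- preprocess_collection(col, n_pcs = 20)$pc_view
  sub <- subsample_cells(pv, 40, 2)
  sched <- make_schedule(names(pv$batches), 2)
  cfg <- sida_config(steps = 150L, seed = 2)
  m1 <- sida_train(sub, sched, cfg)
  m2 <- sida_train(sub, sched, cfg)
  expect_equal(m1$log, m2$log)
  e1 <- sida_embed(m1, pv); e2 <- sida_embed(m2, pv)
  expect_identical(e1$coordinates, e2$coordinates)
  # same-type cross-batch pairs end closer than different-type pairs
  pb <- withr::with_seed(3, draw_pair_batch(sub, c("batch1", "batch2"), 200))
  key <- function(emb) paste(emb$batch_ids, emb$cell_ids)
  i_s <- match(paste("batch1", pb$source_cells), key(e1))
  i_t <- match(paste("batch2", pb$target_cells), key(e1))
  d <- sqrt(rowSums((e1$coordinates[i_s, ] - e1$coordinates[i_t, ])^2))
  expect_lt(mean(d[pb$same_type]), mean(d[!pb$same_type]))
})

test_that("with contrastive terms off, training reduces to a working classifier", {
  fx <- smoke_fixture("tiny", batch_magnitude = 0, seed = 6)
  col <- consolidate_labels(fx$collection, fx$truth$label_map)
  pv <- preprocess_collection(col, n_pcs = 20)$pc_view
  sub <- subsample_cells(pv, 40, 3)
  model <- sida_train(sub, make_schedule(names(pv$batches), 3),
                      sida_config(steps = 250L, weights = c(0, 0, 1), seed = 3))
  correct <- 0; total <- 0
  for (b in sub$batches) {
    g <- sida:::nn_forward(model$g, b$coords / model$input_scale)$out
    logits <- sida:::nn_forward(model$h, g)$out
    pred <- model$cell_type_universe[max.col(logits, ties.method = "first")]
    correct <- correct + sum(pred == b$cell_types)
    total <- total + length(pred)
  }
  expect_gte(correct / total, 0.95)
})

test_that("embedding extraction conserves cells and is a pure function", {
  fx <- smoke_fixture("tiny", batch_magnitude = 1, seed = 7)
  col <- consolidate_labels(fx$collection, fx$truth$label_map)
  pv <- preprocess_collection(col, n_pcs = 15)$pc_view
  model <- sida_train(subsample_cells(pv, 30, 1),
                      make_schedule(names(pv$batches), 1),
                      sida_config(steps = 40L, seed = 1))
  emb <- sida_embed(model, pv)
  expect_equal(nrow(emb$coordinates),
               sum(vapply(pv$batches, function(b) nrow(b$coords), integer(1))))
  expect_equal(ncol(emb$coordinates), model$config$embedding_dim)
  # duplicated PC vector from the same batch maps to identical coordinates
  pv2 <- pv
  pv2$batches[[1]]$coords[2, ] <- pv2$batches[[1]]$coords[1, ]
  emb2 <- sida_embed(model, pv2)
  expect_identical(emb2$coordinates[1, ], emb2$coordinates[2, ])
  pv_bad <- preprocess_collection(
    consolidate_labels(smoke_fixture("tiny", seed = 8)$collection,
                       smoke_fixture("tiny", seed = 8)$truth$label_map),
    n_pcs = 9)$pc_view
  expect_error(sida_embed(model, pv_bad), "dimensionality")
})

test_that("training aborts with a diagnostic on divergence", {
  fx <- smoke_fixture("tiny", batch_magnitude = 1, seed = 9)
  col <- consolidate_labels(fx$collection, fx$truth$label_map)
  pv <- preprocess_collection(col, n_pcs = 10)$pc_view
  expect_error(
    sida_train(subsample_cells(pv, 30, 1),
               make_schedule(names(pv$batches), 1),
               sida_config(steps = 400L, lr = 1e80, seed = 1)),
    "diverged")
})
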