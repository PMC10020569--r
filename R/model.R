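#' Configuration for the integration network
#'
#' Collects every tunable of the Siamese domain-adaptation network. The
#' feature branch `g` maps each cell's per-batch PC coordinates into a
#' common space where the contrastive semantic alignment objective acts;
#' the classifier `h` (two feed-forward feature layers plus a softmax head)
#' is attached to the source branch, and the output of its second feature
#' layer is the integrated embedding.
#'
#' @param margin Separation margin `m` of the hinge in the separation loss;
#'   negative pairs further apart than `m` contribute nothing.
#' @param weights Numeric triple `c(sa, s, c)` weighting the semantic
#'   alignment, separation and classification losses.
#' @param steps Number of training minibatches (pair batches).
#' @param lr Adam step size.
#' @param batch_size Pairs per minibatch.
#' @param embedding_dim Width of the second feature layer of `h` = dimension
#'   of the integrated embedding.
#' @param g_spec Layer list for `g`. Default: two 1-D convolutions (kernel 3,
#'   8 channels, ReLU) over the PC axis followed by a linear map to
#'   `g_dim`; set `sida_mlp_g()` for a plain multilayer perceptron.
#' @param g_dim Output width of `g`.
#' @param h_hidden Width of the first feature layer of `h`.
#' @param sa_squared If `FALSE` (default) the alignment loss uses the
#'   Euclidean distance itself; if `TRUE`, its square (the classic
#'   contrastive form).
#' @param pos_fraction Fraction of same-type pairs per minibatch.
#' @param cells_per_type Per-(batch, type) subsample size before pairing.
#' @param seed Master seed for initialization and pair sampling.
#' @param early_stop,es_window,es_patience,es_rel_tol Plateau stopping: stop
#'   when `es_patience` consecutive windows of `es_window` steps fail to
#'   improve the windowed mean total loss by a relative `es_rel_tol`.
#' @return A `SidaConfig` list.
#' @export
sida_config <- function(margin = 1, weights = c(sa = 1, s = 1, c = 1),
                        steps = 1500L, lr = 1e-3, batch_size = 128L,
                        embedding_dim = 32L, g_spec = sida_conv_g(),
                        g_dim = 32L, h_hidden = 64L, sa_squared = FALSE,
                        pos_fraction = 0.5, cells_per_type = 400L,
                        seed = 1L, early_stop = TRUE, es_window = 50L,
                        es_patience = 4L, es_rel_tol = 1e-3) {
  stopifnot(margin > 0, length(weights) == 3, all(weights >= 0),
            any(weights > 0), embedding_dim >= 2, steps >= 1)
  structure(list(margin = margin, weights = unname(weights), steps = steps,
                 lr = lr, batch_size = batch_size,
                 embedding_dim = embedding_dim, g_spec = g_spec,
                 g_dim = g_dim, h_hidden = h_hidden, sa_squared = sa_squared,
                 pos_fraction = pos_fraction, cells_per_type = cells_per_type,
                 seed = as.integer(seed), early_stop = early_stop,
                 es_window = es_window, es_patience = es_patience,
                 es_rel_tol = es_rel_tol),
            class = "SidaConfig")
}

#' Default convolutional feature branch
#' @param channels Channels of the two 1-D convolution layers.
#' @param kernel Kernel width.
#' @return Layer descriptor list for `g` (final linear layer appended at
#'   build time with width `g_dim`).
#' @export
sida_conv_g <- function(channels = c(8L, 8L), kernel = 3L) {
  c(lapply(channels, function(ch)
    list(type = "conv", cout = ch, k = kernel, act = "relu")),
    list(list(type = "dense", n_out = NA_integer_, act = "linear")))
}

#' Plain multilayer-perceptron feature branch
#' @param hidden Hidden layer widths.
#' @return Layer descriptor list for `g`.
#' @export
sida_mlp_g <- function(hidden = c(64L, 64L)) {
  c(lapply(hidden, function(w)
    list(type = "dense", n_out = w, act = "relu")),
    list(list(type = "dense", n_out = NA_integer_, act = "linear")))
}

#' Construct an integrated embedding object
#' @param coordinates Cells x d numeric matrix (finite).
#' @param cell_ids,cell_types,batch_ids Per-row annotations.
#' @return An `Embedding`.
#' @export
Embedding <- function(coordinates, cell_ids, cell_types, batch_ids) {
  coordinates <- as.matrix(coordinates)
  n <- nrow(coordinates)
  if (length(cell_ids) != n || length(cell_types) != n || length(batch_ids) != n)
    stop("annotation lengths must match the number of rows")
  if (n && !all(is.finite(coordinates))) stop("non-finite embedding coordinates")
  structure(list(coordinates = coordinates,
                 cell_ids = as.character(cell_ids),
                 cell_types = as.character(cell_types),
                 batch_ids = as.character(batch_ids)),
            class = "Embedding")
}

#' @export
print.Embedding <- function(x, ...) {
  cat(sprintf("Embedding: %d cells x %d dims, %d batches, %d cell types\n",
              nrow(x$coordinates), ncol(x$coordinates),
              length(unique(x$batch_ids)), length(unique(x$cell_types))))
  invisible(x)
}

#' Concatenated per-batch PCs as an (unintegrated) embedding
#'
#' The no-integration baseline: per-batch PC coordinates stacked directly.
#' Because each batch's PCA basis is its own, batches are generally not
#' aligned in this space.
#'
#' @param pc_view A `PCView`.
#' @return An [Embedding].
#' @export
pc_embedding <- function(pc_view) {
  stopifnot(inherits(pc_view, "PCView"))
  Embedding(do.call(rbind, lapply(pc_view$batches, `[[`, "coords")),
            unlist(lapply(pc_view$batches, `[[`, "cell_ids")),
            unlist(lapply(pc_view$batches, `[[`, "cell_types")),
            rep(vapply(pc_view$batches, `[[`, character(1), "batch_id"),
                vapply(pc_view$batches, function(b) nrow(b$coords), integer(1))))
}

pair_dists <- function(g_s, g_t) sqrt(rowSums((g_s - g_t)^2))

#' Semantic alignment loss
#'
#' Mean over same-type cross-batch pairs of half the Euclidean distance
#' between the two cells' `g` outputs (or half the squared distance when
#' `sa_squared`). Zero iff every positive pair coincides.
#'
#' @param g_s,g_t Matrices of `g` outputs for source and target cells.
#' @param same_type Logical vector marking same-type pairs.
#' @param sa_squared Use squared distance.
#' @return Non-negative scalar; 0 with a warning when no positive pairs.
#' @export
semantic_alignment_loss <- function(g_s, g_t, same_type, sa_squared = FALSE) {
  if (!any(same_type)) {
    warning("no positive pairs; semantic alignment loss is 0")
    return(0)
  }
  d <- pair_dists(g_s[same_type, , drop = FALSE], g_t[same_type, , drop = FALSE])
  if (sa_squared) mean(0.5 * d^2) else mean(0.5 * d)
}

#' Separation loss
#'
#' Mean over different-type pairs of `0.5 * max(0, m - dist)^2`: pairs of
#' different cell types are pushed at least `margin` apart; beyond the
#' margin the hinge (and its gradient) vanishes. Bounded by `margin^2 / 2`.
#'
#' @inheritParams semantic_alignment_loss
#' @param margin Hinge margin `m > 0`.
#' @return Scalar in `[0, margin^2/2]`; 0 with a warning when no negative
#'   pairs.
#' @export
separation_loss <- function(g_s, g_t, same_type, margin = 1) {
  stopifnot(margin > 0)
  neg <- !same_type
  if (!any(neg)) {
    warning("no negative pairs; separation loss is 0")
    return(0)
  }
  d <- pair_dists(g_s[neg, , drop = FALSE], g_t[neg, , drop = FALSE])
  mean(0.5 * pmax(0, margin - d)^2)
}

#' Cross-entropy classification loss
#'
#' Mean cross-entropy of `softmax(logits)` against integer class labels;
#' `log(C)` for uniform logits, 0 in the perfect-classifier limit.
#'
#' @param logits Cells x C matrix of unnormalized class scores.
#' @param y_source Integer labels in `1..C`.
#' @return Non-negative scalar.
#' @export
classification_loss <- function(logits, y_source) {
  logits <- as.matrix(logits)
  C <- ncol(logits)
  if (any(y_source < 1 | y_source > C)) stop("labels outside 1..", C)
  if (C == 1) return(0)
  mx <- apply(logits, 1, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  mean(lse - logits[cbind(seq_along(y_source), y_source)])
}

# --- internal: losses with gradients wrt the g outputs / logits ----------

sa_loss_grad <- function(g_s, g_t, same_type, sa_squared) {
  dgs <- g_s * 0; dgt <- g_t * 0
  pos <- which(same_type)
  if (!length(pos)) return(list(value = 0, dgs = dgs, dgt = dgt))
  diff <- g_s[pos, , drop = FALSE] - g_t[pos, , drop = FALSE]
  d <- sqrt(rowSums(diff^2))
  n <- length(pos)
  if (sa_squared) {
    val <- mean(0.5 * d^2)
    gd <- diff / n
  } else {
    val <- mean(0.5 * d)
    safe <- ifelse(d > 0, d, 1)
    gd <- 0.5 * diff / safe / n
    gd[d == 0, ] <- 0
  }
  dgs[pos, ] <- gd
  dgt[pos, ] <- -gd
  list(value = val, dgs = dgs, dgt = dgt)
}

sep_loss_grad <- function(g_s, g_t, same_type, margin) {
  dgs <- g_s * 0; dgt <- g_t * 0
  neg <- which(!same_type)
  if (!length(neg)) return(list(value = 0, dgs = dgs, dgt = dgt))
  diff <- g_s[neg, , drop = FALSE] - g_t[neg, , drop = FALSE]
  d <- sqrt(rowSums(diff^2))
  n <- length(neg)
  hinge <- pmax(0, margin - d)
  val <- mean(0.5 * hinge^2)
  safe <- ifelse(d > 0, d, 1)
  gd <- -hinge * diff / safe / n     # zero both beyond margin and at d == 0
  gd[d == 0, ] <- 0
  dgs[neg, ] <- gd
  dgt[neg, ] <- -gd
  list(value = val, dgs = dgs, dgt = dgt)
}

ce_loss_grad <- function(logits, y) {
  n <- nrow(logits); C <- ncol(logits)
  mx <- apply(logits, 1, max)
  ex <- exp(logits - mx)
  p <- ex / rowSums(ex)
  val <- mean(-log(pmax(p[cbind(seq_len(n), y)], 1e-300)))
  gr <- p
  gr[cbind(seq_len(n), y)] <- gr[cbind(seq_len(n), y)] - 1
  list(value = val, grad = gr / n)
}

#' Total training objective on one pair batch
#'
#' Weighted sum `w_sa * L_SA + w_s * L_S + w_c * L_C` evaluated with the
#' model's current parameters; components are returned for logging.
#'
#' @param pair_batch A `PairBatch` from [draw_pair_batch()].
#' @param model A `SidaModel`.
#' @param config The `SidaConfig` (weights, margin, `sa_squared`).
#' @return List with `total`, `sa`, `s`, `c`.
#' @export
total_loss <- function(pair_batch, model, config) {
  gs <- nn_forward(model$g, pair_batch$x_source / model$input_scale)$out
  gt <- nn_forward(model$g, pair_batch$x_target / model$input_scale)$out
  logits <- nn_forward(model$h, gs)$out
  sa <- suppressWarnings(
    semantic_alignment_loss(gs, gt, pair_batch$same_type, config$sa_squared))
  s <- suppressWarnings(
    separation_loss(gs, gt, pair_batch$same_type, config$margin))
  ce <- classification_loss(logits, pair_batch$y_source)
  w <- config$weights
  list(total = w[1] * sa + w[2] * s + w[3] * ce, sa = sa, s = s, c = ce)
}

build_model <- function(config, n_pcs, universe, input_scale) {
  g_spec <- config$g_spec
  g_spec[[length(g_spec)]]$n_out <- config$g_dim
  h_spec <- list(list(type = "dense", n_out = config$h_hidden, act = "relu"),
                 list(type = "dense", n_out = config$embedding_dim, act = "relu"),
                 list(type = "dense", n_out = length(universe), act = "linear"))
  structure(list(g = init_layers(g_spec, n_pcs),
                 h = init_layers(h_spec, config$g_dim),
                 config = config, n_pcs = n_pcs,
                 cell_type_universe = universe,
                 input_scale = input_scale, trained = FALSE,
                 log = NULL),
            class = "SidaModel")
}

#' Train the Siamese domain-adaptation network
#'
#' Iterates minibatches of cross-batch cell pairs along the rotated batch
#' schedule, minimizing the classification + contrastive semantic alignment
#' objective with Adam. Both Siamese branches are the same parameter set
#' (`g` is applied to source and target inputs and receives the summed
#' gradients), so weight sharing holds exactly at every step. Training is
#' deterministic given `config$seed`.
#'
#' @param pc_view A (typically subsampled) `PCView`.
#' @param schedule A `PairSchedule` from [make_schedule()].
#' @param config A `SidaConfig`.
#' @return A trained `SidaModel`; `$log` holds the per-step component losses.
#' @export
sida_train <- function(pc_view, schedule, config = sida_config()) {
  stopifnot(inherits(pc_view, "PCView"), inherits(schedule, "PairSchedule"))
  if (length(pc_view$batches) < 2) stop("need at least two batches to integrate")
  input_scale <- sqrt(mean(unlist(lapply(pc_view$batches,
                                         function(b) b$coords^2))))
  if (!is.finite(input_scale) || input_scale == 0) input_scale <- 1
  cycle <- schedule$cycle
  w <- config$weights
  n_log <- config$steps
  log <- data.frame(step = integer(n_log), source = character(n_log),
                    target = character(n_log), sa = numeric(n_log),
                    s = numeric(n_log), c = numeric(n_log),
                    total = numeric(n_log), stringsAsFactors = FALSE)
  model <- NULL
  withr::with_seed(config$seed, {
    model <- build_model(config, pc_view$n_pcs, pc_view$cell_type_universe,
                         input_scale)
    st_g <- adam_init(model$g)
    st_h <- adam_init(model$h)
    win_prev <- Inf; stall <- 0L; done <- 0L
    for (t in seq_len(config$steps)) {
      step <- cycle[(t - 1L) %% nrow(cycle) + 1L, ]
      pb <- draw_pair_batch(pc_view, step, config$batch_size,
                            config$pos_fraction)
      xs <- pb$x_source / input_scale
      xt <- pb$x_target / input_scale
      fs <- nn_forward(model$g, xs)
      ft <- nn_forward(model$g, xt)
      sa <- sa_loss_grad(fs$out, ft$out, pb$same_type, config$sa_squared)
      sp <- sep_loss_grad(fs$out, ft$out, pb$same_type, config$margin)
      fh <- nn_forward(model$h, fs$out)
      ce <- ce_loss_grad(fh$out, pb$y_source)
      total <- w[1] * sa$value + w[2] * sp$value + w[3] * ce$value
      if (!is.finite(total))
        stop("training diverged at step ", t, " (non-finite loss; ",
             "components sa=", sa$value, " s=", sp$value, " c=", ce$value, ")")
      bh <- nn_backward(model$h, fh$caches, w[3] * ce$grad)
      dgs <- w[1] * sa$dgs + w[2] * sp$dgs + bh$dx
      dgt <- w[1] * sa$dgt + w[2] * sp$dgt
      bs <- nn_backward(model$g, fs$caches, dgs)
      bt <- nn_backward(model$g, ft$caches, dgt)
      up_g <- adam_step(model$g, grads_add(bs$grads, bt$grads), st_g,
                        config$lr, t)
      model$g <- up_g$layers; st_g <- up_g$state
      up_h <- adam_step(model$h, bh$grads, st_h, config$lr, t)
      model$h <- up_h$layers; st_h <- up_h$state
      log[t, ] <- list(t, step[1], step[2], sa$value, sp$value, ce$value, total)
      done <- t
      if (config$early_stop && t %% config$es_window == 0 &&
          t >= 2L * nrow(cycle)) {
        win <- mean(log$total[(t - config$es_window + 1L):t])
        if (win > win_prev * (1 - config$es_rel_tol)) stall <- stall + 1L
        else stall <- 0L
        win_prev <- min(win_prev, win)
        if (stall >= config$es_patience) break
      }
    }
    model$log <- log[seq_len(done), , drop = FALSE]
  })
  model$trained <- TRUE
  model
}

#' @export
print.SidaModel <- function(x, ...) {
  cat(sprintf("SidaModel: %s, %d PCs in, embedding dim %d, %d cell types\n",
              if (x$trained) sprintf("trained (%d steps)", nrow(x$log))
              else "untrained",
              x$n_pcs, x$config$embedding_dim, length(x$cell_type_universe)))
  invisible(x)
}

#' Extract the integrated embedding for all cells
#'
#' Every cell of every batch is passed through `g` and then through the two
#' feature layers of `h`; the second feature layer's output is the
#' integrated embedding.
#'
#' @param model A trained `SidaModel`.
#' @param pc_view The `PCView` to embed (any cells in the training PC
#'   dimensionality, typically the full unsubsampled view).
#' @return An [Embedding] with one row per cell, all batches concatenated.
#' @export
sida_embed <- function(model, pc_view) {
  stopifnot(inherits(model, "SidaModel"), inherits(pc_view, "PCView"))
  if (!model$trained) stop("model is not trained")
  if (pc_view$n_pcs != model$n_pcs)
    stop("PC dimensionality ", pc_view$n_pcs,
         " does not match the training dimensionality ", model$n_pcs)
  feat_layers <- model$h[1:2]
  parts <- lapply(pc_view$batches, function(b) {
    g_out <- nn_forward(model$g, b$coords / model$input_scale)$out
    nn_forward(feat_layers, g_out)$out
  })
  Embedding(do.call(rbind, parts),
            unlist(lapply(pc_view$batches, `[[`, "cell_ids")),
            unlist(lapply(pc_view$batches, `[[`, "cell_types")),
            rep(vapply(pc_view$batches, `[[`, character(1), "batch_id"),
                vapply(pc_view$batches, function(b) nrow(b$coords), integer(1))))
}

#' One-call supervised integration of a raw collection
#'
#' Runs the full pipeline: preprocessing (gene intersection, normalization,
#' log transform, per-batch PCA), per-type subsampling, rotated pair
#' schedule, network training, and embedding extraction for all cells.
#'
#' @param collection A raw [DataCollection] with consolidated labels.
#' @param config A `SidaConfig`.
#' @param n_pcs Number of PCs for preprocessing.
#' @return List with `model`, `embedding`, `pc_view` (full view) and
#'   `collection` (preprocessed, gene space).
#' @export
sida_integrate <- function(collection, config = sida_config(), n_pcs = 50) {
  prep <- preprocess_collection(collection, n_pcs = n_pcs)
  sub <- subsample_cells(prep$pc_view, config$cells_per_type, config$seed)
  sched <- make_schedule(names(prep$pc_view$batches), config$seed)
  model <- sida_train(sub, sched, config)
  list(model = model,
       embedding = sida_embed(model, prep$pc_view),
       pc_view = prep$pc_view,
       collection = prep$collection)
}
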