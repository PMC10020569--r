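#' Configuration for the synthetic multi-batch generator
#'
#' The generator emulates the structure integration methods face: several
#' batches over a shared gene set, cell types drawn as well-separated
#' clusters in log-expression space, per-batch technical effects, optional
#' batch-specific cell types, and (optionally) inconsistent annotation
#' vocabularies that require consolidation.
#'
#' Cells of a type are Gaussian around a type mean in log space; type means
#' sit on random orthogonal directions scaled so that the distance between
#' any two type means is `effect_size` within-type standard deviations.
#' The `"shift"` batch effect adds a constant per-batch vector whose
#' per-gene RMS is `batch_magnitude` within-type SDs (exactly invertible);
#' `"affine"` additionally mixes genes with a random near-identity map.
#'
#' @param n_batches Number of batches.
#' @param n_shared_types Cell types present in every batch.
#' @param n_specific_types Cell types present in exactly one batch
#'   (assigned round-robin).
#' @param cells_per_type Cells per (batch, type) combination.
#' @param n_genes Genes.
#' @param effect_size Distance between type means, in within-type SDs.
#' @param batch_effect `"shift"`, `"affine"` or `"none"`.
#' @param batch_magnitude Per-gene RMS of the batch effect, in within-type
#'   SDs.
#' @param count_model `"gaussian-log"` (continuous expression, matching the
#'   post-log pipeline) or `"negative-binomial"` (integer counts).
#' @param dispersion NB dispersion (1/size).
#' @param within_sd Within-type SD per gene in log space.
#' @param label_noise Emit batch-specific spelling variants of the type
#'   labels (the truth record carries the consolidating map).
#' @param seed Master seed.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(n_batches = 3L, n_shared_types = 5L,
                       n_specific_types = 1L, cells_per_type = 200L,
                       n_genes = 500L, effect_size = 30,
                       batch_effect = c("shift", "affine", "none"),
                       batch_magnitude = 2, count_model = c("gaussian-log",
                                                            "negative-binomial"),
                       dispersion = 0.5, within_sd = 0.35,
                       label_noise = FALSE, seed = 1L) {
  batch_effect <- match.arg(batch_effect)
  count_model <- match.arg(count_model)
  stopifnot(n_batches >= 1, n_shared_types + n_specific_types >= 1,
            cells_per_type >= 1, n_genes >= 2, effect_size >= 0,
            batch_magnitude >= 0, within_sd > 0)
  if (n_batches >= 2 && n_shared_types < 1)
    stop("multi-batch collections need at least one shared type")
  n_types <- n_shared_types + n_specific_types
  if (n_types > n_genes)
    stop("more types than genes: orthogonal type directions unavailable")
  structure(list(n_batches = as.integer(n_batches),
                 n_shared_types = as.integer(n_shared_types),
                 n_specific_types = as.integer(n_specific_types),
                 cells_per_type = as.integer(cells_per_type),
                 n_genes = as.integer(n_genes), effect_size = effect_size,
                 batch_effect = batch_effect,
                 batch_magnitude = batch_magnitude,
                 count_model = count_model, dispersion = dispersion,
                 within_sd = within_sd, label_noise = label_noise,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

label_variants <- function(label, n) {
  forms <- c(label, toupper(label), gsub("type", "T-", label, fixed = TRUE))
  forms[(seq_len(n) - 1L) %% length(forms) + 1L]
}

#' Simulate a multi-batch collection with known ground truth
#'
#' @param config A [sim_config()].
#' @return List with `collection` (a raw [DataCollection]) and `truth`
#'   (`label_map`, per-type log-space means, per-batch effects, the config).
#'   Fully reproducible from `config$seed`.
#' @export
simulate_collection <- function(config = sim_config()) {
  stopifnot(inherits(config, "SimConfig"))
  withr::with_seed(config$seed, {
    G <- config$n_genes
    n_types <- config$n_shared_types + config$n_specific_types
    types <- sprintf("type%02d", seq_len(n_types))
    shared <- types[seq_len(config$n_shared_types)]
    specific <- setdiff(types, shared)
    owner <- if (length(specific))
      stats::setNames(((seq_along(specific) - 1L) %% config$n_batches) + 1L,
                      specific) else integer(0)
    mu0 <- stats::runif(G, 2, 4)
    U <- qr.Q(qr(matrix(stats::rnorm(G * n_types), G, n_types)))
    # pairwise distance between means = effect_size * within_sd
    means <- mu0 + U * (config$effect_size * config$within_sd / sqrt(2))
    colnames(means) <- types
    effects <- lapply(seq_len(config$n_batches), function(b) {
      if (config$batch_effect == "none") return(list(shift = numeric(G)))
      z <- stats::rnorm(G)
      shift <- config$batch_magnitude * config$within_sd *
        z / sqrt(mean(z^2))
      if (config$batch_effect == "affine")
        list(shift = shift,
             A = diag(G) + matrix(stats::rnorm(G * G,
                                               sd = 0.1 * config$batch_magnitude /
                                                 sqrt(G)), G, G))
      else list(shift = shift)
    })
    genes <- sprintf("gene%04d", seq_len(G))
    batches <- lapply(seq_len(config$n_batches), function(b) {
      bt <- c(shared, names(owner)[owner == b])
      lab <- rep(bt, each = config$cells_per_type)
      n <- length(lab)
      L <- t(means[, lab, drop = FALSE]) +
        matrix(stats::rnorm(n * G, sd = config$within_sd), n, G)
      ef <- effects[[b]]
      if (!is.null(ef$A)) L <- L %*% t(ef$A)
      L <- sweep(L, 2, ef$shift, `+`)
      expr <- expm1(pmax(L, 0))
      if (config$count_model == "negative-binomial")
        expr <- matrix(stats::rnbinom(n * G, mu = as.vector(expr),
                                      size = 1 / config$dispersion), n, G)
      raw <- if (config$label_noise)
        vapply(lab, function(x) label_variants(x, config$n_batches)[b],
               character(1)) else lab
      ExpressionBatch(expr, genes,
                      sprintf("b%d_cell%05d", b, seq_len(n)),
                      unname(raw), sprintf("batch%d", b))
    })
    label_map <- if (config$label_noise) {
      raw_all <- unique(unlist(lapply(types, label_variants,
                                      n = config$n_batches)))
      base <- vapply(raw_all, function(r) {
        hit <- types[vapply(types, function(tp)
          r %in% label_variants(tp, config$n_batches), logical(1))]
        hit[1]
      }, character(1))
      stats::setNames(base, raw_all)
    } else stats::setNames(types, types)
    list(collection = DataCollection(batches),
         truth = list(label_map = label_map, type_means = means,
                      batch_effects = effects,
                      specific_owner = owner, config = config))
  })
}

#' Ready-made smoke fixtures
#'
#' `"tiny"` (2 batches x 3 shared types x 60 cells x 120 genes) runs the
#' full integrate-and-evaluate pipeline in well under two minutes;
#' `"small"` (3 batches x 6 types, one batch-specific, 200 cells per
#' (batch, type) x 500 genes) is the standard study fixture.
#'
#' @param scale `"tiny"` or `"small"`.
#' @param batch_magnitude Batch-shift strength (per-gene RMS in within-type
#'   SDs); 2 is a strong shift, 0 disables the batch effect.
#' @param seed Master seed.
#' @param label_noise Emit inconsistent label vocabularies.
#' @return List with `collection` and `truth`, as [simulate_collection()].
#' @export
smoke_fixture <- function(scale = c("tiny", "small"), batch_magnitude = 2,
                          seed = 1L, label_noise = FALSE) {
  scale <- match.arg(scale)
  cfg <- if (scale == "tiny")
    sim_config(n_batches = 2L, n_shared_types = 3L, n_specific_types = 0L,
               cells_per_type = 60L, n_genes = 120L,
               batch_effect = if (batch_magnitude > 0) "shift" else "none",
               batch_magnitude = batch_magnitude, label_noise = label_noise,
               seed = seed)
  else
    sim_config(n_batches = 3L, n_shared_types = 5L, n_specific_types = 1L,
               cells_per_type = 200L, n_genes = 500L,
               batch_effect = if (batch_magnitude > 0) "shift" else "none",
               batch_magnitude = batch_magnitude, label_noise = label_noise,
               seed = seed)
  simulate_collection(cfg)
}
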