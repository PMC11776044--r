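#' Train the encoder by semisupervised contrastive learning
#'
#' Each epoch runs two phases. Phase A (self-supervised) iterates multiview
#' batches covering the *entire* image set — controls included — and steps
#' on the replicate-positive contrastive loss, so the representation learns
#' to be invariant to batch (plate) effects between replicates. Phase B
#' (supervised) iterates multiview batches drawn only from images of
#' annotated compounds, labels each entry with the compound's first
#' annotation, and steps on `supervised_weight` times the supervised
#' contrastive loss, pulling same-class treatments together. No classifier
#' is fit here; annotations only define positives. When no compound is
#' annotated, phase B is skipped and training is purely self-supervised.
#'
#' @param records List of image records (all sharing pixel dimensions).
#' @param annotations An [annotation_table()] (may be empty).
#' @param config A [contrastive_config()].
#' @param epochs Number of epochs to run (default `config$max_epochs`).
#' @return List with `model` (the trained `encoder_model`) and `history`
#'   (data frame with one row per epoch: mean phase-A loss `self_loss` and
#'   mean phase-B loss `sup_loss`, `NA` when phase B is skipped).
#' @export
train_semisupervised <- function(records, annotations, config,
                                 epochs = config$max_epochs) {
  stopifnot(length(records) >= 1L, inherits(config, "contrastive_config"))
  validate_image_set(records)
  X <- stack_pixels(records)
  model <- init_encoder(config, dim(X)[2:4])
  cindex <- compound_index(records)
  cid <- compound_ids(records)
  annotated <- annotated_compounds(annotations)
  ann_pos <- which(!is_control(records) & cid %in% annotated)
  N <- config$batch_size
  rng <- local_rng(config$seed + 1L)
  on.exit(rng())
  history <- data.frame(epoch = seq_len(epochs),
                        self_loss = NA_real_, sup_loss = NA_real_)
  for (e in seq_len(epochs)) {
    # ---- phase A: self-supervised over every image ----
    losses <- c()
    for (grp in epoch_anchor_groups(seq_along(records), N)) {
      step <- contrastive_step(model, X, records, cindex, grp,
                               annotations = NULL, weight = 1)
      model <- step$model
      losses <- c(losses, step$loss)
    }
    history$self_loss[e] <- mean(losses)
    # ---- phase B: supervised over the annotated subset ----
    if (length(ann_pos) >= 2L) {
      losses <- c()
      for (grp in epoch_anchor_groups(ann_pos, N)) {
        step <- contrastive_step(model, X, records, cindex, grp,
                                 annotations = annotations,
                                 weight = config$supervised_weight)
        model <- step$model
        losses <- c(losses, step$loss)
      }
      history$sup_loss[e] <- mean(losses)
    }
    model$epochs_trained <- e
  }
  list(model = model, history = history)
}

# One gradient step on a multiview batch built from the given anchors.
# Consumes the caller's RNG stream (positive sampling).
contrastive_step <- function(model, X, records, cindex, anchors,
                             annotations = NULL, weight = 1) {
  bat <- build_multiview_batch(records, cindex, N = length(anchors),
                               seed = sample.int(.Machine$integer.max, 1L),
                               annotations = annotations, anchors = anchors)
  xb <- X[bat$entries, , , , drop = FALSE]
  fw <- encoder_forward(model, xb, keep_cache = TRUE)
  loss <- if (is.null(bat$labels)) {
    self_supervised_loss(fw$Z, bat$pair_index, model$config$temperature)
  } else {
    supervised_contrastive_loss(fw$Z, bat$pair_index, bat$labels,
                                model$config$temperature)
  }
  dZ <- contrastive_loss_grad(fw$Z, bat$pair_index, bat$labels,
                              model$config$temperature)
  grads <- encoder_backward(model, fw$cache, dZ)
  model <- rmsprop_step(model, grads, lr_scale = weight)
  list(model = model, loss = loss)
}

#' Score images and compounds by batchwise self-supervised loss
#'
#' Assigns every image to fixed seeded multiview batches, computes each
#' image's per-anchor self-supervised loss term within its batch, and
#' aggregates replicate scores per compound. A low score marks a treatment
#' whose replicates map to self-consistent latents relative to the rest of
#' the batch — a phenotypically active, reproducible compound.
#'
#' @param model A trained `encoder_model`.
#' @param records List of image records.
#' @param batch_size Anchors per batch (default `config$batch_size`).
#' @param seed Integer seed fixing batch composition.
#' @param aggregate `"min"` (default: score of the most self-consistent
#'   replicate) or `"mean"` over replicates.
#' @return List with `image_scores` (data frame: image_id, compound_id,
#'   loss) and `compound_scores` (data frame: compound_id, score,
#'   n_replicates, sorted ascending by score with lexical tie-break).
#' @export
batchwise_contrastive_loss <- function(model, records,
                                       batch_size = model$config$batch_size,
                                       seed = 1L,
                                       aggregate = c("min", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(model, "encoder_model"))
  if (model$epochs_trained < 1L) {
    stop("model is untrained; run train_semisupervised first")
  }
  validate_image_set(records)
  X <- stack_pixels(records)
  cindex <- compound_index(records)
  rng <- local_rng(seed)
  on.exit(rng())
  loss_of <- rep(NA_real_, length(records))
  for (grp in epoch_anchor_groups(seq_along(records), batch_size)) {
    bat <- build_multiview_batch(records, cindex, N = length(grp),
                                 seed = sample.int(.Machine$integer.max, 1L),
                                 anchors = grp)
    Z <- project(model, X[bat$entries, , , , drop = FALSE])
    terms <- contrastive_terms(Z, bat$pair_index,
                               tau = model$config$temperature)
    anchor_slots <- seq(1L, 2L * bat$N, 2L)
    loss_of[bat$entries[anchor_slots]] <- terms[anchor_slots]
  }
  img <- data.frame(image_id = image_ids(records),
                    compound_id = compound_ids(records),
                    loss = loss_of, stringsAsFactors = FALSE)
  agg_fun <- if (aggregate == "min") min else mean
  sc <- vapply(split(img$loss, img$compound_id), agg_fun, 0)
  cmp <- data.frame(compound_id = names(sc), score = unname(sc),
                    n_replicates = as.vector(table(img$compound_id)[names(sc)]),
                    stringsAsFactors = FALSE)
  cmp <- cmp[order(cmp$score, cmp$compound_id), , drop = FALSE]
  rownames(cmp) <- NULL
  list(image_scores = img, compound_scores = cmp)
}
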