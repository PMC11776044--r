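#' Extract per-image embeddings
#'
#' Runs every image through the trained encoder and projector; the
#' normalized projector output `z` is the representation used for all
#' downstream analysis.
#'
#' @param model A trained `encoder_model`.
#' @param records List of image records.
#' @return An object of class `embedding_matrix`: list with `image_ids`,
#'   `compound_ids` and `features` (M x P, unit-norm rows, input order).
#' @export
extract_embeddings <- function(model, records) {
  if (length(records) == 0L) stop("no images to embed")
  Z <- project(model, records)
  if (anyNA(Z)) stop("NaN in embeddings")
  structure(
    list(image_ids = image_ids(records),
         compound_ids = compound_ids(records),
         features = Z),
    class = "embedding_matrix"
  )
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat(sprintf("<embedding_matrix> %d images x %d dims, %d compounds\n",
              nrow(x$features), ncol(x$features),
              length(unique(x$compound_ids))))
  invisible(x)
}

#' Subset an embedding matrix by row index
#' @param emb An `embedding_matrix`.
#' @param idx Integer or logical row index.
#' @return An `embedding_matrix` over the selected rows.
#' @export
subset_embeddings <- function(emb, idx) {
  structure(
    list(image_ids = emb$image_ids[idx],
         compound_ids = emb$compound_ids[idx],
         features = emb$features[idx, , drop = FALSE]),
    class = "embedding_matrix"
  )
}

#' Write embeddings as a delimited table
#' @param emb An `embedding_matrix`.
#' @param path Output CSV path (columns image_id, compound_id, z1..zP).
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(emb, path) {
  df <- data.frame(image_id = emb$image_ids, compound_id = emb$compound_ids,
                   emb$features, stringsAsFactors = FALSE)
  names(df)[-(1:2)] <- paste0("z", seq_len(ncol(emb$features)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read embeddings written by [write_embeddings()]
#' @param path CSV path.
#' @return An `embedding_matrix`.
#' @export
read_embeddings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(
    list(image_ids = as.character(df$image_id),
         compound_ids = as.character(df$compound_id),
         features = as.matrix(df[, grep("^z\\d+$", names(df)), drop = FALSE])),
    class = "embedding_matrix"
  )
}

# per-image label targets from an annotation table
image_label_sets <- function(emb, annotations) {
  lapply(emb$compound_ids, function(cp) label_set(annotations, cp))
}

#' Train a downstream random forest on embeddings
#'
#' Single-label mode fits one multi-class probability forest on the primary
#' labels; multilabel mode fits one-vs-rest (binary relevance) forests over
#' the class vocabulary. 500 trees and sqrt-mtry by default; fitting and
#' prediction are deterministic given `seed` (single-threaded forests).
#'
#' @param train An `embedding_matrix` of training images; every compound
#'   must be annotated.
#' @param annotations An [annotation_table()].
#' @param task `"single"` or `"multi"`.
#' @param rf_params List overriding `num.trees` (500) and `mtry`
#'   (`floor(sqrt(P))`).
#' @param seed Integer seed.
#' @param threshold Multilabel decision threshold on class probability
#'   (default 0.5).
#' @return An object of class `phenocon_classifier`.
#' @export
train_random_forest <- function(train, annotations,
                                task = c("single", "multi"),
                                rf_params = list(), seed = 1L,
                                threshold = 0.5) {
  task <- match.arg(task)
  x <- as.data.frame(train$features)
  names(x) <- paste0("z", seq_len(ncol(x)))
  num_trees <- rf_params$num.trees %||% 500L
  mtry <- rf_params$mtry %||% max(1L, floor(sqrt(ncol(x))))
  sets <- image_label_sets(train, annotations)
  if (any(lengths(sets) == 0L)) {
    stop("every training image's compound must be annotated")
  }
  if (task == "single") {
    y <- vapply(sets, `[[`, "", 1L)
    classes <- sort(unique(y))
    fit <- ranger::ranger(x = x, y = factor(y, levels = classes),
                          probability = TRUE, num.trees = num_trees,
                          mtry = min(mtry, ncol(x)), seed = seed,
                          num.threads = 1L)
    fits <- list(fit)
  } else {
    vocab <- sort(unique(unlist(sets)))
    keep <- vapply(vocab, function(cl) {
      any(vapply(sets, function(s) cl %in% s, TRUE))
    }, TRUE)
    if (any(!keep)) {
      warning("dropping classes with no training example: ",
              paste(vocab[!keep], collapse = ", "))
    }
    classes <- vocab[keep]
    fits <- lapply(seq_along(classes), function(k) {
      pos <- vapply(sets, function(s) classes[k] %in% s, TRUE)
      if (all(pos) || all(!pos)) {
        return(list(constant = mean(pos)))  # degenerate one-level class
      }
      ranger::ranger(x = x, y = factor(ifelse(pos, "yes", "no"),
                                       levels = c("no", "yes")),
                     probability = TRUE, num.trees = num_trees,
                     mtry = min(mtry, ncol(x)), seed = seed + k,
                     num.threads = 1L)
    })
  }
  structure(list(type = "rf", task = task, classes = classes, fits = fits,
                 threshold = threshold),
            class = "phenocon_classifier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-class scores from a downstream classifier
#'
#' @param classifier A `phenocon_classifier`.
#' @param emb An `embedding_matrix` (or bare feature matrix).
#' @return Numeric n x K matrix of class scores (probabilities), columns
#'   named by class.
#' @export
predict_scores <- function(classifier, emb) {
  feats <- if (inherits(emb, "embedding_matrix")) emb$features else emb
  x <- as.data.frame(feats)
  names(x) <- paste0("z", seq_len(ncol(x)))
  cl <- classifier$classes
  if (classifier$type == "rf" && classifier$task == "single") {
    pr <- stats::predict(classifier$fits[[1L]], data = x)$predictions
    scores <- pr[, cl, drop = FALSE]
  } else if (classifier$type == "rf") {
    scores <- vapply(seq_along(cl), function(k) {
      f <- classifier$fits[[k]]
      if (!is.null(f$constant)) {
        rep(f$constant, nrow(x))
      } else {
        stats::predict(f, data = x)$predictions[, "yes"]
      }
    }, numeric(nrow(x)))
    if (nrow(x) == 1L) scores <- matrix(scores, 1L)
    colnames(scores) <- cl
  } else {
    scores <- mlp_forward_scores(classifier$net, feats)
    colnames(scores) <- cl
  }
  as.matrix(scores)
}

#' Predicted label sets from a downstream classifier
#'
#' Single-label mode returns the arg-max class (lexically first on ties);
#' multilabel mode thresholds each class score at `classifier$threshold`.
#'
#' @inheritParams predict_scores
#' @return List of character vectors, one per image.
#' @export
predict_label_sets <- function(classifier, emb) {
  scores <- predict_scores(classifier, emb)
  cl <- colnames(scores)
  if (classifier$task == "single") {
    lapply(seq_len(nrow(scores)), function(i) {
      cl[which.max(scores[i, ])]  # ties: first = lexically smallest
    })
  } else {
    lapply(seq_len(nrow(scores)), function(i) {
      cl[scores[i, ] >= classifier$threshold]
    })
  }
}

#' Train the downstream multilayer-perceptron head (multilabel)
#'
#' A 3-layer head (512 and 256 hidden units by default) with ReLU on the
#' input and hidden layers, 50% dropout on the first two layers, per-class
#' sigmoid outputs with binary cross-entropy, RMSprop at learning rate
#' `10^-2.5`, and early stopping on a held-out validation slice of the
#' training images (10%, patience 10 epochs; the best-validation weights
#' are restored).
#'
#' @param train An `embedding_matrix` of training images (annotated
#'   compounds only).
#' @param annotations An [annotation_table()].
#' @param mlp_params List overriding `hidden` (c(512, 256)), `dropout`
#'   (0.5), `learning_rate` (`10^-2.5`), `max_epochs` (200), `patience`
#'   (10), `val_fraction` (0.1), `batch_size` (32).
#' @param seed Integer seed (initialization, dropout, validation split).
#' @param threshold Decision threshold on the sigmoid outputs.
#' @return A `phenocon_classifier` with `type = "mlp"`, `task = "multi"`.
#' @export
train_mlp <- function(train, annotations, mlp_params = list(), seed = 1L,
                      threshold = 0.5) {
  p <- list(hidden = c(512L, 256L), dropout = 0.5,
            learning_rate = 10^-2.5, max_epochs = 200L, patience = 10L,
            val_fraction = 0.1, batch_size = 32L)
  p[names(mlp_params)] <- mlp_params
  sets <- image_label_sets(train, annotations)
  if (any(lengths(sets) == 0L)) {
    stop("every training image's compound must be annotated")
  }
  classes <- sort(unique(unlist(sets)))
  if (length(classes) < 2L) stop("need at least 2 classes to train the MLP")
  Y <- vapply(classes, function(cl) {
    vapply(sets, function(s) as.numeric(cl %in% s), 0)
  }, numeric(length(sets)))
  X <- train$features
  rng <- local_rng(seed)
  on.exit(rng())
  n <- nrow(X)
  n_val <- max(1L, round(p$val_fraction * n))
  if (n - n_val < 1L) stop("validation slice leaves no training images")
  val <- sample.int(n, n_val)
  tr <- setdiff(seq_len(n), val)
  net <- mlp_init(ncol(X), p$hidden, length(classes))
  best <- list(loss = Inf, net = net, epoch = 0L)
  state <- lapply(net, function(w) w * 0)
  for (e in seq_len(p$max_epochs)) {
    for (grp in epoch_anchor_groups(tr, p$batch_size)) {
      gr <- mlp_grad(net, X[grp, , drop = FALSE], Y[grp, , drop = FALSE],
                     dropout = p$dropout)
      for (nm in names(gr)) {
        state[[nm]] <- 0.9 * state[[nm]] + 0.1 * gr[[nm]]^2
        net[[nm]] <- net[[nm]] - p$learning_rate * gr[[nm]] /
          sqrt(state[[nm]] + 1e-8)
      }
    }
    vl <- mlp_bce(mlp_forward_scores(net, X[val, , drop = FALSE]),
                  Y[val, , drop = FALSE])
    if (vl < best$loss - 1e-6) {
      best <- list(loss = vl, net = net, epoch = e)
    } else if (e - best$epoch >= p$patience) {
      break
    }
  }
  structure(list(type = "mlp", task = "multi", classes = classes,
                 net = best$net, threshold = threshold,
                 epochs_run = best$epoch),
            class = "phenocon_classifier")
}

mlp_init <- function(nin, hidden, nout) {
  dims <- c(nin, hidden, nout)
  net <- list()
  for (l in seq_len(length(dims) - 1L)) {
    net[[paste0("W", l)]] <- he_init(dims[l], dims[l + 1L])
    net[[paste0("b", l)]] <- numeric(dims[l + 1L])
  }
  net
}

# deterministic forward (no dropout): sigmoid class scores
mlp_forward_scores <- function(net, X) {
  nl <- length(net) / 2L
  a <- as.matrix(X)
  for (l in seq_len(nl - 1L)) {
    a <- sweep(a %*% net[[paste0("W", l)]], 2, net[[paste0("b", l)]], "+")
    a <- a * (a > 0)
  }
  o <- sweep(a %*% net[[paste0("W", nl)]], 2, net[[paste0("b", nl)]], "+")
  1 / (1 + exp(-o))
}

mlp_bce <- function(scores, Y) {
  eps <- 1e-12
  -mean(Y * log(scores + eps) + (1 - Y) * log(1 - scores + eps))
}

# gradient of mean BCE with inverted dropout on the two hidden activations
mlp_grad <- function(net, X, Y, dropout = 0.5) {
  nl <- length(net) / 2L
  a <- as.matrix(X)
  acts <- list(a)
  masks <- list()
  for (l in seq_len(nl - 1L)) {
    a <- sweep(a %*% net[[paste0("W", l)]], 2, net[[paste0("b", l)]], "+")
    a <- a * (a > 0)
    m <- matrix(stats::runif(length(a)) >= dropout, nrow(a), ncol(a)) /
      (1 - dropout)
    a <- a * m
    masks[[l]] <- m
    acts[[l + 1L]] <- a
  }
  o <- sweep(a %*% net[[paste0("W", nl)]], 2, net[[paste0("b", nl)]], "+")
  s <- 1 / (1 + exp(-o))
  d <- (s - Y) / length(Y)          # d mean-BCE / d logits
  grads <- list()
  for (l in nl:1) {
    grads[[paste0("W", l)]] <- crossprod(acts[[l]], d)
    grads[[paste0("b", l)]] <- colSums(d)
    if (l > 1L) {
      d <- (d %*% t(net[[paste0("W", l)]])) * masks[[l - 1L]] *
        (acts[[l]] > 0)
    }
  }
  grads
}

#' Grouped cross-validation of a downstream classifier
#'
#' For every fold of the plan: fit the classifier on the images of
#' out-of-fold annotated compounds and predict every image of in-fold
#' compounds, keeping per-image predictions (no premature aggregation).
#' Train and test compound sets are asserted disjoint on every fold. The
#' procedure is identical whatever model produced the embeddings.
#'
#' @param embeddings An `embedding_matrix` over all images.
#' @param annotations An [annotation_table()].
#' @param plan A `split_plan` covering the annotated compounds.
#' @param model_spec List: `type` ("rf" or "mlp"), `task` ("single" or
#'   "multi"), optional `params` passed to the trainer, optional `seed`
#'   (default 1), optional `threshold`.
#' @return List of `prediction_set` objects, one per fold, each holding
#'   image ids, per-class scores, predicted and true label sets.
#' @export
cross_validate <- function(embeddings, annotations, plan, model_spec) {
  stopifnot(inherits(embeddings, "embedding_matrix"),
            inherits(plan, "split_plan"))
  type <- model_spec$type %||% "rf"
  task <- model_spec$task %||% "single"
  seed <- model_spec$seed %||% 1L
  fold_of <- plan$assignments[embeddings$compound_ids]  # NA if unannotated
  out <- vector("list", plan$fold_count)
  for (f in seq_len(plan$fold_count)) {
    tr_idx <- which(!is.na(fold_of) & fold_of != f)
    te_idx <- which(!is.na(fold_of) & fold_of == f)
    if (length(te_idx) == 0L) stop(sprintf("fold %d has an empty test set", f))
    tr_cp <- unique(embeddings$compound_ids[tr_idx])
    te_cp <- unique(embeddings$compound_ids[te_idx])
    if (length(intersect(tr_cp, te_cp))) {
      stop("train/test compound leakage detected")  # defensive; cannot occur
    }
    tr_emb <- subset_embeddings(embeddings, tr_idx)
    te_emb <- subset_embeddings(embeddings, te_idx)
    clf <- if (type == "rf") {
      train_random_forest(tr_emb, annotations, task = task,
                          rf_params = model_spec$params %||% list(),
                          seed = seed + f,
                          threshold = model_spec$threshold %||% 0.5)
    } else {
      train_mlp(tr_emb, annotations, mlp_params = model_spec$params %||% list(),
                seed = seed + f, threshold = model_spec$threshold %||% 0.5)
    }
    scores <- predict_scores(clf, te_emb)
    truth <- image_label_sets(te_emb, annotations)
    if (task == "single") truth <- lapply(truth, `[`, 1L)
    out[[f]] <- structure(
      list(image_ids = te_emb$image_ids, compound_ids = te_emb$compound_ids,
           fold = f, task = task, classes = colnames(scores),
           scores = scores,
           predicted = predict_label_sets(clf, te_emb),
           truth = truth),
      class = "prediction_set"
    )
  }
  out
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("<prediction_set fold %d> %d images, %d classes, task %s\n",
              x$fold, length(x$image_ids), length(x$classes), x$task))
  invisible(x)
}

#' Aggregate replicate predictions of one compound
#'
#' Predicts a single class per replicate embedding, tallies the classes and
#' returns the `top_k` most frequent (count ties broken lexically) — the
#' replicate-vote readout used to annotate unlabeled compounds.
#'
#' @param classifier A single-label `phenocon_classifier`.
#' @param emb An `embedding_matrix` holding one compound's replicates.
#' @param top_k Number of classes to report (default 3).
#' @return Data frame with columns `class` and `count`, at most `top_k`
#'   rows, ordered by decreasing count.
#' @export
predict_compound_classes <- function(classifier, emb, top_k = 3L) {
  stopifnot(classifier$task == "single")
  feats <- if (inherits(emb, "embedding_matrix")) emb$features else emb
  if (nrow(feats) == 0L) stop("need at least one replicate embedding")
  preds <- unlist(predict_label_sets(classifier, feats))
  tab <- table(preds)
  df <- data.frame(class = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$class), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, top_k)
}
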