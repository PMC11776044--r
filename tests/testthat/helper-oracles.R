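# Independent oracles and small fixture builders shared across tests.
# The loss oracles are deliberate double/triple loops over the definitions —
# they never share code with the vectorized implementations they check.

naive_self_loss <- function(Z, pair, tau) {
  n <- nrow(Z)
  total <- 0
  for (i in seq_len(n)) {
    den <- 0
    for (a in setdiff(seq_len(n), i)) {
      den <- den + exp(sum(Z[i, ] * Z[a, ]) / tau)
    }
    num <- exp(sum(Z[i, ] * Z[pair[i], ]) / tau)
    total <- total - log(num / den)
  }
  total / n
}

naive_sup_loss <- function(Z, pair, labels, tau) {
  n <- nrow(Z)
  total <- 0
  for (i in seq_len(n)) {
    P <- setdiff(which(labels == labels[i]), i)
    den <- 0
    for (a in setdiff(seq_len(n), i)) {
      den <- den + exp(sum(Z[i, ] * Z[a, ]) / tau)
    }
    acc <- 0
    for (p in P) {
      acc <- acc - log(exp(sum(Z[i, ] * Z[p, ]) / tau) / den)
    }
    total <- total + acc / length(P)
  }
  total / n
}

# brute-force average precision from the PR staircase at every distinct
# score threshold (decreasing)
naive_average_precision <- function(scores, positive) {
  if (sum(positive) == 0) return(NA_real_)
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0
  ap <- 0
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(sel & positive)
    prec <- tp / sum(sel)
    rec <- tp / sum(positive)
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

# build a synthetic prediction_set with random scores/label sets
random_prediction_set <- function(n_images, classes, task = "single",
                                  fold = 1L, seed = 1L) {
  set.seed(seed)
  scores <- matrix(runif(n_images * length(classes)), n_images,
                   dimnames = list(NULL, classes))
  if (task == "single") {
    predicted <- lapply(seq_len(n_images), function(i) {
      classes[which.max(scores[i, ])]
    })
    truth <- lapply(seq_len(n_images), function(i) sample(classes, 1))
  } else {
    predicted <- lapply(seq_len(n_images), function(i) {
      classes[scores[i, ] >= 0.5]
    })
    truth <- lapply(seq_len(n_images), function(i) {
      sample(classes, sample.int(length(classes), 1))
    })
  }
  structure(
    list(image_ids = sprintf("img%03d", seq_len(n_images)),
         compound_ids = sprintf("CPD%03d", seq_len(n_images)),
         fold = fold, task = task, classes = classes,
         scores = scores, predicted = predicted, truth = truth),
    class = "prediction_set"
  )
}

# well-separated unit-norm embeddings clustered by class, with matching
# annotations; used to test downstream heads without any encoder training
make_separable_embeddings <- function(n_classes = 2L, n_compounds_per = 4L,
                                      n_reps = 3L, dim = 8L, spread = 0.05,
                                      seed = 1L, extra_labels = FALSE) {
  set.seed(seed)
  centers <- diag(1, n_classes, dim)          # orthogonal class centers
  ids <- character(0); cids <- character(0)
  rows <- NULL
  labs <- list()
  for (k in seq_len(n_classes)) {
    for (cpd in seq_len(n_compounds_per)) {
      cid <- sprintf("C%02d_%02d", k, cpd)
      labs[[cid]] <- if (extra_labels && cpd == 1L) {
        c(sprintf("class_%02d", k), sprintf("class_%02d", (k %% n_classes) + 1))
      } else {
        sprintf("class_%02d", k)
      }
      for (r in seq_len(n_reps)) {
        v <- centers[k, ] + rnorm(dim, 0, spread)
        rows <- rbind(rows, v / sqrt(sum(v^2)))
        ids <- c(ids, sprintf("%s_r%d", cid, r))
        cids <- c(cids, cid)
      }
    }
  }
  list(
    emb = structure(list(image_ids = ids, compound_ids = cids,
                         features = rows),
                    class = "embedding_matrix"),
    annotations = annotation_table(labs, "custom")
  )
}

# small synthetic image set for pipeline tests (divisible by 16 for the CNN)
tiny_dataset <- function(seed = 1L, n_classes = 4L, n_compounds = 12L,
                         reps = 3L, hw = c(32L, 32L), n_controls = 4L,
                         annotation_fraction = 0.75, ...) {
  generate_dataset(synth_spec(
    n_classes = n_classes, n_compounds = n_compounds,
    replicates_per_compound = reps, image_hw = hw,
    n_controls = n_controls, annotation_fraction = annotation_fraction,
    seed = seed, ...
  ))
}

tiny_config <- function(seed = 1L, epochs = 3L, ...) {
  contrastive_config(projector_dim = 16L, batch_size = 12L,
                     max_epochs = epochs, n_filters = c(8L, 12L, 16L),
                     projector_hidden = 24L, seed = seed, ...)
}
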