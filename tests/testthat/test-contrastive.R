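test_that("losses match their analytic limits", {
  fx <- generate_embedding_fixture(1L, 6L, seed = 1L)
  expect_identical(self_supervised_loss(fx$Z, fx$pair_index), 0)

  fid <- generate_embedding_fixture(2L, 6L, list(identical = TRUE,
                                                 n_classes = 1L), seed = 2L)
  expect_equal(self_supervised_loss(fid$Z, fid$pair_index), log(3),
               tolerance = 1e-9)
  expect_equal(supervised_contrastive_loss(fid$Z, fid$pair_index,
                                           fid$labels), log(3),
               tolerance = 1e-9)
  fid4 <- generate_embedding_fixture(4L, 6L, list(identical = TRUE), seed = 3L)
  expect_equal(self_supervised_loss(fid4$Z, fid4$pair_index), log(7),
               tolerance = 1e-9)
})

test_that("vectorized losses agree with brute-force loops", {
  worst <- 0
  for (i in 1:40) {
    N <- sample(2:6, 1)
    fx <- generate_embedding_fixture(N, sample(3:8, 1),
                                     list(n_classes = sample(1:3, 1)),
                                     seed = 400L + i)
    v <- self_supervised_loss(fx$Z, fx$pair_index, 0.07)
    s <- supervised_contrastive_loss(fx$Z, fx$pair_index, fx$labels, 0.07)
    expect_gte(v, 0); expect_gte(s, 0)
    worst <- max(worst,
                 abs(v - naive_self_loss(fx$Z, fx$pair_index, 0.07)) /
                   max(v, 1e-3),
                 abs(s - naive_sup_loss(fx$Z, fx$pair_index, fx$labels,
                                        0.07)) / max(s, 1e-3))
  }
  expect_lt(worst, 1e-6)
})

test_that("supervised loss reduces to the self-supervised loss for distinct labels", {
  for (i in 1:25) {
    N <- sample(2:6, 1)
    fx <- generate_embedding_fixture(N, 6L, seed = 500L + i)
    labels <- rep(sprintf("solo_%02d", seq_len(N)), each = 2)
    expect_equal(
      supervised_contrastive_loss(fx$Z, fx$pair_index, labels, 0.07),
      self_supervised_loss(fx$Z, fx$pair_index, 0.07),
      tolerance = 1e-12
    )
  }
})

test_that("losses are invariant to batch permutation", {
  fx <- generate_embedding_fixture(5L, 6L, list(n_classes = 2L), seed = 7L)
  base_self <- self_supervised_loss(fx$Z, fx$pair_index)
  base_sup <- supervised_contrastive_loss(fx$Z, fx$pair_index, fx$labels)
  for (i in 1:10) {
    set.seed(i)
    perm <- sample(10)
    inv <- order(perm)
    Zp <- fx$Z[perm, ]
    pairp <- inv[fx$pair_index[perm]]
    labp <- fx$labels[perm]
    expect_equal(self_supervised_loss(Zp, pairp), base_self,
                 tolerance = 1e-9)
    expect_equal(supervised_contrastive_loss(Zp, pairp, labp), base_sup,
                 tolerance = 1e-9)
  }
})

test_that("loss contracts reject malformed input", {
  fx <- generate_embedding_fixture(3L, 5L, list(n_classes = 2L), seed = 8L)
  expect_error(self_supervised_loss(fx$Z * 2, fx$pair_index), "unit-norm")
  Zna <- fx$Z; Zna[2, 3] <- NaN
  expect_error(self_supervised_loss(Zna, fx$pair_index), "non-finite")
  expect_error(self_supervised_loss(fx$Z, seq_len(6)), "involution")
  expect_error(supervised_contrastive_loss(fx$Z, fx$pair_index, NULL),
               "label")
  expect_error(supervised_contrastive_loss(fx$Z, fx$pair_index,
                                           c(fx$labels[-1], NA)), "label")
  expect_error(self_supervised_loss(fx$Z, fx$pair_index, tau = 0),
               "temperature")
})

test_that("analytic loss gradients match finite differences", {
  for (use_labels in c(FALSE, TRUE)) {
    fx <- generate_embedding_fixture(4L, 5L,
                                     if (use_labels) list(n_classes = 2L),
                                     seed = 17L)
    raw_loss <- function(Z) {
      S <- tcrossprod(Z) / 0.07
      diag(S) <- -Inf
      m <- apply(S, 1, max)
      lse <- m + log(rowSums(exp(S - m)))
      if (!use_labels) {
        mean(lse - S[cbind(1:8, fx$pair_index)])
      } else {
        pos <- outer(fx$labels, fx$labels, "==")
        diag(pos) <- FALSE
        mean(lse - rowSums(ifelse(pos, S, 0)) / rowSums(pos))
      }
    }
    G <- phenocon:::contrastive_loss_grad(fx$Z, fx$pair_index,
                                          if (use_labels) fx$labels,
                                          0.07)
    eps <- 1e-6
    worst <- 0
    for (i in 1:8) for (j in 1:5) {
      Zp <- fx$Z; Zp[i, j] <- Zp[i, j] + eps
      Zm <- fx$Z; Zm[i, j] <- Zm[i, j] - eps
      fd <- (raw_loss(Zp) - raw_loss(Zm)) / (2 * eps)
      worst <- max(worst, abs(fd - G[i, j]) / max(abs(fd), 1e-8))
    }
    expect_lt(worst, 1e-4)
  }
})

test_that("multiview batches pair anchors with same-compound replicates", {
  ds <- tiny_dataset(seed = 31, n_compounds = 6L, reps = 3L, n_controls = 0L,
                     hw = c(16L, 16L))
  cid <- compound_ids(ds$records)
  bat <- build_multiview_batch(ds$records, N = 3L, seed = 4L)
  expect_length(bat$entries, 6L)
  expect_identical(bat$pair_index[bat$pair_index], 1:6)
  expect_true(all(bat$pair_index != 1:6))
  # paired slots hold same-compound images, anchor != positive image
  for (k in 1:3) {
    a <- bat$entries[2 * k - 1]; p <- bat$entries[2 * k]
    expect_identical(cid[a], cid[p])
    expect_false(a == p)  # all compounds here have >= 2 images
  }
  expect_identical(build_multiview_batch(ds$records, N = 3L, seed = 4L), bat)
  expect_error(build_multiview_batch(ds$records, N = 0L), "N")
})

test_that("single-image compounds self-pair", {
  recs <- lapply(1:3, function(i) {
    image_record(sprintf("img%d", i), sprintf("cpd%d", i), "p1", "A01", i,
                 array(runif(64), c(8, 8, 1)))
  })
  bat <- build_multiview_batch(recs, N = 3L, seed = 1L)
  for (k in 1:3) {
    expect_identical(bat$entries[2 * k - 1], bat$entries[2 * k])
  }
  expect_true(all(bat$pair_index != 1:6))  # slot pairing stays fixed-point-free
})

test_that("training records per-epoch losses and makes progress", {
  ds <- tiny_dataset(seed = 41)
  fit <- train_semisupervised(ds$records, ds$annotations,
                              tiny_config(seed = 41, epochs = 4L))
  expect_identical(nrow(fit$history), 4L)
  expect_true(all(is.finite(fit$history$self_loss)))
  expect_true(all(is.finite(fit$history$sup_loss)))
  expect_identical(fit$model$epochs_trained, 4L)
  expect_lt(fit$history$self_loss[4], fit$history$self_loss[1])
})

test_that("with no annotations training equals pure self-supervision", {
  ds <- tiny_dataset(seed = 42, annotation_fraction = 0)
  expect_length(annotated_compounds(ds$annotations), 0L)
  cfg <- tiny_config(seed = 42, epochs = 2L)
  fit1 <- train_semisupervised(ds$records, ds$annotations, cfg)
  fit2 <- train_semisupervised(ds$records, annotation_table(list(), "custom"),
                               cfg)
  expect_identical(fit1$model$params, fit2$model$params)
  expect_true(all(is.na(fit1$history$sup_loss)))
})

test_that("projection honors the configured dimension and normalization", {
  ds <- tiny_dataset(seed = 43, n_compounds = 4L, reps = 2L, n_controls = 0L)
  cfg <- tiny_config(seed = 43)
  model <- init_encoder(cfg, c(32L, 32L, 3L))
  Z <- project(model, ds$records)
  expect_identical(dim(Z), c(8L, 16L))
  expect_true(all(abs(sqrt(rowSums(Z^2)) - 1) < 1e-6))
  # duplicate images map to identical rows
  Z2 <- project(model, ds$records[c(1, 1, 2)])
  expect_identical(Z2[1, ], Z2[2, ])
  expect_error(project(model, array(0, c(2, 16, 16, 3))), "expects")

  cfg224 <- contrastive_config()
  expect_identical(cfg224$projector_dim, 224L)
  expect_identical(cfg224$temperature, 0.07)
  expect_identical(cfg224$batch_size, 40L)
  expect_equal(cfg224$learning_rate, 10^-2.5)
})

test_that("batchwise scoring is deterministic with ordered aggregates", {
  ds <- tiny_dataset(seed = 44, n_compounds = 8L, reps = 3L, n_controls = 0L)
  cfg <- tiny_config(seed = 44, epochs = 2L)
  fit <- train_semisupervised(ds$records, ds$annotations, cfg)
  expect_error(
    batchwise_contrastive_loss(init_encoder(cfg, c(32L, 32L, 3L)),
                               ds$records),
    "untrained"
  )
  bw1 <- batchwise_contrastive_loss(fit$model, ds$records, batch_size = 8L,
                                    seed = 7L, aggregate = "min")
  bw2 <- batchwise_contrastive_loss(fit$model, ds$records, batch_size = 8L,
                                    seed = 7L, aggregate = "min")
  expect_identical(bw1, bw2)
  expect_true(all(diff(bw1$compound_scores$score) >= 0 |
                    diff(bw1$compound_scores$score) == 0))
  bwm <- batchwise_contrastive_loss(fit$model, ds$records, batch_size = 8L,
                                    seed = 7L, aggregate = "mean")
  # min aggregate never exceeds mean aggregate, compound by compound
  m1 <- stats::setNames(bw1$compound_scores$score,
                        bw1$compound_scores$compound_id)
  m2 <- stats::setNames(bwm$compound_scores$score,
                        bwm$compound_scores$compound_id)
  expect_true(all(m1[names(m2)] <= m2 + 1e-12))
})

test_that("per-anchor scoring identifies self-consistent latent geometry", {
  # constructed latents: compound A's replicates identical, the rest mutually
  # near-orthogonal -> A's anchors take the lowest per-anchor loss terms
  dim <- 12L
  Z <- diag(1, 8, dim)
  Z[2, ] <- Z[1, ]                       # entries 1,2 = compound A pair
  pair <- as.integer(rbind(seq(2, 8, 2), seq(1, 8, 2)))
  terms <- phenocon:::contrastive_terms(Z, pair, tau = 0.07)
  expect_identical(which.min(terms[c(1, 3, 5, 7)]), 1L)
  expect_lt(terms[1], min(terms[c(3, 5, 7)]) - 1)
})
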