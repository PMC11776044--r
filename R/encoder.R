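#' Configuration for contrastive representation learning
#'
#' Bundles the loss, optimizer and architecture settings. Defaults follow
#' the reference training setup: temperature 0.07, learning rate
#' `10^-2.5`, projector output dimension 224, batch size 40 anchor images,
#' up to 250 epochs, and equal weighting of the supervised phase.
#'
#' @param temperature Softmax temperature tau, `> 0`.
#' @param learning_rate Optimizer step size (RMSprop, momentum-free).
#' @param projector_dim Width P of the projector output `z`.
#' @param batch_size Number N of anchor images per multiview batch (the
#'   batch holds 2N images).
#' @param max_epochs Upper bound on training epochs.
#' @param supervised_weight Multiplier on the supervised-phase gradient.
#' @param seed Integer seed governing initialization and batch sampling.
#' @param backbone_name Encoder family; `"small_cnn"` is the built-in
#'   compact patch-convolution CNN.
#' @param patch_sizes Integer vector of per-layer patch (= stride) sizes;
#'   image height/width must be divisible by their product.
#' @param n_filters Integer vector of per-layer output channels (same length
#'   as `patch_sizes`).
#' @param projector_hidden Width of the projector's hidden layer.
#' @param rmsprop_rho,rmsprop_eps RMSprop decay and stabilizer.
#' @return An object of class `contrastive_config`.
#' @export
contrastive_config <- function(temperature = 0.07,
                               learning_rate = 10^-2.5,
                               projector_dim = 224L,
                               batch_size = 40L,
                               max_epochs = 250L,
                               supervised_weight = 1.0,
                               seed = 1L,
                               backbone_name = "small_cnn",
                               patch_sizes = c(4L, 2L, 2L),
                               n_filters = c(16L, 32L, 64L),
                               projector_hidden = 64L,
                               rmsprop_rho = 0.9,
                               rmsprop_eps = 1e-8) {
  stopifnot(temperature > 0, batch_size >= 1L, projector_dim >= 2L,
            length(patch_sizes) == length(n_filters),
            backbone_name == "small_cnn")
  structure(
    list(temperature = temperature, learning_rate = learning_rate,
         projector_dim = as.integer(projector_dim),
         batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs),
         supervised_weight = supervised_weight, seed = as.integer(seed),
         backbone_name = backbone_name,
         patch_sizes = as.integer(patch_sizes),
         n_filters = as.integer(n_filters),
         projector_hidden = as.integer(projector_hidden),
         rmsprop_rho = rmsprop_rho, rmsprop_eps = rmsprop_eps),
    class = "contrastive_config"
  )
}

# ---- non-overlapping patch extraction (stride = kernel) ------------------

# x: (B, H, W, C) -> matrix (B*Hk*Wk, k*k*C); rows index (b, hk, wk),
# b fastest. Exactly invertible, which keeps the backward pass a reshape.
patchify <- function(x, k) {
  d <- dim(x)
  B <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  Hk <- H %/% k; Wk <- W %/% k
  stopifnot(Hk * k == H, Wk * k == W)
  dim(x) <- c(B, k, Hk, k, Wk, C)
  x <- aperm(x, c(1, 3, 5, 2, 4, 6))
  dim(x) <- c(B * Hk * Wk, k * k * C)
  attr(x, "grid") <- c(B, Hk, Wk, k, C)
  x
}

unpatchify <- function(mat, grid) {
  B <- grid[1]; Hk <- grid[2]; Wk <- grid[3]; k <- grid[4]; C <- grid[5]
  dim(mat) <- c(B, Hk, Wk, k, k, C)
  mat <- aperm(mat, c(1, 4, 2, 5, 3, 6))
  dim(mat) <- c(B, Hk * k, Wk * k, C)
  mat
}

he_init <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}

#' Initialize an encoder + projector model
#'
#' Builds the compact patch-convolution CNN: a stack of non-overlapping
#' patch convolutions with ReLU, a global average pool, and a two-layer MLP
#' projector whose output is L2-normalized. Weights are He-initialized,
#' deterministically from `config$seed`.
#'
#' @param config A [contrastive_config()].
#' @param input_dim Integer triple `(H, W, C)` of the images the model will
#'   see; H and W must be divisible by `prod(config$patch_sizes)`.
#' @return An object of class `encoder_model` (untrained).
#' @export
init_encoder <- function(config, input_dim) {
  stopifnot(inherits(config, "contrastive_config"), length(input_dim) == 3L)
  input_dim <- as.integer(input_dim)
  red <- prod(config$patch_sizes)
  if (input_dim[1] %% red != 0 || input_dim[2] %% red != 0) {
    stop(sprintf("image height/width must be divisible by %d", red))
  }
  rng <- local_rng(config$seed)
  on.exit(rng())
  params <- list()
  cin <- input_dim[3]
  for (l in seq_along(config$patch_sizes)) {
    k <- config$patch_sizes[l]; f <- config$n_filters[l]
    params[[paste0("convW", l)]] <- he_init(k * k * cin, f)
    params[[paste0("convb", l)]] <- numeric(f)
    cin <- f
  }
  fdim <- config$n_filters[length(config$n_filters)]
  params$projW1 <- he_init(fdim, config$projector_hidden)
  params$projb1 <- numeric(config$projector_hidden)
  params$projW2 <- he_init(config$projector_hidden, config$projector_dim)
  params$projb2 <- numeric(config$projector_dim)
  structure(
    list(config = config, input_dim = input_dim, params = params,
         opt_state = NULL, epochs_trained = 0L),
    class = "encoder_model"
  )
}

#' @export
print.encoder_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf(
    "<encoder_model small_cnn> input %s, projector dim %d, %d parameters, %d epochs trained\n",
    paste(x$input_dim, collapse = "x"), x$config$projector_dim, np,
    x$epochs_trained
  ))
  invisible(x)
}

# Forward pass. X: (B, H, W, C). Returns list(Z = unit-norm B x P latents,
# cache) — the cache carries every intermediate needed for backprop.
encoder_forward <- function(model, X, keep_cache = FALSE) {
  p <- model$params; cfg <- model$config
  nconv <- length(cfg$patch_sizes)
  cache <- list(conv = vector("list", nconv))
  a <- X
  for (l in seq_len(nconv)) {
    mat <- patchify(a, cfg$patch_sizes[l])
    grid <- attr(mat, "grid")
    pre <- sweep(mat %*% p[[paste0("convW", l)]], 2,
                 p[[paste0("convb", l)]], "+")
    post <- pre * (pre > 0)
    if (keep_cache) {
      cache$conv[[l]] <- list(mat = mat, grid = grid, mask = pre > 0)
    }
    a <- array(post, c(grid[1], grid[2], grid[3], ncol(post)))
  }
  d <- dim(a)
  npos <- d[2] * d[3]
  feat <- apply(a, c(1, 4), mean)                  # global average pool
  h_pre <- sweep(feat %*% p$projW1, 2, p$projb1, "+")
  h <- h_pre * (h_pre > 0)
  u <- sweep(h %*% p$projW2, 2, p$projb2, "+")
  # an image whose activations die completely would have no direction;
  # map it to the first basis vector (deterministic, zero gradient)
  dead <- rowSums(u^2) < 1e-16
  if (any(dead)) u[dead, 1L] <- 1
  nrm <- sqrt(rowSums(u^2))
  Z <- u / nrm
  if (keep_cache) {
    cache$npos <- npos
    cache$grid_last <- d
    cache$feat <- feat
    cache$h_mask <- h_pre > 0
    cache$h <- h
    cache$u <- u
    cache$nrm <- nrm
    cache$dead <- dead
    cache$Z <- Z
  }
  list(Z = Z, cache = if (keep_cache) cache else NULL)
}

# Backward pass: gradient of the loss w.r.t. every parameter, given dZ.
encoder_backward <- function(model, cache, dZ) {
  p <- model$params; cfg <- model$config
  grads <- list()
  # through L2 normalization: z = u / |u|
  du <- (dZ - cache$Z * rowSums(dZ * cache$Z)) / cache$nrm
  if (any(cache$dead)) du[cache$dead, ] <- 0
  grads$projW2 <- crossprod(cache$h, du)
  grads$projb2 <- colSums(du)
  dh <- (du %*% t(p$projW2)) * cache$h_mask
  grads$projW1 <- crossprod(cache$feat, dh)
  grads$projb1 <- colSums(dh)
  dfeat <- dh %*% t(p$projW1)
  d <- cache$grid_last
  # undo global average pool: each position receives dfeat / npos
  da_mat <- dfeat[rep(seq_len(d[1]), times = cache$npos), , drop = FALSE] /
    cache$npos
  for (l in rev(seq_along(cfg$patch_sizes))) {
    cc <- cache$conv[[l]]
    dpre <- da_mat * cc$mask
    grads[[paste0("convW", l)]] <- crossprod(cc$mat, dpre)
    grads[[paste0("convb", l)]] <- colSums(dpre)
    if (l > 1L) {
      dmat <- dpre %*% t(p[[paste0("convW", l)]])
      da <- unpatchify(dmat, cc$grid)
      dd <- dim(da)
      da_mat <- da
      dim(da_mat) <- c(dd[1] * dd[2] * dd[3], dd[4])
    }
  }
  grads
}

# One RMSprop step (adaptive per-parameter scaling, no momentum).
rmsprop_step <- function(model, grads, lr_scale = 1) {
  cfg <- model$config
  if (is.null(model$opt_state)) {
    model$opt_state <- lapply(model$params, function(p) p * 0)
  }
  for (nm in names(grads)) {
    g <- grads[[nm]]
    model$opt_state[[nm]] <- cfg$rmsprop_rho * model$opt_state[[nm]] +
      (1 - cfg$rmsprop_rho) * g^2
    model$params[[nm]] <- model$params[[nm]] -
      lr_scale * cfg$learning_rate * g /
        sqrt(model$opt_state[[nm]] + cfg$rmsprop_eps)
  }
  model
}

#' Project images into the learned latent space
#'
#' Computes `z = g(f(x))` for every image and L2-normalizes each row, so
#' temperature-scaled dot products between rows are cosine similarities.
#' Deterministic: the forward pass has no stochastic components.
#'
#' @param model An `encoder_model`.
#' @param images Either a list of [image_record()]s or a `(B, H, W, C)`
#'   array matching the model's `input_dim`.
#' @return Numeric B x P matrix with unit-norm rows, P =
#'   `config$projector_dim`.
#' @export
project <- function(model, images) {
  stopifnot(inherits(model, "encoder_model"))
  X <- if (is.array(images) && length(dim(images)) == 4L) {
    images
  } else {
    stack_pixels(images)
  }
  if (!identical(as.integer(dim(X)[2:4]), model$input_dim)) {
    stop(sprintf("images are %s but the encoder expects %s",
                 paste(dim(X)[2:4], collapse = "x"),
                 paste(model$input_dim, collapse = "x")))
  }
  encoder_forward(model, X, keep_cache = FALSE)$Z
}
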