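#' Self-supervised contrastive loss over a multiviewed batch
#'
#' For a multiviewed batch of 2N unit-norm latents, each entry `i` acts as
#' anchor once; its positive is its replicate `j(i)` and the contrast set
#' `A(i)` is every other entry (the remaining `2N - 1`, including `j(i)`).
#' The loss is the mean over anchors of
#' `-log[ exp(z_i . z_j(i) / tau) / sum_{a in A(i)} exp(z_i . z_a / tau) ]`,
#' i.e. temperature-scaled InfoNCE with replicates playing the role that
#' augmentations play in standard contrastive learning. Computed with
#' max-subtracted log-sum-exp for numerical stability.
#'
#' @param Z Numeric 2N x P matrix of latents; rows must be unit-norm
#'   (tolerance 1e-3) and free of non-finite values.
#' @param pair_index Integer vector of length 2N; `pair_index[i]` is the
#'   index of entry `i`'s replicate. Must be an involution without fixed
#'   points.
#' @param tau Temperature, `> 0` (default 0.07).
#' @return Non-negative scalar. Zero when N = 1 (the only contrast is the
#'   positive itself); `log(2N - 1)` when all latents coincide.
#' @export
self_supervised_loss <- function(Z, pair_index, tau = 0.07) {
  terms <- contrastive_terms(Z, pair_index, labels = NULL, tau = tau)
  mean(terms)
}

#' Supervised contrastive loss over a labeled multiviewed batch
#'
#' Extends [self_supervised_loss()] by treating every same-label entry as a
#' positive: with `P(i)` the set of other entries sharing anchor `i`'s label
#' (the replicate `j(i)` always belongs to it, since paired entries share
#' their label), the loss is the mean over anchors of
#' `(-1/|P(i)|) * sum_{p in P(i)} log[ exp(z_i . z_p / tau) /
#' sum_{a in A(i)} exp(z_i . z_a / tau) ]` — the "sum outside the log"
#' formulation. When all labels are distinct across pairs it reduces exactly
#' to the self-supervised loss.
#'
#' @inheritParams self_supervised_loss
#' @param labels Character vector of length 2N; every entry must be labeled
#'   (callers pre-filter to the annotated subset) and paired entries must
#'   share their label.
#' @return Non-negative scalar.
#' @export
supervised_contrastive_loss <- function(Z, pair_index, labels, tau = 0.07) {
  if (is.null(labels)) stop("labels are required; use self_supervised_loss")
  terms <- contrastive_terms(Z, pair_index, labels = labels, tau = tau)
  mean(terms)
}

# Per-anchor loss terms shared by both losses and by batchwise scoring.
# Returns a length-2N vector; labels = NULL gives the self-supervised terms.
contrastive_terms <- function(Z, pair_index, labels = NULL, tau = 0.07) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (tau <= 0) stop("temperature must be positive")
  if (anyNA(Z) || any(!is.finite(Z))) stop("non-finite values in latents")
  nrm <- sqrt(rowSums(Z^2))
  if (any(abs(nrm - 1) > 1e-3)) {
    stop("latent rows must be unit-normalized (max |norm - 1| = ",
         format(max(abs(nrm - 1))), ")")
  }
  pair_index <- as.integer(pair_index)
  if (length(pair_index) != n || any(pair_index == seq_len(n)) ||
      any(pair_index[pair_index] != seq_len(n))) {
    stop("pair_index must be a fixed-point-free involution on 1..2N")
  }
  if (!is.null(labels)) {
    if (length(labels) != n || anyNA(labels)) {
      stop("every multiview entry must carry a label")
    }
    if (any(labels != labels[pair_index])) {
      stop("paired entries must share the same label")
    }
  }
  if (n == 2L) {
    # single pair: A(i) = {j(i)}, every log-ratio is 0
    return(numeric(2L))
  }
  S <- tcrossprod(Z) / tau
  diag(S) <- -Inf                        # anchor never contrasts with itself
  m <- apply(S, 1L, max)
  lse <- m + log(rowSums(exp(S - m)))
  if (is.null(labels)) {
    lse - S[cbind(seq_len(n), pair_index)]
  } else {
    pos <- outer(labels, labels, "==")
    diag(pos) <- FALSE
    npos <- rowSums(pos)                 # >= 1: the replicate shares the label
    mean_pos_sim <- rowSums(ifelse(pos, S, 0)) / npos
    lse - mean_pos_sim
  }
}

# Gradient of mean contrastive loss w.r.t. the (unit-norm) latent matrix Z.
# Shared machinery: d loss / d s_ia summed over anchor roles, then mapped
# back through the symmetric similarity matrix. labels = NULL gives Eq-1
# behaviour. Used by the training loop; finite-difference-checked in tests.
contrastive_loss_grad <- function(Z, pair_index, labels = NULL, tau = 0.07) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (n == 2L) return(matrix(0, n, ncol(Z)))
  S <- tcrossprod(Z) / tau
  diag(S) <- -Inf
  m <- apply(S, 1L, max)
  P_soft <- exp(S - m)
  P_soft <- P_soft / rowSums(P_soft)
  if (is.null(labels)) {
    Tgt <- matrix(0, n, n)
    Tgt[cbind(seq_len(n), as.integer(pair_index))] <- 1
  } else {
    pos <- outer(labels, labels, "==")
    diag(pos) <- FALSE
    Tgt <- pos / rowSums(pos)
  }
  G <- (P_soft - Tgt) / n                # d(mean loss)/d s_ia, anchor rows
  (G + t(G)) %*% Z / tau
}
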