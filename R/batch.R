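#' Index images by compound
#'
#' @param records List of image records.
#' @return Named list mapping each compound id to the integer positions of
#'   its images in `records`.
#' @export
compound_index <- function(records) {
  split(seq_along(records), compound_ids(records))
}

#' Build one multiviewed batch
#'
#' Samples N anchor images and, for each, one replicate of the same compound
#' as its positive, giving 2N entries: slot `2k-1` holds anchor k and slot
#' `2k` its positive. Positives are drawn uniformly from the compound's
#' other images, avoiding reuse within the batch while possible; a compound
#' with a single image is self-paired (the same image fills both slots — the
#' pairing over slots remains a fixed-point-free involution).
#'
#' @param records List of image records.
#' @param cindex Compound index from [compound_index()] (rebuilt if `NULL`).
#' @param N Number of anchors, `>= 1`.
#' @param seed Integer seed; the batch is deterministic given it.
#' @param annotations Optional [annotation_table()]; when supplied, each
#'   entry is labeled with its compound's primary label (all sampled
#'   compounds must be annotated).
#' @param anchors Optional integer vector of anchor record positions
#'   (length N) to use instead of sampling them.
#' @return List of class `multiview_batch` with fields `entries` (integer
#'   record positions, length 2N), `pair_index`, `labels` (or `NULL`) and
#'   `N`.
#' @export
build_multiview_batch <- function(records, cindex = NULL, N, seed = 1L,
                                  annotations = NULL, anchors = NULL) {
  if (N < 1L) stop("N must be >= 1")
  if (is.null(cindex)) cindex <- compound_index(records)
  rng <- local_rng(seed)
  on.exit(rng())
  M <- length(records)
  if (is.null(anchors)) {
    anchors <- sample.int(M, N, replace = N > M)
  }
  stopifnot(length(anchors) == N)
  cid <- compound_ids(records)
  used <- integer(0)
  positives <- integer(N)
  for (k in seq_len(N)) {
    i <- anchors[k]
    cands <- setdiff(cindex[[cid[i]]], i)
    fresh <- setdiff(cands, used)
    pick_from <- if (length(fresh)) fresh else cands
    positives[k] <- if (length(pick_from)) {
      pick_from[sample.int(length(pick_from), 1L)]
    } else {
      i  # single-image compound: self-pairing
    }
    used <- c(used, positives[k])
  }
  entries <- integer(2L * N)
  entries[seq(1L, 2L * N, 2L)] <- anchors
  entries[seq(2L, 2L * N, 2L)] <- positives
  pair_index <- as.integer(rbind(seq(2L, 2L * N, 2L), seq(1L, 2L * N, 2L)))
  labels <- NULL
  if (!is.null(annotations)) {
    labels <- vapply(cid[entries], function(cp) {
      primary_label(annotations, cp)
    }, "")
    if (anyNA(labels)) {
      stop("all compounds in a labeled batch must be annotated")
    }
  }
  structure(list(entries = entries, pair_index = pair_index,
                 labels = labels, N = as.integer(N)),
            class = "multiview_batch")
}

# Partition a set of record positions into anchor groups of size <= N that
# cover it exactly once (an epoch's batches). A trailing single anchor is
# folded into the previous group. Consumes the current RNG stream.
epoch_anchor_groups <- function(positions, N) {
  positions <- sample(positions)
  n <- length(positions)
  if (n == 0L) return(list())
  starts <- seq(1L, n, N)
  groups <- lapply(starts, function(s) positions[s:min(s + N - 1L, n)])
  k <- length(groups)
  if (k > 1L && length(groups[[k]]) == 1L) {
    groups[[k - 1L]] <- c(groups[[k - 1L]], groups[[k]])
    groups[[k]] <- NULL
  }
  groups
}
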