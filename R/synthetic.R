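#' Specification for a synthetic Cell-Painting-like image set
#'
#' The generator emulates the structure of a high-content screen: K latent
#' phenotype classes, each driving channel-wise texture (oriented sinusoids)
#' and punctate structure (Gaussian blob density/size); compounds belong to
#' one class with a compound-specific modulation; replicate images of one
#' compound are acquired on different synthetic plates (batches) with
#' per-plate gain/offset shifts; a vehicle-control population is drawn from a
#' class-free background process; and only a fraction of compounds carry
#' annotations, some with a second (correlated) label.
#'
#' Default values define the package's standard synthetic benchmark: 10
#' classes, 80 compounds with 4 replicates each, 48 x 48 x 3 images, half of
#' the compounds annotated.
#'
#' @param n_classes Number of latent phenotype classes K.
#' @param n_compounds Number of treated compounds.
#' @param replicates_per_compound Replicate images per compound.
#' @param image_hw Integer pair, image height and width.
#' @param n_channels Number of fluorescence channels.
#' @param signal_strength Multiplier (`>= 0`) on the class-specific component;
#'   0 removes all class structure.
#' @param replicate_noise Replicate-inconsistency scale (`>= 0`); either a
#'   scalar or a vector recycled over compounds, so replicate consistency
#'   can differ between compounds. Each replicate of a compound with noise
#'   level `v` blends a fraction `Uniform(0, min(1, 0.35 v))` of a random
#'   contaminant class phenotype into its expressed morphology (an
#'   off-target/toxic response differing between replicates), jitters its
#'   expressed strength by 15% sd per unit, and receives i.i.d. Gaussian
#'   pixel noise with sd 0.08 and a 5% brightness jitter per unit. At 0,
#'   replicates express the identical phenotype (only stochastic blob
#'   placement and batch effects differ).
#' @param batch_effect Scale (`>= 0`) of per-plate multiplicative gain
#'   (sd 0.15 per unit) and additive offset (sd 0.04 per unit) per channel.
#' @param annotation_fraction Fraction of compounds receiving their true
#'   class as first label (class-stratified selection).
#' @param multilabel_fraction Fraction of annotated compounds that receive a
#'   second, correlated label.
#' @param n_controls Number of vehicle-control (DMSO-like) images.
#' @param n_batches Number of synthetic plates replicates are spread over.
#' @param seed Integer seed; the whole data set is a deterministic function
#'   of the spec.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_classes = 10L, n_compounds = 80L,
                       replicates_per_compound = 4L,
                       image_hw = c(48L, 48L), n_channels = 3L,
                       signal_strength = 1, replicate_noise = 1,
                       batch_effect = 1, annotation_fraction = 0.5,
                       multilabel_fraction = 0.25, n_controls = 16L,
                       n_batches = 2L, seed = 1L) {
  spec <- list(
    n_classes = as.integer(n_classes),
    n_compounds = as.integer(n_compounds),
    replicates_per_compound = as.integer(replicates_per_compound),
    image_hw = as.integer(image_hw),
    n_channels = as.integer(n_channels),
    signal_strength = signal_strength,
    replicate_noise = replicate_noise,
    batch_effect = batch_effect,
    annotation_fraction = annotation_fraction,
    multilabel_fraction = multilabel_fraction,
    n_controls = as.integer(n_controls),
    n_batches = as.integer(n_batches),
    seed = as.integer(seed)
  )
  with(spec, {
    stopifnot(
      n_classes >= 0, n_compounds >= 0, replicates_per_compound >= 0,
      all(image_hw >= 1), n_channels >= 1, signal_strength >= 0,
      all(replicate_noise >= 0), batch_effect >= 0,
      annotation_fraction >= 0, annotation_fraction <= 1,
      multilabel_fraction >= 0, multilabel_fraction <= 1,
      n_controls >= 0, n_batches >= 1
    )
    if (annotation_fraction > 0 && n_classes == 0) {
      stop("annotation_fraction > 0 requires n_classes >= 1")
    }
    if (annotation_fraction > 0 && n_compounds < n_classes) {
      stop("need n_compounds >= n_classes when annotations are requested")
    }
  })
  structure(spec, class = "synth_spec")
}

# Separable Gaussian blob added in place: A * exp(-d2/(2 rho^2))
add_blob <- function(img, cx, cy, rho, amp) {
  ex <- exp(-(seq_len(nrow(img)) - cx)^2 / (2 * rho^2))
  ey <- exp(-(seq_len(ncol(img)) - cy)^2 / (2 * rho^2))
  img + amp * (ex %o% ey)
}

# n random blobs with common radius/amplitude jitter
add_blobs <- function(img, n, rho, amp) {
  for (b in seq_len(n)) {
    img <- add_blob(img,
                    cx = stats::runif(1, 1, nrow(img)),
                    cy = stats::runif(1, 1, ncol(img)),
                    rho = rho * stats::runif(1, 0.7, 1.3),
                    amp = amp * stats::runif(1, 0.7, 1.3))
  }
  img
}

#' Generate a synthetic image set with known class structure
#'
#' See [synth_spec()] for the generative model. Pixel values are clipped to
#' `[0, 1]` and quantized to 16-bit levels, so writing with
#' [write_image_set()] and reloading with [load_image_set()] reproduces them
#' exactly.
#'
#' @param spec A [synth_spec()].
#' @return List with elements `records` (image records; controls have
#'   compound id `"DMSO"`), `annotations` (an [annotation_table()], system
#'   `"custom"`) and `truth` (named character vector mapping every treated
#'   compound to its latent class).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  rng <- local_rng(spec$seed)
  on.exit(rng())
  H <- spec$image_hw[1]; W <- spec$image_hw[2]; C <- spec$n_channels
  K <- spec$n_classes
  xg <- (seq_len(H) - 1) / max(H - 1, 1)
  yg <- (seq_len(W) - 1) / max(W - 1, 1)

  # class-level generative parameters, one set per class x channel
  cls <- vector("list", K)
  for (k in seq_len(K)) {
    cls[[k]] <- list(
      freq   = matrix(stats::runif(2 * C, 1.5, 5.5), 2, C),
      phase  = stats::runif(C, 0, 2 * pi),
      amp    = stats::runif(C, 0.10, 0.18),
      blob_rate = stats::runif(C, 0, 5),
      blob_rho  = stats::runif(C, 1.2, 3.0),
      blob_amp  = stats::runif(C, 0.15, 0.30)
    )
  }

  compounds <- sprintf("CPD%03d", seq_len(spec$n_compounds))
  truth <- if (K > 0) {
    stats::setNames(sprintf("class_%02d", ((seq_len(spec$n_compounds) - 1) %% K) + 1),
                    compounds)
  } else {
    stats::setNames(character(spec$n_compounds), compounds)
  }
  cpd_class <- ((seq_len(spec$n_compounds) - 1) %% max(K, 1)) + 1
  cpd_gain <- stats::runif(spec$n_compounds, 0.8, 1.2)      # compound modulation
  noise <- rep_len(spec$replicate_noise, max(spec$n_compounds, 1L))
  # compound-level individuation: each compound expresses its class template
  # with its own parameter deviations plus a private fingerprint texture, so
  # within-class variance sits between class- and replicate-level variance
  # (as in a real screen, where same-class compounds are distinguishable)
  cpd_par <- lapply(seq_len(spec$n_compounds), function(ci) {
    if (K == 0) return(NULL)
    par <- cls[[cpd_class[ci]]]
    par$freq <- par$freq * (1 + 0.12 * stats::rnorm(2 * C))
    par$amp <- par$amp * stats::runif(C, 0.7, 1.3)
    par$phase <- par$phase + 0.8 * stats::rnorm(C)
    par$blob_rate <- par$blob_rate * stats::runif(C, 0.5, 1.5)
    par$fp_freq <- matrix(stats::runif(2 * C, 1.5, 6.5), 2, C)
    par$fp_phase <- stats::runif(C, 0, 2 * pi)
    par$fp_amp <- rep(0.09, C)
    par
  })

  render_background <- function() {
    px <- array(0, c(H, W, C))
    for (ch in seq_len(C)) {
      img <- matrix(0.22, H, W)
      img <- add_blobs(img, n = 10L, rho = 2.2, amp = 0.16)
      px[, , ch] <- img
    }
    px
  }

  finalize <- function(px, plate_fx, nz) {
    for (ch in seq_len(C)) {
      img <- px[, , ch]
      img <- img * plate_fx$gain[ch] + plate_fx$offset[ch]
      img <- img * (1 + 0.05 * nz * stats::rnorm(1))
      img <- img + stats::rnorm(H * W, 0, 0.08 * nz)
      img[img < 0] <- 0; img[img > 1] <- 1
      px[, , ch] <- round(img * 65535) / 65535
    }
    px
  }

  plates <- sprintf("plate%02d", seq_len(spec$n_batches))
  plate_fx <- lapply(plates, function(p) {
    list(gain = 1 + 0.15 * spec$batch_effect * stats::rnorm(C),
         offset = 0.04 * spec$batch_effect * stats::rnorm(C))
  })
  names(plate_fx) <- plates

  records <- list()
  for (ci in seq_len(spec$n_compounds)) {
    k <- cpd_class[ci]
    par <- cpd_par[[ci]]
    for (r in seq_len(spec$replicates_per_compound)) {
      plate <- plates[((r - 1) %% spec$n_batches) + 1]
      px <- render_background()
      if (!is.null(par) && spec$signal_strength > 0) {
        # replicate-level phenotype inconsistency: a noisy compound's
        # replicates wobble in expressed strength and, more importantly,
        # blend in a random contaminant phenotype (off-target/toxic
        # response), so they scatter towards other populated regions of
        # phenotype space instead of merely shrinking in amplitude
        rep_gain <- max(0, 1 + 0.15 * noise[ci] * stats::rnorm(1))
        beta <- if (K > 1) stats::runif(1, 0, min(1, 0.35 * noise[ci])) else 0
        k2 <- if (K > 1) sample(setdiff(seq_len(K), k), 1L) else k
        par2 <- cls[[k2]]
        s <- spec$signal_strength * cpd_gain[ci] * rep_gain
        for (ch in seq_len(C)) {
          wave <- (1 - beta) * (par$amp[ch] * sin(
            2 * pi * outer(par$freq[1, ch] * xg, par$freq[2, ch] * yg, "+") +
            par$phase[ch]
          ) + par$fp_amp[ch] * sin(
            2 * pi * outer(par$fp_freq[1, ch] * xg, par$fp_freq[2, ch] * yg,
                           "+") + par$fp_phase[ch]
          )) + beta * par2$amp[ch] * sin(
            2 * pi * outer(par2$freq[1, ch] * xg, par2$freq[2, ch] * yg, "+") +
            par2$phase[ch]
          )
          img <- px[, , ch] + s * wave
          nb1 <- stats::rpois(1, s * (1 - beta) * par$blob_rate[ch])
          img <- add_blobs(img, nb1, par$blob_rho[ch], s * par$blob_amp[ch])
          nb2 <- stats::rpois(1, s * beta * par2$blob_rate[ch])
          img <- add_blobs(img, nb2, par2$blob_rho[ch], s * par2$blob_amp[ch])
          px[, , ch] <- img
        }
      }
      px <- finalize(px, plate_fx[[plate]], noise[ci])
      records[[length(records) + 1L]] <- image_record(
        image_id = sprintf("%s_r%02d", compounds[ci], r),
        compound_id = compounds[ci], plate_id = plate,
        well = sprintf("W%03d", ci), site = r, pixels = px
      )
    }
  }
  for (i in seq_len(spec$n_controls)) {
    plate <- plates[((i - 1) %% spec$n_batches) + 1]
    px <- finalize(render_background(), plate_fx[[plate]],
                   mean(spec$replicate_noise))
    records[[length(records) + 1L]] <- image_record(
      image_id = sprintf("DMSO_r%02d", i), compound_id = "DMSO",
      plate_id = plate, well = sprintf("CT%02d", i), site = 1L,
      pixels = px, control = TRUE
    )
  }

  # class-stratified annotation of a fixed fraction of compounds
  n_annot <- round(spec$annotation_fraction * spec$n_compounds)
  labs <- list()
  if (n_annot > 0) {
    # stratified pick: shuffle within class, interleave classes round-robin
    picked <- character(0)
    shuffled <- sample(compounds)
    cls_of <- truth[shuffled]
    by_cls <- split(shuffled, cls_of)
    while (length(picked) < n_annot) {
      for (k in names(by_cls)) {
        if (length(picked) >= n_annot) break
        if (length(by_cls[[k]])) {
          picked <- c(picked, by_cls[[k]][1])
          by_cls[[k]] <- by_cls[[k]][-1]
        }
      }
    }
    labs <- stats::setNames(as.list(truth[picked]), picked)
    n_multi <- round(spec$multilabel_fraction * n_annot)
    if (n_multi > 0 && K > 1) {
      multi <- sample(picked, n_multi)
      for (cp in multi) {
        k <- as.integer(sub("class_", "", truth[cp]))
        labs[[cp]] <- c(labs[[cp]], sprintf("class_%02d", (k %% K) + 1))
      }
    }
  }
  list(records = records,
       annotations = annotation_table(labs, system_name = "custom"),
       truth = truth)
}

#' Generate a unit-norm embedding fixture with multiview pairing
#'
#' Produces the `2N x dim` latent matrix, mutual pairing and optional labels
#' used to exercise the contrastive losses without any encoder. Entries are
#' ordered as consecutive pairs `(1,2), (3,4), ...`; paired entries share a
#' label when labels are requested.
#'
#' @param n_pairs Number of anchor/positive pairs N (`>= 1`).
#' @param dim Latent dimension (`>= 2`).
#' @param label_spec `NULL` for no labels, or a list with optional entries
#'   `n_classes` (labels drawn per pair from that many classes) and
#'   `identical` (logical: force every row equal to one random unit vector).
#' @param seed Integer seed.
#' @return List with `Z` (2N x dim, unit rows), `pair_index` (integer vector,
#'   an involution without fixed points) and `labels` (character or `NULL`).
#' @export
generate_embedding_fixture <- function(n_pairs, dim, label_spec = NULL,
                                       seed = 1L) {
  stopifnot(n_pairs >= 1L, dim >= 2L)
  rng <- local_rng(seed)
  on.exit(rng())
  n <- 2L * n_pairs
  if (!is.null(label_spec) && isTRUE(label_spec$identical)) {
    v <- stats::rnorm(dim)
    Z <- matrix(rep(v / sqrt(sum(v^2)), each = n), n, dim)
  } else {
    Z <- matrix(stats::rnorm(n * dim), n, dim)
    Z <- Z / sqrt(rowSums(Z^2))
  }
  pair_index <- as.integer(rbind(seq(2, n, 2), seq(1, n, 2)))
  labels <- NULL
  if (!is.null(label_spec) && !is.null(label_spec$n_classes)) {
    per_pair <- sample(sprintf("class_%02d", seq_len(label_spec$n_classes)),
                       n_pairs, replace = TRUE)
    labels <- rep(per_pair, each = 2)
  }
  list(Z = Z, pair_index = pair_index, labels = labels)
}
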