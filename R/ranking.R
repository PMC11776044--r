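#' Rank unannotated compounds and annotate them by replicate vote
#'
#' The discovery readout: restricts to unannotated, non-control compounds,
#' scores them by batchwise self-supervised contrastive loss (low loss =
#' replicates map to self-consistent latents), keeps the `top_n`
#' lowest-scoring compounds, and labels each with the `top_k` classes most
#' frequently predicted across its replicates by a single-label downstream
#' classifier.
#'
#' @param model A trained `encoder_model`.
#' @param classifier A single-label `phenocon_classifier`.
#' @param records List of image records (the full set; filtering happens
#'   here).
#' @param annotations An [annotation_table()] defining which compounds are
#'   annotated.
#' @param top_n Number of lowest-loss compounds to keep (default 10).
#' @param top_k Number of predicted classes to report per compound
#'   (default 3).
#' @param aggregate `"min"` (default) or `"mean"` replicate-loss
#'   aggregation, see [batchwise_contrastive_loss()].
#' @param batch_size Anchors per scoring batch (default from the model's
#'   config).
#' @param seed Integer seed fixing scoring-batch composition.
#' @return Data frame of class `ranked_predictions`: one row per compound
#'   with `rank` (1..top_n, no gaps), `compound_id`, `score` (non-decreasing
#'   with rank), `n_replicates` and `top_classes`
#'   (`"class:count|class:count|..."`); attribute `"details"` holds the
#'   per-compound prediction tallies.
#' @export
rank_unannotated <- function(model, classifier, records, annotations,
                             top_n = 10L, top_k = 3L,
                             aggregate = c("min", "mean"),
                             batch_size = model$config$batch_size,
                             seed = 1L) {
  aggregate <- match.arg(aggregate)
  stopifnot(classifier$task == "single")
  annotated <- annotated_compounds(annotations)
  keep <- !is_control(records) & !(compound_ids(records) %in% annotated)
  if (!any(keep)) stop("no unannotated non-control compounds to rank")
  sub <- records[keep]
  bw <- batchwise_contrastive_loss(model, sub, batch_size = batch_size,
                                   seed = seed, aggregate = aggregate)
  cmp <- bw$compound_scores                 # already sorted, lexical ties
  cmp <- utils::head(cmp, top_n)
  cid <- compound_ids(sub)
  details <- vector("list", nrow(cmp))
  top_str <- character(nrow(cmp))
  for (i in seq_len(nrow(cmp))) {
    reps <- sub[cid == cmp$compound_id[i]]
    emb <- extract_embeddings(model, reps)
    tal <- predict_compound_classes(classifier, emb, top_k = top_k)
    details[[i]] <- tal
    top_str[i] <- paste(sprintf("%s:%d", tal$class, tal$count),
                        collapse = "|")
  }
  out <- data.frame(rank = seq_len(nrow(cmp)),
                    compound_id = cmp$compound_id,
                    score = cmp$score,
                    n_replicates = cmp$n_replicates,
                    top_classes = top_str,
                    stringsAsFactors = FALSE)
  attr(out, "details") <- stats::setNames(details, cmp$compound_id)
  class(out) <- c("ranked_predictions", "data.frame")
  out
}

#' Write ranked predictions as CSV and JSON
#' @param ranked A `ranked_predictions` data frame.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_ranked_predictions <- function(ranked, csv_path = NULL,
                                     json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(ranked), csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    det <- attr(ranked, "details")
    jsonlite::write_json(
      lapply(seq_len(nrow(ranked)), function(i) {
        list(rank = ranked$rank[i], compound_id = ranked$compound_id[i],
             score = ranked$score[i],
             n_replicates = ranked$n_replicates[i],
             top_classes = det[[ranked$compound_id[i]]])
      }),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(c(csv = csv_path, json = json_path))
}
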