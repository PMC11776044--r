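#' Construct an annotation table
#'
#' Maps compound ids to an *ordered* list of bioactivity class labels under
#' one annotation system (MeSH pharmacological classes, mode-of-action,
#' target, or a custom vocabulary). Compounds absent from the map are
#' unannotated; a compound may carry several labels, and the order is
#' meaningful: the first label is the one used for supervised contrastive
#' learning and single-label classification.
#'
#' @param labels Named list; names are compound ids, each element a character
#'   vector of class labels (possibly empty, which counts as unannotated).
#' @param system_name One of `"MeSH"`, `"MoA"`, `"target"`, `"custom"`.
#' @return An object of class `annotation_table`.
#' @export
annotation_table <- function(labels, system_name = c("MeSH", "MoA", "target",
                                                     "custom")) {
  system_name <- match.arg(system_name)
  stopifnot(is.list(labels))
  if (length(labels) && is.null(names(labels))) {
    stop("labels must be named by compound_id")
  }
  labels <- lapply(labels, as.character)
  structure(
    list(system_name = system_name, labels = labels),
    class = "annotation_table"
  )
}

#' @export
print.annotation_table <- function(x, ...) {
  cat(sprintf(
    "<annotation_table %s> %d annotated compounds, %d classes\n",
    x$system_name, length(annotated_compounds(x)),
    length(class_vocabulary(x))
  ))
  invisible(x)
}

#' First (primary) label of a compound
#'
#' Multi-label compounds contribute only their first listed annotation to
#' supervised contrastive learning and single-label classification; the
#' remaining labels are used only for multilabel targets.
#'
#' @param table An [annotation_table()].
#' @param compound_id Single compound id.
#' @return The first label as a string, or `NA_character_` if the compound is
#'   unannotated (absent from the table or with an empty label list).
#' @export
primary_label <- function(table, compound_id) {
  stopifnot(inherits(table, "annotation_table"), length(compound_id) == 1L)
  lab <- table$labels[[compound_id]]
  if (is.null(lab) || length(lab) == 0L) NA_character_ else lab[[1L]]
}

#' Compounds carrying at least one label
#' @param table An [annotation_table()].
#' @return Character vector of annotated compound ids, in table order.
#' @export
annotated_compounds <- function(table) {
  stopifnot(inherits(table, "annotation_table"))
  names(table$labels)[lengths(table$labels) > 0L]
}

#' Class vocabulary of an annotation table
#' @param table An [annotation_table()].
#' @return Sorted character vector: the union of all listed labels.
#' @export
class_vocabulary <- function(table) {
  stopifnot(inherits(table, "annotation_table"))
  sort(unique(unlist(table$labels, use.names = FALSE)))
}

#' Full label set of a compound
#' @param table An [annotation_table()].
#' @param compound_id Single compound id.
#' @return Character vector of labels (length 0 if unannotated).
#' @export
label_set <- function(table, compound_id) {
  lab <- table$labels[[compound_id]]
  if (is.null(lab)) character(0) else lab
}

#' Write annotations as a delimited table
#'
#' One row per annotated compound; ordered labels joined by `"|"`.
#'
#' @param table An [annotation_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(table, path) {
  stopifnot(inherits(table, "annotation_table"))
  df <- data.frame(
    compound_id = names(table$labels),
    labels = vapply(table$labels, paste, "", collapse = "|"),
    system_name = table$system_name,
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read annotations written by [write_annotations()]
#' @param path CSV path with columns compound_id, labels, system_name.
#' @return An [annotation_table()].
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("compound_id", "labels")
  if (!all(need %in% names(df))) {
    stop("annotation table requires columns: ", paste(need, collapse = ", "))
  }
  labs <- strsplit(df$labels, "|", fixed = TRUE)
  labs <- lapply(labs, function(x) x[nzchar(x)])
  names(labs) <- df$compound_id
  sys <- if ("system_name" %in% names(df) && nrow(df)) {
    df$system_name[[1L]]
  } else {
    "custom"
  }
  annotation_table(labs, system_name = sys)
}
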