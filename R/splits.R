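#' Build a treatment-level cross-validation split plan
#'
#' Splitting always operates on annotated compounds (treatments), never on
#' individual images: every image of a compound inherits the compound's fold,
#' so no treatment ever straddles a train/test boundary. Folds are stratified
#' by primary label where a class has at least `fold_count` members;
#' remaining compounds are distributed at random to balance fold sizes.
#' Deterministic given `seed`.
#'
#' @param table An [annotation_table()].
#' @param records Image records (used only to check that annotated compounds
#'   are present); may be `NULL` to skip the check.
#' @param fold_count Number of CV folds, `>= 2` (default 5).
#' @param train_fraction Recorded train fraction; defaults to
#'   `1 - 1/fold_count` (e.g. 0.8 for 5 folds).
#' @param seed Integer seed.
#' @return An object of class `split_plan` with fields `fold_count`,
#'   `assignments` (named integer vector compound -> fold), `train_fraction`,
#'   `seed`.
#' @export
make_splits <- function(table, records = NULL, fold_count = 5L,
                        train_fraction = NULL, seed = 1L) {
  stopifnot(inherits(table, "annotation_table"), fold_count >= 2L)
  comps <- annotated_compounds(table)
  if (!is.null(records)) {
    present <- unique(compound_ids(records))
    comps <- comps[comps %in% present]
  }
  if (length(comps) < fold_count) {
    stop(sprintf("need at least %d annotated compounds for %d folds, have %d",
                 fold_count, fold_count, length(comps)))
  }
  if (is.null(train_fraction)) train_fraction <- 1 - 1 / fold_count
  prim <- vapply(comps, function(cp) primary_label(table, cp), "")
  rng <- local_rng(seed)
  assignments <- stats::setNames(integer(length(comps)), comps)
  counts <- table(prim)
  big <- names(counts)[counts >= fold_count]
  fold_load <- integer(fold_count)  # balances leftover assignment
  for (cl in sample(big)) {
    members <- sample(comps[prim == cl])
    f <- ((seq_along(members) - 1L) %% fold_count) + 1L
    assignments[members] <- f
    fold_load <- fold_load + tabulate(f, fold_count)
  }
  rest <- sample(comps[!(prim %in% big)])
  for (cp in rest) {
    f <- which.min(fold_load + stats::runif(fold_count, 0, 0.5))
    assignments[cp] <- f
    fold_load[f] <- fold_load[f] + 1L
  }
  rng()
  structure(
    list(fold_count = as.integer(fold_count),
         assignments = assignments,
         train_fraction = train_fraction,
         seed = as.integer(seed)),
    class = "split_plan"
  )
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d folds over %d compounds (train fraction %.2f)\n",
              x$fold_count, length(x$assignments), x$train_fraction))
  print(table(fold = x$assignments))
  invisible(x)
}

#' Record indices of one fold's train/test sides
#'
#' @param plan A `split_plan`.
#' @param records Image records.
#' @param fold Fold index in `1..fold_count`.
#' @return List with integer vectors `train` and `test`: positions in
#'   `records` whose compounds are annotated and fall outside/inside the
#'   fold. Control and unannotated images appear on neither side.
#' @export
fold_indices <- function(plan, records, fold) {
  stopifnot(inherits(plan, "split_plan"), fold >= 1L, fold <= plan$fold_count)
  cid <- compound_ids(records)
  f <- plan$assignments[cid]  # NA for unannotated compounds
  list(train = which(!is.na(f) & f != fold),
       test = which(!is.na(f) & f == fold))
}

#' Serialize a split plan as a two-column CSV
#' @param plan A `split_plan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_split_plan <- function(plan, path) {
  df <- data.frame(compound_id = names(plan$assignments),
                   fold = unname(plan$assignments),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a split plan written by [write_split_plan()]
#' @param path CSV path with columns compound_id, fold.
#' @param train_fraction,seed Metadata to attach (not stored in the CSV).
#' @return A `split_plan`.
#' @export
read_split_plan <- function(path, train_fraction = NULL, seed = NA_integer_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  k <- max(df$fold)
  if (is.null(train_fraction)) train_fraction <- 1 - 1 / k
  structure(
    list(fold_count = as.integer(k),
         assignments = stats::setNames(as.integer(df$fold), df$compound_id),
         train_fraction = train_fraction,
         seed = as.integer(seed)),
    class = "split_plan"
  )
}

# Seed the RNG locally and restore the caller's RNG state on request.
# Returns a restore function; call it when done. Using this everywhere keeps
# package functions deterministic without clobbering the user's RNG stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    invisible(NULL)
  }
}
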