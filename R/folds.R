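#' Patient-level stratified fold assignment
#'
#' Partitions a cohort into `k` folds so that every patient appears in
#' exactly one fold and per-class counts differ by at most one across
#' folds. All of a patient's data therefore lands on one side of every
#' train/test split. Fold indices are 1-based (`1..k`).
#'
#' @param cohort a [new_cohort()] object, or a character vector of labels
#'   named by patient id.
#' @param k number of folds (>= 2).
#' @param seed integer seed; the assignment is deterministic given the seed.
#' @return An object of class `"fold_assignment"`: a named integer vector
#'   mapping `patient_id -> fold`, with attribute `k`.
#' @examples
#' coh <- generate_cohort(synthetic_config(n_per_class = 10, d_f = 4,
#'                                         d_g = 4, shared_dim = 2))
#' table(stratified_folds(coh, k = 5, seed = 1), coh$label)
#' @export
stratified_folds <- function(cohort, k, seed = 1L) {
  if (inherits(cohort, "cohort")) {
    labels <- cohort$label
    ids <- cohort$patient_id
  } else {
    labels <- as.character(cohort)
    ids <- names(cohort)
    if (is.null(ids)) stop("labels must be named by patient id")
  }
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  counts <- table(labels)
  small <- names(counts)[counts < k]
  if (length(small) > 0L) {
    stop("class(es) with fewer than k = ", k, " members: ",
         paste(small, collapse = ", "))
  }
  fold <- integer(length(ids))
  names(fold) <- ids
  with_seed(seed, {
    for (cl in names(counts)) {
      members <- which(labels == cl)
      members <- members[sample.int(length(members))]
      # rotate the fold order per class so remainder folds vary
      start <- sample.int(k, 1L)
      fold[members] <- ((seq_along(members) - 1L + start - 1L) %% k) + 1L
    }
  })
  structure(fold, k = k, class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat("<fold_assignment> ", length(x), " patients in ", attr(x, "k"),
      " folds\n", sep = "")
  print(table(fold = unclass(x)))
  invisible(x)
}

#' Write a fold assignment as a two-column CSV
#'
#' @param folds a [stratified_folds()] result.
#' @param path output path; columns `patient_id,fold` (1-based folds).
#' @return `path`, invisibly.
#' @export
write_folds <- function(folds, path) {
  data.table::fwrite(
    data.table::data.table(patient_id = names(folds),
                           fold = as.integer(folds)),
    path
  )
  invisible(path)
}
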