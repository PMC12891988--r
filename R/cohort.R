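#' Construct a bimodal patient cohort
#'
#' A cohort holds, for every patient, a diagnosis label and one embedding
#' per modality: `f`, the pooled histopathology image embedding, and `g`,
#' the immunogenomic sequence embedding. Embedding dimensions are constant
#' across the cohort and all values must be finite.
#'
#' @param patient_id character vector of unique patient identifiers.
#' @param label character (or factor) diagnosis class per patient.
#' @param f numeric matrix, one row per patient (image modality).
#' @param g numeric matrix, one row per patient (sequence modality).
#' @return An object of class `"cohort"`: a list with elements
#'   `patient_id`, `label`, `f`, `g` and `label_set`.
#' @examples
#' coh <- new_cohort(c("p1", "p2"), c("A", "B"),
#'                   matrix(rnorm(8), 2), matrix(rnorm(8), 2))
#' coh
#' @export
new_cohort <- function(patient_id, label, f, g) {
  patient_id <- as.character(patient_id)
  label <- as.character(label)
  f <- as.matrix(f)
  g <- as.matrix(g)
  n <- length(patient_id)
  if (length(label) != n || nrow(f) != n || nrow(g) != n) {
    stop("patient_id, label, f and g must describe the same patients")
  }
  if (anyDuplicated(patient_id)) {
    stop("duplicate patient_id: ",
         paste(unique(patient_id[duplicated(patient_id)]), collapse = ", "))
  }
  if (!all(is.finite(f))) stop("non-finite values in image embeddings f")
  if (!all(is.finite(g))) stop("non-finite values in sequence embeddings g")
  rownames(f) <- patient_id
  rownames(g) <- patient_id
  structure(
    list(patient_id = patient_id, label = label, f = f, g = g,
         label_set = sort(unique(label))),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", length(x$patient_id), " patients, ",
      length(x$label_set), " classes (",
      paste(x$label_set, collapse = ", "), ")\n", sep = "")
  cat("  image embedding f: ", ncol(x$f), " dims; sequence embedding g: ",
      ncol(x$g), " dims\n", sep = "")
  invisible(x)
}

#' Subset a cohort by patient index or id
#'
#' @param cohort a [new_cohort()] object.
#' @param idx integer indices or character patient ids.
#' @return A `"cohort"` with the selected patients, in the given order.
#' @export
cohort_subset <- function(cohort, idx) {
  if (is.character(idx)) idx <- match(idx, cohort$patient_id)
  if (anyNA(idx)) stop("unknown patient id in subset")
  new_cohort(cohort$patient_id[idx], cohort$label[idx],
             cohort$f[idx, , drop = FALSE], cohort$g[idx, , drop = FALSE])
}

# Read one delimited embedding table and split it into id, label and the
# numeric block for one prefix. Errors name the offending row/column.
read_modality_table <- function(path, prefix, id_col, label_col) {
  dt <- data.table::fread(path, colClasses = list(character = id_col))
  if (!id_col %in% names(dt)) stop(path, ": missing id column '", id_col, "'")
  emb_cols <- grep(paste0("^", prefix, "[0-9]+$"), names(dt), value = TRUE)
  if (length(emb_cols) == 0L) {
    stop(path, ": no embedding columns matching prefix '", prefix, "'")
  }
  # order numerically by suffix
  emb_cols <- emb_cols[order(as.integer(sub(paste0("^", prefix), "", emb_cols)))]
  ids <- as.character(dt[[id_col]])
  if (anyDuplicated(ids)) {
    stop(path, ": duplicate patient_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  emb <- as.matrix(dt[, emb_cols, with = FALSE])
  if (!is.numeric(emb)) {
    bad <- which(!vapply(dt[, emb_cols, with = FALSE], is.numeric, logical(1)))
    stop(path, ": non-numeric embedding column '", emb_cols[bad[1]], "'")
  }
  if (!all(is.finite(emb))) {
    ij <- which(!is.finite(emb), arr.ind = TRUE)[1, ]
    stop(path, ": non-finite embedding value at row ", ij[1],
         " (patient ", ids[ij[1]], "), column '", emb_cols[ij[2]], "'")
  }
  lab <- if (label_col %in% names(dt)) as.character(dt[[label_col]]) else NULL
  list(ids = ids, label = lab, emb = emb)
}

#' Load a bimodal cohort from delimited text files
#'
#' Accepts either a single wide table holding both modalities
#' (`patient_id`, `label`, `f_0..f_{d-1}`, `g_0..g_{d-1}`) or two
#' per-modality tables keyed by `patient_id` (each with its modality's
#' columns; the label may sit in either file). Files may be CSV or TSV;
#' the delimiter is auto-detected. Patients present in only one modality
#' are dropped with a warning; duplicate ids, non-numeric cells and
#' inconsistent dimensions are hard errors naming the offending cell.
#'
#' @param path path to the wide table, or to the image-modality table.
#' @param seq_path optional path to the sequence-modality table.
#' @param id_col,label_col column names (defaults `"patient_id"`, `"label"`).
#' @param f_prefix,g_prefix embedding column prefixes (defaults `"f_"`, `"g_"`).
#' @return A [new_cohort()] object.
#' @export
load_cohort <- function(path, seq_path = NULL, id_col = "patient_id",
                        label_col = "label", f_prefix = "f_",
                        g_prefix = "g_") {
  if (is.null(seq_path)) {
    fm <- read_modality_table(path, f_prefix, id_col, label_col)
    gm <- read_modality_table(path, g_prefix, id_col, label_col)
  } else {
    fm <- read_modality_table(path, f_prefix, id_col, label_col)
    gm <- read_modality_table(seq_path, g_prefix, id_col, label_col)
  }
  common <- intersect(fm$ids, gm$ids)
  dropped <- setdiff(union(fm$ids, gm$ids), common)
  if (length(dropped) > 0L) {
    warning(length(dropped), " patient(s) present in only one modality ",
            "dropped: ", paste(head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ..." else "")
  }
  if (length(common) == 0L) stop("no patients shared between modalities")
  fi <- match(common, fm$ids)
  gi <- match(common, gm$ids)
  lab <- if (!is.null(fm$label)) fm$label[fi] else gm$label[gi]
  if (is.null(lab)) stop("no '", label_col, "' column found in input files")
  if (!is.null(fm$label) && !is.null(gm$label) &&
      !identical(fm$label[fi], gm$label[gi])) {
    stop("label mismatch between modality files")
  }
  new_cohort(common, lab, fm$emb[fi, , drop = FALSE],
             gm$emb[gi, , drop = FALSE])
}

#' Write a cohort as a single wide delimited table
#'
#' Writes `patient_id`, `label`, `f_0..`, `g_0..` columns in the format
#' [load_cohort()] reads back.
#'
#' @param cohort a cohort.
#' @param path output file path (CSV).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  f <- cohort$f
  g <- cohort$g
  colnames(f) <- paste0("f_", seq_len(ncol(f)) - 1L)
  colnames(g) <- paste0("g_", seq_len(ncol(g)) - 1L)
  dt <- data.table::data.table(patient_id = cohort$patient_id,
                               label = cohort$label)
  dt <- cbind(dt, data.table::as.data.table(f), data.table::as.data.table(g))
  data.table::fwrite(dt, path)
  invisible(path)
}
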