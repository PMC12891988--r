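#' Save / load trained models
#'
#' Serializes a trained [train_hybrid_autoencoder()] or
#' [train_monogram_model()] object (weights plus its spec and loss curve)
#' to a single file via RDS.
#'
#' @param model the model object.
#' @param path file path.
#' @return `path` invisibly ([save_model()]); the model ([load_model()]).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, c("hybrid_autoencoder", "monogram_model")))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, c("hybrid_autoencoder", "monogram_model"))) {
    stop("file does not contain a marblix model")
  }
  model
}

#' Write / read latent matrices as delimited text
#'
#' Tabular export of per-patient latents (`patient_id`, `label`,
#' `<prefix>0..<prefix>{l-1}`), readable back with [read_latents()].
#'
#' @param ids,labels per-row patient ids and labels.
#' @param latents n x l numeric matrix.
#' @param path file path.
#' @param prefix column prefix, e.g. `"u_"` or `"v_"`.
#' @return `path` invisibly; [read_latents()] returns a list with `ids`,
#'   `labels`, `latents`.
#' @export
write_latents <- function(ids, labels, latents, path, prefix = "u_") {
  latents <- as.matrix(latents)
  colnames(latents) <- paste0(prefix, seq_len(ncol(latents)) - 1L)
  dt <- data.table::data.table(patient_id = as.character(ids),
                               label = as.character(labels))
  data.table::fwrite(cbind(dt, data.table::as.data.table(latents)), path)
  invisible(path)
}

#' @rdname write_latents
#' @export
read_latents <- function(path, prefix = "u_") {
  dt <- data.table::fread(path, colClasses = list(character = "patient_id"))
  cols <- grep(paste0("^", prefix, "[0-9]+$"), names(dt), value = TRUE)
  cols <- cols[order(as.integer(sub(paste0("^", prefix), "", cols)))]
  if (length(cols) == 0L) stop("no latent columns with prefix '", prefix, "'")
  list(ids = as.character(dt$patient_id),
       labels = if ("label" %in% names(dt)) as.character(dt$label) else NULL,
       latents = as.matrix(dt[, cols, with = FALSE]))
}
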