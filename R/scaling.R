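#' Fit per-dimension min-max harmonization parameters
#'
#' Embeddings from different pretrained backbones live on different scales,
#' so each modality is rescaled to \[0, 1\] per dimension before association
#' learning. Parameters are fitted on training rows only and later applied
#' to held-out rows with [apply_minmax()], which prevents test-set leakage.
#'
#' @param train_matrix numeric matrix (rows = training patients).
#' @param modality optional tag ("image", "sequence", ...) kept for
#'   bookkeeping.
#' @return An object of class `"minmax_scaler"`: list with `min`, `max`
#'   (per-dimension vectors) and `modality`. Dimensions with `max == min`
#'   carry no information and trigger a warning; [apply_minmax()] maps them
#'   to 0.
#' @examples
#' sp <- fit_minmax(matrix(c(2, 4, 6), ncol = 1))
#' sp$min; sp$max
#' @export
fit_minmax <- function(train_matrix, modality = NULL) {
  x <- as.matrix(train_matrix)
  if (nrow(x) < 1L || ncol(x) < 1L) stop("empty training matrix")
  if (!all(is.finite(x))) stop("non-finite values in training matrix")
  mn <- apply(x, 2L, min)
  mx <- apply(x, 2L, max)
  n_flat <- sum(mx == mn)
  if (n_flat > 0L) {
    warning(n_flat, " constant dimension(s) (max == min); they map to 0")
  }
  structure(list(min = mn, max = mx, modality = modality),
            class = "minmax_scaler")
}

#' Apply min-max harmonization
#'
#' Rescales each dimension as `(x - min) / (max - min)` using parameters
#' from [fit_minmax()]. Values outside the training range are clipped to
#' \[0, 1\]; constant training dimensions map to 0.
#'
#' @param matrix numeric matrix with the same number of columns the scaler
#'   was fitted on.
#' @param params a `"minmax_scaler"`.
#' @return Matrix of the same shape with values in \[0, 1\].
#' @examples
#' sp <- fit_minmax(matrix(c(2, 4, 6), ncol = 1))
#' apply_minmax(matrix(c(2, 4, 8), ncol = 1), sp)
#' @export
apply_minmax <- function(matrix, params) {
  stopifnot(inherits(params, "minmax_scaler"))
  x <- as.matrix(matrix)
  d <- length(params$min)
  if (ncol(x) != d) {
    stop("matrix has ", ncol(x), " columns but scaler was fitted on ", d)
  }
  rng <- params$max - params$min
  flat <- rng == 0
  rng[flat] <- 1 # placeholder; flat columns are zeroed below
  out <- sweep(x, 2L, params$min, "-")
  out <- sweep(out, 2L, rng, "/")
  out[out < 0] <- 0
  out[out > 1] <- 1
  if (any(flat)) out[, flat] <- 0
  out
}
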