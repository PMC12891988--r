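#' Specify a cross-modal (hybrid) autoencoder
#'
#' Architecture and training settings for one hybrid autoencoder: an
#' encoder of two dense layers (512, 256), a 128-unit bottleneck, and a
#' decoder of two dense layers (256, 512) ending at the target modality's
#' width. Hidden layers use the rectifier; the output layer is linear
#' (targets are min-max rescaled to \[0, 1\]). Trained with Adam on
#' mean-squared error for a fixed number of epochs.
#'
#' Defaults follow the image-to-genomic direction (150 epochs, learning
#' rate 1e-5); the genomic-to-image direction conventionally uses 50
#' epochs at 1e-4 (see [run_experiment()]).
#'
#' @param input_dim width of the source modality.
#' @param output_dim width of the target modality.
#' @param encoder_widths,decoder_widths hidden layer widths.
#' @param bottleneck bottleneck (latent) width, default 128.
#' @param epochs number of training epochs.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size (rows), shuffled each epoch.
#' @param seed integer seed controlling initialization and shuffling.
#' @return An object of class `"autoencoder_spec"`.
#' @export
autoencoder_spec <- function(input_dim, output_dim,
                             encoder_widths = c(512L, 256L),
                             bottleneck = 128L,
                             decoder_widths = c(256L, 512L),
                             epochs = 150L, learning_rate = 1e-5,
                             batch_size = 32L, seed = 1L) {
  stopifnot(input_dim >= 1, output_dim >= 1, bottleneck >= 1,
            all(encoder_widths >= 1), all(decoder_widths >= 1),
            epochs >= 1, learning_rate > 0, batch_size >= 1)
  structure(
    list(input_dim = as.integer(input_dim),
         output_dim = as.integer(output_dim),
         encoder_widths = as.integer(encoder_widths),
         bottleneck = as.integer(bottleneck),
         decoder_widths = as.integer(decoder_widths),
         epochs = as.integer(epochs),
         learning_rate = learning_rate,
         batch_size = as.integer(batch_size),
         seed = as.integer(seed)),
    class = "autoencoder_spec"
  )
}

#' Train a hybrid cross-modal autoencoder
#'
#' Trains an encoder-decoder network that takes one modality's (rescaled)
#' embedding as input and reconstructs the \emph{other} modality, so the
#' bottleneck retains only cross-modally predictive features. Minimizes
#' mean-squared reconstruction error with Adam over shuffled minibatches;
#' fully deterministic given `spec$seed`. Whether the two modalities can
#' predict each other at all is itself informative: on decoupled data the
#' trained model cannot beat the column-mean predictor (a built-in
#' coherence check).
#'
#' The output layer's bias starts at the training targets' column means,
#' i.e. training starts from the mean predictor and any progress reflects
#' learned cross-modal structure rather than output recalibration.
#'
#' @param source n x d_src matrix in \[0, 1\] (input modality, row-aligned
#'   with `target` by patient).
#' @param target n x d_tgt matrix in \[0, 1\] (modality to reconstruct).
#' @param spec an [autoencoder_spec()].
#' @return An object of class `"hybrid_autoencoder"`: snapshot of trained
#'   weights, the encoder depth, the spec, and `loss_curve` (per-epoch
#'   training MSE, length `spec$epochs`).
#' @seealso [encode_latents()], [reconstruction_report()]
#' @export
train_hybrid_autoencoder <- function(source, target, spec) {
  stopifnot(inherits(spec, "autoencoder_spec"))
  source <- as.matrix(source)
  target <- as.matrix(target)
  n <- nrow(source)
  if (n < 2L) stop("need at least 2 training rows")
  if (nrow(target) != n) stop("source and target must be row-aligned")
  if (ncol(source) != spec$input_dim) {
    stop("source has ", ncol(source), " columns, spec expects ",
         spec$input_dim)
  }
  if (ncol(target) != spec$output_dim) {
    stop("target has ", ncol(target), " columns, spec expects ",
         spec$output_dim)
  }
  widths <- c(spec$input_dim, spec$encoder_widths, spec$bottleneck,
              spec$decoder_widths, spec$output_dim)
  L <- length(widths) - 1L
  act <- c(rep("relu", L - 1L), "linear")
  n_enc <- length(spec$encoder_widths) + 1L # layers up to the bottleneck
  d_tgt <- ncol(target)
  loss_curve <- numeric(spec$epochs)
  snap <- NULL
  with_seed(spec$seed, {
    net <- nn_init(widths, act, out_bias = colMeans(target))
    st <- adam_init(net)
    for (ep in seq_len(spec$epochs)) {
      ord <- sample.int(n)
      total <- 0
      for (b0 in seq.int(1L, n, by = spec$batch_size)) {
        rows <- ord[b0:min(b0 + spec$batch_size - 1L, n)]
        A <- nn_forward(net, source[rows, , drop = FALSE], cache = TRUE)
        pred <- A[[length(A)]]
        err <- pred - target[rows, , drop = FALSE]
        mse <- mean(err * err)
        total <- total + mse * length(rows)
        grads <- nn_backward(net, A, 2 * err / length(err))
        adam_step(net, st, grads, spec$learning_rate)
      }
      loss_curve[ep] <- total / n
      if (!is.finite(loss_curve[ep])) {
        stop("non-finite training loss at epoch ", ep)
      }
    }
    snap <- nn_snapshot(net)
  })
  structure(
    list(net = snap, n_encoder_layers = n_enc, spec = spec,
         loss_curve = loss_curve),
    class = "hybrid_autoencoder"
  )
}

#' @export
print.hybrid_autoencoder <- function(x, ...) {
  cat("<hybrid_autoencoder> ", paste(x$net$widths, collapse = "-"),
      "; trained ", length(x$loss_curve), " epochs, final MSE ",
      signif(x$loss_curve[length(x$loss_curve)], 4), "\n", sep = "")
  invisible(x)
}

#' Encode embeddings into bottleneck latents
#'
#' Applies only the encoder stack (through the bottleneck) of a trained
#' hybrid autoencoder; decoder parameters play no role.
#'
#' @param ae a [train_hybrid_autoencoder()] model.
#' @param matrix n x d matrix of (rescaled) source-modality embeddings.
#' @return n x bottleneck latent matrix (u for the image autoencoder, v
#'   for the sequence autoencoder).
#' @export
encode_latents <- function(ae, matrix) {
  stopifnot(inherits(ae, "hybrid_autoencoder"))
  x <- as.matrix(matrix)
  net <- nn_from_snapshot(ae$net)
  nn_forward(net, x, from = 1L, to = ae$n_encoder_layers)
}

#' Reconstruct the target modality from source embeddings
#'
#' Full forward pass (encoder + decoder) of a trained hybrid autoencoder.
#'
#' @inheritParams encode_latents
#' @return n x d_tgt matrix of reconstructed target embeddings.
#' @export
reconstruct <- function(ae, matrix) {
  stopifnot(inherits(ae, "hybrid_autoencoder"))
  net <- nn_from_snapshot(ae$net)
  nn_forward(net, as.matrix(matrix))
}

#' Cross-reconstruction quality report
#'
#' For each patient, the cosine similarity between the true target-modality
#' embedding and its cross-modal reconstruction, plus the overall
#' mean-squared error. Samples whose true or reconstructed vector has zero
#' norm have undefined cosine and are reported as `NA` with a warning.
#'
#' @param ae a trained [train_hybrid_autoencoder()] model.
#' @param source n x d_src source-modality matrix.
#' @param target n x d_tgt target-modality matrix (row-aligned).
#' @return A list of class `"reconstruction_report"`: `cosine` (per-sample),
#'   `mse`, and `cosine_summary` (median and quartiles over defined values).
#' @export
reconstruction_report <- function(ae, source, target) {
  source <- as.matrix(source)
  target <- as.matrix(target)
  if (nrow(source) != nrow(target)) stop("source/target must be row-aligned")
  rec <- reconstruct(ae, source)
  err <- rec - target
  mse <- mean(err * err)
  num <- rowSums(rec * target)
  den <- sqrt(rowSums(rec * rec)) * sqrt(rowSums(target * target))
  cosine <- ifelse(den > 0, num / den, NA_real_)
  if (anyNA(cosine)) {
    warning(sum(is.na(cosine)),
            " sample(s) with zero-norm vector: cosine undefined")
  }
  qs <- quantile(cosine, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  structure(
    list(cosine = cosine, mse = mse,
         cosine_summary = c(q1 = qs[1], median = qs[2], q3 = qs[3])),
    class = "reconstruction_report"
  )
}

#' @export
print.reconstruction_report <- function(x, ...) {
  cat("<reconstruction_report> n = ", length(x$cosine),
      "; MSE = ", signif(x$mse, 4),
      "; cosine median = ", signif(x$cosine_summary["median"], 4),
      " [Q1 ", signif(x$cosine_summary["q1"], 4),
      ", Q3 ", signif(x$cosine_summary["q3"], 4), "]\n", sep = "")
  invisible(x)
}
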