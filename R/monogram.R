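#' Specify the monogram fusion network
#'
#' The fusion ("Q") network takes a patient's latent pair (u, v), forms
#' their outer product (latent_dim x latent_dim), flattens it row-major,
#' and passes it through dense layers (defaults 1024 and 256, rectifier)
#' to a 64-unit tanh output reshaped into an 8x8 real monogram. It is
#' trained with a triplet margin loss over hard-mined triplets, refreshed
#' every epoch, using Adam.
#'
#' @param latent_dim width of each latent (default 128).
#' @param hidden_widths widths of the two hidden dense layers.
#' @param margin triplet margin alpha (> 0), default 1.
#' @param epochs training epochs (default 150).
#' @param learning_rate Adam learning rate (default 1e-5).
#' @param batch_size triplets per gradient update; `NULL` (the default)
#'   uses the whole refreshed triplet set in one update per epoch.
#'   Full-batch updates give a better-conditioned gradient and avoid many
#'   small dense updates of the large fusion layer, whose parameter count
#'   (latent_dim^2 x 1024) dominates the cost of every update.
#' @param mining `"hard"` (farthest positive, closest negative on the
#'   concatenated latents) or `"random"` (uniform valid choices).
#' @param threshold binarization threshold theta; bits are 1 where the
#'   tanh output strictly exceeds it (default 0, the sign rule).
#' @param seed integer seed for initialization, shuffling and random mining.
#' @return An object of class `"monogram_spec"`. The output width is fixed
#'   at 64 = 8 x 8; the code space therefore holds 2^64 distinct monograms.
#' @export
monogram_spec <- function(latent_dim = 128L, hidden_widths = c(1024L, 256L),
                          margin = 1, epochs = 150L, learning_rate = 1e-5,
                          batch_size = NULL, mining = c("hard", "random"),
                          threshold = 0, seed = 1L) {
  mining <- match.arg(mining)
  stopifnot(latent_dim >= 1, all(hidden_widths >= 1), margin > 0,
            epochs >= 1, learning_rate > 0,
            is.null(batch_size) || batch_size >= 1)
  structure(
    list(latent_dim = as.integer(latent_dim),
         hidden_widths = as.integer(hidden_widths),
         n_bits = 64L,
         margin = margin,
         epochs = as.integer(epochs),
         learning_rate = learning_rate,
         batch_size = if (is.null(batch_size)) NULL else
           as.integer(batch_size),
         mining = mining,
         threshold = threshold,
         seed = as.integer(seed)),
    class = "monogram_spec"
  )
}

#' Outer-product fusion of a latent pair
#'
#' Fuses the image latent u and sequence latent v into the rank-1 matrix
#' `M[i, j] = u[i] * v[j]`, the joint feature grid the monogram network
#' operates on.
#'
#' @param u,v numeric vectors of equal length.
#' @return length(u) x length(v) matrix.
#' @examples
#' outer_fuse(c(1, 0), c(0, 2))
#' @export
outer_fuse <- function(u, v) {
  u <- as.numeric(u)
  v <- as.numeric(v)
  if (length(u) != length(v)) {
    stop("latent lengths differ: ", length(u), " vs ", length(v))
  }
  outer(u, v)
}

# Row-major flatten of the outer products of row-aligned latent matrices:
# row r of the result is c(t(outer(U[r, ], V[r, ]))), i.e. cell (i, j) of
# the fusion matrix sits at column (i-1)*l + j.
fuse_rows <- function(U, V) {
  l <- ncol(U)
  stopifnot(ncol(V) == l, nrow(U) == nrow(V))
  U[, rep(seq_len(l), each = l), drop = FALSE] *
    V[, rep(seq_len(l), times = l), drop = FALSE]
}

# Internal constructor for the fusion network given a spec.
monogram_net_init <- function(spec) {
  widths <- c(spec$latent_dim^2, spec$hidden_widths, spec$n_bits)
  L <- length(widths) - 1L
  nn_init(widths, c(rep("relu", L - 1L), "tanh"))
}

#' Triplet margin loss
#'
#' `max(d(a, p) - d(a, n) + margin, 0)` where d is the Euclidean distance
#' over the 64 real monogram values: same-diagnosis pairs are pulled
#' together, different-diagnosis pairs pushed at least `margin` further
#' apart.
#'
#' @param m_a,m_p,m_n real monograms (8x8 matrices or length-64 vectors) of
#'   the anchor, positive and negative case.
#' @param margin margin alpha > 0.
#' @return Non-negative scalar loss.
#' @examples
#' a <- matrix(0, 8, 8); p <- matrix(0.1, 8, 8); n <- matrix(0.9, 8, 8)
#' triplet_loss(a, p, n, margin = 1)
#' @export
triplet_loss <- function(m_a, m_p, m_n, margin = 1) {
  a <- as.numeric(m_a)
  p <- as.numeric(m_p)
  n <- as.numeric(m_n)
  if (length(p) != length(a) || length(n) != length(a)) {
    stop("monogram shapes differ")
  }
  stopifnot(margin > 0)
  d_ap <- sqrt(sum((a - p)^2))
  d_an <- sqrt(sum((a - n)^2))
  max(d_ap - d_an + margin, 0)
}

#' Mine triplets from latent pairs
#'
#' Builds one (anchor, positive, negative) triplet per eligible anchor.
#' In `"hard"` mode the positive is the same-label sample with the
#' \emph{largest} Euclidean distance to the anchor and the negative the
#' different-label sample with the \emph{smallest} distance, both measured
#' on the concatenated latents `[u; v]`; ties break toward the lowest
#' index. In `"random"` mode both are uniform over the valid candidates.
#' Anchors whose class has no other member are skipped with a warning.
#'
#' @param U,V n x latent_dim matrices of image and sequence latents.
#' @param labels diagnosis label per row.
#' @param mode `"hard"` or `"random"`.
#' @param seed seed used in `"random"` mode (and for reproducibility of
#'   the call); `NULL` uses the current RNG stream.
#' @return data.frame of class `"triplet_set"` with integer columns
#'   `anchor`, `positive`, `negative` (row indices into U/V).
#' @export
mine_triplets <- function(U, V, labels, mode = c("hard", "random"),
                          seed = NULL) {
  mode <- match.arg(mode)
  U <- as.matrix(U)
  V <- as.matrix(V)
  labels <- as.character(labels)
  n <- nrow(U)
  stopifnot(nrow(V) == n, length(labels) == n)
  if (length(unique(labels)) < 2L) {
    stop("triplet mining needs at least 2 classes")
  }
  feat <- cbind(U, V)
  res <- with_seed(seed, {
    D <- NULL
    if (mode == "hard") D <- as.matrix(stats::dist(feat))
    out <- matrix(NA_integer_, n, 3L)
    skipped <- character(0)
    for (a in seq_len(n)) {
      pos_cand <- which(labels == labels[a])
      pos_cand <- pos_cand[pos_cand != a]
      neg_cand <- which(labels != labels[a])
      if (length(pos_cand) == 0L) {
        skipped <- c(skipped, labels[a])
        next
      }
      if (mode == "hard") {
        p <- pos_cand[which.max(D[a, pos_cand])]
        ng <- neg_cand[which.min(D[a, neg_cand])]
      } else {
        p <- pos_cand[sample.int(length(pos_cand), 1L)]
        ng <- neg_cand[sample.int(length(neg_cand), 1L)]
      }
      out[a, ] <- c(a, p, ng)
    }
    list(out = out, skipped = skipped)
  })
  if (length(res$skipped) > 0L) {
    warning("skipped ", length(res$skipped),
            " anchor(s) from singleton class(es): ",
            paste(unique(res$skipped), collapse = ", "))
  }
  keep <- !is.na(res$out[, 1L])
  structure(
    data.frame(anchor = res$out[keep, 1L], positive = res$out[keep, 2L],
               negative = res$out[keep, 3L]),
    class = c("triplet_set", "data.frame")
  )
}

#' Train the monogram fusion network with triplet loss
#'
#' Conceptually the network has three weight-sharing branches (anchor,
#' positive, negative); it is implemented as a single network applied to
#' each triplet member, which enforces the sharing exactly. Each epoch the
#' triplet set is refreshed (re-mined in hard mode, re-sampled in random
#' mode), shuffled, and consumed in minibatches; the loss is the mean
#' triplet margin loss over the epoch's triplets, computed on the
#' \emph{real-valued} monograms (binarization is applied only at
#' inference). Deterministic given `spec$seed`.
#'
#' @param U,V n x latent_dim training latents (row-aligned).
#' @param labels diagnosis label per row; at least 2 classes.
#' @param spec a [monogram_spec()].
#' @return An object of class `"monogram_model"`: trained weight snapshot,
#'   the spec, and `loss_curve` (mean triplet loss per epoch).
#' @export
train_monogram_model <- function(U, V, labels, spec) {
  stopifnot(inherits(spec, "monogram_spec"))
  U <- as.matrix(U)
  V <- as.matrix(V)
  labels <- as.character(labels)
  n <- nrow(U)
  stopifnot(nrow(V) == n, length(labels) == n)
  if (ncol(U) != spec$latent_dim || ncol(V) != spec$latent_dim) {
    stop("latent width must be ", spec$latent_dim)
  }
  if (length(unique(labels)) < 2L) stop("need at least 2 classes")
  X <- fuse_rows(U, V) # fused input per patient, fixed during training
  loss_curve <- numeric(spec$epochs)
  snap <- NULL
  with_seed(spec$seed, {
    net <- monogram_net_init(spec)
    st <- adam_init(net)
    for (ep in seq_len(spec$epochs)) {
      trip <- suppressWarnings(
        mine_triplets(U, V, labels, mode = spec$mining, seed = NULL)
      )
      nt <- nrow(trip)
      if (nt == 0L) stop("no valid triplets to train on")
      trip <- trip[sample.int(nt), , drop = FALSE]
      total <- 0
      bs <- if (is.null(spec$batch_size)) nt else spec$batch_size
      for (b0 in seq.int(1L, nt, by = bs)) {
        tb <- trip[b0:min(b0 + bs - 1L, nt), , drop = FALSE]
        nb <- nrow(tb)
        members <- c(tb$anchor, tb$positive, tb$negative)
        rows <- sort(unique(members)) # each patient forwarded once
        pos_of <- match(members, rows)
        A <- nn_forward(net, X[rows, , drop = FALSE], cache = TRUE)
        out <- A[[length(A)]]
        ia <- pos_of[seq_len(nb)]
        ip <- pos_of[nb + seq_len(nb)]
        im <- pos_of[2L * nb + seq_len(nb)]
        dap_v <- out[ia, , drop = FALSE] - out[ip, , drop = FALSE]
        dan_v <- out[ia, , drop = FALSE] - out[im, , drop = FALSE]
        d_ap <- sqrt(rowSums(dap_v^2))
        d_an <- sqrt(rowSums(dan_v^2))
        hinge <- d_ap - d_an + spec$margin
        active <- hinge > 0
        total <- total + sum(pmax(hinge, 0))
        # Gradient of the mean hinge loss w.r.t. the three outputs; unit
        # vectors (m_a - m_p)/d_ap etc., guarded against zero distances.
        gA <- matrix(0, nb, spec$n_bits)
        gP <- matrix(0, nb, spec$n_bits)
        gN <- matrix(0, nb, spec$n_bits)
        ok_p <- active & d_ap > 1e-12
        ok_n <- active & d_an > 1e-12
        if (any(ok_p)) {
          u_ap <- dap_v[ok_p, , drop = FALSE] / d_ap[ok_p]
          gA[ok_p, ] <- gA[ok_p, , drop = FALSE] + u_ap
          gP[ok_p, ] <- -u_ap
        }
        if (any(ok_n)) {
          u_an <- dan_v[ok_n, , drop = FALSE] / d_an[ok_n]
          gA[ok_n, ] <- gA[ok_n, , drop = FALSE] - u_an
          gN[ok_n, ] <- u_an
        }
        G <- rbind(gA, gP, gN) / nb
        dOut <- rowsum(G, pos_of) # collapses repeated member rows
        # rowsum orders groups by sorted unique pos_of == seq_along(rows)
        grads <- nn_backward(net, A, dOut)
        adam_step(net, st, grads, spec$learning_rate)
      }
      loss_curve[ep] <- total / nt
      if (!is.finite(loss_curve[ep])) {
        stop("non-finite triplet loss at epoch ", ep)
      }
    }
    snap <- nn_snapshot(net)
  })
  structure(
    list(net = snap, spec = spec, loss_curve = loss_curve),
    class = "monogram_model"
  )
}

#' @export
print.monogram_model <- function(x, ...) {
  cat("<monogram_model> latent ", x$spec$latent_dim, " -> ",
      paste(x$net$widths[-1L], collapse = "-"),
      " (8x8 tanh); ", length(x$loss_curve), " epochs, final loss ",
      signif(x$loss_curve[length(x$loss_curve)], 4), "\n", sep = "")
  invisible(x)
}

#' Forward one latent pair to a real-valued monogram
#'
#' Outer product, row-major flatten, dense layers, tanh; the 64 outputs
#' are reshaped row-major into an 8x8 matrix with values strictly inside
#' (-1, 1).
#'
#' @param model a [train_monogram_model()] model.
#' @param u,v latent vectors of length `latent_dim`.
#' @return 8x8 numeric matrix (the real monogram).
#' @export
forward_monogram <- function(model, u, v) {
  out <- forward_monograms(model, matrix(as.numeric(u), nrow = 1L),
                           matrix(as.numeric(v), nrow = 1L))
  matrix(out[1L, ], 8L, 8L, byrow = TRUE)
}

#' Forward a batch of latent pairs
#'
#' @param model a [train_monogram_model()] model.
#' @param U,V n x latent_dim matrices.
#' @return n x 64 matrix; row r holds patient r's real monogram in
#'   row-major order.
#' @export
forward_monograms <- function(model, U, V) {
  stopifnot(inherits(model, "monogram_model"))
  U <- as.matrix(U)
  V <- as.matrix(V)
  if (ncol(U) != model$spec$latent_dim || ncol(V) != model$spec$latent_dim) {
    stop("latent width must be ", model$spec$latent_dim)
  }
  net <- nn_from_snapshot(model$net)
  nn_forward(net, fuse_rows(U, V))
}

#' Binarize a real monogram
#'
#' Bits are 1 where the tanh output strictly exceeds the threshold and 0
#' otherwise (a value exactly at the threshold maps to 0). The default
#' threshold 0 is the sign rule: positive values become 1, negative 0.
#'
#' @param m real monogram (matrix or vector) or a batch matrix of
#'   row-major monograms.
#' @param threshold scalar theta, default 0.
#' @return Integer 0/1 object of the same shape.
#' @examples
#' binarize(matrix(c(-0.3, 0.7, 0, 0.1), 2, 2))
#' @export
binarize <- function(m, threshold = 0) {
  out <- m
  out[] <- as.integer(m > threshold)
  storage.mode(out) <- "integer"
  out
}

#' Encode a cohort's latents into a monogram archive
#'
#' Runs every patient through the trained fusion network and stores the
#' binarized 64-bit code (and, optionally, the real-valued monogram)
#' under the patient's id and label.
#'
#' @param model a [train_monogram_model()] model.
#' @param patient_id,labels id and diagnosis per row of U/V.
#' @param U,V n x latent_dim latent matrices.
#' @param keep_real keep the real-valued monograms for real-vs-binary
#'   comparisons (default TRUE).
#' @return A [monogram_archive()] with one record per patient.
#' @export
encode_monograms <- function(model, patient_id, labels, U, V,
                             keep_real = TRUE) {
  real <- forward_monograms(model, U, V)
  bits <- binarize(real, model$spec$threshold)
  monogram_archive(patient_id, labels, bits,
                   real = if (keep_real) real else NULL)
}
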