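# Dense feed-forward core shared by the cross-modal autoencoders and the
# monogram fusion network. Layers are plain matrices driven by BLAS; the
# Adam update is the fused C++ loop in src/adam.cpp. Parameters live in an
# environment so the optimizer can update them in place; a trained model
# snapshots them into an ordinary list.

# widths: vector of layer sizes, length L+1 (input .. output).
# act: activation tag per layer, length L, each of "relu", "tanh", "linear".
# Weights: fan-scaled uniform (Glorot); biases zero unless `out_bias` is
# supplied, which seeds the final layer's bias (used to start cross-modal
# decoders at the target column means). Draws from the current RNG stream.
nn_init <- function(widths, act, out_bias = NULL) {
  stopifnot(length(act) == length(widths) - 1L, length(act) >= 1L)
  stopifnot(all(act %in% c("relu", "tanh", "linear")))
  net <- new.env(parent = emptyenv())
  net$widths <- as.integer(widths)
  net$act <- act
  L <- length(act)
  net$W <- vector("list", L)
  net$b <- vector("list", L)
  for (l in seq_len(L)) {
    fin <- widths[l]
    fout <- widths[l + 1L]
    lim <- sqrt(6 / (fin + fout))
    net$W[[l]] <- matrix(runif(fin * fout, -lim, lim), fin, fout)
    net$b[[l]] <- numeric(fout)
  }
  if (!is.null(out_bias)) {
    stopifnot(length(out_bias) == widths[L + 1L])
    net$b[[L]] <- as.numeric(out_bias)
  }
  net
}

nn_apply_act <- function(Z, tag) {
  switch(tag,
    relu = {
      Z[Z < 0] <- 0
      Z
    },
    tanh = tanh(Z),
    linear = Z
  )
}

# Forward pass over rows of X through layers `from`..`to`.
# Returns the output matrix, or (cache = TRUE) a list of post-activation
# matrices A[[1]] = X .. A[[L+1]] = output for backprop.
nn_forward <- function(net, X, from = 1L, to = length(net$W), cache = FALSE) {
  if (ncol(X) != net$widths[from]) {
    stop("input width ", ncol(X), " does not match layer width ",
         net$widths[from])
  }
  layers <- seq.int(from, to)
  A <- vector("list", length(layers) + 1L)
  A[[1L]] <- X
  for (i in seq_along(layers)) {
    l <- layers[i]
    Z <- A[[i]] %*% net$W[[l]]
    Z <- Z + rep(net$b[[l]], each = nrow(Z))
    A[[i + 1L]] <- nn_apply_act(Z, net$act[l])
  }
  if (cache) A else A[[length(A)]]
}

# Backward pass. `A` is the cache from nn_forward(cache = TRUE) over the
# full network, `dOut` the loss gradient w.r.t. the output activations.
# The gradient w.r.t. the input X is never needed (inputs are fixed
# embeddings / fused latents), so it is not computed.
nn_backward <- function(net, A, dOut) {
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  dA <- dOut
  for (l in rev(seq_len(L))) {
    Al <- A[[l + 1L]]
    dZ <- switch(net$act[l],
      linear = dA,
      relu = dA * (Al > 0),
      tanh = dA * (1 - Al * Al)
    )
    gW[[l]] <- crossprod(A[[l]], dZ)
    gb[[l]] <- colSums(dZ)
    if (l > 1L) dA <- dZ %*% t(net$W[[l]])
  }
  list(W = gW, b = gb)
}

adam_init <- function(net) {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$mW <- lapply(net$W, function(w) array(0, dim(w)))
  st$vW <- lapply(net$W, function(w) array(0, dim(w)))
  st$mb <- lapply(net$b, function(b) numeric(length(b)))
  st$vb <- lapply(net$b, function(b) numeric(length(b)))
  st
}

adam_step <- function(net, st, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  for (l in seq_along(net$W)) {
    adam_update_inplace(net$W[[l]], st$mW[[l]], st$vW[[l]], grads$W[[l]],
                        lr, beta1, beta2, eps, st$t)
    adam_update_inplace(net$b[[l]], st$mb[[l]], st$vb[[l]], grads$b[[l]],
                        lr, beta1, beta2, eps, st$t)
  }
  invisible(NULL)
}

# Deep-copy a trained net's parameters into a plain list snapshot.
nn_snapshot <- function(net) {
  list(
    widths = net$widths,
    act = net$act,
    W = lapply(net$W, function(w) w + 0),
    b = lapply(net$b, function(b) b + 0)
  )
}

# Rehydrate a snapshot into the environment form nn_forward expects.
nn_from_snapshot <- function(snap) {
  net <- new.env(parent = emptyenv())
  net$widths <- snap$widths
  net$act <- snap$act
  net$W <- snap$W
  net$b <- snap$b
  net
}
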