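# Matrix-algebra core of the window classifier.
#
# The network maps an E x W window (with a column mask) to K class logits:
#   entry conv1D kernel-1 (E -> F), then a residual bottleneck branch
#   conv1D kernel-3 (F -> Fb) -> ReLU -> conv1D kernel-3 (Fb -> F) added to
#   the skip path, ReLU, masked max-pool over the window (F x 1), linear
#   layer to K classes. Convolutions use same-padding and are computed as
#   dense products over im2col-expanded inputs. Batches are laid out as
#   C x (W*B) matrices, columns grouped by window.

nn_init_params <- function(E, W, F, Fb, K, seed) {
  he <- function(nr, nc, fan_in) {
    matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  }
  with_seed(derive_seed(seed, "init"), {
    list(
      W_in  = he(F, E, E),       b_in  = rep(0, F),
      W1    = he(Fb, 3L * F, 3L * F),  b1 = rep(0, Fb),
      W2    = he(F, 3L * Fb, 3L * Fb), b2 = rep(0, F),
      W_out = he(K, F, F),       b_out = rep(0, K)
    )
  })
}

# kernel-3 same-padding neighbourhood expansion: C x (W*B) -> 3C x (W*B),
# windows independent (no bleed across the window boundary).
nn_im2col <- function(M, W, B) {
  C <- nrow(M)
  idx <- seq_len(W * B)
  w <- ((idx - 1L) %% W) + 1L
  prev <- ifelse(w > 1L, idx - 1L, 0L)
  nxt <- ifelse(w < W, idx + 1L, 0L)
  Mpad <- cbind(matrix(0, C, 1L), M)
  rbind(Mpad[, prev + 1L, drop = FALSE],
        M,
        Mpad[, nxt + 1L, drop = FALSE])
}

# Adjoint of nn_im2col: fold a 3C x (W*B) gradient back to C x (W*B).
nn_col2im <- function(G, C, W, B) {
  idx <- seq_len(W * B)
  w <- ((idx - 1L) %% W) + 1L
  Gprev <- G[seq_len(C), , drop = FALSE]
  Gmid  <- G[C + seq_len(C), , drop = FALSE]
  Gnext <- G[2L * C + seq_len(C), , drop = FALSE]
  src_from_prev <- ifelse(w < W, idx + 1L, 0L)   # our column sits in the
  src_from_next <- ifelse(w > 1L, idx - 1L, 0L)  # prev/next slot there
  Gp <- cbind(matrix(0, C, 1L), Gprev)
  Gn <- cbind(matrix(0, C, 1L), Gnext)
  Gmid + Gp[, src_from_prev + 1L, drop = FALSE] +
    Gn[, src_from_next + 1L, drop = FALSE]
}

# X: E x (W*B); mask: logical W x B. Returns logits K x B plus a cache for
# the backward pass.
nn_forward <- function(params, X, W, B, mask, keep_cache = TRUE) {
  F <- nrow(params$W_in)
  H0 <- params$W_in %*% X + params$b_in
  I1 <- nn_im2col(H0, W, B)
  C1 <- params$W1 %*% I1 + params$b1
  A1 <- relu(C1)
  I2 <- nn_im2col(A1, W, B)
  C2 <- params$W2 %*% I2 + params$b2
  Z <- H0 + C2
  H1 <- relu(Z)
  # masked max-pool over the window: padded columns can never win
  Hm <- H1
  if (!all(mask)) {
    Hm[, !as.vector(mask)] <- -Inf
  }
  P <- matrix(-Inf, F, B)
  amax <- matrix(1L, F, B)
  for (w in seq_len(W)) {
    col <- Hm[, (seq_len(B) - 1L) * W + w, drop = FALSE]
    upd <- col > P
    amax[upd] <- w
    P[upd] <- col[upd]
  }
  logits <- params$W_out %*% P + params$b_out
  cache <- if (keep_cache) {
    list(X = X, H0 = H0, I1 = I1, C1 = C1, A1 = A1, I2 = I2, Z = Z,
         P = P, amax = amax, W = W, B = B)
  }
  list(logits = logits, cache = cache)
}

# dlogits: K x B. Returns a gradient list with the same shapes as params.
nn_backward <- function(params, cache, dlogits) {
  F <- nrow(params$W_in)
  Fb <- nrow(params$W1)
  W <- cache$W; B <- cache$B
  dW_out <- dlogits %*% t(cache$P)
  db_out <- rowSums(dlogits)
  dP <- t(params$W_out) %*% dlogits
  # unpool: route each pooled gradient to its argmax column
  dH1 <- matrix(0, F, W * B)
  cols <- (rep(seq_len(B), each = F) - 1L) * W + as.vector(cache$amax)
  lin <- (cols - 1L) * F + rep(seq_len(F), times = B)
  dH1[lin] <- as.vector(dP)
  dZ <- dH1 * (cache$Z > 0)
  dC2 <- dZ
  dW2 <- dC2 %*% t(cache$I2)
  db2 <- rowSums(dC2)
  dA1 <- nn_col2im(t(params$W2) %*% dC2, Fb, W, B)
  dC1 <- dA1 * (cache$C1 > 0)
  dW1 <- dC1 %*% t(cache$I1)
  db1 <- rowSums(dC1)
  dH0 <- dZ + nn_col2im(t(params$W1) %*% dC1, F, W, B)
  dW_in <- dH0 %*% t(cache$X)
  db_in <- rowSums(dH0)
  list(W_in = dW_in, b_in = db_in, W1 = dW1, b1 = db1,
       W2 = dW2, b2 = db2, W_out = dW_out, b_out = db_out)
}

# Softmax cross-entropy over a batch; y: integer class per column.
# Returns loss and dlogits (already averaged over the batch).
nn_softmax_ce <- function(logits, y) {
  B <- ncol(logits)
  probs <- softmax_cols(logits)
  picked <- probs[cbind(y, seq_len(B))]
  loss <- -mean(log(pmax(picked, 1e-300)))
  dlogits <- probs
  dlogits[cbind(y, seq_len(B))] <- dlogits[cbind(y, seq_len(B))] - 1
  list(loss = loss, dlogits = dlogits / B)
}

adam_init <- function(params) {
  zeros <- lapply(params, function(p) p * 0)
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Stack a list of windows into (X matrix E x (W*B), mask W x B, labels).
nn_batch <- function(windows) {
  B <- length(windows)
  W <- ncol(windows[[1L]]$slice)
  E <- nrow(windows[[1L]]$slice)
  X <- matrix(0, E, W * B)
  mask <- matrix(TRUE, W, B)
  y <- integer(B)
  for (b in seq_len(B)) {
    X[, (b - 1L) * W + seq_len(W)] <- windows[[b]]$slice
    mask[, b] <- windows[[b]]$mask
    y[b] <- windows[[b]]$label
  }
  list(X = X, mask = mask, y = y, W = W, B = B)
}
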