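# Internal helpers shared across modules.

# Deterministic 31-bit hash of a character/integer mix, for deriving
# independent sub-seeds from one user-facing seed. Never returns 0.
derive_seed <- function(seed, ...) {
  salts <- unlist(lapply(list(...), as.character), use.names = FALSE)
  h <- as.double(seed %% 2147483647L)
  m <- 2147483647
  for (s in salts) {
    for (code in utf8ToInt(s)) {
      h <- (h * 31 + code) %% m
    }
  }
  as.integer(max(1, h))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

# Column-wise softmax of a matrix of logits (classes in rows).
softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max), "-")
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

# Row-wise softmax (classes in columns).
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# argmax with ties broken by lowest index (which.max's contract).
argmax1 <- function(x) which.max(x)

relu <- function(x) {
  x[x < 0] <- 0
  x
}

stopifnot_scalar_int <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}
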