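# small internal helpers shared across modules

sigmoid <- function(x) 1 / (1 + exp(-x))

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# add a bias row-wise to a B x h matrix (column-major broadcast)
add_bias <- function(M, b) M + rep(b, each = nrow(M))

# log-sum-exp by rows, numerically stable
row_softmax <- function(logits) {
  mx <- apply(logits, 1L, max)
  e <- exp(logits - mx)
  e / rowSums(e)
}
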