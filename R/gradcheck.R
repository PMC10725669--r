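# flatten/unflatten the trainable cell weights for numeric gradient checks

params_flatten <- function(params) {
  unlist(lapply(cell_weight_names(params), function(nm)
    as.vector(params[[nm]])), use.names = FALSE)
}

params_unflatten <- function(params, vec) {
  pos <- 0L
  for (nm in cell_weight_names(params)) {
    w <- params[[nm]]
    n <- length(w)
    val <- vec[pos + seq_len(n)]
    params[[nm]] <- if (is.matrix(w)) matrix(val, nrow(w), ncol(w)) else val
    pos <- pos + n
  }
  params
}

# forward-only scalar loss used by the finite-difference probe
gc_loss <- function(Xs, phars, mask, params, head, gold_idx, lambda) {
  H <- rnn_forward(Xs, phars, mask, params)$H
  cross_entropy_loss(H, gold_idx, head, lambda = lambda)
}

#' Check analytic gradients against central finite differences
#'
#' Builds a small random problem for the requested cell variant (random
#' weights, inputs and a padded mask), computes the analytic gradient of a
#' cross-entropy loss with respect to every cell weight and the head, and
#' compares each coordinate with a central finite difference. The returned
#' maximum relative error should be well below 1e-4 for a correct
#' backward pass.
#'
#' @param variant one of [lstm_variants()]
#' @param hidden_size,input_dim,p_dim,T_len,batch small problem dimensions
#' @param n_classes head size
#' @param seed RNG seed
#' @param eps finite-difference step
#' @param lambda ridge weight (exercises the head regularizer)
#' @param conventional_gate_roles see [cell_params()]
#' @return list with `max_rel_error`, per-parameter-block errors
#'   (`by_block`), and the problem dimensions
#' @export
check_gradients <- function(variant, hidden_size = 3L, input_dim = 2L,
                            p_dim = 2L, T_len = 3L, batch = 2L,
                            n_classes = 2L, seed = 1L, eps = 1e-5,
                            lambda = 0.01,
                            conventional_gate_roles = FALSE) {
  params <- cell_params(variant, input_dim = input_dim,
                        hidden_size = hidden_size, p_dim = p_dim,
                        seed = seed,
                        conventional_gate_roles = conventional_gate_roles)
  head <- classifier_head(n_classes, hidden_size, seed = seed + 1L)
  with_seed(seed + 2L, {
    Xs <- lapply(seq_len(T_len), function(t)
      matrix(stats::rnorm(batch * input_dim, sd = 0.5), batch, input_dim))
    phars <- lapply(seq_len(T_len), function(t)
      matrix(stats::runif(batch * 4L), batch, 4L))
    mask <- matrix(1, batch, T_len)
    if (batch > 1L && T_len > 1L) mask[1L, T_len] <- 0  # exercise padding
    gold_idx <- sample.int(n_classes, batch, replace = TRUE)
  })
  # analytic gradients
  fwd <- rnn_forward(Xs, phars, mask, params, keep_cache = TRUE)
  B <- batch
  logits <- add_bias(tcrossprod(fwd$H, head$W), head$b)
  mx <- apply(logits, 1L, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  probs <- exp(logits - lse)
  dlogits <- probs
  dlogits[cbind(seq_len(B), gold_idx)] <-
    dlogits[cbind(seq_len(B), gold_idx)] - 1
  dlogits <- dlogits / B
  gW_head <- crossprod(dlogits, fwd$H) + lambda * head$W
  gb_head <- colSums(dlogits)
  dHn <- dlogits %*% head$W
  bwd <- rnn_backward(dHn, fwd$caches, params)
  analytic <- c(params_flatten(bwd$grads), as.vector(gW_head), gb_head)
  # numeric gradients
  theta <- c(params_flatten(params), as.vector(head$W), head$b)
  n_cell <- length(params_flatten(params))
  n_W <- length(head$W)
  rebuild <- function(v) {
    p2 <- params_unflatten(params, v[seq_len(n_cell)])
    h2 <- head
    h2$W <- matrix(v[n_cell + seq_len(n_W)], nrow(head$W), ncol(head$W))
    h2$b <- v[n_cell + n_W + seq_along(head$b)]
    list(p = p2, h = h2)
  }
  numeric_g <- vapply(seq_along(theta), function(i) {
    up <- theta; up[i] <- up[i] + eps
    dn <- theta; dn[i] <- dn[i] - eps
    ru <- rebuild(up); rd <- rebuild(dn)
    (gc_loss(Xs, phars, mask, ru$p, ru$h, gold_idx, lambda) -
     gc_loss(Xs, phars, mask, rd$p, rd$h, gold_idx, lambda)) / (2 * eps)
  }, numeric(1))
  rel <- abs(analytic - numeric_g) / pmax(abs(analytic) + abs(numeric_g), 1e-4)
  blocks <- c(unlist(lapply(cell_weight_names(params), function(nm)
    rep(nm, length(params[[nm]])))), rep("head_W", n_W),
    rep("head_b", length(head$b)))
  list(max_rel_error = max(rel),
       by_block = tapply(rel, blocks, max),
       dims = c(hidden = hidden_size, d = input_dim, p = p_dim,
                T = T_len, B = batch),
       variant = params$variant)
}
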