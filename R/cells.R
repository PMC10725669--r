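#' The recurrent cell family
#'
#' `lstm_variants()` lists the eleven supported cells. `"PHAR"` is the
#' pharmacological cell: the 4-dimensional filter vector is passed through
#' its own sigmoid gate and concatenated with the recurrent input
#' `(H_{t-1}, x_t)` before feeding the input/forget/cell/output gates. The
#' ten variants ablate or extend it:
#' \describe{
#'   \item{NPG}{no pharmacological gate (the vanilla LSTM).}
#'   \item{NIG / NFG / NOG}{drop the gate multiplying the previous cell
#'     state / the candidate / the output (as the cell equations are
#'     published, the "input"-named gate multiplies \eqn{C_{t-1}} and the
#'     "forget"-named gate multiplies the candidate; see
#'     `conventional_gate_roles` in [cell_params()]).}
#'   \item{NIAF / NFAF / NOAF}{remove the sigmoid from the respective gate,
#'     leaving an unbounded linear gate.}
#'   \item{CIFG}{couple the two cell-state gates as \eqn{a} and \eqn{1-a}.}
#'   \item{PEEPHOLE}{append \eqn{C_{t-1}} to the input of the two
#'     cell-state gates and \eqn{C_t} to the output gate's input (full
#'     peephole matrices, not diagonal).}
#'   \item{FGR}{full gate recurrence: every gate additionally receives
#'     \eqn{(I_{t-1}, F_{t-1}, O_{t-1}, C_{t-1})}.}
#' }
#' @return character vector of variant names
#' @export
lstm_variants <- function() {
  c("PHAR", "NPG", "NIG", "NIAF", "NFG", "NFAF", "NOG", "NOAF",
    "CIFG", "PEEPHOLE", "FGR")
}

variant_traits <- function(variant) {
  v <- match.arg(variant, lstm_variants())
  list(
    variant = v,
    has_pg = v != "NPG",
    has_i = !(v %in% "NIG"),          # gate derived from W_I
    has_f = !(v %in% c("NFG", "CIFG")),  # gate derived from W_F
    has_o = v != "NOG",
    i_raw = v == "NIAF",              # identity instead of sigmoid
    f_raw = v == "NFAF",
    o_raw = v == "NOAF",
    cifg = v == "CIFG",
    peephole = v == "PEEPHOLE",
    fgr = v == "FGR")
}

gate_extra_cols <- function(tr, hidden) {
  # extra input columns (beyond P_t) of the I/F gates and the O gate
  if (tr$peephole) c(if_extra = hidden, o_extra = hidden)
  else if (tr$fgr) c(if_extra = 4L * hidden, o_extra = 4L * hidden)
  else c(if_extra = 0L, o_extra = 0L)
}

#' Initialise cell parameters
#'
#' Weights are drawn uniformly from \eqn{[-s, s]} with \eqn{s =
#' 1/\sqrt{\mathrm{fan~in}}} per matrix (biases start at zero), seeded for
#' reproducibility. Only the matrices the chosen variant uses are
#' allocated.
#'
#' @param variant one of [lstm_variants()]
#' @param input_dim token embedding dimension d
#' @param hidden_size hidden state size
#' @param p_dim output dimension of the pharmacological gate (the 4 filter
#'   values are mapped to `p_dim` gated features; default 4 keeps the
#'   filter signal at its native scale)
#' @param seed RNG seed
#' @param conventional_gate_roles if `FALSE` (default), the cell equations
#'   are evaluated exactly as published: the gate parameterised by `W_I`
#'   multiplies \eqn{C_{t-1}} and the `W_F` gate multiplies the candidate.
#'   `TRUE` swaps the two roles into the conventional LSTM arrangement
#'   (forget gate on \eqn{C_{t-1}}, input gate on the candidate).
#' @param init_scale optional fixed half-width for the uniform init
#' @return object of class `cell_params`
#' @export
cell_params <- function(variant = "PHAR", input_dim = 400L,
                        hidden_size = 128L, p_dim = 4L, seed = 1L,
                        conventional_gate_roles = FALSE,
                        init_scale = NULL) {
  tr <- variant_traits(variant)
  d <- as.integer(input_dim); h <- as.integer(hidden_size)
  p <- if (tr$has_pg) as.integer(p_dim) else 0L
  np <- p + h + d
  extras <- gate_extra_cols(tr, h)
  mk <- function(nr, nc) {
    s <- if (is.null(init_scale)) 1 / sqrt(nr) else init_scale
    matrix(stats::runif(nr * nc, -s, s), nr, nc)
  }
  params <- with_seed(seed, {
    out <- list()
    if (tr$has_pg) { out$W_P <- mk(4L, p); out$b_P <- numeric(p) }
    if (tr$has_i) {
      out$W_I <- mk(np + extras[["if_extra"]], h); out$b_I <- numeric(h)
    }
    if (tr$has_f) {
      out$W_F <- mk(np + extras[["if_extra"]], h); out$b_F <- numeric(h)
    }
    out$W_C <- mk(np, h); out$b_C <- numeric(h)
    if (tr$has_o) {
      out$W_O <- mk(np + extras[["o_extra"]], h); out$b_O <- numeric(h)
    }
    out
  })
  structure(c(params,
              list(variant = tr$variant, input_dim = d, hidden_size = h,
                   p_dim = p, n_p = np,
                   conventional_gate_roles = isTRUE(conventional_gate_roles))),
            class = "cell_params")
}

#' @export
print.cell_params <- function(x, ...) {
  cat(sprintf("<cell_params> variant=%s d=%d hidden=%d p_dim=%d (%d weights)\n",
              x$variant, x$input_dim, x$hidden_size, x$p_dim,
              sum(vapply(cell_weight_names(x), function(nm) length(x[[nm]]), 1))))
  invisible(x)
}

cell_weight_names <- function(params) {
  intersect(c("W_P", "b_P", "W_I", "b_I", "W_F", "b_F", "W_C", "b_C",
              "W_O", "b_O"), names(params))
}

zero_like_params <- function(params) {
  out <- lapply(cell_weight_names(params), function(nm) {
    w <- params[[nm]]
    if (is.matrix(w)) matrix(0, nrow(w), ncol(w)) else numeric(length(w))
  })
  stats::setNames(out, cell_weight_names(params))
}

check_shapes <- function(params, d) {
  if (params$input_dim != d)
    stop("token vector length ", d, " does not match W_C input layout (d=",
         params$input_dim, ")", call. = FALSE)
}

#' Zero recurrent state
#'
#' @param params a [cell_params()] object
#' @param batch number of parallel sequences
#' @return list with `C`, `H` (batch x hidden) and, for the FGR variant,
#'   the retained previous gate activations `I`, `F`, `O`
#' @export
cell_state <- function(params, batch = 1L) {
  h <- params$hidden_size
  z <- matrix(0, batch, h)
  st <- list(C = z, H = z)
  if (params$variant == "FGR") st <- c(st, list(I = z, F = z, O = z))
  st
}

# One batched forward step. X: B x d, phar: B x 4, state as in cell_state().
# Returns list(state = new state, cache = quantities needed for backward).
cell_forward_step <- function(state, X, phar, params, mask = NULL,
                              keep_cache = FALSE) {
  tr <- variant_traits(params$variant)
  B <- nrow(X); h <- params$hidden_size
  check_shapes(params, ncol(X))
  H_prev <- state$H; C_prev <- state$C
  z <- cbind(H_prev, X)
  if (tr$has_pg) {
    if (ncol(phar) != 4L)
      stop("phar input must have 4 columns for W_P", call. = FALSE)
    pg <- sigmoid(add_bias(phar %*% params$W_P, params$b_P))
    P <- cbind(pg, z)
  } else {
    pg <- NULL
    P <- z
  }
  Gin_if <- if (tr$peephole) cbind(P, C_prev)
            else if (tr$fgr) cbind(P, state$I, state$F, state$O, C_prev)
            else P
  gi <- if (tr$has_i) {
    a <- add_bias(Gin_if %*% params$W_I, params$b_I)
    if (tr$i_raw) a else sigmoid(a)
  } else NULL
  gf <- if (tr$cifg) 1 - gi
        else if (tr$has_f) {
    a <- add_bias(Gin_if %*% params$W_F, params$b_F)
    if (tr$f_raw) a else sigmoid(a)
  } else NULL
  ccand <- tanh(add_bias(P %*% params$W_C, params$b_C))
  if (params$conventional_gate_roles) {
    mult_prev <- gf; mult_cand <- gi
  } else {
    mult_prev <- gi; mult_cand <- gf
  }
  C_raw <- (if (is.null(mult_prev)) C_prev else mult_prev * C_prev) +
           (if (is.null(mult_cand)) ccand else mult_cand * ccand)
  Gin_o <- if (tr$peephole) cbind(P, C_raw)
           else if (tr$fgr) cbind(P, state$I, state$F, state$O, C_prev)
           else P
  go <- if (tr$has_o) {
    a <- add_bias(Gin_o %*% params$W_O, params$b_O)
    if (tr$o_raw) a else sigmoid(a)
  } else NULL
  tanhC <- tanh(C_raw)
  H_raw <- if (is.null(go)) tanhC else go * tanhC
  if (!all(is.finite(H_raw)) || !all(is.finite(C_raw)))
    stop("non-finite cell output (variant ", params$variant, ")",
         call. = FALSE)
  if (is.null(mask)) mask <- rep(1, B)
  blend <- function(new, old) new * mask + old * (1 - mask)
  new_state <- list(C = blend(C_raw, C_prev), H = blend(H_raw, H_prev))
  if (tr$fgr) {
    new_state$I <- blend(gi, state$I)
    new_state$F <- blend(gf, state$F)
    new_state$O <- blend(go, state$O)
  }
  cache <- NULL
  if (keep_cache)
    cache <- list(P = P, pg = pg, phar = phar, gi = gi, gf = gf, go = go,
                  ccand = ccand, C_prev = C_prev, C_raw = C_raw,
                  tanhC = tanhC, Ip = state$I, Fp = state$F, Op = state$O,
                  mask = mask)
  list(state = new_state, cache = cache)
}

#' Run one cell update
#'
#' Applies a single recurrent step of the configured variant to one input
#' position. For the PHAR cell the update is: gate the 4-dim filter vector,
#' concatenate with \eqn{(H_{t-1}, x_t)} to form \eqn{P_t}, then
#' \eqn{C_t = g(W_I P_t + b_I) \circ C_{t-1} + g(W_F P_t + b_F) \circ
#' \tanh(W_C P_t + b_C)}, \eqn{O_t = g(W_O P_t + b_O)},
#' \eqn{H_t = O_t \circ \tanh(C_t)} (sigmoid \eqn{g}).
#'
#' @param state a [cell_state()] (or the result of a previous step)
#' @param x_token numeric token vector (length d)
#' @param x_phar numeric filter vector (length 4)
#' @param params a [cell_params()]
#' @return updated state list (`C`, `H`, and previous gate activations for
#'   the FGR variant), each a 1 x hidden matrix
#' @export
cell_step <- function(state, x_token, x_phar, params) {
  X <- matrix(x_token, nrow = 1L)
  phar <- matrix(x_phar, nrow = 1L)
  cell_forward_step(state, X, phar, params)$state
}

#' Encode a pharmacological representation into a feature vector
#'
#' Iterates the configured cell over the token sequence from a zero state
#' and returns the final hidden state \eqn{H_n}, the feature the SoftMax
#' heads consume.
#'
#' @param rep a [build_representation()] object, or any list with
#'   `token_vectors` (n x d) and `phar_vectors` (n x 4)
#' @param params a [cell_params()]
#' @return numeric hidden vector of length `hidden_size`
#' @export
encode_sequence <- function(rep, params) {
  n <- nrow(rep$token_vectors)
  if (is.null(n) || n < 1L) stop("empty sequence", call. = FALSE)
  st <- cell_state(params, batch = 1L)
  for (t in seq_len(n))
    st <- cell_step(st, rep$token_vectors[t, ], rep$phar_vectors[t, ], params)
  drop(st$H)
}

# For variants whose gates all read the same input P_t, the four gate
# products collapse into one BLAS call against a column-fused weight
# matrix. PEEPHOLE and FGR gates read different inputs and keep the
# per-gate path.
fuse_params <- function(params) {
  tr <- variant_traits(params$variant)
  if (tr$peephole || tr$fgr) return(NULL)
  gates <- c(if (tr$has_i) "I", if (tr$has_f) "F", "C",
             if (tr$has_o) "O")
  W <- do.call(cbind, lapply(gates, function(gt) params[[paste0("W_", gt)]]))
  b <- unlist(lapply(gates, function(gt) params[[paste0("b_", gt)]]),
              use.names = FALSE)
  h <- params$hidden_size
  blocks <- stats::setNames(lapply(seq_along(gates), function(i)
    (i - 1L) * h + seq_len(h)), gates)
  list(W = W, b = b, blocks = blocks, gates = gates)
}

# fused batched step; semantics identical to cell_forward_step
fused_forward_step <- function(state, X, phar, params, fused, mask,
                               keep_cache = FALSE) {
  tr <- variant_traits(params$variant)
  B <- nrow(X)
  H_prev <- state$H; C_prev <- state$C
  if (tr$has_pg) {
    pg <- sigmoid(add_bias(phar %*% params$W_P, params$b_P))
    P <- cbind(pg, H_prev, X)
  } else {
    pg <- NULL
    P <- cbind(H_prev, X)
  }
  A <- add_bias(P %*% fused$W, fused$b)
  bl <- fused$blocks
  gi <- if (tr$has_i) {
    a <- A[, bl$I, drop = FALSE]
    if (tr$i_raw) a else sigmoid(a)
  } else NULL
  gf <- if (tr$cifg) 1 - gi
        else if (tr$has_f) {
    a <- A[, bl$F, drop = FALSE]
    if (tr$f_raw) a else sigmoid(a)
  } else NULL
  ccand <- tanh(A[, bl$C, drop = FALSE])
  if (params$conventional_gate_roles) {
    mult_prev <- gf; mult_cand <- gi
  } else {
    mult_prev <- gi; mult_cand <- gf
  }
  C_raw <- (if (is.null(mult_prev)) C_prev else mult_prev * C_prev) +
           (if (is.null(mult_cand)) ccand else mult_cand * ccand)
  go <- if (tr$has_o) {
    a <- A[, bl$O, drop = FALSE]
    if (tr$o_raw) a else sigmoid(a)
  } else NULL
  tanhC <- tanh(C_raw)
  H_raw <- if (is.null(go)) tanhC else go * tanhC
  if (!all(is.finite(H_raw)) || !all(is.finite(C_raw)))
    stop("non-finite cell output (variant ", params$variant, ")",
         call. = FALSE)
  blend <- function(new, old) new * mask + old * (1 - mask)
  new_state <- list(C = blend(C_raw, C_prev), H = blend(H_raw, H_prev))
  cache <- NULL
  if (keep_cache)
    cache <- list(P = P, pg = pg, phar = phar, gi = gi, gf = gf, go = go,
                  ccand = ccand, C_prev = C_prev, C_raw = C_raw,
                  tanhC = tanhC, mask = mask)
  list(state = new_state, cache = cache)
}

# reverse-mode through the fused steps; returns dX per step and grads
fused_backward <- function(dH_final, caches, params, fused) {
  tr <- variant_traits(params$variant)
  T_len <- length(caches)
  B <- nrow(dH_final); h <- params$hidden_size
  d <- params$input_dim; p <- params$p_dim; np <- params$n_p
  bl <- fused$blocks
  gW_all <- matrix(0, nrow(fused$W), ncol(fused$W))
  gb_all <- numeric(length(fused$b))
  g <- zero_like_params(params)
  dX <- vector("list", T_len)
  dH <- dH_final; dC <- matrix(0, B, h)
  conv <- params$conventional_gate_roles
  for (t in rev(seq_len(T_len))) {
    ca <- caches[[t]]
    M <- ca$mask
    dH_cell <- dH * M; dH_prev <- dH * (1 - M)
    dC_cell <- dC * M; dC_prev <- dC * (1 - M)
    if (tr$has_o) {
      do_ <- dH_cell * ca$tanhC
      dtanh <- dH_cell * ca$go
    } else dtanh <- dH_cell
    dC_raw <- dC_cell + dtanh * (1 - ca$tanhC^2)
    dA <- matrix(0, B, ncol(fused$W))
    if (tr$has_o)
      dA[, bl$O] <- if (tr$o_raw) do_ else do_ * ca$go * (1 - ca$go)
    mult_prev <- if (conv) ca$gf else ca$gi
    mult_cand <- if (conv) ca$gi else ca$gf
    dmult_prev <- if (!is.null(mult_prev)) dC_raw * ca$C_prev else NULL
    dmult_cand <- if (!is.null(mult_cand)) dC_raw * ca$ccand else NULL
    dccand <- if (is.null(mult_cand)) dC_raw else dC_raw * mult_cand
    dC_prev <- dC_prev +
      (if (is.null(mult_prev)) dC_raw else dC_raw * mult_prev)
    dgi <- if (conv) dmult_cand else dmult_prev
    dgf <- if (conv) dmult_prev else dmult_cand
    if (tr$cifg) dgi <- dgi - dgf
    if (tr$has_i && !is.null(dgi))
      dA[, bl$I] <- if (tr$i_raw) dgi else dgi * ca$gi * (1 - ca$gi)
    if (tr$has_f && !is.null(dgf))
      dA[, bl$F] <- if (tr$f_raw) dgf else dgf * ca$gf * (1 - ca$gf)
    dA[, bl$C] <- dccand * (1 - ca$ccand^2)
    gW_all <- gW_all + crossprod(ca$P, dA)
    gb_all <- gb_all + colSums(dA)
    dP <- tcrossprod(dA, fused$W)
    if (tr$has_pg) {
      dpg <- dP[, seq_len(p), drop = FALSE]
      dH_prev <- dH_prev + dP[, p + seq_len(h), drop = FALSE]
      dX[[t]] <- dP[, p + h + seq_len(d), drop = FALSE]
      dapg <- dpg * ca$pg * (1 - ca$pg)
      g$W_P <- g$W_P + crossprod(ca$phar, dapg)
      g$b_P <- g$b_P + colSums(dapg)
    } else {
      dH_prev <- dH_prev + dP[, seq_len(h), drop = FALSE]
      dX[[t]] <- dP[, h + seq_len(d), drop = FALSE]
    }
    dH <- dH_prev
    dC <- dC_prev
  }
  for (gt in fused$gates) {
    g[[paste0("W_", gt)]] <- gW_all[, bl[[gt]], drop = FALSE]
    g[[paste0("b_", gt)]] <- gb_all[bl[[gt]]]
  }
  list(dX = dX, grads = g)
}

# Batched multi-step forward over padded sequences.
# Xs, phars: lists of length T (B x d, B x 4); mask: B x T.
rnn_forward <- function(Xs, phars, mask, params, keep_cache = FALSE) {
  T_len <- length(Xs); B <- nrow(Xs[[1]])
  check_shapes(params, ncol(Xs[[1]]))
  st <- cell_state(params, batch = B)
  caches <- if (keep_cache) vector("list", T_len) else NULL
  fused <- fuse_params(params)
  for (t in seq_len(T_len)) {
    step <- if (is.null(fused))
      cell_forward_step(st, Xs[[t]], phars[[t]], params,
                        mask = mask[, t], keep_cache = keep_cache)
    else
      fused_forward_step(st, Xs[[t]], phars[[t]], params, fused,
                         mask = mask[, t], keep_cache = keep_cache)
    st <- step$state
    if (keep_cache) caches[[t]] <- step$cache
  }
  list(H = st$H, state = st, caches = caches)
}

# Reverse-mode gradients through rnn_forward. dH_final: B x h gradient of
# the loss w.r.t. the final hidden state. Returns per-step input gradients
# dX (list of B x d) and parameter gradients.
rnn_backward <- function(dH_final, caches, params) {
  fused <- fuse_params(params)
  if (!is.null(fused))
    return(fused_backward(dH_final, caches, params, fused))
  tr <- variant_traits(params$variant)
  T_len <- length(caches)
  B <- nrow(dH_final); h <- params$hidden_size
  d <- params$input_dim; p <- params$p_dim; np <- params$n_p
  g <- zero_like_params(params)
  dX <- vector("list", T_len)
  zeros <- matrix(0, B, h)
  dH <- dH_final; dC <- zeros
  dIc <- zeros; dFc <- zeros; dOc <- zeros  # FGR stored-gate carries
  for (t in rev(seq_len(T_len))) {
    ca <- caches[[t]]
    M <- ca$mask
    dH_cell <- dH * M; dH_prev <- dH * (1 - M)
    dC_cell <- dC * M; dC_prev <- dC * (1 - M)
    if (tr$fgr) {
      dgi_extra <- dIc * M; dgf_extra <- dFc * M; dgo_extra <- dOc * M
      dIc <- dIc * (1 - M); dFc <- dFc * (1 - M); dOc <- dOc * (1 - M)
    }
    # ---- output side ----
    if (tr$has_o) {
      do_ <- dH_cell * ca$tanhC
      if (tr$fgr) do_ <- do_ + dgo_extra
      dtanh <- dH_cell * ca$go
    } else {
      do_ <- NULL
      dtanh <- dH_cell
    }
    dC_raw <- dC_cell + dtanh * (1 - ca$tanhC^2)
    dP <- matrix(0, B, np)
    if (tr$has_o) {
      daO <- if (tr$o_raw) do_ else do_ * ca$go * (1 - ca$go)
      Gin_o <- if (tr$peephole) cbind(ca$P, ca$C_raw)
               else if (tr$fgr) cbind(ca$P, ca$Ip, ca$Fp, ca$Op, ca$C_prev)
               else ca$P
      g$W_O <- g$W_O + crossprod(Gin_o, daO)
      g$b_O <- g$b_O + colSums(daO)
      dGin <- tcrossprod(daO, params$W_O)
      dP <- dP + dGin[, seq_len(np), drop = FALSE]
      if (tr$peephole)
        dC_raw <- dC_raw + dGin[, np + seq_len(h), drop = FALSE]
      if (tr$fgr) {
        dIc <- dIc + dGin[, np + seq_len(h), drop = FALSE]
        dFc <- dFc + dGin[, np + h + seq_len(h), drop = FALSE]
        dOc <- dOc + dGin[, np + 2L * h + seq_len(h), drop = FALSE]
        dC_prev <- dC_prev + dGin[, np + 3L * h + seq_len(h), drop = FALSE]
      }
    }
    # ---- cell-state split ----
    conv <- params$conventional_gate_roles
    mult_prev <- if (conv) ca$gf else ca$gi
    mult_cand <- if (conv) ca$gi else ca$gf
    dmult_prev <- if (!is.null(mult_prev)) dC_raw * ca$C_prev else NULL
    dmult_cand <- if (!is.null(mult_cand)) dC_raw * ca$ccand else NULL
    dccand <- if (is.null(mult_cand)) dC_raw else dC_raw * mult_cand
    dC_prev <- dC_prev +
      (if (is.null(mult_prev)) dC_raw else dC_raw * mult_prev)
    dgi <- if (conv) dmult_cand else dmult_prev
    dgf <- if (conv) dmult_prev else dmult_cand
    if (tr$cifg) dgi <- dgi - dgf  # gf = 1 - gi
    if (tr$fgr) { dgi <- dgi + dgi_extra; dgf <- dgf + dgf_extra }
    Gin_if <- if (tr$peephole) cbind(ca$P, ca$C_prev)
              else if (tr$fgr) cbind(ca$P, ca$Ip, ca$Fp, ca$Op, ca$C_prev)
              else ca$P
    backgate <- function(da, W_name) {
      g[[W_name]] <<- g[[W_name]] + crossprod(Gin_if, da)
      b_name <- sub("W", "b", W_name)
      g[[b_name]] <<- g[[b_name]] + colSums(da)
      dGin <- tcrossprod(da, params[[W_name]])
      dP <<- dP + dGin[, seq_len(np), drop = FALSE]
      if (tr$peephole)
        dC_prev <<- dC_prev + dGin[, np + seq_len(h), drop = FALSE]
      if (tr$fgr) {
        dIc <<- dIc + dGin[, np + seq_len(h), drop = FALSE]
        dFc <<- dFc + dGin[, np + h + seq_len(h), drop = FALSE]
        dOc <<- dOc + dGin[, np + 2L * h + seq_len(h), drop = FALSE]
        dC_prev <<- dC_prev + dGin[, np + 3L * h + seq_len(h), drop = FALSE]
      }
    }
    if (tr$has_i && !is.null(dgi)) {
      daI <- if (tr$i_raw) dgi else dgi * ca$gi * (1 - ca$gi)
      backgate(daI, "W_I")
    }
    if (tr$has_f && !is.null(dgf)) {
      daF <- if (tr$f_raw) dgf else dgf * ca$gf * (1 - ca$gf)
      backgate(daF, "W_F")
    }
    daC <- dccand * (1 - ca$ccand^2)
    g$W_C <- g$W_C + crossprod(ca$P, daC)
    g$b_C <- g$b_C + colSums(daC)
    dP <- dP + tcrossprod(daC, params$W_C)
    # ---- P decomposition ----
    if (tr$has_pg) {
      dpg <- dP[, seq_len(p), drop = FALSE]
      dH_prev <- dH_prev + dP[, p + seq_len(h), drop = FALSE]
      dX[[t]] <- dP[, p + h + seq_len(d), drop = FALSE]
      dapg <- dpg * ca$pg * (1 - ca$pg)
      g$W_P <- g$W_P + crossprod(ca$phar, dapg)
      g$b_P <- g$b_P + colSums(dapg)
    } else {
      dH_prev <- dH_prev + dP[, seq_len(h), drop = FALSE]
      dX[[t]] <- dP[, h + seq_len(d), drop = FALSE]
    }
    dH <- dH_prev
    dC <- dC_prev
  }
  list(dX = dX, grads = g)
}
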