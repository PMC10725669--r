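zero_params <- function(variant, d = 3L, h = 4L, p = 2L) {
  par <- cell_params(variant, input_dim = d, hidden_size = h, p_dim = p,
                     seed = 1L)
  for (nm in pharddi:::cell_weight_names(par)) par[[nm]][] <- 0
  par
}

test_that("all-zero parameters from a zero state yield zero C and H", {
  for (v in lstm_variants()) {
    par <- zero_params(v)
    st <- cell_step(cell_state(par), c(1, -2, 0.5), c(1, 0, 1, 0.25), par)
    expect_equal(max(abs(st$C)), 0, info = v)
    expect_equal(max(abs(st$H)), 0, info = v)
  }
})

test_that("a scalar cell step matches the hand-evaluated equation chain", {
  par <- cell_params("PHAR", input_dim = 1L, hidden_size = 1L, p_dim = 1L,
                     seed = 1L)
  for (nm in pharddi:::cell_weight_names(par))
    par[[nm]][] <- if (is.matrix(par[[nm]])) 1 else 0
  st <- cell_step(cell_state(par), 0, rep(0, 4), par)
  # hand evaluation: pg = s(0) = 1/2; P = (1/2, 0, 0);
  # every gate preactivation = 1/2
  g5 <- 1 / (1 + exp(-0.5))
  C1 <- g5 * 0 + g5 * tanh(0.5)
  H1 <- g5 * tanh(C1)
  expect_equal(drop(st$C), C1, tolerance = 1e-10)
  expect_equal(drop(st$H), H1, tolerance = 1e-10)
})

test_that("a constant pharmacological gate reduces PHAR to NPG with folded biases", {
  # with W_P = 0, the phar gate emits the constant c = s(b_P); folding
  # c through the first input column of each gate matrix gives an NPG
  # cell with adjusted biases that must match exactly
  d <- 3L; h <- 4L; p <- 1L
  phar_par <- cell_params("PHAR", input_dim = d, hidden_size = h,
                          p_dim = p, seed = 7L)
  phar_par$W_P[] <- 0
  phar_par$b_P[] <- 0.8
  cc <- 1 / (1 + exp(-0.8))
  npg_par <- cell_params("NPG", input_dim = d, hidden_size = h, seed = 7L)
  for (nm in c("W_I", "W_F", "W_C", "W_O")) {
    npg_par[[nm]] <- phar_par[[nm]][-seq_len(p), , drop = FALSE]
    bn <- sub("W", "b", nm)
    npg_par[[bn]] <- phar_par[[bn]] +
      colSums(phar_par[[nm]][seq_len(p), , drop = FALSE]) * cc
  }
  x <- c(0.3, -1, 0.2)
  st_phar <- cell_step(cell_state(phar_par), x, c(1, 0, 1, 0.25), phar_par)
  st_npg <- cell_step(cell_state(npg_par), x, c(1, 0, 1, 0.25), npg_par)
  expect_equal(st_phar$H, st_npg$H, tolerance = 1e-12)
  expect_equal(st_phar$C, st_npg$C, tolerance = 1e-12)
})

test_that("sequence encoding over one step equals a single cell step", {
  par <- cell_params("PHAR", input_dim = 2L, hidden_size = 3L, seed = 2L)
  rep <- list(token_vectors = matrix(c(0.5, -0.5), 1L),
              phar_vectors = matrix(c(1, 0, 0, 1), 1L))
  expect_equal(encode_sequence(rep, par),
               drop(cell_step(cell_state(par), c(0.5, -0.5),
                              c(1, 0, 0, 1), par)$H))
  expect_error(encode_sequence(list(token_vectors =
    matrix(numeric(), 0L, 2L), phar_vectors = matrix(numeric(), 0L, 4L)),
    par), "empty")
})

test_that("batched evaluation equals the per-instance loop on ragged input", {
  set.seed(31)
  d <- 3L; h <- 5L
  for (v in c("PHAR", "CIFG", "PEEPHOLE", "FGR", "NOAF")) {
    par <- cell_params(v, input_dim = d, hidden_size = h, p_dim = 2L,
                       seed = 4L)
    lens <- c(1L, 3L, 5L)
    reps <- lapply(lens, function(n)
      list(token_vectors = matrix(rnorm(n * d), n, d),
           phar_vectors = matrix(runif(n * 4L), n, 4L)))
    T_len <- max(lens); B <- length(lens)
    Xs <- lapply(seq_len(T_len), function(t) {
      out <- matrix(0, B, d)
      for (b in seq_len(B)) if (t <= lens[b])
        out[b, ] <- reps[[b]]$token_vectors[t, ]
      out
    })
    phars <- lapply(seq_len(T_len), function(t) {
      out <- matrix(0, B, 4L)
      for (b in seq_len(B)) if (t <= lens[b])
        out[b, ] <- reps[[b]]$phar_vectors[t, ]
      out
    })
    mask <- outer(lens, seq_len(T_len), ">=") * 1
    H_batch <- pharddi:::rnn_forward(Xs, phars, mask, par)$H
    for (b in seq_len(B))
      expect_equal(H_batch[b, ], encode_sequence(reps[[b]], par),
                   tolerance = 1e-6, info = paste(v, b))
  }
})

test_that("full gate recurrence threads previous gate activations", {
  set.seed(77)
  d <- 2L; h <- 3L
  par <- cell_params("FGR", input_dim = d, hidden_size = h, p_dim = 2L,
                     seed = 6L)
  x_toks <- lapply(1:3, function(t) rnorm(d))
  x_phars <- lapply(1:3, function(t) runif(4))
  ref <- ref_fgr_sequence(x_toks, x_phars, par)
  st <- cell_state(par)
  for (t in 1:3) st <- cell_step(st, x_toks[[t]], x_phars[[t]], par)
  expect_equal(drop(st$H), ref$H, tolerance = 1e-12)
  expect_equal(drop(st$C), ref$C, tolerance = 1e-12)
})

test_that("gate activations respect their ranges; ablated activations do not", {
  set.seed(11)
  x <- rnorm(3); ph <- runif(4)
  probe_cache <- function(v, scale) {
    par <- cell_params(v, input_dim = 3L, hidden_size = 4L, p_dim = 2L,
                       seed = 3L, init_scale = scale)
    st <- cell_state(par)
    pharddi:::cell_forward_step(st, matrix(x, 1L), matrix(ph, 1L), par,
                                keep_cache = TRUE)
  }
  out <- probe_cache("PHAR", 2)
  for (gate in c("gi", "gf", "go")) {
    val <- out$cache[[gate]]
    expect_true(all(val > 0 & val < 1), info = gate)
  }
  expect_true(all(abs(tanh(out$cache$C_raw)) < 1))
  # unbounded ablations must be able to leave [-1, 1] under large weights
  expect_gt(max(abs(probe_cache("NOAF", 8)$cache$go)), 1)
  expect_gt(max(abs(probe_cache("NIAF", 8)$cache$gi)), 1)
  expect_gt(max(abs(probe_cache("NFAF", 8)$cache$gf)), 1)
  # coupled gates sum to one exactly
  cifg <- probe_cache("CIFG", 2)$cache
  expect_identical(cifg$gi + cifg$gf, matrix(1, 1L, 4L))
})

test_that("NPG reproduces an independent vanilla LSTM step", {
  set.seed(19)
  d <- 3L; h <- 4L
  # draw standard-LSTM weights, then map them onto the printed gate roles:
  # the W_I-parameterised gate multiplies C_{t-1} (the conventional forget
  # gate) and the W_F gate multiplies the candidate (conventional input)
  Wi <- matrix(rnorm((h + d) * h, sd = 0.4), h + d, h)
  Wf <- matrix(rnorm((h + d) * h, sd = 0.4), h + d, h)
  Wc <- matrix(rnorm((h + d) * h, sd = 0.4), h + d, h)
  Wo <- matrix(rnorm((h + d) * h, sd = 0.4), h + d, h)
  bi <- rnorm(h); bf <- rnorm(h); bc <- rnorm(h); bo <- rnorm(h)
  h0 <- rnorm(h); c0 <- rnorm(h); x <- rnorm(d)
  ref <- ref_vanilla_lstm_step(h0, c0, x, Wi, bi, Wf, bf, Wc, bc, Wo, bo)
  par <- cell_params("NPG", input_dim = d, hidden_size = h, seed = 1L)
  par$W_I <- Wf; par$b_I <- bf    # printed-role mapping
  par$W_F <- Wi; par$b_F <- bi
  par$W_C <- Wc; par$b_C <- bc
  par$W_O <- Wo; par$b_O <- bo
  st <- cell_step(list(C = matrix(c0, 1L), H = matrix(h0, 1L)),
                  x, rep(0, 4), par)
  expect_equal(drop(st$H), ref$H, tolerance = 1e-6)
  expect_equal(drop(st$C), ref$C, tolerance = 1e-6)
  # under conventional gate roles the mapping is the identity
  par2 <- cell_params("NPG", input_dim = d, hidden_size = h, seed = 1L,
                      conventional_gate_roles = TRUE)
  par2$W_I <- Wi; par2$b_I <- bi
  par2$W_F <- Wf; par2$b_F <- bf
  par2$W_C <- Wc; par2$b_C <- bc
  par2$W_O <- Wo; par2$b_O <- bo
  st2 <- cell_step(list(C = matrix(c0, 1L), H = matrix(h0, 1L)),
                   x, rep(0, 4), par2)
  expect_equal(drop(st2$H), ref$H, tolerance = 1e-6)
})

test_that("shape mismatches raise informative dimension errors", {
  par <- cell_params("PHAR", input_dim = 3L, hidden_size = 2L, seed = 1L)
  expect_error(cell_step(cell_state(par), c(1, 2), c(1, 0, 0, 1), par),
               "does not match")
  expect_error(cell_step(cell_state(par), c(1, 2, 3), c(1, 0), par),
               "4 columns")
})
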