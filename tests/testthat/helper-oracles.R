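# Independent reference implementations and fixture builders used as
# oracles. These share no code with the package's vectorized paths: all
# reference math is written as explicit element-wise loops.

sig_ref <- function(x) 1 / (1 + exp(-x))

# matrix-vector product written as explicit sums (no %*%)
mv_ref <- function(W, x, b) {
  out <- numeric(ncol(W))
  for (j in seq_len(ncol(W))) {
    acc <- b[j]
    for (k in seq_len(nrow(W))) acc <- acc + W[k, j] * x[k]
    out[j] <- acc
  }
  out
}

# one step of the textbook vanilla LSTM:
#   i = s(Wi [h,x] + bi); f = s(Wf [h,x] + bf); cc = tanh(Wc [h,x] + bc)
#   C = f * Cprev + i * cc; o = s(Wo [h,x] + bo); H = o * tanh(C)
ref_vanilla_lstm_step <- function(h_prev, c_prev, x, Wi, bi, Wf, bf,
                                  Wc, bc, Wo, bo) {
  z <- c(h_prev, x)
  i <- sig_ref(mv_ref(Wi, z, bi))
  f <- sig_ref(mv_ref(Wf, z, bf))
  cc <- tanh(mv_ref(Wc, z, bc))
  C <- f * c_prev + i * cc
  o <- sig_ref(mv_ref(Wo, z, bo))
  list(H = o * tanh(C), C = C)
}

# unrolled full-gate-recurrence reference: every gate input is
# (P_t, I_{t-1}, F_{t-1}, O_{t-1}, C_{t-1}); cell equations in their published arrangement
# (the W_I gate multiplies C_{t-1}, the W_F gate multiplies the candidate)
ref_fgr_sequence <- function(x_toks, x_phars, params) {
  h <- params$hidden_size
  H <- numeric(h); C <- numeric(h)
  I <- numeric(h); F_ <- numeric(h); O <- numeric(h)
  for (t in seq_along(x_toks)) {
    pg <- sig_ref(mv_ref(params$W_P, x_phars[[t]], params$b_P))
    P <- c(pg, H, x_toks[[t]])
    gin <- c(P, I, F_, O, C)
    I_new <- sig_ref(mv_ref(params$W_I, gin, params$b_I))
    F_new <- sig_ref(mv_ref(params$W_F, gin, params$b_F))
    cc <- tanh(mv_ref(params$W_C, P, params$b_C))
    C <- I_new * C + F_new * cc
    O_new <- sig_ref(mv_ref(params$W_O, gin, params$b_O))
    H <- O_new * tanh(C)
    I <- I_new; F_ <- F_new; O <- O_new
  }
  list(H = H, C = C)
}

# ---- fixtures -------------------------------------------------------------

write_fixture_xml <- function(lines) {
  path <- tempfile(fileext = ".xml")
  writeLines(lines, path)
  path
}

minimal_corpus_xml <- function() {
  write_fixture_xml(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<corpus>',
    ' <document id="d1">',
    '  <sentence id="d1.s0" text="aspirin potentiates warfarin effects">',
    '   <entity id="d1.s0.e0" charOffset="0-6" type="drug" text="aspirin"/>',
    '   <entity id="d1.s0.e1" charOffset="20-27" type="drug" text="warfarin"/>',
    '   <pair id="d1.s0.p0" e1="d1.s0.e0" e2="d1.s0.e1" ddi="true"/>',
    '  </sentence>',
    ' </document>',
    '</corpus>'))
}

no_pairs_corpus_xml <- function() {
  write_fixture_xml(c(
    '<corpus>',
    ' <document id="d1">',
    '  <sentence id="d1.s0" text="aspirin with warfarin and heparin">',
    '   <entity id="e0" charOffset="0-6" type="drug" text="aspirin"/>',
    '   <entity id="e1" charOffset="13-20" type="drug" text="warfarin"/>',
    '   <entity id="e2" charOffset="26-32" type="drug" text="heparin"/>',
    '  </sentence>',
    ' </document>',
    '</corpus>'))
}

bad_surface_corpus_xml <- function() {
  write_fixture_xml(c(
    '<corpus>',
    ' <document id="d1">',
    '  <sentence id="d1.s0" text="aspirin potentiates warfarin">',
    '   <entity id="d1.s0.eBAD" charOffset="0-6" type="drug" text="heparin"/>',
    '  </sentence>',
    ' </document>',
    '</corpus>'))
}

# a sentence object with n single-token drug mentions at known positions
make_sentence_n_drugs <- function(n, id = "s0") {
  words <- c("filler0")
  ents <- list()
  for (i in seq_len(n)) {
    words <- c(words, paste0("drug", i), paste0("filler", i))
  }
  text <- paste(words, collapse = " ")
  starts <- cumsum(c(0L, nchar(words[-length(words)]) + 1L))
  for (i in seq_len(n)) {
    w <- 2L * i  # position of drug i in `words`
    ents[[i]] <- ddi_entity(paste0(id, ".e", i - 1L), starts[w],
                            starts[w] + nchar(words[w]) - 1L, words[w])
  }
  ddi_sentence(id, text, ents)
}
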