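#' Initialise a SoftMax classification head
#'
#' @param n_classes number of classes k (2 for the binary task, 5 for the
#'   typed task)
#' @param hidden_size encoder hidden size
#' @param labels optional class labels (length k)
#' @param seed RNG seed
#' @return list with `W` (k x hidden), `b` (length k), `labels`
#' @export
classifier_head <- function(n_classes, hidden_size, labels = NULL,
                            seed = 1L) {
  stopifnot(n_classes >= 2L)
  s <- 1 / sqrt(hidden_size)
  W <- with_seed(seed,
    matrix(stats::runif(n_classes * hidden_size, -s, s),
           n_classes, hidden_size))
  if (is.null(labels)) labels <- as.character(seq_len(n_classes) - 1L)
  list(W = W, b = numeric(n_classes), labels = labels)
}

#' SoftMax prediction from an encoded feature vector
#'
#' Probabilities are `softmax(W h + b)`; the predicted label is the argmax,
#' ties broken by the lowest class index.
#'
#' @param h hidden feature vector (length hidden), or a matrix with one row
#'   per instance
#' @param head a [classifier_head()]
#' @return for a single vector, a list with `label` and `prob` (named
#'   k-vector summing to 1); for a matrix, a list with `labels` and `probs`
#' @export
head_predict <- function(h, head) {
  single <- !is.matrix(h)
  H <- if (single) matrix(h, nrow = 1L) else h
  logits <- add_bias(tcrossprod(H, head$W), head$b)
  probs <- row_softmax(logits)
  colnames(probs) <- head$labels
  idx <- max.col(probs, ties.method = "first")
  if (single) list(label = head$labels[idx], prob = drop(probs))
  else list(labels = head$labels[idx], probs = probs)
}

#' Cross-entropy plus ridge objective
#'
#' \eqn{J = \mathrm{mean}_i(-\log p_i(\mathrm{gold}_i)) +
#' (\lambda/2)\,\lVert W\rVert_F^2}, computed through log-sum-exp so
#' underflow cannot produce `NaN`.
#'
#' @param H matrix of encoded features (instances x hidden)
#' @param gold integer class indices (1-based) or labels matching
#'   `head$labels`
#' @param head a [classifier_head()]
#' @param lambda ridge weight on the head's `W`
#' @return scalar objective value
#' @export
cross_entropy_loss <- function(H, gold, head, lambda = 0) {
  stopifnot(lambda >= 0)
  if (!is.matrix(H)) H <- matrix(H, nrow = 1L)
  if (is.character(gold)) gold <- match(gold, head$labels)
  logits <- add_bias(tcrossprod(H, head$W), head$b)
  mx <- apply(logits, 1L, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  gold_logit <- logits[cbind(seq_len(nrow(logits)), gold)]
  mean(lse - gold_logit) + lambda / 2 * sum(head$W^2)
}

#' Training configuration
#'
#' Defaults follow the published training setup: RMSprop with learning
#' rate 0.001, dropout 0.2 on the embedding and hidden layers, batch size
#' 32, 200 epochs, with the first `pretrain_epochs` used to pretrain the
#' shared encoder through throwaway heads before joint fine-tuning.
#'
#' @param learning_rate RMSprop learning rate
#' @param dropout dropout rate in `[0, 1)`
#' @param batch_size mini-batch size
#' @param epochs total training epochs (pretraining included)
#' @param lambda ridge weight on head matrices
#' @param seed RNG seed controlling init, shuffling and dropout
#' @param variant cell variant, one of [lstm_variants()]
#' @param embed_dim token embedding dimension d
#' @param hidden_size encoder hidden size
#' @param p_dim pharmacological gate output size
#' @param pretrain_epochs epochs of shared-parameter pretraining
#' @param neighbor_radius filter adjacency radius (see [phar_vector()])
#' @param keep_punctuation tokenizer mode (see [tokenize()])
#' @param conventional_gate_roles see [cell_params()]
#' @param rmsprop_decay,rmsprop_epsilon RMSprop smoothing constants
#' @param on_divergence `"error"` to stop with an error at the first
#'   non-finite loss, `"stop"` to end training and keep the trace so far
#' @return list of class `train_config`
#' @export
train_config <- function(learning_rate = 0.001, dropout = 0.2,
                         batch_size = 32L, epochs = 200L, lambda = 1e-4,
                         seed = 1L, variant = "PHAR", embed_dim = 400L,
                         hidden_size = 128L, p_dim = 4L,
                         pretrain_epochs = 20L, neighbor_radius = 1L,
                         keep_punctuation = FALSE,
                         conventional_gate_roles = FALSE,
                         rmsprop_decay = 0.9, rmsprop_epsilon = 1e-8,
                         on_divergence = c("error", "stop")) {
  stopifnot(learning_rate > 0, dropout >= 0, dropout < 1, batch_size >= 1,
            epochs >= 1, lambda >= 0, pretrain_epochs >= 0,
            pretrain_epochs <= epochs)
  structure(list(learning_rate = learning_rate, dropout = dropout,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lambda = lambda,
                 seed = as.integer(seed),
                 variant = match.arg(variant, lstm_variants()),
                 embed_dim = as.integer(embed_dim),
                 hidden_size = as.integer(hidden_size),
                 p_dim = as.integer(p_dim),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 neighbor_radius = as.integer(neighbor_radius),
                 keep_punctuation = isTRUE(keep_punctuation),
                 conventional_gate_roles = isTRUE(conventional_gate_roles),
                 rmsprop_decay = rmsprop_decay,
                 rmsprop_epsilon = rmsprop_epsilon,
                 on_divergence = match.arg(on_divergence)),
            class = "train_config")
}

# ---- instance preparation -------------------------------------------------

# Precompute token ids and filter matrices for a list of instances.
prepare_instances <- function(instances, table, config) {
  lapply(instances, function(inst) {
    rep <- build_representation(inst, table,
                                neighbor_radius = config$neighbor_radius,
                                keep_punctuation = config$keep_punctuation)
    list(ids = rep$token_ids, phar = rep$phar_vectors, label = rep$label,
         len = length(rep$token_ids),
         sentence_id = inst$sentence$id, e1 = inst$target1,
         e2 = inst$target2)
  })
}

# Pad a set of prepared instances into batch arrays.
make_batch <- function(prep, idx, unk_index = 1L) {
  B <- length(idx)
  T_len <- max(vapply(prep[idx], `[[`, 1L, "len"))
  ids <- matrix(unk_index, B, T_len)
  mask <- matrix(0, B, T_len)
  phars <- lapply(seq_len(T_len), function(t) matrix(0, B, 4L))
  for (b in seq_len(B)) {
    x <- prep[[idx[b]]]
    ids[b, seq_len(x$len)] <- x$ids
    mask[b, seq_len(x$len)] <- 1
    for (t in seq_len(x$len)) phars[[t]][b, ] <- x$phar[t, ]
  }
  list(ids = ids, mask = mask, phars = phars, T_len = T_len, B = B,
       labels = vapply(prep[idx], `[[`, "", "label"))
}

# Forward + backward for one batch; returns loss, grads for E, cell, head.
batch_loss_grads <- function(batch, E, params, head, lambda,
                             dropout = 0, gold_idx = NULL,
                             compute_grads = TRUE) {
  B <- batch$B; T_len <- batch$T_len
  d <- ncol(E); h <- params$hidden_size
  keep <- 1 - dropout
  Xs <- vector("list", T_len)
  emb_masks <- if (dropout > 0) vector("list", T_len) else NULL
  for (t in seq_len(T_len)) {
    X <- E[batch$ids[, t], , drop = FALSE]
    if (dropout > 0) {
      m <- matrix(stats::rbinom(B * d, 1L, keep), B, d) / keep
      emb_masks[[t]] <- m
      X <- X * m
    }
    Xs[[t]] <- X
  }
  fwd <- rnn_forward(Xs, batch$phars, batch$mask, params,
                     keep_cache = compute_grads)
  Hn <- fwd$H
  hid_mask <- NULL
  if (dropout > 0) {
    hid_mask <- matrix(stats::rbinom(B * h, 1L, keep), B, h) / keep
    Hn <- Hn * hid_mask
  }
  if (is.null(gold_idx)) gold_idx <- match(batch$labels, head$labels)
  logits <- add_bias(tcrossprod(Hn, head$W), head$b)
  mx <- apply(logits, 1L, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  loss <- mean(lse - logits[cbind(seq_len(B), gold_idx)]) +
    lambda / 2 * sum(head$W^2)
  if (!compute_grads) return(list(loss = loss))
  probs <- exp(logits - lse)
  dlogits <- probs
  dlogits[cbind(seq_len(B), gold_idx)] <-
    dlogits[cbind(seq_len(B), gold_idx)] - 1
  dlogits <- dlogits / B
  gW_head <- crossprod(dlogits, Hn) + lambda * head$W
  gb_head <- colSums(dlogits)
  dHn <- dlogits %*% head$W
  if (!is.null(hid_mask)) dHn <- dHn * hid_mask
  bwd <- rnn_backward(dHn, fwd$caches, params)
  # embedding gradient: scatter-add the per-step input gradients
  all_ids <- as.vector(batch$ids)
  dX_rows <- do.call(rbind, lapply(seq_len(T_len), function(t) {
    dx <- bwd$dX[[t]]
    if (!is.null(emb_masks)) dx <- dx * emb_masks[[t]]
    dx
  }))
  gE_rows <- rowsum(dX_rows, group = all_ids)
  list(loss = loss, grads_cell = bwd$grads,
       gW_head = gW_head, gb_head = gb_head,
       gE_rows = gE_rows, gE_ids = as.integer(rownames(gE_rows)))
}

# ---- RMSprop --------------------------------------------------------------

rmsprop_new <- function() new.env(parent = emptyenv())

rmsprop_update <- function(opt, key, param, grad, lr, decay, eps) {
  cache <- if (is.null(opt[[key]])) grad * 0 else opt[[key]]
  cache <- decay * cache + (1 - decay) * grad^2
  opt[[key]] <- cache
  param - lr * grad / (sqrt(cache) + eps)
}

apply_updates <- function(state, upd, opt, prefix, cfg) {
  for (nm in names(upd))
    state[[nm]] <- rmsprop_update(opt, paste0(prefix, nm), state[[nm]],
                                  upd[[nm]], cfg$learning_rate,
                                  cfg$rmsprop_decay, cfg$rmsprop_epsilon)
  state
}

# ---- training -------------------------------------------------------------

#' Train a pharmacological-representation LSTM
#'
#' Multi-task training: one shared embedding table and recurrent encoder,
#' one SoftMax head per task. Phase 1 (`pretrain_epochs`) updates the
#' shared parameters through temporary throwaway heads; phase 2 attaches
#' fresh heads and fine-tunes everything jointly. Mini-batches of the
#' tasks are interleaved in shuffled order, so tasks contribute in
#' proportion to their corpus sizes. Dropout is applied to the embedding
#' output and the final hidden feature during training only. Parameters
#' are updated with RMSprop. Training is deterministic for a fixed
#' `config$seed`.
#'
#' @param corpora named list of [ddi_corpus()] objects, one per task (e.g.
#'   `list(binary = ..., typed = ...)`); a single corpus may be passed
#'   directly
#' @param config a [train_config()]
#' @param eval optional named list of held-out corpora (same names) whose
#'   per-epoch F-scores are recorded in the trace
#' @param eval_positive for a binary eval task, the label whose F is
#'   traced; multi-class tasks trace micro-F excluding `"NEGATIVE"`
#' @param verbose print per-epoch progress
#' @return object of class `phar_lstm_model`: embedding table, cell
#'   parameters, per-task heads, config, and a per-epoch `trace` data
#'   frame (one row per epoch and task with mean training loss and, when
#'   `eval` is given, held-out F)
#' @export
train_phar_lstm <- function(corpora, config = train_config(), eval = NULL,
                            eval_positive = DDI_POSITIVE, verbose = FALSE) {
  if (inherits(corpora, "ddi_corpus")) corpora <- list(task = corpora)
  if (length(corpora) == 0L ||
      all(vapply(corpora, function(x) length(corpus_instances(x)) == 0L,
                 TRUE)))
    stop("no training instances in any task corpus", call. = FALSE)
  task_names <- names(corpora)
  with_seed(config$seed, {
    instances <- lapply(corpora, corpus_instances, gold = TRUE)
    # vocabulary from the training split; unseen tokens map to <UNK>
    vocab <- sort(unique(unlist(lapply(corpora, function(corp)
      unlist(lapply(corp$documents, function(doc)
        lapply(doc$sentences, function(s)
          tokenize(s$text, config$keep_punctuation)$token)))))))
    E_table <- embedding_table(vocab, dim = config$embed_dim,
                               seed = config$seed)
    E <- E_table$vectors
    params <- cell_params(config$variant, input_dim = config$embed_dim,
                          hidden_size = config$hidden_size,
                          p_dim = config$p_dim, seed = config$seed + 1L,
                          conventional_gate_roles =
                            config$conventional_gate_roles)
    labels <- lapply(corpora, function(corp) task_labels(corp$task))
    new_heads <- function(offset)
      lapply(seq_along(corpora), function(i)
        classifier_head(length(labels[[i]]), config$hidden_size,
                        labels = labels[[i]],
                        seed = config$seed + offset + i))
    prep <- lapply(seq_along(corpora), function(i)
      prepare_instances(instances[[i]], E_table, config))
    eval_prep <- NULL
    if (!is.null(eval))
      eval_prep <- lapply(eval, function(corp)
        prepare_instances(corpus_instances(corp, gold = TRUE), E_table,
                          config))
    heads <- new_heads(10L)       # phase-1 throwaway heads
    opt <- rmsprop_new()
    trace <- list()
    diverged <- FALSE
    for (epoch in seq_len(config$epochs)) {
      if (epoch == config$pretrain_epochs + 1L) {
        heads <- new_heads(100L)  # phase 2: fresh heads, joint fine-tuning
        opt <- rmsprop_new()
      }
      # interleave task batches in shuffled order (size-proportional)
      sched <- list()
      for (i in seq_along(prep)) {
        ord <- sample.int(length(prep[[i]]))
        nb <- ceiling(length(ord) / config$batch_size)
        for (k in seq_len(nb)) {
          lo <- (k - 1L) * config$batch_size + 1L
          hi <- min(k * config$batch_size, length(ord))
          sched[[length(sched) + 1L]] <- list(task = i, idx = ord[lo:hi])
        }
      }
      sched <- sched[sample.int(length(sched))]
      ep_loss <- stats::setNames(numeric(length(prep)), task_names)
      ep_n <- stats::setNames(integer(length(prep)), task_names)
      for (bt in sched) {
        i <- bt$task
        batch <- make_batch(prep[[i]], bt$idx)
        res <- tryCatch(
          batch_loss_grads(batch, E, params, heads[[i]], config$lambda,
                           dropout = config$dropout),
          error = function(e) e)
        if (inherits(res, "error") || !is.finite(res$loss)) {
          msg <- sprintf("training diverged at epoch %d (task %s)%s",
                         epoch, task_names[i],
                         if (inherits(res, "error"))
                           paste0(": ", conditionMessage(res)) else "")
          if (config$on_divergence == "error") stop(msg, call. = FALSE)
          warning(msg, call. = FALSE)
          diverged <- TRUE
          break
        }
        ep_loss[i] <- ep_loss[i] + res$loss * batch$B
        ep_n[i] <- ep_n[i] + batch$B
        params <- apply_updates(params, res$grads_cell, opt, "cell.",
                                config)
        heads[[i]]$W <- rmsprop_update(opt, paste0("headW.", i),
                                       heads[[i]]$W, res$gW_head,
                                       config$learning_rate,
                                       config$rmsprop_decay,
                                       config$rmsprop_epsilon)
        heads[[i]]$b <- rmsprop_update(opt, paste0("headb.", i),
                                       heads[[i]]$b, res$gb_head,
                                       config$learning_rate,
                                       config$rmsprop_decay,
                                       config$rmsprop_epsilon)
        gE <- matrix(0, nrow(E), ncol(E))
        gE[res$gE_ids, ] <- res$gE_rows
        E <- rmsprop_update(opt, "emb", E, gE, config$learning_rate,
                            config$rmsprop_decay, config$rmsprop_epsilon)
      }
      for (i in seq_along(prep)) {
        row <- list(epoch = epoch, task = task_names[i],
                    phase = if (epoch <= config$pretrain_epochs)
                      "pretrain" else "finetune",
                    loss = unname(ep_loss[i] / max(ep_n[i], 1L)),
                    eval_f = NA_real_)
        if (!is.null(eval_prep) && task_names[i] %in% names(eval_prep) &&
            !diverged) {
          ev <- eval_prepared(eval_prep[[task_names[i]]], E, params,
                              heads[[i]], config$batch_size)
          row$eval_f <- trace_f(ev$pred, ev$gold, labels[[i]],
                                eval_positive)
        }
        trace[[length(trace) + 1L]] <- row
      }
      if (verbose)
        message(sprintf("epoch %3d  loss %s", epoch,
                        paste(sprintf("%s=%.4f", task_names,
                                      ep_loss / pmax(ep_n, 1L)),
                              collapse = " ")))
      if (diverged) break
    }
    E_table$vectors <- E
    structure(list(embedding = E_table, params = params, heads = heads,
                   task_names = task_names, labels = labels,
                   config = config,
                   trace = do.call(rbind, lapply(trace, as.data.frame)),
                   diverged = diverged),
              class = "phar_lstm_model")
  })
}

# F-score recorded in the per-epoch trace: positive-class F for binary
# label sets, micro-F over the interaction types otherwise
trace_f <- function(pred, gold, labels, positive) {
  if (length(labels) == 2L) {
    ct <- binary_contingency(pred, gold, positive)
    unname(contingency_metrics(ct$TP, ct$FP, ct$FN, ct$TN)["F"])
  } else {
    rep <- multiclass_report(pred, gold, classes = labels,
                             exclude = DDI_NEGATIVE)
    rep$CLA
  }
}

eval_prepared <- function(prep, E, params, head, batch_size) {
  n <- length(prep)
  pred <- character(n)
  probs <- NULL
  for (k in seq_len(ceiling(n / batch_size))) {
    idx <- ((k - 1L) * batch_size + 1L):min(k * batch_size, n)
    batch <- make_batch(prep, idx)
    fwd <- rnn_forward(lapply(seq_len(batch$T_len), function(t)
      E[batch$ids[, t], , drop = FALSE]), batch$phars, batch$mask, params)
    out <- head_predict(fwd$H, head)
    pred[idx] <- out$labels
    probs <- rbind(probs, out$probs)
  }
  list(pred = pred, gold = vapply(prep, `[[`, "", "label"), probs = probs)
}

#' @export
print.phar_lstm_model <- function(x, ...) {
  cat(sprintf("<phar_lstm_model> variant=%s d=%d hidden=%d tasks: %s (%d epochs)\n",
              x$config$variant, x$config$embed_dim, x$config$hidden_size,
              paste(x$task_names, collapse = ", "),
              max(x$trace$epoch)))
  invisible(x)
}

#' Predict DDI labels for a corpus
#'
#' Dropout is disabled at prediction time, so repeated evaluations of the
#' same model give identical output.
#'
#' @param model a [train_phar_lstm()] model
#' @param corpus a [ddi_corpus()] to label
#' @param task which head to use (default the first)
#' @param gold use annotated pairs (`TRUE`) or enumerate all entity pairs
#' @return data frame: `sentence_id`, `e1`, `e2`, `gold` (when available),
#'   `label`, and one `p_<class>` probability column per class
#' @export
predict_corpus <- function(model, corpus, task = model$task_names[1],
                           gold = TRUE) {
  i <- match(task, model$task_names)
  if (is.na(i)) stop("unknown task '", task, "'", call. = FALSE)
  instances <- corpus_instances(corpus, gold = gold)
  prep <- prepare_instances(instances, model$embedding, model$config)
  ev <- eval_prepared(prep, model$embedding$vectors, model$params,
                      model$heads[[i]], model$config$batch_size)
  out <- data.frame(
    sentence_id = vapply(prep, `[[`, "", "sentence_id"),
    e1 = vapply(prep, `[[`, "", "e1"),
    e2 = vapply(prep, `[[`, "", "e2"),
    gold = vapply(prep, `[[`, "", "label"),
    label = ev$pred, stringsAsFactors = FALSE)
  probs <- as.data.frame(ev$probs)
  names(probs) <- paste0("p_", model$labels[[i]])
  cbind(out, probs)
}
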