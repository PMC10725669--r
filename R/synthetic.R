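# Built-in disjoint trigger lexicons. The trigger placed strictly between
# two drug mentions determines the pair's gold class, so the path and
# importance filters carry real signal by construction.
default_triggers <- function(classes) {
  lex <- list(
    POSITIVE = c("interacts", "potentiates", "antagonizes"),
    ADVICE = c("avoid", "recommended", "caution"),
    EFFECT = c("enhances", "increases", "prolongs"),
    MECHANISM = c("inhibits", "accelerates", "metabolism"),
    INT = c("interacts", "synergizes"))
  lex[setdiff(classes, "NEGATIVE")]
}

filler_lexicon <- function(n) {
  # deterministic pronounceable filler words, disjoint from triggers/drugs
  syl <- c("ta", "re", "mo", "li", "sa", "ne", "ko", "vi", "du", "pe")
  words <- character(n)
  for (i in seq_len(n)) {
    k <- 2L + (i %% 3L)
    idx <- (floor(i * 7L^(seq_len(k) - 1L)) %% length(syl)) + 1L
    words[i] <- paste0("w", i, paste(syl[idx], collapse = ""))
  }
  words
}

drug_lexicon <- function(n) {
  stem <- c("velo", "cari", "zopra", "melan", "tubi", "xandi", "quro",
            "farna", "gisto", "plev")
  suffix <- c("mycin", "olol", "pril", "azole", "statin", "mab", "dine")
  vapply(seq_len(n), function(i)
    paste0(stem[(i - 1L) %% length(stem) + 1L],
           suffix[(i - 1L) %% length(suffix) + 1L], i), "")
}

#' Configuration of the synthetic DDI corpus generator
#'
#' The generator emits DDIExtraction-dialect sentences in which every pair
#' of drug mentions is annotated, and the gold class of a pair is a
#' deterministic function of the trigger tokens lying strictly between the
#' two mentions (the first such trigger's class; no trigger means
#' `NEGATIVE`). Label noise optionally replaces a gold label with a
#' uniform draw over all classes with probability `label_noise`, so the
#' best achievable accuracy is `1 - label_noise * (k - 1) / k`.
#'
#' @param n_sentences number of sentences to generate
#' @param drugs_min,drugs_max range of drug mentions per sentence (min 2)
#' @param vocabulary_size number of filler word types
#' @param classes label set; must contain `"NEGATIVE"`. Use
#'   `c("NEGATIVE", "POSITIVE")` for a coarse-grained corpus or a subset
#'   of `c("NEGATIVE", DDI_TYPES)` for a fine-grained one
#' @param priors named class priors (sum to 1) used when sampling the
#'   intended class of each adjacent drug pair
#' @param triggers named list of trigger tokens per positive class;
#'   lexicons must be pairwise disjoint
#' @param label_noise noise rate in `[0, 0.5)`
#' @param seed RNG seed
#' @return list of class `synth_config`
#' @export
synth_config <- function(n_sentences = 200L, drugs_min = 2L, drugs_max = 3L,
                         vocabulary_size = 120L,
                         classes = c("NEGATIVE", "POSITIVE"),
                         priors = NULL, triggers = NULL,
                         label_noise = 0, seed = 1L) {
  stopifnot(n_sentences >= 1L, drugs_min >= 2L, drugs_max >= drugs_min,
            label_noise >= 0, label_noise < 0.5,
            "NEGATIVE" %in% classes, length(classes) >= 2L)
  if (is.null(priors)) {
    priors <- stats::setNames(rep(0.5 / (length(classes) - 1L),
                                  length(classes)), classes)
    priors["NEGATIVE"] <- 0.5
  }
  if (!setequal(names(priors), classes))
    stop("priors must be named by the classes", call. = FALSE)
  if (abs(sum(priors) - 1) > 1e-8)
    stop("priors must sum to 1", call. = FALSE)
  if (is.null(triggers)) triggers <- default_triggers(classes)
  pos <- setdiff(classes, "NEGATIVE")
  if (!setequal(names(triggers), pos))
    stop("triggers must be named by the positive classes", call. = FALSE)
  all_trig <- unlist(triggers, use.names = FALSE)
  if (anyDuplicated(all_trig))
    stop("trigger lexicons must be disjoint", call. = FALSE)
  structure(list(n_sentences = as.integer(n_sentences),
                 drugs_min = as.integer(drugs_min),
                 drugs_max = as.integer(drugs_max),
                 vocabulary_size = as.integer(vocabulary_size),
                 classes = classes, priors = priors[classes],
                 triggers = triggers, label_noise = label_noise,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# class of the first trigger token strictly between the two target runs
path_trigger_class <- function(tokens, run1, run2, triggers) {
  if (run1[1] > run2[1]) { tmp <- run1; run1 <- run2; run2 <- tmp }
  between <- if (run2[1] - run1[2] > 1L)
    tokens[(run1[2] + 1L):(run2[1] - 1L)] else character()
  for (tok in between)
    for (cls in names(triggers))
      if (tok %in% triggers[[cls]]) return(cls)
  "NEGATIVE"
}

#' The generator's own labeling rule, applied to an instance
#'
#' Reads only the tokens strictly between the two target mentions and
#' returns the class of the first trigger found (or `"NEGATIVE"`). On a
#' noiseless synthetic corpus this rule is the Bayes-optimal classifier
#' and recovers every gold label exactly; it is the reference against
#' which learned models are compared.
#'
#' @param instance a `ddi_instance` (see [candidate_instances()])
#' @param triggers trigger lexicons as in [synth_config()]
#' @return predicted class label
#' @export
trigger_rule_label <- function(instance, triggers) {
  s <- instance$sentence
  toks <- tokenize(s$text)
  ents <- stats::setNames(s$entities, vapply(s$entities, `[[`, "", "id"))
  run1 <- entity_token_run(toks, ents[[instance$target1]])
  run2 <- entity_token_run(toks, ents[[instance$target2]])
  path_trigger_class(toks$token, run1, run2, triggers)
}

#' Generate a synthetic DDI corpus
#'
#' Deterministic for a fixed `config$seed` (identical corpus objects and,
#' through [write_ddi_corpus()], identical XML bytes). Every sentence with
#' n drug mentions carries exactly `choose(n, 2)` pair annotations whose
#' labels follow the trigger-on-path rule of [synth_config()], then label
#' noise.
#'
#' @param config a [synth_config()]
#' @return a [ddi_corpus()] (task `"binary"` when the classes are
#'   NEGATIVE/POSITIVE, `"five_class"` otherwise)
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  task <- if (setequal(config$classes, c("NEGATIVE", "POSITIVE")))
    "binary" else "five_class"
  fillers <- filler_lexicon(config$vocabulary_size)
  pos_classes <- setdiff(config$classes, "NEGATIVE")
  with_seed(config$seed, {
    drugs_all <- drug_lexicon(max(50L, 4L * config$drugs_max))
    sentences <- vector("list", config$n_sentences)
    for (si in seq_len(config$n_sentences)) {
      k <- if (config$drugs_max > config$drugs_min)
        sample(config$drugs_min:config$drugs_max, 1L) else config$drugs_min
      drugs <- sample(drugs_all, k)
      filler <- function(n) sample(fillers, n, replace = TRUE)
      toks <- character()
      is_drug <- logical()
      push <- function(words, drug = FALSE) {
        toks <<- c(toks, words)
        is_drug <<- c(is_drug, rep(drug, length(words)))
      }
      # sentence shape mimics corpus sentences: a preamble, drug mentions
      # separated by several-token gaps (optionally holding the trigger),
      # and a tail clause after the last mention
      push(filler(sample(2:5, 1L)))
      for (j in seq_len(k)) {
        push(drugs[j], drug = TRUE)
        if (j < k) {
          gap <- filler(sample(3:7, 1L))
          cls <- sample(config$classes, 1L, prob = config$priors)
          if (cls != "NEGATIVE") {
            trig <- sample(config$triggers[[cls]], 1L)
            gap[sample(seq_along(gap), 1L)] <- trig
          }
          push(gap)
        }
      }
      push(filler(sample(3:7, 1L)))
      text <- paste(toks, collapse = " ")
      starts <- cumsum(c(0L, nchar(toks[-length(toks)]) + 1L))
      ends <- starts + nchar(toks) - 1L
      drug_pos <- which(is_drug)
      entities <- lapply(seq_along(drug_pos), function(j) {
        tp <- drug_pos[j]
        ddi_entity(sprintf("d0.s%d.e%d", si - 1L, j - 1L),
                   starts[tp], ends[tp], toks[tp])
      })
      pairs <- list()
      for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
        label <- path_trigger_class(toks, rep(drug_pos[a], 2L),
                                    rep(drug_pos[b], 2L), config$triggers)
        if (config$label_noise > 0 &&
            stats::runif(1) < config$label_noise)
          label <- sample(config$classes, 1L)
        pairs[[length(pairs) + 1L]] <- list(
          e1 = entities[[a]]$id, e2 = entities[[b]]$id,
          interacts = label != "NEGATIVE",
          ddi_type = if (task == "five_class" && label != "NEGATIVE")
            label else NA_character_)
      }
      sentences[[si]] <- ddi_sentence(sprintf("d0.s%d", si - 1L), text,
                                      entities, pairs)
    }
    ddi_corpus(list(ddi_document("d0", sentences)), task = task)
  })
}
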