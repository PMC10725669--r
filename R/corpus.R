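#' DDI type labels of the fine-grained task
#'
#' The four positive interaction types of the fine-grained task plus the
#' non-interacting label. Coarse-grained (binary) corpora use only
#' `"POSITIVE"`/`"NEGATIVE"`.
#' @export
DDI_TYPES <- c("ADVICE", "EFFECT", "MECHANISM", "INT")

#' @rdname DDI_TYPES
#' @export
DDI_NEGATIVE <- "NEGATIVE"

#' @rdname DDI_TYPES
#' @export
DDI_POSITIVE <- "POSITIVE"

task_labels <- function(task) {
  if (task == "binary") c(DDI_NEGATIVE, DDI_POSITIVE) else c(DDI_NEGATIVE, DDI_TYPES)
}

#' Construct a drug entity mention
#'
#' Character offsets are 0-based with inclusive start and end, the
#' DDIExtraction community convention: `surface` must equal
#' `substr(text, char_start + 1, char_end + 1)` of the owning sentence.
#'
#' @param id entity identifier, unique within the sentence
#' @param char_start,char_end 0-based inclusive character offsets
#' @param surface the mention text at those offsets
#' @return an object of class `ddi_entity`
#' @export
ddi_entity <- function(id, char_start, char_end, surface) {
  stopifnot(is.character(id), length(id) == 1L,
            char_start >= 0, char_end >= char_start)
  structure(list(id = id, char_start = as.integer(char_start),
                 char_end = as.integer(char_end), surface = surface),
            class = "ddi_entity")
}

#' Construct a sentence with entity mentions and pair annotations
#'
#' @param id sentence identifier
#' @param text sentence text
#' @param entities list of [ddi_entity()] objects
#' @param pairs list of pair annotations, each a list with fields
#'   `e1`, `e2` (entity ids), `interacts` (logical) and `ddi_type`
#'   (one of [DDI_TYPES] or `NA`)
#' @return an object of class `ddi_sentence`
#' @export
ddi_sentence <- function(id, text, entities = list(), pairs = list()) {
  structure(list(id = id, text = text, entities = entities, pairs = pairs),
            class = "ddi_sentence")
}

#' Construct a document
#' @param id document identifier
#' @param sentences list of [ddi_sentence()] objects
#' @return an object of class `ddi_document`
#' @export
ddi_document <- function(id, sentences = list()) {
  structure(list(id = id, sentences = sentences), class = "ddi_document")
}

#' Construct a DDI corpus
#'
#' @param documents list of [ddi_document()] objects
#' @param task `"binary"` (coarse-grained: does the pair interact?) or
#'   `"five_class"` (fine-grained: ADVICE/EFFECT/MECHANISM/INT/NEGATIVE)
#' @param validate check offset/surface/pair invariants
#' @return an object of class `ddi_corpus`
#' @export
ddi_corpus <- function(documents = list(), task = c("binary", "five_class"),
                       validate = TRUE) {
  task <- match.arg(task)
  corpus <- structure(list(documents = documents, task = task),
                      class = "ddi_corpus")
  if (validate) validate_corpus(corpus)
  corpus
}

#' @export
print.ddi_corpus <- function(x, ...) {
  ns <- sum(vapply(x$documents, function(d) length(d$sentences), 1L))
  np <- sum(unlist(lapply(x$documents, function(d)
    vapply(d$sentences, function(s) length(s$pairs), 1L))), 0L)
  cat(sprintf("<ddi_corpus> task=%s  %d document(s), %d sentence(s), %d annotated pair(s)\n",
              x$task, length(x$documents), ns, np))
  invisible(x)
}

validate_sentence <- function(s, task) {
  nchar_text <- nchar(s$text)
  ids <- vapply(s$entities, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate entity id in sentence ", s$id, ": ",
         ids[duplicated(ids)][1], call. = FALSE)
  for (e in s$entities) {
    if (e$char_start < 0 || e$char_end >= nchar_text)
      stop("entity ", e$id, " offsets [", e$char_start, ",", e$char_end,
           "] outside sentence text (", nchar_text, " chars)", call. = FALSE)
    slice <- substr(s$text, e$char_start + 1L, e$char_end + 1L)
    if (!identical(slice, e$surface))
      stop("entity ", e$id, " surface mismatch: annotation '", e$surface,
           "' but text slice is '", slice, "'", call. = FALSE)
  }
  for (p in s$pairs) {
    if (identical(p$e1, p$e2))
      stop("pair in sentence ", s$id, " references entity ", p$e1,
           " twice", call. = FALSE)
    if (!all(c(p$e1, p$e2) %in% ids))
      stop("pair in sentence ", s$id, " references unknown entity id: ",
           setdiff(c(p$e1, p$e2), ids)[1], call. = FALSE)
    if (isTRUE(p$interacts) && task == "five_class") {
      if (is.null(p$ddi_type) || is.na(p$ddi_type) || !(p$ddi_type %in% DDI_TYPES))
        stop("positive pair (", p$e1, ",", p$e2, ") in sentence ", s$id,
             " lacks a valid ddi_type", call. = FALSE)
    }
  }
  invisible(TRUE)
}

validate_corpus <- function(corpus) {
  for (d in corpus$documents) {
    sids <- vapply(d$sentences, `[[`, "", "id")
    if (anyDuplicated(sids))
      stop("duplicate sentence id in document ", d$id, call. = FALSE)
    for (s in d$sentences) validate_sentence(s, corpus$task)
  }
  invisible(TRUE)
}

parse_char_offset <- function(off, id) {
  # real corpora may carry discontinuous mentions "a-b;c-d": only the first
  # span is used for positioning
  first <- strsplit(off, ";", fixed = TRUE)[[1]][1]
  parts <- strsplit(first, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2L || anyNA(suppressWarnings(as.integer(parts))))
    stop("entity ", id, ": cannot parse charOffset '", off, "'", call. = FALSE)
  as.integer(parts)
}

#' Read a DDIExtraction-style XML corpus
#'
#' Parses the community XML dialect: a `<corpus>` (or single `<document>`)
#' root containing `<document id>` elements, each holding
#' `<sentence id text>` with `<entity id charOffset text>` and
#' `<pair e1 e2 ddi type>` children. `charOffset` is `start-end`, 0-based
#' inclusive; for discontinuous mentions (`a-b;c-d`) only the first span is
#' used. Entity offsets are validated against the sentence text on read.
#'
#' @param path path to the XML file
#' @param task `"binary"` or `"five_class"`
#' @return a [ddi_corpus()] object
#' @export
read_ddi_corpus <- function(path, task = c("binary", "five_class")) {
  task <- match.arg(task)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed XML in ", path, ": ", conditionMessage(e), call. = FALSE))
  root <- xml2::xml_name(doc)
  doc_nodes <- if (root == "document") list(doc) else
    xml2::xml_find_all(doc, "./document")
  documents <- lapply(doc_nodes, function(dn) {
    sents <- lapply(xml2::xml_find_all(dn, "./sentence"), function(sn) {
      text <- xml2::xml_attr(sn, "text")
      ents <- lapply(xml2::xml_find_all(sn, "./entity"), function(en) {
        id <- xml2::xml_attr(en, "id")
        off <- parse_char_offset(xml2::xml_attr(en, "charOffset"), id)
        surf <- xml2::xml_attr(en, "text")
        # discontinuous mention: surface attribute may cover all spans; trust
        # the first-span slice instead
        slice <- substr(text, off[1] + 1L, off[2] + 1L)
        if (grepl(";", xml2::xml_attr(en, "charOffset"), fixed = TRUE))
          surf <- slice
        ddi_entity(id, off[1], off[2], surf)
      })
      prs <- lapply(xml2::xml_find_all(sn, "./pair"), function(pn) {
        ddi <- tolower(xml2::xml_attr(pn, "ddi"))
        type <- xml2::xml_attr(pn, "type")
        if (!is.na(type)) {
          type <- toupper(type)
          # 2013 files abbreviate "advise"/"effect"/"mechanism"/"int"
          type <- switch(type, ADVISE = "ADVICE", type)
          if (!(type %in% DDI_TYPES))
            stop("unknown ddi_type '", type, "' in sentence ",
                 xml2::xml_attr(sn, "id"), call. = FALSE)
        }
        list(e1 = xml2::xml_attr(pn, "e1"), e2 = xml2::xml_attr(pn, "e2"),
             interacts = identical(ddi, "true"),
             ddi_type = if (is.na(type)) NA_character_ else type)
      })
      ddi_sentence(xml2::xml_attr(sn, "id"), text, ents, prs)
    })
    ddi_document(xml2::xml_attr(dn, "id"), sents)
  })
  ddi_corpus(documents, task = task, validate = TRUE)
}

xml_escape_attr <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

#' Write a corpus in the DDIExtraction XML dialect
#'
#' Emits the same dialect [read_ddi_corpus()] parses; `read(write(x))`
#' round-trips to an identical corpus model, and output bytes are
#' deterministic for a given corpus.
#'
#' @param corpus a [ddi_corpus()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_ddi_corpus <- function(corpus, path) {
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
             sprintf("<corpus task=\"%s\">", corpus$task))
  for (d in corpus$documents) {
    lines <- c(lines, sprintf("  <document id=\"%s\">", xml_escape_attr(d$id)))
    for (s in d$sentences) {
      lines <- c(lines, sprintf("    <sentence id=\"%s\" text=\"%s\">",
                                xml_escape_attr(s$id), xml_escape_attr(s$text)))
      for (e in s$entities)
        lines <- c(lines, sprintf(
          "      <entity id=\"%s\" charOffset=\"%d-%d\" type=\"drug\" text=\"%s\"/>",
          xml_escape_attr(e$id), e$char_start, e$char_end,
          xml_escape_attr(e$surface)))
      for (i in seq_along(s$pairs)) {
        p <- s$pairs[[i]]
        type_attr <- if (!is.null(p$ddi_type) && !is.na(p$ddi_type))
          sprintf(" type=\"%s\"", p$ddi_type) else ""
        lines <- c(lines, sprintf(
          "      <pair id=\"%s.p%d\" e1=\"%s\" e2=\"%s\" ddi=\"%s\"%s/>",
          xml_escape_attr(s$id), i - 1L, xml_escape_attr(p$e1),
          xml_escape_attr(p$e2), if (isTRUE(p$interacts)) "true" else "false",
          type_attr))
      }
      lines <- c(lines, "    </sentence>")
    }
    lines <- c(lines, "  </document>")
  }
  lines <- c(lines, "</corpus>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Enumerate candidate drug-pair instances of a sentence
#'
#' A sentence with n drug mentions yields choose(n, 2) candidate pairs, the
#' classification units of DDI extraction. With `gold = TRUE` one instance
#' is produced per annotated pair, carrying the annotated label; otherwise
#' every unordered entity pair is enumerated and labeled `"NEGATIVE"`.
#' Instances are ordered by (char_start of first target, char_start of
#' second target, entity ids), so batching is reproducible.
#'
#' @param sentence a [ddi_sentence()]
#' @param task `"binary"` or `"five_class"` (controls the label set)
#' @param gold use the annotated pairs and labels
#' @return list of `ddi_instance` objects with fields `sentence`,
#'   `target1`, `target2`, `label`
#' @export
candidate_instances <- function(sentence, task = "binary", gold = TRUE) {
  ents <- sentence$entities
  if (length(ents) < 2L && !gold) return(list())
  by_id <- stats::setNames(ents, vapply(ents, `[[`, "", "id"))
  mk <- function(id1, id2, label) {
    e1 <- by_id[[id1]]; e2 <- by_id[[id2]]
    if (is.null(e1) || is.null(e2))
      stop("pair references unknown entity in sentence ", sentence$id,
           call. = FALSE)
    # order targets by position in text
    if (e1$char_start > e2$char_start ||
        (e1$char_start == e2$char_start && e1$id > e2$id)) {
      tmp <- e1; e1 <- e2; e2 <- tmp
    }
    structure(list(sentence = sentence, target1 = e1$id, target2 = e2$id,
                   label = label), class = "ddi_instance")
  }
  if (gold) {
    inst <- lapply(sentence$pairs, function(p) {
      label <- if (!isTRUE(p$interacts)) DDI_NEGATIVE
      else if (task == "binary") DDI_POSITIVE
      else p$ddi_type
      mk(p$e1, p$e2, label)
    })
  } else {
    ids <- vapply(ents, `[[`, "", "id")
    inst <- list()
    n <- length(ids)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      inst[[length(inst) + 1L]] <- mk(ids[i], ids[j], DDI_NEGATIVE)
  }
  if (length(inst) == 0L) return(inst)
  key1 <- vapply(inst, function(x) by_id[[x$target1]]$char_start, 1L)
  key2 <- vapply(inst, function(x) by_id[[x$target2]]$char_start, 1L)
  id1 <- vapply(inst, `[[`, "", "target1")
  inst[order(key1, key2, id1)]
}

#' Enumerate candidate instances over a whole corpus
#'
#' @param corpus a [ddi_corpus()]
#' @param gold use annotated pairs and labels (see [candidate_instances()])
#' @return flat list of `ddi_instance` objects in document/sentence order
#' @export
corpus_instances <- function(corpus, gold = TRUE) {
  out <- list()
  for (d in corpus$documents) for (s in d$sentences)
    out <- c(out, candidate_instances(s, task = corpus$task, gold = gold))
  out
}

#' Emit a JSONL mirror of a corpus's candidate instances
#'
#' One JSON object per line: sentence id, targets, label, sentence text.
#' Intended for eyeballing and downstream debugging.
#'
#' @param corpus a [ddi_corpus()]
#' @param path output path
#' @param gold see [candidate_instances()]
#' @return `path`, invisibly
#' @export
write_instances_jsonl <- function(corpus, path, gold = TRUE) {
  inst <- corpus_instances(corpus, gold = gold)
  lines <- vapply(inst, function(x) {
    jsonlite::toJSON(list(sentence_id = x$sentence$id, e1 = x$target1,
                          e2 = x$target2, label = x$label,
                          text = x$sentence$text),
                     auto_unbox = TRUE)
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write model predictions as tab-separated text
#'
#' Columns: sentence_id, e1, e2, predicted_label, then one probability
#' column per class.
#'
#' @param predictions data frame as returned by [predict_corpus()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_predictions <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Split a corpus into train and held-out parts by sentence
#'
#' Sentences are shuffled (deterministically for a given seed) and split,
#' so all candidate pairs of one sentence land on the same side.
#'
#' @param corpus a [ddi_corpus()]
#' @param train_fraction fraction of sentences in the training part
#' @param seed RNG seed for the shuffle
#' @return list with `train` and `test` corpora
#' @export
split_corpus <- function(corpus, train_fraction = 0.75, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  sents <- list()
  for (d in corpus$documents) sents <- c(sents, d$sentences)
  n <- length(sents)
  ord <- with_seed(seed, sample.int(n))
  n_train <- max(1L, floor(n * train_fraction))
  mk <- function(idx, id) ddi_corpus(list(ddi_document(id, sents[idx])),
                                     task = corpus$task, validate = FALSE)
  list(train = mk(ord[seq_len(n_train)], "train"),
       test = mk(ord[(n_train + 1L):n], "test"))
}
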