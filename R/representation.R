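#' Tokenize sentence text
#'
#' Splits on whitespace, then on punctuation (hyphens, periods, commas and
#' the rest of `[[:punct:]]`), so `"aspirin-warfarin interaction."` yields
#' the three tokens `aspirin`, `warfarin`, `interaction`. The resulting
#' token count is therefore at least the whitespace word count.
#' Punctuation-only fragments are dropped unless `keep_punctuation` is set.
#' Each token carries its source character range (0-based, inclusive), so
#' entity mentions can be mapped onto token runs.
#'
#' @param text sentence text
#' @param keep_punctuation retain punctuation fragments as tokens
#' @return data frame with columns `token`, `char_start`, `char_end`
#'   (0-based inclusive source offsets), in text order
#' @export
tokenize <- function(text, keep_punctuation = FALSE) {
  empty <- data.frame(token = character(), char_start = integer(),
                      char_end = integer(), stringsAsFactors = FALSE)
  if (is.null(text) || !nzchar(text)) return(empty)
  # maximal non-whitespace runs
  m <- gregexpr("[^[:space:]]+", text)[[1]]
  if (m[1] == -1L) return(empty)
  toks <- list()
  pat <- if (keep_punctuation) "[[:punct:]]|[^[:punct:][:space:]]+"
         else "[^[:punct:][:space:]]+"
  for (k in seq_along(m)) {
    start <- m[k]
    word <- substr(text, start, start + attr(m, "match.length")[k] - 1L)
    sub <- gregexpr(pat, word)[[1]]
    if (sub[1] == -1L) next
    for (j in seq_along(sub)) {
      s0 <- start + sub[j] - 1L
      len <- attr(sub, "match.length")[j]
      toks[[length(toks) + 1L]] <- list(
        token = substr(text, s0, s0 + len - 1L),
        char_start = s0 - 1L, char_end = s0 + len - 2L)
    }
  }
  if (length(toks) == 0L) return(empty)
  data.frame(token = vapply(toks, `[[`, "", "token"),
             char_start = vapply(toks, function(x) x$char_start, 1L),
             char_end = vapply(toks, function(x) x$char_end, 1L),
             stringsAsFactors = FALSE)
}

#' Build a random-encoding embedding table
#'
#' Every vocabulary token (plus a reserved `<UNK>` entry for unseen tokens)
#' is assigned a d-dimensional vector with components drawn uniformly from
#' \eqn{[-1/\sqrt d, 1/\sqrt d]}. No pretrained vectors are used: random
#' encoding is the intended strategy, and target drug surface tokens are
#' kept verbatim rather than blinded to "drug1"/"drug2". The table is
#' deterministic given `seed`.
#'
#' @param vocabulary character vector of token types (duplicates collapsed)
#' @param dim embedding dimension d (default 400)
#' @param seed RNG seed
#' @return object of class `embedding_table` with fields `vocabulary`
#'   (token -> row index), `vectors` (matrix, rows = tokens), `dim`,
#'   `unk_index`, `seed`
#' @export
embedding_table <- function(vocabulary, dim = 400L, seed = 1L) {
  stopifnot(dim >= 1L)
  vocabulary <- unique(as.character(vocabulary))
  tokens <- c("<UNK>", setdiff(vocabulary, "<UNK>"))
  bound <- 1 / sqrt(dim)
  vectors <- with_seed(seed, matrix(
    stats::runif(length(tokens) * dim, -bound, bound),
    nrow = length(tokens), ncol = dim, byrow = TRUE))
  rownames(vectors) <- tokens
  structure(list(vocabulary = stats::setNames(seq_along(tokens), tokens),
                 vectors = vectors, dim = as.integer(dim),
                 unk_index = 1L, seed = as.integer(seed)),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d tokens (incl. <UNK>), d=%d, seed=%d\n",
              length(x$vocabulary), x$dim, x$seed))
  invisible(x)
}

#' Look up token indices in an embedding table
#' @param table an [embedding_table()]
#' @param tokens character vector
#' @return integer row indices (unknown tokens map to the UNK row)
#' @export
token_indices <- function(table, tokens) {
  idx <- table$vocabulary[tokens]
  idx[is.na(idx)] <- table$unk_index
  unname(idx)
}

run_distance <- function(t, run) {
  # token-position distance to the nearest token of a run; 0 inside
  if (t >= run[1] && t <= run[2]) 0L
  else if (t < run[1]) run[1] - t
  else t - run[2]
}

#' Target-drug filter vector for one token
#'
#' The four pharmacological filters relate a token to the candidate pair's
#' two target drug mentions (given as token-index runs):
#' \describe{
#'   \item{is_target}{1 if the token lies in either target run.}
#'   \item{is_neighbor}{1 if the token is within `neighbor_radius` token
#'     positions of a run (default radius 1: directly adjacent).}
#'   \item{on_path}{1 if the token lies strictly between the two runs.}
#'   \item{importance}{\eqn{I = 1/(r+1)^2} with r the token distance to the
#'     nearest token of the nearer target run; a target token has r = 0 and
#'     importance 1, an adjacent token r = 1 and importance 0.25.}
#' }
#'
#' @param t token position (1-based)
#' @param run1,run2 integer length-2 vectors `(first, last)` token positions
#'   of the two target mentions, `run1` before `run2`, non-overlapping
#' @param n_tokens sequence length (bounds check)
#' @param neighbor_radius adjacency radius in token positions
#' @return named numeric vector `(is_target, is_neighbor, on_path, importance)`
#' @export
phar_vector <- function(t, run1, run2, n_tokens, neighbor_radius = 1L) {
  if (t < 1L || t > n_tokens)
    stop("token index ", t, " out of range 1..", n_tokens, call. = FALSE)
  if (run1[1] > run2[1]) { tmp <- run1; run1 <- run2; run2 <- tmp }
  r <- min(run_distance(t, run1), run_distance(t, run2))
  c(is_target = as.numeric(r == 0L),
    is_neighbor = as.numeric(r > 0L && r <= neighbor_radius),
    on_path = as.numeric(t > run1[2] && t < run2[1]),
    importance = 1 / (r + 1)^2)
}

#' Map an entity mention to its token run
#'
#' Tokens whose character range overlaps the entity span form the run; the
#' run must be contiguous (a multi-token mention like "beta-blockers" maps
#' to the run `beta`,`blockers`).
#'
#' @param tokens a [tokenize()] data frame
#' @param entity a [ddi_entity()]
#' @return integer `(first, last)` token positions (1-based)
#' @export
entity_token_run <- function(tokens, entity) {
  hit <- which(tokens$char_start <= entity$char_end &
               tokens$char_end >= entity$char_start)
  if (length(hit) == 0L)
    stop("entity ", entity$id, " ('", entity$surface,
         "') maps to no tokens", call. = FALSE)
  if (any(diff(hit) != 1L))
    stop("entity ", entity$id, " maps to a non-contiguous token run",
         call. = FALSE)
  c(hit[1], hit[length(hit)])
}

#' Build the pharmacological representation of a candidate instance
#'
#' Tokenizes the sentence, maps every token to its embedding vector and to
#' the 4-dimensional filter vector of [phar_vector()] relative to the two
#' target drugs. Target drug tokens are kept verbatim (no drug blinding).
#'
#' @param instance a `ddi_instance` from [candidate_instances()]
#' @param table an [embedding_table()]
#' @param neighbor_radius see [phar_vector()]
#' @param keep_punctuation see [tokenize()]
#' @return object of class `phar_representation`: list with `tokens`
#'   (character), `token_ids` (embedding rows), `token_vectors` (n x d),
#'   `phar_vectors` (n x 4), `label`
#' @export
build_representation <- function(instance, table, neighbor_radius = 1L,
                                 keep_punctuation = FALSE) {
  s <- instance$sentence
  toks <- tokenize(s$text, keep_punctuation = keep_punctuation)
  if (nrow(toks) == 0L)
    stop("sentence ", s$id, " has no tokens", call. = FALSE)
  ents <- stats::setNames(s$entities, vapply(s$entities, `[[`, "", "id"))
  run1 <- entity_token_run(toks, ents[[instance$target1]])
  run2 <- entity_token_run(toks, ents[[instance$target2]])
  n <- nrow(toks)
  phar <- t(vapply(seq_len(n), phar_vector, numeric(4),
                   run1 = run1, run2 = run2, n_tokens = n,
                   neighbor_radius = neighbor_radius))
  ids <- token_indices(table, toks$token)
  structure(list(tokens = toks$token, token_ids = ids,
                 token_vectors = table$vectors[ids, , drop = FALSE],
                 phar_vectors = phar, label = instance$label),
            class = "phar_representation")
}
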