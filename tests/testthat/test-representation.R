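test_that("tokenization splits on whitespace then punctuation", {
  toks <- tokenize("aspirin-warfarin interaction.")
  expect_equal(toks$token, c("aspirin", "warfarin", "interaction"))
  expect_equal(nrow(toks), 3L)          # n = 3 > m = 2 whitespace words
  expect_equal(nrow(tokenize("")), 0L)
  expect_equal(nrow(tokenize("   ")), 0L)
  # token count never drops below the whitespace word count
  for (txt in c("a b c", "x-y z", "one, two; three.", "a.b.c-d"))
    expect_gte(nrow(tokenize(txt)),
               length(strsplit(trimws(txt), "[[:space:]]+")[[1]]))
  # source ranges point back at the text
  toks2 <- tokenize("beta-blockers slow heart")
  for (i in seq_len(nrow(toks2)))
    expect_equal(substr("beta-blockers slow heart",
                        toks2$char_start[i] + 1L, toks2$char_end[i] + 1L),
                 toks2$token[i])
  expect_true("." %in% tokenize("end.", keep_punctuation = TRUE)$token)
})

test_that("a multi-token entity span maps to a contiguous token run", {
  text <- "taking beta-blockers daily"
  toks <- tokenize(text)
  ent <- ddi_entity("e0", 7L, 19L, "beta-blockers")
  run <- entity_token_run(toks, ent)
  expect_equal(toks$token[run[1]:run[2]], c("beta", "blockers"))
})

test_that("random-encoding tables are bounded, seeded and UNK-complete", {
  tab <- embedding_table(c("alpha", "beta"), dim = 400L, seed = 5L)
  expect_true(all(abs(tab$vectors) <= 1 / sqrt(400)))  # = 0.05
  tab1 <- embedding_table(letters, dim = 1L, seed = 2L)
  expect_true(all(abs(tab1$vectors) <= 1))
  expect_identical(embedding_table(letters, 16L, seed = 9L)$vectors,
                   embedding_table(letters, 16L, seed = 9L)$vectors)
  expect_false(identical(embedding_table(letters, 16L, seed = 9L)$vectors,
                         embedding_table(letters, 16L, seed = 10L)$vectors))
  # empty vocabulary still has the UNK row; unknown tokens hit it
  empty <- embedding_table(character(), dim = 8L, seed = 1L)
  expect_equal(nrow(empty$vectors), 1L)
  expect_equal(token_indices(tab, c("alpha", "never-seen")),
               c(tab$vocabulary[["alpha"]], tab$unk_index))
})

test_that("the four filters follow the target-relative definitions", {
  # r = 0 on a target, importance 1
  v <- phar_vector(2, c(2, 2), c(5, 5), 6)
  expect_equal(unname(v), c(1, 0, 0, 1))
  # adjacent token: r = 1, importance 1/4
  v <- phar_vector(3, c(2, 2), c(6, 6), 7)
  expect_equal(v[["importance"]], 0.25)
  expect_equal(v[["is_neighbor"]], 1)
  # r = 3 from any target
  v <- phar_vector(1, c(4, 4), c(9, 9), 9)
  expect_equal(v[["importance"]], 1 / 16)
  expect_equal(v[["is_target"]], 0)
  expect_error(phar_vector(10, c(1, 1), c(3, 3), 5), "out of range")
})

test_that("a 5-token candidate yields the hand-evaluated filter matrix", {
  s <- ddi_sentence("s", "drugA word1 word2 word3 drugB",
                    list(ddi_entity("e0", 0L, 4L, "drugA"),
                         ddi_entity("e1", 24L, 28L, "drugB")))
  inst <- structure(list(sentence = s, target1 = "e0", target2 = "e1",
                         label = "POSITIVE"), class = "ddi_instance")
  tab <- embedding_table(c("drugA", "drugB"), dim = 6L, seed = 1L)
  rep <- build_representation(inst, tab)
  expect_equal(rep$phar_vectors[, "importance"],
               c(1, 0.25, 1 / 9, 0.25, 1))
  expect_equal(rep$phar_vectors[, "on_path"], c(0, 1, 1, 1, 0))
  expect_equal(rep$phar_vectors[, "is_target"], c(1, 0, 0, 0, 1))
  # middle token adjacent to both targets at distance 1 when targets are
  # two apart
  s2 <- ddi_sentence("s2", "drugA word1 drugB",
                     list(ddi_entity("e0", 0L, 4L, "drugA"),
                          ddi_entity("e1", 12L, 16L, "drugB")))
  inst2 <- structure(list(sentence = s2, target1 = "e0", target2 = "e1",
                          label = "POSITIVE"), class = "ddi_instance")
  rep2 <- build_representation(inst2, tab)
  expect_equal(unname(rep2$phar_vectors[2, ]), c(0, 1, 1, 0.25))
  # unknown tokens share the UNK vector
  expect_equal(rep2$token_vectors[2, ], unname(tab$vectors[1, ]))
})

test_that("filter matrices are symmetric in the target pair", {
  cfg <- synth_config(n_sentences = 10L, seed = 21L)
  corp <- generate_corpus(cfg)
  tab <- embedding_table("x", dim = 4L, seed = 1L)
  for (inst in corpus_instances(corp)) {
    swapped <- inst
    swapped$target1 <- inst$target2
    swapped$target2 <- inst$target1
    expect_equal(build_representation(inst, tab)$phar_vectors,
                 build_representation(swapped, tab)$phar_vectors)
  }
})

test_that("importance peaks exactly on target runs; path count equals the gap", {
  cfg <- synth_config(n_sentences = 15L, seed = 33L)
  corp <- generate_corpus(cfg)
  tab <- embedding_table("x", dim = 4L, seed = 1L)
  for (inst in corpus_instances(corp)) {
    rep <- build_representation(inst, tab)
    ph <- rep$phar_vectors
    expect_equal(max(ph[, "importance"]), 1)
    expect_equal(ph[, "importance"] == 1, ph[, "is_target"] == 1)
    # brute-force scan oracle for the between-run gap
    s <- inst$sentence
    toks <- tokenize(s$text)
    ents <- stats::setNames(s$entities,
                            vapply(s$entities, `[[`, "", "id"))
    r1 <- entity_token_run(toks, ents[[inst$target1]])
    r2 <- entity_token_run(toks, ents[[inst$target2]])
    if (r1[1] > r2[1]) { tmp <- r1; r1 <- r2; r2 <- tmp }
    gap <- sum(seq_len(nrow(toks)) > r1[2] & seq_len(nrow(toks)) < r2[1])
    expect_equal(sum(ph[, "on_path"]), gap)
  }
})
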