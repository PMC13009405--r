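test_that("normalize_token applies irregulars, suffix rules and cleanup", {
  expect_equal(normalize_token("cookie"), "cookie")
  expect_equal(normalize_token("stealing"), "steal")
  expect_equal(normalize_token("children"), "child")
  expect_equal(normalize_token(c("Cookies!", "took", "dropped", "taking",
                                 "babies", "dishes", "plates", "climbing")),
               c("cookie", "take", "drop", "take",
                 "baby", "dish", "plate", "climb"))
  # unknown word passes through; case and punctuation stripped
  expect_equal(normalize_token("Zorp,"), "zorp")
  expect_error(normalize_token(""), "non-empty")
  # user-supplied irregulars take precedence
  expect_equal(normalize_token("geese", extra_irregular = c(geese = "goose")),
               "goose")
})

test_that("score_cwf reproduces the worked coding example", {
  cl <- tiny_checklist()
  tr <- make_transcript(c("the", "boy", "is", "stealing", "cookies", "and",
                          "he", "took", "a", "cookie", "cookie"))
  res <- score_cwf(tr, cl)
  expect_equal(res$total, 4L)
  expect_equal(res$per_item_counts, c(cookie = 2L, steal = 2L, fall = 0L))
  expect_equal(res$audit$match_kind, c("inflected", "inflected", "synonym", "lemma"))
  expect_equal(res$excluded$reason, "immediate_repetition")
  expect_equal(res$excluded$position, 11L)
})

test_that("score_cwf identity and empty cases", {
  cl <- tiny_checklist()
  expect_equal(score_cwf(transcript("p0"), cl)$total, 0L)
  expect_equal(nrow(score_cwf(transcript("p0"), cl)$audit), 0L)
  tr <- make_transcript(c("cookie", "steal", "fall"), phrase = c(1L, 2L, 3L))
  res <- score_cwf(tr, cl)
  expect_equal(res$total, 3L)
  expect_true(all(res$audit$match_kind == "lemma"))
})

test_that("repetition rules: filler transparency, resets, phrases, perseveration", {
  cl <- tiny_checklist()
  # filler between identical matches stays an immediate repetition
  tr <- transcript("p1", data.frame(
    position = 1:3, surface = c("cookie", "uh", "cookie"),
    flags = c("", "filler", ""), phrase_id = c(1L, 1L, 1L)))
  expect_equal(score_cwf(tr, cl)$total, 1L)
  # a contentful token in between makes the repeat count
  expect_equal(score_cwf(make_transcript(c("cookie", "boy", "cookie")), cl)$total, 2L)
  # re-use in a later phrase always counts, even when adjacent
  tr2 <- make_transcript(c("cookie", "cookie"), phrase = c(1L, 2L))
  expect_equal(score_cwf(tr2, cl)$total, 2L)
  # third consecutive resolution is a perseveration
  res <- score_cwf(make_transcript(c("cookie", "cookie", "cookie")), cl)
  expect_equal(res$total, 1L)
  expect_equal(res$excluded$reason, c("immediate_repetition", "perseveration"))
  # synonym then lemma of the same item is still a repetition
  expect_equal(score_cwf(make_transcript(c("take", "steal")), cl)$total, 1L)
  # unintelligible tokens never match
  tr3 <- transcript("p1", data.frame(
    position = 1:2, surface = c("cookie", "cookie"),
    flags = c("unintelligible", ""), phrase_id = c(1L, 1L)))
  res3 <- score_cwf(tr3, cl)
  expect_equal(res3$total, 1L)
  expect_equal(res3$audit$position, 2L)
})

test_that("score_cwf is invariant to case and trailing punctuation", {
  cl <- tiny_checklist()
  a <- score_cwf(make_transcript(c("Cookie,", "STEALING", "fall!")), cl)
  b <- score_cwf(make_transcript(c("cookie", "stealing", "fall")), cl)
  expect_equal(a$total, b$total)
  expect_equal(a$per_item_counts, b$per_item_counts)
})

test_that("count_cius applies flag and repetition exclusions", {
  expect_equal(count_cius(make_transcript(c("uh", "um"), flags = "filler")), 0L)
  tr <- transcript("p1", data.frame(
    position = 1:10,
    surface = c("uh", "boy", "steals", "um", "xxx", "cookie", "cookie",
                "mother", "washes", "dishes"),
    flags = c("filler", "", "", "filler", "unintelligible", "", "", "", "", ""),
    phrase_id = rep(1L, 10)))
  # 2 fillers + 1 unintelligible + 1 immediate repetition excluded -> 6
  expect_equal(count_cius(tr), 6L)
  tr2 <- make_transcript(c("boy", "girl", "mother", "sink", "water"))
  expect_equal(count_cius(tr2), 5L)
  # repetition adjacency is evaluated after removing flagged tokens
  tr3 <- transcript("p1", data.frame(
    position = 1:3, surface = c("cookie", "uh", "cookie"),
    flags = c("", "filler", ""), phrase_id = rep(1L, 3)))
  expect_equal(count_cius(tr3), 1L)
})

test_that("word_count excludes only unintelligible and non-words", {
  expect_equal(word_count(transcript("p0")), 0L)
  tr <- transcript("p1", data.frame(
    position = 1:6, surface = c("a", "b", "c", "d", "e", "xxx"),
    flags = c("", "", "filler", "off_topic", "", "unintelligible"),
    phrase_id = rep(1L, 6)))
  expect_equal(word_count(tr), 5L)
  expect_gte(word_count(tr), count_cius(tr))
})

test_that("audit reconstructs per-item counts and respects word_count bound", {
  cl <- tiny_checklist()
  set.seed(7)
  vocab <- c("cookie", "cookies", "steal", "take", "fall", "boy", "uh", "the")
  for (i in 1:25) {
    words <- sample(vocab, sample(3:14, 1), replace = TRUE)
    flags <- ifelse(words == "uh", "filler", "")
    tr <- transcript("p1", data.frame(
      position = seq_along(words), surface = words, flags = flags,
      phrase_id = cumsum(seq_along(words) %% 4 == 1)))
    res <- score_cwf(tr, cl)
    rebuilt <- table(factor(res$audit$item_id, levels = cl$items$item_id))
    expect_equal(as.integer(rebuilt), unname(res$per_item_counts))
    expect_equal(sum(res$per_item_counts), res$total)
    expect_lte(res$total, word_count(tr))
  }
})

test_that("response_matrix dichotomizes and drops degenerate columns", {
  cl <- tiny_checklist()
  mk <- function(counts) {
    structure(list(participant_id = paste0("p", sample.int(1e6, 1)),
                   per_item_counts = stats::setNames(counts, cl$items$item_id),
                   total = sum(counts),
                   audit = NULL, excluded = NULL), class = "cwf_result")
  }
  rm0 <- response_matrix(list(mk(c(0L, 3L, 1L)), mk(c(2L, 0L, 1L))), cl)
  expect_equal(unname(rm0$data[1, ]), c(0L, 1L, 1L))
  expect_equal(unname(rm0$data[2, ]), c(1L, 0L, 1L))
  expect_equal(ncol(rm0$data), 3L)       # no filtering without for_irt
  rmi <- response_matrix(list(mk(c(0L, 3L, 1L)), mk(c(2L, 0L, 1L))), cl,
                         for_irt = TRUE)
  expect_equal(rmi$dropped_items, "fall")  # all-1 column dropped
  expect_equal(ncol(rmi$data), 2L)
  expect_error(response_matrix(list(), cl), "non-empty")
})

test_that("a 22-item cohort with degenerate items retains the informative ones", {
  cfg <- simulation_config(n_participants = 60, n_items = 22,
                           grid_shape = c(12, 12, 12), seed = 5)
  coh <- generate_cohort(cfg)
  rmi <- response_matrix(coh$cwf_results, coh$checklist, for_irt = TRUE)
  expect_equal(ncol(rmi$data) + length(rmi$dropped_items), 22L)
  expect_true(all(colMeans(rmi$data) > 0 & colMeans(rmi$data) < 1))
})

test_that("transcript TSV and CHAT-lite readers round-trip", {
  tr <- transcript("p9", data.frame(
    position = 1:4, surface = c("the", "boy", "uh", "cookie"),
    flags = c("", "", "filler", ""), phrase_id = c(1L, 1L, 1L, 2L)))
  f <- tempfile(fileext = ".tsv")
  write_transcript_tsv(tr, f)
  back <- read_transcript_tsv(f, participant_id = "p9")
  expect_equal(back$tokens$surface, tr$tokens$surface)
  expect_equal(back$tokens$flags, tr$tokens$flags)
  expect_equal(back$tokens$phrase_id, tr$tokens$phrase_id)

  chat <- tempfile(fileext = ".cha")
  writeLines(c("@Begin", "the boy &-uh steals cookies [x 3]",
               "%com: ignored", "xxx mother washes"), chat)
  ct <- read_transcript_chat(chat, "p2")
  expect_equal(ct$tokens$surface[3], "uh")
  expect_equal(ct$tokens$flags[3], "filler")
  # [x 3] expands to three total copies of "cookies"
  expect_equal(sum(ct$tokens$surface == "cookies"), 3L)
  expect_equal(ct$tokens$flags[ct$tokens$surface == "xxx"], "unintelligible")
  expect_equal(unique(ct$tokens$phrase_id), c(1L, 2L))
})

test_that("transcript and checklist constructors enforce invariants", {
  expect_error(transcript(""), "non-empty")
  expect_error(transcript("p1", data.frame(position = c(1L, 1L),
                                           surface = c("a", "b"),
                                           flags = "", phrase_id = 1L)),
               "strictly increasing")
  expect_error(make_transcript("a", flags = "bogus"), "unknown token flags")
  items <- tiny_checklist()$items
  expect_error(checklist(items, synonyms = list(cookie = "steal")), "synonym")
  expect_error(checklist(rbind(items, items)), "unique")
  f <- tempfile(fileext = ".json")
  write_checklist(tiny_checklist(), f)
  back <- read_checklist(f)
  expect_equal(back$items$lemma, items$lemma)
  expect_equal(back$synonyms$steal, "take")
})
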