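test_that("pubtator parsing verifies offsets and splits composite concepts", {
  f <- withr::local_tempfile(lines = tiny_pubtator_lines())
  x <- read_pubtator(f)
  expect_s3_class(x, "ner_corpus")
  expect_equal(nrow(x$docs), 3L)
  expect_equal(nrow(x$mentions), 3L)
  expect_equal(x$mentions$surface[1], "colorectal cancer")
  # composite concept field split on "|"
  expect_equal(x$mentions$concept_ids[[3]], c("MESH:D000740", "OMIM:104225"))

  # offset/surface mismatch is a record-level error
  bad <- tiny_pubtator_lines()
  bad[3] <- paste("101", 42, 59, "colorectal tumour", "Disease", "MESH:D015179",
                  sep = "\t")
  fb <- withr::local_tempfile(lines = bad)
  expect_error(read_pubtator(fb), "mismatch")

  # malformed annotation line reports its line number
  bad2 <- tiny_pubtator_lines()
  bad2[3] <- "101\t42\t59"
  fb2 <- withr::local_tempfile(lines = bad2)
  expect_error(read_pubtator(fb2), "line 3")
})

test_that("pubtator write/read round-trip is byte-identical", {
  for (seed in 1:3) {
    sim <- sim_small(seed)
    f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
    write_pubtator(sim$test, f1)
    x <- read_pubtator(f1)
    write_pubtator(x, f2)
    expect_identical(readLines(f1), readLines(f2))
  }
})

test_that("conll write/read round-trip preserves tokens and tags", {
  sim <- sim_small(4)
  cn <- corpus_to_conll(sim$train)
  f <- withr::local_tempfile()
  write_conll(cn, f)
  cn2 <- read_conll(f)
  expect_equal(length(cn2), length(cn))
  for (i in seq_along(cn)) {
    expect_identical(cn2[[i]]$token, cn[[i]]$token)
    expect_identical(cn2[[i]]$tag, cn[[i]]$tag)
  }
})

test_that("tokenizer splits punctuation but keeps internal hyphens", {
  tk <- tokenize("Treatment of COVID-19 ( severe ) , with MK-486 .")
  expect_true(all(c("COVID-19", "MK-486", "(", ")", ",", ".") %in% tk$token))
  tk2 <- tokenize("(acute) encephalopathy,")
  expect_identical(tk2$token, c("(", "acute", ")", "encephalopathy", ","))
  # offsets always slice back to the token
  txt <- "a (b-c) d."
  tk3 <- tokenize(txt)
  expect_identical(tk3$token, substring(txt, tk3$start + 1L, tk3$end))
})

test_that("mentions_to_bio follows the B/I/O definition", {
  txt <- "acute encephalopathy after dosing"
  tok <- tokenize(txt)
  m <- mentions("d", 0L, 20L, "acute encephalopathy", "Disease", list("C1"))
  expect_identical(mentions_to_bio(tok, m), c("B", "I", "O", "O"))
  expect_identical(mentions_to_bio(tok, mentions()), rep("O", 4L))
  # misaligned mention expands to covering tokens, with a warning
  m2 <- mentions("d", 0L, 9L, "acute enc", "Disease", list("C1"))
  expect_warning(tags <- mentions_to_bio(tok, m2), "expanded")
  expect_identical(tags, c("B", "I", "O", "O"))
  # overlapping gold mentions are rejected
  m3 <- mentions(c("d", "d"), c(0L, 6L), c(20L, 26L),
                 c("acute encephalopathy", "encephalopathy after"),
                 "Disease", list("C1", "C2"))
  expect_error(mentions_to_bio(tok, m3), "overlap")
})

test_that("bio decoding handles runs, orphan I repair, and empty input", {
  txt <- "aa bb cc dd"
  tok <- tokenize(txt)
  m <- bio_to_mentions(tok, c("B", "I", "O", "B"), txt)
  expect_equal(m$surface, c("aa bb", "dd"))
  m2 <- bio_to_mentions(tok, c("O", "I", "I", "O"), txt)
  expect_equal(m2$surface, "bb cc")
  expect_equal(nrow(bio_to_mentions(tok, rep("O", 4L), txt)), 0L)
})

test_that("mentions<->BIO round-trips on random synthetic sentences", {
  n_checked <- 0L
  for (seed in 1:2) {
    sim <- sim_small(seed)
    txt <- doc_text(sim$test)
    for (id in sim$test$docs$doc_id) {
      tok <- tokenize(txt[[id]])
      gold <- sim$test$mentions[sim$test$mentions$doc_id == id, , drop = FALSE]
      tags <- mentions_to_bio(tok, gold)
      back <- bio_to_mentions(tok, tags, txt[[id]], id)
      expect_identical(back$start, gold$start[order(gold$start)])
      expect_identical(back$end, gold$end[order(gold$start)])
      # tag round-trip: decode then re-encode
      expect_identical(mentions_to_bio(tok, back), tags)
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 40L)
})

test_that("corpus construction enforces the slice invariant and unique IDs", {
  docs <- data.frame(doc_id = "d1", title = "a bb c .", abstract = "")
  expect_error(
    corpus(docs, mentions("d1", 2L, 4L, "xx", "Disease", list("C1")),
           entity_types = "Disease"),
    "mismatch")
  docs2 <- data.frame(doc_id = c("d1", "d1"), title = c("x .", "y ."),
                      abstract = "")
  expect_error(corpus(docs2, mentions(), entity_types = "Disease"),
               "duplicate")
})
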