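mk_pred <- function(gold, rows) {
  p <- gold[rows, , drop = FALSE]
  class(p) <- c("ner_mentions", "data.frame")
  p
}

test_that("entity-level P/R/F1 match hand-computed values", {
  sim <- sim_small(1)
  gold <- sim$test$mentions
  # identity -> perfect scores
  r <- entity_prf(gold, gold)
  expect_equal(c(r$precision, r$recall, r$f1), c(1, 1, 1))
  # 4 gold, 2 predictions, 1 exact hit -> P=0.5 R=0.25 F1=1/3
  g4 <- gold[1:4, ]
  fake <- g4[2, ]; fake$start <- fake$start + 1L
  fake$end <- fake$end + 1L
  txt <- doc_text(sim$test)
  fake$surface <- substring(txt[[fake$doc_id]], fake$start + 1L, fake$end)
  pred <- rbind(g4[1, ], fake)
  r2 <- entity_prf(g4, pred)
  expect_equal(r2$precision, 0.5)
  expect_equal(r2$recall, 0.25)
  expect_equal(r2$f1, 1 / 3)
  # empty predictions -> flagged zero precision, zero recall
  r3 <- entity_prf(g4, mentions())
  expect_equal(c(r3$precision, r3$recall, r3$f1), c(0, 0, 0))
  expect_false(r3$precision_defined)
  # duplicated predictions collapse with a warning
  expect_warning(r4 <- entity_prf(g4, rbind(g4[1, ], g4[1, ])), "duplicate")
  expect_equal(r4$tp, 1L)
})

test_that("per-split recall counts hits within each split only", {
  sim <- sim_small(2)
  ga <- assign_split(sim$test$mentions, build_inventory(sim$train))
  mem_rows <- which(ga$split == "Mem")
  pred <- mk_pred(ga, mem_rows)
  r <- split_recall(ga, pred)
  expect_equal(r$recall[r$split == "Mem"], 1.0)
  expect_equal(r$recall[r$split == "Syn"], 0.0)
  expect_equal(r$recall[r$split == "Con"], 0.0)
  expect_equal(r$n, as.integer(table(ga$split)))
  # brute-force per-mention recount
  for (seed in 3:6) {
    sim <- sim_small(seed)
    ga <- assign_split(sim$test$mentions, build_inventory(sim$train))
    keep <- sample(nrow(ga), nrow(ga) %/% 2)
    pred <- mk_pred(ga, keep)
    r <- split_recall(ga, pred)
    for (s in c("Mem", "Syn", "Con")) {
      sel <- which(ga$split == s)
      expect_equal(r$hits[r$split == s], length(intersect(sel, keep)))
    }
  }
  # missing assignments are an error
  expect_error(split_recall(sim$test$mentions, pred), "split")
})

test_that("overall recall is the split-size-weighted mean of split recalls", {
  sim <- sim_small(8)
  ga <- assign_split(sim$test$mentions, build_inventory(sim$train))
  pred <- mk_pred(ga, sample(nrow(ga), nrow(ga) %/% 3))
  overall <- entity_prf(ga, pred)$recall
  r <- split_recall(ga, pred)
  weighted <- sum(ifelse(r$n > 0, r$recall, 0) * r$n) / sum(r$n)
  expect_equal(overall, weighted)
})

test_that("relaxed recall uses containment per occurrence", {
  docs <- data.frame(doc_id = "d",
    title = "About severe COVID-19 pneumonia .",
    abstract = "We studied COVID-19 and COVID cases .")
  x <- corpus(docs, mentions(), entity_types = "Disease")
  # occurrences of COVID-19 at [13,21) and [45,53)
  pred_contains <- mentions("d", 6L, 31L, "severe COVID-19 pneumonia",
                            "Disease", list("UNKNOWN"))
  pred_exact <- mentions("d", 45L, 53L, "COVID-19", "Disease", list("UNKNOWN"))
  pred_short <- mentions("d", 45L, 50L, "COVID", "Disease", list("UNKNOWN"))
  expect_equal(relaxed_recall(x, pred_contains, "COVID-19")$recall, 0.5)
  expect_equal(relaxed_recall(x, pred_exact, "COVID-19")$recall, 0.5)
  expect_equal(relaxed_recall(x, rbind(pred_contains, pred_exact),
                              "COVID-19")$recall, 1.0)
  # a shorter span does not contain the occurrence
  expect_equal(relaxed_recall(x, pred_short, "COVID-19")$recall, 0)
  expect_error(relaxed_recall(x, pred_exact, "MERS"), "undefined")
  # relaxed >= exact-match recall on identical inputs
  exact_hits <- relaxed_recall(x, pred_exact, "COVID-19")
  expect_gte(relaxed_recall(x, rbind(pred_contains, pred_exact),
                            "COVID-19")$recall, exact_hits$recall)
})

test_that("abbreviation heuristic and Con-subset recall", {
  expect_true(all(is_abbreviation(c("ANT-MI", "COVID-19", "MI", "EA-2"))))
  expect_false(any(is_abbreviation(c("anterior infarction", "mi", "A",
                                     "Covid"))))
  sim <- generate_corpus(generator_config(seed = 12, n_train_docs = 40L,
    n_test_docs = 30L, n_concepts = 12L,
    props = c(mem = 0.4, syn = 0.2, con = 0.4, homonym = 0)))
  ga <- assign_split(sim$test$mentions, build_inventory(sim$train))
  led <- sim$ledger$mentions
  r <- abbreviation_recall(ga, mk_pred(ga, seq_len(nrow(ga))))
  expect_equal(r$n_abbrev, sum(led$is_abbreviation[led$split == "Con"]))
  if (r$n_abbrev > 0L) expect_equal(r$recall, 1.0)
  # zero flagged mentions -> undefined metric
  no_con <- ga[ga$split == "Mem", , drop = FALSE]
  r2 <- abbreviation_recall(no_con, mentions())
  expect_true(is.na(r2$recall))
})

test_that("metrics are invariant under document reordering", {
  sim <- sim_small(9)
  ga <- assign_split(sim$test$mentions, build_inventory(sim$train))
  pred <- mk_pred(ga, sample(nrow(ga), 8L))
  r1 <- entity_prf(ga, pred)
  perm <- sample(nrow(ga))
  r2 <- entity_prf(ga[perm, ], pred[sample(nrow(pred)), ])
  expect_equal(r1$f1, r2$f1)
  expect_equal(split_recall(ga, pred)$recall,
               split_recall(ga[perm, ], pred)$recall)
})
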