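test_that("generation is a pure function of the config", {
  a <- sim_small(21)
  b <- sim_small(21)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_pubtator(a$train, f1); write_pubtator(b$train, f2)
  expect_identical(readLines(f1), readLines(f2))
  write_pubtator(a$test, f1); write_pubtator(b$test, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(a$ledger$mentions, b$ledger$mentions)
})

test_that("split proportions are realized exactly", {
  cfg <- generator_config(seed = 31, n_train_docs = 60L, n_test_docs = 40L,
                          n_concepts = 16L,
                          props = c(mem = 0.6, syn = 0.25, con = 0.15,
                                    homonym = 0))
  sim <- generate_corpus(cfg)
  part <- partition_corpus(sim$test, build_inventory(sim$train))
  expect_identical(part$counts, sim$ledger$counts)
  expect_equal(part$counts[["Mem"]], 24L)
  expect_equal(part$counts[["Syn"]], 10L)
  expect_equal(part$counts[["Con"]], 6L)
  # mem = 1 -> everything memorizable
  sim2 <- generate_corpus(generator_config(seed = 32, n_train_docs = 40L,
    n_test_docs = 20L, n_concepts = 12L,
    props = c(mem = 1, syn = 0, con = 0, homonym = 0)))
  p2 <- partition_corpus(sim2$test, build_inventory(sim2$train))
  expect_equal(p2$counts[["Mem"]], 20L)
})

test_that("infeasible configurations are rejected", {
  expect_error(generator_config(props = c(mem = 0.5, syn = 0.5, con = 0.5,
                                          homonym = 0)), "sum to 1")
  expect_error(generate_corpus(generator_config(seed = 1,
    synonyms_per_concept = 0L,
    props = c(mem = 0.7, syn = 0.3, con = 0, homonym = 0))),
    "Syn")
  expect_error(generate_corpus(generator_config(seed = 1,
    n_train_docs = 10L)), "slots")
})

test_that("pseudo entities follow the ABBREV-NUMBER pattern", {
  set.seed(77)
  s <- make_pseudo_entity(10000L)
  expect_true(all(grepl("^[A-Z]{3,5}-[0-9]{1,3}$", s)))
  # letter-count uniform over {3,4,5}
  nl <- nchar(sub("-.*", "", s))
  expect_gt(stats::chisq.test(table(factor(nl, levels = 3:5)))$p.value, 1e-4)
  # digit-count uniform over {1,2,3}
  nd <- nchar(sub(".*-", "", s))
  expect_gt(stats::chisq.test(table(factor(nd, levels = 1:3)))$p.value, 1e-4)
})

test_that("replace_target rewrites all occurrences and preserves the rest", {
  sim <- generate_corpus(generator_config(seed = 41, n_train_docs = 40L,
    n_test_docs = 20L, n_concepts = 12L, n_target_docs = 10L))
  tc <- sim$target$corpus
  old <- sim$target$surface
  out <- replace_target(tc, old, "COVID")
  # every mention of the target shrank to the new surface
  sel <- sim$target$corpus$mentions$surface == old
  expect_true(all(out$mentions$surface[sel] == "COVID"))
  # slice invariant re-verified for every mention
  expect_silent(validate_corpus(out))
  # untouched characters identical: replacing back restores the corpus
  back <- replace_target(out, "COVID", old)
  expect_identical(doc_text(back), doc_text(tc))
  expect_equal(back$mentions$start, tc$mentions$start)
})

test_that("inject_pseudo_mentions alters exactly k abbreviation mentions", {
  sim <- generate_corpus(generator_config(seed = 51,
    pattern_mix = c(conventional = 0.5, abbrev = 0.5, abbrev_num = 0)))
  res <- inject_pseudo_mentions(sim$train, k = 10L, seed = 9L)
  expect_equal(nrow(res$injected), 10L)
  expect_true(all(grepl("^[A-Z]{3,5}-[0-9]{1,3}$", res$injected$new)))
  expect_silent(validate_corpus(res$corpus))
  # exactly 10 mention rows changed surface
  changed <- sum(res$corpus$mentions$surface != sim$train$mentions$surface)
  expect_equal(changed, 10L)
  # too few abbreviations -> error
  sim2 <- generate_corpus(generator_config(seed = 52, n_train_docs = 40L,
    n_test_docs = 20L, n_concepts = 10L,
    pattern_mix = c(conventional = 1, abbrev = 0, abbrev_num = 0)))
  expect_error(inject_pseudo_mentions(sim2$train, k = 10L), "abbreviation")
})

test_that("label-bias injection shifts word statistics between splits", {
  cfg <- generator_config(seed = 61, props = c(mem = 0.5, syn = 0.2,
                                               con = 0.3, homonym = 0),
                          bias_strength = 1)
  sim <- generate_corpus(cfg)
  bt <- compute_bias_table(corpus_to_conll(sim$train))
  led <- sim$ledger$mentions
  biased <- led[led$pattern == "biased", ]
  expect_gt(nrow(biased), 0L)
  heads <- unique(vapply(strsplit(biased$surface, " "), `[`, "", 2L))
  for (w in heads) {
    # one-hot towards B in training
    expect_gt(bias_rows(bt, w)[1, "B"], 0.99)
  }
  # in the test corpus the head word sits inside a longer mention (tag I)
  txt <- doc_text(sim$test)
  id <- biased$doc_id[1]
  tok <- tokenize(txt[[id]])
  tags <- mentions_to_bio(tok, sim$test$mentions[sim$test$mentions$doc_id == id, ])
  w <- strsplit(biased$surface[1], " ")[[1]][2]
  expect_equal(tags[match(w, tok$token)], "I")
  # post-hoc injection on an unbiased simulation does the same
  sim0 <- generate_corpus(generator_config(seed = 62,
    props = c(mem = 0.5, syn = 0.2, con = 0.3, homonym = 0)))
  sim1 <- inject_label_bias(sim0, strength = 1, seed = 3L)
  expect_silent(validate_corpus(sim1$test))
  part <- partition_corpus(sim1$test, build_inventory(sim1$train))
  expect_identical(as.character(part$assignments$split),
                   sim1$ledger$mentions$split)
  # strength 0 is the identity
  expect_identical(inject_label_bias(sim0, 0), sim0)
})

test_that("inconsistency injection leaves synonym surfaces unannotated", {
  sim <- generate_corpus(generator_config(seed = 71,
                                          inconsistency_rate = 0.3))
  expect_equal(sim$ledger$n_inconsistent, 36L)
  ds <- build_dict_syn(sim$train, sim$synonym_map)
  dt <- build_dict_train(sim$train)
  ps <- entity_prf(sim$test$mentions, dict_tag(sim$test, ds))
  pt <- entity_prf(sim$test$mentions, dict_tag(sim$test, dt))
  expect_lt(ps$precision, pt$precision)
})
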