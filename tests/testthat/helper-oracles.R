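# Independent brute-force oracles and tiny fixtures.  The oracles use
# nested loops and explicit enumeration, never the package's set-based or
# greedy code paths.

sim_small <- function(seed, ...) {
  generate_corpus(generator_config(seed = seed, n_train_docs = 40L,
                                   n_test_docs = 20L, n_concepts = 12L, ...))
}

# nested-loop membership tests, no set machinery
brute_partition <- function(test_mentions, train_corpus, policy = norm_policy()) {
  tm <- train_corpus$mentions
  out <- character(nrow(test_mentions))
  for (i in seq_len(nrow(test_mentions))) {
    surf <- normalize_surface(test_mentions$surface[i], policy)
    surface_seen <- FALSE
    for (j in seq_len(nrow(tm))) {
      if (normalize_surface(tm$surface[j], policy) == surf) surface_seen <- TRUE
    }
    concept_seen <- FALSE
    for (cid in test_mentions$concept_ids[[i]]) {
      if (cid == "UNKNOWN") next
      for (j in seq_len(nrow(tm))) {
        for (tc in tm$concept_ids[[j]]) {
          if (tc != "UNKNOWN" && tc == cid) concept_seen <- TRUE
        }
      }
    }
    out[i] <- if (surface_seen && concept_seen) "Mem"
      else if (!surface_seen && concept_seen) "Syn"
      else if (!surface_seen && !concept_seen) "Con"
      else "Homonym"
  }
  out
}

# all token spans, then iterative longest/leftmost selection
brute_dict_tag <- function(text, entries, policy = norm_policy()) {
  tok <- tokenize(text)
  norm_entries <- unique(normalize_surface(entries, policy))
  cand <- NULL
  n <- nrow(tok)
  for (i in seq_len(n)) {
    for (j in i:n) {
      s <- tok$start[i]; e <- tok$end[j]
      piece <- normalize_surface(substring(text, s + 1L, e), policy)
      if (piece %in% norm_entries) {
        cand <- rbind(cand, data.frame(start = s, end = e))
      }
    }
  }
  acc <- NULL
  while (!is.null(cand) && nrow(cand) > 0L) {
    len <- cand$end - cand$start
    best <- which(len == max(len))
    best <- best[which.min(cand$start[best])]
    acc <- rbind(acc, cand[best, ])
    keep <- cand$end <= acc$start[nrow(acc)] | cand$start >= acc$end[nrow(acc)]
    cand <- cand[keep, , drop = FALSE]
  }
  if (is.null(acc)) return(data.frame(start = integer(0), end = integer(0)))
  acc[order(acc$start), , drop = FALSE]
}

# per-word tag counting with explicit loops
brute_bias_row <- function(conll, word, classes, case_fold = TRUE) {
  counts <- setNames(numeric(length(classes)), classes)
  for (d in conll) {
    for (i in seq_len(nrow(d))) {
      w <- if (case_fold) tolower(d$token[i]) else d$token[i]
      if (w == word) counts[d$tag[i]] <- counts[d$tag[i]] + 1
    }
  }
  counts / sum(counts)
}

# a 3-document PubTator fixture as text lines
tiny_pubtator_lines <- function() {
  c("101|t|Colorectal cancer studies .",
    "101|a|Patients with colorectal cancer were enrolled .",
    paste("101", 42, 59, "colorectal cancer", "Disease", "MESH:D015179",
          sep = "\t"),
    "",
    "102|t|A report on MI .",
    "102|a|We observed MI and anemia in the cohort .",
    paste("102", 29, 31, "MI", "Disease", "MESH:D009203", sep = "\t"),
    paste("102", 36, 42, "anemia", "Disease", "MESH:D000740|OMIM:104225",
          sep = "\t"),
    "",
    "103|t|Negative control .",
    "103|a|No findings were reported .",
    "")
}

random_sentence_corpus <- function(seed, n_docs = 10L) {
  sim <- sim_small(seed)
  sim$test
}
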