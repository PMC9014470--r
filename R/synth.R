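# Synthetic BioNER corpus generator.  Emits paired train/test corpora, a
# concept-synonym map and a ground-truth ledger, with controllable:
#   * test split proportions (Mem / Syn / Con / Homonym), realized exactly;
#   * name-pattern mix: conventional two-word names ("<stem> disease",
#     "<stem> syndrome"), plain abbreviations (capital letters) and
#     identifier-like "ABBREV-NUMBER" names;
#   * annotation inconsistency (dictionary surfaces occurring unannotated);
#   * per-word label skew ("biased" head words that are single-class in
#     training but shift class in the test set).
# Concept IDs are synthetic ("SYN:000123"); synonymy is generated (shared
# concept, distinct surfaces), so the dictionary-expansion baseline is
# testable offline.  Generation is a pure function of the config: the same
# seed yields byte-identical output.

MODIFIERS <- c("acute", "chronic", "severe", "refractory")

#' Generator configuration
#'
#' Defaults describe a small benchmark-like world: test mentions dominated
#' by memorizable surfaces (as real BioNER benchmarks are), a majority of
#' conventionally named concepts, a minority of abbreviations.
#'
#' @param seed integer RNG seed; generation is a pure function of the
#'   config.
#' @param n_train_docs,n_test_docs document counts (train docs carry two
#'   entity mentions, test docs one).
#' @param entity_type single entity type label.
#' @param props named numeric: target test proportions for `mem`, `syn`,
#'   `con`, `homonym`; must sum to 1.
#' @param n_concepts number of regular concepts (pattern scaffolding
#'   concepts for the bias machinery are added on top).
#' @param synonyms_per_concept held-out synonyms per regular concept
#'   (the pool the Syn split and the synonym map draw from).
#' @param pattern_mix named numeric over `conventional`, `abbrev`,
#'   `abbrev_num`; must sum to 1.
#' @param inconsistency_rate fraction of test documents receiving an
#'   unannotated occurrence of a synonym-map surface (label inconsistency
#'   between corpus and database).
#' @param bias_strength fraction of Con test mentions rewritten to
#'   `"<modifier> <biased-head>"`, where the biased head is a training word
#'   with a one-hot class distribution (always `B` in training, shifted to
#'   `I` in the test usage).
#' @param n_target_docs if positive, an extra single-entity evaluation set
#'   (one novel `ABBREV-NUMBER` concept, as the COVID-19-style probe) with
#'   this many documents is generated.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_train_docs = 160L,
                             n_test_docs = 120L, entity_type = "Disease",
                             props = c(mem = 0.6, syn = 0.25, con = 0.15,
                                       homonym = 0),
                             n_concepts = 40L, synonyms_per_concept = 3L,
                             pattern_mix = c(conventional = 0.5,
                                             abbrev = 0.3, abbrev_num = 0.2),
                             inconsistency_rate = 0,
                             bias_strength = 0,
                             n_target_docs = 0L) {
  props <- props[c("mem", "syn", "con", "homonym")]
  pattern_mix <- pattern_mix[c("conventional", "abbrev", "abbrev_num")]
  if (anyNA(props) || abs(sum(props) - 1) > 1e-8) {
    stop("props must name mem/syn/con/homonym and sum to 1")
  }
  if (anyNA(pattern_mix) || abs(sum(pattern_mix) - 1) > 1e-8) {
    stop("pattern_mix must name conventional/abbrev/abbrev_num and sum to 1")
  }
  rates <- c(props, pattern_mix, inconsistency_rate, bias_strength)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  structure(list(seed = as.integer(seed), n_train_docs = as.integer(n_train_docs),
                 n_test_docs = as.integer(n_test_docs),
                 entity_type = entity_type, props = props,
                 n_concepts = as.integer(n_concepts),
                 synonyms_per_concept = as.integer(synonyms_per_concept),
                 pattern_mix = pattern_mix,
                 inconsistency_rate = inconsistency_rate,
                 bias_strength = bias_strength,
                 n_target_docs = as.integer(n_target_docs)),
            class = "generator_config")
}

#' Generate an identifier-like pseudo entity surface
#'
#' 3-5 random capital letters, a hyphen, then 1-3 digits (no leading zero):
#' surfaces like `IST-5`, `CHF-113`, `SRS-3517`-style identifiers.  Letter
#' and digit counts are drawn uniformly.  Uses the current RNG state.
#'
#' @param n how many surfaces to draw.
#' @return character vector matching `^[A-Z]{3,5}-[0-9]{1,3}$`.
#' @export
make_pseudo_entity <- function(n = 1L) {
  vapply(seq_len(n), function(i) {
    nl <- sample(3:5, 1L)
    nd <- sample(1:3, 1L)
    digits <- c(sample(1:9, 1L),
                if (nd > 1L) sample(0:9, nd - 1L, replace = TRUE))
    paste0(paste(sample(LETTERS, nl, replace = TRUE), collapse = ""),
           "-", paste(digits, collapse = ""))
  }, "")
}

# -- word factories -----------------------------------------------------

CONSONANTS <- c("b","c","d","f","g","l","m","n","p","r","s","t","v","z")
VOWELS <- c("a","e","i","o","u")

make_word <- function(n_syll = sample(2:3, 1L)) {
  paste0(paste0(sample(CONSONANTS, n_syll, replace = TRUE),
                sample(VOWELS, n_syll, replace = TRUE), collapse = ""),
         sample(c("", "n", "s", "x"), 1L))
}

make_abbrev <- function() {
  paste(sample(LETTERS, sample(2:5, 1L), replace = TRUE), collapse = "")
}

# head words carry disease-like morphology ("-itis", "-emia", "-oma") so
# their suffix features are distinctive entity cues, distinct from filler
# vocabulary
make_head_word <- function() {
  paste0(paste0(sample(CONSONANTS, 2L, replace = TRUE),
                sample(VOWELS, 2L, replace = TRUE), collapse = ""),
         sample(c("itis", "emia", "oma"), 1L))
}

# Draw from `factory` until the (case-folded) result is new, then register
# it.  `pool` is an environment carrying the used-string set.
draw_unique <- function(pool, factory) {
  for (i in 1:1000) {
    w <- factory()
    key <- tolower(w)
    if (!key %in% pool$used) {
      pool$used <- c(pool$used, key)
      return(w)
    }
  }
  stop("could not draw a unique string after 1000 attempts")
}

# -- sentence assembly --------------------------------------------------

# A sentence is built from word vectors `pre`, entity surface, `post`; the
# mention offset is recovered from the joined string.  All sentences are
# single-space joined and end with a detached period, so whitespace
# tokenization is exact.
sent_with_entity <- function(pre, ent, post) {
  text <- paste(c(pre, ent, post), collapse = " ")
  start <- sum(nchar(pre)) + length(pre)
  list(text = text, start = start, end = start + nchar(ent))
}

# "cued" sentences place the entity after strong lexical triggers
# ("patients with", "diagnosis of"); "flat" sentences give it an
# uninformative context, so word identity is the only reliable training
# signal there -- the situation in which models fall back on per-word label
# statistics.
entity_sentence <- function(ent, fill, style = "cued") {
  f1 <- sample(fill, 1L); f2 <- sample(fill, 1L)
  if (style == "flat") {
    return(switch(sample.int(3L, 1L),
      sent_with_entity(c("The"), ent, c("episodes", "were", "frequent", ".")),
      sent_with_entity(c("The"), ent,
                       c("burden", "increased", "in", f1, "settings", ".")),
      sent_with_entity(c("Reported"), ent,
                       c("rates", "varied", "across", f1, "registries", "."))))
  }
  switch(sample.int(4L, 1L),
    sent_with_entity(c("Patients", "with"), ent,
                     c("were", "treated", "with", f1, "therapy", ".")),
    sent_with_entity(c("We", "report", "a", "case", "of"), ent,
                     c("in", "a", f1, "cohort", ".")),
    sent_with_entity(c("The", "diagnosis", "of"), ent,
                     c("was", "confirmed", "by", f1, "testing", ".")),
    sent_with_entity(c("Early", "detection", "of"), ent,
                     c("improved", f1, "and", f2, "outcomes", ".")))
}

# registry-code sentences teach the tagger that identifier-like
# ABBREV-NUMBER tokens are ordinarily non-entities (as chemical identifiers
# and trial codes are for a disease tagger); they appear in ~40% of context
# sentences so the cue carries real weight
context_sentence <- function(fill, codes) {
  f1 <- sample(fill, 1L); f2 <- sample(fill, 1L)
  mod <- sample(MODIFIERS, 1L)
  if (stats::runif(1L) < 0.4) {
    return(switch(sample.int(2L, 1L),
      paste("The trial was registered under", sample(codes, 1L), "."),
      paste("Samples were archived under", sample(codes, 1L),
            "for", f1, "review .")))
  }
  switch(sample.int(3L, 1L),
    paste("The", mod, f1, "group received", f2, "support ."),
    paste("Baseline", f1, "values were stable across", f2, "sites ."),
    paste("Treatment with", sample(c(5L, 10L, 20L, 50L), 1L),
          "mg of", f1, "was continued ."))
}

target_sentence <- function(ent, fill) {
  f1 <- sample(fill, 1L)
  switch(sample.int(3L, 1L),
    sent_with_entity(c("The"), ent,
                     c("pandemic", "remains", "an", "ongoing", "global",
                       "emergency", ".")),
    sent_with_entity(c("Treatment", "of"), ent,
                     c("patients", "with", f1, "support", "improved",
                       "outcomes", ".")),
    sent_with_entity(c("Patients", "with"), ent,
                     c("presented", f1, "symptoms", ".")))
}

# Assemble a document from a title and a list of sentence objects (plain
# strings or sent_with_entity() results).  Returns docs row + mention rows.
assemble_doc <- function(doc_id, title, sents, entity_type) {
  texts <- vapply(sents, function(s) if (is.list(s)) s$text else s, "")
  abstract <- paste(texts, collapse = " ")
  offsets <- c(0L, cumsum(nchar(texts) + 1L))  # sentence starts in abstract
  base <- nchar(title) + 1L                    # abstract start in full text
  ms <- list()
  for (i in seq_along(sents)) {
    s <- sents[[i]]
    if (is.list(s)) {
      ms[[length(ms) + 1L]] <- data.frame(
        doc_id = doc_id,
        start = base + offsets[i] + s$start,
        end = base + offsets[i] + s$end,
        stringsAsFactors = FALSE)
    }
  }
  list(doc = data.frame(doc_id = doc_id, title = title, abstract = abstract,
                        stringsAsFactors = FALSE),
       mention_spans = if (length(ms)) do.call(rbind, ms) else NULL)
}

largest_remainder <- function(props, n) {
  raw <- props * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  as.integer(counts)
}

# -- main generator -----------------------------------------------------

#' Generate a synthetic benchmark
#'
#' Produces a paired train/test corpus, a concept-synonym map, and a ledger
#' recording each test mention's intended split, pattern class and
#' abbreviation flag -- the ground truth the partitioner and the metrics
#' are tested against.  See [generator_config()] for the dials.
#'
#' @param config a [generator_config()].
#' @return object of class `ner_sim`: list with `train`, `test`
#'   (`ner_corpus`), `synonym_map`, `ledger` (list: `mentions` data.frame,
#'   `bias_words`, `counts`), `config`, and -- when `n_target_docs > 0` --
#'   `target` (list: `corpus`, `surface`, `concept_id`).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(config$seed)

  # every word that can occur in a template must be registered, so no
  # generated entity surface collides with ambient text (which would create
  # unintended annotation inconsistency)
  pool <- new.env(parent = emptyenv())
  pool$used <- c(MODIFIERS, "disease", "syndrome",
                 "patients", "with", "were", "treated", "therapy", "we",
                 "report", "a", "case", "of", "in", "cohort", "the",
                 "diagnosis", "was", "confirmed", "by", "testing", "early",
                 "detection", "improved", "and", "outcomes", "episodes",
                 "frequent", "burden", "increased", "settings", "reported",
                 "rates", "varied", "across", "registries", "group",
                 "received", "support", "baseline", "values", "stable",
                 "sites", "treatment", "mg", "continued", "trial",
                 "registered", "under", "pandemic", "remains", "an",
                 "ongoing", "global", "emergency", "presented", "symptoms",
                 "clinical", "study", "observational", "on", "management",
                 "reports", "response", "earlier", "inconclusive",
                 "samples", "archived", "for", "review")

  fillers <- vapply(1:30, function(i) draw_unique(pool, make_word), "")
  trial_codes <- vapply(1:8, function(i)
    draw_unique(pool, function() make_pseudo_entity(1L)), "")

  # ---- concept inventory ----
  ent <- config$entity_type
  n_pat <- largest_remainder(config$pattern_mix, config$n_concepts)
  concept_rows <- list()
  next_id <- 0L
  new_concept <- function() {
    next_id <<- next_id + 1L
    sprintf("SYN:%06d", next_id)
  }
  make_surface <- function(pattern) {
    switch(pattern,
      conventional = paste(draw_unique(pool, make_word),
                           sample(c("disease", "syndrome"), 1L)),
      abbrev = draw_unique(pool, make_abbrev),
      abbrev_num = draw_unique(pool, function() make_pseudo_entity(1L)))
  }
  for (pat in names(config$pattern_mix)) {
    for (i in seq_len(n_pat[[match(pat, names(config$pattern_mix))]])) {
      surfaces <- vapply(seq_len(1L + config$synonyms_per_concept),
                         function(j) make_surface(pat), "")
      concept_rows[[length(concept_rows) + 1L]] <- list(
        id = new_concept(), pattern = pat,
        train_surfaces = surfaces[1L], heldout = surfaces[-1L])
    }
  }
  # pattern scaffolding for the per-word bias machinery: "plain" concepts
  # whose single lowercase surface word is always tagged B in training, and
  # "mixed" concepts contributing both B and I occurrences of their head
  # word (so word statistics are skewed for the former, mixed for the
  # latter)
  n_plain <- 6L; n_mixed <- 8L
  bias_heads <- character(0)
  for (i in seq_len(n_plain)) {
    w <- draw_unique(pool, make_head_word)
    bias_heads <- c(bias_heads, w)
    concept_rows[[length(concept_rows) + 1L]] <- list(
      id = new_concept(), pattern = "plain",
      train_surfaces = w, heldout = character(0))
  }
  for (i in seq_len(n_mixed)) {
    w <- draw_unique(pool, make_head_word)
    mod <- MODIFIERS[1L + (i - 1L) %% length(MODIFIERS)]  # cover all modifiers
    concept_rows[[length(concept_rows) + 1L]] <- list(
      id = new_concept(), pattern = "mixed",
      train_surfaces = c(w, paste(mod, w)), heldout = character(0))
  }

  regular <- which(vapply(concept_rows, function(x)
    x$pattern %in% names(config$pattern_mix), NA))
  n_reserved <- max(1L, floor(0.3 * length(regular)))
  reserved <- sample(regular, n_reserved)      # Con-only concepts
  trainable <- setdiff(seq_along(concept_rows), reserved)

  # ---- split allocation ----
  counts <- largest_remainder(config$props, config$n_test_docs)
  names(counts) <- c("Mem", "Syn", "Con", "Homonym")
  syn_pool <- Filter(function(i) length(concept_rows[[i]]$heldout) > 0L,
                     trainable)
  if (counts[["Syn"]] > 0L && length(syn_pool) == 0L) {
    stop("infeasible proportions: Syn requested but no held-out synonyms")
  }
  if (counts[["Con"]] > 0L && length(reserved) == 0L) {
    stop("infeasible proportions: Con requested but no reserved concepts")
  }

  # ---- training corpus ----
  train_pairs <- do.call(rbind, lapply(trainable, function(i) {
    data.frame(idx = i, surface = concept_rows[[i]]$train_surfaces,
               stringsAsFactors = FALSE)
  }))
  # plain (biased-head) concepts recur heavily when label bias is being
  # injected, so their word statistics are sharply one-hot and carry real
  # training weight; mixed concepts recur enough for stable mixed rows
  pat_of <- vapply(concept_rows, function(x) x$pattern, "")
  heavy <- config$bias_strength > 0
  reps <- ifelse(pat_of[train_pairs$idx] == "plain",
                 if (heavy) 24L else 3L,
                 ifelse(pat_of[train_pairs$idx] == "mixed",
                        if (heavy) 6L else 2L, 1L))
  mandatory <- train_pairs[rep(seq_len(nrow(train_pairs)), reps), ]
  n_slots <- 2L * config$n_train_docs
  if (nrow(mandatory) > n_slots) {
    stop("infeasible config: ", nrow(mandatory),
         " mandatory training mentions exceed ", n_slots, " slots; ",
         "increase n_train_docs")
  }
  extra <- train_pairs[sample.int(nrow(train_pairs),
                                  n_slots - nrow(mandatory), replace = TRUE), ]
  slots <- rbind(mandatory, extra)
  slots <- slots[sample.int(nrow(slots)), ]

  train_docs <- list(); train_mrows <- list(); train_surf <- character(0)
  train_cid <- character(0)
  slot_style <- function(s) {
    p_flat <- if (pat_of[s$idx] == "plain") 0.85 else 0.15
    if (stats::runif(1L) < p_flat) "flat" else "cued"
  }
  for (d in seq_len(config$n_train_docs)) {
    id <- sprintf("TR%04d", d)
    s1 <- slots[2L * d - 1L, ]; s2 <- slots[2L * d, ]
    sents <- list(entity_sentence(s1$surface, fillers, slot_style(s1)),
                  context_sentence(fillers, trial_codes),
                  entity_sentence(s2$surface, fillers, slot_style(s2)))
    title <- paste("Clinical study of", sample(fillers, 1L), "outcomes .")
    a <- assemble_doc(id, title, sents, ent)
    train_docs[[d]] <- a$doc
    train_mrows[[d]] <- a$mention_spans
    train_surf <- c(train_surf, s1$surface, s2$surface)
    train_cid <- c(train_cid,
                   concept_rows[[s1$idx]]$id, concept_rows[[s2$idx]]$id)
  }
  tm <- do.call(rbind, train_mrows)
  train_corpus <- corpus(do.call(rbind, train_docs),
                         mentions(tm$doc_id, tm$start, tm$end, train_surf,
                                  ent, as.list(train_cid)),
                         entity_types = ent, split_role = "train")

  # ---- test corpus ----
  train_surface_set <- tolower(unique(train_surf))
  plan <- list()
  add_plan <- function(surface, cid, split, pattern) {
    plan[[length(plan) + 1L]] <<- data.frame(
      surface = surface, concept_id = cid, split = split, pattern = pattern,
      stringsAsFactors = FALSE)
  }
  pair_idx <- sample.int(nrow(train_pairs), counts[["Mem"]], replace = TRUE)
  for (k in pair_idx) {
    add_plan(train_pairs$surface[k], concept_rows[[train_pairs$idx[k]]]$id,
             "Mem", concept_rows[[train_pairs$idx[k]]]$pattern)
  }
  for (k in seq_len(counts[["Syn"]])) {
    i <- if (length(syn_pool) == 1L) syn_pool else sample(syn_pool, 1L)
    add_plan(sample(concept_rows[[i]]$heldout, 1L), concept_rows[[i]]$id,
             "Syn", concept_rows[[i]]$pattern)
  }
  n_bias_con <- round(config$bias_strength * counts[["Con"]])
  for (k in seq_len(counts[["Con"]])) {
    if (k <= n_bias_con) {
      surf <- paste(sample(MODIFIERS, 1L), sample(bias_heads, 1L))
      add_plan(surf, new_concept(), "Con", "biased")
    } else {
      i <- if (length(reserved) == 1L) reserved else sample(reserved, 1L)
      add_plan(concept_rows[[i]]$train_surfaces[1L], concept_rows[[i]]$id,
               "Con", concept_rows[[i]]$pattern)
    }
  }
  for (k in seq_len(counts[["Homonym"]])) {
    add_plan(train_pairs$surface[sample.int(nrow(train_pairs), 1L)],
             new_concept(), "Homonym", "homonym")
  }
  plan <- do.call(rbind, plan)
  plan <- plan[sample.int(nrow(plan)), ]

  # held-out synonym strings of trainable concepts: the synonym-map-only
  # surfaces used for the annotation-inconsistency injection
  syn_only <- unlist(lapply(syn_pool, function(i) concept_rows[[i]]$heldout))
  n_inconsistent <- round(config$inconsistency_rate * config$n_test_docs)
  inconsistent_docs <- if (n_inconsistent > 0L) {
    sample.int(config$n_test_docs, n_inconsistent)
  } else integer(0)
  if (n_inconsistent > 0L && length(syn_only) == 0L) {
    stop("infeasible config: inconsistency requested but no synonym surfaces")
  }

  test_docs <- list(); test_mrows <- list()
  for (d in seq_len(config$n_test_docs)) {
    id <- sprintf("TE%04d", d)
    sents <- list(entity_sentence(plan$surface[d], fillers),
                  context_sentence(fillers, trial_codes))
    if (d %in% inconsistent_docs) {
      sents[[length(sents) + 1L]] <- paste(
        "Earlier reports of", sample(syn_only, 1L), "were inconclusive .")
    }
    title <- paste("Observational report on", sample(fillers, 1L),
                   "management .")
    a <- assemble_doc(id, title, sents, ent)
    test_docs[[d]] <- a$doc
    test_mrows[[d]] <- a$mention_spans
  }
  tm2 <- do.call(rbind, test_mrows)
  test_corpus <- corpus(do.call(rbind, test_docs),
                        mentions(tm2$doc_id, tm2$start, tm2$end, plan$surface,
                                 ent, as.list(plan$concept_id)),
                        entity_types = ent, split_role = "test")

  # ---- synonym map (all surfaces of all concepts) ----
  synonym_map <- do.call(rbind, lapply(concept_rows, function(cr) {
    data.frame(concept_id = cr$id,
               synonym = c(cr$train_surfaces, cr$heldout),
               stringsAsFactors = FALSE)
  }))

  ledger_mentions <- data.frame(
    doc_id = tm2$doc_id, start = tm2$start, end = tm2$end,
    surface = plan$surface, concept_id = plan$concept_id,
    split = plan$split, pattern = plan$pattern,
    is_abbreviation = is_abbreviation(plan$surface),
    stringsAsFactors = FALSE)
  ledger <- list(mentions = ledger_mentions,
                 bias_words = if (n_bias_con > 0L) bias_heads else character(0),
                 bias_head_pool = bias_heads,
                 counts = setNames(as.integer(counts), names(counts)),
                 n_inconsistent = n_inconsistent)

  sim <- list(train = train_corpus, test = test_corpus,
              synonym_map = synonym_map, ledger = ledger, config = config)

  # ---- optional single-entity probe set (novel identifier-like name) ----
  if (config$n_target_docs > 0L) {
    surf <- draw_unique(pool, function() make_pseudo_entity(1L))
    cid <- new_concept()
    tdocs <- list(); tmr <- list()
    for (d in seq_len(config$n_target_docs)) {
      id <- sprintf("TG%04d", d)
      sents <- list(target_sentence(surf, fillers),
                    context_sentence(fillers, trial_codes))
      a <- assemble_doc(id, paste("Reports on the", sample(fillers, 1L),
                                  "response ."), sents, ent)
      tdocs[[d]] <- a$doc
      tmr[[d]] <- a$mention_spans
    }
    tm3 <- do.call(rbind, tmr)
    sim$target <- list(
      corpus = corpus(do.call(rbind, tdocs),
                      mentions(tm3$doc_id, tm3$start, tm3$end,
                               rep(surf, nrow(tm3)), ent,
                               as.list(rep(cid, nrow(tm3)))),
                      entity_types = ent, split_role = "test"),
      surface = surf, concept_id = cid)
  }
  class(sim) <- "ner_sim"
  sim
}

#' @export
print.ner_sim <- function(x, ...) {
  cat(sprintf("<ner_sim: %d train docs, %d test docs, %d concepts; splits %s>\n",
              nrow(x$train$docs), nrow(x$test$docs),
              length(unique(x$synonym_map$concept_id)),
              paste(names(x$ledger$counts), x$ledger$counts, collapse = " ",
                    sep = "=")))
  invisible(x)
}
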