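# Longest-match dictionary baselines.  DICT_train uses the training mention
# surfaces as its dictionary; DICT_syn additionally includes database
# synonyms of every concept observed in training.  Matching is over
# token-boundary-aligned spans after the shared surface normalization, so
# "MI" never matches inside "MIld".  Overlapping candidates are resolved
# longest-first (characters), leftmost on ties.

#' Build an entity dictionary
#' @param entries character vector of surface strings (normalized on
#'   construction).
#' @param entity_type type stamped on matches.
#' @param provenance `"train_mentions"` or `"train_plus_synonyms"`.
#' @param policy shared [norm_policy()] used for entries and queries.
#' @return object of class `entity_dictionary`.
#' @export
entity_dictionary <- function(entries, entity_type = "Entity",
                              provenance = "train_mentions",
                              policy = norm_policy()) {
  entries <- unique(normalize_surface(entries, policy))
  entries <- entries[nzchar(entries)]
  structure(list(entries = sort(entries), entity_type = entity_type,
                 provenance = provenance, policy = policy),
            class = "entity_dictionary")
}

#' @export
print.entity_dictionary <- function(x, ...) {
  cat(sprintf("<entity_dictionary: %d entries, type=%s, provenance=%s>\n",
              length(x$entries), x$entity_type, x$provenance))
  invisible(x)
}

#' DICT_train: dictionary of training mention surfaces
#'
#' @param train_corpus training `ner_corpus`.
#' @param entity_type type to extract (defaults to the corpus' first type).
#' @param policy shared [norm_policy()].
#' @return an `entity_dictionary` whose entry set equals the partitioner's
#'   surface inventory.
#' @export
build_dict_train <- function(train_corpus,
                             entity_type = train_corpus$entity_types[1L],
                             policy = norm_policy()) {
  m <- train_corpus$mentions
  m <- m[m$entity_type == entity_type, , drop = FALSE]
  if (nrow(m) == 0L) stop("empty training corpus: no mentions of type ",
                          entity_type)
  entity_dictionary(m$surface, entity_type, "train_mentions", policy)
}

#' DICT_syn: training surfaces plus database synonyms
#'
#' Expands DICT_train with every synonym (from a concept-synonym map) of
#' every concept ID observed in the training mentions.  Concepts missing
#' from the map produce a warning, not an error.
#'
#' @param train_corpus training `ner_corpus`.
#' @param synonym_map data.frame with columns `concept_id`, `synonym`.
#' @param entity_type,policy as in [build_dict_train()].
#' @return an `entity_dictionary` with provenance `"train_plus_synonyms"`.
#' @export
build_dict_syn <- function(train_corpus, synonym_map,
                           entity_type = train_corpus$entity_types[1L],
                           policy = norm_policy()) {
  base <- build_dict_train(train_corpus, entity_type, policy)
  m <- train_corpus$mentions
  m <- m[m$entity_type == entity_type, , drop = FALSE]
  train_concepts <- setdiff(unique(unlist(m$concept_ids)), "UNKNOWN")
  missing <- setdiff(train_concepts, unique(synonym_map$concept_id))
  if (length(missing) > 0L) {
    warning(length(missing), " training concept(s) missing from synonym map")
  }
  syns <- synonym_map$synonym[synonym_map$concept_id %in% train_concepts]
  entity_dictionary(c(base$entries, syns), entity_type,
                    "train_plus_synonyms", policy)
}

# All token-aligned candidate spans of a document whose normalized text is a
# dictionary entry.  max_tokens bounds the span length to the longest entry.
dict_candidates <- function(text, tokens, dict) {
  n <- nrow(tokens)
  if (n == 0L || length(dict$entries) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  max_tokens <- max(lengths(strsplit(dict$entries, "\\s+"))) + 1L
  starts <- integer(0); ends <- integer(0)
  for (i in seq_len(n)) {
    for (j in i:min(n, i + max_tokens - 1L)) {
      s <- tokens$start[i]; e <- tokens$end[j]
      if (normalize_surface(substr0(text, s, e), dict$policy)
          %in% dict$entries) {
        starts <- c(starts, s); ends <- c(ends, e)
      }
    }
  }
  data.frame(start = starts, end = ends)
}

#' Tag a corpus with a dictionary (longest match wins)
#'
#' Finds every token-boundary-aligned span whose normalized text is a
#' dictionary entry, then resolves overlaps greedily: candidates are sorted
#' by character length (descending) then start offset (ascending), and a
#' candidate is accepted iff disjoint from all previously accepted spans.
#' This implements the longest-one-is-selected rule with a deterministic
#' leftmost tie-break; the output spans never overlap.
#'
#' @param x an `ner_corpus`.
#' @param dict an `entity_dictionary`.
#' @return a [mentions()] table of predictions (concept IDs `"UNKNOWN"`).
#' @export
dict_tag <- function(x, dict) {
  txt <- doc_text(x)
  out <- lapply(x$docs$doc_id, function(id) {
    text <- txt[[id]]
    cand <- dict_candidates(text, tokenize(text), dict)
    if (nrow(cand) == 0L) return(NULL)
    cand <- cand[order(-(cand$end - cand$start), cand$start), , drop = FALSE]
    acc_s <- integer(0); acc_e <- integer(0)
    for (k in seq_len(nrow(cand))) {
      s <- cand$start[k]; e <- cand$end[k]
      if (all(e <= acc_s | s >= acc_e)) {
        acc_s <- c(acc_s, s); acc_e <- c(acc_e, e)
      }
    }
    ord <- order(acc_s)
    data.frame(doc_id = id, start = acc_s[ord], end = acc_e[ord],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(mentions())
  mentions(out$doc_id, out$start, out$end,
           surface = substr0(txt[out$doc_id], out$start, out$end),
           entity_type = dict$entity_type,
           concept_ids = rep(list("UNKNOWN"), nrow(out)))
}
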