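# Corpus perturbations: surgical text edits that preserve every untouched
# annotation and re-verify the slice invariant afterwards.  Used to probe
# name-regularity effects (renaming an entity, injecting identifier-like
# pseudo entities) and to shift per-word label statistics between train and
# test.

# Apply non-overlapping span edits to a corpus.  `edits`: data.frame with
# doc_id, start, end (existing 0-based half-open spans) and `new` (the
# replacement string).  Mentions exactly covering an edited span are
# rewritten; all other mentions are shifted; a mention partially
# overlapping an edit is an error.
splice_spans <- function(x, edits) {
  if (nrow(edits) == 0L) return(x)
  docs <- x$docs
  m <- x$mentions
  for (id in unique(edits$doc_id)) {
    e <- edits[edits$doc_id == id, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)])) {
      stop("overlapping edits in document ", id)
    }
    di <- match(id, docs$doc_id)
    if (is.na(di)) stop("edit references unknown document ", id)
    title_len <- nchar(docs$title[di])
    full <- doc_text(x)[[id]]
    delta <- nchar(e$new) - (e$end - e$start)
    # rebuild the full text
    pieces <- character(0); cursor <- 0L
    for (k in seq_len(nrow(e))) {
      pieces <- c(pieces, substr0(full, cursor, e$start[k]), e$new[k])
      cursor <- e$end[k]
    }
    new_full <- paste0(paste(pieces, collapse = ""),
                       substr0(full, cursor, nchar(full)))
    # edits must not straddle the title/abstract boundary
    if (any(e$start < title_len & e$end > title_len)) {
      stop("edit straddles the title/abstract boundary in ", id)
    }
    shift_at <- function(pos) {  # cumulative shift for an original offset
      vapply(pos, function(p) sum(delta[e$end <= p]), 0) |> as.integer()
    }
    t_edit <- e$end <= title_len
    docs$title[di] <- substr0(new_full, 0L,
                              title_len + sum(delta[t_edit]))
    docs$abstract[di] <- if (nzchar(docs$abstract[di])) {
      substr0(new_full, title_len + sum(delta[t_edit]) + 1L, nchar(new_full))
    } else ""
    mi <- which(m$doc_id == id)
    for (j in mi) {
      hit <- which(e$start == m$start[j] & e$end == m$end[j])
      partial <- e$start < m$end[j] & e$end > m$start[j]
      if (length(hit) == 1L) {
        m$start[j] <- m$start[j] + shift_at(m$start[j])
        m$end[j] <- m$start[j] + nchar(e$new[hit])
        m$surface[j] <- e$new[hit]
      } else if (any(partial)) {
        stop("edit partially overlaps mention at [", m$start[j], ",",
             m$end[j], ") in ", id)
      } else {
        sh <- shift_at(m$start[j])
        m$start[j] <- m$start[j] + sh
        m$end[j] <- m$end[j] + sh
      }
    }
  }
  out <- x
  out$docs <- docs
  out$mentions <- m
  validate_corpus(out)
  out
}

#' Replace every occurrence of a target string
#'
#' Rewrites all occurrences of `target` in the document texts (annotated or
#' not) with `replacement`, updating mention offsets and surfaces; all
#' other characters and annotations are unchanged and the slice invariant
#' is re-verified.  The canonical use is renaming an identifier-like entity
#' to a more conventional-looking one (or vice versa) while keeping its
#' contexts.
#'
#' @param x an `ner_corpus`.
#' @param target string to replace (matched exactly).
#' @param replacement replacement string.
#' @return the perturbed `ner_corpus`.
#' @export
replace_target <- function(x, target, replacement) {
  txt <- doc_text(x)
  edits <- list()
  for (id in names(txt)) {
    g <- gregexpr(target, txt[[id]], fixed = TRUE)[[1L]]
    if (g[1L] == -1L) next
    s <- as.integer(g) - 1L
    edits[[length(edits) + 1L]] <- data.frame(
      doc_id = id, start = s, end = s + nchar(target), new = replacement,
      stringsAsFactors = FALSE)
  }
  if (length(edits) == 0L) return(x)
  splice_spans(x, do.call(rbind, edits))
}

#' Replace k abbreviation mentions with fresh pseudo entities
#'
#' Samples `k` gold mentions whose surface the abbreviation heuristic flags
#' and replaces each occurrence with a distinct, freshly generated
#' `ABBREV-NUMBER` pseudo entity ([make_pseudo_entity()]).  Other
#' occurrences of the same surface are left alone -- the edit is
#' per-mention, emulating training-set augmentation with identifier-like
#' name patterns.
#'
#' @param x an `ner_corpus` (typically the training corpus).
#' @param k how many mentions to replace.
#' @param seed RNG seed for the sampling and the generated surfaces.
#' @return list with `corpus` (perturbed) and `injected` (data.frame of
#'   doc_id/start/end/new surfaces actually placed).
#' @export
inject_pseudo_mentions <- function(x, k, seed = 1L) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  ab <- which(is_abbreviation(x$mentions$surface))
  if (length(ab) < k) {
    stop("only ", length(ab), " abbreviation mentions available; need ", k)
  }
  pick <- if (length(ab) == 1L) ab else sample(ab, k)
  news <- character(k)
  seen <- tolower(unique(x$mentions$surface))
  for (i in seq_len(k)) {
    repeat {
      w <- make_pseudo_entity(1L)
      if (!tolower(w) %in% c(seen, tolower(news))) break
    }
    news[i] <- w
  }
  edits <- data.frame(doc_id = x$mentions$doc_id[pick],
                      start = x$mentions$start[pick],
                      end = x$mentions$end[pick],
                      new = news, stringsAsFactors = FALSE)
  list(corpus = splice_spans(x, edits), injected = edits)
}

#' Shift per-word label statistics between train and test
#'
#' Takes a generated simulation and rewrites a fraction `strength` of its
#' Con-split test mentions to `"<modifier> <head>"`, where `head` is a
#' training word with a one-hot class distribution (always `B`: it only
#' occurs as a single-token mention in training).  In the rewritten test
#' usage the head word carries `I`, so its class distribution shifts
#' between train and test -- the statistical-cue failure mode the bias
#' product targets.  The rewritten mentions keep fresh concept IDs and stay
#' in the Con split; the ledger is updated.
#'
#' @param sim an `ner_sim` from [generate_corpus()].
#' @param strength fraction of Con test mentions to rewrite.
#' @param seed RNG seed.
#' @return the modified `ner_sim`.
#' @export
inject_label_bias <- function(sim, strength, seed = 1L) {
  stopifnot(inherits(sim, "ner_sim"), strength >= 0, strength <= 1)
  if (strength == 0) return(sim)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  led <- sim$ledger$mentions
  con <- which(led$split == "Con" & led$pattern != "biased")
  n <- round(strength * sum(led$split == "Con"))
  n <- min(n, length(con))
  if (n == 0L) return(sim)
  pick <- if (length(con) == 1L) con else sample(con, n)
  heads <- sim$ledger$bias_head_pool
  new_surf <- paste(sample(MODIFIERS, n, replace = TRUE),
                    sample(heads, n, replace = TRUE))
  edits <- data.frame(doc_id = led$doc_id[pick], start = led$start[pick],
                      end = led$end[pick], new = new_surf,
                      stringsAsFactors = FALSE)
  sim$test <- splice_spans(sim$test, edits)
  # refresh the rewritten ledger rows; offsets are taken back from the
  # corpus, whose row order the splice preserves
  led$surface[pick] <- new_surf
  led$pattern[pick] <- "biased"
  led$is_abbreviation[pick] <- is_abbreviation(new_surf)
  led$start <- sim$test$mentions$start
  led$end <- sim$test$mentions$end
  sim$ledger$mentions <- led
  sim$ledger$bias_words <- sim$ledger$bias_head_pool
  sim
}
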