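# Span <-> BIO conversion.  Token coordinates come from tokenize(); all
# offsets are 0-based half-open within the document (or sentence) text.

#' Convert mentions to a BIO tag sequence
#'
#' The first token of each mention is tagged `B` (or `B-<type>`), subsequent
#' tokens `I`, all others `O`.  Mentions whose boundaries do not coincide
#' with token boundaries are expanded to the smallest covering token span,
#' with a warning, so token labels stay total.
#'
#' @param tokens token table from [tokenize()].
#' @param mention_table mentions lying within the same text (same offset
#'   frame as `tokens`).
#' @param scheme a [label_scheme()].
#' @return character vector of tags, one per token.
#' @export
mentions_to_bio <- function(tokens, mention_table, scheme = label_scheme()) {
  tags <- rep("O", nrow(tokens))
  if (is.null(mention_table) || nrow(mention_table) == 0L) return(tags)
  m <- mention_table[order(mention_table$start), , drop = FALSE]
  if (nrow(m) > 1L && any(m$start[-1L] < m$end[-nrow(m)])) {
    stop("overlapping gold mentions cannot be expressed in BIO tags")
  }
  for (i in seq_len(nrow(m))) {
    cover <- which(tokens$end > m$start[i] & tokens$start < m$end[i])
    if (length(cover) == 0L) {
      warning("mention at [", m$start[i], ",", m$end[i],
              ") covers no token; skipped")
      next
    }
    if (tokens$start[cover[1L]] != m$start[i] ||
        tokens$end[cover[length(cover)]] != m$end[i]) {
      warning("mention ", dQuote(m$surface[i]),
              " not aligned to token boundaries; expanded to covering tokens")
    }
    ty <- m$entity_type[i]
    tags[cover[1L]] <- scheme_tag(scheme, "B", ty)
    if (length(cover) > 1L) {
      tags[cover[-1L]] <- scheme_tag(scheme, "I", ty)
    }
  }
  tags
}

#' Decode a BIO tag sequence into mention spans
#'
#' Maximal `B (I)*` runs become mentions; character offsets are recovered
#' from the token table.  An orphan `I` (no preceding `B` of the same type)
#' starts a new mention -- the standard lenient repair, deterministic.
#'
#' @param tokens token table from [tokenize()].
#' @param tags character vector of tags, one per token.
#' @param text the text the tokens index into (for surfaces).
#' @param doc_id document ID stamped on the result.
#' @param scheme a [label_scheme()].
#' @return a [mentions()] table with concept IDs `"UNKNOWN"`.
#' @export
bio_to_mentions <- function(tokens, tags, text, doc_id = "doc",
                            scheme = label_scheme()) {
  stopifnot(nrow(tokens) == length(tags))
  starts <- integer(0); ends <- integer(0); types <- character(0)
  cur <- NULL
  cur_type <- ""
  flush <- function() {
    if (!is.null(cur)) {
      starts <<- c(starts, tokens$start[cur[1L]])
      ends <<- c(ends, tokens$end[cur[length(cur)]])
      types <<- c(types, cur_type)
    }
    cur <<- NULL
  }
  for (i in seq_along(tags)) {
    tag <- tags[i]
    if (tag == "O") { flush(); next }
    prefix <- substr(tag, 1L, 1L)
    ty <- scheme_tag_type(scheme, tag)
    if (prefix == "B" || is.null(cur) || ty != cur_type) {
      flush()
      cur <- i
      cur_type <- ty
    } else {
      cur <- c(cur, i)
    }
  }
  flush()
  if (length(starts) == 0L) return(mentions())
  mentions(doc_id = rep(doc_id, length(starts)), start = starts, end = ends,
           surface = substr0(text, starts, ends),
           entity_type = types,
           concept_ids = rep(list("UNKNOWN"), length(starts)))
}
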