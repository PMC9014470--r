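# Readers/writers for the two corpus dialects used by BioNER benchmarks:
# PubTator (title/abstract lines plus TSV annotations) and two-column CoNLL.
# Document text is reconstructed as "title SPACE abstract", the frame in
# which PubTator annotation offsets are expressed.

#' Read a PubTator-format corpus
#'
#' Expects blocks of the form `PMID|t|title`, `PMID|a|abstract`, followed by
#' tab-separated annotation lines `PMID start end surface type concept`,
#' with blank lines between documents.  Annotation offsets are 0-based
#' half-open into `title + " " + abstract` and are verified against the
#' surface string; a mismatch is a record-level error.  Composite concept
#' fields are split on `"|"`; empty or `-1` concepts map to `"UNKNOWN"`.
#'
#' @param path file path or connection.
#' @param entity_types optional filter: keep only these types (others are
#'   dropped, as when scoring a single-type task on a multi-type corpus).
#' @param split_role stored on the corpus: `"train"`, `"dev"` or `"test"`.
#' @return an [corpus()] object.
#' @export
read_pubtator <- function(path, entity_types = NULL, split_role = "test") {
  lines <- readLines(path, warn = FALSE)
  doc_id <- character(0); title <- character(0); abstract <- character(0)
  a_doc <- character(0); a_start <- integer(0); a_end <- integer(0)
  a_surf <- character(0); a_type <- character(0); a_conc <- character(0)
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(line)) next
    tm <- regmatches(line, regexec("^([^|\t]+)\\|t\\|(.*)$", line))[[1L]]
    if (length(tm) == 3L) {
      doc_id <- c(doc_id, tm[2L]); title <- c(title, tm[3L])
      abstract <- c(abstract, "")
      next
    }
    am <- regmatches(line, regexec("^([^|\t]+)\\|a\\|(.*)$", line))[[1L]]
    if (length(am) == 3L) {
      i <- match(am[2L], doc_id)
      if (is.na(i)) stop("abstract line ", ln, " before title for ", am[2L])
      abstract[i] <- am[3L]
      next
    }
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(fields) >= 6L) {
      a_doc <- c(a_doc, fields[1L])
      a_start <- c(a_start, suppressWarnings(as.integer(fields[2L])))
      a_end <- c(a_end, suppressWarnings(as.integer(fields[3L])))
      a_surf <- c(a_surf, fields[4L])
      a_type <- c(a_type, fields[5L])
      a_conc <- c(a_conc, fields[6L])
      next
    }
    stop("malformed PubTator line ", ln, ": ", dQuote(line))
  }
  if (any(is.na(a_start)) || any(is.na(a_end))) {
    stop("non-integer offsets in annotation lines")
  }
  docs <- data.frame(doc_id = doc_id, title = title, abstract = abstract,
                     stringsAsFactors = FALSE)
  m <- mentions(a_doc, a_start, a_end, a_surf, a_type, a_conc)
  if (!is.null(entity_types)) {
    keep <- m$entity_type %in% entity_types
    m <- m[keep, , drop = FALSE]
    class(m) <- c("ner_mentions", "data.frame")
  }
  corpus(docs, m,
         entity_types = if (is.null(entity_types)) unique(m$entity_type)
                        else entity_types,
         split_role = split_role)
}

#' Write a corpus in PubTator format
#'
#' Inverse of [read_pubtator()]; `write_pubtator(read_pubtator(f))` is
#' byte-identical for well-formed input.
#'
#' @param x an `ner_corpus`.
#' @param path output file path.
#' @export
write_pubtator <- function(x, path) {
  out <- character(0)
  m <- x$mentions
  for (i in seq_len(nrow(x$docs))) {
    id <- x$docs$doc_id[i]
    out <- c(out, paste0(id, "|t|", x$docs$title[i]))
    if (nzchar(x$docs$abstract[i])) {
      out <- c(out, paste0(id, "|a|", x$docs$abstract[i]))
    }
    mi <- m[m$doc_id == id, , drop = FALSE]
    if (nrow(mi) > 0L) {
      mi <- mi[order(mi$start), , drop = FALSE]
      out <- c(out, paste(mi$doc_id, mi$start, mi$end, mi$surface,
                          mi$entity_type,
                          vapply(mi$concept_ids, paste, "", collapse = "|"),
                          sep = "\t"))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Convert a corpus to CoNLL token/tag records
#'
#' Each document becomes one CoNLL "sentence" (token TAB tag lines, blank
#' line separated).  Partitioning and scoring never depend on sentence
#' boundaries, so documents are emitted unsplit.
#'
#' @param x an `ner_corpus`.
#' @param scheme a [label_scheme()]; defaults to the corpus type set.
#' @return list of data.frames with columns `token`, `tag`, `start`, `end`
#'   (one per document, named by doc ID).
#' @export
corpus_to_conll <- function(x, scheme = label_scheme(x$entity_types)) {
  txt <- doc_text(x)
  out <- lapply(x$docs$doc_id, function(id) {
    tok <- tokenize(txt[[id]])
    mt <- x$mentions[x$mentions$doc_id == id, , drop = FALSE]
    tok$tag <- mentions_to_bio(tok, mt, scheme)
    tok[, c("token", "tag", "start", "end")]
  })
  names(out) <- x$docs$doc_id
  out
}

#' Write CoNLL two-column format
#' @param conll list of data.frames as from [corpus_to_conll()].
#' @param path output file path.
#' @export
write_conll <- function(conll, path) {
  out <- unlist(lapply(conll, function(d) {
    c(paste(d$token, d$tag, sep = "\t"), "")
  }), use.names = FALSE)
  writeLines(out, path)
  invisible(path)
}

#' Read CoNLL two-column format
#' @param path file path.
#' @return list of data.frames with columns `token`, `tag`, one element per
#'   blank-line-separated sentence.
#' @export
read_conll <- function(path) {
  lines <- readLines(path, warn = FALSE)
  grp <- cumsum(!nzchar(lines))
  keep <- nzchar(lines)
  sents <- split(lines[keep], grp[keep])
  lapply(unname(sents), function(ls) {
    parts <- strsplit(ls, "\t", fixed = TRUE)
    bad <- vapply(parts, length, 0L) < 2L
    if (any(bad)) stop("malformed CoNLL line: ", dQuote(ls[bad][1L]))
    data.frame(token = vapply(parts, `[`, "", 1L),
               tag = vapply(parts, `[`, "", 2L),
               stringsAsFactors = FALSE)
  })
}

#' Read a concept-synonym map
#'
#' Tab-separated `conceptID TAB synonym`, one pair per line, emulating a
#' MeSH/OMIM vocabulary export.
#'
#' @param path file path.
#' @return data.frame with columns `concept_id`, `synonym`.
#' @export
read_synonym_map <- function(path) {
  df <- read.table(path, sep = "\t", quote = "", comment.char = "",
                   stringsAsFactors = FALSE, col.names = c("concept_id",
                                                           "synonym"))
  df
}

#' Write a concept-synonym map
#' @param map data.frame with columns `concept_id`, `synonym`.
#' @param path output file path.
#' @export
write_synonym_map <- function(map, path) {
  write.table(map[, c("concept_id", "synonym")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
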