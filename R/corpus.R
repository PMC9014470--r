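#' @importFrom stats rnorm setNames
#' @importFrom utils head tail write.table read.table
NULL

# Character offsets are 0-based half-open throughout: a mention covers
# [start, end) of the document text.
substr0 <- function(text, start, end) substring(text, start + 1L, end)

#' Construct a mention table
#'
#' Mentions are the atomic annotation unit: a character span of a document
#' with an entity type and one or more concept identifiers (e.g. MeSH or
#' OMIM IDs).  Offsets are 0-based half-open within the full document text.
#'
#' @param doc_id character vector of document identifiers.
#' @param start,end integer character offsets, 0-based half-open.
#' @param surface mention surface strings; must equal the document text
#'   sliced at `[start, end)`.
#' @param entity_type entity type label(s), recycled.
#' @param concept_ids a list of character vectors (one per mention) or a
#'   character vector of `"|"`-separated concept IDs.  Empty or `"-1"`
#'   concepts map to the sentinel `"UNKNOWN"`.
#' @return a `data.frame` with class `ner_mentions`; `concept_ids` is a
#'   list-column of character vectors.
#' @export
mentions <- function(doc_id = character(), start = integer(), end = integer(),
                     surface = character(), entity_type = character(),
                     concept_ids = list()) {
  n <- length(doc_id)
  if (is.character(concept_ids)) {
    concept_ids <- strsplit(concept_ids, "|", fixed = TRUE)
  }
  if (length(concept_ids) == 0L && n > 0L) {
    concept_ids <- rep(list("UNKNOWN"), n)
  }
  concept_ids <- lapply(concept_ids, function(x) {
    x <- x[!is.na(x)]
    x <- x[nzchar(x)]
    x[x == "-1"] <- "UNKNOWN"
    if (length(x) == 0L) "UNKNOWN" else x
  })
  df <- data.frame(doc_id = as.character(doc_id),
                   start = as.integer(start), end = as.integer(end),
                   surface = as.character(surface),
                   entity_type = rep_len(as.character(entity_type), n),
                   stringsAsFactors = FALSE)
  df$concept_ids <- concept_ids
  if (n > 0L && any(df$end <= df$start)) {
    stop("mention with end <= start at row ",
         which(df$end <= df$start)[1L])
  }
  class(df) <- c("ner_mentions", "data.frame")
  df
}

#' Construct a corpus
#'
#' A corpus is an ordered set of documents (each with an optional
#' title/abstract division, as in PubTator) plus a mention table.  The
#' mention slice invariant -- every surface equals the document text at its
#' offsets -- is enforced at construction.
#'
#' @param docs `data.frame` with columns `doc_id`, `title`, `abstract`.
#'   The full document text is `title` + `" "` + `abstract` (title-only
#'   documents may leave `abstract` empty).
#' @param mention_table a [mentions()] table.
#' @param entity_types character vector of admissible entity types.
#' @param split_role one of `"train"`, `"dev"`, `"test"`.
#' @return an object of class `ner_corpus` with elements `docs`,
#'   `mentions`, `entity_types`, `split_role`.
#' @export
corpus <- function(docs, mention_table = mentions(),
                   entity_types = unique(mention_table$entity_type),
                   split_role = "test") {
  stopifnot(is.data.frame(docs), all(c("doc_id", "title") %in% names(docs)))
  if (is.null(docs$abstract)) docs$abstract <- ""
  docs$doc_id <- as.character(docs$doc_id)
  if (anyDuplicated(docs$doc_id)) {
    stop("duplicate document IDs: ",
         paste(unique(docs$doc_id[duplicated(docs$doc_id)]), collapse = ", "))
  }
  split_role <- match.arg(split_role, c("train", "dev", "test"))
  if (length(entity_types) == 0L) entity_types <- "Entity"
  obj <- structure(list(docs = docs[, c("doc_id", "title", "abstract")],
                        mentions = mention_table,
                        entity_types = entity_types,
                        split_role = split_role),
                   class = "ner_corpus")
  validate_corpus(obj)
  obj
}

#' Full document text of each document
#' @param x an `ner_corpus`.
#' @return named character vector (names = doc IDs).
#' @export
doc_text <- function(x) {
  txt <- ifelse(nzchar(x$docs$abstract),
                paste(x$docs$title, x$docs$abstract), x$docs$title)
  names(txt) <- x$docs$doc_id
  txt
}

#' Validate corpus invariants
#'
#' Checks document-ID uniqueness, entity-type membership and the mention
#' slice invariant (`surface == substr(text, start, end)` in 0-based
#' half-open coordinates).
#'
#' @param x an `ner_corpus`.
#' @return `x`, invisibly; stops with a record-level error message naming
#'   the document and offsets otherwise.
#' @export
validate_corpus <- function(x) {
  m <- x$mentions
  if (nrow(m) == 0L) return(invisible(x))
  unknown_doc <- !(m$doc_id %in% x$docs$doc_id)
  if (any(unknown_doc)) {
    stop("mention references unknown document ", m$doc_id[unknown_doc][1L])
  }
  bad_type <- !(m$entity_type %in% x$entity_types)
  if (any(bad_type)) {
    stop("mention entity type not in corpus type set: ",
         m$entity_type[bad_type][1L])
  }
  txt <- doc_text(x)
  slice <- substr0(txt[m$doc_id], m$start, m$end)
  bad <- slice != m$surface
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf(
      "offset/surface mismatch in document %s at [%d,%d): text has %s, annotation says %s",
      m$doc_id[i], m$start[i], m$end[i], dQuote(slice[i]), dQuote(m$surface[i])))
  }
  invisible(x)
}

#' @export
print.ner_corpus <- function(x, ...) {
  cat(sprintf("<ner_corpus: %d documents, %d mentions, types={%s}, role=%s>\n",
              nrow(x$docs), nrow(x$mentions),
              paste(x$entity_types, collapse = ","), x$split_role))
  invisible(x)
}

#' BIO label scheme
#'
#' Ordered tag classes for BIO token tagging.  With a single entity type the
#' classes are `B`, `I`, `O`; with several they are `B-<type>`, `I-<type>`
#' per type, then `O`.  `O` is always last.
#'
#' @param entity_types character vector of entity types.
#' @return object of class `label_scheme` with elements `entity_types`,
#'   `classes`, `K`.
#' @export
label_scheme <- function(entity_types = "Entity") {
  stopifnot(length(entity_types) >= 1L)
  if (length(entity_types) == 1L) {
    classes <- c("B", "I", "O")
  } else {
    classes <- c(rbind(paste0("B-", entity_types), paste0("I-", entity_types)),
                 "O")
  }
  structure(list(entity_types = entity_types, classes = classes,
                 K = length(classes)),
            class = "label_scheme")
}

scheme_tag <- function(scheme, prefix, type) {
  if (length(scheme$entity_types) == 1L) prefix else paste0(prefix, "-", type)
}

scheme_tag_type <- function(scheme, tag) {
  ifelse(tag %in% c("B", "I", "O") | tag == "O",
         scheme$entity_types[1L], sub("^[BI]-", "", tag))
}

#' Tokenize text
#'
#' Whitespace tokenization with leading/trailing punctuation split off into
#' separate one-character tokens.  Internal hyphens are kept so identifier
#' surfaces such as `COVID-19` or `MK-486` remain single tokens.
#'
#' @param text a single string.
#' @return `data.frame` with columns `start`, `end` (0-based half-open
#'   character offsets into `text`) and `token`.
#' @export
tokenize <- function(text) {
  stopifnot(length(text) == 1L)
  m <- gregexpr("\\S+", text, perl = TRUE)[[1L]]
  starts <- integer(0); ends <- integer(0)
  if (m[1L] != -1L) {
    for (i in seq_along(m)) {
      s <- as.integer(m[i]) - 1L                # 0-based
      e <- s + attr(m, "match.length")[i]
      # peel leading punctuation
      while (e - s > 1L &&
             grepl("^[[:punct:]]", substr0(text, s, s + 1L))) {
        starts <- c(starts, s); ends <- c(ends, s + 1L)
        s <- s + 1L
      }
      # peel trailing punctuation (never an internal hyphen)
      tail_s <- integer(0); tail_e <- integer(0)
      while (e - s > 1L &&
             grepl("^[[:punct:]]$", substr0(text, e - 1L, e))) {
        tail_s <- c(e - 1L, tail_s); tail_e <- c(e, tail_e)
        e <- e - 1L
      }
      starts <- c(starts, s, tail_s)
      ends <- c(ends, e, tail_e)
    }
  }
  ord <- order(starts)
  data.frame(start = starts[ord], end = ends[ord],
             token = substr0(text, starts[ord], ends[ord]),
             stringsAsFactors = FALSE)
}
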