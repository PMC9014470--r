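# Train/test overlap partitioning.  Every test mention is assigned to one
# of four buckets by whether its normalized surface and any of its concept
# IDs were seen in training:
#   (seen, seen)     -> Mem      memorization
#   (unseen, seen)   -> Syn      synonym generalization
#   (unseen, unseen) -> Con      concept generalization
#   (seen, unseen)   -> Homonym  (reported, excluded from the three splits)

SPLIT_LEVELS <- c("Mem", "Syn", "Con", "Homonym")

#' Surface normalization policy
#'
#' The membership tests are string-level, so the normalization applied to
#' both the inventory and the queries is an explicit, recorded policy:
#' case-folding and collapsing of internal whitespace by default, never
#' stemming (synonyms like Motrin/Ibuprofen must stay distinct surfaces).
#'
#' @param case_fold lower-case before comparison.
#' @param squeeze_whitespace trim and collapse runs of whitespace to one
#'   space.
#' @return object of class `norm_policy`.
#' @export
norm_policy <- function(case_fold = TRUE, squeeze_whitespace = TRUE) {
  structure(list(case_fold = case_fold,
                 squeeze_whitespace = squeeze_whitespace),
            class = "norm_policy")
}

#' Apply a normalization policy to surface strings
#' @param x character vector.
#' @param policy a [norm_policy()].
#' @return normalized character vector.
#' @export
normalize_surface <- function(x, policy = norm_policy()) {
  if (policy$squeeze_whitespace) {
    x <- gsub("\\s+", " ", trimws(x))
  }
  if (policy$case_fold) x <- tolower(x)
  x
}

#' Build the training mention/concept inventory
#'
#' Collects the set of normalized gold mention surfaces (the training
#' dictionary of surface forms) and the set of concept IDs appearing in any
#' training mention.  The sentinel `"UNKNOWN"` is never entered as a
#' concept.
#'
#' @param train_corpus an `ner_corpus` with `split_role == "train"`.
#' @param policy surface [norm_policy()].
#' @return object of class `train_inventory` with elements `surfaces`,
#'   `concepts`, `policy`.
#' @export
build_inventory <- function(train_corpus, policy = norm_policy()) {
  stopifnot(inherits(train_corpus, "ner_corpus"))
  if (train_corpus$split_role != "train") {
    stop("inventory must be built from the training corpus (split_role = 'train')")
  }
  m <- train_corpus$mentions
  if (nrow(m) == 0L) stop("empty training corpus: no mentions")
  surfaces <- sort(unique(normalize_surface(m$surface, policy)))
  concepts <- sort(unique(unlist(m$concept_ids, use.names = FALSE)))
  concepts <- setdiff(concepts, "UNKNOWN")
  structure(list(surfaces = surfaces, concepts = concepts, policy = policy),
            class = "train_inventory")
}

#' @export
print.train_inventory <- function(x, ...) {
  cat(sprintf("<train_inventory: %d surfaces, %d concepts>\n",
              length(x$surfaces), length(x$concepts)))
  invisible(x)
}

#' Assign test mentions to generalization splits
#'
#' @param mention_table a [mentions()] table.
#' @param inventory a [build_inventory()] result.
#' @param concept_rule `"any"` (default): a mention's concept is "seen" if
#'   any of its concept IDs is in the inventory; `"all"` requires all of
#'   them.  `"any"` keeps Con strictly "no known concept".
#' @return the mention table with added columns `surface_seen`,
#'   `concept_seen` (logical) and `split`
#'   (factor: Mem/Syn/Con/Homonym).
#' @export
assign_split <- function(mention_table, inventory, concept_rule = c("any", "all")) {
  concept_rule <- match.arg(concept_rule)
  m <- mention_table
  norm <- normalize_surface(m$surface, inventory$policy)
  m$surface_seen <- norm %in% inventory$surfaces
  seen_fun <- if (concept_rule == "any") any else all
  m$concept_seen <- vapply(m$concept_ids, function(ids) {
    ids <- setdiff(ids, "UNKNOWN")
    if (length(ids) == 0L) FALSE else seen_fun(ids %in% inventory$concepts)
  }, NA)
  m$split <- factor(ifelse(m$surface_seen,
                           ifelse(m$concept_seen, "Mem", "Homonym"),
                           ifelse(m$concept_seen, "Syn", "Con")),
                    levels = SPLIT_LEVELS)
  class(m) <- c("ner_mentions", "data.frame")
  m
}

#' Partition a test corpus into Mem/Syn/Con (+ Homonym) splits
#'
#' @param test_corpus an `ner_corpus`.
#' @param inventory inventory built from the paired training corpus.
#' @param concept_rule see [assign_split()].
#' @return object of class `ner_partition`: list with `assignments` (the
#'   mention table with `split` column) and `counts` (named integer vector
#'   over Mem/Syn/Con/Homonym).
#' @export
partition_corpus <- function(test_corpus, inventory,
                             concept_rule = c("any", "all")) {
  stopifnot(inherits(test_corpus, "ner_corpus"),
            inherits(inventory, "train_inventory"))
  assignments <- assign_split(test_corpus$mentions, inventory,
                              concept_rule = concept_rule)
  counts <- table(assignments$split)
  counts <- setNames(as.integer(counts), names(counts))
  structure(list(assignments = assignments, counts = counts),
            class = "ner_partition")
}

#' @export
print.ner_partition <- function(x, ...) {
  n <- sum(x$counts)
  cat("<ner_partition>\n")
  for (s in names(x$counts)) {
    cat(sprintf("  %-8s %6d  (%.1f%%)\n", s, x$counts[[s]],
                if (n > 0) 100 * x$counts[[s]] / n else 0))
  }
  invisible(x)
}

#' Write split assignments as TSV
#'
#' Columns: doc ID, start, end, surface, concepts (`|`-joined), split.
#'
#' @param partition an `ner_partition`.
#' @param path output file path.
#' @export
write_partition <- function(partition, path) {
  a <- partition$assignments
  df <- data.frame(doc_id = a$doc_id, start = a$start, end = a$end,
                   surface = a$surface,
                   concepts = vapply(a$concept_ids, paste, "", collapse = "|"),
                   split = as.character(a$split), stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read split assignments written by [write_partition()]
#' @param path TSV path.
#' @return data.frame with a `split` factor column.
#' @export
read_partition <- function(path) {
  df <- read.table(path, sep = "\t", quote = "", header = TRUE,
                   stringsAsFactors = FALSE,
                   colClasses = c("character", "integer", "integer",
                                  "character", "character", "character"))
  df$split <- factor(df$split, levels = SPLIT_LEVELS)
  df$concept_ids <- strsplit(df$concepts, "|", fixed = TRUE)
  df
}
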