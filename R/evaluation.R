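# Entity-level scoring.  A prediction is a true positive iff its
# (document, start, end, entity_type) exactly matches a gold mention,
# one-to-one.  Recall is additionally reported within the Mem/Syn/Con
# (+ Homonym) splits; false positives are never attributed to a split,
# since an invented span has no gold split to belong to.

mention_key <- function(m) {
  paste(m$doc_id, m$start, m$end, m$entity_type, sep = "\r")
}

#' Entity-level precision / recall / F1
#'
#' @param gold,pred [mentions()] tables.  Duplicate identical predictions
#'   are deduplicated with a warning.
#' @return object of class `eval_report`: list with `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1` (fractions in \[0,1\]) and
#'   `precision_defined` (`FALSE` when tp+fp = 0, in which case precision is
#'   reported as 0 rather than NaN).
#' @export
entity_prf <- function(gold, pred) {
  gk <- mention_key(gold)
  pk <- mention_key(pred)
  if (anyDuplicated(pk)) {
    warning("duplicate identical predictions deduplicated")
    pk <- unique(pk)
  }
  gk <- unique(gk)
  tp <- sum(pk %in% gk)
  fp <- length(pk) - tp
  fn <- length(gk) - tp
  precision_defined <- (tp + fp) > 0L
  p <- if (precision_defined) tp / (tp + fp) else 0
  r <- if ((tp + fn) > 0L) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = p, recall = r,
                 f1 = f1, precision_defined = precision_defined),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("P=%.1f%% R=%.1f%% F1=%.1f%%  (tp=%d fp=%d fn=%d)\n",
              100 * x$precision, 100 * x$recall, 100 * x$f1,
              x$tp, x$fp, x$fn))
  invisible(x)
}

#' Recall within each generalization split
#'
#' @param gold_assigned gold mentions carrying a `split` column (from
#'   [assign_split()] / [partition_corpus()]).
#' @param pred predicted mentions.
#' @return data.frame with one row per split: `split`, `n` (gold size),
#'   `hits`, `recall` (NA for empty splits).
#' @export
split_recall <- function(gold_assigned, pred) {
  if (is.null(gold_assigned$split) || anyNA(gold_assigned$split)) {
    stop("every gold mention needs a split assignment")
  }
  pk <- unique(mention_key(pred))
  hit <- mention_key(gold_assigned) %in% pk
  out <- data.frame(split = SPLIT_LEVELS, n = 0L, hits = 0L,
                    recall = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(SPLIT_LEVELS)) {
    sel <- gold_assigned$split == SPLIT_LEVELS[i]
    out$n[i] <- sum(sel)
    out$hits[i] <- sum(hit[sel])
    if (out$n[i] > 0L) out$recall[i] <- out$hits[i] / out$n[i]
  }
  out
}

#' Relaxed (containment) recall for a target string
#'
#' Locates every occurrence of `target` in the document texts; an
#' occurrence is a true positive iff some predicted span's character range
#' contains the occurrence's range (equality included).  Counting is per
#' occurrence: a document with two occurrences contributes two units.
#'
#' @param x an `ner_corpus` (supplies the document texts).
#' @param pred predicted mentions.
#' @param target the target surface string (matched exactly, not as regex).
#' @return list with `n_occurrences`, `hits`, `recall`.
#' @export
relaxed_recall <- function(x, pred, target) {
  txt <- doc_text(x)
  occ_doc <- character(0); occ_s <- integer(0); occ_e <- integer(0)
  for (id in names(txt)) {
    m <- gregexpr(target, txt[[id]], fixed = TRUE)[[1L]]
    if (m[1L] == -1L) next
    s <- as.integer(m) - 1L
    occ_doc <- c(occ_doc, rep(id, length(s)))
    occ_s <- c(occ_s, s)
    occ_e <- c(occ_e, s + nchar(target))
  }
  if (length(occ_s) == 0L) {
    stop("target string ", dQuote(target), " does not occur; metric undefined")
  }
  hits <- vapply(seq_along(occ_s), function(i) {
    sel <- pred$doc_id == occ_doc[i] &
      pred$start <= occ_s[i] & pred$end >= occ_e[i]
    any(sel)
  }, NA)
  list(n_occurrences = length(occ_s), hits = sum(hits),
       recall = sum(hits) / length(occ_s))
}

#' Abbreviation heuristic
#'
#' A surface is flagged as an abbreviation iff it is a single token
#' (no whitespace), has length >= 2, contains no lowercase letters and at
#' least one uppercase letter (digits and hyphens allowed): `ANT-MI` and
#' `COVID-19` qualify, `anterior infarction` does not.  The criterion is a
#' declared heuristic, configurable via the `detector` argument of
#' [abbreviation_recall()].
#'
#' @param surface character vector.
#' @return logical vector.
#' @export
is_abbreviation <- function(surface) {
  !grepl("\\s", surface) & nchar(surface) >= 2L &
    !grepl("[a-z]", surface) & grepl("[A-Z]", surface)
}

#' Recall on abbreviation mentions of the Con split
#'
#' @param gold_assigned gold mentions with a `split` column.
#' @param pred predicted mentions.
#' @param detector function flagging abbreviation surfaces; defaults to
#'   [is_abbreviation()].
#' @return list with `n_con` (Con split size), `n_abbrev` (flagged Con
#'   mentions), `abbrev_fraction`, `hits` and `recall` (`NA` when no Con
#'   mention is flagged -- the metric is then undefined).
#' @export
abbreviation_recall <- function(gold_assigned, pred,
                                detector = is_abbreviation) {
  if (is.null(gold_assigned$split)) {
    stop("every gold mention needs a split assignment")
  }
  con <- gold_assigned[gold_assigned$split == "Con", , drop = FALSE]
  flagged <- detector(con$surface)
  n_ab <- sum(flagged)
  res <- list(n_con = nrow(con), n_abbrev = n_ab,
              abbrev_fraction = if (nrow(con) > 0L) n_ab / nrow(con) else NA_real_,
              hits = NA_integer_, recall = NA_real_)
  if (n_ab == 0L) return(res)
  pk <- unique(mention_key(pred))
  hits <- sum(mention_key(con[flagged, , drop = FALSE]) %in% pk)
  res$hits <- hits
  res$recall <- hits / n_ab
  res
}
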