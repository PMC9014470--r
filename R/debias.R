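# Statistics-based bias product.  The "biased model" is nothing but the
# per-word tag-class frequency table of the training set: for word w and
# class k, b_k(w) = count(w tagged k) / count(w).  During training the
# original model's per-token distribution p is combined with the fixed b as
#   p_hat = softmax(log p + log b)  =  (p * b) / sum(p * b)
# and the negative log-likelihood of p_hat is minimized; gradients flow only
# through p.  At inference only p is used.  Words with a one-hot class
# distribution therefore contribute almost no training signal, which stops
# the model from memorizing per-word label statistics.

#' Per-word class-distribution table (the biased model)
#'
#' Counts, for every normalized word of the training token stream, how often
#' it carries each tag class, and converts the counts to a probability row.
#' Exact zeros (single-class words) are floored at `epsilon` and the row is
#' renormalized, so `log b` is always finite.  Unseen words get the uniform
#' row `1/K` (no signal).
#'
#' @param conll list of token/tag data.frames (see [corpus_to_conll()] /
#'   [read_conll()]).
#' @param scheme a [label_scheme()]; its `classes` fix the column order.
#' @param epsilon flooring constant, default `1e-6`.
#' @param case_fold normalize words by lower-casing (must match the tagger
#'   vocabulary normalization).
#' @return object of class `bias_table`: list with `rows` (matrix, words x
#'   K), `classes`, `default_row`, `epsilon`.
#' @export
compute_bias_table <- function(conll, scheme = label_scheme(),
                               epsilon = 1e-6, case_fold = TRUE) {
  tok <- unlist(lapply(conll, `[[`, "token"), use.names = FALSE)
  tag <- unlist(lapply(conll, `[[`, "tag"), use.names = FALSE)
  if (length(tok) == 0L) stop("empty training corpus: no tokens")
  if (!all(tag %in% scheme$classes)) {
    stop("tag outside the label scheme: ",
         dQuote(setdiff(tag, scheme$classes)[1L]))
  }
  if (case_fold) tok <- tolower(tok)
  counts <- table(factor(tok), factor(tag, levels = scheme$classes))
  rows <- unclass(counts) / rowSums(counts)
  rows <- pmax(rows, epsilon)
  rows <- rows / rowSums(rows)
  dimnames(rows) <- list(rownames(counts), scheme$classes)
  structure(list(rows = rows, classes = scheme$classes,
                 default_row = rep(1 / scheme$K, scheme$K),
                 epsilon = epsilon, case_fold = case_fold),
            class = "bias_table")
}

#' Look up bias rows for a word vector
#' @param bt a `bias_table`.
#' @param words character vector (normalized with the table's policy
#'   internally).
#' @return matrix (length(words) x K); unseen words get the uniform default.
#' @export
bias_rows <- function(bt, words) {
  if (bt$case_fold) words <- tolower(words)
  idx <- match(words, rownames(bt$rows))
  out <- matrix(bt$default_row, nrow = length(words), ncol = length(bt$classes),
                byrow = TRUE, dimnames = list(NULL, bt$classes))
  hit <- !is.na(idx)
  out[hit, ] <- bt$rows[idx[hit], , drop = FALSE]
  out
}

#' Bias-product combination of two distributions
#'
#' `softmax(log p + log b)`, i.e. the elementwise product renormalized:
#' `p_hat_k = p_k b_k / sum_j p_j b_j`.  With a uniform `b` this is exactly
#' the identity.  Operates rowwise when given matrices.
#'
#' @param p,b probability vectors of length K, or matrices with K columns
#'   (rows are tokens).  Must be strictly positive (the bias table's epsilon
#'   flooring guarantees this for `b`).
#' @return combined distribution, same shape as `p`.
#' @export
combine_bias <- function(p, b) {
  if (is.null(dim(p))) {
    z <- p * b
    s <- sum(z)
    if (s <= 0) stop("zero product distribution; inputs must be positive")
    return(z / s)
  }
  z <- p * b
  s <- rowSums(z)
  if (any(s <= 0)) stop("zero product distribution; inputs must be positive")
  z / s
}

#' Debiased negative log-likelihood
#'
#' `-log p_hat[gold]` with `p_hat = combine_bias(p, b)`.  When the bias
#' already assigns the gold class more than `1/K`, this loss (and its
#' gradient with respect to `p`) is smaller than the plain NLL `-log
#' p[gold]` -- skewed words are down-weighted during training.
#'
#' @param p,b probability vectors (length K) or matrices (tokens x K).
#' @param gold_class 1-based gold class index (vector for matrices).
#' @return scalar loss, summed over tokens for matrix input.
#' @export
debiased_loss <- function(p, b, gold_class) {
  ph <- combine_bias(p, b)
  if (is.null(dim(ph))) return(-log(ph[gold_class]))
  -sum(log(ph[cbind(seq_len(nrow(ph)), gold_class)]))
}

#' Write a bias table as TSV (`word TAB p_class1 TAB ...`)
#' @param bt a `bias_table`.
#' @param path output file path.
#' @export
write_bias_table <- function(bt, path) {
  df <- data.frame(word = rownames(bt$rows), bt$rows, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a bias table written by [write_bias_table()]
#' @param path TSV path.
#' @param epsilon,case_fold stored on the result (must match how the table
#'   was produced).
#' @return a `bias_table`.
#' @export
read_bias_table <- function(path, epsilon = 1e-6, case_fold = TRUE) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  rows <- as.matrix(df[, -1L, drop = FALSE])
  rownames(rows) <- df$word
  structure(list(rows = rows, classes = colnames(rows),
                 default_row = rep(1 / ncol(rows), ncol(rows)),
                 epsilon = epsilon, case_fold = case_fold),
            class = "bias_table")
}
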