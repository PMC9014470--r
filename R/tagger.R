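# Reference tagger: a linear-softmax token classifier over sparse indicator
# features, trained by full-batch gradient descent.  It is a desk-scale
# stand-in for large pretrained taggers: strong enough to memorize word
# identities and to exploit context cues, which is exactly the behaviour the
# bias-product debiasing targets.  External taggers can instead plug in via
# per-token probability matrices (see token_distributions() for the
# expected shape).

FEAT_START <- "<S>"
FEAT_END <- "</S>"

token_shape_features <- function(token) {
  f <- character(0)
  if (grepl("[0-9]", token)) f <- c(f, "has_digit")
  if (grepl("-", token, fixed = TRUE)) f <- c(f, "has_hyphen")
  if (!grepl("[a-z]", token) && grepl("[A-Z]", token)) f <- c(f, "all_caps")
  if (grepl("^[A-Z]", token)) f <- c(f, "init_cap")
  f
}

# One character-vector of feature names per token.  Word-identity features
# are case-folded; shape features look at the raw token.
token_features <- function(tokens) {
  lc <- tolower(tokens)
  n <- length(tokens)
  prev <- c(FEAT_START, lc[-n])
  nxt <- c(lc[-1L], FEAT_END)
  lapply(seq_len(n), function(i) {
    tk <- tokens[i]
    c("BIAS",
      paste0("w=", lc[i]),
      paste0("p=", prev[i]),
      paste0("n=", nxt[i]),
      paste0("s2=", substr(lc[i], max(1L, nchar(lc[i]) - 1L), nchar(lc[i]))),
      paste0("s3=", substr(lc[i], max(1L, nchar(lc[i]) - 2L), nchar(lc[i]))),
      token_shape_features(tk))
  })
}

feature_matrix <- function(feat_list, vocab) {
  idx <- lapply(feat_list, function(f) {
    i <- match(unique(f), vocab)
    i[!is.na(i)]
  })
  rows <- rep(seq_along(idx), lengths(idx))
  Matrix::sparseMatrix(i = rows, j = unlist(idx), x = 1,
                       dims = c(length(feat_list), length(vocab)))
}

row_softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Train the reference tagger
#'
#' Fits a multinomial logistic regression over token indicator features
#' (word identity, neighbouring words, digit/caps/hyphen shape flags,
#' suffix bigrams/trigrams) by full-batch gradient descent.  When a
#' [compute_bias_table()] is supplied, training minimizes the debiased loss
#' `-log softmax(log p + log b)[gold]`: the fixed bias row enters the
#' per-token logits, gradients flow only through the model, and the bias
#' table itself is never modified.  Inference ([predict_tags()]) always uses
#' the model distribution alone.
#'
#' @param train_corpus training `ner_corpus`.
#' @param scheme a [label_scheme()].
#' @param seed integer; initial weights are drawn `N(0, 0.01)` under this
#'   seed, so training is bitwise reproducible.
#' @param bias_table optional `bias_table` enabling debiased training.
#' @param epochs,learning_rate,l2 optimizer settings.
#' @return object of class `ref_tagger` with the weight matrix, feature
#'   vocabulary and class order.
#' @export
train_tagger <- function(train_corpus, scheme = label_scheme(train_corpus$entity_types),
                         seed = 1L, bias_table = NULL, epochs = 400L,
                         learning_rate = 4, l2 = 1e-4) {
  conll <- corpus_to_conll(train_corpus, scheme)
  feat_list <- list(); tags <- character(0); words <- character(0)
  for (d in conll) {
    feat_list <- c(feat_list, token_features(d$token))
    tags <- c(tags, d$tag)
    words <- c(words, d$token)
  }
  n <- length(tags)
  if (n == 0L) stop("empty training corpus: no tokens")
  vocab <- sort(unique(unlist(feat_list, use.names = FALSE)))
  X <- feature_matrix(feat_list, vocab)
  K <- scheme$K
  y <- match(tags, scheme$classes)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), y)] <- 1
  logB <- if (!is.null(bias_table)) log(bias_rows(bias_table, words)) else NULL

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  W <- matrix(rnorm(length(vocab) * K, sd = 0.01), length(vocab), K)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())

  for (ep in seq_len(epochs)) {
    Z <- as.matrix(X %*% W)
    P <- row_softmax(if (is.null(logB)) Z else Z + logB)
    G <- as.matrix(Matrix::crossprod(X, P - Y)) / n + l2 * W
    W <- W - learning_rate * G
  }
  structure(list(W = W, vocab = vocab, classes = scheme$classes,
                 scheme = scheme, debiased = !is.null(bias_table),
                 seed = seed, epochs = epochs,
                 learning_rate = learning_rate, l2 = l2),
            class = "ref_tagger")
}

#' @export
print.ref_tagger <- function(x, ...) {
  cat(sprintf("<ref_tagger: %d features, K=%d, %s, seed=%d>\n",
              length(x$vocab), length(x$classes),
              if (x$debiased) "debias-trained" else "plain NLL", x$seed))
  invisible(x)
}

#' Per-token class distributions of the reference tagger
#'
#' The model distribution `p` alone -- no bias combination (the contract for
#' inference).  This is also the shape external taggers must provide to
#' reuse the evaluation stack: one row per token, one column per class.
#'
#' @param model a `ref_tagger`.
#' @param tokens character vector of tokens (one sentence/document).
#' @return matrix `length(tokens) x K` of probabilities.
#' @export
token_distributions <- function(model, tokens) {
  X <- feature_matrix(token_features(tokens), model$vocab)
  P <- row_softmax(as.matrix(X %*% model$W))
  colnames(P) <- model$classes
  P
}

#' Predict mentions for a corpus
#'
#' Argmax of the model distribution per token, then BIO decoding into
#' mention spans.  By contract the prediction is invariant to whatever bias
#' table was used during training.
#'
#' @param model a `ref_tagger`.
#' @param x an `ner_corpus`.
#' @return a [mentions()] table of predictions.
#' @export
predict_tags <- function(model, x) {
  txt <- doc_text(x)
  preds <- lapply(x$docs$doc_id, function(id) {
    tok <- tokenize(txt[[id]])
    if (nrow(tok) == 0L) return(NULL)
    P <- token_distributions(model, tok$token)
    tags <- model$classes[max.col(P, ties.method = "first")]
    m <- bio_to_mentions(tok, tags, txt[[id]], id, model$scheme)
    if (nrow(m) == 0L) NULL else m
  })
  preds <- preds[!vapply(preds, is.null, NA)]
  if (length(preds) == 0L) return(mentions())
  out <- do.call(rbind, preds)
  class(out) <- c("ner_mentions", "data.frame")
  out
}
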